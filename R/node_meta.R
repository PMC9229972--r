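#' Node metadata for typed trio-omics networks
#'
#' Every variable entering a network is a typed node.  Types follow the
#' maternal/newborn convention: `MG`/`NG` maternal/newborn genotype (SNP
#' dosage), `MM`/`NM` maternal/newborn (cord blood) metabolite, `MP`/`NP`
#' maternal/newborn phenotype.  SNP nodes must carry a chromosome label so
#' that the cross-chromosome SNP-to-SNP edge rule of the blocklist can be
#' evaluated.
#'
#' @param node_id character vector of unique node identifiers.
#' @param node_type one of `"MG"`, `"MM"`, `"MP"`, `"NG"`, `"NM"`, `"NP"`
#'   (recycled if length 1).
#' @param timepoint `"fasting"`, `"1hr"`, `"cord"` or `"none"`.
#' @param chromosome chromosome label for SNP nodes, `NA` otherwise.
#' @param metabolite_class metabolite compound class (`"AA"`, `"AC"`,
#'   `"CHO"`, `"FA"`, `"GC/TCA"`, `"OA"`, `"PUR/PYR"`, `"other"`) or `NA`.
#' @param role `"exposure"`, `"outcome"` or `"intermediate"`.
#'
#' @return a tibble with one row per node and columns `node_id`,
#'   `node_type`, `timepoint`, `chromosome`, `metabolite_class`, `role`.
#' @export
#' @examples
#' node_meta(c("rs1", "glycine"), c("MG", "MM"),
#'           timepoint = c("none", "fasting"), chromosome = c("2", NA))
node_meta <- function(node_id, node_type,
                      timepoint = "none",
                      chromosome = NA_character_,
                      metabolite_class = NA_character_,
                      role = "intermediate") {
  meta <- tibble(
    node_id = as.character(node_id),
    node_type = as.character(node_type),
    timepoint = as.character(timepoint),
    chromosome = as.character(chromosome),
    metabolite_class = as.character(metabolite_class),
    role = as.character(role)
  )
  validate_node_meta(meta)
}

node_types <- function() c("MG", "MM", "MP", "NG", "NM", "NP")
snp_types <- function() c("MG", "NG")
maternal_types <- function() c("MG", "MM", "MP")
metabolite_classes <- function() {
  c("AA", "AC", "CHO", "FA", "GC/TCA", "OA", "PUR/PYR", "other")
}

#' Validate a node metadata table
#'
#' @param meta a data frame as produced by [node_meta()].
#' @return the validated tibble, invisibly coerced.
#' @export
validate_node_meta <- function(meta) {
  meta <- as_tibble(meta)
  need <- c("node_id", "node_type", "timepoint", "chromosome",
            "metabolite_class", "role")
  miss <- setdiff(need, names(meta))
  if (length(miss)) abort(paste0("meta lacks columns: ", paste(miss, collapse = ", ")))
  if (nrow(meta) == 0L) abort("meta must contain at least one node")
  if (anyDuplicated(meta$node_id)) {
    abort(paste0("duplicated node ids: ",
                 paste(unique(meta$node_id[duplicated(meta$node_id)]), collapse = ", ")))
  }
  if (!all(meta$node_type %in% node_types())) {
    abort("node_type must be one of MG, MM, MP, NG, NM, NP")
  }
  if (!all(meta$timepoint %in% c("fasting", "1hr", "cord", "none"))) {
    abort("timepoint must be one of fasting, 1hr, cord, none")
  }
  if (!all(meta$role %in% c("exposure", "outcome", "intermediate"))) {
    abort("role must be one of exposure, outcome, intermediate")
  }
  snp <- meta$node_type %in% snp_types()
  if (any(snp & is.na(meta$chromosome))) {
    abort("SNP nodes (MG, NG) must have a chromosome label")
  }
  ok_class <- is.na(meta$metabolite_class) |
    meta$metabolite_class %in% metabolite_classes()
  if (!all(ok_class)) abort("unknown metabolite_class")
  meta
}
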