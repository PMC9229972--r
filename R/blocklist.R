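#' Build the typed-edge blocklist
#'
#' Structure search over trio-omics nodes is constrained a priori by a
#' blocklist that encodes biological ordering: metabolites and phenotypes
#' cannot cause genotypes, offspring features cannot cause maternal
#' upstream features, and SNP-to-SNP edges may only connect SNPs on the
#' same chromosome.  Eleven rules are encoded: the ten forbidden ordered
#' node-type pairs
#' `NG->MG`, `NP->MG`, `NM->MG`, `NG->MP`, `NG->MM`, `NP->NG`, `NM->NG`,
#' `MP->NG`, `MM->MG`, `MM->NG`, plus the cross-chromosome rule that
#' forbids edges between SNPs on different chromosomes.  Every other
#' directed type pair is permitted.
#'
#' @param meta node metadata ([node_meta()]); used for validation and to
#'   precompute the per-node-pair allowed matrix.
#' @param extra_rules optional data frame with columns `from_type`,
#'   `to_type` of additional forbidden ordered type pairs.
#'
#' @return an object of class `blocklist` holding the forbidden type-pair
#'   table and the cross-chromosome predicate.
#' @export
#' @examples
#' meta <- node_meta(c("rs1", "ac_c2"), c("NG", "MM"),
#'                   chromosome = c("2", NA))
#' bl <- build_blocklist(meta)
#' edge_blocked(bl, "rs1", "ac_c2", meta)  # offspring SNP -> maternal metabolite
build_blocklist <- function(meta, extra_rules = NULL) {
  meta <- validate_node_meta(meta)
  rules <- tibble(
    from_type = c("NG", "NP", "NM", "NG", "NG", "NP", "NM", "MP", "MM", "MM"),
    to_type   = c("MG", "MG", "MG", "MP", "MM", "NG", "NG", "NG", "MG", "NG")
  )
  if (!is.null(extra_rules)) {
    extra_rules <- as_tibble(extra_rules)[, c("from_type", "to_type")]
    rules <- distinct(bind_rows(rules, extra_rules))
  }
  structure(
    list(
      forbidden_type_rules = rules,
      extra_predicates = list(
        cross_chromosome_snp = function(from_meta, to_meta) {
          from_meta$node_type %in% snp_types() &
            to_meta$node_type %in% snp_types() &
            !is.na(from_meta$chromosome) & !is.na(to_meta$chromosome) &
            from_meta$chromosome != to_meta$chromosome
        }
      )
    ),
    class = "blocklist"
  )
}

#' Query whether directed edges are blocked
#'
#' Direction-specific and deterministic: `edge_blocked(bl, a, b)` answers
#' for the edge a -> b only.
#'
#' @param blocklist a [build_blocklist()] object.
#' @param from,to node ids (vectors of equal length, recycled).
#' @param meta node metadata containing all queried nodes.
#' @return logical vector, `TRUE` where the directed edge is forbidden.
#' @export
edge_blocked <- function(blocklist, from, to, meta) {
  stopifnot(inherits(blocklist, "blocklist"))
  meta <- validate_node_meta(meta)
  idx_f <- match(from, meta$node_id)
  idx_t <- match(to, meta$node_id)
  if (anyNA(idx_f) || anyNA(idx_t)) {
    abort(paste0("unknown node id(s): ",
                 paste(unique(c(from[is.na(idx_f)], to[is.na(idx_t)])), collapse = ", ")))
  }
  fm <- meta[idx_f, ]
  tm <- meta[idx_t, ]
  key <- paste(fm$node_type, tm$node_type, sep = "->")
  rule_key <- paste(blocklist$forbidden_type_rules$from_type,
                    blocklist$forbidden_type_rules$to_type, sep = "->")
  blocked <- key %in% rule_key
  for (pred in blocklist$extra_predicates) {
    blocked <- blocked | pred(fm, tm)
  }
  blocked
}

# p x p logical matrix, allowed[i, j] == TRUE iff edge node_i -> node_j
# is permitted by the blocklist (diagonal always FALSE).
allowed_edge_matrix <- function(blocklist, meta) {
  meta <- validate_node_meta(meta)
  p <- nrow(meta)
  from <- rep(meta$node_id, times = p)
  to <- rep(meta$node_id, each = p)
  blocked <- edge_blocked(blocklist, from, to, meta)
  m <- matrix(!blocked, p, p, dimnames = list(meta$node_id, meta$node_id))
  diag(m) <- FALSE
  m
}

# Ordered type pairs not fully forbidden by the type rules (the tally rows
# of edge summaries).  The cross-chromosome predicate only partially
# restricts SNP-SNP pairs, so those pairs remain.
allowed_type_pairs <- function(blocklist) {
  all_pairs <- tidyr::expand_grid(from_type = node_types(), to_type = node_types())
  dplyr::anti_join(all_pairs, blocklist$forbidden_type_rules,
                   by = c("from_type", "to_type"))
}

#' @export
print.blocklist <- function(x, ...) {
  cat("<blocklist>", nrow(x$forbidden_type_rules), "forbidden type pairs +",
      length(x$extra_predicates), "predicate(s)\n")
  print(x$forbidden_type_rules, n = Inf)
  invisible(x)
}
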