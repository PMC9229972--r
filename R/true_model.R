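#' Ground-truth generative model for synthetic trio cohorts
#'
#' A `true_model` is a linear-Gaussian structural model over typed nodes:
#' each non-genotype node is generated in topological order as
#' `intercept + sum(coef * parent) + Normal(0, noise_sd)`.  Genotype nodes
#' are generated genetically: maternal SNP dosages are Binomial(2, maf)
#' under Hardy-Weinberg equilibrium, and a newborn SNP whose parent edge
#' comes from a maternal SNP receives one allele sampled uniformly from
#' the mother's two alleles plus one paternal allele drawn at the
#' population frequency.  For such transmission edges the stored
#' coefficient is the implied regression of offspring on maternal dosage,
#' 0.5, used by covariance calculations and by [true_serial_ide()].
#'
#' The model graph must be acyclic and must respect the same blocklist
#' used for structure learning: ground truth never violates the stated
#' biological ordering.
#'
#' @param nodes node metadata ([node_meta()]).
#' @param edges data frame with columns `from`, `to`, `coef`.
#' @param noise_sd named numeric, residual standard deviation per
#'   non-genotype node (all > 0, or 0 for deterministic children).
#' @param intercepts optional named numeric, default 0.
#' @param maf named numeric in (0, 0.5], one entry per SNP node.
#'
#' @return an object of class `true_model`.
#' @seealso [simulate_cohort()], [example_true_model()],
#'   [trio_benchmark_model()]
#' @export
true_model <- function(nodes, edges, noise_sd, intercepts = NULL, maf = NULL) {
  nodes <- validate_node_meta(nodes)
  edges <- as_tibble(edges)
  stopifnot(all(c("from", "to", "coef") %in% names(edges)))
  if (!all(c(edges$from, edges$to) %in% nodes$node_id)) {
    abort("edge endpoints must be node ids")
  }
  if (anyDuplicated(edges[, c("from", "to")])) abort("duplicated edges")

  g <- igraph::graph_from_data_frame(edges[, c("from", "to")],
                                     vertices = nodes$node_id)
  if (!igraph::is_dag(g)) abort("model graph must be acyclic")

  bl <- build_blocklist(nodes)
  bad <- edge_blocked(bl, edges$from, edges$to, nodes)
  if (any(bad)) {
    abort(paste0("ground-truth edges violate the blocklist: ",
                 paste(paste(edges$from[bad], edges$to[bad], sep = "->"),
                       collapse = ", ")))
  }

  snp <- nodes$node_id[nodes$node_type %in% snp_types()]
  non_snp <- setdiff(nodes$node_id, snp)
  if (length(snp)) {
    maf <- maf[snp]
    if (length(maf) != length(snp) || anyNA(maf)) {
      abort("maf must be a named vector covering every SNP node")
    }
    if (any(maf <= 0 | maf > 0.5)) abort("maf must lie in (0, 0.5]")
  } else {
    maf <- setNames(numeric(0), character(0))
  }

  noise_sd <- noise_sd[non_snp]
  if (length(non_snp) && (length(noise_sd) != length(non_snp) || anyNA(noise_sd))) {
    abort("noise_sd must be a named vector covering every non-genotype node")
  }
  if (any(noise_sd < 0)) abort("noise_sd must be non-negative")
  roots <- setdiff(non_snp, edges$to)
  if (any(noise_sd[roots] <= 0)) abort("root nodes must have noise_sd > 0")

  ic <- setNames(rep(0, nrow(nodes)), nodes$node_id)
  if (!is.null(intercepts)) ic[names(intercepts)] <- intercepts

  structure(
    list(nodes = nodes, edges = edges, noise_sd = noise_sd,
         intercepts = ic, maf = maf),
    class = "true_model"
  )
}

#' @export
print.true_model <- function(x, ...) {
  cat("<true_model>", nrow(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  invisible(x)
}

#' Seven-node illustrative trio model
#'
#' A small packaged generative model with two maternal genotypes (`MG1`,
#' `MG2`), one fetal genotype at the `MG1` locus (`FG1`), two maternal
#' fasting metabolites (`MMa`, `MMb`) and two cord-blood metabolites
#' (`FMc`, `FMd`).  All drawn structural edges carry coefficient `coef`
#' (default 0.8); the `MG1 -> FG1` edge is Mendelian transmission (implied
#' linear coefficient 0.5).
#'
#' @param coef structural coefficient on each non-transmission edge.
#' @return a [true_model()].
#' @export
example_true_model <- function(coef = 0.8) {
  nodes <- node_meta(
    node_id = c("MG1", "MG2", "FG1", "MMa", "MMb", "FMc", "FMd"),
    node_type = c("MG", "MG", "NG", "MM", "MM", "NM", "NM"),
    timepoint = c("none", "none", "none", "fasting", "fasting", "cord", "cord"),
    chromosome = c("2", "10", "2", NA, NA, NA, NA),
    metabolite_class = c(NA, NA, NA, "AA", "AC", "AA", "AC")
  )
  edges <- tibble(
    from = c("MG1", "MG1", "MG2", "MMa", "MMa", "FG1", "MMb"),
    to   = c("FG1", "MMa", "MMb", "MMb", "FMc", "FMd", "FMd"),
    coef = c(0.5, rep(coef, 6))
  )
  true_model(
    nodes, edges,
    noise_sd = c(MMa = 1, MMb = 1, FMc = 1, FMd = 1),
    maf = c(MG1 = 0.3, MG2 = 0.4, FG1 = 0.3)
  )
}

#' Twelve-node structure-recovery benchmark model
#'
#' A typed trio model whose DAG is fully identifiable from observational
#' Gaussian data under the blocklist: every edge is either
#' blocklist-forced (its reversal is a forbidden type pair) or compelled
#' by an unshielded collider.  Used for structure-recovery benchmarks of
#' the penalized network learner.
#'
#' @param coef absolute structural coefficient on non-transmission edges
#'   (default 0.8); a subset of edges is negated to mix signs.
#' @return a [true_model()].
#' @export
trio_benchmark_model <- function(coef = 0.8) {
  nodes <- node_meta(
    node_id = c("MG1", "MG2", "NG1", "MM1", "MM2", "MM3", "MP1",
                "NM1", "NM2", "NM3", "NP1", "NP2"),
    node_type = c("MG", "MG", "NG", "MM", "MM", "MM", "MP",
                  "NM", "NM", "NM", "NP", "NP"),
    timepoint = c("none", "none", "none", "fasting", "fasting", "fasting",
                  "none", "cord", "cord", "cord", "none", "none"),
    chromosome = c("2", "10", "2", NA, NA, NA, NA, NA, NA, NA, NA, NA),
    metabolite_class = c(NA, NA, NA, "AA", "AC", "OA", NA, "AA", "AC", "FA",
                         NA, NA),
    role = c(rep("intermediate", 6), "exposure", "intermediate",
             "intermediate", "intermediate", "outcome", "outcome")
  )
  edges <- tibble(
    from = c("MG1", "MG1", "MG2", "MG2", "MP1", "MM1", "NG1",
             "MM2", "MM3", "NM1", "NM2", "NM2", "NM3"),
    to   = c("NG1", "MM1", "MM2", "MM3", "MM3", "NM1", "NM1",
             "NM2", "NM2", "NP1", "NP1", "NM3", "NP2"),
    coef = c(0.5, coef, -coef, coef, coef, coef, coef,
             -coef, coef, coef, -coef, coef, coef)
  )
  nm <- setdiff(nodes$node_id, c("MG1", "MG2", "NG1"))
  true_model(nodes, edges,
             noise_sd = setNames(rep(1, length(nm)), nm),
             maf = c(MG1 = 0.3, MG2 = 0.4, NG1 = 0.3))
}

#' Serial indirect effect implied by the generative model
#'
#' Product of the model coefficients along an ordered node path; the
#' ground-truth oracle for serial-mediation benchmarks.
#'
#' @param model a [true_model()].
#' @param path ordered character vector of node ids; each consecutive pair
#'   must be an edge of the model DAG.
#' @return the product of coefficients along the path (a scalar).
#' @export
#' @examples
#' m <- example_true_model()
#' true_serial_ide(m, c("MG1", "MMa", "FMc"))
true_serial_ide <- function(model, path) {
  stopifnot(inherits(model, "true_model"), length(path) >= 2L)
  key <- paste(model$edges$from, model$edges$to, sep = "->")
  steps <- paste(path[-length(path)], path[-1L], sep = "->")
  hit <- match(steps, key)
  if (anyNA(hit)) {
    abort(paste0("path step(s) not edges of the model: ",
                 paste(steps[is.na(hit)], collapse = ", ")))
  }
  prod(model$edges$coef[hit])
}

#' Write a generative model to GraphML and JSON
#'
#' @param model a [true_model()].
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
write_true_model <- function(model, dir) {
  stopifnot(inherits(model, "true_model"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  g <- igraph::graph_from_data_frame(
    transform(model$edges, weight = coef)[, c("from", "to", "weight")],
    vertices = as.data.frame(model$nodes)
  )
  f_graphml <- file.path(dir, "true_model.graphml")
  igraph::write_graph(g, f_graphml, format = "graphml")
  f_json <- file.path(dir, "true_model.json")
  jsonlite::write_json(
    list(nodes = model$nodes, edges = model$edges,
         noise_sd = as.list(model$noise_sd),
         intercepts = as.list(model$intercepts),
         maf = as.list(model$maf)),
    f_json, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(c(graphml = f_graphml, json = f_json))
}
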