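# Solution-path reporting: edge tallies by node-type pair, first
# occurrence of edge classes, per-lambda frame export, and light
# metabolite preprocessing.

#' Tally network edges by ordered node-type pair
#'
#' Counts edges per ordered (parent type, child type) pair, with the
#' percentage of the total edge count.  Rows cover exactly the type pairs
#' not fully forbidden by the blocklist; pairs without edges report 0.
#'
#' @param dag a `weighted_dag`.
#' @param meta node metadata; defaults to the dag's own.
#' @return tibble with `from_type`, `to_type`, `count`, `percent` and a
#'   `lambda` column.
#' @export
tally_edges_by_type <- function(dag, meta = NULL) {
  meta <- validate_node_meta(meta %||% dag$nodes)
  if (nrow(dag$edges) &&
      !all(c(dag$edges$from, dag$edges$to) %in% meta$node_id)) {
    abort("edge endpoints missing from meta")
  }
  rows <- allowed_type_pairs(build_blocklist(meta))
  ft <- meta$node_type[match(dag$edges$from, meta$node_id)]
  tt <- meta$node_type[match(dag$edges$to, meta$node_id)]
  counts <- table(factor(paste(ft, tt, sep = "->"),
                         levels = paste(rows$from_type, rows$to_type,
                                        sep = "->")))
  total <- nrow(dag$edges)
  mutate(rows,
         count = as.integer(counts),
         percent = if (total > 0) 100 * .data$count / total else 0,
         lambda = dag$lambda %||% NA_real_)
}

#' First-occurrence penalty of an edge class
#'
#' Scanning from the most stringent penalty downward, returns the largest
#' lambda at which any edge satisfying `edge_class` is present in the
#' solution path, or `NA` if the class never occurs.
#'
#' @param path a `solution_path`.
#' @param edge_class predicate taking an edge tibble (columns `from`,
#'   `to`, `weight`, `from_type`, `to_type`) and returning a logical
#'   vector.
#' @return scalar lambda or `NA`.
#' @export
#' @examples
#' \dontrun{
#' # penalty at which a genotype first connects to a non-genotype node
#' first_occurrence(path, function(e)
#'   e$from_type %in% c("MG", "NG") & !(e$to_type %in% c("MG", "NG")))
#' }
first_occurrence <- function(path, edge_class) {
  stopifnot(inherits(path, "solution_path"))
  meta <- path$nodes
  for (lam in sort(path$lambdas, decreasing = TRUE)) {
    dag <- path$models[[as.character(lam)]]
    if (!nrow(dag$edges)) next
    e <- mutate(dag$edges,
                from_type = meta$node_type[match(.data$from, meta$node_id)],
                to_type = meta$node_type[match(.data$to, meta$node_id)])
    if (any(edge_class(e))) return(lam)
  }
  NA_real_
}

#' Export per-penalty network growth frames
#'
#' Writes one GraphML file (edge attribute `weight`, node attributes
#' `node_type`, `metabolite_class`, `timepoint`) and optionally one
#' static PNG plot per penalty value.  Frame index 1 corresponds to the
#' most stringent penalty (lambda = 15 on the default grid) and the index
#' increases as the penalty relaxes, so the frame sequence shows network
#' growth.  Node positions are computed once on the union (least
#' stringent) network so frames are comparable; maternal features are
#' drawn as squares and offspring features as circles, outcomes grey,
#' genotypes green and metabolites colored by compound class.
#'
#' @param path a `solution_path`.
#' @param meta node metadata; defaults to the path's own.
#' @param out_dir output directory (created if needed).
#' @param plot write PNG frames as well as GraphML (default `TRUE`).
#' @param layout_seed seed for the layout.
#' @param width,height,dpi PNG geometry.
#' @return tibble of written files (`lambda`, `frame`, `graphml`, `png`).
#' @export
export_growth_frames <- function(path, meta = NULL, out_dir, plot = TRUE,
                                 layout_seed = 1L, width = 7, height = 6,
                                 dpi = 150) {
  stopifnot(inherits(path, "solution_path"))
  meta <- validate_node_meta(meta %||% path$nodes)
  ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) abort(paste0("cannot create out_dir: ", out_dir))
  lambdas <- sort(path$lambdas, decreasing = TRUE)

  union_dag <- path$models[[as.character(min(lambdas))]]
  g_union <- dag_as_igraph(union_dag)
  coords <- with_seed(layout_seed,
                      igraph::layout_with_fr(g_union, weights = NA))
  rownames(coords) <- igraph::V(g_union)$name

  files <- vector("list", length(lambdas))
  for (k in seq_along(lambdas)) {
    lam <- lambdas[k]
    dag <- path$models[[as.character(lam)]]
    stem <- sprintf("frame_%02d", k)
    f_graphml <- file.path(out_dir, paste0(stem, ".graphml"))
    res <- tryCatch(
      igraph::write_graph(dag_as_igraph(dag), f_graphml, format = "graphml"),
      error = function(e) abort(paste0("failed writing ", f_graphml, ": ",
                                       conditionMessage(e)))
    )
    f_png <- NA_character_
    if (plot) {
      f_png <- file.path(out_dir, paste0(stem, ".png"))
      gg <- plot_dag_frame(dag, meta, coords,
                           title = bquote(lambda == .(lam)))
      ggplot2::ggsave(f_png, gg, width = width, height = height, dpi = dpi)
    }
    files[[k]] <- tibble(lambda = lam, frame = k, graphml = f_graphml,
                         png = f_png)
  }
  bind_rows(files)
}

#' Filter and impute a metabolite matrix
#'
#' Drops metabolite columns whose missing fraction exceeds
#' `max_missing_fraction` (the study convention: 10% for targeted
#' assays, 20% for non-targeted) and, when `impute` is on, replaces the
#' remaining missing entries by the metabolite-specific minimum observed
#' value — missingness in non-targeted assays is attributed to low
#' abundance.
#'
#' @param mat samples x metabolites numeric matrix (NAs = missing).
#' @param max_missing_fraction threshold in \[0, 1\] (default 0.2).
#' @param impute impute remaining missing values (default `TRUE`).
#' @return filtered (and imputed) matrix; dropped column names in
#'   attribute `"dropped"`.
#' @export
preprocess_metabolites <- function(mat, max_missing_fraction = 0.2,
                                   impute = TRUE) {
  stopifnot(max_missing_fraction >= 0, max_missing_fraction <= 1)
  mat <- as.matrix(mat)
  frac <- colMeans(is.na(mat))
  drop <- frac > max_missing_fraction
  out <- mat[, !drop, drop = FALSE]
  if (impute && anyNA(out)) {
    for (j in seq_len(ncol(out))) {
      miss <- is.na(out[, j])
      if (any(miss)) out[miss, j] <- min(out[, j], na.rm = TRUE)
    }
  }
  attr(out, "dropped") <- colnames(mat)[drop]
  out
}

#' Per-penalty summary of a solution path
#'
#' Edge count and number of nodes with at least one incident edge for
#' every penalty value — the headline network-growth summary.
#'
#' @param x a `solution_path`.
#' @param ... unused.
#' @return tibble with one row per lambda.
#' @export
glance.solution_path <- function(x, ...) {
  bind_rows(lapply(sort(x$lambdas, decreasing = TRUE), function(lam) {
    dag <- x$models[[as.character(lam)]]
    tibble(lambda = lam,
           n_edges = nrow(dag$edges),
           n_connected_nodes = length(unique(c(dag$edges$from, dag$edges$to))),
           score = dag$score,
           converged = dag$converged)
  }))
}

#' @rdname glance.solution_path
#' @export
tidy.solution_path <- function(x, ...) {
  bind_rows(lapply(sort(x$lambdas, decreasing = TRUE), function(lam) {
    mutate(x$models[[as.character(lam)]]$edges, lambda = lam)
  }))
}

#' Edge table of a fitted network
#'
#' @param x a `weighted_dag`.
#' @param ... unused.
#' @return tibble of edges with endpoint types.
#' @export
tidy.weighted_dag <- function(x, ...) {
  meta <- x$nodes
  mutate(x$edges,
         from_type = meta$node_type[match(.data$from, meta$node_id)],
         to_type = meta$node_type[match(.data$to, meta$node_id)],
         lambda = x$lambda)
}

#' @rdname tidy.weighted_dag
#' @export
glance.weighted_dag <- function(x, ...) {
  tibble(lambda = x$lambda,
         n_nodes = nrow(x$nodes),
         n_connected_nodes = length(unique(c(x$edges$from, x$edges$to))),
         n_edges = nrow(x$edges),
         score = x$score,
         penalty = x$penalty,
         converged = x$converged)
}
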