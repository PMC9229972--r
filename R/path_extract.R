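#' All shortest directed paths between two nodes
#'
#' Unweighted (edge-count) shortest paths from `source` to `target`,
#' keeping every path that ties at the minimal length.  Output is ordered
#' lexicographically by node-id sequence and is empty when the target is
#' unreachable.
#'
#' @param dag a `weighted_dag` or an igraph directed graph.
#' @param source,target node ids (`source != target`).
#' @return list of character vectors (node-id sequences).
#' @export
shortest_directed_paths <- function(dag, source, target) {
  g <- if (inherits(dag, "weighted_dag")) dag_as_igraph(dag) else dag
  stopifnot(igraph::is_igraph(g))
  if (source == target) abort("source and target must differ")
  nms <- igraph::V(g)$name
  if (!(source %in% nms) || !(target %in% nms)) {
    abort(paste0("node(s) not in graph: ",
                 paste(setdiff(c(source, target), nms), collapse = ", ")))
  }
  res <- suppressWarnings(
    igraph::all_shortest_paths(g, from = source, to = target, mode = "out",
                               weights = NA)  # edge-count distance, not
  )                                           # the weight attribute
  paths <- lapply(res$vpaths %||% res$res, function(v) igraph::V(g)$name[v])
  paths <- paths[vapply(paths, length, integer(1)) >= 2L]
  if (!length(paths)) return(list())
  paths[order(vapply(paths, path_to_string, character(1)))]
}

#' Is one path a contiguous subpath of another?
#'
#' `TRUE` iff `short` occurs as a contiguous ordered slice of `long`
#' (a path is a subpath of itself).
#'
#' @param short,long character vectors of node ids, length >= 2.
#' @return logical scalar.
#' @export
#' @examples
#' is_subpath(c("b", "c"), c("a", "b", "c", "d"))  # TRUE
#' is_subpath(c("a", "c"), c("a", "b", "c"))       # FALSE: not contiguous
is_subpath <- function(short, long) {
  ns <- length(short); nl <- length(long)
  stopifnot(ns >= 2L, nl >= 2L)
  if (ns > nl) return(FALSE)
  for (start in seq_len(nl - ns + 1L)) {
    if (all(long[start:(start + ns - 1L)] == short)) return(TRUE)
  }
  FALSE
}

#' Extract candidate mediation pathways from a network
#'
#' Pools all shortest directed paths from every maternal feature node
#' (types MG, MM, MP) to every newborn outcome node (type NP with role
#' `"outcome"`), drops paths below `min_nodes` nodes, removes duplicates,
#' and removes any path that is a contiguous subpath of a longer path in
#' the pooled set.  Intended for the network at the least stringent
#' penalty of a solution path.
#'
#' @param dag a `weighted_dag`.
#' @param meta node metadata; defaults to the dag's own.
#' @param min_nodes minimum number of nodes per path (default 3: at least
#'   one mediator between exposure and outcome).
#' @return tibble with columns `path` (list of node-id vectors),
#'   `path_str` (`;`-joined ids), `length`, `source`, `source_type`,
#'   `outcome`, sorted deterministically.
#' @export
extract_candidates <- function(dag, meta = NULL, min_nodes = 3L) {
  meta <- validate_node_meta(meta %||% dag$nodes)
  g <- dag_as_igraph(dag)
  sources <- meta$node_id[meta$node_type %in% maternal_types() &
                            meta$node_id %in% igraph::V(g)$name]
  targets <- meta$node_id[meta$node_type == "NP" & meta$role == "outcome" &
                            meta$node_id %in% igraph::V(g)$name]
  paths <- list()
  for (s in sources) {
    for (t in targets) {
      paths <- c(paths, shortest_directed_paths(g, s, t))
    }
  }
  paths <- paths[vapply(paths, length, integer(1)) >= min_nodes]
  if (!length(paths)) {
    return(tibble(path = list(), path_str = character(0), length = integer(0),
                  source = character(0), source_type = character(0),
                  outcome = character(0)))
  }
  strs <- vapply(paths, path_to_string, character(1))
  keep_first <- !duplicated(strs)
  paths <- paths[keep_first]; strs <- strs[keep_first]
  lens <- vapply(paths, length, integer(1))
  # subpath exclusion across the pooled candidate set
  drop <- vapply(seq_along(paths), function(k) {
    longer <- which(lens > lens[k])
    any(vapply(longer, function(m) is_subpath(paths[[k]], paths[[m]]),
               logical(1)))
  }, logical(1))
  paths <- paths[!drop]; strs <- strs[!drop]; lens <- lens[!drop]
  ord <- order(strs)
  paths <- paths[ord]; strs <- strs[ord]; lens <- lens[ord]
  tibble(
    path = paths,
    path_str = strs,
    length = lens,
    source = vapply(paths, function(p) p[[1L]], character(1)),
    source_type = meta$node_type[match(vapply(paths, function(p) p[[1L]],
                                              character(1)), meta$node_id)],
    outcome = vapply(paths, function(p) p[[length(p)]], character(1))
  )
}
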