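# Sparse Gaussian Bayesian-network estimation under a typed blocklist.
#
# The objective, on column-standardized data with sample correlation
# matrix S = X'X/n, is the per-n-normalized penalized profile likelihood
#
#   f(B) = sum_j (1/2) (1 + log(2 pi q_j)) + sum_{i->j} pen(|B_ij|)
#
# with q_j = RSS_j / n the profiled conditional variance of node j given
# its parents, and pen either an L1 or an MCP(gamma) penalty with
# multiplier lambda_n = lambda / sqrt(n), so that the printed integer
# grid lambda = 15 ... 1 keeps its meaning across sample sizes.
# penalized_score() reports n * f(B) (the usual likelihood scale).

penalty_value <- function(t, lam_n, penalty, gamma) {
  if (penalty == "l1") return(lam_n * t)
  ifelse(t <= gamma * lam_n, lam_n * t - t^2 / (2 * gamma),
         gamma * lam_n^2 / 2)
}

# q_j(B_.j) = 1 - 2 B'.j s_j + B'.j S B_.j ; clamped away from zero so the
# profiled log stays finite on (near-)deterministic fits.
node_q <- function(S, bj, j) {
  q <- 1 - 2 * sum(bj * S[, j]) + drop(crossprod(bj, S %*% bj))
  max(q, 1e-12)
}

#' Penalized score of a network on data
#'
#' Sum over nodes of the Gaussian negative log-likelihood of each child
#' given its parents (conditional variance profiled at the residual
#' variance implied by the stored edge weights), plus the sparsity
#' penalty: `n * pen(|w|)` per edge with multiplier `lambda / sqrt(n)`.
#' Computed on column-standardized data, matching the scale on which
#' networks are learned.
#'
#' @param dag a `weighted_dag` (from [learn_dag()]) or any list with
#'   `nodes` and `edges` (`from`, `to`, `weight`).
#' @param data samples x nodes matrix or data frame; column names must
#'   cover the dag's nodes.
#' @param lambda penalty multiplier on the printed integer scale.
#' @param penalty `"mcp"` or `"l1"`.
#' @param gamma MCP concavity parameter.
#' @return the penalized score (scalar; smaller is better).
#' @export
penalized_score <- function(dag, data, lambda = dag$lambda,
                            penalty = dag$penalty %||% "mcp",
                            gamma = dag$gamma %||% 2) {
  penalty <- match.arg(penalty, c("mcp", "l1"))
  ids <- dag$nodes$node_id
  data <- as.matrix(as.data.frame(data)[, ids, drop = FALSE])
  n <- nrow(data)
  xs <- standardize_cols(data)
  S <- crossprod(xs) / n
  p <- length(ids)
  B <- matrix(0, p, p, dimnames = list(ids, ids))
  if (nrow(dag$edges)) {
    B[cbind(match(dag$edges$from, ids), match(dag$edges$to, ids))] <-
      dag$edges$weight
  }
  n_parents <- colSums(B != 0)
  if (any(n_parents >= n)) abort("node with more parents than samples; ill-posed")
  lam_n <- lambda / sqrt(n)
  q <- vapply(seq_len(p), function(j) node_q(S, B[, j], j), numeric(1))
  nll <- sum((n / 2) * (1 + log(2 * pi * q)))
  pen <- n * sum(penalty_value(abs(B[B != 0]), lam_n, penalty, gamma))
  nll + pen
}

#' Largest useful penalty for a data set
#'
#' The smallest `lambda` at which the empty graph is a stationary point
#' of the objective (no blocklist-allowed edge can enter), computed as
#' `sqrt(n) * max |cor|` over allowed node pairs.
#'
#' @inheritParams learn_dag
#' @return scalar lambda on the printed scale.
#' @export
lambda_max <- function(data, meta, blocklist = build_blocklist(meta)) {
  data <- as.matrix(as.data.frame(data)[, meta$node_id, drop = FALSE])
  n <- nrow(data)
  S <- crossprod(standardize_cols(data)) / n
  allowed <- allowed_edge_matrix(blocklist, meta)
  if (!any(allowed)) return(0)
  sqrt(n) * max(abs(S[allowed]))
}

#' Learn a sparse Gaussian Bayesian network
#'
#' Score-based structure and weight estimation by block-cyclic coordinate
#' descent: node pairs (i, j) are visited in fixed lexicographic order and
#' the two potential coefficients (i->j, j->i) are updated jointly,
#' allowing at most one to be nonzero.  Updates in a blocklisted direction
#' or that would create a directed cycle are rejected; every acceptance is
#' by exact comparison of the penalized objective, so the score is
#' non-increasing across sweeps.  Ties between directions with equal
#' score go to the blocklist-permitted direction, then to the lower
#' (parent, child) lexicographic order.
#'
#' Data are standardized to zero mean and unit variance before learning;
#' reported edge weights are on the standardized scale.
#'
#' @param data samples x nodes numeric matrix or data frame; column names
#'   must match `meta$node_id`.
#' @param meta node metadata ([node_meta()]).
#' @param blocklist a [build_blocklist()] object.
#' @param lambda penalty value on the printed integer scale (>= 0).
#' @param init optional `weighted_dag` warm start.
#' @param penalty `"mcp"` (default, concavity `gamma`) or `"l1"`.
#' @param gamma MCP concavity parameter (default 2).
#' @param max_iter maximum number of full sweeps.
#' @param tol convergence threshold on the maximum absolute coefficient
#'   change per sweep.
#' @param refine after convergence, attempt edge-reversal perturbations
#'   (trial-reverse an edge, reconverge, keep on improvement) to escape
#'   orientation local optima.  Default: on for cold starts, off for
#'   warm starts, whose initializing solution already fixes the basin.
#' @param restarts number of deterministic multi-start runs over node
#'   orderings when fitting from scratch (identity order plus fixed
#'   pseudo-random permutations; the best penalized score wins).  Ignored
#'   when `init` is supplied.
#' @param debug if `TRUE`, record the objective after every sweep in
#'   attribute `"score_trace"` (asserted non-increasing).
#' @return an object of class `weighted_dag`: node metadata, an edge
#'   tibble (`from`, `to`, `weight`), profiled node noise variances (on
#'   the standardized scale), the lambda value, the penalized score, and
#'   a convergence flag.
#' @export
learn_dag <- function(data, meta, blocklist = build_blocklist(meta), lambda,
                      init = NULL, penalty = c("mcp", "l1"), gamma = 2,
                      max_iter = 200L, tol = 1e-8, refine = is.null(init),
                      restarts = 8L, debug = FALSE) {
  penalty <- match.arg(penalty)
  meta <- validate_node_meta(meta)
  stopifnot(lambda >= 0)
  ids <- meta$node_id
  data <- as.matrix(as.data.frame(data)[, ids, drop = FALSE])
  n <- nrow(data)
  p <- length(ids)
  xs <- standardize_cols(data)
  S <- crossprod(xs) / n
  lam_n <- lambda / sqrt(n)
  allowed <- allowed_edge_matrix(blocklist, meta)

  B0 <- matrix(0, p, p, dimnames = list(ids, ids))
  if (!is.null(init)) {
    stopifnot(inherits(init, "weighted_dag"))
    if (!setequal(init$nodes$node_id, ids)) abort("init node set mismatch")
    if (nrow(init$edges)) {
      ii <- match(init$edges$from, ids)
      jj <- match(init$edges$to, ids)
      if (any(!allowed[cbind(ii, jj)])) abort("init violates the blocklist")
      B0[cbind(ii, jj)] <- init$edges$weight
    }
  }

  if (is.null(init) && restarts > 1L) {
    # deterministic multi-start: identity node order first, then fixed
    # pseudo-random permutations.  Different sweep orders and tie-break
    # preferences reach different orientation basins; restarts run
    # without the (more expensive) reversal refinement, which is then
    # applied once to the winning basin.
    perms <- c(list(seq_len(p)),
               with_seed(760219L, lapply(seq_len(restarts - 1L),
                                         function(r) sample.int(p))))
    best <- NULL
    for (perm in perms) {
      inv <- order(perm)
      res_p <- cd_search(S[perm, perm, drop = FALSE],
                         allowed[perm, perm, drop = FALSE],
                         B0[perm, perm, drop = FALSE],
                         lam_n, penalty, gamma, max_iter, tol,
                         refine = FALSE, debug = FALSE)
      res_p$B <- res_p$B[inv, inv, drop = FALSE]
      res_p$q <- res_p$q[inv]
      if (is.null(best) || res_p$f < best$f - 1e-12) best <- res_p
    }
    res <- cd_search(S, allowed, best$B, lam_n, penalty, gamma,
                     max_iter, tol, refine = refine, debug = debug)
  } else {
    res <- cd_search(S, allowed, B0, lam_n, penalty, gamma, max_iter, tol,
                     refine, debug)
  }
  B <- res$B
  q <- res$q
  if (!res$converged) {
    warn(paste0("learn_dag did not converge in ", max_iter,
                " sweeps (lambda = ", lambda, ")"))
  }

  idx <- which(B != 0, arr.ind = TRUE)
  edges <- tibble(from = ids[idx[, 1]], to = ids[idx[, 2]],
                  weight = B[idx])
  edges <- arrange(edges, .data$from, .data$to)
  out <- structure(
    list(nodes = meta, edges = edges,
         node_noise_var = setNames(q, ids),
         lambda = lambda, penalty = penalty, gamma = gamma,
         n = n, converged = res$converged,
         score = n * res$f),
    class = "weighted_dag"
  )
  if (debug) attr(out, "score_trace") <- res$trace
  out
}

# Core block-cyclic coordinate-descent search in index space (C++
# implementation in src/cd_search.cpp).  Returns list(B, q, f, converged,
# trace) where f is the per-n-normalized penalized objective.
cd_search <- function(S, allowed, B, lam_n, penalty, gamma, max_iter, tol,
                      refine, debug) {
  res <- .cd_search_cpp(S, allowed, B, lam_n, penalty, gamma,
                        as.integer(max_iter), tol, refine, debug)
  if (debug && length(res$trace) > 1L && any(diff(res$trace) > 1e-8)) {
    abort("internal error: penalized score increased between sweeps")
  }
  res
}

#' @export
print.weighted_dag <- function(x, ...) {
  cat("<weighted_dag> lambda =", x$lambda, "|", nrow(x$nodes), "nodes,",
      nrow(x$edges), "edges | penalty =", x$penalty,
      if (!x$converged) "| NOT CONVERGED" else "", "\n")
  invisible(x)
}

#' Estimate networks over a decreasing penalty solution path
#'
#' Fits one network per lambda, from the most to the least stringent
#' penalty, warm-starting each fit from the previous solution.  The
#' default grid is the integer sequence 15, 14, ..., 1.
#'
#' @inheritParams learn_dag
#' @param lambdas strictly decreasing penalty values.
#' @return an object of class `solution_path`: `lambdas` and a named list
#'   `models` of `weighted_dag`s.
#' @export
learn_solution_path <- function(data, meta, blocklist = build_blocklist(meta),
                                lambdas = 15:1, penalty = c("mcp", "l1"),
                                gamma = 2, max_iter = 200L, tol = 1e-8,
                                restarts = 8L) {
  penalty <- match.arg(penalty)
  lambdas <- as.numeric(lambdas)
  if (length(lambdas) > 1L && any(diff(lambdas) >= 0)) {
    abort("lambdas must be strictly decreasing")
  }
  models <- vector("list", length(lambdas))
  names(models) <- as.character(lambdas)
  init <- NULL
  for (k in seq_along(lambdas)) {
    models[[k]] <- learn_dag(data, meta, blocklist, lambda = lambdas[k],
                             init = init, penalty = penalty, gamma = gamma,
                             max_iter = max_iter, tol = tol,
                             restarts = restarts)
    init <- models[[k]]
  }
  structure(list(lambdas = lambdas, models = models, nodes = meta),
            class = "solution_path")
}

#' @export
print.solution_path <- function(x, ...) {
  cat("<solution_path>", length(x$lambdas), "penalty values (",
      max(x$lambdas), "->", min(x$lambdas), "),", nrow(x$nodes), "nodes\n")
  print(glance(x))
  invisible(x)
}

#' Structural Hamming distance between two DAGs
#'
#' Number of edge additions, deletions and reversals (each counting one)
#' separating two directed graphs over the same node set.
#'
#' @param edges_a,edges_b data frames with `from`/`to` columns, or
#'   `weighted_dag` / `true_model` objects.
#' @return integer distance.
#' @export
shd <- function(edges_a, edges_b) {
  get_edges <- function(x) {
    if (inherits(x, "weighted_dag")) x$edges[, c("from", "to")]
    else if (inherits(x, "true_model")) x$edges[, c("from", "to")]
    else as.data.frame(x)[, c("from", "to")]
  }
  a <- get_edges(edges_a); b <- get_edges(edges_b)
  ka <- paste(a$from, a$to, sep = "\r")
  kb <- paste(b$from, b$to, sep = "\r")
  ra <- paste(a$to, a$from, sep = "\r")  # reversed keys of a
  reversals <- sum(ra %in% kb & !(ka %in% kb))
  only_a <- setdiff(ka, kb)
  only_b <- setdiff(kb, ka)
  # a reversal accounts for one edge on each side
  length(only_a) + length(only_b) - reversals
}

# igraph view of a weighted_dag (internal; also used by path/report modules)
dag_as_igraph <- function(dag) {
  igraph::graph_from_data_frame(dag$edges[, c("from", "to", "weight")],
                                vertices = as.data.frame(dag$nodes))
}
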