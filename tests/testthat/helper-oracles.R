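# Independent oracles used across the test suite.  These deliberately
# reimplement the quantities under test with different machinery
# (normal equations, exhaustive enumeration, brute-force search).

# ---- linear regression (normal equations, classical SE) --------------
ols_oracle <- function(X, y) {
  XtX <- crossprod(X)
  beta <- solve(XtX, crossprod(X, y))
  res <- y - X %*% beta
  df <- nrow(X) - ncol(X)
  sigma2 <- sum(res^2) / df
  se <- sqrt(sigma2 * diag(solve(XtX)))
  stat <- beta / se
  p <- 2 * pt(-abs(stat), df)
  list(beta = drop(beta), se = drop(se), stat = drop(stat), p = drop(p))
}

# ---- exhaustive DAG enumeration with per-node penalized refits -------

# all DAG adjacency matrices on p nodes (list of logical matrices)
enumerate_dags <- function(p) {
  pairs <- t(combn(p, 2))
  n_pairs <- nrow(pairs)
  states <- expand.grid(rep(list(0:2), n_pairs))
  out <- list()
  for (r in seq_len(nrow(states))) {
    adj <- matrix(FALSE, p, p)
    for (k in seq_len(n_pairs)) {
      s <- states[r, k]
      if (s == 1) adj[pairs[k, 1], pairs[k, 2]] <- TRUE
      if (s == 2) adj[pairs[k, 2], pairs[k, 1]] <- TRUE
    }
    if (oracle_is_acyclic(adj)) out[[length(out) + 1L]] <- adj
  }
  out
}

oracle_is_acyclic <- function(adj) {
  p <- ncol(adj)
  indeg <- colSums(adj)
  active <- rep(TRUE, p)
  for (step in seq_len(p)) {
    roots <- which(active & indeg == 0)
    if (!length(roots)) return(!any(active))
    for (r in roots) {
      indeg[adj[r, ]] <- indeg[adj[r, ]] - 1L
      active[r] <- FALSE
    }
  }
  !any(active)
}

oracle_penalty <- function(t, lam_n, penalty, gamma) {
  if (penalty == "l1") lam_n * abs(t)
  else ifelse(abs(t) <= gamma * lam_n,
              lam_n * abs(t) - t^2 / (2 * gamma),
              gamma * lam_n^2 / 2)
}

# per-node penalized regression for a fixed parent set, solved by cyclic
# 1-D minimization with stats::optimize (independent of the package's
# thresholding updates)
oracle_fit_node <- function(S, j, parents, lam_n, penalty, gamma) {
  beta <- setNames(rep(0, length(parents)), parents)
  qfun <- function(b) {
    bv <- rep(0, ncol(S)); bv[parents] <- b
    max(1 - 2 * sum(bv * S[, j]) + drop(crossprod(bv, S %*% bv)), 1e-12)
  }
  if (length(parents)) {
    for (pass in 1:200) {
      delta <- 0
      for (k in seq_along(parents)) {
        obj <- function(bk) {
          b <- beta; b[k] <- bk
          0.5 * log(qfun(b)) +
            sum(oracle_penalty(b, lam_n, penalty, gamma))
        }
        opt <- optimize(obj, interval = c(-3, 3), tol = 1e-12)
        # optimize can miss the kink at zero; compare explicitly
        new_bk <- if (obj(0) <= opt$objective) 0 else opt$minimum
        delta <- max(delta, abs(new_bk - beta[k]))
        beta[k] <- new_bk
      }
      if (delta < 1e-11) break
    }
  }
  list(beta = beta, q = qfun(beta))
}

# penalized score (likelihood scale) of a fixed structure with refit
# weights; returns the score and the fitted weight matrix
oracle_score_structure <- function(adj, S, n, lambda, penalty = "mcp",
                                   gamma = 2) {
  p <- ncol(S)
  lam_n <- lambda / sqrt(n)
  score <- 0
  Bfit <- matrix(0, p, p)
  for (j in seq_len(p)) {
    parents <- which(adj[, j])
    fit <- oracle_fit_node(S, j, parents, lam_n, penalty, gamma)
    Bfit[parents, j] <- fit$beta
    score <- score + (n / 2) * (1 + log(2 * pi * fit$q)) +
      n * sum(oracle_penalty(fit$beta, lam_n, penalty, gamma))
  }
  list(score = score, B = Bfit)
}

# global optimum over all DAGs on a handful of nodes: per-node scores are
# precomputed for every (node, parent subset) pair, then summed per
# enumerated structure
oracle_global_optimum <- function(data, lambda, penalty = "mcp", gamma = 2,
                                  dags = NULL) {
  data <- as.matrix(data)
  n <- nrow(data)
  p <- ncol(data)
  xc <- sweep(data, 2, colMeans(data))
  xs <- sweep(xc, 2, sqrt(colMeans(xc^2)), "/")
  S <- crossprod(xs) / n
  lam_n <- lambda / sqrt(n)
  dags <- dags %||% enumerate_dags(p)

  subset_key <- function(parents) {
    if (!length(parents)) "root" else paste(sort(parents), collapse = ",")
  }
  node_score <- vector("list", p)
  for (j in seq_len(p)) node_score[[j]] <- new.env(parent = emptyenv())
  get_node_score <- function(j, parents) {
    key <- subset_key(parents)
    env <- node_score[[j]]
    if (is.null(env[[key]])) {
      fit <- oracle_fit_node(S, j, parents, lam_n, penalty, gamma)
      env[[key]] <- (n / 2) * (1 + log(2 * pi * fit$q)) +
        n * sum(oracle_penalty(fit$beta, lam_n, penalty, gamma))
    }
    env[[key]]
  }
  best <- Inf
  for (adj in dags) {
    sc <- 0
    for (j in seq_len(p)) sc <- sc + get_node_score(j, which(adj[, j]))
    if (sc < best) best <- sc
  }
  best
}

# ---- brute-force shortest directed paths ----------------------------

# all simple directed paths from `from` to `to` by DFS on an edge list
brute_all_paths <- function(edges, from, to, nodes) {
  out <- list()
  adj <- split(edges$to, edges$from)
  recurse <- function(path) {
    v <- path[length(path)]
    if (v == to) {
      out[[length(out) + 1L]] <<- path
      return(invisible(NULL))
    }
    for (w in adj[[v]] %||% character(0)) {
      if (!(w %in% path)) recurse(c(path, w))
    }
  }
  if (from %in% nodes && to %in% nodes && from != to) recurse(from)
  out
}

brute_shortest_paths <- function(edges, from, to, nodes) {
  paths <- brute_all_paths(edges, from, to, nodes)
  if (!length(paths)) return(list())
  lens <- vapply(paths, length, integer(1))
  paths <- paths[lens == min(lens)]
  paths[order(vapply(paths, paste, character(1), collapse = ";"))]
}

# brute-force candidate extraction: pooled shortest paths, type filter,
# exhaustive pairwise subpath elimination to a fixpoint
brute_extract_candidates <- function(edges, meta, min_nodes = 3) {
  sources <- meta$node_id[meta$node_type %in% c("MG", "MM", "MP")]
  targets <- meta$node_id[meta$node_type == "NP" & meta$role == "outcome"]
  pool <- list()
  for (s in sources) for (t in targets) {
    pool <- c(pool, brute_shortest_paths(edges, s, t, meta$node_id))
  }
  pool <- pool[vapply(pool, length, integer(1)) >= min_nodes]
  strs <- vapply(pool, paste, character(1), collapse = ";")
  pool <- pool[!duplicated(strs)]
  contiguous_in <- function(a, b) {
    na <- length(a); nb <- length(b)
    if (na > nb) return(FALSE)
    any(vapply(seq_len(nb - na + 1L), function(s)
      all(b[s:(s + na - 1L)] == a), logical(1)))
  }
  repeat {
    drop <- rep(FALSE, length(pool))
    for (k in seq_along(pool)) {
      for (m in seq_along(pool)) {
        if (k != m && length(pool[[m]]) > length(pool[[k]]) &&
            contiguous_in(pool[[k]], pool[[m]])) {
          drop[k] <- TRUE
          break
        }
      }
    }
    if (!any(drop)) break
    pool <- pool[!drop]
  }
  sort(vapply(pool, paste, character(1), collapse = ";"))
}

# ---- implied covariance of a linear trio model ----------------------

# Sigma = (I - B')^{-1} Omega (I - B)^{-1} on the raw scale, with
# Mendelian transmission edges contributing linear coefficient 1/2 and
# genotype-node variances 2 maf (1 - maf) (residual 3/2 maf (1 - maf)
# for a transmitted offspring SNP).
implied_covariance <- function(model) {
  ids <- model$nodes$node_id
  p <- length(ids)
  B <- matrix(0, p, p, dimnames = list(ids, ids))
  for (r in seq_len(nrow(model$edges))) {
    B[model$edges$from[r], model$edges$to[r]] <- model$edges$coef[r]
  }
  omega <- numeric(p)
  names(omega) <- ids
  snp <- model$nodes$node_id[model$nodes$node_type %in% c("MG", "NG")]
  for (id in ids) {
    if (id %in% snp) {
      pq2 <- 2 * model$maf[[id]] * (1 - model$maf[[id]])
      parents <- model$edges$from[model$edges$to == id]
      omega[id] <- if (length(parents)) 0.75 * pq2 else pq2
    } else {
      omega[id] <- model$noise_sd[[id]]^2
    }
  }
  inv <- solve(diag(p) - t(B))
  sig <- inv %*% diag(omega) %*% t(inv)
  dimnames(sig) <- list(ids, ids)
  sig
}
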