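meta_mm <- function(ids) {
  node_meta(ids, "MM", timepoint = "fasting")
}

test_that("penalized score of the empty graph is the marginal likelihood", {
  set.seed(5)
  X <- matrix(rnorm(200 * 3), 200, 3, dimnames = list(NULL, c("a", "b", "c")))
  meta <- meta_mm(c("a", "b", "c"))
  dag <- make_wdag(meta, tibble::tibble(from = character(0),
                                        to = character(0),
                                        weight = numeric(0)), lambda = 2)
  sc <- penalized_score(dag, X, lambda = 2)
  # standardized columns have unit variance (denominator n)
  expect_equal(sc, 3 * (200 / 2) * (1 + log(2 * pi)), tolerance = 1e-10)
})

test_that("penalized score matches a hand-computed 3-node oracle", {
  set.seed(8)
  n <- 150
  a <- rnorm(n); b <- 0.7 * a + rnorm(n); c <- -0.5 * b + rnorm(n)
  X <- cbind(a = a, b = b, c = c)
  meta <- meta_mm(c("a", "b", "c"))
  w_ab <- 0.6; w_bc <- -0.4
  dag <- make_wdag(meta, tibble::tibble(from = c("a", "b"), to = c("b", "c"),
                                        weight = c(w_ab, w_bc)), lambda = 3)
  # oracle: explicit residual sums of squares on standardized columns
  zs <- function(v) (v - mean(v)) / sqrt(mean((v - mean(v))^2))
  za <- zs(a); zb <- zs(b); zc <- zs(c)
  q_a <- 1
  q_b <- mean((zb - w_ab * za)^2)
  q_c <- mean((zc - w_bc * zb)^2)
  lam_n <- 3 / sqrt(n)
  mcp <- function(t) ifelse(t <= 2 * lam_n, lam_n * t - t^2 / 4, lam_n^2)
  oracle <- (n / 2) * sum(1 + log(2 * pi * c(q_a, q_b, q_c))) +
    n * (mcp(abs(w_ab)) + mcp(abs(w_bc)))
  expect_equal(penalized_score(dag, X, lambda = 3), oracle,
               tolerance = 1e-10)
})

test_that("with no penalty a true parent never worsens the score", {
  set.seed(9)
  n <- 300
  x <- rnorm(n); y <- 0.8 * x + rnorm(n)
  X <- cbind(x = x, y = y)
  meta <- meta_mm(c("x", "y"))
  empty <- make_wdag(meta, tibble::tibble(from = character(0),
                                          to = character(0),
                                          weight = numeric(0)))
  with_edge <- make_wdag(meta, tibble::tibble(from = "x", to = "y",
                                              weight = cor(x, y)))
  expect_lte(penalized_score(with_edge, X, lambda = 0),
             penalized_score(empty, X, lambda = 0))
})

test_that("at lambda_max and above the learned graph is empty", {
  set.seed(10)
  n <- 250
  x <- rnorm(n); y <- 0.6 * x + rnorm(n); z <- rnorm(n)
  X <- cbind(x = x, y = y, z = z)
  meta <- meta_mm(c("x", "y", "z"))
  lmax <- lambda_max(X, meta)
  d <- learn_dag(X, meta, lambda = lmax * 1.001)
  expect_identical(nrow(d$edges), 0L)
  d2 <- learn_dag(X, meta, lambda = lmax * 0.8)
  expect_gt(nrow(d2$edges), 0L)
})

test_that("a blocklisted direction is never estimated", {
  set.seed(11)
  n <- 400
  x <- rnorm(n); y <- 0.9 * x + rnorm(n)
  # x is a cord metabolite, y an offspring SNP-typed node: x -> y (NM -> NG)
  # is forbidden, the reverse is allowed
  X <- cbind(x = x, y = y)
  meta <- node_meta(c("x", "y"), c("NM", "NG"),
                    timepoint = c("cord", "none"),
                    chromosome = c(NA, "2"))
  d <- learn_dag(X, meta, lambda = 2)
  expect_false(any(d$edges$from == "x" & d$edges$to == "y"))
})

test_that("with lambda 0 the single fitted edge carries the OLS slope", {
  set.seed(12)
  n <- 500
  x <- rnorm(n); y <- 0.7 * x + rnorm(n)
  X <- cbind(x = x, y = y)
  meta <- meta_mm(c("x", "y"))
  d <- learn_dag(X, meta, lambda = 0)
  expect_identical(nrow(d$edges), 1L)
  zs <- function(v) (v - mean(v)) / sqrt(mean((v - mean(v))^2))
  ols <- sum(zs(x) * zs(y)) / n  # standardized-scale slope (symmetric)
  expect_equal(abs(d$edges$weight), abs(ols), tolerance = 1e-8)
})

test_that("the debug score trace is monotone non-increasing", {
  set.seed(13)
  m <- trio_benchmark_model()
  co <- simulate_cohort(m, 400, seed = 13)
  df <- as.data.frame(co)
  d <- learn_dag(df[, m$nodes$node_id], m$nodes, lambda = 5, debug = TRUE)
  trace <- attr(d, "score_trace")
  expect_gt(length(trace), 1L)
  expect_true(all(diff(trace) <= 1e-8))
})

test_that("the learner attains the exhaustive 4-node optimum (spot check)", {
  dags4 <- enumerate_dags(4)
  expect_length(dags4, 543L)
  meta4 <- meta_mm(paste0("m", 1:4))
  hits <- 0L
  for (s in 1:5) {
    set.seed(s)
    repeat {
      adj <- dags4[[sample(length(dags4), 1)]]
      if (sum(adj) >= 2) break
    }
    Btrue <- adj * matrix(sample(c(-1, 1), 16, TRUE) * runif(16, 0.5, 1), 4)
    X <- matrix(0, 500, 4)
    ord <- as.integer(igraph::topo_sort(
      igraph::graph_from_adjacency_matrix(adj)))
    for (j in ord) X[, j] <- X %*% Btrue[, j] + rnorm(500)
    colnames(X) <- paste0("m", 1:4)
    d <- learn_dag(X, meta4, lambda = 4)
    opt <- oracle_global_optimum(X, 4, dags = dags4)
    expect_gte(d$score, opt - 1e-6 * abs(opt))  # can never beat it
    if (abs(d$score - opt) < 1e-6 * abs(opt)) hits <- hits + 1L
  }
  expect_gte(hits, 4L)
})

test_that("solution paths warm-start and stay valid at every penalty", {
  m <- trio_benchmark_model()
  co <- simulate_cohort(m, 500, seed = 17)
  df <- as.data.frame(co)[, m$nodes$node_id]
  sp <- learn_solution_path(df, m$nodes, lambdas = c(12, 8, 4, 2))
  expect_s3_class(sp, "solution_path")
  expect_length(sp$models, 4L)

  # a single-lambda path equals a direct fit
  sp1 <- learn_solution_path(df, m$nodes, lambdas = 8)
  d1 <- learn_dag(df, m$nodes, lambda = 8)
  expect_equal(sp1$models[["8"]]$edges, d1$edges, tolerance = 1e-12)

  bl <- build_blocklist(m$nodes)
  for (d in sp$models) {
    g <- igraph::graph_from_data_frame(d$edges[, c("from", "to")],
                                       vertices = m$nodes$node_id)
    expect_true(igraph::is_dag(g))
    if (nrow(d$edges)) {
      expect_false(any(edge_blocked(bl, d$edges$from, d$edges$to, m$nodes)))
    }
  }
  # sparsest endpoint has no more edges than the densest
  expect_lte(nrow(sp$models[["12"]]$edges), nrow(sp$models[["2"]]$edges))
  expect_error(learn_solution_path(df, m$nodes, lambdas = c(1, 5)),
               "decreasing")
})

test_that("structural Hamming distance counts reversals once", {
  a <- data.frame(from = c("x", "y"), to = c("y", "z"))
  expect_identical(shd(a, a), 0L)
  b <- data.frame(from = c("y", "y"), to = c("x", "z"))  # x->y reversed
  expect_identical(shd(a, b), 1L)
  c3 <- data.frame(from = "x", to = "y")                  # y->z missing
  expect_identical(shd(a, c3), 1L)
})
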