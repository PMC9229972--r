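test_that("a noiseless fit recovers the exact slope with p near zero", {
  set.seed(1)
  d <- rbinom(20, 2, 0.4)
  rec <- fit_snp_metabolite(d, 2 * d)
  expect_equal(rec$beta, 2, tolerance = 1e-10)
  expect_lt(rec$p, 1e-12)
  expect_gt(rec$p, 0)
  expect_identical(rec$n_used, 20L)
})

test_that("fit matches the normal-equations oracle on random instances", {
  set.seed(99)
  for (r in 1:100) {
    n <- 60
    d <- rbinom(n, 2, runif(1, 0.1, 0.5))
    if (var(d) < 1e-8) next
    Z <- matrix(rnorm(n * 3), n, 3)
    y <- 0.3 * d + Z %*% rnorm(3) + rnorm(n)
    rec <- fit_snp_metabolite(d, y, Z)
    X <- cbind(1, d, Z)
    o <- ols_oracle(X, y)
    expect_equal(rec$beta, unname(o$beta[2]), tolerance = 1e-8)
    expect_equal(rec$se, unname(o$se[2]), tolerance = 1e-8)
    expect_equal(rec$p, unname(o$p[2]), tolerance = 1e-8)
    expect_equal(rec$statistic, rec$beta / rec$se, tolerance = 1e-10)
  }
})

test_that("degenerate designs raise informative errors", {
  y <- rnorm(30)
  expect_error(fit_snp_metabolite(rep(1, 30), y, snp_id = "rs1"),
               "monomorphic.*rs1")
  d <- rbinom(30, 2, 0.4)
  Z <- cbind(c1 = d, c2 = rnorm(30))  # c1 duplicates the dosage
  expect_error(fit_snp_metabolite(d, y, Z), "collinear.*c1")
})

test_that("scan retains associations below the default 10^-7.5 threshold", {
  set.seed(7)
  n <- 400
  G <- cbind(strong = rbinom(n, 2, 0.4), null = rbinom(n, 2, 0.4))
  M <- cbind(met1 = 1.2 * G[, "strong"] + rnorm(n),
             met2 = rnorm(n))
  res <- run_metabotype_scan(G, M)
  expect_identical(unique(res$snp_id), "strong")
  expect_true(all(res$p < 10^-7.5))

  all_res <- run_metabotype_scan(G, M, p_threshold = 1, keep_all = FALSE)
  expect_identical(nrow(all_res), 4L)

  # invariant to sample row order
  perm <- sample(n)
  res2 <- run_metabotype_scan(G[perm, ], M[perm, ], p_threshold = 1)
  expect_equal(res$beta, res2$beta[match(
    paste(res$snp_id, res$metabolite_id),
    paste(res2$snp_id, res2$metabolite_id))], tolerance = 1e-12)
})

test_that("LD trimming keeps the strongest SNP per correlated block", {
  set.seed(21)
  n <- 300
  base <- rbinom(n, 2, 0.3)
  G <- cbind(dup1 = base, dup2 = base, indep = rbinom(n, 2, 0.3))
  assoc <- tibble::tibble(snp_id = c("dup1", "dup2", "indep"),
                          p = c(1e-9, 1e-8, 1e-8))
  kept <- ld_trim(assoc, G, r2_threshold = 0.5)
  expect_identical(kept, c("dup1", "indep"))

  # mutually independent SNPs all survive
  Gi <- sapply(1:5, function(k) rbinom(n, 2, 0.3))
  colnames(Gi) <- paste0("s", 1:5)
  ai <- tibble::tibble(snp_id = colnames(Gi), p = runif(5) * 1e-8)
  expect_setequal(ld_trim(ai, Gi, 0.5), colnames(Gi))
  expect_identical(ld_trim(ai[0, ], Gi), character(0))
})

test_that("greedy trimming matches an exhaustive greedy-trace oracle", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- 200
    base <- matrix(rbinom(n * 3, 2, 0.3), n, 3)
    G <- sapply(1:10, function(k) {
      src <- base[, sample(3, 1)]
      flip <- runif(n) < runif(1, 0, 0.6)
      ifelse(flip, rbinom(n, 2, 0.3), src)
    })
    colnames(G) <- sprintf("s%02d", 1:10)
    assoc <- tibble::tibble(snp_id = colnames(G),
                            p = sort(runif(10)) * 1e-8)
    kept <- ld_trim(assoc, G, r2_threshold = 0.5)

    # oracle: explicit greedy trace in ascending-p order
    oracle_kept <- character(0)
    for (s in assoc$snp_id[order(assoc$p)]) {
      r2 <- vapply(oracle_kept,
                   function(k) cor(G[, s], G[, k])^2, numeric(1))
      if (all(r2 < 0.5)) oracle_kept <- c(oracle_kept, s)
    }
    expect_identical(kept, oracle_kept)
    # result is pairwise below the threshold
    if (length(kept) > 1) {
      cc <- cor(G[, kept])^2
      expect_true(all(cc[upper.tri(cc)] < 0.5))
    }
  }
})
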