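test_that("a (near-)noiseless chain is recovered to the exact limit", {
  # exact collinearity of X and M1 makes the outcome design singular, so
  # the deterministic chain is probed at vanishing mediator noise
  set.seed(30)
  x <- rnorm(50)
  m1 <- 2 * x + rnorm(50) * 1e-4
  df <- data.frame(x = x, m1 = m1, y = 3 * m1)
  fit <- fit_serial_chain(df, c("x", "m1", "y"))
  expect_equal(unname(fit$chain), c(2, 3), tolerance = 1e-3)
  expect_equal(fit$de, 0, tolerance = 1e-2)
  expect_equal(fit$te, 6, tolerance = 1e-3)
  expect_equal(serial_ide(fit), 6, tolerance = 1e-2)
})

test_that("serial_ide is the product of chain coefficients", {
  expect_equal(serial_ide(c(2, 3)), 6)
  expect_equal(serial_ide(c(0.5, 0.5, 0.5)), 0.125)
  expect_equal(serial_ide(c(0.7, 0, 3)), 0)
  expect_error(serial_ide(numeric(0)), "empty")
})

test_that("chain coefficients match an lm() oracle with covariates", {
  set.seed(31)
  n <- 200
  cov1 <- rnorm(n); cov2 <- rnorm(n)
  x <- rnorm(n)
  m1 <- 0.5 * x + 0.3 * cov1 + rnorm(n)
  m2 <- 0.6 * m1 + 0.2 * x + rnorm(n)
  y <- 0.4 * m2 + 0.1 * x - 0.2 * cov2 + rnorm(n)
  df <- data.frame(x = x, m1 = m1, m2 = m2, y = y,
                   cov1 = cov1, cov2 = cov2)
  fit <- fit_serial_chain(df, c("x", "m1", "m2", "y"),
                          covariates = c("cov1", "cov2"))
  o1 <- lm(m1 ~ x + cov1 + cov2, df)
  o2 <- lm(m2 ~ x + m1 + cov1 + cov2, df)
  o3 <- lm(y ~ x + m1 + m2 + cov1 + cov2, df)
  o4 <- lm(y ~ x + cov1 + cov2, df)
  expect_equal(unname(fit$chain),
               unname(c(coef(o1)["x"], coef(o2)["m1"], coef(o3)["m2"])),
               tolerance = 1e-8)
  expect_equal(fit$de, unname(coef(o3)["x"]), tolerance = 1e-8)
  expect_equal(fit$te, unname(coef(o4)["x"]), tolerance = 1e-8)
})

test_that("single-mediator effects decompose exactly: te = de + ide", {
  set.seed(32)
  n <- 150
  x <- rnorm(n)
  m <- 0.5 * x + rnorm(n)
  y <- 0.6 * m + 0.2 * x + rnorm(n)
  fit <- fit_serial_chain(data.frame(x = x, m = m, y = y), c("x", "m", "y"))
  expect_equal(fit$te, fit$de + serial_ide(fit), tolerance = 1e-8)
})

test_that("rank-deficient or undersized chains error", {
  set.seed(33)
  x <- rnorm(30)
  df <- data.frame(x = x, m1 = x, y = rnorm(30))  # m1 collinear with x
  expect_error(fit_serial_chain(df, c("x", "m1", "y")), "collinear")
  expect_error(fit_serial_chain(df, c("x", "y")), ">= 3 nodes")
  small <- data.frame(x = rnorm(3), m = rnorm(3), y = rnorm(3),
                      c1 = rnorm(3), c2 = rnorm(3))
  expect_error(fit_serial_chain(small, c("x", "m", "y"),
                                covariates = c("c1", "c2")),
               "too few")
})

test_that("bootstrap inference is reproducible and point estimates are
           independent of the replicate count", {
  set.seed(34)
  n <- 200
  x <- rnorm(n)
  m <- 0.5 * x + rnorm(n)
  y <- 0.5 * m + rnorm(n)
  df <- data.frame(x = x, m = m, y = y)
  f1 <- bootstrap_smm(df, c("x", "m", "y"), n_boot = 200, seed = 4)
  f2 <- bootstrap_smm(df, c("x", "m", "y"), n_boot = 200, seed = 4)
  expect_identical(tidy(f1), tidy(f2))
  f3 <- bootstrap_smm(df, c("x", "m", "y"), n_boot = 400, seed = 4)
  expect_identical(f1$ide, f3$ide)
  expect_identical(f1$te, f3$te)
  expect_lte(f1$ide_ci[1], f1$ide_ci[2])
  expect_equal(f1$pm, f1$ide / f1$te, tolerance = 1e-12)
  expect_error(bootstrap_smm(df, c("x", "m", "y"), n_boot = 50), ">= 100")
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(35)
  p <- runif(50)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p) && all(adj <= 1))
  perm <- sample(50)
  expect_equal(bh_adjust(p[perm]), adj[perm], tolerance = 1e-15)
  expect_error(bh_adjust(c(0.5, 0)), "0, 1")
})

test_that("discovery and replication finds a planted pathway", {
  set.seed(36)
  n <- 600
  x <- rnorm(n)
  m1 <- 0.5 * x + rnorm(n)
  m2 <- 0.5 * m1 + rnorm(n)
  y <- 0.5 * m2 + rnorm(n)
  df <- data.frame(x = x, m1 = m1, m2 = m2, y = y,
                   nx = rnorm(n), nm1 = rnorm(n), nm2 = rnorm(n),
                   ny = rnorm(n))
  train <- df[1:400, ]; valid <- df[401:600, ]
  paths <- list(c("x", "m1", "m2", "y"), c("nx", "nm1", "nm2", "ny"))
  rep <- discover_and_validate(paths, train, valid, n_boot = 200, seed = 2)
  tr <- tidy(rep, "training")
  expect_identical(nrow(tr), 2L)
  expect_true(tr$discovered[tr$path == "x;m1;m2;y"])
  va <- tidy(rep, "validation")
  expect_true(all(va$path == "x;m1;m2;y"))
  expect_true(va$validated[1])
  expect_identical(glance(rep)$n_validated, 1L)

  # a zero FDR threshold yields no discoveries and no validation stage
  rep0 <- discover_and_validate(paths, train, valid, alpha_fdr = 0,
                                n_boot = 200, seed = 2)
  expect_identical(sum(tidy(rep0, "training")$discovered), 0L)
  expect_identical(nrow(tidy(rep0, "validation")), 0L)
})
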