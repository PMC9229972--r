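test_that("trio genotype simulation respects Mendelian constraints", {
  expect_error(simulate_trio_genotypes(10, c(0.6), seed = 1), "0, 0.5")
  expect_error(simulate_trio_genotypes(10, c(0), seed = 1), "0, 0.5")

  g <- simulate_trio_genotypes(2000, c(a = 0.3, b = 0.5), seed = 1)
  expect_true(all(g$maternal %in% 0:2))
  expect_true(all(g$offspring %in% 0:2))
  expect_identical(colnames(g$maternal), c("a", "b"))

  # homozygous mothers always transmit one copy
  hom <- g$maternal[, 1] == 2
  expect_true(all(g$offspring[hom, 1] >= 1))
  # dosage-0 mothers never transmit
  ref <- g$maternal[, 1] == 0
  expect_true(all(g$offspring[ref, 1] <= 1))

  g2 <- simulate_trio_genotypes(2000, c(a = 0.3, b = 0.5), seed = 1)
  expect_identical(g, g2)
})

test_that("mother-offspring dosage correlation is near one half", {
  g <- simulate_trio_genotypes(20000, c(s = 0.3), seed = 42)
  expect_equal(cor(g$maternal[, 1], g$offspring[, 1]), 0.5,
               tolerance = 0.04)
})

test_that("null model reproduces intercepts and noise variances", {
  m0 <- example_true_model(coef = 0)
  m0$edges$coef[m0$edges$to != "FG1"] <- 0
  m0$intercepts[c("MMa", "FMc")] <- c(1.5, -2)
  n <- 10000
  co <- simulate_cohort(m0, n, seed = 3)
  df <- as.data.frame(co)
  for (nd in c("MMa", "MMb", "FMc", "FMd")) {
    sd_true <- m0$noise_sd[[nd]]
    expect_equal(mean(df[[nd]]), m0$intercepts[[nd]],
                 tolerance = 3 * sd_true / sqrt(n))
    expect_equal(var(df[[nd]]), sd_true^2,
                 tolerance = 3 * sd_true^2 * sqrt(2 / n))
  }
})

test_that("a unit edge with zero noise copies the parent column", {
  meta <- node_meta(c("MMx", "NMy"), c("MM", "NM"),
                    timepoint = c("fasting", "cord"))
  m <- true_model(meta,
                  data.frame(from = "MMx", to = "NMy", coef = 1),
                  noise_sd = c(MMx = 1, NMy = 0))
  co <- simulate_cohort(m, 200, seed = 5)
  df <- as.data.frame(co)
  expect_equal(df$NMy, df$MMx)
})

test_that("simulated covariance matches the path-analysis closed form", {
  m <- example_true_model(coef = 0.8)
  n <- 5000
  co <- simulate_cohort(m, n, seed = 11)
  df <- as.data.frame(co)
  ids <- m$nodes$node_id
  emp <- cov(df[, ids])
  sig <- implied_covariance(m)
  for (r in seq_len(nrow(m$edges))) {
    a <- m$edges$from[r]; b <- m$edges$to[r]
    se_cov <- sqrt((sig[a, a] * sig[b, b] + sig[a, b]^2) / n)
    expect_lt(abs(emp[a, b] - sig[a, b]), 3 * se_cov)
  }
})

test_that("cyclic or blocklist-violating models are rejected", {
  meta <- node_meta(c("a", "b"), c("MM", "MM"), timepoint = "fasting")
  expect_error(
    true_model(meta, data.frame(from = c("a", "b"), to = c("b", "a"),
                                coef = c(1, 1)),
               noise_sd = c(a = 1, b = 1)),
    "acyclic")
  meta2 <- node_meta(c("snp", "met"), c("MG", "MM"),
                     timepoint = c("none", "fasting"),
                     chromosome = c("2", NA))
  expect_error(
    true_model(meta2, data.frame(from = "met", to = "snp", coef = 1),
               noise_sd = c(met = 1), maf = c(snp = 0.3)),
    "blocklist")
})

test_that("stratified split applies round-half-up within strata", {
  m <- example_true_model()
  co <- simulate_cohort(m, 9, seed = 1)
  co$strata <- rep("anc1", 9)
  sp <- split_train_validation(co, 2 / 3, seed = 2)
  expect_length(sp$train$pair_ids, 6)
  expect_length(sp$validation$pair_ids, 3)

  co2 <- simulate_cohort(m, 30, seed = 1)
  co2$strata <- rep(c("g1", "g2"), c(10, 20))
  sp2 <- split_train_validation(co2, 2 / 3, seed = 2)
  expect_identical(
    unname(table(sp2$train$strata)[c("g1", "g2")]),
    table(factor(c(rep("g1", 7), rep("g2", 13))))[c("g1", "g2")] |> unname())

  # a single 1385-pair stratum gives 923 under round half up
  co3 <- simulate_cohort(m, 1385, seed = 1)
  co3$strata <- rep("all", 1385)
  sp3 <- split_train_validation(co3, 2 / 3, seed = 7)
  expect_length(sp3$train$pair_ids, 923)
})

test_that("split is a deterministic partition", {
  m <- example_true_model()
  co <- simulate_cohort(m, 137, seed = 4)
  sp <- split_train_validation(co, 2 / 3, seed = 9)
  ids <- c(sp$train$pair_ids, sp$validation$pair_ids)
  expect_setequal(ids, co$pair_ids)
  expect_length(intersect(sp$train$pair_ids, sp$validation$pair_ids), 0)
  sp2 <- split_train_validation(co, 2 / 3, seed = 9)
  expect_identical(sp$train$pair_ids, sp2$train$pair_ids)
  # degenerate fraction on a tiny cohort errors
  co$strata <- rep("one", 137)
  expect_error(split_train_validation(co, 1e-4, seed = 1), "empty split")
})

test_that("true serial indirect effect is the coefficient product", {
  m <- example_true_model(coef = 0.8)
  expect_equal(true_serial_ide(m, c("MG1", "MMa")), 0.8)
  expect_equal(true_serial_ide(m, c("MG1", "MMa", "MMb", "FMd")), 0.8^3)
  m0 <- example_true_model(coef = 0)
  expect_equal(true_serial_ide(m0, c("MG1", "MMa", "FMc")), 0)
  expect_error(true_serial_ide(m, c("MG1", "FMd")), "not edges")
})
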