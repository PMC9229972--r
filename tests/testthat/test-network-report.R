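report_meta <- node_meta(
  node_id = c("mm1", "mm2", "nm1", "nm2", "np1"),
  node_type = c("MM", "MM", "NM", "NM", "NP"),
  timepoint = c("fasting", "fasting", "cord", "cord", "none"),
  metabolite_class = c("AA", "AC", "AA", "AC", NA),
  role = c(rep("intermediate", 4), "outcome")
)

test_that("edge tallies count ordered type pairs with percentages", {
  dag <- make_wdag(report_meta, tibble::tibble(
    from = c("mm1", "mm1", "nm1"), to = c("mm2", "nm1", "nm2"), weight = 1),
    lambda = 7)
  tl <- tally_edges_by_type(dag)
  expect_identical(nrow(tl), 26L)
  expect_identical(sum(tl$count), 3L)
  get <- function(f, t) tl$count[tl$from_type == f & tl$to_type == t]
  expect_identical(get("MM", "MM"), 1L)
  expect_identical(get("MM", "NM"), 1L)
  expect_identical(get("NM", "NM"), 1L)
  expect_equal(tl$percent[tl$count == 1], rep(100 / 3, 3), tolerance = 1e-9)
  expect_equal(sum(tl$percent), 100, tolerance = 1e-9)
  expect_identical(unique(tl$lambda), 7)

  empty <- make_wdag(report_meta, tibble::tibble(from = character(0),
                                                 to = character(0),
                                                 weight = numeric(0)))
  tl0 <- tally_edges_by_type(empty)
  expect_true(all(tl0$count == 0L) && all(tl0$percent == 0))
})

test_that("tallies agree with a per-edge classification oracle", {
  for (seed in c(2, 9, 23)) {
    td <- rand_typed_dag(10, seed, edge_prob = 0.4)
    tl <- tally_edges_by_type(td$dag)
    expect_identical(sum(tl$count), nrow(td$edges))
    if (!nrow(td$edges)) next
    ft <- td$meta$node_type[match(td$edges$from, td$meta$node_id)]
    tt <- td$meta$node_type[match(td$edges$to, td$meta$node_id)]
    recount <- table(paste(ft, tt, sep = "->"))
    for (k in names(recount)) {
      parts <- strsplit(k, "->", fixed = TRUE)[[1]]
      expect_identical(
        tl$count[tl$from_type == parts[1] & tl$to_type == parts[2]],
        as.integer(recount[[k]]))
    }
  }
})

# a hand-built solution path: genotype-to-metabolite edge enters at
# lambda = 10, mirroring a genotype-glycine first connection
build_fake_path <- function() {
  meta <- node_meta(
    node_id = c("rs_a", "rs_b", "gly", "np"),
    node_type = c("MG", "NG", "MM", "NP"),
    timepoint = c("none", "none", "fasting", "none"),
    chromosome = c("2", "2", NA, NA),
    role = c("intermediate", "intermediate", "intermediate", "outcome")
  )
  lambdas <- 15:1
  models <- lapply(lambdas, function(lam) {
    edges <- tibble::tibble(from = "rs_a", to = "rs_b", weight = 0.5)
    if (lam <= 10) {
      edges <- dplyr::bind_rows(
        edges, tibble::tibble(from = "rs_a", to = "gly", weight = 0.3))
    }
    if (lam <= 4) {
      edges <- dplyr::bind_rows(
        edges, tibble::tibble(from = "gly", to = "np", weight = 0.2))
    }
    make_wdag(meta, edges, lambda = lam)
  })
  names(models) <- as.character(lambdas)
  structure(list(lambdas = as.numeric(lambdas), models = models,
                 nodes = meta), class = "solution_path")
}

test_that("first occurrence scans from the most stringent penalty", {
  sp <- build_fake_path()
  is_geno <- function(t) t %in% c("MG", "NG")
  expect_equal(first_occurrence(sp, function(e)
    is_geno(e$from_type) & is_geno(e$to_type)), 15)
  expect_equal(first_occurrence(sp, function(e)
    is_geno(e$from_type) & !is_geno(e$to_type)), 10)
  expect_equal(first_occurrence(sp, function(e) e$to_type == "NP"), 4)
  expect_true(is.na(first_occurrence(sp, function(e)
    e$from_type == "NM")))
  # relaxing a predicate can only move the first occurrence earlier
  expect_gte(first_occurrence(sp, function(e) rep(TRUE, nrow(e))),
             first_occurrence(sp, function(e) e$to_type == "NP"))
})

test_that("growth frames map index 1 to the most stringent penalty", {
  sp <- build_fake_path()
  out_dir <- withr::local_tempdir()
  files <- export_growth_frames(sp, out_dir = out_dir, plot = FALSE)
  expect_identical(nrow(files), 15L)
  expect_identical(basename(files$graphml[1]), "frame_01.graphml")
  expect_identical(files$lambda[1], 15)
  expect_identical(files$lambda[15], 1)
  expect_identical(sort(basename(files$graphml)), basename(files$graphml))

  # frame k holds the model at lambda = 16 - k
  for (k in c(1, 6, 15)) {
    g <- igraph::read_graph(files$graphml[k], format = "graphml")
    model <- sp$models[[as.character(16 - k)]]
    got <- igraph::as_data_frame(g)
    expect_setequal(paste(got$from, got$to),
                    paste(model$edges$from, model$edges$to))
    expect_equal(sort(got$weight), sort(model$edges$weight),
                 tolerance = 1e-9)
  }
  # node attributes survive the round trip
  g1 <- igraph::read_graph(files$graphml[1], format = "graphml")
  expect_setequal(igraph::vertex_attr(g1, "node_type"),
                  c("MG", "NG", "MM", "NP"))
})

test_that("PNG frames are written when plotting is on", {
  sp <- build_fake_path()
  sp$lambdas <- c(15, 14)
  sp$models <- sp$models[c("15", "14")]
  out_dir <- withr::local_tempdir()
  files <- export_growth_frames(sp, out_dir = out_dir, plot = TRUE)
  expect_true(all(file.exists(files$png)))
  expect_true(all(file.size(files$png) > 0))
})

test_that("metabolite preprocessing drops and imputes by column minimum", {
  m <- cbind(
    quarter_missing = c(1, NA, 3, NA, 5, 2, 4, 2),        # 25% missing
    little_missing = c(1.7, 2.5, NA, 3.1, 2.0, 4, 2.2, 1.9),  # 12.5%
    complete = 1:8
  )
  # a 25%-missing column exceeds the 20% threshold and is dropped
  out <- preprocess_metabolites(m, max_missing_fraction = 0.2)
  expect_identical(colnames(out), c("little_missing", "complete"))
  expect_identical(attr(out, "dropped"), "quarter_missing")
  expect_equal(unname(out[3, "little_missing"]), 1.7)  # column min imputed

  out2 <- preprocess_metabolites(m, max_missing_fraction = 0.3,
                                 impute = FALSE)
  expect_identical(colnames(out2), colnames(m))
  expect_true(anyNA(out2))

  out3 <- preprocess_metabolites(m, max_missing_fraction = 1, impute = FALSE)
  expect_equal(unname(out3[, ]), unname(m[, ]))
})
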