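#' Simulate maternal-offspring SNP dosages with Mendelian transmission
#'
#' Maternal dosages are Binomial(2, maf) under Hardy-Weinberg equilibrium.
#' Each offspring receives one allele drawn uniformly at random from the
#' mother's two alleles plus one paternal allele drawn as Bernoulli(maf)
#' from the population (paternal genotypes are not modeled as nodes).
#' Under this scheme the maternal-offspring dosage correlation converges
#' to the parent-offspring additive value of 1/2.
#'
#' @param n_pairs number of mother-offspring pairs (>= 1).
#' @param mafs vector of minor-allele frequencies, each in (0, 0.5];
#'   names, if present, become SNP column names.
#' @param seed integer RNG seed.
#' @return a list with `maternal` and `offspring` integer dosage matrices
#'   (`n_pairs` x `length(mafs)`, entries in 0/1/2).
#' @export
#' @examples
#' g <- simulate_trio_genotypes(100, c(rs1 = 0.3), seed = 1)
#' table(g$maternal[, 1], g$offspring[, 1])
simulate_trio_genotypes <- function(n_pairs, mafs, seed) {
  stopifnot(length(n_pairs) == 1L, n_pairs >= 1)
  if (any(mafs <= 0 | mafs > 0.5)) {
    abort("mafs must lie in (0, 0.5]")
  }
  ids <- names(mafs) %||% paste0("snp", seq_along(mafs))
  with_seed(seed, {
    m <- matrix(0L, n_pairs, length(mafs), dimnames = list(NULL, ids))
    o <- m
    for (k in seq_along(mafs)) {
      p <- mafs[k]
      a1 <- rbinom(n_pairs, 1L, p)
      a2 <- rbinom(n_pairs, 1L, p)
      transmitted <- ifelse(runif(n_pairs) < 0.5, a1, a2)
      paternal <- rbinom(n_pairs, 1L, p)
      m[, k] <- a1 + a2
      o[, k] <- transmitted + paternal
    }
    list(maternal = m, offspring = o)
  })
}

#' Simulate a mother-offspring multi-omics cohort
#'
#' Generates a cohort from a [true_model()]: genotype nodes by Mendelian
#' trio sampling ([simulate_trio_genotypes()]; a newborn SNP with a
#' maternal-SNP parent edge inherits from that mother, any other SNP is an
#' independent Hardy-Weinberg draw), then all non-genotype nodes in
#' topological order as `intercept + sum(coef * parent) + N(0, noise_sd)`.
#' Covariates are independent standard normals by default; optional
#' `covariate_effects` inject confounding edges from covariates into
#' named nodes.  Ancestry strata are assigned from Dirichlet-sampled
#' proportions over `n_strata` groups, mirroring a multi-ancestry cohort
#' without claiming any particular composition.
#'
#' @param model a [true_model()].
#' @param n_pairs number of mother-offspring pairs.
#' @param seed integer RNG seed.
#' @param n_covariates number of independent N(0,1) covariates.
#' @param n_strata number of ancestry strata.
#' @param covariate_effects optional data frame with columns `covariate`,
#'   `node`, `coef` adding linear covariate contributions to nodes.
#' @return a `trio_cohort` object: aligned per-pair matrices of maternal
#'   and offspring genotypes, fasting/1-hr maternal and cord metabolites,
#'   phenotypes and covariates, plus strata labels and node metadata.
#' @export
simulate_cohort <- function(model, n_pairs, seed, n_covariates = 2L,
                            n_strata = 4L, covariate_effects = NULL) {
  stopifnot(inherits(model, "true_model"), n_pairs >= 1)
  nodes <- model$nodes
  g <- igraph::graph_from_data_frame(model$edges[, c("from", "to")],
                                     vertices = nodes$node_id)
  if (!igraph::is_dag(g)) abort("model graph must be acyclic")
  topo <- names(igraph::topo_sort(g, mode = "out"))

  snp_ids <- nodes$node_id[nodes$node_type %in% snp_types()]
  ng_ids <- nodes$node_id[nodes$node_type == "NG"]
  # transmission pairing: NG node -> its maternal-SNP parent (if any)
  trans_parent <- vapply(ng_ids, function(id) {
    par <- model$edges$from[model$edges$to == id]
    par <- par[par %in% nodes$node_id[nodes$node_type == "MG"]]
    if (length(par)) par[[1L]] else NA_character_
  }, character(1))

  with_seed(seed, {
    vals <- matrix(NA_real_, n_pairs, nrow(nodes),
                   dimnames = list(NULL, nodes$node_id))

    # maternal SNPs and paired newborn SNPs via trio transmission
    mg_ids <- nodes$node_id[nodes$node_type == "MG"]
    for (id in mg_ids) {
      p <- model$maf[[id]]
      child <- names(trans_parent)[!is.na(trans_parent) & trans_parent == id]
      trio <- simulate_trio_genotypes(n_pairs, setNames(p, id),
                                      seed = sample.int(.Machine$integer.max, 1L))
      vals[, id] <- trio$maternal[, 1L]
      for (ch in child) vals[, ch] <- trio$offspring[, 1L]
    }
    # unpaired SNPs: independent HWE draws
    for (id in setdiff(snp_ids, c(mg_ids, names(trans_parent)[!is.na(trans_parent)]))) {
      vals[, id] <- rbinom(n_pairs, 2L, model$maf[[id]])
    }

    covariates <- matrix(rnorm(n_pairs * n_covariates), n_pairs, n_covariates,
                         dimnames = list(NULL, if (n_covariates)
                           paste0("cov", seq_len(n_covariates)) else NULL))

    for (id in topo) {
      if (id %in% snp_ids) next
      mu <- rep(model$intercepts[[id]], n_pairs)
      pe <- model$edges[model$edges$to == id, ]
      for (r in seq_len(nrow(pe))) {
        mu <- mu + pe$coef[r] * vals[, pe$from[r]]
      }
      if (!is.null(covariate_effects)) {
        ce <- covariate_effects[covariate_effects$node == id, , drop = FALSE]
        for (r in seq_len(nrow(ce))) {
          mu <- mu + ce$coef[r] * covariates[, ce$covariate[r]]
        }
      }
      vals[, id] <- mu + rnorm(n_pairs, 0, model$noise_sd[[id]])
    }

    props <- rgamma(n_strata, shape = 4)
    props <- props / sum(props)
    strata <- sample(paste0("anc", seq_len(n_strata)), n_pairs,
                     replace = TRUE, prob = props)

    pick <- function(type, tp = NULL) {
      sel <- nodes$node_type == type
      if (!is.null(tp)) sel <- sel & nodes$timepoint %in% tp
      vals[, nodes$node_id[sel], drop = FALSE]
    }
    cohort <- structure(
      list(
        pair_ids = sprintf("pair%05d", seq_len(n_pairs)),
        strata = strata,
        maternal_genotypes = pick("MG"),
        offspring_genotypes = pick("NG"),
        maternal_metabolites_fasting = pick("MM", "fasting"),
        maternal_metabolites_1hr = pick("MM", "1hr"),
        cord_metabolites = pick("NM"),
        phenotypes = cbind(pick("MP"), pick("NP")),
        covariates = covariates,
        node_meta = nodes
      ),
      class = "trio_cohort"
    )
    const <- vapply(as.data.frame(vals), function(x) var(x) < 1e-12, logical(1))
    if (any(const)) {
      warn(paste0("constant simulated column(s): ",
                  paste(names(const)[const], collapse = ", ")))
    }
    cohort
  })
}

#' @export
print.trio_cohort <- function(x, ...) {
  cat("<trio_cohort>", length(x$pair_ids), "pairs |",
      ncol(x$maternal_genotypes), "maternal SNPs,",
      ncol(x$offspring_genotypes), "offspring SNPs,",
      ncol(x$maternal_metabolites_fasting), "fasting +",
      ncol(x$maternal_metabolites_1hr), "1-hr maternal metabolites,",
      ncol(x$cord_metabolites), "cord metabolites,",
      ncol(x$phenotypes), "phenotypes,",
      ncol(x$covariates), "covariates\n")
  cat("strata:", paste(sprintf("%s=%d", names(table(x$strata)),
                               table(x$strata)), collapse = " "), "\n")
  invisible(x)
}

n_pairs <- function(cohort) length(cohort$pair_ids)

cohort_matrices <- function() {
  c("maternal_genotypes", "offspring_genotypes",
    "maternal_metabolites_fasting", "maternal_metabolites_1hr",
    "cord_metabolites", "phenotypes", "covariates")
}

# row subset preserving structure
subset_cohort <- function(cohort, idx) {
  out <- cohort
  out$pair_ids <- cohort$pair_ids[idx]
  out$strata <- cohort$strata[idx]
  for (m in cohort_matrices()) out[[m]] <- cohort[[m]][idx, , drop = FALSE]
  out
}

#' Flatten a cohort to a single analysis table
#'
#' One row per mother-offspring pair, one column per node and covariate,
#' plus `pair_id` and `stratum`.
#'
#' @param x a `trio_cohort`.
#' @param ... unused.
#' @return a tibble.
#' @export
as_tibble.trio_cohort <- function(x, ...) {
  bind_cols_mat <- do.call(cbind, lapply(cohort_matrices(), function(m) x[[m]]))
  out <- as_tibble(as.data.frame(bind_cols_mat))
  dplyr::bind_cols(tibble(pair_id = x$pair_ids, stratum = x$strata), out)
}

#' @export
as.data.frame.trio_cohort <- function(x, ...) {
  as.data.frame(as_tibble(x))
}

#' Stratified training/validation split
#'
#' Within each ancestry stratum, `round(train_fraction * stratum size)`
#' pairs (rounding half up) are sampled into the training set; the rest
#' form the validation set.  The two sets partition the cohort and the
#' split is deterministic given the seed.
#'
#' @param cohort a `trio_cohort`.
#' @param train_fraction fraction in (0, 1); default two-thirds.
#' @param seed integer RNG seed.
#' @return list with elements `train` and `validation`, both `trio_cohort`s.
#' @export
split_train_validation <- function(cohort, train_fraction = 2 / 3, seed) {
  stopifnot(inherits(cohort, "trio_cohort"))
  if (!(train_fraction > 0 && train_fraction < 1)) {
    abort("train_fraction must lie strictly between 0 and 1")
  }
  n <- n_pairs(cohort)
  with_seed(seed, {
    train_idx <- integer(0)
    for (s in sort(unique(cohort$strata))) {
      idx <- which(cohort$strata == s)
      if (!length(idx)) next
      n_tr <- floor(train_fraction * length(idx) + 0.5)  # round half up
      n_tr <- min(n_tr, length(idx))
      if (n_tr > 0L) train_idx <- c(train_idx, sample(idx)[seq_len(n_tr)])
    }
    train_idx <- sort(train_idx)
    valid_idx <- setdiff(seq_len(n), train_idx)
    if (!length(train_idx) || !length(valid_idx)) {
      abort("train_fraction produced an empty split")
    }
    list(train = subset_cohort(cohort, train_idx),
         validation = subset_cohort(cohort, valid_idx))
  })
}
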