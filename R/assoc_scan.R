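#' Single SNP-metabolite association fit
#'
#' Ordinary least squares of a metabolite outcome on an additive genotype
#' dosage plus covariates (intercept always included).  Rows with missing
#' values in the outcome, dosage or covariates are dropped.  `beta` is the
#' per-allele dosage coefficient, `p` the two-sided t-test p-value on
#' residual degrees of freedom.
#'
#' @param dosages numeric vector of dosages (hard calls in 0/1/2 or
#'   fractional dosages in \[0, 2\]).
#' @param metabolite numeric outcome vector, same length.
#' @param covariates optional numeric matrix/data frame of adjustment
#'   covariates.
#' @param snp_id,metabolite_id optional labels carried into the result.
#' @return a one-row tibble: `snp_id`, `metabolite_id`, `beta`, `se`,
#'   `statistic`, `p`, `n_used`.
#' @export
fit_snp_metabolite <- function(dosages, metabolite, covariates = NULL,
                               snp_id = "snp", metabolite_id = "metabolite") {
  dosages <- as.numeric(dosages)
  metabolite <- as.numeric(metabolite)
  if (length(dosages) != length(metabolite)) abort("unequal lengths")
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != length(dosages)) abort("covariate rows mismatch")
    if (is.null(colnames(covariates))) {
      colnames(covariates) <- paste0("cov", seq_len(ncol(covariates)))
    }
  }
  X <- cbind(`(Intercept)` = 1, dosage = dosages, covariates)
  keep <- complete.cases(X) & !is.na(metabolite)
  X <- X[keep, , drop = FALSE]
  y <- metabolite[keep]
  n <- length(y)
  if (n <= ncol(X)) abort("too few complete observations for the design")
  if (var(X[, "dosage"]) < 1e-12) {
    abort(paste0("monomorphic SNP: ", snp_id, " has constant dosage"))
  }
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    dropped <- colnames(X)[qr_x$pivot[(qr_x$rank + 1L):ncol(X)]]
    abort(paste0("singular design; collinear column(s): ",
                 paste(dropped, collapse = ", ")))
  }
  coefs <- qr.coef(qr_x, y)
  res <- y - X %*% coefs
  df <- n - ncol(X)
  sigma2 <- sum(res^2) / df
  xtx_inv <- chol2inv(qr.R(qr_x))
  # chol2inv on R of the pivoted QR: map back to original column order
  xtx_inv <- xtx_inv[order(qr_x$pivot), order(qr_x$pivot), drop = FALSE]
  se <- sqrt(pmax(sigma2, 0) * diag(xtx_inv))
  j <- which(colnames(X) == "dosage")
  stat <- unname(if (se[j] > 0) coefs[j] / se[j] else sign(coefs[j]) * Inf)
  p <- .p_floor(2 * pt(-abs(stat), df))
  tibble(snp_id = snp_id, metabolite_id = metabolite_id,
         beta = unname(coefs[j]), se = unname(se[j]),
         statistic = unname(stat), p = p, n_used = n)
}

#' Per-metabolite genome-wide association scan ("metabotyping")
#'
#' Runs [fit_snp_metabolite()] for every SNP x metabolite combination and
#' retains associations with `p < p_threshold`.  The default threshold
#' 10^-7.5 (~3.16e-8) is slightly more inclusive than the conventional
#' genome-wide 1e-8, anticipating that downstream penalized network
#' estimation performs the final selection.  Per-fit failures (monomorphic
#' SNPs, singular designs) are skipped with a warning.
#'
#' @param genotypes samples x SNP dosage matrix (column names = SNP ids).
#' @param metabolites samples x metabolite matrix (column names = ids).
#' @param covariates optional samples x covariate matrix.
#' @param p_threshold retention threshold on the nominal p-value.
#' @param keep_all if `TRUE`, return every testable pair with a
#'   `significant` flag instead of filtering.
#' @return tibble of association records sorted by p.
#' @export
run_metabotype_scan <- function(genotypes, metabolites, covariates = NULL,
                                p_threshold = 10^-7.5, keep_all = FALSE) {
  genotypes <- as.matrix(genotypes)
  metabolites <- as.matrix(metabolites)
  stopifnot(nrow(genotypes) == nrow(metabolites))
  if (is.null(colnames(genotypes))) {
    colnames(genotypes) <- paste0("snp", seq_len(ncol(genotypes)))
  }
  if (is.null(colnames(metabolites))) {
    colnames(metabolites) <- paste0("metab", seq_len(ncol(metabolites)))
  }
  res <- vector("list", ncol(genotypes) * ncol(metabolites))
  k <- 0L
  for (m in colnames(metabolites)) {
    for (s in colnames(genotypes)) {
      k <- k + 1L
      res[[k]] <- tryCatch(
        fit_snp_metabolite(genotypes[, s], metabolites[, m], covariates,
                           snp_id = s, metabolite_id = m),
        error = function(e) {
          warn(paste0("skipping ", s, " x ", m, ": ", conditionMessage(e)))
          NULL
        }
      )
    }
  }
  out <- bind_rows(res)
  if (nrow(out) == 0L) return(out)
  out <- mutate(out, significant = .data$p < p_threshold)
  out <- arrange(out, .data$p, .data$snp_id, .data$metabolite_id)
  if (keep_all) out else select(filter(out, .data$significant), -"significant")
}

#' Greedy LD trimming of significant SNPs
#'
#' Within the significant SNP set of one metabolite, SNPs are visited in
#' ascending p order (strongest signal first) and kept iff their squared
#' Pearson dosage correlation with every already-kept SNP is below
#' `r2_threshold`.  The default of 0.5 is a conventional pruning level;
#' it is exposed because downstream SNP counts depend on it.
#'
#' @param assoc association records for one metabolite (tibble with
#'   `snp_id` and `p`), e.g. a filtered [run_metabotype_scan()] result.
#' @param genotypes dosage matrix containing the candidate SNP columns.
#' @param r2_threshold r-squared threshold in (0, 1].
#' @return character vector of kept SNP ids, ordered by ascending p.
#' @export
ld_trim <- function(assoc, genotypes, r2_threshold = 0.5) {
  if (!(r2_threshold > 0 && r2_threshold <= 1)) {
    abort("r2_threshold must lie in (0, 1]")
  }
  assoc <- as_tibble(assoc)
  if (nrow(assoc) == 0L) return(character(0))
  genotypes <- as.matrix(genotypes)
  assoc <- arrange(assoc, .data$p, .data$snp_id)
  kept <- character(0)
  for (s in assoc$snp_id) {
    x <- genotypes[, s]
    r2 <- if (length(kept)) {
      vapply(kept, function(k) cor(x, genotypes[, k],
                                   use = "complete.obs")^2, numeric(1))
    } else numeric(0)
    if (all(r2 < r2_threshold)) kept <- c(kept, s)
  }
  kept
}
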