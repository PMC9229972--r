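# Serial mediation along ordered pathways, PROCESS Model-6 style, with
# bootstrap inference and the discovery/replication protocol.

# internal: intercept + named data columns as a model matrix
.design <- function(data, cols, covariates) {
  X <- cbind(`(Intercept)` = 1,
             as.matrix(data[, cols, drop = FALSE]),
             covariates)
  storage.mode(X) <- "double"
  X
}

.check_full_rank <- function(X, n) {
  if (n <= ncol(X)) abort("too few observations for the serial chain design")
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    dropped <- colnames(X)[qr_x$pivot[(qr_x$rank + 1L):ncol(X)]]
    abort(paste0("singular design; collinear column(s): ",
                 paste(dropped, collapse = ", ")))
  }
}

#' Fit a serial mediation chain by ordinary least squares
#'
#' For a path X -> M1 -> ... -> Mk -> Y, fits with covariates in every
#' equation: each mediator on the exposure and all earlier mediators, the
#' outcome on the exposure and all mediators (giving the direct effect),
#' and the outcome on the exposure alone (giving the total effect).  The
#' serial chain coefficients are a1 (X -> M1), d_j (M_{j-1} -> M_j) and
#' b_k (M_k -> Y).
#'
#' @param data data frame containing the path variables (and covariates).
#' @param path ordered character vector of column names, exposure first,
#'   outcome last, length >= 3.
#' @param covariates `NULL`, a character vector of column names in
#'   `data`, or a numeric matrix.
#' @return object of class `serial_chain_fit` with elements `chain`
#'   (named coefficients along the chain), `de`, `te`, `path`, `n`.
#' @export
fit_serial_chain <- function(data, path, covariates = NULL) {
  data <- as.data.frame(data)
  if (length(path) < 3L) abort("path must have >= 3 nodes (>= 1 mediator)")
  if (!all(path %in% names(data))) {
    abort(paste0("path nodes absent from data: ",
                 paste(setdiff(path, names(data)), collapse = ", ")))
  }
  Z <- resolve_covariates(data, covariates)
  x <- path[[1L]]
  y <- path[[length(path)]]
  meds <- path[-c(1L, length(path))]
  k <- length(meds)
  n <- nrow(data)

  chain <- numeric(k + 1L)
  names(chain) <- paste(path[-length(path)], path[-1L], sep = "->")
  for (m in seq_len(k)) {
    pred <- c(x, meds[seq_len(m - 1L)])
    X <- .design(data, pred, Z)
    .check_full_rank(X, n)
    cf <- qr.coef(qr(X), data[[meds[m]]])
    # chain coefficient: effect of the immediately preceding node
    chain[m] <- cf[[if (m == 1L) x else meds[m - 1L]]]
  }
  X_out <- .design(data, c(x, meds), Z)
  .check_full_rank(X_out, n)
  cf_out <- qr.coef(qr(X_out), data[[y]])
  chain[k + 1L] <- cf_out[[meds[k]]]
  de <- cf_out[[x]]
  X_red <- .design(data, x, Z)
  te <- qr.coef(qr(X_red), data[[y]])[[x]]

  structure(list(chain = chain, de = de, te = te, path = path,
                 k = k, n = n),
            class = "serial_chain_fit")
}

resolve_covariates <- function(data, covariates) {
  if (is.null(covariates)) return(NULL)
  if (is.character(covariates)) {
    miss <- setdiff(covariates, names(data))
    if (length(miss)) abort(paste0("covariates absent from data: ",
                                   paste(miss, collapse = ", ")))
    return(as.matrix(data[, covariates, drop = FALSE]))
  }
  as.matrix(covariates)
}

#' Serial indirect effect
#'
#' Product of the chained coefficients a1 * d_2 * ... * b_k.
#'
#' @param coefficients a `serial_chain_fit` or a numeric vector of chain
#'   coefficients.
#' @return scalar indirect effect.
#' @export
serial_ide <- function(coefficients) {
  if (inherits(coefficients, "serial_chain_fit")) {
    coefficients <- coefficients$chain
  }
  if (!length(coefficients)) abort("empty coefficient chain")
  prod(coefficients)
}

#' Bootstrap inference for a serial mediation pathway
#'
#' Resamples individuals with replacement, recomputes the serial indirect
#' effect per replicate, and reports the bootstrap standard error, the
#' percentile confidence interval, and a two-sided normal-approximation
#' p-value `2 * pnorm(-|ide| / se)`.  The proportion mediated is
#' `ide / te` (total-effect denominator), which may be negative or exceed
#' one.  Point estimates come from the full-sample fit and do not depend
#' on `n_boot`.  Replicates whose design becomes singular are dropped and
#' counted; more than 10% failures is an error.
#'
#' @inheritParams fit_serial_chain
#' @param n_boot number of bootstrap replicates (>= 100, default 1000).
#' @param seed integer RNG seed; results are bitwise reproducible given
#'   (data, seed, n_boot).
#' @param conf_level confidence level for the percentile interval.
#' @param keep_boot if `TRUE`, store the replicate IDE values.
#' @return object of class `smm_fit`; see [tidy.smm_fit()] for the
#'   one-row tibble view.
#' @export
bootstrap_smm <- function(data, path, covariates = NULL, n_boot = 1000L,
                          seed = 1L, conf_level = 0.95, keep_boot = FALSE) {
  if (n_boot < 100L) abort("n_boot must be >= 100")
  data <- as.data.frame(data)
  fit <- fit_serial_chain(data, path, covariates)
  Z <- resolve_covariates(data, covariates)
  n <- nrow(data)
  x <- path[[1L]]; y <- path[[length(path)]]
  meds <- path[-c(1L, length(path))]
  k <- length(meds)

  # prebuild design matrices / outcomes; per replicate only rows change
  designs <- vector("list", k + 1L)
  outcomes <- vector("list", k + 1L)
  coef_pos <- integer(k + 1L)
  for (m in seq_len(k)) {
    X <- .design(data, c(x, meds[seq_len(m - 1L)]), Z)
    designs[[m]] <- X
    outcomes[[m]] <- data[[meds[m]]]
    coef_pos[m] <- which(colnames(X) == if (m == 1L) x else meds[m - 1L])
  }
  X_out <- .design(data, c(x, meds), Z)
  designs[[k + 1L]] <- X_out
  outcomes[[k + 1L]] <- data[[y]]
  coef_pos[k + 1L] <- which(colnames(X_out) == meds[k])

  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(r) {
      idx <- sample.int(n, n, replace = TRUE)
      out <- 1
      for (e in seq_len(k + 1L)) {
        cf <- tryCatch(
          .lm.fit(designs[[e]][idx, , drop = FALSE],
                  outcomes[[e]][idx])$coefficients,
          error = function(err) NULL
        )
        if (is.null(cf) || anyNA(cf)) return(NA_real_)
        out <- out * cf[coef_pos[e]]
      }
      out
    }, numeric(1))
  })
  n_failed <- sum(is.na(boots))
  if (n_failed > 0.1 * n_boot) {
    abort(paste0("unstable fit: ", n_failed, "/", n_boot,
                 " bootstrap replicates failed"))
  }
  bb <- boots[!is.na(boots)]
  ide <- serial_ide(fit)
  se <- sd(bb)
  alpha <- (1 - conf_level) / 2
  ci <- unname(quantile(bb, c(alpha, 1 - alpha)))
  p <- if (se > 0) .p_floor(2 * pnorm(-abs(ide) / se)) else .Machine$double.xmin
  pm <- if (abs(fit$te) > 1e-12) ide / fit$te else NA_real_

  out <- list(path = path, fit = fit, ide = ide, de = fit$de, te = fit$te,
              pm = pm, ide_se = se, ide_ci = ci, p_ide = p,
              conf_level = conf_level, n_boot = n_boot, n_failed = n_failed,
              seed = seed, n = n)
  if (keep_boot) out$boot <- boots
  structure(out, class = "smm_fit")
}

#' @export
print.smm_fit <- function(x, ...) {
  cat("<smm_fit>", path_to_string(x$path), "\n")
  cat(sprintf("  IDE %.4g (%.4g, %.4g); p = %.3g; DE %.4g; TE %.4g; PM %.1f%%\n",
              x$ide, x$ide_ci[1], x$ide_ci[2], x$p_ide, x$de, x$te,
              100 * x$pm))
  invisible(x)
}

#' @rdname bootstrap_smm
#' @param x an `smm_fit`.
#' @param ... unused.
#' @export
tidy.smm_fit <- function(x, ...) {
  tibble(
    path = path_to_string(x$path),
    n_nodes = length(x$path),
    ide = x$ide, de = x$de, te = x$te, pm = x$pm,
    ide_se = x$ide_se, ci_low = x$ide_ci[1], ci_high = x$ide_ci[2],
    p_ide = x$p_ide, n_boot = x$n_boot, n_failed = x$n_failed,
    seed = x$seed, n = x$n
  )
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment with enforced monotonicity,
#' capped at 1 (a thin validating wrapper over `stats::p.adjust`).
#'
#' @param pvalues numeric vector with all values in (0, 1].
#' @return adjusted p-values, elementwise >= input.
#' @export
bh_adjust <- function(pvalues) {
  if (!length(pvalues)) return(numeric(0))
  if (any(is.na(pvalues)) || any(pvalues <= 0 | pvalues > 1)) {
    abort("pvalues must lie in (0, 1]")
  }
  p.adjust(pvalues, method = "BH")
}

#' Discovery and replication of mediation pathways
#'
#' Stage 1 (discovery): every candidate path is bootstrap-tested on the
#' training data; IDE p-values are BH-adjusted within each analysis
#' family (e.g. fasting-network and 1-hr-network paths separately), and
#' paths with adjusted p below `alpha_fdr` and positive proportion
#' mediated are retained.  Stage 2 (replication): survivors are refit on
#' the validation data and replicate iff the nominal IDE p-value is below
#' `alpha_nominal` with positive proportion mediated.
#'
#' @param paths candidate paths: a list of node-id vectors, a character
#'   vector of `;`-joined paths, or a tibble with a `path_str` (or
#'   `path`) column and optional `family` column for the FDR families.
#' @param train,validation training and validation data (data frames or
#'   `trio_cohort`s); must be disjoint samples.
#' @param covariates as in [fit_serial_chain()] (column names must exist
#'   in both data sets).
#' @param alpha_fdr FDR threshold for discovery (default 0.05).
#' @param alpha_nominal nominal threshold for replication (default 0.05).
#' @param n_boot,seed bootstrap settings; path i uses seed `seed + i` in
#'   training and `seed + 10000 + i` in validation.
#' @param require_positive_pm require PM > 0 at both stages (default).
#' @return object of class `smm_report` with tibbles `training` (all
#'   candidates, `discovered` flag) and `validation` (refitted survivors,
#'   `validated` flag).
#' @export
discover_and_validate <- function(paths, train, validation, covariates = NULL,
                                  alpha_fdr = 0.05, alpha_nominal = 0.05,
                                  n_boot = 1000L, seed = 1L,
                                  require_positive_pm = TRUE) {
  pl <- normalize_paths(paths)
  train <- as.data.frame(train)
  validation <- as.data.frame(validation)
  params <- list(alpha_fdr = alpha_fdr, alpha_nominal = alpha_nominal,
                 n_boot = n_boot, seed = seed,
                 require_positive_pm = require_positive_pm)

  if (!nrow(pl)) {
    empty <- tibble()
    return(structure(list(training = empty, validation = empty,
                          params = params), class = "smm_report"))
  }

  stage1 <- bind_rows(lapply(seq_len(nrow(pl)), function(i) {
    res <- tidy(bootstrap_smm(train, pl$path[[i]], covariates,
                              n_boot = n_boot, seed = seed + i))
    res$family <- pl$family[[i]]
    res
  }))
  stage1 <- stage1 |>
    group_by(.data$family) |>
    mutate(p_adjusted = bh_adjust(.data$p_ide)) |>
    ungroup() |>
    mutate(discovered = .data$p_adjusted < alpha_fdr &
             (!require_positive_pm | (!is.na(.data$pm) & .data$pm > 0)))

  surv <- which(stage1$discovered)
  stage2 <- if (length(surv)) {
    bind_rows(lapply(surv, function(i) {
      res <- tidy(bootstrap_smm(validation, pl$path[[i]], covariates,
                                n_boot = n_boot, seed = seed + 10000L + i))
      res$family <- pl$family[[i]]
      res
    })) |>
      mutate(validated = .data$p_ide < alpha_nominal &
               (!require_positive_pm | (!is.na(.data$pm) & .data$pm > 0)))
  } else {
    tibble()
  }
  structure(list(training = stage1, validation = stage2, params = params),
            class = "smm_report")
}

normalize_paths <- function(paths) {
  if (inherits(paths, "data.frame")) {
    tb <- as_tibble(paths)
    pcol <- if ("path" %in% names(tb) && is.list(tb$path)) tb$path
    else if ("path_str" %in% names(tb)) lapply(tb$path_str, string_to_path)
    else lapply(tb$path, string_to_path)
    fam <- if ("family" %in% names(tb)) as.character(tb$family)
    else rep("all", nrow(tb))
    tibble(path = pcol, family = fam)
  } else if (is.character(paths)) {
    tibble(path = lapply(paths, string_to_path), family = "all")
  } else {
    tibble(path = lapply(paths, as.character), family = "all")
  }
}

#' @export
print.smm_report <- function(x, ...) {
  nd <- if (nrow(x$training)) sum(x$training$discovered) else 0L
  nv <- if (nrow(x$validation)) sum(x$validation$validated) else 0L
  cat("<smm_report>", nrow(x$training), "candidate paths;",
      nd, "discovered;", nv, "validated\n")
  invisible(x)
}

#' @rdname discover_and_validate
#' @param x an `smm_report`.
#' @param stage `"validation"` (default) or `"training"`.
#' @param ... unused.
#' @export
tidy.smm_report <- function(x, stage = c("validation", "training"), ...) {
  stage <- match.arg(stage)
  x[[stage]]
}

#' @rdname discover_and_validate
#' @export
glance.smm_report <- function(x, ...) {
  tibble(
    n_candidates = nrow(x$training),
    n_discovered = if (nrow(x$training)) sum(x$training$discovered) else 0L,
    n_validated = if (nrow(x$validation)) sum(x$validation$validated) else 0L,
    alpha_fdr = x$params$alpha_fdr,
    alpha_nominal = x$params$alpha_nominal,
    n_boot = x$params$n_boot
  )
}
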