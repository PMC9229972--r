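# End-to-end pipeline: simulate -> scan -> learn -> paths -> mediate ->
# report, with a YAML-serializable configuration and a reproducibility
# manifest.

#' Pipeline configuration
#'
#' Collects every tunable of the pipeline with the study defaults:
#' association threshold 10^-7.5, LD r-squared 0.5, penalty grid
#' 15 ... 1, minimum path length 3 nodes, two-thirds training split, FDR
#' 0.05 at discovery and nominal 0.05 at replication.  All randomness
#' flows from the named per-stage seeds.
#'
#' @param model generative model name (`"example"` or `"benchmark"`) or a
#'   [true_model()] object.
#' @param n_pairs cohort size to simulate.
#' @param n_covariates number of simulated covariates.
#' @param p_threshold association-scan retention threshold.
#' @param ld_r2 LD-trimming r-squared threshold.
#' @param lambdas penalty grid (strictly decreasing).
#' @param penalty,gamma penalty family and MCP concavity.
#' @param min_nodes minimum nodes per candidate path.
#' @param n_boot bootstrap replicates for mediation.
#' @param alpha_fdr,alpha_nominal discovery and replication thresholds.
#' @param train_fraction training fraction of the stratified split.
#' @param families metabolite timepoint families to analyse.
#' @param transforms named character vector mapping phenotype columns to
#'   `"identity"`, `"log10"` or `"sqrt"`.
#' @param seeds named list of per-stage integer seeds.
#' @param stages named list of logical stage toggles.
#' @param plot write PNG network frames (default `FALSE`).
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(model = "example",
                            n_pairs = 600L,
                            n_covariates = 2L,
                            p_threshold = 10^-7.5,
                            ld_r2 = 0.5,
                            lambdas = 15:1,
                            penalty = "mcp",
                            gamma = 2,
                            min_nodes = 3L,
                            n_boot = 1000L,
                            alpha_fdr = 0.05,
                            alpha_nominal = 0.05,
                            train_fraction = 2 / 3,
                            families = c("fasting", "1hr"),
                            transforms = character(0),
                            seeds = list(simulate = 1L, split = 2L,
                                         mediate = 3L),
                            stages = list(simulate = TRUE, scan = TRUE,
                                          learn = TRUE, paths = TRUE,
                                          mediate = TRUE, report = TRUE),
                            plot = FALSE) {
  cfg <- list(model = model, n_pairs = as.integer(n_pairs),
              n_covariates = as.integer(n_covariates),
              p_threshold = p_threshold, ld_r2 = ld_r2,
              lambdas = as.numeric(lambdas), penalty = penalty,
              gamma = gamma, min_nodes = as.integer(min_nodes),
              n_boot = as.integer(n_boot), alpha_fdr = alpha_fdr,
              alpha_nominal = alpha_nominal,
              train_fraction = train_fraction,
              families = families, transforms = transforms,
              seeds = seeds, stages = stages, plot = plot)
  validate_pipeline_config(cfg)
}

validate_pipeline_config <- function(cfg) {
  stopifnot(
    cfg$p_threshold > 0, cfg$p_threshold <= 1,
    cfg$ld_r2 > 0, cfg$ld_r2 <= 1,
    cfg$min_nodes >= 2L,
    cfg$train_fraction > 0, cfg$train_fraction < 1,
    cfg$n_boot >= 100L,
    all(cfg$families %in% c("fasting", "1hr")),
    all(unlist(cfg$transforms) %in% c("identity", "log10", "sqrt")),
    all(c("simulate", "split", "mediate") %in% names(cfg$seeds))
  )
  if (length(cfg$lambdas) > 1L && any(diff(cfg$lambdas) >= 0)) {
    abort("lambdas must be strictly decreasing")
  }
  cfg$penalty <- match.arg(cfg$penalty, c("mcp", "l1"))
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  base <- pipeline_config()
  for (nm in names(raw)) base[[nm]] <- raw[[nm]]
  base$transforms <- unlist(base$transforms) %||% character(0)
  validate_pipeline_config(base)
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  cfg <- unclass(config)
  if (inherits(cfg$model, "true_model")) {
    abort("only named builtin models serialize to YAML")
  }
  cfg$transforms <- as.list(cfg$transforms)
  yaml::write_yaml(cfg, path, precision = 15L)
  invisible(path)
}

resolve_model <- function(model) {
  if (inherits(model, "true_model")) return(model)
  switch(model,
         example = example_true_model(),
         benchmark = trio_benchmark_model(),
         abort(paste0("unknown model name: ", model)))
}

apply_transforms <- function(df, transforms) {
  for (nm in names(transforms)) {
    if (!nm %in% names(df)) next
    df[[nm]] <- switch(transforms[[nm]],
                       identity = df[[nm]],
                       log10 = log10(df[[nm]]),
                       sqrt = sqrt(df[[nm]]))
  }
  df
}

#' Run the full pipeline
#'
#' Simulates (or accepts) a cohort, splits it by stratified sampling,
#' scans SNP-metabolite associations on the combined data with LD
#' trimming, estimates one penalized Bayesian network solution path per
#' metabolite timepoint family on the training data, extracts candidate
#' mediation pathways from the least-stringent network, runs the
#' bootstrap serial-mediation discovery/replication protocol, and writes
#' all artifacts plus a manifest of seeds and file hashes to `out_dir`.
#' Outputs contain no timestamps, so a rerun with the same configuration
#' is byte-identical.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @param cohort optional pre-built `trio_cohort` (skips simulation).
#' @return invisibly, a list with the cohort, per-family results and the
#'   manifest path.
#' @export
run_pipeline <- function(config, out_dir, cohort = NULL) {
  config <- validate_pipeline_config(unclass(config))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_msg <- function(stage, ...) {
    message("[", stage, "] ", ...)
  }
  run_stage <- function(stage, code) {
    tryCatch(code, error = function(e) {
      abort(paste0("pipeline stage '", stage, "' failed: ",
                   conditionMessage(e)))
    })
  }

  model <- resolve_model(config$model)
  if (is.null(cohort)) {
    log_msg("simulate", "n_pairs = ", config$n_pairs,
            " (seed ", config$seeds$simulate, ")")
    cohort <- run_stage("simulate",
                        simulate_cohort(model, config$n_pairs,
                                        seed = config$seeds$simulate,
                                        n_covariates = config$n_covariates))
  }
  meta_all <- cohort$node_meta

  log_msg("split", "train_fraction = ", round(config$train_fraction, 4),
          " (seed ", config$seeds$split, ")")
  sp <- run_stage("split",
                  split_train_validation(cohort, config$train_fraction,
                                         seed = config$seeds$split))
  train_df <- as.data.frame(sp$train)
  valid_df <- as.data.frame(sp$validation)
  covar_cols <- colnames(cohort$covariates)

  # association scans on the combined data (training + validation)
  full_df <- as.data.frame(cohort)
  selected_snps <- list()
  scans <- list()
  if (isTRUE(config$stages$scan)) {
    scan_one <- function(geno, metab, label) {
      if (!ncol(geno) || !ncol(metab)) return(NULL)
      log_msg("scan", label, ": ", ncol(geno), " SNPs x ", ncol(metab),
              " metabolites")
      sc <- run_metabotype_scan(geno, metab, cohort$covariates,
                                p_threshold = config$p_threshold,
                                keep_all = TRUE)
      readr::write_tsv(sc, file.path(out_dir, paste0("scan_", label, ".tsv")))
      hits <- filter(sc, .data$significant)
      kept <- unique(unlist(lapply(split(hits, hits$metabolite_id),
                                   function(h) ld_trim(h, geno, config$ld_r2))))
      scans[[label]] <<- sc
      kept
    }
    selected_snps$fasting <- run_stage("scan", scan_one(
      cohort$maternal_genotypes, cohort$maternal_metabolites_fasting,
      "maternal_fasting"))
    selected_snps$`1hr` <- run_stage("scan", scan_one(
      cohort$maternal_genotypes, cohort$maternal_metabolites_1hr,
      "maternal_1hr"))
    selected_snps$cord <- run_stage("scan", scan_one(
      cohort$offspring_genotypes, cohort$cord_metabolites, "cord"))
  } else {
    selected_snps$fasting <- colnames(cohort$maternal_genotypes)
    selected_snps$`1hr` <- colnames(cohort$maternal_genotypes)
    selected_snps$cord <- colnames(cohort$offspring_genotypes)
  }

  results <- list()
  for (fam in config$families) {
    mm_cols <- colnames(if (fam == "fasting") {
      cohort$maternal_metabolites_fasting
    } else cohort$maternal_metabolites_1hr)
    if (!length(mm_cols)) next
    snps <- unique(c(selected_snps[[fam]], selected_snps$cord))
    node_ids <- c(snps, mm_cols, colnames(cohort$cord_metabolites),
                  colnames(cohort$phenotypes))
    fam_meta <- meta_all[match(node_ids, meta_all$node_id), ]
    fam_meta <- fam_meta[!is.na(fam_meta$node_id), ]
    tr <- apply_transforms(train_df, config$transforms)
    va <- apply_transforms(valid_df, config$transforms)

    fam_res <- list(meta = fam_meta)
    if (isTRUE(config$stages$learn)) {
      log_msg("learn", fam, " family: ", nrow(fam_meta), " nodes, lambda ",
              max(config$lambdas), " -> ", min(config$lambdas))
      spath <- run_stage("learn", learn_solution_path(
        tr[, fam_meta$node_id, drop = FALSE], fam_meta,
        lambdas = config$lambdas, penalty = config$penalty,
        gamma = config$gamma))
      fam_res$solution_path <- spath
      readr::write_tsv(tidy(spath),
                       file.path(out_dir, paste0("edges_", fam, ".tsv")))

      if (isTRUE(config$stages$report)) {
        tall <- bind_rows(lapply(spath$models, tally_edges_by_type))
        readr::write_tsv(tall,
                         file.path(out_dir, paste0("tally_", fam, ".tsv")))
        frames <- run_stage("report", export_growth_frames(
          spath, out_dir = file.path(out_dir, paste0("frames_", fam)),
          plot = isTRUE(config$plot)))
        jsonlite::write_json(
          glance(spath), file.path(out_dir, paste0("summary_", fam, ".json")),
          auto_unbox = TRUE, digits = NA, pretty = TRUE)
        fam_res$frames <- frames
      }

      if (isTRUE(config$stages$paths)) {
        dag_min <- spath$models[[as.character(min(config$lambdas))]]
        cand <- run_stage("paths",
                          extract_candidates(dag_min, fam_meta,
                                             min_nodes = config$min_nodes))
        log_msg("paths", fam, ": ", nrow(cand), " candidate pathway(s)")
        readr::write_tsv(select(cand, -"path"),
                         file.path(out_dir, paste0("paths_", fam, ".tsv")))
        fam_res$candidates <- cand

        if (isTRUE(config$stages$mediate) && nrow(cand)) {
          cand$family <- fam
          rep <- run_stage("mediate", discover_and_validate(
            cand, tr, va, covariates = covar_cols,
            alpha_fdr = config$alpha_fdr,
            alpha_nominal = config$alpha_nominal,
            n_boot = config$n_boot, seed = config$seeds$mediate))
          readr::write_tsv(tidy(rep, "training"),
                           file.path(out_dir,
                                     paste0("mediation_training_", fam, ".tsv")))
          if (nrow(rep$validation)) {
            readr::write_tsv(tidy(rep, "validation"),
                             file.path(out_dir,
                                       paste0("mediation_validation_", fam,
                                              ".tsv")))
          }
          fam_res$mediation <- rep
        }
      }
    }
    results[[fam]] <- fam_res
  }

  manifest <- list(
    package = "triomics",
    version = as.character(utils::packageVersion("triomics")),
    config = unclass(config)[setdiff(names(config), "model")],
    model = if (inherits(config$model, "true_model")) "<custom>"
    else config$model,
    files = {
      fs <- sort(setdiff(list.files(out_dir, recursive = TRUE),
                         "manifest.json"))
      setNames(as.list(unname(tools::md5sum(file.path(out_dir, fs)))), fs)
    }
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(cohort = cohort, split = sp, results = results,
                 manifest = manifest_path))
}
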