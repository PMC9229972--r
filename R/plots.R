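# ggplot2 displays for scans, solution paths and mediation reports.

node_palette <- function() {
  c("genotype" = "#2e7d32", "outcome" = "grey55", "phenotype" = "grey20",
    "AA" = "#d32f2f", "AC" = "#1565c0", "CHO" = "#ef6c00", "FA" = "#6a1b9a",
    "GC/TCA" = "#6d4c41", "OA" = "#c2185b", "PUR/PYR" = "#00838f",
    "other" = "#9e9d24")
}

node_color_key <- function(meta) {
  dplyr::case_when(
    meta$node_type %in% snp_types() ~ "genotype",
    meta$role == "outcome" ~ "outcome",
    meta$node_type %in% c("MP", "NP") ~ "phenotype",
    !is.na(meta$metabolite_class) ~ meta$metabolite_class,
    TRUE ~ "other"
  )
}

# single network frame at fixed coordinates (internal, used by
# export_growth_frames)
plot_dag_frame <- function(dag, meta, coords, title = NULL) {
  nodes <- as_tibble(meta) |>
    filter(.data$node_id %in% rownames(coords)) |>
    mutate(x = coords[.data$node_id, 1],
           y = coords[.data$node_id, 2],
           colour_key = node_color_key(.data),
           maternal = .data$node_type %in% maternal_types())
  edges <- dag$edges |>
    mutate(x = coords[.data$from, 1], y = coords[.data$from, 2],
           xend = coords[.data$to, 1], yend = coords[.data$to, 2])
  gg <- ggplot2::ggplot()
  if (nrow(edges)) {
    gg <- gg + ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x, y = .data$y,
                   xend = .data$xend, yend = .data$yend),
      arrow = grid::arrow(length = grid::unit(5, "pt"), type = "closed"),
      colour = "grey40", linewidth = 0.3, alpha = 0.7)
  }
  gg +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, colour = .data$colour_key,
                   shape = .data$maternal), size = 2.6) +
    ggplot2::scale_colour_manual(values = node_palette(), name = NULL) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 15, `FALSE` = 16),
                                labels = c(`TRUE` = "maternal",
                                           `FALSE` = "offspring"),
                                name = NULL) +
    ggplot2::labs(title = title) +
    ggplot2::theme_void()
}

#' Network growth over the penalty path
#'
#' Edge count and connected-node count against the penalty value, most
#' stringent penalty on the left.
#'
#' @param object a `solution_path`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.solution_path <- function(object, ...) {
  gl <- glance(object) |>
    tidyr::pivot_longer(c("n_edges", "n_connected_nodes"),
                        names_to = "measure", values_to = "count") |>
    mutate(measure = dplyr::recode(.data$measure,
                                   n_edges = "edges",
                                   n_connected_nodes = "connected nodes"))
  ggplot2::ggplot(gl, ggplot2::aes(x = .data$lambda, y = .data$count,
                                   colour = .data$measure)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_reverse(breaks = sort(object$lambdas)) +
    ggplot2::labs(x = expression(lambda ~ "(penalty, most stringent left)"),
                  y = "count", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Association-scan p-value plot
#'
#' Minimal -log10(p) scatter of scan records by SNP index, colored by
#' metabolite, with the retention threshold marked.
#'
#' @param scan tibble from [run_metabotype_scan()] (use `keep_all = TRUE`
#'   for the full picture).
#' @param p_threshold threshold line (default 10^-7.5).
#' @return a ggplot.
#' @export
plot_scan <- function(scan, p_threshold = 10^-7.5) {
  scan <- as_tibble(scan) |>
    mutate(snp_index = as.integer(factor(.data$snp_id)))
  ggplot2::ggplot(scan, ggplot2::aes(x = .data$snp_index,
                                     y = -log10(.data$p),
                                     colour = .data$metabolite_id)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_hline(yintercept = -log10(p_threshold),
                        colour = "red", linetype = 2) +
    ggplot2::labs(x = "SNP", y = expression(-log[10](p)), colour = NULL) +
    ggplot2::theme_minimal()
}

#' Forest plot of mediation results
#'
#' Indirect effects and bootstrap confidence intervals per candidate
#' path, facetted by stage when validation results exist.
#'
#' @param object an `smm_report`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.smm_report <- function(object, ...) {
  tr <- mutate(object$training, stage = "training")
  va <- if (nrow(object$validation)) {
    mutate(object$validation, stage = "validation")
  } else NULL
  dat <- bind_rows(tr, va)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$ide, y = .data$path)) +
    ggplot2::geom_vline(xintercept = 0, colour = "grey70") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high),
                            height = 0.2) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~stage) +
    ggplot2::labs(x = "indirect effect (bootstrap 95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}
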