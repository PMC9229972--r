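# Shared fixture builders (everything is generated in code at test time).

# a weighted_dag-shaped object without running the learner
make_wdag <- function(meta, edges, lambda = 1) {
  edges <- tibble::as_tibble(edges)
  if (!"weight" %in% names(edges)) edges$weight <- 0.5
  structure(
    list(nodes = meta, edges = edges,
         node_noise_var = setNames(rep(1, nrow(meta)), meta$node_id),
         lambda = lambda, penalty = "mcp", gamma = 2,
         n = NA_integer_, converged = TRUE, score = NA_real_),
    class = "weighted_dag"
  )
}

# random typed node metadata; SNP nodes get one of two chromosomes
rand_typed_meta <- function(p, seed) {
  set.seed(seed)
  types <- sample(c("MG", "MM", "MP", "NG", "NM", "NP"), p, replace = TRUE)
  node_meta(
    node_id = sprintf("n%02d", seq_len(p)),
    node_type = types,
    timepoint = ifelse(types == "MM", "fasting",
                       ifelse(types == "NM", "cord", "none")),
    chromosome = ifelse(types %in% c("MG", "NG"),
                        sample(c("2", "10"), p, replace = TRUE), NA),
    metabolite_class = ifelse(types %in% c("MM", "NM"),
                              sample(c("AA", "AC", "OA"), p, replace = TRUE),
                              NA),
    role = ifelse(types == "NP", "outcome",
                  ifelse(types == "MP", "exposure", "intermediate"))
  )
}

# random blocklist-respecting DAG over typed nodes (edge list)
rand_typed_dag <- function(p, seed, edge_prob = 0.25) {
  meta <- rand_typed_meta(p, seed)
  bl <- build_blocklist(meta)
  set.seed(seed + 1000L)
  ord <- sample(meta$node_id)  # topological order
  edges <- list()
  for (a in seq_len(p - 1L)) {
    for (b in (a + 1L):p) {
      if (runif(1) < edge_prob &&
          !edge_blocked(bl, ord[a], ord[b], meta)) {
        edges[[length(edges) + 1L]] <-
          tibble::tibble(from = ord[a], to = ord[b],
                         weight = round(runif(1, 0.3, 1), 3))
      }
    }
  }
  edges <- if (length(edges)) dplyr::bind_rows(edges) else
    tibble::tibble(from = character(0), to = character(0),
                   weight = numeric(0))
  list(meta = meta, edges = edges, dag = make_wdag(meta, edges))
}

# random typed linear-Gaussian true model for learner invariant tests
rand_true_model <- function(p, seed, coef = 0.7) {
  td <- rand_typed_dag(p, seed, edge_prob = 0.3)
  snp <- td$meta$node_id[td$meta$node_type %in% c("MG", "NG")]
  non_snp <- setdiff(td$meta$node_id, snp)
  edges <- td$edges
  # drop edges into SNP nodes except maternal->offspring transmission
  keep <- !(edges$to %in% snp)
  trans <- edges$to %in% snp & edges$from %in% snp
  edges <- edges[keep | trans, , drop = FALSE]
  edges$coef <- ifelse(edges$to %in% snp, 0.5,
                       sample(c(-coef, coef), nrow(edges), replace = TRUE))
  true_model(
    td$meta, edges[, c("from", "to", "coef")],
    noise_sd = setNames(rep(1, length(non_snp)), non_snp),
    maf = setNames(runif(length(snp), 0.2, 0.5), snp)
  )
}
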