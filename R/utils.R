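# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# All user-facing randomness flows through this so results are reproducible
# given (inputs, seed) and independent of ambient RNG state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Column standardization to zero mean / unit variance, with variance
# computed with denominator n so that crossprod(xs)/n has unit diagonal.
standardize_cols <- function(x) {
  x <- as.matrix(x)
  if (!is.numeric(x)) abort("data must be numeric")
  if (anyNA(x) || any(!is.finite(x))) abort("data contains missing or non-finite values")
  n <- nrow(x)
  mu <- colMeans(x)
  xc <- sweep(x, 2L, mu, "-")
  s <- sqrt(colSums(xc^2) / n)
  bad <- s < 1e-12
  if (any(bad)) {
    abort(paste0("constant column(s): ",
                 paste(colnames(x)[bad] %||% which(bad), collapse = ", ")))
  }
  xs <- sweep(xc, 2L, s, "/")
  attr(xs, "center") <- mu
  attr(xs, "scale") <- s
  xs
}

# smallest representable p-value; used to keep p in (0, 1]
.p_floor <- function(p) pmax(p, .Machine$double.xmin)

path_to_string <- function(path) paste(path, collapse = ";")

string_to_path <- function(s) strsplit(s, ";", fixed = TRUE)[[1]]
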