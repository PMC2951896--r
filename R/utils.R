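# Internal helpers shared across modules.

# Run `code` with the RNG seeded, restoring the caller's RNG state afterwards
# so seeded stages never perturb each other or the user's session.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else {
      suppressWarnings(rm(".Random.seed", envir = globalenv()))
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministic per-stage seed derived from a global seed and a stage name:
# adding a stage never perturbs another stage's random stream.
stage_seed <- function(seed, stage) {
  codes <- utf8ToInt(stage)
  h <- sum(codes * seq_along(codes)) %% 100003L
  out <- ((as.numeric(seed) %% 100003) * 10007 + h) %% 2147483646
  as.integer(out) + 1L
}

# Clamp correlations into [-1, 1]; floating-point sums can overshoot by eps.
# In-place assignment keeps dims and dimnames intact.
clamp_cor <- function(r) {
  r[r > 1] <- 1
  r[r < -1] <- -1
  r
}

validate_expression_matrix <- function(m, what = "expression matrix") {
  if (!is.matrix(m) || !is.numeric(m)) {
    stop(what, " must be a numeric matrix", call. = FALSE)
  }
  if (nrow(m) < 1L || ncol(m) < 1L) {
    stop(what, " must have at least one gene and one condition", call. = FALSE)
  }
  if (anyNA(m) || any(!is.finite(m))) {
    stop(what, " contains missing or non-finite values", call. = FALSE)
  }
  if (any(m < 0)) {
    stop(what, " contains negative values; intensities must be >= 0",
         call. = FALSE)
  }
  if (is.null(rownames(m)) || anyDuplicated(rownames(m))) {
    stop(what, " must have unique gene identifiers as row names",
         call. = FALSE)
  }
  if (is.null(colnames(m)) || anyDuplicated(colnames(m))) {
    stop(what, " must have unique condition labels as column names",
         call. = FALSE)
  }
  invisible(m)
}

validate_pcm <- function(p, what = "PCM") {
  if (!is.matrix(p) || !is.numeric(p) || nrow(p) != ncol(p)) {
    stop(what, " must be a square numeric matrix", call. = FALSE)
  }
  if (anyNA(p) || any(p < -1 - 1e-8) || any(p > 1 + 1e-8)) {
    stop(what, " entries must be correlations in [-1, 1]", call. = FALSE)
  }
  invisible(p)
}

# Format numbers so that a text round-trip is exact (17 significant digits).
format_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "NA" else sprintf("%.17g", v)
  }, character(1))
  out
}
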