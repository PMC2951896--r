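#' Background distribution of correlations from random gene pairs
#'
#' Draws `n_pairs` ordered gene pairs (i, j), i != j, uniformly with
#' replacement from the rows of an expression matrix and records the Pearson
#' correlation of each pair's expression profiles over all conditions of
#' that species. The empirical distribution calibrates the significance
#' threshold for conserved co-expression ([correlation_threshold()]).
#' Draws hitting a constant (degenerate) profile are skipped and counted.
#'
#' @param m Expression matrix with >= 2 genes and >= 3 conditions.
#' @param n_pairs Number of random pairs to draw (default 20000).
#' @param seed Integer seed; the same seed reproduces the sample exactly.
#' @param species_tag Optional label recorded in the result.
#' @return An object of class `background_distribution`: list with `samples`
#'   (correlations in \[-1, 1\]), `n_pairs`, `n_degenerate`, `seed`,
#'   `species_tag`.
#' @export
background_correlations <- function(m, n_pairs = 20000L, seed,
                                    species_tag = "") {
  validate_expression_matrix(m)
  if (nrow(m) < 2L) stop("need at least 2 genes", call. = FALSE)
  if (ncol(m) < 3L) stop("need at least 3 conditions", call. = FALSE)
  stopifnot(n_pairs >= 0L)
  k <- nrow(m)
  t <- ncol(m)
  mu <- rowMeans(m)
  sds <- sqrt(rowSums((m - mu)^2) / (t - 1))
  nondeg <- sds > 0
  if (sum(nondeg) < 2L) {
    stop("fewer than 2 non-constant genes", call. = FALSE)
  }
  draws <- with_seed(seed, {
    i <- sample.int(k, n_pairs, replace = TRUE)
    j0 <- sample.int(k - 1L, n_pairs, replace = TRUE)
    list(i = i, j = j0 + (j0 >= i))     # skip j == i
  })
  ok <- nondeg[draws$i] & nondeg[draws$j]
  # row-standardize once so each correlation is a single inner product
  z <- (m - mu) / (sds * sqrt(t - 1))
  samples <- rowSums(z[draws$i[ok], , drop = FALSE] *
                     z[draws$j[ok], , drop = FALSE])
  structure(
    list(samples = clamp_cor(unname(samples)),
         n_pairs = as.integer(n_pairs),
         n_degenerate = sum(!ok),
         seed = seed,
         species_tag = species_tag),
    class = "background_distribution"
  )
}

#' @export
print.background_distribution <- function(x, ...) {
  cat("Background correlation distribution",
      if (nzchar(x$species_tag)) paste0("(", x$species_tag, ")"), "\n")
  cat("  draws:", x$n_pairs, " degenerate skipped:", x$n_degenerate, "\n")
  if (length(x$samples)) {
    cat(sprintf("  quantiles 0.95/0.975/0.99: %.3f / %.3f / %.3f\n",
                stats::quantile(x$samples, 0.95),
                stats::quantile(x$samples, 0.975),
                stats::quantile(x$samples, 0.99)))
  }
  invisible(x)
}

#' Correlation significance threshold from a background distribution
#'
#' Empirical quantile of the background correlation sample, using the
#' linear-interpolation definition (R's default type-7 quantile).
#'
#' @param bg A `background_distribution`.
#' @param x Quantile in \[0, 1\] (0.95, 0.975 and 0.99 are the conventional
#'   choices).
#' @return The threshold correlation.
#' @export
correlation_threshold <- function(bg, x) {
  stopifnot(inherits(bg, "background_distribution"))
  if (length(bg$samples) == 0L) {
    stop("background distribution is empty", call. = FALSE)
  }
  if (!is.numeric(x) || length(x) != 1L || x < 0 || x > 1) {
    stop("quantile x must be a single number in [0, 1]", call. = FALSE)
  }
  unname(stats::quantile(bg$samples, probs = x, type = 7, names = FALSE))
}

#' Identify conserved co-expression network (CCN) nodes
#'
#' Scans all unordered ortholog pairs {i, j}: the pair is a conserved
#' co-expression edge when its intra-species correlation exceeds the
#' species-specific background threshold strictly in both species
#' (`pcm_a[i, j] > thr_a` and `pcm_b[i, j] > thr_b`). Every ortholog
#' incident to at least one conserved edge is a CCN node; the node set is
#' Essien's reference ortholog set. Raising either threshold can only shrink
#' the node set, so node sets at increasing quantiles are nested.
#'
#' @param pcm_a,pcm_b Aligned k x k correlation matrices.
#' @param thr_a,thr_b Per-species correlation thresholds in \[-1, 1\]
#'   (from [correlation_threshold()]).
#' @param quantile_x Optional quantile used to derive the thresholds
#'   (recorded only).
#' @return An object of class `ccn_nodes`: list with `node_indices` (sorted),
#'   `threshold_a`, `threshold_b`, `quantile_x`, `n_conserved_edges`.
#' @export
identify_ccn_nodes <- function(pcm_a, pcm_b, thr_a, thr_b, quantile_x = NA) {
  check_pcm_pair(pcm_a, pcm_b)
  stopifnot(thr_a >= -1, thr_a <= 1, thr_b >= -1, thr_b <= 1)
  edge <- (pcm_a > thr_a) & (pcm_b > thr_b)
  diag(edge) <- FALSE
  edge <- edge | t(edge)     # symmetric edge criterion
  nodes <- which(rowSums(edge) > 0)
  structure(
    list(node_indices = as.integer(nodes),
         threshold_a = thr_a,
         threshold_b = thr_b,
         quantile_x = quantile_x,
         n_conserved_edges = sum(edge[upper.tri(edge)])),
    class = "ccn_nodes"
  )
}

#' @export
print.ccn_nodes <- function(x, ...) {
  cat("CCN nodes:", length(x$node_indices), "orthologs,",
      x$n_conserved_edges, "conserved edges\n")
  cat(sprintf("  thresholds: A > %.4f, B > %.4f (quantile %s)\n",
              x$threshold_a, x$threshold_b, format(x$quantile_x)))
  invisible(x)
}
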