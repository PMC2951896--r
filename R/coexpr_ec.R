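#' Pairwise correlation matrix over the ortholog reference set
#'
#' Converts a gene-by-condition expression matrix into the k x k matrix of
#' Pearson correlations between the expression profiles of every pair of
#' reference genes, computed over all conditions of that species. The
#' diagonal is set to exactly 1 and the matrix is exactly symmetric.
#'
#' Constant rows make the correlation undefined and signal a preprocessing
#' bug (run [drop_zero_variance()] first); they raise an error naming the
#' first offending gene.
#'
#' @param m Expression matrix with >= 3 conditions and no constant rows.
#' @return A k x k numeric correlation matrix with gene row/column names.
#' @export
pairwise_correlation_matrix <- function(m) {
  validate_expression_matrix(m)
  if (ncol(m) < 3L) {
    stop("need at least 3 conditions to correlate expression profiles",
         call. = FALSE)
  }
  rng <- apply(m, 1L, function(r) max(r) - min(r))
  if (any(rng == 0)) {
    stop("constant expression profile for gene '",
         rownames(m)[which(rng == 0)[1L]],
         "'; run drop_zero_variance() first", call. = FALSE)
  }
  p <- stats::cor(t(m))
  p <- (p + t(p)) / 2      # enforce exact symmetry
  diag(p) <- 1
  clamp_cor(p)
}

check_pcm_pair <- function(pcm_a, pcm_b) {
  validate_pcm(pcm_a, "pcm_a")
  if (!is.matrix(pcm_b) || nrow(pcm_b) != ncol(pcm_b)) {
    stop("pcm_b must be a square numeric matrix", call. = FALSE)
  }
  if (nrow(pcm_a) != nrow(pcm_b)) {
    stop("PCMs must have the same number of ortholog pairs (k mismatch)",
         call. = FALSE)
  }
  if (nrow(pcm_a) < 3L) {
    stop("need at least 3 ortholog pairs in the reference set", call. = FALSE)
  }
  invisible(NULL)
}

# Reference positions used for pair i: all other orthologs, or a restricted
# node set; self-exclusion because the diagonal carries no cross-species
# information. Ascending order fixes the summation order.
ref_positions <- function(i, k, node_indices = NULL, exclude_self = TRUE) {
  ref <- if (is.null(node_indices)) seq_len(k) else node_indices
  if (exclude_self) ref <- ref[ref != i]
  ref
}

row_cor <- function(x, y) {
  if (max(x) == min(x) || max(y) == min(y)) return(NA_real_)
  clamp_cor(stats::cor(x, y))
}

#' Whole-ortholog-set co-expression conservation
#'
#' Dutilh-style EC: the Pearson correlation between row i of the species-A
#' pairwise correlation matrix and row i of the species-B matrix, i.e. how
#' similarly gene i co-varies with the whole 1-1 ortholog reference set in
#' the two species. The self position (j = i) is excluded by default: both
#' diagonals are 1 by construction and carry no information.
#'
#' `pcm_b` need not be symmetric: the permuted-reference null
#' ([permute_reference_orthology()]) feeds a column-permuted matrix here.
#'
#' @param pcm_a,pcm_b k x k correlation matrices from
#'   [pairwise_correlation_matrix()], rows aligned to the same ortholog pairs.
#' @param exclude_self Drop position j = i from each row before correlating.
#' @return An `ec_result` with method `"dutilh"`.
#' @export
dutilh_ec <- function(pcm_a, pcm_b, exclude_self = TRUE) {
  check_pcm_pair(pcm_a, pcm_b)
  k <- nrow(pcm_a)
  ec <- rep(NA_real_, k)
  valid <- rep(FALSE, k)
  for (i in seq_len(k)) {
    ref <- ref_positions(i, k, exclude_self = exclude_self)
    r <- row_cor(pcm_a[i, ref], pcm_b[i, ref])
    if (!is.na(r)) {
      ec[i] <- r
      valid[i] <- TRUE
    }
  }
  ec_result("dutilh", ec = ec, valid = valid,
            params = list(exclude_self = exclude_self))
}

#' Weighted Pearson correlation
#'
#' Product-moment correlation with observation weights: weighted means,
#' variances and covariance, all computed with weights normalized to sum 1.
#' This is the elementary step of the iterative co-expression comparison
#' ([icc()]), where reference orthologs are weighted by their
#' previous-iteration EC.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @param w Nonnegative weights, not all zero.
#' @return The weighted correlation in \[-1, 1\], or `NA` when either
#'   weighted variance is zero (undefined correlation).
#' @export
weighted_pearson <- function(x, y, w) {
  n <- length(x)
  if (length(y) != n || length(w) != n) {
    stop("x, y and w must have equal length", call. = FALSE)
  }
  if (n < 3L) stop("need at least 3 observations", call. = FALSE)
  if (anyNA(x) || anyNA(y) || anyNA(w)) {
    stop("missing values are not allowed", call. = FALSE)
  }
  if (any(w < 0)) stop("weights must be nonnegative", call. = FALSE)
  sw <- sum(w)
  if (sw <= 0) stop("weights must not be all zero", call. = FALSE)
  w <- w / sw
  mx <- sum(w * x)
  my <- sum(w * y)
  vx <- sum(w * (x - mx)^2)
  vy <- sum(w * (y - my)^2)
  if (vx <= 0 || vy <= 0) return(NA_real_)
  clamp_cor(sum(w * (x - mx) * (y - my)) / sqrt(vx * vy))
}

icc_weights <- function(ec, valid, weight_floor, weight_transform) {
  w <- switch(weight_transform,
              clamp = pmax(ec, weight_floor),
              raw = ec,
              shifted = (ec + 1) / 2)
  w[!valid | is.na(w)] <- 0
  if (weight_transform == "raw" && any(w < 0)) {
    stop("raw weight transform produced negative weights; ",
         "use 'clamp' or 'shifted'", call. = FALSE)
  }
  w
}

#' Iterative comparison of co-expression (ICC)
#'
#' Tirosh-Barkai-style refinement of the whole-ortholog-set EC: reference
#' orthologs whose own expression is conserved should count more when
#' comparing co-expression rows across species. Iteration 0 computes EC with
#' uniform weights (identical to [dutilh_ec()]); each subsequent iteration
#' sets the weight of reference ortholog j from its previous-iteration EC and
#' recomputes every EC as a weighted Pearson correlation of the two PCM rows
#' (self position excluded). Iteration stops when the largest absolute EC
#' change drops below `tol`, or after `max_iter` iterations.
#'
#' Weight transforms: `"clamp"` (default) uses `max(EC, weight_floor)`, so
#' reference orthologs with negative EC get zero weight; `"shifted"` uses
#' `(EC + 1) / 2`; `"raw"` uses the EC itself and fails if any is negative.
#' Invalid ECs always get weight 0.
#'
#' @inheritParams dutilh_ec
#' @param tol Convergence tolerance on the max-norm of the EC change.
#' @param max_iter Maximum number of weighted iterations.
#' @param weight_floor Lower clamp for the `"clamp"` transform.
#' @param weight_transform One of `"clamp"`, `"raw"`, `"shifted"`.
#' @return An object of class `icc_fit`: list with `result` (an `ec_result`,
#'   method `"icc"`), `history` (data frame of per-iteration `max_delta`),
#'   `converged`, `n_iterations`, and `weights` (weights used in the final
#'   iteration, needed by the random-pairing null).
#' @export
icc <- function(pcm_a, pcm_b, tol = 1e-3, max_iter = 100L, weight_floor = 0,
                weight_transform = c("clamp", "raw", "shifted")) {
  weight_transform <- match.arg(weight_transform)
  stopifnot(tol > 0, max_iter >= 1L)
  check_pcm_pair(pcm_a, pcm_b)
  k <- nrow(pcm_a)

  it0 <- dutilh_ec(pcm_a, pcm_b)     # iteration 0: uniform weights
  ec_prev <- it0$ec
  valid <- it0$valid
  history <- data.frame(iteration = 0L, max_delta = NA_real_,
                        converged = FALSE)
  converged <- FALSE
  iter <- 0L
  w <- rep(1, k)
  while (!converged && iter < max_iter) {
    iter <- iter + 1L
    w <- icc_weights(ec_prev, valid, weight_floor, weight_transform)
    if (all(w <= 0)) {
      stop("ICC weight collapse: all reference weights are zero",
           call. = FALSE)
    }
    ec_new <- rep(NA_real_, k)
    valid_new <- rep(FALSE, k)
    for (i in seq_len(k)) {
      if (!valid[i]) next
      ref <- ref_positions(i, k)
      wi <- w[ref]
      if (sum(wi) <= 0) next
      r <- weighted_pearson(pcm_a[i, ref], pcm_b[i, ref], wi)
      if (!is.na(r)) {
        ec_new[i] <- r
        valid_new[i] <- TRUE
      }
    }
    both <- valid & valid_new
    max_delta <- if (any(both)) max(abs(ec_new[both] - ec_prev[both])) else 0
    converged <- max_delta < tol
    history <- rbind(history,
                     data.frame(iteration = iter, max_delta = max_delta,
                                converged = converged))
    ec_prev <- ec_new
    valid <- valid_new
  }
  result <- ec_result("icc", ec = ec_prev, valid = valid,
                      params = list(tol = tol, max_iter = max_iter,
                                    weight_floor = weight_floor,
                                    weight_transform = weight_transform,
                                    n_iterations = iter,
                                    converged = converged))
  structure(list(result = result, history = history, converged = converged,
                 n_iterations = iter, weights = w),
            class = "icc_fit")
}

#' @export
print.icc_fit <- function(x, ...) {
  cat("ICC fit:", x$n_iterations, "iteration(s),",
      if (x$converged) "converged" else "NOT converged", "\n")
  print(x$result)
  invisible(x)
}

#' CCN-restricted co-expression conservation
#'
#' Essien-style EC: like [dutilh_ec()] but the reference ortholog set is
#' restricted to the nodes of conserved co-expression networks
#' (see [identify_ccn_nodes()]), excluding the query pair itself when it is
#' a node. Restricting the reference to orthologs whose co-expression is
#' itself conserved avoids letting fast-evolving reference genes distort the
#' comparison.
#'
#' @inheritParams dutilh_ec
#' @param node_indices Integer indices (into 1..k) of the reference nodes;
#'   at least 4 (so every query keeps >= 3 reference positions).
#' @return An `ec_result` with method `"essien"`.
#' @export
essien_ec <- function(pcm_a, pcm_b, node_indices) {
  check_pcm_pair(pcm_a, pcm_b)
  k <- nrow(pcm_a)
  node_indices <- sort(unique(as.integer(node_indices)))
  if (any(node_indices < 1L | node_indices > k)) {
    stop("node_indices out of range 1..k", call. = FALSE)
  }
  if (length(node_indices) < 4L) {
    stop("reference set too small: need at least 4 CCN nodes", call. = FALSE)
  }
  ec <- rep(NA_real_, k)
  valid <- rep(FALSE, k)
  for (i in seq_len(k)) {
    ref <- ref_positions(i, k, node_indices)
    if (length(ref) < 3L) next
    r <- row_cor(pcm_a[i, ref], pcm_b[i, ref])
    if (!is.na(r)) {
      ec[i] <- r
      valid[i] <- TRUE
    }
  }
  ec_result("essien", ec = ec, valid = valid,
            params = list(n_nodes = length(node_indices)))
}

#' Co-expression divergence (Euclidean distance between PCM rows)
#'
#' Euclidean distance between row i of the two pairwise correlation matrices
#' over the reference positions (all other orthologs, or a CCN node set),
#' the divergence counterpart of the co-expression ECs.
#'
#' @inheritParams dutilh_ec
#' @param node_indices Optional CCN node restriction as in [essien_ec()].
#' @return An `ec_result` carrying the `distance` field.
#' @export
coexpr_distance <- function(pcm_a, pcm_b, node_indices = NULL) {
  check_pcm_pair(pcm_a, pcm_b)
  k <- nrow(pcm_a)
  if (!is.null(node_indices)) {
    node_indices <- sort(unique(as.integer(node_indices)))
    if (any(node_indices < 1L | node_indices > k)) {
      stop("node_indices out of range 1..k", call. = FALSE)
    }
    if (length(node_indices) < 4L) {
      stop("reference set too small: need at least 4 CCN nodes",
           call. = FALSE)
    }
  }
  d <- rep(NA_real_, k)
  valid <- rep(FALSE, k)
  for (i in seq_len(k)) {
    ref <- ref_positions(i, k, node_indices)
    if (length(ref) < 1L) next
    d[i] <- sqrt(sum((pcm_a[i, ref] - pcm_b[i, ref])^2))
    valid[i] <- TRUE
  }
  method <- if (is.null(node_indices)) "coexpr_distance"
            else "coexpr_distance_ccn"
  ec_result(method, distance = d, valid = valid,
            params = list(n_nodes = if (is.null(node_indices)) nrow(pcm_a)
                          else length(node_indices)))
}
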