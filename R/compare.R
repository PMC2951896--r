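#' Summarize an EC distribution
#'
#' Mean and sample standard deviation of the defined (valid) EC scores,
#' the per-method distribution summary used to compare ortholog and
#' random-pair populations.
#'
#' @param ec An `ec_result` carrying EC scores.
#' @param population Label for the scored population, conventionally
#'   `"orthologs"` or `"random_pairs"`.
#' @return One-row data frame with columns `method`, `population`, `mean`,
#'   `sd`, `n_valid`.
#' @export
summarize_ec <- function(ec, population = "orthologs") {
  stopifnot(inherits(ec, "ec_result"))
  if (is.null(ec$ec)) stop("result carries no EC scores", call. = FALSE)
  v <- ec$ec[ec$valid & !is.na(ec$ec)]
  if (length(v) < 2L) {
    stop("need at least 2 valid ECs to summarize", call. = FALSE)
  }
  data.frame(method = ec$method, population = population,
             mean = mean(v), sd = stats::sd(v), n_valid = length(v),
             stringsAsFactors = FALSE)
}

draw_permutation <- function(k, seed, perm = NULL) {
  if (is.null(perm)) {
    perm <- with_seed(seed, sample.int(k))
  }
  stopifnot(length(perm) == k, all(sort(perm) == seq_len(k)))
  perm
}

#' Random-pair null EC scores
#'
#' Scores randomly paired genes instead of orthologs: a seeded uniform
#' permutation `perm` of the B-side indices pairs gene i in A with gene
#' `perm[i]` in B (fixed points are allowed and counted). For the
#' corresponding-tissue method, pass a `paired_expression` restricted to
#' corresponding tissues; for co-expression methods, pass the two PCMs. In
#' the co-expression case only the query pairing is shuffled: each score
#' correlates row i of `pcm_a` with row `perm[i]` of `pcm_b` over the same
#' reference positions the ortholog analysis would use for pair i (the
#' reference orthology itself is untouched).
#'
#' On conserved data the ortholog EC distribution should dominate this null;
#' its mean should sit near 0.
#'
#' @param x A `paired_expression` (corresponding-tissue method) or a PCM
#'   matrix (co-expression methods).
#' @param ... Passed to methods.
#' @return An `ec_result`; `params` records the seed, the permutation and the
#'   number of fixed points.
#' @export
random_pair_ec <- function(x, ...) UseMethod("random_pair_ec")

#' @rdname random_pair_ec
#' @param seed Integer seed for the permutation.
#' @param perm Optional explicit permutation of 1..k (overrides `seed`).
#' @export
random_pair_ec.paired_expression <- function(x, seed, perm = NULL, ...) {
  check_common_panels(x)
  k <- x$k
  perm <- draw_permutation(k, seed, perm)
  shuffled <- structure(list(A = x$A,
                             B = x$B[perm, , drop = FALSE],
                             pairs = x$pairs, k = k),
                        class = "paired_expression")
  out <- liao_zhang_ec(shuffled)
  out$method <- "liao_zhang"
  out$params <- c(out$params,
                  list(population = "random_pairs", seed = seed, perm = perm,
                       n_fixed_points = sum(perm == seq_len(k))))
  out
}

#' @rdname random_pair_ec
#' @param pcm_b Species-B PCM (when `x` is the species-A PCM).
#' @param node_indices Optional CCN node set: scores the Essien variant.
#' @param weights Optional reference weights (e.g. `icc_fit$weights`):
#'   scores the ICC variant with the orthologous fit's final weights.
#' @export
random_pair_ec.matrix <- function(x, pcm_b, seed, perm = NULL,
                                  node_indices = NULL, weights = NULL, ...) {
  check_pcm_pair(x, pcm_b)
  k <- nrow(x)
  if (!is.null(node_indices)) {
    node_indices <- sort(unique(as.integer(node_indices)))
    if (length(node_indices) < 4L) {
      stop("reference set too small: need at least 4 CCN nodes",
           call. = FALSE)
    }
  }
  if (!is.null(weights)) {
    stopifnot(length(weights) == k, all(weights >= 0))
  }
  perm <- draw_permutation(k, seed, perm)
  ec <- rep(NA_real_, k)
  valid <- rep(FALSE, k)
  for (i in seq_len(k)) {
    ref <- ref_positions(i, k, node_indices)
    if (length(ref) < 3L) next
    xv <- x[i, ref]
    yv <- pcm_b[perm[i], ref]
    r <- if (is.null(weights)) {
      row_cor(xv, yv)
    } else {
      wi <- weights[ref]
      if (sum(wi) <= 0) NA_real_ else weighted_pearson(xv, yv, wi)
    }
    if (!is.na(r)) {
      ec[i] <- r
      valid[i] <- TRUE
    }
  }
  method <- if (!is.null(weights)) "icc"
            else if (!is.null(node_indices)) "essien"
            else "dutilh"
  ec_result(method, ec = ec, valid = valid,
            params = list(population = "random_pairs", seed = seed,
                          perm = perm,
                          n_fixed_points = sum(perm == seq_len(k))))
}

#' Permute reference orthology (negative control)
#'
#' Disturbs the orthology relationships inside the reference set by
#' permuting the columns of the species-B PCM with a seeded uniform
#' permutation while leaving row identity intact: reference position j of a
#' B-row no longer corresponds to ortholog j. Feeding the result as the
#' reference-side input of any co-expression EC method should abolish the
#' ortholog-versus-random separation. The output is generally not symmetric
#' and is meant only as the `pcm_b` argument of EC computations.
#'
#' @param pcm_b Species-B PCM.
#' @param seed Integer seed.
#' @param perm Optional explicit permutation (overrides `seed`).
#' @return The column-permuted matrix, with attribute `perm`.
#' @export
permute_reference_orthology <- function(pcm_b, seed, perm = NULL) {
  validate_pcm(pcm_b, "pcm_b")
  k <- nrow(pcm_b)
  perm <- draw_permutation(k, seed, perm)
  out <- pcm_b[, perm, drop = FALSE]
  colnames(out) <- colnames(pcm_b)[perm]
  attr(out, "perm") <- perm
  out
}

agreement_core <- function(v1, v2, ok, labels) {
  if (sum(ok) < 3L) {
    stop("need at least 3 jointly valid pairs", call. = FALSE)
  }
  a <- v1[ok]
  b <- v2[ok]
  if (max(a) == min(a) || max(b) == min(b)) {
    warning("zero variance in one score vector; agreement undefined")
    return(data.frame(method_1 = labels[1L], method_2 = labels[2L],
                      pearson_r = NA_real_, spearman_rho = NA_real_,
                      n_pairs_used = sum(ok), stringsAsFactors = FALSE))
  }
  data.frame(method_1 = labels[1L], method_2 = labels[2L],
             pearson_r = clamp_cor(stats::cor(a, b)),
             spearman_rho = clamp_cor(stats::cor(a, b, method = "spearman")),
             n_pairs_used = sum(ok), stringsAsFactors = FALSE)
}

#' Agreement between two EC methods
#'
#' Pearson and Spearman (average-rank ties) correlations between two
#' methods' EC vectors over the ortholog pairs valid under both methods
#' (complete cases only, since invalid pairs differ across methods).
#'
#' @param ec1,ec2 `ec_result` objects over the same ortholog pairs.
#' @return One-row data frame with columns `method_1`, `method_2`,
#'   `pearson_r`, `spearman_rho`, `n_pairs_used`.
#' @export
method_agreement <- function(ec1, ec2) {
  stopifnot(inherits(ec1, "ec_result"), inherits(ec2, "ec_result"))
  if (ec1$k != ec2$k) stop("results cover different pair sets", call. = FALSE)
  if (is.null(ec1$ec) || is.null(ec2$ec)) {
    stop("both results must carry EC scores", call. = FALSE)
  }
  ok <- ec1$valid & ec2$valid & !is.na(ec1$ec) & !is.na(ec2$ec)
  agreement_core(ec1$ec, ec2$ec, ok, c(ec1$method, ec2$method))
}

#' Agreement between two divergence (distance) vectors
#'
#' Same machinery as [method_agreement()] applied to the Euclidean-distance
#' fields, used to ask whether two methods' divergence measures rank
#' orthologs concordantly.
#'
#' @param ec1,ec2 `ec_result` objects carrying `distance` vectors.
#' @return One-row data frame as in [method_agreement()].
#' @export
distance_agreement <- function(ec1, ec2) {
  stopifnot(inherits(ec1, "ec_result"), inherits(ec2, "ec_result"))
  if (ec1$k != ec2$k) stop("results cover different pair sets", call. = FALSE)
  if (is.null(ec1$distance) || is.null(ec2$distance)) {
    stop("both results must carry distance vectors", call. = FALSE)
  }
  ok <- ec1$valid & ec2$valid & !is.na(ec1$distance) & !is.na(ec2$distance)
  agreement_core(ec1$distance, ec2$distance, ok, c(ec1$method, ec2$method))
}

coexpr_ec_by_method <- function(pcm_a, pcm_b, method, node_indices = NULL,
                                tol = 1e-3, max_iter = 100L) {
  switch(method,
         dutilh = dutilh_ec(pcm_a, pcm_b),
         icc = icc(pcm_a, pcm_b, tol = tol, max_iter = max_iter)$result,
         essien = {
           if (is.null(node_indices)) {
             stop("essien method needs node_indices", call. = FALSE)
           }
           essien_ec(pcm_a, pcm_b, node_indices)
         },
         stop("unknown co-expression method '", method, "'", call. = FALSE))
}

#' Whole-data versus common-tissue EC comparison
#'
#' Quantifies what restricting to corresponding tissues costs a
#' co-expression method: ECs are computed twice, from PCMs built on all
#' conditions and from PCMs built on the corresponding-tissue columns only,
#' then compared by a Welch two-sample t-test on the two EC distributions
#' and by the paired agreement correlation between the two EC vectors.
#'
#' Pairs whose profile is constant on the tissue subset are excluded from
#' both computations (synchronized), so the two EC vectors stay aligned.
#'
#' For `method = "essien"` each data set gets its own background
#' distributions and CCN node set (quantile `node_quantile`), mirroring how
#' the method would be applied to that data in isolation.
#'
#' @param paired A `paired_expression` (all conditions).
#' @param common_a,common_b Corresponding-tissue labels (see
#'   [subset_tissues()]).
#' @param method One of `"dutilh"`, `"icc"`, `"essien"`.
#' @param node_quantile Background quantile for the Essien node sets.
#' @param n_background Background sample size per species.
#' @param seed Integer seed for the background sampling.
#' @param tol,max_iter ICC convergence parameters.
#' @return List with `full` and `common` (`ec_result`s), `t_statistic`,
#'   `p_value` (Welch test), and `agreement` (data frame from
#'   [method_agreement()]).
#' @export
compare_tissue_subsets <- function(paired, common_a, common_b,
                                   method = c("dutilh", "icc", "essien"),
                                   node_quantile = 0.975,
                                   n_background = 20000L, seed = 1L,
                                   tol = 1e-3, max_iter = 100L) {
  method <- match.arg(method)
  stopifnot(inherits(paired, "paired_expression"))
  sub <- subset_tissues(paired, common_a, common_b)
  nz <- function(m) apply(m, 1L, function(r) max(r) > min(r))
  keep <- nz(paired$A) & nz(paired$B) & nz(sub$A) & nz(sub$B)
  if (sum(keep) < 5L) {
    stop("too few pairs with non-constant profiles on both panels",
         call. = FALSE)
  }
  paired <- subset_pairs(paired, keep)
  sub <- subset_pairs(sub, keep)

  build <- function(pe, tag) {
    pcm_a <- pairwise_correlation_matrix(pe$A)
    pcm_b <- pairwise_correlation_matrix(pe$B)
    nodes <- NULL
    if (method == "essien") {
      bg_a <- background_correlations(pe$A, n_background,
                                      seed = stage_seed(seed, paste0(tag, "_A")),
                                      species_tag = "A")
      bg_b <- background_correlations(pe$B, n_background,
                                      seed = stage_seed(seed, paste0(tag, "_B")),
                                      species_tag = "B")
      nodes <- identify_ccn_nodes(pcm_a, pcm_b,
                                  correlation_threshold(bg_a, node_quantile),
                                  correlation_threshold(bg_b, node_quantile),
                                  node_quantile)$node_indices
    }
    coexpr_ec_by_method(pcm_a, pcm_b, method, nodes, tol, max_iter)
  }
  ec_full <- build(paired, "background_full")
  ec_common <- build(sub, "background_common")

  vf <- ec_full$ec[ec_full$valid]
  vc <- ec_common$ec[ec_common$valid]
  tt <- if (isTRUE(all.equal(vf, vc, tolerance = 0))) {
    list(statistic = c(t = 0), p.value = 1)    # identical vectors: no difference
  } else {
    stats::t.test(vf, vc, var.equal = FALSE)
  }
  list(full = ec_full, common = ec_common,
       t_statistic = unname(tt$statistic), p_value = tt$p.value,
       agreement = method_agreement(ec_full, ec_common))
}
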