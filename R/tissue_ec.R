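#' Relative abundance profile
#'
#' Normalizes a gene's expression profile over a tissue panel to relative
#' abundance (RA): each tissue's value divided by the profile sum. RA removes
#' platform- and gene-specific intensity scale, making profiles comparable
#' across species: RA(c * v) = RA(v) for any c > 0.
#'
#' @param profile Nonnegative numeric vector of length >= 3 with at least one
#'   strictly positive entry.
#' @return Numeric vector of the same length summing to 1.
#' @export
relative_abundance <- function(profile) {
  if (!is.numeric(profile) || length(profile) < 3L) {
    stop("profile must be numeric with at least 3 tissues", call. = FALSE)
  }
  if (anyNA(profile) || any(!is.finite(profile)) || any(profile < 0)) {
    stop("profile must be finite and nonnegative", call. = FALSE)
  }
  s <- sum(profile)
  if (s <= 0) {
    stop("relative abundance undefined: all-zero profile", call. = FALSE)
  }
  profile / s
}

check_common_panels <- function(paired) {
  if (ncol(paired$A) != ncol(paired$B)) {
    stop("corresponding-tissue methods need equal column counts; ",
         "restrict both matrices to corresponding tissues first",
         call. = FALSE)
  }
  if (ncol(paired$A) < 3L) {
    stop("need at least 3 corresponding tissues", call. = FALSE)
  }
  invisible(paired)
}

#' Corresponding-tissue expression conservation
#'
#' The corresponding-tissue method of Liao and Zhang: each ortholog pair's
#' two expression profiles over n matched tissues are normalized to relative
#' abundance, and EC is their Pearson product-moment correlation. Column j of
#' the A-matrix must correspond biologically to column j of the B-matrix
#' (use [subset_tissues()]).
#'
#' A pair is flagged invalid (EC missing) when either profile is all zero
#' (RA undefined) or its RA vector is constant (zero variance); such pairs
#' are excluded from distribution summaries rather than scored 0.
#'
#' @param paired A `paired_expression` restricted to corresponding tissues.
#' @return An `ec_result` with method `"liao_zhang"`.
#' @export
liao_zhang_ec <- function(paired) {
  stopifnot(inherits(paired, "paired_expression"))
  check_common_panels(paired)
  k <- paired$k
  ec <- rep(NA_real_, k)
  valid <- rep(FALSE, k)
  for (i in seq_len(k)) {
    a <- paired$A[i, ]
    b <- paired$B[i, ]
    if (sum(a) <= 0 || sum(b) <= 0) next
    ra <- a / sum(a)
    rb <- b / sum(b)
    if (max(ra) == min(ra) || max(rb) == min(rb)) next
    ec[i] <- clamp_cor(stats::cor(ra, rb))
    valid[i] <- TRUE
  }
  ec_result("liao_zhang", ec = ec, valid = valid,
            params = list(n_common = ncol(paired$A)))
}

#' Corresponding-tissue expression divergence (Euclidean distance)
#'
#' Euclidean distance between the two relative-abundance vectors of each
#' ortholog pair over the corresponding tissues. Because RA vectors lie on
#' the probability simplex, the distance is always in \[0, sqrt(2)\].
#' A pair is invalid only when RA is undefined (all-zero profile).
#'
#' @inheritParams liao_zhang_ec
#' @return An `ec_result` with method `"liao_zhang_distance"` carrying the
#'   `distance` field.
#' @export
liao_zhang_distance <- function(paired) {
  stopifnot(inherits(paired, "paired_expression"))
  check_common_panels(paired)
  k <- paired$k
  d <- rep(NA_real_, k)
  valid <- rep(FALSE, k)
  for (i in seq_len(k)) {
    a <- paired$A[i, ]
    b <- paired$B[i, ]
    if (sum(a) <= 0 || sum(b) <= 0) next
    ra <- a / sum(a)
    rb <- b / sum(b)
    d[i] <- sqrt(sum((ra - rb)^2))
    valid[i] <- TRUE
  }
  ec_result("liao_zhang_distance", distance = d, valid = valid,
            params = list(n_common = ncol(paired$A)))
}
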