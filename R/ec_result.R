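#' Per-ortholog expression conservation result
#'
#' Container returned by every EC and distance method. `ec` and `distance`
#' hold one value per ortholog pair (NA where undefined); `valid` flags the
#' pairs for which the score is defined. Undefined scores stay missing rather
#' than being coerced to 0, so that distribution summaries are not
#' contaminated by degenerate pairs.
#'
#' @param method Character method label (e.g. `"liao_zhang"`, `"dutilh"`).
#' @param ec Numeric vector of EC scores in \[-1, 1\], NA where undefined,
#'   or NULL for distance-only results.
#' @param distance Numeric vector of nonnegative Euclidean divergences, or
#'   NULL for EC-only results.
#' @param valid Logical vector, FALSE where the score is undefined.
#' @param params Named list of method parameters (recorded for provenance).
#'
#' @return An object of class `ec_result` with fields `method`, `ec`,
#'   `distance`, `valid`, `params` and `k` (number of ortholog pairs).
#' @export
ec_result <- function(method, ec = NULL, distance = NULL, valid, params = list()) {
  stopifnot(is.character(method), length(method) == 1L, is.logical(valid))
  k <- length(valid)
  if (!is.null(ec)) {
    stopifnot(length(ec) == k)
    if (any(!is.na(ec) & (ec < -1 - 1e-8 | ec > 1 + 1e-8))) {
      stop("EC values must lie in [-1, 1]", call. = FALSE)
    }
  }
  if (!is.null(distance)) {
    stopifnot(length(distance) == k)
    if (any(!is.na(distance) & distance < -1e-12)) {
      stop("distances must be nonnegative", call. = FALSE)
    }
  }
  structure(
    list(method = method, ec = ec, distance = distance, valid = valid,
         params = params, k = k),
    class = "ec_result"
  )
}

#' @export
print.ec_result <- function(x, ...) {
  cat("Expression conservation result (", x$method, ")\n", sep = "")
  cat("  ortholog pairs:", x$k, " valid:", sum(x$valid), "\n")
  if (!is.null(x$ec)) {
    v <- x$ec[x$valid & !is.na(x$ec)]
    if (length(v)) {
      cat(sprintf("  EC: mean %.3f sd %.3f range [%.3f, %.3f]\n",
                  mean(v), stats::sd(v), min(v), max(v)))
    }
  }
  if (!is.null(x$distance)) {
    d <- x$distance[!is.na(x$distance)]
    if (length(d)) {
      cat(sprintf("  distance: mean %.3f range [%.3f, %.3f]\n",
                  mean(d), min(d), max(d)))
    }
  }
  invisible(x)
}

#' @export
as.data.frame.ec_result <- function(x, ...) {
  data.frame(
    pair_index = seq_len(x$k),
    method = x$method,
    ec = if (is.null(x$ec)) NA_real_ else x$ec,
    distance = if (is.null(x$distance)) NA_real_ else x$distance,
    valid_flag = x$valid,
    stringsAsFactors = FALSE
  )
}

#' Write an EC result table
#'
#' Writes the standard result layout: one row per ortholog pair with columns
#' `pair_index`, `gene_id_A`, `gene_id_B`, `method`, `ec`, `distance`,
#' `valid_flag`. Numbers are written at full precision so re-reading is exact.
#'
#' @param x An `ec_result`.
#' @param path Output file path (tab-delimited).
#' @param pairs Optional data frame with columns `gene_a`, `gene_b` giving the
#'   ortholog pair identifiers in row order.
#' @return Invisibly, the path.
#' @export
write_ec_result <- function(x, path, pairs = NULL) {
  stopifnot(inherits(x, "ec_result"))
  df <- as.data.frame(x)
  if (!is.null(pairs)) {
    stopifnot(nrow(pairs) == x$k)
    df$gene_id_A <- pairs$gene_a
    df$gene_id_B <- pairs$gene_b
  } else {
    df$gene_id_A <- NA_character_
    df$gene_id_B <- NA_character_
  }
  df <- df[, c("pair_index", "gene_id_A", "gene_id_B", "method",
               "ec", "distance", "valid_flag")]
  df$ec <- format_num(df$ec)
  df$distance <- format_num(df$distance)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
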