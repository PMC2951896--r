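new_filter_report <- function(n_input, low = 0L, zerovar = 0L, multiprobe = 0L,
                              retained_ids) {
  structure(
    list(n_input_genes = n_input,
         n_removed_low_expression = low,
         n_removed_zero_variance = zerovar,
         n_removed_multiprobe = multiprobe,
         retained_ids = retained_ids),
    class = "filter_report"
  )
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Filter report\n")
  cat("  input pairs:          ", x$n_input_genes, "\n")
  cat("  removed (low expr):   ", x$n_removed_low_expression, "\n")
  cat("  removed (zero var):   ", x$n_removed_zero_variance, "\n")
  cat("  removed (multiprobe): ", x$n_removed_multiprobe, "\n")
  cat("  retained:             ", length(x$retained_ids), "\n")
  invisible(x)
}

subset_pairs <- function(paired, keep) {
  paired_expression(paired$A[keep, , drop = FALSE],
                    paired$B[keep, , drop = FALSE],
                    paired$pairs[keep, , drop = FALSE])
}

#' Remove ortholog pairs that never reach an expression floor
#'
#' Low intensities carry mostly noise and distort correlation estimates, so a
#' pair is dropped when, in either species, the gene's maximum expression
#' across all conditions stays below `floor` (default 200, the conventional
#' MAS 5.0-scale cutoff). Removal is synchronized: dropping pair i removes
#' row i from both matrices, keeping the two matrices row-aligned.
#'
#' Masking individual values below the floor (`mode = "value_mask"`) would
#' create incomplete vectors, which the correlation machinery forbids; that
#' mode is rejected.
#'
#' @param paired A `paired_expression` object.
#' @param floor Nonnegative expression floor.
#' @param mode Filtering rule; only `"max_below"` is supported.
#' @return A list with elements `paired` (filtered) and `report`
#'   (a `filter_report`).
#' @export
filter_low_expression <- function(paired, floor = 200,
                                  mode = c("max_below", "value_mask")) {
  stopifnot(inherits(paired, "paired_expression"))
  mode <- match.arg(mode)
  if (mode == "value_mask") {
    stop("mode 'value_mask' is not supported: masking single values creates ",
         "incomplete expression vectors", call. = FALSE)
  }
  if (!is.numeric(floor) || length(floor) != 1L || floor < 0) {
    stop("floor must be a single nonnegative number", call. = FALSE)
  }
  max_a <- apply(paired$A, 1L, max)
  max_b <- apply(paired$B, 1L, max)
  keep <- max_a >= floor & max_b >= floor
  if (!any(keep)) {
    stop("all ortholog pairs fall below the expression floor", call. = FALSE)
  }
  report <- new_filter_report(paired$k, low = sum(!keep),
                              retained_ids = paired$pairs$gene_a[keep])
  list(paired = subset_pairs(paired, keep), report = report)
}

#' Remove ortholog pairs with a constant expression profile
#'
#' Pearson correlation is undefined for constant vectors, so a pair is
#' dropped when its expression vector is constant across conditions in either
#' species. Removal is synchronized across the two matrices.
#'
#' @param paired A `paired_expression` object.
#' @return A list with elements `paired` and `report`.
#' @export
drop_zero_variance <- function(paired) {
  stopifnot(inherits(paired, "paired_expression"))
  const_a <- apply(paired$A, 1L, function(r) max(r) == min(r))
  const_b <- apply(paired$B, 1L, function(r) max(r) == min(r))
  keep <- !(const_a | const_b)
  report <- new_filter_report(paired$k, zerovar = sum(!keep),
                              retained_ids = paired$pairs$gene_a[keep])
  paired <- if (any(keep)) subset_pairs(paired, keep) else {
    # empty result is allowed here; downstream stages reject it
    structure(list(A = paired$A[0, , drop = FALSE],
                   B = paired$B[0, , drop = FALSE],
                   pairs = paired$pairs[0, , drop = FALSE], k = 0L),
              class = "paired_expression")
  }
  list(paired = paired, report = report)
}

#' Restrict a pair of expression matrices to corresponding tissues
#'
#' `common_a[j]` and `common_b[j]` name the j-th corresponding tissue in the
#' two species; the output matrices contain exactly those columns, in that
#' order, so that column j of the A-subset corresponds biologically to
#' column j of the B-subset.
#'
#' @param paired A `paired_expression` object.
#' @param common_a,common_b Equal-length character vectors of condition
#'   labels present in `paired$A` / `paired$B`; at least 3 tissues
#'   (correlation over fewer points is degenerate).
#' @return A `paired_expression` restricted to the corresponding tissues.
#' @export
subset_tissues <- function(paired, common_a, common_b) {
  stopifnot(inherits(paired, "paired_expression"))
  if (length(common_a) != length(common_b)) {
    stop("common tissue lists must have equal length", call. = FALSE)
  }
  if (length(common_a) < 3L) {
    stop("need at least 3 corresponding tissues", call. = FALSE)
  }
  miss_a <- setdiff(common_a, colnames(paired$A))
  if (length(miss_a)) {
    stop("unknown condition label(s) in A: ",
         paste(miss_a, collapse = ", "), call. = FALSE)
  }
  miss_b <- setdiff(common_b, colnames(paired$B))
  if (length(miss_b)) {
    stop("unknown condition label(s) in B: ",
         paste(miss_b, collapse = ", "), call. = FALSE)
  }
  paired_expression(paired$A[, common_a, drop = FALSE],
                    paired$B[, common_b, drop = FALSE],
                    paired$pairs)
}

#' Read a corresponding-tissue table
#'
#' Two-column tab-delimited file (label in species A, label in species B);
#' row order defines the correspondence.
#'
#' @param path Path to the table.
#' @param header Logical, whether the file has a header row.
#' @return Data frame with columns `label_a`, `label_b`.
#' @export
read_common_tissues <- function(path, header = FALSE) {
  df <- utils::read.delim(path, header = header, sep = "\t",
                          colClasses = "character", quote = "")
  if (ncol(df) < 2L) {
    stop("common-tissue table must have two tab-separated columns",
         call. = FALSE)
  }
  data.frame(label_a = df[[1L]], label_b = df[[2L]], stringsAsFactors = FALSE)
}
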