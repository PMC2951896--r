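#' Read a gene-by-condition expression table
#'
#' Expression tables are tab-delimited: first row holds condition (tissue)
#' labels, first column holds gene identifiers, remaining cells are
#' nonnegative numeric intensities (MAS 5.0-style summarized values).
#' Matrices must be complete: empty cells and "NA" tokens are rejected,
#' since every downstream correlation assumes complete vectors.
#'
#' @param path Path to a tab-delimited expression table.
#' @return A numeric matrix with gene identifiers as row names and condition
#'   labels as column names.
#' @seealso [write_expression_table()], [align_by_orthology()]
#' @export
read_expression_table <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character",
                           quote = "")
  if (ncol(raw) < 2L) {
    stop("expression table needs a gene-id column plus >= 1 condition column",
         call. = FALSE)
  }
  ids <- raw[[1L]]
  if (anyDuplicated(ids)) {
    stop("duplicate gene identifier(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  cond <- colnames(raw)[-1L]
  if (anyDuplicated(cond)) {
    stop("duplicate condition label(s): ",
         paste(unique(cond[duplicated(cond)]), collapse = ", "), call. = FALSE)
  }
  cells <- as.matrix(raw[, -1L, drop = FALSE])
  vals <- suppressWarnings(matrix(as.numeric(cells), nrow = nrow(cells)))
  bad <- which(is.na(vals), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("non-numeric or missing cell at gene '%s', condition '%s'",
                 ids[bad[1L, 1L]], cond[bad[1L, 2L]]), call. = FALSE)
  }
  dimnames(vals) <- list(ids, cond)
  validate_expression_matrix(vals)
  vals
}

#' Write an expression matrix as a tab-delimited table
#'
#' Values are written with 17 significant digits so that
#' `read_expression_table(write_expression_table(m, f))` reproduces `m`
#' exactly.
#'
#' @param m Numeric expression matrix with gene row names and condition
#'   column names.
#' @param path Output path.
#' @param id_column Header of the gene-identifier column.
#' @return Invisibly, the path.
#' @export
write_expression_table <- function(m, path, id_column = "gene_id") {
  validate_expression_matrix(m)
  chr <- matrix(format_num(m), nrow = nrow(m))
  df <- data.frame(rownames(m), chr, stringsAsFactors = FALSE,
                   check.names = FALSE)
  colnames(df) <- c(id_column, colnames(m))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a 1-1 ortholog pair table
#'
#' Two-column tab-delimited file: gene id in species A, gene id in species B.
#' Only 1-1 orthology is accepted; any gene appearing in more than one pair
#' makes the file invalid and the offending identifiers are reported.
#'
#' @param path Path to the pair table.
#' @param header Logical, whether the file has a header row.
#' @return A data frame with columns `gene_a`, `gene_b` (possibly 0 rows).
#' @export
read_ortholog_pairs <- function(path, header = FALSE) {
  if (length(readLines(path, n = 1L, warn = FALSE)) == 0L) {
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      stringsAsFactors = FALSE))
  }
  df <- utils::read.delim(path, header = header, sep = "\t",
                          colClasses = "character", quote = "")
  if (ncol(df) < 2L) {
    stop("ortholog pair table must have two tab-separated columns",
         call. = FALSE)
  }
  out <- data.frame(gene_a = df[[1L]], gene_b = df[[2L]],
                    stringsAsFactors = FALSE)
  dup_a <- unique(out$gene_a[duplicated(out$gene_a)])
  dup_b <- unique(out$gene_b[duplicated(out$gene_b)])
  if (length(dup_a) || length(dup_b)) {
    stop("orthology is not 1-1; duplicated identifiers: ",
         paste(c(dup_a, dup_b), collapse = ", "), call. = FALSE)
  }
  out
}

#' Paired two-species expression matrices
#'
#' Bundles two expression matrices whose rows are aligned so that row i of
#' each matrix is the same 1-1 ortholog pair i. The two condition panels may
#' differ in size and labels.
#'
#' @param A,B Numeric expression matrices (genes x conditions).
#' @param pairs Data frame with columns `gene_a`, `gene_b` naming the ortholog
#'   pair on each row.
#' @return An object of class `paired_expression` with fields `A`, `B`,
#'   `pairs` and `k`.
#' @export
paired_expression <- function(A, B, pairs) {
  validate_expression_matrix(A, "matrix A")
  validate_expression_matrix(B, "matrix B")
  if (nrow(A) != nrow(B)) {
    stop("paired matrices must have the same number of ortholog rows",
         call. = FALSE)
  }
  stopifnot(is.data.frame(pairs), nrow(pairs) == nrow(A),
            all(c("gene_a", "gene_b") %in% names(pairs)))
  if (!identical(rownames(A), pairs$gene_a) ||
      !identical(rownames(B), pairs$gene_b)) {
    stop("row names of A/B must match the pair table order", call. = FALSE)
  }
  structure(list(A = A, B = B, pairs = pairs, k = nrow(A)),
            class = "paired_expression")
}

#' @export
print.paired_expression <- function(x, ...) {
  cat("Paired two-species expression data\n")
  cat("  ortholog pairs (k):", x$k, "\n")
  cat("  conditions: A =", ncol(x$A), ", B =", ncol(x$B), "\n")
  invisible(x)
}

#' Align two expression matrices by a 1-1 ortholog map
#'
#' Pairs whose A-gene is absent from `A` or whose B-gene is absent from `B`
#' are dropped (the count is recorded); retained pairs keep the map's order,
#' so row i of both output matrices is ortholog pair i.
#'
#' @param A,B Expression matrices for species A and B.
#' @param map Data frame with columns `gene_a`, `gene_b`
#'   (see [read_ortholog_pairs()]).
#' @return A `paired_expression` object; attribute `n_dropped` records how
#'   many map rows had a missing side.
#' @export
align_by_orthology <- function(A, B, map) {
  validate_expression_matrix(A, "matrix A")
  validate_expression_matrix(B, "matrix B")
  stopifnot(all(c("gene_a", "gene_b") %in% names(map)))
  keep <- map$gene_a %in% rownames(A) & map$gene_b %in% rownames(B)
  n_dropped <- sum(!keep)
  if (!any(keep)) {
    stop("zero retained pairs: no ortholog pair present in both matrices",
         call. = FALSE)
  }
  kept <- map[keep, c("gene_a", "gene_b"), drop = FALSE]
  rownames(kept) <- NULL
  out <- paired_expression(A[kept$gene_a, , drop = FALSE],
                           B[kept$gene_b, , drop = FALSE],
                           kept)
  attr(out, "n_dropped") <- n_dropped
  out
}
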