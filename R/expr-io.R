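#' Construct a validated expression matrix
#'
#' An expression matrix is a plain numeric matrix (genes in rows, samples in
#' columns) carrying a `scale` attribute that records whether values are on a
#' log scale (normalised log2 intensities) or a linear scale (RPKM).  All
#' downstream functions accept the object wherever an expression matrix is
#' expected.
#'
#' @param values numeric matrix, genes x samples, with unique rownames
#'   (gene identifiers) and unique colnames (sample identifiers).
#' @param scale `"log"` for log2-intensity data, `"linear"` for RPKM-like
#'   non-negative data.
#' @return the matrix with class `expr_matrix` and attribute `scale`.
#' @examples
#' m <- matrix(1:6, 3, 2, dimnames = list(paste0("g", 1:3), c("s1", "s2")))
#' x <- expression_matrix(m, "log")
#' attr(x, "scale")
#' @export
expression_matrix <- function(values, scale = c("log", "linear")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene identifiers: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample identifiers: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  if (!all(is.finite(values)))
    stop("expression values must be finite")
  if (scale == "linear" && any(values < 0))
    stop("linear-scale (RPKM) values must be non-negative")
  structure(values, scale = scale, class = c("expr_matrix", class(values)))
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("Expression matrix: %d genes x %d samples (%s scale)\n",
              nrow(x), ncol(x), attr(x, "scale")))
  invisible(x)
}

# dropping into plain-matrix ops must not invalidate the scale tag
#' @export
`[.expr_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out))
    out <- structure(out, scale = attr(x, "scale"),
                     class = c("expr_matrix", "matrix", "array"))
  out
}

.sniff_sep <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read an expression table from delimited text
#'
#' Reads a genes-x-samples table (first column gene identifiers, header row
#' sample identifiers).  The separator is sniffed from the extension
#' (`.csv` comma, anything else tab).  Rows sharing a gene identifier are
#' collapsed to their arithmetic mean on the stored scale, with a message
#' noting how many rows were merged.
#'
#' @param path file path.
#' @param scale `"log"` or `"linear"`; see [expression_matrix()].
#' @return an [expression_matrix()].
#' @export
read_expression_table <- function(path, scale = c("log", "linear")) {
  scale <- match.arg(scale)
  sep <- .sniff_sep(path)
  raw <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                           colClasses = "character", comment.char = "#",
                           quote = "\"", stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stop("expression table needs a gene column plus samples")
  sample_ids <- colnames(raw)[-1]
  if (anyDuplicated(sample_ids))
    stop("duplicate sample header: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  genes <- raw[[1]]
  vals <- matrix(NA_real_, nrow(raw), length(sample_ids))
  for (j in seq_along(sample_ids)) {
    col <- raw[[j + 1L]]
    v <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(v) & !is.na(col) & col != "NA")
    if (length(bad))
      stop(sprintf("non-numeric value '%s' at row %d (gene %s), column '%s'",
                   col[bad[1]], bad[1], genes[bad[1]], sample_ids[j]))
    vals[, j] <- v
  }
  if (anyDuplicated(genes)) {
    ndup <- sum(duplicated(genes))
    message(sprintf("collapsing %d duplicate gene row(s) by mean", ndup))
    vals <- rowsum(vals, group = genes, reorder = FALSE) /
      as.vector(table(factor(genes, levels = unique(genes))))
    genes <- unique(genes)
  }
  dimnames(vals) <- list(genes, sample_ids)
  expression_matrix(vals, scale)
}

#' Write an expression matrix to delimited text
#'
#' Inverse of [read_expression_table()]; values are written with full
#' precision so a round trip reproduces the matrix.
#'
#' @param x an [expression_matrix()] (or numeric matrix with dimnames).
#' @param path output path; extension selects the separator.
#' @param gene_col header of the gene-identifier column.
#' @export
write_expression_table <- function(x, path, gene_col = "gene_id") {
  sep <- .sniff_sep(path)
  df <- data.frame(rownames(x), format(unclass(x)[, , drop = FALSE],
                                       digits = 15, trim = TRUE,
                                       scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c(gene_col, colnames(x))
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample annotation table
#'
#' Tab-separated table with columns `sample_id`, `class_label`
#' (`case` = tumorigenic, `control` = healthy dividing), and optionally
#' `cell_type` and `origin`.
#'
#' @param path file path.
#' @return data.frame with the four columns (missing optional columns filled
#'   with `NA`).
#' @export
read_sample_annotation <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "\"")
  sample_annotation(df)
}

#' Validate a sample annotation data.frame
#'
#' @param df data.frame with at least `sample_id` and `class_label`.
#' @return the validated data.frame with columns
#'   `sample_id`, `class_label`, `cell_type`, `origin`.
#' @export
sample_annotation <- function(df) {
  need <- c("sample_id", "class_label")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("sample annotation lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in annotation")
  if (any(!nzchar(df$class_label)) || anyNA(df$class_label))
    stop("class_label must be non-empty for every sample")
  for (col in c("cell_type", "origin"))
    if (is.null(df[[col]])) df[[col]] <- NA_character_
  df[, c("sample_id", "class_label", "cell_type", "origin")]
}

#' Restrict two expression matrices to their shared genes
#'
#' Both matrices are subset to the intersection of their gene identifiers, in
#' a common order (the order of appearance in `m1`).  Sample sets are
#' untouched.  Needed before projecting an independently normalised dataset
#' onto a discriminant fitted elsewhere.
#'
#' @param m1,m2 expression matrices.
#' @return list with elements `m1` and `m2`, row-aligned.
#' @export
align_matrices <- function(m1, m2) {
  shared <- intersect(rownames(m1), rownames(m2))
  if (!length(shared))
    stop("no shared genes between the two matrices")
  list(m1 = m1[shared, , drop = FALSE], m2 = m2[shared, , drop = FALSE])
}
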