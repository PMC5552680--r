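#' Project sample expression profiles onto a characteristic direction
#'
#' The score of sample s is
#' \deqn{score_s = \sum_i b_i (x_{is} - \bar x_{i\cdot})}
#' summed over the genes shared by the fit and the matrix (optionally
#' restricted to a gene set), where \eqn{\bar x_{i\cdot}} is the gene's mean
#' over the samples of the projected matrix itself.  Centering on the
#' projected matrix's own means means independently normalised validation
#' sets need no parameters from the training data.  When restricted to a
#' regulon the restricted direction is deliberately not renormalised, so the
#' score preserves the regulon's relative weight within the global direction.
#'
#' @param cd a `chardir` fit.
#' @param X expression matrix to project.
#' @param subset optional [gene_set()] (or character vector) restricting the
#'   genes used.
#' @return object of class `projection_scores`: list with `sample_ids`,
#'   `scores` (named numeric), and `gene_subset` (set name or `NA`).
#' @export
project_samples <- function(cd, X, subset = NULL) {
  shared <- intersect(cd$gene_ids, rownames(X))
  if (!length(shared))
    stop("no genes shared between the fit and the matrix")
  subset_name <- NA_character_
  if (!is.null(subset)) {
    if (inherits(subset, "gene_set")) subset_name <- subset$name
    shared <- intersect(shared, .as_gene_ids(subset))
    # disjoint subset still yields defined (all-zero) scores
  }
  if (!length(shared)) {
    scores <- stats::setNames(numeric(ncol(X)), colnames(X))
  } else {
    V <- unclass(X)[shared, , drop = FALSE]
    Vc <- V - rowMeans(V)
    scores <- drop(crossprod(Vc, cd$b[shared]))
    names(scores) <- colnames(X)
  }
  structure(list(sample_ids = colnames(X), scores = scores,
                 gene_subset = subset_name),
            class = "projection_scores")
}

#' @export
print.projection_scores <- function(x, ...) {
  cat(sprintf("Projection scores for %d samples%s\n", length(x$scores),
              if (is.na(x$gene_subset)) ""
              else sprintf(" (restricted to '%s')", x$gene_subset)))
  print(utils::head(x$scores), ...)
  if (length(x$scores) > 6) cat("...\n")
  invisible(x)
}

#' Predict method for characteristic-direction fits
#'
#' Projects new samples onto the fitted direction; equivalent to
#' [project_samples()].
#'
#' @param object a `chardir` fit.
#' @param newdata expression matrix; defaults would require the training
#'   matrix, which is not stored, so `newdata` is mandatory.
#' @param subset optional gene set restriction.
#' @param ... unused.
#' @return a `projection_scores` object.
#' @export
predict.chardir <- function(object, newdata, subset = NULL, ...) {
  if (missing(newdata)) stop("'newdata' (an expression matrix) is required")
  project_samples(object, newdata, subset)
}

#' Principal-component overview of an expression matrix
#'
#' Coordinates of each sample on the top k principal components of the
#' gene-centred matrix, for exploratory structure plots.  Component signs
#' are fixed by making the largest-magnitude gene loading positive, so
#' results are reproducible across platforms.
#'
#' @param X expression matrix (genes x samples).
#' @param k number of components, `1 <= k <= rank` of the centred matrix.
#' @return list with `coords` (samples x k), `loadings` (genes x k) and
#'   `var_share` (proportion of variance per component).
#' @export
pca_overview <- function(X, k) {
  if (!is.numeric(k) || length(k) != 1 || k < 1)
    stop("k must be a positive integer")
  pc <- stats::prcomp(t(unclass(X)), center = TRUE, scale. = FALSE)
  tol <- max(pc$sdev) * 1e-8
  rank <- sum(pc$sdev > tol)
  if (k > rank)
    stop(sprintf("k = %d exceeds the rank of the centred matrix (%d)", k, rank))
  coords <- pc$x[, seq_len(k), drop = FALSE]
  loads <- pc$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    top <- which.max(abs(loads[, j]))
    if (loads[top, j] < 0) {
      loads[, j] <- -loads[, j]
      coords[, j] <- -coords[, j]
    }
  }
  list(coords = coords, loadings = loads,
       var_share = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)])
}
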