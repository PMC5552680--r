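#' Estimate a transcription factor's activity across samples
#'
#' Projects the characteristic direction, restricted to the genes of a
#' regulon, onto each sample's expression profile.  The resulting per-sample
#' score is used as an estimate of the transcription factor's activity in
#' that sample: samples in which the regulon's genes move coherently along
#' the discriminating direction score high.
#'
#' @param cd a `chardir` fit.
#' @param X expression matrix.
#' @param regulon a [gene_set()] of putative targets of the factor.
#' @return a `projection_scores` object tagged with the regulon's name.
#' @export
regulon_activity <- function(cd, X, regulon) {
  if (!inherits(regulon, "gene_set"))
    regulon <- gene_set("regulon", regulon)
  shared <- intersect(intersect(cd$gene_ids, rownames(X)), regulon$genes)
  if (!length(shared))
    stop(sprintf("regulon '%s' shares no genes with the fitted direction",
                 regulon$name))
  project_samples(cd, X, subset = regulon)
}

#' Correlate two activity score vectors across samples
#'
#' @param s1,s2 `projection_scores` over the same samples (any order), or
#'   plain named numeric vectors.
#' @param method `"pearson"` or `"spearman"`.
#' @return object of class `correlation_result`: list with `pair`, `method`,
#'   `r`, `p` (two-sided), and `n`.  Pearson p-values come from the t
#'   transform of r; Spearman p-values from the t approximation on the rank
#'   correlation.
#' @export
activity_correlation <- function(s1, s2, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  v1 <- .as_scores(s1); v2 <- .as_scores(s2)
  if (is.null(names(v1)) || is.null(names(v2)))
    stop("score vectors must carry sample names")
  if (!setequal(names(v1), names(v2)))
    stop("the two score vectors cover different samples")
  v2 <- v2[names(v1)]
  n <- length(v1)
  if (n < 3) stop("need at least 3 samples to correlate")
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0)
    stop("zero variance in a score vector; correlation undefined")
  ct <- stats::cor.test(v1, v2, method = method, exact = FALSE)
  structure(list(pair = c(.score_name(s1), .score_name(s2)),
                 method = method,
                 r = unname(ct$estimate), p = ct$p.value, n = n),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("%s correlation %s vs %s: r = %.4f, p = %.3g (n = %d)\n",
              x$method, x$pair[1], x$pair[2], x$r, x$p, x$n))
  invisible(x)
}

.as_scores <- function(s) {
  if (inherits(s, "projection_scores")) s$scores else s
}

.score_name <- function(s) {
  if (inherits(s, "projection_scores") && !is.na(s$gene_subset))
    s$gene_subset
  else "scores"
}
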