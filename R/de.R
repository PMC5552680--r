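#' Differential expression on an RPKM matrix
#'
#' Compares case against control samples gene by gene.  Fold changes are
#' ratios of group means on the raw RPKM scale (with the pseudocount added
#' to both means); p-values come from Welch's unequal-variance t-test on
#' log2(RPKM + pseudocount), which tames the heavy right tail of RPKM data;
#' q-values are Benjamini-Hochberg over all tested genes.  Genes at zero in
#' every sample of both groups carry no information and are dropped before
#' testing; genes with zero variance and equal means in both groups get
#' p = 1.
#'
#' A gene is called `up` when `q < alpha` and `fold_change >= fc_threshold`,
#' `down` when `q < alpha` and `fold_change <= 1/fc_threshold`, `ns`
#' otherwise.
#'
#' @param X linear-scale (RPKM) expression matrix.
#' @param ann sample annotation or label vector.
#' @param alpha FDR level for the direction call.
#' @param pseudocount added before the ratio and the log transform.
#' @param fc_threshold linear fold-change cut-off for the direction call.
#' @param case,control class labels.
#' @return data.frame with columns `gene_id`, `mean_case`, `mean_ctrl`,
#'   `fold_change`, `log2fc`, `t`, `p`, `minus_log10_p`, `q`, `direction`.
#' @export
differential_expression <- function(X, ann, alpha = 0.05, pseudocount = 1,
                                    fc_threshold = 2,
                                    case = "case", control = "control") {
  if (identical(attr(X, "scale"), "log"))
    stop("differential_expression expects a linear-scale (RPKM) matrix")
  grp <- .match_classes(X, ann, case, control)
  if (length(grp$case_idx) < 2 || length(grp$ctrl_idx) < 2)
    stop("each class needs >= 2 samples")
  V <- unclass(X)
  keep <- rowSums(V[, c(grp$case_idx, grp$ctrl_idx), drop = FALSE]) > 0
  if (any(!keep))
    message(sprintf("dropping %d gene(s) at zero in both groups", sum(!keep)))
  V <- V[keep, , drop = FALSE]
  A <- V[, grp$case_idx, drop = FALSE]
  B <- V[, grp$ctrl_idx, drop = FALSE]
  mean_case <- rowMeans(A)
  mean_ctrl <- rowMeans(B)
  fc <- (mean_case + pseudocount) / (mean_ctrl + pseudocount)

  LA <- log2(A + pseudocount); LB <- log2(B + pseudocount)
  n1 <- ncol(LA); n2 <- ncol(LB)
  m1 <- rowMeans(LA); m2 <- rowMeans(LB)
  v1 <- rowSums((LA - m1)^2) / (n1 - 1)
  v2 <- rowSums((LB - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  degen <- se2 == 0
  if (any(degen)) {
    p[degen] <- ifelse(m1[degen] == m2[degen], 1, 0)
    tstat[degen] <- ifelse(m1[degen] == m2[degen], 0, Inf * sign(m1 - m2)[degen])
  }
  q <- bh_adjust(p)
  dir <- rep("ns", length(p))
  dir[q < alpha & fc >= fc_threshold] <- "up"
  dir[q < alpha & fc <= 1 / fc_threshold] <- "down"
  data.frame(gene_id = rownames(V),
             mean_case = mean_case, mean_ctrl = mean_ctrl,
             fold_change = fc, log2fc = log2(fc),
             t = tstat, p = p, minus_log10_p = -log10(p), q = q,
             direction = dir, stringsAsFactors = FALSE, row.names = NULL)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin validated wrapper around `p.adjust(..., method = "BH")`: q_(i) =
#' min over j >= i of p_(j) * m / j, returned in the input order.
#'
#' @param p vector of p-values in \[0, 1\].
#' @return q-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must be numeric in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Per-sample sum of expression over a gene set
#'
#' Total RPKM of a gene set's members in each sample — the global expression
#' level of the set, used e.g. to track a regulon's output across cell
#' lines.  Members absent from the matrix are ignored with a message.
#'
#' @param X linear-scale expression matrix.
#' @param s a [gene_set()] (or character vector).
#' @return object of class `set_sum`: list with `sample_ids`, `sum` (named
#'   numeric), `set_name`, and `n_used`/`n_missing` gene counts.
#' @export
gene_set_sum <- function(X, s) {
  genes <- .as_gene_ids(s)
  nm <- if (inherits(s, "gene_set")) s$name else "set"
  found <- intersect(genes, rownames(X))
  if (!length(found))
    stop(sprintf("gene set '%s' shares no genes with the matrix", nm))
  n_missing <- length(genes) - length(found)
  if (n_missing > 0)
    message(sprintf("gene set '%s': %d member(s) absent from the matrix",
                    nm, n_missing))
  sums <- colSums(unclass(X)[found, , drop = FALSE])
  structure(list(sample_ids = colnames(X),
                 sum = stats::setNames(sums, colnames(X)),
                 set_name = nm, n_used = length(found),
                 n_missing = n_missing),
            class = "set_sum")
}

#' @export
print.set_sum <- function(x, ...) {
  cat(sprintf("Expression sum of set '%s' (%d genes) over %d samples\n",
              x$set_name, x$n_used, length(x$sum)))
  print(utils::head(x$sum), ...)
  if (length(x$sum) > 6) cat("...\n")
  invisible(x)
}

#' Screen transcription-factor genes against a target expression sum
#'
#' For each transcription-factor gene present in the matrix, computes the
#' Spearman rank correlation (midranks for ties) between that gene's
#' expression and a target per-sample sum (typically the summed expression
#' of a consensus gene list), with the two-sided p-value from the t
#' approximation.  Results are ranked by decreasing correlation.
#'
#' @param X linear-scale expression matrix.
#' @param tf_genes [gene_set()] of transcription-factor gene identifiers.
#' @param target a `set_sum` (from [gene_set_sum()]) or named numeric vector
#'   over at least 5 samples shared with `X`.
#' @return data.frame `tf`, `r`, `p`, `rank`, ordered by descending `r`;
#'   factors absent from the matrix are skipped with a message.
#' @export
tf_correlation_screen <- function(X, tf_genes, target) {
  tgt <- if (inherits(target, "set_sum")) target$sum else target
  shared <- intersect(colnames(X), names(tgt))
  if (length(shared) < 5)
    stop("need >= 5 shared samples between matrix and target")
  tgt <- tgt[shared]
  genes <- .as_gene_ids(tf_genes)
  present <- intersect(genes, rownames(X))
  absent <- setdiff(genes, present)
  if (length(absent))
    message(sprintf("%d TF gene(s) absent from the matrix: %s",
                    length(absent),
                    paste(utils::head(absent, 5), collapse = ", ")))
  if (!length(present)) stop("no TF genes found in the matrix")
  V <- unclass(X)[present, shared, drop = FALSE]
  res <- lapply(present, function(g) {
    ct <- stats::cor.test(V[g, ], tgt, method = "spearman", exact = FALSE)
    data.frame(tf = g, r = unname(ct$estimate), p = ct$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out <- out[order(-out$r), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
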