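#' Fit the characteristic direction separating two sample classes
#'
#' Computes the unit vector `b` normal to the hyperplane that best separates
#' the two classes in gene-expression space — a shrinkage-regularised linear
#' discriminant:
#' \deqn{b \propto ((1-\gamma)\,\Sigma_{pooled} + \gamma I)^{-1}
#'       (\mu_{case} - \mu_{control})}
#' normalised to unit Euclidean length.  The shrinkage weight `gamma` mixes
#' the pooled within-class covariance with the identity, which keeps the
#' system well-posed in the usual p >> n regime of expression data.  The sign
#' is fixed so that the mean projection score of case samples is at least
#' that of control samples.
#'
#' For p > n the inverse is applied through the Woodbury identity on the
#' low-rank form of the pooled covariance, so the cost is O(p n^2) rather
#' than O(p^3).
#'
#' @param X expression matrix (genes x samples); see [expression_matrix()].
#' @param ann sample annotation (see [sample_annotation()]) or a vector of
#'   class labels aligned with `colnames(X)`.
#' @param gamma shrinkage weight in \[0, 1\]; `gamma = 1` reduces the
#'   direction to the raw class-mean difference, `gamma = 0` is classical
#'   LDA (requires p < n).
#' @param case,control the labels denoting the two classes.
#' @return object of class `chardir` with components `gene_ids`, `b` (named
#'   unit vector of per-gene contributions), `gamma`, `class_order`,
#'   `p`/`q` (per-gene significance, `NULL` until [gene_significance()] is
#'   run), sample counts and the matched annotation.
#' @seealso [gene_significance()], [predict.chardir()], [pca_overview()]
#' @examples
#' sim <- simulate_two_class(n_genes = 50, n_case = 5, n_ctrl = 5, seed = 1)
#' cd <- characteristic_direction(sim$X, sim$ann, gamma = 0.5)
#' head(coef(cd))
#' @export
characteristic_direction <- function(X, ann, gamma = 0.5,
                                     case = "case", control = "control") {
  if (!is.numeric(gamma) || length(gamma) != 1 || gamma < 0 || gamma > 1)
    stop("gamma must be a single value in [0, 1]")
  grp <- .match_classes(X, ann, case, control)
  n1 <- length(grp$case_idx); n2 <- length(grp$ctrl_idx)
  if (n1 < 2 || n2 < 2)
    stop(sprintf("each class needs >= 2 samples (got %d '%s', %d '%s')",
                 n1, case, n2, control))
  b <- .cd_direction(unclass(X), grp$case_idx, grp$ctrl_idx, gamma)
  structure(list(gene_ids = rownames(X),
                 b = stats::setNames(b, rownames(X)),
                 gamma = gamma,
                 class_order = c(case = case, control = control),
                 p = NULL, q = NULL,
                 n_case = n1, n_ctrl = n2,
                 ann = grp$ann,
                 call = match.call()),
            class = "chardir")
}

# map annotation to column indices of X
.match_classes <- function(X, ann, case, control) {
  if (is.data.frame(ann)) {
    ann <- sample_annotation(ann)
    idx <- match(colnames(X), ann$sample_id)
    if (anyNA(idx))
      stop("samples missing from annotation: ",
           paste(colnames(X)[is.na(idx)], collapse = ", "))
    labels <- ann$class_label[idx]
    ann <- ann[idx, ]
  } else {
    labels <- as.character(ann)
    if (length(labels) != ncol(X))
      stop("label vector length does not match sample count")
    ann <- data.frame(sample_id = colnames(X), class_label = labels,
                      cell_type = NA_character_, origin = NA_character_,
                      stringsAsFactors = FALSE)
  }
  list(case_idx = which(labels == case),
       ctrl_idx = which(labels == control),
       ann = ann)
}

# core direction computation on a plain matrix; returns the unit vector with
# the case-over-control sign convention applied
.cd_direction <- function(X, case_idx, ctrl_idx, gamma) {
  p <- nrow(X)
  n1 <- length(case_idx); n2 <- length(ctrl_idx)
  d <- n1 + n2 - 2L
  mu1 <- rowMeans(X[, case_idx, drop = FALSE])
  mu2 <- rowMeans(X[, ctrl_idx, drop = FALSE])
  delta <- mu1 - mu2
  if (gamma == 1) {
    b <- delta
  } else {
    C <- cbind(X[, case_idx, drop = FALSE] - mu1,
               X[, ctrl_idx, drop = FALSE] - mu2)   # p x n, rank <= d
    if (gamma == 0) {
      if (p > d)
        stop("pooled covariance is singular (more genes than samples); ",
             "use gamma > 0")
      Sigma <- tcrossprod(C) / d
      b <- tryCatch(solve(Sigma, delta), error = function(e)
        stop("regularised covariance is singular; use gamma > 0"))
    } else if (p <= ncol(C)) {
      R <- (1 - gamma) * tcrossprod(C) / d + gamma * diag(p)
      b <- solve(R, delta)
    } else {
      # Woodbury: (gI + (1-g)/d CC')^{-1} x =
      #   (x - C (d g/(1-g) I + C'C)^{-1} C'x) / g
      n <- ncol(C)
      M <- crossprod(C) + diag(d * gamma / (1 - gamma), n)
      b <- (delta - C %*% solve(M, crossprod(C, delta))) / gamma
      b <- drop(b)
    }
  }
  nb <- sqrt(sum(b^2))
  if (nb == 0) stop("degenerate direction: class means are identical")
  b <- b / nb
  if (sum(b * delta) < 0) b <- -b
  b
}

#' @export
print.chardir <- function(x, ...) {
  cat("Characteristic direction\n")
  cat(sprintf("  genes: %d   samples: %d '%s' vs %d '%s'   gamma: %g\n",
              length(x$b), x$n_case, x$class_order[["case"]],
              x$n_ctrl, x$class_order[["control"]], x$gamma))
  if (!is.null(x$q))
    cat(sprintf("  significant genes (q < 0.05): %d\n", sum(x$q < 0.05)))
  else
    cat("  significance not yet computed; see gene_significance()\n")
  invisible(x)
}

#' Summarise a fitted characteristic direction
#'
#' @param object a `chardir` fit.
#' @param n number of top-|b| genes to tabulate.
#' @param alpha FDR threshold used in the significance count.
#' @param ... unused.
#' @return data.frame of the top genes ordered by |contribution| with
#'   columns `gene_id`, `b`, and, when available, `p` and `q`; printed with a
#'   header summarising the fit.
#' @export
summary.chardir <- function(object, n = 10, alpha = 0.05, ...) {
  ord <- order(abs(object$b), decreasing = TRUE)
  top <- data.frame(gene_id = object$gene_ids[ord],
                    b = unname(object$b[ord]),
                    stringsAsFactors = FALSE)
  if (!is.null(object$p)) {
    top$p <- unname(object$p[ord])
    top$q <- unname(object$q[ord])
  }
  out <- list(fit = object, top = utils::head(top, n), alpha = alpha)
  class(out) <- "summary.chardir"
  out
}

#' @export
print.summary.chardir <- function(x, ...) {
  print(x$fit)
  if (!is.null(x$fit$q))
    cat(sprintf("  genes with q < %g: %d\n", x$alpha,
                sum(x$fit$q < x$alpha)))
  cat("\nTop contributing genes:\n")
  print(x$top, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
coef.chardir <- function(object, ...) object$b

#' Extract the per-gene result table of a fit
#'
#' @param cd a `chardir` fit.
#' @return data.frame with columns `gene_id`, `b` and, if significance was
#'   computed, `p` and `q`.
#' @export
chardir_table <- function(cd) {
  df <- data.frame(gene_id = cd$gene_ids, b = unname(cd$b),
                   stringsAsFactors = FALSE)
  if (!is.null(cd$p)) { df$p <- unname(cd$p); df$q <- unname(cd$q) }
  df
}

#' Plot projection scores along the characteristic direction
#'
#' Strip chart of the per-sample projection scores, split by class, for a
#' quick view of the separation the direction achieves.
#'
#' @param x a `chardir` fit.
#' @param X expression matrix to project (genes x samples).
#' @param ann annotation for `X` (defaults to the training annotation).
#' @param ... passed to [graphics::stripchart()].
#' @return invisibly, the projection scores.
#' @export
plot.chardir <- function(x, X, ann = x$ann, ...) {
  sc <- project_samples(x, X)
  grp <- .match_classes(X, ann, x$class_order[["case"]],
                        x$class_order[["control"]])
  lab <- rep("other", ncol(X))
  lab[grp$case_idx] <- x$class_order[["case"]]
  lab[grp$ctrl_idx] <- x$class_order[["control"]]
  graphics::stripchart(split(sc$scores, lab), vertical = TRUE,
                       method = "jitter", pch = 19,
                       ylab = "projection score", ...)
  invisible(sc)
}
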