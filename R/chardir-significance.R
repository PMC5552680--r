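#' Permutation significance of per-gene contributions
#'
#' Assesses which genes contribute significantly to the characteristic
#' direction by refitting the direction under random permutations of the
#' class labels.  The two-sided p-value of gene i is the fraction of
#' permutation directions whose |b_i| reaches the observed |b_i|
#' (ties counted, i.e. the comparison is inclusive), with the usual
#' add-one pseudocount:
#' \deqn{p_i = (1 + \#\{|b^{perm}_i| \ge |b^{obs}_i|\}) / (n_{perm} + 1).}
#' False-discovery rates are Benjamini-Hochberg step-up over all genes.
#'
#' @param cd a `chardir` fit.
#' @param X the expression matrix the fit was made on.
#' @param ann its sample annotation (or label vector).
#' @param n_perm number of label permutations, at least 100.
#' @param seed integer seed for the permutation stream (mandatory, for
#'   reproducibility).
#' @return the `chardir` object with `p` and `q` filled in.
#' @export
gene_significance <- function(cd, X, ann, n_perm = 1000, seed) {
  if (n_perm < 100)
    stop("n_perm must be >= 100; fewer permutations give unstable tail estimates")
  if (missing(seed)) stop("a seed is required for reproducible permutations")
  grp <- .match_classes(X, ann, cd$class_order[["case"]],
                        cd$class_order[["control"]])
  used <- c(grp$case_idx, grp$ctrl_idx)
  n1 <- length(grp$case_idx)
  Xm <- unclass(X)[cd$gene_ids, used, drop = FALSE]
  obs <- abs(cd$b)
  hits <- integer(length(obs))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  n <- length(used)
  for (r in seq_len(n_perm)) {
    idx <- sample.int(n)
    bperm <- .cd_direction(Xm, idx[seq_len(n1)], idx[-seq_len(n1)], cd$gamma)
    hits <- hits + (abs(bperm) >= obs)
  }
  p <- (hits + 1) / (n_perm + 1)
  cd$p <- stats::setNames(p, cd$gene_ids)
  cd$q <- stats::setNames(bh_adjust(p), cd$gene_ids)
  cd$n_perm <- n_perm
  cd
}

# preserve the caller's RNG state around seeded internals
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
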