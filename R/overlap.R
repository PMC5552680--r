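#' Consensus differentially expressed genes across two platforms
#'
#' Genes called in the requested direction by both analyses — e.g. genes
#' down-regulated in the microarray discriminant AND down-regulated in the
#' RNA-seq comparison.
#'
#' @param a,b data.frames with columns `gene_id` and `direction`
#'   (`"up"`/`"down"`/`"ns"`), as returned by [differential_expression()] or
#'   [chardir_calls()].
#' @param direction `"up"` or `"down"`.
#' @return a [gene_set()] named `consensus_<direction>`; an empty
#'   intersection returns a zero-size placeholder with a message rather
#'   than an error.
#' @export
consensus_genes <- function(a, b, direction = c("down", "up")) {
  direction <- match.arg(direction)
  for (df in list(a, b))
    if (!all(c("gene_id", "direction") %in% colnames(df)))
      stop("inputs need columns 'gene_id' and 'direction'")
  ga <- a$gene_id[a$direction == direction]
  gb <- b$gene_id[b$direction == direction]
  shared <- intersect(ga, gb)
  nm <- paste0("consensus_", direction)
  if (!length(shared)) {
    message("consensus set is empty")
    return(structure(list(name = nm, genes = character(0),
                          direction = direction), class = "gene_set"))
  }
  gene_set(nm, shared, direction)
}

#' Direction calls from a significance-annotated characteristic direction
#'
#' Converts a `chardir` fit with permutation significance into the
#' `gene_id`/`direction` table [consensus_genes()] expects: `up` for a
#' significant positive contribution, `down` for a significant negative one.
#'
#' @param cd a `chardir` fit after [gene_significance()].
#' @param alpha FDR threshold.
#' @return data.frame with `gene_id`, `b`, `q`, `direction`.
#' @export
chardir_calls <- function(cd, alpha = 0.05) {
  if (is.null(cd$q))
    stop("run gene_significance() before extracting direction calls")
  dir <- rep("ns", length(cd$b))
  dir[cd$q < alpha & cd$b > 0] <- "up"
  dir[cd$q < alpha & cd$b < 0] <- "down"
  data.frame(gene_id = cd$gene_ids, b = unname(cd$b), q = unname(cd$q),
             direction = dir, stringsAsFactors = FALSE)
}

#' Fisher-exact overlap enrichment
#'
#' Given an observed overlap `k` between a query set of size `n` and a
#' property held by `D` of the `N` universe genes, computes the expected
#' overlap `n*D/N`, the fold-enrichment ratio `k/expected`, and the
#' one-sided Fisher exact p-value from the hypergeometric tail:
#' P\[X >= k\] for `test_side = "greater"` (enrichment), P\[X <= k\] for
#' `"less"` (depletion), with X ~ Hypergeometric(N, D, n).
#'
#' @param k observed overlap count.
#' @param n query set size.
#' @param D number of universe genes with the property.
#' @param N universe size.
#' @param test_side `"greater"` or `"less"`.
#' @return object of class `overlap_result` with fields `k`, `n`, `D`, `N`,
#'   `expected`, `ratio`, `p`, `test_side`.
#' @export
overlap_enrichment <- function(k, n, D, N, test_side = c("greater", "less")) {
  test_side <- match.arg(test_side)
  for (v in list(k = k, n = n, D = D, N = N))
    if (!is.numeric(v) || length(v) != 1 || v < 0 || v != round(v))
      stop("k, n, D, N must be single non-negative integers")
  if (D == 0 || n == 0) stop("expected overlap undefined for D = 0 or n = 0")
  if (N < max(n, D)) stop("universe smaller than a set: need N >= max(n, D)")
  if (k > min(n, D)) stop("k cannot exceed min(n, D)")
  if (k < n + D - N) stop("k below the feasible minimum n + D - N")
  expected <- n * D / N
  p <- if (test_side == "greater")
    stats::phyper(k - 1, D, N - D, n, lower.tail = FALSE)
  else
    stats::phyper(k, D, N - D, n, lower.tail = TRUE)
  structure(list(k = k, n = n, D = D, N = N, expected = expected,
                 ratio = k / expected, p = p, test_side = test_side),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf(
    "Overlap %d of %d (universe %d, annotated %d): expected %.2f, ratio %.2f, Fisher p (%s) = %.3g\n",
    x$k, x$n, x$N, x$D, x$expected, x$ratio, x$test_side, x$p))
  invisible(x)
}

#' @export
as.data.frame.overlap_result <- function(x, ...) {
  data.frame(k = x$k, n = x$n, D = x$D, N = x$N, expected = x$expected,
             ratio = x$ratio, p = x$p, test_side = x$test_side,
             stringsAsFactors = FALSE)
}

#' Venn partition of two or three gene sets
#'
#' Exact counts of every membership region, plus the aggregate counts of
#' genes in exactly one set and in two or more sets.
#'
#' @param sets list of 2 or 3 [gene_set()] objects (or character vectors).
#' @return object of class `venn_partition`: list with `set_names`,
#'   `regions` (named counts keyed by membership pattern such as `"110"`),
#'   `exactly_one`, `two_or_more`, `union_size`.
#' @export
venn_partition <- function(sets) {
  if (!is.list(sets) || length(sets) < 2 || length(sets) > 3)
    stop("venn_partition handles 2 or 3 sets")
  ids <- lapply(sets, .as_gene_ids)
  nms <- vapply(seq_along(sets), function(i) {
    if (inherits(sets[[i]], "gene_set")) sets[[i]]$name
    else paste0("set", i)
  }, character(1))
  all_genes <- unique(unlist(ids))
  member <- vapply(ids, function(g) all_genes %in% g, logical(length(all_genes)))
  if (length(all_genes) == 1) member <- matrix(member, nrow = 1)
  pattern <- apply(member, 1, function(z) paste(as.integer(z), collapse = ""))
  counts <- table(pattern)
  degree <- rowSums(member)
  structure(list(set_names = nms,
                 regions = stats::setNames(as.integer(counts), names(counts)),
                 exactly_one = sum(degree == 1),
                 two_or_more = sum(degree >= 2),
                 union_size = length(all_genes)),
            class = "venn_partition")
}

#' @export
print.venn_partition <- function(x, ...) {
  cat(sprintf("Venn partition of %d sets (%s): union %d genes\n",
              length(x$set_names), paste(x$set_names, collapse = ", "),
              x$union_size))
  cat(sprintf("  exactly one set: %d   two or more: %d\n",
              x$exactly_one, x$two_or_more))
  for (nm in names(x$regions))
    cat(sprintf("  pattern %s: %d\n", nm, x$regions[[nm]]))
  invisible(x)
}
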