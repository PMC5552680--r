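#' Construct a gene set (regulon or signature)
#'
#' @param name set name, e.g. a transcription-factor symbol such as `"LEF1"`.
#' @param genes character vector of gene identifiers; duplicates are removed.
#' @param direction optional tag `"up"`, `"down"` or `"none"` recording the
#'   regulation direction the set describes.
#' @return list of class `gene_set` with fields `name`, `genes`, `direction`.
#' @export
gene_set <- function(name, genes, direction = c("none", "up", "down")) {
  direction <- match.arg(direction)
  genes <- unique(as.character(genes))
  if (!length(genes)) stop("gene set '", name, "' is empty")
  structure(list(name = as.character(name), genes = genes,
                 direction = direction),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("Gene set '%s': %d genes (direction: %s)\n",
              x$name, length(x$genes), x$direction))
  invisible(x)
}

#' @export
length.gene_set <- function(x) length(x$genes)

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated fields
#' `name<TAB>description<TAB>gene1<TAB>gene2...`.  Empty lines are skipped;
#' duplicate genes within a line are de-duplicated.
#'
#' @param path GMT file path.
#' @return named list of [gene_set()] objects, input order preserved.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  sets <- vector("list", length(keep))
  nm <- character(length(keep))
  for (i in seq_along(keep)) {
    fields <- strsplit(lines[keep[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3)
      stop(sprintf("GMT line %d has %d field(s); need name, description, >=1 gene",
                   keep[i], length(fields)))
    nm[i] <- fields[1]
    sets[[i]] <- gene_set(fields[1], fields[-(1:2)])
  }
  names(sets) <- nm
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets list of [gene_set()] objects.
#' @param path output path.
#' @param description description field for each line (recycled).
#' @export
write_gene_sets <- function(sets, path, description = "na") {
  lines <- vapply(sets, function(s)
    paste(c(s$name, description, s$genes), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Set difference of two regulons
#'
#' Returns the genes of `a` that are not in `b`, named `"<A>_not_<B>"`.
#' Used to compare regulons without their shared targets, so that a
#' correlation between the projected activities cannot be driven by common
#' genes.
#'
#' @param a,b [gene_set()] objects.
#' @return a [gene_set()]; error if the difference is empty.
#' @export
exclusive_regulon <- function(a, b) {
  rest <- setdiff(a$genes, b$genes)
  if (!length(rest))
    stop(sprintf("'%s' minus '%s' is empty; nothing to project", a$name, b$name))
  gene_set(paste0(a$name, "_not_", b$name), rest, a$direction)
}

.as_gene_ids <- function(s) {
  if (inherits(s, "gene_set")) s$genes else unique(as.character(s))
}
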