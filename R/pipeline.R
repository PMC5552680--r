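#' Assemble and validate a pipeline configuration
#'
#' A flat key-value list (or path to a YAML file of one) naming the input
#' files and numeric parameters of the end-to-end analysis.  Recognised
#' keys: `expr`, `ann` (discovery matrix and annotation), `validation_expr`,
#' `validation_ann`, `gmt` (regulons), `regulon_pairs` (e.g.
#' `"TF_A:TF_B"`), `rnaseq_expr`, `rnaseq_ann`, `model`, `uptake`,
#' `outdir`, and parameters `gamma`, `n_perm`, `alpha`, `fc_threshold`,
#' `pseudocount`, `seed`.  All referenced files must exist at run start.
#'
#' @param config list or YAML path.
#' @return validated config list with defaults filled, class
#'   `pipeline_config`.
#' @export
pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  defaults <- list(gamma = 0.5, n_perm = 1000, alpha = 0.05,
                   fc_threshold = 2, pseudocount = 1, seed = 1,
                   outdir = "chardir_out")
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  if (config$gamma < 0 || config$gamma > 1) stop("gamma must be in [0, 1]")
  if (config$n_perm < 100) stop("n_perm must be >= 100")
  if (config$alpha <= 0 || config$alpha >= 1) stop("alpha must be in (0, 1)")
  file_keys <- c("expr", "ann", "validation_expr", "validation_ann", "gmt",
                 "rnaseq_expr", "rnaseq_ann", "model", "uptake")
  for (nm in intersect(file_keys, names(config))) {
    if (!file.exists(config[[nm]]))
      stop(sprintf("config key '%s': file not found: %s", nm, config[[nm]]))
  }
  class(config) <- c("pipeline_config", "list")
  config
}

# stable fingerprint of the analysis-relevant configuration, stamped into
# every output file; the output location does not affect the results and is
# excluded so reruns into a different directory hash identically
.config_hash <- function(config) {
  cfg <- config[setdiff(names(config), "outdir")]
  cfg <- cfg[order(names(cfg))]
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste(names(cfg),
                   vapply(cfg, function(v) paste(format(v, digits = 15),
                                                 collapse = ","),
                          character(1)), sep = "="), tmp)
  unname(tools::md5sum(tmp))
}

.write_artifact <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# config_hash: ", hash), con)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) format(v, digits = 15, trim = TRUE))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Discovery stage: fit, test and project the characteristic direction
#'
#' Reads the discovery expression matrix and annotation, fits the
#' characteristic direction, computes permutation significance, projects
#' the training samples, and writes `cd.tsv` (gene_id, b, p, q),
#' `scores.tsv` (per-sample projection scores with class labels) and
#' `significant_genes.tsv` (genes with q below `alpha`) into `outdir`.
#'
#' @param config a [pipeline_config()] (or list/YAML path).
#' @return list with the fitted `cd`, the `scores`, and `files` written.
#' @export
run_discovery <- function(config) {
  config <- pipeline_config(config)
  for (nm in c("expr", "ann"))
    if (is.null(config[[nm]])) stop("discovery needs config key '", nm, "'")
  hash <- .config_hash(config)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  X <- read_expression_table(config$expr, "log")
  ann <- read_sample_annotation(config$ann)
  message(sprintf("discovery: %d genes x %d samples", nrow(X), ncol(X)))
  cd <- characteristic_direction(X, ann, gamma = config$gamma)
  cd <- gene_significance(cd, X, ann, n_perm = config$n_perm,
                          seed = config$seed)
  scores <- project_samples(cd, X)
  tab <- chardir_table(cd)
  sig <- tab[tab$q < config$alpha, , drop = FALSE]
  message(sprintf("discovery: %d of %d genes significant at q < %g",
                  nrow(sig), nrow(tab), config$alpha))
  lab <- ann$class_label[match(scores$sample_ids, ann$sample_id)]
  files <- c(
    .write_artifact(tab, file.path(config$outdir, "cd.tsv"), hash),
    .write_artifact(data.frame(sample_id = scores$sample_ids,
                               score = unname(scores$scores),
                               class_label = lab, stringsAsFactors = FALSE),
                    file.path(config$outdir, "scores.tsv"), hash),
    .write_artifact(sig, file.path(config$outdir, "significant_genes.tsv"),
                    hash))
  list(cd = cd, scores = scores, files = files)
}

#' Validation stage: project an independently normalised dataset
#'
#' Aligns the validation matrix with the fitted direction's gene space
#' (warning when fewer than half the genes are shared), projects its
#' samples, and reports the separation margin: the minimum case score minus
#' the maximum control score.
#'
#' @param config a [pipeline_config()] with `validation_expr` and
#'   `validation_ann`.
#' @param cd a fitted `chardir` (e.g. from [run_discovery()]).
#' @return list with `scores`, `separation`, and the file written.
#' @export
run_validation <- function(config, cd) {
  config <- pipeline_config(config)
  for (nm in c("validation_expr", "validation_ann"))
    if (is.null(config[[nm]])) stop("validation needs config key '", nm, "'")
  hash <- .config_hash(config)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  X <- read_expression_table(config$validation_expr, "log")
  ann <- read_sample_annotation(config$validation_ann)
  shared <- length(intersect(cd$gene_ids, rownames(X)))
  if (shared == 0) stop("validation matrix shares no genes with the fit")
  if (shared < 0.5 * length(cd$gene_ids))
    warning(sprintf("validation matrix shares only %d of %d fitted genes",
                    shared, length(cd$gene_ids)))
  scores <- project_samples(cd, X)
  lab <- ann$class_label[match(scores$sample_ids, ann$sample_id)]
  case_s <- scores$scores[lab == cd$class_order[["case"]]]
  ctrl_s <- scores$scores[lab == cd$class_order[["control"]]]
  sep <- min(case_s) - max(ctrl_s)
  message(sprintf("validation: separation margin %.4f over %d samples",
                  sep, length(scores$scores)))
  f <- .write_artifact(
    data.frame(sample_id = scores$sample_ids, score = unname(scores$scores),
               class_label = lab, stringsAsFactors = FALSE),
    file.path(config$outdir, "validation_scores.tsv"), hash)
  list(scores = scores, separation = sep, files = f)
}

#' Regulon stage: activities and their correlations
#'
#' Projects the direction on every regulon of the GMT file against the
#' discovery matrix and correlates the requested activity pairs.
#'
#' @param config a [pipeline_config()] with `gmt` (and optionally
#'   `regulon_pairs`, strings like `"TF_A:TF_B"`).
#' @param cd fitted `chardir`.
#' @return list with the `activities` table, `correlations`, files.
#' @export
run_regulons <- function(config, cd) {
  config <- pipeline_config(config)
  if (is.null(config$gmt)) stop("regulon stage needs config key 'gmt'")
  hash <- .config_hash(config)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  X <- read_expression_table(config$expr, "log")
  sets <- read_gene_sets(config$gmt)
  acts <- lapply(sets, function(s) regulon_activity(cd, X, s))
  act_tab <- data.frame(sample_id = colnames(X),
                        lapply(acts, function(a) unname(a$scores)),
                        check.names = FALSE, stringsAsFactors = FALSE)
  files <- .write_artifact(act_tab,
                           file.path(config$outdir, "activities.tsv"), hash)
  cors <- NULL
  pairs <- config$regulon_pairs
  if (!is.null(pairs)) {
    rows <- lapply(pairs, function(pp) {
      ab <- strsplit(pp, ":", fixed = TRUE)[[1]]
      if (length(ab) != 2 || !all(ab %in% names(acts)))
        stop("regulon pair '", pp, "' not found in the GMT sets")
      cr <- activity_correlation(acts[[ab[1]]], acts[[ab[2]]], "pearson")
      data.frame(set_a = ab[1], set_b = ab[2], r = cr$r, p = cr$p, n = cr$n,
                 stringsAsFactors = FALSE)
    })
    cors <- do.call(rbind, rows)
    files <- c(files, .write_artifact(
      cors, file.path(config$outdir, "regulon_correlations.tsv"), hash))
  }
  list(activities = act_tab, correlations = cors, files = files)
}

#' Consensus stage: RNA-seq differential expression and platform overlap
#'
#' Runs Welch-t differential expression on the RNA-seq RPKM matrix,
#' intersects its calls with the array-based direction calls in each
#' direction, and tests the overlaps by one-sided Fisher exact tests
#' (enrichment for the down-consensus, depletion for the up-consensus)
#' against the universe of genes measured on both platforms.
#'
#' @param config a [pipeline_config()] with `rnaseq_expr`, `rnaseq_ann`.
#' @param cd fitted `chardir` with significance.
#' @return list with `de`, the consensus [gene_set()]s, the
#'   `overlap` results, files.
#' @export
run_consensus <- function(config, cd) {
  config <- pipeline_config(config)
  for (nm in c("rnaseq_expr", "rnaseq_ann"))
    if (is.null(config[[nm]])) stop("consensus needs config key '", nm, "'")
  hash <- .config_hash(config)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  X <- read_expression_table(config$rnaseq_expr, "linear")
  ann <- read_sample_annotation(config$rnaseq_ann)
  de <- differential_expression(X, ann, alpha = config$alpha,
                                pseudocount = config$pseudocount,
                                fc_threshold = config$fc_threshold)
  calls <- chardir_calls(cd, alpha = config$alpha)
  universe <- intersect(calls$gene_id, de$gene_id)
  message(sprintf("consensus: universe of %d genes shared by both platforms",
                  length(universe)))
  files <- .write_artifact(de, file.path(config$outdir, "rnaseq_de.tsv"),
                           hash)
  out <- list(de = de)
  ov_rows <- NULL
  for (dir in c("down", "up")) {
    cons <- consensus_genes(calls, de, dir)
    out[[paste0("consensus_", dir)]] <- cons
    a_dir <- intersect(calls$gene_id[calls$direction == dir], universe)
    b_dir <- intersect(de$gene_id[de$direction == dir], universe)
    k <- length(intersect(a_dir, b_dir))
    message(sprintf("consensus %s: %d array, %d rna-seq, %d shared",
                    dir, length(a_dir), length(b_dir), k))
    if (length(a_dir) && length(b_dir)) {
      ov <- overlap_enrichment(k, length(a_dir), length(b_dir),
                               length(universe),
                               test_side = if (dir == "down") "greater"
                               else "less")
      ov_rows <- rbind(ov_rows, cbind(direction = dir, as.data.frame(ov)))
      out[[paste0("overlap_", dir)]] <- ov
    }
    if (length(cons$genes))
      files <- c(files, .write_artifact(
        data.frame(gene_id = cons$genes, stringsAsFactors = FALSE),
        file.path(config$outdir, paste0("consensus_", dir, ".tsv")), hash))
  }
  if (!is.null(ov_rows))
    files <- c(files, .write_artifact(
      ov_rows, file.path(config$outdir, "overlap_enrichment.tsv"), hash))
  out$files <- files
  out
}

#' Read a table of per-cell-line metabolite exchange rates
#'
#' TSV with a `cell_line` column and one signed-rate column per metabolite
#' (uptake negative, secretion positive).
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_uptake_profiles <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "#")
  if (!"cell_line" %in% colnames(df))
    stop("uptake table needs a 'cell_line' column")
  df
}

#' ATP stage: flux fits and ATP source attribution
#'
#' @param config a [pipeline_config()] with `model` (JSON, or SBML by
#'   `.xml`/`.sbml` extension) and `uptake`.
#' @return list with the `breakdown` table and file written.
#' @export
run_atp <- function(config) {
  config <- pipeline_config(config)
  for (nm in c("model", "uptake"))
    if (is.null(config[[nm]])) stop("atp stage needs config key '", nm, "'")
  hash <- .config_hash(config)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  model <- if (grepl("\\.(xml|sbml)$", config$model, ignore.case = TRUE))
    read_model_sbml(config$model, atp = "atp", inorganic = c("o2", "co2"))
  else load_model(config$model)
  profiles <- read_uptake_profiles(config$uptake)
  bd <- atp_accounting(model, profiles)
  message(sprintf("atp: %d cell lines, BCAA fraction %.2f-%.2f",
                  nrow(bd), min(bd$frac_leu + bd$frac_ile + bd$frac_val),
                  max(bd$frac_leu + bd$frac_ile + bd$frac_val)))
  f <- .write_artifact(bd, file.path(config$outdir, "atp_breakdown.tsv"),
                       hash)
  list(breakdown = bd, files = f)
}

#' Run the full pipeline and write a manifest
#'
#' Executes the five stages (discovery, validation, regulons, consensus,
#' ATP accounting) in order, skipping stages whose inputs are not
#' configured, recording per-stage status in `manifest.tsv` together with
#' MD5 checksums of every artifact.  A stage failure is recorded and the
#' remaining stages still run; if any stage failed the returned manifest
#' carries `attr(, "failed") = TRUE` and a warning is raised.
#'
#' @param config a [pipeline_config()] (or list/YAML path).
#' @return the manifest data.frame (stage, status, outputs, md5, note).
#' @export
run_full <- function(config) {
  config <- pipeline_config(config)
  hash <- .config_hash(config)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  cd <- NULL
  stage_defs <- list(
    discovery = function() {
      res <- run_discovery(config); cd <<- res$cd; res$files
    },
    validation = function() {
      if (is.null(config$validation_expr)) return(NULL)
      run_validation(config, cd)$files
    },
    regulons = function() {
      if (is.null(config$gmt)) return(NULL)
      run_regulons(config, cd)$files
    },
    consensus = function() {
      if (is.null(config$rnaseq_expr)) return(NULL)
      run_consensus(config, cd)$files
    },
    atp = function() {
      if (is.null(config$model)) return(NULL)
      run_atp(config)$files
    })
  rows <- list()
  for (nm in names(stage_defs)) {
    res <- tryCatch(list(files = stage_defs[[nm]](), err = NULL),
                    error = function(e) list(files = NULL,
                                             err = conditionMessage(e)))
    if (!is.null(res$err)) {
      rows[[nm]] <- data.frame(stage = nm, status = "failed", outputs = "",
                               md5 = "", note = res$err,
                               stringsAsFactors = FALSE)
    } else if (is.null(res$files)) {
      rows[[nm]] <- data.frame(stage = nm, status = "skipped", outputs = "",
                               md5 = "", note = "inputs not configured",
                               stringsAsFactors = FALSE)
    } else {
      rows[[nm]] <- data.frame(stage = nm, status = "complete",
                               outputs = paste(basename(res$files),
                                               collapse = ";"),
                               md5 = paste(unname(tools::md5sum(res$files)),
                                           collapse = ";"),
                               note = "", stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  .write_artifact(manifest, file.path(config$outdir, "manifest.tsv"), hash)
  if (any(manifest$status == "failed")) {
    attr(manifest, "failed") <- TRUE
    warning("pipeline stage(s) failed: ",
            paste(manifest$stage[manifest$status == "failed"],
                  collapse = ", "))
  }
  manifest
}
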