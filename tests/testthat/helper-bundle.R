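# build a complete synthetic input bundle on disk and return a config list
make_bundle <- function(dir, seed = 17, effect = 3) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_two_class(n_genes = 1000, n_case = 20, n_ctrl = 20,
                            planted_up = 10, planted_down = 10,
                            effect_size = effect, seed = seed)
  write_expression_table(sim$X, file.path(dir, "expr.tsv"))
  utils::write.table(sim$ann, file.path(dir, "ann.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  val <- simulate_two_class(n_genes = 1000, n_case = 8, n_ctrl = 8,
                            planted_up = 10, planted_down = 10,
                            effect_size = effect, seed = seed + 500)
  write_expression_table(val$X, file.path(dir, "val_expr.tsv"))
  utils::write.table(val$ann, file.path(dir, "val_ann.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  sets <- list(
    planted_up = sim$planted_up,
    planted_down = sim$planted_down)
  names(sets) <- c("planted_up", "planted_down")
  write_gene_sets(sets, file.path(dir, "sets.gmt"))
  rna <- simulate_two_class(n_genes = 1000, n_case = 8, n_ctrl = 8,
                            planted_up = 10, planted_down = 10,
                            effect_size = effect, rpkm_mode = TRUE,
                            seed = seed + 900)
  write_expression_table(rna$X, file.path(dir, "rpkm.tsv"))
  utils::write.table(rna$ann, file.path(dir, "rna_ann.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_model(toy_core_model(), file.path(dir, "model.json"))
  up <- simulate_uptake_profiles(5, seed = seed)
  utils::write.table(up, file.path(dir, "uptake.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  list(expr = file.path(dir, "expr.tsv"), ann = file.path(dir, "ann.tsv"),
       validation_expr = file.path(dir, "val_expr.tsv"),
       validation_ann = file.path(dir, "val_ann.tsv"),
       gmt = file.path(dir, "sets.gmt"),
       regulon_pairs = "planted_up:planted_down",
       rnaseq_expr = file.path(dir, "rpkm.tsv"),
       rnaseq_ann = file.path(dir, "rna_ann.tsv"),
       model = file.path(dir, "model.json"),
       uptake = file.path(dir, "uptake.tsv"),
       n_perm = 1000, seed = 11,
       outdir = file.path(dir, "out"),
       planted = c(sim$planted_up$genes, sim$planted_down$genes))
}
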