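# small labelled fixture: p genes, n1+n2 samples, optional planted shift on
# gene 1 of the case class
small_fixture <- function(p = 3, n1 = 4, n2 = 4, shift = 2, seed = 7) {
  set.seed(seed)
  X <- matrix(rnorm(p * (n1 + n2)), p,
              dimnames = list(paste0("g", seq_len(p)),
                              paste0("s", seq_len(n1 + n2))))
  X[1, seq_len(n1)] <- X[1, seq_len(n1)] + shift
  list(X = expression_matrix(X, "log"),
       labels = rep(c("case", "control"), c(n1, n2)))
}

test_that("gamma = 1 reduces the direction to the class-mean difference", {
  X <- expression_matrix(
    matrix(c(2, 0, 2, 0, 0, 0, 0, 0), 2,
           dimnames = list(c("g1", "g2"), paste0("s", 1:4))), "log")
  labels <- c("case", "case", "control", "control")
  # g1 differs by +2 between classes, g2 not at all
  cd <- characteristic_direction(X, labels, gamma = 1)
  expect_equal(unname(coef(cd)), c(1, 0))

  fx <- small_fixture(p = 20, seed = 11)
  cd2 <- characteristic_direction(fx$X, fx$labels, gamma = 1)
  delta <- rowMeans(unclass(fx$X)[, 1:4]) - rowMeans(unclass(fx$X)[, 5:8])
  expect_equal(unname(coef(cd2)), unname(delta / sqrt(sum(delta^2))),
               tolerance = 1e-12)
})

test_that("the fitted direction matches a dense linear-solve oracle", {
  fx <- small_fixture(p = 3, seed = 1)
  cd <- characteristic_direction(fx$X, fx$labels, gamma = 0.5)
  b_ref <- ref_direction(unclass(fx$X), 1:4, 5:8, 0.5)
  expect_equal(unname(coef(cd)), unname(b_ref), tolerance = 1e-10)

  # p > n exercises the Woodbury path against the same dense oracle
  fx2 <- small_fixture(p = 50, seed = 2)
  for (g in c(0.3, 0.5, 0.9)) {
    cd2 <- characteristic_direction(fx2$X, fx2$labels, gamma = g)
    b_ref2 <- ref_direction(unclass(fx2$X), 1:4, 5:8, g)
    expect_equal(unname(coef(cd2)), unname(b_ref2), tolerance = 1e-10)
  }
})

test_that("the direction is unit length with case-over-control sign", {
  for (seed in 1:5) {
    fx <- small_fixture(p = 30, seed = seed)
    cd <- characteristic_direction(fx$X, fx$labels, gamma = 0.5)
    expect_equal(sum(coef(cd)^2), 1, tolerance = 1e-9)
    sc <- project_samples(cd, fx$X)
    expect_gte(mean(sc$scores[1:4]), mean(sc$scores[5:8]))
  }
})

test_that("permuting gene rows permutes the direction identically", {
  fx <- small_fixture(p = 12, seed = 3)
  cd <- characteristic_direction(fx$X, fx$labels, gamma = 0.5)
  perm <- sample(12)
  cd_p <- characteristic_direction(fx$X[perm, ], fx$labels, gamma = 0.5)
  expect_equal(coef(cd_p), coef(cd)[perm], tolerance = 1e-12)
})

test_that("degenerate fits are refused with instructive errors", {
  fx <- small_fixture(p = 10, n1 = 1, n2 = 4)
  expect_error(characteristic_direction(fx$X, fx$labels), ">= 2 samples")
  fx2 <- small_fixture(p = 50, n1 = 4, n2 = 4)
  expect_error(characteristic_direction(fx2$X, fx2$labels, gamma = 0),
               "gamma > 0")
  expect_error(characteristic_direction(fx2$X, fx2$labels, gamma = 2),
               "gamma")
})

test_that("permutation p-values are exact at the pseudocount ceiling", {
  # a constant gene has b = 0 observed; every permutation ties it, so
  # p = (n_perm + 1)/(n_perm + 1) = 1 exactly
  fx <- small_fixture(p = 10, seed = 5)
  Xc <- unclass(fx$X)
  Xc[10, ] <- 3.14
  X <- expression_matrix(Xc, "log")
  cd <- characteristic_direction(X, fx$labels, gamma = 0.5)
  cd <- gene_significance(cd, X, fx$labels, n_perm = 100, seed = 9)
  expect_identical(unname(cd$p["g10"]), 1)
  expect_true(all(cd$p >= 1 / 101 & cd$p <= 1))
  expect_equal(unname(cd$q), ref_bh(unname(cd$p)), tolerance = 1e-12)
  expect_error(gene_significance(cd, X, fx$labels, n_perm = 50, seed = 1),
               "n_perm")
  expect_error(gene_significance(cd, X, fx$labels, n_perm = 100), "seed")
})

test_that("permutation significance is reproducible and recovers signal", {
  sim <- simulate_two_class(n_genes = 200, n_case = 10, n_ctrl = 10,
                            planted_up = 5, planted_down = 5,
                            effect_size = 3, seed = 21)
  cd <- characteristic_direction(sim$X, sim$ann, 0.5)
  s1 <- gene_significance(cd, sim$X, sim$ann, n_perm = 200, seed = 4)
  s2 <- gene_significance(cd, sim$X, sim$ann, n_perm = 200, seed = 4)
  expect_identical(s1$p, s2$p)
  planted <- c(sim$planted_up$genes, sim$planted_down$genes)
  expect_true(mean(s1$p[planted]) < mean(s1$p[setdiff(names(s1$p), planted)]))
})

test_that("projection scores follow the centred inner-product definition", {
  fx <- small_fixture(p = 5, seed = 8)
  cd <- characteristic_direction(fx$X, fx$labels, gamma = 1)
  # force b = e1 to check the closed form
  cd$b <- stats::setNames(c(1, 0, 0, 0, 0), cd$gene_ids)
  sc <- project_samples(cd, fx$X)
  g1 <- unclass(fx$X)[1, ]
  expect_equal(unname(sc$scores), unname(g1 - mean(g1)), tolerance = 1e-12)

  # subset disjoint from the support of b gives all-zero scores
  sc0 <- project_samples(cd, fx$X, subset = gene_set("rest", c("g4", "g5")))
  expect_true(all(sc0$scores == 0))

  # centering invariance: per-gene constants do not move the scores
  shifted <- expression_matrix(unclass(fx$X) + seq_len(5) * 10, "log")
  sc_s <- project_samples(cd, fx$X)
  sc_t <- project_samples(cd, shifted)
  expect_equal(sc_t$scores, sc_s$scores, tolerance = 1e-9)
})

test_that("projection is equivariant under joint gene permutation", {
  fx <- small_fixture(p = 15, seed = 13)
  cd <- characteristic_direction(fx$X, fx$labels, 0.5)
  perm <- sample(15)
  cd_p <- characteristic_direction(fx$X[perm, ], fx$labels, 0.5)
  expect_equal(project_samples(cd_p, fx$X[perm, ])$scores,
               project_samples(cd, fx$X)$scores, tolerance = 1e-10)
})

test_that("well-separated classes give disjoint projection ranges", {
  sim <- simulate_two_class(n_genes = 500, n_case = 10, n_ctrl = 10,
                            planted_up = 10, planted_down = 10,
                            effect_size = 3, seed = 33)
  cd <- characteristic_direction(sim$X, sim$ann, 0.5)
  sc <- project_samples(cd, sim$X)
  lab <- sim$ann$class_label
  expect_gt(min(sc$scores[lab == "case"]), max(sc$scores[lab == "control"]))
})

test_that("predict() delegates to the projection", {
  fx <- small_fixture()
  cd <- characteristic_direction(fx$X, fx$labels, 0.5)
  expect_equal(predict(cd, fx$X)$scores, project_samples(cd, fx$X)$scores)
  expect_error(predict(cd), "newdata")
})

test_that("pca_overview separates displaced clusters and centres genes", {
  set.seed(14)
  X <- matrix(rnorm(40 * 10, sd = 0.1), 40,
              dimnames = list(paste0("g", 1:40), paste0("s", 1:10)))
  X[1, 6:10] <- X[1, 6:10] + 10      # one gene displaces half the samples
  Xm <- expression_matrix(X, "log")
  pc <- pca_overview(Xm, 2)
  expect_gt(pc$var_share[1], 0.9)
  expect_gt(min(pc$coords[6:10, 1]), max(pc$coords[1:5, 1]))

  off <- expression_matrix(X + rnorm(40), "log")  # per-gene constant offset
  pc2 <- pca_overview(off, 2)
  expect_equal(pc2$coords, pc$coords, tolerance = 1e-9)

  expect_error(pca_overview(Xm, 0), "positive")
  expect_error(pca_overview(Xm, 11), "rank")
})

test_that("print, summary and table accessors expose the fit", {
  sim <- simulate_two_class(n_genes = 50, n_case = 5, n_ctrl = 5, seed = 2)
  cd <- characteristic_direction(sim$X, sim$ann, 0.5)
  expect_output(print(cd), "Characteristic direction")
  cd <- gene_significance(cd, sim$X, sim$ann, n_perm = 100, seed = 1)
  sm <- summary(cd, n = 5)
  expect_s3_class(sm, "summary.chardir")
  expect_output(print(sm), "Top contributing genes")
  tab <- chardir_table(cd)
  expect_named(tab, c("gene_id", "b", "p", "q"))
  expect_equal(nrow(tab), 50)
})
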