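test_that("generators are pure functions of their seed", {
  a <- simulate_two_class(n_genes = 100, n_case = 5, n_ctrl = 5, seed = 3)
  b <- simulate_two_class(n_genes = 100, n_case = 5, n_ctrl = 5, seed = 3)
  expect_identical(unclass(a$X), unclass(b$X))
  expect_identical(a$ann, b$ann)
  c1 <- simulate_latent_regulons(n_genes = 200, regulons = c(A = 20, B = 20),
                                 seed = 4)
  c2 <- simulate_latent_regulons(n_genes = 200, regulons = c(A = 20, B = 20),
                                 seed = 4)
  expect_identical(unclass(c1$X), unclass(c2$X))
  expect_identical(c1$latents, c2$latents)
  u1 <- simulate_uptake_profiles(5, seed = 5)
  u2 <- simulate_uptake_profiles(5, seed = 5)
  expect_identical(u1, u2)
  # generators do not perturb the caller's RNG stream
  set.seed(1); before <- rnorm(1)
  set.seed(1); invisible(simulate_two_class(n_genes = 10, n_case = 2,
                                            n_ctrl = 2, planted_up = 1,
                                            planted_down = 1, seed = 99))
  expect_identical(rnorm(1), before)
})

test_that("generator preconditions are enforced", {
  expect_error(simulate_two_class(n_genes = 10, planted_up = 8,
                                  planted_down = 8, seed = 1), "exceed")
  expect_error(simulate_two_class(effect_size = -1, seed = 1), "effect_size")
  expect_error(simulate_two_class(n_genes = 10), "seed")
  expect_error(simulate_latent_regulons(regulons = c(A = 10), seed = 1),
               "two regulons")
  expect_error(simulate_latent_regulons(n_genes = 10,
                                        regulons = c(A = 50, B = 50),
                                        seed = 1), "exceed")
  expect_error(simulate_latent_regulons(coupling = 0, class_shift = 5,
                                        seed = 1), "class_shift")
  expect_error(simulate_uptake_profiles(5, ranges = list(glucose = c(1, 2)),
                                        seed = 1), "cover")
  bad <- list(glucose = c(0.5, 2), ferm_fraction = c(0.5, 1.4),
              leucine = c(0, 1), isoleucine = c(0, 1), valine = c(0, 1))
  expect_error(simulate_uptake_profiles(5, ranges = bad, seed = 1),
               "ferm_fraction")
})

test_that("RPKM-mode matrices are non-negative, log-mode unrestricted", {
  lin <- simulate_two_class(n_genes = 50, n_case = 4, n_ctrl = 4,
                            rpkm_mode = TRUE, seed = 6)
  expect_true(all(unclass(lin$X) >= 0))
  expect_identical(attr(lin$X, "scale"), "linear")
  lg <- simulate_two_class(n_genes = 50, n_case = 4, n_ctrl = 4, seed = 6)
  expect_identical(attr(lg$X, "scale"), "log")
})

test_that("planted latent coupling equals the requested marginal correlation", {
  cc <- vapply(1:30, function(s)
    cor(simulate_latent_regulons(n_genes = 100,
                                 regulons = c(A = 10, B = 10),
                                 coupling = 0.95, seed = s)$latents)[1, 2],
    numeric(1))
  expect_lt(abs(mean(cc) - 0.95), 0.02)
  cc0 <- vapply(1:30, function(s)
    cor(simulate_latent_regulons(n_genes = 100,
                                 regulons = c(A = 10, B = 10),
                                 coupling = 0, seed = s)$latents)[1, 2],
    numeric(1))
  expect_lt(abs(mean(cc0)), 0.1)
})

test_that("the noiseless fully coupled limit gives identical activities", {
  lr <- simulate_latent_regulons(n_genes = 100, regulons = c(A = 20, B = 20),
                                 coupling = 1, noise_sd = 1e-9, seed = 11)
  cd <- characteristic_direction(lr$X, lr$ann, gamma = 1)
  a1 <- regulon_activity(cd, lr$X, lr$regulons$A)
  a2 <- regulon_activity(cd, lr$X, lr$regulons$B)
  expect_equal(activity_correlation(a1, a2, "pearson")$r, 1,
               tolerance = 1e-6)
})

test_that("the toy core model satisfies the structural invariants", {
  m <- toy_core_model()
  expect_s3_class(m, "metabolic_model")
  expect_true(all(m$lb <= m$ub))
  for (id in m$rxns[m$exchange])
    expect_equal(sum(m$S[, id] != 0), 1)
  expect_true(m$atp %in% m$mets)
  expect_setequal(names(exchange_map(m)),
                  c("glc", "lac", "o2", "co2", "leu", "ile", "val"))
})

test_that("simulated uptake tables are feasible by construction", {
  pr <- simulate_uptake_profiles(25, seed = 17)
  expect_true(all(pr$glc < 0))
  expect_true(all(pr$lac >= 0))
  expect_true(all(pr$lac <= 2 * abs(pr$glc) + 1e-12))
  expect_true(all(pr$leu <= 0 & pr$ile <= 0 & pr$val <= 0))
  m <- toy_core_model()
  for (i in c(1, 13, 25))
    expect_s3_class(fit_fluxes(m, pr[i, , drop = FALSE]),
                    "flux_distribution")

  z <- list(glucose = c(1, 1), ferm_fraction = c(0.5, 0.5),
            leucine = c(0.1, 0.1), isoleucine = c(0.1, 0.1),
            valine = c(0.1, 0.1))
  zp <- simulate_uptake_profiles(3, ranges = z, seed = 1)
  expect_equal(zp$glc, rep(-1, 3))
  expect_true(all(vapply(zp[-1], function(col) length(unique(col)) == 1,
                         logical(1))))
})

test_that("a null simulation yields no significant genes", {
  sim <- simulate_two_class(n_genes = 300, n_case = 10, n_ctrl = 10,
                            planted_up = 0, planted_down = 0,
                            effect_size = 0, seed = 12)
  cd <- characteristic_direction(sim$X, sim$ann, 0.5)
  cd <- gene_significance(cd, sim$X, sim$ann, n_perm = 200, seed = 12)
  expect_lte(mean(cd$q < 0.05), 0.05)
})
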