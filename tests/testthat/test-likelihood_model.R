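# Per-state likelihoods and the diplotype expansion.

one_icn_site <- cnv_sites("icn1", "ICN")

test_that("state likelihoods are Gaussian densities of the measurement", {
  model <- gaussian_signal_model(one_icn_site, sd = 0.5)
  comp <- model[["icn1"]]
  # density at the mean
  expect_equal(state_likelihood(2, "2", comp), 1 / (0.5 * sqrt(2 * pi)))
  # two sd away
  expect_equal(state_likelihood(2 + 1, "2", comp),
               exp(-2) / (0.5 * sqrt(2 * pi)))
  # midpoint between equal-variance clusters: equal likelihood
  expect_equal(state_likelihood(1.5, "1", comp),
               state_likelihood(1.5, "2", comp))
  expect_error(state_likelihood(1, "9", comp), "no component")
})

test_that("genotype likelihoods collapse to copy-number likelihoods by size", {
  got <- icn_likelihoods_from_genotypes(c(A = 0.5, B = 0.3, AA = 0.2))
  expect_equal(got, c(`1` = 0.8, `2` = 0.2))
  expect_equal(icn_likelihoods_from_genotypes(c(AAG = 0.7)), c(`3` = 0.7))
  expect_equal(unname(icn_likelihoods_from_genotypes(
    c(`-` = 0, A = 0, AB = 0))), c(0, 0, 0))
  # "-" counts as zero copies
  got0 <- icn_likelihoods_from_genotypes(c(`-` = 0.4, A = 0.6))
  expect_equal(got0, c(`0` = 0.4, `1` = 0.6))
})

test_that("pruning renormalizes and keeps at least the best state", {
  gs <- geno_spectrum(rep("i1", 2), rep("icn1", 2), c("1", "2"),
                      c(0.98, 0.02))
  pruned <- prune_states(gs, 0.05)
  expect_equal(nrow(pruned), 1)
  expect_equal(pruned$state, "1")
  expect_equal(pruned$likelihood, 1)

  # threshold 0: nothing dropped, only normalized
  same <- prune_states(gs, 0)
  expect_equal(nrow(same), 2)
  expect_equal(sum(same$likelihood), 1)

  # uniform likelihoods below-threshold-proof
  gs3 <- geno_spectrum(rep("i1", 4), rep("icn1", 4), as.character(0:3),
                       rep(2, 4))
  expect_equal(nrow(prune_states(gs3, 0.2)), 4)

  # degenerate: everything below threshold, best survives
  gs4 <- geno_spectrum(rep("i1", 3), rep("icn1", 3), as.character(0:2),
                       c(0.5, 0.3, 0.2))
  best_only <- prune_states(gs4, 0.9)
  expect_equal(best_only$state, "0")
})

test_that("missing calls become uniform spectra over the state universe", {
  expect_equal(missing_call_spectrum(one_icn_site),
               c(`0` = 1, `1` = 1, `2` = 1, `3` = 1, `4` = 1))
  snp <- cnv_sites("p", "SNP", alphabet = "a,t")
  expect_setequal(names(missing_call_spectrum(snp)), c("aa", "at", "tt"))
  snvc <- cnv_sites("v", "SNVC", alphabet = "A,B", max_total_copies = 2)
  expect_setequal(names(missing_call_spectrum(snvc)),
                  c("-", "A", "B", "AA", "AB", "BB"))
})

test_that("expansion enumerates positive-likelihood states with product lambdas", {
  # single ICN site, point mass on total 3 (cap 3 so [0/3] is allowed)
  site3 <- cnv_sites("icn1", "ICN", max_allele_copies = 3)
  gs <- geno_spectrum("i1", "icn1", "3", 1)
  ex <- build_expansion(gs, site3)
  expect_setequal(diplotype_string(ex$table$h1, ex$table$h2),
                  c("0/3", "1/2"))
  expect_equal(ex$table$lambda, c(1, 1))

  # two sites: lambda is the product of per-site state likelihoods
  sites2 <- validate_sites(rbind(cnv_sites("icn1", "ICN", max_allele_copies = 3),
                                 cnv_sites("snp1", "SNP", alphabet = "a,t")))
  gs2 <- geno_spectrum(c("i1", "i1"), c("icn1", "snp1"), c("3", "at"),
                       c(0.9, 1.0))
  ex2 <- build_expansion(gs2, sites2)
  expect_equal(nrow(ex2$table), 4)
  expect_equal(ex2$table$lambda, rep(0.9, 4))

  # zero-likelihood states never appear
  gs3 <- geno_spectrum(rep("i1", 2), rep("icn1", 2), c("3", "4"), c(1, 0))
  ex3 <- build_expansion(gs3, site3)
  expect_false("2/2" %in% diplotype_string(ex3$table$h1, ex3$table$h2))

  # lambda values match an independent per-row product recomputation
  gs4 <- geno_spectrum(c("i1", "i1", "i1"), c("icn1", "icn1", "snp1"),
                       c("3", "2", "at"), c(0.7, 0.2, 0.6))
  ex4 <- build_expansion(gs4, sites2)
  lik <- list(icn1 = c(`3` = 0.7, `2` = 0.2), snp1 = c(at = 0.6))
  states <- collapse_diplotypes(ex4$table$h1, ex4$table$h2, sites2)
  manual <- lik$icn1[states[, 1]] * lik$snp1[states[, 2]]
  expect_equal(ex4$table$lambda, unname(manual))
})

test_that("individuals missing a site get a missing-call substitution", {
  sites2 <- validate_sites(rbind(cnv_sites("icn1", "ICN"),
                                 cnv_sites("snp1", "SNP", alphabet = "a,t")))
  gs <- geno_spectrum(c("i1", "i1", "i2"), c("icn1", "snp1", "icn1"),
                      c("2", "at", "2"), c(1, 1, 1))
  ex <- build_expansion(gs, sites2)  # i2 has no snp1 row
  i2 <- ex$table[ex$table$individual_id == "i2", ]
  states <- collapse_diplotypes(i2$h1, i2$h2, sites2)
  expect_setequal(unique(states[, 2]), c("aa", "at", "tt"))
})

test_that("point-mass spectra reproduce deterministic enumeration", {
  # with hard calls, all lambdas are equal within an individual
  sites <- cnv_sites("v", "SNVC", alphabet = "A,G", max_allele_copies = 3)
  gs <- point_mass_spectrum("i1", "v", "AAG")
  ex <- build_expansion(gs, sites)
  expect_setequal(diplotype_string(ex$table$h1, ex$table$h2),
                  c("-/A,A,G", "A,A/G", "A/A,G"))
  expect_true(all(ex$table$lambda == ex$table$lambda[1]))
})

test_that("argmax_spectrum keeps exactly the most likely state per site", {
  gs <- geno_spectrum(rep(c("i1", "i2"), each = 3), rep("icn1", 6),
                      rep(as.character(0:2), 2),
                      c(0.1, 0.7, 0.2, 0.5, 0.25, 0.25))
  am <- argmax_spectrum(gs)
  expect_equal(nrow(am), 2)
  expect_equal(am$state[am$individual_id == "i1"], "1")
  expect_equal(am$state[am$individual_id == "i2"], "0")
  expect_true(all(am$likelihood == 1))
})

test_that("per-individual rescaling of likelihoods leaves EM output unchanged", {
  set.seed(7)
  sc <- sim_scenario("one_icn")
  model <- gaussian_signal_model(sc$sites, sd = 0.4)
  sim <- simulate_dataset(sc$freqs, sc$sites, 40, seed = 7, model = model)
  ex1 <- build_expansion(sim$spectra, sc$sites)

  scaled <- sim$spectra
  scale_by <- stats::setNames(10^runif(40, -3, 3),
                              unique(scaled$individual_id))
  scaled$likelihood <- scaled$likelihood * scale_by[scaled$individual_id]
  ex2 <- build_expansion(scaled, sc$sites)

  cfg <- em_config(seed = 5, n_restarts = 2)
  r1 <- run_em(ex1, cfg)
  r2 <- run_em(ex2, cfg)
  expect_equal(as.numeric(r1$frequencies), as.numeric(r2$frequencies),
               tolerance = 1e-12)
  expect_equal(r1$posteriors$w, r2$posteriors$w, tolerance = 1e-12)
  # ln L shifts by exactly the sum of the log scale factors
  expect_equal(r2$loglik - r1$loglik, sum(log(scale_by)), tolerance = 1e-6)
})
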