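# The EM engine: HWE priors, E/M steps, log-likelihood, full runs.

make_expansion <- function(spectra, sites) build_expansion(spectra, sites)

test_that("HWE priors square homozygotes and double heterozygotes", {
  f <- freq_table(c(h1 = 0.9, h2 = 0.1))
  expect_equal(hwe_prior("h1/h1", f), 0.81)
  expect_equal(hwe_prior("h1/h2", f), 0.18)
  expect_equal(hwe_prior("h1/h3", f), 0)  # absent haplotype

  # priors over all diplotypes from a normalized table sum to 1
  f3 <- freq_table(c(a = 0.5, b = 0.3, c = 0.2))
  dips <- outer(names(f3), names(f3), diplotype_string)
  dips <- unique(as.vector(dips))
  expect_equal(sum(hwe_prior(dips, f3)), 1)
})

test_that("E step normalizes lambda-weighted priors per individual", {
  site <- cnv_sites("icn1", "ICN", max_allele_copies = 3)
  gs <- geno_spectrum("i1", "icn1", "2", 1)  # diplotypes [0/2], [1/1]
  ex <- make_expansion(gs, site)
  f <- freq_table(c(`1` = 0.9, `0` = 0.05, `2` = 0.05))
  post <- e_step(ex, f)
  w <- stats::setNames(post$w, diplotype_string(post$h1, post$h2))
  # lambda equal: w proportional to priors 2*.05*.05 vs .9^2
  expect_equal(unname(w["1/1"]), 0.81 / (0.81 + 0.005))
  expect_equal(sum(post$w), 1)

  # single-diplotype individual
  gs1 <- geno_spectrum("i1", "icn1", "0", 1)
  post1 <- e_step(make_expansion(gs1, site), freq_table(c(`0` = 1)))
  expect_equal(post1$w, 1)

  # priors cancel when uniform: w follows lambda ([0/0] vs [2/2], cap 2)
  site2 <- cnv_sites("icn1", "ICN")
  gs2 <- geno_spectrum(c("i1", "i1"), c("icn1", "icn1"), c("0", "4"),
                       c(0.9, 0.1))
  ex2 <- make_expansion(gs2, site2)
  post2 <- e_step(ex2, freq_table(c(`0` = 0.25, `2` = 0.25, `1` = 0.25,
                                    `3` = 0.25)))
  w2 <- stats::setNames(post2$w, diplotype_string(post2$h1, post2$h2))
  expect_equal(unname(w2[c("0/0", "2/2")]), c(0.9, 0.1))
})

test_that("M step counts posterior-weighted chromosomes over 2N", {
  site <- cnv_sites("icn1", "ICN", max_allele_copies = 3)
  # one het individual with a single diplotype
  gs <- geno_spectrum("i1", "icn1", "1", 1)  # only [0/1]
  ex <- make_expansion(gs, site)
  post <- e_step(ex, freq_table(c(`0` = 0.5, `1` = 0.5)))
  f <- m_step(post, ex)
  expect_equal(unname(f[c("0", "1")]), c(0.5, 0.5))

  # homozygote: delta = 2
  gs2 <- geno_spectrum("i1", "icn1", "0", 1)
  ex2 <- make_expansion(gs2, site)
  f2 <- m_step(e_step(ex2, freq_table(c(`0` = 1))), ex2)
  expect_equal(unname(f2["0"]), 1)

  # hand-summed two-individual case: A fixed [h1/h1], B half [h1/h2], [h1/h3]
  tab <- data.frame(ind = c(1L, 2L, 2L),
                    individual_id = c("A", "B", "B"),
                    h1 = c("1", "1", "1"), h2 = c("1", "2", "3"),
                    loglambda = 0, lambda = 1)
  ex3 <- structure(list(table = tab, individuals = c("A", "B"),
                        sites = site, excluded = character(0)),
                   class = "diplotype_expansion")
  post3 <- data.frame(ind = tab$ind, individual_id = tab$individual_id,
                      h1 = tab$h1, h2 = tab$h2, w = c(1, 0.5, 0.5))
  f3 <- m_step(post3, ex3)
  expect_equal(unname(f3[c("1", "2", "3")]), c(0.75, 0.125, 0.125))
})

test_that("log-likelihood sums per-individual log mixture masses", {
  site <- cnv_sites("icn1", "ICN", max_allele_copies = 3)
  gs <- geno_spectrum("i1", "icn1", "0", 1)
  ex <- make_expansion(gs, site)
  f <- freq_table(c(`0` = 0.5, `1` = 0.5))
  expect_equal(log_likelihood(ex, f), log(0.25))

  # doubling lambda adds N log 2 and changes nothing else
  gs2 <- geno_spectrum(c("i1", "i2"), c("icn1", "icn1"), c("0", "1"),
                       c(1, 1))
  ex2 <- make_expansion(gs2, site)
  gs2b <- gs2
  gs2b$likelihood <- 2 * gs2b$likelihood
  ex2b <- make_expansion(gs2b, site)
  expect_equal(log_likelihood(ex2b, f) - log_likelihood(ex2, f), 2 * log(2))

  # identical individuals contribute additively
  gs3 <- geno_spectrum(c("i1", "i2"), c("icn1", "icn1"), c("3", "3"), c(1, 1))
  ex3 <- make_expansion(gs3, site)
  gs1 <- geno_spectrum("i1", "icn1", "3", 1)
  ex1 <- make_expansion(gs1, site)
  f2 <- freq_table(c(`0` = 0.25, `1` = 0.25, `2` = 0.25, `3` = 0.25))
  expect_equal(log_likelihood(ex3, f2), 2 * log_likelihood(ex1, f2))
})

test_that("EM on unambiguous data returns empirical counts immediately", {
  site <- cnv_sites("icn1", "ICN", max_allele_copies = 1)
  # totals 0, 1, 2 with allele cap 1 are unambiguous: [0/0], [0/1], [1/1]
  states <- c("0", "1", "1", "2", "2", "2")
  gs <- point_mass_spectrum(paste0("i", 1:6), "icn1", states)
  res <- run_em(build_expansion(gs, site), em_config(n_restarts = 0))
  # chromosomes: 0 appears 0+0+1+1 = 4 of 12
  expect_equal(unname(res$frequencies[c("0", "1")]), c(4, 8) / 12)
  expect_true(res$converged)
  expect_lte(res$n_iterations, 3)
})

test_that("EM on hard calls matches an independent classic-EM oracle", {
  site <- cnv_sites("icn1", "ICN", max_allele_copies = 2)
  set.seed(31)
  for (case in 1:5) {
    n <- 12
    totals <- as.character(sample(0:4, n, TRUE, prob = c(1, 2, 4, 2, 1)))
    gs <- point_mass_spectrum(paste0("i", 1:n), "icn1", totals)
    ex <- build_expansion(gs, site)
    res <- run_em(ex, em_config(n_restarts = 0, tolerance = 1e-12))

    dip_list <- lapply(split(ex$table, ex$table$ind),
                       function(s) cbind(s$h1, s$h2))
    po <- oracle_classic_em(dip_list)
    for (h in names(po)) {
      expect_equal(unname(res$frequencies[h]), unname(po[h]),
                   tolerance = 1e-5, info = paste("case", case, "hap", h))
    }
  }
})

test_that("log-likelihood is monotone and posteriors/frequencies normalized", {
  set.seed(13)
  sc <- sim_scenario("one_icn")
  model <- gaussian_signal_model(sc$sites, sd = 0.45)
  for (case in 1:4) {
    sim <- simulate_dataset(sc$freqs, sc$sites, 60, seed = 100 + case,
                            model = model)
    res <- run_em(build_expansion(sim$spectra, sc$sites),
                  em_config(seed = case, n_restarts = 3))
    expect_true(all(diff(res$loglik_trace) > -1e-8))
    expect_equal(sum(res$frequencies), 1, tolerance = 1e-9)
    wsum <- tapply(res$posteriors$w, res$posteriors$ind, sum)
    expect_equal(unname(as.numeric(wsum)), rep(1, length(wsum)),
                 tolerance = 1e-9)
  }
})

test_that("EM fixed point matches grid maximization of the likelihood", {
  # <= 3 haplotypes, 5 individuals, ambiguous states with uneven lambdas
  site <- cnv_sites("icn1", "ICN", max_allele_copies = 2)
  ids <- paste0("i", 1:5)
  gs <- geno_spectrum(
    rep(ids, each = 2),
    "icn1",
    c("2", "3", "2", "1", "4", "3", "2", "3", "1", "2"),
    c(0.8, 0.2, 0.6, 0.4, 0.7, 0.3, 1.0, 0, 0.5, 0.5)
  )
  ex <- build_expansion(gs, site)
  res <- run_em(ex, em_config(tolerance = 1e-12, n_restarts = 5, seed = 3))
  haps <- names(res$frequencies)
  expect_length(haps, 3)
  grid_best <- oracle_grid_max(ex$table, haps, step = 1e-3)
  expect_equal(unname(as.numeric(res$frequencies)), grid_best,
               tolerance = 2e-3)
})

test_that("frequencies recover the truth as noise vanishes at large n", {
  sc <- sim_scenario("one_icn")
  model <- gaussian_signal_model(sc$sites, sd = 0.02)  # near-noiseless
  sim <- simulate_dataset(sc$freqs, sc$sites, 2000, seed = 17, model = model)
  res <- run_em(build_expansion(sim$spectra, sc$sites),
                em_config(seed = 18, n_restarts = 2))
  for (h in names(sc$freqs)) {
    expect_equal(unname(res$frequencies[h]), unname(sc$freqs[h]),
                 tolerance = 0.02, info = h)
  }
})

test_that("restart bookkeeping returns the best chain deterministically", {
  sc <- sim_scenario("one_icn")
  model <- gaussian_signal_model(sc$sites, sd = 0.4)
  sim <- simulate_dataset(sc$freqs, sc$sites, 50, seed = 23, model = model)
  ex <- build_expansion(sim$spectra, sc$sites)
  cfg <- em_config(seed = 9, n_restarts = 4)
  r1 <- run_em(ex, cfg)
  r2 <- run_em(ex, cfg)
  expect_identical(r1$frequencies, r2$frequencies)
  expect_length(r1$chain_logliks, 5)  # uniform + 4 restarts
  expect_equal(r1$loglik, max(r1$chain_logliks))
})
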