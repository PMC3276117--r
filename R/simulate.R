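# Synthetic-data generator: known haplotype frequencies -> HWE-paired
# diplotypes -> per-site unphased states -> Gaussian signal intensities ->
# likelihood spectra. Cluster means are equally spaced per state (1-D for
# ICN log-ratio-like signals, one channel per base for SNVC/SNP) and the
# common per-site sd is calibrated so the argmax-likelihood hard call is
# wrong at a chosen rate, anchoring the simulation to a realistic amount of
# microarray noise.

#' Sample diplotypes from haplotype frequencies under HWE
#'
#' Draws `2n` haplotypes i.i.d. from the frequency table and pairs them
#' sequentially into `n` individuals.
#'
#' @param freqs A [freq_table()].
#' @param n Number of individuals.
#' @param seed Optional integer seed.
#' @return `data.frame` with columns `individual_id` (`"ind0001"`, ...),
#'   `h1`, `h2` (canonical order within the pair).
#' @export
sample_population_hwe <- function(freqs, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (abs(sum(freqs) - 1) > 1e-9) stop("frequencies must sum to 1")
  chrom <- sample(names(freqs), 2 * n, replace = TRUE, prob = as.numeric(freqs))
  h1 <- chrom[seq(1, 2 * n, 2)]
  h2 <- chrom[seq(2, 2 * n, 2)]
  swap <- cstring_gt(h1, h2)
  data.frame(
    individual_id = sprintf("ind%04d", seq_len(n)),
    h1 = ifelse(swap, h2, h1),
    h2 = ifelse(swap, h1, h2),
    stringsAsFactors = FALSE
  )
}

# ---- Gaussian cluster layouts -----------------------------------------------

# cluster means for every state of one site:
#   ICN : 1-D, mean = total copies * spacing
#   SNVC: one channel per alphabet base, mean = per-base copy count * spacing
#   SNP : one channel per base, mean = per-base allele count * spacing
state_means <- function(site, spacing = 1) {
  states <- enumerate_states(site)
  if (site$site_type[1] == "ICN") {
    m <- matrix(as.numeric(states) * spacing, ncol = 1)
  } else {
    ab <- site_alphabet(site)
    counts <- lapply(states, function(st) {
      units <- if (site$site_type[1] == "SNVC") {
        parse_snvc(st, ab)
      } else {
        strsplit(st, "", fixed = TRUE)[[1]]
      }
      tabulate(match(units, ab), nbins = length(ab)) * spacing
    })
    m <- matrix(unlist(counts), nrow = length(states), byrow = TRUE)
  }
  rownames(m) <- states
  m
}

#' Gaussian signal model over a site table
#'
#' One spherical Gaussian component per possible unphased state and site,
#' with equally spaced means (see package vignette) and a common per-site
#' standard deviation.
#'
#' @param sites A [cnv_sites()] table.
#' @param sd Per-site standard deviation: scalar or vector named by
#'   `site_id`.
#' @param spacing Distance between adjacent cluster means (default 1;
#'   signal units are arbitrary, only `spacing/sd` matters).
#' @return Object of class `signal_model`: named list (by `site_id`) of
#'   components `list(site_id, states, means, sd)`.
#' @export
gaussian_signal_model <- function(sites, sd, spacing = 1) {
  sites <- validate_sites(sites)
  sdv <- if (length(sd) == 1L) {
    stats::setNames(rep(as.numeric(sd), nrow(sites)), sites$site_id)
  } else {
    if (is.null(names(sd)) || !all(sites$site_id %in% names(sd))) {
      stop("per-site sd must be named by site_id")
    }
    sd
  }
  if (any(sdv <= 0)) stop("sd must be positive")
  model <- lapply(seq_len(nrow(sites)), function(s) {
    m <- state_means(sites[s, ], spacing)
    list(site_id = sites$site_id[s], states = rownames(m), means = m,
         sd = unname(sdv[sites$site_id[s]]))
  })
  names(model) <- sites$site_id
  structure(model, class = "signal_model")
}

# ---- noise calibration ------------------------------------------------------

# P(argmax-density state != true state) for each state under a spherical
# Gaussian with sd `sigma`; equal sd means argmax = nearest mean.
# 1-D: exact via midpoint boundaries. >=2-D: deterministic grid quadrature
# of the standard normal (accurate to ~1e-3, well inside the calibration
# tolerance).
miscall_by_state <- function(means, sigma, grid = seq(-5, 5, length.out = 81)) {
  d <- ncol(means)
  n <- nrow(means)
  if (d == 1L) {
    ord <- order(means[, 1])
    m <- means[ord, 1]
    lo <- c(-Inf, (m[-n] + m[-1]) / 2)
    hi <- c((m[-n] + m[-1]) / 2, Inf)
    pc <- stats::pnorm(hi, m, sigma) - stats::pnorm(lo, m, sigma)
    out <- numeric(n)
    out[ord] <- 1 - pc
    return(out)
  }
  w1 <- stats::dnorm(grid)
  w1 <- w1 / sum(w1)
  pts <- as.matrix(expand.grid(rep(list(grid), d)))
  wts <- apply(matrix(w1[match(pts, grid)], nrow(pts), d), 1, prod)
  vapply(seq_len(n), function(i) {
    x <- sweep(pts * sigma, 2, means[i, ], `+`)
    d2 <- outer(rowSums(x^2), rep(1, n)) - 2 * x %*% t(means) +
      outer(rep(1, nrow(x)), rowSums(means^2))
    sum(wts[max.col(-d2, ties.method = "first") != i])
  }, 0)
}

#' Expected hard-call miscall rate of a cluster layout
#'
#' Probability, under the given distribution over true states, that a
#' signal drawn from its state's Gaussian cluster is closest to (has the
#' highest density under) a different state's cluster.
#'
#' @param means Numeric matrix of cluster means (rows = states).
#' @param state_probs Probabilities of the true states (rows of `means`).
#' @param sigma Common standard deviation.
#' @return Numeric scalar in `[0, 1)`.
#' @export
expected_miscall_rate <- function(means, state_probs, sigma) {
  stopifnot(nrow(means) == length(state_probs), abs(sum(state_probs) - 1) < 1e-6)
  sum(state_probs * miscall_by_state(means, sigma))
}

#' Calibrate cluster noise to a target miscall rate
#'
#' Finds the common standard deviation at which the expected
#' argmax-likelihood miscall rate (weighted by the true-state distribution)
#' equals `target`, by root finding on `sigma`.
#'
#' @inheritParams expected_miscall_rate
#' @param target Desired miscall rate in `(0, 1)`.
#' @param tol Acceptable deviation from `target` (default 0.005).
#' @return The calibrated `sigma`.
#' @export
calibrate_noise <- function(means, state_probs, target, tol = 0.005) {
  if (target <= 0 || target >= 1) stop("target miscall rate must be in (0, 1)")
  if (nrow(means) < 2) stop("calibration needs at least two clusters")
  span <- max(stats::dist(means))
  f <- function(sig) expected_miscall_rate(means, state_probs, sig) - target
  lo <- span * 1e-4
  hi <- span * 20
  if (f(lo) > 0 || f(hi) < 0) {
    stop("target miscall rate ", target, " unattainable with this layout")
  }
  sig <- stats::uniroot(f, c(lo, hi), tol = span * 1e-6)$root
  if (abs(f(sig)) > tol) {
    stop("calibration did not reach target within ", tol)
  }
  sig
}

# distribution of true unphased states per site implied by HWE on freqs
site_state_distribution <- function(freqs, sites) {
  haps <- names(freqs)
  p <- as.numeric(freqs)
  pair <- expand.grid(a = seq_along(haps), b = seq_along(haps))
  pr <- p[pair$a] * p[pair$b]
  states <- collapse_diplotypes(haps[pair$a], haps[pair$b], sites)
  lapply(seq_len(nrow(sites)), function(s) {
    agg <- rowsum(pr, states[, s])
    stats::setNames(agg[, 1], rownames(agg))
  })
}

#' Calibrated Gaussian signal model for a simulated population
#'
#' Builds the equally spaced cluster layout for each site and calibrates
#' each site's sd so the expected hard-call miscall rate under the
#' population's true-state distribution matches `target_miscall`.
#'
#' @param freqs Population haplotype [freq_table()].
#' @param sites A [cnv_sites()] table.
#' @param target_miscall Per-site target miscall rate: scalar or vector
#'   named by `site_id`.
#' @param spacing Cluster mean spacing (default 1).
#' @return A [gaussian_signal_model()] with calibrated per-site sd.
#' @export
calibrate_signal_model <- function(freqs, sites, target_miscall, spacing = 1) {
  sites <- validate_sites(sites)
  tm <- if (length(target_miscall) == 1L) {
    stats::setNames(rep(target_miscall, nrow(sites)), sites$site_id)
  } else {
    target_miscall
  }
  dists <- site_state_distribution(freqs, sites)
  sdv <- vapply(seq_len(nrow(sites)), function(s) {
    means <- state_means(sites[s, ], spacing)
    probs <- stats::setNames(rep(0, nrow(means)), rownames(means))
    probs[names(dists[[s]])] <- dists[[s]]
    calibrate_noise(means, probs, tm[sites$site_id[s]])
  }, 0)
  gaussian_signal_model(sites, stats::setNames(sdv, sites$site_id), spacing)
}

# ---- signal generation and likelihoods --------------------------------------

#' Simulate signal intensities for true diplotypes
#'
#' Draws one Gaussian sample per individual and site from the cluster of
#' the individual's true unphased state.
#'
#' @param truth `data.frame` with `individual_id`, `h1`, `h2`.
#' @param model A [gaussian_signal_model()].
#' @param sites The matching [cnv_sites()] table.
#' @param seed Optional integer seed.
#' @return Object of class `signal_data`: named list (by `site_id`) of
#'   numeric matrices (individuals x channels, rownames = individual ids).
#' @export
simulate_signals <- function(truth, model, sites, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sites <- validate_sites(sites)
  states <- collapse_diplotypes(truth$h1, truth$h2, sites)
  out <- lapply(seq_len(nrow(sites)), function(s) {
    comp <- model[[sites$site_id[s]]]
    if (is.null(comp)) stop("signal model lacks site ", sites$site_id[s])
    i <- match(states[, s], comp$states)
    if (anyNA(i)) {
      stop("state '", states[is.na(i), s][1], "' has no cluster at site ",
           sites$site_id[s])
    }
    mu <- comp$means[i, , drop = FALSE]
    x <- mu + matrix(stats::rnorm(length(mu), 0, comp$sd), nrow(mu))
    rownames(x) <- truth$individual_id
    x
  })
  names(out) <- sites$site_id
  structure(out, class = "signal_data")
}

#' Likelihood spectra of simulated signals
#'
#' Per individual and site, the Gaussian density of the measurement under
#' every state's cluster.
#'
#' @param signals A [simulate_signals()] result.
#' @param model The generating (or assumed) [gaussian_signal_model()].
#' @return A [geno_spectrum()] table.
#' @export
build_genospectrum <- function(signals, model) {
  rows <- lapply(names(signals), function(sid) {
    comp <- model[[sid]]
    if (is.null(comp)) stop("signal model lacks site ", sid)
    x <- signals[[sid]]
    # log-density of every individual under every state cluster
    ll <- vapply(seq_along(comp$states), function(i) {
      rowSums(stats::dnorm(sweep(x, 2, comp$means[i, ], `-`),
                           0, comp$sd, log = TRUE))
    }, numeric(nrow(x)))
    if (is.null(dim(ll))) ll <- matrix(ll, nrow = 1)
    data.frame(
      individual_id = rep(rownames(x), times = length(comp$states)),
      site_id = sid,
      state = rep(comp$states, each = nrow(x)),
      likelihood = exp(as.vector(ll)),
      stringsAsFactors = FALSE
    )
  })
  validate_spectrum(do.call(rbind, rows))
}

# ---- packaged study scenarios ----------------------------------------------

#' Reference simulation scenarios
#'
#' Three packaged study designs emulating a tri-allelic deletion/duplication
#' CNV locus as observed in a 588-individual panel: a single ICN site
#' (haplotypes = 0, 1 or 2 copies), a single SNVC site (copy units carrying
#' base A or B), and a pair of SNVC sites. Haplotype frequencies are the
#' panel's known values renormalized to sum one; the default miscall targets
#' (22% ICN, 21% SNVC) reproduce a realistic microarray noise level.
#'
#' @param name One of `"one_icn"`, `"one_snvc"`, `"two_snvc"`.
#' @return List with elements `name`, `freqs` (a [freq_table()]), `sites`
#'   (a [cnv_sites()] table) and `target_miscall`.
#' @export
sim_scenario <- function(name = c("one_icn", "one_snvc", "two_snvc")) {
  name <- match.arg(name)
  switch(name,
    one_icn = list(
      name = name,
      freqs = freq_table(c(`1` = 0.9609, `0` = 0.0196, `2` = 0.0196),
                         normalize = TRUE),
      sites = cnv_sites("icn1", "ICN"),
      target_miscall = 0.22
    ),
    one_snvc = list(
      name = name,
      freqs = freq_table(c(A = 0.9600, `-` = 0.0196, `A,A` = 0.0196,
                           B = 0.0009), normalize = TRUE),
      sites = cnv_sites("snvc1", "SNVC", alphabet = "A,B"),
      target_miscall = 0.21
    ),
    two_snvc = list(
      name = name,
      freqs = freq_table(c(`-_A` = 0.9592, `-_-` = 0.0196, `-_A,A` = 0.0196,
                           `-_B` = 0.0009, `A_A` = 0.0009), normalize = TRUE),
      sites = cnv_sites(c("snvc1", "snvc2"), "SNVC",
                        alphabet = c("A", "A,B")),
      target_miscall = 0.21
    )
  )
}

#' Simulate a complete dataset
#'
#' Runs the full generator: HWE population sample, Gaussian signals from a
#' calibrated (or supplied) signal model, and likelihood spectra computed
#' under the same model.
#'
#' @param freqs Population haplotype [freq_table()].
#' @param sites A [cnv_sites()] table.
#' @param n Number of individuals.
#' @param seed Integer seed (drives population and signal draws).
#' @param target_miscall Per-site hard-call miscall rate used to calibrate
#'   noise (ignored when `model` is given).
#' @param model Optional pre-built [gaussian_signal_model()].
#' @param spacing Cluster spacing (default 1).
#' @return List of class `cnv_simulation`: `truth`, `signals`, `spectra`,
#'   `model`, `sites`, `freqs`, `seed`.
#' @export
simulate_dataset <- function(freqs, sites, n, seed,
                             target_miscall = 0.22, model = NULL,
                             spacing = 1) {
  sites <- validate_sites(sites)
  if (is.null(model)) {
    model <- calibrate_signal_model(freqs, sites, target_miscall, spacing)
  }
  set.seed(seed)
  truth <- sample_population_hwe(freqs, n)
  signals <- simulate_signals(truth, model, sites)
  spectra <- build_genospectrum(signals, model)
  structure(
    list(truth = truth, signals = signals, spectra = spectra, model = model,
         sites = sites, freqs = freqs, seed = seed),
    class = "cnv_simulation"
  )
}

#' Simulate, phase and evaluate one replicate
#'
#' Convenience wrapper chaining [simulate_dataset()], [build_expansion()],
#' [run_em()] and [evaluate_replicate()]; optionally also runs the
#' deterministic variant (EM on argmax point-mass spectra) on the same
#' dataset.
#'
#' @inheritParams simulate_dataset
#' @param config An [em_config()] (its `seed` is re-derived from `seed`).
#' @param deterministic Also phase the argmax hard calls (`tv_argmax`
#'   column)?
#' @return One-row `data.frame` of [evaluate_replicate()] metrics (plus
#'   `tv_argmax` if requested).
#' @export
phase_replicate <- function(freqs, sites, n, seed, target_miscall = 0.22,
                            model = NULL, config = em_config(),
                            deterministic = FALSE) {
  sim <- simulate_dataset(freqs, sites, n, seed, target_miscall, model)
  config$seed <- seed + 1L
  res <- run_em(build_expansion(sim$spectra, sites), config)
  rep <- evaluate_replicate(sim$truth, res, sim$spectra, sites)
  if (deterministic) {
    res0 <- run_em(build_expansion(argmax_spectrum(sim$spectra), sites), config)
    rep$tv_argmax <- total_variation(empirical_frequencies(sim$truth),
                                     res0$frequencies)
  }
  rep
}
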