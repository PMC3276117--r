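# Per-state likelihoods and the per-individual diplotype expansion.
#
# A GenoSpectrum is the probabilistic replacement for hard genotype calls:
# for each individual and site it maps every possible unphased state to a
# likelihood. Only relative values within one (individual, site) matter.

#' Construct a GenoSpectrum table
#'
#' @param individual_id,site_id,state,likelihood Equal-length vectors giving,
#'   per row, the likelihood of one unphased state for one individual at one
#'   site. State strings use the package dialect (see [cnv_sites()]).
#' @return A `data.frame` of class `geno_spectrum`.
#' @export
geno_spectrum <- function(individual_id, site_id, state, likelihood) {
  gs <- data.frame(
    individual_id = as.character(individual_id),
    site_id = as.character(site_id),
    state = as.character(state),
    likelihood = as.numeric(likelihood),
    stringsAsFactors = FALSE
  )
  validate_spectrum(gs)
}

validate_spectrum <- function(gs) {
  needed <- c("individual_id", "site_id", "state", "likelihood")
  missing_cols <- setdiff(needed, names(gs))
  if (length(missing_cols)) {
    stop("spectrum lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (any(!is.finite(gs$likelihood)) || any(gs$likelihood < 0)) {
    stop("likelihoods must be finite and non-negative")
  }
  if (anyDuplicated(gs[c("individual_id", "site_id", "state")])) {
    stop("duplicated (individual, site, state) row in spectrum")
  }
  class(gs) <- c("geno_spectrum", "data.frame")
  gs
}

#' Gaussian likelihood of a measurement under one unphased state
#'
#' Evaluates the (spherical) Gaussian probability density of an observed
#' signal intensity under the cluster assigned to a state. A density, not a
#' probability mass: only relative values across states are meaningful.
#'
#' @param x Numeric vector, one value per channel.
#' @param state Unphased state string.
#' @param site_model One site's component of a [gaussian_signal_model()].
#' @return The probability density (numeric scalar).
#' @export
state_likelihood <- function(x, state, site_model) {
  i <- match(state, site_model$states)
  if (is.na(i)) {
    stop("signal model for site '", site_model$site_id,
         "' has no component for state '", state, "'")
  }
  mu <- site_model$means[i, ]
  if (length(x) != length(mu)) {
    stop("measurement has ", length(x), " channel(s), model expects ", length(mu))
  }
  exp(sum(stats::dnorm(x, mu, site_model$sd, log = TRUE)))
}

#' Collapse genotype likelihoods to total-copy-number likelihoods
#'
#' Sums the likelihoods of all unphased genotypes sharing the same total
#' copy number (multiset size), turning an SNVC-style spectrum into an
#' ICN-style one.
#'
#' @param genotype_likelihoods Named numeric vector, names = genotype state
#'   strings (`"AAG"`, `"-"`, ...).
#' @return Named numeric vector, names = total copy numbers.
#' @examples
#' icn_likelihoods_from_genotypes(c(A = 0.5, B = 0.3, AA = 0.2))
#' @export
icn_likelihoods_from_genotypes <- function(genotype_likelihoods) {
  states <- names(genotype_likelihoods)
  if (is.null(states)) stop("genotype likelihoods must be named by state")
  size <- ifelse(states == "-", 0L, nchar(states))
  sums <- tapply(as.numeric(genotype_likelihoods), size, sum)
  out <- as.numeric(sums)
  names(out) <- names(sums)
  out[order(as.integer(names(out)))]
}

#' Drop near-zero-likelihood states from a spectrum
#'
#' Per (individual, site), normalizes the likelihoods to sum one and removes
#' states whose normalized likelihood falls below `threshold`; the single
#' best state is always kept. A speed device: fewer surviving states mean
#' fewer enumerated diplotypes.
#'
#' @param spectra A [geno_spectrum()] table.
#' @param threshold Real in `[0, 1)`; `0` disables pruning (only exact-zero
#'   states are dropped downstream anyway).
#' @return A pruned `geno_spectrum` with renormalized likelihoods.
#' @export
prune_states <- function(spectra, threshold = 0) {
  spectra <- validate_spectrum(spectra)
  if (threshold < 0 || threshold >= 1) stop("threshold must be in [0, 1)")
  key <- paste(spectra$individual_id, spectra$site_id, sep = "\r")
  tot <- rowsum(spectra$likelihood, key)
  if (any(tot[, 1] <= 0)) {
    bad <- rownames(tot)[tot[, 1] <= 0][1]
    stop("all-zero likelihoods for (individual, site) ", gsub("\r", ", ", bad))
  }
  norm <- spectra$likelihood / tot[key, 1]
  best <- stats::ave(norm, key, FUN = max)
  keep <- norm >= threshold | norm == best
  out <- spectra[keep, , drop = FALSE]
  key <- key[keep]
  tot2 <- rowsum(norm[keep], key)
  out$likelihood <- norm[keep] / tot2[key, 1]
  rownames(out) <- NULL
  validate_spectrum(out)
}

#' Uninformative spectrum for a missing call
#'
#' Uniform likelihood over every unphased state the site allows; used to
#' substitute (individual, site) entries absent from the input.
#'
#' @param site One row of a [cnv_sites()] table.
#' @return Named numeric vector of equal likelihoods.
#' @export
missing_call_spectrum <- function(site) {
  states <- enumerate_states(site)
  stats::setNames(rep(1, length(states)), states)
}

# ---- the diplotype expansion ------------------------------------------------

#' Enumerate consistent diplotypes with multi-site likelihoods
#'
#' For every individual, enumerates all multi-site diplotypes consistent
#' with any positive-likelihood state at each site, and scores each
#' diplotype `d` by the product over sites of the likelihood of the unphased
#' state `d` implies there (signal intensities do not distinguish, e.g.,
#' `[0/3]` from `[1/2]`). Products are accumulated in log space. Individuals
#' missing a site receive the uniform [missing_call_spectrum()]; individuals
#' with no positive-likelihood diplotype are excluded with a warning.
#'
#' @param spectra A [geno_spectrum()] table.
#' @param sites A [cnv_sites()] table; site order defines haplotype order.
#' @return An object of class `diplotype_expansion`: list with `table` (a
#'   `data.frame` with columns `ind` (integer index), `individual_id`, `h1`,
#'   `h2`, `loglambda`, `lambda`), `individuals`, `sites`, and
#'   `excluded` (ids dropped for having zero total likelihood).
#' @export
build_expansion <- function(spectra, sites) {
  spectra <- validate_spectrum(spectra)
  sites <- validate_sites(sites)
  unknown <- setdiff(spectra$site_id, sites$site_id)
  if (length(unknown)) {
    stop("spectrum references unknown site(s): ", paste(unknown, collapse = ", "))
  }
  individuals <- unique(spectra$individual_id)
  per_site <- split(spectra, spectra$site_id)

  # per individual and site: named likelihood vector over positive states
  lik_maps <- lapply(seq_len(nrow(sites)), function(s) {
    sid <- sites$site_id[s]
    sub <- per_site[[sid]]
    if (is.null(sub)) sub <- spectra[0, ]
    split(stats::setNames(sub$likelihood, sub$state), sub$individual_id)
  })

  uniform <- lapply(seq_len(nrow(sites)),
                    function(s) missing_call_spectrum(sites[s, ]))

  cache <- new.env(parent = emptyenv())
  rows <- vector("list", length(individuals))
  excluded <- character(0)
  for (j in seq_along(individuals)) {
    id <- individuals[j]
    liks <- lapply(seq_len(nrow(sites)), function(s) {
      v <- lik_maps[[s]][[id]]
      if (is.null(v)) v <- uniform[[s]]
      v <- v[v > 0]
      # an all-zero map carries no information: treat as a missing call
      if (!length(v)) v <- uniform[[s]]
      v
    })
    tmpl <- expansion_template(liks, sites, cache)
    loglam <- rep(0, nrow(tmpl$pairs))
    for (s in seq_len(nrow(sites))) {
      loglam <- loglam + log(liks[[s]][tmpl$states[, s]])
    }
    keep <- is.finite(loglam)
    if (!any(keep)) {
      excluded <- c(excluded, id)
      next
    }
    rows[[j]] <- data.frame(
      individual_id = id,
      h1 = tmpl$pairs[keep, 1],
      h2 = tmpl$pairs[keep, 2],
      loglambda = loglam[keep],
      stringsAsFactors = FALSE
    )
  }
  if (length(excluded)) {
    warning("excluded ", length(excluded),
            " individual(s) with zero total likelihood: ",
            paste(utils::head(excluded, 5), collapse = ", "),
            if (length(excluded) > 5) ", ..." else "")
  }
  tab <- do.call(rbind, rows)
  if (is.null(tab) || !nrow(tab)) stop("no usable individual in spectrum")
  used <- setdiff(individuals, excluded)
  tab$ind <- match(tab$individual_id, used)
  tab$lambda <- exp(tab$loglambda)
  tab <- tab[, c("ind", "individual_id", "h1", "h2", "loglambda", "lambda")]
  rownames(tab) <- NULL
  structure(
    list(table = tab, individuals = used, sites = sites, excluded = excluded),
    class = "diplotype_expansion"
  )
}

# enumeration depends only on the set of positive states per site, which is
# shared by most individuals; cache the (pairs, implied states) template
expansion_template <- function(liks, sites, cache) {
  key <- paste(vapply(liks, function(v) paste(names(v), collapse = ","), ""),
               collapse = "|")
  if (!is.null(cache[[key]])) return(cache[[key]])
  per_site_sets <- lapply(seq_len(nrow(sites)), function(s) {
    mats <- lapply(names(liks[[s]]),
                   function(st) enumerate_site_diplotypes(st, sites[s, ]))
    do.call(rbind, mats)
  })
  pairs <- expand_multisite(per_site_sets)
  states <- collapse_diplotypes(pairs[, 1], pairs[, 2], sites)
  tmpl <- list(pairs = pairs, states = states)
  cache[[key]] <- tmpl
  tmpl
}

#' @export
print.diplotype_expansion <- function(x, ...) {
  cat("Diplotype expansion:", length(x$individuals), "individual(s),",
      nrow(x$sites), "site(s),", nrow(x$table), "diplotype row(s)\n")
  if (length(x$excluded)) {
    cat("  excluded (zero likelihood):", length(x$excluded), "\n")
  }
  invisible(x)
}

#' Replace each spectrum by a point mass on its most likely state
#'
#' Reproduces the input of the earlier deterministic phasing algorithms:
#' per (individual, site), keep only the state with the largest likelihood
#' (ties broken by state string order) with likelihood 1.
#'
#' @param spectra A [geno_spectrum()] table.
#' @return A `geno_spectrum` of point masses.
#' @export
argmax_spectrum <- function(spectra) {
  spectra <- validate_spectrum(spectra)
  ord <- order(spectra$individual_id, spectra$site_id,
               -spectra$likelihood, spectra$state, method = "radix")
  sp <- spectra[ord, ]
  key <- paste(sp$individual_id, sp$site_id, sep = "\r")
  best <- sp[!duplicated(key), , drop = FALSE]
  best$likelihood <- 1
  rownames(best) <- NULL
  validate_spectrum(best)
}
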