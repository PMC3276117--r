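# Accuracy metrics for simulation studies: total variation distance between
# frequency tables, exact-match diplotype accuracy, most-likely-call
# accuracy, correction/corruption rates, and allele frequency spectra.

#' Total variation distance between two frequency tables
#'
#' Half the L1 distance over the union of haplotype keys (absent = 0);
#' ranges from 0 (identical) to 1 (disjoint support).
#'
#' @param truth,estimate Named numeric vectors of frequencies, each summing
#'   to one (within `tol`).
#' @param tol Tolerance on the sum-to-one check.
#' @return Numeric scalar in `[0, 1]`.
#' @export
total_variation <- function(truth, estimate, tol = 1e-6) {
  if (is.null(names(truth)) || is.null(names(estimate))) {
    stop("frequency tables must be named by haplotype")
  }
  if (abs(sum(truth) - 1) > tol) stop("truth frequencies do not sum to 1")
  if (abs(sum(estimate) - 1) > tol) stop("estimate frequencies do not sum to 1")
  keys <- union(names(truth), names(estimate))
  p <- ifelse(keys %in% names(truth), truth[keys], 0)
  q <- ifelse(keys %in% names(estimate), estimate[keys], 0)
  0.5 * sum(abs(p - q))
}

#' Empirical haplotype frequencies of a diplotype set
#'
#' Chromosome counts over `2N`; the "answer frequencies" of a simulated
#' dataset.
#'
#' @param truth `data.frame` with columns `h1`, `h2` (one row per
#'   individual).
#' @return A [freq_table()].
#' @export
empirical_frequencies <- function(truth) {
  chrom <- c(truth$h1, truth$h2)
  tab <- table(chrom)
  freq_table(stats::setNames(as.numeric(tab) / length(chrom), names(tab)),
             normalize = TRUE)
}

canonical_calls <- function(x) {
  # accepts a call_diplotypes() result, a truth data.frame (h1/h2), or a
  # named character vector of diplotype strings; returns named vector
  if (is.character(x)) {
    if (is.null(names(x))) stop("diplotype vector must be named by individual")
    return(x)
  }
  if (is.data.frame(x) && all(c("h1", "h2") %in% names(x)) &&
      !"diplotype" %in% names(x)) {
    return(stats::setNames(diplotype_string(x$h1, x$h2), x$individual_id))
  }
  if (is.data.frame(x) && "diplotype" %in% names(x)) {
    return(stats::setNames(x$diplotype, x$individual_id))
  }
  stop("cannot interpret diplotype calls object")
}

#' Exact-match diplotype accuracy
#'
#' Fraction of individuals whose called diplotype equals the true one at
#' every site (canonical string comparison); no-calls count as incorrect.
#'
#' @param called Calls as a [call_diplotypes()] result or named character
#'   vector.
#' @param truth True diplotypes as a `data.frame` with `individual_id`,
#'   `h1`, `h2`, or a named character vector.
#' @return Numeric scalar in `[0, 1]`.
#' @export
diplotype_accuracy <- function(called, truth) {
  cc <- canonical_calls(called)
  tt <- canonical_calls(truth)
  if (!setequal(names(cc), names(tt))) {
    stop("called and truth cover different individual sets")
  }
  mean(!is.na(cc) & cc == tt[names(cc)])
}

#' Most-likely unphased states of a spectrum
#'
#' Per individual and site, the state with the largest likelihood (ties by
#' state string order) - the hard calls a deterministic pipeline would use.
#'
#' @param spectra A [geno_spectrum()] table.
#' @return `data.frame` with columns `individual_id`, `site_id`, `state`.
#' @export
ml_states <- function(spectra) {
  best <- argmax_spectrum(spectra)
  best[, c("individual_id", "site_id", "state")]
}

all_sites_match <- function(calls, truth_states) {
  # logical per individual: TRUE iff states match truth at every site
  key <- paste(truth_states$individual_id, truth_states$site_id, sep = "\r")
  truth_map <- stats::setNames(truth_states$state, key)
  ckey <- paste(calls$individual_id, calls$site_id, sep = "\r")
  if (!setequal(ckey, key)) {
    stop("calls and truth cover different (individual, site) sets")
  }
  hit <- calls$state == truth_map[ckey]
  ok <- tapply(hit, calls$individual_id, all)
  stats::setNames(as.logical(ok), names(ok))
}

#' Accuracy of the most-likely unphased calls
#'
#' Fraction of individuals whose argmax-likelihood state agrees with the
#' truth at every site.
#'
#' @param spectra A [geno_spectrum()] table.
#' @param truth_states `data.frame` with `individual_id`, `site_id`,
#'   `state` (e.g. from collapsing true diplotypes).
#' @return Numeric scalar in `[0, 1]`.
#' @export
ml_call_accuracy <- function(spectra, truth_states) {
  mean(all_sites_match(ml_states(spectra), truth_states))
}

#' Correction and corruption rates
#'
#' Correction: fraction of all individuals whose most-likely call was wrong
#' but whose EM diplotype call is right. Corruption: the converse. With
#' these all-individual denominators the identity
#' `accuracy_EM = accuracy_ML + correction - corruption` holds exactly.
#'
#' @param called EM calls ([call_diplotypes()] result or named vector).
#' @param ml `data.frame` of most-likely states ([ml_states()]).
#' @param truth True diplotypes (`data.frame` with `individual_id`, `h1`,
#'   `h2`).
#' @param sites The [cnv_sites()] table (to collapse truth to states).
#' @return Named numeric vector `c(correction = , corruption = )`.
#' @export
correction_corruption <- function(called, ml, truth, sites) {
  cc <- canonical_calls(called)
  tt <- canonical_calls(truth)
  em_ok <- !is.na(cc) & cc == tt[names(cc)]
  ts <- truth_states_table(truth, sites)
  ml_ok <- all_sites_match(ml, ts)[names(cc)]
  c(correction = mean(!ml_ok & em_ok), corruption = mean(ml_ok & !em_ok))
}

#' True unphased states of a truth diplotype table
#'
#' @param truth `data.frame` with `individual_id`, `h1`, `h2`.
#' @param sites A [cnv_sites()] table.
#' @return `data.frame` with `individual_id`, `site_id`, `state`.
#' @export
truth_states_table <- function(truth, sites) {
  sites <- validate_sites(sites)
  states <- collapse_diplotypes(truth$h1, truth$h2, sites)
  data.frame(
    individual_id = rep(truth$individual_id, times = nrow(sites)),
    site_id = rep(sites$site_id, each = nrow(truth)),
    state = as.vector(states),
    stringsAsFactors = FALSE
  )
}

#' Evaluate one phased replicate against its simulation truth
#'
#' Computes the five replicate-level metrics: TV between answer and
#' estimated frequencies, exact-match diplotype accuracy, most-likely-call
#' accuracy, and correction/corruption rates.
#'
#' @param truth True diplotypes (`individual_id`, `h1`, `h2`).
#' @param result A [run_em()] result.
#' @param spectra The [geno_spectrum()] the EM consumed.
#' @param sites The [cnv_sites()] table.
#' @param truth_freqs Answer frequencies; default the empirical frequencies
#'   of `truth`.
#' @param threshold Optional call threshold passed to [call_diplotypes()].
#' @return One-row `data.frame` with columns `tv`, `diplotype_accuracy`,
#'   `ml_call_accuracy`, `correction_rate`, `corruption_rate`.
#' @export
evaluate_replicate <- function(truth, result, spectra, sites,
                               truth_freqs = NULL, threshold = NULL) {
  if (is.null(truth_freqs)) truth_freqs <- empirical_frequencies(truth)
  called <- call_diplotypes(result, threshold)
  ml <- ml_states(spectra)
  cc <- correction_corruption(called, ml, truth, sites)
  data.frame(
    tv = total_variation(truth_freqs, result$frequencies),
    diplotype_accuracy = diplotype_accuracy(called, truth),
    ml_call_accuracy = ml_call_accuracy(spectra, truth_states_table(truth, sites)),
    correction_rate = unname(cc["correction"]),
    corruption_rate = unname(cc["corruption"])
  )
}

#' Aggregate replicate metrics as mean and SD
#'
#' @param reports `data.frame` of replicate rows ([evaluate_replicate()]).
#' @return `data.frame` with one row per metric: `metric`, `mean`, `sd`,
#'   `n`.
#' @export
aggregate_reports <- function(reports) {
  metrics <- names(reports)[vapply(reports, is.numeric, TRUE)]
  data.frame(
    metric = metrics,
    mean = vapply(metrics, function(m) mean(reports[[m]]), 0),
    sd = vapply(metrics, function(m) stats::sd(reports[[m]]), 0),
    n = nrow(reports),
    row.names = NULL
  )
}

#' Allele frequency spectrum with rare/fixed exclusion
#'
#' Bins frequencies into fixed-width bins after excluding values below
#' `1/(2N)` or above `1 - 1/(2N)` (alleles effectively absent from, or
#' fixed in, a sample of `N` diploid individuals).
#'
#' @param freqs Numeric vector of allele frequencies.
#' @param n_individuals Sample size `N` defining the exclusion bounds.
#' @param bin_width Bin width on the frequency axis (default 0.02).
#' @return `data.frame` with columns `bin_lo`, `bin_hi` (half-open
#'   `[lo, hi)` bins) and `count`; empty if everything is excluded.
#' @export
frequency_spectrum <- function(freqs, n_individuals, bin_width = 0.02) {
  stopifnot(n_individuals >= 1)
  lo <- 1 / (2 * n_individuals)
  keep <- freqs >= lo & freqs <= 1 - lo
  f <- freqs[keep]
  if (!length(f)) {
    return(data.frame(bin_lo = numeric(0), bin_hi = numeric(0),
                      count = integer(0)))
  }
  bin <- floor(f / bin_width)
  tab <- table(bin)
  idx <- as.integer(names(tab))
  data.frame(bin_lo = idx * bin_width, bin_hi = (idx + 1) * bin_width,
             count = as.integer(tab), row.names = NULL)
}
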