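# Individual-level diplotype calls from EM posteriors.

#' Call each individual's diplotype from posterior proportions
#'
#' Selects, per individual, the diplotype with the largest posterior
#' proportion `w_jk`. With a `threshold`, individuals whose best proportion
#' does not exceed it become no-calls (`NA` diplotype). Exact ties are
#' broken deterministically by canonical diplotype string order.
#'
#' @param result A [run_em()] result.
#' @param threshold `NULL` (no threshold) or a real in `[0, 1]`; a call is
#'   emitted only when the best proportion is strictly greater.
#' @return `data.frame` with columns `individual_id`, `diplotype` (`NA` for
#'   a no-call), `h1`, `h2`, `proportion`, `called`.
#' @export
call_diplotypes <- function(result, threshold = NULL) {
  stopifnot(inherits(result, "cnv_em"))
  post <- result$posteriors
  ord <- order(post$ind, -post$w, post$diplotype, method = "radix")
  best <- post[ord, ][!duplicated(post$ind[ord]), , drop = FALSE]
  called <- if (is.null(threshold)) {
    rep(TRUE, nrow(best))
  } else {
    if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
    best$w > threshold
  }
  data.frame(
    individual_id = best$individual_id,
    diplotype = ifelse(called, best$diplotype, NA_character_),
    h1 = ifelse(called, best$h1, NA_character_),
    h2 = ifelse(called, best$h2, NA_character_),
    proportion = best$w,
    called = called,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Unphased states implied by called diplotypes
#'
#' Collapses each called diplotype back to its per-site total copy number or
#' unphased genotype; the package's copy-number/genotype calls are obtained
#' this way rather than from the raw likelihoods.
#'
#' @param called A [call_diplotypes()] result (no-calls are skipped).
#' @param sites The [cnv_sites()] table used for phasing.
#' @return `data.frame` with columns `individual_id`, `site_id`, `state`.
#' @export
implied_unphased_calls <- function(called, sites) {
  sites <- validate_sites(sites)
  ok <- called$called & !is.na(called$diplotype)
  sub <- called[ok, , drop = FALSE]
  if (!nrow(sub)) {
    return(data.frame(individual_id = character(0), site_id = character(0),
                      state = character(0), stringsAsFactors = FALSE))
  }
  states <- collapse_diplotypes(sub$h1, sub$h2, sites)
  data.frame(
    individual_id = rep(sub$individual_id, times = nrow(sites)),
    site_id = rep(sites$site_id, each = nrow(sub)),
    state = as.vector(states),
    stringsAsFactors = FALSE
  )
}
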