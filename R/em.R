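# Expectation-maximization over diplotype expansions.
#
# Model: haplotypes h_i with population frequencies theta = (P(h_1), ...);
# an individual's diplotype is drawn under Hardy-Weinberg equilibrium and
# observed only through per-site likelihoods, giving the mixture likelihood
#   ln L = sum_j ln sum_k lambda_jk * P(d_jk | theta).
# The E step computes posterior diplotype proportions w_jk, the M step
# re-estimates frequencies as posterior-weighted chromosome counts / 2N.

#' Construct a haplotype frequency table
#'
#' @param x Named numeric vector (names = canonical haplotype strings).
#' @param normalize If `TRUE`, rescale to sum one (used e.g. when entering
#'   frequencies printed at limited precision).
#' @return Named numeric vector of class `freq_table`, summing to one.
#' @export
freq_table <- function(x, normalize = FALSE) {
  if (is.null(names(x)) || any(!nzchar(names(x)))) {
    stop("frequencies must be named by haplotype")
  }
  nm <- names(x)
  x <- as.numeric(x)
  names(x) <- nm
  if (any(x < 0)) stop("negative frequency")
  if (normalize) {
    x <- x / sum(x)
  } else if (abs(sum(x) - 1) > 1e-9) {
    stop("frequencies must sum to 1 (got ", format(sum(x)), ")")
  }
  structure(x, class = "freq_table")
}

#' Hardy-Weinberg prior probability of a diplotype
#'
#' `P(h_l)^2` for a homozygote, `2 P(h_l) P(h_m)` otherwise; haplotypes
#' absent from the table have frequency zero.
#'
#' @param d Character vector of diplotype strings (`"h1/h2"`).
#' @param freqs A [freq_table()].
#' @return Numeric vector of prior probabilities.
#' @export
hwe_prior <- function(d, freqs) {
  sp <- split_diplotype(d)
  p1 <- ifelse(sp$h1 %in% names(freqs), freqs[sp$h1], 0)
  p2 <- ifelse(sp$h2 %in% names(freqs), freqs[sp$h2], 0)
  unname(p1 * p2 * ifelse(sp$h1 == sp$h2, 1, 2))
}

#' EM configuration
#'
#' @param tolerance Convergence threshold on the change in log-likelihood
#'   between iterations.
#' @param max_iterations Iteration cap per chain.
#' @param n_restarts Number of additional chains started from random
#'   frequency vectors (flat Dirichlet draws); the chain with the highest
#'   final log-likelihood wins, ties going to the earliest chain.
#' @param seed Integer seed for the restart draws.
#' @param initialization `"uniform"` starts the first chain from equal
#'   frequencies; `"random"` makes every chain random.
#' @return List of class `em_config`.
#' @export
em_config <- function(tolerance = 1e-8, max_iterations = 10000L,
                      n_restarts = 10L, seed = 1L,
                      initialization = c("uniform", "random")) {
  stopifnot(tolerance > 0, max_iterations >= 1, n_restarts >= 0)
  structure(
    list(tolerance = tolerance, max_iterations = as.integer(max_iterations),
         n_restarts = as.integer(n_restarts), seed = as.integer(seed),
         initialization = match.arg(initialization)),
    class = "em_config"
  )
}

# indexed internal view of an expansion: integer haplotype codes, per-row
# het multiplier, per-individual log-lambda offsets for a stable ln L, and
# sparse accumulators (rows -> individuals; rows -> haplotype counts) so
# each EM iteration is a handful of vector ops and two sparse mat-vecs
index_expansion <- function(expansion) {
  tab <- expansion$table
  haps <- csort(unique(c(tab$h1, tab$h2)))
  i1 <- match(tab$h1, haps)
  i2 <- match(tab$h2, haps)
  ind <- tab$ind
  n <- length(expansion$individuals)
  nr <- nrow(tab)
  off <- as.vector(tapply(tab$loglambda, ind, max))
  lam <- exp(tab$loglambda - off[ind])
  by_ind <- Matrix::sparseMatrix(i = ind, j = seq_len(nr), x = 1,
                                 dims = c(n, nr))
  # duplicate (i, j) entries sum: a homozygous row contributes 2
  hap_count <- Matrix::sparseMatrix(i = c(i1, i2), j = rep(seq_len(nr), 2),
                                    x = 1, dims = c(length(haps), nr))
  list(haps = haps, i1 = i1, i2 = i2, ind = ind, n = n,
       lam = lam, mult = ifelse(i1 == i2, 1, 2), off = off, offset = sum(off),
       by_ind = by_ind, hap_count = hap_count)
}

em_prior <- function(ix, p) p[ix$i1] * p[ix$i2] * ix$mult

#' E step: posterior diplotype proportions
#'
#' `w_jk` proportional to `lambda_jk * P(d_jk)` under HWE, normalized to sum
#' one within each individual.
#'
#' @param expansion A [build_expansion()] result.
#' @param freqs A [freq_table()] over (at least) the expansion's haplotypes.
#' @return `data.frame` with columns `ind`, `individual_id`, `h1`, `h2`,
#'   `w`. Individuals whose every diplotype has zero `lambda * prior` are
#'   dropped with a warning.
#' @export
e_step <- function(expansion, freqs) {
  ix <- index_expansion(expansion)
  p <- freq_lookup(freqs, ix$haps)
  num <- ix$lam * em_prior(ix, p)
  den <- as.numeric(ix$by_ind %*% num)
  dead <- den <= 0
  if (any(dead)) {
    warning(sum(dead), " individual(s) with zero posterior mass dropped")
  }
  w <- num / den[ix$ind]
  keep <- !dead[ix$ind]
  out <- expansion$table[keep, c("ind", "individual_id", "h1", "h2")]
  out$w <- w[keep]
  rownames(out) <- NULL
  out
}

freq_lookup <- function(freqs, haps) {
  p <- rep(0, length(haps))
  hit <- haps %in% names(freqs)
  p[hit] <- unclass(freqs)[haps[hit]]
  p
}

#' M step: frequencies as posterior-weighted chromosome counts
#'
#' Each diplotype row contributes `w` copies of each of its two haplotypes;
#' frequencies are total weighted counts over `2N` chromosomes.
#'
#' @param posteriors An [e_step()] result.
#' @param expansion The matching [build_expansion()] result (supplies the
#'   haplotype universe so unobserved haplotypes keep frequency zero).
#' @return A [freq_table()].
#' @export
m_step <- function(posteriors, expansion) {
  haps <- csort(unique(c(expansion$table$h1, expansion$table$h2)))
  n <- length(unique(posteriors$ind))
  idx <- c(match(posteriors$h1, haps), match(posteriors$h2, haps))
  cnt <- rowsum(c(posteriors$w, posteriors$w),
                factor(idx, levels = seq_along(haps)))[, 1]
  cnt[is.na(cnt)] <- 0
  freq_table(stats::setNames(cnt / (2 * n), haps), normalize = TRUE)
}

#' Observed-data log-likelihood
#'
#' `sum_j ln sum_k lambda_jk P(d_jk)`, computed stably in log space.
#' Individuals with non-positive inner sum are excluded (with a warning),
#' mirroring [e_step()].
#'
#' @inheritParams e_step
#' @return Numeric scalar.
#' @export
log_likelihood <- function(expansion, freqs) {
  ix <- index_expansion(expansion)
  p <- freq_lookup(freqs, ix$haps)
  em_loglik(ix, p, warn = TRUE)
}

em_loglik <- function(ix, p, warn = FALSE) {
  den <- as.numeric(ix$by_ind %*% (ix$lam * em_prior(ix, p)))
  dead <- den <= 0
  if (any(dead) && warn) {
    warning(sum(dead), " individual(s) with zero likelihood excluded from ln L")
  }
  sum(log(den[!dead])) + sum(ix$off[!dead])
}

#' Run the EM to estimate haplotype frequencies
#'
#' Alternates [e_step()] and [m_step()] until the log-likelihood changes by
#' less than `config$tolerance` or `config$max_iterations` is reached.
#' Multiple chains (uniform start plus random restarts) guard against local
#' maxima; the chain with the highest final log-likelihood is returned.
#'
#' @param expansion A [build_expansion()] result.
#' @param config An [em_config()].
#' @return Object of class `cnv_em`: list with `frequencies` (a
#'   [freq_table()], descending order), `loglik_trace` (winning chain),
#'   `loglik`, `posteriors` (final [e_step()] table with a `diplotype`
#'   column), `converged`, `n_iterations`, `n_individuals_used`,
#'   `chain_logliks`, and `excluded` (carried over from the expansion).
#' @export
run_em <- function(expansion, config = em_config()) {
  stopifnot(inherits(expansion, "diplotype_expansion"))
  ix <- index_expansion(expansion)
  h <- length(ix$haps)
  if (h == 0L) stop("expansion contains no haplotypes")

  inits <- list()
  if (config$initialization == "uniform") {
    inits[[1]] <- rep(1 / h, h)
  }
  n_random <- config$n_restarts + (config$initialization == "random")
  if (n_random > 0) {
    set.seed(config$seed)
    for (r in seq_len(n_random)) {
      g <- stats::rgamma(h, 1)  # flat Dirichlet
      inits[[length(inits) + 1]] <- g / sum(g)
    }
  }

  chains <- lapply(inits, function(p0) em_chain(ix, p0, config))
  finals <- vapply(chains, function(ch) ch$loglik, 0)
  best <- which.max(finals)  # ties: earliest chain
  win <- chains[[best]]

  p <- win$p
  names(p) <- ix$haps
  ord <- order(-p, names(p), method = "radix")
  freqs <- freq_table(p[ord], normalize = TRUE)

  post <- e_step(expansion, freqs)
  post$diplotype <- paste0(post$h1, "/", post$h2)

  structure(
    list(frequencies = freqs,
         loglik_trace = win$trace,
         loglik = win$loglik,
         posteriors = post,
         converged = win$converged,
         n_iterations = length(win$trace),
         n_individuals_used = win$n_used,
         chain_logliks = finals,
         excluded = expansion$excluded),
    class = "cnv_em"
  )
}

em_chain <- function(ix, p, config) {
  trace <- numeric(config$max_iterations)
  ll_old <- -Inf
  converged <- FALSE
  i1 <- ix$i1; i2 <- ix$i2; ind <- ix$ind; lam <- ix$lam
  lam_mult <- lam * ix$mult
  n_used <- ix$n
  live <- rep(TRUE, ix$n)
  it <- 0L
  while (it < config$max_iterations) {
    it <- it + 1L
    num <- lam_mult * p[i1] * p[i2]
    den <- as.numeric(ix$by_ind %*% num)
    dead <- den <= 0 & live
    if (any(dead)) {
      warning(sum(dead), " individual(s) lost all posterior mass; excluded")
      live <- live & !dead
      n_used <- sum(live)
      if (!n_used) stop("no usable individual left in EM")
      num[!live[ind]] <- 0
    }
    w <- num / den[ind]
    w[!is.finite(w)] <- 0
    cnt <- as.numeric(ix$hap_count %*% w)
    p <- cnt / (2 * n_used)
    ll <- sum(log(den[live])) + sum(ix$off[live])
    trace[it] <- ll
    if (is.finite(ll_old) && abs(ll - ll_old) < config$tolerance) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  list(p = p, trace = trace[seq_len(it)], loglik = trace[it],
       converged = converged, n_used = n_used)
}

#' @export
print.cnv_em <- function(x, ...) {
  cat("CNV haplotype EM:", length(x$frequencies), "haplotype(s),",
      x$n_individuals_used, "individual(s), ln L =",
      format(x$loglik, digits = 8),
      if (x$converged) "(converged)" else "(max iterations)", "\n")
  top <- utils::head(x$frequencies, 8)
  for (h in names(top)) cat(sprintf("  %-20s %.6f\n", h, top[h]))
  if (length(x$frequencies) > 8) cat("  ...\n")
  invisible(x)
}
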