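---
title: "Methods: likelihood-aware EM phasing of CNV haplotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: likelihood-aware EM phasing of CNV haplotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvhaplo)
```

## The statistical model

At a CNV locus an experiment observes, per individual and site, not a
haplotype pair but an *unphased state*: the total copy number at an ICN
site, the pooled base multiset at an SNVC site, or the genotype at a SNP.
Because intensity clusters for neighbouring states overlap, the state
itself is uncertain; the data the model actually consumes is a
**GenoSpectrum** — for each individual $j$ and site $s$, a map from every
possible unphased state to a likelihood $\Pr(x_{j,s}\mid\text{state})$.
Only relative values within one (individual, site) matter; any positive
rescaling leaves every result unchanged (this is asserted as a test
invariant).

Let $h_i$ denote haplotypes with population frequencies
$\theta = (P(h_1), P(h_2), \dots)$. The *enumeration* step lists, for each
individual, all multi-site diplotypes $d_{j,k}$ consistent with any
positive-likelihood state, and attaches

$$\lambda_{j,k} \;=\; \prod_{s=1}^{S} \Pr\!\big(x_{j,s} \mid d_{j,k,s}\big),$$

where the factor at site $s$ is the likelihood of the state implied by
$d_{j,k}$ there — intensities cannot distinguish, say, $[0/3]$ from
$[1/2]$, so both receive the likelihood of "total 3". Measurements at
different sites are assumed conditionally independent given the diplotype
(this is *not* an assumption of linkage equilibrium between sites).

The EM iteration maximizes
$\ln L = \sum_j \ln \sum_k \lambda_{j,k} P(d_{j,k}\mid\theta)$ with
Hardy–Weinberg diplotype priors
$P(h_l/h_m) = P(h_l)P(h_m)$ if $l = m$ and $2P(h_l)P(h_m)$ otherwise:

* **E step** $\;w_{j,k} = \dfrac{\lambda_{j,k} P(d_{j,k})}
  {\sum_{k'} \lambda_{j,k'} P(d_{j,k'})}$,
* **M step** $\;P(h_i) = \dfrac{\sum_j \sum_k \delta(h_i, d_{j,k})\,
  w_{j,k}}{2N}$, with $\delta \in \{0, 1, 2\}$ counting copies of $h_i$ in
  $d_{j,k}$.

Individual diplotypes are read off as $\arg\max_k w_{j,k}$, and the
implied per-site copy numbers or genotypes come from collapsing that call
— which is how the algorithm "corrects" hard calls that the raw
likelihoods rank wrongly.

### Assumptions and their limits

* **HWE priors.** Diplotype priors factor over haplotypes; a strongly
  inbred or stratified sample violates this. Deviations degrade accuracy
  gracefully rather than catastrophically in the analogous SNP setting.
* **Site-wise conditional independence of measurements** given the
  diplotype. Probes aggregated from a common segmentation should be
  collapsed (e.g. by median) to one site beforehand.
* **Exhaustive enumeration.** The diplotype count grows roughly
  exponentially with the number of jointly phased sites; the design target
  is 1–3 sites, which covers per-region association testing and two-site
  LD (tag-SNP) uses. `prune_states()` trims near-zero states to push that
  boundary, at the cost of discarding mass the EM would otherwise use.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `max_allele_copies` | 2 | cap on copies per haplotype at a site (alleles 0–2) |
| `max_total_copies` | 4 | cap on the summed copies over a diplotype (states 0–4) |
| `tolerance` | 1e-8 | stop when $|\Delta \ln L|$ falls below this |
| `max_iterations` | 10000 | per-chain cap |
| `n_restarts` | 10 | random-restart chains beside the uniform start |
| `prune_states()` threshold | 0 (off) | drop states below this normalized likelihood |
| call `threshold` | none | minimum posterior proportion for a diplotype call |

The copy caps mirror a typical deletion/duplication locus (per-haplotype
alleles 0–2 copies, observed totals 0–4); both are per-site configuration,
not constants. Convergence uses $\ln L$ deltas because the likelihood is
the quantity EM provably improves; 1e-8 on a data-set scale log-likelihood
is far below any scientifically meaningful difference. Initialization is a
uniform frequency vector plus `n_restarts` flat-Dirichlet draws from a
fixed seed; the chain with the best final $\ln L$ wins, ties going to the
earliest chain, making runs bit-reproducible. In practice the likelihood
surface for 1–2 sites is benign and all chains agree; restarts are cheap
insurance against ridge cases (e.g. states whose diplotype support barely
overlaps).

### Numerical choices

$\lambda$ products are accumulated in log space and normalized per
individual by their maximum before exponentiation; the discarded offsets
are added back when $\ln L$ is reported, so the trace is exact while the
arithmetic never underflows. Exact-zero likelihood states are simply never
enumerated. Haplotype and diplotype identity is canonical-string based
(copy units sorted by alphabet order, pair sorted lexicographically in the
C locale), which fixes every tie-break — the posterior argmax resolves
exact ties toward the smaller canonical diplotype string, and the
most-likely-state call toward the smaller state string. Individuals whose
every enumerated diplotype has zero likelihood (or whose posterior mass
vanishes at the current $\theta$, possible only with degenerate inputs)
are excluded with a warning and $N$ is reduced accordingly, keeping the M
step normalized.

## The simulator

`simulate_dataset()` reproduces the generative design the estimator is
meant for: known frequencies → i.i.d. haplotype draws paired under HWE →
per-site unphased states → Gaussian signal intensities → likelihood
spectra computed under the same Gaussian model.

Cluster means are equally spaced: an ICN state with total $T$ sits at
$T\cdot\Delta$ on a one-dimensional (log-ratio-like) axis; an SNVC state
sits at its per-base copy counts times $\Delta$, one channel per alphabet
base (so a two-base site yields two-channel data). Units are arbitrary —
only $\Delta/\sigma$ matters. The common per-site $\sigma$ is not chosen
directly but **calibrated**: `calibrate_noise()` root-finds the $\sigma$
at which the expected argmax miscall rate, weighted by the population's
true-state distribution, hits a target (exactly computed from midpoint
boundaries in 1-D; by deterministic Gaussian grid quadrature in ≥2-D).
The packaged scenarios target a 22% (ICN) or 21% per site (SNVC) hard-call
error — the realism anchor for noisy microarray data — so the simulation
is pinned to an observable error rate rather than to unavailable
real-array cluster parameters.

The three `sim_scenario()` presets describe a tri-allelic
deletion/duplication locus from a 588-individual panel: a major one-copy
(or single-`A`) haplotype near 96%, deletion and duplication haplotypes
near 2% each, and, for SNVC sites, a rare second base at 0.09%. The
printed reference frequencies sum to 1.0001 from rounding and are
renormalized. For the two-site preset the second site carries the
variation while the first is nearly monomorphic (its `A` allele rides only
on the rarest haplotype); per-site alleles are multisets, so a
two-copy-unit deletion haplotype is represented identically to a plain
deletion — observationally indistinguishable states collapse.

What the generator deliberately does **not** emulate: heterogeneous
per-site noise (every replicate site set shares one calibrated $\sigma$,
where real arrays vary probe by probe — so replicate-to-replicate spread
of every metric is narrower than on real data), skewed or heavy-tailed
intensity distributions, correlated noise across sites, batch effects, and
segmentation error upstream of the likelihoods. Passing tests therefore
show the estimator is correct and well-behaved under its own model at a
realistic average error rate; they do not certify any particular real
platform.

## Study sizes used in tests

The bundled studies follow the reference design at full scale: 14
replicate site sets × 588 individuals for the three scenario types, and a
sample-size grid with 10 answer sets × 14 noise replicates (reduced to
5 × 3 inside the test suite, which the corresponding check anticipates) at
n = 100 and n = 50. The EM's correctness is additionally pinned by
independent oracles at small scale: brute-force bipartition enumeration,
an independently coded hard-call EM, and direct grid maximization of
$\ln L$ on a 3-haplotype simplex (step 1e-3), which the EM fixed point
matches to 2e-3 per frequency.

## Known limitations

* No partition–ligation, HMM, or sampling-based extension: joint phasing
  beyond ~3 sites is exponential and out of scope.
* The Gaussian signal model is spherical per state; correlated channels
  would need a full-covariance extension of `state_likelihood()`.
* No trio or pedigree constraints, and no LD statistics — both computable
  downstream from the frequency table and posteriors.
* No VCF emission: multi-copy unphased states do not map cleanly onto VCF
  genotype fields; TSV formats are documented on each reader/writer.
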