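# cnvhaplo

Haplotype and diplotype inference at copy-number-variable (CNV) loci from
noisy, probabilistically represented high-throughput data.

## The problem

Microarrays (and read-depth methods) do not observe haplotypes at CNV loci.
At an integer-copy-number (ICN) site they measure only the **total copy
number** over the two chromosomes; at a site with single-nucleotide
variation inside the duplicated copy units (SNVC) they measure only the
**unphased base multiset** (e.g. `AAG`, unlike a SNP's `AG`). Worse, signal
intensities from neighbouring copy numbers or genotypes overlap, so the
hard call — the state with the largest likelihood — is frequently wrong.
Feeding those wrong hard calls to a phasing algorithm corrupts both the
estimated haplotype frequencies and the inferred diplotypes.

`cnvhaplo` is for population geneticists and statistical-genetics tool
builders who have per-state likelihoods (a *GenoSpectrum*) from a calling
model such as a Gaussian mixture over intensities, and want frequencies and
diplotypes that properly account for that uncertainty.

## The model

For individual *j*, the enumeration step lists every multi-site diplotype
*d<sub>j,k</sub>* consistent with any positive-likelihood state (a total of
3 at an ICN site yields the one-site diplotypes `[0/3]` and `[1/2]`; the
genotype `AAG` yields `[-/A,A,G]`, `[A,A/G]`, `[A/A,G]`), with the
across-site likelihood

λ<sub>j,k</sub> = Pr(x<sub>j,k</sub> | d<sub>j,k</sub>) = ∏<sub>s</sub>
Pr(x<sub>j,k,s</sub> | d<sub>j,k,s</sub>),

where the per-site factor is the likelihood of the unphased state the
diplotype implies there. The EM algorithm then iterates, with
Hardy–Weinberg priors P(h<sub>l</sub>/h<sub>m</sub>) =
P(h<sub>l</sub>)P(h<sub>m</sub>) (homozygote) or
2P(h<sub>l</sub>)P(h<sub>m</sub>):

* E step: w<sub>j,k</sub> ∝ λ<sub>j,k</sub> P(d<sub>j,k</sub>), normalized
  within each individual;
* M step: P(h<sub>i</sub>) = Σ<sub>j,k</sub> δ(h<sub>i</sub>,
  d<sub>j,k</sub>) w<sub>j,k</sub> / 2N, with δ counting how many copies of
  h<sub>i</sub> the diplotype carries;

until ln L = Σ<sub>j</sub> ln Σ<sub>k</sub> λ<sub>j,k</sub>
P(d<sub>j,k</sub>) converges. Individual diplotypes are called as the
posterior argmax (optionally with a confidence threshold), and estimation
error is summarized by the total variation distance
TV = ½ Σ<sub>i</sub> |p<sub>i</sub> − p̂<sub>i</sub>|.

## Worked example

Simulate a noisy single-copy-number locus (a rare deletion and a rare
duplication around a one-copy major allele), then phase it:

```r
library(cnvhaplo)

sc <- sim_scenario("one_icn")       # frequencies 0.9609 / 0.0196 / 0.0196
model <- calibrate_signal_model(sc$freqs, sc$sites, target_miscall = 0.22)
sim <- simulate_dataset(sc$freqs, sc$sites, n = 588, seed = 11, model = model)

res <- run_em(build_expansion(sim$spectra, sc$sites), em_config(seed = 12))
res
#> CNV haplotype EM: 3 haplotype(s), 588 individual(s), ln L = -410.14366 (converged)
#>   1                    0.961290
#>   0                    0.021752
#>   2                    0.016958

evaluate_replicate(sim$truth, res, sim$spectra, sc$sites)
#>            tv diplotype_accuracy ml_call_accuracy correction_rate corruption_rate
#> 1 0.002106574          0.9404762        0.7891156       0.1955782      0.04421769
```

Although 21% of the hard copy-number calls are wrong
(`ml_call_accuracy = 0.789`), the likelihood-aware EM recovers the answer
frequencies to TV ≈ 0.002 and calls 94% of diplotypes exactly, correcting
most of the bad hard calls (`correction_rate = 0.196`) while corrupting few
(`corruption_rate = 0.044`).

The same workflow runs from a shell via the bundled script
(`system.file("cli", "cnvhaplo.R", package = "cnvhaplo")`), with
`simulate`, `phase` and `evaluate` subcommands reading and writing the TSV
formats documented in the function reference.

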