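# clipHMM

Detection of individual protein–RNA crosslink sites from single-nucleotide
resolution CLIP-seq data (iCLIP/eCLIP), for analysts who want
nucleotide-level binding footprints rather than broad peaks.

In truncation-based CLIP protocols, reverse transcription stops at the
crosslinked nucleotide, so read 5′ ends pile up exactly at protein–RNA
contact positions. Calling those positions naively confounds three things:
true binding, transcript abundance (and background-protein binding), and
the sequence preference of crosslinking itself (polypyrimidine-rich "CL
motifs"). `clipHMM` separates them with a four-state hidden Markov model
over two observed signals derived per chromosome and strand:

* the **read-start count** `k_t` (truncation evidence), and
* the **pulled-down fragment density** `c_t`, a Gaussian kernel density
  over the read starts (bandwidth `h = 50` bp by default), which estimates
  fragment-level coverage undistorted by truncation pile-ups.

Each position carries an *enrichment* state (fragment-level) and a
*crosslink* state (nucleotide-level); the four joint states emit

* `c_t ~` left-truncated gamma `(μ_s1, λ_s1, tp)` — enrichment dimension,
* `k_t ~` zero-truncated binomial `(n̂_t, p_s2)` — crosslink dimension,

where the trial count `n̂_t = max(k_t, round(c_t · h))` is a surrogate for
the number of locally contributing fragments. Parameters are learned by
Baum–Welch with numerically optimised M-steps; sites are the positions
posterior-decoded as *enriched + crosslink*, scored by the log posterior
ratio of the two most likely states, and optionally merged into binding
regions (default 8 bp).

Two optional covariates make the emissions non-homogeneous and cut false
positives: the log fragment density of an **input control** enters the
enrichment means through a gamma GLM with log link (abundance/background
normalisation), and per-position **CL-motif scores** enter the crosslink
probabilities through per-motif logistic regressions (crosslinking
sequence-bias correction). With zero coefficients both reduce exactly to
the basic model.

The package also contains the full evaluation stack: an iCLIP/eCLIP read
simulator with ground-truth crosslink annotations (fragmentation,
pull-down, truncation, size selection, background regions, noise reads),
CL-motif track construction (DREME window export, MEME-format ingestion,
an internal FIMO-compatible PWM scanner), and evaluation statistics
(motif-anchored precision, 3′-splice-site positioning, simulation
precision/recall, bias-corrected replicate agreement).

## Worked example

Simulate an eCLIP-like dataset with background binding and noise, fit the
model, and compare the calls with the simulated truth:

```r
library(clipHMM)

cs  <- c(chrA = 60000L, chrB = 40000L)
sim <- simulate_clip(cs, n_fragments = 2e5, n_regions = 12,
                     n_bg_regions = 3, seed = 1)
sim
#> <clip_sim> 3768 reads (background: 146, noise: 639, target: 2983), 12 target regions, 30 crosslink sites

fit <- clip_hmm(sim$tracks)
fit
#> Crosslink-site HMM fit
#>   chains: 108 covered intervals, 26,466 positions
#>   EM: 50 iterations, NOT converged, loglik 61060.82
#>   enrichment (LTG): mu = (0.0177, 1.8), lambda = (0.161, 1.63), tp = 0.00798
#>   crosslink (ZTB): p = (0.00853, 0.745)

sites <- predict(fit)
head(sites, 4)
#>   chrom  pos strand    score posterior
#> 1  chrA 7902      - 61.58136         1
#> 2  chrA 7903      - 53.32699         1
#> 3  chrA 7907      - 61.41413         1
#> 4  chrA 7908      - 53.06977         1

pr <- sim_precision_recall(sites, sim)
tail(pr$site_curve, 2)
#>    threshold n_called n_tp precision    recall
#> 28  23.50540       28   27 0.9642857 0.9000000
#> 29  22.48882       29   28 0.9655172 0.9333333
```

The fitted emission parameters say what the model found: non-enriched
positions average a fragment density of ~0.02 against ~1.8 in enriched
regions, and at crosslink sites roughly 75% of the locally contributing
fragments truncate (`p1 = 0.745`) against under 1% elsewhere
(`p0 = 0.009`). Of the 29 called sites, 28 coincide exactly with a
simulated crosslink position (site-level precision 0.97, recall 0.93);
the `EM ... NOT converged` line reports that the trace was still moving by
more than `tol` at `max_iter` — the emissions are fitted only to positions
with read starts, so the trace can wobble slightly below the default
tolerance on sparse data (see the vignette).

`write_sites_bed()` / `write_regions_bed()` export BED6(+1) files;
`coef()`, `logLik()`, `summary()`, `plot()` and `simulate()` work on the
fit; `write_params()` round-trips the parameter file.

A thin command-line wrapper ships in `exec/`:

```sh
cliphmm simulate --chrom-sizes chrom.sizes --out-prefix sim --seed 5
cliphmm call --chrom-sizes chrom.sizes --bedgraph-plus sim.plus.bedgraph \
             --bedgraph-minus sim.minus.bedgraph --out-prefix run
cliphmm evaluate --sites run.sites.bed --truth-crosslinks sim.crosslinks.bed \
             --truth-regions sim.regions.bed --out-prefix eval
```

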