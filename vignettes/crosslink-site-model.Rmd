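---
title: "Calling crosslink sites from truncation-based CLIP-seq data"
author: "clipHMM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling crosslink sites from truncation-based CLIP-seq data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clipHMM)
```

## The problem

In iCLIP- and eCLIP-style experiments, UV light covalently crosslinks an RNA
binding protein to its RNA targets, the protein-bound fragments are
immunoprecipitated, and reverse transcription frequently stops at the
crosslinked nucleotide. The 5' ends of the sequenced reads therefore pile up
at crosslink sites, giving nucleotide-resolution evidence of where the
protein touched the RNA. Two confounders make naive pile-up calling
unreliable: local read density scales with transcript abundance (and with
background protein binding), and crosslinking itself has a sequence
preference (polypyrimidine-rich "CL motifs") that produces truncation
pile-ups with no target binding.

`clipHMM` separates these effects with a four-state hidden Markov model at
single-nucleotide resolution. Each position carries two binary labels:

* an *enrichment* state $S^{(1)} \in \{0, 1\}$ — is the position inside a
  region enriched in pulled-down fragments? — and
* a *crosslink* state $S^{(2)} \in \{0, 1\}$ — does a significant fraction
  of the local fragments truncate exactly here?

The four joint states are ordered (0,0), (0,1), (1,0), (1,1); called
crosslink sites are the positions decoded as (1,1), *enriched + crosslink*.

## Observed signals

From the mapped, deduplicated reads the package derives, per chromosome and
strand:

* **read-start counts** $k_t$: the number of reads whose
  truncation-indicating end maps to position $t$ (the 5' end of the read for
  iCLIP, or of the second mate for eCLIP, selected with `which_end`). No
  upstream shift is applied; the model calls the truncation-accumulation
  position itself.
* **pulled-down fragment density** $c_t$: a Gaussian kernel density over
  the read starts,
  $c_t = \frac{1}{h} \sum_{i=t-4h}^{t+4h} k_i \, K\!\left(\frac{t-i}{h}\right)$,
  with bandwidth $h$ (default 50 bp) and the kernel truncated at four
  bandwidths. Position-wise raw coverage is *not* used because truncation
  pile-ups distort it; the smoothed signal estimates fragment-level
  coverage instead. The kernel conserves mass, so $\sum_t c_t \approx
  \sum_t k_t$ away from chromosome ends.

Strands are processed fully independently; the model runs per *covered
interval* (maximal runs with $c_t$ above the truncation point, optionally
merged across short gaps), with transitions shared across all intervals.

## Emission model

**Enrichment.** Fragment densities are continuous, non-negative and
right-skewed; each enrichment state emits from a *left-truncated gamma*
(LTG) with mean $\mu_{s_1}$ and shape $\lambda_{s_1}$, renormalised to the
open support $(tp, \infty)$. The truncation point $tp$ is fixed before EM.
The distributions are fitted only to positions carrying at least one read
start, which keeps the fit away from the vast majority of near-zero
positions.

**Crosslinking.** Given $n_t$ fragments overlapping position $t$, the
number that truncate there is binomial; conditioning on observing the
position at all gives a *zero-truncated binomial* (ZTB) on $k_t$ with
per-read start probability $p_{s_2}$. The trial count is not observed and
is approximated by the surrogate $\hat n_t = \max(k_t,
\operatorname{round}(c_t \cdot s))$ with rescale factor $s$. Because
$\hat n_t$ is a function of $c_t$, the joint emission factorises:
$P(c_t, k_t \mid s_1, s_2) = f_{\mathrm{LTG}}(c_t; \mu_{s_1},
\lambda_{s_1}, tp) \cdot f_{\mathrm{ZTB}}(k_t; \hat n_t, p_{s_2})$.

At positions with $k_t = 0$ the crosslink dimension carries no information:
the ZTB factor is dropped there and decoding forces the non-crosslink
state, so positions without read starts are never called.

## Covariates

Two kinds of position-wise external data can enter the emissions through
generalized linear models, giving a non-homogeneous HMM:

* **Input control** (background normalisation): the log of the input
  experiment's fragment density $b_t$ (same bandwidth as the target) drives
  the enrichment means through a log link,
  $\log \mu_{s_1,t} = \alpha_{s_1,0} + \alpha_{s_1,1} b_t$, with a constant
  shape per state. Positions where the input density does not exceed its
  own truncation point are masked and use the covariate-free mean — the
  GLM is never extrapolated below its support.
* **CL motifs** (crosslinking sequence bias): each position carries the
  index $i$ and score $x_{i,t}$ of its best-scoring CL-motif occurrence
  (0 where none). The crosslink probability follows one logistic
  regression per motif,
  $\operatorname{logit} p_{s_2,t} = \beta_{s_2,0} + \beta_{s_2,i}\,x_{i,t}$.
  The intercept is estimated from motif-free positions exactly as in the
  basic model and the slopes are fitted per motif, independently, by
  Brent's method; both are refit in every EM iteration.

With $\alpha_{s_1,1} = 0$ and all slopes zero, the covariate model runs
through the same code path as the basic model and produces bit-identical
emissions and site calls (asserted by a test).

## Training and decoding

Parameters are learned by Baum–Welch: the E-step runs scaled
forward–backward (compiled) over all covered intervals; the M-step
re-estimates transitions from expected counts and refits the emissions by
weighted maximum likelihood with the smoothed posteriors as weights.
Training can be restricted to a chromosome subset (`train_chroms`) and the
learned parameters applied genome-wide.

Decoding is posterior decoding (not Viterbi): at each position the state
with the highest smoothed posterior wins, ties broken toward the lower flat
state index for determinism. Each called site is scored with the log
posterior ratio of the first and second most likely state,
$\mathrm{score}_t = \log P(\text{1st} \mid Y_{1:T}) - \log P(\text{2nd}
\mid Y_{1:T}) \ge 0$. Sites within 8 bp (default) of each other can be
merged into binding regions, scored by their best member site.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `h` | 50 bp | kernel bandwidth for the fragment density; larger for longer cDNAs |
| `rescale` | `h` | surrogate-trial factor $s$; since $\sum c \approx \sum k$, $c_t$ is a per-position rate and $c_t \cdot h$ approximates the locally contributing fragment count |
| `tp` | data-driven | LTG truncation point, fixed before EM (below) |
| `min_gap` | 1 | covered-interval merge gap (gaps shorter than this are bridged) |
| `merge_distance` | 8 bp | site-to-region merge distance |
| `max_iter`, `tol` | 50, 1e-3 | EM stop: absolute change in total log-likelihood |

## Numerical and design choices

Several details are deliberate choices where the method description leaves
room; they are recorded here as the package's own decisions.

* **Truncation point.** $tp$ is fixed once, before EM, at just below the
  minimum density observed at positions with a read start
  ($tp = (1 - 10^{-6}) \cdot \min\{c_t : k_t \ge 1\}$). The one-sided
  nudge keeps every such position strictly inside the open LTG support, so
  covered intervals (defined by $c_t > tp$) contain every read-start
  position. Positions inside merged gaps may fall below $tp$; their LTG
  factor is evaluated at the support edge.
* **Surrogate rescale** $s = h$, exposed as `rescale`; flooring at $k_t$
  keeps $k_t \le \hat n_t$ so the ZTB is always well defined. Counts above
  $\hat n_t$ cannot occur with the floor, but are clamped to probability
  zero defensively.
* **ZTB kernel.** The pmf uses the standard kernel
  $p^{k}(1-p)^{\hat n - k}$ with the zero-truncation normaliser
  $1/(1 - (1-p)^{\hat n})$, which sums to one and is monotone in $k$ in
  the usual way.
* **M-step optimisers.** The LTG fit runs bounded quasi-Newton
  (`L-BFGS-B`, gradient tolerance $10^{-6}$) on $(\log\mu, \log\lambda)$;
  the weighted truncated-gamma likelihood is reduced to three sufficient
  statistics so each objective call is $O(1)$ in the data. The ZTB fit is
  Brent's method (absolute tolerance $10^{-6}$) with the likelihood
  aggregated over distinct trial counts. The gamma GLM is a 3-parameter
  bounded quasi-Newton fit warm-started from the previous EM iterate;
  per-motif slopes use Brent on $[-10, 10]$ (tolerance $10^{-5}$).
* **Initialisation.** Uniform initial state distribution per interval
  (intervals begin at low-coverage boundaries, so a stationary solve is
  unnecessary); LTG moments from a split at the weighted median density;
  $p_0 = 0.01$, $p_1 = 0.2$; transitions 0.9 self / 0.1 split off-diagonal.
  Label switching is prevented by reordering states after each M-step so
  that $\mu_1 > \mu_0$ and $p_1 > p_0$.
* **Partial-likelihood M-step.** Because the emissions are fitted only to
  positions with read starts (by design, to avoid the mass of empty
  positions), the EM objective and the full-data likelihood differ
  slightly; on sparse data the total log-likelihood can dip by a small
  amount late in a run. On data where every position carries a read start
  the algorithm is exact EM and the trace is monotone (asserted by tests).
  Convergence is therefore judged on the absolute change, not the sign.
* **Degenerate cases.** Constant fit data raises an error rather than
  letting $\lambda \to \infty$; a constant covariate pins the GLM slope to
  zero with a warning; a state receiving no posterior mass keeps its
  parameters; fits on the probability boundary are flagged.
* **Motif windows.** Discovery windows are centre-anchored: a 10-nt window
  centred on the called site, controls centred 20 nt up- and downstream;
  windows clipped by chromosome ends are dropped. The PWM scanner scores
  $\log_2(\mathrm{pwm}/\mathrm{bg})$ on the sense strand only and keeps
  hits with exact-null p-value $\le 0.01$ and positive score; the exact
  null is the convolution of per-column score distributions under the
  background, so the internal scanner and ingested FIMO output are
  interchangeable.

## The simulator

`simulate_clip()` emulates the experimental workflow on a synthetic
transcriptome (non-overlapping transcripts, log-normal abundances standing
in for RNA-seq input): fragment lengths are Normal(165, 50) resampled to be
positive; binding regions (8 nt, minimum spacing 300 nt, placed
proportional to abundance) carry 1–4 uniformly drawn crosslink sites;
region-overlapping fragments are pulled down at a configurable rate
(1.0 or 0.5 in the standard settings); reads truncate at an in-fragment
crosslink with probability 0.7, at a random other in-fragment position
with probability 0.1, and otherwise start at the fragment 5' end; size
selection keeps fragments of 30–140 nt inclusive. Background-protein
regions run through the same machinery with per-region rates drawn from
U(0.1, 0.5) (pull-down) and U(0.2, 0.7) (truncation) — configurable
ranges, since only the fact that they vary is prescribed — and 1% of the
fragment pool is added as untruncated noise reads. If the at-crosslink
branch fires but no crosslink of the region lies inside the fragment, the
read is left untruncated rather than resampled, which would distort the
pull-down fraction.

What the simulator does **not** emulate: base-level sequence (no
sequencing errors, qualities or adapter content), mappability, splicing,
PCR duplication, or diagnostic events other than truncation
(mutations/deletions of other protocols). Passing tests on simulated data
therefore demonstrate correctness of the statistical machinery under the
model's own assumptions, not robustness to every artefact of real
libraries.

## Problem sizes used by the checks

The test-suite and the acceptance script size their simulations so the
whole battery runs comfortably on a single core: distribution
normalisation by quadrature/summation on randomised parameters; exact
forward–backward against brute-force path enumeration on chains of up to
8 positions; EM monotonicity on a $10^5$-position model-generated chain;
parameter recovery (all six emission parameters within 5% relative error)
on $10^6$ positions in the tests and $2 \times 10^5$ in the acceptance
script; covariate recovery on $10^5$ sites; simulator fidelity at
$10^4$–$10^5$ draws (three Monte-Carlo standard errors); and an
end-to-end gate requiring at least 80% of simulated crosslink positions
to be recovered on a high-signal dataset (pull-down 1.0, homogeneous
transcript abundances so every region is covered at the $\ge 50\times$
level the gate presumes).

## Limitations

* Transition probabilities are homogeneous along the genome; covariates
  act on emissions only.
* The enrichment dimension is learned from the data's own density mixture;
  when coverage is strongly heterogeneous across transcripts (no input
  control supplied), weakly covered binding regions can fall below the
  enriched state's reach — exactly the failure mode the input-control GLM
  is meant to correct.
* Binding-region output is a distance-based merge of called sites, not a
  segmentation in its own right.
* The evaluation helpers implement exact-position matching; no slack is
  given for 1-nt offsets beyond what the respective rule defines.
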