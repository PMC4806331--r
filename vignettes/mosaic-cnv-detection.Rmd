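---
title: "Detecting organ-private mosaic CNVs from dual-platform SNP arrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting organ-private mosaic CNVs from dual-platform SNP arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mosaicnv)
```

## The problem

Somatic mosaicism — genetically distinct cell populations within one
individual — can be read out at the copy-number level by assaying several
organs of the same person and asking which copy-number variants (CNVs) are
*organ-private*: present in exactly one organ. A CNV found in every organ
is constitutional (germline); one found in a strict subset is mosaic, and
one confined to a single organ is the operational signature of a
post-zygotic event in that organ's lineage. The analytically delicate part
is that mosaic events live in a fraction of cells, so their array signal
is attenuated, and single-platform artefacts readily masquerade as somatic
events. `mosaicnv` implements a deliberately stringent design: every
sample is assayed on **two array platforms of different marker density**,
and only events concordant between the platforms survive.

One organ is special. The thymus of any T-cell-competent individual
carries genuine, physiological somatic deletions: V(D)J recombination
removes DNA inside the T-cell receptor loci (TCRG, TCRD, TCRB, TCRA) in
every T-cell clone. Because the thymus is polyclonal, no single breakpoint
dominates; instead the per-position deleted cell fraction is a step
function — the sum of the cell fractions of all clones whose deletion
covers that position. The simulator models this explicitly, and the
calling pipeline annotates calls overlapping configured TCR intervals so
that physiological rearrangements can be separated from pathological
mosaicism.

## Signal model

Per probe the simulator and the segmentation model share one dosage
model. If a fraction $f$ of cells carries $c$ copies of a segment (the
rest being diploid), the expected log2 ratio is

$$L(c, f) = \log_2\frac{2(1-f) + c\,f}{2},$$

floored at $-5$ to keep a clonal homozygous deletion finite. A clonal
heterozygous loss gives $L = -1$; a 50% loss gives $\log_2 0.75 \approx
-0.415$. Inverting the model for single-copy events yields the mosaic
fraction estimate $f = 2 - 2^{1+L}$ (loss) or $f = 2^{1+L} - 2$ (gain)
that the pipeline reports per call; multi-copy events are clipped to 1
rather than solved.

The B-allele frequency (BAF) channel uses standard allelic-dosage
algebra. Diploid SNPs sit in bands at $0, 0.5, 1$ (genotypes drawn
AA/AB/BB at 0.25/0.5/0.25). Under a one-copy loss at fraction $f$ the
heterozygous band splits to $0.5(1-f)/(1-f/2)$ and its mirror; under a
one-copy gain to $1/(2+f)$ and $(1+f)/(2+f)$; homozygous bands stay at
0/1. A clonal homozygous deletion leaves no genotype signal and emits
uniform BAF. Because the physical B allele is arbitrary marker to marker,
each het probe picks a side of the split at random.

## Quality control

Two per-sample gates, both inclusive:

* **MAPD** — the median absolute difference of consecutive log2 ratios
  (never across a chromosome boundary). For i.i.d. Gaussian noise of sd
  $\sigma$, MAPD $= \sigma\sqrt{2}\,\Phi^{-1}(0.75) \approx 0.954\sigma$;
  the pipeline also uses this identity in reverse to estimate each
  sample's noise for segmentation. MAPD is robust to true CNVs — a
  variance-based metric over large windows is not, which is why no such
  metric is used here. Default gate: MAPD $\le 0.25$.
* **SNPQC** — genotype-cluster separation: SNP BAFs are assigned to the
  nearest of the $\{0, 0.5, 1\}$ bands and the score is the minimum over
  adjacent band pairs of $|\Delta\text{mean}|/\text{pooled sd}$ (sentinel
  $10^6$ when a pooled sd is exactly zero). The exact vendor formula is
  proprietary; this definition keeps its monotone behaviour (it decreases
  in BAF noise, which the tests check). Default gate: SNPQC $\ge 15$. On
  uniform BAF the definition evaluates to $\approx 3$, far below any
  passing sample.

## Segmentation

Each sample is segmented per chromosome by a hidden Markov model whose
emissions combine a Gaussian log2 term (mean $L(c,f)$ per state) with the
state's BAF band mixture; copy-number-only probes contribute the log2
term alone. The state set is CN0–CN4 plus a copy-neutral allelic
imbalance/LOH state, with CN1 and CN3 expanded over a mosaic fraction
grid $\{0.2, 0.4, 0.6, 0.8, 1.0\}$ — a pure-clonal state set cannot
represent subclonal events, and the reported `event_type` collapses the
sub-states back to loss/gain. The AI/LOH state has log2 mean 0 and
mirrored het bands at $0.5 \pm \{0.15, 0.35\}$, covering moderate to
strong imbalance.

Numerical choices, made once:

* **Transitions**: leaving the current state costs probability
  $\tau = 10^{-6}$ per probe, shared uniformly among the other states —
  a strong persistence prior appropriate at high marker density. Raising
  $\tau$ can only increase the number of segments, which is tested.
* **Decoding**: hard Viterbi (implemented in C++ for the inner loop) with
  ties broken toward the diploid state, for determinism. The decoder is
  checked against exhaustive path enumeration on small instances.
* **Boundaries**: segment bp coordinates are midpoints between adjacent
  probes of differing state (chromosome ends for terminal segments), so
  that coordinates are platform-independent — a prerequisite for
  cross-platform reciprocal overlap.
* **Degenerate input**: a chromosome with fewer than two probes emits a
  single diploid segment with a warning.
* A median-centering pre-step exists but is off by default; simulated
  data are centred by construction.

## The calling cascade

Per platform and sample: segments spanning fewer than `min_probes`
consecutive markers are removed (50 in the primary analysis, 10 in the
relaxed secondary analysis; the bound is inclusive), allelic
imbalance/LOH segments are removed (they are not copy-number variants),
and directly adjacent segments of the same type are merged. The filter
runs before the merge, following the stage order of the exported-segment
workflow the pipeline emulates.

Cross-platform validation then pairs, within each (patient, organ), the
two platforms' surviving segments: a pair must share chromosome and event
type and pass **50% reciprocal overlap** — the overlap must cover at
least half of *each* segment, so a large artefact cannot validate a
fragment. Matching is one-to-one, greedy by descending overlap product
with deterministic leftmost tie-breaks. The validated call's interval is
the **intersection** of its two supports — conservative where the choice
was open.

Sharing classification is a pairwise all-organ intersection: a call is
*germline* iff every other assayed organ of the patient has a same-type
call passing reciprocal overlap with it, *private* iff none has, and
*shared-mosaic* otherwise. The pairwise rule is order-invariant (a
base-level multi-way intersection would not respect reciprocity) and
requires matching event types. With a single assayed organ, sharing is
undefined and calls are left unclassified.

Finally, calls overlapping a configured TCR locus by at least 1 bp are
annotated with the locus name, and per-call mosaic fractions are
estimated from the averaged support log2.

## What the simulator emulates — and what it does not

`simulate_cohort()` generates, for each (patient, organ), one sample per
platform: platforms share the embedded truth but have independent probe
maps (made disjoint by construction, as physical markers differ),
independent noise, and independently drawn genotypes. Defaults are chosen
once to represent the study conditions at desk scale:

* two platforms of 62,000 and 100,000 markers (the 2.67M : 4.3M density
  ratio of the real array pair, scaled down) over a three-chromosome
  150 Mb toy genome carrying all four TCR loci;
* `noise_sd = 0.21`, putting MAPD at $\approx 0.20$, below the 0.25 gate;
  `baf_sd = 0.025`, putting SNPQC near 20 — above the 15 gate even in
  samples whose genuine CNVs inflate the heterozygous cluster. The source
  study does not state platform noise levels, so these are calibrated
  only to sit on the passing side of the vendor-style gates;
* germline events at cell fraction 1 in all organs; mosaic events
  confined to stated organ sets at stated fractions;
* thymus TCR clone mixtures: each clone deletes one copy of a uniformly
  drawn sub-interval of its locus (minimum width 5 kb, echoing the
  smallest rearrangements such a pipeline should resolve), and the
  per-probe deleted fraction is the sum of covering clone fractions.

Not modelled: vendor raw formats, GC waviness and batch artefacts,
probe-specific response, polyploidy, and overlap resolution between
embedded events (overlapping event specifications are an error). Passing
tests therefore demonstrate correctness of the calling logic under an
idealised noise model, not robustness to platform-specific artefacts of
real arrays.

## FISH aneusomy scoring

Interphase FISH counts are scored two ways. The single-probe **aneusomy
index** is the fraction of nuclei with a non-disomic count; with
per-probe error rate $e$ it carries $e$ as irreducible background. The
dual-probe rule scores two same-chromosome probes per nucleus: $(2,2)$ is
disomic, equal non-disomic counts $(k,k)$ are true aneusomy, unequal
counts are technical noise. Under independent per-probe errors the false
true-aneusomy rate falls to the sum of squared per-direction error rates
(e.g. $\approx 0.0017$ at $e = 0.05$) while the noise category absorbs
$2e(1-e)$ — the model-level reason dual-probe scoring separates genuine
aneusomy from single-probe artefact. Counts above 5 are binned to 5
before classification; the expected count is fixed at 2 (autosomes).
Tissue noise rates are compared by Fisher's exact test (two-sided by the
"probability not exceeding the observed table" convention).

## Statistics

Per-organ private-CNV rates between cohorts (e.g. against an adult
reference of ~2.2 somatic CNVs per organ) are compared with a two-sided
Mann-Whitney U test using exact enumeration of the permutation
distribution (midranks for ties) up to combined $n = 20$ and the normal
approximation with tie correction beyond; the two-sided p is twice the
smaller tail, capped at 1. The exact path is enumerated in-package
because the count data are heavily tied, which rules out the standard
exact algorithms that assume no ties.

## Problem sizes used by the tests and the acceptance script

All verification runs are synthetic and sized for a desktop: repeated
end-to-end cohorts use the default platform pair scaled to 30–60%
(19k–60k markers per sample), 1–2 patients with three organs each, and
10–20 seeds per property; detection-power and fraction-recovery curves
use a single 20 Mb chromosome with 2,000 markers and 200-probe events;
oracle checks run on instances small enough for exhaustive enumeration
(per-base interval painting below $10^4$ bp, all $3^n$ Viterbi paths for
$n \le 12$, all rank arrangements for combined $n \le 8$). The defaults
of the generator itself are the full desk-scale study conditions above.

## Known limitations

* FASST2-style segmentation is emulated in role (joint log2/BAF HMM with
  mosaic sub-states), not reverse-engineered: the proprietary
  normalisation and calling thresholds of the commercial tool are not
  reproduced.
* The mosaic-fraction estimator assumes single-copy events; CN0/CN4
  calls get clipped estimates and a flagged interpretation.
* Breakpoint uncertainty is not quantified (no posterior intervals), and
  events below ~10% cell fraction are below the detection floor of the
  default noise level — consistent with the detection-limit claims such
  array designs make.
* The germline/private classification needs at least two organs passing
  QC on both platforms; organs missing a platform are skipped with a
  warning rather than rescued.

## A worked example

```{r example, eval = FALSE}
library(mosaicnv)
demo <- replay_demo(seed = 1)
demo
```

The demo generates five patients over eight organ types, embeds germline
CNVs in all organs and polyclonal TCRG/TCRD (plus one TCRB) deletion
mixtures in three thymus samples, runs the full pipeline at the 50- and
10-probe thresholds, and prints the private calls (all thymus TCR-locus
losses, with their estimated aggregate cell fractions), the candidate
bookkeeping at both thresholds, and the Mann-Whitney comparison of
non-thymus private-CNV rates against a Poisson adult reference.
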