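---
title: "Methods: dead-time initiation, burden signatures, and their statistics"
author: "burdenlab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dead-time initiation, burden signatures, and their statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(burdenlab)
```

# The scientific question

Cells forced to over-express a useless protein ("protein burden") grow
slower, get bigger, and broadly up-regulate transcription — yet their
most highly expressed genes fail to follow the global scale-up. This
package implements, on synthetic data with known ground truth, the
quantitative machinery needed to study one candidate explanation:
**transcription initiation has a hard rate ceiling**, set by the time a
polymerase needs to clear the promoter before the next one can start.

# The dead-time initiation model

A promoter receives stochastic initiation *attempts* as a Poisson
process with rate $a$ (attempts/s). An attempt succeeds only if at
least $\tau$ seconds — the *dead time* — have passed since the last
**successful** attempt. The dead time is *non-paralyzable*: the clock
restarts only on success, never on a failed attempt. This follows
directly from the physical picture (a failed attempt does not place a
polymerase on the DNA), and a paralyzable variant is deliberately not
implemented. The first attempt of a run always succeeds (empty
history); over the durations used here ($10^4$–$10^5\,\tau$) this edge
rule is negligible.

Renewal theory gives the mean successful-initiation rate in closed
form: intervals between successes are $\tau$ plus an $\mathrm{Exp}(a)$
wait, so

$$ r(a) \;=\; \frac{a}{1 + a\tau}, $$

rising linearly at small $a$ and saturating at $1/\tau$. The package
carries both the closed form (`analytic_effective_rate()`) and an
event-level simulator (`simulate_initiation()`); their agreement across
$a\tau \in [10^{-2}, 10^2]$, within renewal-CLT standard errors, is the
central cross-check of the test suite. Simulation variance is assessed
with the renewal formula
$\mathrm{SE}(r) = a^{-1}\,(\tau + 1/a)^{-3/2}\,T^{-1/2}$ rather than
re-estimated empirically.

The geometric ceiling itself comes from polymerase geometry:
`clearance_time(35, 2000)` divides the ~35 bp DNA footprint by a 2
kb/min elongation velocity, giving **1.05 s per transcript** (a maximal
rate of ~0.95/s). The literature sometimes rounds this quantity to
"~1.2 s"; the discrepancy (an effective clearance distance slightly
larger than the footprint would explain it) is noted but not resolved —
the function returns the literal quotient.

Burdened cells are modeled as raising the *global* attempt frequency by
a capacity factor $g \ge 1$ while $\tau$ is fixed. Each gene's
expression then changes by

$$ \frac{r(ga)}{r(a)} = \frac{g(1 + a\tau)}{1 + g a\tau} \in [1, g], $$

which equals $g$ for rarely transcribed genes and approaches 1 for
genes near saturation (`burden_fold_change()`). This single decreasing
function of $a$ is what produces the burden expression signature.

An optional two-state (telegraph) promoter layers bursting on top:
attempts are thinned to ON periods. It exists for the qualitative
property (bursting lowers the effective rate at equal attempt rate);
no closed form is provided for it.

# The synthetic study conditions

`sim_config()` fixes the conditions all generators share. Defaults were
chosen once, to emulate the burden-library setting, and are not tuned
per analysis:

* **Copy numbers 0–20** (strains at 0, 2, 5, 10, 15, 20 tandem
  reporter copies), with **growth slope 0.015/copy** (−30% growth at 20
  copies) and **size slope 0.025/copy** (+50% size at 20 copies) —
  the linear phenotypes of tandem-integration burden libraries.
* **Capacity slope 0.0375/copy**, so the 20-copy strain has
  $g = 1.75$ — matching the ~75% total-mRNA-per-cell increase measured
  in heavily burdened cells by spike-in calibration.
* **Dead time 1.05 s**, the geometric clearance quotient.
* **Attempt-rate spectrum**: log-normal with $\log$-mean $\log(0.02)$
  and $\log$-sd 2. The median gene sits far from saturation
  ($a\tau \approx 0.02$) while the upper tail reaches and exceeds
  $a\tau \sim 1$ — mirroring the wide initiation-rate range inferred
  for yeast, where only highly expressed genes approach the ceiling.
* **TATA fraction 0.2**, flagged by sampling from the top attempt-rate
  quantile: the package's proxy for the association of TATA promoters
  with bursty, high-rate transcription. No separate generative
  mechanism for TATA regulation is claimed.
* **Measurement noise**: multiplicative log-normal per gene × sample,
  sd 0.2 in log2 units — a typical replicate spread for bulk RNA-seq.
  No noise model is asserted beyond this.
* **mRNA decay 1/600 s⁻¹** for all genes, so abundance is proportional
  to initiation rate. Decay variation would decouple the abundance
  axis from $a$ and dilute (not create) the signatures below.

Library expression uses the **analytic mean-field rate**, not
event-level simulation: fixture generation is deliberately separated
from the model under test, and the simulator is checked against the
same closed form independently.

What the generators do *not* emulate: real genome annotation and
sequence, mapping artifacts, batch effects, replicate structure,
decay-rate regulation, and any transcription-factor-specific response.
Passing tests therefore demonstrate the internal consistency and
statistical power of the *methods*, not biological conclusions about
real strains.

# Expression-signature statistics

**Normalization.** `normalize_log2()` divides each gene by its mean
within each condition and log2-transforms. For relative comparisons
between strains, `relative_abundance()` normalizes each sample to sum
1, so a pure global scale-up reads as zero change — the "relative
expression" framing under which the burden signature is defined.

**Growth-rate response $E_g$** (`growth_response()`): the per-gene OLS
slope of log2 expression on relative growth rate, with residual-based
standard errors; genes with fewer than three informative samples are
omitted and logged. Slopes are computed vectorized for complete rows
and by per-gene fits otherwise.

**Expression-dependent bias $\delta$** (`expression_bias()`): the OLS
slope of a strain's log2 relative change versus **log10** wild-type
abundance (the plotted abundance scale is not stated in the field's
figures; log10 is declared here and the units — log2 per decade — are
reported with it). Fits are unweighted and untrimmed; subsets (TATA /
non-TATA) are fit separately. With a dead time, $\delta < 0$ and
$\delta(\mathrm{TATA}) < \delta(\text{non-TATA})$; with $\tau = 0$,
$\delta = 0$ up to noise.

One numerical subtlety is handled deliberately: the abundance axis is
the **noise-free reference abundance** (`wt_reference_abundance()`),
not the measured wild-type sample. Using the same noisy measurement on
both axes induces a spurious negative slope (regression of $y - x$
noise on $x$), which would fake the signature at $\tau = 0$. A real
study has the analogous option of an independent wild-type reference
dataset.

**Compendium correlations.** `signature_correlation()` uses
pairwise-complete Pearson correlation over shared genes (≥ 3 required,
n reported). `burden_growth_plane()` correlates each mutant signature
with the burden $E_g$ profile and with the growth program; when several
condition-specific profiles are supplied the per-condition correlations
are averaged arithmetically. Capacity mutants ($g < 1$) separate from
slow-growth-only mutants along the burden axis; by the closed form
their fold change $g(1 + a\tau)/(1 + ga\tau)$ *increases* with $a$ for
$g < 1$, so their per-mutant $\delta$ is positive — the mirror image of
the burden signature.

**Ranking and enrichment.** `top_bottom_sets()` ranks by $E_g$ with
lexicographic gene-id tie-breaks (declared, so results are
reproducible). `enrichment()` is the one-sided hypergeometric tail via
`phyper`, Benjamini–Hochberg adjusted (`p.adjust`); no particular
multiple-testing procedure is canonical here, BH is the package's
choice. The suite verifies exact agreement with exhaustive enumeration
for all universes up to 12 genes.

**GFP library.** `gfp_ratio_trend()` takes gated median GFP per protein
under high and low burden, excludes proteins below the
autofluorescence threshold (default 200 A.U.; both medians must clear
it), reports per-protein ratios, their mean percentage increase, and a
`lowess` trend versus log10 control abundance (span 0.3, 2 robustness
iterations — the smoother is named by the field, its parameters are
this package's defaults).

# Fitness and epistasis

`generations_from_dilution()` is $\log_2$ of the dilution factor.
`competition_fitness()` fits the **log2 odds** of the wild-type
frequency against generations: under constant selection log-odds are
exactly linear while log-frequency is not, so the slope is the
per-generation advantage with no approximation. The field's phrasing
("slope divided by log 2") is ambiguous; the interpretation — the
fitted log2-scale slope *is* the advantage — is isolated in
`advantage_from_slope()` so it can be swapped. Fixed frequencies (0 or
1) are excluded with a message. `burden_per_copy()` fits relative
division rate on copy number; the per-copy fitness is $1 + S$.

`scaled_epistasis()` implements
$\tilde\varepsilon = (w_{xy} - w_x w_y)/|\tilde w_{xy} - w_x w_y|$ with
$\tilde w_{xy} = \min(w_x, w_y)$ on the positive side (buffering
saturates when the double mutant matches the better single — the
appropriate bound when one perturbation, the burden, is mild) and
$\tilde w_{xy} = 0$ on the negative side (aggravation saturates at
synthetic lethality), giving $+1$ / $-1$ at the bounds and 0 on the
multiplicative surface. The negative-side bound is not spelled out in
the field's formulation, which defines $\tilde w_{xy}$ only for
$w_{xy} > w_x w_y$; the lethality bound is the standard completion.
Out-of-range values from noisy fitness estimates are clamped to
$[-1, 1]$ with a warning.

# ChIP track processing

Coordinates are 0-based, half-open throughout (BED convention). The
processing chain follows the standard background-removal recipe:

1. `estimate_fragment_length()`: the shift best aligning plus- and
   minus-strand read-start profiles (raw cross-correlation; ties to the
   smallest shift). With fragments of span $L$ the strand modes are
   $L - 1$ apart, so the estimate carries a one-base convention; the
   pipeline's ±5 bp accuracy makes this immaterial.
2. `extend_reads()`: plus starts cover $[p, p+L)$, minus starts
   $(p-L, p]$; implemented as cumulative-sum window sums, truncating at
   contig ends.
3. `normalize_subtract()`: scale to 1,000,000 reads; compute the mean
   coverage over **background** positions — the complement of the gene
   signal regions (TSS − 500 bp to TTS, strand-aware, merged when
   overlapping) on the genome contigs, computed genome-wide rather than
   per contig; subtract it from *every* position including the plasmid
   contig (which belongs to neither signal nor background); clip
   negatives to zero. The output's read total is set to $10^6$, making
   the operation idempotent once the background is zero.
4. `promoter_binding()`: per-gene mean over each gene's own signal
   interval (merging affects only the partition, not the means).
5. `plasmid_occupancy()`: plasmid read share of **raw** read counts —
   the fraction of the profiled factor sitting on the burden construct.

Clipping in step 3 biases residual background slightly above zero
(folded noise); at the default background rate this residue is below
1% of promoter signal, which the acceptance suite checks.

# Spike-in calibration of total mRNA

With a constant amount of *S. paradoxus* mixed into every sample,
`total_mrna_per_cell()` computes
$(\text{cer reads}/\text{par reads})/\text{cells}$ — depth-invariant,
comparable across samples of one experiment. Cell counts refer to the
mixed aliquot. `condition_summary()` reports mean ± SE per condition;
`flag_spike_outliers()` flags samples whose spike recovery deviates
> 3 MAD from the batch (QC only; the flag never enters the
estimator). Cross-mapping between species is out of scope for the
estimator and absent from the generator by default.

# The critical-size growth model

`critical_size_curve()` formalizes a verbal allocation argument as a
piecewise model — this specific functional form is this package's own
formalization, and is labeled as such. A fixed proteome fraction is
ribosomal, so ribosome count grows with protein content $P$; the
transcriptome can employ at most
$C = \text{mRNA count} \times \text{max ribosomes per transcript}$
ribosomes. Growth is $\mu_{\mathrm{opt}}$ while $R(P) \le C$ and
$\mu_{\mathrm{opt}} C / R(P)$ beyond, giving a plateau, a critical
content $P^*$ (linear in mRNA count), and $\mu_{\mathrm{opt}}/2$ at
$2P^*$. Stored default constants (35,000 transcripts; 8 ribosomes per
transcript) are documented literature round numbers — the quotient
200,000/35,000 is actually ≈ 5.7, and the constants are carried as
cited, not re-derived.

# Problem sizes and reproducibility

Analyses and tests run at sizes where every statistical check has
comfortable power: libraries of 300–2000 genes, initiation simulations
of $10^4$–$10^5\,\tau$ (renewal SEs of 0.1–1%), ChIP tracks of
$10^5$ reads over ~120 genes, spike-in depths of $10^5$–$10^6$. Every
generator is a pure function of its config and seed (RNG state is
saved and restored), so identical configs give byte-identical outputs;
grid simulations use `seed + index`.

Known limitations: no polymerase traffic or elongation dynamics along
the gene body; no mRNA decay dynamics in the initiation module; no
per-gene absolute quantification in the spike-in module; enrichment
takes gene groups as given; the telegraph promoter has no analytic
treatment. The numbered scripts under `analysis/` run the full
pipeline and write their tables under `results/`.
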