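---
title: "Decomposing composite Sanger traces into indel spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing composite Sanger traces into indel spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tracedec)
```

## The measurement problem

A targeted nuclease cuts one genomic site in a pool of cells; error-prone
end-joining repair converts the double-strand break into a mixture of alleles
— mostly short deletions, more rarely short insertions, centred on the break.
A capillary sequencing read of the bulk PCR product is a faithful single
sequence up to the cut, and a *superposition* of the allele signals after it:
each allele's downstream sequence is shifted by its net indel size, so the
four-channel peak signal at every downstream position is a mixture whose
weights are the allele frequencies.

`tracedec` inverts this superposition. The observable it works with is not
the called base string but the per-position, per-channel peak heights, which
carry the quantitative mixture information.

## Model and fitting procedure

**Signal fractions.** Each trace's $N \times 4$ peak-height matrix is
normalised row-wise: position $i$ of a trace becomes the vector of channel
fractions $f_{ib} = h_{ib} / \sum_{b'} h_{ib'}$. Per-row normalisation makes
the analysis invariant to overall amplitude, to signal decay along the read,
and to any per-trace rescaling applied by base-calling software — which is
also why it is immaterial whether raw or vendor-normalised peak heights are
supplied. Rows whose channel sum is zero (late-read dropout) are masked and
excluded from fitting rather than treated as errors.

**Break-site location.** The 20-nt guide and its reverse complement are
aligned to the control called bases by Smith–Waterman local alignment
(match +2, mismatch −1, a gap of length $L$ costs $5 + 2L$; an exact guide
match scores 40). The blunt cut is placed 3 bp 5′ of the PAM — between
protospacer positions 17 and 18 — mapped through the matched orientation.
This convention is the canonical SpCas9 geometry; note its consequence that
searching with the reverse complement of a guide designates the
opposite-strand protospacer and moves the cut by 14 bp, since the PAM then
sits on the other side. Matches are accepted at ≥ 90% identity; an identity
tie between orientations, or a tied best ungapped match at two positions
(repetitive target), is reported as "guide not found" rather than resolved
arbitrarily. The control↔sample coordinate offset is estimated the same way
from the up-to-100-bp control region immediately 5′ of the cut, which
editing cannot have altered; a poor probe match (< 90%) almost always means
swapped or unrelated samples and is an error, not a warning.

**Decomposition window.** Fitting is restricted to
$[\,\mathrm{cut} + n + 5,\ \min(L_c,\ L_s - \mathrm{offset}) - (n+5)\,)$
where $n$ is the largest modelled indel. The left margin guarantees that for
any insertion up to $+n$ every window position of the shifted model is
determined by *known* control sequence (the unknown inserted bases stay left
of the window); the right margin keeps every shifted model inside both
reads. A window shorter than $10(2n+1)/4$ positions is refused — below
roughly ten observations per free coefficient the fit is not worth
reporting. The window can be overridden, e.g. to steer around a locally
noisy stretch.

**Shifted-trace models and the fit.** For each indel size
$k \in \{-n..n\}$ a model column is built from the control fractions: at
window position $i$ the model presents the control row at $i - k$ (so a
deletion of $d$ reads $i + d$, an insertion of $k$ reads $i - k$). The four
per-base vectors over the window are concatenated — block order A, C, G, T —
into a column of length $4W$, and the analogous concatenation of the sample
fractions (shifted into the control frame by the offset) forms the
observation vector $y$. The frequencies are estimated by non-negative least
squares (Lawson–Hanson active set, via `pracma::lsqnonneg`):
$\hat c = \arg\min_{c\ge 0} \lVert y - Mc \rVert^2$.

**Inference.** $R^2 = 1 - \mathrm{RSS}/\mathrm{TSS}$ with TSS about the mean
of $y$ — the ordinary definition. Standard errors are taken from the
*unconstrained* linear model's variance–covariance matrix
$\hat\sigma^2 (M^\top M)^{-1}$, $\hat\sigma^2 = \mathrm{RSS}/(4W - (2n+1))$,
evaluated at the NNLS solution, with two-tailed $t$ p-values on
$4W - (2n+1)$ degrees of freedom. Coefficients estimated at the zero
boundary get $p = 1$: the NNLS active set provides no evidence for them, and
assigning the unconstrained p-value there would overstate significance. This
boundary rule is a deliberate conservative choice — the standard theory does
not cover active-set estimates — and is the reason absent indels report
$p = 1$ rather than values near it. The default detection threshold
$\alpha = 0.001$ is strict on purpose: $2n+1 = 21$ sizes are tested
implicitly and no formal multiplicity correction is applied.

**Rescaling.** The reported percentages are the coefficients multiplied by
the single constant that makes their sum equal $R^2$ (×100). This absorbs
systematic intensity differences between the two sequencing runs. The
wild-type coefficient is rescaled along with all others — the alternative
(renormalising to exactly 100) would silently hide unexplained signal —
so the percentages sum to $100 R^2$ exactly and the unexplained mass
$100(1 - R^2)$ remains visible. Total editing efficiency is the summed
percentage of all nonzero indel sizes.

**+1 insertion base.** Only for single-base insertions is the inserted
nucleotide identifiable: at the first position 3′ of the cut, every
non-insertion allele presents a *known* control base (the wild type shows
the cut-adjacent base, a deletion of $d$ shows the base $d$ further
downstream), so their aggregate expected signal can be subtracted from the
observed sample fractions. Insertions of ≥ 2 bases, whose first inserted
base is unknown, contribute a flat ¼ per channel; since their fitted
coefficients are typically small this approximation is second order. The
clipped (at zero), renormalised residual is the composition estimate. It is
only reported as supported when the fitted +1 frequency reaches 1%, the
practical detection floor; the inference uses the single first post-cut
position, the only one where the inserted base is unambiguous. Base
composition of larger insertions is out of scope.

## Quality rules of thumb

Three conditions flag a decomposition for caution (they warn, they do not
abort): mean pre-break aberrant signal ≥ 10% in either trace (dirty
template, failing read or impure PCR product); $R^2 \le 0.9$; and an
aberrant signal that fails to rise at the expected cut
(post-break − pre-break mean < 2 percentage points) while > 5% editing is
reported, which usually indicates a mis-located break site or the wrong
guide. The aberrant signal at a position is one minus the signal fraction of
the control-called base; it saturates near 75% for a fully edited pool
because a random aberrant base coincides with the reference one time in
four.

## The synthetic-data generator

The generator exists so that every stage — file IO, alignment, windowing,
fitting, insertion calling — is testable end to end with known ground truth.
`render_trace()` renders one allele: position $i$ (0-based) carries
amplitude $A e^{-ri}$ in the called channel, a crosstalk fraction leaked
uniformly into the other three channels, and independent multiplicative
lognormal noise (unit mean, coefficient of variation `noise_cv`) per channel
per position. `mix_traces()` sums the noise-free component matrices with the
allele weights — components aligned at their shared 5′ end, exactly as
co-amplified alleles sharing a sequencing primer superpose — and applies the
noise once, after mixing; called bases are the per-position channel argmax.
Multiplicative noise was chosen over additive because fluorescence noise
scales with signal; additive noise would swamp late-read decayed peaks.

Defaults: amplitude 1000 (arbitrary fluorescence units), decay
0.0015/position, `noise_cv` 0.05, crosstalk 0.02, emulating a clean modern
capillary run — under them a pure-control self-decomposition attains
$R^2 > 0.99$. These defaults are also the conditions under which the
package's sensitivity properties are measured.

What the generator deliberately does *not* emulate: peak shape and overlap,
mobility shifts, dye blobs, local re-phasing, quality collapse at the very
start of reads, or base-caller idiosyncrasies. Passing tests on synthetic
mixtures therefore validate the decomposition arithmetic and its statistical
behaviour under realistic noise — not robustness to every pathology of real
electropherograms, for which the quality rules above are the guard.

## Numerical and design choices

* **Coordinates** are 0-based half-open internally (uniform shift
  arithmetic); all user-facing output is 1-based.
* **Masked positions** (zero channel sum in either trace) are dropped from
  $y$ and from all model columns, consistently across the four base blocks.
* **Degenerate model sets**: a perfectly periodic control makes shifted
  columns coincide and $M^\top M$ singular. The fit still runs (NNLS does
  not require full rank); the affected indels get missing p-values and the
  result carries a warning, mirroring the practical advice that highly
  repetitive targets hamper decomposition.
* **Exact fits** (RSS = 0, noiseless simulations) give $\hat\sigma = 0$;
  positive coefficients then report $p = 0$ rather than NaN.
* **Called-base ties** in the generator's argmax resolve to the first
  channel in A < C < G < T order; with realistic noise levels ties occur
  only at exactly 50/50 mixtures of two bases.
* **Ambiguity codes** other than N in called bases are collapsed to N; calls
  are used only for alignment and display, never for fitting.
* **IO formats**: ABIF reading uses the analyzed channels DATA9–12, the
  FWO_1 channel order, PLOC2/PLOC1 peak locations and PBAS2/PBAS1 calls,
  sampling each channel at the recorded peak index (no windowed maximum —
  the simplest faithful reading). The package also reads SCF v3 and a
  tab-separated plain-text dialect (`pos base A C G T`, 1-based), chosen for
  diffability in tests; minimal ABIF and SCF emitters exist so round-trip
  fixtures are generated in code.

## Problem sizes used in the test-suite

The validation suite simulates 600–800-nt amplicons with the cut roughly
mid-read — the short end of the 500–1500 bp amplicons typical of this assay,
which keeps the suite quick while leaving a ≥ 350-position decomposition
window, comfortably above the minimum. Sensitivity properties are measured
as: +1 spike-ins at 20/10/5/2.5% across 20 seeds per fraction (detection
p < 0.001 within 2-fold in ≥ 90% of seeds, down to 2.5%); single indels of
sizes 1–10 at 2% frequency across 50 runs (≥ 90% detection); and 100 random
multi-indel spectra (mean absolute percentage error < 1.5 points, detection
of every component ≥ 2.5%). Forward- and reverse-strand decompositions of
the same simulated pool agree within 1 percentage point.

## Limitations

* One cut site, one guide; paired-nickase or two-guide excision designs are
  not modelled.
* Homology-directed repair products are not modelled: an HDR allele is
  whatever indel size its net length change implies, plus unexplained
  signal.
* Insertion base composition only for +1.
* Indels larger than `max_indel` fold into unexplained variance (lower
  $R^2$), not into the spectrum; raise `max_indel` if large deletions are
  expected, at the cost of a wider excluded margin around the cut.
* No PAM check is enforced at the matched guide position; the guide is
  trusted.
* Sanger-specific: the method needs clean single-peak signal upstream of the
  cut and breaks down when the pre-cut background approaches the 10%
  guideline.
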