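---
title: "Models and methods behind puredisplay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind puredisplay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(puredisplay)
```

`puredisplay` models the computational side of selecting synthetic
nanobody libraries by ribosome display in a reconstituted (PURE)
cell-free system. This vignette explains the models, the parameters that
matter, what the synthetic data emulate, and the numerical and design
choices a maintainer should know about. It states no empirical result
that the package's tests and acceptance script do not themselves compute.

## Library design

A synthetic nanobody library is defined by a constant framework scaffold
(FR1–FR4) and three randomized CDR loops. The scaffold is derived from an
alignment of published library frameworks by per-column majority vote:
columns that are gaps in a strict majority of rows are dropped, the modal
non-gap residue is taken elsewhere, and ties break alphabetically so the
consensus is a pure function of the alignment. (A single-row alignment
therefore returns the row with its gaps removed.)

CDR randomization follows a frequency-threshold rule: a candidate
position is fixed to its modal residue only if that residue's frequency
*strictly exceeds* the threshold — 30% for the flanking positions of
CDR1/CDR2, 50% for the first and last CDR3 positions in the reference
design. All other positions are randomized over 19 amino acids; cysteine
is excluded so randomized loops cannot introduce unpaired disulfides.

The phrase "first and last two amino acids … G, M, and G" for CDR1 names
three residues for what reads like four positions. Both readings are
supported; the default (`cdr1_fixed_layout = "GM_G"`) fixes positions 1,
2 and 10, giving 7 randomized CDR1 positions and the reference total of
23 randomized positions. The alternative (`"both_pairs"`) fixes four.

Theoretical diversity is `|alphabet|^k` with `k` randomized positions —
`19^23 ≈ 2.6 × 10^29` for the default scheme, beyond exact double
precision, so the package carries a small base-10⁴ digit-vector big
integer (`format()` gives the exact decimal expansion). Reverse
translation uses one preferred *E. coli* codon per residue, matching the
rare-codon avoidance of an expression-optimized gene synthesis; any codon
table can be supplied.

## Synthesis errors and library QC

Sequencing clones from a chemically synthesized library mostly reveals
single-nucleotide deletions, which frameshift the open reading frame. The
error model applies independent per-nucleotide deletions (rate `d`) and
optional substitutions. Sampling draws each clone's hit count binomially
and places hits uniformly — exactly equivalent to per-base Bernoulli
thinning, but fast for 10⁵-clone batches.

A clone passes QC only if it is in frame (length divisible by 3, no
internal stop), full length (translated length equals the design), and
framework-exact. Under pure deletions *any* deletion disqualifies: one or
two shift the frame, and an in-frame triple shortens the protein. Hence
the per-clone pass probability is `(1 − d)^L`, and the rate that
reproduces a target pass probability `p` for a 360-nt clone is
`d = 1 − p^(1/360)` (`calibrate_deletion_rate()`); `p = 2/3` gives
`d ≈ 1.1 × 10⁻³` per nucleotide. Compensating deletion pairs that restore
the frame are ignored — at these rates a clone with ≥ 2 deletions is
vanishingly rare and would fail the full-length check anyway. The
observed pass fraction is summarized with a Clopper–Pearson interval
(exact at the small n = 30 of a colony-sequencing batch). Internal stop
codons are counted as not in frame: such clones cannot yield full-length
protein regardless of reading frame arithmetic.

## Spacer scoring

The spacer gene tethers the nascent nanobody inside the ribosome exit
tunnel. In a PURE system there are no RNA helicases, so stable mRNA
secondary structure in the spacer stalls ribosomes and costs display
efficiency. The package scores structure propensity with a Nussinov-style
dynamic program: the maximum number of nested Watson–Crick (+ GU wobble)
base pairs with at least `min_loop` unpaired bases inside every
hairpin-closing pair. Defaults: `min_loop = 3` (the usual steric
convention) and wobble on, because the scored molecule is mRNA. This is a
combinatorial score, not a free-energy model: it ranks sequences by
pairing potential without Turner parameters or pseudoknots, which is all
the spacer comparison needs. `pairing_density` normalizes by `length/2`
(the maximum possible pairs) so spacers of different lengths compare
fairly; candidates are ranked by ascending density, then ascending GC.

One subtlety the test suite documents: maximum pairing is invariant under
reverse complement only for pure Watson–Crick pairing. With wobble
enabled the symmetry is broken by construction, because complementing a
G–U pair yields C–A, which cannot pair.

Windowed GC uses half-open 0-based windows internally, includes the final
partial window, and the overall GC equals the length-weighted window
mean.

## Quantification arithmetic

The arithmetic layer is deliberately plain: display efficiency is
`eluted/input` (≈ 4% for a structured, ~70% GC spacer; ≈ 20% for a
low-structure one); covering a library of diversity `D` with `c`
functional complexes per member at efficiency `e` needs `D·c/e` input
molecules (10¹¹ × 4 / 0.04 = 10¹³, rounded up with a relative-tolerance
guard so mathematically integral values do not creep past the next
integer in floating point); the chance a clone with mean complex count
`m` is displayed at all is the Poisson `1 − exp(−m)`. PCR quantification
assumes perfect doubling by default (`per_cycle_factor = 2`, matching
gel-based back-calculation `mass/2^cycles`); sub-exponential efficiency
is exposed as a factor in (1, 2]. `detection_cycles()` inverts the
doubling to the smallest cycle count reaching a detectable mass
(default 10 ng) and settles floating-point edge cases by explicit
adjustment, so it agrees exactly with brute-force doubling. Molecule
counts are held as doubles (magnitudes reach 10¹³); the spike-proportion
arithmetic divides back-calculated spike template mass by total template
mass without correcting for amplicon-length differences, mirroring how
such gel estimates are made in practice.

## Biopanning simulator

Each round thins every clone through explicit stages:

1. **Translation**: functional complexes ~ Binomial(copies,
   `display_efficiency × (1 − incubation_release)`). The
   `incubation_release` knob models complex drop-off during long
   translation incubations.
2. **Pre-incubation depletion** (optional): streptavidin-motif complexes
   are removed with the configured probability before target exposure —
   the countermeasure against HPQ/M-motif background binders that bind
   streptavidin's biotin pocket directly.
3. **Capture**: per class × surface probability. On Ni-NTA the
   streptavidin-motif class falls to baseline capture, which is why
   alternating surfaces breaks its enrichment.
4. **Washes**: each wash keeps a captured complex with its class's
   retention probability. Affinity is abstracted into these class-level
   retention/capture probabilities; no kinetic constants are modelled
   because selection-grade Kd values are not what class-level enrichment
   depends on here.
5. **Elution**: EDTA disassembles everything still captured;
   biotin-then-EDTA recovers target-bound and streptavidin-pocket
   complexes but leaves surface-stuck material behind (`discarded`).
6. **Amplification**: recovered molecules are amplified
   Poisson(`amplification_factor`, default 50 — the mRNA regeneration
   factor per round), and optionally the next round's input is
   regenerated at a fixed pool size with multinomial resampling,
   mirroring re-transcription to a constant input amount.

Within a round, pre-amplification counts satisfy exactly
`functional = depleted + flow_through + washed + eluted + discarded`;
with no depletion and EDTA elution the last two buckets are structurally
zero. Every sampling layer has an expectation twin (`mode =
"expectation"`) that propagates exact means — for a two-type
(spike/background) competition with per-round survivals `s` and `b` the
eluate spike fraction after `r` rounds is

> p_r = p₀·sʳ / (p₀·sʳ + (1 − p₀)·bʳ),

which expectation mode reproduces to machine precision and the sampler
matches in mean. Binomial and Poisson draws fall back to clamped normal
approximations above 2³⁰ expected counts, so full-scale populations do
not overflow R's integer samplers; full-scale (10¹³) campaigns are
intended for expectation mode, and stochastic resampling of a fixed pool
size is limited to sizes below 2³¹.

A per-round mutation option (off by default) splits a Bernoulli-drawn
variant record off each clone's amplified pool, modelling polymerase
errors during amplification that can produce variant binders.

## Scenario presets and calibration

The wash-survival and capture probabilities of real campaigns are not
measurable per class, so the shipped scenarios are calibrated fixtures,
not measurements:

* Display efficiency 0.04, two washes, target capture 0.9, target
  retention 0.85 per wash, background capture 0.2.
* The background wash retention is solved in closed form from the
  two-type formula above so the spike reaches 10% of the eluate at round
  4 from the scenario's own starting fraction (10⁻¹¹ full scale, 10⁻⁵
  scaled).

The scaled scenarios put 100 spike copies in a 10⁷ pool rather than
preserving the full 10²:10¹³ ratio at reduced totals: 100 copies × 4%
efficiency keeps the characteristic ~4 functional spike complexes per
round, whereas ten copies would make stochastic extinction of the spike
lineage the dominant outcome and defeat the purpose of a scaled
demonstration. The exact input ratio is preserved in the full-scale
preset, which expectation mode handles directly. Scaled stochastic runs
finish in well under a second per campaign; their round-4 spike fractions
scatter widely around the calibrated 10% because the early-round spike
complex counts are single digits — that scatter is a real feature of
spike-in tracking at these copy numbers, not simulator noise to be
averaged away silently.

The hFABP4-like preset adds HPQ/M-motif and surface-sticker background
classes and encodes the rescue schedule: pre-incubation depletion from
round 2 and a Ni-NTA surface in round 3. In round 1 the motif class
survives exactly as well as the target binder on a streptavidin surface —
which is precisely why the countermeasures exist, and why the strict
spike-monotonicity property applies to that preset only from round 2
onward.

## Synthetic data, and what passing tests do not show

Every fixture is generated in code under a seed: framework alignments (a
base sequence plus point variants; the true base is recovered by
consensus at almost all columns for 10 rows at 10% variation), CDR
frequency tables with declared modal residues at declared frequencies
(the remaining mass spread by a concentrated Dirichlet draw so no stray
residue approaches the modal one), spacers built to an exact GC target
either as a full-length inverted repeat (structured) or as a uniform
shuffle of the same composition, scenario presets, and ELISA plates with
a known number of true hits well separated from background.

These fixtures exercise every code path, but they are idealized:
real framework alignments have indels and correlated positions; real CDR
frequency tables come from structural databases with phylogenetic bias;
real spacer sequences are not extreme palindromes; real synthesis error
rates vary along the molecule; and real selection campaigns have
class-continuous affinity spectra rather than four discrete binding
classes. Passing tests therefore validate the arithmetic, the sampling
distributions and the bookkeeping — not the biology of any particular
library. The synthetic frameworks and spacers are explicitly labelled
synthetic and are not the published sequences.

## Numerical choices and problem sizes

* Consensus ties break alphabetically; gap-majority means strictly
  > 50%.
* Positions are 1-based in schemes and reports; window coordinates are
  0-based half-open internally.
* ELISA hit calling uses strict inequality at the ratio threshold, and
  control wells below 0.01 absorbance are flagged rather than divided by.
* The big-integer power uses square-and-multiply over base-10⁴ digits;
  only non-negative integers, multiplication and powers are implemented.
* Test and acceptance problem sizes were chosen so the whole suite runs
  in a couple of minutes on one core: 10,000 sequencing batches of 30
  clones for the QC sampling distribution, 500 random sequences ≤ 12 nt
  against the exhaustive pairing oracle, 10³ replicate campaigns for the
  sampler-vs-expectation comparison, and 10⁷-molecule scaled populations
  for stochastic panning.

## Known limitations

* The pairing score is combinatorial; it orders structure propensity but
  does not predict folds or free energies, and it ignores pseudoknots.
* The simulator's geometric round-over-round enrichment cannot reproduce
  campaigns whose first round behaves qualitatively differently from
  later rounds (e.g. a much larger first-round jump), short of per-round
  survival overrides, which the config structure allows.
* Compensating frameshifts and chimeric clones are outside the QC model.
* `required_input()` treats efficiency as scale-free; crowding effects
  (ribosome availability at 10¹³ molecules) are not modelled.
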