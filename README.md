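# puredisplay

Design, quality control and selection simulation for PURE ribosome display
of synthetic nanobody libraries.

Ribosome display in a reconstituted (PURE) cell-free system selects
nanobodies (VHH single-domain binders) by keeping each nascent protein
tethered to its own mRNA in a ribosome–mRNA–protein (RMP) ternary complex,
panning those complexes against an immobilized target, and amplifying what
elutes. `puredisplay` packages the computational layer of such a campaign
for people who design and troubleshoot these selections:

* **Library design** — derive a consensus framework from an alignment of
  published library scaffolds; fix CDR positions whose modal residue
  frequency exceeds a threshold (30% for the CDR1/CDR2 flanks, 50% for
  CDR3) and randomize the rest over the 19-residue cysteine-free alphabet;
  compute the exact theoretical diversity `19^k` (arbitrary-precision);
  sample clone sequences and reverse-translate them with preferred
  *E. coli* codons.
* **Library QC** — inject single-nucleotide-deletion synthesis errors (the
  dominant failure mode of chemically synthesized genes), classify clones
  as in-frame / full-length / framework-matched, and summarize the pass
  fraction with an exact Clopper–Pearson interval. Under pure deletions a
  length-`L` clone passes with probability `(1 − d)^L`.
* **Spacer evaluation** — windowed GC content plus a Nussinov
  maximum-base-pairing dynamic program (Watson–Crick + GU wobble, hairpin
  loops ≥ 3 nt) to rank spacer genes by secondary-structure propensity;
  GC-rich structured spacers stall ribosomes in a helicase-free PURE
  system and depress display efficiency.
* **Quantification arithmetic** — display efficiency `eluted/input`
  (about 4% with an M13 pIII spacer, about 20% with TolA), the coverage
  rule `input = diversity × complexes_per_member / efficiency`, the
  Poisson display probability `1 − exp(−m)`, and PCR doubling arithmetic:
  back-calculated template mass `mass/2^cycles`, spike proportions, and
  detection-cycle estimates.
* **Biopanning simulation** — a stochastic multi-round simulator over
  binding classes (target binders, streptavidin-pocket HPQ/M motif
  binders, surface stickers, nonbinders) with per-round surfaces, washes,
  pre-incubation depletion, EDTA vs biotin-then-EDTA elution,
  amplification and spike-in tracking — plus an exact expectation mode
  whose trajectories the sampler converges to. Molecule counts are
  conserved exactly within every round.
* **ELISA screening** — hit calling at a strict A450 target/control ratio
  threshold (default 1.9).

All fixtures (framework alignments, CDR frequency tables, spacers,
scenarios, plates) are generated synthetically in code; the package needs
no external data.

## Worked example

```r
library(puredisplay)

scheme <- default_library_scheme(seed = 1)
scheme
#> <library_scheme>
#>   protein length 120 aa (360 nt); randomized positions: 23
#>   ...
#> <cdr_scheme> CDR1: length 10, 3 fixed (1:G 2:M 10:G), 7 randomized over 19 residues
#> <cdr_scheme> CDR2: length 10, 4 fixed (1:A 2:I 9:T 10:Y), 6 randomized over 19 residues
#> <cdr_scheme> CDR3: length 12, 2 fixed (1:A 12:Y), 10 randomized over 19 residues

format(theoretical_diversity(scheme))
#> [1] "257829627945307727248226067259"   # 19^23, exact
```

Thirty sequenced colonies at the deletion rate calibrated to a 2/3 pass
probability:

```r
clones  <- sample_clones(scheme, 30, seed = 7)
mutated <- apply_synthesis_errors(clones,
             error_model(calibrate_deletion_rate(2/3, 360)), seed = 7)
in_frame_fraction(qc_classify(mutated, scheme))
#> <qc_summary> 21/30 pass (70.0%), 95% CI [0.506, 0.853]
```

A four-round selection with a spike-in binder, in exact expectation mode
(the scaled scenario carries 100 spike copies in a 10^7 pool; background
wash survival is calibrated so the spike reaches 10% of the eluate at
round 4):

```r
camp <- run_scenario(make_scenario("egfp_campaign"), mode = "expectation")
camp$trajectory[, c("round", "spike_fraction_eluted", "detection_cycles")]
#>   round spike_fraction_eluted detection_cycles
#> 1     1             0.000103                20
#> 2     2             0.00105                 17
#> 3     3             0.0107                  14
#> 4     4             0.100                   10
autoplot(camp)   # enrichment trajectory on a log scale
```

The spike fraction multiplies by the ratio of per-round survivals each
round; the detection-cycle column is the PCR readout a gel would show
(~10% of a 0.1 ng template needs 10 doubling cycles to reach 10 ng).
Stochastic runs (`mode = "sample"`, with a seed) scatter around these
trajectories because a 100-copy spike lineage is genuinely noisy.

Spacer comparison and ELISA screening:

```r
sp <- make_spacer_pair(seed = 3)   # synthetic ~70% GC vs ~56% GC spacers
compare_spacers(list(spacer_profile(sp$seq[1], sp$name[1]),
                     spacer_profile(sp$seq[2], sp$name[2])))
#>    rank name               length gc_overall pairing_score pairing_density
#> 1     1 TolAlike_synthetic    150       0.56            58           0.773
#> 2     2 M13like_synthetic     150       0.7             73           0.973

glance(call_hits(make_elisa_plate(seed = 1)))   # 10 of 87 clones exceed 1.9
```

A thin command-line front end over the same functions lives at
`inst/cli/puredisplay.R` (subcommands `design`, `qc`, `spacer`,
`quantify`, `simulate`, `elisa`, `fixtures`).

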