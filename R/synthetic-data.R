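# Synthetic fixture generators. The reference study deposits no sequence
# data (framework alignments live in a figure, spacer sequences are not
# printed), so every input the pipeline needs is emulated here: framework
# alignments with point variation, CDR frequency tables whose declared
# modal residues sit above or below the fixing thresholds, spacer sequences
# at a target GC with or without embedded inverted repeats, scaled
# biopanning scenarios, and ELISA plates with a known number of true hits.
# All generators are deterministic under a seed.

revcomp_dna <- function(seq) {
  chartr("ACGT", "TGCA",
         vapply(strsplit(seq, "", fixed = TRUE),
                function(x) paste(rev(x), collapse = ""), character(1)))
}

#' Synthetic framework alignment
#'
#' A base framework sequence plus `n_frameworks - 1` variants carrying
#' independent point substitutions at `variation_rate`, emulating an
#' alignment of frameworks from previously published synthetic libraries.
#' At low variation the base is the modal residue of almost every column,
#' so [consensus_framework()] recovers it.
#'
#' @param n_frameworks Number of aligned rows (>= 2).
#' @param length Alignment columns.
#' @param variation_rate Per-position substitution probability in variants.
#' @param seed Optional integer seed.
#' @return Tibble with `name`, `seq`; the generating base sequence is in
#'   `attr(, "base")`.
#' @export
make_framework_alignment <- function(n_frameworks = 10, length = 88,
                                     variation_rate = 0.05, seed = NULL) {
  stopifnot(n_frameworks >= 2, length >= 1,
            variation_rate >= 0, variation_rate <= 1)
  with_seed(seed, {
    base <- sample(AA20, length, replace = TRUE)
    rows <- vapply(seq_len(n_frameworks - 1L), function(i) {
      v <- base
      mut <- runif(length) < variation_rate
      if (any(mut)) {
        v[mut] <- vapply(v[mut], function(r) sample(setdiff(AA20, r), 1),
                         character(1))
      }
      paste(v, collapse = "")
    }, character(1))
    out <- tibble::tibble(
      name = sprintf("framework_%02d", seq_len(n_frameworks)),
      seq = c(paste(base, collapse = ""), rows))
    attr(out, "base") <- paste(base, collapse = "")
    out
  })
}

#' Synthetic CDR residue-frequency table
#'
#' Builds a per-position frequency table in which declared positions carry
#' a specified modal residue at a specified frequency (e.g. 0.35 to sit
#' above a 30% fixing threshold, or 0.29 to sit just below it) and the
#' remaining mass is spread over the other residues with a Dirichlet draw
#' concentrated enough that no other residue approaches the modal one.
#'
#' @param cdr_id Identifier.
#' @param length Number of positions.
#' @param fixed_spec Optional data frame with columns `position`, `residue`,
#'   `frequency` describing the declared modal residues.
#' @param alphabet Residues in the table (default the 19-residue
#'   cysteine-free alphabet).
#' @param concentration Dirichlet concentration for the spread mass.
#' @param seed Optional integer seed.
#' @return Tibble with `cdr_id`, `position`, `residue`, `frequency`;
#'   frequencies sum to 1 per position.
#' @export
make_cdr_table <- function(cdr_id, length, fixed_spec = NULL,
                           alphabet = aa_alphabet_19(),
                           concentration = 5, seed = NULL) {
  stopifnot(length >= 1)
  if (!is.null(fixed_spec)) {
    stopifnot(all(c("position", "residue", "frequency") %in% names(fixed_spec)))
    if (!all(fixed_spec$residue %in% alphabet)) {
      abort("declared residues must be in the alphabet")
    }
    if (any(fixed_spec$frequency <= 1 / base::length(alphabet)) ||
        any(fixed_spec$frequency >= 1)) {
      abort("declared frequencies must be in (1/|alphabet|, 1) to be modal")
    }
  }
  with_seed(seed, {
    rows <- purrr::map_dfr(seq_len(length), function(p) {
      decl <- if (!is.null(fixed_spec)) fixed_spec[fixed_spec$position == p, ]
              else NULL
      if (!is.null(decl) && nrow(decl) == 1) {
        others <- setdiff(alphabet, decl$residue)
        w <- rgamma(base::length(others), concentration)
        spread <- (1 - decl$frequency) * w / sum(w)
        # cap any stray component below the declared modal frequency
        while (max(spread) >= decl$frequency) {
          i <- which.max(spread)
          excess <- spread[i] - 0.9 * decl$frequency
          spread[i] <- spread[i] - excess
          spread[-i] <- spread[-i] + excess / (base::length(spread) - 1)
        }
        tibble::tibble(position = p,
                       residue = c(decl$residue, others),
                       frequency = c(decl$frequency, spread))
      } else {
        w <- rgamma(base::length(alphabet), concentration)
        tibble::tibble(position = p, residue = alphabet,
                       frequency = w / sum(w))
      }
    })
    dplyr::mutate(rows, cdr_id = cdr_id, .before = 1)
  })
}

#' Reference CDR frequency tables
#'
#' The three tables matching the reference library design: CDR1 (length 10,
#' positions 1/2/10 modal G/M/G at 35%, above the 30% threshold), CDR2
#' (length 10, positions 1/2/9/10 modal A/I/T/Y at 35%) and CDR3 (length
#' 12, positions 1/12 modal A/Y at 55%/60%, above the 50% threshold).
#'
#' @param seed Optional integer seed.
#' @return Named list of three tibbles (`CDR1`, `CDR2`, `CDR3`).
#' @export
default_cdr_tables <- function(seed = NULL) {
  with_seed(seed, list(
    CDR1 = make_cdr_table("CDR1", 10, tibble::tibble(
      position = c(1, 2, 10), residue = c("G", "M", "G"),
      frequency = c(0.35, 0.35, 0.35))),
    CDR2 = make_cdr_table("CDR2", 10, tibble::tibble(
      position = c(1, 2, 9, 10), residue = c("A", "I", "T", "Y"),
      frequency = c(0.35, 0.35, 0.35, 0.35))),
    CDR3 = make_cdr_table("CDR3", 12, tibble::tibble(
      position = c(1, 12), residue = c("A", "Y"),
      frequency = c(0.55, 0.60)))))
}

#' Reference library scheme built from synthetic fixtures
#'
#' Assembles the full design: a consensus framework from a synthetic
#' 10-row alignment (FR1 25, FR2 14, FR3 38, FR4 11 residues), CDR1/CDR2
#' fixed at their above-30% flanking residues (G, M ... G and A, I ... T,
#' Y), CDR3 fixed at its above-50% first and last residues (A ... Y), and
#' all remaining CDR positions randomized over 19 residues. The encoded
#' protein is 120 aa (360 nt) with 23 randomized positions.
#'
#' @param seed Integer seed for the synthetic framework and tables.
#' @param cdr1_fixed_layout `"GM_G"` (default: positions 1, 2 and 10) or
#'   `"GM_MG"`-style four-position reading `"both_pairs"` (positions 1, 2,
#'   9, 10) of the "first and last two" rule; the named-residue reading
#'   fixes three positions, the positional reading four.
#' @return A [library_scheme()].
#' @export
default_library_scheme <- function(seed = 1,
                                   cdr1_fixed_layout = c("GM_G", "both_pairs")) {
  cdr1_fixed_layout <- match.arg(cdr1_fixed_layout)
  with_seed(seed, {
    aln <- make_framework_alignment(10, 88, 0.05)
    cons <- consensus_framework(aln)
    framework <- c(FR1 = substr(cons, 1, 25), FR2 = substr(cons, 26, 39),
                   FR3 = substr(cons, 40, 77), FR4 = substr(cons, 78, 88))
    tabs <- default_cdr_tables()
    cdr1_candidates <- if (cdr1_fixed_layout == "GM_G") c(1, 2, 10)
                       else c(1, 2, 9, 10)
    cdr1_tab <- tabs$CDR1
    if (cdr1_fixed_layout == "both_pairs") {
      # positional reading: also declare position 9 above threshold
      cdr1_tab <- make_cdr_table("CDR1", 10, tibble::tibble(
        position = c(1, 2, 9, 10), residue = c("G", "M", "M", "G"),
        frequency = c(0.35, 0.35, 0.35, 0.35)))
    }
    cdrs <- list(
      design_cdr_scheme(cdr1_tab, cdr1_candidates, threshold = 0.3),
      design_cdr_scheme(tabs$CDR2, c(1, 2, 9, 10), threshold = 0.3),
      design_cdr_scheme(tabs$CDR3, c(1, 12), threshold = 0.5))
    library_scheme(framework, cdrs)
  })
}

#' Synthetic spacer sequence at a target GC content
#'
#' Generates a DNA spacer whose GC fraction is within `1/length` of the
#' target. With `structured = TRUE` the sequence is a long perfect inverted
#' repeat (a stem-loop), maximizing base-pairing potential the way a
#' GC-rich natural spacer folds; with `structured = FALSE` the same base
#' composition is shuffled uniformly, suppressing designed repeats.
#'
#' @param length Sequence length (nt).
#' @param target_gc Target GC fraction in \[0, 1\].
#' @param structured Embed a full-length inverted repeat?
#' @param seed Optional integer seed.
#' @return A DNA string.
#' @export
make_spacer <- function(length = 150, target_gc = 0.7, structured = FALSE,
                        seed = NULL) {
  stopifnot(length >= 10, target_gc >= 0, target_gc <= 1)
  gc_n <- round(target_gc * length)
  with_seed(seed, {
    if (!structured) {
      g <- ceiling(gc_n / 2); cc <- gc_n - g
      at <- length - gc_n
      a <- ceiling(at / 2); tt <- at - a
      paste(sample(c(rep("G", g), rep("C", cc), rep("A", a), rep("T", tt))),
            collapse = "")
    } else {
      h <- (length - 3L) %/% 2L
      loop_len <- length - 2L * h
      g_stem <- min(h, gc_n %/% 2L)
      loop_gc <- min(loop_len, gc_n - 2L * g_stem)
      stem <- sample(c(rep("G", ceiling(g_stem / 2)),
                       rep("C", g_stem - ceiling(g_stem / 2)),
                       rep("A", ceiling((h - g_stem) / 2)),
                       rep("T", h - g_stem - ceiling((h - g_stem) / 2))))
      stem <- paste(stem, collapse = "")
      loop <- paste(c(rep("G", loop_gc), rep("A", loop_len - loop_gc)),
                    collapse = "")
      paste0(stem, loop, revcomp_dna(stem))
    }
  })
}

#' Synthetic spacer pair emulating the M13 pIII / TolA comparison
#'
#' Two ~150 nt spacers: a structure-prone one at ~70% GC built as an
#' inverted repeat ("M13-like") and a low-structure one at ~56% GC
#' ("TolA-like"). These are synthetic stand-ins constructed to match the
#' reported GC contents, not the natural gene sequences.
#'
#' @param length Spacer length (nt).
#' @param seed Optional integer seed.
#' @return Tibble with `name`, `seq`.
#' @export
make_spacer_pair <- function(length = 150, seed = NULL) {
  with_seed(seed, tibble::tibble(
    name = c("M13like_synthetic", "TolAlike_synthetic"),
    seq = c(make_spacer(length, 0.70, structured = TRUE),
            make_spacer(length, 0.56, structured = FALSE))))
}

# closed-form calibration: background wash retention such that a two-type
# competition starting at spike fraction p0 reaches `target_fraction` of the
# eluate after n_rounds, given the spike's per-round survival
calibrate_background_retention <- function(p0, target_fraction, n_rounds,
                                           spike_survival, efficiency,
                                           background_capture, washes) {
  odds_ratio <- (target_fraction / (1 - target_fraction)) / (p0 / (1 - p0))
  enrich_per_round <- odds_ratio^(1 / n_rounds)
  b <- spike_survival / enrich_per_round
  ret <- (b / (efficiency * background_capture))^(1 / washes)
  if (ret <= 0 || ret >= 1) {
    abort("calibration infeasible: background retention outside (0, 1)")
  }
  ret
}

#' Preset biopanning scenarios
#'
#' Encodes the two campaign layouts of the reference workflow as
#' ready-to-run scenarios (population + class parameters + per-round
#' configs):
#'
#' * `"egfp_campaign"`: 4 rounds against an EGFP-like target at display
#'   efficiency 0.04 with 2 washes per round. Full scale carries the
#'   spike at its 1e2 : 1e13 input ratio (expectation mode); the scaled
#'   variant keeps 100 spike copies in a 1e7 pool so stochastic runs finish
#'   in seconds while preserving the ~4 expected spike complexes per round.
#'   Background wash retention is calibrated in closed form so the spike
#'   reaches ~10% of the eluate at round 4 from the preset's own starting
#'   fraction.
#' * `"hfabp4_campaign"`: adds streptavidin-motif (HPQ/M) background
#'   binders and surface stickers; pre-incubation depletion on bare
#'   streptavidin from round 2, and a Ni-NTA surface in round 3 to break
#'   streptavidin-specific enrichment.
#'
#' @param preset `"egfp_campaign"` or `"hfabp4_campaign"`.
#' @param scaled Use the scaled-count population (default TRUE; the
#'   full-scale population is intended for expectation mode).
#' @param elution Elution chemistry for every round (`"edta"` default, or
#'   `"biotin_then_edta"` for the target-elution variant).
#' @param target_round_fraction Spike eluate fraction the calibration aims
#'   for at the final round (default 0.10).
#' @param n_rounds Number of rounds (default 4).
#' @return List with `preset`, `scaled`, `population` ([clone_population()]),
#'   `classes` ([clone_classes()]) and `rounds` (list of [panning_config()]).
#' @export
make_scenario <- function(preset = c("egfp_campaign", "hfabp4_campaign"),
                          scaled = TRUE, elution = c("edta", "biotin_then_edta"),
                          target_round_fraction = 0.10, n_rounds = 4) {
  preset <- match.arg(preset)
  elution <- match.arg(elution)
  efficiency <- 0.04
  washes <- 2L
  target_capture <- 0.9
  target_retention <- 0.85
  background_capture <- 0.2
  total <- if (scaled) 1e7 else 1e13
  spike_count <- 100

  spike_survival <- efficiency * target_capture * target_retention^washes
  p0 <- spike_count / total
  bg_retention <- calibrate_background_retention(
    p0, target_round_fraction, n_rounds, spike_survival,
    efficiency, background_capture, washes)
  classes <- clone_classes(
    target_retention = target_retention,
    motif_retention = target_retention,
    sticker_retention = 0.7,
    nonbinder_retention = bg_retention,
    target_capture = target_capture,
    motif_capture_streptavidin = target_capture,
    baseline_capture = background_capture,
    sticker_capture = 0.5)

  if (preset == "egfp_campaign") {
    population <- clone_population(tibble::tibble(
      clone_id = c("Nb2_spike", "library_background"),
      class_id = c("target_binder", "nonbinder"),
      count = c(spike_count, total - spike_count),
      spike = c(TRUE, FALSE)))
    rounds <- lapply(seq_len(n_rounds), function(r) {
      panning_config(display_efficiency = efficiency, washes = washes,
                     surface = "streptavidin_plate", elution = elution,
                     input_size = total)
    })
  } else {
    motif_total <- if (scaled) 1e3 else 1e9
    sticker_total <- if (scaled) 1e3 else 1e9
    population <- clone_population(tibble::tibble(
      clone_id = c("F4_spike", "hpqm_background", "sticker_background",
                   "library_background"),
      class_id = c("target_binder", "streptavidin_motif_binder",
                   "surface_sticker", "nonbinder"),
      count = c(spike_count, motif_total, sticker_total,
                total - spike_count - motif_total - sticker_total),
      spike = c(TRUE, FALSE, FALSE, FALSE)))
    rounds <- lapply(seq_len(n_rounds), function(r) {
      panning_config(
        display_efficiency = efficiency, washes = washes,
        surface = if (r == 3) "ni_nta" else "streptavidin_plate",
        preincubation_depletion = if (r >= 2 && r != 3) 0.9 else 0,
        elution = elution, input_size = total)
    })
  }
  list(preset = preset, scaled = scaled, population = population,
       classes = classes, rounds = rounds)
}

#' Run a preset scenario
#'
#' @param scenario Output of [make_scenario()] (or a preset name).
#' @param mode `"sample"` or `"expectation"`.
#' @param seed Optional integer seed.
#' @return A `panning_campaign`.
#' @export
run_scenario <- function(scenario, mode = c("sample", "expectation"),
                         seed = NULL) {
  if (is.character(scenario)) scenario <- make_scenario(scenario)
  run_campaign(scenario$population, scenario$rounds, scenario$classes,
               mode = mode, seed = seed)
}

#' Synthetic single-clone ELISA plate
#'
#' A plate table with a known number of true hits: hit rows get a
#' target/control ratio well above the 1.9 calling threshold, background
#' rows sit well below it.
#'
#' @param n_rows Number of clones on the plate (default 87).
#' @param n_true_hits Number of constructed hits (default 10).
#' @param seed Optional integer seed.
#' @return Tibble with `clone_id`, `a450_target`, `a450_control`.
#' @export
make_elisa_plate <- function(n_rows = 87, n_true_hits = 10, seed = NULL) {
  stopifnot(n_rows >= 1, n_true_hits >= 0, n_true_hits <= n_rows)
  with_seed(seed, {
    ratio <- c(runif(n_true_hits, 2.2, 6.0),
               runif(n_rows - n_true_hits, 0.4, 1.6))
    control <- runif(n_rows, 0.2, 0.5)
    ord <- sample.int(n_rows)
    tibble::tibble(
      clone_id = sprintf("colony_%02d", seq_len(n_rows)),
      a450_target = (ratio * control)[ord],
      a450_control = control[ord])
  })
}
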