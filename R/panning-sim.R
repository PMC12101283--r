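# Stochastic multi-round biopanning simulator. A clone population (mRNA
# copy counts with binding-class labels) is thinned round by round:
# translation into functional ribosome-mRNA-protein complexes, optional
# pre-incubation depletion of streptavidin-motif binders, capture on the
# round's surface, washes, elution chemistry, and amplification back to the
# next round's input. Every layer has a sampling form (binomial / Poisson /
# multinomial) and an exact expectation form, and within-round molecule
# counts are conserved exactly before amplification.

PAN_SURFACES <- c("streptavidin_beads", "streptavidin_plate", "ni_nta")
PAN_CLASSES <- c("target_binder", "streptavidin_motif_binder",
                 "surface_sticker", "nonbinder")

#' Binding-class parameter table
#'
#' Per-class wash-survival (retention) and per-surface capture
#' probabilities. Affinity is abstracted into these class-level
#' probabilities rather than explicit kinetics. The
#' `streptavidin_motif_binder` class models background clones whose CDRs
#' carry an HPQ/M streptavidin-pocket motif: captured avidly on any
#' streptavidin surface but only at baseline on Ni-NTA, and released by
#' biotin elution.
#'
#' @param target_retention,motif_retention,sticker_retention,nonbinder_retention
#'   Per-wash survival probabilities.
#' @param target_capture Capture probability of true target binders on a
#'   target-coated surface (any chemistry).
#' @param motif_capture_streptavidin Capture of HPQ/M clones on
#'   streptavidin surfaces.
#' @param baseline_capture Background capture probability (nonspecific).
#' @param sticker_capture Capture of surface-sticking clones.
#' @return Tibble with one row per class: `class_id`, `retention`, and one
#'   capture column per surface.
#' @export
clone_classes <- function(target_retention = 0.85,
                          motif_retention = 0.85,
                          sticker_retention = 0.7,
                          nonbinder_retention = 0.3,
                          target_capture = 0.9,
                          motif_capture_streptavidin = 0.9,
                          baseline_capture = 0.05,
                          sticker_capture = 0.5) {
  tibble::tibble(
    class_id = PAN_CLASSES,
    retention = c(target_retention, motif_retention, sticker_retention,
                  nonbinder_retention),
    capture_streptavidin_beads = c(target_capture, motif_capture_streptavidin,
                                   sticker_capture, baseline_capture),
    capture_streptavidin_plate = c(target_capture, motif_capture_streptavidin,
                                   sticker_capture, baseline_capture),
    capture_ni_nta = c(target_capture, baseline_capture,
                       sticker_capture, baseline_capture))
}

#' Clone population for a selection campaign
#'
#' @param df Data frame with columns `clone_id`, `class_id` (one of
#'   `target_binder`, `streptavidin_motif_binder`, `surface_sticker`,
#'   `nonbinder`), `count` (non-negative mRNA copies) and logical `spike`
#'   (at most one spike clone).
#' @return Validated tibble of class `clone_population`.
#' @export
clone_population <- function(df) {
  need <- c("clone_id", "class_id", "count", "spike")
  if (!all(need %in% names(df))) {
    abort(paste0("population needs columns: ", paste(need, collapse = ", ")))
  }
  if (!all(df$class_id %in% PAN_CLASSES)) {
    abort(paste0("unknown class_id; allowed: ", paste(PAN_CLASSES, collapse = ", ")))
  }
  if (any(df$count < 0)) abort("counts must be >= 0")
  if (sum(df$spike) > 1) abort("at most one spike clone")
  if (anyDuplicated(df$clone_id)) abort("clone_id must be unique")
  out <- tibble::as_tibble(df)
  class(out) <- c("clone_population", class(out))
  out
}

#' One selection round's parameters
#'
#' @param display_efficiency Fraction of input mRNA forming functional
#'   complexes (spacer-dependent: ~0.04 for an M13 pIII spacer, ~0.20 for
#'   TolA at short incubation).
#' @param incubation_release Extra complex drop-off probability from long
#'   translation incubation (0 = short incubation).
#' @param surface Immobilization surface for this round.
#' @param preincubation_depletion Probability that a streptavidin-motif
#'   complex is removed by pre-incubation on a bare streptavidin surface
#'   before target exposure.
#' @param washes Number of washes (>= 0).
#' @param elution `"edta"` recovers every still-captured complex;
#'   `"biotin_then_edta"` recovers target-bound and streptavidin-pocket
#'   (HPQ/M) complexes only, leaving surface-stuck material behind.
#' @param amplification_factor Expected copies per recovered molecule from
#'   RT-PCR plus T7 transcription (default 50).
#' @param mutation_rate Per-round probability that an amplified copy picks
#'   up a polymerase mutation, splitting off a variant clone record
#'   (default 0).
#' @param input_size If set, the next round's input pool is regenerated at
#'   this total size from the amplified proportions (re-transcription to a
#'   fixed input amount).
#' @param template_mass_ng Total RT-PCR template mass used for the round's
#'   spike quantification readout.
#' @param detection [pcr_model()] used for the detection-cycle readout.
#' @return Object of class `panning_config`.
#' @export
panning_config <- function(display_efficiency = 0.04,
                           incubation_release = 0,
                           surface = "streptavidin_plate",
                           preincubation_depletion = 0,
                           washes = 2,
                           elution = c("edta", "biotin_then_edta"),
                           amplification_factor = 50,
                           mutation_rate = 0,
                           input_size = NULL,
                           template_mass_ng = 0.1,
                           detection = pcr_model()) {
  surface <- match.arg(surface, PAN_SURFACES)
  elution <- match.arg(elution)
  probs <- c(display_efficiency, incubation_release, preincubation_depletion,
             mutation_rate)
  if (any(probs < 0) || any(probs > 1)) abort("probabilities must be in [0, 1]")
  stopifnot(washes >= 0, washes == floor(washes), amplification_factor > 0)
  structure(
    list(display_efficiency = display_efficiency,
         incubation_release = incubation_release,
         surface = surface,
         preincubation_depletion = preincubation_depletion,
         washes = as.integer(washes),
         elution = elution,
         amplification_factor = amplification_factor,
         mutation_rate = mutation_rate,
         input_size = input_size,
         template_mass_ng = template_mass_ng,
         detection = detection),
    class = "panning_config")
}

# classes recovered by each elution chemistry; EDTA strips everything
# (ribosome disassembly), biotin displaces target- and pocket-bound
# complexes but leaves surface-stuck ones behind
eluted_classes <- function(elution) {
  if (elution == "edta") PAN_CLASSES
  else c("target_binder", "streptavidin_motif_binder")
}

draw <- function(mode, size, prob) {
  if (mode == "expectation") size * prob else rbinom2(size, prob)
}

#' Simulate one biopanning round
#'
#' Thins each clone through the round's stages. Pre-amplification counts are
#' conserved exactly:
#' `functional = depleted + flow_through + washed + eluted + discarded`
#' (with no pre-incubation and EDTA elution the `depleted` and `discarded`
#' buckets are structurally zero, recovering the three-term form).
#'
#' @param pop A [clone_population()].
#' @param cfg A [panning_config()].
#' @param classes A [clone_classes()] table.
#' @param mode `"sample"` (stochastic) or `"expectation"` (exact expected
#'   counts, no sampling).
#' @param seed Optional integer seed.
#' @return Object of class `panning_round`: per-clone tibble plus spike
#'   fractions and a detection-cycle readout.
#' @export
simulate_round <- function(pop, cfg, classes = clone_classes(),
                           mode = c("sample", "expectation"), seed = NULL) {
  mode <- match.arg(mode)
  pop <- clone_population(pop)
  if (nrow(pop) == 0) abort("population is empty")
  cap_col <- paste0("capture_", cfg$surface)
  if (!cap_col %in% names(classes)) {
    abort(paste0("classes table lacks capture column for surface ", cfg$surface))
  }
  par <- dplyr::left_join(pop, classes, by = "class_id")
  if (anyNA(par$retention)) abort("class_id missing from classes table")
  capture <- par[[cap_col]]

  with_seed(seed, {
    p_func <- cfg$display_efficiency * (1 - cfg$incubation_release)
    functional <- draw(mode, par$count, p_func)

    is_motif <- par$class_id == "streptavidin_motif_binder"
    depleted <- numeric(nrow(par))
    if (cfg$preincubation_depletion > 0 && any(is_motif)) {
      depleted[is_motif] <- draw(mode, functional[is_motif],
                                 cfg$preincubation_depletion)
    }
    after_dep <- functional - depleted

    captured <- draw(mode, after_dep, capture)
    flow_through <- after_dep - captured

    wash_counts <- matrix(0, nrow(par), cfg$washes)
    if (cfg$washes > 0) {
      for (w in seq_len(cfg$washes)) {
        kept <- draw(mode, captured, par$retention)
        wash_counts[, w] <- captured - kept
        captured <- kept
      }
    }
    washed <- if (cfg$washes > 0) rowSums(wash_counts) else numeric(nrow(par))

    recover <- par$class_id %in% eluted_classes(cfg$elution)
    eluted <- ifelse(recover, captured, 0)
    discarded <- ifelse(recover, 0, captured)

    amplified <- if (mode == "expectation") {
      eluted * cfg$amplification_factor
    } else {
      rpois2(eluted * cfg$amplification_factor)
    }

    res <- tibble::tibble(
      clone_id = par$clone_id, class_id = par$class_id, spike = par$spike,
      input = par$count, functional = functional, depleted = depleted,
      flow_through = flow_through, washed = washed, eluted = eluted,
      discarded = discarded, amplified = amplified)
    res$wash_counts <- lapply(seq_len(nrow(res)), function(i) wash_counts[i, ])

    # optional polymerase mutation: split a variant record off each clone
    if (cfg$mutation_rate > 0 && mode == "sample") {
      mut <- rbinom2(res$amplified, cfg$mutation_rate)
      if (any(mut > 0)) {
        variants <- res[mut > 0, ]
        variants$clone_id <- paste0(variants$clone_id, "_mut")
        variants$spike <- FALSE
        variants[c("input", "functional", "depleted", "flow_through",
                   "washed", "eluted", "discarded")] <- 0
        variants$amplified <- mut[mut > 0]
        variants$wash_counts <- lapply(variants$wash_counts, function(x) x * 0)
        res$amplified <- res$amplified - mut
        res <- dplyr::bind_rows(res, variants)
        res$clone_id <- make.unique(res$clone_id)
      }
    }

    spike_frac <- function(col) {
      tot <- sum(res[[col]])
      if (tot == 0) return(NA_real_)
      sum(res[[col]][res$spike]) / tot
    }
    fractions <- c(input = spike_frac("input"),
                   functional = spike_frac("functional"),
                   eluted = spike_frac("eluted"),
                   amplified = spike_frac("amplified"))
    spike_mass <- fractions[["eluted"]] * cfg$template_mass_ng
    cycles <- if (is.na(spike_mass) || spike_mass <= 0) NA_integer_
              else detection_cycles(spike_mass, cfg$detection)

    structure(
      list(data = res, config = cfg, mode = mode,
           spike_fractions = fractions, detection_cycles = cycles),
      class = "panning_round")
  })
}

#' @export
print.panning_round <- function(x, ...) {
  cat(sprintf("<panning_round> %s, surface %s, elution %s: input %.4g -> eluted %.4g",
              x$mode, x$config$surface, x$config$elution,
              sum(x$data$input), sum(x$data$eluted)))
  if (!is.na(x$spike_fractions[["eluted"]])) {
    cat(sprintf(", spike %.3g of eluate", x$spike_fractions[["eluted"]]))
  }
  cat("\n")
  invisible(x)
}

# next round's input from a round result: either the amplified pool as-is,
# or regenerated at a fixed input size preserving proportions
next_population <- function(round_res, mode) {
  res <- round_res$data
  counts <- res$amplified
  size <- round_res$config$input_size
  if (!is.null(size) && sum(counts) > 0) {
    if (mode == "expectation") {
      counts <- counts / sum(counts) * size
    } else {
      if (size > .Machine$integer.max) {
        abort("stochastic mode supports input_size up to 2^31 - 1; use expectation mode for full-scale counts")
      }
      counts <- as.numeric(rmultinom(1, size, prob = counts))
    }
  }
  clone_population(tibble::tibble(
    clone_id = res$clone_id, class_id = res$class_id,
    count = counts, spike = res$spike))
}

#' Run a multi-round biopanning campaign
#'
#' Chains [simulate_round()] across a per-round config list, feeding each
#' round's amplified pool (optionally re-scaled to a fixed input size) into
#' the next. Tracks the spike-in fraction and its detection-cycle readout
#' round by round. `mode = "expectation"` propagates exact expected counts
#' (the analytic twin of the sampler; sampler means converge to it).
#'
#' @param pop A [clone_population()].
#' @param configs List of [panning_config()] objects, one per round.
#' @param classes A [clone_classes()] table.
#' @param mode `"sample"` or `"expectation"`.
#' @param seed Optional integer seed covering the whole campaign.
#' @return Object of class `panning_campaign`: per-round results, a
#'   trajectory tibble, and a `status` of `"completed"` or `"extinct"`.
#' @export
run_campaign <- function(pop, configs, classes = clone_classes(),
                         mode = c("sample", "expectation"), seed = NULL) {
  mode <- match.arg(mode)
  if (inherits(configs, "panning_config")) configs <- list(configs)
  if (length(configs) < 1) abort("need at least one round config")
  pop <- clone_population(pop)
  with_seed(seed, {
    rounds <- vector("list", length(configs))
    status <- "completed"
    current <- pop
    for (r in seq_along(configs)) {
      if (sum(current$count) == 0) {
        status <- "extinct"
        rounds <- rounds[seq_len(r - 1L)]
        break
      }
      rounds[[r]] <- simulate_round(current, configs[[r]], classes, mode)
      current <- next_population(rounds[[r]], mode)
    }
    trajectory <- purrr::imap_dfr(rounds, function(rr, r) {
      tibble::tibble(
        round = r,
        total_input = sum(rr$data$input),
        total_eluted = sum(rr$data$eluted),
        spike_fraction_input = rr$spike_fractions[["input"]],
        spike_fraction_eluted = rr$spike_fractions[["eluted"]],
        detection_cycles = rr$detection_cycles %||% NA_integer_)
    })
    structure(
      list(rounds = rounds, trajectory = trajectory, status = status,
           mode = mode, final_population = current),
      class = "panning_campaign")
  })
}

#' @export
print.panning_campaign <- function(x, ...) {
  cat(sprintf("<panning_campaign> %d round(s), mode %s, status %s\n",
              length(x$rounds), x$mode, x$status))
  print(x$trajectory)
  invisible(x)
}

#' Deterministic expectation trajectories for a campaign
#'
#' Convenience wrapper for [run_campaign()] with `mode = "expectation"`:
#' propagates expected counts exactly with no sampling, supporting
#' full-scale molecule counts (1e13).
#'
#' @inheritParams run_campaign
#' @return A `panning_campaign` in expectation mode.
#' @export
expectation_mode <- function(pop, configs, classes = clone_classes()) {
  run_campaign(pop, configs, classes, mode = "expectation")
}
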