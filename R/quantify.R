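# Display-efficiency, coverage and PCR-doubling arithmetic for ribosome
# display campaigns. Molecule counts are held as doubles (magnitudes reach
# 1e13); integer-valued results are snapped to integers at reporting time.

# ceiling with a relative guard so values that are mathematically integral
# (1e11 * 4 / 0.04 = 1e13) do not creep past the next integer in floating point
ceiling_safe <- function(x) {
  r <- round(x)
  ifelse(abs(x - r) < 1e-9 * pmax(1, abs(x)), r, ceiling(x))
}

#' Display efficiency from input and eluted molecule counts
#'
#' Fraction of input mRNA molecules recovered in the elution fraction as
#' target-retained functional ribosome-mRNA-protein complexes (e.g. about
#' 4% with an M13 pIII spacer, about 20% with a TolA spacer).
#'
#' @param input_molecules Input mRNA molecules (> 0).
#' @param eluted_molecules Eluted molecules (>= 0). A value above the input
#'   is allowed with a warning (measurement noise), not an error.
#' @return Efficiency fraction `eluted / input`.
#' @examples
#' display_efficiency(1e13, 4e11)
#' @export
display_efficiency <- function(input_molecules, eluted_molecules) {
  if (any(input_molecules <= 0)) abort("input_molecules must be > 0")
  if (any(eluted_molecules < 0)) abort("eluted_molecules must be >= 0")
  if (any(eluted_molecules > input_molecules)) {
    warn("eluted exceeds input for some records; check quantification")
  }
  eluted_molecules / input_molecules
}

#' Input molecules required to cover a library
#'
#' How many mRNA molecules must enter translation so that each distinct
#' library member forms, on average, `complexes_per_member` functional
#' complexes at the given display efficiency:
#' `diversity * complexes_per_member / efficiency`, rounded up.
#'
#' @param diversity Number of distinct library members (>= 1).
#' @param efficiency Display efficiency in (0, 1].
#' @param complexes_per_member Target mean functional complexes per member.
#' @return Required molecule count.
#' @examples
#' required_input(1e11, 0.04, 4)   # 1e13
#' @export
required_input <- function(diversity, efficiency, complexes_per_member) {
  if (any(efficiency <= 0) || any(efficiency > 1)) {
    abort("efficiency must be in (0, 1]")
  }
  stopifnot(all(diversity >= 1), all(complexes_per_member >= 1))
  ceiling_safe(diversity * complexes_per_member / efficiency)
}

#' Expected functional complexes for a clone
#'
#' @param copies mRNA copies of the clone in the input (>= 0).
#' @param efficiency Display efficiency in \[0, 1\].
#' @return Mean functional complex count `copies * efficiency`.
#' @examples
#' expected_complexes(100, 0.04)   # 4
#' @export
expected_complexes <- function(copies, efficiency) {
  stopifnot(all(copies >= 0), all(efficiency >= 0), all(efficiency <= 1))
  copies * efficiency
}

#' Probability a clone is displayed at least once
#'
#' Poisson representation of binomial thinning: with mean complex count `m`,
#' the probability of at least one functional complex is `1 - exp(-m)`.
#'
#' @param mean_complexes Mean functional complex count (>= 0).
#' @return Probability in \[0, 1\].
#' @examples
#' prob_displayed(4)   # ~0.982
#' @export
prob_displayed <- function(mean_complexes) {
  stopifnot(all(mean_complexes >= 0))
  -expm1(-mean_complexes)
}

#' PCR doubling model
#'
#' @param per_cycle_factor Amplification factor per cycle in (1, 2];
#'   default 2 (perfect doubling, as assumed by gel-based quantification).
#' @param detection_threshold_mass Product mass (ng) at which a band is
#'   detectable; default 10 ng.
#' @return Object of class `pcr_model`.
#' @export
pcr_model <- function(per_cycle_factor = 2, detection_threshold_mass = 10) {
  if (per_cycle_factor <= 1 || per_cycle_factor > 2) {
    abort("per_cycle_factor must be in (1, 2]")
  }
  stopifnot(detection_threshold_mass > 0)
  structure(list(per_cycle_factor = per_cycle_factor,
                 detection_threshold_mass = detection_threshold_mass),
            class = "pcr_model")
}

#' Amplify template mass through PCR cycles
#'
#' @param mass0_ng Starting template mass in ng (>= 0).
#' @param cycles Number of cycles (>= 0).
#' @param model A [pcr_model()].
#' @return Product mass `mass0 * factor^cycles` in ng.
#' @examples
#' pcr_amplify(0.01, 10)   # ~10 ng
#' @export
pcr_amplify <- function(mass0_ng, cycles, model = pcr_model()) {
  if (any(cycles < 0)) abort("cycles must be >= 0")
  stopifnot(all(mass0_ng >= 0))
  mass0_ng * model$per_cycle_factor^cycles
}

#' Back-calculate initial template mass from a PCR product
#'
#' Exact inverse of [pcr_amplify()]: `mass / factor^cycles`. This is the
#' gel-quantification arithmetic for spike-in templates (10 ng after 10
#' doubling cycles implies ~0.01 ng of starting template).
#'
#' @param mass_ng Product mass in ng.
#' @param cycles Number of cycles run.
#' @param model A [pcr_model()].
#' @return Initial template mass in ng.
#' @examples
#' initial_template(10, 10)   # 10 / 2^10 ~ 0.01 ng
#' @export
initial_template <- function(mass_ng, cycles, model = pcr_model()) {
  if (any(cycles < 0)) abort("cycles must be >= 0")
  mass_ng / model$per_cycle_factor^cycles
}

#' Spike-in proportion of a template pool
#'
#' @param spike_mass0_ng Back-calculated spike template mass (ng).
#' @param total_mass_ng Total template mass used (> 0).
#' @return Fraction `spike / total`.
#' @examples
#' spike_proportion(initial_template(10, 10), 0.1)   # ~0.10
#' @export
spike_proportion <- function(spike_mass0_ng, total_mass_ng) {
  if (any(total_mass_ng <= 0)) abort("total_mass_ng must be > 0")
  stopifnot(all(spike_mass0_ng >= 0))
  spike_mass0_ng / total_mass_ng
}

#' Cycles needed before a template becomes detectable
#'
#' Smallest integer cycle count `c` with
#' `mass0 * factor^c >= detection_threshold_mass`. Enriched spikes need
#' fewer cycles (10 at ~10% abundance versus 25 after a first round).
#'
#' @param mass0_ng Starting template mass (> 0).
#' @param model A [pcr_model()].
#' @return Integer cycle count (0 if already above threshold).
#' @examples
#' detection_cycles(0.01)   # 10
#' @export
detection_cycles <- function(mass0_ng, model = pcr_model()) {
  if (any(mass0_ng <= 0)) abort("mass0_ng must be > 0")
  f <- model$per_cycle_factor
  th <- model$detection_threshold_mass
  vapply(mass0_ng, function(m) {
    if (m >= th) return(0L)
    c0 <- ceiling(log(th / m) / log(f) - 1e-12)
    # settle floating-point edge cases exactly
    while (m * f^c0 < th) c0 <- c0 + 1
    while (c0 > 0 && m * f^(c0 - 1) >= th) c0 <- c0 - 1
    as.integer(c0)
  }, integer(1))
}

#' Per-round quantification report
#'
#' Tidy wrapper applying the quantification arithmetic to a table of round
#' measurements: RT-qPCR molecule counts give display efficiencies, and
#' gel-quantified spike masses after a known cycle count give back-calculated
#' template masses, spike proportions and detection-cycle estimates.
#'
#' @param rounds Data frame with columns `round`, `input_molecules`,
#'   `eluted_molecules`, `template_mass_ng` (total RT-PCR template used),
#'   `spike_product_ng` (spike product mass after `cycles` cycles), `cycles`.
#' @param model A [pcr_model()].
#' @return Tibble adding `efficiency`, `spike_template_ng`,
#'   `spike_proportion`, `detection_cycles`.
#' @export
quantify_rounds <- function(rounds, model = pcr_model()) {
  need <- c("round", "input_molecules", "eluted_molecules",
            "template_mass_ng", "spike_product_ng", "cycles")
  if (!all(need %in% names(rounds))) {
    abort(paste0("rounds table needs columns: ", paste(need, collapse = ", ")))
  }
  dplyr::mutate(
    tibble::as_tibble(rounds),
    efficiency = display_efficiency(.data$input_molecules, .data$eluted_molecules),
    spike_template_ng = initial_template(.data$spike_product_ng, .data$cycles, model),
    spike_proportion = spike_proportion(.data$spike_template_ng, .data$template_mass_ng),
    detection_cycles = detection_cycles(.data$spike_template_ng, model))
}
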