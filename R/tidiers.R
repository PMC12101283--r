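# broom-style tidiers and ggplot2 autoplot methods for the package's
# result objects.

#' @exportS3Method generics::tidy
tidy.qc_summary <- function(x, ...) {
  tibble::tibble(outcome = c("pass", "fail"),
                 n = c(x$passes, x$n - x$passes),
                 fraction = c(x$fraction, 1 - x$fraction))
}

#' @exportS3Method generics::glance
glance.qc_summary <- function(x, ...) {
  tibble::tibble(n = x$n, passes = x$passes, fraction = x$fraction,
                 conf_low = x$conf_low, conf_high = x$conf_high,
                 conf_level = x$conf_level)
}

#' @exportS3Method generics::tidy
tidy.spacer_profile <- function(x, ...) {
  dplyr::mutate(x$gc_windows, name = x$name,
                window = dplyr::row_number(), .before = 1)
}

#' @exportS3Method generics::glance
glance.spacer_profile <- function(x, ...) {
  tibble::tibble(name = x$name, length = x$length, gc_overall = x$gc_overall,
                 pairing_score = x$pairing_score,
                 pairing_density = x$pairing_density)
}

#' @exportS3Method generics::tidy
tidy.panning_round <- function(x, ...) {
  tidyr::pivot_longer(
    dplyr::select(x$data, -"wash_counts"),
    cols = c("input", "functional", "depleted", "flow_through", "washed",
             "eluted", "discarded", "amplified"),
    names_to = "fraction", values_to = "count")
}

#' @exportS3Method generics::glance
glance.panning_round <- function(x, ...) {
  d <- x$data
  tibble::tibble(
    mode = x$mode, surface = x$config$surface, elution = x$config$elution,
    total_input = sum(d$input), total_functional = sum(d$functional),
    total_eluted = sum(d$eluted),
    spike_fraction_eluted = x$spike_fractions[["eluted"]],
    detection_cycles = x$detection_cycles)
}

#' @exportS3Method generics::tidy
tidy.panning_campaign <- function(x, ...) x$trajectory

#' @exportS3Method generics::glance
glance.panning_campaign <- function(x, ...) {
  last <- x$trajectory[nrow(x$trajectory), ]
  tibble::tibble(
    n_rounds = length(x$rounds), mode = x$mode, status = x$status,
    final_spike_fraction = last$spike_fraction_eluted,
    final_detection_cycles = last$detection_cycles)
}

#' @exportS3Method generics::tidy
tidy.elisa_hits <- function(x, ...) {
  dplyr::mutate(x$table, hit = .data$ratio > x$ratio_threshold)
}

#' @exportS3Method generics::glance
glance.elisa_hits <- function(x, ...) {
  tibble::tibble(n = nrow(x$table) + nrow(x$flagged), usable = nrow(x$table),
                 flagged = nrow(x$flagged), n_hits = x$n_hits,
                 ratio_threshold = x$ratio_threshold)
}

#' Plot a spacer GC profile
#'
#' Windowed GC content along the spacer with the overall GC as a dashed
#' reference line; the subtitle reports the pairing statistics.
#'
#' @param object A [spacer_profile()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.spacer_profile <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = (.data$start + .data$end) / 2,
                                   y = .data$gc)) +
    ggplot2::geom_step() +
    ggplot2::geom_hline(yintercept = object$gc_overall, linetype = "dashed") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(
      x = "position (nt)", y = "GC fraction",
      title = paste0("Spacer GC profile: ", object$name),
      subtitle = sprintf("overall GC %.1f%%, max pairs %d (density %.2f)",
                         100 * object$gc_overall, object$pairing_score,
                         object$pairing_density))
}

#' Plot a campaign's spike-in enrichment trajectory
#'
#' Spike fraction of the eluate per round on a log scale, the standard
#' round-by-round enrichment readout.
#'
#' @param object A `panning_campaign`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.panning_campaign <- function(object, ...) {
  ggplot2::ggplot(object$trajectory,
                  ggplot2::aes(x = .data$round,
                               y = .data$spike_fraction_eluted)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "biopanning round", y = "spike fraction of eluate",
                  title = "Spike-in enrichment trajectory",
                  subtitle = paste0("mode: ", object$mode))
}

#' Plot ELISA ratios with the calling threshold
#'
#' @param object An [call_hits()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.elisa_hits <- function(object, ...) {
  df <- tidy(object)
  df <- df[order(-df$ratio), ]
  df$rank <- seq_len(nrow(df))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$ratio,
                                   colour = .data$hit)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$ratio_threshold,
                        linetype = "dashed") +
    ggplot2::labs(x = "clone (ranked)", y = "A450 ratio (target / control)",
                  title = sprintf("ELISA screen: %d hit(s) above ratio %.1f",
                                  object$n_hits, object$ratio_threshold),
                  colour = "hit")
}
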