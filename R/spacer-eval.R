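# Spacer-gene suitability scoring. In PURE-system ribosome display the
# spacer mRNA must thread the ribosome without stalling; GC-rich regions
# that base-pair into stable secondary structure (the natural M13 pIII
# spacer, ~70% GC) depress display efficiency, while low-structure spacers
# (TolA-like, ~56% GC) display far better. Structure propensity is scored
# with a maximum base-pairing dynamic program rather than a thermodynamic
# folding model.

#' Windowed GC profile of a nucleotide sequence
#'
#' @param seq A single DNA or RNA sequence (`T` and `U` both accepted).
#' @param window Window width in nucleotides (>= 1).
#' @param step Step between window starts; defaults to `window`
#'   (non-overlapping tiling). The final partial window is included.
#' @return Tibble with 0-based half-open `start`, `end` and per-window `gc`;
#'   attribute `gc_overall` carries the whole-sequence fraction.
#' @examples
#' gc_profile("GGGGAAAA", window = 4)
#' @export
gc_profile <- function(seq, window = 50, step = window) {
  stopifnot(window >= 1, step >= 1)
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n == 0) abort("empty sequence")
  if (grepl("[^ACGTU]", seq)) abort("sequence contains non-nucleotide characters")
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  is_gc <- chars %in% c("G", "C")
  starts <- seq(0L, max(0L, n - 1L), by = step)
  starts <- starts[starts < n]
  ends <- pmin(starts + window, n)
  gc <- vapply(seq_along(starts), function(i) {
    mean(is_gc[(starts[i] + 1L):ends[i]])
  }, numeric(1))
  out <- tibble::tibble(start = starts, end = ends, gc = gc)
  attr(out, "gc_overall") <- mean(is_gc)
  out
}

# Allowed pair lookup: Watson-Crick plus (optionally) GU wobble, on an
# RNA-normalized alphabet.
pair_ok_matrix <- function(allow_gu = TRUE) {
  b <- c("A", "C", "G", "U")
  m <- matrix(FALSE, 4, 4, dimnames = list(b, b))
  m["A", "U"] <- m["U", "A"] <- TRUE
  m["G", "C"] <- m["C", "G"] <- TRUE
  if (allow_gu) m["G", "U"] <- m["U", "G"] <- TRUE
  m
}

#' Maximum number of nested base pairs (Nussinov dynamic program)
#'
#' Scores secondary-structure propensity as the maximum number of nested
#' Watson-Crick (+ GU wobble) base pairs, with at least `min_loop` unpaired
#' bases enclosed by every hairpin-closing pair. This is a combinatorial
#' stand-in for thermodynamic folding: it ranks structure-prone sequences
#' without free-energy parameters.
#'
#' @param seq One DNA or RNA sequence.
#' @param min_loop Minimum unpaired bases inside a hairpin loop (default 3,
#'   the usual steric convention).
#' @param allow_gu Allow GU wobble pairs (default TRUE; the scored molecule
#'   is mRNA).
#' @return Integer maximum pair count.
#' @examples
#' max_pairing("GGGAAACCC")
#' @export
max_pairing <- function(seq, min_loop = 3, allow_gu = TRUE) {
  stopifnot(min_loop >= 0)
  seq <- chartr("Tt", "Uu", toupper(seq))
  if (grepl("[^ACGU]", seq)) abort("sequence contains non-nucleotide characters")
  s <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(s)
  if (n < min_loop + 2) return(0L)
  ok <- pair_ok_matrix(allow_gu)
  can <- ok[s, s, drop = FALSE]  # n x n pairability
  N <- matrix(0L, n, n)
  for (span in (min_loop + 1L):(n - 1L)) {
    for (ii in seq_len(n - span)) {
      jj <- ii + span
      best <- N[ii + 1L, jj]                       # ii unpaired
      if (can[ii, jj]) {
        v <- 1L + (if (ii + 1L <= jj - 1L) N[ii + 1L, jj - 1L] else 0L)
        if (v > best) best <- v
      }
      # bifurcation: ii pairs with some k < jj
      ks <- if (ii + min_loop + 1L <= jj - 1L) (ii + min_loop + 1L):(jj - 1L)
            else integer(0)
      ks <- ks[can[ii, ks]]
      if (length(ks) > 0) {
        inner <- ifelse(ks - 1L >= ii + 1L, N[cbind(ii + 1L, ks - 1L)], 0L)
        v <- max(1L + inner + N[cbind(ks + 1L, jj)])
        if (v > best) best <- v
      }
      N[ii, jj] <- best
    }
  }
  N[1L, n]
}

#' Full spacer profile: GC content and pairing statistics
#'
#' @param seq One DNA or RNA sequence.
#' @param name Spacer identifier.
#' @param window,step Passed to [gc_profile()].
#' @param min_loop,allow_gu Passed to [max_pairing()].
#' @return Object of class `spacer_profile` with fields `name`, `length`,
#'   `gc_overall`, `gc_windows`, `pairing_score`, `pairing_density`
#'   (pairs / (length / 2)).
#' @export
spacer_profile <- function(seq, name = "spacer", window = 50, step = window,
                           min_loop = 3, allow_gu = TRUE) {
  windows <- gc_profile(seq, window, step)
  n <- nchar(seq)
  score <- max_pairing(seq, min_loop = min_loop, allow_gu = allow_gu)
  structure(
    list(name = name, length = n,
         gc_overall = attr(windows, "gc_overall"),
         gc_windows = windows,
         pairing_score = score,
         pairing_density = score / (n / 2),
         min_loop = min_loop, allow_gu = allow_gu),
    class = "spacer_profile")
}

#' @export
print.spacer_profile <- function(x, ...) {
  cat(sprintf("<spacer_profile> %s: %d nt, GC %.1f%%, max pairs %d (density %.2f)\n",
              x$name, x$length, 100 * x$gc_overall, x$pairing_score,
              x$pairing_density))
  invisible(x)
}

#' Rank spacer candidates by structure propensity
#'
#' Orders profiles by ascending pairing density, then ascending overall GC;
#' the best PURE-display spacer candidate (least secondary structure) comes
#' first. Ties preserve input order.
#'
#' @param profiles List of [spacer_profile()] objects.
#' @return Tibble with `rank`, `name`, `length`, `gc_overall`,
#'   `pairing_score`, `pairing_density`.
#' @export
compare_spacers <- function(profiles) {
  if (inherits(profiles, "spacer_profile")) profiles <- list(profiles)
  if (length(profiles) < 2) abort("need at least two spacer profiles to compare")
  tab <- purrr::map_dfr(profiles, function(p) {
    tibble::tibble(name = p$name, length = p$length, gc_overall = p$gc_overall,
                   pairing_score = p$pairing_score,
                   pairing_density = p$pairing_density)
  })
  ord <- order(tab$pairing_density, tab$gc_overall)  # stable sort
  tab <- tab[ord, ]
  dplyr::mutate(tab, rank = dplyr::row_number(), .before = 1)
}
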