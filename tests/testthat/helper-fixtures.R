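# Shared fixtures and independent oracles for the test suite. Everything is
# generated in code; no external files.

# Independent brute-force maximum-pairing oracle: plain recursive
# enumeration of every nested structure, no memoization, no shared code
# with the package's dynamic program. Only usable for short sequences.
bf_max_pairing <- function(seq, min_loop = 3, allow_gu = TRUE) {
  s <- strsplit(chartr("Tt", "Uu", toupper(seq)), "")[[1]]
  pairs <- list(c("A", "U"), c("U", "A"), c("G", "C"), c("C", "G"))
  if (allow_gu) pairs <- c(pairs, list(c("G", "U"), c("U", "G")))
  can <- function(a, b) any(vapply(pairs, function(p) p[1] == a && p[2] == b,
                                   logical(1)))
  rec <- function(i, j) {
    if (j - i < min_loop + 1) return(0L)
    best <- rec(i + 1L, j)
    for (k in (i + min_loop + 1L):j) {
      if (can(s[i], s[k])) {
        inner <- if (k - 1L >= i + 1L) rec(i + 1L, k - 1L) else 0L
        rest <- if (k + 1L <= j) rec(k + 1L, j) else 0L
        best <- max(best, 1L + inner + rest)
      }
    }
    best
  }
  if (length(s) < 2) return(0L)
  rec(1L, length(s))
}

random_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n, replace = TRUE),
                                collapse = "")

# A tiny deterministic scheme for fast tests: short frameworks, small CDRs.
tiny_scheme <- function() {
  library_scheme(
    framework = c(FR1 = "QVQL", FR2 = "WYRQ", FR3 = "RFTI", FR4 = "WGQG"),
    cdrs = list(
      cdr_scheme("CDR1", 4, c("1" = "G", "4" = "G")),
      cdr_scheme("CDR2", 3, c("1" = "A")),
      cdr_scheme("CDR3", 5, c("1" = "A", "5" = "Y"))))
}

ref_scheme <- function() default_library_scheme(seed = 1)

# closed-form two-type competition: spike eluate fraction after r rounds
two_type_fraction <- function(p0, s, b, r) {
  (p0 * s^r) / (p0 * s^r + (1 - p0) * b^r)
}

# per-round survival probability of a class under a config + classes table
class_survival <- function(cfg, classes, class_id) {
  row <- classes[classes$class_id == class_id, ]
  cap <- row[[paste0("capture_", cfg$surface)]]
  dep <- if (class_id == "streptavidin_motif_binder") cfg$preincubation_depletion else 0
  recovered <- class_id %in% c("target_binder", "streptavidin_motif_binder") ||
    cfg$elution == "edta"
  cfg$display_efficiency * (1 - cfg$incubation_release) * (1 - dep) *
    cap * row$retention^cfg$washes * as.numeric(recovered)
}
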