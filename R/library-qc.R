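#' Synthesis error model
#'
#' Per-nucleotide error process observed when sequencing clones from a
#' chemically synthesized library: independent single-nucleotide deletions
#' (the dominant mode, causing frameshifts) and optional substitutions.
#'
#' @param del_rate Per-nucleotide deletion probability in \[0, 1\].
#' @param sub_rate Per-nucleotide substitution probability (default 0).
#' @return An object of class `error_model`.
#' @export
error_model <- function(del_rate, sub_rate = 0) {
  stopifnot(del_rate >= 0, del_rate <= 1, sub_rate >= 0, sub_rate <= 1)
  structure(list(del_rate = del_rate, sub_rate = sub_rate),
            class = "error_model")
}

#' Deletion rate that yields a target per-clone pass probability
#'
#' Under pure single-nucleotide deletions any hit disqualifies a clone
#' (either frameshift or in-frame shortening), so a length-`L` clone passes
#' QC with probability `(1 - d)^L`. Inverting gives the calibrated rate.
#'
#' @param target_pass Desired per-clone pass probability in (0, 1\].
#' @param length Clone length in nucleotides.
#' @return Deletion rate `d = 1 - target_pass^(1/length)`.
#' @examples
#' calibrate_deletion_rate(2 / 3, 360)
#' @export
calibrate_deletion_rate <- function(target_pass, length) {
  stopifnot(target_pass > 0, target_pass <= 1, length >= 1)
  1 - target_pass^(1 / length)
}

#' Apply synthesis errors to clone DNA
#'
#' Each nucleotide is independently substituted with `sub_rate` (to a random
#' different base) and deleted with `del_rate`. Sampling draws the per-clone
#' hit count binomially and then places hits uniformly, which is equivalent
#' to per-base Bernoulli thinning but fast for large clone sets.
#'
#' @param clones Tibble with a `dna` column (other columns pass through), or
#'   a character vector of DNA sequences.
#' @param model An [error_model()].
#' @param seed Optional integer seed.
#' @return Same shape as `clones`, with mutated DNA.
#' @export
apply_synthesis_errors <- function(clones, model, seed = NULL) {
  vec_in <- !is.data.frame(clones)
  dna <- if (vec_in) toupper(clones) else toupper(clones$dna)
  with_seed(seed, {
    lens <- nchar(dna)
    if (model$sub_rate > 0) {
      nsub <- rbinom(length(dna), lens, model$sub_rate)
      hit <- which(nsub > 0)
      for (i in hit) {
        chars <- strsplit(dna[i], "", fixed = TRUE)[[1]]
        pos <- sample.int(lens[i], nsub[i])
        chars[pos] <- vapply(chars[pos], function(b) {
          sample(setdiff(DNA_BASES, b), 1)
        }, character(1))
        dna[i] <- paste(chars, collapse = "")
      }
    }
    if (model$del_rate > 0) {
      if (model$del_rate >= 1) {
        dna[] <- ""
      } else {
        ndel <- rbinom(length(dna), lens, model$del_rate)
        hit <- which(ndel > 0)
        for (i in hit) {
          pos <- sample.int(lens[i], ndel[i])
          chars <- strsplit(dna[i], "", fixed = TRUE)[[1]]
          dna[i] <- paste(chars[-pos], collapse = "")
        }
      }
    }
    if (vec_in) dna else dplyr::mutate(clones, dna = .env$dna)
  })
}

#' Classify sequenced clones as full-length and in-frame
#'
#' Reproduces the library-quality call applied to sequenced colonies:
#' `in_frame` requires a length divisible by 3 with no internal stop codon,
#' `full_length` requires the translated protein to have exactly the
#' scheme's length, and `framework_match` requires every framework position
#' to carry the scheme's consensus residue. A clone passes only if all
#' three hold.
#'
#' @param dna Character vector of clone DNA (or tibble with `clone_id`, `dna`).
#' @param scheme The [library_scheme()] the clones were sampled from.
#' @return Tibble with `clone_id`, `in_frame`, `full_length`,
#'   `framework_match`, `pass`, `fail_reason`.
#' @export
qc_classify <- function(dna, scheme) {
  if (is.data.frame(dna)) {
    ids <- dna$clone_id
    dna <- dna$dna
  } else {
    ids <- names(dna) %||% sprintf("clone_%d", seq_along(dna))
  }
  dna <- toupper(dna)
  bad <- grepl("[^ACGT]", dna)
  if (any(bad)) {
    abort(paste0("non-nucleotide characters in clone(s): ",
                 paste(head(ids[bad], 5), collapse = ", ")))
  }
  tmpl <- scheme_template(scheme)
  exp_len <- length(tmpl$residues)

  prot <- translate_dna(dna)
  has_stop <- grepl("*", prot, fixed = TRUE)
  in_frame <- (nchar(dna) %% 3L == 0L) & !has_stop
  full_length <- in_frame & nchar(prot) == exp_len
  # framework regions are contiguous runs, so compare them as substrings
  runs <- rle(tmpl$framework_mask)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  framework_match <- full_length
  idx <- which(full_length)
  for (k in which(runs$values)) {
    seg <- paste(tmpl$residues[starts[k]:ends[k]], collapse = "")
    framework_match[idx] <- framework_match[idx] &
      substr(prot[idx], starts[k], ends[k]) == seg
  }

  fail_reason <- dplyr::case_when(
    nchar(dna) %% 3L != 0L ~ "frameshift",
    has_stop ~ "internal_stop",
    !full_length ~ "length_mismatch",
    !framework_match ~ "framework_mismatch",
    TRUE ~ "none")
  tibble::tibble(clone_id = ids, in_frame = in_frame,
                 full_length = full_length, framework_match = framework_match,
                 pass = in_frame & full_length & framework_match,
                 fail_reason = fail_reason)
}

#' Fraction of clones passing QC, with exact binomial interval
#'
#' @param verdicts Tibble from [qc_classify()] (needs a logical `pass`
#'   column), or a logical vector.
#' @param conf_level Confidence level for the Clopper-Pearson interval.
#' @return An object of class `qc_summary` with `n`, `passes`, `fraction`,
#'   `conf_low`, `conf_high`; see [tidy()] / [glance()].
#' @examples
#' in_frame_fraction(c(rep(TRUE, 20), rep(FALSE, 10)))
#' @export
in_frame_fraction <- function(verdicts, conf_level = 0.95) {
  pass <- if (is.data.frame(verdicts)) verdicts$pass else as.logical(verdicts)
  if (length(pass) == 0) abort("no verdicts supplied")
  k <- sum(pass); n <- length(pass)
  bt <- binom.test(k, n, conf.level = conf_level)
  structure(
    list(n = n, passes = k, fraction = k / n,
         conf_low = unname(bt$conf.int[1]), conf_high = unname(bt$conf.int[2]),
         conf_level = conf_level),
    class = "qc_summary")
}

#' @export
print.qc_summary <- function(x, ...) {
  cat(sprintf("<qc_summary> %d/%d pass (%.1f%%), %.0f%% CI [%.3f, %.3f]\n",
              x$passes, x$n, 100 * x$fraction, 100 * x$conf_level,
              x$conf_low, x$conf_high))
  invisible(x)
}

#' Simulate sequencing batches through the full QC pipeline
#'
#' For each batch: sample clones from the scheme, apply the synthesis error
#' model, classify with [qc_classify()], and count passes. Used to study the
#' sampling distribution of the in-frame statistic at small sequencing
#' depth (e.g. 30 colonies per batch).
#'
#' @param scheme A [library_scheme()].
#' @param model An [error_model()].
#' @param n_batches Number of sequencing batches.
#' @param batch_size Clones sequenced per batch.
#' @param seed Optional integer seed.
#' @param chunk Internal batching granularity (clones per chunk).
#' @return Tibble with `batch`, `passes`, `fraction`.
#' @export
simulate_qc_batches <- function(scheme, model, n_batches, batch_size = 30,
                                seed = NULL, chunk = 20000L) {
  stopifnot(n_batches >= 1, batch_size >= 1)
  total <- n_batches * batch_size
  with_seed(seed, {
    passes <- logical(total)
    done <- 0L
    while (done < total) {
      m <- min(chunk, total - done)
      clones <- sample_clones(scheme, m)
      mutated <- apply_synthesis_errors(clones, model)
      passes[done + seq_len(m)] <- qc_classify(mutated, scheme)$pass
      done <- done + m
    }
    counts <- colSums(matrix(passes, nrow = batch_size))
    tibble::tibble(batch = seq_len(n_batches), passes = as.integer(counts),
                   fraction = counts / batch_size)
  })
}
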