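#' Consensus framework from an alignment of published frameworks
#'
#' Collapses an alignment of framework sequences to the most frequently
#' occurring residue per column, the way a synthetic library scaffold is
#' derived from previously published library frameworks. Columns that are
#' gap in a strict majority of rows are dropped; among non-gap residues the
#' modal one is taken, with ties broken alphabetically so the consensus is
#' deterministic.
#'
#' @param aln A data frame with columns `name` and `seq` (equal-length
#'   aligned amino-acid sequences, `-` for gaps), or a character vector of
#'   aligned sequences.
#' @return A single gapless consensus amino-acid string.
#' @examples
#' consensus_framework(c("QVQLVE", "QVQLVE", "QVKLVE"))
#' @export
consensus_framework <- function(aln) {
  rows <- if (is.data.frame(aln)) aln$seq else unname(aln)
  rows <- toupper(as.character(rows))
  if (length(rows) == 0) abort("alignment is empty")
  widths <- nchar(rows)
  if (length(unique(widths)) != 1L) {
    abort("aligned rows must all have the same length")
  }
  mat <- matrix(unlist(strsplit(rows, "", fixed = TRUE), use.names = FALSE),
                nrow = length(rows), byrow = TRUE)
  bad <- setdiff(unique(as.vector(mat)), c(AA20, GAP))
  if (length(bad) > 0) {
    abort(paste0("alignment contains non-amino-acid characters: ",
                 paste(bad, collapse = ", ")))
  }
  cons <- vapply(seq_len(ncol(mat)), function(j) {
    col <- mat[, j]
    if (mean(col == GAP) > 0.5) return(NA_character_)
    col <- col[col != GAP]
    tab <- table(col)
    top <- names(tab)[tab == max(tab)]
    sort(top)[1]  # alphabetical tie-break
  }, character(1))
  paste(cons[!is.na(cons)], collapse = "")
}

#' CDR randomization scheme
#'
#' Describes one complementarity-determining region of the library: its
#' length, which positions are fixed to a single residue, and the alphabet
#' randomized positions draw from (19 residues, no cysteine, by default).
#'
#' @param cdr_id Identifier such as `"CDR1"`.
#' @param length Number of residues in the loop.
#' @param fixed Named character vector: names are 1-based positions, values
#'   single residues (e.g. `c("1" = "G", "2" = "M")`). May be empty.
#' @param alphabet Residues allowed at randomized positions.
#' @return An object of class `cdr_scheme`.
#' @export
cdr_scheme <- function(cdr_id, length, fixed = character(0),
                       alphabet = aa_alphabet_19()) {
  stopifnot(length >= 1, length == floor(length))
  pos <- as.integer(names(fixed))
  if (length(fixed) > 0) {
    if (anyNA(pos) || any(pos < 1) || any(pos > length)) {
      abort("fixed positions must lie in [1, length]")
    }
    if (anyDuplicated(pos)) abort("duplicate fixed positions")
    if (!all(fixed %in% AA20)) abort("fixed residues must be amino acids")
  }
  if (!all(alphabet %in% AA20)) abort("alphabet must be amino acids")
  structure(
    list(cdr_id = cdr_id, length = as.integer(length),
         fixed = fixed[order(pos)], alphabet = sort(unique(alphabet))),
    class = "cdr_scheme")
}

#' @export
print.cdr_scheme <- function(x, ...) {
  cat(sprintf("<cdr_scheme> %s: length %d, %d fixed (%s), %d randomized over %d residues\n",
              x$cdr_id, x$length, length(x$fixed),
              if (length(x$fixed)) paste0(names(x$fixed), ":", x$fixed, collapse = " ") else "-",
              x$length - length(x$fixed), length(x$alphabet)))
  invisible(x)
}

n_randomized <- function(scheme) scheme$length - length(scheme$fixed)

validate_cdr_table <- function(freqs) {
  need <- c("position", "residue", "frequency")
  if (!all(need %in% names(freqs))) {
    abort("CDR frequency table needs columns position, residue, frequency")
  }
  sums <- tapply(freqs$frequency, freqs$position, sum)
  off <- abs(sums - 1) > 1e-9
  if (any(off)) {
    abort(paste0("per-position frequencies must sum to 1; off at position(s) ",
                 paste(names(sums)[off], collapse = ", ")))
  }
  invisible(freqs)
}

#' Derive a CDR scheme from a residue-frequency table
#'
#' Applies the frequency-threshold fixing rule used to design the library:
#' a candidate position is fixed to its modal residue if and only if that
#' residue's frequency strictly exceeds the threshold (30% for the flanking
#' CDR1/CDR2 positions, 50% for CDR3 in the reference design); every other
#' position is fully randomized over the cysteine-free 19-residue alphabet.
#'
#' @param freqs Tibble with columns `position`, `residue`, `frequency`
#'   (frequencies sum to 1 per position) and optionally `cdr_id`.
#' @param candidate_fixed Integer positions considered for fixing.
#' @param threshold Frequency that must be strictly exceeded, in (0, 1).
#' @param cdr_id Identifier; defaults to the table's `cdr_id` if present.
#' @param alphabet Randomization alphabet.
#' @return A [cdr_scheme()].
#' @export
design_cdr_scheme <- function(freqs, candidate_fixed, threshold,
                              cdr_id = NULL, alphabet = aa_alphabet_19()) {
  if (threshold <= 0 || threshold >= 1) abort("threshold must be in (0, 1)")
  validate_cdr_table(freqs)
  len <- max(freqs$position)
  candidate_fixed <- as.integer(candidate_fixed)
  if (!all(candidate_fixed %in% freqs$position)) {
    abort("candidate_fixed positions must appear in the table")
  }
  cdr_id <- cdr_id %||% (if ("cdr_id" %in% names(freqs)) freqs$cdr_id[1] else "CDR")
  fixed <- character(0)
  for (p in sort(candidate_fixed)) {
    sub <- freqs[freqs$position == p, ]
    sub <- sub[order(-sub$frequency, sub$residue), ]  # modal, alphabetical tie-break
    if (sub$frequency[1] > threshold) {
      fixed[as.character(p)] <- sub$residue[1]
    }
  }
  cdr_scheme(cdr_id, len, fixed, alphabet)
}

#' Full library scheme: framework segments plus three CDR schemes
#'
#' The generative definition of the synthetic library. The displayed protein
#' is FR1 + CDR1 + FR2 + CDR2 + FR3 + CDR3 + FR4; framework and fixed-CDR
#' residues are constant, the remaining CDR positions are randomized.
#'
#' @param framework Named character vector of the four framework segments,
#'   in order (names `FR1`..`FR4`).
#' @param cdrs List of three [cdr_scheme()] objects (CDR1, CDR2, CDR3).
#' @param codon_table Amino acid to codon map used for reverse translation.
#' @return An object of class `library_scheme`.
#' @export
library_scheme <- function(framework, cdrs, codon_table = ecoli_codon_table()) {
  stopifnot(length(framework) == 4, length(cdrs) == 3)
  if (!all(vapply(cdrs, inherits, logical(1), "cdr_scheme"))) {
    abort("cdrs must be cdr_scheme objects")
  }
  framework <- toupper(unname(framework))
  names(framework) <- paste0("FR", 1:4)
  fr_res <- unlist(strsplit(framework, "", fixed = TRUE))
  fixed_res <- unlist(lapply(cdrs, function(cs) cs$fixed))
  needed <- unique(c(fr_res, fixed_res, unlist(lapply(cdrs, `[[`, "alphabet"))))
  missing <- setdiff(needed, names(codon_table))
  if (length(missing) > 0) {
    abort(paste0("codon table lacks residues: ", paste(missing, collapse = ", ")))
  }
  x <- structure(
    list(framework = framework, cdrs = cdrs, codon_table = codon_table),
    class = "library_scheme")
  x
}

#' @export
print.library_scheme <- function(x, ...) {
  cat("<library_scheme>\n")
  cat(sprintf("  protein length %d aa (%d nt); randomized positions: %d\n",
              scheme_protein_length(x), 3L * scheme_protein_length(x),
              sum(vapply(x$cdrs, n_randomized, integer(1)))))
  for (i in 1:4) cat(sprintf("  FR%d %s\n", i, x$framework[i]))
  for (cs in x$cdrs) print(cs)
  invisible(x)
}

#' Length of the assembled protein a scheme encodes
#'
#' @param scheme A [library_scheme()].
#' @return Integer residue count (FR1..FR4 plus the three CDR lengths).
#' @export
scheme_protein_length <- function(scheme) {
  sum(nchar(scheme$framework)) +
    sum(vapply(scheme$cdrs, `[[`, integer(1), "length"))
}

# Per-position template of the assembled protein: constant residues where the
# scheme fixes them, NA at randomized positions; plus a logical framework mask.
scheme_template <- function(scheme) {
  segs <- list(
    fr = strsplit(scheme$framework[["FR1"]], "")[[1]],
    c1 = scheme$cdrs[[1]], fr2 = strsplit(scheme$framework[["FR2"]], "")[[1]],
    c2 = scheme$cdrs[[2]], fr3 = strsplit(scheme$framework[["FR3"]], "")[[1]],
    c3 = scheme$cdrs[[3]], fr4 = strsplit(scheme$framework[["FR4"]], "")[[1]])
  res <- character(0); is_fr <- logical(0)
  for (s in segs) {
    if (inherits(s, "cdr_scheme")) {
      v <- rep(NA_character_, s$length)
      if (length(s$fixed)) v[as.integer(names(s$fixed))] <- s$fixed
      res <- c(res, v); is_fr <- c(is_fr, rep(FALSE, s$length))
    } else {
      res <- c(res, s); is_fr <- c(is_fr, rep(TRUE, length(s)))
    }
  }
  list(residues = res, framework_mask = is_fr)
}

#' Exact theoretical diversity of a library scheme
#'
#' Number of distinct proteins the scheme can encode:
#' `|alphabet| ^ (total randomized positions)`, computed as an exact
#' arbitrary-precision integer (the reference design has 23 randomized
#' positions over 19 residues, far beyond double precision).
#'
#' @param scheme A [library_scheme()].
#' @return A `bigint`; use `format()`/`as.character()` for the exact decimal
#'   digits and `as.numeric()` for an approximation.
#' @examples
#' sc <- default_library_scheme(seed = 1)
#' format(theoretical_diversity(sc))
#' @export
theoretical_diversity <- function(scheme) {
  n_rand <- sum(vapply(scheme$cdrs, n_randomized, integer(1)))
  k <- length(scheme$cdrs[[1]]$alphabet)
  ks <- vapply(scheme$cdrs, function(cs) length(cs$alphabet), integer(1))
  if (length(unique(ks)) == 1L) {
    big_pow(k, n_rand)
  } else {
    Reduce(big_mul, Map(function(cs) big_pow(length(cs$alphabet), n_randomized(cs)),
                        scheme$cdrs))
  }
}

#' Reverse-translate protein sequences with a fixed codon table
#'
#' @param protein Character vector of protein sequences.
#' @param codon_table Named codon map; every residue must be present.
#' @return Character vector of DNA sequences (3x protein length).
#' @examples
#' reverse_translate("GM", c(G = "GGT", M = "ATG"))
#' @export
reverse_translate <- function(protein, codon_table = ecoli_codon_table()) {
  vapply(strsplit(toupper(protein), "", fixed = TRUE), function(res) {
    if (length(res) == 0) return("")
    cod <- codon_table[res]
    if (anyNA(cod)) {
      abort(paste0("no codon for residue(s): ",
                   paste(unique(res[is.na(cod)]), collapse = ", ")))
    }
    paste(cod, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Translate DNA sequences (standard genetic code)
#'
#' Thin vectorized wrapper over Biostrings; trailing bases that do not fill
#' a codon are ignored.
#'
#' @param dna Character vector of DNA sequences.
#' @return Character vector of protein sequences (`*` for stop codons).
#' @export
translate_dna <- function(dna) {
  dna <- toupper(dna)
  trimmed <- substr(dna, 1L, 3L * (nchar(dna) %/% 3L))
  out <- character(length(dna))
  nonempty <- nchar(trimmed) > 0
  if (any(nonempty)) {
    aa <- Biostrings::translate(Biostrings::DNAStringSet(trimmed[nonempty]),
                                no.init.codon = TRUE)
    out[nonempty] <- as.character(aa)
  }
  out
}

#' Sample clones from a library scheme
#'
#' Draws `n` library members: framework and fixed-CDR residues exactly as the
#' scheme dictates, randomized positions uniform over the scheme's alphabet,
#' and the DNA produced by [reverse_translate()].
#'
#' @param scheme A [library_scheme()].
#' @param n Number of clones.
#' @param seed Optional integer seed for reproducibility.
#' @return Tibble with columns `clone_id`, `protein`, `dna`.
#' @examples
#' sample_clones(default_library_scheme(seed = 1), 3, seed = 42)
#' @export
sample_clones <- function(scheme, n, seed = NULL) {
  stopifnot(n >= 0)
  tmpl <- scheme_template(scheme)
  L <- length(tmpl$residues)
  if (n == 0) {
    return(tibble::tibble(clone_id = character(0), protein = character(0),
                          dna = character(0)))
  }
  with_seed(seed, {
    mat <- matrix(rep(tmpl$residues, each = n), nrow = n)
    rand_cols <- which(is.na(tmpl$residues))
    alpha <- scheme$cdrs[[1]]$alphabet
    for (j in rand_cols) {
      mat[, j] <- sample(alpha, n, replace = TRUE)
    }
    protein <- do.call(paste0, asplit(mat, 2))
    # column-wise codon lookup keeps this fast for large n
    cod <- matrix(scheme$codon_table[mat], nrow = n)
    dna <- do.call(paste0, asplit(cod, 2))
    tibble::tibble(
      clone_id = sprintf("clone_%0*d", nchar(as.character(n)), seq_len(n)),
      protein = protein, dna = dna)
  })
}
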