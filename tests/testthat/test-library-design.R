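test_that("consensus takes the modal residue per column with alphabetical ties", {
  expect_equal(consensus_framework(c("QVQLVE", "QVQLVE", "QVQLVE")), "QVQLVE")
  expect_equal(consensus_framework(c("QA", "QV", "QV")), "QV")
  # tie at column 2: A vs V, alphabetical tie-break picks A
  expect_equal(consensus_framework(c("QA", "QV")), "QA")
})

test_that("consensus drops gap-majority columns and handles single rows", {
  # column 3 is gap in 2/3 rows (> 50%): dropped
  expect_equal(consensus_framework(c("QV-L", "QV-L", "QVQL")), "QVL")
  # exactly 50% gaps is kept
  expect_equal(consensus_framework(c("Q-", "QA")), "QA")
  # single-row alignment: the row itself, gaps removed
  expect_equal(consensus_framework("QV-LV-"), "QVLV")
})

test_that("consensus rejects bad input", {
  expect_error(consensus_framework(character(0)), "empty")
  expect_error(consensus_framework(c("QV", "QVL")), "same length")
  expect_error(consensus_framework(c("QZ", "QZ")), "non-amino-acid")
})

test_that("threshold rule fixes exactly the positions whose modal frequency exceeds it", {
  tabs <- default_cdr_tables(seed = 3)
  cdr3 <- design_cdr_scheme(tabs$CDR3, c(1, 12), threshold = 0.5)
  expect_equal(cdr3$fixed, c("1" = "A", "12" = "Y"))
  expect_equal(cdr3$length - length(cdr3$fixed), 10)

  cdr2 <- design_cdr_scheme(tabs$CDR2, c(1, 2, 9, 10), threshold = 0.3)
  expect_equal(cdr2$fixed, c("1" = "A", "2" = "I", "9" = "T", "10" = "Y"))
  expect_equal(cdr2$length - length(cdr2$fixed), 6)

  # a threshold nothing exceeds leaves the scheme fully random
  none <- design_cdr_scheme(tabs$CDR1, c(1, 2, 10), threshold = 0.999)
  expect_length(none$fixed, 0)
  expect_error(design_cdr_scheme(tabs$CDR1, c(1), threshold = 1.2), "threshold")
})

test_that("no position at or below the threshold is ever fixed (property)", {
  set.seed(71)
  for (i in 1:25) {
    len <- sample(4:12, 1)
    tab <- make_cdr_table("x", len)
    th <- runif(1, 0.15, 0.6)
    sch <- design_cdr_scheme(tab, seq_len(len), threshold = th)
    for (p in as.integer(names(sch$fixed))) {
      sub <- tab[tab$position == p, ]
      expect_gt(max(sub$frequency), th)
    }
    # and conversely: every candidate above threshold is fixed
    above <- vapply(seq_len(len), function(p) {
      max(tab$frequency[tab$position == p]) > th
    }, logical(1))
    expect_setequal(as.integer(names(sch$fixed)), which(above))
  }
})

test_that("theoretical diversity is exact and multiplicative", {
  sc1 <- library_scheme(
    c(FR1 = "Q", FR2 = "V", FR3 = "Q", FR4 = "L"),
    list(cdr_scheme("CDR1", 2, c("1" = "G")),
         cdr_scheme("CDR2", 1, c("1" = "A")),
         cdr_scheme("CDR3", 1)))
  expect_equal(format(theoretical_diversity(sc1)), "361")  # 19^2
  # reference design: 23 randomized positions over 19 residues;
  # exact value frozen from an independent big-integer computation
  expect_equal(format(theoretical_diversity(ref_scheme())),
               "257829627945307727248226067259")
})

test_that("diversity equals brute-force enumeration for tiny 3-letter schemes", {
  sc <- library_scheme(
    c(FR1 = "Q", FR2 = "V", FR3 = "Q", FR4 = "L"),
    list(cdr_scheme("CDR1", 2, character(0), alphabet = c("A", "G", "Y")),
         cdr_scheme("CDR2", 1, c("1" = "A"), alphabet = c("A", "G", "Y")),
         cdr_scheme("CDR3", 2, c("1" = "A"), alphabet = c("A", "G", "Y"))),
    codon_table = ecoli_codon_table())
  # 3 randomized positions over {A, G, Y}: enumerate all protein strings
  combos <- expand.grid(p1 = c("A","G","Y"), p2 = c("A","G","Y"),
                        p3 = c("A","G","Y"))
  expect_equal(as.numeric(theoretical_diversity(sc)), nrow(combos))
})

test_that("sampled clones honor the scheme and are seed-reproducible", {
  sc <- tiny_scheme()
  expect_equal(nrow(sample_clones(sc, 0)), 0)
  a <- sample_clones(sc, 50, seed = 9)
  b <- sample_clones(sc, 50, seed = 9)
  expect_identical(a, b)
  tmpl <- puredisplay:::scheme_template(sc)
  fixed_pos <- which(!is.na(tmpl$residues))
  for (i in 1:10) {
    chars <- strsplit(a$protein[i], "")[[1]]
    expect_equal(chars[fixed_pos], tmpl$residues[fixed_pos])
  }
  expect_false(any(grepl("C", substr(a$protein, 5, 8))))  # no Cys in CDR1
})

test_that("randomized residues are uniform over the 19-residue alphabet", {
  sc <- ref_scheme()
  n <- 10000
  cl <- sample_clones(sc, n, seed = 4)
  tmpl <- puredisplay:::scheme_template(sc)
  rand_pos <- which(is.na(tmpl$residues))
  mat <- matrix(unlist(strsplit(cl$protein, "")), nrow = n, byrow = TRUE)
  se <- sqrt((1 / 19) * (18 / 19) / n)
  for (p in sample(rand_pos, 5)) {
    freqs <- table(factor(mat[, p], levels = aa_alphabet_19())) / n
    expect_true(all(abs(freqs - 1 / 19) < 4 * se))
  }
})

test_that("reverse translation concatenates codons and round-trips", {
  expect_equal(reverse_translate("M", c(M = "ATG")), "ATG")
  expect_equal(reverse_translate("GM", c(G = "GGT", M = "ATG")), "GGTATG")
  expect_error(reverse_translate("GZ", c(G = "GGT")), "no codon")
  set.seed(12)
  for (i in 1:10) {
    s <- paste(sample(AA20 <- puredisplay:::AA20, 30, replace = TRUE),
               collapse = "")
    dna <- reverse_translate(s)
    expect_equal(nchar(dna), 3 * nchar(s))
    expect_equal(translate_dna(dna), s)
  }
})

test_that("every unmutated sampled clone passes QC", {
  sc <- ref_scheme()
  cl <- sample_clones(sc, 200, seed = 31)
  expect_true(all(qc_classify(cl, sc)$pass))
})
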