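test_that("reverse_complement complements, reverses, and is an involution", {
  expect_identical(reverse_complement("TTAGGG"), "CCCTAA")
  expect_identical(reverse_complement("TTTAGGG"), "CCCTAAA")
  expect_identical(reverse_complement(""), "")
  expect_identical(reverse_complement("ACGTN"), "NACGT")
  expect_error(reverse_complement("ACGU"), "non-nucleotide")
  set.seed(11)
  for (i in 1:20) {
    s <- rand_seq(sample(1:40, 1))
    expect_identical(reverse_complement(reverse_complement(s)), s)
  }
})

test_that("canonical_rotation is minimal, idempotent and rotation-invariant", {
  expect_identical(canonical_rotation("TTAGGG"), "AGGGTT")
  expect_identical(canonical_rotation("AAAA"), "AAAA")
  expect_error(canonical_rotation(""), "empty")
  set.seed(12)
  for (i in 1:30) {
    u <- rand_seq(sample(2:15, 1))
    cu <- canonical_rotation(u)
    expect_identical(canonical_rotation(cu), cu)
    expect_identical(canonical_rotation(rotate(u, sample(0:14, 1))), cu)
    # minimality against plain enumeration
    expect_identical(cu, min(vapply(seq_len(nchar(u)) - 1L, rotate,
                                    character(1), s = u)))
  }
})

test_that("display_rotation reproduces every published motif spelling", {
  spellings <- c("TTTAGGG", "TTAGGG", "CTCGGTTATGGG", "TTCAGG", "TTTCAGG",
                 "TTTTTTAGGG", "ATTAGGG", "TTTAGG", "TTTACGG")
  for (sp in spellings) {
    for (k in seq_len(nchar(sp)) - 1L) {
      expect_identical(display_rotation(rotate(sp, k)), sp)
    }
  }
  expect_identical(display_rotation("GGTTTAG"), "TTTAGGG")
  expect_identical(display_rotation("ATGGGCTCGGTT"), "CTCGGTTATGGG")
  # no G: documented fallback to the canonical rotation
  expect_identical(display_rotation("TCA"), canonical_rotation("TCA"))
})

test_that("minimal_period matches brute-force oracle exhaustively", {
  expect_identical(minimal_period("CTAAACCCT"), 7L)
  expect_identical(minimal_period("AACCGAGCCCATAACCGA"), 12L)
  expect_identical(minimal_period("AAAA"), 1L)
  # every string of length <= 12 over a 2-letter alphabet
  strs <- all_strings(12, c("A", "C"))
  expect_identical(vapply(strs, minimal_period, integer(1)),
                   vapply(strs, period_oracle, integer(1)))
})

test_that("telomere_motif validates alphabet and primitivity", {
  m <- telomere_motif("CTCGGTTATGGG")
  expect_s3_class(m, "telomere_motif")
  expect_identical(m$length, 12L)
  expect_identical(m$canonical_form, canonical_rotation("CTCGGTTATGGG"))
  expect_identical(m$display_form, "CTCGGTTATGGG")
  expect_error(telomere_motif("AAAAAA"), "primitive")
  expect_error(telomere_motif("TATA"), "primitive")
  expect_error(telomere_motif("TTAXGG"), "non-nucleotide")
  expect_error(telomere_motif(""), "non-empty")
  # any rotation of a primitive unit is accepted and identifies the motif
  expect_identical(telomere_motif("GTTAGG")$canonical_form,
                   telomere_motif("TTAGGG")$canonical_form)
})

test_that("c_strand_unit is the reverse complement of the G-strand unit", {
  expect_identical(c_strand_unit(telomere_motif("TTAGGG")), "CCCTAA")
  expect_identical(c_strand_unit(telomere_motif("TTTAGGG")), "CCCTAAA")
  expect_identical(c_strand_unit(telomere_motif("CTCGGTTATGGG")),
                   "CCCATAACCGAG")
})

test_that("template_permutations generates the minimal-template window sets", {
  expect_setequal(template_permutations("TTAGGG", 1),
                  c("CCCTAAC", "CCTAACC", "CTAACCC", "TAACCCT",
                    "AACCCTA", "ACCCTAA"))
  allium <- template_permutations("CTCGGTTATGGG", 1)
  expect_length(allium, 12L)
  expect_true(all(nchar(allium) == 13L))
  doubled <- strrep("CCCATAACCGAG", 2)
  expect_true(all(vapply(allium, grepl, logical(1), x = doubled,
                         fixed = TRUE)))
  expect_error(template_permutations("TTAGGG", 0), ">= 1")
  expect_warning(template_permutations("TTAGGG", 6), "wrap")
  # |set| == L for primitive motifs, extension < L
  set.seed(13)
  for (i in 1:25) {
    u <- rand_unambiguous_motif(sample(5:15, 1))
    expect_length(template_permutations(u, 1), nchar(u))
  }
})

test_that("predict_telomere_motif reproduces published template/motif pairs", {
  at <- predict_telomere_motif("CTAAACCCT")
  expect_identical(at$predicted_motif$display_form, "TTTAGGG")
  expect_identical(at$period, 7L)
  expect_identical(at$anchor_nt, 2L)
  al <- predict_telomere_motif("AACCGAGCCCATAACCGA")
  expect_identical(al$predicted_motif$display_form, "CTCGGTTATGGG")
  expect_identical(al$period, 12L)
  expect_equal(al$span_units, 1.5)
  expect_identical(al$unit_c, "AACCGAGCCCAT")
  # template mutants and the repeats they template
  mutants <- c(TAAACCTAAACC = "TTTAGG", TAATCCCTAATCC = "ATTAGGG",
               TAAACCGTAAACC = "TTTACGG")
  for (tmpl in names(mutants)) {
    expect_identical(
      predict_telomere_motif(tmpl)$predicted_motif$display_form,
      unname(mutants[tmpl]))
  }
})

test_that("predict_telomere_motif rejects degenerate and aperiodic input", {
  expect_error(predict_telomere_motif("CCCCCCCC"), "degenerate template")
  expect_error(predict_telomere_motif("ACACACACAC", min_unit = 5),
               "degenerate template")
  expect_error(predict_telomere_motif("ACGTTGCAAGCTTGACGATG"),
               "no periodic template")
  expect_error(predict_telomere_motif("CCCTA"), "shorter than")
  expect_error(predict_telomere_motif("CCCTAANCCCTAA"), "template contains N")
})

test_that("template_span measures repeat units and rejects mismatches", {
  expect_equal(template_span("AACCGAGCCCATAACCGA", "CTCGGTTATGGG"), 1.5)
  expect_equal(template_span("CTAAACCCT", "TTTAGGG"), 9 / 7)
  expect_equal(template_span("CCCTAA", "TTAGGG"), 1.0)
  expect_error(template_span("CCCTAAC", "TTTAGGG"), "template/motif mismatch")
})

test_that("enumerate_compatible_motifs reports verified maximal windows", {
  # template carrying both a human-type and an Arabidopsis-type window
  mixed <- "ACCCTAACCCTAAACCCT"
  em <- enumerate_compatible_motifs(mixed, 5, 15)
  expect_true(any(em$motif == "TTAGGG"))
  expect_true(any(em$motif == "TTTAGGG"))
  at <- enumerate_compatible_motifs("CTAAACCCT", 5, 15)
  expect_true(any(at$start == 0L & at$end == 9L & at$motif == "TTTAGGG"))
  # a strict 4-periodic string: odd/non-multiple periods never match, and
  # multiple-of-4 periods give power units, so no window qualifies
  expect_identical(nrow(enumerate_compatible_motifs(strrep("ACGT", 5))), 0L)
  # every reported window re-verifies: p-periodic over its whole extent,
  # maximal, length >= p + 1
  for (tmpl in c(mixed, "CTAAACCCT", "AACCGAGCCCATAACCGA")) {
    em <- enumerate_compatible_motifs(tmpl, 5, 15)
    ch <- strsplit(tmpl, "", fixed = TRUE)[[1]]
    for (r in seq_len(nrow(em))) {
      s <- em$start[r] + 1L; e <- em$end[r]; p <- em$period[r]
      expect_gte(e - s + 1L, p + 1L)
      idx <- s:(e - p)
      expect_true(all(ch[idx] == ch[idx + p]))
      if (s > 1L) expect_false(ch[s - 1L] == ch[s - 1L + p])
      if (e < nchar(tmpl)) expect_false(ch[e + 1L - p] == ch[e + 1L])
    }
  }
})

test_that("random template windows recover the planted motif", {
  set.seed(14)
  for (i in 1:25) {
    u <- rand_unambiguous_motif(sample(5:15, 1))
    m <- telomere_motif(u)
    ext <- sample(1:6, 1)
    rot <- sample(seq_len(nchar(u)) - 1L, 1)
    cu <- rotate(c_strand_unit(m), rot)
    tmpl <- substr(strrep(cu, 3), 1, nchar(u) + ext)
    got <- predict_telomere_motif(tmpl, min_unit = 5, max_unit = 15)
    expect_identical(got$predicted_motif$canonical_form, m$canonical_form)
    expect_identical(got$period, m$length)
  }
})
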