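test_that("find_template_domain locates planted templates and filters junk", {
  # flanks engineered so no spurious window reaches the span filter:
  # poly-G left (power units are skipped), alternating GC right (odd periods
  # never match, even periods give power units)
  tr <- paste0(strrep("G", 60), "CTAAACCCT", strrep("GC", 40))
  cand <- find_template_domain(tr)
  expect_identical(nrow(cand), 1L)
  expect_identical(cand$start, 60L)
  expect_identical(cand$end, 69L)
  expect_identical(cand$motif, "TTTAGGG")
  # a poly-C tract passes no distinct-base / complexity filter
  expect_identical(nrow(find_template_domain(strrep("C", 50))), 0L)
  # Allium-like transcript: top candidate is the 12-bp planted template
  # (its maximal window may extend by chance matches in the flanks)
  spec <- simulation_spec(seed = 301, n_datasets = 1L, decoys_per_dataset = 0L)
  sim <- simulate_datasets(spec)
  tr_seq <- sim$datasets[[1]][[sim$truth$tr$id[1]]]
  top <- find_template_domain(tr_seq)[1, ]
  expect_identical(top$period, 12L)
  expect_lte(top$start, sim$truth$tr$template_start)
  expect_gte(top$end, sim$truth$tr$template_end)
})

test_that("composition_scan flags rich blocks trimmed to their edges", {
  s <- paste0(strrep("G", 20), strrep("A", 100))
  cs <- composition_scan(s)
  g <- cs[cs$feature == "g_rich", ]
  expect_identical(nrow(g), 1L)
  expect_identical(g$start, 0L)
  expect_identical(g$end, 20L)
  expect_equal(g$score, 1)
  # at_rich fires on the poly-A tail
  expect_true(any(cs$feature == "at_rich" & cs$end == 120L))
  # impossible thresholds yield nothing on random sequence
  set.seed(52)
  r <- rand_seq(300)
  none <- composition_scan(r, thresholds = list(g_rich = 1.0, c_rich = 1.0,
                                                at_rich = 1.0))
  expect_identical(nrow(none), 0L)
  expect_error(composition_scan("ACGT", window = 10), "window larger")
})

test_that("build_pwm computes log-odds weights with pseudocount", {
  pwm <- build_pwm(c("TATAAA", "TATATA"), pseudocount = 0.5)
  expect_s3_class(pwm, "pwm")
  expect_identical(pwm$width, 6L)
  # column 5: A and T once each -> (1 + 0.5)/(2 + 2) = 0.375 vs background
  expect_equal(unname(pwm$weights["A", 5]), log2(0.375 / 0.25))
  expect_equal(unname(pwm$weights["T", 5]), log2(0.375 / 0.25))
  expect_equal(unname(pwm$weights["C", 5]), log2(0.125 / 0.25))
  expect_equal(pwm$max_score, sum(apply(pwm$weights, 2, max)))
  expect_error(build_pwm("TATAAA"), "at least 2")
  expect_error(build_pwm(c("TATAAA", "TATA")), "equal-length")
  expect_error(build_pwm(c("TAT-AA", "TATAAA")), "non-nucleotide")
})

test_that("scan_pwm finds planted consensus sites at full score", {
  pwm <- build_pwm(rep("TATAAA", 4))
  set.seed(53)
  s <- paste0(rand_seq(40), "TATAAA", rand_seq(40))
  hits <- scan_pwm(s, pwm, min_fraction_of_max = 0.99)
  expect_true(any(hits$start == 40L & hits$end == 46L))
  expect_equal(max(hits$score), pwm$max_score)
  expect_identical(nrow(scan_pwm(s, pwm, min_fraction_of_max = 1.01)), 0L)
  # minus-strand site found only in both-strand mode
  s2 <- paste0(rand_seq(30), reverse_complement("TATAAA"), rand_seq(30))
  expect_identical(nrow(scan_pwm(s2, pwm, 0.99, "sense")), 0L)
  both <- scan_pwm(s2, pwm, 0.99, "both")
  expect_true(any(both$strand == "-" & both$start == 30L))
  expect_error(scan_pwm("ACG", pwm), "shorter than PWM")
})

test_that("rescanning a reported PWM hit reproduces its stored score", {
  set.seed(54)
  sites <- c("TCCCACATCG", "TCCCACATCG", "TCGCACATCG", "TCCCACTTCG")
  pwm <- build_pwm(sites)
  s <- paste0(rand_seq(25), sites[1], rand_seq(25))
  hits <- scan_pwm(s, pwm, min_fraction_of_max = 0.5)
  for (r in seq_len(nrow(hits))) {
    win <- substr(s, hits$start[r] + 1L, hits$end[r])
    ch <- strsplit(win, "", fixed = TRUE)[[1]]
    manual <- sum(vapply(seq_along(ch), function(k) pwm$weights[ch[k], k],
                         numeric(1)))
    expect_equal(hits$score[r], manual)
  }
})

test_that("find_pol3_terminator finds the first qualifying T-run", {
  t1 <- find_pol3_terminator("ACGTTTTTACG")
  expect_identical(t1$start, 3L)
  expect_identical(t1$end, 8L)
  expect_identical(nrow(find_pol3_terminator("ACGTTT", min_t = 4)), 0L)
  # runs starting beyond the search span are ignored
  far <- paste0(strrep("A", 250), "TTTTTT")
  expect_identical(nrow(find_pol3_terminator(far, search_span = 200)), 0L)
  expect_identical(find_pol3_terminator(far, search_span = 260)$start, 250L)
})

test_that("end_support counts terminal k-mer carrying reads", {
  set.seed(55)
  tr <- rand_seq(240)
  reads5 <- setNames(vapply(1:3, function(i)
    paste0(rand_seq(10), substr(tr, 1, 20), rand_seq(10)), character(1)),
    paste0("r", 1:3))
  expect_identical(end_support(tr, reads5), c(n5 = 3L, n3 = 0L))
  # simulated uniform coverage: counts equal a naive scan and support both
  # ends (long reads, since a read supports an end only by covering it fully)
  reads <- simulate_reads(tr, n = 100, read_len = 200, seed = 56)
  got <- end_support(tr, reads, k = 20)
  k5 <- substr(tr, 1, 20); k3 <- substr(tr, 221, 240)
  naive <- function(kmer) sum(vapply(reads, function(r)
    grepl(kmer, r, fixed = TRUE) ||
      grepl(reverse_complement(kmer), r, fixed = TRUE), logical(1)))
  expect_identical(unname(got["n5"]), naive(k5))
  expect_identical(unname(got["n3"]), naive(k3))
  expect_gt(got[["n5"]], 0L)
  expect_gt(got[["n3"]], 0L)
  # a full-length read supports both ends
  expect_identical(end_support(tr, c(full = tr)), c(n5 = 1L, n3 = 1L))
  expect_error(end_support("ACGT", c(r = "ACGT"), k = 10), "k exceeds")
})

test_that("annotate_tr recovers the full planted gene architecture", {
  gene <- simulate_tr_genes(n = 1, seed = 302)[[1]]
  use_pwm <- build_pwm(c("TCCCACATCG", "TCCCACATCG", "TACCACATCG",
                         "TCCCACATAG"))
  ann <- suppressWarnings(
    annotate_tr(gene$transcript, upstream = gene$upstream,
                downstream = gene$downstream, pwms = list(use = use_pwm)))
  lay <- gene$truth$layout
  tmpl <- ann[ann$feature == "template", ]
  expect_true(any(tmpl$start <= lay$template[1] &
                    tmpl$end >= lay$template[2] &
                    grepl("period=12", tmpl$note)))
  for (feat in c("g_rich", "c_rich", "at_rich")) {
    f <- ann[ann$feature == feat & ann$seqid == "transcript", ]
    expect_gt(nrow(f), 0L)
    # recovered block overlaps the planted block
    expect_true(any(f$start < lay[[feat]][2] & f$end > lay[[feat]][1]))
  }
  use <- ann[ann$feature == "use", ]
  expect_true(any(use$start == gene$truth$use[1]))
  tata <- ann[ann$feature == "tata", ]
  expect_true(any(tata$start == gene$truth$tata[1]))
  term <- ann[ann$feature == "terminator", ]
  expect_identical(c(term$start, term$end), unname(gene$truth$terminator))
  # transcript-only input: promoter/terminator absent, with warnings
  expect_warning(expect_warning(
    ann2 <- annotate_tr(gene$transcript), "upstream"), "downstream")
  expect_false(any(ann2$feature %in% c("use", "tata", "terminator")))
})

test_that("GFF3 export is deterministic and 1-based inclusive", {
  gene <- simulate_tr_genes(n = 1, seed = 303)[[1]]
  ann <- suppressWarnings(annotate_tr(gene$transcript,
                                      upstream = gene$upstream,
                                      downstream = gene$downstream))
  f1 <- tempfile(fileext = ".gff3"); f2 <- tempfile(fileext = ".gff3")
  write_gff3(ann, f1)
  write_gff3(ann, f2)
  expect_identical(readLines(f1), readLines(f2))
  lines <- readLines(f1)
  expect_identical(lines[1], "##gff-version 3")
  body <- read.table(f1, sep = "\t", skip = 1, stringsAsFactors = FALSE)
  expect_identical(body$V4, ann$start + 1L)   # 1-based start
  expect_identical(body$V5, ann$end)          # inclusive end
})
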