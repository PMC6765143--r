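prm <- alignment_params()

test_that("identical datasets are fully shared; 7-mer overlap is not homology", {
  set.seed(41)
  seqs <- setNames(vapply(1:3, function(i) rand_seq(100), character(1)),
                   c("t1", "t2", "t3"))
  pm <- cross_compare(list(A = seqs, B = seqs), prm)
  expect_true(all(pm$matrix$class == "shared_in_all"))
  # sharing only a minimal-template 7-mer fails min_length and stays unique
  only7 <- list(
    A = c(a1 = paste0(rand_seq(60), "ACCCTAA", rand_seq(60))),
    B = c(b1 = paste0(rand_seq(60), "ACCCTAA", rand_seq(60))))
  pm7 <- cross_compare(only7, prm)
  expect_true(all(pm7$matrix$class == "unique"))
  expect_identical(nrow(pm7$hits), 0L)
})

test_that("empty datasets keep their column with all-false presence", {
  set.seed(42)
  seqs <- c(x = rand_seq(80))
  pm <- cross_compare(list(A = seqs, B = seqs, C = character(0)), prm)
  expect_true("C" %in% colnames(pm$matrix))
  expect_true(all(!pm$matrix$C))
  expect_true(all(pm$matrix$class == "shared_in_some"))
})

test_that("planted orthologs in small simulated datasets are shared_in_all", {
  spec <- simulation_spec(seed = 202, n_datasets = 3L,
                          decoys_per_dataset = 60L, divergence = 0.10)
  sim <- simulate_datasets(spec)
  scr <- scan_datasets(sim$datasets, template_permutations(spec$motif, 1))
  pm <- cross_compare(scr$candidates, prm)
  truth <- sim$truth$tr
  for (i in seq_len(nrow(truth))) {
    row <- pm$matrix[pm$matrix$dataset == truth$dataset[i] &
                       pm$matrix$transcript_id == truth$id[i], ]
    expect_identical(row$class, "shared_in_all")
  }
  grp <- classify_and_group(pm, scr$candidates)
  expect_setequal(grp$final$transcript_id, truth$id)
})

test_that("grouping covers all datasets or is excluded; coverage is anti-monotone", {
  set.seed(43)
  fam_all <- rand_seq(120)    # ortholog present in all four datasets
  fam_two <- rand_seq(120)    # ortholog present in only two
  mk <- function(ds, with_two) {
    v <- c(fam_all, if (with_two) fam_two, rand_seq(90))
    setNames(v, sprintf("%s_t%d", ds, seq_along(v)))
  }
  sets4 <- list(A = mk("A", TRUE), B = mk("B", TRUE),
                C = mk("C", FALSE), D = mk("D", FALSE))
  grp4 <- classify_and_group(cross_compare(sets4, prm), sets4)
  final_seqs <- mapply(function(d, id) sets4[[d]][[id]],
                       grp4$final$dataset, grp4$final$transcript_id)
  expect_identical(length(unique(final_seqs)), 1L)
  expect_identical(unname(unique(final_seqs)), fam_all)
  expect_true(any(grp4$groups$n_datasets == 2L))  # fam_two group exists
  # a fifth dataset with no homolog demotes the previously final group
  sets5 <- c(sets4, list(E = c(E_t1 = rand_seq(90))))
  grp5 <- classify_and_group(cross_compare(sets5, prm), sets5)
  expect_identical(nrow(grp5$final), 0L)
  # representative: longest member, ties by smallest id
  g1 <- grp4$groups[grp4$groups$n_datasets == 4L, ][1, ]
  expect_identical(g1$representative, "A_t1")
})

test_that("extend_orthologs ranks hits and distinguishes strict from relaxed", {
  set.seed(44)
  q <- rand_seq(400)
  own <- setNames(c(q, rand_seq(100)), c("self", "other"))
  top <- extend_orthologs(q, own, prm)
  expect_identical(top$transcript_id[1], "self")
  expect_identical(top$score[1], 800L)
  # heavily diverged ortholog: missed by strict +2/-3, found by relaxed +1/-1
  div <- teloseeker:::.mutate(q, 0.42)
  tgt <- c(hom = div, bg = rand_seq(400))
  strict <- extend_orthologs(q, tgt, prm, relaxed = FALSE)
  relaxed <- extend_orthologs(q, tgt, prm, relaxed = TRUE)
  expect_false("hom" %in% strict$transcript_id)
  expect_true("hom" %in% relaxed$transcript_id)
  # template-window annotation flags transcripts with periodic windows
  tr_like <- c(tr = paste0(rand_seq(40), "CCCTAACCCTAACC", rand_seq(40)))
  hit <- extend_orthologs(tr_like[["tr"]], tr_like, prm)
  expect_true(hit$has_template_window[1])
  expect_identical(nrow(extend_orthologs(q, c(none = rand_seq(60)), prm)), 0L)
})

test_that("identity_to_consensus follows the majority/tie rules", {
  two <- c(s1 = "ACGTACGT", s2 = "ACGTACGT")
  idc <- identity_to_consensus(two)
  expect_identical(idc$consensus, "ACGTACGT")
  expect_equal(unname(idc$per_sequence), c(1, 1))
  gapped <- c(r1 = "AC-T", r2 = "ACGT")
  idg <- identity_to_consensus(gapped)
  expect_identical(idg$consensus, "ACGT")
  expect_equal(unname(idg$per_sequence), c(1, 1))  # 3/3 and 4/4
  # tie in a column resolves alphabetically
  tie <- c(a = "AT", b = "CT")
  expect_identical(identity_to_consensus(tie)$consensus, "AT")
  expect_error(identity_to_consensus(c(x = "ACG", y = "AC")), "ragged")
  expect_equal(mean_pairwise_identity(two), 1)
  expect_equal(mean_pairwise_identity(gapped), 1)  # both non-gap columns match
})

test_that("simulated 15% substitution gives ~85% identity to consensus", {
  set.seed(45)
  anc <- rand_seq(400)
  fam <- setNames(vapply(1:4, function(i) teloseeker:::.mutate(anc, 0.15),
                         character(1)), paste0("m", 1:4))
  idc <- identity_to_consensus(fam)
  expect_gt(idc$mean, 0.80)
  expect_lt(idc$mean, 0.92)
})
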