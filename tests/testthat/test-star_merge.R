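mk_aln <- function(cr, or) {
  structure(list(center_row = cr, other_row = or, score = 0),
            class = "pairwise_alignment")
}

test_that("merge_gap_profiles takes the pointwise maximum", {
  p <- merge_gap_profiles(list(data.frame(pos = 1L, len = 1L),
                               data.frame(pos = 4L, len = 1L)),
                          center_len = 4L)
  expect_equal(as.integer(p), c(0L, 1L, 0L, 0L, 1L))

  p2 <- merge_gap_profiles(list(data.frame(pos = 1L, len = 2L),
                                data.frame(pos = 1L, len = 3L)),
                           center_len = 4L)
  expect_equal(as.integer(p2), c(0L, 3L, 0L, 0L, 0L))

  expect_equal(as.integer(merge_gap_profiles(list(), 4L)), rep(0L, 5L))
  expect_error(merge_gap_profiles(list(data.frame(pos = 9L, len = 1L)), 4L),
               "outside")
})

test_that("apply_profile re-pads rows against the merged profile", {
  prof1 <- merge_gap_profiles(list(data.frame(pos = 1L, len = 1L)), 4L)
  expect_equal(apply_profile(mk_aln("A-CGT", "AACGT"), prof1), "AACGT")
  expect_equal(apply_profile(mk_aln("ACGT", "ACGT"), prof1), "A-CGT")

  prof2 <- merge_gap_profiles(list(data.frame(pos = c(1L, 4L),
                                              len = c(1L, 1L))), 4L)
  expect_equal(apply_profile(mk_aln("ACGT-", "ACGTT"), prof2), "A-CGTT")

  # profile must dominate the pair's own runs
  small <- merge_gap_profiles(list(data.frame(pos = 1L, len = 1L)), 4L)
  expect_error(apply_profile(mk_aln("A--CGT", "AAACGT"), small), "smaller")
})

test_that("assemble produces a consistent star MSA", {
  d <- msa_dataset(c("ACGT", "AACGT", "ACGTT"))
  alns <- list(nw_align("ACGT", "AACGT"), nw_align("ACGT", "ACGTT"))
  msa <- assemble(d, 0L, alns)
  expect_valid_msa(msa, d)
  expect_equal(nchar(msa$rows[1]), 6L)

  same <- msa_dataset(rep("ACGTACGT", 4))
  alns <- lapply(2:4, function(i) nw_align(same$seq[1], same$seq[i]))
  msa0 <- assemble(same, 0L, alns)
  expect_equal(unique(msa0$rows), "ACGTACGT")

  two <- msa_dataset(c("ACGT", "AGT"))
  aln <- nw_align("ACGT", "AGT")
  msa2 <- assemble(two, 0L, list(aln))
  expect_identical(msa2$rows, c(aln$center_row, aln$other_row))
})

test_that("MSA width equals center length plus merged profile mass", {
  set.seed(71)
  for (rep in 1:15) {
    gen <- generate_sequences(sim_config(n = sample(3:12, 1),
                                         length = sample(40:120, 1),
                                         sub_rate = 0.04, ins_rate = 0.01,
                                         del_rate = 0.01, seed = 100 + rep))
    d <- gen$data
    ci <- as.integer(select_center(d))
    center <- d$seq[ci + 1L]
    others <- setdiff(seq_len(n_seq(d)), ci + 1L)
    alns <- lapply(others, function(i) nw_align(center, d$seq[i]))
    profile <- merge_gap_profiles(lapply(alns, gap_insertions),
                                  nchar(center))
    msa <- assemble(d, ci, alns)
    expect_valid_msa(msa, d)
    expect_equal(nchar(msa$rows[1]), nchar(center) + sum(profile))
    # no all-gap columns
    mat <- do.call(rbind, strsplit(msa$rows, NULL))
    expect_true(all(colSums(mat != "-") > 0))
    # idempotence: re-assembling identical inputs gives identical bytes
    expect_identical(assemble(d, ci, alns), msa)
  }
})
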