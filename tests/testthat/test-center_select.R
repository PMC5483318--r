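test_that("encode_segment reproduces the worked 16-bit codes", {
  expect_identical(encode_segment("ATCGCGAT"), 7905L)
  expect_identical(encode_segment("AAAAAAAA"), 0L)
  expect_identical(encode_segment("CCCCCCCC"), 65535L)
  expect_identical(encode_segment("GGGGGGGG"), 43690L)   # 0xAAAA
  # prose mapping (A,T,C,G -> 0,1,2,3) yields a different code
  expect_identical(encode_segment("ATCGCGAT", mapping = "prose"), 7089L)
  expect_error(encode_segment("ACGT"), "8 characters")
  expect_error(encode_segment("ATCGCGAN"), "outside")
})

test_that("segment_codes uses disjoint windows and drops the remainder", {
  expect_identical(segment_codes("ATCGCGATATCGCGAT"), c(7905L, 7905L))
  expect_length(segment_codes("ATCGCGATAT"), 1L)   # 2 trailing chars dropped
  expect_identical(segment_codes("ATCGCGA"), integer(0))
  # ambiguous characters kept by the skip-segment policy drop their segment
  expect_identical(segment_codes("ATCGCGANATCGCGAT"), 7905L)
})

test_that("occurrence table counts each sequence at most once per code", {
  d <- msa_dataset(c("ATCGCGAT", "ATCGCGAT"))
  occ <- build_occurrence_table(d)
  expect_identical(unclass(occ)[7906L], 2L)
  expect_identical(sum(occ), 2L)

  d2 <- msa_dataset("ATCGCGATATCGCGAT")   # same segment twice in one record
  expect_identical(unclass(build_occurrence_table(d2))[7906L], 1L)

  d3 <- msa_dataset(c("ACGT", "ACG"))     # all shorter than one segment
  expect_identical(sum(build_occurrence_table(d3)), 0L)
})

test_that("similarity scores follow the accumulation formula", {
  d <- msa_dataset(c("ATCGCGAT", "ATCGCGAT", "AAAAAAAA"))
  expect_equal(as.numeric(similarity_scores(d)), c(2, 2, 1))
  # all-distinct segments in a lone sequence score p (self-occurrences)
  lone <- msa_dataset("AAAAAAAACCCCCCCC")
  expect_equal(as.numeric(similarity_scores(lone)), 2)
  expect_equal(as.numeric(similarity_scores(msa_dataset(c("ACGT", "ACG")))),
               c(0, 0))
  # self-exclusion removes one count per accumulated term
  expect_equal(as.numeric(similarity_scores(d, include_self = FALSE)),
               c(1, 1, 0))
})

test_that("select_center maximizes SS with smallest-index ties", {
  d <- msa_dataset(c("ATCGCGAT", "ATCGCGAT", "AAAAAAAA"))
  expect_identical(as.integer(select_center(d)), 0L)
  same <- msa_dataset(rep("ACGTACGTACGTACGT", 4))
  expect_identical(as.integer(select_center(same)), 0L)
  set.seed(5)
  uniq <- random_seq(8)
  pairset <- msa_dataset(c(uniq, "TTTTGGGG", "TTTTGGGG"))
  expect_identical(as.integer(select_center(pairset)), 1L)
  expect_error(select_center(msa_dataset("ACGT")), "at least 2")
})

test_that("bitmap Occ/SS agree exactly with the dictionary oracle", {
  set.seed(31)
  for (rep in 1:40) {
    d <- random_dataset(sample(2:30, 1), 120)
    occ <- build_occurrence_table(d)
    ss <- similarity_scores(d, occ)
    oracle <- oracle_occ_ss(d$seq)
    expect_equal(as.numeric(ss), oracle$ss)
    expect_identical(sum(occ), sum(as.integer(oracle$counts)))
    if (length(oracle$counts)) {
      codes <- vapply(names(oracle$counts), encode_segment, integer(1))
      expect_identical(unclass(occ)[codes + 1L],
                       as.integer(oracle$counts))
    }
    expect_true(max(occ) <= n_seq(d))
  }
})

test_that("permuting the dataset permutes SS and keeps the same center", {
  set.seed(37)
  for (rep in 1:10) {
    d <- random_dataset(sample(3:20, 1), 100)
    ss <- as.numeric(similarity_scores(d))
    perm <- sample(n_seq(d))
    dp <- msa_dataset(d$seq[perm], id = d$id[perm])
    expect_equal(as.numeric(similarity_scores(dp)), ss[perm])
    if (sum(ss == max(ss)) == 1L) {
      expect_identical(dp$seq[as.integer(select_center(dp)) + 1L],
                       d$seq[as.integer(select_center(d)) + 1L])
    }
  }
})

test_that("table operations stay linear in the number of segments", {
  set.seed(41)
  d <- random_dataset(200, 64)
  occ <- build_occurrence_table(d)
  ss <- similarity_scores(d, occ)
  total_segments <- sum(nchar(d$seq) %/% 8L)
  ops <- attr(occ, "n_updates") + attr(ss, "n_lookups")
  expect_lte(ops, 2L * total_segments)
})
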