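# independent oracles and fixture generators shared across tests

random_seq <- function(len) {
  if (len == 0L) return("")
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

random_dataset <- function(n, max_len, min_len = 1L) {
  msa_dataset(vapply(sample(min_len:max_len, n, replace = TRUE),
                     random_seq, character(1)))
}

# dictionary-count oracle for the occurrence table and similarity scores:
# maps each distinct 8-character window *text* to the number of sequences
# containing it, never touching the 2-bit encoding.
oracle_occ_ss <- function(seqs) {
  segs <- lapply(seqs, function(s) {
    p <- nchar(s) %/% 8L
    if (p == 0L) return(character(0))
    substring(s, seq(1L, by = 8L, length.out = p),
              seq(8L, by = 8L, length.out = p))
  })
  counts <- table(unlist(lapply(segs, unique)))
  ss <- vapply(segs, function(sg) {
    if (!length(sg)) 0 else sum(as.integer(counts[sg]))
  }, numeric(1))
  list(counts = counts, ss = ss)
}

# exhaustive recursive enumeration of all global alignments (no
# memoization): the brute-force optimum for tiny sequences.
oracle_nw_score <- function(a, b, scheme = scoring_scheme()) {
  av <- strsplit(a, NULL)[[1L]]; bv <- strsplit(b, NULL)[[1L]]
  rec <- function(i, j) {
    if (i == 0L && j == 0L) return(0)
    best <- -Inf
    if (i > 0L && j > 0L) {
      sc <- if (av[i] == bv[j]) scheme$match else scheme$mismatch
      best <- max(best, rec(i - 1L, j - 1L) + sc)
    }
    if (i > 0L) best <- max(best, rec(i - 1L, j) + scheme$gap)
    if (j > 0L) best <- max(best, rec(i, j - 1L) + scheme$gap)
    best
  }
  rec(length(av), length(bv))
}

# O(n^2 * width) brute-force sum-of-pairs loop
oracle_sp <- function(rows, scheme = scoring_scheme()) {
  n <- length(rows)
  mat <- do.call(rbind, strsplit(rows, NULL))
  total <- 0
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    for (c in seq_len(ncol(mat))) {
      x <- mat[i, c]; y <- mat[j, c]
      total <- total +
        if (x == "-" && y == "-") 0
        else if (x == "-" || y == "-") scheme$gap
        else if (x == y) scheme$match
        else scheme$mismatch
    }
  }
  list(sp_total = total, sp_average = total / n)
}

# a mutated copy of `seq` (substitutions only), for similar-pair fixtures
mutate_seq <- function(seq, sub_rate) {
  ch <- strsplit(seq, NULL)[[1L]]
  hit <- runif(length(ch)) < sub_rate
  ch[hit] <- vapply(ch[hit], function(x) {
    sample(setdiff(c("A", "C", "G", "T"), x), 1L)
  }, character(1))
  paste(ch, collapse = "")
}

expect_valid_msa <- function(msa, data) {
  expect_s3_class(msa, "star_msa")
  expect_length(msa$rows, n_seq(data))
  expect_length(unique(nchar(msa$rows)), 1L)
  expect_identical(gsub("-", "", msa$rows, fixed = TRUE), data$seq)
  expect_identical(msa$id, data$id)
}
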