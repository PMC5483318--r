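#' Configuration for the similar-sequence simulator
#'
#' The generator emulates the regime the center-star method targets: `n`
#' highly similar sequences derived independently from one common ancestor
#' (star topology) by point substitutions and short indels. Defaults
#' describe a typical high-similarity nucleotide dataset: ancestor length
#' 252 nt, 2% per-site substitution probability, 0.5% per-site indel
#' initiation with geometric lengths of mean 2.
#'
#' @param n number of derived sequences (>= 1)
#' @param length ancestor length in residues (>= 1)
#' @param sub_rate per-site substitution probability in `[0, 1)`
#' @param ins_rate,del_rate per-site indel initiation probabilities in
#'   `[0, 1)`
#' @param indel_len_mean mean of the geometric indel length (>= 1)
#' @param seed RNG seed; identical config implies byte-identical output
#' @return an object of class `"sim_config"`
#' @export
sim_config <- function(n = 100L, length = 252L, sub_rate = 0.02,
                       ins_rate = 0.005, del_rate = 0.005,
                       indel_len_mean = 2, seed = 1L) {
  rates <- c(sub_rate, ins_rate, del_rate)
  if (any(rates < 0) || any(rates >= 1))
    stop("rates must lie in [0, 1)")
  stopifnot(n >= 1L, length >= 1L, indel_len_mean >= 1)
  structure(list(n = as.integer(n), length = as.integer(length),
                 sub_rate = sub_rate, ins_rate = ins_rate,
                 del_rate = del_rate, indel_len_mean = indel_len_mean,
                 seed = as.integer(seed)),
            class = "sim_config")
}

ALPHABET <- c("A", "C", "G", "T")

# geometric run length with mean mu (support >= 1)
rgeom_len <- function(k, mu) rgeom(k, prob = 1 / mu) + 1L

derive_one <- function(anc_code, cfg) {
  L <- length(anc_code)
  code <- anc_code
  sub <- runif(L) < cfg$sub_rate
  if (any(sub))
    code[sub] <- (code[sub] + sample.int(3L, sum(sub), replace = TRUE)) %% 4L
  keep <- rep(TRUE, L)
  if (cfg$del_rate > 0) {
    starts <- which(runif(L) < cfg$del_rate)
    if (length(starts)) {
      lens <- rgeom_len(length(starts), cfg$indel_len_mean)
      for (t in seq_along(starts))
        keep[starts[t]:min(L, starts[t] + lens[t] - 1L)] <- FALSE
    }
  }
  ins <- character(L + 1L)
  if (cfg$ins_rate > 0) {
    pts <- which(runif(L + 1L) < cfg$ins_rate)
    if (length(pts)) {
      lens <- rgeom_len(length(pts), cfg$indel_len_mean)
      for (t in seq_along(pts))
        ins[pts[t]] <- paste(ALPHABET[sample.int(4L, lens[t],
                                                 replace = TRUE)],
                             collapse = "")
    }
  }
  ch <- ifelse(keep, ALPHABET[code + 1L], "")
  paste0(paste0(ins[seq_len(L)], ch, collapse = ""), ins[L + 1L])
}

#' Generate a synthetic dataset of highly similar sequences
#'
#' Draws a uniform-random ancestor over `{A,C,G,T}` and derives `n`
#' sequences independently: each site is substituted with `sub_rate`
#' (uniformly over the 3 alternatives), deletion runs start with
#' `del_rate`, and insertion runs (uniform residues) start with `ins_rate`
#' before each site and at the end; run lengths are geometric with mean
#' `indel_len_mean`. Deterministic under `cfg$seed`.
#'
#' @param cfg a [sim_config()]
#' @return list with `data` (an `msa_dataset` of the `n` derived
#'   sequences), `ancestor` (character scalar), and `config`
#' @export
generate_sequences <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  anc_code <- sample.int(4L, cfg$length, replace = TRUE) - 1L
  seqs <- vapply(seq_len(cfg$n), function(i) derive_one(anc_code, cfg),
                 character(1))
  list(data = msa_dataset(seqs),
       ancestor = paste(ALPHABET[anc_code + 1L], collapse = ""),
       config = cfg)
}
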