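#' Scoring scheme for pairwise alignment and SP scoring
#'
#' Linear gap penalty; defaults match = +1, mismatch = -1, gap = -2. The
#' constraints `match > mismatch` and `gap < match` keep the alignment
#' non-degenerate.
#'
#' @param match score of an identical residue pair
#' @param mismatch score of a differing residue pair
#' @param gap penalty for a residue-gap column (applied per gap character)
#' @return an object of class `"scoring_scheme"`
#' @export
scoring_scheme <- function(match = 1, mismatch = -1, gap = -2) {
  stopifnot(is.numeric(match), is.numeric(mismatch), is.numeric(gap))
  if (match <= mismatch) stop("match score must exceed mismatch score")
  if (gap >= match) stop("gap penalty must be below the match score")
  structure(list(match = match, mismatch = mismatch, gap = gap),
            class = "scoring_scheme")
}

new_pairwise_alignment <- function(center_row, other_row, score) {
  structure(list(center_row = center_row, other_row = other_row,
                 score = score),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("pairwise alignment, score %g\n  %s\n  %s\n",
              x$score, x$center_row, x$other_row))
  invisible(x)
}

#' Global pairwise alignment (Needleman-Wunsch)
#'
#' Full dynamic-programming global alignment with linear gap penalty.
#' Backtrace ties are resolved in the fixed order diagonal, then up (gap in
#' `other`), then left (gap in `center`), so results are bit-reproducible.
#'
#' @param center residues of the center sequence (character scalar)
#' @param other residues of the sequence aligned against it
#' @param scheme a [scoring_scheme()]
#' @return a `"pairwise_alignment"`: equal-length gapped rows `center_row`
#'   and `other_row` plus the optimal `score`
#' @export
#' @examples
#' nw_align("ACGT", "AGT")   # score 1
nw_align <- function(center, other, scheme = scoring_scheme()) {
  stopifnot(is.character(center), length(center) == 1L,
            is.character(other), length(other) == 1L,
            inherits(scheme, "scoring_scheme"))
  la <- nchar(center); lb <- nchar(other)
  res <- .nw_core(center, other, scheme$match, scheme$mismatch,
                  scheme$gap, -(la + 1L), lb + 1L)
  new_pairwise_alignment(res$row_a, res$row_b, res$score)
}

#' Banded global alignment (k-band)
#'
#' Restricts the dynamic program to a diagonal band of half-width `k`
#' around the main diagonal (corrected for the length difference), which
#' is sufficient for highly similar sequences. The band is widened
#' (`k` doubled and the alignment recomputed) until either it covers the
#' whole table or the in-band optimum is certified globally optimal:
#' the backtraced path must not touch the band boundary *and* the in-band
#' score must strictly exceed the upper bound
#' `match * max(0, min(la, lb) - (k + 1)) + gap * (|la - lb| + 2(k + 1))`
#' attainable by any path leaving the band (such a path needs at least
#' `|la - lb| + 2(k + 1)` gap columns and so at most
#' `min(la, lb) - (k + 1)` residue pairs). Under that certificate every
#' optimal path lies in the band and the banded backtrace reproduces the
#' full-table one, so the result equals [nw_align()] exactly (rows and
#' score).
#'
#' @inheritParams nw_align
#' @param k initial half-band width (>= 1); default
#'   `max(abs(nchar(center) - nchar(other)) + 1, 8)`
#' @return a `"pairwise_alignment"`, identical to the full-table result
#' @export
kband_align <- function(center, other, scheme = scoring_scheme(), k = NULL) {
  stopifnot(is.character(center), length(center) == 1L,
            is.character(other), length(other) == 1L,
            inherits(scheme, "scoring_scheme"))
  la <- nchar(center); lb <- nchar(other)
  if (is.null(k)) k <- max(abs(la - lb) + 1L, 8L)
  k <- as.integer(k)
  if (k < 1L) stop("band half-width k must be >= 1")
  delta <- lb - la
  repeat {
    if (k >= max(la, lb)) return(nw_align(center, other, scheme))
    lo <- min(0L, delta) - k
    hi <- max(0L, delta) + k
    res <- .nw_core(center, other, scheme$match, scheme$mismatch,
                    scheme$gap, lo, hi)
    escape_bound <- scheme$match * max(0L, min(la, lb) - (k + 1L)) +
      scheme$gap * (abs(delta) + 2L * (k + 1L))
    if (!res$touched && res$score > escape_bound)
      return(new_pairwise_alignment(res$row_a, res$row_b, res$score))
    k <- 2L * k
  }
}

#' Gap insertions demanded by a pairwise alignment
#'
#' Extracts the maximal runs of `-` in the center row: each run is
#' reported as the 0-based index of the center residue *before which* it
#' is inserted (index `nchar(center)` for a trailing run) together with
#' its length.
#'
#' @param aln a `"pairwise_alignment"`
#' @return data.frame with integer columns `pos` and `len` (0 rows for a
#'   gap-free center row)
#' @export
gap_insertions <- function(aln) {
  stopifnot(inherits(aln, "pairwise_alignment"))
  chars <- strsplit(aln$center_row, NULL)[[1L]]
  pos <- integer(0); len <- integer(0)
  res_idx <- 0L; run <- 0L
  for (ch in chars) {
    if (ch == "-") {
      run <- run + 1L
    } else {
      if (run > 0L) { pos <- c(pos, res_idx); len <- c(len, run); run <- 0L }
      res_idx <- res_idx + 1L
    }
  }
  if (run > 0L) { pos <- c(pos, res_idx); len <- c(len, run) }
  data.frame(pos = pos, len = len)
}
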