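#' Merge per-pair gap insertions into a gap profile on the center
#'
#' The profile records, for every insertion point on the center sequence
#' (0-based residue index; index `center_len` is the trailing point), the
#' *maximum* gap run length demanded by any pairwise alignment there.
#' Aggregating the inserted spaces by maximum (rather than literal
#' addition) is the standard center-star construction: it yields the
#' narrowest set of columns accommodating every pairwise alignment.
#'
#' @param per_pair list of gap-insertion tables as returned by
#'   [gap_insertions()] (data.frames with `pos`, `len`)
#' @param center_len length of the ungapped center sequence
#' @return integer vector of length `center_len + 1` (entry `p + 1` is the
#'   gap count inserted before center residue `p`), class `"gap_profile"`
#' @export
merge_gap_profiles <- function(per_pair, center_len) {
  stopifnot(is.list(per_pair), center_len >= 0L)
  profile <- integer(center_len + 1L)
  for (ins in per_pair) {
    if (NROW(ins) == 0L) next
    if (any(ins$pos < 0L) || any(ins$pos > center_len))
      stop("gap insertion point outside [0, center length]")
    idx <- ins$pos + 1L
    profile[idx] <- pmax(profile[idx], ins$len)
  }
  structure(profile, class = "gap_profile")
}

#' Re-pad one pairwise alignment to the merged gap profile
#'
#' Expands the `other` row of a center/other pairwise alignment so that
#' exactly `profile[p]` gap columns precede center residue `p`. Within an
#' expanded gap block the pair's own characters are left-justified and the
#' remainder filled with `-`. Degapping the result reproduces the original
#' `other` sequence.
#'
#' @param aln a `"pairwise_alignment"` of the center against one sequence
#' @param profile a `"gap_profile"` at least as large, pointwise, as the
#'   alignment's own insertions
#' @return the re-padded `other` row (character scalar)
#' @export
apply_profile <- function(aln, profile) {
  stopifnot(inherits(aln, "pairwise_alignment"))
  prof <- as.integer(profile)
  cc <- strsplit(aln$center_row, NULL)[[1L]]
  oc <- strsplit(aln$other_row, NULL)[[1L]]
  center_len <- length(prof) - 1L
  # other-row characters aligned to the gap run before each center residue
  pending <- character(center_len + 1L); pending[] <- ""
  match_char <- character(center_len)
  p <- 0L
  for (i in seq_along(cc)) {
    if (cc[i] == "-") {
      pending[p + 1L] <- paste0(pending[p + 1L], oc[i])
    } else {
      p <- p + 1L
      match_char[p] <- oc[i]
    }
  }
  if (p != center_len)
    stop("profile length does not match the alignment's center sequence")
  own <- nchar(pending)
  if (any(own > prof))
    stop("gap profile is smaller than this pair's own insertion run")
  blocks <- paste0(pending, strrep("-", prof - own))
  parts <- character(2L * center_len + 1L)
  parts[seq(1L, by = 2L, length.out = center_len + 1L)] <- blocks
  if (center_len > 0L)
    parts[seq(2L, by = 2L, length.out = center_len)] <- match_char
  paste(parts, collapse = "")
}

# center residues expanded by the merged profile
expand_center <- function(center, profile) {
  prof <- as.integer(profile)
  cc <- strsplit(center, NULL)[[1L]]
  parts <- character(2L * length(cc) + 1L)
  parts[seq(1L, by = 2L, length.out = length(cc) + 1L)] <- strrep("-", prof)
  if (length(cc) > 0L)
    parts[seq(2L, by = 2L, length.out = length(cc))] <- cc
  paste(parts, collapse = "")
}

#' Assemble the final multiple alignment from pairwise results
#'
#' Merges the gap insertions of all center/other alignments into one
#' profile, expands the center accordingly, and re-pads every other row.
#' Row order equals dataset order; every row degaps back to its input
#' sequence and all rows share the width
#' `nchar(center) + sum(profile)`.
#'
#' @param data the input `msa_dataset`
#' @param center_index 0-based index of the center sequence
#' @param alignments list of `"pairwise_alignment"` objects, one per
#'   non-center sequence, in dataset order
#' @return an object of class `"star_msa"`: fields `id`, `rows` (gapped,
#'   equal length), `center_index`
#' @export
assemble <- function(data, center_index, alignments) {
  stopifnot(inherits(data, "msa_dataset"))
  n <- n_seq(data)
  ci <- as.integer(center_index)
  if (ci < 0L || ci >= n) stop("center index out of range")
  if (length(alignments) != n - 1L)
    stop("need one pairwise alignment per non-center sequence")
  center <- data$seq[ci + 1L]
  ins <- lapply(alignments, gap_insertions)
  profile <- merge_gap_profiles(ins, nchar(center))
  rows <- character(n)
  rows[ci + 1L] <- expand_center(center, profile)
  others <- setdiff(seq_len(n), ci + 1L)
  for (t in seq_along(others))
    rows[others[t]] <- apply_profile(alignments[[t]], profile)
  widths <- nchar(rows)
  if (length(unique(widths)) != 1L)
    stop("internal consistency failure: ragged alignment rows")
  structure(list(id = data$id, rows = rows, center_index = ci),
            class = "star_msa")
}

#' @export
print.star_msa <- function(x, ...) {
  cat(sprintf("star MSA: %d rows, width %d, center row %d\n",
              length(x$rows), nchar(x$rows[1L]), x$center_index))
  show <- head(seq_along(x$rows), 8L)
  for (i in show) {
    mark <- if (i - 1L == x$center_index) "*" else " "
    cat(sprintf(" %s%-12s %s\n", mark, x$id[i],
                if (nchar(x$rows[i]) > 60) paste0(substr(x$rows[i], 1, 57), "...")
                else x$rows[i]))
  }
  if (length(x$rows) > 8L) cat(sprintf("  ... and %d more\n",
                                       length(x$rows) - 8L))
  invisible(x)
}

#' Run the whole center-star pipeline on a dataset
#'
#' Convenience wrapper: selects the center (unless overridden), aligns
#' every other sequence against it — serially or on two worker pools —
#' and assembles the final MSA. The result carries a `"report"` attribute
#' with the center index, its SS, the workload partition and the MSA
#' width.
#'
#' @param data an `msa_dataset` with at least 2 sequences
#' @param scheme a [scoring_scheme()]
#' @param center optional 0-based center override
#' @param band optional k-band half-width (`NULL` = full-table DP)
#' @param pool1,pool2 [worker_pool()]s; defaults run serially
#' @param ratio optional fixed capability ratio `R = t1/t2` (skips
#'   measurement)
#' @param mapping residue mapping for center selection
#' @return a `"star_msa"` with attribute `"report"`
#' @export
align_star <- function(data, scheme = scoring_scheme(), center = NULL,
                       band = NULL, pool1 = worker_pool(1L),
                       pool2 = worker_pool(0L), ratio = NULL,
                       mapping = "table2") {
  stopifnot(inherits(data, "msa_dataset"))
  if (n_seq(data) < 2L) stop("need at least 2 sequences to align")
  ss_center <- NA_real_
  if (is.null(center)) {
    center <- select_center(data, mapping = mapping)
    ss_center <- attr(center, "ss")[as.integer(center) + 1L]
  }
  run <- run_corun(data, center, scheme = scheme, band = band,
                   pool1 = pool1, pool2 = pool2, ratio = ratio)
  msa <- assemble(data, center, run$alignments)
  attr(msa, "report") <- list(center_index = as.integer(center),
                              ss_center = ss_center,
                              n1 = run$n1, n2 = run$n2, ratio = run$ratio,
                              width = nchar(msa$rows[1L]))
  msa
}
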