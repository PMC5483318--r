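#' Residue-to-2-bit code mappings
#'
#' The default `"table2"` mapping (A=00, T=01, G=10, C=11) reproduces the
#' worked encoding example "ATCGCGAT" -> 7905; the alternative `"prose"`
#' mapping (A=00, T=01, C=10, G=11) gives 7089 for the same segment. A
#' custom mapping may be supplied as a named integer vector assigning the
#' values 0:3 to A, C, G, T.
#'
#' @param mapping `"table2"`, `"prose"`, or a named integer vector
#' @return named integer vector over A, C, G, T with values 0..3
#' @export
residue_mapping <- function(mapping = "table2") {
  if (is.character(mapping) && length(mapping) == 1L) {
    mapping <- switch(mapping,
      table2 = c(A = 0L, T = 1L, G = 2L, C = 3L),
      prose  = c(A = 0L, T = 1L, C = 2L, G = 3L),
      stop(sprintf("unknown mapping '%s'", mapping)))
  }
  mapping <- mapping[c("A", "C", "G", "T")]
  if (anyNA(mapping) || !setequal(mapping, 0:3))
    stop("mapping must assign the values 0..3 to A, C, G, T")
  storage.mode(mapping) <- "integer"
  mapping
}

#' Encode one 8-character segment as a 16-bit integer
#'
#' Each residue contributes 2 bits; codes are concatenated left to right,
#' first character in the most significant position, giving a value in
#' `[0, 65535]`.
#'
#' @param segment character scalar of exactly 8 residues over A, C, G, T
#' @param mapping see [residue_mapping()]
#' @return integer segment code
#' @export
#' @examples
#' encode_segment("ATCGCGAT")   # 7905
encode_segment <- function(segment, mapping = "table2") {
  stopifnot(is.character(segment), length(segment) == 1L)
  if (nchar(segment) != 8L)
    stop(sprintf("segment must have exactly 8 characters, got %d",
                 nchar(segment)))
  m <- residue_mapping(mapping)
  v <- m[strsplit(segment, NULL)[[1L]]]
  if (anyNA(v)) stop("segment contains characters outside {A,C,G,T}")
  as.integer(sum(v * 4^(7:0)))
}

# codes of consecutive disjoint 8-mers for a whole character vector of
# sequences at once; trailing remainders (< 8 chars) are discarded and
# segments containing non-ACGT characters (skip-segment policy) are dropped.
segment_codes_all <- function(seqs, mapping = "table2") {
  m <- residue_mapping(mapping)
  p <- nchar(seqs) %/% 8L
  out <- vector("list", length(seqs))
  has <- p > 0L
  if (any(has)) {
    trimmed <- substr(seqs[has], 1L, 8L * p[has])
    chars <- unlist(strsplit(trimmed, NULL), use.names = FALSE)
    v <- unname(m[chars])                      # NA for non-ACGT
    codes <- as.integer(colSums(matrix(v, nrow = 8L) * 4^(7:0)))
    grp <- rep.int(seq_along(trimmed), p[has])
    lst <- split(codes, grp)
    lst <- lapply(lst, function(cs) cs[!is.na(cs)])
    out[has] <- lst
  }
  out[!has] <- list(integer(0))
  out
}

#' Segment codes of a single sequence
#'
#' Consecutive non-overlapping 8-character windows starting at position 0;
#' a trailing remainder shorter than 8 is discarded; duplicate codes are
#' retained. Segments containing non-ACGT characters (possible under the
#' `"skip-segment"` ambiguity policy) are omitted.
#'
#' @param seq character scalar of residues
#' @inheritParams encode_segment
#' @return integer vector of codes (possibly empty)
#' @export
segment_codes <- function(seq, mapping = "table2") {
  stopifnot(is.character(seq), length(seq) == 1L)
  segment_codes_all(seq, mapping)[[1L]]
}

#' Build the 2^16-slot segment occurrence table
#'
#' Slot `d` counts the number of *sequences* containing at least one
#' segment with code `d`: per sequence, each distinct code increments its
#' slot by exactly one, so every count is at most `n`. The attribute
#' `"n_updates"` is an instrumentation counter of table increments (one per
#' distinct code per sequence), used by the linear-time complexity witness.
#'
#' @param data an `msa_dataset`
#' @inheritParams encode_segment
#' @return an integer vector of length 65536, class `"occurrence_table"`,
#'   with attribute `"n_updates"`
#' @export
build_occurrence_table <- function(data, mapping = "table2") {
  stopifnot(inherits(data, "msa_dataset"), n_seq(data) >= 1L)
  codes <- segment_codes_all(data$seq, mapping)
  uniq <- lapply(codes, unique)
  flat <- unlist(uniq, use.names = FALSE)
  counts <- tabulate(flat + 1L, nbins = 65536L)
  structure(counts, n_updates = length(flat), class = "occurrence_table")
}

#' Similarity scores (SS) from the occurrence table
#'
#' The SS of sequence `i` is the sum of occurrence-table counts over its
#' full segment-code list (duplicates included). By default each term
#' includes the sequence's own contribution to the table; with
#' `include_self = FALSE` one self-count is subtracted per accumulated
#' term, approximating the all-pairs similarity total that excludes
#' self-comparison. The attribute `"n_lookups"` counts table reads (one per
#' segment), for the complexity witness.
#'
#' @param data an `msa_dataset`
#' @param occ occurrence table built from the same dataset (built on the
#'   fly if omitted)
#' @param include_self keep the self-contribution in each term (default)
#' @inheritParams encode_segment
#' @return numeric vector of scores, one per sequence in input order, with
#'   attribute `"n_lookups"`
#' @export
similarity_scores <- function(data, occ = NULL, mapping = "table2",
                              include_self = TRUE) {
  stopifnot(inherits(data, "msa_dataset"))
  if (is.null(occ)) occ <- build_occurrence_table(data, mapping)
  stopifnot(inherits(occ, "occurrence_table"))
  codes <- segment_codes_all(data$seq, mapping)
  counts <- unclass(occ)
  ss <- vapply(codes, function(cs) sum(counts[cs + 1L]), numeric(1))
  if (!include_self) ss <- ss - lengths(codes)
  structure(ss, n_lookups = sum(lengths(codes)))
}

#' Select the center sequence
#'
#' Returns the 0-based index of the sequence with maximal similarity score
#' SS; ties are broken by the smallest index, so selection is
#' deterministic.
#'
#' @inheritParams similarity_scores
#' @return 0-based integer index, with attribute `"ss"` holding the full
#'   score vector
#' @export
#' @examples
#' d <- msa_dataset(c("ATCGCGAT", "ATCGCGAT", "AAAAAAAA"))
#' select_center(d)   # 0
select_center <- function(data, mapping = "table2", include_self = TRUE) {
  stopifnot(inherits(data, "msa_dataset"))
  if (n_seq(data) < 2L)
    stop("need at least 2 sequences to select a center")
  ss <- similarity_scores(data, mapping = mapping,
                          include_self = include_self)
  structure(which.max(ss) - 1L, ss = as.numeric(ss))
}
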