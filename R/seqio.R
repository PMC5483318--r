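#' Normalize raw residue text to the 4-letter DNA alphabet
#'
#' Uppercases, maps RNA `U` to `T`, and resolves characters outside
#' `{A,C,G,T,U}` according to `policy`:
#' \describe{
#'   \item{`"map-to-a"`}{(default) replace each ambiguous character by `A`;
#'     the number of replacements is returned in the `"n_replaced"`
#'     attribute so callers can log it. Keeps the 2-bit encoding total.}
#'   \item{`"strict"`}{error on the first non-ACGTU character, naming its
#'     0-based position.}
#'   \item{`"skip-segment"`}{keep ambiguous characters (uppercased) in
#'     place; downstream segment encoding drops any 8-mer containing one.}
#' }
#'
#' Normalization is idempotent for every policy.
#'
#' @param raw character scalar of residues (DNA or RNA, any case)
#' @param policy ambiguity policy, one of `"map-to-a"`, `"strict"`,
#'   `"skip-segment"`
#' @return normalized character scalar; attribute `"n_replaced"` gives the
#'   number of ambiguous characters replaced (0 unless policy is
#'   `"map-to-a"`)
#' @export
#' @examples
#' normalize_residues("acgu")                       # "ACGT"
#' normalize_residues("ACNT")                       # "ACAT", n_replaced = 1
normalize_residues <- function(raw, policy = c("map-to-a", "strict",
                                               "skip-segment")) {
  policy <- match.arg(policy)
  stopifnot(is.character(raw), length(raw) == 1L)
  if (!nzchar(raw)) stop("empty residue text")
  up <- chartr("u", "U", toupper(raw))
  if (policy == "strict") {
    bad <- regexpr("[^ACGTU]", up)
    if (bad > 0L)
      stop(sprintf("non-ACGTU character '%s' at position %d (0-based)",
                   substr(up, bad, bad), bad - 1L))
  }
  out <- chartr("U", "T", up)
  n_replaced <- 0L
  if (policy == "map-to-a") {
    n_replaced <- nchar(gsub("[ACGT]", "", out))
    if (n_replaced > 0L) out <- gsub("[^ACGT]", "A", out)
  }
  structure(out, n_replaced = n_replaced)
}

#' Construct a dataset of named sequences
#'
#' The in-memory container used throughout the package: parallel vectors of
#' record ids, descriptions and residue strings, in input order. Row `i` of
#' every downstream result corresponds to record `i`.
#'
#' @param seq character vector of residue strings
#' @param id character vector of unique, non-empty record ids
#' @param desc optional character vector of free-text descriptions
#' @return an object of class `"msa_dataset"`
#' @export
msa_dataset <- function(seq, id = paste0("seq", seq_along(seq) - 1L),
                        desc = rep("", length(seq))) {
  stopifnot(is.character(seq), is.character(id),
            length(id) == length(seq), length(desc) == length(seq))
  if (any(!nzchar(id))) stop("sequence ids must be non-empty")
  dup <- id[duplicated(id)]
  if (length(dup))
    stop(sprintf("duplicate sequence id '%s'", dup[[1L]]))
  structure(list(id = unname(id), desc = unname(desc), seq = unname(seq)),
            class = "msa_dataset")
}

#' Number of sequences in a dataset
#' @param x an `msa_dataset`
#' @return integer count
#' @export
n_seq <- function(x) length(x$seq)

#' @export
print.msa_dataset <- function(x, ...) {
  cat(sprintf("msa_dataset: %d sequence(s), mean length %.1f\n",
              n_seq(x), mean(nchar(x$seq))))
  show <- head(seq_len(n_seq(x)), 6L)
  for (i in show)
    cat(sprintf("  [%d] %s (%d nt)\n", i - 1L, x$id[i], nchar(x$seq[i])))
  if (n_seq(x) > 6L) cat(sprintf("  ... and %d more\n", n_seq(x) - 6L))
  invisible(x)
}

#' Read a FASTA file into a dataset
#'
#' Records keep their input order; residues are normalized with
#' [normalize_residues()]. The id is the first whitespace-delimited token of
#' the header, the rest is kept as the description. Replacements made under
#' the `"map-to-a"` policy are reported with one `message()` per affected
#' record.
#'
#' @param path FASTA file
#' @param policy ambiguity policy, see [normalize_residues()]
#' @return an `msa_dataset`
#' @export
read_fasta <- function(path, policy = c("map-to-a", "strict",
                                        "skip-segment")) {
  policy <- match.arg(policy)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop(sprintf("no sequences in %s", path))
  hdr <- names(set)
  id <- sub("\\s.*$", "", hdr)
  desc <- ifelse(grepl("\\s", hdr), sub("^\\S+\\s+", "", hdr), "")
  raw <- as.character(set)
  seqs <- character(length(raw))
  for (i in seq_along(raw)) {
    if (!nzchar(raw[i]))
      stop(sprintf("record '%s' has empty residue text", id[i]))
    norm <- normalize_residues(raw[i], policy)
    if (attr(norm, "n_replaced") > 0L)
      message(sprintf("record '%s': %d ambiguous character(s) mapped to A",
                      id[i], attr(norm, "n_replaced")))
    seqs[i] <- as.character(norm)
  }
  msa_dataset(seqs, id = id, desc = desc)
}

#' Write sequences or alignment rows to FASTA
#'
#' @param rows named character vector of (possibly gapped) rows, or an
#'   `msa_dataset`, or a `star_msa` result
#' @param path output file
#' @param line_width residues per line (default 60)
#' @param check_equal_width require all rows to have equal length (set
#'   automatically for `star_msa` input)
#' @return `path`, invisibly
#' @export
write_fasta <- function(rows, path, line_width = 60L,
                        check_equal_width = FALSE) {
  if (inherits(rows, "msa_dataset")) {
    rows <- stats::setNames(rows$seq, rows$id)
  } else if (inherits(rows, "star_msa")) {
    check_equal_width <- TRUE
    rows <- stats::setNames(rows$rows, rows$id)
  }
  stopifnot(is.character(rows), !is.null(names(rows)))
  if (check_equal_width && length(unique(nchar(rows))) > 1L)
    stop("alignment rows must all have equal length")
  set <- Biostrings::BStringSet(rows)
  Biostrings::writeXStringSet(set, filepath = path, width = line_width)
  invisible(path)
}

# strip gap characters from a row
degap <- function(row) gsub("-", "", row, fixed = TRUE)
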