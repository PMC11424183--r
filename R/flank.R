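#' Affine-gap alignment parameters for flank anchoring
#'
#' Scores for the Smith-Waterman local alignments that locate the prefix and
#' suffix flanks inside a read. `gap_open`/`gap_extend` are non-negative
#' penalties. `min_flank_identity` is the fraction of matching columns a
#' flank hit must reach for the read to be usable.
#'
#' @param match Match score (default 2).
#' @param mismatch Mismatch score (default -3).
#' @param gap_open,gap_extend Gap penalties (default 5 and 2).
#' @param min_flank_identity Identity floor in `[0,1]` (default 0.75).
#' @return An object of class `alignment_params`.
#' @export
alignment_params <- function(match = 2, mismatch = -3,
                             gap_open = 5, gap_extend = 2,
                             min_flank_identity = 0.75) {
  if (gap_open < gap_extend || gap_extend < 0)
    stop("need gap_open >= gap_extend >= 0", call. = FALSE)
  if (min_flank_identity < 0 || min_flank_identity > 1)
    stop("min_flank_identity must lie in [0, 1]", call. = FALSE)
  structure(list(match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend,
                 min_flank_identity = min_flank_identity),
            class = "alignment_params")
}

.substitution_matrix <- function(params) {
  bases <- c("A", "C", "G", "T", "N")
  m <- matrix(params$mismatch, 5, 5, dimnames = list(bases, bases))
  diag(m) <- params$match
  m["N", ] <- 0
  m[, "N"] <- 0
  m
}

# vectorised local alignment of one flank against many reads;
# reverse = TRUE aligns reversed sequences so the single best hit returned by
# pairwiseAlignment prefers the rightmost equivalent placement.
.flank_hits <- function(read_seqs, flank, params, reverse = FALSE) {
  stopifnot(length(read_seqs) >= 1L, nzchar(flank))
  seqs <- read_seqs
  fl <- flank
  if (reverse) {
    seqs <- vapply(strsplit(seqs, ""), function(x) paste(rev(x), collapse = ""), "")
    fl <- paste(rev(strsplit(fl, "")[[1]]), collapse = "")
  }
  al <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAStringSet(seqs),
    subject = Biostrings::DNAString(fl),
    type = "local",
    substitutionMatrix = .substitution_matrix(params),
    gapOpening = params$gap_open, gapExtension = params$gap_extend
  )
  p <- Biostrings::pattern(al)
  st <- BiocGenerics::start(p)
  en <- BiocGenerics::end(p)
  if (reverse) {
    n <- nchar(read_seqs)
    tmp <- st
    st <- n - en + 1L
    en <- n - tmp + 1L
  }
  data.frame(
    start = st, end = en,
    score = BiocGenerics::score(al),
    # fraction of the flank recovered as matches: unaligned flank positions
    # count as mismatches, otherwise a short chance hit in a random read
    # would look perfect
    identity = Biostrings::nmatch(al) / nchar(flank),
    stringsAsFactors = FALSE
  )
}

#' Locate a flank anchor inside a read
#'
#' Smith-Waterman local alignment (affine gaps) of a flank sequence against a
#' read. Identity is the number of matching columns of the best local hit
#' divided by the full flank length, so a partial chance hit in a read that
#' lacks the flank scores low.
#'
#' @param read_seq Read nucleotide string.
#' @param flank Flank nucleotide string.
#' @param params An [alignment_params()].
#' @param prefer Either `"leftmost"` (default; used for prefix flanks) or
#'   `"rightmost"` (used for suffix flanks) for breaking ties between
#'   equally scoring hits.
#' @return A one-row data frame with columns `start`, `end` (1-based, closed
#'   interval on the read), `score` and `identity`.
#' @export
locate_flank <- function(read_seq, flank, params = alignment_params(),
                         prefer = c("leftmost", "rightmost")) {
  prefer <- match.arg(prefer)
  .flank_hits(read_seq, flank, params, reverse = prefer == "rightmost")
}

#' Trim a spanning read down to its repeat core
#'
#' Locates the prefix and suffix flanks by local alignment and extracts the
#' enclosed core, retaining `pad` extra flank bases on each side. A read is
#' rejected when either flank hit falls below `min_flank_identity`
#' (`PREFIX_NOT_FOUND` / `SUFFIX_NOT_FOUND`) or when the hits cross
#' (`FLANKS_OVERLAP`). If a pad would extend past the read edge it is
#' truncated rather than rejecting the read.
#'
#' @param read_seq Read nucleotide string (reference orientation).
#' @param locus A [panel_locus()].
#' @param params An [alignment_params()].
#' @param pad Retained flank bases per side (default 3).
#' @return A list with `core_seq`, `pad_left`, `pad_right`, `prefix_score`,
#'   `suffix_score`, or `NULL` core plus a `reject` reason.
#' @export
trim_to_core <- function(read_seq, locus, params = alignment_params(), pad = 3L) {
  res <- trim_reads(read_seq, locus, params, pad)
  out <- list(core_seq = res$core_seq[1],
              pad_left = res$pad_left[1], pad_right = res$pad_right[1],
              prefix_score = res$prefix_score[1],
              suffix_score = res$suffix_score[1],
              reject = res$reject[1])
  if (!is.na(out$reject)) out$core_seq <- NULL
  out
}

#' Trim many reads to their repeat cores (vectorised)
#'
#' @param read_seqs Character vector of read sequences.
#' @param locus A [panel_locus()].
#' @param params An [alignment_params()].
#' @param pad Retained flank bases per side (default 3).
#' @return A data frame with one row per read: `core_seq`, `pad_left`,
#'   `pad_right`, `prefix_score`, `suffix_score`, `reject` (NA when usable,
#'   else one of PREFIX_NOT_FOUND, SUFFIX_NOT_FOUND, FLANKS_OVERLAP).
#' @export
trim_reads <- function(read_seqs, locus, params = alignment_params(), pad = 3L) {
  stopifnot(inherits(locus, "panel_locus"))
  pad <- as.integer(pad)
  pre <- .flank_hits(read_seqs, locus$prefix_flank, params, reverse = FALSE)
  suf <- .flank_hits(read_seqs, locus$suffix_flank, params, reverse = TRUE)

  n <- length(read_seqs)
  reject <- rep(NA_character_, n)
  reject[suf$identity < params$min_flank_identity] <- "SUFFIX_NOT_FOUND"
  reject[pre$identity < params$min_flank_identity] <- "PREFIX_NOT_FOUND"
  cross <- is.na(reject) & suf$start <= pre$end
  reject[cross] <- "FLANKS_OVERLAP"

  # core with pads, truncated at read edges when a hit sits at the boundary
  from <- pmax(pre$end - pad + 1L, 1L)
  to <- pmin(suf$start + pad - 1L, nchar(read_seqs))
  core <- substr(read_seqs, from, to)
  core[!is.na(reject)] <- NA_character_
  data.frame(
    core_seq = core,
    pad_left = ifelse(is.na(reject), pre$end - from + 1L, NA_integer_),
    pad_right = ifelse(is.na(reject), to - suf$start + 1L, NA_integer_),
    prefix_score = pre$score, suffix_score = suf$score,
    reject = reject, stringsAsFactors = FALSE
  )
}
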