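#' Extract reads spanning an STR locus from an indexed BAM
#'
#' Returns the primary alignments whose aligned reference interval contains
#' the repeat core padded by `pad` bases on each side. Secondary,
#' supplementary and unmapped records are excluded. SEQ fields in BAM are
#' stored in reference orientation (minus-strand reads were
#' reverse-complemented by the aligner), so all returned sequences are
#' directly comparable to the panel flanks. Soft-clipped tails are part of
#' the returned sequence but do not count toward the aligned span.
#'
#' @param bam Path to a coordinate-sorted, indexed BAM file.
#' @param locus A [panel_locus()].
#' @param pad Extra reference bases the alignment must cover on each side
#'   of the core (default 3).
#' @return A data frame with columns `read_id`, `sequence`, `strand`;
#'   attribute `locus` carries the locus name.
#' @export
extract_spanning_reads <- function(bam, locus, pad = 3L) {
  stopifnot(inherits(locus, "panel_locus"))
  if (!file.exists(bam)) stop("BAM file not found: ", bam, call. = FALSE)
  bf <- Rsamtools::BamFile(bam)
  hdr <- Rsamtools::scanBamHeader(bf)
  if (!locus$chrom %in% names(hdr$targets))
    stop("chromosome '", locus$chrom, "' absent from BAM header of ", bam,
         call. = FALSE)
  win_start <- locus$core_start - pad
  win_end <- locus$core_end + pad
  which <- GenomicRanges::GRanges(locus$chrom,
                                  IRanges::IRanges(max(1L, win_start), win_end))
  param <- Rsamtools::ScanBamParam(
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE),
    what = c("qname", "pos", "cigar", "strand", "seq"),
    which = which
  )
  res <- Rsamtools::scanBam(bf, param = param)[[1]]
  if (length(res$qname) == 0L) {
    out <- data.frame(read_id = character(0), sequence = character(0),
                      strand = character(0), stringsAsFactors = FALSE)
    attr(out, "locus") <- locus$name
    return(out)
  }
  ref_width <- GenomicAlignments::cigarWidthAlongReferenceSpace(res$cigar)
  ref_end <- res$pos + ref_width - 1L
  spans <- res$pos <= win_start & ref_end >= win_end
  out <- data.frame(read_id = res$qname[spans],
                    sequence = as.character(res$seq)[spans],
                    strand = as.character(res$strand)[spans],
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$read_id))
    stop("duplicate read IDs at locus '", locus$name,
         "' (possible multi-mapping artifact)", call. = FALSE)
  attr(out, "locus") <- locus$name
  out
}
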