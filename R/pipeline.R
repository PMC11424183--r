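#' Genotype trimmed reads at one locus
#'
#' Runs the post-extraction pipeline on a set of spanning-read sequences:
#' flank trimming, one-substitution clustering, top-`k` candidate
#' selection, repeat-structure inference, stutter filtering and the SN/SNR
#' decision ladder.
#'
#' @param read_seqs Character vector of spanning-read sequences (reference
#'   orientation).
#' @param locus A [panel_locus()].
#' @param cfg A [threshold_config()].
#' @param pad Retained flank bases per side (default 3).
#' @param k Candidate alleles considered (default 3).
#' @param read_ids Optional read identifiers.
#' @return A `locus_genotype`; attribute `stats` carries read and rejection
#'   tallies, attribute `candidates` the pre-filter [allele_call()]s.
#' @export
call_locus <- function(read_seqs, locus, cfg = threshold_config(),
                       pad = 3L, k = 3L, read_ids = NULL) {
  n_reads <- length(read_seqs)
  empty_stats <- function(rej = character(0)) {
    tal <- table(factor(rej, levels = c("PREFIX_NOT_FOUND", "SUFFIX_NOT_FOUND",
                                        "FLANKS_OVERLAP")))
    c(list(n_reads = n_reads, n_used = n_reads - length(rej)), as.list(tal))
  }
  if (n_reads == 0L) {
    gt <- call_genotype(list(), cfg, locus$name)
    attr(gt, "stats") <- empty_stats()
    return(gt)
  }
  trimmed <- trim_reads(read_seqs, locus, cfg$alignment, pad)
  usable <- is.na(trimmed$reject)
  rejects <- trimmed$reject[!usable]
  if (!any(usable)) {
    gt <- call_genotype(list(), cfg, locus$name)
    attr(gt, "stats") <- empty_stats(rejects)
    return(gt)
  }
  if (is.null(read_ids)) read_ids <- paste0("read", seq_len(n_reads))
  clusters <- cluster_fragments(trimmed$core_seq[usable], read_ids[usable])
  cand_clusters <- select_candidates(clusters, k)
  pads <- c(pad, pad)
  candidates <- lapply(cand_clusters, function(cl) {
    st <- infer_structure(cl$representative, locus$motifs, cfg$max_iterations)
    allele_call(designate_allele(st, locus, pads), st, cl$sn, cl$snr)
  })
  fs <- filter_stutter(candidates, cfg, locus$period)
  gt <- call_genotype(fs$kept, cfg, locus$name, filtered_stutter = fs$removed)
  attr(gt, "stats") <- empty_stats(rejects)
  attr(gt, "candidates") <- candidates
  gt
}

#' Genotype STR loci from a BAM file
#'
#' The full pipeline over a panel: extract spanning reads per locus, trim
#' flanks, cluster fragments, infer repeat structures of the top candidate
#' alleles, filter stutter and apply the SN/SNR decision ladder. Loci are
#' processed independently and reported sorted by name, so output is
#' deterministic regardless of processing order.
#'
#' @param bam Path to a coordinate-sorted, indexed BAM.
#' @param panel Named list of [panel_locus()] (from [read_panel()] or
#'   [build_toy_panel()]).
#' @param cfg A [threshold_config()].
#' @param sample Sample name carried into the report (default the BAM
#'   basename).
#' @param pad Retained flank bases per side (default 3).
#' @return An object of class `str_genotypes`: a named list of
#'   `locus_genotype` results with the sample name attached.
#' @export
genotype_str <- function(bam, panel, cfg = threshold_config(),
                         sample = sub("\\.bam$", "", basename(bam)),
                         pad = 3L) {
  stopifnot(length(panel) >= 1L)
  panel <- panel[order(names(panel))]
  results <- lapply(panel, function(locus) {
    reads <- extract_spanning_reads(bam, locus, pad)
    call_locus(reads$sequence, locus, cfg, pad, read_ids = reads$read_id)
  })
  structure(results, sample = sample, class = "str_genotypes")
}

#' @export
print.str_genotypes <- function(x, ...) {
  cat(sprintf("<str_genotypes> sample '%s', %d loci\n",
              attr(x, "sample"), length(x)))
  print(as.data.frame(x)[, c("locus", "status", "allele1", "allele2",
                             "sn1", "sn2")], row.names = FALSE)
  invisible(x)
}

#' @method summary str_genotypes
#' @export
summary.str_genotypes <- function(object, ...) {
  df <- as.data.frame(object)
  cat(sprintf("sample '%s': %d loci (%d Pass, %d Interpretation, %d Imbalance)\n",
              attr(object, "sample"), nrow(df), sum(df$status == "Pass"),
              sum(df$status == "Interpretation"), sum(df$status == "Imbalance")))
  for (loc in names(object)) {
    st <- attr(object[[loc]], "stats")
    if (!is.null(st))
      cat(sprintf("  %s: %d reads, %d usable (rejected: %d prefix, %d suffix, %d overlap)\n",
                  loc, st$n_reads, st$n_used, st$PREFIX_NOT_FOUND,
                  st$SUFFIX_NOT_FOUND, st$FLANKS_OVERLAP))
  }
  invisible(df)
}

#' Flatten genotype results to a report table
#'
#' @param x An `str_genotypes` object.
#' @param ... Unused.
#' @method as.data.frame str_genotypes
#' @return A data frame with one row per locus: `sample`, `locus`,
#'   `status`, `allele1`, `allele2`, `structure1`, `structure2`, `sn1`,
#'   `sn2`, `snr1`, `snr2`. Non-`Pass` rows carry empty allele fields.
#' @export
as.data.frame.str_genotypes <- function(x, ...) {
  rows <- lapply(x, function(gt) {
    field <- function(i, what, fmt = identity) {
      if (gt$status == "Pass" && length(gt$calls) >= i) {
        v <- gt$calls[[i]][[what]]
        if (is.null(v)) "" else fmt(v)
      } else ""
    }
    # a homozygote reports its single allele in both columns
    i2 <- if (length(gt$calls) >= 2L) 2L else 1L
    data.frame(
      sample = attr(x, "sample"), locus = gt$locus, status = gt$status,
      allele1 = field(1L, "designation"),
      allele2 = field(i2, "designation"),
      structure1 = field(1L, "structure", function(v) v$bracket),
      structure2 = field(i2, "structure", function(v) v$bracket),
      sn1 = field(1L, "sn", as.character), sn2 = field(i2, "sn", as.character),
      snr1 = field(1L, "snr", function(v) sprintf("%.4f", v)),
      snr2 = field(i2, "snr", function(v) sprintf("%.4f", v)),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a genotype report as TSV
#'
#' One row per locus with a deterministic column order (`sample`, `locus`,
#' `status`, `allele1`, `allele2`, `structure1`, `structure2`, `sn1`,
#' `sn2`, `snr1`, `snr2`); `Interpretation`/`Imbalance` rows carry the flag
#' with empty allele fields. An empty result list yields a header-only
#' file.
#'
#' @param genotypes An `str_genotypes` object, or a list of
#'   `locus_genotype` objects.
#' @param path Output TSV path.
#' @param sample Sample name used when `genotypes` is a bare list.
#' @return Invisibly, `path`.
#' @export
write_report <- function(genotypes, path, sample = "sample") {
  if (!inherits(genotypes, "str_genotypes"))
    genotypes <- structure(genotypes, sample = sample, class = "str_genotypes")
  cols <- c("sample", "locus", "status", "allele1", "allele2", "structure1",
            "structure2", "sn1", "sn2", "snr1", "snr2")
  df <- if (length(genotypes)) as.data.frame(genotypes) else
    as.data.frame(stats::setNames(
      replicate(length(cols), character(0), simplify = FALSE), cols))
  utils::write.table(df[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
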