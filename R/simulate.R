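# run code with a private RNG stream so simulation is reproducible and does
# not disturb the caller's random state
.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

.rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                               collapse = "")

#' Nanopore-like error model
#'
#' Per-base substitution/insertion/deletion probabilities, a multiplier
#' boosting indel rates inside homopolymer runs of four or more identical
#' bases (the dominant nanopore failure mode), and the probability that a
#' read is a stutter artifact missing exactly one repeat unit.
#'
#' @param sub_rate,ins_rate,del_rate Per-base error probabilities.
#' @param homopolymer_boost Multiplier on indel rates inside runs >= 4 nt
#'   (default 3).
#' @param stutter_prob Probability a read loses one full repeat unit from
#'   its longest run (default 0.1).
#' @param seed Integer seed making simulation deterministic.
#' @return An object of class `error_model`.
#' @export
error_model <- function(sub_rate = 0.03, ins_rate = 0.01, del_rate = 0.01,
                        homopolymer_boost = 3, stutter_prob = 0.10,
                        seed = 1L) {
  stopifnot(sub_rate >= 0, ins_rate >= 0, del_rate >= 0,
            sub_rate < 1, ins_rate < 1, del_rate < 1,
            sub_rate + ins_rate + del_rate < 0.5,
            stutter_prob >= 0, stutter_prob <= 1)
  structure(list(sub_rate = sub_rate, ins_rate = ins_rate,
                 del_rate = del_rate, homopolymer_boost = homopolymer_boost,
                 stutter_prob = stutter_prob, seed = as.integer(seed)),
            class = "error_model")
}

#' Build a deterministic toy STR panel with a reference sequence
#'
#' Generates `n_loci` synthetic markers: random flanks (>= 30 nt, so local
#' alignment can anchor), a random set of distinct repeat motifs per locus,
#' and a reference allele of `ref_units` copies of the first motif. Loci are
#' concatenated (with random spacers) into a single toy reference contig
#' and their core coordinates recorded.
#'
#' @param n_loci Number of loci (>= 1).
#' @param period Repeat-unit length.
#' @param seed Integer seed; the same seed reproduces the panel exactly.
#' @param n_motifs Motifs per locus (default 3).
#' @param flank_len Flank length (default 40; must be >= 30).
#' @param ref_units Repeat units in the reference allele (default 10).
#' @return A list with `panel` (named list of [panel_locus()]),
#'   `reference` (character), and `ref_name` (`"toyref"`).
#' @export
build_toy_panel <- function(n_loci = 1L, period = 4L, seed = 1L,
                            n_motifs = 3L, flank_len = 40L, ref_units = 10L) {
  stopifnot(n_loci >= 1L, flank_len >= 30L, period >= 2L)
  .with_seed(seed, {
    ref <- .rand_dna(20L)
    panel <- list()
    for (i in seq_len(n_loci)) {
      motifs <- character(0)
      while (length(motifs) < n_motifs) {
        m <- .rand_dna(period)
        # avoid homopolymer motifs: a homopolymer "run count" is not a
        # meaningful repeat unit and destabilises toy designations
        if (length(unique(strsplit(m, "")[[1]])) > 1L)
          motifs <- unique(c(motifs, m))
      }
      prefix <- .rand_dna(flank_len)
      suffix <- .rand_dna(flank_len)
      core <- strrep(motifs[1], ref_units)
      core_start <- nchar(ref) + flank_len + 1L
      core_end <- core_start + nchar(core) - 1L
      ref <- paste0(ref, prefix, core, suffix, .rand_dna(20L))
      locus <- panel_locus(
        name = sprintf("TL%02d", i), chrom = "toyref",
        core_start = core_start, core_end = core_end,
        prefix_flank = prefix, suffix_flank = suffix,
        motifs = motifs, period = period
      )
      panel[[locus$name]] <- locus
    }
    list(panel = panel, reference = ref, ref_name = "toyref")
  })
}

# remove one copy from the longest motif run of a bracket genotype
.apply_stutter <- function(bracket) {
  tokens <- strsplit(bracket, "_", fixed = TRUE)[[1]]
  m <- regmatches(tokens, regexec("^\\[([ACGTN]+)\\]([0-9]+)$", tokens))
  counts <- vapply(m, function(x) if (length(x) == 3L) as.integer(x[3]) else 0L, 0L)
  lens <- vapply(m, function(x) if (length(x) == 3L) nchar(x[2]) else 0L, 0L)
  run_len <- counts * lens
  if (!any(run_len > 0L)) return(bracket)
  i <- which.max(run_len)
  tokens[i] <- sprintf("[%s]%d", m[[i]][2], counts[i] - 1L)
  if (counts[i] - 1L == 0L) tokens <- tokens[-i]
  paste(tokens, collapse = "_")
}

# introduce substitution/indel noise into one sequence; returns the string
.noisy_copy <- function(template, em) {
  bases <- strsplit(template, "")[[1]]
  n <- length(bases)
  r <- rle(bases)
  in_hp <- rep(r$lengths >= 4L, r$lengths)
  boost <- ifelse(in_hp, em$homopolymer_boost, 1)
  alphabet <- c("A", "C", "G", "T")
  del <- stats::runif(n) < pmin(em$del_rate * boost, 0.95)
  sub <- stats::runif(n) < em$sub_rate
  ins <- stats::runif(n) < pmin(em$ins_rate * boost, 0.95)
  # substitution replaces the base by one of the three others, uniformly
  if (any(sub)) {
    shift <- sample.int(3L, sum(sub), replace = TRUE)
    bases[sub] <- alphabet[((match(bases[sub], alphabet) - 1L + shift) %% 4L) + 1L]
  }
  ins_char <- rep("", n)
  if (any(ins)) ins_char[ins] <- sample(alphabet, sum(ins), replace = TRUE)
  out <- paste0(ifelse(del, "", bases), ins_char)
  paste(out, collapse = "")
}

#' Simulate nanopore-like amplicon reads for one locus
#'
#' Each read picks one of the genotype's alleles uniformly (both for a
#' heterozygote, the single one for a homozygote), optionally loses one
#' full repeat unit from its longest run (stutter), and then accumulates
#' per-base substitution/insertion/deletion noise with boosted indel rates
#' in homopolymer runs. Reads span the full amplicon
#' (prefix flank + core + suffix flank) and are emitted in reference
#' orientation; strand is assigned alternately and only flips the SAM FLAG
#' and the FASTQ orientation. When `reference` is supplied, each read also
#' receives a true alignment (POS/CIGAR against the toy reference) computed
#' by global alignment of the noisy read to the amplicon window.
#'
#' @param locus A [panel_locus()].
#' @param genotype Character vector of 1-2 bracket strings (e.g.
#'   `"[AAAG]10"`), expanded via [expand_structure()].
#' @param depth Number of reads.
#' @param em An [error_model()]; its `seed` makes output deterministic.
#' @param reference Toy reference string (from [build_toy_panel()]); when
#'   `NULL`, alignment fields are omitted (FASTQ-only simulation).
#' @return A data frame of class `simulated_reads`: `read_id`, `sequence`
#'   (reference orientation), `strand`, `true_allele` (index into
#'   `genotype`), `stutter`, and (with a reference) `pos` and `cigar`.
#' @export
simulate_reads <- function(locus, genotype, depth, em = error_model(),
                           reference = NULL) {
  stopifnot(inherits(locus, "panel_locus"), depth >= 1L,
            length(genotype) %in% 1:2)
  cores <- vapply(genotype, expand_structure, "")
  .with_seed(em$seed, {
    allele_idx <- sample(seq_along(genotype), depth, replace = TRUE)
    is_stutter <- stats::runif(depth) < em$stutter_prob
    seqs <- character(depth)
    for (i in seq_len(depth)) {
      g <- genotype[allele_idx[i]]
      core <- if (is_stutter[i]) expand_structure(.apply_stutter(g)) else cores[allele_idx[i]]
      template <- paste0(locus$prefix_flank, core, locus$suffix_flank)
      seqs[i] <- .noisy_copy(template, em)
    }
    reads <- data.frame(
      read_id = sprintf("%s_read%04d", locus$name, seq_len(depth)),
      sequence = seqs,
      strand = rep(c("+", "-"), length.out = depth),
      true_allele = allele_idx,
      stutter = is_stutter,
      stringsAsFactors = FALSE
    )
    if (!is.null(reference)) {
      win_start <- locus$core_start - nchar(locus$prefix_flank)
      win_end <- locus$core_end + nchar(locus$suffix_flank)
      window <- substr(reference, win_start, win_end)
      al <- Biostrings::pairwiseAlignment(
        pattern = Biostrings::DNAStringSet(seqs),
        subject = Biostrings::DNAString(window),
        type = "global",
        substitutionMatrix = .substitution_matrix(alignment_params()),
        gapOpening = 5, gapExtension = 2
      )
      pat <- as.character(Biostrings::alignedPattern(al))
      sub <- as.character(Biostrings::alignedSubject(al))
      cig <- mapply(.cigar_from_gapped, pat, sub, SIMPLIFY = FALSE,
                    USE.NAMES = FALSE)
      reads$pos <- win_start + vapply(cig, `[[`, 0L, "ref_offset")
      reads$cigar <- vapply(cig, `[[`, "", "cigar")
    }
    class(reads) <- c("simulated_reads", "data.frame")
    reads
  })
}

# turn a gapped (pattern, subject) alignment pair into a CIGAR string plus
# the offset of the first consumed reference base; leading/trailing
# reference gaps become nothing (offset), read overhangs become soft clips
.cigar_from_gapped <- function(pat, sub) {
  p <- strsplit(pat, "")[[1]]
  s <- strsplit(sub, "")[[1]]
  op <- ifelse(p != "-" & s != "-", "M",
               ifelse(p != "-", "I", "D"))
  # trim alignment columns outside the read
  keep <- cumsum(p != "-") > 0 & rev(cumsum(rev(p != "-")) > 0)
  ref_offset <- sum(s[!keep & seq_along(s) <= which(keep)[1]] != "-")
  op <- op[keep]
  r <- rle(op)
  # leading/trailing D cannot start or end a CIGAR
  if (r$values[1] == "D") {
    ref_offset <- ref_offset + r$lengths[1]
    r$values <- r$values[-1]; r$lengths <- r$lengths[-1]
  }
  if (r$values[length(r$values)] == "D") {
    r$values <- r$values[-length(r$values)]
    r$lengths <- r$lengths[-length(r$lengths)]
  }
  # insertions at the alignment edges are soft clips
  if (r$values[1] == "I") r$values[1] <- "S"
  if (r$values[length(r$values)] == "I") r$values[length(r$values)] <- "S"
  list(cigar = paste0(r$lengths, r$values, collapse = ""),
       ref_offset = ref_offset)
}

#' Write simulated reads as SAM
#'
#' Emits a valid SAM file (`@HD`/`@SQ` header for the toy reference) with
#' one primary alignment per read; minus-strand reads get FLAG 16 with SEQ
#' kept in reference orientation, as an aligner would store it. Qualities
#' are constant Q20 (the caller uses none).
#'
#' @param reads A `simulated_reads` data frame with `pos` and `cigar`.
#' @param reference Toy reference string.
#' @param path Output SAM path.
#' @param ref_name Reference contig name (default `"toyref"`).
#' @return Invisibly, `path`.
#' @export
write_sam <- function(reads, reference, path, ref_name = "toyref") {
  header <- c("@HD\tVN:1.6\tSO:unknown",
              sprintf("@SQ\tSN:%s\tLN:%d", ref_name, nchar(reference)))
  body <- character(0)
  if (nrow(reads)) {
    stopifnot(all(c("pos", "cigar") %in% names(reads)))
    flag <- ifelse(reads$strand == "-", 16L, 0L)
    qual <- strrep("5", nchar(reads$sequence))  # Q20
    body <- sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t%s",
                    reads$read_id, flag, ref_name, reads$pos, reads$cigar,
                    reads$sequence, qual)
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write simulated reads as FASTQ
#'
#' Minus-strand reads are written as sequenced (reverse-complemented from
#' the reference orientation); qualities are constant Q20.
#'
#' @param reads A `simulated_reads` data frame.
#' @param path Output FASTQ path.
#' @return Invisibly, `path`.
#' @export
write_fastq <- function(reads, path) {
  seqs <- reads$sequence
  minus <- reads$strand == "-"
  if (any(minus))
    seqs[minus] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(seqs[minus])))
  lines <- as.vector(rbind(paste0("@", reads$read_id), seqs,
                           "+", strrep("5", nchar(seqs))))
  writeLines(lines, path)
  invisible(path)
}

#' Convert a SAM file to a sorted, indexed BAM
#'
#' @param sam_path Input SAM path.
#' @param bam_prefix Output path without the `.bam` extension (defaults to
#'   the SAM path minus its extension).
#' @return The BAM path (with a `.bai` index alongside).
#' @export
sam_to_bam <- function(sam_path, bam_prefix = sub("\\.sam$", "", sam_path)) {
  Rsamtools::asBam(sam_path, destination = bam_prefix, overwrite = TRUE,
                   indexDestination = TRUE)
}
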