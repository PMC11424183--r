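#' Define one STR panel locus
#'
#' A `panel_locus` bundles everything the caller needs to know about one STR
#' marker: where its repeat core sits on the reference, the fixed flanking
#' sequences used as trimming anchors, and the repeat motifs searched during
#' structure inference.
#'
#' @param name Marker identifier (e.g. `"FGA"`).
#' @param chrom Reference sequence name the marker lies on.
#' @param core_start,core_end 1-based, closed reference coordinates of the
#'   repeat core.
#' @param prefix_flank,suffix_flank Nucleotide strings immediately 5' / 3' of
#'   the core. Flanks of at least 30 nt are recommended so local alignment can
#'   anchor reliably in noisy reads.
#' @param motifs Character vector of repeat-unit strings, all of length
#'   `period` (e.g. `c("GGAA","AAAG","AGAA","GAAA")` for FGA).
#' @param period Repeat-unit length in nucleotides.
#' @param designation_offset Signed number of nucleotides added to the core
#'   length before allele designation; carries locus-specific nomenclature
#'   adjustments. Default 0.
#'
#' @return An object of class `panel_locus`.
#' @export
panel_locus <- function(name, chrom, core_start, core_end,
                        prefix_flank, suffix_flank,
                        motifs, period, designation_offset = 0L) {
  motifs <- toupper(as.character(motifs))
  prefix_flank <- toupper(as.character(prefix_flank))
  suffix_flank <- toupper(as.character(suffix_flank))
  core_start <- as.integer(core_start)
  core_end <- as.integer(core_end)
  period <- as.integer(period)

  fail <- function(field, msg) {
    stop(sprintf("panel locus '%s', field '%s': %s", name, field, msg),
         call. = FALSE)
  }
  if (is.na(core_start) || is.na(core_end) || core_start > core_end)
    fail("core_start/core_end", "malformed coordinates (need start <= end)")
  if (!nzchar(prefix_flank) || !grepl("^[ACGTN]+$", prefix_flank))
    fail("prefix_flank", "must be a non-empty ACGTN string")
  if (!nzchar(suffix_flank) || !grepl("^[ACGTN]+$", suffix_flank))
    fail("suffix_flank", "must be a non-empty ACGTN string")
  if (length(motifs) == 0L) fail("motifs", "at least one motif required")
  if (anyDuplicated(motifs)) fail("motifs", "motifs must be distinct")
  if (any(!grepl("^[ACGT]+$", motifs))) fail("motifs", "motifs must be ACGT strings")
  if (any(nchar(motifs) != period))
    fail("motifs", sprintf("every motif must have length == period (%d)", period))

  structure(
    list(name = as.character(name), chrom = as.character(chrom),
         core_start = core_start, core_end = core_end,
         prefix_flank = prefix_flank, suffix_flank = suffix_flank,
         motifs = motifs, period = period,
         designation_offset = as.integer(designation_offset)),
    class = "panel_locus"
  )
}

#' @export
print.panel_locus <- function(x, ...) {
  cat(sprintf("<panel_locus> %s  %s:%d-%d  period %d  motifs {%s}\n",
              x$name, x$chrom, x$core_start, x$core_end, x$period,
              paste(x$motifs, collapse = ",")))
  invisible(x)
}

.panel_columns <- c("locus", "chrom", "start", "end", "coord_system", "period",
                    "motifs", "prefix_flank", "suffix_flank",
                    "designation_offset")

panel_record_to_locus <- function(rec) {
  coord <- if (is.null(rec$coord_system) || is.na(rec$coord_system) ||
               !nzchar(rec$coord_system)) "1-based" else as.character(rec$coord_system)
  start <- as.integer(rec$start)
  end <- as.integer(rec$end)
  if (grepl("^0", coord)) {
    # 0-based half-open -> 1-based closed
    start <- start + 1L
  } else if (!grepl("^1", coord)) {
    stop(sprintf("panel locus '%s', field 'coord_system': unknown value '%s'",
                 rec$locus, coord), call. = FALSE)
  }
  off <- rec$designation_offset
  if (is.null(off) || is.na(off)) off <- 0L
  panel_locus(
    name = rec$locus, chrom = rec$chrom,
    core_start = start, core_end = end,
    prefix_flank = rec$prefix_flank, suffix_flank = rec$suffix_flank,
    motifs = strsplit(as.character(rec$motifs), ",", fixed = TRUE)[[1]],
    period = rec$period, designation_offset = off
  )
}

#' Read an STR panel definition
#'
#' Reads a panel configuration from TSV (columns `locus, chrom, start, end,
#' coord_system, period, motifs` (comma-separated), `prefix_flank,
#' suffix_flank, designation_offset`) or JSON (an array of objects with the
#' same keys). Coordinates declared `coord_system: 0based` are converted to
#' the 1-based closed convention used internally.
#'
#' @param path Path to a `.tsv`/`.txt` or `.json` panel file.
#' @return A named list of [panel_locus] objects.
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) stop("panel file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    recs <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    df <- as.data.frame(recs, stringsAsFactors = FALSE)
  } else {
    df <- utils::read.delim(path, sep = "\t", header = TRUE,
                            colClasses = "character", comment.char = "#")
  }
  if (nrow(df) == 0L) {
    warning("panel file '", path, "' contains no loci")
    return(structure(list(), names = character(0)))
  }
  missing <- setdiff(setdiff(.panel_columns, c("coord_system", "designation_offset")),
                     names(df))
  if (length(missing))
    stop("panel file '", path, "' is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  loci <- lapply(seq_len(nrow(df)), function(i) panel_record_to_locus(as.list(df[i, ])))
  names(loci) <- vapply(loci, `[[`, "", "name")
  if (anyDuplicated(names(loci)))
    stop("panel file '", path, "' defines duplicate loci", call. = FALSE)
  loci
}

#' Write an STR panel definition as TSV
#'
#' Inverse of [read_panel()]; round-trips field for field.
#'
#' @param panel Named list of [panel_locus] objects.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_panel <- function(panel, path) {
  df <- do.call(rbind, lapply(panel, function(l) {
    data.frame(locus = l$name, chrom = l$chrom,
               start = l$core_start, end = l$core_end,
               coord_system = "1-based", period = l$period,
               motifs = paste(l$motifs, collapse = ","),
               prefix_flank = l$prefix_flank, suffix_flank = l$suffix_flank,
               designation_offset = l$designation_offset,
               stringsAsFactors = FALSE)
  }))
  if (is.null(df)) df <- as.data.frame(stats::setNames(
    replicate(length(.panel_columns), character(0), simplify = FALSE), .panel_columns))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Genotype-calling thresholds
#'
#' Holds the SN/SNR decision thresholds. `sn_interpretation` is the floor on
#' the major allele's supporting-read number below which a locus is flagged
#' "Interpretation" (inadequate coverage). `sn_allele` is the SN a minor
#' allele must reach for a confident heterozygous call; a minor allele above
#' the SNR threshold but below this SN yields an "Imbalance" flag. `snr_het`
#' is the per-locus SNR threshold for declaring heterozygosity: either a
#' single unnamed value applied to every locus, or a named vector mapping
#' locus names to thresholds (then a locus absent from the map is a
#' configuration error). `stutter_snr` is the SNR ceiling under which a
#' candidate one repeat unit shorter than a stronger candidate is discarded
#' as stutter.
#'
#' @param sn_interpretation Integer, default 10.
#' @param sn_allele Integer, default 25.
#' @param snr_het Numeric in `[0,1]`; unnamed scalar or named per-locus map.
#'   Default 0.30 for all loci.
#' @param stutter_snr Numeric in `[0,1]`, default 0.30.
#' @param max_iterations Recursion cap for structure inference, default 50.
#' @param alignment An [alignment_params()] object used for flank trimming.
#' @return An object of class `threshold_config`.
#' @export
threshold_config <- function(sn_interpretation = 10L, sn_allele = 25L,
                             snr_het = 0.30, stutter_snr = 0.30,
                             max_iterations = 50L,
                             alignment = alignment_params()) {
  sn_interpretation <- as.integer(sn_interpretation)
  sn_allele <- as.integer(sn_allele)
  if (sn_interpretation <= 0L || sn_interpretation > sn_allele)
    stop("need 0 < sn_interpretation <= sn_allele", call. = FALSE)
  if (any(snr_het < 0 | snr_het > 1) || stutter_snr < 0 || stutter_snr > 1)
    stop("SNR thresholds must lie in [0, 1]", call. = FALSE)
  if (max_iterations < 1L) stop("max_iterations must be >= 1", call. = FALSE)
  structure(
    list(sn_interpretation = sn_interpretation, sn_allele = sn_allele,
         snr_het = snr_het, stutter_snr = stutter_snr,
         max_iterations = as.integer(max_iterations), alignment = alignment),
    class = "threshold_config"
  )
}

#' Look up the heterozygosity SNR threshold for a locus
#'
#' @param cfg A [threshold_config()].
#' @param locus Locus name.
#' @return The SNR threshold; error if `snr_het` is a per-locus map and the
#'   locus is absent (no silent default).
#' @export
snr_het_for <- function(cfg, locus) {
  thr <- cfg$snr_het
  if (is.null(names(thr))) {
    if (length(thr) != 1L)
      stop("unnamed snr_het must be a single value", call. = FALSE)
    return(unname(thr))
  }
  if (!locus %in% names(thr))
    stop("no snr_het threshold configured for locus '", locus, "'",
         call. = FALSE)
  unname(thr[[locus]])
}

#' Read a thresholds configuration from YAML
#'
#' Recognised keys: `sn_interpretation`, `sn_allele`, `snr_het` (scalar or
#' locus->value map), `stutter_snr`, `max_iterations`, and an `alignment:`
#' block (`match`, `mismatch`, `gap_open`, `gap_extend`,
#' `min_flank_identity`). Missing keys fall back to the defaults of
#' [threshold_config()].
#'
#' @param path YAML file path.
#' @return A `threshold_config`.
#' @export
read_thresholds <- function(path) {
  if (!file.exists(path)) stop("thresholds file not found: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  if (is.null(y)) y <- list()
  ap <- do.call(alignment_params,
                if (is.null(y$alignment)) list() else as.list(y$alignment))
  snr <- y$snr_het
  if (is.null(snr)) snr <- 0.30
  if (is.list(snr)) snr <- unlist(snr)
  args <- list(snr_het = snr, alignment = ap)
  for (k in c("sn_interpretation", "sn_allele", "stutter_snr", "max_iterations"))
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  do.call(threshold_config, args)
}

#' Read a population allele-frequency table
#'
#' Expects a TSV with columns `locus`, `allele`, `freq`. Frequencies must lie
#' in (0, 1] and sum to at most 1 (small tolerance) within each locus.
#'
#' @param path TSV file path.
#' @return A named list (by locus) of named numeric vectors (by allele
#'   designation), class `allele_freqs`.
#' @export
read_allele_freqs <- function(path) {
  if (!file.exists(path)) stop("frequency file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = c("character", "character", "numeric"))
  need <- c("locus", "allele", "freq")
  if (!all(need %in% names(df)))
    stop("frequency file must have columns locus, allele, freq", call. = FALSE)
  if (any(df$freq <= 0 | df$freq > 1))
    stop("allele frequencies must lie in (0, 1]", call. = FALSE)
  out <- lapply(split(df, df$locus), function(d) {
    if (anyDuplicated(d$allele))
      stop("duplicate allele entries for locus '", d$locus[1], "'", call. = FALSE)
    if (sum(d$freq) > 1 + 1e-6)
      stop("frequencies for locus '", d$locus[1], "' sum to > 1", call. = FALSE)
    stats::setNames(d$freq, d$allele)
  })
  structure(out, class = "allele_freqs")
}

#' Read genotype profiles
#'
#' Expects a TSV with columns `sample`, `locus`, `allele1`, `allele2`
#' (`allele2` may equal `allele1` or be empty for homozygotes).
#'
#' @param path TSV file path.
#' @return A named list (by sample) of named lists (by locus) of character
#'   vectors of 1-2 allele designations.
#' @export
read_profiles <- function(path) {
  if (!file.exists(path)) stop("profile file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character")
  need <- c("sample", "locus", "allele1", "allele2")
  if (!all(need %in% names(df)))
    stop("profile file must have columns sample, locus, allele1, allele2",
         call. = FALSE)
  lapply(split(df, df$sample), function(d) {
    g <- lapply(seq_len(nrow(d)), function(i) {
      a <- c(d$allele1[i], d$allele2[i])
      a <- a[nzchar(a) & !is.na(a)]
      unique_or_pair(a)
    })
    stats::setNames(g, d$locus)
  })
}

# keep a homozygote as one designation, a heterozygote as two
unique_or_pair <- function(a) {
  if (length(a) == 2L && a[1] == a[2]) a[1] else a
}
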