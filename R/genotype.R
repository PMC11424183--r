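#' Construct an allele call
#'
#' One candidate allele: its CE-compatible designation, inferred repeat
#' structure, supporting-read number and ratio.
#'
#' @param designation Designation string, e.g. `"24.2"`.
#' @param structure A `repeat_structure` (may be `NULL` for hand-built
#'   calls in calibration workflows).
#' @param sn Supporting-read number.
#' @param snr Supporting-read number ratio in (0, 1].
#' @return An object of class `allele_call`.
#' @export
allele_call <- function(designation, structure = NULL, sn, snr) {
  stopifnot(nzchar(designation), sn >= 1, snr > 0, snr <= 1)
  structure(list(designation = as.character(designation),
                 structure = structure, sn = as.integer(sn), snr = snr),
            class = "allele_call")
}

.call_core_len <- function(call, period) {
  if (!is.null(call$structure)) return(call$structure$core_len)
  # designation-derived length (pads cancel when comparing two calls)
  d <- as.numeric(strsplit(call$designation, ".", fixed = TRUE)[[1]])
  as.integer(d[1] * period + if (length(d) > 1) d[2] else 0)
}

#' Filter stutter artifacts from candidate alleles
#'
#' A candidate is removed as stutter when its core is exactly one repeat
#' unit (one period) shorter than a kept candidate with a larger SN *and*
#' its SNR is below `cfg$stutter_snr`. A strong minor allele one unit short
#' of the major (a genuine adjacent heterozygote) is kept because its SNR
#' exceeds the ceiling.
#'
#' @param candidates List of [allele_call()]s sorted by `sn` descending.
#' @param cfg A [threshold_config()].
#' @param period Repeat-unit length of the locus.
#' @return A list with elements `kept` and `removed`.
#' @export
filter_stutter <- function(candidates, cfg, period) {
  kept <- list()
  removed <- list()
  for (cand in candidates) {
    len <- .call_core_len(cand, period)
    is_stutter <- FALSE
    for (k in kept) {
      if (k$sn > cand$sn &&
          .call_core_len(k, period) - len == period &&
          cand$snr < cfg$stutter_snr) {
        is_stutter <- TRUE
        break
      }
    }
    if (is_stutter) removed[[length(removed) + 1L]] <- cand
    else kept[[length(kept) + 1L]] <- cand
  }
  list(kept = kept, removed = removed)
}

#' Call the genotype of one locus from candidate alleles
#'
#' Applies the SN/SNR decision ladder to stutter-filtered candidates sorted
#' by SN descending:
#' \enumerate{
#'   \item no candidates, or major SN below `sn_interpretation` ->
#'     status `Interpretation` (inadequate coverage);
#'   \item a single candidate -> `Pass`, homozygous;
#'   \item minor SNR at or above the locus threshold and minor SN at least
#'     `sn_allele` -> `Pass`, heterozygous;
#'   \item minor SNR at or above the threshold but minor SN below
#'     `sn_allele` while the major reaches it -> status `Imbalance`
#'     (ambiguous minor-allele support);
#'   \item minor SNR below the threshold -> `Pass`, homozygous for the
#'     major allele.
#' }
#'
#' @param candidates List of [allele_call()]s, post-stutter filter, sorted
#'   by `sn` descending.
#' @param cfg A [threshold_config()].
#' @param locus Locus name (used to look up the per-locus SNR threshold;
#'   a locus absent from a per-locus map is a configuration error).
#' @param filtered_stutter Optional list of removed stutter calls, carried
#'   into the result for reporting.
#' @return An object of class `locus_genotype` with fields `locus`,
#'   `status` (`"Pass"`, `"Interpretation"`, `"Imbalance"`), `zygosity`
#'   (`"HET"`/`"HOM"`, `Pass` only), `calls` (0-2 [allele_call()]s ordered
#'   by designation) and `filtered_stutter`.
#' @export
call_genotype <- function(candidates, cfg, locus,
                          filtered_stutter = list()) {
  thr <- snr_het_for(cfg, locus)
  result <- function(status, zygosity = NA_character_, calls = list()) {
    if (length(calls) == 2L) {
      ord <- order(vapply(calls, function(x) .designation_sortkey(x$designation), 0))
      calls <- calls[ord]
    }
    structure(list(locus = locus, status = status, zygosity = zygosity,
                   calls = calls, filtered_stutter = filtered_stutter),
              class = "locus_genotype")
  }
  if (length(candidates) == 0L || candidates[[1]]$sn < cfg$sn_interpretation)
    return(result("Interpretation"))
  major <- candidates[[1]]
  if (length(candidates) == 1L)
    return(result("Pass", "HOM", list(major)))
  minor <- candidates[[2]]
  if (minor$snr >= thr) {
    if (minor$sn >= cfg$sn_allele)
      return(result("Pass", "HET", list(major, minor)))
    if (major$sn >= cfg$sn_allele)
      return(result("Imbalance"))
    # neither allele reaches the confident-call SN: insufficient support
    return(result("Imbalance"))
  }
  result("Pass", "HOM", list(major))
}

.designation_sortkey <- function(d) {
  p <- as.numeric(strsplit(d, ".", fixed = TRUE)[[1]])
  p[1] + if (length(p) > 1) p[2] / 100 else 0
}

#' @export
print.locus_genotype <- function(x, ...) {
  des <- vapply(x$calls, `[[`, "", "designation")
  cat(sprintf("<locus_genotype> %s  %s%s  [%s]\n", x$locus, x$status,
              if (!is.na(x$zygosity)) paste0("/", x$zygosity) else "",
              paste(des, collapse = ", ")))
  invisible(x)
}

#' Classify a genotype call against a benchmark genotype
#'
#' Five mutually exclusive categories, comparing designation multisets
#' (a homozygote counts as a duplicated allele): `EXACT_MATCH` both alleles
#' correct; `INCOMPLETE_MATCH` both correct once the fractional
#' (incomplete-repeat) part is ignored; `ONE_MATCH` exactly one allele
#' correct; `INCOMPLETE_ONE_MATCH` exactly one correct ignoring fractional
#' parts; `MISMATCH` otherwise.
#'
#' @param call A `Pass` [call_genotype()] result, or a character vector of
#'   1-2 designations.
#' @param truth Character vector of 1-2 benchmark designations.
#' @return The category string.
#' @export
classify_concordance <- function(call, truth) {
  des <- if (inherits(call, "locus_genotype")) {
    if (call$status != "Pass")
      stop("only Pass calls are classified; '", call$status,
           "' results are excluded upstream", call. = FALSE)
    vapply(call$calls, `[[`, "", "designation")
  } else as.character(call)
  stopifnot(length(des) %in% 1:2, length(truth) %in% 1:2)
  pair <- function(x) if (length(x) == 1L) c(x, x) else x
  des <- pair(des); truth <- pair(as.character(truth))
  n_common <- function(a, b) {
    cnt <- 0L
    for (x in a) {
      i <- match(x, b)
      if (!is.na(i)) { b <- b[-i]; cnt <- cnt + 1L }
    }
    cnt
  }
  strip <- function(x) sub("\\..*$", "", x)
  full <- n_common(des, truth)
  part <- n_common(strip(des), strip(truth))
  if (full == 2L) "EXACT_MATCH"
  else if (part == 2L) "INCOMPLETE_MATCH"
  else if (full == 1L) "ONE_MATCH"
  else if (part == 1L) "INCOMPLETE_ONE_MATCH"
  else "MISMATCH"
}

#' Sweep SN and SNR thresholds against a truth set
#'
#' Re-calls genotypes for every combination of a minor-allele SN threshold
#' and an SNR heterozygosity threshold and computes per-locus genotyping
#' accuracy: the proportion of all truth items at the locus called exactly
#' right (`Interpretation`/`Imbalance` results are excluded from comparison
#' and so count against accuracy). The per-locus SNR threshold is then
#' selected, at `chosen_sn`, as the median of the SNR grid values attaining
#' that locus's peak accuracy.
#'
#' @param items A list; each element is a list with `locus` (name),
#'   `candidates` (list of [allele_call()]s sorted by sn descending, post
#'   stutter filter) and `truth` (character vector of 1-2 designations).
#' @param sn_grid SN grid (default `seq(0, 50, by = 5)`).
#' @param snr_grid SNR grid (default `seq(0, 1, by = 0.01)`).
#' @param chosen_sn The SN value at which per-locus SNR thresholds are
#'   selected (default 25).
#' @param cfg Base [threshold_config()] supplying `sn_interpretation`.
#' @return A list of class `snr_sweep`: `surface` (data frame `locus`,
#'   `sn`, `snr`, `n_called`, `accuracy`), `selection` (data frame `locus`,
#'   `snr_het`), and `chosen_sn`.
#' @export
sweep_thresholds <- function(items, sn_grid = seq(0, 50, by = 5),
                             snr_grid = seq(0, 1, by = 0.01),
                             chosen_sn = 25,
                             cfg = threshold_config()) {
  if (!length(items)) stop("empty truth set", call. = FALSE)
  loci <- sort(unique(vapply(items, `[[`, "", "locus")))

  # precompute per item: major/minor sn + snr and concordance of the two
  # possible Pass outcomes (HOM major / HET major+minor)
  pre <- lapply(items, function(it) {
    cand <- it$candidates
    major <- if (length(cand)) cand[[1]] else NULL
    minor <- if (length(cand) > 1L) cand[[2]] else NULL
    des1 <- if (!is.null(major)) major$designation
    hom_exact <- !is.null(major) &&
      classify_concordance(des1, it$truth) == "EXACT_MATCH"
    het_exact <- !is.null(minor) &&
      classify_concordance(c(des1, minor$designation), it$truth) == "EXACT_MATCH"
    list(locus = it$locus,
         major_sn = if (is.null(major)) 0L else major$sn,
         minor_sn = if (is.null(minor)) NA_integer_ else minor$sn,
         minor_snr = if (is.null(minor)) NA_real_ else minor$snr,
         hom_exact = hom_exact, het_exact = het_exact)
  })

  grid <- expand.grid(sn = sn_grid, snr = snr_grid, KEEP.OUT.ATTRS = FALSE)
  rows <- vector("list", length(loci) * nrow(grid))
  k <- 0L
  for (loc in loci) {
    its <- pre[vapply(pre, `[[`, "", "locus") == loc]
    major_sn <- vapply(its, `[[`, 0L, "major_sn")
    minor_sn <- vapply(its, `[[`, NA_integer_, "minor_sn")
    minor_snr <- vapply(its, `[[`, NA_real_, "minor_snr")
    hom_ok <- vapply(its, `[[`, NA, "hom_exact")
    het_ok <- vapply(its, `[[`, NA, "het_exact")
    for (g in seq_len(nrow(grid))) {
      sn <- grid$sn[g]; snr <- grid$snr[g]
      interp <- major_sn < cfg$sn_interpretation
      is_het <- !is.na(minor_snr) & minor_snr >= snr
      imbal <- !interp & is_het & (is.na(minor_sn) | minor_sn < sn)
      called <- !interp & !imbal
      exact <- called & ifelse(is_het, het_ok, hom_ok)
      k <- k + 1L
      rows[[k]] <- data.frame(locus = loc, sn = sn, snr = snr,
                              n_called = sum(called),
                              accuracy = sum(exact) / length(called))
    }
  }
  surface <- do.call(rbind, rows)

  selection <- do.call(rbind, lapply(loci, function(loc) {
    s <- surface[surface$locus == loc & surface$sn == chosen_sn, ]
    acc <- s$accuracy
    if (all(is.na(acc)))
      return(data.frame(locus = loc, snr_het = NA_real_))
    peak <- max(acc, na.rm = TRUE)
    plateau <- s$snr[!is.na(acc) & acc == peak]
    data.frame(locus = loc, snr_het = stats::median(plateau))
  }))
  structure(list(surface = surface, selection = selection,
                 chosen_sn = chosen_sn),
            class = "snr_sweep")
}

#' @export
print.snr_sweep <- function(x, ...) {
  cat(sprintf("<snr_sweep> %d loci, %d grid cells (at SN = %s):\n",
              nrow(x$selection),
              nrow(x$surface) / max(1, nrow(x$selection)), x$chosen_sn))
  print(x$selection, row.names = FALSE)
  invisible(x)
}
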