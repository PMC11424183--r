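#' Draw random true genotypes for a toy panel
#'
#' For each replicate and locus, draws a heterozygous (probability `p_het`)
#' or homozygous genotype whose alleles are pure runs of the locus's first
#' motif with unit counts sampled uniformly from `units_range`
#' (heterozygote alleles are distinct).
#'
#' @param panel Named list of [panel_locus()].
#' @param n Number of replicates.
#' @param seed Integer seed.
#' @param units_range Length-2 integer vector of repeat-unit counts
#'   (default `c(8, 14)`).
#' @param p_het Probability of a heterozygous genotype (default 0.5).
#' @return A data frame: `replicate`, `locus`, `bracket1`, `bracket2`
#'   (`NA` for homozygotes), `truth1`, `truth2` (allele designations).
#' @export
simulate_genotypes <- function(panel, n, seed = 1L,
                               units_range = c(8L, 14L), p_het = 0.5) {
  .with_seed(seed, {
    rows <- list()
    for (rep_i in seq_len(n)) {
      for (locus in panel) {
        units <- sample(seq(units_range[1], units_range[2]), 2L)
        het <- stats::runif(1) < p_het
        b1 <- sprintf("[%s]%d", locus$motifs[1], units[1])
        b2 <- if (het) sprintf("[%s]%d", locus$motifs[1], units[2]) else NA
        d1 <- designate_allele(units[1] * locus$period, locus, c(0L, 0L))
        d2 <- if (het) designate_allele(units[2] * locus$period, locus, c(0L, 0L)) else d1
        rows[[length(rows) + 1L]] <- data.frame(
          replicate = rep_i, locus = locus$name,
          bracket1 = b1, bracket2 = b2, truth1 = d1, truth2 = d2,
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
}

#' Simulate and genotype replicate read sets
#'
#' For every row of a truth table (one locus in one replicate), simulates
#' `depth` noisy reads of the true genotype and runs the in-memory pipeline
#' (trim, cluster, structure inference, stutter filter, decision ladder).
#' Each replicate draws its own simulation seed from `seed`.
#'
#' @param panel Named list of [panel_locus()].
#' @param truth Truth table from [simulate_genotypes()].
#' @param depth Reads per locus per replicate (default 100).
#' @param em An [error_model()] template; its `seed` field is replaced per
#'   replicate.
#' @param cfg A [threshold_config()].
#' @param seed Base seed for the per-replicate simulation seeds.
#' @return A data frame with one row per truth row: `replicate`, `locus`,
#'   `status`, `allele1`, `allele2`, `truth1`, `truth2`, `category`
#'   (concordance category for `Pass` calls, `NA` otherwise). Attribute
#'   `items` holds, per row, the stutter-filtered candidate
#'   [allele_call()]s with the truth pair, ready for [sweep_thresholds()].
#' @export
genotype_replicates <- function(panel, truth, depth = 100L,
                                em = error_model(), cfg = threshold_config(),
                                seed = 1L) {
  items <- vector("list", nrow(truth))
  rows <- vector("list", nrow(truth))
  for (i in seq_len(nrow(truth))) {
    locus <- panel[[truth$locus[i]]]
    gt <- c(truth$bracket1[i],
            if (!is.na(truth$bracket2[i])) truth$bracket2[i])
    em_i <- em
    em_i$seed <- (seed + 7919L * i) %% .Machine$integer.max
    reads <- simulate_reads(locus, gt, depth, em_i)
    res <- call_locus(reads$sequence, locus, cfg)
    truth_pair <- unique_or_pair(c(truth$truth1[i], truth$truth2[i]))
    des <- vapply(res$calls, `[[`, "", "designation")
    rows[[i]] <- data.frame(
      replicate = truth$replicate[i], locus = truth$locus[i],
      status = res$status,
      allele1 = if (length(des)) des[1] else NA_character_,
      allele2 = if (length(des)) des[length(des)] else NA_character_,
      truth1 = truth$truth1[i], truth2 = truth$truth2[i],
      category = if (res$status == "Pass")
        classify_concordance(res, truth_pair) else NA_character_,
      stringsAsFactors = FALSE)
    kept <- filter_stutter(attr(res, "candidates"), cfg, locus$period)$kept
    items[[i]] <- list(locus = truth$locus[i], candidates = kept,
                       truth = truth_pair)
  }
  out <- do.call(rbind, rows)
  attr(out, "items") <- items
  out
}

#' Select the SN threshold from a sweep surface
#'
#' Mirrors the calibration rule used for threshold selection: for each SN
#' grid value compute each locus's maximum accuracy over the SNR grid, and
#' pick the smallest SN at which every locus reaches `min_accuracy`. If no
#' SN qualifies, the SN maximising the mean per-locus peak accuracy is
#' returned.
#'
#' @param sweep An `snr_sweep` from [sweep_thresholds()].
#' @param min_accuracy Per-locus peak-accuracy requirement (default 0.95).
#' @return The selected SN grid value.
#' @export
select_sn_threshold <- function(sweep, min_accuracy = 0.95) {
  surf <- sweep$surface
  sn_vals <- sort(unique(surf$sn))
  peak <- sapply(sn_vals, function(sn) {
    s <- surf[surf$sn == sn, ]
    tapply(s$accuracy, s$locus, function(a)
      if (all(is.na(a))) NA_real_ else max(a, na.rm = TRUE))
  })
  peak <- matrix(peak, ncol = length(sn_vals))
  ok <- apply(peak, 2L, function(p) all(!is.na(p) & p >= min_accuracy))
  if (any(ok)) return(sn_vals[which(ok)[1]])
  sn_vals[which.max(colMeans(peak, na.rm = TRUE))]
}

#' Calibrate thresholds on training replicates, then measure recovery
#'
#' The desk-scale validation workflow: simulate training replicates, sweep
#' the SN x SNR grid against their truth, select the SN threshold
#' ([select_sn_threshold()]) and the per-locus SNR thresholds (median of
#' each locus's peak-accuracy plateau at the selected SN), then genotype
#' fresh evaluation replicates under the calibrated config and measure the
#' exact-match rate among `Pass` calls (the accuracy metric: results
#' flagged `Interpretation`/`Imbalance` are excluded) plus the calling
#' ratio.
#'
#' @param panel Named list of [panel_locus()].
#' @param n_train,n_eval Training / evaluation replicates (defaults 50 and
#'   200).
#' @param depth Reads per locus (default 100).
#' @param em An [error_model()] template.
#' @param seed Integer seed driving genotypes and reads.
#' @return A list: `recovery` (exact-match rate among Pass calls),
#'   `calling_ratio`, `cfg` (calibrated [threshold_config()]), `sweep`,
#'   `results` (evaluation data frame from [genotype_replicates()]).
#' @export
recovery_experiment <- function(panel, n_train = 50L, n_eval = 200L,
                                depth = 100L, em = error_model(),
                                seed = 1L) {
  base_cfg <- threshold_config(snr_het = 0.0001)  # call everything, then sweep
  truth_tr <- simulate_genotypes(panel, n_train, seed = seed)
  train <- genotype_replicates(panel, truth_tr, depth, em, base_cfg,
                               seed = seed + 1L)
  sw <- sweep_thresholds(attr(train, "items"))
  sn_sel <- select_sn_threshold(sw)
  sw_at_sn <- sweep_thresholds(attr(train, "items"), chosen_sn = sn_sel)
  snr_map <- stats::setNames(sw_at_sn$selection$snr_het,
                             sw_at_sn$selection$locus)
  snr_map[is.na(snr_map)] <- 0.30
  # the Interpretation floor is fixed at 10; sn_allele may not undercut it
  cfg <- threshold_config(sn_allele = max(sn_sel, 10L), snr_het = snr_map)

  truth_ev <- simulate_genotypes(panel, n_eval, seed = seed + 2L)
  eval <- genotype_replicates(panel, truth_ev, depth, em, cfg,
                              seed = seed + 3L)
  called <- eval$status == "Pass"
  list(recovery = mean(eval$category[called] == "EXACT_MATCH"),
       calling_ratio = mean(called),
       cfg = cfg, sweep = sw_at_sn, results = eval)
}

#' Build a toy allele-frequency table
#'
#' Random but deterministic per-locus frequency distributions over integer
#' allele designations, normalised to sum to 1.
#'
#' @param n_loci Number of loci (default 15).
#' @param n_alleles Alleles per locus (default 7, designations 8-14).
#' @param seed Integer seed.
#' @return An `allele_freqs` object.
#' @export
toy_allele_freqs <- function(n_loci = 15L, n_alleles = 7L, seed = 1L) {
  .with_seed(seed, {
    out <- lapply(seq_len(n_loci), function(i) {
      w <- stats::rgamma(n_alleles, shape = 2)
      stats::setNames(w / sum(w), as.character(seq(8L, by = 1L,
                                                   length.out = n_alleles)))
    })
    names(out) <- sprintf("TL%02d", seq_len(n_loci))
    structure(out, class = "allele_freqs")
  })
}

#' Simulate a true parent-child trio by Mendelian dropping
#'
#' Parents are drawn from Hardy-Weinberg proportions of the frequency
#' table; the child inherits one allele from each parent, uniformly.
#'
#' @param freqs An `allele_freqs` object.
#' @param seed Integer seed.
#' @return A list of profiles `child`, `mother`, `father` (named lists:
#'   locus -> 1-2 designations).
#' @export
simulate_trio <- function(freqs, seed = 1L) {
  .with_seed(seed, {
    draw_gt <- function(p) sample(names(p), 2L, replace = TRUE, prob = p)
    child <- list(); mother <- list(); father <- list()
    for (loc in names(freqs)) {
      m <- draw_gt(freqs[[loc]])
      f <- draw_gt(freqs[[loc]])
      c_al <- c(sample(m, 1L), sample(f, 1L))
      mother[[loc]] <- unique_or_pair(m)
      father[[loc]] <- unique_or_pair(f)
      child[[loc]] <- unique_or_pair(c_al)
    }
    list(child = child, mother = mother, father = father)
  })
}
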