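# allele frequency lookup with optional floor for alleles absent from the table
.freq_of <- function(freqs, locus, allele, min_freq = NULL) {
  tab <- freqs[[locus]]
  if (is.null(tab))
    stop("locus '", locus, "' absent from frequency table", call. = FALSE)
  f <- unname(tab[allele])
  if (length(f) != 1L || is.na(f)) {
    if (is.null(min_freq))
      stop("allele '", allele, "' at locus '", locus,
           "' absent from frequency table (supply min_freq to floor it)",
           call. = FALSE)
    f <- min_freq
  }
  f
}

.gt_alleles <- function(g) if (length(g) == 1L) c(g, g) else as.character(g)

# P(genotype) under Hardy-Weinberg
.gt_prob <- function(a, p) if (a[1] == a[2]) p[1]^2 else 2 * p[1] * p[2]

# transmission probabilities of a parent's alleles: named vector
.transmit <- function(g) {
  a <- .gt_alleles(g)
  if (a[1] == a[2]) stats::setNames(1, a[1])
  else stats::setNames(c(0.5, 0.5), a)
}

#' Identity likelihood ratio (random-match product rule)
#'
#' Per-locus LR = 1 / P(genotype) under Hardy-Weinberg: `1 / p^2` for a
#' homozygote, `1 / (2 p_a p_b)` for a heterozygote; the combined LR is the
#' product over loci (accumulated in log space).
#'
#' @param profile Named list: locus -> character vector of 1-2 allele
#'   designations.
#' @param freqs An `allele_freqs` table from [read_allele_freqs()], or a
#'   named list of named numeric vectors.
#' @param min_freq Optional floor substituted for alleles absent from the
#'   table; by default an absent allele is an error.
#' @return A list of class `identity_lr`: `per_locus` (data frame `locus`,
#'   `genotype`, `lr`), `combined`, `log10_combined`.
#' @export
identity_lr <- function(profile, freqs, min_freq = NULL) {
  stopifnot(length(profile) >= 1L)
  loci <- sort(names(profile))
  per <- do.call(rbind, lapply(loci, function(loc) {
    a <- .gt_alleles(profile[[loc]])
    p <- vapply(a, function(x) .freq_of(freqs, loc, x, min_freq), 0)
    data.frame(locus = loc, genotype = paste(sort(a), collapse = "/"),
               lr = 1 / .gt_prob(a, p), stringsAsFactors = FALSE)
  }))
  log10_combined <- sum(log10(per$lr))
  structure(list(per_locus = per, combined = 10^log10_combined,
                 log10_combined = log10_combined),
            class = "identity_lr")
}

#' @export
print.identity_lr <- function(x, ...) {
  cat(sprintf("<identity_lr> %d loci, combined LR = %.4g (log10 = %.2f)\n",
              nrow(x$per_locus), x$combined, x$log10_combined))
  invisible(x)
}

# per-locus trio PI: X = P(child | mother, alleged father is father),
# Y = P(child | mother, random man); both sum over consistent transmissions
.pi_trio <- function(child, mother, father, p_of) {
  ca <- .gt_alleles(child)
  tm <- .transmit(mother)
  tf <- .transmit(father)
  consistent <- function(m, f) {
    (m == ca[1] && f == ca[2]) || (m == ca[2] && f == ca[1])
  }
  # ordered (maternal, paternal) assignments are distinct events
  x <- 0; y <- 0
  for (m in names(tm)) for (f in unique(c(names(tf), ca))) {
    if (!consistent(m, f)) next
    if (f %in% names(tf)) x <- x + tm[[m]] * tf[[f]]
    y <- y + tm[[m]] * p_of(f)
  }
  if (y == 0) return(NA_real_)  # child inconsistent with mother
  x / y
}

# per-locus duo PI (no mother): X = P(child | alleged father, random mother),
# Y = P(child) under Hardy-Weinberg
.pi_duo <- function(child, father, p_of) {
  ca <- .gt_alleles(child)
  tf <- .transmit(father)
  p <- c(p_of(ca[1]), p_of(ca[2]))
  y <- .gt_prob(ca, p)
  x <- 0
  if (ca[1] == ca[2]) {
    if (ca[1] %in% names(tf)) x <- tf[[ca[1]]] * p[1]
  } else {
    if (ca[1] %in% names(tf)) x <- x + tf[[ca[1]]] * p[2]
    if (ca[2] %in% names(tf)) x <- x + tf[[ca[2]]] * p[1]
  }
  x / y
}

#' Paternity index for a trio or motherless duo
#'
#' Standard Essen-Moller likelihood ratios under Hardy-Weinberg with no
#' mutation model and no coancestry correction. For a trio the maternal
#' allele is resolved first and ambiguous cases are summed over all
#' consistent transmissions; for a duo the motherless formulas are used. A
#' locus where the alleged father carries neither child allele (or, in a
#' trio, where no consistent transmission exists) is an exclusion and gets
#' PI 0 with a warning. The combined PI is the product over shared loci.
#'
#' @param child,alleged_father Named lists: locus -> 1-2 designations.
#' @param mother Optional named list for the mother (trio formulas).
#' @param freqs An `allele_freqs` table.
#' @param min_freq Optional frequency floor for alleles absent from the
#'   table.
#' @return A list of class `paternity_index`: `per_locus` (data frame),
#'   `combined`, `log10_combined`, `n_exclusions` and `confirmable`
#'   (combined PI above 1e4, the conventional confirmation standard).
#' @export
paternity_index <- function(child, alleged_father, mother = NULL, freqs,
                            min_freq = NULL) {
  loci <- intersect(names(child), names(alleged_father))
  if (!is.null(mother)) loci <- intersect(loci, names(mother))
  loci <- sort(loci)
  if (!length(loci)) stop("no shared loci between profiles", call. = FALSE)
  per <- do.call(rbind, lapply(loci, function(loc) {
    p_of <- function(a) .freq_of(freqs, loc, a, min_freq)
    pi <- if (is.null(mother)) .pi_duo(child[[loc]], alleged_father[[loc]], p_of)
          else .pi_trio(child[[loc]], mother[[loc]], alleged_father[[loc]], p_of)
    if (is.na(pi)) {
      warning("locus ", loc, ": child genotype inconsistent with mother; ",
              "locus skipped")
      return(data.frame(locus = loc, pi = NA_real_))
    }
    if (pi == 0)
      warning("locus ", loc, ": alleged father excluded (PI = 0; ",
              "no mutation model)")
    data.frame(locus = loc, pi = pi)
  }))
  used <- per$pi[!is.na(per$pi)]
  combined <- if (any(used == 0)) 0 else exp(sum(log(used)))
  log10_combined <- if (combined > 0) sum(log10(used)) else -Inf
  structure(list(per_locus = per, combined = combined,
                 log10_combined = log10_combined,
                 n_exclusions = sum(used == 0),
                 confirmable = combined > 1e4),
            class = "paternity_index")
}

#' @export
print.paternity_index <- function(x, ...) {
  cat(sprintf(
    "<paternity_index> %d loci, combined PI = %.4g (log10 = %.2f)%s%s\n",
    nrow(x$per_locus), x$combined, x$log10_combined,
    if (x$n_exclusions) sprintf(", %d exclusion(s)", x$n_exclusions) else "",
    if (x$confirmable) " - relationship confirmable (PI > 1e4)" else ""))
  invisible(x)
}
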