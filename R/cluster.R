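# Hamming distance for equal-length strings; Inf when lengths differ.
.sub_distance <- function(a, b) {
  if (nchar(a) != nchar(b)) return(Inf)
  sum(utf8ToInt(a) != utf8ToInt(b))
}

#' Cluster trimmed core fragments into candidate alleles
#'
#' Greedy clustering of trimmed core sequences under the "identical or 1-bp
#' mismatch" rule: two sequences belong to one group when a gap-free global
#' alignment relates them with at most one substitution, i.e. they have
#' equal length and Hamming distance <= 1 (an indel would change the allele
#' length and hence its designation, so indels never merge). Distinct
#' sequences are processed in descending order of exact multiplicity
#' (ties lexicographic) and each joins the first existing cluster whose
#' representative is within one substitution, else founds a new cluster;
#' the representative is the cluster's most frequent exact sequence. This
#' order makes the clustering invariant to the input ordering of fragments.
#'
#' @param core_seqs Character vector of trimmed core sequences (pads
#'   included).
#' @param read_ids Optional character vector of read identifiers, parallel
#'   to `core_seqs`.
#' @return A list of clusters sorted by `sn` (supporting-read number)
#'   descending, ties by representative; each cluster is a list with
#'   `representative`, `sn`, `snr` (sn over the major cluster's sn) and
#'   `members` (read ids). Class `allele_clusters`.
#' @export
cluster_fragments <- function(core_seqs, read_ids = NULL) {
  if (length(core_seqs) == 0L)
    return(structure(list(), class = "allele_clusters"))
  if (is.null(read_ids)) read_ids <- paste0("read", seq_along(core_seqs))
  stopifnot(length(read_ids) == length(core_seqs))

  tab <- table(core_seqs)
  uniq <- names(tab)[order(-as.integer(tab), names(tab))]

  reps <- character(0)
  assign_of <- integer(length(uniq))
  for (i in seq_along(uniq)) {
    hit <- 0L
    for (c in seq_along(reps)) {
      if (.sub_distance(uniq[i], reps[c]) <= 1) { hit <- c; break }
    }
    if (hit == 0L) {
      reps <- c(reps, uniq[i])
      hit <- length(reps)
    }
    assign_of[i] <- hit
  }

  members_by_seq <- split(read_ids, core_seqs)
  clusters <- lapply(seq_along(reps), function(c) {
    seqs <- uniq[assign_of == c]
    ids <- sort(unlist(members_by_seq[seqs], use.names = FALSE))
    list(representative = reps[c], sn = length(ids), members = ids)
  })
  sn <- vapply(clusters, `[[`, 0L, "sn")
  rep_seq <- vapply(clusters, `[[`, "", "representative")
  clusters <- clusters[order(-sn, rep_seq)]
  major_sn <- clusters[[1]]$sn
  clusters <- lapply(clusters, function(cl) { cl$snr <- cl$sn / major_sn; cl })
  structure(clusters, class = "allele_clusters")
}

#' @export
print.allele_clusters <- function(x, ...) {
  cat(sprintf("<allele_clusters> %d cluster(s)\n", length(x)))
  for (cl in utils::head(x, 5))
    cat(sprintf("  sn %4d  snr %.3f  %s\n", cl$sn, cl$snr, cl$representative))
  if (length(x) > 5) cat("  ...\n")
  invisible(x)
}

#' Select the top candidate alleles
#'
#' Keeps the `k` clusters with the highest supporting-read numbers (the
#' input is already sorted by `sn` descending with lexicographic
#' tie-break, so a tie at rank `k` retains the lexicographically smaller
#' representative). SNR values are unchanged: the major cluster is always
#' retained.
#'
#' @param clusters An `allele_clusters` list from [cluster_fragments()].
#' @param k Number of candidates to keep (default 3).
#' @return The first `min(k, length(clusters))` clusters.
#' @export
select_candidates <- function(clusters, k = 3L) {
  structure(utils::head(clusters, k), class = "allele_clusters")
}
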