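# Shared fixtures, built in code at test time.

# an FGA-like locus: period-4 motif family, 30-nt flanks
fga_locus <- function() {
  panel_locus(
    name = "FGA", chrom = "chr4", core_start = 101L, core_end = 198L,
    prefix_flank = "TTCTATGACTTTGCGCTTCAGGGATAAATG",
    suffix_flank = "TCTGTCTGTCTGTCCTTCCCAGGTTGTCCC",
    motifs = c("GGAA", "AAAG", "AGAA", "GAAA"), period = 4L
  )
}

# printed-form bracket of the FGA 24.2 variant allele used as the worked
# example throughout the suite
fga_f25_bracket <- "[GGAA]2_GGAG_AA_[AAAG]16_[AGAA]1_AAAA_[GAAA]3"

# one deterministic toy locus + reference for pipeline tests
toy_fixture <- function(seed = 7L, n_loci = 1L, period = 4L) {
  build_toy_panel(n_loci = n_loci, period = period, seed = seed)
}

# thresholds sized for shallow simulated depth: the Interpretation floor is
# the method's fixed 10, the confident-allele SN matches depth/10
shallow_cfg <- function(sn_allele = 10L, snr_het = 0.30) {
  threshold_config(sn_interpretation = 10L, sn_allele = sn_allele,
                   snr_het = snr_het)
}

# write a simulated read set to an indexed BAM; returns the BAM path
sim_bam_fixture <- function(reads, reference, dir = NULL) {
  if (is.null(dir)) {
    dir <- tempfile("bamfix")
    dir.create(dir)
  }
  sam <- file.path(dir, "sim.sam")
  write_sam(reads, reference, sam)
  sam_to_bam(sam)
}

make_call <- function(designation, sn, snr, core_len = NULL, period = 4L) {
  st <- NULL
  if (!is.null(core_len))
    st <- structure(list(core_len = core_len), class = "repeat_structure")
  allele_call(designation, st, sn = sn, snr = snr)
}
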