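test_that("panel_locus validates its invariants", {
  expect_error(panel_locus("X", "chr1", 10, 5, "ACGT", "ACGT", "AAAG", 4),
               "malformed coordinates")
  expect_error(panel_locus("X", "chr1", 1, 10, "ACGT", "ACGT", "AAAGA", 5,
                           ),
               NA)
  expect_error(panel_locus("X", "chr1", 1, 10, "ACGT", "ACGT", "AAAG", 5),
               "length == period")
  expect_error(panel_locus("X", "chr1", 1, 10, "", "ACGT", "AAAG", 4),
               "prefix_flank")
  expect_error(panel_locus("X", "chr1", 1, 10, "ACGT", "ACGT",
                           c("AAAG", "AAAG"), 4),
               "distinct")
  loc <- panel_locus("fga", "chr4", 1, 98, "acgt", "ACGT",
                     c("ggaa", "aaag"), 4)
  expect_equal(loc$motifs, c("GGAA", "AAAG"))  # upper-cased
  expect_equal(loc$prefix_flank, "ACGT")
})

test_that("panel TSV round-trips field for field", {
  panel <- list(FGA = fga_locus(),
                P5 = panel_locus("P5", "chr1", 11L, 40L, strrep("AC", 16),
                                 strrep("GT", 16), c("ATCTG", "TGATC"), 5L,
                                 designation_offset = -2L))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_panel(panel, path)
  back <- read_panel(path)
  expect_identical(back, panel[names(back)])
})

test_that("0-based panel coordinates are converted at load", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    paste(c("locus", "chrom", "start", "end", "coord_system", "period",
            "motifs", "prefix_flank", "suffix_flank", "designation_offset"),
          collapse = "\t"),
    paste(c("L1", "chr1", "100", "140", "0based", "4", "AAAG,AGAA",
            strrep("A", 30), strrep("C", 30), "0"), collapse = "\t")),
    path)
  p <- read_panel(path)
  expect_equal(p$L1$core_start, 101L)  # 0-based half-open -> 1-based closed
  expect_equal(p$L1$core_end, 140L)
  expect_equal(p$L1$motifs, c("AAAG", "AGAA"))
})

test_that("panel JSON is accepted and bad records fail with named errors", {
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(list(
    locus = "LJ", chrom = "chr2", start = 5, end = 20, coord_system = "1based",
    period = 4, motifs = "GGAA,AAAG", prefix_flank = strrep("T", 30),
    suffix_flank = strrep("G", 30), designation_offset = 0
  )), path, auto_unbox = TRUE)
  p <- read_panel(path)
  expect_equal(p$LJ$period, 4L)

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("locus\tchrom\tstart\tend\tcoord_system\tperiod\tmotifs\tprefix_flank\tsuffix_flank\tdesignation_offset",
               paste(c("B1", "chr1", "1", "20", "1based", "5", "AAAG",
                       strrep("A", 30), strrep("C", 30), "0"),
                     collapse = "\t")), bad)
  expect_error(read_panel(bad), "B1")
})

test_that("an empty panel file yields an empty list with a warning", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(paste(c("locus", "chrom", "start", "end", "coord_system",
                     "period", "motifs", "prefix_flank", "suffix_flank",
                     "designation_offset"), collapse = "\t"), path)
  expect_warning(p <- read_panel(path), "no loci")
  expect_length(p, 0L)
})

test_that("threshold config validates and reads from YAML", {
  expect_error(threshold_config(sn_interpretation = 30, sn_allele = 25),
               "sn_interpretation")
  expect_error(threshold_config(snr_het = 1.5), "\\[0, 1\\]")
  expect_error(threshold_config(max_iterations = 0), "max_iterations")

  cfg <- threshold_config()
  expect_equal(cfg$sn_interpretation, 10L)
  expect_equal(cfg$sn_allele, 25L)
  expect_equal(snr_het_for(cfg, "ANY"), 0.30)

  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("sn_interpretation: 8",
               "sn_allele: 20",
               "snr_het:",
               "  FGA: 0.35",
               "  TPOX: 0.20",
               "stutter_snr: 0.25",
               "alignment:",
               "  match: 3",
               "  min_flank_identity: 0.8"), path)
  cfg2 <- read_thresholds(path)
  expect_equal(cfg2$sn_allele, 20L)
  expect_equal(snr_het_for(cfg2, "FGA"), 0.35)
  expect_error(snr_het_for(cfg2, "D18S51"), "D18S51")  # no silent default
  expect_equal(cfg2$alignment$match, 3)
  expect_equal(cfg2$alignment$min_flank_identity, 0.8)
})

test_that("allele frequency tables are validated on load", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("locus\tallele\tfreq",
               "FGA\t24\t0.15", "FGA\t24.2\t0.05",
               "TPOX\t8\t0.5", "TPOX\t9\t0.5"), path)
  fq <- read_allele_freqs(path)
  expect_equal(fq$FGA[["24.2"]], 0.05)
  expect_equal(sum(fq$TPOX), 1)

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("locus\tallele\tfreq", "FGA\t24\t0.7", "FGA\t25\t0.6"), bad)
  expect_error(read_allele_freqs(bad), "sum to > 1")
  writeLines(c("locus\tallele\tfreq", "FGA\t24\t0"), bad)
  expect_error(read_allele_freqs(bad), "\\(0, 1\\]")
})

test_that("genotype reports serialise statuses and allele fields", {
  st <- infer_structure("AAAGAAAGAAAG", "AAAG")
  het <- call_genotype(list(allele_call("10", st, 50, 1.0),
                            allele_call("12", st, 40, 0.8)),
                       shallow_cfg(), "L1")
  interp <- call_genotype(list(), shallow_cfg(), "L2")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_report(list(L1 = het, L2 = interp), path, sample = "S1")
  df <- read.delim(path, colClasses = "character")
  expect_equal(nrow(df), 2L)
  expect_equal(df$status, c("Pass", "Interpretation"))
  expect_equal(df$allele1[1], "10")
  expect_equal(df$allele2[1], "12")
  expect_equal(df$allele1[2], "")  # flag rows carry empty allele fields
  expect_equal(names(df)[1:5],
               c("sample", "locus", "status", "allele1", "allele2"))

  write_report(list(), path)
  df0 <- read.delim(path)
  expect_equal(nrow(df0), 0L)
  expect_equal(ncol(df0), 11L)
})

test_that("profiles read back homozygotes and heterozygotes", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample\tlocus\tallele1\tallele2",
               "S1\tFGA\t24\t24.2",
               "S1\tTPOX\t8\t8",
               "S2\tFGA\t21\t"), path)
  pr <- read_profiles(path)
  expect_equal(pr$S1$FGA, c("24", "24.2"))
  expect_equal(pr$S1$TPOX, "8")
  expect_equal(pr$S2$FGA, "21")
})
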