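test_that("find_motif_runs reports maximal tandem runs at every phase", {
  r <- find_motif_runs("AAAGAAAGAAAG", "AAAG")
  expect_equal(r, data.frame(start = 1L, count = 3L))

  r <- find_motif_runs("GGAAGGAAGGAG", "GGAA")
  expect_equal(r, data.frame(start = 1L, count = 2L))

  # single occurrence at a shifted phase inside another motif's repeat
  r <- find_motif_runs("AAAGAAAG", "AGAA")
  expect_equal(r, data.frame(start = 3L, count = 1L))

  # overlapping runs at different phases are all reported
  r <- find_motif_runs("AAAAAG", "AA")
  expect_equal(r$start, c(1L, 2L))
  expect_equal(r$count, c(2L, 2L))

  expect_equal(nrow(find_motif_runs("ACGT", "AAAG")), 0L)
  expect_equal(nrow(find_motif_runs("AC", "AAAG")), 0L)
})

test_that("fully decomposable sequences score zero", {
  st <- infer_structure("AAAGAAAGAAAG", "AAAG")
  expect_s3_class(st, "repeat_structure")
  expect_equal(st$bracket, "[AAAG]3")
  expect_equal(st$score, 0)
  expect_equal(st$nonmotif_bases, 0)
  expect_equal(st$nonmotif_parts, 0)
})

test_that("a sequence shorter than the period is a single interrupt", {
  st <- infer_structure("AG", c("AAAG"))
  expect_equal(st$blocks$kind, "INTERRUPT")
  expect_equal(st$bracket, "AG")
  expect_equal(st$score, 3)  # 2 bases + 1 part
})

test_that("the FGA 24.2 worked example round-trips and designates 24.2", {
  seq <- expand_structure(fga_f25_bracket)
  expect_equal(nchar(seq), 98L)
  st <- infer_structure(seq, fga_locus()$motifs)
  # the inferred bracket must expand back to the input exactly
  expect_identical(expand_structure(st$bracket), seq)
  # and its score must not exceed the printed decomposition's
  # (10 non-motif bases in GGAG+AA+AAAA)
  expect_lte(st$score, 13)
  expect_equal(designate_allele(st, fga_locus(), pads = c(0L, 0L)), "24.2")
})

test_that("expand_structure parses bracket notation and rejects malformed tokens", {
  expect_equal(expand_structure("[AAAG]3"), "AAAGAAAGAAAG")
  expect_equal(expand_structure("[AAAG]1_GA"), "AAAGGA")
  expect_equal(nchar(expand_structure(fga_f25_bracket)), 98L)
  expect_error(expand_structure("[AAAG]"), "malformed")
  expect_error(expand_structure("[AAAG]x"), "malformed")
  expect_error(expand_structure("AAXG"), "malformed")
})

test_that("structure inference matches the segmentation-DP oracle exhaustively", {
  motifs <- c("AAAG", "AGAA")
  # every {A,G} sequence of length 4..10
  for (n in c(4L, 7L, 10L)) {
    grid <- expand.grid(rep(list(c("A", "G")), n), stringsAsFactors = FALSE)
    seqs <- do.call(paste0, grid)
    sts <- lapply(seqs, infer_structure, motifs = motifs)
    expect_identical(vapply(sts, function(x) expand_structure(x$bracket), ""),
                     seqs)
    expect_equal(vapply(sts, `[[`, 0, "score"),
                 vapply(seqs, dp_min_score, 0, motifs = motifs,
                        USE.NAMES = FALSE))
  }
})

test_that("structure inference matches the DP oracle on random sequences", {
  withr::local_seed(421)
  motif_sets <- list(c("GGAA", "AAAG", "AGAA", "GAAA"),
                     c("ATCT", "ATCG"),
                     c("AATG", "TATC", "AATA"))
  ok_roundtrip <- logical(120)
  ok_score <- logical(120)
  for (i in seq_len(120)) {
    motifs <- motif_sets[[1L + (i %% length(motif_sets))]]
    # repeat-rich sequence: runs of motifs with random interruptions
    parts <- replicate(sample(2:5, 1), {
      if (runif(1) < 0.7)
        strrep(sample(motifs, 1), sample(1:8, 1))
      else rand_seq(sample(1:6, 1))
    })
    s <- paste0(paste(parts, collapse = ""), rand_seq(sample(0:4, 1)))
    st <- infer_structure(s, motifs)
    ok_roundtrip[i] <- identical(expand_structure(st$bracket), s)
    ok_score[i] <- st$score == dp_min_score(s, motifs)
  }
  expect_true(all(ok_roundtrip))
  expect_true(all(ok_score))
})

test_that("appending a motif copy to a decomposable sequence keeps score zero", {
  motifs <- c("TAGA", "CAGA")
  s <- "TAGATAGACAGA"
  st0 <- infer_structure(s, motifs)
  expect_equal(st0$score, 0)
  st1 <- infer_structure(paste0(s, "CAGA"), motifs)
  expect_equal(st1$score, 0)
  runs0 <- st0$blocks[st0$blocks$kind == "MOTIF_RUN", ]
  runs1 <- st1$blocks[st1$blocks$kind == "MOTIF_RUN", ]
  expect_equal(sum(runs1$count), sum(runs0$count) + 1L)
})

test_that("designation arithmetic follows the n.r convention", {
  loc4 <- fga_locus()
  expect_equal(designate_allele(98L, loc4, c(0L, 0L)), "24.2")
  expect_equal(designate_allele(104L, loc4, c(3L, 3L)), "24.2")
  expect_equal(designate_allele(12L, loc4, c(0L, 0L)), "3")
  loc5 <- panel_locus("P5", "chr1", 1L, 63L, strrep("A", 30), strrep("C", 30),
                      "ATCTG", 5L)
  expect_equal(designate_allele(63L, loc5, c(0L, 0L)), "12.3")
  # designation offset shifts the effective length
  loc_off <- panel_locus("OFF", "chr1", 1L, 98L, strrep("A", 30),
                         strrep("C", 30), "AAAG", 4L,
                         designation_offset = 2L)
  expect_equal(designate_allele(98L, loc_off, c(0L, 0L)), "25")
  expect_error(designate_allele(4L, loc4, c(3L, 3L)), "invalid allele")
})

test_that("bracket/expansion round trip holds on fuzzed repeat sequences", {
  withr::local_seed(99)
  for (i in 1:60) {
    motifs <- unique(replicate(sample(1:3, 1), rand_seq(4)))
    s <- paste0(rand_seq(sample(0:5, 1)),
                strrep(motifs[1], sample(0:6, 1)),
                rand_seq(sample(1:10, 1)))
    st <- infer_structure(s, motifs)
    expect_identical(expand_structure(st$bracket), s)
    expect_equal(st$core_len, nchar(s))
    expect_equal(st$score, st$nonmotif_bases + st$nonmotif_parts)
  }
})
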