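cfg_default <- threshold_config()  # sn 10/25, snr_het 0.30, stutter_snr 0.30

test_that("stutter one period short with low SNR is filtered", {
  major <- make_call("12", 100, 1.00, core_len = 54)
  stut <- make_call("11", 15, 0.15, core_len = 50)
  res <- filter_stutter(list(major, stut), cfg_default, period = 4L)
  expect_length(res$kept, 1L)
  expect_equal(res$kept[[1]]$designation, "12")
  expect_length(res$removed, 1L)
  expect_equal(res$removed[[1]]$designation, "11")
})

test_that("a strong adjacent minor allele is not mistaken for stutter", {
  major <- make_call("12", 100, 1.00, core_len = 54)
  minor <- make_call("11", 60, 0.60, core_len = 50)
  res <- filter_stutter(list(major, minor), cfg_default, period = 4L)
  expect_length(res$kept, 2L)
  expect_length(res$removed, 0L)

  # two periods short is a deletion variant, not stutter
  far <- make_call("10", 15, 0.15, core_len = 46)
  res2 <- filter_stutter(list(major, far), cfg_default, period = 4L)
  expect_length(res2$kept, 2L)

  single <- filter_stutter(list(major), cfg_default, period = 4L)
  expect_length(single$kept, 1L)
})

test_that("the decision ladder is total and matches the printed rules", {
  mk <- function(...) list(...)

  # (1) inadequate coverage: major SN below 10
  gt <- call_genotype(mk(make_call("12", 9, 1.0)), cfg_default, "L")
  expect_equal(gt$status, "Interpretation")
  expect_length(gt$calls, 0L)
  gt <- call_genotype(list(), cfg_default, "L")
  expect_equal(gt$status, "Interpretation")

  # (2) single candidate: homozygote
  gt <- call_genotype(mk(make_call("12", 40, 1.0)), cfg_default, "L")
  expect_equal(gt$status, "Pass")
  expect_equal(gt$zygosity, "HOM")
  expect_length(gt$calls, 1L)

  # (3) confident heterozygote: minor SNR and SN both sufficient
  gt <- call_genotype(mk(make_call("12", 50, 1.0),
                         make_call("13", 40, 0.8)), cfg_default, "L")
  expect_equal(gt$status, "Pass")
  expect_equal(gt$zygosity, "HET")
  expect_equal(vapply(gt$calls, `[[`, "", "designation"), c("12", "13"))

  # (4) ambiguous minor support: SNR passes, SN does not
  gt <- call_genotype(mk(make_call("12", 50, 1.0),
                         make_call("13", 20, 0.4)), cfg_default, "L")
  expect_equal(gt$status, "Imbalance")
  expect_length(gt$calls, 0L)

  # (5) minor below the SNR threshold: homozygote for the major
  gt <- call_genotype(mk(make_call("12", 100, 1.0),
                         make_call("13", 20, 0.2)), cfg_default, "L")
  expect_equal(gt$status, "Pass")
  expect_equal(gt$zygosity, "HOM")
  expect_equal(gt$calls[[1]]$designation, "12")

  # calls are ordered by designation, numerically with fractional parts
  gt <- call_genotype(mk(make_call("13", 50, 1.0),
                         make_call("12.2", 40, 0.8)), cfg_default, "L")
  expect_equal(vapply(gt$calls, `[[`, "", "designation"), c("12.2", "13"))
})

test_that("per-locus SNR maps have no silent default", {
  cfg <- threshold_config(snr_het = c(FGA = 0.35))
  expect_error(call_genotype(list(make_call("12", 50, 1.0)), cfg, "TPOX"),
               "TPOX")
  gt <- call_genotype(list(make_call("12", 50, 1.0)), cfg, "FGA")
  expect_equal(gt$status, "Pass")
})

test_that("threshold monotonicity: stricter thresholds never upgrade a call", {
  withr::local_seed(77)
  status_rank <- c(Interpretation = 0L, Imbalance = 1L, Pass = 2L)
  for (i in 1:50) {
    major_sn <- sample(1:120, 1)
    cand <- list(make_call("12", major_sn, 1.0))
    if (runif(1) < 0.8) {
      minor_sn <- sample(seq_len(major_sn), 1)
      cand <- c(cand, list(make_call("13", minor_sn, minor_sn / major_sn)))
    }
    lo <- call_genotype(cand, threshold_config(snr_het = 0.2), "L")
    hi <- call_genotype(cand, threshold_config(snr_het = 0.6), "L")
    # raising snr_het never converts HOM to HET
    if (identical(lo$zygosity, "HOM")) expect_false(identical(hi$zygosity, "HET"))
    lo_i <- call_genotype(cand, threshold_config(sn_interpretation = 5,
                                                 sn_allele = 25), "L")
    hi_i <- call_genotype(cand, threshold_config(sn_interpretation = 25,
                                                 sn_allele = 25), "L")
    # raising sn_interpretation never converts Interpretation to Pass
    if (lo_i$status == "Interpretation")
      expect_equal(hi_i$status, "Interpretation")
    expect_true(lo$status %in% names(status_rank))  # ladder is total
  }
})

test_that("concordance categories follow the five-way classification", {
  expect_equal(classify_concordance(c("12", "13"), c("12", "13")), "EXACT_MATCH")
  expect_equal(classify_concordance(c("13", "12"), c("12", "13")), "EXACT_MATCH")
  expect_equal(classify_concordance(c("12", "13.1"), c("12", "13")),
               "INCOMPLETE_MATCH")
  expect_equal(classify_concordance(c("12", "14"), c("12", "13")), "ONE_MATCH")
  expect_equal(classify_concordance(c("12.2", "14"), c("12", "13")),
               "INCOMPLETE_ONE_MATCH")
  expect_equal(classify_concordance(c("10", "14"), c("12", "13")), "MISMATCH")
  # homozygotes compare as duplicated alleles
  expect_equal(classify_concordance("12", c("12", "12")), "EXACT_MATCH")
  expect_equal(classify_concordance("12", c("12", "13")), "ONE_MATCH")
  expect_equal(classify_concordance(c("12", "13"), "12"), "ONE_MATCH")
  # non-Pass calls are excluded upstream
  gt <- call_genotype(list(), cfg_default, "L")
  expect_error(classify_concordance(gt, c("12", "13")), "excluded")
})

test_that("the sweep evaluates the full printed grid", {
  items <- list(list(locus = "L1",
                     candidates = list(make_call("10", 100, 1.0),
                                       make_call("12", 40, 0.4)),
                     truth = c("10", "12")))
  sw <- sweep_thresholds(items)
  expect_equal(sort(unique(sw$surface$sn)), seq(0, 50, by = 5))
  expect_equal(length(unique(sw$surface$snr)), 101L)
  expect_equal(nrow(sw$surface), 11L * 101L)
})

test_that("the SNR threshold is the median of the peak-accuracy plateau", {
  # item A: true heterozygote with minor snr just above 0.40 -> exact only
  # for thresholds <= 0.40; item B: true homozygote with a noise minor just
  # below 0.20 -> exact only for thresholds >= 0.20. Joint accuracy peaks on
  # the grid plateau [0.20, 0.40], whose median is 0.30.
  items <- list(
    list(locus = "L1",
         candidates = list(make_call("10", 100, 1.0),
                           make_call("12", 40, 0.405)),
         truth = c("10", "12")),
    list(locus = "L1",
         candidates = list(make_call("11", 150, 1.0),
                           make_call("9", 29, 0.195)),
         truth = "11")
  )
  sw <- sweep_thresholds(items, chosen_sn = 25)
  expect_equal(sw$selection$snr_het, 0.30)

  # a single grid value attaining the maximum selects that value
  items_single <- list(
    list(locus = "L2",
         candidates = list(make_call("10", 100, 1.0),
                           make_call("12", 40, 0.405)),
         truth = c("10", "12")),
    list(locus = "L2",
         candidates = list(make_call("11", 150, 1.0),
                           make_call("9", 59, 0.395)),
         truth = "11")
  )
  sw2 <- sweep_thresholds(items_single, chosen_sn = 25)
  expect_equal(sw2$selection$snr_het, 0.40)

  expect_error(sweep_thresholds(list()), "empty truth set")
})
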