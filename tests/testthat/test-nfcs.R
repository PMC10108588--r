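test_that("constellation totals sum binary cells with the right maxima", {
  ones <- matrix(1, 7, 10)
  expect_equal(score_constellation(coding_from_matrix(ones), "nfcs7")$total, 70)
  expect_equal(score_constellation(coding_from_matrix(ones), "nfcs3")$total, 30)
  zeros <- matrix(0, 7, 10)
  for (cc in c("nfcs7", "nfcs3", "nfcs_p3")) {
    expect_equal(score_constellation(coding_from_matrix(zeros), cc)$total, 0)
  }
  m <- matrix(0, 7, 10)
  m[match("brow bulge", nfcs_actions()), 1:4] <- 1
  m[match("eye squeeze", nfcs_actions()), 1:2] <- 1
  expect_equal(score_constellation(coding_from_matrix(m), "nfcs_p3")$total, 6)
  # that matrix scores 0 on the constellation that excludes those actions
  expect_equal(score_constellation(coding_from_matrix(m), "nfcs3")$total, 2)
  m[1, 1] <- NA
  expect_error(score_constellation(coding_from_matrix(m), "nfcs_p3"),
               "handle_missing")
})

test_that("constancy rule fills from the closest preceding value", {
  m <- matrix(0, 7, 10)
  i <- match("brow bulge", nfcs_actions())
  m[i, ] <- c(1, 1, NA, NA, 1, 1, 1, 1, 1, 1)
  h <- handle_missing(coding_from_matrix(m), "nfcs_p3")
  filled <- h$coding$value[h$coding$action == "brow bulge"]
  expect_equal(filled, rep(1, 10))
  expect_true(h$flags$constancy_used)
  expect_false(h$flags$prorated)
  expect_equal(score_nfcs(coding_from_matrix(m), "nfcs_p3")$total, 10)
  # a gap opening the epoch takes the nearest following value, flagged
  m[i, ] <- c(NA, NA, 0, 1, 1, 1, 1, 1, 1, 1)
  h2 <- handle_missing(coding_from_matrix(m), "nfcs_p3")
  expect_equal(h2$coding$value[h2$coding$action == "brow bulge"][1:3],
               c(0, 0, 0))
  expect_true(h2$flags$forward_filled)
  # constancy never touches observed cells
  cm <- dplyr::arrange(coding_from_matrix(m), subject_id, epoch, action,
                       second)
  h3 <- handle_missing(cm, "nfcs7")
  expect_equal(h3$coding$value[!is.na(cm$value)],
               cm$value[!is.na(cm$value)])
})

test_that("proration scales the observed sum by the missing fraction", {
  # one action 50% codable, cry not constant, 21/30 cells observed,
  # observed sum 14 -> 14 * 30/21 = 20
  m <- matrix(0, 7, 10)
  acts <- nfcs_actions()
  m[match("brow bulge", acts), ] <- c(rep(1, 5), rep(NA, 5))
  m[match("eye squeeze", acts), ] <- c(rep(1, 5), rep(0, 3), NA, NA)
  m[match("nasolabial furrow", acts), ] <- c(rep(1, 4), rep(0, 4), NA, NA)
  rec <- coding_from_matrix(m, cry = FALSE)
  h <- handle_missing(rec, "nfcs_p3")
  expect_false(h$flags$constancy_used)
  expect_true(h$flags$prorated)
  expect_equal(h$flags$observed_cells, 21)
  s <- score_nfcs(rec, "nfcs_p3")
  expect_equal(s$total, 14 * 30 / 21)
  expect_equal(s$total, 20)
  # below 60% overall coverage the record is excluded, not prorated
  m2 <- matrix(NA_real_, 7, 10)
  m2[match("brow bulge", acts), 1:5] <- 1
  rec2 <- coding_from_matrix(m2, cry = FALSE)
  s2 <- score_nfcs(rec2, "nfcs_p3")
  expect_true(s2$excluded)
  expect_true(is.na(s2$total))
  # proration is the identity for complete records
  full <- coding_from_matrix(matrix(1, 7, 10))
  sfull <- score_nfcs(full, "nfcs7")
  expect_equal(sfull$total, 70)
  expect_false(any(sfull$prorated | sfull$constancy_used | sfull$excluded))
})

test_that("totals stay within [0, max] on every rule path", {
  set.seed(41)
  for (i in 1:40) {
    m <- matrix(rbinom(70, 1, 0.7), 7, 10)
    m[sample(70, sample(0:30, 1))] <- NA
    cry <- runif(1) < 0.5
    s <- score_nfcs(coding_from_matrix(m, cry = cry),
                    sample(c("nfcs7", "nfcs_p3", "nfcs3"), 1))
    if (!is.na(s$total)) {
      expect_gte(s$total, 0)
      expect_lte(s$total, s$max_score)
    }
  }
})

test_that("the 0-70 to 0-30 rescaling is exact and bounded", {
  expect_equal(scale_to_30(70), 30)
  expect_equal(scale_to_30(0), 0)
  expect_equal(scale_to_30(21), 9)
  expect_error(scale_to_30(71), "\\[0, 70\\]")
  expect_error(scale_to_30(-1), "\\[0, 70\\]")
})

test_that("the clinical threshold splits at 9/30 and rejects baseline scores", {
  expect_equal(classify_clinical(c(9, 8.99, 30, 0)),
               c("NFCS-clinical", "NFCS-subclinical", "NFCS-clinical",
                 "NFCS-subclinical"))
  # monotone in the total
  x <- sort(runif(50, 0, 30))
  cl <- classify_clinical(x)
  expect_true(all(diff(cl == "NFCS-clinical") >= 0))
  tb <- tibble::tibble(total = c(10, 5), epoch = c("reactivity", "baseline"))
  expect_error(classify_clinical(tb), "reactivity")
  ok <- classify_clinical(tb[1, ])
  expect_equal(ok$clinical_group, "NFCS-clinical")
})

test_that("clinical grouping recovers the generating groups at p = 0.8 vs 0.1", {
  coh <- generate_facial_cohort(facial_sim_spec(50, c(0.8, 0.1), seed = 6))
  s <- score_nfcs(coh$coding, "nfcs_p3")
  react <- classify_clinical(s[s$epoch == "reactivity", ])
  truth <- ifelse(react$group == "group1", "NFCS-clinical",
                  "NFCS-subclinical")
  acc <- mean(react$clinical_group == truth, na.rm = TRUE)
  expect_gte(acc, 0.9)
})
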