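# LOD/LOQ thresholds, the sub-LOQ acceptance rule, percent recovery and
# detection-status classification.

test_that("blank-based LOD/LOQ follow the mean + 3s / + 10s rule", {
  th0 <- compute_lod_loq(c(0, 0, 0))
  expect_equal(th0$lod, 0)
  expect_equal(th0$loq, 0)
  # blanks with mean 1, sd 2
  th <- compute_lod_loq(c(-1, 1, 3))
  expect_equal(th$lod, 7)
  expect_equal(th$loq, 21)
  # homogeneity: scaling blanks scales both limits
  th10 <- compute_lod_loq(10 * c(-1, 1, 3))
  expect_equal(th10$lod, 70)
  expect_equal(th10$loq, 210)
  expect_error(compute_lod_loq(c(1, 2)), class = "srmquant_invalid_input")
  # volume chain converts to in-sample concentration (x resus/inj / volume)
  chain <- volume_chain(20, 100, 5)
  thc <- compute_lod_loq(c(-1, 1, 3), chain)
  expect_equal(thc$lod, 7 * 20 / 20)
  expect_equal(thc$loq, 21 * 20 / 20)
  # calibration-residual variant
  cv <- fit_standard_addition(c(0, 25, 50, 250), c(100, 600, 1100, 5100))
  cv$residual_sd <- 40
  thr <- compute_lod_loq(c(0, 0, 0), method = "calibration", curve = cv)
  expect_equal(thr$lod, 3 * 40 / 20)
  expect_equal(thr$loq, 10 * 40 / 20)
})

test_that("sub-LOQ acceptance is the conjunction of all four criteria", {
  # brute force over the 16 flag combinations
  for (i in 0:15) {
    flags <- as.logical(bitwAnd(i, c(1, 2, 4, 8)) > 0)
    ev <- subloq_evaluation(flags[1], flags[2], flags[3], flags[4])
    expect_identical(ev$accepted, all(flags))
  }
  expect_error(subloq_evaluation(TRUE, TRUE, TRUE, NA),
               class = "srmquant_invalid_input")
})

test_that("sub-LOQ criteria are judged from peak evidence", {
  std <- tibble::tibble(fragment_index = 1:2, area = c(60, 40),
                        apex_time = c(2.60, 2.61))
  good <- tibble::tibble(fragment_index = 1:2, area = c(6, 4),
                         apex_time = c(2.62, 2.63))
  ev <- evaluate_subloq(good, std, blank_mean_area = 3)
  expect_true(ev$rt_match)
  expect_true(ev$two_fragments_cooccur)
  expect_true(ev$intensity_order_match)
  expect_true(ev$area_exceeds_2x_blank)
  expect_true(ev$accepted)
  # apex offset 0.3 min -> retention-time criterion fails, peak rejected
  late <- good
  late$apex_time <- late$apex_time + 0.3
  ev2 <- evaluate_subloq(late, std, blank_mean_area = 3)
  expect_false(ev2$rt_match)
  expect_false(ev2$accepted)
  # inverted fragment intensity order -> criterion (iii) fails
  swapped <- tibble::tibble(fragment_index = 1:2, area = c(4, 6),
                            apex_time = c(2.62, 2.63))
  expect_false(evaluate_subloq(swapped, std, 3)$intensity_order_match)
  # near-equal fragments (within 5%) are order-compatible
  tie <- tibble::tibble(fragment_index = 1:2, area = c(5.0, 5.1),
                        apex_time = c(2.62, 2.63))
  expect_true(evaluate_subloq(tie, std, 3)$intensity_order_match)
  # a single detected fragment cannot satisfy co-occurrence
  one <- tibble::tibble(fragment_index = 1:2, area = c(6, 0),
                        apex_time = c(2.62, 2.63))
  expect_false(evaluate_subloq(one, std, 3)$two_fragments_cooccur)
  # area below twice the blank average -> criterion (iv) fails
  expect_false(evaluate_subloq(good, std, blank_mean_area = 8)$area_exceeds_2x_blank)
  # reference standard is mandatory
  expect_error(evaluate_subloq(good, std[1, ], 3), class = "srmquant_invalid_input")
})

test_that("percent recovery subtracts the endogenous signal", {
  r <- percent_recovery(220, 20, 400)
  expect_equal(r$percent_recovery, 50)
  expect_false(r$suspect)
  r0 <- percent_recovery(150, 150, 150)
  expect_equal(r0$percent_recovery, 0)
  expect_true(r0$suspect)
  expect_error(percent_recovery(1, 0, 0), class = "srmquant_invalid_input")
  a <- assumed_recovery(50, "FAMP")
  expect_true(a$assumed)
  expect_equal(a$percent_recovery, 50)
})

test_that("noise-free spiked/unspiked pairs invert the extraction efficiency", {
  for (eff in c(0.25, 0.5, 1.0)) {
    design <- make_test_design(concs = c(100, 100, 100, 100), efficiency = eff,
                               spike_pM = 200, noise_sd = 0,
                               baseline_level = 40, seed = 3)
    b <- simulate_batch(design, famp_panel())
    q <- quantify_batch(b)
    rec <- recovery_from_pair(q, "FAMP", "S_spiked", "S1", 200)
    expect_equal(rec$percent_recovery, 100 * eff, tolerance = 0.01)
  }
})

test_that("detection status ranks nd < nq <= reported_subloq < quantified", {
  chain <- volume_chain(20, 100, 5)
  th <- compute_lod_loq(c(0.8, 1.0, 1.2), chain)  # lod/loq in pM
  ok <- subloq_evaluation(TRUE, TRUE, TRUE, TRUE)
  bad <- subloq_evaluation(TRUE, TRUE, TRUE, FALSE)
  expect_identical(classify_detection(2 * th$loq, th), "quantified")
  mid <- (th$lod + th$loq) / 2
  expect_identical(classify_detection(mid, th, ok), "reported_subloq")
  expect_identical(classify_detection(mid, th, bad), "nq")
  expect_identical(classify_detection(mid, th, NULL), "nq")
  expect_identical(classify_detection(0, th), "nd")
  # monotonicity along a concentration ladder
  ladder <- seq(0, 2 * th$loq, length.out = 50)
  status <- vapply(ladder, classify_detection, character(1), thresholds = th,
                   subloq = ok)
  rank <- c(nd = 1, nq = 2, reported_subloq = 2, quantified = 3)[status]
  expect_true(all(diff(rank) >= 0))
})
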