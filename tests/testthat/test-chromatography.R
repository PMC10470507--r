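# Peak integration, signal-to-noise and quantifier-transition selection.

make_gaussian_trace <- function(amplitude, rt = 2.6, sigma = 0.05,
                                baseline = 0, noise = NULL,
                                t = seq(0, 12, by = 0.5 / 60)) {
  y <- amplitude * exp(-(t - rt)^2 / (2 * sigma^2)) + baseline
  if (!is.null(noise)) y <- y + noise
  tibble::tibble(time_min = t, intensity = y)
}

test_that("trapezoidal integration matches the closed-form Gaussian area", {
  for (sigma in c(0.02, 0.05, 0.1)) {
    tr <- make_gaussian_trace(1000, sigma = sigma, baseline = 30)
    pk <- integrate_peak(tr, integration_window(2.6, half_width = max(0.2, 4 * sigma)))
    expect_equal(pk$area, gaussian_area(1000, sigma), tolerance = 0.005)
    expect_equal(pk$apex_time, 2.6, tolerance = 1e-6)
    expect_equal(pk$apex_intensity, 1000, tolerance = 0.01)
  }
})

test_that("flat and tail-only windows integrate to (almost) zero", {
  flat <- tibble::tibble(time_min = seq(0, 12, by = 0.01), intensity = 75)
  expect_equal(integrate_peak(flat, integration_window(5))$area, 0)
  # window on the far tail of a real peak: < 0.1% of the full area
  tr <- make_gaussian_trace(1000, rt = 2.6, sigma = 0.05)
  tail_area <- integrate_peak(tr, integration_window(3.5))$area
  expect_lt(tail_area, 0.001 * gaussian_area(1000, 0.05))
})

test_that("integration window must lie inside the trace span", {
  tr <- make_gaussian_trace(100)
  expect_error(integrate_peak(tr, integration_window(0.1)),
               class = "srmquant_invalid_window")
  expect_error(integrate_peak(tr, integration_window(11.95)),
               class = "srmquant_invalid_window")
})

test_that("area is invariant under joint peak/window translation", {
  a1 <- integrate_peak(make_gaussian_trace(500, rt = 2.6),
                       integration_window(2.6))$area
  a2 <- integrate_peak(make_gaussian_trace(500, rt = 7.1),
                       integration_window(7.1))$area
  expect_equal(a1, a2, tolerance = 1e-9)
})

test_that("signal-to-noise is apex over MAD noise with an Inf sentinel", {
  win <- integration_window(2.6)
  # zero-noise peak -> sentinel
  expect_identical(signal_to_noise(make_gaussian_trace(1000), win), Inf)
  # pure noise, no peak: snr of order 1-5 (median over 100 seeds)
  snrs <- vapply(1:100, function(s) {
    noise <- withr::with_seed(s, rnorm(1441, 0, 10))
    signal_to_noise(make_gaussian_trace(0, baseline = 50, noise = noise), win)
  }, numeric(1))
  expect_lt(median(snrs), 5)
  expect_gt(median(snrs), 0.5)
  # doubling the amplitude at fixed noise doubles snr within 5%
  noise <- withr::with_seed(42, rnorm(1441, 0, 10))
  s1 <- signal_to_noise(make_gaussian_trace(1000, noise = noise), win)
  s2 <- signal_to_noise(make_gaussian_trace(2000, noise = noise), win)
  expect_equal(s2 / s1, 2, tolerance = 0.05)
  # needs enough out-of-window points
  short <- tibble::tibble(time_min = seq(2.4, 2.8, by = 0.01), intensity = 1)
  expect_error(signal_to_noise(short, win), class = "srmquant_invalid_input")
})

test_that("quantifier selection prefers clean, high-S/N fragments", {
  area_row <- function(inj, frag, area, snr, added = 25) {
    tibble::tibble(injection_id = inj, compound = "X", fragment_index = frag,
                   area = area, apex_time = 2.6, apex_intensity = area,
                   snr = snr, added_fmol = added)
  }
  # equal snr, fragment 1 suffers blank interference -> fragment 2 chosen
  cal <- dplyr::bind_rows(area_row("c1", 1, 100, 50), area_row("c1", 2, 100, 50))
  blank <- dplyr::bind_rows(area_row("b1", 1, 40, 1, added = NA),
                            area_row("b1", 2, 0, 1, added = NA))
  sel <- select_quantifier_transitions(cal, blank)
  expect_identical(sel$fragment_index[sel$quantifier], 2)
  # single fragment -> that fragment
  sel1 <- select_quantifier_transitions(area_row("c1", 1, 100, 50),
                                        area_row("b1", 1, 0, 1, added = NA))
  expect_identical(sel1$fragment_index[sel1$quantifier], 1)
  # deterministic tie-break on fragment index
  tie <- select_quantifier_transitions(
    dplyr::bind_rows(area_row("c1", 1, 100, 50), area_row("c1", 2, 100, 50)),
    dplyr::bind_rows(area_row("b1", 1, 0, 1, added = NA),
                     area_row("b1", 2, 0, 1, added = NA))
  )
  expect_identical(tie$fragment_index[tie$quantifier], 1)
  # no blanks -> warns and scores by snr alone
  expect_warning(select_quantifier_transitions(cal), "blank")
})

test_that("the stronger fragment wins selection under simulated noise", {
  cmp <- test_compound(rel = c(0.25, 0.75))
  design <- batch_design(noise_sd = 15, baseline_level = 50)
  win_panel <- list(X = cmp)
  names(win_panel) <- cmp$name
  wins <- vapply(1:100, function(s) {
    cal_tr <- simulate_traces(cmp, 25, design, seed = s)
    cal_tr$injection_id <- "cal"
    cal_tr$compound <- cmp$name
    bl_tr <- simulate_traces(cmp, 0, design, seed = s + 1000)
    bl_tr$injection_id <- "blank"
    bl_tr$compound <- cmp$name
    areas <- integrate_batch(dplyr::bind_rows(cal_tr, bl_tr), win_panel)
    areas$added_fmol <- ifelse(areas$injection_id == "cal", 25, NA)
    sel <- select_quantifier_transitions(areas[areas$injection_id == "cal", ],
                                         areas[areas$injection_id == "blank", ])
    sel$fragment_index[sel$quantifier] == 2
  }, logical(1))
  expect_gte(sum(wins), 95)
})

test_that("summed areas add up and refuse mixed injections", {
  df <- tibble::tibble(injection_id = "i1", compound = "X",
                       fragment_index = 1:2, area = c(10, 5))
  expect_equal(summed_area(df), 15)
  expect_equal(summed_area(df[1, ]), 10)
  expect_equal(summed_area(dplyr::bind_rows(df, df)), 30)
  mixed <- df
  mixed$injection_id <- c("i1", "i2")
  expect_error(summed_area(mixed), class = "srmquant_invalid_input")
})
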