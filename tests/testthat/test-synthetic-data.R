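# Synthetic SRM batch generator: panel, extraction arithmetic, trace model,
# QC pooling and whole-batch ground truth.

test_that("default panel has seven compounds, one heavy IS, >=2 fragments each", {
  panel <- make_default_panel()
  expect_length(panel, 7)
  roles <- vapply(panel, `[[`, character(1), "role")
  expect_equal(sum(roles == "heavy_internal_standard"), 1L)
  expect_true(all(vapply(panel, function(p) length(p$fragment_mzs), integer(1)) >= 2))
  for (p in panel) {
    expect_equal(sum(p$fragment_rel_intensities), 1, tolerance = 1e-12)
    expect_true(all(p$fragment_rel_intensities > 0))
    expect_true(p$retention_time > 0 && p$retention_time < 12)
  }
  # heavy standard co-elutes with the light compound it labels
  expect_identical(panel$B1_13C$retention_time, panel$B1$retention_time)
  # deterministic construction
  expect_identical(panel, make_default_panel())
})

test_that("compound_spec enforces its invariants", {
  expect_error(compound_spec("x", 100, c(50, 60), c(0.5, 0.4), 2),
               class = "srmquant_invalid_input")  # sums to 0.9
  expect_error(compound_spec("x", 100, 50, 1, 2),
               class = "srmquant_invalid_input")  # single-fragment analyte
  expect_error(compound_spec("x", 100, c(50, 60), c(0.5, 0.5), 15),
               class = "srmquant_invalid_input")  # RT outside run
  # a heavy IS may carry a single fragment
  expect_s3_class(compound_spec("hIS", 100, 50, 1, 2,
                                role = "heavy_internal_standard"),
                  "compound_spec")
})

test_that("simulate_extraction follows the volume/efficiency chain", {
  # 100 pM x 20 mL x 0.5 = 1000 fmol in vial; 5/100 injected
  expect_equal(simulate_extraction(100, 20, 0.5, 100, 5), 50)
  expect_equal(simulate_extraction(0, 20, 0.5, 100, 5), 0)
  # linear in efficiency
  expect_equal(simulate_extraction(100, 20, 1.0, 100, 5), 100)
  expect_error(simulate_extraction(100, -1, 0.5, 100, 5),
               class = "srmquant_invalid_input")
  expect_error(simulate_extraction(100, 20, 1.5, 100, 5),
               class = "srmquant_invalid_input")
  expect_error(simulate_extraction(100, 20, 0, 100, 5),
               class = "srmquant_invalid_input")
})

test_that("noise-free traces are Gaussian peaks with the closed-form area", {
  cmp <- test_compound()
  design <- batch_design(noise_sd = 0, baseline_level = 0)
  tr <- simulate_traces(cmp, 40, design, seed = 7)
  # zero amount, zero noise, zero baseline -> all-zero traces
  tr0 <- simulate_traces(cmp, 0, design, seed = 7)
  expect_true(all(tr0$intensity == 0))
  for (k in seq_along(cmp$fragment_rel_intensities)) {
    frag <- tr[tr$fragment_index == k, ]
    # apex at the retention time
    expect_equal(frag$time_min[which.max(frag$intensity)], cmp$retention_time,
                 tolerance = 1e-8)
    # trapezoidal area over +-4 sigma matches G * fmol * rel * sigma * sqrt(2pi)
    sel <- abs(frag$time_min - cmp$retention_time) <= 4 * cmp$peak_sigma
    area <- pracma::trapz(frag$time_min[sel], frag$intensity[sel])
    expected <- gaussian_area(design$gain * 40 * cmp$fragment_rel_intensities[k],
                              cmp$peak_sigma)
    expect_equal(area, expected, tolerance = 0.005)
  }
  # identical (compound, fmol, seed) -> identical traces, with noise on
  dn <- batch_design(noise_sd = 8, baseline_level = 50)
  expect_identical(simulate_traces(cmp, 40, dn, seed = 3),
                   simulate_traces(cmp, 40, dn, seed = 3))
  expect_error(simulate_traces(cmp, -1, design), class = "srmquant_invalid_input")
})

test_that("QC pools average members' vial concentrations", {
  mk <- function(id, conc) {
    sample_design(id, "environmental_dissolved", c(FAMP = conc),
                  sample_volume = 1, extraction_efficiency = 1,
                  resuspension_volume = 1000)
  }
  # conc pM, 1 mL, eff 1, 1000 uL vial -> vial level equals conc
  p <- make_qc_pool(list(mk("a", 10), mk("b", 30)))
  expect_equal(unname(p$true_concentrations[["FAMP"]]), 20)
  expect_identical(p$sample_type, "qc_pool")
  # one sample -> pool at its own vial level
  p1 <- make_qc_pool(list(mk("a", 10)))
  expect_equal(unname(p1$true_concentrations[["FAMP"]]), 10)
  # pool of pools equals pool of the union for equal group sizes
  g1 <- list(mk("a", 4), mk("b", 8))
  g2 <- list(mk("c", 16), mk("d", 32))
  pp <- make_qc_pool(list(make_qc_pool(g1, "p1"), make_qc_pool(g2, "p2")))
  pu <- make_qc_pool(c(g1, g2))
  expect_equal(pp$true_concentrations[["FAMP"]],
               mean(c(4, 8, 16, 32)))  # brute-force mean of the union
  expect_equal(pp$true_concentrations[["FAMP"]], pu$true_concentrations[["FAMP"]])
  expect_error(make_qc_pool(list()), class = "srmquant_invalid_input")
  expect_error(
    make_qc_pool(list(mk("a", 1),
                      sample_design("b", "spent_medium", c(FAMP = 1)))),
    class = "srmquant_invalid_input"
  )
})

test_that("simulate_batch lays out the study's calibration design", {
  env <- list(sample_design("S1", "environmental_dissolved", c(FAMP = 50, HET = 50),
                            20, 0.5, 100))
  pool <- make_qc_pool(env, "QC", compounds = c("FAMP", "HET"))
  design <- batch_design(c(env, list(pool)), seed = 11)
  panel <- make_default_panel()[c("FAMP", "HET")]
  b <- simulate_batch(design, panel)
  cal <- b$truth[b$truth$sample_type == "qc_pool", ]
  for (cmp in c("FAMP", "HET")) {
    cc <- cal[cal$compound == cmp, ]
    # 4 levels x duplicate injections
    expect_equal(nrow(cc), 8L)
    expect_equal(table(cc$added_fmol) |> as.vector(), rep(2L, 4))
  }
  # HET uses its reduced addition series
  expect_setequal(unique(cal$added_fmol[cal$compound == "HET"]), c(0, 5, 10, 50))
  expect_setequal(unique(cal$added_fmol[cal$compound == "FAMP"]), c(0, 25, 50, 250))
})

test_that("batches are reproducible and their ledger matches the extraction math", {
  d1 <- make_test_design(seed = 5, noise_sd = 7, response_rel_sd = 0.05)
  b1 <- simulate_batch(d1, famp_panel())
  b2 <- simulate_batch(d1, famp_panel())
  expect_identical(b1$truth, b2$truth)
  expect_identical(b1$traces, b2$traces)
  # conservation: ledger fmol equals simulate_extraction for each sample
  env <- Filter(function(s) s$sample_type == "environmental_dissolved", d1$samples)
  for (s in env) {
    rows <- b1$truth[b1$truth$sample_id == s$sample_id &
                       b1$truth$compound == "FAMP", ]
    expect_equal(
      unique(rows$true_fmol),
      simulate_extraction(s$true_concentrations[["FAMP"]], s$sample_volume,
                          s$extraction_efficiency, s$resuspension_volume,
                          d1$injection_volume)
    )
  }
})

test_that("noise-free peak areas are proportional to on-column amount", {
  cmp <- test_compound()
  design <- batch_design(noise_sd = 0, baseline_level = 20)
  win <- integration_window(cmp$retention_time)
  fmols <- c(10, 40, 160)
  ratio <- vapply(fmols, function(f) {
    tr <- simulate_traces(cmp, f, design, seed = 1)
    integrate_peak(tr[tr$fragment_index == 1, ], win)$area / f
  }, numeric(1))
  expect_lt(diff(range(ratio)) / mean(ratio), 1e-6)
})
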