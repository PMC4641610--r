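# synthetic plate generator

test_that("identical seed and design reproduce the run exactly", {
  d <- c(armigera = 5, zea = 5, non_target = 2, ntc = 1)
  r1 <- generate_plate(d, seed = 99)
  r2 <- generate_plate(d, seed = 99)
  expect_identical(r1$cq_table, r2$cq_table)
  expect_identical(r1$traces, r2$traces)
  expect_identical(r1$truth, r2$truth)
  r3 <- generate_plate(d, seed = 100)
  expect_false(identical(r1$cq_table$cq, r3$cq_table$cq))
})

test_that("empty designs produce empty outputs", {
  r <- generate_plate(c(armigera = 0), seed = 1)
  expect_equal(nrow(r$cq_table), 0)
  expect_equal(nrow(r$truth), 0)
})

test_that("drawn Cqs respect the profile coupling and truncation bounds", {
  r <- generate_plate(c(armigera = 200), seed = 5)
  tr <- r$truth
  delta <- tr$control_cq - tr$target_cq
  expect_true(all(delta > 0.09 - 1e-9 & delta < 6.68 + 1e-9))
  expect_true(all(tr$control_cq >= 13.87 & tr$control_cq <= 31.45))
  expect_true(all(tr$target_channel == "FAM"))
  # NTC wells emit nothing
  rn <- generate_plate(c(ntc = 5), seed = 6)
  expect_true(all(is.na(rn$cq_table$cq)))
  expect_true(all(abs(rn$cq_table$end_rfu) < 50))
})

test_that("large cohorts reproduce the configured class means", {
  r <- generate_plate(c(armigera = 10000), seed = 77, emit = "cq_table")
  tr <- r$truth
  expect_lt(abs(mean(tr$control_cq) - 20.15), 0.1)
  expect_lt(abs(mean(tr$control_cq - tr$target_cq) - 3.41), 0.05)
  rz <- generate_plate(c(zea = 10000), seed = 78, emit = "cq_table")
  expect_lt(abs(mean(rz$truth$control_cq) - 17.58), 0.1)
  expect_lt(abs(mean(rz$truth$control_cq - rz$truth$target_cq) - 2.64), 0.05)
})

test_that("cross-reactive signal stays below the calling threshold", {
  r <- generate_plate(c(armigera = 150, zea = 150), seed = 13)
  cq <- r$cq_table
  wrong <- merge(cq, r$truth[, c("sample_id", "target_channel")], by = "sample_id")
  wrong <- wrong[wrong$channel %in% c("FAM", "HEX") &
                 wrong$channel != wrong$target_channel, ]
  expect_true(all(is.na(wrong$cq)))
  expect_true(all(wrong$end_rfu < 1000))
  # cross-reactive (non-silent) wrong-channel events occur at the configured rate
  xreact <- wrong$end_rfu > 90
  expect_gt(mean(xreact), 0.35)
  expect_lt(mean(xreact), 0.65)
  # and never become a Cq call after thresholding the traces at 1000 RFU
  called <- call_plate(r$traces)
  mm <- merge(called, r$truth[, c("sample_id", "target_channel")], by = "sample_id")
  mm <- mm[mm$channel %in% c("FAM", "HEX") & mm$channel != mm$target_channel, ]
  expect_true(all(is.na(mm$cq)))
})

test_that("trace synthesis is consistent with the drawn Cqs", {
  r <- generate_plate(c(armigera = 30, zea = 30, non_target = 10, ntc = 2),
                      seed = 31)
  res <- call_plate(r$traces)
  m <- merge(res, r$cq_table, by = c("well", "sample_id", "channel"),
             suffixes = c(".called", ".true"))
  both <- !is.na(m$cq.called) & !is.na(m$cq.true)
  expect_equal(is.na(m$cq.called), is.na(m$cq.true))
  expect_lt(max(abs(m$cq.called - m$cq.true)[both]), 0.1)
})

test_that("impossible truncation bounds are refused", {
  bad <- species_profile("armigera", control_mean = 20, control_sd = 1,
                         control_bounds = c(30, 31),
                         delta_mean = 3, delta_sd = 1, delta_bounds = c(0, 7),
                         target_channel = "armigera_target")
  # bounds 10 SD from the mean leave no mass to sample from
  expect_error(generate_plate(c(armigera = 1), seed = 1,
                              profiles = list(armigera = bad)),
               "truncation bounds")
  expect_error(generate_plate(c(unknown_class = 3), seed = 1), "no profile")
})

test_that("dilution series round-trips through the curve fitter", {
  pts <- generate_dilution_series(noise_sd = 0, slope = -3.3219, seed = 2)
  fit <- fit_standard_curve(pts)
  expect_equal(fit$slope, -3.3219, tolerance = 1e-9)
  noisy <- fit_standard_curve(generate_dilution_series(noise_sd = 0.2, seed = 12))
  expect_gte(noisy$r_squared, 0.98)
})

test_that("mixed-template patterns follow the characterised positivity", {
  # armigera minor in zea DNA: FAM only at 1:1
  for (ratio in c(1, 10, 100, 1000)) {
    mt <- generate_mixed_template("armigera", "zea", ratio, "dna",
                                  replicates = 3, seed = 21)
    if (ratio == 1) {
      expect_true(all(!is.na(mt$armigera_cq)))
      expect_lt(abs(mean(mt$armigera_cq) - 19.35), 0.5)
    } else {
      expect_true(all(is.na(mt$armigera_cq)))
    }
    expect_true(all(!is.na(mt$zea_cq)))   # major species always reports
    expect_true(all(!is.na(mt$control_cq)))
  }
  # zea minor in armigera DNA: HEX through 1:100 with the recorded means
  means <- c("1" = 16.70, "10" = 19.85, "100" = 22.77)
  for (ratio in c(1, 10, 100)) {
    mt <- generate_mixed_template("zea", "armigera", ratio, "dna",
                                  replicates = 6, seed = 22)
    expect_lt(abs(mean(mt$zea_cq) - means[[as.character(ratio)]]), 0.5)
  }
  expect_true(all(is.na(generate_mixed_template("zea", "armigera", 1000, "dna",
                                                seed = 23)$zea_cq)))
  # bulk legs: armigera minor reports only at 1:1
  leg1 <- generate_mixed_template("armigera", "zea", 1, "legs",
                                  replicates = 5, seed = 24)
  expect_lt(abs(mean(leg1$armigera_cq) - 21.02), 0.5)
  for (ratio in c(4, 9, 19)) {
    expect_true(all(is.na(generate_mixed_template("armigera", "zea", ratio,
                                                  "legs", seed = 25)$armigera_cq)))
  }
})

test_that("mixed-template designs outside the enumerated sets are refused", {
  expect_error(generate_mixed_template("armigera", "zea", 50, "dna"), "ratio")
  expect_error(generate_mixed_template("armigera", "zea", 10, "legs"), "ratio")
  expect_error(generate_mixed_template("zea", "zea", 1, "dna"), "differ")
  expect_error(generate_mixed_template("zea", "armigera", 1, "legs"),
               "not characterised")
})
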