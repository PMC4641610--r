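# the four-rule decision tree

test_that("published mean patterns map to the expected calls", {
  # armigera means: control 20.15, FAM 17.58
  c1 <- interpret_sample(20.15, 17.58, NA)
  expect_equal(c1$call, "H_ARMIGERA")
  expect_equal(c1$delta_cq, 2.57, tolerance = 1e-9)
  # zea means: control 17.58, HEX 14.94
  c2 <- interpret_sample(17.58, NA, 14.94)
  expect_equal(c2$call, "H_ZEA")
  expect_equal(c2$delta_cq, 2.64, tolerance = 1e-9)
  # non-target: control only
  expect_equal(interpret_sample(21.92, NA, NA)$call, "NEGATIVE_NON_TARGET")
})

test_that("the two documented outlier specimens remain inconclusive", {
  # strong HEX far below control: deltaCq 18.86 exceeds the 7-cycle bound
  out1 <- interpret_sample(27.10, NA, 8.24)
  expect_equal(out1$call, "INCONCLUSIVE")
  expect_equal(out1$delta_cq, 18.86, tolerance = 1e-9)
  expect_false(out1$rule_trace$pass[out1$rule_trace$rule == "rule3_delta_cq_in_bounds"])
  # HEX above control: deltaCq <= 0
  out2 <- interpret_sample(24.86, NA, 26.02)
  expect_equal(out2$call, "INCONCLUSIVE")
  expect_lt(out2$delta_cq, 0)
})

test_that("rules 1 and 4 dominate the remaining logic", {
  expect_equal(interpret_sample(NA, 15, NA)$call, "NO_DNA")
  expect_equal(interpret_sample(NA, NA, NA)$call, "NO_DNA")
  expect_equal(interpret_sample(20, 18, 18)$call, "INCONCLUSIVE")  # dual positive
})

test_that("window and delta boundaries follow '> 0 and <= 40' / '> 0 and <= 7'", {
  expect_equal(interpret_sample(40.0, 36, NA)$call, "H_ARMIGERA")   # control at 40 passes
  expect_equal(interpret_sample(40.01, 36, NA)$call, "NO_DNA")      # just above fails
  expect_equal(interpret_sample(27, 20, NA)$call, "H_ARMIGERA")     # delta 7 passes
  expect_equal(interpret_sample(27.5, 20, NA)$call, "INCONCLUSIVE") # delta 7.5 fails
  expect_equal(interpret_sample(20, 20, NA)$call, "INCONCLUSIVE")   # delta 0 fails
  # a target beyond cycle 40 is treated as absent
  expect_equal(interpret_sample(20, 40.5, NA)$call, "NEGATIVE_NON_TARGET")
  expect_equal(interpret_sample(20, 40.5, 18)$call, "H_ZEA")
})

test_that("every channel combination matches the brute-force rule oracle", {
  vals <- c(NA, 0.5, 20, 39.9, 40.0, 40.1)
  n_checked <- 0
  for (ctrl in vals) for (fam in vals) for (hex in vals) {
    got <- interpret_sample(ctrl, fam, hex)
    want <- oracle_interpret(ctrl, fam, hex)
    expect_equal(got$call, want,
                 info = sprintf("ctrl=%s fam=%s hex=%s", ctrl, fam, hex))
    # totality: always exactly one of the five calls, with a non-empty trace
    expect_true(got$call %in% c("NO_DNA", "H_ARMIGERA", "H_ZEA",
                                "NEGATIVE_NON_TARGET", "INCONCLUSIVE"))
    expect_gt(nrow(got$rule_trace), 0)
    n_checked <- n_checked + 1
  }
  expect_equal(n_checked, 216)
})

test_that("swapping the target channels swaps the species call", {
  set.seed(9)
  for (i in 1:40) {
    ctrl <- runif(1, 10, 40)
    fam <- if (runif(1) < 0.3) NA else runif(1, 5, 41)
    hex <- if (runif(1) < 0.3) NA else runif(1, 5, 41)
    a <- interpret_sample(ctrl, fam, hex)$call
    b <- interpret_sample(ctrl, hex, fam)$call
    swapped <- c(H_ARMIGERA = "H_ZEA", H_ZEA = "H_ARMIGERA")
    expect_equal(b, if (a %in% names(swapped)) unname(swapped[a]) else a)
  }
})

test_that("delta_cq is reported iff exactly one target fired", {
  expect_true(is.na(interpret_sample(20, 18, 18)$delta_cq))
  expect_true(is.na(interpret_sample(20, NA, NA)$delta_cq))
  expect_false(is.na(interpret_sample(20, NA, 30)$delta_cq))  # inconclusive but single
  expect_true(is.na(interpret_sample(NA, 18, NA)$delta_cq))   # no control
})

test_that("interpret_plate groups channels by sample and maps fluorophores", {
  res <- tibble::tibble(
    well = c("A1", "A1", "A1", "A2", "A2", "A2"),
    sample_id = rep(c("arm", "zea"), each = 3),
    channel = rep(c("Quasar 670", "FAM", "HEX"), 2),
    cq = c(20.15, 17.58, NA, 17.58, NA, 14.94),
    end_rfu = rep(2500, 6)
  )
  calls <- interpret_plate(res, default_assay_config())
  expect_equal(calls$call, c("H_ARMIGERA", "H_ZEA"))
  # alias normalisation: Cy5 is the control channel
  res$channel <- rep(c("cy5", "FAM", "HEX"), 2)
  expect_equal(interpret_plate(res, default_assay_config())$call,
               c("H_ARMIGERA", "H_ZEA"))
  # unmapped channel errors
  res$channel[2] <- "ROX"
  expect_error(interpret_plate(res, default_assay_config()), "ROX")
  # empty plate
  expect_equal(nrow(interpret_plate(res[0, ], default_assay_config())), 0)
})

test_that("samples without a control-channel entry are NO_DNA with a note", {
  res <- tibble::tibble(well = "A1", sample_id = "s1", channel = "FAM",
                        cq = 18, end_rfu = 2500)
  calls <- interpret_plate(res, default_assay_config())
  expect_equal(calls$call, "NO_DNA")
  expect_match(calls$rule_trace[[1]]$detail[1], "control channel missing")
})

test_that("run validation flags contaminated negative controls", {
  calls <- tibble::tibble(
    sample_id = c("s1", "NTC1", "NTC2"),
    call = c("H_ZEA", "NO_DNA", "H_ZEA"),
    delta_cq = c(2.5, NA, 2.0),
    rule_trace = list(tibble::tibble(), tibble::tibble(), tibble::tibble())
  )
  v_ok <- validate_run(calls[1:2, ], "NTC1")
  expect_true(v_ok$valid)
  v_bad <- validate_run(calls, c("NTC1", "NTC2"))
  expect_false(v_bad$valid)
  expect_equal(v_bad$offending, "NTC2")
  v_none <- validate_run(calls[1, ], character(0))
  expect_true(v_none$valid)
  expect_true(v_none$no_controls_designated)
  expect_error(validate_run(calls, "NTC9"), "absent")
})
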