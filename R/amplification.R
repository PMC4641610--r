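# Cq calling from raw per-cycle fluorescence traces: linear baseline
# subtraction over a pre-amplification window, then single-threshold crossing
# with linear interpolation between the flanking cycles. Absence of a call is
# a distinct state (NA), never a 0 -- 0-coded absence exists only in the
# instrument-export CSV dialect (see read_cq_export()).

#' Cq caller settings
#'
#' @param rfu_threshold Detection threshold in baseline-subtracted RFU. The
#'   assay's published operating point is a user-defined 1000.00: wrong-species
#'   probe cross-reaction produces end RFU below 1000, so this threshold is
#'   what suppresses those false positives.
#' @param baseline_window Integer `c(first, last)` cycle range used to
#'   estimate the baseline (auto-shrunk away from amplification; see
#'   [subtract_baseline()]).
#' @param max_cycles Last cycle eligible for a crossing (the cycling program
#'   runs 40 cycles).
#' @return A list of class `"caller_settings"`.
#' @export
caller_settings <- function(rfu_threshold = 1000, baseline_window = c(3L, 15L),
                            max_cycles = 40L) {
  stopifnot(rfu_threshold > 0, length(baseline_window) == 2L,
            baseline_window[1] >= 1L, baseline_window[2] >= baseline_window[1],
            max_cycles > 0L)
  structure(list(rfu_threshold = rfu_threshold,
                 baseline_window = as.integer(baseline_window),
                 max_cycles = as.integer(max_cycles)),
            class = "caller_settings")
}

#' Construct a single-well, single-channel fluorescence trace
#'
#' @param well Plate coordinate (e.g. `"A1"`).
#' @param sample_id Sample identifier.
#' @param channel Fluorophore name.
#' @param rfu Numeric vector of per-cycle readings, cycles `1..C` (`C >= 10`).
#' @return An object of class `"well_trace"`.
#' @export
well_trace <- function(well, sample_id, channel, rfu) {
  rfu <- as.numeric(rfu)
  if (length(rfu) < 10L) stop("a trace needs at least 10 cycles", call. = FALSE)
  if (any(!is.finite(rfu))) stop("trace readings must be finite", call. = FALSE)
  structure(list(well = well, sample_id = sample_id, channel = channel,
                 rfu = rfu),
            class = "well_trace")
}

# Pick the baseline window: start from settings$baseline_window, and when the
# trace shows amplification (range > 200 RFU, i.e. clearly above drift and
# read noise), pull the window end back to 5 cycles before the first cycle
# exceeding 10% of the signal range (the sigmoid's tail biases the drift fit
# closer in). If that leaves fewer than 3 cycles, the start is allowed to
# drop to cycle 1 before giving up.
baseline_window_for <- function(rfu, settings, auto_shrink = TRUE) {
  C <- length(rfu)
  start <- min(settings$baseline_window[1], C)
  end <- min(settings$baseline_window[2], C)
  if (auto_shrink) {
    rng <- max(rfu) - min(rfu)
    if (rng > 200) {
      first_amp <- which(rfu > min(rfu) + 0.1 * rng)[1]
      end <- min(end, first_amp - 5L)
      if (end - start + 1L < 3L) start <- 1L
    }
  }
  if (end - start + 1L < 3L) {
    stop(sprintf("degenerate baseline: only %d pre-amplification cycle(s) available",
                 max(0L, end - start + 1L)), call. = FALSE)
  }
  c(start, end)
}

#' Subtract a fitted linear baseline from a trace
#'
#' Fits RFU on cycle number by least squares over the baseline window and
#' subtracts the fitted line from every cycle, so constant offsets and linear
#' drift vanish. The window is auto-shrunk to end 5 cycles before detectable
#' amplification (first cycle above 10% of the signal range); traces without
#' detectable amplification keep the configured window.
#'
#' @param trace A [well_trace()].
#' @param settings A [caller_settings()].
#' @param auto_shrink Disable to force the configured window.
#' @return The trace with corrected readings; the window used is attached as
#'   attribute `"baseline_window"`.
#' @export
subtract_baseline <- function(trace, settings = caller_settings(),
                              auto_shrink = TRUE) {
  stopifnot(inherits(trace, "well_trace"))
  rfu <- trace$rfu
  win <- baseline_window_for(rfu, settings, auto_shrink)
  idx <- win[1]:win[2]
  # with few clean cycles a fitted slope extrapolates its noise into the
  # crossing region; a constant baseline is then the stabler estimate
  if (length(idx) >= 8L) {
    x <- idx - mean(idx)
    slope <- sum(x * rfu[idx]) / sum(x * x)
  } else {
    slope <- 0
  }
  intercept <- mean(rfu[idx]) - slope * mean(idx)
  cycles <- seq_along(rfu)
  trace$rfu <- rfu - (intercept + slope * cycles)
  attr(trace, "baseline_window") <- win
  trace
}

#' Call the quantification cycle of a baseline-subtracted trace
#'
#' Cq is the first crossing of the threshold, linearly interpolated between
#' the flanking cycles, restricted to cycles `1..max_cycles`; a trace that
#' never reaches the threshold yields an absent Cq (`NA`). A crossing followed
#' by a dip back below the threshold (single-cycle blip) is still reported,
#' with a QC note.
#'
#' @param trace A baseline-subtracted [well_trace()].
#' @param settings A [caller_settings()].
#' @return A list of class `"cq_result"`: `well`, `sample_id`, `channel`,
#'   `cq` (`NA` when absent), `end_rfu` (final-cycle reading) and `qc`.
#' @export
call_cq <- function(trace, settings = caller_settings()) {
  stopifnot(inherits(trace, "well_trace"))
  rfu <- trace$rfu
  C <- min(length(rfu), settings$max_cycles)
  thr <- settings$rfu_threshold
  above <- which(rfu[1:C] >= thr)
  qc <- character(0)
  if (length(above) == 0L) {
    cq <- NA_real_
  } else {
    c1 <- above[1]
    if (c1 == 1L) {
      cq <- 1
      qc <- c(qc, "threshold already exceeded at cycle 1")
    } else {
      cq <- (c1 - 1) + (thr - rfu[c1 - 1]) / (rfu[c1] - rfu[c1 - 1])
    }
    if (any(rfu[c1:C] < thr)) {
      qc <- c(qc, "transient crossing: trace dips below threshold after Cq")
    }
  }
  structure(list(well = trace$well, sample_id = trace$sample_id,
                 channel = trace$channel, cq = cq,
                 end_rfu = rfu[length(rfu)],
                 qc = paste(qc, collapse = "; ")),
            class = "cq_result")
}

#' @export
print.cq_result <- function(x, ...) {
  cat(sprintf("<cq_result> %s %s [%s]: Cq %s, end RFU %.1f%s\n",
              x$well, x$sample_id, x$channel,
              if (is.na(x$cq)) "absent" else sprintf("%.2f", x$cq),
              x$end_rfu, if (nzchar(x$qc)) paste0(" (", x$qc, ")") else ""))
  invisible(x)
}

#' Call Cq for every well/channel trace on a plate
#'
#' Takes traces in the long CSV layout (`well`, `sample_id`, `channel`,
#' `cycle`, `rfu`), baseline-subtracts each (well, channel) trace and calls
#' its Cq. A trace whose baseline window degenerates (amplification too early
#' to leave 3 clean cycles) is called on the uncorrected readings with a QC
#' note rather than failing the plate.
#'
#' @param traces Data frame of per-cycle readings in long format.
#' @param settings A [caller_settings()].
#' @return A tibble with one row per (well, channel): `well`, `sample_id`,
#'   `channel`, `cq` (`NA` for absent), `end_rfu`, `qc`, ordered by well then
#'   channel.
#' @export
call_plate <- function(traces, settings = caller_settings()) {
  needed <- c("well", "sample_id", "channel", "cycle", "rfu")
  missing_cols <- setdiff(needed, names(traces))
  if (length(missing_cols) > 0L) {
    stop("traces input lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(traces) == 0L) {
    return(tibble::tibble(well = character(), sample_id = character(),
                          channel = character(), cq = numeric(),
                          end_rfu = numeric(), qc = character()))
  }
  if (anyDuplicated(traces[, c("well", "channel", "cycle")])) {
    d <- traces[duplicated(traces[, c("well", "channel", "cycle")]), ][1, ]
    stop(sprintf("duplicate reading for well %s channel %s cycle %d",
                 d$well, d$channel, d$cycle), call. = FALSE)
  }
  key <- interaction(traces$well, traces$channel, drop = TRUE)
  parts <- split(seq_len(nrow(traces)), key)
  out <- lapply(parts, function(idx) {
    part <- traces[idx, ]
    part <- part[order(part$cycle), ]
    tr <- well_trace(part$well[1], part$sample_id[1], part$channel[1], part$rfu)
    extra_qc <- character(0)
    corrected <- tryCatch(subtract_baseline(tr, settings), error = function(e) {
      # amplification too early to fit a drift line: fall back to a constant
      # offset from the first readings rather than failing the plate
      extra_qc <<- paste0("linear baseline degenerate, constant offset used: ",
                          conditionMessage(e))
      tr$rfu <- tr$rfu - mean(tr$rfu[1:3])
      tr
    })
    res <- call_cq(corrected, settings)
    res$qc <- paste(c(extra_qc, if (nzchar(res$qc)) res$qc), collapse = "; ")
    tibble::tibble(well = res$well, sample_id = res$sample_id,
                   channel = res$channel, cq = res$cq, end_rfu = res$end_rfu,
                   qc = res$qc)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$well, out$channel), ]
  rownames(out) <- NULL
  out
}
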