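# The diagnostic decision tree. Four rules, evaluated 1 -> 4 -> 2 -> 3 so that
# dual positivity is decided before any single-species logic:
#   1) control probe Cq in (0, 40]  -- DNA present and amplifiable;
#   2) target probe Cq in (0, 40];
#   3) deltaCq = control Cq - target Cq in (0, 7]  -- the control is tuned to
#      be the less sensitive system, so a genuine target sits a bounded
#      distance *below* the control;
#   4) both target probes must not be in (0, 40] simultaneously.
# A target Cq outside (0, 40] is treated as absent throughout (rules 2 and 4
# share the same window). Every input maps to exactly one of five calls.

DIAGNOSTIC_CALLS <- c("NO_DNA", "H_ARMIGERA", "H_ZEA", "NEGATIVE_NON_TARGET",
                      "INCONCLUSIVE")

#' Interpretation-rule thresholds
#'
#' @param max_cq Upper Cq bound (inclusive) for rules 1, 2 and 4; cycles.
#' @param delta_min Exclusive lower deltaCq bound for rule 3 (the control Cq
#'   must be strictly higher than the target Cq).
#' @param delta_max Inclusive upper deltaCq bound for rule 3; cycles.
#' @return A list of class `"rule_thresholds"`.
#' @export
rule_thresholds <- function(max_cq = 40, delta_min = 0, delta_max = 7) {
  stopifnot(max_cq > 0, delta_max > 0)
  structure(list(max_cq = max_cq, delta_min = delta_min, delta_max = delta_max),
            class = "rule_thresholds")
}

cq_in_window <- function(cq, max_cq) {
  !is.na(cq) & cq > 0 & cq <= max_cq
}

#' Interpret one sample's three channels
#'
#' Applies the four interpretation rules to the control / H. armigera /
#' H. zea channel Cq values of a single sample and returns the diagnostic
#' call with a rule-by-rule trace. Absent Cq values are `NA`.
#'
#' @param control_cq,armigera_cq,zea_cq Channel Cq values (`NA` when absent).
#' @param thresholds A [rule_thresholds()].
#' @param sample_id Identifier carried into the result.
#' @return A list of class `"diagnostic_call"`: `sample_id`, `call` (one of
#'   `NO_DNA`, `H_ARMIGERA`, `H_ZEA`, `NEGATIVE_NON_TARGET`, `INCONCLUSIVE`),
#'   `delta_cq` (control - target when exactly one target fired, else `NA`)
#'   and `rule_trace`, a tibble of `(rule, pass, detail)` rows in evaluation
#'   order.
#' @examples
#' interpret_sample(control_cq = 20.15, armigera_cq = 17.58, zea_cq = NA)
#' @export
interpret_sample <- function(control_cq, armigera_cq, zea_cq,
                             thresholds = rule_thresholds(),
                             sample_id = "sample") {
  th <- thresholds
  trace <- list()
  note <- function(rule, pass, detail) {
    trace[[length(trace) + 1L]] <<- tibble::tibble(rule = rule, pass = pass,
                                                   detail = detail)
  }
  fmt <- function(cq) if (is.na(cq)) "absent" else sprintf("%.2f", cq)
  finish <- function(call, delta = NA_real_) {
    structure(list(sample_id = sample_id, call = call, delta_cq = delta,
                   rule_trace = do.call(rbind, trace)),
              class = "diagnostic_call")
  }

  r1 <- cq_in_window(control_cq, th$max_cq)
  note("rule1_control_in_window", r1,
       sprintf("control Cq %s; window (0, %g]", fmt(control_cq), th$max_cq))
  if (!r1) return(finish("NO_DNA"))

  arm <- cq_in_window(armigera_cq, th$max_cq)
  zea <- cq_in_window(zea_cq, th$max_cq)
  r4 <- !(arm && zea)
  note("rule4_single_target_only", r4,
       sprintf("FAM-channel Cq %s, HEX-channel Cq %s", fmt(armigera_cq), fmt(zea_cq)))
  if (!r4) return(finish("INCONCLUSIVE"))

  if (!arm && !zea) {
    note("rule2_target_in_window", FALSE, "no target signal in window")
    return(finish("NEGATIVE_NON_TARGET"))
  }

  target_cq <- if (arm) armigera_cq else zea_cq
  species <- if (arm) "H_ARMIGERA" else "H_ZEA"
  note("rule2_target_in_window", TRUE,
       sprintf("%s target Cq %s", species, fmt(target_cq)))
  delta <- control_cq - target_cq
  r3 <- delta > th$delta_min & delta <= th$delta_max
  note("rule3_delta_cq_in_bounds", r3,
       sprintf("deltaCq %.2f; bounds (%g, %g]", delta, th$delta_min, th$delta_max))
  if (!r3) return(finish("INCONCLUSIVE", delta))
  finish(species, delta)
}

#' @export
print.diagnostic_call <- function(x, ...) {
  cat(sprintf("<diagnostic_call> %s: %s%s\n", x$sample_id, x$call,
              if (!is.na(x$delta_cq)) sprintf(" (deltaCq %.2f)", x$delta_cq) else ""))
  for (i in seq_len(nrow(x$rule_trace))) {
    cat(sprintf("  %-28s %-4s %s\n", x$rule_trace$rule[i],
                if (x$rule_trace$pass[i]) "pass" else "FAIL",
                x$rule_trace$detail[i]))
  }
  invisible(x)
}

#' Interpret every sample on a plate of Cq results
#'
#' Groups Cq results by sample, maps channels to roles through the
#' fluorophore->role map, and applies [interpret_sample()]. Samples with no
#' control-channel entry are called `NO_DNA` with a trace note.
#'
#' @param results Data frame of Cq results (`sample_id`, `channel`, `cq`; the
#'   output of [call_plate()] or [read_cq_export()]).
#' @param channel_roles Named character vector fluorophore -> role, e.g.
#'   `c("Quasar 670" = "control", FAM = "armigera_target", HEX =
#'   "zea_target")`; an [assay_config()] is also accepted.
#' @param thresholds A [rule_thresholds()].
#' @return A tibble with `sample_id`, `call`, `delta_cq` and a `rule_trace`
#'   list-column, one row per sample in input order.
#' @export
interpret_plate <- function(results, channel_roles,
                            thresholds = rule_thresholds()) {
  if (inherits(channel_roles, "assay_config")) {
    thresholds <- channel_roles$rules
    channel_roles <- channel_roles$channel_roles
  }
  names(channel_roles) <- normalize_fluorophore(names(channel_roles))
  if (nrow(results) == 0L) {
    return(tibble::tibble(sample_id = character(), call = character(),
                          delta_cq = numeric(), rule_trace = list()))
  }
  chan <- normalize_fluorophore(results$channel)
  unmapped <- setdiff(unique(chan), names(channel_roles))
  if (length(unmapped) > 0L) {
    stop("channel '", unmapped[1], "' has no role in the channel map",
         call. = FALSE)
  }
  role <- unname(channel_roles[chan])
  samples <- unique(results$sample_id)
  calls <- lapply(samples, function(sid) {
    sel <- results$sample_id == sid
    pick <- function(r) {
      v <- results$cq[sel & role == r]
      v <- v[!is.na(v)]
      if (length(v) == 0L) NA_real_ else v[1]
    }
    if (!any(sel & role == "control")) {
      dc <- interpret_sample(NA_real_, pick("armigera_target"),
                             pick("zea_target"), thresholds, sample_id = sid)
      dc$rule_trace$detail[1] <- paste0(dc$rule_trace$detail[1],
                                        "; control channel missing from plate")
      return(dc)
    }
    interpret_sample(pick("control"), pick("armigera_target"),
                     pick("zea_target"), thresholds, sample_id = sid)
  })
  tibble::tibble(
    sample_id = vapply(calls, `[[`, character(1), "sample_id"),
    call = vapply(calls, `[[`, character(1), "call"),
    delta_cq = vapply(calls, `[[`, numeric(1), "delta_cq"),
    rule_trace = lapply(calls, `[[`, "rule_trace")
  )
}

#' Run-level validation against designated negative controls
#'
#' A run is invalid when any designated no-template / extraction-control
#' sample produced anything other than `NO_DNA`.
#'
#' @param calls Tibble from [interpret_plate()].
#' @param control_samples Character vector of sample ids designated as
#'   negative controls; may be empty (the verdict is then valid but flagged).
#' @return A list of class `"run_verdict"`: `valid`, `offending` (sample ids),
#'   `no_controls_designated`.
#' @export
validate_run <- function(calls, control_samples = character(0)) {
  missing_ctrl <- setdiff(control_samples, calls$sample_id)
  if (length(missing_ctrl) > 0L) {
    stop("designated control sample(s) absent from plate: ",
         paste(missing_ctrl, collapse = ", "), call. = FALSE)
  }
  sel <- calls$sample_id %in% control_samples
  offending <- calls$sample_id[sel & calls$call != "NO_DNA"]
  structure(list(valid = length(offending) == 0L,
                 offending = offending,
                 no_controls_designated = length(control_samples) == 0L),
            class = "run_verdict")
}

#' @export
print.run_verdict <- function(x, ...) {
  cat(sprintf("<run_verdict> %s%s\n",
              if (x$valid) "VALID" else "INVALID",
              if (x$no_controls_designated) " (no negative controls designated)" else ""))
  if (length(x$offending) > 0L) {
    cat("  contaminated control(s): ", paste(x$offending, collapse = ", "), "\n")
  }
  invisible(x)
}
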