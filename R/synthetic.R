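# Seeded synthetic plate generator. Emulates the statistical structure the
# triplex assay shows on real specimens: per-class control-channel Cq
# distributions, deltaCq-coupled target channels (draw the control Cq, then
# the difference), sub-threshold cross-reactive signal on the wrong target
# channel, dilution series with a known slope and detection floor, and
# mixed-template positivity patterns. Distributions are truncated normals:
# published summaries give mean/SD/range only, so the family is a modelling
# choice (see the methods vignette).

rtrunc_norm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) return(rep(mean, n))
  lo <- stats::pnorm(lower, mean, sd)
  hi <- stats::pnorm(upper, mean, sd)
  if (lo >= hi) stop("impossible truncation bounds", call. = FALSE)
  stats::qnorm(stats::runif(n, lo, hi), mean, sd)
}

#' Define a species profile for plate simulation
#'
#' @param label One of `"armigera"`, `"zea"`, `"non_target"`, `"ntc"`.
#' @param control_mean,control_sd,control_bounds Truncated-normal parameters
#'   of the control-channel Cq (cycles). `NA` mean = no control signal (NTC).
#' @param delta_mean,delta_sd,delta_bounds Truncated-normal parameters of
#'   deltaCq = control Cq - target Cq; the target channel is derived as
#'   control - delta. `NA` mean = no target signal.
#' @param target_channel `"armigera_target"`, `"zea_target"` or `NA`.
#' @param crossreact_prob Probability of a sub-threshold cross-reactive signal
#'   on the wrong target channel.
#' @param crossreact_rfu_range End-RFU interval of cross-reactive signal; must
#'   sit entirely below the caller threshold.
#' @return A list of class `"species_profile"`.
#' @export
species_profile <- function(label, control_mean = NA_real_, control_sd = 0,
                            control_bounds = c(-Inf, Inf),
                            delta_mean = NA_real_, delta_sd = 0,
                            delta_bounds = c(0, 7),
                            target_channel = NA_character_,
                            crossreact_prob = 0,
                            crossreact_rfu_range = c(100, 600)) {
  stopifnot(control_sd >= 0, delta_sd >= 0,
            crossreact_prob >= 0, crossreact_prob <= 1,
            length(crossreact_rfu_range) == 2L,
            crossreact_rfu_range[1] <= crossreact_rfu_range[2])
  structure(list(label = label, control_mean = control_mean,
                 control_sd = control_sd, control_bounds = control_bounds,
                 delta_mean = delta_mean, delta_sd = delta_sd,
                 delta_bounds = delta_bounds, target_channel = target_channel,
                 crossreact_prob = crossreact_prob,
                 crossreact_rfu_range = crossreact_rfu_range),
            class = "species_profile")
}

#' Default species profiles
#'
#' The per-class control-Cq and deltaCq summaries observed on the 452-sample
#' development cohort: H. armigera control 20.15 +/- 2.80 (range 13.87-31.45)
#' with deltaCq 3.41 +/- 1.07 (0.09-6.68); H. zea control 17.58 +/- 2.89
#' (10.74-30.62) with deltaCq 2.64 +/- 0.86 (0.04-6.16); non-target
#' Heliothinae control 21.92 +/- 4.83 (12.60-39.71) with no target signal;
#' no-template controls emit nothing. Cross-reactive wrong-channel signal is
#' generated with probability 0.5 and end RFU in 100-600 (below the 1000-RFU
#' threshold, usually < 500).
#'
#' @return Named list of [species_profile()]s.
#' @export
default_species_profiles <- function() {
  list(
    armigera = species_profile("armigera",
                               control_mean = 20.15, control_sd = 2.80,
                               control_bounds = c(13.87, 31.45),
                               delta_mean = 3.41, delta_sd = 1.07,
                               delta_bounds = c(0.09, 6.68),
                               target_channel = "armigera_target",
                               crossreact_prob = 0.5),
    zea = species_profile("zea",
                          control_mean = 17.58, control_sd = 2.89,
                          control_bounds = c(10.74, 30.62),
                          delta_mean = 2.64, delta_sd = 0.86,
                          delta_bounds = c(0.04, 6.16),
                          target_channel = "zea_target",
                          crossreact_prob = 0.5),
    non_target = species_profile("non_target",
                                 control_mean = 21.92, control_sd = 4.83,
                                 control_bounds = c(12.60, 39.71)),
    ntc = species_profile("ntc")
  )
}

# Synthesise one 40-cycle trace. A present Cq becomes a logistic sigmoid whose
# analytic crossing of `threshold` (after baseline removal) equals the drawn
# Cq; cross-reactive signal is a logistic whose plateau sits below threshold;
# silent channels are baseline only. All traces carry offset + linear drift +
# Gaussian read noise.
synth_trace <- function(cycles, kind = c("positive", "crossreact", "silent"),
                        cq = NA, plateau = NA, threshold = 1000) {
  kind <- match.arg(kind)
  cyc <- seq_len(cycles)
  offset <- stats::runif(1, 50, 300)
  drift <- stats::runif(1, 0, 1.5)
  k <- stats::runif(1, 0.8, 1.2)
  base <- offset + drift * cyc + stats::rnorm(cycles, 0, 2)
  sig <- switch(kind,
    positive = {
      midpoint <- cq + log(plateau / threshold - 1) / k
      plateau / (1 + exp(-k * (cyc - midpoint)))
    },
    crossreact = {
      midpoint <- stats::runif(1, 28, 36)
      plateau / (1 + exp(-k * (cyc - midpoint)))
    },
    silent = 0
  )
  base + sig
}

#' Generate a synthetic multi-plate run
#'
#' Draws per-well channel Cqs from the species profiles (control Cq from a
#' truncated normal, target Cq = control - deltaCq with deltaCq from its own
#' truncated normal), adds sub-threshold cross-reactive signal on the wrong
#' target channel, and optionally renders every channel as a 40-cycle
#' logistic fluorescence trace whose analytic threshold crossing equals the
#' drawn Cq. Ground-truth labels and drawn values are returned alongside, so
#' the Cq caller and the rule engine can be validated end to end.
#'
#' @param design Named integer vector of well counts per profile, e.g.
#'   `c(armigera = 139, zea = 258, non_target = 55, ntc = 2)`.
#' @param seed Integer seed; identical seed + design reproduces the run
#'   byte for byte.
#' @param profiles Named list of [species_profile()]s covering `names(design)`.
#' @param emit Any of `"cq_table"`, `"traces"`.
#' @param channels Fluorophore name per role, matching the assay
#'   configuration.
#' @param cycles Cycles per trace.
#' @param rfu_threshold Caller threshold the traces are built against.
#' @return A list with `cq_table` (well, sample_id, channel, cq, end_rfu),
#'   `traces` (long per-cycle tibble, or `NULL`), and `truth` (well,
#'   sample_id, label, control_cq, target_cq, target_channel).
#' @examples
#' run <- generate_plate(c(armigera = 3, ntc = 1), seed = 7)
#' run$truth
#' @export
generate_plate <- function(design, seed,
                           profiles = default_species_profiles(),
                           emit = c("cq_table", "traces"),
                           channels = c(control = "Quasar 670",
                                        armigera_target = "FAM",
                                        zea_target = "HEX"),
                           cycles = 40L, rfu_threshold = 1000) {
  stopifnot(!is.null(names(design)), all(design >= 0))
  emit <- match.arg(emit, several.ok = TRUE)
  missing_prof <- setdiff(names(design), names(profiles))
  if (length(missing_prof) > 0L) {
    stop("no profile for design class '", missing_prof[1], "'", call. = FALSE)
  }
  for (p in profiles[names(design)]) {
    if (p$crossreact_rfu_range[2] >= rfu_threshold) {
      stop("profile '", p$label,
           "': cross-reactive RFU range must sit below the caller threshold",
           call. = FALSE)
    }
  }
  set.seed(seed)
  n_total <- sum(design)
  target_chans <- unname(channels[c("armigera_target", "zea_target")])

  well_ids <- if (n_total > 0) {
    plate <- (seq_len(n_total) - 1L) %/% 96L + 1L
    pos <- (seq_len(n_total) - 1L) %% 96L
    sprintf("P%d-%s%02d", plate, LETTERS[pos %/% 12L + 1L], pos %% 12L + 1L)
  } else character(0)

  labels <- rep(names(design), times = design)
  truth <- vector("list", n_total)
  cq_rows <- vector("list", n_total)
  trace_rows <- if ("traces" %in% emit) vector("list", n_total) else NULL

  for (i in seq_len(n_total)) {
    prof <- profiles[[labels[i]]]
    sid <- sprintf("SYN-%04d", i)
    ctrl <- if (is.na(prof$control_mean)) NA_real_ else
      rtrunc_norm(1, prof$control_mean, prof$control_sd,
                  prof$control_bounds[1], prof$control_bounds[2])
    if (!is.na(prof$delta_mean) && !is.na(ctrl)) {
      delta <- rtrunc_norm(1, prof$delta_mean, prof$delta_sd,
                           prof$delta_bounds[1], prof$delta_bounds[2])
      tgt <- ctrl - delta
    } else {
      tgt <- NA_real_
    }
    tgt_chan <- if (is.na(prof$target_channel)) NA_character_ else
      unname(channels[prof$target_channel])

    # per-channel plan: cq, plateau, kind
    chan_names <- unname(c(channels["control"], target_chans))
    plan <- lapply(chan_names, function(ch) {
      if (ch == channels[["control"]] && !is.na(ctrl)) {
        list(kind = "positive", cq = ctrl, plateau = stats::runif(1, 1500, 4000))
      } else if (!is.na(tgt_chan) && ch == tgt_chan) {
        list(kind = "positive", cq = tgt, plateau = stats::runif(1, 1500, 4000))
      } else if (!is.na(tgt_chan) && ch %in% target_chans &&
                 stats::runif(1) < prof$crossreact_prob) {
        list(kind = "crossreact", cq = NA_real_,
             plateau = stats::runif(1, prof$crossreact_rfu_range[1],
                                    prof$crossreact_rfu_range[2]))
      } else {
        list(kind = "silent", cq = NA_real_, plateau = NA_real_)
      }
    })

    cq_rows[[i]] <- tibble::tibble(
      well = well_ids[i], sample_id = sid, channel = chan_names,
      cq = vapply(plan, `[[`, numeric(1), "cq"),
      end_rfu = vapply(plan, function(p) switch(p$kind,
        positive = p$plateau, crossreact = p$plateau,
        silent = stats::rnorm(1, 0, 5)), numeric(1))
    )
    if (!is.null(trace_rows)) {
      rfu <- unlist(lapply(plan, function(p) {
        synth_trace(cycles, p$kind, cq = p$cq, plateau = p$plateau,
                    threshold = rfu_threshold)
      }))
      trace_rows[[i]] <- tibble::tibble(
        well = well_ids[i], sample_id = sid,
        channel = rep(chan_names, each = cycles),
        cycle = rep(seq_len(cycles), times = length(chan_names)),
        rfu = rfu
      )
    }
    truth[[i]] <- tibble::tibble(well = well_ids[i], sample_id = sid,
                                 label = labels[i], control_cq = ctrl,
                                 target_cq = tgt, target_channel = tgt_chan)
  }

  empty_cq <- tibble::tibble(well = character(), sample_id = character(),
                             channel = character(), cq = numeric(),
                             end_rfu = numeric())
  list(
    cq_table = if (n_total > 0) do.call(rbind, cq_rows) else empty_cq,
    traces = if (!is.null(trace_rows)) {
      if (n_total > 0) do.call(rbind, trace_rows) else
        tibble::tibble(well = character(), sample_id = character(),
                       channel = character(), cycle = integer(),
                       rfu = numeric())
    },
    truth = if (n_total > 0) do.call(rbind, truth) else
      tibble::tibble(well = character(), sample_id = character(),
                     label = character(), control_cq = numeric(),
                     target_cq = numeric(), target_channel = character())
  )
}

#' Generate a synthetic 10-fold dilution series
#'
#' Cq follows the standard-curve model `intercept + slope * log10(conc)` with
#' Gaussian noise; below a floor concentration replicates drop out with the
#' given probability, emulating a finite detection limit.
#'
#' @param top_concentration Highest concentration in ng/ul.
#' @param decades Number of 10-fold steps (>= 3).
#' @param replicates Replicates per concentration.
#' @param slope Cycles per log10(concentration) (negative).
#' @param intercept Cq at 1 ng/ul.
#' @param noise_sd Replicate noise SD in cycles.
#' @param floor_conc Concentrations strictly below this can drop out.
#' @param dropout_below Dropout probability below the floor.
#' @param channel Channel label carried in the output.
#' @param seed Integer seed.
#' @return A tibble of dilution points: `concentration`, `channel`,
#'   `replicate`, `cq` (`NA` = dropout).
#' @export
generate_dilution_series <- function(top_concentration = 100, decades = 5L,
                                     replicates = 3L, slope = -3.3219,
                                     intercept = 22, noise_sd = 0.2,
                                     floor_conc = 0.01, dropout_below = 1,
                                     channel = "FAM", seed = 1L) {
  stopifnot(decades >= 3L, replicates >= 1L, top_concentration > 0)
  set.seed(seed)
  concs <- top_concentration * 10^(-(seq_len(decades) - 1L))
  grid <- expand.grid(replicate = seq_len(replicates), concentration = concs)
  cq <- intercept + slope * log10(grid$concentration) +
    stats::rnorm(nrow(grid), 0, noise_sd)
  drop <- grid$concentration < floor_conc &
    stats::runif(nrow(grid)) < dropout_below
  cq[drop] <- NA_real_
  tibble::tibble(concentration = grid$concentration, channel = channel,
                 replicate = grid$replicate, cq = cq)
}

# Observed positivity/mean-Cq patterns of the minor species' channel in
# mixed-template runs. DNA mixtures: the H. armigera probe reports its
# species only at 1:1 (mean Cq 19.35); the H. zea probe reports down to
# 1:100 (means 16.70 / 19.85 / 22.77). Bulk leg extractions (armigera minor):
# only 1:1 reports (mean Cq 21.02).
MIXED_PATTERNS <- list(
  dna = list(
    armigera = c("1" = 19.35),
    zea = c("1" = 16.70, "10" = 19.85, "100" = 22.77)
  ),
  legs = list(
    armigera = c("1" = 21.02)
  )
)
MIXED_RATIOS <- list(dna = c(1, 10, 100, 1000), legs = c(1, 4, 9, 19))

#' Generate mixed-template (spiked/bulk) samples
#'
#' Emulates contamination and bulk-trap scenarios: DNA of a minor species
#' mixed into a major species at an enumerated ratio (`minor:major = 1:ratio`),
#' either as purified DNA or as a bulk leg extraction. Channel positivity is
#' pattern-programmed from the observed outcomes -- the minor species'
#' channel only reports at the ratios where the wet assay did; the major
#' species' channel always reports (its template is at full concentration);
#' the control channel is coupled to the major channel through the major
#' species' deltaCq distribution.
#'
#' @param minor,major `"armigera"` or `"zea"` (must differ).
#' @param ratio Major-species parts per 1 part minor: one of 1, 10, 100, 1000
#'   for `type = "dna"`; 1, 4, 9, 19 for `type = "legs"`. Leg bulks are only
#'   characterised with H. armigera as the minor species.
#' @param type `"dna"` or `"legs"`.
#' @param replicates Number of replicate samples.
#' @param seed Integer seed.
#' @param noise_sd Replicate noise SD in cycles around the pattern means.
#' @param profiles Profiles supplying the control-coupling deltaCq.
#' @return A tibble of sample channels: `sample_id`, `control_cq`,
#'   `armigera_cq`, `zea_cq` (`NA` = absent).
#' @export
generate_mixed_template <- function(minor, major, ratio,
                                    type = c("dna", "legs"),
                                    replicates = 3L, seed = 1L,
                                    noise_sd = 0.3,
                                    profiles = default_species_profiles()) {
  type <- match.arg(type)
  minor <- match.arg(minor, c("armigera", "zea"))
  major <- match.arg(major, c("armigera", "zea"))
  if (minor == major) stop("minor and major species must differ", call. = FALSE)
  if (!(ratio %in% MIXED_RATIOS[[type]])) {
    stop(sprintf("ratio 1:%s is not in the %s design {%s}", format(ratio), type,
                 paste(MIXED_RATIOS[[type]], collapse = ", ")), call. = FALSE)
  }
  patterns <- MIXED_PATTERNS[[type]]
  if (is.null(patterns[[minor]])) {
    stop(sprintf("%s mixtures with '%s' as the minor species are not characterised",
                 type, minor), call. = FALSE)
  }
  set.seed(seed)
  minor_mean <- patterns[[minor]][as.character(ratio)]
  # the major species' template is at full concentration in every ratio, so
  # its channel reports at its 1:1 mean throughout
  major_mean <- switch(type,
                       dna = MIXED_PATTERNS$dna[[major]][["1"]],
                       legs = 18.0)
  major_cq <- stats::rnorm(replicates, major_mean, noise_sd)
  minor_cq <- if (is.na(minor_mean)) rep(NA_real_, replicates) else
    stats::rnorm(replicates, minor_mean, noise_sd)
  prof <- profiles[[major]]
  control_cq <- major_cq + rtrunc_norm(replicates, prof$delta_mean,
                                       prof$delta_sd, prof$delta_bounds[1],
                                       prof$delta_bounds[2])
  arm_cq <- if (minor == "armigera") minor_cq else major_cq
  zea_cq <- if (minor == "zea") minor_cq else major_cq
  tibble::tibble(
    sample_id = sprintf("MIX-%s1to%s-%s-%02d", substr(minor, 1, 3),
                        format(ratio), type, seq_len(replicates)),
    control_cq = control_cq, armigera_cq = arm_cq, zea_cq = zea_cq
  )
}
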