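# Assay configuration: the oligo panel, fluorophore->role map, caller settings
# and interpretation thresholds. Thresholds live here rather than in code
# because they are instrument-dependent: the rules were calibrated on one
# platform and may need adjustment on others.

FLUOR_ALIASES <- c(
  "fam" = "FAM",
  "hex" = "HEX",
  "tet" = "TET",
  "quasar670" = "Quasar 670",
  "cy5" = "Quasar 670",
  "calfluorred610" = "CAL Fluor Red 610",
  "calred610" = "CAL Fluor Red 610",
  "texasred" = "CAL Fluor Red 610"
)

#' Normalise a fluorophore name
#'
#' Case- and whitespace-insensitive, with an alias table (Quasar 670 = Cy5;
#' CAL Fluor Red 610 = Texas Red). Unknown names are returned as given.
#'
#' @param x Character vector of fluorophore names.
#' @return Canonical names.
#' @export
normalize_fluorophore <- function(x) {
  key <- gsub("[^a-z0-9]", "", tolower(x))
  out <- unname(FLUOR_ALIASES[key])
  ifelse(is.na(out), x, out)
}

#' Assemble an assay configuration
#'
#' @param panel List of [oligo()]s (names are taken from the oligos).
#' @param channel_roles Named character vector mapping fluorophore ->
#'   one of `"control"`, `"armigera_target"`, `"zea_target"`.
#' @param pairs List of primer pairs, each `list(name, forward, reverse,
#'   probes)` referring to panel oligo names.
#' @param caller A [caller_settings()] object.
#' @param rules A [rule_thresholds()] object.
#' @param protocol_metadata Free-form list (cycling program, reagent
#'   concentrations); informational only.
#' @return An object of class `"assay_config"`.
#' @export
assay_config <- function(panel, channel_roles, pairs = list(),
                         caller = caller_settings(), rules = rule_thresholds(),
                         protocol_metadata = list()) {
  stopifnot(is.list(panel), length(panel) > 0L)
  for (o in panel) {
    if (!inherits(o, "oligo")) stop("panel entries must be oligo objects", call. = FALSE)
  }
  nm <- vapply(panel, `[[`, character(1), "name")
  if (anyDuplicated(nm)) {
    stop("duplicate oligo name in panel: ", nm[duplicated(nm)][1], call. = FALSE)
  }
  names(panel) <- nm
  names(channel_roles) <- normalize_fluorophore(names(channel_roles))
  bad_role <- setdiff(channel_roles, c("control", "armigera_target", "zea_target"))
  if (length(bad_role) > 0L) {
    stop("channel_roles: unknown role '", bad_role[1], "'", call. = FALSE)
  }
  if (anyDuplicated(names(channel_roles))) {
    stop("channel_roles: fluorophore mapped twice: ",
         names(channel_roles)[duplicated(names(channel_roles))][1], call. = FALSE)
  }
  if (sum(channel_roles == "control") != 1L) {
    stop("channel_roles: exactly one control channel is required", call. = FALSE)
  }
  for (r in c("armigera_target", "zea_target")) {
    if (sum(channel_roles == r) != 1L) {
      stop("channel_roles: exactly one ", r, " channel is required", call. = FALSE)
    }
  }
  for (o in panel) {
    if (o$role == "probe") {
      o$fluorophore <- normalize_fluorophore(o$fluorophore)
      if (is.null(o$fluorophore) || !(o$fluorophore %in% names(channel_roles))) {
        stop("probe '", o$name, "' has no channel role for fluorophore '",
             o$fluorophore %||% "<none>", "'", call. = FALSE)
      }
    }
  }
  for (pair in pairs) {
    for (field in c("forward", "reverse")) {
      if (!(pair[[field]] %in% nm)) {
        stop("pairs: '", pair$name, "' refers to unknown oligo '",
             pair[[field]], "'", call. = FALSE)
      }
    }
    if (!all(unlist(pair$probes) %in% nm)) {
      stop("pairs: '", pair$name, "' refers to an unknown probe", call. = FALSE)
    }
  }
  structure(list(panel = panel, channel_roles = channel_roles, pairs = pairs,
                 caller = caller, rules = rules,
                 protocol_metadata = protocol_metadata),
            class = "assay_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.assay_config <- function(x, ...) {
  cat(sprintf("<assay_config> %d oligos, %d primer pair(s)\n",
              length(x$panel), length(x$pairs)))
  for (f in names(x$channel_roles)) {
    cat(sprintf("  %-18s -> %s\n", f, x$channel_roles[[f]]))
  }
  cat(sprintf("  threshold %.1f RFU, %d cycles, deltaCq (%g, %g]\n",
              x$caller$rfu_threshold, x$caller$max_cycles,
              x$rules$delta_min, x$rules$delta_max))
  invisible(x)
}

#' Load an assay configuration from JSON
#'
#' @param path Path to a JSON file with fields `panel`, `channel_roles`,
#'   `pairs`, `caller`, `rules`, `protocol_metadata`.
#' @return A validated [assay_config()].
#' @export
load_assay_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  j <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  for (field in c("panel", "channel_roles")) {
    if (is.null(j[[field]])) stop("config missing field '", field, "'", call. = FALSE)
  }
  panel <- lapply(j$panel, function(e) {
    for (field in c("name", "sequence", "role")) {
      if (is.null(e[[field]])) stop("panel entry missing field '", field, "'", call. = FALSE)
    }
    oligo(e$name, e$sequence, e$role,
          fluorophore = e$fluorophore %||% NULL,
          quencher = e$quencher %||% NULL)
  })
  caller <- do.call(caller_settings, utils::modifyList(
    list(), lapply(j$caller %||% list(), unlist)))
  rules <- do.call(rule_thresholds, utils::modifyList(
    list(), lapply(j$rules %||% list(), unlist)))
  pairs <- lapply(j$pairs %||% list(), function(p) {
    list(name = p$name, forward = p$forward, reverse = p$reverse,
         probes = as.character(unlist(p$probes)))
  })
  assay_config(panel = panel,
               channel_roles = unlist(j$channel_roles),
               pairs = pairs, caller = caller, rules = rules,
               protocol_metadata = j$protocol_metadata %||% list())
}

#' Write an assay configuration to JSON
#'
#' Inverse of [load_assay_config()]; load -> write -> load is the identity.
#'
#' @param config An [assay_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_assay_config <- function(config, path) {
  stopifnot(inherits(config, "assay_config"))
  j <- list(
    panel = lapply(unname(config$panel), function(o) {
      e <- list(name = o$name, sequence = o$sequence, role = o$role)
      if (!is.null(o$fluorophore)) e$fluorophore <- o$fluorophore
      if (!is.null(o$quencher)) e$quencher <- o$quencher
      e
    }),
    channel_roles = as.list(config$channel_roles),
    pairs = lapply(config$pairs, function(p) {
      list(name = p$name, forward = p$forward, reverse = p$reverse,
           probes = as.list(p$probes))
    }),
    caller = list(rfu_threshold = config$caller$rfu_threshold,
                  baseline_window = config$caller$baseline_window,
                  max_cycles = config$caller$max_cycles),
    rules = list(max_cq = config$rules$max_cq,
                 delta_min = config$rules$delta_min,
                 delta_max = config$rules$delta_max),
    protocol_metadata = config$protocol_metadata
  )
  jsonlite::write_json(j, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Bundled assay configurations
#'
#' `default_assay_config()` is the published triplex panel as run on the
#' development platform: FAM = H. armigera ITS2 probe, HEX = H. zea ITS2
#' probe, Quasar 670 = 18S rDNA control, 1000-RFU threshold, 40 cycles,
#' delta-Cq window (0, 7]. The `"cepheid"` variant keeps the same sequences
#' but swaps fluorophores for the SmartCycler platform (CAL Fluor Red 610
#' control, TET for H. zea, FAM for H. armigera) and its default 30-unit
#' threshold.
#'
#' @param variant `"biorad"` (default) or `"cepheid"`.
#' @return An [assay_config()].
#' @export
default_assay_config <- function(variant = c("biorad", "cepheid")) {
  variant <- match.arg(variant)
  path <- system.file("extdata", paste0("assay_", variant, ".json"),
                      package = "heliplex", mustWork = TRUE)
  load_assay_config(path)
}
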