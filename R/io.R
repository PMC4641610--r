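# Readers/writers for the package's external formats: long-format trace CSV,
# Cq results CSV (two dialects), dilution-point CSV and oligo panels as
# FASTA. All writers use a stable column order and fixed decimal formatting
# so outputs are diffable across runs at a fixed seed.

fmt_num <- function(x, digits = 4) {
  ifelse(is.na(x), "", formatC(x, format = "f", digits = digits))
}

#' Write / read per-cycle fluorescence traces
#'
#' Long CSV layout: `well`, `sample_id`, `channel`, `cycle`, `rfu`.
#'
#' @param traces Data frame of traces in long format.
#' @param path CSV path.
#' @return `read_traces()` returns a tibble; `write_traces()` returns `path`
#'   invisibly.
#' @export
write_traces <- function(traces, path) {
  df <- data.frame(well = traces$well, sample_id = traces$sample_id,
                   channel = traces$channel, cycle = traces$cycle,
                   rfu = fmt_num(traces$rfu, 3))
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_traces
#' @export
read_traces <- function(path) {
  if (!file.exists(path)) stop("trace file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("well", "sample_id", "channel", "cycle", "rfu")
  miss <- setdiff(needed, names(df))
  if (length(miss) > 0L) {
    stop(basename(path), ": missing column(s) ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  tibble::as_tibble(df[needed])
}

#' Write / read Cq results
#'
#' Results CSV: `well`, `sample_id`, `channel`, `cq`, `end_rfu`. Two
#' dialects: `"native"` leaves absent Cq cells empty; `"zero_coded"` writes
#' absent Cq as `0` (the SmartCycler-style export convention, where a
#' detection is reported as "Cq > 0"). Reading is the inverse, so a
#' write-then-read round trip is lossless in either dialect.
#'
#' @param results Data frame of Cq results (from [call_plate()]).
#' @param path CSV path.
#' @param dialect `"native"` or `"zero_coded"`.
#' @param max_cycles Upper integrity bound on Cq when reading.
#' @return `read_cq_export()` returns a tibble with `NA` for absent Cq.
#' @export
write_cq_export <- function(results, path, dialect = c("native", "zero_coded")) {
  dialect <- match.arg(dialect)
  cq <- results$cq
  cq_str <- if (dialect == "zero_coded") {
    formatC(ifelse(is.na(cq), 0, cq), format = "f", digits = 4)
  } else {
    fmt_num(cq, 4)
  }
  df <- data.frame(well = results$well, sample_id = results$sample_id,
                   channel = results$channel, cq = cq_str,
                   end_rfu = fmt_num(results$end_rfu, 2))
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_cq_export
#' @export
read_cq_export <- function(path, dialect = c("native", "zero_coded"),
                           max_cycles = 40) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("Cq file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(cq = "character"))
  needed <- c("well", "sample_id", "channel", "cq")
  miss <- setdiff(needed, names(df))
  if (length(miss) > 0L) {
    stop(basename(path), ": missing column(s) ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  cq <- suppressWarnings(as.numeric(df$cq))
  cq[df$cq == ""] <- NA_real_
  bad <- which(!is.na(cq) & (cq < 0 | cq > max_cycles))
  if (length(bad) > 0L) {
    stop(sprintf("%s: row %d has Cq %s outside [0, %g]", basename(path),
                 bad[1], df$cq[bad[1]], max_cycles), call. = FALSE)
  }
  if (dialect == "zero_coded") cq[!is.na(cq) & cq == 0] <- NA_real_
  out <- tibble::tibble(well = df$well, sample_id = df$sample_id,
                        channel = df$channel, cq = cq)
  out$end_rfu <- if ("end_rfu" %in% names(df)) as.numeric(df$end_rfu) else NA_real_
  out
}

#' Write / read dilution points
#'
#' CSV: `concentration`, `channel`, `replicate`, `cq` (empty = dropout).
#'
#' @param points Data frame of dilution points.
#' @param path CSV path.
#' @export
write_dilution_points <- function(points, path) {
  df <- data.frame(concentration = points$concentration,
                   channel = points$channel, replicate = points$replicate,
                   cq = fmt_num(points$cq, 4))
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_dilution_points
#' @export
read_dilution_points <- function(path) {
  if (!file.exists(path)) stop("dilution file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(cq = "character"))
  cq <- suppressWarnings(as.numeric(df$cq))
  cq[df$cq == ""] <- NA_real_
  tibble::tibble(concentration = as.numeric(df$concentration),
                 channel = df$channel,
                 replicate = as.integer(df$replicate), cq = cq)
}

#' Write / read an oligo panel as FASTA
#'
#' One record per oligo; the description line carries `key=value` tokens for
#' role, fluorophore and quencher, e.g.
#' `>RT-ITS-zea role=probe fluorophore=HEX quencher=BHQ-1`.
#'
#' @param panel List of [oligo()]s.
#' @param path FASTA path.
#' @return `read_oligo_fasta()` returns a named list of oligos.
#' @export
write_oligo_fasta <- function(panel, path) {
  seqs <- Biostrings::DNAStringSet(vapply(panel, `[[`, character(1), "sequence"))
  names(seqs) <- vapply(panel, function(o) {
    tokens <- paste0("role=", o$role)
    if (!is.null(o$fluorophore)) {
      tokens <- paste(tokens, paste0("fluorophore=", gsub(" ", "_", o$fluorophore)))
    }
    if (!is.null(o$quencher)) {
      tokens <- paste(tokens, paste0("quencher=", o$quencher))
    }
    paste(o$name, tokens)
  }, character(1))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' @rdname write_oligo_fasta
#' @export
read_oligo_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA not found: ", path, call. = FALSE)
  seqs <- Biostrings::readDNAStringSet(path)
  panel <- lapply(seq_along(seqs), function(i) {
    header <- names(seqs)[i]
    parts <- strsplit(header, "\\s+")[[1]]
    name <- parts[1]
    kv <- parts[grepl("=", parts, fixed = TRUE)]
    vals <- stats::setNames(sub("^[^=]*=", "", kv), sub("=.*$", "", kv))
    fl <- if ("fluorophore" %in% names(vals)) gsub("_", " ", vals[["fluorophore"]]) else NULL
    oligo(name, as.character(seqs[[i]]),
          role = if ("role" %in% names(vals)) vals[["role"]] else "forward_primer",
          fluorophore = fl,
          quencher = if ("quencher" %in% names(vals)) vals[["quencher"]] else NULL)
  })
  stats::setNames(panel, vapply(panel, `[[`, character(1), "name"))
}

#' Read templates from FASTA
#'
#' @param path Multi-record FASTA of template sequences.
#' @return Named character vector (IUPAC validated).
#' @export
read_templates <- function(path) {
  if (!file.exists(path)) stop("FASTA not found: ", path, call. = FALSE)
  seqs <- Biostrings::readDNAStringSet(path)
  out <- stats::setNames(as.character(seqs), sub("\\s.*$", "", names(seqs)))
  for (i in seq_along(out)) out[[i]] <- validate_iupac(out[[i]], names(out)[i])
  out
}

#' Write diagnostic calls to CSV
#'
#' Columns `sample_id`, `call`, `delta_cq` plus a JSON-encoded `rule_trace`.
#'
#' @param calls Tibble from [interpret_plate()].
#' @param path CSV path.
#' @export
write_calls <- function(calls, path) {
  df <- data.frame(
    sample_id = calls$sample_id, call = calls$call,
    delta_cq = fmt_num(calls$delta_cq, 4),
    rule_trace = vapply(calls$rule_trace, function(tr) {
      as.character(jsonlite::toJSON(tr, auto_unbox = FALSE, digits = NA))
    }, character(1))
  )
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
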