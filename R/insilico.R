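# In-silico PCR: IUPAC-aware binding-site search, amplicon prediction and
# hydrolysis-probe scanning. Site search delegates to Biostrings'
# ambiguity-aware matcher (fixed = FALSE => base-set intersection), with
# per-position mismatch accounting layered on top. Coordinates are 0-based
# half-open on the forward strand of the template; amplicon length includes
# both primer footprints.

# Per-position incompatibility count between a pattern and a template window.
count_mismatches <- function(pattern_chars, window_chars) {
  sum(!iupac_compatible(pattern_chars, window_chars))
}

scan_one_strand <- function(template, template_id, pattern, oligo_name, strand,
                            max_mismatches, anchor_3prime) {
  subject <- Biostrings::DNAString(template)
  hits <- Biostrings::matchPattern(Biostrings::DNAString(pattern), subject,
                                   max.mismatch = max_mismatches, fixed = FALSE)
  starts1 <- IRanges::start(hits)          # 1-based
  if (length(starts1) == 0L) return(empty_sites())
  pat_chars <- strsplit(pattern, "", fixed = TRUE)[[1]]
  tpl_chars <- strsplit(template, "", fixed = TRUE)[[1]]
  k <- length(pat_chars)
  keep <- logical(length(starts1))
  mm <- integer(length(starts1))
  for (i in seq_along(starts1)) {
    win <- tpl_chars[starts1[i]:(starts1[i] + k - 1L)]
    ok <- iupac_compatible(pat_chars, win)
    mm[i] <- sum(!ok)
    keep[i] <- mm[i] <= max_mismatches
    if (keep[i] && anchor_3prime && max_mismatches > 0L) {
      # the oligo's 3' end must pair perfectly (extension-critical bases);
      # on the - strand the search pattern is reverse-complemented, so the
      # oligo 3' end maps to the left edge of the matched window
      idx <- if (strand == "+") (k - 2L):k else 1:3
      keep[i] <- all(ok[idx])
    }
  }
  tibble::tibble(
    template_id = template_id,
    start = starts1[keep] - 1L,
    end = starts1[keep] - 1L + k,
    strand = strand,
    oligo_name = oligo_name,
    mismatches = mm[keep]
  )
}

empty_sites <- function() {
  tibble::tibble(template_id = character(), start = integer(), end = integer(),
                 strand = character(), oligo_name = character(),
                 mismatches = integer())
}

#' Find binding sites of an oligo on a template
#'
#' Searches both strands of the template for windows compatible with the
#' (possibly degenerate) oligo pattern. Two IUPAC codes match when their base
#' sets intersect, so an `N` on either side matches anything. When
#' `max_mismatches > 0` and the oligo is a primer, the three 3'-terminal bases
#' must still match exactly (the extension-critical region); probes are exempt.
#'
#' @param template Template DNA string (IUPAC allowed).
#' @param oligo An [oligo()].
#' @param max_mismatches Maximum number of incompatible positions.
#' @param template_id Identifier recorded in the output.
#' @return A tibble of binding sites with 0-based half-open `start`/`end`
#'   on the forward strand, `strand` (`"+"`/`"-"`), `oligo_name` and
#'   `mismatches`, sorted by `start` then strand.
#' @export
find_binding_sites <- function(template, oligo, max_mismatches = 0L,
                               template_id = "template") {
  stopifnot(inherits(oligo, "oligo"), max_mismatches >= 0L)
  if (!nzchar(template)) return(empty_sites())
  template <- validate_iupac(template, what = paste0("template '", template_id, "'"))
  if (nchar(oligo$sequence) > nchar(template)) return(empty_sites())
  anchor <- oligo$role %in% c("forward_primer", "reverse_primer")
  fwd <- scan_one_strand(template, template_id, oligo$sequence, oligo$name,
                         "+", max_mismatches, anchor)
  rev <- scan_one_strand(template, template_id, reverse_complement(oligo$sequence),
                         oligo$name, "-", max_mismatches, anchor)
  out <- rbind(fwd, rev)
  out[order(out$start, out$strand), , drop = FALSE]
}

#' Predict PCR amplicons on a template
#'
#' Pairs every forward-strand primer site with every reverse-strand site of
#' the other primer downstream of it (both orientations, so predictions are
#' symmetric under reverse-complementing the template), keeping products up
#' to `max_len`. Amplicon length spans both primer footprints.
#'
#' @param template Template DNA string.
#' @param forward,reverse Primer [oligo()]s.
#' @param max_mismatches Per-primer mismatch allowance.
#' @param max_len Maximum product length in bp.
#' @param template_id Identifier recorded in the predictions.
#' @return A list of `"amplicon"` objects ordered by length then start. Each
#'   carries `template_id`, `forward_site`, `reverse_site`, `length`,
#'   `sequence` (forward strand) and an initially empty `probe_hits` table.
#' @export
predict_amplicons <- function(template, forward, reverse, max_mismatches = 0L,
                              max_len = 1000L, template_id = "template") {
  fall <- find_binding_sites(template, forward, max_mismatches, template_id)
  rall <- find_binding_sites(template, reverse, max_mismatches, template_id)
  out <- list()
  # a product forms whenever one primer's + site lies upstream of the other
  # primer's - site; on a reverse-complemented template the two primers swap
  # strands, so both orientations must be enumerated for strand symmetry
  pair_up <- function(plus, minus) {
    if (nrow(plus) == 0L || nrow(minus) == 0L) return()
    for (i in seq_len(nrow(plus))) {
      for (j in seq_len(nrow(minus))) {
        len <- minus$end[j] - plus$start[i]
        if (plus$start[i] < minus$start[j] && len <= max_len) {
          amp <- structure(list(
            template_id = template_id,
            forward_site = plus[i, ],
            reverse_site = minus[j, ],
            length = len,
            sequence = substr(template, plus$start[i] + 1L, minus$end[j]),
            probe_hits = empty_sites()
          ), class = "amplicon")
          out[[length(out) + 1L]] <<- amp
        }
      }
    }
  }
  pair_up(fall[fall$strand == "+", , drop = FALSE],
          rall[rall$strand == "-", , drop = FALSE])
  pair_up(rall[rall$strand == "+", , drop = FALSE],
          fall[fall$strand == "-", , drop = FALSE])
  ord <- order(vapply(out, `[[`, numeric(1), "length"),
               vapply(out, function(a) a$forward_site$start, numeric(1)))
  out[ord]
}

#' @export
print.amplicon <- function(x, ...) {
  cat(sprintf("<amplicon> %s:%d-%d (%d bp) %s/%s, %d probe hit(s)\n",
              x$template_id, x$forward_site$start, x$reverse_site$end, x$length,
              x$forward_site$oligo_name, x$reverse_site$oligo_name,
              nrow(x$probe_hits)))
  invisible(x)
}

#' Scan an amplicon for hydrolysis-probe binding sites
#'
#' Reports every probe match on either strand of the amplicon. Hits that
#' overlap a primer footprint are retained but flagged
#' (`in_primer_footprint`), since a probe competing with a primer for the
#' same bases is unlikely to report cleanly.
#'
#' @param amplicon An `"amplicon"` from [predict_amplicons()].
#' @param probes List of probe [oligo()]s; each must carry a fluorophore.
#' @param max_mismatches Mismatch allowance for probe binding.
#' @return The amplicon with `probe_hits` populated (template coordinates).
#' @export
probe_scan <- function(amplicon, probes, max_mismatches = 0L) {
  stopifnot(inherits(amplicon, "amplicon"))
  if (inherits(probes, "oligo")) probes <- list(probes)
  for (p in probes) {
    if (is.null(p$fluorophore)) {
      stop(sprintf("probe '%s' carries no fluorophore label", p$name), call. = FALSE)
    }
  }
  offset <- amplicon$forward_site$start
  flen <- amplicon$forward_site$end - amplicon$forward_site$start
  rlen <- amplicon$reverse_site$end - amplicon$reverse_site$start
  hits <- lapply(probes, function(p) {
    h <- find_binding_sites(amplicon$sequence, p, max_mismatches,
                            template_id = amplicon$template_id)
    if (nrow(h) > 0L) {
      h$in_primer_footprint <- h$start < flen | h$end > amplicon$length - rlen
      h$start <- h$start + offset
      h$end <- h$end + offset
    } else {
      h$in_primer_footprint <- logical(0)
    }
    h
  })
  amplicon$probe_hits <- do.call(rbind, hits)
  amplicon
}

#' Tabulate amplicons and probe hits for a set of templates
#'
#' Runs every primer pair of an assay configuration against every template and
#' reports one row per predicted amplicon and probe hit (rows with `NA`
#' amplicon columns mark template/pair combinations with no product).
#'
#' @param templates Named character vector or `Biostrings::DNAStringSet`.
#' @param config An [assay_config()].
#' @param max_mismatches Mismatch allowance for primers and probes.
#' @param max_len Maximum product length.
#' @return A tibble with columns `template_id`, `primer_pair`,
#'   `amplicon_start`, `amplicon_end`, `length`, `probe`, `probe_mismatches`,
#'   `strand`, in deterministic order.
#' @export
assay_specificity_report <- function(templates, config, max_mismatches = 0L,
                                     max_len = 1000L) {
  stopifnot(inherits(config, "assay_config"))
  if (methods::is(templates, "DNAStringSet")) {
    templates <- stats::setNames(as.character(templates), names(templates))
  }
  if (is.null(names(templates)) && length(templates) > 0L) {
    names(templates) <- paste0("template_", seq_along(templates))
  }
  rows <- list()
  add <- function(...) rows[[length(rows) + 1L]] <<- tibble::tibble(...)
  for (tid in names(templates)) {
    for (pair in config$pairs) {
      fwd <- config$panel[[pair$forward]]
      rev <- config$panel[[pair$reverse]]
      probes <- lapply(pair$probes, function(nm) config$panel[[nm]])
      amps <- predict_amplicons(templates[[tid]], fwd, rev, max_mismatches,
                                max_len, template_id = tid)
      if (length(probes) > 0L) {
        amps <- lapply(amps, probe_scan, probes = probes,
                       max_mismatches = max_mismatches)
      }
      if (length(amps) == 0L) {
        add(template_id = tid, primer_pair = pair$name,
            amplicon_start = NA_integer_, amplicon_end = NA_integer_,
            length = NA_integer_, probe = NA_character_,
            probe_mismatches = NA_integer_, strand = NA_character_)
        next
      }
      for (a in amps) {
        if (nrow(a$probe_hits) == 0L) {
          add(template_id = tid, primer_pair = pair$name,
              amplicon_start = a$forward_site$start,
              amplicon_end = a$reverse_site$end, length = a$length,
              probe = NA_character_, probe_mismatches = NA_integer_,
              strand = NA_character_)
        } else {
          for (k in seq_len(nrow(a$probe_hits))) {
            add(template_id = tid, primer_pair = pair$name,
                amplicon_start = a$forward_site$start,
                amplicon_end = a$reverse_site$end, length = a$length,
                probe = a$probe_hits$oligo_name[k],
                probe_mismatches = a$probe_hits$mismatches[k],
                strand = a$probe_hits$strand[k])
          }
        }
      }
    }
  }
  if (length(rows) == 0L) {
    return(tibble::tibble(template_id = character(), primer_pair = character(),
                          amplicon_start = integer(), amplicon_end = integer(),
                          length = integer(), probe = character(),
                          probe_mismatches = integer(), strand = character()))
  }
  do.call(rbind, rows)
}
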