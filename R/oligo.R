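#' Construct a primer or probe
#'
#' An oligo bundles an IUPAC sequence (5'->3') with its role in the assay and,
#' for hydrolysis probes, the fluorophore/quencher pair.
#'
#' @param name Short unique identifier (e.g. `"425F"`).
#' @param sequence IUPAC DNA string; lowercase accepted, `U` rejected.
#' @param role One of `"forward_primer"`, `"reverse_primer"`, `"probe"`.
#' @param fluorophore,quencher Optional label names (probes only, by
#'   convention).
#' @return An object of class `"oligo"`.
#' @examples
#' oligo("425F", "ACAAYACCAGAGGGGGTYGC", "forward_primer")
#' @export
oligo <- function(name, sequence, role = c("forward_primer", "reverse_primer", "probe"),
                  fluorophore = NULL, quencher = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  role <- match.arg(role)
  structure(
    list(
      name = name,
      sequence = validate_iupac(sequence, what = paste0("oligo '", name, "' sequence")),
      role = role,
      fluorophore = fluorophore,
      quencher = quencher
    ),
    class = "oligo"
  )
}

#' @export
print.oligo <- function(x, ...) {
  lab <- if (!is.null(x$fluorophore)) paste0(" [", x$fluorophore,
                                             if (!is.null(x$quencher)) paste0("/", x$quencher),
                                             "]") else ""
  cat(sprintf("<oligo> %s (%s%s): 5'-%s (%d nt)\n",
              x$name, x$role, lab, x$sequence, nchar(x$sequence)))
  invisible(x)
}

#' Melting-temperature parameters
#'
#' @param sodium_molar Monovalent cation concentration in mol/L. The default
#'   0.05 M reproduces the assay panel's published salt-adjusted values.
#' @param rounding Decimal places used when reporting Tm.
#' @return A list of class `"tm_params"`.
#' @export
tm_params <- function(sodium_molar = 0.05, rounding = 1L) {
  stopifnot(is.numeric(sodium_molar), length(sodium_molar) == 1L, sodium_molar > 0)
  structure(list(sodium_molar = sodium_molar, rounding = as.integer(rounding)),
            class = "tm_params")
}

# Commercial-style rounding: half away from zero. base::round() rounds half to
# even, which would mis-report values ending in .x5.
round_half_away <- function(x, digits = 1L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Salt-adjusted melting temperature of a non-degenerate oligo
#'
#' Long-oligo (>= 14 nt) salt-adjusted formula:
#' \deqn{Tm = 100.5 + 41 \cdot GC/N - 820/N + 16.6 \log_{10}[Na^+]}
#' with `N` the length and `GC` the G+C count. Shorter oligos fall outside this
#' formula's regime and are rejected.
#'
#' @param sequence Concrete ACGT string, length >= 14.
#' @param params A [tm_params()] object.
#' @param round Report rounded per `params$rounding` (default) or at full
#'   precision.
#' @return Tm in degrees Celsius.
#' @examples
#' tm_salt_adjusted("ACCGCCCTAGTTCTAACCGTAAA")  # 62.9
#' @export
tm_salt_adjusted <- function(sequence, params = tm_params(), round = TRUE) {
  s <- validate_iupac(sequence)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  if (any(!(chars %in% c("A", "C", "G", "T")))) {
    stop("tm_salt_adjusted() requires a non-degenerate ACGT sequence; use tm_range() for degenerate oligos",
         call. = FALSE)
  }
  n <- length(chars)
  if (n < 14L) {
    stop(sprintf("sequence length %d is below the long-oligo regime (>= 14 nt); short-oligo Tm is not supported", n),
         call. = FALSE)
  }
  gc <- sum(chars %in% c("G", "C"))
  tm <- 100.5 + 41 * gc / n - 820 / n + 16.6 * log10(params$sodium_molar)
  if (round) round_half_away(tm, params$rounding) else tm
}

#' Melting-temperature range of a (possibly degenerate) oligo
#'
#' Exhaustively expands the degenerate positions and reports the minimum and
#' maximum salt-adjusted Tm over all concrete sequences. For a non-degenerate
#' oligo the two bounds coincide.
#'
#' @param x An [oligo()] or an IUPAC DNA string.
#' @param params A [tm_params()] object.
#' @param cap Expansion cap forwarded to [expand_degenerate()].
#' @return A list of class `"tm_range"` with fields `tm_min` and `tm_max`.
#' @examples
#' tm_range("ACAAYACCAGAGGGGGTYGC")  # 60.5 - 64.6
#' @export
tm_range <- function(x, params = tm_params(), cap = 1024L) {
  seqs <- expand_degenerate(if (inherits(x, "oligo")) x$sequence else x, cap = cap)
  # full precision internally; round only when reporting
  tms <- vapply(seqs, tm_salt_adjusted, numeric(1), params = params, round = FALSE)
  structure(list(tm_min = min(tms), tm_max = max(tms)), class = "tm_range")
}

#' @export
print.tm_range <- function(x, ...) {
  cat(sprintf("Tm: %s degC\n", format(x)))
  invisible(x)
}

# displayed at reporting precision; the stored bounds keep full precision
#' @export
format.tm_range <- function(x, digits = 1L, ...) {
  lo <- round_half_away(x$tm_min, digits)
  hi <- round_half_away(x$tm_max, digits)
  if (lo == hi) format(lo) else paste0(format(lo), "-", format(hi))
}
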