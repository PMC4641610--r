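# IUPAC degenerate-base machinery shared by the oligo and in-silico PCR layers.
# Each code is a 4-bit mask over (A, C, G, T); two codes are compatible when
# their masks intersect, which is the matching rule used throughout.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  M = c("A", "C"), R = c("A", "G"), W = c("A", "T"),
  S = c("C", "G"), Y = c("C", "T"), K = c("G", "T"),
  V = c("A", "C", "G"), H = c("A", "C", "T"),
  D = c("A", "G", "T"), B = c("C", "G", "T"),
  N = c("A", "C", "G", "T")
)

IUPAC_CODES <- names(IUPAC_SETS)

# bit masks: A=1, C=2, G=4, T=8
IUPAC_MASK <- vapply(IUPAC_SETS, function(b) {
  sum(c(A = 1L, C = 2L, G = 4L, T = 8L)[b])
}, integer(1))

IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  M = "K", R = "Y", W = "W", S = "S", Y = "R", K = "M",
  V = "B", H = "D", D = "H", B = "V", N = "N"
)

#' Validate and normalise an IUPAC DNA sequence
#'
#' Uppercases the input and checks that every character is one of the 15 IUPAC
#' DNA codes. `U` is rejected: this is a DNA assay.
#'
#' @param sequence A single character string.
#' @param what Label used in error messages.
#' @return The validated, uppercased sequence.
#' @export
validate_iupac <- function(sequence, what = "sequence") {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence)) {
    stop(what, " must be a single character string", call. = FALSE)
  }
  if (nchar(sequence) == 0L) {
    stop(what, " must be non-empty", call. = FALSE)
  }
  s <- toupper(sequence)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  bad <- which(!(chars %in% IUPAC_CODES))
  if (length(bad) > 0L) {
    stop(sprintf("%s contains non-IUPAC character '%s' at position %d",
                 what, chars[bad[1]], bad[1]), call. = FALSE)
  }
  s
}

#' Reverse complement of an IUPAC DNA sequence
#'
#' IUPAC-aware: degenerate codes map to the complement of their base set
#' (e.g. `Y` -> `R`). Applying the function twice returns the input.
#'
#' @param sequence IUPAC DNA string (5'->3').
#' @return The reverse complement, 5'->3'.
#' @examples
#' reverse_complement("ACGT")   # palindrome
#' reverse_complement("Y")      # "R"
#' @export
reverse_complement <- function(sequence) {
  s <- validate_iupac(sequence)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  paste(rev(unname(IUPAC_COMPLEMENT[chars])), collapse = "")
}

#' Number of concrete sequences an IUPAC pattern matches
#'
#' @param sequence IUPAC DNA string.
#' @return Product of per-position code sizes.
#' @export
degeneracy <- function(sequence) {
  s <- validate_iupac(sequence)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  prod(vapply(IUPAC_SETS[chars], length, integer(1)))
}

#' Expand a degenerate sequence into all concrete ACGT sequences
#'
#' @param sequence IUPAC DNA string.
#' @param cap Maximum number of expansions permitted; the call is refused
#'   (with the offending count) when the pattern expands beyond it.
#' @return Character vector of all distinct ACGT sequences matched by the
#'   pattern, in lexicographic order.
#' @examples
#' expand_degenerate("AY")  # "AC" "AT"
#' @export
expand_degenerate <- function(sequence, cap = 1024L) {
  s <- validate_iupac(sequence)
  n_exp <- degeneracy(s)
  if (n_exp > cap) {
    stop(sprintf("sequence expands to %d concrete sequences, exceeding cap %d",
                 n_exp, cap), call. = FALSE)
  }
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  out <- ""
  for (ch in chars) {
    out <- as.vector(outer(out, IUPAC_SETS[[ch]], paste0))
  }
  sort(out)
}

#' Range of G+C counts over all degenerate expansions
#'
#' @param sequence IUPAC DNA string.
#' @return Integer vector `c(min, max)` of the G/C base count over all
#'   concrete expansions; the two are equal for non-degenerate input.
#' @export
gc_count_range <- function(sequence) {
  s <- validate_iupac(sequence)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  contrib <- vapply(IUPAC_SETS[chars], function(b) {
    gc <- b %in% c("G", "C")
    c(min = as.integer(all(gc)), max = as.integer(any(gc)))
  }, integer(2))
  c(min = sum(contrib["min", ]), max = sum(contrib["max", ]))
}

# TRUE when the base sets of two IUPAC codes intersect (vectorised).
iupac_compatible <- function(a, b) {
  bitwAnd(IUPAC_MASK[a], IUPAC_MASK[b]) > 0L
}
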