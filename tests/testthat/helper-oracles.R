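# Independent oracles, deliberately coded from scratch (no reuse of package
# internals) so implementation and oracle can disagree.

# -- brute-force IUPAC machinery ---------------------------------------------

oracle_sets <- list(
  A = "A", C = "C", G = "G", T = "T",
  M = c("A", "C"), R = c("A", "G"), W = c("A", "T"),
  S = c("C", "G"), Y = c("C", "T"), K = c("G", "T"),
  V = c("A", "C", "G"), H = c("A", "C", "T"),
  D = c("A", "G", "T"), B = c("C", "G", "T"),
  N = c("A", "C", "G", "T")
)

oracle_expand <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  out <- ""
  for (ch in chars) out <- as.vector(outer(out, oracle_sets[[ch]], paste0))
  sort(out)
}

# position-by-position scan of one strand; returns 0-based starts with the
# given mismatch budget
oracle_scan <- function(template, pattern, max_mm) {
  tpl <- strsplit(template, "")[[1]]
  pat <- strsplit(pattern, "")[[1]]
  k <- length(pat)
  hits <- list()
  for (s in seq_len(length(tpl) - k + 1L)) {
    mm <- 0L
    for (j in seq_len(k)) {
      a <- oracle_sets[[pat[j]]]
      b <- oracle_sets[[tpl[s + j - 1L]]]
      if (length(intersect(a, b)) == 0L) mm <- mm + 1L
    }
    if (mm <= max_mm) hits[[length(hits) + 1L]] <- c(start = s - 1L, mm = mm)
  }
  if (length(hits) == 0L) {
    return(data.frame(start = integer(), mm = integer()))
  }
  as.data.frame(do.call(rbind, hits))
}

oracle_revcomp <- function(seq) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", M = "K", R = "Y", W = "W",
            S = "S", Y = "R", K = "M", V = "B", H = "D", D = "H", B = "V",
            N = "N")
  paste(rev(comp[strsplit(seq, "")[[1]]]), collapse = "")
}

# -- brute-force rule engine --------------------------------------------------
# Direct transcription of the four printed rules, evaluated independently of
# the package's decision-tree ordering:
#   1) control Cq in (0, 40]; 2) target Cq in (0, 40];
#   3) 0 < control - target <= 7; 4) not both targets in (0, 40].
oracle_interpret <- function(control, fam, hex, max_cq = 40,
                             dmin = 0, dmax = 7) {
  inw <- function(x) !is.na(x) && x > 0 && x <= max_cq
  if (!inw(control)) return("NO_DNA")
  fam_on <- inw(fam)
  hex_on <- inw(hex)
  if (fam_on && hex_on) return("INCONCLUSIVE")          # rule 4 violated
  if (!fam_on && !hex_on) return("NEGATIVE_NON_TARGET") # rule 2 unmet, control fine
  target <- if (fam_on) fam else hex
  d <- control - target
  if (d > dmin && d <= dmax) {
    if (fam_on) "H_ARMIGERA" else "H_ZEA"
  } else {
    "INCONCLUSIVE"                                      # rule 3 violated
  }
}

# -- shared fixtures ----------------------------------------------------------

logistic_trace <- function(plateau, midpoint, k = 1, cycles = 40,
                           drift = 0, offset = 0) {
  cyc <- seq_len(cycles)
  plateau / (1 + exp(-k * (cyc - midpoint))) + offset + drift * cyc
}

test_panel <- function() default_assay_config()$panel
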