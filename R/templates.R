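# Synthetic template sequences for exercising the in-silico PCR layer
# offline. These are constructed stand-ins, NOT the deposited GenBank
# sequences: each carries the real primer footprints and probe binding sites
# embedded in arbitrary filler, arranged to reproduce the assay's amplicon
# geometry (68 bp for the 18S control pair; 140-143 bp across the ITS2
# haplotype set, with the H. armigera probe's C/T polymorphism at its 10th
# base and mutually exclusive probe sites between the species).

# fixed arbitrary filler; no primer/probe motifs
SYN_FILLER <- paste0(
  "ATCTGAACTTCAGTCATAGCTAGCTTAGAAGCATCATGATCTTGAGTTCAAACCACTTGT",
  "AGTCCTTAGAATGAAGTTCACTATCAAGATTCAGAATCGTACTTAAGCTAGTCAATTCGA",
  "TTGACCATTCAGAAGTCTAAGGTTCAGATCACTTAGGATCTAAGTTGAAGTCATTCAGGA"
)

syn_fill <- function(n, from = 1L) substr(SYN_FILLER, from, from + n - 1L)

#' Synthetic assay templates
#'
#' A small set of synthetic template sequences that reproduce the assay's
#' amplicon geometry for offline in-silico PCR testing: one 18S-like control
#' template yielding a 68 bp product with the control probe site, two
#' H. armigera-like ITS2 haplotypes (140/141 bp products; C and T variants at
#' the armigera probe's degenerate position) and four H. zea-like ITS2
#' haplotypes (140-143 bp products carrying the zea probe site). These are
#' constructed sequences, not database accessions; filler between the
#' functional sites is arbitrary.
#'
#' @return Named character vector of template sequences.
#' @examples
#' tpl <- synthetic_templates()
#' names(tpl)
#' @export
synthetic_templates <- function() {
  f18 <- "ACCGCCCTAGTTCTAACCGTAAA"                    # 18S forward primer
  p18 <- "TGTCATCTAGCGATCCGCCGA"                      # 18S probe site
  r18rc <- reverse_complement("CCGCCGAGCCATTGTAGTAA") # 18S reverse primer site
  f425 <- function(y1, y2) sprintf("ACAA%sACCAGAGGGGGT%sGC", y1, y2)
  r568rc <- reverse_complement("CGTCGATGCGCTCTTCGG")
  harm <- function(y) sprintf("TGTCGTCCG%sTTTAGCGTGAGAC", y)  # armigera probe
  zea <- "CAACGCCATTAGTAGGCGGACTC"                            # zea probe

  pad5 <- syn_fill(15L)
  pad3 <- syn_fill(15L, from = 60L)
  # ITS2-like interior: filler + probe site + filler, interior length =
  # total - 20 (forward) - 18 (reverse)
  its2 <- function(fwd, probe, total) {
    interior <- total - nchar(fwd) - nchar(r568rc)
    left <- 30L
    right <- interior - left - nchar(probe)
    paste0(pad5, fwd, syn_fill(left, from = 25L), probe,
           syn_fill(right, from = 95L), r568rc, pad3)
  }
  c(
    syn_18S = paste0(pad5, f18, p18, "ATCG", r18rc, pad3),
    syn_armigera_h1 = its2(f425("C", "C"), harm("C"), 140L),
    syn_armigera_h2 = its2(f425("C", "T"), harm("T"), 141L),
    syn_zea_h1 = its2(f425("T", "C"), zea, 140L),
    syn_zea_h2 = its2(f425("T", "T"), zea, 141L),
    syn_zea_h3 = its2(f425("C", "C"), zea, 142L),
    syn_zea_h4 = its2(f425("C", "T"), zea, 143L)
  )
}
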