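# binding-site search, amplicon prediction, probe scanning

fwd425 <- function() oligo("425F", "ACAAYACCAGAGGGGGTYGC", "forward_primer")
rev568 <- function() oligo("568R", "CGTCGATGCGCTCTTCGG", "reverse_primer")

test_that("an oligo finds itself and its reverse complement", {
  o <- fwd425()
  hits <- find_binding_sites(expand_degenerate(o$sequence)[1], o)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$strand, "+")
  expect_equal(hits$mismatches, 0)
  rc_hits <- find_binding_sites(reverse_complement(o$sequence), o)
  expect_equal(rc_hits$strand, "-")
  expect_equal(rc_hits$start, 0)
})

test_that("degenerate positions match any compatible base", {
  # Y matches C and T at both degenerate positions of the forward ITS2 primer
  hits <- find_binding_sites("ACAACACCAGAGGGGGTTGC", fwd425())
  expect_equal(nrow(hits), 1)
  expect_equal(hits$mismatches, 0)
  # G at a Y position is a mismatch
  expect_equal(nrow(find_binding_sites("ACAAGACCAGAGGGGGTTGC", fwd425())), 0)
  expect_equal(find_binding_sites("ACAAGACCAGAGGGGGTTGC", fwd425(),
                                  max_mismatches = 1)$mismatches, 1)
})

test_that("binding sites agree with the brute-force IUPAC scan", {
  set.seed(11)
  o <- fwd425()
  for (i in 1:12) {
    mm <- sample(0:2, 1)
    tpl <- paste(sample(c("A", "C", "G", "T", "N", "Y"), 180, replace = TRUE,
                        prob = c(.24, .24, .24, .24, .02, .02)), collapse = "")
    # embed a near-site to make hits likely
    site <- expand_degenerate(o$sequence)[sample(4, 1)]
    substr(tpl, 50, 49 + nchar(site)) <- site
    got <- find_binding_sites(tpl, oligo("x", o$sequence, "probe"), mm)
    want_f <- oracle_scan(tpl, o$sequence, mm)
    want_r <- oracle_scan(tpl, oracle_revcomp(o$sequence), mm)
    expect_setequal(got$start[got$strand == "+"], want_f$start)
    expect_setequal(got$start[got$strand == "-"], want_r$start)
  }
})

test_that("primer 3'-terminal bases must match exactly when mismatches allowed", {
  o <- rev568()
  tpl_plus <- o$sequence
  substr(tpl_plus, nchar(tpl_plus), nchar(tpl_plus)) <- "A"  # break 3' end
  expect_equal(nrow(find_binding_sites(tpl_plus, o, max_mismatches = 1)[
    find_binding_sites(tpl_plus, o, max_mismatches = 1)$strand == "+", ]), 0)
  tpl_mid <- o$sequence
  substr(tpl_mid, 5, 5) <- "A"  # internal mismatch is tolerated
  hits <- find_binding_sites(tpl_mid, o, max_mismatches = 1)
  expect_true(any(hits$strand == "+" & hits$mismatches == 1))
  # probes are exempt from the 3' anchor
  p <- oligo("p", o$sequence, "probe", fluorophore = "FAM")
  expect_true(any(find_binding_sites(tpl_plus, p, max_mismatches = 1)$strand == "+"))
})

test_that("a constructed template yields exactly one amplicon of known size", {
  o_f <- fwd425(); o_r <- rev568()
  fconc <- expand_degenerate(o_f$sequence)[1]
  tpl <- paste0(fconc, strrep("AT", 11), reverse_complement(o_r$sequence))
  amps <- predict_amplicons(tpl, o_f, o_r)
  expect_length(amps, 1)
  expect_equal(amps[[1]]$length, 60)
  expect_equal(amps[[1]]$length, nchar(amps[[1]]$sequence))
  expect_equal(amps[[1]]$forward_site$start, 0)
  # no reverse site -> no product
  expect_length(predict_amplicons(paste0(fconc, strrep("AT", 30)), o_f, o_r), 0)
})

test_that("amplicon length multiset is strand symmetric", {
  tpl <- synthetic_templates()
  cfg <- default_assay_config()
  for (nm in c("syn_18S", "syn_armigera_h1", "syn_zea_h4")) {
    pair <- if (nm == "syn_18S") cfg$pairs[[1]] else cfg$pairs[[2]]
    a1 <- predict_amplicons(tpl[[nm]], cfg$panel[[pair$forward]],
                            cfg$panel[[pair$reverse]])
    a2 <- predict_amplicons(reverse_complement(tpl[[nm]]),
                            cfg$panel[[pair$forward]], cfg$panel[[pair$reverse]])
    expect_equal(sort(sapply(a1, `[[`, "length")),
                 sort(sapply(a2, `[[`, "length")), info = nm)
  }
})

test_that("amplicon ends are compatible with the primer pair", {
  cfg <- default_assay_config()
  tpl <- synthetic_templates()
  amp <- predict_amplicons(tpl[["syn_armigera_h1"]], cfg$panel[["425F"]],
                           cfg$panel[["568R"]], template_id = "syn_armigera_h1")[[1]]
  fwd_part <- substr(amp$sequence, 1, nchar(cfg$panel[["425F"]]$sequence))
  expect_equal(nrow(oracle_scan(fwd_part, cfg$panel[["425F"]]$sequence, 0)), 1)
  rc_rev <- reverse_complement(cfg$panel[["568R"]]$sequence)
  expect_equal(substr(amp$sequence, amp$length - nchar(rc_rev) + 1, amp$length),
               rc_rev)
})

test_that("raising the mismatch allowance never removes a site", {
  set.seed(23)
  o <- oligo("p", "TGTCGTCCGYTTTAGCGTGAGAC", "probe", fluorophore = "FAM")
  for (i in 1:8) {
    tpl <- paste(sample(c("A", "C", "G", "T"), 150, replace = TRUE), collapse = "")
    prev <- NULL
    for (mm in 0:3) {
      cur <- find_binding_sites(tpl, o, mm)
      key <- paste(cur$start, cur$strand)
      if (!is.null(prev)) expect_true(all(prev %in% key))
      prev <- key
    }
  }
})

test_that("probe scanning reports hits, absences and primer-footprint overlap", {
  cfg <- default_assay_config()
  tpl <- synthetic_templates()
  probes <- list(cfg$panel[["QP-Harm-ITS2-P8"]], cfg$panel[["RT-ITS-zea"]])
  amp_arm <- predict_amplicons(tpl[["syn_armigera_h1"]], cfg$panel[["425F"]],
                               cfg$panel[["568R"]])[[1]]
  amp_arm <- probe_scan(amp_arm, probes)
  expect_equal(amp_arm$probe_hits$oligo_name, "QP-Harm-ITS2-P8")
  expect_equal(amp_arm$probe_hits$mismatches, 0)
  expect_false(any(amp_arm$probe_hits$in_primer_footprint))

  amp_zea <- predict_amplicons(tpl[["syn_zea_h2"]], cfg$panel[["425F"]],
                               cfg$panel[["568R"]])[[1]]
  amp_zea <- probe_scan(amp_zea, probes)
  expect_equal(amp_zea$probe_hits$oligo_name, "RT-ITS-zea")

  # probe overlapping the forward primer footprint is reported but flagged
  o_f <- fwd425(); o_r <- rev568()
  fconc <- expand_degenerate(o_f$sequence)[1]
  tpl2 <- paste0(fconc, strrep("CAAT", 10), reverse_complement(o_r$sequence))
  amp2 <- predict_amplicons(tpl2, o_f, o_r)[[1]]
  edge_probe <- oligo("edge", substr(tpl2, 11, 34), "probe", fluorophore = "HEX")
  amp2 <- probe_scan(amp2, list(edge_probe))
  expect_true(all(amp2$probe_hits$in_primer_footprint[amp2$probe_hits$oligo_name == "edge"]))

  expect_error(probe_scan(amp2, list(oligo("nofluor", "ACGTACGTACGT", "probe"))),
               "fluorophore")
})

test_that("specificity report covers every template/pair with stable shape", {
  cfg <- default_assay_config()
  expect_equal(nrow(assay_specificity_report(character(0), cfg)), 0)
  rep <- assay_specificity_report(synthetic_templates(), cfg)
  its2 <- rep[rep$primer_pair == "ITS2" & !is.na(rep$length), ]
  expect_setequal(its2$length[grepl("zea", its2$template_id)] |> unique(),
                  c(140, 141, 142, 143))
  expect_equal(unique(rep$length[rep$primer_pair == "18S" & !is.na(rep$length)]), 68)
  # species-specific probes only ever hit their own species' templates
  expect_false(any(its2$probe == "RT-ITS-zea" & grepl("armigera", its2$template_id),
                   na.rm = TRUE))
  expect_false(any(its2$probe == "QP-Harm-ITS2-P8" & grepl("zea", its2$template_id),
                   na.rm = TRUE))
})
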