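mitoModel <- defaultMitoModel()

fixtureAnnotations <- function() {
  path <- tempfile(fileext = ".tsv")
  writeLines(paste(c(
    "Entry\tLength\tSubcellular location [CC]\tTransmembrane\tTopological domain",
    "M1\t300\tMitochondrion matrix\t\t",
    "M2\t250\tMitochondrion inner membrane; Mitochondrion outer membrane\t\t",
    "M3\t180\t\t\t",
    paste0("M4\t150\tMitochondrion inner membrane\t",
           "TRANSMEM 40..60; /note=\"Helical\"\t",
           "TOPO_DOM 1..39; /note=\"Matrix side\""),
    "M5\t120\tCytoplasm Note=also nuclear\t\t",
    "M6\t200\tMitochondrion intermembrane space\t\t"),
    collapse = "\n"), path)
  readAnnotations(path, mitoModel)
}

test_that("auto-selection keeps unequivocal soluble and orientable membrane proteins", {
  ann <- fixtureAnnotations()
  cand <- autoSelectCandidates(ann, mitoModel)
  # hand-derived expectation from the selection rules:
  # M1 matrix LM, M4 oriented IMM LM (matrix then IMS), M6 IMS LM;
  # M2 equivocal, M3 unannotated, M5 has a Note= qualifier
  expect_setequal(unique(cand$accession), c("M1", "M4", "M6"))
  expect_equal(cand$compartment[cand$accession == "M1"], "matrix")
  expect_equal(cand[cand$accession == "M4", c("start", "end")],
               data.frame(start = c(1L, 61L), end = c(39L, 150L)),
               ignore_attr = TRUE)
  expect_equal(cand$compartment[cand$accession == "M4"], c("matrix", "IMS"))
  excl <- attr(cand, "excluded")
  expect_setequal(excl$accession, c("M2", "M3", "M5"))
})

test_that("marker locales resolve per region with membrane gaps", {
  mk <- makeMarkers(c("L1", "L2", "L2"), c(1L, 1L, 61L),
                    c(100L, 39L, 150L), c("matrix", "matrix", "IMS"))
  expect_equal(markerLocale(mk, "L1", 50), "matrix")
  expect_equal(markerLocale(mk, "L2", 10), "matrix")
  expect_equal(markerLocale(mk, "L2", 100), "IMS")
  expect_equal(markerLocale(mk, "L2", 45), "membrane")
  expect_true(is.na(markerLocale(mk, "L9", 1)))
  expect_error(makeMarkers("L1", 1, 50, "IMM"), "aqueous")
})

test_that("validation removes every candidate touching a contradiction", {
  mk <- makeMarkers(c("L1", "L2", "L3", "L4"), 1L, 200L,
                    c("matrix", "matrix", "IMS", "IMS"))
  xl <- CrossLinkSet(data.frame(
    protein_a = c("L1", "L3", "L2"), residue_a = c(5L, 9L, 30L),
    protein_b = c("L2", "L4", "L3"), residue_b = c(8L, 14L, 40L)))
  res <- validateCandidates(mk, xl, mitoModel)
  rep <- res$report
  expect_equal(rep@n_lm_links, 3L)
  expect_equal(nrow(rep@contradictions), 1L)  # the injected matrix-IMS link
  expect_equal(rep@contradictions$locale_a, "matrix")
  expect_equal(rep@contradictions$locale_b, "IMS")
  expect_setequal(rep@removed, c("L2", "L3"))  # both endpoints suspect
  expect_setequal(unique(res$markers$accession), c("L1", "L4"))
  expect_equal(rep@consistent_fraction, 100 * 2 / 3)
})

test_that("validation is idempotent and clean sets stay intact", {
  mk <- makeMarkers(c("L1", "L2"), 1L, 100L, c("IMS", "IMS"))
  xl <- CrossLinkSet(data.frame(
    protein_a = "L1", residue_a = 5L, protein_b = "L2", residue_b = 8L))
  res1 <- validateCandidates(mk, xl, mitoModel)
  expect_equal(res1$report@consistent_fraction, 100)
  expect_equal(res1$report@removed, character())
  res2 <- validateCandidates(res1$markers, xl, mitoModel)
  expect_identical(res2$markers, res1$markers)
  expect_equal(res2$report@consistent_fraction, 100)

  # no marker-marker links at all -> fraction 100, all retained
  none <- validateCandidates(mk, CrossLinkSet(data.frame(
    protein_a = "X", residue_a = 1L, protein_b = "Y", residue_b = 2L)),
    mitoModel)
  expect_equal(none$report@n_lm_links, 0L)
  expect_equal(none$report@consistent_fraction, 100)
})

test_that("removing markers never creates new contradictions", {
  set.seed(41)
  org <- generateOrganelle(40, 0.6, 0.2, seed = 41)
  sim <- simulateCrossLinks(org, 600, 0.05, seed = 41)
  mk <- organelleMarkers(org)
  full <- validateCandidates(mk, sim$links, org@model)
  n_full <- nrow(full$report@contradictions)
  for (drop in sample(unique(mk$accession), 5)) {
    sub <- mk[mk$accession != drop, ]
    n_sub <- nrow(validateCandidates(sub, sim$links,
                                     org@model)$report@contradictions)
    expect_lte(n_sub, n_full)
  }
})

test_that("links through membrane-embedded marker residues are skipped", {
  mk <- makeMarkers(c("L1", "L1", "L2"), c(1L, 61L, 1L), c(39L, 150L, 90L),
                    c("matrix", "IMS", "matrix"))
  xl <- CrossLinkSet(data.frame(
    protein_a = "L1", residue_a = 50L,  # inside the 40..60 TM gap
    protein_b = "L2", residue_b = 7L))
  expect_warning(res <- validateCandidates(mk, xl, mitoModel),
                 "membrane-embedded")
  expect_equal(res$report@n_lm_links, 0L)
  expect_equal(res$report@n_skipped, 1L)
})

test_that("manual markers are re-validated before acceptance", {
  mk <- makeMarkers(c("L1", "L2"), 1L, 100L, c("matrix", "matrix"))
  xl <- CrossLinkSet(data.frame(
    protein_a = c("L1", "L1"), residue_a = c(5L, 9L),
    protein_b = c("L2", "BAD"), residue_b = c(8L, 14L)))
  val <- validateCandidates(mk, xl, mitoModel)$markers

  # a manual marker with no cross-links is accepted
  lone <- makeMarkers("L9", 1L, 80L, "IMS", source = "manual")
  aug <- augmentCandidates(val, lone, xl, mitoModel)
  expect_true("L9" %in% aug$accession)
  expect_length(attr(aug, "rejected"), 0L)

  # a manual marker contradicting the links is rejected with its conflicts
  bad <- makeMarkers("BAD", 1L, 80L, "IMS", source = "manual")
  aug2 <- augmentCandidates(val, bad, xl, mitoModel)
  expect_false("BAD" %in% aug2$accession)
  expect_equal(names(attr(aug2, "rejected")), "BAD")
  expect_equal(nrow(attr(aug2, "rejected")$BAD), 1L)
})

test_that("mislabeled markers are removed at a rate rising with their degree", {
  # parameter-recovery property: deliberately mislabel markers; those with
  # more marker-marker cross-links are caught more often
  set.seed(43)
  org <- generateOrganelle(60, 0.8, 0, seed = 43)
  sim <- simulateCrossLinks(org, 1500, 0, seed = 43)
  mk <- organelleMarkers(org)
  lk <- as.data.frame(sim$links)
  deg <- table(c(lk$protein_a, lk$protein_b))
  caught <- data.frame(deg = integer(), caught = logical())
  aq <- aqueousCompartments(org@model)
  for (acc in sample(unique(mk$accession), 20)) {
    wrong <- mk
    truth <- wrong$compartment[wrong$accession == acc][1]
    wrong$compartment[wrong$accession == acc] <-
      setdiff(aq, truth)[1]
    res <- validateCandidates(wrong, sim$links, org@model)
    d <- suppressWarnings(as.integer(deg[acc]))
    caught <- rbind(caught, data.frame(
      deg = if (is.na(d)) 0L else d,
      caught = acc %in% res$report@removed))
  }
  high <- caught$caught[caught$deg >= stats::median(caught$deg)]
  low <- caught$caught[caught$deg < stats::median(caught$deg)]
  expect_gte(mean(high), mean(low))
  expect_true(any(caught$caught))
})
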