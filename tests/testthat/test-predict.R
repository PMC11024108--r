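mito <- defaultMitoModel()

test_that("votes are one per unique residue pair to a marker", {
  mk <- makeMarkers(c("LM1", "LM2", "LM2"), c(1L, 1L, 61L),
                    c(100L, 39L, 150L), c("IMS", "matrix", "IMS"))
  xl <- CrossLinkSet(data.frame(
    protein_a = c("T", "T", "LM2", "T", "X"),
    residue_a = c(10L, 20L, 50L, 30L, 1L),
    protein_b = c("LM1", "LM2", "T", "X", "Y"),
    residue_b = c(5L, 70L, 40L, 2L, 3L)))
  v <- collectVotes("T", xl, mk, mito)
  # LM1 residue 5 -> IMS; LM2 residue 70 -> IMS; LM2 residue 50 is
  # TM-embedded and skipped; X is not a marker
  expect_equal(nrow(v), 2L)
  expect_setequal(v$locale, "IMS")
  expect_equal(attr(v, "n_skipped"), 1L)
  expect_equal(nrow(collectVotes("Z", xl, mk, mito)), 0L)
})

test_that("a soluble target with agreeing votes is unambiguous and novel", {
  # four votes, all IMS, no prior annotation
  votes <- data.frame(target = "T", target_residue = c(10L, 20L, 30L, 40L),
                      lm = c("L1", "L2", "L3", "L3"),
                      lm_residue = c(1L, 2L, 3L, 9L),
                      locale = "IMS")
  p <- predictTarget(solubleTopology("T", 200), votes, NA_character_, mito)
  expect_equal(nrow(p), 1L)
  expect_equal(p$supported, "IMS")
  expect_equal(p$status, "unambiguous")
  expect_equal(p$classification, "novel")
  expect_equal(p$n_votes, 4L)
  expect_equal(p$n_supporting_lms, 3L)
  expect_equal(c(p$region_start, p$region_end), c(1L, 200L))
})

test_that("classification confirms or contradicts the prior annotation", {
  votes <- data.frame(target = "T", target_residue = 10L, lm = "L1",
                      lm_residue = 1L, locale = "matrix")
  top <- solubleTopology("T", 100)
  expect_equal(predictTarget(top, votes, "matrix", mito)$classification,
               "confirms")
  # matrix votes against an OMM prior: a revision
  expect_equal(predictTarget(top, votes, "OMM", mito)$classification,
               "contradicts")
  expect_equal(predictTarget(top, votes, "IMS", mito)$classification,
               "contradicts")
})

test_that("disagreeing votes make the prediction ambiguous", {
  votes <- data.frame(target = "T", target_residue = c(10L, 20L),
                      lm = c("L1", "L2"), lm_residue = c(1L, 2L),
                      locale = c("matrix", "IMS"))
  p <- predictTarget(solubleTopology("T", 100), votes, NA_character_, mito)
  expect_equal(p$status, "ambiguous")
  expect_equal(p$supported, "IMS;matrix")
  expect_true(is.na(p$classification))
})

test_that("an unannotated cytosol-only target is noted membrane-associated", {
  votes <- data.frame(target = "T", target_residue = c(5L, 9L),
                      lm = c("L1", "L2"), lm_residue = c(1L, 2L),
                      locale = "cytosol")
  p <- predictTarget(solubleTopology("T", 150), votes, NA_character_, mito)
  expect_equal(p$classification, "novel")
  expect_match(p$note, "membrane-associated")
  # with a prior, the same votes just confirm
  p2 <- predictTarget(solubleTopology("T", 150), votes, "cytosol", mito)
  expect_true(is.na(p2$note))
})

test_that("membrane targets are predicted per region and completed by topology", {
  # 2-TM protein, votes only on the C-terminal region (IMS):
  # even parity puts the N-terminus in the IMS as well
  top <- buildRegions("T", 120,
                      annotated = data.frame(start = c(30, 70),
                                             end = c(50, 90)))
  votes <- data.frame(target = "T", target_residue = c(100L, 110L),
                      lm = c("L1", "L2"), lm_residue = c(1L, 2L),
                      locale = "IMS")
  p <- predictTarget(top, votes, "IMM", mito)
  expect_equal(nrow(p), 3L)
  vote_row <- p[p$basis == "votes", ]
  expect_equal(c(vote_row$region_start, vote_row$region_end), c(91L, 120L))
  inferred <- p[p$basis == "topology", ]
  expect_equal(inferred$supported[order(inferred$region_start)],
               c("IMS", "matrix"))
  expect_equal(unique(p$classification), "confirms")

  # votes on TM-embedded residues are excluded with a warning
  votes_tm <- rbind(votes, data.frame(target = "T", target_residue = 40L,
                                      lm = "L3", lm_residue = 3L,
                                      locale = "matrix"))
  expect_warning(p2 <- predictTarget(top, votes_tm, "IMM", mito),
                 "TM-embedded")
  expect_equal(nrow(p2), 3L)
})

test_that("the full pipeline recovers a noise-free simulated organelle", {
  org <- generateOrganelle(120, 0.3, 0.3, seed = 71)
  sim <- simulateCrossLinks(org, 1800, 0, seed = 71)
  res <- runClasp(sim$links, organelleMarkers(org),
                  annotations = organelleAnnotations(org))
  s <- claspSummary(res)
  expect_equal(s$pct_unambiguous, 100)
  expect_equal(s$marker_consistency_pct, 100)
  acc <- predictionAccuracy(res, org)
  expect_equal(acc$accuracy_pct, 100)
  # votes only ever cite validated markers
  expect_true(all(res@votes$lm %in% res@markers$accession))
  # every vote's target residue lies inside its predict region
  for (i in sample(nrow(res@predictions),
                   min(25, nrow(res@predictions)))) {
    p <- res@predictions[i, ]
    if (p$basis != "votes") next
    v <- res@votes[res@votes$target == p$accession, ]
    v <- v[v$target_residue >= p$region_start &
           v$target_residue <= p$region_end, ]
    expect_gte(nrow(v), 1L)
  }
  expect_error(runClasp(CrossLinkSet(data.frame(
    protein_a = character(), residue_a = integer(),
    protein_b = character(), residue_b = integer())),
    organelleMarkers(org)), "empty")
})

test_that("inference is deterministic and marker addition only adds votes", {
  org <- generateOrganelle(60, 0.3, 0.2, seed = 73)
  sim <- simulateCrossLinks(org, 700, 0, seed = 73)
  mk <- organelleMarkers(org)
  ann <- organelleAnnotations(org)
  r1 <- runClasp(sim$links, mk, annotations = ann)
  r2 <- runClasp(sim$links, mk, annotations = ann)
  expect_identical(predictions(r1), predictions(r2))

  # dropping one marker can only remove votes, never add
  drop <- unique(mk$accession)[1]
  r3 <- runClasp(sim$links, mk[mk$accession != drop, ], annotations = ann)
  expect_lte(nrow(r3@votes), nrow(r1@votes))
})

test_that("run comparison reports unambiguous overlap agreement", {
  org <- generateOrganelle(80, 0.3, 0.2, seed = 79)
  mk <- organelleMarkers(org)
  ann <- organelleAnnotations(org)
  simA <- simulateCrossLinks(org, 900, 0, seed = 80)
  simB <- simulateCrossLinks(org, 900, 0, seed = 81)
  ra <- runClasp(simA$links, mk, annotations = ann)
  rb <- runClasp(simB$links, mk, annotations = ann)

  same <- compareRuns(ra, ra)
  expect_equal(same$pct_agreement, 100)
  expect_equal(same$n_overlap,
               length(unique(predictions(ra)$accession[
                 predictions(ra)$basis == "votes"])))

  cmp <- compareRuns(ra, rb)
  # hand scan over the raw prediction tables
  handSig <- function(res) {
    df <- predictions(res)
    df <- df[df$basis == "votes", ]
    out <- list()
    for (accn in unique(df$accession)) {
      rows <- df[df$accession == accn, ]
      if (all(rows$status == "unambiguous"))
        out[[accn]] <- sort(unique(rows$supported))
    }
    out
  }
  sa <- handSig(ra); sb <- handSig(rb)
  common <- intersect(names(sa), names(sb))
  hand <- sum(vapply(common, function(a) identical(sa[[a]], sb[[a]]),
                     logical(1L)))
  expect_equal(cmp$n_overlap, length(common))
  expect_equal(cmp$pct_agreement, 100 * hand / length(common))
  # same ground truth, different sampling: high but not necessarily perfect
  # agreement, since different soluble regions of membrane proteins may
  # receive votes in each run
  expect_gt(cmp$pct_agreement, 90)

  # disjoint accession sets -> empty overlap
  pb <- predictions(rb)
  pb$accession <- paste0("OTHER_", pb$accession)
  expect_equal(compareRuns(predictions(ra), pb)$n_overlap, 0L)
})
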