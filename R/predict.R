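#' Collect marker votes for a target protein
#'
#' One vote per unique cross-linked residue pair between the target and a
#' validated marker; the vote's locale is the aqueous compartment of the
#' marker residue. Links through membrane-embedded or unresolved marker
#' residues carry no spatial information and are skipped (tallied in the
#' `"n_skipped"` attribute).
#'
#' @param target target accession.
#' @param crosslinks a [CrossLinkSet-class].
#' @param markers validated marker data.frame.
#' @param model a [CompartmentModel-class].
#' @return data.frame `target`, `target_residue`, `lm`, `lm_residue`,
#'   `locale`.
#' @export
collectVotes <- function(target, crosslinks, markers,
                         model = defaultMitoModel()) {
  lk <- as.data.frame(crosslinks)
  lmset <- unique(markers$accession)
  a_side <- lk$protein_a == target & lk$protein_b %in% lmset &
    lk$protein_b != target
  b_side <- lk$protein_b == target & lk$protein_a %in% lmset &
    lk$protein_a != target
  votes <- rbind(
    data.frame(target = rep(target, sum(a_side)),
               target_residue = lk$residue_a[a_side],
               lm = lk$protein_b[a_side], lm_residue = lk$residue_b[a_side]),
    data.frame(target = rep(target, sum(b_side)),
               target_residue = lk$residue_b[b_side],
               lm = lk$protein_a[b_side], lm_residue = lk$residue_a[b_side]))
  if (!nrow(votes)) {
    votes$locale <- character()
    attr(votes, "n_skipped") <- 0L
    return(votes)
  }
  votes$locale <- mapply(function(p, r) markerLocale(markers, p, r),
                         votes$lm, votes$lm_residue, USE.NAMES = FALSE)
  drop <- is.na(votes$locale) | votes$locale == "membrane"
  out <- votes[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_skipped") <- sum(drop)
  out
}

voteRegion <- function(sol, residue) {
  hit <- which(sol$start <= residue & sol$end >= residue)
  if (length(hit)) sol$region[hit[1L]] else NA_integer_
}

emptyPredictions <- function() {
  data.frame(accession = character(), region_start = integer(),
             region_end = integer(), supported = character(),
             status = character(), basis = character(),
             classification = character(), n_votes = integer(),
             n_supporting_lms = integer(), supporting_lms = character(),
             note = character(), stringsAsFactors = FALSE)
}

#' Predict the localization of one target from its votes
#'
#' Soluble targets get one prediction over the whole protein; membrane
#' targets get votes grouped per soluble region, each region predicted
#' separately, after which side alternation ([orientTopology()]) completes
#' regions without votes of their own (reported with basis `"topology"`).
#' A prediction is unambiguous when all its votes name the same compartment.
#' Against the prior annotation it `confirms` (same compartment/membrane),
#' `contradicts` (different), or is `novel` (no prior). A soluble target
#' supported only by the outermost aqueous compartment and lacking a prior
#' is additionally noted as membrane-associated (bound to the outer
#' membrane's cytosolic face rather than imported).
#'
#' @param topology the target's [Topology-class] (use [solubleTopology()]
#'   for non-membrane targets).
#' @param votes vote data.frame from [collectVotes()]; votes on residues
#'   inside TM segments are excluded with a warning.
#' @param prior normalized prior compartment (aqueous or membrane name) or
#'   `NA`.
#' @param model a [CompartmentModel-class].
#' @return data.frame of per-region predictions (possibly several rows for
#'   membrane targets).
#' @export
predictTarget <- function(topology, votes, prior = NA_character_,
                          model = defaultMitoModel()) {
  if (!nrow(votes)) return(emptyPredictions())
  acc <- topology@accession
  loc_t <- residueLocale(topology, votes$target_residue)
  in_tm <- !is.na(loc_t) & loc_t == "membrane"
  if (any(in_tm)) {
    warning(sum(in_tm), " vote(s) on TM-embedded residues of ", acc,
            " excluded")
    votes <- votes[!in_tm, , drop = FALSE]
  }
  if (!nrow(votes)) return(emptyPredictions())
  sol <- solubleRegions(topology)
  votes$region <- vapply(votes$target_residue,
                         function(r) voteRegion(sol, r), integer(1L))

  mk_row <- function(start, end, supported, status, basis, nv, lms, note) {
    data.frame(accession = acc, region_start = start, region_end = end,
               supported = paste(supported, collapse = ";"),
               status = status, basis = basis,
               classification = NA_character_, n_votes = nv,
               n_supporting_lms = length(lms),
               supporting_lms = if (length(lms))
                 paste(sort(lms), collapse = ";") else NA_character_,
               note = note, stringsAsFactors = FALSE)
  }

  rows <- list()
  anchors <- data.frame(region = integer(), compartment = character())
  for (rg in sort(unique(votes$region))) {
    v <- votes[votes$region == rg, , drop = FALSE]
    supported <- sort(unique(v$locale))
    status <- if (length(supported) == 1L) "unambiguous" else "ambiguous"
    if (status == "unambiguous")
      anchors <- rbind(anchors, data.frame(region = rg,
                                           compartment = supported))
    rows[[length(rows) + 1L]] <-
      mk_row(sol$start[sol$region == rg], sol$end[sol$region == rg],
             supported, status, "votes", nrow(v), unique(v$lm),
             NA_character_)
  }
  pred <- do.call(rbind, rows)

  is_membrane <- tmCount(topology) > 0L
  oriented <- topology
  if (is_membrane && nrow(anchors)) {
    membrane_hint <- if (!is.na(prior) &&
                         prior %in% membraneCompartments(model))
      prior else NA_character_
    oriented <- tryCatch(
      orientTopology(topology, anchors, membrane_hint, model),
      error = function(e) orientTopology(topology, anchors,
                                         NA_character_, model))
    if (oriented@orientation %in% c("partial", "full")) {
      osol <- solubleRegions(oriented)
      infer <- osol[!osol$region %in% votes$region &
                    !is.na(osol$compartment), , drop = FALSE]
      note <- if (any(oriented@regions$confidence == "potential",
                      na.rm = TRUE)) "potential TM topology" else
        NA_character_
      for (i in seq_len(nrow(infer)))
        pred <- rbind(pred, mk_row(infer$start[i], infer$end[i],
                                   infer$compartment[i], "unambiguous",
                                   "topology", 0L, character(), note))
    } else if (oriented@orientation == "inconsistent") {
      pred$note <- "parity-inconsistent region anchors"
    }
  }

  # classification versus the prior annotation, protein level
  vote_rows <- pred$basis == "votes"
  unamb <- all(pred$status[vote_rows] == "unambiguous")
  cls <- NA_character_
  if (unamb) {
    if (is_membrane) {
      cls <- if (is.na(prior)) "novel"
      else if (!is.na(oriented@membrane) && prior == oriented@membrane)
        "confirms"
      else "contradicts"
    } else {
      supported <- pred$supported[1L]
      cls <- if (is.na(prior)) "novel"
      else if (prior == supported) "confirms" else "contradicts"
      outer <- aqueousCompartments(model)[1L]
      if (is.na(prior) && supported == outer && length(
            membraneCompartments(model)))
        pred$note[1L] <- paste0("membrane-associated (",
                                membraneCompartments(model)[1L], ", ",
                                outer, " face)")
    }
  }
  pred$classification <- cls
  ord <- order(pred$region_start)
  pred <- pred[ord, , drop = FALSE]
  rownames(pred) <- NULL
  pred
}

#' Run the full localization-inference pipeline
#'
#' Deduplicated cross-links are turned into a protein-protein network and
#' filtered to the well-connected core; marker candidates are validated for
#' mutual cross-link consistency; every first-tier interactor of the
#' validated markers is then predicted from its direct marker votes.
#' Inference is fully deterministic.
#'
#' @param crosslinks a [CrossLinkSet-class]; empty is a fatal error.
#' @param markers marker candidate data.frame (manual, auto-selected via
#'   [autoSelectCandidates()], or both).
#' @param annotations optional annotation list from [readAnnotations()]
#'   (prior locations, lengths, TM features).
#' @param tmpred optional TM-prediction list from [readTMPredictions()].
#' @param model a [CompartmentModel-class].
#' @param min_component_size network filter threshold (see
#'   [filterNetwork()]).
#' @return a [ClaspResult-class].
#' @export
runClasp <- function(crosslinks, markers, annotations = NULL, tmpred = NULL,
                     model = defaultMitoModel(), min_component_size = 3L) {
  if (length(crosslinks) == 0L)
    stop("empty cross-link set: nothing to predict")
  val <- validateCandidates(markers, crosslinks, model)
  markers_v <- val$markers
  if (!nrow(markers_v))
    stop("no marker survived consistency validation")

  net <- filterNetwork(buildNetwork(crosslinks), min_component_size)
  lms <- intersect(unique(markers_v$accession), networkNodes(net))
  targets <- suppressWarnings(firstTier(net, unique(markers_v$accession)))

  lk <- as.data.frame(crosslinks)
  obs_len <- function(acc) max(c(lk$residue_a[lk$protein_a == acc],
                                 lk$residue_b[lk$protein_b == acc], 1L))
  all_pred <- list()
  all_votes <- list()
  for (tg in targets) {
    votes <- collectVotes(tg, crosslinks, markers_v, model)
    if (!nrow(votes)) next
    ann <- annotations[[tg]]
    len <- if (!is.null(ann)) ann$length else obs_len(tg)
    prior <- if (!is.null(ann)) ann$prior_location else NA_character_
    ann_tm <- if (!is.null(ann) && nrow(ann$tm)) ann$tm else NULL
    pred_tm <- tmpred[[tg]]
    top <- if (is.null(ann_tm) && is.null(pred_tm))
      solubleTopology(tg, len)
    else buildRegions(tg, len, predicted = pred_tm, annotated = ann_tm,
                      membrane = if (!is.na(prior) &&
                                     prior %in% membraneCompartments(model))
                        prior else NA_character_)
    pred <- predictTarget(top, votes, prior = prior, model = model)
    if (nrow(pred)) {
      all_pred[[tg]] <- pred
      all_votes[[tg]] <- votes
    }
  }
  predictions <- if (length(all_pred)) do.call(rbind, all_pred) else
    emptyPredictions()
  rownames(predictions) <- NULL
  votes <- if (length(all_votes)) do.call(rbind, all_votes) else
    data.frame(target = character(), target_residue = integer(),
               lm = character(), lm_residue = integer(), locale = character())
  rownames(votes) <- NULL

  # corroborating non-marker neighbors: one propagation round only -- a
  # neighbor counts if it is itself unambiguously predicted to a shared
  # compartment; never used as a vote.
  predictions$n_consistent_neighbors <- 0L
  sig <- protSignature(predictions)
  if (nrow(predictions)) {
    g <- net@graph
    for (tg in unique(predictions$accession)) {
      s <- sig[[tg]]
      if (is.null(s)) next
      nb <- setdiff(igraph::adjacent_vertices(g, tg)[[1L]]$name,
                    unique(markers_v$accession))
      n_ok <- sum(vapply(nb, function(x) {
        sx <- sig[[x]]
        !is.null(sx) && length(intersect(sx, s)) > 0L
      }, logical(1L)))
      predictions$n_consistent_neighbors[predictions$accession == tg] <- n_ok
    }
  }

  vote_based <- predictions[predictions$basis == "votes", , drop = FALSE]
  prot_status <- tapply(vote_based$status, vote_based$accession,
                        function(s) all(s == "unambiguous"))
  cls <- vapply(split(vote_based$classification, vote_based$accession),
                function(x) x[1L], character(1L))
  summary <- list(
    n_proteins = length(networkNodes(net)),
    n_connections = nrow(networkEdges(net)),
    n_markers = length(unique(markers_v$accession)),
    n_markers_in_network = length(lms),
    coverage_pct = if (length(networkNodes(net)))
      networkCoverage(net, unique(markers_v$accession)) else NA_real_,
    n_first_tier = length(targets),
    n_proteins_predicted = length(unique(predictions$accession)),
    n_region_predictions = nrow(vote_based),
    pct_unambiguous = if (length(prot_status))
      100 * mean(prot_status) else NA_real_,
    n_confirms = sum(cls == "confirms", na.rm = TRUE),
    n_contradicts = sum(cls == "contradicts", na.rm = TRUE),
    n_novel = sum(cls == "novel", na.rm = TRUE),
    marker_consistency_pct = val$report@consistent_fraction)

  new("ClaspResult", predictions = predictions, votes = votes,
      network = net, markers = markers_v, report = val$report,
      summary = summary)
}

# per-protein supported-compartment signature over unambiguous vote-based
# rows; NULL when any vote-based row is ambiguous
protSignature <- function(predictions) {
  out <- list()
  vb <- predictions[predictions$basis == "votes", , drop = FALSE]
  for (acc in unique(vb$accession)) {
    p <- vb[vb$accession == acc, , drop = FALSE]
    if (all(p$status == "unambiguous"))
      out[[acc]] <- sort(unique(p$supported))
  }
  out
}

#' Result accessors
#'
#' @param result a [ClaspResult-class].
#' @return `predictions()`: the per-region prediction data.frame;
#'   `claspSummary()`: the summary list.
#' @export
predictions <- function(result) result@predictions

#' @rdname predictions
#' @export
claspSummary <- function(result) result@summary

#' Compare two prediction runs
#'
#' Intersects the proteins unambiguously predicted in both runs and flags,
#' per protein, whether the supported compartment signatures agree.
#'
#' @param a,b [ClaspResult-class] objects or prediction data.frames.
#' @return list with `overlap` (data.frame `accession`, `agree`),
#'   `n_overlap` and `pct_agreement` (`NA` when the overlap is empty).
#' @export
compareRuns <- function(a, b) {
  pa <- if (is(a, "ClaspResult")) a@predictions else a
  pb <- if (is(b, "ClaspResult")) b@predictions else b
  sa <- protSignature(pa)
  sb <- protSignature(pb)
  common <- intersect(names(sa), names(sb))
  agree <- vapply(common, function(x) setequal(sa[[x]], sb[[x]]),
                  logical(1L))
  list(overlap = data.frame(accession = common, agree = unname(agree)),
       n_overlap = length(common),
       pct_agreement = if (length(common)) 100 * mean(agree) else NA_real_)
}

setMethod("show", "ClaspResult", function(object) {
  s <- object@summary
  cat("ClaspResult:", s$n_proteins_predicted, "proteins predicted (",
      s$n_region_predictions, "vote-based region predictions )\n")
  cat(sprintf("  network: %d proteins / %d connections; %d markers (%.1f%% consistent); coverage %.1f%%\n",
              s$n_proteins, s$n_connections, s$n_markers,
              s$marker_consistency_pct, s$coverage_pct))
  cat(sprintf("  unambiguous: %.1f%%; confirms %d / contradicts %d / novel %d\n",
              s$pct_unambiguous, s$n_confirms, s$n_contradicts, s$n_novel))
})
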