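#' Classify a TM-prediction posterior probability
#'
#' Thresholds calibrated on membrane proteins of known topology:
#' posterior above 0.75 is a high-confidence TM segment, 0.037-0.75 a
#' potential TM segment, below 0.037 soluble.
#'
#' @param posterior numeric vector of posterior probabilities in `[0, 1]`.
#' @param high,low the two thresholds (defaults 0.75 and 0.037).
#' @return character vector: `"high"`, `"potential"`, or `"soluble"`.
#' @export
classifyTM <- function(posterior, high = 0.75, low = 0.037) {
  if (any(is.na(posterior)) || any(posterior < 0 | posterior > 1))
    stop("posterior probabilities must lie in [0, 1]")
  ifelse(posterior > high, "high",
         ifelse(posterior >= low, "potential", "soluble"))
}

#' Build an unoriented topology from TM intervals
#'
#' Merges annotated TM intervals with predicted segments classified as
#' `high` or `potential` (overlapping or adjacent intervals unite into one
#' TM segment; a merged segment keeps the strongest evidence class, with
#' annotation outranking prediction). The complement of the TM segments
#' defines the soluble regions; all sides start unknown.
#'
#' @param accession protein accession.
#' @param length protein length in residues.
#' @param predicted data.frame `start`, `end`, `posterior` of predicted
#'   segments (may be `NULL`).
#' @param annotated data.frame `start`, `end` of annotation TM features
#'   (may be `NULL`).
#' @param membrane optional membrane name for later orientation.
#' @return an unoriented [Topology-class].
#' @export
buildRegions <- function(accession, length, predicted = NULL,
                         annotated = NULL, membrane = NA_character_) {
  length <- as.integer(length)
  seg <- data.frame(start = integer(), end = integer(), conf = character())
  if (!is.null(annotated) && nrow(annotated))
    seg <- rbind(seg, data.frame(start = annotated$start, end = annotated$end,
                                 conf = "annotated"))
  if (!is.null(predicted) && nrow(predicted)) {
    cls <- classifyTM(predicted$posterior)
    keep <- cls != "soluble"
    if (any(keep))
      seg <- rbind(seg, data.frame(start = predicted$start[keep],
                                   end = predicted$end[keep],
                                   conf = cls[keep]))
  }
  if (any(seg$start < 1L | seg$end > length | seg$start > seg$end))
    stop("TM interval outside [1, ", length, "] for ", accession)
  if (nrow(seg) == 0L) {
    regions <- data.frame(start = 1L, end = length, type = "soluble",
                          compartment = NA_character_,
                          confidence = NA_character_)
    return(new("Topology", accession = accession, length = length,
               regions = regions, membrane = membrane,
               orientation = "unoriented"))
  }
  ir <- IRanges::IRanges(start = seg$start, end = seg$end)
  merged <- IRanges::reduce(ir)
  ov <- IRanges::findOverlaps(ir, merged)
  rank <- c(annotated = 3L, high = 2L, potential = 1L)
  conf <- vapply(seq_along(merged), function(j) {
    members <- seg$conf[S4Vectors::queryHits(ov)[S4Vectors::subjectHits(ov) == j]]
    names(which.max(rank[members]))
  }, character(1L))
  tm <- data.frame(start = IRanges::start(merged), end = IRanges::end(merged),
                   type = "tm", compartment = NA_character_,
                   confidence = conf)
  gaps <- IRanges::gaps(merged, start = 1L, end = length)
  sol <- data.frame(start = IRanges::start(gaps), end = IRanges::end(gaps),
                    type = "soluble", compartment = NA_character_,
                    confidence = NA_character_)
  regions <- rbind(tm, sol)
  regions <- regions[order(regions$start), , drop = FALSE]
  rownames(regions) <- NULL
  new("Topology", accession = accession, length = length, regions = regions,
      membrane = membrane, orientation = "unoriented")
}

#' Topology for a soluble (non-membrane) protein
#'
#' @param accession protein accession.
#' @param length protein length.
#' @param compartment aqueous compartment faced by the whole protein
#'   (`NA` if unknown).
#' @return a [Topology-class] with one soluble region.
#' @export
solubleTopology <- function(accession, length, compartment = NA_character_) {
  regions <- data.frame(start = 1L, end = as.integer(length),
                        type = "soluble", compartment = compartment,
                        confidence = NA_character_)
  new("Topology", accession = accession, length = as.integer(length),
      regions = regions, membrane = NA_character_,
      orientation = if (is.na(compartment)) "unoriented" else "full")
}

#' Soluble regions of a topology
#'
#' @param topology a [Topology-class].
#' @return data.frame of the soluble regions in sequence order, with a
#'   `region` index column.
#' @export
solubleRegions <- function(topology) {
  rg <- topology@regions
  sol <- rg[rg$type == "soluble", , drop = FALSE]
  sol$region <- seq_len(nrow(sol))
  rownames(sol) <- NULL
  sol
}

#' Count of TM segments
#'
#' @param topology a [Topology-class].
#' @return integer.
#' @export
tmCount <- function(topology) sum(topology@regions$type == "tm")

#' Orient a membrane topology from anchored regions
#'
#' Soluble regions alternate between the two aqueous sides of the membrane:
#' regions separated by an even number of TM segments share a side, odd
#' separation puts them on opposite sides (hence a protein with an even TM
#' count has both termini in the same compartment). Anchors fix the side of
#' one or more soluble regions; alternation then propagates the assignment.
#'
#' If anchors name two different compartments, the membrane is identified as
#' the one having both as sides and every region resolves (`full`). With
#' anchors on a single compartment, the opposite side is only known when the
#' membrane is (e.g. from prior annotation): otherwise even-parity regions
#' resolve and the rest stay unknown (`partial`). Parity-inconsistent
#' anchors flag the topology `inconsistent` and attach the conflict set as
#' attribute `"conflicts"`.
#'
#' @param topology a [Topology-class] with at least one TM segment.
#' @param anchors data.frame with columns `region` (index among soluble
#'   regions, in sequence order) and `compartment` (aqueous).
#' @param membrane membrane name, or `NA` to infer it from the anchors.
#' @param model a [CompartmentModel-class].
#' @return the oriented [Topology-class].
#' @export
orientTopology <- function(topology, anchors, membrane = NA_character_,
                           model = defaultMitoModel()) {
  if (is.na(membrane) && !is.na(topology@membrane))
    membrane <- topology@membrane
  sol <- solubleRegions(topology)
  k <- nrow(sol)
  if (!nrow(anchors)) return(topology)
  if (any(anchors$region < 1L | anchors$region > k))
    stop("anchor region index out of range")
  if (!all(anchors$compartment %in% aqueousCompartments(model)))
    stop("anchor compartments must be aqueous compartments of the model")
  if (!is.na(membrane)) {
    sides <- membraneSides(model, membrane)
    if (!all(anchors$compartment %in% sides))
      stop("anchor compartment not adjacent to membrane '", membrane, "'")
  }

  # parity of a soluble region = (#TM segments before it) mod 2; since the
  # regions strictly alternate this is (region index - 1) mod 2 shifted by
  # whether the protein starts with a TM segment (which does not change
  # relative parity between soluble regions).
  parity <- (anchors$region - 1L) %% 2L
  bycomp <- split(parity, anchors$compartment)
  conflict_within <- any(vapply(bycomp, function(p)
    length(unique(p)) > 1L, logical(1L)))
  comps <- names(bycomp)
  conflict_between <- length(comps) == 2L &&
    unique(bycomp[[1L]])[1L] == unique(bycomp[[2L]])[1L]
  if (conflict_within || length(comps) > 2L || conflict_between) {
    topology@orientation <- "inconsistent"
    attr(topology@regions, "conflicts") <- anchors
    return(topology)
  }

  side_of <- rep(NA_character_, 2L)  # indexed by parity + 1
  for (cc in comps) side_of[unique(bycomp[[cc]]) + 1L] <- cc
  if (any(is.na(side_of))) {
    if (is.na(membrane) && length(comps) == 1L) {
      # try to identify the membrane: unique membrane with this side plus,
      # for membrane-spanning proteins, no other constraint available
      cand <- Filter(function(m) comps %in% membraneSides(model, m),
                     membraneCompartments(model))
      if (length(cand) == 1L) membrane <- cand[[1L]]
    }
    if (!is.na(membrane)) {
      other <- setdiff(membraneSides(model, membrane), comps)
      if (length(other) == 1L) side_of[is.na(side_of)] <- other
    }
  } else if (is.na(membrane)) {
    cand <- Filter(function(m) setequal(membraneSides(model, m), side_of),
                   membraneCompartments(model))
    if (length(cand) == 1L) membrane <- cand[[1L]]
    else {
      topology@orientation <- "inconsistent"
      attr(topology@regions, "conflicts") <- anchors
      return(topology)
    }
  }

  rg <- topology@regions
  solidx <- which(rg$type == "soluble")
  for (i in seq_len(k))
    rg$compartment[solidx[i]] <- side_of[((i - 1L) %% 2L) + 1L]
  topology@regions <- rg
  topology@membrane <- membrane
  topology@orientation <-
    if (anyNA(rg$compartment[solidx])) "partial" else "full"
  topology
}

setMethod("show", "Topology", function(object) {
  cat("Topology ", object@accession, " (", object@length, " aa, ",
      tmCount(object), " TM, ", object@orientation,
      if (!is.na(object@membrane)) paste0(", ", object@membrane), ")\n",
      sep = "")
  rg <- object@regions
  lab <- ifelse(rg$type == "tm",
                paste0("TM[", rg$confidence, "]"),
                ifelse(is.na(rg$compartment), "?", rg$compartment))
  cat(" ", paste0(rg$start, "-", rg$end, ":", lab, collapse = " | "), "\n")
})
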