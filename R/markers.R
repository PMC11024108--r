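#' Construct a localization-marker table
#'
#' Markers are proteins (or soluble regions of membrane proteins) with an
#' established aqueous-compartment assignment; they are the source of the
#' spatial votes. One row per region: a soluble marker has exactly one
#' region spanning the whole protein; a membrane marker lists its soluble
#' regions with their per-region compartments (residues outside the listed
#' regions are treated as membrane-embedded).
#'
#' @param accession,start,end,compartment vectors defining the regions.
#' @param source `"manual"` or `"auto"` per region.
#' @param evidence free-text provenance per region.
#' @param model a [CompartmentModel-class]; all compartments must be aqueous
#'   members of it.
#' @return marker data.frame with the five columns above.
#' @export
makeMarkers <- function(accession, start, end, compartment,
                        source = "manual", evidence = NA_character_,
                        model = defaultMitoModel()) {
  df <- data.frame(accession = as.character(accession),
                   start = as.integer(start), end = as.integer(end),
                   compartment = as.character(compartment),
                   source = source, evidence = evidence,
                   stringsAsFactors = FALSE)
  bad <- !df$compartment %in% aqueousCompartments(model)
  if (any(bad))
    stop("marker compartments must be aqueous compartments of the model: ",
         paste(unique(df$compartment[bad]), collapse = ", "))
  if (any(df$start < 1L | df$start > df$end))
    stop("marker regions need 1 <= start <= end")
  df
}

#' Locale of a residue on a marker protein
#'
#' @param markers marker data.frame (see [makeMarkers()]).
#' @param accession marker accession.
#' @param residue position.
#' @return the region's aqueous compartment, `"membrane"` when the residue
#'   falls outside every listed region (TM-embedded for membrane markers),
#'   `NA` for unknown accessions.
#' @export
markerLocale <- function(markers, accession, residue) {
  rows <- markers[markers$accession == accession, , drop = FALSE]
  if (!nrow(rows)) return(NA_character_)
  hit <- which(rows$start <= residue & rows$end >= residue)
  if (!length(hit)) "membrane" else rows$compartment[hit[1L]]
}

#' Automatically select marker candidates from annotations
#'
#' A protein becomes a soluble marker candidate when its location text
#' normalizes to exactly one aqueous compartment of the model and it has no
#' TM features; a membrane protein becomes a marker when its TM features
#' plus topological-domain side notes yield a fully oriented topology
#' (per-region compartments). Everything else is excluded, with the reason
#' recorded in the `"excluded"` attribute.
#'
#' @param annotations annotation list from [readAnnotations()].
#' @param model a [CompartmentModel-class].
#' @return marker data.frame (source `"auto"`), with attribute `"excluded"`
#'   (data.frame `accession`, `reason`).
#' @export
autoSelectCandidates <- function(annotations, model = defaultMitoModel()) {
  rows <- list()
  excluded <- list()
  aq <- aqueousCompartments(model)
  for (ann in annotations) {
    acc <- ann$accession
    loc <- if (is.null(ann$prior_location) || is.na(ann$prior_location))
      normalizeLocation(model, ann$location_text) else ann$prior_location
    has_tm <- !is.null(ann$tm) && nrow(ann$tm) > 0L
    if (!has_tm) {
      if (is.na(loc)) {
        excluded[[acc]] <- "no unequivocal location annotation"
      } else if (!loc %in% aq) {
        excluded[[acc]] <- paste0("location '", loc,
                                  "' is not a single aqueous compartment")
      } else {
        rows[[acc]] <- data.frame(accession = acc, start = 1L,
                                  end = ann$length, compartment = loc,
                                  source = "auto",
                                  evidence = "annotation location")
      }
      next
    }
    # membrane candidate: needs side notes that fully orient the topology
    membrane <- if (!is.na(loc) && loc %in% membraneCompartments(model))
      loc else NA_character_
    top <- buildRegions(acc, ann$length, annotated = ann$tm,
                        membrane = membrane)
    sol <- solubleRegions(top)
    anchors <- data.frame(region = integer(), compartment = character())
    if (!is.null(ann$topo) && nrow(ann$topo)) {
      for (j in seq_len(nrow(ann$topo))) {
        comp <- ann$topo$compartment[j]
        if (is.na(comp) || !comp %in% aq) next
        hit <- which(sol$start <= ann$topo$start[j] &
                     sol$end >= ann$topo$start[j])
        if (length(hit))
          anchors <- rbind(anchors, data.frame(region = sol$region[hit[1L]],
                                               compartment = comp))
      }
    }
    if (!nrow(anchors)) {
      excluded[[acc]] <- "membrane protein without orienting side notes"
      next
    }
    top <- tryCatch(orientTopology(top, anchors, membrane, model),
                    error = function(e) NULL)
    if (is.null(top) || top@orientation != "full") {
      excluded[[acc]] <- "membrane topology could not be fully oriented"
      next
    }
    osol <- solubleRegions(top)
    rows[[acc]] <- data.frame(accession = acc, start = osol$start,
                              end = osol$end, compartment = osol$compartment,
                              source = "auto",
                              evidence = "annotation topology")
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(accession = character(), start = integer(), end = integer(),
               compartment = character(), source = character(),
               evidence = character())
  rownames(out) <- NULL
  attr(out, "excluded") <- data.frame(
    accession = names(excluded),
    reason = unlist(excluded, use.names = FALSE) %||% character())
  out
}

#' Validate marker candidates against the cross-link set
#'
#' Tallies every unique cross-linked residue pair whose two endpoints both
#' lie on candidate markers, resolves both residue locales, and flags the
#' pairs that could not legally be bridged (different aqueous compartments)
#' as contradictions. Links with a membrane-embedded endpoint are skipped
#' from the tally with a warning. Every candidate touching at least one
#' contradiction is removed: either endpoint may be the mislocalized one
#' (dual localization or a false-positive identification), so both are
#' suspect.
#'
#' @param candidates marker data.frame.
#' @param crosslinks a [CrossLinkSet-class].
#' @param model a [CompartmentModel-class].
#' @return list with `report` (a [ConsistencyReport-class]) and `markers`
#'   (the validated marker table).
#' @export
validateCandidates <- function(candidates, crosslinks,
                               model = defaultMitoModel()) {
  lk <- as.data.frame(crosslinks)
  cand <- unique(candidates$accession)
  sub <- lk[lk$protein_a %in% cand & lk$protein_b %in% cand, , drop = FALSE]
  if (nrow(sub)) {
    la <- mapply(function(p, r) markerLocale(candidates, p, r),
                 sub$protein_a, sub$residue_a, USE.NAMES = FALSE)
    lb <- mapply(function(p, r) markerLocale(candidates, p, r),
                 sub$protein_b, sub$residue_b, USE.NAMES = FALSE)
  } else la <- lb <- character()
  skip <- la == "membrane" | lb == "membrane" | is.na(la) | is.na(lb)
  if (any(skip, na.rm = TRUE))
    warning(sum(skip), " marker-marker link(s) with a membrane-embedded or ",
            "unresolved endpoint skipped from the consistency tally")
  tallied <- sub[!skip, , drop = FALSE]
  ok <- mayCrosslink(la[!skip], lb[!skip], model)
  contr <- tallied[!ok, , drop = FALSE]
  contr$locale_a <- la[!skip][!ok]
  contr$locale_b <- lb[!skip][!ok]
  rownames(contr) <- NULL
  removed <- sort(unique(c(contr$protein_a, contr$protein_b)))
  n <- nrow(tallied)
  report <- new("ConsistencyReport",
                n_lm_links = as.integer(n),
                contradictions = contr,
                consistent_fraction =
                  if (n == 0L) 100 else 100 * (n - nrow(contr)) / n,
                removed = removed,
                n_skipped = as.integer(sum(skip)))
  list(report = report,
       markers = candidates[!candidates$accession %in% removed, ,
                            drop = FALSE])
}

#' Add manually curated markers to a validated set
#'
#' Manual entries (full region/compartment specification) are unioned with
#' the validated set and re-validated against the cross-links before
#' acceptance: a manual marker participating in any contradiction is
#' rejected, with its conflicting links reported in the `"rejected"`
#' attribute. When an `abundance` vector is supplied it only orders the
#' rejection report (most abundant first), it never influences acceptance.
#'
#' @param validated validated marker data.frame.
#' @param manual manual marker data.frame (see [makeMarkers()]).
#' @param crosslinks a [CrossLinkSet-class].
#' @param model a [CompartmentModel-class].
#' @param abundance optional named numeric vector (accession -> abundance).
#' @return the augmented, validated marker table with attribute
#'   `"rejected"`.
#' @export
augmentCandidates <- function(validated, manual, crosslinks,
                              model = defaultMitoModel(),
                              abundance = NULL) {
  union <- rbind(validated[, c("accession", "start", "end", "compartment",
                               "source", "evidence")],
                 manual[, c("accession", "start", "end", "compartment",
                            "source", "evidence")])
  res <- validateCandidates(union, crosslinks, model)
  rej_acc <- intersect(res$report@removed, unique(manual$accession))
  if (!is.null(abundance) && length(rej_acc))
    rej_acc <- rej_acc[order(-abundance[rej_acc], rej_acc)]
  rejected <- lapply(rej_acc, function(a) {
    cn <- res$report@contradictions
    cn[cn$protein_a == a | cn$protein_b == a, , drop = FALSE]
  })
  names(rejected) <- rej_acc
  out <- res$markers
  attr(out, "rejected") <- rejected
  out
}

#' Consistency report as a plain list (for JSON export)
#'
#' @param report a [ConsistencyReport-class].
#' @return list of counts, the consistent percentage and removed accessions.
#' @export
reportAsList <- function(report) {
  list(n_lm_links = report@n_lm_links,
       n_contradictions = nrow(report@contradictions),
       consistent_fraction = report@consistent_fraction,
       n_skipped = report@n_skipped,
       removed = report@removed)
}

setMethod("show", "ConsistencyReport", function(object) {
  cat("ConsistencyReport:", object@n_lm_links,
      "marker-marker residue pairs,", nrow(object@contradictions),
      sprintf("contradictions (%.1f%% consistent), %d candidate(s) removed\n",
              object@consistent_fraction, length(object@removed)))
})
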