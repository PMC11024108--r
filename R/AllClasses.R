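#' @import methods
NULL

#' Compartment model of an organelle
#'
#' An ordered alternation of aqueous compartments and membranes, e.g. for
#' mitochondria `cytosol | OMM | IMS | IMM | matrix`. The model defines which
#' residue locales may be bridged by a cross-linker: only residues sharing an
#' aqueous compartment, because membranes (~70 Angstrom thick) exceed the
#' labeling radius.
#'
#' @slot compartments data.frame with columns `name`, `kind`
#'   (`"aqueous"`/`"membrane"`), `thickness_A` (Angstrom, membranes only,
#'   `NA` for aqueous compartments).
#' @slot gaps data.frame with columns `membrane_a`, `membrane_b`, `gap_A`:
#'   pairwise membrane-to-membrane distances used by protrusion feasibility.
#' @slot synonyms data.frame with columns `text`, `compartment`: controlled
#'   vocabulary mapping annotation location text to model compartments.
#'
#' @seealso [defaultMitoModel()], [svModel()], [mayCrosslink()]
#' @exportClass CompartmentModel
setClass("CompartmentModel",
  representation(
    compartments = "data.frame",
    gaps = "data.frame",
    synonyms = "data.frame"
  )
)

setValidity("CompartmentModel", function(object) {
  cmp <- object@compartments
  msg <- character()
  if (!all(c("name", "kind", "thickness_A") %in% names(cmp)))
    return("compartments must have columns name, kind, thickness_A")
  if (nrow(cmp) < 1L) return("model needs at least one compartment")
  if (anyDuplicated(cmp$name)) msg <- c(msg, "compartment names must be unique")
  if (!all(cmp$kind %in% c("aqueous", "membrane")))
    msg <- c(msg, "kind must be 'aqueous' or 'membrane'")
  if (cmp$kind[1L] != "aqueous" || cmp$kind[nrow(cmp)] != "aqueous")
    msg <- c(msg, "first and last compartments must be aqueous")
  if (any(cmp$kind[-1L] == cmp$kind[-nrow(cmp)]))
    msg <- c(msg, "compartments must alternate aqueous/membrane")
  mem <- cmp$kind == "membrane"
  if (any(mem & (is.na(cmp$thickness_A) | cmp$thickness_A <= 0)))
    msg <- c(msg, "every membrane needs thickness_A > 0")
  if (nrow(object@gaps)) {
    bad <- !(object@gaps$membrane_a %in% cmp$name[mem]) |
      !(object@gaps$membrane_b %in% cmp$name[mem])
    if (any(bad)) msg <- c(msg, "gap entries must reference membranes")
    if (any(object@gaps$gap_A <= 0)) msg <- c(msg, "gap_A must be positive")
  }
  if (length(msg)) msg else TRUE
})

#' Set of unique cross-linked residue pairs
#'
#' Holds deduplicated, canonically ordered unique residue pairs from an XL-MS
#' search (post FDR filtering). Canonical order puts the lexicographically
#' smaller `(protein, residue)` endpoint first so symmetric duplicates
#' collapse; redundant rows merge with spectral counts summed and the best
#' score retained.
#'
#' @slot links data.frame with columns `protein_a`, `residue_a`, `protein_b`,
#'   `residue_b`, `score`, `n_csm`.
#'
#' @seealso [CrossLinkSet()], [readCrossLinks()]
#' @exportClass CrossLinkSet
setClass("CrossLinkSet", representation(links = "data.frame"))

setValidity("CrossLinkSet", function(object) {
  lk <- object@links
  need <- c("protein_a", "residue_a", "protein_b", "residue_b", "score", "n_csm")
  if (!all(need %in% names(lk))) return("missing link columns")
  if (nrow(lk) == 0L) return(TRUE)
  if (any(lk$residue_a < 1L) || any(lk$residue_b < 1L))
    return("residue positions are 1-based and must be >= 1")
  swapped <- lk$protein_a > lk$protein_b |
    (lk$protein_a == lk$protein_b & lk$residue_a > lk$residue_b)
  if (any(swapped)) return("links are not in canonical endpoint order")
  key <- paste(lk$protein_a, lk$residue_a, lk$protein_b, lk$residue_b)
  if (anyDuplicated(key)) return("duplicate unique residue pairs present")
  TRUE
})

#' Cross-link protein-protein network
#'
#' Undirected network whose nodes are protein accessions and whose edges are
#' distinct protein pairs connected by at least one inter-protein cross-link;
#' the edge weight is the number of unique inter-protein residue pairs.
#' Intra-protein links are never edges (no self-loops). Nodes with no
#' inter-protein link appear isolated until [filterNetwork()] removes them.
#'
#' @slot graph an igraph object (weight as edge attribute).
#' @slot removed list describing nodes/components dropped by filtering.
#'
#' @seealso [buildNetwork()], [filterNetwork()], [firstTier()]
#' @exportClass XLNetwork
setClass("XLNetwork", representation(graph = "ANY", removed = "list"))

#' Membrane-protein topology
#'
#' Partition of a protein sequence into soluble regions and transmembrane
#' (TM) segments. Soluble regions on either side of a TM segment face
#' opposite membrane sides; once one region is anchored to an aqueous
#' compartment, alternation propagates the side assignment.
#'
#' @slot accession protein accession.
#' @slot length protein length (residues).
#' @slot regions data.frame with columns `start`, `end` (1-based inclusive),
#'   `type` (`"soluble"`/`"tm"`), `compartment` (aqueous compartment for
#'   oriented soluble regions, otherwise `NA`), `confidence`
#'   (`"annotated"`, `"high"`, `"potential"` for TM segments).
#' @slot membrane name of the membrane the protein spans (`NA` if unknown).
#' @slot orientation one of `"unoriented"`, `"partial"`, `"full"`,
#'   `"inconsistent"`.
#'
#' @seealso [buildRegions()], [orientTopology()], [residueLocale()]
#' @exportClass Topology
setClass("Topology",
  representation(
    accession = "character",
    length = "integer",
    regions = "data.frame",
    membrane = "character",
    orientation = "character"
  )
)

setValidity("Topology", function(object) {
  rg <- object@regions
  if (!all(c("start", "end", "type", "compartment", "confidence") %in% names(rg)))
    return("regions must have start, end, type, compartment, confidence")
  if (nrow(rg) == 0L) return("topology needs at least one region")
  if (rg$start[1L] != 1L || rg$end[nrow(rg)] != object@length)
    return("regions must tile [1, length]")
  if (nrow(rg) > 1L && any(rg$start[-1L] != rg$end[-nrow(rg)] + 1L))
    return("regions must tile the sequence without gaps or overlaps")
  if (!all(rg$type %in% c("soluble", "tm"))) return("region type must be soluble or tm")
  if (nrow(rg) > 1L && any(rg$type[-1L] == rg$type[-nrow(rg)]))
    return("soluble and tm regions must alternate")
  if (!object@orientation %in% c("unoriented", "partial", "full", "inconsistent"))
    return("bad orientation state")
  TRUE
})

#' Consistency report for localization-marker validation
#'
#' Produced by [validateCandidates()]: tallies the unique cross-linked residue
#' pairs among marker candidates, lists pairs whose two residue locales could
#' not legally be bridged (a contradiction), and records which candidates were
#' removed for touching a contradiction.
#'
#' @slot n_lm_links number of marker-marker unique residue pairs tallied.
#' @slot contradictions data.frame of contradictory links with both locales.
#' @slot consistent_fraction percentage of tallied links that are consistent.
#' @slot removed accessions removed from the candidate set.
#' @slot n_skipped links skipped because an endpoint locale was
#'   membrane-embedded or unresolved.
#'
#' @exportClass ConsistencyReport
setClass("ConsistencyReport",
  representation(
    n_lm_links = "integer",
    contradictions = "data.frame",
    consistent_fraction = "numeric",
    removed = "character",
    n_skipped = "integer"
  )
)

setValidity("ConsistencyReport", function(object) {
  f <- object@consistent_fraction
  if (length(f) != 1L || is.na(f) || f < 0 || f > 100)
    return("consistent_fraction must be in [0, 100]")
  TRUE
})

#' Residue-resolved structure map
#'
#' C-alpha coordinates from a PDB structure plus the mapping from protein
#' sequence positions to structure residues, used to test cross-links against
#' the labeling-radius distance constraint.
#'
#' @slot pdb_id structure identifier.
#' @slot coords data.frame `chain`, `resno`, `x`, `y`, `z` (Angstrom) of
#'   C-alpha atoms.
#' @slot map data.frame `accession`, `position`, `chain`, `resno`.
#' @slot unmapped data.frame of mapping rows without a resolved C-alpha.
#'
#' @seealso [readStructure()], [structuralSatisfaction()]
#' @exportClass StructureMap
setClass("StructureMap",
  representation(
    pdb_id = "character",
    coords = "data.frame",
    map = "data.frame",
    unmapped = "data.frame"
  )
)

setValidity("StructureMap", function(object) {
  key <- paste(object@map$accession, object@map$position)
  if (anyDuplicated(key))
    return("every mapped residue must resolve to exactly one coordinate")
  TRUE
})

#' Synthetic organelle with ground truth
#'
#' A simulated multi-compartment organelle: proteins with known localization
#' or full membrane topology, simulated lysine positions, and designated
#' localization markers. Serves as ground truth for validating the whole
#' inference pipeline.
#'
#' @slot model the [CompartmentModel-class] used.
#' @slot proteins data.frame `accession`, `length`, `type`
#'   (`"soluble"`/`"membrane"`), `compartment` (aqueous compartment or
#'   membrane name), `is_lm`.
#' @slot topologies named list of [Topology-class], one per protein (soluble
#'   proteins get a single fully-oriented region).
#' @slot lysines named list of integer vectors: simulated lysine positions.
#' @slot seed integer seed used for generation.
#'
#' @seealso [generateOrganelle()], [simulateCrossLinks()]
#' @exportClass SyntheticOrganelle
setClass("SyntheticOrganelle",
  representation(
    model = "CompartmentModel",
    proteins = "data.frame",
    topologies = "list",
    lysines = "list",
    seed = "integer"
  )
)

#' Result of a full localization-inference run
#'
#' Bundle returned by [runClasp()]: per-region predictions, the votes behind
#' them, the filtered network, the validated marker set, the marker
#' consistency report, and summary counts.
#'
#' @slot predictions data.frame of per-region predictions.
#' @slot votes data.frame of individual marker votes.
#' @slot network the filtered [XLNetwork-class].
#' @slot markers validated marker table.
#' @slot report [ConsistencyReport-class] from marker validation.
#' @slot summary list of summary counts and fractions.
#'
#' @seealso [runClasp()], [writePredictions()]
#' @exportClass ClaspResult
setClass("ClaspResult",
  representation(
    predictions = "data.frame",
    votes = "data.frame",
    network = "XLNetwork",
    markers = "data.frame",
    report = "ConsistencyReport",
    summary = "list"
  )
)
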