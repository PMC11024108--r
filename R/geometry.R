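#' Cross-linker labeling-radius model
#'
#' The maximum bridgeable C-alpha to C-alpha distance for a lysine-reactive
#' cross-linker: spacer arm plus two lysine side chains plus in-solution
#' flexibility. For DSSO: 10.3 A spacer, 7.6 A side chain, 10 A
#' flexibility, capped at 40 A (4 nm); DSBSO shares the same cap.
#'
#' @param spacer_A,side_chain_A,flexibility_A component lengths (Angstrom),
#'   recorded for provenance.
#' @param max_ca_ca_A the distance cap applied in all checks (default 40).
#' @return list with the four fields.
#' @export
radiusModel <- function(spacer_A = 10.3, side_chain_A = 7.6,
                        flexibility_A = 10, max_ca_ca_A = 40) {
  if (max_ca_ca_A <= 0) stop("max_ca_ca_A must be positive")
  list(spacer_A = spacer_A, side_chain_A = side_chain_A,
       flexibility_A = flexibility_A, max_ca_ca_A = max_ca_ca_A)
}

#' Linear length of a peptide stretch
#'
#' Maximum protrusion of an n-residue stretch in extended conformation,
#' 3.5 Angstrom per residue.
#'
#' @param n_residues non-negative integer vector.
#' @return length(s) in Angstrom.
#' @export
linearLength <- function(n_residues) {
  if (any(n_residues < 0)) stop("residue counts must be non-negative")
  3.5 * n_residues
}

#' Can two membrane-anchored proteins bridge a gap?
#'
#' Two proteins sitting in membranes separated by `gap_A` can only be
#' cross-linked if their protrusions into the shared aqueous space are long
#' enough to bring their lysines within the labeling radius: feasible iff
#' `gap_A - 3.5*a - 3.5*b <= max_ca_ca_A`. For the mitochondrial OMM-IMM
#' gap of 200 A, bare membrane surfaces (a = b = 0) can never link.
#'
#' @param ims_len_a,ims_len_b protrusion lengths in residues.
#' @param gap_A membrane-to-membrane distance (Angstrom).
#' @param radius a [radiusModel()].
#' @return logical.
#' @export
protrusionFeasible <- function(ims_len_a, ims_len_b, gap_A,
                               radius = radiusModel()) {
  gap_A - linearLength(ims_len_a) - linearLength(ims_len_b) <=
    radius$max_ca_ca_A
}

#' Euclidean C-alpha distance
#'
#' @param p,q numeric 3-vectors (Angstrom) or 3-column matrices of points.
#' @return distance(s) in Angstrom.
#' @export
caDistance <- function(p, q) {
  if (is.null(dim(p))) p <- matrix(p, ncol = 3L)
  if (is.null(dim(q))) q <- matrix(q, ncol = 3L)
  if (any(!is.finite(p)) || any(!is.finite(q)))
    stop("coordinates must be finite")
  sqrt(rowSums((p - q)^2))
}

lookupCa <- function(structure, accession, position) {
  m <- structure@map
  i <- which(m$accession == accession & m$position == position)
  if (!length(i)) return(NULL)
  co <- structure@coords
  j <- which(co$chain == m$chain[i[1L]] & co$resno == m$resno[i[1L]])
  c(co$x[j[1L]], co$y[j[1L]], co$z[j[1L]])
}

#' Structural satisfaction of cross-links
#'
#' Maps every cross-link onto the structure via the residue mapping and
#' tests the C-alpha to C-alpha distance against the labeling radius.
#' Links with an unmapped endpoint are excluded and counted separately.
#'
#' @param crosslinks a [CrossLinkSet-class].
#' @param structure a [StructureMap-class].
#' @param radius a [radiusModel()].
#' @return list with `fraction` (of mappable links satisfying the cap),
#'   `table` (per-link distances and verdicts) and `n_unmappable`.
#'   Zero mappable links is an error.
#' @export
structuralSatisfaction <- function(crosslinks, structure,
                                   radius = radiusModel()) {
  lk <- as.data.frame(crosslinks)
  rows <- lapply(seq_len(nrow(lk)), function(i) {
    p <- lookupCa(structure, lk$protein_a[i], lk$residue_a[i])
    q <- lookupCa(structure, lk$protein_b[i], lk$residue_b[i])
    if (is.null(p) || is.null(q)) return(NULL)
    d <- caDistance(p, q)
    cbind(lk[i, c("protein_a", "residue_a", "protein_b", "residue_b")],
          data.frame(distance_A = d, satisfied = d <= radius$max_ca_ca_A))
  })
  mapped <- do.call(rbind, rows)
  if (is.null(mapped) || nrow(mapped) == 0L)
    stop("no cross-link could be mapped onto the structure")
  rownames(mapped) <- NULL
  list(fraction = mean(mapped$satisfied),
       table = mapped,
       n_unmappable = nrow(lk) - nrow(mapped))
}

#' Audit cross-links against the compartment model
#'
#' Resolves both residue locales of every link from the supplied topologies
#' and lists the links that could not legally form (locales failing
#' [mayCrosslink()]); links with an unresolvable locale are reported
#' separately as indeterminate, not as violations.
#'
#' @param crosslinks a [CrossLinkSet-class].
#' @param topologies named list of [Topology-class] (accession -> topology).
#' @param model a [CompartmentModel-class].
#' @return list with `violations` and `indeterminate` data.frames (links
#'   plus both locales).
#' @export
crossMembraneAudit <- function(crosslinks, topologies,
                               model = defaultMitoModel()) {
  lk <- as.data.frame(crosslinks)
  locale <- function(p, r) {
    top <- topologies[[p]]
    if (is.null(top) || r > top@length) NA_character_
    else residueLocale(top, r)
  }
  la <- mapply(locale, lk$protein_a, lk$residue_a, USE.NAMES = FALSE)
  lb <- mapply(locale, lk$protein_b, lk$residue_b, USE.NAMES = FALSE)
  lk$locale_a <- as.character(la)
  lk$locale_b <- as.character(lb)
  ok <- mayCrosslink(lk$locale_a, lk$locale_b, model)
  out_v <- lk[!is.na(ok) & !ok, , drop = FALSE]
  out_i <- lk[is.na(ok), , drop = FALSE]
  rownames(out_v) <- rownames(out_i) <- NULL
  list(violations = out_v, indeterminate = out_i)
}
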