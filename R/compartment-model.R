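#' Construct a compartment model
#'
#' @param compartments data.frame with `name`, `kind`, `thickness_A`.
#' @param gaps data.frame with `membrane_a`, `membrane_b`, `gap_A`
#'   (Angstrom), may be empty.
#' @param synonyms data.frame with `text`, `compartment` mapping annotation
#'   location strings to model compartments.
#' @return a [CompartmentModel-class].
#' @export
CompartmentModel <- function(compartments,
                             gaps = data.frame(membrane_a = character(),
                                               membrane_b = character(),
                                               gap_A = numeric()),
                             synonyms = data.frame(text = character(),
                                                   compartment = character())) {
  compartments$name <- as.character(compartments$name)
  compartments$kind <- as.character(compartments$kind)
  compartments$thickness_A <- as.numeric(compartments$thickness_A)
  new("CompartmentModel", compartments = compartments, gaps = gaps,
      synonyms = synonyms)
}

#' Built-in mitochondrial compartment model
#'
#' Five compartments in spatial order: cytosol, outer membrane (OMM),
#' intermembrane space (IMS), inner membrane (IMM), matrix. Both membranes
#' are 70 Angstrom (~7 nm) thick, which exceeds the cross-linker labeling
#' radius, so no cross-link may span a membrane. The OMM-IMM gap is
#' 200 Angstrom (20 nm, from electron tomography), used by the protrusion
#' feasibility rule.
#'
#' @return a [CompartmentModel-class].
#' @export
defaultMitoModel <- function() {
  CompartmentModel(
    compartments = data.frame(
      name = c("cytosol", "OMM", "IMS", "IMM", "matrix"),
      kind = c("aqueous", "membrane", "aqueous", "membrane", "aqueous"),
      thickness_A = c(NA, 70, NA, 70, NA)
    ),
    gaps = data.frame(membrane_a = "OMM", membrane_b = "IMM", gap_A = 200),
    synonyms = data.frame(
      text = c("Mitochondrion matrix", "Mitochondrion intermembrane space",
               "Mitochondrion inner membrane", "Mitochondrion outer membrane",
               "Cytoplasm", "Cytosol", "Mitochondrion matrix side",
               "Mitochondrial matrix", "Mitochondrial intermembrane",
               "Intermembrane side", "Matrix side", "Cytoplasmic side",
               "IMS side"),
      compartment = c("matrix", "IMS", "IMM", "OMM", "cytosol", "cytosol",
                      "matrix", "matrix", "IMS", "IMS", "matrix", "cytosol",
                      "IMS")
    )
  )
}

#' Built-in single-membrane vesicle model
#'
#' Three compartments for a synaptic-vesicle-like system: lumen, vesicle
#' membrane, cytosol.
#'
#' @return a [CompartmentModel-class].
#' @export
svModel <- function() {
  CompartmentModel(
    compartments = data.frame(
      name = c("lumen", "membrane", "cytosol"),
      kind = c("aqueous", "membrane", "aqueous"),
      thickness_A = c(NA, 70, NA)
    ),
    synonyms = data.frame(
      text = c("Vesicle lumen", "Cytoplasm", "Cytosol", "Lumenal side",
               "Cytoplasmic side", "Synaptic vesicle membrane"),
      compartment = c("lumen", "cytosol", "cytosol", "lumen", "cytosol",
                      "membrane")
    )
  )
}

#' Compartment accessors
#'
#' `compartmentNames()` returns all compartments in spatial order;
#' `aqueousCompartments()` and `membraneCompartments()` the respective
#' subsets; `membraneSides()` the two aqueous neighbors of a membrane;
#' `gapDistance()` the configured distance between two membranes.
#'
#' @param model a [CompartmentModel-class].
#' @return character vectors (numeric for `gapDistance`).
#' @export
compartmentNames <- function(model) model@compartments$name

#' @rdname compartmentNames
#' @export
aqueousCompartments <- function(model)
  model@compartments$name[model@compartments$kind == "aqueous"]

#' @rdname compartmentNames
#' @export
membraneCompartments <- function(model)
  model@compartments$name[model@compartments$kind == "membrane"]

#' @rdname compartmentNames
#' @param membrane membrane name.
#' @export
membraneSides <- function(model, membrane) {
  i <- match(membrane, model@compartments$name)
  if (is.na(i) || model@compartments$kind[i] != "membrane")
    stop("'", membrane, "' is not a membrane of this model")
  model@compartments$name[c(i - 1L, i + 1L)]
}

#' @rdname compartmentNames
#' @param membrane_a,membrane_b membrane names.
#' @export
gapDistance <- function(model, membrane_a, membrane_b) {
  g <- model@gaps
  hit <- (g$membrane_a == membrane_a & g$membrane_b == membrane_b) |
    (g$membrane_a == membrane_b & g$membrane_b == membrane_a)
  if (!any(hit)) stop("no gap distance configured for ",
                      membrane_a, "-", membrane_b)
  g$gap_A[which(hit)[1L]]
}

#' Normalize a location string to a model compartment
#'
#' Matches annotation text (trimmed, case-insensitive, trailing punctuation
#' ignored) against the model's compartment names and synonym vocabulary. Text with multiple
#' semicolon-separated locations or "Note=" qualifiers is treated as
#' equivocal and returns `NA`.
#'
#' @param model a [CompartmentModel-class].
#' @param text character vector of location strings.
#' @return character vector of compartment names, `NA` where unmatched or
#'   equivocal.
#' @export
normalizeLocation <- function(model, text) {
  clean <- function(x) tolower(trimws(sub("[.;]+$", "", x)))
  syn <- model@synonyms
  vapply(text, function(x) {
    if (is.na(x) || !nzchar(trimws(x))) return(NA_character_)
    if (grepl("Note=", x, fixed = TRUE)) return(NA_character_)
    parts <- trimws(strsplit(x, ";", fixed = TRUE)[[1L]])
    parts <- parts[nzchar(parts)]
    if (length(parts) != 1L) return(NA_character_)
    j <- match(clean(parts), clean(model@compartments$name))
    if (!is.na(j)) return(model@compartments$name[j])
    i <- match(clean(parts), clean(syn$text))
    if (is.na(i)) NA_character_ else syn$compartment[i]
  }, character(1L), USE.NAMES = FALSE)
}

#' Locale of a residue within a topology
#'
#' Returns the aqueous compartment faced by the soluble region containing
#' the residue, `"membrane"` if the residue lies inside a TM segment
#' (boundary residues belong to the TM segment), or `NA` if the containing
#' soluble region is unoriented.
#'
#' @param topology a [Topology-class].
#' @param residue integer position(s), 1-based.
#' @return character vector of locales.
#' @export
residueLocale <- function(topology, residue) {
  residue <- as.integer(residue)
  if (any(is.na(residue)) || any(residue < 1L) || any(residue > topology@length))
    stop("residue out of range for ", topology@accession,
         " (length ", topology@length, ")")
  rg <- topology@regions
  idx <- findInterval(residue, rg$start)
  ifelse(rg$type[idx] == "tm", "membrane", rg$compartment[idx])
}

#' May two residue locales be cross-linked?
#'
#' Cross-links only form between residues sharing an aqueous compartment:
#' membranes are thicker than the labeling radius, so membrane-embedded
#' residues never link and no link may span a membrane. Unresolved locales
#' give `NA` (indeterminate), not an error.
#'
#' @param locale_a,locale_b character locales as returned by
#'   [residueLocale()] (an aqueous compartment name, `"membrane"`, or `NA`).
#' @param model a [CompartmentModel-class].
#' @return logical vector (`NA` = indeterminate).
#' @export
mayCrosslink <- function(locale_a, locale_b, model) {
  aq <- aqueousCompartments(model)
  out <- locale_a == locale_b & locale_a %in% aq & locale_b %in% aq
  out[is.na(locale_a) | is.na(locale_b)] <- NA
  out[!is.na(locale_a) & locale_a == "membrane"] <- FALSE
  out[!is.na(locale_b) & locale_b == "membrane"] <- FALSE
  out
}

#' Read / write a compartment model as YAML
#'
#' The YAML layout has a `compartments` list (name, kind, thickness_A),
#' an optional `gaps` list (membrane_a, membrane_b, gap_A) and an optional
#' `synonyms` map of location text to compartment name.
#'
#' @param path file path.
#' @return `readCompartmentModel` returns a [CompartmentModel-class];
#'   `writeCompartmentModel` returns `path` invisibly.
#' @export
readCompartmentModel <- function(path) {
  y <- yaml::read_yaml(path)
  cmp <- do.call(rbind, lapply(y$compartments, function(c)
    data.frame(name = c$name, kind = c$kind,
               thickness_A = if (is.null(c$thickness_A)) NA_real_
                             else as.numeric(c$thickness_A))))
  gaps <- if (length(y$gaps))
    do.call(rbind, lapply(y$gaps, function(g)
      data.frame(membrane_a = g$membrane_a, membrane_b = g$membrane_b,
                 gap_A = as.numeric(g$gap_A))))
  else data.frame(membrane_a = character(), membrane_b = character(),
                  gap_A = numeric())
  syn <- if (length(y$synonyms))
    data.frame(text = names(y$synonyms),
               compartment = unlist(y$synonyms, use.names = FALSE))
  else data.frame(text = character(), compartment = character())
  CompartmentModel(cmp, gaps, syn)
}

#' @rdname readCompartmentModel
#' @param model a [CompartmentModel-class].
#' @export
writeCompartmentModel <- function(model, path) {
  cmp <- model@compartments
  y <- list(
    compartments = lapply(seq_len(nrow(cmp)), function(i) {
      out <- list(name = cmp$name[i], kind = cmp$kind[i])
      if (!is.na(cmp$thickness_A[i])) out$thickness_A <- cmp$thickness_A[i]
      out
    }),
    gaps = lapply(seq_len(nrow(model@gaps)), function(i)
      as.list(model@gaps[i, ])),
    synonyms = stats::setNames(as.list(model@synonyms$compartment),
                               model@synonyms$text)
  )
  yaml::write_yaml(y, path)
  invisible(path)
}

setMethod("show", "CompartmentModel", function(object) {
  cmp <- object@compartments
  cat("CompartmentModel:", paste(cmp$name, collapse = " | "), "\n")
  cat("  aqueous:", paste(cmp$name[cmp$kind == "aqueous"], collapse = ", "),
      "\n")
  mem <- cmp$kind == "membrane"
  if (any(mem))
    cat("  membranes:", paste0(cmp$name[mem], " (", cmp$thickness_A[mem],
                               " A)", collapse = ", "), "\n")
  if (nrow(object@gaps))
    cat("  gaps:", paste0(object@gaps$membrane_a, "-", object@gaps$membrane_b,
                          " = ", object@gaps$gap_A, " A", collapse = "; "),
        "\n")
})
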