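#' Column dialect for cross-link tables
#'
#' Search engines export cross-link tables under different column headers.
#' A dialect maps the six canonical fields onto the file's column names;
#' `score` and `n_csm` may be `NA` (absent). The default follows a generic
#' XlinkX-style export.
#'
#' @param protein_a,residue_a,protein_b,residue_b,score,n_csm column names
#'   in the file.
#' @return named character vector usable as the `dialect` argument of
#'   [readCrossLinks()].
#' @export
claspDialect <- function(protein_a = "Protein A", residue_a = "Residue A",
                         protein_b = "Protein B", residue_b = "Residue B",
                         score = "Score", n_csm = "CSMs") {
  c(protein_a = protein_a, residue_a = residue_a,
    protein_b = protein_b, residue_b = residue_b,
    score = score, n_csm = n_csm)
}

readTable <- function(path, sep = NULL, quote = "\"") {
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                    quote = quote, comment.char = "",
                    stringsAsFactors = FALSE)
}

#' Read a cross-link table
#'
#' Reads a CSV/TSV export of unique cross-linked residue pairs (as produced
#' by an XL-MS search engine after FDR filtering), normalizes endpoint order
#' and deduplicates: symmetric duplicates collapse, spectral counts sum, the
#' best score is kept.
#'
#' @param path file path (`.csv` comma-separated, otherwise tab-separated).
#' @param dialect column mapping from [claspDialect()].
#' @return a [CrossLinkSet-class]; a message reports the unique/intra/inter
#'   counts.
#' @export
readCrossLinks <- function(path, dialect = claspDialect()) {
  if (!file.exists(path)) stop("cross-link file not found: ", path)
  tab <- readTable(path)
  need <- c("protein_a", "residue_a", "protein_b", "residue_b")
  for (field in need) {
    if (is.na(dialect[[field]]) || !dialect[[field]] %in% names(tab))
      stop("cross-link table is missing mapped column '", dialect[[field]],
           "' (field ", field, ")")
  }
  getcol <- function(field) {
    nm <- dialect[[field]]
    if (!is.na(nm) && nm %in% names(tab)) tab[[nm]] else NULL
  }
  ra <- getcol("residue_a"); rb <- getcol("residue_b")
  badr <- which(is.na(suppressWarnings(as.integer(ra))) |
                is.na(suppressWarnings(as.integer(rb))))
  if (length(badr))
    stop("non-integer residue position in row(s) ",
         paste(badr + 1L, collapse = ", "), " of ", path)
  df <- data.frame(protein_a = getcol("protein_a"),
                   residue_a = as.integer(ra),
                   protein_b = getcol("protein_b"),
                   residue_b = as.integer(rb),
                   stringsAsFactors = FALSE)
  sc <- getcol("score"); if (!is.null(sc)) df$score <- as.numeric(sc)
  nc <- getcol("n_csm"); if (!is.null(nc)) df$n_csm <- as.integer(nc)
  xl <- CrossLinkSet(df)
  message(sprintf("%d unique cross-links (%d intra, %d inter) from %d proteins",
                  length(xl), sum(isIntra(xl)), sum(!isIntra(xl)),
                  length(unique(c(xl@links$protein_a, xl@links$protein_b)))))
  xl
}

parseFeatureIntervals <- function(text, keyword) {
  if (is.na(text) || !nzchar(text))
    return(data.frame(start = integer(), end = integer(), note = character()))
  # features look like: KEYWORD 12..34; /note="Helical"; KEYWORD 50..70; ...
  chunks <- regmatches(text, gregexpr(
    paste0(keyword, "\\s+\\d+\\.\\.\\d+(;\\s*/note=\"[^\"]*\")?"), text))[[1L]]
  ok <- grepl(paste0("^", keyword, "\\s+\\d+\\.\\.\\d+"), chunks)
  out <- do.call(rbind, lapply(chunks[ok], function(ch) {
    m <- regmatches(ch, regexec(paste0(keyword, "\\s+(\\d+)\\.\\.(\\d+)"),
                                ch))[[1L]]
    note <- regmatches(ch, regexec("/note=\"([^\"]*)\"", ch))[[1L]]
    data.frame(start = as.integer(m[2L]), end = as.integer(m[3L]),
               note = if (length(note)) note[2L] else NA_character_)
  }))
  if (is.null(out))
    out <- data.frame(start = integer(), end = integer(), note = character())
  leftover <- grepl(keyword, text, fixed = TRUE) &&
    length(chunks) < lengths(gregexpr(keyword, text, fixed = TRUE))
  if (leftover)
    warning("malformed ", keyword, " feature skipped in: ",
            substr(text, 1L, 60L))
  out[order(out$start), , drop = FALSE]
}

#' Read a Swiss-Prot-style annotation table
#'
#' Expects a TSV with columns `Entry`, `Length` and optionally
#' `Subcellular location [CC]`, `Transmembrane`, `Topological domain`.
#' `TRANSMEM a..b` feature strings are parsed into 1-based inclusive
#' intervals; topological-domain notes (e.g. "Matrix side") are retained and,
#' when a model is supplied, normalized to its compartment vocabulary,
#' as is the location text.
#'
#' @param path TSV file path.
#' @param model optional [CompartmentModel-class] used to normalize location
#'   and side vocabulary.
#' @return named list (by accession) of annotation records: `accession`,
#'   `length`, `location_text`, `prior_location`, `tm` (data.frame
#'   `start`,`end`), `topo` (data.frame `start`,`end`,`note`,`compartment`).
#' @export
readAnnotations <- function(path, model = NULL) {
  # feature strings embed quoted /note="..." qualifiers: keep quotes intact
  tab <- readTable(path, sep = "\t", quote = "")
  if (!all(c("Entry", "Length") %in% names(tab)))
    stop("annotation table needs 'Entry' and 'Length' columns")
  loc <- if ("Subcellular location [CC]" %in% names(tab))
    tab[["Subcellular location [CC]"]] else rep(NA_character_, nrow(tab))
  tmcol <- if ("Transmembrane" %in% names(tab)) tab[["Transmembrane"]]
    else rep(NA_character_, nrow(tab))
  topocol <- if ("Topological domain" %in% names(tab))
    tab[["Topological domain"]] else rep(NA_character_, nrow(tab))
  out <- lapply(seq_len(nrow(tab)), function(i) {
    tm <- parseFeatureIntervals(tmcol[i], "TRANSMEM")
    len <- as.integer(tab$Length[i])
    bad <- tm$start < 1L | tm$end > len | tm$start > tm$end
    if (any(bad)) {
      warning("TRANSMEM interval outside [1, length] skipped for ",
              tab$Entry[i])
      tm <- tm[!bad, , drop = FALSE]
    }
    topo <- parseFeatureIntervals(topocol[i], "TOPO_DOM")
    topo$compartment <- if (!is.null(model) && nrow(topo))
      normalizeLocation(model, topo$note) else rep(NA_character_, nrow(topo))
    ltext <- loc[i]
    if (!is.na(ltext)) {
      ltext <- sub("^SUBCELLULAR LOCATION:\\s*", "", ltext)
      if (!nzchar(trimws(ltext))) ltext <- NA_character_
    }
    list(accession = tab$Entry[i], length = len,
         location_text = ltext,
         prior_location = if (is.null(model)) NA_character_
                          else normalizeLocation(model, ltext),
         tm = tm[, c("start", "end"), drop = FALSE],
         topo = topo)
  })
  names(out) <- tab$Entry
  out
}

#' Read a TM-prediction table
#'
#' TMHMM-style tabular output: one row per predicted segment with columns
#' `accession`, `start`, `end`, `posterior` (column names remappable via
#' `dialect`). Segments are sorted per protein; overlapping segments within
#' one protein are an error.
#'
#' @param path file path.
#' @param dialect named character vector mapping the four fields to the
#'   file's column names.
#' @return named list (by accession) of data.frames
#'   `start`, `end`, `posterior`.
#' @export
readTMPredictions <- function(path,
                              dialect = c(accession = "accession",
                                          start = "start", end = "end",
                                          posterior = "posterior")) {
  tab <- readTable(path)
  miss <- setdiff(unname(dialect), names(tab))
  if (length(miss)) stop("TM prediction table missing column(s): ",
                         paste(miss, collapse = ", "))
  df <- data.frame(accession = as.character(tab[[dialect[["accession"]]]]),
                   start = as.integer(tab[[dialect[["start"]]]]),
                   end = as.integer(tab[[dialect[["end"]]]]),
                   posterior = as.numeric(tab[[dialect[["posterior"]]]]))
  if (any(df$posterior < 0 | df$posterior > 1))
    stop("posterior probabilities must lie in [0, 1]")
  lapply(split(df[, c("start", "end", "posterior")], df$accession),
         function(s) {
    s <- s[order(s$start), , drop = FALSE]
    if (nrow(s) > 1L && any(s$start[-1L] <= s$end[-nrow(s)]))
      stop("overlapping TM prediction segments")
    rownames(s) <- NULL
    s
  })
}

#' Write / read a prediction table
#'
#' Tab-separated, one row per predicted region: accession, region interval,
#' semicolon-joined supported compartment set, ambiguity status, evidence
#' basis, classification versus prior annotation, vote counts and the
#' semicolon-joined supporting-marker list. `readPredictions()` restores the
#' same data.frame, so write-then-read round-trips losslessly.
#'
#' @param predictions a prediction data.frame (from [runClasp()]'s
#'   `predictions()` accessor) or a [ClaspResult-class].
#' @param path output TSV path.
#' @return `path` invisibly; `readPredictions` returns the data.frame.
#' @export
writePredictions <- function(predictions, path) {
  if (is(predictions, "ClaspResult")) predictions <- predictions@predictions
  utils::write.table(predictions, path, sep = "\t", row.names = FALSE,
                     quote = FALSE, na = "")
  invisible(path)
}

#' @rdname writePredictions
#' @export
readPredictions <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = "", quote = "", colClasses = NA)
  for (col in c("region_start", "region_end", "n_votes", "n_supporting_lms",
                "n_consistent_neighbors"))
    if (col %in% names(df)) df[[col]] <- as.integer(df[[col]])
  for (col in c("supported", "status", "basis", "classification",
                "supporting_lms", "note", "accession"))
    if (col %in% names(df)) df[[col]] <- as.character(df[[col]])
  df
}

#' Export a cross-link network
#'
#' GraphML export carries the marker flag and compartment as node attributes
#' and the unique-residue-pair count as the edge weight; SIF export writes
#' one `A xl B` line per edge (Cytoscape-compatible).
#'
#' @param net an [XLNetwork-class].
#' @param path output file path.
#' @param format `"graphml"` or `"sif"`.
#' @param lms optional accession set to flag as markers.
#' @param compartments optional named character vector accession ->
#'   compartment written as a node attribute.
#' @return `path` invisibly.
#' @export
writeNetwork <- function(net, path, format = c("graphml", "sif"),
                         lms = NULL, compartments = NULL) {
  format <- match.arg(format)
  g <- net@graph
  nodes <- igraph::V(g)$name
  igraph::V(g)$lm <- as.integer(nodes %in% (lms %||% character()))
  igraph::V(g)$compartment <-
    if (is.null(compartments)) "" else
      ifelse(is.na(compartments[nodes]), "", compartments[nodes])
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
  } else {
    ed <- networkEdges(net)
    lines <- if (nrow(ed)) paste(ed$from, "xl", ed$to) else character()
    solo <- setdiff(nodes, c(ed$from, ed$to))
    writeLines(c(lines, solo), path)
  }
  invisible(path)
}

#' Re-import a network written by [writeNetwork()]
#'
#' @param path file path.
#' @param format `"graphml"` or `"sif"`.
#' @return an [XLNetwork-class] (SIF edges get weight 1, the format does not
#'   carry attributes).
#' @export
readNetwork <- function(path, format = c("graphml", "sif")) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    if (is.null(igraph::V(g)$name)) igraph::V(g)$name <- igraph::V(g)$id
  } else {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(lines, "[ \t]+")
    solo <- unlist(lapply(parts[lengths(parts) == 1L], `[`, 1L))
    ed <- do.call(rbind, lapply(parts[lengths(parts) >= 3L], function(p)
      data.frame(from = p[1L], to = p[3L])))
    g <- igraph::graph_from_data_frame(
      ed %||% data.frame(from = character(), to = character()),
      directed = FALSE,
      vertices = unique(c(if (!is.null(ed)) c(ed$from, ed$to), solo)))
    igraph::E(g)$weight <- rep(1, igraph::ecount(g))
  }
  new("XLNetwork", graph = g, removed = list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a PDB structure with a residue mapping
#'
#' Loads C-alpha coordinates from a PDB file and joins them with a mapping
#' table (TSV columns `accession`, `position`, `chain`, `resno`) that
#' translates protein sequence positions into structure residue numbers
#' (identity for same-sequence structures, alignment-derived for homologs).
#' Mapping rows whose structure residue lacks a C-alpha are dropped with a
#' warning and listed in the `unmapped` slot.
#'
#' @param pdb_path PDB file.
#' @param mapping_path mapping TSV.
#' @return a [StructureMap-class].
#' @export
readStructure <- function(pdb_path, mapping_path) {
  pdb <- bio3d::read.pdb(pdb_path, verbose = FALSE)
  ca <- pdb$atom[pdb$atom$elety == "CA" & pdb$atom$type == "ATOM", ,
                 drop = FALSE]
  coords <- data.frame(chain = as.character(ca$chain),
                       resno = as.integer(ca$resno),
                       x = ca$x, y = ca$y, z = ca$z)
  coords <- coords[!duplicated(paste(coords$chain, coords$resno)), ,
                   drop = FALSE]
  map <- readTable(mapping_path, sep = "\t")
  need <- c("accession", "position", "chain", "resno")
  if (!all(need %in% names(map)))
    stop("mapping table needs columns: ", paste(need, collapse = ", "))
  map$position <- as.integer(map$position)
  map$resno <- as.integer(map$resno)
  hit <- match(paste(map$chain, map$resno), paste(coords$chain, coords$resno))
  unmapped <- map[is.na(hit), , drop = FALSE]
  if (nrow(unmapped))
    warning(nrow(unmapped), " mapped residue(s) without a C-alpha dropped")
  new("StructureMap",
      pdb_id = sub("\\.pdb$", "", basename(pdb_path)),
      coords = coords,
      map = map[!is.na(hit), need, drop = FALSE],
      unmapped = unmapped)
}

setMethod("show", "StructureMap", function(object) {
  cat("StructureMap", object@pdb_id, "-", nrow(object@coords),
      "C-alpha coordinates,", nrow(object@map), "mapped residues",
      if (nrow(object@unmapped)) paste0("(", nrow(object@unmapped),
                                        " unmapped)") else "", "\n")
})
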