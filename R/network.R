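#' Build the cross-link protein-protein network
#'
#' Nodes are every protein seen in the cross-link set; one undirected edge
#' per distinct protein pair connected by inter-protein links, weighted by
#' the number of unique inter-protein residue pairs between them.
#' Intra-protein links never become edges, so proteins with only
#' intra-protein links start out isolated.
#'
#' @param crosslinks a [CrossLinkSet-class] (already deduplicated).
#' @return an [XLNetwork-class].
#' @export
buildNetwork <- function(crosslinks) {
  lk <- as.data.frame(crosslinks)
  nodes <- sort(unique(c(lk$protein_a, lk$protein_b)))
  inter <- lk[lk$protein_a != lk$protein_b, , drop = FALSE]
  if (nrow(inter)) {
    key <- paste(inter$protein_a, inter$protein_b, sep = "\r")
    tab <- table(key)
    pairs <- do.call(rbind, strsplit(names(tab), "\r", fixed = TRUE))
    edges <- data.frame(from = pairs[, 1L], to = pairs[, 2L],
                        weight = as.integer(tab))
  } else {
    edges <- data.frame(from = character(), to = character(),
                        weight = integer())
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = nodes)
  new("XLNetwork", graph = g, removed = list())
}

#' Network accessors
#'
#' `networkNodes()` returns node accessions, `networkEdges()` the edge table
#' (`from`, `to`, `weight`), `networkDegree()` the named degree vector.
#'
#' @param net an [XLNetwork-class].
#' @export
networkNodes <- function(net) igraph::V(net@graph)$name

#' @rdname networkNodes
#' @export
networkEdges <- function(net) {
  g <- net@graph
  if (igraph::ecount(g) == 0L)
    return(data.frame(from = character(), to = character(),
                      weight = integer()))
  el <- igraph::as_edgelist(g)
  data.frame(from = el[, 1L], to = el[, 2L],
             weight = igraph::E(g)$weight %||% rep(1L, nrow(el)))
}

#' @rdname networkNodes
#' @export
networkDegree <- function(net) igraph::degree(net@graph)

#' Filter the network to its well-connected core
#'
#' Removes proteins lacking inter-protein links (isolated nodes) and
#' connected components smaller than `min_component_size` proteins; the
#' removed nodes and components are recorded in the result's `removed` slot.
#' Idempotent.
#'
#' @param net an [XLNetwork-class].
#' @param min_component_size minimum component size kept (must be >= 2;
#'   the default 3 discards trivial pairs, and the value should be set
#'   deliberately per dataset).
#' @return a filtered [XLNetwork-class].
#' @export
filterNetwork <- function(net, min_component_size = 3L) {
  if (min_component_size < 2L)
    stop("min_component_size must be at least 2")
  g <- net@graph
  deg <- igraph::degree(g)
  isolated <- names(deg)[deg == 0L]
  g2 <- igraph::delete_vertices(g, isolated)
  comp <- igraph::components(g2)
  small <- which(comp$csize < min_component_size)
  dropped <- split(names(comp$membership), comp$membership)[as.character(small)]
  g3 <- igraph::delete_vertices(g2, unlist(dropped, use.names = FALSE))
  new("XLNetwork", graph = g3,
      removed = list(isolated = isolated,
                     small_components = unname(dropped),
                     min_component_size = as.integer(min_component_size)))
}

#' Rank proteins by connectivity
#'
#' Orders nodes by decreasing degree (number of distinct interaction
#' partners); degree ties break by accession lexicographic order so the
#' ranking is deterministic.
#'
#' @param net an [XLNetwork-class] (typically filtered).
#' @param top_n how many accessions to return; larger than the node count
#'   returns all with a warning.
#' @return character vector of accessions, most connected first.
#' @export
rankConnectivity <- function(net, top_n = 50L) {
  deg <- networkDegree(net)
  if (top_n > length(deg)) {
    warning("top_n exceeds node count; returning all ", length(deg),
            " proteins")
    top_n <- length(deg)
  }
  ord <- order(-deg, names(deg))
  names(deg)[ord][seq_len(top_n)]
}

#' First-tier interactors of a marker set
#'
#' All non-marker proteins directly cross-linked to at least one marker;
#' these are the proteins amenable to marker-based localization inference.
#'
#' @param net an [XLNetwork-class].
#' @param lms marker accessions (non-members of the network are ignored
#'   with a warning).
#' @return character vector of first-tier accessions.
#' @export
firstTier <- function(net, lms) {
  nodes <- networkNodes(net)
  absent <- setdiff(lms, nodes)
  if (length(absent))
    warning(length(absent), " marker(s) not in the network ignored")
  lms <- intersect(lms, nodes)
  if (!length(lms)) return(character())
  nb <- unique(unlist(lapply(
    igraph::adjacent_vertices(net@graph, lms),
    function(v) v$name), use.names = FALSE))
  sort(setdiff(nb, lms))
}

#' Marker coverage of the network
#'
#' Fraction of the network reachable by marker-based inference: markers
#' themselves plus their first-tier interactors, as a percentage of all
#' nodes.
#'
#' @param net a filtered [XLNetwork-class]; an empty network is an error.
#' @param lms marker accessions.
#' @return percentage in `[0, 100]`.
#' @export
networkCoverage <- function(net, lms) {
  nodes <- networkNodes(net)
  if (!length(nodes)) stop("coverage is undefined on an empty network")
  ft <- suppressWarnings(firstTier(net, lms))
  100 * (length(intersect(lms, nodes)) + length(ft)) / length(nodes)
}

setMethod("show", "XLNetwork", function(object) {
  g <- object@graph
  comp <- igraph::components(g)
  cat("XLNetwork:", igraph::vcount(g), "proteins,", igraph::ecount(g),
      "connections,", comp$no, "component(s)\n")
  if (length(object@removed))
    cat("  filtered: ", length(object@removed$isolated), " isolated, ",
        length(object@removed$small_components),
        " small component(s) removed (min size ",
        object@removed$min_component_size, ")\n", sep = "")
})
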