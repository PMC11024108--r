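# Brute-force oracles, deliberately written without igraph or any package
# internals, so they stay independent of the implementation they check.

# connected components by BFS over an edge list
oracleComponents <- function(nodes, edges) {
  comp <- stats::setNames(rep(NA_integer_, length(nodes)), nodes)
  adj <- lapply(stats::setNames(vector("list", length(nodes)), nodes),
                identity)
  for (i in seq_len(nrow(edges))) {
    adj[[edges$from[i]]] <- c(adj[[edges$from[i]]], edges$to[i])
    adj[[edges$to[i]]] <- c(adj[[edges$to[i]]], edges$from[i])
  }
  k <- 0L
  for (n in nodes) {
    if (!is.na(comp[n])) next
    k <- k + 1L
    queue <- n
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      if (!is.na(comp[v])) next
      comp[v] <- k
      queue <- c(queue, adj[[v]])
    }
  }
  split(names(comp), comp)
}

# nodes surviving isolated-node removal + component size filter
oracleFilter <- function(nodes, edges, min_size) {
  deg <- stats::setNames(rep(0L, length(nodes)), nodes)
  for (i in seq_len(nrow(edges))) {
    deg[edges$from[i]] <- deg[edges$from[i]] + 1L
    deg[edges$to[i]] <- deg[edges$to[i]] + 1L
  }
  keep <- names(deg)[deg > 0L]
  comps <- oracleComponents(keep, edges)
  sort(as.character(unlist(
    comps[vapply(comps, length, integer(1L)) >= min_size],
    use.names = FALSE)))
}

# non-marker nodes adjacent to at least one marker, by linear scan
oracleFirstTier <- function(edges, lms) {
  hits <- character()
  for (i in seq_len(nrow(edges))) {
    if (edges$from[i] %in% lms && !(edges$to[i] %in% lms))
      hits <- c(hits, edges$to[i])
    if (edges$to[i] %in% lms && !(edges$from[i] %in% lms))
      hits <- c(hits, edges$from[i])
  }
  sort(unique(hits))
}

oracleDegreeRank <- function(nodes, edges, top_n) {
  deg <- stats::setNames(rep(0L, length(nodes)), nodes)
  for (i in seq_len(nrow(edges))) {
    deg[edges$from[i]] <- deg[edges$from[i]] + 1L
    deg[edges$to[i]] <- deg[edges$to[i]] + 1L
  }
  ord <- order(-deg, names(deg))
  names(deg)[ord][seq_len(min(top_n, length(deg)))]
}

# enumerate both global orientations of a membrane topology and keep the
# anchor-consistent side assignments for the soluble regions
oracleOrient <- function(n_soluble, anchors, sides) {
  assignments <- list(
    rep(sides, length.out = n_soluble),
    rep(rev(sides), length.out = n_soluble))
  ok <- Filter(function(a)
    all(a[anchors$region] == anchors$compartment), assignments)
  unique(ok)
}

# random protein-pair edge list (simple graph) on n nodes
randomEdges <- function(n, p) {
  nodes <- sprintf("P%02d", seq_len(n))
  pairs <- t(utils::combn(nodes, 2L))
  keep <- stats::runif(nrow(pairs)) < p
  list(nodes = nodes,
       edges = data.frame(from = pairs[keep, 1L], to = pairs[keep, 2L],
                          stringsAsFactors = FALSE))
}

# build a CrossLinkSet realizing one inter-protein residue pair per edge
linksFromEdges <- function(edges) {
  CrossLinkSet(data.frame(
    protein_a = edges$from, residue_a = seq_len(nrow(edges)),
    protein_b = edges$to, residue_b = seq_len(nrow(edges)) + 1L))
}

# in-memory StructureMap from bare coordinates via a temporary PDB + mapping
fixtureStructure <- function(xyz, accessions = "P1",
                             positions = seq_len(nrow(xyz))) {
  pdb <- tempfile(fileext = ".pdb")
  map <- tempfile(fileext = ".tsv")
  writeFixturePdb(pdb, rep("A", nrow(xyz)), seq_len(nrow(xyz)), xyz)
  utils::write.table(data.frame(accession = accessions,
                                position = positions, chain = "A",
                                resno = seq_len(nrow(xyz))),
                     map, sep = "\t", row.names = FALSE)
  on.exit(unlink(c(pdb, map)))
  readStructure(pdb, map)
}

# tiny synthetic PDB writer: CA-only atoms at given coordinates
writeFixturePdb <- function(path, chain, resno, xyz) {
  lines <- vapply(seq_along(resno), function(i)
    sprintf("ATOM  %5d  CA  ALA %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            i, chain[i], resno[i], xyz[i, 1L], xyz[i, 2L], xyz[i, 3L]),
    character(1L))
  writeLines(c(lines, "END"), path)
}
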