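#' Build a set of unique cross-linked residue pairs
#'
#' Canonicalizes endpoint order (lexicographically smaller
#' `(protein, residue)` first) and collapses duplicate residue pairs:
#' spectral counts (`n_csm`) are summed and the best (maximum) score kept.
#'
#' @param df data.frame with columns `protein_a`, `residue_a`, `protein_b`,
#'   `residue_b` and optionally `score`, `n_csm`.
#' @return a [CrossLinkSet-class].
#' @export
CrossLinkSet <- function(df) {
  if (nrow(df) == 0L) {
    return(new("CrossLinkSet", links = data.frame(
      protein_a = character(), residue_a = integer(),
      protein_b = character(), residue_b = integer(),
      score = numeric(), n_csm = integer())))
  }
  df$protein_a <- as.character(df$protein_a)
  df$protein_b <- as.character(df$protein_b)
  df$residue_a <- as.integer(df$residue_a)
  df$residue_b <- as.integer(df$residue_b)
  if (is.null(df$score)) df$score <- NA_real_
  if (is.null(df$n_csm)) df$n_csm <- 1L
  df$score <- as.numeric(df$score)
  df$n_csm <- as.integer(ifelse(is.na(df$n_csm), 1L, df$n_csm))
  if (any(df$residue_a < 1L | df$residue_b < 1L, na.rm = TRUE) ||
      anyNA(df$residue_a) || anyNA(df$residue_b))
    stop("residue positions must be integers >= 1")

  swap <- df$protein_a > df$protein_b |
    (df$protein_a == df$protein_b & df$residue_a > df$residue_b)
  pa <- ifelse(swap, df$protein_b, df$protein_a)
  ra <- ifelse(swap, df$residue_b, df$residue_a)
  pb <- ifelse(swap, df$protein_a, df$protein_b)
  rb <- ifelse(swap, df$residue_a, df$residue_b)

  key <- paste(pa, ra, pb, rb, sep = "\r")
  grp <- match(key, unique(key))
  n_csm <- as.integer(rowsum(df$n_csm, grp)[, 1L])
  score <- vapply(split(df$score, grp), function(s)
    if (all(is.na(s))) NA_real_ else max(s, na.rm = TRUE), numeric(1L))
  first <- !duplicated(grp)
  links <- data.frame(
    protein_a = pa[first], residue_a = ra[first],
    protein_b = pb[first], residue_b = rb[first],
    score = as.numeric(score), n_csm = n_csm,
    row.names = NULL, stringsAsFactors = FALSE)
  ord <- order(links$protein_a, links$residue_a, links$protein_b,
               links$residue_b)
  new("CrossLinkSet", links = links[ord, , drop = FALSE])
}

#' @describeIn CrossLinkSet number of unique residue pairs.
#' @param x a `CrossLinkSet`.
#' @export
setMethod("length", "CrossLinkSet", function(x) nrow(x@links))

#' @export
setMethod("as.data.frame", "CrossLinkSet", function(x, ...) {
  out <- x@links
  rownames(out) <- NULL
  out
})

#' Is a link intra-protein?
#'
#' @param x a [CrossLinkSet-class].
#' @return logical vector, `TRUE` where both endpoints are on one protein.
#' @export
isIntra <- function(x) x@links$protein_a == x@links$protein_b

setMethod("show", "CrossLinkSet", function(object) {
  n <- nrow(object@links)
  cat("CrossLinkSet with", n, "unique residue pairs (",
      sum(isIntra(object)), "intra,", sum(!isIntra(object)), "inter )\n")
  if (n) print(utils::head(object@links, 4L))
})
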