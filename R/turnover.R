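# Simpson's beta species turnover between grid cells.

#' Simpson's beta dissimilarity between two species sets
#'
#' With a = |i intersect j|, b = |i \\ j|, c = |j \\ i|, Simpson's beta is
#' \deqn{\beta_{sim} = \min(b, c) / (\min(b, c) + a),}
#' which discounts richness differences between the two cells: a nested
#' pair (one set inside the other) scores 0 regardless of the richness gap,
#' and disjoint sets score 1. Low values mean many shared taxa.
#'
#' @param speciesI,speciesJ character vectors of species identifiers
#'   (non-empty; duplicates ignored).
#' @return dissimilarity in [0, 1].
#' @examples
#' simpsonBeta(c("A", "B", "C", "D", "E"), c("A", "B", "C", "F"))  # 0.25
#' @export
simpsonBeta <- function(speciesI, speciesJ) {
  speciesI <- unique(speciesI); speciesJ <- unique(speciesJ)
  if (length(speciesI) == 0L || length(speciesJ) == 0L) {
    stop("degenerate cell: empty species set")
  }
  a <- length(intersect(speciesI, speciesJ))
  b <- length(speciesI) - a
  c <- length(speciesJ) - a
  if (a == 0L) return(1)
  min(b, c) / (min(b, c) + a)
}

#' Pairwise Simpson's beta turnover matrix over all grid cells
#'
#' Computes beta for all unordered cell pairs of a site-by-species matrix
#' in one sparse cross-product (shared counts a = P P'), keeping the a, b,
#' c counts for audit. The result is independent of cell ordering up to
#' consistent relabeling.
#'
#' @param mat a [SiteBySpeciesMatrix-class]; every cell must be non-empty.
#' @return a [TurnoverMatrix-class].
#' @export
turnoverMatrix <- function(mat) {
  p <- mat@presence
  rich <- Matrix::rowSums(p)
  if (any(rich < 1)) {
    stop("degenerate cell(s) with no species: ",
         paste(utils::head(mat@cells[rich < 1], 5), collapse = ", "))
  }
  a <- as.matrix(Matrix::tcrossprod(p))
  b <- outer(as.numeric(rich), rep(1, length(rich))) - a   # unique to i
  cc <- t(b)                                               # unique to j
  mbc <- pmin(b, cc)
  beta <- ifelse(a == 0, 1, mbc / (mbc + a))
  diag(beta) <- 0
  dimnames(beta) <- list(mat@cells, mat@cells)
  storage.mode(a) <- "integer"
  storage.mode(b) <- "integer"
  storage.mode(cc) <- "integer"
  new("TurnoverMatrix", cells = mat@cells, beta = beta,
      a = a, b = b, c = cc)
}
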