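# WPGMA clustering of the turnover matrix with the Corrected Weighted
# Endemism tie-breaker, dendrogram construction, and region extraction.

#' Corrected Weighted Endemism of a cell set
#'
#' For each taxon t present in the set, the contribution is r_t / R_t where
#' r_t counts the set's cells containing t and R_t counts all matrix cells
#' containing t; weighted endemism WE is the sum of contributions and CWE is
#' WE divided by the number of taxa present in the set.
#'
#' @param cellSet character cell identifiers (non-empty, all in the matrix).
#' @param mat a [SiteBySpeciesMatrix-class].
#' @return a [CWEScore-class].
#' @examples
#' # a cell whose taxa are one endemic (range 1 cell) and one widespread
#' # (range 4 cells) scores WE = 1 + 0.25 = 1.25, CWE = 0.625
#' @export
cwe <- function(cellSet, mat) {
  idx <- match(cellSet, mat@cells)
  if (length(idx) == 0L || any(is.na(idx))) {
    stop("cellSet must be a non-empty subset of the matrix cells")
  }
  Rt <- Matrix::colSums(mat@presence)
  rt <- Matrix::colSums(mat@presence[idx, , drop = FALSE])
  present <- rt > 0
  we <- sum(rt[present] / Rt[present])
  new("CWEScore", we = we, richness = as.integer(sum(present)),
      cwe = we / sum(present))
}

# CWE value only, from precomputed global ranges (hot path of the
# tie-breaker).
.cweValue <- function(idx, presence, Rt) {
  rt <- Matrix::colSums(presence[idx, , drop = FALSE])
  present <- rt > 0
  sum(rt[present] / Rt[present]) / sum(present)
}

#' WPGMA clustering with the CWE tie-breaker
#'
#' Agglomerative clustering of the turnover matrix: at each step the pair
#' of active clusters at minimum dissimilarity is merged at a height equal
#' to that dissimilarity, and the merged cluster's distance to any other
#' cluster is the simple average of its two children's distances (WPGMA /
#' McQuitty linkage). When two or more candidate pairs tie on the minimum
#' dissimilarity (within \code{tieTol}), the pair whose union has the
#' highest CWE is merged; any remaining tie is broken by lexicographic
#' order of the union's sorted member identifiers, so repeated runs always
#' produce the identical dendrogram.
#'
#' @param turnover a [TurnoverMatrix-class] (or a plain symmetric
#'   dissimilarity matrix with dimnames, for testing).
#' @param mat the [SiteBySpeciesMatrix-class] behind the turnover matrix,
#'   used to evaluate the CWE tie-breaker. When \code{NULL}, ties fall
#'   through to the lexicographic rule alone.
#' @param tieTol dissimilarities equal within this tolerance are ties.
#' @return a [Dendrogram-class].
#' @seealso [cutRegions()], [toNewick()]
#' @export
wpgma <- function(turnover, mat = NULL, tieTol = 1e-12) {
  if (is(turnover, "TurnoverMatrix")) {
    D <- turnover@beta
    labels <- turnover@cells
  } else {
    D <- as.matrix(turnover)
    labels <- rownames(D)
    if (is.null(labels)) labels <- as.character(seq_len(nrow(D)))
  }
  n <- nrow(D)
  if (n < 2L) {
    return(new("Dendrogram", merge = matrix(integer(), 0, 2),
               height = numeric(), labels = labels))
  }
  if (any(!is.finite(D))) stop("non-finite dissimilarities in turnover matrix")
  if (!is.null(mat)) {
    if (!identical(labels, mat@cells)) {
      mat <- NULL
      warning("site matrix cells do not match turnover cells; CWE tie-breaker disabled")
    } else {
      Rt <- Matrix::colSums(mat@presence)
    }
  }

  D <- unname(D)
  diag(D) <- Inf
  code <- -seq_len(n)                 # hclust node code per active slot
  members <- as.list(seq_len(n))      # leaf indices per active slot
  keys <- labels                      # sorted-member key per active slot
  active <- rep(TRUE, n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)

  for (s in seq_len(n - 1L)) {
    dmin <- min(D)
    cand <- which(D <= dmin + tieTol, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    if (nrow(cand) > 1L) {
      pick <- seq_len(nrow(cand))
      if (!is.null(mat)) {
        scores <- vapply(pick, function(p) {
          .cweValue(c(members[[cand[p, 1]]], members[[cand[p, 2]]]),
                    mat@presence, Rt)
        }, 0)
        pick <- pick[scores >= max(scores) - tieTol]
      }
      if (length(pick) > 1L) {
        unionKey <- vapply(pick, function(p) {
          paste(sort(c(strsplit(keys[cand[p, 1]], "\037", fixed = TRUE)[[1]],
                       strsplit(keys[cand[p, 2]], "\037", fixed = TRUE)[[1]])),
                collapse = "\037")
        }, "")
        pick <- pick[order(unionKey)[1]]
      }
      cand <- cand[pick, , drop = FALSE]
    }
    i <- cand[1, 1]; j <- cand[1, 2]

    h <- D[i, j]
    if (s > 1L && h < height[s - 1L] - 1e-9) {
      stop("height inversion in WPGMA merge sequence")
    }
    height[s] <- if (s > 1L) max(h, height[s - 1L]) else h
    merge[s, ] <- c(code[i], code[j])  # slot order = first-leaf order

    newd <- (D[i, ] + D[j, ]) / 2
    D[i, ] <- newd; D[, i] <- newd
    D[i, i] <- Inf
    D[j, ] <- Inf; D[, j] <- Inf
    code[i] <- s
    members[[i]] <- c(members[[i]], members[[j]])
    keys[i] <- paste(sort(c(strsplit(keys[i], "\037", fixed = TRUE)[[1]],
                            strsplit(keys[j], "\037", fixed = TRUE)[[1]])),
                     collapse = "\037")
    active[j] <- FALSE
  }

  new("Dendrogram", merge = merge, height = height, labels = labels)
}

# Leaf order (left-to-right) of the merge tree.
dendroLeafOrder <- function(dend) {
  n <- length(dend@labels)
  if (n == 1L) return(1L)
  expand <- function(node) {
    if (node < 0) return(-node)
    c(expand(dend@merge[node, 1]), expand(dend@merge[node, 2]))
  }
  expand(n - 1L)
}

# Leaf index sets for every internal node.
.nodeLeafSets <- function(dend) {
  n <- length(dend@labels)
  sets <- vector("list", max(n - 1L, 0L))
  for (k in seq_len(n - 1L)) {
    grab <- function(v) if (v < 0) -v else sets[[v]]
    sets[[k]] <- c(grab(dend@merge[k, 1]), grab(dend@merge[k, 2]))
  }
  sets
}

# Parent merge row for every node (merge rows 1..n-1; leaves -1..-n).
.nodeParents <- function(dend) {
  n <- length(dend@labels)
  parentOfMerge <- rep(NA_integer_, max(n - 1L, 0L))
  parentOfLeaf <- rep(NA_integer_, n)
  for (k in seq_len(n - 1L)) {
    for (v in dend@merge[k, ]) {
      if (v < 0) parentOfLeaf[-v] <- k else parentOfMerge[v] <- k
    }
  }
  list(merge = parentOfMerge, leaf = parentOfLeaf)
}

#' Extract regions from the dendrogram
#'
#' Two extraction modes, exactly one of which must be supplied:
#' \describe{
#'   \item{\code{k}}{cut the tree into exactly k clusters at the
#'     appropriate height.}
#'   \item{\code{minBranch}}{report the maximal clusters whose subtending
#'     branch length (parent merge height minus own height; leaves have
#'     height 0) is at least \code{minBranch}; cells in no such cluster
#'     are left unlabeled.}
#' }
#' Diagnostics give, per cluster, its subtending branch length and a
#' contiguity score: the size of its largest adjacency-connected component
#' divided by cluster size (rook adjacency on the grid; 1 = fully
#' contiguous).
#'
#' @param dend a [Dendrogram-class].
#' @param k number of regions.
#' @param minBranch branch-length separation threshold (turnover units).
#' @param adjacency optional 2-column matrix of adjacent cell-id pairs;
#'   derived from the cell identifiers when \code{NULL}.
#' @return list with \code{classification} (a
#'   [RegionClassification-class]) and \code{diagnostics} (data.frame:
#'   region, size, branchLength, contiguity).
#' @export
cutRegions <- function(dend, k = NULL, minBranch = NULL, adjacency = NULL) {
  if (is.null(k) == is.null(minBranch)) {
    stop("supply exactly one of k or minBranch")
  }
  n <- length(dend@labels)
  if (!is.null(k) && (k < 1L || k > n)) {
    stop("k must lie in [1, number of cells]")
  }
  sets <- .nodeLeafSets(dend)
  parents <- .nodeParents(dend)

  if (!is.null(k)) {
    grp <- if (n == 1L) 1L else stats::cutree(as.hclust.Dendrogram(dend), k = k)
    labelsPerCell <- sprintf("R%02d", grp)
    clusters <- split(seq_len(n), labelsPerCell)
  } else {
    # branch length of every node; root excluded (no subtending branch)
    blMerge <- ifelse(is.na(parents$merge), -Inf,
                      dend@height[parents$merge] - dend@height)
    blLeaf <- dend@height[parents$leaf]
    selected <- integer()      # merge rows
    selectedLeaves <- integer()
    covered <- logical(n)
    # parents always carry a larger merge index, so reverse merge order
    # visits ancestors before descendants even under tied heights
    for (kk in rev(seq_len(n - 1L))) {
      if (is.finite(blMerge[kk]) && blMerge[kk] >= minBranch &&
          !any(covered[sets[[kk]]])) {
        selected <- c(selected, kk)
        covered[sets[[kk]]] <- TRUE
      }
    }
    for (lf in seq_len(n)) {
      if (!covered[lf] && !is.na(parents$leaf[lf]) &&
          blLeaf[lf] >= minBranch) {
        selectedLeaves <- c(selectedLeaves, lf)
        covered[lf] <- TRUE
      }
    }
    labelsPerCell <- rep(NA_character_, n)
    ri <- 0L
    clusters <- list()
    for (kk in selected) {
      ri <- ri + 1L
      lab <- sprintf("R%02d", ri)
      labelsPerCell[sets[[kk]]] <- lab
      clusters[[lab]] <- sets[[kk]]
    }
    for (lf in selectedLeaves) {
      ri <- ri + 1L
      lab <- sprintf("R%02d", ri)
      labelsPerCell[lf] <- lab
      clusters[[lab]] <- lf
    }
  }

  if (is.null(adjacency)) {
    adjacency <- tryCatch(cellAdjacency(dend@labels),
                          error = function(e) NULL)
  }

  diag <- do.call(rbind, lapply(names(clusters), function(lab) {
    idx <- clusters[[lab]]
    # subtree root of this cluster: deepest node containing exactly idx
    if (length(idx) == 1L) {
      h <- 0
      par <- parents$leaf[idx]
    } else {
      node <- which(vapply(sets, function(s) {
        length(s) == length(idx) && all(sort(s) == sort(idx))
      }, TRUE))[1]
      h <- if (is.na(node)) NA_real_ else dend@height[node]
      par <- if (is.na(node)) NA_integer_ else parents$merge[node]
    }
    bl <- if (is.na(par)) NA_real_ else dend@height[par] - h
    contig <- if (is.null(adjacency)) NA_real_ else {
      largestComponent(dend@labels[idx], adjacency) / length(idx)
    }
    data.frame(region = lab, size = length(idx), branchLength = bl,
               contiguity = contig, stringsAsFactors = FALSE)
  }))

  list(classification = regionClassification(
         dend@labels, labelsPerCell,
         provenance = c(list(method = "wpgma_cut"),
                        if (!is.null(k)) list(k = k) else list(minBranch = minBranch))),
       diagnostics = diag)
}

#' Serialize a dendrogram to Newick text
#'
#' Branch lengths are height differences between each node and its parent;
#' a parse-then-serialize round trip preserves topology and lengths.
#'
#' @param dend a [Dendrogram-class].
#' @param digits significant digits for branch lengths.
#' @return single Newick string (terminated with ";").
#' @examples
#' d <- wpgma(matrix(c(0, .2, .6, .2, 0, .4, .6, .4, 0), 3,
#'            dimnames = list(c("x", "y", "z"), c("x", "y", "z"))))
#' toNewick(d)  # "((x:0.2,y:0.2):0.3,z:0.5);"
#' @export
toNewick <- function(dend, digits = 10) {
  n <- length(dend@labels)
  fmt <- function(v) sprintf("%.*g", digits, v)
  if (n == 1L) return(paste0(dend@labels, ":0.0;"))
  build <- function(node, parentH) {
    if (node < 0) {
      return(paste0(dend@labels[-node], ":", fmt(parentH)))
    }
    h <- dend@height[node]
    inner <- paste(build(dend@merge[node, 1], h),
                   build(dend@merge[node, 2], h), sep = ",")
    if (is.na(parentH)) paste0("(", inner, ")")
    else paste0("(", inner, "):", fmt(parentH - h))
  }
  paste0(build(n - 1L, NA), ";")
}
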