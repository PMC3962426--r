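# Internal helpers shared across modules.

# Evaluate expr under a local RNG stream; the caller's RNG state is untouched.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Deterministic sub-seed derivation, bounded below 2^31.
subSeed <- function(seed, k) {
  ((as.numeric(seed) %% 59999) * 31013 + 7919 * k) %% 2147483647
}

# Row-major cell identifier; zero-padded so lexicographic order equals
# (row, col) order.
cellId <- function(row, col) sprintf("r%03d_c%03d", row, col)

cellRowCol <- function(ids) {
  m <- regmatches(ids, regexec("^r([0-9]+)_c([0-9]+)$", ids))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) stop("malformed cell identifier(s): ",
                     paste(utils::head(ids[bad], 5), collapse = ", "))
  data.frame(row = as.integer(vapply(m, `[`, "", 2L)),
             col = as.integer(vapply(m, `[`, "", 3L)))
}

# Rook (4-neighbour) adjacency between the given cell ids, as a 2-column
# matrix of cell-id pairs.
cellAdjacency <- function(ids) {
  rc <- cellRowCol(ids)
  key <- function(r, c) paste(r, c, sep = ",")
  idx <- stats::setNames(seq_along(ids), key(rc$row, rc$col))
  pairs <- NULL
  for (d in list(c(1L, 0L), c(0L, 1L))) {
    nb <- idx[key(rc$row + d[1], rc$col + d[2])]
    ok <- !is.na(nb)
    if (any(ok)) pairs <- rbind(pairs, cbind(seq_along(ids)[ok], nb[ok]))
  }
  if (is.null(pairs)) return(matrix(character(), 0, 2))
  cbind(ids[pairs[, 1]], ids[pairs[, 2]])
}

# Size of the largest connected component among `members` under the given
# adjacency pairs, via BFS.
largestComponent <- function(members, adjacency) {
  if (length(members) <= 1L) return(length(members))
  inset <- stats::setNames(seq_along(members), members)
  nbrs <- vector("list", length(members))
  keep <- adjacency[, 1] %in% members & adjacency[, 2] %in% members
  if (any(keep)) {
    e1 <- inset[adjacency[keep, 1]]; e2 <- inset[adjacency[keep, 2]]
    for (i in seq_along(e1)) {
      nbrs[[e1[i]]] <- c(nbrs[[e1[i]]], e2[i])
      nbrs[[e2[i]]] <- c(nbrs[[e2[i]]], e1[i])
    }
  }
  seen <- logical(length(members))
  best <- 0L
  for (s in seq_along(members)) {
    if (seen[s]) next
    queue <- s; seen[s] <- TRUE; size <- 0L
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]; size <- size + 1L
      for (w in nbrs[[v]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
    }
    best <- max(best, size)
  }
  best
}

#' Best-case label agreement between two classifications
#'
#' Fraction of cells on which two label vectors agree after optimally
#' matching the label sets (exhaustive search over label permutations, so
#' intended for small numbers of labels as produced by region cuts).
#'
#' @param labels,reference label vectors over the same cells (same order).
#' @return agreement fraction in [0, 1].
#' @examples
#' matchedAgreement(c("a", "a", "b"), c("x", "x", "y"))  # 1
#' @export
matchedAgreement <- function(labels, reference) {
  stopifnot(length(labels) == length(reference))
  ok <- !is.na(labels) & !is.na(reference)
  labels <- labels[ok]; reference <- reference[ok]
  ul <- sort(unique(labels)); ur <- sort(unique(reference))
  if (length(ul) > 8L || length(ur) > 8L) {
    stop("matchedAgreement uses exhaustive matching; too many labels")
  }
  conf <- table(factor(labels, ul), factor(reference, ur))
  # pad to square so a permutation exists
  k <- max(length(ul), length(ur))
  m <- matrix(0, k, k)
  m[seq_along(ul), seq_along(ur)] <- conf
  perms <- permutations(k)
  best <- 0
  for (i in seq_len(nrow(perms))) {
    s <- sum(m[cbind(seq_len(k), perms[i, ])])
    if (s > best) best <- s
  }
  best / length(labels)
}

permutations <- function(k) {
  if (k == 1L) return(matrix(1L, 1, 1))
  sub <- permutations(k - 1L)
  out <- matrix(0L, 0, k)
  for (i in seq_len(k)) {
    rest <- setdiff(seq_len(k), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  out
}
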