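#' Symmetry-operation distance matrix
#'
#' `A[i, j] = |T Q_i - Q_j|^2` on the centered coordinates. Entries pairing
#' atoms of different equivalence classes are masked to `Inf`, so any finite
#' assignment respects element and environment classes.
#'
#' @param mol a [molecule()] (re-centered internally).
#' @param op a [operation_matrix()] result.
#' @param partition optional [equivalence_classes()]; computed if missing.
#' @param mask_classes set `FALSE` to skip the class mask.
#' @return N x N matrix with attribute `classes`.
#' @export
distance_matrix <- function(mol, op, partition = NULL, mask_classes = TRUE) {
  q <- sweep(mol$coords, 2, colMeans(mol$coords))
  tq <- q %*% t(op$matrix)
  a <- outer(rowSums(tq^2), rowSums(q^2), `+`) - 2 * tcrossprod(tq, q)
  a[a < 0] <- 0
  classes <- NULL
  if (mask_classes) {
    if (is.null(partition)) partition <- equivalence_classes(mol)
    classes <- partition$class_id
    a[outer(classes, classes, `!=`)] <- Inf
  }
  attr(a, "classes") <- classes
  a
}

#' Greedy assignment on a distance matrix
#'
#' Repeatedly selects the globally smallest remaining entry `A[i0, j0]`, sets
#' `pi(i0) = j0`, and greys out that row and column. Ties break to the lowest
#' row, then column, index.
#'
#' @param A square cost matrix (Inf = forbidden).
#' @return list with `perm` (integer), `cost` (sum of selected entries) and
#'   `method = "greedy"`.
#' @export
greedy_assignment <- function(A) {
  a <- unclass(A)
  attr(a, "classes") <- NULL
  n <- nrow(a)
  perm <- integer(n)
  for (step in seq_len(n)) {
    m <- suppressWarnings(min(a))
    if (!is.finite(m)) stop("greedy assignment infeasible: no finite entry left")
    idx <- which(a == m, arr.ind = TRUE)
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    i0 <- idx[1, 1]; j0 <- idx[1, 2]
    perm[i0] <- j0
    a[i0, ] <- Inf
    a[, j0] <- Inf
  }
  list(perm = perm, cost = sum(A[cbind(seq_len(n), perm)]), method = "greedy")
}

# Jonker-Volgenant style shortest-augmenting-path solver for the linear
# assignment problem (square, finite costs). Column index 1 is the virtual
# unmatched column; real columns live at 2..n+1.
solve_lap <- function(a) {
  n <- nrow(a)
  u <- numeric(n)
  v <- numeric(n + 1L)
  p <- integer(n + 1L)
  way <- integer(n + 1L)
  cols <- 2:(n + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 1L
    minv <- rep(Inf, n + 1L)
    used <- logical(n + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      jr <- cols[!used[cols]]
      cur <- a[i0, jr - 1L] - u[i0] - v[jr]
      upd <- cur < minv[jr]
      if (any(upd)) {
        minv[jr[upd]] <- cur[upd]
        way[jr[upd]] <- j0
      }
      k <- which.min(minv[jr])
      j1 <- jr[k]
      delta <- minv[j1]
      uj <- which(used)
      u[p[uj]] <- u[p[uj]] + delta
      v[uj] <- v[uj] - delta
      minv[!used] <- minv[!used] - delta
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  perm <- integer(n)
  perm[p[cols]] <- cols - 1L
  perm
}

#' Hungarian (optimal) assignment on a distance matrix
#'
#' Returns a global minimizer of `sum_i A[i, pi(i)]`; its cost is never above
#' the greedy cost on the same matrix. Class-masked matrices (from
#' [distance_matrix()]) are solved block-by-block within each class.
#'
#' @param A square cost matrix, optionally with a `classes` attribute.
#' @param classes optional per-row class ids overriding the attribute.
#' @return list with `perm`, `cost` and `method = "hungarian"`.
#' @export
hungarian_assignment <- function(A, classes = NULL) {
  if (is.null(classes)) classes <- attr(A, "classes")
  n <- nrow(A)
  if (is.null(classes)) {
    if (any(!is.finite(A))) {
      stop("Hungarian assignment on a masked matrix needs class ids")
    }
    classes <- rep(1L, n)
  }
  perm <- integer(n)
  for (cl in unique(classes)) {
    idx <- which(classes == cl)
    sub <- A[idx, idx, drop = FALSE]
    if (any(!is.finite(sub))) stop("infeasible assignment block (class ", cl, ")")
    perm[idx] <- idx[solve_lap(unclass(sub))]
  }
  list(perm = perm, cost = sum(A[cbind(seq_len(n), perm)]),
       method = "hungarian")
}
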