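#' Specify a cyclic point group
#'
#' The measurable groups are the cyclic groups generated by one proper rotation
#' (C_n, n >= 2) or one improper rotation (S_n with n = 1 or n even; S1 is the
#' mirror group C_s and S2 the inversion group C_i).
#'
#' @param label a string such as `"C5"`, `"c2"`, `"S4"`, `"Cs"`, `"Ci"`.
#' @return object of class `molsym_group`: list with `family` (`"C"` or
#'   `"S"`), `n` (order parameter of the generator), `order` (size g of the
#'   generated group) and `label`.
#' @export
point_group <- function(label) {
  if (inherits(label, "molsym_group")) return(label)
  s <- tolower(trimws(as.character(label)[1]))
  if (s == "cs") s <- "s1"
  if (s == "ci") s <- "s2"
  m <- regmatches(s, regexec("^([cs])([0-9]+)$", s))[[1]]
  if (length(m) != 3L) stop("cannot parse point group '", label, "'")
  family <- toupper(m[2])
  n <- as.integer(m[3])
  if (family == "C" && n < 2L) {
    stop("C_n requires n >= 2 (use 'Cs' for the mirror group)")
  }
  if (family == "S" && !(n == 1L || n %% 2L == 0L)) {
    stop("S_n requires n = 1 or n even")
  }
  g <- if (family == "S" && n <= 2L) 2L else n
  lab <- if (family == "S" && n == 1L) "Cs"
         else if (family == "S" && n == 2L) "Ci"
         else paste0(family, n)
  structure(list(family = family, n = n, order = g, label = lab),
            class = "molsym_group")
}

is_improper <- function(spec) spec$family == "S"
is_inversion <- function(spec) spec$family == "S" && spec$n == 2L

#' @export
print.molsym_group <- function(x, ...) {
  cat(sprintf("<point group %s (family %s, n = %d, group order %d)>\n",
              x$label, x$family, x$n, x$order))
  invisible(x)
}

unit_vector <- function(v) {
  nv <- sqrt(sum(v^2))
  if (nv < 1e-14) stop("axis vector must be non-zero")
  v / nv
}

# Canonical sign: first component of magnitude > 1e-9 made positive.
canonical_axis <- function(v) {
  for (k in 1:3) {
    if (abs(v[k]) > 1e-9) {
      if (v[k] < 0) v <- -v
      break
    }
  }
  v
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

rotation_about <- function(axis, angle) {
  v <- unit_vector(axis)
  K <- matrix(c(0, v[3], -v[2],
                -v[3], 0, v[1],
                v[2], -v[1], 0), 3, 3)   # column-major: K %*% x = v x x
  diag(3) * cos(angle) + sin(angle) * K + (1 - cos(angle)) * tcrossprod(v)
}

reflection_through <- function(axis) {
  v <- unit_vector(axis)
  diag(3) - 2 * tcrossprod(v)
}

#' Build a symmetry operation matrix
#'
#' For C_n: proper rotation by 360/n degrees about `axis` (Rodrigues formula).
#' For S_n: the same rotation composed with reflection through the plane
#' normal to `axis`; S1 is a pure reflection and S2 the inversion -I.
#'
#' @param spec a [point_group()] (or parseable label).
#' @param axis direction vector (normalized internally).
#' @return object of class `molsym_operation`: list with `spec`, unit `axis`,
#'   and the 3 x 3 orthogonal `matrix` (det +1 proper, -1 improper).
#' @export
operation_matrix <- function(spec, axis = c(0, 0, 1)) {
  spec <- point_group(spec)
  v <- unit_vector(axis)
  angle <- 2 * pi / spec$n
  m <- rotation_about(v, angle)
  if (is_improper(spec)) m <- m %*% reflection_through(v)
  structure(list(spec = spec, axis = v, matrix = m),
            class = "molsym_operation")
}

# i-th power of the generator: rotation by i*angle, improper when the family
# is S and i is odd.
operation_power <- function(spec, axis, i) {
  angle <- 2 * pi * i / spec$n
  m <- rotation_about(axis, angle)
  if (is_improper(spec) && i %% 2L == 1L) m <- m %*% reflection_through(axis)
  m
}

perm_power <- function(perm, i) {
  p <- seq_along(perm)
  for (k in seq_len(i)) p <- perm[p]
  p
}

cycle_lengths <- function(perm) {
  n <- length(perm)
  seen <- logical(n)
  out <- integer(0)
  for (i in seq_len(n)) {
    if (!seen[i]) {
      len <- 0L
      j <- i
      repeat {
        seen[j] <- TRUE
        len <- len + 1L
        j <- perm[j]
        if (j == i) break
      }
      out <- c(out, len)
    }
  }
  out
}

is_cycle_valid <- function(perm, spec) {
  all(cycle_lengths(perm) %in% allowed_cycle_lengths(spec))
}

# Single-operation objective prefactor. The full objective averages the i-th
# power terms with weight 1/(2g); keeping only the i = 1 term, the factor that
# reproduces the full value exactly for involutions under an order-2 group is
# 1/4 (= 1/(2g)), while for n > 2 the single term stands in for the n - 1
# nonzero ones and the conventional 1/2 is used.
m_hat_factor <- function(spec) if (spec$order <= 2L) 0.25 else 0.5

#' Evaluate the symmetry objective M for a fixed permutation and operation
#'
#' `mode = "full"` computes the complete group-averaged objective
#' M = (1/2g) * sum_{i=1..g} sum_k |T^i Q_k - Q_{pi^i(k)}|^2, the quantity the
#' measure `S = 100 M / D` is defined from. `mode = "single"` computes the
#' one-operation surrogate M-hat used by the approximate search engines; for
#' order-2 groups (C2, Cs, Ci) it equals the full value whenever the
#' permutation is an involution.
#'
#' @param mol a [molecule()] (re-centered internally).
#' @param perm integer permutation of the atoms.
#' @param op a [operation_matrix()] result.
#' @param mode `"full"` or `"single"`.
#' @return scalar objective value (angstrom squared).
#' @export
symmetry_objective <- function(mol, perm, op, mode = c("full", "single")) {
  mode <- match.arg(mode)
  n <- n_atoms(mol)
  if (length(perm) != n) stop("permutation size does not match atom count")
  q <- sweep(mol$coords, 2, colMeans(mol$coords))
  spec <- op$spec
  if (mode == "single") {
    tq <- q %*% t(op$matrix)
    return(m_hat_factor(spec) * sum((tq - q[perm, , drop = FALSE])^2))
  }
  g <- spec$order
  total <- 0
  p_i <- seq_len(n)
  for (i in seq_len(g)) {
    p_i <- perm[p_i]
    ti <- operation_power(spec, op$axis, i)
    total <- total + sum((q %*% t(ti) - q[p_i, , drop = FALSE])^2)
  }
  total / (2 * g)
}

#' Convert an objective value to the 0-100 symmetry measure
#'
#' @param M objective value (angstrom squared).
#' @param D normalization factor from [normalization_factor()].
#' @return `100 * M / D`.
#' @export
csm_value <- function(M, D) {
  if (!is.finite(D) || D <= 0) stop("degenerate geometry: D must be positive")
  100 * M / D
}

#' Nearest symmetric structure by orbit averaging
#'
#' For a fixed operation T and permutation pi, the T-invariant structure
#' closest to Q (in summed squared displacement) is the orbit average
#' P_k = (1/g) * sum_{i=0..g-1} T^{-i} Q_{pi^i(k)}. When pi's cycle lengths
#' are compatible with the group (see [allowed_cycle_lengths()]) the result
#' satisfies T P_k = P_{pi(k)} and sum |Q_k - P_k|^2 equals the full
#' objective; for other permutations the same formula is returned with
#' `cycle_valid = FALSE` and no invariance guarantee.
#'
#' @param mol a [molecule()] (re-centered internally).
#' @param perm integer permutation.
#' @param op a [operation_matrix()] result.
#' @return list with `coords` (N x 3) and `cycle_valid`.
#' @export
nearest_symmetric_structure <- function(mol, perm, op) {
  n <- n_atoms(mol)
  q <- sweep(mol$coords, 2, colMeans(mol$coords))
  spec <- op$spec
  g <- spec$order
  p <- q   # i = 0 term
  p_i <- seq_len(n)
  for (i in seq_len(g - 1L)) {
    p_i <- perm[p_i]
    ti <- operation_power(spec, op$axis, i)
    # rows are coordinates: T^{-i} Q_k as a row is Q_k %*% t(T^{-i}) = Q_k %*% T^i
    p <- p + q[p_i, , drop = FALSE] %*% ti
  }
  list(coords = p / g, cycle_valid = is_cycle_valid(perm, spec))
}

#' Fibonacci lattice of near-uniform unit directions
#'
#' Deterministic set of M unit vectors spread almost evenly over the sphere:
#' u_k = (x, r cos theta, r sin theta) with theta = pi (sqrt(5) + 1) k,
#' x = 1 - 2k/(M-1), r = sqrt(1 - x^2), k = 0..M-1. Used as multistart
#' directions for the symmetry axis.
#'
#' @param M number of directions (>= 2).
#' @return object of class `molsym_directions`: list with `vectors` (M x 3)
#'   and `origin = "fibonacci"`.
#' @export
fibonacci_lattice <- function(M) {
  M <- as.integer(M)
  if (is.na(M) || M < 2L) stop("Fibonacci lattice needs M >= 2")
  k <- 0:(M - 1L)
  theta <- pi * (sqrt(5) + 1) * k
  x <- 1 - 2 * k / (M - 1)
  r <- sqrt(pmax(0, 1 - x^2))
  structure(list(vectors = cbind(x, r * cos(theta), r * sin(theta),
                                 deparse.level = 0),
                 origin = "fibonacci"),
            class = "molsym_directions")
}

#' Educated initial axis guesses from equivalence-class centroids
#'
#' Fits the best line and best plane (via SVD) through the centroids of the
#' atom equivalence classes, after dropping outlying centroids (largest plane
#' residual while it exceeds twice the median residual, at most 20% of the
#' centroids). Emits the line direction, the plane normal, and two mutually
#' perpendicular complements of each, deduplicated up to sign. With fewer than
#' two distinct centroids, falls back to the coordinate axes.
#'
#' @param mol a [molecule()].
#' @param partition optional [equivalence_classes()] result.
#' @return a `molsym_directions` object with `origin = "educated_guess"`.
#' @export
initial_direction_guesses <- function(mol, partition = NULL) {
  if (is.null(partition)) partition <- equivalence_classes(mol)
  cls <- partition$class_id
  cent <- do.call(rbind, lapply(seq_len(max(cls)), function(cl) {
    colMeans(mol$coords[cls == cl, , drop = FALSE])
  }))
  cent <- unique(round(cent, 12))
  dirs <- list()
  if (nrow(cent) >= 2L &&
      max(stats::dist(cent)) > 1e-9) {
    cent <- remove_centroid_outliers(cent)
    cc <- sweep(cent, 2, colMeans(cent))
    sv <- svd(cc)
    line_dir <- sv$v[, 1]
    dirs <- c(dirs, list(line_dir))
    if (nrow(cent) >= 3L && sv$d[2] > 1e-9 * max(sv$d[1], 1)) {
      dirs <- c(dirs, list(sv$v[, 3]))   # plane normal
    }
  }
  if (!length(dirs)) {
    dirs <- list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  } else {
    # two perpendicular complements per candidate, spanning 3-space
    base <- dirs
    for (v in base) dirs <- c(dirs, perpendicular_pair(v))
  }
  vecs <- do.call(rbind, lapply(dirs, function(v) canonical_axis(unit_vector(v))))
  vecs <- unique(round(vecs, 10))
  structure(list(vectors = vecs, origin = "educated_guess"),
            class = "molsym_directions")
}

perpendicular_pair <- function(v) {
  v <- unit_vector(v)
  ref <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  a <- unit_vector(cross3(v, ref))
  b <- cross3(v, a)
  list(a, b)
}

remove_centroid_outliers <- function(cent) {
  max_drop <- floor(0.2 * nrow(cent))
  dropped <- 0L
  while (dropped < max_drop && nrow(cent) >= 4L) {
    cc <- sweep(cent, 2, colMeans(cent))
    normal <- svd(cc)$v[, 3]
    res <- abs(cc %*% normal)
    med <- stats::median(res)
    if (med <= 1e-12 || max(res) <= 2 * med) break
    cent <- cent[-which.max(res), , drop = FALSE]
    dropped <- dropped + 1L
  }
  cent
}
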