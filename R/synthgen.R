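# Deterministic synthetic molecules with known symmetry, so every engine is
# testable without external structure downloads. All generators are pure:
# the same arguments always give the bit-identical molecule.

with_preserved_rng <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Regular n-ring with exact C_n symmetry
#'
#' @param n ring size (>= 3).
#' @param radius ring radius, angstrom.
#' @param element element symbol for every atom.
#' @return a [molecule()] in the z = 0 plane with ring bonds; S(C_n) = 0 by
#'   construction.
#' @export
make_ring <- function(n, radius = 1.4, element = "C") {
  n <- as.integer(n)
  stopifnot(n >= 3L)
  ang <- 2 * pi * (seq_len(n) - 1L) / n
  coords <- cbind(radius * cos(ang), radius * sin(ang), 0)
  bonds <- cbind(seq_len(n), c(seq_len(n)[-1], 1L))
  molecule(rep(element, n), coords, bonds, name = sprintf("ring%d", n))
}

#' n-gonal prism with exact C_n symmetry
#'
#' Two stacked regular n-rings joined by vertical bonds.
#'
#' @param n ring size (>= 3).
#' @param radius ring radius, angstrom.
#' @param height separation of the two rings, angstrom.
#' @param element element symbol.
#' @return a [molecule()] with 2n atoms and 3n bonds.
#' @export
make_prism <- function(n, radius = 1.4, height = 1.4, element = "C") {
  n <- as.integer(n)
  stopifnot(n >= 3L)
  ang <- 2 * pi * (seq_len(n) - 1L) / n
  top <- cbind(radius * cos(ang), radius * sin(ang), height / 2)
  bot <- cbind(radius * cos(ang), radius * sin(ang), -height / 2)
  ring <- cbind(seq_len(n), c(seq_len(n)[-1], 1L))
  bonds <- rbind(ring, ring + n, cbind(seq_len(n), seq_len(n) + n))
  molecule(rep(element, 2L * n), rbind(top, bot), bonds,
           name = sprintf("prism%d", n))
}

#' The C60 truncated-icosahedron cage
#'
#' 60 carbon atoms on the vertices of the truncated icosahedron (the vertex
#' orbit of (0, +-1, +-3 phi) with phi the golden ratio, under cyclic
#' coordinate permutation and the other two standard orbits), scaled to a
#' 1.4 angstrom edge, with the 3-regular 90-edge bond graph. All 60 atoms fall
#' in one equivalence class.
#'
#' @return a [molecule()].
#' @export
make_truncated_icosahedron <- function() {
  phi <- (1 + sqrt(5)) / 2
  base <- rbind(
    expand_signs(c(0, 1, 3 * phi)),
    expand_signs(c(1, 2 + phi, 2 * phi)),
    expand_signs(c(phi, 2, 2 * phi + 1))
  )
  coords <- unique(do.call(rbind, lapply(seq_len(nrow(base)), function(k) {
    v <- base[k, ]
    rbind(v, v[c(3, 1, 2)], v[c(2, 3, 1)])
  })))
  stopifnot(nrow(coords) == 60L)
  coords <- coords * (1.4 / 2)      # native edge length is 2
  d <- as.matrix(stats::dist(coords))
  edge <- min(d[d > 1e-9])
  bonds <- which(d <= edge * 1.01 & upper.tri(d), arr.ind = TRUE)
  molecule(rep("C", 60L), coords, bonds, name = "C60")
}

expand_signs <- function(v) {
  nz <- which(abs(v) > 1e-12)
  signs <- as.matrix(expand.grid(rep(list(c(1, -1)), length(nz))))
  out <- matrix(rep(v, each = nrow(signs)), nrow(signs), 3)
  out[, nz] <- out[, nz] * signs
  out
}

#' Two bonded atoms of distinct elements
#'
#' The minimal fixture whose only admissible inversion permutation is the
#' identity: its nearest inversion-symmetric structure collapses to the
#' center, giving S(C_i) = 100 exactly.
#'
#' @param elements two distinct element symbols.
#' @param separation bond length, angstrom.
#' @return a [molecule()].
#' @export
make_two_element_pair <- function(elements = c("N", "O"), separation = 1.4) {
  stopifnot(length(elements) == 2L, elements[1] != elements[2])
  coords <- rbind(c(separation / 2, 0, 0), c(-separation / 2, 0, 0))
  molecule(elements, coords, cbind(1L, 2L), name = "pair")
}

#' A small chiral test structure
#'
#' Four atoms of four distinct elements on an irregular (scalene) tetrahedron
#' with a small seeded jitter: no improper symmetry, so the chirality measure
#' is strictly positive. Its mirror image has the identical measure, and
#' flattening it into a plane makes it achiral (S(C_s) = 0).
#'
#' @param seed integer seed for the jitter.
#' @return a [molecule()] with a central-atom star bond graph.
#' @export
make_chiral_toy <- function(seed = 1L) {
  base <- rbind(
    c(0.0, 0.0, 0.0),
    c(1.6, 0.0, 0.0),
    c(0.5, 1.4, 0.0),
    c(0.4, 0.5, 1.3)
  )
  jitter <- with_preserved_rng(seed, matrix(stats::rnorm(12, sd = 0.05), 4, 3))
  molecule(c("C", "N", "O", "S"), base + jitter,
           cbind(1L, 2:4), name = "chiral_toy")
}

#' Add seeded Gaussian coordinate noise
#'
#' Independent zero-mean normal displacements of standard deviation `sigma`
#' are added to every coordinate. Bonds are unchanged. The global RNG state is
#' left untouched.
#'
#' @param mol a [molecule()].
#' @param sigma noise standard deviation, angstrom (>= 0).
#' @param seed integer seed.
#' @return the distorted molecule.
#' @export
distort <- function(mol, sigma, seed = 1L) {
  stopifnot(sigma >= 0)
  if (sigma == 0) return(mol)
  n <- n_atoms(mol)
  noise <- with_preserved_rng(seed, matrix(stats::rnorm(3 * n, sd = sigma), n, 3))
  mol$coords <- mol$coords + noise
  mol
}
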