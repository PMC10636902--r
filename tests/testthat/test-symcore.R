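test_that("point group parsing and aliases", {
  expect_equal(point_group("C5")$order, 5L)
  expect_equal(point_group("cs")$n, 1L)
  expect_equal(point_group("Cs")$order, 2L)
  expect_equal(point_group("Ci")$order, 2L)
  expect_equal(point_group("S1")$label, "Cs")
  expect_equal(point_group("S2")$label, "Ci")
  expect_equal(point_group("S4")$order, 4L)
  expect_error(point_group("C1"), "n >= 2")
  expect_error(point_group("S3"), "even")
  expect_error(point_group("banana"), "parse")
})

test_that("operation matrices have the defining closed forms", {
  expect_equal(operation_matrix("Ci", c(1, 2, 3))$matrix, -diag(3))
  expect_equal(operation_matrix("C2", c(0, 0, 1))$matrix,
               diag(c(-1, -1, 1)), tolerance = 1e-12)
  # Cs about z: reflection through the xy plane
  expect_equal(operation_matrix("Cs", c(0, 0, 1))$matrix,
               diag(c(1, 1, -1)), tolerance = 1e-12)

  set.seed(3)
  ax <- rnorm(3)
  op5 <- operation_matrix("C5", ax)
  expect_equal(det(op5$matrix), 1, tolerance = 1e-12)
  expect_equal(sum(diag(op5$matrix)), 1 + 2 * cos(2 * pi / 5),
               tolerance = 1e-12)
  expect_equal(crossprod(op5$matrix), diag(3), tolerance = 1e-12)

  # T^g = identity, det = -1 for improper generators
  for (lab in c("C2", "C3", "C6", "Cs", "Ci", "S4", "S6")) {
    spec <- point_group(lab)
    op <- operation_matrix(spec, c(0.3, -0.5, 0.81))
    expect_equal(det(op$matrix), if (spec$family == "S") -1 else 1,
                 tolerance = 1e-12)
    tg <- diag(3)
    for (i in seq_len(spec$order)) tg <- op$matrix %*% tg
    expect_equal(tg, diag(3), tolerance = 1e-9)
  }
})

test_that("symmetry objective matches direct summation and known cases", {
  # perfect C3 ring with the rotation permutation: objective 0
  ring <- center_molecule(make_ring(3))
  op <- operation_matrix("C3", c(0, 0, 1))
  expect_lt(symmetry_objective(ring, c(2, 3, 1), op, "full"), 1e-10)

  # two distinct atoms under inversion with the identity: M = D, so S = 100
  pair <- center_molecule(make_two_element_pair())
  opi <- operation_matrix("Ci")
  m <- symmetry_objective(pair, 1:2, opi, "full")
  expect_equal(csm_value(m, normalization_factor(pair)), 100)

  # distorted square under C4: term-by-term oracle agreement, both modes
  sq <- distort(make_ring(4), 0.08, seed = 21)
  perm <- c(2L, 3L, 4L, 1L)
  ax <- c(0.2, -0.1, 0.95)
  op4 <- operation_matrix("C4", ax)
  expect_equal(symmetry_objective(sq, perm, op4, "full"),
               oracle_M(sq$coords, perm, "C", 4, ax / sqrt(sum(ax^2))),
               tolerance = 1e-9)

  # single-operation mode equals the full objective for involutions, order 2
  mirror <- distort(make_ring(6), 0.05, seed = 8)
  swap <- c(1L, 6L, 5L, 4L, 3L, 2L)
  ops <- operation_matrix("Cs", c(1, 0, 0))
  expect_equal(symmetry_objective(mirror, swap, ops, "single"),
               symmetry_objective(mirror, swap, ops, "full"),
               tolerance = 1e-9)
})

test_that("csm_value is linear and guards D", {
  expect_equal(csm_value(0, 3), 0)
  expect_equal(csm_value(3, 3), 100)
  expect_equal(csm_value(0.75, 3), 25)
  expect_error(csm_value(1, 0), "degenerate")
})

test_that("nearest symmetric structure is the orbit-average projection", {
  # already symmetric: projection is the identity
  ring <- center_molecule(make_ring(5))
  op <- operation_matrix("C5", c(0, 0, 1))
  near <- nearest_symmetric_structure(ring, c(2:5, 1L), op)
  expect_true(near$cycle_valid)
  expect_equal(near$coords, ring$coords, tolerance = 1e-10)

  # distorted: T-invariance and Eq-2/Eq-3 consistency
  m <- distort(make_ring(5), 0.1, seed = 13)
  mc <- center_molecule(m)
  perm <- c(2:5, 1L)
  axis <- optimal_axis(mc, perm, "C5", mode = "full")
  op <- operation_matrix("C5", axis)
  near <- nearest_symmetric_structure(mc, perm, op)
  expect_equal(near$coords %*% t(op$matrix),
               near$coords[perm, ], tolerance = 1e-9)
  q <- sweep(mc$coords, 2, colMeans(mc$coords))
  expect_equal(sum((q - near$coords)^2),
               symmetry_objective(mc, perm, op, "full"), tolerance = 1e-9)

  # the orbit average beats any other T-invariant competitor
  set.seed(5)
  for (r in 1:10) {
    pert <- matrix(rnorm(15, sd = 0.1), 5, 3)
    # project the perturbation onto the T-invariant subspace by averaging
    comp <- near$coords + nearest_symmetric_structure(
      molecule(m$elements, pert), perm, op)$coords
    expect_gte(sum((q - comp)^2), sum((q - near$coords)^2) - 1e-12)
  }

  # identity permutation under inversion: everything collapses to the origin
  pair <- center_molecule(make_two_element_pair())
  opi <- operation_matrix("Ci")
  expect_equal(nearest_symmetric_structure(pair, 1:2, opi)$coords,
               matrix(0, 2, 3), tolerance = 1e-12)
})

test_that("optimal axis recovers true axes and matches a dense grid oracle", {
  # perfect C2 pair of rings: true axis z
  m <- make_prism(4)          # C4 positions contain C2
  perm <- c(3L, 4L, 1L, 2L, 7L, 8L, 5L, 6L)   # rotation by pi in both rings
  ax <- optimal_axis(m, perm, "C2")
  expect_equal(abs(ax[3]), 1, tolerance = 1e-8)
  op <- operation_matrix("C2", ax)
  expect_lt(symmetry_objective(m, perm, op, "single"), 1e-12)

  expect_equal(optimal_axis(make_ring(4), c(2L, 1L, 4L, 3L), "Ci"), c(0, 0, 1))

  # seeded distorted rings: returned axis at least as good as the grid oracle
  for (seed in c(2, 9, 17)) {
    m <- distort(make_ring(6), 0.12, seed = seed)
    mc <- center_molecule(m)
    perm <- c(3L, 4L, 5L, 6L, 1L, 2L)          # a 3-cycle pair pattern for C3
    ax <- optimal_axis(mc, perm, "C3", mode = "full")
    mine <- oracle_M(mc$coords, perm, "C", 3, ax)
    grid <- oracle_min_axis(mc$coords, perm, "C", 3, n_dirs = 2000)$M
    expect_lte(mine, grid + 1e-8)
  }
})

test_that("fibonacci lattice follows its defining formula", {
  fl <- fibonacci_lattice(7)
  expect_equal(fl$vectors[1, ], c(1, 0, 0), tolerance = 1e-12)
  expect_equal(fl$vectors[7, ], c(-1, 0, 0), tolerance = 1e-12)
  k <- 3
  expect_equal(fl$vectors[k + 1, 1], 1 - 2 * k / 6)

  big <- fibonacci_lattice(500)$vectors
  expect_equal(nrow(big), 500L)
  expect_equal(rowSums(big^2), rep(1, 500), tolerance = 1e-12)
  # near-uniform: no two directions coincide
  dots <- tcrossprod(big)
  diag(dots) <- -1
  expect_lt(max(dots), 1 - 1e-6)
  expect_error(fibonacci_lattice(1), "M >= 2")
})

test_that("educated direction guesses fit class centroids", {
  # ring of distinct elements: each atom its own class, plane normal = z
  els <- c("C", "N", "O", "F", "P", "S")
  ang <- 2 * pi * (0:5) / 6
  ringd <- molecule(els, cbind(cos(ang), sin(ang), 0))
  g <- initial_direction_guesses(ringd)
  has_z <- any(apply(g$vectors, 1, function(v) abs(abs(v[3]) - 1) < 1e-9))
  expect_true(has_z)

  # collinear centroids: line direction along the chain
  chain <- molecule(c("C", "N", "O"), cbind(c(0, 1.3, 2.6), 0, 0),
                    rbind(c(1, 2), c(2, 3)))
  g2 <- initial_direction_guesses(chain)
  expect_true(any(apply(g2$vectors, 1,
                        function(v) abs(abs(v[1]) - 1) < 1e-9)))

  # single class: coordinate-axis fallback
  g3 <- initial_direction_guesses(make_ring(6))
  expect_equal(nrow(g3$vectors), 3L)

  # planted outlier centroid is dropped before the plane fit
  set.seed(31)
  els8 <- c("C", "N", "O", "F", "P", "S", "Cl", "Br")
  ang8 <- 2 * pi * (0:7) / 8
  pts <- cbind(cos(ang8), sin(ang8), rnorm(8, sd = 0.02))
  pts[8, ] <- c(0.2, -0.1, 9)           # far off-plane outlier
  noisy <- molecule(els8, pts)
  g4 <- initial_direction_guesses(noisy)
  angles <- apply(g4$vectors, 1, function(v) {
    acos(min(1, abs(v[3]))) * 180 / pi
  })
  expect_lt(min(angles), 5)
  # all emitted directions are unit norm
  expect_equal(rowSums(g4$vectors^2), rep(1, nrow(g4$vectors)),
               tolerance = 1e-10)
})

test_that("the measure is invariant to rigid motion and scale", {
  base <- distort(make_ring(5), 0.07, seed = 12)
  s0 <- exact_csm(base, "C5")$S
  rot <- oracle_rotation(c(1, 2, 2) / 3, 1.1)
  moved <- base
  moved$coords <- sweep(base$coords %*% t(rot), 2, c(5, -3, 2), `+`)
  expect_equal(exact_csm(moved, "C5")$S, s0, tolerance = 1e-6)
  scaled <- base
  scaled$coords <- base$coords * 3.7
  expect_equal(exact_csm(scaled, "C5")$S, s0, tolerance = 1e-8)
})
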