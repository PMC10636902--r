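test_that("XYZ files round-trip and parse errors name the line", {
  path <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("1", "lone helium", "He 0.0 0.0 0.0"), path)
  mol <- read_molecule(path)
  expect_s3_class(mol, "molsym_molecule")
  expect_equal(length(mol$elements), 1L)
  expect_equal(mol$elements, "He")
  expect_equal(nrow(mol$bonds), 0L)

  m2 <- distort(make_ring(5, radius = 1.3, element = "N"), 0.1, seed = 4)
  out <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(m2, out)
  m3 <- read_molecule(out)
  expect_equal(m3$elements, m2$elements)
  expect_equal(m3$coords, m2$coords, tolerance = 1e-6)

  bad <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("2", "broken", "C 0 0 0", "C 0 zero 0"), bad)
  expect_error(read_molecule(bad), "line 4")
  bad2 <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("1", "", "Zz 0 0 0"), bad2)
  expect_error(read_molecule(bad2), "element")
})

test_that("SDF atom and bond blocks are read", {
  path <- withr::local_tempfile(fileext = ".sdf")
  writeLines(c(
    "diatomic", "  molsym", "",
    "  2  1  0  0  0  0  0  0  0  0999 V2000",
    "    0.0000    0.0000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0",
    "    0.9600    0.0000    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0",
    "  1  2  1  0  0  0  0",
    "M  END",
    "$$$$"), path)
  mol <- read_molecule(path)
  expect_equal(mol$elements, c("O", "H"))
  expect_equal(mol$bonds, matrix(c(1L, 2L), 1))
  expect_equal(mol$coords[2, 1], 0.96)
})

test_that("PDB CONECT records become bonds with the index shift", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  O   HOH A   1       0.000   0.000   0.000  1.00  0.00           O",
    "ATOM      2  H1  HOH A   1       0.960   0.000   0.000  1.00  0.00           H",
    "ATOM      3  H2  HOH A   1      -0.240   0.930   0.000  1.00  0.00           H",
    "CONECT    1    2    3",
    "END"), path)
  mol <- read_molecule(path)
  expect_equal(mol$elements, c("O", "H", "H"))
  expect_equal(mol$bonds, matrix(c(1L, 1L, 2L, 3L), 2))
})

test_that("bond inference follows covalent radii plus tolerance", {
  h2 <- molecule(c("H", "H"), rbind(c(0, 0, 0), c(0.74, 0, 0)))
  expect_equal(nrow(infer_bonds(h2, 0.4)$bonds), 1L)
  far <- molecule(c("C", "C"), rbind(c(0, 0, 0), c(5, 0, 0)))
  expect_equal(nrow(infer_bonds(far, 0.4)$bonds), 0L)
  expect_error(infer_bonds(molecule(c("Og", "C"), rbind(0:2 * 0, 1:3))),
               "covalent radius")

  # benzene: 6 C at 1.39 A and 6 H radially outside at C-H 1.09 A
  ang <- 2 * pi * (0:5) / 6
  benzene <- molecule(
    rep(c("C", "H"), each = 6),
    rbind(cbind(1.39 * cos(ang), 1.39 * sin(ang), 0),
          cbind(2.48 * cos(ang), 2.48 * sin(ang), 0))
  )
  expect_equal(nrow(infer_bonds(benzene)$bonds), 12L)
})

test_that("atom selection induces the subgraph and re-indexes bonds", {
  methane <- infer_bonds(molecule(
    c("C", "H", "H", "H", "H"),
    rbind(c(0, 0, 0), c(0.63, 0.63, 0.63), c(-0.63, -0.63, 0.63),
          c(-0.63, 0.63, -0.63), c(0.63, -0.63, -0.63))
  ))
  expect_equal(nrow(methane$bonds), 4L)
  core <- select_atoms(methane, drop_hydrogens = TRUE)
  expect_equal(core$elements, "C")
  expect_equal(nrow(core$bonds), 0L)

  chain <- molecule(c("C", "O", "C"),
                    rbind(c(0, 0, 0), c(1.4, 0, 0), c(2.8, 0, 0)),
                    rbind(c(1, 2), c(2, 3)))
  ends <- select_atoms(chain, drop_indices = 2)
  expect_equal(length(ends$elements), 2L)
  expect_equal(nrow(ends$bonds), 0L)

  # pillar-like host with one guest atom bonded into the cavity
  host <- make_prism(5)
  guest <- molecule(c(host$elements, "Li"),
                    rbind(host$coords, c(0, 0, 0)),
                    rbind(host$bonds, c(1L, 11L)))
  no_guest <- select_atoms(guest, drop_indices = 11L)
  expect_equal(length(no_guest$elements), length(guest$elements) - 1L)
  expect_equal(nrow(no_guest$bonds), nrow(host$bonds))
  expect_error(select_atoms(chain, drop_indices = 1:3), "empty")
})

test_that("equivalence classes come from neighbour colour refinement", {
  expect_equal(equivalence_classes(make_ring(6))$n_classes, 1L)
  xyx <- molecule(c("C", "O", "C"),
                  rbind(c(-1.4, 0, 0), c(0, 0, 0), c(1.4, 0, 0)),
                  rbind(c(1, 2), c(2, 3)))
  part <- equivalence_classes(xyx)
  expect_equal(part$n_classes, 2L)
  expect_equal(part$class_id[1], part$class_id[3])
  expect_equal(equivalence_classes(make_truncated_icosahedron())$n_classes, 1L)
  # element mix is never merged, even without bonds
  nobond <- molecule(c("C", "N"), rbind(c(0, 0, 0), c(1, 0, 0)))
  expect_equal(equivalence_classes(nobond)$n_classes, 2L)
})

test_that("geometric center and normalization factor", {
  one <- molecule("C", matrix(c(1, 2, 3), 1))
  expect_equal(geometric_center(one), c(1, 2, 3))
  pair <- molecule(c("C", "C"), rbind(c(1, 0, 0), c(-1, 0, 0)))
  expect_equal(geometric_center(pair), c(0, 0, 0))

  set.seed(11)
  cloud <- molecule(rep("C", 5), matrix(runif(15, -2, 2), 5))
  expect_equal(geometric_center(cloud), colMeans(cloud$coords))
  ctr <- colMeans(cloud$coords)
  expect_equal(normalization_factor(cloud),
               sum(sweep(cloud$coords, 2, ctr)^2))

  square <- molecule(rep("C", 4),
                     rbind(c(1, 1, 0), c(1, -1, 0), c(-1, 1, 0), c(-1, -1, 0)))
  expect_equal(normalization_factor(square), 8)
  expect_error(normalization_factor(molecule(c("C", "C"),
                                             rbind(c(0, 0, 0), c(0, 0, 0)))),
               "degenerate")

  # translation invariance
  shifted <- cloud
  shifted$coords <- sweep(cloud$coords, 2, c(12.3, -4.5, 6.7), `+`)
  expect_equal(normalization_factor(shifted), normalization_factor(cloud),
               tolerance = 1e-9)
})

test_that("molecule validation rejects malformed input", {
  expect_error(molecule(character(0), matrix(0, 0, 3)), "at least one atom")
  expect_error(molecule("C", matrix(c(1, 2, Inf), 1)), "finite")
  expect_error(molecule(c("C", "C"), rbind(c(0, 0, 0), c(1, 0, 0)),
                        rbind(c(1, 1))), "self-bond")
  expect_error(molecule(c("C", "C"), rbind(c(0, 0, 0), c(1, 0, 0)),
                        rbind(c(1, 3))), "out of range")
})
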