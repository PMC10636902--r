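#' Construct a molecule
#'
#' The basic container used throughout the package: element symbols, Cartesian
#' coordinates in angstrom, and an undirected bond graph. Atom indices are
#' 1-based everywhere, including serialized output.
#'
#' @param elements character vector of element symbols.
#' @param coords numeric N x 3 matrix of coordinates (angstrom).
#' @param bonds two-column integer matrix of atom index pairs (may have zero
#'   rows), or `NULL` for no bonds.
#' @param name optional text label.
#' @return an object of class `molsym_molecule` with fields `elements`,
#'   `coords`, `bonds` (canonicalized: i < j, unique, sorted) and `name`.
#' @export
molecule <- function(elements, coords, bonds = NULL, name = "") {
  elements <- normalize_element(as.character(elements))
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  n <- length(elements)
  if (n < 1L) stop("a molecule needs at least one atom")
  if (!is.matrix(coords) || ncol(coords) != 3L || nrow(coords) != n) {
    stop("coords must be an N x 3 matrix matching length(elements)")
  }
  if (!all(is.finite(coords))) stop("all coordinates must be finite")
  bad <- setdiff(elements, .element_symbols)
  if (length(bad)) {
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
  }
  dimnames(coords) <- NULL
  structure(
    list(elements = elements, coords = coords,
         bonds = canonical_bonds(bonds, n), name = as.character(name)[1]),
    class = "molsym_molecule"
  )
}

canonical_bonds <- function(bonds, n) {
  if (is.null(bonds) || length(bonds) == 0L) {
    return(matrix(integer(0), ncol = 2L))
  }
  bonds <- as.matrix(bonds)
  storage.mode(bonds) <- "integer"
  if (ncol(bonds) != 2L) stop("bonds must be a two-column matrix")
  if (any(bonds < 1L | bonds > n)) stop("bond index out of range")
  if (any(bonds[, 1] == bonds[, 2])) stop("self-bonds are not allowed")
  bonds <- cbind(pmin(bonds[, 1], bonds[, 2]), pmax(bonds[, 1], bonds[, 2]))
  bonds <- unique(bonds)
  bonds[order(bonds[, 1], bonds[, 2]), , drop = FALSE]
}

#' @export
print.molsym_molecule <- function(x, ...) {
  cat(sprintf("<molecule%s: %d atoms, %d bonds>\n",
              if (nzchar(x$name)) paste0(" ", x$name) else "",
              n_atoms(x), nrow(x$bonds)))
  invisible(x)
}

n_atoms <- function(mol) length(mol$elements)

bond_matrix <- function(mol) {
  n <- n_atoms(mol)
  b <- matrix(FALSE, n, n)
  if (nrow(mol$bonds)) {
    b[mol$bonds] <- TRUE
    b[mol$bonds[, 2:1, drop = FALSE]] <- TRUE
  }
  b
}

#' Read a molecular structure file
#'
#' Supports XYZ (count / comment / element-x-y-z lines), SDF (MOL V2000, first
#' record; bond block read), and PDB (ATOM/HETATM records; CONECT records give
#' bonds). XYZ carries no connectivity: follow with [infer_bonds()] if a bond
#' graph is needed.
#'
#' @param path file path.
#' @param format one of `"auto"`, `"xyz"`, `"sdf"`, `"pdb"`. `"auto"` picks by
#'   file extension (`.mol` counts as sdf, `.ent` as pdb).
#' @return a [molecule()].
#' @export
read_molecule <- function(path, format = c("auto", "xyz", "sdf", "pdb")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      xyz = "xyz", sdf = "sdf", mol = "sdf", pdb = "pdb", ent = "pdb",
      stop("cannot infer format from extension '", ext, "'; pass format=")
    )
  }
  switch(format,
    xyz = read_xyz(path),
    sdf = read_sdf(path),
    pdb = read_pdb_file(path)
  )
}

read_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 1L) stop("XYZ parse error at line 1: empty file")
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 1L) {
    stop("XYZ parse error at line 1: expected a positive atom count")
  }
  if (length(lines) < n + 2L) {
    stop("XYZ parse error at line ", length(lines) + 1L,
         ": expected ", n, " atom lines")
  }
  name <- if (length(lines) >= 2L) trimws(lines[2]) else ""
  elements <- character(n)
  coords <- matrix(NA_real_, n, 3)
  for (k in seq_len(n)) {
    ln <- n_fields <- strsplit(trimws(lines[k + 2L]), "\\s+")[[1]]
    if (length(ln) < 4L) {
      stop("XYZ parse error at line ", k + 2L, ": need 'element x y z'")
    }
    xyz <- suppressWarnings(as.numeric(ln[2:4]))
    if (anyNA(xyz)) {
      stop("XYZ parse error at line ", k + 2L, ": non-numeric coordinate")
    }
    elements[k] <- ln[1]
    coords[k, ] <- xyz
  }
  molecule(elements, coords, NULL, name = name)
}

read_sdf <- function(path) {
  sdf <- ChemmineR::read.SDFset(path)
  if (length(sdf) < 1L) stop("SDF parse error: no molecule records in ", path)
  sdf1 <- sdf[[1]]
  ab <- ChemmineR::atomblock(sdf1)
  elements <- sub("_.*$", "", rownames(ab))
  coords <- ab[, 1:3, drop = FALSE]
  bb <- ChemmineR::bondblock(sdf1)
  bonds <- if (!is.null(bb) && nrow(bb)) {
    cbind(as.integer(bb[, 1]), as.integer(bb[, 2]))
  } else NULL
  nm <- tryCatch(ChemmineR::header(sdf1)[["Molecule_Name"]],
                 error = function(e) "")
  molecule(elements, coords, bonds, name = if (is.null(nm)) "" else nm)
}

read_pdb_file <- function(path) {
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) stop("PDB parse error: ",
                                           conditionMessage(e)))
  at <- pdb$atom
  if (nrow(at) < 1L) stop("PDB parse error: no ATOM/HETATM records")
  elements <- trimws(at$elesy)
  missing_el <- is.na(elements) | elements == ""
  if (any(missing_el)) {
    # fall back to the leading letters of the atom name
    elements[missing_el] <- sub("^([A-Za-z]+).*$", "\\1", at$elety[missing_el])
  }
  coords <- cbind(at$x, at$y, at$z)
  # bio3d does not retain CONECT records; scan them from the raw text.
  serial_to_row <- match(seq_len(max(at$eleno)), at$eleno)
  lines <- grep("^CONECT", readLines(path, warn = FALSE), value = TRUE)
  bonds <- NULL
  if (length(lines)) {
    pairs <- do.call(rbind, lapply(lines, function(ln) {
      f <- suppressWarnings(as.integer(strsplit(trimws(ln), "\\s+")[[1]][-1]))
      f <- f[!is.na(f)]
      if (length(f) < 2L) return(NULL)
      cbind(f[1], f[-1])
    }))
    if (!is.null(pairs) && nrow(pairs)) {
      bonds <- cbind(serial_to_row[pairs[, 1]], serial_to_row[pairs[, 2]])
      if (anyNA(bonds)) stop("PDB parse error: CONECT names an unknown serial")
    }
  }
  molecule(elements, coords, bonds, name = basename(path))
}

#' Write a molecule (or bare coordinates) as an XYZ file
#'
#' @param mol a [molecule()], or an N x 3 coordinate matrix if `elements` is
#'   given.
#' @param path output path.
#' @param comment text for the XYZ comment line.
#' @param elements element symbols, only needed when `mol` is a matrix.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(mol, path, comment = NULL, elements = NULL) {
  if (is.matrix(mol)) {
    coords <- mol
    if (is.null(elements)) stop("elements required when writing a matrix")
  } else {
    coords <- mol$coords
    elements <- mol$elements
    if (is.null(comment)) comment <- mol$name
  }
  if (is.null(comment)) comment <- ""
  lines <- c(
    as.character(nrow(coords)),
    comment,
    sprintf("%-3s %14.8f %14.8f %14.8f",
            elements, coords[, 1], coords[, 2], coords[, 3])
  )
  writeLines(lines, path)
  invisible(path)
}

#' Infer covalent bonds from interatomic distances
#'
#' Adds a bond between atoms i and j when their distance does not exceed the
#' sum of tabulated covalent radii plus `tolerance`. Deterministic; replaces
#' any existing bond set.
#'
#' @param mol a [molecule()].
#' @param tolerance slack added to the radii sum, angstrom (default 0.4, the
#'   common cheminformatics heuristic).
#' @return the molecule with inferred bonds.
#' @export
infer_bonds <- function(mol, tolerance = 0.4) {
  stopifnot(inherits(mol, "molsym_molecule"), tolerance >= 0)
  n <- n_atoms(mol)
  r <- covalent_radius(mol$elements)
  d <- as.matrix(stats::dist(mol$coords))
  cutoff <- outer(r, r, `+`) + tolerance
  hit <- which(d <= cutoff & upper.tri(d), arr.ind = TRUE)
  mol$bonds <- canonical_bonds(hit, n)
  mol
}

#' Select a subset of atoms
#'
#' Returns the induced substructure: kept atoms with bonds re-indexed; bonds
#' touching dropped atoms disappear.
#'
#' @param mol a [molecule()].
#' @param drop_hydrogens drop all H atoms.
#' @param drop_indices additional atom indices (1-based) to drop.
#' @return a [molecule()].
#' @export
select_atoms <- function(mol, drop_hydrogens = FALSE, drop_indices = integer()) {
  n <- n_atoms(mol)
  drop_indices <- as.integer(drop_indices)
  if (length(drop_indices) && any(drop_indices < 1L | drop_indices > n)) {
    stop("drop_indices out of range")
  }
  drop <- rep(FALSE, n)
  drop[drop_indices] <- TRUE
  if (drop_hydrogens) drop[mol$elements == "H"] <- TRUE
  keep <- which(!drop)
  if (!length(keep)) stop("atom selection is empty")
  remap <- rep(NA_integer_, n)
  remap[keep] <- seq_along(keep)
  b <- mol$bonds
  if (nrow(b)) {
    ok <- !drop[b[, 1]] & !drop[b[, 2]]
    b <- cbind(remap[b[ok, 1]], remap[b[ok, 2]])
  }
  molecule(mol$elements[keep], mol$coords[keep, , drop = FALSE], b,
           name = mol$name)
}

#' Atom equivalence classes by neighbourhood colour refinement
#'
#' Starts from element symbols and repeatedly refines each atom's colour by the
#' multiset of its neighbours' colours until a fixpoint (at most N rounds).
#' Atoms in one class share an element and an indistinguishable bond-graph
#' environment; only such atoms are candidates for mutual permutation.
#'
#' @param mol a [molecule()] (bonds may be empty, giving element-only classes).
#' @return an object of class `molsym_partition`: list with `class_id`
#'   (integer per atom, canonical by first occurrence) and `n_classes`.
#' @export
equivalence_classes <- function(mol) {
  n <- n_atoms(mol)
  nb <- vector("list", n)
  if (nrow(mol$bonds)) {
    for (k in seq_len(nrow(mol$bonds))) {
      i <- mol$bonds[k, 1]; j <- mol$bonds[k, 2]
      nb[[i]] <- c(nb[[i]], j)
      nb[[j]] <- c(nb[[j]], i)
    }
  }
  color <- match(mol$elements, unique(mol$elements))
  repeat {
    sig <- vapply(seq_len(n), function(i) {
      paste(color[i], paste(sort(color[nb[[i]]]), collapse = ","), sep = "|")
    }, character(1))
    new_color <- match(sig, unique(sig))
    if (identical(new_color, color)) break
    color <- new_color
  }
  structure(list(class_id = color, n_classes = max(color)),
            class = "molsym_partition")
}

#' @export
print.molsym_partition <- function(x, ...) {
  cat(sprintf("<equivalence partition: %d classes over %d atoms>\n",
              x$n_classes, length(x$class_id)))
  invisible(x)
}

#' Geometric center (unweighted centroid)
#'
#' @param mol a [molecule()].
#' @return length-3 numeric vector.
#' @export
geometric_center <- function(mol) colMeans(mol$coords)

#' Translate a molecule so its geometric center is the origin
#'
#' @param mol a [molecule()].
#' @return the centered molecule.
#' @export
center_molecule <- function(mol) {
  mol$coords <- sweep(mol$coords, 2, geometric_center(mol))
  mol
}

#' CSM normalization factor D
#'
#' The summed squared distance of all atoms from the geometric center,
#' in angstrom squared. The symmetry measure is `100 * M / D`; D = 0 (all
#' atoms coincident) leaves it undefined.
#'
#' @param mol a [molecule()].
#' @return scalar D.
#' @export
normalization_factor <- function(mol) {
  centered <- sweep(mol$coords, 2, geometric_center(mol))
  d <- sum(centered^2)
  if (d <= 1e-12) {
    stop("degenerate geometry: all atoms coincide, the CSM is undefined")
  }
  d
}
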