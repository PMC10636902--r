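# Shared CSM result constructor: derives every reported field from the
# (molecule, group, permutation, axis) tuple so all engines agree on
# conventions. The headline S uses the full group-averaged objective whenever
# the permutation's cycle structure is group-compatible (then the nearest
# structure is exactly T-invariant); otherwise S falls back to the
# single-operation surrogate M-hat and the result is flagged.
make_csm_result <- function(mol, spec, perm, axis, algorithm,
                            iterations = NA_integer_, converged = TRUE,
                            trajectory = NULL, complete = TRUE) {
  spec <- point_group(spec)
  molc <- center_molecule(mol)
  op <- operation_matrix(spec, axis)
  d <- normalization_factor(molc)
  m_hat <- symmetry_objective(molc, perm, op, mode = "single")
  m_full <- symmetry_objective(molc, perm, op, mode = "full")
  near <- nearest_symmetric_structure(molc, perm, op)
  s <- csm_value(if (near$cycle_valid) m_full else m_hat, d)
  pres <- preservation_percentage(molc, perm)
  structure(
    list(
      S = s, group = spec, axis = axis, permutation = perm,
      nearest = near$coords, M_full = m_full, M_hat = m_hat, D = d,
      preservation = pres, algorithm = algorithm,
      iterations = iterations, converged = converged,
      cycle_valid = near$cycle_valid, complete = complete,
      trajectory = trajectory, elements = molc$elements
    ),
    class = "molsym_csm"
  )
}

#' @export
print.molsym_csm <- function(x, digits = 4, ...) {
  cat(sprintf("S(%s) = %.*f   [%s]\n", x$group$label, digits, x$S,
              x$algorithm))
  cat(sprintf("  axis: (%.4f, %.4f, %.4f)   cycle-valid: %s\n",
              x$axis[1], x$axis[2], x$axis[3], x$cycle_valid))
  cat(sprintf("  M = %.6g  M-hat = %.6g  D = %.6g\n", x$M_full, x$M_hat, x$D))
  if (!is.na(x$preservation)) {
    cat(sprintf("  structure preservation: %.1f%%\n", x$preservation))
  }
  invisible(x)
}

#' Bond-preservation percentage of a permutation
#'
#' The fraction (as a percent) of bonds (i, j) whose image
#' (pi(i), pi(j)) is also a bond. Structure-preserving permutations score 100
#' by construction. `NA` for a bond-free molecule (not applicable).
#'
#' @param mol a [molecule()].
#' @param perm integer permutation.
#' @return percent in \[0, 100\], or `NA`.
#' @export
preservation_percentage <- function(mol, perm) {
  b <- mol$bonds
  if (!nrow(b)) return(NA_real_)
  bm <- bond_matrix(mol)
  mapped <- bm[cbind(perm[b[, 1]], perm[b[, 2]])]
  100 * mean(mapped)
}
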