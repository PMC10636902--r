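#' Permutation-direction iterations from one starting axis
#'
#' Alternates two minimization steps until convergence: with the axis fixed,
#' the distance matrix is built and an assignment engine proposes a
#' permutation; with the permutation fixed, the optimal axis is recomputed
#' analytically. The single-operation objective M-hat is non-increasing across
#' iterations (with the greedy assigner, a proposal that would raise it ends
#' the iteration instead, since greedy is not a minimizer). Stops when the
#' permutation repeats, M-hat improves by less than `tol`, or `max_iter`
#' iterations.
#'
#' @param mol a [molecule()].
#' @param spec a [point_group()].
#' @param start_axis starting direction (unit-normalized internally).
#' @param assigner `"hungarian"` or `"greedy"`.
#' @param max_iter iteration cap (default 50).
#' @param tol convergence threshold on the M-hat improvement (default 1e-10).
#' @param partition optional precomputed [equivalence_classes()].
#' @return a `molsym_csm` result; `trajectory` holds the per-iteration M-hat.
#' @export
permutation_direction_iterate <- function(mol, spec, start_axis,
                                          assigner = c("hungarian", "greedy"),
                                          max_iter = 50L, tol = 1e-10,
                                          partition = NULL) {
  assigner <- match.arg(assigner)
  spec <- point_group(spec)
  molc <- center_molecule(mol)
  if (is.null(partition)) partition <- equivalence_classes(molc)
  assign_fun <- switch(assigner,
                       hungarian = hungarian_assignment,
                       greedy = greedy_assignment)
  fac <- m_hat_factor(spec)
  axis <- unit_vector(start_axis)
  m_hat <- Inf
  perm <- NULL
  traj <- numeric(0)
  iter <- 0L
  converged <- FALSE
  repeat {
    iter <- iter + 1L
    op <- operation_matrix(spec, axis)
    a <- distance_matrix(molc, op, partition)
    sol <- assign_fun(a)
    cand_m <- fac * sol$cost
    if (cand_m > m_hat + tol) {
      # only possible with greedy: keep the incumbent and stop
      converged <- TRUE
      break
    }
    perm_repeat <- identical(sol$perm, perm)
    perm <- sol$perm
    if (!is_inversion(spec)) {
      axis <- optimal_axis(molc, perm, spec, mode = "single")
      op <- operation_matrix(spec, axis)
    }
    new_m <- symmetry_objective(molc, perm, op, mode = "single")
    traj <- c(traj, new_m)
    improved <- m_hat - new_m
    m_hat <- min(m_hat, new_m)
    if (perm_repeat || improved < tol) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
  }
  res <- make_csm_result(molc, spec, perm, axis, algorithm = assigner,
                         iterations = iter, converged = converged,
                         trajectory = traj)
  # report the best M-hat seen (the axis/perm pair achieving it is current:
  # both steps only ever improve or terminate)
  res
}

#' Fibonacci-lattice multistart CSM
#'
#' Runs [permutation_direction_iterate()] from every vector of a Fibonacci
#' lattice of size `n_dirs` plus the educated guesses of
#' [initial_direction_guesses()], and returns the minimum-M-hat result.
#' Deterministic for fixed inputs: ties resolve to the lowest start index.
#' For the inversion group the axis is immaterial and a single run is made.
#'
#' @param mol a [molecule()].
#' @param spec a [point_group()].
#' @param n_dirs lattice size (default 100, the usual working size; more
#'   directions help mainly for large single-class structures).
#' @param assigner `"hungarian"` (default) or `"greedy"`.
#' @return the best `molsym_csm` result; `algorithm` is tagged "fibonacci".
#' @export
fibonacci_multistart <- function(mol, spec, n_dirs = 100L,
                                 assigner = "hungarian") {
  spec <- point_group(spec)
  molc <- center_molecule(mol)
  partition <- equivalence_classes(molc)
  if (is_inversion(spec)) {
    starts <- matrix(c(0, 0, 1), 1)
  } else {
    starts <- rbind(fibonacci_lattice(max(2L, n_dirs))$vectors,
                    initial_direction_guesses(molc, partition)$vectors)
  }
  best <- NULL
  for (k in seq_len(nrow(starts))) {
    res <- permutation_direction_iterate(molc, spec, starts[k, ],
                                         assigner = assigner,
                                         partition = partition)
    if (is.null(best) || res$M_hat < best$M_hat - 1e-15) best <- res
  }
  best$algorithm <- "fibonacci"
  best
}

#' Approximate structure-preserving CSM (prioritized branch-and-bound)
#'
#' Permutation-direction iterations in which the assignment step searches
#' structure-preserving permutations only: candidate values pi(i) = j are
#' tried in ascending order of the distance-matrix entry A[i, j], and any
#' partial permutation whose partial cost already exceeds the best complete
#' cost is pruned. Bond preservation is therefore 100% by construction. The
#' search runs from each educated-guess direction until convergence or until
#' `time_limit` elapses.
#'
#' @param mol a [molecule()] with bonds.
#' @param spec a [point_group()].
#' @param time_limit wall-clock budget in seconds (default 300).
#' @param max_iter direction-iteration cap per start.
#' @param cap node cap per branch-and-bound call.
#' @return a `molsym_csm` result, `algorithm = "sp"`; `complete` is `FALSE`
#'   if the budget or cap truncated any search.
#' @export
approx_structure_preserving <- function(mol, spec, time_limit = 300,
                                        max_iter = 50L, cap = 1e7) {
  spec <- point_group(spec)
  molc <- center_molecule(mol)
  partition <- equivalence_classes(molc)
  allowed <- allowed_cycle_lengths(spec)
  bm <- bond_matrix(molc)
  deadline <- Sys.time() + time_limit
  starts <- if (is_inversion(spec)) matrix(c(0, 0, 1), 1)
            else initial_direction_guesses(molc, partition)$vectors
  best <- NULL
  complete <- TRUE
  for (k in seq_len(nrow(starts))) {
    axis <- starts[k, ]
    m_hat <- Inf
    perm <- NULL
    traj <- numeric(0)
    iter <- 0L
    converged <- FALSE
    repeat {
      iter <- iter + 1L
      op <- operation_matrix(spec, axis)
      a <- distance_matrix(molc, op, partition)
      sr <- sp_search(bm, partition$class_id, allowed, mode = "bnb", A = a,
                      cap = cap, deadline = deadline)
      if (!sr$complete) complete <- FALSE
      if (is.null(sr$best_perm)) break
      cand_m <- m_hat_factor(spec) * sr$best_cost
      if (cand_m > m_hat + 1e-10) { converged <- TRUE; break }
      perm_repeat <- identical(sr$best_perm, perm)
      perm <- sr$best_perm
      if (!is_inversion(spec)) {
        axis <- optimal_axis(molc, perm, spec, mode = "single")
        op <- operation_matrix(spec, axis)
      }
      new_m <- symmetry_objective(molc, perm, op, mode = "single")
      traj <- c(traj, new_m)
      improved <- m_hat - new_m
      m_hat <- min(m_hat, new_m)
      if (perm_repeat || improved < 1e-10) { converged <- TRUE; break }
      if (iter >= max_iter || Sys.time() > deadline) break
    }
    if (!is.null(perm)) {
      res <- make_csm_result(molc, spec, perm, axis, algorithm = "sp",
                             iterations = iter, converged = converged,
                             trajectory = traj, complete = complete)
      if (is.null(best) || res$S < best$S - 1e-15) best <- res
    }
    if (Sys.time() > deadline) { complete <- FALSE; break }
  }
  if (is.null(best)) {
    stop("no structure-preserving permutation found for ", spec$label)
  }
  best$complete <- complete
  best
}

#' Upper and lower bounds on the CSM
#'
#' The Fibonacci + Hungarian multistart minimizes the single-operation
#' objective over all permutations (not just structure-preserving ones), so
#' `100 * M_hat / D` bounds the measure from below; the structure-preserving
#' branch-and-bound searches a subset of admissible permutations and axes, so
#' its value bounds it from above. For C_s and C_i the single-operation and
#' full objectives coincide on admissible permutations and the pair brackets
#' the exact measure; for n > 2 the lower value bounds the M-hat-based
#' quantity only (`brackets_exact = FALSE`).
#'
#' @param mol a [molecule()] with bonds.
#' @param spec a [point_group()].
#' @param n_dirs Fibonacci lattice size for the lower bound.
#' @param time_limit budget (seconds) for the upper-bound search.
#' @return list with `lower`, `upper`, `brackets_exact`, and the two full
#'   results (`lower_result`, `upper_result`).
#' @export
csm_bounds <- function(mol, spec, n_dirs = 100L, time_limit = 300) {
  spec <- point_group(spec)
  lo <- fibonacci_multistart(mol, spec, n_dirs = n_dirs,
                             assigner = "hungarian")
  up <- approx_structure_preserving(mol, spec, time_limit = time_limit)
  list(
    lower = csm_value(lo$M_hat, lo$D),
    upper = up$S,
    brackets_exact = spec$order <= 2L,
    lower_result = lo,
    upper_result = up
  )
}
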