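#' Compute a continuous symmetry measure with engine dispatch
#'
#' `algorithm = "auto"` uses the exact enumeration engine when the
#' structure-preserving search finishes under a node cap (small and
#' medium-sized molecules, or large ones with few structural symmetries, like
#' fullerene cages under C2), and otherwise falls back to the Hungarian
#' engine, the recommended default for large inputs.
#'
#' @param mol a [molecule()].
#' @param group a [point_group()] or label such as `"C5"`, `"Cs"`.
#' @param algorithm one of `"auto"`, `"exact"`, `"hungarian"`, `"greedy"`,
#'   `"sp"`, `"fibonacci"`.
#' @param n_dirs Fibonacci lattice size for the `"fibonacci"` engine.
#' @param time_limit seconds, for the `"sp"` engine.
#' @param cap node cap for exact enumeration (also the auto-dispatch
#'   feasibility probe).
#' @param verbose print the chosen engine and headline numbers.
#' @return a `molsym_csm` result: `S` (0-100), `group`, `axis`, `permutation`
#'   (1-based), `nearest` (coordinates of the nearest symmetric structure),
#'   `M_full`, `M_hat`, `D`, `preservation` (percent of bonds preserved),
#'   `algorithm`, `iterations`, `converged`, `cycle_valid`.
#' @export
compute_csm <- function(mol, group,
                        algorithm = c("auto", "exact", "hungarian", "greedy",
                                      "sp", "fibonacci"),
                        n_dirs = 100L, time_limit = 300, cap = 1e6,
                        verbose = FALSE) {
  algorithm <- match.arg(algorithm)
  spec <- point_group(group)
  res <- switch(algorithm,
    auto = {
      r <- tryCatch(exact_csm(mol, spec, cap = cap), error = function(e) e)
      if (inherits(r, "error")) {
        if (verbose) message("auto dispatch: exact enumeration infeasible (",
                             conditionMessage(r), "); using hungarian")
        hungarian_engine(mol, spec)
      } else r
    },
    exact = exact_csm(mol, spec, cap = cap),
    hungarian = hungarian_engine(mol, spec),
    greedy = greedy_engine(mol, spec),
    sp = approx_structure_preserving(mol, spec, time_limit = time_limit),
    fibonacci = fibonacci_multistart(mol, spec, n_dirs = n_dirs)
  )
  if (verbose) {
    message(sprintf("engine=%s  S(%s)=%.4f  preservation=%s  iterations=%s",
                    res$algorithm, spec$label, res$S,
                    ifelse(is.na(res$preservation), "n/a",
                           sprintf("%.1f%%", res$preservation)),
                    res$iterations))
  }
  res
}

# Single-start engines: best permutation-direction run over the educated
# guesses (one run for the axis-free inversion group).
best_over_guesses <- function(mol, spec, assigner) {
  molc <- center_molecule(mol)
  partition <- equivalence_classes(molc)
  starts <- if (is_inversion(spec)) matrix(c(0, 0, 1), 1)
            else initial_direction_guesses(molc, partition)$vectors
  best <- NULL
  for (k in seq_len(nrow(starts))) {
    res <- permutation_direction_iterate(molc, spec, starts[k, ],
                                         assigner = assigner,
                                         partition = partition)
    if (is.null(best) || res$M_hat < best$M_hat - 1e-15) best <- res
  }
  best
}

hungarian_engine <- function(mol, spec) best_over_guesses(mol, spec, "hungarian")
greedy_engine <- function(mol, spec) best_over_guesses(mol, spec, "greedy")

#' Continuous chirality measure
#'
#' The minimum CSM over a set of achiral (improper) point groups, default
#' \{C_s, C_i\}; extend with "S4", "S6", ... when needed. In most chiral
#' topologies the reflection distance S(C_s) attains the minimum.
#'
#' @param mol a [molecule()].
#' @param groups character vector of improper group labels.
#' @param ... passed to [compute_csm()] (e.g. `algorithm`).
#' @return the minimizing `molsym_csm` result; attribute `per_group` holds
#'   each group's measure.
#' @export
compute_ccm <- function(mol, groups = c("Cs", "Ci"), ...) {
  specs <- lapply(groups, point_group)
  if (!all(vapply(specs, is_improper, logical(1)))) {
    stop("the chirality measure is a minimum over improper (S_n) groups only")
  }
  results <- lapply(specs, function(g) compute_csm(mol, g, ...))
  svals <- vapply(results, `[[`, numeric(1), "S")
  best <- results[[which.min(svals)]]
  attr(best, "per_group") <- stats::setNames(svals,
                                             vapply(specs, `[[`, "", "label"))
  best
}

#' Serialize a CSM result
#'
#' Writes a machine-readable JSON record (S, group, axis, 1-based permutation,
#' M, M-hat, D, preservation, algorithm, convergence and cycle-validity flags)
#' and, optionally, the nearest symmetric structure as XYZ.
#'
#' @param result a `molsym_csm` result.
#' @param json path for the JSON record, or `NULL` to skip.
#' @param nearest_xyz path for the nearest-structure XYZ, or `NULL` to skip.
#' @return the record, invisibly (a list).
#' @export
write_result <- function(result, json = NULL, nearest_xyz = NULL) {
  stopifnot(inherits(result, "molsym_csm"))
  record <- list(
    S = result$S,
    group = result$group$label,
    axis = as.numeric(result$axis),
    permutation = as.integer(result$permutation),
    M = result$M_full,
    M_hat = result$M_hat,
    D = result$D,
    preservation = result$preservation,
    algorithm = result$algorithm,
    iterations = result$iterations,
    converged = result$converged,
    cycle_valid = result$cycle_valid
  )
  if (!is.null(json)) {
    jsonlite::write_json(record, json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
  }
  if (!is.null(nearest_xyz)) {
    write_xyz(result$nearest, nearest_xyz,
              comment = sprintf("nearest %s-symmetric structure (S = %.6f)",
                                result$group$label, result$S),
              elements = result$elements)
  }
  invisible(record)
}
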