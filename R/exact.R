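#' Allowed permutation cycle lengths for a point group
#'
#' The permutation paired with a group generator may only have cycles of
#' length 1, 2 or n; length 2 is allowed only for S_n or C_2. Hence:
#' C_n (n > 2) gives {1, n}; C_2, Cs (= S1) and Ci (= S2) give {1, 2};
#' S_n (n >= 4) gives {1, 2, n}.
#'
#' @param spec a [point_group()].
#' @return sorted integer vector of allowed cycle lengths.
#' @export
allowed_cycle_lengths <- function(spec) {
  spec <- point_group(spec)
  if (spec$family == "C") {
    if (spec$n == 2L) c(1L, 2L) else c(1L, spec$n)
  } else {
    if (spec$n <= 2L) c(1L, 2L) else c(1L, 2L, spec$n)
  }
}

# Core recursive search over structure-preserving permutations.
#
# A structure-preserving permutation maps atoms within their equivalence
# classes, satisfies the bond biconditional pi(i)~pi(j) <=> i~j, and has all
# cycle lengths in `allowed`. The search assigns one image at a time, always
# branching on an atom with the minimal number of remaining options (ties to
# the lowest index). Partial chains i1 -> i2 -> ... are tracked so cycle
# constraints prune early; a chain reaching the maximal allowed length forces
# its closure immediately.
#
# mode "enumerate": collect every permutation (up to `cap` visited nodes).
# mode "count":     count them only.
# mode "bnb":       minimize sum_i A[i, pi(i)]; candidate values are tried in
#                   ascending A order and partial sums above the incumbent are
#                   pruned ("there is no point in carrying on the search").
sp_search <- function(bondmat, classes, allowed, mode = "enumerate",
                      A = NULL, cap = 1e7, deadline = Inf) {
  n <- nrow(bondmat)
  n_max <- max(allowed)
  env <- new.env(parent = emptyenv())
  env$nodes <- 0L
  env$complete <- TRUE
  env$perms <- list()
  env$count <- 0
  env$best_cost <- Inf
  env$best_perm <- NULL

  candidates_for <- function(st, i) {
    poss <- which(classes == classes[i] & !st$has_pre)
    if (!length(poss)) return(integer(0))
    h <- st$head_of[i]
    li <- st$len_of[h]
    merged <- st$len_of[poss] + li
    ok <- ifelse(poss == h, li %in% allowed, merged <= n_max)
    poss <- poss[ok]
    if (!length(poss)) return(poss)
    K <- which(st$pi > 0L)
    if (length(K)) {
      bi <- bondmat[i, K]
      sub <- bondmat[poss, st$pi[K], drop = FALSE]
      ok <- rowSums(sub != matrix(bi, nrow(sub), length(K), byrow = TRUE)) == 0L
      poss <- poss[ok]
    }
    poss
  }

  bond_consistent <- function(st, i, j) {
    K <- which(st$pi > 0L)
    if (!length(K)) return(TRUE)
    all(bondmat[i, K] == bondmat[j, st$pi[K]])
  }

  # Apply pi(i) = j plus any forced chain closures; NULL if inconsistent.
  try_assign <- function(st, i, j) {
    repeat {
      if (!bond_consistent(st, i, j)) return(NULL)
      st$pi[i] <- j
      st$has_pre[j] <- TRUE
      st$n_assigned <- st$n_assigned + 1L
      if (!is.null(A)) {
        st$cost <- st$cost + A[i, j]
        if (st$cost > env$best_cost) return(NULL)
      }
      h <- st$head_of[i]
      if (j == h) return(st)          # closed a cycle (length already vetted)
      t2 <- st$tail_of[j]
      st$head_of[t2] <- h
      st$tail_of[h] <- t2
      st$len_of[h] <- st$len_of[h] + st$len_of[j]
      if (st$len_of[h] < n_max) return(st)
      # chain at maximal length: only closure remains
      if (st$has_pre[h]) return(NULL)
      if (classes[t2] != classes[h]) return(NULL)
      i <- t2
      j <- h
    }
  }

  recurse <- function(st) {
    env$nodes <- env$nodes + 1L
    if (env$nodes > cap || (is.finite(deadline) && Sys.time() > deadline)) {
      env$complete <- FALSE
      return(invisible())
    }
    if (st$n_assigned == n) {
      if (mode == "enumerate") {
        env$perms[[length(env$perms) + 1L]] <- st$pi
      } else if (mode == "count") {
        env$count <- env$count + 1
      } else {
        if (st$cost < env$best_cost) {
          env$best_cost <- st$cost
          env$best_perm <- st$pi
        }
      }
      return(invisible())
    }
    unas <- which(st$pi == 0L)
    cand <- lapply(unas, function(i) candidates_for(st, i))
    lens <- lengths(cand)
    if (any(lens == 0L)) return(invisible())
    sel <- which.min(lens)
    i <- unas[sel]
    js <- cand[[sel]]
    js <- if (mode == "bnb") js[order(A[i, js], js)] else sort(js)
    for (j in js) {
      st2 <- try_assign(st, i, j)
      if (!is.null(st2)) recurse(st2)
      if (!env$complete) return(invisible())
    }
    invisible()
  }

  st0 <- list(
    pi = integer(n), has_pre = logical(n),
    head_of = seq_len(n), tail_of = seq_len(n), len_of = rep(1L, n),
    n_assigned = 0L, cost = 0
  )
  recurse(st0)
  list(perms = env$perms, count = env$count, best_perm = env$best_perm,
       best_cost = env$best_cost, nodes = env$nodes, complete = env$complete)
}

#' Enumerate the structure-preserving permutations of a molecule
#'
#' Yields exactly the permutations that (a) map every atom within its
#' equivalence class, (b) satisfy the bond biconditional
#' pi(i)~pi(j) if and only if i~j, and (c) have all cycle lengths allowed for
#' the group (see [allowed_cycle_lengths()]). The identity is included (all
#' cycles of length 1). Output order is deterministic.
#'
#' @param mol a [molecule()] (bonds may be empty).
#' @param spec a [point_group()].
#' @param partition optional precomputed [equivalence_classes()].
#' @param cap maximum number of visited search nodes (default 1e7).
#' @return list of integer permutations; attribute `complete` reports whether
#'   the search finished under the cap.
#' @export
enumerate_sp_permutations <- function(mol, spec, partition = NULL, cap = 1e7) {
  spec <- point_group(spec)
  if (is.null(partition)) partition <- equivalence_classes(mol)
  res <- sp_search(bond_matrix(mol), partition$class_id,
                   allowed_cycle_lengths(spec), mode = "enumerate", cap = cap)
  structure(res$perms, complete = res$complete, nodes = res$nodes)
}

#' Count permutations of N elements with group-allowed cycle lengths
#'
#' The number of permutations of a single N-atom equivalence class whose cycle
#' lengths all lie in the allowed set for the group, ignoring bonds. For
#' order-2 groups this is the involution count I(N) = I(N-1) + (N-1) I(N-2).
#' Computed in double precision (exact up to ~15 significant digits).
#'
#' @param N number of atoms.
#' @param spec a [point_group()].
#' @return the count, as a double.
#' @export
count_unconstrained_permutations <- function(N, spec) {
  allowed <- allowed_cycle_lengths(point_group(spec))
  a <- numeric(N + 1L)
  a[1] <- 1          # a[k+1] holds the count for k elements
  for (k in seq_len(N)) {
    total <- a[k]    # k is a fixed point
    if (2L %in% allowed && k >= 2L) total <- total + (k - 1) * a[k - 1L]
    nn <- max(allowed)
    if (nn > 2L && k >= nn) {
      # cycles of length nn through element k: choose nn-1 partners, (nn-1)!
      # cyclic orders
      total <- total + prod(seq(k - 1, k - nn + 1)) * a[k - nn + 1L]
    }
    a[k + 1L] <- total
  }
  a[N + 1L]
}

#' Exact continuous symmetry measure
#'
#' Enumerates every structure-preserving permutation, computes the optimal
#' axis for the full group-averaged objective for each, and returns the global
#' minimum. The measure is trivially 0 only if some admissible permutation and
#' axis make the structure exactly invariant; the identity permutation is
#' admissible but the operation itself is never the identity, so the result is
#' non-trivial.
#'
#' @param mol a [molecule()] with bonds (possibly empty).
#' @param spec a [point_group()].
#' @param cap node cap for the enumeration; exceeding it aborts with guidance
#'   to the approximate engines.
#' @return a `molsym_csm` result (see [compute_csm()] for the fields).
#' @export
exact_csm <- function(mol, spec, cap = 1e7) {
  spec <- point_group(spec)
  molc <- center_molecule(mol)
  perms <- enumerate_sp_permutations(molc, spec, cap = cap)
  if (!attr(perms, "complete")) {
    stop("structure-preserving enumeration exceeded the node cap (",
         format(cap, scientific = TRUE), "); use an approximate engine ",
         "(hungarian, sp, fibonacci)", call. = FALSE)
  }
  if (!length(perms)) {
    stop("no admissible structure-preserving permutation for ", spec$label)
  }
  best <- NULL
  for (perm in perms) {
    axis <- optimal_axis(molc, perm, spec, mode = "full")
    op <- operation_matrix(spec, axis)
    m <- symmetry_objective(molc, perm, op, mode = "full")
    if (is.null(best) || m < best$m - 1e-15) {
      best <- list(perm = perm, axis = axis, m = m)
    }
  }
  make_csm_result(molc, spec, best$perm, best$axis, algorithm = "exact",
                  iterations = length(perms), converged = TRUE)
}
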