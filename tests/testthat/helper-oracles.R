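# Independent oracles used across the suite. These deliberately avoid the
# package's search/axis code paths: objectives are evaluated by direct
# summation with locally built matrices, minima come from exhaustive
# enumeration plus dense direction sampling.

# All n! permutations of 1..n as rows.
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L))
  do.call(rbind, lapply(seq_len(n), function(k) {
    sub <- all_perms(n - 1L)
    cbind(k, matrix((seq_len(n)[-k])[sub], nrow(sub)))
  }))
}

# Rotation by `angle` about unit `v`, written out componentwise.
oracle_rotation <- function(v, angle) {
  v <- v / sqrt(sum(v^2))
  c1 <- cos(angle); s1 <- sin(angle); t1 <- 1 - c1
  matrix(c(
    c1 + t1 * v[1]^2,        t1 * v[1] * v[2] + s1 * v[3], t1 * v[1] * v[3] - s1 * v[2],
    t1 * v[1] * v[2] - s1 * v[3], c1 + t1 * v[2]^2,        t1 * v[2] * v[3] + s1 * v[1],
    t1 * v[1] * v[3] + s1 * v[2], t1 * v[2] * v[3] - s1 * v[1], c1 + t1 * v[3]^2
  ), 3, 3)
}

# Generator power T^i for group (family, n) about axis v.
oracle_op_power <- function(family, n, v, i) {
  m <- oracle_rotation(v, 2 * pi * i / n)
  if (family == "S" && i %% 2 == 1) {
    v <- v / sqrt(sum(v^2))
    m <- m %*% (diag(3) - 2 * outer(v, v))
  }
  m
}

# Full group-averaged objective by direct term-by-term summation.
oracle_M <- function(coords, perm, family, n, axis) {
  g <- if (family == "S" && n <= 2) 2L else n
  q <- sweep(coords, 2, colMeans(coords))
  total <- 0
  p_i <- seq_len(nrow(q))
  for (i in seq_len(g)) {
    p_i <- perm[p_i]
    ti <- oracle_op_power(family, n, axis, i)
    for (k in seq_len(nrow(q))) {
      total <- total + sum((ti %*% q[k, ] - q[p_i[k], ])^2)
    }
  }
  total / (2 * g)
}

# Minimum of oracle_M over axes: dense seeded direction sample + local polish.
oracle_min_axis <- function(coords, perm, family, n, n_dirs = 300,
                            dir_seed = 99) {
  if (family == "S" && n == 2) {
    return(list(axis = c(0, 0, 1),
                M = oracle_M(coords, perm, family, n, c(0, 0, 1))))
  }
  set.seed(dir_seed)
  dirs <- matrix(rnorm(3 * n_dirs), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  dirs <- rbind(dirs, diag(3))
  vals <- apply(dirs, 1, function(v) oracle_M(coords, perm, family, n, v))
  best <- order(vals)[1:5]
  refine <- lapply(best, function(b) {
    optim(dirs[b, ], function(x) {
      nx <- sqrt(sum(x^2))
      if (nx < 1e-10) return(Inf)
      oracle_M(coords, perm, family, n, x / nx)
    }, method = "Nelder-Mead",
    control = list(reltol = 1e-15, maxit = 2000))
  })
  vals2 <- vapply(refine, `[[`, numeric(1), "value")
  k <- which.min(vals2)
  v <- refine[[k]]$par
  list(axis = v / sqrt(sum(v^2)), M = vals2[k])
}

# Direct check of the structure-preserving conditions for one permutation.
oracle_is_sp <- function(perm, elements, bondmat, allowed) {
  if (any(elements[perm] != elements)) return(FALSE)
  n <- length(perm)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (bondmat[i, j] != bondmat[perm[i], perm[j]]) return(FALSE)
    }
  }
  seen <- logical(n)
  for (i in seq_len(n)) {
    if (!seen[i]) {
      len <- 0L; j <- i
      repeat {
        seen[j] <- TRUE; len <- len + 1L; j <- perm[j]
        if (j == i) break
      }
      if (!(len %in% allowed)) return(FALSE)
    }
  }
  TRUE
}

# Brute-force exact CSM: filter all n! permutations by the SP conditions
# (element identity is used as the class relation: finer graph classes only
# subdivide it, and the bond biconditional is checked in full), then minimize
# the direct objective over axes for each.
oracle_exact_csm <- function(mol, family, n, n_dirs = 300) {
  q <- sweep(mol$coords, 2, colMeans(mol$coords))
  bm <- matrix(FALSE, nrow(q), nrow(q))
  if (nrow(mol$bonds)) {
    bm[mol$bonds] <- TRUE
    bm[mol$bonds[, 2:1, drop = FALSE]] <- TRUE
  }
  allowed <- if (family == "C") {
    if (n == 2) c(1, 2) else c(1, n)
  } else {
    if (n <= 2) c(1, 2) else c(1, 2, n)
  }
  pm <- all_perms(nrow(q))
  best <- Inf
  for (r in seq_len(nrow(pm))) {
    perm <- pm[r, ]
    if (!oracle_is_sp(perm, mol$elements, bm, allowed)) next
    m <- oracle_min_axis(q, perm, family, n, n_dirs = n_dirs)$M
    if (m < best) best <- m
  }
  100 * best / sum(q^2)
}

# A seeded random small molecule: nc atoms of element a, rest element b,
# coordinates uniform in a box, bonds by covalent inference.
random_small_molecule <- function(seed, n_atoms = 5, elements = c("C", "N")) {
  set.seed(seed)
  els <- sample(elements, n_atoms, replace = TRUE)
  coords <- matrix(runif(3 * n_atoms, -1.5, 1.5), ncol = 3)
  infer_bonds(molecule(els, coords), tolerance = 0.4)
}
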