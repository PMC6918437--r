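# Shared fixtures and independent oracles for the test suite.
# Everything is generated in code; no stored data files.

# Direct SimulationState construction for hand-built geometries.
makeState <- function(positions, species, box, moleculeId = NULL,
                      bonds = NULL, velocities = NULL, seed = 1L) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  if (is.null(moleculeId)) moleculeId <- seq_len(n)
  if (is.null(bonds)) bonds <- matrix(integer(), 0, 2)
  storage.mode(bonds) <- "integer"
  if (is.null(velocities)) velocities <- matrix(0, n, 3)
  if (!is.factor(species)) species <- factor(species)
  box <- rep_len(box, 3)
  for (d in 1:3) positions[, d] <- positions[, d] - box[d] * floor(positions[, d] / box[d])
  new("SimulationState", positions = positions, velocities = velocities,
      species = species, moleculeId = as.integer(moleculeId), bonds = bonds,
      box = box, step = 0L, rngSeed = as.integer(seed))
}

zeroChi <- function(species = c("A", "B")) {
  m <- matrix(0, length(species), length(species),
              dimnames = list(species, species))
  chiMatrix(m, temperature = 303)
}

# Brute-force cloud-in-cell deposition oracle: per-bead weight accumulation
# written independently in plain R.
depositOracle <- function(state, ncell) {
  box <- state@box
  h <- box / ncell
  lev <- levels(state@species)
  arr <- array(0, c(ncell, length(lev)))
  cv <- prod(h)
  for (i in seq_len(nrow(state@positions))) {
    u <- state@positions[i, ] / h
    j <- floor(u)
    t <- u - j
    k <- as.integer(state@species[i])
    for (a in 0:1) for (b in 0:1) for (cc in 0:1) {
      node <- (j + c(a, b, cc)) %% ncell + 1
      w <- prod(ifelse(c(a, b, cc) == 1, t, 1 - t))
      arr[node[1], node[2], node[3], k] <- arr[node[1], node[2], node[3], k] +
        w / cv
    }
  }
  arr
}

# Independent R re-implementation of the field-force path: central
# differences on the periodic mesh plus trilinear interpolation.
fieldForceOracle <- function(state, potentials) {
  vals <- gridValues(potentials)
  nc <- dim(vals)[1:3]
  h <- potentials@cellSize
  roll <- function(a, shift, dim) {
    idx <- lapply(dim(a), seq_len)
    idx[[dim]] <- (idx[[dim]] - 1 - shift) %% dim(a)[dim] + 1
    do.call(`[`, c(list(a), idx, list(drop = FALSE)))
  }
  grads <- lapply(1:3, function(d)
    (roll(vals, -1, d) - roll(vals, 1, d)) / (2 * h[d]))
  n <- nrow(state@positions)
  F <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    u <- state@positions[i, ] / h
    j <- floor(u)
    t <- u - j
    k <- as.integer(state@species[i])
    for (a in 0:1) for (b in 0:1) for (cc in 0:1) {
      node <- (j + c(a, b, cc)) %% nc + 1
      w <- prod(ifelse(c(a, b, cc) == 1, t, 1 - t))
      for (d in 1:3)
        F[i, d] <- F[i, d] - w * grads[[d]][node[1], node[2], node[3], k]
    }
  }
  F
}

# Union-find single-linkage oracle over all chain pairs.
unionFindOracle <- function(state, cutoff, linkageSpecies = "PPO") {
  link <- which(state@species %in% linkageSpecies)
  chains <- sort(unique(state@moleculeId[link]))
  parent <- seq_along(chains)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  mi <- function(d, L) d - L * round(d / L)
  for (ci in seq_along(chains)) for (cj in seq_len(ci - 1)) {
    bi <- link[state@moleculeId[link] == chains[ci]]
    bj <- link[state@moleculeId[link] == chains[cj]]
    touching <- FALSE
    for (x in bi) {
      d <- sweep(state@positions[bj, , drop = FALSE], 2,
                 state@positions[x, ])
      for (dd in 1:3) d[, dd] <- mi(d[, dd], state@box[dd])
      if (any(rowSums(d^2) <= cutoff^2)) {
        touching <- TRUE
        break
      }
    }
    if (touching) {
      ri <- find(ci); rj <- find(cj)
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_along(chains), find, integer(1))
  split(chains, roots)
}

# Dense gyration-tensor oracle: explicit tensor build + base eigen.
gyrationOracle <- function(coords) {
  cm <- colMeans(coords)
  S <- matrix(0, 3, 3)
  for (i in seq_len(nrow(coords)))
    S <- S + tcrossprod(coords[i, ] - cm)
  S <- S / nrow(coords)
  sort(eigen(S, symmetric = TRUE)$values)
}

# Random P123-in-water test box at reduced size.
smallP123System <- function(totalBeads = 2000, frac = 0.05, seed = 11L,
                            extra = c()) {
  comp <- compose(totalBeads, c(c(P123 = frac), extra))
  randomConfiguration(comp, seed = seed)
}
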