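# Density assignment, mean-field potentials, forces and energy.

test_that("deposition puts a node-centered bead entirely on its node", {
  st <- makeState(matrix(c(2, 4, 6), 1, 3), "PEO", box = 8)
  g <- assignDensity(st, ncell = c(4, 4, 4))
  v <- gridValues(g)
  cv <- prod(g@cellSize)
  expect_equal(v[2, 3, 4, 1], 1 / cv)
  v[2, 3, 4, 1] <- 0
  expect_true(all(v == 0))
})

test_that("a commensurate lattice of beads deposits a uniform field", {
  pts <- as.matrix(expand.grid(x = 0:3, y = 0:3, z = 0:3)) * 2
  st <- makeState(pts, rep("Water", 64), box = 8)
  g <- assignDensity(st, ncell = c(4, 4, 4))
  expect_equal(as.vector(gridValues(g)), rep(64 / 8^3, 64), tolerance = 1e-12)
})

test_that("deposition conserves per-species mass and matches the oracle", {
  set.seed(99)
  for (rep in 1:3) {
    st <- makeState(matrix(runif(3000, 0, 12.3), 1000, 3),
                    sample(c("PEO", "PPO", "Water"), 1000, replace = TRUE),
                    box = 12.3)
    g <- assignDensity(st, ncell = c(6, 6, 6))
    cv <- prod(g@cellSize)
    counts <- table(st@species)
    for (k in seq_along(speciesNames(g))) {
      integral <- sum(gridValues(g)[, , , k]) * cv
      expect_equal(integral, unname(counts[[speciesNames(g)[k]]]),
                   tolerance = 1e-10)
    }
    expect_equal(gridValues(g), depositOracle(st, c(6, 6, 6)),
                 tolerance = 1e-12)
    expect_true(all(gridValues(g) >= 0))
  }
})

test_that("grid resolution targets the requested cell size", {
  st <- makeState(matrix(5, 1, 3), "PEO", box = 21)
  g <- assignDensity(st, gridSize = 2.1)
  expect_identical(g@ncell, rep(10L, 3))
  expect_equal(g@cellSize, rep(2.1, 3))
})

uniformTwoSpecies <- function(phiEach, box = 8, ncell = 4) {
  # equal per-node counts of A and B give exactly uniform CIC fields
  pts <- as.matrix(expand.grid(x = seq_len(ncell) - 1,
                               y = seq_len(ncell) - 1,
                               z = seq_len(ncell) - 1)) * (box / ncell)
  n <- nrow(pts)
  makeState(rbind(pts, pts), c(rep("A", n), rep("B", n)), box = box)
}

test_that("potentials reduce to closed forms on uniform fields", {
  ncell <- 4; box <- 8
  st <- uniformTwoSpecies(box = box, ncell = ncell)
  g <- assignDensity(st, ncell = rep(ncell, 3))
  phiTot <- 2 * ncell^3 / box^3
  chiAB <- 5.5
  m <- matrix(c(0, chiAB, chiAB, 0), 2, 2,
              dimnames = rep(list(c("A", "B")), 2))
  # two species each at phi0/2: V_A = chiRT/2, incompressibility silent
  fp <- fieldParams(m, kappaInverse = 7, phi0 = phiTot)
  pot <- computePotentials(g, fp)
  expect_equal(as.vector(gridValues(pot)),
               rep(chiAB / 2, 2 * ncell^3), tolerance = 1e-12)
  # single species at 1.1 phi0 with chi = 0: V = 0.1 kappaInv everywhere
  gA <- assignDensity(makeState(st@positions[1:ncell^3, ], rep("A", ncell^3),
                                box), ncell = rep(ncell, 3))
  fpA <- fieldParams(matrix(0, 1, 1, dimnames = list("A", "A")),
                     kappaInverse = 7, phi0 = (ncell^3 / box^3) / 1.1)
  potA <- computePotentials(gA, fpA)
  expect_equal(as.vector(gridValues(potA)), rep(0.1 * 7, ncell^3),
               tolerance = 1e-9)
  # same single species exactly at phi0: V = 0 everywhere
  fp0 <- fieldParams(matrix(0, 1, 1, dimnames = list("A", "A")),
                     kappaInverse = 7, phi0 = ncell^3 / box^3)
  expect_equal(max(abs(gridValues(computePotentials(gA, fp0)))), 0)
})

test_that("potential chi term is linear in chiRT", {
  st <- smallP123System(800, seed = 3)
  g <- assignDensity(st, gridSize = 2.1)
  cmx <- referenceChiMatrix()
  fp1 <- fieldParams(cmx, kappaInverse = 0, phi0 = 0.725)
  fp2 <- fieldParams(chiMatrix(2 * chi(cmx), 303), kappaInverse = 0,
                     phi0 = 0.725)
  expect_equal(gridValues(computePotentials(g, fp2)),
               2 * gridValues(computePotentials(g, fp1)), tolerance = 1e-12)
})

test_that("field energy matches closed forms on uniform fields", {
  ncell <- 4; box <- 8
  st <- uniformTwoSpecies(box = box, ncell = ncell)
  g <- assignDensity(st, ncell = rep(ncell, 3))
  phiTot <- 2 * ncell^3 / box^3
  chiAB <- 3.3
  m <- matrix(c(0, chiAB, chiAB, 0), 2, 2,
              dimnames = rep(list(c("A", "B")), 2))
  fp <- fieldParams(m, kappaInverse = 9, phi0 = phiTot)
  # W = V_box phi0 chiRT_AB / 4 for two uniform species at phi0/2
  expect_equal(fieldEnergy(g, fp), box^3 * phiTot * chiAB / 4,
               tolerance = 1e-12)
  # single species exactly at phi0: W = 0
  gA <- assignDensity(makeState(st@positions[1:ncell^3, ], rep("A", ncell^3),
                                box), ncell = rep(ncell, 3))
  fpA <- fieldParams(matrix(0, 1, 1, dimnames = list("A", "A")),
                     kappaInverse = 9, phi0 = ncell^3 / box^3)
  expect_equal(fieldEnergy(gA, fpA), 0)
})

test_that("uniform potentials give zero force; ideal system gives zero force", {
  ncell <- 4; box <- 8
  st <- uniformTwoSpecies(box = box, ncell = ncell)
  g <- assignDensity(st, ncell = rep(ncell, 3))
  m <- matrix(c(0, 4, 4, 0), 2, 2, dimnames = rep(list(c("A", "B")), 2))
  fp <- fieldParams(m, kappaInverse = 5, phi0 = 2 * ncell^3 / box^3)
  F <- fieldForces(st, computePotentials(g, fp))
  expect_equal(max(abs(F)), 0)
  # chi = 0 and kappaInv = 0 reduces to an ideal system for any geometry
  st2 <- smallP123System(600, seed = 4)
  g2 <- assignDensity(st2, gridSize = 2.1)
  lev <- levels(st2@species)
  z <- matrix(0, length(lev), length(lev), dimnames = list(lev, lev))
  fpz <- fieldParams(z, kappaInverse = 0, phi0 = 0.725)
  F2 <- fieldForces(st2, computePotentials(g2, fpz))
  expect_equal(max(abs(F2)), 0)
})

test_that("forces match an independent dense finite-difference oracle", {
  set.seed(17)
  st <- makeState(matrix(runif(450, 0, 9), 150, 3),
                  sample(c("PEO", "Water"), 150, replace = TRUE), box = 9)
  g <- assignDensity(st, ncell = c(5, 5, 5))
  m <- matrix(c(0, 12, 12, 0), 2, 2,
              dimnames = rep(list(c("PEO", "Water")), 2))
  fp <- fieldParams(m, kappaInverse = 8, phi0 = 150 / 9^3)
  pot <- computePotentials(g, fp)
  F <- fieldForces(st, pot)
  expect_equal(F, fieldForceOracle(st, pot), tolerance = 1e-10)
  # discrete translation symmetry: total force vanishes
  expect_lt(max(abs(colSums(F))), 1e-8 * mean(sqrt(rowSums(F^2))))
})

test_that("forces agree with the energy gradient on a mesh-resolved field", {
  # smooth long-wavelength density along x on a fine quasi-1D mesh; the
  # probe bead sits at a cell midpoint where the central-difference /
  # trilinear force equals dW/dx to O(h^2) < 1e-4
  nx <- 400; boxv <- c(16, 2, 2)
  nb <- 400000
  qs <- (seq_len(nb) - 0.5) / nb
  # invert the CDF of rho(x) ~ 1 + 0.2 sin(2 pi x / L) by Newton iteration
  L <- boxv[1]
  x <- qs * L
  for (it in 1:40) {
    cdf <- (x + 0.2 * L / (2 * pi) * (1 - cos(2 * pi * x / L))) / L
    x <- x - (cdf - qs) * L / (1 + 0.2 * sin(2 * pi * x / L))
  }
  pos <- cbind(x, rep(1, nb), rep(1, nb))  # one y-z node plane, noise-free
  h <- L / nx
  probe <- c(37.5 * h, 1, 1)              # cell midpoint in x
  st <- makeState(rbind(pos, probe), rep("A", nb + 1), box = boxv)
  m <- matrix(0, 1, 1, dimnames = list("A", "A"))
  fp <- fieldParams(m, kappaInverse = 10, phi0 = nb / prod(boxv))
  ncell <- c(nx, 2L, 2L)
  force <- function(state) {
    g <- assignDensity(state, ncell = ncell)
    fieldForces(state, computePotentials(g, fp))
  }
  energy <- function(state)
    fieldEnergy(assignDensity(state, ncell = ncell), fp)
  Fx <- force(st)[nb + 1, 1]
  eps <- 1e-4
  shift <- function(dx) {
    s <- st
    s@positions[nb + 1, 1] <- s@positions[nb + 1, 1] + dx
    s
  }
  dWdx <- (energy(shift(eps)) - energy(shift(-eps))) / (2 * eps)
  expect_equal(Fx, -dWdx, tolerance = 1e-4)
  expect_gt(abs(Fx), 1e-3)  # the check is not vacuous
})

test_that("field energy decreases under overdamped demixing relaxation", {
  set.seed(31)
  n <- 1200; box <- 10
  st <- makeState(matrix(runif(3 * n, 0, box), n, 3),
                  sample(c("A", "B"), n, replace = TRUE), box = box)
  m <- matrix(c(0, 25, 25, 0), 2, 2, dimnames = rep(list(c("A", "B")), 2))
  fp <- fieldParams(m, kappaInverse = 10, phi0 = n / box^3)
  gamma <- 2e-4
  W <- numeric(25)
  for (it in 1:25) {
    g <- assignDensity(st, ncell = c(5, 5, 5))
    W[it] <- fieldEnergy(g, fp)
    F <- fieldForces(st, computePotentials(g, fp))
    p <- st@positions + gamma * F
    for (d in 1:3) p[, d] <- p[, d] - box * floor(p[, d] / box)
    p[p >= box] <- 0
    st@positions <- p
  }
  expect_true(all(diff(W) <= 1e-9 * abs(W[-length(W)])))
  expect_lt(W[25], W[1])
})

test_that("field dumps are self-describing text", {
  st <- smallP123System(300, seed = 19)
  g <- assignDensity(st, gridSize = 2.1)
  f <- tempfile(fileext = ".txt")
  writeFieldDump(g, f)
  lines <- readLines(f)
  expect_match(lines[1], "DensityGrid")
  expect_match(lines[1], paste(g@ncell, collapse = " "))
  for (s in speciesNames(g))
    expect_true(any(grepl(paste("# species", s), lines, fixed = TRUE)))
})

test_that("species mismatches and corrupt states are reported", {
  st <- smallP123System(500, seed = 6)
  g <- assignDensity(st, gridSize = 2.1)
  m <- matrix(0, 2, 2, dimnames = rep(list(c("X", "Y")), 2))
  expect_error(computePotentials(g, fieldParams(m)), "configuration error")
  stBad <- st
  stBad@positions[1, 1] <- NaN
  expect_error(assignDensity(stBad, gridSize = 2.1), "corrupt")
})
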