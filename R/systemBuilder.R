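#' Cubic box edge from bead count and number density
#'
#' @param totalBeads number of beads.
#' @param numberDensity beads/nm^3.
#' @return box edge length, nm.
#' @examples
#' boxFromDensity(192000, 0.725)   # ~64.2 nm
#' @export
boxFromDensity <- function(totalBeads, numberDensity = 0.725) {
  if (totalBeads <= 0 || numberDensity <= 0)
    stop("invalid parameter: totalBeads and numberDensity must be positive")
  (totalBeads / numberDensity)^(1 / 3)
}

.roundHalfUp <- function(x) floor(x + 0.5)

#' Turn a volume-fraction recipe into exact bead counts
#'
#' Polymer components (fraction names matching a template name) are rounded to
#' the nearest whole chain; single-bead species to the nearest bead; the
#' solvent absorbs the rounding remainder so counts sum exactly to
#' \code{totalBeads}.
#'
#' @param totalBeads total bead count.
#' @param fractions named volume fractions in [0, 1] summing to at most 1;
#'   names are template names (e.g. "P123") or species labels (e.g.
#'   "Ethanol", "Oil"). The remainder is assigned to \code{solventSpecies}.
#' @param templates list of \linkS4class{ChainTemplate} objects.
#' @param numberDensity bead number density, beads/nm^3.
#' @param solventSpecies label of the filler solvent.
#' @return a \linkS4class{SystemComposition}.
#' @examples
#' compose(192000, c(P123 = 0.10))   # 19,206 polymer beads + 172,794 water
#' @export
compose <- function(totalBeads = 192000, fractions = numeric(),
                    templates = list(p123Template()), numberDensity = 0.725,
                    solventSpecies = "Water") {
  if (length(fractions) && (any(fractions < 0) || any(fractions > 1)))
    stop("fractions must lie in [0, 1]")
  if (sum(fractions) > 1 + 1e-12)
    stop("over-filled recipe: fractions sum to more than 1")
  templateNames <- vapply(templates, function(t) t@name, character(1))
  chainCounts <- numeric()
  beadCounts <- numeric()
  for (nm in names(fractions)) {
    if (nm %in% templateNames) {
      tpl <- templates[[match(nm, templateNames)]]
      len <- length(tpl@sequence)
      nchain <- .roundHalfUp(totalBeads * fractions[[nm]] / len)
      chainCounts[nm] <- nchain
      beadCounts[nm] <- nchain * len
    } else {
      beadCounts[nm] <- .roundHalfUp(totalBeads * fractions[[nm]])
    }
  }
  solvent <- totalBeads - sum(beadCounts)
  if (solvent < 0)
    stop("over-filled recipe: no room left for ", solventSpecies)
  beadCounts[solventSpecies] <- solvent
  new("SystemComposition", totalBeads = totalBeads,
      fractions = unlist(fractions) %||% numeric(), chainCounts = chainCounts,
      beadCounts = beadCounts,
      boxLength = boxFromDensity(totalBeads, numberDensity),
      numberDensity = numberDensity)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.canonicalSpecies <- c("PEO", "PPO", "Water", "Ethanol", "Oil")

.speciesLevels <- function(labels) {
  known <- .canonicalSpecies[.canonicalSpecies %in% labels]
  c(known, setdiff(labels, known))
}

.wrap <- function(x, L) {
  x <- x - L * floor(x / L)
  x[x >= L] <- 0
  x
}

.defaultMasses <- function(species) {
  stats::setNames(rep(360, length(species)), species) # 20 x 18.015 u water bead
}

.mbVelocities <- function(n, massPerBead, temperature) {
  sigma <- sqrt(.gasConstantKJ * temperature / massPerBead)
  matrix(stats::rnorm(3 * n), n, 3) * sigma
}

# Assemble a SimulationState from per-component blocks.
.buildState <- function(posList, specList, molList, bondList, box, seed,
                        temperature, masses) {
  positions <- do.call(rbind, posList)
  labels <- unlist(specList, use.names = FALSE)
  lev <- .speciesLevels(unique(labels))
  species <- factor(labels, levels = lev)
  moleculeId <- as.integer(unlist(molList, use.names = FALSE))
  bonds <- if (length(bondList)) do.call(rbind, bondList)
           else matrix(integer(), 0, 2)
  storage.mode(bonds) <- "integer"
  if (is.null(masses)) masses <- .defaultMasses(lev)
  vel <- .mbVelocities(nrow(positions), masses[as.character(species)],
                       temperature)
  for (d in 1:3) positions[, d] <- .wrap(positions[, d], box)
  new("SimulationState",
      positions = positions,
      velocities = vel, species = species, moleculeId = moleculeId,
      bonds = bonds, box = rep(box, 3), step = 0L, rngSeed = as.integer(seed))
}

#' Random initial configuration for a composition
#'
#' Polymer chains are grown as freely jointed random walks with the template
#' bond length; solvent beads are placed uniformly at random. The model has no
#' excluded volume beyond the density field, so overlaps are permitted.
#' Velocities are drawn from the Maxwell--Boltzmann distribution at
#' \code{temperature}. Fully reproducible for a given seed.
#'
#' @param composition a \linkS4class{SystemComposition}.
#' @param templates list of \linkS4class{ChainTemplate} objects.
#' @param temperature velocity-initialization temperature, K.
#' @param masses named per-species bead masses, u (default 360 u for all).
#' @param seed integer seed.
#' @return a \linkS4class{SimulationState}.
#' @export
randomConfiguration <- function(composition, templates = list(p123Template()),
                                temperature = 303, masses = NULL, seed = 1L) {
  set.seed(seed)
  box <- composition@boxLength
  templateNames <- vapply(templates, function(t) t@name, character(1))
  posList <- list(); specList <- list(); molList <- list(); bondList <- list()
  offset <- 0L; mol <- 0L
  for (nm in names(composition@chainCounts)) {
    tpl <- templates[[match(nm, templateNames)]]
    len <- length(tpl@sequence)
    for (k in seq_len(composition@chainCounts[[nm]])) {
      mol <- mol + 1L
      pos <- matrix(0, len, 3)
      pos[1, ] <- stats::runif(3, 0, box)
      if (len > 1) {
        # random unit steps of length rBond
        u <- matrix(stats::rnorm(3 * (len - 1)), len - 1, 3)
        u <- u / sqrt(rowSums(u^2))
        pos[-1, ] <- u * tpl@rBond
        pos <- apply(pos, 2, cumsum)
      }
      posList[[length(posList) + 1L]] <- pos
      specList[[length(specList) + 1L]] <- tpl@sequence
      molList[[length(molList) + 1L]] <- rep(mol, len)
      if (nrow(tpl@bonds) > 0)
        bondList[[length(bondList) + 1L]] <- tpl@bonds + offset
      offset <- offset + len
    }
  }
  solventCounts <- composition@beadCounts[
    setdiff(names(composition@beadCounts), names(composition@chainCounts))]
  for (nm in names(solventCounts)) {
    n <- solventCounts[[nm]]
    if (n == 0) next
    posList[[length(posList) + 1L]] <- matrix(stats::runif(3 * n, 0, box), n, 3)
    specList[[length(specList) + 1L]] <- rep(nm, n)
    molList[[length(molList) + 1L]] <- mol + seq_len(n)
    mol <- mol + as.integer(n)
    offset <- offset + as.integer(n)
  }
  .buildState(posList, specList, molList, bondList, box, seed, temperature,
              masses)
}

#' Preassembled core--shell micelle fixture
#'
#' Places the core species (PPO) beads of each chain uniformly inside a sphere
#' of \code{coreRadius} centered in the box, the corona (PEO) beads in a
#' surrounding shell, and solvent uniformly outside the corona. Bond lengths
#' are not respected; this is a geometric fixture for validating aggregate
#' detection, shape descriptors and radial profiles against construction
#' parameters.
#'
#' @param nChains number of copolymer chains (>= 1).
#' @param coreRadius core radius, nm.
#' @param seed integer seed.
#' @param shellThickness corona shell thickness, nm.
#' @param box cubic box edge, nm; default 4 * (coreRadius + shellThickness).
#' @param solventSpecies filler species label.
#' @param numberDensity total bead density used to size the solvent bath.
#' @param template chain template (default P123).
#' @param temperature velocity-initialization temperature, K.
#' @return a \linkS4class{SimulationState}.
#' @export
preassembledMicelle <- function(nChains, coreRadius, seed = 1L,
                                shellThickness = 1.5, box = NULL,
                                solventSpecies = "Water",
                                numberDensity = 0.725,
                                template = p123Template(),
                                temperature = 303) {
  if (nChains < 1) stop("nChains must be >= 1")
  coronaRadius <- coreRadius + shellThickness
  if (is.null(box)) box <- 4 * coronaRadius
  if (2 * coronaRadius >= box)
    stop("geometry error: core plus shell does not fit in the box")
  set.seed(seed)
  center <- rep(box / 2, 3)
  sphere <- function(n, rmin, rmax) {
    r <- (stats::runif(n, rmin^3, rmax^3))^(1 / 3)
    u <- matrix(stats::rnorm(3 * n), n, 3)
    u <- u / sqrt(rowSums(u^2))
    sweep(u * r, 2, center, "+")
  }
  len <- length(template@sequence)
  core <- template@sequence == "PPO"
  posList <- list(); specList <- list(); molList <- list(); bondList <- list()
  offset <- 0L
  for (k in seq_len(nChains)) {
    pos <- matrix(0, len, 3)
    pos[core, ] <- sphere(sum(core), 0, coreRadius)
    pos[!core, ] <- sphere(sum(!core), coreRadius, coronaRadius)
    posList[[k]] <- pos
    specList[[k]] <- template@sequence
    molList[[k]] <- rep(k, len)
    if (nrow(template@bonds) > 0) bondList[[k]] <- template@bonds + offset
    offset <- offset + len
  }
  nSolvent <- max(0L, .roundHalfUp(numberDensity * box^3) - nChains * len)
  if (nSolvent > 0) {
    pts <- matrix(numeric(), 0, 3)
    while (nrow(pts) < nSolvent) {
      cand <- matrix(stats::runif(3 * nSolvent, 0, box), nSolvent, 3)
      d <- sqrt(rowSums(sweep(cand, 2, center)^2))
      pts <- rbind(pts, cand[d > coronaRadius, , drop = FALSE])
    }
    pts <- pts[seq_len(nSolvent), , drop = FALSE]
    posList[[length(posList) + 1L]] <- pts
    specList[[length(specList) + 1L]] <- rep(solventSpecies, nSolvent)
    molList[[length(molList) + 1L]] <- nChains + seq_len(nSolvent)
  }
  .buildState(posList, specList, molList, bondList, box, seed, temperature,
              NULL)
}
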