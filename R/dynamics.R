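#' NVT integrator parameters
#'
#' Defaults follow the production protocol of the bundled model: dt = 0.03 ps,
#' 303 K, Andersen collision frequency 20/ps. Bead masses are not part of the
#' coarse-grained mapping; every species defaults to the water-bead mass
#' (20 x 18.015 u, ~360 u) since dynamics at this level are fictitious anyway.
#'
#' @param dt time step, ps.
#' @param temperature target temperature, K.
#' @param collisionFrequency Andersen collision frequency, 1/ps.
#' @param mass per-species bead mass, u: a single number or a named vector.
#' @param nSteps number of steps for \code{runSimulation}.
#' @param species species labels the mass vector should cover.
#' @return an \linkS4class{IntegratorParams}.
#' @export
integratorParams <- function(dt = 0.03, temperature = 303,
                             collisionFrequency = 20, mass = 360,
                             nSteps = 0, species = .canonicalSpecies) {
  if (is.null(names(mass)))
    mass <- stats::setNames(rep_len(mass, length(species)), species)
  new("IntegratorParams", dt = dt, temperature = temperature,
      collisionFrequency = collisionFrequency, mass = mass, nSteps = nSteps)
}

.massVector <- function(params, lev) {
  m <- params@mass[lev]
  if (any(is.na(m)))
    stop("no mass given for species ", paste(lev[is.na(m)], collapse = ", "))
  unname(m)
}

#' Harmonic bond forces and energy
#'
#' V(R) = (1/2) k (R - r0)^2 per bond under the minimum-image convention;
#' forces are equal and opposite along the bond. A bond longer than half the
#' shortest box edge raises a minimum-image violation error.
#'
#' @param state a \linkS4class{SimulationState}.
#' @param kBond force constant, kJ/mol/nm^2.
#' @param rBond equilibrium length, nm.
#' @return list with \code{forces} (N x 3, kJ/mol/nm) and \code{energy}
#'   (kJ/mol).
#' @export
bondForces <- function(state, kBond = 10000, rBond = 1.12) {
  if (nrow(state@bonds) == 0)
    return(list(forces = matrix(0, nrow(state@positions), 3), energy = 0))
  cpp_bond_forces(state@positions, state@bonds - 1L, kBond, rBond, state@box)
}

#' One velocity-Verlet step
#'
#' Standard half-kick / drift / half-kick update: velocities advance half a
#' step on the supplied forces, positions drift and are rewrapped, forces are
#' recomputed via \code{forceFn} at the new positions, and velocities finish
#' the step. Useful for driving the integrator with an arbitrary external
#' force (the production loop lives in \code{\link{runSimulation}}).
#'
#' @param state a \linkS4class{SimulationState}.
#' @param forces N x 3 forces current for \code{state}, kJ/mol/nm.
#' @param params an \linkS4class{IntegratorParams}.
#' @param forceFn function(state) -> N x 3 forces at the drifted positions.
#' @return list with the updated \code{state} and the new \code{forces}.
#' @export
velocityVerletStep <- function(state, forces, params,
                               forceFn = function(s) forces * 0) {
  m <- .massVector(params, levels(state@species))[as.integer(state@species)]
  dt <- params@dt
  vel <- state@velocities + 0.5 * dt * forces / m
  pos <- state@positions + vel * dt
  if (!all(is.finite(pos)))
    stop("integration blow-up at step ", state@step + 1L,
         ": non-finite positions (max displacement ",
         signif(max(abs(vel * dt)), 4), " nm)")
  for (d in 1:3) pos[, d] <- .wrap(pos[, d], state@box[d])
  state@positions <- pos
  newForces <- forceFn(state)
  vel <- vel + 0.5 * dt * newForces / m
  state@velocities <- vel
  state@step <- state@step + 1L
  validObject(state)
  list(state = state, forces = newForces)
}

#' Andersen thermostat collisions
#'
#' Each bead independently has its velocity resampled from the
#' Maxwell--Boltzmann distribution at the target temperature with probability
#' 1 - exp(-nu dt) per step (exact for any nu dt). Uses R's RNG stream, so
#' wrap in \code{set.seed} for reproducibility; the production loop in
#' \code{\link{runSimulation}} uses its own seeded stream instead.
#'
#' @param state a \linkS4class{SimulationState}.
#' @param params an \linkS4class{IntegratorParams}.
#' @return the state with resampled velocities.
#' @export
andersenCollisions <- function(state, params) {
  nu <- params@collisionFrequency
  if (nu == 0) return(state)
  n <- nrow(state@velocities)
  p <- 1 - exp(-nu * params@dt)
  hit <- stats::runif(n) < p
  if (any(hit)) {
    m <- .massVector(params, levels(state@species))[as.integer(state@species)]
    sigma <- sqrt(.gasConstantKJ * params@temperature / m[hit])
    state@velocities[hit, ] <- matrix(stats::rnorm(3 * sum(hit)),
                                      sum(hit), 3) * sigma
  }
  state
}

#' Instantaneous kinetic temperature
#'
#' @param state a \linkS4class{SimulationState}.
#' @param params an \linkS4class{IntegratorParams} (for the masses).
#' @return temperature in K from equipartition over 3N degrees of freedom.
#' @export
kineticTemperature <- function(state, params) {
  m <- .massVector(params, levels(state@species))[as.integer(state@species)]
  sum(m * rowSums(state@velocities^2)) /
    (3 * nrow(state@velocities) * .gasConstantKJ)
}

#' Run the stale-field particle-field MD loop
#'
#' Velocity-Verlet NVT dynamics with harmonic bonds and mean-field forces.
#' The density field, node potentials and mesh gradients are refreshed every
#' \code{params@updateInterval} steps and frozen in between; forces between
#' updates are interpolated from the frozen mesh at the current bead
#' positions. Andersen collisions are applied after each full step. The run
#' is bit-reproducible for a given seed (single-threaded).
#'
#' @param state initial \linkS4class{SimulationState}.
#' @param fieldParams a \linkS4class{FieldParams}.
#' @param integratorParams an \linkS4class{IntegratorParams}.
#' @param gridSize target mesh cell edge, nm.
#' @param ncell explicit cells per axis (overrides gridSize).
#' @param frameStride steps between stored frames (0 = endpoints only).
#' @param logStride steps between log records.
#' @param kBond,rBond harmonic bond constants.
#' @param seed integer seed for the thermostat stream; defaults to the
#'   state's \code{rngSeed}.
#' @param trajectoryPath optional extended-XYZ file to write frames to.
#' @param logPath optional TSV file for the time series.
#' @return a \linkS4class{Trajectory}; its log holds step, instantaneous
#'   temperature, bond energy and field energy.
#' @export
runSimulation <- function(state, fieldParams, integratorParams,
                          gridSize = 2.1, ncell = NULL, frameStride = 0L,
                          logStride = 0L, kBond = 10000, rBond = 1.12,
                          seed = NULL, trajectoryPath = NULL,
                          logPath = NULL) {
  lev <- levels(state@species)
  chiRT <- .matchChiRT(fieldParams, lev)
  ncell <- .gridCells(state@box, gridSize, ncell)
  mass <- .massVector(integratorParams, lev)
  if (is.null(seed)) seed <- state@rngSeed
  res <- cpp_run(state@positions, state@velocities,
                 as.integer(state@species) - 1L, state@bonds - 1L,
                 state@box, ncell, chiRT, fieldParams@kappaInverse,
                 fieldParams@phi0, fieldParams@updateInterval,
                 integratorParams@dt, integratorParams@temperature,
                 integratorParams@collisionFrequency, mass, kBond, rBond,
                 as.integer(integratorParams@nSteps),
                 as.integer(frameStride), as.integer(logStride),
                 as.double(seed))
  logDf <- as.data.frame(res$log)
  names(logDf) <- c("step", "temperature", "bondEnergy", "fieldEnergy")
  finalState <- state
  finalState@positions <- res$finalPositions
  finalState@velocities <- res$finalVelocities
  finalState@step <- state@step + as.integer(integratorParams@nSteps)
  traj <- new("Trajectory", steps = res$frameSteps + state@step,
              dt = integratorParams@dt, positions = res$frames,
              unwrapped = res$framesUnwrapped, species = state@species,
              moleculeId = state@moleculeId, bonds = state@bonds,
              box = state@box, log = logDf, finalState = finalState)
  if (!is.null(trajectoryPath)) writeTrajectory(traj, trajectoryPath)
  if (!is.null(logPath)) {
    ok <- tryCatch({
      utils::write.table(logDf, logPath, sep = "\t", row.names = FALSE,
                         quote = FALSE)
      TRUE
    }, error = function(e) e)
    if (!isTRUE(ok))
      stop("failed to write run log to '", logPath, "': ",
           conditionMessage(ok))
  }
  traj
}

#' Checkpoint a simulation state to disk
#'
#' Serializes the complete state (positions, velocities, topology, box, step,
#' seed) losslessly; \code{readCheckpoint} restores an identical object.
#'
#' @param state a \linkS4class{SimulationState}.
#' @param path checkpoint file.
#' @return invisibly, the path.
#' @export
writeCheckpoint <- function(state, path) {
  saveRDS(state, path)
  invisible(path)
}

#' @rdname writeCheckpoint
#' @export
readCheckpoint <- function(path) {
  state <- readRDS(path)
  validObject(state)
  state
}
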