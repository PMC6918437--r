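#' @import methods
NULL

# Physical constants used throughout (SI where noted).
.kBoltzmann <- 1.380649e-23   # J/K
.gasConstant <- 8.314         # J/mol/K
.gasConstantKJ <- 8.314e-3    # kJ/mol/K
.avogadro <- 6.02214e23

#' Pairwise Flory--Huggins interaction matrix
#'
#' Holds the dimensionless chi matrix for a set of bead species together with
#' its energy-unit counterpart chiRT = chi * R * T (kJ/mol), the form in which
#' the mean-field potentials consume it. Both matrices are symmetric with a
#' zero diagonal; asymmetric input is rejected by the validity method rather
#' than silently averaged.
#'
#' @slot species ordered character vector of species labels.
#' @slot chi symmetric dimensionless matrix, zero diagonal.
#' @slot chiRT symmetric matrix in kJ/mol, \code{chi * R * T}.
#' @slot temperature temperature in K used for the chi -> chiRT conversion.
#' @export
setClass("ChiMatrix",
  representation(species = "character", chi = "matrix", chiRT = "matrix",
                 temperature = "numeric"))

setValidity("ChiMatrix", function(object) {
  ns <- length(object@species)
  msg <- character()
  if (!all(dim(object@chi) == c(ns, ns)) || !all(dim(object@chiRT) == c(ns, ns)))
    msg <- c(msg, "chi and chiRT must be square matrices matching species")
  else {
    if (max(abs(object@chi - t(object@chi))) > 1e-12 * (1 + max(abs(object@chi))))
      msg <- c(msg, "chi matrix must be symmetric")
    if (any(abs(diag(object@chi)) > 1e-12))
      msg <- c(msg, "chi diagonal must be zero")
    expected <- object@chi * .gasConstantKJ * object@temperature
    rel <- abs(object@chiRT - expected) / pmax(abs(expected), 1e-12)
    if (any(rel[object@chi != 0] > 0.01))
      msg <- c(msg, "chiRT must equal chi * R * T within 1%")
  }
  if (length(object@temperature) != 1 || object@temperature <= 0)
    msg <- c(msg, "temperature must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Linear chain template
#'
#' Describes one coarse-grained molecule type: the ordered bead species along
#' the chain and the harmonic bond parameters joining consecutive beads. The
#' model has no angular terms.
#'
#' @slot name template label, e.g. "P123".
#' @slot sequence ordered species labels along the chain.
#' @slot bonds two-column integer matrix of bonded bead indices (consecutive).
#' @slot rBond equilibrium bond length, nm.
#' @slot kBond force constant, kJ/mol/nm^2.
#' @export
setClass("ChainTemplate",
  representation(name = "character", sequence = "character", bonds = "matrix",
                 rBond = "numeric", kBond = "numeric"))

setValidity("ChainTemplate", function(object) {
  msg <- character()
  nb <- nrow(object@bonds)
  if (nb > 0) {
    if (ncol(object@bonds) != 2) msg <- c(msg, "bonds must have two columns")
    else if (any(object@bonds[, 2] - object@bonds[, 1] != 1))
      msg <- c(msg, "bonds must connect consecutive beads only")
  }
  if (object@rBond <= 0) msg <- c(msg, "rBond must be positive")
  if (object@kBond < 0) msg <- c(msg, "kBond must be non-negative")
  if (length(msg)) msg else TRUE
})

#' System composition from a volume-fraction recipe
#'
#' @slot totalBeads total bead count.
#' @slot fractions named volume fractions of the recipe (templates and
#'   single-bead species); the remainder is solvent.
#' @slot chainCounts named chain counts per template.
#' @slot beadCounts named per-species or per-component bead counts summing to
#'   \code{totalBeads}.
#' @slot boxLength cubic box edge, nm.
#' @slot numberDensity bead number density, beads/nm^3.
#' @export
setClass("SystemComposition",
  representation(totalBeads = "numeric", fractions = "numeric",
                 chainCounts = "numeric", beadCounts = "numeric",
                 boxLength = "numeric", numberDensity = "numeric"))

setValidity("SystemComposition", function(object) {
  msg <- character()
  if (abs(sum(object@beadCounts) - object@totalBeads) > 1e-9)
    msg <- c(msg, "bead counts must sum exactly to totalBeads")
  if (any(object@beadCounts < 0)) msg <- c(msg, "negative bead count")
  if (object@numberDensity <= 0) msg <- c(msg, "numberDensity must be positive")
  if (length(msg)) msg else TRUE
})

#' Complete particle state of a simulation
#'
#' Positions are wrapped into the half-open periodic box [0, L). Bonds are
#' intra-molecular only.
#'
#' @slot positions N x 3 matrix, nm, wrapped.
#' @slot velocities N x 3 matrix, nm/ps.
#' @slot species per-bead species as a factor (levels define the ordering used
#'   by chi matrices and density fields).
#' @slot moleculeId per-bead molecule index.
#' @slot bonds two-column integer matrix of bonded bead indices (1-based).
#' @slot box box edge lengths, nm (length 3).
#' @slot step integration step counter.
#' @slot rngSeed integer seed from which the run's random streams derive.
#' @export
setClass("SimulationState",
  representation(positions = "matrix", velocities = "matrix",
                 species = "factor", moleculeId = "integer", bonds = "matrix",
                 box = "numeric", step = "integer", rngSeed = "integer"))

setValidity("SimulationState", function(object) {
  msg <- character()
  n <- nrow(object@positions)
  if (!all(is.finite(object@positions))) msg <- c(msg, "non-finite positions")
  if (!all(is.finite(object@velocities))) msg <- c(msg, "non-finite velocities")
  if (length(object@box) != 3 || any(object@box <= 0))
    msg <- c(msg, "box must be three positive edge lengths")
  if (nrow(object@velocities) != n || length(object@species) != n ||
      length(object@moleculeId) != n)
    msg <- c(msg, "positions, velocities, species, moleculeId must agree in length")
  if (all(is.finite(object@positions)) && n > 0) {
    for (d in 1:3)
      if (any(object@positions[, d] < 0 | object@positions[, d] >= object@box[d])) {
        msg <- c(msg, "positions must lie in the half-open box [0, L)")
        break
      }
  }
  if (nrow(object@bonds) > 0) {
    b <- object@bonds
    if (any(b < 1 | b > n)) msg <- c(msg, "bond index out of range")
    else if (any(object@moleculeId[b[, 1]] != object@moleculeId[b[, 2]]))
      msg <- c(msg, "bond partners must belong to the same molecule")
  }
  if (length(msg)) msg else TRUE
})

#' Scalar fields on the periodic mesh
#'
#' \code{FieldGrid} is the common container: a 4-D array of per-species node
#' values with grid geometry. \code{DensityGrid} (beads/nm^3, non-negative,
#' mass-conserving) and \code{PotentialField} (kJ/mol) specialize it.
#'
#' @slot values array with dim (nx, ny, nz, nspecies).
#' @slot ncell integer cells per axis.
#' @slot cellSize cell edge lengths, nm.
#' @slot box box edge lengths, nm.
#' @slot species species labels in slab order.
#' @export
setClass("FieldGrid",
  representation(values = "array", ncell = "integer", cellSize = "numeric",
                 box = "numeric", species = "character"))

setValidity("FieldGrid", function(object) {
  msg <- character()
  d <- dim(object@values)
  if (length(d) != 4) msg <- c(msg, "values must be a 4-D array")
  else {
    if (!all(d[1:3] == object@ncell)) msg <- c(msg, "values dim must match ncell")
    if (d[4] != length(object@species))
      msg <- c(msg, "fourth dim must match species")
  }
  if (any(abs(object@cellSize * object@ncell - object@box) >
          1e-9 * max(object@box)))
    msg <- c(msg, "cellSize * ncell must equal box")
  if (length(msg)) msg else TRUE
})

#' @rdname FieldGrid-class
#' @export
setClass("DensityGrid", contains = "FieldGrid")

setValidity("DensityGrid", function(object) {
  if (any(object@values < 0)) "densities must be non-negative" else TRUE
})

#' @rdname FieldGrid-class
#' @export
setClass("PotentialField", contains = "FieldGrid")

#' Mean-field interaction parameters for the field engine
#'
#' @slot species species ordering shared with the density grid.
#' @slot chiRT symmetric interaction matrix, kJ/mol.
#' @slot kappaInverse incompressibility strength 1/kappa, kJ/mol.
#' @slot phi0 reference total number density, beads/nm^3.
#' @slot updateInterval steps between density-field refreshes.
#' @export
setClass("FieldParams",
  representation(species = "character", chiRT = "matrix",
                 kappaInverse = "numeric", phi0 = "numeric",
                 updateInterval = "integer"))

setValidity("FieldParams", function(object) {
  msg <- character()
  ns <- length(object@species)
  if (!all(dim(object@chiRT) == c(ns, ns)))
    msg <- c(msg, "chiRT must be square matching species")
  else if (max(abs(object@chiRT - t(object@chiRT))) >
           1e-10 * (1 + max(abs(object@chiRT))))
    msg <- c(msg, "chiRT must be symmetric")
  if (object@kappaInverse < 0) msg <- c(msg, "kappaInverse must be >= 0")
  if (object@phi0 <= 0) msg <- c(msg, "phi0 must be positive")
  if (object@updateInterval < 1) msg <- c(msg, "updateInterval must be >= 1")
  if (length(msg)) msg else TRUE
})

#' NVT integrator parameters
#'
#' @slot dt time step, ps.
#' @slot temperature thermostat target, K.
#' @slot collisionFrequency Andersen collision frequency, 1/ps.
#' @slot mass named per-species bead masses, u.
#' @slot nSteps number of integration steps.
#' @export
setClass("IntegratorParams",
  representation(dt = "numeric", temperature = "numeric",
                 collisionFrequency = "numeric", mass = "numeric",
                 nSteps = "numeric"))

setValidity("IntegratorParams", function(object) {
  msg <- character()
  if (object@dt <= 0) msg <- c(msg, "dt must be positive")
  if (object@temperature <= 0) msg <- c(msg, "temperature must be positive")
  if (object@collisionFrequency < 0)
    msg <- c(msg, "collisionFrequency must be >= 0")
  if (any(object@mass <= 0)) msg <- c(msg, "masses must be positive")
  if (object@nSteps < 0) msg <- c(msg, "nSteps must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Trajectory of a particle-field MD run
#'
#' @slot steps frame step numbers.
#' @slot dt integration time step, ps.
#' @slot positions list of wrapped N x 3 frames, nm.
#' @slot unwrapped list of unwrapped N x 3 frames, nm.
#' @slot species per-bead species factor.
#' @slot moleculeId per-bead molecule index.
#' @slot bonds bonded index pairs.
#' @slot box box edges, nm.
#' @slot log data.frame with step, temperature, bondEnergy, fieldEnergy.
#' @slot finalState \code{SimulationState} at the last step.
#' @export
setClass("Trajectory",
  representation(steps = "integer", dt = "numeric", positions = "list",
                 unwrapped = "list", species = "factor",
                 moleculeId = "integer", bonds = "matrix", box = "numeric",
                 log = "data.frame", finalState = "SimulationState"))

#' A detected aggregate of copolymer chains
#'
#' @slot chainIds molecule ids of the member chains.
#' @slot beadIndices indices of all member beads.
#' @slot com aggregate center of mass (minimum-image consistent, wrapped), nm.
#' @slot size number of member chains (the aggregation number P_i).
#' @export
setClass("Aggregate",
  representation(chainIds = "integer", beadIndices = "integer",
                 com = "numeric", size = "integer"))

setValidity("Aggregate", function(object) {
  if (object@size < 1) "aggregate size must be >= 1" else TRUE
})

#' Gyration-tensor shape descriptors of an aggregate
#'
#' Eigenvalues are sorted ascending; \code{rg^2 = lambda1+lambda2+lambda3};
#' the asphericity \code{q} is 0 for a sphere and 1 for a rod (defined as 0
#' for a single bead).
#'
#' @slot lambda eigenvalues (nm^2), ascending.
#' @slot rg radius of gyration, nm.
#' @slot rgCore radius of gyration of the core species only, nm.
#' @slot q asphericity, dimensionless in [0, 1].
#' @export
setClass("ShapeDescriptors",
  representation(lambda = "numeric", rg = "numeric", rgCore = "numeric",
                 q = "numeric"))

setValidity("ShapeDescriptors", function(object) {
  msg <- character()
  if (length(object@lambda) != 3 || is.unsorted(object@lambda) ||
      any(object@lambda < -1e-12))
    msg <- c(msg, "lambda must be three non-negative ascending eigenvalues")
  if (abs(object@rg^2 - sum(object@lambda)) >
      1e-10 * max(1, sum(object@lambda)))
    msg <- c(msg, "rg^2 must equal the eigenvalue sum")
  if (object@q < -1e-12 || object@q > 1 + 1e-12)
    msg <- c(msg, "q must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Shell-averaged radial density profile around micelle centers of mass
#'
#' @slot binEdges shell edges, nm.
#' @slot density matrix (bins x species), beads/nm^3.
#' @slot species species labels.
#' @slot nMicelles number of micelles averaged.
#' @export
setClass("RadialProfile",
  representation(binEdges = "numeric", density = "matrix",
                 species = "character", nMicelles = "integer"))

setValidity("RadialProfile", function(object) {
  msg <- character()
  if (any(object@density < 0)) msg <- c(msg, "densities must be non-negative")
  if (nrow(object@density) != length(object@binEdges) - 1)
    msg <- c(msg, "density rows must match the number of shells")
  if (length(msg)) msg else TRUE
})

#' Resolved run configuration
#'
#' All defaults materialized; \code{derived} carries quantities computed from
#' the resolved values (box length, total simulated time).
#'
#' @slot model model block (temperatures, chi source).
#' @slot composition composition block (total beads, fractions, density).
#' @slot engine engine block (dt, n_steps, grid, update interval, thermostat).
#' @slot io io block (strides, seed).
#' @slot derived derived quantities.
#' @export
setClass("RunConfig",
  representation(model = "list", composition = "list", engine = "list",
                 io = "list", derived = "list"))
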