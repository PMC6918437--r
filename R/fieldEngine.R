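#' Field-engine parameters
#'
#' @param chi a \linkS4class{ChiMatrix}, or a symmetric chiRT matrix in kJ/mol
#'   with species dimnames.
#' @param kappaInverse incompressibility strength 1/kappa, kJ/mol. The default
#'   10 kJ/mol is of the order of the chiRT entries ("sufficiently small"
#'   compressibility).
#' @param phi0 reference total number density, beads/nm^3.
#' @param updateInterval steps between density-field refreshes.
#' @return a \linkS4class{FieldParams}.
#' @export
fieldParams <- function(chi, kappaInverse = 10, phi0 = 0.725,
                        updateInterval = 300L) {
  if (is(chi, "ChiMatrix")) {
    m <- chi@chiRT
    sp <- chi@species
  } else {
    m <- chi
    sp <- rownames(chi)
    if (is.null(sp)) stop("chiRT matrix needs species dimnames")
  }
  new("FieldParams", species = sp, chiRT = m, kappaInverse = kappaInverse,
      phi0 = phi0, updateInterval = as.integer(updateInterval))
}

# Subset/permute a FieldParams chiRT to the state's species levels.
.matchChiRT <- function(params, stateLevels) {
  missing <- setdiff(stateLevels, params@species)
  if (length(missing))
    stop("configuration error: species ", paste(missing, collapse = ", "),
         " absent from the chi matrix")
  params@chiRT[stateLevels, stateLevels, drop = FALSE]
}

.gridCells <- function(box, gridSize, ncell = NULL) {
  if (is.null(ncell)) ncell <- pmax(1L, as.integer(round(box / gridSize)))
  ncell <- as.integer(rep_len(ncell, 3))
  ncell
}

#' Deposit bead positions onto the density mesh
#'
#' Cloud-in-cell (trilinear) deposition of every bead onto its eight
#' surrounding mesh nodes with periodic wrap-around. The per-species integral
#' of the field over the box equals the particle count exactly (partition of
#' unity), which every downstream energy and force inherits.
#'
#' @param state a \linkS4class{SimulationState} (positions wrapped).
#' @param gridSize target cell edge, nm; the cell count per axis is the
#'   nearest integer \code{box/gridSize} and the actual cell size is
#'   recomputed from the box.
#' @param ncell explicit cells per axis (overrides \code{gridSize}).
#' @return a \linkS4class{DensityGrid}, beads/nm^3.
#' @export
assignDensity <- function(state, gridSize = 2.1, ncell = NULL) {
  if (!all(is.finite(state@positions)))
    stop("state corruption: non-finite coordinates")
  ncell <- .gridCells(state@box, gridSize, ncell)
  lev <- levels(state@species)
  vals <- cpp_assign_density(state@positions,
                             as.integer(state@species) - 1L,
                             length(lev), ncell, state@box)
  new("DensityGrid", values = vals, ncell = ncell,
      cellSize = state@box / ncell, box = state@box, species = lev)
}

#' Mean-field external potentials from a density grid
#'
#' V_K(r) = sum_K' chiRT[K,K'] phi_K'(r)/phi0
#'          + kappaInverse (sum_K phi_K(r) - phi0)/phi0,
#' evaluated at every node. Densities are normalized by phi0 inside the
#' potential so chiRT enters in energy units directly and V is in kJ/mol.
#'
#' @param grid a \linkS4class{DensityGrid}.
#' @param params a \linkS4class{FieldParams} sharing the grid's species.
#' @return a \linkS4class{PotentialField}, kJ/mol.
#' @export
computePotentials <- function(grid, params) {
  chiRT <- .matchChiRT(params, grid@species)
  vals <- cpp_potentials(grid@values, chiRT, params@kappaInverse, params@phi0)
  new("PotentialField", values = vals, ncell = grid@ncell,
      cellSize = grid@cellSize, box = grid@box, species = grid@species)
}

#' Field forces on every bead
#'
#' The force on bead i of species K is -grad V_K interpolated at the bead
#' position: gradients are central finite differences on the periodic mesh,
#' interpolated trilinearly with the same kernel used for deposition (which
#' makes the total field force vanish identically).
#'
#' @param state a \linkS4class{SimulationState}.
#' @param potentials a \linkS4class{PotentialField} current as of the last
#'   density update.
#' @return N x 3 force matrix, kJ/mol/nm.
#' @export
fieldForces <- function(state, potentials) {
  lev <- levels(state@species)
  if (!identical(lev, potentials@species))
    stop("configuration error: state and potential species ordering differ")
  g <- cpp_mesh_gradient(potentials@values, potentials@cellSize)
  cpp_interp_forces(state@positions, as.integer(state@species) - 1L,
                    g$x, g$y, g$z, state@box)
}

#' Total mean-field interaction energy
#'
#' W = sum_cells cellVolume [ (1/2) sum_KK' chiRT phi_K phi_K' / phi0
#'     + (1/2) kappaInverse (sum_K phi_K - phi0)^2 / phi0 ]   (kJ/mol).
#' The incompressibility term is the quadratic form whose functional
#' derivative is the potential of \code{computePotentials}.
#'
#' @param grid a \linkS4class{DensityGrid}.
#' @param params a \linkS4class{FieldParams}.
#' @return scalar energy, kJ/mol.
#' @export
fieldEnergy <- function(grid, params) {
  chiRT <- .matchChiRT(params, grid@species)
  cpp_field_energy(grid@values, chiRT, params@kappaInverse, params@phi0,
                   prod(grid@cellSize))
}

#' Dump density or potential fields for inspection
#'
#' Writes each species slab as a plain-text matrix block with a header line,
#' plus grid metadata, to a self-describing text container.
#'
#' @param grid a \linkS4class{FieldGrid}.
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeFieldDump <- function(grid, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s ncell %s cell_nm %s box_nm %s species %s",
                     class(grid), paste(grid@ncell, collapse = " "),
                     paste(signif(grid@cellSize, 10), collapse = " "),
                     paste(signif(grid@box, 10), collapse = " "),
                     paste(grid@species, collapse = " ")), con)
  for (k in seq_along(grid@species)) {
    writeLines(sprintf("# species %s", grid@species[k]), con)
    utils::write.table(matrix(grid@values[, , , k], nrow = grid@ncell[1]),
                       con, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
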