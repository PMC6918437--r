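#' Extended-XYZ frame I/O
#'
#' Frames carry the species label, position and molecule id per bead, with the
#' box on the comment line as a Lattice specification plus the step number.
#' Writing then reading then writing again produces a byte-identical file;
#' frames are appendable.
#'
#' @param state a \linkS4class{SimulationState}.
#' @param path output file.
#' @param append append as an additional frame.
#' @return invisibly, the path.
#' @export
writeFrame <- function(state, path, append = FALSE) {
  n <- nrow(state@positions)
  b <- state@box
  header <- sprintf(
    paste0('Lattice="%s 0 0 0 %s 0 0 0 %s" ',
           "Properties=species:S:1:pos:R:3:molid:I:1 Step=%d"),
    fmtNum(b[1]), fmtNum(b[2]), fmtNum(b[3]), state@step)
  body <- sprintf("%s %s %s %s %d", as.character(state@species),
                  fmtNum(state@positions[, 1]), fmtNum(state@positions[, 2]),
                  fmtNum(state@positions[, 3]), state@moleculeId)
  ok <- tryCatch({
    con <- file(path, if (append) "a" else "w")
    writeLines(c(as.character(n), header, body), con)
    close(con)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop("failed to write frame to '", path, "': ", conditionMessage(ok))
  invisible(path)
}

fmtNum <- function(x) sprintf("%.10g", x)

#' @rdname writeFrame
#' @param trajectory a \linkS4class{Trajectory} whose frames to write.
#' @export
writeTrajectory <- function(trajectory, path) {
  first <- TRUE
  for (fi in seq_along(trajectory@positions)) {
    st <- .frameState(trajectory, fi)
    writeFrame(st, path, append = !first)
    first <- FALSE
  }
  invisible(path)
}

.parseFrameAt <- function(lines, at, path) {
  n <- suppressWarnings(as.integer(lines[at]))
  if (is.na(n) || n < 0)
    stop("parse error at line ", at, " of ", path,
         ": expected a bead count, got '", lines[at], "'")
  if (at + 1 + n > length(lines))
    stop("parse error at line ", at, " of ", path, ": truncated frame")
  header <- lines[at + 1]
  lat <- regmatches(header, regexec('Lattice="([^"]*)"', header))[[1]]
  if (length(lat) < 2)
    stop("parse error at line ", at + 1, " of ", path, ": missing Lattice")
  latv <- as.numeric(strsplit(trimws(lat[2]), "\\s+")[[1]])
  box <- latv[c(1, 5, 9)]
  stepM <- regmatches(header, regexec("Step=([0-9]+)", header))[[1]]
  step <- if (length(stepM) >= 2) as.integer(stepM[2]) else 0L
  rows <- strsplit(lines[at + 1 + seq_len(n)], "\\s+")
  bad <- which(lengths(rows) != 5)
  if (length(bad))
    stop("parse error at line ", at + 1 + bad[1], " of ", path,
         ": expected 5 columns")
  m <- do.call(rbind, rows)
  pos <- matrix(as.numeric(m[, 2:4]), n, 3)
  if (any(!is.finite(pos)))
    stop("parse error in ", path, ": non-numeric coordinate")
  list(species = m[, 1], positions = pos, molid = as.integer(m[, 5]),
       box = box, step = step, next_at = at + 2 + n)
}

#' Read extended-XYZ frames
#'
#' @param path file written by \code{\link{writeFrame}} /
#'   \code{\link{writeTrajectory}}.
#' @param bonds optional bond matrix to attach (extended-XYZ stores none;
#'   by default consecutive beads sharing a molecule id are re-bonded).
#' @param rebond rebuild bonds from molecule ids.
#' @return list of \linkS4class{SimulationState} objects, one per frame.
#' @export
readTrajectoryXYZ <- function(path, bonds = NULL, rebond = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  at <- 1L
  out <- list()
  while (at <= length(lines)) {
    if (!nzchar(trimws(lines[at]))) {
      at <- at + 1L
      next
    }
    fr <- .parseFrameAt(lines, at, path)
    lev <- .speciesLevels(unique(fr$species))
    b <- bonds
    if (is.null(b) && rebond) {
      same <- which(diff(fr$molid) == 0)
      b <- cbind(same, same + 1L, deparse.level = 0)
    }
    if (is.null(b)) b <- matrix(integer(), 0, 2)
    storage.mode(b) <- "integer"
    pos <- fr$positions
    for (d in 1:3) pos[, d] <- .wrap(pos[, d], fr$box[d])
    out[[length(out) + 1L]] <- new("SimulationState", positions = pos,
      velocities = matrix(0, nrow(pos), 3),
      species = factor(fr$species, levels = lev),
      moleculeId = fr$molid, bonds = b, box = fr$box, step = fr$step,
      rngSeed = 0L)
    at <- fr$next_at
  }
  if (length(out) == 0) stop("parse error: no frames in ", path)
  out
}

#' @rdname readTrajectoryXYZ
#' @param which frame number to read.
#' @export
readFrame <- function(path, which = 1L, bonds = NULL, rebond = TRUE) {
  frames <- readTrajectoryXYZ(path, bonds, rebond)
  if (which < 1 || which > length(frames))
    stop("frame ", which, " not present (file has ", length(frames), ")")
  frames[[which]]
}

# ---------------------------------------------------------------------------
# Run configuration: YAML blocks with strict key checking and full defaults.
# ---------------------------------------------------------------------------
.configSchema <- function() list(
  model = list(temperature = 303, solubility_temperature = 298, bead_volume = 600),
  composition = list(total_beads = 192000, number_density = 0.725,
                     fractions = list()),
  engine = list(dt = 0.03, n_steps = 8e7, grid_size = 2.1,
                update_interval = 300, kappa_inverse = 10,
                collision_frequency = 20, bead_mass = 360,
                k_bond = 10000, r_bond = 1.12),
  io = list(frame_stride = 300000, log_stride = 10000, seed = 1))

.resolveBlock <- function(given, defaults, block) {
  if (is.null(given)) return(defaults)
  unknown <- setdiff(names(given), names(defaults))
  if (length(unknown))
    stop("unknown key '", block, ".", unknown[1], "' in config")
  utils::modifyList(defaults, given)
}

#' Read and validate a run configuration
#'
#' Reads a YAML config with blocks \code{model}, \code{composition},
#' \code{engine} and \code{io}, rejects unknown keys by name, materializes
#' every default, and computes derived quantities (box length, total
#' simulated time). \code{configEcho} renders the fully resolved values so a
#' run log carries the provenance of every number used.
#'
#' @param path YAML file; may contain any subset of the blocks.
#' @return a \linkS4class{RunConfig}.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  resolveRunConfig(raw)
}

#' @rdname readRunConfig
#' @param raw nested list of config blocks (as from \code{yaml::read_yaml}).
#' @export
resolveRunConfig <- function(raw = list()) {
  schema <- .configSchema()
  unknown <- setdiff(names(raw), names(schema))
  if (length(unknown))
    stop("unknown key '", unknown[1], "' in config")
  cfg <- lapply(names(schema), function(b)
    .resolveBlock(raw[[b]], schema[[b]], b))
  names(cfg) <- names(schema)
  totalTimePs <- cfg$engine$n_steps * cfg$engine$dt
  derived <- list(
    box_length_nm = boxFromDensity(cfg$composition$total_beads,
                                   cfg$composition$number_density),
    total_time_ps = totalTimePs,
    total_time_us = totalTimePs * 1e-6)
  new("RunConfig", model = cfg$model, composition = cfg$composition,
      engine = cfg$engine, io = cfg$io, derived = derived)
}

#' @rdname readRunConfig
#' @param config a \linkS4class{RunConfig}.
#' @return for \code{configEcho}: character vector of resolved settings.
#' @export
configEcho <- function(config) {
  e <- config@engine
  c(sprintf("model: T = %g K, solubility-route T = %g K, bead volume = %g A^3",
            config@model$temperature, config@model$solubility_temperature,
            config@model$bead_volume),
    sprintf("composition: %g beads at %g beads/nm^3 -> box %.4g nm",
            config@composition$total_beads,
            config@composition$number_density,
            config@derived$box_length_nm),
    if (length(config@composition$fractions))
      sprintf("fractions: %s",
              paste(names(config@composition$fractions),
                    unlist(config@composition$fractions), sep = "=",
                    collapse = ", ")),
    sprintf("engine: dt = %g ps, grid = %g nm, density update every %g steps",
            e$dt, e$grid_size, e$update_interval),
    sprintf("engine: 1/kappa = %g kJ/mol, Andersen nu = %g /ps",
            e$kappa_inverse, e$collision_frequency),
    sprintf("bonds: k = %g kJ/mol/nm^2, r0 = %g nm", e$k_bond, e$r_bond),
    sprintf("schedule: %g steps x %g ps = %g ps (%g us)",
            e$n_steps, e$dt, config@derived$total_time_ps,
            config@derived$total_time_us),
    sprintf("io: frame stride %g, log stride %g, seed %g",
            config@io$frame_stride, config@io$log_stride, config@io$seed))
}

#' @rdname readRunConfig
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(list(model = config@model,
                        composition = config@composition,
                        engine = config@engine, io = config@io), path)
  invisible(path)
}
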