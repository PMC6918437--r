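#' Accessors for hpfmd containers
#'
#' Small generic/accessor layer so user code never reaches into slots.
#'
#' @param object an hpfmd S4 object.
#' @return the requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("chi", function(object) standardGeneric("chi"))
#' @rdname accessors
#' @export
setGeneric("chiRT", function(object) standardGeneric("chiRT"))
#' @rdname accessors
#' @export
setGeneric("speciesNames", function(object) standardGeneric("speciesNames"))
#' @rdname accessors
#' @export
setGeneric("positions", function(object) standardGeneric("positions"))
#' @rdname accessors
#' @export
setGeneric("velocities", function(object) standardGeneric("velocities"))
#' @rdname accessors
#' @export
setGeneric("boxLength", function(object) standardGeneric("boxLength"))
#' @rdname accessors
#' @export
setGeneric("beadCounts", function(object) standardGeneric("beadCounts"))
#' @rdname accessors
#' @export
setGeneric("chainCounts", function(object) standardGeneric("chainCounts"))
#' @rdname accessors
#' @export
setGeneric("gridValues", function(object) standardGeneric("gridValues"))
#' @rdname accessors
#' @export
setGeneric("runLog", function(object) standardGeneric("runLog"))
#' @rdname accessors
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))

#' @rdname accessors
#' @export
setMethod("chi", "ChiMatrix", function(object) object@chi)
#' @rdname accessors
#' @export
setMethod("chiRT", "ChiMatrix", function(object) object@chiRT)
#' @rdname accessors
#' @export
setMethod("chiRT", "FieldParams", function(object) object@chiRT)
#' @rdname accessors
#' @export
setMethod("speciesNames", "ChiMatrix", function(object) object@species)
#' @rdname accessors
#' @export
setMethod("speciesNames", "SimulationState",
          function(object) levels(object@species))
#' @rdname accessors
#' @export
setMethod("speciesNames", "FieldGrid", function(object) object@species)
#' @rdname accessors
#' @export
setMethod("positions", "SimulationState", function(object) object@positions)
#' @rdname accessors
#' @export
setMethod("velocities", "SimulationState", function(object) object@velocities)
#' @rdname accessors
#' @export
setMethod("boxLength", "SimulationState", function(object) object@box)
#' @rdname accessors
#' @export
setMethod("boxLength", "SystemComposition", function(object) object@boxLength)
#' @rdname accessors
#' @export
setMethod("beadCounts", "SystemComposition", function(object) object@beadCounts)
#' @rdname accessors
#' @export
setMethod("chainCounts", "SystemComposition",
          function(object) object@chainCounts)
#' @rdname accessors
#' @export
setMethod("gridValues", "FieldGrid", function(object) object@values)
#' @rdname accessors
#' @export
setMethod("runLog", "Trajectory", function(object) object@log)
#' @rdname accessors
#' @export
setMethod("nFrames", "Trajectory", function(object) length(object@positions))

setMethod("show", "ChiMatrix", function(object) {
  cat("ChiMatrix:", length(object@species), "species at",
      object@temperature, "K\n")
  cat("chiRT (kJ/mol):\n")
  m <- round(object@chiRT, 2)
  dimnames(m) <- list(object@species, object@species)
  print(m)
})

setMethod("show", "SimulationState", function(object) {
  cat("SimulationState:", nrow(object@positions), "beads,",
      nrow(object@bonds), "bonds, box",
      paste(signif(object@box, 6), collapse = " x "), "nm, step",
      object@step, "\n")
  print(table(object@species))
})

setMethod("show", "SystemComposition", function(object) {
  cat("SystemComposition:", object@totalBeads, "beads, box",
      signif(object@boxLength, 6), "nm (density",
      object@numberDensity, "beads/nm^3)\n")
  if (length(object@chainCounts))
    cat("chains:", paste(names(object@chainCounts), object@chainCounts,
                         sep = "=", collapse = ", "), "\n")
  cat("beads: ", paste(names(object@beadCounts), object@beadCounts,
                       sep = "=", collapse = ", "), "\n")
})

setMethod("show", "FieldGrid", function(object) {
  cat(class(object), ": ", paste(object@ncell, collapse = " x "),
      " mesh (cell ", paste(signif(object@cellSize, 4), collapse = " x "),
      " nm), species ", paste(object@species, collapse = ", "), "\n",
      sep = "")
})

setMethod("show", "Trajectory", function(object) {
  cat("Trajectory:", length(object@positions), "frames,",
      nrow(object@positions[[1]]), "beads, dt", object@dt, "ps, steps",
      object@steps[1], "..", object@steps[length(object@steps)], "\n")
})

setMethod("show", "ShapeDescriptors", function(object) {
  cat("ShapeDescriptors: lambda = (",
      paste(signif(object@lambda, 4), collapse = ", "), ") nm^2, Rg =",
      signif(object@rg, 4), "nm, Rg(core) =", signif(object@rgCore, 4),
      "nm, Q =", signif(object@q, 4), "\n")
})

setMethod("show", "Aggregate", function(object) {
  cat("Aggregate of", object@size, "chains (",
      length(object@beadIndices), "beads ), COM (",
      paste(signif(object@com, 4), collapse = ", "), ") nm\n")
})

setMethod("show", "RadialProfile", function(object) {
  cat("RadialProfile:", nrow(object@density), "shells to",
      signif(max(object@binEdges), 4), "nm, averaged over",
      object@nMicelles, "micelle(s)\n")
})
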