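#' @rdname Ensemble-class
#' @param x an object.
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname Ensemble-class
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' @rdname Ensemble-class
#' @export
setGeneric("atomTable", function(x) standardGeneric("atomTable"))

#' @rdname Ensemble-class
#' @export
setGeneric("coordArray", function(x) standardGeneric("coordArray"))

#' @rdname Ensemble-class
#' @param i frame index.
#' @export
setGeneric("frameCoords", function(x, i = 1L) standardGeneric("frameCoords"))

#' @rdname Ensemble-class
#' @export
setGeneric("timesPs", function(x) standardGeneric("timesPs"))

#' @rdname Ensemble-class
#' @export
setGeneric("ensembleLabel", function(x) standardGeneric("ensembleLabel"))

setMethod("nFrames", "Ensemble", function(x) dim(x@coords)[3])
setMethod("nAtoms", "Ensemble", function(x) dim(x@coords)[1])
setMethod("atomTable", "Ensemble", function(x) x@atoms)
setMethod("coordArray", "Ensemble", function(x) x@coords)
setMethod("frameCoords", "Ensemble", function(x, i = 1L) {
    stopifnot(i >= 1L, i <= nFrames(x))
    m <- x@coords[, , i, drop = FALSE]
    dim(m) <- dim(m)[1:2]
    colnames(m) <- c("x", "y", "z")
    m
})
setMethod("timesPs", "Ensemble", function(x) x@timePs)
setMethod("ensembleLabel", "Ensemble", function(x) x@label)

setMethod("show", "Ensemble", function(object) {
    cat("Ensemble '", object@label, "': ", nFrames(object), " snapshot(s) of ",
        nAtoms(object), " atoms, ", length(unique(object@atoms$resno)),
        " residue number(s), chains: ",
        paste(unique(object@atoms$chain), collapse = " "), "\n", sep = "")
})

#' @rdname AtomSelection-class
#' @param x an object.
#' @export
setGeneric("selectionIndices", function(x) standardGeneric("selectionIndices"))
setMethod("selectionIndices", "AtomSelection", function(x) x@indices)

setMethod("show", "AtomSelection", function(object) {
    cat("AtomSelection '", object@expression, "': ",
        length(object@indices), " atom(s)\n", sep = "")
})

setMethod("length", "AtomSelection", function(x) length(x@indices))

setMethod("show", "EnergyComponentSeries", function(object) {
    cat("EnergyComponentSeries: construct ", object@construct, ", ligand ",
        object@ligand, ", ", length(object@eVdw), " snapshot(s)\n",
        "  mean E_vdw  = ", sprintf("%.3f", mean(object@eVdw)),
        " kcal/mol\n",
        "  mean E_elec = ", sprintf("%.3f", mean(object@eElec)),
        " kcal/mol\n", sep = "")
})

setMethod("length", "EnergyComponentSeries", function(x) length(x@eVdw))

setMethod("show", "CalibrationResult", function(object) {
    cat("CalibrationResult: alpha = ", object@alpha, ", beta = ", object@beta,
        " (grid step ", object@gridStep, ")\n",
        "  RMSE = ", sprintf("%.4f", object@rmse), " kcal/mol, R^2 = ",
        sprintf("%.4f", object@rSquared), ", r = ",
        sprintf("%.4f", object@pearsonR), "\n", sep = "")
})

setMethod("show", "DwellDataset", function(object) {
    iv <- object@intervals
    cat("DwellDataset: construct ", object@construct, ", ",
        length(unique(iv$cluster_id)), " cluster(s), ", nrow(iv),
        " interval(s) at ", format(object@concM, digits = 3), " M, ",
        object@voltageMv, " mV\n", sep = "")
})

setMethod("show", "GatingScheme", function(object) {
    cat("GatingScheme A+C <-> AC <-> AO\n",
        "  kOn    = ", format(object@kOn, digits = 4), " /M/s\n",
        "  kOff   = ", format(object@kOff, digits = 4), " /s\n",
        "  fOpen  = ", format(object@fOpen, digits = 4), " /s\n",
        "  bClose = ", format(object@bClose, digits = 4), " /s\n", sep = "")
})

#' Equilibrium constants of a gating scheme
#'
#' `schemeE1` returns the mono-liganded gating equilibrium constant
#' `fOpen/bClose`; `schemeKd` the resting-state dissociation constant
#' `kOff/kOn` (molar).
#'
#' @param x a [GatingScheme-class].
#' @return numeric scalar.
#' @export
setGeneric("schemeE1", function(x) standardGeneric("schemeE1"))
#' @rdname schemeE1
#' @export
setGeneric("schemeKd", function(x) standardGeneric("schemeKd"))
setMethod("schemeE1", "GatingScheme", function(x) x@fOpen / x@bClose)
setMethod("schemeKd", "GatingScheme", function(x) x@kOff / x@kOn)
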