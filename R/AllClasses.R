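#' @import methods
NULL

## Column layout shared by every atom table. Residue numbers are stored
## exactly as given (the gamma-subunit numbering convention is the caller's);
## cross-subunit equivalences live in run configuration, never here.
.ATOM_COLS <- c("serial", "name", "resname", "chain", "resno", "element")

#' Coordinate ensemble
#'
#' An ordered set of coordinate snapshots sharing one atom table, the
#' universal substrate of the geometry and dynamics analyses. Coordinates are
#' in Angstrom, times in picoseconds.
#'
#' @slot atoms data.frame with columns `serial`, `name`, `resname`, `chain`,
#'   `resno`, `element`; one row per atom, shared by all snapshots.
#' @slot coords numeric array of dimension `c(nAtoms, 3, nFrames)`.
#' @slot timePs numeric vector of frame times (ps), one per frame.
#' @slot label construct identifier (e.g. `"ag_WT"`, `"ad_C4g"`).
#'
#' @export
setClass("Ensemble",
    representation(atoms = "data.frame", coords = "array",
                   timePs = "numeric", label = "character"))

setValidity("Ensemble", function(object) {
    msg <- character()
    if (!all(.ATOM_COLS %in% names(object@atoms)))
        msg <- c(msg, paste("atom table must have columns:",
                            paste(.ATOM_COLS, collapse = ", ")))
    d <- dim(object@coords)
    if (length(d) != 3L || d[2] != 3L)
        msg <- c(msg, "coords must be an nAtoms x 3 x nFrames array")
    else {
        if (d[1] != nrow(object@atoms))
            msg <- c(msg, "coords first dimension must match atom count")
        if (d[3] < 1L)
            msg <- c(msg, "ensemble must contain at least one snapshot")
        if (length(object@timePs) != d[3])
            msg <- c(msg, "timePs must have one entry per frame")
        if (!all(is.finite(object@coords)))
            msg <- c(msg, "all coordinates must be finite")
    }
    if (anyDuplicated(object@atoms$serial))
        msg <- c(msg, "atom serials must be unique within a snapshot")
    if (length(msg)) msg else TRUE
})

#' Construct an Ensemble
#'
#' @param atoms atom table (see [Ensemble-class]).
#' @param coords `nAtoms x 3 x nFrames` array, or an `nAtoms x 3` matrix for
#'   a single snapshot.
#' @param timePs frame times in ps; defaults to `0, 1, ...`.
#' @param label construct label.
#' @return An [Ensemble-class] object.
#' @export
Ensemble <- function(atoms, coords, timePs = NULL, label = "ensemble") {
    if (is.matrix(coords))
        coords <- array(coords, dim = c(nrow(coords), ncol(coords), 1L))
    if (is.null(timePs))
        timePs <- as.numeric(seq_len(dim(coords)[3]) - 1L)
    atoms <- as.data.frame(atoms)[, .ATOM_COLS]
    new("Ensemble", atoms = atoms, coords = coords,
        timePs = as.numeric(timePs), label = label)
}

#' Atom selection
#'
#' The result of evaluating a selection expression against an ensemble's atom
#' table: the expression and the strictly increasing atom indices it resolved
#' to.
#'
#' @slot expression the selection expression string.
#' @slot indices integer atom indices (1-based, strictly increasing).
#' @export
setClass("AtomSelection",
    representation(expression = "character", indices = "integer"))

setValidity("AtomSelection", function(object) {
    idx <- object@indices
    if (length(idx) && (any(idx < 1L) || is.unsorted(idx, strictly = TRUE)))
        return("indices must be strictly increasing positive integers")
    TRUE
})

#' Per-snapshot binding-energy components
#'
#' Van der Waals and electrostatic interaction-energy terms (kcal/mol) for one
#' construct/ligand, one pair per ensemble snapshot. The electrostatic term is
#' consumed as provided upstream (a continuum-solvent calculation); it is
#' never computed here.
#'
#' @slot construct construct label.
#' @slot ligand ligand name (`"ACh"`, `"TMA"`, `"CCh"`, `"choline"`).
#' @slot eVdw,eElec numeric vectors of equal length, kcal/mol.
#' @slot timePs optional frame times (ps); may be empty.
#' @export
setClass("EnergyComponentSeries",
    representation(construct = "character", ligand = "character",
                   eVdw = "numeric", eElec = "numeric", timePs = "numeric"))

setValidity("EnergyComponentSeries", function(object) {
    msg <- character()
    if (length(object@eVdw) != length(object@eElec))
        msg <- c(msg, "eVdw and eElec must have equal length")
    if (!all(is.finite(object@eVdw)) || !all(is.finite(object@eElec)))
        msg <- c(msg, "energy components must be finite")
    if (length(object@timePs) &&
        length(object@timePs) != length(object@eVdw))
        msg <- c(msg, "timePs must be empty or match component length")
    if (length(msg)) msg else TRUE
})

#' @rdname EnergyComponentSeries-class
#' @param construct,ligand labels.
#' @param eVdw,eElec component vectors, kcal/mol.
#' @param timePs optional frame times, ps.
#' @export
EnergyComponentSeries <- function(construct, eVdw, eElec, ligand = "ACh",
                                  timePs = numeric()) {
    new("EnergyComponentSeries", construct = construct, ligand = ligand,
        eVdw = as.numeric(eVdw), eElec = as.numeric(eElec),
        timePs = as.numeric(timePs))
}

#' Calibration of the binding-energy weights
#'
#' Result of the exhaustive grid scan for the dimensionless weights
#' (alpha on the van der Waals term, beta on the electrostatic term) that
#' minimize the RMSE between simulated and experimental binding energies.
#'
#' @slot alpha,beta fitted weights (dimensionless).
#' @slot rmse root-mean-square error at the optimum, kcal/mol.
#' @slot rSquared coefficient of determination (may be `NA` when the
#'   experimental energies have zero variance).
#' @slot pearsonR Pearson correlation between predicted and experimental
#'   energies.
#' @slot gridStep grid resolution used for the scan.
#' @export
setClass("CalibrationResult",
    representation(alpha = "numeric", beta = "numeric", rmse = "numeric",
                   rSquared = "numeric", pearsonR = "numeric",
                   gridStep = "numeric"))

setValidity("CalibrationResult", function(object) {
    if (object@rmse < 0) return("rmse must be non-negative")
    TRUE
})

#' Single-channel dwell-time dataset
#'
#' Alternating open/closed interval durations grouped into clusters (runs of
#' activity of one receptor between desensitized gaps), with recording
#' metadata. Durations are in seconds.
#'
#' @slot intervals data.frame with columns `cluster_id`, `state`
#'   (`"open"`/`"closed"`), `duration_s`; states strictly alternate within a
#'   cluster.
#' @slot concM agonist concentration, molar.
#' @slot voltageMv membrane potential, mV (metadata only).
#' @slot construct construct label.
#' @export
setClass("DwellDataset",
    representation(intervals = "data.frame", concM = "numeric",
                   voltageMv = "numeric", construct = "character"))

setValidity("DwellDataset", function(object) {
    iv <- object@intervals
    need <- c("cluster_id", "state", "duration_s")
    if (!all(need %in% names(iv)))
        return(paste("intervals must have columns:",
                     paste(need, collapse = ", ")))
    if (nrow(iv) == 0L) return("dataset contains no intervals")
    if (!all(iv$state %in% c("open", "closed")))
        return("state must be 'open' or 'closed'")
    if (any(iv$duration_s <= 0)) return("durations must be positive")
    bad <- vapply(split(iv$state, iv$cluster_id), function(s)
        any(s[-1] == s[-length(s)]), logical(1))
    if (any(bad))
        return(paste0("states must strictly alternate within a cluster ",
                      "(violated in cluster ", names(bad)[bad][1], ")"))
    TRUE
})

#' @rdname DwellDataset-class
#' @param intervals interval table (see slots).
#' @param concM,voltageMv,construct recording metadata.
#' @export
DwellDataset <- function(intervals, concM, voltageMv = -100,
                         construct = "WT") {
    new("DwellDataset", intervals = as.data.frame(intervals),
        concM = as.numeric(concM), voltageMv = as.numeric(voltageMv),
        construct = construct)
}

#' Gating scheme A+C <-> AC <-> AO
#'
#' Rate constants of the one-site activation scheme: agonist association
#' (`kOn`, /M/s) and dissociation (`kOff`, /s) plus channel opening (`fOpen`,
#' /s, AC to AO) and closing (`bClose`, /s, AO to AC).
#'
#' @slot kOn association rate constant, per molar per second.
#' @slot kOff dissociation rate constant, per second.
#' @slot fOpen opening rate constant, per second.
#' @slot bClose closing rate constant, per second.
#' @export
setClass("GatingScheme",
    representation(kOn = "numeric", kOff = "numeric",
                   fOpen = "numeric", bClose = "numeric"))

setValidity("GatingScheme", function(object) {
    r <- c(object@kOn, object@kOff, object@fOpen, object@bClose)
    if (length(r) != 4L || any(!is.finite(r)) || any(r <= 0))
        return("all four rate constants must be positive and finite")
    TRUE
})

#' @rdname GatingScheme-class
#' @param kOn,kOff,fOpen,bClose rate constants (see slots).
#' @export
GatingScheme <- function(kOn, kOff, fOpen, bClose) {
    new("GatingScheme", kOn = as.numeric(kOn), kOff = as.numeric(kOff),
        fOpen = as.numeric(fOpen), bClose = as.numeric(bClose))
}
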