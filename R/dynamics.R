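## Trajectory stability and flexibility analytics: RMSD (with optional
## least-squares superposition and region exclusion), rolling-average drift
## slopes, and per-residue RMSF about the ensemble-average structure.

#' Root-mean-square deviation between two snapshots
#'
#' RMSD over the selected atoms. With `superpose = TRUE` an optimal
#' least-squares rigid-body fit (Kabsch) is applied first. The default is no
#' superposition: production trajectories of this kind restrain distal
#' C-alpha atoms, so frames share a common frame of reference.
#'
#' @param coords,reference n x 3 coordinate matrices over the same atoms.
#' @param superpose apply an optimal rigid fit before the deviation.
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(coords, reference, superpose = FALSE) {
    coords <- as.matrix(coords); reference <- as.matrix(reference)
    if (!all(dim(coords) == dim(reference)))
        stop("structural error: coordinate sets differ in size")
    if (superpose) coords <- kabschFit(coords, reference)
    sqrt(mean(rowSums((coords - reference)^2)))
}

#' Optimal rigid-body superposition
#'
#' Rotates and translates `coords` onto `reference` by the Kabsch algorithm
#' (SVD of the cross-covariance of the mean-centred sets, with reflection
#' correction).
#'
#' @param coords,reference n x 3 matrices over the same atoms.
#' @return The transformed `coords`.
#' @export
kabschFit <- function(coords, reference) {
    cm <- colMeans(coords); rm <- colMeans(reference)
    a <- sweep(coords, 2, cm); b <- sweep(reference, 2, rm)
    s <- svd(crossprod(a, b))
    d <- sign(det(s$u %*% t(s$v)))
    rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
    sweep(a %*% rot, 2, rm, "+")
}

#' Per-frame RMSD series of an ensemble
#'
#' RMSD of every snapshot against a reference frame over a selection, with an
#' optional exclusion (e.g. removing a disordered loop F from the
#' calculation). Atoms in `exclude` that are not part of `selection` trigger a
#' warning and are ignored.
#'
#' @param ensemble an [Ensemble-class].
#' @param reference reference frame index (default the first frame).
#' @param selection [AtomSelection-class]/indices; `NULL` = all atoms.
#' @param exclude [AtomSelection-class]/indices removed from the selection;
#'   `NULL` = none.
#' @param superpose see [rmsd()].
#' @return data.frame with columns `time_ps`, `rmsd_A`; attributes
#'   `superposed` and `excluded` record the settings.
#' @export
rmsdSeries <- function(ensemble, reference = 1L, selection = NULL,
                       exclude = NULL, superpose = FALSE) {
    idx <- if (is.null(selection)) seq_len(nAtoms(ensemble))
           else .asIndices(selection)
    exc <- if (is.null(exclude)) integer() else .asIndices(exclude)
    orphan <- setdiff(exc, idx)
    if (length(orphan)) {
        warning(length(orphan),
                " excluded atom(s) are not in the selection; ignored")
        exc <- intersect(exc, idx)
    }
    idx <- setdiff(idx, exc)
    if (!length(idx)) stop("structural error: empty atom set after exclusion")
    ref <- frameCoords(ensemble, reference)[idx, , drop = FALSE]
    vals <- vapply(seq_len(nFrames(ensemble)), function(i)
        rmsd(frameCoords(ensemble, i)[idx, , drop = FALSE], ref,
             superpose = superpose), numeric(1))
    out <- data.frame(time_ps = timesPs(ensemble), rmsd_A = vals)
    attr(out, "superposed") <- superpose
    attr(out, "excluded") <- exc
    out
}

#' Rolling average and drift slope of an RMSD series
#'
#' Centred moving average over `windowPs`, then an ordinary least-squares
#' regression of the rolling mean over the trailing `fitSpanPs` of the
#' series. The slope is reported in Angstrom per nanosecond; a small value
#' indicates a stabilized trajectory.
#'
#' @param series data.frame with `time_ps` and `rmsd_A` (see [rmsdSeries()]).
#' @param windowPs rolling-window width, ps.
#' @param fitSpanPs span of the trailing regression, ps.
#' @return List: `rolling` (data.frame `time_ps`, `rmsd_A`),
#'   `slopeAPerNs`, `interceptA`.
#' @export
rollingDrift <- function(series, windowPs = 5000, fitSpanPs = 10000) {
    t <- series$time_ps; y <- series$rmsd_A
    dur <- max(t) - min(t)
    if (windowPs > dur || fitSpanPs > dur)
        stop("usage error: window or fit span exceeds series duration")
    dt <- stats::median(diff(t))
    k <- max(1L, round(windowPs / dt))
    if (k %% 2 == 0) k <- k + 1L
    roll <- as.numeric(stats::filter(y, rep(1 / k, k), sides = 2))
    keep <- !is.na(roll)
    rolling <- data.frame(time_ps = t[keep], rmsd_A = roll[keep])
    tail <- rolling$time_ps >= max(rolling$time_ps) - fitSpanPs
    fit <- stats::lm(rmsd_A ~ time_ps, data = rolling[tail, ])
    list(rolling = rolling,
         slopeAPerNs = unname(stats::coef(fit)[2]) * 1000,
         interceptA = unname(stats::coef(fit)[1]))
}

#' Drift-slope summary across trajectories
#'
#' Mean and standard deviation of the absolute drift slopes of several
#' replicate trajectories.
#'
#' @param seriesList list of RMSD series (see [rmsdSeries()]).
#' @inheritParams rollingDrift
#' @return List: `slopesAPerNs`, `meanAbsSlope`, `sdAbsSlope`.
#' @export
driftSummary <- function(seriesList, windowPs = 5000, fitSpanPs = 10000) {
    slopes <- vapply(seriesList, function(s)
        rollingDrift(s, windowPs, fitSpanPs)$slopeAPerNs, numeric(1))
    list(slopesAPerNs = slopes, meanAbsSlope = mean(abs(slopes)),
         sdAbsSlope = stats::sd(abs(slopes)))
}

#' Root-mean-square fluctuation profile
#'
#' Per-atom RMS fluctuation about the coordinate-wise mean structure of the
#' ensemble; with `groupByResidue = TRUE` (default) atoms are averaged into a
#' per-residue profile.
#'
#' @param ensemble an [Ensemble-class] with at least two snapshots.
#' @param selection [AtomSelection-class]/indices; `NULL` = all atoms.
#' @param groupByResidue average atom RMSF within each residue number.
#' @param superpose superpose every frame onto the first before averaging.
#' @return data.frame: `resno`, `rmsf_A` (or `atom`, `resno`, `rmsf_A` when
#'   ungrouped).
#' @export
rmsf <- function(ensemble, selection = NULL, groupByResidue = TRUE,
                 superpose = FALSE) {
    if (nFrames(ensemble) < 2L)
        stop("usage error: RMSF needs at least two snapshots")
    idx <- if (is.null(selection)) seq_len(nAtoms(ensemble))
           else .asIndices(selection)
    arr <- coordArray(ensemble)[idx, , , drop = FALSE]
    if (superpose) {
        ref <- arr[, , 1]
        for (i in seq_len(dim(arr)[3]))
            arr[, , i] <- kabschFit(arr[, , i], ref)
    }
    meanStruct <- apply(arr, c(1, 2), mean)
    dev2 <- sweep(arr, c(1, 2), meanStruct)^2
    perAtom <- sqrt(apply(dev2, 1, mean) * 3)  # mean over xyz*frames -> sum xyz
    resno <- atomTable(ensemble)$resno[idx]
    if (!groupByResidue)
        return(data.frame(atom = idx, resno = resno, rmsf_A = perAtom))
    agg <- tapply(perAtom, resno, mean)
    data.frame(resno = as.integer(names(agg)), rmsf_A = as.numeric(agg),
               row.names = NULL)
}

#' Difference of two RMSF profiles
#'
#' Elementwise `profileHA - profileLA` over the shared residue numbers;
#' non-shared residues are dropped with a warning.
#'
#' @param profileHA,profileLA data.frames from [rmsf()].
#' @return data.frame: `resno`, `delta_rmsf_A`.
#' @export
rmsfDifference <- function(profileHA, profileLA) {
    shared <- intersect(profileHA$resno, profileLA$resno)
    if (!length(shared))
        stop("usage error: profiles share no residues")
    dropped <- length(union(profileHA$resno, profileLA$resno)) -
        length(shared)
    if (dropped > 0)
        warning(dropped, " residue(s) present in only one profile; dropped")
    ha <- profileHA$rmsf_A[match(shared, profileHA$resno)]
    la <- profileLA$rmsf_A[match(shared, profileLA$resno)]
    data.frame(resno = shared, delta_rmsf_A = ha - la)
}
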