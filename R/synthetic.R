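## Seeded generators that emulate the statistical structure each analysis
## stage assumes: idealized beta-hairpin ensembles with controllable twist,
## tilt and per-residue fluctuation; binding-pocket snapshots with exact ring
## geometry and agonist torsion; hydrogen-bond ensembles with exact target
## occupancy; calibration sets built from known weights; and dwell-time
## records from known gating schemes, including a two-mode switching variant.
## Every generator attaches its generating values as a `truth` attribute and
## recovery tests read only that bookkeeping.

.BACKBONE_NAMES <- c("N", "CA", "C", "O")

.rotationAboutY <- function(deg) {
    th <- deg * pi / 180
    matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3, 3)
}

#' Idealized beta-hairpin ensemble
#'
#' Two antiparallel straight strand backbones whose axes are separated by
#' exactly `twistDeg` and whose mean hairpin axis makes exactly `tiltDeg`
#' with the laboratory +z direction. Each residue carries four collinear
#' backbone atoms (N, CA, C, O) so the strand axes are exact lines at zero
#' fluctuation. Snapshots add independent Gaussian displacements with the
#' requested per-residue amplitudes (sd per coordinate, Angstrom). Residue
#' numbering follows the gamma-subunit hairpin convention: the first strand
#' starts at 107, the second at 115 and runs antiparallel.
#'
#' @param nResidues residues per strand (default 4: 107-110 / 115-118).
#' @param twistDeg inter-axis angle, degrees.
#' @param tiltDeg mean-axis tilt against +z, degrees.
#' @param riseA rise per residue along the strand, Angstrom.
#' @param fluctuationA per-residue Gaussian amplitude(s), recycled across the
#'   two strands (sd per coordinate, Angstrom).
#' @param nSnapshots number of frames.
#' @param seed integer seed.
#' @param label construct label.
#' @return An [Ensemble-class]; `attr(, "truth")` records the generating
#'   values, including the exact strand axis vectors.
#' @export
makeHairpinEnsemble <- function(nResidues = 4L, twistDeg = 9, tiltDeg = 0,
                                riseA = 3.4, fluctuationA = 0,
                                nSnapshots = 100L, seed = 1L,
                                label = "hairpin") {
    stopifnot(nResidues >= 3L, nSnapshots >= 1L, all(fluctuationA >= 0))
    h <- .rotationAboutY(tiltDeg) %*% c(0, 0, 1)      # mean hairpin axis
    p <- .rotationAboutY(tiltDeg) %*% c(1, 0, 0)      # in-plane perpendicular
    half <- twistDeg / 2 * pi / 180
    u1 <- as.vector(cos(half) * h - sin(half) * p)    # strand 1, first->last
    u2r <- as.vector(cos(half) * h + sin(half) * p)   # strand 2 reversed
    u2 <- -u2r                                        # strand 2, first->last
    span <- riseA * (nResidues - 1) + riseA * 0.75
    atomOffsets <- riseA * (0:3) / 4
    pos1 <- lapply(seq_len(nResidues) - 1, function(i)
        outer(i * riseA + atomOffsets, u1))
    base2 <- c(4.8, 0, 0) + span * u2r                # strand 2 top
    pos2 <- lapply(seq_len(nResidues) - 1, function(i)
        sweep(outer(i * riseA + atomOffsets, u2), 2, base2, "+"))
    coords0 <- do.call(rbind, c(pos1, pos2))
    resno <- rep(c(107:(107 + nResidues - 1), 115:(115 + nResidues - 1)),
                 each = 4L)
    atoms <- data.frame(serial = seq_len(nrow(coords0)),
                        name = rep(.BACKBONE_NAMES, 2L * nResidues),
                        resname = "GLY", chain = "G", resno = resno,
                        element = rep(c("N", "C", "C", "O"),
                                      2L * nResidues),
                        stringsAsFactors = FALSE)
    amp <- rep_len(fluctuationA, 2L * nResidues)
    ampPerAtom <- rep(amp, each = 4L)
    set.seed(as.integer(seed))
    arr <- array(coords0, dim = c(nrow(coords0), 3, nSnapshots))
    if (any(amp > 0)) {
        noise <- stats::rnorm(length(arr), sd = rep(ampPerAtom,
                                                    times = 3 * nSnapshots))
        arr <- arr + array(noise, dim = dim(arr))
    }
    ens <- Ensemble(atoms, arr, timePs = 20 * (seq_len(nSnapshots) - 1),
                    label = label)
    attr(ens, "truth") <- list(twistDeg = twistDeg, tiltDeg = tiltDeg,
                               riseA = riseA, fluctuationA = amp,
                               axis1 = u1, axis2 = u2, meanAxis = as.vector(h),
                               seed = seed)
    ens
}

#' Hairpin strand selections
#'
#' The selection expressions matching the two strands of
#' [makeHairpinEnsemble()] output (and real structures following the
#' gamma-subunit numbering convention).
#'
#' @param nResidues residues per strand.
#' @return List with `strand1`, `strand2` expression strings.
#' @export
hairpinStrandSelections <- function(nResidues = 4L) {
    list(strand1 = sprintf("chain G and resid 107-%d", 107 + nResidues - 1),
         strand2 = sprintf("chain G and resid 115-%d", 115 + nResidues - 1))
}

.hexagonCoords <- function(centroid, normal, radius = 1.39) {
    normal <- normal / sqrt(sum(normal^2))
    ref <- if (abs(normal[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    e1 <- .cross3(normal, ref); e1 <- e1 / sqrt(sum(e1^2))
    e2 <- .cross3(normal, e1)
    ang <- 2 * pi * (0:5) / 6
    t(vapply(ang, function(a)
        centroid + radius * (cos(a) * e1 + sin(a) * e2), numeric(3)))
}

## place the fourth torsion atom at a prescribed signed dihedral
.fourthAtom <- function(p1, p2, p3, bond, angleDeg, torsionDeg) {
    th <- angleDeg * pi / 180; ph <- torsionDeg * pi / 180
    bc <- p3 - p2; bc <- bc / sqrt(sum(bc^2))
    n <- .cross3(p2 - p1, bc); n <- n / sqrt(sum(n^2))
    m <- .cross3(n, bc)
    d <- bond * (-cos(th) * bc + sin(th) * (cos(ph) * m - sin(ph) * n))
    p3 + d
}

#' Synthetic binding-pocket snapshot
#'
#' One-frame ensemble holding five aromatic rings (hexagons of radius 1.39
#' Angstrom at the requested centroids and plane normals), a four-atom
#' agonist fragment realizing the requested N-C-C-O torsion (tau2), and a
#' structural-water triplet. Ring centroid, orientation, torsion and pocket
#' volume computed from the snapshot reproduce the requested values exactly.
#'
#' @param ringCentroids 5 x 3 matrix, rownames `aW149`, `aY198`, `aY190`,
#'   `aY93`, `W55` (default: a compact, non-degenerate pocket).
#' @param ringNormals 5 x 3 matrix of plane normals (rows need not be unit).
#' @param tau2Deg agonist N-C-C-O torsion, degrees.
#' @param qaPosition position of the agonist fragment's first atom.
#' @return An [Ensemble-class] (single frame) with a `truth` attribute.
#' @export
makePocketSnapshot <- function(ringCentroids = NULL, ringNormals = NULL,
                               tau2Deg = 60, qaPosition = c(2, 2, 2)) {
    labs <- c("aW149", "aY198", "aY190", "aY93", "W55")
    if (is.null(ringCentroids)) {
        ringCentroids <- rbind(c(0, 0, 0), c(5, 0, 0), c(2.5, 4.3, 0),
                               c(2.5, 1.4, 4.1), c(-2.5, 3, 2))
        rownames(ringCentroids) <- labs
    }
    if (is.null(ringNormals)) {
        ringNormals <- rbind(c(0, 0, 1), c(0, 1, 1), c(1, 0, 1),
                             c(0, 1, 0), c(1, 1, 1))
        rownames(ringNormals) <- labs
    }
    if (!setequal(rownames(ringCentroids), labs))
        stop("usage error: ring centroids must be labelled ",
             paste(labs, collapse = ", "))
    ringInfo <- list(chainOf = c(aW149 = "A", aY198 = "A", aY190 = "A",
                                 aY93 = "A", W55 = "G"),
                     resnoOf = c(aW149 = 149, aY198 = 198, aY190 = 190,
                                 aY93 = 93, W55 = 55),
                     resnameOf = c(aW149 = "TRP", aY198 = "TYR",
                                   aY190 = "TYR", aY93 = "TYR", W55 = "TRP"))
    ringNames <- c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")
    rows <- list(); xyz <- NULL
    for (lab in labs) {
        hex <- .hexagonCoords(ringCentroids[lab, ], ringNormals[lab, ])
        rows[[lab]] <- data.frame(
            name = ringNames, resname = ringInfo$resnameOf[[lab]],
            chain = ringInfo$chainOf[[lab]], resno = ringInfo$resnoOf[[lab]],
            element = "C", stringsAsFactors = FALSE)
        xyz <- rbind(xyz, hex)
    }
    ## agonist fragment N-C5-C4-O3 with the requested torsion
    b <- 1.5
    p1 <- qaPosition
    p2 <- p1 + c(b, 0, 0)
    p3 <- p2 + b * c(cos(pi - 111 * pi / 180), sin(pi - 111 * pi / 180), 0)
    p4 <- .fourthAtom(p1, p2, p3, b, 111, tau2Deg)
    rows[["ACH"]] <- data.frame(name = c("N", "C5", "C4", "O3"),
                                resname = "ACH", chain = "L", resno = 1,
                                element = c("N", "C", "C", "O"),
                                stringsAsFactors = FALSE)
    xyz <- rbind(xyz, rbind(p1, p2, p3, p4))
    ## structural water
    wO <- c(1.0, -3.0, 1.5)
    rows[["HOH"]] <- data.frame(name = c("O", "H1", "H2"), resname = "HOH",
                                chain = "W", resno = 1,
                                element = c("O", "H", "H"),
                                stringsAsFactors = FALSE)
    xyz <- rbind(xyz, rbind(wO, wO + c(0.76, 0.59, 0), wO + c(-0.76, 0.59, 0)))
    atoms <- do.call(rbind, rows)
    atoms$serial <- seq_len(nrow(atoms))
    rownames(xyz) <- NULL
    ens <- Ensemble(atoms, as.matrix(xyz), label = "pocket")
    attr(ens, "truth") <- list(ringCentroids = ringCentroids,
                               ringNormals = ringNormals, tau2Deg = tau2Deg)
    ens
}

#' Hydrogen-bond ensemble with exact target occupancy
#'
#' Three-atom ensemble (donor N, hydrogen, acceptor O) in which exactly
#' `floor(targetOccupancy * nSnapshots)` frames satisfy the 3.5-Angstrom /
#' 30-degree criterion (donor-acceptor 2.9 Angstrom, angle 0 in bonded
#' frames; 4.5 Angstrom in broken frames). Which frames are bonded is a
#' seeded random permutation.
#'
#' @param targetOccupancy target fraction in `[0, 1]`.
#' @param nSnapshots number of frames.
#' @param seed integer seed.
#' @return An [Ensemble-class] with a `truth` attribute recording the exact
#'   realized occupancy.
#' @export
makeHbondSeries <- function(targetOccupancy, nSnapshots = 2000L, seed = 1L) {
    stopifnot(targetOccupancy >= 0, targetOccupancy <= 1, nSnapshots >= 1L)
    nOn <- floor(targetOccupancy * nSnapshots)
    set.seed(as.integer(seed))
    on <- seq_len(nSnapshots) %in% sample.int(nSnapshots, nOn)
    atoms <- data.frame(serial = 1:3, name = c("N", "H", "O"),
                        resname = c("GLY", "GLY", "SER"), chain = "G",
                        resno = c(115L, 115L, 111L),
                        element = c("N", "H", "O"), stringsAsFactors = FALSE)
    arr <- array(0, dim = c(3, 3, nSnapshots))
    for (i in seq_len(nSnapshots)) {
        dAcc <- if (on[i]) 2.9 else 4.5
        arr[, , i] <- rbind(c(0, 0, 0), c(1, 0, 0), c(dAcc, 0, 0))
    }
    ens <- Ensemble(atoms, arr, label = "hbond-series")
    attr(ens, "truth") <- list(targetOccupancy = targetOccupancy,
                               realizedOccupancy = nOn / nSnapshots,
                               donor = 1L, hydrogen = 2L, acceptor = 3L,
                               seed = seed)
    ens
}

#' Screened-Coulomb surrogate electrostatic energy
#'
#' A Debye-screened Coulomb interaction used only to give synthetic
#' electrostatic components physically plausible magnitudes. It is explicitly
#' not a continuum-solvent (Poisson-Boltzmann) calculation.
#'
#' @param rA separation, Angstrom.
#' @param q1,q2 charges, elementary units.
#' @param dielectric relative dielectric constant.
#' @param screeningA Debye length, Angstrom.
#' @return Energy in kcal/mol.
#' @export
screenedCoulomb <- function(rA, q1 = 1, q2 = -1, dielectric = 4,
                            screeningA = 8) {
    332.0637 * q1 * q2 / (dielectric * rA) * exp(-rA / screeningA)
}

#' Synthetic calibration set from known weights
#'
#' Calibration points whose experimental energies are
#' `alphaTrue * mean_e_vdw + betaTrue * mean_e_elec + N(0, noiseSd)`.
#' Van der Waals components are drawn uniformly over `vdwRange`; the
#' electrostatic component is a [screenedCoulomb()] surrogate at seeded
#' random separations, linearly scaled into `elecRange`. Default ranges keep
#' the resulting energies in the single-digit kcal/mol regime typical of
#' agonist-site alanine scans, with enough spread in each component to
#' identify both weights from a 13-point design.
#'
#' @param alphaTrue,betaTrue generating weights.
#' @param nPoints number of constructs (default 13, a WT + alanine-scan sized
#'   design).
#' @param noiseSd Gaussian noise sd on the experimental energy, kcal/mol.
#' @param seed integer seed.
#' @param vdwRange,elecRange component ranges, kcal/mol.
#' @return data.frame (`construct`, `mean_e_vdw`, `mean_e_elec`,
#'   `experimental_kcal`) with a `truth` attribute.
#' @export
makeCalibrationSet <- function(alphaTrue = 0.22, betaTrue = 1.24,
                               nPoints = 13L, noiseSd = 0, seed = 1L,
                               vdwRange = c(-14, -7),
                               elecRange = c(-4.5, -1.2)) {
    stopifnot(nPoints >= 1L, noiseSd >= 0)
    set.seed(as.integer(seed))
    v <- stats::runif(nPoints, vdwRange[1], vdwRange[2])
    rSep <- stats::runif(nPoints, 3, 6)
    eRaw <- screenedCoulomb(rSep)
    e <- if (nPoints > 1L && diff(range(eRaw)) > 0)
        elecRange[1] + (eRaw - min(eRaw)) / diff(range(eRaw)) *
            diff(elecRange)
    else rep(mean(elecRange), nPoints)
    y <- alphaTrue * v + betaTrue * e +
        if (noiseSd > 0) stats::rnorm(nPoints, 0, noiseSd) else 0
    out <- data.frame(construct = sprintf("mut%02d", seq_len(nPoints)),
                      mean_e_vdw = v, mean_e_elec = e,
                      experimental_kcal = y)
    attr(out, "truth") <- list(alphaTrue = alphaTrue, betaTrue = betaTrue,
                               noiseSd = noiseSd, seed = seed)
    out
}

#' Synthetic per-snapshot energy series
#'
#' Gaussian per-snapshot components around stated means, emulating the
#' snapshot-to-snapshot spread of an ensemble energy evaluation.
#'
#' @param meanVdw,meanElec component means, kcal/mol.
#' @param sdVdw,sdElec per-snapshot sds, kcal/mol.
#' @param nSnapshots number of snapshots.
#' @param seed integer seed.
#' @param construct,ligand labels.
#' @return An [EnergyComponentSeries-class] with a `truth` attribute.
#' @export
makeEnergySeries <- function(meanVdw, meanElec, sdVdw = 1, sdElec = 0.5,
                             nSnapshots = 2000L, seed = 1L,
                             construct = "WT", ligand = "ACh") {
    set.seed(as.integer(seed))
    s <- EnergyComponentSeries(construct,
                               stats::rnorm(nSnapshots, meanVdw, sdVdw),
                               stats::rnorm(nSnapshots, meanElec, sdElec),
                               ligand = ligand,
                               timePs = 20 * (seq_len(nSnapshots) - 1))
    attr(s, "truth") <- list(meanVdw = meanVdw, meanElec = meanElec,
                             sdVdw = sdVdw, sdElec = sdElec, seed = seed)
    s
}

#' Dwell records across several concentrations
#'
#' Wraps [simulateDwells()] over a concentration series with per-dataset
#' sub-seeds derived from `seed`.
#'
#' @param scheme a [GatingScheme-class].
#' @param concsM concentrations, molar.
#' @param nEvents dwell pairs per concentration.
#' @param seed integer seed.
#' @param construct label.
#' @return List of [DwellDataset-class] with a `truth` attribute.
#' @export
makeDwellData <- function(scheme, concsM, nEvents = 5000L, seed = 1L,
                          construct = "sim") {
    out <- lapply(seq_along(concsM), function(i)
        simulateDwells(scheme, concsM[i], nEvents,
                       seed = as.integer(seed) + 1000L * i,
                       construct = construct))
    attr(out, "truth") <- list(kOn = scheme@kOn, kOff = scheme@kOff,
                               fOpen = scheme@fOpen, bClose = scheme@bClose,
                               kdM = schemeKd(scheme), seed = seed)
    out
}

#' Two-mode switching dwell record
#'
#' Emulates modal gating: mode episodes alternate between a high-affinity and
#' a low-affinity scheme with exponentially distributed episode durations
#' (mean `switchTauS`). Each episode becomes one cluster filled with dwell
#' pairs from its scheme; the final dwell is trimmed so the cluster duration
#' equals the drawn episode length exactly.
#'
#' @param schemeHA,schemeLA the two [GatingScheme-class] modes.
#' @param switchTauS mean mode lifetime, seconds.
#' @param nClusters number of clusters (mode episodes).
#' @param concM agonist concentration, molar.
#' @param seed integer seed.
#' @param construct label.
#' @return A [DwellDataset-class] with a `truth` attribute (true mode per
#'   cluster, switching constant, schemes).
#' @export
makeBimodalDwells <- function(schemeHA, schemeLA, switchTauS = 0.020,
                              nClusters = 500L, concM = 1e-4, seed = 1L,
                              construct = "bimodal") {
    stopifnot(nClusters >= 2L, switchTauS > 0)
    set.seed(as.integer(seed))
    modes <- rep(c("HA", "LA"), length.out = nClusters)
    episodes <- stats::rexp(nClusters, 1 / switchTauS)
    rows <- vector("list", nClusters)
    for (i in seq_len(nClusters)) {
        sch <- if (modes[i] == "HA") schemeHA else schemeLA
        target <- episodes[i]
        durs <- numeric(0); states <- character(0); tot <- 0
        while (tot < target) {
            pair <- .sampleDwellPairs(sch, concM, 1L)
            durs <- c(durs, pair$closed, pair$open)
            states <- c(states, "closed", "open")
            tot <- tot + pair$closed + pair$open
        }
        ## trim from the end so the cluster spans the episode exactly
        excess <- tot - target
        while (excess > 0 && length(durs)) {
            if (durs[length(durs)] > excess) {
                durs[length(durs)] <- durs[length(durs)] - excess
                excess <- 0
            } else {
                excess <- excess - durs[length(durs)]
                durs <- durs[-length(durs)]
                states <- states[-length(states)]
            }
        }
        if (!length(durs)) { durs <- target; states <- "closed" }
        rows[[i]] <- data.frame(cluster_id = i, state = states,
                                duration_s = durs)
    }
    ds <- DwellDataset(do.call(rbind, rows), concM = concM,
                       voltageMv = -100, construct = construct)
    attr(ds, "truth") <- list(modes = modes, switchTauS = switchTauS,
                              episodes = episodes, seed = seed,
                              schemeHA = schemeHA, schemeLA = schemeLA)
    ds
}
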