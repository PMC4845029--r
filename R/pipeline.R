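## Config-driven orchestration: figure-level aggregation of the structural,
## energetic and kinetic analyses. Every number in a report traces to a
## module function; report code only arranges and formats.

#' Read a YAML run configuration
#'
#' @param path YAML file path.
#' @return Named list of configuration entries.
#' @export
readRunConfig <- function(path) {
    if (!file.exists(path)) stop("config error: file not found: ", path)
    yaml::read_yaml(path)
}

#' Per-snapshot hairpin metrics of an ensemble
#'
#' Strand axes, twist and tilt evaluated in every snapshot, in tidy form.
#'
#' @param ensemble an [Ensemble-class].
#' @param strand1,strand2 selection expressions (or [AtomSelection-class])
#'   for the two strands' backbone atoms.
#' @param reference reference direction for the tilt (default +z).
#' @return data.frame: `construct`, `snapshot_index`, `metric`, `value` with
#'   metrics `twist_deg` and `tilt_deg`.
#' @export
hairpinMetrics <- function(ensemble, strand1, strand2,
                           reference = c(0, 0, 1)) {
    s1 <- if (is.character(strand1)) selectAtoms(ensemble, strand1)
          else strand1
    s2 <- if (is.character(strand2)) selectAtoms(ensemble, strand2)
          else strand2
    i1 <- selectionIndices(s1); i2 <- selectionIndices(s2)
    if (!length(i1) || !length(i2))
        stop("config error: strand selection matched no atoms")
    out <- lapply(seq_len(nFrames(ensemble)), function(k) {
        m <- frameCoords(ensemble, k)
        a1 <- strandAxis(m[i1, , drop = FALSE])
        a2 <- strandAxis(m[i2, , drop = FALSE])
        hp <- a1 - a2  # strands are antiparallel: difference = mean direction
        data.frame(construct = ensembleLabel(ensemble), snapshot_index = k,
                   metric = c("twist_deg", "tilt_deg"),
                   value = c(hairpinTwist(a1, a2),
                             hairpinTilt(hp, reference)))
    })
    do.call(rbind, out)
}

#' Structural comparison report
#'
#' Computes per-snapshot hairpin metrics (and optional H-bond occupancies)
#' for each construct, histograms them on shared bins pooled over the
#' high-affinity and low-affinity roles, and tabulates HA-vs-LA mean
#' differences.
#'
#' @param ensembles named list of [Ensemble-class] objects.
#' @param roles named list/character mapping roles `HA` and `LA` to names in
#'   `ensembles`.
#' @param strand1,strand2 strand selection expressions (see
#'   [hairpinMetrics()]).
#' @param hbonds optional named list of H-bond specs, each a list with
#'   `donor`, `hydrogen`, `acceptor` atom indices.
#' @param bins histogram bin count over the pooled range.
#' @param reference tilt reference direction.
#' @return List: `metrics` (tidy per-snapshot values), `summary` (mean/sd per
#'   construct and metric), `histograms` (per metric: shared `breaks`,
#'   per-construct `counts`), `comparison` (HA mean, LA mean, delta per
#'   metric), `hbondOccupancy` (or `NULL`).
#' @export
runStructureReport <- function(ensembles, roles, strand1, strand2,
                               hbonds = NULL, bins = 30,
                               reference = c(0, 0, 1)) {
    for (role in c("HA", "LA"))
        if (!role %in% names(roles) || !roles[[role]] %in% names(ensembles))
            stop("config error: missing construct for role ", role)
    metrics <- do.call(rbind, lapply(names(ensembles), function(nm) {
        m <- hairpinMetrics(ensembles[[nm]], strand1, strand2, reference)
        m$construct <- nm
        m
    }))
    summary <- do.call(rbind, lapply(
        split(metrics, metrics[c("metric", "construct")], drop = TRUE),
        function(g)
            data.frame(construct = g$construct[1], metric = g$metric[1],
                       mean = mean(g$value), sd = stats::sd(g$value))))
    rownames(summary) <- NULL
    histograms <- lapply(split(metrics, metrics$metric), function(g) {
        rng <- range(g$value)
        if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
        breaks <- seq(rng[1], rng[2], length.out = bins + 1)
        counts <- lapply(split(g$value, g$construct), function(v)
            graphics::hist(v, breaks = breaks, plot = FALSE)$counts)
        list(breaks = breaks, counts = counts)
    })
    cmp <- do.call(rbind, lapply(unique(metrics$metric), function(m) {
        ha <- summary$mean[summary$construct == roles[["HA"]] &
                           summary$metric == m]
        la <- summary$mean[summary$construct == roles[["LA"]] &
                           summary$metric == m]
        data.frame(metric = m, HA_mean = ha, LA_mean = la, delta = ha - la)
    }))
    hb <- NULL
    if (!is.null(hbonds)) {
        hb <- do.call(rbind, lapply(names(ensembles), function(nm)
            do.call(rbind, lapply(names(hbonds), function(lab) {
                s <- hbonds[[lab]]
                data.frame(construct = nm, label = lab,
                           occupancy = hbondOccupancy(
                               ensembles[[nm]], s$donor, s$hydrogen,
                               s$acceptor))
            }))))
    }
    list(metrics = metrics, summary = summary, histograms = histograms,
         comparison = cmp, hbondOccupancy = hb)
}

#' Percent swap of a binding energy
#'
#' `100 * (E_construct - E_parent) / (E_target - E_parent)`: 100 means the
#' swap fully converted the parent's energy into the target's. The reported
#' value is clamped to `[0, 200]` for display; the raw value is returned
#' alongside.
#'
#' @param eConstruct,eParent,eTarget energies on a common scale, kcal/mol.
#' @return List: `percent` (raw), `percentClamped`.
#' @export
percentSwap <- function(eConstruct, eParent, eTarget) {
    if (abs(eTarget - eParent) < 1e-12)
        stop("usage error: parent and target energies coincide")
    p <- 100 * (eConstruct - eParent) / (eTarget - eParent)
    list(percent = p, percentClamped = min(max(p, 0), 200))
}

#' Affinity calibration and swap report
#'
#' Calibrates the binding-energy weights on the supplied points, predicts
#' per-construct energies from their component series, compares them with
#' experimental energies, and evaluates swap effectiveness for the requested
#' parent/construct/target triples. Simulated and experimental energies are
#' kept on separately labelled scales throughout.
#'
#' @param calibrationPoints data.frame (see [gridCalibrate()]).
#' @param series named list of [EnergyComponentSeries-class], one per
#'   construct.
#' @param experimental named numeric of experimental energies (kcal/mol,
#'   `RT ln Kd` scale) for the same constructs; optional.
#' @param swaps optional data.frame with columns `construct`, `parent`,
#'   `target` naming entries of `series` (simulated scale) or of
#'   `experimental` (experimental scale, when `scale = "experimental"`).
#' @param scale which energy scale the swap table uses.
#' @param gridStep calibration grid resolution.
#' @return List: `calibration` ([CalibrationResult-class]), `energies`
#'   (data.frame `construct`, `simulated_kcal`, `experimental_kcal`),
#'   `quality`, `swapTable`.
#' @export
runAffinityReport <- function(calibrationPoints, series,
                              experimental = NULL, swaps = NULL,
                              scale = c("simulated", "experimental"),
                              gridStep = 0.01) {
    scale <- match.arg(scale)
    cal <- gridCalibrate(calibrationPoints, step = gridStep)
    quality <- fitQuality(calibrationPoints, cal)
    sim <- vapply(series, function(s)
        ensembleEnergy(s, cal@alpha, cal@beta)$energyKcal, numeric(1))
    energies <- data.frame(construct = names(series),
                           simulated_kcal = unname(sim),
                           experimental_kcal = if (is.null(experimental))
                               NA_real_ else
                               unname(experimental[names(series)]),
                           row.names = NULL)
    swapTable <- NULL
    if (!is.null(swaps)) {
        lookup <- if (scale == "simulated")
            stats::setNames(energies$simulated_kcal, energies$construct)
        else experimental
        swapTable <- do.call(rbind, lapply(seq_len(nrow(swaps)), function(i) {
            sw <- percentSwap(lookup[[swaps$construct[i]]],
                              lookup[[swaps$parent[i]]],
                              lookup[[swaps$target[i]]])
            data.frame(construct = swaps$construct[i],
                       parent = swaps$parent[i], target = swaps$target[i],
                       scale = scale, percent_swap = sw$percent,
                       percent_swap_clamped = sw$percentClamped)
        }))
    }
    list(calibration = cal, energies = energies, quality = quality,
         swapTable = swapTable)
}

#' Kinetics report
#'
#' Fits gating rates across concentrations, derives Kd and binding energy
#' with an explicit provenance chain, and optionally runs modal-gating and
#' phi-value analyses.
#'
#' @param datasets list of [DwellDataset-class] across concentrations.
#' @param bimodal optional [DwellDataset-class] for mode segmentation.
#' @param phiPoints optional data.frame for [phiValue()].
#' @param temperatureK temperature for the energy conversion.
#' @return List: `fit` (see [mleFit()]), `kdM`, `energyKcal` (each with a
#'   `provenance` attribute), `modes`, `phi`.
#' @export
runKineticsReport <- function(datasets, bimodal = NULL, phiPoints = NULL,
                              temperatureK = 296.15) {
    fit <- mleFit(datasets)
    kd <- kdFromRates(fit$scheme@kOff, fit$scheme@kOn)
    en <- energyFromKd(kd, temperatureK)
    attr(kd, "provenance") <- "kOff/kOn from dwell-time maximum likelihood"
    attr(en, "provenance") <- paste0("RT(", temperatureK, " K) * ln(Kd), ",
                                     "Kd from rate constants")
    list(fit = fit, kdM = kd, energyKcal = en,
         modes = if (is.null(bimodal)) NULL else segmentModes(bimodal),
         phi = if (is.null(phiPoints)) NULL else phiValue(phiPoints))
}
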