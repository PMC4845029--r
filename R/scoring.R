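## Empirically calibrated ensemble binding-energy score: a linear combination
## of per-snapshot van der Waals and continuum-electrostatic components,
## dE = mean(alpha * E_vdw + beta * E_elec), with the dimensionless weights
## fitted by an exhaustive grid scan against experimental binding energies.

#' Ensemble binding energy
#'
#' Mean over snapshots of `alpha * E_vdw + beta * E_elec` (kcal/mol), plus the
#' per-snapshot distribution for histogramming.
#'
#' @param series an [EnergyComponentSeries-class].
#' @param alpha,beta dimensionless component weights.
#' @return List: `energyKcal` (scalar mean), `perSnapshot` (numeric vector).
#' @export
ensembleEnergy <- function(series, alpha, beta) {
    if (!length(series@eVdw)) stop("usage error: empty component series")
    per <- alpha * series@eVdw + beta * series@eElec
    list(energyKcal = mean(per), perSnapshot = per)
}

#' Grid calibration of the binding-energy weights
#'
#' Exhaustive scan of `(alpha, beta)` over `[rangeLo, rangeHi]^2` at
#' resolution `step`, minimizing the RMSE between predicted
#' (`alpha * mean_e_vdw + beta * mean_e_elec`) and experimental energies.
#' Exact RMSE ties are broken towards smaller alpha, then smaller beta (a
#' fixed convention; a message is emitted when it fires).
#'
#' @param points data.frame with columns `construct`, `mean_e_vdw`,
#'   `mean_e_elec`, `experimental_kcal` (kcal/mol).
#' @param rangeLo,rangeHi,step scan range and resolution (dimensionless).
#' @return A [CalibrationResult-class].
#' @export
gridCalibrate <- function(points, rangeLo = 0, rangeHi = 2, step = 0.01) {
    .checkCalibrationPoints(points, allowSingle = TRUE)
    if (nrow(points) < 2L)
        warning("single calibration point: (alpha, beta) not identifiable")
    grid <- seq(rangeLo, rangeHi, by = step)
    v <- points$mean_e_vdw; e <- points$mean_e_elec
    y <- points$experimental_kcal
    n <- length(y)
    ## SSE(a, b) expanded so the scan is three rank-1 updates, not a loop
    sse <- outer(grid^2, rep(sum(v^2), length(grid))) +
        outer(rep(1, length(grid)), grid^2 * sum(e^2)) +
        2 * outer(grid, grid) * sum(v * e) -
        2 * outer(grid * sum(v * y), rep(1, length(grid))) -
        2 * outer(rep(1, length(grid)), grid * sum(e * y)) + sum(y^2)
    sse[sse < 0] <- 0  # numerical guard
    best <- which(sse == min(sse), arr.ind = TRUE)
    if (nrow(best) > 1L) {
        message("RMSE tie over ", nrow(best),
                " grid points; choosing smallest alpha, then beta")
        best <- best[order(best[, 1], best[, 2]), , drop = FALSE]
    }
    alpha <- grid[best[1, 1]]; beta <- grid[best[1, 2]]
    q <- fitQuality(points, alpha, beta)
    new("CalibrationResult", alpha = alpha, beta = beta, rmse = q$rmse,
        rSquared = q$rSquared, pearsonR = q$pearsonR, gridStep = step)
}

#' Goodness of fit of a calibration
#'
#' RMSE between predicted and experimental energies, the coefficient of
#' determination `R^2 = 1 - SSres/SStot`, and the Pearson correlation between
#' predicted and experimental values. `R^2` and `r` are `NA` when the
#' experimental energies have zero variance.
#'
#' @inheritParams gridCalibrate
#' @param alpha,beta weights to evaluate (or a [CalibrationResult-class]).
#' @return List: `rmse`, `rSquared`, `pearsonR`, `predicted`.
#' @export
fitQuality <- function(points, alpha, beta = NULL) {
    if (is(alpha, "CalibrationResult")) {
        beta <- alpha@beta; alpha <- alpha@alpha
    }
    .checkCalibrationPoints(points, allowSingle = TRUE)
    pred <- alpha * points$mean_e_vdw + beta * points$mean_e_elec
    y <- points$experimental_kcal
    res <- y - pred
    rmse <- sqrt(mean(res^2))
    sstot <- sum((y - mean(y))^2)
    if (sstot < 1e-24 || length(y) < 2L) {
        warning("experimental energies have zero variance: ",
                "R^2 and r undefined")
        return(list(rmse = rmse, rSquared = NA_real_,
                    pearsonR = NA_real_, predicted = pred))
    }
    r <- if (stats::sd(pred) < 1e-24) NA_real_ else stats::cor(pred, y)
    list(rmse = rmse, rSquared = 1 - sum(res^2) / sstot,
         pearsonR = r, predicted = pred)
}

.checkCalibrationPoints <- function(points, allowSingle = FALSE) {
    need <- c("mean_e_vdw", "mean_e_elec", "experimental_kcal")
    if (!all(need %in% names(points)))
        stop("usage error: calibration points need columns ",
             paste(need, collapse = ", "))
    if (nrow(points) < 1L)
        stop("usage error: empty calibration point list")
    if (!allowSingle && nrow(points) < 2L)
        stop("usage error: at least two calibration points required")
    invisible(points)
}

#' Top contributors of a per-residue energy partition
#'
#' Ranks residues by the magnitude of their contribution to the binding
#' energy (favourable contributions are negative) and reports the top
#' fraction together with its share of the total summed magnitude.
#'
#' @param partitions data.frame with columns `residue`, `contribution`
#'   (kcal/mol, signed).
#' @param topFraction fraction of residues to report (default 0.05).
#' @return List: `top` (data.frame `residue`, `contribution`, `rank`,
#'   `cumulative_fraction`), `share` (fraction of total magnitude held by the
#'   top set), `nTop`.
#' @export
partitionReport <- function(partitions, topFraction = 0.05) {
    if (!all(c("residue", "contribution") %in% names(partitions)) ||
        nrow(partitions) == 0L)
        stop("usage error: need a non-empty residue/contribution table")
    mag <- abs(partitions$contribution)
    total <- sum(mag)
    if (total < 1e-24)
        stop("usage error: all contributions are zero")
    ord <- order(mag, decreasing = TRUE)
    ranked <- partitions[ord, , drop = FALSE]
    ranked$rank <- seq_len(nrow(ranked))
    ranked$cumulative_fraction <- cumsum(mag[ord]) / total
    nTop <- ceiling(topFraction * nrow(ranked))
    list(top = ranked[seq_len(nTop), , drop = FALSE],
         share = ranked$cumulative_fraction[nTop], nTop = nTop)
}
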