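## Single-channel gating kinetics under the one-site activation scheme
##   A + C <-> AC <-> AO
## with rates kOn*[A], kOff, fOpen, bClose. The observable record aggregates
## {C, AC} into a closed class and {AO} into an open class: open dwells are
## exponential with rate bClose; closed dwells follow the phase-type
## distribution of the 2-state closed-class generator entered at AC (the state
## reached from the open class).

.GAS_CONSTANT_KCAL <- 1.98720425864083e-3  # kcal / (mol K)

#' RT in kcal/mol
#'
#' The thermal energy factor converting a log equilibrium constant into a
#' free energy. At the default 296.15 K (23 C) it rounds to the conventional
#' 0.59 kcal/mol per ln unit.
#'
#' @param temperatureK absolute temperature, kelvin.
#' @return RT in kcal/mol (full precision).
#' @export
rtCoefficient <- function(temperatureK = 296.15) {
    .GAS_CONSTANT_KCAL * temperatureK
}

#' Simulate an idealized dwell-time record
#'
#' Exact continuous-time Markov sampling of the gating scheme, emitted as
#' alternating closed/open interval durations. Each closed dwell starts in AC
#' (the closed-class entry state from the open class); the number of visits
#' to the unbound state C within a closed dwell is geometric, and the sojourn
#' sums are gamma, so the sampler is vectorized yet distributionally exact.
#' No dead-time (missed-event) censoring is applied: a nonzero
#' `deadTimeS` is accepted but only triggers an "uncorrected" warning.
#'
#' @param scheme a [GatingScheme-class].
#' @param concM agonist concentration, molar.
#' @param nEvents number of closed/open dwell pairs.
#' @param seed integer seed (the record is reproducible byte-for-byte).
#' @param voltageMv,construct metadata for the dataset.
#' @param clusterId cluster label for the emitted intervals.
#' @param deadTimeS accepted for interface compatibility; must be 0 for an
#'   uncensored record (a warning is raised otherwise and no correction is
#'   applied).
#' @return A [DwellDataset-class] with `2 * nEvents` alternating intervals.
#' @export
simulateDwells <- function(scheme, concM, nEvents, seed = 1L,
                           voltageMv = -100, construct = "sim",
                           clusterId = 1L, deadTimeS = 0) {
    if (nEvents < 1L) stop("usage error: nEvents must be >= 1")
    if (concM <= 0) stop("usage error: concentration must be positive")
    if (deadTimeS > 0)
        warning("dead time supplied but no missed-event correction is ",
                "applied (record left uncorrected)")
    set.seed(as.integer(seed))
    iv <- .sampleDwellPairs(scheme, concM, nEvents)
    DwellDataset(data.frame(cluster_id = clusterId,
                            state = rep(c("closed", "open"), nEvents),
                            duration_s = as.vector(rbind(iv$closed,
                                                         iv$open))),
                 concM = concM, voltageMv = voltageMv, construct = construct)
}

## Closed dwell entered at AC: leave AC at rate kOff+fOpen, opening with
## probability fOpen/(kOff+fOpen); N ~ Geom counts the returns to C.
.sampleDwellPairs <- function(scheme, concM, n) {
    a <- scheme@kOn * concM
    exitAC <- scheme@kOff + scheme@fOpen
    p <- scheme@fOpen / exitAC
    nC <- stats::rgeom(n, p)
    closed <- stats::rgamma(n, shape = nC + 1, rate = exitAC) +
        ifelse(nC > 0, stats::rgamma(n, shape = pmax(nC, 1), rate = a), 0)
    open <- stats::rexp(n, scheme@bClose)
    list(closed = closed, open = open)
}

#' Stationary occupancies of the gating scheme
#'
#' Analytic stationary distribution over (C, AC, AO) at a given
#' concentration (detailed balance along the linear chain).
#'
#' @inheritParams simulateDwells
#' @return Named numeric probabilities summing to 1.
#' @export
stationaryOccupancy <- function(scheme, concM) {
    piC <- 1
    piAC <- scheme@kOn * concM / scheme@kOff
    piAO <- piAC * scheme@fOpen / scheme@bClose
    tot <- piC + piAC + piAO
    c(C = piC, AC = piAC, AO = piAO) / tot
}

## log-density of closed dwells entered at AC, as a two-exponential mixture
## from the eigendecomposition of Qc = [[-a, a], [kOff, -(kOff+f)]].
.closedLogDensity <- function(t, kOn, kOff, fOpen, concM) {
    a <- kOn * concM
    s <- a + kOff + fOpen
    disc <- s^2 - 4 * a * fOpen
    disc <- max(disc, 0)
    mu1 <- (-s + sqrt(disc)) / 2
    mu2 <- (-s - sqrt(disc)) / 2
    q22 <- -(kOff + fOpen)
    if (abs(mu1 - mu2) < 1e-12 * abs(mu2)) mu1 <- mu2 * (1 - 1e-9)
    w1 <- (q22 - mu2) / (mu1 - mu2)
    w2 <- (q22 - mu1) / (mu2 - mu1)
    dens <- fOpen * (w1 * exp(mu1 * t) + w2 * exp(mu2 * t))
    log(pmax(dens, 1e-300))
}

.dwellDurations <- function(dataset, state) {
    iv <- dataset@intervals
    iv$duration_s[iv$state == state]
}

#' Maximum-likelihood gating rates from dwell times
#'
#' Global fit of the four rate constants across datasets recorded at two or
#' more agonist concentrations. Open dwells are exponential in `bClose`
#' (estimated in closed form); closed dwells contribute the phase-type
#' likelihood of the closed-class generator with `kOn` entering as
#' `kOn * conc`. `kOn`, `kOff` and `fOpen` are optimized on a log10 scale by
#' Nelder-Mead from several starting points seeded by the linear relation
#' between mean closed duration and 1/conc, then polished by BFGS. Standard
#' errors come from the observed information (delta method back to the rate
#' scale).
#'
#' @param datasets list of [DwellDataset-class] at distinct concentrations.
#' @param nRestarts number of optimizer starting points.
#' @return List: `scheme` ([GatingScheme-class]), `logLik`, `se` (named,
#'   rate scale), `convergence`, `nEvents`.
#' @export
mleFit <- function(datasets, nRestarts = 4L) {
    if (is(datasets, "DwellDataset")) datasets <- list(datasets)
    concs <- vapply(datasets, function(d) d@concM, numeric(1))
    if (length(unique(concs)) < 2L)
        stop("usage error: datasets at >= 2 distinct concentrations required")
    open <- lapply(datasets, .dwellDurations, "open")
    closed <- lapply(datasets, .dwellDurations, "closed")
    nTot <- sum(lengths(open)) + sum(lengths(closed))
    if (nTot < 100L)
        warning("fewer than 100 events in total; estimates will be noisy")
    allOpen <- unlist(open)
    bHat <- 1 / mean(allOpen)

    negll <- function(logp) {
        kOn <- 10^logp[1]; kOff <- 10^logp[2]; f <- 10^logp[3]
        -sum(vapply(seq_along(datasets), function(i)
            sum(.closedLogDensity(closed[[i]], kOn, kOff, f, concs[i])),
            numeric(1)))
    }

    ## starting values: mean closed = 1/f + (kOff/kOn)/(f * conc),
    ## linear in 1/conc -> intercept gives f, slope gives Kd/f
    mc <- vapply(closed, mean, numeric(1))
    co <- stats::coef(stats::lm(mc ~ I(1 / concs)))
    f0 <- if (co[1] > 0) 1 / co[1] else 1 / min(mc)
    kd0 <- max(co[2] * f0, 1e-12)
    starts <- lapply(10^seq(7, 7 + nRestarts - 1), function(kOn0)
        log10(c(kOn0, kd0 * kOn0, f0)))

    best <- NULL
    for (st in starts) {
        fit <- tryCatch({
            nm <- stats::optim(st, negll, method = "Nelder-Mead",
                               control = list(maxit = 2000))
            stats::optim(nm$par, negll, method = "BFGS", hessian = TRUE,
                         control = list(maxit = 500))
        }, error = function(e) NULL)
        if (!is.null(fit) && (is.null(best) || fit$value < best$value))
            best <- fit
    }
    if (is.null(best))
        stop("non-convergence: optimizer failed from every starting point")
    kOn <- 10^best$par[1]; kOff <- 10^best$par[2]; f <- 10^best$par[3]
    scheme <- GatingScheme(kOn, kOff, f, bHat)
    ## SEs: delta method, d(rate)/d(log10 rate) = rate * ln(10)
    seLog <- tryCatch({
        cv <- solve(best$hessian)
        sqrt(pmax(diag(cv), 0))
    }, error = function(e) rep(NA_real_, 3))
    se <- c(kOn = kOn * log(10) * seLog[1],
            kOff = kOff * log(10) * seLog[2],
            fOpen = f * log(10) * seLog[3],
            bClose = bHat / sqrt(length(allOpen)))
    ll <- -best$value +
        sum(stats::dexp(allOpen, bHat, log = TRUE))
    list(scheme = scheme, logLik = ll, se = se,
         convergence = best$convergence, nEvents = nTot)
}

#' Log-likelihood of a dwell record under a gating scheme
#'
#' The aggregated two-class likelihood used by [mleFit()], exposed for
#' model comparison and consistency checks.
#'
#' @inheritParams mleFit
#' @param scheme a [GatingScheme-class].
#' @return Log-likelihood (numeric scalar).
#' @export
dwellLogLik <- function(datasets, scheme) {
    if (is(datasets, "DwellDataset")) datasets <- list(datasets)
    sum(vapply(datasets, function(d) {
        op <- .dwellDurations(d, "open")
        cl <- .dwellDurations(d, "closed")
        sum(stats::dexp(op, scheme@bClose, log = TRUE)) +
            sum(.closedLogDensity(cl, scheme@kOn, scheme@kOff,
                                  scheme@fOpen, d@concM))
    }, numeric(1)))
}

#' Kd from rate constants
#'
#' Resting-state equilibrium dissociation constant as the ratio of the
#' dissociation and association rate constants.
#'
#' @param kOff dissociation rate, /s.
#' @param kOn association rate, /M/s.
#' @return Kd in molar.
#' @export
kdFromRates <- function(kOff, kOn) {
    if (kOff <= 0 || kOn <= 0) stop("usage error: rates must be positive")
    kOff / kOn
}

#' Kd proxy from gating equilibrium constants
#'
#' `E0 / E1`, the ratio of the unliganded (allosteric) and mono-liganded
#' gating equilibrium constants. Dimensionally this is a proxy, not a molar
#' Kd (the omitted open-state affinity constant is shared between
#' constructs); it is flagged as such and is valid for ddG-style comparisons
#' where the constant cancels.
#'
#' @param E0,E1 gating equilibrium constants (dimensionless, positive).
#' @return Numeric with attribute `provenance = "E0/E1 proxy"`.
#' @export
kdFromEquilibrium <- function(E0, E1) {
    if (E0 <= 0 || E1 <= 0)
        stop("usage error: equilibrium constants must be positive")
    structure(E0 / E1, provenance = "E0/E1 proxy")
}

#' Gating equilibrium constant from a dwell record
#'
#' Two-state estimate `E = mean open / mean closed`, valid at full saturation
#' (closed dwells are then sojourns in AC) or for unliganded gating. The
#' caller asserts the regime.
#'
#' @param dataset a [DwellDataset-class].
#' @return Dimensionless equilibrium constant.
#' @export
estimateEFromCluster <- function(dataset) {
    op <- .dwellDurations(dataset, "open")
    cl <- .dwellDurations(dataset, "closed")
    if (length(op) < 10L || length(cl) < 10L)
        warning("fewer than 10 events; E estimate will be unreliable")
    mean(op) / mean(cl)
}

#' Remove an engineered background from a measured E0
#'
#' Constitutively active backgrounds multiply the unliganded gating
#' equilibrium constant by known, energetically independent fold changes; the
#' aggregate E0 is the wild-type value times their product. This inverts the
#' enhancement.
#'
#' @param E0Measured measured aggregate E0 (positive).
#' @param foldChanges numeric vector of known fold changes (positive); empty
#'   means no background.
#' @return Background-corrected E0.
#' @export
correctBackground <- function(E0Measured, foldChanges = numeric()) {
    if (E0Measured <= 0) stop("usage error: E0 must be positive")
    if (length(foldChanges) && any(foldChanges <= 0))
        stop("usage error: fold changes must be positive")
    E0Measured / prod(foldChanges)
}

#' Free energy from an equilibrium constant
#'
#' `RT * ln(x)` in kcal/mol. At the default temperature (296.15 K, 23 C) the
#' RT factor rounds to the conventional 0.59 kcal/mol per ln unit; the full
#' precision value is used in the computation and also returned as an
#' attribute.
#'
#' @param kdOrRatio positive equilibrium constant or ratio.
#' @param temperatureK absolute temperature, kelvin.
#' @return Energy in kcal/mol, with attributes `rtKcal` (full precision) and
#'   `rtRounded` (two decimals).
#' @export
energyFromKd <- function(kdOrRatio, temperatureK = 296.15) {
    if (any(kdOrRatio <= 0))
        stop("usage error: equilibrium constant must be positive")
    rt <- rtCoefficient(temperatureK)
    structure(rt * log(kdOrRatio), rtKcal = rt, rtRounded = round(rt, 2))
}

#' Fold change from a free-energy difference
#'
#' `exp(delta / RT)`; the exact inverse of [energyFromKd()].
#'
#' @param deltaKcal energy difference, kcal/mol.
#' @inheritParams energyFromKd
#' @return Dimensionless fold change.
#' @export
foldFromEnergy <- function(deltaKcal, temperatureK = 296.15) {
    exp(deltaKcal / rtCoefficient(temperatureK))
}

#' Two-site additivity ledger
#'
#' Binding energies measured from two sites combined are approximately the
#' sums of the single-site energies. Given per-site energies, returns the
#' combined total, all pairwise site-sums, and the pairwise ddG table.
#'
#' @param siteEnergies named numeric vector of per-site binding energies,
#'   kcal/mol.
#' @return List: `totalKcal` (sum; 0 for an empty map), `pairTotals`
#'   (data.frame `site1`, `site2`, `total_kcal`), `ddG` (data.frame `site1`,
#'   `site2`, `ddG_kcal` = E(site2) - E(site1)).
#' @export
additivityLedger <- function(siteEnergies) {
    n <- length(siteEnergies)
    nm <- names(siteEnergies)
    if (is.null(nm)) nm <- paste0("site", seq_len(n))
    pairs <- if (n >= 2) utils::combn(n, 2) else
        matrix(integer(), nrow = 2)
    pairTotals <- data.frame(site1 = nm[pairs[1, ]], site2 = nm[pairs[2, ]],
        total_kcal = siteEnergies[pairs[1, ]] + siteEnergies[pairs[2, ]],
        row.names = NULL)
    ddG <- data.frame(site1 = nm[pairs[1, ]], site2 = nm[pairs[2, ]],
        ddG_kcal = siteEnergies[pairs[2, ]] - siteEnergies[pairs[1, ]],
        row.names = NULL)
    list(totalKcal = sum(siteEnergies), pairTotals = pairTotals, ddG = ddG)
}

#' Phi value from a rate-equilibrium relationship
#'
#' Unweighted ordinary least-squares slope of `log10(opening rate)` against
#' `log10(gating equilibrium constant)` across a series of constructs. The
#' slope maps the transition-state position of the perturbed region on a
#' 0-to-1 scale; values outside `[0, 1]` raise a warning.
#'
#' @param points data.frame with columns `opening_rate` (/s) and `gating_E`
#'   (dimensionless), both positive.
#' @return List: `phi` (slope), `intercept`, `r` (Pearson, `NA` for 2
#'   points' perfect fit degeneracies).
#' @export
phiValue <- function(points) {
    if (nrow(points) < 2L)
        stop("usage error: at least two constructs required")
    if (any(points$opening_rate <= 0) || any(points$gating_E <= 0))
        stop("usage error: rates and equilibrium constants must be positive")
    x <- log10(points$gating_E); y <- log10(points$opening_rate)
    if (stats::sd(x) < 1e-24)
        stop("usage error: gating equilibrium constants are all equal")
    fit <- stats::lm(y ~ x)
    phi <- unname(stats::coef(fit)[2])
    if (phi < 0 || phi > 1)
        warning("phi outside [0, 1]: ", format(phi, digits = 3))
    r <- if (stats::sd(y) < 1e-24) NA_real_ else stats::cor(x, y)
    list(phi = phi, intercept = unname(stats::coef(fit)[1]), r = r)
}

#' Modal-gating segmentation of clusters
#'
#' Classifies clusters into up to two activity modes by a Gaussian mixture
#' fit (BIC-selected between one and two components) on log10 mean open
#' duration per cluster. Prevalence is the time-weighted fraction of each
#' mode; the switching time constant is the mean duration of runs of
#' consecutive same-mode clusters (the maximum-likelihood mean of an
#' exponential run length). This segmentation is a documented convention of
#' the package.
#'
#' @param dataset a [DwellDataset-class] with at least 10 clusters (fewer
#'   raises a warning).
#' @return List: `nModes`, `modeLabels` (per cluster, in order of first
#'   appearance; mode 1 = shorter open durations), `prevalence`
#'   (time-weighted), `switchingTauS` (`NA` when unimodal), `clusterStats`.
#' @importFrom mclust Mclust mclustBIC
#' @export
segmentModes <- function(dataset) {
    iv <- dataset@intervals
    ids <- unique(iv$cluster_id)
    if (length(ids) < 10L)
        warning("fewer than 10 clusters; mode analysis will be unreliable")
    stats <- do.call(rbind, lapply(ids, function(id) {
        g <- iv[iv$cluster_id == id, ]
        data.frame(cluster_id = id,
                   mean_open_s = mean(g$duration_s[g$state == "open"]),
                   duration_s = sum(g$duration_s))
    }))
    stats <- stats[is.finite(stats$mean_open_s), , drop = FALSE]
    if (nrow(stats) < 2L)
        stop("usage error: fewer than 2 clusters contain open dwells")
    x <- log10(stats$mean_open_s)
    fit <- mclust::Mclust(x, G = 1:2, modelNames = c("E", "V"),
                          verbose = FALSE)
    if (is.null(fit) || fit$G == 1L || length(unique(fit$classification)) < 2L)
        return(list(nModes = 1L,
                    modeLabels = rep(1L, nrow(stats)),
                    prevalence = c(mode1 = 1),
                    switchingTauS = NA_real_, clusterStats = stats))
    cls <- fit$classification
    ## label modes so mode 1 has the shorter open durations
    ord <- order(tapply(x, cls, mean))
    labels <- match(cls, ord)
    w <- tapply(stats$duration_s, labels, sum)
    prevalence <- as.numeric(w / sum(w))
    names(prevalence) <- paste0("mode", seq_along(prevalence))
    runs <- rle(labels)
    runDur <- vapply(seq_along(runs$lengths), function(i) {
        j <- sum(runs$lengths[seq_len(i - 1)])
        sum(stats$duration_s[j + seq_len(runs$lengths[i])])
    }, numeric(1))
    list(nModes = 2L, modeLabels = labels, prevalence = prevalence,
         switchingTauS = mean(runDur), clusterStats = stats)
}
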