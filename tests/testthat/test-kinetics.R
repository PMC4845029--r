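wtScheme <- function() GatingScheme(1e8, 1e4, 1e3, 1e3)

test_that("simulated dwell moments match the scheme's sojourn structure", {
    sch <- wtScheme()
    ds <- simulateDwells(sch, 1e-4, 10000, seed = 3)
    open <- ds@intervals$duration_s[ds@intervals$state == "open"]
    ## mean open = 1/bClose within 3 standard errors
    se <- (1 / sch@bClose) / sqrt(length(open))
    expect_lt(abs(mean(open) - 1 / sch@bClose), 3 * se)

    ## saturation limit: closed dwells -> exponential with rate fOpen
    sat <- simulateDwells(sch, 1, 10000, seed = 4)  # kOn*c >> kOff
    closed <- sat@intervals$duration_s[sat@intervals$state == "closed"]
    seC <- (1 / sch@fOpen) / sqrt(length(closed))
    expect_lt(abs(mean(closed) - 1 / sch@fOpen), 4 * seC)
    ## exponential shape: cv ~ 1
    expect_equal(sd(closed) / mean(closed), 1, tolerance = 0.05)

    ## fixed seed gives a byte-identical record
    again <- simulateDwells(sch, 1e-4, 10000, seed = 3)
    expect_identical(ds@intervals, again@intervals)
})

test_that("aggregate occupancies match the analytic stationary distribution", {
    sch <- wtScheme()
    for (conc in c(2e-5, 1e-4, 5e-4)) {
        ds <- simulateDwells(sch, conc, 20000, seed = round(conc * 1e6))
        iv <- ds@intervals
        openFrac <- sum(iv$duration_s[iv$state == "open"]) /
            sum(iv$duration_s)
        pi <- stationaryOccupancy(sch, conc)
        expect_equal(openFrac, unname(pi["AO"]), tolerance = 0.05)
    }
})

test_that("the closed-dwell density is a proper phase-type density", {
    skip_if_not_installed("Matrix")
    sch <- wtScheme(); conc <- 1e-4
    t <- c(1e-5, 1e-4, 5e-4, 2e-3, 1e-2)
    mine <- exp(SiteAffinity:::.closedLogDensity(t, sch@kOn, sch@kOff,
                                                 sch@fOpen, conc))
    ## independent numerics: matrix exponential of the closed-class generator
    a <- sch@kOn * conc
    Q <- matrix(c(-a, a, sch@kOff, -(sch@kOff + sch@fOpen)), 2, 2,
                byrow = TRUE)
    oracle <- vapply(t, function(ti) {
        E <- as.matrix(Matrix::expm(Q * ti))
        sch@fOpen * E[2, 2]
    }, numeric(1))
    expect_equal(mine, oracle, tolerance = 1e-8)
    ## integrates to one
    total <- integrate(function(x)
        exp(SiteAffinity:::.closedLogDensity(x, sch@kOn, sch@kOff,
                                             sch@fOpen, conc)),
        0, Inf, rel.tol = 1e-9)$value
    expect_equal(total, 1, tolerance = 1e-6)
})

test_that("the likelihood prefers the generating rates over perturbed ones", {
    sch <- wtScheme()
    ds <- makeDwellData(sch, c(2e-5, 1e-4, 5e-4), 5000, seed = 8)
    llTrue <- dwellLogLik(ds, sch)
    for (fac in c(0.5, 2)) {
        pert <- GatingScheme(sch@kOn * fac, sch@kOff * fac,
                             sch@fOpen * fac, sch@bClose * fac)
        expect_gt(llTrue, dwellLogLik(ds, pert))
    }
})

test_that("maximum likelihood recovers the generating rates", {
    sch <- wtScheme()
    ds <- makeDwellData(sch, c(2e-5, 1e-4, 5e-4), 5000, seed = 15)
    fit <- mleFit(ds)
    expect_lt(abs(fit$scheme@kOn - sch@kOn) / sch@kOn, 0.10)
    expect_lt(abs(fit$scheme@kOff - sch@kOff) / sch@kOff, 0.10)
    expect_lt(abs(fit$scheme@fOpen - sch@fOpen) / sch@fOpen, 0.10)
    expect_lt(abs(fit$scheme@bClose - sch@bClose) / sch@bClose, 0.10)
    ## end-to-end Kd consistency
    kd <- kdFromRates(fit$scheme@kOff, fit$scheme@kOn)
    expect_lt(abs(kd - schemeKd(sch)) / schemeKd(sch), 0.10)
    expect_true(all(is.finite(fit$se)))

    expect_error(mleFit(list(ds[[1]])), ">= 2 distinct concentrations")
})

test_that("Kd and proxy arithmetic behave as stated", {
    expect_equal(kdFromRates(1e3, 1e8), 1e-5)
    expect_equal(kdFromRates(7, 7), 1)
    prox <- kdFromEquilibrium(7.4e-7, 7.4)
    expect_equal(as.numeric(prox), 1e-7)
    expect_equal(attr(prox, "provenance"), "E0/E1 proxy")
    expect_equal(as.numeric(kdFromEquilibrium(2, 2)), 1)

    ## ddG from proxies equals ddG from molar Kd when the shared open-state
    ## constant cancels
    kA <- 1e-6; kB <- 3e-5; shared <- 17.3
    ddgMolar <- energyFromKd(kB) - energyFromKd(kA)
    ddgProxy <- energyFromKd(kB * shared) - energyFromKd(kA * shared)
    expect_equal(as.numeric(ddgProxy), as.numeric(ddgMolar),
                 tolerance = 1e-12)
})

test_that("saturated-cluster E estimate recovers fOpen/bClose", {
    expect_equal(estimateEFromCluster(DwellDataset(data.frame(
        cluster_id = 1, state = rep(c("closed", "open"), 20),
        duration_s = rep(c(1e-3, 2e-3), 20)), concM = 1)), 2.0)
    sch <- wtScheme()
    sat <- simulateDwells(sch, 1, 5000, seed = 21)  # >> 5 Kd
    expect_equal(estimateEFromCluster(sat), schemeE1(sch), tolerance = 0.05)
    expect_warning(estimateEFromCluster(DwellDataset(data.frame(
        cluster_id = 1, state = c("closed", "open"),
        duration_s = c(1e-3, 1e-3)), concM = 1)), "fewer than 10")
})

test_that("background correction inverts known fold changes", {
    expect_equal(correctBackground(7.4e-4, c(10, 100)), 7.4e-7)
    expect_equal(correctBackground(0.3), 0.3)
    e0 <- 5.2e-7
    expect_equal(correctBackground(e0 * 10 * 25, c(10, 25)), e0,
                 tolerance = 1e-15)
    expect_error(correctBackground(1, c(2, 0)), "positive")
})

test_that("energy/fold conversions are exact inverses on the RT scale", {
    expect_equal(as.numeric(energyFromKd(1)), 0)
    expect_equal(attr(energyFromKd(1), "rtRounded"), 0.59)
    expect_equal(foldFromEnergy(0), 1)
    set.seed(2)
    for (x in runif(20, -5, 5))
        expect_equal(as.numeric(energyFromKd(foldFromEnergy(x))), x,
                     tolerance = 1e-10)
})

test_that("two-site additivity totals and ddG are permutation invariant", {
    led <- additivityLedger(c(ad = -5.1, ag = -7.1))
    expect_equal(led$totalKcal, -12.2)
    expect_equal(led$pairTotals$total_kcal, -12.2)
    led2 <- additivityLedger(c(ag = -7.1, ad = -5.1))
    expect_equal(led2$totalKcal, led$totalKcal)
    expect_equal(additivityLedger(c(ad = -5.1, ae = -5.1))$totalKcal, -10.2)
    expect_equal(additivityLedger(numeric())$totalKcal, 0)
    expect_equal(abs(led$ddG$ddG_kcal), 2.0, tolerance = 1e-12)
})

test_that("phi regression recovers constructed log-log slopes", {
    e <- c(0.1, 1, 10, 100)
    prop <- data.frame(opening_rate = 50 * e, gating_E = e)
    expect_equal(phiValue(prop)$phi, 1, tolerance = 1e-12)
    flat <- data.frame(opening_rate = rep(200, 4), gating_E = e)
    expect_equal(phiValue(flat)$phi, 0, tolerance = 1e-12)
    two <- data.frame(opening_rate = c(10^2.43, 10^3), gating_E = c(1, 10))
    expect_equal(phiValue(two)$phi, 0.57, tolerance = 1e-9)
    expect_error(phiValue(prop[1, , drop = FALSE]), "two constructs")
    steep <- data.frame(opening_rate = c(1, 1000), gating_E = c(1, 10))
    expect_warning(phiValue(steep), "outside")
})

test_that("mode segmentation recovers a two-mode switching record", {
    ha <- GatingScheme(1e8, 1e4, 2e4, 5e2)   # long openings
    la <- GatingScheme(1e8, 1e4, 2e4, 5e3)   # 10x briefer openings
    bim <- makeBimodalDwells(ha, la, switchTauS = 0.020, nClusters = 500,
                             concM = 1, seed = 33)
    tr <- attr(bim, "truth")
    seg <- segmentModes(bim)
    expect_equal(seg$nModes, 2L)
    expect_equal(unname(seg$prevalence[1]), 0.5, tolerance = 0.1)
    expect_equal(unname(seg$prevalence[2]), 0.5, tolerance = 0.1)
    expect_equal(seg$switchingTauS, tr$switchTauS, tolerance = 0.2)
    ## labels align with the generating modes (mode 2 = longer openings = HA)
    truthLabels <- ifelse(tr$modes == "HA", 2L, 1L)
    keep <- seg$clusterStats$cluster_id
    expect_gt(mean(seg$modeLabels == truthLabels[keep]), 0.9)

    ## unimodal input is reported as a single mode, not force-split
    uni <- makeBimodalDwells(ha, ha, switchTauS = 0.020, nClusters = 100,
                             concM = 1, seed = 34)
    segU <- segmentModes(uni)
    expect_equal(segU$nModes, 1L)
    expect_true(is.na(segU$switchingTauS))
})
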