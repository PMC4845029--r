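test_that("ring centroids are means and translate with the ring", {
    hex <- hexagonXY(1.39)
    ens <- ensembleFromFrames(list(hex))
    expect_equal(ringCentroid(ens, 1:6), c(x = 0, y = 0, z = 0),
                 tolerance = 1e-12, ignore_attr = TRUE)
    shifted <- ensembleFromFrames(list(sweep(hex, 2, c(1, 2, 3), "+")))
    expect_equal(unname(ringCentroid(shifted, 1:6)), c(1, 2, 3),
                 tolerance = 1e-12)
    ## partial ring: plain average of the atoms present
    expect_equal(unname(ringCentroid(ens, 1:5)), colMeans(hex[1:5, ]),
                 tolerance = 1e-12)
})

test_that("pocket volume matches the adjoining-tetrahedra construction", {
    ## unit regular tetrahedron + mirror apex through one face
    s <- 1
    base <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0))
    apex <- c(0.5, sqrt(3) / 6, sqrt(2 / 3))
    mirror <- apex * c(1, 1, -1)
    pts <- rbind(base, apex, mirror)
    rownames(pts) <- c("aW149", "aY198", "aY93", "aY190", "W55")
    vol <- pocketVolume(pts)
    expect_equal(vol, 2 * sqrt(2) / 12, tolerance = 1e-9)

    ## coplanar degenerate configuration has zero volume
    flat <- pts; flat[, 3] <- 0
    expect_equal(pocketVolume(flat), 0, tolerance = 1e-12)

    ## decomposition contract
    expect_error(pocketVolume(pts, list(rownames(pts)[1:4],
                                        rownames(pts)[1:4])),
                 "cover all five")
    expect_error(pocketVolume(pts, list(c("aW149", "aY198", "aY93", "aY190"),
                                        c("W55", "aY198", "aY93", "aY190"))),
                 NA)  # shares exactly 3: valid
    expect_error(pocketVolume(pts,
                              list(c("aW149", "aY198", "aY93", "aY190"),
                                   c("W55", "aW149", "aY198", "aY93"))),
                 NA)
})

test_that("pocket volume equals independent Cayley-Menger sums on random sets", {
    set.seed(42)
    for (i in 1:1000) {
        pts <- matrix(rnorm(15, sd = 3), 5, 3)
        rownames(pts) <- c("aW149", "aY198", "aY190", "aY93", "W55")
        dec <- list(c("aW149", "aY198", "aY190", "aY93"),
                    c("aW149", "aY93", "W55", "aY198"))
        oracle <- cayleyMengerVolume(pts[dec[[1]], ]) +
            cayleyMengerVolume(pts[dec[[2]], ])
        expect_equal(pocketVolume(pts, dec), oracle, tolerance = 1e-8)
    }
})

test_that("strand axis is the least-squares line with first-to-last sign", {
    z <- cbind(0, 0, seq(0, 10, length.out = 8))
    expect_equal(strandAxis(z), c(0, 0, 1), tolerance = 1e-12)
    expect_equal(strandAxis(z[8:1, ]), c(0, 0, -1), tolerance = 1e-12)

    ## helically jittered line: compare against a per-coordinate regression
    set.seed(7)
    t <- seq(0, 12, length.out = 20)
    pts <- cbind(0.1 * cos(2 * t) + rnorm(20, sd = 0.05),
                 0.1 * sin(2 * t) + rnorm(20, sd = 0.05), t)
    ax <- strandAxis(pts)
    expect_lt(acos(abs(ax[3])) * 180 / pi, 2)  # within 2 degrees of +z
    lmdir <- c(coef(lm(pts[, 1] ~ pts[, 3]))[2],
               coef(lm(pts[, 2] ~ pts[, 3]))[2], 1)
    lmdir <- lmdir / sqrt(sum(lmdir^2))
    expect_lt(acos(min(1, abs(sum(ax * lmdir)))) * 180 / pi, 0.5)

    expect_error(strandAxis(matrix(1, 4, 3)), "identical")
})

test_that("hairpin twist folds to [0, 90] and reproduces built angles", {
    expect_equal(hairpinTwist(c(0, 0, 1), c(0, 0, 1)), 0)
    expect_equal(hairpinTwist(c(0, 0, 1), c(0, 0, -1)), 0)  # antiparallel
    expect_equal(hairpinTwist(c(1, 0, 0), c(0, 1, 0)), 90)
    th <- 9 * pi / 180
    expect_equal(hairpinTwist(c(0, 0, 1), c(sin(th), 0, cos(th))), 9,
                 tolerance = 1e-6)
    expect_error(hairpinTwist(c(0, 0, 0), c(0, 0, 1)), "zero")
})

test_that("hairpin tilt is the unfolded angle against the reference", {
    expect_equal(hairpinTilt(c(0, 0, 1), c(0, 0, 1)), 0)
    expect_equal(hairpinTilt(c(0, 0, 1), c(0, 0, -1)), 180)
    th <- 8 * pi / 180
    expect_equal(hairpinTilt(c(sin(th), 0, cos(th)), c(0, 0, 1)), 8,
                 tolerance = 1e-6)
})

test_that("torsions follow the IUPAC convention with mirror antisymmetry", {
    ## planar cis and trans butane-like frames
    cis <- rbind(c(1, 1, 0), c(0, 1, 0), c(0, 0, 0), c(1, 0, 0))
    expect_equal(dihedralAngle(cis[1, ], cis[2, ], cis[3, ], cis[4, ]), 0,
                 tolerance = 1e-9)
    trans <- rbind(c(-1, 2, 0), c(0, 1, 0), c(0, 0, 0), c(1, -1, 0))
    expect_equal(abs(dihedralAngle(trans[1, ], trans[2, ], trans[3, ],
                                   trans[4, ])), 180, tolerance = 1e-9)
    set.seed(3)
    for (i in 1:50) {
        p <- matrix(rnorm(12), 4, 3)
        d <- tryCatch(dihedralAngle(p[1, ], p[2, ], p[3, ], p[4, ]),
                      error = function(e) NA)
        if (is.na(d)) next
        mir <- p %*% diag(c(1, 1, -1))
        expect_equal(dihedralAngle(mir[1, ], mir[2, ], mir[3, ], mir[4, ]),
                     -d, tolerance = 1e-8)
        ## reversal symmetry
        expect_equal(dihedralAngle(p[4, ], p[3, ], p[2, ], p[1, ]), d,
                     tolerance = 1e-8)
    }
    expect_error(dihedralAngle(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0),
                               c(3, 1, 0)), "collinear")
})

test_that("tau2 basin fractions count by sign within the basin window", {
    expect_equal(tau2BasinFractions(rep(60, 10)),
                 c(f_minus60 = 0, f_plus60 = 1))
    mix <- c(rep(60, 5), -60)
    expect_equal(tau2BasinFractions(mix),
                 c(f_minus60 = 1 / 6, f_plus60 = 5 / 6))
    expect_equal(tau2BasinFractions(c(175, -175)),
                 c(f_minus60 = 0, f_plus60 = 0))
    expect_error(tau2BasinFractions(numeric()), "empty")
})

test_that("hydrogen-bond criterion applies the printed bounds", {
    donor <- c(0, 0, 0)
    mkAcc <- function(d, angleDeg) {
        th <- angleDeg * pi / 180
        d * c(cos(th), sin(th), 0)
    }
    hyd <- c(1, 0, 0)
    expect_true(detectHBond(donor, hyd, mkAcc(3.4, 20)))
    expect_false(detectHBond(donor, hyd, mkAcc(3.6, 0)))
    expect_false(detectHBond(donor, hyd, mkAcc(3.0, 31)))
    ## boundary behaviour: distance strict, angle inclusive
    expect_true(detectHBond(donor, hyd, mkAcc(3.4999, 30)))
    expect_false(detectHBond(donor, hyd, mkAcc(3.5, 0)))
    ## distance-only fallback for heavy-atom structures
    expect_true(detectHBond(donor, NULL, mkAcc(3.4, 90),
                            requireHydrogen = FALSE))
})

test_that("occupancy equals the generator's target bookkeeping exactly", {
    ens <- makeHbondSeries(0.8, 2000, seed = 9)
    tr <- attr(ens, "truth")
    expect_equal(hbondOccupancy(ens, tr$donor, tr$hydrogen, tr$acceptor),
                 tr$realizedOccupancy)
    expect_equal(tr$realizedOccupancy, 0.8)
    expect_equal(hbondOccupancy(makeHbondSeries(0, 50), 1, 2, 3), 0)
    expect_equal(hbondOccupancy(makeHbondSeries(1, 50), 1, 2, 3), 1)
})

test_that("ring orientation reports centroid distance and folded normal angle", {
    hex <- hexagonXY(1.39)
    stacked <- sweep(hex, 2, c(0, 0, 3.5), "+")
    ens <- ensembleFromFrames(list(rbind(hex, stacked)))
    ro <- ringOrientation(ens, 1:6, 7:12)
    expect_equal(ro$distanceA, 3.5, tolerance = 1e-9)
    expect_equal(ro$normalAngleDeg, 0, tolerance = 1e-6)
    expect_equal(ro$class, "face-on")

    ## rotate the second ring by a known 35 degrees about x through its centre
    th <- 35 * pi / 180
    rot <- matrix(c(1, 0, 0, 0, cos(th), sin(th), 0, -sin(th), cos(th)), 3, 3)
    tilted <- sweep(hex %*% t(rot), 2, c(0, 0, 3.5), "+")
    ens2 <- ensembleFromFrames(list(rbind(hex, tilted)))
    expect_equal(ringOrientation(ens2, 1:6, 7:12)$normalAngleDeg, 35,
                 tolerance = 1e-6)

    ## perpendicular rings
    perp <- sweep(hex %*% diag(3)[c(3, 2, 1), ], 2, c(5, 0, 0), "+")
    ens3 <- ensembleFromFrames(list(rbind(hex, perp)))
    ro3 <- ringOrientation(ens3, 1:6, 7:12)
    expect_equal(ro3$normalAngleDeg, 90, tolerance = 1e-6)
    expect_equal(ro3$class, "orthogonal")
})

test_that("site metrics are invariant under rigid motion of the snapshot", {
    set.seed(21)
    pocket <- makePocketSnapshot(tau2Deg = 60)
    at <- atomTable(pocket)
    labs <- list(aW149 = which(at$chain == "A" & at$resno == 149),
                 aY198 = which(at$chain == "A" & at$resno == 198),
                 aY190 = which(at$chain == "A" & at$resno == 190),
                 aY93 = which(at$chain == "A" & at$resno == 93),
                 W55 = which(at$chain == "G" & at$resno == 55))
    lig <- which(at$chain == "L")
    m <- frameCoords(pocket)
    cents <- t(vapply(labs, function(i) colMeans(m[i, ]), numeric(3)))
    v0 <- pocketVolume(cents)
    d0 <- dihedralAngle(m[lig[1], ], m[lig[2], ], m[lig[3], ], m[lig[4], ])
    ro0 <- ringOrientation(pocket, labs$aW149, labs$W55)
    for (i in 1:20) {
        mo <- randomRigidMotion()
        m2 <- applyRigid(m, mo)
        ens2 <- ensembleFromFrames(list(m2))
        c2 <- t(vapply(labs, function(j) colMeans(m2[j, ]), numeric(3)))
        expect_equal(pocketVolume(c2), v0, tolerance = 1e-9)
        expect_equal(dihedralAngle(m2[lig[1], ], m2[lig[2], ],
                                   m2[lig[3], ], m2[lig[4], ]), d0,
                     tolerance = 1e-6)
        ro2 <- ringOrientation(ens2, labs$aW149, labs$W55)
        expect_equal(ro2$distanceA, ro0$distanceA, tolerance = 1e-9)
        expect_equal(ro2$normalAngleDeg, ro0$normalAngleDeg,
                     tolerance = 1e-6)
    }
})
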