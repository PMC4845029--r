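## Structural metrics of the agonist-binding site: aromatic-ring centroids,
## the two-tetrahedron pocket volume, beta-strand axes and hairpin twist/tilt,
## torsions and the tau2 basin split, hydrogen-bond detection and occupancy,
## and ring-ring orientation.

#' Centroid of a set of atoms
#'
#' Unweighted mean of the coordinates of the atoms in `selection` (typically
#' the ring atoms of an aromatic side chain) in one snapshot.
#'
#' @param ensemble an [Ensemble-class].
#' @param selection an [AtomSelection-class] or integer indices.
#' @param frame frame index.
#' @return Numeric length-3 coordinate (Angstrom).
#' @export
ringCentroid <- function(ensemble, selection, frame = 1L) {
    idx <- .asIndices(selection)
    if (any(idx > nAtoms(ensemble)))
        stop("structural error: selection refers to atoms absent from the ",
             "snapshot")
    colMeans(frameCoords(ensemble, frame)[idx, , drop = FALSE])
}

.asIndices <- function(selection) {
    idx <- if (is(selection, "AtomSelection")) selectionIndices(selection)
           else as.integer(selection)
    if (!length(idx)) stop("structural error: empty selection")
    idx
}

#' Binding-pocket volume from five ring centroids
#'
#' The pocket is the union of two adjoining tetrahedra built on the five
#' aromatic-ring centroids; the two 4-point sets must share exactly three
#' points (the common face). Each tetrahedron volume is the three-simplex
#' determinant `|det(b-a, c-a, d-a)|/6`.
#'
#' @param centroids numeric 5 x 3 matrix with rownames labelling the rings.
#' @param decomposition list of two character vectors of 4 labels each,
#'   covering all five rownames and sharing exactly 3. The default is the
#'   package's convention (see the methods vignette): triad + principal-pair
#'   tetrahedra sharing the aW149/aY93/aY198 face.
#' @return Volume in cubic Angstrom.
#' @export
pocketVolume <- function(centroids,
                         decomposition = list(
                             c("aW149", "aY198", "aY190", "aY93"),
                             c("aW149", "aY93", "W55", "aY198"))) {
    if (is.null(rownames(centroids)) || nrow(centroids) != 5L)
        stop("usage error: centroids must be a 5 x 3 matrix with rownames")
    if (length(decomposition) != 2L ||
        any(lengths(decomposition) != 4L))
        stop("usage error: decomposition must be two 4-label sets")
    labs <- unique(unlist(decomposition))
    if (!setequal(labs, rownames(centroids)))
        stop("usage error: decomposition must cover all five centroids")
    if (length(intersect(decomposition[[1]], decomposition[[2]])) != 3L)
        stop("usage error: the two tetrahedra must share exactly 3 points")
    sum(vapply(decomposition, function(tet)
        .simplexVolume(centroids[tet, , drop = FALSE]), numeric(1)))
}

.simplexVolume <- function(p) {
    abs(det(rbind(p[2, ] - p[1, ], p[3, ] - p[1, ], p[4, ] - p[1, ]))) / 6
}

#' Central axis of a beta strand
#'
#' Least-squares line through ordered backbone coordinates, computed as the
#' dominant right-singular vector of the mean-centred coordinates. The sign is
#' fixed so the axis points from the first towards the last residue.
#'
#' @param coords n x 3 matrix of ordered backbone coordinates (n >= 3).
#' @return Unit length-3 vector.
#' @export
strandAxis <- function(coords) {
    coords <- as.matrix(coords)
    if (nrow(coords) < 3L)
        stop("usage error: need at least 3 backbone points")
    centred <- sweep(coords, 2, colMeans(coords))
    if (all(abs(centred) < 1e-12))
        stop("degenerate geometry: all points identical")
    v <- svd(centred)$v[, 1]
    span <- coords[nrow(coords), ] - coords[1, ]
    if (sum(v * span) < 0) v <- -v
    v / sqrt(sum(v^2))
}

#' Hairpin twist angle between two strand axes
#'
#' Angle between the central axial vectors of the two hairpin strands, folded
#' to `[0, 90]` degrees via `acos(|dot|)` — the strands are antiparallel, so
#' only the magnitude of the inter-axis angle is meaningful.
#'
#' @param axis1,axis2 length-3 vectors (need not be normalized).
#' @return Angle in degrees in `[0, 90]`.
#' @export
hairpinTwist <- function(axis1, axis2) {
    .checkNonzero(axis1); .checkNonzero(axis2)
    d <- abs(sum(axis1 * axis2)) /
        (sqrt(sum(axis1^2)) * sqrt(sum(axis2^2)))
    acos(min(1, d)) * 180 / pi
}

#' Hairpin tilt against a reference direction
#'
#' Unfolded angle in `[0, 180]` degrees between the mean hairpin axis and a
#' user-supplied reference vector. No default reference is provided: the
#' biologically meaningful frame (membrane normal, subunit axis, ...) is the
#' caller's choice.
#'
#' @param hairpinAxis,reference length-3 vectors.
#' @return Angle in degrees.
#' @export
hairpinTilt <- function(hairpinAxis, reference) {
    .checkNonzero(hairpinAxis); .checkNonzero(reference)
    d <- sum(hairpinAxis * reference) /
        (sqrt(sum(hairpinAxis^2)) * sqrt(sum(reference^2)))
    acos(max(-1, min(1, d))) * 180 / pi
}

.checkNonzero <- function(v) {
    if (length(v) != 3L || sum(v^2) < 1e-24)
        stop("usage error: zero or malformed direction vector")
    invisible(v)
}

#' Signed torsion angle
#'
#' IUPAC torsion over four points: 0 degrees for cis (eclipsed), sign by the
#' right-hand rule about the `p2 -> p3` bond; range `(-180, 180]`.
#'
#' @param p1,p2,p3,p4 length-3 coordinates.
#' @return Angle in degrees.
#' @export
dihedralAngle <- function(p1, p2, p3, p4) {
    b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
    if (sum(b2^2) < 1e-20)
        stop("degenerate geometry: central bond has zero length")
    n1 <- .cross3(b1, b2); n2 <- .cross3(b2, b3)
    if (sum(n1^2) < 1e-20 || sum(n2^2) < 1e-20)
        stop("degenerate geometry: collinear points define no torsion plane")
    m1 <- .cross3(n1, b2 / sqrt(sum(b2^2)))
    ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
    if (ang <= -180) ang <- ang + 360
    ang
}

.cross3 <- function(a, b) {
    c(a[2] * b[3] - a[3] * b[2],
      a[3] * b[1] - a[1] * b[3],
      a[1] * b[2] - a[2] * b[1])
}

#' Fractions of torsions in the two tau2 basins
#'
#' The agonist N-C-C-O torsion (tau2) is bimodal at -60 and +60 degrees.
#' Angles are assigned to a basin by sign when within `halfWidthDeg` of the
#' basin centre; angles outside both basins are excluded, so the two fractions
#' sum to at most 1.
#'
#' @param anglesDeg numeric vector of torsions in degrees.
#' @param halfWidthDeg basin half-width around the -60/+60 centres.
#' @return Named numeric: `f_minus60`, `f_plus60`.
#' @export
tau2BasinFractions <- function(anglesDeg, halfWidthDeg = 60) {
    if (!length(anglesDeg)) stop("usage error: empty angle list")
    inMinus <- abs(anglesDeg - (-60)) <= halfWidthDeg & anglesDeg < 0
    inPlus <- abs(anglesDeg - 60) <= halfWidthDeg & anglesDeg > 0
    c(f_minus60 = mean(inMinus), f_plus60 = mean(inPlus))
}

#' Hydrogen-bond criterion
#'
#' A hydrogen bond is present when the donor-acceptor distance is below
#' `distMaxA` (default 3.5 Angstrom) and the angle at the donor between the
#' donor-hydrogen and donor-acceptor directions is at most `angleMaxDeg`
#' (default 30 degrees). For heavy-atom-only structures a distance-only
#' fallback can be enabled with `requireHydrogen = FALSE` (callers should
#' label such occupancies accordingly).
#'
#' @param donor,hydrogen,acceptor length-3 coordinates; `hydrogen` may be
#'   `NULL` when `requireHydrogen = FALSE`.
#' @param distMaxA donor-acceptor distance bound (exclusive), Angstrom.
#' @param angleMaxDeg H-donor-acceptor angle bound (inclusive), degrees.
#' @param requireHydrogen apply the angular criterion (default).
#' @return Logical.
#' @export
detectHBond <- function(donor, hydrogen, acceptor, distMaxA = 3.5,
                        angleMaxDeg = 30, requireHydrogen = TRUE) {
    da <- acceptor - donor
    d <- sqrt(sum(da^2))
    if (d < 1e-9) stop("degenerate geometry: donor and acceptor coincide")
    if (d >= distMaxA) return(FALSE)
    if (!requireHydrogen) return(TRUE)
    if (is.null(hydrogen))
        stop("usage error: hydrogen coordinates required unless ",
             "requireHydrogen = FALSE")
    dh <- hydrogen - donor
    if (sum(dh^2) < 1e-18)
        stop("degenerate geometry: donor and hydrogen coincide")
    cosang <- sum(dh * da) / (sqrt(sum(dh^2)) * d)
    ang <- acos(max(-1, min(1, cosang))) * 180 / pi
    ang <= angleMaxDeg
}

#' Hydrogen-bond occupancy over an ensemble
#'
#' Fraction of snapshots in which [detectHBond()] holds for the given
#' donor/hydrogen/acceptor atoms.
#'
#' @param ensemble an [Ensemble-class].
#' @param donor,hydrogen,acceptor single atom indices (or length-1
#'   selections); `hydrogen` may be `NULL` with `requireHydrogen = FALSE`.
#' @inheritParams detectHBond
#' @return Fraction in `[0, 1]`.
#' @export
hbondOccupancy <- function(ensemble, donor, hydrogen, acceptor,
                           distMaxA = 3.5, angleMaxDeg = 30,
                           requireHydrogen = TRUE) {
    d <- .asIndices(donor)[1]
    a <- .asIndices(acceptor)[1]
    h <- if (is.null(hydrogen)) NULL else .asIndices(hydrogen)[1]
    if (max(c(d, a, h)) > nAtoms(ensemble))
        stop("structural error: H-bond atoms absent from the ensemble")
    hits <- vapply(seq_len(nFrames(ensemble)), function(i) {
        m <- frameCoords(ensemble, i)
        detectHBond(m[d, ], if (is.null(h)) NULL else m[h, ], m[a, ],
                    distMaxA, angleMaxDeg, requireHydrogen)
    }, logical(1))
    mean(hits)
}

#' Best-fit plane normal of a ring
#'
#' Unit normal of the least-squares plane through the ring atoms (the
#' right-singular vector of the smallest singular value of the mean-centred
#' coordinates).
#'
#' @param coords n x 3 matrix of ring-atom coordinates (n >= 3).
#' @return Unit length-3 vector (sign arbitrary).
#' @export
ringPlaneNormal <- function(coords) {
    coords <- as.matrix(coords)
    if (nrow(coords) < 3L) stop("degenerate geometry: need >= 3 ring atoms")
    centred <- sweep(coords, 2, colMeans(coords))
    s <- svd(centred)
    if (s$d[2] < 1e-9)
        stop("degenerate geometry: ring atoms are collinear")
    s$v[, 3]
}

#' Relative orientation of two rings
#'
#' Centroid-centroid distance and the angle between the best-fit plane
#' normals, folded to `[0, 90]` degrees (0 = face-on stacking, 90 =
#' orthogonal, edge-on). A qualitative class is attached using configurable
#' thresholds.
#'
#' @param ensemble an [Ensemble-class].
#' @param ring1,ring2 selections of the two rings' atoms.
#' @param frame frame index.
#' @param faceOnMaxDeg,orthogonalMinDeg classification thresholds (degrees).
#' @return List with `distanceA`, `normalAngleDeg`, `class`
#'   (`"face-on"`, `"orthogonal"` or `"intermediate"`).
#' @export
ringOrientation <- function(ensemble, ring1, ring2, frame = 1L,
                            faceOnMaxDeg = 30, orthogonalMinDeg = 60) {
    m <- frameCoords(ensemble, frame)
    i1 <- .asIndices(ring1); i2 <- .asIndices(ring2)
    c1 <- colMeans(m[i1, , drop = FALSE])
    c2 <- colMeans(m[i2, , drop = FALSE])
    n1 <- ringPlaneNormal(m[i1, , drop = FALSE])
    n2 <- ringPlaneNormal(m[i2, , drop = FALSE])
    ang <- acos(min(1, abs(sum(n1 * n2)))) * 180 / pi
    cls <- if (ang <= faceOnMaxDeg) "face-on"
           else if (ang >= orthogonalMinDeg) "orthogonal"
           else "intermediate"
    list(distanceA = sqrt(sum((c2 - c1)^2)), normalAngleDeg = ang,
         class = cls)
}
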