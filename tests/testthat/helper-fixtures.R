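## Shared fixture builders. All randomness is seeded inside the builders.

## random rigid motion: rotation from QR of a Gaussian matrix + translation
randomRigidMotion <- function() {
    qr <- qr(matrix(rnorm(9), 3, 3))
    rot <- qr.Q(qr)
    if (det(rot) < 0) rot[, 1] <- -rot[, 1]
    list(rot = rot, shift = rnorm(3, sd = 10))
}

applyRigid <- function(coords, motion) {
    sweep(coords %*% motion$rot, 2, motion$shift, "+")
}

## regular hexagon of given radius in the xy-plane
hexagonXY <- function(radius = 1.39, centre = c(0, 0, 0)) {
    ang <- 2 * pi * (0:5) / 6
    sweep(cbind(radius * cos(ang), radius * sin(ang), 0), 2, centre, "+")
}

## independent tetrahedron volume via the Cayley-Menger determinant
cayleyMengerVolume <- function(p) {
    d2 <- as.matrix(dist(p))^2
    cm <- rbind(c(0, 1, 1, 1, 1), cbind(1, d2))
    sqrt(max(det(cm) / 288, 0))
}

## tiny ensemble: nAtoms atoms, frames supplied as list of n x 3 matrices
ensembleFromFrames <- function(frames, resno = NULL, name = "CA",
                               chain = "A") {
    n <- nrow(frames[[1]])
    if (is.null(resno)) resno <- seq_len(n)
    atoms <- data.frame(serial = seq_len(n), name = rep_len(name, n),
                        resname = "GLY", chain = rep_len(chain, n),
                        resno = resno, element = "C",
                        stringsAsFactors = FALSE)
    arr <- array(NA_real_, dim = c(n, 3, length(frames)))
    for (i in seq_along(frames)) arr[, , i] <- frames[[i]]
    Ensemble(atoms, arr)
}
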