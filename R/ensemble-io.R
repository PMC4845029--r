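#' Read a coordinate ensemble
#'
#' Reads a multi-model PDB (MODEL/ENDMDL delimited; the canonical format) or a
#' multi-frame XYZ file into an [Ensemble-class]. The atom table is taken from
#' the first frame; every subsequent frame must contain the same number of
#' atoms.
#'
#' @param path file path.
#' @param format `"pdb"` (multi-model) or `"xyz"`.
#' @param label construct label attached to the ensemble; defaults to the
#'   file name.
#' @param stridePs time between frames (ps) when the file carries no times.
#' @return An [Ensemble-class].
#' @export
readEnsemble <- function(path, format = c("pdb", "xyz"), label = NULL,
                         stridePs = 1) {
    format <- match.arg(format)
    if (!file.exists(path)) stop("file not found: ", path)
    if (is.null(label)) label <- sub("\\.[^.]*$", "", basename(path))
    switch(format,
           pdb = .readPdbEnsemble(path, label, stridePs),
           xyz = .readXyzEnsemble(path, label, stridePs))
}

## Frame-wise atom-count check before handing the file to bio3d, so a
## mismatch is reported with the offending frame number.
.checkPdbFrames <- function(lines) {
    starts <- grep("^MODEL", lines)
    if (!length(starts)) return(invisible(1L))
    ends <- grep("^ENDMDL", lines)
    if (length(ends) < length(starts))
        stop("structural error: unterminated MODEL block")
    counts <- mapply(function(s, e)
        sum(grepl("^(ATOM|HETATM)", lines[s:e])), starts, ends)
    if (length(unique(counts)) > 1L) {
        bad <- which(counts != counts[1])[1]
        stop("structural error: frame ", bad, " has ", counts[bad],
             " atoms but frame 1 has ", counts[1])
    }
    invisible(length(starts))
}

.readPdbEnsemble <- function(path, label, stridePs) {
    .checkPdbFrames(readLines(path, warn = FALSE))
    pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    a <- pdb$atom
    atoms <- data.frame(serial = a$eleno, name = a$elety, resname = a$resid,
                        chain = ifelse(is.na(a$chain), "A", a$chain),
                        resno = a$resno,
                        element = ifelse(is.na(a$elesy) | a$elesy == "",
                                         substr(trimws(a$elety), 1, 1),
                                         a$elesy),
                        stringsAsFactors = FALSE)
    xyz <- pdb$xyz
    if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
    nfr <- nrow(xyz)
    nat <- ncol(xyz) / 3
    coords <- array(NA_real_, dim = c(nat, 3, nfr))
    for (i in seq_len(nfr))
        coords[, , i] <- matrix(xyz[i, ], ncol = 3, byrow = TRUE)
    Ensemble(atoms, coords, timePs = stridePs * (seq_len(nfr) - 1L),
             label = label)
}

## Plain XYZ: per frame a line with the atom count, a comment line
## ("t= <ps>" is honoured if present), then "element x y z" records.
## No installed R package reads this dialect, hence the small parser here.
.readXyzEnsemble <- function(path, label, stridePs) {
    lines <- readLines(path, warn = FALSE)
    pos <- 1L
    frames <- list(); times <- numeric()
    while (pos <= length(lines) && nzchar(trimws(lines[pos]))) {
        nat <- suppressWarnings(as.integer(trimws(lines[pos])))
        if (is.na(nat)) stop("format error: bad atom count at line ", pos)
        comment <- lines[pos + 1L]
        tm <- regmatches(comment, regexec("t=\\s*([-0-9.eE+]+)", comment))[[1]]
        block <- lines[pos + 1L + seq_len(nat)]
        if (anyNA(block))
            stop("structural error: frame ", length(frames) + 1L,
                 " is truncated")
        toks <- strsplit(trimws(block), "\\s+")
        if (any(lengths(toks) < 4L))
            stop("format error: malformed atom record in frame ",
                 length(frames) + 1L)
        el <- vapply(toks, `[`, character(1), 1L)
        xyz <- matrix(as.numeric(unlist(lapply(toks, `[`, 2:4))),
                      ncol = 3, byrow = TRUE)
        if (!all(is.finite(xyz)))
            stop("format error: non-numeric coordinate in frame ",
                 length(frames) + 1L)
        frames[[length(frames) + 1L]] <- list(el = el, xyz = xyz)
        times <- c(times, if (length(tm) == 2) as.numeric(tm[2]) else NA_real_)
        pos <- pos + 2L + nat
        while (pos <= length(lines) && !nzchar(trimws(lines[pos])))
            pos <- pos + 1L
    }
    if (!length(frames)) stop("format error: no records")
    nat <- nrow(frames[[1]]$xyz)
    for (i in seq_along(frames))
        if (nrow(frames[[i]]$xyz) != nat)
            stop("structural error: frame ", i, " has ",
                 nrow(frames[[i]]$xyz), " atoms but frame 1 has ", nat)
    coords <- array(NA_real_, dim = c(nat, 3, length(frames)))
    for (i in seq_along(frames)) coords[, , i] <- frames[[i]]$xyz
    if (anyNA(times)) times <- stridePs * (seq_along(frames) - 1L)
    atoms <- data.frame(serial = seq_len(nat), name = frames[[1]]$el,
                        resname = "UNK", chain = "A", resno = seq_len(nat),
                        element = frames[[1]]$el, stringsAsFactors = FALSE)
    Ensemble(atoms, coords, timePs = times, label = label)
}

#' Write a coordinate ensemble
#'
#' @param ensemble an [Ensemble-class].
#' @param path output file path.
#' @param format `"pdb"` or `"xyz"`.
#' @return `path`, invisibly.
#' @export
writeEnsemble <- function(ensemble, path, format = c("pdb", "xyz")) {
    format <- match.arg(format)
    a <- atomTable(ensemble)
    if (format == "pdb") {
        nfr <- nFrames(ensemble)
        xyz <- matrix(NA_real_, nrow = nfr, ncol = 3 * nAtoms(ensemble))
        for (i in seq_len(nfr))
            xyz[i, ] <- as.vector(t(frameCoords(ensemble, i)))
        bio3d::write.pdb(file = path, xyz = xyz, eleno = a$serial,
                         elety = a$name, resid = a$resname, chain = a$chain,
                         resno = a$resno, elesy = a$element)
    } else {
        con <- file(path, "w"); on.exit(close(con))
        for (i in seq_len(nFrames(ensemble))) {
            m <- frameCoords(ensemble, i)
            writeLines(c(as.character(nAtoms(ensemble)),
                         sprintf("t= %.6g %s", timesPs(ensemble)[i],
                                 ensembleLabel(ensemble)),
                         sprintf("%-3s %12.6f %12.6f %12.6f",
                                 a$element, m[, 1], m[, 2], m[, 3])), con)
        }
    }
    invisible(path)
}

#' Select atoms by expression
#'
#' Evaluates a conjunction of clauses over the atom table. Clauses are joined
#' by `and` and take the forms `chain <id...>`, `resid <n>`, `resid <a>-<b>`,
#' `resid <n1> <n2> ...`, `name <name...>` and `resname <name...>`.
#'
#' @param ensemble an [Ensemble-class].
#' @param expression selection string, e.g. `"chain G and resid 166-183"`.
#' @return An [AtomSelection-class]; an empty match raises a warning and
#'   returns an empty selection.
#' @export
selectAtoms <- function(ensemble, expression) {
    atoms <- atomTable(ensemble)
    keep <- rep(TRUE, nrow(atoms))
    clauses <- strsplit(expression, "\\band\\b")[[1]]
    if (!length(clauses) || !nzchar(trimws(expression)))
        stop("usage error: empty selection expression")
    for (cl in clauses) {
        toks <- strsplit(trimws(cl), "\\s+")[[1]]
        if (length(toks) < 2L)
            stop("usage error: malformed selection clause '", trimws(cl), "'")
        key <- toks[1]; vals <- toks[-1]
        keep <- keep & switch(key,
            chain = atoms$chain %in% vals,
            name = atoms$name %in% vals,
            resname = atoms$resname %in% vals,
            resid = atoms$resno %in% .parseResidValues(vals),
            stop("usage error: unknown selection keyword '", key, "'"))
    }
    idx <- which(keep)
    if (!length(idx))
        warning("selection '", expression, "' matched no atoms")
    new("AtomSelection", expression = expression, indices = as.integer(idx))
}

.parseResidValues <- function(vals) {
    vals <- unlist(strsplit(vals, ","))
    vals <- vals[nzchar(vals)]
    out <- integer()
    for (v in vals) {
        if (grepl("^-?[0-9]+--?[0-9]+$", v)) {
            ab <- as.integer(strsplit(v, "(?<=[0-9])-", perl = TRUE)[[1]])
            out <- c(out, seq(ab[1], ab[2]))
        } else {
            n <- suppressWarnings(as.integer(v))
            if (is.na(n))
                stop("usage error: bad residue token '", v, "'")
            out <- c(out, n)
        }
    }
    out
}

#' Restrict an ensemble to a selection
#'
#' @param ensemble an [Ensemble-class].
#' @param selection an [AtomSelection-class] or integer atom indices.
#' @return An [Ensemble-class] containing only the selected atoms.
#' @export
subsetEnsemble <- function(ensemble, selection) {
    idx <- if (is(selection, "AtomSelection")) selectionIndices(selection)
           else as.integer(selection)
    Ensemble(atomTable(ensemble)[idx, , drop = FALSE],
             coordArray(ensemble)[idx, , , drop = FALSE],
             timePs = timesPs(ensemble), label = ensembleLabel(ensemble))
}

#' Read a per-snapshot energy-component table
#'
#' CSV dialect: columns `snapshot_index`, `time_ps`, `e_vdw_kcal`,
#' `e_elec_kcal` (kcal/mol). Row order is preserved.
#'
#' @param path CSV file path.
#' @param construct,ligand labels attached to the series.
#' @return An [EnergyComponentSeries-class].
#' @export
readEnergyTable <- function(path, construct = "WT", ligand = "ACh") {
    df <- .readCsvChecked(path, c("snapshot_index", "time_ps",
                                  "e_vdw_kcal", "e_elec_kcal"))
    for (col in c("time_ps", "e_vdw_kcal", "e_elec_kcal")) {
        v <- suppressWarnings(as.numeric(df[[col]]))
        if (anyNA(v))
            stop("format error: non-numeric value in column '", col,
                 "' at row ", which(is.na(v))[1])
        df[[col]] <- v
    }
    EnergyComponentSeries(construct, df$e_vdw_kcal, df$e_elec_kcal,
                          ligand = ligand, timePs = df$time_ps)
}

#' @rdname readEnergyTable
#' @param series an [EnergyComponentSeries-class] to write.
#' @export
writeEnergyTable <- function(series, path) {
    n <- length(series@eVdw)
    tp <- if (length(series@timePs)) series@timePs else seq_len(n) - 1
    utils::write.csv(data.frame(snapshot_index = seq_len(n), time_ps = tp,
                                e_vdw_kcal = series@eVdw,
                                e_elec_kcal = series@eElec),
                     path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Read a dwell-time table
#'
#' CSV dialect: columns `cluster_id`, `state` (`open`/`closed`), `duration_s`,
#' `conc_M`, `voltage_mV`, `construct`. Rows are split by
#' (construct, conc_M, voltage_mV) combination into one dataset each.
#'
#' @param path CSV file path.
#' @return A list of [DwellDataset-class] objects (one per metadata
#'   combination, in order of first appearance).
#' @export
readDwellTable <- function(path) {
    df <- .readCsvChecked(path, c("cluster_id", "state", "duration_s",
                                  "conc_M", "voltage_mV", "construct"))
    for (col in c("duration_s", "conc_M", "voltage_mV")) {
        v <- suppressWarnings(as.numeric(df[[col]]))
        if (anyNA(v))
            stop("format error: non-numeric value in column '", col,
                 "' at row ", which(is.na(v))[1])
        df[[col]] <- v
    }
    bad <- which(!df$state %in% c("open", "closed"))
    if (length(bad))
        stop("format error: bad state '", df$state[bad[1]], "' at row ",
             bad[1])
    ## alternation check with file row numbers
    key <- paste(df$construct, df$conc_M, df$voltage_mV, df$cluster_id)
    prev <- c(NA, key[-length(key)])
    same <- which(key == prev & df$state == c(NA, df$state[-nrow(df)]))
    if (length(same))
        stop("format error: consecutive '", df$state[same[1]],
             "' states at row ", same[1])
    grp <- paste(df$construct, df$conc_M, df$voltage_mV, sep = "\r")
    lapply(split(df, factor(grp, levels = unique(grp))), function(g)
        DwellDataset(g[, c("cluster_id", "state", "duration_s")],
                     concM = g$conc_M[1], voltageMv = g$voltage_mV[1],
                     construct = g$construct[1]))
}

#' @rdname readDwellTable
#' @param dataset a [DwellDataset-class] (or list of them) to write.
#' @export
writeDwellTable <- function(dataset, path) {
    if (is(dataset, "DwellDataset")) dataset <- list(dataset)
    rows <- do.call(rbind, lapply(dataset, function(d)
        cbind(d@intervals, conc_M = d@concM, voltage_mV = d@voltageMv,
              construct = d@construct)))
    utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

.readCsvChecked <- function(path, required) {
    if (!file.exists(path)) stop("file not found: ", path)
    df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE,
                                   colClasses = "character"),
                   error = function(e) stop("format error: no records"))
    if (nrow(df) == 0L) stop("format error: no records")
    missing <- setdiff(required, names(df))
    if (length(missing))
        stop("format error: missing column(s): ",
             paste(missing, collapse = ", "))
    df
}
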