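# Structure container and PDB IO (bio3d-backed), rigid superposition and
# per-residue conservation tools.

.aa_three_to_one <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V")
.aa_one_to_three <- stats::setNames(names(.aa_three_to_one),
                                    unname(.aa_three_to_one))

#' Construct a structure model
#'
#' A light container over an atom table (PDB-style records) used by the
#' superposition, conservation and pocket-volume tools.
#'
#' @param atoms Data frame with columns `type`, `serial`, `atom` (atom name),
#'   `resname`, `chain`, `resno`, `x`, `y`, `z`, `occ`, `b`, `element`.
#'   Missing metadata columns are filled with defaults.
#' @param label Model label (used to match structures to alignment rows).
#' @param remarks Character vector of provenance notes written as REMARK
#'   lines on output.
#' @return Object of class `structure_model`.
#' @export
structure_model <- function(atoms, label = "model", remarks = character(0)) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  need <- c("x", "y", "z")
  if (!all(need %in% names(atoms))) stop("atoms need x, y, z columns")
  if (nrow(atoms) == 0) stop("structure has no atoms")
  if (!all(is.finite(as.matrix(atoms[, need]))))
    stop("non-finite coordinates in structure")
  defaults <- list(type = "ATOM", serial = seq_len(nrow(atoms)), atom = "CA",
                   resname = "ALA", chain = "A", resno = seq_len(nrow(atoms)),
                   occ = 1, b = 0, element = "C")
  for (nm in names(defaults)) {
    if (is.null(atoms[[nm]])) atoms[[nm]] <- defaults[[nm]]
  }
  structure(list(atoms = atoms, label = label, remarks = remarks),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("structure_model '%s': %d atoms, %d residues\n", x$label,
              nrow(x$atoms),
              nrow(unique(x$atoms[, c("chain", "resno")]))))
  invisible(x)
}

#' Read a PDB structure
#'
#' Parses ATOM/HETATM records, resolves alternate locations to the highest
#' occupancy, and excludes waters by default.
#'
#' @param path PDB file path.
#' @param label Model label (default: file name without extension).
#' @param keep_waters Keep HOH/WAT residues (default `FALSE`).
#' @return A [structure_model].
#' @export
read_structure <- function(path, label = NULL, keep_waters = FALSE) {
  if (is.null(label)) label <- tools::file_path_sans_ext(basename(path))
  pdb <- bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)
  at <- pdb$atom
  if (nrow(at) == 0) stop("no ATOM records in ", path)
  if (!keep_waters) at <- at[!at$resid %in% c("HOH", "WAT", "DOD"), ]
  if (nrow(at) == 0) stop("no non-water atoms in ", path)
  # altloc resolution: within each (chain, resno, insert, atom name) keep the
  # highest-occupancy record (ties: first)
  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "|")
  ord <- order(key, -replace(at$o, is.na(at$o), 1))
  at <- at[ord, ]
  at <- at[!duplicated(paste(at$chain, at$resno, at$insert, at$elety,
                             sep = "|")), ]
  at <- at[order(at$eleno), ]
  elem <- at$elesy
  elem[is.na(elem) | elem == ""] <- substr(trimws(at$elety[is.na(elem) | elem == ""]), 1, 1)
  structure_model(data.frame(
    type = at$type, serial = at$eleno, atom = at$elety, resname = at$resid,
    chain = at$chain, resno = at$resno, x = at$x, y = at$y, z = at$z,
    occ = replace(at$o, is.na(at$o), 1), b = replace(at$b, is.na(at$b), 0),
    element = elem, stringsAsFactors = FALSE), label = label)
}

#' Write a structure model to PDB
#'
#' B-factors are written with two decimals (PDB fixed format); any remarks on
#' the model are emitted as REMARK header lines.
#'
#' @param x A [structure_model].
#' @param path Output PDB path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(x, path) {
  stopifnot(inherits(x, "structure_model"))
  a <- x$atoms
  bio3d::write.pdb(file = path,
                   type = a$type, eleno = a$serial, elety = a$atom,
                   resid = a$resname, chain = ifelse(is.na(a$chain), "A", a$chain),
                   resno = a$resno,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   o = a$occ, b = round(a$b, 2), elesy = a$element)
  if (length(x$remarks)) {
    body <- readLines(path, warn = FALSE)
    writeLines(c(sprintf("REMARK   3 %s", x$remarks), body), path)
  }
  invisible(path)
}

# n x 3 Calpha coordinate matrix of a structure (one per residue, file order)
calpha_coords <- function(x) {
  stopifnot(inherits(x, "structure_model"))
  ca <- x$atoms[trimws(x$atoms$atom) == "CA" & x$atoms$type == "ATOM", ]
  as.matrix(ca[, c("x", "y", "z")])
}

#' Kabsch least-squares superposition
#'
#' Finds the proper rotation and translation minimising the RMSD of paired
#' coordinate sets; `B` is moved onto `A` (`B %*% rotation + translation`).
#'
#' @param A,B Numeric n x 3 matrices of paired coordinates, n >= 3.
#' @return Object of class `superposition`: `rotation` (3 x 3, det +1),
#'   `translation`, `rmsd`, `n_atoms_used`, `cycles_run`, `used` (indices of
#'   the pairs entering the fit).
#' @export
kabsch_superpose <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (!all(dim(A) == dim(B))) stop("coordinate sets must have equal dimensions")
  if (nrow(A) < 3) stop("superposition needs at least 3 paired atoms")
  ca <- colMeans(A); cb <- colMeans(B)
  Ac <- sweep(A, 2, ca); Bc <- sweep(B, 2, cb)
  if (qr(Ac)$rank < 2 || qr(Bc)$rank < 2)
    stop("degenerate (collinear) coordinate set")
  H <- t(Bc) %*% Ac
  s <- svd(H)
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  dev <- sqrt(rowSums((Bc %*% R - Ac)^2))
  structure(list(rotation = R, translation = as.numeric(ca - cb %*% R),
                 rmsd = sqrt(mean(dev^2)), n_atoms_used = nrow(A),
                 cycles_run = 0L, used = seq_len(nrow(A)),
                 deviations = dev),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("superposition: rmsd = %.4f A over %d atoms (%d refinement cycles)\n",
              x$rmsd, x$n_atoms_used, x$cycles_run))
  invisible(x)
}

#' Apply a superposition to coordinates
#' @param sp A `superposition` result.
#' @param X n x 3 coordinate matrix (the `B` frame).
#' @return Transformed n x 3 matrix.
#' @export
apply_superposition <- function(sp, X) {
  sweep(as.matrix(X) %*% sp$rotation, 2, sp$translation, "+")
}

#' Outlier-refined superposition
#'
#' Iterates the Kabsch fit, at each cycle dropping pairs whose deviation
#' exceeds `mean + cutoff_sigma * sd` of the current deviations, and
#' refitting on the remainder (the convention behind align-style RMSDs with
#' outlier rejection). The refined RMSD is never larger than the plain one.
#'
#' @param A,B Paired n x 3 coordinate matrices, n >= 3.
#' @param cycles Maximum refinement cycles (default 5).
#' @param cutoff_sigma Rejection threshold in standard deviations (default 2).
#' @return A `superposition` (see [kabsch_superpose]) with `n_atoms_used`,
#'   `cycles_run` and the retained pair indices in `used`.
#' @export
refined_superpose <- function(A, B, cycles = 5, cutoff_sigma = 2.0) {
  A <- as.matrix(A); B <- as.matrix(B)
  keep <- seq_len(nrow(A))
  fit <- kabsch_superpose(A, B)
  cycles_run <- 0L
  for (cy in seq_len(cycles)) {
    dev <- fit$deviations
    thr <- mean(dev) + cutoff_sigma * stats::sd(dev)
    # the 1e-8 A floor keeps numerically-zero deviation profiles intact
    drop <- which(dev > thr & dev > 1e-8 & is.finite(thr))
    if (length(drop) == 0) break
    if (length(keep) - length(drop) < 3)
      stop("outlier rejection left fewer than 3 atom pairs")
    keep <- keep[-drop]
    fit <- kabsch_superpose(A[keep, , drop = FALSE], B[keep, , drop = FALSE])
    cycles_run <- cy
  }
  fit$n_atoms_used <- length(keep)
  fit$cycles_run <- cycles_run
  fit$used <- keep
  fit
}

#' Pair Calpha coordinates across structures via a protein alignment
#'
#' Each structure's Calpha sequence must match its (ungapped) alignment row;
#' only columns with a residue present in every structure are paired. The
#' column-to-residue-number map is returned in both directions.
#'
#' @param paln A [protein_alignment] whose taxa include every model label.
#' @param structures List of [structure_model]s (labels must match rows).
#' @param max_mismatch Tolerated sequence/structure mismatches (default 0).
#' @return List: `coords` (named list of n_paired x 3 Calpha matrices),
#'   `map` (data frame: `column`, then one residue-number column per model),
#'   `columns` (paired alignment columns).
#' @export
pair_by_alignment <- function(paln, structures, max_mismatch = 0) {
  stopifnot(inherits(paln, "protein_alignment"))
  labels <- vapply(structures, function(s) s$label, character(1))
  if (!all(labels %in% paln$taxa))
    stop("structure labels missing from alignment: ",
         paste(setdiff(labels, paln$taxa), collapse = ", "))
  info <- lapply(structures, function(st) {
    ca <- st$atoms[trimws(st$atoms$atom) == "CA" & st$atoms$type == "ATOM", ]
    seq1 <- unname(.aa_three_to_one[ca$resname])
    seq1[is.na(seq1)] <- "X"
    row <- paln$residues[match(st$label, paln$taxa), ]
    cols <- which(row != "-")
    if (length(cols) != nrow(ca))
      stop(sprintf("structure '%s' has %d residues but alignment row has %d",
                   st$label, nrow(ca), length(cols)))
    mism <- which(seq1 != row[cols])
    if (length(mism) > max_mismatch)
      stop(sprintf(
        "sequence/structure mismatch for '%s' at alignment column %d (structure %s, alignment %s)",
        st$label, cols[mism[1]], seq1[mism[1]], row[cols[mism[1]]]))
    list(cols = cols, resno = ca$resno, chain = ca$chain,
         xyz = as.matrix(ca[, c("x", "y", "z")]))
  })
  paired_cols <- Reduce(intersect, lapply(info, `[[`, "cols"))
  paired_cols <- sort(paired_cols)
  if (length(paired_cols) == 0) stop("no alignment column has a residue in every structure")
  coords <- list()
  map <- data.frame(column = paired_cols)
  for (i in seq_along(structures)) {
    idx <- match(paired_cols, info[[i]]$cols)
    coords[[labels[i]]] <- info[[i]]$xyz[idx, , drop = FALSE]
    map[[paste0(labels[i], "_resno")]] <- info[[i]]$resno[idx]
  }
  list(coords = coords, map = map, columns = paired_cols)
}

#' Superpose an ensemble of paired coordinate sets onto a reference
#'
#' @param coords Named list of paired n x 3 matrices (e.g. from
#'   [pair_by_alignment]).
#' @param reference Index or name of the reference set (default first).
#' @param refined Use [refined_superpose] instead of the plain Kabsch fit.
#' @return List of transformed coordinate matrices (reference unchanged).
#' @export
superpose_ensemble <- function(coords, reference = 1, refined = FALSE) {
  ref <- coords[[reference]]
  lapply(coords, function(X) {
    if (identical(dim(X), dim(ref)) && all(X == ref)) return(X)
    sp <- if (refined) refined_superpose(ref, X) else kabsch_superpose(ref, X)
    apply_superposition(sp, X)
  })
}

#' Per-residue structural divergence across superposed models
#'
#' For each paired residue, the mean over model pairs of the Calpha-Calpha
#' distance, and a normalised conservation score mapping the least divergent
#' residue to 1 and the most divergent to 0 (all-equal profiles map to 1).
#'
#' @param coords Named list (>= 2) of superposed paired n x 3 matrices.
#' @return Data frame: `index` (paired-residue index), `divergence` (A),
#'   `conservation` in `[0, 1]`.
#' @export
per_residue_divergence <- function(coords) {
  if (length(coords) < 2) stop("need at least 2 models")
  n <- nrow(coords[[1]])
  acc <- numeric(n); npair <- 0
  for (i in seq_along(coords)) for (j in seq_along(coords)) {
    if (j <= i) next
    acc <- acc + sqrt(rowSums((coords[[i]] - coords[[j]])^2))
    npair <- npair + 1
  }
  dev <- acc / npair
  rng <- range(dev)
  cons <- if (diff(rng) < .Machine$double.eps^0.5) rep(1, n)
          else 1 - (dev - rng[1]) / (rng[2] - rng[1])
  data.frame(index = seq_len(n), divergence = dev, conservation = cons)
}

#' Paint a conservation profile into the B-factor column
#'
#' Every atom of a scored residue gets the residue score (2 decimals on
#' output); residues not covered by the profile get the sentinel 99.99.
#'
#' @param x A [structure_model].
#' @param profile Data frame with `resno` (and optionally `chain`) plus a
#'   `score` column.
#' @param path Optional output PDB path; if given the painted model is
#'   written there.
#' @return The painted [structure_model], invisibly if written.
#' @export
write_conservation_bfactor <- function(x, profile, path = NULL) {
  stopifnot(inherits(x, "structure_model"))
  if (!all(c("resno", "score") %in% names(profile)))
    stop("profile needs resno and score columns")
  key_at <- if ("chain" %in% names(profile))
    paste(x$atoms$chain, x$atoms$resno) else as.character(x$atoms$resno)
  key_pr <- if ("chain" %in% names(profile))
    paste(profile$chain, profile$resno) else as.character(profile$resno)
  idx <- match(key_at, key_pr)
  x$atoms$b <- ifelse(is.na(idx), 99.99, round(profile$score[idx], 2))
  if (!is.null(path)) {
    write_structure(x, path)
    return(invisible(x))
  }
  x
}

#' Specify a point mutation
#'
#' @param position 1-based residue number in the background structure.
#' @param from_res,to_res One-letter residue codes.
#' @param background Label of the background model.
#' @return Object of class `mutation_spec`.
#' @export
mutation_spec <- function(position, from_res, to_res, background = "model") {
  stopifnot(from_res %in% names(.aa_one_to_three),
            to_res %in% names(.aa_one_to_three))
  structure(list(position = as.integer(position), from_res = from_res,
                 to_res = to_res, background = background),
            class = "mutation_spec")
}

#' Apply a stub point mutation to a structure
#'
#' Renames the residue and truncates its side chain beyond the Cbeta atom (a
#' stub mutation; no rotamer building is attempted, and mutated structures
#' destined for docking must be rebuilt with a side-chain modelling tool).
#' A provenance REMARK is attached to the model. Mutating to glycine also
#' removes the Cbeta.
#'
#' @param x A [structure_model].
#' @param m A [mutation_spec]; `from_res` must match the residue present at
#'   `position`.
#' @return The mutated [structure_model].
#' @export
apply_point_mutation <- function(x, m) {
  stopifnot(inherits(x, "structure_model"), inherits(m, "mutation_spec"))
  sel <- x$atoms$resno == m$position & x$atoms$type == "ATOM"
  if (!any(sel)) stop("no residue numbered ", m$position, " in structure")
  obs3 <- unique(x$atoms$resname[sel])[1]
  obs1 <- unname(.aa_three_to_one[obs3])
  if (is.na(obs1) || obs1 != m$from_res)
    stop(sprintf("residue %d is %s (%s), not %s", m$position, obs3,
                 ifelse(is.na(obs1), "?", obs1), m$from_res))
  keep_names <- c("N", "CA", "C", "O", "OXT")
  if (m$to_res != "G") keep_names <- c(keep_names, "CB")
  drop <- sel & !(trimws(x$atoms$atom) %in% keep_names)
  x$atoms <- x$atoms[!drop, ]
  sel <- x$atoms$resno == m$position & x$atoms$type == "ATOM"
  x$atoms$resname[sel] <- .aa_one_to_three[m$to_res]
  note <- sprintf(
    "STUB MUTATION %s%d%s: side chain truncated at CB; rebuild before docking",
    m$from_res, m$position, m$to_res)
  if (m$from_res == "G")
    note <- sprintf("STUB MUTATION %s%d%s: glycine background, rename only",
                    m$from_res, m$position, m$to_res)
  x$remarks <- c(x$remarks, note)
  x$label <- sprintf("%s_%s%d%s", x$label, m$from_res, m$position, m$to_res)
  x
}
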