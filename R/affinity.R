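# Docking-energy bookkeeping: Vina-style log parsing, free energy to
# dissociation constant conversion, lipid-swap feasibility calls and
# mutational-scan comparisons.

#' Gas constant in kcal/(mol K)
#' @export
R_KCAL <- 0.0019872

#' Convert binding free energy to a dissociation constant
#'
#' `Kd = exp(dG / (R T))` with `R = 0.0019872` kcal/(mol K); a dG of 0 gives
#' 1 M, more negative dG gives tighter (smaller) Kd.
#'
#' @param delta_g Binding free energy in kcal/mol (negative = favourable).
#' @param temperature Temperature in Kelvin (default 298.15).
#' @return Kd in molar units.
#' @export
kd_from_dg <- function(delta_g, temperature = 298.15) {
  if (any(!is.finite(delta_g))) stop("delta_g must be finite")
  if (any(temperature <= 0)) stop("temperature must be positive")
  exp(delta_g / (R_KCAL * temperature))
}

#' Assemble a docking record table
#'
#' @param receptor,ligand Labels.
#' @param ligand_class `"endogenous"` or `"exogenous"` per record.
#' @param delta_g Binding free energies (kcal/mol).
#' @param pose_rank Integer pose rank (1 = best pose of its run).
#' @return Data frame of class `docking_table`.
#' @export
docking_table <- function(receptor, ligand, ligand_class, delta_g,
                          pose_rank = 1L) {
  if (any(!is.finite(delta_g))) stop("delta_g must be finite")
  if (!all(ligand_class %in% c("endogenous", "exogenous")))
    stop("ligand_class must be 'endogenous' or 'exogenous'")
  df <- data.frame(receptor = receptor, ligand = ligand,
                   ligand_class = ligand_class, delta_g = delta_g,
                   pose_rank = as.integer(pose_rank),
                   stringsAsFactors = FALSE)
  class(df) <- c("docking_table", "data.frame")
  df
}

#' Parse an AutoDock-Vina-style result log
#'
#' Extracts the mode/affinity table (`mode | affinity (kcal/mol) | ...`);
#' one record per pose with pose rank preserved. Receptor and ligand default
#' to labels derived from the file name (`receptor__ligand.log`).
#'
#' @param path Log file path.
#' @param receptor,ligand Optional explicit labels.
#' @param ligand_class Class for all records (default `"endogenous"`).
#' @return A [docking_table]; rank-1 rows carry the lowest energy pose.
#' @export
parse_vina_output <- function(path, receptor = NULL, ligand = NULL,
                              ligand_class = "endogenous") {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^\\s*mode\\s*\\|", lines)
  if (length(hdr) == 0) stop("no Vina affinity table found in ", path)
  rows <- grep("^\\s*\\d+\\s+-?\\d+(\\.\\d+)?\\s", lines)
  rows <- rows[rows > hdr[1]]
  if (length(rows) == 0) stop("Vina affinity table in ", path, " has no poses")
  parsed <- do.call(rbind, lapply(lines[rows], function(l) {
    f <- strsplit(trimws(l), "\\s+")[[1]]
    as.numeric(f[1:2])
  }))
  stem <- tools::file_path_sans_ext(basename(path))
  parts <- strsplit(stem, "__", fixed = TRUE)[[1]]
  if (is.null(receptor)) receptor <- parts[1]
  if (is.null(ligand)) ligand <- if (length(parts) > 1) parts[2] else stem
  docking_table(receptor, ligand, ligand_class,
                delta_g = parsed[, 2], pose_rank = as.integer(parsed[, 1]))
}

# lowest-energy pose per (receptor, ligand)
.best_poses <- function(records) {
  key <- paste(records$receptor, records$ligand, sep = "\r")
  best <- unlist(lapply(split(seq_len(nrow(records)), key), function(i) {
    i[which.min(records$delta_g[i])]
  }), use.names = FALSE)
  records[sort(best), , drop = FALSE]
}

#' Lipid-swap feasibility call for one receptor
#'
#' Using the lowest-energy pose per ligand, the best (lowest-Kd) endogenous
#' ligand is compared with the named exogenous ligand:
#' `fold = Kd_best_endogenous / Kd_exogenous`, and the verdict is `swap` iff
#' `fold >= threshold`. At the default threshold of 1 an exogenous ligand at
#' least as tight as the best endogenous one swaps (ties swap).
#'
#' @param records A [docking_table] for one receptor.
#' @param exo_ligand Name of the exogenous ligand to test.
#' @param threshold Fold threshold for a swap verdict (default 1).
#' @param temperature Kelvin, for the Kd conversion (default 298.15).
#' @return Object of class `swap_call`: `receptor`, `best_endogenous`
#'   (ligand, kd), `exogenous` (ligand, kd), `fold`, `verdict`, `threshold`,
#'   `temperature`.
#' @export
swap_feasibility <- function(records, exo_ligand, threshold = 1,
                             temperature = 298.15) {
  rec <- unique(records$receptor)
  if (length(rec) != 1) stop("records must cover exactly one receptor")
  best <- .best_poses(records)
  endo <- best[best$ligand_class == "endogenous", ]
  exo <- best[best$ligand == exo_ligand, ]
  if (nrow(endo) == 0) stop("no endogenous ligands for receptor ", rec)
  if (nrow(exo) != 1) stop("exogenous ligand '", exo_ligand,
                           "' not found for receptor ", rec)
  kd_endo <- kd_from_dg(endo$delta_g, temperature)
  i <- which.min(kd_endo)
  kd_exo <- kd_from_dg(exo$delta_g, temperature)
  fold <- kd_endo[i] / kd_exo
  structure(list(
    receptor = rec,
    best_endogenous = list(ligand = endo$ligand[i], kd = kd_endo[i]),
    exogenous = list(ligand = exo_ligand, kd = kd_exo),
    fold = fold,
    verdict = if (fold >= threshold) "swap" else "no_swap",
    threshold = threshold, temperature = temperature),
    class = "swap_call")
}

#' @export
print.swap_call <- function(x, ...) {
  cat(sprintf(
    "swap_call [%s]: best endogenous %s (Kd %.3g M) vs %s (Kd %.3g M); fold %.3g -> %s\n",
    x$receptor, x$best_endogenous$ligand, x$best_endogenous$kd,
    x$exogenous$ligand, x$exogenous$kd, x$fold, x$verdict))
  invisible(x)
}

#' Compare docking tables of a wild-type and a mutant receptor
#'
#' Per-ligand Kd fold changes (mutant over wild type, lowest-energy pose
#' each), direction flags, the swap verdict of both backgrounds against the
#' named exogenous ligand, and a one-line summary of the endogenous-affinity
#' direction.
#'
#' @param wt,mut [docking_table]s sharing the same ligand panel.
#' @param exo_ligand Exogenous ligand for the swap verdicts.
#' @param threshold,temperature Passed to [swap_feasibility].
#' @return Object of class `scan_comparison`: `per_ligand` data frame
#'   (`ligand`, `ligand_class`, `kd_wt`, `kd_mut`, `fold_change`,
#'   `direction`), `wt_call`, `mut_call`, `verdict_change`, `summary`.
#' @export
mutational_scan <- function(wt, mut, exo_ligand, threshold = 1,
                            temperature = 298.15) {
  lw <- sort(unique(wt$ligand)); lm <- sort(unique(mut$ligand))
  if (!identical(lw, lm))
    stop("ligand panels differ; wt-only: {",
         paste(setdiff(lw, lm), collapse = ", "), "}; mut-only: {",
         paste(setdiff(lm, lw), collapse = ", "), "}")
  bw <- .best_poses(wt); bm <- .best_poses(mut)
  bw <- bw[match(lw, bw$ligand), ]
  bm <- bm[match(lw, bm$ligand), ]
  kd_wt <- kd_from_dg(bw$delta_g, temperature)
  kd_mut <- kd_from_dg(bm$delta_g, temperature)
  fold <- kd_mut / kd_wt
  per <- data.frame(
    ligand = lw, ligand_class = bw$ligand_class, kd_wt = kd_wt,
    kd_mut = kd_mut, fold_change = fold,
    direction = ifelse(fold < 1, "tighter", ifelse(fold > 1, "weaker", "unchanged")),
    stringsAsFactors = FALSE)
  wt_call <- swap_feasibility(wt, exo_ligand, threshold, temperature)
  mut_call <- swap_feasibility(mut, exo_ligand, threshold, temperature)
  endo <- per[per$ligand_class == "endogenous", ]
  summary <- if (all(endo$fold_change < 1)) {
    "increased affinity for all endogenous ligands"
  } else if (all(endo$fold_change > 1)) {
    "decreased affinity for all endogenous ligands"
  } else "mixed direction across endogenous ligands"
  structure(list(per_ligand = per, wt_call = wt_call, mut_call = mut_call,
                 verdict_change = !identical(wt_call$verdict, mut_call$verdict),
                 summary = summary),
            class = "scan_comparison")
}

#' @export
print.scan_comparison <- function(x, ...) {
  cat(sprintf("scan_comparison: %s; verdict %s -> %s\n", x$summary,
              x$wt_call$verdict, x$mut_call$verdict))
  invisible(x)
}

#' Read a binding free-energy table from CSV
#'
#' Expected columns: `receptor`, `ligand`, `ligand_class`,
#' `delta_g_kcal_mol`, optional `pose_rank`.
#'
#' @param path CSV path.
#' @return A [docking_table].
#' @export
read_dg_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("receptor", "ligand", "ligand_class", "delta_g_kcal_mol")
  if (!all(need %in% names(df)))
    stop("dG table must have columns: ", paste(need, collapse = ", "))
  docking_table(df$receptor, df$ligand, df$ligand_class, df$delta_g_kcal_mol,
                if ("pose_rank" %in% names(df)) df$pose_rank else 1L)
}

#' Write a docking table to CSV
#'
#' @param records A [docking_table].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_dg_table <- function(records, path) {
  df <- data.frame(receptor = records$receptor, ligand = records$ligand,
                   ligand_class = records$ligand_class,
                   delta_g_kcal_mol = records$delta_g,
                   pose_rank = records$pose_rank)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
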