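# End-to-end orchestration: clean -> selection scan -> conservation/pocket ->
# swap/mutational comparison, driven by a declarative config, with a run
# manifest recording every parameter, seed and threshold.

.pipeline_defaults <- function() {
  list(
    seed = 1,
    selection = list(comparison = "M7M8", k_categories = 10,
                     posterior_cut = 0.9, p_cut = 0.1, n_polish = 2),
    pocket = list(probe_radius = 0.75, spacing = 0.5,
                  small_probe = 0.75, large_probe = 2.5),
    affinity = list(exo_ligand = "DDM", threshold = 1, temperature = 298.15)
  )
}

.merge_config <- function(defaults, user) {
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(defaults[[nm]]))
      defaults[[nm]] <- .merge_config(defaults[[nm]], user[[nm]])
    else defaults[[nm]] <- user[[nm]]
  }
  defaults
}

.stage <- function(name, expr) {
  message(sprintf("[lipidshift] stage %s", name))
  tryCatch(force(expr), error = function(e) {
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full inference pipeline from a config
#'
#' Stages run in dependency order; a partial config runs a partial chain.
#' `alignment` + `tree` drive cleaning and the selection scan;
#' `structures` (a list of PDB paths) drives conservation mapping and pocket
#' volumetrics; `affinity$dg_table` (CSV, see [read_dg_table]) drives the
#' swap call, plus [mutational_scan] when `affinity$mut_table` is given.
#' Every run emits a manifest (YAML) capturing the config snapshot, input
#' checksums, seeds and per-stage parameters; deterministic stages re-run
#' from the same manifest reproduce their outputs byte-identically.
#'
#' @param config Path to a YAML config file, or an equivalent named list.
#'   Recognised keys: `seed`, `output_dir`, `alignment`, `tree`,
#'   `protein_alignment`, `structures`, `selection` (`comparison`,
#'   `k_categories`, `posterior_cut`, `p_cut`, `n_polish`), `pocket`
#'   (`probe_radius`, `spacing`, `small_probe`, `large_probe`), `affinity`
#'   (`dg_table`, `mut_table`, `exo_ligand`, `threshold`, `temperature`).
#' @return List of stage results (`cleaned`, `selection`, `conservation`,
#'   `pocket`, `swap`, `scan_comparison` as applicable) plus `manifest` and
#'   `skipped` (stages without inputs).
#' @export
run_pipeline <- function(config) {
  user <- if (is.character(config)) yaml::read_yaml(config) else config
  cfg <- .merge_config(.pipeline_defaults(), user)
  out_dir <- cfg$output_dir %||% tempfile("lipidshift_run_")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)

  results <- list()
  skipped <- character(0)
  outputs <- character(0)
  inputs <- character(0)

  if (!is.null(cfg$alignment)) {
    inputs <- c(inputs, cfg$alignment, cfg$tree)
    cleaned <- .stage("clean", {
      aln <- read_alignment(cfg$alignment, "nucleotide")
      cl <- clean_codon_alignment(aln)
      write_alignment(cl, file.path(out_dir, "cleaned.fasta"))
      write_removal_log(cl, file.path(out_dir, "removal_log.tsv"))
      cl
    })
    outputs <- c(outputs, file.path(out_dir, c("cleaned.fasta", "removal_log.tsv")))
    results$cleaned <- cleaned

    if (!is.null(cfg$tree)) {
      sel <- .stage("scan-selection", {
        tree <- ape::read.tree(cfg$tree)
        ml <- scan_selection_ml(cleaned, tree,
                                comparison = cfg$selection$comparison,
                                k_categories = cfg$selection$k_categories,
                                n_polish = cfg$selection$n_polish)
        counting <- slac_site_scan(cleaned, tree)
        calls <- classify_selected_sites(ml$posteriors, counting,
                                         cfg$selection$posterior_cut,
                                         cfg$selection$p_cut)
        write_site_table(ml$posteriors, file.path(out_dir, "neb_posteriors.tsv"))
        write_site_table(counting, file.path(out_dir, "slac_sites.tsv"))
        write_site_table(calls, file.path(out_dir, "selected_sites.tsv"))
        meta <- list(
          comparison = cfg$selection$comparison,
          null = list(model = ml$null$model_id, lnL = ml$null$lnL,
                      params = as.list(ml$null$params)),
          alt = list(model = ml$alt$model_id, lnL = ml$alt$lnL,
                     params = as.list(ml$alt$params)),
          lrt = ml$lrt, kappa = ml$null$kappa,
          branch_scale = ml$null$branch_scale,
          k_categories = cfg$selection$k_categories)
        jsonlite::write_json(meta, file.path(out_dir, "model_fits.json"),
                             auto_unbox = TRUE, digits = NA)
        list(ml = ml, counting = counting, calls = calls)
      })
      outputs <- c(outputs, file.path(out_dir, c(
        "neb_posteriors.tsv", "slac_sites.tsv", "selected_sites.tsv",
        "model_fits.json")))
      results$selection <- sel
    } else skipped <- c(skipped, "scan-selection")
  } else skipped <- c(skipped, "clean", "scan-selection")

  if (!is.null(cfg$structures) && length(cfg$structures) >= 2) {
    inputs <- c(inputs, unlist(cfg$structures))
    cons <- .stage("conservation", {
      models <- lapply(cfg$structures, read_structure)
      coords <- if (!is.null(cfg$protein_alignment)) {
        paln <- read_alignment(cfg$protein_alignment, "protein")
        pair_by_alignment(paln, models)$coords
      } else {
        stats::setNames(lapply(models, calpha_coords),
                        vapply(models, `[[`, character(1), "label"))
      }
      sup <- superpose_ensemble(coords)
      prof <- per_residue_divergence(sup)
      ref <- models[[1]]
      ca <- ref$atoms[trimws(ref$atoms$atom) == "CA" & ref$atoms$type == "ATOM", ]
      profile <- data.frame(resno = ca$resno[prof$index],
                            score = prof$conservation)
      write_conservation_bfactor(ref, profile,
                                 file.path(out_dir, "conservation.pdb"))
      utils::write.table(prof, file.path(out_dir, "divergence.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      prof
    })
    outputs <- c(outputs, file.path(out_dir, c("conservation.pdb", "divergence.tsv")))
    results$conservation <- cons
  } else skipped <- c(skipped, "conservation")

  if (!is.null(cfg$structures) && length(cfg$structures) >= 1) {
    pock <- .stage("pocket", {
      res <- lapply(cfg$structures, function(p) {
        st <- read_structure(p)
        r <- cavity_volume(st, probe_radius = cfg$pocket$probe_radius,
                           spacing = cfg$pocket$spacing)
        r$portal_count <- portal_count(
          st, small_probe = cfg$pocket$small_probe,
          large_probe = cfg$pocket$large_probe, spacing = cfg$pocket$spacing)
        r
      })
      names(res) <- vapply(cfg$structures, function(p)
        tools::file_path_sans_ext(basename(p)), character(1))
      write_pocket_table(res, file.path(out_dir, "pocket.tsv"))
      res
    })
    outputs <- c(outputs, file.path(out_dir, "pocket.tsv"))
    results$pocket <- pock
  } else skipped <- c(skipped, "pocket")

  if (!is.null(cfg$affinity$dg_table)) {
    inputs <- c(inputs, cfg$affinity$dg_table, cfg$affinity$mut_table)
    swp <- .stage("swap", {
      wt <- read_dg_table(cfg$affinity$dg_table)
      calls <- lapply(split(wt, wt$receptor), function(r) {
        class(r) <- c("docking_table", "data.frame")
        swap_feasibility(r, cfg$affinity$exo_ligand,
                         cfg$affinity$threshold, cfg$affinity$temperature)
      })
      df <- do.call(rbind, lapply(calls, function(cl) data.frame(
        receptor = cl$receptor, best_endogenous = cl$best_endogenous$ligand,
        kd_best_endogenous = cl$best_endogenous$kd,
        exogenous = cl$exogenous$ligand, kd_exogenous = cl$exogenous$kd,
        fold = cl$fold, verdict = cl$verdict)))
      utils::write.csv(df, file.path(out_dir, "swap_calls.csv"),
                       row.names = FALSE)
      calls
    })
    outputs <- c(outputs, file.path(out_dir, "swap_calls.csv"))
    results$swap <- swp

    if (!is.null(cfg$affinity$mut_table)) {
      cmp <- .stage("scan-compare", {
        wt <- read_dg_table(cfg$affinity$dg_table)
        mut <- read_dg_table(cfg$affinity$mut_table)
        sc <- mutational_scan(wt, mut, cfg$affinity$exo_ligand,
                              cfg$affinity$threshold,
                              cfg$affinity$temperature)
        utils::write.csv(sc$per_ligand,
                         file.path(out_dir, "mutational_scan.csv"),
                         row.names = FALSE)
        writeLines(c(sprintf("background: %s -> %s", sc$wt_call$receptor,
                             sc$mut_call$receptor),
                     sprintf("summary: %s", sc$summary),
                     sprintf("verdict: %s -> %s", sc$wt_call$verdict,
                             sc$mut_call$verdict)),
                   file.path(out_dir, "mutational_scan.txt"))
        sc
      })
      outputs <- c(outputs, file.path(out_dir, c("mutational_scan.csv",
                                                 "mutational_scan.txt")))
      results$scan_comparison <- cmp
    } else skipped <- c(skipped, "scan-compare")
  } else skipped <- c(skipped, "swap", "scan-compare")

  inputs <- inputs[!vapply(inputs, is.null, logical(1))]
  manifest <- list(
    tool = "lipidshift",
    version = as.character(utils::packageVersion("lipidshift")),
    seed = cfg$seed,
    config = cfg,
    input_checksums = as.list(tools::md5sum(unlist(inputs))),
    outputs = outputs,
    skipped_stages = skipped)
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  results$manifest <- manifest
  results$skipped <- skipped
  results$output_dir <- out_dir
  results
}

`%||%` <- function(a, b) if (is.null(a)) b else a
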