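# Synthetic-data generators: every input class the pipeline consumes, with
# ground truth attached. Component RNG streams are derived from the master
# seed so adding one stage never perturbs another.

.stream_seed <- function(seed, component) {
  idx <- match(component, c("tree", "sites", "evolution", "structure",
                            "affinity", "orientation"))
  if (is.na(idx)) stop("unknown RNG component: ", component)
  as.integer((seed * 7919 + idx * 104729) %% 2147483647L)
}

#' Define a synthetic scenario
#'
#' Bundles the generator configuration for all input classes: the tree and
#' codon-mixture truth for alignments, the cavity geometry for structures,
#' and the affinity gap for docking tables. Defaults mirror the study scale:
#' 19 taxa, 300 codon sites, exponential branch lengths of mean 0.05
#' substitutions per codon site, and an M7 beta(0.5, 1.5) omega mixture.
#'
#' @param seed Master seed (all component streams derive from it).
#' @param n_taxa,n_sites Alignment dimensions.
#' @param branch_mean Mean of the exponential branch-length law.
#' @param kappa Transition/transversion ratio of the simulation truth.
#' @param mixture Truth omega mixture: `list(model = "M7", p, q)`,
#'   `list(model = "M8", p0, p, q, omega_s)`, or
#'   `list(model = "single", omega)`.
#' @param k_categories Beta discretisation used when simulating beta models.
#' @param nt_freqs 3 x 4 matrix of position-specific nucleotide frequencies
#'   (columns A, C, G, T) feeding the F3x4 root distribution.
#' @param cavity `list(shape, void, rotate)` with shape one of `"sealed"`,
#'   `"one_channel"`, `"two_channels"`.
#' @param ensemble `list(n_models, n_residues, loop, amplitude, rigid)` for
#'   the structure-ensemble generator.
#' @param affinity `list(n_endo, endo_dg_mean, endo_dg_sd, gap_factor,
#'   mut_endo_factor, mut_exo_factor, n_extra_poses)`.
#' @return Object of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(seed = 1,
                               n_taxa = 19, n_sites = 300,
                               branch_mean = 0.05, kappa = 2,
                               mixture = list(model = "M7", p = 0.5, q = 1.5),
                               k_categories = 10,
                               nt_freqs = matrix(0.25, 3, 4,
                                                 dimnames = list(NULL, c("A", "C", "G", "T"))),
                               cavity = list(shape = "sealed", void = 4,
                                             rotate = FALSE),
                               ensemble = list(n_models = 14, n_residues = 60,
                                               loop = 25:34, amplitude = 3,
                                               rigid = TRUE),
                               affinity = list(n_endo = 3, endo_dg_mean = -7,
                                               endo_dg_sd = 1,
                                               gap_factor = 10,
                                               mut_endo_factor = 1,
                                               mut_exo_factor = 1,
                                               n_extra_poses = 2)) {
  stopifnot(seed == as.integer(seed), n_taxa >= 2, n_sites >= 1)
  structure(list(seed = as.integer(seed), n_taxa = n_taxa, n_sites = n_sites,
                 branch_mean = branch_mean, kappa = kappa, mixture = mixture,
                 k_categories = k_categories, nt_freqs = nt_freqs,
                 cavity = cavity, ensemble = ensemble, affinity = affinity),
            class = "synthetic_scenario")
}

.scenario_pi <- function(scenario) {
  nf <- scenario$nt_freqs
  colnames(nf) <- c("A", "C", "G", "T")
  pi <- nf[1, substr(SENSE_CODONS, 1, 1)] *
    nf[2, substr(SENSE_CODONS, 2, 2)] *
    nf[3, substr(SENSE_CODONS, 3, 3)]
  pi <- pmax(pi, 1e-10)
  stats::setNames(pi / sum(pi), SENSE_CODONS)
}

.scenario_mixture <- function(scenario) {
  mx <- scenario$mixture
  k <- scenario$k_categories
  switch(mx$model,
    single = list(omegas = mx$omega, props = 1),
    M7 = list(omegas = .discretize_beta(mx$p, mx$q, k), props = rep(1 / k, k)),
    M8 = list(omegas = c(.discretize_beta(mx$p, mx$q, k), mx$omega_s),
              props = c(rep(mx$p0 / k, k), 1 - mx$p0)),
    stop("unknown mixture model: ", mx$model))
}

#' Simulate the species tree of a scenario
#'
#' Random topology with exponential branch lengths (mean
#' `scenario$branch_mean`, in expected substitutions per codon site).
#'
#' @param scenario A [synthetic_scenario].
#' @return An `ape::phylo` tree with `n_taxa` leaves labelled `sp01, ...`.
#' @export
simulate_tree <- function(scenario) {
  set.seed(.stream_seed(scenario$seed, "tree"))
  tree <- ape::rtree(scenario$n_taxa,
                     br = function(n) stats::rexp(n, 1 / scenario$branch_mean))
  tree$tip.label <- sprintf("sp%02d", seq_len(scenario$n_taxa))
  tree
}

#' Simulate a codon alignment under a site-class omega mixture
#'
#' Root codons are drawn from the scenario's F3x4 frequencies; each site
#' draws an omega class from the truth mixture and evolves along the tree by
#' GY94 transition probabilities (generators share the mixture-average rate
#' scaling used in fitting, so branch lengths mean expected substitutions
#' per codon site).
#'
#' @param scenario A [synthetic_scenario].
#' @param tree Optional tree (defaults to [simulate_tree] of the scenario).
#' @return List: `aln` ([codon_alignment]), `tree`, `true_class` (per-site
#'   mixture class index), `true_omega` (per-site omega), `scenario`.
#' @export
simulate_codon_alignment <- function(scenario, tree = NULL) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  if (is.null(tree)) tree <- simulate_tree(scenario)
  pi <- .scenario_pi(scenario)
  mix <- .scenario_mixture(scenario)
  Qs <- lapply(mix$omegas, function(w)
    gy94_rate_matrix(codon_model_params(scenario$kappa, w, pi), scale = FALSE))
  mus <- vapply(Qs, function(Q) -sum(pi * diag(Q)), numeric(1))
  mu_bar <- sum(mix$props * mus)
  if (mu_bar <= 0) mu_bar <- 1

  set.seed(.stream_seed(scenario$seed, "sites"))
  cls <- sample.int(length(mix$props), scenario$n_sites, replace = TRUE,
                    prob = mix$props)

  set.seed(.stream_seed(scenario$seed, "evolution"))
  tre <- stats::reorder(tree, "postorder")
  n_tip <- length(tre$tip.label)
  n_node <- max(tre$edge)
  states <- matrix(0L, n_node, scenario$n_sites)
  states[n_tip + 1, ] <- sample.int(61, scenario$n_sites, replace = TRUE,
                                    prob = pi)
  eigs <- lapply(Qs, function(Q) .q_eigen(Q / mu_bar, pi))
  for (e in rev(seq_len(nrow(tre$edge)))) {
    p <- tre$edge[e, 1]; ch <- tre$edge[e, 2]; t <- tre$edge.length[e]
    for (c in unique(cls)) {
      P <- .transition_matrix(eigs[[c]], t)
      sel <- which(cls == c)
      for (s in unique(states[p, sel])) {
        ss <- sel[states[p, sel] == s]
        pr <- pmax(P[s, ], 0)
        states[ch, ss] <- sample.int(61, length(ss), replace = TRUE, prob = pr)
      }
    }
  }
  cod <- matrix(SENSE_CODONS[states[seq_len(n_tip), , drop = FALSE]], n_tip)
  rownames(cod) <- tre$tip.label
  list(aln = codon_alignment(cod), tree = tree, true_class = cls,
       true_omega = mix$omegas[cls], scenario = scenario)
}

# dense lattice of pseudo-atoms on a rectangle in a coordinate plane
.plane_atoms <- function(axis, level, umin, umax, vmin, vmax, step, holes) {
  u <- seq(umin, umax, by = step)
  v <- seq(vmin, vmax, by = step)
  g <- expand.grid(u = u, v = v)
  pts <- switch(axis,
    x = cbind(level, g$u, g$v),
    y = cbind(g$u, level, g$v),
    z = cbind(g$u, g$v, level))
  if (!is.null(holes)) {
    for (h in holes) {
      d2 <- (pts[, h$u_axis] - h$u0)^2 + (pts[, h$v_axis] - h$v0)^2
      pts <- pts[d2 > h$radius^2, , drop = FALSE]
    }
  }
  pts
}

#' Construct a cavity fixture with analytically known truth
#'
#' Builds a pseudo-atom shell (element `D`, vdW radius 1 A in
#' [default_vdw_radii()]) whose probe-inflated surface encloses a cubic void
#' of side `scenario$cavity$void` exactly, for a 0.75 A probe:
#' atom planes sit at `vdW + probe` outside each void face. `"one_channel"`
#' and `"two_channels"` shapes carve cylindrical channels through thickened
#' walls that pass a 0.75 A probe but block a 2.5 A probe; an open shell has
#' zero buried cavity at the small probe, so their truth volume is 0 and the
#' planted portal count is 1 or 2.
#'
#' @param scenario A [synthetic_scenario]; uses `cavity = list(shape, void,
#'   rotate)`. With `rotate = TRUE` a random rigid rotation is applied
#'   (truth is unchanged).
#' @return List: `structure` ([structure_model]), `truth_volume` (A^3),
#'   `truth_portals`, `probe_radius` the truth refers to.
#' @export
make_cavity_fixture <- function(scenario) {
  cav <- scenario$cavity
  L <- cav$void
  probe <- 0.75
  r_atom <- 1.0
  R <- r_atom + probe            # inflated-surface offset: 1.75 A
  shape <- cav$shape
  # sealed: one dense wall plane per face, the inflated surface coinciding
  # with the void faces; channels: three stacked planes per face so the wall
  # is thick enough that only the carved channels connect in and out
  step <- if (shape == "sealed") 0.4 else 0.8
  offs <- if (shape == "sealed") R else c(R, R + 2, R + 4)
  hole_r <- 2.8                  # passes 0.75 A probe, blocks 2.5 A probe

  holes_for <- function(axis, level) {
    if (shape == "sealed") return(NULL)
    # channels along +x (and -x for the two-channel shape)
    if (axis != "x") return(NULL)
    mid <- L / 2
    if (level > L && shape %in% c("one_channel", "two_channels"))
      return(list(list(u_axis = 2, v_axis = 3, u0 = mid, v0 = mid,
                       radius = hole_r)))
    if (level < 0 && shape == "two_channels")
      return(list(list(u_axis = 2, v_axis = 3, u0 = mid, v0 = mid,
                       radius = hole_r)))
    NULL
  }

  # wall planes extend past the corners; the 2.15 margin keeps void faces
  # from landing exactly on voxel centres of the default grids
  ext <- max(offs) + 2.15
  pts <- list()
  for (o in offs) {
    for (axis in c("x", "y", "z")) {
      pts[[length(pts) + 1]] <- .plane_atoms(axis, -o, -ext, L + ext, -ext,
                                             L + ext, step, holes_for(axis, -o))
      pts[[length(pts) + 1]] <- .plane_atoms(axis, L + o, -ext, L + ext, -ext,
                                             L + ext, step, holes_for(axis, L + o))
    }
  }
  xyz <- do.call(rbind, pts)
  if (isTRUE(cav$rotate)) {
    set.seed(.stream_seed(scenario$seed, "orientation"))
    ang <- stats::runif(3, 0, 2 * pi)
    Rx <- rbind(c(1, 0, 0), c(0, cos(ang[1]), -sin(ang[1])),
                c(0, sin(ang[1]), cos(ang[1])))
    Ry <- rbind(c(cos(ang[2]), 0, sin(ang[2])), c(0, 1, 0),
                c(-sin(ang[2]), 0, cos(ang[2])))
    Rz <- rbind(c(cos(ang[3]), -sin(ang[3]), 0),
                c(sin(ang[3]), cos(ang[3]), 0), c(0, 0, 1))
    xyz <- xyz %*% (Rx %*% Ry %*% Rz)
  }
  st <- structure_model(data.frame(
    type = "HETATM", serial = seq_len(nrow(xyz)), atom = "D",
    resname = "DUM", chain = "X", resno = 1L,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], occ = 1, b = 0,
    element = "D", stringsAsFactors = FALSE),
    label = paste0("cavity_", shape))
  list(structure = st,
       truth_volume = if (shape == "sealed") L^3 else 0,
       truth_portals = switch(shape, sealed = 0L, one_channel = 1L,
                              two_channels = 2L),
       probe_radius = probe)
}

#' Generate a structure ensemble with a known displacement field
#'
#' Replicates an ideal alpha-helical Calpha trace across models, displaces a
#' contiguous loop by Gaussian noise of RMS amplitude
#' `scenario$ensemble$amplitude` (A), and optionally applies a random rigid
#' motion to each model (which superposition must undo).
#'
#' @param scenario A [synthetic_scenario].
#' @return List: `models` (list of Calpha-only [structure_model]s named
#'   `m01, ...`), `loop` (residue indices carrying the signal), `amplitude`.
#' @export
make_model_ensemble <- function(scenario) {
  en <- scenario$ensemble
  set.seed(.stream_seed(scenario$seed, "structure"))
  n <- en$n_residues
  idx <- seq_len(n)
  base <- cbind(2.3 * cos(idx * 100 * pi / 180),
                2.3 * sin(idx * 100 * pi / 180),
                1.5 * idx)
  models <- lapply(seq_len(en$n_models), function(m) {
    xyz <- base
    if (en$amplitude > 0 && m > 1) {
      xyz[en$loop, ] <- xyz[en$loop, ] +
        matrix(stats::rnorm(length(en$loop) * 3, 0, en$amplitude / sqrt(3)),
               ncol = 3)
    }
    if (isTRUE(en$rigid)) {
      ang <- stats::runif(3, 0, 2 * pi)
      Rz <- rbind(c(cos(ang[1]), -sin(ang[1]), 0),
                  c(sin(ang[1]), cos(ang[1]), 0), c(0, 0, 1))
      Ry <- rbind(c(cos(ang[2]), 0, sin(ang[2])), c(0, 1, 0),
                  c(-sin(ang[2]), 0, cos(ang[2])))
      xyz <- sweep(xyz %*% (Rz %*% Ry), 2, stats::runif(3, -20, 20), "+")
    }
    structure_model(data.frame(
      type = "ATOM", serial = idx, atom = "CA", resname = "ALA", chain = "A",
      resno = idx, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], occ = 1, b = 0,
      element = "C", stringsAsFactors = FALSE),
      label = sprintf("m%02d", m))
  })
  names(models) <- sprintf("m%02d", seq_len(en$n_models))
  list(models = models, loop = en$loop, amplitude = en$amplitude)
}

#' Generate docking tables with known swap-verdict truth
#'
#' Endogenous binding free energies are drawn from a normal law; the
#' exogenous ligand's dG is set so that `Kd_best_endogenous / Kd_exogenous`
#' equals `gap_factor` exactly. The mutant background rescales endogenous
#' and exogenous Kd by the configured factors. Truth verdicts are computed
#' from the truth Kd values by the swap rule itself (fold >= threshold).
#'
#' @param scenario A [synthetic_scenario]; uses the `affinity` block.
#' @param threshold Swap threshold the truth verdicts refer to (default 1).
#' @param temperature Kelvin (default 298.15).
#' @return List: `wt`, `mut` ([docking_table]s, with `n_extra_poses`
#'   higher-energy decoy poses per ligand), `truth` (folds and verdicts per
#'   background), `exo_ligand`.
#' @export
make_affinity_tables <- function(scenario, threshold = 1,
                                 temperature = 298.15) {
  af <- scenario$affinity
  set.seed(.stream_seed(scenario$seed, "affinity"))
  rt <- R_KCAL * temperature
  endo_lig <- sprintf("endo%02d", seq_len(af$n_endo))
  dg_endo <- stats::rnorm(af$n_endo, af$endo_dg_mean, af$endo_dg_sd)
  dg_exo <- min(dg_endo) - rt * log(af$gap_factor)
  dg_endo_mut <- dg_endo + rt * log(af$mut_endo_factor)
  dg_exo_mut <- dg_exo + rt * log(af$mut_exo_factor)

  build <- function(receptor, dg_e, dg_x) {
    lig <- c(endo_lig, "exo")
    cls <- c(rep("endogenous", af$n_endo), "exogenous")
    dg <- c(dg_e, dg_x)
    rows <- docking_table(receptor, lig, cls, dg, 1L)
    if (af$n_extra_poses > 0) {
      for (k in seq_len(af$n_extra_poses)) {
        rows <- rbind(rows, docking_table(
          receptor, lig, cls, dg + k * stats::runif(length(dg), 0.3, 1.5),
          k + 1L))
      }
      class(rows) <- c("docking_table", "data.frame")
    }
    rows
  }
  wt <- build("wt", dg_endo, dg_exo)
  mut <- build("mut", dg_endo_mut, dg_exo_mut)

  fold_of <- function(dg_e, dg_x) {
    min(kd_from_dg(dg_e, temperature)) / kd_from_dg(dg_x, temperature)
  }
  fw <- fold_of(dg_endo, dg_exo)
  fm <- fold_of(dg_endo_mut, dg_exo_mut)
  list(wt = wt, mut = mut, exo_ligand = "exo",
       truth = list(
         fold_wt = fw, verdict_wt = if (fw >= threshold) "swap" else "no_swap",
         fold_mut = fm, verdict_mut = if (fm >= threshold) "swap" else "no_swap",
         gap_factor = af$gap_factor, threshold = threshold))
}
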