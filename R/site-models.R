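# Site-class (M-series) codon model fitting, likelihood ratio tests and
# empirical-Bayes site posteriors.

# beta(p, q) discretised into k equal-probability classes, class omega at the
# category median (PAML convention)
.discretize_beta <- function(p, q, k) {
  stats::qbeta((seq_len(k) - 0.5) / k, p, q)
}

# mixture (omegas, props) for a model at a parameter vector
.model_mixture <- function(model_id, par, k) {
  switch(model_id,
    M0 = list(omegas = par[["omega"]], props = 1),
    M1 = list(omegas = c(par[["omega0"]], 1),
              props = c(par[["p0"]], 1 - par[["p0"]])),
    M2 = list(omegas = c(par[["omega0"]], 1, par[["omega2"]]),
              props = c(par[["p0"]], par[["p1"]],
                        1 - par[["p0"]] - par[["p1"]])),
    M7 = list(omegas = .discretize_beta(par[["p"]], par[["q"]], k),
              props = rep(1 / k, k)),
    M8 = list(omegas = c(.discretize_beta(par[["p"]], par[["q"]], k),
                         par[["omega_s"]]),
              props = c(rep(par[["p0"]] / k, k), 1 - par[["p0"]])),
    stop("unknown model: ", model_id)
  )
}

# unconstrained <-> natural parameter transforms per model
.par_transforms <- list(
  M1 = list(
    names = c("p0", "omega0"),
    to_nat = function(x) c(p0 = stats::plogis(x[1]), omega0 = stats::plogis(x[2])),
    to_unc = function(p) c(stats::qlogis(p[["p0"]]), stats::qlogis(p[["omega0"]]))
  ),
  M2 = list(
    names = c("p0", "p1", "omega0", "omega2"),
    to_nat = function(x) {
      # stick-breaking keeps p0 + p1 < 1
      p0 <- stats::plogis(x[1]); p1 <- (1 - p0) * stats::plogis(x[2])
      c(p0 = p0, p1 = p1, omega0 = stats::plogis(x[3]), omega2 = 1 + exp(x[4]))
    },
    to_unc = function(p) c(
      stats::qlogis(p[["p0"]]),
      stats::qlogis(p[["p1"]] / (1 - p[["p0"]])),
      stats::qlogis(p[["omega0"]]),
      log(max(p[["omega2"]] - 1, 1e-6))
    )
  ),
  M7 = list(
    names = c("p", "q"),
    to_nat = function(x) c(p = exp(x[1]), q = exp(x[2])),
    to_unc = function(p) c(log(p[["p"]]), log(p[["q"]]))
  ),
  M8 = list(
    names = c("p0", "p", "q", "omega_s"),
    to_nat = function(x) c(p0 = stats::plogis(x[1]), p = exp(x[2]),
                           q = exp(x[3]), omega_s = 1 + exp(x[4])),
    to_unc = function(p) c(
      stats::qlogis(p[["p0"]]), log(p[["p"]]), log(p[["q"]]),
      log(max(p[["omega_s"]] - 1, 1e-6))
    )
  )
)

# fixed multi-start points (natural scale) per model
.model_starts <- function(model_id) {
  switch(model_id,
    M1 = list(c(p0 = 0.7, omega0 = 0.1), c(p0 = 0.5, omega0 = 0.3),
              c(p0 = 0.9, omega0 = 0.05), c(p0 = 0.3, omega0 = 0.5),
              c(p0 = 0.6, omega0 = 0.2)),
    M2 = list(c(p0 = 0.6, p1 = 0.3, omega0 = 0.1, omega2 = 2),
              c(p0 = 0.5, p1 = 0.4, omega0 = 0.3, omega2 = 4),
              c(p0 = 0.8, p1 = 0.15, omega0 = 0.05, omega2 = 1.5),
              c(p0 = 0.4, p1 = 0.3, omega0 = 0.2, omega2 = 3),
              c(p0 = 0.7, p1 = 0.2, omega0 = 0.1, omega2 = 6)),
    M7 = list(c(p = 0.5, q = 1.5), c(p = 1, q = 1), c(p = 0.2, q = 1),
              c(p = 2, q = 5), c(p = 0.5, q = 0.5)),
    M8 = list(c(p0 = 0.9, p = 0.5, q = 1.5, omega_s = 2),
              c(p0 = 0.8, p = 1, q = 2, omega_s = 4),
              c(p0 = 0.95, p = 0.3, q = 1, omega_s = 1.5),
              c(p0 = 0.7, p = 0.5, q = 1, omega_s = 3),
              c(p0 = 0.99, p = 1, q = 1, omega_s = 1.2))
  )
}

# M0 pre-fit of kappa and a single global branch-length scale (and omega);
# site models then hold kappa and the scale fixed
.fit_m0 <- function(aln, tree, pi) {
  obj <- function(x) {
    kappa <- exp(x[1]); omega <- exp(x[2]); bscale <- exp(x[3])
    r <- .mixture_pattern_loglik(aln, tree, pi, kappa, omega, 1, bscale)
    -sum(r$weights * r$loglik[, 1])
  }
  fit <- stats::optim(log(c(2, 0.4, 1)), obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-8, maxit = 400))
  list(kappa = exp(fit$par[1]), omega = exp(fit$par[2]),
       branch_scale = exp(fit$par[3]), lnL = -fit$value,
       convergence = fit$convergence)
}

#' Fit a site-class codon model
#'
#' Maximum-likelihood fit of the M1 (nearly neutral), M2 (positive
#' selection), M7 (beta) or M8 (beta plus omega > 1 class) site model on a
#' fixed tree, under GY94 with F3x4 frequencies taken from the alignment.
#' Beta mixtures are discretised into `k_categories` equal-probability
#' classes at their medians. The transition/transversion ratio kappa and a
#' single global branch-length scale are estimated once under M0 and held
#' fixed during the site-model fit. Optimisation screens a fixed list of five
#' starting points and polishes the best candidates.
#'
#' @param aln A cleaned [codon_alignment].
#' @param tree `ape::phylo` with branch lengths (expected substitutions per
#'   codon site); leaf set must equal the alignment taxa.
#' @param model_id One of `"M1"`, `"M2"`, `"M7"`, `"M8"`.
#' @param k_categories Number of beta discretisation classes (default 10).
#' @param m0 Optional precomputed M0 fit (as returned in `$m0`) to reuse
#'   across nested model fits on the same data.
#' @param extra_starts Additional natural-scale start points (named numeric
#'   vectors) screened alongside the fixed list; used e.g. to seed M8 from an
#'   M7 optimum so the nested fit can never fall below it.
#' @param n_polish How many of the screened starts to optimise fully.
#' @param control `stats::optim` control list for the polish stage.
#' @return An object of class `site_model_fit`: `model_id`, `lnL`, `mixture`
#'   (data frame of class omega and proportion), `params` (natural-scale
#'   parameter vector), `kappa`, `branch_scale`, `pi`, `k_categories`,
#'   `identifiable` flag, `m0`, and the start-point table.
#' @export
fit_site_model <- function(aln, tree, model_id = c("M7", "M8", "M1", "M2"),
                           k_categories = 10, m0 = NULL, extra_starts = list(),
                           n_polish = 2,
                           control = list(reltol = 1e-8, maxit = 600)) {
  model_id <- match.arg(model_id)
  stopifnot(inherits(aln, "codon_alignment"))
  pi <- build_f3x4(aln)
  if (is.null(m0)) m0 <- .fit_m0(aln, tree, pi)
  tr <- .par_transforms[[model_id]]
  k <- k_categories

  # pattern likelihood evaluator for a natural-scale parameter vector
  eval_ll <- function(par) {
    mix <- .model_mixture(model_id, par, k)
    r <- .mixture_pattern_loglik(aln, tree, pi, m0$kappa, mix$omegas,
                                 mix$props, m0$branch_scale)
    .total_loglik(r$loglik, r$weights, mix$props)
  }
  obj <- function(x) {
    par <- tr$to_nat(x)
    ll <- eval_ll(par)
    if (!is.finite(ll)) return(1e10)
    -ll
  }

  starts <- c(.model_starts(model_id), extra_starts)
  screen <- vapply(starts, function(s) -obj(tr$to_unc(s)), numeric(1))
  ord <- order(screen, decreasing = TRUE)
  best <- NULL
  for (i in ord[seq_len(min(n_polish, length(ord)))]) {
    fit <- stats::optim(tr$to_unc(starts[[i]]), obj, method = "Nelder-Mead",
                        control = control)
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best) || !is.finite(best$value))
    stop("site-model optimisation failed for ", model_id)
  par <- tr$to_nat(best$par)
  mix <- .model_mixture(model_id, par, k)
  monomorphic <- all(apply(aln$codons, 2, function(col) {
    v <- col[col != GAP_CODON]; length(unique(v)) <= 1
  }))
  structure(list(
    model_id = model_id,
    lnL = -best$value,
    mixture = data.frame(omega = mix$omegas, proportion = mix$props),
    params = par,
    kappa = m0$kappa,
    branch_scale = m0$branch_scale,
    pi = pi,
    k_categories = k,
    identifiable = !monomorphic,
    convergence = best$convergence,
    m0 = m0,
    starts_screened = data.frame(start = seq_along(starts), lnL = screen)
  ), class = "site_model_fit")
}

#' @export
print.site_model_fit <- function(x, ...) {
  cat(sprintf("site_model_fit %s: lnL = %.4f (kappa = %.3f, branch scale = %.3f)\n",
              x$model_id, x$lnL, x$kappa, x$branch_scale))
  if (!x$identifiable)
    cat("  note: alignment is monomorphic; mixture parameters unidentifiable\n")
  invisible(x)
}

#' Fit a nested site-model pair and test for positive selection
#'
#' Fits the null and alternative of one of the two standard comparisons
#' (M1 vs M2, M7 vs M8) sharing a single M0 pre-fit, seeds the alternative
#' from the null optimum (so the nested likelihood ordering holds
#' numerically), and returns the LRT together with NEB site posteriors from
#' the selection model.
#'
#' @param aln A cleaned [codon_alignment].
#' @param tree `ape::phylo` tree with branch lengths.
#' @param comparison `"M7M8"` or `"M1M2"`.
#' @param k_categories Beta discretisation classes (default 10).
#' @param n_polish Start points optimised fully per model.
#' @return List with `null`, `alt` ([fit_site_model] objects), `lrt`
#'   (see [lrt]) and `posteriors` (see [neb_site_posteriors]).
#' @export
scan_selection_ml <- function(aln, tree, comparison = c("M7M8", "M1M2"),
                              k_categories = 10, n_polish = 2) {
  comparison <- match.arg(comparison)
  null_id <- substr(comparison, 1, 2)
  alt_id <- substr(comparison, 3, 4)
  f0 <- fit_site_model(aln, tree, null_id, k_categories = k_categories,
                       n_polish = n_polish)
  inf <- if (comparison == "M7M8") {
    list(c(p0 = 0.995, p = f0$params[["p"]], q = f0$params[["q"]],
           omega_s = 1.01),
         c(p0 = 0.9, p = f0$params[["p"]], q = f0$params[["q"]], omega_s = 4))
  } else {
    list(c(p0 = f0$params[["p0"]] * 0.95, p1 = 0.04,
           omega0 = f0$params[["omega0"]], omega2 = 1.01),
         c(p0 = f0$params[["p0"]] * 0.9, p1 = 0.08,
           omega0 = f0$params[["omega0"]], omega2 = 4))
  }
  f1 <- fit_site_model(aln, tree, alt_id, k_categories = k_categories,
                       m0 = f0$m0, extra_starts = inf, n_polish = n_polish)
  list(null = f0, alt = f1, lrt = lrt(f0, f1),
       posteriors = neb_site_posteriors(f1, aln, tree))
}

#' Likelihood ratio test between nested site models
#'
#' Twice the log-likelihood difference, clamped at zero, referred to a
#' chi-square distribution. For the M1/M2 and M7/M8 comparisons `df = 2` by
#' the usual convention.
#'
#' @param null,alt Fitted [fit_site_model] objects (alt nests null).
#' @param df Degrees of freedom (default 2).
#' @param tol Optimizer tolerance: a deficit of `lnL_alt` below `lnL_null`
#'   larger than this triggers a warning before clamping.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
lrt <- function(null, alt, df = 2, tol = 1e-3) {
  stat <- 2 * (alt$lnL - null$lnL)
  if (stat < -tol)
    warning(sprintf(
      "alternative lnL (%.6f) below null lnL (%.6f) beyond tolerance; clamping",
      alt$lnL, null$lnL))
  stat <- max(stat, 0)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df = df, lower.tail = FALSE))
}

#' Naive empirical-Bayes posteriors for the positive-selection class
#'
#' For an M2 or M8 fit, the per-site posterior probability of belonging to a
#' class with omega > 1: `prop_s L_site(omega_s) / sum_c prop_c L_site(c)`.
#'
#' @param fit A [fit_site_model] result for M2 or M8.
#' @param aln,tree The data the model was fitted to.
#' @return Data frame (one row per site): `site`, `posterior_pos`, `method`.
#' @export
neb_site_posteriors <- function(fit, aln, tree) {
  stopifnot(inherits(fit, "site_model_fit"))
  if (!fit$model_id %in% c("M2", "M8"))
    stop("NEB posteriors need a selection model (M2 or M8), got ", fit$model_id)
  mix <- .model_mixture(fit$model_id, fit$params, fit$k_categories)
  r <- .mixture_pattern_loglik(aln, tree, fit$pi, fit$kappa, mix$omegas,
                               mix$props, fit$branch_scale)
  ll <- r$loglik
  m <- apply(ll, 1, max)
  w <- exp(ll - m) * rep(mix$props, each = nrow(ll))
  post <- rowSums(w[, mix$omegas > 1, drop = FALSE]) / rowSums(w)
  data.frame(site = seq_along(r$site_pattern),
             posterior_pos = post[r$site_pattern],
             method = "NEB", stringsAsFactors = FALSE)
}
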