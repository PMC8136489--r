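# Tree/alignment plumbing for the pruning likelihood.

# integer codon-state matrix (1..61; 0 = gap/missing), rows in `taxa` order
.aln_state_matrix <- function(aln, taxa = aln$taxa) {
  cod <- aln$codons[match(taxa, aln$taxa), , drop = FALSE]
  st <- codon_index(cod)
  st[is.na(st)] <- 0L
  matrix(as.integer(st), nrow = length(taxa))
}

# collapse identical site patterns; returns states (n_tip x n_pat), weights,
# and the pattern index of every original site
.compress_patterns <- function(states) {
  key <- apply(states, 2, paste, collapse = ",")
  u <- !duplicated(key)
  idx <- match(key, key[u])
  list(states = states[, u, drop = FALSE],
       weights = as.numeric(tabulate(idx, nbins = sum(u))),
       site_pattern = idx)
}

# validate leaf concordance and put the tree in postorder
.prep_tree <- function(tree, taxa) {
  if (!inherits(tree, "phylo")) stop("tree must be an ape 'phylo' object")
  extra <- setdiff(tree$tip.label, taxa)
  missing <- setdiff(taxa, tree$tip.label)
  if (length(extra) || length(missing)) {
    stop("tree/alignment taxa mismatch; only in tree: {",
         paste(extra, collapse = ", "), "}; only in alignment: {",
         paste(missing, collapse = ", "), "}")
  }
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (any(tree$edge.length < 0)) stop("branch lengths must be non-negative")
  tree <- stats::reorder(tree, "postorder")
  list(edges = tree$edge, blens = tree$edge.length, tip_order = tree$tip.label)
}

# mixture site log-likelihoods on unique patterns.
# omegas/props define the site classes; the generator of every class is
# scaled by one common factor so the mixture-average substitution rate is 1
# (PAML convention), and branch lengths are multiplied by branch_scale.
.mixture_pattern_loglik <- function(aln, tree, pi, kappa, omegas, props,
                                    branch_scale = 1) {
  tp <- .prep_tree(tree, aln$taxa)
  states <- .aln_state_matrix(aln, tp$tip_order)
  cp <- .compress_patterns(states)
  qcube <- array(0, dim = c(61, 61, length(omegas)))
  mus <- numeric(length(omegas))
  for (c in seq_along(omegas)) {
    Q <- gy94_rate_matrix(codon_model_params(kappa, omegas[c], pi),
                          scale = FALSE)
    mus[c] <- -sum(pi * diag(Q))
    qcube[, , c] <- Q
  }
  mu_bar <- sum(props * mus)
  if (mu_bar <= 0) mu_bar <- 1
  ll <- site_loglik_mix(cp$states, tp$edges,
                        tp$blens * branch_scale / mu_bar, qcube, pi)
  list(loglik = ll, weights = cp$weights, site_pattern = cp$site_pattern)
}

#' Per-site log-likelihood under a single-class GY94 model
#'
#' Felsenstein pruning over the 61 sense-codon states; gap codons are treated
#' as missing data (flat partial likelihood).
#'
#' @param aln A cleaned [codon_alignment].
#' @param tree An `ape::phylo` tree whose leaf set equals the alignment taxa;
#'   branch lengths in expected substitutions per codon site.
#' @param params A [codon_model_params] object.
#' @param branch_scale Global multiplier applied to all branch lengths.
#' @return Numeric vector of per-site log-likelihoods (length `n_sites`).
#' @export
site_log_likelihood <- function(aln, tree, params, branch_scale = 1) {
  stopifnot(inherits(aln, "codon_alignment"),
            inherits(params, "codon_model_params"))
  r <- .mixture_pattern_loglik(aln, tree, params$pi, params$kappa,
                               params$omega, 1, branch_scale)
  as.numeric(r$loglik[r$site_pattern, 1])
}

# total mixture log-likelihood from a pattern loglik matrix
.total_loglik <- function(ll_mat, weights, props) {
  m <- apply(ll_mat, 1, max)
  site <- m + log(as.numeric(exp(ll_mat - m) %*% props))
  sum(weights * site)
}
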