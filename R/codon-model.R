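# GY94 codon substitution model with F3x4 equilibrium frequencies.

#' Codon model parameters
#'
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param omega dN/dS ratio (>= 0).
#' @param pi Vector of 61 sense-codon frequencies (alphabetical codon order,
#'   see [sense_codons()]), summing to 1.
#' @return An object of class `codon_model_params`.
#' @export
codon_model_params <- function(kappa, omega, pi) {
  stopifnot(is.finite(kappa), kappa > 0, is.finite(omega), omega >= 0)
  pi <- as.numeric(pi)
  if (length(pi) != 61) stop("pi must have 61 entries (sense codons)")
  if (any(pi < 0)) stop("pi must be non-negative")
  if (abs(sum(pi) - 1) > 1e-9) stop("pi must sum to 1 within 1e-9")
  structure(list(kappa = kappa, omega = omega, pi = pi),
            class = "codon_model_params")
}

#' F3x4 codon frequencies from an alignment
#'
#' Position-specific nucleotide frequencies (codon positions 1-3, gaps
#' ignored) are multiplied across positions, stop codons are dropped, and the
#' result is renormalised over the 61 sense codons.
#'
#' Codons whose product frequency is zero (an unobserved nucleotide at some
#' position) are floored at `floor_freq` so the reversible-model machinery
#' (which divides by `sqrt(pi)`) stays well conditioned.
#'
#' @param aln A cleaned [codon_alignment].
#' @param floor_freq Minimum codon frequency before renormalisation
#'   (default 1e-10).
#' @return Named numeric vector of 61 codon frequencies summing to 1.
#' @export
build_f3x4 <- function(aln, floor_freq = 1e-10) {
  stopifnot(inherits(aln, "codon_alignment"))
  cod <- aln$codons[.codon_is_clean(aln$codons)]
  if (length(cod) == 0) stop("no unambiguous codons in alignment")
  pos_freq <- matrix(0, nrow = 3, ncol = 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  for (p in 1:3) {
    nt <- substr(cod, p, p)
    tab <- table(factor(nt, levels = c("A", "C", "G", "T")))
    if (sum(tab) == 0) stop("codon position ", p, " has zero observed nucleotides")
    pos_freq[p, ] <- tab / sum(tab)
  }
  b1 <- substr(SENSE_CODONS, 1, 1)
  b2 <- substr(SENSE_CODONS, 2, 2)
  b3 <- substr(SENSE_CODONS, 3, 3)
  pi <- pos_freq[1, b1] * pos_freq[2, b2] * pos_freq[3, b3]
  if (sum(pi) <= 0) stop("degenerate F3x4 frequencies")
  pi <- pmax(pi, floor_freq)
  stats::setNames(pi / sum(pi), SENSE_CODONS)
}

#' GY94 instantaneous rate matrix
#'
#' Off-diagonal rate from codon i to j is zero unless the codons differ at a
#' single nucleotide; otherwise it is `pi_j`, multiplied by `kappa` for a
#' transition and by `omega` for a nonsynonymous change. Diagonals make rows
#' sum to zero. With `scale = TRUE` the matrix is rescaled so the expected
#' substitution rate at equilibrium is 1 (branch lengths then read as expected
#' substitutions per codon site at this omega).
#'
#' @param params A [codon_model_params] object.
#' @param scale Rescale to unit mean rate (default `TRUE`).
#' @return 61 x 61 generator matrix (rows sum to 0).
#' @export
gy94_rate_matrix <- function(params, scale = TRUE) {
  stopifnot(inherits(params, "codon_model_params"))
  tab <- .codon_pair_tables
  Q <- matrix(0, 61, 61, dimnames = list(SENSE_CODONS, SENSE_CODONS))
  Q[tab$single] <- rep(params$pi, each = 61)[tab$single]
  Q[tab$single & tab$transition] <- Q[tab$single & tab$transition] * params$kappa
  ns <- tab$single & !tab$synonymous
  Q[ns] <- Q[ns] * params$omega
  diag(Q) <- -rowSums(Q)
  if (scale) {
    mu <- -sum(params$pi * diag(Q))
    if (mu > 0) Q <- Q / mu
  }
  Q
}

# Symmetric eigendecomposition of a reversible generator; P(t) = exp(Qt)
# recovered as S^-1 V exp(L t) V' S with S = diag(sqrt(pi)).
.q_eigen <- function(Q, pi) {
  sq <- sqrt(pi)
  B <- Q * outer(sq, 1 / sq)
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  list(vals = e$values,
       left = e$vectors / sq,          # S^-1 V  (rows scaled)
       right = t(e$vectors * sq))      # V' S
}

.transition_matrix <- function(qe, t) {
  P <- qe$left %*% (exp(qe$vals * t) * qe$right)
  P[P < 0] <- 0
  P
}
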