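# Standard genetic code and codon bookkeeping shared by the selection-scan
# machinery. Codon order everywhere is alphabetical (A < C < G < T) over the
# 61 sense codons; ties in parsimony are broken in this order.

.base_order_tcag <- c("T", "C", "A", "G")

.genetic_code <- local({
  aas <- strsplit(
    "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG",
    ""
  )[[1]]
  codons <- character(64)
  k <- 0L
  for (b1 in .base_order_tcag) for (b2 in .base_order_tcag) for (b3 in .base_order_tcag) {
    k <- k + 1L
    codons[k] <- paste0(b1, b2, b3)
  }
  stats::setNames(aas, codons)
})

STOP_CODONS <- names(.genetic_code)[.genetic_code == "*"]

#' Sense codons in alphabetical order
#'
#' The 61 codons of the standard genetic code that encode an amino acid,
#' sorted alphabetically (A < C < G < T). This ordering defines codon state
#' indices throughout the package.
#' @return Character vector of length 61.
#' @export
sense_codons <- function() SENSE_CODONS

SENSE_CODONS <- sort(names(.genetic_code)[.genetic_code != "*"])

CODON_AA <- unname(.genetic_code[SENSE_CODONS])

GAP_CODON <- "---"

codon_index <- function(codons) match(codons, SENSE_CODONS)

translate_codon <- function(codon) {
  aa <- .genetic_code[codon]
  ifelse(is.na(aa), NA_character_, unname(aa))
}

is_stop_codon <- function(codon) codon %in% STOP_CODONS

# purine/pyrimidine transition test for a pair of single nucleotides
.is_transition_nt <- function(a, b) {
  (a == "A" & b == "G") | (a == "G" & b == "A") |
    (a == "C" & b == "T") | (a == "T" & b == "C")
}

# Pairwise structure of the 61-state codon space, computed once at load:
# number of differing positions, transition vs transversion (single-nt pairs),
# synonymous vs nonsynonymous.
.codon_pair_tables <- local({
  n <- length(SENSE_CODONS)
  mat <- matrix(unlist(strsplit(SENSE_CODONS, "")), nrow = n, byrow = TRUE)
  ndiff <- matrix(0L, n, n)
  for (p in 1:3) ndiff <- ndiff + outer(mat[, p], mat[, p], "!=")
  single <- ndiff == 1L
  transition <- matrix(FALSE, n, n)
  for (p in 1:3) {
    d <- outer(mat[, p], mat[, p], "!=")
    tr <- outer(mat[, p], mat[, p], .is_transition_nt)
    transition <- transition | (single & d & tr)
  }
  synonymous <- outer(CODON_AA, CODON_AA, "==")
  list(ndiff = ndiff, single = single, transition = transition,
       synonymous = synonymous)
})
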