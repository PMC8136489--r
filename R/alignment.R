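# Codon and protein alignment containers, FASTA IO, cleaning and the
# column-identity divergence statistic.

#' Construct a codon alignment
#'
#' A codon alignment is the unit all selection statistics operate on: an
#' in-frame, gap-aware matrix of codons (rows = taxa, columns = codon sites).
#'
#' @param codons Character matrix of 3-letter codons (rows named by taxon, or
#'   supply `taxa`), using `-` for gaps (`"---"` is a gapped codon).
#' @param taxa Character vector of unique taxon labels.
#' @return An object of class `codon_alignment` with fields `taxa`, `codons`
#'   and `n_sites`.
#' @export
codon_alignment <- function(codons, taxa = rownames(codons)) {
  if (is.null(taxa)) stop("taxon labels required")
  codons <- as.matrix(codons)
  if (anyDuplicated(taxa)) stop("taxon labels must be unique")
  if (length(taxa) != nrow(codons)) stop("taxa/row mismatch")
  if (ncol(codons) > 0 && any(nchar(codons) != 3L)) stop("all codons must be 3 characters")
  rownames(codons) <- taxa
  structure(
    list(taxa = as.character(taxa), codons = codons, n_sites = ncol(codons)),
    class = "codon_alignment"
  )
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat(sprintf("codon_alignment: %d taxa x %d codon sites\n",
              length(x$taxa), x$n_sites))
  invisible(x)
}

#' Construct a protein alignment
#'
#' @param residues Character matrix of one-letter residues (`-` for gap).
#' @param taxa Unique taxon labels.
#' @return An object of class `protein_alignment`.
#' @export
protein_alignment <- function(residues, taxa = rownames(residues)) {
  if (is.null(taxa)) stop("taxon labels required")
  residues <- as.matrix(residues)
  if (anyDuplicated(taxa)) stop("taxon labels must be unique")
  rownames(residues) <- taxa
  structure(
    list(taxa = as.character(taxa), residues = residues,
         n_sites = ncol(residues)),
    class = "protein_alignment"
  )
}

#' @export
print.protein_alignment <- function(x, ...) {
  cat(sprintf("protein_alignment: %d taxa x %d residue columns\n",
              length(x$taxa), x$n_sites))
  invisible(x)
}

# FASTA records as named uppercase strings, order preserved
.read_fasta_chars <- function(path) {
  x <- Biostrings::readBStringSet(path)
  if (length(x) == 0) stop("empty FASTA file: ", path)
  seqs <- toupper(as.character(x))
  names(seqs) <- sub("\\s.*$", "", names(x))
  seqs
}

#' Read an aligned FASTA file
#'
#' Reads a nucleotide FASTA into a [codon_alignment] (the aligned length must
#' be divisible by 3) or a protein FASTA into a [protein_alignment]. Record
#' order is preserved. Ragged record lengths are a hard error naming the
#' offending record.
#'
#' @param path Path to an aligned FASTA file (gap character `-`).
#' @param kind `"nucleotide"` or `"protein"`.
#' @return A [codon_alignment] or [protein_alignment].
#' @export
read_alignment <- function(path, kind = c("nucleotide", "protein")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  seqs <- .read_fasta_chars(path)
  widths <- nchar(seqs)
  if (length(unique(widths)) > 1) {
    bad <- which(widths != widths[1])[1]
    stop(sprintf(
      "alignment is ragged: record %d ('%s') has length %d, expected %d",
      bad, names(seqs)[bad], widths[bad], widths[1]))
  }
  mat <- matrix(unlist(strsplit(seqs, "")), nrow = length(seqs), byrow = TRUE)
  rownames(mat) <- names(seqs)
  if (kind == "protein") return(protein_alignment(mat))
  if (widths[1] %% 3 != 0)
    stop("aligned nucleotide length ", widths[1], " is not divisible by 3")
  n_sites <- widths[1] %/% 3
  cod <- matrix("", nrow = nrow(mat), ncol = n_sites,
                dimnames = list(rownames(mat), NULL))
  for (k in seq_len(n_sites)) {
    cod[, k] <- paste0(mat[, 3 * k - 2], mat[, 3 * k - 1], mat[, 3 * k])
  }
  codon_alignment(cod)
}

#' Write an alignment to FASTA
#'
#' @param aln A [codon_alignment] or [protein_alignment].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  rows <- if (inherits(aln, "codon_alignment")) {
    apply(aln$codons, 1, paste, collapse = "")
  } else {
    apply(aln$residues, 1, paste, collapse = "")
  }
  writeLines(paste0(">", aln$taxa, "\n", rows), path)
  invisible(path)
}

.codon_is_gap <- function(codon) codon == GAP_CODON

.codon_is_clean <- function(codon) {
  grepl("^[ACGT]{3}$", codon)
}

#' Remove ambiguous and stop-codon columns
#'
#' Drops every codon column containing a stop codon in any taxon, or any
#' ambiguity (a codon that is neither three unambiguous bases `ACGT` nor the
#' full gap `---`; partially gapped codons count as ambiguous). Whole columns
#' are removed so the taxon set stays concordant with the tree.
#'
#' @param aln A [codon_alignment].
#' @return The cleaned [codon_alignment], carrying a `removal_log` attribute:
#'   a data frame with 1-based `column` indices (strictly increasing, relative
#'   to the input alignment) and `reason` (`stop_codon` and/or `ambiguity`).
#' @export
clean_codon_alignment <- function(aln) {
  stopifnot(inherits(aln, "codon_alignment"))
  has_stop <- apply(aln$codons, 2, function(col) any(is_stop_codon(col)))
  has_amb <- apply(aln$codons, 2, function(col) {
    any(!.codon_is_clean(col) & !.codon_is_gap(col) & !is_stop_codon(col))
  })
  drop <- has_stop | has_amb
  if (all(drop)) stop("cleaning removed every column of the alignment")
  reason <- ifelse(
    has_stop & has_amb, "stop_codon;ambiguity",
    ifelse(has_stop, "stop_codon", "ambiguity")
  )[drop]
  log <- data.frame(column = which(drop), reason = reason,
                    stringsAsFactors = FALSE)
  out <- codon_alignment(aln$codons[, !drop, drop = FALSE], aln$taxa)
  attr(out, "removal_log") <- log
  out
}

#' Write a column-removal log as TSV
#'
#' @param aln A cleaned [codon_alignment] (output of [clean_codon_alignment]).
#' @param path Output TSV path (`column<TAB>reason`).
#' @return `path`, invisibly.
#' @export
write_removal_log <- function(aln, path) {
  log <- attr(aln, "removal_log")
  if (is.null(log)) log <- data.frame(column = integer(0), reason = character(0))
  utils::write.table(log, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Fraction of fully identical alignment columns
#'
#' The divergence statistic reported for ortholog alignments: the fraction of
#' counted columns in which every sequence carries the identical residue.
#' With `exclude_gap_columns` (default) any column containing a gap is removed
#' from the denominator; with `count_gap_columns` all columns are counted and
#' a gap-containing column is never identical.
#'
#' @param aln A [protein_alignment] (or [codon_alignment], scored on codons).
#' @param gap_policy `"exclude_gap_columns"` or `"count_gap_columns"`.
#' @return Fraction in `[0, 1]`.
#' @export
percent_identity <- function(aln,
                             gap_policy = c("exclude_gap_columns",
                                            "count_gap_columns")) {
  gap_policy <- match.arg(gap_policy)
  mat <- if (inherits(aln, "codon_alignment")) aln$codons else aln$residues
  if (nrow(mat) < 2) stop("percent identity needs at least 2 sequences")
  gapchr <- if (inherits(aln, "codon_alignment")) GAP_CODON else "-"
  has_gap <- apply(mat, 2, function(col) any(col == gapchr))
  mono <- apply(mat, 2, function(col) all(col == col[1]))
  if (gap_policy == "exclude_gap_columns") {
    counted <- !has_gap
    if (!any(counted)) stop("no gap-free columns to count")
    sum(mono & counted) / sum(counted)
  } else {
    sum(mono & !has_gap) / ncol(mat)
  }
}

#' Translate a cleaned codon alignment
#'
#' Standard-code translation, column k of the protein alignment corresponding
#' to codon column k; gap codons map to `-`. A residual stop codon is a hard
#' error (the cleaning contract was violated).
#'
#' @param aln A cleaned [codon_alignment].
#' @return A [protein_alignment].
#' @export
translate_alignment <- function(aln) {
  stopifnot(inherits(aln, "codon_alignment"))
  if (any(is_stop_codon(aln$codons)))
    stop("alignment contains stop codons; run clean_codon_alignment() first")
  aa <- matrix(translate_codon(aln$codons), nrow = nrow(aln$codons))
  aa[.codon_is_gap(aln$codons)] <- "-"
  if (any(is.na(aa)))
    stop("alignment contains ambiguous codons; run clean_codon_alignment() first")
  rownames(aa) <- aln$taxa
  protein_alignment(aa)
}
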