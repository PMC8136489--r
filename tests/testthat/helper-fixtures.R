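# Shared fixtures and independent oracles.

tmp_fasta <- function(seqs, path = tempfile(fileext = ".fasta")) {
  writeLines(paste0(">", names(seqs), "\n", unname(seqs)), path)
  path
}

aln_from_strings <- function(seqs) {
  read_alignment(tmp_fasta(seqs), "nucleotide")
}

paln_from_strings <- function(seqs) {
  read_alignment(tmp_fasta(seqs), "protein")
}

# Brute-force codon site likelihood by explicit enumeration of all internal
# node states; transition matrices via Matrix::expm, independent of the
# pruning engine's eigendecomposition route. Gapped tips contribute no edge
# factor (their state marginalises to 1).
brute_force_site_loglik <- function(aln, tree, params, branch_scale = 1) {
  codons <- sense_codons()
  tre <- stats::reorder(tree, "postorder")
  edges <- tre$edge
  n_tip <- length(tre$tip.label)
  n_node <- max(edges)
  internal <- (n_tip + 1):n_node
  root <- edges[nrow(edges), 1]
  Q <- gy94_rate_matrix(params, scale = TRUE)
  P <- lapply(seq_len(nrow(edges)), function(e) {
    as.matrix(Matrix::expm(Q * tre$edge.length[e] * branch_scale))
  })
  obs <- aln$codons[match(tre$tip.label, aln$taxa), , drop = FALSE]
  combos <- as.matrix(expand.grid(rep(list(seq_len(61)), length(internal))))
  vapply(seq_len(aln$n_sites), function(s) {
    lik <- params$pi[combos[, match(root, internal)]]
    for (e in seq_len(nrow(edges))) {
      p_state <- combos[, match(edges[e, 1], internal)]
      ch <- edges[e, 2]
      if (ch <= n_tip) {
        cod <- obs[ch, s]
        if (cod == "---") next
        ci <- match(cod, codons)
        lik <- lik * P[[e]][cbind(p_state, ci)]
      } else {
        c_state <- combos[, match(ch, internal)]
        lik <- lik * P[[e]][cbind(p_state, c_state)]
      }
    }
    log(sum(lik))
  }, numeric(1))
}

# exhaustive minimum-change parsimony score of one codon site by enumerating
# every internal-node assignment (for tiny trees)
brute_force_parsimony <- function(aln, tree, site) {
  codons <- sense_codons()
  tre <- stats::reorder(tree, "postorder")
  edges <- tre$edge
  n_tip <- length(tre$tip.label)
  internal <- (n_tip + 1):max(edges)
  obs <- match(aln$codons[match(tre$tip.label, aln$taxa), site], codons)
  combos <- as.matrix(expand.grid(rep(list(seq_len(61)), length(internal))))
  changes <- rep(0L, nrow(combos))
  for (e in seq_len(nrow(edges))) {
    p_state <- combos[, match(edges[e, 1], internal)]
    ch <- edges[e, 2]
    c_state <- if (ch <= n_tip) rep(obs[ch], nrow(combos))
               else combos[, match(ch, internal)]
    changes <- changes + (p_state != c_state)
  }
  min(changes)
}

# number of state changes implied by a fitch_ancestral assignment at a site
fitch_changes <- function(anc, site) {
  edges <- stats::reorder(anc$tree, "postorder")$edge
  st <- anc$states[, site]
  sum(st[edges[, 1]] != st[edges[, 2]], na.rm = TRUE)
}

random_rotation <- function() {
  ang <- stats::runif(3, 0, 2 * pi)
  Rx <- rbind(c(1, 0, 0), c(0, cos(ang[1]), -sin(ang[1])),
              c(0, sin(ang[1]), cos(ang[1])))
  Ry <- rbind(c(cos(ang[2]), 0, sin(ang[2])), c(0, 1, 0),
              c(-sin(ang[2]), 0, cos(ang[2])))
  Rz <- rbind(c(cos(ang[3]), -sin(ang[3]), 0),
              c(sin(ang[3]), cos(ang[3]), 0), c(0, 0, 1))
  Rx %*% Ry %*% Rz
}

# minimal hand-built PDB text (fixed-width ATOM records)
write_mini_pdb <- function(df, path = tempfile(fileext = ".pdb")) {
  alt <- if (is.null(df$alt)) rep(" ", nrow(df)) else df$alt
  lines <- sprintf(
    "%-6s%5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    df$type, df$serial, df$atom, alt,
    df$resname, df$chain, df$resno, df$x, df$y, df$z, df$occ, df$b,
    df$element)
  writeLines(c(lines, "END"), path)
  path
}
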