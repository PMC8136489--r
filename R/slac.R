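# SLAC-style counting scan: Fitch parsimony ancestral codons, per-branch
# synonymous/nonsynonymous change counting with minimal-path averaging, and
# NG86-style expected site counts.

# Per-codon expected synonymous site count: over the non-stop single-nt
# neighbours of a codon, 3 times the synonymous fraction (so S + N = 3).
.codon_syn_sites <- local({
  tab <- .codon_pair_tables
  vapply(seq_len(61), function(i) {
    nb <- which(tab$single[i, ])
    if (length(nb) == 0) return(0)
    3 * sum(tab$synonymous[i, nb]) / length(nb)
  }, numeric(1))
})

# Average synonymous/nonsynonymous step counts over minimal mutational paths
# between two codons. Orderings passing through a stop codon are discarded;
# if every ordering does, all paths are used with steps into/out of stops
# scored as nonsynonymous.
.codon_path_counts <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  diff_pos <- which(ca != cb)
  d <- length(diff_pos)
  if (d == 0) return(c(syn = 0, nonsyn = 0))
  perms <- if (d == 1) list(diff_pos) else {
    if (d == 2) lapply(list(c(1, 2), c(2, 1)), function(o) diff_pos[o])
    else lapply(list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1)),
                function(o) diff_pos[o])
  }
  score_path <- function(order) {
    cur <- ca
    syn <- 0; nonsyn <- 0; valid <- TRUE
    for (p in order) {
      nxt <- cur
      nxt[p] <- cb[p]
      aa1 <- .genetic_code[paste(cur, collapse = "")]
      aa2 <- .genetic_code[paste(nxt, collapse = "")]
      if (aa2 == "*" || aa1 == "*") valid <- FALSE
      if (identical(unname(aa1), unname(aa2)) && aa1 != "*") syn <- syn + 1
      else nonsyn <- nonsyn + 1
      cur <- nxt
    }
    c(syn = syn, nonsyn = nonsyn, valid = as.numeric(valid))
  }
  sc <- vapply(perms, score_path, numeric(3))
  use <- sc["valid", ] == 1
  if (!any(use)) use <- rep(TRUE, ncol(sc))
  c(syn = mean(sc["syn", use]), nonsyn = mean(sc["nonsyn", use]))
}

# root an unrooted tree at a fixed, documented leaf (the first alignment taxon)
.ensure_rooted <- function(tree, taxa) {
  if (ape::is.rooted(tree)) return(tree)
  ape::root(tree, outgroup = taxa[1], resolve.root = TRUE)
}

#' Fitch parsimony ancestral codon states
#'
#' Per-site Fitch parsimony over the 61 sense-codon states on a rooted tree
#' (unrooted trees are rooted at the first alignment taxon). Gap codons at
#' tips act as wildcards. Ambiguity in the final assignment is broken by
#' alphabetical codon order and every non-forced choice is recorded.
#'
#' @param aln A cleaned [codon_alignment].
#' @param tree `ape::phylo`; leaf set must equal the alignment taxa.
#' @return An object of class `ancestral_states`: `states` (node x site
#'   matrix of codon indices into [sense_codons()]; `NA` for gapped tips),
#'   `ties` (data frame: site, node, candidates), and the rooted, postordered
#'   `tree` the node numbering refers to.
#' @export
fitch_ancestral <- function(aln, tree) {
  stopifnot(inherits(aln, "codon_alignment"))
  tree <- .ensure_rooted(tree, aln$taxa)
  tp <- .prep_tree(tree, aln$taxa)
  tree <- stats::reorder(tree, "postorder")
  n_tip <- length(tp$tip_order)
  n_node <- max(tp$edges)
  obs <- .aln_state_matrix(aln, tp$tip_order)
  n_sites <- ncol(obs)
  states <- matrix(NA_integer_, n_node, n_sites)
  ties <- list()

  children <- split(tp$edges[, 2], tp$edges[, 1])
  node_order <- unique(tp$edges[, 1])          # postorder parents
  root <- tp$edges[nrow(tp$edges), 1]

  for (s in seq_len(n_sites)) {
    sets <- matrix(FALSE, n_node, 61)
    for (i in seq_len(n_tip)) {
      if (obs[i, s] > 0) sets[i, obs[i, s]] <- TRUE else sets[i, ] <- TRUE
    }
    for (nd in node_order) {
      ch <- children[[as.character(nd)]]
      inter <- rep(TRUE, 61)
      for (c in ch) inter <- inter & sets[c, ]
      if (any(inter)) sets[nd, ] <- inter
      else {
        uni <- rep(FALSE, 61)
        for (c in ch) uni <- uni | sets[c, ]
        sets[nd, ] <- uni
      }
    }
    # top-down assignment, preorder
    rs <- which(sets[root, ])
    states[root, s] <- rs[1]
    if (length(rs) > 1)
      ties[[length(ties) + 1]] <- data.frame(
        site = s, node = root,
        candidates = paste(SENSE_CODONS[rs], collapse = ","))
    for (e in rev(seq_len(nrow(tp$edges)))) {
      p <- tp$edges[e, 1]; ch <- tp$edges[e, 2]
      if (ch <= n_tip) {
        states[ch, s] <- if (obs[ch, s] > 0) obs[ch, s] else NA_integer_
        next
      }
      cs <- which(sets[ch, ])
      if (sets[ch, states[p, s]]) states[ch, s] <- states[p, s]
      else {
        states[ch, s] <- cs[1]
        if (length(cs) > 1)
          ties[[length(ties) + 1]] <- data.frame(
            site = s, node = ch,
            candidates = paste(SENSE_CODONS[cs], collapse = ","))
      }
    }
  }
  ties <- if (length(ties)) do.call(rbind, ties)
          else data.frame(site = integer(0), node = integer(0),
                          candidates = character(0))
  structure(list(states = states, ties = ties, tree = tree,
                 tip_order = tp$tip_order),
            class = "ancestral_states")
}

#' SLAC-style counting scan for site-wise selection
#'
#' For every codon column, counts observed synonymous and nonsynonymous
#' changes along branches between parsimony-reconstructed ancestral codons
#' (averaging over minimal mutational paths for multi-step changes; branches
#' with a gapped endpoint contribute nothing), computes NG86-style expected
#' synonymous/nonsynonymous site counts from the observed codon composition,
#' and tests nonsynonymous excess with a two-tailed binomial test on the
#' (rounded) change counts.
#'
#' @param aln A cleaned [codon_alignment].
#' @param tree `ape::phylo`; leaf set must equal the alignment taxa.
#' @param ancestors Optional precomputed [fitch_ancestral] result.
#' @return Data frame, one row per retained site: `site`, `n_syn`, `n_nonsyn`
#'   (possibly fractional), `es`, `en` (expected site counts), `dn`, `ds`,
#'   `dnds`, `p_value`, `method`. Sites with zero expected sites of either
#'   class are excluded and listed in the `excluded_sites` attribute.
#' @export
slac_site_scan <- function(aln, tree, ancestors = NULL) {
  stopifnot(inherits(aln, "codon_alignment"))
  if (is.null(ancestors)) ancestors <- fitch_ancestral(aln, tree)
  st <- ancestors$states
  tp <- .prep_tree(ancestors$tree, aln$taxa)
  n_tip <- length(tp$tip_order)
  obs <- .aln_state_matrix(aln, tp$tip_order)
  n_sites <- ncol(obs)

  # cache path counts for codon pairs seen at this scan
  path_cache <- new.env(hash = TRUE, parent = emptyenv())
  pair_counts <- function(i, j) {
    key <- paste0(i, "_", j)
    hit <- path_cache[[key]]
    if (!is.null(hit)) return(hit)
    v <- .codon_path_counts(SENSE_CODONS[i], SENSE_CODONS[j])
    path_cache[[key]] <- v
    v
  }

  rows <- vector("list", n_sites)
  excluded <- integer(0)
  for (s in seq_len(n_sites)) {
    syn <- 0; nonsyn <- 0
    for (e in seq_len(nrow(tp$edges))) {
      a <- st[tp$edges[e, 1], s]
      b <- st[tp$edges[e, 2], s]
      if (is.na(a) || is.na(b) || a == b) next
      pc <- pair_counts(a, b)
      syn <- syn + pc[["syn"]]
      nonsyn <- nonsyn + pc[["nonsyn"]]
    }
    tip_states <- obs[, s]
    tip_states <- tip_states[tip_states > 0]
    if (length(tip_states) == 0) { excluded <- c(excluded, s); next }
    es <- mean(.codon_syn_sites[tip_states])
    en <- 3 - es
    if (es <= 0 || en <= 0) { excluded <- c(excluded, s); next }
    n_tot <- round(syn + nonsyn)
    k <- min(round(nonsyn), n_tot)
    p <- if (n_tot == 0) 1 else
      stats::binom.test(k, n_tot, p = en / 3)$p.value
    dn <- nonsyn / en
    ds <- syn / es
    rows[[s]] <- data.frame(
      site = s, n_syn = syn, n_nonsyn = nonsyn, es = es, en = en,
      dn = dn, ds = ds,
      dnds = if (ds > 0) dn / ds else if (dn > 0) Inf else NA_real_,
      p_value = p, method = "SLAC", stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  attr(out, "excluded_sites") <- excluded
  out
}

#' Intersect ML and counting evidence into a selected-site set
#'
#' A site is called positively selected iff its NEB posterior for the
#' omega > 1 class is at least `posterior_cut` and its counting-scan p-value
#' is at most `p_cut`. Raw p-values drive the call; a Benjamini-Hochberg
#' adjusted column is reported alongside.
#'
#' @param ml Data frame from [neb_site_posteriors].
#' @param counting Data frame from [slac_site_scan].
#' @param posterior_cut Posterior threshold (default 0.9).
#' @param p_cut Counting p-value threshold (default 0.1).
#' @return Data frame with `site`, `posterior_pos`, `p_value`, `bh_q`,
#'   `selected`; the selected sites are `$site[$selected]`.
#' @export
classify_selected_sites <- function(ml, counting, posterior_cut = 0.9,
                                    p_cut = 0.1) {
  common <- intersect(ml$site, counting$site)
  if (!setequal(ml$site, counting$site)) {
    only_ml <- setdiff(ml$site, counting$site)
    only_ct <- setdiff(counting$site, ml$site)
    # counting legitimately drops zero-expectation sites; anything else is
    # a contract violation
    if (length(only_ct))
      stop("site sets mismatch; counting-only sites: ",
           paste(only_ct, collapse = ", "))
  }
  m <- merge(ml[, c("site", "posterior_pos")],
             counting[, c("site", "p_value")], by = "site")
  m <- m[order(m$site), ]
  m$bh_q <- stats::p.adjust(m$p_value, method = "BH")
  m$selected <- m$posterior_pos >= posterior_cut & m$p_value <= p_cut
  rownames(m) <- NULL
  m
}

#' Write a per-site scan table as TSV
#'
#' @param df A data frame from any of the site-scan functions.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_site_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
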