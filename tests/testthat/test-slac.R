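test_that("minimal-path change counting matches enumeration of orderings", {
  pc <- lipidshift:::.codon_path_counts
  # single synonymous step
  expect_equal(pc("AAA", "AAG"), c(syn = 1, nonsyn = 0))
  # single nonsynonymous step
  expect_equal(pc("AAA", "AGA"), c(syn = 0, nonsyn = 1))
  # AAA -> ACG, both orderings enumerated by hand:
  #   AAA -> ACA (K->T, nonsyn) -> ACG (T->T, syn)
  #   AAA -> AAG (K->K, syn)    -> ACG (K->T, nonsyn)
  # average: 1 syn + 1 nonsyn
  expect_equal(pc("AAA", "ACG"), c(syn = 1, nonsyn = 1))
  # orderings through stops are discarded: TCA -> TTG
  #   TCA -> TTA (S->L, nonsyn) -> TTG (L->L, syn)
  #   TCA -> TCG (S->S, syn)    -> TTG (S->L, nonsyn)
  # neither passes a stop: average 1/1
  expect_equal(pc("TCA", "TTG"), c(syn = 1, nonsyn = 1))
  # TGC -> TGG: direct path passes no stop; C->W nonsynonymous
  expect_equal(pc("TGC", "TGG"), c(syn = 0, nonsyn = 1))
  # AGA -> TGG: ordering via TGA (stop) is discarded, leaving
  #   AGA -> AGG (R->R syn) -> TGG (R->W nonsyn)
  expect_equal(pc("AGA", "TGG"), c(syn = 1, nonsyn = 1))
})

test_that("NG86-style expected synonymous site counts match hand values", {
  s <- lipidshift:::.codon_syn_sites
  cods <- sense_codons()
  # AAA (Lys): neighbours excluding TAA; 8 non-stop, 1 synonymous (AAG)
  expect_equal(s[match("AAA", cods)], 3 * 1 / 8)
  # TGG (Trp): neighbours exclude TGA and TAG; 7 non-stop, none synonymous
  expect_equal(s[match("TGG", cods)], 0)
  # GGG (Gly): 9 non-stop neighbours, 3 synonymous (GGA, GGC, GGT)
  expect_equal(s[match("GGG", cods)], 1)
})

test_that("Fitch ancestral states are parsimonious and tie-aware", {
  # invariant site: every internal node carries the tip codon
  tr <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  inv <- codon_alignment(matrix("ATG", 4, 1), c("a", "b", "c", "d"))
  anc <- fitch_ancestral(inv, tr)
  expect_true(all(anc$states == match("ATG", sense_codons())))
  expect_equal(nrow(anc$ties), 0)

  # two-leaf disagreement: root tie recorded, alphabetical winner
  tr2 <- ape::read.tree(text = "(a:1,b:1);")
  dis <- codon_alignment(matrix(c("ATG", "CTG"), 2, 1), c("a", "b"))
  anc2 <- fitch_ancestral(dis, tr2)
  root <- nrow(dis$codons) + 1
  expect_equal(sense_codons()[anc2$states[root, 1]], "ATG")
  expect_equal(anc2$ties$site, 1)
  expect_match(anc2$ties$candidates, "ATG,CTG")

  # leaf assignments always equal the observed data
  expect_equal(anc2$states[1:2, 1],
               match(c("ATG", "CTG"), sense_codons()))

  # 4-taxon cases: the Fitch assignment achieves the exhaustive minimum
  withr::with_seed(19, {
    for (rep in 1:5) {
      cods <- sample(sense_codons(), 4, replace = TRUE)
      aln <- codon_alignment(matrix(cods, 4, 1), c("a", "b", "c", "d"))
      anc4 <- fitch_ancestral(aln, tr)
      expect_equal(fitch_changes(anc4, 1), brute_force_parsimony(aln, tr, 1))
    }
  })
})

test_that("SLAC scan counts changes and tests nonsynonymous excess", {
  tr <- ape::read.tree(text = "(a:1,b:1);")
  # column 1 invariant; column 2 a single synonymous change AAA->AAG
  aln <- codon_alignment(matrix(c("AAA", "AAA", "AAA", "AAG"), 2, 2,
                                byrow = TRUE), c("a", "b"))
  res <- slac_site_scan(aln, tr)
  expect_equal(res$n_syn, c(0, 1))
  expect_equal(res$n_nonsyn, c(0, 0))
  expect_equal(res$dn[1], 0)
  expect_equal(res$ds[1], 0)
  expect_equal(res$p_value[1], 1)
  # expected sites for the AAA/AAG column: mean of hand NG86 values
  s <- lipidshift:::.codon_syn_sites
  cods <- sense_codons()
  es_hand <- mean(s[match(c("AAA", "AAG"), cods)])
  expect_equal(res$es[2], es_hand)
  expect_equal(res$ds[2], 1 / es_hand)

  # taxon-order permutation invariance
  aln_p <- codon_alignment(aln$codons[2:1, ], aln$taxa[2:1])
  res_p <- slac_site_scan(aln_p, tr)
  expect_equal(res_p$n_syn, res$n_syn)
  expect_equal(res_p$p_value, res$p_value)
})

test_that("site classification intersects posterior and counting evidence", {
  ml <- data.frame(site = 1:4, posterior_pos = c(0.95, 0.95, 0.5, 0.99))
  ct <- data.frame(site = 1:4, p_value = c(0.05, 0.5, 0.01, 0.1))
  out <- classify_selected_sites(ml, ct)
  expect_equal(out$site[out$selected], c(1, 4))
  expect_true(all(c("bh_q") %in% names(out)))
  expect_equal(out$bh_q, p.adjust(ct$p_value, "BH"))

  ct_extra <- data.frame(site = 1:5, p_value = rep(0.05, 5))
  expect_error(classify_selected_sites(ml, ct_extra), "mismatch")
})
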