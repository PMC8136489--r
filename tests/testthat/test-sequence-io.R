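test_that("FASTA reading preserves order and enforces rectangular alignments", {
  aln <- aln_from_strings(c(s1 = "ATGGCT", s2 = "ATGGCT"))
  expect_s3_class(aln, "codon_alignment")
  expect_equal(aln$n_sites, 2)
  expect_equal(aln$taxa, c("s1", "s2"))

  ragged <- tmp_fasta(c(a = "ATGGCT", b = "ATGGCTATG"))
  expect_error(read_alignment(ragged, "nucleotide"), "record 2.*'b'")

  empty <- tempfile(fileext = ".fasta")
  writeLines(character(0), empty)
  expect_error(read_alignment(empty, "nucleotide"), "empty")

  expect_error(read_alignment(tmp_fasta(c(a = "ATGG", b = "ATGG")),
                              "nucleotide"), "divisible by 3")
  expect_error(codon_alignment(matrix("ATG", 2, 1), c("a", "a")), "unique")
})

test_that("cleaning drops stop and ambiguity columns and is idempotent", {
  aln <- aln_from_strings(c(
    a = "ATGTAAGCTNNNGGA---",
    b = "ATGGCTGCTAAAGGAATG"))
  cl <- clean_codon_alignment(aln)
  log <- attr(cl, "removal_log")
  expect_equal(cl$n_sites, 4)
  expect_equal(log$column, c(2, 4))
  expect_equal(log$reason, c("stop_codon", "ambiguity"))
  expect_true(all(diff(log$column) > 0))

  # partially gapped codons count as ambiguity; full gaps survive
  expect_equal(unname(cl$codons[1, 4]), "---")

  cl2 <- clean_codon_alignment(cl)
  expect_equal(cl2$codons, cl$codons)
  expect_equal(nrow(attr(cl2, "removal_log")), 0)

  all_stop <- aln_from_strings(c(a = "TAA", b = "TGA"))
  expect_error(clean_codon_alignment(all_stop), "every column")
})

test_that("percent identity counts monomorphic columns under both gap policies", {
  p <- paln_from_strings(c(a = "AC", b = "AD"))
  expect_equal(percent_identity(p), 0.5)

  self2 <- paln_from_strings(c(a = "MKVL", b = "MKVL"))
  expect_equal(percent_identity(self2), 1.0)

  # gap policy: column 3 has a gap; identical columns: 1, 2
  g <- paln_from_strings(c(a = "MK-L", b = "MKVL", c = "MKVI"))
  expect_equal(percent_identity(g, "exclude_gap_columns"), 2 / 3)
  expect_equal(percent_identity(g, "count_gap_columns"), 2 / 4)

  # permutation invariance over sequence order
  perm <- paln_from_strings(c(c = "MKVI", a = "MK-L", b = "MKVL"))
  expect_equal(percent_identity(perm), percent_identity(g))

  single <- protein_alignment(matrix(c("M", "K"), 1, 2), "a")
  expect_error(percent_identity(single), "at least 2")
})

test_that("translation follows the standard code and preserves columns", {
  aln <- aln_from_strings(c(a = "ATGGCT", b = "---GCT"))
  p <- translate_alignment(aln)
  expect_equal(unname(p$residues[1, ]), c("M", "A"))
  expect_equal(unname(p$residues[2, ]), c("-", "A"))

  withr::with_seed(42, {
    codons <- sample(sense_codons(), 50 * 3, replace = TRUE)
    m <- matrix(codons, nrow = 3)
    rand <- codon_alignment(m, c("x", "y", "z"))
    expect_equal(translate_alignment(rand)$n_sites, rand$n_sites)
  })

  stopy <- codon_alignment(matrix(c("ATG", "TAA"), 1, 2), "a")
  expect_error(translate_alignment(stopy), "stop")
})

test_that("clean then translate never raises on messy simulated input", {
  withr::with_seed(7, {
    for (rep in 1:5) {
      bases <- c("A", "C", "G", "T", "N", "-")
      m <- matrix(sample(bases, 4 * 30, replace = TRUE, prob = c(rep(0.23, 4), 0.04, 0.04)),
                  nrow = 4)
      seqs <- apply(m, 1, paste, collapse = "")
      names(seqs) <- paste0("t", 1:4)
      aln <- aln_from_strings(seqs)
      cl <- tryCatch(clean_codon_alignment(aln), error = function(e) NULL)
      if (!is.null(cl)) expect_no_error(translate_alignment(cl))
    }
  })
})

test_that("alignment FASTA round-trips", {
  aln <- aln_from_strings(c(a = "ATGGCTAAA", b = "ATG---AAA"))
  f <- tempfile(fileext = ".fasta")
  write_alignment(aln, f)
  back <- read_alignment(f, "nucleotide")
  expect_equal(back$codons, aln$codons)
})
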