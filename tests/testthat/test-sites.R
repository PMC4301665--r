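test_that("codon-aware alignment handles identity, indels, and frame", {
  cds <- paste(rep(c("GCT", "AAA", "CGT", "GAT"), 10), collapse = "")
  aln <- align_cds_pair(cds, cds)
  expect_equal(length(aln$a_chars), nchar(cds))
  expect_equal(aln$n_gap_cols_removed, 0)
  expect_identical(aln$a_chars, aln$b_chars)

  # deleting one codon produces one 3-column gap, removed afterwards
  codons <- rep(c("GCT", "AAA", "CGT", "GAT"), 10)
  del <- paste(codons[-20], collapse = "")
  aln2 <- align_cds_pair(cds, del)
  expect_equal(aln2$n_gap_cols_removed, 3)
  expect_equal(length(aln2$a_chars), nchar(del))
  expect_equal(length(aln2$a_chars) %% 3, 0)
  # removing alignment gaps recovers contiguous codon frames in both
  expect_equal(aln2$codon_pos, rep_len(0:2, length(aln2$a_chars)))

  # third-position-only differences: trivial protein alignment, all columns
  cds_b <- cds
  substr(cds_b, 6, 6) <- "G"   # AAA -> AAG, synonymous third position
  aln3 <- align_cds_pair(cds, cds_b)
  expect_equal(length(aln3$a_chars), nchar(cds))
  expect_equal(sum(aln3$a_chars != aln3$b_chars), 1)

  # trailing stop codons are stripped; internal stops are an error
  expect_equal(length(align_cds_pair("ATGGCGTAA", "ATGGCGTAA")$a_chars), 6)
  expect_error(align_cds_pair("ATGTAAGCG", "ATGTAAGCG"), "internal stop")
})

test_that("UTR alignment removes gap columns and keeps positions", {
  aln <- align_utr_pair("ACGTACGT", "ACGTACGT", "utr5")
  expect_equal(length(aln$a_chars), 8)
  expect_equal(aln$n_gap_cols_removed, 0)
  aln2 <- align_utr_pair("AAAATTTTCCCC", "AAAACCCC", "utr3")
  expect_equal(length(aln2$a_chars), 8)
  expect_true(all(aln2$region == "utr3"))
  # one empty UTR yields an empty alignment, not an error
  expect_equal(length(align_utr_pair("", "ACGT")$a_chars), 0)
})

test_that("degeneracy labels match the stated codon rules", {
  aln <- mk_cds_aln("GGA", "GGG")
  expect_equal(classify_degeneracy(aln), c("nd", "nd", "fourfold"))

  aln2 <- mk_cds_aln("TTT", "TTT")
  expect_equal(classify_degeneracy(aln2)[2], "nd")

  # Ile ATT: third position is 3-fold (ATA syn, ATG nonsyn) -> other
  aln3 <- mk_cds_aln("ATT", "ATT")
  expect_equal(classify_degeneracy(aln3)[3], "other")

  # noncoding columns
  u <- mk_utr_aln("ACGT", "ACGT")
  expect_equal(unique(classify_degeneracy(u)), "noncoding")
})

test_that("degeneracy depends only on the column's two codons (exhaustive)", {
  # independent re-derivation from the genetic code for every sense pair
  for (ca in SENSE_CODONS) {
    for (cb in SENSE_CODONS) {
      got <- classify_degeneracy(mk_cds_aln(ca, cb))
      for (pos in 1:3) {
        nd_a <- all(vapply(setdiff(c("A", "C", "G", "T"),
                                   substr(ca, pos, pos)), function(b) {
          nb <- ca; substr(nb, pos, pos) <- b
          oracle_translate(nb) == "*" ||
            oracle_translate(nb) != oracle_translate(ca)
        }, logical(1))) && any(vapply(setdiff(c("A", "C", "G", "T"),
                                              substr(ca, pos, pos)),
          function(b) {
            nb <- ca; substr(nb, pos, pos) <- b
            oracle_translate(nb) != "*"
          }, logical(1)))
        nd_b <- all(vapply(setdiff(c("A", "C", "G", "T"),
                                   substr(cb, pos, pos)), function(b) {
          nb <- cb; substr(nb, pos, pos) <- b
          oracle_translate(nb) == "*" ||
            oracle_translate(nb) != oracle_translate(cb)
        }, logical(1))) && any(vapply(setdiff(c("A", "C", "G", "T"),
                                              substr(cb, pos, pos)),
          function(b) {
            nb <- cb; substr(nb, pos, pos) <- b
            oracle_translate(nb) != "*"
          }, logical(1)))
        ff <- pos == 3 && substr(ca, 1, 2) == substr(cb, 1, 2) &&
          length(unique(oracle_translate(paste0(substr(ca, 1, 2),
                                                c("A", "C", "G", "T"))))) == 1
        want <- if (ff) "fourfold" else if (nd_a && nd_b) "nd" else "other"
        expect_equal(got[pos], want, label = paste(ca, cb, pos))
      }
    }
  }
})

test_that("CpG flags use either-sequence context on original neighbours", {
  aln <- mk_utr_aln("ACGT", "ATGT")
  expect_equal(classify_cpg(aln), c(FALSE, TRUE, TRUE, FALSE))
  expect_equal(classify_cpg(mk_utr_aln("AAAA", "AAAA")),
               rep(FALSE, 4))
  expect_equal(classify_cpg(mk_utr_aln("CGCG", "CGCG")), rep(TRUE, 4))
  # symmetric in the two sequences
  expect_equal(classify_cpg(mk_utr_aln("ACGT", "ATGT")),
               classify_cpg(mk_utr_aln("ATGT", "ACGT")))
  # "both" mode demands the dinucleotide in both sequences
  expect_equal(classify_cpg(mk_utr_aln("ACGT", "ATGT"), mode = "both"),
               rep(FALSE, 4))
})

test_that("site partition is consistent and CpG splits ALL exactly", {
  set.seed(17)
  cfg <- sim_config(n_pairs = 4, cds_codons = 60, utr5_len = 60,
                    utr3_len = 60, t = 0.15, seed = 17)
  sim <- simulate_ortholog_pairs(cfg)
  for (i in 1:4) {
    aln <- align_transcript_pair(sim$set_a, sim$set_b,
                                 sim$truth$map$id_a[i],
                                 sim$truth$map$id_b[i])
    part <- site_partition(aln)
    expect_equal(nrow(part), length(aln$a_chars))
    # degeneracy = noncoding exactly off the CDS
    expect_equal(part$degeneracy == "noncoding", part$region != "cds")
    # nd + fourfold + other = comparable CDS columns
    cds_comp <- part$comparable & part$region == "cds"
    expect_equal(sum(part$degeneracy[cds_comp] %in%
                       c("nd", "fourfold", "other")), sum(cds_comp))
    # CpG + non-CpG partition every region's comparable columns
    for (reg in c("utr5", "cds", "utr3")) {
      sel <- part$comparable & part$region == reg
      expect_equal(sum(sel & part$cpg) + sum(sel & !part$cpg), sum(sel))
    }
  }
})
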