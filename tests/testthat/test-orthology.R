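rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                     replace = TRUE), collapse = "")

# recode every third codon position to a synonymous alternative where one
# exists: protein is unchanged but no 11-mer survives
synonymize <- function(cds) {
  n <- nchar(cds) %/% 3
  codons <- substring(cds, 3 * (1:n) - 2, 3 * (1:n))
  for (i in seq_len(n)) {
    fam <- substr(codons[i], 1, 2)
    alts <- paste0(fam, setdiff(c("A", "C", "G", "T"),
                                substr(codons[i], 3, 3)))
    alts <- alts[!is.na(Biostrings::GENETIC_CODE[alts]) &
                   Biostrings::GENETIC_CODE[alts] ==
                   Biostrings::GENETIC_CODE[codons[i]]]
    if (length(alts)) codons[i] <- alts[1]
  }
  paste(codons, collapse = "")
}

test_that("similarity search: identity, containment, and seed absence", {
  set.seed(41)
  subs <- transcript_table(c("s1", "s2"), c(rand_seq(300), rand_seq(300)))
  q_same <- transcript_table("q", subs$seq[1])
  hits <- similarity_search(q_same, subs)
  top <- hits[order(-hits$score), ][1, ]
  expect_equal(top$subject_id, "s1")
  expect_equal(top$query_cov, 1.0)

  # query = 5' half of a subject
  q_half <- transcript_table("qh", substr(subs$seq[1], 1, 150))
  hh <- similarity_search(q_half, subs)
  th <- hh[order(-hh$score), ][1, ]
  expect_equal(th$subject_id, "s1")
  expect_equal(th$query_cov, 1.0)
  expect_equal(th$matched_len, 150)

  # no shared 11-mer -> no hits (query alternates far from random subjects)
  q_none <- transcript_table("qn", strrep("ACT", 60))
  expect_equal(nrow(similarity_search(q_none, subs)), 0)

  expect_error(similarity_search(q_none, subs[0, ]), "empty")
})

test_that("reciprocal best hits require mutuality and 50% coverage", {
  hit <- function(q, s, score, cov) data.frame(
    query_id = q, subject_id = s, score = score, matched_len = 100L,
    query_cov = cov, level = "nucleotide", stringsAsFactors = FALSE)
  # A1<->B1 mutual best; A2 prefers B2 but B2's best is A1
  ab <- rbind(hit("A1", "B1", 100, 0.9), hit("A2", "B2", 80, 0.9))
  ba <- rbind(hit("B1", "A1", 100, 0.9), hit("B2", "A1", 70, 0.9))
  pairs <- reciprocal_best_hits(ab, ba)
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs$id_a, "A1")
  # A1 is the best hit of both B1 and B2, so the pair is paralog-involved
  expect_equal(pairs$relationship, "many")

  # with B2 pointing elsewhere the mutual pair is cleanly one-to-one
  ba3 <- rbind(hit("B1", "A1", 100, 0.9), hit("B2", "A2", 70, 0.9))
  p3 <- reciprocal_best_hits(ab, ba3)
  expect_equal(p3$relationship[p3$id_a == "A1"], "one_to_one")

  # mutual best with 40% coverage on one side is rejected
  ab2 <- hit("A1", "B1", 100, 0.4)
  ba2 <- hit("B1", "A1", 100, 0.9)
  expect_equal(nrow(reciprocal_best_hits(ab2, ba2)), 0)
})

test_that("identical duplicated genes are flagged paralog-involved", {
  set.seed(43)
  g <- rand_seq(400)
  set_a <- transcript_table(c("A1", "A2"), c(g, g))
  set_b <- transcript_table("B1", g)
  res <- find_orthologs(set_a, set_b)
  expect_true(all(res$category %in% c("many")))
  if (nrow(res$pairs) > 0)
    expect_true(all(res$pairs$relationship == "many"))
})

test_that("translated rescue drops short queries and recovers synonymous-saturated orthologs", {
  set.seed(47)
  # a CDS-like query whose protein matches a subject but whose nucleotide
  # third positions were all recoded (no shared 11-mer)
  cds <- paste0("ATG", paste(random_sense_codons(120), collapse = ""))
  q <- synonymize(cds)
  expect_equal(nrow(similarity_search(transcript_table("q", q),
                                      transcript_table("s", cds))), 0)
  unmatched <- transcript_table(c("q", "tiny"), c(q, rand_seq(240)))
  subs <- transcript_table("s", cds)
  pairs <- translated_rescue(unmatched, subs)
  expect_equal(attr(pairs, "too_short_ids"), "tiny")
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs$id_a, "q")
  expect_equal(pairs$level, "translated")

  empty <- translated_rescue(unmatched[0, ], subs)
  expect_equal(nrow(empty), 0)
})

test_that("inventory categories partition the query set on simulated data", {
  cfg <- sim_config(n_pairs = 8, cds_codons = 100, utr5_len = 60,
                    utr3_len = 60, t = 0.1, n_decoys = 3, seed = 53)
  sim <- simulate_ortholog_pairs(cfg)
  sim <- add_decoys_and_paralogs(sim, n_decoys = 3, n_paralogs = 0,
                                 decoy_len = 420)
  res <- find_orthologs(sim$set_a, sim$set_b)
  counts <- classify_inventory(res)
  expect_equal(counts[["n_query"]], nrow(sim$set_a))
  expect_equal(counts[["one_to_one"]] + counts[["many"]] +
                 counts[["species_specific"]] + counts[["too_short"]],
               counts[["n_query"]])
  # all true orthologs recovered one-to-one, decoys species-specific
  expect_equal(counts[["one_to_one"]], 8)
  expect_equal(counts[["species_specific"]], 3)
  got <- paste(res$pairs$id_a, res$pairs$id_b)
  want <- paste(sim$truth$map$id_a, sim$truth$map$id_b)
  expect_true(all(want %in% got))
})

test_that("a decoy shorter than 250 bp counts as too short, not specific", {
  cfg <- sim_config(n_pairs = 3, cds_codons = 80, utr5_len = 40,
                    utr3_len = 40, t = 0.05, seed = 59)
  sim <- simulate_ortholog_pairs(cfg)
  sim <- add_decoys_and_paralogs(sim, n_decoys = 1, n_paralogs = 0,
                                 decoy_len = 240)
  res <- find_orthologs(sim$set_a, sim$set_b)
  expect_equal(classify_inventory(res)[["too_short"]], 1)
})

test_that("RBH is symmetric under swapping the two species", {
  cfg <- sim_config(n_pairs = 5, cds_codons = 80, utr5_len = 40,
                    utr3_len = 40, t = 0.1, seed = 61)
  sim <- simulate_ortholog_pairs(cfg)
  ab <- find_orthologs(sim$set_a, sim$set_b)$pairs
  ba <- find_orthologs(sim$set_b, sim$set_a)$pairs
  expect_equal(sort(paste(ab$id_a, ab$id_b)),
               sort(paste(ba$id_b, ba$id_a)))
})
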