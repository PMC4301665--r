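test_that("NG86 site fractions match hand enumeration", {
  expect_equal(ng86_sites("TTT"), c(s = 1 / 3, n = 8 / 3))
  expect_equal(ng86_sites("GGG"), c(s = 1, n = 2))
  expect_equal(ng86_sites("ATG"), c(s = 0, n = 3))
  expect_error(ng86_sites("TAA"), "sense")
})

test_that("NG86 site fractions equal the oracle on all 61 sense codons", {
  for (cdn in SENSE_CODONS) {
    expect_equal(ng86_sites(cdn), oracle_sites(cdn), tolerance = 1e-12,
                 label = cdn)
  }
})

test_that("pathway-averaged differences match hand counts and the oracle", {
  expect_equal(unclass(ng86_differences("TTT", "TTC"))[1:2],
               c(sd = 1, nd = 0))
  expect_equal(unclass(ng86_differences("TTT", "GTA"))[1:2],
               c(sd = 0.5, nd = 1.5))
  expect_equal(unclass(ng86_differences("TTT", "TTT"))[1:2],
               c(sd = 0, nd = 0))

  set.seed(8)
  for (i in 1:200) {
    ca <- sample(SENSE_CODONS, 1); cb <- sample(SENSE_CODONS, 1)
    got <- ng86_differences(ca, cb)
    want <- oracle_differences(ca, cb)
    expect_equal(unname(got[1:2]), unname(want), tolerance = 1e-12,
                 label = paste(ca, cb))
    # symmetry and triangle sanity
    rev <- ng86_differences(cb, ca)
    expect_equal(unname(got[1:2]), unname(rev[1:2]), tolerance = 1e-12)
    hamming <- sum(strsplit(ca, "")[[1]] != strsplit(cb, "")[[1]])
    expect_gte(got[["sd"]] + got[["nd"]] + 1e-12, hamming)
  }
})

test_that("the constructed 100-codon glycine alignment gives the analytic Ks", {
  aln <- mk_cds_aln(rep("GGA", 100), c(rep("GGC", 10), rep("GGA", 90)))
  r <- ng86_kaks(aln)
  expect_equal(r$S, 100)
  expect_equal(r$N, 200)
  expect_equal(r$Sd, 10)
  expect_equal(r$Nd, 0)
  expect_equal(r$Ks, -0.75 * log(1 - 0.4 / 3), tolerance = 1e-12)
  expect_lt(abs(r$Ks - 0.10733), 1e-5)
  expect_equal(r$Ka, 0)
  expect_equal(r$omega, 0)
})

test_that("identical CDSs give Ka = Ks = 0 for both methods", {
  aln <- mk_cds_aln(rep(c("GCT", "AAA", "CGT"), 10),
                    rep(c("GCT", "AAA", "CGT"), 10))
  expect_equal(ng86_kaks(aln)$Ks, 0)
  expect_equal(ng86_kaks(aln)$Ka, 0)
  yn <- yn_kaks(aln, kappa = 2)
  expect_equal(yn$Ks, 0)
  expect_equal(yn$Ka, 0)
})

test_that("ng86_kaks equals the brute-force oracle on random small alignments", {
  set.seed(21)
  for (i in 1:150) {
    n <- sample(3:30, 1)
    ca <- random_sense_codons(n)
    cb <- ca
    mut <- sample(n, max(1, rpois(1, 2)), replace = TRUE)
    for (m in mut) cb[m] <- random_sense_codons(1)
    got <- ng86_kaks(mk_cds_aln(ca, cb))
    want <- oracle_kaks(ca, cb)
    expect_equal(got$S, want$S, tolerance = 1e-10)
    expect_equal(got$N, want$N, tolerance = 1e-10)
    expect_equal(got$Sd, want$Sd, tolerance = 1e-10)
    expect_equal(got$Nd, want$Nd, tolerance = 1e-10)
    if (!is.na(want$Ks)) expect_equal(got$Ks, want$Ks, tolerance = 1e-10)
    if (!is.na(want$Ka)) expect_equal(got$Ka, want$Ka, tolerance = 1e-10)
  }
})

test_that("YN with kappa = 1 and uniform codon usage reduces to NG86 counting", {
  set.seed(33)
  for (i in 1:20) {
    ca <- random_sense_codons(60)
    cb <- ca
    for (m in sample(60, 8)) cb[m] <- random_sense_codons(1)
    aln <- mk_cds_aln(ca, cb)
    ng <- ng86_kaks(aln)
    yn <- yn_kaks(aln, kappa = 1, codon_freqs = "uniform")
    expect_equal(yn$S, ng$S, tolerance = 0.02 * ng$S)
    expect_equal(yn$N, ng$N, tolerance = 0.02 * ng$N)
  }
})

test_that("YN falls back to NG86 when kappa cannot be estimated", {
  aln <- mk_cds_aln(c("ATG", "TGG", "ATG"), c("ATG", "TGG", "ATG"))
  expect_warning(r <- yn_kaks(aln), "kappa")
  expect_true("ng86_fallback" %in% r$flags)
  expect_equal(r$method, "YN")
})

test_that("Fisher exact test matches the hypergeometric hand-computed values", {
  expect_equal(fisher_pvalue(matrix(c(1, 1, 1, 1), 2)), 1.0)
  expect_equal(fisher_pvalue(matrix(c(0, 10, 10, 0), 2)),
               2 / choose(20, 10), tolerance = 1e-9)
  expect_error(fisher_pvalue(matrix(c(-2, 1, 1, 1), 2)), "negative")
  r <- ng86_kaks(mk_cds_aln(rep("GGA", 100),
                            c(rep("GGC", 10), rep("GGA", 90))))
  r <- fisher_pvalue(r)
  expect_lt(r$p_value, 0.01)
})

test_that("Ka/Ks bins are right-closed and report undefined separately", {
  mk <- function(om, ks = 0.1) {
    r <- list(pair_id = "x", method = "NG86", S = 10, N = 20, Sd = 1,
              Nd = 1, Ka = om * ks, Ks = ks, omega = om, kappa = NA,
              p_value = NA, flags = character())
    class(r) <- "kaks_result"
    r
  }
  b <- bin_kaks(list(mk(2.5), mk(1.5), mk(0.7), mk(0.2)))
  expect_equal(unname(b$bins), c(1, 1, 1, 1))
  expect_equal(unname(bin_kaks(list(mk(1.0)))$bins), c(0, 0, 1, 0))
  expect_equal(unname(bin_kaks(list(mk(2.0)))$bins), c(0, 1, 0, 0))
  undef <- mk(Inf, ks = 0)
  expect_equal(bin_kaks(list(undef, mk(0.2)))$n_undefined, 1)
})

test_that("sliding windows count, localize, and aggregate consistently", {
  # 300-bp alignment -> 41 windows of 57 bp at step 6
  ca <- random_sense_codons(100)
  aln <- mk_cds_aln(ca, ca)
  sc <- sliding_window_scan(aln, 57, 6)
  expect_equal(nrow(sc$windows), 41)
  expect_equal(sc$windows$start[2] - sc$windows$start[1], 6)

  # synonymous-only pair: omega 0 everywhere it is defined
  cb <- ca
  set.seed(9)
  for (i in seq(2, 98, by = 7)) {
    fam <- substr(ca[i], 1, 2)
    alt <- paste0(fam, setdiff(c("A", "C", "G", "T"), substr(ca[i], 3, 3)))
    alt <- alt[!is.na(Biostrings::GENETIC_CODE[alt]) &
                 Biostrings::GENETIC_CODE[alt] ==
                 Biostrings::GENETIC_CODE[ca[i]]]
    if (length(alt)) cb[i] <- alt[1]
  }
  scs <- sliding_window_scan(mk_cds_aln(ca, cb), 57, 6)
  def <- scs$windows$omega[!is.na(scs$windows$omega)]
  expect_true(all(def == 0))

  # non-overlapping windows aggregate to the whole-gene counts
  sc2 <- sliding_window_scan(aln, 60, 60)
  whole <- ng86_kaks(aln)
  expect_equal(sum(sc2$windows$S), whole$S, tolerance = 1e-9)
  expect_equal(sum(sc2$windows$Sd), whole$Sd, tolerance = 1e-9)
  expect_equal(sum(sc2$windows$Nd), whole$Nd, tolerance = 1e-9)

  # shorter than one window: single whole-alignment window with a warning
  expect_warning(s1 <- sliding_window_scan(mk_cds_aln(ca[1:10], ca[1:10]),
                                           57, 6), "shorter")
  expect_equal(nrow(s1$windows), 1)
})
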