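# Independent brute-force oracle for NG86 quantities. Deliberately written
# from first principles (direct genetic-code lookups, recursive pathway
# enumeration) so it shares no code with the package's table-driven
# implementation.

ORACLE_GC <- as.character(Biostrings::GENETIC_CODE)
names(ORACLE_GC) <- names(Biostrings::GENETIC_CODE)

oracle_translate <- function(codon) unname(ORACLE_GC[codon])

oracle_mutate <- function(codon, pos, base) {
  substr(codon, pos, pos) <- base
  codon
}

# synonymous site count of a sense codon: per position, synonymous non-stop
# neighbours over non-stop neighbours
oracle_sites <- function(codon) {
  aa <- oracle_translate(codon)
  s <- 0
  for (pos in 1:3) {
    syn <- 0; tot <- 0
    for (b in c("A", "C", "G", "T")) {
      if (b == substr(codon, pos, pos)) next
      nb <- oracle_mutate(codon, pos, b)
      if (oracle_translate(nb) == "*") next
      tot <- tot + 1
      if (oracle_translate(nb) == aa) syn <- syn + 1
    }
    if (tot > 0) s <- s + syn / tot
  }
  c(s = s, n = 3 - s)
}

# recursive enumeration of minimal mutational pathways; returns a matrix of
# (sd, nd) rows, one per stop-free pathway (or all pathways with stops
# allowed when allow_stops = TRUE)
oracle_paths <- function(ca, cb, allow_stops = FALSE) {
  if (ca == cb) return(matrix(c(0, 0), 1, dimnames = list(NULL, c("sd", "nd"))))
  acc <- NULL
  for (pos in 1:3) {
    if (substr(ca, pos, pos) == substr(cb, pos, pos)) next
    mid <- oracle_mutate(ca, pos, substr(cb, pos, pos))
    if (!allow_stops && oracle_translate(mid) == "*") next
    rest <- oracle_paths(mid, cb, allow_stops)
    if (is.null(rest)) next
    syn <- oracle_translate(ca) == oracle_translate(mid)
    step <- if (syn) c(1, 0) else c(0, 1)
    acc <- rbind(acc, sweep(rest, 2, step, `+`))
  }
  acc
}

oracle_differences <- function(ca, cb) {
  m <- oracle_paths(ca, cb)
  if (is.null(m)) m <- oracle_paths(ca, cb, allow_stops = TRUE)
  colMeans(m)
}

# whole-alignment NG86 with Jukes-Cantor correction from codon vectors
oracle_kaks <- function(codons_a, codons_b) {
  sa <- vapply(codons_a, function(x) oracle_sites(x)[["s"]], numeric(1))
  sb <- vapply(codons_b, function(x) oracle_sites(x)[["s"]], numeric(1))
  S <- (sum(sa) + sum(sb)) / 2
  N <- 3 * length(codons_a) - S
  d <- mapply(function(x, y) oracle_differences(x, y), codons_a, codons_b)
  Sd <- sum(d["sd", ]); Nd <- sum(d["nd", ])
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  list(S = S, N = N, Sd = Sd, Nd = Nd, Ks = jc(Sd / S), Ka = jc(Nd / N))
}

SENSE_CODONS <- names(ORACLE_GC)[ORACLE_GC != "*"]

random_sense_codons <- function(n) {
  sample(setdiff(SENSE_CODONS, c("ATG", "TGG")), n, replace = TRUE)
}

# build an in-frame gap-free CDS pair_alignment directly from codon vectors
# (bypasses the protein-guided aligner for unit-level checks)
mk_cds_aln <- function(codons_a, codons_b) {
  a <- paste(codons_a, collapse = ""); b <- paste(codons_b, collapse = "")
  orthodiverge:::new_pair_alignment(
    strsplit(a, "")[[1]], strsplit(b, "")[[1]],
    region = rep("cds", nchar(a)),
    codon_pos = rep_len(0:2, nchar(a)),
    a_pos = seq_len(nchar(a)), b_pos = seq_len(nchar(b)),
    seq_a = a, seq_b = b)
}

# direct UTR-style alignment from two equal-length ungapped strings
mk_utr_aln <- function(a, b, region = "utr5") {
  orthodiverge:::new_pair_alignment(
    strsplit(a, "")[[1]], strsplit(b, "")[[1]],
    region = rep(region, nchar(a)),
    codon_pos = rep(NA_integer_, nchar(a)),
    a_pos = seq_len(nchar(a)), b_pos = seq_len(nchar(b)),
    seq_a = a, seq_b = b)
}
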