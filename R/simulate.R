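# Synthetic ortholog-pair generator: two transcript sets descended from
# common ancestral transcripts (5'UTR + CDS + 3'UTR) under an HKY-like
# point-mutation process with transition/transversion ratio kappa, a
# CpG-context transition multiplier, and codon-level selection omega applied
# as acceptance thinning; plus decoy and paralog transcripts for orthology
# testing. Every substitution is recorded, so downstream estimates can be
# checked against known truth.

#' Simulation configuration
#'
#' @param n_pairs Number of ortholog pairs.
#' @param cds_codons CDS length in codons, including the fixed ATG start and
#'   stop codon.
#' @param utr5_len,utr3_len UTR lengths in bp.
#' @param base_freqs Named A/C/G/T fractions summing to 1.
#' @param kappa Transition/transversion rate ratio (>= 0).
#' @param omega Selection intensity: nonsynonymous proposals are accepted
#'   with probability \code{min(1, omega)} and synonymous proposals with
#'   probability \code{min(1, 1/omega)}, so the realized dN/dS equals
#'   \code{omega} on both sides of 1.
#' @param cpg_mult CpG-context transition-rate multiplier (>= 1).
#' @param t Expected neutral substitutions per site summed over both
#'   branches.
#' @param n_decoys Unrelated transcripts appended to set A.
#' @param n_paralogs Genes of set A duplicated (with extra divergence).
#' @param decoy_len Decoy length in bp (default: same as the ortholog
#'   transcripts).
#' @param seed RNG seed (runs are byte-reproducible under a fixed seed).
#' @export
sim_config <- function(n_pairs = 50L, cds_codons = 200L, utr5_len = 100L,
                       utr3_len = 150L,
                       base_freqs = c(A = 0.3, C = 0.2, G = 0.2, T = 0.3),
                       kappa = 2, omega = 0.2, cpg_mult = 1, t = 0.1,
                       n_decoys = 0L, n_paralogs = 0L, decoy_len = NULL,
                       seed = NULL) {
  stopifnot(n_pairs >= 0, cds_codons >= 3, utr5_len >= 0, utr3_len >= 0,
            kappa >= 0, omega >= 0, cpg_mult >= 1, t >= 0,
            n_decoys >= 0, n_paralogs >= 0,
            all(base_freqs >= 0), abs(sum(base_freqs) - 1) < 1e-9,
            all(c("A", "C", "G", "T") %in% names(base_freqs)))
  if (is.null(decoy_len))
    decoy_len <- utr5_len + 3L * cds_codons + utr3_len
  as.list(environment())
}

.STOPS <- c("TAA", "TAG", "TGA")

.sample_bases <- function(n, freqs) {
  if (n == 0) return(character(0))
  sample(names(freqs), n, replace = TRUE, prob = freqs)
}

# one random sense (non-stop) codon at the given base frequencies
.sample_sense_codons <- function(n, freqs) {
  out <- character(n)
  i <- 1L
  while (i <= n) {
    cdn <- paste(.sample_bases(3, freqs), collapse = "")
    if (.AA[cdn] != "*") { out[i] <- cdn; i <- i + 1L }
  }
  out
}

.random_transcript <- function(config) {
  freqs <- config$base_freqs[c("A", "C", "G", "T")]
  stopw <- vapply(.STOPS, function(s)
    prod(freqs[.codon_chars(s)]), numeric(1))
  cds <- paste0("ATG",
                paste(.sample_sense_codons(config$cds_codons - 2L, freqs),
                      collapse = ""),
                sample(.STOPS, 1, prob = stopw))
  paste0(paste(.sample_bases(config$utr5_len, freqs), collapse = ""),
         cds,
         paste(.sample_bases(config$utr3_len, freqs), collapse = ""))
}

# CpG participation flags of a character vector
.cpg_flags <- function(ch) {
  n <- length(ch)
  if (n == 0) return(logical(0))
  nxt <- c(ch[-1], ""); prv <- c("", ch[-n])
  (ch == "C" & nxt == "G") | (ch == "G" & prv == "C")
}

# Evolve one lineage for n_prop proposed point mutations. `mutable` is a
# logical mask (start and stop codons of the CDS are frozen so the reading
# frame stays recoverable). Returns the evolved characters plus per-region
# realized substitution counts.
.evolve_lineage <- function(ch, region, cds_start, cds_end, mutable,
                            config, n_prop) {
  kappa <- config$kappa; cpg_mult <- config$cpg_mult; omega <- config$omega
  p_nonsyn <- min(1, omega)
  p_syn <- if (omega > 1) 1 / omega else 1
  cpg <- .cpg_flags(ch)
  w_ts <- ifelse(cpg, kappa * cpg_mult, kappa)
  w <- ifelse(mutable, w_ts + 2, 0)
  zero <- stats::setNames(rep(0, 6), c("subs", "syn", "nonsyn", "ts", "tv",
                                       "cpg"))
  counts <- list(utr5 = zero, cds = zero, utr3 = zero)
  L <- length(ch)
  for (k in seq_len(n_prop)) {
    j <- sample.int(L, 1L, prob = w)
    base <- ch[j]
    wts <- w_ts[j]
    is_ts <- stats::runif(1) < wts / (wts + 2)
    target <- if (is_ts) .TS_PARTNER[[base]] else
      sample(setdiff(.BASES, c(base, .TS_PARTNER[[base]])), 1L)
    reg <- region[j]
    syn <- NA
    if (reg == "cds") {
      off <- j - cds_start - 1L           # 0-based offset into CDS
      c0 <- j - off %% 3L                 # first position of the codon
      old_codon <- paste(ch[c0:(c0 + 2L)], collapse = "")
      nb <- ch[c0:(c0 + 2L)]; nb[off %% 3L + 1L] <- target
      new_codon <- paste(nb, collapse = "")
      if (.AA[new_codon] == "*") next     # stop-creating: rejected
      syn <- .AA[new_codon] == .AA[old_codon]
      if (!syn && stats::runif(1) > p_nonsyn) next
      if (syn && stats::runif(1) > p_syn) next
    }
    # accepted
    counts[[reg]]["subs"] <- counts[[reg]]["subs"] + 1
    counts[[reg]][if (is_ts) "ts" else "tv"] <-
      counts[[reg]][if (is_ts) "ts" else "tv"] + 1
    if (cpg[j]) counts[[reg]]["cpg"] <- counts[[reg]]["cpg"] + 1
    if (!is.na(syn))
      counts[[reg]][if (syn) "syn" else "nonsyn"] <-
        counts[[reg]][if (syn) "syn" else "nonsyn"] + 1
    ch[j] <- target
    upd <- max(1L, j - 1L):min(L, j + 1L)
    cpg[upd] <- .cpg_flags(ch[max(1L, j - 2L):min(L, j + 2L)])[
      upd - max(1L, j - 2L) + 1L]
    w_ts[upd] <- ifelse(cpg[upd], kappa * cpg_mult, kappa)
    w[upd] <- ifelse(mutable[upd], w_ts[upd] + 2, 0)
  }
  list(ch = ch, counts = counts)
}

#' Simulate ortholog pairs with recorded truth
#'
#' Draws ancestral transcripts (CDS from stop-free codons at the configured
#' base frequencies, flanked by i.i.d. UTRs) and evolves two descendant
#' lineages independently, each receiving \code{Poisson(t/2 * length)}
#' proposed point mutations: the site and change are picked proportionally
#' to rate (transitions weighted \code{kappa}, CpG-context transitions
#' further multiplied by \code{cpg_mult}), stop-creating CDS changes are
#' rejected, and selection thins nonsynonymous (synonymous) acceptances so
#' that realized dN/dS equals \code{omega}. The CDS start and stop codons
#' are held fixed.
#'
#' @param config A [sim_config()].
#' @return A list of class \code{ortholog_sim}: \code{set_a}, \code{set_b}
#'   (annotated transcript tables), and \code{truth} (ortholog map,
#'   ancestors, per-pair per-region realized substitution counts, CDS
#'   coordinates, decoy/paralog bookkeeping, implants).
#' @export
simulate_ortholog_pairs <- function(config) {
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_pairs
  cds_start <- config$utr5_len
  cds_end <- cds_start + 3L * config$cds_codons
  ids_a <- sprintf("gA_%04d", seq_len(n))
  ids_b <- sprintf("gB_%04d", seq_len(n))
  seqs_a <- character(n); seqs_b <- character(n)
  ancestors <- character(n)
  counts <- vector("list", n)
  for (i in seq_len(n)) {
    anc <- .random_transcript(config)
    ancestors[i] <- anc
    ch <- .chars(anc)
    L <- length(ch)
    region <- rep("utr3", L)
    region[seq_len(cds_start)] <- "utr5"
    region[(cds_start + 1L):cds_end] <- "cds"
    mutable <- rep(TRUE, L)
    mutable[(cds_start + 1L):(cds_start + 3L)] <- FALSE   # ATG
    mutable[(cds_end - 2L):cds_end] <- FALSE              # stop
    evolve <- function() {
      n_prop <- stats::rpois(1, config$t / 2 * sum(mutable))
      .evolve_lineage(ch, region, cds_start, cds_end, mutable, config,
                      n_prop)
    }
    ea <- evolve(); eb <- evolve()
    seqs_a[i] <- paste(ea$ch, collapse = "")
    seqs_b[i] <- paste(eb$ch, collapse = "")
    counts[[i]] <- list(a = ea$counts, b = eb$counts)
  }
  set_a <- transcript_table(ids_a, seqs_a, cds_start, cds_end)
  set_b <- transcript_table(ids_b, seqs_b, cds_start, cds_end)
  set_a$coding <- TRUE; set_b$coding <- TRUE
  truth <- list(
    map = data.frame(id_a = ids_a, id_b = ids_b, stringsAsFactors = FALSE),
    ancestors = stats::setNames(ancestors, ids_a),
    counts = stats::setNames(counts, ids_a),
    cds = data.frame(id = c(ids_a, ids_b), cds_start = cds_start,
                     cds_end = cds_end, strand = "+",
                     stringsAsFactors = FALSE),
    decoy_ids = character(0), paralog_ids = character(0),
    implants = list())
  structure(list(set_a = set_a, set_b = set_b, truth = truth,
                 config = config), class = "ortholog_sim")
}

#' Implant a cluster of nonsynonymous substitutions
#'
#' Adds \code{n_nonsyn} extra nonsynonymous substitutions to a random
#' in-frame window of the species-B copy of one pair (no stop codons
#' created), recording the window coordinates in the truth -- the fixture
#' for sliding-window positive-selection scans.
#'
#' @param sim An \code{ortholog_sim}.
#' @param pair_id Pair to modify (an id from set A; default the first).
#' @param window_len Window length in bp (multiple of 3).
#' @param n_nonsyn Number of nonsynonymous substitutions to implant.
#' @return The modified \code{ortholog_sim}; the implant is appended to
#'   \code{truth$implants} with CDS-relative 0-based half-open coordinates.
#' @export
implant_selection_window <- function(sim, pair_id = NULL, window_len = 57L,
                                     n_nonsyn = 5L) {
  stopifnot(inherits(sim, "ortholog_sim"), window_len %% 3 == 0)
  if (is.null(pair_id)) pair_id <- sim$truth$map$id_a[1]
  i <- match(pair_id, sim$set_a$id)
  j <- match(sim$truth$map$id_b[match(pair_id, sim$truth$map$id_a)],
             sim$set_b$id)
  cds_start <- sim$set_b$cds_start[j]; cds_end <- sim$set_b$cds_end[j]
  internal_lo <- cds_start + 3L       # skip ATG (0-based)
  internal_hi <- cds_end - 3L         # skip stop
  if (internal_hi - internal_lo < window_len)
    stop("implant window longer than internal CDS")
  if (n_nonsyn == 0) return(sim)
  starts <- seq(internal_lo, internal_hi - window_len, by = 3L)
  w0 <- sample(starts, 1)
  ch <- .chars(sim$set_b$seq[j])
  # nonsynonymous non-stop targets of position p given the current sequence
  # state (changes sharing a codon are revalidated after each application)
  valid_targets <- function(p) {
    off <- (p - cds_start - 1L) %% 3L
    c0 <- p - off
    old_codon <- paste(ch[c0:(c0 + 2L)], collapse = "")
    tg <- character(0)
    for (b in setdiff(.BASES, ch[p])) {
      nb <- ch[c0:(c0 + 2L)]; nb[off + 1L] <- b
      nc <- paste(nb, collapse = "")
      if (.AA[nc] != "*" && .AA[nc] != .AA[old_codon]) tg <- c(tg, b)
    }
    tg
  }
  window_pos <- (w0 + 1L):(w0 + window_len)
  picks <- integer(0)
  for (k in seq_len(n_nonsyn)) {
    open <- setdiff(window_pos, picks)
    open <- open[vapply(open, function(p) length(valid_targets(p)) > 0,
                        logical(1))]
    if (length(open) == 0)
      stop("not enough mutable nonsynonymous positions in window")
    p <- if (length(open) == 1) open else sample(open, 1)
    tg <- valid_targets(p)
    ch[p] <- if (length(tg) == 1) tg else sample(tg, 1)
    picks <- c(picks, p)
  }
  sim$set_b$seq[j] <- paste(ch, collapse = "")
  sim$truth$implants[[length(sim$truth$implants) + 1L]] <- list(
    pair_id = pair_id, side = "b",
    cds_window_start = w0 - cds_start, cds_window_end =
      w0 - cds_start + window_len,
    positions = sort(picks) - cds_start - 1L, n_nonsyn = n_nonsyn)
  sim
}

#' Append decoy and paralog transcripts to the simulated sets
#'
#' Decoys are unrelated random transcripts (truth: species-specific);
#' paralogs duplicate existing set-A genes with extra divergence (truth:
#' paralog-involved, so the affected orthologs are no longer one-to-one).
#'
#' @param sim An \code{ortholog_sim}.
#' @param n_decoys,n_paralogs Counts (default from the sim's config).
#' @param decoy_len Decoy length in bp.
#' @return The augmented \code{ortholog_sim}.
#' @export
add_decoys_and_paralogs <- function(sim, n_decoys = NULL, n_paralogs = NULL,
                                    decoy_len = NULL) {
  stopifnot(inherits(sim, "ortholog_sim"))
  cfg <- sim$config
  if (is.null(n_decoys)) n_decoys <- cfg$n_decoys
  if (is.null(n_paralogs)) n_paralogs <- cfg$n_paralogs
  if (is.null(decoy_len)) decoy_len <- cfg$decoy_len
  freqs <- cfg$base_freqs[c("A", "C", "G", "T")]
  if (n_decoys > 0) {
    ids <- sprintf("decoyA_%03d", seq_len(n_decoys))
    seqs <- vapply(seq_len(n_decoys), function(i)
      paste(.sample_bases(decoy_len, freqs), collapse = ""), character(1))
    sim$set_a <- rbind(sim$set_a, transcript_table(ids, seqs))
    sim$truth$decoy_ids <- c(sim$truth$decoy_ids, ids)
  }
  if (n_paralogs > 0) {
    stopifnot(n_paralogs <= nrow(sim$truth$map))
    for (k in seq_len(n_paralogs)) {
      src <- sim$truth$map$id_a[k]
      i <- match(src, sim$set_a$id)
      ch <- .chars(sim$set_a$seq[i])
      L <- length(ch)
      cds_start <- sim$set_a$cds_start[i]; cds_end <- sim$set_a$cds_end[i]
      region <- rep("utr3", L)
      region[seq_len(cds_start)] <- "utr5"
      region[(cds_start + 1L):cds_end] <- "cds"
      mutable <- rep(TRUE, L)
      mutable[(cds_start + 1L):(cds_start + 3L)] <- FALSE
      mutable[(cds_end - 2L):cds_end] <- FALSE
      n_prop <- stats::rpois(1, cfg$t / 2 * sum(mutable))
      ev <- .evolve_lineage(ch, region, cds_start, cds_end, mutable, cfg,
                            n_prop)
      pid <- paste0(src, "_p")
      para <- transcript_table(pid, paste(ev$ch, collapse = ""),
                               cds_start, cds_end)
      para$coding <- TRUE
      sim$set_a <- rbind(sim$set_a, para)
      sim$truth$paralog_ids <- c(sim$truth$paralog_ids, pid)
    }
  }
  sim
}

#' Write a simulation to FASTA/TSV/JSON files
#'
#' Emits \code{speciesA.fasta}, \code{speciesB.fasta},
#' \code{cds_coords.tsv} and \code{truth.json} into a directory.
#'
#' @param sim An \code{ortholog_sim}.
#' @param dir Output directory (created if needed).
#' @export
write_sim <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(sim$set_a, file.path(dir, "speciesA.fasta"))
  write_fasta(sim$set_b, file.path(dir, "speciesB.fasta"))
  utils::write.table(sim$truth$cds, file.path(dir, "cds_coords.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(map = sim$truth$map, decoy_ids = sim$truth$decoy_ids,
         paralog_ids = sim$truth$paralog_ids,
         implants = sim$truth$implants),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
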