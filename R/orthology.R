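# Ortholog identification between two transcript sets: reciprocal best hits
# over a k-mer-seeded local aligner, with a translated rescue pass for
# queries too diverged to seed at the nucleotide level.

.kmer_set <- function(s, k) {
  if (nchar(s) < k) return(character())
  unique(substring(s, 1:(nchar(s) - k + 1L), k:nchar(s)))
}

.translate_nt <- function(s) {
  n <- nchar(s) %/% 3
  if (n == 0) return("")
  codons <- substring(s, seq(1L, by = 3L, length.out = n),
                      seq(3L, by = 3L, length.out = n))
  aa <- unname(.AA[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

# the six reading-frame translations of a nucleotide sequence
.six_frames <- function(s) {
  rc <- .revcomp(s)
  frames <- c(lapply(0:2, function(f) substr(s, f + 1L, nchar(s))),
              lapply(0:2, function(f) substr(rc, f + 1L, nchar(rc))))
  vapply(frames, .translate_nt, character(1))
}

# Karlin-Altschul parameters used for E-values (ungapped standard values
# for match 2 / mismatch -3 nucleotide scoring and for BLOSUM62)
.KA_NT <- c(lambda = 0.625, K = 0.41)
.KA_AA <- c(lambda = 0.267, K = 0.041)

.evalue <- function(score, m, n, ka) {
  unname(ka["K"] * m * n * exp(-ka["lambda"] * score))
}

#' Similarity search between two transcript sets
#'
#' A self-contained, deterministic stand-in for a BLAST-style search.
#' Candidate pairs must share at least \code{min_seed_hits} exact seeds
#' (11-mers at the nucleotide level; amino-acid 4-mers within a
#' reading-frame pair at the translated level) -- the classic two-hit
#' trigger. Candidates are scored by Smith-Waterman local alignment
#' (match 2 / mismatch -3 with affine gaps at the nucleotide level;
#' BLOSUM62 over reading-frame pairs at the translated level, reporting
#' the best frame combination), and hits are retained when their
#' Karlin-Altschul E-value against the subject set is at most
#' \code{max_evalue} -- mirroring the conventional 1e-10 BLAST cutoff for
#' cross-species transcript matching.
#'
#' @param queries,subjects Transcript tables (see [read_fasta()]).
#' @param level \code{"nucleotide"} or \code{"translated"}.
#' @param max_evalue E-value cutoff (default 1e-10).
#' @param min_seed_hits Minimum shared exact seeds to attempt alignment.
#' @param max_frame_pairs At the translated level, align at most this many
#'   seed-richest reading-frame pairs per query/subject combination.
#' @return A \code{data.frame} of hits: \code{query_id}, \code{subject_id},
#'   \code{score}, \code{evalue}, \code{matched_len} (bp of the aligned
#'   continuous region on the query), \code{query_cov}
#'   (\code{matched_len} / query length) and \code{level}.
#' @export
similarity_search <- function(queries, subjects,
                              level = c("nucleotide", "translated"),
                              max_evalue = 1e-10, min_seed_hits = 2L,
                              max_frame_pairs = 4L) {
  level <- match.arg(level)
  if (nrow(queries) == 0 || nrow(subjects) == 0)
    stop("similarity_search: empty transcript set")
  hits <- list()
  if (level == "nucleotide") {
    submat <- Biostrings::nucleotideSubstitutionMatrix(match = 2,
                                                       mismatch = -3)
    n_db <- sum(nchar(subjects$seq))
    skmers <- lapply(subjects$seq, .kmer_set, k = 11L)
    subj_dna <- lapply(subjects$seq, Biostrings::DNAString)
    for (qi in seq_len(nrow(queries))) {
      qk <- .kmer_set(queries$seq[qi], 11L)
      qlen <- nchar(queries$seq[qi])
      qdna <- Biostrings::DNAString(queries$seq[qi])
      for (si in seq_len(nrow(subjects))) {
        if (sum(qk %in% skmers[[si]]) < min_seed_hits) next
        sc <- Biostrings::pairwiseAlignment(
          qdna, subj_dna[[si]], type = "local",
          substitutionMatrix = submat, gapOpening = 5, gapExtension = 2,
          scoreOnly = TRUE)
        ev <- .evalue(sc, qlen, n_db, .KA_NT)
        if (ev > max_evalue) next
        aln <- Biostrings::pairwiseAlignment(
          qdna, subj_dna[[si]], type = "local",
          substitutionMatrix = submat, gapOpening = 5, gapExtension = 2)
        pat <- Biostrings::pattern(aln)
        mlen <- IRanges::end(pat) - IRanges::start(pat) + 1L
        hits[[length(hits) + 1L]] <- data.frame(
          query_id = queries$id[qi], subject_id = subjects$id[si],
          score = sc, evalue = ev, matched_len = mlen,
          query_cov = mlen / qlen, level = level, stringsAsFactors = FALSE)
      }
    }
  } else {
    data("BLOSUM62", package = "Biostrings", envir = environment())
    qframes <- lapply(queries$seq, .six_frames)
    sframes <- lapply(subjects$seq, .six_frames)
    qfk <- lapply(qframes, function(fr) lapply(fr, .kmer_set, k = 4L))
    sfk <- lapply(sframes, function(fr) lapply(fr, .kmer_set, k = 4L))
    n_db <- sum(nchar(subjects$seq)) / 3
    for (qi in seq_len(nrow(queries))) {
      qlen <- nchar(queries$seq[qi])
      for (si in seq_len(nrow(subjects))) {
        seeds <- matrix(0L, 6, 6)
        for (fq in 1:6) for (fs in 1:6)
          seeds[fq, fs] <- sum(qfk[[qi]][[fq]] %in% sfk[[si]][[fs]])
        cand <- which(seeds >= min_seed_hits, arr.ind = TRUE)
        if (nrow(cand) == 0) next
        cand <- cand[order(-seeds[cand]), , drop = FALSE]
        cand <- cand[seq_len(min(nrow(cand), max_frame_pairs)), ,
                     drop = FALSE]
        best <- NULL
        for (r in seq_len(nrow(cand))) {
          fq <- cand[r, 1]; fs <- cand[r, 2]
          aln <- Biostrings::pairwiseAlignment(
            Biostrings::AAString(qframes[[qi]][fq]),
            Biostrings::AAString(sframes[[si]][fs]),
            type = "local", substitutionMatrix = BLOSUM62,
            gapOpening = 10, gapExtension = 0.5)
          sc <- Biostrings::score(aln)
          if (is.null(best) || sc > best$score) {
            pat <- Biostrings::pattern(aln)
            mlen <- 3L * (IRanges::end(pat) - IRanges::start(pat) + 1L)
            best <- list(score = sc, matched_len = mlen)
          }
        }
        ev <- .evalue(best$score, qlen / 3, n_db, .KA_AA)
        if (ev > max_evalue) next
        hits[[length(hits) + 1L]] <- data.frame(
          query_id = queries$id[qi], subject_id = subjects$id[si],
          score = best$score, evalue = ev,
          matched_len = best$matched_len,
          query_cov = min(1, best$matched_len / qlen),
          level = level, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(hits) == 0)
    return(data.frame(query_id = character(), subject_id = character(),
                      score = numeric(), evalue = numeric(),
                      matched_len = integer(), query_cov = numeric(),
                      level = character(), stringsAsFactors = FALSE))
  do.call(rbind, hits)
}

# best hit per query: higher score, then longer matched_len, then
# lexicographic subject id (deterministic tie-break)
.best_hits <- function(hits) {
  if (nrow(hits) == 0) return(hits)
  hits <- hits[order(hits$query_id, -hits$score, -hits$matched_len,
                     hits$subject_id), , drop = FALSE]
  hits[!duplicated(hits$query_id), , drop = FALSE]
}

#' Reciprocal best hits with the 50% continuous-region rule
#'
#' A pair (a, b) is emitted when b is a's best surviving hit and a is b's
#' best surviving hit, where a hit survives only if its aligned continuous
#' region covers at least \code{min_query_cov} of the query (applied on the
#' query side of each direction). A pair is \code{one_to_one} when neither
#' member is the best hit of any third transcript; otherwise it is flagged
#' \code{many} (paralog-involved).
#'
#' @param hits_ab,hits_ba Hit tables from [similarity_search()] in the two
#'   directions.
#' @param min_query_cov Minimum query coverage (default 0.5).
#' @return A \code{data.frame} of pairs: \code{id_a}, \code{id_b},
#'   \code{relationship}, \code{level}, \code{score}, \code{cov_a},
#'   \code{cov_b}.
#' @export
reciprocal_best_hits <- function(hits_ab, hits_ba, min_query_cov = 0.5) {
  empty <- data.frame(id_a = character(), id_b = character(),
                      relationship = character(), level = character(),
                      score = numeric(), cov_a = numeric(),
                      cov_b = numeric(), stringsAsFactors = FALSE)
  fab <- hits_ab[hits_ab$query_cov >= min_query_cov, , drop = FALSE]
  fba <- hits_ba[hits_ba$query_cov >= min_query_cov, , drop = FALSE]
  if (nrow(fab) == 0 || nrow(fba) == 0) return(empty)
  bab <- .best_hits(fab)
  bba <- .best_hits(fba)
  best_of_a <- stats::setNames(bab$subject_id, bab$query_id)
  best_of_b <- stats::setNames(bba$subject_id, bba$query_id)
  pairs <- list()
  for (i in seq_len(nrow(bab))) {
    a <- bab$query_id[i]; b <- bab$subject_id[i]
    if (is.na(best_of_b[b]) || best_of_b[b] != a) next
    # multiplicity: is a or b the best hit of some other transcript?
    many <- sum(best_of_a == b) > 1 || sum(best_of_b == a) > 1
    j <- match(b, bba$query_id)
    pairs[[length(pairs) + 1L]] <- data.frame(
      id_a = a, id_b = b,
      relationship = if (many) "many" else "one_to_one",
      level = bab$level[i], score = bab$score[i],
      cov_a = bab$query_cov[i], cov_b = bba$query_cov[j],
      stringsAsFactors = FALSE)
  }
  if (length(pairs) == 0) return(empty)
  do.call(rbind, pairs)
}

#' Translated rescue of queries unmatched at the nucleotide level
#'
#' Queries shorter than \code{min_translate_bp} are dropped (too short to be
#' usefully translated and compared) and counted; the rest are searched at
#' the translated level against the full subject set and passed through
#' [reciprocal_best_hits()].
#'
#' @param unmatched Transcript table of queries with no nucleotide-level hit.
#' @param subjects Transcript table of the other species.
#' @param min_translate_bp Length cutoff in bp (default 250).
#' @param min_query_cov Coverage rule (default 0.5).
#' @return Pair table as in [reciprocal_best_hits()], with attributes
#'   \code{too_short_ids} and \code{hit_ids} (queries with any translated
#'   hit).
#' @export
translated_rescue <- function(unmatched, subjects, min_translate_bp = 250L,
                              min_query_cov = 0.5) {
  short <- nchar(unmatched$seq) < min_translate_bp
  too_short_ids <- unmatched$id[short]
  keep <- unmatched[!short, , drop = FALSE]
  e_hits <- data.frame(query_id = character(), subject_id = character(),
                       score = numeric(), evalue = numeric(),
                       matched_len = integer(), query_cov = numeric(),
                       level = character())
  empty <- reciprocal_best_hits(e_hits, e_hits)
  if (nrow(keep) == 0 || nrow(subjects) == 0) {
    attr(empty, "too_short_ids") <- too_short_ids
    attr(empty, "hit_ids") <- character()
    return(empty)
  }
  hits_ab <- similarity_search(keep, subjects, level = "translated")
  if (nrow(hits_ab) == 0) {
    attr(empty, "too_short_ids") <- too_short_ids
    attr(empty, "hit_ids") <- character()
    return(empty)
  }
  hits_ba <- similarity_search(subjects, keep, level = "translated")
  pairs <- reciprocal_best_hits(hits_ab, hits_ba,
                                min_query_cov = min_query_cov)
  attr(pairs, "too_short_ids") <- too_short_ids
  attr(pairs, "hit_ids") <- unique(hits_ab$query_id)
  pairs
}

#' Find ortholog pairs between two transcript sets
#'
#' Full orthology pass: nucleotide-level reciprocal best hits, then a
#' translated rescue of nucleotide-unmatched queries (dropping those below
#' \code{min_translate_bp}), and a per-query inventory category.
#'
#' @param set_a,set_b Transcript tables for the two species.
#' @param min_query_cov Continuous-region coverage rule (default 0.5).
#' @param min_translate_bp Translation length cutoff (default 250).
#' @return An object of class \code{ortholog_result}: a list with
#'   \code{pairs} (combined pair table), \code{category} (named character:
#'   one of \code{one_to_one}, \code{many}, \code{species_specific},
#'   \code{too_short} per query in \code{set_a}) and \code{counts}.
#' @export
find_orthologs <- function(set_a, set_b, min_query_cov = 0.5,
                           min_translate_bp = 250L) {
  hits_ab <- similarity_search(set_a, set_b, level = "nucleotide")
  hits_ba <- similarity_search(set_b, set_a, level = "nucleotide")
  pairs_nt <- reciprocal_best_hits(hits_ab, hits_ba,
                                   min_query_cov = min_query_cov)
  nt_hit_ids <- unique(hits_ab$query_id)
  unmatched <- set_a[!(set_a$id %in% nt_hit_ids), , drop = FALSE]
  resc <- translated_rescue(unmatched, set_b,
                            min_translate_bp = min_translate_bp,
                            min_query_cov = min_query_cov)
  pairs <- rbind(pairs_nt, resc)
  category <- stats::setNames(rep("species_specific", nrow(set_a)), set_a$id)
  hit_any <- union(nt_hit_ids, attr(resc, "hit_ids"))
  category[names(category) %in% hit_any] <- "many"
  category[attr(resc, "too_short_ids")] <- "too_short"
  if (nrow(pairs) > 0) {
    o2o <- pairs$id_a[pairs$relationship == "one_to_one"]
    category[names(category) %in% o2o] <- "one_to_one"
    # paired-but-flagged stays "many"
  }
  res <- list(pairs = pairs, category = category,
              counts = classify_inventory_counts(category, pairs))
  class(res) <- "ortholog_result"
  res
}

classify_inventory_counts <- function(category, pairs) {
  c(n_query = length(category),
    paired = sum(names(category) %in% pairs$id_a),
    one_to_one = sum(category == "one_to_one"),
    many = sum(category == "many"),
    species_specific = sum(category == "species_specific"),
    too_short = sum(category == "too_short"))
}

#' Inventory of query transcripts by orthology category
#'
#' Every query transcript is assigned exactly one category: a one-to-one
#' ortholog, homologous but paralog-involved or below the coverage rule
#' (\code{many}), unmatched and below the translation length cutoff
#' (\code{too_short}), or species-specific. The categories partition the
#' query set.
#'
#' @param x An \code{ortholog_result} from [find_orthologs()].
#' @return Named integer vector of counts (\code{n_query}, \code{paired},
#'   \code{one_to_one}, \code{many}, \code{species_specific},
#'   \code{too_short}).
#' @export
classify_inventory <- function(x) {
  stopifnot(inherits(x, "ortholog_result"))
  x$counts
}
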