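# End-to-end orchestration: load/annotate two transcript sets, pair
# orthologs, align and classify sites, tabulate divergence, estimate Ka/Ks
# (NG86 and YN are both emitted), optionally scan windows, and write a
# manifest whose per-stage counts partition the input.

#' Pipeline configuration
#'
#' All thresholds default to the analysis' standard values: 150 bp minimum
#' CDS alignment for Ka/Ks, 250 bp minimum length for translated rescue,
#' 50% continuous-region query coverage, 57 bp / 6 bp sliding windows.
#'
#' @param min_orf_nt Minimum ORF length for CDS annotation (nt).
#' @param min_pair_cds_bp Minimum gap-free CDS alignment length for a pair
#'   to enter Ka/Ks estimation.
#' @param min_translate_bp Minimum query length for translated rescue.
#' @param min_query_cov Continuous-region coverage rule.
#' @param method Ka/Ks method driving the binning (\code{"YN"} or
#'   \code{"NG86"}); both are always written to the results table.
#' @param divergence_mode \code{"per_pair"} or \code{"pooled"}.
#' @param window_len,step Sliding-window parameters (bp, multiples of 3).
#' @param scan Run sliding-window scans for candidate positive-selection
#'   pairs.
#' @param seed RNG seed recorded in the manifest.
#' @export
run_config <- function(min_orf_nt = 150L, min_pair_cds_bp = 150L,
                       min_translate_bp = 250L, min_query_cov = 0.5,
                       method = c("YN", "NG86"),
                       divergence_mode = c("per_pair", "pooled"),
                       window_len = 57L, step = 6L, scan = FALSE,
                       seed = NULL) {
  method <- match.arg(method)
  divergence_mode <- match.arg(divergence_mode)
  stopifnot(min_orf_nt > 0, min_pair_cds_bp > 0, min_translate_bp > 0,
            min_query_cov > 0, min_query_cov <= 1,
            window_len %% 3 == 0, step %% 3 == 0)
  as.list(environment())
}

.load_set <- function(x) {
  if (is.character(x) && length(x) == 1) x <- read_fasta(x)
  stopifnot(is.data.frame(x), all(c("id", "seq") %in% names(x)))
  x[order(x$id), , drop = FALSE]
}

#' Run the full ortholog-divergence pipeline
#'
#' Stages: load, CDS annotation (ORF prediction unless coordinates are
#' supplied), reciprocal-best-hit ortholog pairing with translated rescue,
#' region-stratified alignment and site classification, divergence table,
#' Ka/Ks estimation (both NG86 and YN), binning with Fisher p-values, and
#' optional sliding-window scans. Every filter logs the rule and the number
#' of records it removed; the manifest's stage counts partition the input.
#'
#' @param fasta_a,fasta_b FASTA paths or transcript tables for the two
#'   species.
#' @param out_dir Output directory; TSV/JSON outputs and the manifest are
#'   written there.
#' @param cds_coords Optional CDS-coordinate TSV path (overrides ORF
#'   prediction).
#' @param config A [run_config()].
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with \code{pairs}, \code{inventory},
#'   \code{divergence}, \code{kaks}, \code{bins}, \code{scans} and
#'   \code{manifest}.
#' @export
run_pipeline <- function(fasta_a, fasta_b, out_dir = NULL,
                         cds_coords = NULL, config = run_config(),
                         quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  if (!is.null(config$seed)) set.seed(config$seed)
  set_a <- .load_set(fasta_a)
  set_b <- .load_set(fasta_b)
  say("loaded ", nrow(set_a), " + ", nrow(set_b), " transcripts")

  if (!is.null(cds_coords)) {
    set_a <- apply_cds_coords(set_a, cds_coords)
    set_b <- apply_cds_coords(set_b, cds_coords)
  }
  if (anyNA(set_a$coding)) set_a <- annotate_transcripts(set_a,
                                                         config$min_orf_nt)
  if (anyNA(set_b$coding)) set_b <- annotate_transcripts(set_b,
                                                         config$min_orf_nt)
  say("coding: ", sum(set_a$coding), "/", nrow(set_a), " (A), ",
      sum(set_b$coding), "/", nrow(set_b), " (B)")

  orth <- find_orthologs(set_a, set_b,
                         min_query_cov = config$min_query_cov,
                         min_translate_bp = config$min_translate_bp)
  pairs <- orth$pairs
  say("pairs: ", nrow(pairs), " (one-to-one ",
      sum(pairs$relationship == "one_to_one"), ")")

  # alignment + site classification for pairs with two annotated CDSs
  alignments <- list(); partitions <- list()
  skipped_noncoding <- 0L
  for (k in seq_len(nrow(pairs))) {
    i <- match(pairs$id_a[k], set_a$id); j <- match(pairs$id_b[k], set_b$id)
    if (!isTRUE(set_a$coding[i]) || !isTRUE(set_b$coding[j])) {
      skipped_noncoding <- skipped_noncoding + 1L
      next
    }
    key <- paste(pairs$id_a[k], pairs$id_b[k], sep = "|")
    aln <- tryCatch(
      align_transcript_pair(set_a, set_b, pairs$id_a[k], pairs$id_b[k]),
      error = function(e) NULL)
    if (is.null(aln)) { skipped_noncoding <- skipped_noncoding + 1L; next }
    alignments[[key]] <- aln
    partitions[[key]] <- site_partition(aln)
  }
  if (skipped_noncoding > 0)
    say("skipped (non-coding member or failed alignment): ",
        skipped_noncoding)

  divergence <- if (length(alignments) > 0)
    divergence_table(alignments, partitions,
                     mode = config$divergence_mode) else NULL

  # 150-bp CDS-alignment rule for Ka/Ks
  cds_len <- vapply(alignments, function(a) sum(a$region == "cds"),
                    integer(1))
  kaks_keys <- names(alignments)[cds_len >= config$min_pair_cds_bp]
  say("Ka/Ks-eligible pairs (CDS alignment >= ", config$min_pair_cds_bp,
      " bp): ", length(kaks_keys), " of ", length(alignments),
      " (removed ", length(alignments) - length(kaks_keys), ")")
  results <- list()
  for (key in kaks_keys) {
    aln <- alignments[[key]]
    r_ng <- tryCatch(ng86_kaks(aln, key), error = function(e) NULL)
    r_yn <- tryCatch(suppressWarnings(yn_kaks(aln, key)),
                     error = function(e) NULL)
    if (!is.null(r_ng)) results[[paste0(key, ".NG86")]] <-
      tryCatch(fisher_pvalue(r_ng), error = function(e) r_ng)
    if (!is.null(r_yn)) results[[paste0(key, ".YN")]] <-
      tryCatch(fisher_pvalue(r_yn), error = function(e) r_yn)
  }
  kaks <- if (length(results)) kaks_table(results) else NULL
  primary <- if (!is.null(kaks))
    kaks[kaks$method == config$method, , drop = FALSE] else NULL
  bins <- if (!is.null(primary) && nrow(primary) > 0)
    bin_kaks(primary) else NULL

  scans <- NULL
  if (config$scan && !is.null(primary)) {
    cand <- primary$pair_id[is.finite(primary$omega) & primary$omega > 1]
    scans <- lapply(cand, function(key)
      sliding_window_scan(alignments[[key]], config$window_len,
                          config$step, method = "NG86", pair_id = key))
    names(scans) <- cand
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("orthodiverge")),
    seed = config$seed,
    thresholds = config[c("min_orf_nt", "min_pair_cds_bp",
                          "min_translate_bp", "min_query_cov",
                          "window_len", "step")],
    counts = list(
      n_a = nrow(set_a), n_b = nrow(set_b),
      coding_a = sum(set_a$coding), coding_b = sum(set_b$coding),
      inventory = as.list(orth$counts),
      aligned_pairs = length(alignments),
      skipped_noncoding = skipped_noncoding,
      kaks_pairs = length(kaks_keys),
      removed_150bp = length(alignments) - length(kaks_keys)))

  out <- list(pairs = pairs, inventory = orth$counts,
              category = orth$category, divergence = divergence,
              kaks = kaks, bins = bins, scans = scans,
              alignments = alignments, partitions = partitions,
              manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wt <- function(df, f) utils::write.table(
      df, file.path(out_dir, f), sep = "\t", quote = FALSE,
      row.names = FALSE)
    wt(pairs, "pairs.tsv")
    wt(data.frame(category = names(orth$counts),
                  count = as.integer(orth$counts)), "inventory.tsv")
    if (!is.null(divergence)) wt(divergence, "divergence.tsv")
    if (!is.null(kaks)) wt(kaks, "kaks.tsv")
    if (!is.null(scans) && length(scans) > 0) {
      wdf <- do.call(rbind, lapply(scans, function(s)
        cbind(pair_id = s$pair_id, s$windows)))
      wt(wdf, "windows.tsv")
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(out)
}
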