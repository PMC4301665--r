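# Region x context divergence statistics for ortholog pairs: percent
# difference, transition/transversion counts, compared kb, and GC/CpG
# content, stratified by region (5'UTR, CDS, nd sites, 4d sites, 3'UTR) and
# CpG context (ALL, non-CpG, CpG).

.DIV_REGIONS <- c("utr5", "cds", "nd", "fourfold", "utr3")
.DIV_CONTEXTS <- c("all", "non_cpg", "cpg")

# column selector for a (region, context) cell
.cell_columns <- function(partition, region, context) {
  sel <- partition$comparable
  sel <- sel & switch(region,
    utr5 = partition$region == "utr5",
    cds = partition$region == "cds",
    utr3 = partition$region == "utr3",
    nd = partition$degeneracy == "nd",
    fourfold = partition$degeneracy == "fourfold",
    stop("unknown region: ", region))
  switch(context,
    all = sel,
    cpg = sel & partition$cpg,
    non_cpg = sel & !partition$cpg,
    stop("unknown context: ", context))
}

#' Count differences in one (region, context) cell of an aligned pair
#'
#' Over the comparable columns selected by \code{region} and \code{context}:
#' mismatched columns, split into transitions (A<->G, C<->T) and
#' transversions, plus the number of columns compared.
#'
#' @param aln A \code{pair_alignment}.
#' @param partition Its [site_partition()] table.
#' @param region One of \code{"utr5"}, \code{"cds"}, \code{"nd"},
#'   \code{"fourfold"}, \code{"utr3"}.
#' @param context One of \code{"all"}, \code{"non_cpg"}, \code{"cpg"}.
#' @return Named numeric vector \code{c(diffs, compared, ts, tv)}.
#' @export
count_differences <- function(aln, partition, region = "cds",
                              context = "all") {
  sel <- .cell_columns(partition, region, context)
  a <- aln$a_chars[sel]; b <- aln$b_chars[sel]
  diff <- a != b
  ts <- diff & .TS_PARTNER[a] == b
  c(diffs = sum(diff), compared = sum(sel), ts = sum(ts),
    tv = sum(diff) - sum(ts))
}

# per-pair cell stats for every region x context, plus GC/CpG tallies
.pair_cell_stats <- function(aln, partition) {
  out <- list()
  for (region in .DIV_REGIONS) for (context in .DIV_CONTEXTS) {
    cd <- count_differences(aln, partition, region, context)
    sel <- .cell_columns(partition, region, context)
    bases <- c(aln$a_chars[sel], aln$b_chars[sel])
    out[[paste(region, context, sep = ".")]] <- c(
      cd,
      gc = sum(bases %in% c("G", "C")),
      bases = length(bases),
      cpg_cols = sum(partition$cpg[sel]))
  }
  out
}

#' Region x context divergence table
#'
#' The summary table of sequence divergence between ortholog pairs: for each
#' region (5'UTR, CDS, nd sites, 4d sites, 3'UTR) and CpG context (ALL,
#' non-CpG, CpG), the percent difference with its dispersion, total compared
#' kb, transition/transversion counts and ratio, and GC and CpG content.
#'
#' Two averaging modes are provided. \code{per_pair} (default) reports the
#' unweighted mean over pairs of each pair's percent difference with the
#' standard error of that mean across pairs; pairs contributing zero
#' comparable columns to a cell are excluded from that cell (not imputed as
#' zero). \code{pooled} reports \code{100 * sum(diffs) / sum(compared)}.
#' Compared kb, ts/tv, GC and CpG content are always pooled.
#'
#' @param alignments List of \code{pair_alignment} objects.
#' @param partitions Optional list of matching [site_partition()] tables
#'   (computed if omitted).
#' @param mode \code{"per_pair"} or \code{"pooled"}.
#' @return A \code{data.frame} with one row per (region, context):
#'   \code{region}, \code{context}, \code{n_pairs}, \code{diff_percent},
#'   \code{diff_se}, \code{compared_kb}, \code{diffs}, \code{ts}, \code{tv},
#'   \code{ts_tv}, \code{gc_percent}, \code{cpg_percent}.
#' @export
divergence_table <- function(alignments, partitions = NULL,
                             mode = c("per_pair", "pooled")) {
  mode <- match.arg(mode)
  if (length(alignments) == 0) stop("divergence_table: no pairs")
  if (is.null(partitions)) partitions <- lapply(alignments, site_partition)
  stats <- mapply(.pair_cell_stats, alignments, partitions,
                  SIMPLIFY = FALSE)
  rows <- list()
  for (region in .DIV_REGIONS) for (context in .DIV_CONTEXTS) {
    key <- paste(region, context, sep = ".")
    m <- do.call(rbind, lapply(stats, `[[`, key))
    nonzero <- m[, "compared"] > 0
    pair_pct <- 100 * m[nonzero, "diffs"] / m[nonzero, "compared"]
    diffs <- sum(m[, "diffs"]); compared <- sum(m[, "compared"])
    ts <- sum(m[, "ts"]); tv <- sum(m[, "tv"])
    diff_percent <- if (mode == "per_pair") {
      if (length(pair_pct) > 0) mean(pair_pct) else NA_real_
    } else {
      if (compared > 0) 100 * diffs / compared else NA_real_
    }
    diff_se <- if (mode == "per_pair" && length(pair_pct) > 1)
      stats::sd(pair_pct) / sqrt(length(pair_pct)) else NA_real_
    rows[[key]] <- data.frame(
      region = region, context = context, n_pairs = sum(nonzero),
      diff_percent = diff_percent, diff_se = diff_se,
      compared_kb = compared / 1000, diffs = diffs, ts = ts, tv = tv,
      ts_tv = if (tv > 0) ts / tv else NA_real_,
      gc_percent = if (sum(m[, "bases"]) > 0)
        100 * sum(m[, "gc"]) / sum(m[, "bases"]) else NA_real_,
      cpg_percent = if (compared > 0)
        100 * sum(m[, "cpg_cols"]) / compared else NA_real_,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pooled GC and CpG content per region
#'
#' GC percentage over the comparable columns of each region, pooling both
#' sequences of every pair, and the percentage of comparable columns in CpG
#' context.
#'
#' @inheritParams divergence_table
#' @return A \code{data.frame} with \code{region}, \code{gc_percent},
#'   \code{cpg_percent}.
#' @export
context_content <- function(alignments, partitions = NULL) {
  tab <- divergence_table(alignments, partitions, mode = "pooled")
  tab[tab$context == "all", c("region", "gc_percent", "cpg_percent")]
}
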