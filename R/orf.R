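#' Find open reading frames on both strands
#'
#' Enumerates every ATG-to-stop ORF on both strands with length at least
#' \code{min_len_nt}. ORFs whose reading frame runs off the 3' end without a
#' stop (common in truncated transcripts) are accepted, clipped to the last
#' full codon. Coordinates are 0-based half-open on the stored sequence;
#' minus-strand calls are mapped back to stored-sequence coordinates.
#'
#' @param seq A nucleotide sequence (string over A,C,G,T,N).
#' @param min_len_nt Minimum ORF length in nt (>= 6, multiple of 3).
#' @return A \code{data.frame} with columns \code{start}, \code{end},
#'   \code{strand}, \code{frame}, \code{len}, \code{has_stop},
#'   \code{protein}, sorted by length descending, ties broken by strand
#'   (\code{+} first) then smaller start.
#' @export
find_orfs <- function(seq, min_len_nt = 150L) {
  stopifnot(min_len_nt >= 6, min_len_nt %% 3 == 0)
  seq <- toupper(seq)
  L <- nchar(seq)
  scan_strand <- function(s, strand) {
    out <- list()
    ch <- .chars(s)
    for (frame in 0:2) {
      starts <- seq.int(frame + 1L, by = 3L,
                        length.out = max(0L, (nchar(s) - frame) %/% 3))
      if (length(starts) == 0) next
      codons <- substring(s, starts, starts + 2L)
      aa <- ifelse(grepl("N", codons), "X",
                   unname(.AA[codons]))
      is_stop <- !is.na(aa) & aa == "*"
      is_atg <- codons == "ATG"
      # next stop index at-or-after each codon
      n <- length(codons)
      nxt <- rep(NA_integer_, n)
      last <- NA_integer_
      for (i in rev(seq_len(n))) {
        if (is_stop[i]) last <- i
        nxt[i] <- last
      }
      for (i in which(is_atg)) {
        j <- nxt[i]
        if (!is.na(j) && j < i) next
        has_stop <- !is.na(j)
        endc <- if (has_stop) j else n   # clip to last full codon
        # skip ATGs downstream of a previous stop only matters per-start; each
        # ATG gets its own ORF (nested ORFs share a stop)
        len <- (endc - i + 1L) * 3L
        if (len < min_len_nt) next
        st <- starts[i] - 1L
        en <- st + len
        prot_codons <- codons[i:(endc - has_stop)]
        if (length(prot_codons) == 0) prot <- "" else
          prot <- paste(ifelse(grepl("N", prot_codons), "X",
                               unname(.AA[prot_codons])), collapse = "")
        if (strand == "-") { tmp <- st; st <- L - en; en <- L - tmp }
        out[[length(out) + 1L]] <- data.frame(
          start = st, end = en, strand = strand, frame = frame, len = len,
          has_stop = has_stop, protein = prot, stringsAsFactors = FALSE)
      }
    }
    out
  }
  res <- c(scan_strand(seq, "+"), scan_strand(.revcomp(seq), "-"))
  if (length(res) == 0)
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), frame = integer(),
                      len = integer(), has_stop = logical(),
                      protein = character(), stringsAsFactors = FALSE))
  df <- do.call(rbind, res)
  df[order(-df$len, df$strand != "+", df$start), , drop = FALSE]
}

#' Partition transcripts into 5'UTR / CDS / 3'UTR from the top-ranked ORF
#'
#' The longest ORF (ties: plus strand, then leftmost) defines the CDS. When
#' the top ORF lies on the minus strand the stored sequence is
#' reverse-complemented first, so CDS coordinates are always forward.
#' Transcripts with no ORF of at least \code{min_len_nt} are flagged
#' non-coding (\code{coding = FALSE}) and excluded from CDS-level analyses.
#'
#' @param tx A transcript table.
#' @param min_len_nt Minimum ORF length in nt passed to [find_orfs()].
#' @return The transcript table with \code{cds_start}, \code{cds_end} and
#'   \code{coding} filled in.
#' @export
annotate_transcripts <- function(tx, min_len_nt = 150L) {
  for (i in seq_len(nrow(tx))) {
    orfs <- find_orfs(tx$seq[i], min_len_nt)
    if (nrow(orfs) == 0) {
      tx$coding[i] <- FALSE
      tx$cds_start[i] <- NA_integer_
      tx$cds_end[i] <- NA_integer_
      next
    }
    top <- orfs[1, ]
    if (top$strand == "-") {
      tx$seq[i] <- .revcomp(tx$seq[i])
      # coordinates of the same ORF on the flipped sequence
      L <- nchar(tx$seq[i])
      st <- L - top$end; en <- L - top$start
      top$start <- st; top$end <- en
    }
    tx$coding[i] <- TRUE
    tx$cds_start[i] <- as.integer(top$start)
    tx$cds_end[i] <- as.integer(top$end)
  }
  tx
}

#' Apply externally provided CDS coordinates
#'
#' Reads a TSV with columns \code{id, cds_start, cds_end, strand} (0-based
#' half-open) and applies it to a transcript table, reverse-complementing
#' minus-strand entries so coordinates are forward. Overrides ORF prediction.
#'
#' @param tx A transcript table.
#' @param path Path to the coordinate TSV.
#' @export
apply_cds_coords <- function(tx, path) {
  co <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "cds_start", "cds_end", "strand") %in% names(co)))
  for (i in seq_len(nrow(co))) {
    j <- match(co$id[i], tx$id)
    if (is.na(j)) next
    st <- co$cds_start[i]; en <- co$cds_end[i]
    if ((en - st) %% 3 != 0) stop("CDS length not a multiple of 3: ", co$id[i])
    if (co$strand[i] == "-") {
      tx$seq[j] <- .revcomp(tx$seq[j])
      L <- nchar(tx$seq[j])
      tmp <- st; st <- L - en; en <- L - tmp
    }
    tx$cds_start[j] <- as.integer(st)
    tx$cds_end[j] <- as.integer(en)
    tx$coding[j] <- TRUE
  }
  tx$coding[is.na(tx$cds_start)] <- FALSE
  tx
}

# region extraction helpers (0-based half-open CDS coordinates)
.tx_utr5 <- function(tx, i) substr(tx$seq[i], 1L, tx$cds_start[i])
.tx_cds  <- function(tx, i) substr(tx$seq[i], tx$cds_start[i] + 1L,
                                   tx$cds_end[i])
.tx_utr3 <- function(tx, i) substr(tx$seq[i], tx$cds_end[i] + 1L,
                                   nchar(tx$seq[i]))

#' Pooled GC content by codon position
#'
#' The classic "cusp"-style statistic: GC percentage computed separately over
#' all first, second and third codon positions of a set of CDSs.
#'
#' @param cds_set Character vector of CDS strings, each a multiple of 3 long.
#' @return A list with \code{gc1}, \code{gc2}, \code{gc3} and \code{gc_all}
#'   (percentages).
#' @export
codon_position_gc <- function(cds_set) {
  if (any(nchar(cds_set) %% 3 != 0))
    stop("codon_position_gc: CDS length not a multiple of 3")
  counts <- matrix(0, 3, 2, dimnames = list(NULL, c("gc", "acgt")))
  for (s in toupper(cds_set)) {
    ch <- .chars(s)
    pos <- rep_len(1:3, length(ch))
    for (p in 1:3) {
      b <- ch[pos == p]
      counts[p, "gc"] <- counts[p, "gc"] + sum(b %in% c("G", "C"))
      counts[p, "acgt"] <- counts[p, "acgt"] +
        sum(b %in% c("A", "C", "G", "T"))
    }
  }
  pct <- ifelse(counts[, "acgt"] > 0, 100 * counts[, "gc"] / counts[, "acgt"],
                0)
  list(gc1 = pct[1], gc2 = pct[2], gc3 = pct[3],
       gc_all = if (sum(counts[, "acgt"]) > 0)
         100 * sum(counts[, "gc"]) / sum(counts[, "acgt"]) else 0)
}
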