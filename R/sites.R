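# Codon-aware pairwise alignment of ortholog CDSs, direct alignment of
# UTRs, gap-column removal, and per-column labelling by region, codon
# degeneracy (nd / fourfold / other) and CpG context.

new_pair_alignment <- function(a_chars, b_chars, region, codon_pos,
                               a_pos, b_pos, seq_a, seq_b,
                               n_gap_cols_removed = 0L) {
  stopifnot(length(a_chars) == length(b_chars),
            length(region) == length(a_chars))
  structure(list(a_chars = a_chars, b_chars = b_chars, region = region,
                 codon_pos = codon_pos, a_pos = a_pos, b_pos = b_pos,
                 seq_a = seq_a, seq_b = seq_b,
                 n_gap_cols_removed = n_gap_cols_removed),
            class = "pair_alignment")
}

#' @export
print.pair_alignment <- function(x, ...) {
  cat("pair_alignment:", length(x$a_chars), "columns (",
      x$n_gap_cols_removed, "gap columns removed )\n")
  cat("  regions:", paste(sprintf("%s=%d", names(table(x$region)),
                                  table(x$region)), collapse = " "), "\n")
  invisible(x)
}

.strip_stop <- function(cds) {
  n <- nchar(cds)
  if (n >= 3 && !is.na(.AA[substr(cds, n - 2, n)]) &&
      .AA[substr(cds, n - 2, n)] == "*")
    substr(cds, 1, n - 3) else cds
}

.check_internal_stops <- function(cds, label) {
  n <- nchar(cds) %/% 3
  if (n == 0) return(invisible())
  codons <- substring(cds, seq(1, by = 3, length.out = n),
                      seq(3, by = 3, length.out = n))
  aa <- .AA[codons]
  if (any(!is.na(aa) & aa == "*"))
    stop("internal stop codon in CDS ", label)
  invisible()
}

#' Codon-aware alignment of a CDS pair
#'
#' The two CDSs (trailing stop codons stripped) are translated, the proteins
#' globally aligned under BLOSUM62, and the alignment back-mapped to
#' nucleotides so that gaps fall in multiples of three at codon boundaries.
#' Gap columns are then removed, leaving an in-frame, gap-free codon
#' alignment.
#'
#' @param cds_a,cds_b CDS strings (length a multiple of 3, no internal
#'   stop codons).
#' @return A \code{pair_alignment} with \code{region = "cds"} throughout.
#' @export
align_cds_pair <- function(cds_a, cds_b) {
  stopifnot(nchar(cds_a) %% 3 == 0, nchar(cds_b) %% 3 == 0)
  cds_a <- .strip_stop(toupper(cds_a))
  cds_b <- .strip_stop(toupper(cds_b))
  .check_internal_stops(cds_a, "a")
  .check_internal_stops(cds_b, "b")
  prot_a <- .translate_nt(cds_a)
  prot_b <- .translate_nt(cds_b)
  data("BLOSUM62", package = "Biostrings", envir = environment())
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(prot_a), Biostrings::AAString(prot_b),
    type = "global", substitutionMatrix = BLOSUM62,
    gapOpening = 10, gapExtension = 0.5)
  pa <- .chars(as.character(Biostrings::alignedPattern(aln)))
  pb <- .chars(as.character(Biostrings::alignedSubject(aln)))
  ca <- .chars(cds_a); cb <- .chars(cds_b)
  ia <- 0L; ib <- 0L
  a_chars <- character(0); b_chars <- character(0)
  a_pos <- integer(0); b_pos <- integer(0)
  removed <- 0L
  for (k in seq_along(pa)) {
    ga <- pa[k] == "-"; gb <- pb[k] == "-"
    if (!ga && !gb) {
      idx_a <- ia * 3L + 1:3
      idx_b <- ib * 3L + 1:3
      a_chars <- c(a_chars, ca[idx_a]); b_chars <- c(b_chars, cb[idx_b])
      a_pos <- c(a_pos, idx_a); b_pos <- c(b_pos, idx_b)
    } else {
      removed <- removed + 3L
    }
    if (!ga) ia <- ia + 1L
    if (!gb) ib <- ib + 1L
  }
  n <- length(a_chars)
  new_pair_alignment(a_chars, b_chars,
                     region = rep("cds", n),
                     codon_pos = rep_len(0:2, n),
                     a_pos = a_pos, b_pos = b_pos,
                     seq_a = cds_a, seq_b = cds_b,
                     n_gap_cols_removed = removed)
}

#' Direct global alignment of a UTR pair
#'
#' Global nucleotide alignment with affine gaps (match 2 / mismatch -3,
#' gap open 5 / extend 2), followed by gap-column removal.
#'
#' @param utr_a,utr_b UTR strings (possibly empty).
#' @param region Region label for the columns (\code{"utr5"} or
#'   \code{"utr3"}).
#' @return A \code{pair_alignment} with \code{codon_pos = NA}.
#' @export
align_utr_pair <- function(utr_a, utr_b, region = "utr5") {
  utr_a <- toupper(utr_a); utr_b <- toupper(utr_b)
  if (nchar(utr_a) == 0 || nchar(utr_b) == 0)
    return(new_pair_alignment(character(0), character(0), character(0),
                              integer(0), integer(0), integer(0),
                              utr_a, utr_b,
                              n_gap_cols_removed = nchar(utr_a) +
                                nchar(utr_b)))
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 2,
                                                     mismatch = -3,
                                                     baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(utr_a), Biostrings::DNAString(utr_b),
    type = "global", substitutionMatrix = submat,
    gapOpening = 5, gapExtension = 2)
  pa <- .chars(as.character(Biostrings::alignedPattern(aln)))
  pb <- .chars(as.character(Biostrings::alignedSubject(aln)))
  ga <- pa == "-"; gb <- pb == "-"
  keep <- !ga & !gb
  a_pos <- cumsum(!ga)[keep]
  b_pos <- cumsum(!gb)[keep]
  new_pair_alignment(pa[keep], pb[keep],
                     region = rep(region, sum(keep)),
                     codon_pos = rep(NA_integer_, sum(keep)),
                     a_pos = a_pos, b_pos = b_pos,
                     seq_a = utr_a, seq_b = utr_b,
                     n_gap_cols_removed = sum(!keep))
}

# concatenate region alignments into a transcript-level alignment; offsets
# shift per-sequence positions into whole-transcript coordinates
.concat_alignments <- function(parts, offsets_a, offsets_b, seq_a, seq_b) {
  new_pair_alignment(
    unlist(lapply(parts, `[[`, "a_chars")),
    unlist(lapply(parts, `[[`, "b_chars")),
    unlist(lapply(parts, `[[`, "region")),
    unlist(lapply(parts, `[[`, "codon_pos")),
    unlist(mapply(function(p, o) p$a_pos + o, parts, offsets_a,
                  SIMPLIFY = FALSE)),
    unlist(mapply(function(p, o) p$b_pos + o, parts, offsets_b,
                  SIMPLIFY = FALSE)),
    seq_a, seq_b,
    n_gap_cols_removed = sum(vapply(parts, `[[`, integer(1),
                                    "n_gap_cols_removed")))
}

#' Region-stratified alignment of an annotated transcript pair
#'
#' Aligns the 5'UTRs and 3'UTRs directly and the CDSs through the protein
#' guide, then concatenates the gap-free columns with region labels.
#' Positions refer to the full (forward-oriented) transcript sequences so
#' that CpG context is evaluated on the original neighbours.
#'
#' @param tx_a,tx_b Annotated transcript tables.
#' @param id_a,id_b Transcript ids to pair.
#' @return A \code{pair_alignment}.
#' @export
align_transcript_pair <- function(tx_a, tx_b, id_a, id_b) {
  i <- match(id_a, tx_a$id); j <- match(id_b, tx_b$id)
  if (is.na(i) || is.na(j)) stop("unknown transcript id")
  if (!isTRUE(tx_a$coding[i]) || !isTRUE(tx_b$coding[j]))
    stop("both transcripts must have an annotated CDS")
  u5 <- align_utr_pair(.tx_utr5(tx_a, i), .tx_utr5(tx_b, j), "utr5")
  cds <- align_cds_pair(.tx_cds(tx_a, i), .tx_cds(tx_b, j))
  u3 <- align_utr_pair(.tx_utr3(tx_a, i), .tx_utr3(tx_b, j), "utr3")
  .concat_alignments(list(u5, cds, u3),
                     offsets_a = c(0L, tx_a$cds_start[i], tx_a$cds_end[i]),
                     offsets_b = c(0L, tx_b$cds_start[j], tx_b$cds_end[j]),
                     seq_a = tx_a$seq[i], seq_b = tx_b$seq[j])
}

# codon strings (one per column) for the CDS columns of an alignment
.column_codons <- function(aln) {
  idx <- which(aln$region == "cds")
  n_codons <- length(idx) / 3
  codon_id <- rep(seq_len(n_codons), each = 3)
  ca <- vapply(split(aln$a_chars[idx], codon_id), paste, character(1),
               collapse = "")
  cb <- vapply(split(aln$b_chars[idx], codon_id), paste, character(1),
               collapse = "")
  list(idx = idx, codon_a = ca[codon_id], codon_b = cb[codon_id],
       codons_a = unname(ca), codons_b = unname(cb))
}

#' Per-column degeneracy classification
#'
#' A CDS column is \emph{fourfold} iff it is a third codon position whose
#' first two codon positions agree between the two sequences and all four
#' third-position variants encode the same amino acid; it is \emph{nd}
#' (non-degenerate) iff in both codon contexts every non-stop
#' single-nucleotide change at that position alters the amino acid. All
#' remaining CDS columns are \emph{other}; non-CDS columns are
#' \emph{noncoding}. Columns whose codons contain \code{N} (or a stop) fall
#' into \emph{other}.
#'
#' @param aln A \code{pair_alignment}.
#' @return Character vector, one label per column.
#' @export
classify_degeneracy <- function(aln) {
  out <- rep("noncoding", length(aln$a_chars))
  cc <- .column_codons(aln)
  if (length(cc$idx) == 0) return(out)
  pos <- aln$codon_pos[cc$idx]
  lab <- rep("other", length(cc$idx))
  ki <- which(cc$codon_a %in% .SENSE & cc$codon_b %in% .SENSE)
  if (length(ki)) {
    ca <- cc$codon_a[ki]; cb <- cc$codon_b[ki]; p <- pos[ki]
    ff <- p == 2L & substr(ca, 1, 2) == substr(cb, 1, 2) &
      .FF_POS3[ca] & .FF_POS3[cb]
    nd <- .ND_POS[cbind(match(ca, .CODONS), p + 1L)] &
      .ND_POS[cbind(match(cb, .CODONS), p + 1L)]
    lab[ki[which(nd)]] <- "nd"
    lab[ki[which(ff)]] <- "fourfold"
  }
  out[cc$idx] <- lab
  out
}

#' Per-column CpG-context flags
#'
#' A column is in CpG context iff in \emph{either} ungapped sequence the
#' base at that position participates in a CG dinucleotide (a C directly
#' followed by G, or a G directly preceded by C), evaluated on the original
#' sequence neighbours; terminal positions use only the available
#' neighbour. The union-over-sequences rule keeps the flag symmetric in the
#' two species.
#'
#' @param aln A \code{pair_alignment}.
#' @param mode \code{"either"} (default) or \code{"both"}: whether one or
#'   both sequences must show the CG dinucleotide.
#' @return Logical vector, one flag per column.
#' @export
classify_cpg <- function(aln, mode = c("either", "both")) {
  mode <- match.arg(mode)
  flags <- function(s) {
    ch <- .chars(s)
    n <- length(ch)
    if (n == 0) return(logical(0))
    nxt <- c(ch[-1], "")
    prv <- c("", ch[-n])
    (ch == "C" & nxt == "G") | (ch == "G" & prv == "C")
  }
  fa <- flags(aln$seq_a)[aln$a_pos]
  fb <- flags(aln$seq_b)[aln$b_pos]
  if (mode == "either") fa | fb else fa & fb
}

#' Site partition table for an aligned ortholog pair
#'
#' @param aln A \code{pair_alignment}.
#' @param cpg_mode Passed to [classify_cpg()].
#' @return A \code{data.frame} with one row per alignment column:
#'   \code{column} (0-based), \code{region}, \code{degeneracy}, \code{cpg},
#'   \code{comparable} (no \code{N} in either sequence; gap columns were
#'   already removed).
#' @export
site_partition <- function(aln, cpg_mode = "either") {
  data.frame(
    column = seq_along(aln$a_chars) - 1L,
    region = aln$region,
    degeneracy = classify_degeneracy(aln),
    cpg = classify_cpg(aln, mode = cpg_mode),
    comparable = aln$a_chars != "N" & aln$b_chars != "N",
    stringsAsFactors = FALSE)
}
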