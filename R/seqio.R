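#' Read a transcript FASTA file
#'
#' Reads a (wrapped or unwrapped) multi-FASTA nucleotide file into a
#' transcript table. Sequences are upper-cased, RNA \code{U} is mapped to
#' \code{T}, and only the alphabet \code{A,C,G,T,N} is accepted: ambiguity
#' codes other than \code{N} are rejected because every downstream site
#' classifier assumes an unambiguous base or \code{N}.
#'
#' @param path Path to a FASTA file.
#' @return A \code{data.frame} with columns \code{id}, \code{seq},
#'   \code{cds_start}, \code{cds_end} (0-based half-open CDS coordinates,
#'   \code{NA} until annotated) and \code{coding} (logical, \code{NA} until
#'   annotated). This "transcript table" is the common currency of the
#'   package; CDS coordinates always refer to the stored (forward) strand.
#' @seealso [annotate_transcripts()], [write_fasta()], [assembly_summary()]
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0) stop("empty FASTA file: ", path)
  if (!startsWith(trimws(lines[nonblank[1]]), ">"))
    stop("malformed FASTA: line ", nonblank[1], " does not start with '>'")
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(ids))) stop("malformed FASTA: empty sequence id")
  if (anyDuplicated(ids))
    stop("duplicate sequence id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- chartr("u", "t", tolower(as.character(set)))
  seqs <- toupper(seqs)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop("sequence(s) with characters outside {A,C,G,T,N}: ",
         paste(utils::head(ids[bad], 5), collapse = ", "))
  transcript_table(ids, seqs)
}

#' @rdname read_fasta
#' @param ids Character vector of unique, non-empty transcript ids.
#' @param seqs Character vector of nucleotide sequences over
#'   \code{A,C,G,T,N}.
#' @param cds_start,cds_end Optional 0-based half-open CDS coordinates.
#' @export
transcript_table <- function(ids, seqs, cds_start = NA_integer_,
                             cds_end = NA_integer_) {
  stopifnot(length(ids) == length(seqs), all(nzchar(ids)),
            !anyDuplicated(ids))
  n <- length(ids)
  data.frame(id = as.character(ids), seq = toupper(as.character(seqs)),
             cds_start = rep_len(as.integer(cds_start), n),
             cds_end = rep_len(as.integer(cds_end), n),
             coding = rep_len(NA, n), stringsAsFactors = FALSE)
}

#' Write a transcript table to FASTA
#'
#' @param tx A transcript table (see [read_fasta()]).
#' @param path Output path.
#' @param width Line-wrap width (default 70).
#' @export
write_fasta <- function(tx, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(tx))) {
    writeLines(paste0(">", tx$id[i]), con)
    s <- tx$seq[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Assembly summary statistics (N50/N90, lengths, base composition)
#'
#' N50 (N90) is the length of the shortest sequence in the smallest
#' descending-length prefix whose cumulative length reaches 50% (90%) of the
#' total assembled bases -- the standard assembly-stats convention.
#'
#' @param tx A transcript table.
#' @return A list with \code{n_seqs}, \code{total_bp}, \code{mean_len},
#'   \code{longest}, \code{n50}, \code{n90}, \code{base_fracs} (A/T/C/G/N
#'   fractions summing to 1) and \code{gc_percent} (N excluded from the
#'   denominator).
#' @export
assembly_summary <- function(tx) {
  if (nrow(tx) == 0) stop("assembly_summary: empty transcript set")
  len <- nchar(tx$seq)
  total <- sum(len)
  sorted <- sort(len, decreasing = TRUE)
  csum <- cumsum(sorted)
  n_at <- function(frac) sorted[which(csum >= frac * total)[1]]
  base_counts <- vapply(c("A", "T", "C", "G", "N"), function(b)
    sum(vapply(tx$seq, function(s)
      nchar(s) - nchar(gsub(b, "", s, fixed = TRUE)), numeric(1))),
    numeric(1))
  acgt <- sum(base_counts[c("A", "C", "G", "T")])
  list(
    n_seqs = nrow(tx),
    total_bp = total,
    mean_len = total / nrow(tx),
    longest = max(len),
    n50 = n_at(0.5),
    n90 = n_at(0.9),
    base_fracs = base_counts / total,
    gc_percent = 100 * sum(base_counts[c("G", "C")]) / acgt
  )
}

#' GC content of a nucleotide sequence
#'
#' Percent G+C over the non-\code{N} bases. Vectorised over sequences.
#'
#' @param seq Character vector of nucleotide sequences.
#' @return Numeric vector of percentages on the 0--100 scale; \code{NaN}
#'   signalled as an error for all-\code{N}/empty input.
#' @export
gc_content <- function(seq) {
  count <- function(s, pat) nchar(s) - nchar(gsub(pat, "", s))
  gc <- count(toupper(seq), "[GC]")
  denom <- count(toupper(seq), "[ACGT]")
  if (any(denom == 0))
    stop("gc_content: sequence with no unambiguous bases")
  100 * gc / denom
}

# -- small shared helpers -----------------------------------------------------

.chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

.revcomp <- function(s) {
  paste(rev(.chars(chartr("ACGTN", "TGCAN", s))), collapse = "")
}

# half-up rounding (documented convention for the Fisher table)
.round_half_up <- function(x) floor(x + 0.5)
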