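# Internal codon bookkeeping shared by the site classifier and the Ka/Ks
# engine. Everything here is computed once at install time from the standard
# genetic code, so the per-alignment code paths are pure table lookups.

.BASES <- c("T", "C", "A", "G")

.CODONS <- as.vector(t(outer(
  as.vector(t(outer(.BASES, .BASES, paste0))), .BASES, paste0)))

.AA <- {
  gc <- Biostrings::GENETIC_CODE
  stats::setNames(as.character(gc[.CODONS]), .CODONS)
}

.SENSE <- .CODONS[.AA != "*"]

# transition partner of each base (A<->G, C<->T)
.TS_PARTNER <- c(A = "G", G = "A", C = "T", T = "C")

.is_transition <- function(x, y) .TS_PARTNER[x] == y

.codon_chars <- function(codon) substring(codon, 1:3, 1:3)

# the three single-nucleotide neighbours of `codon` at position `pos` (1..3)
.neighbours <- function(codon, pos) {
  ch <- .codon_chars(codon)
  vapply(setdiff(.BASES, ch[pos]), function(b) {
    nb <- ch; nb[pos] <- b; paste(nb, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Per-position synonymous-site fractions (NG86): synonymous non-stop
# neighbours over non-stop neighbours. Rows are codons, NA for stop codons.
.S_FRAC <- {
  m <- matrix(NA_real_, 64, 3, dimnames = list(.CODONS, NULL))
  for (cdn in .SENSE) {
    for (pos in 1:3) {
      nb <- .neighbours(cdn, pos)
      nb <- nb[.AA[nb] != "*"]
      m[cdn, pos] <- if (length(nb) == 0) 0 else
        sum(.AA[nb] == .AA[cdn]) / length(nb)
    }
  }
  m
}

# Position is non-degenerate: every non-stop single-nucleotide change alters
# the amino acid.
.ND_POS <- {
  m <- matrix(NA, 64, 3, dimnames = list(.CODONS, NULL))
  for (cdn in .SENSE) for (pos in 1:3) {
    nb <- .neighbours(cdn, pos)
    nb <- nb[.AA[nb] != "*"]
    m[cdn, pos] <- length(nb) > 0 && all(.AA[nb] != .AA[cdn])
  }
  m
}

# Third position sits in a fourfold-degenerate family: all four third-position
# variants encode the same amino acid.
.FF_POS3 <- {
  v <- stats::setNames(rep(NA, 64), .CODONS)
  for (cdn in .SENSE) {
    ch <- .codon_chars(cdn)
    fam <- paste0(ch[1], ch[2], .BASES)
    v[cdn] <- all(.AA[fam] == .AA[cdn])
  }
  v
}

.PERMS <- list(
  `1` = list(1L),
  `2` = list(c(1L, 2L), c(2L, 1L)),
  `3` = list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
             c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
)

# Pathway-averaged difference counts between two sense codons, split into
# synonymous/nonsynonymous x transition/transversion. Pathways through stop
# codons are discarded; when none survive, steps touching stops are counted
# (stop treated as its own amino-acid state) and the pair is flagged.
.count_codon_paths <- function(ca, cb) {
  cha <- .codon_chars(ca); chb <- .codon_chars(cb)
  diffpos <- which(cha != chb)
  k <- length(diffpos)
  out <- c(sd = 0, nd = 0, sd_ts = 0, sd_tv = 0, nd_ts = 0, nd_tv = 0,
           stop_fallback = 0)
  if (k == 0) return(out)
  walk <- function(allow_stops) {
    acc <- NULL
    for (perm in .PERMS[[k]]) {
      cur <- cha
      tot <- c(sd = 0, nd = 0, sd_ts = 0, sd_tv = 0, nd_ts = 0, nd_tv = 0)
      ok <- TRUE
      for (p in diffpos[perm]) {
        nxt <- cur; nxt[p] <- chb[p]
        aa1 <- .AA[paste(cur, collapse = "")]
        aa2 <- .AA[paste(nxt, collapse = "")]
        if (!allow_stops && (aa1 == "*" || aa2 == "*")) { ok <- FALSE; break }
        ts <- .is_transition(cur[p], nxt[p])
        if (aa1 == aa2) {
          tot["sd"] <- tot["sd"] + 1
          tot[if (ts) "sd_ts" else "sd_tv"] <-
            tot[if (ts) "sd_ts" else "sd_tv"] + 1
        } else {
          tot["nd"] <- tot["nd"] + 1
          tot[if (ts) "nd_ts" else "nd_tv"] <-
            tot[if (ts) "nd_ts" else "nd_tv"] + 1
        }
        cur <- nxt
      }
      if (ok) acc <- rbind(acc, tot)
    }
    acc
  }
  acc <- walk(allow_stops = FALSE)
  if (is.null(acc)) {
    acc <- walk(allow_stops = TRUE)
    out["stop_fallback"] <- 1
  }
  out[colnames(acc)] <- colMeans(acc)
  out
}

# 64 x 64 lookup matrices for pathway counts (rows/cols named by codon;
# NA where either codon is a stop).
.PATHS <- {
  nm <- c("sd", "nd", "sd_ts", "sd_tv", "nd_ts", "nd_tv", "stop_fallback")
  mats <- lapply(nm, function(x)
    matrix(NA_real_, 64, 64, dimnames = list(.CODONS, .CODONS)))
  names(mats) <- nm
  for (ca in .SENSE) for (cb in .SENSE) {
    v <- .count_codon_paths(ca, cb)
    for (x in nm) mats[[x]][ca, cb] <- v[[x]]
  }
  mats
}
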