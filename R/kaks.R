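# Ka/Ks estimation between aligned coding sequences.
#
# Two estimators are provided: Nei-Gojobori counting (NG86) with
# Jukes-Cantor correction, which doubles as the in-house oracle baseline,
# and a Yang-Nielsen-style approximate method (YN) that estimates the
# transition/transversion rate ratio kappa from fourfold-degenerate and
# non-degenerate sites, weights site counts by kappa and the observed codon
# composition (F3x4), and applies a K80-style multiple-hit correction
# separately to the synonymous and nonsynonymous classes.

#' Synonymous/nonsynonymous site fractions of a sense codon (NG86)
#'
#' Per position, the synonymous-site fraction is the number of synonymous
#' single-nucleotide neighbours divided by the number of non-stop
#' neighbours; the codon's synonymous site count is the sum over its three
#' positions and the nonsynonymous count is the complement to 3.
#'
#' @param codon A sense codon string.
#' @return Named numeric \code{c(s, n)} with \code{s + n == 3}.
#' @export
ng86_sites <- function(codon) {
  codon <- toupper(codon)
  if (!(codon %in% .SENSE)) stop("ng86_sites: not a sense codon: ", codon)
  s <- sum(.S_FRAC[codon, ])
  c(s = s, n = 3 - s)
}

#' Pathway-averaged synonymous/nonsynonymous differences between codons
#'
#' Averages the synonymous and nonsynonymous step counts over all minimal
#' mutational pathways between the two codons; pathways that pass through a
#' stop codon are discarded. When every pathway crosses a stop, differences
#' are counted with stops allowed (stop treated as its own amino-acid
#' state) and the result is flagged via the \code{"stop_fallback"}
#' attribute.
#'
#' @param codon_a,codon_b Sense codon strings.
#' @return Named numeric \code{c(sd, nd)}.
#' @export
ng86_differences <- function(codon_a, codon_b) {
  codon_a <- toupper(codon_a); codon_b <- toupper(codon_b)
  if (!(codon_a %in% .SENSE) || !(codon_b %in% .SENSE))
    stop("ng86_differences: not a sense codon")
  out <- c(sd = .PATHS$sd[codon_a, codon_b],
           nd = .PATHS$nd[codon_a, codon_b])
  attr(out, "stop_fallback") <- .PATHS$stop_fallback[codon_a, codon_b] > 0
  out
}

# comparable codon pairs of a CDS alignment: both sense, no N
.codon_pairs <- function(aln) {
  cc <- .column_codons(aln)
  ca <- cc$codons_a; cb <- cc$codons_b
  keep <- ca %in% .SENSE & cb %in% .SENSE
  list(a = ca[keep], b = cb[keep])
}

.jc_correct <- function(p) {
  if (is.na(p)) return(NA_real_)
  if (p >= 0.75) return(NA_real_)
  -0.75 * log(1 - 4 * p / 3) + 0   # + 0 normalizes IEEE negative zero
}

.new_kaks_result <- function(pair_id, method, S, N, Sd, Nd, Ka, Ks,
                             kappa = NA_real_, flags = character()) {
  omega <- if (!is.na(Ka) && !is.na(Ks) && Ks > 0) Ka / Ks else NA_real_
  if (!is.na(Ks) && Ks == 0 && !is.na(Ka) && Ka > 0) {
    omega <- Inf
    flags <- c(flags, "ks_zero")
  }
  structure(list(pair_id = pair_id, method = method, S = S, N = N,
                 Sd = Sd, Nd = Nd, Ka = Ka, Ks = Ks, omega = omega,
                 kappa = kappa, p_value = NA_real_, flags = flags),
            class = "kaks_result")
}

#' @export
print.kaks_result <- function(x, ...) {
  cat(sprintf("%s [%s]: Ka=%.5g Ks=%.5g Ka/Ks=%.4g (S=%.2f N=%.2f Sd=%.2f Nd=%.2f",
              x$pair_id, x$method, x$Ka, x$Ks, x$omega, x$S, x$N, x$Sd,
              x$Nd))
  if (!is.na(x$kappa)) cat(sprintf(" kappa=%.3g", x$kappa))
  if (!is.na(x$p_value)) cat(sprintf(" p=%.3g", x$p_value))
  if (length(x$flags)) cat(" [", paste(x$flags, collapse = ","), "]")
  cat(")\n")
  invisible(x)
}

#' Ka/Ks by Nei-Gojobori counting with Jukes-Cantor correction
#'
#' Site counts are averaged over the two sequences; differences are
#' pathway-averaged per codon pair; \code{pS = Sd/S} and \code{pN = Nd/N}
#' are corrected with \code{d = -(3/4) log(1 - 4p/3)}. A proportion at or
#' beyond the correction's domain (p >= 3/4) leaves that component
#' \code{NA} with a \code{"saturated"} flag.
#'
#' @param aln A \code{pair_alignment} with CDS columns (or any in-frame
#'   gap-free codon alignment).
#' @param pair_id Label carried into the result.
#' @return A \code{kaks_result} list: \code{S}, \code{N}, \code{Sd},
#'   \code{Nd}, \code{Ka}, \code{Ks}, \code{omega}, \code{flags}.
#' @export
ng86_kaks <- function(aln, pair_id = "pair") {
  cp <- .codon_pairs(aln)
  if (length(cp$a) == 0) stop("ng86_kaks: no comparable codons")
  s_a <- rowSums(.S_FRAC[cp$a, , drop = FALSE])
  s_b <- rowSums(.S_FRAC[cp$b, , drop = FALSE])
  S <- (sum(s_a) + sum(s_b)) / 2
  N <- 3 * length(cp$a) - S
  Sd <- sum(.PATHS$sd[cbind(cp$a, cp$b)])
  Nd <- sum(.PATHS$nd[cbind(cp$a, cp$b)])
  flags <- character()
  if (any(.PATHS$stop_fallback[cbind(cp$a, cp$b)] > 0))
    flags <- c(flags, "stop_fallback")
  pS <- if (S > 0) Sd / S else NA_real_
  pN <- if (N > 0) Nd / N else NA_real_
  Ks <- .jc_correct(pS); Ka <- .jc_correct(pN)
  if (!is.na(pS) && pS >= 0.75) flags <- c(flags, "saturated")
  if (!is.na(pN) && pN >= 0.75) flags <- c(flags, "saturated")
  .new_kaks_result(pair_id, "NG86", S, N, Sd, Nd, Ka, Ks, flags = flags)
}

# K80 transition (A) and transversion (B) distance components from observed
# proportions P (ts) and Q (tv); NA when outside the domain
.k80_components <- function(P, Q) {
  w1 <- 1 - 2 * P - Q; w2 <- 1 - 2 * Q
  if (is.na(w1) || is.na(w2) || w1 <= 0 || w2 <= 0)
    return(c(A = NA_real_, B = NA_real_))
  c(A = -0.5 * log(w1) + 0.25 * log(w2) + 0, B = -0.5 * log(w2) + 0)
}

# kappa (instantaneous ts/tv rate ratio) from fourfold-degenerate and
# non-degenerate columns, K80-corrected and weighted by site counts
.estimate_kappa <- function(aln) {
  part <- data.frame(region = aln$region,
                     degeneracy = classify_degeneracy(aln),
                     comparable = aln$a_chars != "N" & aln$b_chars != "N")
  num <- 0; den <- 0
  for (cls in c("fourfold", "nd")) {
    sel <- part$comparable & part$degeneracy == cls
    L <- sum(sel)
    if (L == 0) next
    a <- aln$a_chars[sel]; b <- aln$b_chars[sel]
    diff <- a != b
    ts <- diff & .TS_PARTNER[a] == b
    comp <- .k80_components(sum(ts) / L, sum(diff & !ts) / L)
    if (any(is.na(comp))) next
    num <- num + L * comp["A"]
    den <- den + L * comp["B"]
  }
  if (den <= 0) return(NA_real_)
  unname(2 * num / den)
}

# F3x4 position-specific base frequencies from the comparable codons
.f3x4_freqs <- function(cp) {
  m <- matrix(0, 3, 4, dimnames = list(NULL, .BASES))
  all_codons <- c(cp$a, cp$b)
  for (pos in 1:3) {
    b <- substr(all_codons, pos, pos)
    tab <- table(factor(b, levels = .BASES))
    m[pos, ] <- as.numeric(tab) / length(b)
  }
  m
}

# kappa- and composition-weighted site counts for one codon
.yn_codon_sites <- function(codon, kappa, freqs) {
  ch <- .codon_chars(codon)
  s <- 0
  for (pos in 1:3) {
    wsyn <- 0; wtot <- 0
    for (tb in setdiff(.BASES, ch[pos])) {
      nb <- ch; nb[pos] <- tb
      nbc <- paste(nb, collapse = "")
      if (.AA[nbc] == "*") next
      w <- freqs[pos, tb] * (if (.is_transition(ch[pos], tb)) kappa else 1)
      wtot <- wtot + w
      if (.AA[nbc] == .AA[codon]) wsyn <- wsyn + w
    }
    if (wtot > 0) s <- s + wsyn / wtot
  }
  c(s = s, n = 3 - s)
}

#' Ka/Ks by a Yang-Nielsen-style approximate method
#'
#' Estimates kappa from fourfold-degenerate and non-degenerate sites via
#' K80 correction, counts synonymous/nonsynonymous sites with each possible
#' change weighted by kappa and the F3x4 codon composition, counts
#' differences by pathway averaging, and corrects the synonymous and
#' nonsynonymous proportions with a K80-style two-parameter formula using
#' their observed transition/transversion split. When kappa cannot be
#' estimated (no informative sites or saturated), the NG86 result is
#' returned with method \code{"YN"} and an \code{"ng86_fallback"} flag.
#'
#' @inheritParams ng86_kaks
#' @param kappa Fix kappa instead of estimating it (e.g. \code{1} for the
#'   reduction to unweighted counting).
#' @param codon_freqs \code{"f3x4"} (default) or \code{"uniform"}.
#' @return A \code{kaks_result}; \code{kappa} is filled in.
#' @export
yn_kaks <- function(aln, pair_id = "pair", kappa = NULL,
                    codon_freqs = c("f3x4", "uniform")) {
  codon_freqs <- match.arg(codon_freqs)
  cp <- .codon_pairs(aln)
  if (length(cp$a) == 0) stop("yn_kaks: no comparable codons")
  flags <- character()
  if (is.null(kappa)) {
    kappa <- .estimate_kappa(aln)
    if (is.na(kappa) || kappa <= 0) {
      res <- ng86_kaks(aln, pair_id)
      res$method <- "YN"
      res$kappa <- NA_real_
      res$flags <- c(res$flags, "ng86_fallback")
      warning("yn_kaks: kappa estimation undefined; NG86 fallback for ",
              pair_id)
      return(res)
    }
  }
  freqs <- if (codon_freqs == "f3x4") .f3x4_freqs(cp) else
    matrix(0.25, 3, 4, dimnames = list(NULL, .BASES))
  ucod <- unique(c(cp$a, cp$b))
  tab <- t(vapply(ucod, .yn_codon_sites, numeric(2), kappa = kappa,
                  freqs = freqs))
  dimnames(tab) <- list(ucod, c("s", "n"))
  s_a <- tab[cp$a, "s"]; s_b <- tab[cp$b, "s"]
  S <- (sum(s_a) + sum(s_b)) / 2
  N <- 3 * length(cp$a) - S
  idx <- cbind(cp$a, cp$b)
  Sd <- sum(.PATHS$sd[idx]); Nd <- sum(.PATHS$nd[idx])
  sd_ts <- sum(.PATHS$sd_ts[idx]); sd_tv <- sum(.PATHS$sd_tv[idx])
  nd_ts <- sum(.PATHS$nd_ts[idx]); nd_tv <- sum(.PATHS$nd_tv[idx])
  if (any(.PATHS$stop_fallback[idx] > 0))
    flags <- c(flags, "stop_fallback")
  Ks <- NA_real_; Ka <- NA_real_
  if (S > 0) {
    comp <- .k80_components(sd_ts / S, sd_tv / S)
    if (all(!is.na(comp))) Ks <- sum(comp) else
      flags <- c(flags, "saturated")
  }
  if (N > 0) {
    comp <- .k80_components(nd_ts / N, nd_tv / N)
    if (all(!is.na(comp))) Ka <- sum(comp) else
      flags <- c(flags, "saturated")
  }
  .new_kaks_result(pair_id, "YN", S, N, Sd, Nd, Ka, Ks, kappa = kappa,
                   flags = flags)
}

#' Fisher exact test for a Ka/Ks result
#'
#' Two-sided Fisher exact test on the 2x2 table
#' \code{[[round(Sd), round(S - Sd)], [round(Nd), round(N - Nd)]]}
#' (rounding half-up), the conventional small-sample significance test for
#' an excess of nonsynonymous substitution.
#'
#' @param result A \code{kaks_result}, or a numeric 2x2 matrix.
#' @return The p-value; when given a \code{kaks_result}, the result with
#'   \code{p_value} filled in is returned instead.
#' @export
fisher_pvalue <- function(result) {
  if (is.matrix(result)) {
    tab <- .round_half_up(result)
    if (any(tab < 0)) stop("fisher_pvalue: negative cell")
    return(stats::fisher.test(tab, alternative = "two.sided")$p.value)
  }
  stopifnot(inherits(result, "kaks_result"))
  tab <- .round_half_up(matrix(c(result$Sd, result$S - result$Sd,
                                 result$Nd, result$N - result$Nd),
                               2, 2, byrow = TRUE))
  if (any(!is.finite(tab))) stop("fisher_pvalue: non-finite counts")
  if (any(tab < 0)) stop("fisher_pvalue: negative cell")
  result$p_value <- stats::fisher.test(tab,
                                       alternative = "two.sided")$p.value
  result
}

#' Bin Ka/Ks values into selection classes
#'
#' Counts pairs in the right-closed bins \code{>2}, \code{(1,2]},
#' \code{(0.5,1]}, \code{<=0.5} over the finite omega values; pairs with
#' undefined or infinite omega (Ks = 0) are reported separately, never
#' silently coerced.
#'
#' @param results List of \code{kaks_result} objects (or a data.frame from
#'   [kaks_table()]).
#' @return A list with \code{bins} (named counts), \code{n_undefined}, and
#'   means of Ka, Ks and omega over pairs where each is finite.
#' @export
bin_kaks <- function(results) {
  if (is.data.frame(results)) {
    ka <- results$Ka; ks <- results$Ks; om <- results$omega
  } else {
    ka <- vapply(results, `[[`, numeric(1), "Ka")
    ks <- vapply(results, `[[`, numeric(1), "Ks")
    om <- vapply(results, `[[`, numeric(1), "omega")
  }
  fin <- is.finite(om)
  v <- om[fin]
  bins <- c(`>2` = sum(v > 2), `(1,2]` = sum(v > 1 & v <= 2),
            `(0.5,1]` = sum(v > 0.5 & v <= 1), `<=0.5` = sum(v <= 0.5))
  list(bins = bins, n_undefined = sum(!fin),
       mean_ka = mean(ka[is.finite(ka)]),
       mean_ks = mean(ks[is.finite(ks)]),
       mean_omega = mean(v))
}

#' Flatten Ka/Ks results to a table
#'
#' @param results List of \code{kaks_result} objects.
#' @return A \code{data.frame} with one row per pair.
#' @export
kaks_table <- function(results) {
  do.call(rbind, lapply(results, function(r) data.frame(
    pair_id = r$pair_id, method = r$method, Ka = r$Ka, Ks = r$Ks,
    omega = r$omega, S = r$S, N = r$N, Sd = r$Sd, Nd = r$Nd,
    kappa = r$kappa, p_value = r$p_value,
    flags = paste(r$flags, collapse = ";"), stringsAsFactors = FALSE)))
}

#' Sliding-window Ka/Ks scan
#'
#' Computes Ka/Ks in sliding windows over the gap-free codon columns of a
#' CDS alignment (default 57 bp windows advanced 6 bp at a time, both
#' multiples of 3 so windows stay codon-aligned). Windows with omega > 1
#' are flagged as candidate positively selected loci. Coordinates are
#' 0-based half-open on the gap-column-removed alignment.
#'
#' @param aln A \code{pair_alignment} with CDS columns.
#' @param window_len,step Window length and step in bp (multiples of 3).
#' @param method \code{"NG86"} (default) or \code{"YN"}.
#' @param pair_id Label carried into the result.
#' @return A list of class \code{window_scan} with \code{windows}, a
#'   \code{data.frame} (\code{start}, \code{end}, \code{Ka}, \code{Ks},
#'   \code{omega}, \code{candidate}).
#' @export
sliding_window_scan <- function(aln, window_len = 57L, step = 6L,
                                method = c("NG86", "YN"), pair_id = "pair") {
  method <- match.arg(method)
  stopifnot(window_len %% 3 == 0, step %% 3 == 0, window_len > 0, step > 0)
  idx <- which(aln$region == "cds")
  L <- length(idx)
  kappa <- if (method == "YN") .estimate_kappa(aln) else NULL
  if (!is.null(kappa) && (is.na(kappa) || kappa <= 0)) kappa <- 1
  sub_result <- function(from, to) {
    cols <- idx[(from + 1L):to]
    sub <- new_pair_alignment(aln$a_chars[cols], aln$b_chars[cols],
                              rep("cds", length(cols)),
                              rep_len(0:2, length(cols)),
                              aln$a_pos[cols], aln$b_pos[cols],
                              aln$seq_a, aln$seq_b)
    r <- tryCatch(
      if (method == "NG86") ng86_kaks(sub, pair_id) else
        yn_kaks(sub, pair_id, kappa = kappa),
      error = function(e) NULL)
    if (is.null(r)) rep(NA_real_, 7) else
      c(r$Ka, r$Ks, r$omega, r$S, r$N, r$Sd, r$Nd)
  }
  row_df <- function(s, e) {
    v <- sub_result(s, e)
    data.frame(start = s, end = e, Ka = v[1], Ks = v[2], omega = v[3],
               S = v[4], N = v[5], Sd = v[6], Nd = v[7])
  }
  if (L < window_len) {
    warning("alignment shorter than window; single whole-alignment window")
    windows <- row_df(0L, L)
  } else {
    starts <- seq(0L, L - window_len, by = step)
    windows <- do.call(rbind, lapply(starts, function(s)
      row_df(s, s + window_len)))
  }
  windows$candidate <- is.finite(windows$omega) & windows$omega > 1 |
    (!is.na(windows$omega) & is.infinite(windows$omega))
  structure(list(pair_id = pair_id, window_len = window_len, step = step,
                 method = method, windows = windows),
            class = "window_scan")
}

#' @export
print.window_scan <- function(x, ...) {
  cat(sprintf("window_scan %s [%s]: %d windows of %d bp, step %d bp, %d candidate(s)\n",
              x$pair_id, x$method, nrow(x$windows), x$window_len, x$step,
              sum(x$windows$candidate, na.rm = TRUE)))
  invisible(x)
}
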