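# Nei-Gojobori synonymous/nonsynonymous substitution estimation.
#
# Site counting: each codon position contributes f synonymous sites,
# where f is the fraction of the three possible single-nucleotide
# changes at that position that leave the amino acid unchanged;
# changes creating a stop codon count as nonsynonymous.  Difference
# counting between two codons averages synonymous/nonsynonymous step
# counts over all orderings of the differing positions; orderings that
# pass through a stop codon are excluded (with a fall-back when every
# ordering is blocked).  Proportions are Jukes-Cantor corrected:
# d = -(3/4) ln(1 - (4/3) p).

NT <- c("A", "C", "G", "T")

.codon_env <- new.env(parent = emptyenv())

.genetic_code <- function() Biostrings::GENETIC_CODE

sense_codons <- function() {
  code <- .genetic_code()
  names(code)[code != "*"]
}

.aa_of <- function(codon) unname(.genetic_code()[codon])

#' Nei-Gojobori synonymous and nonsynonymous site counts of a codon
#'
#' @param codon A sense codon (3-nt string, A/C/G/T, not a stop).
#' @return Named numeric vector `c(s = ..., n = ...)` with `s + n = 3`.
#' @export
ng_sites <- function(codon) {
  codon <- toupper(codon)
  tab <- ng_sites_table()
  if (!codon %in% rownames(tab))
    stop("excluded codon (stop or ambiguous): ", codon, call. = FALSE)
  c(s = tab[codon, "s"], n = tab[codon, "n"])
}

# 61 x 2 lookup of ng_sites (internal, cached)
ng_sites_table <- function() {
  if (!is.null(.codon_env$sites)) return(.codon_env$sites)
  code <- .genetic_code()
  sense <- sense_codons()
  tab <- t(vapply(sense, function(cdn) {
    aa <- code[[cdn]]
    syn <- 0
    for (p in 1:3) for (alt in setdiff(NT, substr(cdn, p, p))) {
      mut <- cdn
      substr(mut, p, p) <- alt
      if (code[[mut]] != "*" && code[[mut]] == aa) syn <- syn + 1
    }
    c(s = syn / 3, n = 3 - syn / 3)
  }, numeric(2)))
  .codon_env$sites <- tab
  tab
}

# pathway-averaged (sd, nd) between two sense codons (internal core)
.ng_pair_one <- function(a, b) {
  code <- .genetic_code()
  diff_pos <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  k <- length(diff_pos)
  if (k == 0L) return(c(sd = 0, nd = 0))
  orders <- switch(k,
                   list(diff_pos),
                   list(diff_pos, rev(diff_pos)),
                   {
                     p <- diff_pos
                     list(p[c(1, 2, 3)], p[c(1, 3, 2)], p[c(2, 1, 3)],
                          p[c(2, 3, 1)], p[c(3, 1, 2)], p[c(3, 2, 1)])
                   })
  walk <- function(ord, count_stop_steps) {
    cur <- a
    sd <- 0; nd <- 0
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(b, p, p)
      if (code[[nxt]] == "*") {
        if (!count_stop_steps) return(NULL)  # blocked ordering
        nd <- nd + 1
      } else if (code[[nxt]] == code[[cur]]) {
        sd <- sd + 1
      } else {
        nd <- nd + 1
      }
      cur <- nxt
    }
    c(sd, nd)
  }
  res <- Filter(Negate(is.null), lapply(orders, walk, count_stop_steps = FALSE))
  if (!length(res))
    res <- lapply(orders, walk, count_stop_steps = TRUE)
  m <- colMeans(do.call(rbind, res))
  c(sd = m[[1]], nd = m[[2]])
}

#' Pathway-averaged codon differences
#'
#' Synonymous and nonsynonymous difference counts between two sense
#' codons, averaged over all orderings of the differing positions.
#' Orderings passing through a stop codon are excluded from the
#' average; when all orderings are blocked the average falls back to
#' every ordering with stop steps counted as nonsynonymous.
#'
#' @param a,b Sense codons.
#' @return Named numeric vector `c(sd = ..., nd = ...)`, with
#'   `sd + nd` = number of differing positions.
#' @export
ng_pair_codon <- function(a, b) {
  a <- toupper(a); b <- toupper(b)
  tab <- ng_pair_table()
  key <- paste0(a, b)
  if (!key %in% rownames(tab))
    stop("excluded codon pair (stop or ambiguous): ", a, "/", b,
         call. = FALSE)
  c(sd = tab[key, "sd"], nd = tab[key, "nd"])
}

# 3721 x 2 lookup over all ordered sense-codon pairs (internal, cached)
ng_pair_table <- function() {
  if (!is.null(.codon_env$pairs)) return(.codon_env$pairs)
  sense <- sense_codons()
  keys <- as.vector(outer(sense, sense, paste0))
  tab <- matrix(0, length(keys), 2,
                dimnames = list(keys, c("sd", "nd")))
  for (a in sense) for (b in sense) {
    if (a < b) {
      v <- .ng_pair_one(a, b)
      tab[paste0(a, b), ] <- v
      tab[paste0(b, a), ] <- v   # pathway sets coincide under reversal
    } else if (a == b) {
      tab[paste0(a, b), ] <- c(0, 0)
    }
  }
  .codon_env$pairs <- tab
  tab
}

#' Jukes-Cantor correction of a proportion of differences
#'
#' @param p Proportion in `[0, 3/4)`.
#' @return `-(3/4) * log(1 - (4/3) * p)`.
#' @export
jc69_correct <- function(p) {
  if (any(p >= 0.75))
    stop("saturation: proportion >= 3/4, Jukes-Cantor undefined",
         call. = FALSE)
  -0.75 * log(1 - 4 / 3 * p)
}

# indices of codons usable for a row pair: unmasked and sense in both
.pair_usable <- function(aln, ci, cj) {
  sense <- sense_codons()
  aln$mask & ci %in% sense & cj %in% sense
}

#' Pairwise Nei-Gojobori dN/dS
#'
#' Computes synonymous/nonsynonymous sites (averaged over the two
#' sequences), pathway-averaged differences, proportions and
#' Jukes-Cantor-corrected dS and dN for one pair of rows of a codon
#' alignment.  `omega = dN/dS` is `NA` when `dS = 0`.
#'
#' @param i,j Row indices or identifiers.
#' @param aln A [build_codon_alignment] result.
#' @return Object of class `ng_pair`: list with `S`, `N`, `Sd`, `Nd`,
#'   `pS`, `pN`, `dS`, `dN`, `omega`, `n_codons` and `pair`.
#' @export
ng_pairwise <- function(i, j, aln) {
  if (is.character(i)) i <- match(i, aln$ids)
  if (is.character(j)) j <- match(j, aln$ids)
  ci <- aln_codons(aln, i)
  cj <- aln_codons(aln, j)
  use <- .pair_usable(aln, ci, cj)
  if (!any(use))
    stop(sprintf("empty overlap: no usable codons for pair %s/%s",
                 aln$ids[i], aln$ids[j]), call. = FALSE)
  st <- ng_sites_table()
  pt <- ng_pair_table()
  S <- (sum(st[ci[use], "s"]) + sum(st[cj[use], "s"])) / 2
  N <- (sum(st[ci[use], "n"]) + sum(st[cj[use], "n"])) / 2
  key <- paste0(ci[use], cj[use])
  Sd <- sum(pt[key, "sd"])
  Nd <- sum(pt[key, "nd"])
  pS <- Sd / S
  pN <- Nd / N
  if (pS >= 0.75 || pN >= 0.75)
    stop(sprintf("saturation for pair %s/%s (pS=%.3f, pN=%.3f)",
                 aln$ids[i], aln$ids[j], pS, pN), call. = FALSE)
  dS <- jc69_correct(pS)
  dN <- jc69_correct(pN)
  structure(list(S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
                 dS = dS, dN = dN,
                 omega = if (dS > 0) dN / dS else NA_real_,
                 n_codons = sum(use),
                 pair = aln$ids[c(i, j)]),
            class = "ng_pair")
}

#' @export
print.ng_pair <- function(x, ...) {
  cat(sprintf("<ng_pair %s/%s: dS=%.4f dN=%.4f omega=%s (%d codons)>\n",
              x$pair[1], x$pair[2], x$dS, x$dN,
              if (is.na(x$omega)) "undef" else sprintf("%.3f", x$omega),
              x$n_codons))
  invisible(x)
}

#' Alignment-wide dN/dS summary
#'
#' Mean and standard deviation of `omega = dN/dS` over all unordered
#' row pairs with defined omega (a pairwise approximation to branch-wise
#' estimation).  Saturated pairs are skipped with a warning.
#'
#' @param aln A codon alignment with at least two rows.
#' @return Object of class `rate_summary`: list with `mean_omega`,
#'   `sd_omega`, `n_pairs` (pairs with defined omega) and `n_skipped`.
#' @export
dnds_summary <- function(aln) {
  n <- length(aln$ids)
  if (n < 2) stop("need at least two rows", call. = FALSE)
  omegas <- c()
  skipped <- 0L
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    r <- tryCatch(ng_pairwise(i, j, aln), error = function(e) e)
    if (inherits(r, "error")) { skipped <- skipped + 1L; next }
    if (!is.na(r$omega)) omegas <- c(omegas, r$omega)
  }
  if (skipped > 0)
    warning(sprintf("%d pair(s) skipped (saturation or empty overlap)",
                    skipped))
  if (!length(omegas))
    stop("undefined summary: no pair with defined omega", call. = FALSE)
  structure(list(mean_omega = mean(omegas),
                 sd_omega = if (length(omegas) > 1) stats::sd(omegas) else 0,
                 n_pairs = length(omegas), n_skipped = skipped),
            class = "rate_summary")
}

#' @export
print.rate_summary <- function(x, ...) {
  cat(sprintf("<rate_summary: mean dN/dS = %.3f (SD %.3f, %d pairs; pairwise approximation)>\n",
              x$mean_omega, x$sd_omega, x$n_pairs))
  invisible(x)
}

#' Per-codon substitution profile of a codon alignment
#'
#' For every codon column, the synonymous and nonsynonymous
#' pathway-averaged difference counts are averaged over all unordered
#' sequence pairs; cumulative sums along the coding region give the
#' cumulative-average substitution curves.  Codon columns that are
#' masked (or not sense codons in some pair) contribute 0 for the pairs
#' concerned and are flagged.
#'
#' @param aln A codon alignment with at least two rows.
#' @return Object of class `substitution_profile`: list with `mean_syn`,
#'   `mean_nonsyn`, `cum_syn`, `cum_nonsyn`, `L` and `excluded`
#'   (codon columns unusable in every pair).
#' @export
substitution_profile <- function(aln) {
  n <- length(aln$ids)
  if (n < 2) stop("need at least two rows", call. = FALSE)
  L <- aln$n_codon
  pt <- ng_pair_table()
  syn <- numeric(L); nonsyn <- numeric(L)
  used_any <- rep(FALSE, L)
  codons <- lapply(seq_len(n), function(i) aln_codons(aln, i))
  n_pairs <- 0L
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    use <- .pair_usable(aln, codons[[i]], codons[[j]])
    used_any <- used_any | use
    key <- paste0(codons[[i]][use], codons[[j]][use])
    syn[use] <- syn[use] + pt[key, "sd"]
    nonsyn[use] <- nonsyn[use] + pt[key, "nd"]
    n_pairs <- n_pairs + 1L
  }
  mean_syn <- syn / n_pairs
  mean_nonsyn <- nonsyn / n_pairs
  structure(list(mean_syn = mean_syn, mean_nonsyn = mean_nonsyn,
                 cum_syn = cumsum(mean_syn),
                 cum_nonsyn = cumsum(mean_nonsyn),
                 L = L, excluded = !used_any, n_pairs = n_pairs),
            class = "substitution_profile")
}

#' @export
print.substitution_profile <- function(x, ...) {
  cat(sprintf("<substitution_profile: %d codons, %d pairs; per-100-codon rates syn=%.2f nonsyn=%.2f>\n",
              x$L, x$n_pairs, x$cum_syn[x$L] * 100 / x$L,
              x$cum_nonsyn[x$L] * 100 / x$L))
  invisible(x)
}

#' Delineate conserved regions from a substitution profile
#'
#' A sliding mean (centred window, shrunk at the ends) of the per-codon
#' nonsynonymous track is compared against a fraction of the exon-wide
#' mean; codons below the cut-off are merged into maximal runs, and runs
#' of at least `min_len` codons are reported.  Regions longer than 20
#' codons are flagged as extended conserved regions.  When the exon-wide
#' mean is 0 the whole exon is reported as a single conserved region.
#'
#' @param profile A [substitution_profile].
#' @param window Sliding-window width in codons (default 10).
#' @param factor Cut-off as a fraction of the exon-wide mean (default
#'   0.5).
#' @param min_len Minimum reported run length in codons (default 5).
#' @return data.frame with columns `start`, `end` (1-based inclusive
#'   codon positions), `length`, `mean_rate` (mean of the raw
#'   nonsynonymous track inside the region) and `extended`.
#' @export
delineate_conserved_regions <- function(profile, window = 10L,
                                        factor = 0.5, min_len = 5L) {
  L <- profile$L
  if (L < window) stop("profile shorter than window", call. = FALSE)
  track <- profile$mean_nonsyn
  overall <- mean(track)
  empty <- data.frame(start = integer(0), end = integer(0),
                      length = integer(0), mean_rate = numeric(0),
                      extended = logical(0))
  if (overall == 0)
    return(data.frame(start = 1L, end = L, length = L, mean_rate = 0,
                      extended = L > 20L))
  half <- window %/% 2L
  smoothed <- vapply(seq_len(L), function(i)
    mean(track[max(1L, i - half):min(L, i + half)]), numeric(1))
  below <- smoothed < factor * overall
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_len
  if (!any(keep)) return(empty)
  out <- data.frame(start = starts[keep], end = ends[keep],
                    length = r$lengths[keep])
  out$mean_rate <- vapply(seq_len(nrow(out)), function(k)
    mean(track[out$start[k]:out$end[k]]), numeric(1))
  out$extended <- out$length > 20L
  rownames(out) <- NULL
  out
}
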