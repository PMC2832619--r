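# Gene-conversion detection: stretches of codons with no or minimal
# accumulation of synonymous substitutions between a paralog pair are
# the signature of a recent conversion/recombination tract.  The
# statistic is the longest run of low-synonymous-difference codons and
# its null is a permutation of the observed per-codon values, so the
# test conditions on the observed synonymous opportunities.  Percent
# identity segments between raw gene loci are computed by exact k-mer
# seeding with ungapped X-drop extension.

#' Per-codon synonymous difference track of a sequence pair
#'
#' @param i,j Row indices or identifiers.
#' @param aln A codon alignment.
#' @return Object of class `syn_diff_track`: list with `values`
#'   (pathway-averaged synonymous differences per codon, `NA` where
#'   excluded), `excluded` (logical), `pair` and `L`.
#' @export
syn_diff_track <- function(i, j, aln) {
  if (is.character(i)) i <- match(i, aln$ids)
  if (is.character(j)) j <- match(j, aln$ids)
  ci <- aln_codons(aln, i)
  cj <- aln_codons(aln, j)
  use <- .pair_usable(aln, ci, cj)
  if (!any(use))
    stop(sprintf("empty overlap for pair %s/%s", aln$ids[i], aln$ids[j]),
         call. = FALSE)
  pt <- ng_pair_table()
  vals <- rep(NA_real_, aln$n_codon)
  vals[use] <- pt[paste0(ci[use], cj[use]), "sd"]
  structure(list(values = vals, excluded = !use,
                 pair = aln$ids[c(i, j)], L = aln$n_codon),
            class = "syn_diff_track")
}

# longest run of values <= eps in a numeric vector (internal)
.longest_run <- function(v, eps) {
  r <- rle(v <= eps)
  runs <- r$lengths[r$values]
  if (!length(runs)) return(0L)
  max(runs)
}

#' Permutation test for a gene-conversion tract
#'
#' The observed statistic is the length of the longest run of
#' consecutive usable codons whose synonymous-difference value is at
#' most `epsilon` (excluded codons carry no information and do not
#' break runs).  The null distribution is obtained by permuting the
#' observed per-codon values `B` times; the p-value is
#' `(1 + #\{null run >= observed\}) / (B + 1)`.
#'
#' @param track A [syn_diff_track].
#' @param epsilon Per-codon tolerance (default 0, the "no accumulation"
#'   reading; set > 0 for the "minimal accumulation" reading).
#' @param B Number of permutations (default 1000).
#' @param seed Random seed (mandatory).
#' @return Object of class `conversion_call`: list with `pair`,
#'   `run_start`, `run_end` (1-based codon positions in the original
#'   alignment), `run_length` (number of usable codons in the run),
#'   `run_total` (observed synonymous differences inside the run),
#'   `p_value`, `B` and `seed`.
#' @export
conversion_test <- function(track, epsilon = 0, B = 1000L, seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  keep <- which(!track$excluded)
  v <- track$values[keep]
  if (!length(v) || sum(v) <= 0)
    stop("inapplicable test: no synonymous differences in track",
         call. = FALSE)
  set.seed(seed)
  r <- rle(v <= epsilon)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  obs <- .longest_run(v, epsilon)
  if (obs == 0L) {
    run_start <- run_end <- NA_integer_
    run_total <- NA_real_
  } else {
    k <- which(r$values & r$lengths == obs)[1]
    run_start <- keep[starts[k]]
    run_end <- keep[ends[k]]
    run_total <- sum(v[starts[k]:ends[k]])
  }
  null_ge <- 0L
  for (b in seq_len(B)) {
    if (.longest_run(sample(v), epsilon) >= obs) null_ge <- null_ge + 1L
  }
  structure(list(pair = track$pair, run_start = run_start,
                 run_end = run_end, run_length = obs,
                 run_total = run_total,
                 p_value = (1 + null_ge) / (B + 1),
                 B = as.integer(B), seed = seed),
            class = "conversion_call")
}

#' @export
print.conversion_call <- function(x, ...) {
  cat(sprintf("<conversion_call %s/%s: run %d-%d (%d codons), p = %.4g (B=%d)>\n",
              x$pair[1], x$pair[2], x$run_start, x$run_end, x$run_length,
              x$p_value, x$B))
  invisible(x)
}

#' Percent-identity segments between two sequences
#'
#' Identifies conserved contiguous stretches of nucleotides between two
#' ungapped sequences (a percent-identity-plot analogue): exact k-mer
#' seeds are extended without gaps in both directions under an X-drop
#' rule (match +1, mismatch -1), overlapping extensions on the same
#' diagonal are merged, and segments are filtered by minimum length and
#' identity.
#'
#' @param s1,s2 Nucleotide [cea_seq] records (ungapped).
#' @param k Seed word length (default 11).
#' @param xdrop Score drop-off that terminates extension (default 20).
#' @param min_len Minimum segment length in nt (default 40).
#' @param min_id Minimum percent identity (default 60).
#' @return data.frame with columns `start1`, `end1`, `start2`, `end2`
#'   (1-based inclusive), `length` and `pct_identity`, sorted by
#'   `start1`.
#' @export
pip_segments <- function(s1, s2, k = 11L, xdrop = 20L, min_len = 40L,
                         min_id = 60) {
  a <- strsplit(toupper(s1$residues), "")[[1]]
  b <- strsplit(toupper(s2$residues), "")[[1]]
  if (any(a == "-") || any(b == "-"))
    stop("sequences must be ungapped", call. = FALSE)
  empty <- data.frame(start1 = integer(0), end1 = integer(0),
                      start2 = integer(0), end2 = integer(0),
                      length = integer(0), pct_identity = numeric(0))
  if (length(a) < k || length(b) < k) return(empty)
  kmers1 <- substring(s1$residues, seq_len(length(a) - k + 1L),
                      seq_len(length(a) - k + 1L) + k - 1L)
  kmers2 <- substring(s2$residues, seq_len(length(b) - k + 1L),
                      seq_len(length(b) - k + 1L) + k - 1L)
  idx2 <- split(seq_along(kmers2), kmers2)
  seeds <- list()
  for (i in seq_along(kmers1)) {
    js <- idx2[[kmers1[i]]]
    if (is.null(js)) next
    for (j in js) seeds[[length(seeds) + 1L]] <- c(i, j)
  }
  if (!length(seeds)) return(empty)
  seeds <- do.call(rbind, seeds)
  diag_id <- seeds[, 1] - seeds[, 2]
  segs <- list()
  for (dg in unique(diag_id)) {
    # positions along this diagonal, in s1 coordinates
    lo1 <- max(1L, 1L + dg)
    hi1 <- min(length(a), length(b) + dg)
    pos1 <- lo1:hi1
    match_vec <- a[pos1] == b[pos1 - dg]
    score <- ifelse(match_vec, 1L, -1L)
    dseeds <- seeds[diag_id == dg, 1, drop = TRUE]
    ivals <- list()
    for (s0 in sort(unique(dseeds))) {
      i0 <- s0 - lo1 + 1L           # seed start in diagonal coords
      i1 <- i0 + k - 1L             # seed end
      cur <- k; best <- k; best_r <- i1
      p <- i1
      while (p < length(pos1)) {
        p <- p + 1L
        cur <- cur + score[p]
        if (cur > best) { best <- cur; best_r <- p }
        if (best - cur > xdrop) break
      }
      cur <- best; best_l <- i0
      p <- i0
      while (p > 1L) {
        p <- p - 1L
        cur <- cur + score[p]
        if (cur > best) { best <- cur; best_l <- p }
        if (best - cur > xdrop) break
      }
      ivals[[length(ivals) + 1L]] <- c(best_l, best_r)
    }
    iv <- do.call(rbind, ivals)
    iv <- iv[order(iv[, 1]), , drop = FALSE]
    # merge overlapping extensions on the diagonal
    merged <- list(iv[1, ])
    if (nrow(iv) > 1) for (r in 2:nrow(iv)) {
      last <- merged[[length(merged)]]
      if (iv[r, 1] <= last[2] + 1L)
        merged[[length(merged)]] <- c(last[1], max(last[2], iv[r, 2]))
      else merged[[length(merged) + 1L]] <- iv[r, ]
    }
    for (mv in merged) {
      len <- mv[2] - mv[1] + 1L
      ident <- 100 * mean(match_vec[mv[1]:mv[2]])
      if (len >= min_len && ident >= min_id)
        segs[[length(segs) + 1L]] <- data.frame(
          start1 = pos1[mv[1]], end1 = pos1[mv[2]],
          start2 = pos1[mv[1]] - dg, end2 = pos1[mv[2]] - dg,
          length = len, pct_identity = ident)
    }
  }
  if (!length(segs)) return(empty)
  out <- do.call(rbind, segs)
  out <- out[order(out$start1, out$start2), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Locate the highest-identity segment relative to exon annotation
#'
#' @param segments A [pip_segments] result (coordinates in sequence 1).
#' @param annotation data.frame with columns `exon`, `start`, `end`
#'   (1-based inclusive, sequence-1 coordinates).
#' @return List with `segment` (the maximal-identity row, ties broken
#'   by length then position; `NULL` when empty) and `exons` (names of
#'   annotated exons the segment overlaps).
#' @export
locate_high_identity_region <- function(segments, annotation) {
  if (!nrow(segments)) return(list(segment = NULL, exons = character(0)))
  o <- order(-segments$pct_identity, -segments$length, segments$start1)
  seg <- segments[o[1], , drop = FALSE]
  hit <- annotation$start <= seg$end1 & annotation$end >= seg$start1
  list(segment = seg, exons = annotation$exon[hit])
}
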