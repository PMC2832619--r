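# Immunoreceptor tyrosine-based motif grammar.
#
# Consensus formulas (x = any residue, alternatives in brackets):
#   ITIM       [ILVS] x Y x x [LV]
#   ITSM       T x Y x x [VI]
#   ITAM       [DE] x{0-2} Y x x [LI] x{6-8} Y x x [LI]
#   ITAM_like  Y x x [LI] x{6-8} Y x x [LI], with NO D/E at offsets
#              -1..-3 before the first Y
#   endocytic  Y x x [LMVIF]
#   GRB2_YxN   Y x N
#   YxxM_variant Y x x M
#   TEHKxS_box T E H K x S  (the transposed spelling T H E K x S is
#              additionally reported with variant = TRUE)

MOTIF_NAMES <- c("ITIM", "ITSM", "ITAM", "ITAM_like", "endocytic",
                 "GRB2_YxN", "YxxM_variant", "TEHKxS_box")

# fixed-length patterns: list of allowed-residue sets per position
# (NULL = any residue)
.fixed_patterns <- list(
  ITIM         = list(c("I", "L", "V", "S"), NULL, "Y", NULL, NULL, c("L", "V")),
  ITSM         = list("T", NULL, "Y", NULL, NULL, c("V", "I")),
  endocytic    = list("Y", NULL, NULL, c("L", "M", "V", "I", "F")),
  GRB2_YxN     = list("Y", NULL, "N"),
  YxxM_variant = list("Y", NULL, NULL, "M")
)

# vectorized: all 0-based start offsets where a fixed pattern matches
.match_fixed <- function(chars, pat) {
  n <- length(chars)
  w <- length(pat)
  if (n < w) return(integer(0))
  ok <- rep(TRUE, n - w + 1L)
  for (p in seq_len(w)) {
    set <- pat[[p]]
    if (is.null(set)) next
    ok <- ok & chars[seq(p, p + n - w)] %in% set
  }
  which(ok) - 1L
}

# all 0-based offsets of a "Y x x [LI]" half-motif
.yxxli_starts <- function(chars) {
  .match_fixed(chars, list("Y", NULL, NULL, c("L", "I")))
}

.hit_row <- function(motif, start, end, chars, anchors, variant = FALSE) {
  data.frame(motif = motif, start = start, end = end,
             matched = paste(chars[(start + 1L):end], collapse = ""),
             anchors = paste(anchors, collapse = ","),
             variant = variant, stringsAsFactors = FALSE)
}

# D/E present at offsets -1..-3 before position y0 (0-based)?
.acidic_before <- function(chars, y0) {
  lo <- max(0L, y0 - 3L)
  if (lo >= y0) return(FALSE)
  any(chars[(lo + 1L):y0] %in% c("D", "E"))
}

#' Scan an amino-acid sequence for immunoreceptor motifs
#'
#' Finds every match of the requested motif consensus patterns at every
#' start offset (overlaps included).  For the two-tyrosine spacer
#' patterns (ITAM, ITAM-like) every admissible spacer length is reported
#' as a separate hit.  ITAM-like hits are suppressed where the same
#' tyrosine pair also satisfies the canonical ITAM (an acidic residue at
#' offsets -1..-3 before the first tyrosine).  The `TEHKxS_box` scan
#' additionally reports matches of the transposed spelling `THEKxS`
#' with `variant = TRUE`.
#'
#' @param aa Amino-acid string without gaps.
#' @param which Character vector of motif names (subset of
#'   `r paste(MOTIF_NAMES, collapse = ", ")`).
#' @return A data.frame with columns `motif`, `start` (0-based), `end`
#'   (half-open), `matched`, `anchors` (comma-separated 0-based offsets
#'   of the anchor tyrosines) and `variant`; ordered leftmost-first.
#' @export
scan_motifs <- function(aa, which = MOTIF_NAMES) {
  bad <- setdiff(which, MOTIF_NAMES)
  if (length(bad))
    stop("unknown motif name(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (grepl("-", aa, fixed = TRUE))
    stop("amino-acid sequence must be gap-free", call. = FALSE)
  chars <- strsplit(toupper(aa), "")[[1]]
  out <- list()
  for (m in intersect(names(.fixed_patterns), which)) {
    pat <- .fixed_patterns[[m]]
    for (s in .match_fixed(chars, pat)) {
      anch <- s + which(vapply(pat, function(x) identical(x, "Y"),
                               logical(1))) - 1L
      if (!length(anch)) anch <- s + which(chars[(s + 1L):(s + length(pat))] == "Y") - 1L
      out[[length(out) + 1L]] <- .hit_row(m, s, s + length(pat), chars, anch)
    }
  }
  if ("TEHKxS_box" %in% which) {
    for (s in .match_fixed(chars, list("T", "E", "H", "K", NULL, "S")))
      out[[length(out) + 1L]] <- .hit_row("TEHKxS_box", s, s + 6L, chars,
                                          integer(0))
    for (s in .match_fixed(chars, list("T", "H", "E", "K", NULL, "S")))
      out[[length(out) + 1L]] <- .hit_row("TEHKxS_box", s, s + 6L, chars,
                                          integer(0), variant = TRUE)
  }
  if (any(c("ITAM", "ITAM_like") %in% which)) {
    halves <- .yxxli_starts(chars)
    for (y1 in halves) {
      for (spacer in 6:8) {
        y2 <- y1 + 4L + spacer
        if (!(y2 %in% halves)) next
        acidic <- .acidic_before(chars, y1)
        if (acidic && "ITAM" %in% which) {
          # one hit per admissible acidic-prefix position
          for (d in 1:3) {
            p <- y1 - d
            if (p >= 0L && chars[p + 1L] %in% c("D", "E"))
              out[[length(out) + 1L]] <-
                .hit_row("ITAM", p, y2 + 4L, chars, c(y1, y2))
          }
        }
        if (!acidic && "ITAM_like" %in% which)
          out[[length(out) + 1L]] <-
            .hit_row("ITAM_like", y1, y2 + 4L, chars, c(y1, y2))
      }
    }
  }
  if (!length(out))
    return(data.frame(motif = character(0), start = integer(0),
                      end = integer(0), matched = character(0),
                      anchors = character(0), variant = logical(0),
                      stringsAsFactors = FALSE))
  hits <- do.call(rbind, out)
  hits <- hits[order(hits$start, hits$motif, hits$end), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Classify a cytoplasmic domain by its motif content
#'
#' Applies the precedence ITAM > ITAM-like > (ITIM and ITSM) >
#' (two or more ITIM) > (one ITIM) > none.  Spacer variants of one
#' two-tyrosine motif are counted once (distinct first-tyrosine
#' offsets), because receptors are classified by motifs, not matches.
#'
#' @param aa Amino-acid string without gaps.
#' @return Object of class `cytoplasmic_class`: list with `label` (one
#'   of `ITAM`, `ITAM_like`, `ITIM_ITSM`, `ITIM_ITIM`, `ITIM_only`,
#'   `none`) and `hits` (the supporting [scan_motifs] rows).
#' @export
classify_cytoplasmic <- function(aa) {
  hits <- scan_motifs(aa, c("ITAM", "ITAM_like", "ITIM", "ITSM"))
  first_y <- function(m) {
    h <- hits[hits$motif == m, , drop = FALSE]
    unique(vapply(strsplit(h$anchors, ","), function(a)
      as.integer(a[1]), integer(1)))
  }
  n_itam  <- length(first_y("ITAM"))
  n_itaml <- length(first_y("ITAM_like"))
  n_itim  <- length(unique(hits$start[hits$motif == "ITIM"]))
  n_itsm  <- length(unique(hits$start[hits$motif == "ITSM"]))
  label <-
    if (n_itam > 0) "ITAM"
    else if (n_itaml > 0) "ITAM_like"
    else if (n_itim >= 1 && n_itsm >= 1) "ITIM_ITSM"
    else if (n_itim >= 2) "ITIM_ITIM"
    else if (n_itim == 1) "ITIM_only"
    else "none"
  structure(list(label = label, hits = hits), class = "cytoplasmic_class")
}

#' @export
print.cytoplasmic_class <- function(x, ...) {
  cat(sprintf("<cytoplasmic_class %s (%d supporting hits)>\n", x$label,
              nrow(x$hits)))
  invisible(x)
}

#' Second-half variant of a two-tyrosine activation motif
#'
#' Inspects the residue three positions after the second anchor
#' tyrosine of an ITAM or ITAM-like hit: methionine marks the
#' `YxxM` variant (Vav/PI3K-binding), leucine/isoleucine the canonical
#' `YxxL_I` second half.
#'
#' @param hit One row of a [scan_motifs] result with motif `ITAM` or
#'   `ITAM_like`.
#' @param aa The scanned amino-acid string.
#' @return `"YxxM"` or `"YxxL_I"`.
#' @export
itam_second_half_variant <- function(hit, aa) {
  if (nrow(hit) != 1L || !hit$motif %in% c("ITAM", "ITAM_like"))
    stop("contract error: hit must be a single ITAM or ITAM_like row",
         call. = FALSE)
  y2 <- as.integer(strsplit(hit$anchors, ",")[[1]][2])
  pos <- y2 + 3L
  if (is.na(y2) || pos + 1L > nchar(aa))
    stop("contract error: hit out of bounds for sequence", call. = FALSE)
  if (substr(aa, pos + 1L, pos + 1L) == "M") "YxxM" else "YxxL_I"
}
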