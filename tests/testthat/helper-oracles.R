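# Independent oracles used by the unit and acceptance tests.  These are
# deliberately separate implementations (regex window enumeration,
# explicit pathway enumeration, connected components) of the rules the
# package implements with different machinery.

GENETIC_CODE_ORACLE <- Biostrings::GENETIC_CODE

# --- Nei-Gojobori oracles ------------------------------------------------

# synonymous/nonsynonymous site counts by explicit neighbour enumeration
oracle_ng_sites <- function(codon) {
  nts <- c("A", "C", "G", "T")
  aa <- GENETIC_CODE_ORACLE[[codon]]
  syn <- 0L
  for (pos in 1:3) {
    for (nt in nts) {
      if (nt == substr(codon, pos, pos)) next
      mut <- codon
      substr(mut, pos, pos) <- nt
      aa2 <- GENETIC_CODE_ORACLE[[mut]]
      if (aa2 != "*" && aa2 == aa) syn <- syn + 1L
    }
  }
  c(s = syn / 3, n = 3 - syn / 3)
}

# all orderings of a vector (recursive permutation enumeration)
all_orderings <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in all_orderings(v[-i]))
      out[[length(out) + 1L]] <- c(v[i], rest)
  out
}

# pathway-averaged differences by explicit enumeration
oracle_ng_pair <- function(a, b) {
  diffs <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  if (!length(diffs)) return(c(sd = 0, nd = 0))
  walk_path <- function(ord, count_stops) {
    cur <- a; sd <- 0; nd <- 0
    for (pos in ord) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(b, pos, pos)
      if (GENETIC_CODE_ORACLE[[nxt]] == "*") {
        if (!count_stops) return(NULL)
        nd <- nd + 1
      } else if (GENETIC_CODE_ORACLE[[nxt]] == GENETIC_CODE_ORACLE[[cur]])
        sd <- sd + 1
      else nd <- nd + 1
      cur <- nxt
    }
    c(sd, nd)
  }
  paths <- Filter(Negate(is.null),
                  lapply(all_orderings(diffs), walk_path, count_stops = FALSE))
  if (!length(paths))
    paths <- lapply(all_orderings(diffs), walk_path, count_stops = TRUE)
  avg <- Reduce(`+`, paths) / length(paths)
  c(sd = avg[1], nd = avg[2])
}

oracle_sense_codons <- function() {
  names(GENETIC_CODE_ORACLE)[GENETIC_CODE_ORACLE != "*"]
}

# --- motif oracle (regex window enumeration) -----------------------------

# all 0-based (start, end) matches of a motif via perl lookahead regexes
oracle_motif_spans <- function(aa, motif) {
  find <- function(rx, width) {
    m <- gregexpr(paste0("(?=", rx, ")"), aa, perl = TRUE)[[1]]
    if (m[1] == -1) return(NULL)
    cbind(start = as.integer(m) - 1L, end = as.integer(m) - 1L + width)
  }
  spans <- switch(motif,
    ITIM = find("[ILVS].Y..[LV]", 6L),
    ITSM = find("T.Y..[VI]", 6L),
    endocytic = find("Y..[LMVIF]", 4L),
    GRB2_YxN = find("Y.N", 3L),
    YxxM_variant = find("Y..M", 4L),
    TEHKxS_box = rbind(find("TEHK.S", 6L), find("THEK.S", 6L)),
    ITAM = {
      out <- NULL
      for (sp in 6:8) for (d in 1:3) {
        rx <- sprintf("[DE].{%d}Y..[LI].{%d}Y..[LI]", d - 1L, sp)
        out <- rbind(out, find(rx, d + 4L + sp + 4L))
      }
      out
    },
    ITAM_like = {
      out <- NULL
      for (sp in 6:8) {
        rx <- sprintf("Y..[LI].{%d}Y..[LI]", sp)
        hits <- find(rx, 4L + sp + 4L)
        if (is.null(hits)) next
        keep <- vapply(hits[, 1], function(s) {
          lo <- max(0L, s - 3L)
          if (lo >= s) return(TRUE)
          !any(strsplit(substr(aa, lo + 1L, s), "")[[1]] %in% c("D", "E"))
        }, logical(1))
        out <- rbind(out, hits[keep, , drop = FALSE])
      }
      out
    },
    stop("unknown motif"))
  if (is.null(spans)) return(character(0))
  sort(unique(paste(spans[, 1], spans[, 2], sep = ":")))
}

random_aa <- function(n, alphabet = c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# --- clustering oracle ---------------------------------------------------

# connected components of the "divergence <= threshold" graph
oracle_cluster_components <- function(dmat, threshold) {
  n <- nrow(dmat)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i != j && dmat[i, j] <= threshold && comp[j] != comp[i]) {
        comp[comp == comp[j]] <- comp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(comp, unique(comp))
}

# --- tree helpers --------------------------------------------------------

random_additive_matrix <- function(n_taxa) {
  tr <- ape::rtree(n_taxa, rooted = FALSE,
                   br = function(k) stats::runif(k, 0.1, 1))
  dm <- ape::cophenetic.phylo(tr)
  dm <- dm[sort(rownames(dm)), sort(rownames(dm))]
  list(tree = tr, dm = dm)
}

same_topology <- function(t1, t2) {
  ape::dist.topo(ape::unroot(t1), ape::unroot(t2)) == 0
}

# --- misc ----------------------------------------------------------------

random_nt_seq <- function(id, len, gap_frac = 0) {
  v <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  if (gap_frac > 0) {
    k <- rbinom(1, len, gap_frac)
    if (k > 0) v[sample(len, k)] <- "-"
  }
  cea_seq(id, paste(v, collapse = ""), "nucleotide")
}

make_track <- function(values, excluded = rep(FALSE, length(values)),
                       pair = c("a", "b")) {
  vals <- values
  vals[excluded] <- NA_real_
  structure(list(values = vals, excluded = excluded, pair = pair,
                 L = length(values)), class = "syn_diff_track")
}
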