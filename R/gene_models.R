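# Exon-structured gene models and the family delineation rules:
# GT-AG splice checks, pseudogene calling (N-exon stops / splice lesions,
# plus leader-exon lesions in opossum mode), donor read-through
# truncation, N-exon clustering for gene counting, and inhibitory /
# activating receptor pairing.

EXON_TYPES <- c("L", "N", "A", "B", "TM", "GPI_signal",
                "Cyt1", "Cyt2", "Cyt3", "Cyt4")

#' Create an exon model
#'
#' @param exon_type One of `L`, `N`, `A`, `B`, `TM`, `GPI_signal`,
#'   `Cyt1`..`Cyt4`.
#' @param sequence Exonic nucleotide string.
#' @param acceptor Two-nt splice acceptor dinucleotide immediately
#'   upstream (`""` for a terminal first exon).
#' @param donor Two-nt splice donor dinucleotide immediately downstream
#'   (`""` for a terminal last exon).
#' @param phase_after Intron phase after the exon: 0 (`xxx-intron-xxx`),
#'   1 (`x-intron-xx`) or 2 (`xx-intron-x`).
#' @param frame_offset Reading-frame offset of the first codon within
#'   the exon (0, 1 or 2).
#' @return Object of class `exon_model`.
#' @export
exon_model <- function(exon_type, sequence, acceptor = "", donor = "",
                       phase_after = 0L, frame_offset = 0L) {
  stopifnot(exon_type %in% EXON_TYPES,
            phase_after %in% 0:2, frame_offset %in% 0:2,
            nchar(acceptor) %in% c(0L, 2L), nchar(donor) %in% c(0L, 2L))
  structure(list(exon_type = exon_type,
                 sequence = toupper(sequence),
                 acceptor = toupper(acceptor), donor = toupper(donor),
                 phase_after = as.integer(phase_after),
                 frame_offset = as.integer(frame_offset)),
            class = "exon_model")
}

#' Create a gene model
#'
#' @param gene_id Unique gene identifier.
#' @param species Species tag.
#' @param exons List of [exon_model] in transcript order (canonical
#'   layout `L, N..., A/B..., [TM], [Cyt...]`).
#' @param anchor_class Membrane anchorage taken from the input
#'   annotation: `"transmembrane"`, `"secreted"` or `"GPI"`.
#' @return Object of class `gene_model` with `status`/`status_reasons`
#'   unset (see [call_pseudogene]) and `receptor_class` unset (see
#'   [classify_cytoplasmic]).
#' @export
gene_model <- function(gene_id, species, exons,
                       anchor_class = c("transmembrane", "secreted", "GPI")) {
  anchor_class <- match.arg(anchor_class)
  stopifnot(is.character(gene_id), nzchar(gene_id),
            all(vapply(exons, inherits, logical(1), "exon_model")))
  structure(list(gene_id = gene_id, species = species, exons = exons,
                 anchor_class = anchor_class,
                 status = NA_character_, status_reasons = character(0),
                 receptor_class = NA_character_),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model %s (%s): %s; status=%s; class=%s>\n",
              x$gene_id, x$species,
              paste(vapply(x$exons, `[[`, character(1), "exon_type"),
                    collapse = "-"),
              x$status, x$receptor_class))
  invisible(x)
}

# exons of a given type (internal)
gene_exons <- function(gene, type) {
  Filter(function(e) e$exon_type == type, gene$exons)
}

#' Check splice-site dinucleotides of an exon
#'
#' The canonical GT-AG rule: the acceptor dinucleotide must be `AG`, the
#' donor `GT`.  Terminal ends (empty dinucleotide) are skipped.
#'
#' @param exon An [exon_model].
#' @return List with `acceptor_valid`, `donor_valid` (logical, `NA` for
#'   a skipped terminal end) and `valid` (no populated end invalid).
#' @export
check_splice_sites <- function(exon) {
  acc <- if (nzchar(exon$acceptor)) exon$acceptor == "AG" else NA
  don <- if (nzchar(exon$donor)) exon$donor == "GT" else NA
  list(acceptor_valid = acc, donor_valid = don,
       valid = !isFALSE(acc) && !isFALSE(don))
}

# in-frame stop codon in an exon's own frame? (internal)
exon_has_stop <- function(exon) {
  grepl("*", translate_nt(exon$sequence, exon$frame_offset), fixed = TRUE)
}

#' Call gene versus pseudogene status
#'
#' A family member is registered as a pseudogene when its N-domain exon
#' contains an in-frame stop codon or lacks appropriate splice acceptor
#' (`AG`) / donor (`GT`) sites.  In `"opossum"` mode a corrupted leader
#' peptide exon (in-frame stop or invalid splice site on the L exon) is
#' an additional pseudogene criterion.
#'
#' @param gene A [gene_model] with at least one N exon.
#' @param mode `"default"` or `"opossum"`.
#' @return The gene with `status` (`"gene"` or `"pseudogene"`) and
#'   `status_reasons` filled in.
#' @export
call_pseudogene <- function(gene, mode = c("default", "opossum")) {
  mode <- match.arg(mode)
  n_exons <- gene_exons(gene, "N")
  if (!length(n_exons))
    stop(sprintf("structure error: gene %s has no N exon", gene$gene_id),
         call. = FALSE)
  reasons <- character(0)
  for (ex in n_exons) {
    if (exon_has_stop(ex))
      reasons <- c(reasons, "stop in N exon")
    if (!check_splice_sites(ex)$valid)
      reasons <- c(reasons, "invalid splice site on N exon")
  }
  if (mode == "opossum") {
    for (ex in gene_exons(gene, "L")) {
      if (exon_has_stop(ex))
        reasons <- c(reasons, "stop in L exon")
      if (!check_splice_sites(ex)$valid)
        reasons <- c(reasons, "invalid splice site on L exon")
    }
  }
  gene$status_reasons <- unique(reasons)
  gene$status <- if (length(gene$status_reasons)) "pseudogene" else "gene"
  gene
}

#' Detect splice-donor read-through and premature termination
#'
#' For an exon with a defective splice donor the transcript reads
#' through into the intron; translation continues in the exon's frame
#' across the exon/intron boundary.  Reports the read-through codons
#' (codons containing at least one intronic nucleotide) that are stop
#' codons, up to the first two stops within the first 60 intronic
#' nucleotides, and classifies the product as secreted-truncated when a
#' stop is found.
#'
#' @param exon An [exon_model] whose donor is invalid.
#' @param downstream Intronic nucleotide string following the exon.
#' @return List with `stop_codons` (1-based indices among read-through
#'   codons), `stop_nt_positions` (1-based first-nt position of each
#'   stop within `downstream`), `truncated`, and `product`
#'   (`"secreted-truncated"` or `"full-length"`).
#' @export
detect_donor_readthrough <- function(exon, downstream) {
  if (check_splice_sites(exon)$donor_valid %in% TRUE)
    stop("contract error: donor site is valid; no read-through expected",
         call. = FALSE)
  leftover_n <- (nchar(exon$sequence) - exon$frame_offset) %% 3L
  leftover <- if (leftover_n > 0)
    substr(exon$sequence, nchar(exon$sequence) - leftover_n + 1L,
           nchar(exon$sequence)) else ""
  downstream <- toupper(downstream)
  window <- substr(downstream, 1L, 60L)
  aa <- translate_nt(paste0(leftover, window), 0L)
  stops <- which(strsplit(aa, "")[[1]] == "*")
  stops <- utils::head(stops, 2L)
  # first nt of stop codon k within downstream (1-based)
  nt_pos <- (stops - 1L) * 3L + 1L - leftover_n
  list(stop_codons = stops, stop_nt_positions = nt_pos,
       truncated = length(stops) > 0,
       product = if (length(stops)) "secreted-truncated" else "full-length")
}

# uncorrected p-distance between two equal-length nt strings with
# pairwise deletion of non-ACGT sites (internal)
p_distance_nt <- function(a, b) {
  va <- strsplit(toupper(a), "")[[1]]
  vb <- strsplit(toupper(b), "")[[1]]
  stopifnot(length(va) == length(vb))
  use <- va %in% c("A", "C", "G", "T") & vb %in% c("A", "C", "G", "T")
  if (!any(use)) return(NA_real_)
  mean(va[use] != vb[use])
}

#' Cluster N-domain exons for gene counting
#'
#' Distinct N-domain exons with sequence divergence above the threshold
#' are counted as distinct genes; exon pairs at or below the threshold
#' are joined by single linkage (connectivity, not centroids).
#' Divergence is the uncorrected nucleotide p-distance over sites where
#' both sequences carry an unambiguous base.
#'
#' @param seqs List of equal-length nucleotide [cea_seq] records.
#' @param threshold Divergence fraction above which exons count as
#'   distinct (default 0.01, i.e. the 1 percent rule).
#' @return List with `partition` (named integer vector of cluster
#'   memberships) and `count` (number of clusters).
#' @export
cluster_n_exons <- function(seqs, threshold = 0.01) {
  if (!length(seqs)) return(list(partition = integer(0), count = 0L))
  ids <- vapply(seqs, function(s) s$id, character(1))
  n <- length(seqs)
  if (n == 1L)
    return(list(partition = stats::setNames(1L, ids), count = 1L))
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d[i, j] <- d[j, i] <- p_distance_nt(seqs[[i]]$residues,
                                        seqs[[j]]$residues)
  }
  hc <- stats::hclust(stats::as.dist(d), method = "single")
  part <- stats::cutree(hc, h = threshold)
  list(partition = part, count = length(unique(part)))
}

# fraction of identical residues between two equal-length aa strings,
# over positions where neither has a gap/X (internal)
aa_identity <- function(a, b) {
  va <- strsplit(toupper(a), "")[[1]]
  vb <- strsplit(toupper(b), "")[[1]]
  stopifnot(length(va) == length(vb))
  use <- !(va %in% c("-", "X", "*")) & !(vb %in% c("-", "X", "*"))
  if (!any(use)) return(NA_real_)
  mean(va[use] == vb[use])
}

#' Pair inhibitory with activating receptor genes
#'
#' Paired immune receptors are extracellularly near-identical gene pairs
#' in which one member signals through ITIM/ITSM motifs and the other
#' through an ITAM or ITAM-like motif.  For every inhibitory gene the
#' same-species activating gene with maximal N-domain amino-acid
#' identity is emitted as a candidate, provided the identity reaches the
#' floor.
#'
#' @param genes List of [gene_model]s with `status` and `receptor_class`
#'   assigned.
#' @param n_domain_aa Named character vector: per-gene amino-acid
#'   N-domain sequences (equal length within a species).
#' @param identity_floor Minimum N-domain identity (default 0.80).
#' @return data.frame with columns `inhibitory`, `activating`,
#'   `identity`, `species`; zero rows when nothing qualifies.
#' @export
pair_receptors <- function(genes, n_domain_aa, identity_floor = 0.80) {
  genes <- Filter(function(g) identical(g$status, "gene"), genes)
  cls <- vapply(genes, `[[`, character(1), "receptor_class")
  ids <- vapply(genes, `[[`, character(1), "gene_id")
  sp  <- vapply(genes, `[[`, character(1), "species")
  inhib <- which(cls %in% c("ITIM_ITSM", "ITIM_ITIM", "ITIM_only"))
  activ <- which(cls %in% c("ITAM", "ITAM_like"))
  out <- list()
  for (i in inhib[order(ids[inhib])]) {
    cand <- activ[sp[activ] == sp[i]]
    if (!length(cand)) next
    idy <- vapply(cand, function(j)
      aa_identity(n_domain_aa[[ids[i]]], n_domain_aa[[ids[j]]]), numeric(1))
    idy[is.na(idy)] <- -Inf
    best <- cand[order(-idy, ids[cand])][1]
    best_idy <- max(idy)
    if (is.finite(best_idy) && best_idy >= identity_floor)
      out[[length(out) + 1L]] <- data.frame(
        inhibitory = ids[i], activating = ids[best],
        identity = best_idy, species = sp[i], stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(inhibitory = character(0), activating = character(0),
                      identity = numeric(0), species = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Summarize a gene family catalog
#'
#' Per-species counts in the style of a family characteristics table:
#' total genes, pseudogenes, activating (ITAM/ITAM-like), inhibitory
#' (ITIM/ITSM-bearing) and secreted members.
#'
#' @param genes List of classified [gene_model]s (`status` and
#'   `receptor_class` assigned).
#' @return data.frame with one row per species.
#' @export
family_counts <- function(genes) {
  sp  <- vapply(genes, `[[`, character(1), "species")
  cls <- vapply(genes, `[[`, character(1), "receptor_class")
  st  <- vapply(genes, `[[`, character(1), "status")
  anc <- vapply(genes, `[[`, character(1), "anchor_class")
  out <- lapply(sort(unique(sp)), function(s) {
    k <- sp == s
    data.frame(species = s,
               total = sum(k),
               pseudogenes = sum(k & st == "pseudogene"),
               itam_like = sum(k & st == "gene" &
                                 cls %in% c("ITAM", "ITAM_like")),
               itim_itsm = sum(k & st == "gene" &
                                 cls %in% c("ITIM_ITSM", "ITIM_ITIM",
                                            "ITIM_only")),
               secreted = sum(k & anc == "secreted"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Read a gene-structure table
#'
#' Tab-separated, one exon per row, columns `gene_id`, `species`,
#' `exon_index`, `exon_type`, `acceptor`, `donor`, `phase_after`,
#' `frame_offset`, `sequence`, `anchor_class` (anchor repeated per
#' gene; `.` stands for an empty dinucleotide).  Lines starting with
#' `#` are ignored.
#'
#' @param path Path to the TSV file.
#' @return List of [gene_model]s in first-appearance order.
#' @export
read_gene_table <- function(path) {
  tb <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("gene_id", "species", "exon_index", "exon_type", "acceptor",
            "donor", "phase_after", "frame_offset", "sequence",
            "anchor_class")
  miss <- setdiff(need, names(tb))
  if (length(miss))
    stop("gene table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  undot <- function(x) ifelse(x == ".", "", x)
  lapply(unique(tb$gene_id), function(g) {
    rows <- tb[tb$gene_id == g, , drop = FALSE]
    rows <- rows[order(as.integer(rows$exon_index)), , drop = FALSE]
    exons <- lapply(seq_len(nrow(rows)), function(r)
      exon_model(rows$exon_type[r], rows$sequence[r],
                 undot(rows$acceptor[r]), undot(rows$donor[r]),
                 as.integer(rows$phase_after[r]),
                 as.integer(rows$frame_offset[r])))
    gene_model(g, rows$species[1], exons, rows$anchor_class[1])
  })
}

#' Write a gene-structure table
#'
#' @param genes List of [gene_model]s.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_gene_table <- function(genes, path) {
  dot <- function(x) ifelse(nzchar(x), x, ".")
  rows <- do.call(rbind, lapply(genes, function(g)
    do.call(rbind, lapply(seq_along(g$exons), function(k) {
      e <- g$exons[[k]]
      data.frame(gene_id = g$gene_id, species = g$species, exon_index = k,
                 exon_type = e$exon_type, acceptor = dot(e$acceptor),
                 donor = dot(e$donor), phase_after = e$phase_after,
                 frame_offset = e$frame_offset, sequence = e$sequence,
                 anchor_class = g$anchor_class, stringsAsFactors = FALSE)
    }))))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
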