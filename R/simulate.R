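# Gene-family simulator with known ground truth.
#
# Codon evolution uses a transparent acceptance-probability scheme: a
# proposed single-nucleotide change is accepted with probability 1 when
# synonymous, probability omega when nonsynonymous, and never when it
# creates a stop codon.  Realized dN/dS therefore approximates omega,
# which makes the simulator the recovery oracle for the Nei-Gojobori
# estimator.  The family generator assembles exon-structured genes
# (leader, N, IgC-like A, TM, cytoplasmic exons), implants motif
# classes, pseudogenizing lesions, N-exon clusters at controlled
# divergence and gene-conversion tracts between a paired inhibitory /
# activating receptor couple.

# synonymous-codon table (internal)
.syn_table <- function() {
  if (!is.null(.codon_env$syn)) return(.codon_env$syn)
  code <- .genetic_code()
  sense <- sense_codons()
  .codon_env$syn <- split(sense, unname(code[sense]))
  .codon_env$syn
}

.random_sense_codons <- function(L) sample(sense_codons(), L, replace = TRUE)

#' Simulation configuration for codon evolution
#'
#' @param L Number of codons (default 300).
#' @param omega dN/dS acceptance probability for nonsynonymous changes
#'   (>= 0).
#' @param seed Random seed (mandatory).
#' @param tree Optional newick text; when `NULL` a random topology with
#'   `n_taxa` tips and uniform branch lengths in `branch_range`
#'   (substitution proposals per site) is drawn.
#' @param n_taxa Number of tips for the random topology (default 7).
#' @param branch_range Branch-length range (default 0.02-0.12, keeping
#'   pairwise synonymous divergence well below saturation).
#' @param mu Proposal rate per nucleotide site per unit branch length
#'   (default 1, so branch lengths are in proposal units).
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(L = 300L, omega = 0.5, seed, tree = NULL,
                       n_taxa = 7L, branch_range = c(0.02, 0.12),
                       mu = 1) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  if (omega < 0) stop("config error: omega must be >= 0", call. = FALSE)
  structure(list(L = as.integer(L), omega = omega, seed = seed,
                 tree = tree, n_taxa = as.integer(n_taxa),
                 branch_range = branch_range, mu = mu),
            class = "sim_config")
}

# evolve codons along one branch (internal)
.evolve_branch <- function(codons, t, omega, mu) {
  code <- .genetic_code()
  L <- length(codons)
  n_events <- stats::rpois(1, mu * 3 * L * t)
  if (n_events == 0) return(codons)
  sites <- sample.int(3L * L, n_events, replace = TRUE)
  for (s in sites) {
    ci <- (s - 1L) %/% 3L + 1L
    p <- (s - 1L) %% 3L + 1L
    cur <- codons[ci]
    alt <- sample(setdiff(NT, substr(cur, p, p)), 1L)
    mut <- cur
    substr(mut, p, p) <- alt
    if (code[[mut]] == "*") next
    if (code[[mut]] == code[[cur]] || stats::runif(1) < omega)
      codons[ci] <- mut
  }
  codons
}

#' Simulate codon evolution along a tree
#'
#' A root sequence of random sense codons evolves along each branch
#' with Poisson-distributed mutation proposals; acceptance follows the
#' omega rule described above.  Deterministic given the seed.
#'
#' @param cfg A [sim_config].
#' @return List with `aln` (codon alignment of the tip sequences),
#'   `tree` (the generating `phylo`), `omega` and `seed`.
#' @export
simulate_codon_evolution <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  tree <- if (is.null(cfg$tree)) {
    ape::rtree(cfg$n_taxa, rooted = FALSE,
               br = function(n) stats::runif(n, cfg$branch_range[1],
                                             cfg$branch_range[2]))
  } else read_newick(text = cfg$tree)
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  node_seq <- vector("list", n_tip + tree$Nnode)
  node_seq[[root]] <- .random_sense_codons(cfg$L)
  # parent-before-child edge order
  ord <- rev(postorder_edges(tree))
  for (e in ord) {
    par <- tree$edge[e, 1]; child <- tree$edge[e, 2]
    node_seq[[child]] <- .evolve_branch(node_seq[[par]],
                                        tree$edge.length[e],
                                        cfg$omega, cfg$mu)
  }
  rows <- lapply(seq_len(n_tip), function(i)
    cea_seq(tree$tip.label[i], paste(node_seq[[i]], collapse = ""),
            "nucleotide"))
  list(aln = build_codon_alignment(rows), tree = tree,
       omega = cfg$omega, seed = cfg$seed)
}

# edge indices in postorder (children before parents); internal
postorder_edges <- function(tree) {
  tr <- ape::reorder.phylo(tree, "postorder")
  match(paste(tr$edge[, 1], tr$edge[, 2]),
        paste(tree$edge[, 1], tree$edge[, 2]))
}

#' Implant a gene-conversion tract
#'
#' Replaces the acceptor row's codons inside the tract by the donor's,
#' emulating a nonreciprocal transfer between paralogs.
#'
#' @param aln A codon alignment.
#' @param donor,acceptor Row identifiers or indices.
#' @param start First tract codon (1-based).
#' @param length Tract length in codons (0 = no-op).
#' @return List with `aln` (modified alignment) and `truth`
#'   (`donor`, `acceptor`, `start`, `end`).
#' @export
implant_conversion <- function(aln, donor, acceptor, start, length) {
  if (is.character(donor)) donor <- match(donor, aln$ids)
  if (is.character(acceptor)) acceptor <- match(acceptor, aln$ids)
  if (length < 0 || start < 1 || (length > 0 && start + length - 1 > aln$n_codon))
    stop("config error: conversion tract out of bounds", call. = FALSE)
  if (length > 0) {
    cols <- (3L * (start - 1L) + 1L):(3L * (start + length - 1L))
    aln$mat[acceptor, cols] <- aln$mat[donor, cols]
  }
  list(aln = aln,
       truth = list(donor = aln$ids[donor], acceptor = aln$ids[acceptor],
                    start = start,
                    end = if (length > 0) start + length - 1L else NA_integer_))
}

# ---- gene-family generation -------------------------------------------

.FILLER_AA <- c("A", "G", "P", "Q", "R", "K", "N", "F", "H", "W", "C", "M")

.rand_filler <- function(n) paste(sample(.FILLER_AA, n, replace = TRUE),
                                  collapse = "")

# motif cassette for a cytoplasmic class (internal)
.motif_cassette <- function(class) {
  switch(class,
         ITIM_ITSM = paste0("LAYSEL", .rand_filler(2), "TAYASV"),
         ITIM_ITIM = paste0("LAYSEL", .rand_filler(2), "VAYSEV"),
         ITAM      = paste0("EAA", "YAAL", .rand_filler(6), "YAAL"),
         ITAM_like = paste0("YAAL", .rand_filler(6), "YAAL"),
         none      = .rand_filler(12),
         stop("unknown motif class: ", class, call. = FALSE))
}

# build a cytoplasmic-domain aa string of the requested class by
# construction plus rejection sampling (internal)
.make_cyt_aa <- function(class, len = 30L, max_attempts = 10000L) {
  for (attempt in seq_len(max_attempts)) {
    cassette <- .motif_cassette(class)
    pad <- max(0L, len - nchar(cassette) - 3L)
    aa <- paste0(.rand_filler(3), cassette, .rand_filler(pad))
    if (classify_cytoplasmic(aa)$label == class) return(aa)
  }
  stop("generation error: rejection sampling failed for class ", class,
       call. = FALSE)
}

# reverse-translate an aa string to random codons (internal)
.reverse_translate <- function(aa) {
  syn <- .syn_table()
  paste(vapply(strsplit(aa, "")[[1]], function(a)
    sample(syn[[a]], 1L), character(1)), collapse = "")
}

# mutate nt string at n_mut exclusive positions drawn from pool,
# keeping all codons sense; returns list(seq, pool) (internal)
.mutate_sense <- function(nt, n_mut, pool) {
  code <- .genetic_code()
  done <- 0L
  while (done < n_mut && length(pool)) {
    pos <- pool[sample.int(length(pool), 1L)]
    pool <- setdiff(pool, pos)
    ci <- (pos - 1L) %/% 3L + 1L
    codon <- substr(nt, 3L * ci - 2L, 3L * ci)
    p <- pos - 3L * (ci - 1L)
    for (alt in sample(setdiff(NT, substr(codon, p, p)))) {
      mut <- codon
      substr(mut, p, p) <- alt
      if (code[[mut]] != "*") {
        substr(nt, pos, pos) <- alt
        done <- done + 1L
        break
      }
    }
  }
  list(seq = nt, pool = pool)
}

# per-codon synonymous scrambling; optional nonsynonymous substitutions
# at rate nonsyn_rate (internal)
.scramble <- function(nt, syn_rate, nonsyn_rate = 0) {
  syn <- .syn_table()
  code <- .genetic_code()
  L <- nchar(nt) %/% 3L
  starts <- seq(1L, by = 3L, length.out = L)
  codons <- substring(nt, starts, starts + 2L)
  for (i in seq_len(L)) {
    if (stats::runif(1) < syn_rate) {
      alts <- setdiff(syn[[unname(code[codons[i]])]], codons[i])
      if (length(alts)) codons[i] <- sample(alts, 1L)
    }
    if (nonsyn_rate > 0 && stats::runif(1) < nonsyn_rate) {
      aa <- unname(code[codons[i]])
      other <- setdiff(names(syn), c(aa, "*"))
      codons[i] <- sample(syn[[sample(other, 1L)]], 1L)
    }
  }
  paste(codons, collapse = "")
}

#' Gene-family simulation configuration
#'
#' @param genes List of per-gene directives, each a list with fields
#'   `id`, `cluster` (label; genes sharing a label form one N-exon
#'   cluster), `motif_class` (`ITIM_ITSM`, `ITIM_ITIM`, `ITAM`,
#'   `ITAM_like`, `none`), `anchor_class`, `lesion` (`none`,
#'   `stop_in_N`, `bad_splice_N`, `corrupt_L`) and optional
#'   `paired_with` (id of the inhibitory template this activating gene
#'   derives from).
#' @param species Species tag (default `"synthetica"`; the emitted data
#'   are synthetic, no real accession stands behind them).
#' @param seed Random seed (mandatory).
#' @param n_len,l_len,a_len,tm_len,cyt_len Exon sizes (codons / aa).
#'   The N exon defaults to 108 codons, the first 12 of which encode
#'   leader-derived residues.
#' @param within_divergence,between_divergence Target nucleotide
#'   p-distances inside and between N-exon clusters (defaults 0.004 and
#'   0.04, bracketing the 1 percent counting threshold).
#' @param pair_syn_divergence Per-codon synonymous scrambling rate
#'   between a paired activating gene and its inhibitory template
#'   (default 0.2, i.e. a synonymous background of roughly dS 0.3 with
#'   near-identical protein sequence).
#' @param pair_nonsyn_divergence Nonsynonymous substitution rate within
#'   the pair (default 0.02, keeping N-domain identity ~0.98).
#' @param conversion Optional tract directive
#'   `list(donor=, acceptor=, start=, length=)` in N-exon codon
#'   coordinates.
#' @param pseudogene_mode `"default"` or `"opossum"` (used for the
#'   truth labels).
#' @return Object of class `family_config`.
#' @export
family_config <- function(genes = NULL, species = "synthetica", seed,
                          n_len = 108L, l_len = 18L, a_len = 93L,
                          tm_len = 24L, cyt_len = 30L,
                          within_divergence = 0.004,
                          between_divergence = 0.04,
                          pair_syn_divergence = 0.2,
                          pair_nonsyn_divergence = 0.02,
                          conversion = list(start = 21L, length = 60L),
                          pseudogene_mode = "default") {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  if (is.null(genes)) {
    genes <- list(
      list(id = "CC1a", cluster = "c1", motif_class = "ITIM_ITSM",
           anchor_class = "transmembrane", lesion = "none"),
      list(id = "CC1b", cluster = "c1", motif_class = "ITIM_ITSM",
           anchor_class = "transmembrane", lesion = "none"),
      list(id = "CC3", cluster = "pair", motif_class = "ITAM_like",
           anchor_class = "transmembrane", lesion = "none",
           paired_with = "CC1a"),
      list(id = "CC5", cluster = "c2", motif_class = "none",
           anchor_class = "secreted", lesion = "none"),
      list(id = "CCps", cluster = "c3", motif_class = "none",
           anchor_class = "transmembrane", lesion = "stop_in_N"))
    if (!is.null(conversion) && is.null(conversion$donor)) {
      conversion$donor <- "CC1a"; conversion$acceptor <- "CC3"
    }
  }
  if (!is.null(conversion) &&
      (conversion$start < 1 ||
       conversion$start + conversion$length - 1L > n_len))
    stop("config error: conversion tract outside the N exon",
         call. = FALSE)
  structure(list(genes = genes, species = species, seed = seed,
                 n_len = as.integer(n_len), l_len = as.integer(l_len),
                 a_len = as.integer(a_len), tm_len = as.integer(tm_len),
                 cyt_len = as.integer(cyt_len),
                 within_divergence = within_divergence,
                 between_divergence = between_divergence,
                 pair_syn_divergence = pair_syn_divergence,
                 pair_nonsyn_divergence = pair_nonsyn_divergence,
                 conversion = conversion,
                 pseudogene_mode = pseudogene_mode),
            class = "family_config")
}

#' Simulate an exon-structured gene family with ground truth
#'
#' Assembles gene models from exon scaffolds: N exons drawn from
#' clusters at controlled divergence, cytoplasmic exons encoding the
#' configured motif class (and no higher-precedence motif, enforced by
#' rejection sampling), pseudogenizing lesions, and an optional
#' gene-conversion tract copied from the inhibitory to the activating
#' member of a receptor pair.
#'
#' @param cfg A [family_config].
#' @return List with `genes` (list of [gene_model]), `truth` (classes,
#'   status, cluster partition, pair table, conversion tract) and `cfg`.
#' @export
simulate_gene_family <- function(cfg) {
  stopifnot(inherits(cfg, "family_config"))
  set.seed(cfg$seed)
  anc <- list(
    L = paste(.random_sense_codons(cfg$l_len), collapse = ""),
    N = paste(.random_sense_codons(cfg$n_len), collapse = ""),
    A = paste(.random_sense_codons(cfg$a_len), collapse = ""),
    TM = paste(.random_sense_codons(cfg$tm_len), collapse = ""))
  ids <- vapply(cfg$genes, `[[`, character(1), "id")
  clusters <- vapply(cfg$genes, `[[`, character(1), "cluster")
  paired <- vapply(cfg$genes, function(g)
    if (is.null(g$paired_with)) NA_character_ else g$paired_with,
    character(1))
  nt_len <- 3L * cfg$n_len
  pool <- seq_len(nt_len)
  n_between <- max(1L, round(nt_len * cfg$between_divergence / 2))
  n_within <- round(nt_len * cfg$within_divergence / 2)
  founders <- list()
  n_seqs <- stats::setNames(vector("list", length(ids)), ids)
  for (cl in unique(clusters[is.na(paired)])) {
    f <- .mutate_sense(anc$N, n_between, pool)
    founders[[cl]] <- f$seq; pool <- f$pool
    for (k in which(clusters == cl & is.na(paired))) {
      m <- .mutate_sense(founders[[cl]], n_within, pool)
      n_seqs[[ids[k]]] <- m$seq; pool <- m$pool
    }
  }
  # paired activating genes: synonymous-heavy divergence from template
  for (k in which(!is.na(paired))) {
    tmpl <- n_seqs[[paired[k]]]
    if (is.null(tmpl))
      stop("config error: paired_with references unknown gene",
           call. = FALSE)
    n_seqs[[ids[k]]] <- .scramble(tmpl, cfg$pair_syn_divergence,
                                  cfg$pair_nonsyn_divergence)
  }
  conv_truth <- NULL
  if (!is.null(cfg$conversion) && !is.null(cfg$conversion$donor)) {
    cv <- cfg$conversion
    cols <- (3L * (cv$start - 1L) + 1L):(3L * (cv$start + cv$length - 1L))
    don <- n_seqs[[cv$donor]]
    acc <- n_seqs[[cv$acceptor]]
    substr(acc, min(cols), max(cols)) <- substr(don, min(cols), max(cols))
    n_seqs[[cv$acceptor]] <- acc
    conv_truth <- list(donor = cv$donor, acceptor = cv$acceptor,
                       start = cv$start,
                       end = cv$start + cv$length - 1L)
  }
  genes <- lapply(seq_along(cfg$genes), function(k) {
    gspec <- cfg$genes[[k]]
    exons <- list(exon_model("L", .scramble(anc$L, 0.05), "", "GT"))
    exons <- c(exons, list(exon_model("N", n_seqs[[gspec$id]], "AG", "GT")))
    exons <- c(exons, list(exon_model("A", .scramble(anc$A, 0.05), "AG",
                                      if (gspec$anchor_class == "secreted")
                                        "" else "GT")))
    if (gspec$anchor_class != "secreted") {
      exons <- c(exons, list(exon_model("TM", .scramble(anc$TM, 0.05),
                                        "AG", "GT")))
      cyt_aa <- .make_cyt_aa(gspec$motif_class, cfg$cyt_len)
      box_aa <- paste0(.rand_filler(4), "TEHK",
                       sample(.FILLER_AA, 1), "S", .rand_filler(4))
      exons <- c(exons,
                 list(exon_model("Cyt1", .reverse_translate(box_aa),
                                 "AG", "GT"),
                      exon_model("Cyt2", .reverse_translate(.rand_filler(10)),
                                 "AG", "GT"),
                      exon_model("Cyt3", .reverse_translate(cyt_aa),
                                 "AG", "")))
    }
    g <- gene_model(gspec$id, cfg$species, exons, gspec$anchor_class)
    # lesions
    les <- gspec$lesion
    if (identical(les, "stop_in_N")) {
      ex <- g$exons[[2]]
      mid <- 3L * (cfg$n_len %/% 2L) + 1L
      substr(ex$sequence, mid, mid + 2L) <- "TAA"
      g$exons[[2]] <- ex
    } else if (identical(les, "bad_splice_N")) {
      g$exons[[2]]$donor <- "AT"
    } else if (identical(les, "corrupt_L")) {
      ex <- g$exons[[1]]
      substr(ex$sequence, 7L, 9L) <- "TGA"
      g$exons[[1]] <- ex
    }
    g
  })
  lesions <- vapply(cfg$genes, `[[`, character(1), "lesion")
  expect_pseudo <- lesions %in% c("stop_in_N", "bad_splice_N") |
    (lesions == "corrupt_L" & cfg$pseudogene_mode == "opossum")
  classes <- vapply(cfg$genes, `[[`, character(1), "motif_class")
  classes[vapply(cfg$genes, `[[`, character(1), "anchor_class") ==
            "secreted"] <- "none"
  truth <- list(
    classes = stats::setNames(classes, ids),
    status = stats::setNames(ifelse(expect_pseudo, "pseudogene", "gene"),
                             ids),
    clusters = stats::setNames(clusters, ids),
    conversion = conv_truth,
    pairs = data.frame(inhibitory = paired[!is.na(paired)],
                       activating = ids[!is.na(paired)],
                       stringsAsFactors = FALSE),
    seed = cfg$seed)
  list(genes = genes, truth = truth, cfg = cfg)
}
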