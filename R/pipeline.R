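# End-to-end orchestration: classify cytoplasmic domains, call
# pseudogenes, count genes by N-exon clustering, build the NJ tree with
# bootstrap, profile dN/dS along the N exons, delineate conserved
# regions, pair inhibitory/activating receptors and test candidate
# pairs for gene-conversion tracts.  All reports are plain data.frames
# (written as TSV with a '#' metadata preamble when an output directory
# is given), and every stochastic stage derives its seed from the run
# seed, so a report is reproducible from inputs + config + seed.

#' Pipeline run configuration
#'
#' @param genes List of [gene_model]s, or `gene_table` path to a
#'   gene-structure TSV (see [read_gene_table]).
#' @param gene_table Optional TSV path (used when `genes` is `NULL`).
#' @param seed Run seed (mandatory; all stochastic stages derive from
#'   it).
#' @param cluster_threshold N-exon divergence threshold for gene
#'   counting (default 0.01).
#' @param distance_model Distance model for the N-exon tree (default
#'   `"jc69_nt"`).
#' @param bootstrap_B Bootstrap replicates (default 100).
#' @param conversion_epsilon,conversion_B Conversion-test tolerance and
#'   permutation count (defaults 0 and 1000).
#' @param identity_floor Pairing identity floor (default 0.80).
#' @param pseudogene_mode `"default"`, `"opossum"`, or `"auto"`
#'   (opossum rules applied to genes whose species tag is `"opossum"`).
#' @param out_dir Optional directory for TSV/newick outputs.
#' @param verbosity `"quiet"`, `"info"` or `"debug"`.
#' @return Object of class `run_config`.
#' @export
run_config <- function(genes = NULL, gene_table = NULL, seed,
                       cluster_threshold = 0.01,
                       distance_model = "jc69_nt", bootstrap_B = 100L,
                       conversion_epsilon = 0, conversion_B = 1000L,
                       identity_floor = 0.80,
                       pseudogene_mode = c("auto", "default", "opossum"),
                       out_dir = NULL,
                       verbosity = c("info", "quiet", "debug")) {
  if (missing(seed)) stop("config error: seed is mandatory", call. = FALSE)
  if (cluster_threshold <= 0 || cluster_threshold >= 1)
    stop("config error: cluster_threshold must lie in (0,1)",
         call. = FALSE)
  if (is.null(genes) && is.null(gene_table))
    stop("config error: provide genes or a gene_table path", call. = FALSE)
  structure(list(genes = genes, gene_table = gene_table, seed = seed,
                 cluster_threshold = cluster_threshold,
                 distance_model = distance_model,
                 bootstrap_B = as.integer(bootstrap_B),
                 conversion_epsilon = conversion_epsilon,
                 conversion_B = as.integer(conversion_B),
                 identity_floor = identity_floor,
                 pseudogene_mode = match.arg(pseudogene_mode),
                 out_dir = out_dir, verbosity = match.arg(verbosity)),
            class = "run_config")
}

.log <- function(cfg, level, ...) {
  lv <- c(quiet = 0, info = 1, debug = 2)
  if (lv[[cfg$verbosity]] >= lv[[level]])
    message(sprintf(...))
}

# translated cytoplasmic domain of a gene (internal)
.cyt_translation <- function(gene) {
  cyt <- Filter(function(e) startsWith(e$exon_type, "Cyt"), gene$exons)
  if (!length(cyt)) return("")
  paste(vapply(cyt, function(e)
    translate_nt(e$sequence, e$frame_offset), character(1)),
    collapse = "")
}

# write a report data.frame as TSV with '#' metadata preamble (internal)
.write_report <- function(df, path, meta) {
  con <- file(path, "w")
  on.exit(close(con))
  for (m in meta) writeLines(paste0("# ", m), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Run the full gene-family analysis
#'
#' Stages, in dependency order: load gene models; classify cytoplasmic
#' receptor class; call pseudogene status; cluster N exons and count
#' genes; summarize the family catalog; build the neighbour-joining
#' N-exon tree with bootstrap supports; compute the pairwise dN/dS
#' summary, per-codon substitution profile and conserved regions over
#' the N exons of intact genes; pair inhibitory with activating
#' receptors; run the gene-conversion permutation test on each
#' candidate pair.  Deterministic given the config seed.
#'
#' @param cfg A [run_config].
#' @return Object of class `analysis_report`: list with `catalog`
#'   (per-gene table), `counts` (per-species family table),
#'   `cluster_count`, `partition`, `tree` (with bootstrap supports),
#'   `dnds` ([dnds_summary] result or `NULL`), `profile`,
#'   `conserved_regions`, `pairs`, `conversion_calls` (data.frame) and
#'   `meta`.
#' @export
run_full_analysis <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  stage <- "load"
  report <- tryCatch({
    genes <- if (!is.null(cfg$genes)) cfg$genes
    else read_gene_table(cfg$gene_table)
    if (!length(genes))
      stop("config error: no genes in input", call. = FALSE)
    .log(cfg, "info", "loaded %d gene models", length(genes))

    stage <- "classify"
    genes <- lapply(genes, function(g) {
      aa <- gsub("\\*.*$", "", .cyt_translation(g))  # up to first stop
      g$receptor_class <- if (nzchar(aa)) classify_cytoplasmic(aa)$label
      else "none"
      g
    })

    stage <- "pseudogene"
    genes <- lapply(genes, function(g) {
      mode <- switch(cfg$pseudogene_mode,
                     auto = if (identical(g$species, "opossum"))
                       "opossum" else "default",
                     cfg$pseudogene_mode)
      call_pseudogene(g, mode)
    })

    stage <- "cluster"
    n_seqs <- lapply(genes, function(g)
      cea_seq(g$gene_id, gene_exons(g, "N")[[1]]$sequence, "nucleotide"))
    cl <- cluster_n_exons(n_seqs, cfg$cluster_threshold)
    .log(cfg, "info", "N-exon clustering: %d genes in %d clusters",
         length(genes), cl$count)

    stage <- "catalog"
    catalog <- do.call(rbind, lapply(genes, function(g)
      data.frame(gene_id = g$gene_id, species = g$species,
                 status = g$status,
                 reasons = paste(g$status_reasons, collapse = "; "),
                 receptor_class = g$receptor_class,
                 anchor_class = g$anchor_class,
                 cluster = cl$partition[[g$gene_id]],
                 stringsAsFactors = FALSE)))
    counts <- family_counts(genes)

    stage <- "tree"
    aln <- build_codon_alignment(n_seqs)
    tree <- if (length(n_seqs) >= 3)
      nj_bootstrap(aln, cfg$distance_model, B = cfg$bootstrap_B,
                   seed = cfg$seed + 1L)
    else NULL

    stage <- "dnds"
    intact <- vapply(genes, function(g) g$status == "gene", logical(1))
    aln_ok <- if (sum(intact) >= 2)
      build_codon_alignment(n_seqs[intact]) else NULL
    dnds <- if (!is.null(aln_ok))
      tryCatch(dnds_summary(aln_ok), error = function(e) NULL)
    else NULL
    profile <- if (!is.null(aln_ok)) substitution_profile(aln_ok) else NULL
    conserved <- if (!is.null(profile))
      delineate_conserved_regions(profile)
    else NULL

    stage <- "pairing"
    n_aa <- stats::setNames(lapply(genes, function(g) {
      ex <- gene_exons(g, "N")[[1]]
      translate_nt(ex$sequence, ex$frame_offset)
    }), vapply(genes, `[[`, character(1), "gene_id"))
    pairs <- pair_receptors(genes, n_aa, cfg$identity_floor)

    stage <- "conversion"
    calls <- list()
    if (nrow(pairs)) for (r in seq_len(nrow(pairs))) {
      p_aln <- build_codon_alignment(
        n_seqs[match(c(pairs$inhibitory[r], pairs$activating[r]),
                     vapply(genes, `[[`, character(1), "gene_id"))])
      trk <- syn_diff_track(1, 2, p_aln)
      call <- tryCatch(
        conversion_test(trk, epsilon = cfg$conversion_epsilon,
                        B = cfg$conversion_B,
                        seed = cfg$seed + 100L + r),
        error = function(e) NULL)
      if (!is.null(call))
        calls[[length(calls) + 1L]] <- data.frame(
          inhibitory = pairs$inhibitory[r],
          activating = pairs$activating[r],
          run_start = call$run_start, run_end = call$run_end,
          run_length = call$run_length, p_value = call$p_value,
          B = call$B, stringsAsFactors = FALSE)
    }
    calls <- if (length(calls)) do.call(rbind, calls)
    else data.frame(inhibitory = character(0), activating = character(0),
                    run_start = integer(0), run_end = integer(0),
                    run_length = integer(0), p_value = numeric(0),
                    B = integer(0), stringsAsFactors = FALSE)

    structure(list(catalog = catalog, counts = counts,
                   cluster_count = cl$count, partition = cl$partition,
                   tree = tree, dnds = dnds, profile = profile,
                   conserved_regions = conserved, pairs = pairs,
                   conversion_calls = calls,
                   meta = list(seed = cfg$seed,
                               cluster_threshold = cfg$cluster_threshold,
                               distance_model = cfg$distance_model,
                               bootstrap_B = cfg$bootstrap_B,
                               conversion_B = cfg$conversion_B,
                               package_version =
                                 as.character(utils::packageVersion("ceafam")))),
              class = "analysis_report")
  }, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    meta <- sprintf("seed=%d threshold=%g model=%s B=%d",
                    cfg$seed, cfg$cluster_threshold, cfg$distance_model,
                    cfg$bootstrap_B)
    .write_report(report$catalog,
                  file.path(cfg$out_dir, "catalog.tsv"), meta)
    .write_report(report$counts,
                  file.path(cfg$out_dir, "family_counts.tsv"), meta)
    .write_report(report$pairs,
                  file.path(cfg$out_dir, "paired_receptors.tsv"), meta)
    .write_report(report$conversion_calls,
                  file.path(cfg$out_dir, "conversion_calls.tsv"), meta)
    if (!is.null(report$profile))
      .write_report(
        data.frame(codon = seq_len(report$profile$L),
                   mean_syn = report$profile$mean_syn,
                   mean_nonsyn = report$profile$mean_nonsyn,
                   cum_syn = report$profile$cum_syn,
                   cum_nonsyn = report$profile$cum_nonsyn),
        file.path(cfg$out_dir, "substitution_profile.tsv"), meta)
    if (!is.null(report$conserved_regions))
      .write_report(report$conserved_regions,
                    file.path(cfg$out_dir, "conserved_regions.tsv"), meta)
    if (!is.null(report$tree))
      write_newick(report$tree, file.path(cfg$out_dir, "n_exon_tree.nwk"))
  }
  report
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("<analysis_report: %d genes, %d clusters, %d receptor pair(s), %d conversion call(s)>\n",
              nrow(x$catalog), x$cluster_count, nrow(x$pairs),
              nrow(x$conversion_calls)))
  invisible(x)
}
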