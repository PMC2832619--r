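# small intact gene used across tests: L, N, A exons, clean GT-AG sites
make_test_gene <- function(id = "g1", species = "testus",
                           n_seq = "ATGAAATTTGGGCCCAAA",
                           l_seq = "ATGCTGCTG",
                           n_donor = "GT", n_acceptor = "AG") {
  gene_model(id, species, list(
    exon_model("L", l_seq, "", "GT"),
    exon_model("N", n_seq, n_acceptor, n_donor),
    exon_model("A", "GCAGCAGCA", "AG", "")),
    anchor_class = "transmembrane")
}

test_that("splice sites follow the GT-AG rule with terminal skipping", {
  e <- exon_model("N", "ATGAAA", "AG", "GT")
  r <- check_splice_sites(e)
  expect_true(r$acceptor_valid)
  expect_true(r$donor_valid)
  expect_true(r$valid)

  e <- exon_model("A", "ATGAAA", "AG", "AT")
  expect_false(check_splice_sites(e)$donor_valid)
  expect_false(check_splice_sites(e)$valid)

  e <- exon_model("L", "ATGAAA", "", "GT")   # terminal first exon
  r <- check_splice_sites(e)
  expect_true(is.na(r$acceptor_valid))
  expect_true(r$valid)
})

test_that("pseudogene calling applies stop and splice rules", {
  g <- call_pseudogene(make_test_gene())
  expect_equal(g$status, "gene")
  expect_length(g$status_reasons, 0)

  g <- call_pseudogene(make_test_gene(n_seq = "ATGTAATTTGGGCCCAAA"))
  expect_equal(g$status, "pseudogene")
  expect_match(g$status_reasons, "stop in N exon")

  g <- call_pseudogene(make_test_gene(n_donor = "AT"))
  expect_equal(g$status, "pseudogene")
  expect_match(g$status_reasons, "splice site on N exon")

  expect_error(call_pseudogene(gene_model("x", "sp",
    list(exon_model("L", "ATG", "", "GT")), "secreted")), "no N exon")
})

test_that("leader-exon lesions pseudogenize only in opossum mode", {
  g <- make_test_gene(l_seq = "ATGTAGCTG")   # stop in L exon
  expect_equal(call_pseudogene(g, "default")$status, "gene")
  expect_equal(call_pseudogene(g, "opossum")$status, "pseudogene")
})

test_that("pseudogene calling is monotone in lesions", {
  set.seed(5)
  for (rep in 1:10) {
    base <- make_test_gene(n_seq = paste(sample(
      c("ATG", "AAA", "TTC", "GGG"), 6, replace = TRUE), collapse = ""))
    st0 <- call_pseudogene(base)$status
    lesioned <- base
    lesioned$exons[[2]]$donor <- "AT"   # add a lesion
    st1 <- call_pseudogene(lesioned)$status
    expect_false(st0 == "pseudogene" && st1 == "gene")
    expect_equal(st1, "pseudogene")
  }
})

test_that("donor read-through finds tandem in-frame stops", {
  # defective donor directly followed by the TAG/TGA tandem stops
  ex <- exon_model("A", "ATGAAACCC", "AG", "AT")
  r <- detect_donor_readthrough(ex, "TAGTGACCC")
  expect_equal(r$stop_codons, c(1, 2))
  expect_true(r$truncated)
  expect_equal(r$product, "secreted-truncated")

  r <- detect_donor_readthrough(ex, paste(rep("AAA", 25), collapse = ""))
  expect_false(r$truncated)
  expect_equal(r$product, "full-length")

  ok <- exon_model("A", "ATGAAACCC", "AG", "GT")
  expect_error(detect_donor_readthrough(ok, "TAGTGA"), "contract")
})

test_that("read-through respects a partial terminal codon", {
  # exon ends with 1 leftover nt 'T'; TA completes a TTA (Leu), then TGA
  ex <- exon_model("A", "ATGAAAT", "AG", "AT")
  r <- detect_donor_readthrough(ex, "TATGACCC")
  expect_equal(r$stop_codons, 2)
  expect_equal(r$stop_nt_positions, 3)
})

test_that("N-exon clustering implements the divergence threshold", {
  s <- function(id, x) cea_seq(id, x, "nucleotide")
  base <- paste(rep("ACGTACGTAC", 20), collapse = "")  # 200 nt
  mut <- function(x, k) {
    v <- strsplit(x, "")[[1]]
    for (p in seq_len(k)) v[p] <- setdiff(c("A", "C", "G", "T"), v[p])[1]
    paste(v, collapse = "")
  }
  seqs <- list(s("a", base), s("b", mut(base, 1)), s("c", mut(base, 10)))
  cl <- cluster_n_exons(seqs, threshold = 0.01)
  expect_equal(cl$count, 2)       # a-b at 0.5%, c at 5%/4.5%
  expect_equal(cl$partition[["a"]], cl$partition[["b"]])
  expect_false(cl$partition[["a"]] == cl$partition[["c"]])

  cl <- cluster_n_exons(list(s("a", base), s("b", base), s("c", base)))
  expect_equal(cl$count, 1)
  expect_equal(cluster_n_exons(list())$count, 0)
  expect_equal(cluster_n_exons(list(s("solo", base)))$count, 1)
})

test_that("clustering equals the connected-components oracle", {
  set.seed(77)
  for (rep in 1:10) {
    n_cl <- sample(2:4, 1)
    base <- random_nt_seq("r", 300)$residues
    seqs <- list()
    for (cl in seq_len(n_cl)) {
      v <- strsplit(base, "")[[1]]
      pos <- sample(300, 12 * cl)  # >= 3% between clusters
      for (p in pos) v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
      founder <- paste(v, collapse = "")
      for (m in 1:2) {
        w <- strsplit(founder, "")[[1]]
        p <- sample(300, 1)        # <= 0.5% within
        w[p] <- sample(setdiff(c("A", "C", "G", "T"), w[p]), 1)
        seqs[[length(seqs) + 1]] <-
          cea_seq(sprintf("c%dm%d", cl, m), paste(w, collapse = ""),
                  "nucleotide")
      }
    }
    cl_res <- cluster_n_exons(seqs, 0.01)
    n <- length(seqs)
    dm <- matrix(0, n, n)
    for (i in 1:n) for (j in 1:n)
      dm[i, j] <- mean(strsplit(seqs[[i]]$residues, "")[[1]] !=
                       strsplit(seqs[[j]]$residues, "")[[1]])
    oracle <- oracle_cluster_components(dm, 0.01)
    # same partition up to label permutation
    expect_equal(length(unique(oracle)), cl_res$count)
    for (i in 1:n) for (j in 1:n)
      expect_equal(oracle[i] == oracle[j],
                   unname(cl_res$partition[i] == cl_res$partition[j]))
  }
})

test_that("cluster count is non-increasing in the threshold", {
  set.seed(3)
  seqs <- lapply(1:8, function(i) random_nt_seq(paste0("s", i), 150))
  counts <- vapply(c(0.005, 0.02, 0.08, 0.2, 0.5), function(th)
    cluster_n_exons(seqs, th)$count, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("receptor pairing picks the best same-species activating gene", {
  mk <- function(id, cls, sp = "testus") {
    g <- make_test_gene(id, species = sp)
    g$status <- "gene"
    g$receptor_class <- cls
    g
  }
  genes <- list(mk("inh", "ITIM_ITSM"), mk("act1", "ITAM_like"),
                mk("act2", "ITAM"), mk("other", "none"))
  aa <- list(inh = "MKLVVFGAGA", act1 = "MKLVVFGAGV", act2 = "MKLAAAAAAA",
             other = "MKLVVFGAGA")
  p <- pair_receptors(genes, aa, identity_floor = 0.8)
  expect_equal(nrow(p), 1)
  expect_equal(p$activating, "act1")   # 0.9 identity beats 0.4
  expect_equal(p$identity, 0.9)

  p <- pair_receptors(genes, aa, identity_floor = 0.95)
  expect_equal(nrow(p), 0)

  # no same-species activating partner
  genes2 <- list(mk("inh", "ITIM_ITSM"), mk("act1", "ITAM_like", sp = "x"))
  expect_equal(nrow(pair_receptors(genes2, aa)), 0)

  # invariance to input order
  p1 <- pair_receptors(genes, aa, identity_floor = 0.8)
  p2 <- pair_receptors(rev(genes), aa, identity_floor = 0.8)
  rownames(p1) <- rownames(p2) <- NULL
  expect_equal(p1, p2)
})

test_that("gene-structure tables round-trip", {
  fam <- simulate_gene_family(family_config(seed = 9))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_gene_table(fam$genes, f)
  back <- read_gene_table(f)
  expect_equal(length(back), length(fam$genes))
  for (k in seq_along(back)) {
    expect_equal(back[[k]]$gene_id, fam$genes[[k]]$gene_id)
    expect_equal(length(back[[k]]$exons), length(fam$genes[[k]]$exons))
    expect_equal(vapply(back[[k]]$exons, `[[`, "", "sequence"),
                 vapply(fam$genes[[k]]$exons, `[[`, "", "sequence"))
    expect_equal(vapply(back[[k]]$exons, `[[`, "", "donor"),
                 vapply(fam$genes[[k]]$exons, `[[`, "", "donor"))
  }
})

test_that("family counts sum consistently", {
  fam <- simulate_gene_family(family_config(seed = 21))
  genes <- lapply(fam$genes, call_pseudogene)
  genes <- lapply(genes, function(g) {
    aa <- paste(vapply(Filter(function(e) startsWith(e$exon_type, "Cyt"),
                              g$exons),
                       function(e) translate_nt(e$sequence), ""),
                collapse = "")
    g$receptor_class <- if (nzchar(aa)) classify_cytoplasmic(aa)$label
    else "none"
    g
  })
  ct <- family_counts(genes)
  expect_equal(sum(ct$total), length(genes))
  expect_true(all(ct$pseudogenes + ct$itam_like + ct$itim_itsm <= ct$total))
})
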