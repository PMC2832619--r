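test_that("distance models apply the stated corrections", {
  m <- matrix(c("A", "C", "G", "T",
                "A", "C", "G", "T"), 2, 4, byrow = TRUE,
              dimnames = list(c("a", "b"), NULL))
  for (model in c("p_nt", "jc69_nt"))
    expect_equal(distance_matrix(m, model)["a", "b"], 0)

  # p = 0.3 over 10 sites
  m <- rbind(a = strsplit("AAAAAAAAAA", "")[[1]],
             b = strsplit("CCCAAAAAAA", "")[[1]])
  expect_equal(distance_matrix(m, "p_nt")["a", "b"], 0.3)
  expect_equal(distance_matrix(m, "jc69_nt")["a", "b"], 0.38312,
               tolerance = 1e-5)

  # amino-acid Poisson correction at p = 0.5
  m <- rbind(a = strsplit("KKKKLLLL", "")[[1]],
             b = strsplit("KKKKMMMM", "")[[1]])
  expect_equal(distance_matrix(m, "p_aa")["a", "b"], 0.5)
  expect_equal(distance_matrix(m, "poisson_aa")["a", "b"], 0.69315,
               tolerance = 1e-5)

  # pairwise-complete deletion: gap columns dropped per pair
  m <- rbind(a = strsplit("A-AAA", "")[[1]],
             b = strsplit("ACAAC", "")[[1]])
  expect_equal(distance_matrix(m, "p_nt")["a", "b"], 0.25)

  m <- rbind(a = rep("A", 4), b = rep("C", 4))
  expect_error(distance_matrix(m, "jc69_nt"), "saturation")
})

test_that("distances agree with the ape reference on simulated alignments", {
  sim <- simulate_codon_evolution(sim_config(L = 60, omega = 0.8, seed = 61,
                                             n_taxa = 5))
  aln <- sim$aln
  rows <- lapply(seq_along(aln$ids), function(i)
    cea_seq(aln$ids[i], paste(aln$mat[i, ], collapse = ""), "nucleotide"))
  mine <- distance_matrix(aln, "jc69_nt")
  chars <- lapply(rows, function(s) strsplit(tolower(s$residues), "")[[1]])
  names(chars) <- aln$ids
  bin <- ape::as.DNAbin(chars)
  ref <- as.matrix(ape::dist.dna(bin, model = "JC69",
                                 pairwise.deletion = TRUE))
  expect_equal(unname(mine), unname(ref[rownames(mine), rownames(mine)]),
               tolerance = 1e-10)
})

test_that("NJ reconstructs the worked additive example exactly", {
  dm <- matrix(c(0, 3, 5, 6,
                 3, 0, 6, 7,
                 5, 6, 0, 7,
                 6, 7, 7, 0), 4, 4,
               dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  tr <- nj_tree(dm)
  expect_equal(sort(tr$tip.label), c("A", "B", "C", "D"))
  coph <- ape::cophenetic.phylo(tr)[rownames(dm), colnames(dm)]
  expect_equal(coph, dm)
  # branch lengths: A=1, B=2, C=3, D=4, internal=1
  expect_equal(sort(tr$edge.length), c(1, 1, 2, 3, 4))
  expect_error(nj_tree(dm[1:2, 1:2]), "taxa")
})

test_that("NJ recovers random additive matrices exactly", {
  set.seed(83)
  for (rep in 1:20) {
    inst <- random_additive_matrix(sample(4:12, 1))
    rec <- nj_tree(inst$dm)
    expect_true(same_topology(inst$tree, rec))
    coph <- ape::cophenetic.phylo(rec)[rownames(inst$dm), colnames(inst$dm)]
    expect_equal(coph, inst$dm, tolerance = 1e-8)
  }
})

test_that("NJ is invariant to taxon order and agrees with the ape oracle", {
  set.seed(29)
  for (rep in 1:10) {
    n <- sample(5:9, 1)
    dm <- matrix(0, n, n, dimnames = list(letters[1:n], letters[1:n]))
    v <- runif(n * (n - 1) / 2, 0.1, 1)
    dm[lower.tri(dm)] <- v
    dm <- dm + t(dm)
    t1 <- nj_tree(dm)
    perm <- sample(n)
    t2 <- nj_tree(dm[perm, perm])
    expect_true(same_topology(t1, t2))
    # independent implementation cross-check (no ties for random dists)
    t_ape <- ape::nj(as.dist(dm))
    expect_true(same_topology(t1, t_ape))
  }
})

test_that("bootstrap supports are deterministic and bounded", {
  set.seed(2)
  sim <- simulate_codon_evolution(sim_config(L = 120, omega = 0.5,
                                             seed = 2, n_taxa = 6))
  t1 <- nj_bootstrap(sim$aln, "jc69_nt", B = 25, seed = 99)
  t2 <- nj_bootstrap(sim$aln, "jc69_nt", B = 25, seed = 99)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  sup <- suppressWarnings(as.numeric(t1$node.label))
  sup <- sup[!is.na(sup)]
  expect_true(all(sup >= 0 & sup <= 100))

  tB1 <- nj_bootstrap(sim$aln, "jc69_nt", B = 1, seed = 5)
  supB1 <- suppressWarnings(as.numeric(tB1$node.label))
  expect_true(all(supB1[!is.na(supB1)] %in% c(0, 100)))
})

test_that("deep divergence between two clades yields full support", {
  # two 2-taxon clades separated by a long internal branch
  cfg <- sim_config(L = 500, omega = 0.5, seed = 8,
                    tree = "((A:0.02,B:0.02):0.25,(C:0.02,D:0.02):0.25);")
  sim <- simulate_codon_evolution(cfg)
  tr <- nj_bootstrap(sim$aln, "jc69_nt", B = 100, seed = 12)
  sup <- suppressWarnings(as.numeric(tr$node.label))
  expect_true(all(sup[!is.na(sup)] == 100))
})

test_that("clade support grows with branch-length separation", {
  support_at <- function(x, seed) {
    cfg <- sim_config(L = 150, omega = 0.5, seed = seed,
                      tree = sprintf("((A:0.03,B:0.03):%g,(C:0.03,D:0.03):%g);",
                                     x / 2, x / 2))
    sim <- simulate_codon_evolution(cfg)
    tr <- nj_bootstrap(sim$aln, "jc69_nt", B = 60, seed = seed + 1)
    sup <- suppressWarnings(as.numeric(tr$node.label))
    max(c(0, sup[!is.na(sup)]))
  }
  sups <- vapply(c(0.001, 0.03, 0.3), support_at, numeric(1), seed = 44)
  expect_true(all(diff(sups) >= 0))
  expect_true(sups[3] > sups[1])
})

test_that("newick text round-trips with supports", {
  tr <- read_newick("(A:1,B:2,(C:3,D:4):1);")
  expect_equal(sort(tr$tip.label), c("A", "B", "C", "D"))
  txt <- write_newick(tr)
  tr2 <- read_newick(txt)
  expect_true(same_topology(tr, tr2))
  expect_equal(sort(tr2$edge.length), sort(tr$edge.length))

  tr <- read_newick("(A:1,B:2,(C:3,D:4)87:1);")
  txt <- write_newick(tr)
  expect_match(txt, "87")
  expect_equal(read_newick(txt)$node.label, tr$node.label)

  expect_error(read_newick("(A:1,(B:2;"), "parse error")
  expect_error(read_newick("(A:1,B:2)"), "parse error")

  f <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, f)
  expect_true(same_topology(read_newick(file = f), tr))
})
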