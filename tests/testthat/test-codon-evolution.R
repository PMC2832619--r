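test_that("site counts match hand-derived codon cases", {
  expect_equal(ng_sites("TTT"), c(s = 1 / 3, n = 8 / 3))
  expect_equal(ng_sites("ATG"), c(s = 0, n = 3))
  # every sense codon splits its 3 sites exactly
  for (cdn in oracle_sense_codons())
    expect_equal(sum(ng_sites(cdn)), 3)
  expect_error(ng_sites("TAA"), "excluded")
  expect_error(ng_sites("TNT"), "excluded")
})

test_that("pathway-averaged differences match hand-derived pairs", {
  expect_equal(ng_pair_codon("TTT", "TTT"), c(sd = 0, nd = 0))
  expect_equal(ng_pair_codon("TTT", "TTA"), c(sd = 0, nd = 1))
  # two orderings: via GTT (1 syn + 1 nonsyn) or via TTA (2 nonsyn)
  expect_equal(ng_pair_codon("TTT", "GTA"), c(sd = 0.5, nd = 1.5))
  expect_error(ng_pair_codon("TAA", "TTT"), "excluded")
})

test_that("difference counts are symmetric and sum to the hamming distance", {
  set.seed(19)
  sense <- oracle_sense_codons()
  for (rep in 1:100) {
    a <- sample(sense, 1); b <- sample(sense, 1)
    v <- ng_pair_codon(a, b)
    expect_equal(v, ng_pair_codon(b, a))
    k <- sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
    expect_equal(unname(sum(v)), k)
  }
})

test_that("pairwise dN/dS follows the Jukes-Cantor closed form", {
  rows <- list(cea_seq("a", "ATGAAATTTGGG"), cea_seq("b", "ATGAAATTTGGG"))
  aln <- build_codon_alignment(rows)
  r <- ng_pairwise(1, 2, aln)
  expect_equal(r$Sd, 0)
  expect_equal(r$Nd, 0)
  expect_equal(r$dS, 0)
  expect_equal(r$dN, 0)
  expect_true(is.na(r$omega))
  expect_equal(r$S + r$N, 3 * r$n_codons)

  expect_equal(jc69_correct(0.3), 0.38312, tolerance = 1e-5)
  expect_equal(jc69_correct(0), 0)
  expect_error(jc69_correct(0.8), "saturation")

  # one synonymous difference: TTT -> TTC at codon 2; S sums to 10/3
  rows <- list(cea_seq("a", "ATGTTTGGGAAACCCTTA"),
               cea_seq("b", "ATGTTCGGGAAACCCTTA"))
  r <- ng_pairwise("a", "b", build_codon_alignment(rows))
  expect_equal(r$Sd, 1)
  expect_equal(r$Nd, 0)
  expect_equal(r$pS, 0.3)
  expect_equal(r$dS, jc69_correct(0.3))
  expect_equal(r$dN, 0)
})

test_that("dN/dS is symmetric in the pair", {
  set.seed(23)
  sim <- simulate_codon_evolution(sim_config(L = 100, omega = 0.5,
                                             seed = 23, n_taxa = 4))
  r12 <- ng_pairwise(1, 2, sim$aln)
  r21 <- ng_pairwise(2, 1, sim$aln)
  expect_equal(r12$dS, r21$dS)
  expect_equal(r12$dN, r21$dN)
})

test_that("summary aggregates pairs with defined omega", {
  rows <- list(cea_seq("a", "ATGAAATTTGGG"), cea_seq("b", "ATGAAATTTGGG"))
  expect_error(dnds_summary(build_codon_alignment(rows)), "undefined")

  sim <- simulate_codon_evolution(sim_config(L = 200, omega = 0.3,
                                             seed = 4, n_taxa = 5))
  s <- dnds_summary(sim$aln)
  expect_true(s$mean_omega > 0)
  expect_true(s$sd_omega >= 0)
  expect_equal(s$n_pairs, choose(5, 2))
})

test_that("substitution profiles localize and accumulate differences", {
  rows <- list(cea_seq("a", "ATGAAATTTGGGCCCAAA"),
               cea_seq("b", "ATGAAATTTGGGCCCAAA"))
  p <- substitution_profile(build_codon_alignment(rows))
  expect_equal(p$mean_syn, rep(0, 6))
  expect_equal(p$mean_nonsyn, rep(0, 6))

  # single synonymous change at codon 5 (CCC -> CCA)
  rows <- list(cea_seq("a", "ATGAAATTTGGGCCCAAA"),
               cea_seq("b", "ATGAAATTTGGGCCAAAA"))
  p <- substitution_profile(build_codon_alignment(rows))
  expect_equal(p$mean_syn, c(0, 0, 0, 0, 1, 0))
  expect_equal(p$cum_syn, c(0, 0, 0, 0, 1, 1))
  expect_equal(p$mean_nonsyn, rep(0, 6))
  expect_true(all(diff(p$cum_syn) >= 0))
})

test_that("cumulative profile totals equal summed pairwise differences", {
  sim <- simulate_codon_evolution(sim_config(L = 80, omega = 0.6,
                                             seed = 31, n_taxa = 4))
  p <- substitution_profile(sim$aln)
  tot_sd <- 0; tot_nd <- 0
  for (i in 1:3) for (j in (i + 1):4) {
    r <- ng_pairwise(i, j, sim$aln)
    tot_sd <- tot_sd + r$Sd
    tot_nd <- tot_nd + r$Nd
  }
  expect_equal(p$cum_syn[p$L] * p$n_pairs, tot_sd)
  expect_equal(p$cum_nonsyn[p$L] * p$n_pairs, tot_nd)
  # per-100-codon rate identity
  expect_equal(p$cum_syn[p$L] * 100 / p$L,
               (tot_sd / p$n_pairs) * 100 / p$L)
})

test_that("conserved-region delineation follows the run rules", {
  mk_profile <- function(track) {
    structure(list(mean_syn = track * 0, mean_nonsyn = track,
                   cum_syn = cumsum(track * 0), cum_nonsyn = cumsum(track),
                   L = length(track), excluded = rep(FALSE, length(track)),
                   n_pairs = 1L), class = "substitution_profile")
  }
  # flat nonzero track: nothing below 0.5x mean
  expect_equal(nrow(delineate_conserved_regions(mk_profile(rep(0.4, 50)))), 0)

  # 30-codon zero stretch in a nonzero background
  track <- c(rep(0.5, 30), rep(0, 30), rep(0.5, 30))
  reg <- delineate_conserved_regions(mk_profile(track))
  expect_equal(nrow(reg), 1)
  expect_true(reg$extended)
  expect_true(reg$start >= 28 && reg$end <= 63)

  # all-zero exon reported whole
  reg <- delineate_conserved_regions(mk_profile(rep(0, 40)))
  expect_equal(reg$start, 1)
  expect_equal(reg$end, 40)
  expect_true(reg$extended)

  expect_error(delineate_conserved_regions(mk_profile(rep(0.1, 5))),
               "window")
})

test_that("delineation equals a brute-force run scan on random tracks", {
  set.seed(57)
  brute <- function(track, window = 10, factor = 0.5, min_len = 5) {
    L <- length(track)
    half <- window %/% 2
    sm <- sapply(seq_len(L), function(i)
      mean(track[max(1, i - half):min(L, i + half)]))
    below <- sm < factor * mean(track)
    regions <- NULL
    i <- 1
    while (i <= L) {
      if (below[i]) {
        j <- i
        while (j < L && below[j + 1]) j <- j + 1
        if (j - i + 1 >= min_len)
          regions <- rbind(regions, c(i, j))
        i <- j + 1
      } else i <- i + 1
    }
    regions
  }
  for (rep in 1:20) {
    track <- rpois(60, 0.4) * runif(60)
    if (mean(track) == 0) next
    reg <- delineate_conserved_regions(
      structure(list(mean_nonsyn = track, L = 60),
                class = "substitution_profile"))
    b <- brute(track)
    if (is.null(b)) {
      expect_equal(nrow(reg), 0)
    } else {
      expect_equal(cbind(reg$start, reg$end), unname(b))
    }
  }
})
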