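test_that("haplotype diversity matches Nei's unbiased formula", {
  # two haplotypes at counts 2,2 in n = 4: Hd = 2/3
  rec <- tibble::tibble(id = paste0("s", 1:4), species = "sp", region = "R",
                        site = "S1",
                        seq = c("AAA", "AAA", "AAG", "AAG"))
  expect_equal(haplotype_diversity(pop_of(rec)), 2 / 3)

  mono <- make_fixture("mono")
  expect_equal(haplotype_diversity(population_sample(mono$aln)), 0)

  rec$seq <- c("AAA", "AAC", "AAG", "AAT")
  expect_equal(haplotype_diversity(pop_of(rec)), 1)
})

test_that("Jukes-Cantor correction matches the closed form and bounds", {
  rec <- tibble::tibble(id = c("a", "b"), species = "sp", region = "R",
                        site = "S1",
                        seq = c(strrep("A", 100),
                                paste0(strrep("A", 99), "G")))
  pop <- pop_of(rec)
  expect_equal(nucleotide_diversity(pop, "none"), 0.01)
  expect_equal(nucleotide_diversity(pop, "JC"),
               -0.75 * log(1 - 4 * 0.01 / 3), tolerance = 1e-12)

  # JC >= p on (0, 0.75), equality iff p = 0
  p <- seq(0.01, 0.7, by = 0.01)
  d <- -0.75 * log(1 - 4 * p / 3)
  expect_true(all(d > p))
  mono <- make_fixture("mono")
  expect_equal(nucleotide_diversity(population_sample(mono$aln), "JC"), 0)

  # saturation: p >= 0.75 is undefined under JC
  rec$seq <- c(strrep("A", 20), strrep("G", 20))
  expect_error(nucleotide_diversity(pop_of(rec), "JC"), "0.75")
})

test_that("summary statistics agree with the enumeration oracle", {
  fx <- make_fixture("tajima_toy")
  pop <- population_sample(fx$aln)
  o <- oracle_stats(fx$aln$seq)
  expect_equal(segregating_sites(pop), o$S)
  expect_equal(nucleotide_diversity(pop, "none"), o$pi)
  expect_equal(haplotype_diversity(pop), o$hd)
  expect_equal(nrow(collapse_haplotypes(pop)), o$n_hap)

  # random synthetic samples, including against ape's distance engine
  for (s in 1:4) {
    cfg <- synth_config(n = 8, L = 120, theta = 8, seed = 40 + s)
    aln <- generate_population(cfg)
    pop <- population_sample(aln)
    o <- oracle_stats(aln$seq)
    expect_equal(segregating_sites(pop), o$S)
    expect_equal(nucleotide_diversity(pop, "none"), o$pi)
    expect_equal(haplotype_diversity(pop), o$hd)
    expect_equal(nrow(collapse_haplotypes(pop)), o$n_hap)

    bin <- ape::as.DNAbin(t(sapply(strsplit(tolower(aln$seq), ""), identity)))
    d_ape <- mean(ape::dist.dna(bin, model = "JC69"))
    expect_equal(nucleotide_diversity(pop, "JC"), d_ape, tolerance = 1e-10)
  }
})

test_that("diversity is invariant to sequence order", {
  cfg <- synth_config(n = 10, L = 90, theta = 6, seed = 77)
  aln <- generate_population(cfg)
  pop1 <- population_sample(aln)
  shuffled <- codon_alignment(aln[sample(nrow(aln)), ], frame_offset = 0L)
  pop2 <- population_sample(shuffled)
  expect_equal(nucleotide_diversity(pop2), nucleotide_diversity(pop1))
  expect_equal(haplotype_diversity(pop2), haplotype_diversity(pop1))
  expect_equal(segregating_sites(pop2), segregating_sites(pop1))
})

test_that("synonymous/nonsynonymous partition follows the code table", {
  # GGA -> GGG: third-position change, Gly in both: synonymous only
  rec <- tibble::tibble(id = c("a", "b"), species = "sp", region = "R",
                        site = "S1",
                        seq = c("GGAGGAGGA", "GGGGGAGGA"))
  ps <- pi_syn_nonsyn(pop_of(rec))
  expect_equal(ps$pi_a, 0)
  expect_gt(ps$pi_s, 0)
  expect_equal(ps$ratio, 0)

  # GGA -> AGA: first-position change, Gly -> Ser: nonsynonymous only
  rec$seq <- c("GGAGGAGGA", "AGAGGAGGA")
  ps <- pi_syn_nonsyn(pop_of(rec))
  expect_equal(ps$pi_s, 0)
  expect_gt(ps$pi_a, 0)
  expect_true(is.infinite(ps$ratio))

  # identical sequences: both zero, ratio undefined
  rec$seq <- c("GGAGGAGGA", "GGAGGAGGA")
  ps <- pi_syn_nonsyn(pop_of(rec))
  expect_true(is.na(ps$ratio))
})

test_that("p-distance summaries handle degenerate and two-group cases", {
  rec <- tibble::tibble(
    id = paste0("s", 1:4),
    species = rep(c("A", "B"), each = 2),
    region = "R", site = "S1",
    seq = c(strrep("A", 10), strrep("A", 10),
            paste0(strrep("A", 8), "GG"), paste0(strrep("A", 8), "GG"))
  )
  out <- p_distance_summary(rec, bootstrap_reps = 50, seed = 1)
  a <- out[out$group == "A", ]
  expect_equal(a$within_mean, 0)
  expect_equal(a$within_se, 0)
  expect_equal(a$between_min, 0.2)  # fixed 20% divergence between groups
  expect_equal(a$between_max, 0.2)

  # size-1 group: within stats undefined
  solo <- rec[c(1, 3, 4), ]
  solo$species[1] <- "solo"
  out2 <- p_distance_summary(solo, bootstrap_reps = 10, seed = 2)
  expect_true(is.na(out2$within_mean[out2$group == "solo"]))
})

test_that("the diversity table reports gated populations with counts only", {
  rnd <- related_records(7, 30, nmut = 2, seed = 50)
  rnd$site <- c(rep("big", 5), "small", "small")
  aln <- codon_alignment(rnd)
  tab <- diversity_summary(aln, overall = FALSE)
  small <- tab[tab$site == "small", ]
  expect_true(small$excluded)
  expect_equal(small$n_seq, 2L)
  expect_true(is.na(small$hd))
  big <- tab[tab$site == "big", ]
  expect_false(big$excluded)
  expect_false(is.na(big$pi))
})
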