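test_that("coalescent tree heights match theory", {
  set.seed(1)
  expect_error(simulate_genealogy(1), "n must be >= 2")

  # E[T_MRCA] = 2(1 - 1/n): 1.0 for n = 2, 1.8 for n = 10
  reps <- 20000L
  h2 <- replicate(reps, tree_height(simulate_genealogy(2)))
  expect_lt(abs(mean(h2) - 1), 3 * sd(h2) / sqrt(reps))

  h10 <- replicate(reps, tree_height(simulate_genealogy(10)))
  expect_lt(abs(mean(h10) - 1.8), 3 * sd(h10) / sqrt(reps))
})

test_that("growth shifts branch length toward the tips", {
  set.seed(2)
  reps <- 2000L
  frac <- function(growth) {
    mean(replicate(reps, {
      tr <- simulate_genealogy(10, growth = growth)
      external_length(tr) / tree_length(tr)
    }))
  }
  expect_gt(frac(50), frac(0))
})

test_that("mutation overlay behaves across the theta range", {
  # theta -> 0: monomorphic, Hd = 0
  cfg <- synth_config(n = 8, L = 300, theta = 1e-9, seed = 5)
  aln <- generate_population(cfg)
  pop <- population_sample(codon_alignment(aln))
  expect_equal(segregating_sites(pop), 0L)
  expect_equal(haplotype_diversity(pop), 0)

  # generated data always pass the ORF screen with stop suppression on
  for (s in 1:5) {
    cfg <- synth_config(n = 10, L = 300, theta = 20, seed = 600 + s)
    aln <- generate_population(cfg)
    expect_true(all(screen_orf(aln)$pass))
  }
})

test_that("Watterson's estimator recovers theta on neutral simulations", {
  reps <- 150L
  theta <- 5
  set.seed(9)
  th_w <- replicate(reps, {
    tr <- simulate_genealogy(20)
    cfg <- synth_config(n = 20, L = 1500, theta = theta, omega = 1,
                        suppress_stops = FALSE, seed = 1)  # seed unused here
    aln <- drop_mutations(tr, cfg)
    pop <- population_sample(aln)
    segregating_sites(pop) / sum(1 / 1:19)
  })
  se <- sd(th_w) / sqrt(reps)
  # finite-sites recurrent hits bias theta_W down slightly; 3 SE + 2% slack
  expect_lt(abs(mean(th_w) - theta), 3 * se + 0.02 * theta)
})

test_that("purifying-selection mode drives pi_a/pi_s well below 1", {
  set.seed(12)
  ratios <- replicate(30, {
    tr <- simulate_genealogy(8)
    cfg <- synth_config(n = 8, L = 300, theta = 12, omega = 0.05, seed = 1)
    aln <- drop_mutations(tr, cfg)
    ps <- pi_syn_nonsyn(population_sample(aln))
    if (is.na(ps$ratio) || is.infinite(ps$ratio)) NA else ps$ratio
  })
  expect_lt(mean(ratios, na.rm = TRUE), 0.2)
})

test_that("fixtures carry their enumerated expectations", {
  fx <- make_fixture("tajima_toy")
  o <- oracle_stats(fx$aln$seq)
  expect_equal(o$S, fx$expected$S)
  expect_equal(o$k, fx$expected$k)
  expect_equal(o$pi, fx$expected$pi)
  expect_equal(o$n_hap, fx$expected$n_hap)
  expect_equal(o$hd, fx$expected$hd)

  mono <- make_fixture("mono")
  om <- oracle_stats(mono$aln$seq)
  expect_equal(om$S, 0L)
  expect_equal(om$hd, 0)

  expect_error(make_fixture("nope"), "unknown fixture")
})

test_that("synthesized datasets round-trip through the io layer", {
  dir <- withr::local_tempdir()
  cfgs <- list(
    siteA = synth_config(n = 6, L = 300, theta = 4, seed = 21),
    siteB = synth_config(n = 5, L = 300, theta = 4, seed = 22)
  )
  paths <- synthesize_dataset(cfgs, dir)
  rec <- read_fasta(paths$fasta)
  sheet <- read_sample_sheet(paths$sheet)
  expect_equal(nrow(rec), 11L)
  expect_equal(sort(unique(sheet$site)), c("siteA", "siteB"))
  expect_true(all(screen_orf(codon_alignment(rec))$pass))
})
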