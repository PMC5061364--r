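test_that("Tajima's D matches the hand-derived fixture value and the oracle", {
  fx <- make_fixture("tajima_toy")
  pop <- population_sample(fx$aln)
  # n = 4, S = 2 singletons, k = 1: hand evaluation of the 1989 constants
  expect_equal(tajima_d(pop), -0.709896, tolerance = 1e-5)
  expect_equal(tajima_d(pop), oracle_tajima(fx$aln$seq), tolerance = 1e-10)

  for (s in 1:3) {
    cfg <- synth_config(n = 12, L = 300, theta = 10, seed = 70 + s)
    aln <- generate_population(cfg)
    pop <- population_sample(aln)
    expect_equal(tajima_d(pop), oracle_tajima(aln$seq), tolerance = 1e-10)
  }
})

test_that("Fu's Fs equals the exact Chinese-restaurant enumeration", {
  for (s in 1:5) {
    cfg <- synth_config(n = sample(6:12, 1), L = 300, theta = 6,
                        seed = 90 + s)
    set.seed(90 + s)
    aln <- generate_population(cfg)
    pop <- population_sample(aln)
    o <- oracle_stats(aln$seq)
    if (o$k == 0) next
    fs <- fu_fs(pop)
    expect_equal(as.numeric(fs),
                 oracle_fu_fs(nrow(aln), o$k, o$n_hap),
                 tolerance = 1e-8)
  }
})

test_that("R2 matches direct evaluation of the singleton formula", {
  fx <- make_fixture("tajima_toy")
  pop <- population_sample(fx$aln)
  # U = (0,1,0,1), k = 1, S = 2 -> sqrt(mean((U - 1/2)^2)) / 2 = 0.25
  expect_equal(r2_statistic(pop), 0.25)
})

test_that("raggedness follows the boundary-step convention", {
  mono <- make_fixture("mono")
  mr <- mismatch_and_raggedness(population_sample(mono$aln))
  expect_equal(mr$raggedness, 2)          # all mass at zero differences
  expect_equal(sum(mr$mismatch$count), choose(5, 2))

  # two haplotypes at counts 2,2 one step apart: freqs (1/3, 2/3)
  rec <- tibble::tibble(id = paste0("s", 1:4), species = "sp", region = "R",
                        site = "S1",
                        seq = c("AAA", "AAA", "AAG", "AAG"))
  mr2 <- mismatch_and_raggedness(pop_of(rec))
  expect_equal(mr2$raggedness, (1 / 3)^2 + (1 / 3)^2 + (2 / 3)^2)

  fx <- make_fixture("tajima_toy")
  mr3 <- mismatch_and_raggedness(population_sample(fx$aln))
  expect_equal(mr3$raggedness, 20 / 36)   # freqs (1/6, 4/6, 1/6) by hand
})

test_that("demographic statistics are order-invariant", {
  cfg <- synth_config(n = 10, L = 300, theta = 8, seed = 123)
  aln <- generate_population(cfg)
  shuffled <- codon_alignment(aln[sample(nrow(aln)), ], frame_offset = 0L)
  p1 <- population_sample(aln); p2 <- population_sample(shuffled)
  expect_equal(tajima_d(p2), tajima_d(p1))
  expect_equal(as.numeric(fu_fs(p2)), as.numeric(fu_fs(p1)))
  expect_equal(r2_statistic(p2), r2_statistic(p1))
  expect_equal(mismatch_and_raggedness(p2)$raggedness,
               mismatch_and_raggedness(p1)$raggedness)
})

test_that("coalescent P-values behave like probabilities under the null", {
  cfg <- synth_config(n = 15, L = 300, theta = 5, growth = 0, omega = 1,
                      seed = 321)
  aln <- generate_population(cfg)
  pop <- population_sample(aln)
  pv <- coalescent_pvalues(pop, reps = 200, seed = 11)
  expect_true(all(pv$p >= 0 & pv$p <= 1))
  expect_equal(pv$statistic, c("d", "fs", "r2", "rg"))

  # a statistic placed at the null median gets P ~ 0.5
  null_d <- replicate(400, {
    a <- generate_population(synth_config(n = 15, L = 300, theta = 5,
                                          growth = 0, omega = 1,
                                          seed = sample.int(1e6, 1)))
    tajima_d(population_sample(a))
  })
  med <- median(null_d, na.rm = TRUE)
  pv2 <- coalescent_pvalues(pop, stats = list(d = med, fs = NULL, r2 = NULL,
                                              rg = NULL),
                            reps = 400, seed = 12)
  expect_lt(abs(pv2$p[pv2$statistic == "d"] - 0.5), 0.12)
})

test_that("strong growth yields significantly negative Tajima's D", {
  set.seed(55)
  hits <- replicate(8, {
    # strong expansion with a mutation supply high enough that S is large
    # (a shrunken star tree with few mutations has little power)
    a <- generate_population(synth_config(n = 25, L = 600, theta = 100,
                                          growth = 100,
                                          seed = sample.int(1e6, 1)))
    pop <- population_sample(a)
    pv <- coalescent_pvalues(pop, reps = 200)
    pv$p[pv$statistic == "d"] < 0.05
  })
  expect_gte(mean(hits, na.rm = TRUE), 0.5)
})

test_that("the demography table gates small populations", {
  rnd <- random_records(6, 30, seed = 99)
  rnd$site <- c(rep("big", 4), "small", "small")
  tab <- demography_summary(codon_alignment(rnd), overall = FALSE,
                            reps = 50, seed = 3)
  expect_true(tab$excluded[tab$site == "small"])
  expect_true(is.na(tab$tajima_d[tab$site == "small"]))
  expect_false(is.na(tab$tajima_d[tab$site == "big"]))
})
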