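make_hap_records <- function(seqs, sites = NULL) {
  n <- length(seqs)
  tibble::tibble(
    id = paste0("s", seq_len(n)),
    species = "sp", region = "R",
    site = sites %||% rep("S1", n),
    seq = seqs
  )
}

test_that("connection limit is monotone and matches direct evaluation", {
  expect_gte(parsimony_limit(600), parsimony_limit(300))
  # near-certain connections only as alpha -> 1
  expect_equal(parsimony_limit(657, alpha = 0.9999), 1L)

  # independent numeric evaluation of the non-homoplasy probability at 657
  L <- 657
  p_direct <- function(j) {
    q <- j / L
    lam <- -3 / 4 * log(1 - 4 * q / 3)
    pdiff <- 3 / 4 * (1 - exp(-4 * lam / 3))
    (lam * exp(-lam) / pdiff)^j * (exp(-lam) / (1 - pdiff))^(L - j)
  }
  direct_limit <- max(which(sapply(1:50, p_direct) >= 0.95))
  expect_equal(parsimony_limit(657), direct_limit)
})

test_that("forced topologies come out of the constructor", {
  # one haplotype observed at two localities: a single node
  rec <- make_hap_records(rep("AAAAAA", 4), sites = c("X", "X", "Y", "Y"))
  hap <- collapse_haplotypes(population_sample(codon_alignment(rec)))
  net <- build_network(hap)
  expect_equal(nrow(net$nodes), 1L)
  expect_equal(nrow(net$edges), 0L)
  expect_equal(length(net$nodes$by_site[[1]]), 2L)

  # A-B-C chain at unit distances: path, no intermediates
  rec <- make_hap_records(c("AAAAAA", "AAAAAG", "AAAAGG"))
  hap <- collapse_haplotypes(population_sample(codon_alignment(rec)))
  net <- build_network(hap)
  expect_equal(sum(net$nodes$type == "inferred"), 0L)
  expect_equal(nrow(net$edges), 2L)
  expect_equal(max(net$nodes$component), 1L)

  # two haplotypes at distance 3, past a limit of 2: separate components
  rec <- make_hap_records(c("AAAAAA", "GGGAAA"))
  hap <- collapse_haplotypes(population_sample(codon_alignment(rec)))
  net <- build_network(hap, limit = 2L)
  expect_equal(max(net$nodes$component), 2L)
  expect_equal(nrow(net$edges), 0L)

  # distance 3 within the limit: two inferred intermediates on the chain
  net2 <- build_network(hap, limit = 3L)
  expect_equal(sum(net2$nodes$type == "inferred"), 2L)
  expect_equal(nrow(net2$edges), 3L)
  expect_equal(max(net2$nodes$component), 1L)
})

test_that("observed node counts conserve the sample size", {
  for (s in 1:3) {
    cfg <- synth_config(n = 15, L = 120, theta = 8, seed = 150 + s)
    aln <- generate_population(cfg)
    hap <- collapse_haplotypes(population_sample(aln))
    net <- build_network(hap)
    obs <- net$nodes[net$nodes$type == "observed", ]
    expect_equal(sum(obs$n), 15L)
    expect_equal(nrow(obs), nrow(hap))
  }
})

test_that("the edge set is invariant to input order", {
  cfg <- synth_config(n = 12, L = 90, theta = 6, seed = 161)
  aln <- generate_population(cfg)
  hap <- collapse_haplotypes(population_sample(aln))
  net1 <- build_network(hap)
  aln2 <- codon_alignment(aln[rev(seq_len(nrow(aln))), ], frame_offset = 0L)
  hap2 <- collapse_haplotypes(population_sample(aln2))
  net2 <- build_network(hap2)
  # same haplotype labels (frequency-then-occurrence ordering) -> same edges
  key <- function(net) {
    e <- net$edges
    sort(paste(pmin(e$from, e$to), pmax(e$from, e$to)))
  }
  expect_equal(key(net2), key(net1))
})

test_that("locality sharing reports shared haplotypes and association", {
  # one haplotype shared (2,3) across two sites, one private
  rec <- make_hap_records(c(rep("AAAAAA", 5), "AAAAAG"),
                          sites = c("X", "X", "Y", "Y", "Y", "X"))
  hap <- collapse_haplotypes(population_sample(codon_alignment(rec)))
  ls <- locality_sharing(hap, reps = 99, seed = 6)
  expect_equal(nrow(ls$shared), 2L)       # two localities of the shared hap
  expect_setequal(ls$shared$count, c(2L, 3L))

  # all haplotypes private to one locality each
  rec2 <- make_hap_records(rep(c("AAAAAA", "GGGGGG"), each = 3),
                           sites = rep(c("X", "Y"), each = 3))
  hap2 <- collapse_haplotypes(population_sample(codon_alignment(rec2)))
  ls2 <- locality_sharing(hap2, reps = 199, seed = 7)
  expect_equal(nrow(ls2$shared), 0L)
  expect_lt(ls2$p_value, 0.2)  # private structure -> strong association

  # single-locality data: empty report
  ls3 <- locality_sharing(
    collapse_haplotypes(population_sample(codon_alignment(
      make_hap_records(c("AAAAAA", "AAAAAG"))))), reps = 9)
  expect_equal(nrow(ls3$shared), 0L)
  expect_true(is.na(ls3$p_value))
})

test_that("expansion genealogies center the network on the common haplotype", {
  set.seed(44)
  hits <- replicate(15, {
    aln <- generate_population(synth_config(n = 25, L = 300, theta = 4,
                                            growth = 80, omega = 1,
                                            seed = sample.int(1e6, 1)))
    hap <- collapse_haplotypes(population_sample(aln))
    if (nrow(hap) < 3) return(NA)
    net <- build_network(hap)
    g <- as_igraph(net)
    deg <- igraph::degree(g)
    top <- hap$haplotype[which.max(hap$n)]
    deg[top] >= max(deg[setdiff(names(deg), top)])
  })
  expect_gte(mean(hits, na.rm = TRUE), 0.6)
})

test_that("GraphML export round-trips through igraph", {
  rec <- make_hap_records(c("AAAAAA", "AAAAAG", "AAAAGG"),
                          sites = c("X", "Y", "Y"))
  net <- build_network(collapse_haplotypes(population_sample(
    codon_alignment(rec))))
  tmp <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(net, tmp)
  g <- igraph::read_graph(tmp, format = "graphml")
  expect_equal(igraph::vcount(g), nrow(net$nodes))
  expect_equal(igraph::ecount(g), nrow(net$edges))
  expect_true("count" %in% igraph::vertex_attr_names(g))
})
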