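# Coalescent generator of mtCOI-like population samples. Downstream modules
# are tested against data with the statistical structure the real marker
# shows: high haplotype diversity, low nucleotide diversity, an excess of
# singletons under population growth, and strong purifying selection on
# amino-acid positions (pi_a/pi_s << 1), emulated by acceptance-sampling
# nonsynonymous mutations.

#' Configuration for the synthetic mtCOI generator
#'
#' @param n Number of haploid sequences (>= 2).
#' @param L Number of sites; must be a multiple of 3 (whole codons).
#' @param theta Population-scaled mutation rate per locus (2*N*mu*L for
#'   mtDNA); mutations are dropped as Poisson(theta/2 * branch length).
#' @param growth Exponential growth rate in coalescent units; 0 = constant
#'   size, large values give star-like genealogies.
#' @param omega Acceptance probability for nonsynonymous mutations in (0, 1];
#'   1 = neutral, small values emulate purifying selection.
#' @param suppress_stops Reject mutations that create stop codons, so that
#'   generated alignments always pass [screen_orf()].
#' @param seed RNG seed (mandatory: every synthetic dataset is reproducible).
#' @details The defaults emulate the empirical regime of vent-copepod mtCOI
#'   samples: an expanding population under strong purifying selection, with
#'   high haplotype diversity (~0.9-1), low nucleotide diversity
#'   (~0.003-0.015 per site), clearly negative Tajima's D, and pi_a/pi_s
#'   well below 1. With `theta = 150`, `growth = 30`, `omega = 0.05` the
#'   effective neutral mutation supply is about 0.29 * theta (three in four
#'   candidate changes are nonsynonymous and mostly rejected), which lands
#'   samples of 15-30 sequences in that regime.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n, L = 657L, theta = 150, growth = 30, omega = 0.05,
                         suppress_stops = TRUE, seed) {
  if (n < 2) abort("n must be >= 2")
  if (L %% 3L != 0L) abort("L must be a multiple of 3")
  if (theta <= 0) abort("theta must be > 0")
  if (omega <= 0 || omega > 1) abort("omega must be in (0, 1]")
  if (missing(seed)) abort("seed is mandatory")
  structure(list(n = as.integer(n), L = as.integer(L), theta = theta,
                 growth = growth, omega = omega,
                 suppress_stops = suppress_stops, seed = as.integer(seed)),
            class = "synth_config")
}

#' Simulate a coalescent genealogy
#'
#' Kingman coalescent for `n` haploid lineages, optionally with exponential
#' population growth: looking back from the present the pairwise coalescence
#' rate at time t is inflated by exp(growth * t), which shortens internal
#' branches and yields the star-like genealogies characteristic of
#' expanding populations.
#'
#' @param n Sample size (>= 2).
#' @param growth Exponential growth rate in coalescent units (>= 0).
#' @param seed Optional RNG seed.
#' @return A `coal_tree`: list with `n`, `parent` (length 2n-1, 0 at the
#'   root), `time` (node ages in coalescent units, tips at 0), `children`.
#'   Nodes 1..n are tips; n+1..2n-1 are coalescences in time order.
#' @export
simulate_genealogy <- function(n, growth = 0, seed = NULL) {
  if (n < 2) abort("n must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n)
  n_nodes <- 2L * n - 1L
  parent <- integer(n_nodes)
  time <- numeric(n_nodes)
  children <- vector("list", n_nodes)
  active <- 1:n
  t <- 0
  nxt <- n + 1L
  k <- n
  while (k > 1L) {
    rate <- k * (k - 1) / 2
    e <- rexp(1L)
    if (growth > 0) {
      # inverse of the time-inhomogeneous intensity rate * exp(growth * t)
      dt <- log1p(growth * exp(-growth * t) * e / rate) / growth
    } else {
      dt <- e / rate
    }
    t <- t + dt
    pick <- sample.int(k, 2L)
    a <- active[pick[1]]; b <- active[pick[2]]
    parent[a] <- nxt; parent[b] <- nxt
    children[[nxt]] <- c(a, b)
    time[nxt] <- t
    active <- c(active[-pick], nxt)
    nxt <- nxt + 1L
    k <- k - 1L
  }
  structure(list(n = n, parent = parent, time = time, children = children),
            class = "coal_tree")
}

#' Branch-length summaries of a coalescent tree
#'
#' `tree_height()` is the time to the most recent common ancestor,
#' `tree_length()` the total branch length, `external_length()` the summed
#' length of the n tip-subtending branches (all in coalescent units).
#'
#' @param tree A `coal_tree` from [simulate_genealogy()].
#' @return A scalar.
#' @export
tree_height <- function(tree) tree$time[length(tree$time)]

#' @rdname tree_height
#' @export
tree_length <- function(tree) {
  non_root <- seq_len(length(tree$parent) - 1L)
  sum(tree$time[tree$parent[non_root]] - tree$time[non_root])
}

#' @rdname tree_height
#' @export
external_length <- function(tree) {
  tips <- seq_len(tree$n)
  sum(tree$time[tree$parent[tips]])
}

#' Overlay finite-sites mutations on a genealogy
#'
#' Drops Poisson(theta/2 * branch length) candidate mutations per branch,
#' placed uniformly over sites, under a Jukes-Cantor base-change model.
#' Candidates that are nonsynonymous in their codon context are retained
#' with probability `omega`; candidates creating a stop codon are rejected
#' outright when `suppress_stops` is on. The ancestral sequence is a random
#' string of sense codons.
#'
#' @param tree A `coal_tree` from [simulate_genealogy()].
#' @param config A [synth_config()]; `config$seed` is *not* re-applied here
#'   (seed once at the start of a run, or use [generate_population()]).
#' @param ancestral Optional ancestral sequence (character scalar of sense
#'   codons, length `config$L`); drawn at random when omitted. Supplying
#'   one lets several populations share common ancestry, as conspecific
#'   populations do.
#' @return A [codon_alignment()] of the `n` tip sequences (ids `t1..tn`).
#' @export
drop_mutations <- function(tree, config, ancestral = NULL) {
  L <- config$L
  code <- "invertebrate_mito"
  tab <- genetic_code(code)
  sense <- sense_codons(code)
  if (is.null(ancestral)) {
    anc_codons <- sample(sense, L %/% 3L, replace = TRUE)
    ancestral <- paste(anc_codons, collapse = "")
  } else if (nchar(ancestral) != L) {
    abort("ancestral sequence length does not match config$L")
  }
  anc <- strsplit(ancestral, "")[[1]]
  bases <- c("A", "C", "G", "T")
  n_nodes <- length(tree$parent)
  root <- n_nodes
  seqs <- vector("list", n_nodes)
  seqs[[root]] <- anc

  mutate_branch <- function(seq_chars, len) {
    n_mut <- rpois(1L, config$theta / 2 * len)
    if (n_mut == 0L) return(seq_chars)
    for (i in seq_len(n_mut)) {
      site <- sample.int(L, 1L)
      old <- seq_chars[site]
      new <- sample(setdiff(bases, old), 1L)
      cod_i <- (site - 1L) %/% 3L
      pos <- site - 3L * cod_i
      cod <- paste(seq_chars[(3L * cod_i + 1L):(3L * cod_i + 3L)], collapse = "")
      newcod <- cod
      substr(newcod, pos, pos) <- new
      if (config$suppress_stops && tab[newcod] == "*") next
      if (tab[newcod] != tab[cod] && runif(1L) > config$omega) next
      seq_chars[site] <- new
    }
    seq_chars
  }

  # preorder: parents before children (nodes are time-ordered, so descend
  # from high index to low)
  for (node in rev(seq_len(n_nodes - 1L))) {
    p <- tree$parent[node]
    len <- tree$time[p] - tree$time[node]
    seqs[[node]] <- mutate_branch(seqs[[p]], len)
  }
  records <- tibble(
    id = paste0("t", seq_len(tree$n)),
    species = NA_character_, region = NA_character_, site = NA_character_,
    seq = vapply(seqs[seq_len(tree$n)], paste, character(1), collapse = "")
  )
  codon_alignment(records, frame_offset = 0L, genetic_code = code)
}

#' Generate one synthetic population sample
#'
#' Convenience wrapper: seeds the RNG from the config, simulates a genealogy
#' and overlays mutations, and attaches population metadata.
#'
#' @param config A [synth_config()].
#' @param species,region,site Metadata labels stamped on every record.
#' @param prefix Id prefix (default the site label or "t").
#' @param ancestral Optional shared ancestral sequence, see
#'   [drop_mutations()].
#' @return A [codon_alignment()] with metadata columns filled in.
#' @export
generate_population <- function(config, species = "synthetic sp.",
                                region = "SIM", site = "site1",
                                prefix = NULL, ancestral = NULL) {
  set.seed(config$seed)
  tree <- simulate_genealogy(config$n, config$growth)
  aln <- drop_mutations(tree, config, ancestral = ancestral)
  prefix <- prefix %||% gsub("[^A-Za-z0-9]", "", site)
  aln$id <- paste0(prefix, "_", seq_len(nrow(aln)))
  aln$species <- species
  aln$region <- region
  aln$site <- site
  aln
}

#' Write a synthetic multi-site dataset to disk
#'
#' Generates one population per site label and writes a combined FASTA plus
#' the matching sample sheet, the exact input contract of [read_fasta()] and
#' [read_sample_sheet()].
#'
#' @param configs Named list of [synth_config()]s, one per site (names are
#'   the site labels).
#' @param dir Output directory (created if needed).
#' @param species,region Labels shared by all sites.
#' @return Invisibly, list with `fasta` and `sheet` paths.
#' @export
synthesize_dataset <- function(configs, dir, species = "synthetic sp.",
                               region = "SIM") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  # one ancestral sequence shared by all sites: conspecific populations
  # descend from common ancestry, so between-site divergence stays in the
  # Jukes-Cantor-correctable range
  set.seed(configs[[1]]$seed)
  L <- configs[[1]]$L
  anc <- paste(sample(sense_codons(), L %/% 3L, replace = TRUE),
               collapse = "")
  alns <- purrr::imap(configs, function(cfg, site) {
    generate_population(cfg, species = species, region = region,
                        site = site, ancestral = anc)
  })
  all_rec <- bind_rows(alns)
  fasta <- file.path(dir, "synthetic.fasta")
  sheet_path <- file.path(dir, "samples.tsv")
  write_fasta(all_rec, fasta)
  write_sample_sheet(all_rec[c("id", "species", "region", "site")], sheet_path)
  invisible(list(fasta = fasta, sheet = sheet_path))
}

#' Hand-constructed test fixtures with oracle-computed expectations
#'
#' Small alignments whose summary statistics are known by direct
#' enumeration, used across the test suite.
#'
#' * `"tajima_toy"`: 4 sequences, 10 sites, two singleton variant columns
#'   (S = 2, mean pairwise differences k = 1, pi = 0.1).
#' * `"fst_fixed"`: two populations of 5, each fixed for its own haplotype
#'   (F_ST = 1).
#' * `"mono"`: 5 identical sequences (Hd = 0, pi = 0, S = 0).
#'
#' @param name Fixture name.
#' @return List with `aln` (a [codon_alignment()]; `frame_offset` 0 but the
#'   short fixtures are not codon-complete and are used for nucleotide-level
#'   statistics only), `sheet`, and `expected` (named list).
#' @export
make_fixture <- function(name) {
  fix <- switch(name,
    tajima_toy = {
      seqs <- c(a = "AAAAAAAAAA",
                b = "AACAAAAAAA",   # singleton at column 3
                c = "AAAAAAAAAA",
                d = "AAAAAAGAAA")   # singleton at column 7
      list(seqs = seqs, pops = rep("P1", 4),
           expected = list(S = 2L, k = 1.0, pi = 0.1, n_hap = 3L,
                           hd = 5 / 6))
    },
    fst_fixed = {
      seqs <- c(setNames(rep("AAAAAAAAA", 5), paste0("x", 1:5)),
                setNames(rep("AAAAAAAAG", 5), paste0("y", 1:5)))
      list(seqs = seqs, pops = rep(c("P1", "P2"), each = 5),
           expected = list(fst = 1))
    },
    mono = {
      seqs <- setNames(rep("ACGTACGTA", 5), paste0("m", 1:5))
      list(seqs = seqs, pops = rep("P1", 5),
           expected = list(S = 0L, pi = 0, n_hap = 1L, hd = 0))
    },
    abort(paste0("unknown fixture '", name, "'"))
  )
  records <- tibble(
    id = names(fix$seqs),
    species = "fixture sp.", region = "FIX", site = fix$pops,
    seq = unname(fix$seqs)
  )
  aln <- codon_alignment(records, frame_offset = 0L)
  sheet <- records[c("id", "species", "region", "site")]
  list(aln = aln, sheet = sheet, expected = fix$expected)
}
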