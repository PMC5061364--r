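# Brute-force oracles: every statistic recomputed by naive enumeration,
# independent of the package's code paths.

# summary statistics by direct pair/column enumeration
oracle_stats <- function(seqs) {
  m <- do.call(rbind, strsplit(seqs, ""))
  n <- nrow(m)
  L <- ncol(m)
  diffs <- c()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      diffs <- c(diffs, sum(m[i, ] != m[j, ]))
    }
  }
  S <- 0L
  for (col in seq_len(L)) if (length(unique(m[, col])) > 1) S <- S + 1L
  haps <- unique(seqs)
  counts <- sapply(haps, function(h) sum(seqs == h))
  p <- counts / n
  list(
    S = S,
    k = mean(diffs),
    pi = mean(diffs) / L,
    n_hap = length(haps),
    hd = n * (1 - sum(p^2)) / (n - 1),
    mismatch = diffs
  )
}

# Weir-Cockerham haploid theta via aov() mean squares per allele
oracle_wc_theta <- function(hap, pops) {
  pops <- factor(pops)
  r <- nlevels(pops)
  ni <- as.numeric(table(pops))
  ntot <- sum(ni)
  nc <- (ntot - sum(ni^2) / ntot) / (r - 1)
  num <- 0; den <- 0
  for (al in unique(hap)) {
    y <- as.numeric(hap == al)
    fit <- stats::aov(y ~ pops)
    ms <- summary(fit)[[1]][["Mean Sq"]]
    msp <- ms[1]; msg <- ms[2]
    if (is.na(msg)) msg <- 0  # saturated (one obs per group) cannot occur here
    num <- num + (msp - msg)
    den <- den + (msp + (nc - 1) * msg)
  }
  num / den
}

# Fu's Fs S' via the Chinese-restaurant representation: the number of
# distinct haplotypes K is a sum of independent Bernoulli(theta/(theta+i-1))
# indicators, convolved exactly.
oracle_fu_fs <- function(n, theta, K_obs) {
  p <- theta / (theta + 0:(n - 1))
  dist <- 1
  for (pi in p) dist <- convolve_bern(dist, pi)
  # dist[j+1] = P(K = j), j = 0..n (P(K=0) = 0 since first draw is new)
  sprime <- sum(dist[(K_obs + 1):(n + 1)])
  log(sprime / (1 - sprime))
}

convolve_bern <- function(dist, p) {
  out <- numeric(length(dist) + 1)
  out[seq_along(dist)] <- dist * (1 - p)
  out[seq_along(dist) + 1] <- out[seq_along(dist) + 1] + dist * p
  out
}

# independent re-implementation of Tajima's D from the published constants
oracle_tajima <- function(seqs) {
  o <- oracle_stats(seqs)
  n <- length(seqs)
  if (o$S == 0) return(NA_real_)
  a1 <- sum(1 / 1:(n - 1)); a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  (o$k - o$S / a1) / sqrt(c1 / a1 * o$S + c2 / (a1^2 + a2) * o$S * (o$S - 1))
}

# random ACGT alignment tibble (no codon structure; nucleotide-level tests)
random_records <- function(n, L, seed) {
  set.seed(seed)
  tibble::tibble(
    id = paste0("r", seq_len(n)),
    species = "sp", region = "R", site = "S1",
    seq = replicate(n, paste(sample(c("A", "C", "G", "T"), L, TRUE),
                             collapse = ""))
  )
}

# records derived from one reference by a few substitutions each, so all
# pairwise distances stay far below Jukes-Cantor saturation
related_records <- function(n, L, nmut, seed, sites = NULL) {
  set.seed(seed)
  ref <- sample(c("A", "C", "G", "T"), L, TRUE)
  seqs <- replicate(n, {
    s <- ref
    pos <- sample(L, nmut)
    for (p in pos) s[p] <- sample(setdiff(c("A", "C", "G", "T"), s[p]), 1)
    paste(s, collapse = "")
  })
  tibble::tibble(id = paste0("r", seq_len(n)), species = "sp", region = "R",
                 site = sites %||% rep("S1", n), seq = seqs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# single population sample straight from records
pop_of <- function(records, frame_offset = 0L) {
  population_sample(codon_alignment(records, frame_offset = frame_offset))
}
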