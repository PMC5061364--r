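# Demographic / neutrality statistics: Tajima's D, Fu's Fs, the
# Ramos-Onsins & Rozas R2, and the mismatch-distribution raggedness index,
# with coalescent significance tests. Jointly negative / small values of
# these statistics are the classical signature of recent population
# expansion, the regime the vent-copepod marker consistently shows.

# Core summaries from a character matrix (rows = sequences over masked
# sites). Handles multi-allelic columns (finite-sites data).
.demog_core <- function(m) {
  n <- nrow(m)
  d <- pairwise_diffs(m)
  pairs <- d[upper.tri(d)]
  k <- mean(pairs)
  # singletons: per column, alleles carried by exactly one sequence
  U <- integer(n)
  S <- 0L
  eta <- 0L
  for (col in seq_len(ncol(m))) {
    tabc <- table(m[, col])
    if (length(tabc) > 1L) {
      S <- S + 1L
      eta <- eta + (length(tabc) - 1L)
      ones <- names(tabc)[tabc == 1L]
      for (al in ones) U[which(m[, col] == al)] <- U[which(m[, col] == al)] + 1L
    }
  }
  K <- length(unique(apply(m, 1, paste, collapse = "")))
  list(n = n, L = ncol(m), S = S, eta = eta, k = k, K = K, U = U,
       pair_diffs = pairs)
}

tajima_constants <- function(n) {
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = e1, e2 = e2)
}

.tajima <- function(n, S, k) {
  if (S == 0L) return(NA_real_)
  cst <- tajima_constants(n)
  (k - S / cst$a1) / sqrt(cst$e1 * S + cst$e2 * S * (S - 1))
}

#' Tajima's D
#'
#' `D = (k - S/a1) / sd` with the 1989 variance constants; negative values
#' indicate an excess of low-frequency (singleton) variants relative to the
#' neutral constant-size expectation.
#'
#' @param pop A `pop_sample` with n >= 4.
#' @return D, or `NA` when there is no segregating site.
#' @export
tajima_d <- function(pop) {
  m <- as_seq_matrix(pop)
  if (nrow(m) < 4) abort("Tajima's D needs n >= 4")
  core <- .demog_core(m)
  .tajima(core$n, core$S, core$k)
}

# log unsigned Stirling numbers of the first kind, row n (k = 1..n), cached
.stirling_cache <- new.env(parent = emptyenv())
log_stirling_row <- function(n) {
  key <- as.character(n)
  if (!is.null(.stirling_cache[[key]])) return(.stirling_cache[[key]])
  ls <- 0 # row 1: |s(1,1)| = 1
  if (n > 1) {
    for (m in 1:(n - 1)) {
      # |s(m+1,k)| = |s(m,k-1)| + m * |s(m,k)|
      prev <- c(-Inf, ls)            # shifted: |s(m, k-1)|
      keep <- c(ls, -Inf) + log(m)   # m * |s(m, k)|
      ls <- pmax(prev, keep) + log1p(exp(-abs(prev - keep)))
      ls[is.nan(ls)] <- -Inf
    }
  }
  .stirling_cache[[key]] <- ls
  ls
}

#' Distribution of the number of distinct haplotypes under neutrality
#'
#' `P(K = j)` for j = 1..n under the Ewens sampling formula,
#' `P(K = j) = |s(n, j)| theta^j / theta^(n)` with unsigned Stirling
#' numbers of the first kind and the rising factorial, computed in log
#' space. This is the ingredient of Fu's Fs.
#'
#' @param n Sample size.
#' @param theta Scaled mutation rate.
#' @return Numeric vector of length `n` summing to 1.
#' @export
ewens_k_distribution <- function(n, theta) {
  ls <- log_stirling_row(n)
  j <- seq_len(n)
  logp <- ls + j * log(theta) - sum(log(theta + 0:(n - 1)))
  p <- exp(logp)
  p / sum(p)
}

.fu_fs <- function(n, k, K, eps = 1e-8) {
  if (k <= 0) return(NA_real_)
  p <- ewens_k_distribution(n, k)
  sprime <- sum(p[K:n])
  clamped <- FALSE
  if (sprime < eps) { sprime <- eps; clamped <- TRUE }
  if (sprime > 1 - eps) { sprime <- 1 - eps; clamped <- TRUE }
  out <- log(sprime / (1 - sprime))
  attr(out, "clamped") <- clamped
  out
}

#' Fu's Fs
#'
#' `Fs = ln(S'/(1-S'))` where `S'` is the probability, under the Ewens
#' sampling formula with theta set to the observed mean pairwise difference
#' k, of observing at least as many distinct haplotypes as seen. Strongly
#' negative values flag an excess of haplotypes, as produced by expansion.
#' When `S'` degenerates to 0 or 1 the value is clamped (attribute
#' `clamped`).
#'
#' @param pop A `pop_sample` with n >= 4 and k > 0.
#' @return Fs (with attribute `clamped`), or `NA` when k = 0.
#' @export
fu_fs <- function(pop) {
  m <- as_seq_matrix(pop)
  if (nrow(m) < 4) abort("Fu's Fs needs n >= 4")
  core <- .demog_core(m)
  .fu_fs(core$n, core$k, core$K)
}

.r2 <- function(n, U, k, S) {
  if (S == 0L) return(NA_real_)
  sqrt(mean((U - k / 2)^2)) / S
}

#' Ramos-Onsins & Rozas R2
#'
#' `R2 = sqrt(mean((U_i - k/2)^2)) / S`, where `U_i` is the number of
#' singleton mutations carried by sequence i (minor-allele count 1; no
#' outgroup polarisation). Small values indicate expansion.
#'
#' @param pop A `pop_sample` with n >= 4.
#' @return R2, or `NA` when S = 0.
#' @export
r2_statistic <- function(pop) {
  m <- as_seq_matrix(pop)
  if (nrow(m) < 4) abort("R2 needs n >= 4")
  core <- .demog_core(m)
  .r2(core$n, core$U, core$k, core$S)
}

.raggedness <- function(freqs) {
  # freqs: relative frequency of pairs with 0..d differences; boundary
  # steps on both sides (x_{-1} = x_{d+1} = 0) are included, so a
  # degenerate distribution scores 2.
  x <- c(0, freqs, 0)
  sum(diff(x)^2)
}

#' Mismatch distribution and raggedness index
#'
#' The mismatch distribution is the histogram of pairwise nucleotide
#' differences; under sudden expansion it is smooth and unimodal, and the
#' raggedness index (sum of squared steps between adjacent frequency
#' classes, including the boundary steps into and out of the observed
#' range) is small.
#'
#' @param pop A `pop_sample` with n >= 2.
#' @return List with `mismatch` (tibble `differences`, `count`, `freq`) and
#'   `raggedness`.
#' @export
mismatch_and_raggedness <- function(pop) {
  m <- as_seq_matrix(pop)
  if (nrow(m) < 2) abort("mismatch distribution needs n >= 2")
  core <- .demog_core(m)
  dmax <- max(core$pair_diffs)
  counts <- tabulate(core$pair_diffs + 1L, nbins = dmax + 1L)
  freqs <- counts / length(core$pair_diffs)
  list(
    mismatch = tibble(differences = 0:dmax, count = counts, freq = freqs),
    raggedness = .raggedness(freqs)
  )
}

# ---- coalescent null machinery --------------------------------------------

# One neutral constant-size replicate at (n, theta): infinite-sites
# mutations dropped on a simulated genealogy; returns the same statistics.
.null_replicate_stats <- function(n, theta) {
  tree <- simulate_genealogy(n)
  n_nodes <- 2L * n - 1L
  lens <- tree$time[tree$parent[seq_len(n_nodes - 1L)]] -
    tree$time[seq_len(n_nodes - 1L)]
  M <- rpois(1L, theta / 2 * sum(lens))
  if (M == 0L) {
    return(list(S = 0L, k = 0, D = NA_real_, Fs = NA_real_, R2 = NA_real_,
                rg = .raggedness(1)))
  }
  # descendant tip sets per node
  desc <- vector("list", n_nodes)
  for (i in seq_len(n)) desc[[i]] <- i
  for (v in (n + 1L):n_nodes) {
    ch <- tree$children[[v]]
    desc[[v]] <- c(desc[[ch[1]]], desc[[ch[2]]])
  }
  branch <- sample.int(n_nodes - 1L, M, replace = TRUE, prob = lens)
  G <- matrix(FALSE, n, M)
  for (j in seq_len(M)) G[desc[[branch[j]]], j] <- TRUE
  dcount <- colSums(G)
  k <- sum(dcount * (n - dcount)) / choose(n, 2)
  # pairwise difference matrix
  Gi <- G * 1L
  cross <- tcrossprod(Gi)
  tot <- diag(cross)
  dm <- outer(tot, tot, "+") - 2 * cross
  pairs <- dm[upper.tri(dm)]
  # singletons, minor-allele definition
  U <- integer(n)
  for (j in seq_len(M)) {
    if (dcount[j] == 1L) U[which(G[, j])] <- U[which(G[, j])] + 1L
    else if (dcount[j] == n - 1L) U[which(!G[, j])] <- U[which(!G[, j])] + 1L
  }
  K <- length(unique(apply(Gi, 1, paste, collapse = "")))
  dmax <- max(pairs)
  freqs <- tabulate(pairs + 1L, nbins = dmax + 1L) / length(pairs)
  list(S = M, k = k,
       D = .tajima(n, M, k),
       Fs = .fu_fs(n, k, K),
       R2 = .r2(n, U, k, M),
       rg = .raggedness(freqs))
}

#' Neutral coalescent null distributions of the demographic statistics
#'
#' Simulates constant-size neutral coalescent samples (infinite sites, no
#' recombination) at a given theta and returns the four demographic
#' statistics per replicate. This is the engine behind
#' [coalescent_pvalues()], exposed for calibration studies.
#'
#' @param n Sample size.
#' @param theta Population-scaled mutation rate per locus.
#' @param reps Number of replicates.
#' @param seed Optional RNG seed.
#' @return Tibble with columns `S`, `k`, `d`, `fs`, `r2`, `rg`, one row per
#'   replicate (`NA` statistics when a replicate has no polymorphism).
#' @export
simulate_neutral_null <- function(n, theta, reps = 1000L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  bind_rows(purrr::map(seq_len(reps), function(r) {
    x <- .null_replicate_stats(n, theta)
    tibble(S = x$S, k = x$k, d = x$D, fs = as.numeric(x$Fs), r2 = x$R2,
           rg = x$rg)
  }))
}

#' Coalescent significance tests for the demographic statistics
#'
#' Simulates `reps` neutral constant-size coalescent samples (no
#' recombination) at Watterson's theta fitted from the observed number of
#' segregating sites, recomputes each statistic, and reports empirical
#' P-values with `+1/(reps+1)` smoothing. D, Fs and R2 are tested on the
#' lower tail (the expansion direction); the raggedness index on the
#' upper-or-equal tail. Both orientations are available via `tails`.
#'
#' @param pop A `pop_sample`.
#' @param stats Optional precomputed list with elements `d`, `fs`, `r2`,
#'   `rg` (computed from `pop` when omitted).
#' @param reps Number of null replicates (default 1000).
#' @param seed Optional RNG seed.
#' @param tails Named character vector giving the tail per statistic
#'   (`"lower"` = P(null <= obs), `"upper"` = P(null >= obs)).
#' @return Tibble with columns `statistic`, `value`, `p`, `tail`,
#'   `n_replicates`.
#' @export
coalescent_pvalues <- function(pop, stats = NULL, reps = 1000L, seed = NULL,
                               tails = c(d = "lower", fs = "lower",
                                         r2 = "lower", rg = "upper")) {
  if (!is.null(seed)) set.seed(seed)
  m <- as_seq_matrix(pop)
  core <- .demog_core(m)
  if (is.null(stats)) {
    stats <- list(
      d = .tajima(core$n, core$S, core$k),
      fs = as.numeric(.fu_fs(core$n, core$k, core$K)),
      r2 = .r2(core$n, core$U, core$k, core$S),
      rg = .raggedness(tabulate(core$pair_diffs + 1L,
                                nbins = max(core$pair_diffs) + 1L) /
                       length(core$pair_diffs))
    )
  }
  theta_w <- core$S / tajima_constants(core$n)$a1
  null <- purrr::map(seq_len(reps), function(r) {
    .null_replicate_stats(core$n, theta_w)
  })
  pull_stat <- function(key) {
    map_dbl(null, function(x) {
      as.numeric(x[[switch(key, d = "D", fs = "Fs", r2 = "R2", rg = "rg")]])
    })
  }
  rows <- purrr::map(names(tails), function(key) {
    obs <- stats[[key]]
    if (is.null(obs) || is.na(obs)) {
      return(tibble(statistic = key, value = NA_real_, p = NA_real_,
                    tail = tails[[key]], n_replicates = reps))
    }
    nullv <- pull_stat(key)
    nullv <- nullv[!is.na(nullv)]
    hits <- if (tails[[key]] == "lower") sum(nullv <= obs) else sum(nullv >= obs)
    tibble(statistic = key, value = as.numeric(obs),
           p = (hits + 1) / (length(nullv) + 1),
           tail = tails[[key]], n_replicates = reps)
  })
  bind_rows(rows)
}

#' Per-population demography summary table
#'
#' One row per (species, site) population with Tajima's D, Fu's Fs, R2 and
#' the raggedness index plus their coalescent P-values; populations under
#' the estimation gate report `NA`. An `overall` row per species pools all
#' sites.
#'
#' @inheritParams diversity_summary
#' @param reps Coalescent replicates per population for the P-values.
#' @param seed RNG seed.
#' @return A tibble with columns `species`, `region`, `site`, `n_seq`,
#'   `n_hap`, `tajima_d`, `p_d`, `fu_fs`, `p_fs`, `r2`, `p_r2`, `rg`,
#'   `p_rg`, `excluded`.
#' @export
demography_summary <- function(aln, sheet = NULL, min_n = 4L, overall = TRUE,
                               reps = 1000L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(sheet)) sheet <- aln[c("id", "species", "region", "site")]
  combos <- distinct(sheet[c("species", "region", "site")])
  pops <- purrr::pmap(combos, function(species, region, site) {
    subsample_population(aln, sheet, species, site, min_n = min_n)
  })
  if (overall) {
    for (sp in unique(combos$species)) {
      ids <- sheet$id[sheet$species == sp]
      pops <- c(pops, list(population_sample(
        aln, intersect(ids, aln$id), species = sp, site = "overall",
        region = paste(sort(unique(sheet$region[sheet$species == sp])),
                       collapse = "+"),
        min_n = min_n)))
    }
  }
  bind_rows(purrr::map(pops, .demography_row, reps = reps))
}

.demography_row <- function(pop, reps = 1000L) {
  n <- nrow(pop$records)
  hap_n <- nrow(collapse_haplotypes(pop))
  base <- tibble(
    species = pop$species, region = pop$region, site = pop$site,
    n_seq = n, n_hap = hap_n,
    tajima_d = NA_real_, p_d = NA_real_, fu_fs = NA_real_, p_fs = NA_real_,
    r2 = NA_real_, p_r2 = NA_real_, rg = NA_real_, p_rg = NA_real_,
    excluded = pop$excluded
  )
  if (pop$excluded || n < 4) return(base)
  core <- .demog_core(as_seq_matrix(pop))
  if (core$S == 0L) return(base)
  pv <- coalescent_pvalues(pop, reps = reps)
  get <- function(key, col) pv[[col]][pv$statistic == key]
  base$tajima_d <- get("d", "value"); base$p_d <- get("d", "p")
  base$fu_fs <- get("fs", "value"); base$p_fs <- get("fs", "p")
  base$r2 <- get("r2", "value"); base$p_r2 <- get("r2", "p")
  base$rg <- get("rg", "value"); base$p_rg <- get("rg", "p")
  base
}
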