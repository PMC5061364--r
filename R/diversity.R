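# Per-population diversity statistics for a single protein-coding marker:
# haplotype counts and diversity, segregating sites, Jukes-Cantor corrected
# nucleotide diversity, its synonymous/nonsynonymous partition
# (Nei-Gojobori), and p-distance summaries between groups.

# ---- pairwise machinery ----------------------------------------------------

# Pairwise difference counts over the columns of a character matrix
# (rows = sequences). Returns list(diff = matrix of counts, n = nrow).
pairwise_diffs <- function(m) {
  n <- nrow(m)
  d <- matrix(0L, n, n)
  if (n >= 2) {
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        d[i, j] <- d[j, i] <- sum(m[i, ] != m[j, ])
      }
    }
  }
  d
}

jc_correct <- function(p, what = "a pair") {
  if (any(p >= 0.75)) {
    abort(paste0("Jukes-Cantor distance undefined (p >= 0.75) for ", what))
  }
  -0.75 * log(1 - 4 * p / 3)
}

# ---- haplotypes ------------------------------------------------------------

#' Collapse a population sample into haplotypes
#'
#' Haplotypes are exact string matches over the masked (complete,
#' unambiguous) sites. Haplotypes are labelled `H1, H2, ...` in order of
#' decreasing total frequency (ties: first occurrence).
#'
#' @param pop A `pop_sample` (see [population_sample()]).
#' @return A tibble with columns `haplotype`, `seq` (masked-site string),
#'   `n`, and `by_site` (list column of named per-locality counts); attribute
#'   `n_seq` = sample size.
#' @export
collapse_haplotypes <- function(pop) {
  m <- as_seq_matrix(pop)
  strings <- apply(m, 1, paste, collapse = "")
  sites <- pop$records$site
  tab <- tibble(seq = strings, locality = sites) |>
    group_by(.data$seq) |>
    summarise(n = dplyr::n(),
              by_site = list(table(.data$locality)),
              .groups = "drop")
  # deterministic labels: frequency first, then sequence, so the table is
  # invariant to the input order of specimens
  ord <- order(-tab$n, tab$seq)
  tab <- tab[ord, ]
  tab$haplotype <- paste0("H", seq_len(nrow(tab)))
  out <- tab[c("haplotype", "seq", "n", "by_site")]
  attr(out, "n_seq") <- nrow(m)
  out
}

#' Haplotype diversity (Nei's unbiased estimator)
#'
#' The probability that two sequences sampled without replacement carry
#' different haplotypes: `Hd = n (1 - sum p_i^2) / (n - 1)`.
#'
#' @param pop A `pop_sample`.
#' @return Hd in \[0, 1\]; 0 iff monomorphic, 1 iff all haplotypes distinct.
#' @export
haplotype_diversity <- function(pop) {
  n <- nrow(pop$records)
  if (n < 2) abort("haplotype diversity needs n >= 2")
  counts <- collapse_haplotypes(pop)$n
  p <- counts / n
  n * (1 - sum(p^2)) / (n - 1)
}

#' Number of segregating sites
#'
#' Count of masked columns carrying two or more distinct bases.
#'
#' @param pop A `pop_sample`.
#' @return Integer count `S`.
#' @export
segregating_sites <- function(pop) {
  m <- as_seq_matrix(pop)
  sum(apply(m, 2, function(col) length(unique(col)) > 1L))
}

#' Nucleotide diversity
#'
#' Mean pairwise per-site difference proportion over masked sites,
#' optionally Jukes-Cantor corrected per pair before averaging (the
#' correction compensates multiple hits at a site; it is applied to each
#' pairwise p, not to the average).
#'
#' @param pop A `pop_sample`.
#' @param correction `"JC"` (default) or `"none"`.
#' @return pi (per site).
#' @export
nucleotide_diversity <- function(pop, correction = c("JC", "none")) {
  correction <- match.arg(correction)
  m <- as_seq_matrix(pop)
  n <- nrow(m)
  if (n < 2) abort("nucleotide diversity needs n >= 2")
  L <- ncol(m)
  d <- pairwise_diffs(m)
  p <- d[upper.tri(d)] / L
  if (correction == "JC") {
    bad <- which(p >= 0.75)
    if (length(bad)) {
      pairs <- which(upper.tri(d), arr.ind = TRUE)[bad[1], ]
      abort(sprintf(
        "Jukes-Cantor distance undefined (p >= 0.75) for pair %s / %s",
        rownames(m)[pairs[1]], rownames(m)[pairs[2]]))
    }
    p <- -0.75 * log(1 - 4 * p / 3)
  }
  mean(p)
}

#' Mean pairwise differences (k)
#'
#' @param pop A `pop_sample`.
#' @return Mean number of pairwise differences over masked sites.
#' @export
mean_pairwise_differences <- function(pop) {
  m <- as_seq_matrix(pop)
  if (nrow(m) < 2) abort("needs n >= 2")
  d <- pairwise_diffs(m)
  mean(d[upper.tri(d)])
}

# ---- synonymous / nonsynonymous partition ---------------------------------

# Trim a site mask to whole in-frame codons: returns list of codon column
# triplets (each fully inside the mask).
codon_triplets <- function(mask, frame_offset, n_total) {
  starts <- seq(frame_offset + 1L, n_total - 2L, by = 3L)
  keep <- starts[(starts %in% mask) &
                 ((starts + 1L) %in% mask) &
                 ((starts + 2L) %in% mask)]
  if (length(keep) == 0L) abort("no complete codons in the site mask")
  keep
}

# Nei-Gojobori pathway counts for one codon pair. Returns c(sd, nd):
# synonymous and nonsynonymous differences averaged over mutational
# pathways; pathways through stop codons are excluded (if all pathways hit
# a stop, all are used with stop steps counted nonsynonymous).
ng_pair_counts <- function(cod1, cod2, tab) {
  pos <- which(strsplit(cod1, "")[[1]] != strsplit(cod2, "")[[1]])
  ndiff <- length(pos)
  if (ndiff == 0L) return(c(0, 0))
  perms <- switch(ndiff,
    list(pos),
    list(pos, rev(pos)),
    {
      p <- pos
      list(p[c(1, 2, 3)], p[c(1, 3, 2)], p[c(2, 1, 3)],
           p[c(2, 3, 1)], p[c(3, 1, 2)], p[c(3, 2, 1)])
    })
  walk <- function(order) {
    cur <- cod1
    sd <- 0; nd <- 0; hit_stop <- FALSE
    for (p in order) {
      nxt <- cur
      substr(nxt, p, p) <- substr(cod2, p, p)
      if (tab[nxt] == "*") hit_stop <- TRUE
      if (tab[nxt] == tab[cur] && tab[nxt] != "*") sd <- sd + 1
      else nd <- nd + 1
      cur <- nxt
    }
    c(sd, nd, hit_stop)
  }
  res <- vapply(perms, walk, numeric(3))
  ok <- res[3, ] == 0
  if (any(ok)) res <- res[, ok, drop = FALSE]
  c(mean(res[1, ]), mean(res[2, ]))
}

#' Synonymous and nonsynonymous nucleotide diversity
#'
#' Nei-Gojobori (1986) pathway counting under the alignment's genetic code:
#' per sequence pair, synonymous/nonsynonymous sites and differences are
#' counted over the codon-complete part of the site mask, each per-pair
#' proportion is Jukes-Cantor corrected, and corrected values are averaged
#' over pairs. A ratio much below 1 indicates purifying selection, as
#' expected for a functional mitochondrial protein-coding gene (and its
#' absence is a NUMT warning sign).
#'
#' @param pop A `pop_sample` whose alignment has a valid `frame_offset`.
#' @return A list with `pi_a`, `pi_s`, `ratio` (`NA` when both are 0,
#'   0 when only `pi_a` is 0, `Inf` when only `pi_s` is 0), `n_codons`.
#' @export
pi_syn_nonsyn <- function(pop) {
  tab <- genetic_code(pop$genetic_code)
  syn_tab <- syn_site_table(pop$genetic_code)
  starts <- codon_triplets(pop$mask, pop$frame_offset, pop$sites_alignment)
  full <- do.call(rbind, strsplit(pop$records$seq, ""))
  n <- nrow(full)
  if (n < 2) abort("pi_a/pi_s needs n >= 2")
  codons <- vapply(starts, function(s) {
    apply(full[, s:(s + 2L), drop = FALSE], 1, paste, collapse = "")
  }, character(n))
  if (n == 1L) codons <- matrix(codons, nrow = 1)
  # per-sequence synonymous site totals
  syn_sites_seq <- vapply(seq_len(n), function(i) {
    sum(syn_tab[codons[i, ], ])
  }, numeric(1))
  total_sites <- 3 * length(starts)
  da <- c(); ds <- c()
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      cnt <- vapply(seq_along(starts), function(ci) {
        ng_pair_counts(codons[i, ci], codons[j, ci], tab)
      }, numeric(2))
      sdiff <- sum(cnt[1, ]); ndiff <- sum(cnt[2, ])
      s_sites <- mean(syn_sites_seq[c(i, j)])
      n_sites <- total_sites - s_sites
      ps <- if (s_sites > 0) sdiff / s_sites else 0
      pn <- if (n_sites > 0) ndiff / n_sites else 0
      ds <- c(ds, jc_correct(ps, what = "synonymous sites"))
      da <- c(da, jc_correct(pn, what = "nonsynonymous sites"))
    }
  }
  pi_a <- mean(da); pi_s <- mean(ds)
  ratio <- if (pi_a == 0 && pi_s == 0) NA_real_
           else if (pi_s == 0) Inf
           else pi_a / pi_s
  list(pi_a = pi_a, pi_s = pi_s, ratio = ratio, n_codons = length(starts))
}

# ---- p-distances -----------------------------------------------------------

#' Within- and between-group p-distance summary
#'
#' Uncorrected pairwise p-distances with pairwise deletion of non-ACGT
#' positions. Within-group standard errors come from a site-resampling
#' bootstrap of the mean (columns are resampled with replacement, the
#' within-group mean recomputed, and the SE is the standard deviation of
#' the bootstrap means).
#'
#' @param records Tibble with columns `seq` and a grouping column; all
#'   sequences must share the aligned length.
#' @param group Name of the grouping column (default `"species"`).
#' @param bootstrap_reps Bootstrap replicates (default 500).
#' @param seed Optional RNG seed.
#' @return A tibble, one row per group: `group`, `n`, `within_min`,
#'   `within_mean`, `within_max`, `within_se`, `between_min`, `between_max`
#'   (`NA` for size-1 groups / single-group inputs).
#' @export
p_distance_summary <- function(records, group = "species",
                               bootstrap_reps = 500L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- records[[group]]
  mats <- do.call(rbind, strsplit(records$seq, ""))
  ok <- matrix(mats %in% c("A", "C", "G", "T"), nrow = nrow(mats))
  groups <- unique(g)
  pdist_pair <- function(i, j, cols = NULL) {
    use <- ok[i, ] & ok[j, ]
    if (!is.null(cols)) {
      use_cols <- cols[use[cols]]
    } else use_cols <- which(use)
    if (length(use_cols) == 0L) return(NA_real_)
    mean(mats[i, use_cols] != mats[j, use_cols])
  }
  within <- function(idx, cols = NULL) {
    if (length(idx) < 2) return(numeric(0))
    combn_idx <- utils::combn(idx, 2)
    vapply(seq_len(ncol(combn_idx)), function(k) {
      pdist_pair(combn_idx[1, k], combn_idx[2, k], cols)
    }, numeric(1))
  }
  between_mean <- function(ia, ib) {
    vals <- as.vector(outer(ia, ib, Vectorize(function(i, j) pdist_pair(i, j))))
    mean(vals, na.rm = TRUE)
  }
  L <- ncol(mats)
  rows <- purrr::map(groups, function(gr) {
    idx <- which(g == gr)
    wd <- within(idx)
    if (length(wd)) {
      boots <- vapply(seq_len(bootstrap_reps), function(r) {
        cols <- sample.int(L, L, replace = TRUE)
        mean(within(idx, cols = cols), na.rm = TRUE)
      }, numeric(1))
      w <- list(min = min(wd), mean = mean(wd), max = max(wd),
                se = sd(boots))
    } else {
      w <- list(min = NA_real_, mean = NA_real_, max = NA_real_,
                se = NA_real_)
    }
    others <- setdiff(groups, gr)
    if (length(others)) {
      bm <- vapply(others, function(og) {
        between_mean(idx, which(g == og))
      }, numeric(1))
      btw <- list(min = min(bm), max = max(bm))
    } else btw <- list(min = NA_real_, max = NA_real_)
    tibble(group = gr, n = length(idx),
           within_min = w$min, within_mean = w$mean, within_max = w$max,
           within_se = w$se, between_min = btw$min, between_max = btw$max)
  })
  bind_rows(rows)
}

# ---- summary table ---------------------------------------------------------

#' Per-population diversity summary table
#'
#' One row per (species, site) population, with the layout of a standard
#' mtCOI diversity table: sample size, sites used / alignment length,
#' haplotype count, haplotype diversity, segregating sites, Jukes-Cantor
#' corrected nucleotide diversity, and the pi_a/pi_s ratio. Populations
#' below the estimation gate (`min_n`, default 4) report counts only, with
#' `NA` statistics. When `overall = TRUE` an additional row per species
#' pools all its sites.
#'
#' @param aln A [codon_alignment()].
#' @param sheet Sample sheet tibble; defaults to the alignment's own
#'   metadata columns.
#' @param min_n Estimation gate.
#' @param overall Add one pooled row per species.
#' @return A tibble with columns `species`, `region`, `site`, `n_seq`,
#'   `sites_used`, `sites_alignment`, `n_hap`, `hd`, `s`, `pi`, `pi_a`,
#'   `pi_s`, `pi_ratio`, `excluded`.
#' @export
diversity_summary <- function(aln, sheet = NULL, min_n = 4L, overall = TRUE) {
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
  bind_rows(purrr::map(pops, .diversity_row))
}

.diversity_row <- function(pop) {
  n <- nrow(pop$records)
  hap <- collapse_haplotypes(pop)
  base <- tibble(
    species = pop$species, region = pop$region, site = pop$site,
    n_seq = n, sites_used = length(pop$mask),
    sites_alignment = pop$sites_alignment,
    n_hap = nrow(hap), hd = NA_real_, s = NA_integer_, pi = NA_real_,
    pi_a = NA_real_, pi_s = NA_real_, pi_ratio = NA_real_,
    excluded = pop$excluded
  )
  if (pop$excluded || n < 2) return(base)
  base$hd <- haplotype_diversity(pop)
  base$s <- segregating_sites(pop)
  base$pi <- nucleotide_diversity(pop, "JC")
  ps <- tryCatch(pi_syn_nonsyn(pop), error = function(e) NULL)
  if (!is.null(ps)) {
    base$pi_a <- ps$pi_a; base$pi_s <- ps$pi_s; base$pi_ratio <- ps$ratio
  }
  base
}
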