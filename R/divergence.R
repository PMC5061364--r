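# Weir & Cockerham (1984) theta for haploid haplotype data (mtDNA
# sequences are single alleles, so the individual-within-population
# components of the diploid estimator drop out), with a permutation test
# of individuals among populations. A distance-weighted Phi_ST variant is
# available as an option.

#' Weir-Cockerham theta from haplotype and population labels
#'
#' Multi-allelic, haploid variance-components estimator: with population
#' sizes n_i, allele frequencies p_i and weighted mean p-bar,
#' `MSP = sum n_i (p_i - pbar)^2 / (r - 1)`,
#' `MSG = sum n_i p_i (1 - p_i) / sum (n_i - 1)`,
#' `theta = sum_alleles (MSP - MSG) / sum_alleles (MSP + (n_c - 1) MSG)`
#' where `n_c = (sum n_i - sum n_i^2 / sum n_i) / (r - 1)`. Negative
#' estimates are retained (they are informative about theta ~ 0).
#'
#' @param hap Character/factor vector of haplotype labels, one per sequence.
#' @param pops Parallel vector of population labels (>= 2 populations).
#' @return theta (may be slightly negative; 1 at fixed differences).
#' @export
wc_theta <- function(hap, pops) {
  pops <- as.character(pops)
  hap <- as.character(hap)
  pl <- unique(pops)
  r <- length(pl)
  if (r < 2) abort("need at least 2 populations")
  ni <- vapply(pl, function(p) sum(pops == p), numeric(1))
  ntot <- sum(ni)
  nc <- (ntot - sum(ni^2) / ntot) / (r - 1)
  alleles <- unique(hap)
  num <- 0; den <- 0
  for (al in alleles) {
    p_i <- vapply(pl, function(p) mean(hap[pops == p] == al), numeric(1))
    pbar <- sum(ni * p_i) / ntot
    msp <- sum(ni * (p_i - pbar)^2) / (r - 1)
    msg <- sum(ni * p_i * (1 - p_i)) / sum(ni - 1)
    num <- num + (msp - msg)
    den <- den + (msp + (nc - 1) * msg)
  }
  if (den == 0) return(0)
  num / den
}

# Distance-weighted Phi_ST: AMOVA variance components with the pairwise
# difference matrix over masked sites as the (squared) distance.
phi_st <- function(dmat, pops) {
  pops <- as.character(pops)
  pl <- unique(pops)
  n <- nrow(dmat)
  ni <- vapply(pl, function(p) sum(pops == p), numeric(1))
  ntot <- sum(ni)
  r <- length(pl)
  if (r < 2) abort("need at least 2 populations")
  ssd_total <- sum(dmat[upper.tri(dmat)]) / ntot
  ssd_within <- 0
  for (p in pl) {
    idx <- which(pops == p)
    sub <- dmat[idx, idx, drop = FALSE]
    ssd_within <- ssd_within + sum(sub[upper.tri(sub)]) / length(idx)
  }
  ssd_among <- ssd_total - ssd_within
  df_among <- r - 1
  df_within <- ntot - r
  ms_within <- ssd_within / df_within
  nc <- (ntot - sum(ni^2) / ntot) / (r - 1)
  sigma_a <- (ssd_among / df_among - ms_within) / nc
  sigma_w <- ms_within
  if (sigma_a + sigma_w == 0) return(0)
  sigma_a / (sigma_a + sigma_w)
}

#' AMOVA-based F_ST between site populations
#'
#' Builds the shared complete-case site mask over all retained sequences,
#' collapses them to haplotypes, and computes the Weir-Cockerham haploid
#' theta (default) or the distance-weighted Phi_ST. Populations below the
#' estimation gate are dropped with a message recorded in the result.
#'
#' @param aln A [codon_alignment()].
#' @param sheet Sample sheet; defaults to the alignment metadata.
#' @param species Restrict to one species (default: all sequences in the
#'   sheet).
#' @param method `"frequency"` (Weir-Cockerham haplotype-frequency theta,
#'   default) or `"phi"` (distance-weighted).
#' @param min_n Per-population minimum sample size (default 4).
#' @return An `fst_result` object; see [tidy.fst_result()]. Use
#'   [permutation_test()] for a P-value.
#' @export
amova_fst <- function(aln, sheet = NULL, species = NULL,
                      method = c("frequency", "phi"), min_n = 4L) {
  method <- match.arg(method)
  if (is.null(sheet)) sheet <- aln[c("id", "species", "region", "site")]
  if (!is.null(species)) sheet <- sheet[sheet$species == species, ]
  sheet <- sheet[sheet$id %in% aln$id, ]
  sizes <- table(sheet$site)
  dropped <- names(sizes)[sizes < min_n]
  keep <- sheet[!sheet$site %in% dropped, ]
  if (length(unique(keep$site)) < 2) {
    abort(paste0("fewer than 2 populations meet the n >= ", min_n,
                 " gate (dropped: ", paste(dropped, collapse = ", "), ")"))
  }
  pop <- population_sample(aln, keep$id, min_n = min_n)
  m <- as_seq_matrix(pop)
  labels <- keep$site[match(rownames(m), keep$id)]
  hap <- apply(m, 1, paste, collapse = "")
  fst <- if (method == "frequency") {
    wc_theta(hap, labels)
  } else {
    phi_st(pairwise_diffs(m), labels)
  }
  structure(list(
    fst = fst, method = method,
    p_value = NA_real_, n_permutations = 0L,
    populations = tibble(site = names(table(labels)),
                         n = as.integer(table(labels))),
    hap = hap, labels = labels, dmat = pairwise_diffs(m),
    dropped = dropped, species = species %||% NA_character_
  ), class = "fst_result")
}

#' Permutation test for an F_ST estimate
#'
#' Permutes individuals among populations (sizes preserved) and reports
#' `p = (#(theta_perm >= theta_obs) + 1) / (reps + 1)`.
#'
#' @param fst An `fst_result` from [amova_fst()].
#' @param reps Number of permutations (default 1000; a warning flag is set
#'   below 99).
#' @param seed Optional RNG seed.
#' @return The `fst_result` with `p_value` and `n_permutations` filled in.
#' @export
permutation_test <- function(fst, reps = 1000L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (reps < 99L) warn("fewer than 99 permutations; P-value is coarse")
  stat <- function(labels) {
    if (fst$method == "frequency") wc_theta(fst$hap, labels)
    else phi_st(fst$dmat, labels)
  }
  perm <- vapply(seq_len(reps), function(r) {
    stat(sample(fst$labels))
  }, numeric(1))
  fst$p_value <- (sum(perm >= fst$fst) + 1) / (reps + 1)
  fst$n_permutations <- as.integer(reps)
  fst
}

#' @export
print.fst_result <- function(x, ...) {
  cat("<fst_result> ", x$method, " F_ST = ", signif(x$fst, 4), sep = "")
  if (!is.na(x$p_value)) {
    cat("  (P = ", signif(x$p_value, 3), ", ", x$n_permutations,
        " permutations)", sep = "")
  }
  cat("\n populations: ",
      paste0(x$populations$site, " (n=", x$populations$n, ")",
             collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Tidy an F_ST result
#'
#' @param x An `fst_result`.
#' @param ... Unused.
#' @return One-row tibble with `species`, `method`, `fst`, `p_value`,
#'   `n_permutations`, `n_populations`, `n_seq`.
#' @export
tidy.fst_result <- function(x, ...) {
  tibble(species = x$species, method = x$method, fst = x$fst,
         p_value = x$p_value, n_permutations = x$n_permutations,
         n_populations = nrow(x$populations), n_seq = sum(x$populations$n))
}

#' @rdname tidy.fst_result
#' @export
glance.fst_result <- function(x, ...) tidy(x, ...)
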