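# Two-deme isolation-with-migration machinery: simulation of
# pseudo-observed datasets, Monte-Carlo expected joint site-frequency
# spectra, composite-likelihood estimation of (N, T_div, m), and the
# fragment-count performance study.

#' Configuration for the isolation-with-migration model
#'
#' Two demes of `N` diploid individuals exchange migrants at per-generation
#' backward rates `m12`/`m21` and merge into one ancestral deme of `N_anc`
#' diploids `T_div` generations in the past. Each dataset consists of
#' `n_frag` unlinked fragments of `L` bp with mutation rate `mu` per bp per
#' generation; `n_ind` diploid individuals (2 gene copies each) are sampled
#' per deme. `rec` is carried in the configuration for provenance, but
#' intra-fragment recombination is not simulated (fragments are unlinked,
#' sites within a fragment fully linked); the joint SFS is insensitive to
#' intra-fragment linkage.
#'
#' @param N Diploid deme size (default 10000).
#' @param N_anc Ancestral diploid size (default `N`).
#' @param T_div Divergence time in generations.
#' @param m12,m21 Per-generation migration probabilities (symmetric
#'   default 1e-4, so N*m = 1 migrant per generation).
#' @param n_frag Fragments per dataset.
#' @param L Fragment length in bp (default 600).
#' @param mu Mutation rate per bp per generation (default 1e-8).
#' @param rec Recombination rate per bp per generation (recorded only).
#' @param n_ind Diploid individuals sampled per deme (default 20).
#' @param seed RNG seed (mandatory).
#' @return An `im_config` list.
#' @export
im_config <- function(N = 10000, N_anc = N, T_div = 100000, m12 = 1e-4,
                      m21 = 1e-4, n_frag = 100L, L = 600L, mu = 1e-8,
                      rec = 1e-8, n_ind = 20L, seed) {
  if (missing(seed)) abort("seed is mandatory")
  if (any(c(N, N_anc, T_div) <= 0)) abort("N, N_anc, T_div must be > 0")
  if (any(c(m12, m21, mu, rec) < 0)) abort("rates must be >= 0")
  if (n_ind < 1) abort("n_ind must be >= 1")
  structure(list(N = N, N_anc = N_anc, T_div = T_div, m12 = m12, m21 = m21,
                 n_frag = as.integer(n_frag), L = as.integer(L), mu = mu,
                 rec = rec, n_ind = as.integer(n_ind),
                 seed = as.integer(seed)),
            class = "im_config")
}

#' Number of migrants per generation implied by a configuration
#'
#' `N * m` for each direction: the expected number of (diploid) individuals
#' in a deme that immigrated in the previous generation.
#'
#' @param config An [im_config()].
#' @return Named vector `c(Nm12 = , Nm21 = )`.
#' @export
migrants_per_generation <- function(config) {
  c(Nm12 = config$N * config$m12, Nm21 = config$N * config$m21)
}

#' Fold a joint site-frequency spectrum
#'
#' Cells (i, j) and their complements (n1-i, n2-j) are pooled onto the
#' minor-allele half (total derived count <= (n1+n2)/2; exact-half cells
#' keep the canonical member of the pair).
#'
#' @param sfs Unfolded (n1+1) x (n2+1) matrix.
#' @return Folded matrix of the same shape (upper half zeroed).
#' @export
fold_sfs <- function(sfs) {
  n1 <- nrow(sfs) - 1L; n2 <- ncol(sfs) - 1L
  ntot <- n1 + n2
  out <- matrix(0, n1 + 1L, n2 + 1L)
  for (i in 0:n1) {
    for (j in 0:n2) {
      tot <- i + j
      ci <- n1 - i; cj <- n2 - j
      if (tot < ntot - tot ||
          (tot == ntot - tot && (i < ci || (i == ci && j <= cj)))) {
        out[i + 1L, j + 1L] <- sfs[i + 1L, j + 1L] + sfs[ci + 1L, cj + 1L]
        if (i == ci && j == cj) {
          out[i + 1L, j + 1L] <- sfs[i + 1L, j + 1L]
        }
      }
    }
  }
  out
}

# polymorphic-cell mask for an (n1+1) x (n2+1) SFS (fixed corners out)
.poly_mask <- function(n1, n2, folded) {
  m <- matrix(TRUE, n1 + 1L, n2 + 1L)
  m[1, 1] <- FALSE
  m[n1 + 1L, n2 + 1L] <- FALSE
  m
}

#' Simulate a pseudo-observed dataset under the IM model
#'
#' Structured coalescent with two demes merging at `T_div`, infinite-sites
#' mutation within each 600 bp fragment. Returns the joint SFS (unfolded
#' and folded); with `genotypes = TRUE` also per-fragment 0/1 haplotype
#' matrices (rows = segregating sites, columns = sampled gene copies,
#' deme 1 first).
#'
#' @param config An [im_config()].
#' @param genotypes Also return per-fragment genotype matrices.
#' @return List with `sfs` (unfolded counts), `sfs_folded`, `n_snps`,
#'   `genotypes` (or `NULL`), `config`.
#' @export
simulate_im <- function(config, genotypes = FALSE) {
  set.seed(config$seed)
  n1 <- 2L * config$n_ind; n2 <- 2L * config$n_ind
  muL <- config$mu * config$L
  if (genotypes) {
    gl <- im_genotypes_cpp(n1, n2, config$N, config$N_anc, config$T_div,
                           config$m12, config$m21, muL, config$n_frag)
    sfs <- matrix(0L, n1 + 1L, n2 + 1L)
    for (G in gl) {
      if (nrow(G) == 0) next
      d1 <- rowSums(G[, seq_len(n1), drop = FALSE])
      d2 <- rowSums(G[, n1 + seq_len(n2), drop = FALSE])
      for (k in seq_along(d1)) {
        sfs[d1[k] + 1L, d2[k] + 1L] <- sfs[d1[k] + 1L, d2[k] + 1L] + 1L
      }
    }
  } else {
    gl <- NULL
    sfs <- im_mutation_sfs_cpp(n1, n2, config$N, config$N_anc, config$T_div,
                               config$m12, config$m21, muL, config$n_frag)
  }
  mask <- .poly_mask(n1, n2, FALSE)
  list(sfs = sfs, sfs_folded = fold_sfs(sfs),
       n_snps = sum(sfs[mask]), genotypes = gl, config = config)
}

#' Monte-Carlo expected joint SFS
#'
#' Averages branch lengths per frequency configuration over `n_mc`
#' simulated fragments; the expected SFS entry for a polymorphic cell is
#' `mu * L * E[branch length subtending that configuration]`. Returned as
#' proportions over polymorphic cells plus the expected number of SNPs per
#' fragment (the absolute-scale information that identifies `N` given
#' `mu`).
#'
#' @param params List/`im_config` with `N`, `N_anc`, `T_div`, `m12`, `m21`,
#'   `mu`, `L`, `n_ind`.
#' @param n_mc Monte-Carlo fragment replicates (>= 100 recommended).
#' @param seed Optional seed (set it for common-random-number likelihood
#'   surfaces).
#' @param folded Fold the spectrum (default TRUE).
#' @return List with `prop` (proportions over polymorphic cells, floored at
#'   a small pseudo-count), `snps_per_frag`, `n_mc`, `folded`.
#' @export
expected_sfs <- function(params, n_mc = 1000L, seed = NULL, folded = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  n1 <- 2L * params$n_ind; n2 <- 2L * params$n_ind
  bl <- im_branch_sfs_cpp(n1, n2, params$N, params$N_anc %||% params$N,
                          params$T_div, params$m12, params$m21, n_mc)
  lam <- params$mu * params$L * bl / n_mc
  if (folded) lam <- fold_sfs(lam)
  mask <- .poly_mask(n1, n2, folded)
  tot <- sum(lam[mask])
  if (tot <= 0) abort("theta too small: all Monte-Carlo output monomorphic")
  prop <- lam
  prop[!mask] <- 0
  prop[mask] <- prop[mask] / tot
  # pseudo-count floor for likelihood stability
  floor_val <- 0.1 / max(n_mc, 1) / sum(mask)
  prop[mask] <- pmax(prop[mask], floor_val)
  prop[mask] <- prop[mask] / sum(prop[mask])
  list(prop = prop, snps_per_frag = tot, n_mc = n_mc, folded = folded)
}

#' Composite log-likelihood of an observed joint SFS
#'
#' Multinomial composite log-likelihood over polymorphic cells,
#' `sum obs_ij * log(prop_ij)`, optionally plus a Poisson term on the total
#' SNP count (`include_total = TRUE`, the default): with proportions alone
#' the absolute population size is unidentifiable because the coalescent is
#' scale-free in (T_div/2N, 2Nm); the total polymorphic-site count at known
#' mutation rate restores the scale.
#'
#' @param obs Observed SFS counts (same folding and shape as `expd`).
#' @param expd Expected SFS from [expected_sfs()].
#' @param n_frag Number of fragments behind `obs` (needed for the total
#'   term).
#' @param include_total Add the Poisson total-SNP term.
#' @return Composite log-likelihood (finite).
#' @export
composite_loglik <- function(obs, expd, n_frag = NULL, include_total = TRUE) {
  if (!all(dim(obs) == dim(expd$prop))) abort("SFS dimension mismatch")
  n1 <- nrow(obs) - 1L; n2 <- ncol(obs) - 1L
  mask <- .poly_mask(n1, n2, expd$folded)
  o <- obs[mask]; p <- expd$prop[mask]
  ll <- sum(o[o > 0] * log(p[o > 0]))
  if (include_total) {
    if (is.null(n_frag)) abort("n_frag needed when include_total = TRUE")
    lam_tot <- n_frag * expd$snps_per_frag
    S_tot <- sum(obs[mask])
    ll <- ll + S_tot * log(lam_tot) - lam_tot
  }
  ll
}

#' Estimate IM parameters by composite likelihood
#'
#' Coarse log10 grid over (N, T_div, m) (plus m21 under the asymmetric
#' model) followed by Nelder-Mead refinement on log10 parameters. Every
#' likelihood evaluation re-simulates the expected SFS with a common
#' random-number seed, so the surface is deterministic given `seed`.
#'
#' @param obs Observed joint SFS counts (folded if `folded`).
#' @param n_frag Fragments behind the observation.
#' @param model `"symmetric"` (m12 = m21) or `"asymmetric"`.
#' @param n_ind Diploid individuals sampled per deme.
#' @param mu,L Mutation rate and fragment length (known constants of the
#'   experiment).
#' @param bounds List of log10 bounds: `N`, `T`, `m` (each `c(lo, hi)`).
#' @param grid_points Grid resolution per axis.
#' @param n_mc_grid,n_mc_refine Monte-Carlo budgets for the grid and the
#'   refinement stages.
#' @param maxit Nelder-Mead iteration cap.
#' @param folded Use the folded spectrum.
#' @param include_total Keep the Poisson total-SNP term (see
#'   [composite_loglik()]).
#' @param seed RNG seed (mandatory; controls the common random numbers).
#' @return An `im_fit`: estimates `N_hat`, `T_hat`, `m_hat` (and `m21_hat`),
#'   `logCL`, `trace` tibble, `at_bound` flag. See [tidy.im_fit()].
#' @export
estimate_params <- function(obs, n_frag, model = c("symmetric", "asymmetric"),
                            n_ind = 20L, mu = 1e-8, L = 600L,
                            bounds = list(N = c(2, 6), T = c(2, 7),
                                          m = c(-6, -2)),
                            grid_points = 5L, n_mc_grid = 200L,
                            n_mc_refine = 600L, maxit = 60L, folded = TRUE,
                            include_total = TRUE, seed) {
  model <- match.arg(model)
  if (missing(seed)) abort("seed is mandatory")
  if (sum(obs) == 0) abort("no polymorphism: composite likelihood is flat")
  cr_seed <- seed %% 2147483647L

  par_list <- function(th) {
    # th on log10 scale: N, T, m (, m21)
    list(N = 10^th[1], N_anc = 10^th[1], T_div = 10^th[2],
         m12 = 10^th[3],
         m21 = if (model == "asymmetric") 10^th[4] else 10^th[3],
         mu = mu, L = L, n_ind = n_ind)
  }
  trace <- list()
  objective <- function(th, n_mc) {
    lo <- c(bounds$N[1], bounds$T[1], bounds$m[1],
            if (model == "asymmetric") bounds$m[1])
    hi <- c(bounds$N[2], bounds$T[2], bounds$m[2],
            if (model == "asymmetric") bounds$m[2])
    if (any(th < lo) || any(th > hi)) return(1e12)
    set.seed(cr_seed)
    e <- expected_sfs(par_list(th), n_mc = n_mc, folded = folded)
    ll <- composite_loglik(obs, e, n_frag = n_frag,
                           include_total = include_total)
    trace[[length(trace) + 1L]] <<- c(th, ll)
    -ll
  }

  gN <- seq(bounds$N[1], bounds$N[2], length.out = grid_points)
  gT <- seq(bounds$T[1], bounds$T[2], length.out = grid_points)
  gm <- seq(bounds$m[1], bounds$m[2], length.out = grid_points)
  grid <- if (model == "symmetric") {
    as.matrix(expand.grid(gN, gT, gm))
  } else {
    gma <- seq(bounds$m[1], bounds$m[2],
               length.out = max(3L, grid_points - 1L))
    as.matrix(expand.grid(gN, gT, gma, gma))
  }
  vals <- apply(grid, 1, objective, n_mc = n_mc_grid)
  best <- grid[which.min(vals), ]

  fit <- optim(best, objective, n_mc = n_mc_refine, method = "Nelder-Mead",
               control = list(maxit = maxit))
  th <- fit$par
  tol <- 0.02
  at_bound <- any(abs(th[1] - bounds$N) < tol) ||
    any(abs(th[2] - bounds$T) < tol) ||
    any(abs(th[3] - bounds$m) < tol) ||
    (model == "asymmetric" && any(abs(th[4] - bounds$m) < tol))
  tr <- do.call(rbind, trace)
  colnames(tr) <- c("log10_N", "log10_T", "log10_m",
                    if (model == "asymmetric") "log10_m21", "logCL")
  structure(list(
    N_hat = 10^th[1], T_hat = 10^th[2], m_hat = 10^th[3],
    m21_hat = if (model == "asymmetric") 10^th[4] else NULL,
    logCL = -fit$value, model = model, at_bound = at_bound,
    convergence = fit$convergence,
    trace = as_tibble(as.data.frame(tr)), seed = seed
  ), class = "im_fit")
}

#' @export
print.im_fit <- function(x, ...) {
  cat("<im_fit> ", x$model, " IM model, composite logL = ",
      signif(x$logCL, 6), "\n  N_hat = ", signif(x$N_hat, 4),
      "  T_hat = ", signif(x$T_hat, 4), "  m_hat = ", signif(x$m_hat, 4),
      sep = "")
  if (!is.null(x$m21_hat)) cat("  m21_hat =", signif(x$m21_hat, 4))
  if (x$at_bound) cat("  [estimate at search bound]")
  cat("\n")
  invisible(x)
}

#' Tidy an IM composite-likelihood fit
#'
#' @param x An `im_fit`.
#' @param ... Unused.
#' @return `tidy()`: tibble with one row per parameter (`term`,
#'   `estimate`); `glance()`: one-row fit summary.
#' @export
tidy.im_fit <- function(x, ...) {
  tibble(term = c("N", "T_div", "m12",
                  if (!is.null(x$m21_hat)) "m21"),
         estimate = c(x$N_hat, x$T_hat, x$m_hat, x$m21_hat))
}

#' @rdname tidy.im_fit
#' @export
glance.im_fit <- function(x, ...) {
  tibble(model = x$model, logCL = x$logCL, at_bound = x$at_bound,
         convergence = x$convergence, n_evals = nrow(x$trace))
}

#' Estimator performance study over fragment counts
#'
#' For each model and fragment count, simulates `n_pseudo` pseudo-observed
#' datasets at the true parameters and re-estimates (N, T_div, m) from
#' each, recording the per-dataset seeds. This is the design that shows how
#' many independent 600 bp fragments are needed before migration rate and
#' population size are recovered reliably.
#'
#' @param fragment_counts Integer vector of fragments per dataset.
#' @param models Character vector from `c("symmetric", "asymmetric")`.
#' @param T_div Divergence times (generations) to cross with the models.
#' @param n_pseudo Pseudo-observed datasets per cell (default 20).
#' @param truth Baseline [im_config()] values (N, m, mu, L, n_ind).
#' @param seed Master seed; per-dataset seeds are derived from it and
#'   recorded.
#' @param ... Passed to [estimate_params()] (budgets, bounds).
#' @return An `im_performance` tibble: one row per estimated dataset with
#'   `model`, `T_div`, `n_frag`, `pseudo`, `seed`, `N_hat`, `T_hat`,
#'   `m_hat`, `m21_hat`, `logCL`, `at_bound`, plus attribute `truth`.
#' @export
run_performance_study <- function(fragment_counts = c(10L, 100L),
                                  models = "symmetric",
                                  T_div = 100000,
                                  n_pseudo = 5L,
                                  truth = list(N = 10000, m = 1e-4,
                                               mu = 1e-8, L = 600L,
                                               n_ind = 20L),
                                  seed = 1L, ...) {
  grid <- expand.grid(model = models, T_div = T_div,
                      n_frag = fragment_counts, pseudo = seq_len(n_pseudo),
                      stringsAsFactors = FALSE)
  rows <- purrr::pmap(grid, function(model, T_div, n_frag, pseudo) {
    ds_seed <- (seed * 10007L + pseudo * 101L + n_frag +
                  as.integer(T_div %% 997)) %% 2147483647L
    cfg <- im_config(
      N = truth$N, T_div = T_div,
      m12 = if (model == "asymmetric") 0 else truth$m,
      m21 = truth$m, n_frag = n_frag, L = truth$L, mu = truth$mu,
      n_ind = truth$n_ind, seed = ds_seed)
    sim <- simulate_im(cfg)
    fit <- estimate_params(sim$sfs_folded, n_frag = n_frag, model = model,
                           n_ind = truth$n_ind, mu = truth$mu, L = truth$L,
                           seed = ds_seed + 1L, ...)
    tibble(model = model, T_div = T_div, n_frag = n_frag, pseudo = pseudo,
           seed = ds_seed, N_hat = fit$N_hat, T_hat = fit$T_hat,
           m_hat = fit$m_hat,
           m21_hat = fit$m21_hat %||% NA_real_,
           logCL = fit$logCL, at_bound = fit$at_bound)
  })
  out <- bind_rows(rows)
  attr(out, "truth") <- truth
  class(out) <- c("im_performance", class(out))
  out
}

#' Summarise a performance study
#'
#' @param object An `im_performance` tibble.
#' @param ... Unused.
#' @return Tibble of medians and IQRs per (model, T_div, n_frag) cell.
#' @export
summary.im_performance <- function(object, ...) {
  object |>
    group_by(.data$model, .data$T_div, .data$n_frag) |>
    summarise(n = dplyr::n(),
              N_med = median(.data$N_hat), N_iqr = stats::IQR(.data$N_hat),
              T_med = median(.data$T_hat), T_iqr = stats::IQR(.data$T_hat),
              m_med = median(.data$m_hat), m_iqr = stats::IQR(.data$m_hat),
              .groups = "drop")
}

#' Boxplots of re-estimated parameters by fragment count
#'
#' @param object An `im_performance` tibble.
#' @param ... Unused.
#' @return A ggplot object (log10 estimates, true values as dashed lines).
#' @export
autoplot.im_performance <- function(object, ...) {
  truth <- attr(object, "truth")
  long <- object |>
    tidyr::pivot_longer(c("N_hat", "T_hat", "m_hat"),
                        names_to = "parameter", values_to = "estimate")
  ref <- tibble(parameter = c("N_hat", "T_hat", "m_hat"),
                value = c(truth$N, unique(object$T_div)[1], truth$m))
  ggplot2::ggplot(long,
                  ggplot2::aes(factor(.data$n_frag), .data$estimate)) +
    ggplot2::geom_boxplot() +
    ggplot2::geom_hline(data = ref,
                        ggplot2::aes(yintercept = .data$value),
                        linetype = "dashed", colour = "red") +
    ggplot2::scale_y_log10() +
    ggplot2::facet_grid(.data$parameter ~ .data$model + .data$T_div,
                        scales = "free_y") +
    ggplot2::labs(x = "fragments per dataset", y = "estimate")
}
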