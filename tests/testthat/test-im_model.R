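test_that("configuration arithmetic gives one migrant per generation", {
  cfg <- im_config(seed = 1)
  expect_equal(unname(migrants_per_generation(cfg)), c(1, 1))
  expect_error(im_config(N = -1, seed = 1), "must be > 0")
  expect_error(im_config(m12 = -1e-4, seed = 1), ">= 0")
})

test_that("single-deme reduction reproduces E[S] = theta * a1", {
  # immediate merge: one deme of 2N copies; theta = 2 * 2N * mu * L
  cfg <- im_config(N = 10000, T_div = 1, n_frag = 3000, n_ind = 5, seed = 7)
  sim <- simulate_im(cfg)
  n <- 4 * cfg$n_ind
  theta <- 2 * (2 * cfg$N) * cfg$mu * cfg$L
  a1 <- sum(1 / seq_len(n - 1))
  s_mean <- sim$n_snps / cfg$n_frag
  # 3 Monte-Carlo SEs of the per-fragment S mean
  se <- sd_of_sfs_total(sim, cfg) / sqrt(cfg$n_frag)
  expect_lt(abs(s_mean - theta * a1), 3 * se)
})

test_that("panmixia gives no differentiation, isolation does", {
  cfg0 <- im_config(N = 5000, T_div = 1, n_frag = 60, n_ind = 10,
                    mu = 1e-7, seed = 21)
  f0 <- mean_fst_of(cfg0)
  cfg1 <- im_config(N = 5000, T_div = 200000, m12 = 0, m21 = 0,
                    n_frag = 60, n_ind = 10, mu = 1e-7, seed = 22)
  f1 <- mean_fst_of(cfg1)
  expect_lt(abs(f0), 0.05)
  expect_gt(f1, f0 + 0.2)
})

test_that("folding pools complementary cells and conserves the total", {
  set.seed(3)
  u <- matrix(rpois(5 * 7, 3), 5, 7)
  f <- fold_sfs(u)
  expect_equal(sum(f), sum(u))
  # folded mass sits on the minor-allele half
  n1 <- 4; n2 <- 6
  for (i in 0:n1) for (j in 0:n2) {
    if (i + j > (n1 + n2) / 2) expect_equal(f[i + 1, j + 1], 0)
  }
  # symmetric model: expected SFS is transpose-symmetric up to MC noise
  e <- expected_sfs(list(N = 5000, N_anc = 5000, T_div = 50000, m12 = 1e-3,
                         m21 = 1e-3, mu = 1e-8, L = 600, n_ind = 4),
                    n_mc = 4000, seed = 5, folded = FALSE)
  asym <- sum(abs(e$prop - t(e$prop))) / sum(e$prop)
  expect_lt(asym, 0.2)
})

test_that("fragments are exchangeable: SFS unchanged under reordering", {
  cfg <- im_config(N = 5000, T_div = 1000, n_frag = 30, n_ind = 5,
                   mu = 1e-7, seed = 31)
  sim <- simulate_im(cfg, genotypes = TRUE)
  sfs <- matrix(0L, 11, 11)              # 2 * n_ind = 10 copies per deme
  for (G in rev(sim$genotypes)) {        # reversed fragment order
    if (nrow(G) == 0) next
    d1 <- rowSums(G[, 1:10, drop = FALSE])
    d2 <- rowSums(G[, 11:20, drop = FALSE])
    for (k in seq_along(d1)) sfs[d1[k] + 1, d2[k] + 1] <-
        sfs[d1[k] + 1, d2[k] + 1] + 1L
  }
  expect_equal(sfs, unclass(sim$sfs))
})

test_that("composite likelihood obeys the Gibbs inequality", {
  set.seed(13)
  e <- expected_sfs(list(N = 8000, N_anc = 8000, T_div = 50000, m12 = 1e-4,
                         m21 = 1e-4, mu = 1e-8, L = 600, n_ind = 3),
                    n_mc = 2000, seed = 14)
  # observation exactly proportional to the expectation
  obs <- round(e$prop * 1000)
  ll_true <- composite_loglik(obs, e, n_frag = 100, include_total = FALSE)
  # any permutation of the expected proportions can only lower it
  for (r in 1:5) {
    e_perm <- e
    mask <- e$prop > 0
    e_perm$prop[mask] <- sample(e$prop[mask])
    ll_perm <- composite_loglik(obs, e_perm, n_frag = 100,
                                include_total = FALSE)
    expect_lte(ll_perm, ll_true + 1e-9)
  }
  expect_error(composite_loglik(obs[1:3, 1:3], e), "dimension mismatch")
})

test_that("composite log-likelihood matches hand arithmetic on a toy SFS", {
  # 1 diploid per deme: 3x3 SFS; hand-built expectation
  prop <- matrix(0, 3, 3)
  prop[2, 1] <- 0.5; prop[1, 2] <- 0.3; prop[2, 2] <- 0.2
  e <- list(prop = prop, snps_per_frag = 2, folded = TRUE)
  obs <- matrix(0, 3, 3)
  obs[2, 1] <- 4; obs[1, 2] <- 1
  expect_equal(
    composite_loglik(obs, e, include_total = FALSE),
    4 * log(0.5) + 1 * log(0.3))
  # Poisson total term: S_tot log(lam) - lam with lam = n_frag * 2
  expect_equal(
    composite_loglik(obs, e, n_frag = 3, include_total = TRUE),
    4 * log(0.5) + 1 * log(0.3) + 5 * log(6) - 6)
})

test_that("estimation recovers interior truth from a clean dataset", {
  cfg <- im_config(N = 10000, T_div = 1e5, n_frag = 100, seed = 11)
  sim <- simulate_im(cfg)
  fit <- estimate_params(sim$sfs_folded, n_frag = 100, model = "symmetric",
                         seed = 12)
  expect_true(fit$m_hat > 1e-4 / 3 && fit$m_hat < 3e-4)
  expect_true(fit$N_hat > 5000 && fit$N_hat < 20000)
  expect_s3_class(tidy(fit), "tbl_df")
  expect_equal(tidy(fit)$term, c("N", "T_div", "m12"))
  expect_true(is.finite(glance(fit)$logCL))

  # determinism: same seed, same estimate
  fit2 <- estimate_params(sim$sfs_folded, n_frag = 100, model = "symmetric",
                          seed = 12)
  expect_equal(fit2$m_hat, fit$m_hat)
  expect_equal(fit2$logCL, fit$logCL)
})

test_that("the asymmetric model estimates direction-specific rates", {
  cfg <- im_config(N = 10000, T_div = 1e5, m12 = 0, m21 = 1e-4,
                   n_frag = 50, seed = 31)
  sim <- simulate_im(cfg)
  fit <- estimate_params(sim$sfs_folded, n_frag = 50, model = "asymmetric",
                         n_mc_grid = 100, n_mc_refine = 300, maxit = 40,
                         seed = 32)
  expect_equal(tidy(fit)$term, c("N", "T_div", "m12", "m21"))
  expect_true(fit$N_hat > 2500 && fit$N_hat < 40000)
  # the active direction is estimated above the silent one
  expect_gt(fit$m21_hat, fit$m_hat)
})

test_that("a scaled-down performance study completes and summarises", {
  perf <- run_performance_study(fragment_counts = 10L, n_pseudo = 2L,
                                seed = 5L, grid_points = 4L,
                                n_mc_grid = 100L, n_mc_refine = 200L,
                                maxit = 20L)
  expect_equal(nrow(perf), 2L)
  expect_true(all(is.finite(perf$m_hat)))
  sm <- summary(perf)
  expect_equal(sm$n, 2L)
  expect_true(all(c("m_med", "N_med") %in% names(sm)))
  p <- autoplot(perf)
  expect_s3_class(p, "ggplot")
})
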