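# Helpers for the isolation-with-migration tests.

# Theoretical SD of per-fragment S for a single panmictic deme of 2N copies
# (no recombination): var(S) = theta*a1 + theta^2*a2.
sd_of_sfs_total <- function(sim, cfg) {
  n <- 4 * cfg$n_ind
  theta <- 2 * (2 * cfg$N) * cfg$mu * cfg$L
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  sqrt(theta * a1 + theta^2 * a2)
}

# Mean Weir-Cockerham theta over the polymorphic fragments of a simulated
# two-deme dataset (haplotype strings per fragment).
mean_fst_of <- function(cfg) {
  sim <- simulate_im(cfg, genotypes = TRUE)
  n1 <- 2 * cfg$n_ind
  pops <- rep(c("P1", "P2"), each = n1)
  vals <- vapply(sim$genotypes, function(G) {
    if (nrow(G) == 0) return(NA_real_)
    hap <- apply(G, 2, paste, collapse = "")
    if (length(unique(hap)) < 2) return(NA_real_)
    wc_theta(hap, pops)
  }, numeric(1))
  mean(vals, na.rm = TRUE)
}
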