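# fixtures and independent oracles used across the suite

# random valid count matrix
make_counts <- function(G = 20, n = 6, seed = 1, lambda = 50) {
  set.seed(seed)
  m <- matrix(rpois(G * n, lambda), G, n,
              dimnames = list(sprintf("g%03d", seq_len(G)),
                              sprintf("s%02d", seq_len(n))))
  count_matrix(m)
}

# a small balanced two-group sample layout mapped onto the package's design
# (2 "parts", 1 individual per group is not allowed, so use 2 individuals
# per species-free group via a plain design matrix where needed)
two_group_design <- function(n_per_group) {
  X <- cbind(intercept = 1,
             group = rep(c(0, 1), each = n_per_group))
  rownames(X) <- paste0("s", seq_len(2 * n_per_group))
  X
}

small_sim <- function(..., seed = 42) {
  simulate_experiment(sim_config(..., seed = seed))
}

# ---- independent oracles -------------------------------------------------

# step-up BH from its defining formula
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  sorted <- p[o]
  run <- Inf
  for (i in n:1) {
    run <- min(run, sorted[i] * n / i)
    adj[i] <- min(run, 1)
  }
  out <- numeric(n)
  out[o] <- adj
  out
}

# step-down Holm from its defining formula
holm_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  sorted <- p[o]
  adj <- numeric(n)
  run <- -Inf
  for (i in 1:n) {
    run <- max(run, (n - i + 1) * sorted[i])
    adj[i] <- min(run, 1)
  }
  out <- numeric(n)
  out[o] <- adj
  out
}

# direct evaluation of the doubly-trimmed precision-weighted TMM formula for
# one sample against a reference, written independently of the package code
# (explicit index dropping after ordering; assumes no ties in M or A)
tmm_pair_oracle <- function(obs, refc, n_obs, n_ref,
                            trim_m = 0.30, trim_a = 0.05) {
  keep <- obs > 0 & refc > 0
  o <- obs[keep]; r <- refc[keep]
  M <- log2((o / n_obs) / (r / n_ref))
  A <- 0.5 * log2((o / n_obs) * (r / n_ref))
  w <- (n_obs - o) / (n_obs * o) + (n_ref - r) / (n_ref * r)
  ng <- length(M)
  lo <- floor(ng * trim_m) + 1
  hi <- ng + 1 - lo
  keep_m <- seq_len(ng) %in% order(M)[lo:hi]
  lo_a <- floor(ng * trim_a) + 1
  hi_a <- ng + 1 - lo_a
  keep_a <- seq_len(ng) %in% order(A)[lo_a:hi_a]
  sel <- keep_m & keep_a
  2^(sum(M[sel] / w[sel]) / sum(1 / w[sel]))
}

# classical MDS by explicit double centering + eigendecomposition
cmds_oracle <- function(D, k = 2) {
  D <- as.matrix(D)
  n <- nrow(D)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (D^2) %*% J
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  e$vectors[, 1:k, drop = FALSE] %*% diag(sqrt(e$values[1:k]), k)
}

# full standard analysis chain on a simulated experiment (no normalization
# surprises: TMM + trended/squeezed dispersions)
analysis_chain <- function(sim) {
  fc <- sim$counts
  f <- tmm_factors(fc)
  off <- log(f$eff_lib_size)
  d <- build_design(sim$samples)
  disp <- estimate_dispersion(fc, d, off)
  list(counts = fc, factors = f, offsets = off, design = d,
       contrasts_within = within_species_contrasts(d),
       contrasts_interaction = interaction_contrasts(d),
       dispersions = disp)
}
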