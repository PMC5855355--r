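test_that("NB group means equal arithmetic means for a one-factor design", {
  X <- cbind(g1 = rep(c(1, 0), each = 4), g2 = rep(c(0, 1), each = 4))
  rownames(X) <- paste0("s", 1:8)
  y <- c(5, 9, 7, 3, 20, 25, 31, 18)
  for (phi in c(0, 0.1, 0.7)) {
    fit <- fit_gene(y, X, offsets = rep(0, 8), dispersion = phi)
    expect_equal(unname(exp(fit$coefficients)),
                 c(mean(y[1:4]), mean(y[5:8])), tolerance = 1e-7)
  }
})

test_that("the NB fit at phi = 0 matches an independent Poisson GLM", {
  sim <- small_sim(n_genes = 10, seed = 23)
  d <- build_design(sim$samples)
  off <- log(sim$counts$lib_sizes)
  fit <- fit_gene_models(sim$counts, d, off, dispersion = 0)
  for (g in 1:5) {
    y <- sim$counts$counts[g, ]
    oracle <- stats::glm(y ~ 0 + d$matrix + offset(off), family = poisson())
    expect_equal(unname(fit$coefficients[g, ]), unname(coef(oracle)),
                 tolerance = 1e-8)
    expect_equal(unname(fit$deviance[g]), oracle$deviance, tolerance = 1e-6)
  }
})

test_that("all-zero rows yield degenerate zero-deviance fits", {
  X <- two_group_design(3)
  y <- rbind(gz = rep(0, 6), gy = c(1, 2, 3, 9, 8, 7))
  fit <- fit_gene_models(y, X, offsets = rep(0, 6), dispersion = 0.1)
  expect_true(fit$degenerate[1])
  expect_false(fit$degenerate[2])
  expect_equal(unname(fit$deviance[1]), 0)
  expect_equal(unname(fit$fitted[1, ]), rep(0, 6))
})

test_that("constrained deviances never fall below the full fit", {
  sim <- small_sim(n_genes = 40, seed = 29, frac_part_de = 0.3)
  st <- analysis_chain(sim)
  out <- ql_f_test(st$counts, st$design, st$offsets, st$dispersions,
                   st$contrasts_within)
  expect_true(all(out$f_stat >= 0))
  one <- ql_f_test(st$counts, st$design, st$offsets, st$dispersions,
                   st$contrasts_within[, 3, drop = FALSE])
  expect_true(all(one$f_stat >= 0))
  expect_true(all(one$p_value >= 0 & one$p_value <= 1))
})

test_that("contrast estimates are equivariant to a constant offset shift", {
  sim <- small_sim(n_genes = 20, seed = 31, frac_part_de = 0.5)
  st <- analysis_chain(sim)
  r1 <- ql_f_test(st$counts, st$design, st$offsets, st$dispersions,
                  st$contrasts_within[, 1, drop = FALSE])
  r2 <- ql_f_test(st$counts, st$design, st$offsets + 2.5, st$dispersions,
                  st$contrasts_within[, 1, drop = FALSE])
  expect_equal(r1$log2fc, r2$log2fc, tolerance = 1e-6)
})

test_that("the QL F with infinite prior df and unit QL dispersion is the LRT", {
  sim <- small_sim(n_genes = 8, seed = 37)
  d <- build_design(sim$samples)
  off <- log(sim$counts$lib_sizes)
  phi <- 0.08
  disp <- structure(
    list(phi_trend = setNames(rep(phi, 8), sim$counts$gene_ids),
         s2_post = setNames(rep(1, 8), sim$counts$gene_ids),
         df_prior = Inf, df_residual = ncol(sim$counts$counts) - 20),
    class = "dispersion_model")
  cw <- within_species_contrasts(d)
  Cmat <- unclass(cw)[, 1:3]
  out <- ql_f_test(sim$counts, d, off, disp, Cmat)
  K <- svd(t(Cmat), nu = 0, nv = 20)$v[, (qr(Cmat)$rank + 1):20]
  X0 <- d$matrix %*% K
  fam <- MASS::negative.binomial(theta = 1 / phi)
  for (g in 1:4) {
    y <- sim$counts$counts[g, ]
    full <- stats::glm(y ~ 0 + d$matrix + offset(off), family = fam)
    null <- stats::glm(y ~ 0 + X0 + offset(off), family = fam)
    lrt <- null$deviance - full$deviance
    expect_equal(out$f_stat[g] * out$df1[g], lrt,
                 tolerance = 1e-6)
  }
})

test_that("gene-wise dispersion estimates recover Poisson and NB truths", {
  # Poisson counts: trended dispersion collapses towards zero
  sim0 <- simulate_experiment(sim_config(
    n_genes = 600, seed = 41, dispersion_shape = 1e-8, dispersion_rate = 1,
    frac_part_de = 0, frac_interaction = 0, individual_sd = 0))
  st0 <- analysis_chain(sim0)
  expect_lt(median(st0$dispersions$phi_trend), 0.05)
  # NB with phi = 0.1 at high counts: gene-wise estimates near truth
  sim1 <- simulate_experiment(sim_config(
    n_genes = 400, seed = 43, dispersion_shape = 1e6, dispersion_rate = 1e7,
    lib_size_range = c(3e6, 3e6), baseline_sd = 0.3,
    frac_part_de = 0, frac_interaction = 0, individual_sd = 0))
  st1 <- analysis_chain(sim1)
  expect_gt(median(st1$dispersions$phi_gene), 0.08)
  expect_lt(median(st1$dispersions$phi_gene), 0.12)
})

test_that("identical raw QL dispersions squeeze to infinite prior df", {
  sq <- squeeze_var(rep(1.3, 50), df = 40)
  expect_true(is.infinite(sq$df_prior))
  expect_equal(sq$var_post, rep(1.3, 50), tolerance = 1e-9)
  # squeezing pulls values between raw and prior
  set.seed(47)
  s2 <- rchisq(200, 10) / 10
  sq2 <- squeeze_var(s2, df = 10)
  expect_true(all((sq2$var_post - s2) * (sq2$var_post - sq2$var_prior) <= 1e-10))
})

test_that("null omnibus p-values are approximately uniform", {
  sim <- simulate_experiment(sim_config(
    n_genes = 1200, seed = 53, frac_part_de = 0, frac_interaction = 0))
  st <- analysis_chain(sim)
  out <- ql_f_test(st$counts, st$design, st$offsets, st$dispersions,
                   st$contrasts_within)
  ks <- suppressWarnings(stats::ks.test(out$p_value, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("zero or misaligned contrasts are rejected", {
  sim <- small_sim(n_genes = 5, seed = 59)
  st <- analysis_chain(sim)
  zero <- matrix(0, 20, 1, dimnames = list(colnames(st$design$matrix), "z"))
  expect_error(ql_f_test(st$counts, st$design, st$offsets, st$dispersions,
                         zero), "zero contrast")
  short <- matrix(1, 3, 1)
  expect_error(ql_f_test(st$counts, st$design, st$offsets, st$dispersions,
                         short), "match design")
})
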