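# two-group fixture whose MLE log2FC is exactly known: equal counts within
# groups make the fitted group means equal the counts themselves
exact_lfc_fixture <- function(mean_a, mean_b, n_per_group = 10, phi = 0.05) {
  X <- two_group_design(n_per_group)
  y <- rbind(g1 = rep(c(mean_a, mean_b), each = n_per_group))
  disp <- structure(
    list(phi_trend = c(g1 = phi), s2_post = c(g1 = 1), df_prior = Inf,
         df_residual = 2 * n_per_group - 2),
    class = "dispersion_model")
  contrast <- matrix(c(0, 1), 2, 1, dimnames = list(colnames(X), "grp"))
  list(y = y, X = X, off = rep(0, 2 * n_per_group), disp = disp,
       contrast = contrast)
}

test_that("threshold test p-values follow the two-boundary construction", {
  # estimate 0: deep inside the null
  fx <- exact_lfc_fixture(1000, 1000)
  p0 <- treat_test(fx$y, fx$X, fx$off, fx$disp, fx$contrast, tau_log2 = 2)
  expect_gt(p0$p_value, 0.95)
  expect_equal(p0$log2fc, 0, tolerance = 1e-8)
  # estimate exactly at the threshold with small SE: p about one half
  fx2 <- exact_lfc_fixture(5000, 20000, phi = 0.01)
  p2 <- treat_test(fx2$y, fx2$X, fx2$off, fx2$disp, fx2$contrast,
                   tau_log2 = 2)
  expect_equal(p2$log2fc, 2, tolerance = 1e-8)
  expect_equal(p2$p_value, 0.5, tolerance = 0.02)
  expect_error(treat_test(fx$y, fx$X, fx$off, fx$disp, fx$contrast,
                          tau_log2 = -1), "non-negative")
})

test_that("the threshold test at tau = 0 is the ordinary two-sided Wald test", {
  fx <- exact_lfc_fixture(900, 2100, phi = 0.08)
  tt <- treat_test(fx$y, fx$X, fx$off, fx$disp, fx$contrast, tau_log2 = 0)
  df2 <- fx$disp$df_prior + fx$disp$df_residual
  wald <- 2 * pt(abs(tt$log2fc) / tt$se_log2, df = df2, lower.tail = FALSE)
  expect_equal(tt$p_value, wald, tolerance = 1e-8)
  # and it agrees with the QL F-test closely at these counts
  qf <- ql_f_test(fx$y, fx$X, fx$off, fx$disp, fx$contrast)
  expect_equal(tt$p_value, qf$p_value, tolerance = 0.2)
  # p is monotone non-decreasing in tau
  taus <- c(0, 0.5, 1, 2, 4)
  ps <- vapply(taus, function(tau) {
    treat_test(fx$y, fx$X, fx$off, fx$disp, fx$contrast,
               tau_log2 = tau)$p_value
  }, numeric(1))
  expect_true(all(diff(ps) >= -1e-12))
})

test_that("TOST behaves correctly at the centre and boundary of equivalence", {
  # true difference zero, large counts, low dispersion: clearly equivalent
  fx <- exact_lfc_fixture(8000, 8000, phi = 0.01)
  t0 <- tost_equivalence(fx$y, fx$X, fx$off, fx$disp, fx$contrast,
                         delta_log2 = 2)
  expect_lt(t0$p_tost, 1e-6)
  # estimate exactly +delta: the upper one-sided test sits at its boundary
  fx2 <- exact_lfc_fixture(5000, 20000, phi = 0.01)
  t2 <- tost_equivalence(fx2$y, fx2$X, fx2$off, fx2$disp, fx2$contrast,
                         delta_log2 = 2)
  expect_gte(t2$p_tost, 0.5 - 0.02)
  expect_equal(t2$log2fc, 2, tolerance = 1e-8)
  expect_error(tost_equivalence(fx$y, fx$X, fx$off, fx$disp, fx$contrast,
                                delta_log2 = 0), "positive")
})

test_that("TOST p is invariant to flipping the contrast sign", {
  sim <- small_sim(n_genes = 25, seed = 79, frac_interaction = 0.4)
  st <- analysis_chain(sim)
  cvec <- st$contrasts_interaction[, 2, drop = FALSE]
  a <- tost_equivalence(st$counts, st$design, st$offsets, st$dispersions,
                        cvec)
  b <- tost_equivalence(st$counts, st$design, st$offsets, st$dispersions,
                        -cvec)
  expect_equal(a$p_tost, b$p_tost, tolerance = 1e-6)
  expect_equal(a$log2fc, -b$log2fc, tolerance = 1e-6)
})

test_that("offset-shift TOST agrees with a Wald-style TOST", {
  sim <- small_sim(n_genes = 30, seed = 83)
  st <- analysis_chain(sim)
  cvec <- st$contrasts_interaction[, 5, drop = FALSE]
  got <- tost_equivalence(st$counts, st$design, st$offsets, st$dispersions,
                          cvec, delta_log2 = 2)
  tt <- treat_test(st$counts, st$design, st$offsets, st$dispersions, cvec,
                   tau_log2 = 0)  # supplies estimate and QL SE
  df2 <- st$dispersions$df_prior + st$dispersions$df_residual
  p_up <- pt((tt$log2fc - 2) / tt$se_log2, df2)
  p_lo <- pt((tt$log2fc + 2) / tt$se_log2, df2, lower.tail = FALSE)
  wald <- pmax(p_up, p_lo)
  ok <- wald > 1e-4 & wald < 1 - 1e-4
  expect_gt(mean(abs(got$p_tost[ok] - wald[ok]) /
                   pmax(wald[ok], 0.05) < 0.10), 0.9)
})

test_that("per-contrast equivalence proportions and global flags behave", {
  P <- matrix(0, 10, 3, dimnames = list(paste0("g", 1:10), paste0("c", 1:3)))
  eq <- equivalence_per_contrast(P)
  expect_equal(eq$by_contrast$prop_equivalent, rep(1, 3))
  expect_equal(eq$mean_prop_equivalent, 1)
  glob <- equivalence_global(P)
  expect_true(all(glob$equivalent))
  # one contrast at p = 1 blocks global equivalence for that gene
  P2 <- P
  P2["g1", 2] <- 1
  glob2 <- equivalence_global(P2)
  expect_false(glob2$equivalent[glob2$gene_id == "g1"])
  P3 <- P
  P3[1, 1] <- NA
  expect_error(equivalence_global(P3), "NA")
})

test_that("equivalence power increases with the number of individuals", {
  props <- vapply(c(3, 5, 10), function(ni) {
    sim <- simulate_experiment(sim_config(
      n_genes = 80, individuals_per_species = ni, seed = 89,
      frac_part_de = 0, frac_interaction = 0, dispersion_shape = 8,
      dispersion_rate = 40))
    st <- analysis_chain(sim)
    tost <- tost_equivalence(st$counts, st$design, st$offsets,
                             st$dispersions, st$contrasts_interaction)
    equivalence_per_contrast(tost)$mean_prop_equivalent
  }, numeric(1))
  expect_true(all(diff(props) >= -0.02))
  expect_gt(props[3], props[1])
})

test_that("a gene cannot be both equivalent and beyond the threshold", {
  sim <- small_sim(n_genes = 150, seed = 97, frac_interaction = 0.15)
  st <- analysis_chain(sim)
  si <- stagewise_analysis(st$counts, st$design, st$offsets, st$dispersions,
                           st$contrasts_interaction)
  thr <- threshold_decisions(st$counts, st$design, st$offsets,
                             st$dispersions, st$contrasts_interaction, si,
                             tau_log2 = 2, alpha = 0.05)
  tost <- tost_equivalence(st$counts, st$design, st$offsets, st$dispersions,
                           st$contrasts_interaction)
  eq <- equivalence_per_contrast(tost, alpha = 0.05)
  joined <- dplyr::inner_join(
    thr[, c("gene_id", "contrast", "exceeds_threshold")],
    eq$flags[, c("gene_id", "contrast", "equivalent")],
    by = c("gene_id", "contrast"))
  expect_equal(sum(joined$exceeds_threshold & joined$equivalent), 0)
})
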