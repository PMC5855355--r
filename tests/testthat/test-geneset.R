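test_that("VIF estimation recovers independence and perfect correlation", {
  set.seed(101)
  n <- 30
  X <- two_group_design(n / 2)
  # independent genes: mean correlation near zero, VIF near one
  Y <- matrix(rnorm(50 * n), 50, n, dimnames = list(paste0("g", 1:50), NULL))
  v <- estimate_vif(Y, X, seq_len(50))
  expect_lt(abs(v$rho), 0.05)
  # one gene duplicated with tiny noise: rho -> 1, VIF -> m
  base <- rnorm(n)
  Y2 <- matrix(base, 10, n, byrow = TRUE) +
    matrix(rnorm(10 * n, sd = 1e-3), 10, n)
  rownames(Y2) <- paste0("h", 1:10)
  v2 <- estimate_vif(Y2, X, 1:10)
  expect_gt(v2$rho, 0.99)
  expect_gt(v2$vif, 9.9)
  # singleton sets carry no inflation
  v1 <- estimate_vif(Y, X, 1)
  expect_equal(v1$vif, 1)
  expect_error(estimate_vif(Y, X, integer(0)), "empty")
})

test_that("the set test with VIF 1 equals an ordinary two-sample t-test", {
  set.seed(103)
  stats <- setNames(rnorm(200), paste0("g", 1:200))
  stats[1:30] <- stats[1:30] + 0.8
  in_set <- c(rep(TRUE, 30), rep(FALSE, 170))
  got <- camera_test(stats, in_set, vif = 1)
  oracle <- t.test(stats[in_set], stats[!in_set], var.equal = TRUE)
  expect_equal(got$stat, unname(oracle$statistic), tolerance = 1e-8)
  expect_equal(got$p_value, oracle$p.value, tolerance = 1e-8)
  expect_equal(got$direction, "up")
  # identical in/out statistics: no signal, no direction
  flat <- setNames(rep(1.7, 50), paste0("g", 1:50))
  got2 <- camera_test(flat, c(rep(TRUE, 10), rep(FALSE, 40)))
  expect_equal(got2$p_value, 1)
  expect_equal(got2$direction, "none")
  expect_error(camera_test(stats, rep(TRUE, 200)), "universe")
})

test_that("the VIF correction restores calibration for correlated sets", {
  set.seed(107)
  n <- 20
  X <- two_group_design(n / 2)
  grp <- X[, "group"]
  B <- 400
  m <- 50
  G <- 300
  rej_vif <- rej_novif <- logical(B)
  for (b in seq_len(B)) {
    Y <- matrix(rnorm(G * n), G, n)
    f <- rnorm(n)
    Y[1:m, ] <- sqrt(0.1) * matrix(f, m, n, byrow = TRUE) +
      sqrt(0.9) * Y[1:m, ]
    rownames(Y) <- paste0("g", 1:G)
    tt <- apply(Y, 1, function(y) {
      t.test(y[grp == 1], y[grp == 0], var.equal = TRUE)$statistic
    })
    z <- setNames(qnorm(pt(tt, df = n - 2)), rownames(Y))
    v <- estimate_vif(Y, X, 1:m)
    in_set <- seq_len(G) %in% 1:m
    rej_vif[b] <- camera_test(z, in_set, vif = v$vif)$p_value <= 0.05
    rej_novif[b] <- camera_test(z, in_set, vif = 1)$p_value <= 0.05
  }
  expect_lt(mean(rej_vif), 0.10)
  expect_gt(mean(rej_novif), mean(rej_vif))
  expect_gt(mean(rej_novif), 0.10)
})

test_that("set results are invariant to gene order", {
  set.seed(109)
  stats <- setNames(rnorm(100), paste0("g", 1:100))
  ids <- paste0("g", c(3, 10, 44, 80, 81))
  a <- camera_test(stats, ids, vif = 1.3)
  perm <- sample(100)
  b <- camera_test(stats[perm], ids, vif = 1.3)
  expect_equal(a, b)
})

test_that("planted enrichment is detected and species relabelling is symmetric", {
  # plant a strong CE-only up-effect (8-fold) on a block of genes, in both
  # species, on top of a background with scattered part effects (so the
  # all-DE universe is larger than the set)
  sim <- simulate_experiment(sim_config(
    n_genes = 200, seed = 127, frac_part_de = 0.25, frac_interaction = 0))
  counts <- sim$counts$counts
  ce <- sim$samples$brain_part == "CE"
  idx <- 1:12
  counts[idx, ce] <- counts[idx, ce] * 8
  cm <- count_matrix(counts)
  f <- tmm_factors(cm)
  off <- log(f$eff_lib_size)
  d <- build_design(sim$samples)
  disp <- estimate_dispersion(cm, d, off)
  sw <- stagewise_analysis(cm, d, off, disp, within_species_contrasts(d))
  lcpm <- cpm(cm, factors = f, log = TRUE)
  set.seed(113)
  gs <- structure(list(GOplant = rownames(counts)[idx],
                       GOnull = sample(rownames(counts)[-idx], 30)),
                  class = "gene_set_collection")
  enr <- enrichment_workflow(sw, gs, lcpm, d)
  hit <- enr$results[enr$results$set_id == "GOplant" &
                       enr$results$part == "CE" & enr$results$tested, ]
  expect_equal(nrow(hit), 2)   # both species
  expect_true(all(hit$direction == "up"))
  expect_true(all(hit$significant))
  # relabelling the species swaps the labels and nothing else
  tab <- as_tibble(sim$samples)[, c("sample_id", "individual", "species",
                                    "brain_part")]
  tab$species <- ifelse(tab$species == "Na", "Ve", "Na")
  d2 <- build_design(sample_table(tab))
  sw2 <- stagewise_analysis(cm, d2, off, disp, within_species_contrasts(d2))
  enr2 <- enrichment_workflow(sw2, gs, lcpm, d2)
  a <- enr$results[enr$results$tested, ]
  b <- enr2$results[enr2$results$tested, ]
  b$species <- ifelse(b$species == "Na", "Ve", "Na")
  ord <- function(x) x[order(x$species, x$part, x$set_id), ]
  a <- ord(a)
  b <- ord(b)
  expect_equal(a[, c("species", "part", "set_id", "size")],
               b[, c("species", "part", "set_id", "size")])
  expect_equal(a$p_value, b$p_value, tolerance = 1e-4)
})
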