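test_that("cpm is count over effective library size per million", {
  m <- matrix(c(10, 0, 90, 100), 2, 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  cm <- count_matrix(m, lib_sizes = c(100, 1000))
  x <- cpm(cm)
  expect_equal(x["g1", "s1"], 1e5)
  expect_equal(x["g2", "s1"], 0)
  # doubling counts and library sizes leaves cpm unchanged
  cm2 <- count_matrix(2 * m, lib_sizes = 2 * c(100, 1000))
  expect_equal(cpm(cm2), cpm(cm))
  expect_error(cpm(cm, factors = c(0, 1)), "effective library")
})

test_that("low-count filter applies the >=15 cpm in >=4 samples rule", {
  # unit library sizes of 1e6 make cpm equal to the raw count
  build <- function(rows) {
    m <- do.call(rbind, rows)
    rownames(m) <- paste0("g", seq_along(rows))
    colnames(m) <- paste0("s", seq_len(ncol(m)))
    count_matrix(m, lib_sizes = rep(1e6, ncol(m)))
  }
  cm <- build(list(c(15, 15, 15, 15, 0, 0),    # exactly 15 in exactly 4
                   c(15, 15, 15, 0, 0, 0),     # only 3 samples
                   c(0, 0, 0, 0, 0, 0)))       # all zero
  mask <- filter_low_counts(cm, min_cpm = 15, min_samples = 4)
  expect_true(mask[["g1"]])
  expect_false(mask[["g2"]])
  expect_false(mask[["g3"]])
  expect_error(filter_low_counts(cm, min_samples = 7), "min_samples")
})

test_that("filter mask is monotone in the cpm threshold", {
  cm <- make_counts(G = 60, n = 8, seed = 5, lambda = 10)
  prev <- filter_low_counts(cm, min_cpm = 1, min_samples = 3)
  for (thr in c(5, 20, 100, 1000)) {
    cur <- filter_low_counts(cm, min_cpm = thr, min_samples = 3)
    expect_true(all(prev | !cur))  # raising the threshold never adds genes
    prev <- cur
  }
})

test_that("TMM factors are unity for identical or rescaled samples", {
  m <- matrix(rpois(200, 40), 100, 2,
              dimnames = list(paste0("g", 1:100), c("a", "b")))
  same <- count_matrix(cbind(a = m[, 1], b = m[, 1]))
  expect_equal(tmm_factors(same)$factor, c(1, 1))
  doubled <- count_matrix(cbind(a = m[, 1], b = 2 * m[, 1]))
  expect_equal(tmm_factors(doubled)$factor, c(1, 1))
})

test_that("TMM matches a direct evaluation of the trimmed weighted-mean formula", {
  set.seed(8)
  G <- 100
  a <- as.numeric(sample(10000:20000, G))
  b <- as.numeric(sample(30000:50000, G))
  b[1] <- 50 * a[1]   # one strongly up gene in b
  cm <- count_matrix(cbind(a = a, b = b) |>
                       `rownames<-`(paste0("g", seq_len(G))))
  # no ties in M or A for this fixture (checked so rank- and order-based
  # trimming agree)
  M <- log2((b / sum(b)) / (a / sum(a)))
  A <- 0.5 * log2((b / sum(b)) * (a / sum(a)))
  expect_false(any(duplicated(M)) || any(duplicated(A)))
  got <- tmm_factors(cm, ref = "a")
  f_b <- tmm_pair_oracle(b, a, sum(b), sum(a))
  f_a <- 1
  centred <- c(f_a, f_b) / exp(mean(log(c(f_a, f_b))))
  expect_equal(got$factor, centred, tolerance = 1e-10)
  expect_equal(attr(got, "reference"), "a")
})

test_that("TMM factors have geometric mean one and permute with samples", {
  cm <- make_counts(G = 80, n = 6, seed = 9, lambda = 30)
  f <- tmm_factors(cm)
  expect_equal(exp(mean(log(f$factor))), 1, tolerance = 1e-12)
  perm <- c(4, 1, 6, 2, 3, 5)
  cm_p <- subset_counts(cm, samples = perm)
  f_p <- tmm_factors(cm_p, ref = attr(f, "reference"))
  expect_equal(f_p$factor[match(f$sample_id, f_p$sample_id)], f$factor)
})

test_that("scaling one sample's counts is absorbed by its factor", {
  cm <- make_counts(G = 200, n = 4, seed = 10, lambda = 100)
  f1 <- tmm_factors(cm, ref = "s01")
  m2 <- cm$counts
  m2[, 3] <- m2[, 3] * 5
  f2 <- tmm_factors(count_matrix(m2), ref = "s01")
  e1 <- cpm(cm, factors = f1)
  e2 <- cpm(count_matrix(m2), factors = f2)
  expect_equal(log(e2[, 3] + 1), log(e1[, 3] + 1), tolerance = 0.02)
})

test_that("a sample with no shared positive genes is an error", {
  m <- matrix(c(5, 0, 0, 7), 2, 2,
              dimnames = list(c("g1", "g2"), c("a", "b")))
  expect_error(tmm_factors(count_matrix(m), ref = "a"), "share no positive")
})

test_that("MDS coordinates match a brute-force classical-MDS solve", {
  set.seed(11)
  lc <- matrix(rnorm(80), 20, 4, dimnames = list(NULL, paste0("s", 1:4)))
  res <- mds_coordinates(lc, top = 10, k = 2)
  oracle <- cmds_oracle(res$distance, k = 2)
  d_got <- as.matrix(dist(as.matrix(res$points[, c("dim1", "dim2")])))
  d_exp <- as.matrix(dist(oracle))
  expect_equal(unname(d_got), unname(d_exp), tolerance = 1e-8)
  expect_equal(res$distance, t(res$distance))
  expect_equal(diag(res$distance), setNames(rep(0, 4), colnames(lc)))
  expect_true(all(diff(res$var_explained) <= 1e-12))
})

test_that("duplicated samples have zero MDS distance and groups separate", {
  set.seed(12)
  lc <- matrix(rnorm(80), 20, 4,
               dimnames = list(NULL, c("a", "b", "a2", "c")))
  lc[, "a2"] <- lc[, "a"]
  res <- mds_coordinates(lc, top = 20, k = 2)
  expect_equal(res$distance["a", "a2"], 0)
  # two groups separated by a large shift on many genes
  base <- matrix(rnorm(50 * 8, sd = 0.2), 50, 8,
                 dimnames = list(NULL, paste0("s", 1:8)))
  base[1:30, 5:8] <- base[1:30, 5:8] + 4
  res2 <- mds_coordinates(base, top = 30, k = 2, selection = "common")
  s <- sign(res2$points$dim1)
  expect_true(all(s[1:4] == s[1]) && all(s[5:8] == -s[1]))
  expect_error(mds_coordinates(lc, top = 20, k = 3), "eigenvalues")
})
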