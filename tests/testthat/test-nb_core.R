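test_that("size factors: symmetry, worked median-of-ratios case, equivariance", {
  m <- matrix(c(10, 100, 10, 100), 2, 2,
              dimnames = list(c("t1", "t2"), c("a", "b")))
  expect_equal(unname(estimate_size_factors(m)), c(1, 1))

  m2 <- matrix(c(10, 100, 20, 200), 2, 2,
               dimnames = list(c("t1", "t2"), c("a", "b")))
  expect_equal(unname(estimate_size_factors(m2)), c(sqrt(0.5), sqrt(2)),
               tolerance = 1e-12)

  set.seed(1)
  m3 <- matrix(rpois(60, 50) + 1L, 10, 6,
               dimnames = list(paste0("t", 1:10), paste0("s", 1:6)))
  sf <- estimate_size_factors(m3)
  m3c <- m3
  m3c[, 3] <- m3[, 3] * 5L
  sf_c <- estimate_size_factors(m3c)
  # scaling one library rescales its factor by c relative to the others
  # (the geometric-mean reference shifts by a common c^(1/n))
  expect_equal(unname(sf_c[3] / sf_c[1]), unname(5 * sf[3] / sf[1]),
               tolerance = 1e-12)
  expect_equal(unname(sf_c[-3] / sf_c[1]), unname(sf[-3] / sf[1]),
               tolerance = 1e-12)
  # invariant to transcript permutation
  expect_equal(estimate_size_factors(m3[sample(10), ]), sf)
})

test_that("size factors agree with the reference median-of-ratios implementation", {
  set.seed(11)
  m <- matrix(rnbinom(600, mu = 80, size = 5) + 1L, 100, 6,
              dimnames = list(paste0("t", 1:100), paste0("s", 1:6)))
  ours <- estimate_size_factors(m)
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  expect_equal(unname(ours), unname(ref), tolerance = 1e-10)
})

test_that("strict mode errors without an all-positive transcript; fallback works", {
  m <- matrix(c(0L, 5L, 3L, 0L), 2, 2,
              dimnames = list(c("t1", "t2"), c("a", "b")))
  expect_error(estimate_size_factors(m), "fallback")
  expect_true(all(estimate_size_factors(m, fallback = TRUE) > 0))
})

test_that("dispersion: moments formula, zero-variance floor, Poisson limit", {
  m <- matrix(c(10, 20, 10, 20), 1, 4,
              dimnames = list("t1", paste0("s", 1:4)))
  a <- estimate_dispersions(m, rep(1, 4), c("A", "A", "B", "B"),
                            shrink = FALSE)
  # each group (10, 20): mean 15, var 50 -> alpha = 35/225
  expect_equal(as.vector(a), 35 / 225, tolerance = 1e-12)

  m0 <- matrix(rep(7L, 4), 1, 4, dimnames = list("t1", paste0("s", 1:4)))
  a0 <- estimate_dispersions(m0, rep(1, 4), c("A", "A", "B", "B"),
                             shrink = FALSE)
  expect_equal(as.vector(a0), 1e-8)

  set.seed(5)
  mp <- matrix(rpois(2000 * 8, 200), 2000, 8,
               dimnames = list(paste0("t", 1:2000), paste0("s", 1:8)))
  ap <- estimate_dispersions(mp, rep(1, 8), rep(c("A", "B"), each = 4),
                             shrink = FALSE)
  expect_lt(median(ap), 0.005)  # Poisson data: alpha ~ 0

  expect_error(estimate_dispersions(m, rep(1, 4), c("A", "A", "A", "B")),
               ">= 2")
})

test_that("Wald test: symmetry and Poisson closed-form information", {
  yi <- matrix(rep(12L, 6), 1, 6, dimnames = list("t1", paste0("s", 1:6)))
  r <- nb_wald_test(yi, rep(1, 6), 0.2, rep(c("A", "B"), each = 3))
  expect_equal(r$log2fc, 0, tolerance = 1e-10)
  expect_equal(r$stat, 0, tolerance = 1e-10)
  expect_equal(r$pvalue, 1, tolerance = 1e-10)

  yw <- matrix(c(10L, 10L, 40L, 40L), 1, 4,
               dimnames = list("t1", paste0("s", 1:4)))
  r2 <- nb_wald_test(yw, rep(1, 4), 0, c("A", "A", "B", "B"))
  expect_equal(r2$log2fc, 2, tolerance = 1e-8)
  expect_equal(r2$se * log(2), sqrt(1 / 20 + 1 / 80), tolerance = 1e-8)
  expect_equal(r2$stat, log(4) / 0.25, tolerance = 1e-7)
})

test_that("Wald MLE matches brute-force likelihood maximization on small cases", {
  set.seed(99)
  for (i in 1:25) {
    n <- 4
    groups <- c("A", "A", "B", "B")
    y <- matrix(sample(1:50, n, replace = TRUE), 1, n,
                dimnames = list("t1", paste0("s", 1:n)))
    sf <- exp(runif(n, -0.3, 0.3))
    alpha <- runif(1, 0.01, 1)
    fit <- nb_wald_test(y, sf, alpha, groups)
    oracle <- nb_mle_oracle(as.vector(y), sf, groups, alpha)
    expect_equal(fit$log2fc, unname(oracle), tolerance = 1e-4)
  }
})

test_that("all-zero and one-group-zero transcripts degrade to missing p", {
  y <- rbind(t1 = c(0L, 0L, 0L, 0L), t2 = c(0L, 0L, 25L, 30L),
             t3 = c(5L, 6L, 7L, 8L))
  colnames(y) <- paste0("s", 1:4)
  r <- nb_wald_test(y, rep(1, 4), rep(0.1, 3), c("A", "A", "B", "B"))
  expect_true(is.na(r$pvalue[1]))
  expect_true(is.na(r$pvalue[2]))  # infinite MLE flagged, not crashed
  expect_false(is.na(r$pvalue[3]))
})

test_that("BH adjustment: worked example, single p, oracle property, shape", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.5)),
               c(0.04, 0.04, 0.04, 0.5), tolerance = 1e-12)
  expect_equal(bh_adjust(0.3), 0.3)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(3)
  for (i in 1:25) {
    m <- sample(1:40, 1)
    p <- runif(m)
    p[sample(m, size = rbinom(1, m, 0.15))] <- NA
    q <- bh_adjust(p)
    expect_equal(q, bh_oracle(p), tolerance = 1e-12)
    expect_equal(q, p.adjust(p, "BH"), tolerance = 1e-12)
    obs <- !is.na(p)
    expect_true(all(q[obs] >= p[obs] - 1e-15))
    expect_true(all(q[obs] <= 1))
    ord <- order(p[obs])
    expect_true(all(diff(q[obs][ord]) >= -1e-15))
  }
})

test_that("low-count filter is monotone in its threshold", {
  set.seed(8)
  m <- matrix(rpois(50, 3), 10, 5,
              dimnames = list(paste0("t", 1:10), paste0("s", 1:5)))
  m[1, ] <- 0L
  sf <- rep(1, 5)
  expect_true(all(low_count_filter(m, sf, min_mean = 0)))
  expect_false(low_count_filter(m, sf, min_mean = 1)[1])
  k2 <- low_count_filter(m, sf, min_mean = 2)
  k1 <- low_count_filter(m, sf, min_mean = 1)
  expect_true(all(k1[k2]))  # lowering the threshold never drops a kept one
})

test_that("nb_test is deterministic and pairs padj with the filter", {
  set.seed(21)
  sim <- simulate_ripseq(small_cfg(300), seed = 4)
  sub <- sim$counts
  sel <- sub$samples$condition == "exposed"
  x <- rip_counts(sub$counts[, sub$samples$sample_id[sel]],
                  sub$samples[sel, ])
  r1 <- nb_test(x, groups = x$samples$fraction, test = "rip", ref = "input")
  r2 <- nb_test(x, groups = x$samples$fraction, test = "rip", ref = "input")
  expect_identical(r1, r2)
  expect_true(all(is.na(r1$padj) | !is.na(r1$pvalue)))
  expect_true(all(r1$padj >= r1$pvalue - 1e-15, na.rm = TRUE))
})
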