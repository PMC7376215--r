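test_that("discrimination rule: worked example with unique and ratio members", {
  exposed <- make_enriched(c("A", "B", "C"), log2(c(128, 16, 5.3)))
  control <- make_enriched(c("B", "C"), log2(c(8, 4.8)), "control")
  ind <- discriminate_induced(exposed, control, ratio_threshold = 1.5)
  expect_identical(ind$members$transcript_id, c("A", "B"))
  expect_identical(ind$members$provenance, c("unique", "ratio"))
  expect_equal(ind$members$fc_ratio[2], 2, tolerance = 1e-12)
  # C excluded: ratio 5.3/4.8 ~ 1.10
  expect_equal(ind$min_log2fc, log2(16), tolerance = 1e-12)
})

test_that("empty control makes every exposed member unique", {
  exposed <- make_enriched(c("x", "y"), c(4, 7))
  control <- make_enriched(character(0), numeric(0), "control")
  ind <- discriminate_induced(exposed, control)
  expect_identical(ind$members$transcript_id, c("x", "y"))
  expect_true(all(ind$members$provenance == "unique"))
  expect_true(all(is.na(ind$members$fc_ratio)))
  expect_equal(ind$min_log2fc, 4)
})

test_that("discrimination matches brute-force enumeration on random set pairs", {
  set.seed(17)
  universe <- sprintf("T%03d", 1:40)
  for (i in 1:60) {
    ne <- sample(0:15, 1)
    nc <- sample(0:15, 1)
    e_ids <- sort(sample(universe, ne))
    c_ids <- sort(sample(universe, nc))
    exposed <- make_enriched(e_ids, runif(ne, 1.1, 9))
    control <- make_enriched(c_ids, runif(nc, 1.1, 9), "control")
    thr <- runif(1, 0.8, 3)
    ind <- discriminate_induced(exposed, control, thr)
    oracle <- induced_oracle(exposed, control, thr)
    expect_identical(ind$members$transcript_id, oracle$transcript_id)
    expect_identical(ind$members$provenance, oracle$provenance)
  }
})

test_that("raising the ratio threshold never adds a member", {
  set.seed(2)
  exposed <- make_enriched(sprintf("t%02d", 1:20), runif(20, 1.1, 8))
  control <- make_enriched(sprintf("t%02d", 8:20), runif(13, 1.1, 8),
                           "control")
  prev <- discriminate_induced(exposed, control, 1.0)$members$transcript_id
  for (thr in c(1.5, 2, 3, 5)) {
    cur <- discriminate_induced(exposed, control, thr)$members$transcript_id
    expect_true(all(cur %in% prev))
    prev <- cur
  }
  expect_error(discriminate_induced(exposed, control, 0), "> 0")
})

test_that("overlap partitions the union with paired effect sizes", {
  a <- discriminate_induced(make_enriched(c("p", "q", "r"), c(3, 4, 5)),
                            make_enriched(character(0), numeric(0), "control"))
  b <- discriminate_induced(make_enriched(c("q", "r", "s"), c(2, 6, 7)),
                            make_enriched(character(0), numeric(0), "control"))
  ov <- overlap_conditions(a, b)
  expect_identical(ov$shared, c("q", "r"))
  expect_identical(ov$unique_a, "p")
  expect_identical(ov$unique_b, "s")
  expect_equal(length(ov$shared) + length(ov$unique_a),
               nrow(a$members))
  expect_equal(length(ov$shared) + length(ov$unique_b),
               nrow(b$members))
  expect_equal(ov$paired_log2fc$log2fc_a, c(4, 5))
  expect_equal(ov$paired_log2fc$log2fc_b, c(2, 6))

  # disjoint and identical edge cases
  ov2 <- overlap_conditions(a, a)
  expect_identical(ov2$shared, sort(a$members$transcript_id))
  expect_length(ov2$unique_a, 0)
})

test_that("profile clustering: zero-distance pair merges first, oracle heights", {
  m <- rbind(t1 = c(1, 2), t2 = c(1, 2), t3 = c(5, 9))
  co <- cluster_enrichment_profiles(m)
  expect_equal(co$height[1], 0)
  expect_setequal(co$order, rownames(m))

  set.seed(23)
  for (i in 1:15) {
    k <- sample(3:6, 1)
    x <- matrix(rnorm(k * 2), k, 2,
                dimnames = list(sprintf("g%02d", sample(99, k)), NULL))
    co <- cluster_enrichment_profiles(x)
    expect_equal(sort(co$height), avg_linkage_heights_oracle(x[order(rownames(x)), ]),
                 tolerance = 1e-10)
    # heights nondecreasing along merges (UPGMA on Euclidean data here)
    expect_true(all(diff(sort(co$height)) >= -1e-12))
    # permutation invariance of the leaf order
    perm <- sample(k)
    co2 <- cluster_enrichment_profiles(x[perm, , drop = FALSE])
    expect_identical(co2$order, co$order)
  }
})

test_that("clustering handles missing values and single transcripts", {
  m <- rbind(t1 = c(1, NA), t2 = c(1, 0), t3 = c(4, 4))
  co <- cluster_enrichment_profiles(m)
  expect_identical(co$imputed, "t1")
  expect_equal(co$height[1], 0)  # NA imputed to 0 makes t1 == t2

  single <- cluster_enrichment_profiles(rbind(only = c(1, 2)))
  expect_identical(single$order, "only")
  expect_match(attr(single, "note"), "trivial")
})
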