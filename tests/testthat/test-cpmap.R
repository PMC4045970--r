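test_that("Kosambi map function matches its closed form and inverse", {
  expect_equal(kosambi_cm(0), 0)
  expect_equal(kosambi_cm(0.10), 10.14, tolerance = 1e-3)
  expect_equal(kosambi_cm(0.25), 27.47, tolerance = 1e-3)
  expect_identical(kosambi_cm(0.5), Inf)
  expect_error(kosambi_cm(-0.1), "must be >= 0")
  r <- seq(0, 0.49, by = 0.005)
  d <- kosambi_cm(r)
  # strictly increasing, convex, and at least the Morgan-scale distance
  expect_true(all(diff(d) > 0))
  expect_true(all(diff(diff(d)) > -1e-9))
  expect_true(all(d >= 100 * r - 1e-9))
  expect_equal(kosambi_r(d), r, tolerance = 1e-12)
})

test_that("testcross two-point estimates match the closed-form examples", {
  # N = 50, R = 5
  a <- rep(c("nn", "np"), each = 25)
  b <- a; b[1:5] <- ifelse(a[1:5] == "nn", "np", "nn")
  e <- estimate_rf(a, b, "nnxnp", "nnxnp")
  expect_equal(e$r, 0.10)
  expect_equal(e$lod, 45 * log10(2 * 0.9) + 5 * log10(2 * 0.1), tolerance = 1e-9)
  expect_equal(e$lod, 7.99, tolerance = 1e-2)
  # N = 50, R = 25: independence
  b2 <- a; b2[1:25] <- ifelse(a[1:25] == "nn", "np", "nn")
  e2 <- estimate_rf(a, b2, "nnxnp", "nnxnp")
  expect_equal(e2$r, 0.5)
  expect_equal(e2$lod, 0)
  # N = 40, R = 0
  a3 <- rep(c("nn", "np"), 20)
  e3 <- estimate_rf(a3, a3, "nnxnp", "nnxnp")
  expect_equal(e3$r, 0)
  expect_equal(e3$lod, 40 * log10(2), tolerance = 1e-9)
  expect_equal(e3$lod, 12.04, tolerance = 1e-2)
})

test_that("two-point estimate is symmetric and phase-aware", {
  set.seed(11)
  p <- sim_tc_pair(51, 0.1)
  # flipping one marker's phase must not change r or lod
  flip <- ifelse(p$b == "nn", "np", "nn")
  e1 <- estimate_rf(p$a, p$b, "nnxnp", "nnxnp")
  e2 <- estimate_rf(p$a, flip, "nnxnp", "nnxnp")
  e3 <- estimate_rf(p$b, p$a, "nnxnp", "nnxnp")
  expect_equal(e1$r, e2$r)
  expect_equal(e1$lod, e2$lod)
  expect_equal(e1$r, e3$r)
  # cross-parent testcross pairs share no meioses
  mat <- rep(c("ll", "lm"), length.out = 51)
  e4 <- estimate_rf(p$a, mat, "nnxnp", "lmxll")
  expect_true(is.na(e4$r))
  expect_equal(e4$lod, 0)
})

test_that("intercross pairs are estimated by maximum likelihood", {
  set.seed(21)
  # simulate an hkxhk pair at r = 0.1 through both parents
  n <- 200; r <- 0.1
  gam <- function() {
    g1 <- sample(0:1, n, replace = TRUE)
    g2 <- (g1 + (runif(n) < r)) %% 2
    cbind(g1, g2)
  }
  f <- gam(); m <- gam()
  a <- c("hh", "hk", "kk")[f[, 1] + m[, 1] + 1]
  b <- c("hh", "hk", "kk")[f[, 2] + m[, 2] + 1]
  e <- estimate_rf(a, b, "hkxhk", "hkxhk")
  expect_lt(abs(e$r - r), 0.05)
  expect_gt(e$lod, 5)
  r_grid <- oracle_grid_r(a, b, "hkxhk", "hkxhk")
  expect_lt(abs(e$r - r_grid), 0.001)
})

test_that("grouping partitions by LOD and rf thresholds", {
  tp <- data.table::data.table(
    a = c("A", "B", "C"), b = c("B", "C", "D"),
    r = c(0.1, 0.2, 0.1), lod = c(6, 7, 2), n = 50, phase = "coupling")
  grp <- group_markers(tp, c("A", "B", "C", "D"))
  expect_equal(sort(grp$groups[[1]]), c("A", "B", "C"))
  expect_equal(grp$unlinked, "D")
  # r above threshold breaks an otherwise strong edge
  tp2 <- data.table::data.table(a = "A", b = "B", r = 0.3, lod = 10, n = 50,
                                phase = "coupling")
  grp2 <- group_markers(tp2, c("A", "B"))
  expect_equal(length(grp2$groups), 0)
  expect_equal(sort(grp2$unlinked), c("A", "B"))
})

test_that("three-marker ordering respects additivity", {
  set.seed(5)
  n <- 2000  # large n so r-hats are near truth
  a <- sample(c("nn", "np"), n, replace = TRUE)
  b <- ifelse(runif(n) < 0.05, ifelse(a == "nn", "np", "nn"), a)
  c_ <- ifelse(runif(n) < 0.05, ifelse(b == "nn", "np", "nn"), b)
  g <- make_geno(A = a, B = b, C = c_, seg_type = "nnxnp")
  tp <- two_point_table(g)
  ord <- order_group(c("A", "B", "C"), tp)
  expect_true(identical(ord, c("A", "B", "C")) ||
                identical(ord, c("C", "B", "A")))
  pos <- map_positions(ord, tp)
  expect_equal(pos$cm[1], 0)
  expect_true(all(diff(pos$cm) >= 0))
})

test_that("map positions accumulate Kosambi distances over adjacent pairs", {
  tp <- data.table::data.table(
    a = c("A", "B", "A"), b = c("B", "C", "C"),
    r = c(0.05, 0.05, 0.10), lod = c(10, 10, 8), n = 50, phase = "coupling")
  pos <- map_positions(c("A", "B", "C"), tp)
  expect_equal(pos$cm, c(0, 5.02, 10.03), tolerance = 1e-3)
  # single marker sits at zero
  expect_equal(map_positions("A", tp)$cm, 0)
  # a missing adjacent estimate falls back to the shortest path
  tp2 <- tp[1:2]
  pos2 <- map_positions(c("A", "C", "B"), tp2)  # A-C has no direct estimate
  expect_equal(pos2$cm[2], 5.02 + 5.02, tolerance = 1e-3)
})

test_that("external CP markers merge with integrity and distortion filtering", {
  set.seed(7)
  n <- 51
  base <- make_geno(m1 = rep(c("nn", "np"), length.out = n),
                    m2 = rep(c("np", "nn"), length.out = n))
  ok <- rep(c("nn", "np"), length.out = n)
  miss20 <- ok; miss20[1:11] <- "--"               # 21.6% missing
  distorted <- c(rep("nn", 45), rep("np", 6))      # ratio 7.5 > 3
  ext <- make_geno(ssr1 = ok, ssr2 = miss20, ssr3 = distorted)
  ext$info$source <- "external"
  merged <- merge_external_markers(base, ext)
  expect_equal(nrow(merged$calls), 3)              # base 2 + ssr1
  expect_true("ssr1" %in% rownames(merged$calls))
  expect_false(any(c("ssr2", "ssr3") %in% rownames(merged$calls)))
  expect_equal(merged$info$source[merged$info$marker == "ssr1"], "external")
  # empty external table is a no-op
  empty <- list(calls = base$calls[0, , drop = FALSE], info = base$info[0, ])
  expect_identical(merge_external_markers(base, empty), base)
  # mismatched progeny rejected
  ext2 <- make_geno(x = rep("nn", 10))
  expect_error(merge_external_markers(base, ext2), "progeny ids")
})

test_that("map construction is invariant to progeny relabeling", {
  tm <- sim_truth_map(n_lg = 2, markers_per_lg = 12, lg_cm = 60)
  geno <- sim_f1_genotypes(tm, n_progeny = 51, missing_rate = 0.02, seed = 9)
  map1 <- build_genetic_map(geno, "paternal")
  perm <- sample(ncol(geno$calls))
  geno2 <- cp_geno(geno$calls[, perm], geno$info)
  colnames(geno2$calls) <- colnames(geno$calls)
  map2 <- build_genetic_map(geno2, "paternal")
  expect_equal(map1$total_cm, map2$total_cm)
  expect_equal(lapply(map1$lgs, `[[`, "marker"),
               lapply(map2$lgs, `[[`, "marker"))
})
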