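test_that("pixel difference map equals the diagonal-neighbor formula", {
  expect_equal(pixel_pdf(matrix(5, 4, 4)), matrix(0, 3, 3))
  expect_equal(pixel_pdf(matrix(c(1, 0, 3, 5), 2, 2)), matrix(4, 1, 1))
  set.seed(2)
  m <- matrix(runif(30), 5, 6)
  expect_equal(pixel_pdf(t(m)), t(pixel_pdf(m))) # diagonal offset symmetry
})

test_that("region averages follow hand-computed values and invariances", {
  plane <- matrix(c(10, 30, 20, 40), 2, 2) # rows: (10,20),(30,40)
  labels <- matrix(c(1, 2, 1, 2), 2, 2)    # row 1 -> 1, row 2 -> 2
  expect_equal(region_averages(plane, labels, 2), c(15, 35))
  expect_equal(region_averages(plane, matrix(1, 2, 2), 1), 25)
  expect_error(region_averages(plane, matrix(1, 2, 2), 2), "region 2")
  # permutation within regions leaves g unchanged
  set.seed(3)
  p2 <- matrix(runif(64), 8); l2 <- matrix(rep(1:2, each = 32), 8)
  perm <- p2
  perm[l2 == 1] <- sample(p2[l2 == 1])
  expect_equal(region_averages(perm, l2, 2), region_averages(p2, l2, 2))
})

test_that("region-level summary computes pdf, gbar and dispersion", {
  s <- acica_summary(g = c(15, 35), centers = c(15, 35))
  expect_equal(s$region_pdf, 400)
  expect_equal(s$gbar, 25)
  expect_equal(s$ica, 200)
  # all-equal degenerate case
  s0 <- acica_summary(g = c(7, 7, 7), centers = c(7, 7, 7))
  expect_equal(s0$region_pdf, c(0, 0))
  expect_equal(s0$ica, 0)
  # translation invariance of the dispersion
  s1 <- acica_summary(g = c(1, 4, 9), centers = c(2, 5, 8))
  s2 <- acica_summary(g = c(1, 4, 9) + 11, centers = c(2, 5, 8) + 11)
  expect_equal(s1$ica, s2$ica)
})

test_that("fcm memberships follow the closed-form update", {
  # x = 0 against fixed centers (1, 3), m = 2: membership to center 1 is 9/10
  d <- abs(0 - c(1, 3))
  u <- (1 / d^2) / sum(1 / d^2)
  expect_equal(u[1], 9 / 10)
  fit <- fcm_cluster(c(0, 1, 3), ncluster = 2, seed = 1)
  expect_equal(rowSums(fit$memberships), rep(1, 3), tolerance = 1e-9)
})

test_that("fcm recovers two well-separated blobs across seeds", {
  for (seed in 1:5) {
    tb <- two_blob_values(seed = seed)
    fit <- fcm_cluster(tb$values, ncluster = 2, seed = seed)
    expect_lt(max(abs(fit$centers - tb$means)), 1)
    expect_true(all(diff(fit$objective_trace) <= 1e-8))
  }
})

test_that("fcm agrees with the independent e1071 implementation", {
  tb <- two_blob_values(seed = 99)
  fit <- fcm_cluster(tb$values, ncluster = 2, seed = 2)
  ref <- e1071::cmeans(matrix(tb$values), centers = 2, m = 2)
  expect_lt(max(abs(sort(fit$centers) - sort(as.vector(ref$centers)))), 0.5)
})

test_that("fcm partition is invariant under affine intensity rescaling", {
  tb <- two_blob_values(n_per = 200, seed = 4)
  a <- 3.5; b <- 120
  f1 <- fcm_cluster(tb$values, 2, tol = 1e-7, seed = 5)
  f2 <- fcm_cluster(a * tb$values + b, 2, tol = a * 1e-7, seed = 5)
  l1 <- max.col(f1$memberships, "first")
  l2 <- max.col(f2$memberships, "first")
  expect_equal(l1, l2)
})

test_that("level assignment takes the max membership with low-label ties", {
  tb <- two_blob_values(n_per = 50, seed = 6)
  fit <- fcm_cluster(tb$values, 2, seed = 6)
  lab <- assign_levels(fit, c(10, 10))
  expect_equal(dim(lab), c(10L, 10L))
  expect_gte(mean(as.vector(lab) == tb$truth), 0.99)
  # documented tie-break: equal memberships resolve to the lower label
  fake <- structure(list(ncluster = 2L, centers = c(0, 1),
                         memberships = matrix(0.5, 1, 2), m = 2,
                         objective_trace = 0, iterations = 1L),
                    class = "cluster_model")
  expect_equal(as.vector(assign_levels(fake, c(1, 1))), 1L)
  expect_error(fcm_cluster(c(1, 1, 1), 2, seed = 1), "distinct")
})

test_that("ica unmixing recovers independent sources from a known mix", {
  set.seed(10)
  n <- 10000
  s_true <- rbind(runif(n), runif(n))
  x <- matrix(c(1, 0.5, 0.5, 1), 2) %*% s_true
  m <- unmix_components(x, seed = 3)
  expect_true(m$converged)
  expect_lt(max(abs(m$unmixing %*% m$mixing - diag(2))), 1e-6)
  for (k in 1:2) {
    best <- max(abs(cor(m$sources[k, ], s_true[1, ])),
                abs(cor(m$sources[k, ], s_true[2, ])))
    expect_gt(best, 0.99)
  }
  # identity mixing: sources come back up to permutation/sign
  m0 <- unmix_components(s_true, seed = 3)
  expect_gt(max(abs(cor(m0$sources[1, ], s_true[1, ])),
                abs(cor(m0$sources[1, ], s_true[2, ]))), 0.99)
})

test_that("ica flags Gaussian-only data and rank-deficient channels", {
  set.seed(11)
  gau <- rbind(rnorm(5000), rnorm(5000))
  expect_warning(m <- unmix_components(gau, seed = 1), "unidentifiable")
  expect_false(m$identifiable)
  dep <- rbind(runif(500), runif(500))
  dep <- rbind(dep, dep[1, ] + dep[2, ]) # third channel dependent
  expect_error(unmix_components(dep, seed = 1), "rank-deficient")
})

test_that("full segmentation labels a two-tone image almost perfectly", {
  set.seed(12)
  plane <- matrix(c(rnorm(500, 20, 1), rnorm(500, 80, 1)), 25, 40)
  seg <- acica_segment(plane, ncluster = 2, seed = 7)
  truth <- matrix(c(rep(1, 500), rep(2, 500)), 25, 40)
  expect_gte(mean(seg$labels == truth), 0.99)
  expect_equal(seg$summary$g,
               region_averages(plane, seg$labels, 2))
  expect_equal(dim(seg$pdf), c(24L, 39L))
})
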