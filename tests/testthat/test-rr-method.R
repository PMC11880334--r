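test_that("quantization discards dark pixels and maps to bin centers", {
  p <- rr_params(zth = 10, dth = 16, qlevels = 8)
  plane <- matrix(c(5, 100, 5, 200), 2, 2)
  qd <- quantize_discard(plane, p)
  expect_equal(qd$discarded, plane < 10)
  expect_equal(sum(!qd$discarded), 2)
  # 8 levels over 0..255 -> 8 distinct outputs on a full ramp
  ramp <- matrix(0:255, 16, 16)
  q8 <- quantize_discard(ramp, rr_params(zth = 0, qlevels = 8))
  expect_equal(length(unique(as.vector(q8$quantized))), 8)
  # identity case
  qid <- quantize_discard(ramp, rr_params(zth = 0, qlevels = 256))
  expect_equal(qid$quantized, ramp)
  expect_false(any(qid$discarded))
  expect_error(quantize_discard(matrix(1, 2, 2), rr_params(zth = 50)),
               "empty image")
})

test_that("histogram peaks become centers; near peaks merge; unimodal gives one", {
  p <- rr_params(zth = 0, dth = 20)
  h <- integer(256)
  h[61] <- 100; h[60] <- 50; h[62] <- 50    # mode at 60
  h[181] <- 120; h[180] <- 60; h[182] <- 60 # mode at 180
  pc <- find_peak_centers(h, p)
  expect_equal(pc$centers, c(60, 180))
  # modes 100 and 110 merge under dth = 20 into a weighted position between
  # (low background bins keep the mean-count acceptance threshold below both)
  h2 <- integer(256)
  h2[101] <- 100; h2[111] <- 80
  h2[seq(10, 220, by = 11)] <- 2
  pc2 <- find_peak_centers(h2, p)
  expect_length(pc2$centers, 1)
  expect_gt(pc2$centers, 100); expect_lt(pc2$centers, 110)
  # unimodal
  h3 <- integer(256); h3[41] <- 10; h3[40] <- 3
  expect_equal(find_peak_centers(h3, p)$centers, 40)
})

test_that("center gaps stay >= dth over random histograms", {
  p <- rr_params(zth = 0, dth = 16)
  for (seed in 1:100) {
    set.seed(seed)
    h <- as.integer(rpois(256, lambda = sample(1:20, 1)))
    h[sample(256, 5)] <- sample(100:200, 5)
    pc <- find_peak_centers(h, p)
    if (length(pc$centers) > 1) expect_gte(min(diff(pc$centers)), 16)
  }
})

test_that("labeling is total, tie-breaks to the lower center, idempotent", {
  p <- rr_params(zth = 0, dth = 16, th = 1000)
  h <- integer(256); h[61] <- 10; h[181] <- 10
  pc <- find_peak_centers(h, p)
  img <- label_by_centers(matrix(c(100, 120, 60, 180), 2, 2), pc, p)
  expect_equal(img$labels[1, 1], 1L) # 100 nearer to 60
  expect_equal(img$labels[2, 1], 1L) # exact midpoint 120 -> lower center
  expect_equal(sum(img$counts), 4)
  expect_gte(min(img$labels), 1)
  # idempotence on a constant-per-region image whose values are the centers
  cplane <- matrix(c(60, 60, 180, 180), 2, 2)
  l1 <- label_by_centers(cplane, pc, p)
  back <- matrix(pc$centers[l1$labels], 2, 2)
  l2 <- label_by_centers(back, pc, p)
  expect_equal(l1$labels, l2$labels)
})

test_that("second-pass threshold raise labels far-away pixels", {
  p <- rr_params(zth = 0, dth = 16, th = 5)
  h <- integer(256); h[61] <- 10
  pc <- find_peak_centers(h, p)
  img <- label_by_centers(matrix(c(60, 255), 1, 2), pc, p)
  expect_equal(as.vector(img$labels), c(1L, 1L)) # raised th covers 255
  expect_gte(img$th_final, 195)
})

test_that("agent percentages count label shares and conserve to 100", {
  p <- rr_params(zth = 0, dth = 16, th = 1000)
  h <- integer(256); h[11] <- 10; h[201] <- 10
  pc <- find_peak_centers(h, p)
  plane <- matrix(c(rep(10, 50), rep(200, 50)), 10, 10)
  img <- label_by_centers(plane, pc, p)
  expect_equal(agent_percentage(img, 2), 50)
  expect_equal(agent_percentage(img, 1) + agent_percentage(img, 2), 100)
  expect_equal(agent_percentage(img, 1:2), 100)
  expect_error(agent_percentage(img, 3), "subset")
})

test_that("full rr segmentation is total on random phantoms", {
  for (seed in c(1, 2, 3)) {
    sp <- phantom_spec(size = c(64, 64),
                       fractions = c(superficial = 0.2, dermal = 0.15,
                                     deep = 0.1), seed = seed)
    luv <- rgb_to_luv(generate_phantom(sp)$image)
    seg <- rr_segment(luv$L / 100 * 255)
    expect_gte(min(seg$agent$labels), 1)
    expect_equal(sum(seg$percent), 100)
    expect_equal(sum(seg$agent$counts), 64 * 64)
  }
})
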