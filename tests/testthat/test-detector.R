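test_that("difference sum matches hand-computed values", {
  img <- matrix(0, 3, 3); img[2, 2] <- 255
  full <- decode_rule(511)
  noncenter <- decode_rule(511 - 16)
  expect_equal(difference_sum(img, 2, 2, noncenter), 8 * 255)
  expect_equal(difference_sum(img, 2, 2, full), 8 * 255)  # center neutral
  expect_equal(difference_sum(img, 2, 2, decode_rule(16)), 0)
  uniform <- matrix(7, 5, 5)
  expect_equal(difference_sum(uniform, 3, 3, full), 0)
  # replicate padding: corner of a uniform image sees no frame edges
  expect_equal(difference_sum(uniform, 1, 1, full), 0)
})

test_that("edge membership is the saturating ratio with the 0/0 convention", {
  expect_equal(edge_membership(0, 100), 0)
  expect_equal(edge_membership(2040, 255), 2040 / 2295)
  expect_equal(edge_membership(500, 0), 1)
  expect_equal(edge_membership(0, 0), 0)
  expect_error(edge_membership(-1, 10), "non-negative")
  # monotone in phi for delta > 0; non-increasing in delta for phi > 0
  phis <- seq(0, 3000, by = 100)
  expect_true(all(diff(edge_membership(phis, 50)) > 0))
  expect_true(all(diff(sapply(c(0, 50, 150, 255),
                              function(d) edge_membership(500, d))) < 0))
})

test_that("thresholding is strict: membership equal to tau is not an edge", {
  expect_equal(threshold_membership(0.5, 0.5), 0)
  expect_equal(threshold_membership(0.5001, 0.5), 1)
  expect_equal(threshold_membership(0, 0), 0)
  expect_equal(threshold_membership(1e-9, 0), 1)
  expect_error(threshold_membership(0.5, 1), "\\[0, 1\\)")
})

test_that("the detector marks the two columns flanking an intensity step", {
  img <- step_image(5, 5, split = 2)
  out <- apply_detector(img, detector_params(255, 0.4, 511))
  expected <- matrix(0, 5, 5); expected[, 2:3] <- 1
  expect_equal(out, expected)
})

test_that("degenerate inputs give empty edge maps", {
  uniform <- matrix(120, 6, 6)
  expect_equal(sum(apply_detector(uniform, detector_params(10, 0.1, 511))), 0)
  img <- step_image(6, 6)
  expect_equal(sum(apply_detector(img, detector_params(100, 0.2, 0))), 0)
  expect_error(apply_detector(matrix(0, 2, 5), detector_params(1, 0.1, 1)),
               "at least")
})

test_that("vectorized detector agrees exactly with the naive reference", {
  set.seed(41)
  for (rep in 1:20) {
    img <- matrix(runif(64, 0, 255), 8, 8)
    p <- random_params()
    expect_identical(apply_detector(img, p),
                     reference_detector(img, p$delta, p$tau, p$rule))
  }
})

test_that("center-bit neutrality: flipping bit 4 never changes the map", {
  set.seed(42)
  for (rep in 1:10) {
    img <- matrix(runif(100, 0, 255), 10, 10)
    p <- random_params()
    flipped <- detector_params(p$delta, p$tau, bitwXor(p$rule, 16L))
    expect_identical(apply_detector(img, p), apply_detector(img, flipped))
  }
})

test_that("edge sets shrink as tau or delta grow and grow with the mask", {
  set.seed(43)
  img <- matrix(runif(144, 0, 255), 12, 12)
  # tau-monotonicity: edges at larger tau are a subset
  for (rep in 1:5) {
    d <- sample(0:255, 1); r <- sample(1:511, 1)
    taus <- sort(runif(2, 0, 0.99))
    e_lo <- apply_detector(img, detector_params(d, taus[1], r))
    e_hi <- apply_detector(img, detector_params(d, taus[2], r))
    expect_true(all(e_hi <= e_lo))
  }
  # delta-monotonicity: edge count non-increasing in delta
  for (rep in 1:5) {
    tau <- runif(1, 0, 0.9); r <- sample(1:511, 1)
    counts <- sapply(c(0, 60, 130, 255), function(d)
      sum(apply_detector(img, detector_params(d, tau, r))))
    expect_true(all(diff(counts) <= 0))
  }
  # mask-monotonicity: submask implies subset edge set at equal delta, tau
  for (rep in 1:5) {
    full_rule <- sample(1:511, 1)
    bits <- which(as.logical(bitwAnd(full_rule, 2L^(0:8))))
    sub_rule <- sum(2L^(bits[seq_len(max(1, length(bits) - 1))] - 1L))
    d <- sample(0:255, 1); tau <- runif(1, 0, 0.9)
    e_sub <- apply_detector(img, detector_params(d, tau, sub_rule))
    e_full <- apply_detector(img, detector_params(d, tau, full_rule))
    expect_true(all(e_sub <= e_full))
  }
})
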