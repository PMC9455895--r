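# Synthetic dynamics generators: determinism, marginals, and each
# regime's designed information signature.

test_that("every generator is a pure function of its arguments and seed", {
  gens <- list(
    function(s) gen_iid(n_rois = 3, T = 40, seed = s),
    function(s) gen_oscillator(n_rois = 3, T = 40, seed = s),
    function(s) gen_coupled_chain(n_rois = 3, T = 40, seed = s),
    function(s) gen_common_driver(T = 40, seed = s),
    function(s) gen_bleaching(n_rois = 3, T = 40, seed = s),
    function(s) gen_two_channel_model(n_rois = 3, T = 40, seed = s)
  )
  for (g in gens) {
    expect_identical(g(7), g(7))
    expect_false(identical(g(7), g(8)))
  }
})

test_that("iid marginals and entropy match their configured targets at large T", {
  tr <- gen_iid(n_rois = 2, T = 10000, q = 0.5, seed = 30)
  af <- active_fraction(tr)$active_fraction
  expect_true(all(abs(af - 0.5) < 3 * sqrt(0.25 / 10000)))
  ent <- roi_metrics(tr, "entropy")$value_bits
  expect_true(all(abs(ent - 1) < 0.01))

  tr3 <- gen_iid(n_rois = 2, T = 10000, q = 0.3, seed = 31)
  af3 <- active_fraction(tr3)$active_fraction
  expect_true(all(abs(af3 - 0.3) < 3 * sqrt(0.3 * 0.7 / 10000)))
})

test_that("independent traces show only plug-in bias in MI", {
  mis <- vapply(1:200, function(s) {
    tr <- gen_iid(n_rois = 2, T = 600, seed = s)
    mutual_information(
      tr$state[tr$roi == "r1"], tr$state[tr$roi == "r2"]
    )
  }, numeric(1))
  expect_lt(mean(mis), 0.02)
})

test_that("shuffled sources transfer no information as T grows", {
  tes <- vapply(1:200, function(s) {
    tr <- gen_iid(n_rois = 2, T = 600, seed = 1000 + s)
    src <- shuffle_surrogate(tr$state[tr$roi == "r1"], seed = s)
    transfer_entropy(src, tr$state[tr$roi == "r2"], 1, 1)
  }, numeric(1))
  expect_lt(mean(tes), 0.02)
})

test_that("noiseless period-2 oscillators have unit AIS; full noise erases it", {
  tr <- gen_oscillator(n_rois = 1, T = 61, period = 2, noise_p = 0, seed = 32)
  expect_equal(
    active_information_storage(tr$state, 1), 1
  )
  # noise_p = 0.5 is indistinguishable from iid at matched length
  ais_noisy <- vapply(1:100, function(s) {
    tr <- gen_oscillator(n_rois = 1, T = 200, period = 2, noise_p = 0.5, seed = s)
    active_information_storage(tr$state, 1)
  }, numeric(1))
  ais_iid <- vapply(1:100, function(s) {
    tr <- gen_iid(n_rois = 1, T = 200, seed = 5000 + s)
    active_information_storage(tr$state, 1)
  }, numeric(1))
  expect_gt(rank_sum_compare(ais_noisy, ais_iid)$p_value, 0.05)
})

test_that("in-phase oscillators produce the delayed-MI false positive", {
  tr <- gen_oscillator(
    n_rois = 2, T = 61, period = 2, noise_p = 0, phase = c(0, 0), seed = 33
  )
  x <- tr$state[tr$roi == "r1"]
  y <- tr$state[tr$roi == "r2"]
  expect_equal(delayed_mutual_information(x, y, 1), 1)
  expect_equal(transfer_entropy(x, y, 1, 1), 0, tolerance = 1e-12)
  expect_equal(transfer_entropy(y, x, 1, 1), 0, tolerance = 1e-12)
})

test_that("coupled chain: perfect coupling saturates forward TE, zero coupling decouples", {
  tr <- gen_coupled_chain(n_rois = 2, T = 2000, coupling_eps = 1, seed = 34)
  x <- tr$state[tr$roi == "r1"]
  y <- tr$state[tr$roi == "r2"]
  expect_gt(transfer_entropy(x, y, 1, 1), 0.95)
  expect_lt(transfer_entropy(y, x, 1, 1), 0.01)
  expect_equal(transfer_entropy(x, y, 1, 1), oracle_te(x, y, 1, 1), tolerance = 1e-12)

  tr0 <- gen_coupled_chain(n_rois = 2, T = 2000, coupling_eps = 0, seed = 35)
  mi0 <- mutual_information(
    tr0$state[tr0$roi == "r1"], tr0$state[tr0$roi == "r2"]
  )
  expect_lt(mi0, 0.01)
})

test_that("common driver: copies correlate maximally but transfer nothing", {
  tr <- gen_common_driver(T = 600, noise_p = 0, seed = 36)
  x <- tr$state[tr$roi == "r1"]
  y <- tr$state[tr$roi == "r2"]
  expect_identical(x, y)
  expect_equal(mutual_information(x, y), shannon_information(x))
  expect_equal(transfer_entropy(x, y, 1, 1), 0, tolerance = 1e-12)
  expect_equal(transfer_entropy(y, x, 1, 1), 0, tolerance = 1e-12)

  # the oscillator driver realizes exactly 1 bit on even-length series
  tro <- gen_common_driver(T = 60, noise_p = 0, driver = "oscillator", seed = 37)
  expect_equal(
    mutual_information(
      tro$state[tro$roi == "r1"], tro$state[tro$roi == "r2"]
    ), 1
  )

  # full noise decouples the copies
  trn <- gen_common_driver(T = 2000, noise_p = 0.5, seed = 38)
  expect_lt(
    mutual_information(
      trn$state[trn$roi == "r1"], trn$state[trn$roi == "r2"]
    ), 0.01
  )
})

test_that("bleaching decay is shared and monotone in expectation", {
  tr <- gen_bleaching(n_rois = 3, T = 60, drift_rate = 0.05, noise_sd = 0, seed = 39)
  for (lb in unique(tr$roi)) {
    v <- tr$intensity[tr$roi == lb]
    expect_true(all(diff(v) <= 0))
  }
  # zero drift leaves pure noise around the baseline
  tr0 <- gen_bleaching(n_rois = 2, T = 60, drift_rate = 0, seed = 40)
  expect_gt(min(tr0$intensity), 50)
})

test_that("two-channel model records its generative couplings", {
  tr <- gen_two_channel_model(n_rois = 3, T = 60, seed = 41)
  gt <- attr(tr, "ground_truth")
  expect_true(all(c("source", "target", "mechanism", "strength") %in% names(gt)))
  expect_true("r1@actin" %in% gt$source)
  expect_true("r2@calcium" %in% gt$target)
  expect_setequal(unique(tr$channel), c("actin", "calcium"))
})

test_that("two-channel model: the persistent channel stores more information", {
  wins <- vapply(1:50, function(s) {
    tr <- gen_two_channel_model(n_rois = 3, T = 600, seed = s)
    ais <- roi_metrics(tr, "ais")
    mean(ais$value_bits[ais$channel == "actin"]) >
      mean(ais$value_bits[ais$channel == "calcium"])
  }, logical(1))
  expect_gte(mean(wins), 0.9)
})
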