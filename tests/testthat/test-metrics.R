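# Plug-in estimators against closed forms and the brute-force
# joint-count oracles.

test_that("Shannon information matches the binary entropy function", {
  # reporters active 10%, 90%, 50% of the time
  expect_equal(shannon_information(c(rep(1, 1), rep(0, 9))), 0.47, tolerance = 0.005)
  expect_equal(shannon_information(c(rep(1, 9), rep(0, 1))), 0.47, tolerance = 0.005)
  expect_equal(shannon_information(rep(c(0, 1), 5)), 1)
  expect_equal(shannon_information(rep(0, 10)), 0)
  # closed form at arbitrary active fractions
  for (ones in 1:9) {
    x <- c(rep(1L, ones), rep(0L, 10 - ones))
    p <- ones / 10
    expect_equal(
      shannon_information(x), -(p * log2(p) + (1 - p) * log2(1 - p)),
      tolerance = 1e-12
    )
  }
})

test_that("mutual information: factorizing joint gives 0, bijection gives 1, self gives entropy", {
  expect_equal(mutual_information(c(0, 0, 1, 1), c(0, 1, 0, 1)), 0)
  expect_equal(mutual_information(c(0, 1, 0, 1), c(1, 0, 1, 0)), 1)
  withr::with_seed(11, {
    for (i in 1:20) {
      x <- rand_bin(40, runif(1, 0.2, 0.8))
      expect_equal(mutual_information(x, x), shannon_information(x), tolerance = 1e-12)
    }
  })
  expect_error(mutual_information(c(0, 1), c(0, 1, 0)), "lengths differ")
})

test_that("delayed MI reduces to MI at lag 0 and matches shift identities", {
  withr::with_seed(21, {
    x <- rand_bin(60)
    y <- rand_bin(60)
    expect_identical(
      delayed_mutual_information(x, y, 0),
      mutual_information(x, y)
    )
  })
  # y = x shifted by one frame: DMI(lag 1) = plug-in entropy of x[1..T-1]
  x <- c(0L, 1L, 1L, 0L, 1L, 0L, 0L, 1L, 0L)
  y <- c(0L, x[1:8])
  expect_equal(
    delayed_mutual_information(x, y, 1),
    oracle_entropy(x[1:8]),
    tolerance = 1e-12
  )
  expect_equal(delayed_mutual_information(x, y, 1), oracle_dmi(x, y, 1), tolerance = 1e-12)
  # two in-phase strictly alternating series: 1 bit at lag 1 despite no coupling
  a <- rep(c(0L, 1L), length.out = 9)
  expect_equal(delayed_mutual_information(a, a, 1), 1, tolerance = 1e-12)
  expect_error(delayed_mutual_information(x, y, 9), "lag")
})

test_that("AIS: periodic signals store information, constant signals store none", {
  expect_equal(
    suppressWarnings(active_information_storage(rep(c(0L, 1L), length.out = 9), 1)), 1
  )
  expect_equal(suppressWarnings(
    active_information_storage(rep(0L, 20), 1)
  ), 0)
  # period-4 word: longer history can only add information
  w <- rep(c(0L, 0L, 1L, 1L), 4)
  a1 <- active_information_storage(w, 1)
  a2 <- suppressWarnings(active_information_storage(w, 2))
  expect_gte(a2, a1)
  expect_equal(a1, oracle_ais(w, 1), tolerance = 1e-12)
  expect_equal(a2, oracle_ais(w, 2), tolerance = 1e-12)
  expect_error(active_information_storage(c(0L, 1L), 1), "too short")
})

test_that("TE is zero for self-predictable targets and hidden common drivers", {
  alt <- rep(c(0L, 1L), 30)
  withr::with_seed(31, {
    src <- rand_bin(60)
    expect_equal(transfer_entropy(src, alt, 1, 1), 0, tolerance = 1e-12)
  })
  # both traces copies of one hidden alternating driver: DMI fires, TE is silent
  expect_equal(transfer_entropy(alt, alt, 1, 1), 0, tolerance = 1e-12)
  expect_equal(delayed_mutual_information(alt, alt, 1), 1, tolerance = 0.01)
})

test_that("TE recovers a deterministic lag-1 copy from a balanced source word", {
  # de Bruijn-style period-4 source makes source[t] empirically
  # independent of the target's own 1-history
  source <- rep(c(0L, 0L, 1L, 1L), 4)
  target <- c(0L, source[1:15])
  te <- suppressWarnings(transfer_entropy(source, target, 1, 1))
  expect_equal(te, oracle_te(source, target, 1, 1), tolerance = 1e-12)
  expect_gt(te, 0.9)
})

test_that("effective information: permutation maps, constant maps, noisy flip matrix", {
  expect_equal(effective_information(diag(4)), 2)
  expect_equal(
    effective_information(matrix(c(0.3, 0.7, 0.3, 0.7), 2, byrow = TRUE)), 0
  )
  m <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, byrow = TRUE)
  closed_form <- 1 + 0.9 * log2(0.9) + 0.1 * log2(0.1)
  expect_equal(effective_information(m), closed_form, tolerance = 1e-12)
  # Monte-Carlo interventional sampler as independent cross-check
  expect_equal(effective_information(m), oracle_ei_mc(m), tolerance = 0.01)
  expect_error(effective_information(matrix(c(0.5, 0.4, 0.1, 0.9), 2, byrow = TRUE)),
               "row-stochastic")
  # non-uniform intervention: degenerate point mass gives zero
  expect_equal(effective_information(m, intervention = c(1, 0)), 0)
})

test_that("effective information is invariant under simultaneous row/column permutation", {
  withr::with_seed(41, {
    for (i in 1:10) {
      n <- sample(2:5, 1)
      m <- matrix(runif(n * n), n)
      m <- m / rowSums(m)
      perm <- sample.int(n)
      expect_equal(
        effective_information(m),
        effective_information(m[perm, perm]),
        tolerance = 1e-12
      )
    }
  })
})

test_that("metric bounds hold on random series", {
  withr::with_seed(51, {
    for (i in 1:50) {
      T <- sample(20:80, 1)
      x <- rand_bin(T, runif(1, 0.1, 0.9))
      y <- rand_bin(T, runif(1, 0.1, 0.9))
      mi <- mutual_information(x, y)
      expect_gte(mi, -1e-12)
      expect_lte(mi, min(shannon_information(x), shannon_information(y)) + 1e-12)
      expect_identical(mi, mutual_information(y, x))
      ais <- suppressWarnings(active_information_storage(x, 1))
      expect_gte(ais, -1e-12)
      expect_lte(ais, oracle_entropy(x[2:T]) + 1e-12)
      te <- suppressWarnings(transfer_entropy(y, x, 1, 1))
      expect_gte(te, -1e-12)
      # TE cannot exceed what is left unexplained by the target's own history
      cond_h <- oracle_entropy(x[2:T]) - ais
      expect_lte(te, cond_h + 1e-12)
      # AIS(x, 1) = DMI of x with itself at lag 1
      expect_equal(ais, delayed_mutual_information(x, x, 1), tolerance = 1e-12)
    }
  })
})

test_that("roi_metrics computes per-trace entropy and AIS on tidy tables", {
  traces <- gen_iid(n_rois = 3, T = 40, seed = 5)
  ent <- roi_metrics(traces, "entropy")
  expect_equal(nrow(ent), 3)
  expect_true(all(ent$metric == "entropy"))
  s1 <- traces$state[traces$roi == "r1"]
  expect_equal(ent$value_bits[ent$roi == "r1"], shannon_information(s1))
  ais <- roi_metrics(traces, "ais", k = 1)
  expect_equal(
    ais$value_bits[ais$roi == "r1"],
    active_information_storage(s1, 1)
  )
})

test_that("binary input is validated", {
  expect_error(shannon_information(c(0, 2)), "0 and 1")
  expect_error(shannon_information(integer(0)), "non-empty")
  expect_error(mutual_information(c(0, NA), c(0, 1)), "0 and 1")
})
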