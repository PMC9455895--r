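# Seeded generators of multi-ROI binary/intensity dynamics. Each generator
# is a pure function of its arguments and seed, and realizes one
# qualitative regime against which the estimators are validated: an
# independent null, intrinsic oscillators (delayed-MI false positives),
# lagged coupled chains (true directed flow), hidden common drivers
# (correlation without causation), shared photobleaching drift (an MI
# artifact), and a gated two-channel mechanism (persistent "actin-like"
# channel gating flow in a coupled "calcium-like" channel).
#
# Defaults mirror the reference acquisition: 9 ROIs per specimen and 60
# frames at one frame per minute.

.roi_labels <- function(n) sprintf("r%d", seq_len(n))

# T x n 0/1 (or intensity) matrix -> tidy trace table
.mat_to_tbl <- function(mat, channel, value = c("state", "intensity")) {
  value <- match.arg(value)
  labels <- .roi_labels(ncol(mat))
  out <- tibble(
    roi = rep(labels, each = nrow(mat)),
    channel = channel,
    frame = rep(seq_len(nrow(mat)), times = ncol(mat))
  )
  out[[value]] <- as.vector(mat)
  out
}

.flip <- function(x, p) {
  if (p <= 0) return(x)
  flips <- runif(length(x)) < p
  as.integer(xor(x == 1L, flips))
}

#' Independent Bernoulli traces (null regime)
#'
#' Each ROI is an i.i.d. Bernoulli(`q`) state sequence, independent of
#' every other ROI: the no-structure null against which estimator bias
#' and false-positive rates are calibrated.
#'
#' @param n_rois Number of ROIs.
#' @param T Number of frames.
#' @param q Per-frame activation probability.
#' @param seed Integer seed.
#' @param channel Channel name on the output.
#' @return Tidy binary table (`roi`, `channel`, `frame`, `state`).
#' @export
gen_iid <- function(n_rois = 9L, T = 60L, q = 0.5, seed = 1L,
                    channel = "calcium") {
  withr::with_seed(as.integer(seed), {
    mat <- matrix(as.integer(runif(T * n_rois) < q), nrow = T)
    .mat_to_tbl(mat, channel)
  })
}

#' Independent square-wave oscillators
#'
#' Each ROI is a deterministic square wave of the given period (half on,
#' half off) with an independent random phase, corrupted by per-frame
#' flip noise. In-phase noiseless oscillators are the canonical
#' delayed-MI false positive: maximal lagged correlation with zero
#' transfer entropy.
#'
#' @inheritParams gen_iid
#' @param period Oscillation period in frames (>= 2).
#' @param noise_p Per-frame state-flip probability in `[0, 0.5]`.
#' @param phase Optional integer vector of phases (one per ROI, in
#'   `0..period-1`); default independent uniform phases. `phase = 0` for
#'   all ROIs gives in-phase oscillators.
#' @export
gen_oscillator <- function(n_rois = 9L, T = 60L, period = 6L,
                           noise_p = 0.05, phase = NULL, seed = 1L,
                           channel = "calcium") {
  period <- as.integer(period)
  if (period < 2L) abort("`period` must be >= 2.")
  withr::with_seed(as.integer(seed), {
    ph <- phase %||% sample.int(period, n_rois, replace = TRUE) - 1L
    ph <- rep_len(as.integer(ph), n_rois)
    mat <- sapply(seq_len(n_rois), function(j) {
      wave <- as.integer(((seq_len(T) - 1L + ph[j]) %% period) < period / 2)
      .flip(wave, noise_p)
    })
    .mat_to_tbl(matrix(mat, nrow = T), channel)
  })
}

#' Lagged coupled chain (true directed flow)
#'
#' ROI 1 is i.i.d. Bernoulli(0.5); each subsequent ROI copies its
#' predecessor with a one-frame lag, each copied bit flipped with
#' probability `(1 - coupling_eps) / 2`. At `coupling_eps = 1` the copy
#' is perfect; at `coupling_eps = 0` the chain degenerates to
#' independent noise. Ground truth: information flows forward along the
#' chain only.
#'
#' @inheritParams gen_iid
#' @param coupling_eps Coupling strength in `[0, 1]`.
#' @export
gen_coupled_chain <- function(n_rois = 9L, T = 60L, coupling_eps = 0.8,
                              seed = 1L, channel = "calcium") {
  if (coupling_eps < 0 || coupling_eps > 1) abort("`coupling_eps` must be in [0, 1].")
  flip_p <- (1 - coupling_eps) / 2
  withr::with_seed(as.integer(seed), {
    mat <- matrix(0L, nrow = T, ncol = n_rois)
    mat[, 1] <- as.integer(runif(T) < 0.5)
    for (j in seq_len(n_rois)[-1]) {
      mat[1, j] <- as.integer(runif(1) < 0.5)
      mat[2:T, j] <- .flip(mat[1:(T - 1), j - 1], flip_p)
    }
    .mat_to_tbl(mat, channel)
  })
}

#' Hidden common driver (correlation without causation)
#'
#' A latent driver sequence (not emitted) is copied, at equal lag, by
#' every observed ROI, each copy corrupted by independent flip noise.
#' Noiseless copies are identical: maximal MI with zero transfer entropy
#' in both directions, the textbook confound for correlational metrics.
#'
#' @inheritParams gen_iid
#' @param n_rois Number of observed copies (default 2).
#' @param noise_p Independent per-copy flip probability.
#' @param driver `"bernoulli"` (latent i.i.d. Bernoulli(0.5)) or
#'   `"oscillator"` (latent deterministic period-2 wave, which makes the
#'   noiseless regime exactly balanced and hence exactly 1 bit of MI on
#'   even-length series).
#' @export
gen_common_driver <- function(n_rois = 2L, T = 60L, noise_p = 0.1,
                              driver = c("bernoulli", "oscillator"),
                              seed = 1L, channel = "calcium") {
  driver <- rlang::arg_match(driver)
  withr::with_seed(as.integer(seed), {
    d <- switch(driver,
      bernoulli = as.integer(runif(T) < 0.5),
      oscillator = as.integer(seq_len(T) %% 2L)
    )
    mat <- sapply(seq_len(n_rois), function(j) .flip(d, noise_p))
    .mat_to_tbl(matrix(mat, nrow = T), channel)
  })
}

#' Shared photobleaching drift (intensity-level MI artifact)
#'
#' Independent Gaussian noise traces superimposed on a shared monotone
#' exponential decay of rate `drift_rate` per frame. After mean
#' thresholding, the shared early-high/late-low structure inflates
#' pairwise MI far above the shuffle null even though the ROIs never
#' exchange information — the classic photobleaching artifact. At
#' `drift_rate = 0` the traces are pure independent noise.
#'
#' @inheritParams gen_iid
#' @param drift_rate Exponential decay rate per frame (>= 0).
#' @param baseline Initial intensity of the shared decay component.
#' @param noise_sd Standard deviation of the per-ROI Gaussian noise.
#' @return Tidy intensity table (`roi`, `channel`, `frame`,
#'   `intensity`) — feed through [binarize()] before computing metrics.
#' @export
gen_bleaching <- function(n_rois = 9L, T = 60L, drift_rate = 0.05,
                          baseline = 100, noise_sd = 5, seed = 1L,
                          channel = "calcium") {
  if (drift_rate < 0) abort("`drift_rate` must be >= 0.")
  withr::with_seed(as.integer(seed), {
    decay <- baseline * exp(-drift_rate * (seq_len(T) - 1))
    mat <- sapply(seq_len(n_rois), function(j) decay + rnorm(T, sd = noise_sd))
    .mat_to_tbl(matrix(mat, nrow = T), channel, value = "intensity")
  })
}

#' Gated two-channel mechanism (persistent channel gates a coupled one)
#'
#' A stylized mechanism for validating cross-channel inference, not a
#' biophysical model. Channel A ("actin"-like) is, per ROI, an
#' independent symmetric two-state Markov chain with high self-transition
#' probability `a_stay`: slow, persistent pulsing with high active
#' information storage. Channel B ("calcium"-like) at each frame copies,
#' with probability `w_a`, its own ROI's previous A state; otherwise,
#' with probability `coupling` and only when the local A gate was open
#' (A = 1), it copies the previous B state of the neighboring ROI;
#' otherwise it flips a fair coin. Ground truth: directed flow along B
#' (gated by A), directed A-to-B influence within each ROI, no influence
#' into A, and no direct coupling within channel A.
#'
#' @inheritParams gen_iid
#' @param a_stay Self-transition probability of the A chains (> 0.5 for
#'   persistence).
#' @param w_a Probability that B copies its ROI's previous A state.
#' @param coupling Probability (given the A gate open and the coin not
#'   already resolved by `w_a`) that B copies the neighboring ROI's
#'   previous B state; requires `w_a + coupling <= 1`.
#' @return Tidy binary table with channels `"actin"` (A) and `"calcium"`
#'   (B); attribute `ground_truth` lists the generative couplings.
#' @export
gen_two_channel_model <- function(n_rois = 9L, T = 60L, a_stay = 0.9,
                                  w_a = 0.3, coupling = 0.6, seed = 1L) {
  if (a_stay < 0.5 || a_stay > 1) abort("`a_stay` must be in [0.5, 1].")
  if (w_a < 0 || coupling < 0 || w_a + coupling > 1) {
    abort("Need w_a >= 0, coupling >= 0, and w_a + coupling <= 1.")
  }
  withr::with_seed(as.integer(seed), {
    A <- matrix(0L, nrow = T, ncol = n_rois)
    B <- matrix(0L, nrow = T, ncol = n_rois)
    A[1, ] <- as.integer(runif(n_rois) < 0.5)
    B[1, ] <- as.integer(runif(n_rois) < 0.5)
    for (t in 2:T) {
      stay <- runif(n_rois) < a_stay
      A[t, ] <- ifelse(stay, A[t - 1, ], 1L - A[t - 1, ])
      u <- runif(n_rois)
      coin <- as.integer(runif(n_rois) < 0.5)
      for (j in seq_len(n_rois)) {
        if (u[j] < w_a) {
          B[t, j] <- A[t - 1, j]
        } else if (j > 1L && A[t - 1, j] == 1L && u[j] < w_a + coupling) {
          B[t, j] <- B[t - 1, j - 1]
        } else {
          B[t, j] <- coin[j]
        }
      }
    }
    out <- dplyr::bind_rows(
      .mat_to_tbl(A, "actin"),
      .mat_to_tbl(B, "calcium")
    )
    labels <- .roi_labels(n_rois)
    gt <- dplyr::bind_rows(
      tibble(
        source = paste0(labels, "@actin"), target = paste0(labels, "@calcium"),
        mechanism = "within-ROI A drives B", strength = w_a
      ),
      if (n_rois > 1L) tibble(
        source = paste0(labels[-n_rois], "@calcium"),
        target = paste0(labels[-1], "@calcium"),
        mechanism = "lag-1 neighbor coupling in B, gated by A",
        strength = coupling
      )
    )
    attr(out, "ground_truth") <- gt
    out
  })
}
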