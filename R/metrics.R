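# Plug-in (maximum-likelihood) discrete information estimators on binary
# state sequences. All logarithms are base 2; empty cells (0 log 0) and
# undefined conditionals (0/0) contribute zero. No bias correction is
# applied: small-sample bias is absorbed by the frame-permutation surrogate
# null (see surrogate_test()).

# entropy in bits of a vector of non-negative counts
.H <- function(counts) {
  n <- sum(counts)
  if (n == 0L) return(0)
  p <- counts[counts > 0] / n
  -sum(p * log2(p))
}

.check_binary <- function(x, arg = "x") {
  if (length(x) == 0L) {
    abort(sprintf("`%s` must be a non-empty binary (0/1) vector.", arg))
  }
  if (anyNA(x) || any(x != 0L & x != 1L)) {
    abort(sprintf("`%s` must contain only 0 and 1 (no NA).", arg))
  }
  as.integer(x)
}

.check_equal_length <- function(x, y) {
  if (length(x) != length(y)) {
    abort(sprintf(
      "Series lengths differ (%d vs %d); metrics require frame-aligned traces.",
      length(x), length(y)
    ))
  }
}

# integer codes 0..2^k-1 of the k-step history word (x[t-1], ..., x[t-k])
# for t = (offset+1)..T, offset >= k; bit i-1 carries x[t-i]
.history_codes <- function(x, k, offset) {
  T <- length(x)
  idx <- (offset + 1L):T
  code <- integer(length(idx))
  for (i in seq_len(k)) {
    code <- code + x[idx - i] * 2L^(i - 1L)
  }
  code
}

.warn_undersampled <- function(n_cells, T) {
  if (n_cells > T / 3) {
    warn(
      sprintf(
        "Embedding uses %d joint states for %d frames; plug-in estimates will be undersampled.",
        n_cells, T
      ),
      class = "infoflow_undersampled"
    )
  }
}

# fast unvalidated kernels used by the surrogate machinery ---------------

.entropy0 <- function(x) {
  .H(tabulate(x + 1L, 2L))
}

.mi0 <- function(x, y) {
  joint <- tabulate(1L + x + 2L * y, 4L)
  .H(tabulate(x + 1L, 2L)) + .H(tabulate(y + 1L, 2L)) - .H(joint)
}

.dmi0 <- function(x, y, lag) {
  T <- length(x)
  if (lag == 0L) return(.mi0(x, y))
  .mi0(x[1:(T - lag)], y[(1 + lag):T])
}

.ais0 <- function(x, k) {
  T <- length(x)
  nxt <- x[(k + 1L):T]
  hist <- .history_codes(x, k, k)
  joint <- tabulate(1L + nxt + 2L * hist, 2L^(k + 1L))
  .H(tabulate(nxt + 1L, 2L)) + .H(tabulate(hist + 1L, 2L^k)) - .H(joint)
}

.te0 <- function(source, target, k, l) {
  T <- length(target)
  m <- max(k, l)
  nxt <- target[(m + 1L):T]
  xh <- .history_codes(target, k, m)
  yh <- .history_codes(source, l, m)
  n_xh <- 2L^k
  c_xh    <- tabulate(1L + xh, n_xh)
  c_nxh   <- tabulate(1L + nxt + 2L * xh, 2L * n_xh)
  c_xhyh  <- tabulate(1L + xh + n_xh * yh, n_xh * 2L^l)
  c_nxhyh <- tabulate(1L + nxt + 2L * xh + 2L * n_xh * yh, 2L * n_xh * 2L^l)
  # H(next | Xk) - H(next | Xk, Yl), each as a joint-minus-marginal difference
  (.H(c_nxh) - .H(c_xh)) - (.H(c_nxhyh) - .H(c_xhyh))
}

# exported estimators ----------------------------------------------------

#' Shannon information of a binary state sequence
#'
#' Information content in bits, `-[p log2 p + (1-p) log2 (1-p)]`, where `p`
#' is the empirical active fraction (fraction of frames in state 1). Maximal
#' (1 bit) at `p = 0.5`, zero for a constant sequence.
#'
#' @param x Integer/numeric vector of 0/1 states.
#' @return Information in bits (scalar, in `[0, 1]`).
#' @examples
#' shannon_information(c(1, rep(0, 9))) # a reporter active 10% of the time
#' shannon_information(rep(c(0, 1), 5)) # 1 bit at p = 0.5
#' @export
shannon_information <- function(x) {
  x <- .check_binary(x)
  .entropy0(x)
}

#' Mutual information between two frame-aligned binary sequences
#'
#' Plug-in MI from the empirical joint distribution of `(x[t], y[t])` pooled
#' over all frames. Symmetric; zero iff the empirical joint factorizes. MI of
#' a sequence with itself equals its Shannon information.
#'
#' @param x,y Equal-length 0/1 vectors.
#' @return MI in bits.
#' @export
mutual_information <- function(x, y) {
  x <- .check_binary(x, "x")
  y <- .check_binary(y, "y")
  .check_equal_length(x, y)
  .mi0(x, y)
}

#' Delayed mutual information
#'
#' MI over the lag-aligned pairs `(x[t], y[t + lag])`: how well the present
#' of `x` predicts the future of `y`. Detects lagged correlation, not
#' causation — two independent in-phase oscillators score maximally.
#'
#' @param x,y Equal-length 0/1 vectors (`x` the putative sender).
#' @param lag Non-negative integer delay in frames; `lag = 0` reduces to
#'   [mutual_information()].
#' @return DMI in bits.
#' @export
delayed_mutual_information <- function(x, y, lag = 1L) {
  x <- .check_binary(x, "x")
  y <- .check_binary(y, "y")
  .check_equal_length(x, y)
  lag <- as.integer(lag)
  if (lag < 0L || lag >= length(x)) {
    abort("`lag` must satisfy 0 <= lag < length(x).")
  }
  .dmi0(x, y, lag)
}

#' Active information storage
#'
#' Plug-in MI between the length-`k` history word `x[t-k..t-1]` and the
#' present value `x[t]`, pooled over all frames with a complete history.
#' High AIS marks self-predictable (periodic or persistent) dynamics.
#'
#' @param x 0/1 vector of length at least `k + 2`.
#' @param k History length (frames), `k >= 1`.
#' @return AIS in bits.
#' @export
active_information_storage <- function(x, k = 1L) {
  x <- .check_binary(x)
  k <- as.integer(k)
  if (k < 1L) abort("`k` must be a positive integer.")
  if (length(x) < k + 2L) {
    abort(sprintf("Series of length %d too short for history k = %d.", length(x), k))
  }
  .warn_undersampled(2L^(k + 1L), length(x))
  .ais0(x, k)
}

#' Transfer entropy (source -> target)
#'
#' Schreiber transfer entropy in its plug-in form: the information the
#' source's `l`-step history provides about the target's next state beyond
#' the target's own `k`-step history,
#' `H(x_t | x_{t-k..t-1}) - H(x_t | x_{t-k..t-1}, y_{t-l..t-1})`,
#' pooled over every frame with complete windows (no circular wrapping).
#' Directional: zero whenever the target is deterministic given its own
#' history, which is how it avoids the false positives that delayed MI
#' produces for independent oscillators or shared hidden drivers.
#'
#' @param source,target Equal-length 0/1 vectors.
#' @param k Target (self) history length, `k >= 1`.
#' @param l Source history length, `l >= 1`.
#' @return TE in bits.
#' @export
transfer_entropy <- function(source, target, k = 1L, l = 1L) {
  source <- .check_binary(source, "source")
  target <- .check_binary(target, "target")
  .check_equal_length(source, target)
  k <- as.integer(k); l <- as.integer(l)
  if (k < 1L || l < 1L) abort("`k` and `l` must be positive integers.")
  if (length(target) < max(k, l) + 2L) {
    abort(sprintf(
      "Series of length %d too short for histories k = %d, l = %d.",
      length(target), k, l
    ))
  }
  .warn_undersampled(2L^(k + l + 1L), length(target))
  .te0(source, target, k, l)
}

#' Effective information of a transition model
#'
#' MI between a maximum-entropy intervention (each of the `n` states imposed
#' with equal probability, or `intervention` if supplied) and the resulting
#' next-state distribution of a row-stochastic transition matrix:
#' `EI = sum_r pi_r sum_s M[r,s] log2( M[r,s] / pbar(s) )` with
#' `pbar(s) = sum_r pi_r M[r,s]`. Quantifies causal control: `log2 n` bits
#' for a permutation map, zero when the outcome ignores the intervention.
#'
#' @param m Square numeric matrix; row `r` is the distribution over next
#'   states after setting the system to state `r`. Rows must sum to 1
#'   within `1e-9`.
#' @param intervention Optional probability vector over intervened states;
#'   defaults to uniform.
#' @return EI in bits.
#' @examples
#' effective_information(diag(4))           # 2 bits
#' effective_information(matrix(0.5, 2, 2)) # 0 bits
#' @export
effective_information <- function(m, intervention = NULL) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m) || nrow(m) < 1L) {
    abort("`m` must be a square matrix with at least one state.")
  }
  if (any(m < 0) || any(abs(rowSums(m) - 1) > 1e-9)) {
    abort("`m` must be row-stochastic: non-negative rows summing to 1 (tol 1e-9).")
  }
  n <- nrow(m)
  if (is.null(intervention)) {
    pi_r <- rep(1 / n, n)
  } else {
    if (length(intervention) != n || any(intervention < 0) ||
        abs(sum(intervention) - 1) > 1e-9) {
      abort("`intervention` must be a probability vector over the n states.")
    }
    pi_r <- intervention
  }
  pbar <- as.numeric(pi_r %*% m)
  ei <- 0
  for (r in seq_len(n)) {
    nz <- m[r, ] > 0 & pi_r[r] > 0
    ei <- ei + pi_r[r] * sum(m[r, nz] * log2(m[r, nz] / pbar[nz]))
  }
  ei
}

# data-frame interface ---------------------------------------------------

#' Per-trace information metrics on a binary trace table
#'
#' Computes a self-metric (Shannon information or active information
#' storage) for every `(roi, channel)` trace in a tidy binary table, as
#' produced by [binarize()] or the `gen_*()` simulators.
#'
#' @param states Tibble with columns `roi`, `channel`, `frame`, `state`.
#' @param metric `"entropy"` or `"ais"`.
#' @param k AIS history length (ignored for entropy).
#' @return Tibble with one row per trace: `roi`, `channel`, `metric`,
#'   `value_bits`.
#' @export
roi_metrics <- function(states, metric = c("entropy", "ais"), k = 1L) {
  metric <- rlang::arg_match(metric)
  states <- .check_states_tbl(states)
  fn <- switch(metric,
    entropy = function(s) shannon_information(s),
    ais = function(s) active_information_storage(s, k = k)
  )
  states |>
    dplyr::arrange(.data$roi, .data$channel, .data$frame) |>
    dplyr::summarise(
      value_bits = fn(.data$state),
      .by = c("roi", "channel")
    ) |>
    dplyr::mutate(metric = metric, .before = "value_bits")
}

.check_states_tbl <- function(states) {
  need <- c("roi", "channel", "frame", "state")
  missing <- setdiff(need, names(states))
  if (length(missing) > 0) {
    abort(paste0(
      "Binary trace table must have columns roi, channel, frame, state; missing: ",
      paste(missing, collapse = ", ")
    ))
  }
  as_tibble(states)
}
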