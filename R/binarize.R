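# Thresholding of intensity traces into binary active/inactive state
# sequences. Each (roi, channel) trace is thresholded on its own values;
# the mean threshold is the documented default cutoff between signal and
# noise. Values exactly at the threshold map to 0 (inactive), which makes
# the constant-trace case deterministic: all zeros, flagged degenerate.

.otsu_threshold <- function(v) {
  # maximize between-class variance over midpoints of adjacent sorted values
  u <- sort(unique(v))
  if (length(u) < 2L) return(u[1])
  cand <- (u[-length(u)] + u[-1]) / 2
  best <- cand[1]; best_var <- -Inf
  n <- length(v)
  for (thr in cand) {
    hi <- v > thr
    n1 <- sum(hi)
    if (n1 == 0L || n1 == n) next
    w1 <- n1 / n
    between <- w1 * (1 - w1) * (mean(v[hi]) - mean(v[!hi]))^2
    if (between > best_var) {
      best_var <- between
      best <- thr
    }
  }
  best
}

.threshold_for <- function(v, method, fixed_value) {
  switch(method,
    mean = mean(v),
    median = median(v),
    fixed = fixed_value,
    otsu = .otsu_threshold(v)
  )
}

#' Binarize intensity traces
#'
#' Converts each `(roi, channel)` trace of a tidy trace table into a 0/1
#' state sequence: `state[t] = 1` iff `intensity[t] > threshold`. The
#' threshold is the trace's arithmetic mean (default), its median, a
#' supplied fixed value, or Otsu's inter-class-variance-maximizing level
#' on the trace's values. A constant trace yields all zeros and is marked
#' degenerate (with a warning), not an error.
#'
#' @param traces Tidy trace tibble (`roi`, `channel`, `frame`,
#'   `intensity`), e.g. from [extract_traces()] or [read_trace_table()].
#' @param method Thresholding method: `"mean"`, `"median"`, `"fixed"`, or
#'   `"otsu"`.
#' @param fixed_value Threshold for `method = "fixed"` (required then,
#'   ignored otherwise).
#' @return Tidy binary table: `roi`, `channel`, `frame`, `state` (0/1),
#'   plus per-trace `threshold`, `method`, and `degenerate` columns.
#' @examples
#' traces <- tibble::tibble(
#'   roi = "r1", channel = "calcium", frame = 1:4, intensity = c(1, 2, 3, 4)
#' )
#' binarize(traces)$state # 0 0 1 1 around the mean of 2.5
#' @export
binarize <- function(traces, method = c("mean", "median", "fixed", "otsu"),
                     fixed_value = NULL) {
  method <- rlang::arg_match(method)
  if (method == "fixed" && is.null(fixed_value)) {
    abort("`fixed_value` is required when method = \"fixed\".")
  }
  need <- c("roi", "channel", "frame", "intensity")
  missing <- setdiff(need, names(traces))
  if (length(missing) > 0) {
    abort(paste0("Trace table missing columns: ", paste(missing, collapse = ", ")))
  }
  if (any(!is.finite(traces$intensity))) abort("Trace intensities must be finite.")

  out <- traces |>
    as_tibble() |>
    dplyr::arrange(.data$roi, .data$channel, .data$frame) |>
    dplyr::group_by(.data$roi, .data$channel) |>
    dplyr::group_modify(function(d, key) {
      if (nrow(d) < 2L) {
        abort(sprintf("Trace '%s' has fewer than 2 frames.", key$roi))
      }
      thr <- .threshold_for(d$intensity, method, fixed_value)
      degen <- method != "fixed" && length(unique(d$intensity)) == 1L
      tibble(
        frame = d$frame,
        state = as.integer(d$intensity > thr),
        threshold = thr,
        method = method,
        degenerate = degen
      )
    }) |>
    dplyr::ungroup() |>
    dplyr::select("roi", "channel", "frame", "state", "threshold", "method",
                  "degenerate")

  degenerate <- out |>
    dplyr::distinct(.data$roi, .data$channel, .data$degenerate) |>
    dplyr::filter(.data$degenerate)
  if (nrow(degenerate) > 0) {
    warn(
      paste0(
        "Constant trace(s) binarized to all-inactive: ",
        paste(degenerate$roi, degenerate$channel, sep = "@", collapse = ", ")
      ),
      class = "infoflow_degenerate_trace"
    )
  }
  out
}

#' Active fraction of binary traces
#'
#' Fraction of frames each trace spends in state 1 — the empirical
#' probability that the signal is active, which sets the information
#' content ceiling for every other metric.
#'
#' @param states Tidy binary table (`roi`, `channel`, `frame`, `state`).
#' @return Tibble with `roi`, `channel`, `active_fraction`.
#' @export
active_fraction <- function(states) {
  states <- .check_states_tbl(states)
  states |>
    dplyr::summarise(
      active_fraction = mean(.data$state),
      .by = c("roi", "channel")
    )
}
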