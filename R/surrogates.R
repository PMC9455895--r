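# Frame-permutation surrogate nulls and group-level rank statistics.
# The null destroys all temporal structure while preserving each trace's
# marginal exactly (a permutation of frame order), so surrogate entropy
# equals observed entropy for every replicate and any excess in a
# history-dependent metric is attributable to temporal organization.

.metric_fn <- function(metric, k, l, lag) {
  switch(metric,
    entropy = function(x, y) .entropy0(x),
    mi = function(x, y) .mi0(x, y),
    dmi = function(x, y) .dmi0(x, y, lag),
    ais = function(x, y) .ais0(x, k),
    te = function(x, y) .te0(x, y, k, l)
  )
}

.default_null <- function(metric) {
  if (metric %in% c("entropy", "ais")) "shuffle_self" else "shuffle_source"
}

#' Frame-shuffle surrogate of a state sequence
#'
#' Reorders a trace by a uniformly random permutation of its frame
#' indices, drawn from a seeded generator. The multiset of states (hence
#' the active fraction and entropy) is preserved exactly; all temporal
#' structure is destroyed.
#'
#' @param x State (or intensity) vector.
#' @param seed Integer seed; the same seed reproduces the surrogate
#'   bit-for-bit.
#' @return Permuted vector of the same length.
#' @export
shuffle_surrogate <- function(x, seed) {
  if (length(x) == 0L) abort("Cannot shuffle an empty trace.")
  withr::with_seed(as.integer(seed), x[sample.int(length(x))])
}

#' Surrogate-randomization significance test for an information metric
#'
#' Computes the observed metric on the real trace(s), then re-computes it
#' on `n` replicates in which the designated trace(s) are independently
#' frame-shuffled, and reports the one-sided empirical p-value
#' `(1 + #\{surrogate >= observed\}) / (1 + n)` (never zero). One-sided
#' because all metrics are non-negative and only values exceeding the
#' null are of interest.
#'
#' @param x State vector (the source for directed metrics).
#' @param y Second state vector (the target), for the pairwise metrics
#'   `"mi"`, `"dmi"`, `"te"`; `NULL` for `"entropy"`/`"ais"`.
#' @param metric One of `"entropy"`, `"mi"`, `"dmi"`, `"ais"`, `"te"`.
#' @param k,l,lag Embedding parameters: target/self history `k`, source
#'   history `l`, delay `lag` (see the individual estimators).
#' @param n Number of surrogate replicates (the conventional choice is
#'   1000).
#' @param seed Integer seed; `(inputs, seed, n)` determine every output
#'   bit.
#' @param null Which trace(s) to shuffle: `"shuffle_source"`,
#'   `"shuffle_target"`, `"shuffle_both"` for pairwise metrics,
#'   `"shuffle_self"` for self-metrics. Defaults to `"shuffle_self"` for
#'   entropy/AIS and `"shuffle_source"` otherwise.
#' @return An object of class `infoflow_surrogate_test`; see [tidy()] and
#'   [glance()] methods, or access `$value_bits`, `$p_value`,
#'   `$surrogate_values` directly.
#' @export
surrogate_test <- function(x, y = NULL,
                           metric = c("mi", "dmi", "ais", "te", "entropy"),
                           k = 1L, l = 1L, lag = 1L,
                           n = 1000L, seed = 1L, null = NULL) {
  metric <- rlang::arg_match(metric)
  n <- as.integer(n)
  if (n < 1L) abort("`n` must be >= 1.")
  null <- null %||% .default_null(metric)
  null <- rlang::arg_match(null, c(
    "shuffle_source", "shuffle_target", "shuffle_both", "shuffle_self"
  ))
  pairwise <- metric %in% c("mi", "dmi", "te")
  if (pairwise && is.null(y)) {
    abort(sprintf("Metric '%s' needs both `x` and `y`.", metric))
  }
  if (!pairwise && !is.null(y)) {
    abort(sprintf("Metric '%s' is a self-metric; leave `y` NULL.", metric))
  }
  if (pairwise && null == "shuffle_self") {
    abort("`shuffle_self` applies only to self-metrics (entropy, AIS).")
  }
  if (!pairwise && null != "shuffle_self") {
    abort(sprintf("Self-metric '%s' requires null = \"shuffle_self\".", metric))
  }

  x <- .check_binary(x, "x")
  if (!is.null(y)) {
    y <- .check_binary(y, "y")
    .check_equal_length(x, y)
  }
  # validate embedding feasibility once via the exported estimators
  fn <- .metric_fn(metric, as.integer(k), as.integer(l), as.integer(lag))
  observed <- switch(metric,
    entropy = shannon_information(x),
    mi = mutual_information(x, y),
    dmi = delayed_mutual_information(x, y, lag),
    ais = active_information_storage(x, k),
    te = transfer_entropy(x, y, k, l)
  )

  Tn <- length(x)
  shuffle_x <- null %in% c("shuffle_source", "shuffle_both", "shuffle_self")
  shuffle_y <- null %in% c("shuffle_target", "shuffle_both")
  surr <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n), function(i) {
      xs <- if (shuffle_x) x[sample.int(Tn)] else x
      ys <- if (shuffle_y) y[sample.int(Tn)] else y
      fn(xs, ys)
    }, numeric(1))
  })
  p <- (1 + sum(surr >= observed - 1e-12)) / (1 + n)

  structure(
    list(
      metric = metric, value_bits = observed, p_value = p,
      n_surrogates = n, seed = as.integer(seed), null = null,
      params = list(k = as.integer(k), l = as.integer(l), lag = as.integer(lag)),
      surrogate_values = surr
    ),
    class = "infoflow_surrogate_test"
  )
}

#' @export
print.infoflow_surrogate_test <- function(x, ...) {
  cat(sprintf(
    "Surrogate test: %s = %.4f bits, p = %.4g (%d surrogates, %s null)\n",
    toupper(x$metric), x$value_bits, x$p_value, x$n_surrogates, x$null
  ))
  invisible(x)
}

#' Tidy a surrogate test: one row per surrogate replicate
#'
#' @param x An `infoflow_surrogate_test` object.
#' @param ... Unused.
#' @return Tibble with `replicate` and `value_bits`.
#' @exportS3Method generics::tidy
tidy.infoflow_surrogate_test <- function(x, ...) {
  tibble(replicate = seq_len(x$n_surrogates), value_bits = x$surrogate_values)
}

#' Glance at a surrogate test: one-row summary
#'
#' @param x An `infoflow_surrogate_test` object.
#' @param ... Unused.
#' @return One-row tibble with the observed value, p-value and settings.
#' @exportS3Method generics::glance
glance.infoflow_surrogate_test <- function(x, ...) {
  tibble(
    metric = x$metric, value_bits = x$value_bits, p_value = x$p_value,
    n_surrogates = x$n_surrogates, null = x$null,
    k = x$params$k, l = x$params$l, lag = x$params$lag, seed = x$seed
  )
}

#' Mann-Whitney rank-sum comparison of two groups of metric values
#'
#' Two-sided Mann-Whitney U test, the distribution-free contrast used for
#' group-level comparisons of information metrics (no Gaussian
#' assumption). Exact enumeration for group sizes of at most 8 without
#' ties; tie-corrected normal approximation otherwise.
#'
#' @param a,b Numeric vectors of metric values (each non-empty).
#' @return One-row tibble: `statistic` (U for the first group), `p_value`,
#'   `n_a`, `n_b`, `method`.
#' @export
rank_sum_compare <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) abort("Both groups must be non-empty.")
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- !ties && max(length(a), length(b)) <= 8L
  res <- suppressWarnings(wilcox.test(a, b, exact = exact, correct = !exact))
  tibble(
    statistic = unname(res$statistic),
    p_value = res$p.value,
    n_a = length(a), n_b = length(b),
    method = if (exact) "exact" else "normal approximation (tie-corrected)"
  )
}

#' Pairwise metric table with surrogate significance
#'
#' Computes an information metric for every trace pair (or every trace,
#' for self-metrics) of a tidy binary table and attaches a
#' frame-permutation surrogate p-value and significance flag to each cell.
#' The MI table is symmetric, so only one orientation per unordered pair
#' is computed, and its diagonal holds each trace's information content
#' (self-MI = entropy) with no p-value: the permutation null preserves the
#' marginal, so it carries no test for a marginal quantity. TE tables are
#' fully asymmetric with self-cells omitted.
#'
#' @param states Tidy binary table (`roi`, `channel`, `frame`, `state`).
#'   Traces are labelled `roi` when one channel is present, `roi@channel`
#'   otherwise.
#' @param metric `"mi"`, `"dmi"`, `"te"` (pairwise) or `"entropy"`,
#'   `"ais"` (per-trace).
#' @param k,l,lag Embedding parameters passed to the estimator.
#' @param n Surrogates per cell.
#' @param seed Master seed; per-cell seeds are derived from it, so the
#'   whole table is reproducible bit-for-bit.
#' @param alpha Significance level for the flag (conventionally 0.05; no
#'   multiplicity correction is applied across cells — flag counts are
#'   exploratory, mirroring standard practice for these tables).
#' @param null Null construction passed to [surrogate_test()]; default
#'   per metric.
#' @return Tidy tibble: `metric`, `source`, `target`, `value_bits`,
#'   `p_value`, `significant`, `n_surrogates`.
#' @export
pairwise_table <- function(states,
                           metric = c("mi", "dmi", "te", "entropy", "ais"),
                           k = 1L, l = 1L, lag = 1L,
                           n = 1000L, seed = 1L, alpha = 0.05,
                           null = NULL) {
  metric <- rlang::arg_match(metric)
  states <- .check_states_tbl(states)
  traces <- states |>
    dplyr::arrange(.data$roi, .data$channel, .data$frame)
  one_channel <- dplyr::n_distinct(traces$channel) == 1L
  traces <- traces |>
    dplyr::mutate(
      label = if (one_channel) .data$roi else paste0(.data$roi, "@", .data$channel)
    )
  labels <- unique(traces$label)
  series <- lapply(labels, function(lb) traces$state[traces$label == lb])
  names(series) <- labels

  pairwise <- metric %in% c("mi", "dmi", "te")
  if (pairwise && length(labels) < 2L) {
    abort("Pairwise metrics need at least two traces.")
  }

  cells <- if (!pairwise) {
    tibble(source = labels, target = labels)
  } else if (metric == "mi") {
    # unordered pairs; diagonal handled separately as information content
    tidyr::expand_grid(source = labels, target = labels) |>
      dplyr::filter(match(.data$source, labels) < match(.data$target, labels))
  } else {
    tidyr::expand_grid(source = labels, target = labels) |>
      dplyr::filter(.data$source != .data$target)
  }

  cell_seeds <- withr::with_seed(
    as.integer(seed),
    sample.int(.Machine$integer.max - 1L, nrow(cells))
  )

  rows <- purrr::pmap(
    list(cells$source, cells$target, cell_seeds),
    function(src, tgt, cell_seed) {
      st <- if (pairwise) {
        surrogate_test(series[[src]], series[[tgt]], metric = metric,
                       k = k, l = l, lag = lag, n = n, seed = cell_seed,
                       null = null)
      } else {
        surrogate_test(series[[src]], NULL, metric = metric,
                       k = k, l = l, lag = lag, n = n, seed = cell_seed,
                       null = null)
      }
      tibble(
        metric = metric, source = src, target = tgt,
        value_bits = st$value_bits, p_value = st$p_value,
        significant = st$p_value < alpha, n_surrogates = n
      )
    }
  )
  out <- dplyr::bind_rows(rows)

  if (metric == "mi") {
    diag_rows <- tibble(
      metric = "mi", source = labels, target = labels,
      value_bits = unname(vapply(series, .entropy0, numeric(1))),
      p_value = NA_real_, significant = NA, n_surrogates = n
    )
    out <- dplyr::bind_rows(out, diag_rows) |>
      dplyr::arrange(match(.data$source, labels), match(.data$target, labels))
  }
  attr(out, "alpha") <- alpha
  attr(out, "labels") <- labels
  out
}
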