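# Independent brute-force oracles. These materialize full joint count
# tables by explicit enumeration over observed symbol combinations and
# substitute the counts into the defining formulas directly. They share
# no code with the package's estimators (which use integer word codes
# and tabulate()).

oracle_entropy <- function(x) {
  n <- length(x)
  h <- 0
  for (v in unique(x)) {
    p <- sum(x == v) / n
    h <- h - p * log2(p)
  }
  h
}

# generic plug-in MI over two aligned symbol vectors
oracle_mi_pairs <- function(a, b) {
  n <- length(a)
  mi <- 0
  for (va in unique(a)) {
    for (vb in unique(b)) {
      c_ab <- sum(a == va & b == vb)
      if (c_ab == 0) next
      p_ab <- c_ab / n
      p_a <- sum(a == va) / n
      p_b <- sum(b == vb) / n
      mi <- mi + p_ab * log2(p_ab / (p_a * p_b))
    }
  }
  mi
}

oracle_mi <- function(x, y) oracle_mi_pairs(x, y)

oracle_dmi <- function(x, y, lag) {
  T <- length(x)
  if (lag == 0) return(oracle_mi_pairs(x, y))
  oracle_mi_pairs(x[1:(T - lag)], y[(1 + lag):T])
}

oracle_history_strings <- function(x, k, offset) {
  T <- length(x)
  vapply((offset + 1):T, function(t) {
    paste(x[(t - k):(t - 1)], collapse = "")
  }, character(1))
}

oracle_ais <- function(x, k) {
  T <- length(x)
  hist <- oracle_history_strings(x, k, k)
  nxt <- x[(k + 1):T]
  oracle_mi_pairs(hist, nxt)
}

oracle_te <- function(source, target, k, l) {
  T <- length(target)
  m <- max(k, l)
  xh <- oracle_history_strings(target, k, m)
  yh <- oracle_history_strings(source, l, m)
  nxt <- target[(m + 1):T]
  n <- length(nxt)
  te <- 0
  for (a in unique(xh)) {
    for (b in unique(yh)) {
      for (v in unique(nxt)) {
        c_vab <- sum(xh == a & yh == b & nxt == v)
        if (c_vab == 0) next
        c_ab <- sum(xh == a & yh == b)
        c_va <- sum(xh == a & nxt == v)
        c_a <- sum(xh == a)
        te <- te + (c_vab / n) * log2((c_vab / c_ab) / (c_va / c_a))
      }
    }
  }
  te
}

# Monte-Carlo interventional sampler: impose a uniformly drawn state,
# sample the next state from the imposed row, and estimate the MI of the
# (intervention, outcome) sample.
oracle_ei_mc <- function(m, n_samples = 2e5, seed = 99L) {
  withr::with_seed(seed, {
    n <- nrow(m)
    r <- sample.int(n, n_samples, replace = TRUE)
    s <- vapply(r, function(ri) {
      sample.int(n, 1L, prob = m[ri, ])
    }, integer(1))
    oracle_mi_pairs(r, s)
  })
}

# random 0/1 series of length T (helper for property loops)
rand_bin <- function(T, p = 0.5) as.integer(runif(T) < p)
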