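# Interval arithmetic on the patient's global clock.
# Intervals are two-column numeric matrices of half-open [start, end) rows,
# in seconds. All set operations normalize (sort + merge) their output.

iv <- function(start, end) {
  m <- cbind(start = as.numeric(start), end = as.numeric(end))
  if (any(m[, 2L] < m[, 1L])) stop("interval end precedes start", call. = FALSE)
  m
}

iv_empty <- function() {
  cbind(start = numeric(0), end = numeric(0))
}

iv_normalize <- function(m) {
  if (is.null(m) || nrow(m) == 0L) return(iv_empty())
  m <- m[m[, 2L] > m[, 1L], , drop = FALSE]
  if (nrow(m) <= 1L) return(iv(m[, 1L], m[, 2L]))
  m <- m[order(m[, 1L], m[, 2L]), , drop = FALSE]
  st <- m[1L, 1L]
  en <- m[1L, 2L]
  out_s <- numeric(0)
  out_e <- numeric(0)
  for (i in 2:nrow(m)) {
    if (m[i, 1L] <= en) {
      en <- max(en, m[i, 2L])
    } else {
      out_s <- c(out_s, st); out_e <- c(out_e, en)
      st <- m[i, 1L]; en <- m[i, 2L]
    }
  }
  iv(c(out_s, st), c(out_e, en))
}

iv_length <- function(m) {
  if (is.null(m) || nrow(m) == 0L) return(0)
  sum(m[, 2L] - m[, 1L])
}

iv_intersect <- function(a, b) {
  a <- iv_normalize(a)
  b <- iv_normalize(b)
  s <- numeric(0)
  e <- numeric(0)
  for (i in seq_len(nrow(a))) {
    lo <- pmax(a[i, 1L], b[, 1L])
    hi <- pmin(a[i, 2L], b[, 2L])
    keep <- hi > lo
    s <- c(s, lo[keep])
    e <- c(e, hi[keep])
  }
  iv_normalize(iv(s, e))
}

# complement of m within domain
iv_complement <- function(m, domain) {
  domain <- iv_normalize(domain)
  m <- iv_normalize(m)
  s <- numeric(0)
  e <- numeric(0)
  for (i in seq_len(nrow(domain))) {
    cur <- domain[i, 1L]
    for (j in seq_len(nrow(m))) {
      if (m[j, 2L] <= cur || m[j, 1L] >= domain[i, 2L]) next
      if (m[j, 1L] > cur) {
        s <- c(s, cur); e <- c(e, m[j, 1L])
      }
      cur <- max(cur, m[j, 2L])
    }
    if (cur < domain[i, 2L]) {
      s <- c(s, cur); e <- c(e, domain[i, 2L])
    }
  }
  iv(s, e)
}

# which interval row contains each point (NA if none); [start, end)
iv_locate <- function(m, t) {
  vapply(t, function(x) {
    hit <- which(m[, 1L] <= x & x < m[, 2L])
    if (length(hit)) hit[1L] else NA_integer_
  }, integer(1))
}

iv_contains <- function(m, t) !is.na(iv_locate(m, t))

# vectorized: does [starts_i, ends_i) overlap any row of m?
iv_overlaps_any <- function(starts, ends, m) {
  hit <- rep(FALSE, length(starts))
  for (j in seq_len(nrow(m))) {
    hit <- hit | (starts < m[j, 2L] & ends > m[j, 1L])
  }
  hit
}

# vectorized: is [starts_i, ends_i) entirely inside some single row of m?
iv_within_any <- function(starts, ends, m) {
  hit <- rep(FALSE, length(starts))
  for (j in seq_len(nrow(m))) {
    hit <- hit | (starts >= m[j, 1L] & ends <= m[j, 2L])
  }
  hit
}
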