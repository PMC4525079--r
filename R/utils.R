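# Internal helpers: half-open ms intervals, seeded RNG streams.
#
# Intervals are numeric matrices with two columns (start, end), half-open
# [start, end): a time t belongs to the interval iff start <= t < end.

iv_empty <- function() matrix(numeric(0), ncol = 2L,
                              dimnames = list(NULL, c("start", "end")))

iv <- function(start, end) {
  m <- cbind(start = as.numeric(start), end = as.numeric(end))
  m[m[, 2] > m[, 1], , drop = FALSE]
}

iv_duration <- function(x) if (nrow(x) == 0L) 0 else sum(x[, 2] - x[, 1])

# Sort and merge overlapping/adjacent intervals.
iv_union <- function(x) {
  if (nrow(x) <= 1L) return(x)
  x <- x[order(x[, 1]), , drop = FALSE]
  out <- x[1, , drop = FALSE]
  for (i in seq_len(nrow(x))[-1]) {
    k <- nrow(out)
    if (x[i, 1] <= out[k, 2]) {
      out[k, 2] <- max(out[k, 2], x[i, 2])
    } else {
      out <- rbind(out, x[i, , drop = FALSE])
    }
  }
  out
}

iv_intersect <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) return(iv_empty())
  res <- iv_empty()
  for (i in seq_len(nrow(a))) {
    lo <- pmax(a[i, 1], b[, 1])
    hi <- pmin(a[i, 2], b[, 2])
    keep <- hi > lo
    if (any(keep)) res <- rbind(res, cbind(lo[keep], hi[keep]))
  }
  colnames(res) <- c("start", "end")
  iv_union(res)
}

iv_setdiff <- function(a, b) {
  if (nrow(a) == 0L) return(iv_empty())
  b <- iv_union(b)
  if (nrow(b) == 0L) return(iv_union(a))
  out <- iv_empty()
  for (i in seq_len(nrow(a))) {
    segs <- a[i, , drop = FALSE]
    for (j in seq_len(nrow(b))) {
      nxt <- iv_empty()
      for (k in seq_len(nrow(segs))) {
        s <- segs[k, 1]; e <- segs[k, 2]
        bs <- b[j, 1]; be <- b[j, 2]
        if (be <= s || bs >= e) {
          nxt <- rbind(nxt, c(s, e))
        } else {
          if (bs > s) nxt <- rbind(nxt, c(s, bs))
          if (be < e) nxt <- rbind(nxt, c(be, e))
        }
      }
      segs <- nxt
      if (nrow(segs) == 0L) break
    }
    out <- rbind(out, segs)
  }
  colnames(out) <- c("start", "end")
  iv_union(out)
}

# Which of `t` fall inside the union of intervals (half-open).
in_iv <- function(t, x) {
  if (nrow(x) == 0L || length(t) == 0L) return(rep(FALSE, length(t)))
  x <- iv_union(x)
  idx <- findInterval(t, as.vector(t(x)))
  idx %% 2L == 1L
}

# n points uniform on the union of intervals.
runif_iv <- function(n, x) {
  x <- iv_union(x)
  len <- x[, 2] - x[, 1]
  tot <- sum(len)
  u <- runif(n, 0, tot)
  cum <- c(0, cumsum(len))
  k <- findInterval(u, cum, rightmost.closed = TRUE)
  k[k > nrow(x)] <- nrow(x)
  x[k, 1] + (u - cum[k])
}

# Derived 31-bit seed for independent substreams.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(k)) %% 2147483647)
}

# Evaluate expr under a temporary RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
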