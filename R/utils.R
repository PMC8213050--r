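# Internal helpers shared across modules.

#' @importFrom stats rnorm rlnorm sd pt lm runif
NULL

BOUNDARY_NAMES <- c("ILM", "NFL_GCL", "IPL_INL", "ISOS", "RPE_CH")
DOMAIN_LABELS <- c("FULL", "ISOS_ILM", "ISOS_IPLINL", "ISOS_NFLGCL", "RPECH_ISOS")

# Evaluate expr with a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Replicate-pad a matrix along rows by n rows on each side.
pad_rows <- function(x, n) {
  rbind(x[rep(1L, n), , drop = FALSE], x, x[rep(nrow(x), n), , drop = FALSE])
}

# Shift a vector by k (positive = towards larger indices), replicating edges.
shift_replicate <- function(v, k) {
  n <- length(v)
  if (k == 0) return(v)
  if (k > 0) c(rep(v[1L], k), v[seq_len(n - k)])
  else c(v[seq(1L - k, n)], rep(v[n], -k))
}

# Linear interpolation across NA runs of length <= max_gap; longer runs and
# leading/trailing NAs stay NA.
interpolate_gaps <- function(v, max_gap = 20L) {
  na <- is.na(v)
  if (!any(na) || all(na)) return(v)
  idx <- which(!na)
  r <- rle(na)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (i in seq_along(r$lengths)) {
    if (!r$values[i]) next
    s <- starts[i]; e <- ends[i]
    if (s == 1L || e == length(v)) next          # edge gap: leave missing
    if (r$lengths[i] > max_gap) next
    x0 <- s - 1L; x1 <- e + 1L
    v[s:e] <- v[x0] + (v[x1] - v[x0]) * ((s:e) - x0) / (x1 - x0)
  }
  v
}

stop_retfreq <- function(...) stop(..., call. = FALSE)

# 3x3 median filter with replicated borders, via a 19-comparator sorting
# network on the 9 shifted copies (vectorized; much faster than per-pixel
# filtering in R).
median3x3 <- function(x) {
  H <- nrow(x); W <- ncol(x)
  xp <- cbind(x[, 1L], x, x[, W])
  xp <- rbind(xp[1L, ], xp, xp[H, ])
  v <- vector("list", 9L)
  i <- 1L
  for (dr in 0:2) for (dc in 0:2) {
    v[[i]] <- xp[dr + seq_len(H), dc + seq_len(W)]
    i <- i + 1L
  }
  cmp <- function(a, b) {        # ensure v[[a]] <= v[[b]]
    lo <- pmin(v[[a]], v[[b]])
    v[[b]] <<- pmax(v[[a]], v[[b]])
    v[[a]] <<- lo
  }
  net <- list(c(2,3), c(5,6), c(8,9), c(1,2), c(4,5), c(7,8), c(2,3),
              c(5,6), c(8,9), c(1,4), c(6,9), c(5,8), c(4,7), c(2,5),
              c(3,6), c(5,8), c(5,3), c(7,5), c(5,3))
  for (p in net) cmp(p[1], p[2])   # pair order is part of the network
  v[[5L]]
}
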