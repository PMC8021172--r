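# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. seed = NULL evaluates unchanged.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1) # materialise a seed so it can be saved
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# 2-D correlation of matrix `m` with a small odd-sized kernel, zero-padded:
# out[i, j] = sum_{di, dj} kern[di, dj] * m[i + di, j + dj].
# Implemented as shift-and-add over the non-zero kernel entries, which is
# fast for the compact kernels used here (blur and threat-decay kernels).
conv2 <- function(m, kern) {
  nr <- nrow(m); nc <- ncol(m)
  kr <- (nrow(kern) - 1L) %/% 2L
  kc <- (ncol(kern) - 1L) %/% 2L
  out <- matrix(0, nr, nc)
  for (di in -kr:kr) {
    r1 <- max(1L, 1L - di); r2 <- min(nr, nr - di)
    if (r1 > r2) next
    for (dj in -kc:kc) {
      w <- kern[di + kr + 1L, dj + kc + 1L]
      if (w == 0) next
      c1 <- max(1L, 1L - dj); c2 <- min(nc, nc - dj)
      if (c1 > c2) next
      out[r1:r2, c1:c2] <- out[r1:r2, c1:c2] +
        w * m[(r1 + di):(r2 + di), (c1 + dj):(c2 + dj)]
    }
  }
  out
}

# Moving-window (box) sum with an odd window edge `size`, truncated at the
# grid edge. Uses padded cumulative sums along each dimension: O(cells).
box_sum <- function(m, size) {
  h <- (size - 1L) %/% 2L
  nr <- nrow(m); nc <- ncol(m)
  cs <- rbind(0, apply(m, 2, cumsum))
  lo <- pmax(seq_len(nr) - h, 1L); hi <- pmin(seq_len(nr) + h, nr)
  rowwin <- cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]
  cs2 <- cbind(0, t(apply(rowwin, 1, cumsum)))
  lo <- pmax(seq_len(nc) - h, 1L); hi <- pmin(seq_len(nc) + h, nc)
  cs2[, hi + 1L, drop = FALSE] - cs2[, lo, drop = FALSE]
}

# One-dimensional squared-distance transform (Felzenszwalb & Huttenlocher):
# d[q] = min_p (q - p)^2 + f[p]. `f` must be finite (use a large sentinel
# instead of Inf so the parabola intersections stay well defined).
dt1d <- function(f) {
  n <- length(f)
  if (n == 1L) return(f)
  d <- numeric(n)
  v <- integer(n)
  z <- numeric(n + 1L)
  k <- 1L; v[1L] <- 1L; z[1L] <- -Inf; z[2L] <- Inf
  for (q in 2:n) {
    s <- ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2 * q - 2 * v[k])
    while (s <= z[k]) {
      k <- k - 1L
      s <- ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2 * q - 2 * v[k])
    }
    k <- k + 1L
    v[k] <- q
    z[k] <- s
    z[k + 1L] <- Inf
  }
  k <- 1L
  for (q in 1:n) {
    while (z[k + 1L] < q) k <- k + 1L
    d[q] <- (q - v[k])^2 + f[v[k]]
  }
  d
}

# Exact Euclidean squared-distance transform of a logical source mask,
# in cell units: two separable 1-D passes.
edt_squared <- function(src) {
  nr <- nrow(src); nc <- ncol(src)
  big <- (nr * nr + nc * nc + 1) * 4 # exceeds any attainable squared distance
  f <- matrix(ifelse(src, 0, big), nr, nc)
  for (j in seq_len(nc)) f[, j] <- dt1d(f[, j])
  for (i in seq_len(nr)) f[i, ] <- dt1d(f[i, ])
  f
}

# Largest-remainder rounding of non-negative reals to integers preserving
# the (integer) total.
round_preserve_sum <- function(x, total = round(sum(x))) {
  fl <- floor(x)
  rem <- total - sum(fl)
  if (rem > 0) {
    ord <- order(x - fl, decreasing = TRUE)
    fl[ord[seq_len(rem)]] <- fl[ord[seq_len(rem)]] + 1
  } else if (rem < 0) {
    ord <- order(x - fl)
    take <- ord[fl[ord] > 0][seq_len(-rem)]
    fl[take] <- fl[take] - 1
  }
  as.integer(fl)
}
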