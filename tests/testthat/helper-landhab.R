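# Shared fixtures and independent oracles, built in code at test time.

# land grid from a bare matrix, upper-left origin at (0, nrows * cell)
make_lu <- function(m, cell = 1000, legend = default_legend()) {
  land_grid(m, cell, c(0, nrow(as.matrix(m)) * cell), legend)
}

legend2 <- function() class_legend(1:2, c("farmland", "urban"))

# brute-force all-pairs minimum distance (metres), oracle for the
# distance transform on small grids
brute_distance <- function(lu, source_codes) {
  v <- lu$values
  nr <- nrow(v); nc <- ncol(v)
  src <- which(!is.na(v) & v %in% source_codes)
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      if (is.na(v[i, j])) next
      sr <- (src - 1) %% nr + 1
      sc <- (src - 1) %/% nr + 1
      out[i, j] <- sqrt(min((i - sr)^2 + (j - sc)^2)) * lu$cell_size
    }
  }
  out
}

# literal double-sum threat degradation: for every cell x, sum the decayed
# impact of every source cell y over all threats, via explicit pairwise
# distances (independent of the kernel-convolution implementation)
brute_degradation <- function(lu, threats, sens, decay_const = 2.99) {
  v <- lu$values
  nr <- nrow(v); nc <- ncol(v)
  idx <- which(!is.na(v))
  rr <- (idx - 1) %% nr + 1
  cc <- (idx - 1) %/% nr + 1
  w <- vapply(threats, function(t) t$weight, 0)
  wn <- w / sum(w)
  cls <- landhab:::legend_name(lu$legend, v[idx])
  D <- numeric(length(idx))
  for (t in seq_along(threats)) {
    th <- threats[[t]]
    sidx <- which(!is.na(v) & v %in% th$source_classes)
    if (!length(sidx)) next
    sr <- (sidx - 1) %% nr + 1
    sc <- (sidx - 1) %/% nr + 1
    dd <- sqrt(outer(rr, sr, function(a, b) (a - b)^2) +
               outer(cc, sc, function(a, b) (a - b)^2)) * lu$cell_size / 1000
    imp <- decay_weight(dd, th, decay_const)
    imp[dd > th$d_rmax] <- 0
    S <- sens$sensitivity[cls, th$name]
    D <- D + wn[t] * S * rowSums(imp)
  }
  out <- matrix(NA_real_, nr, nc)
  out[idx] <- D
  out
}

# random row-stochastic matrix
random_stochastic <- function(n) {
  P <- matrix(stats::rexp(n * n), n, n)
  P / rowSums(P)
}

# smooth random suitability fields in [0, 1], one per class (synthetic
# atlas for CA tests that do not need fitted models)
flat_atlas <- function(lu, classes, seed = 1) {
  layers <- list()
  set.seed(seed)
  for (cl in classes) {
    f <- matrix(stats::runif(length(lu$values)), nrow(lu$values))
    f <- landhab:::box_sum(f, 5) /
      landhab:::box_sum(matrix(1, nrow(f), ncol(f)), 5)
    layers[[as.character(cl)]] <- cont_grid(f, lu$cell_size, lu$origin)
  }
  suitability_atlas(layers)
}
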