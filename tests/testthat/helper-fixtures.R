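# shared builders and independent oracles for the suite

random_vol4d <- function(dims = c(4, 4, 4, 10), tr = 2, seed = 1,
                         affine = NULL) {
  set.seed(seed)
  if (is.null(affine)) {
    affine <- diag(c(3, 3, 3, 1))
    affine[1:3, 4] <- c(-6, -6, -6)
  }
  volume4d(array(rnorm(prod(dims)), dim = dims), affine, tr)
}

# sinusoid sampled at tr whose phase is symmetric about the window centre,
# hence exactly orthogonal to the linear-trend regressor
centred_sinusoid <- function(freq_hz, t, tr, amplitude = 1) {
  idx <- (seq_len(t) - 1) - (t - 1) / 2
  amplitude * cos(2 * pi * freq_hz * idx * tr)
}

# brute-force Kendall's W: explicit ranking, explicit rank sums
kcc_bruteforce <- function(cluster) {
  n <- nrow(cluster); k <- ncol(cluster)
  ranks <- matrix(0, n, k)
  for (j in seq_len(k)) ranks[, j] <- rank(cluster[, j])
  ri <- numeric(n)
  for (i in seq_len(n)) ri[i] <- sum(ranks[i, ])
  rbar <- sum(ri) / n
  num <- sum((ri - rbar)^2)
  num / (k^2 * (n^3 - n) / 12)
}

# step-up BH enumeration, deliberately naive
bh_survivors_oracle <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  k <- 0L
  for (i in seq_len(m)) if (ps[i] <= i * q / m) k <- i
  if (k == 0L) return(logical(m))
  p <= ps[k]
}

# recursive flood fill over a logical 3D array (the labeling oracle)
floodfill_labels <- function(bin, connectivity) {
  offs <- restkit:::stencil_offsets(connectivity)
  d <- dim(bin)
  labels <- array(0L, dim = d)
  lab <- 0L
  for (start in which(bin & labels == 0L)) {
    if (labels[start] != 0L) next
    lab <- lab + 1L
    queue <- start
    labels[start] <- lab
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      pos <- arrayInd(cur, d)
      for (r in seq_len(nrow(offs))) {
        np <- pos + offs[r, ]
        if (any(np < 1L) || any(np > d)) next
        ni <- np[1] + (np[2] - 1L) * d[1] + (np[3] - 1L) * d[1] * d[2]
        if (bin[ni] && labels[ni] == 0L) {
          labels[ni] <- lab
          queue <- c(queue, ni)
        }
      }
    }
  }
  labels
}

# sizes of components as a sorted multiset, for label-agreement checks
component_sizes <- function(labels) sort(tabulate(labels[labels > 0L]))
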