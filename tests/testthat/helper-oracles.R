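# Independent brute-force oracles, written from the set-theoretic
# definitions and kept free of the package's implementation internals.

seOffsetsOracle <- function(fp, origin) {
  idx <- which(fp, arr.ind = TRUE)
  sweep(idx, 2, origin)
}

# Erosion from the definition {z : B_z subset A}; outside the frame is
# background, so any tap landing outside disqualifies z.
bruteErode <- function(A, fp = matrix(TRUE, 3, 3), origin = c(2L, 2L)) {
  offs <- seOffsetsOracle(fp, origin)
  d <- dim(A)
  out <- array(FALSE, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    ok <- TRUE
    for (k in seq_len(nrow(offs))) {
      y <- i + offs[k, 1]; x <- j + offs[k, 2]
      if (y < 1 || y > d[1] || x < 1 || x > d[2] || !A[y, x]) { ok <- FALSE; break }
    }
    out[i, j] <- ok
  }
  out
}

# Second route, from the complement formulation {z : B_z intersect A^c = empty}
# (the complement includes everything outside the frame).
bruteErodeComplement <- function(A, fp = matrix(TRUE, 3, 3), origin = c(2L, 2L)) {
  offs <- seOffsetsOracle(fp, origin)
  d <- dim(A)
  out <- array(FALSE, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    hitsComplement <- FALSE
    for (k in seq_len(nrow(offs))) {
      y <- i + offs[k, 1]; x <- j + offs[k, 2]
      inFrame <- y >= 1 && y <= d[1] && x >= 1 && x <= d[2]
      if (!inFrame || !A[y, x]) { hitsComplement <- TRUE; break }
    }
    out[i, j] <- !hitsComplement
  }
  out
}

# Dilation from {z : Bhat_z intersect A != empty}: taps at z minus the
# offsets of B.
bruteDilate <- function(A, fp = matrix(TRUE, 3, 3), origin = c(2L, 2L)) {
  offs <- seOffsetsOracle(fp, origin)
  d <- dim(A)
  out <- array(FALSE, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    hit <- FALSE
    for (k in seq_len(nrow(offs))) {
      y <- i - offs[k, 1]; x <- j - offs[k, 2]
      if (y >= 1 && y <= d[1] && x >= 1 && x <= d[2] && A[y, x]) { hit <- TRUE; break }
    }
    out[i, j] <- hit
  }
  out
}

# Exhaustive pairwise rank AUC: P(s+ > s-) + 0.5 P(tie).
pairwiseAUC <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Naive sliding-window median with mirror-reflect edges.
bruteMedianFilter <- function(a, k = 3L) {
  r <- (k - 1L) %/% 2L
  d <- dim(a)
  refl <- function(i, n) {
    while (any(i < 1 | i > n)) {
      i[i < 1] <- 2 - i[i < 1]
      i[i > n] <- 2 * n - i[i > n]
    }
    i
  }
  out <- a
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    ys <- refl(i + (-r:r), d[1]); xs <- refl(j + (-r:r), d[2])
    out[i, j] <- median(a[ys, xs])
  }
  out
}

randomMask <- function(n, p = 0.4) {
  matrix(runif(n * n) < p, n, n)
}
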