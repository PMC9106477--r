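# Internal helpers shared across modules.

# Deterministic fan-out of a master seed into per-task seeds, kept inside
# the 32-bit integer range R's RNG accepts.
deriveSeed <- function(master, k) {
  as.integer((as.double(master) * 48271 + as.double(k) * 16807) %% 2147483629) + 1L
}

# Evaluate expr under a local RNG seed without disturbing the caller's RNG.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# All integer offset vectors of a structuring element relative to its origin,
# as a k x ndim matrix (one row per active footprint cell).
seOffsets <- function(se) {
  stopifnot(is(se, "StructuringElement"))
  idx <- which(se@footprint, arr.ind = TRUE)
  if (is.null(dim(idx))) idx <- matrix(idx, ncol = 1L)
  sweep(idx, 2L, se@origin)
}

# Reflect B about its origin (the B-hat of dilation).
reflectSE <- function(se) {
  fp <- se@footprint
  nd <- length(dim(fp))
  rev_idx <- lapply(dim(fp), function(n) n:1)
  rfp <- do.call(`[`, c(list(fp), rev_idx, list(drop = FALSE)))
  StructuringElement(rfp, origin = as.integer(dim(fp) + 1L - se@origin))
}

# Translate a logical/numeric array by an integer offset, filling with `fill`.
shiftArray <- function(a, offset, fill) {
  d <- dim(a)
  out <- array(fill, d)
  src <- dst <- vector("list", length(d))
  for (ax in seq_along(d)) {
    o <- offset[ax]
    if (o >= d[ax] || o <= -d[ax]) return(out)
    if (o >= 0) { dst[[ax]] <- seq_len(d[ax] - o); src[[ax]] <- seq_len(d[ax] - o) + o }
    else        { dst[[ax]] <- seq_len(d[ax] + o) - o; src[[ax]] <- seq_len(d[ax] + o) }
  }
  out_idx <- do.call(`[<-`, c(list(out), dst,
                              list(do.call(`[`, c(list(a), src, list(drop = FALSE))))))
  out_idx
}

# Reflected (mirror) index lookup for out-of-range positions, 1-based.
reflectIndex <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  p <- (i - 1L) %% (2L * (n - 1L))
  p <- ifelse(p < 0, p + 2L * (n - 1L), p)
  as.integer(ifelse(p >= n, 2L * (n - 1L) - p, p) + 1L)
}

# Linear indices of an array shifted by `offset` with reflect padding:
# returns idx such that a[idx] is the neighbor value for every voxel.
reflectShiftIndex <- function(d, offset) {
  coords <- lapply(seq_along(d), function(ax)
    reflectIndex(seq_len(d[ax]) + offset[ax], d[ax]))
  g <- as.matrix(do.call(expand.grid, coords))
  mult <- cumprod(c(1, d[-length(d)]))
  as.integer(1 + (g - 1) %*% mult)
}

# FNV-1a hash of a serialized R object, as a hex string (used for run
# manifests; stable across sessions for plain data).
contentHash <- function(x) {
  raw <- serialize(x, NULL, version = 2)
  h <- 2166136261
  for (b in as.integer(raw)) {
    h <- bitwXor(as.integer(h %% 2147483648), b)
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%08x", as.integer(h %% 2147483647))
}

asImageArray <- function(x) {
  if (is(x, "RawImage")) imgData(x) else as.array(x)
}

asMaskArray <- function(x) {
  if (is(x, "BinaryMask")) imgData(x) else array(as.logical(x), dim = dim(x))
}
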