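# Internal array helpers shared by the filter bank and phantom generator.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Shift a 3D array by `offset` voxels along `axis` with replicate (clamped)
# boundary handling: out[i] = a[i + offset].
shift_array <- function(a, offset, axis) {
  d <- dim(a)
  idx <- pmin(pmax(seq_len(d[axis]) + offset, 1L), d[axis])
  switch(axis,
         a[idx, , , drop = FALSE],
         a[, idx, , drop = FALSE],
         a[, , idx, drop = FALSE])
}

# Separable 1D convolution along one axis: out = sum_j taps[j] * shift(a, offs[j]).
conv_axis <- function(a, taps, offsets, axis) {
  out <- array(0, dim(a))
  for (j in seq_along(taps)) {
    out <- out + taps[j] * shift_array(a, offsets[j], axis)
  }
  out
}

# Gaussian smoothing with per-axis sigma in voxels (separable, replicate edges).
gaussian_smooth <- function(a, sigma_vox) {
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    r <- max(1L, as.integer(ceiling(3 * s)))
    off <- (-r):r
    taps <- exp(-off^2 / (2 * s^2))
    taps <- taps / sum(taps)
    a <- conv_axis(a, taps, off, ax)
  }
  a
}

# Derive a bounded child seed from a root seed and a stream label.
child_seed <- function(seed, stream, i = 0L) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 7919 + h * 131 + i) %% 2147483629)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
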