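# Minimal CNN inference primitives (H x W x C arrays, single image).
# Convolution is im2col + one BLAS matmul; all ops are deterministic.

pad_array <- function(x, pad, value = 0) {
  if (pad == 0) return(x)
  d <- dim(x)
  out <- array(value, c(d[1] + 2 * pad, d[2] + 2 * pad, d[3]))
  out[pad + seq_len(d[1]), pad + seq_len(d[2]), ] <- x
  out
}

# w: kh x kw x Cin x Cout (ResNet convolutions carry no bias)
conv2d <- function(x, w, stride = 1, pad = 0) {
  dw <- dim(w)
  kh <- dw[1]; kw <- dw[2]; cin <- dw[3]; cout <- dw[4]
  xp <- pad_array(x, pad)
  d <- dim(xp)
  oh <- (d[1] - kh) %/% stride + 1L
  ow <- (d[2] - kw) %/% stride + 1L
  i0 <- seq(1L, by = stride, length.out = oh)
  j0 <- seq(1L, by = stride, length.out = ow)
  patches <- matrix(0, oh * ow, kh * kw * cin)
  for (dj in seq_len(kw)) {
    for (di in seq_len(kh)) {
      slice <- xp[i0 + di - 1L, j0 + dj - 1L, , drop = FALSE]
      cols <- (dj - 1L) * kh + di + (seq_len(cin) - 1L) * (kh * kw)
      patches[, cols] <- matrix(slice, oh * ow, cin)
    }
  }
  out <- patches %*% matrix(w, nrow = kh * kw * cin)
  array(out, c(oh, ow, cout))
}

# inference-mode batch normalization with stored running statistics
batchnorm <- function(x, bn, eps = 1e-5) {
  d <- dim(x)
  scale <- bn$gamma / sqrt(bn$var + eps)
  shift <- bn$beta - bn$mean * scale
  y <- t(t(matrix(x, d[1] * d[2], d[3])) * scale + shift)
  array(y, d)
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

maxpool2d <- function(x, k = 3, stride = 2, pad = 1) {
  xp <- pad_array(x, pad, value = -Inf)
  d <- dim(xp)
  oh <- (d[1] - k) %/% stride + 1L
  ow <- (d[2] - k) %/% stride + 1L
  i0 <- seq(1L, by = stride, length.out = oh)
  j0 <- seq(1L, by = stride, length.out = ow)
  out <- array(-Inf, c(oh, ow, d[3]))
  for (dj in seq_len(k)) {
    for (di in seq_len(k)) {
      out <- pmax(out, xp[i0 + di - 1L, j0 + dj - 1L, , drop = FALSE])
    }
  }
  out
}

global_avgpool <- function(x) {
  array(colMeans(matrix(x, dim(x)[1] * dim(x)[2], dim(x)[3])), c(1, 1, dim(x)[3]))
}
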