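# 2-D convolution with reflective boundary padding, shared by the synthetic
# renderer and the feature bank. EBImage::filter2 does the FFT work; we pad
# reflectively first so that boundary behaviour matches the documented rule.

# mirror-without-repeat index for arbitrary overshoot (period 2n - 2)
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  p <- 2L * n - 2L
  j <- (i - 1L) %% p
  ifelse(j >= n, p - j, j) + 1L
}

reflect_pad <- function(m, pr, pc = pr) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- reflect_index((1L - pr):(nr + pr), nr)
  ci <- reflect_index((1L - pc):(nc + pc), nc)
  m[ri, ci, drop = FALSE]
}

# correlation/convolution with an odd-sized kernel; symmetric kernels make
# the distinction moot, and Sobel/derivative kernels are stored pre-flipped
convolve_reflect <- function(m, kernel) {
  kr <- (nrow(kernel) - 1L) %/% 2L
  kc <- (ncol(kernel) - 1L) %/% 2L
  if (nrow(kernel) %% 2L == 0L || ncol(kernel) %% 2L == 0L)
    stop_validation("kernel dimensions must be odd")
  padded <- reflect_pad(m, kr, kc)
  out <- EBImage::filter2(padded, kernel, boundary = "circular")
  out[(kr + 1L):(kr + nrow(m)), (kc + 1L):(kc + ncol(m)), drop = FALSE]
}

gaussian_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  g <- exp(-(-r:r)^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

gaussian_blur <- function(m, sigma) convolve_reflect(m, gaussian_kernel(sigma))
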