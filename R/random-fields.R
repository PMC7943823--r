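#' Derive a reproducible sub-stream seed from a master seed
#'
#' Every stochastic stage of the generator draws from its own named
#' sub-stream so that stages can be re-run independently and adding a stage
#' never perturbs another stage's draws. Simple multiplicative mixing keeps
#' the result a valid 32-bit seed.
#' @keywords internal
sub_seed <- function(seed, stream) {
  offsets <- c(terrain = 11L, cover = 23L, logging = 37L, noise = 41L,
               density = 53L, plots = 67L, climate = 79L, subset = 97L,
               points = 113L)
  if (!stream %in% names(offsets)) stop("unknown RNG stream: ", stream)
  ((48271 * (as.double(seed) %% 44488) + offsets[[stream]]) %% 2147483647)
}

#' Simulate a stationary Gaussian random field with exponential correlogram
#'
#' Circulant embedding on a padded torus: the target covariance
#' `sigma^2 * exp(-d / range)` is wrapped onto a doubled grid, its eigenvalues
#' obtained by FFT, and one complex white-noise draw yields an exact sample
#' (up to clamping of the occasional small negative embedding eigenvalue,
#' which is negligible at the padding used here).
#'
#' @param nr,nc grid dimensions.
#' @param res cell size (m).
#' @param range correlogram range rho (m): correlation `exp(-d/rho)`.
#' @param sigma marginal standard deviation.
#' @return numeric `nr x nc` matrix. Uses the current RNG state.
#' @keywords internal
sim_grf_exp <- function(nr, nc, res, range, sigma = 1) {
  if (sigma == 0) return(matrix(0, nr, nc))
  if (range <= 0) return(matrix(stats::rnorm(nr * nc, sd = sigma), nr, nc))
  # pad to at least twice the extent plus several ranges, power-of-two FFT
  need_r <- 2 * nr + ceiling(4 * range / res)
  need_c <- 2 * nc + ceiling(4 * range / res)
  M1 <- 2^ceiling(log2(need_r)); M2 <- 2^ceiling(log2(need_c))
  d1 <- pmin(0:(M1 - 1), M1 - 0:(M1 - 1)) * res
  d2 <- pmin(0:(M2 - 1), M2 - 0:(M2 - 1)) * res
  dist <- sqrt(outer(d1^2, d2^2, "+"))
  covm <- sigma^2 * exp(-dist / range)
  lambda <- Re(stats::fft(covm))
  lambda[lambda < 0] <- 0
  eps <- matrix(complex(real = stats::rnorm(M1 * M2),
                        imaginary = stats::rnorm(M1 * M2)), M1, M2)
  field <- stats::fft(sqrt(lambda) * eps) / sqrt(M1 * M2)
  Re(field)[seq_len(nr), seq_len(nc)]
}

#' Simulate a smooth Gaussian field by kernel smoothing of white noise
#'
#' White noise convolved (via FFT on a padded grid) with a Gaussian kernel of
#' standard deviation `length_scale`, rescaled analytically to the requested
#' marginal standard deviation. Used for terrain and logging-intensity
#' surfaces, where a smooth (infinitely differentiable) field is wanted.
#'
#' @inheritParams sim_grf_exp
#' @param length_scale Gaussian kernel sd (m) controlling the correlation
#'   length of the resulting field.
#' @return numeric `nr x nc` matrix with marginal sd `sigma` (exactly, by the
#'   analytic normalization of the kernel's sum of squares).
#' @keywords internal
sim_smoothed_field <- function(nr, nc, res, length_scale, sigma = 1) {
  if (sigma == 0) return(matrix(0, nr, nc))
  if (length_scale <= 0) return(matrix(stats::rnorm(nr * nc, sd = sigma), nr, nc))
  s_cells <- length_scale / res
  pad <- ceiling(4 * s_cells)
  M1 <- 2^ceiling(log2(nr + 2 * pad)); M2 <- 2^ceiling(log2(nc + 2 * pad))
  k1 <- stats::dnorm(pmin(0:(M1 - 1), M1 - 0:(M1 - 1)), sd = s_cells)
  k2 <- stats::dnorm(pmin(0:(M2 - 1), M2 - 0:(M2 - 1)), sd = s_cells)
  kern <- outer(k1, k2)
  norm <- sqrt(sum(kern^2))           # var of smoothed unit white noise
  kern <- kern / norm
  w <- matrix(stats::rnorm(M1 * M2), M1, M2)
  sm <- Re(stats::fft(stats::fft(kern) * stats::fft(w), inverse = TRUE)) /
    (M1 * M2)
  sigma * sm[seq_len(nr), seq_len(nc)]
}
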