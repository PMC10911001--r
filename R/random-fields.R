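# Stationary Gaussian random fields on a regular grid by circulant embedding.
#
# Exponential covariance C(h) = exp(-|h| / range). The grid is embedded in a
# torus of twice the size; the covariance of the wrapped process is
# diagonalised by the 2-D DFT, so independent realizations cost one FFT each.
# Negative embedding eigenvalues (possible for non-smooth covariances on
# small embeddings) are clamped to zero — the standard approximate remedy.

grf_spectrum <- function(spec, range_km) {
  m1 <- 2L * spec$ny
  m2 <- 2L * spec$nx
  # toroidal lags in physical units
  iy <- c(0:(spec$ny), (spec$ny - 1):1)
  ix <- c(0:(spec$nx), (spec$nx - 1):1)
  dyy <- iy * spec$dy
  dxx <- ix * spec$dx
  d <- sqrt(outer(dyy^2, dxx^2, "+"))
  cov <- exp(-d / range_km)
  lam <- Re(stats::fft(cov))
  lam[lam < 0] <- 0
  list(lam = lam, m1 = m1, m2 = m2, ny = spec$ny, nx = spec$nx)
}

# n independent standard (unit-variance) GRF realizations; returns array
# c(n, ny, nx). Consumes RNG state: 2 * m1 * m2 normals per pair of fields.
grf_simulate <- function(spectrum, n) {
  m1 <- spectrum$m1
  m2 <- spectrum$m2
  scale <- sqrt(spectrum$lam / (m1 * m2))
  out <- array(0, dim = c(n, spectrum$ny, spectrum$nx))
  k <- 1L
  while (k <= n) {
    eps <- matrix(stats::rnorm(m1 * m2), m1, m2) +
      1i * matrix(stats::rnorm(m1 * m2), m1, m2)
    z <- stats::fft(scale * eps)
    out[k, , ] <- Re(z)[seq_len(spectrum$ny), seq_len(spectrum$nx)]
    k <- k + 1L
    if (k <= n) {
      out[k, , ] <- Im(z)[seq_len(spectrum$ny), seq_len(spectrum$nx)]
      k <- k + 1L
    }
  }
  out
}

# Evaluate a single GRF (matrix ny x nx) at points, by containing cell.
grf_at_points <- function(field, spec, x, y) {
  idx <- cell_index(spec, x, y)
  field[cbind(idx$row, idx$col)]
}

# Run code under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Counter-based child seeds so pipeline stages are individually reproducible.
child_seed <- function(seed, stage) {
  (as.double(seed) * 48271 + stage * 16807) %% 2147483647
}
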