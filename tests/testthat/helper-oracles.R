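# Shared fixtures and independent brute-force oracles for the test suite.
# Oracles deliberately avoid the package's vectorized/precomputed paths.

# Small filter bank for fast tests.
tiny_bank <- function(sigma = 3, r = 5 * pi / 8, n_freq = 8, stride = 2) {
  build_filter_bank(sigma = sigma, r = r, n_freq = n_freq, stride = stride)
}

# Small texture patch (make_texture enforces size >= 64; crop afterwards).
tiny_texture <- function(seed, size = 48) {
  make_texture(seed, 64)[seq_len(size), seq_len(size), drop = FALSE]
}

# Brute-force windowed quadrature sum at one centre and frequency.
oracle_quadrature_1 <- function(frame, sigma, rad, x0, y0, wx, wy) {
  a <- 0; b <- 0
  for (dy in -rad:rad) for (dx in -rad:rad) {
    u <- frame[y0 + dy, x0 + dx]
    w <- exp(-(dx^2 + dy^2) / (2 * sigma^2))
    a <- a + u * w * cos(wx * dx + wy * dy)
    b <- b - u * w * sin(wx * dx + wy * dy)
  }
  c(a = a, b = b)
}

# Brute-force Radon line integral of a field given as a function of
# (wx, wy), restricted to the disc |w| <= r, with a fine s-step.
oracle_radon_fun <- function(f, rho, theta, r, s_step) {
  smax <- sqrt(max(r^2 - rho^2, 0))
  if (smax == 0) return(0)
  s <- seq(-smax, smax, by = s_step)
  if (s[length(s)] < smax) s <- c(s, smax)
  px <- rho * cos(theta) + s * sin(theta)
  py <- rho * sin(theta) - s * cos(theta)
  inside <- px^2 + py^2 <= r^2 + 1e-12
  vals <- ifelse(inside, f(px, py), 0)
  sum((c(diff(s) / 2, 0) + c(0, diff(s) / 2)) * vals)
}

# Brute-force Radon of a gridded field: bilinear interpolation over the
# same Cartesian grid the package uses (independent reimplementation, with
# a finer quadrature step).
oracle_radon_grid <- function(field_vals, freqs, n_grid, r, rho, theta,
                              s_step) {
  step <- 2 * r / (n_grid - 1)
  w1 <- seq(-r, r, length.out = n_grid)
  grid_vals <- matrix(NA_real_, n_grid, n_grid) # [ix, iy]
  ix <- round((freqs$wx + r) / step) + 1
  iy <- round((freqs$wy + r) / step) + 1
  grid_vals[cbind(ix, iy)] <- field_vals
  interp <- function(px, py) {
    gx <- min(max(floor((px + r) / step) + 1, 1), n_grid - 1)
    gy <- min(max(floor((py + r) / step) + 1, 1), n_grid - 1)
    fx <- (px - w1[gx]) / step
    fy <- (py - w1[gy]) / step
    vv <- c(grid_vals[gx, gy], grid_vals[gx + 1, gy],
            grid_vals[gx, gy + 1], grid_vals[gx + 1, gy + 1])
    ww <- c((1 - fx) * (1 - fy), fx * (1 - fy),
            (1 - fx) * fy, fx * fy)
    ok <- !is.na(vv)
    if (!any(ok) || sum(ww[ok]) < 1e-12) {
      # nearest retained node (rim fallback, mirroring the operator's rule)
      j <- which.min((freqs$wx - px)^2 + (freqs$wy - py)^2)
      return(field_vals[j])
    }
    sum(vv[ok] * ww[ok]) / sum(ww[ok])
  }
  oracle_radon_fun(function(px, py)
    vapply(seq_along(px), function(i) interp(px[i], py[i]), numeric(1)),
    rho, theta, r, s_step)
}

# Brute-force Volterra response: direct double sum with separable
# second-order kernel, zero initial conditions.
oracle_volterra <- function(dc0, dc1, dc2, taps, x) {
  taps <- taps / sum(taps)
  L <- length(taps)
  y <- numeric(length(x))
  for (t in seq_along(x)) {
    lin <- 0
    for (s in 0:(L - 1)) if (t - s >= 1) lin <- lin + taps[s + 1] * x[t - s]
    quad <- 0
    for (s1 in 0:(L - 1)) for (s2 in 0:(L - 1))
      if (t - s1 >= 1 && t - s2 >= 1)
        quad <- quad + taps[s1 + 1] * taps[s2 + 1] * x[t - s1] * x[t - s2]
    y[t] <- dc0 + dc1 * lin + dc2 * quad
  }
  y
}

# Constant-image frame sequence.
const_seq <- function(value, hw = c(8, 8), n = 40) {
  frame_sequence(array(value, dim = c(hw, n)))
}
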