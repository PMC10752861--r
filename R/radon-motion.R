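#' Chord length of the frequency disc
#'
#' Length of the intersection of the line at signed distance `rho` from the
#' origin with the disc of radius `r`: `2*sqrt(r^2 - rho^2)` for
#' `|rho| < r`, 0 otherwise. This is the Radon transform of the disc
#' indicator and the normalizer used by the Phase Motion Indicator.
#'
#' @param rho signed line offset(s), rad/px.
#' @param r disc radius, rad/px (> 0).
#' @return Numeric vector of chord lengths.
#' @export
chord_length <- function(rho, r) {
  stopifnot(r > 0)
  ifelse(abs(rho) >= r, 0, 2 * sqrt(pmax(r^2 - rho^2, 0)))
}

#' Discretized Radon operator over the circular frequency domain
#'
#' Precomputes the quadrature for line integrals of a phase-gradient field
#' over the disc `|omega| <= r`: `n_theta` normal angles uniform in
#' `[0, pi)`, `n_rho` offsets uniform in `[-r, r]`, and for each line a set
#' of sample points at spacing `s_step` combined with bilinear interpolation
#' weights on the field's Cartesian frequency grid (points outside the disc
#' contribute zero, implementing the domain indicator). The whole operator
#' is stored as a dense weight matrix so a sinogram is a single matrix
#' product.
#'
#' @param bank_or_field a [build_filter_bank()] or `phase_gradient_field`
#'   supplying the frequency grid and disc radius.
#' @param n_theta number of angles (>= 16).
#' @param n_rho number of offsets (odd values place a sample at `rho = 0`).
#' @param s_step quadrature step along each line; default one eighth of the
#'   frequency grid spacing.
#' @param chord_frac lines with chord shorter than `chord_frac * 2r` are
#'   treated as near-tangent (their |sinogram|/chord integrand is
#'   interpolation-noise dominated and is extrapolated, not measured).
#' @return An object of class `radon_operator`.
#' @export
radon_operator <- function(bank_or_field, n_theta = 90, n_rho = 33,
                           s_step = NULL, chord_frac = 0.05) {
  stopifnot(n_theta >= 16, n_rho >= 9)
  x <- bank_or_field
  freqs <- x$freqs; r <- x$r
  n_grid <- x$n_freq
  step <- x$grid_step
  if (is.null(s_step)) s_step <- step / 8
  w1 <- seq(-r, r, length.out = n_grid)
  # column index of each kept disc frequency in the full n_grid^2 grid
  ix <- round((freqs$wx + r) / step) + 1
  iy <- round((freqs$wy + r) / step) + 1
  col_of_node <- rep(NA_integer_, n_grid * n_grid)
  col_of_node[(iy - 1) * n_grid + ix] <- seq_len(nrow(freqs))
  theta <- seq(0, pi, length.out = n_theta + 1)[seq_len(n_theta)]
  rho <- seq(-r, r, length.out = n_rho)
  chord <- chord_length(rho, r)
  W <- matrix(0, n_theta * n_rho, nrow(freqs))
  for (i in seq_len(n_theta)) {
    ct <- cos(theta[i]); st <- sin(theta[i])
    for (j in seq_len(n_rho)) {
      smax <- sqrt(max(r^2 - rho[j]^2, 0))
      if (smax == 0) next
      s <- seq(-smax, smax, by = s_step)
      if (length(s) < 2) { s <- 0; wq <- 2 * smax } else {
        if (s[length(s)] < smax) s <- c(s, smax)
        wq <- c(diff(s) / 2, 0) + c(0, diff(s) / 2) # trapezoid
      }
      px <- rho[j] * ct + s * st
      py <- rho[j] * st - s * ct
      inside <- px^2 + py^2 <= r^2 + 1e-12
      px <- clamp(px[inside], -r, r); py <- clamp(py[inside], -r, r)
      wq <- wq[inside]
      if (!length(wq)) next
      gx <- clamp(floor((px + r) / step) + 1, 1, n_grid - 1)
      gy <- clamp(floor((py + r) / step) + 1, 1, n_grid - 1)
      fx <- (px - w1[gx]) / step
      fy <- (py - w1[gy]) / step
      row <- (i - 1) * n_rho + j
      # bilinear corner weights; corners of the cell that fall outside the
      # retained disc nodes get their weight redistributed to the available
      # corners (the line itself stays inside the disc)
      cw <- matrix(0, length(wq), 4)
      cols4 <- matrix(NA_integer_, length(wq), 4)
      for (corner in 1:4) {
        cx <- gx + (corner == 2 | corner == 4)
        cy <- gy + (corner >= 3)
        wxc <- if (corner %in% c(2, 4)) fx else 1 - fx
        wyc <- if (corner >= 3) fy else 1 - fy
        cw[, corner] <- wxc * wyc
        cols4[, corner] <- col_of_node[(cy - 1) * n_grid + cx]
      }
      cw[is.na(cols4)] <- 0
      wsum <- rowSums(cw)
      valid <- wsum > 1e-12
      acc <- numeric(nrow(freqs))
      # rim samples whose whole cell lies outside the retained nodes:
      # fall back to the nearest retained node
      for (b in which(!valid & wq > 0)) {
        nn <- which.min((freqs$wx - px[b])^2 + (freqs$wy - py[b])^2)
        acc[nn] <- acc[nn] + wq[b]
      }
      for (corner in 1:4) {
        wt <- ifelse(valid, cw[, corner] / pmax(wsum, 1e-300), 0) * wq
        ok <- !is.na(cols4[, corner]) & wt != 0
        if (any(ok)) {
          tab <- rowsum(wt[ok], cols4[ok, corner])
          ridx <- as.integer(rownames(tab))
          acc[ridx] <- acc[ridx] + tab[, 1]
        }
      }
      W[row, ] <- acc
    }
  }
  structure(list(theta = theta, rho = rho, r = r, chord = chord,
                 n_theta = n_theta, n_rho = n_rho, s_step = s_step,
                 chord_frac = chord_frac, weights = W, freqs = freqs),
            class = "radon_operator")
}

#' @export
print.radon_operator <- function(x, ...) {
  cat(sprintf("<radon_operator> %d angles x %d offsets, r = %.4g rad/px, s-step %.3g\n",
              x$n_theta, x$n_rho, x$r, x$s_step))
  invisible(x)
}

#' Radon transform of a phase-gradient field (sinogram)
#'
#' Line integrals of the field over the circular frequency domain, for every
#' (offset, angle) pair of the operator's grid. For a field that is the
#' plane `-vx*wx - vy*wy` (pure translation), the sinogram is
#' `rho * (-vx*cos(theta) - vy*sin(theta)) * chord(rho)`.
#'
#' @param field a `phase_gradient_field` (or any matrix of field values on
#'   the operator's frequency set, centres in rows).
#' @param op a [radon_operator()] built on the same frequency grid.
#' @return Object of class `sinogram`: matrix centres x (rho, theta) values.
#' @export
radon_circular <- function(field, op) {
  stopifnot(inherits(op, "radon_operator"))
  vals <- if (inherits(field, "phase_gradient_field")) {
    if (!isTRUE(all.equal(field$r, op$r)) ||
        nrow(field$freqs) != nrow(op$freqs))
      stopf("field and radon_operator were built on different frequency grids")
    field$dphi
  } else if (is.matrix(field)) field else matrix(field, nrow = 1)
  if (ncol(vals) != ncol(op$weights))
    stopf("field has %d frequencies, operator expects %d",
          ncol(vals), ncol(op$weights))
  structure(list(values = vals %*% t(op$weights), op = op),
            class = "sinogram")
}

# Chord-normalized |sinogram| integrand on the rho grid, with near-tangent
# lines replaced by linear extrapolation from the adjacent interior nodes.
# Returns an array n_centers x n_rho x n_theta.
pmi_integrand <- function(sino) {
  op <- sino$op
  g <- array(abs(sino$values), dim = c(nrow(sino$values), op$n_rho, op$n_theta))
  keep <- op$chord >= op$chord_frac * 2 * op$r
  for (j in which(keep)) g[, j, ] <- g[, j, ] / op$chord[j]
  bad <- which(!keep)
  for (j in bad) {
    if (j <= 2 && op$n_rho >= 3 && keep[j + 1] && keep[j + 2]) {
      g[, j, ] <- pmax(2 * g[, j + 1, ] - g[, j + 2, ], 0)
    } else if (j >= op$n_rho - 1 && keep[j - 1] && keep[j - 2]) {
      g[, j, ] <- pmax(2 * g[, j - 1, ] - g[, j - 2, ], 0)
    } else {
      g[, j, ] <- 0
    }
  }
  g
}

#' Phase Motion Indicator
#'
#' Integrates the chord-normalized absolute sinogram over offsets
#' (trapezoid rule; near-tangent offsets are linearly extrapolated rather
#' than divided by a vanishing chord) and maximizes over angles. For a
#' planar phase-gradient field induced by translation at velocity `v`, the
#' PMI equals `r^2 * |v|` and the maximizing angle is the motion angle
#' modulo pi. The discrete argmax is refined by parabolic interpolation of
#' the PMI profile around its peak (the profile is pi-periodic in theta).
#'
#' @param sino a [radon_circular()] sinogram.
#' @param op the [radon_operator()] (defaults to the one stored in `sino`).
#' @param refine logical: sub-grid parabolic refinement of `theta_hat`.
#' @return A tibble with one row per centre: `pmi`, `theta_hat` (radians in
#'   `[0, pi)`, `NA` when the sinogram is all zero), `theta_idx` (grid index
#'   of the maximizing angle).
#' @export
pmi <- function(sino, op = NULL, refine = TRUE) {
  stopifnot(inherits(sino, "sinogram"))
  if (is.null(op)) op <- sino$op
  g <- pmi_integrand(sino)
  drho <- diff(op$rho)[1]
  wtrap <- rep(drho, op$n_rho); wtrap[c(1, op$n_rho)] <- drho / 2
  prof <- apply(g * rep(wtrap, each = dim(g)[1]), c(1, 3), sum) # centres x theta
  if (is.null(dim(prof))) prof <- matrix(prof, nrow = 1)
  idx <- apply(prof, 1, which.max)
  val <- prof[cbind(seq_len(nrow(prof)), idx)]
  theta_hat <- op$theta[idx]
  if (refine) {
    nt <- op$n_theta
    im <- ((idx - 2) %% nt) + 1
    ip <- (idx %% nt) + 1
    gm <- prof[cbind(seq_len(nrow(prof)), im)]
    gp <- prof[cbind(seq_len(nrow(prof)), ip)]
    den <- gm - 2 * val + gp
    off <- ifelse(abs(den) > 1e-12 * pmax(val, 1e-300),
                  clamp(0.5 * (gm - gp) / den, -0.5, 0.5), 0)
    dtheta <- pi / nt
    # keep the refined angle unwrapped (it may dip just below 0 when the
    # peak sits at the first grid angle) so that the direction-sign rule,
    # which is evaluated at the grid angle, stays consistent
    theta_hat <- op$theta[idx] + off * dtheta
    val <- pmax(val - 0.25 * (gm - gp) * off, val)
  }
  zero <- val <= 0
  tibble::tibble(pmi = val,
                 theta_hat = ifelse(zero, NA_real_, theta_hat),
                 theta_idx = ifelse(zero, NA_integer_, idx))
}

#' Direction disambiguation along the PMI angle
#'
#' The PMI angle is defined modulo pi; the actual direction is fixed by the
#' sign of the chord-normalized sinogram at positive offsets along the
#' maximizing angle: a negative sign means motion along `theta_hat`, a
#' positive sign motion along `theta_hat + pi`.
#'
#' @param sino a [radon_circular()] sinogram.
#' @param theta_idx integer vector of maximizing-angle grid indices (from
#'   [pmi()]), one per centre; `NA` propagates.
#' @param op the [radon_operator()] (defaults to the one stored in `sino`).
#' @return Integer vector in `{-1, +1}` (`NA` for undefined angle or an
#'   exact-zero tie).
#' @export
resolve_direction <- function(sino, theta_idx, op = NULL) {
  stopifnot(inherits(sino, "sinogram"))
  if (is.null(op)) op <- sino$op
  s <- array(sino$values, dim = c(nrow(sino$values), op$n_rho, op$n_theta))
  pos <- which(op$rho > 0 & op$chord >= op$chord_frac * 2 * op$r)
  out <- rep(NA_integer_, nrow(sino$values))
  for (i in seq_len(nrow(sino$values))) {
    if (is.na(theta_idx[i])) next
    ssum <- sum(s[i, pos, theta_idx[i]] / op$chord[pos])
    if (ssum != 0) out[i] <- as.integer(sign(ssum))
  }
  out
}

#' Velocity vector from PMI, angle and direction sign
#'
#' Inverts `PMI = r^2 * |v|`: speed is `pmi / r^2` and the motion angle is
#' `theta_hat` when `direction_sign == -1`, `theta_hat + pi` otherwise.
#' Speeds above `pi / r` px/frame exceed the phase-aliasing bound and are
#' flagged.
#'
#' @param pmi_value nonnegative PMI value(s).
#' @param theta_hat PMI angle(s) in `[0, pi)`.
#' @param direction_sign -1 or +1 per centre (see [resolve_direction()]).
#' @param r disc radius of the detector, rad/px.
#' @return Tibble with `vx`, `vy`, `speed`, `angle` (radians in `[0, 2pi)`,
#'   image coordinates with y pointing down) and logical `aliased`.
#' @export
estimate_velocity <- function(pmi_value, theta_hat, direction_sign, r) {
  stopifnot(all(pmi_value >= 0, na.rm = TRUE), r > 0)
  speed <- pmi_value / r^2
  psi <- (theta_hat + ifelse(direction_sign < 0, 0, pi)) %% (2 * pi)
  tibble::tibble(vx = speed * cos(psi), vy = speed * sin(psi),
                 speed = speed, angle = psi,
                 aliased = speed > max_unaliased_speed(r) + 1e-12)
}

#' Maximum speed free of phase aliasing
#'
#' A translation by `k` px/frame shifts the local phase at frequency
#' `omega` by `k * omega` per frame; once this exceeds pi the shift wraps
#' and becomes ambiguous, so speeds are recoverable only up to `pi / r` for
#' a detector using frequencies up to radius `r`.
#'
#' @param r disc radius, rad/px.
#' @return Speed bound in px/frame (e.g. 1.6 for `r = 5*pi/8`).
#' @export
max_unaliased_speed <- function(r) {
  stopifnot(r > 0)
  pi / r
}

#' End-to-end phase-based motion detection on a frame sequence
#'
#' Runs the full second-stage pipeline: quadrature filtering of each frame,
#' DNP phase derivative across consecutive frame pairs, circular-domain
#' Radon transform, PMI maximization, direction disambiguation and velocity
#' estimation, at a set of detection centres.
#'
#' @param seq a [frame_sequence()] (>= 2 frames).
#' @param bank a [build_filter_bank()]; default bank with `r = 5*pi/8`.
#' @param op a [radon_operator()]; default built from `bank`.
#' @param centers tibble of detection centres (`x`, `y`); default: stride
#'   grid over the valid interior.
#' @param pairs integer vector of frame indices `t` for which the pair
#'   `(t-1, t)` is evaluated; default: all pairs.
#' @param tau PMI detection threshold; default `0.05 * r^2` (i.e. an
#'   apparent speed of 0.05 px/frame).
#' @param method phase-derivative method, see [phase_derivative_dnp()].
#' @return A tibble with one row per centre and frame pair: `x`, `y`, `t`,
#'   `pmi`, `theta_hat`, `direction_sign`, `vx`, `vy`, `speed`, `angle`,
#'   `detected`, `aliased`.
#' @export
detect_motion <- function(seq, bank = build_filter_bank(), op = NULL,
                          centers = NULL, pairs = NULL, tau = NULL,
                          method = "atan") {
  stopifnot(inherits(seq, "frame_sequence"))
  if (n_frames(seq) < 2) stopf("motion needs at least 2 frames")
  if (is.null(op)) op <- radon_operator(bank)
  if (is.null(centers)) centers <- default_centers(dim(seq)[1:2], bank)
  if (is.null(pairs)) pairs <- 2:n_frames(seq)
  if (is.null(tau)) tau <- 0.05 * bank$r^2
  stopifnot(all(pairs >= 2), all(pairs <= n_frames(seq)))
  q_cache <- new.env(parent = emptyenv())
  quad <- function(t) {
    k <- as.character(t)
    if (is.null(q_cache[[k]]))
      q_cache[[k]] <- compute_quadrature(get_frame(seq, t), bank, centers)
    q_cache[[k]]
  }
  res <- purrr::map_dfr(pairs, function(t) {
    fld <- phase_derivative_dnp(quad(t), quad(t - 1), method = method)
    rm(list = as.character(t - 1), envir = q_cache)
    sino <- radon_circular(fld, op)
    est <- pmi(sino, op)
    est$direction_sign <- resolve_direction(sino, est$theta_idx, op)
    vel <- estimate_velocity(est$pmi, est$theta_hat, est$direction_sign, bank$r)
    dplyr::bind_cols(
      tibble::tibble(x = centers$x, y = centers$y, t = t),
      est[c("pmi", "theta_hat", "direction_sign")], vel)
  })
  res$detected <- res$pmi > tau & !is.na(res$theta_hat) &
    !is.na(res$direction_sign)
  class(res) <- c("motion_estimates", class(res))
  res
}
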