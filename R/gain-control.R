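#' Parameters of the photoreceptor/amacrine-cell gain-control DNP
#'
#' The divisive normalization processor computes, per channel (pixel),
#' `v = T1(u) / (T2(u) + T3(v) + L4(v_pool))`: a Volterra-processed input
#' divided by the sum of a second Volterra term on the input, a local
#' feedback term on the channel's own output, and a pooled (multi-input)
#' feedback term over a spatial neighbourhood of channel outputs. Only the
#' kernels' DC sums matter for steady-state behaviour; temporal dynamics use
#' exponential low-pass taps of time constant `tau` frames.
#'
#' In normalized mode (`c2 == a2`, coefficients positive, `c1 >= a1`,
#' `a0/c0 < 1`) the feedforward steady-state response is a monotone sigmoid
#' of `log10(I)` with range (0, 1).
#'
#' @param a DC sums `(a0, a1, a2)` of the numerator processor T1 (> 0).
#' @param cc DC sums `(c0, c1, c2)` of the input normalizer T2 (> 0).
#' @param d DC sums `(d0, d1, d2)` of the local feedback T3 (>= 0; zeros
#'   reduce to the feedforward processor).
#' @param tau tap time constant, frames.
#' @param mvp pooled-feedback description: list with `b4` (constant), `r1`
#'   (total first-order DC over the pool), `r2` (total second-order DC),
#'   `patch` (side of the square pooling block in channels; pooling weights
#'   are uniform).
#' @return Object of class `dnp_params`.
#' @export
dnp_params <- function(a = c(1e-3, 0.1, 1), cc = c(1, 0.2, 1),
                       d = c(0, 0, 0), tau = 2,
                       mvp = list(b4 = 0, r1 = 1, r2 = 0, patch = 16)) {
  stopifnot(length(a) == 3, length(cc) == 3, length(d) == 3)
  if (any(a <= 0) || any(cc <= 0))
    stopf("feedforward coefficients a0..a2, c0..c2 must be positive")
  if (any(d < 0)) stopf("feedback coefficients d0..d2 must be nonnegative")
  mvp <- utils::modifyList(list(b4 = 0, r1 = 1, r2 = 0, patch = 16), mvp)
  if (cc[2] < a[2] - 1e-12)
    warning("c1 < a1: the steady-state response may be non-monotone in I")
  structure(list(a = a, cc = cc, d = d, tau = tau, mvp = mvp,
                 normalized = isTRUE(all.equal(a[3], cc[3]))),
            class = "dnp_params")
}

#' @export
print.dnp_params <- function(x, ...) {
  cat(sprintf("<dnp_params> a = (%g, %g, %g), c = (%g, %g, %g), d = (%g, %g, %g)\n",
              x$a[1], x$a[2], x$a[3], x$cc[1], x$cc[2], x$cc[3],
              x$d[1], x$d[2], x$d[3]))
  cat(sprintf("  tau = %g frames; MVP: b4 = %g, r1 = %g, r2 = %g, patch = %d; normalized: %s\n",
              x$tau, x$mvp$b4, x$mvp$r1, x$mvp$r2, x$mvp$patch,
              x$normalized))
  invisible(x)
}

#' Feedforward steady-state response
#'
#' Closed form for constant input intensity `I`:
#' `v(I) = (a0 + a1 I + a2 I^2) / (c0 + c1 I + c2 I^2)`. With `c2 = a2` the
#' response is a sigmoid of `log10(I)` rising from `a0/c0` at `I = 0` to 1
#' as `I -> Inf`; `c1 >= a1` guarantees monotonicity.
#'
#' @param I nonnegative intensity (vectorized).
#' @param params a [dnp_params()].
#' @return Steady-state output, same length as `I`.
#' @export
steady_state_ff <- function(I, params) {
  stopifnot(inherits(params, "dnp_params"), all(I >= 0))
  a <- params$a; cc <- params$cc
  (a[1] + a[2] * I + a[3] * I^2) / (cc[1] + cc[2] * I + cc[3] * I^2)
}

# Vectorized positive real root of d2 v^3 + d1 v^2 + C v + A = 0 via the
# Cardano branch formulas (Delta0 = d1^2 - 3 d2 C,
# Delta1 = 2 d1^3 - 9 d2 d1 C + 27 d2^2 A); all three cube-root branches are
# evaluated and the positive real root selected.
cardano_positive_root <- function(d1, d2, C, A) {
  n <- length(C)
  if (d2 == 0) {
    if (d1 == 0) return(-A / C)
    # algebraically (-C + sqrt(C^2 - 4 d1 A)) / (2 d1); this form avoids
    # the catastrophic cancellation of -C + sqrt(C^2 + small) at large I
    return(-2 * A / (C + sqrt(C^2 - 4 * d1 * A)))
  }
  delta0 <- d1^2 - 3 * d2 * C
  delta1 <- 2 * d1^3 - 9 * d2 * d1 * C + 27 * d2^2 * A
  disc <- sqrt(as.complex(delta1^2 - 4 * delta0^3))
  D <- (delta1 + disc) / 2
  # avoid the degenerate cube root when Delta1 + sqrt(disc) == 0
  alt <- (delta1 - disc) / 2
  D <- ifelse(Mod(D) < 1e-300, alt, D)
  D <- D^(1 / 3)
  xi <- complex(real = -0.5, imaginary = sqrt(3) / 2)
  best <- rep(NA_real_, n)
  best_im <- rep(Inf, n)
  for (k in 0:2) {
    Dk <- D * xi^k
    vk <- -(d1 + Dk + delta0 / Dk) / (3 * d2)
    ok <- abs(Im(vk)) < 1e-7 * pmax(1, Mod(vk)) & Re(vk) > 0
    take <- ok & abs(Im(vk)) < best_im
    best[take] <- Re(vk)[take]
    best_im[take] <- abs(Im(vk))[take]
  }
  if (anyNA(best))
    stopf("no positive real root found for %d inputs (should not occur with positive coefficients)",
          sum(is.na(best)))
  best
}

#' Steady-state response with local feedback
#'
#' Closed form for constant input `I` of the DNP with feedforward and local
#' feedback: the output is the unique positive real root of
#' `d2 v^3 + d1 v^2 + C v + A = 0` with `A = -(a0 + a1 I + a2 I^2)` and
#' `C = c0 + d0 + c1 I + c2 I^2` (uniqueness follows from one sign change
#' among positive coefficients). `method = "polyroot"` uses the standard
#' polynomial root finder; `method = "cardano"` evaluates the closed
#' cube-root branch formulas (vectorized); both agree to numerical
#' precision. Increasing the feedback strength `d1` (or `d2`) decreases the
#' slope of the sigmoid.
#'
#' @inheritParams steady_state_ff
#' @param method `"polyroot"` or `"cardano"`.
#' @param w optional extra additive divisor (adaptive feedback state),
#'   recycled over `I`.
#' @return Steady-state output, same length as `I`.
#' @export
steady_state_fb <- function(I, params, method = c("polyroot", "cardano"),
                            w = 0) {
  stopifnot(inherits(params, "dnp_params"), all(I >= 0))
  method <- match.arg(method)
  a <- params$a; cc <- params$cc; d <- params$d
  A <- -(a[1] + a[2] * I + a[3] * I^2)
  C <- cc[1] + d[1] + cc[2] * I + cc[3] * I^2 + w
  d1 <- d[2]; d2 <- d[3]
  if (method == "cardano") return(cardano_positive_root(d1, d2, C, A))
  vapply(seq_along(I), function(i) {
    if (d2 == 0 && d1 == 0) return(-A[i] / C[i])
    coefs <- if (d2 == 0) c(A[i], C[i], d1) else c(A[i], C[i], d1, d2)
    roots <- polyroot(coefs)
    real <- Re(roots)[abs(Im(roots)) < 1e-7 * pmax(1, Mod(roots))]
    pos <- real[real > 0]
    if (!length(pos)) stopf("no positive real root at I = %g", I[i])
    pos[1]
  }, numeric(1))
}

# Pooling block id per channel for an H x W channel layout (uniform MVP
# neighbourhood of `patch` x `patch` channels); matrix inputs with no
# spatial layout pool globally.
block_ids <- function(frame_dim, patch) {
  if (is.null(frame_dim)) return(NULL)
  by <- (seq_len(frame_dim[1]) - 1) %/% patch
  bx <- (seq_len(frame_dim[2]) - 1) %/% patch
  as.vector(outer(by, bx * (max(by) + 1), `+`)) + 1L
}

# Shared engine: simulate the DNP over a channels x T input matrix.
# `w_fun(t, v_fun)` optionally supplies the adaptive divisor per block.
dnp_engine <- function(u_mat, params, variant, blocks = NULL,
                       adaptive = NULL) {
  a <- params$a; cc <- params$cc; d <- params$d
  nch <- nrow(u_mat); Tn <- ncol(u_mat)
  n <- ceiling(8 * params$tau) + 1
  ff <- exp(-(0:(n - 1)) / params$tau); ff <- ff / sum(ff)
  fb <- exp(-(1:n) / params$tau); fb <- fb / sum(fb) # delayed (lags 1..n)
  fu <- taps_filter(u_mat, ff, 0:(n - 1))
  t1 <- a[1] + a[2] * fu + a[3] * fu^2
  t2 <- cc[1] + cc[2] * fu + cc[3] * fu^2
  use_local <- variant %in% c("local_fb", "mvp_fb", "adaptive") && any(d > 0)
  use_mvp <- variant %in% c("mvp_fb")
  if (is.null(blocks)) blocks <- rep(1L, nch)
  nb <- max(blocks)
  bsize <- tabulate(blocks, nb)
  mvp <- params$mvp
  v <- matrix(0, nch, Tn)
  w_trace <- matrix(0, nb, Tn)
  w <- if (!is.null(adaptive)) rep(adaptive$w0, nb) else rep(0, nb)
  target <- 0.5 * (mvp$b4 + mvp$r1 + mvp$r2)
  for (t in seq_len(Tn)) {
    fv <- numeric(nch)   # delayed tap-filtered own output
    if (use_local || use_mvp || !is.null(adaptive)) {
      for (k in seq_along(fb)) {
        ts <- t - k
        if (ts >= 1) fv <- fv + fb[k] * v[, ts]
      }
    }
    t3 <- if (use_local) d[1] + d[2] * fv + d[3] * fv^2 else 0
    l4 <- 0
    if (use_mvp) {
      pool <- rowsum(fv, blocks)[, 1] / bsize
      l4 <- (mvp$b4 + mvp$r1 * pool + mvp$r2 * pool^2)[blocks]
    }
    denom_fixed <- t2[, t] + t3 + l4
    if (is.null(adaptive)) {
      den <- denom_fixed
      if (any(den <= 0))
        stopf("nonpositive DNP denominator at t = %d, channel %d",
              t, which(den <= 0)[1])
      v[, t] <- t1[, t] / den
    } else {
      v_of_w <- function(wb) t1[, t] / (denom_fixed + wb[blocks])
      l4_of_v <- function(vv) {
        pool <- rowsum(vv, blocks)[, 1] / bsize
        mvp$b4 + mvp$r1 * pool + mvp$r2 * pool^2
      }
      if (adaptive$solver == "euler") {
        nsub <- max(1L, round(1 / adaptive$dt_ode))
        for (s in seq_len(nsub)) {
          vv <- v_of_w(w)
          w <- pmax(w + adaptive$alpha * (1 / nsub) * (l4_of_v(vv) - target), 0)
          if (any(!is.finite(w)))
            stopf("adaptive state diverged at t = %d", t)
        }
      } else { # quasi_steady: alpha -> Inf limit of the integrator
        for (bidx in seq_len(nb)) {
          sel <- blocks == bidx
          g <- function(wb) {
            vv <- t1[sel, t] / (denom_fixed[sel] + wb)
            m <- mean(vv)
            mvp$b4 + mvp$r1 * m + mvp$r2 * m^2 - target
          }
          if (g(0) <= 0) { w[bidx] <- 0; next }
          hi <- 1
          while (g(hi) > 0 && hi < 1e18) hi <- hi * 10
          if (hi >= 1e18) stopf("adaptive state diverged at t = %d", t)
          w[bidx] <- stats::uniroot(g, c(0, hi), tol = 1e-10 * max(1, hi))$root
        }
      }
      v[, t] <- v_of_w(w)
      w_trace[, t] <- w
    }
  }
  list(v = v, w_trace = w_trace)
}

#' Simulate the gain-control DNP on a frame sequence
#'
#' Runs the discrete-time divisive normalization loop per channel (pixel):
#' at each frame the output is `T1(u) / (T2(u) + T3(v) + L4(v))`, with the
#' feedback terms evaluated on outputs up to the previous frame (one-step
#' delayed causal loop). Variants: `"ff"` (feedforward only), `"local_fb"`
#' (adds per-channel feedback T3), `"mvp_fb"` (adds the pooled uniform MVP
#' feedback over `patch x patch` neighbourhoods, which shifts the operating
#' curve with the local brightness level).
#'
#' @param u a [frame_sequence()] with nonnegative intensities, or a
#'   channels x T matrix.
#' @param params a [dnp_params()].
#' @param variant `"ff"`, `"local_fb"` or `"mvp_fb"`.
#' @return Same container as `u` with the channel outputs (in (0, 1) in
#'   normalized mode).
#' @export
dnp_simulate <- function(u, params, variant = c("ff", "local_fb", "mvp_fb")) {
  variant <- match.arg(variant)
  stopifnot(inherits(params, "dnp_params"))
  is_seq <- inherits(u, "frame_sequence")
  if (is_seq) {
    fd <- dim(u$frames)[1:2]
    u_mat <- matrix(u$frames, prod(fd), dim(u$frames)[3])
    blocks <- block_ids(fd, params$mvp$patch)
  } else {
    u_mat <- if (is.null(dim(u))) matrix(u, nrow = 1) else u
    blocks <- NULL
    fd <- NULL
  }
  if (any(u_mat < 0)) stopf("DNP inputs must be nonnegative")
  out <- dnp_engine(u_mat, params, variant, blocks)$v
  if (is_seq)
    frame_sequence(array(out, dim = c(fd, ncol(out))),
                   dt = u$dt, intensity_scale = "dnp-normalized",
                   flow = u$flow)
  else if (is.null(dim(u))) drop(out) else out
}

#' Simulate the adaptive-feedback DNP
#'
#' Replaces the pooled MVP divisor with a dynamic state `w` per pooling
#' block, integrated as `dw/dt = alpha * (L4(v) - 0.5 * (b4 + r1 + r2))`
#' and clamped at 0. At steady state on constant input the pooled MVP
#' output equals its half-range value, which for a first-order-only uniform
#' MVP centres the mean channel output at 0.5 regardless of the input
#' scale. `solver = "euler"` integrates with forward-Euler substeps of
#' `dt_ode` frames; `solver = "quasi_steady"` takes the fast-adaptation
#' limit (per-frame root solve for the centred `w`), which tracks abrupt
#' brightness steps of several orders of magnitude that a fixed small
#' `alpha` cannot follow within a staircase period.
#'
#' @inheritParams dnp_simulate
#' @param alpha adaptation rate (> 0), 1/frames.
#' @param dt_ode Euler substep, frames.
#' @param w0 initial adaptive state.
#' @param solver `"euler"` or `"quasi_steady"`.
#' @return List with `v` (same container as `u`) and `w_trace`
#'   (blocks x T matrix of the adaptive state).
#' @export
adaptive_simulate <- function(u, params, alpha = 0.5, dt_ode = 0.1, w0 = 0,
                              solver = c("euler", "quasi_steady")) {
  solver <- match.arg(solver)
  stopifnot(inherits(params, "dnp_params"), alpha > 0 || solver == "quasi_steady")
  is_seq <- inherits(u, "frame_sequence")
  if (is_seq) {
    fd <- dim(u$frames)[1:2]
    u_mat <- matrix(u$frames, prod(fd), dim(u$frames)[3])
    blocks <- block_ids(fd, params$mvp$patch)
  } else {
    u_mat <- if (is.null(dim(u))) matrix(u, nrow = 1) else u
    blocks <- NULL
    fd <- NULL
  }
  if (any(u_mat < 0)) stopf("DNP inputs must be nonnegative")
  res <- dnp_engine(u_mat, params, "adaptive", blocks,
                    adaptive = list(alpha = alpha, dt_ode = dt_ode, w0 = w0,
                                    solver = solver))
  v <- if (is_seq)
    frame_sequence(array(res$v, dim = c(fd, ncol(res$v))),
                   dt = u$dt, intensity_scale = "dnp-normalized",
                   flow = u$flow)
  else if (is.null(dim(u))) drop(res$v) else res$v
  list(v = v, w_trace = res$w_trace)
}

#' Converged adaptive-DNP response to a constant image
#'
#' Drives the adaptive-feedback DNP with a constant-intensity input (one
#' image held fixed) and integrates the adaptation state with forward Euler
#' until `|dw/dt| < tol`, using the steady-state channel response at the
#' current `w` (local feedback resolved by its closed form). Returns the
#' converged outputs, whose spatial mean is 0.5 for a first-order-only
#' uniform MVP whenever centring is attainable (`w >= 0`).
#'
#' @param image numeric matrix of nonnegative intensities (the constant
#'   input; pooled as a single block).
#' @param params a [dnp_params()].
#' @param alpha adaptation rate (> 0).
#' @param dt_ode Euler substep, frames.
#' @param tol convergence threshold on `|dw/dt|`.
#' @param max_steps iteration budget.
#' @param solver `"euler"` (explicit integration of the adaptation state)
#'   or `"fixed_point"` (direct root solve for the converged `w`; same
#'   fixed point, useful when the required divisor is orders of magnitude
#'   large and the bounded Euler slew rate would need many steps).
#' @return List with `v` (matrix of converged outputs), `w`, `steps`,
#'   `converged`, `dwdt`.
#' @export
adaptive_steady_state <- function(image, params, alpha = 0.5, dt_ode = 0.1,
                                  tol = 1e-8, max_steps = 1e6,
                                  solver = c("euler", "fixed_point")) {
  stopifnot(is.matrix(image), all(image >= 0), alpha > 0)
  solver <- match.arg(solver)
  I <- as.vector(image)
  mvp <- params$mvp
  target <- 0.5 * (mvp$b4 + mvp$r1 + mvp$r2)
  v_of_w <- function(w) steady_state_fb(I, params, method = "cardano", w = w)
  if (solver == "fixed_point") {
    g <- function(w) {
      m <- mean(v_of_w(w))
      alpha * (mvp$b4 + mvp$r1 * m + mvp$r2 * m^2 - target)
    }
    if (g(0) <= 0) {
      w <- 0
    } else {
      hi <- 1
      while (g(hi) > 0 && hi < 1e18) hi <- hi * 10
      if (hi >= 1e18) stopf("adaptive state diverged")
      w <- stats::uniroot(g, c(0, hi), tol = 1e-12 * max(1, hi))$root
    }
    return(list(v = matrix(v_of_w(w), nrow(image), ncol(image)), w = w,
                steps = NA_integer_, converged = TRUE, dwdt = g(w)))
  }
  w <- 0; steps <- 0L; dwdt <- Inf
  repeat {
    vv <- v_of_w(w)
    m <- mean(vv)
    dwdt <- alpha * (mvp$b4 + mvp$r1 * m + mvp$r2 * m^2 - target)
    if (abs(dwdt) < tol || (w == 0 && dwdt < 0)) break
    w <- max(w + dt_ode * dwdt, 0)
    steps <- steps + 1L
    if (!is.finite(w) || steps >= max_steps)
      stopf("adaptive state failed to converge within %d steps", max_steps)
  }
  list(v = matrix(v_of_w(w), nrow(image), ncol(image)), w = w,
       steps = steps, converged = abs(dwdt) < tol || (w == 0 && dwdt < 0),
       dwdt = dwdt)
}
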