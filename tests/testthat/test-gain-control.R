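test_that("volterra processors: DC response, identity, causality, oracle", {
  k <- volterra_kernels(dc0 = 0.4, dc1 = 1.5, dc2 = 0.8, tau = 2)
  x <- rep(3, 80)
  y <- volterra_apply(k, x)
  expect_equal(y[80], 0.4 + 1.5 * 3 + 0.8 * 9, tolerance = 1e-9)
  # unit impulse first-order kernel, no second order: identity
  kid <- volterra_kernels(dc0 = 0, dc1 = 1, dc2 = 0, taps = 1)
  set.seed(3); z <- stats::runif(30)
  expect_equal(volterra_apply(kid, z), z)
  expect_error(volterra_kernels(taps = c(1, 2), lags = c(-1, 0)),
               "causal")
  # random taps and signal vs brute-force double sum
  set.seed(9)
  taps <- stats::runif(6)
  x2 <- stats::rnorm(40)
  k2 <- volterra_kernels(dc0 = 0.2, dc1 = 0.7, dc2 = 1.3, taps = taps)
  expect_equal(volterra_apply(k2, x2),
               oracle_volterra(0.2, 0.7, 1.3, taps, x2), tolerance = 1e-12)
})

test_that("feedforward steady state: limits, normalization, monotonicity", {
  p <- dnp_params()
  expect_equal(steady_state_ff(0, p), p$a[1] / p$cc[1])
  expect_equal(steady_state_ff(1e12, p), 1, tolerance = 1e-9)
  I <- 10^seq(-2, 6, length.out = 200)
  v <- steady_state_ff(I, p)
  expect_true(all(diff(v) > 0))          # c1 >= a1 ensures monotone
  expect_true(all(v > 0 & v < 1))        # normalized mode bounds
  # spec'd coefficient set evaluates to 1.000 at 1e12
  p5 <- dnp_params(a = c(0.1, 1, 1), cc = c(0.1, 1, 1))
  expect_equal(steady_state_ff(1e12, p5), 1, tolerance = 1e-9)
  expect_warning(dnp_params(a = c(0.1, 2, 1), cc = c(1, 0.5, 1)), "monoton")
})

test_that("local-feedback steady state solves the cubic exactly", {
  p <- dnp_params(d = c(0.1, 1, 0.2))
  I <- 10^seq(-2, 6, length.out = 60)
  v <- steady_state_fb(I, p)
  A <- -(p$a[1] + p$a[2] * I + p$a[3] * I^2)
  C <- p$cc[1] + p$d[1] + p$cc[2] * I + p$cc[3] * I^2
  resid <- abs(p$d[3] * v^3 + p$d[2] * v^2 + C * v + A)
  expect_true(all(resid < 1e-9 * pmax(1, abs(A))))
  expect_true(all(v > 0))
  # printed closed-form branches (Cardano) agree with polyroot
  expect_equal(steady_state_fb(I, p, method = "cardano"), v,
               tolerance = 1e-7)
  # d2 = 0 quadratic branch
  pq <- dnp_params(d = c(0.05, 0.8, 0))
  vq <- steady_state_fb(I, pq)
  expect_equal(steady_state_fb(I, pq, method = "cardano"), vq,
               tolerance = 1e-7)
  expect_true(all(abs(pq$d[2] * vq^2 +
                        (pq$cc[1] + pq$d[1] + pq$cc[2] * I + pq$cc[3] * I^2) * vq +
                        -(pq$a[1] + pq$a[2] * I + pq$a[3] * I^2)) <
                    1e-9 * pmax(1, abs(A))))
  # zero feedback reduces to the feedforward form
  p0 <- dnp_params(d = c(0, 0, 0))
  expect_equal(steady_state_fb(I, p0), steady_state_ff(I, p0))
})

test_that("sigmoid slope orderings with feedforward ratio and feedback", {
  slope_at_half <- function(f, vmax = 1) {
    lh <- stats::uniroot(function(l) f(10^l) - vmax / 2, c(-6, 10))$root
    (f(10^(lh + 0.01)) - f(10^(lh - 0.01))) / 0.02
  }
  # increasing a2/a1 steepens the feedforward sigmoid
  ps <- list(dnp_params(a = c(1e-3, 1, 1e-6), cc = c(1, 1, 1e-6)),
             dnp_params(a = c(1e-3, 0.1, 1), cc = c(1, 0.2, 1)),
             dnp_params(a = c(1e-3, 1e-4, 1), cc = c(1, 2e-4, 1)))
  slopes <- vapply(ps, function(p)
    slope_at_half(function(I) steady_state_ff(I, p)), numeric(1))
  expect_true(all(diff(slopes) > 0))
  # increasing d1 flattens the local-feedback sigmoid
  sl_fb <- vapply(c(0, 0.5, 5), function(d1) {
    p <- dnp_params(d = c(0, d1, 0))
    slope_at_half(function(I) steady_state_fb(I, p))
  }, numeric(1))
  expect_true(all(diff(sl_fb) < 0))
})

test_that("dnp_simulate converges to the closed-form fixed points", {
  p <- dnp_params()
  u <- matrix(5, 1, 150)
  v_ff <- dnp_simulate(u, p, "ff")
  expect_lt(abs(v_ff[150] - steady_state_ff(5, p)), 1e-6)
  pfb <- dnp_params(d = c(0.1, 1, 0.1))
  v_fb <- dnp_simulate(u, pfb, "local_fb")
  expect_lt(abs(v_fb[150] - steady_state_fb(5, pfb)), 1e-6)
  # d = 0 makes local_fb identical to ff
  p0 <- dnp_params(d = c(0, 0, 0))
  expect_equal(dnp_simulate(u, p0, "local_fb"), dnp_simulate(u, p0, "ff"))
  # outputs bounded in (0, 1) in normalized mode for wide-ranging inputs
  set.seed(5)
  wide <- matrix(10^stats::runif(300, -2, 5), 3, 100)
  v_wide <- dnp_simulate(wide, p, "ff")
  expect_true(all(v_wide > 0 & v_wide < 1))
  expect_error(dnp_simulate(matrix(-1, 1, 50), p, "ff"), "nonnegative")
})

test_that("uniform MVP feedback shifts the response curve right", {
  patch <- tiny_texture(4, 16) * 3
  sim_in <- function(mat, nfr = 80)
    frame_sequence(array(rep(mat, nfr), dim = c(dim(mat), nfr)))
  p_ff <- dnp_params()
  v_ff <- mean(get_frame(dnp_simulate(sim_in(patch), p_ff, "ff"), 80))
  shifts <- vapply(c(5, 20), function(r1) {
    pm <- dnp_params(mvp = list(r1 = r1))
    v_ff - mean(get_frame(dnp_simulate(sim_in(patch), pm, "mvp_fb"), 80))
  }, numeric(1))
  expect_true(all(shifts > 0))          # curve shifted toward larger I
  expect_gt(shifts[2], shifts[1])       # stronger pool, larger shift
  # MVP with zero weights reduces to ff
  pz <- dnp_params(mvp = list(r1 = 0, r2 = 0, b4 = 0))
  expect_equal(dnp_simulate(sim_in(patch), pz, "mvp_fb")$frames,
               dnp_simulate(sim_in(patch), p_ff, "ff")$frames)
})

test_that("adaptive feedback centres the mean output at 0.5", {
  p <- dnp_params()
  img <- tiny_texture(3, 16) * 20
  ss <- adaptive_steady_state(img, p, alpha = 0.5, tol = 1e-8)
  expect_true(ss$converged)
  expect_lt(abs(mean(ss$v) - 0.5), 1e-3)
  expect_true(all(ss$v > 0 & ss$v < 1))
  # fixed-point solver lands on the same state
  fp <- adaptive_steady_state(img, p, solver = "fixed_point")
  expect_equal(fp$w, ss$w, tolerance = 1e-4)
  expect_lt(abs(mean(fp$v) - 0.5), 1e-6)
})

test_that("adaptive outputs are invariant to input scale over decades", {
  p <- dnp_params()
  img <- tiny_texture(3, 16) * 20
  v1 <- adaptive_steady_state(img, p, solver = "fixed_point")$v
  for (lambda in c(10, 100, 1e4)) {
    vl <- adaptive_steady_state(img * lambda, p, solver = "fixed_point")$v
    expect_lt(max(abs(vl - v1)), 0.05)
  }
})

test_that("adaptive_simulate: frozen adaptation and euler tracking", {
  p <- dnp_params()
  u <- frame_sequence(array(6, c(4, 4, 60)))
  # quasi-steady solver centres a constant input within one frame
  res_q <- adaptive_simulate(u, p, solver = "quasi_steady")
  expect_lt(abs(mean(get_frame(res_q$v, 60)) - 0.5), 1e-6)
  # euler solver drifts toward the same state monotonically
  res_e <- adaptive_simulate(u, p, alpha = 0.5, dt_ode = 0.1)
  w_tr <- res_e$w_trace[1, ]
  expect_true(all(diff(w_tr) >= -1e-12))
  expect_lt(w_tr[60], res_q$w_trace[1, 60] + 1e-6)
  # with a tiny alpha the divisor barely moves: near-frozen loop
  res_f <- adaptive_simulate(u, p, alpha = 1e-9)
  expect_lt(max(res_f$w_trace), 1e-6)
  v_fixed <- dnp_simulate(u, p, "ff")
  expect_equal(res_f$v$frames, v_fixed$frames, tolerance = 1e-5)
})

test_that("adaptive gain control preserves edge contrast that static
           saturation destroys", {
  p <- dnp_params()
  edge <- edge_image(32, lo = 400, hi = 1600) # ~1.5 decades above half point
  v_dnp <- adaptive_steady_state(edge, p, solver = "fixed_point")$v
  sat <- get_frame(photoreceptor_sigmoid(frame_sequence(edge), half_point = 30), 1)
  mc <- function(m) (max(m) - min(m)) / (max(m) + min(m))
  expect_gt(mc(v_dnp), mc(sat))
  expect_gt(mc(v_dnp), 0.3) # healthy output contrast in absolute terms
})
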