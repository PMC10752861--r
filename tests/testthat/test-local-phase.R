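test_that("filter bank construction honours the frequency disc contract", {
  bank <- tiny_bank()
  expect_true(all(sqrt(bank$freqs$wx^2 + bank$freqs$wy^2) <= bank$r + 1e-12))
  expect_true(all(sqrt(bank$freqs$wx^2 + bank$freqs$wy^2) > 0.1)) # DC guard
  expect_error(build_filter_bank(r = 1.1 * pi), "pi")
  # sine kernel is odd about the centre: sums to zero
  expect_lt(max(abs(colSums(bank$kernel_sin))), 1e-10)
  # cosine kernel even: matches its 180-degree rotation
  n <- 2 * bank$support_radius + 1
  for (i in c(1, ncol(bank$kernel_cos))) {
    k <- matrix(bank$kernel_cos[, i], n, n)
    expect_equal(k, k[n:1, n:1], tolerance = 1e-12)
  }
})

test_that("quadrature responses match closed forms on designed inputs", {
  bank <- tiny_bank()
  rad <- bank$support_radius
  n <- 4 * rad + 1
  ctr <- tibble::tibble(x = 2 * rad + 1, y = 2 * rad + 1)
  # constant frame: b = 0 at every frequency, hence phase 0
  qc <- compute_quadrature(matrix(3, n, n), bank, ctr)
  expect_lt(max(abs(qc$b)), 1e-9)
  ph <- local_phase(qc)
  expect_lt(max(abs(ph$phase)), 1e-9)
  # sinusoid sin(wx * (x - x0)): quadrature phase is -pi/2 at any (wx, wy)
  # frequency with that wx (the y-sums of the odd window terms vanish)
  k <- 1
  wx <- bank$freqs_half$wx[k]
  xs <- matrix(rep(seq_len(n) - (2 * rad + 1), each = n), n, n)
  qs <- compute_quadrature(sin(wx * xs), bank, ctr)
  expect_equal(atan2(qs$b[1, k], qs$a[1, k]), -pi / 2, tolerance = 1e-8)
  # non-finite pixels rejected
  bad <- matrix(1, n, n); bad[3, 3] <- NA
  expect_error(compute_quadrature(bad, bank, ctr), "finite")
})

test_that("quadrature equals the brute-force windowed sum oracle", {
  bank <- tiny_bank()
  frame <- tiny_texture(11, 4 * bank$support_radius + 3)
  ctr <- tibble::tibble(x = c(2 * bank$support_radius + 1, 25),
                        y = c(20, 2 * bank$support_radius + 2))
  q <- compute_quadrature(frame, bank, ctr)
  for (ci in 1:2) for (k in c(1, 7, ncol(q$a))) {
    o <- oracle_quadrature_1(frame, bank$sigma, bank$support_radius,
                             ctr$x[ci], ctr$y[ci],
                             bank$freqs_half$wx[k], bank$freqs_half$wy[k])
    expect_equal(q$a[ci, k], o[["a"]], tolerance = 1e-10)
    expect_equal(q$b[ci, k], o[["b"]], tolerance = 1e-10)
  }
})

test_that("phase derivative: rotation of a unit phasor and literal dnp form", {
  bank <- tiny_bank()
  # synthetic quadrature fields: a = 1, b = 0 -> a = 1, b = omega_like
  mk_q <- function(a, b) {
    structure(list(a = matrix(a, 1, nrow(bank$freqs_half)),
                   b = matrix(b, 1, nrow(bank$freqs_half)),
                   centers = tibble::tibble(x = 1, y = 1), bank = bank),
              class = "quadrature_field")
  }
  w <- 0.3
  f_dnp <- phase_derivative_dnp(mk_q(1, w), mk_q(1, 0), eps = 1e-12,
                                method = "dnp")
  # T1 = w, T2-denominator = 1 + w^2: matches the divisive form
  expect_equal(unique(as.vector(round(abs(f_dnp$dphi), 12))),
               round(w / (1 + w^2 + 1e-12), 12))
  f_atan <- phase_derivative_dnp(mk_q(1, w), mk_q(1, 0), eps = 1e-12)
  expect_equal(unique(as.vector(round(abs(f_atan$dphi), 10))),
               round(atan(w), 10))
  # bank mismatch errors
  other <- tiny_bank(sigma = 2.5)
  q_other <- structure(list(a = matrix(1, 1, nrow(other$freqs_half)),
                            b = matrix(0, 1, nrow(other$freqs_half)),
                            centers = tibble::tibble(x = 1, y = 1),
                            bank = other),
                       class = "quadrature_field")
  expect_error(phase_derivative_dnp(mk_q(1, 0), q_other), "bank")
})

test_that("phase derivative agrees with the unwrap-and-difference oracle", {
  bank <- tiny_bank()
  nh <- nrow(bank$freqs_half)
  set.seed(4)
  # smoothly rotating phasors with random rates, amplitude >> eps
  amp <- runif(nh, 0.5, 2)
  phi0 <- runif(nh, -pi, pi)
  rate <- runif(nh, -0.5, 0.5)
  mk_q <- function(t) {
    structure(list(a = matrix(amp * cos(phi0 + rate * t), 1, nh),
                   b = matrix(amp * sin(phi0 + rate * t), 1, nh),
                   centers = tibble::tibble(x = 1, y = 1), bank = bank),
              class = "quadrature_field")
  }
  f <- phase_derivative_dnp(mk_q(1), mk_q(0), eps = 1e-12)
  # oracle: unwrapped arctan2 difference
  dphi_o <- atan2(amp * sin(phi0 + rate), amp * cos(phi0 + rate)) -
    atan2(amp * sin(phi0), amp * cos(phi0))
  dphi_o <- ((dphi_o + pi) %% (2 * pi)) - pi
  expect_equal(f$dphi[1, bank$half_sign > 0], dphi_o, tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("static scenes give exactly zero phase derivative", {
  bank <- tiny_bank()
  frame <- tiny_texture(5, 4 * bank$support_radius + 3)
  ctr <- tibble::tibble(x = 22, y = 22)
  q <- compute_quadrature(frame, bank, ctr)
  f <- phase_derivative_dnp(q, q)
  expect_true(all(f$dphi == 0))
})

test_that("phase derivative is amplitude invariant (contrast independence)", {
  bank <- tiny_bank()
  img <- tiny_texture(6, 64)
  s <- translate_sequence(img, c(0.5, 0.25), 3, wrap = TRUE)
  ctr <- tibble::tibble(x = c(25, 32), y = c(28, 30))
  q1 <- compute_quadrature(get_frame(s, 2), bank, ctr)
  q0 <- compute_quadrature(get_frame(s, 1), bank, ctr)
  f_ref <- phase_derivative_dnp(q1, q0, eps = 1e-12)
  for (lambda in c(10, 1000)) {
    q1s <- compute_quadrature(lambda * get_frame(s, 2), bank, ctr)
    q0s <- compute_quadrature(lambda * get_frame(s, 1), bank, ctr)
    fs <- phase_derivative_dnp(q1s, q0s, eps = 1e-12)
    expect_equal(fs$dphi, f_ref$dphi, tolerance = 1e-6)
  }
})

test_that("a planar phase increment passes through the pipeline unchanged", {
  # quadrature fields whose phasors rotate by exactly -w'v per frame: the
  # extracted field must be the plane itself to numerical precision
  bank <- tiny_bank()
  nh <- nrow(bank$freqs_half)
  v <- c(0.9, -0.4)
  dphi_true <- -(bank$freqs_half$wx * v[1] + bank$freqs_half$wy * v[2])
  mk_q <- function(t) {
    structure(list(a = matrix(cos(dphi_true * t), 1, nh),
                   b = matrix(sin(dphi_true * t), 1, nh),
                   centers = tibble::tibble(x = 1, y = 1), bank = bank),
              class = "quadrature_field")
  }
  f <- phase_derivative_dnp(mk_q(1), mk_q(0), eps = 1e-14)
  plane_full <- -(f$freqs$wx * v[1] + f$freqs$wy * v[2])
  expect_equal(f$dphi[1, ], plane_full, tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("translation induces an approximately planar phase-gradient field", {
  # On broadband textures each frequency bin carries spectral-bias noise of
  # order |v| / sigma (the window averages a ~1/sigma-wide patch of the
  # scene spectrum), so per-bin residuals are intrinsically tens of percent;
  # the chord-normalized Radon integral is what averages this out. Here we
  # check the field is plane-like: the weighted LS plane recovers -v and
  # dominates the residual.
  bank <- build_filter_bank()
  img <- make_texture(0, 256)
  ctr <- tidyr::expand_grid(y = c(80, 128, 176), x = c(80, 128, 176))
  for (v in list(c(1, 0), c(-0.6, 0.9))) {
    s <- translate_sequence(img, v, 3, wrap = TRUE)
    q1 <- compute_quadrature(get_frame(s, 3), bank, ctr)
    q0 <- compute_quadrature(get_frame(s, 2), bank, ctr)
    f <- phase_derivative_dnp(q1, q0)
    A2 <- (q1$a^2 + q1$b^2)[, bank$half_index] # weights per full frequency
    for (i in seq_len(nrow(ctr))) {
      fit <- stats::lm(dphi ~ 0 + wx + wy, weights = A2[i, ],
                       data = data.frame(dphi = f$dphi[i, ],
                                         wx = f$freqs$wx, wy = f$freqs$wy))
      expect_equal(unname(coef(fit)), -v, tolerance = 0.15)
      res <- sqrt(sum(A2[i, ] * fit$residuals^2) / sum(A2[i, ]))
      mag <- sqrt(sum(A2[i, ] * (f$freqs$wx * v[1] + f$freqs$wy * v[2])^2) /
                    sum(A2[i, ]))
      expect_lt(res / mag, 0.35)
    }
  }
})
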