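# Process L, photic drive, Process P and the integrator.

cfg <- model_config()  # CS input: I0 = 0.7

test_that("activation rate alpha(I) matches closed-form values", {
  expect_identical(alpha_of_I(0, cfg), 0)
  expect_equal(alpha_of_I(cfg$I0, cfg), 0.05)
  expect_equal(alpha_of_I(2 * cfg$I0, cfg), 0.05 * 2^0.6, tolerance = 1e-12)
  # monotone in I
  I <- seq(0, cfg$I0, length.out = 50)
  expect_true(all(diff(alpha_of_I(I, cfg)) > 0))
  expect_error(alpha_of_I(-1, cfg), "nonnegative")
})

test_that("pool dynamics vanish at the fixed point and match arithmetic", {
  a <- alpha_of_I(0.3, cfg)
  expect_equal(process_l_rhs(a / (a + cfg$beta), 0.3, cfg), 0,
               tolerance = 1e-12)
  # dark decay: ndot = -60 * beta * n
  expect_equal(process_l_rhs(0.5, 0, cfg), -60 * 0.0075 * 0.5)
  # full ready pool at I0: ndot = 60 * alpha0
  expect_equal(process_l_rhs(0, cfg$I0, cfg), 3.0)
  expect_error(process_l_rhs(1.2, 0, cfg), "\\[0, 1\\]")
})

test_that("photic drive honors pool, modulator and bypass semantics", {
  origin <- pacemaker_state(0, 0, 0)
  expect_equal(photic_drive(origin, cfg$I0, cfg), 33.75 * 0.05)
  # exhausted pool kills the drive
  expect_equal(photic_drive(pacemaker_state(0, 0, 1), cfg$I0, cfg), 0)
  # modulator is the identity at the origin
  cfg_nomod <- model_config(modulator = FALSE)
  expect_equal(photic_drive(origin, 0.3, cfg),
               photic_drive(origin, 0.3, cfg_nomod))
  # away from the origin the modulator scales by (1-0.4x)(1-0.4xc)
  st <- pacemaker_state(0.5, -0.5, 0.2)
  expect_equal(photic_drive(st, 0.3, cfg),
               photic_drive(st, 0.3, cfg_nomod) * (1 - 0.2) * (1 + 0.2))
  # bypass freezes the adaptation term at 1
  cfg_nol <- model_config(process_l = FALSE)
  expect_equal(photic_drive(pacemaker_state(0, 0, 0.9), 0.3, cfg_nol),
               photic_drive(pacemaker_state(0, 0, 0), 0.3, cfg_nol))
  # darkness produces no drive under any toggles
  expect_identical(photic_drive(st, 0, cfg), 0)
  expect_identical(photic_drive(st, 0, cfg_nol), 0)
})

test_that("drive is nondecreasing in light at fixed state", {
  set.seed(11)
  for (i in 1:10) {
    st <- pacemaker_state(stats::runif(1, -1.2, 1.2),
                          stats::runif(1, -1.2, 1.2), stats::runif(1))
    I <- seq(0, 0.69, length.out = 40)
    B <- vapply(I, function(ii) photic_drive(st, ii, cfg), numeric(1))
    expect_true(all(diff(B) >= -1e-12))
  }
})

test_that("oscillator right-hand side matches independent evaluation", {
  # x = 0: polynomial and frequency terms vanish
  expect_equal(process_p_rhs(pacemaker_state(0, 1, 0), 0, cfg),
               c(dx = pi / 12, dxc = 0), tolerance = 1e-12)
  # x = 1, B = 0: literal arithmetic
  r <- process_p_rhs(pacemaker_state(1, 0, 0), 0, cfg)
  expect_equal(r[["dx"]], (pi / 12) * 0.13 * (1 / 3 + 4 / 3 - 256 / 105),
               tolerance = 1e-12)
  expect_equal(r[["dxc"]], -(pi / 12) * (24 / (0.99669 * 24.2))^2,
               tolerance = 1e-12)
  # random states against an independently coded expression
  set.seed(23)
  for (i in 1:25) {
    x <- stats::runif(1, -1.5, 1.5); xc <- stats::runif(1, -1.5, 1.5)
    B <- stats::runif(1, 0, 1.5)
    got <- process_p_rhs(pacemaker_state(x, xc, 0), B, cfg)
    mu <- 0.13; q <- 0.33; k <- 0.55
    om2 <- (24 / (0.99669 * 24.2))^2
    expect_equal(got[["dx"]],
                 pi / 12 * (xc + B + mu * (x / 3 + 4 * x^3 / 3 - 256 * x^7 / 105)),
                 tolerance = 1e-12)
    expect_equal(got[["dxc"]], pi / 12 * (q * B * xc - x * (om2 + k * B)),
                 tolerance = 1e-12)
  }
})

test_that("zero-length span returns the initial state unchanged", {
  ser <- light_series(c(0, 1), c(0.2, 0.2), unit = "cs")
  s0 <- pacemaker_state(0.3, -0.8, 0.1)
  tr <- integrate_pacemaker(s0, ser, cfg, t_span = c(0, 0))
  expect_equal(nrow(tr), 1L)
  expect_equal(unlist(tr[1, c("x", "xc", "n")]),
               c(x = 0.3, xc = -0.8, n = 0.1))
})

test_that("pool fraction converges to alpha/(alpha+beta) under constant light", {
  lvl <- 0.35
  a <- alpha_of_I(lvl, cfg)
  ser <- light_series(seq(0, 8, by = 0.05), rep(lvl, 161), unit = "cs")
  tr <- integrate_pacemaker(pacemaker_state(0, -1, 0), ser, cfg)
  expect_equal(tr$n[nrow(tr)], a / (a + cfg$beta), tolerance = 1e-7)
  # and n stays inside [0, 1] throughout
  expect_true(all(tr$n >= 0 & tr$n <= 1))
})

test_that("integrator matches a 2-s Euler brute-force oracle over two days", {
  pre <- protocol_preset("advance", seed = 11)
  bs <- pre$baseline; bs$n_days <- 2
  drv <- prepare_drive_series(generate_series(bs), "cs")
  s0 <- initialize_from_cbt_min(4, cfg)
  traj <- integrate_pacemaker(s0, drv, cfg)
  t_end <- max(drv$series$time)
  orc <- euler_pacemaker(s0, drv$series$time, drv$series$value, cfg,
                         0, t_end, dt = 2 / 3600)
  m <- match(round(orc$time, 6), round(traj$time, 6))
  expect_true(all(!is.na(m)))
  expect_lt(max(abs(orc$x - traj$x[m])), 1e-3)
  expect_lt(max(abs(orc$n - traj$n[m])), 1e-3)
})

test_that("dark free-run agrees with an adaptive RK45 reference solver", {
  skip_if_not_installed("deSolve")
  s0 <- initialize_from_cbt_min(4, cfg)
  tr <- csoscillator:::.integrate_constant(s0, 0, 100, cfg)
  rhs <- function(t, y, parms) {
    om2 <- (24 / (0.99669 * 24.2))^2
    list(c(pi / 12 * (y[2] + 0.13 * (y[1] / 3 + 4 * y[1]^3 / 3 -
                                       256 * y[1]^7 / 105)),
           pi / 12 * (-y[1] * om2)))
  }
  ref <- deSolve::ode(c(s0[["x"]], s0[["xc"]]), times = seq(0, 100, by = 0.1),
                      func = rhs, parms = NULL, method = "ode45",
                      rtol = 1e-9, atol = 1e-10)
  m <- match(round(ref[, 1], 6), round(tr$time, 6))
  expect_true(all(!is.na(m)))
  expect_lt(max(abs(ref[, 2] - tr$x[m])), 1e-4)
})

test_that("long gaps are filled with darkness and divergence is caught", {
  # 180-s logger series with a 1.3-h recording dropout after t = 1
  tt <- c(seq(0, 1, by = 0.05), seq(2.3, 4, by = 0.05))
  ser <- light_series(tt, rep(0.3, length(tt)), unit = "cs")
  expect_warning(
    tr <- integrate_pacemaker(pacemaker_state(0, -1, 0), ser, cfg),
    "darkness")
  # during the dark-filled gap the pool decays instead of charging
  in_gap <- tr$time > 1.05 & tr$time < 2.25
  expect_gt(sum(in_gap), 3)
  expect_true(all(diff(tr$n[in_gap]) < 0))
  # an absurd gain blows the state past the divergence guard
  cfg_big <- model_config(G = 1e4)
  bright <- light_series(seq(0, 48, by = 0.05), rep(0.5, 961), unit = "cs")
  expect_error(integrate_pacemaker(pacemaker_state(0, -1, 0), bright, cfg_big),
               "diverged")
})
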