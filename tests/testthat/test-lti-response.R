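test_that("step response starts at baseline, passes the one-tau point and saturates", {
  p <- lti_params(gain = 100, tau = 500, delay = 120, baseline = 700)
  expect_equal(step_response(p$delay, p), 700)
  expect_equal(step_response(p$delay + p$tau, p), 700 + 100 * (1 - exp(-1)))
  expect_lt(abs(step_response(p$delay + 20 * p$tau, p) - 800), 1e-6 * 100)
  # causality and vectorisation
  t <- c(-300, 0, 119.9, 120, 1000)
  y <- step_response(t, p)
  expect_equal(y[1:3], rep(700, 3))
  expect_length(y, 5)
})

test_that("constructors reject invalid parameters", {
  expect_error(lti_params(100, -1, 0, 700), "tau")
  expect_error(lti_params(100, 500, -5, 700), "delay")
  expect_error(lti_params(100, 500, 0, 0), "baseline")
  expect_error(rect_shape(0), "delta")
  expect_error(trapezoid_shape(0, 10, 10), "delta1")
  expect_error(trapezoid_shape(10, -1, 10), "delta2")
})

test_that("rectangular response matches its two-exponential closed form", {
  # zero gain: flat at baseline
  p0 <- lti_params(0, 2614, 758, 740)
  sh <- rect_shape(1303)
  expect_equal(rect_response(seq(-600, 5000, 100), p0, sh),
               rep(740, length(seq(-600, 5000, 100))))
  # reference liver dynamics at the end of the pulse: direct evaluation
  p <- lti_params(147.8, 2614, 758, 740)
  expect_equal(rect_response(758 + 1303, p, sh),
               740 + 147.8 * (1 - exp(-1303 / 2614)),
               tolerance = 1e-12)
  expect_equal(round(rect_response(2061, p, sh), 1), 798.0)
  # causality
  expect_equal(rect_response(c(-100, 0, 757.99), p, sh), rep(740, 3))
})

test_that("trapezoid response is causal and degenerates to the rectangle", {
  m <- ref_spleen(0.5)
  expect_equal(trapezoid_response(c(-50, 0, m$params$delay - 1e-9),
                                  m$params, m$shape),
               rep(1300, 3))
  p <- lti_params(80, 900, 300, 700)
  delta <- 1500
  near_rect <- trapezoid_shape(1e-6, delta, 1e-6)
  tg <- seq(0, 8000, by = 5)
  expect_lt(max(abs(trapezoid_response(tg, p, near_rect) -
                      rect_response(tg, p, rect_shape(delta + 2e-6)))),
            1e-6 * p$gain)
})

test_that("closed forms agree with the RK4 reference integrator", {
  m <- ref_spleen(0.5)
  tg <- seq(0, 5000, by = 10)
  y_ode <- ode_oracle(lti_input(m$params, m$shape), m$params, tg,
                      breaks = lti_breaks(m$params, m$shape))
  expect_lt(max(abs(y_ode - trapezoid_response(tg, m$params, m$shape))), 1e-4)
  l <- ref_liver(1)
  y_ode_l <- ode_oracle(lti_input(l$params, l$shape), l$params, tg,
                        breaks = lti_breaks(l$params, l$shape))
  expect_lt(max(abs(y_ode_l - rect_response(tg, l$params, l$shape))), 1e-4)
})

test_that("RK4 integrator handles trivial inputs and rejects bad grids", {
  p <- lti_params(100, 500, 120, 700)
  tg <- seq(0, 3000, by = 10)
  expect_equal(ode_oracle(function(t) rep(0, length(t)), p, tg),
               rep(700, length(tg)))
  y <- ode_oracle(function(t) 100 * (t >= 120), p, tg, breaks = 120)
  expect_lt(max(abs(y - step_response(tg, p))), 1e-6 * 100)
  expect_error(ode_oracle(function(t) t, p, c(0, 10, 5)), "increasing")
})

test_that("response properties hold across random parameter draws", {
  set.seed(101)
  for (i in 1:20) {
    m <- random_model()
    p <- m$params
    d_tot <- m$trap$delta1 + m$trap$delta2 + m$trap$delta3
    tg <- seq(p$delay - 200, p$delay + d_tot + 5 * p$tau, length.out = 400)
    for (shape in list(m$rect, m$trap)) {
      y <- if (inherits(shape, "rect_shape")) {
        rect_response(tg, p, shape)
      } else {
        trapezoid_response(tg, p, shape)
      }
      # causality (exact) and boundedness within [baseline, baseline + gain]
      expect_equal(y[tg < p$delay], rep(p$baseline, sum(tg < p$delay)))
      expect_true(all(y >= p$baseline - 1e-9 * p$gain))
      expect_true(all(y <= p$baseline + p$gain * (1 + 1e-9)))
      # return to baseline long after the input has ended
      dur <- if (inherits(shape, "rect_shape")) shape$delta else d_tot
      y_end <- if (inherits(shape, "rect_shape")) {
        rect_response(p$delay + dur + 20 * p$tau, p, shape)
      } else {
        trapezoid_response(p$delay + dur + 20 * p$tau, p, shape)
      }
      expect_lt(abs(y_end - p$baseline), 1e-6 * p$gain)
    }
    # rect response rises strictly during the pulse and decays after it
    t_on <- seq(p$delay + 1, p$delay + m$rect$delta - 1, length.out = 50)
    t_off <- seq(p$delay + m$rect$delta + 1,
                 p$delay + m$rect$delta + 5 * p$tau, length.out = 50)
    expect_true(all(diff(rect_response(t_on, p, m$rect)) > 0))
    expect_true(all(diff(rect_response(t_off, p, m$rect)) < 0))
  }
})

test_that("rectangle converges to the delayed step as the pulse lengthens", {
  p <- lti_params(120, 800, 400, 700)
  tg <- seq(0, 400 + 20 * 800, by = 50)
  expect_lt(max(abs(rect_response(tg, p, rect_shape(1e7)) -
                      step_response(tg, p))), 1e-6 * p$gain)
})

test_that("peak analytics match closed-form algebra and flag degeneracy", {
  p <- lti_params(100, 2614, 758, 740)
  pk <- peak(p, rect_shape(1303))
  expect_equal(pk$t_peak, 758 + 1303)
  expect_equal((pk$y_peak - 740) / 100, 1 - exp(-1303 / 2614), tolerance = 1e-12)
  expect_equal(round((pk$y_peak - 740) / 100, 4), 0.3925)
  expect_false(pk$degenerate)
  # zero gain is degenerate
  pk0 <- peak(lti_params(0, 2614, 758, 740), rect_shape(1303))
  expect_true(pk0$degenerate)
  expect_equal(pk0$t_peak, 758)
  expect_equal(pk0$y_peak, 740)
  # a flat top much longer than tau reaches the input plateau
  p2 <- lti_params(60, 200, 100, 1300)
  pk2 <- peak(p2, trapezoid_shape(100, 50 * 200, 100))
  expect_lt(abs(pk2$y_peak - (1300 + 60)), 1e-4 * 60)
  # trapezoid peak matches a dense evaluation of the closed form
  m <- ref_spleen(1)
  pk3 <- peak(m$params, m$shape)
  tg <- seq(m$params$delay, m$params$delay + 6000, by = 0.5)
  expect_equal(pk3$y_peak, max(trapezoid_response(tg, m$params, m$shape)),
               tolerance = 1e-6)
})

test_that("parameters round-trip through JSON with unit-tagged names", {
  m <- ref_spleen(1.5)
  js <- lti_params_to_json(m$params, m$shape)
  expect_match(js, "tau_s")
  expect_match(js, "delta2_s")
  back <- lti_params_from_json(js)
  expect_equal(back$params, m$params)
  expect_equal(back$shape, m$shape)
  l <- ref_liver(0.5)
  back_l <- lti_params_from_json(lti_params_to_json(l$params, l$shape))
  expect_equal(back_l$shape$delta, l$shape$delta)
})
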