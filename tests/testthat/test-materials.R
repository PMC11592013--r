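# Bone constitutive behaviour: Cowper-Symonds rate scaling, multilinear
# hardening, radial-return stress integration.

test_that("rate factor follows the Cowper-Symonds law", {
  rl <- rate_law(360.7, 4.61, TRUE)
  expect_identical(rate_factor(rl, 0), 1)
  expect_equal(rate_factor(rl, 360.7), 2)           # (rate/D) = 1 forces R = 2
  # oracle: invert rate = D (R-1)^n by bisection and compare at 1000 1/s
  lo <- 1; hi <- 10
  for (i in 1:80) {
    mid <- (lo + hi) / 2
    if (360.7 * (mid - 1)^4.61 < 1000) lo <- mid else hi <- mid
  }
  expect_equal(rate_factor(rl, 1000), (lo + hi) / 2, tolerance = 1e-9)
  expect_equal(round(rate_factor(rl, 1000), 3), 2.248)
  # disabled law is identically 1
  expect_identical(rate_factor(rate_law(enabled = FALSE), c(0, 10, 1e4)),
                   rep(1, 3))
  expect_error(rate_factor(rl, -1), "negative")
})

test_that("rate factor round-trips and recovers the exponent by regression", {
  rl <- rate_law()
  rates <- c(1, 10, 100, 1000)
  R <- rate_factor(rl, rates)
  expect_equal(rl$D * (R - 1)^rl$n, rates, tolerance = 1e-9)
  fit <- stats::lm(log(rates) ~ log(R - 1))
  expect_equal(unname(stats::coef(fit)[2]), 4.61, tolerance = 1e-6)
  # strict monotonicity
  r <- rate_factor(rl, seq(0, 2000, by = 10))
  expect_true(all(diff(r) > 0))
})

test_that("flow stress interpolates the hardening curve and scales with rate", {
  card <- cortical_card()
  expect_equal(flow_stress(card, 0, 0), 110)        # curve origin
  expect_equal(flow_stress(card, 0.01, 0), 145)     # midpoint interpolant
  expect_equal(flow_stress(card, 0.5, 0), 180)      # clamped beyond last point
  # rate = D doubles the quasi-static value everywhere
  eps <- c(0, 0.005, 0.013, 0.02, 0.1)
  expect_equal(flow_stress(card, eps, 360.7), 2 * flow_stress(card, eps, 0))
  # trabecular response is rate-independent
  tc <- trabecular_card()
  expect_equal(flow_stress(tc, 0.01, 1000), flow_stress(tc, 0.01, 0))
  expect_error(flow_stress(card, -0.01), "negative")
})

test_that("hardening curve invariants are enforced", {
  expect_error(hardening_curve(c(0.01, 0.02), c(100, 120)), "eps_pl = 0")
  expect_error(hardening_curve(c(0, 0.02, 0.01), c(100, 120, 130)),
               "increasing")
  expect_error(hardening_curve(c(0, 0.02), c(120, 100)), "non-softening")
  expect_error(material_card("x", elastic_constants(5.5, 0.3, 2.12),
                             hardening_curve(0, 30), rate_law(enabled = TRUE),
                             "trabecular"),
               "disabled")
})

test_that("stress update: identity, elastic slope, and yield consistency", {
  card <- cortical_card()
  # zero increment leaves the state untouched
  r0 <- stress_update(card, matrix(0, 3, 3))
  expect_identical(r0$stress, numeric(6))
  expect_identical(r0$delta_eps_pl, 0)
  # small uniaxial strain with Poisson-free lateral contraction: axial
  # stress = E * eps (Table-constants check, 13.7 GPa)
  eps <- 1e-4; nu <- 0.3
  r <- stress_update(card, diag(c(eps, -nu * eps, -nu * eps)))
  expect_equal(r$stress[1] / eps, 13.7e3, tolerance = 1e-10)
  expect_equal(r$stress[2], 0, tolerance = 1e-9)
  # monotonic stretch past yield: von Mises never exceeds the flow stress
  st <- list(stress = numeric(6), eps_pl = 0)
  for (i in 1:40) {
    st <- stress_update(card, diag(c(5e-4, -2.5e-4, -2.5e-4)), st, dt = 1e-3)
    lim <- flow_stress(card, st$eps_pl, st$eps_dot_pl)
    expect_lte(st$q, lim * (1 + 1e-8))
  }
  expect_gt(st$eps_pl, 0)
  expect_error(stress_update(card, matrix(NaN, 3, 3)), "non-finite")
})

test_that("stress update is incrementally objective under pure rotation", {
  card <- cortical_card()
  # preload a uniaxial stress, then spin the point through 90 degrees in
  # many small rigid-rotation increments: magnitude must be preserved
  st <- stress_update(card, diag(c(5e-4, -1.5e-4, -1.5e-4)))
  st <- list(stress = st$stress, eps_pl = st$eps_pl)
  n <- 500
  dth <- (pi / 2) / n
  for (i in seq_len(n)) {
    w <- matrix(c(0, -dth, 0, dth, 0, 0, 0, 0, 0), 3, 3, byrow = TRUE)
    r <- stress_update(card, w, st)
    st <- list(stress = r$stress, eps_pl = r$eps_pl)
  }
  norm0 <- function(s) sqrt(sum(s[1:3]^2) + 2 * sum(s[4:6]^2))
  s_init <- stress_update(card, diag(c(5e-4, -1.5e-4, -1.5e-4)))$stress
  expect_equal(norm0(st$stress), norm0(s_init), tolerance = 1e-8)
  expect_identical(st$eps_pl, 0)      # no plastic flow from rotation
})

test_that("coarse stress integration matches a 10x finer oracle within 0.5%", {
  for (card in list(cortical_card(), trabecular_card())) {
    for (rate in c(0, 50)) {
      if (card$phase == "trabecular" && rate > 0) next
      eps_tot <- 0.03
      n <- 60
      dt <- if (rate > 0) (eps_tot / n) / rate else 1e9
      # package path: uniaxial rig at the same increments
      rig <- uniaxial_test(card, damage = NULL, eps_max = eps_tot,
                           n_steps = n, rate = rate)
      ora <- oracle_uniaxial_stress(card, eps_tot, 10 * n, rate)
      expect_equal(rig$data$stress_MPa[n + 1], ora$sigma_axial,
                   tolerance = 5e-3)
    }
  }
})

test_that("material cards round-trip through the serialized list form", {
  card <- cortical_card()
  lst <- material_to_list(card)
  expect_equal(lst$E_GPa, 13.7)
  expect_equal(lst$rho_g_cm3, 2.12)
  back <- material_from_list(lst)
  expect_equal(back$elastic, card$elastic)
  expect_equal(back$hardening, card$hardening)
  expect_equal(back$rate, card$rate)
})
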