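# Skin-surrogate contact: pressure-overclosure law, cylinder geometry,
# friction, action-reaction.

test_that("pressure-overclosure anchors and monotonicity", {
  law <- contact_law()
  expect_identical(contact_pressure(law, 1.5), 0)   # zero at the clearance
  expect_identical(contact_pressure(law, 2.5), 0)
  expect_equal(contact_pressure(law, 0), 100)       # p0 at touch
  # closed-form midpoint value
  expect_equal(contact_pressure(law, 0.75),
               100 * (exp(0.5) - 1) / (exp(1) - 1))
  expect_equal(round(contact_pressure(law, 0.75), 2), 37.75)
  # continuous, monotone non-increasing in clearance across the whole range
  c_grid <- seq(-1, 2, by = 1e-3)
  p <- contact_pressure(law, c_grid)
  expect_true(all(diff(p) <= 1e-12))
  expect_lt(max(abs(diff(p))), 0.2)                 # no jumps at branch points
  # penetration slope matches the exponential slope at c = 0
  eps <- 1e-8
  slope_out <- (contact_pressure(law, eps) - contact_pressure(law, 0)) / eps
  slope_in <- (contact_pressure(law, 0) - contact_pressure(law, -eps)) / eps
  expect_equal(slope_in, slope_out, tolerance = 1e-5)
})

test_that("contact potential is the integral of the pressure", {
  law <- contact_law()
  for (c0 in c(-0.5, 0.2, 1.0)) {
    num <- stats::integrate(function(s) contact_pressure(law, s), c0, law$c0,
                            rel.tol = 1e-10)$value
    expect_equal(contact_potential(law, c0), num, tolerance = 1e-8)
  }
  expect_identical(contact_potential(law, 1.5), 0)
})

test_that("cylinder clearance handles axis, lateral and cap regions", {
  imp <- make_impactor(length = 200, diameter = 40, speed_kmh = 0,
                       aim = c(0, 0, 0), standoff = 0)
  # construct a cylinder at the origin along y for direct geometry checks
  imp$origin <- c(0, 0, 0); imp$axis <- c(0, 1, 0)
  cc <- cylinder_clearance(imp, rbind(c(0, 0, 0),      # on the axis
                                      c(21.5, 0, 0),   # radial, outside
                                      c(0, 120, 0),    # beyond the cap
                                      c(19, 99, 0)))   # inside, near the cap
  expect_equal(cc$clearance, c(-20, 1.5, 20, -1))
  # random points: normals have unit length everywhere
  set.seed(42)
  pts <- matrix(stats::runif(300, -150, 150), ncol = 3)
  cc2 <- cylinder_clearance(imp, pts)
  expect_equal(sqrt(rowSums(cc2$normal^2)), rep(1, 100), tolerance = 1e-12)
  # clearance is the distance to the surface: stepping along the normal by
  # the clearance lands on the surface (outside points)
  out <- cc2$clearance > 0
  onsurf <- pts[out, ] - cc2$clearance[out] * cc2$normal[out, ]
  cc3 <- cylinder_clearance(imp, onsurf)
  expect_lt(max(abs(cc3$clearance)), 1e-9)
})

test_that("contact resolution: far field, action-reaction, friction ratio", {
  law <- contact_law()
  fric <- friction_model(0.2, 1)
  imp <- make_impactor(speed_kmh = 0, aim = c(0, 0, 0), standoff = 5)
  pts <- cbind(stats::runif(20, -5, 5), stats::runif(20, -5, 5), 0)
  # all clearances beyond c0: no force at all
  far <- resolve_contact(pts, matrix(0, 20, 3), rep(1, 20), imp, law, fric)
  expect_equal(far$force, matrix(0, 20, 3))
  expect_equal(far$reaction, c(0, 0, 0))
  # push the impactor into the surface: reaction balances nodal forces
  imp2 <- make_impactor(speed_kmh = 0, aim = c(0, 0, 0), standoff = 0.4)
  ct <- resolve_contact(pts, matrix(0, 20, 3), rep(1, 20), imp2, law, fric)
  expect_gt(sum(ct$normal_force), 0)
  expect_equal(colSums(ct$force) + ct$reaction, c(0, 0, 0), tolerance = 1e-10)
  # steady sliding above the regularisation velocity: |F_t| / |F_n| = mu.
  # nodes sit on the line directly under the cylinder so slip is exactly
  # tangential
  line <- cbind(0, seq(-5, 5, length.out = 15), 0)
  vel <- matrix(rep(c(50, 0, 0), each = 15), ncol = 3)
  ct2 <- resolve_contact(line, vel, rep(1, 15), imp2, law, fric, dt = 1e-6)
  fn <- sum(abs(ct2$force[, 3]))          # normal points towards the nodes
  ftan <- sum(abs(ct2$force[, 1]))        # tangential opposes the slip
  expect_equal(ftan / fn, 0.2, tolerance = 1e-9)
  expect_gt(ct2$dissipation, 0)
})

test_that("skin surrogate delays the transmitted-force peak vs hard contact", {
  # elastic comparison (fracture would confound the timing): same start
  # position and speed, the same 2 kg impactor, skin law vs a thin stiff
  # overclosure layer standing in for bare hard contact
  mesh <- small_free_block(nx = 5, ny = 5)
  mesh$node_sets$fixed <- mesh$node_sets$back_face
  ztop <- max(mesh$nodes[, 3])
  elastic <- list(
    cortical = material_card("c", elastic_constants(13.7, 0.3, 2.12),
                             hardening_curve(0, 1e5), rate_law(), "cortical"),
    trabecular = material_card("t", elastic_constants(5.5, 0.3, 2.12),
                               hardening_curve(0, 1e5),
                               rate_law(enabled = FALSE), "trabecular"))
  imp <- make_impactor(speed_kmh = 10, aim = c(0, 0, ztop), mass_kg = 2,
                       standoff = 1.6)
  t_peak <- function(law) {
    scn <- impact_scenario(mesh, imp, duration = 2e-3, law = law,
                           materials = elastic,
                           damage = damage_card(enabled = FALSE),
                           output_interval = 5e-6)
    h <- suppressWarnings(run_scenario(scn))$history
    h$time_s[which.max(h$force_N)]
  }
  expect_gt(t_peak(contact_law(c0 = 1.5, p0 = 100)),
            t_peak(contact_law(c0 = 0.05, p0 = 300)))
})
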