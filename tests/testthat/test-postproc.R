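# Post-processing: SAE channel-class filtering, von Mises, nodal averaging,
# fracture components, file outputs.

test_that("channel-class filter: DC gain, sine attenuation, idempotence", {
  fs <- 1e5
  t <- seq(0, 0.05, by = 1 / fs)
  # constant signal passes unchanged (DC gain 1)
  expect_equal(sae_filter(rep(3.7, length(t)), 180, fs), rep(3.7, length(t)),
               tolerance = 1e-6)
  # 1 kHz sine under CFC180: gain matches the squared 2-pole Butterworth
  # magnitude 1/(1 + (f/fc)^4) (phaseless double application)
  x <- sin(2 * pi * 1000 * t)
  y <- sae_filter(x, 180, fs)
  core <- seq(round(length(t) * 0.3), round(length(t) * 0.7))
  gain_meas <- sqrt(mean(y[core]^2) / mean(x[core]^2))
  fc <- 180 * 5 / 3
  gain_theor <- 1 / (1 + (1000 / fc)^4)
  expect_equal(gain_meas, gain_theor, tolerance = 0.02)
  # a low-frequency component survives while HF rides are stripped
  x2 <- sin(2 * pi * 50 * t) + 0.5 * sin(2 * pi * 5000 * t)
  y2 <- sae_filter(x2, 180, fs)
  expect_equal(sqrt(2 * mean(y2[core]^2)), 1, tolerance = 0.02)
  # idempotent within 1%
  expect_equal(sae_filter(y2, 180, fs)[core], y2[core], tolerance = 0.01)
  # too-short history errors with advice
  expect_error(sae_filter(c(1, 2), 180, fs), "short")
})

test_that("filter accepts a data.frame history and resamples if needed", {
  t <- seq(0, 0.02, by = 1e-5)
  df <- data.frame(time_s = t, force_N = pmax(0, sin(2 * pi * 100 * t)))
  out <- sae_filter(df, cfc = 180)
  expect_true("force_N_cfc180" %in% names(out))
  expect_equal(length(out$force_N_cfc180), nrow(df))
})

test_that("filtered peak stays within 1 ms of the unfiltered peak", {
  # impact-like half-sine pulse with superimposed ringing
  fs <- 1e5
  t <- seq(0, 0.02, by = 1 / fs)
  pulse <- ifelse(t > 0.004 & t < 0.010,
                  sin(pi * (t - 0.004) / 0.006), 0) *
    (1 + 0.3 * sin(2 * pi * 3000 * t))
  filt <- sae_filter(pulse, 180, fs)
  expect_lt(abs(t[which.max(filt)] - t[which.max(pulse)]), 1e-3)
})

test_that("von Mises equivalent stress", {
  expect_equal(von_mises(c(100, 0, 0, 0, 0, 0)), 100)
  expect_equal(von_mises(c(-50, -50, -50, 0, 0, 0)), 0)
  expect_equal(von_mises(c(0, 0, 0, 50, 0, 0)), sqrt(3) * 50)
  expect_equal(round(von_mises(c(0, 0, 0, 50, 0, 0)), 2), 86.60)
  # 3x3 input and row-matrix input agree
  s <- matrix(c(120, 10, 5, 10, -30, 0, 5, 0, 40), 3, 3)
  expect_equal(von_mises(s),
               von_mises(c(120, -30, 40, 10, 0, 5)))
})

test_that("nodal averaging is volume-weighted and skips deleted elements", {
  m <- make_layered_plate(plate_spec(span = 6, width = 3, core_thickness = 1.5,
                                     elem_size = 1.5))
  vals <- seq_along(m$nen)
  nf <- nodal_field(m, vals)
  # a node shared by elements e1..ek gets sum(v V)/sum(V)
  vol <- mesh_volumes(m)$vol
  nid <- m$conn[1, 1]
  att <- which(apply(m$conn[, 1:8], 1, function(r) nid %in% r))
  expect_equal(nf[nid], sum(vals[att] * vol[att]) / sum(vol[att]))
  # deleting every attached element leaves NA
  del <- rep(FALSE, length(m$nen))
  del[att] <- TRUE
  expect_true(is.na(nodal_field(m, vals, deleted = del)[nid]))
})

test_that("fracture components: empty, two clusters, partition property", {
  m <- make_layered_plate(plate_spec(span = 12, width = 12, core_thickness = 3,
                                     elem_size = 1.5))
  none <- extract_fracture_lines(m, deleted = rep(FALSE, length(m$nen)))
  expect_equal(none$n_components, 0)
  expect_equal(none$n_failed, 0)
  # two disjoint clusters in opposite corners
  cen <- t(vapply(seq_along(m$nen), function(e)
    colMeans(m$nodes[m$conn[e, 1:8], ]), numeric(3)))
  del <- (cen[, 1] < -3 & cen[, 2] < -3) | (cen[, 1] > 3 & cen[, 2] > 3)
  rep2 <- extract_fracture_lines(m, deleted = del)
  expect_equal(rep2$n_components, 2)
  expect_equal(sum(rep2$components$n_elements), sum(del))
  # with an impactor footprint over one corner the crush fraction is partial
  imp <- make_impactor(length = 10, diameter = 8, aim = c(-5, -5, 3))
  rep3 <- extract_fracture_lines(m, deleted = del, impactor = imp)
  expect_true(rep3$crush_fraction > 0 && rep3$crush_fraction < 1)
})

test_that("VTU and full-output round trips", {
  m <- make_single_element("cortical", 2)
  f <- tempfile(fileext = ".vtu")
  pd <- list(displacement = matrix(seq_len(24) / 10, 8, 3))
  cd <- list(von_mises_MPa = 42.5)
  write_vtu(m, f, point_data = pd, cell_data = cd)
  arr <- read_vtu_arrays(f)
  expect_equal(arr$Points, m$nodes, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(arr$displacement, pd$displacement, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(arr$von_mises_MPa, 42.5)
  unlink(f)
})

test_that("write_outputs emits consistent CSV, VTU series and JSON report", {
  res <- cached_default_run(20)
  dir <- tempfile("out")
  paths <- write_outputs(res, dir)
  hist <- utils::read.csv(file.path(dir, "history.csv"))
  expect_equal(nrow(hist), nrow(res$history))
  expect_true(all(c("force_N", "force_N_cfc180", "force_kgf") %in%
                    names(hist)))
  expect_equal(hist$force_kgf, hist$force_N / 9.80665, tolerance = 1e-9)
  vtus <- list.files(dir, pattern = "\\.vtu$")
  expect_equal(length(vtus), length(res$snapshots))
  rep <- jsonlite::read_json(file.path(dir, "report.json"))
  expect_equal(rep$n_failed, res$fracture$n_failed)
  expect_equal(rep$peak_force_N, max(res$history$force_N))
  unlink(dir, recursive = TRUE)
})
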