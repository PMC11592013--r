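# shared fixtures and memoised scenario runs (several tests reuse the same
# explicit runs; they are computed once per test session)

.run_cache <- new.env(parent = emptyenv())

cached_default_run <- function(speed_kmh, duration = 5e-3) {
  key <- sprintf("v%g_d%g", speed_kmh, duration)
  if (is.null(.run_cache[[key]]))
    .run_cache[[key]] <- suppressWarnings(
      run_scenario(default_plate_scenario(speed_kmh, duration = duration)))
  .run_cache[[key]]
}

# a small free-floating block mesh (no fixed set) for momentum tests
small_free_block <- function(nx = 4, ny = 4, h = 2) {
  sp <- plate_spec(span = nx * h, width = ny * h, cortical_thickness = 1.5,
                   core_thickness = 1, elem_size = h,
                   cortical_bounds = c(0, 100))
  m <- make_layered_plate(sp)
  m$node_sets$fixed <- integer(0)
  m
}

# Independent fine-increment oracle for the uniaxial elastoplastic response:
# explicit substepping in principal space, radial return by plain bisection,
# lateral strain solved by bisection so the lateral stress vanishes.
oracle_uniaxial_stress <- function(card, eps_total, n, rate) {
  E <- card$elastic$E; nu <- card$elastic$nu
  mu <- E / (2 * (1 + nu))
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  dt <- if (rate > 0) (eps_total / n) / rate else 1e9
  de <- eps_total / n
  sig <- c(0, 0, 0)
  ep <- 0

  return_map <- function(s, ep) {
    pm <- mean(s); sd <- s - pm
    q <- sqrt(1.5 * sum(sd^2))
    if (q <= flow_stress(card, ep, 0)) return(list(s = s, dlp = 0))
    g <- function(x) q - 3 * mu * x - flow_stress(card, ep + x, x / dt)
    lo <- 0; hi <- q / (3 * mu)
    for (j in 1:45) {
      mid <- (lo + hi) / 2
      if (g(mid) > 0) lo <- mid else hi <- mid
    }
    dlp <- (lo + hi) / 2
    list(s = pm + sd * (1 - 3 * mu * dlp / q), dlp = dlp)
  }
  step_stress <- function(dl) {
    tr <- de + 2 * dl
    s_tr <- sig + lam * tr + 2 * mu * c(de, dl, dl)
    return_map(s_tr, ep)
  }
  for (i in seq_len(n)) {
    lo <- -de; hi <- de
    flo <- step_stress(lo)$s[2]
    for (j in 1:45) {
      mid <- (lo + hi) / 2
      fm <- step_stress(mid)$s[2]
      if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
    }
    r <- step_stress((lo + hi) / 2)
    sig <- r$s
    ep <- ep + r$dlp
  }
  list(sigma_axial = sig[1], eps_pl = ep)
}
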