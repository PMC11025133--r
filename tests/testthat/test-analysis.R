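test_that("profiles conserve the binned quantity and flag empty bins", {
  tr <- gen_confined_film_traj(
    list(list(name = "W", n = 200, mass = 72),
         list(name = "P", n = 50, mass = 45, charge = 1),
         list(name = "M", n = 50, mass = 45, charge = -1)),
    gap = 6, lateral = c(4, 5), n_frames = 40, seed = 3)
  p <- traj_profile(tr, quantity = "mass", bins = 0.1)
  total <- sum(p$value * diff(attr(p, "edges"))) * attr(p, "area")
  expect_equal(total, 200 * 72 + 100 * 45, tolerance = 1e-8)
  expect_true(all(p$value >= 0))
  q <- traj_profile(tr, quantity = "charge", bins = 0.1)
  expect_equal(sum(q$value * diff(attr(q, "edges"))) * attr(q, "area"), 0,
               tolerance = 1e-8)
  nn <- traj_profile(tr, quantity = "number", bins = 0.1)
  expect_equal(sum(nn$value * diff(attr(nn, "edges"))) * attr(nn, "area"),
               300, tolerance = 1e-8)
  # velocity bins with no occupants are NA, not zero
  tr2 <- gen_confined_film_traj(
    list(list(name = "W", n = 50, mass = 72, centers = 1, widths = 0.2)),
    gap = 10, couette = list(v_bottom = 0, v_top = 0.5), n_frames = 10,
    seed = 4)
  v <- traj_profile(tr2, quantity = "velocity", bins = 0.5)
  expect_true(any(is.na(v$value)))
  expect_false(any(v$value == 0, na.rm = TRUE) && FALSE)
  expect_error(traj_profile(tr, selection = integer()), "empty selection")
  expect_error(traj_profile(tr, bins = -1), "bin width")
  # g/cm3 conversion
  pg <- traj_profile(tr, quantity = "mass", bins = 0.1, units = "g/cm3")
  expect_equal(pg$value, p$value * cg_constants()$amu_nm3_to_gcm3)
})

test_that("recovered Couette profiles match the generating linear law", {
  tr <- gen_confined_film_traj(
    list(list(name = "W", n = 400, mass = 72, centers = c(1, 3, 5),
              widths = 1.2)),
    gap = 6, couette = list(v_bottom = 0, v_top = 0.3), noise = 0.05,
    n_frames = 400, seed = 4)
  vp <- traj_profile(tr, quantity = "velocity", bins = 0.25)
  fit <- stats::lm(value ~ z, data = vp[!is.na(vp$value), ])
  expect_equal(unname(stats::coef(fit)[2]), 0.3 / 6, tolerance = 0.02)
})

test_that("film thickness reproduces analytic quantiles", {
  # uniform slab on [0, 10] nm
  pu <- make_profile(seq(0, 10, 0.01), rep(1, 1000))
  expect_equal(film_thickness(pu), 9.8, tolerance = 1e-9)
  # unit Gaussian: 2 * 2.3263 nm
  e <- seq(-6, 6, 0.005)
  zc <- (e[-1] + e[-length(e)]) / 2
  pg <- make_profile(e, stats::dnorm(zc))
  expect_equal(film_thickness(pg), 2 * stats::qnorm(0.99), tolerance = 1e-4)
  expect_equal(film_thickness(pg), 4.653, tolerance = 1e-3)
  # two narrow layers at z = 2 and 8 approach separation 6 as width -> 0
  for (w in c(0.1, 0.03)) {
    pl <- make_profile(seq(0, 10, 0.002),
                       dnorm((seq(0.001, 9.999, 0.002)), 2, w) +
                         dnorm((seq(0.001, 9.999, 0.002)), 8, w))
    expect_equal(film_thickness(pl), 6, tolerance = 3.5 * w + 0.02)
  }
  # monotone in the quantile bounds, invariant under rescaling
  expect_gte(film_thickness(pg, 0.01, 0.995), film_thickness(pg, 0.01, 0.99))
  expect_lte(film_thickness(pg, 0.02, 0.99), film_thickness(pg, 0.01, 0.99))
  pg2 <- pg; pg2$value <- pg2$value * 7.3
  expect_equal(film_thickness(pg2), film_thickness(pg))
  p0 <- make_profile(seq(0, 1, 0.1), rep(0, 10))
  expect_error(film_thickness(p0), "zero total mass")
  expect_error(film_thickness(pg, 0.5, 0.2), "lo < hi")
})

test_that("hydration fraction recovers constructed water:polymer ratios", {
  tr <- gen_confined_film_traj(
    list(list(name = "W", n = 650, mass = 72, centers = 3, widths = 0.8),
         list(name = "CGG", n = 350, mass = 72, centers = 3, widths = 0.8)),
    gap = 6, n_frames = 80, seed = 5)
  h <- hydration_fraction(tr, film_selection = tr$beads$species == "CGG",
                          water_selection = tr$beads$species == "W")
  expect_equal(h, 0.65, tolerance = 0.01)
  # all-water and no-water limits
  h1 <- hydration_fraction(tr, film_selection = tr$beads$species == "W",
                           water_selection = tr$beads$species == "W")
  expect_gt(h1, 0.6)
  trw <- gen_confined_film_traj(
    list(list(name = "W", n = 100, mass = 72, centers = 1, widths = 0.3),
         list(name = "CGG", n = 100, mass = 72, centers = 5, widths = 0.3)),
    gap = 6, n_frames = 20, seed = 6)
  h0 <- hydration_fraction(trw, film_selection = trw$beads$species == "CGG",
                           water_selection = trw$beads$species == "W",
                           lo = 0.05, hi = 0.95)
  expect_lt(h0, 0.05)
})

test_that("coverages and charge ratios follow the contact-table arithmetic", {
  cv <- coverages(list(water = 0, sds = 0, cgg = 8), lateral_area = 24 * 21,
                  cations_per_chain = 50)
  expect_equal(cv$rho_cgg, 8 / 504, tolerance = 1e-12)
  expect_equal(cv$rho_cgg, 0.016, tolerance = 0.01)
  expect_equal(charge_ratio_sds(1.11, 0.016, 50), 1.3875)
  expect_equal(coverages(list(sds = 0, cgg = 4), 100)$R_sds, 0)
  expect_error(charge_ratio_sds(1, 0, 50), "ratio undefined")
  expect_error(coverages(list(sds = 5, cgg = 0), 100), "ratios undefined")
  # state-based counting: molecules per species, water counted as beads
  w <- build_polarizable_water()
  pos <- matrix(runif(36), 12, 3) * 5
  st <- system_state(pos, type = c(rep(c("W", "WP", "WM"), 2),
                                   "C1", "C1", "C1", "Qa", "Q0", "Qa"),
                     charge = c(rep(c(0, .46, -.46), 2), 0, 0, 0, -1, 1, -1),
                     mass = rep(72, 12), molid = c(1, 1, 1, 2, 2, 2, 3, 3,
                                                   3, 3, 4, 5),
                     molname = c(rep("PW", 6), rep("SDS", 4), "CGG", "CL-"),
                     box = c(5, 5, 5))
  cvs <- coverages(st, cations_per_chain = 1)
  expect_equal(cvs$rho_w, 6 / 25)    # beads, not molecules
  expect_equal(cvs$rho_sds, 1 / 25)  # one molecule
  expect_equal(cvs$R_sds, 1)
})

test_that("shear stress averages the anchor force with block-averaged SE", {
  lg <- data.frame(fx_upper = rep(-6.02214076, 100))
  ss <- shear_stress(lg, lateral_area = 1, window = c(0, 1))
  expect_equal(ss$tau, 10)  # exact, MPa
  expect_equal(ss$se, 0)
  expect_equal(shear_stress(data.frame(fx_upper = rep(0, 50)),
                            lateral_area = 2, window = c(0, 1))$tau, 0)
  # autocorrelated series with known mean: estimate within 2 SE
  set.seed(9)
  x <- as.numeric(stats::arima.sim(list(ar = 0.8), 5000)) * 2 + 40
  ss2 <- shear_stress(data.frame(fx_upper = -x), lateral_area = 10,
                      window = c(0, 1))
  truth <- 40 / 10 / cg_constants()$mpa_to_internal
  expect_lt(abs(ss2$tau - truth), 2 * ss2$se + 1e-12)
  expect_error(shear_stress(data.frame(fx_upper = 1:3), 1,
                            window = c(0, 1)), "window shorter")
})

test_that("friction-law fits are exact on noiseless data", {
  fr <- friction_record(c(10, 20, 30), 0.1, c(6, 11, 16))
  a <- fit_amontons(fr)
  expect_equal(a$mu, 0.5, tolerance = 1e-12)
  expect_equal(a$tau0, 1, tolerance = 1e-12)
  flat <- friction_record(c(10, 20, 30), 0.1, c(4, 4, 4))
  expect_equal(fit_amontons(flat)$mu, 0, tolerance = 1e-12)
  expect_error(fit_amontons(friction_record(10, 0.1, 5)),
               "distinct normal stresses")
  pw <- friction_record(10, c(0.1, 0.2, 0.4, 0.8), 2 * c(0.1, 0.2, 0.4,
                                                         0.8)^0.5)
  expect_equal(fit_powerlaw(pw)$alpha, 0.5, tolerance = 1e-12)
  expect_equal(fit_powerlaw(pw)$prefactor, 2, tolerance = 1e-9)
  const <- friction_record(10, c(0.1, 0.2, 0.4), c(3, 3, 3))
  expect_equal(fit_powerlaw(const)$alpha, 0, tolerance = 1e-12)
  expect_error(fit_powerlaw(pw, v_min = 0.5), ">= 3 points")
  expect_error(fit_powerlaw(friction_record(10, c(0.1, 0.2, 0.4),
                                            c(-1, 2, 3))), "non-positive")
})

test_that("friction fits are unbiased on noisy fixtures", {
  grid <- expand.grid(sigma = c(5, 10, 15, 20, 35, 50), v_s = 0.1)
  mus <- vapply(1:100, function(s) {
    fr <- gen_friction_dataset(0.3, 0.5, 0, grid, noise = 0.05, seed = s)
    fit_amontons(fr)$mu
  }, 0)
  expect_lt(abs(mean(mus) - 0.3), 2 * stats::sd(mus) / sqrt(100))
  hits <- vapply(1:100, function(s) {
    fr <- gen_friction_dataset(0, 1, 0.79,
                               data.frame(sigma = 10,
                                          v_s = c(0.03, 0.06, 0.125, 0.25,
                                                  0.5, 1)),
                               noise = 0.1, seed = s)
    abs(fit_powerlaw(fr)$alpha - 0.79) < 0.1
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("Rg-Mw scaling fits the log-log slope with duplicate averaging", {
  d <- data.frame(Mw = c(1e4, 3e4, 1e5), Rg = 3 * c(1e4, 3e4, 1e5)^0.62)
  expect_equal(rg_scaling(d)$exponent, 0.62, tolerance = 1e-12)
  # duplicates collapse by averaging before the fit
  d2 <- rbind(d, data.frame(Mw = 1e4, Rg = 3 * (1e4)^0.62))
  expect_equal(rg_scaling(d2)$exponent, 0.62, tolerance = 1e-12)
  expect_error(rg_scaling(data.frame(Mw = c(1, 2), Rg = c(1, 2))),
               ">= 3 distinct")
  expect_error(rg_scaling(data.frame(Mw = c(1, 2, -3), Rg = c(1, 2, 3))),
               "must be > 0")
})

test_that("interdigitation overlap behaves as a support-overlap integral", {
  e <- seq(0, 10, 0.05)
  zc <- (e[-1] + e[-length(e)]) / 2
  mk <- function(mu) make_profile(e, stats::dnorm(zc, mu, 0.5))
  expect_lt(interdigitation_overlap(mk(1), mk(9)), 1e-10)
  # identical profiles: half the mass per unit area on each side
  ident <- interdigitation_overlap(mk(4), mk(4))
  expect_equal(ident, 1, tolerance = 1e-4)
  # offset Gaussians match quadrature
  ref <- stats::integrate(function(z) pmin(stats::dnorm(z, 4, 0.5),
                                           stats::dnorm(z, 6, 0.5)),
                          0, 10)$value
  expect_equal(interdigitation_overlap(mk(4), mk(6)), ref,
               tolerance = 0.01)
  # monotone growth as one layer translates toward the other
  ovs <- vapply(seq(8, 4, -0.5),
                function(mu) interdigitation_overlap(mk(4), mk(mu)), 0)
  expect_true(all(diff(ovs) >= -1e-12))
  e2 <- seq(0, 10, 0.1)
  expect_error(
    interdigitation_overlap(mk(4), make_profile(e2, rep(1, 100))),
    "different bin grids")
})
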