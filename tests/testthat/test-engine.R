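test_that("a force-free bead moves uniformly and exactly", {
  st <- system_state(pos = matrix(2, 1, 3), type = "W", charge = 0,
                     mass = 72, molid = 1L, box = c(10, 10, 10),
                     periodic = rep(FALSE, 3))
  st$vel <- matrix(c(0.1, -0.05, 0.02), 1, 3)
  log <- run_md(st, 1000, integrator_config(dt = 0.01), lj = FALSE,
                sample_every = 1000)
  expect_equal(log$state$pos[1, ], c(2, 2, 2) + c(0.1, -0.05, 0.02) * 10,
               tolerance = 1e-12)
  expect_equal(log$state$vel, st$vel, tolerance = 1e-15)
})

test_that("the harmonic dimer oscillates at the closed-form period", {
  st <- make_bond_dimer(r = 0.6, r0 = 0.5, K = 625)
  period <- 2 * pi * sqrt(36 / (2 * 625))  # reduced mass 36 amu
  log <- run_md(st, 20000, integrator_config(dt = period / 1000),
                lj = FALSE, sample_every = 20000, frame_every = 1)
  d <- sqrt(colSums((log$frames[1, , ] - log$frames[2, , ])^2)) - 0.5
  zc <- which(d[-1] * d[-length(d)] < 0)
  frac <- d[zc] / (d[zc] - d[zc + 1])
  tz <- (zc + frac) * period / 1000
  expect_equal(2 * mean(diff(tz)), period, tolerance = 1e-3)
})

test_that("energy and momentum are conserved in NVE", {
  # short-run check; the long 1e5-step drift bound runs with the
  # acceptance suite
  st <- system_state(pos = rbind(c(2, 2, 2), c(2.55, 2, 2)),
                     type = c("C1", "C1"), charge = c(0, 0),
                     mass = c(72, 72), molid = 1:2, box = c(6, 6, 6),
                     periodic = rep(FALSE, 3))
  st$vel <- rbind(c(0.05, 0, 0), c(-0.05, 0, 0))
  log <- run_md(st, 20000, integrator_config(dt = 0.005), sample_every = 10)
  E <- log$scalars$KE + log$scalars$PE
  expect_lt((max(E) - min(E)) / abs(mean(E)), 1e-4)
  # many-body momentum conservation
  stf <- make_lj_fluid(nside = 4, spacing = 0.62, seed = 2)
  log2 <- run_md(stf, 500, integrator_config(dt = 0.002),
                 sample_every = 500)
  p0 <- colSums(stf$vel * stf$mass)
  p1 <- colSums(log2$state$vel * log2$state$mass)
  expect_lt(max(abs(p1 - p0)), 1e-9)
})

test_that("the Langevin thermostat samples the target temperature", {
  st <- make_lj_fluid(nside = 5, spacing = 0.6, T = 250, seed = 1)
  log <- run_md(st, 30000,
                integrator_config(dt = 0.005, thermostat = "langevin",
                                  T_target = 300, damping = 1, seed = 7),
                sample_every = 20)
  Tbar <- mean(log$scalars$T[log$scalars$step > 6000])
  expect_equal(Tbar, 300, tolerance = 0.02)
})

test_that("speed components in equilibrium are Gaussian", {
  st <- make_lj_fluid(nside = 5, spacing = 0.6, seed = 3)
  log <- run_md(st, 30000,
                integrator_config(dt = 0.005, thermostat = "langevin",
                                  T_target = 300, damping = 1, seed = 9),
                sample_every = 1000, frame_every = 200)
  vx <- as.vector(log$vel_frames[, 1, 51:150])
  expect_gte(length(vx), 1e4)
  set.seed(5)
  expect_gt(nortest::ad.test(sample(vx, 1e4))$p.value, 0.01)
})

test_that("axis- and group-restricted Langevin perturbs only its targets", {
  set.seed(4)
  st <- system_state(pos = matrix(runif(30) * 4 + 10, 10, 3),
                     type = rep("W", 10), charge = rep(0, 10),
                     mass = rep(72, 10), molid = 1:10,
                     box = c(50, 50, 50), periodic = rep(FALSE, 3))
  st$vel <- matrix(0.1, 10, 3)
  log <- run_md(st, 200, integrator_config(dt = 0.005,
                                           thermostat = "langevin",
                                           axes = "y", seed = 3),
                lj = FALSE, sample_every = 200)
  expect_true(all(log$state$vel[, c(1, 3)] == 0.1))
  expect_false(any(log$state$vel[, 2] == 0.1))
  # zero-temperature limit: velocity decays monotonically
  st1 <- system_state(pos = matrix(2, 1, 3), type = "W", charge = 0,
                      mass = 72, molid = 1L, box = c(5, 5, 5),
                      periodic = rep(FALSE, 3))
  st1$vel <- matrix(c(0.3, 0, 0), 1, 3)
  lg <- run_md(st1, 500, integrator_config(dt = 0.01,
                                           thermostat = "langevin",
                                           T_target = 0, damping = 0.5,
                                           seed = 1),
               lj = FALSE, sample_every = 10)
  expect_true(all(diff(lg$scalars$KE) <= 1e-15))
  expect_error(run_md(st1, 10, integrator_config(thermostat = "langevin",
                                                 group = "nope")),
               "thermostat group is empty")
})

test_that("the Nose-Hoover thermostat holds the target on average", {
  st <- make_lj_fluid(nside = 5, spacing = 0.62, T = 250, seed = 2)
  log <- run_md(st, 40000,
                integrator_config(dt = 0.005, thermostat = "nose-hoover",
                                  T_target = 300, damping = 1),
                sample_every = 20)
  expect_equal(mean(log$scalars$T[log$scalars$step > 10000]), 300,
               tolerance = 0.03)
})

test_that("SHAKE holds water constraints and preserves centre of mass", {
  w <- build_polarizable_water()
  st <- system_state(w$coords + 1.5, w$beads$type, w$beads$charge,
                     w$beads$mass, rep(1L, 3), rep("PW", 3),
                     angles = w$angles, constraints = w$constraints,
                     exclusions = w$exclusions, box = c(3, 3, 3),
                     periodic = rep(FALSE, 3))
  st <- init_velocities(st, 300, seed = 2)
  log <- run_md(st, 2000, integrator_config(dt = 0.005,
                                            thermostat = "langevin",
                                            seed = 3),
                lj = FALSE, sample_every = 100, frame_every = 50,
                shake_tol = 1e-8)
  viol <- vapply(seq_len(dim(log$frames)[3]), function(f) {
    p <- log$frames[, , f]
    max(abs(sqrt(sum((p[1, ] - p[2, ])^2)) - 0.14),
        abs(sqrt(sum((p[1, ] - p[3, ])^2)) - 0.14))
  }, 0)
  expect_lt(max(viol), 1e-6)
  # stretched constrained dimer relaxes with its centre of mass fixed
  std <- system_state(pos = rbind(c(1, 1, 1), c(1.3, 1, 1)),
                      type = c("W", "W"), charge = c(0, 0),
                      mass = c(24, 24), molid = c(1L, 1L),
                      constraints = data.frame(i = 1, j = 2, length = 0.14),
                      box = c(5, 5, 5), periodic = rep(FALSE, 3))
  lgd <- run_md(std, 10, integrator_config(dt = 0.005), lj = FALSE,
                sample_every = 10)
  p <- lgd$state$pos
  expect_equal(sqrt(sum((p[1, ] - p[2, ])^2)), 0.14, tolerance = 1e-6)
  expect_equal(colMeans(p), colMeans(std$pos), tolerance = 1e-9)
  # already-satisfied constraints are a fixed point
  stw <- st; stw$vel[] <- 0
  lg0 <- run_md(stw, 5, integrator_config(dt = 0.001), lj = FALSE,
                sample_every = 5)
  d12 <- sqrt(sum((lg0$state$pos[1, ] - lg0$state$pos[2, ])^2))
  expect_equal(d12, 0.14, tolerance = 1e-9)
})

test_that("damped force-shifted Coulomb matches signs and the closed form", {
  mk <- function(q1, q2, box = 2000) system_state(
    pos = rbind(c(1, 1, 1), c(1.5, 1, 1)), type = c("Qd", "Qa"),
    charge = c(q1, q2), mass = c(72, 72), molid = 1:2,
    box = rep(box, 3), periodic = rep(FALSE, 3))
  f <- cg_constants()$f_coulomb
  # +/- pair at 0.5 nm, vacuum dielectric, no damping, large cutoff
  ce <- coulomb_energy(mk(1, -1), r_cut = 900)
  expect_equal(ce$energy, -f / 0.5, tolerance = 2e-3)
  # like charges: positive energy, repulsive force along the separation
  cp <- coulomb_energy(mk(1, 1), r_cut = 900)
  expect_gt(cp$energy, 0)
  expect_lt(cp$forces[1, 1], 0)
  expect_gt(cp$forces[2, 1], 0)
  expect_identical(coulomb_energy(mk(0, 0), r_cut = 900)$energy, 0)
  # dielectric scaling
  ce2 <- coulomb_energy(mk(1, -1), r_cut = 900, dielectric = 2.5)
  expect_equal(ce2$energy, ce$energy / 2.5, tolerance = 1e-9)
  # energy and force vanish continuously at the cutoff
  st2 <- mk(1, -1, box = 10)
  st2$pos[2, 1] <- 1 + 1.2 - 1e-9
  near <- coulomb_energy(st2, r_cut = 1.2, damping = 1)
  expect_lt(abs(near$energy), 1e-6)
  expect_lt(max(abs(near$forces)), 1e-4)
  stp <- mk(1, -1, box = 2)
  stp$periodic <- rep(TRUE, 3)
  expect_error(run_md(stp, 1, integrator_config(),
                      coulomb = list(r_cut = 1.5)),
               "exceeds half the box")
})

test_that("identical state, config and seed give bit-identical logs", {
  st <- make_lj_fluid(nside = 4, spacing = 0.62, seed = 5)
  run <- function() run_md(st, 1500,
                           integrator_config(dt = 0.005,
                                             thermostat = "langevin",
                                             seed = 11),
                           sample_every = 100, frame_every = 500)
  a <- run(); b <- run()
  expect_identical(a$scalars, b$scalars)
  expect_identical(a$frames, b$frames)
  expect_identical(a$state$pos, b$state$pos)
})

test_that("radius of gyration handles trivial and periodic cases", {
  st1 <- system_state(pos = matrix(1, 1, 3), type = "W", charge = 0,
                      mass = 72, molid = 1L, box = c(5, 5, 5))
  bt1 <- bead_traj(array(1, c(1, 3, 2)),
                   data.frame(name = "a", type = "W", mass = 72))
  expect_equal(sample_rg(bt1, 1, st1), c(0, 0))
  std <- system_state(pos = rbind(c(0, 0, 0), c(1.4, 0, 0)),
                      type = c("W", "W"), charge = c(0, 0), mass = c(1, 1),
                      molid = c(1L, 1L),
                      bonds = data.frame(i = 1, j = 2, r0 = 1.4, K = 1),
                      box = c(10, 10, 10))
  btd <- bead_traj(array(std$pos, c(2, 3, 1)),
                   data.frame(name = c("a", "b"), type = "W", mass = 1))
  expect_equal(sample_rg(btd, 1, std), 0.7)
  # bond split across the boundary unwraps before the Rg computation
  stp <- std
  stp$pos <- rbind(c(0.3, 5, 5), c(9.9, 5, 5))  # true length 0.4 across x
  btp <- bead_traj(array(stp$pos, c(2, 3, 1)),
                   data.frame(name = c("a", "b"), type = "W", mass = 1))
  expect_equal(sample_rg(btp, 1, stp), 0.2)
  expect_error(sample_rg(btd, 7, std), "not found")
})

test_that("a loaded piston transmits the applied normal stress", {
  # reduced-size check; the 5% oracle at full sampling runs with the
  # acceptance suite
  st <- make_lj_film(nf = 220, gap = 3.4, seed = 2)
  eq <- run_confined(st, integrator_config(dt = 0.005,
                                           thermostat = "langevin",
                                           T_target = 300, damping = 0.5,
                                           seed = 3),
                     load_slide_config(sigma = 30, v_s = 0),
                     n_steps = 40000, sample_every = 100,
                     lj_table = film_lj_table())
  pr <- run_confined(eq$state, integrator_config(dt = 0.005,
                                                 thermostat = "langevin",
                                                 T_target = 300,
                                                 damping = 0.5, seed = 4),
                     load_slide_config(sigma = 30, v_s = 0),
                     n_steps = 100000, sample_every = 100,
                     lj_table = film_lj_table())
  A <- st$box[1] * st$box[2]
  sigA <- 30 * cg_constants()$mpa_to_internal * A
  expect_equal(abs(mean(pr$scalars$fz_lower)) / sigA, 1, tolerance = 0.12)
  # gap is recorded and stationary at equilibrium
  g <- pr$scalars$gap
  expect_lt(abs(mean(utils::head(g, 200)) - mean(utils::tail(g, 200))), 0.1)
  expect_error(run_md(make_lj_fluid(nside = 3), 10, integrator_config(),
                      load = load_slide_config(sigma = 1)),
               "upper_anchor")
})

test_that("an unloaded, unsheared empty contact keeps its gap", {
  st <- make_lj_film(nf = 0, gap = 3, seed = 5)
  log <- run_confined(st, integrator_config(dt = 0.005),
                      load_slide_config(sigma = 0, v_s = 0),
                      n_steps = 2000, sample_every = 100,
                      lj_table = film_lj_table())
  expect_lt(max(abs(log$scalars$gap - 3)), 1e-6)
})
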