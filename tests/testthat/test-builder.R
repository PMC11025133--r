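test_that("cationic chains carry round(DS x n) charges and counterions", {
  ch <- build_cgg_chain(chain_spec(50, DS = 1, seed = 7))
  expect_identical(net_charge(ch$template), 50)
  expect_identical(ch$counterions, 50)
  expect_identical(nrow(ch$template$beads), 50L * 11L)
  ch0 <- build_cgg_chain(chain_spec(50, DS = 0, seed = 7))
  expect_identical(net_charge(ch0$template), 0)
  expect_identical(nrow(ch0$template$beads), 50L * 9L)
  chh <- build_cgg_chain(chain_spec(20, DS = 0.5, seed = 3))
  expect_identical(net_charge(chh$template), 10)
  expect_length(chh$functionalized, 10)
  # regular placement spreads the functional groups nearly evenly
  chr <- build_cgg_chain(chain_spec(20, DS = 0.5,
                                    placement = "regular", seed = 3))
  expect_length(chr$functionalized, 10)
  expect_lte(diff(range(diff(chr$functionalized))), 1)
})

test_that("chain builds are deterministic in the seed and self-avoiding", {
  a <- build_cgg_chain(chain_spec(20, DS = 0.5, seed = 9))
  b <- build_cgg_chain(chain_spec(20, DS = 0.5, seed = 9))
  expect_identical(a$template$coords, b$template$coords)
  # different seeds: different walks, identical topology (fixing the
  # functionalization pattern via DS = 1)
  f1 <- build_cgg_chain(chain_spec(20, DS = 1, seed = 9))
  f2 <- build_cgg_chain(chain_spec(20, DS = 1, seed = 10))
  expect_false(identical(f1$template$coords, f2$template$coords))
  expect_identical(f1$template$bonds, f2$template$bonds)
  expect_identical(f1$template$angles, f2$template$angles)
  # self-avoidance: all non-bonded bead pairs at least min_dist apart
  spec <- chain_spec(15, DS = 1, min_dist = 0.3, seed = 4)
  tm <- build_cgg_chain(spec)$template
  d <- as.matrix(dist(tm$coords))
  bonded <- matrix(FALSE, nrow(d), nrow(d))
  bonded[cbind(tm$bonds$i, tm$bonds$j)] <- TRUE
  bonded <- bonded | t(bonded) | diag(nrow(d)) == 1
  expect_gte(min(d[!bonded]), spec$min_dist)
  expect_error(chain_spec(10, DS = 1.5), "DS")
  expect_error(build_cgg_chain(chain_spec(30, DS = 1, min_dist = 0.46,
                                          max_retry = 5, seed = 1)),
               "self-avoiding walk failed")
})

test_that("the surfactant template is a linear 4-bead anion", {
  s <- build_sds()
  expect_identical(nrow(s$sds$beads), 4L)
  expect_identical(net_charge(s$sds), -1)
  expect_identical(nrow(s$sds$bonds), 3L)
  expect_identical(nrow(s$sds$angles), 2L)
  expect_identical(net_charge(s$sds) + net_charge(s$counterion), 0)
  expect_identical(s$sds$beads$type, c("C1", "C1", "C1", "Qa"))
})

test_that("polarizable water has constrained geometry and zero net charge", {
  w <- build_polarizable_water()
  expect_identical(nrow(w$beads), 3L)
  expect_identical(w$constraints$length, c(0.14, 0.14))
  expect_identical(net_charge(w), 0)
  expect_identical(w$angles$theta0, 0)
  expect_identical(w$angles$K_theta, 2.1)
  expect_identical(w$beads$charge[2], -w$beads$charge[3])
})

test_that("bulk assembly neutralizes, avoids overlap and reports molarity", {
  s <- build_sds()
  bk <- assemble_bulk(list(s$sds, s$counterion), counts = c(4, 4),
                      box = c(8, 8, 8), neutralize = TRUE, seed = 3)
  expect_identical(net_charge(bk), 0)
  expect_identical(sum(bk$molname == "SDS"), 16L)
  ch <- build_cgg_chain(chain_spec(10, DS = 1, seed = 3))
  bk2 <- assemble_bulk(list(ch$template), counts = 1, box = c(12, 12, 12),
                       neutralize = TRUE, seed = 4)
  expect_identical(sum(bk2$molname == "CL-"), 10L)
  expect_identical(net_charge(bk2), 0)
  # determinism and minimum-image overlap tolerance
  bk3 <- assemble_bulk(list(s$sds), counts = 6, box = c(6, 6, 6), seed = 5)
  bk4 <- assemble_bulk(list(s$sds), counts = 6, box = c(6, 6, 6), seed = 5)
  expect_identical(bk3$pos, bk4$pos)
  other <- outer(bk3$molid, bk3$molid, "!=")
  dd <- array(Inf, dim(other))
  for (ax in 1:3) {
    d <- outer(bk3$pos[, ax], bk3$pos[, ax], "-")
    d <- d - 6 * round(d / 6)
    dd[] <- ifelse(is.infinite(dd), d^2, dd + d^2)
  }
  expect_gte(sqrt(min(dd[other])), 0.3)
  expect_equal(molarity(400, c(10, 10, 10)), 0.664, tolerance = 0.001)
  expect_error(assemble_bulk(list(s$sds), counts = 500, box = c(3, 3, 3),
                             seed = 1, max_retry = 20), "failed to insert")
})

test_that("grafted surfaces follow the density, charge and tagging rules", {
  sf <- build_graft_surface(surface_spec(24, 21, graft_density = 0.5,
                                         anionic_fraction = 0,
                                         graft_len = 2), seed = 1)
  expect_identical(length(unique(sf$molid[sf$molname == "GRAFT"])), 252L)
  expect_identical(net_charge(sf), 0)
  expect_identical(sum(sf$group == "graft_base"), 252L)
  sf2 <- build_graft_surface(surface_spec(10, 10, graft_density = 1,
                                          anionic_fraction = 0.5,
                                          graft_len = 3), seed = 2)
  expect_identical(sum(sf2$charge == -1), 50L)
  expect_identical(sum(sf2$molname == "NA+"), 50L)
  expect_identical(net_charge(sf2), 0)
  expect_error(build_graft_surface(surface_spec(5, 5, graft_density = 10,
                                                spacing = 1), seed = 1),
               "exceeds lattice capacity")
  expect_error(surface_spec(5, 5, anionic_fraction = 2), "anionic_fraction")
})

test_that("contacts are mirrored without losing beads or group identity", {
  sf <- build_graft_surface(surface_spec(6, 6, graft_density = 0.5,
                                         anionic_fraction = 0.5,
                                         graft_len = 2), seed = 2)
  ct <- make_contact(sf, gap = 24)
  expect_identical(n_beads(ct), 2L * n_beads(sf))
  expect_true(any(ct$group == "upper_anchor"))
  expect_true(any(ct$group == "lower_anchor"))
  zu <- mean(ct$pos[ct$group == "upper_anchor", 3])
  zl <- mean(ct$pos[ct$group == "lower_anchor", 3])
  ztop <- max(sf$pos[, 3])
  expect_equal(zu - zl, 2 * ztop + 24, tolerance = 1e-9)
  # reflection applied twice is the identity
  m <- mirror_z(mirror_z(sf, 5), 5)
  expect_equal(m$pos, sf$pos, tolerance = 1e-12)
  expect_identical(m$group, sf$group)
  bad <- sf; bad$box[1] <- 7
  expect_error(merge_states(sf, bad), "lateral box dimensions differ")
})

test_that("LAMMPS data files round-trip positions, charges and topology", {
  set.seed(11)
  st <- system_state(pos = matrix(runif(30) * 5, 10, 3),
                     type = rep(c("C1", "Qa"), 5),
                     charge = rep(c(0, -1), 5), mass = rep(72, 10),
                     molid = rep(1:5, each = 2),
                     bonds = data.frame(i = c(1, 3), j = c(2, 4),
                                        r0 = 0.47, K = 625),
                     angles = data.frame(i = 1, j = 2, k = 3, theta0 = 120,
                                         K_theta = 12.5),
                     constraints = data.frame(i = 5, j = 6, length = 0.14),
                     box = c(5, 5, 5))
  st$vel <- matrix(rnorm(30, sd = 0.1), 10, 3)
  f <- withr::local_tempfile()
  write_lammps_data(st, f)
  st2 <- read_lammps_data(f)
  expect_lt(max(abs(st2$pos - st$pos)), 1e-8)
  expect_lt(max(abs(st2$vel - st$vel)), 1e-8)
  expect_identical(st2$charge, st$charge)
  expect_identical(sum(st2$charge), sum(st$charge))
  expect_identical(st2$type, st$type)
  expect_equal(st2$bonds$K, st$bonds$K, tolerance = 1e-9)
  expect_equal(st2$bonds$r0, st$bonds$r0, tolerance = 1e-12)
  expect_equal(st2$constraints$length, 0.14, tolerance = 1e-12)
  expect_equal(st2$angles$theta0, 120, tolerance = 1e-12)
  expect_equal(st2$angles$K_theta, 12.5, tolerance = 1e-9)
  # empty system round-trips
  e <- system_state(pos = matrix(0, 0, 3), type = character(),
                    charge = numeric(), mass = numeric(), molid = integer(),
                    box = c(5, 5, 5))
  f2 <- withr::local_tempfile()
  write_lammps_data(e, f2)
  expect_identical(n_beads(read_lammps_data(f2)), 0L)
  # unknown section
  expect_error(read_lammps_data(c("title", "", "Bananas", "", "1 2 3")),
               "unknown section header")
})

test_that("GRO and dump writers preserve coordinates at printed precision", {
  set.seed(12)
  st <- system_state(pos = matrix(runif(12) * 4, 4, 3),
                     type = c("W", "WP", "WM", "C1"),
                     charge = c(0, 0.46, -0.46, 0), mass = rep(24, 4),
                     molid = c(1L, 1L, 1L, 2L),
                     molname = c("PW", "PW", "PW", "SDS"), box = c(4, 4, 4))
  f <- withr::local_tempfile(fileext = ".gro")
  write_gro(st, f)
  g <- read_gro(f)
  expect_lt(max(abs(g$pos - st$pos)), 5.01e-4)
  expect_identical(g$resname, st$molname)
  tr <- gen_confined_film_traj(list(list(name = "W", n = 20, mass = 72)),
                               gap = 3, n_frames = 4, seed = 8)
  fd <- withr::local_tempfile(fileext = ".dump")
  write_lammps_dump(tr, fd)
  tr2 <- read_lammps_dump(fd)
  expect_lt(max(abs(tr2$coords - tr$coords)), 1e-8)
  expect_lt(max(abs(tr2$vel - tr$vel)), 1e-8)
  expect_identical(n_frames(tr2), 4L)
})
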