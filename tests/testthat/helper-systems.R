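# Shared fixtures built in code: small LJ systems, confined films, chains.

kB <- cg_constants()$kB

# dimer bound by one harmonic bond
make_bond_dimer <- function(r = 0.6, r0 = 0.5, K = 625, mass = 72) {
  system_state(pos = rbind(c(1, 1, 1), c(1 + r, 1, 1)),
               type = c("C1", "C1"), charge = c(0, 0),
               mass = rep(mass, 2), molid = c(1L, 1L),
               bonds = data.frame(i = 1, j = 2, r0 = r0, K = K),
               box = c(5, 5, 5), periodic = rep(FALSE, 3))
}

# simple cubic LJ fluid
make_lj_fluid <- function(nside = 5, spacing = 0.6, T = 300, seed = 1) {
  g <- as.matrix(expand.grid(x = seq_len(nside), y = seq_len(nside),
                             z = seq_len(nside))) * spacing
  n <- nrow(g)
  st <- system_state(pos = g, type = rep("C1", n), charge = rep(0, n),
                     mass = rep(72, n), molid = seq_len(n),
                     box = rep(nside * spacing, 3))
  init_velocities(st, T, seed = seed)
}

# confined LJ film between two rough rigid walls
make_lj_film <- function(lx = 3.2, ly = 3.2, gap = 4.6, wall_sp = 0.4,
                         nf = 330, seed = 1) {
  set.seed(seed)
  nx <- round(lx / wall_sp); ny <- round(ly / wall_sp)
  lat <- as.matrix(expand.grid(x = (seq_len(nx) - 0.5) * lx / nx,
                               y = (seq_len(ny) - 0.5) * ly / ny))
  nw <- nrow(lat)
  jit <- function() cbind(runif(nw, -0.06, 0.06), runif(nw, -0.06, 0.06), 0)
  zlo <- 0.5
  lower <- cbind(lat, zlo) + jit()
  upper <- cbind(lat, zlo + gap) + jit()
  ng <- ceiling(nf^(1 / 3))
  fg <- as.matrix(expand.grid(x = seq_len(ng), y = seq_len(ng),
                              z = seq_len(ng)))[seq_len(nf), ]
  fl <- cbind(fg[, 1] / ng * lx, fg[, 2] / ng * ly,
              zlo + 0.45 + (fg[, 3] - 0.5) / ng * (gap - 0.9))
  pos <- rbind(lower, upper, fl)
  n <- nrow(pos)
  st <- system_state(
    pos = pos, type = c(rep("GRA", 2 * nw), rep("C1", nf)),
    charge = rep(0, n), mass = rep(72, n), molid = seq_len(n),
    group = c(rep("lower_anchor", nw), rep("upper_anchor", nw),
              rep("mobile", nf)),
    box = c(lx, ly, zlo * 2 + gap + 1), periodic = c(TRUE, TRUE, FALSE))
  init_velocities(st, 300, seed = seed + 1)
}

# sticky walls so the sheared film does not slip
film_lj_table <- function() {
  lj_pair_table(default_lj_table()$classes,
                pairs = data.frame(class1 = "GRA", class2 = "C1",
                                   epsilon = 6, sigma = 0.47))
}

# linear bonded-only chain (freely jointed when angles absent)
make_chain <- function(N, b = 0.47, K = 1250, angles = NULL) {
  pos <- cbind((seq_len(N) - 1) * b * 0.8, 0.1 * sin(seq_len(N)),
               0.1 * cos(2 * seq_len(N)))
  ang <- if (is.null(angles)) {
    data.frame(i = integer(), j = integer(), k = integer(),
               theta0 = numeric(), K_theta = numeric())
  } else {
    data.frame(i = 1:(N - 2), j = 2:(N - 1), k = 3:N,
               theta0 = angles$theta0, K_theta = angles$K_theta)
  }
  system_state(pos = pos + 30, type = rep("P4", N), charge = rep(0, N),
               mass = rep(72, N), molid = rep(1L, N),
               bonds = data.frame(i = 1:(N - 1), j = 2:N, r0 = b, K = K),
               angles = ang,
               box = c(100, 100, 100), periodic = rep(FALSE, 3))
}

# analytic profile object on a given grid
make_profile <- function(edges, values) {
  structure(data.frame(z = (edges[-1] + edges[-length(edges)]) / 2,
                       value = values),
            class = c("profile", "data.frame"), edges = edges)
}

# <r^2> of the radially weighted harmonic bond distribution
bond_b2_eff <- function(r0, K, T = 300) {
  num <- stats::integrate(function(r) r^4 * exp(-K * (r - r0)^2 / (kB * T)),
                          0, r0 + 8 * sqrt(kB * T / (2 * K)))$value
  den <- stats::integrate(function(r) r^2 * exp(-K * (r - r0)^2 / (kB * T)),
                          0, r0 + 8 * sqrt(kB * T / (2 * K)))$value
  num / den
}
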