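# Synthetic-data generators: Boltzmann bonded samples, pseudo-atomistic
# trajectories with prescribed bonded distributions, confined-film
# trajectories with prescribed layering and Couette flow, and friction
# datasets with known mu, tau0 and alpha.  All generators are deterministic
# in (spec, seed); independent substreams are derived per species/unit by
# hashing the seed with a counter so that adding one component does not
# perturb the others.

.substream <- function(seed, k) {
  (as.numeric(seed) * 2654435761 + 97531 * as.numeric(k)) %% 2147483647
}

#' Draw Boltzmann samples of a harmonic coordinate
#'
#' Samples from the Gaussian implied by the half-included harmonic
#' Boltzmann factor exp(-K (x - x0)^2 / kB T): mean `x0`, variance
#' kB T / (2 K).
#'
#' @param x0 Equilibrium value (nm for bonds, rad for angles).
#' @param K Half-included force constant (> 0).
#' @param T Temperature (K), > 0.
#' @param n Number of samples (>= 2).
#' @param seed RNG seed (mandatory).
#' @return Numeric vector of samples.
#' @export
gen_boltzmann_samples <- function(x0, K, T, n, seed) {
  if (K <= 0) stop("gen_boltzmann_samples: K must be > 0")
  if (T < 0) stop("gen_boltzmann_samples: T must be >= 0")
  if (n < 2) stop("gen_boltzmann_samples: n must be >= 2")
  if (missing(seed)) stop("gen_boltzmann_samples: seed is mandatory")
  .with_seed(seed, stats::rnorm(n, x0, sqrt(.kB * T / (2 * K))))
}

#' Generate a pseudo-atomistic trajectory with prescribed bonded statistics
#'
#' Emulates an atomistic reference trajectory for the mapping/inversion
#' pipeline: a bead skeleton (linear chain) is sampled frame by frame from
#' the target bond/angle Boltzmann distributions, then member atoms are
#' placed rigidly around each bead centre with zero mass-weighted offset,
#' so that [map_trajectory()] recovers the skeleton exactly.
#'
#' @param scheme A [mapping_scheme()] describing one residue whose beads
#'   form a linear chain in listed order; atom masses are taken from
#'   `atom_masses`.
#' @param targets list with `bond = list(r0, K)` and (for >= 3 beads)
#'   `angle = list(theta0, K)` (theta0 in radians), the generating
#'   half-included parameters shared by all bond/angle instances.
#' @param n_frames Number of frames.
#' @param T Temperature (K).
#' @param seed RNG seed (mandatory).
#' @param atom_masses Named masses (amu) for member atoms; atoms not
#'   listed default to 12.
#' @return list(traj = [atom_traj()], skeleton = [bead_traj()],
#'   topology = bond/angle instance tables for
#'   [collect_distributions()]).
#' @export
gen_pseudo_atomistic_traj <- function(scheme, targets, n_frames, T = 300,
                                      seed, atom_masses = NULL) {
  stopifnot(inherits(scheme, "mapping_scheme"))
  if (missing(seed)) stop("gen_pseudo_atomistic_traj: seed is mandatory")
  rn <- names(scheme$residues)[1]
  beads <- scheme$residues[[rn]]
  nb <- length(beads)
  if (is.null(targets$bond))
    stop("gen_pseudo_atomistic_traj: targets must include bond parameters")
  if (nb >= 3 && is.null(targets$angle))
    stop("gen_pseudo_atomistic_traj: angle targets required for a chain of ",
         nb, " beads")
  .with_seed(.substream(seed, 1), {
    r0 <- targets$bond$r0; Kb <- targets$bond$K
    sb <- sqrt(.kB * T / (2 * Kb))
    # skeleton: sequential placement with sampled bond lengths and angles
    skel <- array(0, c(nb, 3, n_frames))
    if (nb >= 2) {
      r1 <- stats::rnorm(n_frames, r0, sb)
      skel[2, 1, ] <- r1
    }
    if (nb >= 3) {
      th0 <- targets$angle$theta0; Ka <- targets$angle$K
      sa <- sqrt(.kB * T / (2 * Ka))
      for (b in 3:nb) {
        rl <- stats::rnorm(n_frames, r0, sb)
        th <- stats::rnorm(n_frames, th0, sa)
        th <- pmin(pi, pmax(0, th))
        phi <- stats::runif(n_frames, 0, 2 * pi)
        # local frame at bead b-1: e1 along previous bond direction
        prev <- matrix(skel[b - 1, , ] - skel[b - 2, , ], nrow = 3)
        pn <- sqrt(colSums(prev^2))
        e1 <- sweep(prev, 2, pn, "/")
        # arbitrary perpendicular pair
        ref <- rbind(rep(0, n_frames), rep(0, n_frames), rep(1, n_frames))
        par <- abs(colSums(e1 * ref)) > 0.99
        ref[, par] <- c(1, 0, 0)
        e2 <- ref - sweep(e1, 2, colSums(e1 * ref), "*")
        e2 <- sweep(e2, 2, sqrt(colSums(e2^2)), "/")
        e3 <- rbind(e1[2, ] * e2[3, ] - e1[3, ] * e2[2, ],
                    e1[3, ] * e2[1, ] - e1[1, ] * e2[3, ],
                    e1[1, ] * e2[2, ] - e1[2, ] * e2[1, ])
        # bond direction at interior angle th to the previous bond
        dirn <- sweep(e1, 2, -cos(th), "*") +
          sweep(e2, 2, sin(th) * cos(phi), "*") +
          sweep(e3, 2, sin(th) * sin(phi), "*")
        skel[b, , ] <- skel[b - 1, , ] + sweep(dirn, 2, rl, "*")
      }
    }
    # atoms placed rigidly around bead centres with zero weighted offset
    atoms_list <- list(); coords_list <- list()
    offset_cache <- list()
    for (b in seq_len(nb)) {
      at <- beads[[b]]$atoms
      na <- length(at)
      ms <- vapply(at, function(a) {
        if (!is.null(atom_masses) && a %in% names(atom_masses))
          atom_masses[[a]] else 12
      }, 0)
      # fixed local offsets with mass-weighted mean zero
      off <- matrix(stats::rnorm(3 * na, sd = 0.05), na, 3)
      off <- sweep(off, 2, colSums(off * ms) / sum(ms))
      offset_cache[[b]] <- off
      atoms_list[[b]] <- data.frame(name = at, resid = 1, resname = rn,
                                    mass = ms, stringsAsFactors = FALSE)
      crd <- array(0, c(na, 3, n_frames))
      for (ax in 1:3)
        crd[, ax, ] <- matrix(rep(skel[b, ax, ], each = na), na, n_frames) +
          off[, ax]
      coords_list[[b]] <- crd
    }
    atoms <- do.call(rbind, atoms_list)
    natom <- nrow(atoms)
    co <- array(0, c(natom, 3, n_frames))
    row0 <- 0
    for (b in seq_len(nb)) {
      na <- nrow(atoms_list[[b]])
      co[row0 + seq_len(na), , ] <- coords_list[[b]]
      row0 <- row0 + na
    }
    btypes <- vapply(beads, `[[`, "", "type")
    topo <- list()
    if (nb >= 2)
      topo$bonds <- data.frame(
        i = 1:(nb - 1), j = 2:nb,
        type = paste(btypes[1:(nb - 1)], btypes[2:nb], sep = "-"),
        stringsAsFactors = FALSE)
    if (nb >= 3)
      topo$angles <- data.frame(
        i = 1:(nb - 2), j = 2:(nb - 1), k = 3:nb,
        type = paste(btypes[1:(nb - 2)], btypes[2:(nb - 1)], btypes[3:nb],
                     sep = "-"),
        stringsAsFactors = FALSE)
    skdf <- data.frame(name = vapply(beads, `[[`, "", "name"),
                       type = btypes, stringsAsFactors = FALSE)
    list(traj = atom_traj(co, atoms),
         skeleton = bead_traj(skel, skdf),
         topology = topo)
  })
}

#' Generate a confined-film trajectory with prescribed layering and flow
#'
#' Bead z-positions are drawn from a per-species mixture of Gaussian
#' layers inside the gap, x/y uniform over the lateral box, and bead
#' x-velocities follow the linear Couette profile between `v_bottom` (at
#' z = 0) and `v_top` (at z = gap) plus Gaussian noise.
#'
#' @param layers list of species: each element
#'   `list(name, n, mass, charge = 0, centers, widths, weights = equal)`
#'   with layer centres/widths in nm.
#' @param gap Film gap (nm).
#' @param lateral Lateral box c(lx, ly) (nm).
#' @param couette list(v_bottom, v_top) in nm/ps.
#' @param noise Velocity noise standard deviation (nm/ps).
#' @param n_frames Number of frames.
#' @param seed RNG seed (mandatory).
#' @return A [bead_traj()] with velocities and species labels.
#' @export
gen_confined_film_traj <- function(layers, gap, lateral = c(5, 5),
                                   couette = list(v_bottom = 0, v_top = 0),
                                   noise = 0, n_frames = 100, seed) {
  if (missing(seed)) stop("gen_confined_film_traj: seed is mandatory")
  if (gap <= 0) stop("gen_confined_film_traj: gap must be > 0")
  if (noise < 0) stop("gen_confined_film_traj: noise sd must be >= 0")
  nms <- vapply(layers, `[[`, "", "name")
  if (anyDuplicated(nms))
    stop("gen_confined_film_traj: duplicate species declaration '",
         nms[duplicated(nms)][1], "'")
  beads <- list(); zs <- list(); spid <- 0
  for (sp in layers) {
    spid <- spid + 1
    if (!is.null(sp$centers) && any(sp$centers < 0 | sp$centers > gap))
      stop("gen_confined_film_traj: layer centre outside the gap for '",
           sp$name, "'")
    zsp <- .with_seed(.substream(seed, spid), {
      if (is.null(sp$centers)) {
        # no layering declared: uniform filling of the gap
        stats::runif(sp$n * n_frames, 0, gap)
      } else {
        wts <- if (is.null(sp$weights)) rep(1, length(sp$centers))
               else sp$weights
        wts <- wts / sum(wts)
        wid <- rep(if (is.null(sp$widths)) 0.5 else sp$widths,
                   length.out = length(sp$centers))
        comp <- sample.int(length(sp$centers), sp$n * n_frames,
                           replace = TRUE, prob = wts)
        z <- stats::rnorm(sp$n * n_frames, sp$centers[comp], wid[comp])
        # reflect into the gap
        z <- abs(z); z <- gap - abs(gap - z)
        pmin(pmax(z, 0), gap)
      }
    })
    beads[[spid]] <- data.frame(
      name = sp$name, type = sp$name,
      charge = if (is.null(sp$charge)) 0 else sp$charge,
      mass = if (is.null(sp$mass)) 72 else sp$mass,
      species = sp$name, stringsAsFactors = FALSE)[rep(1, sp$n), ]
    zs[[spid]] <- matrix(zsp, sp$n, n_frames)
  }
  bd <- do.call(rbind, beads)
  rownames(bd) <- NULL
  n <- nrow(bd)
  z <- do.call(rbind, zs)
  co <- array(0, c(n, 3, n_frames))
  ve <- array(0, c(n, 3, n_frames))
  .with_seed(.substream(seed, 1000003), {
    co[, 1, ] <- matrix(stats::runif(n * n_frames, 0, lateral[1]), n)
    co[, 2, ] <- matrix(stats::runif(n * n_frames, 0, lateral[2]), n)
    co[, 3, ] <- z
    vx <- couette$v_bottom + (couette$v_top - couette$v_bottom) * z / gap
    if (noise > 0) vx <- vx + matrix(stats::rnorm(n * n_frames, 0, noise), n)
    ve[, 1, ] <- vx
  })
  bead_traj(co, bd, box = c(lateral, gap), vel = ve)
}

#' Generate a synthetic friction dataset with known friction law
#'
#' Shear stresses follow the composition rule
#' tau(sigma, v_s) = (mu sigma + tau0) (v_s / v_ref)^alpha, multiplied by
#' lognormal noise exp(N(0, noise)).
#'
#' @param mu Friction coefficient.
#' @param tau0 Derjaguin offset (MPa).
#' @param alpha Velocity power-law exponent.
#' @param grid data.frame with columns `sigma` (MPa) and `v_s` (m/s).
#' @param v_ref Reference velocity (m/s) at which the prefactor equals
#'   mu sigma + tau0.
#' @param noise Lognormal noise scale (sd of log tau); 0 = noiseless.
#' @param seed RNG seed (mandatory).
#' @return A [friction_record()].
#' @export
gen_friction_dataset <- function(mu, tau0, alpha, grid, v_ref = 1,
                                 noise = 0, seed) {
  if (missing(seed)) stop("gen_friction_dataset: seed is mandatory")
  if (noise < 0) stop("gen_friction_dataset: noise sd must be >= 0")
  if (nrow(grid) < 1) stop("gen_friction_dataset: empty grid")
  .with_seed(seed, {
    tau <- (mu * grid$sigma + tau0) * (grid$v_s / v_ref)^alpha
    if (noise > 0) tau <- tau * exp(stats::rnorm(nrow(grid), 0, noise))
    friction_record(grid$sigma, grid$v_s, tau,
                    tau_se = noise * abs(tau))
  })
}
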