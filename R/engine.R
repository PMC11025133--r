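# R-side interface to the compiled MD core.

#' Integrator configuration
#'
#' @param dt Time step (ps).  The coarse-grained default is 0.005 ps (5 fs).
#' @param thermostat `"none"`, `"langevin"` or `"nose-hoover"`.
#' @param T_target Target temperature (K).
#' @param damping Thermostat damping time (ps).
#' @param axes Thermostatted axes, a subset of `"xyz"` as a string
#'   (e.g. `"y"` for the sliding protocol).
#' @param group Bead group tags the thermostat acts on (`NULL` = all mobile
#'   beads).
#' @param seed RNG seed for the Langevin noise.
#' @return An object of class `integrator_config`.
#' @export
integrator_config <- function(dt = 0.005, thermostat = c("none", "langevin",
                                                         "nose-hoover"),
                              T_target = 300, damping = 1, axes = "xyz",
                              group = NULL, seed = 1) {
  thermostat <- match.arg(thermostat)
  if (dt <= 0) stop("integrator_config: dt must be > 0")
  if (thermostat != "none" && damping <= 0)
    stop("integrator_config: damping must be > 0 when a thermostat is active")
  ax <- strsplit(axes, "")[[1]]
  if (!all(ax %in% c("x", "y", "z")))
    stop("integrator_config: axes must be a subset of \"xyz\"")
  structure(list(dt = dt, thermostat = thermostat, T_target = T_target,
                 damping = damping, axes = c("x", "y", "z") %in% ax,
                 group = group, seed = seed), class = "integrator_config")
}

#' Normal-load and sliding configuration
#'
#' @param sigma Normal stress applied to the upper anchor sheet (MPa),
#'   >= 0.  The total downward force is `sigma * A_lateral`.
#' @param v_s Sliding velocity of the upper anchor along x (m/s), >= 0.
#' @return An object of class `load_slide_config`.
#' @export
load_slide_config <- function(sigma = 0, v_s = 0) {
  if (sigma < 0 || v_s < 0)
    stop("load_slide_config: sigma and v_s must be >= 0")
  structure(list(sigma = sigma, v_s = v_s), class = "load_slide_config")
}

# assemble the argument list for the C++ core from a system_state
.engine_args <- function(state, lj_table, shift, coulomb) {
  types <- sort(unique(state$type))
  tidx <- match(state$type, types) - 1L
  nt <- length(types)
  epsM <- matrix(0, nt, nt); sigM <- matrix(0.47, nt, nt)
  for (i in seq_len(nt)) for (j in i:nt) {
    pr <- lj_lookup(lj_table, types[i], types[j])
    epsM[i, j] <- epsM[j, i] <- pr$epsilon
    sigM[i, j] <- sigM[j, i] <- pr$sigma
  }
  grp <- integer(n_beads(state))
  grp[state$group == "lower_anchor"] <- 1L
  grp[state$group == "upper_anchor"] <- 2L
  # exclusions: first bonded neighbours (bonds + constraints) + explicit
  ei <- c(state$bonds$i, state$constraints$i, state$exclusions$i) - 1L
  ej <- c(state$bonds$j, state$constraints$j, state$exclusions$j) - 1L
  list(types = types, tidx = tidx, nt = nt, epsM = epsM, sigM = sigM,
       grp = grp, ei = as.integer(ei), ej = as.integer(ej))
}

.run_core <- function(state, opts, lj_table, shift) {
  ea <- .engine_args(state, lj_table, shift)
  run_md_cpp(state$pos, state$vel, state$mass, state$charge,
             ea$tidx, ea$nt, ea$epsM, ea$sigM,
             as.integer(state$bonds$i - 1L), as.integer(state$bonds$j - 1L),
             state$bonds$r0, state$bonds$K,
             as.integer(state$angles$i - 1L), as.integer(state$angles$j - 1L),
             as.integer(state$angles$k - 1L),
             state$angles$theta0 * pi / 180, state$angles$K_theta,
             as.integer(state$constraints$i - 1L),
             as.integer(state$constraints$j - 1L), state$constraints$length,
             ea$ei, ea$ej, state$box, state$periodic, ea$grp,
             opts$thermo_mask, opts)
}

.default_opts <- function() {
  list(n_steps = 0L, dt = 0.005, sample_every = 100L, frame_every = 0L,
       thermostat = 0L, T_target = 300, damp = 1, axes = rep(TRUE, 3),
       seed = 1, lj_on = TRUE, lj_switch = TRUE, lj_r_on = 0.9,
       lj_r_cut = 1.2, coul_on = FALSE, coul_f = .FCOUL, coul_alpha = 0,
       coul_r_cut = 1.2, wall_on = FALSE, wall_k = 100, wall_zlo = -Inf,
       wall_zhi = Inf, skin = 0.3, shake_tol = 1e-8, load_force = 0,
       v_s = 0, single_point = FALSE)
}

#' Run coarse-grained molecular dynamics
#'
#' Velocity-Verlet integration (BAOAB splitting when the Langevin
#' thermostat is active) with SHAKE/RATTLE constraints.  Beads tagged
#' `"lower_anchor"` are frozen; beads tagged `"upper_anchor"` move as a
#' rigid sheet, driven at the sliding velocity and loaded with the normal
#' force from `load`.
#'
#' @param state A [system_state()].
#' @param n_steps Number of MD steps.
#' @param integ An [integrator_config()].
#' @param load Optional [load_slide_config()].
#' @param lj `TRUE`, `FALSE`, or `"plain"` (untruncated-style cut without
#'   switching, for textbook comparisons).
#' @param lj_table An [lj_pair_table()]; defaults to [default_lj_table()].
#' @param shift A [shift_spec()] for the LJ switching window.
#' @param coulomb `NULL` (off) or a list with `r_cut` (nm), `dielectric`
#'   (relative), `damping` (nm^-1): damped force-shifted point-charge
#'   electrostatics.
#' @param wall `NULL` or list(`zlo`, `zhi`, `k`): one-sided harmonic
#'   repulsive boundaries for non-periodic z.
#' @param sample_every Scalar-log sampling interval (steps).
#' @param frame_every Frame storage interval (steps; 0 = none).
#' @param shake_tol SHAKE convergence tolerance (nm).
#' @return An object of class `md_log`: `scalars` (data.frame with step,
#'   time, KE, PE, instantaneous T, anchor gap and anchor forces), optional
#'   `frames`/`vel_frames` arrays, and `state` (the final
#'   [system_state()]).
#' @export
run_md <- function(state, n_steps, integ = integrator_config(),
                   load = NULL, lj = TRUE, lj_table = default_lj_table(),
                   shift = shift_spec(), coulomb = NULL, wall = NULL,
                   sample_every = 100, frame_every = 0,
                   shake_tol = 1e-8) {
  stopifnot(inherits(state, "system_state"),
            inherits(integ, "integrator_config"))
  opts <- .default_opts()
  opts$n_steps <- as.integer(n_steps)
  opts$dt <- integ$dt
  opts$sample_every <- as.integer(max(1, sample_every))
  opts$frame_every <- as.integer(frame_every)
  opts$thermostat <- match(integ$thermostat,
                           c("none", "langevin", "nose-hoover")) - 1L
  opts$T_target <- integ$T_target
  opts$damp <- integ$damping
  opts$axes <- integ$axes
  opts$seed <- integ$seed
  opts$lj_on <- !identical(lj, FALSE)
  opts$lj_switch <- !identical(lj, "plain")
  opts$lj_r_on <- shift$r_on
  opts$lj_r_cut <- shift$r_cut
  if (!is.null(coulomb)) {
    opts$coul_on <- TRUE
    opts$coul_r_cut <- coulomb$r_cut
    diel <- if (is.null(coulomb$dielectric)) 1 else coulomb$dielectric
    opts$coul_f <- .FCOUL / diel
    opts$coul_alpha <- if (is.null(coulomb$damping)) 0 else coulomb$damping
  }
  if (!is.null(wall)) {
    opts$wall_on <- TRUE
    opts$wall_k <- if (is.null(wall$k)) 100 else wall$k
    opts$wall_zlo <- if (is.null(wall$zlo)) -Inf else wall$zlo
    opts$wall_zhi <- if (is.null(wall$zhi)) Inf else wall$zhi
  }
  if (!is.null(load)) {
    stopifnot(inherits(load, "load_slide_config"))
    if (!any(state$group == "upper_anchor"))
      stop("run_md: load/slide configured but no beads tagged 'upper_anchor'")
    if (!any(state$group == "lower_anchor"))
      stop("run_md: load/slide configured but no beads tagged 'lower_anchor'")
    A <- state$box[1] * state$box[2]
    opts$load_force <- load$sigma * .MPA * A
    opts$v_s <- load$v_s * 1e-3
  }
  mob <- !(state$group %in% c("lower_anchor", "upper_anchor"))
  tm <- if (is.null(integ$group)) mob else mob & state$group %in% integ$group
  if (integ$thermostat != "none" && !any(tm))
    stop("run_md: thermostat group is empty")
  opts$thermo_mask <- tm
  opts$shake_tol <- shake_tol
  res <- .run_core(state, opts, lj_table, shift)
  final <- state
  final$pos <- res$pos
  final$vel <- res$vel
  sc <- as.data.frame(res$scalars)
  structure(list(scalars = sc, frames = res$frames,
                 vel_frames = res$vel_frames, frame_time = res$frame_time,
                 state = final, dt = integ$dt), class = "md_log")
}

#' @export
print.md_log <- function(x, ...) {
  cat("md_log:", nrow(x$scalars), "samples",
      if (!is.null(x$frames)) paste0(", ", dim(x$frames)[3], " frames"),
      "\n")
  invisible(x)
}

#' Single-point potential energy and forces
#'
#' Evaluates the current potential energy and per-bead forces of a system
#' without integrating.
#'
#' @inheritParams run_md
#' @param coulomb As in [run_md()].
#' @return list(pe, forces).
#' @export
compute_forces <- function(state, lj = TRUE, lj_table = default_lj_table(),
                           shift = shift_spec(), coulomb = NULL) {
  opts <- .default_opts()
  opts$single_point <- TRUE
  opts$n_steps <- 0L
  opts$lj_on <- !identical(lj, FALSE)
  opts$lj_switch <- !identical(lj, "plain")
  opts$lj_r_on <- shift$r_on
  opts$lj_r_cut <- shift$r_cut
  if (!is.null(coulomb)) {
    opts$coul_on <- TRUE
    opts$coul_r_cut <- coulomb$r_cut
    diel <- if (is.null(coulomb$dielectric)) 1 else coulomb$dielectric
    opts$coul_f <- .FCOUL / diel
    opts$coul_alpha <- if (is.null(coulomb$damping)) 0 else coulomb$damping
  }
  opts$thermo_mask <- rep(TRUE, n_beads(state))
  .run_core(state, opts, lj_table, shift)
}

#' Damped, force-shifted Coulomb energy of a system
#'
#' Pairwise point-charge electrostatics with optional erfc damping, force
#' shifted so that energy and force are continuous and vanish at the
#' cutoff.  This finite-cutoff scheme replaces mesh electrostatics at desk
#' scale.
#'
#' @param state A [system_state()].
#' @param r_cut Cutoff (nm); must not exceed half the smallest periodic
#'   box edge.
#' @param dielectric Relative dielectric constant.
#' @param damping erfc damping parameter alpha (nm^-1); 0 disables damping.
#' @return list(energy in kJ/mol, forces n x 3 in kJ mol^-1 nm^-1).
#' @export
coulomb_energy <- function(state, r_cut, dielectric = 1, damping = 0) {
  res <- compute_forces(state, lj = FALSE,
                        coulomb = list(r_cut = r_cut, dielectric = dielectric,
                                       damping = damping))
  list(energy = res$pe, forces = res$forces)
}

#' Run a confined, loaded, sliding simulation
#'
#' Convenience wrapper for the squeeze-out/NEMD stage: the lower anchor is
#' frozen, the upper anchor is rigid, driven at `load$v_s` along x and
#' loaded with `load$sigma` times the lateral area.  The returned log
#' records the anchor-sheet gap and the normal/lateral anchor forces at
#' every sample interval.
#'
#' @param state A [system_state()] with both anchor groups.
#' @param integ An [integrator_config()].
#' @param load A [load_slide_config()].
#' @param n_steps Number of steps.
#' @param ... Passed to [run_md()].
#' @return An `md_log`.
#' @export
run_confined <- function(state, integ, load, n_steps, ...) {
  if (!any(state$group == "upper_anchor") ||
      !any(state$group == "lower_anchor"))
    stop("run_confined: state must carry lower_anchor and upper_anchor groups")
  run_md(state, n_steps, integ = integ, load = load, ...)
}

#' Radius-of-gyration series for one molecule
#'
#' Mass-weighted radius of gyration per stored frame, with the molecule
#' unwrapped across periodic boundaries by walking its bond graph
#' (minimum-image shift of each bead relative to its bonded predecessor).
#'
#' @param traj An `md_log` or [bead_traj()].
#' @param molecule Molecule id.
#' @param state Optional [system_state()] providing bonds/masses when
#'   `traj` is a bare `bead_traj`.
#' @return Numeric vector of Rg values (nm), one per frame.
#' @export
sample_rg <- function(traj, molecule, state = NULL) {
  if (inherits(traj, "md_log") && is.null(state)) state <- traj$state
  bt <- as_bead_traj(traj)
  if (is.null(state)) stop("sample_rg: need a system_state for the topology")
  sel <- which(state$molid == molecule)
  if (!length(sel)) stop("sample_rg: molecule ", molecule, " not found")
  n <- length(sel)
  mass <- state$mass[sel]
  co <- bt$coords
  box <- state$box
  per <- state$periodic
  if (n == 1) return(rep(0, dim(co)[3]))
  # unwrap order: BFS over the molecule's bond graph
  b <- state$bonds; csr <- state$constraints
  eb <- rbind(b[b$i %in% sel & b$j %in% sel, c("i", "j")],
              csr[csr$i %in% sel & csr$j %in% sel, c("i", "j")])
  loc <- function(gidx) match(gidx, sel)
  adj <- vector("list", n)
  if (nrow(eb)) for (r in seq_len(nrow(eb))) {
    li <- loc(eb$i[r]); lj <- loc(eb$j[r])
    adj[[li]] <- c(adj[[li]], lj); adj[[lj]] <- c(adj[[lj]], li)
  }
  order_edges <- list()
  seen <- logical(n); seen[1] <- TRUE; queue <- 1L
  while (length(queue)) {
    u <- queue[1]; queue <- queue[-1]
    for (w in adj[[u]]) if (!seen[w]) {
      seen[w] <- TRUE
      order_edges[[length(order_edges) + 1]] <- c(u, w)
      queue <- c(queue, w)
    }
  }
  if (!all(seen))
    stop("sample_rg: molecule ", molecule, " has a disconnected bond graph")
  nf <- dim(co)[3]
  un <- co[sel, , , drop = FALSE]
  for (e in order_edges) {
    u <- e[1]; w <- e[2]
    for (ax in 1:3) {
      if (!per[ax]) next
      d <- un[w, ax, ] - un[u, ax, ]
      un[w, ax, ] <- un[u, ax, ] + .minimg(d, box[ax])
    }
  }
  M <- sum(mass)
  rg <- numeric(nf)
  for (ax in 1:3) {
    xa <- matrix(un[, ax, ], n, nf)
    cm <- colSums(xa * mass) / M
    rg <- rg + colSums(mass * sweep(xa, 2, cm)^2) / M
  }
  sqrt(rg)
}
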