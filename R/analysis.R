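# Measurement layer: through-film profiles, film thickness, hydration,
# coverages and charge ratios, shear stress, friction-law fits, Rg-Mw
# scaling and interdigitation overlap.

#' Through-film profile of a binned quantity
#'
#' Time-averaged binned profile along a box axis.  Supported quantities:
#' `"mass"` (amu nm^-3, or g cm^-3 with `units = "g/cm3"`), `"charge"`
#' (e nm^-3), `"number"` (nm^-3) and `"velocity"` (mean v_x in nm/ps; bins
#' with zero occupancy are `NA`, not zero).
#'
#' @param traj A [bead_traj()] or `md_log`.
#' @param selection Logical or integer bead selection (default: all beads).
#' @param quantity One of `"mass"`, `"charge"`, `"number"`, `"velocity"`.
#' @param bins Either a bin width (nm, scalar) or a vector of bin edges.
#'   Default 0.1 nm bins spanning the box.
#' @param axis Profile axis, 1-3 (default 3 = z, the surface normal).
#' @param units For mass profiles, `"amu/nm3"` (default) or `"g/cm3"`.
#' @return An object of class `profile`: data.frame with `z` (bin centre),
#'   `value`, plus attributes `edges`, `quantity`, `frames`, `area`.
#' @export
traj_profile <- function(traj, selection = NULL,
                         quantity = c("mass", "charge", "number", "velocity"),
                         bins = 0.1, axis = 3, units = "amu/nm3") {
  quantity <- match.arg(quantity)
  bt <- as_bead_traj(traj)
  n <- dim(bt$coords)[1]
  sel <- if (is.null(selection)) seq_len(n)
         else if (is.logical(selection)) which(selection) else selection
  if (!length(sel)) stop("traj_profile: empty selection")
  nf <- dim(bt$coords)[3]
  if (length(bins) == 1) {
    if (bins <= 0) stop("traj_profile: bin width must be > 0")
    zmax <- if (!is.null(bt$box)) bt$box[axis] else max(bt$coords[, axis, ])
    edges <- seq(0, zmax + bins * 1e-9, by = bins)
    if (edges[length(edges)] < zmax) edges <- c(edges, zmax)
  } else edges <- bins
  nb <- length(edges) - 1
  z <- matrix(bt$coords[sel, axis, ], length(sel), nf)
  bin <- findInterval(as.vector(z), edges, rightmost.closed = TRUE)
  bin[bin < 1 | bin > nb] <- NA
  lat <- setdiff(1:3, axis)
  area <- if (!is.null(bt$box)) prod(bt$box[lat]) else 1
  binvol <- diff(edges) * area
  w <- switch(quantity,
              mass = bt$beads$mass[sel],
              charge = bt$beads$charge[sel],
              number = rep(1, length(sel)),
              velocity = NULL)
  if (quantity == "velocity") {
    if (is.null(bt$vel)) stop("traj_profile: trajectory has no velocities")
    vx <- as.vector(matrix(bt$vel[sel, 1, ], length(sel), nf))
    ok <- !is.na(bin)
    cnt <- tabulate(bin[ok], nbins = nb)
    sums <- unname(tapply(vx[ok], factor(bin[ok], levels = seq_len(nb)), sum))
    sums[is.na(sums)] <- 0
    val <- ifelse(cnt > 0, sums / cnt, NA_real_)
  } else {
    W <- rep(w, times = nf)
    ok <- !is.na(bin)
    sums <- unname(tapply(W[ok], factor(bin[ok], levels = seq_len(nb)), sum))
    sums[is.na(sums)] <- 0
    val <- sums / nf / binvol
    if (quantity == "mass" && units == "g/cm3") val <- val * .GCM3
  }
  out <- data.frame(z = (edges[-1] + edges[-length(edges)]) / 2, value = val)
  structure(out, class = c("profile", "data.frame"), edges = edges,
            quantity = quantity, frames = nf, area = area, units = units)
}

#' Film thickness from a density profile
#'
#' The distance along the profile axis containing the central mass between
#' the `lo` and `hi` quantiles of the cumulative distribution (defaults:
#' 1% and 99%, i.e. the span containing 98% of the mass), with linear
#' interpolation inside bins.
#'
#' @param profile A `profile` (from [traj_profile()]) or any data.frame
#'   with columns `z`, `value` and an `edges` attribute.
#' @param lo,hi Cumulative quantiles bounding the film.
#' @return Thickness (nm).
#' @export
film_thickness <- function(profile, lo = 0.01, hi = 0.99) {
  if (lo < 0 || hi > 1 || lo >= hi)
    stop("film_thickness: need 0 <= lo < hi <= 1")
  val <- profile$value
  if (any(val < 0)) stop("film_thickness: density profile must be >= 0")
  edges <- attr(profile, "edges")
  if (is.null(edges)) {
    dz <- diff(profile$z)
    edges <- c(profile$z - c(dz[1], dz) / 2,
               profile$z[length(profile$z)] + dz[length(dz)] / 2)
  }
  w <- diff(edges)
  tot <- sum(val * w)
  if (tot <= 0) stop("film_thickness: zero total mass; thickness undefined")
  cum <- c(0, cumsum(val * w)) / tot
  qat <- function(q) {
    i <- findInterval(q, cum, rightmost.closed = TRUE)
    i <- min(max(i, 1), length(w))
    dc <- cum[i + 1] - cum[i]
    frac <- if (dc > 0) (q - cum[i]) / dc else 0
    edges[i] + frac * w[i]
  }
  qat(hi) - qat(lo)
}

#' Water mass fraction inside a film
#'
#' Film extent is defined by the quantile span of the film species' own
#' mass profile (see [film_thickness()]); the hydration fraction is the
#' water mass inside that z-extent divided by the total mass in the same
#' extent, time-averaged.
#'
#' @param traj A [bead_traj()] or `md_log`.
#' @param film_selection Beads defining the film (logical or indices).
#' @param water_selection Beads counted as water.
#' @param lo,hi Quantiles bounding the film extent.
#' @param bins Bin width passed to [traj_profile()].
#' @return Mass fraction of water in [0, 1].
#' @export
hydration_fraction <- function(traj, film_selection, water_selection,
                               lo = 0.01, hi = 0.99, bins = 0.1) {
  bt <- as_bead_traj(traj)
  pf <- traj_profile(bt, film_selection, "mass", bins = bins)
  edges <- attr(pf, "edges")
  w <- diff(edges)
  tot <- sum(pf$value * w)
  if (tot <= 0) stop("hydration_fraction: empty film")
  cum <- c(0, cumsum(pf$value * w)) / tot
  qat <- function(q) {
    i <- findInterval(q, cum, rightmost.closed = TRUE)
    i <- min(max(i, 1), length(w))
    dc <- cum[i + 1] - cum[i]
    edges[i] + (if (dc > 0) (q - cum[i]) / dc else 0) * w[i]
  }
  zlo <- qat(lo); zhi <- qat(hi)
  n <- dim(bt$coords)[1]; nf <- dim(bt$coords)[3]
  selw <- if (is.logical(water_selection)) which(water_selection)
          else water_selection
  zall <- matrix(bt$coords[, 3, ], n, nf)
  inside <- zall >= zlo & zall <= zhi
  mass <- bt$beads$mass
  wmask <- seq_len(n) %in% selw
  m_wat <- sum(inside[wmask, , drop = FALSE] * mass[wmask])
  m_tot <- sum(inside * mass)
  if (m_tot == 0) stop("hydration_fraction: no mass inside the film extent")
  m_wat / m_tot
}

#' Contact coverages and charge ratios
#'
#' Areal densities of species inside the contact and the two charge ratios
#' used to characterize polyelectrolyte-surfactant films:
#' `R_SDS` = (surfactant anionic charges)/(polymer cationic charges) and
#' `|R_surf|` = (surface anionic charges)/(polymer cationic charges).
#'
#' @param x Either a [system_state()] (species counted by molecule name)
#'   or a named list of counts (e.g. `list(water = 8000, sds = 560,
#'   cgg = 8)`).
#' @param lateral_area Lateral area (nm^2).
#' @param cations_per_chain Cationic beads per polymer chain (DS x repeat
#'   units).
#' @param species Mapping of roles to molecule names used when `x` is a
#'   `system_state`; defaults to
#'   `list(water = "PW", sds = "SDS", cgg = "CGG")`.
#' @param surface_anions Number of anionic surface charges (counted from
#'   bead charges of anchored/grafted groups when `x` is a system).
#' @return An object of class `coverage_report`: list with `rho_w`,
#'   `rho_sds`, `rho_cgg` (nm^-2), `R_sds`, `R_surf`, `area`.
#' @export
coverages <- function(x, lateral_area = NULL, cations_per_chain = 50,
                      species = list(water = "PW", sds = "SDS",
                                     cgg = "CGG"),
                      surface_anions = NULL) {
  if (inherits(x, "system_state")) {
    if (is.null(lateral_area)) lateral_area <- x$box[1] * x$box[2]
    cnt <- function(nm) {
      sel <- x$molname == nm
      if (!any(sel)) return(0)
      length(unique(x$molid[sel]))
    }
    counts <- list(water = cnt(species$water), sds = cnt(species$sds),
                   cgg = cnt(species$cgg))
    # water coverage counts coarse-grained water beads (not molecules)
    counts$water <- sum(x$molname == species$water)
    if (is.null(surface_anions)) {
      surf <- x$group %in% c("lower_anchor", "upper_anchor", "graft_base") |
        x$molname %in% c("GRAFT", "ANCHOR")
      surface_anions <- abs(sum(pmin(x$charge[surf], 0)))
    }
  } else {
    counts <- x
    if (is.null(lateral_area)) stop("coverages: lateral_area required")
    if (is.null(surface_anions)) surface_anions <- 0
  }
  if (lateral_area <= 0) stop("coverages: lateral_area must be > 0")
  g <- function(nm) if (is.null(counts[[nm]])) 0 else counts[[nm]]
  rho_w <- g("water") / lateral_area
  rho_sds <- g("sds") / lateral_area
  rho_cgg <- g("cgg") / lateral_area
  q_cat <- rho_cgg * lateral_area * cations_per_chain
  if (g("sds") > 0 || surface_anions > 0) {
    if (q_cat == 0)
      stop("coverages: zero polymer cationic charge; ratios undefined")
  }
  structure(list(rho_w = rho_w, rho_sds = rho_sds, rho_cgg = rho_cgg,
                 R_sds = if (q_cat > 0) rho_sds * lateral_area / q_cat else 0,
                 R_surf = if (q_cat > 0) abs(surface_anions) / q_cat else 0,
                 area = lateral_area), class = "coverage_report")
}

#' Charge ratio from printed areal coverages
#'
#' Convenience arithmetic for contact-composition tables: the ratio of
#' surfactant anionic charges (one per molecule) to polymer cationic
#' charges per unit area.
#'
#' @param rho_sds Surfactant coverage (nm^-2).
#' @param rho_cgg Polymer chain coverage (nm^-2).
#' @param cations_per_chain Cationic groups per chain.
#' @return Dimensionless charge ratio.
#' @export
charge_ratio_sds <- function(rho_sds, rho_cgg, cations_per_chain = 50) {
  if (rho_cgg * cations_per_chain <= 0)
    stop("charge_ratio_sds: zero polymer cationic charge; ratio undefined")
  rho_sds / (rho_cgg * cations_per_chain)
}

#' @export
print.coverage_report <- function(x, ...) {
  cat(sprintf(
    "coverage_report (A = %.4g nm^2):\n  rho_w   %.4g nm^-2\n  rho_SDS %.4g nm^-2\n  rho_CGG %.4g nm^-2\n  R_SDS   %.4g\n  |R_surf| %.4g\n",
    x$area, x$rho_w, x$rho_sds, x$rho_cgg, x$R_sds, x$R_surf))
  invisible(x)
}

#' Shear stress from an anchor-force log
#'
#' Time average of the lateral force transmitted to the driven anchor over
#' the steady-state window, divided by the lateral area; the standard
#' error is estimated by block averaging over 5 equal blocks.
#'
#' @param log An `md_log` (or a data.frame with column `fx_upper` in
#'   kJ mol^-1 nm^-1).
#' @param lateral_area Lateral area (nm^2); taken from the log's state if
#'   available.
#' @param window Fraction of the record treated as steady state, e.g.
#'   `c(0.5, 1)` discards the first half.
#' @param nblocks Number of blocks for the SE (>= 5 samples per block
#'   required).
#' @return list(tau = shear stress in MPa, se = standard error in MPa).
#' @export
shear_stress <- function(log, lateral_area = NULL, window = c(0.5, 1),
                         nblocks = 5) {
  sc <- if (inherits(log, "md_log")) log$scalars else log
  if (is.null(lateral_area)) {
    if (inherits(log, "md_log"))
      lateral_area <- log$state$box[1] * log$state$box[2]
    else stop("shear_stress: lateral_area required")
  }
  fx <- sc$fx_upper
  n <- length(fx)
  i0 <- max(1, floor(window[1] * n) + 1)
  i1 <- min(n, ceiling(window[2] * n))
  fx <- fx[i0:i1]
  if (length(fx) < nblocks)
    stop("shear_stress: steady-state window shorter than ", nblocks,
         " blocks")
  # stress opposing the drive: reported positive, in MPa
  tau <- -mean(fx) / lateral_area / .MPA
  bl <- split(fx, cut(seq_along(fx), nblocks, labels = FALSE))
  bm <- vapply(bl, mean, 0) / lateral_area / .MPA
  se <- stats::sd(-bm) / sqrt(nblocks)
  list(tau = tau, se = se)
}

#' Friction dataset container
#'
#' @param sigma Normal stresses (MPa).
#' @param v_s Sliding velocities (m/s).
#' @param tau Shear stresses (MPa).
#' @param tau_se Standard errors of tau (MPa), >= 0.
#' @return An object of class `friction_record` (a data.frame).
#' @export
friction_record <- function(sigma, v_s, tau, tau_se = 0) {
  d <- data.frame(sigma = sigma, v_s = v_s, tau = tau, tau_se = tau_se)
  if (any(d$tau_se < 0)) stop("friction_record: tau_se must be >= 0")
  structure(d, class = c("friction_record", "data.frame"))
}

#' Power-law fit of shear stress versus sliding velocity
#'
#' Least-squares line in (ln v_s, ln tau); the slope is the power-law
#' exponent alpha of tau ~ v_s^alpha.
#'
#' @param records A [friction_record()].
#' @param v_min Only points with `v_s >= v_min` enter the fit (the
#'   power-law regime excludes the slowest points when they deviate).
#' @return list(alpha, prefactor, n, v_min).
#' @export
fit_powerlaw <- function(records, v_min = 0) {
  d <- records[records$v_s >= v_min, ]
  if (nrow(d) < 3) stop("fit_powerlaw: need >= 3 points with v_s >= v_min")
  if (any(d$tau <= 0))
    stop("fit_powerlaw: non-positive shear stress in the fit window")
  fit <- stats::lm(log(tau) ~ log(v_s), data = d)
  co <- stats::coef(fit)
  list(alpha = unname(co[2]), prefactor = exp(unname(co[1])), n = nrow(d),
       v_min = v_min)
}

#' Extended Amontons (Amontons-Coulomb) fit
#'
#' Ordinary least squares of tau on sigma: tau = mu sigma + tau0, where mu
#' is the friction coefficient and tau0 the Derjaguin offset
#' (unconstrained in sign).
#'
#' @param records A [friction_record()].
#' @return list(mu, tau0, mu_se, tau0_se, n).
#' @export
fit_amontons <- function(records) {
  if (length(unique(records$sigma)) < 2)
    stop("fit_amontons: need >= 2 distinct normal stresses")
  fit <- stats::lm(tau ~ sigma, data = records)
  co <- stats::coef(fit)
  # vcov warns on exactly collinear input; SEs are then reported as 0/NaN
  se <- tryCatch(suppressWarnings(sqrt(diag(stats::vcov(fit)))),
                 error = function(e) c(NA, NA))
  list(mu = unname(co[2]), tau0 = unname(co[1]), mu_se = unname(se[2]),
       tau0_se = unname(se[1]), n = nrow(records))
}

#' Radius-of-gyration scaling exponent
#'
#' Slope of ln <Rg> versus ln M_w.  Duplicate molecular weights are
#' averaged before fitting.
#'
#' @param rg_by_mw data.frame with columns `Mw` and `Rg` (>= 3 distinct
#'   molecular weights).
#' @return list(exponent, prefactor, n).
#' @export
rg_scaling <- function(rg_by_mw) {
  d <- rg_by_mw
  if (any(d$Mw <= 0) || any(d$Rg <= 0))
    stop("rg_scaling: Mw and Rg must be > 0")
  agg <- stats::aggregate(Rg ~ Mw, data = d, FUN = mean)
  if (nrow(agg) < 3) stop("rg_scaling: need >= 3 distinct molecular weights")
  fit <- stats::lm(log(Rg) ~ log(Mw), data = agg)
  co <- stats::coef(fit)
  list(exponent = unname(co[2]), prefactor = exp(unname(co[1])),
       n = nrow(agg))
}

#' Interdigitation overlap of two opposing density profiles
#'
#' The integral of the pointwise minimum of the two profiles along the
#' surface normal: zero iff the supports are disjoint, and growing as the
#' layers interpenetrate.
#'
#' @param profile_lower,profile_upper `profile` objects on a common bin
#'   grid.
#' @return Overlap integral (units of profile x nm, e.g. amu nm^-2 for
#'   mass profiles).
#' @export
interdigitation_overlap <- function(profile_lower, profile_upper) {
  e1 <- attr(profile_lower, "edges"); e2 <- attr(profile_upper, "edges")
  if (length(e1) != length(e2) || any(abs(e1 - e2) > 1e-9))
    stop("interdigitation_overlap: profiles are on different bin grids")
  v1 <- profile_lower$value; v2 <- profile_upper$value
  v1[is.na(v1)] <- 0; v2[is.na(v2)] <- 0
  sum(pmin(v1, v2) * diff(e1))
}
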