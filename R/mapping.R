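# Mapping of atomistic trajectories onto coarse-grained beads and
# Boltzmann-inversion fitting of harmonic bonded parameters
# (Gaussian moment matching).

#' Mapping scheme: atoms-per-bead assignments
#'
#' Defines, per residue name, the list of beads and the ordered member atom
#' names of each bead.  Hydrogens are conventionally folded into their heavy
#' atom's bead; an approximately 4:1 heavy-atom-to-bead ratio is advisory,
#' not enforced.  Every atom of a residue must appear in exactly one bead.
#'
#' @param residues Named list; each element (named by residue name) is a
#'   list of beads, each bead a list with `name`, `type`, optional `charge`,
#'   and `atoms` (character vector of member atom names).
#' @return An object of class `mapping_scheme`.
#' @export
mapping_scheme <- function(residues) {
  stopifnot(is.list(residues), length(names(residues)) == length(residues))
  for (rn in names(residues)) {
    beads <- residues[[rn]]
    allat <- unlist(lapply(beads, `[[`, "atoms"))
    if (anyDuplicated(allat))
      stop("mapping_scheme: atom '", allat[duplicated(allat)][1],
           "' assigned to more than one bead in residue ", rn)
    for (b in beads)
      if (is.null(b$name) || is.null(b$type) || length(b$atoms) < 1)
        stop("mapping_scheme: each bead needs name, type and atoms (residue ",
             rn, ")")
  }
  structure(list(residues = residues), class = "mapping_scheme")
}

#' Read a mapping scheme from a YAML config
#'
#' Expected layout:
#' \preformatted{
#' residues:
#'   GUA:
#'     - {name: B1, type: P4, charge: 0, atoms: [C1, C2, O2]}
#'     - {name: B2, type: P1, atoms: [C3, C4, O4]}
#' }
#'
#' @param file Path to a YAML file.
#' @return A [mapping_scheme()].
#' @export
read_mapping_scheme <- function(file) {
  cfg <- yaml::read_yaml(file)
  if (is.null(cfg$residues)) stop("read_mapping_scheme: missing 'residues'")
  mapping_scheme(cfg$residues)
}

#' Map an atomistic trajectory onto coarse-grained beads
#'
#' Each bead position is the mass-weighted (or geometric) center of its
#' member atoms.  Member positions are unwrapped by the minimum-image
#' convention relative to the bead's first member atom before averaging, so
#' groups split across a periodic boundary map correctly.
#'
#' @param traj An [atom_traj()].
#' @param scheme A [mapping_scheme()].
#' @param com_mode `"mass"` (default) or `"geometric"`.
#' @return A [bead_traj()] with one frame per source frame.
#' @export
map_trajectory <- function(traj, scheme, com_mode = c("mass", "geometric")) {
  stopifnot(inherits(traj, "atom_traj"), inherits(scheme, "mapping_scheme"))
  com_mode <- match.arg(com_mode)
  atoms <- traj$atoms
  resids <- unique(atoms$resid)
  members <- list(); meta <- list()
  for (rid in resids) {
    sel <- which(atoms$resid == rid)
    rn <- atoms$resname[sel[1]]
    beads <- scheme$residues[[rn]]
    if (is.null(beads))
      stop("map_trajectory: residue name '", rn, "' not in mapping scheme")
    for (b in beads) {
      idx <- sel[match(b$atoms, atoms$name[sel])]
      if (anyNA(idx))
        stop("map_trajectory: atom '", b$atoms[which(is.na(match(b$atoms,
             atoms$name[sel])))[1]], "' missing in residue ", rid,
             " (bead ", b$name, ")")
      members[[length(members) + 1]] <- idx
      meta[[length(meta) + 1]] <- data.frame(
        name = b$name, type = b$type,
        charge = if (is.null(b$charge)) 0 else b$charge,
        mass = sum(atoms$mass[idx]), resid = rid, resname = rn,
        stringsAsFactors = FALSE)
    }
  }
  beads_df <- do.call(rbind, meta)
  nb <- length(members)
  co <- traj$coords
  nf <- dim(co)[3]
  out <- array(0, c(nb, 3, nf))
  box <- traj$box
  for (bi in seq_len(nb)) {
    idx <- members[[bi]]
    w <- if (com_mode == "mass") atoms$mass[idx] else rep(1, length(idx))
    w <- w / sum(w)
    ref <- co[idx[1], , , drop = FALSE]   # 1 x 3 x nf
    acc <- array(0, c(1, 3, nf))
    for (k in seq_along(idx)) {
      d <- co[idx[k], , , drop = FALSE] - ref
      if (!is.null(box)) for (ax in 1:3) d[1, ax, ] <- .minimg(d[1, ax, ], box[ax])
      acc <- acc + w[k] * d
    }
    out[bi, , ] <- (ref + acc)[1, , ]
  }
  bead_traj(out, beads_df, box = box, time = traj$time)
}

#' Collect bond and angle samples from a bead trajectory
#'
#' Pools one sample per frame per bond/angle instance by type label.
#' Angles with a zero-length arm in some frame are skipped in that frame
#' with a warning.
#'
#' @param traj A [bead_traj()].
#' @param topology list with data.frames `bonds` (columns `i`, `j`, `type`)
#'   and/or `angles` (columns `i`, `j`, `k`, `type`); `j` is the angle apex.
#'   Indices are 1-based bead indices into the trajectory.
#' @param temperature Temperature (K) recorded with the distribution set.
#' @return An object of class `distribution_set`: lists `bonds` and
#'   `angles` of per-type sample vectors (bond lengths in nm, angles in
#'   radians), plus `temperature`.
#' @export
collect_distributions <- function(traj, topology, temperature = 300) {
  stopifnot(inherits(traj, "bead_traj"))
  co <- traj$coords
  nb <- dim(co)[1]
  box <- traj$box
  dist_vec <- function(i, j) {
    d <- co[i, , ] - co[j, , ]
    if (is.null(dim(d))) d <- matrix(d, nrow = 3)
    if (!is.null(box)) for (ax in 1:3) d[ax, ] <- .minimg(d[ax, ], box[ax])
    d
  }
  bonds <- list(); angles <- list()
  if (!is.null(topology$bonds) && nrow(topology$bonds) > 0) {
    tb <- topology$bonds
    if (any(tb$i > nb | tb$j > nb | tb$i < 1 | tb$j < 1))
      stop("collect_distributions: bond references a non-existent bead")
    for (r in seq_len(nrow(tb))) {
      d <- dist_vec(tb$i[r], tb$j[r])
      len <- sqrt(colSums(d^2))
      ty <- tb$type[r]
      bonds[[ty]] <- c(bonds[[ty]], len)
    }
  }
  nskip <- 0
  if (!is.null(topology$angles) && nrow(topology$angles) > 0) {
    ta <- topology$angles
    if (any(pmax(ta$i, ta$j, ta$k) > nb | pmin(ta$i, ta$j, ta$k) < 1))
      stop("collect_distributions: angle references a non-existent bead")
    for (r in seq_len(nrow(ta))) {
      a <- dist_vec(ta$i[r], ta$j[r])
      b <- dist_vec(ta$k[r], ta$j[r])
      na <- sqrt(colSums(a^2)); nbv <- sqrt(colSums(b^2))
      ok <- na > 1e-12 & nbv > 1e-12
      nskip <- nskip + sum(!ok)
      ct <- colSums(a * b)[ok] / (na[ok] * nbv[ok])
      th <- acos(pmin(1, pmax(-1, ct)))
      ty <- ta$type[r]
      angles[[ty]] <- c(angles[[ty]], th)
    }
  }
  if (nskip > 0)
    warning("collect_distributions: skipped ", nskip,
            " angle samples with zero-length bond vectors")
  structure(list(bonds = bonds, angles = angles, temperature = temperature),
            class = "distribution_set")
}

#' @export
print.distribution_set <- function(x, ...) {
  cat("distribution_set: ", length(x$bonds), " bond types, ",
      length(x$angles), " angle types (T = ", x$temperature, " K)\n", sep = "")
  invisible(x)
}

.pop_var <- function(x, w = NULL) {
  if (is.null(w)) {
    m <- mean(x); mean((x - m)^2)
  } else {
    w <- w / sum(w); m <- sum(w * x); sum(w * (x - m)^2)
  }
}

#' Fit a harmonic bond by Gaussian moment matching
#'
#' The Boltzmann distribution of a harmonic bond E = K (r - r0)^2 at
#' temperature T is (up to the radial Jacobian) a Gaussian with mean r0 and
#' variance kB T / (2 K).  The estimator inverts the first two sample
#' moments: r0 = mean(r), K = kB T / (2 Var(r)) (population variance).
#'
#' @param samples Bond-length samples (nm); at least two distinct values.
#' @param T Temperature (K).
#' @param convention Energy convention for the returned K.
#' @return list(r0, K, convention, n).
#' @export
fit_harmonic_bond <- function(samples, T = 300,
                              convention = "half-included") {
  .check_convention(convention)
  if (T <= 0) stop("fit_harmonic_bond: T must be > 0")
  if (length(samples) < 2) stop("fit_harmonic_bond: need >= 2 samples")
  v <- .pop_var(samples)
  if (v == 0)
    stop("fit_harmonic_bond: degenerate (zero-variance) distribution; ",
         "consider a constraint instead of a bond")
  K <- .kB * T / (2 * v)
  if (convention == "explicit-half") K <- 2 * K
  list(r0 = mean(samples), K = K, convention = convention,
       n = length(samples))
}

#' Fit a harmonic angle by Gaussian moment matching
#'
#' As [fit_harmonic_bond()], for angles in radians.  With `jacobian = TRUE`
#' (the default) samples are reweighted by 1/sin(theta) before moment
#' matching, removing the spherical volume element that tilts angle
#' distributions sampled from three-dimensional configurations.  Samples at
#' exactly 0 or pi are dropped (with a warning) when the Jacobian weight is
#' applied.
#'
#' @param samples Angle samples in radians, inside [0, pi].
#' @param T Temperature (K).
#' @param jacobian Reweight by 1/sin(theta)?
#' @param convention Energy convention for the returned constant.
#' @return list(theta0 in degrees, K_theta in kJ mol^-1 rad^-2,
#'   convention, n).
#' @export
fit_harmonic_angle <- function(samples, T = 300, jacobian = TRUE,
                               convention = "half-included") {
  .check_convention(convention)
  if (T <= 0) stop("fit_harmonic_angle: T must be > 0")
  if (any(samples < -1e-12 | samples > pi + 1e-12))
    stop("fit_harmonic_angle: samples must lie in [0, pi]")
  w <- NULL
  if (jacobian) {
    s <- sin(samples)
    bad <- s <= 0
    if (any(bad)) {
      warning("fit_harmonic_angle: dropping ", sum(bad),
              " samples at exactly 0 or pi (Jacobian weight undefined)")
      samples <- samples[!bad]; s <- s[!bad]
    }
    w <- 1 / s
  }
  if (length(unique(samples)) < 2)
    stop("fit_harmonic_angle: need >= 2 distinct samples ",
         "(zero-variance distribution)")
  v <- .pop_var(samples, w)
  if (v == 0) stop("fit_harmonic_angle: degenerate (zero-variance) distribution")
  K <- .kB * T / (2 * v)
  if (convention == "explicit-half") K <- 2 * K
  m <- if (is.null(w)) mean(samples) else sum(w / sum(w) * samples)
  list(theta0 = m * 180 / pi, K_theta = K, convention = convention,
       n = length(samples))
}

#' Invert a distribution set into a bonded parameter table
#'
#' Applies [fit_harmonic_bond()] / [fit_harmonic_angle()] to every type in
#' the set.  Type labels must be hyphen-joined bead type names
#' (e.g. `"P1-P4"`, `"P1-P4-P1"`).
#'
#' @param dset A `distribution_set` from [collect_distributions()].
#' @param T Temperature (K); defaults to the set's recorded temperature.
#' @param jacobian Passed to [fit_harmonic_angle()].
#' @param convention Energy convention of the output table.
#' @return A [bonded_parameter_table()].
#' @export
boltzmann_invert <- function(dset, T = NULL, jacobian = TRUE,
                             convention = "half-included") {
  stopifnot(inherits(dset, "distribution_set"))
  if (is.null(T)) T <- dset$temperature
  bonds <- NULL
  if (length(dset$bonds) > 0) {
    bonds <- do.call(rbind, lapply(names(dset$bonds), function(ty) {
      ft <- fit_harmonic_bond(dset$bonds[[ty]], T = T,
                              convention = convention)
      parts <- strsplit(ty, "-")[[1]]
      data.frame(type_i = parts[1], type_j = parts[length(parts)],
                 r0 = ft$r0, K = ft$K, stringsAsFactors = FALSE)
    }))
  }
  angles <- NULL
  if (length(dset$angles) > 0) {
    angles <- do.call(rbind, lapply(names(dset$angles), function(ty) {
      ft <- fit_harmonic_angle(dset$angles[[ty]], T = T, jacobian = jacobian,
                               convention = convention)
      parts <- strsplit(ty, "-")[[1]]
      if (length(parts) < 3) parts <- c(parts[1], parts, parts[1])[1:3]
      data.frame(type_i = parts[1], type_j = parts[2], type_k = parts[3],
                 theta0 = ft$theta0, K_theta = ft$K_theta,
                 stringsAsFactors = FALSE)
    }))
  }
  bonded_parameter_table(bonds = bonds, angles = angles,
                         convention = convention)
}

# normalized histogram of x on given breaks -> density values per bin
.hist_density <- function(x, breaks) {
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)
  h$density
}

#' Compare two distribution sets
#'
#' For every bond/angle type present in both sets, computes the overlap
#' coefficient (the integral of the pointwise minimum of the two normalized
#' histograms on a common grid, in [0, 1]) and the difference of means.
#'
#' @param ref,test `distribution_set` objects with identical type sets.
#' @param nbins Number of histogram bins on the common grid.
#' @return data.frame with columns `kind`, `type`, `overlap`, `mean_diff`.
#' @export
compare_distributions <- function(ref, test, nbins = 100) {
  stopifnot(inherits(ref, "distribution_set"),
            inherits(test, "distribution_set"))
  for (kind in c("bonds", "angles")) {
    a <- names(ref[[kind]]); b <- names(test[[kind]])
    if (!setequal(a, b))
      stop("compare_distributions: ", kind, " type sets differ (ref: ",
           paste(setdiff(a, b), collapse = ","), "; test: ",
           paste(setdiff(b, a), collapse = ","), ")")
  }
  one <- function(kind, ty) {
    x <- ref[[kind]][[ty]]; y <- test[[kind]][[ty]]
    lo <- min(x, y); hi <- max(x, y)
    if (hi == lo) hi <- lo + 1e-9
    breaks <- seq(lo, hi, length.out = nbins + 1)
    dx <- .hist_density(x, breaks); dy <- .hist_density(y, breaks)
    bw <- diff(breaks)[1]
    data.frame(kind = sub("s$", "", kind), type = ty,
               overlap = sum(pmin(dx, dy)) * bw,
               mean_diff = mean(y) - mean(x), stringsAsFactors = FALSE)
  }
  rows <- c(lapply(names(ref$bonds), function(t) one("bonds", t)),
            lapply(names(ref$angles), function(t) one("angles", t)))
  do.call(rbind, rows)
}
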