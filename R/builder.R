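# Molecule templates and system assembly: cationic polysaccharide chains
# with a configurable degree of substitution, a 4-bead anionic surfactant,
# polarizable 3-site water, hydrated counterions, grafted model surfaces
# and bulk/confined composites.

.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

.empty_bonds <- function()
  data.frame(i = integer(), j = integer(), r0 = numeric(), K = numeric())
.empty_angles <- function()
  data.frame(i = integer(), j = integer(), k = integer(),
             theta0 = numeric(), K_theta = numeric())
.empty_cons <- function()
  data.frame(i = integer(), j = integer(), length = numeric())
.empty_excl <- function() data.frame(i = integer(), j = integer())

#' Molecule template
#'
#' A reusable molecule definition: beads with types/charges/masses, harmonic
#' bonds and angles (half-included convention, theta0 in degrees),
#' constraint bonds, optional extra nonbonded exclusions and local
#' coordinates used when inserting copies into a system.
#'
#' @param name Species name.
#' @param beads data.frame: `name`, `type`, `charge`, `mass`.
#' @param bonds data.frame: `i`, `j`, `r0` (nm), `K` (kJ mol^-1 nm^-2).
#' @param angles data.frame: `i`, `j`, `k` (apex `j`), `theta0` (deg),
#'   `K_theta` (kJ mol^-1 rad^-2).
#' @param constraints data.frame: `i`, `j`, `length` (nm).
#' @param exclusions data.frame: `i`, `j` extra intramolecular nonbonded
#'   exclusions (first bonded neighbours are always excluded).
#' @param coords Optional local coordinates (n_beads x 3, nm).
#' @return An object of class `molecule_template`.
#' @export
molecule_template <- function(name, beads, bonds = .empty_bonds(),
                              angles = .empty_angles(),
                              constraints = .empty_cons(),
                              exclusions = .empty_excl(), coords = NULL) {
  n <- nrow(beads)
  refs <- c(bonds$i, bonds$j, angles$i, angles$j, angles$k,
            constraints$i, constraints$j, exclusions$i, exclusions$j)
  if (length(refs) && (max(refs) > n || min(refs) < 1))
    stop("molecule_template: bonded term references a non-existent bead")
  if (!is.null(coords)) {
    coords <- as.matrix(coords)
    stopifnot(nrow(coords) == n, ncol(coords) == 3)
  }
  structure(list(name = name, beads = beads, bonds = bonds, angles = angles,
                 constraints = constraints, exclusions = exclusions,
                 coords = coords),
            class = "molecule_template")
}

#' Net charge of a template or system
#' @param x A `molecule_template` or `system_state`.
#' @return Sum of bead charges (e).
#' @export
net_charge <- function(x) {
  if (inherits(x, "molecule_template")) return(sum(x$beads$charge))
  if (inherits(x, "system_state")) return(sum(x$charge))
  stop("net_charge: unsupported class")
}

#' @export
print.molecule_template <- function(x, ...) {
  cat("molecule_template '", x$name, "': ", nrow(x$beads), " beads, ",
      nrow(x$bonds), " bonds, ", nrow(x$angles), " angles, ",
      nrow(x$constraints), " constraints, net charge ",
      sum(x$beads$charge), "e\n", sep = "")
  invisible(x)
}

#' SDS surfactant template
#'
#' Linear 4-bead anionic surfactant: three apolar C1 tail beads bonded to
#' one anionic Qa head bead (-1 e), net charge -1 e.  The companion
#' hydrated-sodium counterion (a single Qd bead, +1 e) is returned
#' alongside.
#'
#' @param bond_r0,bond_K Harmonic bond parameters (defaults: standard
#'   MARTINI 2 values, half-included convention).
#' @param angle_theta0,angle_K Harmonic angle parameters (degrees,
#'   kJ mol^-1 rad^-2).
#' @return list(sds = template, counterion = template).
#' @export
build_sds <- function(bond_r0 = 0.47, bond_K = 625,
                      angle_theta0 = 180, angle_K = 12.5) {
  beads <- data.frame(name = c("C1A", "C1B", "C1C", "SO4"),
                      type = c("C1", "C1", "C1", "Qa"),
                      charge = c(0, 0, 0, -1), mass = rep(72, 4),
                      stringsAsFactors = FALSE)
  bonds <- data.frame(i = 1:3, j = 2:4, r0 = bond_r0, K = bond_K)
  angles <- data.frame(i = 1:2, j = 2:3, k = 3:4, theta0 = angle_theta0,
                       K_theta = angle_K)
  coords <- cbind(bond_r0 * (0:3), 0, 0)
  sds <- molecule_template("SDS", beads, bonds, angles, coords = coords)
  na <- molecule_template(
    "NA+", data.frame(name = "NA", type = "Qd", charge = 1, mass = 72,
                      stringsAsFactors = FALSE),
    coords = matrix(0, 1, 3))
  list(sds = sds, counterion = na)
}

#' Polarizable three-site water template
#'
#' Central LJ bead (W) plus two oppositely charged satellite beads (WP, WM)
#' held at 0.14 nm by constraint bonds; a harmonic angle with equilibrium
#' 0 degrees and K_theta = 2.1 kJ mol^-1 rad^-2 (half-included) controls
#' satellite rotation.  Satellites carry +/-0.46 e; the molecule is neutral.
#' All intramolecular nonbonded pairs are excluded, following the published
#' polarizable water model.
#'
#' @return A [molecule_template()].
#' @export
build_polarizable_water <- function() {
  beads <- data.frame(name = c("W", "WP", "WM"),
                      type = c("W", "WP", "WM"),
                      charge = c(0, 0.46, -0.46), mass = c(24, 24, 24),
                      stringsAsFactors = FALSE)
  cons <- data.frame(i = c(1, 1), j = c(2, 3), length = 0.14)
  angles <- data.frame(i = 2, j = 1, k = 3, theta0 = 0, K_theta = 2.1)
  excl <- data.frame(i = c(1, 1, 2), j = c(2, 3, 3))
  th <- 25 * pi / 180  # small initial opening so satellites do not coincide
  coords <- rbind(c(0, 0, 0),
                  0.14 * c(cos(th / 2), sin(th / 2), 0),
                  0.14 * c(cos(th / 2), -sin(th / 2), 0))
  molecule_template("PW", beads, bonds = .empty_bonds(), angles = angles,
                    constraints = cons, exclusions = excl, coords = coords)
}

#' Hydrated monovalent ion template
#'
#' @param kind `"Cl"` (Qa bead, -1 e) or `"Na"` (Qd bead, +1 e).
#' @return A [molecule_template()].
#' @export
build_ion <- function(kind = c("Cl", "Na")) {
  kind <- match.arg(kind)
  if (kind == "Cl")
    molecule_template("CL-", data.frame(name = "CL", type = "Qa",
                                        charge = -1, mass = 72,
                                        stringsAsFactors = FALSE),
                      coords = matrix(0, 1, 3))
  else
    molecule_template("NA+", data.frame(name = "NA", type = "Qd",
                                        charge = 1, mass = 72,
                                        stringsAsFactors = FALSE),
                      coords = matrix(0, 1, 3))
}

#' Chain build specification
#'
#' @param n_repeat Number of repeat units.
#' @param DS Degree of substitution: fraction of monomers carrying the
#'   cationic substituent, in [0, 1]; `round(DS * n_repeat)` monomers are
#'   functionalized.
#' @param placement `"random"` (uniform without replacement) or `"regular"`
#'   (evenly spaced) choice of functionalized monomers.
#' @param step Self-avoiding-walk step length (nm).
#' @param min_dist Minimum allowed distance between non-bonded beads (nm).
#' @param max_retry Resampling cap per placed bead.
#' @param seed RNG seed (mandatory for reproducible builds).
#' @return An object of class `chain_spec`.
#' @export
chain_spec <- function(n_repeat, DS = 1, placement = c("random", "regular"),
                       step = 0.47, min_dist = 0.3, max_retry = 500,
                       seed = 1) {
  placement <- match.arg(placement)
  if (DS < 0 || DS > 1) stop("chain_spec: DS must lie in [0, 1]")
  if (n_repeat < 1) stop("chain_spec: n_repeat must be >= 1")
  if (min_dist >= step)
    stop("chain_spec: min_dist must be smaller than the step length")
  structure(list(n_repeat = n_repeat, DS = DS, placement = placement,
                 step = step, min_dist = min_dist, max_retry = max_retry,
                 seed = seed), class = "chain_spec")
}

# default intra-chain bonded parameters for the builder (half-included)
.cgg_defaults <- function() {
  list(bond_r0 = 0.47, bond_K = 625, ang_theta0 = 120, ang_K = 12.5)
}

# random unit vector
.rand_unit <- function() {
  repeat {
    v <- stats::rnorm(3)
    n <- sqrt(sum(v^2))
    if (n > 1e-8) return(v / n)
  }
}

#' Build a cationic polysaccharide chain
#'
#' Constructs a guar-like chain of `n_repeat` monomers.  Each neutral
#' monomer contributes 9 beads (a 6-bead two-ring backbone segment plus a
#' 3-bead side sugar); each functionalized monomer additionally carries a
#' P1 hydroxypropyl bead and a Q0 trimethylammonium bead with charge +1 e.
#' Backbone beads are placed by a self-avoiding random walk: steps that
#' bring a new bead within `min_dist` of any non-bonded placed bead are
#' resampled up to `max_retry` times.  The net charge is
#' `+round(DS * n_repeat)` e and the same number of chloride counterions is
#' requested for neutralization.
#'
#' @param spec A [chain_spec()].
#' @param params Optional list overriding the default bonded parameters
#'   (`bond_r0`, `bond_K`, `ang_theta0`, `ang_K`; half-included convention).
#' @return list(template = [molecule_template()] with coordinates,
#'   counterions = number of chloride beads required,
#'   functionalized = indices of functionalized monomers).
#' @export
build_cgg_chain <- function(spec, params = list()) {
  stopifnot(inherits(spec, "chain_spec"))
  p <- utils::modifyList(.cgg_defaults(), params)
  n <- spec$n_repeat
  ncat <- round(spec$DS * n)
  .with_seed(spec$seed, {
    fidx <- if (ncat == 0) integer() else if (spec$placement == "random")
      sort(sample.int(n, ncat)) else unique(round(seq(1, n, length.out = ncat)))
    # per-monomer bead layout (1-based offsets within the monomer):
    # 1-2-3-4-5-6 backbone, 7-8-9 side sugar on bead 2, optional 10 (P1
    # hydroxypropyl) and 11 (Q0, +1e) on bead 8.
    beads <- list(); bonds <- list(); angles <- list()
    pos <- list()
    parent <- integer()        # bead each non-backbone bead hangs from
    backbone <- integer()      # global indices of backbone beads in order
    nb <- 0
    bt <- function(type, charge = 0)
      data.frame(name = type, type = type, charge = charge, mass = 72,
                 stringsAsFactors = FALSE)
    for (m in seq_len(n)) {
      func <- m %in% fidx
      types <- c("P4", "P1", "P4", "P4", "P1", "P4", "P4", "P1", "P4")
      charges <- rep(0, 9)
      if (func) { types <- c(types, "P1", "Q0"); charges <- c(charges, 0, 1) }
      for (t in seq_along(types))
        beads[[nb + t]] <- bt(types[t], charges[t])
      o <- nb   # offset
      bb <- o + 1:6
      backbone <- c(backbone, bb)
      mb <- rbind(data.frame(i = o + 1:5, j = o + 2:6),      # backbone
                  data.frame(i = o + 2, j = o + 7),           # side attach
                  data.frame(i = o + 7:8, j = o + 8:9))       # side sugar
      if (func)
        mb <- rbind(mb, data.frame(i = c(o + 8, o + 10), j = c(o + 10, o + 11)))
      bonds[[m]] <- mb
      nb <- nb + length(types)
    }
    beads <- do.call(rbind, beads)
    beads$name <- paste0(beads$name, seq_len(nrow(beads)))
    bonds <- do.call(rbind, bonds)
    # inter-monomer links: backbone bead 6 of monomer m-1 to bead 1 of m
    if (n > 1) {
      inter <- data.frame(i = backbone[seq(6, by = 6, length.out = n - 1)],
                          j = backbone[seq(7, by = 6, length.out = n - 1)])
      bonds <- rbind(bonds, inter)
    }
    bonds <- bonds[order(bonds$i, bonds$j), ]
    bonds$r0 <- p$bond_r0; bonds$K <- p$bond_K
    # backbone angles along consecutive backbone triples
    if (length(backbone) >= 3) {
      angles <- data.frame(i = backbone[1:(length(backbone) - 2)],
                           j = backbone[2:(length(backbone) - 1)],
                           k = backbone[3:length(backbone)],
                           theta0 = p$ang_theta0, K_theta = p$ang_K)
    } else angles <- .empty_angles()

    # adjacency for the self-avoidance check
    adj <- vector("list", nrow(beads))
    for (r in seq_len(nrow(bonds))) {
      adj[[bonds$i[r]]] <- c(adj[[bonds$i[r]]], bonds$j[r])
      adj[[bonds$j[r]]] <- c(adj[[bonds$j[r]]], bonds$i[r])
    }
    coords <- matrix(NA_real_, nrow(beads), 3)
    place <- function(from_idx, bead_idx) {
      base <- if (is.na(from_idx)) c(0, 0, 0) else coords[from_idx, ]
      for (try in seq_len(spec$max_retry)) {
        cand <- base + spec$step * .rand_unit()
        placed <- which(!is.na(coords[, 1]))
        placed <- setdiff(placed, adj[[bead_idx]])
        ok <- TRUE
        if (length(placed)) {
          d2 <- colSums((t(coords[placed, , drop = FALSE]) - cand)^2)
          ok <- all(d2 >= spec$min_dist^2)
        }
        if (ok) return(cand)
      }
      stop("build_cgg_chain: self-avoiding walk failed after ",
           spec$max_retry, " retries (monomer around bead ", bead_idx,
           "); consider a larger step or smaller min_dist")
    }
    # deterministic placement order: walk the bond graph from bead 1
    order_idx <- integer(); seen <- logical(nrow(beads))
    stack <- 1L; from <- c(NA_integer_)
    while (length(stack)) {
      b <- stack[1]; f <- from[1]
      stack <- stack[-1]; from <- from[-1]
      if (seen[b]) next
      seen[b] <- TRUE
      coords[b, ] <- if (is.na(f) && b == 1L) c(0, 0, 0) else place(f, b)
      nbrs <- sort(setdiff(adj[[b]], which(seen)))
      stack <- c(nbrs, stack)
      from <- c(rep(b, length(nbrs)), from)
    }
    tmpl <- molecule_template("CGG", beads, bonds, angles, coords = coords)
    list(template = tmpl, counterions = ncat, functionalized = fidx)
  })
}

#' System state
#'
#' The assembled simulation system: bead arrays, bonded topology, box and
#' group tags (`"mobile"`, `"lower_anchor"`, `"upper_anchor"`,
#' `"graft_base"`).
#'
#' @param pos n x 3 positions (nm).
#' @param type Character bead types (used as LJ classes).
#' @param charge,mass Per-bead charge (e) and mass (amu).
#' @param molid Integer molecule ids.
#' @param molname Species name per bead.
#' @param group Group tag per bead.
#' @param bonds,angles,constraints,exclusions Topology data.frames as in
#'   [molecule_template()], with global bead indices.
#' @param box Box lengths c(lx, ly, lz) (nm).
#' @param periodic Logical 3-vector.
#' @param vel Optional n x 3 velocities (nm/ps).
#' @return An object of class `system_state`.
#' @export
system_state <- function(pos, type, charge, mass, molid, molname = NULL,
                         group = NULL, bonds = .empty_bonds(),
                         angles = .empty_angles(),
                         constraints = .empty_cons(),
                         exclusions = .empty_excl(),
                         box = c(10, 10, 10),
                         periodic = c(TRUE, TRUE, TRUE), vel = NULL) {
  pos <- as.matrix(pos)
  n <- nrow(pos)
  stopifnot(ncol(pos) == 3, length(type) == n, length(charge) == n,
            length(mass) == n, length(molid) == n)
  if (is.null(molname)) molname <- rep("MOL", n)
  if (is.null(group)) group <- rep("mobile", n)
  if (is.null(vel)) vel <- matrix(0, n, 3)
  refs <- c(bonds$i, bonds$j, angles$i, angles$j, angles$k,
            constraints$i, constraints$j, exclusions$i, exclusions$j)
  if (length(refs) && (max(refs) > n || min(refs) < 1))
    stop("system_state: topology references a non-existent bead")
  structure(list(pos = pos, vel = as.matrix(vel), type = type,
                 charge = charge, mass = mass, molid = molid,
                 molname = molname, group = group, bonds = bonds,
                 angles = angles, constraints = constraints,
                 exclusions = exclusions, box = box, periodic = periodic),
            class = "system_state")
}

#' @export
print.system_state <- function(x, ...) {
  cat("system_state:", nrow(x$pos), "beads,", nrow(x$bonds), "bonds,",
      nrow(x$angles), "angles,", nrow(x$constraints), "constraints\n")
  cat("  box:", paste(signif(x$box, 5), collapse = " x "), "nm; net charge",
      sum(x$charge), "e\n")
  invisible(x)
}

#' Number of beads in a system
#' @param state A `system_state`.
#' @return Integer.
#' @export
n_beads <- function(state) nrow(state$pos)

# append a placed template copy to accumulating lists
.append_molecule <- function(acc, tmpl, coords, molid, group = "mobile") {
  off <- length(acc$type)
  sh <- function(d, cols) { for (cc in cols) d[[cc]] <- d[[cc]] + off; d }
  acc$pos[[length(acc$pos) + 1]] <- coords
  acc$type <- c(acc$type, tmpl$beads$type)
  acc$charge <- c(acc$charge, tmpl$beads$charge)
  acc$mass <- c(acc$mass, tmpl$beads$mass)
  acc$molid <- c(acc$molid, rep(molid, nrow(tmpl$beads)))
  acc$molname <- c(acc$molname, rep(tmpl$name, nrow(tmpl$beads)))
  acc$group <- c(acc$group, rep(group, length.out = nrow(tmpl$beads)))
  acc$bonds[[length(acc$bonds) + 1]] <- sh(tmpl$bonds, c("i", "j"))
  acc$angles[[length(acc$angles) + 1]] <- sh(tmpl$angles, c("i", "j", "k"))
  acc$cons[[length(acc$cons) + 1]] <- sh(tmpl$constraints, c("i", "j"))
  acc$excl[[length(acc$excl) + 1]] <- sh(tmpl$exclusions, c("i", "j"))
  acc
}

.new_acc <- function() list(pos = list(), type = character(),
                            charge = numeric(), mass = numeric(),
                            molid = integer(), molname = character(),
                            group = character(), bonds = list(),
                            angles = list(), cons = list(), excl = list())

.acc_to_state <- function(acc, box, periodic) {
  rb <- function(l, empty) if (length(l)) do.call(rbind, l) else empty
  system_state(pos = do.call(rbind, acc$pos), type = acc$type,
               charge = acc$charge, mass = acc$mass, molid = acc$molid,
               molname = acc$molname, group = acc$group,
               bonds = rb(acc$bonds, .empty_bonds()),
               angles = rb(acc$angles, .empty_angles()),
               constraints = rb(acc$cons, .empty_cons()),
               exclusions = rb(acc$excl, .empty_excl()),
               box = box, periodic = periodic)
}

# random rotation matrix (uniform over SO(3))
.rand_rot <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Molar concentration from a molecule count and box volume
#'
#' @param count Number of molecules.
#' @param box Box lengths (nm) or a volume in nm^3.
#' @return Concentration in mol/L.
#' @export
molarity <- function(count, box) {
  V <- if (length(box) == 3) prod(box) else box
  count / (cg_constants()$avogadro_nm3_M * V)
}

#' Assemble a bulk system by random insertion
#'
#' Inserts the requested number of copies of each template at random
#' positions and orientations, rejecting placements that bring any bead
#' within `tol` of a bead of another molecule (minimum image in periodic
#' directions).  With `neutralize = TRUE`, hydrated counterions (Qa
#' chloride or Qd sodium beads) are added so the net charge is exactly
#' zero.
#'
#' @param templates List of [molecule_template()]s.
#' @param counts Integer vector, one count per template.
#' @param box Box lengths (nm).
#' @param neutralize Add counterions to reach net charge zero?
#' @param seed RNG seed.
#' @param tol Overlap tolerance (nm).
#' @param max_retry Insertion attempts per molecule before failing.
#' @return A [system_state()].
#' @export
assemble_bulk <- function(templates, counts, box, neutralize = TRUE,
                          seed = 1, tol = 0.3, max_retry = 2000) {
  stopifnot(length(templates) == length(counts))
  box <- as.numeric(box)
  .with_seed(seed, {
    acc <- .new_acc()
    placed <- NULL
    molid <- 0
    insert <- function(tmpl) {
      crd <- tmpl$coords
      if (is.null(crd)) crd <- matrix(0, nrow(tmpl$beads), 3)
      crd <- sweep(crd, 2, colMeans(crd))
      for (try in seq_len(max_retry)) {
        R <- .rand_rot()
        origin <- stats::runif(3) * box
        cand <- sweep(crd %*% t(R), 2, origin, "+")
        ok <- TRUE
        if (!is.null(placed)) {
          for (b in seq_len(nrow(cand))) {
            d <- sweep(placed, 2, cand[b, ])
            for (ax in 1:3) d[, ax] <- .minimg(d[, ax], box[ax])
            if (any(rowSums(d^2) < tol^2)) { ok <- FALSE; break }
          }
        }
        if (ok) return(cand)
      }
      stop("assemble_bulk: failed to insert a copy of '", tmpl$name,
           "' after ", max_retry, " attempts; enlarge the box or reduce ",
           "the overlap tolerance")
    }
    for (t in seq_along(templates)) {
      for (cpy in seq_len(counts[t])) {
        crd <- insert(templates[[t]])
        molid <- molid + 1
        acc <- .append_molecule(acc, templates[[t]], crd, molid)
        placed <- rbind(placed, crd)
      }
    }
    if (neutralize) {
      q <- round(sum(acc$charge))
      if (q != 0) {
        ion <- if (q > 0) build_ion("Cl") else build_ion("Na")
        for (k in seq_len(abs(q))) {
          crd <- insert(ion)
          molid <- molid + 1
          acc <- .append_molecule(acc, ion, crd, molid)
          placed <- rbind(placed, crd)
        }
      }
    }
    .acc_to_state(acc, box, c(TRUE, TRUE, TRUE))
  })
}

#' Grafted surface specification
#'
#' A simplified, configurable grafted monolayer standing in for biomimetic
#' hair-surface models: a rigid anchor lattice carrying linear grafted
#' chains whose head beads can be partially anionic (0 = virgin-like
#' apolar monolayer, >0 = bleached-like partially oxidized monolayer).
#'
#' @param lx,ly Lateral dimensions (nm).
#' @param graft_density Grafts per nm^2; graft count =
#'   `round(graft_density * lx * ly)`.
#' @param anionic_fraction Fraction of graft heads carrying -1 e, in [0,1].
#' @param graft_len Beads per grafted chain.
#' @param spacing Anchor lattice spacing (nm).
#' @return An object of class `surface_spec`.
#' @export
surface_spec <- function(lx, ly, graft_density = 0.5, anionic_fraction = 0,
                         graft_len = 3, spacing = 0.5) {
  if (anionic_fraction < 0 || anionic_fraction > 1)
    stop("surface_spec: anionic_fraction must lie in [0, 1]")
  structure(list(lx = lx, ly = ly, graft_density = graft_density,
                 anionic_fraction = anionic_fraction,
                 graft_len = graft_len, spacing = spacing),
            class = "surface_spec")
}

#' Build a grafted model surface
#'
#' Creates the rigid anchor sheet (group `"lower_anchor"`, frozen during
#' simulation) at z = 0 plus grafted linear chains.  Graft base beads are
#' tagged `"graft_base"` so thermostats can be restricted to them.  The
#' anionic fraction of graft heads carries -1 e; matching sodium
#' counterions are scattered above the monolayer so the fragment is
#' neutral.
#'
#' @param spec A [surface_spec()].
#' @param seed RNG seed.
#' @return A [system_state()] (periodic in x and y, finite in z).
#' @export
build_graft_surface <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "surface_spec"))
  .with_seed(seed, {
    nx <- max(1, round(spec$lx / spec$spacing))
    ny <- max(1, round(spec$ly / spec$spacing))
    sx <- spec$lx / nx; sy <- spec$ly / ny
    lat <- expand.grid(x = (seq_len(nx) - 0.5) * sx,
                       y = (seq_len(ny) - 0.5) * sy)
    ngraft <- round(spec$graft_density * spec$lx * spec$ly)
    if (ngraft > nrow(lat))
      stop("build_graft_surface: graft density exceeds lattice capacity (",
           ngraft, " grafts for ", nrow(lat), " sites)")
    gsites <- sort(sample.int(nrow(lat), ngraft))
    nanion <- round(spec$anionic_fraction * ngraft)
    anion <- if (nanion > 0) sort(sample(seq_len(ngraft), nanion)) else integer()
    acc <- .new_acc()
    # anchor sheet as one rigid molecule
    sheet <- molecule_template(
      "ANCHOR",
      data.frame(name = paste0("GRA", seq_len(nrow(lat))), type = "GRA",
                 charge = 0, mass = 72, stringsAsFactors = FALSE),
      coords = cbind(lat$x, lat$y, 0))
    acc <- .append_molecule(acc, sheet, sheet$coords, 1, "lower_anchor")
    molid <- 1
    b0 <- 0.47
    for (g in seq_len(ngraft)) {
      molid <- molid + 1
      nlen <- spec$graft_len
      types <- rep("C1", nlen)
      charges <- rep(0, nlen)
      if (g %in% anion) { types[nlen] <- "SCA"; charges[nlen] <- -1 }
      beads <- data.frame(name = paste0(types, seq_len(nlen)), type = types,
                          charge = charges, mass = 72,
                          stringsAsFactors = FALSE)
      bonds <- if (nlen > 1)
        data.frame(i = seq_len(nlen - 1), j = seq_len(nlen - 1) + 1,
                   r0 = b0, K = 625) else .empty_bonds()
      site <- lat[gsites[g], ]
      coords <- cbind(site$x + stats::runif(nlen, -0.05, 0.05),
                      site$y + stats::runif(nlen, -0.05, 0.05),
                      b0 * seq_len(nlen))
      tmpl <- molecule_template("GRAFT", beads, bonds, coords = coords)
      grp <- c("graft_base", rep("mobile", nlen - 1))
      acc <- .append_molecule(acc, tmpl, coords, molid, grp)
      # tether: bond from the anchor site bead to the graft base bead
      anchor_idx <- gsites[g]
      base_idx <- length(acc$type) - nlen + 1
      acc$bonds[[length(acc$bonds) + 1]] <-
        data.frame(i = anchor_idx, j = base_idx, r0 = b0, K = 625)
    }
    # counterions above the monolayer
    ztop <- spec$graft_len * b0
    ion <- build_ion("Na")
    for (k in seq_len(nanion)) {
      molid <- molid + 1
      crd <- matrix(c(stats::runif(1) * spec$lx, stats::runif(1) * spec$ly,
                      ztop + 0.5 + stats::runif(1)), 1, 3)
      acc <- .append_molecule(acc, ion, crd, molid)
    }
    .acc_to_state(acc, box = c(spec$lx, spec$ly, ztop + 3),
                  periodic = c(TRUE, TRUE, FALSE))
  })
}

#' Merge two systems (same box conventions)
#'
#' @param a,b `system_state` objects with equal lateral dimensions.
#' @return The combined [system_state()] (box of `a`, z extended to cover
#'   both).
#' @export
merge_states <- function(a, b) {
  stopifnot(inherits(a, "system_state"), inherits(b, "system_state"))
  if (any(abs(a$box[1:2] - b$box[1:2]) > 1e-9))
    stop("merge_states: lateral box dimensions differ")
  off <- n_beads(a)
  sh <- function(d, cols) { for (cc in cols) d[[cc]] <- d[[cc]] + off; d }
  system_state(
    pos = rbind(a$pos, b$pos), vel = rbind(a$vel, b$vel),
    type = c(a$type, b$type), charge = c(a$charge, b$charge),
    mass = c(a$mass, b$mass),
    molid = c(a$molid, b$molid + max(a$molid, 0)),
    molname = c(a$molname, b$molname), group = c(a$group, b$group),
    bonds = rbind(a$bonds, sh(b$bonds, c("i", "j"))),
    angles = rbind(a$angles, sh(b$angles, c("i", "j", "k"))),
    constraints = rbind(a$constraints, sh(b$constraints, c("i", "j"))),
    exclusions = rbind(a$exclusions, sh(b$exclusions, c("i", "j"))),
    box = c(a$box[1:2], max(a$box[3], b$box[3])), periodic = a$periodic)
}

#' Reflect a system through a z-plane
#'
#' z -> 2 z_plane - z, with anchor group tags swapped
#' (lower_anchor <-> upper_anchor).  Applying the same reflection twice is
#' the identity.
#'
#' @param state A `system_state`.
#' @param z_plane Mirror plane position (nm).
#' @return The reflected [system_state()].
#' @export
mirror_z <- function(state, z_plane) {
  state$pos[, 3] <- 2 * z_plane - state$pos[, 3]
  state$vel[, 3] <- -state$vel[, 3]
  g <- state$group
  g[state$group == "lower_anchor"] <- "upper_anchor"
  g[state$group == "upper_anchor"] <- "lower_anchor"
  state$group <- g
  state
}

#' Create a confined contact from a surface assembly
#'
#' Mirrors the (surface + adsorbate) assembly through the mid-plane so that
#' two opposing surfaces face each other across a free gap.  Group tags are
#' preserved, with the mirrored anchor sheet relabelled `"upper_anchor"`.
#' No beads are deleted: the result has exactly twice the input bead count.
#'
#' @param surface_system A [system_state()] whose anchor sheet is tagged
#'   `"lower_anchor"` at the bottom.
#' @param adsorbate_system Optional additional `system_state` (same lateral
#'   dimensions) merged onto the surface before mirroring.
#' @param gap Free separation between the two half-systems (nm).
#' @return A [system_state()] with both anchor groups.
#' @export
make_contact <- function(surface_system, adsorbate_system = NULL, gap = 24) {
  lower <- if (is.null(adsorbate_system)) surface_system
           else merge_states(surface_system, adsorbate_system)
  ztop <- max(lower$pos[, 3])
  upper <- mirror_z(lower, z_plane = ztop + gap / 2)
  out <- merge_states(lower, upper)
  out$box[3] <- 2 * ztop + gap + 0.5
  out$periodic <- c(TRUE, TRUE, FALSE)
  out
}

#' Draw Maxwell-Boltzmann velocities
#'
#' Assigns thermal velocities to mobile beads (anchor groups stay at rest)
#' and removes the centre-of-mass drift of the mobile set.
#'
#' @param state A `system_state`.
#' @param T Temperature (K).
#' @param seed RNG seed.
#' @return The state with velocities set.
#' @export
init_velocities <- function(state, T = 300, seed = 1) {
  .with_seed(seed, {
    n <- n_beads(state)
    mob <- !(state$group %in% c("lower_anchor", "upper_anchor"))
    sd <- sqrt(.kB * T / state$mass)
    v <- matrix(stats::rnorm(3 * n), n, 3) * sd
    v[!mob, ] <- 0
    if (any(mob)) {
      m <- state$mass[mob]
      for (ax in 1:3)
        v[mob, ax] <- v[mob, ax] - sum(m * v[mob, ax]) / sum(m)
    }
    state$vel <- v
    state
  })
}
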