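# MARTINI-style functional forms: force-switched 12-6 Lennard-Jones,
# harmonic bonds and angles, and the bookkeeping objects for bead types and
# interaction parameters.

#' Lennard-Jones shift specification
#'
#' Radii of the polynomial force-switching window.  The force is smoothly
#' ramped to zero between `r_on` and `r_cut`; energy and force are exactly
#' zero at and beyond `r_cut`.  Defaults are the standard MARTINI 2 radii
#' (0.9 and 1.2 nm).
#'
#' @param r_on Inner switch radius (nm).
#' @param r_cut Cutoff radius (nm).
#' @return An object of class `shift_spec`.
#' @export
shift_spec <- function(r_on = 0.9, r_cut = 1.2) {
  stopifnot(is.numeric(r_on), is.numeric(r_cut))
  if (!(r_on > 0 && r_cut > r_on))
    stop("shift_spec: need 0 < r_on < r_cut")
  structure(list(r_on = r_on, r_cut = r_cut), class = "shift_spec")
}

# Coefficients of the GROMACS/MARTINI force-switch polynomial for a 1/r^p
# term.  -dV/dr = p r^-(p+1) + A (r-r1)^2 + B (r-r1)^3 on (r1, rc], and both
# V and -dV/dr vanish at rc.
.fswitch_coefs <- function(p, r1, rc) {
  A <- -p * ((p + 4) * rc - (p + 1) * r1) / (rc^(p + 2) * (rc - r1)^2)
  B <-  p * ((p + 3) * rc - (p + 1) * r1) / (rc^(p + 2) * (rc - r1)^3)
  C <- rc^(-p) - (A / 3) * (rc - r1)^3 - (B / 4) * (rc - r1)^4
  list(A = A, B = B, C = C)
}

.vswitch_term <- function(r, p, r1, rc, co) {
  out <- numeric(length(r))
  below <- r <= r1
  mid   <- r > r1 & r < rc
  out[below] <- r[below]^(-p) - co$C
  rm <- r[mid]
  out[mid] <- rm^(-p) - (co$A / 3) * (rm - r1)^3 -
    (co$B / 4) * (rm - r1)^4 - co$C
  out
}

.fswitch_term <- function(r, p, r1, rc, co) {
  out <- numeric(length(r))
  below <- r <= r1
  mid   <- r > r1 & r < rc
  out[below] <- p * r[below]^(-(p + 1))
  rm <- r[mid]
  out[mid] <- p * rm^(-(p + 1)) + co$A * (rm - r1)^2 + co$B * (rm - r1)^3
  out
}

#' Shifted 12-6 Lennard-Jones potential
#'
#' Force-switched LJ energy: each inverse-power term is modified by the
#' standard cubic/quartic switching polynomial so that energy and force go
#' smoothly and exactly to zero at `shift$r_cut`.  With `shift = NULL` the
#' plain (untruncated) 12-6 form is returned.
#'
#' @param r Separation (nm); vectorized.  Must be > 0.
#' @param epsilon Well depth (kJ/mol).
#' @param sigma LJ diameter (nm).
#' @param shift A [shift_spec()], or `NULL` for the unswitched potential.
#' @return Energy in kJ/mol, same length as `r`.
#' @seealso [lj_shifted_force()]
#' @export
#' @examples
#' lj_shifted_energy(0.5, 3.5, 0.47)               # switched, default radii
#' lj_shifted_energy(1.3, 3.5, 0.47)               # beyond cutoff: exactly 0
lj_shifted_energy <- function(r, epsilon, sigma, shift = shift_spec()) {
  if (any(!is.finite(r)) || any(r <= 0)) stop("lj_shifted_energy: r must be > 0")
  if (is.null(shift))
    return(4 * epsilon * ((sigma / r)^12 - (sigma / r)^6))
  stopifnot(inherits(shift, "shift_spec"))
  r1 <- shift$r_on; rc <- shift$r_cut
  c12 <- .fswitch_coefs(12, r1, rc)
  c6  <- .fswitch_coefs(6, r1, rc)
  4 * epsilon * (sigma^12 * .vswitch_term(r, 12, r1, rc, c12) -
                 sigma^6  * .vswitch_term(r, 6,  r1, rc, c6))
}

#' Shifted Lennard-Jones force
#'
#' Radial force -dE/dr corresponding to [lj_shifted_energy()]; positive
#' values are repulsive.
#'
#' @inheritParams lj_shifted_energy
#' @return Force in kJ mol^-1 nm^-1.
#' @export
lj_shifted_force <- function(r, epsilon, sigma, shift = shift_spec()) {
  if (any(!is.finite(r)) || any(r <= 0)) stop("lj_shifted_force: r must be > 0")
  if (is.null(shift))
    return(4 * epsilon * (12 * sigma^12 / r^13 - 6 * sigma^6 / r^7))
  stopifnot(inherits(shift, "shift_spec"))
  r1 <- shift$r_on; rc <- shift$r_cut
  c12 <- .fswitch_coefs(12, r1, rc)
  c6  <- .fswitch_coefs(6, r1, rc)
  4 * epsilon * (sigma^12 * .fswitch_term(r, 12, r1, rc, c12) -
                 sigma^6  * .fswitch_term(r, 6,  r1, rc, c6))
}

.check_convention <- function(convention) {
  if (!convention %in% c("half-included", "explicit-half"))
    stop("unknown energy convention: '", convention,
         "' (use \"half-included\" or \"explicit-half\")")
  convention
}

#' Convert a harmonic force constant between energy conventions
#'
#' Two dialects exist for harmonic bonded terms: "half-included"
#' (E = K d^2, the LAMMPS convention, in which quoted constants already
#' include the factor of 1/2) and "explicit-half" (E = K/2 d^2, the GROMACS
#' convention).  Conversion is an exact factor of 2 and an involution.
#'
#' @param K Force constant(s).
#' @param from,to Convention names.
#' @return Converted constant(s).
#' @export
convert_force_constant <- function(K, from, to) {
  .check_convention(from); .check_convention(to)
  if (from == to) return(K)
  if (from == "half-included") K * 2 else K / 2
}

#' Harmonic bond energy
#'
#' E = K (r - r0)^2 under the half-included convention, or
#' E = K/2 (r - r0)^2 under explicit-half.
#'
#' @param r Bond length (nm), vectorized; must be > 0.
#' @param r0 Equilibrium length (nm).
#' @param K Force constant (kJ mol^-1 nm^-2), >= 0.
#' @param convention `"half-included"` (default) or `"explicit-half"`.
#' @return Energy in kJ/mol.
#' @export
harmonic_bond_energy <- function(r, r0, K, convention = "half-included") {
  if (any(r <= 0)) stop("harmonic_bond_energy: r must be > 0")
  if (any(K < 0)) stop("harmonic_bond_energy: K must be >= 0")
  .check_convention(convention)
  half <- if (convention == "half-included") 1 else 0.5
  half * K * (r - r0)^2
}

#' Harmonic angle energy
#'
#' E = K_theta (theta - theta0)^2 (half-included) for theta in radians.
#'
#' @param theta Angle (rad) in [0, pi]; vectorized.
#' @param theta0 Equilibrium angle (rad).
#' @param K_theta Force constant (kJ mol^-1 rad^-2), >= 0.
#' @param convention `"half-included"` (default) or `"explicit-half"`.
#' @return Energy in kJ/mol.
#' @export
harmonic_angle_energy <- function(theta, theta0, K_theta,
                                  convention = "half-included") {
  if (any(theta < 0 | theta > pi + 1e-12))
    stop("harmonic_angle_energy: theta must lie in [0, pi]")
  if (any(K_theta < 0)) stop("harmonic_angle_energy: K_theta must be >= 0")
  .check_convention(convention)
  half <- if (convention == "half-included") 1 else 0.5
  half * K_theta * (theta - theta0)^2
}

#' Bead type definition
#'
#' @param name Short label (e.g. "C1", "Qa").
#' @param mass Mass in amu; must be > 0.
#' @param charge Charge in elementary units (integer for ionic beads).
#' @param lj_class Label used to look up LJ pair parameters; defaults to
#'   `name`.
#' @return An object of class `bead_type`.
#' @export
bead_type <- function(name, mass, charge = 0, lj_class = name) {
  stopifnot(is.character(name), length(name) == 1)
  if (!is.numeric(mass) || mass <= 0) stop("bead_type: mass must be > 0")
  structure(list(name = name, mass = mass, charge = charge,
                 lj_class = lj_class), class = "bead_type")
}

#' Symmetric Lennard-Jones pair table
#'
#' Holds per-class (epsilon, sigma) values plus optional explicit pair
#' overrides.  Lookups are symmetric under class swap; missing pairs fall
#' back to Lorentz-Berthelot combination (geometric epsilon, arithmetic
#' sigma) of the per-class values.
#'
#' @param classes data.frame with columns `class`, `epsilon` (kJ/mol),
#'   `sigma` (nm).
#' @param pairs Optional data.frame with columns `class1`, `class2`,
#'   `epsilon`, `sigma`.
#' @return An object of class `lj_pair_table`.
#' @export
lj_pair_table <- function(classes, pairs = NULL) {
  stopifnot(is.data.frame(classes),
            all(c("class", "epsilon", "sigma") %in% names(classes)))
  if (any(classes$epsilon < 0) || any(classes$sigma <= 0))
    stop("lj_pair_table: need epsilon >= 0 and sigma > 0")
  if (!is.null(pairs)) {
    stopifnot(all(c("class1", "class2", "epsilon", "sigma") %in% names(pairs)))
    if (any(pairs$epsilon < 0) || any(pairs$sigma <= 0))
      stop("lj_pair_table: need epsilon >= 0 and sigma > 0")
  }
  structure(list(classes = classes, pairs = pairs), class = "lj_pair_table")
}

#' Look up LJ parameters for a class pair
#'
#' @param table An [lj_pair_table()].
#' @param c1,c2 Class labels.
#' @return list(epsilon, sigma).
#' @export
lj_lookup <- function(table, c1, c2) {
  stopifnot(inherits(table, "lj_pair_table"))
  p <- table$pairs
  if (!is.null(p)) {
    hit <- (p$class1 == c1 & p$class2 == c2) | (p$class1 == c2 & p$class2 == c1)
    if (any(hit)) {
      i <- which(hit)[1]
      return(list(epsilon = p$epsilon[i], sigma = p$sigma[i]))
    }
  }
  cl <- table$classes
  i1 <- match(c1, cl$class); i2 <- match(c2, cl$class)
  if (is.na(i1) || is.na(i2))
    stop("lj_lookup: unknown LJ class '", if (is.na(i1)) c1 else c2, "'")
  list(epsilon = sqrt(cl$epsilon[i1] * cl$epsilon[i2]),
       sigma   = (cl$sigma[i1] + cl$sigma[i2]) / 2)
}

#' Default generic MARTINI 2-like LJ classes
#'
#' A small, generic level-of-interaction table for the bead classes used by
#' the builders (apolar C1, polar P-series, charged Q-series, water W and
#' satellites, graft anchors).  Real parametrizations should supply their own
#' published table; these defaults only guarantee sensible liquid-like
#' packing for desk-scale runs.
#'
#' @return An [lj_pair_table()].
#' @export
default_lj_table <- function() {
  classes <- data.frame(
    class   = c("C1", "P1", "P2", "P4", "Q0", "Qa", "Qd", "W", "WP", "WM",
                "GRA", "SCA"),
    epsilon = c(3.5, 4.5, 4.5, 5.0, 3.5, 3.5, 3.5, 4.0, 0.0, 0.0, 3.5, 3.5),
    sigma   = c(0.47, 0.47, 0.47, 0.47, 0.47, 0.47, 0.47, 0.47, 0.47, 0.47,
                0.47, 0.47),
    stringsAsFactors = FALSE
  )
  lj_pair_table(classes)
}

#' Bonded parameter table
#'
#' Harmonic bond and angle entries in the style of an itp parameter block.
#' `K` values are stored under a single declared energy convention.
#'
#' @param bonds data.frame with columns `type_i`, `type_j`, `r0` (nm),
#'   `K` (kJ mol^-1 nm^-2).
#' @param angles data.frame with columns `type_i`, `type_j`, `type_k`,
#'   `theta0` (degrees), `K_theta` (kJ mol^-1 rad^-2).
#' @param atomtypes Optional data.frame with columns `name`, `mass`,
#'   `charge`, `lj_class`.
#' @param convention Energy convention of the stored constants.
#' @return An object of class `bonded_parameter_table`.
#' @export
bonded_parameter_table <- function(bonds = NULL, angles = NULL,
                                   atomtypes = NULL,
                                   convention = "half-included") {
  .check_convention(convention)
  if (is.null(bonds))
    bonds <- data.frame(type_i = character(), type_j = character(),
                        r0 = numeric(), K = numeric(),
                        stringsAsFactors = FALSE)
  if (is.null(angles))
    angles <- data.frame(type_i = character(), type_j = character(),
                         type_k = character(), theta0 = numeric(),
                         K_theta = numeric(), stringsAsFactors = FALSE)
  stopifnot(all(c("type_i", "type_j", "r0", "K") %in% names(bonds)),
            all(c("type_i", "type_j", "type_k", "theta0", "K_theta") %in%
                  names(angles)))
  if (any(bonds$r0 <= 0)) stop("bonded_parameter_table: r0 must be > 0")
  if (any(bonds$K < 0) || any(angles$K_theta < 0))
    stop("bonded_parameter_table: force constants must be >= 0")
  if (any(angles$theta0 < 0 | angles$theta0 > 180))
    stop("bonded_parameter_table: theta0 must lie in [0, 180] degrees")
  structure(list(bonds = bonds, angles = angles, atomtypes = atomtypes,
                 convention = convention),
            class = "bonded_parameter_table")
}

#' Convert a parameter table between energy conventions
#'
#' @param table A [bonded_parameter_table()].
#' @param to Target convention.
#' @return The converted table.
#' @export
convert_parameter_table <- function(table, to) {
  stopifnot(inherits(table, "bonded_parameter_table"))
  .check_convention(to)
  if (table$convention == to) return(table)
  table$bonds$K <- convert_force_constant(table$bonds$K, table$convention, to)
  table$angles$K_theta <-
    convert_force_constant(table$angles$K_theta, table$convention, to)
  table$convention <- to
  table
}

#' @export
print.bonded_parameter_table <- function(x, ...) {
  cat("bonded_parameter_table (", x$convention, "): ",
      nrow(x$bonds), " bond types, ", nrow(x$angles), " angle types\n",
      sep = "")
  invisible(x)
}

# --- itp-like text dialect ---------------------------------------------------
#
# Grammar: `;` starts a comment; the convention is recorded in a comment of
# the form `; convention = half-included`.  Sections are `[ atomtypes ]`
# (name mass charge lj_class), `[ bonds ]` (type_i type_j r0_nm K) and
# `[ angles ]` (type_i type_j type_k theta0_deg K_theta).  Whitespace
# separated; duplicate type tuples are an error.

.fmtnum <- function(x) vapply(x, function(v) sprintf("%.17g", v), "")

#' Write a bonded parameter table to the itp-like text dialect
#'
#' @param table A [bonded_parameter_table()].
#' @param file Optional path; if `NULL` the text is returned invisibly.
#' @return The text, invisibly (a character vector of lines).
#' @seealso [read_parameter_table()]
#' @export
write_parameter_table <- function(table, file = NULL) {
  stopifnot(inherits(table, "bonded_parameter_table"))
  out <- c("; cgtribo bonded parameter table",
           paste0("; convention = ", table$convention))
  if (!is.null(table$atomtypes) && nrow(table$atomtypes) > 0) {
    at <- table$atomtypes
    out <- c(out, "", "[ atomtypes ]", "; name mass charge lj_class",
             paste(at$name, .fmtnum(at$mass), .fmtnum(at$charge), at$lj_class))
  }
  out <- c(out, "", "[ bonds ]", "; type_i type_j r0_nm K_kJ_mol_nm2")
  if (nrow(table$bonds) > 0) {
    b <- table$bonds
    out <- c(out, paste(b$type_i, b$type_j, .fmtnum(b$r0), .fmtnum(b$K)))
  }
  out <- c(out, "", "[ angles ]",
           "; type_i type_j type_k theta0_deg K_theta_kJ_mol_rad2")
  if (nrow(table$angles) > 0) {
    a <- table$angles
    out <- c(out, paste(a$type_i, a$type_j, a$type_k, .fmtnum(a$theta0),
                        .fmtnum(a$K_theta)))
  }
  if (!is.null(file)) writeLines(out, file)
  invisible(out)
}

#' Read a bonded parameter table from the itp-like text dialect
#'
#' @param text A file path, or a character vector of lines.
#' @return A [bonded_parameter_table()].
#' @export
read_parameter_table <- function(text) {
  lines <- if (length(text) == 1 && file.exists(text)) readLines(text) else text
  convention <- NULL
  section <- ""
  at <- list(); bo <- list(); an <- list()
  for (ln in seq_along(lines)) {
    raw <- lines[ln]
    comment <- sub("^[^;]*", "", raw)
    m <- regmatches(comment,
                    regexec("convention\\s*=\\s*([A-Za-z-]+)", comment))[[1]]
    if (length(m) == 2) {
      conv <- .check_convention(m[2])
      if (!is.null(convention) && convention != conv)
        stop("read_parameter_table: conflicting conventions ('", convention,
             "' vs '", conv, "') at line ", ln)
      convention <- conv
    }
    code <- trimws(sub(";.*$", "", raw))
    if (code == "") next
    sec <- regmatches(code, regexec("^\\[\\s*([A-Za-z]+)\\s*\\]$", code))[[1]]
    if (length(sec) == 2) {
      section <- tolower(sec[2])
      if (!section %in% c("atomtypes", "bonds", "angles"))
        stop("read_parameter_table: unknown section '", sec[2],
             "' at line ", ln)
      next
    }
    tok <- strsplit(code, "\\s+")[[1]]
    if (section == "atomtypes") {
      if (length(tok) != 4)
        stop("read_parameter_table: malformed atomtypes entry at line ", ln)
      at[[length(at) + 1]] <- data.frame(
        name = tok[1], mass = as.numeric(tok[2]), charge = as.numeric(tok[3]),
        lj_class = tok[4], line = ln, stringsAsFactors = FALSE)
    } else if (section == "bonds") {
      if (length(tok) != 4)
        stop("read_parameter_table: malformed bond entry at line ", ln)
      bo[[length(bo) + 1]] <- data.frame(
        type_i = tok[1], type_j = tok[2], r0 = as.numeric(tok[3]),
        K = as.numeric(tok[4]), line = ln, stringsAsFactors = FALSE)
    } else if (section == "angles") {
      if (length(tok) != 5)
        stop("read_parameter_table: malformed angle entry at line ", ln)
      an[[length(an) + 1]] <- data.frame(
        type_i = tok[1], type_j = tok[2], type_k = tok[3],
        theta0 = as.numeric(tok[4]), K_theta = as.numeric(tok[5]),
        line = ln, stringsAsFactors = FALSE)
    } else {
      stop("read_parameter_table: data outside any section at line ", ln)
    }
  }
  bonds <- if (length(bo)) do.call(rbind, bo) else NULL
  angles <- if (length(an)) do.call(rbind, an) else NULL
  atomtypes <- if (length(at)) do.call(rbind, at) else NULL
  if (!is.null(bonds)) {
    key <- vapply(seq_len(nrow(bonds)), function(i)
      paste(sort(c(bonds$type_i[i], bonds$type_j[i])), collapse = "|"), "")
    if (anyDuplicated(key))
      stop("read_parameter_table: duplicate bond entry at line ",
           bonds$line[which(duplicated(key))[1]])
  }
  if (!is.null(angles)) {
    key <- vapply(seq_len(nrow(angles)), function(i) {
      tr <- c(angles$type_i[i], angles$type_j[i], angles$type_k[i])
      rv <- rev(tr)
      paste(if (paste(tr, collapse = "|") <= paste(rv, collapse = "|"))
        tr else rv, collapse = "|")
    }, "")
    if (anyDuplicated(key))
      stop("read_parameter_table: duplicate angle entry at line ",
           angles$line[which(duplicated(key))[1]])
  }
  if (!is.null(atomtypes) && anyDuplicated(atomtypes$name))
    stop("read_parameter_table: duplicate atomtype at line ",
         atomtypes$line[which(duplicated(atomtypes$name))[1]])
  drop_line <- function(d) { if (!is.null(d)) d$line <- NULL; d }
  bonded_parameter_table(
    bonds = drop_line(bonds), angles = drop_line(angles),
    atomtypes = drop_line(atomtypes),
    convention = if (is.null(convention)) "half-included" else convention)
}

#' Export a bonded parameter table as JSON
#'
#' @param table A [bonded_parameter_table()].
#' @param file Optional output path.
#' @return JSON string, invisibly.
#' @export
parameter_table_json <- function(table, file = NULL) {
  stopifnot(inherits(table, "bonded_parameter_table"))
  js <- jsonlite::toJSON(list(convention = table$convention,
                              atomtypes = table$atomtypes,
                              bonds = table$bonds, angles = table$angles),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  if (!is.null(file)) writeLines(js, file)
  invisible(js)
}
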