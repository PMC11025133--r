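# Structure and trajectory file I/O.  Internally everything is in
# GROMACS-style units (nm, kJ/mol, ps, amu); LAMMPS data and dump files are
# written in LAMMPS "real" units (Angstrom, kcal/mol, fs) and converted back
# on read.

.KCAL <- 4.184      # kJ per kcal
.A    <- 10         # Angstrom per nm

# --- LAMMPS data (atom_style full) -------------------------------------------

#' Write a system to a LAMMPS data file (atom_style full)
#'
#' Positions are exported in Angstrom, harmonic coefficients in
#' kcal mol^-1 A^-2 (bonds) / kcal mol^-1 rad^-2 (angles), matching LAMMPS
#' "real" units and the half-included energy convention of
#' `bond_style harmonic`.  Constraint bonds are encoded as bonds of flagged
#' types listed in a `# constraint bond types:` header comment.  Group tags
#' are not representable in the format and are not round-tripped.
#'
#' @param state A [system_state()].
#' @param file Output path.
#' @return Invisibly, the written lines.
#' @export
write_lammps_data <- function(state, file) {
  stopifnot(inherits(state, "system_state"))
  n <- n_beads(state)
  types <- sort(unique(state$type))
  tid <- match(state$type, types)
  # bond types from unique (r0, K); constraints appended as flagged types
  bkey <- if (nrow(state$bonds)) paste(state$bonds$r0, state$bonds$K) else character()
  bu <- unique(bkey)
  ckey <- if (nrow(state$constraints)) paste("cons", state$constraints$length)
          else character()
  cu <- unique(ckey)
  akey <- if (nrow(state$angles)) paste(state$angles$theta0, state$angles$K_theta)
          else character()
  au <- unique(akey)
  nbondtypes <- length(bu) + length(cu)
  fmt <- function(x) sprintf("%.10g", x)
  L <- c("LAMMPS data file generated by cgtribo (real units)",
         if (length(cu)) paste0("# constraint bond types: ",
                                paste(length(bu) + seq_along(cu),
                                      collapse = ",")) else NULL,
         "",
         paste(n, "atoms"),
         paste(nrow(state$bonds) + nrow(state$constraints), "bonds"),
         paste(nrow(state$angles), "angles"),
         "",
         paste(length(types), "atom types"),
         paste(nbondtypes, "bond types"),
         paste(length(au), "angle types"),
         "",
         paste(0, fmt(state$box[1] * .A), "xlo xhi"),
         paste(0, fmt(state$box[2] * .A), "ylo yhi"),
         paste(0, fmt(state$box[3] * .A), "zlo zhi"),
         "")
  # type legend so readers can recover the character types
  L <- c(L, paste0("# type map: ",
                   paste(seq_along(types), types, sep = "=", collapse = " ")),
         "", "Masses", "")
  for (t in seq_along(types))
    L <- c(L, paste(t, fmt(state$mass[match(types[t], state$type)])))
  if (nbondtypes > 0) {
    L <- c(L, "", "Bond Coeffs", "")
    for (b in seq_along(bu)) {
      pr <- as.numeric(strsplit(bu[b], " ")[[1]])
      # K: kJ/mol/nm^2 -> kcal/mol/A^2; r0: nm -> A
      L <- c(L, paste(b, fmt(pr[2] / .KCAL / .A^2), fmt(pr[1] * .A)))
    }
    for (ci in seq_along(cu)) {
      len <- as.numeric(sub("cons ", "", cu[ci]))
      L <- c(L, paste(length(bu) + ci, fmt(0), fmt(len * .A)))
    }
  }
  if (length(au) > 0) {
    L <- c(L, "", "Angle Coeffs", "")
    for (a in seq_along(au)) {
      pr <- as.numeric(strsplit(au[a], " ")[[1]])
      L <- c(L, paste(a, fmt(pr[2] / .KCAL), fmt(pr[1])))
    }
  }
  L <- c(L, "", "Atoms # full", "")
  for (i in seq_len(n))
    L <- c(L, paste(i, state$molid[i], tid[i], fmt(state$charge[i]),
                    fmt(state$pos[i, 1] * .A), fmt(state$pos[i, 2] * .A),
                    fmt(state$pos[i, 3] * .A)))
  if (any(state$vel != 0)) {
    L <- c(L, "", "Velocities", "")
    for (i in seq_len(n))   # nm/ps -> A/fs
      L <- c(L, paste(i, fmt(state$vel[i, 1] * .A / 1000),
                      fmt(state$vel[i, 2] * .A / 1000),
                      fmt(state$vel[i, 3] * .A / 1000)))
  }
  if (nrow(state$bonds) + nrow(state$constraints) > 0) {
    L <- c(L, "", "Bonds", "")
    bid <- 0
    for (r in seq_len(nrow(state$bonds))) {
      bid <- bid + 1
      L <- c(L, paste(bid, match(bkey[r], bu), state$bonds$i[r],
                      state$bonds$j[r]))
    }
    for (r in seq_len(nrow(state$constraints))) {
      bid <- bid + 1
      L <- c(L, paste(bid, length(bu) + match(ckey[r], cu),
                      state$constraints$i[r], state$constraints$j[r]))
    }
  }
  if (nrow(state$angles) > 0) {
    L <- c(L, "", "Angles", "")
    for (r in seq_len(nrow(state$angles)))
      L <- c(L, paste(r, match(akey[r], au), state$angles$i[r],
                      state$angles$j[r], state$angles$k[r]))
  }
  writeLines(L, file)
  invisible(L)
}

#' Read a system from a LAMMPS data file written by [write_lammps_data()]
#'
#' @param file Path (or character vector of lines).
#' @return A [system_state()].
#' @export
read_lammps_data <- function(file) {
  lines <- if (length(file) == 1 && file.exists(file)) readLines(file) else file
  known <- c("Masses", "Bond Coeffs", "Angle Coeffs", "Atoms", "Velocities",
             "Bonds", "Angles")
  constraint_types <- integer()
  typemap <- NULL
  hdr <- list()
  box <- c(NA, NA, NA)
  section <- NULL
  sections <- list()
  for (ln in seq_along(lines)) {
    raw <- lines[ln]
    if (ln == 1) next  # title line
    m <- regmatches(raw, regexec("# constraint bond types:\\s*([0-9,]+)", raw))[[1]]
    if (length(m) == 2) {
      constraint_types <- as.integer(strsplit(m[2], ",")[[1]]); next
    }
    m <- regmatches(raw, regexec("# type map:\\s*(.*)$", raw))[[1]]
    if (length(m) == 2) {
      kv <- strsplit(strsplit(trimws(m[2]), "\\s+")[[1]], "=")
      typemap <- vapply(kv, `[`, "", 2)
      next
    }
    code <- trimws(sub("#.*$", "", raw))
    if (code == "") next
    if (grepl("^[A-Za-z]", code)) {
      name <- sub("\\s*$", "", code)
      base <- sub(" # .*$", "", name)
      hit <- known[vapply(known, function(k) startsWith(base, k), TRUE)]
      # prefer longest match ("Bond Coeffs" before "Bonds")
      hit <- hit[order(-nchar(hit))][1]
      if (is.na(hit)) {
        # header counts like "12 atoms" start with a digit; anything else
        # alphabetic is an unknown section
        stop("read_lammps_data: unknown section header '", code,
             "' at line ", ln)
      }
      section <- hit
      sections[[section]] <- list()
      next
    }
    tok <- strsplit(code, "\\s+")[[1]]
    if (is.null(section)) {
      if (grepl("lo", code)) {
        if (grepl("xlo", code)) box[1] <- as.numeric(tok[2]) - as.numeric(tok[1])
        if (grepl("ylo", code)) box[2] <- as.numeric(tok[2]) - as.numeric(tok[1])
        if (grepl("zlo", code)) box[3] <- as.numeric(tok[2]) - as.numeric(tok[1])
      }
      next
    }
    sections[[section]][[length(sections[[section]]) + 1]] <- tok
  }
  tomat <- function(name) {
    s <- sections[[name]]
    if (is.null(s) || !length(s)) return(NULL)
    do.call(rbind, lapply(s, function(t) as.numeric(t)))
  }
  atoms <- sections[["Atoms"]]
  if (is.null(atoms)) stop("read_lammps_data: missing Atoms section")
  if (!length(atoms))
    return(system_state(pos = matrix(0, 0, 3), type = character(),
                        charge = numeric(), mass = numeric(),
                        molid = integer(), box = box,
                        periodic = c(TRUE, TRUE, TRUE)))
  am <- do.call(rbind, lapply(atoms, as.numeric))
  am <- am[order(am[, 1]), , drop = FALSE]
  n <- nrow(am)
  masses <- tomat("Masses")
  type_idx <- am[, 3]
  type_chr <- if (!is.null(typemap)) typemap[type_idx] else
    as.character(type_idx)
  mass <- masses[match(type_idx, masses[, 1]), 2]
  pos <- am[, 5:7, drop = FALSE] / .A
  vel <- matrix(0, n, 3)
  vm <- tomat("Velocities")
  if (!is.null(vm)) {
    vm <- vm[order(vm[, 1]), , drop = FALSE]
    vel <- vm[, 2:4, drop = FALSE] * 1000 / .A
  }
  bc <- tomat("Bond Coeffs")
  ac <- tomat("Angle Coeffs")
  bonds <- .empty_bonds(); cons <- .empty_cons()
  bm <- tomat("Bonds")
  if (!is.null(bm)) {
    for (r in seq_len(nrow(bm))) {
      bt <- bm[r, 2]
      if (bt %in% constraint_types) {
        cons <- rbind(cons, data.frame(i = bm[r, 3], j = bm[r, 4],
                                       length = bc[match(bt, bc[, 1]), 3] / .A))
      } else {
        bonds <- rbind(bonds,
                       data.frame(i = bm[r, 3], j = bm[r, 4],
                                  r0 = bc[match(bt, bc[, 1]), 3] / .A,
                                  K = bc[match(bt, bc[, 1]), 2] * .KCAL * .A^2))
      }
    }
  }
  anglesdf <- .empty_angles()
  anm <- tomat("Angles")
  if (!is.null(anm)) {
    anglesdf <- data.frame(i = anm[, 3], j = anm[, 4], k = anm[, 5],
                           theta0 = ac[match(anm[, 2], ac[, 1]), 3],
                           K_theta = ac[match(anm[, 2], ac[, 1]), 2] * .KCAL)
  }
  system_state(pos = pos, vel = vel, type = type_chr, charge = am[, 4],
               mass = mass, molid = as.integer(am[, 2]),
               bonds = bonds, angles = anglesdf, constraints = cons,
               box = box, periodic = c(TRUE, TRUE, TRUE))
}

# --- GRO ---------------------------------------------------------------------

#' Write a GRO coordinate file
#'
#' @param state A [system_state()] (or a `bead_traj`, first frame).
#' @param file Output path.
#' @param title Title line.
#' @return Invisibly, the written lines.
#' @export
write_gro <- function(state, file, title = "cgtribo system") {
  if (inherits(state, "bead_traj")) {
    pos <- state$coords[, , 1]
    nm <- state$beads$name; res <- seq_len(nrow(pos)); resn <- state$beads$type
    box <- state$box
  } else {
    pos <- state$pos; nm <- state$type; res <- state$molid
    resn <- state$molname; box <- state$box
  }
  n <- nrow(pos)
  lines <- c(title, sprintf("%5d", n))
  for (i in seq_len(n))
    lines <- c(lines, sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                              res[i] %% 100000, substr(resn[i], 1, 5),
                              substr(nm[i], 1, 5), i %% 100000,
                              pos[i, 1], pos[i, 2], pos[i, 3]))
  lines <- c(lines, sprintf("%10.5f%10.5f%10.5f", box[1], box[2], box[3]))
  writeLines(lines, file)
  invisible(lines)
}

#' Read a GRO coordinate file
#'
#' @param file Path.
#' @return list(pos matrix in nm, name, resid, resname, box).
#' @export
read_gro <- function(file) {
  lines <- readLines(file)
  n <- as.integer(trimws(lines[2]))
  body <- lines[3:(2 + n)]
  resid <- as.integer(substr(body, 1, 5))
  resname <- trimws(substr(body, 6, 10))
  name <- trimws(substr(body, 11, 15))
  x <- as.numeric(substr(body, 21, 28))
  y <- as.numeric(substr(body, 29, 36))
  z <- as.numeric(substr(body, 37, 44))
  box <- as.numeric(strsplit(trimws(lines[3 + n]), "\\s+")[[1]])[1:3]
  list(pos = cbind(x, y, z), name = name, resid = resid, resname = resname,
       box = box)
}

# --- LAMMPS dump -------------------------------------------------------------

#' Write a trajectory as a LAMMPS dump file
#'
#' Format: per frame, `ITEM: TIMESTEP / NUMBER OF ATOMS / BOX BOUNDS /`
#' `ITEM: ATOMS id type x y z vx vy vz`, with coordinates in Angstrom and
#' velocities in Angstrom/fs (LAMMPS real units).
#'
#' @param traj A [bead_traj()] (or object coercible via [as_bead_traj()]).
#' @param file Output path.
#' @return Invisibly `NULL`.
#' @export
write_lammps_dump <- function(traj, file) {
  traj <- as_bead_traj(traj)
  co <- traj$coords
  nf <- dim(co)[3]; n <- dim(co)[1]
  box <- traj$box
  if (is.null(box)) box <- apply(co, 2, max) + 1
  types <- sort(unique(traj$beads$type))
  tid <- match(traj$beads$type, types)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(paste0("# type map: ",
                    paste(seq_along(types), types, sep = "=", collapse = " ")),
             con)
  for (f in seq_len(nf)) {
    v <- if (!is.null(traj$vel)) traj$vel[, , f] else matrix(0, n, 3)
    writeLines(c("ITEM: TIMESTEP", format(f - 1),
                 "ITEM: NUMBER OF ATOMS", format(n),
                 "ITEM: BOX BOUNDS pp pp pp",
                 sprintf("0 %.10g", box[1] * .A),
                 sprintf("0 %.10g", box[2] * .A),
                 sprintf("0 %.10g", box[3] * .A),
                 "ITEM: ATOMS id type x y z vx vy vz"), con)
    writeLines(sprintf("%d %d %.10g %.10g %.10g %.10g %.10g %.10g",
                       seq_len(n), tid, co[, 1, f] * .A, co[, 2, f] * .A,
                       co[, 3, f] * .A, v[, 1] * .A / 1000,
                       v[, 2] * .A / 1000, v[, 3] * .A / 1000), con)
  }
  invisible(NULL)
}

#' Read a LAMMPS dump trajectory
#'
#' Reads dumps written by [write_lammps_dump()] (real units).  Optional
#' atom metadata turns the result into an [atom_traj()] suitable for
#' [map_trajectory()].
#'
#' @param file Path.
#' @param atoms Optional data.frame (`name`, `resid`, `resname`, `mass`)
#'   with one row per atom id.
#' @return A [bead_traj()] (or [atom_traj()] when `atoms` is given).
#' @export
read_lammps_dump <- function(file, atoms = NULL) {
  lines <- readLines(file)
  typemap <- NULL
  m <- regmatches(lines[1], regexec("# type map:\\s*(.*)$", lines[1]))[[1]]
  if (length(m) == 2) {
    kv <- strsplit(strsplit(trimws(m[2]), "\\s+")[[1]], "=")
    typemap <- vapply(kv, `[`, "", 2)
  }
  idx <- which(lines == "ITEM: TIMESTEP")
  frames <- list(); vels <- list(); box <- NULL
  for (s in idx) {
    n <- as.integer(lines[s + 3])
    bx <- vapply(lines[s + 5:7], function(l)
      diff(as.numeric(strsplit(trimws(l), "\\s+")[[1]])), 0)
    box <- bx / .A
    body <- lines[(s + 9):(s + 8 + n)]
    dm <- do.call(rbind, lapply(strsplit(body, "\\s+"), as.numeric))
    dm <- dm[order(dm[, 1]), , drop = FALSE]
    frames[[length(frames) + 1]] <- dm[, 3:5, drop = FALSE] / .A
    vels[[length(vels) + 1]] <- dm[, 6:8, drop = FALSE] * 1000 / .A
  }
  nf <- length(frames); n <- nrow(frames[[1]])
  co <- array(unlist(frames), c(n, 3, nf))
  ve <- array(unlist(vels), c(n, 3, nf))
  first <- do.call(rbind, lapply(strsplit(
    lines[(idx[1] + 9):(idx[1] + 8 + n)], "\\s+"), as.numeric))
  first <- first[order(first[, 1]), , drop = FALSE]
  tnum <- first[, 2]
  tchr <- if (!is.null(typemap)) typemap[tnum] else as.character(tnum)
  if (!is.null(atoms)) {
    stopifnot(nrow(atoms) == n)
    return(atom_traj(co, atoms, box = box))
  }
  bead_traj(co, data.frame(name = tchr, type = tchr,
                           stringsAsFactors = FALSE),
            box = box, vel = ve)
}
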