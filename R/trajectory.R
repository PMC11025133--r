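# Trajectory containers.  Coordinates are stored as a 3-D array
# [site, xyz, frame] in nm so that per-frame operations vectorize across
# frames.

#' Atomistic trajectory container
#'
#' @param coords Numeric array `n_atoms x 3 x n_frames` (nm).
#' @param atoms data.frame with one row per atom: `name`, `resid`,
#'   `resname`, `mass` (amu).
#' @param box Box lengths `c(lx, ly, lz)` in nm, or `NULL` for non-periodic.
#' @param time Optional per-frame times (ps).
#' @return An object of class `atom_traj`.
#' @export
atom_traj <- function(coords, atoms, box = NULL, time = NULL) {
  if (length(dim(coords)) == 2) coords <- array(coords, c(dim(coords), 1))
  stopifnot(length(dim(coords)) == 3, dim(coords)[2] == 3,
            is.data.frame(atoms),
            all(c("name", "resid", "resname", "mass") %in% names(atoms)),
            nrow(atoms) == dim(coords)[1])
  if (is.null(time)) time <- seq_len(dim(coords)[3]) - 1
  structure(list(coords = coords, atoms = atoms, box = box, time = time),
            class = "atom_traj")
}

#' Coarse-grained bead trajectory container
#'
#' @param coords Numeric array `n_beads x 3 x n_frames` (nm).
#' @param beads data.frame with one row per bead: at least `name` and
#'   `type`; optionally `charge`, `mass`, `molid`, `species`, `group`.
#' @param box Box lengths (nm) or `NULL`.
#' @param vel Optional velocity array matching `coords` (nm/ps).
#' @param time Optional per-frame times (ps).
#' @return An object of class `bead_traj`.
#' @export
bead_traj <- function(coords, beads, box = NULL, vel = NULL, time = NULL) {
  if (length(dim(coords)) == 2) coords <- array(coords, c(dim(coords), 1))
  stopifnot(length(dim(coords)) == 3, dim(coords)[2] == 3,
            is.data.frame(beads), nrow(beads) == dim(coords)[1])
  if (!is.null(vel)) stopifnot(all(dim(vel) == dim(coords)))
  if (is.null(time)) time <- seq_len(dim(coords)[3]) - 1
  if (is.null(beads$mass)) beads$mass <- 72
  if (is.null(beads$charge)) beads$charge <- 0
  structure(list(coords = coords, beads = beads, box = box, vel = vel,
                 time = time), class = "bead_traj")
}

#' @export
print.bead_traj <- function(x, ...) {
  cat("bead_traj:", dim(x$coords)[1], "beads,", dim(x$coords)[3], "frames\n")
  invisible(x)
}

#' @export
print.atom_traj <- function(x, ...) {
  cat("atom_traj:", dim(x$coords)[1], "atoms,", dim(x$coords)[3], "frames\n")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj An `atom_traj`, `bead_traj` or `md_log`.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) {
  if (inherits(traj, "md_log")) return(dim(traj$frames)[3])
  dim(traj$coords)[3]
}

#' Coerce an object to a bead trajectory
#'
#' `md_log` objects returned by [run_md()] carry sampled frames plus the
#' bead metadata of the simulated state; this flattens them to the common
#' `bead_traj` container used by the analysis layer.
#'
#' @param x A `bead_traj` or `md_log`.
#' @return A [bead_traj()].
#' @export
as_bead_traj <- function(x) {
  if (inherits(x, "bead_traj")) return(x)
  if (inherits(x, "md_log")) {
    if (is.null(x$frames)) stop("as_bead_traj: md_log has no stored frames")
    st <- x$state
    beads <- data.frame(name = st$type, type = st$type, charge = st$charge,
                        mass = st$mass, molid = st$molid,
                        species = st$molname, group = st$group,
                        stringsAsFactors = FALSE)
    return(bead_traj(x$frames, beads, box = st$box, vel = x$vel_frames,
                     time = x$frame_time))
  }
  stop("as_bead_traj: cannot coerce class ", paste(class(x), collapse = "/"))
}

# minimum-image displacement, vectorized; box may be NULL (no wrapping)
.minimg <- function(d, box_len) {
  if (is.null(box_len) || !is.finite(box_len) || box_len <= 0) return(d)
  d - box_len * round(d / box_len)
}
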