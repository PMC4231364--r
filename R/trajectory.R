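#' Atomic trajectory container
#'
#' Frames-by-atoms-by-3 coordinate array (Å) with atom metadata and frame
#' times (ns). The atom count is constant across frames.
#'
#' @param coords Numeric array `n_frames x n_atoms x 3` (Å), finite.
#' @param times Frame times (ns), increasing; one per frame.
#' @param atoms data.frame with one row per atom and columns `name`
#'   (PDB atom name, e.g. `"CA"`, `"NE2"`), `resno` (residue number),
#'   `resname`, `chain`, and optionally `insert` (insertion code).
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(coords, times, atoms) {
  if (!is.array(coords) || length(dim(coords)) != 3L || dim(coords)[3] != 3L)
    hk_stop_invalid("coords", "must be an n_frames x n_atoms x 3 array")
  if (!all(is.finite(coords)))
    hk_stop_invalid("coords", "must be finite")
  nf <- dim(coords)[1]; na <- dim(coords)[2]
  check_numeric_vec(times, "times", min_len = nf)
  if (length(times) != nf)
    hk_stop_invalid("times", "must have one value per frame")
  if (nf > 1 && is.unsorted(times, strictly = TRUE))
    hk_stop_invalid("times", "must be strictly increasing")
  if (!is.data.frame(atoms) || nrow(atoms) != na)
    hk_stop_invalid("atoms", "must be a data.frame with one row per atom")
  for (col in c("name", "resno", "resname", "chain"))
    if (is.null(atoms[[col]]))
      hk_stop_invalid("atoms", sprintf("missing column '%s'", col))
  if (is.null(atoms$insert)) atoms$insert <- ""
  structure(list(coords = coords, times = times, atoms = atoms),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  d <- dim(x$coords)
  cat(sprintf("Trajectory: %d frames x %d atoms (%g-%g ns), %d residues\n",
              d[1], d[2], min(x$times), max(x$times),
              length(unique(paste(x$atoms$chain, x$atoms$resno, x$atoms$insert)))))
  invisible(x)
}

n_frames <- function(traj) dim(traj$coords)[1]
n_atoms <- function(traj) dim(traj$coords)[2]

frame_coords <- function(traj, f) {
  matrix(traj$coords[f, , ], ncol = 3)
}

#' Select atoms of a trajectory
#'
#' Selections are either the keywords `"backbone"` (atoms named N, CA, C,
#' O), `"calpha"` (atoms named CA), `"all"`, an integer vector of atom
#' indices, or a `"chain:resno:atomname"` pattern in which each field may
#' be the wildcard `*` (e.g. `"A:208:NE2"`, `"*:*:CA"`). Residue numbers
#' may carry an insertion code (`"52A"`).
#'
#' @param traj A [trajectory()].
#' @param selection Selection keyword, pattern, or index vector.
#' @return Integer vector of atom indices (possibly empty).
#' @export
select_atoms <- function(traj, selection) {
  stopifnot(inherits(traj, "trajectory"))
  a <- traj$atoms
  if (is.numeric(selection)) {
    idx <- as.integer(selection)
    if (any(idx < 1L | idx > nrow(a)))
      hk_stop_invalid("selection", "atom index out of range")
    return(idx)
  }
  if (!is.character(selection) || length(selection) != 1L)
    hk_stop_invalid("selection", "must be a keyword, pattern, or index vector")
  name <- trimws(a$name)
  if (selection == "all") return(seq_len(nrow(a)))
  if (selection == "backbone") return(which(name %in% c("N", "CA", "C", "O")))
  if (selection %in% c("calpha", "CA")) return(which(name == "CA"))
  parts <- strsplit(selection, ":", fixed = TRUE)[[1]]
  if (length(parts) != 3L)
    hk_stop_invalid("selection",
      sprintf("'%s' is not a keyword or a chain:resno:atomname pattern", selection))
  reskey <- paste0(a$resno, trimws(a$insert))
  hit <- rep(TRUE, nrow(a))
  if (parts[1] != "*") hit <- hit & trimws(a$chain) == parts[1]
  if (parts[2] != "*") hit <- hit & reskey == parts[2]
  if (parts[3] != "*") hit <- hit & name == parts[3]
  which(hit)
}

describe_atoms <- function(traj, idx) {
  a <- traj$atoms[idx, , drop = FALSE]
  paste(sprintf("%s:%s%s:%s (%s)", a$chain, a$resno, trimws(a$insert),
                trimws(a$name), a$resname), collapse = ", ")
}

resolve_single_atom <- function(traj, spec, label) {
  idx <- select_atoms(traj, spec)
  if (length(idx) == 1L) return(idx)
  if (length(idx) == 0L)
    hk_stop_invalid(label, sprintf("selection '%s' matches no atom", spec))
  hk_stop_invalid(label, sprintf(
    "selection '%s' is ambiguous; candidates: %s", spec,
    describe_atoms(traj, idx)))
}
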