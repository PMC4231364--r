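# Multi-model PDB and XYZ trajectory I/O. Coordinate records only
# (ATOM/HETATM inside MODEL/ENDMDL blocks); fixed-column dialect, 3-decimal
# coordinate precision, altloc 'A' or blank kept, insertion codes preserved.

pdb_atom_name_field <- function(name) {
  name <- trimws(name)
  # atom names up to 3 chars start in column 14; 4-char names fill 13-16
  if (nchar(name) >= 4L) substr(name, 1, 4) else sprintf(" %-3s", name)
}

#' Write a trajectory as a multi-model PDB file
#'
#' One MODEL/ENDMDL block per frame; coordinates are written with the
#' standard fixed 8.3 precision, so a round trip preserves them to 1e-3 Å.
#' Frame times (ns) are recorded in REMARK lines and recovered by
#' [read_pdb()].
#'
#' @param traj A [trajectory()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  a <- traj$atoms
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("REMARK   6 FRAME TIMES NS %s",
                     paste(format(traj$times, digits = 17), collapse = " ")),
             con)
  namef <- vapply(a$name, pdb_atom_name_field, character(1))
  for (f in seq_len(n_frames(traj))) {
    writeLines(sprintf("MODEL     %4d", f), con)
    x <- frame_coords(traj, f)
    lines <- sprintf("ATOM  %5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f",
                     seq_len(nrow(a)), namef, "", substr(a$resname, 1, 3),
                     substr(paste0(a$chain, " "), 1, 1), a$resno,
                     substr(paste0(a$insert, " "), 1, 1),
                     x[, 1], x[, 2], x[, 3], 1, 0)
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a multi-model PDB file as a trajectory
#'
#' Parses ATOM/HETATM coordinate records grouped by MODEL/ENDMDL blocks
#' (a file without MODEL records is read as a single frame). Alternate
#' location indicators other than blank or `A` are dropped; insertion
#' codes are preserved in the atom table. Frame times are taken from a
#' `REMARK   6 FRAME TIMES NS` header when present, else 0, 1, 2, ... ns.
#'
#' @param path PDB file path.
#' @return A [trajectory()].
#' @export
read_pdb <- function(path) {
  lines <- readLines(path)
  times <- NULL
  tl <- grep("^REMARK   6 FRAME TIMES NS ", lines, value = TRUE)
  if (length(tl) == 1L)
    times <- as.numeric(strsplit(sub("^REMARK   6 FRAME TIMES NS ", "", tl),
                                 "\\s+")[[1]])
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  is_model <- grepl("^MODEL", lines)
  is_end <- grepl("^ENDMDL", lines)
  if (!any(is_atom)) hk_stop_invalid("path", "no ATOM/HETATM records found")
  model_id <- cumsum(is_model)
  if (!any(is_model)) model_id <- rep(1L, length(lines))
  atoms_lines <- lines[is_atom]
  frame_of <- model_id[is_atom]
  if (any(frame_of == 0L))
    hk_stop_invalid("path", "ATOM records before the first MODEL record")
  altloc <- substr(atoms_lines, 17, 17)
  keep <- altloc %in% c(" ", "", "A")
  atoms_lines <- atoms_lines[keep]
  frame_of <- frame_of[keep]
  frames <- sort(unique(frame_of))
  nf <- length(frames)
  parse_block <- function(bl) {
    data.frame(
      name = trimws(substr(bl, 13, 16)),
      resname = trimws(substr(bl, 18, 20)),
      chain = trimws(substr(bl, 22, 22)),
      resno = as.integer(substr(bl, 23, 26)),
      insert = trimws(substr(bl, 27, 27)),
      x = as.numeric(substr(bl, 31, 38)),
      y = as.numeric(substr(bl, 39, 46)),
      z = as.numeric(substr(bl, 47, 54)),
      stringsAsFactors = FALSE)
  }
  first <- parse_block(atoms_lines[frame_of == frames[1]])
  na <- nrow(first)
  coords <- array(NA_real_, dim = c(nf, na, 3))
  for (i in seq_len(nf)) {
    b <- parse_block(atoms_lines[frame_of == frames[i]])
    if (nrow(b) != na)
      hk_stop_invalid("path", sprintf(
        "model %d has %d atoms, expected %d", i, nrow(b), na))
    coords[i, , ] <- as.matrix(b[, c("x", "y", "z")])
  }
  if (is.null(times) || length(times) != nf) times <- seq_len(nf) - 1
  trajectory(coords = coords, times = times,
             atoms = first[, c("name", "resno", "resname", "chain", "insert")])
}

#' Read an XYZ trajectory (frame-per-block format)
#'
#' Each block is: atom count, comment line, then one `element x y z` line
#' per atom. Element symbols become atom names; residues are numbered
#' consecutively with resname `UNK` and chain `A`.
#'
#' @param path XYZ file path.
#' @param dt_ns Frame spacing used for the attached times (ns).
#' @return A [trajectory()].
#' @export
read_xyz <- function(path, dt_ns = 1) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) | seq_along(lines) %% 1 == 0]
  pos <- 1L
  frames <- list()
  while (pos <= length(lines) && nzchar(trimws(lines[pos]))) {
    n <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(n) || n < 1L)
      hk_stop_invalid("path", sprintf("bad atom count at line %d", pos))
    if (pos + 1L + n > length(lines))
      hk_stop_invalid("path", "truncated XYZ block")
    block <- lines[(pos + 2L):(pos + 1L + n)]
    tok <- strsplit(trimws(block), "\\s+")
    m <- t(vapply(tok, function(t) as.numeric(t[2:4]), numeric(3)))
    frames[[length(frames) + 1L]] <-
      list(names = vapply(tok, `[`, character(1), 1L), xyz = m)
    pos <- pos + 2L + n
    while (pos <= length(lines) && !nzchar(trimws(lines[pos]))) pos <- pos + 1L
  }
  if (!length(frames)) hk_stop_invalid("path", "no frames found")
  na <- nrow(frames[[1]]$xyz)
  coords <- array(NA_real_, dim = c(length(frames), na, 3))
  for (i in seq_along(frames)) {
    if (nrow(frames[[i]]$xyz) != na)
      hk_stop_invalid("path", "inconsistent atom count between XYZ frames")
    coords[i, , ] <- frames[[i]]$xyz
  }
  trajectory(coords = coords, times = (seq_along(frames) - 1) * dt_ns,
             atoms = data.frame(name = frames[[1]]$names,
                                resno = seq_len(na),
                                resname = "UNK", chain = "A", insert = "",
                                stringsAsFactors = FALSE))
}
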