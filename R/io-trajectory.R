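#' Read a trajectory file
#'
#' Reads DCD (binary, CHARMM-style) or XYZ (plain text) trajectories.
#' The format is chosen from the file extension. DCD frames are read with
#' \pkg{bio3d}; the header is additionally parsed here to recover the frame
#' time step and to reject truncated files instead of silently returning
#' the readable frames.
#'
#' @param path trajectory file (`.dcd` or `.xyz`).
#' @param top the matching [topology()].
#' @param dt time per frame in ps; overrides the value stored in the file
#'   header (DCD `DELTA * NSAVC`, or the `dt=` tag on XYZ comment lines).
#' @return a [trajectory()].
#' @export
read_trajectory <- function(path, top, dt = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "dcd") read_trajectory_dcd(path, top, dt)
  else if (ext == "xyz") read_trajectory_xyz(path, top, dt)
  else stop("unsupported trajectory format '.", ext, "' (use .dcd or .xyz)")
}

#' Write a trajectory file
#'
#' @param path output file (`.dcd` or `.xyz`).
#' @param traj a [trajectory()].
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(path, traj) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "dcd") write_trajectory_dcd(path, traj)
  else if (ext == "xyz") write_trajectory_xyz(path, traj)
  else stop("unsupported trajectory format '.", ext, "' (use .dcd or .xyz)")
  invisible(path)
}

read_dcd_header <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  len1 <- readBin(con, "integer", 1, size = 4)
  magic <- readChar(con, 4, useBytes = TRUE)
  if (length(len1) == 0 || len1 != 84 || magic != "CORD")
    stop("'", path, "' is not a CHARMM/X-PLOR DCD file")
  icntrl <- readBin(con, "integer", 9, size = 4)
  delta <- readBin(con, "numeric", 1, size = 4)
  icntrl2 <- readBin(con, "integer", 10, size = 4)
  readBin(con, "integer", 1, size = 4) # end marker
  len2 <- readBin(con, "integer", 1, size = 4)
  seek(con, len2, origin = "current")
  readBin(con, "integer", 1, size = 4)
  readBin(con, "integer", 1, size = 4)
  natom <- readBin(con, "integer", 1, size = 4)
  readBin(con, "integer", 1, size = 4)
  header_bytes <- seek(con)
  list(nframes = icntrl[1], nsavc = icntrl[3], delta = delta,
       natom = natom, header_bytes = header_bytes)
}

read_trajectory_dcd <- function(path, top, dt = NULL) {
  h <- read_dcd_header(path)
  if (h$natom != n_atoms(top))
    stop("DCD atom count (", h$natom, ") does not match topology (",
         n_atoms(top), ")")
  expected <- h$header_bytes + h$nframes * 3 * (8 + 4 * h$natom)
  actual <- file.info(path)$size
  if (actual < expected)
    stop("truncated DCD file '", path, "': expected ", expected,
         " bytes for ", h$nframes, " frames, found ", actual)
  xyz <- bio3d::read.dcd(path, verbose = FALSE)
  nf <- nrow(xyz)
  coords <- array(NA_real_, c(h$natom, 3, nf))
  for (f in seq_len(nf))
    coords[, , f] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
  if (is.null(dt)) {
    dt <- h$delta * max(h$nsavc, 1)
    if (!is.finite(dt) || dt <= 0) dt <- 1
  }
  trajectory(top, coords, dt)
}

write_trajectory_dcd <- function(path, traj) {
  nf <- n_frames(traj)
  natom <- n_atoms(traj$topology)
  con <- file(path, "wb")
  on.exit(close(con))
  wint <- function(x) writeBin(as.integer(x), con, size = 4)
  # header record: 'CORD' + 20-word control block (word 10 = DELTA as
  # float32, word 20 = CHARMM version tag)
  wint(84)
  writeChar("CORD", con, 4, eos = NULL)
  wint(c(nf, 0, 1, nf, 0, 0, 0, 0, 0))
  writeBin(traj$dt, con, size = 4)
  wint(c(0, 0, 0, 0, 0, 0, 0, 0, 0, 24))
  wint(84)
  # title record
  title <- sprintf("%-80s", "written by ratchetpath")
  wint(84)
  wint(1)
  writeChar(substr(title, 1, 80), con, 80, eos = NULL)
  wint(84)
  # atom-count record
  wint(4)
  wint(natom)
  wint(4)
  for (f in seq_len(nf)) {
    x <- frame_coords(traj, f)
    for (d in 1:3) {
      wint(4 * natom)
      writeBin(as.numeric(x[, d]), con, size = 4)
      wint(4 * natom)
    }
  }
  invisible(path)
}

read_trajectory_xyz <- function(path, top, dt = NULL) {
  lines <- readLines(path, warn = FALSE)
  natom <- n_atoms(top)
  frames <- list()
  i <- 1
  file_dt <- NA_real_
  while (i <= length(lines)) {
    if (trimws(lines[i]) == "") { i <- i + 1; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) stop("malformed XYZ atom-count line ", i, " in '", path, "'")
    if (n != natom)
      stop("XYZ frame atom count (", n, ") does not match topology (",
           natom, ")")
    if (i + 1 + n > length(lines))
      stop("truncated final frame in '", path, "': expected ", n,
           " atom lines after line ", i + 1)
    m <- regmatches(lines[i + 1],
                    regexec("dt=\\s*([0-9.eE+-]+)", lines[i + 1]))[[1]]
    if (length(m) == 2) file_dt <- as.numeric(m[2])
    block <- lines[(i + 2):(i + 1 + n)]
    parts <- strsplit(trimws(block), "\\s+")
    if (any(lengths(parts) < 4))
      stop("malformed XYZ atom line in frame starting at line ", i)
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (anyNA(xyz))
      stop("non-numeric coordinates in XYZ frame starting at line ", i)
    frames[[length(frames) + 1]] <- xyz
    i <- i + 2 + n
  }
  if (!length(frames)) stop("no frames in XYZ file '", path, "'")
  coords <- array(NA_real_, c(natom, 3, length(frames)))
  for (f in seq_along(frames)) coords[, , f] <- frames[[f]]
  if (is.null(dt)) dt <- if (is.finite(file_dt) && file_dt > 0) file_dt else 1
  trajectory(top, coords, dt)
}

write_trajectory_xyz <- function(path, traj) {
  natom <- n_atoms(traj$topology)
  el <- traj$topology$atoms$element
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(n_frames(traj))) {
    x <- frame_coords(traj, f)
    writeLines(as.character(natom), con)
    writeLines(sprintf("frame %d t= %.6f dt= %.6f ps", f,
                       (f - 1) * traj$dt, traj$dt), con)
    writeLines(sprintf("%-2s %14.8f %14.8f %14.8f",
                       el, x[, 1], x[, 2], x[, 3]), con)
  }
  invisible(path)
}
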