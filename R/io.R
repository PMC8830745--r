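# Structure and trajectory I/O: PDB (via bio3d) and GRO (fixed-width text).
# Binary trajectory formats are supported only through the frame-adapter
# contract of frame_stream(): any reader that yields an atoms x 3 x frames
# array can feed the analyses.

detect_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("pdb", "ent")) return("pdb")
  if (ext == "gro") return("gro")
  stopf("cannot detect format of '%s'; pass format = 'pdb' or 'gro'", path)
}

validate_pdb_lines <- function(lines) {
  rec <- substr(lines, 1, 6)
  at <- which(rec %in% c("ATOM  ", "HETATM"))
  for (i in at) {
    ln <- lines[i]
    if (nchar(ln) < 54)
      stopf("malformed PDB record at line %d: fewer than 54 columns", i)
    xyz <- c(substr(ln, 31, 38), substr(ln, 39, 46), substr(ln, 47, 54))
    if (any(is.na(suppressWarnings(as.numeric(xyz)))))
      stopf("malformed PDB record at line %d: non-numeric coordinates", i)
    if (substr(ln, 27, 27) != " ")
      stopf("insertion codes are not supported (line %d)", i)
  }
  invisible(TRUE)
}

read_gro_atoms <- function(lines, path) {
  if (length(lines) < 3) stopf("'%s': truncated GRO file", path)
  n <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(n)) stopf("'%s': malformed atom count at line 2", path)
  if (length(lines) < n + 3) stopf("'%s': expected %d atom lines", path, n)
  al <- lines[3:(2 + n)]
  resid <- suppressWarnings(as.integer(substr(al, 1, 5)))
  if (any(is.na(resid)))
    stopf("malformed GRO record at line %d", 2 + which(is.na(resid))[1])
  resname <- trimws(substr(al, 6, 10))
  name <- trimws(substr(al, 11, 15))
  id <- suppressWarnings(as.integer(substr(al, 16, 20)))
  x <- suppressWarnings(as.numeric(substr(al, 21, 28)))
  y <- suppressWarnings(as.numeric(substr(al, 29, 36)))
  z <- suppressWarnings(as.numeric(substr(al, 37, 44)))
  bad <- which(is.na(x) | is.na(y) | is.na(z))
  if (length(bad)) stopf("malformed GRO coordinates at line %d", 2 + bad[1])
  boxv <- suppressWarnings(as.numeric(strsplit(trimws(lines[n + 3]), "\\s+")[[1]]))
  if (length(boxv) < 3 || any(is.na(boxv[1:3])))
    stopf("'%s': malformed box line", path)
  list(
    atoms = data.frame(id = id, name = name, resid = resid, resname = resname,
                       chain = "A", x = x * 10, y = y * 10, z = z * 10,
                       stringsAsFactors = FALSE),
    box = boxv[1:3] * 10  # nm -> Angstrom
  )
}

#' Read a structure file into a MolecularSystem
#'
#' PDB files are parsed with \pkg{bio3d}; GRO files with a fixed-width reader
#' (coordinates converted from nm to Angstrom). The box is taken from CRYST1 /
#' the GRO box line; if a PDB has no CRYST1 record the box is derived from the
#' coordinate extent with a warning.
#'
#' @param path file path.
#' @param format \code{"auto"} (from extension), \code{"pdb"} or \code{"gro"}.
#' @return a \code{\link{molecular_system}}.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "gro")) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("file not found: '%s'", path)
  if (format == "auto") format <- detect_format(path)
  if (format == "pdb") {
    lines <- readLines(path)
    validate_pdb_lines(lines)
    pdb <- bio3d::read.pdb(path, verbose = FALSE)
    a <- pdb$atom
    box <- NULL
    cr <- grep("^CRYST1", lines, value = TRUE)
    if (length(cr)) {
      box <- as.numeric(c(substr(cr[1], 7, 15), substr(cr[1], 16, 24),
                          substr(cr[1], 25, 33)))
    }
    atoms <- data.frame(
      id = a$eleno, name = a$elety, resid = a$resno, resname = a$resid,
      chain = ifelse(is.na(a$chain) | a$chain == "", "A", a$chain),
      x = a$x, y = a$y, z = a$z, stringsAsFactors = FALSE
    )
    if (is.null(box) || any(!is.finite(box)) || any(box <= 0)) {
      warnf("'%s' has no usable CRYST1 record; box set from coordinate extent", path)
      box <- apply(atoms[, c("x", "y", "z")], 2, function(v) diff(range(v)) + 2)
    }
    return(molecular_system(atoms, box))
  }
  g <- read_gro_atoms(readLines(path), path)
  molecular_system(g$atoms, g$box)
}

fmt_pdb_atom <- function(id, name, resname, chain, resid, x, y, z, hetatm = FALSE) {
  nm <- ifelse(nchar(name) < 4, sprintf(" %-3s", name), sprintf("%-4s", name))
  sprintf("%-6s%5d %s %-4s%1s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
          ifelse(hetatm, "HETATM", "ATOM"), id %% 100000, nm,
          substr(resname, 1, 4), substr(chain, 1, 1), resid %% 10000, x, y, z)
}

#' Write a MolecularSystem (optionally multi-frame) to PDB or GRO
#'
#' Multi-frame coordinates are written as MODEL/ENDMDL blocks (PDB) or as
#' concatenated frames (GRO).
#'
#' @param system a \code{\link{molecular_system}}.
#' @param path output path.
#' @param format \code{"auto"}, \code{"pdb"} or \code{"gro"}.
#' @param frames optional n_atoms x 3 x n_frames array overriding the system
#'   coordinates (one model per frame).
#' @return invisibly, the path.
#' @export
write_structure <- function(system, path, format = c("auto", "pdb", "gro"),
                            frames = NULL) {
  format <- match.arg(format)
  if (format == "auto") format <- detect_format(path)
  a <- system$atoms
  het <- a$class != "protein"
  one_frame <- function(xyz) {
    if (format == "pdb") {
      fmt_pdb_atom(a$id, a$name, a$resname, a$chain, a$resid,
                   xyz[, 1], xyz[, 2], xyz[, 3], hetatm = het)
    } else {
      sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
              a$resid %% 100000, substr(a$resname, 1, 5), substr(a$name, 1, 5),
              a$id %% 100000, xyz[, 1] / 10, xyz[, 2] / 10, xyz[, 3] / 10)
    }
  }
  out <- character(0)
  if (format == "pdb")
    out <- sprintf("CRYST1%9.3f%9.3f%9.3f  90.00  90.00  90.00 P 1           1",
                   system$box[1], system$box[2], system$box[3])
  if (is.null(frames)) {
    if (format == "pdb") out <- c(out, one_frame(coords(system)), "END")
    else out <- c("memscape system", sprintf("%5d", nrow(a)), one_frame(coords(system)),
                  sprintf("%10.5f%10.5f%10.5f", system$box[1] / 10,
                          system$box[2] / 10, system$box[3] / 10))
  } else {
    nf <- dim(frames)[3]
    for (k in seq_len(nf)) {
      if (format == "pdb") {
        out <- c(out, sprintf("MODEL     %4d", k), one_frame(frames[, , k]), "ENDMDL")
      } else {
        out <- c(out, sprintf("memscape frame %d", k), sprintf("%5d", nrow(a)),
                 one_frame(frames[, , k]),
                 sprintf("%10.5f%10.5f%10.5f", system$box[1] / 10,
                         system$box[2] / 10, system$box[3] / 10))
      }
    }
    if (format == "pdb") out <- c(out, "END")
  }
  writeLines(out, path)
  invisible(path)
}

#' Construct a FrameStream
#'
#' The frame-stream contract used by all analyses: an ordered set of frames
#' congruent with a system's atom order, plus the save stride. Any trajectory
#' reader (including adapters for binary formats) can produce one.
#'
#' @param coords n_atoms x 3 x n_frames numeric array (Angstrom).
#' @param box per-frame box: n_frames x 3 matrix, or length-3 vector recycled.
#' @param dt time between saved frames in ps (default 200).
#' @return an object of class \code{frame_stream}.
#' @export
frame_stream <- function(coords, box, dt = 200) {
  d <- dim(coords)
  if (length(d) != 3 || d[2] != 3) stopf("coords must be n_atoms x 3 x n_frames")
  if (d[3] < 1) stopf("no frames")
  if (!is.matrix(box)) box <- matrix(box, nrow = d[3], ncol = 3, byrow = TRUE)
  if (nrow(box) != d[3]) stopf("box must have one row per frame")
  if (!is.numeric(dt) || dt <= 0) stopf("dt must be positive (ps)")
  structure(list(coords = coords, box = box, dt = dt,
                 n_frames = d[3], n_atoms = d[1]),
            class = "frame_stream")
}

#' @export
print.frame_stream <- function(x, ...) {
  cat(sprintf("<frame_stream> %d frames x %d atoms, dt = %g ps (%.1f ns total)\n",
              x$n_frames, x$n_atoms, x$dt, x$n_frames * x$dt / 1000))
  invisible(x)
}

#' Time of a frame in ps
#' @param stream a \code{frame_stream}.
#' @param k 0-based frame index (frame 0 is the initial structure).
#' @return time in ps, \code{k * dt}.
#' @export
frame_time <- function(stream, k) k * stream$dt

#' Coordinates of one frame
#' @param stream a \code{frame_stream}.
#' @param k 1-based frame number.
#' @return n_atoms x 3 matrix.
#' @export
frame_coords <- function(stream, k) stream$coords[, , k, drop = TRUE]

#' Read a trajectory into a FrameStream
#'
#' Accepts a multi-model PDB or a vector of GRO paths (one frame each).
#' Every frame must match the system's atom count.
#'
#' @param paths one multi-model PDB path, or a character vector of GRO paths.
#' @param system the \code{\link{molecular_system}} the frames belong to.
#' @param dt frame stride in ps (default 200).
#' @param format \code{"auto"}, \code{"pdb"} or \code{"gro"}.
#' @return a \code{\link{frame_stream}}.
#' @export
read_frames <- function(paths, system, dt = 200, format = c("auto", "pdb", "gro")) {
  format <- match.arg(format)
  n_atoms <- nrow(system$atoms)
  if (format == "auto") format <- detect_format(paths[1])
  if (format == "pdb") {
    pdb <- bio3d::read.pdb(paths[1], multi = TRUE, verbose = FALSE)
    xyz <- pdb$xyz
    if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
    nf <- nrow(xyz)
    if (nf < 1 || ncol(xyz) == 0) stopf("no frames in '%s'", paths[1])
    if (ncol(xyz) != 3 * n_atoms)
      stopf("frame 1 atom count (%d) does not match system (%d)",
            ncol(xyz) / 3, n_atoms)
    arr <- array(0, dim = c(n_atoms, 3, nf))
    for (k in seq_len(nf)) arr[, , k] <- matrix(xyz[k, ], ncol = 3, byrow = TRUE)
    return(frame_stream(arr, system$box, dt = dt))
  }
  if (length(paths) == 0) stopf("no frames")
  arr <- array(0, dim = c(n_atoms, 3, length(paths)))
  boxes <- matrix(0, length(paths), 3)
  for (k in seq_along(paths)) {
    g <- read_gro_atoms(readLines(paths[k]), paths[k])
    if (nrow(g$atoms) != n_atoms)
      stopf("frame %d atom count (%d) does not match system (%d)",
            k, nrow(g$atoms), n_atoms)
    arr[, , k] <- as.matrix(g$atoms[, c("x", "y", "z")])
    boxes[k, ] <- g$box
  }
  frame_stream(arr, boxes, dt = dt)
}

#' FrameStream view of a system's static coordinates
#' @param system a \code{\link{molecular_system}}.
#' @param n_frames number of (identical) frames.
#' @param dt stride in ps.
#' @return a \code{\link{frame_stream}}.
#' @export
static_stream <- function(system, n_frames = 1, dt = 200) {
  xyz <- coords(system)
  arr <- array(xyz, dim = c(nrow(xyz), 3, n_frames))
  frame_stream(arr, system$box, dt = dt)
}
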