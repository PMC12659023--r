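#' Construct a particle trajectory
#'
#' A `Trajectory` holds an ordered set of frames of particle coordinates
#' together with the periodic box and frame timing.  Coordinates are in
#' angstrom, times in picoseconds.  The `wrapped` flag states whether
#' coordinates are folded into the primary periodic image; estimators
#' apply minimum-image displacement correction when it is `TRUE`.
#'
#' @param coords numeric array of dimension `(n_frames, n_particles, 3)`,
#'   in angstrom.
#' @param box numeric length-3 vector `(Lx, Ly, Lz)` in angstrom, or an
#'   `n_frames x 3` matrix for per-frame boxes.
#' @param frame_interval time between saved frames, ps.
#' @param times optional frame times, ps; defaults to
#'   `0, frame_interval, 2*frame_interval, ...`.
#' @param wrapped logical; are coordinates wrapped into the box?
#' @return an object of class `Trajectory` with elements `coords`, `box`
#'   (matrix, one row per frame), `times`, `frame_interval`, `wrapped`.
#' @export
trajectory <- function(coords, box, frame_interval, times = NULL,
                       wrapped = TRUE) {
  if (length(dim(coords)) != 3L || dim(coords)[3] != 3L)
    stop("'coords' must be an (n_frames, n_particles, 3) array")
  nf <- dim(coords)[1]
  if (nf < 1L) stop("a Trajectory needs at least one frame")
  if (!is.matrix(box)) box <- matrix(rep(as.numeric(box), each = nf), nf, 3)
  if (nrow(box) != nf || ncol(box) != 3L)
    stop("'box' must be length 3 or an n_frames x 3 matrix")
  if (any(box <= 0)) stop("box lengths must be positive")
  if (!is.numeric(frame_interval) || frame_interval <= 0)
    stop("'frame_interval' must be a positive number of picoseconds")
  if (is.null(times)) times <- (seq_len(nf) - 1) * frame_interval
  if (length(times) != nf) stop("'times' length must equal the frame count")
  if (nf > 1L && any(diff(times) <= 0))
    stop("frame times must be strictly increasing")
  structure(
    list(coords = coords, box = box, times = as.numeric(times),
         frame_interval = as.numeric(frame_interval),
         wrapped = isTRUE(wrapped)),
    class = "Trajectory")
}

#' @export
print.Trajectory <- function(x, ...) {
  cat(sprintf(
    "Trajectory: %d frames x %d particles, dt = %g ps, box = (%g, %g, %g) A, %s\n",
    n_frames(x), n_particles(x), x$frame_interval,
    x$box[1, 1], x$box[1, 2], x$box[1, 3],
    if (x$wrapped) "wrapped" else "unwrapped"))
  invisible(x)
}

#' Number of frames / particles in a trajectory
#' @param traj a `Trajectory`.
#' @return integer count.
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

#' @rdname n_frames
#' @export
n_particles <- function(traj) dim(traj$coords)[2]

#' Construct a particle species/charge table
#'
#' The `ParticleTable` is the bridge from topology to the estimators: it
#' assigns every particle a species label and a charge in elementary
#' charges.  Water molecules are tracked through their oxygen atom and are
#' counted (not charge-weighted) by the electroosmotic-flow estimator.
#'
#' @param id integer or character particle identifiers, unique.
#' @param species character vector, each one of `"cation"`, `"anion"`,
#'   `"water_oxygen"`, `"other"`.
#' @param charge numeric charges in elementary charges; cation and anion
#'   entries must be nonzero.
#' @return a `data.frame` of class `ParticleTable`.
#' @export
particle_table <- function(id, species, charge) {
  allowed <- c("cation", "anion", "water_oxygen", "other")
  if (anyDuplicated(id)) stop("particle ids must be unique")
  species <- as.character(species)
  bad <- setdiff(unique(species), allowed)
  if (length(bad))
    stop("unknown species label(s) ", paste(sQuote(bad), collapse = ", "),
         "; allowed: ", paste(allowed, collapse = ", "))
  charge <- as.numeric(charge)
  if (length(charge) == 1L) charge <- rep(charge, length(id))
  if (length(species) == 1L) species <- rep(species, length(id))
  if (anyNA(charge)) stop("charges must be numeric")
  if (any(charge[species %in% c("cation", "anion")] == 0))
    stop("cation and anion charges must be nonzero")
  if (!(length(id) == length(species) && length(id) == length(charge)))
    stop("id, species and charge must have equal length")
  structure(data.frame(id = id, species = species, charge = charge,
                       stringsAsFactors = FALSE),
            class = c("ParticleTable", "data.frame"))
}

#' Run metadata for a non-equilibrium trajectory
#'
#' @param voltage applied voltage, mV (drop along +z).
#' @param discard initial trajectory time to exclude from analysis, ps.
#' @param label free-form force-field / system tag.
#' @return a list of class `RunMeta`.
#' @export
run_meta <- function(voltage, discard = 0, label = "") {
  if (discard < 0) stop("'discard' must be >= 0 ps")
  structure(list(voltage = as.numeric(voltage), discard = as.numeric(discard),
                 label = as.character(label)),
            class = "RunMeta")
}

#' Read a species/charge table
#'
#' Expects a tab-separated file with header columns `id`, `species`,
#' `charge`.  Species labels are validated against the allowed set.
#'
#' @param path file path.
#' @return a `ParticleTable`.
#' @export
read_particle_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "species", "charge")
  if (!all(need %in% names(df)))
    stop("particle table must have header columns: ",
         paste(need, collapse = ", "))
  suppressWarnings(ch <- as.numeric(df$charge))
  if (anyNA(ch)) stop("non-numeric charge in particle table: ", path)
  particle_table(df$id, df$species, ch)
}

#' Write a species/charge table
#' @param particles a `ParticleTable`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_particle_table <- function(particles, path) {
  utils::write.table(as.data.frame(particles)[c("id", "species", "charge")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a trajectory file
#'
#' Supported dialects:
#' \describe{
#'   \item{`table`}{plain TSV fixture dialect: comment header lines
#'     `# box Lx Ly Lz`, `# frame_interval dt`, `# wrapped true|false`,
#'     then a column header `frame id x y z` and one row per particle per
#'     frame.}
#'   \item{`dcd`}{CHARMM/NAMD binary DCD with the unit-cell flag set;
#'     single precision, X-PLOR or CHARMM unit-cell record.}
#' }
#' XTC is not supported: its compressed-coordinate codec has no reader in
#' this toolchain, and reimplementing it is out of scope.
#'
#' @param path file path.
#' @param format one of `"table"`, `"dcd"` (`"xtc"` raises an error).
#' @param frame_interval override / supply the frame interval, ps.
#' @param wrapped override the wrapped flag.
#' @return a `Trajectory`.
#' @export
read_trajectory <- function(path, format = c("table", "dcd", "xtc"),
                            frame_interval = NULL, wrapped = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  traj <- switch(format,
    table = read_trajectory_table(path),
    dcd   = read_trajectory_dcd(path),
    xtc   = stop("XTC is not supported (no decoder for the compressed-",
                 "coordinate codec); convert to DCD or the table dialect"))
  if (!is.null(frame_interval)) {
    traj$frame_interval <- as.numeric(frame_interval)
    traj$times <- (seq_len(n_frames(traj)) - 1) * traj$frame_interval
  }
  if (!is.null(wrapped)) traj$wrapped <- isTRUE(wrapped)
  traj
}

#' Write a trajectory file
#'
#' Round trip through [read_trajectory()] preserves coordinates exactly for
#' `table` (full double precision printed) and to single-float precision
#' for `dcd`.
#'
#' @param traj a `Trajectory`.
#' @param path output file path.
#' @param format `"table"` or `"dcd"`.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, format = c("table", "dcd", "xtc")) {
  format <- match.arg(format)
  stopifnot(inherits(traj, "Trajectory"))
  if (n_frames(traj) < 1L) stop("trajectory must have at least one frame")
  switch(format,
    table = write_trajectory_table(traj, path),
    dcd   = write_trajectory_dcd(traj, path),
    xtc   = stop("XTC writing is not supported"))
  invisible(path)
}

## ---- plain-table dialect ---------------------------------------------------

read_trajectory_table <- function(path) {
  lines <- readLines(path, n = 50L)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) {
    m <- grep(paste0("^#\\s*", key, "\\b"), hdr, value = TRUE)
    if (!length(m)) return(NULL)
    strsplit(trimws(sub(paste0("^#\\s*", key), "", m[1])), "\\s+")[[1]]
  }
  box <- suppressWarnings(as.numeric(get("box")))
  if (length(box) != 3L || anyNA(box))
    stop("table trajectory ", path, ": missing/invalid '# box Lx Ly Lz' header")
  fi <- suppressWarnings(as.numeric(get("frame_interval")))
  if (length(fi) != 1L || is.na(fi))
    stop("table trajectory ", path, ": missing '# frame_interval dt' header")
  wr <- get("wrapped")
  wrapped <- if (is.null(wr)) TRUE else tolower(wr[1]) %in% c("true", "1", "yes")
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("frame", "id", "x", "y", "z")
  if (!all(need %in% names(df)))
    stop("table trajectory must have columns: ", paste(need, collapse = ", "))
  frames <- sort(unique(df$frame))
  ids <- sort(unique(df$id))
  np <- length(ids); nf <- length(frames)
  counts <- table(df$frame)
  if (length(unique(as.integer(counts))) != 1L || any(counts != np))
    stop("inconsistent particle count across frames in ", path)
  coords <- array(NA_real_, c(nf, np, 3))
  fidx <- match(df$frame, frames); pidx <- match(df$id, ids)
  coords[cbind(fidx, pidx, 1L)] <- df$x
  coords[cbind(fidx, pidx, 2L)] <- df$y
  coords[cbind(fidx, pidx, 3L)] <- df$z
  if (anyNA(coords)) stop("missing particle rows in ", path)
  trajectory(coords, box, fi, wrapped = wrapped)
}

write_trajectory_table <- function(traj, path) {
  nf <- n_frames(traj); np <- n_particles(traj)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(
    sprintf("# box %.17g %.17g %.17g",
            traj$box[1, 1], traj$box[1, 2], traj$box[1, 3]),
    sprintf("# frame_interval %.17g", traj$frame_interval),
    sprintf("# wrapped %s", tolower(as.character(traj$wrapped)))), con)
  df <- data.frame(
    frame = rep(seq_len(nf) - 1L, each = np),
    id = rep(seq_len(np), times = nf),
    x = as.vector(t(traj$coords[, , 1, drop = TRUE])),
    y = as.vector(t(traj$coords[, , 2, drop = TRUE])),
    z = as.vector(t(traj$coords[, , 3, drop = TRUE])))
  ## t() above degenerates for single-frame arrays; rebuild explicitly
  if (nf == 1L) {
    df$x <- traj$coords[1, , 1]; df$y <- traj$coords[1, , 2]
    df$z <- traj$coords[1, , 3]
  }
  utils::write.table(format(df, digits = 17, scientific = FALSE, trim = TRUE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

## ---- DCD binary dialect ----------------------------------------------------
## CHARMM/NAMD DCD: Fortran unformatted records. Header record 'CORD' +
## 20 int32 control block (icntrl), title record, natom record, then per
## frame a 6-double unit-cell record (when icntrl[11] == 1) and three
## float32 records (x, y, z). We write NAMD-style files and read files
## with that layout in either endianness.

read_trajectory_dcd <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  endian <- .Platform$endian
  at_eof <- -1L
  rec_len <- function() {
    n <- readBin(con, "integer", 1, size = 4, endian = endian)
    if (!length(n)) at_eof else n
  }
  first <- rec_len()
  if (first == at_eof) stop("DCD parse error in ", path, ": empty file")
  if (first != 84L) {          # try the other byte order
    endian <- if (endian == "little") "big" else "little"
    seek(con, 0)
    first <- rec_len()
    if (first == at_eof || first != 84L)
      stop("DCD parse error in ", path, ": bad header record length at byte 0")
  }
  magic <- readChar(con, 4, useBytes = TRUE)
  if (magic != "CORD") stop("DCD parse error in ", path, ": magic != CORD")
  icntrl <- readBin(con, "integer", 20, size = 4, endian = endian)
  if (rec_len() != 84L) stop("DCD parse error in ", path, ": header trailer")
  nframes_hdr <- icntrl[1]
  has_cell <- icntrl[11] == 1L
  ## NAMD stores delta as float32 in icntrl[10]
  delta <- readBin(writeBin(icntrl[10], raw(), size = 4, endian = endian),
                   "numeric", 1, size = 4, endian = endian)
  tlen <- rec_len()
  if (tlen == at_eof) stop("DCD parse error in ", path, ": truncated titles")
  invisible(readBin(con, "raw", tlen))
  if (rec_len() != tlen) stop("DCD parse error in ", path, ": title trailer")
  if (rec_len() != 4L) stop("DCD parse error in ", path, ": natom record")
  natom <- readBin(con, "integer", 1, size = 4, endian = endian)
  if (rec_len() != 4L) stop("DCD parse error in ", path, ": natom trailer")
  frames <- list(); boxes <- list(); k <- 0L
  repeat {
    n <- rec_len()
    if (n == at_eof) break
    k <- k + 1L
    if (has_cell) {
      if (n != 48L) stop("DCD parse error in ", path, ": frame ", k,
                         " unit-cell record length ", n)
      cell <- readBin(con, "numeric", 6, size = 8, endian = endian)
      if (rec_len() != 48L) stop("DCD parse error in ", path,
                                 ": frame ", k, " cell trailer")
      boxes[[k]] <- cell[c(1, 3, 6)]   # a, b, c (X-PLOR order a, g, b, b, a, c)
      n <- rec_len()
      if (n == at_eof) stop("DCD parse error in ", path,
                           ": truncated at frame ", k)
    }
    if (n != 4L * natom)
      stop("DCD parse error in ", path, ": frame ", k, " x-record length ", n)
    xyz <- matrix(NA_real_, natom, 3)
    for (d in 1:3) {
      if (d > 1 && !identical(rec_len(), 4L * natom))
        stop("DCD parse error in ", path, ": frame ", k, " record ", d)
      vals <- readBin(con, "numeric", natom, size = 4, endian = endian)
      if (length(vals) != natom)
        stop("DCD parse error in ", path, ": frame ", k,
             " truncated coordinate record ", d)
      xyz[, d] <- vals
      if (!identical(rec_len(), 4L * natom))
        stop("DCD parse error in ", path, ": frame ", k, " trailer ", d)
    }
    frames[[k]] <- xyz
    if (!has_cell) boxes[[k]] <- c(NA_real_, NA_real_, NA_real_)
  }
  if (!k) stop("DCD parse error in ", path, ": no frames")
  if (nframes_hdr > 0L && k != nframes_hdr)
    warning("DCD ", path, ": header declares ", nframes_hdr,
            " frames, found ", k)
  coords <- array(NA_real_, c(k, natom, 3))
  for (i in seq_len(k)) coords[i, , ] <- frames[[i]]
  box <- do.call(rbind, boxes)
  if (anyNA(box)) stop("DCD ", path, " has no unit-cell records; ",
                       "box dimensions are required")
  ## frame interval in ps: delta is in AKMA time units (48.88821 fs)
  fi <- if (is.finite(delta) && delta > 0)
    delta * icntrl[3] * 0.0488882129 else 1
  trajectory(coords, box, fi)
}

write_trajectory_dcd <- function(traj, path) {
  con <- file(path, "wb"); on.exit(close(con))
  nf <- n_frames(traj); np <- n_particles(traj)
  w_rec <- function(payload_writer, nbytes) {
    writeBin(as.integer(nbytes), con, size = 4)
    payload_writer()
    writeBin(as.integer(nbytes), con, size = 4)
  }
  ## frame interval ps -> AKMA units, stored as float32 bits in icntrl[10]
  delta <- traj$frame_interval / 0.0488882129
  delta_bits <- readBin(writeBin(as.numeric(delta), raw(), size = 4),
                        "integer", 1, size = 4)
  icntrl <- integer(20)
  icntrl[1] <- nf; icntrl[2] <- 0L; icntrl[3] <- 1L; icntrl[4] <- nf
  icntrl[10] <- delta_bits; icntrl[11] <- 1L; icntrl[20] <- 24L
  w_rec(function() {
    writeChar("CORD", con, 4, eos = NULL)
    writeBin(icntrl, con, size = 4)
  }, 84L)
  title <- sprintf("%-80s", "poreflux synthetic trajectory")
  w_rec(function() {
    writeBin(1L, con, size = 4)
    writeChar(title, con, 80, eos = NULL)
  }, 84L)
  w_rec(function() writeBin(as.integer(np), con, size = 4), 4L)
  for (i in seq_len(nf)) {
    b <- traj$box[i, ]
    w_rec(function() writeBin(as.numeric(c(b[1], 90, b[2], 90, 90, b[3])),
                              con, size = 8), 48L)
    for (d in 1:3)
      w_rec(function() writeBin(as.numeric(traj$coords[i, , d]),
                                con, size = 4), 4L * np)
  }
  path
}
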