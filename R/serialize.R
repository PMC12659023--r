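#' Serialise / read back a cylindrical density map
#'
#' Plain TSV with commented header lines (`# axis x0 y0`,
#' `# species ...`) and columns `r_lo r_hi z_lo z_hi value volume`;
#' missing bins carry `NA` values.  Round trip preserves the map.
#'
#' @param map a `CylMap`.
#' @param path file path.
#' @return `path` invisibly (`write_cylmap`); a `CylMap` (`read_cylmap`).
#' @export
write_cylmap <- function(map, path) {
  stopifnot(inherits(map, "CylMap"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(sprintf("# axis %.17g %.17g", map$axis[1], map$axis[2]),
               sprintf("# species %s", map$species)), con)
  nr <- length(map$r_edges) - 1L; nz <- length(map$z_edges) - 1L
  df <- data.frame(
    r_lo = rep(map$r_edges[-(nr + 1L)], times = nz),
    r_hi = rep(map$r_edges[-1L], times = nz),
    z_lo = rep(map$z_edges[-(nz + 1L)], each = nr),
    z_hi = rep(map$z_edges[-1L], each = nr),
    value = as.vector(map$values),
    volume = as.vector(map$volume))
  utils::write.table(format(df, digits = 17, scientific = FALSE,
                            trim = TRUE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' @rdname write_cylmap
#' @export
read_cylmap <- function(path) {
  hdr <- grep("^#", readLines(path, n = 10L), value = TRUE)
  ax <- grep("^#\\s*axis", hdr, value = TRUE)
  axis <- if (length(ax))
    as.numeric(strsplit(trimws(sub("^#\\s*axis", "", ax[1])), "\\s+")[[1]])
  else c(NA_real_, NA_real_)
  spl <- grep("^#\\s*species", hdr, value = TRUE)
  species <- if (length(spl)) trimws(sub("^#\\s*species", "", spl[1]))
  else "unknown"
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE)
  suppressWarnings({
    df$value <- as.numeric(df$value)
    df$volume <- as.numeric(df$volume)
  })
  r_edges <- sort(unique(c(df$r_lo, df$r_hi)))
  z_edges <- sort(unique(c(df$z_lo, df$z_hi)))
  nr <- length(r_edges) - 1L; nz <- length(z_edges) - 1L
  ri <- match(df$r_lo, r_edges[-(nr + 1L)])
  zi <- match(df$z_lo, z_edges[-(nz + 1L)])
  values <- matrix(NA_real_, nr, nz)
  volume <- matrix(0, nr, nz)
  values[cbind(ri, zi)] <- df$value
  volume[cbind(ri, zi)] <- df$volume
  structure(list(values = values, volume = volume, r_edges = r_edges,
                 z_edges = z_edges, axis = axis, species = species),
            class = "CylMap")
}

#' Read a synthetic-spec file
#'
#' TSV of species rows (`name count charge D` plus `v` or `mu`) with
#' commented scalar headers: `# box Lx Ly Lz`, `# frame_interval dt`,
#' `# duration T`, `# seed n`, optional `# field E` (mobility mode) and
#' `# profile type [r0 width | rate]`.
#'
#' @param path spec file.
#' @return a `SyntheticSpec`.
#' @export
read_synthetic_spec <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) {
    m <- grep(paste0("^#\\s*", key, "\\b"), hdr, value = TRUE)
    if (!length(m)) return(NULL)
    strsplit(trimws(sub(paste0("^#\\s*", key), "", m[1])), "\\s+")[[1]]
  }
  num <- function(key) suppressWarnings(as.numeric(get(key)))
  box <- num("box")
  if (length(box) != 3L || anyNA(box))
    stop("spec ", path, ": missing '# box Lx Ly Lz'")
  fi <- num("frame_interval"); dur <- num("duration")
  if (!length(fi) || !length(dur))
    stop("spec ", path, ": need '# frame_interval' and '# duration'")
  seed <- num("seed"); if (!length(seed)) seed <- 1
  field <- num("field"); if (!length(field)) field <- NULL
  pr <- get("profile")
  profile <- if (is.null(pr)) radial_profile("uniform") else {
    pars <- suppressWarnings(as.numeric(pr[-1]))
    switch(pr[1],
      uniform = radial_profile("uniform"),
      annular_gaussian = radial_profile("annular_gaussian",
                                        r0 = pars[1], width = pars[2]),
      wall_accumulated = radial_profile("wall_accumulated", rate = pars[1]),
      stop("unknown profile type ", pr[1]))
  }
  sp <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE)
  synthetic_spec(box, sp, frame_interval = fi, duration = dur,
                 field = field, profile = profile, seed = as.integer(seed))
}
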