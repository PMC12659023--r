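#' Time-averaged 3-D density grid
#'
#' Divides the box into cubic cells (default edge 1 angstrom) and
#' accumulates the time-averaged number density of the selected species.
#' Conservation holds exactly: the sum of density times cell volume
#' equals the mean per-frame particle count of the selection.
#'
#' @param traj a `Trajectory`.
#' @param particles a `ParticleTable`.
#' @param species selection: one of `"cation"`, `"anion"`,
#'   `"water_oxygen"`, `"other"`, or `"all"`.
#' @param cell cubic cell edge, angstrom.
#' @param wrap fold coordinates into the box before binning?  With
#'   `wrap = FALSE` a particle outside the grid raises an error naming
#'   the frame and particle.
#' @return a `DensityGrid3D`: list with `density` (3-D array,
#'   particles/angstrom^3), `cell`, `origin`, `box`, `dims`,
#'   `n_frames`, `species`.
#' @export
bin_density <- function(traj, particles, species = "all", cell = 1,
                        wrap = TRUE) {
  stopifnot(inherits(traj, "Trajectory"), inherits(particles, "ParticleTable"))
  if (cell <= 0) stop("cell edge must be positive")
  if (nrow(particles) != n_particles(traj))
    stop("particle table / trajectory size mismatch")
  sel <- if (identical(species, "all")) seq_len(nrow(particles))
         else which(particles$species == species)
  if (!length(sel)) stop("no particles of species '", species, "'")
  box <- traj$box[1, ]
  dims <- pmax(1L, as.integer(ceiling(box / cell - 1e-9)))
  counts <- array(0, dims)
  nf <- n_frames(traj)
  for (i in seq_len(nf)) {
    xyz <- traj$coords[i, sel, , drop = FALSE]
    dim(xyz) <- c(length(sel), 3L)
    if (wrap) for (d in 1:3) xyz[, d] <- xyz[, d] %% box[d]
    idx <- floor(xyz / cell) + 1L
    out <- idx < 1L | t(t(idx) > dims)
    if (any(out)) {
      bad <- which(rowSums(out) > 0)[1]
      stop("particle ", particles$id[sel[bad]], " outside the grid in frame ",
           i, " (enable wrap or enlarge the grid)")
    }
    flat <- (idx[, 3] - 1L) * dims[1] * dims[2] +
      (idx[, 2] - 1L) * dims[1] + idx[, 1]
    tb <- tabulate(flat, nbins = prod(dims))
    counts <- counts + array(tb, dims)
  }
  structure(list(density = counts / (nf * cell^3), cell = cell,
                 origin = c(0, 0, 0), box = box, dims = dims,
                 n_frames = nf, species = species),
            class = "DensityGrid3D")
}

#' Angular average of a 3-D grid into an (r, z) map
#'
#' Converts the Cartesian grid to cylindrical coordinates about a z-
#' aligned axis and averages out the angle: each (r, z) value is the
#' volume-weighted mean density of the Cartesian cells whose (sub)cell
#' centres fall in that annulus.  Since cells have equal volume this is
#' the arithmetic mean of contributing cell densities, so a uniform
#' input maps to a uniform output exactly.  Each bin also records its
#' contributing volume (number of cells times cell volume), which makes
#' mass conservation through the transform exact whenever `r_max` covers
#' the whole lateral grid (i.e. reaches the grid corners); with the
#' default inscribed-circle `r_max` the corner cells are outside the
#' map.  Empty annuli (no contributing cells) are `NA`, not zero.
#'
#' @param grid a `DensityGrid3D`.
#' @param axis length-2 `(x0, y0)` of the cylinder axis, angstrom;
#'   default the box centre.
#' @param r_bin,z_bin bin widths, angstrom.
#' @param r_max maximum radius, angstrom; default the largest radius
#'   fully inside the lateral box.
#' @param subdivide odd integer; split each Cartesian cell into
#'   `subdivide^2` lateral subcells before assignment, reducing
#'   discretisation error of the annular volumes.
#' @return a `CylMap`: list with `values` (matrix r x z, possibly `NA`),
#'   `volume` (contributing volume per bin), `r_edges`, `z_edges`,
#'   `axis`, `species`.
#' @export
to_cylindrical <- function(grid, axis = NULL, r_bin = 1, z_bin = 1,
                           r_max = NULL, subdivide = 1L) {
  stopifnot(inherits(grid, "DensityGrid3D"))
  if (is.null(axis)) axis <- grid$box[1:2] / 2
  if (axis[1] < 0 || axis[1] > grid$box[1] ||
      axis[2] < 0 || axis[2] > grid$box[2])
    stop("axis must lie inside the grid footprint")
  if (is.null(r_max))
    r_max <- min(axis[1], grid$box[1] - axis[1],
                 axis[2], grid$box[2] - axis[2])
  subdivide <- as.integer(subdivide)
  if (subdivide < 1L || subdivide %% 2L == 0L)
    stop("'subdivide' must be an odd positive integer")
  cellv <- grid$cell^3
  nx <- grid$dims[1]; ny <- grid$dims[2]; nz <- grid$dims[3]
  r_edges <- seq(0, r_max, by = r_bin)
  if (max(r_edges) < r_max) r_edges <- c(r_edges, max(r_edges) + r_bin)
  z_edges <- seq(0, nz * grid$cell, by = z_bin)
  if (max(z_edges) < nz * grid$cell)
    z_edges <- c(z_edges, max(z_edges) + z_bin)
  nr <- length(r_edges) - 1L; nzb <- length(z_edges) - 1L
  ## lateral subcell centre offsets within a cell
  off <- (seq_len(subdivide) - 0.5) / subdivide * grid$cell
  sub <- expand.grid(dx = off, dy = off)
  xc <- (seq_len(nx) - 1L) * grid$cell
  yc <- (seq_len(ny) - 1L) * grid$cell
  ## radial bin of every lateral (sub)cell, averaged over subcells via
  ## accumulation; lateral index -> vector of (r-bin, weight) pairs
  sum_v <- matrix(0, nr, nzb)    # contributing volume
  sum_d <- matrix(0, nr, nzb)    # density * volume
  zc_centers <- (seq_len(nz) - 0.5) * grid$cell
  zbin <- findInterval(zc_centers, z_edges, rightmost.closed = TRUE)
  zbin[zbin < 1L | zbin > nzb] <- NA_integer_
  subv <- cellv / nrow(sub)
  for (s in seq_len(nrow(sub))) {
    X <- outer(xc + sub$dx[s] - axis[1], rep(1, ny))
    Y <- outer(rep(1, nx), yc + sub$dy[s] - axis[2])
    R <- sqrt(X^2 + Y^2)
    rbin <- findInterval(R, r_edges, rightmost.closed = TRUE)
    rbin[R >= max(r_edges)] <- NA_integer_
    rb <- as.vector(rbin)      # length nx*ny, column-major
    ok_lat <- which(!is.na(rb))
    ## accumulate over z slabs
    for (k in seq_len(nz)) {
      zb <- zbin[k]
      if (is.na(zb)) next
      dslab <- grid$density[, , k]
      dv <- as.vector(dslab)[ok_lat]
      ii <- rb[ok_lat]
      sum_v[, zb] <- sum_v[, zb] + tabulate(ii, nbins = nr) * subv
      sum_d[, zb] <- sum_d[, zb] +
        as.vector(tapply2(dv * subv, ii, nr))
    }
  }
  vals <- sum_d / sum_v
  vals[sum_v == 0] <- NA_real_
  structure(list(values = vals, volume = sum_v, r_edges = r_edges,
                 z_edges = z_edges, axis = axis, species = grid$species),
            class = "CylMap")
}

## fast grouped sum into exactly nbins slots
tapply2 <- function(x, g, nbins) {
  out <- numeric(nbins)
  s <- rowsum(x, g)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

#' Region of interest on an (r, z) map
#'
#' @param r_range length-2 radial range, angstrom (r >= 0).
#' @param z_range length-2 axial range, angstrom.
#' @return list of class `ROI`.
#' @export
roi <- function(r_range, z_range) {
  if (diff(r_range) <= 0 || diff(z_range) <= 0 || r_range[1] < 0)
    stop("ROI ranges must be positive-length and r >= 0")
  structure(list(r_range = as.numeric(r_range),
                 z_range = as.numeric(z_range)), class = "ROI")
}

roi_cells <- function(map, region) {
  rc <- (map$r_edges[-1] + map$r_edges[-length(map$r_edges)]) / 2
  zc <- (map$z_edges[-1] + map$z_edges[-length(map$z_edges)]) / 2
  list(r = which(rc >= region$r_range[1] & rc <= region$r_range[2]),
       z = which(zc >= region$z_range[1] & zc <= region$z_range[2]))
}

#' L2 distance between two (r, z) density maps over an ROI
#'
#' Discrete form of
#' \deqn{d_{ij}^2 = \int_{ROI} [f_i(r,z) - f_j(r,z)]^2 \, dr\, dz}
#' summing `(f_i - f_j)^2 * dr * dz` over ROI cells (cells whose centre
#' lies in the ROI).  The (r, z) map stands for its mirrored display
#' (r and -r), and an ROI stated as a full width (e.g. 40 A across,
#' r in [0, 20]) integrates over both signed halves: the area element is
#' `2 * dr * dz`, so two maps differing by a constant c over a
#' 40 x 70 A ROI have d = c * sqrt(2800).  Cells missing in either map
#' are excluded pairwise, removing their area from the integral.  Maps
#' must share bin geometry; no implicit regridding.
#'
#' @param f_i,f_j `CylMaps` with identical `r_edges`/`z_edges`.
#' @param region an [roi()]; default the full map.
#' @param mirror count the mirrored (-r) half of the display in the
#'   integral (default `TRUE`, matching the full-width ROI convention).
#' @return the distance (density times angstrom units).
#' @export
map_distance <- function(f_i, f_j, region = NULL, mirror = TRUE) {
  stopifnot(inherits(f_i, "CylMap"), inherits(f_j, "CylMap"))
  if (!isTRUE(all.equal(f_i$r_edges, f_j$r_edges)) ||
      !isTRUE(all.equal(f_i$z_edges, f_j$z_edges)))
    stop("maps have mismatched bin geometry; no implicit regridding")
  if (is.null(region))
    region <- roi(range(f_i$r_edges), range(f_i$z_edges))
  cells <- roi_cells(f_i, region)
  if (!length(cells$r) || !length(cells$z)) stop("ROI contains no cells")
  a <- f_i$values[cells$r, cells$z, drop = FALSE]
  b <- f_j$values[cells$r, cells$z, drop = FALSE]
  dr <- diff(f_i$r_edges)[cells$r]
  dz <- diff(f_i$z_edges)[cells$z]
  area <- outer(dr, dz) * (if (mirror) 2 else 1)
  d2 <- (a - b)^2 * area
  sqrt(sum(d2, na.rm = TRUE))
}

#' Intra- and inter-group map-distance statistics
#'
#' All-against-all comparison of replicate density maps: within each
#' group every unordered pair is compared (n(n-1)/2 comparisons for n
#' replicas), and across each group pair every cross combination
#' (n_a * n_b comparisons).  Reported per comparison set: mean distance,
#' its error (standard deviation of the pair distances divided by the
#' square root of the number of comparisons), and the comparison count.
#'
#' @param groups named list; each element a list of `CylMap`s sharing
#'   bin geometry.
#' @param region an [roi()] applied to every distance.
#' @return a `data.frame` of class `GroupComparison` with columns
#'   `group_a`, `group_b`, `kind` (`intra`/`inter`), `mean`, `error`,
#'   `n_comparisons`.
#' @export
group_compare <- function(groups, region = NULL) {
  stopifnot(is.list(groups), length(groups) >= 1L,
            !is.null(names(groups)), all(nzchar(names(groups))))
  gn <- names(groups)
  rows <- list()
  stat <- function(d) c(mean(d), stats::sd(d) / sqrt(length(d)), length(d))
  for (i in seq_along(groups)) {
    maps <- groups[[i]]
    if (length(maps) >= 2L) {
      pr <- utils::combn(length(maps), 2)
      d <- apply(pr, 2, function(p)
        map_distance(maps[[p[1]]], maps[[p[2]]], region))
      s <- stat(d)
      rows[[length(rows) + 1L]] <- data.frame(
        group_a = gn[i], group_b = gn[i], kind = "intra",
        mean = s[1], error = s[2], n_comparisons = as.integer(s[3]))
    }
    if (i < length(groups)) for (j in (i + 1L):length(groups)) {
      other <- groups[[j]]
      d <- as.vector(outer(seq_along(maps), seq_along(other),
        Vectorize(function(a, b)
          map_distance(maps[[a]], other[[b]], region))))
      s <- stat(d)
      rows[[length(rows) + 1L]] <- data.frame(
        group_a = gn[i], group_b = gn[j], kind = "inter",
        mean = s[1], error = s[2], n_comparisons = as.integer(s[3]))
    }
  }
  out <- do.call(rbind, rows)
  structure(out, class = c("GroupComparison", "data.frame"))
}

#' Relative-concentration normalisation of a map
#'
#' Divides a map by a bulk (reference) density so that distances are
#' unit-stable across species: values become local density over bulk
#' density.
#'
#' @param map a `CylMap`.
#' @param bulk reference density in the same units as the map values.
#' @return the normalised `CylMap`.
#' @export
normalize_map <- function(map, bulk) {
  stopifnot(inherits(map, "CylMap"), bulk > 0)
  map$values <- map$values / bulk
  map
}
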