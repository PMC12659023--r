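#' Windowed ionic current from charge-weighted axial displacements
#'
#' Implements the charge-displacement estimator: the average current over
#' the window \eqn{[t, t+\tau]} is
#' \deqn{I(t) = \frac{1}{\tau L_z} \sum_i q_i \, [z_i(t+\tau) - z_i(t)]}
#' with the sum over the selected particles.  For wrapped trajectories,
#' minimum-image correction is applied per consecutive saved frame pair
#' and the corrected displacements are summed to span tau, which is
#' robust to fast particles crossing the boundary repeatedly.  Values are
#' converted from e/ps to nA.
#'
#' By default only ions (cation/anion) enter the sum, matching the usual
#' restriction of the estimator to the mobile charge carriers; set
#' `include_other = TRUE` to add charged `other` particles.
#'
#' @param traj a `Trajectory`.
#' @param particles a `ParticleTable` matching the trajectory column
#'   order.
#' @param tau window length, ps; must be a positive integer multiple of
#'   the frame interval.  Windows are consecutive and non-overlapping.
#' @param species_filter one of `"all"`, `"cation"`, `"anion"`.
#' @param include_other when `species_filter = "all"`, also sum charged
#'   `other` particles.
#' @return a `CurrentTrace`: data.frame with `time` (window start, ps)
#'   and `value` (nA), attributes `tau`, `species`, `units`.
#' @export
windowed_current <- function(traj, particles, tau = traj$frame_interval,
                             species_filter = c("all", "cation", "anion"),
                             include_other = FALSE) {
  species_filter <- match.arg(species_filter)
  check_traj_particles(traj, particles)
  sel <- switch(species_filter,
    all = particles$species %in%
      c("cation", "anion", if (include_other) "other"),
    cation = particles$species == "cation",
    anion = particles$species == "anion")
  if (!any(sel))
    warning("no particles match species filter '", species_filter,
            "'; trace is identically zero")
  dz <- window_displacements(traj, tau, which(sel))
  q <- particles$charge[sel]
  Lz <- traj$box[1, 3]
  val <- as.vector(dz %*% q) / (tau * Lz) * E_PER_PS_TO_NA
  current_trace(attr(dz, "times"), val, tau, species_filter, "nA")
}

#' Species-resolved currents
#'
#' Computes the total, cationic and anionic current traces; the
#' per-window identity `all = cation + anion (+ other)` holds to float
#' round-off by construction.
#'
#' @inheritParams windowed_current
#' @return named list of `CurrentTrace`: `all`, `cation`, `anion`.
#' @export
species_currents <- function(traj, particles, tau = traj$frame_interval,
                             include_other = FALSE) {
  list(
    all = windowed_current(traj, particles, tau, "all",
                           include_other = include_other),
    cation = suppressWarnings(
      windowed_current(traj, particles, tau, "cation")),
    anion = suppressWarnings(
      windowed_current(traj, particles, tau, "anion")))
}

#' Electroosmotic water flux
#'
#' Same windowed displacement estimator as [windowed_current()] but
#' summed over water-oxygen particles with unit weight (molecules are
#' counted, not charge-weighted):
#' \deqn{\Phi(t) = \frac{1}{\tau L_z} \sum_{\mathrm{O}} [z(t+\tau) - z(t)]}
#' reported in molecules/ns.  Positive flux is net water motion toward
#' +z.
#'
#' @inheritParams windowed_current
#' @return a `CurrentTrace` with units `molecules/ns`, species `water`.
#' @export
water_flux <- function(traj, particles, tau = traj$frame_interval) {
  check_traj_particles(traj, particles)
  sel <- which(particles$species == "water_oxygen")
  if (!length(sel)) stop("no water_oxygen particles in the table")
  dz <- window_displacements(traj, tau, sel)
  Lz <- traj$box[1, 3]
  val <- rowSums(dz) / (tau * Lz) * PER_PS_TO_PER_NS
  current_trace(attr(dz, "times"), val, tau, "water", "molecules/ns")
}

current_trace <- function(times, values, tau, species, units) {
  structure(data.frame(time = times, value = values),
            tau = tau, species = species, units = units,
            class = c("CurrentTrace", "data.frame"))
}

check_traj_particles <- function(traj, particles) {
  stopifnot(inherits(traj, "Trajectory"), inherits(particles, "ParticleTable"))
  if (nrow(particles) != n_particles(traj))
    stop("particle table has ", nrow(particles), " rows but trajectory has ",
         n_particles(traj), " particles")
  if (n_frames(traj) < 2L)
    stop("flux estimation needs at least 2 frames")
}

## per-window z displacements for the selected particle indices:
## matrix (n_windows x n_selected), minimum-image corrected per frame
## pair when the trajectory is wrapped, then summed over the stride.
window_displacements <- function(traj, tau, idx) {
  fi <- traj$frame_interval
  stride <- tau / fi
  if (abs(stride - round(stride)) > 1e-9 || stride < 1)
    stop("tau = ", tau, " ps is not a positive integer multiple of the ",
         "frame interval (", fi, " ps)")
  stride <- as.integer(round(stride))
  z <- traj$coords[, idx, 3, drop = FALSE]
  dim(z) <- dim(z)[1:2]
  dz <- z[-1, , drop = FALSE] - z[-nrow(z), , drop = FALSE]
  if (traj$wrapped) {
    Lz <- traj$box[1, 3]
    dz <- dz - Lz * round(dz / Lz)
    if (any(abs(abs(dz) - Lz / 2) < 1e-12))
      stop("a minimum-image-corrected displacement equals Lz/2 exactly; ",
           "the jump direction is ambiguous - save frames more densely")
  }
  nwin <- nrow(dz) %/% stride
  if (nwin < 1L) stop("trajectory shorter than one window of tau = ", tau)
  ## sum consecutive-frame displacements in non-overlapping strides
  dzw <- matrix(0, nwin, ncol(dz))
  for (s in seq_len(stride))
    dzw <- dzw + dz[seq.int(s, by = stride, length.out = nwin), ,
                    drop = FALSE]
  structure(dzw, times = traj$times[seq.int(1, by = stride,
                                            length.out = nwin)])
}

#' Block-average estimate of a trace mean and its error
#'
#' For autocorrelated traces the naive standard error of the mean is an
#' underestimate; the block-average protocol partitions the retained
#' trace into blocks longer than the correlation time and takes the
#' standard error of the block means.  The mean is computed over all
#' retained windows; the error uses complete blocks only (an incomplete
#' trailing block is dropped), with the sample (n-1) standard deviation.
#'
#' @param trace a `CurrentTrace`.
#' @param block block size, ps.
#' @param discard initial time to exclude, ps (windows starting before
#'   `discard` are dropped).
#' @return a `FlowEstimate`: list with `mean`, `error`, `n_blocks`,
#'   `discard`, `units`.
#' @export
block_error <- function(trace, block = 10000, discard = 0) {
  stopifnot(inherits(trace, "CurrentTrace"))
  keep <- trace$time >= discard
  t <- trace$time[keep]; v <- trace$value[keep]
  if (!length(v)) stop("discard removes the whole trace")
  tau <- attr(trace, "tau")
  per_block <- as.integer(floor(block / tau + 1e-9))
  if (per_block < 1L) stop("block size smaller than one window")
  nb <- length(v) %/% per_block
  if (nb < 2L)
    stop("need >= 2 complete blocks: retained duration ", length(v) * tau,
         " ps < ", 2 * block, " ps")
  bm <- colMeans(matrix(v[seq_len(nb * per_block)], per_block, nb))
  flow_estimate(mean(v), stats::sd(bm) / sqrt(nb), n = nb,
                discard = discard, units = attr(trace, "units"),
                kind = "blocks")
}

flow_estimate <- function(mean, error, n, discard = 0, units = "nA",
                          kind = "blocks") {
  structure(list(mean = mean, error = error, n = n, discard = discard,
                 units = units, kind = kind),
            class = "FlowEstimate")
}

#' @export
print.FlowEstimate <- function(x, ...) {
  cat(sprintf("%.6g +/- %.3g %s (n_%s = %d)\n", x$mean, x$error, x$units,
              x$kind, x$n))
  invisible(x)
}

#' Aggregate replica estimates
#'
#' The final estimate over independent replicas is the mean of the
#' replica means; its error is the sample standard deviation of the
#' replica means divided by the square root of the number of replicas.
#' A single replica falls back to its own block error with a warning.
#'
#' @param estimates list of `FlowEstimate` (same units).
#' @return a `FlowEstimate` with `kind = "replicas"`.
#' @export
replica_aggregate <- function(estimates) {
  stopifnot(length(estimates) >= 1L,
            all(vapply(estimates, inherits, TRUE, "FlowEstimate")))
  units <- unique(vapply(estimates, `[[`, "", "units"))
  if (length(units) != 1L) stop("replica estimates have mixed units")
  if (length(estimates) == 1L) {
    warning("single replica: falling back to its block error")
    return(estimates[[1]])
  }
  m <- vapply(estimates, `[[`, 0, "mean")
  flow_estimate(mean(m), stats::sd(m) / sqrt(length(m)), n = length(m),
                units = units, kind = "replicas")
}

#' Selectivity indicators from species currents
#'
#' The difference I+ - I- is the statistically robust selectivity
#' indicator (errors add in quadrature); the ratio |I+|/|I-| is also
#' reported but flagged unreliable whenever either current is
#' statistically indistinguishable from zero (see [is_negligible()]),
#' since the propagated error on a ratio with a near-zero denominator is
#' extremely large.
#'
#' @param cation,anion `FlowEstimate`s in the same units.
#' @return list with `difference` (a `FlowEstimate`) and `ratio` (a
#'   `RescaledEstimate` with a reliability flag).
#' @export
selectivity_indicator <- function(cation, anion) {
  stopifnot(inherits(cation, "FlowEstimate"), inherits(anion, "FlowEstimate"))
  if (!identical(cation$units, anion$units))
    stop("cation and anion estimates must share units")
  diff <- flow_estimate(cation$mean - anion$mean,
                        sqrt(cation$error^2 + anion$error^2),
                        n = min(cation$n, anion$n), units = cation$units,
                        kind = "difference")
  abs_cat <- flow_estimate(abs(cation$mean), cation$error, cation$n,
                           units = cation$units)
  abs_an <- flow_estimate(abs(anion$mean), anion$error, anion$n,
                          units = anion$units)
  list(difference = diff, ratio = normalized_ratio(abs_cat, abs_an))
}
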