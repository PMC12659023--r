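#' Uniform field from an applied voltage
#'
#' In a periodic box a uniform axial field \eqn{E_z = \Delta V / L_z}
#' is equivalent to applying the voltage drop `dV` across the box.
#'
#' @param voltage applied voltage, mV.
#' @param Lz box length along z, angstrom.
#' @return field, mV/angstrom.
#' @export
field_from_voltage <- function(voltage, Lz) {
  if (any(Lz <= 0)) stop("Lz must be positive")
  voltage / Lz
}

#' Assemble an I-V curve
#'
#' @param voltage voltages, mV (distinct).
#' @param current currents, nA.
#' @param error optional current errors, nA (used as 1/error^2 weights
#'   in [fit_conductance()]).
#' @param geometry length-3 box `(Lx, Ly, Lz)`, angstrom.
#' @return a `data.frame` of class `IVCurve`.
#' @export
iv_curve <- function(voltage, current, error = NULL, geometry = NULL) {
  if (anyDuplicated(voltage)) stop("voltages must be distinct")
  if (!is.null(geometry) && (length(geometry) != 3L || any(geometry <= 0)))
    stop("geometry must be 3 positive lengths")
  df <- data.frame(voltage = voltage, current = current,
                   error = if (is.null(error)) NA_real_ else error)
  structure(df, geometry = geometry, class = c("IVCurve", "data.frame"))
}

#' Fit a conductance from an I-V curve
#'
#' Weighted least-squares slope of I (nA) versus voltage (mV), returned
#' in nS.  The default constrains the fit through the origin, appropriate
#' for symmetric bulk electrolyte boxes; `through_origin = FALSE` also
#' fits an intercept.  Weights are `1/error^2` when point errors are
#' present, otherwise uniform.  With point errors the slope error is the
#' analytic weighted-least-squares parameter error (errors taken as
#' known, not rescaled by the residuals); without them it falls back to
#' the residual-based estimate.
#'
#' @param iv an `IVCurve`.
#' @param through_origin constrain I(0) = 0?
#' @return list of class `ConductanceFit`: `G` (nS), `error` (nS),
#'   `intercept` (nA, `NA` when through origin).
#' @export
fit_conductance <- function(iv, through_origin = TRUE) {
  stopifnot(inherits(iv, "IVCurve"))
  npt <- nrow(iv)
  if (npt < (if (through_origin) 1L else 2L))
    stop("need >= ", if (through_origin) 1 else 2, " points")
  if (!through_origin && length(unique(iv$voltage)) < 2L)
    stop("singular design: all voltages equal")
  known_err <- all(is.finite(iv$error)) && all(iv$error > 0)
  w <- if (known_err) 1 / iv$error^2 else rep(1, npt)
  x <- iv$voltage; y <- iv$current
  if (through_origin) {
    if (all(x == 0)) stop("singular design: all voltages zero")
    Sxx <- sum(w * x^2)
    slope <- sum(w * x * y) / Sxx
    intercept <- NA_real_
    se <- if (known_err) sqrt(1 / Sxx)
    else if (npt > 1L) {
      ## residual-based estimate when point errors are unknown
      sqrt(sum(w * (y - slope * x)^2) / (npt - 1L) / Sxx)
    } else 0
  } else {
    S <- sum(w); Sx <- sum(w * x); Sxx <- sum(w * x^2)
    Sy <- sum(w * y); Sxy <- sum(w * x * y)
    delta <- S * Sxx - Sx^2
    slope <- (S * Sxy - Sx * Sy) / delta
    intercept <- (Sxx * Sy - Sx * Sxy) / delta
    se <- if (known_err) sqrt(S / delta)
    else if (npt > 2L) {
      res <- y - intercept - slope * x
      sqrt(sum(w * res^2) / (npt - 2L) * S / delta)
    } else 0
  }
  structure(list(G = slope * NA_PER_MV_TO_NS,
                 error = se * NA_PER_MV_TO_NS,
                 intercept = intercept, through_origin = through_origin),
            class = "ConductanceFit")
}

#' Conductivity from conductance and box geometry
#'
#' \deqn{\sigma = G L_z / A,\qquad A = L_x L_y}
#' converts the geometry-dependent conductance of a periodic box into
#' the bulk material conductivity.
#'
#' @param G conductance, nS (or a `ConductanceFit`).
#' @param geometry length-3 box `(Lx, Ly, Lz)`, angstrom.
#' @param error conductance error, nS (taken from the fit when `G` is a
#'   `ConductanceFit`).
#' @return list of class `ConductivityResult`: `sigma` (S/m), `error`
#'   (S/m), `G` (nS), `G_error` (nS).
#' @export
conductivity_from_conductance <- function(G, geometry, error = 0) {
  if (inherits(G, "ConductanceFit")) { error <- G$error; G <- G$G }
  if (length(geometry) != 3L || any(geometry <= 0))
    stop("geometry must be 3 positive lengths")
  f <- geometry[3] / (geometry[1] * geometry[2]) * NS_PER_ANG_TO_S_PER_M
  structure(list(sigma = G * f, error = error * f, G = G, G_error = error),
            class = "ConductivityResult")
}

#' Conductivity sweep over concentrations
#'
#' For each concentration: species-resolved mean currents per voltage
#' (block-averaged), a conductance fit per species, and the conversion
#' to conductivity.  Input runs are tuples of trajectory, particle table
#' and run metadata; concentration is computed from the cation count and
#' box volume.
#'
#' @param runs list of lists with elements `trajectory`, `particles`,
#'   `meta` (a `RunMeta` carrying the voltage and discard).
#' @param tau current window, ps.
#' @param block block size, ps.
#' @param through_origin passed to [fit_conductance()].
#' @return data.frame with one row per concentration: `concentration`
#'   (mol/L), `sigma_total`, `sigma_cation`, `sigma_anion` and their
#'   errors (S/m).  Concentrations with fewer than 2 voltages are
#'   dropped with a warning.
#' @export
conductivity_sweep <- function(runs, tau = 20, block = 10000,
                               through_origin = TRUE) {
  per_run <- lapply(runs, function(r) {
    traj <- r$trajectory; pt <- r$particles; meta <- r$meta
    sc <- species_currents(traj, pt, tau)
    est <- lapply(sc, block_error, block = block, discard = meta$discard)
    vol <- prod(traj$box[1, ])
    conc <- sum(pt$species == "cation") / vol * PER_A3_TO_MOL_PER_L
    data.frame(concentration = conc, voltage = meta$voltage,
               Lx = traj$box[1, 1], Ly = traj$box[1, 2], Lz = traj$box[1, 3],
               I_all = est$all$mean, e_all = est$all$error,
               I_cat = est$cation$mean, e_cat = est$cation$error,
               I_an = est$anion$mean, e_an = est$anion$error)
  })
  tab <- do.call(rbind, per_run)
  out <- lapply(split(tab, signif(tab$concentration, 6)), function(d) {
    if (length(unique(d$voltage)) < 2L) {
      warning("concentration ", signif(d$concentration[1], 4),
              " mol/L has < 2 voltages; omitted")
      return(NULL)
    }
    geom <- c(d$Lx[1], d$Ly[1], d$Lz[1])
    one <- function(I, e) {
      conductivity_from_conductance(
        fit_conductance(iv_curve(d$voltage, I, e, geom), through_origin),
        geom)
    }
    st <- one(d$I_all, d$e_all); sc <- one(d$I_cat, d$e_cat)
    sa <- one(d$I_an, d$e_an)
    data.frame(concentration = d$concentration[1],
               sigma_total = st$sigma, sigma_total_error = st$error,
               sigma_cation = sc$sigma, sigma_cation_error = sc$error,
               sigma_anion = sa$sigma, sigma_anion_error = sa$error)
  })
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out)) {
    return(data.frame(concentration = numeric(0), sigma_total = numeric(0),
                      sigma_total_error = numeric(0),
                      sigma_cation = numeric(0),
                      sigma_cation_error = numeric(0),
                      sigma_anion = numeric(0),
                      sigma_anion_error = numeric(0)))
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
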