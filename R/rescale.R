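#' Transport constants for rescaling
#'
#' Viscosities per water model (mPa s) and conductivities per force
#' field at a stated KCl concentration (S/m).  Defaults carry the
#' standard shear viscosities of the water models used in nanopore work:
#' TIP3P 0.32 mPa s, OPC 0.80 mPa s, and experimental water 0.90 mPa s.
#' Conductivities have no defaults; measure them with the conductivity
#' module or supply literature values.
#'
#' Constants can be loaded from a plain-text config (TSV with header
#' `type label value concentration`; `type` is `viscosity` or
#' `conductivity`, `concentration` in mol/L, `NA` for viscosities).
#'
#' @param viscosity named numeric vector, mPa s.
#' @param conductivity named numeric vector, S/m.
#' @param concentration mol/L at which the conductivities hold.
#' @return list of class `TransportConstants`.
#' @export
transport_constants <- function(
    viscosity = c(TIP3P = 0.32, OPC = 0.80, water = 0.90),
    conductivity = numeric(0), concentration = NA_real_) {
  if (any(viscosity <= 0) || any(conductivity <= 0))
    stop("transport constants must be positive")
  structure(list(viscosity = viscosity, conductivity = conductivity,
                 concentration = concentration),
            class = "TransportConstants")
}

#' @rdname transport_constants
#' @param path TSV config file.
#' @export
read_transport_constants <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("type", "label", "value")
  if (!all(need %in% names(df)))
    stop("constants file needs columns: ", paste(need, collapse = ", "))
  visc <- df[df$type == "viscosity", ]
  cond <- df[df$type == "conductivity", ]
  conc <- if ("concentration" %in% names(df) && nrow(cond))
    unique(stats::na.omit(cond$concentration)) else NA_real_
  if (length(conc) > 1L)
    stop("conductivities at mixed concentrations in ", path,
         "; one concentration per constants file")
  transport_constants(
    viscosity = stats::setNames(visc$value, visc$label),
    conductivity = stats::setNames(cond$value, cond$label),
    concentration = if (length(conc)) conc else NA_real_)
}

rescaled_estimate <- function(value, error, reliable, units = "") {
  structure(list(value = value, error = error, reliable = reliable,
                 units = units),
            class = "RescaledEstimate")
}

#' @export
print.RescaledEstimate <- function(x, ...) {
  cat(sprintf("%.6g +/- %.3g %s%s\n", x$value, x$error, x$units,
              if (!x$reliable) "  [unreliable]" else ""))
  invisible(x)
}

#' Viscosity rescaling of an electroosmotic flow
#'
#' Multiplies an EOF estimate by the viscosity ratio of its water model
#' to the TIP3P reference,
#' \deqn{EOF_{x,r} = (\mu_x / \mu_{TIP3P})\, EOF_x,}
#' removing the known transport-coefficient difference between water
#' models (OPC is 2.5-fold more viscous than TIP3P).  The error scales
#' by the same factor.
#'
#' @param eof a `FlowEstimate` (molecules/ns).
#' @param model water-model label, present in `constants$viscosity`.
#' @param constants a [transport_constants()].
#' @param reference reference water model label.
#' @return a `RescaledEstimate`.
#' @export
rescale_eof <- function(eof, model, constants = transport_constants(),
                        reference = "TIP3P") {
  stopifnot(inherits(eof, "FlowEstimate"))
  v <- constants$viscosity
  for (lab in c(model, reference)) if (!lab %in% names(v))
    stop("unknown water model ", sQuote(lab), "; known: ",
         paste(names(v), collapse = ", "))
  f <- v[[model]] / v[[reference]]
  rescaled_estimate(f * eof$mean, f * eof$error,
                    reliable = !is_negligible(eof), units = eof$units)
}

#' Conductivity rescaling of an ionic current
#'
#' \deqn{I_{x,r} = (\sigma_{ref} / \sigma_x)\, I_x}
#' scales the current of force field x by the ratio of the reference
#' (CHARMM36) conductivity to its own, both at the same salt
#' concentration; the error scales identically.
#'
#' @param current a `FlowEstimate` (nA).
#' @param ff force-field label, present in `constants$conductivity`.
#' @param constants a [transport_constants()] whose conductivities share
#'   one concentration.
#' @param reference reference force-field label.
#' @return a `RescaledEstimate`.
#' @export
rescale_current <- function(current, ff, constants, reference = "CHARMM36") {
  stopifnot(inherits(current, "FlowEstimate"))
  s <- constants$conductivity
  for (lab in c(ff, reference)) if (!lab %in% names(s))
    stop("unknown force field ", sQuote(lab), "; known: ",
         paste(names(s), collapse = ", "))
  f <- s[[reference]] / s[[ff]]
  rescaled_estimate(f * current$mean, f * current$error,
                    reliable = !is_negligible(current),
                    units = current$units)
}

#' Ratio of two estimates with first-order error propagation
#'
#' \deqn{r = a/b, \qquad \delta r = \sqrt{(\delta a / b)^2 +
#'   (a\,\delta b / b^2)^2}.}
#' The result is flagged unreliable when either input is statistically
#' indistinguishable from zero ([is_negligible()]): with a near-zero
#' numerator or denominator the propagated error on the ratio is
#' extremely large, so the ratio carries no information.
#'
#' @param a,b `FlowEstimate`s in the same units.
#' @return a `RescaledEstimate` (dimensionless).
#' @export
normalized_ratio <- function(a, b) {
  stopifnot(inherits(a, "FlowEstimate"), inherits(b, "FlowEstimate"))
  if (!identical(a$units, b$units)) stop("estimates must share units")
  if (b$mean == 0)
    return(rescaled_estimate(NA_real_, NA_real_, reliable = FALSE))
  val <- a$mean / b$mean
  err <- sqrt((a$error / b$mean)^2 + (a$mean * b$error / b$mean^2)^2)
  rescaled_estimate(val, err,
                    reliable = !(is_negligible(a) || is_negligible(b)))
}

#' Is an estimate statistically indistinguishable from zero?
#'
#' `TRUE` when `|mean| < 2 * error` (strict: a mean exactly twice its
#' error is not negligible).  This is the exclusion rule used when
#' reporting rescaled ratios: a flagged numerator or denominator makes
#' the ratio unreliable.
#'
#' @param e a `FlowEstimate`.
#' @return logical flag.
#' @export
is_negligible <- function(e) {
  stopifnot(inherits(e, "FlowEstimate"), e$error >= 0)
  abs(e$mean) < 2 * e$error
}
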