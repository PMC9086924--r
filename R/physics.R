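# Physical primitives of the 1D hydraulic circuit model: rectangular-channel
# resistance, confined-droplet resistance, droplet speed, Laplace pressure.

#' Fluid pair properties
#'
#' Describes the two-phase system: the continuous (carrier) phase whose
#' viscosity sets channel resistances, the optional dispersed (droplet) phase,
#' and the interfacial tension between them which sets the Laplace pressure
#' thresholds of the squeeze-through objectives.
#'
#' @param viscosity_continuous dynamic viscosity of the carrier phase, mPa s.
#' @param viscosity_dispersed dynamic viscosity of the droplet phase, mPa s
#'   (optional; only used for the viscosity-ratio regime check).
#' @param interfacial_tension interfacial tension, N/m.
#' @param density fluid density, kg/m^3 (optional, informational).
#' @return an object of class `mf_fluid` with fields stored in SI.
#' @examples
#' oil <- fluid(viscosity_continuous = 5, interfacial_tension = 0.05)
#' @export
fluid <- function(viscosity_continuous, viscosity_dispersed = NA_real_,
                  interfacial_tension = 0, density = NA_real_) {
  if (!is.numeric(viscosity_continuous) || length(viscosity_continuous) != 1L ||
      !is.finite(viscosity_continuous) || viscosity_continuous <= 0) {
    stop("`viscosity_continuous` must be a single positive number (mPa s)",
         call. = FALSE)
  }
  if (!is.na(viscosity_dispersed) && viscosity_dispersed <= 0) {
    stop("`viscosity_dispersed` must be positive (mPa s)", call. = FALSE)
  }
  if (!is.numeric(interfacial_tension) || interfacial_tension < 0) {
    stop("`interfacial_tension` must be >= 0 (N/m)", call. = FALSE)
  }
  structure(
    list(
      mu_c = to_si(viscosity_continuous, "viscosity"),
      mu_d = if (is.na(viscosity_dispersed)) NA_real_
             else to_si(viscosity_dispersed, "viscosity"),
      gamma = interfacial_tension,
      density = density
    ),
    class = "mf_fluid"
  )
}

#' @export
print.mf_fluid <- function(x, ...) {
  cat("<mf_fluid>\n")
  cat(sprintf("  mu_c  : %g mPa s\n", from_si(x$mu_c, "viscosity")))
  if (!is.na(x$mu_d)) {
    cat(sprintf("  mu_d  : %g mPa s (lambda = %.3g)\n",
                from_si(x$mu_d, "viscosity"), x$mu_d / x$mu_c))
  }
  cat(sprintf("  gamma : %g N/m\n", x$gamma))
  invisible(x)
}

#' Rectangular channel geometry
#'
#' @param length channel length L, um.
#' @param width channel width w, um.
#' @param height channel height h, um. The closed-form resistance below
#'   requires the section ratio h/w < 1.
#' @return an object of class `mf_geometry` (fields in SI metres).
#' @examples
#' channel_geometry(1000, 100, 50)
#' @export
channel_geometry <- function(length, width, height) {
  v <- c(length = length, width = width, height = height)
  if (!all(is.finite(v)) || any(v <= 0)) {
    stop("channel length, width and height must all be positive (um)",
         call. = FALSE)
  }
  structure(
    list(L = to_si(length, "length"),
         w = to_si(width, "length"),
         h = to_si(height, "length")),
    class = "mf_geometry"
  )
}

#' @export
print.mf_geometry <- function(x, ...) {
  cat(sprintf("<mf_geometry> L = %g um, w = %g um, h = %g um (h/w = %.3g)\n",
              from_si(x$L, "length"), from_si(x$w, "length"),
              from_si(x$h, "length"), x$h / x$w))
  invisible(x)
}

#' Droplet size specification
#'
#' A droplet is described by the length `L_d` it occupies when confined in a
#' channel (plug length) and its unconfined spherical radius `r_d`. A droplet
#' is confined in a channel when `L_d` exceeds the channel width; only then is
#' the plug-resistance estimate valid.
#'
#' @param length plug length L_d, um.
#' @param radius unconfined/trapped spherical radius r_d, um.
#' @return an object of class `mf_droplet` (fields in SI metres).
#' @examples
#' droplet_spec(length = 250, radius = 90)
#' @export
droplet_spec <- function(length, radius) {
  if (!is.finite(length) || length <= 0 || !is.finite(radius) || radius <= 0) {
    stop("droplet `length` and `radius` must be positive (um)", call. = FALSE)
  }
  structure(
    list(L_d = to_si(length, "length"), r_d = to_si(radius, "length")),
    class = "mf_droplet"
  )
}

#' @export
print.mf_droplet <- function(x, ...) {
  cat(sprintf("<mf_droplet> L_d = %g um, r_d = %g um\n",
              from_si(x$L_d, "length"), from_si(x$r_d, "length")))
  invisible(x)
}

#' Operating-regime check for the droplet model
#'
#' The plug-resistance estimate and the constant slip factor are engineering
#' approximations with stated validity windows: capillary number Ca in
#' \[0.001, 0.01\] (slip factor, surfactant-free) and small Ca and viscosity
#' ratio for the plug resistance. Violations warn rather than fail: the model
#' is used as an engineering estimate and hard failures would block design
#' exploration.
#'
#' @param capillary_number Ca = mu_c v / gamma, dimensionless.
#' @param viscosity_ratio lambda = mu_d / mu_c, dimensionless.
#' @return an object of class `mf_regime` with logical fields `ca_ok`,
#'   `lambda_ok`.
#' @examples
#' regime_check(0.005, 0.2)
#' @export
regime_check <- function(capillary_number, viscosity_ratio = 0) {
  if (capillary_number < 0 || viscosity_ratio < 0) {
    stop("capillary number and viscosity ratio must be >= 0", call. = FALSE)
  }
  structure(
    list(
      Ca = capillary_number,
      lambda = viscosity_ratio,
      ca_ok = capillary_number >= 1e-3 && capillary_number <= 1e-2,
      lambda_ok = viscosity_ratio <= 0.1
    ),
    class = "mf_regime"
  )
}

#' Capillary number
#'
#' Ca = mu_c v / gamma, the ratio of viscous to interfacial stresses.
#'
#' @param fluid an [fluid()] object.
#' @param speed characteristic speed, mm/s.
#' @return dimensionless capillary number.
#' @export
capillary_number <- function(fluid, speed) {
  stopifnot(inherits(fluid, "mf_fluid"))
  if (fluid$gamma <= 0) return(Inf)
  fluid$mu_c * to_si(speed, "speed") / fluid$gamma
}

# dimensionless parameter a of the one-term rectangular-duct formula,
# as a function of the section ratio h/w < 1
.duct_a <- function(w, h) {
  12 / (1 - (192 * h) / (pi^5 * w) * tanh(pi * w / (2 * h)))
}

#' Hydrodynamic resistance of a rectangular channel
#'
#' Pressure-driven laminar flow in a rectangular duct of length L, width w and
#' height h obeys `dP = Q R` with
#' \deqn{R = \frac{a\,\mu_c\,L}{w\,h^3},\qquad
#'       a = 12\left[1 - \frac{192\,h}{\pi^5 w}
#'       \tanh\!\left(\frac{\pi w}{2 h}\right)\right]^{-1},}
#' the one-term truncation of the exact Fourier-series duct solution, valid for
#' section ratio h/w < 1 (error below 0.3 percent over that range).
#'
#' @param geom a [channel_geometry()] object with h/w < 1.
#' @param mu_c carrier viscosity: an [fluid()] object or a number in mPa s.
#' @return resistance in SI, Pa s m^-3. Convert with
#'   `from_si(x, "resistance")` for mbar/(ul/min).
#' @examples
#' R <- rect_channel_resistance(channel_geometry(1000, 100, 50), 1)
#' from_si(R, "resistance")
#' @export
rect_channel_resistance <- function(geom, mu_c) {
  stopifnot(inherits(geom, "mf_geometry"))
  mu <- .as_mu(mu_c)
  if (geom$h / geom$w >= 1) {
    stop(sprintf(paste0("rectangular-duct formula requires section ratio ",
                        "h/w < 1 (got h/w = %.3g); swap width and height ",
                        "to orient the wider dimension as w"),
                 geom$h / geom$w), call. = FALSE)
  }
  .duct_a(geom$w, geom$h) * mu * geom$L / (geom$w * geom$h^3)
}

.as_mu <- function(mu_c) {
  if (inherits(mu_c, "mf_fluid")) return(mu_c$mu_c)
  if (!is.numeric(mu_c) || length(mu_c) != 1L || mu_c <= 0) {
    stop("`mu_c` must be an mf_fluid or a positive viscosity in mPa s",
         call. = FALSE)
  }
  to_si(mu_c, "viscosity")
}

# resistance of a channel with the cross-section oriented so the formula
# domain h <= w holds; exact because duct resistance is symmetric under w <-> h
.oriented_resistance <- function(L, w, h, mu) {
  wo <- pmax(w, h)
  ho <- pmin(w, h)
  .duct_a(wo, ho) * mu * L / (wo * ho^3)
}

#' Hydrodynamic resistance of a confined droplet
#'
#' A confined droplet (plug longer than the channel width) adds a resistance
#' estimated as `plug_factor` times the resistance of a continuous-phase slug
#' of the same length:
#' \deqn{R_d = f_{plug}\; \frac{a\,\mu_c\,L_d}{w\,h^3}.}
#' The estimate holds for small capillary number and small viscosity ratio,
#' where the droplet's internal viscosity can be neglected; it has been
#' experimentally supported in that regime. It is only valid for confined flow
#' (`L_d > w`); an unconfined droplet is an error.
#'
#' @param drop a [droplet_spec()].
#' @param geom the hosting [channel_geometry()].
#' @param fluid an [fluid()] object (carrier viscosity).
#' @param regime optional [regime_check()]; when outside the validity window a
#'   warning (not an error) is emitted.
#' @param plug_factor ratio of plug to equivalent-slug resistance, default 3.
#' @return droplet resistance in SI, Pa s m^-3.
#' @examples
#' d <- droplet_spec(250, 90)
#' g <- channel_geometry(1000, 100, 50)
#' droplet_resistance(d, g, fluid(5, interfacial_tension = 0.05))
#' @export
droplet_resistance <- function(drop, geom, fluid, regime = NULL,
                               plug_factor = 3) {
  stopifnot(inherits(drop, "mf_droplet"), inherits(geom, "mf_geometry"),
            inherits(fluid, "mf_fluid"))
  if (drop$L_d <= geom$w) {
    stop(sprintf(paste0("droplet is not confined (L_d = %g um <= w = %g um): ",
                        "the plug-resistance estimate is only valid for a ",
                        "confined flow"),
                 from_si(drop$L_d, "length"), from_si(geom$w, "length")),
         call. = FALSE)
  }
  if (!is.null(regime)) {
    stopifnot(inherits(regime, "mf_regime"))
    if (!regime$ca_ok || !regime$lambda_ok) {
      warning(sprintf(paste0("operating regime outside the validity window of ",
                             "the plug-resistance estimate (Ca = %.3g, ",
                             "lambda = %.3g); treating the result as an ",
                             "engineering estimate"),
                      regime$Ca, regime$lambda), call. = FALSE)
    }
  }
  plug_factor * .oriented_resistance(drop$L_d, geom$w, geom$h, fluid$mu_c)
}

#' Total resistance of a channel carrying droplets
#'
#' `R* = R + n R_d`: the bare channel resistance plus one droplet resistance
#' per droplet currently inside the channel. Assumes droplets are spaced a few
#' channel widths apart so their flow perturbations do not interact.
#'
#' @param R bare channel resistance (any consistent unit).
#' @param n droplet count, non-negative integer.
#' @param R_d single-droplet resistance, same unit as `R`.
#' @return `R + n * R_d` in the unit of the inputs.
#' @examples
#' channel_total_resistance(5, 3, 2)  # 11
#' @export
channel_total_resistance <- function(R, n, R_d) {
  if (any(n < 0) || any(n != round(n))) {
    stop("droplet count `n` must be a non-negative integer", call. = FALSE)
  }
  if (any(R < 0) || any(R_d < 0)) {
    stop("resistances must be >= 0", call. = FALSE)
  }
  R + n * R_d
}

#' Droplet speed from the channel flow rate
#'
#' A confined droplet moves faster than the mean carrier speed by the constant
#' slip factor: `v_d = slip * Q / (w h)`, with `v_c = Q/(w h)` the superficial
#' carrier speed of the hosting channel. The default slip factor 1.28 holds for
#' plug lengths between 1.5 and 7.2 channel widths and Ca between 0.001 and
#' 0.01 without surfactant. The sign of the speed follows the sign of `Q`.
#'
#' @param Q signed volumetric flow rate in the hosting channel, SI m^3/s.
#' @param geom the hosting [channel_geometry()].
#' @param slip slip factor, default 1.28.
#' @return signed droplet speed, SI m/s.
#' @examples
#' droplet_speed(to_si(2, "flow"), channel_geometry(1000, 100, 50))
#' @export
droplet_speed <- function(Q, geom, slip = 1.28) {
  stopifnot(inherits(geom, "mf_geometry"))
  if (!is.finite(slip) || slip <= 0) {
    stop("`slip` must be a positive factor", call. = FALSE)
  }
  area <- geom$w * geom$h
  if (area <= 0) stop("channel cross-section must be positive", call. = FALSE)
  slip * Q / area
}

#' Laplace pressure threshold of a narrow gap
#'
#' The capillary pressure a droplet of radius `r_d` must overcome to be
#' squeezed into a gap of width `w_gap`:
#' \deqn{\Delta P_{Lap} = 2\gamma\left(\frac{2}{w_{gap}} - \frac{1}{r_d}\right),}
#' the front meniscus taking the in-plane radius `w_gap/2` while the rear keeps
#' the droplet curvature `1/r_d` (the height curvature is common to both menisci
#' and cancels). A pressure difference below this threshold cannot push the
#' droplet through; the expression is linear in the interfacial tension.
#'
#' @param gamma interfacial tension, N/m (>= 0).
#' @param w_gap gap width, um (> 0).
#' @param r_d droplet radius, um (> 0). For a trapped droplet `r_d <= r` (trap
#'   radius); the trap radius is used as the default admissible radius.
#' @return Laplace pressure in SI Pa. Convert with `from_si(x, "pressure")`.
#' @examples
#' from_si(laplace_pressure(0.05, 15, 100), "pressure")  # mbar
#' @export
laplace_pressure <- function(gamma, w_gap, r_d) {
  if (!is.numeric(gamma) || any(gamma < 0)) {
    stop("`gamma` must be >= 0 (N/m)", call. = FALSE)
  }
  if (any(!is.finite(w_gap)) || any(w_gap <= 0) ||
      any(!is.finite(r_d)) || any(r_d <= 0)) {
    stop("`w_gap` and `r_d` must be positive (um)", call. = FALSE)
  }
  wg <- to_si(w_gap, "length")
  rd <- to_si(r_d, "length")
  2 * gamma * (2 / wg - 1 / rd)
}
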