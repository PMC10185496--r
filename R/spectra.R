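## Spectral irradiance of each sea-surface light component.
##
## All spectra live on a common wavelength grid (default 400--700 nm at
## 1 nm) in W m^-2 nm^-1.  Broadband values are trapezoid integrals over
## the grid, in W m^-2 unless a function documents microwatts.

#' Wavelength grid for spectral irradiance
#'
#' @param from,to,by Wavelength bounds and spacing in nm.  Bounds must stay
#'   within 380--750 nm.
#' @return Numeric vector of wavelengths (nm), strictly increasing.
#' @export
spectral_grid <- function(from = 400, to = 700, by = 1) {
  stopifnot(from >= 380, to <= 750, from < to, by > 0)
  seq(from, to, by = by)
}

#' Construct a spectral irradiance object
#'
#' @param values Irradiance per wavelength, W m^-2 nm^-1 (non-negative).
#' @param grid Wavelength grid from \code{\link{spectral_grid}}.
#' @param component Component tag, one of "solar_direct", "solar_diffuse",
#'   "solar", "twilight", "lunar", "alan", "floor".
#' @return Object of class \code{spectral_irradiance}.
#' @export
spectral_irradiance <- function(values, grid = spectral_grid(),
                                component = "solar") {
  stopifnot(length(values) == length(grid), all(values >= -1e-15))
  values <- pmax(values, 0)
  structure(list(grid = grid, values = values, component = component),
            class = "spectral_irradiance")
}

#' Broadband (wavelength-integrated) irradiance
#'
#' Trapezoid integral over the spectral grid.
#' @param x A \code{spectral_irradiance}.
#' @return Scalar irradiance, W m^-2.
#' @export
broadband <- function(x) {
  stopifnot(inherits(x, "spectral_irradiance"))
  g <- x$grid; v <- x$values
  sum(diff(g) * (utils::head(v, -1) + utils::tail(v, -1)) / 2)
}

#' @export
print.spectral_irradiance <- function(x, ...) {
  cat(sprintf("<spectral_irradiance> %s, %d bands %g-%g nm, broadband %.4g W m-2\n",
              x$component, length(x$grid), min(x$grid), max(x$grid), broadband(x)))
  invisible(x)
}

## ---- TOA solar ----------------------------------------------------------

## Fraction of total solar output falling in [from, to] nm for a 5778 K
## Planck spectrum; used to scale visible-band integrals to full-spectrum
## equivalents.
.planck_shape <- function(lambda_nm, T_K = 5778) {
  h <- 6.62607015e-34; c <- 2.99792458e8; k <- 1.380649e-23
  lam <- lambda_nm * 1e-9
  lam^-5 / (exp(h * c / (lam * k * T_K)) - 1)
}

#' Fraction of total solar irradiance inside a wavelength band
#'
#' Computed from a 5778 K Planck spectrum; used at the top of the
#' atmosphere to convert visible-band broadband values to full-spectrum
#' equivalents.
#' @param from,to Band limits, nm.
#' @return Unitless fraction in (0, 1).
#' @export
solar_band_fraction <- function(from = 400, to = 700) {
  lam <- seq(50, 5000, by = 1)
  w <- .planck_shape(lam)
  sum(w[lam >= from & lam <= to]) / sum(w)
}

## Visible (400-700 nm) share of global surface irradiance under a clear
## sky: the canonical PAR-to-global ratio.  Larger than the TOA share
## because water vapour absorbs strongly in the infrared.
.SURFACE_VIS_FRACTION <- 0.47

#' Top-of-atmosphere solar spectrum (synthetic surrogate table)
#'
#' A 5778 K Planck spectrum scaled to a total solar irradiance of
#' 1361 W m^-2, evaluated on the grid.  This is a documented synthetic
#' surrogate for a tabulated solar reference spectrum; a measured table
#' can be supplied to \code{\link{toa_solar}} via \code{h0} as a
#' two-column (wavelength_nm, value) data frame.
#' @param grid Wavelength grid, nm.
#' @return Numeric vector, W m^-2 nm^-1 on \code{grid}.
#' @export
solar_reference_spectrum <- function(grid = spectral_grid()) {
  lam <- seq(50, 5000, by = 1)
  w <- .planck_shape(lam)
  scale <- 1361 / sum(w)           # W m^-2 per unit shape, 1 nm steps
  stats::approx(lam, w * scale, xout = grid)$y
}

#' TOA solar spectral irradiance corrected for orbital eccentricity
#'
#' E0(lambda) = H0(lambda) * (1 + eps * cos(2 pi (D - 3) / 365))^2, the
#' Sun--Earth distance correction for day-of-year D with orbital
#' eccentricity eps.
#'
#' @param day_of_year Integer 1..366.
#' @param eccentricity Orbital eccentricity (default 0.0167).
#' @param h0 Optional TOA spectrum: a data frame with columns
#'   \code{wavelength_nm} and \code{value} (W m^-2 nm^-1); resampled onto
#'   \code{grid} by linear interpolation (with a warning) when its
#'   wavelengths differ from the grid.
#' @param grid Wavelength grid, nm.
#' @return \code{spectral_irradiance}, component "solar".
#' @examples
#' e0 <- toa_solar(3)          # perihelion side: multiplier (1.0167)^2
#' broadband(e0)
#' @export
toa_solar <- function(day_of_year, eccentricity = 0.0167, h0 = NULL,
                      grid = spectral_grid()) {
  stopifnot(day_of_year >= 1, day_of_year <= 366)
  if (is.null(h0)) {
    base <- solar_reference_spectrum(grid)
  } else {
    stopifnot(all(c("wavelength_nm", "value") %in% names(h0)))
    if (!isTRUE(all.equal(h0$wavelength_nm, grid))) {
      if (min(h0$wavelength_nm) > min(grid) || max(h0$wavelength_nm) < max(grid))
        stop("supplied TOA table does not cover the grid")
      warning("resampling TOA table onto the grid by linear interpolation")
    }
    base <- stats::approx(h0$wavelength_nm, h0$value, xout = grid)$y
  }
  mult <- (1 + eccentricity * cos(2 * pi * (day_of_year - 3) / 365))^2
  spectral_irradiance(base * mult, grid, "solar")
}

## ---- clear-sky marine atmosphere ---------------------------------------

#' Clear-sky marine atmosphere parameters
#'
#' Defaults describe a clean marine atmosphere; every value is exposed so
#' that site-specific columns can be substituted.
#' @param aot550 Aerosol optical thickness at 550 nm.
#' @param angstrom Angstrom wavelength exponent of the aerosol.
#' @param ssa Aerosol single-scattering albedo.
#' @param fwd Aerosol forward-scattering fraction.
#' @param ozone_du Ozone column, Dobson units.
#' @param pressure_hpa Surface pressure, hPa.
#' @param rel_humidity Relative humidity, 0..1.
#' @param wind_ms Wind speed, m s^-1 (kept for interface completeness).
#' @return List of class \code{atmosphere_params}.
#' @export
atmosphere_params <- function(aot550 = 0.1, angstrom = 1.0, ssa = 0.95,
                              fwd = 0.95, ozone_du = 300,
                              pressure_hpa = 1013.25, rel_humidity = 0.8,
                              wind_ms = 5) {
  p <- list(aot550 = aot550, angstrom = angstrom, ssa = ssa, fwd = fwd,
            ozone_du = ozone_du, pressure_hpa = pressure_hpa,
            rel_humidity = rel_humidity, wind_ms = wind_ms)
  stopifnot(all(vapply(p, function(x) is.finite(x) && x >= 0, logical(1))))
  structure(p, class = "atmosphere_params")
}

## Kasten-Young airmass.
.airmass <- function(theta_z) {
  1 / (cos(theta_z * pi / 180) + 0.50572 * (96.07995 - theta_z)^-1.6364)
}

## Chappuis-band ozone absorption (atm-cm)^-1, parametric approximation.
.ozone_abs <- function(grid) {
  0.12 * exp(-0.5 * ((grid - 600) / 55)^2)
}

## Spectral transmittances for a given zenith angle.
.transmittances <- function(grid, theta_z, atm) {
  M <- .airmass(theta_z)
  Mp <- M * atm$pressure_hpa / 1013.25
  lam_um <- grid / 1000
  tau_r <- 1 / (115.6406 * lam_um^4 - 1.335 * lam_um^2)
  tau_a <- atm$aot550 * (lam_um / 0.55)^(-atm$angstrom)
  tau_oz <- .ozone_abs(grid) * atm$ozone_du / 1000
  list(
    M = M,
    Tr = exp(-Mp * tau_r),
    Ta = exp(-M * tau_a),
    Taa = exp(-M * (1 - atm$ssa) * tau_a),
    Tas = exp(-M * atm$ssa * tau_a),
    Toz = exp(-M * tau_oz)
  )
}

#' Direct and diffuse surface irradiance under a clear marine sky
#'
#' Partitions the TOA spectrum into a direct beam and a diffuse sky
#' component using a clear-sky marine transmittance model (Rayleigh,
#' aerosol, and ozone terms; Rayleigh and aerosol scattering feed the
#' diffuse term).  The total surface irradiance is the sum of the two.
#'
#' @param toa \code{spectral_irradiance} at the top of the atmosphere.
#' @param theta_z Zenith angle of the source, degrees, in [0, 90).
#' @param atm \code{\link{atmosphere_params}}.
#' @return List with \code{direct} and \code{diffuse}
#'   \code{spectral_irradiance} objects (components "solar_direct",
#'   "solar_diffuse").
#' @examples
#' cs <- clear_sky_surface(toa_solar(100), 30)
#' broadband(cs$direct) + broadband(cs$diffuse)
#' @export
clear_sky_surface <- function(toa, theta_z, atm = atmosphere_params()) {
  stopifnot(inherits(toa, "spectral_irradiance"))
  if (theta_z < 0 || theta_z >= 90)
    stop("theta_z must be in [0, 90); use twilight_irradiance() below the horizon")
  tr <- .transmittances(toa$grid, theta_z, atm)
  mu <- cos(theta_z * pi / 180)
  e0 <- toa$values
  direct <- e0 * mu * tr$Tr * tr$Ta * tr$Toz
  ## half of Rayleigh-scattered light reaches the surface; aerosol
  ## scattering is strongly forward-peaked
  Ir <- e0 * mu * tr$Toz * tr$Taa * (1 - tr$Tr^0.95) / 2
  Ia <- e0 * mu * tr$Toz * tr$Taa * tr$Tr^1.5 * (1 - tr$Tas) * atm$fwd
  list(direct = spectral_irradiance(direct, toa$grid, "solar_direct"),
       diffuse = spectral_irradiance(Ir + Ia, toa$grid, "solar_diffuse"))
}

## ---- dark-sky floor and photometry -------------------------------------

#' Convert astronomical surface brightness to luminance
#'
#' L = 10.8e4 * 10^(-0.4 m) cd m^-2 for a surface brightness of m
#' mag arcsec^-2.
#' @param m Surface brightness, mag arcsec^-2.
#' @return Luminance, cd m^-2.
#' @examples
#' mag_to_luminance(22)   # dark-sky zenith brightness
#' @export
mag_to_luminance <- function(m) {
  stopifnot(is.finite(m))
  10.8e4 * 10^(-0.4 * m)
}

#' Convert luminance to broadband irradiance
#'
#' E = L / 683 using the peak photopic luminous efficacy (683 lm W^-1),
#' reported in microwatts per square metre.
#' @param L Luminance, cd m^-2 (>= 0).
#' @return Irradiance, uW m^-2.
#' @examples
#' luminance_to_irradiance(mag_to_luminance(22))   # ~0.25 uW m-2
#' @export
luminance_to_irradiance <- function(L) {
  stopifnot(all(L >= 0))
  L / 683 * 1e6
}

#' Dark-sky background irradiance floor
#'
#' The nighttime background (air glow, zodiacal light, integrated
#' starlight) treated as a constant floor: a 22 mag arcsec^-2 sky,
#' equivalent to 0.25 uW m^-2, spread flat across the grid.
#' @param grid Wavelength grid, nm.
#' @return \code{spectral_irradiance}, component "floor".
#' @export
dark_sky_floor <- function(grid = spectral_grid()) {
  total <- luminance_to_irradiance(mag_to_luminance(22)) * 1e-6  # W m^-2
  span <- max(grid) - min(grid)
  spectral_irradiance(rep(total / span, length(grid)), grid, "floor")
}

## ---- twilight ------------------------------------------------------------

## Anchor: clear-sky broadband (W m^-2) just above the horizon, cached per
## atmosphere parameter set within a session.
.twilight_anchor <- local({
  cache <- new.env(parent = emptyenv())
  function(atm, grid) {
    key <- paste(unlist(atm), collapse = "_")
    key <- paste(key, min(grid), max(grid), length(grid), sep = "_")
    if (!is.null(cache[[key]])) return(cache[[key]])
    cs <- clear_sky_surface(toa_solar(80, grid = grid), 89.5, atm)
    val <- broadband(cs$direct) + broadband(cs$diffuse)
    cache[[key]] <- val
    val
  }
})

#' Twilight partition for a solar altitude
#'
#' @param solar_altitude Sun altitude, degrees.
#' @return "day", "civil", "nautical", "astronomical" or "night".
#' @export
twilight_partition <- function(solar_altitude) {
  if (solar_altitude >= 0) return("day")
  if (solar_altitude > -6) return("civil")
  if (solar_altitude > -12) return("nautical")
  if (solar_altitude > -18) return("astronomical")
  "night"
}

#' Twilight sky irradiance (parametric surrogate)
#'
#' A parametric stand-in for a measured rural twilight lookup table:
#' log10 of the broadband sky irradiance declines linearly with solar
#' depression, from the clear-sky value at the horizon to the dark-sky
#' floor (0.25 uW m^-2) at 18 degrees depression, and continues on the
#' same slope below (so the twilight term becomes negligible against the
#' floor shortly after astronomical dusk).  The spectral shape blue-shifts
#' with depression.  A measured lookup table can be substituted via
#' \code{lut}: a data frame with columns \code{depression_deg} and
#' \code{broadband_w_m2}, interpolated on the log10 scale.
#'
#' @param solar_altitude Sun altitude in degrees, < 0 (depression = -altitude).
#' @param atm \code{\link{atmosphere_params}} (sets the horizon anchor).
#' @param grid Wavelength grid, nm.
#' @param lut Optional measured replacement table (see Details).
#' @return \code{spectral_irradiance} with component "twilight" and
#'   attribute \code{partition} in {"civil","nautical","astronomical","night"}.
#' @export
twilight_irradiance <- function(solar_altitude, atm = atmosphere_params(),
                                grid = spectral_grid(), lut = NULL) {
  if (solar_altitude >= 0)
    stop("solar altitude must be below the horizon; use clear_sky_surface()")
  d <- -solar_altitude
  floor_bb <- 0.25e-6
  if (is.null(lut)) {
    a0 <- .twilight_anchor(atm, grid)
    slope <- (log10(floor_bb) - log10(a0)) / 18
    bb <- 10^(log10(a0) + slope * d)
  } else {
    stopifnot(all(c("depression_deg", "broadband_w_m2") %in% names(lut)))
    bb <- 10^(stats::approx(lut$depression_deg, log10(lut$broadband_w_m2),
                            xout = d, rule = 2)$y)
  }
  ## blue-shifted solar shape: weight (lambda/550)^(-0.15 d)
  shape <- solar_reference_spectrum(grid) * (grid / 550)^(-0.15 * min(d, 18))
  shape <- shape / sum(diff(grid) * (utils::head(shape, -1) +
                                       utils::tail(shape, -1)) / 2)
  out <- spectral_irradiance(shape * bb, grid, "twilight")
  attr(out, "partition") <- twilight_partition(solar_altitude)
  out
}

## ---- lunar ---------------------------------------------------------------

#' Lunar spectral albedo (synthetic surrogate)
#'
#' Flat geometric albedo 0.12 with a mild red slope, standing in for a
#' tabulated lunar albedo spectrum; replace via the \code{albedo} argument
#' of \code{\link{toa_lunar}}.
#' @param grid Wavelength grid, nm.
#' @return Unitless albedo per wavelength, in (0, 1).
#' @export
lunar_albedo_spectrum <- function(grid = spectral_grid()) {
  pmin(0.99, pmax(0.01, 0.12 + 2e-4 * (grid - 550)))
}

#' Lunar phase factor with opposition brightening
#'
#' Analytic phase curve 10^(-0.4 (0.026 |g| + 4e-9 g^4)) normalised to 1
#' at zero phase angle (full moon); monotonically non-increasing in |g|.
#' @param g Phase angle, degrees (0 = full moon).
#' @return Unitless factor in (0, 1].
#' @export
lunar_phase_factor <- function(g) {
  g <- abs(g)
  10^(-0.4 * (0.026 * g + 4e-9 * g^4))
}

#' TOA lunar spectral irradiance
#'
#' E_moon(lambda) = E0(lambda) * a(lambda) * sin^2(0.26 deg) * f(g):
#' the TOA solar spectrum reflected by the lunar albedo, diluted by the
#' solid angle of the lunar disc (semi-diameter view angle 0.26 deg) and
#' modulated by the phase curve.
#'
#' @param day_of_year Integer 1..366 (for the solar eccentricity correction).
#' @param phase_angle Lunar phase angle g, degrees in [0, 180].
#' @param albedo Optional numeric vector of albedo on \code{grid}.
#' @param grid Wavelength grid, nm.
#' @param eccentricity Orbital eccentricity for the solar term.
#' @return \code{spectral_irradiance}, component "lunar".
#' @examples
#' # full-moon TOA lunar is ~5 orders of magnitude below solar
#' broadband(toa_lunar(245, 0)) / broadband(toa_solar(245))
#' @export
toa_lunar <- function(day_of_year, phase_angle, albedo = NULL,
                      grid = spectral_grid(), eccentricity = 0.0167) {
  stopifnot(phase_angle >= 0, phase_angle <= 180)
  if (is.null(albedo)) albedo <- lunar_albedo_spectrum(grid)
  stopifnot(length(albedo) == length(grid), all(albedo > 0), all(albedo < 1))
  e0 <- toa_solar(day_of_year, eccentricity, grid = grid)
  dilution <- sin(0.26 * pi / 180)^2
  spectral_irradiance(e0$values * albedo * dilution *
                        lunar_phase_factor(phase_angle), grid, "lunar")
}

#' Surface lunar spectral irradiance
#'
#' Propagates the TOA lunar spectrum through the same clear-sky marine
#' transmittance model as the solar beam (the atmosphere is
#' source-agnostic), at the lunar zenith angle.  Returns zero when the
#' moon is below the horizon.
#'
#' @param toa \code{spectral_irradiance} from \code{\link{toa_lunar}}.
#' @param lunar_zenith Lunar zenith angle, degrees.
#' @param atm \code{\link{atmosphere_params}}.
#' @return \code{spectral_irradiance}, component "lunar" (direct + diffuse).
#' @export
surface_lunar <- function(toa, lunar_zenith, atm = atmosphere_params()) {
  stopifnot(inherits(toa, "spectral_irradiance"))
  if (lunar_zenith >= 90)
    return(spectral_irradiance(rep(0, length(toa$grid)), toa$grid, "lunar"))
  cs <- clear_sky_surface(toa, lunar_zenith, atm)
  spectral_irradiance(cs$direct$values + cs$diffuse$values, toa$grid, "lunar")
}

## ---- artificial light ----------------------------------------------------

## RGB band limits, nm (blue/green overlap 495-500 nm is as defined;
## the red band is truncated at the grid maximum, 700 nm by default).
.ALAN_BANDS <- list(blue = c(400, 500), green = c(495, 560), red = c(640, 720))

.band_shape <- function(grid, lim, centre, width) {
  v <- exp(-0.5 * ((grid - centre) / width)^2)
  v[grid < lim[1] | grid > lim[2]] <- 0
  v
}

#' Artificial-light configuration
#'
#' Either per-band irradiances (blue 400--500 nm, green 495--560 nm, red
#' 640--720 nm, in uW m^-2) or a lamp class scaled to a total broadband
#' irradiance.  The on/off schedule names which night events switch the
#' lights ("lights on at dusk, off at dawn"); the default is the civil
#' (-6 deg) crossings.
#'
#' @param lamp_class "rgb_bands", "LED", "HPS" or "LPS".
#' @param blue,green,red Band irradiances, uW m^-2 (rgb_bands mode).
#' @param total Total broadband irradiance, uW m^-2 (lamp-class mode).
#' @param on_event,off_event Field names of \code{\link{night_events}}.
#' @return List of class \code{alan_config}.
#' @export
alan_config <- function(lamp_class = c("rgb_bands", "LED", "HPS", "LPS"),
                        blue = 0, green = 0, red = 0, total = NULL,
                        on_event = "civil_dusk", off_event = "civil_dawn") {
  lamp_class <- match.arg(lamp_class)
  if (any(c(blue, green, red) < 0)) stop("band irradiances must be >= 0")
  if (lamp_class != "rgb_bands") {
    if (is.null(total) || total < 0)
      stop("lamp-class mode needs a non-negative `total` (uW m^-2)")
  } else {
    total <- blue + green + red
  }
  structure(list(lamp_class = lamp_class, blue = blue, green = green,
                 red = red, total = total,
                 on_event = on_event, off_event = off_event),
            class = "alan_config")
}

## Normalise a shape to unit band integral over [lim] on grid.
.norm_band <- function(grid, shape, lim) {
  sel <- grid >= lim[1] & grid <= min(lim[2], max(grid))
  g <- grid[sel]; v <- shape[sel]
  integ <- sum(diff(g) * (utils::head(v, -1) + utils::tail(v, -1)) / 2)
  if (integ <= 0) stop("degenerate band shape")
  shape / integ
}

#' ALAN surface spectrum
#'
#' Builds the above-surface artificial-light spectrum from the
#' configuration: in rgb_bands mode each band shape is scaled so its band
#' integral equals the configured irradiance (within 1%); in lamp-class
#' mode a spectral shape function for the lamp type is scaled to the
#' configured total.
#'
#' @param cfg \code{\link{alan_config}}.
#' @param grid Wavelength grid, nm.
#' @return \code{spectral_irradiance}, component "alan" (values W m^-2 nm^-1).
#' @export
alan_spectrum <- function(cfg, grid = spectral_grid()) {
  stopifnot(inherits(cfg, "alan_config"))
  v <- rep(0, length(grid))
  if (cfg$lamp_class == "rgb_bands") {
    ## shape support avoids the printed 495-500 nm blue/green overlap so
    ## that both band integrals can match their configured values
    parts <- list(
      blue = list(lim = c(400, 495), centre = 450, width = 30,
                  amt = cfg$blue),
      green = list(lim = c(500, 560), centre = 530, width = 15,
                   amt = cfg$green),
      red = list(lim = .ALAN_BANDS$red, centre = 660, width = 20,
                 amt = cfg$red))
    for (p in parts) {
      if (p$amt <= 0) next
      s <- .band_shape(grid, p$lim, p$centre, p$width)
      v <- v + .norm_band(grid, s, p$lim) * p$amt * 1e-6
    }
  } else {
    shape <- switch(cfg$lamp_class,
      ## white LED: blue pump + phosphor hump
      LED = .band_shape(grid, c(400, 700), 450, 12) * 1.2 +
        .band_shape(grid, c(400, 700), 570, 60),
      ## high-pressure sodium: broadened emission around 569-600 nm
      HPS = .band_shape(grid, c(400, 700), 590, 15) +
        0.25 * .band_shape(grid, c(400, 700), 569, 8),
      ## low-pressure sodium: near-monochromatic 589 nm doublet
      LPS = .band_shape(grid, c(400, 700), 589, 3))
    v <- .norm_band(grid, shape, range(grid)) * cfg$total * 1e-6
  }
  spectral_irradiance(v, grid, "alan")
}

#' Band integrals of a spectrum over the RGB ALAN bands
#'
#' @param x \code{spectral_irradiance}.
#' @return Named numeric (blue, green, red), uW m^-2.
#' @export
alan_band_integrals <- function(x) {
  stopifnot(inherits(x, "spectral_irradiance"))
  out <- vapply(.ALAN_BANDS, function(lim) {
    sel <- x$grid >= lim[1] & x$grid <= min(lim[2], max(x$grid))
    g <- x$grid[sel]; v <- x$values[sel]
    sum(diff(g) * (utils::head(v, -1) + utils::tail(v, -1)) / 2) * 1e6
  }, numeric(1))
  names(out) <- names(.ALAN_BANDS)
  out
}
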