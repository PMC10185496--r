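## Synthetic spawning data with the statistical structure the inference
## pipeline assumes: genus-specific baselines and lit-site shifts, an
## ecoregion effect, a latitude effect, a Matern-correlated site field,
## and (near-)Poisson counts.  A toy critical-depth raster and trait
## table are generated so that the classification stage reproduces the
## intended exposure labels exactly.

#' Default genus table for the generator
#'
#' Twelve genera with baseline mean transformed day offsets (days, on the
#' positive-transformed scale) and additive lit-site shifts in days
#' (negative = closer to the full moon); mirrors the mix of one-, two-
#' and three-day shifts reported for lit reefs, with one unaffected genus.
#' @return Data frame: genus, baseline_days, lit_shift_days.
#' @export
default_genus_table <- function() {
  data.frame(
    genus = c("Acropora", "Montipora", "Favites", "Dipsastraea",
              "Goniastrea", "Galaxea", "Acanthastrea", "Platygyra",
              "Cyphastrea", "Porites", "Echinophyllia", "Pectinia"),
    baseline_days = c(7, 7, 6, 6, 6, 6, 6, 7, 6, 8, 6, 6),
    lit_shift_days = c(-2, -1, -1, -2, -2, -2, -2, -2, -2, -3, -1, 0)
  )
}

#' Generator configuration
#'
#' @param n_sites Number of spawning sites.
#' @param n_obs_per_site Observations per site.
#' @param genera Data frame as \code{\link{default_genus_table}}.
#' @param n_ecoregions Number of ecoregions (sites are clustered).
#' @param ecoregion_sd SD of ecoregion intercepts on the log scale.
#' @param latitude_slope Log-scale slope per degree of distance from the
#'   equator (negative: higher-latitude corals spawn closer to full moon).
#' @param matern List (nu, rho_km, sigma2) of the site-field Matern
#'   smoothness, range in km, and variance (log scale).
#' @param family "poisson" (default) or "underdispersed"
#'   (binomial-thinned counts with variance ~ \code{target_dispersion}
#'   times the mean).
#' @param target_dispersion Target variance/mean ratio for the
#'   underdispersed family.
#' @param prop_lit Proportion of sites exposed to artificial light.
#' @param prop_depth_recorded Proportion of observations with a recorded
#'   depth (the rest classify via the species trait table).
#' @param dosrtnf_offset Constant subtracted from the positive counts
#'   when writing signed day offsets.
#' @param seed Integer seed; fixed seed gives bit-identical outputs.
#' @return List of class \code{synth_config}.
#' @export
synth_config <- function(n_sites = 52, n_obs_per_site = 41,
                         genera = default_genus_table(),
                         n_ecoregions = 19, ecoregion_sd = 0.10,
                         latitude_slope = -0.01,
                         matern = list(nu = 1.5, rho_km = 400, sigma2 = 0.04),
                         family = c("poisson", "underdispersed"),
                         target_dispersion = 0.8,
                         prop_lit = 0.5, prop_depth_recorded = 0.7,
                         dosrtnf_offset = 7, seed = 1) {
  family <- match.arg(family)
  stopifnot(n_sites >= 2, n_obs_per_site >= 1,
            all(c("genus", "baseline_days", "lit_shift_days") %in%
                  names(genera)),
            all(genera$baseline_days + genera$lit_shift_days > 0),
            matern$sigma2 >= 0, matern$rho_km > 0, matern$nu > 0)
  structure(list(n_sites = n_sites, n_obs_per_site = n_obs_per_site,
                 genera = genera, n_ecoregions = n_ecoregions,
                 ecoregion_sd = ecoregion_sd,
                 latitude_slope = latitude_slope, matern = matern,
                 family = family, target_dispersion = target_dispersion,
                 prop_lit = prop_lit,
                 prop_depth_recorded = prop_depth_recorded,
                 dosrtnf_offset = dosrtnf_offset, seed = seed),
            class = "synth_config")
}

#' Matern correlation function
#'
#' @param d Distances (same units as \code{rho}).
#' @param rho Range parameter.
#' @param nu Smoothness.
#' @return Correlations in [0, 1] (1 at distance 0).
#' @export
matern_correlation <- function(d, rho, nu) {
  out <- array(1, dim = if (is.null(dim(d))) length(d) else dim(d))
  pos <- d > 0
  u <- sqrt(2 * nu) * d[pos] / rho
  out[pos] <- 2^(1 - nu) / gamma(nu) * u^nu * besselK(u, nu)
  if (is.null(dim(d))) out <- as.vector(out)
  out
}

## Great-circle distance matrix, km.
.gc_dist_km <- function(lat, lon) {
  R <- 6371
  n <- length(lat)
  la <- lat * pi / 180; lo <- lon * pi / 180
  m <- matrix(0, n, n)
  for (i in seq_len(n)) {
    dl <- lo - lo[i]
    s <- sin((la - la[i]) / 2)^2 + cos(la[i]) * cos(la) * sin(dl / 2)^2
    m[i, ] <- 2 * R * asin(pmin(1, sqrt(s)))
  }
  m
}

#' Generate spawning sites, exposure assignment, raster and trait table
#'
#' Sites are clustered into ecoregions inside reef latitudes (|lat| <=
#' 32 deg); roughly half are designated artificially lit.  A toy
#' critical-ALAN-depth raster is constructed so that applying the
#' classification rule to it reproduces the intended labels exactly:
#' cells around lit sites carry a critical depth deeper than any
#' generated observation or trait depth, all other cells are 0.  The
#' species trait table provides the minimum-depth fallback.
#'
#' @param cfg \code{\link{synth_config}}.
#' @return List: \code{sites} (site_id, Latitude, Longitude, Ecoregion,
#'   lit, site_effect), \code{raster} (\code{alan_raster}),
#'   \code{traits} (species, lower_depth_m), \code{truth} (true
#'   parameters).
#' @export
gen_sites <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  ## ecoregion cluster centres, then sites jittered around them
  ec_lat <- stats::runif(cfg$n_ecoregions, -30, 30)
  ec_lon <- stats::runif(cfg$n_ecoregions, -175, 175)
  eco <- sort(rep_len(seq_len(cfg$n_ecoregions), cfg$n_sites))
  lat <- pmax(-32, pmin(32, ec_lat[eco] + stats::rnorm(cfg$n_sites, 0, 1.5)))
  lon <- pmax(-179, pmin(179, ec_lon[eco] + stats::rnorm(cfg$n_sites, 0, 1.5)))
  lit <- stats::runif(cfg$n_sites) < cfg$prop_lit

  ## snap each site to a distinct raster cell centre (one-degree cells),
  ## jittered by less than the 0.05-degree buffer radius, so the buffer
  ## around a site always contains exactly its own cell centre
  cs <- 1
  xll <- -180; yll <- -34; nr <- 68; nc <- 360
  col <- pmax(1, pmin(nc, floor((lon - xll) / cs) + 1))
  row <- pmax(1, pmin(nr, nr - floor((lat - yll) / cs)))
  cell <- (row - 1) * nc + col
  for (i in seq_along(cell)) {
    while (cell[i] %in% cell[seq_len(i - 1)]) {
      col[i] <- if (col[i] < nc) col[i] + 1 else 1
      cell[i] <- (row[i] - 1) * nc + col[i]
    }
  }
  lon <- xll + (col - 0.5) * cs + stats::runif(cfg$n_sites, -0.03, 0.03)
  lat <- (yll + (nr - row + 0.5) * cs) + stats::runif(cfg$n_sites, -0.03, 0.03)

  ## Matern Gaussian site field
  if (cfg$matern$sigma2 > 0) {
    D <- .gc_dist_km(lat, lon)
    C <- cfg$matern$sigma2 *
      matern_correlation(D, cfg$matern$rho_km, cfg$matern$nu)
    diag(C) <- cfg$matern$sigma2 + 1e-8
    b <- drop(t(chol(C)) %*% stats::rnorm(cfg$n_sites))
  } else {
    b <- rep(0, cfg$n_sites)
  }

  sites <- data.frame(
    site_id = sprintf("S%03d", seq_len(cfg$n_sites)),
    Latitude = round(lat, 4), Longitude = round(lon, 4),
    Ecoregion = sprintf("ECO%02d", eco), lit = lit, site_effect = b
  )

  ## depth ceiling: every generated obs/trait depth is below this, so a
  ## critical depth of 2 * ceiling guarantees "Lit" at lit sites
  depth_ceiling <- 18
  rast <- list(xll = xll, yll = yll, cellsize = cs, nodata = -9999,
               values = matrix(0, nrow = nr, ncol = nc))
  class(rast) <- "alan_raster"
  rast$values[cbind(row[lit], col[lit])] <- 2 * depth_ceiling

  ## species traits: two species per genus, min depth well under ceiling
  gn <- cfg$genera$genus
  species <- as.vector(t(outer(gn, c("alpha", "beta"), paste, sep = "_")))
  traits <- data.frame(species = species,
                       lower_depth_m = round(stats::runif(length(species),
                                                          1, 8), 1))
  truth <- list(genera = cfg$genera,
                latitude_slope = cfg$latitude_slope,
                matern = cfg$matern,
                ecoregion_sd = cfg$ecoregion_sd,
                depth_ceiling = depth_ceiling,
                dosrtnf_offset = cfg$dosrtnf_offset)
  list(sites = sites, raster = rast, traits = traits, truth = truth,
       depth_ceiling = depth_ceiling)
}

#' Generate the spawning observation table
#'
#' Counts are drawn with log-mean
#' log(baseline_g + shift_g * lit) + slope * DfE_centred + eco_e + b_s,
#' so the marginal lit-minus-unlit difference for genus g is exactly its
#' configured shift in days (at reference covariates).  Signed day
#' offsets are written as count minus the configured constant.
#'
#' @param cfg \code{\link{synth_config}}.
#' @param world Output of \code{\link{gen_sites}}.
#' @return Data frame in the external CSV schema: Site, Latitude,
#'   Longitude, Year, Genus, Species, Depth_m, DoSRtNF, Ecoregion, O_n.
#' @export
gen_observations <- function(cfg, world) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed + 1L)
  sites <- world$sites
  eco_levels <- sort(unique(sites$Ecoregion))
  eco_int <- stats::rnorm(length(eco_levels), 0, cfg$ecoregion_sd)
  eco_int <- eco_int - mean(eco_int)
  names(eco_int) <- eco_levels

  n <- cfg$n_sites * cfg$n_obs_per_site
  si <- rep(seq_len(cfg$n_sites), each = cfg$n_obs_per_site)
  gi <- sample(nrow(cfg$genera), n, replace = TRUE)
  g <- cfg$genera[gi, ]
  dfe <- abs(sites$Latitude[si])
  mu <- (g$baseline_days + g$lit_shift_days * sites$lit[si]) *
    exp(cfg$latitude_slope * (dfe - 16) +
          eco_int[sites$Ecoregion[si]] + sites$site_effect[si])
  y <- if (cfg$family == "poisson") {
    stats::rpois(n, mu)
  } else {
    ## binomial thinning: Binom(round(mu/p), p) has variance ~ (1-p) mu
    p <- 1 - cfg$target_dispersion
    stats::rbinom(n, pmax(1, round(mu / p)), p)
  }
  y <- pmin(y, cfg$dosrtnf_offset + 15)

  has_depth <- stats::runif(n) < cfg$prop_depth_recorded
  depth <- ifelse(has_depth,
                  round(stats::runif(n, 1, world$depth_ceiling - 3), 1), NA)
  species <- paste(g$genus, sample(c("alpha", "beta"), n, TRUE), sep = "_")
  data.frame(
    Site = sites$site_id[si],
    Latitude = sites$Latitude[si], Longitude = sites$Longitude[si],
    Year = sample(2000:2019, n, TRUE),
    Genus = g$genus, Species = species, Depth_m = depth,
    DoSRtNF = as.integer(y - cfg$dosrtnf_offset),
    Ecoregion = sites$Ecoregion[si],
    O_n = "in situ"
  )
}

#' Generate and optionally write a complete synthetic dataset
#'
#' @param cfg \code{\link{synth_config}}.
#' @param dir Optional output directory; when given, writes
#'   \code{spawning.csv}, \code{alan.asc}, \code{traits.csv} and
#'   \code{truth.json}.
#' @return List: \code{observations}, \code{sites}, \code{raster},
#'   \code{traits}, \code{truth}.
#' @export
gen_dataset <- function(cfg = synth_config(), dir = NULL) {
  world <- gen_sites(cfg)
  obs <- gen_observations(cfg, world)
  out <- list(observations = obs, sites = world$sites,
              raster = world$raster, traits = world$traits,
              truth = world$truth)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    utils::write.csv(obs, file.path(dir, "spawning.csv"), row.names = FALSE)
    write_asc_raster(world$raster, file.path(dir, "alan.asc"))
    utils::write.csv(world$traits, file.path(dir, "traits.csv"),
                     row.names = FALSE)
    jsonlite::write_json(world$truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(out)
}
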