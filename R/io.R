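## Readers and writers: spawning-observation CSV, species trait CSV,
## ESRI ASCII-grid rasters, and run outputs.  All coordinates are decimal
## degrees WGS84; raster sampling uses cell-centre containment.  Writes
## are atomic (temp file + rename).

#' Read a critical-ALAN-depth raster (ESRI ASCII grid)
#'
#' Plain-text georeferenced raster: a six-line header (ncols, nrows,
#' xllcorner, yllcorner, cellsize, NODATA_value) followed by rows of cell
#' values, north to south.
#'
#' @param path File path.
#' @return Object of class \code{alan_raster}: \code{values} (matrix,
#'   rows north to south, NA for no-data), \code{xll}, \code{yll},
#'   \code{cellsize}, \code{nodata}.
#' @export
read_asc_raster <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, n = 6)
  hdr <- list()
  for (ln in lines) {
    kv <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(kv) != 2) stop("malformed ASCII-grid header line: ", ln)
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "nodata_value")
  miss <- setdiff(need, names(hdr))
  if (length(miss)) stop("ASCII-grid header missing: ",
                         paste(miss, collapse = ", "))
  vals <- scan(path, skip = 6, quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    stop(sprintf("expected %d cell values, found %d",
                 hdr$ncols * hdr$nrows, length(vals)))
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m[m == hdr$nodata_value] <- NA
  structure(list(values = m, xll = hdr$xllcorner, yll = hdr$yllcorner,
                 cellsize = hdr$cellsize, nodata = hdr$nodata_value),
            class = "alan_raster")
}

#' @rdname read_asc_raster
#' @param raster \code{alan_raster} to write.
#' @export
write_asc_raster <- function(raster, path) {
  stopifnot(inherits(raster, "alan_raster"))
  m <- raster$values
  m[is.na(m)] <- raster$nodata
  tmp <- paste0(path, ".tmp")
  con <- file(tmp, "w")
  on.exit(close(con), add = TRUE)
  writeLines(c(
    paste("ncols", ncol(m)), paste("nrows", nrow(m)),
    paste("xllcorner", raster$xll), paste("yllcorner", raster$yll),
    paste("cellsize", raster$cellsize),
    paste("NODATA_value", raster$nodata)), con)
  utils::write.table(m, con, row.names = FALSE, col.names = FALSE)
  close(con)
  on.exit()
  file.rename(tmp, path)
  invisible(path)
}

#' @export
print.alan_raster <- function(x, ...) {
  cat(sprintf("<alan_raster> %d x %d cells of %g deg, origin (%g, %g)\n",
              nrow(x$values), ncol(x$values), x$cellsize, x$xll, x$yll))
  invisible(x)
}

#' Read a spawning-observation table
#'
#' Validates the external CSV schema and rejects malformed rows with
#' line-numbered messages.
#'
#' @param path CSV with columns Latitude, Longitude, Year, Genus,
#'   Species, Depth_m, DoSRtNF, Ecoregion, O_n ("in situ" / "ex situ").
#' @param max_abs_dosrtnf Rows with |DoSRtNF| above this are rejected.
#' @return Data frame with the source columns plus logical
#'   \code{in_situ}; rejected row numbers are reported in a message and
#'   recorded in attribute \code{rejected}.
#' @export
read_spawning_csv <- function(path, max_abs_dosrtnf = 15) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!nrow(tab)) stop("empty spawning table: ", path)
  need <- c("Latitude", "Longitude", "Year", "Genus", "Species",
            "Depth_m", "DoSRtNF", "Ecoregion", "O_n")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("missing required column(s): ",
                         paste(miss, collapse = ", "))
  bad <- !is.finite(tab$Latitude) | abs(tab$Latitude) > 90 |
    !is.finite(tab$Longitude) | abs(tab$Longitude) > 180 |
    !is.finite(tab$Year) |
    !is.finite(tab$DoSRtNF) | abs(tab$DoSRtNF) > max_abs_dosrtnf |
    (!is.na(tab$Depth_m) & tab$Depth_m < 0) |
    is.na(tab$Genus) | tab$Genus == "" |
    !(tab$O_n %in% c("in situ", "ex situ"))
  if (any(bad))
    message(sprintf("rejecting %d malformed row(s) at line(s): %s",
                    sum(bad),
                    paste(utils::head(which(bad) + 1, 20), collapse = ", ")))
  out <- tab[!bad, , drop = FALSE]
  if (!nrow(out)) stop("no valid rows in ", path)
  out$in_situ <- out$O_n == "in situ"
  attr(out, "rejected") <- which(bad)
  out
}

#' Read a species trait table
#'
#' @param path CSV with columns \code{species} and \code{lower_depth_m}
#'   (the minimum depth at which the species is found).
#' @return Data frame (species, lower_depth_m), one row per species.
#' @export
read_traits <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "lower_depth_m")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("missing required column(s): ",
                         paste(miss, collapse = ", "))
  bad <- is.na(tab$lower_depth_m) | tab$lower_depth_m < 0
  if (any(bad))
    message(sprintf("dropping %d trait row(s) with invalid depths", sum(bad)))
  tab <- tab[!bad, , drop = FALSE]
  tab[!duplicated(tab$species), , drop = FALSE]
}

#' Write a timeline to CSV
#'
#' Columns utc, solar, twilight, lunar, alan, floor, total (uW m^-2).
#' @param tl \code{light_timeline}.
#' @param path Output path.
#' @export
write_timeline_csv <- function(tl, path) {
  stopifnot(inherits(tl, "light_timeline"))
  out <- data.frame(utc = format(tl$time, "%Y-%m-%dT%H:%M:%SZ"),
                    solar = tl$solar, twilight = tl$twilight,
                    lunar = tl$lunar, alan = tl$alan, floor = tl$floor,
                    total = tl$total)
  tmp <- paste0(path, ".tmp")
  utils::write.csv(out, tmp, row.names = FALSE)
  file.rename(tmp, path)
  invisible(path)
}

#' Write pipeline outputs with their resolved configuration
#'
#' Writes whichever results are supplied (model ranking CSV, contrast
#' table CSV, fit summary JSON, filter audit CSV) together with the
#' resolved configuration and seed, so any output directory is
#' reproducible from its own contents.
#'
#' @param dir Output directory (created if needed).
#' @param config Named list of run settings (must include any seed used).
#' @param ranking Optional \code{spawn_model_ranking}.
#' @param contrasts Optional contrast table.
#' @param fit Optional \code{spawn_fit}.
#' @param audit Optional filter audit data frame.
#' @return Invisibly, the paths written.
#' @export
write_outputs <- function(dir, config, ranking = NULL, contrasts = NULL,
                          fit = NULL, audit = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character()
  wr_csv <- function(x, name) {
    p <- file.path(dir, name); tmp <- paste0(p, ".tmp")
    utils::write.csv(as.data.frame(x), tmp, row.names = FALSE)
    file.rename(tmp, p); paths <<- c(paths, p)
  }
  p <- file.path(dir, "config.json"); tmp <- paste0(p, ".tmp")
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  file.rename(tmp, p); paths <- c(paths, p)
  if (!is.null(ranking)) wr_csv(ranking, "model_ranking.csv")
  if (!is.null(contrasts)) wr_csv(contrasts, "genus_contrasts.csv")
  if (!is.null(audit)) wr_csv(audit, "filter_audit.csv")
  if (!is.null(fit)) {
    s <- list(fixed_terms = fit$fixed_terms, loglik = fit$loglik,
              aic = fit$aic, k = fit$k, dispersion = fit$dispersion,
              converged = fit$converged,
              matern = as.list(fit$matern),
              coefficients = as.list(fit$coefficients),
              offset = if (!is.null(fit$offset_record))
                fit$offset_record$offset else NULL)
    p <- file.path(dir, "fit_summary.json"); tmp <- paste0(p, ".tmp")
    jsonlite::write_json(s, tmp, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    file.rename(tmp, p); paths <- c(paths, p)
  }
  invisible(paths)
}
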