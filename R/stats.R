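## Spawning-timing inference pipeline: exposure classification, site
## covariates, the spatially autocorrelated Poisson mixed model, nested
## model selection by AIC, likelihood-ratio tests, and per-genus
## lit-versus-unlit contrasts.

## ---- exposure classification -------------------------------------------

#' Classify observations by underwater light-pollution exposure
#'
#' An observation is "Lit" when the critical depth of biologically
#' important artificial light exceeds the reference depth: the recorded
#' observation depth, or, when none was recorded, the minimum depth at
#' which the species is found.  Observations with neither depth are
#' unclassifiable (NA).
#'
#' @param critical_alan_depth Critical ALAN depth at the site, m (0 allowed).
#' @param obs_depth Observation depth, m, or NA.
#' @param trait_min_depth Species minimum depth, m, or NA.
#' @return Factor with levels c("Unlit", "Lit") (NA when no reference
#'   depth exists).
#' @examples
#' classify_exposure(10, 5, NA)    # Lit
#' classify_exposure(0, 5, NA)     # Unlit
#' classify_exposure(4, NA, 3)     # Lit via the trait fallback
#' @export
classify_exposure <- function(critical_alan_depth, obs_depth = NA,
                              trait_min_depth = NA) {
  n <- max(length(critical_alan_depth), length(obs_depth),
           length(trait_min_depth))
  cad <- rep_len(critical_alan_depth, n)
  od <- rep_len(obs_depth, n)
  td <- rep_len(trait_min_depth, n)
  ref <- ifelse(!is.na(od), od, td)
  out <- ifelse(is.na(ref) | is.na(cad), NA_character_,
                ifelse(cad > ref, "Lit", "Unlit"))
  factor(out, levels = c("Unlit", "Lit"))
}

## ---- raster buffer means -----------------------------------------------

#' Mean raster value inside a circular degree-space buffer
#'
#' Unweighted mean of the cells whose centres fall inside a circle of
#' \code{radius_deg} degrees around the point; no-data cells are
#' excluded.
#'
#' @param raster An \code{alan_raster} (see \code{\link{read_asc_raster}}).
#' @param lat,lon Point coordinates, decimal degrees WGS84.
#' @param radius_deg Buffer radius in degrees (default 0.05).
#' @return Mean cell value, or NA (with a warning) when every cell in the
#'   buffer is no-data.
#' @export
buffer_mean <- function(raster, lat, lon, radius_deg = 0.05) {
  stopifnot(inherits(raster, "alan_raster"))
  xmax <- raster$xll + ncol(raster$values) * raster$cellsize
  ymax <- raster$yll + nrow(raster$values) * raster$cellsize
  if (lon < raster$xll || lon > xmax || lat < raster$yll || lat > ymax)
    stop(sprintf("point (%.4f, %.4f) lies outside the raster extent", lat, lon))
  xc <- raster$xll + (seq_len(ncol(raster$values)) - 0.5) * raster$cellsize
  yc <- ymax - (seq_len(nrow(raster$values)) - 0.5) * raster$cellsize
  dx2 <- outer(rep(1, nrow(raster$values)), (xc - lon)^2)
  dy2 <- outer((yc - lat)^2, rep(1, ncol(raster$values)))
  sel <- (dx2 + dy2) <= radius_deg^2
  v <- raster$values[sel]
  v <- v[!is.na(v)]
  if (!length(v)) {
    warning("all cells inside the buffer are no-data")
    return(NA_real_)
  }
  mean(v)
}

## ---- median-regression trends ------------------------------------------

#' Slope of the median (L1) regression line
#'
#' The tau = 0.5 quantile-regression line, i.e. the line minimising the
#' sum of absolute residuals; used for yearly climate-trend estimates
#' because it resists outlying years.  Solved exactly by enumerating the
#' candidate lines through pairs of points (an optimal L1 line always
#' interpolates at least two observations).
#'
#' @param year Numeric predictor (e.g. calendar years).
#' @param value Numeric response.
#' @return Slope per unit of \code{year}; NA (with a message) when fewer
#'   than 3 points are available.
#' @examples
#' median_trend(2003:2022, 2 * (2003:2022) + 1)   # exactly 2
#' @export
median_trend <- function(year, value) {
  ok <- is.finite(year) & is.finite(value)
  year <- year[ok]; value <- value[ok]
  if (length(year) < 3) {
    message("median_trend: fewer than 3 points; trend undefined")
    return(NA_real_)
  }
  n <- length(year)
  best_obj <- Inf; best_slope <- NA_real_
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    if (year[j] == year[i]) next
    b <- (value[j] - value[i]) / (year[j] - year[i])
    a <- value[i] - b * year[i]
    obj <- sum(abs(value - (a + b * year)))
    if (obj < best_obj - 1e-12 ||
        (obj < best_obj + 1e-12 && abs(b) < abs(best_slope))) {
      best_obj <- obj; best_slope <- b
    }
  }
  best_slope
}

## ---- filtering ----------------------------------------------------------

#' Apply the observation filters with an audit log
#'
#' Retains in-situ observations from the 21st century (year >= 2000), then
#' drops genera with fewer than six observations in either exposure level
#' and ecoregions with fewer than six observations, re-applying the two
#' count rules until no further rows are removed.  Rows with an
#' unclassifiable exposure are removed first.
#'
#' @param tab Data frame with columns \code{Genus}, \code{Ecoregion},
#'   \code{Year}, \code{in_situ} (logical) and \code{exposure} (factor
#'   Unlit/Lit).
#' @param min_per_level Count threshold (default 6).
#' @return The filtered data frame, with an \code{audit} attribute: a data
#'   frame of (pass, rule, removed) rows.  Errors when nothing survives.
#' @export
apply_filters <- function(tab, min_per_level = 6) {
  if (!"in_situ" %in% names(tab) && "O_n" %in% names(tab))
    tab$in_situ <- tab$O_n == "in situ"
  need <- c("Genus", "Ecoregion", "Year", "in_situ", "exposure")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  audit <- list()
  note <- function(pass, rule, removed)
    audit[[length(audit) + 1]] <<- data.frame(pass = pass, rule = rule,
                                              removed = removed)
  n0 <- nrow(tab)
  tab <- tab[!is.na(tab$exposure), , drop = FALSE]
  note(0, "unclassifiable exposure", n0 - nrow(tab))
  n0 <- nrow(tab)
  tab <- tab[tab$in_situ, , drop = FALSE]
  note(0, "ex situ", n0 - nrow(tab))
  n0 <- nrow(tab)
  tab <- tab[tab$Year >= 2000, , drop = FALSE]
  note(0, "pre-2000", n0 - nrow(tab))

  pass <- 0
  repeat {
    pass <- pass + 1
    n_before <- nrow(tab)
    cnt <- table(tab$Genus, tab$exposure)
    bad_gen <- rownames(cnt)[apply(cnt, 1, min) < min_per_level]
    n0 <- nrow(tab)
    tab <- tab[!(tab$Genus %in% bad_gen), , drop = FALSE]
    note(pass, "genus < 6 per exposure level", n0 - nrow(tab))
    eco_cnt <- table(tab$Ecoregion)
    bad_eco <- names(eco_cnt)[eco_cnt < min_per_level]
    n0 <- nrow(tab)
    tab <- tab[!(tab$Ecoregion %in% bad_eco), , drop = FALSE]
    note(pass, "ecoregion < 6 observations", n0 - nrow(tab))
    if (nrow(tab) == n_before) break
  }
  audit <- do.call(rbind, audit)
  if (!nrow(tab)) {
    print(audit)
    stop("no observations survive the filters")
  }
  tab$Genus <- droplevels(factor(tab$Genus))
  tab$Ecoregion <- droplevels(factor(tab$Ecoregion))
  attr(tab, "audit") <- audit
  tab
}

## ---- positive transform -------------------------------------------------

#' Positive transform of the day-offset response
#'
#' Shifts the signed day offsets to non-negative integers by subtracting
#' the pooled minimum; the offset is recorded so fitted means can be
#' back-transformed.  A fixed alternative offset can be supplied.
#'
#' @param y Integer day offsets.
#' @param offset Optional fixed offset to add instead of \code{-min(y)}.
#' @return List of class \code{positive_transform}: \code{values}
#'   (non-negative integers) and \code{offset} (the constant added to
#'   \code{y}).
#' @export
positive_transform <- function(y, offset = NULL) {
  stopifnot(all(y == round(y)))
  if (is.null(offset)) offset <- -min(y)
  stopifnot(offset == round(offset))
  offset <- as.integer(offset)
  values <- y + offset
  if (any(values < 0)) stop("offset leaves negative values")
  structure(list(values = as.integer(values), offset = offset),
            class = "positive_transform")
}

#' @rdname positive_transform
#' @param pt A \code{positive_transform}.
#' @param values Transformed values (defaults to those stored).
#' @export
back_transform <- function(pt, values = pt$values) {
  stopifnot(inherits(pt, "positive_transform"))
  values - pt$offset
}

## ---- the spatial Poisson mixed model ------------------------------------

## Equirectangular projection to kilometres (units of 100 km for the
## optimiser), adequate over reef latitudes.
.project_km <- function(lon, lat) {
  lat0 <- mean(range(lat))
  cbind(x = lon * 111.320 * cos(lat0 * pi / 180) / 100,
        y = lat * 110.574 / 100)
}

.INTERACTIONS <- c("ALAN:Genus", "ALAN:dSST", "ALAN:dKd490", "ALAN:DfE")
.MAINS <- c("ALAN", "Genus", "dSST", "dKd490", "DfE", "Ecoregion")

#' The global fixed-effect structure of the spawning-timing model
#'
#' ALAN crossed with genus, the sea-surface-temperature trend, the
#' water-clarity trend and distance from the equator, plus an ecoregion
#' main effect.
#' @return Character vector of term labels.
#' @export
global_model_terms <- function() c(.MAINS, .INTERACTIONS)

.terms_to_formula <- function(response, terms) {
  rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
  stats::as.formula(paste(response, "~", rhs))
}

#' Fit the spatially autocorrelated Poisson mixed model
#'
#' Fits a Poisson generalized linear mixed model to the
#' positive-transformed day-of-spawning offsets, with a site-level random
#' effect whose covariance follows a Matern correlation function of the
#' projected site coordinates (variance, range and smoothness estimated by
#' maximum likelihood via a Laplace approximation).  With
#' \code{spatial = FALSE} the model reduces to a plain Poisson GLM.
#'
#' @param data Data frame with the response column, the fixed-effect
#'   columns among \code{ALAN}, \code{Genus}, \code{dSST}, \code{dKd490},
#'   \code{DfE}, \code{Ecoregion}, and \code{Longitude}/\code{Latitude}
#'   for the spatial term.
#' @param fixed_terms Character vector of fixed-effect term labels
#'   (default: the global structure).
#' @param response Name of the non-negative integer response column.
#' @param spatial Include the Matern spatial random effect?
#' @param offset_record Optional \code{positive_transform} carried along
#'   so predictions can be reported in days relative to full moon.
#' @param smoothness NULL to estimate the Matern smoothness jointly with
#'   the range (the default), or a fixed positive value.  When the joint
#'   estimate fails to converge the fit falls back to smoothness 1.5
#'   automatically (the profile over smoothness is often flat).
#' @return Object of class \code{spawn_fit}: the underlying model plus
#'   \code{loglik}, \code{aic}, \code{k}, \code{dispersion} (Pearson
#'   chi-square over residual df), \code{matern} (sigma2, range_100km,
#'   smoothness; spatial fits only), \code{converged}, \code{fixed_terms}.
#' @export
fit_glmm <- function(data, fixed_terms = global_model_terms(),
                     response = "y", spatial = TRUE, offset_record = NULL,
                     smoothness = NULL) {
  stopifnot(response %in% names(data))
  y <- data[[response]]
  if (any(y < 0) || any(y != round(y)))
    stop("response must be non-negative integers (positive-transformed)")
  used <- unique(unlist(strsplit(fixed_terms, ":", fixed = TRUE)))
  miss <- setdiff(used, names(data))
  if (length(miss)) stop("missing fixed-effect column(s): ",
                         paste(miss, collapse = ", "))

  if (spatial) {
    stopifnot(all(c("Longitude", "Latitude") %in% names(data)))
    if (length(unique(paste(data$Longitude, data$Latitude))) < 2)
      stop("spatial model needs at least 2 distinct sites")
    xy <- .project_km(data$Longitude, data$Latitude)
    data$..pos <- glmmTMB::numFactor(round(xy[, 1], 4), round(xy[, 2], 4))
    data$..grp <- factor("site_field")
    rhs <- c(fixed_terms, "mat(..pos + 0 | ..grp)")
    fml <- .terms_to_formula(response, rhs)
    ## optimiser chatter near the sigma -> 0 boundary is recorded, not
    ## surfaced as warnings
    notes <- character()
    run <- function(nu_fixed) {
      extra <- if (is.null(nu_fixed)) list() else
        list(map = list(theta = factor(c(1, 2, NA))),
             start = list(theta = c(0, 0, log(nu_fixed))))
      withCallingHandlers(
        do.call(glmmTMB::glmmTMB,
                c(list(fml, data = data, family = stats::poisson()), extra)),
        warning = function(w) {
          notes <<- c(notes, conditionMessage(w))
          invokeRestart("muffleWarning")
        })
    }
    is_ok <- function(f)
      isTRUE(f$fit$convergence == 0) && !isTRUE(f$sdr$pdHess == FALSE) &&
        is.finite(as.numeric(stats::logLik(f)))
    fit <- run(smoothness)
    if (is.null(smoothness) && !is_ok(fit)) {
      notes <- c(notes, "joint smoothness estimate failed; refit at nu = 1.5")
      fit <- run(1.5)
    }
    conv <- is_ok(fit)
    vc <- tryCatch(glmmTMB::VarCorr(fit)$cond[[1]], error = function(e) NULL)
    theta <- fit$fit$parfull[names(fit$fit$parfull) == "theta"]
    matern <- c(sigma2 = if (!is.null(vc)) unname(vc[1, 1]) else NA_real_,
                range_100km = if (length(theta) >= 2)
                  unname(exp(theta[2])) else NA_real_,
                smoothness = if (length(theta) >= 3)
                  unname(exp(theta[3])) else NA_real_)
    mu <- stats::predict(fit, type = "response")
    ll <- as.numeric(stats::logLik(fit))
    k <- attr(stats::logLik(fit), "df")
    n_fixed <- length(glmmTMB::fixef(fit)$cond)
    est <- glmmTMB::fixef(fit)$cond
    se <- tryCatch(sqrt(diag(stats::vcov(fit)$cond)), error = function(e)
      rep(NA_real_, length(est)))
  } else {
    fml <- .terms_to_formula(response, fixed_terms)
    fit <- stats::glm(fml, data = data, family = stats::poisson())
    conv <- fit$converged
    matern <- NULL
    mu <- stats::fitted(fit)
    ll <- as.numeric(stats::logLik(fit))
    k <- attr(stats::logLik(fit), "df")
    n_fixed <- length(stats::coef(fit))
    est <- stats::coef(fit)
    se <- sqrt(diag(stats::vcov(fit)))
  }
  pearson <- sum((y - mu)^2 / pmax(mu, 1e-12))
  structure(list(
    model = fit, formula = fml, fixed_terms = fixed_terms,
    response = response, spatial = spatial,
    coefficients = est, se = se, n_fixed = n_fixed,
    loglik = ll, k = k, aic = -2 * ll + 2 * k,
    dispersion = pearson / max(1, length(y) - k),
    matern = matern, converged = conv,
    notes = if (spatial) notes else character(),
    offset_record = offset_record, n = length(y)
  ), class = "spawn_fit")
}

#' @export
print.spawn_fit <- function(x, ...) {
  cat(sprintf("<spawn_fit> %s Poisson model, n = %d\n",
              if (x$spatial) "spatial (Matern)" else "non-spatial", x$n))
  cat("  fixed terms:", paste(x$fixed_terms, collapse = " + "), "\n")
  cat(sprintf("  logLik %.2f  AIC %.2f  dispersion %.3f  converged: %s\n",
              x$loglik, x$aic, x$dispersion, x$converged))
  if (!is.null(x$matern))
    cat(sprintf("  Matern: sigma2 %.4f  range %.1f (100 km)  smoothness %.2f\n",
                x$matern["sigma2"], x$matern["range_100km"],
                x$matern["smoothness"]))
  invisible(x)
}

#' @export
coef.spawn_fit <- function(object, ...) object$coefficients

#' @export
logLik.spawn_fit <- function(object, ...) {
  structure(object$loglik, df = object$k, class = "logLik")
}

#' @export
summary.spawn_fit <- function(object, ...) summary(object$model, ...)

#' Predicted genus-by-exposure means with spatial effects removed
#'
#' Population-level predictions (random effects set to zero) for every
#' genus under each exposure, at reference values of the remaining
#' covariates; back-transformed to days relative to full moon when the
#' fit carries an offset record.
#'
#' @param object \code{spawn_fit}.
#' @param data The data the model was fitted to (for reference covariate
#'   values and factor levels).
#' @param level Confidence level (default 0.95).
#' @param ... Unused.
#' @return Data frame: Genus, ALAN, mean, lo, hi (response scale; days
#'   when an offset record is present).
#' @export
predict_genus_means <- function(object, data, level = 0.95, ...) {
  stopifnot(inherits(object, "spawn_fit"))
  stopifnot(all(c("Genus", "ALAN") %in% names(data)))
  grid <- expand.grid(Genus = levels(factor(data$Genus)),
                      ALAN = levels(factor(data$ALAN)))
  for (v in c("dSST", "dKd490", "DfE"))
    if (v %in% names(data)) grid[[v]] <- mean(data[[v]])
  if ("Ecoregion" %in% names(data)) {
    lv <- levels(factor(data$Ecoregion))
    grid$Ecoregion <- factor(lv[1], levels = lv)
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  if (object$spatial) {
    grid$..pos <- data$..pos[1]
    grid$..grp <- data$..grp[1]
    pr <- stats::predict(object$model, newdata = grid, re.form = NA,
                         se.fit = TRUE, type = "link")
  } else {
    pr <- stats::predict(object$model, newdata = grid, se.fit = TRUE,
                         type = "link")
  }
  off <- if (!is.null(object$offset_record)) object$offset_record$offset else 0
  out <- grid[c("Genus", "ALAN")]
  out$mean <- exp(pr$fit) - off
  out$lo <- exp(pr$fit - z * pr$se.fit) - off
  out$hi <- exp(pr$fit + z * pr$se.fit) - off
  out
}

#' Per-genus lit-shift estimates from a mixed-model fit
#'
#' Extracts the lit-minus-unlit shift for every genus from a fit whose
#' fixed structure includes \code{ALAN}, \code{Genus} and
#' \code{ALAN:Genus}, on the response scale (days at the genus's unlit
#' mean, population level), with Wald confidence intervals.  Unlike the
#' independent per-genus models of \code{\link{genus_contrasts}}, these
#' intervals inherit the model's site-level random effect and therefore
#' account for between-site variation.
#'
#' @param fit \code{spawn_fit} with ALAN, Genus and ALAN:Genus among its
#'   fixed terms.
#' @param level Confidence level (default 0.95).
#' @return Data frame: genus, shift_days, lo, hi.
#' @export
genus_shift_ci <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "spawn_fit"),
            all(c("ALAN", "Genus", "ALAN:Genus") %in% fit$fixed_terms))
  est <- fit$coefficients
  V <- if (fit$spatial) stats::vcov(fit$model)$cond else
    stats::vcov(fit$model)
  nm <- names(est)
  genus_nm <- sub("^Genus", "", grep("^Genus", nm, value = TRUE))
  genera <- c("(reference)", genus_nm)
  z <- stats::qnorm(1 - (1 - level) / 2)
  rows <- lapply(seq_along(genera), function(i) {
    g <- genera[i]
    wa <- wc <- rep(0, length(est)); names(wa) <- names(wc) <- nm
    wa["(Intercept)"] <- 1
    wc["ALANLit"] <- 1
    if (i > 1) {
      wa[paste0("Genus", g)] <- 1
      wc[paste0("ALANLit:Genus", g)] <- 1
    }
    a <- sum(wa * est)            # log unlit mean
    cc <- sum(wc * est)           # log lit/unlit ratio
    shift <- exp(a) * (exp(cc) - 1)
    ## full delta method: d shift/d beta = shift * wa + exp(a + cc) * wc
    grad <- shift * wa + exp(a + cc) * wc
    se <- sqrt(drop(t(grad) %*% V %*% grad))
    data.frame(genus = g, shift_days = shift,
               lo = shift - z * se, hi = shift + z * se)
  })
  out <- do.call(rbind, rows)
  ## name the reference level from the data stored in the model frame
  mf <- stats::model.frame(fit$model)
  if ("Genus" %in% names(mf))
    out$genus[1] <- levels(factor(mf$Genus))[1]
  out
}

## ---- model enumeration and selection ------------------------------------

#' Enumerate all nested versions of a fixed-effect structure
#'
#' Every subset of the given terms; with \code{marginality = TRUE}
#' (default) only subsets in which each interaction is accompanied by both
#' of its main effects.
#'
#' @param terms Character vector of term labels (mains and
#'   \code{a:b} interactions).
#' @param marginality Enforce marginality?
#' @return List of character vectors (one per model, smallest first; the
#'   first element is the intercept-only model).
#' @export
enumerate_models <- function(terms = global_model_terms(),
                             marginality = TRUE) {
  n <- length(terms)
  stopifnot(n <= 20)
  out <- list()
  for (mask in 0:(2^n - 1)) {
    sel <- terms[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0]
    if (marginality) {
      ok <- TRUE
      for (tm in sel[grepl(":", sel, fixed = TRUE)]) {
        parts <- strsplit(tm, ":", fixed = TRUE)[[1]]
        if (!all(parts %in% sel)) { ok <- FALSE; break }
      }
      if (!ok) next
    }
    out[[length(out) + 1]] <- sel
  }
  out[order(vapply(out, length, integer(1)))]
}

#' Rank all nested models by AIC
#'
#' Fits every marginality-respecting nested version of the global
#' fixed-effect structure (the random term, when present, is retained in
#' every model) and ranks them by AIC, with Akaike weights and the
#' cumulative weight.
#'
#' @inheritParams fit_glmm
#' @param global_terms The global fixed structure to enumerate.
#' @param marginality Enforce marginality in the enumeration.
#' @param progress Print a dot per fitted model?
#' @return Data frame of class \code{spawn_model_ranking}: model (label),
#'   n_terms, k, loglik, AIC, dAIC, weight, cum_weight, converged,
#'   ordered by AIC; failed fits carry NA and sort last.  The fitted
#'   \code{spawn_fit} objects are attached as attribute \code{fits} (in
#'   ranking order).
#' @export
select_model <- function(data, global_terms = global_model_terms(),
                         response = "y", spatial = TRUE,
                         marginality = TRUE, progress = FALSE) {
  models <- enumerate_models(global_terms, marginality)
  fits <- vector("list", length(models))
  rows <- vector("list", length(models))
  for (i in seq_along(models)) {
    tm <- models[[i]]
    label <- if (length(tm)) paste(tm, collapse = " + ") else "(intercept)"
    f <- tryCatch(fit_glmm(data, tm, response, spatial),
                  error = function(e) e)
    if (inherits(f, "error")) {
      rows[[i]] <- data.frame(model = label, n_terms = length(tm),
                              k = NA, loglik = NA, AIC = NA,
                              converged = FALSE)
    } else {
      fits[[i]] <- f
      rows[[i]] <- data.frame(model = label, n_terms = length(tm),
                              k = f$k, loglik = f$loglik, AIC = f$aic,
                              converged = f$converged)
    }
    if (progress) cat(".")
  }
  if (progress) cat("\n")
  tab <- do.call(rbind, rows)
  ord <- order(tab$AIC, na.last = TRUE)
  tab <- tab[ord, ]
  fits <- fits[ord]
  tab$dAIC <- tab$AIC - min(tab$AIC, na.rm = TRUE)
  w <- exp(-tab$dAIC / 2)
  tab$weight <- w / sum(w, na.rm = TRUE)
  tab$cum_weight <- cumsum(ifelse(is.na(tab$weight), 0, tab$weight))
  rownames(tab) <- NULL
  attr(tab, "fits") <- fits
  class(tab) <- c("spawn_model_ranking", "data.frame")
  tab
}

## ---- likelihood-ratio test ----------------------------------------------

#' Likelihood-ratio test between nested fits
#'
#' @param nested,full \code{spawn_fit} objects; the fixed terms of
#'   \code{nested} must be a subset of those of \code{full}.
#' @return List: \code{chisq} (2 * difference in log-likelihood, floored
#'   at 0), \code{df} (difference in estimated fixed-effect coefficients)
#'   and \code{p} (upper chi-square tail; 1 when df = 0).
#' @examples
#' \dontrun{lrt(fit_null, fit_selected)}
#' @export
lrt <- function(nested, full) {
  stopifnot(inherits(nested, "spawn_fit"), inherits(full, "spawn_fit"))
  if (!all(nested$fixed_terms %in% full$fixed_terms))
    stop("models are not nested (fixed terms of `nested` must be a subset)")
  chisq <- max(0, 2 * (full$loglik - nested$loglik))
  df <- full$n_fixed - nested$n_fixed
  p <- if (df <= 0) {
    if (chisq == 0) 1 else NA_real_
  } else {
    stats::pchisq(chisq, df, lower.tail = FALSE)
  }
  list(chisq = chisq, df = df, p = p)
}

#' Reverse-stepwise term tests
#'
#' Likelihood-ratio test for each term of a fit: the term (and, for main
#' effects, any interaction containing it) is dropped and the reduced
#' model refitted.
#'
#' @param fit \code{spawn_fit}.
#' @param data The data the model was fitted to.
#' @return Data frame: term, chisq, df, p.
#' @export
term_tests <- function(fit, data) {
  stopifnot(inherits(fit, "spawn_fit"))
  out <- lapply(fit$fixed_terms, function(tm) {
    drop <- fit$fixed_terms == tm
    if (!grepl(":", tm, fixed = TRUE)) {
      drop <- drop | vapply(fit$fixed_terms, function(t2)
        tm %in% strsplit(t2, ":", fixed = TRUE)[[1]], logical(1))
    }
    red <- fit_glmm(data, fit$fixed_terms[!drop], fit$response, fit$spatial)
    tt <- lrt(red, fit)
    data.frame(term = tm, chisq = tt$chisq, df = tt$df, p = tt$p)
  })
  do.call(rbind, out)
}

## ---- per-genus contrasts -------------------------------------------------

#' Per-genus lit-versus-unlit contrasts
#'
#' Fits an independent Poisson model per genus (negative binomial when the
#' Poisson Pearson dispersion exceeds \code{nb_threshold}) of the
#' positive-transformed response on exposure, and reports the modeled
#' lit and unlit means, their difference in days, Wald confidence
#' intervals at the 95% and 90% levels, and the unadjusted p-value of the
#' pairwise comparison.
#'
#' @param data Data frame with columns \code{Genus}, \code{ALAN}
#'   (factor Unlit/Lit) and the response.
#' @param response Name of the non-negative integer response column.
#' @param offset_record Optional \code{positive_transform} for reporting
#'   means in days relative to full moon.
#' @param nb_threshold Pearson-dispersion cutoff above which the negative
#'   binomial family replaces the Poisson (default 1.5).
#' @return Data frame: genus, n_unlit, n_lit, family, dispersion,
#'   mean_unlit, mean_lit, shift_days (lit - unlit),
#'   ci95_lo/ci95_hi, ci90_lo/ci90_hi (on shift_days), p.
#' @export
genus_contrasts <- function(data, response = "y", offset_record = NULL,
                            nb_threshold = 1.5) {
  stopifnot(all(c("Genus", "ALAN") %in% names(data)),
            response %in% names(data))
  data$ALAN <- factor(data$ALAN, levels = c("Unlit", "Lit"))
  off <- if (!is.null(offset_record)) offset_record$offset else 0
  out <- lapply(levels(factor(data$Genus)), function(g) {
    d <- data[data$Genus == g, , drop = FALSE]
    fml <- stats::as.formula(paste(response, "~ ALAN"))
    fit <- stats::glm(fml, data = d, family = stats::poisson())
    mu <- stats::fitted(fit)
    yv <- d[[response]]
    disp <- sum((yv - mu)^2 / pmax(mu, 1e-12)) /
      max(1, nrow(d) - length(stats::coef(fit)))
    fam <- "poisson"
    if (disp > nb_threshold) {
      fit <- tryCatch(MASS::glm.nb(fml, data = d), error = function(e) fit)
      fam <- if (inherits(fit, "negbin")) "negative binomial" else "poisson"
    }
    cf <- summary(fit)$coefficients
    beta <- cf["ALANLit", "Estimate"]
    se <- cf["ALANLit", "Std. Error"]
    p <- cf["ALANLit", ncol(cf)]
    mu_unlit <- exp(stats::coef(fit)[["(Intercept)"]])
    mu_lit <- mu_unlit * exp(beta)
    shift <- mu_lit - mu_unlit
    ci <- function(lv) {
      z <- stats::qnorm(1 - (1 - lv) / 2)
      mu_unlit * (exp(beta + c(-1, 1) * z * se) - 1)
    }
    c95 <- ci(0.95); c90 <- ci(0.90)
    data.frame(genus = g,
               n_unlit = sum(d$ALAN == "Unlit"), n_lit = sum(d$ALAN == "Lit"),
               family = fam, dispersion = disp,
               mean_unlit = mu_unlit - off, mean_lit = mu_lit - off,
               shift_days = shift,
               ci95_lo = c95[1], ci95_hi = c95[2],
               ci90_lo = c90[1], ci90_hi = c90[2], p = p)
  })
  do.call(rbind, out)
}

## ---- site covariates ------------------------------------------------------

#' Build per-observation site covariates and exposure labels
#'
#' Extracts the critical ALAN depth for each observation from the raster
#' (0.05-degree buffer mean), classifies exposure with the trait-table
#' fallback for missing observation depths, and adds distance from the
#' equator.  Optional yearly climate series are converted to per-site
#' median-regression trends.
#'
#' @param obs Observation table from \code{\link{read_spawning_csv}}.
#' @param raster \code{alan_raster} of critical ALAN depth, m.
#' @param traits Data frame (species, lower_depth_m) from
#'   \code{\link{read_traits}}.
#' @param climate Optional long data frame (Latitude, Longitude, year,
#'   sst, kd490) of yearly site values.
#' @param radius_deg Buffer radius, degrees.
#' @return \code{obs} with added columns \code{critical_alan_depth},
#'   \code{exposure}, \code{ALAN} (alias of exposure), \code{DfE}, and,
#'   when \code{climate} is given, \code{dSST}, \code{dKd490}.
#' @export
build_site_covariates <- function(obs, raster, traits, climate = NULL,
                                  radius_deg = 0.05) {
  key <- paste(obs$Latitude, obs$Longitude)
  sites <- !duplicated(key)
  cad <- vapply(which(sites), function(i)
    buffer_mean(raster, obs$Latitude[i], obs$Longitude[i], radius_deg),
    numeric(1))
  names(cad) <- key[sites]
  obs$critical_alan_depth <- unname(cad[key])
  tmap <- stats::setNames(traits$lower_depth_m, traits$species)
  obs$exposure <- classify_exposure(obs$critical_alan_depth, obs$Depth_m,
                                    unname(tmap[obs$Species]))
  obs$ALAN <- obs$exposure
  obs$DfE <- abs(obs$Latitude)
  if (!is.null(climate)) {
    ckey <- paste(climate$Latitude, climate$Longitude)
    tr_sst <- tapply(seq_len(nrow(climate)), ckey, function(ii)
      median_trend(climate$year[ii], climate$sst[ii]))
    tr_kd <- tapply(seq_len(nrow(climate)), ckey, function(ii)
      median_trend(climate$year[ii], climate$kd490[ii]))
    obs$dSST <- unname(tr_sst[key])
    obs$dKd490 <- unname(tr_kd[key])
  }
  obs
}
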