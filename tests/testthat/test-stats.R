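test_that("exposure classification follows the critical-depth rule", {
  expect_identical(as.character(classify_exposure(10, 5, NA)), "Lit")
  expect_identical(as.character(classify_exposure(0, 5, NA)), "Unlit")
  expect_identical(as.character(classify_exposure(0, 0, NA)), "Unlit")
  # fallback to the species minimum depth when no depth was recorded
  expect_identical(as.character(classify_exposure(4, NA, 3)), "Lit")
  expect_identical(as.character(classify_exposure(2, NA, 3)), "Unlit")
  # no reference depth at all: unclassifiable
  expect_true(is.na(classify_exposure(4, NA, NA)))
  # recorded depth takes precedence over the trait
  expect_identical(as.character(classify_exposure(4, 5, 1)), "Unlit")
})

test_that("classification is a pure function: permuting rows permutes labels", {
  set.seed(1)
  n <- 200
  cad <- runif(n, 0, 20)
  od <- ifelse(runif(n) < 0.7, runif(n, 0, 15), NA)
  td <- runif(n, 0, 10)
  lab <- classify_exposure(cad, od, td)
  p <- sample(n)
  expect_identical(classify_exposure(cad[p], od[p], td[p]), lab[p])
})

test_that("buffer means average the cell centres inside the circle", {
  r <- structure(list(values = matrix(2, 10, 10), xll = 0, yll = 0,
                      cellsize = 0.02, nodata = -9999),
                 class = "alan_raster")
  expect_equal(buffer_mean(r, 0.1, 0.1), 2)
  # half zero, half two inside the buffer
  r2 <- r
  r2$values[, 1:5] <- 0   # west half
  expect_equal(buffer_mean(r2, lat = 0.1, lon = 0.1), 1)
  expect_error(buffer_mean(r, 5, 5), "outside")
  r3 <- r
  r3$values[] <- NA
  expect_warning(v <- buffer_mean(r3, 0.1, 0.1), "no-data")
  expect_true(is.na(v))
})

test_that("median trend recovers exact lines and resists gross outliers", {
  yrs <- 2003:2022
  expect_equal(median_trend(yrs, 2 * yrs + 1), 2)
  expect_equal(median_trend(yrs, rep(4.2, 20)), 0)
  y <- yrs - 2000
  y[7] <- y[7] + 100
  expect_lt(abs(median_trend(yrs, y) - 1), 0.05)
  # the pair-enumeration optimum is no worse than a numerical L1 search
  obj <- function(ab) sum(abs(y - ab[1] - ab[2] * (yrs - 2012)))
  num <- optim(c(mean(y), 1), obj, method = "Nelder-Mead")
  b <- median_trend(yrs, y)
  a <- median(y - b * yrs)
  expect_lte(sum(abs(y - a - b * yrs)), num$value + 1e-6)
  expect_message(v <- median_trend(2003:2004, c(1, 2)), "fewer than 3")
  expect_true(is.na(v))
})

test_that("the observation filters drop the documented cases and log counts", {
  mk <- function(genus, n, expo, year = 2010, situ = "in situ",
                 eco = "ECO1") {
    data.frame(Genus = genus, Ecoregion = eco, Year = year,
               O_n = situ, exposure = factor(expo, c("Unlit", "Lit")))
  }
  tab <- rbind(
    mk("A", 6, rep("Lit", 6)), mk("A", 6, rep("Unlit", 6)),
    mk("B", 6, rep("Lit", 6)), mk("B", 5, rep("Unlit", 5)),
    mk("A", 1, "Lit", year = 1999),
    mk("A", 1, "Lit", situ = "ex situ"))
  out <- apply_filters(tab)
  expect_false("B" %in% out$Genus)
  expect_true(all(out$Year >= 2000))
  expect_true(all(out$in_situ))
  expect_equal(nrow(out), 12)
  audit <- attr(out, "audit")
  expect_equal(audit$removed[audit$rule == "ex situ"], 1)
  expect_equal(audit$removed[audit$rule == "pre-2000"], 1)
  expect_equal(sum(audit$removed[grepl("genus", audit$rule)]), 11)
  expect_error(apply_filters(mk("Z", 1, "Lit", year = 1980)), "survive")
})

test_that("filters re-apply to convergence when rules interact", {
  # dropping a sparse ecoregion pushes a genus below the 6+6 rule
  mk <- function(genus, expo, eco, n) {
    data.frame(Genus = rep(genus, n), Ecoregion = rep(eco, n),
               Year = 2010, O_n = "in situ",
               exposure = factor(rep(expo, n), c("Unlit", "Lit")))
  }
  tab <- rbind(
    mk("A", "Lit", "big", 6), mk("A", "Unlit", "big", 4),
    mk("A", "Unlit", "small", 2),
    mk("C", "Lit", "big", 8), mk("C", "Unlit", "big", 8))
  # pass 1: ecoregion "small" (2 obs) is dropped; pass 2: genus A now has
  # only 4 unlit observations and must go too
  out <- apply_filters(tab)
  expect_identical(sort(unique(as.character(out$Genus))), "C")
  expect_equal(nrow(out), 16)
})

test_that("the positive transform is an exact round trip", {
  y <- c(-7L, -2L, 0L, 3L, 11L)
  pt <- positive_transform(y)
  expect_true(all(pt$values >= 0))
  expect_identical(min(pt$values), 0L)
  expect_identical(back_transform(pt), y)
  pt2 <- positive_transform(y, offset = 15)
  expect_identical(back_transform(pt2), y)
  expect_identical(pt2$values, y + 15L)
})

test_that("an intercept-only Poisson fit returns the sample mean exactly", {
  set.seed(3)
  d <- data.frame(y = rpois(200, 6.5))
  fit <- fit_glmm(d, character(0), response = "y", spatial = FALSE)
  expect_equal(unname(exp(coef(fit)[1])), mean(d$y), tolerance = 1e-8)
  expect_equal(fit$aic, -2 * fit$loglik + 2 * fit$k)
})

test_that("with no spatial variance the mixed model agrees with a plain GLM", {
  st <- small_study(seed = 11, n_sites = 25, n_obs = 40, ecoregion_sd = 0,
                    matern = list(nu = 1.5, rho_km = 400, sigma2 = 0))
  terms <- c("ALAN", "Genus", "DfE")
  mixed <- fit_glmm(st$data, terms, response = "y", spatial = TRUE)
  plain <- glm(y ~ ALAN + Genus + DfE, data = st$data, family = poisson())
  expect_lte(mixed$matern[["sigma2"]], 0.05)
  expect_equal(mixed$loglik, as.numeric(logLik(plain)), tolerance = 1e-4)
  # fixed effects agree within two standard errors
  co <- coef(plain)
  expect_true(all(abs(mixed$coefficients[names(co)] - co) /
                    pmax(sqrt(diag(vcov(plain))), 1e-8) < 2))
})

test_that("model enumeration respects marginality and matches brute force", {
  terms <- global_model_terms()
  models <- enumerate_models(terms)
  # independent oracle: filter all subsets explicitly
  oracle <- list()
  for (mask in 0:(2^length(terms) - 1)) {
    sel <- terms[bitwAnd(mask, 2^(seq_along(terms) - 1)) > 0]
    keep <- TRUE
    for (tm in sel[grepl(":", sel)]) {
      if (!all(strsplit(tm, ":")[[1]] %in% sel)) keep <- FALSE
    }
    if (keep) oracle[[length(oracle) + 1]] <- sel
  }
  expect_length(models, length(oracle))
  expect_length(models, 194)
  key <- function(x) paste(sort(x), collapse = "|")
  expect_setequal(vapply(models, key, character(1)),
                  vapply(oracle, key, character(1)))
  # without marginality: every subset
  expect_length(enumerate_models(terms, marginality = FALSE), 2^10)
})

test_that("AIC ranking finds a strong interaction and weights sum to one", {
  st <- small_study(seed = 5, n_sites = 20, n_obs = 40,
                    matern = list(nu = 1.5, rho_km = 400, sigma2 = 0))
  rank <- select_model(st$data, c("ALAN", "Genus", "ALAN:Genus"),
                       response = "y", spatial = FALSE)
  expect_s3_class(rank, "spawn_model_ranking")
  expect_equal(nrow(rank), 5)   # marginality-respecting subsets
  expect_equal(sum(rank$weight), 1, tolerance = 1e-9)
  expect_true(grepl("ALAN:Genus", rank$model[1]))
  expect_true(all(diff(rank$AIC) >= 0))
  expect_equal(rank$dAIC[1], 0)
})

test_that("AIC ranking order is invariant to the positive-transform offset", {
  st <- small_study(seed = 9, n_sites = 15, n_obs = 30,
                    matern = list(nu = 1.5, rho_km = 400, sigma2 = 0))
  d0 <- st$data
  d1 <- st$data
  d1$y <- d1$y + 1L
  r0 <- select_model(d0, c("ALAN", "Genus"), response = "y", spatial = FALSE)
  r1 <- select_model(d1, c("ALAN", "Genus"), response = "y", spatial = FALSE)
  expect_identical(r0$model, r1$model)
})

test_that("likelihood-ratio tests follow their definition", {
  fake <- function(ll, nfix, terms) {
    structure(list(loglik = ll, n_fixed = nfix, fixed_terms = terms),
              class = "spawn_fit")
  }
  a <- fake(-100, 3, c("ALAN"))
  b <- fake(-95, 5, c("ALAN", "Genus"))
  out <- lrt(a, b)
  expect_equal(out$chisq, 10)
  expect_equal(out$df, 2)
  expect_equal(out$p, pchisq(10, 2, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(out$p, 0.0067, tolerance = 0.01)
  same <- lrt(a, a)
  expect_equal(same$chisq, 0)
  expect_equal(same$p, 1)
  expect_error(lrt(b, a), "not nested")
})

test_that("per-genus contrasts are zero for identical groups and recover shifts", {
  d <- data.frame(Genus = "G",
                  ALAN = factor(rep(c("Unlit", "Lit"), each = 30),
                                c("Unlit", "Lit")),
                  y = rep(c(5L, 6L, 7L), 20))
  out <- genus_contrasts(d)
  expect_equal(out$shift_days, 0, tolerance = 1e-10)
  expect_true(out$ci95_lo < 0 && out$ci95_hi > 0)
  # a -2 day shift at n = 200 per arm is recovered
  set.seed(21)
  d2 <- data.frame(Genus = "H",
                   ALAN = factor(rep(c("Unlit", "Lit"), each = 200),
                                 c("Unlit", "Lit")),
                   y = c(rpois(200, 7), rpois(200, 5)))
  out2 <- genus_contrasts(d2)
  expect_lt(abs(out2$shift_days - (-2)), 0.6)
  expect_identical(out2$family, "poisson")
  # overdispersed counts switch to the negative binomial
  set.seed(22)
  mu <- exp(rnorm(400, log(6), 0.6))
  d3 <- data.frame(Genus = "K",
                   ALAN = factor(rep(c("Unlit", "Lit"), each = 200),
                                 c("Unlit", "Lit")),
                   y = rpois(400, mu))
  out3 <- genus_contrasts(d3)
  expect_identical(out3$family, "negative binomial")
})

test_that("reverse-stepwise term tests flag a simulated interaction", {
  st <- small_study(seed = 13, n_sites = 20, n_obs = 60,
                    matern = list(nu = 1.5, rho_km = 400, sigma2 = 0))
  fit <- fit_glmm(st$data, c("ALAN", "Genus", "ALAN:Genus"),
                  response = "y", spatial = FALSE)
  tt <- term_tests(fit, st$data)
  expect_identical(tt$term, c("ALAN", "Genus", "ALAN:Genus"))
  expect_lt(tt$p[tt$term == "ALAN:Genus"], 0.05)
})
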