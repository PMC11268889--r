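#' Log-scale ratio of group means with a percentile bootstrap CI
#'
#' Estimates the multiplicative difference between two groups of positive
#' values (landing forces are analysed on the log scale) as
#' `exp(mean(log a) - mean(log b))`, with a percentile bootstrap confidence
#' interval. When cluster labels are supplied (repeated measures per owl),
#' the bootstrap resamples whole clusters.
#'
#' @param values_a,values_b Positive numeric vectors.
#' @param n_boot Bootstrap resamples.
#' @param seed Optional seed for the bootstrap.
#' @param conf Confidence level.
#' @param cluster_a,cluster_b Optional cluster labels, same lengths as the
#'   value vectors.
#' @return A list of class `owl_ratio`: `ratio`, `ci_low`, `ci_high`, `n_a`,
#'   `n_b`.
#' @export
ratio_of_means_log <- function(values_a, values_b, n_boot = 1000,
                               seed = NULL, conf = 0.95,
                               cluster_a = NULL, cluster_b = NULL) {
  if (!length(values_a) || !length(values_b)) stop("both groups must be non-empty")
  if (any(values_a <= 0) || any(values_b <= 0)) {
    stop("ratio_of_means_log(): values must be positive")
  }
  la <- log(values_a); lb <- log(values_b)
  est <- exp(mean(la) - mean(lb))
  boot <- function() {
    resample <- function(x, cl) {
      if (is.null(cl)) return(x[sample.int(length(x), replace = TRUE)])
      ids <- unique(cl)
      pick <- sample(ids, length(ids), replace = TRUE)
      unlist(lapply(pick, function(id) x[cl == id]), use.names = FALSE)
    }
    replicate(n_boot, exp(mean(resample(la, cluster_a)) -
                            mean(resample(lb, cluster_b))))
  }
  reps <- if (is.null(seed)) boot() else with_preserved_seed(seed, boot())
  alpha <- (1 - conf) / 2
  ci <- stats::quantile(reps, c(alpha, 1 - alpha), names = FALSE)
  structure(list(ratio = est, ci_low = min(ci[1], est), ci_high = max(ci[2], est),
                 n_a = length(values_a), n_b = length(values_b)),
            class = "owl_ratio")
}

#' @export
print.owl_ratio <- function(x, ...) {
  cat(sprintf("ratio of means (log scale): %.3f [%.3f, %.3f] (n = %d vs %d)\n",
              x$ratio, x$ci_low, x$ci_high, x$n_a, x$n_b))
  invisible(x)
}

#' Logistic model of hunting success
#'
#' Fits the success model at its final structure: success ~ pre-hunt perch
#' force x hunting strategy + sex (any term absent from the data is dropped),
#' as a fixed-effects binomial regression fitted by iteratively reweighted
#' least squares. Continuous predictors are centred and scaled to unit
#' standard deviation before fitting; odds ratios are reported both per SD
#' and per Newton of pre-hunt force, with Wald confidence intervals. The
#' sit-and-wait force effect (the slope for attempts launched from a perch)
#' is returned as `or_sitandwait_per_newton`.
#'
#' @param attempts Tibble with `success` (logical/0-1) and any of
#'   `prehunt_perch_force_N`, `strategy` (`sit_and_wait`/`on_the_wing`),
#'   `sex`.
#' @param conf Confidence level for Wald intervals.
#' @return A list of class `owl_success_model`: `coefficients` (tibble with
#'   estimates, SEs, odds ratios and CIs), `or_per_newton`,
#'   `or_sitandwait_per_newton` (with CI), `force_sd`, `n`, and the fitted
#'   `glm` object.
#' @export
fit_success_glm <- function(attempts, conf = 0.95) {
  y <- as.integer(attempts$success)
  if (length(unique(y)) < 2) {
    stop("success model requires both outcome classes ",
         "(all outcomes identical: separation)")
  }
  dat <- data.frame(success = y)
  terms <- character(0)
  force_sd <- NA_real_
  has_force <- "prehunt_perch_force_N" %in% names(attempts) &&
    any(is.finite(attempts$prehunt_perch_force_N))
  if (has_force) {
    f <- attempts$prehunt_perch_force_N
    keep <- is.finite(f)
    dat <- dat[keep, , drop = FALSE]
    y <- y[keep]
    force_sd <- stats::sd(f[keep])
    dat$force_z <- (f[keep] - mean(f[keep])) / force_sd
    attempts <- attempts[keep, , drop = FALSE]
    terms <- c(terms, "force_z")
  }
  has_strategy <- "strategy" %in% names(attempts) &&
    length(unique(attempts$strategy)) > 1
  if (has_strategy) {
    dat$strategy <- stats::relevel(factor(attempts$strategy), "on_the_wing")
    terms <- c(terms,
               if (has_force) "force_z * strategy" else "strategy")
  }
  if ("sex" %in% names(attempts) && length(unique(attempts$sex)) > 1) {
    dat$sex <- factor(attempts$sex)
    terms <- c(terms, "sex")
  }
  if (!length(terms)) terms <- "1"
  form <- stats::as.formula(paste("success ~", paste(terms, collapse = " + ")))
  fit <- withCallingHandlers(
    stats::glm(form, family = stats::binomial(), data = dat,
               control = stats::glm.control(epsilon = 1e-8, maxit = 100)),
    # separation is diagnosed explicitly below
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })

  co <- summary(fit)$coefficients
  big <- abs(co[, "Estimate"]) > 15
  if (!fit$converged || any(big[-1])) {
    bad <- rownames(co)[-1][big[-1]]
    stop("separation detected in success model (predictor: ",
         paste(if (length(bad)) bad else "unknown", collapse = ", "), ")")
  }
  z <- stats::qnorm(1 - (1 - conf) / 2)
  est <- unname(co[, "Estimate"])
  se <- unname(co[, "Std. Error"])
  coef_tbl <- tibble::tibble(
    term = rownames(co),
    estimate = est, se = se,
    odds_ratio = exp(est),
    or_low = exp(est - z * se),
    or_high = exp(est + z * se)
  )

  or_per_newton <- NULL
  or_sw <- NULL
  if (has_force) {
    b <- stats::coef(fit)
    V <- stats::vcov(fit)
    per_n <- function(est, se) {
      list(or = exp(est / force_sd),
           low = exp((est - z * se) / force_sd),
           high = exp((est + z * se) / force_sd))
    }
    or_per_newton <- per_n(b[["force_z"]], sqrt(V["force_z", "force_z"]))
    int <- grep("^force_z:strategy", names(b), value = TRUE)
    if (has_strategy && length(int) == 1) {
      est <- b[["force_z"]] + b[[int]]
      se <- sqrt(V["force_z", "force_z"] + V[int, int] +
                   2 * V["force_z", int])
      or_sw <- per_n(est, se)
    } else {
      or_sw <- or_per_newton
    }
  }

  structure(list(coefficients = coef_tbl, or_per_newton = or_per_newton,
                 or_sitandwait_per_newton = or_sw, force_sd = force_sd,
                 n = nrow(dat), fit = fit),
            class = "owl_success_model")
}

#' @export
print.owl_success_model <- function(x, ...) {
  cat("logistic hunting-success model (n =", x$n, ")\n")
  print(as.data.frame(x$coefficients), digits = 3)
  if (!is.null(x$or_sitandwait_per_newton)) {
    s <- x$or_sitandwait_per_newton
    cat(sprintf("sit-and-wait odds ratio per Newton: %.3f [%.3f, %.3f]\n",
                s$or, s$low, s$high))
  }
  invisible(x)
}

#' Smoothed force-versus-time-to-hunt trend with derivative band
#'
#' Fits a penalized regression spline (9 basis functions) of log landing
#' force on the time until the next hunting strike, separately per perch
#' type, and identifies when the force changes significantly: the first
#' derivative of the fitted curve is computed by finite differences on a
#' regular grid, a simultaneous confidence band is built by a max-deviation
#' bootstrap (resampling events, refitting, and scaling pointwise standard
#' errors by the bootstrap quantile of the maximal standardized deviation),
#' and grid points whose derivative band excludes zero are flagged. With the
#' grid oriented as time-to-hunt, a significantly *positive* derivative means
#' the force falls as the strike approaches (`significant_decline_mask`).
#'
#' @param perch_events Tibble with `time_to_next_hunt` (s), `force_N`, and a
#'   `perch_type` column.
#' @param by_perch_type Fit separately per perch type (otherwise pooled).
#' @param k Spline basis dimension.
#' @param n_boot Bootstrap resamples for the simultaneous band.
#' @param seed Optional seed.
#' @param grid_n Grid points.
#' @param conf Band confidence level.
#' @param min_events Minimum events per stratum; below it the stratum yields
#'   a NULL trend with a warning.
#' @return Named list (per perch type) of tibbles: `grid` (s), `fitted` (N),
#'   `band_low`, `band_high`, `derivative` (N/s), `deriv_low`, `deriv_high`,
#'   `significant_decline_mask`, `significant_change_mask`.
#' @export
trend_with_derivative <- function(perch_events, by_perch_type = TRUE,
                                  k = 9, n_boot = 200, seed = NULL,
                                  grid_n = 80, conf = 0.95,
                                  min_events = 50) {
  strata <- if (by_perch_type && "perch_type" %in% names(perch_events)) {
    split(perch_events, perch_events$perch_type)
  } else {
    list(pooled = perch_events)
  }
  run <- function() lapply(strata, trend_one, k = k, n_boot = n_boot,
                           grid_n = grid_n, conf = conf,
                           min_events = min_events)
  if (is.null(seed)) run() else with_preserved_seed(seed, run())
}

trend_one <- function(ev, k, n_boot, grid_n, conf, min_events) {
  ev <- ev[is.finite(ev$time_to_next_hunt) & is.finite(ev$force_N) &
             ev$force_N > 0, , drop = FALSE]
  if (nrow(ev) < min_events) {
    warning("fewer than ", min_events, " events in stratum; trend skipped")
    return(NULL)
  }
  x <- ev$time_to_next_hunt
  ly <- log(ev$force_N)
  grid <- seq(min(x), max(x), length.out = grid_n)
  kk <- min(k, max(4, length(unique(x)) - 1))
  fit_curve <- function(xx, yy) {
    g <- mgcv::gam(yy ~ s(xx, k = kk, bs = "cr"))
    stats::predict(g, newdata = data.frame(xx = grid))
  }
  f0 <- fit_curve(x, ly)
  boots <- matrix(NA_real_, n_boot, grid_n)
  for (b in seq_len(n_boot)) {
    ix <- sample.int(nrow(ev), replace = TRUE)
    boots[b, ] <- tryCatch(fit_curve(x[ix], ly[ix]), error = function(e) f0)
  }
  sd_g <- pmax(apply(boots, 2, stats::sd), 1e-12)
  dev <- abs(sweep(sweep(boots, 2, f0), 2, sd_g, "/"))
  crit <- stats::quantile(apply(dev, 1, max), conf, names = FALSE)

  h <- diff(grid[1:2])
  fd <- function(cv) {
    d <- numeric(grid_n)
    d[2:(grid_n - 1)] <- (cv[3:grid_n] - cv[1:(grid_n - 2)]) / (2 * h)
    d[1] <- (cv[2] - cv[1]) / h
    d[grid_n] <- (cv[grid_n] - cv[grid_n - 1]) / h
    d
  }
  fit_N <- exp(f0)
  d0 <- fd(fit_N)
  dboots <- t(apply(exp(boots), 1, fd))
  sd_d <- pmax(apply(dboots, 2, stats::sd), 1e-12)
  dev_d <- abs(sweep(sweep(dboots, 2, d0), 2, sd_d, "/"))
  crit_d <- stats::quantile(apply(dev_d, 1, max), conf, names = FALSE)

  dlow <- d0 - crit_d * sd_d
  dhigh <- d0 + crit_d * sd_d
  change <- dlow > 0 | dhigh < 0
  tibble::tibble(
    grid = grid, fitted = fit_N,
    band_low = exp(f0 - crit * sd_g), band_high = exp(f0 + crit * sd_g),
    derivative = d0, deriv_low = dlow, deriv_high = dhigh,
    significant_change_mask = change,
    significant_decline_mask = change & d0 > 0
  )
}

#' Descriptive summary tables of the night-level analyses
#'
#' One tidy table of the study's headline descriptive quantities: per
#' sex x strategy success rates, per-sex landing-force means (N and N/kg) by
#' landing subtype with the female/male ratio, per-sex on-the-wing flight
#' speed means with the female-male gap, sit-and-wait frequency, and trip
#' durations — each with a percentile bootstrap CI on the mean/proportion.
#'
#' @param attempts Hunting-attempt tibble (needs `sex`, `strategy`,
#'   `success`; optionally `flight_speed`).
#' @param landings Landing tibble (needs `subtype`, `force_N`,
#'   `force_per_kg`; `loaded_with_prey` rows are excluded).
#' @param metadata Optional list of [owl_metadata()] (reserved; per-owl body
#'   mass already enters through the force columns).
#' @param trips Optional trip tibble from [segment_trips()].
#' @param n_boot Bootstrap resamples for the CIs.
#' @param seed Optional seed.
#' @return A tibble: `measure`, `group`, `value`, `ci_low`, `ci_high`, `n`.
#' @export
descriptive_tables <- function(attempts, landings, metadata = NULL,
                               trips = NULL, n_boot = 500, seed = NULL) {
  run <- function() {
    boot_ci <- function(x, stat = mean) {
      x <- x[is.finite(x)]
      if (!length(x)) return(c(NA_real_, NA_real_))
      reps <- replicate(n_boot, stat(x[sample.int(length(x), replace = TRUE)]))
      stats::quantile(reps, c(0.025, 0.975), names = FALSE)
    }
    row <- function(measure, group, x) {
      x <- x[is.finite(x)]
      ci <- boot_ci(x)
      tibble::tibble(measure = measure, group = group,
                     value = if (length(x)) mean(x) else NA_real_,
                     ci_low = ci[1], ci_high = ci[2], n = length(x))
    }
    out <- list()

    if (!is.null(attempts) && nrow(attempts)) {
      cat_att <- attempts[attempts$strategy %in%
                            c("sit_and_wait", "on_the_wing"), ]
      for (sx in sort(unique(cat_att$sex))) {
        for (st in sort(unique(cat_att$strategy))) {
          sel <- cat_att$sex == sx & cat_att$strategy == st
          if (any(sel)) {
            out[[length(out) + 1]] <- row(
              "success_rate", paste(sx, st, sep = "."),
              as.numeric(cat_att$success[sel]))
          }
        }
      }
      if ("flight_speed" %in% names(attempts)) {
        sp <- attempts[is.finite(attempts$flight_speed), ]
        for (sx in sort(unique(sp$sex))) {
          out[[length(out) + 1]] <- row("flight_speed", sx,
                                        sp$flight_speed[sp$sex == sx])
        }
        if (all(c("F", "M") %in% sp$sex)) {
          gap <- mean(sp$flight_speed[sp$sex == "F"]) -
            mean(sp$flight_speed[sp$sex == "M"])
          out[[length(out) + 1]] <- tibble::tibble(
            measure = "flight_speed_gap_FM", group = "F-M", value = gap,
            ci_low = NA_real_, ci_high = NA_real_, n = nrow(sp))
        }
      }
      out[[length(out) + 1]] <- row(
        "sw_frequency", "all",
        as.numeric(cat_att$strategy == "sit_and_wait"))
      excl <- mean(attempts$strategy == "excluded", na.rm = TRUE)
      out[[length(out) + 1]] <- tibble::tibble(
        measure = "excluded_fraction", group = "all", value = excl,
        ci_low = NA_real_, ci_high = NA_real_, n = nrow(attempts))
    }

    if (!is.null(landings) && nrow(landings)) {
      ld <- landings
      if ("loaded_with_prey" %in% names(ld)) ld <- ld[!ld$loaded_with_prey, ]
      sex_of <- if ("sex" %in% names(ld)) ld$sex else NULL
      for (sub in sort(unique(ld$subtype))) {
        for (colv in c("force_N", "force_per_kg")) {
          if (!is.null(sex_of)) {
            for (sx in sort(unique(sex_of))) {
              sel <- ld$subtype == sub & sex_of == sx
              if (any(sel)) {
                out[[length(out) + 1]] <- row(paste0(sub, "_", colv), sx,
                                              ld[[colv]][sel])
              }
            }
            both <- vapply(c("F", "M"), function(sx)
              mean(ld[[colv]][ld$subtype == sub & sex_of == sx],
                   na.rm = TRUE), numeric(1))
            if (all(is.finite(both))) {
              out[[length(out) + 1]] <- tibble::tibble(
                measure = paste0(sub, "_", colv, "_ratio_FM"), group = "F/M",
                value = both[["F"]] / both[["M"]],
                ci_low = NA_real_, ci_high = NA_real_,
                n = sum(ld$subtype == sub))
            }
          } else {
            out[[length(out) + 1]] <- row(paste0(sub, "_", colv), "all",
                                          ld[[colv]][ld$subtype == sub])
          }
        }
      }
    }

    if (!is.null(trips) && nrow(trips)) {
      out[[length(out) + 1]] <- row("trip_duration_min", "all", trips$duration)
    }
    dplyr::bind_rows(out)
  }
  if (is.null(seed)) run() else with_preserved_seed(seed, run())
}
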