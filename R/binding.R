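# Binding readouts: one-site ITC isotherms and four-parameter-logistic
# competitive-displacement curves, with replicate pooling.
#
# The ITC forward model is the standard perfusion-cell convention: cumulative
# displaced-volume dilution of cell and injectant, exact 1:1 quadratic
# complex concentration per injection, and the half-plug heat correction for
# the displaced volume. Fitting is nonlinear least squares in log10(Kd)
# space with a multistart grid over Kd decades.

#' Titration schedule
#'
#' @param cell_volume Cell volume, microlitre (default 200).
#' @param cell_conc Cell (macromolecule) concentration, micromolar
#'   (default 60).
#' @param syringe_conc Injectant (ligand) concentration, micromolar
#'   (default 660).
#' @param injection_volume Per-injection volume, microlitre (default 2).
#' @param n_injections Number of injections (default 19).
#' @return A `titration_schedule` list.
#' @export
titration_schedule <- function(cell_volume = 200, cell_conc = 60,
                               syringe_conc = 660, injection_volume = 2,
                               n_injections = 19) {
  stopifnot(cell_volume > 0, cell_conc > 0, syringe_conc > 0,
            injection_volume > 0, n_injections >= 1)
  structure(list(cell_volume = cell_volume, cell_conc = cell_conc,
                 syringe_conc = syringe_conc,
                 injection_volume = injection_volume,
                 n_injections = as.integer(n_injections)),
            class = "titration_schedule")
}

# Noise-free per-injection heats (microcal) for one-site binding.
# kd, concentrations in uM; dh in kcal/mol; volumes in ul; baseline in ucal.
itc_model_heats <- function(kd, dh, n, baseline, schedule) {
  V0 <- schedule$cell_volume
  dV <- schedule$injection_volume
  M0 <- schedule$cell_conc
  X0 <- schedule$syringe_conc
  i <- seq_len(schedule$n_injections)
  dVi <- i * dV
  # displaced-volume dilution (instantaneous mixing and overflow)
  Mt <- M0 * (1 - dVi / (2 * V0)) / (1 + dVi / (2 * V0))
  Xt <- X0 * (dVi / V0) * (1 - dVi / (2 * V0))
  b <- n * Mt + Xt + kd
  MX <- (b - sqrt(pmax(b^2 - 4 * n * Mt * Xt, 0))) / 2
  # heat content of the cell, kcal: uM * ul = 1e-12 mol
  Q <- dh * MX * V0 * 1e-12
  Qprev <- c(0, Q[-length(Q)])
  q <- Q - Qprev + (dV / V0) * (Q + Qprev) / 2
  q * 1e9 + baseline  # kcal -> microcal
}

#' Simulate a one-site ITC titration
#'
#' Exact 1:1 quadratic binding solution per injection with displaced-volume
#' dilution correction; Gaussian heat noise behind an explicit seed.
#'
#' @param params Named list/vector with `kd` (uM), `dh` (kcal/mol), `n`
#'   (stoichiometry).
#' @param schedule A [titration_schedule()].
#' @param noise_sd Gaussian noise SD, microcal (default 0.1).
#' @param seed Integer seed (required when `noise_sd > 0`).
#' @return data.frame with columns `injection`, `heat_ucal`; attributes
#'   `schedule`, `params`, `noise_sd`, `seed`.
#' @export
simulate_itc <- function(params, schedule = titration_schedule(),
                         noise_sd = 0.1, seed = 1L) {
  stopifnot(params$kd > 0, params$n > 0)
  q <- itc_model_heats(params$kd, params$dh, params$n, 0, schedule)
  if (noise_sd > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    q <- q + stats::rnorm(length(q), 0, noise_sd)
  }
  out <- data.frame(injection = seq_along(q), heat_ucal = q)
  attr(out, "schedule") <- schedule
  attr(out, "params") <- params
  attr(out, "noise_sd") <- noise_sd
  attr(out, "seed") <- seed
  out
}

# Save/restore global RNG state so simulators are seed-local.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

# Numerical jacobian of f (vector-valued) at theta.
num_jacobian <- function(f, theta, eps = 1e-6) {
  f0 <- f(theta)
  J <- matrix(0, length(f0), length(theta))
  for (k in seq_along(theta)) {
    h <- eps * max(1, abs(theta[k]))
    tp <- theta; tp[k] <- tp[k] + h
    tm <- theta; tm[k] <- tm[k] - h
    J[, k] <- (f(tp) - f(tm)) / (2 * h)
  }
  J
}

ls_covariance <- function(resid_fun, theta) {
  J <- num_jacobian(resid_fun, theta)
  r <- resid_fun(theta)
  dof <- max(1L, length(r) - length(theta))
  s2 <- sum(r^2) / dof
  JtJ <- crossprod(J)
  cov <- tryCatch(s2 * solve(JtJ), error = function(e)
    matrix(NA_real_, length(theta), length(theta)))
  cov
}

#' Fit a one-site binding model to an ITC titration
#'
#' Nonlinear least squares over (Kd, dH, N, baseline), parameterized in
#' log10(Kd) for conditioning, with a multistart grid over Kd decades
#' (1e-2 to 1e3 uM). Non-convergence or unidentifiable data yields a
#' flagged fit, not an exception.
#'
#' @param titration data.frame from [simulate_itc()] (or with columns
#'   `injection`, `heat_ucal` plus a `schedule` attribute), or a plain heat
#'   vector with `schedule` supplied.
#' @param schedule A [titration_schedule()]; defaults to the titration's
#'   attribute.
#' @param fit_baseline If `TRUE`, a constant per-injection offset is fitted
#'   alongside the thermodynamic parameters. Default `FALSE`: heats are
#'   assumed control-subtracted (dilution heats removed before fitting, as
#'   in the standard workflow), and a free offset badly degrades Kd
#'   identifiability for low-c titrations.
#' @return An `itc_fit` list: `kd`, `dh`, `n`, `baseline`, standard errors,
#'   `cov` (4x4, order kd/dh/n/baseline in natural units), `rss`, `c_value`,
#'   `converged`, `flag`.
#' @export
fit_one_site <- function(titration, schedule = attr(titration, "schedule"),
                         fit_baseline = FALSE) {
  q <- if (is.data.frame(titration)) titration$heat_ucal else as.numeric(titration)
  if (is.null(schedule)) stop("a titration schedule is required", call. = FALSE)
  if (length(q) < 6L)
    stop("need at least 6 injections for a one-site fit", call. = FALSE)

  flag <- NULL
  if (stats::sd(q) < 1e-9 || all(abs(q - mean(q)) < 1e-9)) {
    return(structure(list(kd = NA_real_, dh = NA_real_, n = NA_real_,
                          baseline = NA_real_, se = rep(NA_real_, 4),
                          cov = matrix(NA_real_, 4, 4), rss = NA_real_,
                          c_value = NA_real_, converged = FALSE,
                          flag = "unidentifiable: flat heats"),
                     class = "itc_fit"))
  }

  resid <- function(theta) {
    base <- if (fit_baseline) theta[4] else 0
    q - itc_model_heats(10^theta[1], theta[2], theta[3], base, schedule)
  }
  obj <- function(theta) sum(resid(theta)^2)

  # initial dh from total heat assuming full saturation at n = 1
  dh0 <- sum(q) / (schedule$cell_conc * schedule$cell_volume * 1e-12) / 1e9
  if (!is.finite(dh0) || dh0 == 0) dh0 <- -5
  best <- NULL
  for (lk in seq(-2, 3, by = 1)) {
    start <- c(lk, dh0, 1, if (fit_baseline) 0)
    fit <- tryCatch(
      stats::optim(start, obj, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (fit$par[3] <= 0) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) {
    return(structure(list(kd = NA_real_, dh = NA_real_, n = NA_real_,
                          baseline = NA_real_, se = rep(NA_real_, 4),
                          cov = matrix(NA_real_, 4, 4), rss = NA_real_,
                          c_value = NA_real_, converged = FALSE,
                          flag = "non-convergence after multistart"),
                     class = "itc_fit"))
  }
  theta <- best$par
  # polish
  pol <- tryCatch(stats::optim(theta, obj, method = "Nelder-Mead",
                               control = list(maxit = 2000, reltol = 1e-14)),
                  error = function(e) best)
  if (pol$value < best$value) { best <- pol; theta <- pol$par }

  kd <- 10^theta[1]; dh <- theta[2]; n <- theta[3]
  baseline <- if (fit_baseline) theta[4] else 0
  if (fit_baseline) {
    resid_nat <- function(th) {
      q - itc_model_heats(th[1], th[2], th[3], th[4], schedule)
    }
    cov <- ls_covariance(resid_nat, c(kd, dh, n, baseline))
  } else {
    resid_nat <- function(th) {
      q - itc_model_heats(th[1], th[2], th[3], 0, schedule)
    }
    cov3 <- ls_covariance(resid_nat, c(kd, dh, n))
    cov <- matrix(0, 4, 4); cov[1:3, 1:3] <- cov3
  }
  se <- sqrt(pmax(diag(cov), 0))
  c_value <- n * schedule$cell_conc / kd
  if (c_value < 1) flag <- c(flag, "low c-value")
  structure(list(kd = kd, dh = dh, n = n, baseline = baseline,
                 se = se, cov = cov, rss = best$value, c_value = c_value,
                 converged = best$convergence == 0,
                 flag = if (is.null(flag)) NA_character_ else
                   paste(flag, collapse = "; ")),
            class = "itc_fit")
}

#' @export
print.itc_fit <- function(x, ...) {
  cat(sprintf("one-site ITC fit: Kd = %.3g uM (se %.2g), dH = %.3g kcal/mol, N = %.3g, c = %.3g\n",
              x$kd, x$se[1], x$dh, x$n, x$c_value))
  if (!is.na(x$flag)) cat("flag:", x$flag, "\n")
  invisible(x)
}

#' Inverse-variance weighted pooling of replicate estimates
#'
#' Maximum-likelihood pooling of replicate fits under known per-replicate
#' variances: weighted mean with weights `1/sigma_i^2`, pooled variance
#' `1/sum(1/sigma_i^2)`. Applied identically to Kd and stoichiometry.
#'
#' @param fits List of `itc_fit` objects (>= 2, finite variances), or a
#'   numeric vector of estimates with `variances` supplied.
#' @param variances Optional numeric vector of per-estimate variances.
#' @param what Which parameter to pool when `fits` are fit objects:
#'   `"kd"` (default) or `"n"`.
#' @return List with `estimate`, `sd` (pooled standard deviation), `n_used`.
#' @export
pool_kd <- function(fits, variances = NULL, what = c("kd", "n")) {
  what <- match.arg(what)
  if (is.list(fits) && !is.numeric(fits)) {
    values <- vapply(fits, function(f) f[[what]], numeric(1))
    idx <- if (what == "kd") 1L else 3L
    variances <- vapply(fits, function(f) f$se[idx]^2, numeric(1))
  } else values <- as.numeric(fits)
  if (length(values) < 2L) stop("need >= 2 replicates to pool", call. = FALSE)
  ok <- is.finite(values) & is.finite(variances)
  if (any(!ok)) warning(sum(!ok), " replicate(s) with non-finite variance dropped")
  values <- values[ok]; variances <- variances[ok]
  if (length(values) < 2L) stop("fewer than 2 usable replicates", call. = FALSE)
  w <- 1 / variances
  list(estimate = sum(w * values) / sum(w),
       sd = sqrt(1 / sum(w)),
       n_used = length(values))
}

#' Simulate a four-parameter-logistic displacement curve
#'
#' `y = bottom + (top - bottom) / (1 + (x / ec50)^hill)` plus Gaussian
#' noise. With `hill > 0` the response falls from `top` to `bottom` with
#' increasing competitor dose (competitive displacement).
#'
#' @param truth Named list/vector with `ec50`, `top`, `bottom`, `hill`
#'   (`ec50` in the dose units).
#' @param doses Strictly increasing dose vector.
#' @param noise_sd Gaussian noise SD (response units).
#' @param seed Integer seed.
#' @return data.frame with columns `dose`, `response`; attributes `truth`,
#'   `noise_sd`, `seed`.
#' @export
simulate_displacement <- function(truth, doses, noise_sd = 0, seed = 1L) {
  stopifnot(truth$ec50 > 0, truth$top >= truth$bottom)
  if (any(diff(doses) <= 0)) stop("doses must be strictly increasing",
                                  call. = FALSE)
  y <- truth$bottom + (truth$top - truth$bottom) /
    (1 + (doses / truth$ec50)^truth$hill)
  if (noise_sd > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    y <- y + stats::rnorm(length(y), 0, noise_sd)
  }
  out <- data.frame(dose = doses, response = y)
  attr(out, "truth") <- truth
  attr(out, "noise_sd") <- noise_sd
  attr(out, "seed") <- seed
  out
}

#' Fit a four-parameter logistic to a dose-response curve
#'
#' Least squares over (bottom, top, log10 EC50, hill) with multistart over
#' hill slopes; EC50 is reported in the input dose units. Flat or
#' non-spanning data yields a flagged fit.
#'
#' @param curve data.frame with columns `dose`, `response` (>= 5 doses).
#' @return A `fourpl_fit` list: `ec50`, `top`, `bottom`, `hill`, `se`
#'   (order ec50/top/bottom/hill), `cov`, `rss`, `converged`, `flag`.
#' @export
fit_4pl <- function(curve) {
  x <- curve$dose; y <- curve$response
  if (length(x) < 5L) stop("need >= 5 doses", call. = FALSE)
  flag <- NULL
  pred <- function(theta) {
    theta[1] + (theta[2] - theta[1]) / (1 + (x / 10^theta[3])^theta[4])
  }
  resid <- function(theta) y - pred(theta)
  obj <- function(theta) sum(resid(theta)^2)
  rng <- max(y) - min(y)
  if (rng < 1e-12) {
    return(structure(list(ec50 = NA_real_, top = NA_real_, bottom = NA_real_,
                          hill = NA_real_, se = rep(NA_real_, 4),
                          cov = matrix(NA_real_, 4, 4), rss = NA_real_,
                          converged = FALSE, flag = "unidentifiable: flat data"),
                     class = "fourpl_fit"))
  }
  mid <- (max(y) + min(y)) / 2
  x_mid <- x[which.min(abs(y - mid))]
  best <- NULL
  for (h0 in c(0.5, 1, 2)) {
    fit <- tryCatch(
      stats::optim(c(min(y), max(y), log10(x_mid), h0), obj, method = "BFGS",
                   control = list(maxit = 1000, reltol = 1e-14)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) {
    return(structure(list(ec50 = NA_real_, top = NA_real_, bottom = NA_real_,
                          hill = NA_real_, se = rep(NA_real_, 4),
                          cov = matrix(NA_real_, 4, 4), rss = NA_real_,
                          converged = FALSE, flag = "non-convergence"),
                     class = "fourpl_fit"))
  }
  theta <- best$par
  bottom <- theta[1]; top <- theta[2]; ec50 <- 10^theta[3]; hill <- theta[4]
  if (top < bottom) {  # canonicalize orientation
    tmp <- top; top <- bottom; bottom <- tmp; hill <- -hill
  }
  if (ec50 > max(x) * 10 || ec50 < min(x) / 10)
    flag <- c(flag, "unidentifiable: EC50 outside dosed range")
  if (rng < 0.5 * (top - bottom))
    flag <- c(flag, "unidentifiable: fitted amplitude extrapolates the data")
  resid_nat <- function(th) {
    y - (th[3] + (th[2] - th[3]) / (1 + (x / th[1])^th[4]))
  }
  cov <- ls_covariance(resid_nat, c(ec50, top, bottom, hill))
  se <- sqrt(pmax(diag(cov), 0))
  structure(list(ec50 = ec50, top = top, bottom = bottom, hill = hill,
                 se = se, cov = cov, rss = best$value,
                 converged = best$convergence == 0,
                 flag = if (is.null(flag)) NA_character_ else
                   paste(flag, collapse = "; ")),
            class = "fourpl_fit")
}

#' @export
print.fourpl_fit <- function(x, ...) {
  cat(sprintf("4PL fit: EC50 = %.4g (se %.2g), top = %.3g, bottom = %.3g, hill = %.3g\n",
              x$ec50, x$se[1], x$top, x$bottom, x$hill))
  if (!is.na(x$flag)) cat("flag:", x$flag, "\n")
  invisible(x)
}

#' Relative binding affinities from displacement curves
#'
#' Each labelled curve is fitted with [fit_4pl()]; the relative affinity of
#' a clone is the fitted half-saturation dose of the reference divided by
#' that of the clone (reference = 1; a clone needing 10x more material
#' scores 0.1). Unfittable curves are excluded with a warning.
#'
#' @param curves Named list of dose-response data.frames.
#' @param reference_label Name of the reference curve.
#' @return Named numeric vector of affinity ratios.
#' @export
relative_affinity <- function(curves, reference_label) {
  if (!reference_label %in% names(curves))
    stop("reference curve not present", call. = FALSE)
  fits <- lapply(curves, function(cu) tryCatch(fit_4pl(cu),
                                               error = function(e) NULL))
  usable <- vapply(fits, function(f) !is.null(f) && is.finite(f$ec50),
                   logical(1))
  if (!usable[[reference_label]])
    stop("reference curve could not be fitted", call. = FALSE)
  if (any(!usable))
    warning("excluded unfittable curve(s): ",
            paste(names(curves)[!usable], collapse = ", "))
  ec <- vapply(fits[usable], function(f) f$ec50, numeric(1))
  ec[[reference_label]] / ec
}

#' Write a titration or dose-response table as TSV
#' @param x data.frame from [simulate_itc()] or [simulate_displacement()].
#' @param path Output path.
#' @export
write_curve_tsv <- function(x, path) write_tsv(x, path)

#' Read a titration table (TSV: injection, heat_ucal)
#' @param path Input path.
#' @param schedule Optional [titration_schedule()] to attach.
#' @return data.frame ready for [fit_one_site()].
#' @export
read_titration_tsv <- function(path, schedule = NULL) {
  df <- read_tsv(path)
  if (!is.null(schedule)) attr(df, "schedule") <- schedule
  df
}
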