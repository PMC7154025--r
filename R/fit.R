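#' Fit leaflet material parameters to biaxial stress--stretch data
#'
#' Nonlinear least squares on the incompressible plane-stress biaxial
#' response: minimizes the stacked residuals of sigma11 and sigma22 (kPa)
#' across all loading protocols with the Levenberg--Marquardt algorithm,
#' restarted from several bounds-scaled initial points to avoid local minima.
#' The fitting objective is unweighted stress least squares.
#'
#' @param data Data frame with columns `protocol_id`, `lam1`, `lam2`,
#'   `sigma11_kPa`, `sigma22_kPa` (the biaxial CSV schema; see
#'   [gen_biaxial_dataset()]).
#' @param init A [material_params()] object supplying the starting point.
#' @param lower,upper Named numeric bounds on `c10` (kPa), `c01`, `k1` (MPa),
#'   `k2` and (when free) `kappa`.
#' @param fixed_kappa If non-`NULL`, the dispersion is held at this value and
#'   not estimated.
#' @param fiber_angle In-plane mean fiber angle of the specimen (radians).
#' @param n_starts Number of Levenberg--Marquardt starts (the supplied `init`
#'   plus `n_starts - 1` random points log-uniform between the bounds).
#' @param seed Integer seed for the random restarts.
#' @return A list of class `material_fit`: `params` (fitted
#'   [material_params()]), `estimates` (named vector, `k1` in MPa), `rss`,
#'   `r_squared`, `se` (approximate standard errors), `n_protocols`,
#'   `converged`, and `message`.
#' @export
fit_material_params <- function(data, init,
                                lower = c(c10 = 1e-4, c01 = 0.05,
                                          k1 = 0, k2 = 0, kappa = 0),
                                upper = c(c10 = 50, c01 = 80,
                                          k1 = 20, k2 = 600, kappa = 1 / 3),
                                fixed_kappa = NULL, fiber_angle = 0,
                                n_starts = 4, seed = 1L) {
  stopifnot(is.data.frame(data), inherits(init, "material_params"))
  req <- c("protocol_id", "lam1", "lam2", "sigma11_kPa", "sigma22_kPa")
  missing_cols <- setdiff(req, names(data))
  if (length(missing_cols)) {
    stop("biaxial data is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  n_protocols <- length(unique(data$protocol_id))
  kappa_free <- is.null(fixed_kappa)
  if (kappa_free && n_protocols < 2) {
    warning(paste("fiber dispersion kappa is not identifiable from a single",
                  "loading protocol; fix kappa or add protocols"))
  }

  par_names <- c("c10", "c01", "k1", "k2", if (kappa_free) "kappa")
  lower <- lower[par_names]
  upper <- upper[par_names]
  obs <- c(data$sigma11_kPa, data$sigma22_kPa)

  make_material <- function(p) {
    material_params(c10 = p[["c10"]], c01 = p[["c01"]],
                    k1 = p[["k1"]], k2 = p[["k2"]],
                    kappa = if (kappa_free) p[["kappa"]] else fixed_kappa,
                    beta_vol = init$beta_mpa)
  }
  residuals_fn <- function(p) {
    p <- pmin(pmax(p, lower), upper)
    # keep the constructor's strict positivity checks satisfied at the bound
    p[c("c10", "c01")] <- pmax(p[c("c10", "c01")], 1e-8)
    mat <- make_material(p)
    pred <- t(mapply(function(l1, l2) {
      plane_stress_biaxial(mat, l1, l2, fiber_angle)[1:2]
    }, data$lam1, data$lam2))
    c(pred[, 1], pred[, 2]) - obs
  }

  start_init <- c(c10 = init$c10, c01 = init$c01, k1 = init$k1_mpa,
                  k2 = init$k2, if (kappa_free) c(kappa = init$kappa))
  start_init <- pmin(pmax(start_init, lower), upper)
  starts <- list(start_init)
  if (n_starts > 1) {
    old_seed <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    set.seed(seed)
    on.exit(if (!is.null(old_seed)) {
      assign(".Random.seed", old_seed, globalenv())
    }, add = TRUE)
    lo <- pmax(lower, c(c10 = 1e-3, c01 = 0.1, k1 = 1e-3, k2 = 1e-3,
                        kappa = 1e-3)[par_names])
    for (i in seq_len(n_starts - 1)) {
      u <- stats::runif(length(par_names))
      starts[[i + 1]] <- stats::setNames(
        exp(log(lo) + u * (log(upper) - log(lo))), par_names)
    }
  }

  best <- NULL
  for (s in starts) {
    fit <- try(minpack.lm::nls.lm(
      par = s, lower = lower, upper = upper, fn = residuals_fn,
      control = minpack.lm::nls.lm.control(
        maxiter = 500, ftol = 1e-14, ptol = 1e-14, maxfev = 20000)),
      silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) {
    stop("material fitting failed to converge from any starting point")
  }

  est <- pmin(pmax(unlist(best$par), lower), upper)
  rss <- best$deviance
  tss <- sum((obs - mean(obs))^2)
  dof <- max(length(obs) - length(par_names), 1)
  se <- rep(NA_real_, length(par_names))
  vcov_try <- try({
    sigma2 <- rss / dof
    sqrt(diag(sigma2 * solve(best$hessian)))
  }, silent = TRUE)
  if (!inherits(vcov_try, "try-error")) se <- vcov_try
  names(se) <- par_names

  structure(list(
    params = make_material(est),
    estimates = est,
    rss = rss,
    r_squared = 1 - rss / tss,
    se = se,
    n_protocols = n_protocols,
    converged = best$info %in% 1:4,
    message = best$message
  ), class = "material_fit")
}

#' @export
print.material_fit <- function(x, ...) {
  cat("Biaxial material fit (unweighted stress least squares)\n")
  est <- x$estimates
  for (nm in names(est)) {
    unit <- switch(nm, c10 = "kPa", k1 = "MPa", "")
    cat(sprintf("  %-5s = %-10.5g %s (se %.3g)\n",
                nm, est[[nm]], unit, x$se[[nm]]))
  }
  cat(sprintf("  RSS = %.4g, R^2 = %.6f, protocols = %d, converged: %s\n",
              x$rss, x$r_squared, x$n_protocols, x$converged))
  invisible(x)
}
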