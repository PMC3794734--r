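## Model observable curve shared by synthetic-data generation and fitting.
## Lean vector path: one system build, warm-started mass-balance solves,
## no per-point result objects.
.predict_curve <- function(ensemble, params, conc_uM,
                           observable = c("sheet_fraction", "mean_length")) {
  observable <- match.arg(observable)
  if (inherits(ensemble, "gc_model")) {
    m <- ensemble; m$params <- params
    cur <- gc_curve(m, conc_uM)
    if (observable != "sheet_fraction") {
      stop("the grand-canonical route provides sheet_fraction only",
           call. = FALSE)
    }
    return(cur$sheet_fraction)
  }
  systems <- .build_systems(ensemble, params)
  lzmax <- log(min(vapply(systems, `[[`, 0, "zmax")))
  phis <- conc_uM / ensemble$standard_state_uM
  zs <- vapply(phis, function(p) .solve_z(p, systems, lzmax), 0)
  if (observable == "sheet_fraction") {
    vapply(seq_along(zs), function(i) .theta2_analytic(systems, zs[i], phis[i]),
           0)
  } else {
    fib <- systems[[ensemble$fibril]]
    vapply(zs, function(z) {
      s <- .species_sums(fib, z)
      if (s[["rho"]] > 0) s[["phi"]] / (fib$m * s[["rho"]]) else fib$min_Lx * 1
    }, 0)
  }
}

#' Generate a synthetic concentration-observable dataset
#'
#' Evaluates the exact model observable (sheet fraction for CD-like data,
#' fibril mean length in columns for AFM-like data) at each concentration,
#' then adds independent Gaussian noise.  Sheet fractions are clipped to
#' `[0, 1]` and lengths to `>= 1`.  The generating truth is recorded in
#' attributes for parameter-recovery studies.
#'
#' @param params True [energy_params()].
#' @param ensemble A [species_ensemble()] or [gc_model()].
#' @param conc_uM Concentration grid (micromolar, strictly positive).
#' @param observable `"sheet_fraction"` or `"mean_length"`.
#' @param noise_sd Additive Gaussian noise standard deviation (>= 0).
#' @param seed Integer seed; the dataset is bit-reproducible given it.
#' @return A tibble of class `curve_dataset` with columns `conc_uM`,
#'   `value`; attributes `truth`, `observable`, `noise_sd`, `seed`.
#' @export
generate_synthetic_curve <- function(params, ensemble, conc_uM,
                                     observable = c("sheet_fraction",
                                                    "mean_length"),
                                     noise_sd = 0, seed) {
  observable <- match.arg(observable)
  stopifnot(noise_sd >= 0, all(conc_uM > 0))
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  conc_uM <- sort(conc_uM)
  mu <- .predict_curve(ensemble, params, conc_uM, observable)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  val <- mu + rnorm(length(mu), 0, noise_sd)
  val <- if (observable == "sheet_fraction") pmin(1, pmax(0, val))
         else pmax(1, val)
  out <- tibble::tibble(conc_uM = conc_uM, value = val)
  class(out) <- c("curve_dataset", class(out))
  attr(out, "truth") <- params
  attr(out, "observable") <- observable
  attr(out, "noise_sd") <- noise_sd
  attr(out, "seed") <- seed
  out
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  invisible()
}

#' Fit model free energies to a concentration-observable curve
#'
#' Bounded least squares (Levenberg-Marquardt via [minpack.lm::nls.lm()])
#' of the dilute-ensemble observable against measured or synthetic data,
#' with seeded multi-start: the optimizer is restarted from jittered
#' initial points and the best converged solution is reported.  If the
#' dataset has an `se` column the residuals are inverse-variance weighted.
#'
#' Standard errors come from the quadratic approximation at the optimum;
#' parameters whose profile is flat across their whole bound interval
#' (objective change below `1e-4`) are flagged instead, as are parameters
#' that ended on a bound.
#'
#' @param data A [generate_synthetic_curve()] result or any data frame with
#'   columns `conc_uM`, `value` (and optionally `se`).
#' @param ensemble A [species_ensemble()] or [gc_model()].
#' @param init [energy_params()] providing starting values and every fixed
#'   parameter.
#' @param free Character vector of free-energy names to optimize over
#'   (subset of R1, R2, R3, P1, P2, K, B, F, A).
#' @param lower,upper Named bounds (RT units) for the free parameters.
#' @param ties Named character vector of parameters slaved to a free
#'   parameter, e.g. `c(K = "P2")` fits a single value for both.
#' @param observable Overrides the dataset attribute if given.
#' @param n_restarts Number of jittered restarts (default 5).
#' @param jitter Relative jitter of the starting point (default 0.2).
#' @param warmup If `TRUE` (default), each start is preceded by a short
#'   one-dimensional fit of the first free parameter.  The polymerization
#'   take-off concentration depends exponentially on the propagation and
#'   binding free energies, so the least-squares landscape has narrow
#'   curved valleys; aligning the take-off first makes the full
#'   Levenberg-Marquardt stage land in the right valley far more reliably.
#' @param seed Seed for the restart jitter.
#' @return An object of class `amyloid_fit`; see [tidy.amyloid_fit()] and
#'   [glance.amyloid_fit()].
#' @export
fit_observable_curve <- function(data, ensemble, init, free,
                                 lower = NULL, upper = NULL,
                                 ties = NULL, observable = NULL,
                                 n_restarts = 5, jitter = 0.2,
                                 warmup = TRUE, seed = 1) {
  stopifnot(inherits(init, "energy_params"), length(free) >= 1)
  observable <- observable %||% attr(data, "observable") %||% "sheet_fraction"
  conc <- data$conc_uM
  obs <- data$value
  wt <- if ("se" %in% names(data) && all(is.finite(data$se)) &&
            all(data$se > 0)) 1 / data$se else rep(1, length(obs))
  lo <- setNames(rep(-25, length(free)), free)
  hi <- setNames(rep(25, length(free)), free)
  if (!is.null(lower)) lo[names(lower)] <- lower
  if (!is.null(upper)) hi[names(upper)] <- upper
  start0 <- vapply(free, function(nm) init[[nm]], 0)
  start0 <- pmin(pmax(start0, lo), hi)
  n_eval <- 0L
  make_params <- function(par) {
    repl <- as.list(par)
    if (!is.null(ties)) for (nm in names(ties)) repl[[nm]] <- par[[ties[[nm]]]]
    do.call(update_params, c(list(init), repl))
  }
  resid_fun <- function(par) {
    n_eval <<- n_eval + 1L
    pars <- make_params(setNames(par, free))
    pred <- tryCatch(.predict_curve(ensemble, pars, conc, observable),
                     error = function(e) rep(NA_real_, length(obs)))
    r <- (obs - pred) * wt
    r[!is.finite(r)] <- 1e6
    r
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  starts <- c(list(start0), lapply(seq_len(max(0, n_restarts - 1)), function(i) {
    pmin(pmax(start0 * (1 + runif(length(start0), -jitter, jitter)) +
                ifelse(start0 == 0, runif(length(start0), -jitter, jitter), 0),
              lo), hi)
  }))
  fits <- lapply(starts, function(st) {
    if (warmup && length(free) > 1L) {
      w <- tryCatch(
        minpack.lm::nls.lm(par = st[1L], lower = lo[1L], upper = hi[1L],
                           fn = function(p1) resid_fun(c(p1, st[-1L])),
                           control = minpack.lm::nls.lm.control(maxiter = 15)),
        error = function(e) NULL
      )
      if (!is.null(w)) st[1L] <- w$par
    }
    tryCatch(
      minpack.lm::nls.lm(par = st, lower = lo, upper = hi, fn = resid_fun,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-12, ptol = 1e-10)),
      error = function(e) NULL
    )
  })
  fits <- Filter(Negate(is.null), fits)
  if (!length(fits)) stop("all optimizer starts failed", call. = FALSE)
  best <- fits[[which.min(vapply(fits, function(f) f$deviance, 0))]]
  est <- setNames(as.numeric(best$par), free)
  n <- length(obs); npar <- length(free)
  sigma2 <- best$deviance / max(1, n - npar)
  vc <- tryCatch(solve(best$hessian) * sigma2, error = function(e) NULL)
  se <- if (is.null(vc)) rep(NA_real_, npar) else sqrt(pmax(0, diag(vc)))
  ## flatness diagnostic: objective change across the bound interval
  flat <- vapply(seq_along(free), function(i) {
    f_at <- function(v) { p <- est; p[i] <- v; sum(resid_fun(p)^2) }
    span <- abs(f_at(lo[i]) - best$deviance) + abs(f_at(hi[i]) - best$deviance)
    span < 1e-4
  }, TRUE)
  at_bound <- est <= lo + 1e-8 | est >= hi - 1e-8
  pars_opt <- make_params(est)
  pred <- .predict_curve(ensemble, pars_opt, conc, observable)
  structure(list(
    estimates = est, std_errors = setNames(se, free),
    flat = setNames(flat, free), at_bound = setNames(at_bound, free),
    params = pars_opt, rss = best$deviance, sigma = sqrt(sigma2),
    converged = best$info %in% 1:4, info = best$info,
    n_eval = n_eval, n_obs = n, observable = observable,
    data = tibble::tibble(conc_uM = conc, value = obs, fitted = pred),
    restart_deviances = vapply(fits, function(f) f$deviance, 0),
    free = free, ties = ties, lower = lo, upper = hi
  ), class = "amyloid_fit")
}

#' @export
print.amyloid_fit <- function(x, ...) {
  cat(sprintf("<amyloid_fit> %s, %d points, RSS %.4g%s\n",
              x$observable, x$n_obs, x$rss,
              if (x$converged) "" else " (NOT converged)"))
  print(generics::tidy(x))
  invisible(x)
}

#' Tidy a fitted observable curve
#'
#' @param x An `amyloid_fit`.
#' @param ... Unused.
#' @return A tibble with one row per free parameter: `term`, `estimate`
#'   (RT units), `std.error`, `flat` (profile flat across the whole bound
#'   interval) and `at_bound`.
#' @importFrom generics tidy
#' @export
tidy.amyloid_fit <- function(x, ...) {
  tibble::tibble(term = x$free, estimate = unname(x$estimates),
                 std.error = unname(x$std_errors),
                 flat = unname(x$flat), at_bound = unname(x$at_bound))
}

#' One-row fit summary
#'
#' @param x An `amyloid_fit`.
#' @param ... Unused.
#' @importFrom generics glance
#' @export
glance.amyloid_fit <- function(x, ...) {
  tibble::tibble(rss = x$rss, sigma = x$sigma, nobs = x$n_obs,
                 n_par = length(x$free), converged = x$converged,
                 n_eval = x$n_eval)
}
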