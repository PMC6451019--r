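#' Configuration of the simultaneous multi-sensillum fit
#'
#' Controls which parameters are free, their bounds, the multistart
#' schedule and the residual weighting of [global_fit()]. The fit structure
#' mirrors the measurement situation: circuit constants are shared across
#' all sensilla, each ORN gets its own odorant sensitivity `k_od`, and for
#' sensilla without measured dendritic surfaces the pair
#' (`A_d2`, spike/LFP ratio `r`) is fitted with `A_d1` derived through
#' [dendrite_area_from_ratio()]. The resting potential `V_0` is always
#' fixed (it anchors the battery calibration).
#'
#' @param free_common Character vector of common parameters to fit, any of
#'   `"E_A"`, `"rho_s"`, `"rho_d0"`, `"n"`, `"g_max"`. Default: all five.
#'   Use `character(0)` for a fixed-common fit that only estimates
#'   sensitivities and dendritic surfaces.
#' @param bounds Named list of `c(lower, upper)` bounds. Defaults cover the
#'   physiologically plausible range; `r` defaults to (1, 5\], the span of
#'   measured spike/LFP slope ratios.
#' @param n_starts Number of multistart runs (jittered initial values).
#' @param seed Integer seed for the start jitter.
#' @param weighting `"unweighted"` (default) or `"inverse_sem"` (weight
#'   replicate means by 1/s.e.m.).
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(free_common = c("E_A", "rho_s", "rho_d0", "n", "g_max"),
                       bounds = list(),
                       n_starts = 32L, seed = 1L,
                       weighting = c("unweighted", "inverse_sem")) {
  weighting <- match.arg(weighting)
  all_common <- c("E_A", "rho_s", "rho_d0", "n", "g_max")
  if (!all(free_common %in% all_common)) {
    abort("`free_common` may only contain E_A, rho_s, rho_d0, n, g_max.",
          class = "sensillum_config_error")
  }
  default_bounds <- list(
    E_A = c(40, 150), rho_s = c(5, 100), rho_d0 = c(2, 100),
    n = c(0.2, 3), g_max = c(1, 100),
    k_od = c(-12, 2), A_d = c(1, 500), r = c(1 + 1e-6, 5)
  )
  for (nm in names(bounds)) default_bounds[[nm]] <- bounds[[nm]]
  for (nm in names(default_bounds)) {
    b <- default_bounds[[nm]]
    if (length(b) != 2L || !all(is.finite(b)) || b[1] >= b[2]) {
      abort(sprintf("Bound for '%s' must be finite and ordered.", nm),
            class = "sensillum_config_error")
    }
  }
  structure(list(free_common = free_common, bounds = default_bounds,
                 n_starts = as.integer(n_starts), seed = as.integer(seed),
                 weighting = weighting),
            class = "fit_config")
}

# Collapse replicate measurements to per-(sensillum, orn, x) means + sem.
.summarize_lfp <- function(data) {
  need <- c("sensillum", "orn", "x", "lfp_mV")
  if (!all(need %in% names(data))) {
    abort(sprintf("Data must have columns %s.", paste(need, collapse = ", ")),
          class = "sensillum_config_error")
  }
  data |>
    dplyr::group_by(.data$sensillum, .data$orn, .data$x) |>
    dplyr::summarise(
      lfp_mean = mean(.data$lfp_mV),
      lfp_sem = sd(.data$lfp_mV) / sqrt(dplyr::n()),
      n_rep = dplyr::n(), .groups = "drop"
    ) |>
    dplyr::arrange(.data$sensillum, .data$orn, .data$x)
}

# Closed-form V_A for given total branch resistances (numeric hot path for
# the optimizer; equivalent to solve_circuit()$V_A).
.va_closed <- function(model, R_1, R_2) {
  E_T <- (model$E_1 * R_2 + model$E_2 * R_1) / (R_1 + R_2)
  R_T <- R_1 * R_2 / (R_1 + R_2)
  model$common$E_A + (E_T - model$common$E_A) / (R_T + model$R_A) * model$R_A
}

#' Residuals of the circuit model against LFP dose-response data
#'
#' Compares model-predicted LFP responses (|transepithelial deflection|
#' from rest, single-odorant stimulation of each ORN) with measured
#' replicate means, one residual per (sensillum, ORN, concentration).
#'
#' @param models Named list of calibrated [sensillum_model()] objects; the
#'   names must cover every sensillum present in `data`.
#' @param data Long-format LFP table with columns `sensillum`, `orn`
#'   ("A"/"B"), `x` (log10 dilution), `replicate`, `lfp_mV`.
#' @param weighting `"unweighted"` or `"inverse_sem"`.
#' @return A tibble with columns `sensillum`, `orn`, `x`, `observed_mean`,
#'   `observed_sem`, `predicted`, `residual` (predicted − observed) and
#'   `weight`.
#' @export
model_residuals <- function(models, data,
                            weighting = c("unweighted", "inverse_sem")) {
  weighting <- match.arg(weighting)
  summ <- .summarize_lfp(data)
  missing_models <- setdiff(unique(summ$sensillum), names(models))
  if (length(missing_models)) {
    abort(sprintf("No model supplied for sensillum: %s.",
                  paste(missing_models, collapse = ", ")),
          class = "sensillum_config_error")
  }
  pred <- purrr::map_dbl(seq_len(nrow(summ)), function(i) {
    m <- models[[summ$sensillum[i]]]
    dr <- dose_response(m, stimulated = if (summ$orn[i] == "A") 1L else 2L,
                        x_grid = summ$x[i])
    dr$lfp_mV
  })
  w <- if (weighting == "inverse_sem") {
    1 / pmax(summ$lfp_sem, 0.05, na.rm = TRUE)
  } else rep(1, nrow(summ))
  tibble::tibble(
    sensillum = summ$sensillum, orn = summ$orn, x = summ$x,
    observed_mean = summ$lfp_mean, observed_sem = summ$lfp_sem,
    predicted = pred, residual = pred - summ$lfp_mean, weight = w
  )
}

# --- parameter-vector plumbing for global_fit ------------------------------

# Describe the free-parameter layout for a given dataset + sensilla specs.
.param_layout <- function(summ, sensilla, common, config) {
  rows <- list()
  for (nm in config$free_common) {
    rows[[length(rows) + 1L]] <- tibble::tibble(
      name = nm, kind = "common", sensillum = NA_character_,
      init = common[[nm]],
      lower = config$bounds[[nm]][1], upper = config$bounds[[nm]][2])
  }
  for (sn in sort(unique(summ$sensillum))) {
    sp <- sensilla[[sn]]
    if (is.null(sp)) {
      abort(sprintf("Dataset sensillum '%s' has no entry in `sensilla`.", sn),
            class = "sensillum_config_error")
    }
    for (side in c("A", "B")) {
      sub <- summ[summ$sensillum == sn & summ$orn == side, ]
      # data-driven init: dilution at which the response crosses half its max
      init_k <- if (nrow(sub) >= 2L && max(sub$lfp_mean) > 0) {
        half <- max(sub$lfp_mean) / 2
        sub$x[which.min(abs(sub$lfp_mean - half))]
      } else -4
      rows[[length(rows) + 1L]] <- tibble::tibble(
        name = paste0("k_od.", sn, side), kind = "k_od", sensillum = sn,
        init = init_k,
        lower = config$bounds$k_od[1], upper = config$bounds$k_od[2])
    }
    measured <- sp$orn1$A_d_is_measured && sp$orn2$A_d_is_measured
    if (!measured) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        name = paste0("A_d2.", sn), kind = "A_d", sensillum = sn,
        init = if (!is.na(sp$orn2$A_d)) sp$orn2$A_d else 20,
        lower = config$bounds$A_d[1], upper = config$bounds$A_d[2])
      rows[[length(rows) + 1L]] <- tibble::tibble(
        name = paste0("r.", sn), kind = "r", sensillum = sn,
        init = 2,
        lower = config$bounds$r[1], upper = config$bounds$r[2])
    }
  }
  dplyr::bind_rows(rows)
}

# Rebuild common params + per-sensillum geometry from a parameter vector.
# Returns NULL on infeasible (calibration / non-physical) parameters.
.models_from_par <- function(par, layout, sensilla, common, sens_names) {
  cm <- unclass(common)
  for (i in which(layout$kind == "common")) cm[[layout$name[i]]] <- par[[i]]
  cm <- tryCatch(do.call(common_params, cm), error = function(e) NULL)
  if (is.null(cm)) return(NULL)
  out <- list()
  for (sn in sens_names) {
    sp <- sensilla[[sn]]
    o1 <- sp$orn1; o2 <- sp$orn2
    k1 <- par[[match(paste0("k_od.", sn, "A"), layout$name)]]
    k2 <- par[[match(paste0("k_od.", sn, "B"), layout$name)]]
    o1$k_od <- k1; o2$k_od <- k2
    measured <- o1$A_d_is_measured && o2$A_d_is_measured
    if (!measured) {
      o2$A_d <- par[[match(paste0("A_d2.", sn), layout$name)]]
      r <- par[[match(paste0("r.", sn), layout$name)]]
      A_d1 <- tryCatch(dendrite_area_from_ratio(r, o1, o2, cm),
                       error = function(e) NULL)
      if (is.null(A_d1)) return(NULL)
      o1$A_d <- A_d1
    }
    m <- tryCatch(calibrate_resting(cm, o1, o2), error = function(e) NULL)
    if (is.null(m)) return(NULL)
    out[[sn]] <- m
  }
  out
}

#' Simultaneous circuit fit of LFP dose-response data from several sensilla
#'
#' Fits the passive circuit model to measured (or synthetic) LFP
#' dose-response tables from one or more sensilla at once, with the common
#' circuit constants shared across all sensilla and ORN-specific
#' sensitivities and (where unmeasured) dendritic surfaces free. The
#' objective is the (optionally 1/s.e.m.-weighted) sum of squared
#' differences between model LFP and replicate-mean LFP. Minimization uses
#' Levenberg-Marquardt least squares ([minpack.lm::nls.lm()]) with box
#' bounds, restarted from `n_starts` jittered initial points; infeasible
#' parameter regions (failed calibration, non-physical ratio inversion)
#' return a large finite penalty so starts can escape them.
#'
#' With a single sensillum and all common parameters free the problem is
#' under-determined (the shared constants are only pinned down jointly
#' across several geometries); such fits are flagged with a warning and
#' `under_determined = TRUE` in the result.
#'
#' @param data Long-format LFP table: columns `sensillum`, `orn` ("A"/"B"),
#'   `x` (log10 dilution), `replicate`, `lfp_mV`. Each curve needs at least
#'   4 concentrations.
#' @param sensilla Named list of per-sensillum specs (elements `orn1`,
#'   `orn2` [orn_spec()] objects), as returned in
#'   `default_params()$sensilla`. Soma areas are always fixed inputs;
#'   `A_d_is_measured` decides whether dendritic surfaces are fixed or
#'   fitted (via `A_d2` + ratio `r`).
#' @param common Starting/fixed values of the common constants.
#' @param config A [fit_config()].
#' @return An object of class `sensillum_fit`: tibbles `parameters`
#'   (estimate per parameter with bounds), `residuals`, `starts` (per-start
#'   objective and convergence), the best `objective`, refitted `models`,
#'   and bookkeeping fields. Supports [tidy()] and [glance()].
#' @examples
#' \donttest{
#' truth <- lapply(c(ab4 = "ab4"), sensillum_model)
#' d <- generate_lfp_data(truth, x_grid = -8:-2, noise_sd = 0, seed = 1)
#' fit <- global_fit(d, config = fit_config(free_common = character(0),
#'                                          n_starts = 2))
#' tidy(fit)
#' }
#' @export
global_fit <- function(data, sensilla = default_params()$sensilla,
                       common = common_params(), config = fit_config()) {
  stopifnot(inherits(config, "fit_config"))
  summ <- .summarize_lfp(data)
  bad <- summ |>
    dplyr::count(.data$sensillum, .data$orn) |>
    dplyr::filter(.data$n < 4L)
  if (nrow(bad)) {
    abort("Every (sensillum, ORN) curve needs at least 4 concentrations.",
          class = "sensillum_config_error")
  }
  sens_names <- sort(unique(summ$sensillum))
  layout <- .param_layout(summ, sensilla, common, config)
  if (nrow(layout) == 0L) {
    abort("No free parameters.", class = "sensillum_config_error")
  }
  under_determined <- length(sens_names) == 1L &&
    length(config$free_common) >= 5L
  if (under_determined) {
    warning("Single-sensillum fit with all common parameters free is under-determined; interpret shared constants with caution.",
            call. = FALSE)
  }

  w <- if (config$weighting == "inverse_sem") {
    1 / pmax(summ$lfp_sem, 0.05, na.rm = TRUE)
  } else rep(1, nrow(summ))
  idx_A <- lapply(sens_names, function(sn) which(summ$sensillum == sn & summ$orn == "A"))
  idx_B <- lapply(sens_names, function(sn) which(summ$sensillum == sn & summ$orn == "B"))
  names(idx_A) <- names(idx_B) <- sens_names
  obs <- summ$lfp_mean
  penalty <- rep(1e3, nrow(summ))

  resid_fn <- function(par) {
    models <- .models_from_par(par, layout, sensilla, common, sens_names)
    if (is.null(models)) return(penalty * w)
    pred <- numeric(length(obs))
    for (sn in sens_names) {
      m <- models[[sn]]
      cm <- m$common
      ia <- idx_A[[sn]]; ib <- idx_B[[sn]]
      base_VA <- m$resting$V_A
      if (length(ia)) {
        gA <- cm$g_max / (1 + 10^(cm$n * (m$orn1$k_od - summ$x[ia])))
        R_1 <- m$R_in1 + cm$rho_d0 / (m$orn1$A_d * (1 + gA))
        pred[ia] <- abs(.va_closed(m, R_1, m$R_2_0) - base_VA)
      }
      if (length(ib)) {
        gB <- cm$g_max / (1 + 10^(cm$n * (m$orn2$k_od - summ$x[ib])))
        R_2 <- m$R_in2 + cm$rho_d0 / (m$orn2$A_d * (1 + gB))
        pred[ib] <- abs(.va_closed(m, m$R_1_0, R_2) - base_VA)
      }
    }
    (pred - obs) * w
  }

  # multistart: first start at the layout inits, the rest jittered in-bounds
  set.seed(config$seed)
  starts <- vector("list", config$n_starts)
  starts[[1L]] <- layout$init
  if (config$n_starts > 1L) {
    for (s in 2:config$n_starts) {
      jit <- layout$init
      for (i in seq_len(nrow(layout))) {
        span <- layout$upper[i] - layout$lower[i]
        step <- switch(layout$kind[i],
                       k_od = runif(1, -1.5, 1.5),
                       A_d = layout$init[i] * runif(1, -0.5, 1),
                       r = runif(1, -1, 2),
                       common = layout$init[i] * runif(1, -0.3, 0.6))
        jit[i] <- min(max(layout$init[i] + step, layout$lower[i]),
                      layout$upper[i])
      }
      starts[[s]] <- jit
    }
  }

  run_one <- function(p0) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = p0, lower = layout$lower, upper = layout$upper,
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) return(list(ok = FALSE, sse = Inf, par = p0, info = -1L))
    list(ok = fit$info %in% 1:4, sse = sum(fit$fvec^2),
         par = unname(fit$par), info = fit$info)
  }
  runs <- lapply(starts, run_one)
  sses <- vapply(runs, function(r) r$sse, numeric(1L))
  if (all(!is.finite(sses))) {
    abort("All multistart runs failed; check data and bounds.",
          class = "sensillum_fit_error")
  }
  best_i <- which.min(sses)
  # polish: refit once from the best optimum (restart-stability contract)
  polished <- run_one(runs[[best_i]]$par)
  best <- if (polished$sse <= runs[[best_i]]$sse) polished else runs[[best_i]]

  models <- .models_from_par(best$par, layout, sensilla, common, sens_names)
  res_tbl <- model_residuals(models, data, config$weighting)

  par_tbl <- layout |>
    dplyr::mutate(estimate = best$par) |>
    dplyr::select("name", "kind", "sensillum", "estimate", "init",
                  "lower", "upper")
  # derived dendritic surfaces for ratio-parameterized sensilla
  derived <- purrr::map_dfr(sens_names, function(sn) {
    m <- models[[sn]]
    if (m$orn1$A_d_is_measured && m$orn2$A_d_is_measured) return(NULL)
    tibble::tibble(name = paste0("A_d1.", sn), kind = "derived",
                   sensillum = sn, estimate = m$orn1$A_d,
                   init = NA_real_, lower = NA_real_, upper = NA_real_)
  })

  structure(list(
    parameters = dplyr::bind_rows(par_tbl, derived),
    objective = best$sse,
    residuals = res_tbl,
    starts = tibble::tibble(
      start = seq_along(runs),
      objective = sses,
      converged = vapply(runs, function(r) r$ok, logical(1L))),
    models = models,
    converged = best$ok,
    under_determined = under_determined,
    config = config,
    n_points = nrow(summ)
  ), class = "sensillum_fit")
}

#' @export
print.sensillum_fit <- function(x, ...) {
  cat(sprintf("<sensillum_fit> %d sensilla, %d data points, %d free parameters\n",
              length(x$models), x$n_points,
              sum(x$parameters$kind != "derived")))
  cat(sprintf("  objective (weighted SSE): %.6g  [best of %d starts, %s]\n",
              x$objective, nrow(x$starts),
              if (x$converged) "converged" else "not converged"))
  if (x$under_determined) cat("  WARNING: under-determined configuration\n")
  print(x$parameters, n = Inf)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a sensillum fit
#'
#' @param x A `sensillum_fit`.
#' @param ... Unused.
#' @return `tidy()`: one row per parameter (free and derived) with
#'   `estimate` and bounds. `glance()`: a one-row model summary.
#' @export
tidy.sensillum_fit <- function(x, ...) x$parameters

#' @rdname tidy.sensillum_fit
#' @export
glance.sensillum_fit <- function(x, ...) {
  tibble::tibble(
    objective = x$objective,
    n_points = x$n_points,
    n_free = sum(x$parameters$kind != "derived"),
    n_starts = nrow(x$starts),
    n_converged = sum(x$starts$converged),
    converged = x$converged,
    under_determined = x$under_determined
  )
}

#' Hill fit of an empirical dose-response curve
#'
#' Fits \eqn{y = p / (1 + 10^{\,n_h (k - x)})} to (log10 dilution,
#' response) pairs by Levenberg-Marquardt least squares — the standard
#' descriptive fit for LFP or firing-rate dose-response data, independent
#' of any circuit mechanism.
#'
#' @param x log10 dilutions (\eqn{\ge 4} distinct values spanning the rise).
#' @param response Responses (e.g. |LFP| in mV), same length.
#' @return An object of class `sensillum_hill_fit` with elements `plateau`,
#'   `k_half`, `n_hill`, `fitted`, `sse`; supports [tidy()].
#' @examples
#' x <- seq(-8, -2)
#' y <- 17.6 / (1 + 10^(0.7 * (-5.9 - x)))
#' tidy(hill_fit(x, y))
#' @export
hill_fit <- function(x, response) {
  if (length(x) != length(response) || length(x) < 4L) {
    abort("Need at least 4 (x, response) pairs.",
          class = "sensillum_fit_error")
  }
  if (sd(response) == 0) {
    abort("Degenerate data: all responses identical.",
          class = "sensillum_fit_error")
  }
  ymax <- max(response)
  if (ymax <= 0) {
    abort("Degenerate data: no positive responses.",
          class = "sensillum_fit_error")
  }
  k0 <- x[which.min(abs(response - ymax / 2))]
  resid_fn <- function(p) {
    p["plateau"] / (1 + 10^(p["n_hill"] * (p["k_half"] - x))) - response
  }
  run <- function(p0) {
    tryCatch(minpack.lm::nls.lm(
      par = p0, lower = c(plateau = 1e-8, k_half = min(x) - 10, n_hill = 0.05),
      upper = c(plateau = 10 * ymax, k_half = max(x) + 10, n_hill = 10),
      fn = resid_fn,
      control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
  }
  fits <- Filter(Negate(is.null), lapply(
    list(c(plateau = ymax, k_half = k0, n_hill = 1),
         c(plateau = 1.5 * ymax, k_half = k0 - 1, n_hill = 0.5),
         c(plateau = 1.1 * ymax, k_half = k0 + 1, n_hill = 2)), run))
  if (!length(fits)) {
    abort("Hill fit failed from every start.", class = "sensillum_fit_error")
  }
  sses <- vapply(fits, function(f) sum(f$fvec^2), numeric(1L))
  best <- fits[[which.min(sses)]]
  sse_const <- sum((response - mean(response))^2)
  if (min(sses) > sse_const + 1e-9) {
    abort("Hill fit is worse than a constant: data do not describe a rising curve.",
          class = "sensillum_fit_error")
  }
  p <- best$par
  structure(list(plateau = unname(p["plateau"]), k_half = unname(p["k_half"]),
                 n_hill = unname(p["n_hill"]),
                 fitted = response + best$fvec, sse = min(sses),
                 x = x, response = response),
            class = "sensillum_hill_fit")
}

#' @export
tidy.sensillum_hill_fit <- function(x, ...) {
  tibble::tibble(term = c("plateau", "k_half", "n_hill"),
                 estimate = c(x$plateau, x$k_half, x$n_hill))
}

#' @export
print.sensillum_hill_fit <- function(x, ...) {
  cat(sprintf("<hill_fit> plateau = %.4g mV, k_half = %.4g, n = %.4g (SSE %.4g)\n",
              x$plateau, x$k_half, x$n_hill, x$sse))
  invisible(x)
}

#' Linear spike-versus-LFP fit
#'
#' Ordinary least-squares line through (|LFP|, peak firing rate) points:
#' the slope is the neuron's spike/LFP ratio, whose A-to-B quotient
#' constrains the circuit fit via [dendrite_area_from_ratio()].
#'
#' @param lfp Abscissa values (|LFP|, mV); must not be constant.
#' @param spikes Ordinate values (spikes/s), same length (\eqn{\ge 3}).
#' @return A one-row tibble with `slope`, `intercept`, `slope_se`,
#'   `intercept_se`, `r_squared`.
#' @examples
#' linear_fit(c(1, 2, 3, 4), c(3.1, 4.9, 7.2, 8.8))
#' @export
linear_fit <- function(lfp, spikes) {
  if (length(lfp) != length(spikes) || length(lfp) < 3L) {
    abort("Need at least 3 (lfp, spikes) pairs.",
          class = "sensillum_fit_error")
  }
  if (sd(lfp) == 0) {
    abort("Degenerate data: constant abscissa.",
          class = "sensillum_fit_error")
  }
  fit <- lm(spikes ~ lfp)
  s <- summary(fit)
  tibble::tibble(
    slope = coef(fit)[["lfp"]],
    intercept = coef(fit)[["(Intercept)"]],
    slope_se = s$coefficients["lfp", "Std. Error"],
    intercept_se = s$coefficients["(Intercept)", "Std. Error"],
    r_squared = s$r.squared
  )
}
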