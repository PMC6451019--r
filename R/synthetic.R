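#' Generate synthetic LFP dose-response datasets
#'
#' Emulates the structure of single-sensillum LFP dose-response
#' measurements: for each sensillum, each ORN is stimulated alone with its
#' private odorant over a log10-dilution grid, and the peak |LFP| is
#' recorded for `replicates` independent sensilla (replicate pairs).
#' Measurements are the noiseless model responses plus i.i.d. additive
#' Gaussian noise of standard deviation `noise_sd` (homoscedastic, in mV,
#' untruncated). The generating models are embedded in the result as
#' ground truth for recovery scoring.
#'
#' @param models Named list of calibrated [sensillum_model()] objects (one
#'   per sensillum); both ORNs need `k_od` set.
#' @param x_grid log10 dilutions at which responses are measured.
#' @param replicates Number of replicate ORN pairs per sensillum
#'   (default 9, the typical sample size of such recordings).
#' @param noise_sd Measurement noise s.d. in mV (default 0.5, matching the
#'   error-bar scale of published LFP dose-response curves).
#' @param seed Integer seed; identical seeds give identical datasets.
#' @return A tibble of class `sensillum_synthetic` with columns
#'   `sensillum`, `orn` ("A"/"B"), `x`, `replicate`, `lfp_mV`
#'   (`sensilla` x 2 x `|x_grid|` x `replicates` rows) and attributes
#'   `ground_truth` (the models) and `noise_sd`, `seed`.
#' @examples
#' m <- list(ab4 = sensillum_model("ab4"))
#' d <- generate_lfp_data(m, x_grid = -8:-2, replicates = 9, seed = 1)
#' nrow(d) # 1 * 2 * 7 * 9
#' @export
generate_lfp_data <- function(models, x_grid, replicates = 9L,
                              noise_sd = 0.5, seed = 1L) {
  if (!is.list(models) || is.null(names(models)) ||
      !all(vapply(models, inherits, logical(1L), "sensillum_model"))) {
    abort("`models` must be a named list of sensillum_model objects.",
          class = "sensillum_config_error")
  }
  if (replicates < 1L) {
    abort("`replicates` must be >= 1.", class = "sensillum_config_error")
  }
  if (noise_sd < 0) {
    abort("`noise_sd` must be >= 0.", class = "sensillum_config_error")
  }
  set.seed(as.integer(seed))
  out <- purrr::imap_dfr(models, function(m, sn) {
    purrr::map_dfr(c(A = 1L, B = 2L), function(side) {
      clean <- dose_response(m, stimulated = side, x_grid = x_grid)$lfp_mV
      tidyr::expand_grid(x = x_grid, replicate = seq_len(replicates)) |>
        dplyr::mutate(
          sensillum = sn,
          orn = if (side == 1L) "A" else "B",
          lfp_mV = rep(clean, each = replicates) +
            rnorm(length(x_grid) * replicates, 0, noise_sd)
        )
    })
  }) |>
    dplyr::select("sensillum", "orn", "x", "replicate", "lfp_mV")
  attr(out, "ground_truth") <- models
  attr(out, "noise_sd") <- noise_sd
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("sensillum_synthetic", class(out))
  out
}

#' Write/read the LFP dose-response CSV dialect
#'
#' The interchange format for measured or synthetic LFP tables: a plain
#' CSV with columns `sensillum`, `orn`, `x_log10_dilution`, `replicate`,
#' `lfp_mV`, preceded by a `# sensillum-lfp-v1` schema comment line.
#'
#' @param data A table with columns `sensillum`, `orn`, `x`, `replicate`,
#'   `lfp_mV`.
#' @param path Output/input file path.
#' @return `write_lfp_csv()` returns `path` invisibly; `read_lfp_csv()`
#'   returns a tibble in the internal column naming (`x`).
#' @export
write_lfp_csv <- function(data, path) {
  out <- data |>
    dplyr::select("sensillum", "orn", x_log10_dilution = "x",
                  "replicate", "lfp_mV")
  con <- file(path, "w")
  writeLines("# sensillum-lfp-v1", con)
  close(con)
  readr::write_csv(out, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_lfp_csv
#' @export
read_lfp_csv <- function(path) {
  readr::read_csv(path, comment = "#", show_col_types = FALSE) |>
    dplyr::rename(x = "x_log10_dilution")
}

#' Monte-Carlo parameter-recovery experiment
#'
#' Repeats generate-then-fit cycles: for each of `n_seeds` child seeds a
#' synthetic dataset is drawn from the ground-truth models and refit with
#' [global_fit()]; recovered odorant sensitivities and dendritic surfaces
#' are scored against truth. This is the package's calibration harness for
#' the fitting stage: it quantifies bias and spread of each estimate under
#' the noise level and replicate structure the data are assumed to have.
#'
#' @param truth Named list of ground-truth [sensillum_model()] objects.
#' @param x_grid,replicates,noise_sd Passed to [generate_lfp_data()].
#' @param config [fit_config()] used for every fit. The default fixes the
#'   common circuit constants at their reference values and estimates
#'   sensitivities and (unmeasured) dendritic surfaces — the configuration
#'   under which a single synthetic study is well identified.
#' @param n_seeds Number of independent generate+fit repetitions.
#' @param seed Master seed; child seeds are drawn from it and reported.
#' @return A list of class `sensillum_recovery` with tibbles `per_run`
#'   (one row per run and parameter: truth, estimate, error) and `summary`
#'   (per parameter: bias = median signed error, `mae` = median absolute
#'   error, and for areas the relative versions), plus `n_failed`.
#' @examples
#' \donttest{
#' truth <- list(ab4 = sensillum_model("ab4"))
#' rec <- recovery_experiment(truth, x_grid = -8:-2, n_seeds = 2,
#'                            config = fit_config(free_common = character(0),
#'                                                n_starts = 2))
#' rec$summary
#' }
#' @export
recovery_experiment <- function(truth, x_grid = -8:-2, replicates = 9L,
                                noise_sd = 0.5,
                                config = fit_config(
                                  free_common = character(0), n_starts = 4L),
                                n_seeds = 20L, seed = 1L) {
  stopifnot(n_seeds >= 1L)
  set.seed(as.integer(seed))
  child_seeds <- sample.int(2^30, n_seeds)

  truth_tbl <- purrr::imap_dfr(truth, function(m, sn) {
    rows <- list(tibble::tibble(name = paste0("k_od.", sn, "A"),
                                truth = m$orn1$k_od),
                 tibble::tibble(name = paste0("k_od.", sn, "B"),
                                truth = m$orn2$k_od))
    if (!(m$orn1$A_d_is_measured && m$orn2$A_d_is_measured)) {
      rows <- c(rows,
                list(tibble::tibble(name = paste0("A_d2.", sn),
                                    truth = m$orn2$A_d),
                     tibble::tibble(name = paste0("A_d1.", sn),
                                    truth = m$orn1$A_d)))
    }
    dplyr::bind_rows(rows)
  })

  sensilla <- lapply(truth, function(m) list(orn1 = m$orn1, orn2 = m$orn2))
  # the fit must not peek at the true sensitivities or free surfaces
  for (sn in names(sensilla)) {
    sensilla[[sn]]$orn1$k_od <- NA_real_
    sensilla[[sn]]$orn2$k_od <- NA_real_
    if (!(sensilla[[sn]]$orn1$A_d_is_measured &&
          sensilla[[sn]]$orn2$A_d_is_measured)) {
      sensilla[[sn]]$orn1$A_d <- NA_real_
    }
  }
  common <- truth[[1L]]$common

  runs <- purrr::map(seq_len(n_seeds), function(i) {
    d <- generate_lfp_data(truth, x_grid = x_grid, replicates = replicates,
                           noise_sd = noise_sd, seed = child_seeds[i])
    fit <- tryCatch(
      global_fit(d, sensilla = sensilla, common = common, config = config),
      error = function(e) NULL)
    if (is.null(fit)) return(tibble::tibble())
    fit$parameters |>
      dplyr::filter(.data$kind %in% c("k_od", "A_d", "derived")) |>
      dplyr::select("name", "estimate") |>
      dplyr::mutate(run = i, child_seed = child_seeds[i])
  })
  n_failed <- sum(vapply(runs, function(r) nrow(r) == 0L, logical(1L)))
  if (n_failed > n_seeds / 2) {
    abort(sprintf("Recovery experiment failed: %d of %d fits errored.",
                  n_failed, n_seeds),
          class = "sensillum_fit_error")
  }
  per_run <- dplyr::bind_rows(runs) |>
    dplyr::inner_join(truth_tbl, by = "name") |>
    dplyr::mutate(error = .data$estimate - .data$truth,
                  rel_error = .data$error / .data$truth)

  summary <- per_run |>
    dplyr::group_by(.data$name) |>
    dplyr::summarise(
      truth = .data$truth[1L],
      bias = median(.data$error),
      mae = median(abs(.data$error)),
      rel_bias = median(.data$rel_error),
      rel_mae = median(abs(.data$rel_error)),
      n_runs = dplyr::n(), .groups = "drop"
    )
  structure(list(per_run = per_run, summary = summary,
                 n_failed = n_failed, child_seeds = child_seeds),
            class = "sensillum_recovery")
}

#' @export
print.sensillum_recovery <- function(x, ...) {
  cat(sprintf("<sensillum_recovery> %d runs (%d failed)\n",
              length(x$child_seeds), x$n_failed))
  print(x$summary, n = Inf)
  invisible(x)
}
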