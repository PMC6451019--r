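#' Sensillum-independent circuit constants
#'
#' Bundles the circuit parameters shared by all sensilla: the auxiliary-cell
#' battery, the common ORN resting potential, membrane resistivities
#' (rescaled by the auxiliary-cell resistance \eqn{R_A}, so they carry units
#' of \eqn{\mu m^2}), the Hill coefficient of odorant activation, and the
#' maximal activation-induced conductance gain.
#'
#' @param E_A Auxiliary-cell battery, mV. Must exceed `V_0`.
#' @param V_0 ORN resting membrane potential, mV.
#' @param rho_s Soma membrane resistivity rescaled by \eqn{R_A}, \eqn{\mu m^2}.
#' @param rho_d0 Basal dendritic membrane resistivity rescaled by \eqn{R_A},
#'   \eqn{\mu m^2}.
#' @param n Hill coefficient of odorant activation (dimensionless, > 0).
#' @param g_max Maximal activation-induced conductance gain (dimensionless,
#'   \eqn{\ge 0}); the product of basal dendritic resistivity and maximal
#'   activation-induced conductivity.
#'
#' @return An object of class `common_params` (a named list).
#' @examples
#' common_params() # defaults for Drosophila antennal basiconic sensilla
#' @export
common_params <- function(E_A = 77, V_0 = -60, rho_s = 30, rho_d0 = 17,
                          n = 0.7, g_max = 10) {
  vals <- list(E_A = E_A, V_0 = V_0, rho_s = rho_s, rho_d0 = rho_d0,
               n = n, g_max = g_max)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      abort(sprintf("`%s` must be a single finite number.", nm),
            class = "sensillum_param_error")
    }
  }
  if (rho_s <= 0) abort("`rho_s` must be positive.", class = "sensillum_param_error")
  if (rho_d0 <= 0) abort("`rho_d0` must be positive.", class = "sensillum_param_error")
  if (n <= 0) abort("`n` must be positive.", class = "sensillum_param_error")
  if (g_max < 0) abort("`g_max` must be non-negative.", class = "sensillum_param_error")
  if (E_A <= V_0) {
    abort("`E_A` must exceed `V_0` (the transepithelial battery drives the receptor current).",
          class = "sensillum_param_error")
  }
  structure(vals, class = "common_params")
}

#' @export
print.common_params <- function(x, ...) {
  cat("<common_params>\n")
  cat(sprintf("  E_A = %g mV, V_0 = %g mV\n", x$E_A, x$V_0))
  cat(sprintf("  rho_s = %g um^2, rho_d0 = %g um^2 (R_A-rescaled)\n",
              x$rho_s, x$rho_d0))
  cat(sprintf("  Hill n = %g, g_max = %g\n", x$n, x$g_max))
  invisible(x)
}

#' One ORN's morphometry and odorant sensitivity
#'
#' @param label Identifier, e.g. `"ab4A"`. By convention the "A" neuron of a
#'   pair is the larger, large-spike neuron.
#' @param A_s Soma surface area, \eqn{\mu m^2}.
#' @param A_d Outer (sensory) dendrite surface area, \eqn{\mu m^2}. May be
#'   `NA` for a neuron whose dendritic surface is a free fitting parameter.
#' @param k_od log10 odorant sensitivity: the half-activating dilution is
#'   \eqn{10^{k_{od}}} (the undiluted stock is dilution \eqn{10^0}).
#' @param A_d_is_measured Whether `A_d` comes from morphometric measurement
#'   (`TRUE`) or is treated as a free parameter (`FALSE`).
#'
#' @return An object of class `orn_spec`.
#' @examples
#' orn_spec("ab4A", A_s = 137, A_d = 38, k_od = -5.9)
#' @export
orn_spec <- function(label, A_s, A_d = NA_real_, k_od = NA_real_,
                     A_d_is_measured = !is.na(A_d)) {
  if (!is.character(label) || length(label) != 1L) {
    abort("`label` must be a single string.", class = "sensillum_param_error")
  }
  if (!is.numeric(A_s) || length(A_s) != 1L || !is.finite(A_s) || A_s <= 0) {
    abort(sprintf("`A_s` for %s must be a single positive number.", label),
          class = "sensillum_param_error")
  }
  if (!is.na(A_d) && (!is.finite(A_d) || A_d <= 0)) {
    abort(sprintf("`A_d` for %s must be positive when set.", label),
          class = "sensillum_param_error")
  }
  if (!is.na(k_od) && !is.finite(k_od)) {
    abort(sprintf("`k_od` for %s must be finite.", label),
          class = "sensillum_param_error")
  }
  structure(list(label = label, A_s = as.numeric(A_s), A_d = as.numeric(A_d),
                 k_od = as.numeric(k_od),
                 A_d_is_measured = isTRUE(A_d_is_measured)),
            class = "orn_spec")
}

#' @export
print.orn_spec <- function(x, ...) {
  cat(sprintf("<orn_spec> %s: A_s = %g um^2, A_d = %s um^2%s, k_od = %s\n",
              x$label, x$A_s,
              ifelse(is.na(x$A_d), "free", format(x$A_d)),
              ifelse(x$A_d_is_measured, " (measured)", ""),
              ifelse(is.na(x$k_od), "unset", format(x$k_od))))
  invisible(x)
}

# Reference geometry and sensitivity for the three basiconic sensillum types
# with both electrophysiological and morphometric data. Dendritic surfaces of
# ab3 and ab4 are fitted values; ab5's were measured directly.
.default_orn_table <- function() {
  sens <- rep(c("ab3", "ab4", "ab5"), each = 2L)
  side <- rep(c("A", "B"), 3L)
  tibble::tibble(
    sensillum = sens,
    orn       = side,
    label     = paste0(sens, side),
    A_s       = c(98, 91, 137, 75, 65, 67),
    A_d       = c(46, 16, 38, 25, 20, 20),
    A_d_is_measured = rep(c(FALSE, FALSE, TRUE), each = 2L),
    k_od      = c(-4.8, -5.1, -5.9, -2.5, -1, -2)
  )
}

#' Reference ORN parameter table
#'
#' Morphometry (soma and outer-dendrite surface areas) and log10 odorant
#' sensitivities for the ORN pairs of the Drosophila ab3, ab4 and ab5
#' basiconic sensilla. The ab5 dendritic surfaces are morphometric
#' measurements; the ab3 and ab4 dendritic surfaces are model-fitted values
#' (flagged by `A_d_is_measured`).
#'
#' @return A tibble with columns `sensillum`, `orn` ("A"/"B"), `label`,
#'   `A_s` (\eqn{\mu m^2}), `A_d` (\eqn{\mu m^2}), `A_d_is_measured`,
#'   `k_od` (log10 dilution).
#' @examples
#' default_orn_params()
#' @export
default_orn_params <- function() .default_orn_table()

#' Read and write circuit parameter files
#'
#' Parameter sets round-trip through a YAML file with a `common:` block (the
#' [common_params()] fields) and a `sensilla:` block (one entry per
#' sensillum, each with `A`/`B` ORN blocks). A packaged default file holding
#' the reference ab3/ab4/ab5 values ships in
#' `system.file("extdata", "default_params.yaml", package = "sensillum")`.
#'
#' @param path File path. For `load_params()` the file must exist and
#'   contain exactly the expected keys.
#' @return `load_params()` returns a list with elements `common` (a
#'   [common_params()] object) and `sensilla` (a named list; each element a
#'   list with `orn1`, `orn2` [orn_spec()] objects). `save_params()` returns
#'   `path` invisibly.
#' @examples
#' p <- load_params(system.file("extdata", "default_params.yaml",
#'                              package = "sensillum"))
#' p$common$E_A
#' @export
load_params <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Parameter file not found: %s", path),
          class = "sensillum_config_error")
  }
  raw <- yaml::read_yaml(path)
  if (!setequal(names(raw), c("common", "sensilla"))) {
    abort("Parameter file must have exactly the top-level keys 'common' and 'sensilla'.",
          class = "sensillum_config_error")
  }
  cm <- raw$common
  # YAML 1.1 scans a bare `n` key as boolean; map it back
  names(cm)[names(cm) %in% c("FALSE", "false")] <- "n"
  need <- c("E_A", "V_0", "rho_s", "rho_d0", "n", "g_max")
  missing_keys <- setdiff(need, names(cm))
  extra_keys <- setdiff(names(cm), need)
  if (length(missing_keys) || length(extra_keys)) {
    abort(sprintf("Bad 'common' block: missing [%s], unexpected [%s].",
                  paste(missing_keys, collapse = ", "),
                  paste(extra_keys, collapse = ", ")),
          class = "sensillum_config_error")
  }
  for (k in need) {
    if (!is.numeric(cm[[k]])) {
      abort(sprintf("Key 'common.%s' must be numeric.", k),
            class = "sensillum_config_error")
    }
  }
  common <- do.call(common_params, cm)
  sensilla <- lapply(names(raw$sensilla), function(sn) {
    blk <- raw$sensilla[[sn]]
    if (!all(c("A", "B") %in% names(blk))) {
      abort(sprintf("Sensillum '%s' must define ORN blocks 'A' and 'B'.", sn),
            class = "sensillum_config_error")
    }
    mk <- function(side) {
      o <- blk[[side]]
      allowed <- c("A_s", "A_d", "k_od", "A_d_is_measured")
      extra <- setdiff(names(o), allowed)
      if (length(extra)) {
        abort(sprintf("Unexpected key(s) [%s] in sensillum '%s' ORN '%s'.",
                      paste(extra, collapse = ", "), sn, side),
              class = "sensillum_config_error")
      }
      if (is.null(o$A_s) || !is.numeric(o$A_s)) {
        abort(sprintf("Key 'sensilla.%s.%s.A_s' must be numeric.", sn, side),
              class = "sensillum_config_error")
      }
      orn_spec(paste0(sn, side), A_s = o$A_s,
               A_d = if (is.null(o$A_d)) NA_real_ else o$A_d,
               k_od = if (is.null(o$k_od)) NA_real_ else o$k_od,
               A_d_is_measured = isTRUE(o$A_d_is_measured))
    }
    list(orn1 = mk("A"), orn2 = mk("B"))
  })
  names(sensilla) <- names(raw$sensilla)
  list(common = common, sensilla = sensilla)
}

#' @param params A list as returned by `load_params()`.
#' @rdname load_params
#' @export
save_params <- function(params, path) {
  stopifnot(is.list(params), inherits(params$common, "common_params"))
  as_blk <- function(o) {
    b <- list(A_s = o$A_s)
    if (!is.na(o$A_d)) b$A_d <- o$A_d
    if (!is.na(o$k_od)) b$k_od <- o$k_od
    b$A_d_is_measured <- o$A_d_is_measured
    b
  }
  out <- list(
    common = unclass(params$common),
    sensilla = lapply(params$sensilla,
                      function(s) list(A = as_blk(s$orn1), B = as_blk(s$orn2)))
  )
  yaml::write_yaml(out, path, precision = 15L)
  invisible(path)
}

#' @rdname load_params
#' @export
default_params <- function() {
  load_params(system.file("extdata", "default_params.yaml",
                          package = "sensillum", mustWork = TRUE))
}
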