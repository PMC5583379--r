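# Peleg-Fermi cell-death model: electric field -> death probability ->
# predicted ablation areas.

#' Electroporation pulse protocol
#'
#' The exposure parameters the survival model depends on. The default is the
#' protocol emulated throughout the package: two trains of four pulses (8
#' pulses altogether), each 100 us long, 700 V amplitude, repeated at 5 kHz.
#'
#' @param n_pulses Number of delivered pulses (N), at least 1.
#' @param t_p_s Single-pulse duration in seconds, positive.
#' @param amplitude_v Applied voltage amplitude (V).
#' @param rep_freq_hz Pulse repetition frequency (Hz).
#' @return An object of class `pulse_protocol`.
#' @export
pulse_protocol <- function(n_pulses = 8L, t_p_s = 100e-6,
                           amplitude_v = 700, rep_freq_hz = 5000) {
  n_pulses <- as.integer(n_pulses)
  if (n_pulses < 1L) stop("pulse_protocol: n_pulses must be >= 1")
  if (!is.finite(t_p_s) || t_p_s <= 0) stop("pulse_protocol: t_p_s must be positive")
  structure(list(n_pulses = n_pulses, t_p_s = t_p_s,
                 amplitude_v = amplitude_v, rep_freq_hz = rep_freq_hz),
            class = "pulse_protocol")
}

#' @export
print.pulse_protocol <- function(x, ...) {
  cat(sprintf("<pulse_protocol> N = %d, t_p = %g us, %g V, %g Hz\n",
              x$n_pulses, x$t_p_s * 1e6, x$amplitude_v, x$rep_freq_hz))
  invisible(x)
}

#' Peleg-Fermi survival-curve parameters
#'
#' `e_c` is the critical field at which half the cells are killed and `k`
#' the kinetic constant setting the steepness of the survival curve; both
#' depend on the pulse number and duration and are quoted in kV/cm.
#'
#' @param e_c_kv_cm Critical field (kV/cm), positive.
#' @param k_kv_cm Kinetic constant (kV/cm), positive.
#' @param n_pulses,t_p_s The `(N, t_p)` exposure the pair was calibrated for.
#' @return An object of class `peleg_fermi_params`.
#' @export
peleg_fermi_params <- function(e_c_kv_cm, k_kv_cm, n_pulses = NA_integer_,
                               t_p_s = NA_real_) {
  if (!is.finite(e_c_kv_cm) || e_c_kv_cm <= 0)
    stop("peleg_fermi_params: e_c_kv_cm must be positive")
  if (!is.finite(k_kv_cm) || k_kv_cm <= 0)
    stop("peleg_fermi_params: k_kv_cm must be positive")
  structure(list(e_c_kv_cm = e_c_kv_cm, k_kv_cm = k_kv_cm,
                 n_pulses = n_pulses, t_p_s = t_p_s),
            class = "peleg_fermi_params")
}

#' @export
print.peleg_fermi_params <- function(x, ...) {
  cat(sprintf("<peleg_fermi_params> Ec = %g kV/cm, k = %g kV/cm (N = %s, t_p = %s us)\n",
              x$e_c_kv_cm, x$k_kv_cm, x$n_pulses, x$t_p_s * 1e6))
  invisible(x)
}

#' Bundled Peleg-Fermi parameter table
#'
#' Reads the calibration table of `(N, t_p) -> (Ec, k)` entries shipped with
#' the package, or a user-supplied CSV with the same columns
#' (`n_pulses`, `t_p_us`, `e_c_kv_cm`, `k_kv_cm`). Only in-vitro calibrated
#' entries for the pulse regime the package targets are bundled; users may
#' extend the table for other exposures.
#'
#' @param path Optional path to a CSV replacing the bundled table.
#' @return A data frame with the columns above.
#' @export
pf_param_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "peleg_fermi_params.csv",
                        package = "mreitire", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("n_pulses", "t_p_us", "e_c_kv_cm", "k_kv_cm")
  if (!all(need %in% names(tab)))
    stop("pf_param_table: table must have columns ", paste(need, collapse = ", "))
  if (any(tab$e_c_kv_cm <= 0) || any(tab$k_kv_cm <= 0))
    stop("pf_param_table: Ec and k must be positive")
  tab
}

#' Look up Peleg-Fermi parameters for a pulse protocol
#'
#' Exact match on pulse number and duration; an unknown `(N, t_p)` raises an
#' error listing the available calibrations rather than extrapolating.
#'
#' @param protocol A [pulse_protocol()].
#' @param table Parameter table from [pf_param_table()].
#' @return A [peleg_fermi_params()].
#' @export
#' @examples
#' lookup_params(pulse_protocol(8, 100e-6))  # Ec 2.344, k 0.2677 kV/cm
lookup_params <- function(protocol, table = pf_param_table()) {
  t_p_us <- protocol$t_p_s * 1e6
  hit <- which(table$n_pulses == protocol$n_pulses &
                 abs(table$t_p_us - t_p_us) <= 1e-9 * pmax(1, abs(t_p_us)))
  if (length(hit) == 0L) {
    avail <- paste(sprintf("(N=%d, t_p=%g us)", table$n_pulses, table$t_p_us),
                   collapse = ", ")
    stop(sprintf(
      "lookup_params: no Peleg-Fermi parameters for (N=%d, t_p=%g us); available: %s",
      protocol$n_pulses, t_p_us, avail))
  }
  row <- table[hit[1L], ]
  peleg_fermi_params(row$e_c_kv_cm, row$k_kv_cm,
                     n_pulses = row$n_pulses, t_p_s = row$t_p_us * 1e-6)
}

#' Peleg-Fermi cell survival
#'
#' The Fermi (logistic) survival curve
#' `S(E) = 1 / (1 + exp((E - Ec) / k))` with `E`, `Ec` and `k` in kV/cm.
#' Death probability is `1 - S`; at `E = Ec` exactly half the cells die.
#'
#' @param e_kv_cm Field value(s) in kV/cm, nonnegative.
#' @param params A [peleg_fermi_params()].
#' @return Survival probability in `[0, 1]`, same shape as `e_kv_cm`.
#' @export
pf_survival <- function(e_kv_cm, params) {
  if (any(e_kv_cm < 0)) stop("pf_survival: field must be nonnegative")
  1 / (1 + exp((e_kv_cm - params$e_c_kv_cm) / params$k_kv_cm))
}

#' Peleg-Fermi cell-death probability
#'
#' @inheritParams pf_survival
#' @return Death probability `1 - S`, in `[0, 1]`.
#' @export
#' @examples
#' p <- lookup_params(pulse_protocol())
#' pf_death(p$e_c_kv_cm, p)  # exactly 0.5
pf_death <- function(e_kv_cm, params) 1 - pf_survival(e_kv_cm, params)

#' Death-probability map from an electric field map
#'
#' Applies the Peleg-Fermi death probability pointwise. Field maps are
#' carried internally in V/m and converted to kV/cm (divide by 1e5) at this
#' module boundary, matching the unit the calibration constants are published
#' in.
#'
#' @param e_map An `efield` [ep_map()] (V/m), finite.
#' @param params A [peleg_fermi_params()].
#' @return A `death_prob` [ep_map()] with values in `[0, 1]`.
#' @export
death_map <- function(e_map, params) {
  grid <- map_grid(e_map)
  if (!identical(map_kind(e_map), "efield"))
    stop("death_map: expected an efield map (V/m)")
  e <- map_data(e_map)
  if (!all(is.finite(e))) stop("death_map: field map contains non-finite values")
  ep_map(pf_death(e / 1e5, params), grid, "death_prob")
}

#' Predicted ablation area at a death-probability level
#'
#' The predicted region is the super-level set `d >= p` (inclusive threshold,
#' no connected-component filtering); its area is the pixel count times the
#' pixel area. Optionally only components touching the inter-electrode axis
#' could be kept via `mask` for histology-like comparisons.
#'
#' @param d A `death_prob` [ep_map()].
#' @param p Probability level, strictly inside `(0, 1)`.
#' @param mask Optional logical matrix intersected with the region.
#' @return List with `area_mm2` and `region` (logical matrix).
#' @export
predict_area <- function(d, p, mask = NULL) {
  if (!is.finite(p) || p <= 0 || p >= 1)
    stop("predict_area: p must be strictly inside (0, 1)")
  grid <- map_grid(d)
  region <- map_data(d) >= p
  if (!is.null(mask)) {
    if (!all(dim(mask) == dim(region))) stop("predict_area: mask shape mismatch")
    region <- region & mask
  }
  list(area_mm2 = sum(region) * grid$pixel_mm^2, region = region)
}

#' Predicted area as a function of the probability level
#'
#' Evaluates [predict_area()] on a strictly increasing grid of levels;
#' the areas are non-increasing in `p` by construction.
#'
#' @param d A `death_prob` [ep_map()].
#' @param p_grid Strictly increasing probabilities in `(0, 1)`.
#' @param mask Optional logical matrix intersected with each region.
#' @return Data frame with columns `p` and `a_ire_mm2`.
#' @export
area_curve <- function(d, p_grid = c(0.1, 0.2, 0.3), mask = NULL) {
  if (length(p_grid) < 1L || any(!is.finite(p_grid)) ||
      any(p_grid <= 0) || any(p_grid >= 1) ||
      (length(p_grid) > 1L && any(diff(p_grid) <= 0)))
    stop("area_curve: p_grid must be strictly increasing inside (0, 1)")
  areas <- vapply(p_grid, function(p) predict_area(d, p, mask)$area_mm2, numeric(1))
  data.frame(p = p_grid, a_ire_mm2 = areas)
}
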