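#' Specification for a synthetic multi-probe temperature log
#'
#' Ground-truth parameters of a saturating-exponential heating/cooling
#' record: per-probe true initial slope (K/s) or saturation rise
#' `dT_max` (degC) together with the time constant `tau` (s); the two are
#' tied by `slope = dT_max / tau` and supplying both inconsistently is an
#' error.  Cooling may use its own time constant (real calorimetry is
#' asymmetric); the default is equal.
#'
#' @param slopes named numeric vector of per-probe true initial slopes,
#'   K/s (names become probe labels).
#' @param tau heating time constant, s.
#' @param dT_max optional named saturation rises, degC; derived from
#'   `slopes * tau` when omitted.
#' @param tau_cooling cooling time constant, s (default `tau`).
#' @param baseline starting temperature, degC.
#' @param field_off_time,duration timing, s (duration > field_off_time).
#' @param sampling_rate Hz.
#' @param noise_sd Gaussian sensor noise SD, degC.
#' @return an object of class `synthetic_log_spec`.
#' @export
synthetic_log_spec <- function(slopes = c(C = 0.3457, R = 0.2957,
                                          L = 0.2657, T = 0.2357, O = 0.238),
                               tau = 250,
                               dT_max = NULL,
                               tau_cooling = tau,
                               baseline = 19,
                               field_off_time = 600, duration = 900,
                               sampling_rate = 1, noise_sd = 0.1) {
  stopifnot(duration > field_off_time, tau > 0, tau_cooling > 0,
            sampling_rate > 0, noise_sd >= 0, !is.null(names(slopes)))
  if (is.null(dT_max)) {
    dT_max <- slopes * tau
  } else {
    if (max(abs(dT_max - slopes * tau)) > 1e-9 * max(abs(dT_max)))
      stop("inconsistent spec: slope must equal dT_max / tau")
  }
  structure(list(slopes = slopes, dT_max = dT_max, tau = tau,
                 tau_cooling = tau_cooling, baseline = baseline,
                 field_off_time = field_off_time, duration = duration,
                 sampling_rate = sampling_rate, noise_sd = noise_sd),
            class = "synthetic_log_spec")
}

#' Generate a synthetic multi-probe temperature log
#'
#' Heating branch `T(t) = baseline + dT_max (1 - exp(-t/tau))`; after
#' field-off, exponential decay toward baseline with the cooling time
#' constant; seeded Gaussian noise per sample.  A pure function of
#' (spec, seed): identical inputs give identical records.
#'
#' The default spec emulates a measured five-probe record of an iron-PLA
#' scaffold in agar: probe C hottest, R/L intermediate, T and the
#' out-of-scaffold probe O lowest.  It is a constructed fixture with
#' known ground truth, not measured data.
#'
#' @param spec a [synthetic_log_spec()].
#' @param seed integer RNG seed.
#' @return a `temperature_record`; the true slopes are carried in
#'   `meta$truth`.
#' @export
generate_temperature_log <- function(spec = synthetic_log_spec(), seed = 1L) {
  stopifnot(inherits(spec, "synthetic_log_spec"))
  tq <- seq(0, spec$duration, by = 1 / spec$sampling_rate)
  probes <- names(spec$slopes)
  temps <- sapply(probes, function(p) {
    dT <- spec$dT_max[[p]]
    Th <- spec$baseline + dT * (1 - exp(-tq / spec$tau))
    Toff <- spec$baseline + dT * (1 - exp(-spec$field_off_time / spec$tau))
    cool <- tq > spec$field_off_time
    Th[cool] <- spec$baseline + (Toff - spec$baseline) *
      exp(-(tq[cool] - spec$field_off_time) / spec$tau_cooling)
    Th
  })
  if (spec$noise_sd > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    temps <- temps + matrix(rnorm(length(temps), 0, spec$noise_sd),
                            nrow(temps), ncol(temps))
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  }
  colnames(temps) <- probes
  temperature_record(tq, temps, spec$field_off_time,
                     meta = list(truth = spec, seed = seed,
                                 synthetic = TRUE))
}

#' Generate a non-magnetic control log
#'
#' Background record of a control (non-magnetic) sample: baseline plus a
#' linear thermal drift plus sensor noise, with zero magnetic heating.
#' Used to validate background subtraction.
#'
#' @param spec a [synthetic_log_spec()] (its probes, timing, noise and
#'   baseline are reused; the magnetic slopes are ignored).
#' @param drift background drift rate, K/s (>= 0).
#' @param seed integer RNG seed.
#' @return a `temperature_record`.
#' @export
generate_control_log <- function(spec = synthetic_log_spec(), drift = 0,
                                 seed = 2L) {
  stopifnot(drift >= 0)
  tq <- seq(0, spec$duration, by = 1 / spec$sampling_rate)
  probes <- names(spec$slopes)
  temps <- matrix(spec$baseline + drift * tq, length(tq), length(probes),
                  dimnames = list(NULL, probes))
  if (spec$noise_sd > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    temps <- temps + matrix(rnorm(length(temps), 0, spec$noise_sd),
                            nrow(temps), ncol(temps))
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  }
  temperature_record(tq, temps, spec$field_off_time,
                     meta = list(drift = drift, seed = seed,
                                 control = TRUE, synthetic = TRUE))
}

#' Generate a noisy pickup-coil EMF reading
#'
#' Faraday closed-form peak-to-peak EMF of the probe coil in a uniform
#' sinusoidal field, plus seeded Gaussian instrument noise.
#'
#' @param field_amplitude flux density amplitude, T (peak).
#' @param frequency Hz (> 0).
#' @param probe a [probe_coil_spec()].
#' @param noise_sd reading noise SD, V.
#' @param seed integer RNG seed.
#' @return peak-to-peak voltage, V.
#' @export
generate_emf_reading <- function(field_amplitude, frequency,
                                 probe = probe_coil_spec(),
                                 noise_sd = 0, seed = 1L) {
  vpp <- field_to_emf(field_amplitude / MU0, frequency, probe)
  if (noise_sd > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    vpp <- vpp + rnorm(1, 0, noise_sd)
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  }
  vpp
}
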