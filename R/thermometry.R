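#' Probe layout for virtual fiber-optic thermometry
#'
#' Named probe positions relative to the scaffold centre.  The standard
#' layout mirrors the measurement protocol: C at the scaffold centre, L
#' and R 7 mm to either side on the x axis, T 9 mm up the axis (all inside
#' the scaffold), and O in the surrounding phantom above the scaffold.
#' O is placed axially (20 mm above centre) because the thin radial agar
#' gap of the reference phantom cannot host a probe 1 cm away radially.
#'
#' @param positions named list (or n x 3 matrix with rownames) of probe
#'   positions in m, relative to the scaffold centre.
#' @param sampling_rate samples per second, Hz.
#' @param noise_sd Gaussian sensor noise SD, degC.
#' @return an object of class `probe_layout`.
#' @export
probe_layout <- function(positions, sampling_rate = 1, noise_sd = 0.1) {
  if (is.list(positions)) {
    positions <- do.call(rbind, positions)
  }
  colnames(positions) <- NULL
  stopifnot(is.matrix(positions), ncol(positions) == 3,
            !is.null(rownames(positions)), sampling_rate > 0, noise_sd >= 0)
  structure(list(positions = positions, sampling_rate = sampling_rate,
                 noise_sd = noise_sd),
            class = "probe_layout")
}

#' @rdname probe_layout
#' @export
default_probe_layout <- function(sampling_rate = 1, noise_sd = 0.1) {
  probe_layout(list(C = c(0, 0, 0),
                    L = c(-7e-3, 0, 0),
                    R = c(7e-3, 0, 0),
                    T = c(0, 0, 9e-3),
                    O = c(0, 0, 20e-3)),
               sampling_rate = sampling_rate, noise_sd = noise_sd)
}

# shift a layout with the sample
shift_layout <- function(layout, offset) {
  layout$positions <- sweep(layout$positions, 2, -as.numeric(offset))
  layout
}

#' Construct a multi-probe temperature record
#'
#' The container consumed by the SAR estimators: a strictly increasing
#' time base, one temperature column per probe, the field-off instant, and
#' metadata (frequency, rated flux density, specific heat used).
#'
#' @param times sample times, s (strictly increasing; at least 3 samples
#'   before `field_off_time`).
#' @param temps numeric matrix, one named column per probe, degC.
#' @param field_off_time s.
#' @param meta named list of metadata.
#' @return object of class `temperature_record`.
#' @export
temperature_record <- function(times, temps, field_off_time, meta = list()) {
  temps <- as.matrix(temps)
  stopifnot(length(times) == nrow(temps), !is.null(colnames(temps)))
  if (is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing")
  if (sum(times < field_off_time) < 3L)
    stop("need at least 3 samples before field_off_time")
  structure(list(times = times, temps = temps,
                 field_off_time = field_off_time, meta = meta),
            class = "temperature_record")
}

#' Sample virtual probes from a simulated temperature history
#'
#' Trilinear interpolation of the temperature field at each probe position
#' (dense solver tracking when the history was run with matching probe
#' points, otherwise interpolation of the stored snapshots), resampled at
#' the layout's sampling rate, with seeded additive Gaussian sensor noise.
#' Deterministic for a fixed seed.
#'
#' @param history a `temperature_history` from [solve_transient()].
#' @param layout a [probe_layout()] in absolute coordinates (use
#'   `origin` to place a scaffold-relative layout).
#' @param seed integer RNG seed for the sensor noise.
#' @param origin absolute position of the layout origin (scaffold centre),
#'   m.
#' @return a `temperature_record`.
#' @export
sample_probes <- function(history, layout, seed = 1L, origin = c(0, 0, 0)) {
  stopifnot(inherits(history, "temperature_history"),
            inherits(layout, "probe_layout"))
  pos <- sweep(layout$positions, 2, -as.numeric(origin))
  tq <- seq(0, max(history$times), by = 1 / layout$sampling_rate)
  n <- nrow(pos)
  tracked <- !is.null(history$probe_points) &&
    nrow(history$probe_points) == n &&
    max(abs(history$probe_points - pos)) < 1e-12
  temps <- matrix(NA_real_, length(tq), n,
                  dimnames = list(NULL, rownames(pos)))
  if (tracked) {
    for (j in seq_len(n))
      temps[, j] <- approx(history$times, history$probes[, j], xout = tq)$y
  } else {
    ax <- history$voxels$axes
    vals <- sapply(seq_along(history$snapshot_times), function(i) {
      arr <- history$snapshots[[i]]
      arr[is.na(arr)] <- history$exposure$ambient_temperature
      interp_grid3(ax, arr, pos)
    })
    vals <- matrix(vals, nrow = n)
    for (j in seq_len(n))
      temps[, j] <- approx(history$snapshot_times, vals[j, ], xout = tq,
                           rule = 2)$y
  }
  if (layout$noise_sd > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    temps <- temps + matrix(rnorm(length(temps), 0, layout$noise_sd),
                            nrow(temps), n)
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  }
  temperature_record(tq, temps, history$field_off_time,
                     meta = list(frequency = history$exposure$frequency,
                                 b0_T = history$exposure$target_flux_density,
                                 seed = seed))
}

#' Subtract a non-magnetic control record
#'
#' Removes background heating (coil self-heating, ambient drift) measured
#' on a non-magnetic control sample: per-probe difference between record
#' and control with the control's initial baseline restored, so a control
#' identical to the record gives a flat trace at baseline and a flat
#' control leaves the record unchanged.  The control is resampled onto the
#' record's time base by interpolation.
#'
#' @param record,control `temperature_record`s with matching probe names
#'   (extra control probes are ignored; a single-probe control is applied
#'   to every record probe).
#' @return a background-corrected `temperature_record` (flagged in
#'   `meta$background_corrected`).
#' @export
subtract_background <- function(record, control) {
  stopifnot(inherits(record, "temperature_record"),
            inherits(control, "temperature_record"))
  if (min(control$times) > min(record$times) + 1e-9 ||
      max(control$times) < max(record$times) - 1e-9)
    stop("alignment error: control does not cover the record's time range")
  out <- record$temps
  for (j in colnames(record$temps)) {
    jc <- if (j %in% colnames(control$temps)) j else colnames(control$temps)[1]
    ctrl <- approx(control$times, control$temps[, jc], xout = record$times,
                   rule = 2)$y
    out[, j] <- record$temps[, j] - ctrl + ctrl[1]
  }
  record$temps <- out
  record$meta$background_corrected <- TRUE
  record
}

#' Initial slope of a heating curve
#'
#' Ordinary least-squares slope of temperature versus time over the fit
#' window starting at field-on; the core of the initial-slope calorimetric
#' method.
#'
#' @param times sample times, s.
#' @param temps temperatures, degC.
#' @param window fit window length, s (must not exceed the field-on
#'   interval when `field_off_time` is given).
#' @param field_off_time optional field-off instant, s.
#' @return list with `slope` (K/s), `se` (standard error), `n`, `window`.
#' @examples
#' t <- 0:30
#' initial_slope(t, 19 + 0.05 * t, window = 30)$slope  # 0.05
#' @export
initial_slope <- function(times, temps, window = 30, field_off_time = NULL) {
  if (!is.null(field_off_time) && window > field_off_time)
    stop("fit window extends past field-off time")
  sel <- times >= 0 & times <= window
  if (sum(sel) < 3L) stop("fit error: fewer than 3 samples in the window")
  fit <- lm(temps[sel] ~ times[sel])
  # suppress the "essentially perfect fit" note for noiseless fixtures
  sm <- suppressWarnings(summary(fit))$coefficients
  list(slope = unname(sm[2, 1]), se = unname(sm[2, 2]),
       n = sum(sel), window = window)
}

#' Loss-corrected slope from the saturating-exponential model
#'
#' Fits the Box-Lucas heating model
#' `T(t) = T0 + dT_max (1 - exp(-t / tau))` to the field-on branch and
#' returns the loss-corrected initial slope `dT_max / tau`.  When the
#' record extends past field-off, the cooling branch is fitted with its
#' own exponential decay and the ratio of the two time constants is
#' reported as a consistency diagnostic.
#'
#' @param times sample times, s.
#' @param temps temperatures, degC.
#' @param field_off_time field-off instant, s.
#' @return list with `slope` (K/s), `se`, `T0`, `dT_max`, `tau`,
#'   `tau_cooling` (NA if no usable cooling branch), `tau_ratio`.
#' @export
corrected_slope <- function(times, temps, field_off_time) {
  heat <- times <= field_off_time
  if (sum(heat) < 5L) stop("estimation error: too few heating samples")
  th <- times[heat]; Th <- temps[heat]
  start <- list(T0 = Th[1], dT = max(Th) - Th[1] + 1e-6,
                tau = field_off_time / 3)
  fit <- tryCatch(
    minpack.lm::nlsLM(Th ~ T0 + dT * (1 - exp(-th / tau)), start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("estimation error: heating fit failed (",
                             conditionMessage(e), ")"))
  cf <- coef(fit)
  V <- stats::vcov(fit)
  # delta method for dT/tau
  grad <- c(0, 1 / cf[["tau"]], -cf[["dT"]] / cf[["tau"]]^2)
  se <- sqrt(drop(t(grad) %*% V %*% grad))
  tau_cool <- NA_real_
  cool <- times > field_off_time
  if (sum(cool) >= 30) {
    tc <- times[cool] - field_off_time; Tc <- temps[cool]
    cfit <- tryCatch(
      minpack.lm::nlsLM(Tc ~ Tb + dTc * exp(-tc / tauc),
                        start = list(Tb = min(Tc), dTc = max(Tc) - min(Tc),
                                     tauc = field_off_time / 3)),
      error = function(e) NULL)
    if (!is.null(cfit)) tau_cool <- coef(cfit)[["tauc"]]
  }
  list(slope = cf[["dT"]] / cf[["tau"]], se = se, T0 = cf[["T0"]],
       dT_max = cf[["dT"]], tau = cf[["tau"]], tau_cooling = tau_cool,
       tau_ratio = tau_cool / cf[["tau"]])
}

#' SAR from a single heating slope
#'
#' The initial-slope calorimetric estimator `SAR = C_p * dT/dt`, with the
#' specific heat of the surrounding agar phantom by default.
#'
#' @param slope heating slope, K/s.
#' @param specific_heat J g^-1 K^-1 (default agar, 4.2).
#' @return SAR in W/g.
#' @examples
#' sar_single(0.05)  # 0.21 W/g
#' @export
sar_single <- function(slope, specific_heat = 4.2) {
  stopifnot(specific_heat > 0)
  specific_heat * slope
}

#' Multi-probe averaged SAR
#'
#' Per-probe initial (or corrected) slopes converted to SAR and averaged:
#' `SAR = C_p * mean_i(dT_i/dt_i)` over the `N_T` selected probe curves,
#' reported as mean +/- sample standard deviation.  The default probe
#' subset is the four probes inside the scaffold (C, R, L, T).  The
#' sensitivity of the mean to the fit window is evaluated over
#' `window_sensitivity` and stored in the result.
#'
#' @param record a `temperature_record`.
#' @param probes character vector of probe names to include.
#' @param specific_heat J g^-1 K^-1.
#' @param window fit window, s.
#' @param method `"slope"` (OLS initial slope) or `"corrected"`
#'   (saturating-exponential fit).
#' @param window_sensitivity windows (s) over which the mean SAR is
#'   re-evaluated for the sensitivity report.
#' @return object of class `sar_result`: `probes`, per-probe `slopes`,
#'   `se`, `sar`, `mean_sar`, `sd_sar`, `n_probes`, `window`,
#'   `window_sensitivity`.
#' @export
sar_average <- function(record, probes = c("C", "R", "L", "T"),
                        specific_heat = 4.2, window = 30,
                        method = c("slope", "corrected"),
                        window_sensitivity = c(10, 30, 60)) {
  method <- match.arg(method)
  stopifnot(inherits(record, "temperature_record"))
  probes <- intersect(probes, colnames(record$temps))
  if (!length(probes)) stop("estimation error: empty probe subset")
  one <- function(j, w) {
    if (method == "slope")
      initial_slope(record$times, record$temps[, j], window = w,
                    field_off_time = record$field_off_time)
    else corrected_slope(record$times, record$temps[, j],
                         record$field_off_time)
  }
  fits <- lapply(probes, one, w = window)
  slopes <- vapply(fits, `[[`, numeric(1), "slope")
  ses <- vapply(fits, `[[`, numeric(1), "se")
  sars <- sar_single(slopes, specific_heat)
  ws <- if (method == "slope") {
    vapply(window_sensitivity, function(w) {
      mean(vapply(probes, function(j) one(j, w)$slope, numeric(1))) *
        specific_heat
    }, numeric(1))
  } else rep(NA_real_, length(window_sensitivity))
  structure(list(probes = probes,
                 slopes = setNames(slopes, probes),
                 se = setNames(ses, probes),
                 sar = setNames(sars, probes),
                 mean_sar = mean(sars),
                 sd_sar = if (length(sars) > 1L) sd(sars) else 0,
                 n_probes = length(probes), window = window,
                 method = method,
                 window_sensitivity = setNames(ws, window_sensitivity),
                 specific_heat = specific_heat),
            class = "sar_result")
}

#' @export
print.sar_result <- function(x, ...) {
  cat(sprintf("SAR (%s method, %g s window, C_p = %g J/g/K):\n",
              x$method, x$window, x$specific_heat))
  for (p in x$probes)
    cat(sprintf("  %s: slope %.4f K/s -> %.3f W/g\n", p, x$slopes[p], x$sar[p]))
  cat(sprintf("  mean +/- SD over %d probes: %.3f +/- %.3f W/g (%.1f%%)\n",
              x$n_probes, x$mean_sar, x$sd_sar,
              100 * x$sd_sar / x$mean_sar))
  invisible(x)
}

#' Read / write multi-probe temperature logs as CSV
#'
#' Header comment lines carry the metadata (`# freq_hz=`, `# b0_mT=`,
#' `# t_off_s=`, `# cp_J_per_gK=`); data follow in long format
#' (`time_s, probe, temp_C`).  The reader also accepts wide format (one
#' column per probe).
#'
#' @param record a `temperature_record` (for writing).
#' @param path file path.
#' @param format `"long"` or `"wide"` (writing).
#' @return `read_temperature_log` returns a `temperature_record`.
#' @export
read_temperature_log <- function(path) {
  hdr <- grep("^#", readLines(path, warn = FALSE), value = TRUE)
  getm <- function(key, default = NA_real_) {
    l <- grep(paste0("^#\\s*", key, "="), hdr, value = TRUE)
    if (!length(l)) return(default)
    v <- suppressWarnings(as.numeric(sub(paste0("^#\\s*", key, "="), "", l[1])))
    if (is.na(v)) default else v
  }
  df <- read.csv(path, comment.char = "#")
  t_off <- getm("t_off_s", Inf)
  if (all(c("time_s", "probe", "temp_C") %in% names(df))) {
    probes <- unique(df$probe)
    times <- sort(unique(df$time_s))
    temps <- sapply(probes, function(p) {
      d <- df[df$probe == p, ]
      d$temp_C[match(times, d$time_s)]
    })
    colnames(temps) <- probes
  } else {
    stopifnot("time_s" %in% names(df))
    times <- df$time_s
    temps <- as.matrix(df[setdiff(names(df), "time_s")])
  }
  temperature_record(times, temps, field_off_time = t_off,
                     meta = list(frequency = getm("freq_hz"),
                                 b0_T = getm("b0_mT") / 1e3,
                                 cp_J_per_gK = getm("cp_J_per_gK")))
}

#' @rdname read_temperature_log
#' @export
write_temperature_log <- function(record, path, format = c("long", "wide")) {
  format <- match.arg(format)
  con <- file(path, "w")
  on.exit(close(con))
  m <- record$meta
  writeLines(c(
    sprintf("# freq_hz=%.10g", m$frequency %||% NA),
    sprintf("# b0_mT=%.10g", (m$b0_T %||% NA) * 1e3),
    sprintf("# t_off_s=%.10g", record$field_off_time),
    sprintf("# cp_J_per_gK=%.10g", m$cp_J_per_gK %||% 4.2)), con)
  if (format == "long") {
    df <- do.call(rbind, lapply(colnames(record$temps), function(p)
      data.frame(time_s = record$times, probe = p,
                 temp_C = record$temps[, p])))
  } else {
    df <- data.frame(time_s = record$times, record$temps)
  }
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
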