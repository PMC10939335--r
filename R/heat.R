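#' Voxelize a scene for the heat solver
#'
#' Regular isotropic voxel grid over the bounding box of the meshed
#' regions.  Each voxel is labelled `scaffold`, `phantom` or `ambient` by a
#' voxel-centre membership test; ambient voxels are not meshed - the
#' surrounding air enters only through the convective (Robin) boundary on
#' exterior faces.  In the in-air exposure mode the scene holds no phantom
#' and the Robin boundary acts directly on the scaffold faces.
#'
#' @param scene a `mags_scene`.
#' @param resolution voxel edge, m; must not exceed a quarter of the
#'   smallest cylinder dimension.
#' @param medium_mode `"agar"`, `"air"` or `"water"`; `"air"` drops the
#'   phantom, `"water"` swaps the phantom material for distilled water.
#' @return an object of class `voxel_scene`: axis vectors, `label` array,
#'   per-role materials, `resolution`, and the source scene.
#' @export
build_voxel_scene <- function(scene, resolution = 2e-3,
                              medium_mode = c("agar", "air", "water")) {
  medium_mode <- match.arg(medium_mode)
  stopifnot(inherits(scene, "mags_scene"))
  regions <- list(scaffold = scene$scaffold)
  mats <- list(scaffold = scene$materials$scaffold)
  if (medium_mode != "air" && !is.null(scene$phantom)) {
    regions$phantom <- scene$phantom
    mats$phantom <- if (medium_mode == "water") default_materials()$water
                    else scene$materials$phantom
  }
  dims <- unlist(lapply(regions, function(r) c(r$diameter, r$height)))
  if (resolution > min(dims) / 4)
    stop("resolution error: voxel edge must be <= min(cylinder dimension)/4")
  lo <- sapply(1:3, function(i) min(sapply(regions, function(r)
    r$center_offset[i] - if (i < 3) r$diameter / 2 else r$height / 2)))
  hi <- sapply(1:3, function(i) max(sapply(regions, function(r)
    r$center_offset[i] + if (i < 3) r$diameter / 2 else r$height / 2)))
  ax <- lapply(1:3, function(i) {
    n <- ceiling((hi[i] - lo[i]) / resolution - 1e-9)
    mid <- (hi[i] + lo[i]) / 2
    mid + (seq_len(n) - (n + 1) / 2) * resolution
  })
  names(ax) <- c("x", "y", "z")
  pts <- as.matrix(expand.grid(x = ax$x, y = ax$y, z = ax$z))
  label <- rep("ambient", nrow(pts))
  if (!is.null(regions$phantom)) label[in_cylinder(regions$phantom, pts)] <- "phantom"
  label[in_cylinder(regions$scaffold, pts)] <- "scaffold"
  label <- array(label, dim = lengths(ax))
  structure(list(axes = ax, label = label, materials = mats,
                 resolution = resolution, scene = scene,
                 medium_mode = medium_mode),
            class = "voxel_scene")
}

# centres of the active (non-ambient) voxels, n x 3, plus their indices
active_voxels <- function(voxels) {
  pts <- as.matrix(expand.grid(x = voxels$axes$x, y = voxels$axes$y,
                               z = voxels$axes$z))
  act <- which(as.vector(voxels$label) != "ambient")
  list(idx = act, pts = pts[act, , drop = FALSE],
       label = as.vector(voxels$label)[act])
}

#' Labelled volume of a region in a voxel scene
#'
#' @param voxels a `voxel_scene`.
#' @param region_label `"scaffold"` or `"phantom"`.
#' @return volume in m^3 (voxel count times voxel volume).
#' @export
voxel_volume <- function(voxels, region_label) {
  sum(voxels$label == region_label) * voxels$resolution^3
}

#' Attach a natural-convection surrogate to an in-water scene
#'
#' The convective term of the heat equation is not resolved as fluid flow;
#' in water it is replaced by an effective-conductivity enhancement
#' `k_eff = k_water * Nu`, with the Nusselt number taken from an enclosure
#' correlation `Nu = max(1, C * Ra^p)` driven by the instantaneous
#' scaffold-water temperature difference.  The Rayleigh number uses the
#' radial water-gap width as characteristic length and handbook water
#' properties.  The enhancement is recomputed during time stepping.
#'
#' Setting `model = list(type = "fixed", factor = 1)` reduces exactly to
#' the conduction-only solution.
#'
#' @param voxels a `voxel_scene` built with `medium_mode = "water"`.
#' @param enhancement_model list; either `type = "fixed"` with `factor`
#'   (>= 1), or `type = "nusselt"` with `coefficient`, `exponent`,
#'   `beta` (1/K), `nu` (m^2/s), `alpha` (m^2/s), optional `gap` (m) and
#'   `update_every` (s).
#' @return the `voxel_scene` with the model attached.
#' @export
apply_water_convection <- function(voxels,
                                   enhancement_model = water_convection_model()) {
  stopifnot(inherits(voxels, "voxel_scene"))
  if (voxels$medium_mode != "water")
    stop("convection surrogate requires medium_mode = 'water'")
  if (is.null(enhancement_model$gap)) {
    ph <- voxels$scene$phantom; sca <- voxels$scene$scaffold
    enhancement_model$gap <- (ph$diameter - sca$diameter) / 2
  }
  voxels$convection <- enhancement_model
  voxels
}

#' @rdname apply_water_convection
#' @param coefficient,exponent correlation constants of `Nu = C * Ra^p`.
#' @param beta,nu,alpha thermal expansion (1/K), kinematic viscosity
#'   (m^2/s) and thermal diffusivity (m^2/s) of water near 30 degC.
#' @param update_every seconds between enhancement updates.
#' @export
water_convection_model <- function(coefficient = 0.18, exponent = 0.25,
                                   beta = 3.0e-4, nu = 8.0e-7,
                                   alpha = 1.43e-7, update_every = 2) {
  list(type = "nusselt", coefficient = coefficient, exponent = exponent,
       beta = beta, nu = nu, alpha = alpha, gap = NULL,
       update_every = update_every)
}

# Nusselt enhancement factor from the current scaffold-water temperature gap
nusselt_factor <- function(model, dT) {
  if (identical(model$type, "fixed")) return(max(1, model$factor))
  dT <- max(dT, 0)
  Ra <- 9.81 * model$beta * dT * model$gap^3 / (model$nu * model$alpha)
  max(1, model$coefficient * Ra^model$exponent)
}

# assemble sparse conduction + Robin system for the active voxels.
# k_by_voxel: thermal conductivity per active voxel (allows water k_eff).
# Returns list(K = sparse matrix adding conduction+robin, rob = robin
# conductance to ambient per voxel (W/K)).
assemble_system <- function(voxels, av, k_by_voxel, h_a) {
  res <- voxels$resolution
  dims <- dim(voxels$label)
  nact <- length(av$idx)
  gidx <- array(0L, dim = dims)
  gidx[av$idx] <- seq_len(nact)
  area <- res^2
  ii <- integer(0); jj <- integer(0); gg <- numeric(0)
  rob <- numeric(nact)
  sub <- arrayInd(av$idx, dims)
  for (d in 1:3) {
    for (s in c(-1L, 1L)) {
      nb <- sub
      nb[, d] <- nb[, d] + s
      inbox <- nb[, d] >= 1L & nb[, d] <= dims[d]
      nb_lin <- rep(NA_integer_, nact)
      nb_lin[inbox] <- (nb[inbox, 1] + (nb[inbox, 2] - 1L) * dims[1] +
                          (nb[inbox, 3] - 1L) * dims[1] * dims[2])
      nb_g <- rep(0L, nact)
      nb_g[inbox] <- gidx[nb_lin[inbox]]
      ext <- nb_g == 0L                       # ambient or outside the box
      # interior faces (count each once, from the s = +1 pass)
      if (s == 1L) {
        f <- which(!ext)
        if (length(f)) {
          k1 <- k_by_voxel[f]; k2 <- k_by_voxel[nb_g[f]]
          g <- (2 * k1 * k2 / (k1 + k2)) * area / res
          ii <- c(ii, f); jj <- c(jj, nb_g[f]); gg <- c(gg, g)
        }
      }
      # exterior faces: Robin with half-cell conduction in series
      e <- which(ext)
      if (length(e) && h_a > 0) {
        U <- area / (1 / h_a + (res / 2) / k_by_voxel[e])
        rob[e] <- rob[e] + U
      }
    }
  }
  K <- Matrix::sparseMatrix(i = c(ii, jj), j = c(jj, ii), x = c(-gg, -gg),
                            dims = c(nact, nact))
  deg <- -Matrix::rowSums(K)
  K <- K + Matrix::Diagonal(nact, deg + rob)
  list(K = K, rob = rob)
}

#' Solve the transient heat equation on a voxel scene
#'
#' Finite-volume conduction with harmonic-mean interface conductivities,
#' backward-Euler (implicit) time stepping at fixed step `dt`, volumetric
#' sources active while the field is on (`t < field_off_time`) and zero
#' after, a Robin condition `-k dT/dn = h_a (T - T_a)` on exterior faces,
#' and a uniform initial condition at ambient temperature.  An explicit
#' forward-Euler mode with an automatic CFL-limited step is provided for
#' cross-checking the integrator.
#'
#' Dense per-step diagnostics (volume and surface averages per region,
#' probe temperatures) are tracked during stepping; full temperature
#' fields are stored at `store_every` intervals.
#'
#' @param voxels a `voxel_scene` (optionally with a convection surrogate
#'   from [apply_water_convection()]).
#' @param power a `power_map` from [power_map()], co-registered with the
#'   voxel grid (or `NULL` for zero sources).
#' @param exposure an [exposure_config()].
#' @param dt time step, s.
#' @param store_every interval between stored full fields, s.
#' @param probe_points optional n x 3 matrix of probe positions tracked
#'   densely by trilinear interpolation.
#' @param method `"implicit"` (default) or `"explicit"`.
#' @return an object of class `temperature_history`: `times` (dense),
#'   per-region volume/surface average series, `probes` matrix,
#'   `snapshots` (list of times + 3d arrays with `NA` outside the mesh),
#'   `field_off_time`, and the voxel scene.
#' @export
solve_transient <- function(voxels, power, exposure,
                            dt = 0.1, store_every = 5,
                            probe_points = NULL,
                            method = c("implicit", "explicit")) {
  method <- match.arg(method)
  stopifnot(inherits(voxels, "voxel_scene"), inherits(exposure, "exposure_config"))
  av <- active_voxels(voxels)
  nact <- length(av$idx)
  res <- voxels$resolution
  Vvox <- res^3
  Ta <- exposure$ambient_temperature
  h_a <- exposure$convective_coeff_air
  t_off <- exposure$field_off_time

  mat_of <- function(lbl) voxels$materials[[lbl]]
  k_vox <- vapply(av$label, function(l) mat_of(l)$thermal_conductivity, numeric(1))
  rhoCp <- vapply(av$label, function(l) mat_of(l)$density * mat_of(l)$specific_heat,
                  numeric(1))
  Mcap <- rhoCp * Vvox                       # heat capacity per voxel, J/K

  q_on <- if (is.null(power)) numeric(nact) else {
    pv <- as.vector(power$volumetric)[av$idx]
    if (length(as.vector(power$volumetric)) != prod(dim(voxels$label)))
      stop("power map not co-registered with the voxel grid")
    pv * Vvox
  }

  conv <- voxels$convection
  water_sel <- av$label == "phantom" & voxels$medium_mode == "water"
  if (!is.null(conv) && identical(conv$type, "fixed")) {
    # static enhancement: fold into the conductivities once
    k_vox[water_sel] <- k_vox[water_sel] * max(1, conv$factor)
    conv <- NULL
  }
  build <- function(kv) assemble_system(voxels, av, kv, h_a)
  sys <- build(k_vox)

  # region bookkeeping for tracked averages
  regions <- unique(av$label)
  reg_idx <- lapply(regions, function(r) which(av$label == r))
  names(reg_idx) <- regions
  surf_w <- lapply(regions, function(r)
    region_surface_weights(voxels, av, r, k_vox, h_a, Ta))
  names(surf_w) <- regions

  probe_W <- NULL
  if (!is.null(probe_points)) {
    probe_points <- rbind(probe_points)
    probe_W <- probe_weights(voxels, av, probe_points)
  }

  nt <- ceiling(exposure$duration / dt)
  times <- seq_len(nt + 1L) * dt - dt
  Tn <- rep(Ta, nact)
  vol_avg <- sapply(regions, function(r) numeric(nt + 1L), simplify = FALSE)
  surf_avg <- sapply(regions, function(r) numeric(nt + 1L), simplify = FALSE)
  probes <- if (is.null(probe_W)) NULL else matrix(NA_real_, nt + 1L, nrow(probe_points))
  snap_t <- numeric(0); snaps <- list()

  record <- function(i, Tvec) {
    for (r in regions) {
      vol_avg[[r]][i] <<- mean(Tvec[reg_idx[[r]]])
      surf_avg[[r]][i] <<- sum(surf_w[[r]]$w * Tvec) + surf_w[[r]]$const
    }
    if (!is.null(probe_W)) probes[i, ] <<- as.numeric(probe_W %*% Tvec)
  }
  store <- function(tnow, Tvec) {
    arr <- array(NA_real_, dim = dim(voxels$label))
    arr[av$idx] <- Tvec
    snap_t <<- c(snap_t, tnow)
    snaps[[length(snaps) + 1L]] <<- arr
  }
  record(1L, Tn); store(0, Tn)
  next_store <- store_every

  if (method == "implicit") {
    lhs_chol <- Matrix::Cholesky(sys$K + Matrix::Diagonal(nact, Mcap / dt),
                                 LDL = FALSE)
    next_conv_update <- if (!is.null(conv)) conv$update_every else Inf
    for (i in seq_len(nt)) {
      tnew <- times[i + 1L]
      q <- if (times[i] < t_off) q_on else numeric(nact)
      rhs <- Mcap / dt * Tn + q + sys$rob * Ta
      Tn <- as.numeric(Matrix::solve(lhs_chol, rhs, system = "A"))
      if (any(!is.finite(Tn)))
        stop("solver error: non-finite temperatures at step ", i,
             " (t = ", tnew, " s)")
      record(i + 1L, Tn)
      if (tnew + 1e-9 >= next_store) { store(tnew, Tn); next_store <- next_store + store_every }
      if (!is.null(conv) && tnew + 1e-9 >= next_conv_update) {
        dT <- mean(Tn[reg_idx[["scaffold"]]]) -
          mean(Tn[reg_idx[["phantom"]]])
        f <- nusselt_factor(conv, dT)
        kv <- k_vox
        kv[water_sel] <- kv[water_sel] * f
        sys <- build(kv)
        lhs_chol <- Matrix::Cholesky(sys$K + Matrix::Diagonal(nact, Mcap / dt),
                                     LDL = FALSE)
        next_conv_update <- next_conv_update + conv$update_every
      }
    }
  } else {
    # explicit cross-check: dt limited by the stability bound of the
    # discrete operator (Gershgorin)
    dmax <- max(Matrix::diag(sys$K) / Mcap)
    dt_cfl <- 0.9 * 2 / (2 * dmax)           # forward Euler limit 2/lambda_max
    nsub <- max(1L, ceiling(dt / dt_cfl))
    dts <- dt / nsub
    for (i in seq_len(nt)) {
      q <- if (times[i] < t_off) q_on else numeric(nact)
      for (s in seq_len(nsub)) {
        Tn <- Tn + dts / Mcap *
          (q + sys$rob * Ta - as.numeric(sys$K %*% Tn))
      }
      if (any(!is.finite(Tn)))
        stop("solver error: non-finite temperatures at step ", i)
      record(i + 1L, Tn)
      if (times[i + 1L] + 1e-9 >= next_store) {
        store(times[i + 1L], Tn); next_store <- next_store + store_every
      }
    }
  }

  structure(list(times = times, volume_avg = vol_avg, surface_avg = surf_avg,
                 probes = probes, probe_points = probe_points,
                 snapshot_times = snap_t, snapshots = snaps,
                 field_off_time = t_off, voxels = voxels,
                 exposure = exposure),
            class = "temperature_history")
}

# Linear functional giving the mean boundary-face temperature of a region:
# surf_avg(T) = w . T + const.  Face temperatures are recovered from the
# discrete flux balance: at an interface with another meshed region the
# conductance-weighted mean of the adjacent cell temperatures, at an
# exterior face the Robin balance between half-cell conduction and
# convection to ambient (for h_a = 0 the face takes the cell temperature).
# This is the virtual IR-camera observable: the true surface, not a
# voxel-shell average.
region_surface_weights <- function(voxels, av, region_label, k_vox, h_a, Ta) {
  dims <- dim(voxels$label)
  res <- voxels$resolution
  nact <- length(av$idx)
  gidx <- array(0L, dim = dims)
  gidx[av$idx] <- seq_len(nact)
  sel <- which(av$label == region_label)
  sub <- arrayInd(av$idx[sel], dims)
  w <- numeric(nact); const <- 0; nfaces <- 0L
  g_half <- 2 * k_vox / res                  # half-cell conductance per area
  for (d in 1:3) for (s in c(-1L, 1L)) {
    nb <- sub
    nb[, d] <- nb[, d] + s
    inbox <- nb[, d] >= 1L & nb[, d] <= dims[d]
    nb_g <- rep(0L, length(sel))
    nb_lin <- (pmin(pmax(nb[, 1], 1L), dims[1]) +
                 (pmin(pmax(nb[, 2], 1L), dims[2]) - 1L) * dims[1] +
                 (pmin(pmax(nb[, 3], 1L), dims[3]) - 1L) * dims[1] * dims[2])
    nb_g[inbox] <- gidx[nb_lin[inbox]]
    same <- nb_g > 0L & av$label[pmax(nb_g, 1L)] == region_label & inbox
    for (f in which(!same)) {
      i <- sel[f]; gi <- g_half[i]
      if (nb_g[f] > 0L) {                    # interface with another region
        j <- nb_g[f]; gj <- g_half[j]
        w[i] <- w[i] + gi / (gi + gj)
        w[j] <- w[j] + gj / (gi + gj)
      } else {                               # exterior face: Robin balance
        w[i] <- w[i] + gi / (gi + h_a)
        const <- const + h_a * Ta / (gi + h_a)
      }
      nfaces <- nfaces + 1L
    }
  }
  if (nfaces == 0L) stop("region error: region has no boundary faces")
  list(w = w / nfaces, const = const / nfaces)
}

#' Exterior surface area of a region as meshed
#'
#' Total area of voxel faces separating the region from everything else
#' (the staircase surface the Robin condition acts on).
#'
#' @param voxels a `voxel_scene`.
#' @param region_label region name.
#' @return area, m^2.
#' @export
voxel_surface_area <- function(voxels, region_label) {
  dims <- dim(voxels$label)
  lab <- voxels$label
  idx <- which(lab == region_label)
  sub <- arrayInd(idx, dims)
  nfaces <- 0L
  for (d in 1:3) for (s in c(-1L, 1L)) {
    nb <- sub
    nb[, d] <- nb[, d] + s
    out <- nb[, d] < 1L | nb[, d] > dims[d]
    nb[, d] <- pmin(pmax(nb[, d], 1L), dims[d])
    nb_lab <- lab[cbind(nb[, 1], nb[, 2], nb[, 3])]
    nfaces <- nfaces + sum(out | nb_lab != region_label)
  }
  nfaces * voxels$resolution^2
}

# sparse trilinear-interpolation weights of probe points onto active voxels
probe_weights <- function(voxels, av, pts) {
  ax <- voxels$axes
  dims <- dim(voxels$label)
  gidx <- array(0L, dim = dims)
  gidx[av$idx] <- seq_len(length(av$idx))
  n <- nrow(pts)
  W <- Matrix::Matrix(0, n, length(av$idx), sparse = TRUE)
  loc <- function(g, v) {
    i <- findInterval(v, g, all.inside = TRUE)
    list(i = i, w = pmin(pmax((v - g[i]) / (g[i + 1] - g[i]), 0), 1))
  }
  lx <- loc(ax$x, pts[, 1]); ly <- loc(ax$y, pts[, 2]); lz <- loc(ax$z, pts[, 3])
  for (p in seq_len(n)) {
    ids <- integer(0); wts <- numeric(0)
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      g <- gidx[lx$i[p] + dx, ly$i[p] + dy, lz$i[p] + dz]
      w <- (if (dx) lx$w[p] else 1 - lx$w[p]) *
        (if (dy) ly$w[p] else 1 - ly$w[p]) *
        (if (dz) lz$w[p] else 1 - lz$w[p])
      if (g > 0L && w > 0) { ids <- c(ids, g); wts <- c(wts, w) }
    }
    if (!length(ids))
      stop("layout error: probe point outside the meshed domain")
    W[p, ids] <- wts / sum(wts)
  }
  W
}

#' Volume-average temperature series of a region
#'
#' Arithmetic mean over the region's voxels at every solver step.
#'
#' @param history a `temperature_history`.
#' @param region region label (`"scaffold"` or `"phantom"`).
#' @return data.frame with columns `time` (s) and `temp` (degC).
#' @export
volume_average <- function(history, region = "scaffold") {
  if (is.null(history$volume_avg[[region]]))
    stop("region error: no '", region, "' region in this history")
  data.frame(time = history$times, temp = history$volume_avg[[region]])
}

#' Surface-average temperature series of a region
#'
#' Mean over the region's boundary voxels - the virtual infrared-camera
#' observable for the in-air setup.
#'
#' @inheritParams volume_average
#' @return data.frame with columns `time` and `temp`.
#' @export
surface_average <- function(history, region = "scaffold") {
  if (is.null(history$surface_avg[[region]]))
    stop("region error: no '", region, "' region in this history")
  data.frame(time = history$times, temp = history$surface_avg[[region]])
}

#' Export a temperature history as tidy CSV
#'
#' One row per stored voxel and snapshot time: `time_s, x_mm, y_mm, z_mm,
#' temp_C`.
#'
#' @param history a `temperature_history`.
#' @param path output file.
#' @export
write_temperature_history <- function(history, path) {
  ax <- history$voxels$axes
  pts <- expand.grid(x = ax$x, y = ax$y, z = ax$z)
  out <- do.call(rbind, lapply(seq_along(history$snapshot_times), function(i) {
    v <- as.vector(history$snapshots[[i]])
    keep <- !is.na(v)
    data.frame(time_s = history$snapshot_times[i],
               x_mm = pts$x[keep] * 1e3, y_mm = pts$y[keep] * 1e3,
               z_mm = pts$z[keep] * 1e3, temp_C = v[keep])
  }))
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
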