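#' Locate the melting section of a screw profile
#'
#' The 1D global model assumes melting is instantaneous and pinned at the
#' first restrictive element (left-handed element or kneading block)
#' downstream of the feed: the melt state begins at the point, just upstream
#' of it, where pressure starts to rise, with temperature equal to the
#' melting temperature of the feed.
#'
#' @param extruder an [extruder()] object.
#' @return Integer index (into `extruder$elements`) of the first restrictive
#'   element downstream of the feed.
#' @export
locate_melting_section <- function(extruder) {
  stopifnot(inherits(extruder, "extruder"))
  starts <- cumsum(c(0, vapply(extruder$elements, `[[`, 0, "length")))
  restr <- which(vapply(extruder$elements, is_restrictive, TRUE) &
                   starts[-length(starts)] >= extruder$feed_position)
  if (!length(restr))
    stopf(paste("no restrictive element downstream of the feed: the melting",
                "section cannot be located. Add a reverse_lh element or a",
                "kneading_block to the screw profile."))
  restr[1L]
}

#' Solver control parameters
#'
#' @param tol_T convergence tolerance on the melting-point temperature
#'   match (°C, default 0.1).
#' @param max_shoot_iter cap on die-exit temperature iterations per shooting
#'   solve (default 60).
#' @param sme_tol relative tolerance of the SME-profile fixed point
#'   (default 1e-3).
#' @param sme_damping damping factor of the SME Picard update in (0, 1]
#'   (default 0.6).
#' @param max_sme_iter cap on SME fixed-point iterations (default 80).
#' @param substeps sub-steps per screw element of the explicit march
#'   (default 4; tames stiffness at reverse elements).
#' @param n_min flow-index clamp floor (default 0.05).
#' @param exchange_area_factor multiplier on the barrel-facing exchange
#'   surface (per-unit-length baseline: one bore perimeter `pi*D` scaled by
#'   the filled fraction). Part of the heat-exchange closure; the default
#'   0.85 reflects that part of the bore faces the intermeshing region
#'   rather than the barrel wall.
#' @param include_melt_enthalpy add the melting enthalpy (per unit mass) to
#'   the reported `SME_com` (default FALSE; it is always reported separately
#'   as `melt_enthalpy_kJkg`).
#' @return A list of class `"extrusion_control"`.
#' @export
extrusion_control <- function(tol_T = 0.1, max_shoot_iter = 60,
                              sme_tol = 1e-3, sme_damping = 0.6,
                              max_sme_iter = 80, substeps = 4,
                              n_min = 0.05, exchange_area_factor = 0.85,
                              include_melt_enthalpy = FALSE) {
  structure(list(tol_T = tol_T, max_shoot_iter = max_shoot_iter,
                 sme_tol = sme_tol, sme_damping = sme_damping,
                 max_sme_iter = max_sme_iter, substeps = as.integer(substeps),
                 n_min = n_min, exchange_area_factor = exchange_area_factor,
                 include_melt_enthalpy = include_melt_enthalpy),
            class = "extrusion_control")
}

# substep grid: one row per substep, hopper -> die order; long elements get
# extra substeps so the explicit march never takes steps coarser than ~12 mm
build_march_grid <- function(extruder, op, substeps, max_step = 12e-3) {
  els <- extruder$elements
  D <- extruder$screw_diameter
  nE <- length(els)
  ztemps <- op$barrel_temps %||% extruder$barrel_zones$temp
  if (length(ztemps) == 1L) ztemps <- rep(ztemps, nrow(extruder$barrel_zones))
  if (length(ztemps) != nrow(extruder$barrel_zones))
    stopf("barrel_temps must have one value per barrel zone (%d), got %d",
          nrow(extruder$barrel_zones), length(ztemps))
  zends <- cumsum(extruder$barrel_zones$length)
  L_tot <- extruder$total_length

  rows <- vector("list", nE)
  start <- 0
  for (i in seq_len(nE)) {
    el <- els[[i]]
    sf <- shape_factors(el, D)
    m <- max(substeps, ceiling(el$length / max_step))
    len <- el$length / m
    centers <- start + (seq_len(m) - 0.5) * len
    zi <- findInterval(centers, zends, left.open = TRUE) + 1L
    zi[zi > length(ztemps)] <- length(ztemps)
    rows[[i]] <- data.frame(
      elem = i, kind = el$kind, restrictive = is_restrictive(el),
      sub = seq_len(m), len = len,
      pos_down_hopper = start + seq_len(m) * len,
      A = sf$A, G_sub = sf$G * m,
      V_ch = sf$V_channel / m, V_gap = sf$V_gap / m,
      S = sf$S_barrel / m, h = sf$channel_depth, gap = sf$gap,
      eff = el$shear_efficiency, htf = el$ht_factor, Tb = ztemps[zi])
    start <- start + el$length
  }
  g <- do.call(rbind, rows)
  g$pos_die <- L_tot - g$pos_down_hopper  # position of downstream boundary
  g
}

die_geometry <- function(die) {
  vol <- 0; area <- 0; hchar <- Inf
  for (el in die) {
    if (el$kind == "circular") {
      vol <- vol + pi * el$radius^2 * el$length
      area <- area + 2 * pi * el$radius * el$length
      hchar <- min(hchar, 2 * el$radius)
    } else {
      vol <- vol + el$width * el$height * el$length
      area <- area + 2 * el$width * el$length
      hchar <- min(hchar, el$height)
    }
  }
  list(volume = vol, area = area, hchar = hchar)
}

#' Simulate an extrusion run (backward shooting solver)
#'
#' Solves the coupled pressure/temperature/SME profiles of the 1D global
#' twin-screw extrusion model. The computation starts from the die exit and
#' proceeds backwards, element by element, to the melting point; the unknown
#' die-exit temperature is found by shooting so that the temperature at the
#' melting point equals the melting temperature of the feed at its moisture
#' content. Because the viscosity model needs the cumulative SME (itself an
#' output of the march), the SME profile is resolved to a fixed point by a
#' damped Picard iteration around the shooting loop.
#'
#' Fill state follows the starved-flow closure of the elementary flow law:
#' elements are fully filled where the backward pressure integration yields
#' P > 0, and partially filled with `fill = Qv/(A*Omega)` (at P = 0)
#' elsewhere. Cumulative SME is accumulated from the melting point towards
#' the die as the sum of per-element dissipated powers over the mass flow,
#' plus the pressure work through the die.
#'
#' @param extruder an [extruder()].
#' @param material an [material()] or the name of a shipped material
#'   ([material_db()]).
#' @param op an [operating_point()].
#' @param control an [extrusion_control()].
#' @return An object of class `"extrusion_sim"`; see [summary.extrusion_sim()].
#'   Main components: `states` (per-substep axial profile, die -> melting
#'   point), `T_com`, `SME_com`, `P_com`, `eta_com`, `T_max`,
#'   `mean_residence_time`, `melting_position` (m from die), `converged`,
#'   `iterations`.
#' @examples
#' \donttest{
#' sim <- solve_profile(extruder_fixture("zsk26_like"), material_db("cb"),
#'                      operating_point(N = 500, Q = 20, MC = 0.15,
#'                                      barrel_temps = c(20, 40, 60, 90, 90, 90, 90)))
#' summary(sim)
#' }
#' @export
solve_profile <- function(extruder, material, op,
                          control = extrusion_control()) {
  stopifnot(inherits(extruder, "extruder"), inherits(op, "operating_point"))
  if (is.character(material)) material <- material_db(material)
  stopifnot(inherits(material, "extrusion_material"))
  if (!inherits(control, "extrusion_control"))
    control <- do.call(extrusion_control, control)

  params <- material$viscosity
  MC <- op$MC
  Tm <- melting_temperature(material, MC)
  rho <- melt_property(material, MC, "rho")
  cp <- melt_property(material, MC, "cp")
  kth <- melt_property(material, MC, "k")
  mdot <- op$Q / 3600                       # kg/s
  Qv <- mdot / rho                          # m^3/s
  omega <- 2 * pi * op$N / 60               # rad/s
  D <- extruder$screw_diameter
  vtip <- pi * D * op$N / 60

  im <- locate_melting_section(extruder)
  grid <- build_march_grid(extruder, op, control$substeps)
  K <- nrow(grid)
  Td <- op$die_temp %||% grid$Tb[K]
  dg <- die_geometry(extruder$die)
  # heat exchange: Nusselt closure on the channel depth (die: channel bore)
  ht_k <- op$nusselt * kth * grid$htf / grid$h
  ht_die <- op$nusselt * kth / max(dg$hchar, 1e-6)

  n_min <- control$n_min
  af <- control$exchange_area_factor
  visc <- function(gdot, T_C, sme)
    apparent_viscosity_fast(params, gdot, T_C, MC, sme, n_min = n_min)

  gd_ch <- grid$eff * vtip / grid$h
  gd_gap <- vtip / grid$gap
  AW <- grid$A * omega
  rQc <- rho * Qv * cp

  march <- function(T_die, sme_prof, sme_com) {
    # --- die ---
    dp_die <- die_pressure_drop(extruder$die, Qv, params, T_die, MC, sme_com)
    W_die <- dp_die * Qv
    dT_die <- (W_die - ht_die * dg$area * (T_die - Td)) / rQc
    dT_die <- (W_die - ht_die * dg$area * ((T_die - dT_die / 2) - Td)) / rQc
    Tc <- max(T_die - dT_die, -150)
    P <- dp_die
    Tarr <- numeric(K); Parr <- numeric(K); farr <- numeric(K)
    Warr <- numeric(K); earr <- numeric(K)
    melt_k <- NA_integer_; melt_frac <- 0; over_fed <- FALSE
    k <- K
    while (k >= 1) {
      in_melt_zone <- grid$elem[k] < im
      if (in_melt_zone && P <= 1e-9) { melt_k <- k + 1L; melt_frac <- 0; break }
      sme_k <- sme_prof[k]
      Tarr[k] <- Tc; Parr[k] <- P
      step <- function(T_eval) {
        # guard against runaway shooting guesses (keep T above the kelvin
        # pole and eta finite); the bracket search discards these states
        T_eval <- max(T_eval, -150)
        eta <- min(visc(gd_ch[k], T_eval, sme_k), 1e12)
        if (AW[k] <= Qv || P > 1e-9) {
          fill <- 1
          dP <- (Qv - AW[k]) * eta / grid$G_sub[k]
        } else {
          fill <- Qv / AW[k]
          dP <- 0
        }
        eta_g <- min(visc(gd_gap[k], T_eval, sme_k), 1e12)
        # drag (channel + flight gap) plus pressure-flow dissipation
        Wd <- fill * (eta * gd_ch[k]^2 * grid$V_ch[k] +
                        eta_g * gd_gap[k]^2 * grid$V_gap[k]) +
          dP * (Qv - AW[k])
        dT <- (Wd - ht_k[k] * fill * grid$S[k] * af *
                 (T_eval - grid$Tb[k])) / rQc
        list(eta = eta, fill = fill, dP = dP, Wd = Wd, dT = dT)
      }
      s1 <- step(Tc)
      s <- step(Tc - s1$dT / 2)       # midpoint corrector
      farr[k] <- s$fill; Warr[k] <- s$Wd; earr[k] <- s$eta
      P_up <- P + s$dP
      if (P_up < 0) {
        if (in_melt_zone) {
          melt_frac <- P / (P - P_up)   # fraction of substep that is molten
          Tarr[k] <- Tc; melt_k <- k
          Tc <- Tc - melt_frac * s$dT
          P <- 0
          break
        }
        P_up <- 0
      }
      Tc <- max(Tc - s$dT, -150)
      P <- P_up
      if (k == 1L && P > 1e-9) { over_fed <- TRUE; melt_k <- 1L }
      k <- k - 1L
    }
    if (is.na(melt_k)) melt_k <- k + 1L   # P hit zero at a boundary
    list(T_melt = Tc, melt_k = melt_k, melt_frac = melt_frac,
         T = Tarr, P = Parr, fill = farr, W = Warr, eta = earr,
         dp_die = dp_die, dT_die = dT_die, over_fed = over_fed)
  }

  sme_from_march <- function(m) {
    prof <- numeric(K)
    k0 <- m$melt_k
    if (k0 <= K) {
      w <- m$W[k0:K]
      w[1] <- w[1] * if (m$melt_frac > 0) m$melt_frac else 1
      prof[k0:K] <- cumsum(w) / mdot / 1000
    }
    com <- (if (k0 <= K) prof[K] else 0) + m$dp_die / rho / 1000
    list(prof = prof, com = com)
  }

  shoot <- function(sme_prof, sme_com) {
    iters <- 0L
    f <- function(T_die) {
      iters <<- iters + 1L
      march(T_die, sme_prof, sme_com)$T_melt - Tm
    }
    lo <- Tm - 40; hi <- Tm + 120
    flo <- f(lo); fhi <- f(hi)
    while (fhi < 0 && hi < Tm + 500) { hi <- hi + 80; fhi <- f(hi) }
    while (flo > 0 && lo > max(Tm - 150, 25)) { lo <- lo - 40; flo <- f(lo) }
    if (flo > 0 && fhi > 0) {
      # cooling-dominated: die exit colder than melting point
      if (flo < fhi) return(list(T_die = lo, iters = iters, ok = abs(flo) < control$tol_T))
    }
    if (flo * fhi > 0)
      stopf(paste("shooting failed to bracket the die-exit temperature",
                  "(f(%.1f) = %.2f, f(%.1f) = %.2f); the operating point may",
                  "be infeasible for this machine"), lo, flo, hi, fhi)
    r <- stats::uniroot(f, c(lo, hi), f.lower = flo, f.upper = fhi,
                        tol = 1e-6, maxiter = control$max_shoot_iter)
    list(T_die = r$root, iters = iters, ok = TRUE)
  }

  sme_prof <- numeric(K); sme_com <- 0
  converged <- FALSE; shoot_iters <- NA_integer_; T_die <- NA_real_
  outer <- 0L
  for (outer in seq_len(control$max_sme_iter)) {
    sol <- shoot(sme_prof, sme_com)
    T_die <- sol$T_die
    shoot_iters <- sol$iters
    m <- march(T_die, sme_prof, sme_com)
    new <- sme_from_march(m)
    denom <- max(new$com, 1e-6)
    delta <- max(abs(c(new$prof - sme_prof, new$com - sme_com))) / denom
    # damp in log space: robust when the beta feedback (viscosity falling
    # exponentially in SME) makes the first iterates swing by decades; the
    # damping shrinks with beta*SME, the loop gain of that feedback
    d <- min(control$sme_damping,
             1 / (1 + params$beta * min(max(new$com, sme_com), 1e4)))
    logd <- function(old, new) exp(d * log(new + 1) + (1 - d) * log(old + 1)) - 1
    sme_prof <- logd(sme_prof, new$prof)
    sme_com <- logd(sme_com, new$com)
    if (delta < control$sme_tol) { converged <- TRUE; break }
  }
  # final consistent march at the converged history
  sol <- shoot(sme_prof, sme_com)
  T_die <- sol$T_die
  m <- march(T_die, sme_prof, sme_com)
  fin <- sme_from_march(m)
  converged <- converged && sol$ok && abs(m$T_melt - Tm) <= control$tol_T

  k0 <- min(m$melt_k, K)
  idx <- K:k0                      # die -> melting point
  rt <- m$fill * (grid$V_ch + grid$V_gap) / Qv
  states <- data.frame(
    position_m = grid$pos_die[idx],
    element_id = grid$elem[idx], kind = grid$kind[idx],
    T_C = m$T[idx], P_Pa = m$P[idx],
    SME_kJkg = sme_prof[idx], eta_Pas = m$eta[idx],
    fill_ratio = m$fill[idx], residence_s = rt[idx])
  melt_pos <- grid$pos_die[k0] + (if (m$melt_frac > 0) m$melt_frac else 1) *
    grid$len[k0]
  SME_com <- fin$com
  dHm <- material$melting_enthalpy / 1000
  if (control$include_melt_enthalpy) SME_com <- SME_com + dHm

  # die-exit viscosity at the wall shear rate of the last die group
  dpd <- die_pressure_drop(extruder$die, Qv, params, T_die, MC, SME_com,
                           details = TRUE)
  eltab <- attr(dpd, "elements")
  gw <- eltab$wall_shear[nrow(eltab)]
  eta_com <- apparent_viscosity_fast(params, gw, T_die, MC, SME_com,
                                     n_min = n_min)
  mrt <- sum(rt[idx]) + dg$volume / Qv

  structure(list(
    states = states, T_com = T_die, SME_com = SME_com, P_com = m$dp_die,
    eta_com = eta_com, die_wall_shear = gw,
    T_max = max(c(m$T[idx], T_die)),
    mean_residence_time = mrt, melting_position = melt_pos,
    melt_temp = Tm, melt_temp_residual = m$T_melt - Tm,
    melt_enthalpy_kJkg = dHm, include_melt_enthalpy = control$include_melt_enthalpy,
    converged = converged, iterations = sol$iters,
    sme_iterations = outer, over_fed = m$over_fed,
    material = material$name, machine = extruder$name,
    op = op, Qv = Qv, control = control),
    class = "extrusion_sim")
}
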