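#' Resonating micromembrane specification
#'
#' Describes a circular tensioned-membrane resonator used to weigh deposited
#' liquid droplets. Each vibration mode `(m, n)` is characterised by its dry
#' resonance frequency and a droplet-coverage rate `gamma`. The geometric
#' mode factor `alpha_mn` is back-calibrated from the dry frequency via
#' \deqn{f_{mn} = \frac{\alpha_{mn}}{2\pi R}\sqrt{Y\varepsilon/\rho}}
#' evaluated at the film density, rather than taken from tabulated Bessel
#' zeros (the nominal device geometry over-constrains the analytical
#' factors). Default numbers correspond to a 500 um silicon-film device:
#' Young's modulus 130 GPa, pre-calibrated tensile strain 4e-6, film density
#' 2650 kg/m^3, intrinsic film volume 0.59 pL, and a calibration mode (3,4)
#' at 82 kHz dry.
#'
#' The coverage rate enters the mass loading of a droplet of volume `V1`:
#' mode `(m, n)` feels an added mass `beta * rho1 * V1` with
#' `beta = 1 / (1 + gamma * V1 / V_f)` - the larger the droplet, the smaller
#' the fraction of it sitting on the high-displacement region of a
#' fine-structured mode. Modes with distinct `gamma` therefore respond
#' differently to the same droplet, which is what makes the density and the
#' volume jointly identifiable from two or more mode shifts.
#'
#' @param radius_m membrane radius in m.
#' @param young_modulus_pa film Young's modulus in Pa.
#' @param strain pre-calibrated tensile strain (dimensionless).
#' @param film_density film density in kg/m^3.
#' @param film_volume_pl intrinsic film volume in pL.
#' @param modes tibble with columns `m`, `n`, `f_dry_hz`, `gamma`.
#' @return An object of class `membrane_spec`.
#' @examples
#' membrane_spec()
#' @export
membrane_spec <- function(radius_m = 250e-6,
                          young_modulus_pa = 130e9,
                          strain = 4e-6,
                          film_density = 2650,
                          film_volume_pl = 0.59,
                          modes = tibble(
                            m = c(0, 3), n = c(1, 4),
                            f_dry_hz = c(18e3, 82e3),
                            gamma = c(0, 1)
                          )) {
  stopifnot(
    radius_m > 0, young_modulus_pa > 0, strain > 0,
    film_density > 0, film_volume_pl > 0
  )
  modes <- as_tibble(modes)
  req <- c("m", "n", "f_dry_hz", "gamma")
  if (!all(req %in% names(modes))) {
    abort("`modes` needs columns m, n, f_dry_hz, gamma")
  }
  if (any(modes$f_dry_hz <= 0) || any(modes$gamma < 0)) {
    abort("mode table: f_dry_hz must be positive and gamma non-negative")
  }
  wave_speed <- sqrt(young_modulus_pa * strain / film_density)
  modes$alpha <- modes$f_dry_hz * 2 * pi * radius_m / wave_speed
  structure(
    list(
      radius_m = radius_m,
      young_modulus_pa = young_modulus_pa,
      strain = strain,
      film_density = film_density,
      film_volume_m3 = film_volume_pl * 1e-15,
      modes = modes
    ),
    class = "membrane_spec"
  )
}

#' @export
print.membrane_spec <- function(x, ...) {
  cat(sprintf(
    "Membrane resonator: R = %g um, rho_f = %g kg/m^3, V_f = %g pL\n",
    x$radius_m * 1e6, x$film_density, x$film_volume_m3 * 1e15
  ))
  print(x$modes)
  invisible(x)
}

#' Droplet load on a membrane
#'
#' @param density average liquid density rho_1 in kg/m^3 (> 0).
#' @param volume_pl droplet volume V_1 in pL (>= 0).
#' @return An object of class `droplet_load`.
#' @examples
#' droplet_load(1004.2, 0.3)
#' @export
droplet_load <- function(density, volume_pl) {
  stopifnot(density > 0, volume_pl >= 0)
  structure(
    list(density = density, volume_m3 = volume_pl * 1e-15),
    class = "droplet_load"
  )
}

#' @export
print.droplet_load <- function(x, ...) {
  cat(sprintf(
    "Droplet load: rho_1 = %g kg/m^3, V_1 = %g pL\n",
    x$density, x$volume_m3 * 1e15
  ))
  invisible(x)
}

#' Composite effective mass density of film plus droplet
#'
#' Volume-weighted mixture of the film density and the droplet density:
#' `rho_eff = (rho_f V_f + rho_1 V_1) / (V_f + V_1)`. It equals the film
#' density for an empty membrane and tends to the liquid density as the
#' droplet volume grows; it always lies between the two.
#'
#' @param spec a [membrane_spec()].
#' @param load a [droplet_load()].
#' @return Effective density in kg/m^3.
#' @examples
#' effective_density(membrane_spec(), droplet_load(1000, 0.59)) # 1825
#' @export
effective_density <- function(spec, load) {
  vf <- spec$film_volume_m3
  v1 <- load$volume_m3
  (spec$film_density * vf + load$density * v1) / (vf + v1)
}

mode_row <- function(spec, mode) {
  i <- which(spec$modes$m == mode[1] & spec$modes$n == mode[2])
  if (length(i) != 1) {
    abort(sprintf("unknown mode (%s, %s)", mode[1], mode[2]))
  }
  spec$modes[i, ]
}

#' Resonance frequency of a mode at a given effective density
#'
#' Membrane dispersion relation
#' `f = alpha_mn / (2 pi R) * sqrt(Y * strain / rho_eff)`: the frequency is
#' inversely proportional to the square root of the effective mass density.
#' By calibration, evaluating at the film density returns the mode's dry
#' frequency.
#'
#' @param spec a [membrane_spec()].
#' @param mode length-2 vector `c(m, n)`; must be present in the spec's
#'   mode table.
#' @param rho_eff effective mass density in kg/m^3.
#' @return Frequency in Hz.
#' @examples
#' mode_frequency(membrane_spec(), c(3, 4), 2650) # 82 kHz (dry)
#' @export
mode_frequency <- function(spec, mode, rho_eff) {
  if (any(rho_eff <= 0)) abort("`rho_eff` must be positive")
  row <- mode_row(spec, mode)
  row$alpha / (2 * pi * spec$radius_m) *
    sqrt(spec$young_modulus_pa * spec$strain / rho_eff)
}

# mass-loading density seen by one mode: added droplet mass (discounted by the
# coverage factor) referenced to the film volume
modal_load_density <- function(spec, mode, load) {
  row <- mode_row(spec, mode)
  beta <- 1 / (1 + row$gamma * load$volume_m3 / spec$film_volume_m3)
  spec$film_density + beta * load$density * load$volume_m3 / spec$film_volume_m3
}

#' Loaded frequency and downward shift of a mode under a droplet
#'
#' The added droplet mass lowers the modal frequency through the mass-loading
#' density `rho_f + beta * rho_1 V_1 / V_f` (with the coverage factor `beta`
#' of [membrane_spec()]); `frequency_shift()` returns
#' `delta_f = f_dry - f_wet >= 0`, monotonically increasing in the added
#' mass `rho_1 V_1`. In the small-droplet limit
#' `delta_f / f_dry -> (1/2) rho_1 V_1 / (rho_f V_f)`.
#'
#' @inheritParams mode_frequency
#' @param load a [droplet_load()].
#' @return Frequency (Hz) for `loaded_frequency()`; downward shift (Hz,
#'   >= 0) for `frequency_shift()`.
#' @examples
#' frequency_shift(membrane_spec(), c(3, 4), droplet_load(1000, 0.3))
#' @export
loaded_frequency <- function(spec, mode, load) {
  mode_frequency(spec, mode, modal_load_density(spec, mode, load))
}

#' @rdname loaded_frequency
#' @export
frequency_shift <- function(spec, mode, load) {
  row <- mode_row(spec, mode)
  row$f_dry_hz - loaded_frequency(spec, mode, load)
}

#' Invert mode observations for droplet density and volume
#'
#' Least-squares inversion of the droplet forward model: given dry and
#' loaded frequencies of two or more modes with distinct coverage rates
#' (or one mode plus a known droplet volume), recovers the average liquid
#' density `rho_1` and droplet volume `V_1`. The fit runs a damped
#' Gauss-Newton iteration on `(log rho_1, log V_1)` (positivity enforced by
#' the parameterisation), initialised from the closed-form two-mode
#' solution; relative tolerance 1e-10, at most 100 iterations.
#'
#' With all shifts zero the droplet volume is returned as 0 and the density
#' flagged unidentifiable. A single mode with unknown volume is
#' underdetermined and raises an error (pure mass loading senses only the
#' product `rho_1 V_1`).
#'
#' @param observations tibble with columns `m`, `n`, `f_dry_hz`, `f_wet_hz`
#'   (one row per mode; `0 < f_wet_hz <= f_dry_hz`).
#' @param spec a [membrane_spec()]; every observed mode must appear in its
#'   mode table.
#' @param volume_pl optional known droplet volume in pL (enables single-mode
#'   inversion).
#' @param tol,max_iter Gauss-Newton convergence controls.
#' @return An object of class `droplet_fit`: a list with `density`,
#'   `volume_pl`, `residual_norm` (relative, over modes), `iterations`,
#'   `converged`, `identifiable`.
#' @examples
#' spec <- membrane_spec()
#' obs <- simulate_resonator(droplet_load(1004.2, 0.3), spec)
#' invert_load(obs, spec)
#' @export
invert_load <- function(observations, spec, volume_pl = NULL,
                        tol = 1e-10, max_iter = 100) {
  obs <- as_tibble(observations)
  req <- c("m", "n", "f_dry_hz", "f_wet_hz")
  if (!all(req %in% names(obs))) abort("observations need columns m, n, f_dry_hz, f_wet_hz")
  if (any(obs$f_wet_hz <= 0) || any(obs$f_wet_hz > obs$f_dry_hz * (1 + 1e-12))) {
    abort("need 0 < f_wet_hz <= f_dry_hz for every mode")
  }
  rows <- purrr::map_dfr(seq_len(nrow(obs)), function(i) mode_row(spec, c(obs$m[i], obs$n[i])))
  rho_f <- spec$film_density
  vf <- spec$film_volume_m3
  mf <- rho_f * vf
  # per-mode apparent added mass (kg): beta_i * rho1 * V1
  s <- (obs$f_dry_hz / obs$f_wet_hz)^2 - 1
  M <- s * mf

  if (all(abs(s) < 1e-12)) {
    return(new_droplet_fit(NA_real_, 0, 0, 0L, TRUE, FALSE))
  }

  if (!is.null(volume_pl)) {
    v1 <- volume_pl * 1e-15
    if (v1 <= 0) abort("known `volume_pl` must be positive when shifts are non-zero")
    # closed form per mode, combined by least squares (equal weights)
    rho_hat <- base::mean(M * (1 + rows$gamma * v1 / vf) / v1)
    fit_load <- droplet_load(rho_hat, volume_pl)
    res <- resonator_residuals(obs, rows, spec, fit_load)
    return(new_droplet_fit(rho_hat, volume_pl, sqrt(sum(res^2)), 0L, TRUE, TRUE))
  }

  if (nrow(obs) < 2 || length(unique(rows$gamma)) < 2) {
    abort("underdetermined: need >= 2 modes with distinct coverage rates, or a known droplet volume")
  }

  # closed-form initialisation from the first two distinct-gamma modes
  i2 <- which(rows$gamma != rows$gamma[1])[1]
  g1 <- rows$gamma[1]; g2 <- rows$gamma[i2]
  m1 <- M[1]; m2 <- M[i2]
  u0 <- (m1 - m2) / (m2 * g2 - m1 * g1) # V1 / Vf
  if (!is.finite(u0) || u0 <= 0) u0 <- 0.1
  mu0 <- m1 * (1 + g1 * u0) # rho1 * V1
  v1_0 <- u0 * vf
  rho_0 <- mu0 / v1_0
  if (!is.finite(rho_0) || rho_0 <= 0) rho_0 <- 1000

  theta <- c(log(rho_0), log(v1_0))
  obj <- function(th) {
    load <- list(density = exp(th[1]), volume_m3 = exp(th[2]))
    resonator_residuals(obs, rows, spec, load)
  }
  r_cur <- obj(theta)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    # numerical Jacobian in log-parameters
    J <- vapply(1:2, function(k) {
      h <- 1e-7
      tp <- theta; tp[k] <- tp[k] + h
      (obj(tp) - r_cur) / h
    }, numeric(length(r_cur)))
    step <- tryCatch(
      qr.solve(J, -r_cur),
      error = function(e) abort(sprintf(
        "inversion failed: singular Jacobian (residual norm %.3g)", sqrt(sum(r_cur^2))
      ))
    )
    lambda <- 1
    improved <- FALSE
    for (half in 1:30) {
      th_new <- theta + lambda * step
      r_new <- obj(th_new)
      if (sum(r_new^2) < sum(r_cur^2) || max(abs(lambda * step)) < tol) {
        improved <- TRUE
        break
      }
      lambda <- lambda / 2
    }
    if (!improved) break
    moved <- max(abs(th_new - theta))
    theta <- th_new
    r_cur <- r_new
    if (moved < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged && sqrt(sum(r_cur^2)) > 1e-6) {
    abort(sprintf(
      "inversion did not converge after %d iterations (residual norm %.3g)",
      iter, sqrt(sum(r_cur^2))
    ))
  }
  new_droplet_fit(
    exp(theta[1]), exp(theta[2]) * 1e15,
    sqrt(sum(r_cur^2)), iter, TRUE, TRUE
  )
}

# relative frequency residuals of the forward model against observations
resonator_residuals <- function(obs, rows, spec, load) {
  beta <- 1 / (1 + rows$gamma * load$volume_m3 / spec$film_volume_m3)
  rho_load <- spec$film_density +
    beta * load$density * load$volume_m3 / spec$film_volume_m3
  f_model <- obs$f_dry_hz * sqrt(spec$film_density / rho_load)
  (f_model - obs$f_wet_hz) / obs$f_dry_hz
}

new_droplet_fit <- function(density, volume_pl, residual_norm, iterations,
                            converged, identifiable) {
  structure(
    list(
      density = density, volume_pl = volume_pl,
      residual_norm = residual_norm, iterations = iterations,
      converged = converged, identifiable = identifiable
    ),
    class = "droplet_fit"
  )
}

#' @export
print.droplet_fit <- function(x, ...) {
  if (!x$identifiable) {
    cat("Droplet fit: V_1 = 0 (no shift); density unidentifiable\n")
  } else {
    cat(sprintf(
      "Droplet fit: rho_1 = %.4f kg/m^3, V_1 = %.5g pL (residual %.3g, %d iteration(s))\n",
      x$density, x$volume_pl, x$residual_norm, x$iterations
    ))
  }
  invisible(x)
}

#' @rdname invert_load
#' @param x a `droplet_fit` object.
#' @param ... unused.
#' @method tidy droplet_fit
#' @export
tidy.droplet_fit <- function(x, ...) {
  tibble(
    density = x$density,
    volume_pl = x$volume_pl,
    residual_norm = x$residual_norm,
    iterations = x$iterations,
    converged = x$converged,
    identifiable = x$identifiable
  )
}
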