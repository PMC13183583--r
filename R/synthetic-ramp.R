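# Bell-model force-ramp simulator for dynamic force spectroscopy.

#' Survival function of the rupture force under a linear ramp
#'
#' For Bell kinetics `k(F) = k0 * exp(F * delta_x / kT)` under a linear
#' ramp `F = r t`, the probability that a state is still folded at force
#' `F` is
#' \deqn{S(F) = \exp\!\left[-\frac{k_0 kT}{r \Delta x}
#'   \left(e^{F \Delta x / kT} - 1\right)\right].}
#'
#' @param F force, pN (vectorized).
#' @param k0 intrinsic unfolding rate at zero force, s^-1.
#' @param delta_x distance to the transition state, nm.
#' @param rate loading rate, pN s^-1.
#' @param kT thermal energy, pN nm.
#' @return survival probabilities.
#' @export
bell_survival <- function(F, k0, delta_x, rate = 1, kT = 4.11) {
  exp(-(k0 * kT) / (rate * delta_x) * (exp(F * delta_x / kT) - 1))
}

#' Most probable rupture force under a linear ramp
#'
#' Analytic mode of the Bell rupture-force distribution,
#' `F* = (kT/delta_x) * log(rate * delta_x / (k0 * kT))` (valid when the
#' argument of the log exceeds 1).
#'
#' @inheritParams bell_survival
#' @return modal force, pN.
#' @examples
#' bell_rupture_mode(1e-4, 0.25)  # 105.4 pN
#' @export
bell_rupture_mode <- function(k0, delta_x, rate = 1, kT = 4.11) {
  (kT / delta_x) * log(rate * delta_x / (k0 * kT))
}

#' Draw rupture forces for a Bell-model state under a linear ramp
#'
#' Exact inverse-CDF sampling from the rupture-force distribution implied
#' by [bell_survival()]:
#' `F = (kT/delta_x) * log(1 - log(U) * rate * delta_x / (k0 * kT))` for
#' uniform `U`. This is the elementary draw used by the trajectory
#' simulator; it does not touch the global RNG state management, so seed
#' it with `withr::with_seed()` or `set.seed()` as needed.
#'
#' @inheritParams bell_survival
#' @param n number of draws.
#' @return rupture forces, pN.
#' @export
bell_rupture_sample <- function(n, k0, delta_x, rate = 1, kT = 4.11) {
  if (k0 <= 0 || delta_x <= 0 || rate <= 0) stop("k0, delta_x, rate must be > 0")
  a <- (k0 * kT) / (rate * delta_x)
  (kT / delta_x) * log(1 - log(stats::runif(n)) / a)
}

#' Simulation settings for a force-ramp trajectory
#'
#' Describes the folded states of the tethered construct (each with its
#' own Bell parameters and contour-length increment), the ramp, and the
#' measurement noise. Defaults emulate an mCherry-like construct: a weak
#' state (22 nm of contour released near 15 pN) and a strong state
#' (65 nm near 50 pN) under the standard 1 pN/s ramp.
#'
#' @param states data frame with columns `k0` (s^-1, > 0), `delta_x`
#'   (nm, > 0), `dLc` (nm, >= 0); one row per unfolding state. May have
#'   zero rows for a bare-tether trace. Each state draws its rupture force
#'   independently; no unfolding order is imposed.
#' @param loading_rate pN s^-1 (> 0).
#' @param sample_rate acquisition rate, Hz.
#' @param noise_sd extension noise, nm (Gaussian per sample).
#' @param drift slow baseline drift, nm s^-1.
#' @param f_max maximum force of the ramp, pN (bead/tether limit); rupture
#'   events beyond it do not appear in the trace.
#' @param seed integer seed.
#' @return object of class `ramp_sim_spec`.
#' @export
ramp_sim_spec <- function(states = data.frame(
                            k0 = c(7.2e-4, 7.2e-7),
                            delta_x = c(1.75, 1.05),
                            dLc = c(22, 65)),
                          loading_rate = 1, sample_rate = 100,
                          noise_sd = 1, drift = 0, f_max = 120,
                          seed = 1L) {
  stopifnot(is.data.frame(states),
            all(c("k0", "delta_x", "dLc") %in% names(states)))
  if (nrow(states) > 0) {
    if (any(states$k0 <= 0) || any(states$delta_x <= 0))
      stop("k0 and delta_x must be > 0")
    if (any(states$dLc < 0)) stop("dLc must be >= 0")
  }
  if (loading_rate <= 0) stop("loading_rate must be > 0")
  if (sample_rate <= 0 || noise_sd < 0 || f_max <= 0)
    stop("invalid sampling or noise settings")
  structure(list(states = states, loading_rate = loading_rate,
                 sample_rate = sample_rate, noise_sd = noise_sd,
                 drift = drift, f_max = f_max, seed = as.integer(seed)),
            class = "ramp_sim_spec")
}

#' Simulate a force-ramp unfolding trajectory with known events
#'
#' Draws one rupture force per state from the Bell ramp distribution,
#' builds the extension as the sum of the FJC extensions of the
#' already-released contour-length increments at the current force, and
#' adds drift and Gaussian noise. The true events (time, force, released
#' contour length, and instantaneous step size at the rupture force) are
#' attached; events whose rupture force exceeds `f_max` are marked
#' unobserved and do not appear in the trace.
#'
#' @param spec a [ramp_sim_spec()].
#' @param constants [fjc_constants()] used for the elastic extension.
#' @return a `ramp_trajectory` data frame with columns `time_s`,
#'   `force_pN`, `extension_nm`; attributes `events` (true-event table:
#'   `t_U`, `F_U`, `step`, `dLc`, `observed`), `loading_rate`,
#'   `sample_rate`, `spec`.
#' @export
gen_ramp_trajectory <- function(spec, constants = fjc_constants()) {
  stopifnot(inherits(spec, "ramp_sim_spec"))
  r <- spec$loading_rate
  n_states <- nrow(spec$states)
  sim <- withr::with_seed(spec$seed, {
    F_U <- if (n_states > 0)
      vapply(seq_len(n_states), function(i)
        bell_rupture_sample(1, spec$states$k0[i], spec$states$delta_x[i], r,
                            constants$kT), numeric(1))
    else numeric(0)
    t_end <- spec$f_max / r
    tt <- seq(1 / spec$sample_rate, t_end, by = 1 / spec$sample_rate)
    ff <- r * tt
    ext <- spec$drift * tt
    if (n_states > 0) {
      ord <- order(F_U)
      for (i in ord) {
        if (F_U[i] > spec$f_max) next
        on <- ff >= F_U[i]
        ext[on] <- ext[on] + fjc_extension(ff[on], spec$states$dLc[i],
                                           constants)
      }
    }
    if (spec$noise_sd > 0)
      ext <- ext + stats::rnorm(length(ext), sd = spec$noise_sd)
    list(tt = tt, ff = ff, ext = ext, F_U = F_U)
  })
  traj <- data.frame(time_s = sim$tt, force_pN = sim$ff,
                     extension_nm = sim$ext)
  events <- if (n_states > 0) {
    ord <- order(sim$F_U)
    data.frame(t_U = sim$F_U[ord] / r, F_U = sim$F_U[ord],
               step = fjc_extension(pmax(sim$F_U[ord], 1e-9),
                                    spec$states$dLc[ord], constants),
               dLc = spec$states$dLc[ord],
               observed = sim$F_U[ord] <= spec$f_max)
  } else {
    data.frame(t_U = numeric(0), F_U = numeric(0), step = numeric(0),
               dLc = numeric(0), observed = logical(0))
  }
  attr(traj, "events") <- events
  attr(traj, "loading_rate") <- r
  attr(traj, "sample_rate") <- spec$sample_rate
  attr(traj, "spec") <- spec
  class(traj) <- c("ramp_trajectory", "data.frame")
  traj
}

#' Write / read ramp trajectories as CSV
#'
#' @param traj a `ramp_trajectory`.
#' @param path CSV path (`time_s`, `force_pN`, `extension_nm`).
#' @param loading_rate,sample_rate metadata restored on read (inferred
#'   from the columns when omitted).
#' @return `read_ramp_trajectory` returns a `ramp_trajectory`.
#' @export
write_ramp_trajectory <- function(traj, path) {
  utils::write.csv(as.data.frame(traj)[c("time_s", "force_pN",
                                         "extension_nm")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ramp_trajectory
#' @export
read_ramp_trajectory <- function(path, loading_rate = NULL,
                                 sample_rate = NULL) {
  d <- utils::read.csv(path)
  stopifnot(all(c("time_s", "force_pN", "extension_nm") %in% names(d)))
  if (is.null(loading_rate))
    loading_rate <- stats::median(diff(d$force_pN) / diff(d$time_s))
  if (is.null(sample_rate))
    sample_rate <- 1 / stats::median(diff(d$time_s))
  attr(d, "loading_rate") <- loading_rate
  attr(d, "sample_rate") <- sample_rate
  class(d) <- c("ramp_trajectory", "data.frame")
  d
}
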