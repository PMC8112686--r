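# Seeded generators for the point-measurement modalities: AFM force curves,
# FRAP region-intensity traces and FCS photon traces. Each is a pure function
# of (parameters, seed).

#' Generate a synthetic AFM force-indentation curve
#'
#' Pre-contact segment is pure baseline noise; past the contact point the
#' force follows the Sneddon cone-contact law
#' `F = 2/pi * E/(1-nu^2) * tan(alpha) * delta^2`.
#'
#' @param e_pa Young's modulus, Pa.
#' @param nu Poisson's ratio.
#' @param alpha_rad Tip half-opening angle, rad, in (0, pi/2).
#' @param contact_nm Contact point position along the ramp, nm.
#' @param max_indentation_nm Maximum indentation depth, nm (> 0).
#' @param n Number of samples along the ramp.
#' @param noise_sd_nn Gaussian force noise sd, nN (0 for a noiseless curve).
#' @param seed Integer seed.
#' @return A tibble of class `force_curve` with columns `z_nm`, `force_nn`
#'   and attributes `alpha_rad`, `nu`, `contact_nm_true`, `e_pa_true`.
#' @export
#' @examples
#' fc <- gen_force_curve(13e3, alpha_rad = 20 * pi / 180)
gen_force_curve <- function(e_pa, nu = 0.5, alpha_rad = 20 * pi / 180,
                            contact_nm = 500, max_indentation_nm = 1000,
                            n = 600, noise_sd_nn = 0, seed = 1L) {
  check_that(e_pa > 0, "`e_pa` must be > 0")
  check_that(alpha_rad > 0 && alpha_rad < pi / 2, "`alpha_rad` must be in (0, pi/2)")
  check_that(max_indentation_nm > 0, "`max_indentation_nm` must be > 0")
  set.seed(seed)
  z <- seq(0, contact_nm + max_indentation_nm, length.out = n)
  delta <- pmax(z - contact_nm, 0)
  f <- sneddon_force_nn(delta, e_pa, nu, alpha_rad)
  if (noise_sd_nn > 0) f <- f + rnorm(n, 0, noise_sd_nn)
  tb <- tibble::tibble(z_nm = z, force_nn = f)
  structure(tb, class = c("force_curve", class(tb)),
            alpha_rad = alpha_rad, nu = nu,
            contact_nm_true = contact_nm, e_pa_true = e_pa)
}

#' Acquisition schedule of a photobleaching-recovery experiment
#'
#' Pre-bleach frames at 1 s spacing before the bleach at `t = 0`, then frames
#' every `dt1` for the first `span1` seconds and every `dt2` for the last
#' `span2` seconds (the default is the 1 s / 4 s, 40 s + 40 s protocol).
#'
#' @param n_pre Number of pre-bleach frames.
#' @param dt1,span1 Early post-bleach frame interval and span, s.
#' @param dt2,span2 Late post-bleach frame interval and span, s.
#' @return Numeric vector of frame times (s); bleach at `t = 0`.
#' @export
frap_schedule <- function(n_pre = 5, dt1 = 1, span1 = 40, dt2 = 4, span2 = 40) {
  c(seq(-n_pre, -1), seq(0, span1, by = dt1),
    seq(span1 + dt2, span1 + span2, by = dt2))
}

#' Generate a synthetic FRAP region-intensity trace
#'
#' Constructs bleached-adhesion, control-adhesion and cytoplasm intensities
#' such that the double normalization (ratio to the control region, then
#' anchoring between the post-bleach and pre-bleach levels) recovers
#' `F(t) = m (1 - exp(-k_off t))` exactly at zero noise. A shared
#' multiplicative per-frame acquisition-bleach decay is applied to all
#' regions; the control-ratio step cancels it by construction.
#'
#' @param k_off Dissociation rate constant, 1/s (> 0).
#' @param m Mobile fraction, in (0, 1].
#' @param times Frame times from [frap_schedule()]; strictly increasing,
#'   bleach at t = 0, at least one pre-bleach frame.
#' @param i_pre,i_o,i_cyt,i_ctrl Intensity levels (arbitrary units) of the
#'   adhesion before bleach, immediately after bleach, the cytoplasm, and the
#'   control adhesion. Must satisfy `i_pre > i_o >= i_cyt` and `i_ctrl > i_cyt`.
#' @param bleach_per_frame Fractional intensity loss per acquired frame
#'   (e.g. 0.002 for 0.2 %/frame), shared by all fluorescent regions.
#' @param noise_sd Gaussian noise sd added to each region trace, same units
#'   as the intensities.
#' @param seed Integer seed.
#' @return A tibble of class `frap_trace` with columns `t_s`, `i_ph_fa`,
#'   `i_c_fa`, `i_cyt`, `i_bkg`; attributes `n_pre`, `k_off_true`, `m_true`.
#' @export
gen_frap_trace <- function(k_off, m, times = frap_schedule(),
                           i_pre = 1000, i_o = 350, i_cyt = 200, i_ctrl = 900,
                           bleach_per_frame = 0, noise_sd = 0, seed = 1L) {
  check_that(k_off > 0, "`k_off` must be > 0")
  check_that(m > 0 && m <= 1, "`m` must be in (0, 1]")
  check_that(all(diff(times) > 0), "`times` must be strictly increasing")
  check_that(any(times < 0) && sum(times >= 0) >= 5,
             "need pre-bleach frames and >= 5 post-bleach frames")
  check_that(i_pre > i_o && i_o >= i_cyt && i_ctrl > i_cyt,
             "intensity levels must satisfy i_pre > i_o >= i_cyt and i_ctrl > i_cyt")
  set.seed(seed)
  nfr <- length(times)
  post <- times >= 0
  # normalized bleached-region ratio r(t) = (I_ph - I_cyt)/(I_ctrl - I_cyt)
  r_pre <- (i_pre - i_cyt) / (i_ctrl - i_cyt)
  r_o <- (i_o - i_cyt) / (i_ctrl - i_cyt)
  recov <- m * (1 - exp(-k_off * pmax(times, 0)))
  r <- ifelse(post, r_o + (r_pre - r_o) * recov, r_pre)
  decay <- (1 - bleach_per_frame)^(seq_len(nfr) - 1)
  i_cyt_t <- i_cyt * decay
  i_ctrl_t <- i_cyt_t + (i_ctrl - i_cyt) * decay
  i_ph_t <- i_cyt_t + (i_ctrl_t - i_cyt_t) * r
  i_bkg_t <- rep(50, nfr)
  if (noise_sd > 0) {
    i_ph_t <- i_ph_t + rnorm(nfr, 0, noise_sd)
    i_ctrl_t <- i_ctrl_t + rnorm(nfr, 0, noise_sd)
    i_cyt_t <- i_cyt_t + rnorm(nfr, 0, noise_sd)
    i_bkg_t <- i_bkg_t + rnorm(nfr, 0, noise_sd)
  }
  tb <- tibble::tibble(t_s = times, i_ph_fa = i_ph_t, i_c_fa = i_ctrl_t,
                       i_cyt = i_cyt_t, i_bkg = i_bkg_t)
  structure(tb, class = c("frap_trace", class(tb)),
            n_pre = sum(!post), k_off_true = k_off, m_true = m)
}

#' Confocal detection volume
#'
#' 3D-Gaussian observation volume with radial waist `w_r` and axial-to-radial
#' aspect ratio `omega = w_z / w_r` (> 1 for a confocal volume elongated
#' along the optical axis).
#'
#' @param w_r_um Radial 1/e^2 waist, micrometres.
#' @param omega Axial-to-radial aspect ratio (> 1).
#' @return A list of class `detection_volume` with `w_r_um`, `w_z_um`, `omega`.
#' @export
detection_volume <- function(w_r_um = 0.25, omega = 5) {
  check_that(w_r_um > 0, "`w_r_um` must be > 0")
  check_that(omega > 1, "`omega` must be > 1 (axial waist exceeds radial)")
  structure(list(w_r_um = w_r_um, w_z_um = omega * w_r_um, omega = omega),
            class = "detection_volume")
}

#' One- or two-component 3D-diffusion autocorrelation model
#'
#' `G(tau) = sum_i G0_i (1 + tau/tauD_i)^-1 (1 + tau/(omega^2 tauD_i))^-1/2`.
#'
#' @param tau_s Lag times, s.
#' @param g0 Per-component amplitudes.
#' @param tau_d_s Per-component characteristic diffusion times, s.
#' @param omega Detection-volume aspect ratio.
#' @return Numeric vector of model ACF values.
#' @export
acf_diffusion_model <- function(tau_s, g0, tau_d_s, omega) {
  check_that(length(g0) == length(tau_d_s), "`g0` and `tau_d_s` must have equal length")
  out <- numeric(length(tau_s))
  for (i in seq_along(g0)) {
    out <- out + g0[i] / ((1 + tau_s / tau_d_s[i]) *
                            sqrt(1 + tau_s / (omega^2 * tau_d_s[i])))
  }
  out
}

#' Generate a model autocorrelation curve directly
#'
#' Fast shortcut for fit-only tests: evaluates the diffusion ACF model on a
#' lag grid and optionally adds Gaussian noise. The characteristic times are
#' derived from diffusion coefficients through `tau_D = w_r^2 / (4 D)`.
#'
#' @param d_um2_s Per-component diffusion coefficients, um^2/s.
#' @param g0 Per-component amplitudes.
#' @param volume A [detection_volume()].
#' @param lags_s Lag grid, s; default 60 log-spaced lags from 1 us to 10 s.
#' @param noise_sd Gaussian noise sd on G (0 for noiseless).
#' @param seed Integer seed.
#' @return An `acf_curve` tibble (`tau_s`, `g`, `g_se`) with attribute
#'   `n_subrecords = NA` (model curve, not estimated).
#' @export
gen_acf_curve <- function(d_um2_s, g0 = rep(0.1, length(d_um2_s)),
                          volume = detection_volume(),
                          lags_s = 10^seq(-6, 1, length.out = 60),
                          noise_sd = 0, seed = 1L) {
  check_that(all(d_um2_s > 0), "diffusion coefficients must be > 0")
  tau_d <- volume$w_r_um^2 / (4 * d_um2_s)
  g <- acf_diffusion_model(lags_s, g0, tau_d, volume$omega)
  if (noise_sd > 0) {
    set.seed(seed)
    g <- g + rnorm(length(g), 0, noise_sd)
  }
  new_acf_curve(lags_s, g, g_se = rep(if (noise_sd > 0) noise_sd else NA_real_,
                                      length(g)), n_subrecords = NA_integer_)
}

#' Simulate an FCS photon trace from Brownian emitters
#'
#' Point emitters perform Brownian motion in a periodic box; emission is
#' weighted by a 3D-Gaussian detection profile
#' `exp(-2 r^2 / w_r^2 - 2 z^2 / w_z^2)` centred in the box, and photon
#' counts per sampling interval are Poisson-distributed.
#'
#' @param d_um2_s Per-component diffusion coefficients, um^2/s.
#' @param rate_hz Per-component mean detected count rate contribution at the
#'   volume centre occupancy (counts/s per molecule); sets the brightness.
#' @param n_molecules Per-component number of molecules in the box.
#' @param volume A [detection_volume()].
#' @param duration_s Trace duration, s.
#' @param sample_rate_hz Sampling rate, Hz.
#' @param box_um Length-3 box half-sizes (x, y, z), um; must dwarf the volume.
#' @param dark_rate_hz Dark-count rate, Hz.
#' @param seed Integer seed.
#' @return A tibble of class `intensity_trace` with column `counts`;
#'   attributes `sample_rate_hz`, `duration_s`.
#' @export
gen_fcs_trace <- function(d_um2_s, rate_hz = 3e4,
                          n_molecules = 8,
                          volume = detection_volume(),
                          duration_s = 10, sample_rate_hz = 2e4,
                          box_um = c(1.5, 1.5, 4),
                          dark_rate_hz = 0, seed = 1L) {
  check_that(all(d_um2_s > 0), "diffusion coefficients must be > 0")
  check_that(all(box_um > 2 * c(volume$w_r_um, volume$w_r_um, volume$w_z_um)),
             "box must be much larger than the detection volume")
  n_steps <- round(duration_s * sample_rate_hz)
  dt <- 1 / sample_rate_hz
  rate_hz <- rep_len(rate_hz, length(d_um2_s))
  n_molecules <- rep_len(n_molecules, length(d_um2_s))
  set.seed(seed)
  lambda <- numeric(n_steps)
  for (ci in seq_along(d_um2_s)) {
    sd_step <- sqrt(2 * d_um2_s[ci] * dt)
    for (mol in seq_len(n_molecules[ci])) {
      pos <- lapply(box_um, function(b) {
        p <- runif(1, -b, b) + cumsum(rnorm(n_steps, 0, sd_step))
        ((p + b) %% (2 * b)) - b  # periodic wrap
      })
      w <- exp(-2 * (pos[[1]]^2 + pos[[2]]^2) / volume$w_r_um^2 -
                 2 * pos[[3]]^2 / volume$w_z_um^2)
      lambda <- lambda + rate_hz[ci] * dt * w
    }
  }
  counts <- rpois(n_steps, lambda + dark_rate_hz * dt)
  tb <- tibble::tibble(counts = as.numeric(counts))
  structure(tb, class = c("intensity_trace", class(tb)),
            sample_rate_hz = sample_rate_hz, duration_s = duration_s)
}
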