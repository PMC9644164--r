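# Synthetic paired accelerometer/GRF trials with ground-truth events.
#
# The generator states a simple but explicit world: single-leg vertical GRF
# that is exactly zero outside stance (single-belt recording), a walking
# stance with the classic double bump (duty factor > 0.5), a running
# stance with a single bump, an impact spike and a flight phase (duty
# factor < 0.5), and a latent shank signal that is a deterministic, smooth
# function of the gait phase, randomly rotated into three accelerometer
# channels and corrupted with Gaussian noise. GRF itself is kept
# noise-free so that event ground truth is unambiguous. Stance onsets and
# offsets carry a brief (1.5% of stance) loading/unloading plateau at 25%
# of peak force so that the 12.5%-of-maximum threshold crossing happens
# within one sample of the true stance boundary at the working rate.

# Loading/unloading plateau heights (fractions of peak force) and ramp
# width, calibrated once per mode so that the 12.5%-threshold crossing of
# the smoothed, resampled waveform coincides with the stance boundary
# within one sample at 2000/14 Hz. Running needs no loading plateau (the
# impact spike already loads fast) and a lower unloading plateau (its
# narrow bump otherwise keeps the +/- 30 ms smoothing window above the
# threshold past foot off).
.plateau_frac <- list(walking = c(inp = 0.25, out = 0.25),
                      running = c(inp = 0.00, out = 0.15))
.edge_frac <- 0.015

#' Gait pattern specification
#'
#' Mode-specific defaults: walking stride 1.10 s, duty factor 0.60, double
#' bump with peak 1.1 body weights and a 0.75-peak valley; running stride
#' 0.72 s, duty factor 0.35, single bump of 2.5 body weights plus a 30%
#' impact spike. Stride durations jitter with a 3% coefficient of
#' variation; accelerometer noise is 5% of the signal SD.
#'
#' @param mode `"walking"` or `"running"`.
#' @param stride_duration mean stride duration in s.
#' @param duty_factor stance fraction of the stride (walking > 0.5 >
#'   running).
#' @param peak_force peak vertical force in body weights.
#' @param valley walking mid-stance valley as a fraction of peak.
#' @param impact_spike running impact-spike amplitude as a fraction of
#'   peak (0 for walking).
#' @param cadence_jitter_cv coefficient of variation of stride durations.
#' @param accel_noise_sd accelerometer noise SD as a fraction of each
#'   channel's signal SD.
#' @param sensor_rotation_seed seed of the fixed random sensor rotation.
#' @export
gait_pattern_spec <- function(mode = c("walking", "running"),
                              stride_duration = NULL, duty_factor = NULL,
                              peak_force = NULL, valley = 0.75,
                              impact_spike = NULL,
                              cadence_jitter_cv = 0.03,
                              accel_noise_sd = 0.05,
                              sensor_rotation_seed = 17L) {
  mode <- match.arg(mode)
  if (is.null(stride_duration)) {
    stride_duration <- if (mode == "walking") 1.10 else 0.72
  }
  if (is.null(duty_factor)) duty_factor <- if (mode == "walking") 0.60 else 0.35
  if (is.null(peak_force)) peak_force <- if (mode == "walking") 1.1 else 2.5
  if (is.null(impact_spike)) impact_spike <- if (mode == "walking") 0 else 0.3
  stopifnot(duty_factor > 0, duty_factor < 1, stride_duration > 0,
            peak_force > 0, cadence_jitter_cv >= 0, accel_noise_sd >= 0)
  if (mode == "walking" && duty_factor <= 0.5) {
    stop("walking requires duty_factor > 0.5")
  }
  if (mode == "running" && duty_factor >= 0.5) {
    stop("running requires duty_factor < 0.5")
  }
  structure(list(mode = mode, stride_duration = stride_duration,
                 duty_factor = duty_factor, peak_force = peak_force,
                 valley = valley, impact_spike = impact_spike,
                 cadence_jitter_cv = cadence_jitter_cv,
                 accel_noise_sd = accel_noise_sd,
                 sensor_rotation_seed = as.integer(sensor_rotation_seed)),
            class = "gait_pattern_spec")
}

#' Synthetic trial specification
#'
#' @param pattern a [gait_pattern_spec()].
#' @param n_strides number of strides (default 72, emulating the typical
#'   trial length; >= 3).
#' @param grf_fs force sampling rate in Hz (default 1000).
#' @param accel_fs accelerometer rate in Hz (default 2000/14).
#' @param body_weight body weight in N (default 700).
#' @param seed trial seed.
#' @export
synthetic_trial_spec <- function(pattern, n_strides = 72, grf_fs = 1000,
                                 accel_fs = 2000 / 14, body_weight = 700,
                                 seed = 1L) {
  stopifnot(inherits(pattern, "gait_pattern_spec"), n_strides >= 3,
            grf_fs > 0, accel_fs > 0, body_weight > 0)
  structure(list(pattern = pattern, n_strides = as.integer(n_strides),
                 grf_fs = grf_fs, accel_fs = accel_fs,
                 body_weight = body_weight, seed = as.integer(seed)),
            class = "synthetic_trial_spec")
}

# C1 smoothstep on [0, 1]
smoothstep <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  u * u * (3 - 2 * u)
}

# raised-cosine ramp from y0 at u = a to y1 at u = b (zero slope at both)
rc_piece <- function(u, a, b, y0, y1) {
  y0 + (y1 - y0) * 0.5 * (1 - cos(pi * (u - a) / (b - a)))
}

# stance template as a function of stance phase u in [0, 1], in body
# weights; zero at both ends, C1-continuous, strictly positive inside
stance_template_fun <- function(pattern) {
  P <- pattern$peak_force
  pf <- .plateau_frac[[pattern$mode]]
  dPi <- pf[["inp"]] * P
  dPo <- pf[["out"]] * P
  e <- .edge_frac
  # plateau level interpolates loading -> unloading height; C1 smoothstep
  # ramps keep the template zero at both stance ends
  plate <- function(u) {
    (dPi * (1 - u) + dPo * u) *
      pmin(smoothstep(u / e), smoothstep((1 - u) / e))
  }
  if (pattern$mode == "walking") {
    A <- P - dPo
    B <- pattern$valley * P - dPo
    core <- function(u) {
      out <- numeric(length(u))
      i1 <- u < 0.25
      i2 <- u >= 0.25 & u < 0.5
      i3 <- u >= 0.5 & u < 0.75
      i4 <- u >= 0.75
      out[i1] <- rc_piece(u[i1], 0, 0.25, 0, A)
      out[i2] <- rc_piece(u[i2], 0.25, 0.5, A, B)
      out[i3] <- rc_piece(u[i3], 0.5, 0.75, B, A)
      out[i4] <- rc_piece(u[i4], 0.75, 1, A, 0)
      out
    }
    function(u) {
      u <- pmin(pmax(u, 0), 1)
      core(u) + plate(u)
    }
  } else {
    A <- P - dPo
    S <- pattern$impact_spike * P
    u0 <- 0.08
    tau <- 0.05
    function(u) {
      u <- pmin(pmax(u, 0), 1)
      core <- ifelse(u < 0.45,
                     rc_piece(u, 0, 0.45, 0, A),
                     rc_piece(u, 0.45, 1, A, 0))
      spike <- ifelse(u < u0,
                      S * u / u0,
                      S * exp(-(u - u0) / tau) * (1 - u) / (1 - u0))
      core + spike + plate(u)
    }
  }
}

#' Stance-phase GRF template
#'
#' Samples the mode's stance waveform (in body-weight units) at
#' `stance_samples` equispaced points of the stance phase, endpoints
#' included (both exactly zero). Walking: a double bump with peaks at 25%
#' and 75% of stance and a valley between; running: a single bump peaking
#' at 45% of stance plus an exponentially decaying impact spike at 8% of
#' stance. Both carry a brief loading/unloading plateau (see the module
#' comments).
#'
#' @param mode `"walking"` or `"running"`.
#' @param stance_samples number of samples (>= 8).
#' @param pattern optional [gait_pattern_spec()]; defaults to the mode's
#'   standard pattern.
#' @return numeric vector of length `stance_samples`.
#' @export
grf_stance_template <- function(mode, stance_samples,
                                pattern = gait_pattern_spec(mode)) {
  stopifnot(stance_samples >= 8)
  f <- stance_template_fun(pattern)
  u <- seq(0, 1, length.out = stance_samples)
  y <- f(u)
  y[c(1, stance_samples)] <- 0
  y
}

# numeric derivative of the stance template (per stance-phase unit)
stance_template_deriv <- function(f, u, h = 1e-4) {
  (f(pmin(u + h, 1)) - f(pmax(u - h, 0))) /
    (pmin(u + h, 1) - pmax(u - h, 0))
}

#' Synthesize one walking or running trial
#'
#' Draws i.i.d. lognormal stride durations (CV = `cadence_jitter_cv`),
#' builds the GRF at `grf_fs` (body weight times the stance template over
#' the first `duty_factor` of each stride, exactly zero elsewhere), records
#' ground-truth FC/FO events at the stance boundaries at both rates, and
#' constructs tri-axial acceleration at `accel_fs` as a fixed random 3D
#' rotation of `(s, 0.3 s shifted by 5% of a stride, 0.1 s)` plus Gaussian
#' noise, where the latent shank signal `s` mixes the template's first
#' derivative during stance, a sinusoidal swing burst and a damped 20 Hz
#' impact transient at each foot contact. Fully reproducible from
#' `spec$seed`.
#'
#' @param spec a [synthetic_trial_spec()].
#' @param trial_id identifier for the returned record.
#' @param speed speed metadata in m/s (default mode-typical).
#' @param rotation optional 3 x 3 sensor rotation matrix; the default is
#'   the fixed random rotation drawn from
#'   `spec$pattern$sensor_rotation_seed`.
#' @return a [trial_record()] whose `events` are the ground-truth events on
#'   the accelerometer sample grid; the GRF-rate events are attached as
#'   attribute `events_grf`.
#' @export
synthesize_trial <- function(spec, trial_id = "trial",
                             speed = NULL, rotation = NULL) {
  stopifnot(inherits(spec, "synthetic_trial_spec"))
  pat <- spec$pattern
  if (is.null(speed)) speed <- if (pat$mode == "walking") 1.24 else 2.20
  f <- stance_template_fun(pat)
  md <- max(abs(stance_template_deriv(f, seq(0.001, 0.999, by = 0.001))))
  with_seed(spec$seed, {
    cv <- pat$cadence_jitter_cv
    sdlog <- sqrt(log(1 + cv^2))
    meanlog <- log(pat$stride_duration) - sdlog^2 / 2
    dur <- stats::rlnorm(spec$n_strides, meanlog, sdlog)
    starts <- cumsum(c(0, dur[-length(dur)]))
    total <- sum(dur)
    fc_t <- starts
    fo_t <- starts + pat$duty_factor * dur

    n_grf <- floor(total * spec$grf_fs)
    t_grf <- (seq_len(n_grf) - 1) / spec$grf_fs
    grf <- grf_at(t_grf, starts, dur, pat, f) * spec$body_weight

    n_acc <- as.integer(ceiling(n_grf * spec$accel_fs / spec$grf_fs))
    t_acc <- (seq_len(n_acc) - 1) / spec$accel_fs
    lat <- function(t) latent_shank(t, starts, dur, pat, f, md)
    s1 <- lat(t_acc)
    s2 <- 0.3 * lat(t_acc - 0.05 * pat$stride_duration)
    s3 <- 0.1 * s1
    A <- rbind(s1, s2, s3)
    R3 <- if (is.null(rotation)) random_rotation(pat$sensor_rotation_seed)
          else rotation
    X <- R3 %*% A
    if (pat$accel_noise_sd > 0) {
      for (i in 1:3) {
        X[i, ] <- X[i, ] + stats::rnorm(n_acc, 0,
                                        pat$accel_noise_sd * stats::sd(X[i, ]))
      }
    }
    ev_at <- function(fs, n) {
      fc <- pmin(pmax(round(fc_t * fs) + 1L, 1L), n)
      fo <- pmin(pmax(round(fo_t * fs) + 1L, 1L), n)
      gait_event_series(fc, fo, fs = fs)
    }
    accel <- sampled_signal(X, fs = spec$accel_fs,
                            labels = c("ax", "ay", "az"))
    grf_sig <- sampled_signal(matrix(grf, nrow = 1), fs = spec$grf_fs,
                              labels = "Fz")
    tr <- trial_record(trial_id, pat$mode, speed, accel, grf_sig,
                       events = ev_at(spec$accel_fs, n_acc))
    attr(tr, "events_grf") <- ev_at(spec$grf_fs, n_grf)
    attr(tr, "stride_starts_s") <- starts
    attr(tr, "stride_durations_s") <- dur
    tr
  })
}

# vectorized GRF evaluation at arbitrary times (body-weight units)
grf_at <- function(t, starts, dur, pat, f) {
  k <- findInterval(t, starts)
  k[k < 1] <- 1
  u <- (t - starts[k]) / dur[k]
  u[u < 0] <- 0
  u[u >= 1] <- 1
  stance <- u < pat$duty_factor
  out <- numeric(length(t))
  out[stance] <- f(u[stance] / pat$duty_factor)
  out
}

# Latent shank signal as a deterministic function of the gait phase.
# During stance it mixes the loading rate (template derivative), a
# force-proportional axial component and a second-harmonic "tibial shock"
# vibration; swing carries a two-component oscillatory burst (leg swing
# plus a higher harmonic) so that every swing phase is uniquely decodable;
# a damped 20 Hz transient marks each foot contact. The mixture is rich
# enough that the gait phase - and hence the force waveform - is
# recoverable from the accelerometer alone, which is what the prediction
# method assumes of real shank accelerometry.
latent_shank <- function(t, starts, dur, pat, f, deriv_scale) {
  out <- numeric(length(t))
  ok <- t >= 0
  if (!any(ok)) return(out)
  t <- t[ok]
  k <- findInterval(t, starts)
  k[k < 1] <- 1
  u <- (t - starts[k]) / dur[k]
  u[u < 0] <- 0
  u[u >= 1] <- 1 - 1e-12
  d <- pat$duty_factor
  stance <- u < d
  s <- numeric(length(t))
  us <- u[stance] / d
  s[stance] <- 3 * f(us) / pat$peak_force +
    0.3 * stance_template_deriv(f, us) / deriv_scale +
    0.1 * sin(4 * pi * us) * sin(pi * us)
  w <- (u[!stance] - d) / (1 - d)
  s[!stance] <- 0.3 * sin(pi * w)^2 * sin(3 * pi * w) +
    0.15 * sin(pi * w) * cos(5 * pi * w)
  tc <- u * dur[k]                      # time since foot contact
  s <- s + 0.2 * exp(-tc / 0.03) * sin(2 * pi * 20 * tc)
  out[ok] <- s
  out
}

# fixed random rotation matrix from a seed (QR of a Gaussian matrix)
random_rotation <- function(seed) {
  with_seed(seed, {
    qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
    Q <- qr.Q(qr_)
    if (det(Q) < 0) Q[, 1] <- -Q[, 1]
    Q
  })
}

# small random rotation: angle <= max_deg about a random axis (Rodrigues)
small_rotation <- function(seed, max_deg = 15) {
  with_seed(seed, {
    ax <- stats::rnorm(3)
    ax <- ax / sqrt(sum(ax^2))
    th <- stats::runif(1, 0, max_deg * pi / 180)
    K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
    diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  })
}

#' Synthesize a cohort of walking and running trials
#'
#' Emulates the standard recording session: `n_per_mode` walking and
#' `n_per_mode` running trials (21 + 21 by default). Per-trial speeds are
#' drawn Normal(1.24, 0.12) m/s for walking and Normal(2.20, 0.14) m/s for
#' running, and the stride duration scales inversely with speed around the
#' mode default. Stride counts are drawn per trial (lognormal around 72,
#' truncated to 49..116) unless `n_strides` is given. Sensor mounting
#' emulates realistic between-subject variability: one random base
#' orientation for the cohort with an independent tilt of up to
#' `mount_tilt_deg` degrees per trial (sensors are strapped to the shank
#' in roughly the same way on every subject, never upside down; arbitrary
#' per-trial orientations would make the sign of the leading principal
#' component inconsistent between trials, which no single readout could
#' reconcile).
#'
#' @param n_per_mode trials per mode.
#' @param n_strides fixed stride count per trial, or `NULL` to draw.
#' @param master_seed integer master seed; per-trial seeds are derived
#'   from it.
#' @param accel_noise_sd accelerometer noise level passed to the patterns.
#' @param cadence_jitter_cv stride-duration jitter passed to the patterns.
#' @param mount_tilt_deg maximum per-trial sensor tilt in degrees.
#' @return list of [trial_record()] objects.
#' @export
synthesize_cohort <- function(n_per_mode = 21, n_strides = NULL,
                              master_seed = 1L, accel_noise_sd = 0.05,
                              cadence_jitter_cv = 0.03,
                              mount_tilt_deg = 15) {
  stopifnot(n_per_mode >= 1)
  base_rot <- random_rotation(derive_seed(master_seed, 999L))
  trials <- list()
  idx <- 0L
  for (mode in c("walking", "running")) {
    mu_v <- if (mode == "walking") 1.24 else 2.20
    sd_v <- if (mode == "walking") 0.12 else 0.14
    for (i in seq_len(n_per_mode)) {
      idx <- idx + 1L
      seed_i <- derive_seed(master_seed, idx)
      meta <- with_seed(derive_seed(master_seed, 1000L + idx), {
        v <- stats::rnorm(1, mu_v, sd_v)
        ns <- if (is.null(n_strides)) {
          min(116L, max(49L, as.integer(round(
            stats::rlnorm(1, log(72), 0.2)))))
        } else {
          as.integer(n_strides)
        }
        list(v = v, ns = ns)
      })
      base_dur <- if (mode == "walking") 1.10 else 0.72
      pat <- gait_pattern_spec(mode,
                               stride_duration = base_dur * mu_v / meta$v,
                               accel_noise_sd = accel_noise_sd,
                               cadence_jitter_cv = cadence_jitter_cv,
                               sensor_rotation_seed = derive_seed(master_seed,
                                                                  2000L + idx))
      spec <- synthetic_trial_spec(pat, n_strides = meta$ns, seed = seed_i)
      id <- sprintf("%s%02d", if (mode == "walking") "walk" else "run", i)
      rot <- base_rot %*% small_rotation(derive_seed(master_seed, 2000L + idx),
                                         mount_tilt_deg)
      trials[[idx]] <- synthesize_trial(spec, trial_id = id, speed = meta$v,
                                        rotation = rot)
    }
  }
  trials
}
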