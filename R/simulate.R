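#' Simulation configuration for synthetic sEMG/force recordings
#'
#' Describes a recording session in which a subject repeatedly grasps a force
#' sensor at prompted strength levels while multi-channel surface EMG is
#' recorded from the forearm. The simulator emulates the statistical structure
#' such a session produces: smooth ~1 s force bursts at four strength levels
#' separated by relaxation, and band-limited zero-mean EMG whose envelope
#' grows with the exerted force. Per-channel coupling gains plant ground
#' truth about which electrode sites are informative (a gain of 0 yields a
#' pure-noise channel).
#'
#' @param n_channels number of sEMG channels.
#' @param fs sampling rate in Hz (EMG and force are sampled synchronously).
#' @param n_actions total number of grasp actions.
#' @param strength_levels target force levels as fractions of `max_force`.
#' @param actions_per_level repetitions of each level;
#'   `actions_per_level * length(strength_levels)` must equal `n_actions`.
#' @param action_duration duration of one grasp action in seconds.
#' @param rest_range range (seconds) from which each inter-action relaxation
#'   duration is drawn uniformly.
#' @param max_force subject's maximum grasp force in Newtons.
#' @param channel_gains per-channel coupling of force to EMG envelope
#'   (dimensionless scale; 0 = channel carries no force information).
#' @param envelope_exponent exponent of the force-to-envelope law; 1 gives a
#'   linear amplitude/force relation.
#' @param envelope_scale EMG envelope standard deviation (uV) contributed at
#'   maximum force by a channel with gain 1.
#' @param noise_floor baseline EMG noise standard deviation in uV.
#' @param band EMG passband in Hz, `c(low, high)`; must lie below `fs/2`.
#' @param level_jitter_sd sigma of the lognormal per-action amplitude jitter
#'   emulating trial-to-trial variability around the prompted level.
#' @param force_noise_sd additive force-sensor noise standard deviation (N).
#' @param seed integer seed; identical seeds give bit-identical recordings.
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [generate_recording()]
#' @export
sim_config <- function(n_channels = 6,
                       fs = 1000,
                       n_actions = 60,
                       strength_levels = c(0.25, 0.50, 0.75, 1.00),
                       actions_per_level = 15,
                       action_duration = 1.0,
                       rest_range = c(0.5, 1.5),
                       max_force = 250,
                       channel_gains = c(1.0, 0.8, 0.6, 0.9, 0.3, 0.0),
                       envelope_exponent = 1,
                       envelope_scale = 150,
                       noise_floor = 10,
                       band = c(10, 500),
                       level_jitter_sd = 0.08,
                       force_noise_sd = 0.3,
                       seed = 1L) {
  cfg <- list(n_channels = as.integer(n_channels), fs = fs,
              n_actions = as.integer(n_actions),
              strength_levels = strength_levels,
              actions_per_level = as.integer(actions_per_level),
              action_duration = action_duration, rest_range = rest_range,
              max_force = max_force, channel_gains = channel_gains,
              envelope_exponent = envelope_exponent,
              envelope_scale = envelope_scale, noise_floor = noise_floor,
              band = band, level_jitter_sd = level_jitter_sd,
              force_noise_sd = force_noise_sd, seed = as.integer(seed))
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  fail <- function(field, why) {
    stop("invalid simulation configuration: field '", field, "' ", why,
         call. = FALSE)
  }
  if (cfg$n_channels < 1) fail("n_channels", "must be >= 1")
  if (cfg$fs <= 0) fail("fs", "must be positive")
  if (cfg$actions_per_level * length(cfg$strength_levels) != cfg$n_actions)
    fail("n_actions",
         "must equal actions_per_level * length(strength_levels)")
  if (length(cfg$band) != 2 || cfg$band[1] <= 0 || cfg$band[2] <= cfg$band[1])
    fail("band", "must be c(low, high) with 0 < low < high")
  if (cfg$band[2] > cfg$fs / 2) fail("band", "upper edge must be <= fs/2")
  if (length(cfg$channel_gains) != cfg$n_channels)
    fail("channel_gains", "must have one entry per channel")
  if (any(cfg$channel_gains < 0)) fail("channel_gains", "must be >= 0")
  if (all(cfg$channel_gains == 0)) fail("channel_gains",
                                        "must include at least one gain > 0")
  if (cfg$max_force <= 0) fail("max_force", "must be positive")
  if (cfg$action_duration <= 0) fail("action_duration", "must be positive")
  if (length(cfg$rest_range) != 2 || cfg$rest_range[1] < 0 ||
      cfg$rest_range[2] < cfg$rest_range[1])
    fail("rest_range", "must be c(min, max) with 0 <= min <= max")
  if (cfg$noise_floor < 0) fail("noise_floor", "must be >= 0")
  if (cfg$envelope_scale < 0) fail("envelope_scale", "must be >= 0")
  structure(cfg, class = "sim_config")
}

#' Generate a synthetic multi-channel sEMG + grasp-force recording
#'
#' Builds the force trace as a shuffled sequence of smooth ramp-plateau-ramp
#' bursts (10% raised-cosine rise and fall) at the configured strength
#' levels, separated by relaxation periods of random duration, then
#' synthesizes each EMG channel as band-limited zero-mean Gaussian noise
#' whose instantaneous standard deviation is
#' `noise_floor + gain * (force/max_force)^envelope_exponent * envelope_scale`.
#' A small truncated-Gaussian sensor noise is added to the force trace.
#'
#' The returned recording carries the planted ground truth (per-action spans,
#' strength levels, channel gains) in its `actions` and `channel_gains`
#' attributes, so segmentation and channel-selection results can be scored
#' against the truth.
#'
#' @param cfg a [sim_config()].
#' @return A `recording` object (see [recording()]); attribute `actions` is a
#'   data frame with columns `action`, `onset`, `offset` (half-open sample
#'   span of the burst), `level`, and `peak_force`; attribute
#'   `channel_gains` echoes the configuration.
#' @export
#' @examples
#' rec <- generate_recording(sim_config(n_actions = 8, actions_per_level = 2,
#'                                      seed = 42))
#' nrow(attr(rec, "actions"))
generate_recording <- function(cfg) {
  if (!inherits(cfg, "sim_config")) cfg <- validate_sim_config(cfg)
  set.seed(cfg$seed)

  n_act_samples <- round(cfg$action_duration * cfg$fs)
  levels_seq <- sample(rep(cfg$strength_levels, each = cfg$actions_per_level))
  rest_s <- stats::runif(cfg$n_actions + 1, cfg$rest_range[1],
                         cfg$rest_range[2])
  jitter <- stats::rlnorm(cfg$n_actions, meanlog = 0,
                          sdlog = cfg$level_jitter_sd)

  burst <- burst_profile(n_act_samples)
  pieces <- vector("list", 2 * cfg$n_actions + 1)
  onsets <- integer(cfg$n_actions)
  pos <- 0L
  for (a in seq_len(cfg$n_actions)) {
    n_rest <- round(rest_s[a] * cfg$fs)
    pieces[[2 * a - 1]] <- numeric(n_rest)
    pos <- pos + n_rest
    onsets[a] <- pos + 1L
    pieces[[2 * a]] <- burst * (levels_seq[a] * jitter[a] * cfg$max_force)
    pos <- pos + n_act_samples
  }
  pieces[[2 * cfg$n_actions + 1]] <- numeric(round(rest_s[cfg$n_actions + 1] *
                                                     cfg$fs))
  force_clean <- unlist(pieces, use.names = FALSE)
  n <- length(force_clean)

  # envelope driven by the noise-free force; sensor noise added afterwards
  rel <- (force_clean / cfg$max_force)^cfg$envelope_exponent
  # an upper edge at Nyquist constrains nothing: design a high-pass there
  nyq <- cfg$fs / 2
  bf <- if (cfg$band[2] >= 0.99 * nyq) {
    signal::butter(4, cfg$band[1] / nyq, type = "high")
  } else {
    signal::butter(4, cfg$band / nyq, type = "pass")
  }
  emg <- matrix(0, nrow = n, ncol = cfg$n_channels)
  for (ch in seq_len(cfg$n_channels)) {
    carrier <- signal::filtfilt(bf, stats::rnorm(n))
    carrier <- carrier / stats::sd(carrier)
    sd_env <- cfg$noise_floor + cfg$channel_gains[ch] * rel *
      cfg$envelope_scale
    emg[, ch] <- carrier * sd_env
  }
  force <- pmax(0, force_clean + stats::rnorm(n, sd = cfg$force_noise_sd))

  rec <- recording(fs = cfg$fs, emg = emg, force = force)
  attr(rec, "actions") <- data.frame(
    action = seq_len(cfg$n_actions),
    onset = onsets,
    offset = onsets + n_act_samples,
    level = levels_seq,
    peak_force = levels_seq * jitter * cfg$max_force
  )
  attr(rec, "channel_gains") <- cfg$channel_gains
  rec
}

# Smooth unit-amplitude burst: raised-cosine rise and fall over ~10% of the
# duration each, flat plateau in between.  Avoids step discontinuities so
# onset detection on the force trace is non-trivial but well posed.
burst_profile <- function(n, ramp_fraction = 0.1) {
  r <- max(1L, round(ramp_fraction * n))
  up <- (1 - cos(pi * seq_len(r) / r)) / 2
  plateau <- rep(1, max(0L, n - 2L * r))
  c(up, plateau, rev(up))[seq_len(n)]
}
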