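## Synthetic EEG cohort generator.  Emulates the shape of the study design
## (four groups A-D, 24 subjects each, 19 channels of the 10-20 system,
## 8-second segments at 128 Hz) and the qualitative spectral contrast
## between healthy controls and AD patients: controls are alpha-dominant,
## AD shows "slowing" (power shifted toward delta/theta).  Each segment is
## a sum of (i) a broadband 1/f background limited to 1-30 Hz with fixed,
## group-independent power, as in real band-limited EEG; (ii) per-band
## rhythms: Gaussian noise with a spectral peak at the band centre, scaled
## to the group's band-power profile, so changing a band's power changes
## the peaked-to-broadband mixture (and hence the temporal dynamics) inside
## that band only; (iii) a narrowband 10 Hz AR(2) alpha oscillator whose
## amplitude is boosted in the eyes-closed groups; and (iv) white
## measurement noise.  Not a biophysical model.

default_band_power <- function() list(
  A = c(delta = 1.0, theta = 0.8, alpha = 1.6, beta = 0.6),
  B = c(delta = 1.0, theta = 0.8, alpha = 1.6, beta = 0.6),
  C = c(delta = 2.6, theta = 2.0, alpha = 0.7, beta = 0.45),
  D = c(delta = 2.6, theta = 2.0, alpha = 0.7, beta = 0.45)
)

default_alpha_gain <- function(channels) {
  posterior <- c("Pz", "P3", "P4", "O1", "O2", "T5", "T6")
  frontal <- c("Fp1", "Fp2", "Fz", "F3", "F4", "F7", "F8")
  g <- ifelse(channels %in% posterior, 1.3,
              ifelse(channels %in% frontal, 0.8, 1.0))
  stats::setNames(g, channels)
}

#' Specification of a synthetic EEG cohort
#'
#' Defaults mirror the reference study design: groups A (controls, eyes
#' open), B (controls, eyes closed), C (AD, eyes open), D (AD, eyes
#' closed); 24 subjects per group; the 19 channels of the 10-20 system;
#' 1024 samples at 128 Hz.
#'
#' @param groups Group labels.
#' @param subjects_per_group Number of subjects per group.
#' @param channels Channel labels.
#' @param T Segment length in samples.
#' @param sampling_rate Sampling frequency, Hz.
#' @param band_power Named list (one entry per group) of band-rhythm
#'   variances (signal-variance units) named `delta`, `theta`, `alpha`,
#'   `beta`.  Each rhythm is spectrally peaked at its band centre.
#' @param background_power Variance of the group-independent broadband
#'   1/f background (1-30 Hz).
#' @param rhythm_power Named numeric: variance of the 10 Hz AR(2) alpha
#'   oscillator per group (eyes-closed groups get more).
#' @param alpha_gain Named numeric per channel: amplitude gain applied to
#'   the alpha oscillator (posterior channels larger).
#' @param contrast Named numeric per channel in \[0, 1\]: scales the
#'   departure of each group's profile from the reference (first) group's
#'   profile.  1 = full class contrast, 0 = channel carries no group
#'   information.
#' @param noise_sd White measurement-noise standard deviation.
#' @param subject_sd Log-scale standard deviation of per-subject
#'   multiplicative band-power variability.
#' @return Object of class `qg_cohort_spec`.
#' @export
cohort_spec <- function(groups = c("A", "B", "C", "D"),
                        subjects_per_group = 24,
                        channels = channels_1020,
                        T = 1024, sampling_rate = 128,
                        band_power = default_band_power()[groups],
                        rhythm_power = c(A = 0.4, B = 1.4, C = 0.15,
                                         D = 0.5)[groups],
                        alpha_gain = default_alpha_gain(channels),
                        contrast = stats::setNames(rep(1, length(channels)),
                                                   channels),
                        background_power = 1.0,
                        noise_sd = 0.3, subject_sd = 0.15) {
  if (anyDuplicated(channels)) stop("channels must be unique")
  band_power <- lapply(band_power, function(p) {
    p <- p[c("delta", "theta", "alpha", "beta")]
    if (any(is.na(p)) || any(p < 0))
      stop("band powers must be nonnegative and named delta/theta/alpha/beta")
    p
  })
  if (!setequal(names(band_power), groups))
    stop("band_power must have one entry per group")
  names(rhythm_power) <- groups
  if (any(rhythm_power < 0)) stop("rhythm powers must be nonnegative")
  structure(list(groups = groups, subjects_per_group = subjects_per_group,
                 channels = channels, T = T, sampling_rate = sampling_rate,
                 band_power = band_power, rhythm_power = rhythm_power,
                 alpha_gain = alpha_gain, contrast = contrast,
                 background_power = background_power,
                 noise_sd = noise_sd, subject_sd = subject_sd),
            class = "qg_cohort_spec")
}

band_edges <- function() list(delta = c(1, 4), theta = c(4, 8),
                              alpha = c(8, 13), beta = c(13, 30))

# Unit-variance Gaussian noise with spectral envelope `env(f)` on [lo, hi]
# Hz (zero outside), shaped by FFT masking.
shaped_noise <- function(T, fs, lo, hi, env = function(f) rep(1, length(f))) {
  z <- rnorm(T)
  f <- (seq_len(T) - 1) * fs / T
  f <- pmin(f, fs - f) # two-sided spectrum folded to [0, fs/2]
  w <- ifelse(f >= lo & f <= hi, env(f), 0)
  x <- Re(fft(fft(z) * w, inverse = TRUE)) / T
  s <- sd(x)
  if (s > 0) x / s else x
}

# Unit-variance band rhythm: narrow spectral peak at the band centre
# (width one sixth of the band), over the band's support.
band_rhythm_noise <- function(T, fs, lo, hi) {
  fc <- (lo + hi) / 2
  sigma <- (hi - lo) / 6
  shaped_noise(T, fs, lo, hi, function(f) exp(-(f - fc)^2 / (2 * sigma^2)))
}

# Unit-variance broadband 1/f background limited to 1-30 Hz.
background_noise <- function(T, fs) {
  shaped_noise(T, fs, 1, 30, function(f) 1 / sqrt(pmax(f, 1)))
}

# Unit-variance narrowband AR(2) oscillator with resonance at f0 Hz.
ar2_oscillator <- function(T, fs, f0 = 10, r = 0.97, burn = 200) {
  phi <- c(2 * r * cos(2 * pi * f0 / fs), -r^2)
  y <- stats::filter(rnorm(T + burn), phi, method = "recursive")
  y <- as.numeric(y)[(burn + 1):(burn + T)]
  s <- sd(y)
  if (s > 0) y / s else y
}

# Group profile at a channel, shrunk toward the reference (first) group's
# profile by the channel's contrast factor.
effective_profile <- function(spec, group, channel) {
  ref <- spec$band_power[[spec$groups[1]]]
  own <- spec$band_power[[group]]
  ctr <- spec$contrast[[channel]]
  ref_r <- spec$rhythm_power[[spec$groups[1]]]
  list(band = ref + ctr * (own - ref),
       rhythm = ref_r + ctr * (spec$rhythm_power[[group]] - ref_r))
}

#' Generate one synthetic EEG segment
#'
#' Deterministic in (seed, group, channel, subject): repeated calls with
#' identical arguments return identical samples.  Subject-level band-power
#' factors are drawn from the subject (not the channel), so a subject's
#' spectral character is coherent across channels.
#'
#' @param spec A [cohort_spec()].
#' @param group,channel Labels present in the spec.
#' @param subject Subject index (1-based within the group) or id string
#'   `"S07"`.
#' @param seed Integer master seed.
#' @return A [qg_segment()].
#' @export
generate_segment <- function(spec, group, channel, subject, seed = 1) {
  stopifnot(inherits(spec, "qg_cohort_spec"))
  gi <- match(group, spec$groups)
  ci <- match(channel, spec$channels)
  if (is.na(gi)) stop(sprintf("unknown group '%s'", group))
  if (is.na(ci)) stop(sprintf("unknown channel '%s'", channel))
  si <- if (is.character(subject)) as.integer(sub("^S", "", subject))
        else as.integer(subject)
  T <- spec$T; fs <- spec$sampling_rate
  prof <- effective_profile(spec, group, channel)

  sub_fac <- with_seed(mix_seed(seed, 7L, gi, si), {
    list(band = exp(rnorm(4, 0, spec$subject_sd)),
         rhythm = exp(rnorm(1, 0, spec$subject_sd)))
  })

  x <- with_seed(mix_seed(seed, 11L, gi, si, ci), {
    edges <- band_edges()
    out <- numeric(T)
    if (spec$background_power > 0)
      out <- out + sqrt(spec$background_power) * background_noise(T, fs)
    for (b in seq_along(edges)) {
      v <- prof$band[[b]] * sub_fac$band[b]
      if (v > 0)
        out <- out + sqrt(v) *
          band_rhythm_noise(T, fs, edges[[b]][1], edges[[b]][2])
    }
    rv <- prof$rhythm * sub_fac$rhythm * spec$alpha_gain[[channel]]^2
    if (rv > 0) out <- out + sqrt(rv) * ar2_oscillator(T, fs)
    if (spec$noise_sd > 0) out <- out + rnorm(T, 0, spec$noise_sd)
    out
  })

  qg_segment(x, sampling_rate = fs, channel = channel, group = group,
             subject = sprintf("S%02d", si))
}

#' Generate a full synthetic cohort
#'
#' All (group, subject, channel) combinations of the spec, deterministically
#' from the seed.
#'
#' @inheritParams generate_segment
#' @return A [qg_cohort()].
#' @export
generate_cohort <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "qg_cohort_spec"))
  grid <- expand.grid(channel = spec$channels,
                      subject = seq_len(spec$subjects_per_group),
                      group = spec$groups,
                      stringsAsFactors = FALSE)
  values <- vector("list", nrow(grid))
  for (r in seq_len(nrow(grid))) {
    seg <- generate_segment(spec, grid$group[r], grid$channel[r],
                            grid$subject[r], seed = seed)
    values[[r]] <- seg$values
  }
  meta <- data.frame(group = grid$group,
                     subject = sprintf("S%02d", grid$subject),
                     channel = grid$channel,
                     stringsAsFactors = FALSE)
  qg_cohort(values, meta, spec$sampling_rate)
}
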