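#' Z-spectrum container
#'
#' A saturated signal series indexed by frequency offset (ppm from water)
#' together with its unsaturated reference S0.
#'
#' @param offsets_ppm strictly increasing saturation offsets (ppm).
#' @param s_sat saturated signals, same length, non-negative.
#' @param s0 unsaturated reference signal (> 0).
#' @return An object of class `zspectrum`.
#' @export
zspectrum <- function(offsets_ppm, s_sat, s0) {
  offsets_ppm <- as.numeric(offsets_ppm)
  s_sat <- as.numeric(s_sat)
  if (length(offsets_ppm) != length(s_sat)) {
    stop("offsets_ppm and s_sat must have equal length")
  }
  if (any(diff(offsets_ppm) <= 0)) stop("offsets_ppm must be strictly increasing")
  if (any(s_sat < 0)) stop("s_sat must be non-negative")
  if (!(is.numeric(s0) && length(s0) == 1L && s0 > 0)) stop("s0 must be a positive scalar")
  structure(list(offsets_ppm = offsets_ppm, s_sat = s_sat, s0 = as.numeric(s0)),
            class = "zspectrum")
}

# Lorentzian line with unit-normalised peak: amp at x = center, FWHM = width
lorentzian <- function(x, amplitude, center, width) {
  hw2 <- (width / 2)^2
  amplitude * hw2 / ((x - center)^2 + hw2)
}

#' Specify a synthetic z-spectrum phantom
#'
#' The saturated spectrum is built as S0 * (1 - sum of Lorentzian pools): a
#' direct-saturation water pool and a semisolid MT pool, both centred on
#' water (0 ppm), plus an amide pool at +3.5 ppm.  A true static-field offset
#' shifts the whole spectrum along the offset axis.  A companion low-power
#' series (water pool only) over a narrow sweep emulates the WASSR-style B0
#' scan.  Pool amplitudes are fractions of S0.
#'
#' @param offsets_ppm saturation offsets of the main series (default 31 steps
#'   spanning -4.5..+4.5 ppm).
#' @param low_power_offsets_ppm offsets of the B0 scan (default 11 steps over
#'   -1..+1 ppm).
#' @param water_pool,mt_pool,amide_pool numeric `c(amplitude, center, width)`
#'   in (fraction of S0, ppm, ppm FWHM); water and MT must be centred at 0,
#'   amide at +3.5.
#' @param low_power_water_width FWHM (ppm) of the water dip in the low-power
#'   series; direct saturation narrows sharply at low saturation power, so
#'   this is much smaller than the main-series water width.
#' @param b0_shift_ppm true field offset (ppm).
#' @param s0 unsaturated signal level.
#' @param snr S0-relative SNR of the Rician noise; `Inf` for noiseless.
#' @param seed integer master seed.
#' @return An object of class `zspectrum_phantom_spec`.
#' @export
zspectrum_phantom_spec <- function(offsets_ppm = seq(-4.5, 4.5, length.out = 31),
                                   low_power_offsets_ppm = seq(-1, 1, length.out = 11),
                                   water_pool = c(amplitude = 0.85, center = 0, width = 1.6),
                                   mt_pool = c(amplitude = 0.06, center = 0, width = 25),
                                   amide_pool = c(amplitude = 0.025, center = 3.5, width = 1.5),
                                   low_power_water_width = 1.0,
                                   b0_shift_ppm = 0,
                                   s0 = 1000,
                                   snr = Inf,
                                   seed = 1L) {
  offsets_ppm <- sort(as.numeric(offsets_ppm))
  low_power_offsets_ppm <- sort(as.numeric(low_power_offsets_ppm))
  if (min(offsets_ppm) > -3.5 || max(offsets_ppm) < 3.5) {
    stop("offsets_ppm must cover +-3.5 ppm")
  }
  chk_pool <- function(p, name, center) {
    p <- as.numeric(p)
    if (length(p) != 3L) stop(sprintf("%s must be (amplitude, center, width)", name))
    if (p[1] < 0 || p[1] >= 1) stop(sprintf("%s amplitude must be in [0, 1)", name))
    if (abs(p[2] - center) > 1e-12) {
      stop(sprintf("%s must be centred at %g ppm", name, center))
    }
    if (p[3] <= 0) stop(sprintf("%s width must be > 0", name))
    p
  }
  water_pool <- chk_pool(water_pool, "water_pool", 0)
  mt_pool <- chk_pool(mt_pool, "mt_pool", 0)
  amide_pool <- chk_pool(amide_pool, "amide_pool", 3.5)
  if (water_pool[1] + mt_pool[1] + amide_pool[1] >= 1) {
    stop("pool amplitudes must sum to < 1 so the spectrum stays non-negative")
  }
  if (!(snr > 0)) stop("snr must be > 0")
  if (low_power_water_width <= 0) stop("low_power_water_width must be > 0")
  structure(list(offsets_ppm = offsets_ppm,
                 low_power_offsets_ppm = low_power_offsets_ppm,
                 water_pool = water_pool, mt_pool = mt_pool,
                 amide_pool = amide_pool,
                 low_power_water_width = as.numeric(low_power_water_width),
                 b0_shift_ppm = as.numeric(b0_shift_ppm),
                 s0 = as.numeric(s0), snr = snr, seed = as.integer(seed)),
            class = "zspectrum_phantom_spec")
}

# pool sum evaluated on the recentred (water at 0) axis
zspec_pool_sum <- function(spec, x) {
  lorentzian(x, spec$water_pool[1], 0, spec$water_pool[3]) +
    lorentzian(x, spec$mt_pool[1], 0, spec$mt_pool[3]) +
    lorentzian(x, spec$amide_pool[1], 3.5, spec$amide_pool[3])
}

#' Analytic MTRasym of a phantom spec
#'
#' The asymmetry at +-3.5 ppm of the noiseless spectrum evaluated on the
#' perfectly recentred axis, i.e. the value an ideal B0 correction would
#' recover.  With a zero-amplitude amide pool this is exactly 0 because the
#' water and MT pools are symmetric.
#'
#' @param spec a [zspectrum_phantom_spec()].
#' @return MTRasym in percent.
#' @export
true_mtrasym <- function(spec) {
  stopifnot(inherits(spec, "zspectrum_phantom_spec"))
  100 * (zspec_pool_sum(spec, 3.5) - zspec_pool_sum(spec, -3.5))
}

#' Amide amplitude that yields a target MTRasym
#'
#' Inverts the (linear) relation between amide-pool amplitude and analytic
#' MTRasym for a given line width, so phantoms can be built to a prescribed
#' asymmetry, e.g. the group medians of a clinical cohort.
#'
#' @param target_pct desired MTRasym in percent.
#' @param width amide Lorentzian FWHM (ppm).
#' @return Amplitude as a fraction of S0.
#' @export
amide_amplitude_for_mtrasym <- function(target_pct, width = 1.5) {
  hw2 <- (width / 2)^2
  tail <- hw2 / ((2 * 3.5)^2 + hw2) # unit-amplitude leakage at -3.5 ppm
  (target_pct / 100) / (1 - tail)
}

#' Generate a synthetic z-spectrum phantom
#'
#' Returns the main saturated series, the low-power B0 series (water pool
#' only, same B0 shift), and the analytic ground-truth MTRasym.  Rician noise
#' with sigma = S0/snr is added to the saturated signals when snr is finite.
#'
#' @param spec a [zspectrum_phantom_spec()].
#' @return A list of class `zspectrum_phantom`: `spectrum` and
#'   `low_power_spectrum` ([zspectrum()] objects), `true_mtrasym_pct`,
#'   `b0_shift_ppm`.
#' @export
generate_zspectrum_phantom <- function(spec) {
  stopifnot(inherits(spec, "zspectrum_phantom_spec"))
  main <- spec$s0 * (1 - zspec_pool_sum(spec, spec$offsets_ppm - spec$b0_shift_ppm))
  lowp <- spec$s0 * (1 - lorentzian(spec$low_power_offsets_ppm - spec$b0_shift_ppm,
                                    spec$water_pool[1], 0, spec$low_power_water_width))
  if (is.finite(spec$snr)) {
    sigma <- spec$s0 / spec$snr
    noisy <- with_stream_seed(spec$seed, "cest_noise", {
      rice <- function(s) sqrt((s + rnorm(length(s), sd = sigma))^2 +
                                 rnorm(length(s), sd = sigma)^2)
      list(main = rice(main), lowp = rice(lowp))
    })
    main <- noisy$main
    lowp <- noisy$lowp
  }
  structure(list(spectrum = zspectrum(spec$offsets_ppm, main, spec$s0),
                 low_power_spectrum = zspectrum(spec$low_power_offsets_ppm, lowp, spec$s0),
                 true_mtrasym_pct = true_mtrasym(spec),
                 b0_shift_ppm = spec$b0_shift_ppm,
                 seed = spec$seed),
            class = "zspectrum_phantom")
}
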