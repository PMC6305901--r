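#' H/M recruitment-curve parameters
#'
#' Parametric model of the soleus H-reflex / M-wave recruitment curve
#' against tibial-nerve stimulation intensity. The M-wave follows a
#' saturating logistic (non-decreasing, plateau at `m_max_mv`); the
#' H-reflex is unimodal: it grows on the ascending limb and collapses
#' as antidromic collision sets in once the M-wave recruits, modelled
#' as a Gaussian bump peaking at `h_peak_intensity`.
#'
#' Intensity is expressed in multiples of motor threshold (xMT), the
#' field's usual normalized unit. Defaults give an H-max of 60% of
#' M-max peaking well below M-wave half-recruitment, the classic
#' standing-soleus picture.
#'
#' @param m_max_mv maximal M-wave peak-to-peak amplitude (mV).
#' @param h_max_mv maximal H-reflex peak-to-peak amplitude (mV).
#' @param h_peak_intensity intensity at the H-reflex maximum (xMT).
#' @param h_width intensity width (SD) of the H-reflex bump.
#' @param m_half_intensity intensity of half-maximal M recruitment.
#' @param m_slope logistic slope of the M recruitment (xMT units).
#' @return an object of class `ps_hm_params`.
#' @export
hm_curve_params <- function(m_max_mv = 8, h_max_mv = 4.8,
                            h_peak_intensity = 1.15, h_width = 0.35,
                            m_half_intensity = 1.55, m_slope = 0.18) {
  check_scalar_num(m_max_mv, "m_max_mv", positive = TRUE)
  check_scalar_num(h_max_mv, "h_max_mv", positive = TRUE)
  check_scalar_num(h_peak_intensity, "h_peak_intensity", positive = TRUE)
  check_scalar_num(h_width, "h_width", positive = TRUE)
  check_scalar_num(m_half_intensity, "m_half_intensity", positive = TRUE)
  check_scalar_num(m_slope, "m_slope", positive = TRUE)
  structure(list(m_max_mv = m_max_mv, h_max_mv = h_max_mv,
                 h_peak_intensity = h_peak_intensity, h_width = h_width,
                 m_half_intensity = m_half_intensity, m_slope = m_slope),
            class = "ps_hm_params")
}

#' Sample an H/M recruitment curve on an intensity grid
#'
#' @param params an [hm_curve_params()] object.
#' @param intensities strictly increasing stimulation-intensity grid.
#' @param noise_sd_mv additive measurement noise SD (mV); 0 = noise-free.
#' @param seed optional integer seed.
#' @return a `ps_recruitment_curve`: list with `intensity`, `h_mv`,
#'   `m_mv`, `m_max_mv` (max of the sampled M amplitudes).
#' @export
generate_hm_curve_samples <- function(params, intensities, noise_sd_mv = 0,
                                      seed = NULL) {
  stopifnot(inherits(params, "ps_hm_params"))
  if (length(intensities) == 0)
    abort_ps("empty intensity grid", "ps_invalid_parameter")
  if (is.unsorted(intensities, strictly = TRUE))
    abort_ps("intensity grid must be strictly increasing",
             "ps_invalid_parameter")
  if (!is.null(seed)) set.seed(seed)
  m <- params$m_max_mv / (1 + exp(-(intensities - params$m_half_intensity) /
                                    params$m_slope))
  h <- params$h_max_mv *
    exp(-0.5 * ((intensities - params$h_peak_intensity) / params$h_width)^2)
  # H threshold: smooth raised-cosine turn-on just below the bump, so the
  # curve is 0 at rest, strictly unimodal, and continuous
  h <- h * platform_profile((intensities - 0.65) * 1000, 250)
  if (noise_sd_mv > 0) {
    m <- pmax(0, m + stats::rnorm(length(m), 0, noise_sd_mv))
    h <- pmax(0, h + stats::rnorm(length(h), 0, noise_sd_mv))
  }
  recruitment_curve(intensities, h, m)
}

#' Construct a recruitment curve from measured amplitudes
#'
#' @param intensity intensity grid.
#' @param h_mv H-reflex peak-to-peak amplitudes (mV).
#' @param m_mv M-wave peak-to-peak amplitudes (mV).
#' @return a `ps_recruitment_curve` object.
#' @export
recruitment_curve <- function(intensity, h_mv, m_mv) {
  if (length(intensity) != length(h_mv) || length(intensity) != length(m_mv))
    abort_ps("intensity, h_mv and m_mv must be aligned", "ps_invalid_parameter")
  if (any(h_mv < 0) || any(m_mv < 0))
    abort_ps("amplitudes must be >= 0", "ps_invalid_parameter")
  structure(list(intensity = as.numeric(intensity), h_mv = as.numeric(h_mv),
                 m_mv = as.numeric(m_mv), m_max_mv = max(m_mv)),
            class = "ps_recruitment_curve")
}
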