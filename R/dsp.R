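# Daily sperm production from testis homogenate haemocytometer counts.

#' Daily sperm production
#'
#' Computes total elongated spermatids per testis from a haemocytometer
#' count of a weighed homogenate fragment, then divides by the number of
#' days spermatids spend in developmental steps 14-16 (4.84 in the mouse)
#' to obtain daily sperm production (DSP, spermatids/day).
#'
#' `total = mean_heads_per_chamber * heads_per_volume_factor *
#' homogenate_volume * (testis_weight / fragment_weight)`; `DSP = total /
#' residence_days`. The chamber count-to-concentration conversion factor
#' depends on the counting protocol and is an explicit input, never a
#' hidden constant.
#'
#' @param mean_heads_per_chamber Mean sperm-head count per chamber (>= 0).
#' @param heads_per_volume_factor Conversion from chamber count to heads/ul
#'   (instrument/protocol constant, > 0).
#' @param homogenate_volume Homogenate volume in ul (default 600).
#' @param fragment_weight Weight of the counted fragment, mg.
#' @param testis_weight Total testis weight, mg (>= fragment weight).
#' @param residence_days Days spermatids spend in steps 14-16 (default
#'   4.84).
#' @return DSP in spermatids/day (vectorised).
#' @export
daily_sperm_production <- function(mean_heads_per_chamber,
                                   heads_per_volume_factor,
                                   fragment_weight, testis_weight,
                                   homogenate_volume = 600,
                                   residence_days = 4.84) {
  if (any(mean_heads_per_chamber < 0)) abort("chamber count must be >= 0")
  if (any(heads_per_volume_factor <= 0)) abort("conversion factor must be > 0")
  if (any(homogenate_volume <= 0)) abort("homogenate volume must be > 0")
  if (any(fragment_weight <= 0) || any(testis_weight <= 0)) {
    abort("weights must be > 0")
  }
  if (any(fragment_weight > testis_weight)) {
    abort("fragment weight cannot exceed testis weight")
  }
  if (any(residence_days <= 0)) abort("residence days must be > 0")
  total <- mean_heads_per_chamber * heads_per_volume_factor *
    homogenate_volume * (testis_weight / fragment_weight)
  total / residence_days
}
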