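#' Plot a modulation spectrum with its energy contour
#'
#' Image of log normalized power over (temporal modulation, spectral
#' modulation) with the articulation-space contour overlaid.
#'
#' @param mps A normalized \code{modulation_spectrum}.
#' @param contour Optional \code{contour_result} to overlay.
#' @param main Title.
#' @return Invisibly, NULL. Draws on the current device.
#' @export
plot_mps_contour <- function(mps, contour = NULL, main = "Speech modulation spectrum") {
  z <- log10(pmax(mps$power, max(mps$power) * 1e-8))
  graphics::image(mps$tm_axis, mps$sm_axis, z,
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  xlab = "Temporal modulation (Hz)",
                  ylab = "Spectral modulation (cycles/kHz)",
                  main = main)
  if (!is.null(contour)) {
    graphics::contour(mps$tm_axis, mps$sm_axis,
                      matrix(as.numeric(contour$mask), nrow(contour$mask)),
                      levels = 0.5, add = TRUE, drawlabels = FALSE,
                      col = "black", lwd = 1.5)
  }
  invisible(NULL)
}

#' Scatterplot of articulation space against a covariate
#'
#' Points per participant plus the mixed-model-implied line for the chosen
#' covariate (slope from the fit, intercept at the covariate-centered
#' grand mean), the analogue of the closeness and AQ scattergrams.
#'
#' @param records Participant-record data frame.
#' @param hlm An \code{hlm_result} fitted on these records.
#' @param covariate \code{"cr"} or \code{"aq"}.
#' @return Invisibly, NULL. Draws on the current device.
#' @export
plot_area_vs_covariate <- function(records, hlm, covariate = c("cr", "aq")) {
  covariate <- match.arg(covariate)
  fe <- hlm$fixed_effects
  slope <- fe$estimate[fe$term == covariate]
  intercept <- fe$estimate[fe$term == "(Intercept)"]
  center <- hlm$fit_meta$centers[[covariate]]
  lab <- c(cr = "Closeness rating", aq = "Autism Spectrum Quotient")[covariate]
  graphics::plot(records[[covariate]], records$area_px,
                 pch = 19, col = grDevices::adjustcolor("steelblue", 0.6),
                 xlab = lab, ylab = "Articulation space (px)")
  graphics::abline(a = intercept - slope * center, b = slope, lwd = 2)
  invisible(NULL)
}
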