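# Anti-aliased rasterization of filament segments. Each segment deposits
# `gain * length_um` expected photons, spread along the segment by dense
# sub-pixel sampling with bilinear weights.
rasterize_filaments <- function(filaments, geometry, gain_photons_per_um) {
  shp <- geometry$image_shape
  img <- matrix(0, shp[1L], shp[2L])
  if (gain_photons_per_um <= 0) return(img)
  px <- geometry$pixel_size_um
  for (f in filaments) {
    if (!f$alive || f$length_um <= 0) next
    n <- max(2L, ceiling(f$length_um / (0.25 * px)))
    s <- seq(0, f$length_um, length.out = n)
    w <- gain_photons_per_um * f$length_um / n
    xs <- (f$origin[1L] + s * f$direction[1L]) / px  # column coordinate
    ys <- (f$origin[2L] + s * f$direction[2L]) / px  # row coordinate
    j0 <- floor(xs); i0 <- floor(ys)
    fx <- xs - j0; fy <- ys - i0
    # bilinear deposition onto the 4 neighbouring pixel centres (0-based)
    ii <- c(i0, i0 + 1, i0, i0 + 1)
    jj <- c(j0, j0, j0 + 1, j0 + 1)
    ww <- w * c((1 - fy) * (1 - fx), fy * (1 - fx), (1 - fy) * fx, fy * fx)
    keep <- ii >= 0 & ii < shp[1L] & jj >= 0 & jj < shp[2L]
    idx <- ii[keep] + 1L + jj[keep] * shp[1L]
    acc <- rowsum(ww[keep], idx)
    img[as.integer(rownames(acc))] <- img[as.integer(rownames(acc))] + acc[, 1L]
  }
  img
}

#' Render one actin-channel frame
#'
#' The expected image is `background_mean_photons` at every pixel inside the
#' nucleus disc (zero outside) plus the filament signal convolved with an
#' isotropic Gaussian PSF. With `noise = "poisson"` each pixel is an
#' independent Poisson draw of its expectation; with `"none"` the expectation
#' itself is returned. Rendering is additive by default; with
#' `conserve_total` the in-nucleus background is lowered uniformly so total
#' expected intensity is independent of filament content.
#'
#' @param filaments List of `filament` objects (dead ones are skipped).
#' @param geometry A [nucleus_geometry()].
#' @param imaging An [imaging_config()].
#' @param seed Integer seed for the Poisson draw (ignored for `noise = "none"`).
#' @return Numeric matrix of photon counts (or expectations).
#' @export
render_frame <- function(filaments, geometry, imaging, seed = 1L) {
  stopifnot(inherits(geometry, "nucleus_geometry"),
            inherits(imaging, "imaging_config"))
  mask <- nucleus_mask(geometry)
  sig <- rasterize_filaments(filaments, geometry,
                             imaging$filament_gain_photons_per_um)
  if (imaging$psf_sigma_um > 0 && any(sig > 0)) {
    sig <- gaussian_blur(sig, imaging$psf_sigma_um / geometry$pixel_size_um)
    sig[sig < 0] <- 0
  }
  bg <- imaging$background_mean_photons
  if (imaging$conserve_total && bg > 0) {
    bg <- max(0, bg - sum(sig) / sum(mask))
  }
  expected <- sig
  expected[mask] <- expected[mask] + bg
  if (imaging$noise == "none") return(expected)
  with_seed(seed, {
    matrix(stats::rpois(length(expected), expected),
           nrow(expected), ncol(expected))
  })
}
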