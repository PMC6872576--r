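#' EM chromatin class codes
#'
#' Integer label codes used in class maps: heterochromatin = 1 (electron
#' dense, dark), euchromatin = 2 (nuclear background), nucleolus = 3,
#' background = 4 (extranuclear). Electron-dense structures are dark in
#' transmission EM.
#' @export
em_classes <- c(heterochromatin = 1L, euchromatin = 2L,
                nucleolus = 3L, background = 4L)

# Ellipse radial coordinate: 0 at the centre, 1 on the boundary.
ellipse_u <- function(shape, center, semi_axes, angle) {
  xs <- seq_len(shape[2L]) - 1; ys <- seq_len(shape[1L]) - 1
  x <- outer(rep(1, shape[1L]), xs) - center[1L]
  y <- outer(ys, rep(1, shape[2L])) - center[2L]
  xr <- x * cos(angle) + y * sin(angle)
  yr <- -x * sin(angle) + y * cos(angle)
  sqrt((xr / semi_axes[1L])^2 + (yr / semi_axes[2L])^2)
}

#' Generate a synthetic EM-like nucleus image
#'
#' Emulates a stained thin-section transmission EM image of a nucleus: an
#' elliptical nucleus darker than the extranuclear background, one compact
#' nucleolus, and dark blob-textured heterochromatin patches placed
#' preferentially near the nuclear rim and occupying a prescribed fraction
#' of the nuclear area. The ground-truth class map is returned alongside the
#' image for validating segmentation.
#'
#' Patches are carved by thresholding a smoothed Gaussian random field
#' biased toward the rim, so the ground-truth heterochromatin pixel count
#' matches `round(fraction * nucleus_area)` exactly (the nucleolus counts
#' toward the nuclear area but is never overwritten, so very high fractions
#' saturate at the available area).
#'
#' @param fraction Target heterochromatin area fraction of the nucleus, in
#'   `[0, 1]`.
#' @param shape Image shape `c(rows, cols)` in pixels.
#' @param seed Integer seed; images are reproducible.
#' @param intensities Named mean gray levels of the four classes (0-1 scale).
#' @param noise_sd Gaussian texture noise standard deviation.
#' @param rim_bias Strength of the rim preference of heterochromatin.
#' @param blob_sigma Correlation length (pixels) of the patch texture field.
#' @return List of class `em_synthetic`: `image` (matrix), `class_map`
#'   (ground-truth `class_map`), `nucleus_mask`, `nucleolus_mask`,
#'   `fraction` (realized ground-truth fraction).
#' @export
generate_em_image <- function(fraction, shape = c(192L, 192L), seed,
                              intensities = c(heterochromatin = 0.28,
                                              euchromatin = 0.62,
                                              nucleolus = 0.42,
                                              background = 0.85),
                              noise_sd = 0.04, rim_bias = 1.2,
                              blob_sigma = 3) {
  if (!is.numeric(fraction) || length(fraction) != 1L || is.na(fraction) ||
      fraction < 0 || fraction > 1) {
    stop_param("`fraction` must lie in [0, 1]")
  }
  shape <- as.integer(shape)
  with_seed(seed, {
    center <- (rev(shape) - 1) / 2 + stats::runif(2, -3, 3)
    semi <- c(0.37, 0.29) * rev(shape) * stats::runif(2, 0.92, 1.05)
    angle <- stats::runif(1, 0, pi)
    u <- ellipse_u(shape, center, semi, angle)
    nucleus <- u <= 1
    n_nuc <- sum(nucleus)

    # nucleolus: one compact disc well inside the nucleus
    nl_r <- 0.10 * min(shape)
    nl_phi <- stats::runif(1, 0, 2 * pi)
    nl_off <- stats::runif(1, 0.15, 0.45)
    nl_center <- center + nl_off * c(semi[1L] * cos(nl_phi),
                                     semi[2L] * sin(nl_phi))
    xs <- seq_len(shape[2L]) - 1; ys <- seq_len(shape[1L]) - 1
    dx2 <- outer(rep(1, shape[1L]), (xs - nl_center[1L])^2)
    dy2 <- outer((ys - nl_center[2L])^2, rep(1, shape[2L]))
    nucleolus <- (dx2 + dy2 <= nl_r^2) & nucleus

    # heterochromatin: top-k pixels of a rim-biased smoothed noise field
    field <- gaussian_blur(matrix(stats::rnorm(prod(shape)), shape[1L]),
                            sigma = blob_sigma)
    field <- (field - mean(field)) / stats::sd(field)
    score <- field + rim_bias * u
    eligible <- nucleus & !nucleolus
    k <- min(round(fraction * n_nuc), sum(eligible))
    het <- matrix(FALSE, shape[1L], shape[2L])
    if (k > 0) {
      sc <- score[eligible]
      thr <- sort(sc, decreasing = TRUE)[k]
      sel <- eligible & (score >= thr)
      # resolve ties at the threshold so the count is exact
      if (sum(sel) > k) {
        idx <- which(sel)
        drop <- idx[score[idx] == thr][seq_len(sum(sel) - k)]
        sel[drop] <- FALSE
      }
      het <- sel
    }

    labels <- matrix(em_classes[["background"]], shape[1L], shape[2L])
    labels[nucleus] <- em_classes[["euchromatin"]]
    labels[nucleolus] <- em_classes[["nucleolus"]]
    labels[het] <- em_classes[["heterochromatin"]]

    img <- matrix(intensities[["background"]], shape[1L], shape[2L])
    img[labels == em_classes[["euchromatin"]]] <- intensities[["euchromatin"]]
    img[labels == em_classes[["nucleolus"]]] <- intensities[["nucleolus"]]
    img[labels == em_classes[["heterochromatin"]]] <- intensities[["heterochromatin"]]
    img <- gaussian_blur(img, 0.7)
    img <- img + matrix(stats::rnorm(prod(shape), sd = noise_sd), shape[1L])

    structure(
      list(image = img,
           class_map = new_class_map(labels, nucleus),
           nucleus_mask = nucleus,
           nucleolus_mask = nucleolus,
           fraction = sum(het) / n_nuc),
      class = "em_synthetic")
  })
}

#' @export
print.em_synthetic <- function(x, ...) {
  cat(sprintf("<em_synthetic> %d x %d px, ground-truth heterochromatin fraction %.3f\n",
              nrow(x$image), ncol(x$image), x$fraction))
  invisible(x)
}

new_class_map <- function(labels, nucleus_mask = NULL) {
  structure(list(labels = labels, nucleus_mask = nucleus_mask),
            class = "class_map")
}

#' @export
print.class_map <- function(x, ...) {
  tab <- table(factor(x$labels, levels = em_classes,
                      labels = names(em_classes)))
  cat("<class_map>", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

# Derive a nucleus mask by smoothing + Otsu threshold (nucleus is darker),
# hole filling and largest-connected-component selection. Returns an
# all-FALSE mask when no convincing dark region exists.
derive_nucleus_mask <- function(image, min_area_frac = 0.05) {
  sm <- gaussian_blur(image, 2)
  rng <- range(sm)
  if (diff(rng) == 0) return(matrix(FALSE, nrow(image), ncol(image)))
  norm <- (sm - rng[1L]) / diff(rng)
  thr <- EBImage::otsu(norm)
  dark <- norm < thr
  # reject threshold splits that only carve noise (weak separation)
  if (mean(sm[!dark]) - mean(sm[dark]) < 3 * stats::sd(sm[dark])) {
    return(matrix(FALSE, nrow(image), ncol(image)))
  }
  lab <- EBImage::bwlabel(dark)
  if (max(lab) == 0) return(matrix(FALSE, nrow(image), ncol(image)))
  sizes <- tabulate(lab[lab > 0])
  comp <- lab == which.max(sizes)
  comp <- EBImage::fillHull(comp) > 0
  if (sum(comp) < min_area_frac * length(image)) {
    return(matrix(FALSE, nrow(image), ncol(image)))
  }
  comp
}

#' Four-class segmentation of an EM nucleus image
#'
#' Clusters pixels into four groups on a small feature vector (raw
#' intensity, Gaussian-smoothed intensity at two scales, local standard
#' deviation) by k-means with deterministic, proportion-robust
#' initialization at four intensity landmarks: the mean of the darkest 2%
#' of nuclear pixels (heterochromatin), the nuclear median (euchromatin),
#' the midpoint of those two (nucleolus-level gray), and the extranuclear
#' median (background). Clusters are then mapped to classes by intensity and
#' spatial rules: the lightest outside-dominant cluster is background; the
#' darkest remaining cluster is heterochromatin; within the
#' dark-intermediate cluster, connected components of at least
#' `min_nucleolus_px` pixels are nucleolus while the thin remainder —
#' blurred patch rims, not compact organelles — is split between
#' heterochromatin and euchromatin at their intensity midpoint; everything
#' else inside the nucleus is euchromatin, and everything outside the
#' nucleus mask is background. Because the cluster-to-class mapping is
#' computed from cluster statistics, relabelling clusters cannot change the
#' result.
#'
#' @param image Numeric matrix (grayscale EM image).
#' @param nucleus_mask Optional logical nucleus mask; derived by smoothing +
#'   Otsu threshold when absent.
#' @param nucleolus_mask Optional logical mask forcing the nucleolus class.
#' @param min_nucleolus_px Minimum connected-component size for
#'   dark-intermediate pixels to count as nucleolus.
#' @return A `class_map` (integer labels per [em_classes]).
#' @export
segment_classes <- function(image, nucleus_mask = NULL, nucleolus_mask = NULL,
                            min_nucleolus_px = 150L) {
  if (!is.matrix(image) || !all(is.finite(image))) {
    stop_param("`image` must be a finite numeric matrix")
  }
  if (stats::sd(image) == 0) {
    stop_param("segmentation error: blank (constant) image")
  }
  if (is.null(nucleus_mask)) nucleus_mask <- derive_nucleus_mask(image)
  if (sum(nucleus_mask) == 0L) {
    return(new_class_map(matrix(em_classes[["background"]],
                                nrow(image), ncol(image)),
                         nucleus_mask))
  }

  g1 <- gaussian_blur(image, 1)
  g2 <- gaussian_blur(image, 2)
  loc_sd <- sqrt(pmax(gaussian_blur(image^2, 2) -
                        gaussian_blur(image, 2)^2, 0))
  feats <- cbind(raw = as.vector(image), g1 = as.vector(g1),
                 g2 = as.vector(g2), lsd = as.vector(loc_sd))

  inside <- as.vector(nucleus_mask)
  vin <- feats[inside, "raw"]
  vout <- feats[!inside, "raw"]
  dark <- mean(vin[vin <= stats::quantile(vin, 0.02)])
  landmarks <- c(dark,
                 (dark + stats::median(vin)) / 2,
                 stats::median(vin),
                 if (length(vout)) stats::median(vout) else max(feats[, "raw"]))
  centers <- t(vapply(landmarks, function(q) {
    idx <- order(abs(feats[, "raw"] - q))[seq_len(min(200L, nrow(feats)))]
    colMeans(feats[idx, , drop = FALSE])
  }, numeric(ncol(feats))))
  if (any(duplicated(round(centers, 10)))) {
    centers <- centers + seq_len(nrow(centers)) * 1e-6
  }
  km <- stats::kmeans(feats, centers = centers, iter.max = 100,
                      algorithm = "Lloyd")
  cl <- matrix(km$cluster, nrow(image), ncol(image))

  present <- sort(unique(km$cluster))
  cl_means <- vapply(present, function(j) mean(image[cl == j]), 0)
  outside_share <- vapply(present, function(j)
    sum(cl == j & !nucleus_mask) / sum(cl == j), 0)

  bg_cand <- which(outside_share > 0.5)
  bg_i <- if (length(bg_cand)) bg_cand[which.max(cl_means[bg_cand])] else
    which.max(cl_means)
  rest_i <- setdiff(seq_along(present), bg_i)
  rest_i <- rest_i[order(cl_means[rest_i])]  # darkest first
  het_cl <- present[rest_i[1L]]
  eu_mean <- if (length(rest_i) >= 2L) cl_means[rest_i[length(rest_i)]] else
    cl_means[rest_i[1L]]

  labels <- matrix(em_classes[["euchromatin"]], nrow(image), ncol(image))
  labels[cl == het_cl] <- em_classes[["heterochromatin"]]
  if (length(rest_i) >= 3L) {
    # dark-intermediate cluster: compact components are nucleolus, thin
    # remainder (blurred patch rims) splits at the het/eu intensity midpoint
    for (i in rest_i[-c(1L, length(rest_i))]) {
      j <- present[i]
      clus <- cl == j & nucleus_mask
      comp <- EBImage::bwlabel(clus)
      keep <- which(tabulate(comp[comp > 0]) >= min_nucleolus_px)
      solid <- matrix(comp %in% keep, nrow(image)) & clus
      labels[solid] <- em_classes[["nucleolus"]]
      ribbon <- clus & !solid
      mid <- (cl_means[rest_i[1L]] + eu_mean) / 2
      labels[ribbon & image < mid] <- em_classes[["heterochromatin"]]
    }
  }

  labels[!nucleus_mask] <- em_classes[["background"]]
  if (!is.null(nucleolus_mask)) {
    labels[nucleolus_mask & nucleus_mask] <- em_classes[["nucleolus"]]
  }
  new_class_map(labels, nucleus_mask)
}

#' Binary heterochromatin mask from a class map
#'
#' @param classmap A `class_map`.
#' @return Logical matrix, `TRUE` exactly where the class is heterochromatin.
#' @export
heterochromatin_mask <- function(classmap) {
  stopifnot(inherits(classmap, "class_map"))
  classmap$labels == em_classes[["heterochromatin"]]
}

#' Heterochromatin area fraction of the nucleus
#'
#' Fraction of nuclear pixels labelled heterochromatin. The denominator is
#' the whole nuclear area including the nucleolus by default; pass a
#' nucleolus mask with `exclude_nucleolus = TRUE` to remove it.
#'
#' @param binary Logical heterochromatin mask.
#' @param nucleus_mask Logical nucleus mask (non-empty).
#' @param nucleolus_mask Optional logical nucleolus mask.
#' @param exclude_nucleolus Remove the nucleolus from the denominator.
#' @return Object of class `chromatin_stats`: `nucleus_area_px`,
#'   `heterochromatin_area_px`, `fraction`.
#' @export
heterochromatin_fraction <- function(binary, nucleus_mask,
                                     nucleolus_mask = NULL,
                                     exclude_nucleolus = FALSE) {
  if (!is.logical(binary) || !is.logical(nucleus_mask) ||
      !identical(dim(binary), dim(nucleus_mask))) {
    stop_param("`binary` and `nucleus_mask` must be logical matrices of equal shape")
  }
  denom_mask <- nucleus_mask
  if (exclude_nucleolus) {
    if (is.null(nucleolus_mask)) {
      stop_param("`exclude_nucleolus = TRUE` requires `nucleolus_mask`")
    }
    denom_mask <- nucleus_mask & !nucleolus_mask
  }
  n_nuc <- sum(denom_mask)
  if (n_nuc == 0L) stop_param("empty nucleus mask")
  n_het <- sum(binary & denom_mask)
  structure(list(nucleus_area_px = n_nuc,
                 heterochromatin_area_px = n_het,
                 fraction = n_het / n_nuc),
            class = "chromatin_stats")
}

#' @export
print.chromatin_stats <- function(x, ...) {
  cat(sprintf("<chromatin_stats> %d / %d px heterochromatin (fraction %.3f)\n",
              x$heterochromatin_area_px, x$nucleus_area_px, x$fraction))
  invisible(x)
}

#' End-to-end heterochromatin measurement of one image
#'
#' Segments an EM image and measures the heterochromatin fraction.
#'
#' @inheritParams segment_classes
#' @inheritParams heterochromatin_fraction
#' @return A `chromatin_stats`.
#' @export
measure_chromatin <- function(image, nucleus_mask = NULL,
                              nucleolus_mask = NULL,
                              exclude_nucleolus = FALSE,
                              min_nucleolus_px = 150L) {
  cm <- segment_classes(image, nucleus_mask, nucleolus_mask,
                        min_nucleolus_px)
  nuc <- if (is.null(nucleus_mask)) cm$nucleus_mask else nucleus_mask
  if (exclude_nucleolus && is.null(nucleolus_mask)) {
    nucleolus_mask <- cm$labels == em_classes[["nucleolus"]]
  }
  heterochromatin_fraction(heterochromatin_mask(cm), nuc,
                           nucleolus_mask, exclude_nucleolus)
}
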