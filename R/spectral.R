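#' @name spectral
#' @title Radiometric calibration and vegetation-index features
#' @description
#' Helpers converting raw multispectral digital numbers (DN) to surface
#' reflectance (SR) via calibration panels, deriving the NIR band from
#' quantum-efficiency coefficients for the single-panel protocol, computing
#' vegetation indices (NDVI, NDRE1, GNDVI-based canopy cover), and
#' aggregating pixel samples into per-plot band means. The full per-plot
#' feature set `H` has 11 entries (8 calibrated bands + NDRE1 + NDVI +
#' CanopyCover); its index-only subset `I` has 3 (CanopyCover, NDRE1, NDVI).
NULL

# fixed 8-band vocabulary of the quad multispectral sensor (450-970 nm)
BAND_NAMES <- c("Blue", "Green", "Red", "RE1", "RE2", "B900", "B975", "NIR")

# wavelength-to-band mapping used by the index formulas: R800 -> NIR,
# R680 -> Red, R700 -> RE1; configurable through compute_indices().
DEFAULT_BAND_MAP <- c(R800 = "NIR", R680 = "Red", R700 = "RE1",
                      Green = "Green")

H_NAMES <- c(BAND_NAMES, "NDRE1", "NDVI", "CanopyCover")
I_NAMES <- c("CanopyCover", "NDRE1", "NDVI")

#' Fit a per-band radiometric calibration line
#'
#' Ordinary least squares of known panel reflectance on observed digital
#' numbers: SR = DN x slope + intercept. The slope must come out positive
#' (brighter panels yield larger DN); a non-positive slope signals a
#' degenerate panel set.
#'
#' @param panel_dn digital numbers observed over the calibration panels.
#' @param panel_reflectance known panel reflectances (same length).
#' @return list with `slope`, `intercept`, `r2`.
#' @export
fit_calibration <- function(panel_dn, panel_reflectance) {
  stopifnot(length(panel_dn) == length(panel_reflectance),
            length(panel_dn) >= 2L)
  if (length(unique(panel_dn)) < 2L) {
    stop("calibration panels have identical DN: singular fit")
  }
  fit <- stats::lm(panel_reflectance ~ panel_dn)
  slope <- unname(stats::coef(fit)[2L])
  # slope must be meaningfully positive: a flat panel response (reflectance
  # not increasing with DN over the panel range) cannot calibrate anything
  if (!is.finite(slope) || slope * diff(range(panel_dn)) <= 1e-10) {
    stop("calibration slope must be positive; got ", format(slope))
  }
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((panel_reflectance - mean(panel_reflectance))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  list(slope = slope, intercept = unname(stats::coef(fit)[1L]), r2 = r2)
}

#' Apply a calibration model to digital numbers
#'
#' SR = DN x slope + intercept, floored at zero (reflectance cannot be
#' negative).
#'
#' @param dn numeric digital numbers.
#' @param model list with `slope` and `intercept` (see [fit_calibration()]).
#' @return reflectance values.
#' @export
apply_calibration <- function(dn, model) {
  pmax(dn * model$slope + model$intercept, 0)
}

#' Derive NIR reflectance from blue and red (single-panel 2019 protocol)
#'
#' NIR = 2.921 x Blue - 0.754 x Red, from the sensor's quantum-efficiency
#' coefficients; when `normalize = TRUE` (the index-computation path) the
#' result is divided by the normalization coefficient 3.07. Negative values
#' are floored at zero.
#'
#' @param blue,red calibrated reflectance values.
#' @param normalize divide by 3.07 (used when feeding index formulas).
#' @return NIR values.
#' @export
derive_nir_2019 <- function(blue, red, normalize = FALSE) {
  nir <- 2.921 * blue - 0.754 * red
  if (normalize) nir <- nir / 3.07
  pmax(nir, 0)
}

#' Vegetation indices and the H / I feature vectors for one plot
#'
#' NDVI = (R800 - R680)/(R800 + R680) and NDRE1 = (R800 - R700)/(R800 +
#' R700) are computed from plot-mean reflectance (per-pixel computation then
#' averaging is available via `per_pixel_indices`). Canopy cover is the mean
#' over pixels of GNDVI = (NIR - Green)/(NIR + Green); an alternative
#' thresholded variant (fraction of pixels with GNDVI > `threshold`) can be
#' selected with `canopy = "threshold"`.
#'
#' @param plot_bands named numeric vector of the 8 plot-mean band
#'   reflectances.
#' @param pixel_bands optional pixels x bands matrix for the same plot (needed
#'   for canopy cover; falls back to `plot_bands` treated as one pixel).
#' @param band_map named character vector mapping formula wavelengths
#'   (R800, R680, R700, Green) to band names.
#' @param canopy `"mean_gndvi"` (printed formula) or `"threshold"`.
#' @param threshold GNDVI cutoff for the threshold variant.
#' @param per_pixel_indices compute NDVI/NDRE1 per pixel and average, instead
#'   of from plot-mean bands.
#' @return list with `H` (11 named values) and `I` (3 named values).
#' @export
compute_indices <- function(plot_bands, pixel_bands = NULL,
                            band_map = DEFAULT_BAND_MAP,
                            canopy = c("mean_gndvi", "threshold"),
                            threshold = 0.5,
                            per_pixel_indices = FALSE) {
  canopy <- match.arg(canopy)
  stopifnot(all(BAND_NAMES %in% names(plot_bands)))
  if (is.null(pixel_bands)) {
    pixel_bands <- matrix(plot_bands[BAND_NAMES], nrow = 1L,
                          dimnames = list(NULL, BAND_NAMES))
  }
  nd <- function(a, b) {
    den <- a + b
    if (any(den == 0)) {
      stop("undefined index: zero band-sum denominator")
    }
    (a - b) / den
  }
  if (per_pixel_indices) {
    ndvi  <- mean(nd(pixel_bands[, band_map[["R800"]]],
                     pixel_bands[, band_map[["R680"]]]))
    ndre1 <- mean(nd(pixel_bands[, band_map[["R800"]]],
                     pixel_bands[, band_map[["R700"]]]))
  } else {
    ndvi  <- nd(plot_bands[[band_map[["R800"]]]],
                plot_bands[[band_map[["R680"]]]])
    ndre1 <- nd(plot_bands[[band_map[["R800"]]]],
                plot_bands[[band_map[["R700"]]]])
  }
  gndvi <- nd(pixel_bands[, band_map[["R800"]]],
              pixel_bands[, band_map[["Green"]]])
  cover <- if (canopy == "mean_gndvi") mean(gndvi) else
    mean(gndvi > threshold)

  h <- c(plot_bands[BAND_NAMES],
         NDRE1 = unname(ndre1), NDVI = unname(ndvi),
         CanopyCover = unname(cover))
  names(h) <- H_NAMES
  list(H = h, I = h[I_NAMES])
}

#' Aggregate pixel samples to per-plot band means
#'
#' @param pixel_table data.frame with a `plot_id` column and one numeric
#'   column per band.
#' @param bands band columns to aggregate (default all 8).
#' @return data.frame, one row per plot: `plot_id`, `n_pixels`, band means.
#' @export
aggregate_pixels <- function(pixel_table, bands = BAND_NAMES) {
  stopifnot("plot_id" %in% names(pixel_table),
            all(bands %in% names(pixel_table)))
  if (nrow(pixel_table) == 0L) stop("empty pixel table")
  sp <- split(pixel_table[, bands, drop = FALSE], pixel_table$plot_id)
  if (any(vapply(sp, nrow, 0L) == 0L)) stop("plot with zero pixels")
  means <- t(vapply(sp, colMeans, numeric(length(bands))))
  out <- data.frame(plot_id = names(sp),
                    n_pixels = vapply(sp, nrow, 0L),
                    means, row.names = NULL, check.names = FALSE)
  out
}

#' Full spectral feature pipeline: pixels + panels to per-cell H and I
#'
#' Calibrates pixel digital numbers band by band from the panel table
#' (`mode = "panel"`), or calibrates Blue/Green/Red/RE1/RE2 and derives
#' NIR = 2.921 Blue - 0.754 Red with the 3.07 normalization
#' (`mode = "single2019"`, B900/B975 calibrated from their panels when
#' present), computes indices per plot, and averages plot features per
#' line-by-environment cell using the plot table's (line, env) keys.
#'
#' @param pixel_table data.frame: `plot_id` plus 8 DN band columns.
#' @param panel_table data.frame: `band`, `dn`, `reflectance`.
#' @param plot_table data.frame with `plot_id`, `line`, `env`.
#' @param mode calibration protocol.
#' @param ... passed to [compute_indices()].
#' @return data.frame, one row per line-by-environment cell: `line`, `env`,
#'   the 11 `H` columns and (as a sub-vector of those) the 3 `I` columns;
#'   attribute `"calibration"` records the fitted per-band models.
#' @export
build_spectral_features <- function(pixel_table, panel_table, plot_table,
                                    mode = c("panel", "single2019"), ...) {
  mode <- match.arg(mode)
  cal_bands <- if (mode == "panel") BAND_NAMES else
    c("Blue", "Green", "Red", "RE1", "RE2", "B900", "B975")
  models <- lapply(cal_bands, function(b) {
    pb <- panel_table[panel_table$band == b, , drop = FALSE]
    fit_calibration(pb$dn, pb$reflectance)
  })
  names(models) <- cal_bands

  refl <- pixel_table
  for (b in cal_bands) refl[[b]] <- apply_calibration(pixel_table[[b]],
                                                      models[[b]])
  if (mode == "single2019") {
    refl[["NIR"]] <- derive_nir_2019(refl$Blue, refl$Red, normalize = TRUE)
  }

  plots <- unique(plot_table[, c("plot_id", "line", "env")])
  feats <- lapply(split(refl, refl$plot_id), function(px) {
    pm <- colMeans(px[, BAND_NAMES, drop = FALSE])
    compute_indices(pm, as.matrix(px[, BAND_NAMES, drop = FALSE]), ...)$H
  })
  fmat <- do.call(rbind, feats)
  idx <- match(rownames(fmat), plots$plot_id)
  if (anyNA(idx)) stop("pixel plot_id(s) missing from plot table")
  df <- data.frame(line = plots$line[idx], env = plots$env[idx],
                   fmat, row.names = NULL, check.names = FALSE)
  agg <- stats::aggregate(df[, H_NAMES], by = df[, c("line", "env")], mean)
  structure(agg, calibration = models)
}
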