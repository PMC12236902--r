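# Thermal frames are represented as numeric matrices of 8-bit gray levels
# (0..255), image row = matrix row, origin top-left, 0-based pixel
# coordinates in the ground truth and spot records.

#' Specify ground-truth spots for a synthetic thermal frame
#'
#' @param cx,cy ellipse centers (0-based pixel column / row).
#' @param rx,ry ellipse semi-axes in pixels (column / row direction).
#' @param klass programmed class per spot: `"void"`, `"leak"` or `"mark"`.
#' @param t_appear_s appearance time of each spot, seconds.
#' @return data.frame of spot specifications.
#' @export
spot_spec <- function(cx, cy, rx, ry = rx, klass = "void",
                      t_appear_s = 0) {
  data.frame(cx = cx, cy = cy, rx = rx, ry = ry,
             klass = rep_len(klass, length(cx)),
             t_appear_s = rep_len(t_appear_s, length(cx)))
}

#' Simulate a thermal camera frame of urine spots on filter paper
#'
#' Cool background, warm elliptical urine spots, and a bright rectangular
#' 10 cm2 reflecting template of exactly known pixel count. Spots are
#' rasterized by pixel-center-inside-ellipse, and the ground truth records
#' the exact pixel area of every region plus the volume assigned through the
#' linear calibration curve (the same curve the analyzer applies, so
#' recovery is closed).
#'
#' @param spots data.frame from [spot_spec()]; may have zero rows.
#' @param nrow_px,ncol_px frame size in pixels.
#' @param template_area_cm2 known area of the template (cm2).
#' @param template_px_w,template_px_h template rectangle size in pixels; its
#'   pixel count divided by `template_area_cm2` defines the true
#'   pixels-per-cm2 scale of the frame.
#' @param bg_level,spot_level,template_level mean 8-bit gray levels.
#' @param noise_sd Gaussian pixel noise SD (gray levels).
#' @param volume_slope_ul_per_cm2,volume_intercept_ul calibration curve used
#'   to assign ground-truth volumes.
#' @param seed RNG seed.
#' @return list with `image` (numeric matrix, 0..255) and `truth`
#'   (data.frame: one row per spot plus one `template` row, with exact
#'   `area_px`, derived `area_cm2`, assigned `volume_ul`, `klass`,
#'   centroids, and the scale `px_per_cm2`).
#' @export
simulate_thermal_frame <- function(spots = spot_spec(numeric(0), numeric(0),
                                                     numeric(0)),
                                   nrow_px = 240, ncol_px = 320,
                                   template_area_cm2 = 10,
                                   template_px_w = 50, template_px_h = 40,
                                   bg_level = 40, spot_level = 180,
                                   template_level = 230, noise_sd = 2,
                                   volume_slope_ul_per_cm2 = 50,
                                   volume_intercept_ul = 0,
                                   seed = 1L) {
  with_seed(seed, {
    img <- matrix(bg_level, nrow_px, ncol_px)
    # template in the top-left margin
    tr0 <- 6L; tc0 <- 6L
    tr <- tr0:(tr0 + template_px_h - 1L)
    tc <- tc0:(tc0 + template_px_w - 1L)
    img[tr, tc] <- template_level
    template_px <- as.integer(template_px_w * template_px_h)
    px_per_cm2 <- template_px / template_area_cm2

    rowg <- matrix(seq_len(nrow_px) - 1, nrow_px, ncol_px)        # y, 0-based
    colg <- matrix(rep(seq_len(ncol_px) - 1, each = nrow_px), nrow_px)  # x
    tmask <- matrix(FALSE, nrow_px, ncol_px); tmask[tr, tc] <- TRUE

    truth <- data.frame(spot_id = character(0), klass = character(0),
                        cx = numeric(0), cy = numeric(0),
                        area_px = integer(0), area_cm2 = numeric(0),
                        volume_ul = numeric(0), t_appear_s = numeric(0))
    for (k in seq_len(nrow(spots))) {
      s <- spots[k, ]
      if (s$cx - s$rx < 0 || s$cx + s$rx > ncol_px - 1 ||
          s$cy - s$ry < 0 || s$cy + s$ry > nrow_px - 1)
        stop(sprintf("simulate_thermal_frame: spot %d out of frame", k))
      mask <- ((colg - s$cx) / s$rx)^2 + ((rowg - s$cy) / s$ry)^2 <= 1
      if (any(mask & tmask))
        stop(sprintf("simulate_thermal_frame: spot %d overlaps the template", k))
      img[mask] <- spot_level
      area_px <- sum(mask)
      area_cm2 <- area_px / px_per_cm2
      truth <- rbind(truth, data.frame(
        spot_id = sprintf("spot%02d", k), klass = s$klass,
        cx = s$cx, cy = s$cy, area_px = area_px, area_cm2 = area_cm2,
        volume_ul = pmax(0, volume_slope_ul_per_cm2 * area_cm2 +
                           volume_intercept_ul),
        t_appear_s = s$t_appear_s))
    }
    truth <- rbind(truth, data.frame(
      spot_id = "template", klass = "template",
      cx = tc0 - 1 + (template_px_w - 1) / 2,
      cy = tr0 - 1 + (template_px_h - 1) / 2,
      area_px = template_px, area_cm2 = template_area_cm2,
      volume_ul = NA_real_, t_appear_s = 0))
    if (noise_sd > 0)
      img <- img + matrix(rnorm(length(img), 0, noise_sd), nrow_px)
    img[] <- pmin(255, pmax(0, img))
    list(image = img, truth = truth, px_per_cm2 = px_per_cm2)
  })
}

#' Write a grayscale image matrix to PNG or TIFF
#' @param img numeric matrix of 8-bit gray levels (0..255).
#' @param path output path ending in `.png` or `.tif`/`.tiff`.
#' @return `path`, invisibly.
#' @export
write_gray_image <- function(img, path) {
  scaled <- img / 255
  scaled[] <- pmin(1, pmax(0, scaled))
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::writePNG(scaled, path)
  } else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    tiff::writeTIFF(scaled, path, bits.per.sample = 16L)
  } else stop("write_gray_image: path must end in .png or .tif(f)")
  invisible(path)
}

#' Read a grayscale PNG or TIFF image as an 8-bit-level matrix
#' @param path image path.
#' @return numeric matrix of gray levels in 0..255 (16-bit inputs are
#'   rescaled onto the 8-bit range).
#' @export
read_gray_image <- function(path) {
  a <- if (grepl("\\.png$", path, ignore.case = TRUE)) png::readPNG(path)
  else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) tiff::readTIFF(path)
  else stop("read_gray_image: path must end in .png or .tif(f)")
  if (length(dim(a)) == 3L) a <- a[, , 1]  # first channel of gray-written RGB
  a * 255
}
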