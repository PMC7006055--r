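# RGB <-> HSL conversions (vectorized, channels in [0, 1], hue in degrees).
# The enhancement recipe is specified in hue-saturation-lightness space;
# grDevices only provides HSV, so the standard HSL formulas are implemented
# here and unit-tested against round-trips.
rgb_to_hsl <- function(r, g, b) {
  mx <- pmax(r, g, b); mn <- pmin(r, g, b)
  l <- (mx + mn) / 2
  d <- mx - mn
  s <- ifelse(d == 0, 0, d / (1 - abs(2 * l - 1)))
  h <- numeric(length(r))
  nz <- d > 0
  hr <- nz & mx == r
  hg <- nz & !hr & mx == g
  hb <- nz & !hr & !hg
  h[hr] <- 60 * (((g[hr] - b[hr]) / d[hr]) %% 6)
  h[hg] <- 60 * ((b[hg] - r[hg]) / d[hg] + 2)
  h[hb] <- 60 * ((r[hb] - g[hb]) / d[hb] + 4)
  list(h = h, s = pmin(s, 1), l = l)
}

hsl_to_rgb <- function(h, s, l) {
  c_ <- (1 - abs(2 * l - 1)) * s
  x <- c_ * (1 - abs((h / 60) %% 2 - 1))
  m <- l - c_ / 2
  seg <- floor((h %% 360) / 60)
  r <- g <- b <- numeric(length(h))
  set <- function(idx, rr, gg, bb) {
    r[idx] <<- rr[idx]; g[idx] <<- gg[idx]; b[idx] <<- bb[idx]
  }
  zero <- numeric(length(h))
  set(seg == 0, c_, x, zero)
  set(seg == 1, x, c_, zero)
  set(seg == 2, zero, c_, x)
  set(seg == 3, zero, x, c_)
  set(seg == 4, x, zero, c_)
  set(seg == 5, c_, zero, x)
  list(r = pmin(pmax(r + m, 0), 1),
       g = pmin(pmax(g + m, 0), 1),
       b = pmin(pmax(b + m, 0), 1))
}

#' Remove the slide background from a histology image
#'
#' Emulates a magic-wand background selection: pixels whose color is within
#' `tolerance` of the dominant border color and that are connected (4-way)
#' to the image border are flagged as background, set to pure white, and
#' excluded from downstream pixel counts. Interior pixels of the same color
#' are never flagged. If no background is found the image is unchanged.
#'
#' @param image h x w x 3 RGB array in \[0, 1\].
#' @param tolerance Per-channel color tolerance (default 0.02, i.e. ~5/255).
#' @param min_background_luminance Minimum luminance (0-1) for the border
#'   color to be treated as empty slide background (default 0.9); an image
#'   whose border is tissue is left unchanged.
#' @return List: `image` (background pixels whitened) and `excluded`
#'   (logical h x w mask of removed background pixels).
#' @export
remove_background <- function(image, tolerance = 0.02,
                              min_background_luminance = 0.9) {
  stopifnot(length(dim(image)) == 3L, dim(image)[3] == 3L)
  h <- dim(image)[1]; w <- dim(image)[2]
  border <- rbind(cbind(1, seq_len(w)), cbind(h, seq_len(w)),
                  cbind(seq_len(h), 1), cbind(seq_len(h), w))
  border_cols <- sapply(1:3, function(ch) image[, , ch][border])
  key <- apply(round(border_cols * 255), 1, paste, collapse = ",")
  mode_key <- names(sort(table(key), decreasing = TRUE))[1]
  mode_col <- as.numeric(strsplit(mode_key, ",")[[1]]) / 255
  if (sum(c(0.299, 0.587, 0.114) * mode_col) < min_background_luminance) {
    # border is tissue, not empty slide: nothing to remove
    return(list(image = image, excluded = matrix(FALSE, h, w)))
  }

  candidate <- abs(image[, , 1] - mode_col[1]) <= tolerance &
    abs(image[, , 2] - mode_col[2]) <= tolerance &
    abs(image[, , 3] - mode_col[3]) <= tolerance
  if (!any(candidate[border])) {
    return(list(image = image, excluded = matrix(FALSE, h, w)))
  }
  labels <- EBImage::bwlabel(candidate)
  border_labels <- setdiff(unique(labels[border]), 0)
  excluded <- matrix(labels %in% border_labels, h, w)

  out <- image
  for (ch in 1:3) {
    plane <- out[, , ch]
    plane[excluded] <- 1
    out[, , ch] <- plane
  }
  list(image = out, excluded = excluded)
}

#' Color enhancement isolating dark red/purple material
#'
#' Deterministic re-expression of the interactive enhancement recipe used
#' for quantifying erythrocyte pools in H&E sections, defined in
#' hue-saturation-lightness space:
#' red-band pixels (hue in \[315, 45) degrees) have their saturation doubled
#' (clipped at 1); blue-band pixels (hue in \[195, 255)) are forced to white
#' (saturation 0, lightness 1); then a global per-channel brightness/contrast
#' map `v' = clip(2 (v - 128) + 128 + 150)` (8-bit scale) polarizes the
#' image so that only the dark red/purple material stays below the
#' luminance threshold.
#'
#' @param image h x w x 3 RGB array in \[0, 1\].
#' @return Enhanced RGB array, same shape.
#' @export
enhance_inflammation <- function(image) {
  stopifnot(length(dim(image)) == 3L, dim(image)[3] == 3L)
  dm <- dim(image)
  hsl <- rgb_to_hsl(as.vector(image[, , 1]), as.vector(image[, , 2]),
                    as.vector(image[, , 3]))
  red_band <- hsl$h >= 315 | hsl$h < 45
  blue_band <- hsl$h >= 195 & hsl$h < 255
  s <- hsl$s; l <- hsl$l
  s[red_band] <- pmin(s[red_band] * 2, 1)
  s[blue_band] <- 0
  l[blue_band] <- 1
  rgb <- hsl_to_rgb(hsl$h, s, l)

  bc <- function(v) pmin(pmax((2 * (v * 255 - 128) + 128 + 150) / 255, 0), 1)
  out <- array(0, dim = dm)
  out[, , 1] <- bc(matrix(rgb$r, dm[1], dm[2]))
  out[, , 2] <- bc(matrix(rgb$g, dm[1], dm[2]))
  out[, , 3] <- bc(matrix(rgb$b, dm[1], dm[2]))
  out
}

pixel_luminance <- function(image) {
  (0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]) * 255
}

#' Inflammation ratio of one enhanced image
#'
#' Counts non-excluded pixels whose 8-bit luminance (`0.299 R + 0.587 G +
#' 0.114 B`) falls below the threshold — the dark red/purple material
#' isolated by [enhance_inflammation()] — and divides by the total pixel
#' count of the *original, unedited* image.
#'
#' @param enhanced Enhanced RGB array.
#' @param total_pixels Pixel count of the original image (before any
#'   background removal).
#' @param threshold Luminance threshold on the 0-255 scale (default 130).
#' @param excluded Optional logical mask of background pixels to ignore.
#' @return List: `ratio`, `inflamed_pixels`, `total_pixels`.
#' @export
threshold_ratio <- function(enhanced, total_pixels, threshold = 130,
                            excluded = NULL) {
  stopifnot(length(dim(enhanced)) == 3L)
  if (total_pixels <= 0) stop("total_pixels must be positive", call. = FALSE)
  if (threshold < 0 || threshold > 255) {
    stop("threshold must be in [0, 255]", call. = FALSE)
  }
  lum <- pixel_luminance(enhanced)
  inflamed <- lum < threshold
  if (!is.null(excluded)) inflamed <- inflamed & !excluded
  n <- sum(inflamed)
  list(ratio = n / total_pixels, inflamed_pixels = n,
       total_pixels = total_pixels)
}

#' Full lung-inflammation pipeline for one mouse
#'
#' Runs background removal, color enhancement and luminance thresholding on
#' each image (conventionally five per mouse) and averages the per-image
#' inflammation ratios into one representative ratio per mouse.
#'
#' @param images List of RGB arrays in \[0, 1\].
#' @param threshold Luminance threshold (default 130).
#' @param denominator `"total"` (all pixels of the original image; default)
#'   or `"tissue"` (original pixels minus removed background).
#' @return An `inflammation_result`: `per_image_ratios`, `mean_ratio`,
#'   `inflamed_pixel_counts`, `total_pixel_counts`, `denominator`.
#' @export
quantify_inflammation <- function(images, threshold = 130,
                                  denominator = c("total", "tissue")) {
  denominator <- match.arg(denominator)
  if (length(images) == 0) stop("no images supplied", call. = FALSE)
  res <- lapply(images, function(img) {
    total <- prod(dim(img)[1:2])
    bg <- remove_background(img)
    enh <- enhance_inflammation(bg$image)
    denom <- if (denominator == "total") total else total - sum(bg$excluded)
    threshold_ratio(enh, denom, threshold = threshold, excluded = bg$excluded)
  })
  ratios <- vapply(res, `[[`, numeric(1), "ratio")
  structure(list(per_image_ratios = ratios,
                 mean_ratio = mean(ratios),
                 inflamed_pixel_counts = vapply(res, `[[`, numeric(1), "inflamed_pixels"),
                 total_pixel_counts = vapply(res, `[[`, numeric(1), "total_pixels"),
                 denominator = denominator),
            class = "inflammation_result")
}

#' Fold change between two group means
#'
#' @param mean_a,mean_b Group means; `mean_b` (the reference) must be > 0.
#' @return `mean_a / mean_b`.
#' @examples
#' fold_change(3.93, 0.78)  # ~5.04
#' @export
fold_change <- function(mean_a, mean_b) {
  if (!is.numeric(mean_b) || mean_b <= 0) {
    stop("reference mean must be positive", call. = FALSE)
  }
  mean_a / mean_b
}

#' Calibrated distance between two anatomical landmarks
#'
#' Euclidean pixel distance between two mandible cardinal points, scaled to
#' mm using a micrometer imaged in the same session.
#'
#' @param p1,p2 Numeric `(x, y)` landmark positions, px.
#' @param mm_per_pixel Scale, > 0.
#' @return Distance in mm.
#' @examples
#' mandible_distance(c(0, 0), c(3, 4), 1)  # 5
#' @export
mandible_distance <- function(p1, p2, mm_per_pixel) {
  if (!is.numeric(mm_per_pixel) || mm_per_pixel <= 0) {
    stop("mm_per_pixel must be positive", call. = FALSE)
  }
  sqrt(sum((as.numeric(p1) - as.numeric(p2))^2)) * mm_per_pixel
}

#' Write / read an RGB image as PNG
#'
#' @param image h x w x 3 array in \[0, 1\].
#' @param path File path.
#' @return `write_image_png` returns `path` invisibly; `read_image_png`
#'   returns the array (alpha channel dropped if present).
#' @export
write_image_png <- function(image, path) {
  png::writePNG(image, path)
  invisible(path)
}

#' @rdname write_image_png
#' @export
read_image_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L && dim(img)[3] == 4L) img <- img[, , 1:3]
  img
}
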