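#' Split a 24-bit RGB image into channels
#'
#' @param image A height x width x 3 numeric array (8-bit intensities,
#'   0-255): red, green, blue planes in that order. Values in \[0, 1\] (as
#'   returned by PNG readers) are rescaled to 0-255.
#' @return A list of class `multichannel_image` with integer matrices `red`,
#'   `green`, `blue` of identical dimensions.
#' @export
split_channels <- function(image) {
  if (length(dim(image)) != 3L || dim(image)[3] != 3L) {
    abort("`image` must be a height x width x 3 RGB array; grayscale input is not supported.")
  }
  if (max(image) <= 1 && min(image) >= 0) image <- round(image * 255)
  if (min(image) < 0) abort("Intensities must be non-negative.")
  structure(
    list(red = image[, , 1], green = image[, , 2], blue = image[, , 3]),
    class = "multichannel_image"
  )
}

#' Recombine channels into an RGB array
#'
#' Inverse of [split_channels()]; exact round trip.
#'
#' @param channels A `multichannel_image` (or list with `red`, `green`,
#'   `blue` matrices of equal dimensions).
#' @return A height x width x 3 array.
#' @export
combine_channels <- function(channels) {
  with(channels, {
    if (!all(dim(red) == dim(green)) || !all(dim(red) == dim(blue))) {
      abort("All channels must share the same dimensions.")
    }
    array(c(red, green, blue), dim = c(dim(red), 3L))
  })
}

#' Read / write an RGB image as PNG
#'
#' Thin wrappers over the \pkg{png} package keeping the package's 8-bit
#' integer convention. (The original microscopy exports are 24-bit TIFF; PNG
#' carries the same 8-bit-per-channel information losslessly.)
#'
#' @param path File path.
#' @return `read_rgb_image`: a height x width x 3 array of 0-255 integers.
#' @export
read_rgb_image <- function(path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    abort("Reading PNG images needs the 'png' package.")
  }
  a <- png::readPNG(path)
  if (length(dim(a)) != 3L) abort("Grayscale PNG: expected an RGB image.")
  round(a[, , 1:3, drop = FALSE] * 255)
}

#' @rdname read_rgb_image
#' @param image A height x width x 3 array of 0-255 intensities.
#' @export
write_rgb_image <- function(image, path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    abort("Writing PNG images needs the 'png' package.")
  }
  png::writePNG(image / 255, path)
  invisible(path)
}

#' Thresholded Manders colocalization coefficients
#'
#' With constant thresholds `t_green` and `t_red` (strictly greater-than,
#' 8-bit scale) defining the signal masks, computes
#' \itemize{
#'   \item `m1`: fraction of (thresholded) green intensity lying on
#'     red-positive pixels — `sum(green over Gmask & Rmask) / sum(green over
#'     Gmask)`;
#'   \item `m2`: the symmetric red fraction over green-positive pixels;
#'   \item `moc`: the intensity-weighted overlap coefficient
#'     `sum(green*red) / sqrt(sum(green^2) * sum(red^2))` over the union
#'     support `Gmask | Rmask` (pixels below both thresholds, including
#'     both-zero background, never enter).
#' }
#' A coefficient whose denominator mask holds fewer than `min_pixels` pixels
#' is reported `NA` ("not applicable due to very low signal").
#'
#' @param green,red Numeric matrices of equal dimensions (0-255).
#' @param t_green,t_red Channel thresholds within the 8-bit range.
#' @param min_pixels Minimum denominator-mask size for a defined coefficient
#'   (default 10).
#' @param cell_id Optional identifier carried into the result.
#' @return A one-row tibble: `cell_id`, `moc`, `m1`, `m2`, `t_green`,
#'   `t_red`, `n_pixels_analyzed`.
#' @export
manders_coefficients <- function(green, red, t_green, t_red,
                                 min_pixels = 10L, cell_id = NA_character_) {
  if (!all(dim(green) == dim(red))) abort("`green` and `red` must have the same dimensions.")
  stopifnot_scalar_number(t_green, "t_green", 0, 255)
  stopifnot_scalar_number(t_red, "t_red", 0, 255)
  gmask <- green > t_green
  rmask <- red > t_red
  support <- gmask | rmask

  m1 <- if (sum(gmask) < min_pixels) NA_real_ else {
    sum(green[gmask & rmask]) / sum(green[gmask])
  }
  m2 <- if (sum(rmask) < min_pixels) NA_real_ else {
    sum(red[gmask & rmask]) / sum(red[rmask])
  }
  moc <- if (sum(support) < min_pixels) NA_real_ else {
    denom <- sqrt(sum(green[support]^2) * sum(red[support]^2))
    if (denom == 0) NA_real_ else sum(green[support] * red[support]) / denom
  }
  tibble(cell_id = cell_id, moc = moc, m1 = m1, m2 = m2,
         t_green = t_green, t_red = t_red,
         n_pixels_analyzed = sum(support))
}

#' Manders coefficients for a batch of cells at constant thresholds
#'
#' Thresholds are set once per experiment and held constant across all
#' images; this wrapper enforces that by construction.
#'
#' @param images A list of RGB arrays (one cell per image) or
#'   `multichannel_image`s.
#' @param t_green,t_red Constant thresholds for the whole batch.
#' @param green_channel,red_channel Which planes carry the two signals
#'   (defaults `"green"` and `"red"`; use `"blue"` for a nuclear
#'   counterstain comparison).
#' @param min_pixels Passed to [manders_coefficients()].
#' @return A tibble with one row per cell.
#' @export
coloc_batch <- function(images, t_green, t_red,
                        green_channel = "green", red_channel = "red",
                        min_pixels = 10L) {
  purrr::map_dfr(seq_along(images), function(i) {
    img <- images[[i]]
    if (!inherits(img, "multichannel_image")) img <- split_channels(img)
    manders_coefficients(img[[green_channel]], img[[red_channel]],
                         t_green, t_red, min_pixels,
                         cell_id = names(images)[i] %||% sprintf("cell_%02d", i))
  })
}

#' Compare colocalization coefficients between two treatment groups
#'
#' Reports mean, SD and n per group and the exact two-tailed Mann-Whitney
#' p-value (exact for the usual 12-cells-per-condition regime). Two
#' identical constant groups give p = 1 with a note.
#'
#' @param a,b Numeric vectors of per-cell coefficients (NAs dropped).
#' @param labels Length-2 character vector naming the groups.
#' @return A list of class `group_comparison` with `summary` (tibble),
#'   `p_value`, `u_statistic` and `test`.
#' @export
compare_groups <- function(a, b, labels = c("group_a", "group_b")) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (!length(a) || !length(b)) abort("Both groups must contain non-missing values.")
  if (length(unique(c(a, b))) == 1L) {
    inform("Both groups are identical constants; p = 1.")
  }
  res <- mwu_exact_two_tailed(a, b)
  structure(
    list(
      summary = tibble(group = labels,
                       n = c(length(a), length(b)),
                       mean = c(mean(a), mean(b)),
                       sd = c(sd(a), sd(b))),
      p_value = res$p_two_tailed,
      u_statistic = res$u_statistic,
      test = paste0(res$method, if (res$exact) "" else " (approximate)")
    ),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("<group_comparison>\n")
  for (i in seq_len(nrow(x$summary))) {
    cat(sprintf("  %s: %.3f +/- %.3f (n = %d)\n", x$summary$group[i],
                x$summary$mean[i], x$summary$sd[i], x$summary$n[i]))
  }
  cat(sprintf("  %s: p = %.5g\n", x$test, x$p_value))
  invisible(x)
}

#' @rdname compare_groups
#' @param x A `group_comparison` object.
#' @param ... Unused.
#' @export
tidy.group_comparison <- function(x, ...) x$summary

#' @rdname compare_groups
#' @export
glance.group_comparison <- function(x, ...) {
  tibble(u_statistic = x$u_statistic, p_value = x$p_value, test = x$test)
}

#' Simulate confocal-like images with a known colocalized fraction
#'
#' Each synthetic cell carries a red channel of `spot_count` disk-shaped
#' puncta (LC3-like vesicles), a green channel (EGFP-tagged protein) whose
#' supra-threshold intensity is placed so that exactly `overlap_fraction` of
#' it falls on red-positive pixels, and a blue nuclear ellipse. At
#' `noise_sd = 0` the thresholded `m1` of every cell equals the planted
#' fraction up to pixel granularity (1/`n_green_px`).
#'
#' @param n_cells Number of cells (one image each).
#' @param overlap_fraction Planted colocalized green fraction in \[0, 1\].
#' @param spot_count Number of red puncta; must be positive when
#'   `overlap_fraction > 0`.
#' @param noise_sd Gaussian intensity noise (8-bit scale) added to every
#'   channel, clipped to 0-255.
#' @param seed Integer seed; generation is bit-reproducible.
#' @param width,height Image size in pixels (default 96 x 96).
#' @param n_green_px Number of green signal pixels per cell (default 200;
#'   granularity of the achievable overlap fraction).
#' @return A list with `images` (list of RGB arrays), `truth` (tibble:
#'   `cell_id`, `overlap_fraction`, `planted_m1`, `t_green`, `t_red`) and the
#'   thresholds used by the construction (`t_green = t_red = 40`).
#' @export
simulate_coloc_images <- function(n_cells = 12L, overlap_fraction = 0.6,
                                  spot_count = 8L, noise_sd = 0, seed = 1L,
                                  width = 96L, height = 96L,
                                  n_green_px = 200L) {
  stopifnot_scalar_number(overlap_fraction, "overlap_fraction", 0, 1)
  if (spot_count == 0L && overlap_fraction > 0) {
    abort("`spot_count` = 0 leaves nowhere to place overlapping signal.")
  }
  t_green <- 40; t_red <- 40
  radius <- 5L
  with_seed_(seed, {
    images <- vector("list", n_cells)
    planted <- numeric(n_cells)
    for (cell in seq_len(n_cells)) {
      red <- matrix(0, height, width)
      if (spot_count > 0L) {
        centers_r <- sample(seq(radius + 2L, height - radius - 1L), spot_count,
                            replace = TRUE)
        centers_c <- sample(seq(radius + 2L, width - radius - 1L), spot_count,
                            replace = TRUE)
        for (s in seq_len(spot_count)) {
          rr <- (centers_r[s] - radius):(centers_r[s] + radius)
          cc <- (centers_c[s] - radius):(centers_c[s] + radius)
          d2 <- outer((rr - centers_r[s])^2, (cc - centers_c[s])^2, `+`)
          red[rr, cc][d2 <= radius^2] <- 200
        }
      }
      inside <- which(red > t_red)
      outside <- which(red == 0)
      n_in <- round(overlap_fraction * n_green_px)
      n_out <- n_green_px - n_in
      if (n_in > length(inside)) {
        abort("Red puncta area too small for the requested overlap; increase `spot_count`.")
      }
      green <- matrix(0, height, width)
      green[inside[sample.int(length(inside), n_in)]] <- 180
      green[outside[sample.int(length(outside), n_out)]] <- 180
      blue <- matrix(0, height, width)
      rows <- matrix(seq_len(height), height, width)
      cols <- matrix(seq_len(width), height, width, byrow = TRUE)
      blue[((rows - height / 2)^2 / (height / 4)^2 +
              (cols - width / 2)^2 / (width / 3)^2) <= 1] <- 150
      img <- combine_channels(list(red = red, green = green, blue = blue))
      if (noise_sd > 0) {
        img <- img + array(rnorm(length(img), 0, noise_sd), dim = dim(img))
        img <- round(pmin(pmax(img, 0), 255))
      }
      images[[cell]] <- img
      planted[cell] <- n_in / n_green_px
    }
    list(
      images = images,
      truth = tibble(cell_id = sprintf("cell_%02d", seq_len(n_cells)),
                     overlap_fraction = overlap_fraction,
                     planted_m1 = planted,
                     t_green = t_green, t_red = t_red),
      t_green = t_green, t_red = t_red
    )
  })
}
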