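#' Configuration for a simulated shear-flow micrograph
#'
#' Describes one synthetic imaging field: bright elliptical cells (the
#' sheared, adherent RBCs) on a dark background, with known centers, axes
#' and orientations, so the downstream segmentation and elongation
#' measurement can be validated against analytic ground truth.
#'
#' Target elongation ratios come either from `er_values` (recycled to
#' `n_cells`) or from a normal distribution `N(er_mean, er_sd)` truncated
#' below at `er_min` (an ER below 1 is geometrically meaningless: the major
#' axis defines ER). Cells are placed with non-overlapping bounding boxes
#' by rejection sampling, so every ground-truth cell maps to exactly one
#' connected component in the rendered image.
#'
#' @param image_width,image_height field size in pixels.
#' @param n_cells number of cells to place.
#' @param er_values optional numeric vector of target ERs (each `>= 1`),
#'   recycled to `n_cells`; overrides the distribution parameters.
#' @param er_mean,er_sd,er_min truncated-normal parameters for sampled ERs.
#' @param cell_semi_minor_px semi-minor axis of each cell, pixels.
#' @param intensity_fg,intensity_bg foreground/background gray levels
#'   (foreground must exceed background: bright cells on a dark field).
#' @param noise_sd additive Gaussian noise, gray levels; clipped to the
#'   valid range after addition.
#' @param min_separation_px minimum gap enforced between cell bounding
#'   boxes, pixels.
#' @param bit_depth image bit depth; gray values live in
#'   `[0, 2^bit_depth - 1]`.
#' @param seed integer seed making the field reproducible; `NULL` uses the
#'   ambient RNG stream.
#' @return An object of class `image_sim_config`.
#' @seealso [render_field()]
#' @export
image_sim_config <- function(image_width = 512, image_height = 512,
                             n_cells = 50, er_values = NULL,
                             er_mean = 1.6, er_sd = 0.15, er_min = 1.0,
                             cell_semi_minor_px = 10,
                             intensity_fg = 200, intensity_bg = 30,
                             noise_sd = 8, min_separation_px = 2,
                             bit_depth = 8, seed = NULL) {
  cfg <- list(image_width = as.integer(image_width),
              image_height = as.integer(image_height),
              n_cells = as.integer(n_cells), er_values = er_values,
              er_mean = er_mean, er_sd = er_sd, er_min = er_min,
              cell_semi_minor_px = cell_semi_minor_px,
              intensity_fg = intensity_fg, intensity_bg = intensity_bg,
              noise_sd = noise_sd, min_separation_px = min_separation_px,
              bit_depth = as.integer(bit_depth), seed = seed)
  if (cfg$image_width < 8 || cfg$image_height < 8) {
    stop("image must be at least 8 x 8 pixels")
  }
  if (cfg$n_cells < 1) stop("n_cells must be >= 1")
  if (!is.null(er_values) && any(er_values < 1)) {
    stop("all target elongation ratios must be >= 1")
  }
  if (is.null(er_values) && (er_min < 1 || er_sd < 0)) {
    stop("er_min must be >= 1 and er_sd >= 0")
  }
  if (cfg$cell_semi_minor_px < 2) stop("cell_semi_minor_px must be >= 2")
  if (cfg$intensity_fg <= cfg$intensity_bg) {
    stop("intensity_fg must exceed intensity_bg")
  }
  if (cfg$noise_sd < 0) stop("noise_sd must be >= 0")
  gmax <- 2^cfg$bit_depth - 1
  if (cfg$intensity_fg > gmax || cfg$intensity_bg < 0) {
    stop("intensities must lie in [0, 2^bit_depth - 1]")
  }
  structure(cfg, class = "image_sim_config")
}

#' Render a ground-truth field of elliptical cells
#'
#' Draws `n_cells` filled ellipses with uniformly random orientations at
#' rejection-sampled, non-overlapping positions, adds Gaussian noise, and
#' returns both the image and the analytic per-cell truth (center, full
#' axes, orientation, ER). The truth ER is exactly the drawn major/minor
#' axis ratio; the rendered image is the measurement target.
#'
#' @param config an [image_sim_config()].
#' @return A list of class `cfa_field` with elements `image` (numeric
#'   matrix, gray levels, row-major with origin at the top-left) and
#'   `truth` (data.frame: `cell_id`, `cx`, `cy` (0-based pixel coordinates,
#'   x = column), `a_px`, `b_px` (full axes), `theta_rad`, `er`).
#' @examples
#' f <- render_field(image_sim_config(n_cells = 5, seed = 1))
#' f$truth
#' @export
render_field <- function(config) {
  stopifnot(inherits(config, "image_sim_config"))
  with_seed_opt(config$seed, render_field_impl(config))
}

render_field_impl <- function(config) {
  n <- config$n_cells
  b_semi <- config$cell_semi_minor_px
  er <- if (!is.null(config$er_values)) {
    rep_len(config$er_values, n)
  } else {
    rtruncnorm_lower(n, config$er_mean, config$er_sd, config$er_min)
  }
  a_semi <- er * b_semi
  theta <- runif(n, 0, pi)

  # rejection-sample centers with non-overlapping (padded) bounding boxes;
  # half-side = circumscribed radius so any orientation fits the box
  half <- a_semi + config$min_separation_px / 2
  W <- config$image_width; H <- config$image_height
  cx <- numeric(n); cy <- numeric(n)
  for (i in seq_len(n)) {
    if (2 * a_semi[i] + 2 >= min(W, H)) {
      stop("cannot place cells: cell ", i, " does not fit the frame")
    }
    placed <- FALSE
    for (try in seq_len(1000)) {
      x <- runif(1, a_semi[i] + 1, W - a_semi[i] - 2)
      y <- runif(1, a_semi[i] + 1, H - a_semi[i] - 2)
      if (i == 1) { ok <- TRUE } else {
        j <- seq_len(i - 1)
        sep <- half[i] + half[j]
        ok <- all(abs(x - cx[j]) >= sep | abs(y - cy[j]) >= sep)
      }
      if (ok) { cx[i] <- x; cy[i] <- y; placed <- TRUE; break }
    }
    if (!placed) {
      stop("cannot place cells: field too dense after 1000 retries ",
           "(placed ", i - 1, " of ", n, ")")
    }
  }

  img <- matrix(config$intensity_bg, nrow = H, ncol = W)
  for (i in seq_len(n)) {
    r0 <- max(0, floor(cy[i] - a_semi[i])); r1 <- min(H - 1, ceiling(cy[i] + a_semi[i]))
    c0 <- max(0, floor(cx[i] - a_semi[i])); c1 <- min(W - 1, ceiling(cx[i] + a_semi[i]))
    rows <- r0:r1; cols <- c0:c1
    dy <- outer(rows - cy[i], rep(1, length(cols)))
    dx <- outer(rep(1, length(rows)), cols - cx[i])
    u <- (dx * cos(theta[i]) + dy * sin(theta[i])) / a_semi[i]
    v <- (-dx * sin(theta[i]) + dy * cos(theta[i])) / b_semi
    inside <- u^2 + v^2 <= 1
    block <- img[rows + 1, cols + 1]
    block[inside] <- config$intensity_fg
    img[rows + 1, cols + 1] <- block
  }
  if (config$noise_sd > 0) {
    img <- img + matrix(rnorm(H * W, 0, config$noise_sd), H, W)
    img <- pmin(pmax(img, 0), 2^config$bit_depth - 1)
  }
  truth <- data.frame(cell_id = seq_len(n), cx = cx, cy = cy,
                      a_px = 2 * a_semi, b_px = 2 * b_semi,
                      theta_rad = theta, er = er)
  structure(list(image = img, truth = truth, config = config),
            class = "cfa_field")
}

# truncated-normal sampler (lower truncation) by inverse-CDF; exact and
# stable even for truncation points far in the tail
rtruncnorm_lower <- function(n, mean, sd, lower) {
  if (sd == 0) return(rep(max(mean, lower), n))
  p0 <- pnorm(lower, mean, sd)
  qnorm(p0 + runif(n) * (1 - p0), mean, sd)
}

#' Write a rendered field to disk
#'
#' Writes the image as a single-page grayscale TIFF (or PNG) and,
#' optionally, the ground-truth table as CSV.
#'
#' @param field a `cfa_field` from [render_field()].
#' @param image_path output image path; format chosen by `format`.
#' @param truth_path optional CSV path for the truth table.
#' @param format `"tiff"` or `"png"`.
#' @return `image_path`, invisibly.
#' @export
write_field <- function(field, image_path, truth_path = NULL,
                        format = c("tiff", "png")) {
  stopifnot(inherits(field, "cfa_field"))
  format <- match.arg(format)
  gmax <- 2^field$config$bit_depth - 1
  # quantize to integer gray levels first: the writers truncate, so
  # pre-rounding keeps the stored image within half a level of the field
  norm <- round(pmin(pmax(field$image, 0), gmax)) / gmax
  if (format == "tiff") {
    tiff::writeTIFF(norm, image_path, bits.per.sample = 8L)
  } else {
    png::writePNG(norm, image_path)
  }
  if (!is.null(truth_path)) {
    write.csv(field$truth, truth_path, row.names = FALSE)
  }
  invisible(image_path)
}

#' Read a grayscale micrograph
#'
#' Reads a single-channel TIFF or PNG into a numeric gray-level matrix on
#' the 0-255 scale (row-major, origin top-left). Multi-channel images are
#' rejected: the measurement contract is single-channel.
#'
#' @param path image file path (`.tif`, `.tiff` or `.png`).
#' @return A numeric matrix of gray levels.
#' @export
read_cell_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                tif = , tiff = tiff::readTIFF(path),
                png = png::readPNG(path),
                stop("unsupported image format: .", ext))
  if (is.list(img)) img <- img[[1]]
  if (length(dim(img)) == 3 && dim(img)[3] == 1) img <- img[, , 1]
  if (length(dim(img)) != 2) {
    stop("multi-channel image: a single-channel grayscale image is required")
  }
  img * 255
}
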