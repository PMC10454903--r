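#' Segmentation settings for cell fields
#'
#' @param threshold_method `"otsu"` (default) or `"fixed"`.
#' @param fixed_threshold gray level used when `threshold_method = "fixed"`.
#' @param min_area_px,max_area_px area bounds (pixels^2); regions outside
#'   them are flagged, not dropped.
#' @param exclude_border flag regions touching the image border (truncated
#'   shapes bias the elongation ratio). Default `TRUE`.
#' @return An object of class `segmentation_config`.
#' @export
segmentation_config <- function(threshold_method = c("otsu", "fixed"),
                                fixed_threshold = NULL,
                                min_area_px = 50, max_area_px = Inf,
                                exclude_border = TRUE) {
  threshold_method <- match.arg(threshold_method)
  if (threshold_method == "fixed" &&
      (is.null(fixed_threshold) || !is.finite(fixed_threshold))) {
    stop("fixed_threshold must be given for threshold_method = 'fixed'")
  }
  if (min_area_px >= max_area_px) stop("min_area_px must be < max_area_px")
  structure(list(threshold_method = threshold_method,
                 fixed_threshold = fixed_threshold,
                 min_area_px = min_area_px, max_area_px = max_area_px,
                 exclude_border = exclude_border),
            class = "segmentation_config")
}

#' Segment cells in a grayscale field
#'
#' Thresholds the image (Otsu by default), labels 8-connected foreground
#' components, and applies quality control: regions outside the area bounds
#' or touching the border (when `exclude_border`) are returned flagged with
#' `qc_pass = FALSE` and a reason, never dropped silently.
#'
#' @param image 2-D single-channel numeric matrix (gray levels).
#' @param config a [segmentation_config()].
#' @return An object of class `cfa_regions`: list with `labels` (label
#'   matrix), `threshold`, and `regions`, a list of per-region records
#'   (`cell_id`, `coords` — n x 2 matrix of 0-based (row, col) pixel
#'   coordinates —, `area`, `cx`, `cy`, `qc_pass`, `qc_reason`). A blank or
#'   all-background image yields zero regions.
#' @export
segment_cells <- function(image, config = segmentation_config()) {
  if (!is.matrix(image) || !is.numeric(image)) {
    stop("image must be a 2-D single-channel numeric matrix")
  }
  stopifnot(inherits(config, "segmentation_config"))
  thr <- if (config$threshold_method == "fixed") {
    config$fixed_threshold
  } else {
    lo <- min(image); hi <- max(image)
    if (hi - lo < .Machine$double.eps) {
      # flat image: nothing to segment
      return(structure(list(labels = matrix(0L, nrow(image), ncol(image)),
                            threshold = NA_real_, regions = list()),
                       class = "cfa_regions"))
    }
    EBImage::otsu((image - lo) / (hi - lo), range = c(0, 1)) * (hi - lo) + lo
  }
  mask <- image > thr
  if (!any(mask)) {
    return(structure(list(labels = matrix(0L, nrow(image), ncol(image)),
                          threshold = thr, regions = list()),
                     class = "cfa_regions"))
  }
  lab <- label_components8(mask)
  nlab <- max(lab)
  idx <- which(lab > 0)
  rc <- cbind(row = (idx - 1L) %% nrow(lab), col = (idx - 1L) %/% nrow(lab))
  coords_by_lab <- split(seq_along(idx), lab[idx])
  regions <- vector("list", nlab)
  H <- nrow(image); W <- ncol(image)
  for (k in seq_len(nlab)) {
    co <- rc[coords_by_lab[[k]], , drop = FALSE]
    area <- nrow(co)
    border <- any(co[, 1] == 0 | co[, 1] == H - 1 |
                  co[, 2] == 0 | co[, 2] == W - 1)
    qc_pass <- TRUE; qc_reason <- ""
    if (area < config$min_area_px) {
      qc_pass <- FALSE; qc_reason <- "area_below_min"
    } else if (area > config$max_area_px) {
      qc_pass <- FALSE; qc_reason <- "area_above_max"
    } else if (border && config$exclude_border) {
      qc_pass <- FALSE; qc_reason <- "touches_border"
    }
    regions[[k]] <- list(cell_id = k, coords = co, area = area,
                         cx = mean(co[, 2]), cy = mean(co[, 1]),
                         touches_border = border,
                         qc_pass = qc_pass, qc_reason = qc_reason)
  }
  structure(list(labels = lab, threshold = thr, regions = regions),
            class = "cfa_regions")
}

# 8-connected component labeling. EBImage::bwlabel labels 4-connected
# components; a union-find pass over diagonally adjacent label pairs then
# merges components that touch only corner-to-corner.
label_components8 <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  nr <- nrow(lab); nc <- ncol(lab)
  if (nr < 2 || nc < 2 || max(lab) < 2) return(lab)
  p1 <- cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1]))
  p2 <- cbind(as.vector(lab[-1, -nc]), as.vector(lab[-nr, -1]))
  pairs <- rbind(p1, p2)
  pairs <- pairs[pairs[, 1] > 0L & pairs[, 2] > 0L &
                 pairs[, 1] != pairs[, 2], , drop = FALSE]
  n <- max(lab)
  if (nrow(pairs)) {
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i] <<- parent[parent[i]]; i }
    for (k in seq_len(nrow(pairs))) {
      a <- find(pairs[k, 1]); b <- find(pairs[k, 2])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
    root <- vapply(seq_len(n), find, 0L)
    relab <- match(root, sort(unique(root)))
    nz <- lab > 0L
    lab[nz] <- relab[lab[nz]]
  }
  lab
}

#' Measure a region's elongation from its second central moments
#'
#' Axes follow the solid-ellipse moment convention: with eigenvalues
#' `lambda1 >= lambda2` of the region's pixel-coordinate covariance matrix
#' (population denominator), the full major and minor axes are
#' `a = 4*sqrt(lambda1)` and `b = 4*sqrt(lambda2)`, so a filled ellipse
#' recovers its generating axes. The elongation ratio `er = a/b` is `>= 1`
#' by the eigenvalue ordering. A degenerate region with (near-)zero minor
#' variance (e.g. a one-pixel-wide line) yields `er = Inf`.
#'
#' @param region a region record from [segment_cells()], or an n x 2
#'   matrix of (row, col) pixel coordinates.
#' @return A list with `a`, `b` (full axes, pixels), `er` and
#'   `theta_rad` (major-axis orientation).
#' @examples
#' co <- as.matrix(expand.grid(r = 0:20, c = 0:20))
#' co <- co[(co[, 1] - 10)^2 + (co[, 2] - 10)^2 <= 100, ]
#' measure_elongation(co)  # er close to 1
#' @export
measure_elongation <- function(region) {
  co <- if (is.list(region) && !is.null(region$coords)) region$coords else region
  if (!is.matrix(co) || ncol(co) != 2) {
    stop("region must be an n x 2 (row, col) coordinate matrix")
  }
  if (nrow(co) < 5) stop("region must have at least 5 pixels")
  mu <- colMeans(co)
  x <- sweep(co, 2, mu)
  cv <- crossprod(x) / nrow(x)
  e <- eigen(cv, symmetric = TRUE)
  l1 <- max(e$values[1], 0); l2 <- max(e$values[2], 0)
  a <- 4 * sqrt(l1); b <- 4 * sqrt(l2)
  er <- if (l2 < 1e-9) Inf else a / b
  # orientation of the major axis in image coordinates (x = col, y = row)
  v <- e$vectors[, 1]
  list(a = a, b = b, er = er, theta_rad = atan2(v[1], v[2]) %% pi)
}

#' Segment and measure all cells in one field
#'
#' @param image 2-D gray-level matrix.
#' @param config a [segmentation_config()].
#' @return A data.frame with one row per segmented region: `cell_id`, `cx`,
#'   `cy`, `a_px`, `b_px`, `er`, `area`, `qc_pass`, `qc_reason`.
#' @export
measure_cells <- function(image, config = segmentation_config()) {
  seg <- segment_cells(image, config)
  rows <- lapply(seg$regions, function(rg) {
    if (rg$area >= 5) {
      m <- measure_elongation(rg)
      if (!is.finite(m$er) && rg$qc_pass) {
        rg$qc_pass <- FALSE; rg$qc_reason <- "degenerate_shape"
      }
    } else {
      m <- list(a = NA_real_, b = NA_real_, er = NA_real_)
      rg$qc_pass <- FALSE
      if (rg$qc_reason == "") rg$qc_reason <- "too_few_pixels"
    }
    data.frame(cell_id = rg$cell_id, cx = rg$cx, cy = rg$cy,
               a_px = m$a, b_px = m$b, er = m$er, area = rg$area,
               qc_pass = rg$qc_pass, qc_reason = rg$qc_reason,
               stringsAsFactors = FALSE)
  })
  if (!length(rows)) {
    return(data.frame(cell_id = integer(), cx = numeric(), cy = numeric(),
                      a_px = numeric(), b_px = numeric(), er = numeric(),
                      area = numeric(), qc_pass = logical(),
                      qc_reason = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Measure a sample's ER distribution across imaging fields
#'
#' Concatenates the QC-passing cell measurements of one or more fields into
#' a single elongation-ratio distribution and summarizes it into the
#' deformability parameters (see [summarize_er()]). Rejected cells are
#' counted per QC reason, never silently dropped.
#'
#' @param images a single matrix, a list of matrices, or a character vector
#'   of image file paths.
#' @param config a [segmentation_config()].
#' @param udfc_threshold,ldfc_threshold ER cutoffs for undeformable and
#'   low-deformable cells.
#' @return A list of class `cfa_sample`: `cells` (per-cell table with a
#'   `field` column), `distribution` (an `er_distribution`), and
#'   `rejected` (named counts per QC reason).
#' @export
analyze_sample <- function(images, config = segmentation_config(),
                           udfc_threshold = 1.1, ldfc_threshold = 1.3) {
  if (is.matrix(images)) images <- list(images)
  if (is.character(images)) images <- lapply(images, read_cell_image)
  if (!length(images)) stop("at least one image is required")
  per_field <- lapply(seq_along(images), function(i) {
    df <- measure_cells(images[[i]], config)
    if (nrow(df)) df$field <- i else df$field <- integer(0)
    df
  })
  cells <- do.call(rbind, per_field)
  keep <- cells$qc_pass & is.finite(cells$er)
  rejected <- table(cells$qc_reason[!cells$qc_pass])
  if (!any(keep)) stop("no measurable cells in the supplied field(s)")
  dist <- summarize_er(cells$er[keep], udfc_threshold = udfc_threshold,
                       ldfc_threshold = ldfc_threshold)
  structure(list(cells = cells, distribution = dist,
                 rejected = rejected), class = "cfa_sample")
}
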