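#' Masked maximum-intensity projection
#'
#' Projects a z-stack to 2D: inside cell masks each pixel takes the maximum
#' intensity across z; pixels outside all cells are set to 0.
#'
#' @param stack 3D array `(z, y, x)`.
#' @param mask 2D integer label matrix `(y, x)`; 0 = outside cells.
#' @return 2D numeric matrix `(y, x)`.
#' @export
max_project <- function(stack, mask) {
  if (!is.array(stack) || length(dim(stack)) != 3L) {
    stop("`stack` must be a 3D (z, y, x) array", call. = FALSE)
  }
  d <- dim(stack)
  if (!is.matrix(mask) || nrow(mask) != d[2] || ncol(mask) != d[3]) {
    stop("mask shape does not match stack (y, x) dimensions", call. = FALSE)
  }
  proj <- apply(stack, c(2, 3), max)
  proj[mask == 0L] <- 0
  proj
}

# 8-connected component labelling of `active` pixels, never merging across
# different cell labels; pure R flood fill over the (sparse) active set
label_components <- function(active, mask) {
  comp <- matrix(0L, nrow(active), ncol(active))
  nr <- nrow(active); nc <- ncol(active)
  next_id <- 0L
  idx <- which(active & mask > 0L)
  off_r <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  off_c <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  for (p in idx) {
    if (comp[p] != 0L) next
    next_id <- next_id + 1L
    lab <- mask[p]
    stack_px <- p
    comp[p] <- next_id
    while (length(stack_px)) {
      q <- stack_px[length(stack_px)]
      stack_px <- stack_px[-length(stack_px)]
      r <- ((q - 1L) %% nr) + 1L
      cc <- ((q - 1L) %/% nr) + 1L
      for (k in 1:8) {
        rr <- r + off_r[k]; ccc <- cc + off_c[k]
        if (rr < 1L || rr > nr || ccc < 1L || ccc > nc) next
        qq <- (ccc - 1L) * nr + rr
        if (active[qq] && comp[qq] == 0L && mask[qq] == lab) {
          comp[qq] <- next_id
          stack_px <- c(stack_px, qq)
        }
      }
    }
  }
  comp
}

#' Intensity threshold from in-mask background
#'
#' `mean + n_sd * SD` of the in-mask pixel intensities. With dots occupying
#' a small fraction of the cell area this approximates the background
#' statistics well enough for thresholding.
#'
#' @param projection 2D intensity matrix.
#' @param mask 2D label matrix.
#' @param n_sd Number of SDs above the mean.
#' @return Scalar threshold.
#' @export
threshold_from_background <- function(projection, mask, n_sd = 5) {
  v <- projection[mask > 0L]
  if (!length(v)) stop("mask selects no pixels", call. = FALSE)
  mean(v) + n_sd * stats::sd(v)
}

# resolve "sd:5" / numeric threshold specs (CLI convenience)
resolve_threshold <- function(spec, projection, mask) {
  if (is.numeric(spec)) return(spec)
  if (is.character(spec) && grepl("^sd:", spec)) {
    return(threshold_from_background(projection, mask,
                                     as.numeric(sub("^sd:", "", spec))))
  }
  stop("threshold must be numeric or 'sd:<n>'", call. = FALSE)
}

#' Detect dots in a projected image
#'
#' Connected components (8-connectivity) of pixels at or above `threshold`
#' inside cell masks; components are split by cell label. The sub-pixel
#' centroid is the background-subtracted intensity-weighted mean over a
#' fixed square aperture (half-width `centroid_halfwidth` pixels) centered
#' on the component's peak and restricted to the component's cell — an
#' aperture centroid is far less sensitive to the exact threshold than a
#' centroid over supra-threshold pixels only. The background is estimated
#' as the median in-mask intensity (dots occupy a small area fraction).
#' Coordinates are micrometres with pixel `(1,1)`'s top-left corner at
#' `(0, 0)`, so a pixel center is at `(col - 0.5) * pixel_size`.
#'
#' @param projection 2D intensity matrix `(y, x)`.
#' @param mask 2D label matrix.
#' @param threshold Absolute intensity threshold, or `"sd:<n>"`.
#' @param pixel_size Micrometres per pixel.
#' @param centroid_halfwidth Aperture half-width in pixels (~2 PSF sigma).
#' @return Data frame of dots: `cell_id`, `x_um`, `y_um`, `peak_intensity`,
#'   `area` (pixels); zero rows when nothing is detected.
#' @export
detect_dots <- function(projection, mask, threshold, pixel_size = 0.1,
                        centroid_halfwidth = 3L) {
  stopifnot(is.matrix(projection), is.matrix(mask),
            all(dim(projection) == dim(mask)))
  stopifnot_positive(pixel_size, "pixel_size")
  threshold <- resolve_threshold(threshold, projection, mask)
  active <- projection >= threshold
  comp <- label_components(active, mask)
  ids <- setdiff(unique(as.integer(comp)), 0L)
  if (!length(ids)) {
    return(data.frame(cell_id = integer(0), x_um = numeric(0),
                      y_um = numeric(0), peak_intensity = numeric(0),
                      area = integer(0)))
  }
  nr <- nrow(comp); nc <- ncol(comp)
  bg <- stats::median(projection[mask > 0L])
  half <- as.integer(centroid_halfwidth)
  rows <- lapply(ids, function(id) {
    px <- which(comp == id)
    peak <- px[which.max(projection[px])]
    lab <- mask[peak]
    pr0 <- ((peak - 1L) %% nr) + 1L
    pc0 <- ((peak - 1L) %/% nr) + 1L
    rr <- max(1L, pr0 - half):min(nr, pr0 + half)
    cc <- max(1L, pc0 - half):min(nc, pc0 + half)
    w <- pmax(projection[rr, cc, drop = FALSE] - bg, 0) *
      (mask[rr, cc, drop = FALSE] == lab)
    if (sum(w) <= 0) {
      # flat or fully-background aperture: fall back to the plain
      # intensity-weighted centroid of the component pixels
      wv <- projection[px]
      r_px <- ((px - 1L) %% nr) + 1L
      c_px <- ((px - 1L) %/% nr) + 1L
      x_px <- sum(wv * (c_px - 0.5)) / sum(wv)
      y_px <- sum(wv * (r_px - 0.5)) / sum(wv)
    } else {
      x_px <- sum(rep(cc - 0.5, each = length(rr)) * w) / sum(w)
      y_px <- sum(rep(rr - 0.5, times = length(cc)) * w) / sum(w)
    }
    data.frame(
      cell_id = lab,
      x_um = x_px * pixel_size,
      y_um = y_px * pixel_size,
      peak_intensity = projection[peak],
      area = length(px)
    )
  })
  out <- do.call(rbind, rows)
  out[order(out$cell_id, out$x_um), , drop = FALSE]
}

#' Minimum pairwise distance between two dot sets
#'
#' Euclidean 2D distance in micrometres, minimized over every cross pair.
#'
#' @param dots_a,dots_b Data frames with `x_um`, `y_um` (one cell each).
#' @return Minimum distance in um, or `NA_real_` (flagged for QC) when
#'   either set is empty.
#' @export
min_pair_distance <- function(dots_a, dots_b) {
  if (!nrow(dots_a) || !nrow(dots_b)) return(NA_real_)
  dx <- outer(dots_a$x_um, dots_b$x_um, "-")
  dy <- outer(dots_a$y_um, dots_b$y_um, "-")
  min(sqrt(dx^2 + dy^2))
}

#' Co-localization call
#'
#' Two dots are co-localized when their distance is within `threshold`
#' (inclusive boundary).
#'
#' @param distance Distance in micrometres (>= 0); `NA` passes through.
#' @param threshold Co-localization threshold, default 0.4 um.
#' @return Logical.
#' @export
classify_colocalization <- function(distance, threshold = 0.4) {
  if (any(distance < 0, na.rm = TRUE)) {
    stop("`distance` must be >= 0", call. = FALSE)
  }
  distance <= threshold
}

#' Measure co-localization across all cells of an image
#'
#' Projects both channels, detects dots per channel per cell, and records
#' the per-cell dot counts, minimum green-red distance, and co-localization
#' call. Cells lacking a dot in either channel are retained with `NA`
#' distance.
#'
#' @param channel_a,channel_b 3D arrays `(z, y, x)` (e.g. GFP and mCherry).
#' @param mask 2D cell label matrix.
#' @param pixel_size Micrometres per pixel.
#' @param threshold_a,threshold_b Per-channel thresholds (absolute or
#'   `"sd:<n>"`).
#' @param coloc_threshold Co-localization threshold in um.
#' @return Data frame: `cell_id`, `n_dots_a`, `n_dots_b`, `min_distance_um`,
#'   `colocalized`.
#' @export
measure_image <- function(channel_a, channel_b, mask, pixel_size = 0.1,
                          threshold_a = "sd:5", threshold_b = "sd:5",
                          coloc_threshold = 0.4) {
  pa <- max_project(channel_a, mask)
  pb <- max_project(channel_b, mask)
  da <- detect_dots(pa, mask, threshold_a, pixel_size)
  db <- detect_dots(pb, mask, threshold_b, pixel_size)
  cells <- setdiff(sort(unique(as.integer(mask))), 0L)
  rows <- lapply(cells, function(cid) {
    a <- da[da$cell_id == cid, , drop = FALSE]
    b <- db[db$cell_id == cid, , drop = FALSE]
    md <- min_pair_distance(a, b)
    data.frame(cell_id = cid, n_dots_a = nrow(a), n_dots_b = nrow(b),
               min_distance_um = md,
               colocalized = if (is.na(md)) NA else classify_colocalization(md, coloc_threshold))
  })
  do.call(rbind, rows)
}

#' Otsu threshold (fixture segmentation fallback)
#'
#' Classic Otsu between-class variance maximization on a 256-bin histogram.
#' Provided only so synthetic fixtures can be segmented without an external
#' mask; real cell segmentation is out of scope.
#'
#' @param image Numeric matrix.
#' @return Scalar threshold.
#' @export
otsu_threshold <- function(image) {
  v <- as.numeric(image)
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1])
  h <- tabulate(pmin(as.integer((v - rng[1]) / diff(rng) * 255) + 1L, 256L),
                nbins = 256L)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(256L))
  mu_t <- mu[256L]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  k <- which.max(sigma_b)
  rng[1] + (k / 256) * diff(rng)
}
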