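#' Multi-channel field image
#'
#' Container for a single 2-D multi-channel fluorescence field. Channels are
#' numeric matrices sharing dimensions; intensities are arbitrary linear units
#' (typically the camera's 16-bit range).
#'
#' @param channels Named list of numeric matrices (e.g. `dapi`, `emerin`).
#' @param pixel_size_um Pixel size in micrometres per pixel.
#' @param provenance Free-text origin of the image.
#' @return An object of class `field_image`.
#' @export
field_image <- function(channels, pixel_size_um, provenance = "") {
  if (!is.list(channels) || length(channels) == 0 || is.null(names(channels)) ||
      any(!nzchar(names(channels))))
    stop_input("channels must be a non-empty named list of matrices")
  dims <- lapply(channels, dim)
  if (any(vapply(channels, function(ch) !is.matrix(ch) || !is.numeric(ch), logical(1))))
    stop_input("all channels must be numeric matrices")
  if (length(unique(lapply(dims, paste, collapse = "x"))) != 1L)
    stop_input("all channels must share dimensions")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L || pixel_size_um <= 0)
    stop_input("pixel_size_um must be a positive scalar")
  structure(list(channels = channels, pixel_size_um = pixel_size_um,
                 provenance = provenance),
            class = "field_image")
}

#' @export
print.field_image <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("field_image: %d x %d px (%.3g um/px), channels: %s\n",
              d[1], d[2], x$pixel_size_um, paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

# ---- histogram auto-thresholding ------------------------------------------

# 256-bin histogram on the 8-bit scale. Images already within [0, 255] are
# binned natively (the ImageJ convention for 8-bit data, which keeps a
# threshold floor absolute); wider-range images are min-max rescaled.
hist256 <- function(image) {
  if (min(image) >= 0 && max(image) <= 255) {
    lo <- 0; hi <- 255
  } else {
    lo <- min(image); hi <- max(image)
  }
  v <- as.integer(round((image - lo) / (hi - lo) * 255))
  counts <- tabulate(v + 1L, nbins = 256L)
  list(counts = counts, lo = lo, hi = hi)
}

# Otsu: index t (0..254) maximizing between-class variance; foreground > t.
# Plateau ties (e.g. clean two-value images) resolve to the plateau midpoint.
otsu_index <- function(counts) {
  p <- counts / sum(counts)
  i <- 0:255
  w0 <- cumsum(p)
  mu <- cumsum(p * i)
  mu_t <- mu[256]
  denom <- w0 * (1 - w0)
  sigma_b <- ifelse(denom > 0, (mu_t * w0 - mu)^2 / denom, -Inf)
  sigma_b <- sigma_b[1:255]
  vmax <- max(sigma_b)
  ties <- which(sigma_b >= vmax - abs(vmax) * 1e-10)
  as.integer(floor(mean(range(ties)))) - 1L
}

# Yen's maximum correlation criterion (as in the ImageJ auto-threshold
# suite); degenerate splits leaving a class empty are not eligible.
yen_index <- function(counts) {
  p <- counts / sum(counts)
  p1 <- cumsum(p)
  p1sq <- cumsum(p^2)
  p2sq <- sum(p^2) - p1sq
  a <- p1sq * p2sq
  b <- p1 * (1 - p1)
  crit <- ifelse(a > 0, -log(a), 0) + ifelse(b > 0, 2 * log(b), 0)
  cum <- cumsum(counts)
  crit[cum == 0 | cum == sum(counts)] <- -Inf
  which.max(crit[1:255]) - 1L
}

# Intermodes: smooth the histogram (running mean, window 3) until exactly two
# local maxima remain; threshold = midpoint of the two modes.
intermodes_index <- function(counts, max_iter = 10000L) {
  y <- as.numeric(counts)
  # local maxima, with virtual -Inf outside the histogram so the end bins
  # can carry a mode
  mode_idx <- function(y) {
    left <- c(-Inf, y[-256]); right <- c(y[-1], -Inf)
    which(y > left & y >= right & y > 0)
  }
  it <- 0L
  while (length(mode_idx(y)) != 2L) {
    it <- it + 1L
    if (it > max_iter)
      stop_degenerate("histogram did not become bimodal under iterated smoothing")
    y <- (c(y[1], y[-256]) + y + c(y[-1], y[256])) / 3
  }
  modes <- mode_idx(y)
  as.integer(floor((modes[1] + modes[2]) / 2)) - 1L
}

#' Automatic histogram thresholding (Otsu, Intermodes, Yen)
#'
#' Reimplements the ImageJ auto-threshold methods used throughout the
#' workflow. The image is internally rescaled to 8-bit (0--255, 256-bin
#' histogram); the selected threshold index is optionally raised to a
#' minimum level (`floor_8bit`, a guard against dim backgrounds) and mapped
#' back to the original intensity scale. Foreground is `image > threshold`.
#'
#' @param image Numeric matrix of intensities.
#' @param method One of `"otsu"`, `"intermodes"`, `"yen"`.
#' @param floor_8bit Optional minimum threshold on the 8-bit scale (0--255),
#'   applied after the automatic method; `NULL` for none.
#' @return Threshold on the original intensity scale, with attributes
#'   `threshold_8bit` (the final 8-bit index) and `method`.
#' @export
auto_threshold <- function(image, method = c("otsu", "intermodes", "yen"),
                           floor_8bit = NULL) {
  method <- match.arg(method)
  if (!is.numeric(image)) stop_input("image must be numeric")
  if (length(unique(as.vector(image))) < 2L)
    stop_degenerate("constant image: threshold undefined")
  h <- hist256(image)
  t8 <- switch(method,
               otsu = otsu_index(h$counts),
               yen = yen_index(h$counts),
               intermodes = intermodes_index(h$counts))
  if (!is.null(floor_8bit)) {
    if (!is.numeric(floor_8bit) || floor_8bit < 0 || floor_8bit > 255)
      stop_config("floor_8bit must be in [0, 255]")
    t8 <- max(t8, as.integer(floor_8bit))
  }
  thr <- h$lo + t8 / 255 * (h$hi - h$lo)
  structure(thr, threshold_8bit = as.integer(t8), method = method)
}

# ---- connected components --------------------------------------------------

#' Label connected components of a binary mask
#'
#' @param mask Binary (logical or 0/1 numeric) matrix.
#' @param connectivity 4 or 8 (default 8, the ImageJ Analyze Particles
#'   behaviour).
#' @return Integer label matrix with consecutive labels `1..n`; attribute
#'   `n_labels`.
#' @export
label_particles <- function(mask, connectivity = 8) {
  if (!connectivity %in% c(4, 8)) stop_config("connectivity must be 4 or 8")
  m <- matrix(as.numeric(mask != 0), nrow(mask), ncol(mask))
  lab <- EBImage::bwlabel(m)           # 4-connected
  lab <- matrix(as.integer(lab), nrow(lab), ncol(lab))
  n <- max(lab)
  if (connectivity == 8 && n > 1) {
    # merge labels touching diagonally (union-find over label ids)
    nr <- nrow(lab); nc <- ncol(lab)
    a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]    # down-right
    a2 <- lab[-nr, -1]; b2 <- lab[-1, -nc]    # down-left
    pairs <- rbind(cbind(as.vector(a1), as.vector(b1)),
                   cbind(as.vector(a2), as.vector(b2)))
    pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2], ,
                   drop = FALSE]
    if (nrow(pairs)) {
      parent <- seq_len(n)
      find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
      for (k in seq_len(nrow(pairs))) {
        ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
      root <- vapply(seq_len(n), find, integer(1))
      lab[lab > 0] <- root[lab[lab > 0]]
    }
  }
  # make labels consecutive
  ids <- sort(unique(lab[lab > 0]))
  if (length(ids)) {
    remap <- integer(max(ids)); remap[ids] <- seq_along(ids)
    lab[lab > 0] <- remap[lab[lab > 0]]
  }
  structure(lab, n_labels = length(ids))
}

n_labels <- function(labels) {
  nl <- attr(labels, "n_labels")
  if (is.null(nl)) nl <- max(0L, max(labels))
  nl
}

# ---- particle measurement --------------------------------------------------

# perimeter (px) of a single-object binary matrix via oriented contour chain
contour_perimeter <- function(obj) {
  oc <- EBImage::ocontour(EBImage::Image(obj))
  if (length(oc) == 0) return(0)
  p <- oc[[1]]
  if (nrow(p) == 1) return(4)          # isolated pixel: unit-square boundary
  q <- rbind(p[-1, , drop = FALSE], p[1, , drop = FALSE])
  sum(sqrt(rowSums((p - q)^2)))
}

# convex hull area (px^2) from pixel coordinates expanded to pixel corners
convex_area <- function(rows, cols) {
  pts <- cbind(c(rows - 0.5, rows - 0.5, rows + 0.5, rows + 0.5),
               c(cols - 0.5, cols + 0.5, cols - 0.5, cols + 0.5))
  h <- grDevices::chull(pts)
  hp <- pts[h, , drop = FALSE]
  n <- nrow(hp)
  if (n < 3) return(length(rows))
  i2 <- c(2:n, 1)
  abs(sum(hp[, 1] * hp[i2, 2] - hp[i2, 1] * hp[, 2])) / 2
}

#' Measure labelled particles
#'
#' Computes, per label, the area (um^2), perimeter (um), centroid (pixel
#' coordinates, x = column, y = row, origin top-left), circularity
#' (4*pi*A/P^2, capped at 1), solidity (area / convex hull area) and the mean
#' intensity over the label's pixels for each requested channel.
#'
#' @param labels Label matrix from [label_particles()].
#' @param intensity_channels Named list of intensity matrices (may be empty).
#' @param pixel_size_um Pixel size in um/px.
#' @return `data.frame` with one row per label.
#' @export
measure_particles <- function(labels, intensity_channels = list(),
                              pixel_size_um = 1) {
  nl <- n_labels(labels)
  cn <- names(intensity_channels)
  empty <- data.frame(label = integer(0), area_um2 = numeric(0),
                      perimeter_um = numeric(0), x = numeric(0), y = numeric(0),
                      circularity = numeric(0), solidity = numeric(0))
  for (nm in cn) empty[[paste0("mean_", nm)]] <- numeric(0)
  if (nl == 0) return(empty)
  idx <- which(labels > 0)
  lab <- labels[idx]
  rows <- ((idx - 1L) %% nrow(labels)) + 1L
  cols <- ((idx - 1L) %/% nrow(labels)) + 1L
  area_px <- tabulate(lab, nbins = nl)
  cy <- rowsum(as.numeric(rows), lab)[, 1] / area_px
  cx <- rowsum(as.numeric(cols), lab)[, 1] / area_px
  per_px <- numeric(nl); sol <- numeric(nl)
  by_lab <- split(seq_along(idx), lab)
  for (k in seq_len(nl)) {
    ii <- by_lab[[k]]
    r <- rows[ii]; cc <- cols[ii]
    r0 <- range(r); c0 <- range(cc)
    obj <- matrix(0, r0[2] - r0[1] + 3, c0[2] - c0[1] + 3)
    obj[cbind(r - r0[1] + 2L, cc - c0[1] + 2L)] <- 1
    per_px[k] <- contour_perimeter(obj)
    sol[k] <- min(1, area_px[k] / convex_area(r, cc))
  }
  area_um2 <- area_px * pixel_size_um^2
  perimeter_um <- per_px * pixel_size_um
  circ <- ifelse(perimeter_um > 0, 4 * pi * area_um2 / perimeter_um^2, 1)
  out <- data.frame(label = seq_len(nl), area_um2 = area_um2,
                    perimeter_um = perimeter_um, x = cx, y = cy,
                    circularity = pmin(circ, 1), solidity = sol)
  for (nm in cn) {
    ch <- intensity_channels[[nm]]
    if (!all(dim(ch) == dim(labels)))
      stop_input(sprintf("channel '%s' dimensions do not match labels", nm))
    out[[paste0("mean_", nm)]] <- rowsum(as.numeric(ch[idx]), lab)[, 1] / area_px
  }
  out
}

# ---- TIFF I/O --------------------------------------------------------------

#' Write a field image as multi-page 16-bit TIFF
#'
#' One page per channel. Channel names and pixel size are stored in a JSON
#' sidecar (`<path>.json`) because baseline TIFF carries neither reliably.
#' Intensities are stored on the 16-bit scale (values clipped to 0..65535).
#'
#' @param field A [field_image()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_field <- function(field, path) {
  stopifnot(inherits(field, "field_image"))
  pages <- lapply(field$channels, function(ch) pmin(pmax(ch, 0), 65535) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  meta <- list(channels = names(field$channels),
               pixel_size_um = field$pixel_size_um,
               provenance = field$provenance, scale = 65535)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a field image written by [write_field()]
#'
#' Also accepts plain multi-page TIFFs: without a sidecar, channels are named
#' `ch1..chN` (or by `channel_names`) and `pixel_size_um` must be supplied.
#'
#' @param path TIFF path.
#' @param pixel_size_um Pixel size override (required when no sidecar).
#' @param channel_names Optional channel names override.
#' @return A [field_image()].
#' @export
read_field <- function(path, pixel_size_um = NULL, channel_names = NULL) {
  if (!file.exists(path)) stop_input(sprintf("no such file: %s", path))
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) if (length(dim(p)) == 3) p[, , 1] else p)
  side <- paste0(path, ".json")
  scale <- 65535; prov <- path
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    if (is.null(channel_names)) channel_names <- meta$channels
    if (is.null(pixel_size_um)) pixel_size_um <- meta$pixel_size_um
    if (!is.null(meta$scale)) scale <- meta$scale
    if (!is.null(meta$provenance)) prov <- meta$provenance
  }
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_along(pages))
  if (is.null(pixel_size_um))
    stop_input("pixel_size_um required: no JSON sidecar with metadata found")
  names(pages) <- channel_names
  field_image(lapply(pages, function(p) p * scale), pixel_size_um, provenance = prov)
}
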