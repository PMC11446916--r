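# Phenotype metrics: nuclear shape, focal adhesion size, signed MTOC-nucleus
# distance, F-actin structure-tensor coherency, spheroid metrics with the
# invading-cell rule, migration path statistics.

#' Per-nucleus area and shape from the DAPI channel
#'
#' Otsu segmentation (as in [segment_nuclei()]) followed by particle
#' measurement.
#'
#' @inheritParams segment_nuclei
#' @return `data.frame` with `label`, `area_um2`, `circularity`, `solidity`
#'   (plus centroid and perimeter columns).
#' @export
nuclear_shape <- function(dapi, pixel_size_um, min_area_um2 = 20,
                          floor_8bit = 25) {
  lab <- segment_nuclei(dapi, pixel_size_um, min_area_um2 = min_area_um2,
                        floor_8bit = floor_8bit)
  measure_particles(lab, list(dapi = dapi), pixel_size_um)
}

#' Focal adhesion sizes from a paxillin channel
#'
#' Intermodes threshold (8-bit floor 25) restricted to the cell mask, then
#' particle measurement. The per-cell mean focal adhesion area is `NA` (not
#' zero) when no particle is found; a signal-free (constant) channel counts
#' as zero adhesions rather than an error.
#'
#' @param paxillin Paxillin intensity matrix (one cell).
#' @param cell_mask Optional logical mask restricting the analysis.
#' @param pixel_size_um um/px.
#' @param floor_8bit 8-bit threshold floor.
#' @return List: `particles` (data.frame), `count`, `mean_area_um2` (`NA`
#'   when `count` is 0).
#' @export
focal_adhesion_sizes <- function(paxillin, cell_mask = NULL, pixel_size_um,
                                 floor_8bit = 25) {
  thr <- tryCatch(auto_threshold(paxillin, "intermodes", floor_8bit = floor_8bit),
                  emdmn_degenerate_image = function(e) NULL)
  if (is.null(thr))
    return(list(particles = measure_particles(matrix(0L, 1, 1)), count = 0L,
                mean_area_um2 = NA_real_))
  mask <- paxillin > thr
  if (!is.null(cell_mask)) mask <- mask & cell_mask
  parts <- measure_particles(label_particles(mask, 8),
                             list(paxillin = paxillin), pixel_size_um)
  list(particles = parts, count = nrow(parts),
       mean_area_um2 = if (nrow(parts)) mean(parts$area_um2) else NA_real_)
}

# border pixels of a binary mask (4-neighbourhood)
mask_border <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2, nc + 2); pad[2:(nr + 1), 2:(nc + 1)] <- mask
  core <- pad[2:(nr + 1), 2:(nc + 1)]
  core & !(pad[1:nr, 2:(nc + 1)] & pad[3:(nr + 2), 2:(nc + 1)] &
             pad[2:(nr + 1), 1:nc] & pad[2:(nr + 1), 3:(nc + 2)])
}

#' Signed MTOC-nucleus distance
#'
#' The centrosome is the largest pericentrin object above a Yen threshold
#' (8-bit floor 25); the nucleus is the largest DAPI object above an Otsu
#' threshold (8-bit floor 100). The distance is the minimum Euclidean
#' distance (um) from the centrosome centroid to the nucleus border pixels;
#' it is negative when the centroid lies within the nucleus footprint (the
#' 2-D operationalization of a centrosome sitting over the nucleus).
#'
#' @param pericentrin,dapi Intensity matrices (one cell).
#' @param pixel_size_um um/px.
#' @return List: `distance_um` (signed), `centrosome_xy`,
#'   `nearest_border_xy` (pixel coordinates), or `NULL` when no pericentrin
#'   signal survives thresholding.
#' @export
mtoc_nucleus_distance <- function(pericentrin, dapi, pixel_size_um) {
  thr_p <- tryCatch(auto_threshold(pericentrin, "yen", floor_8bit = 25),
                    emdmn_degenerate_image = function(e) NULL)
  if (is.null(thr_p)) return(NULL)
  lab_p <- label_particles(pericentrin > thr_p, 8)
  if (n_labels(lab_p) == 0) return(NULL)
  thr_n <- auto_threshold(dapi, "otsu", floor_8bit = 100)
  lab_n <- label_particles(EBImage::fillHull((dapi > thr_n) * 1) > 0, 8)
  if (n_labels(lab_n) == 0) stop_input("no nucleus above threshold")
  area_p <- tabulate(lab_p[lab_p > 0], nbins = n_labels(lab_p))
  kp <- which.max(area_p)
  idx <- which(lab_p == kp)
  cy <- mean(((idx - 1L) %% nrow(lab_p)) + 1L)
  cx <- mean(((idx - 1L) %/% nrow(lab_p)) + 1L)
  area_n <- tabulate(lab_n[lab_n > 0], nbins = n_labels(lab_n))
  nucleus <- lab_n == which.max(area_n)
  border <- which(mask_border(nucleus))
  br <- ((border - 1L) %% nrow(nucleus)) + 1L
  bc <- ((border - 1L) %/% nrow(nucleus)) + 1L
  d2 <- (br - cy)^2 + (bc - cx)^2
  j <- which.min(d2)
  inside <- nucleus[round(cy), round(cx)]
  list(distance_um = sqrt(d2[j]) * pixel_size_um * if (inside) -1 else 1,
       centrosome_xy = c(x = cx, y = cy),
       nearest_border_xy = c(x = bc[j], y = br[j]))
}

#' F-actin structure-tensor coherency
#'
#' Per-pixel structure tensor from Gaussian-smoothed central-difference
#' gradients, window-averaged with a Gaussian of SD `window_sigma_um`;
#' coherency is (lambda1 - lambda2)/(lambda1 + lambda2), set to 0 where the
#' tensor trace vanishes. Returns the mean over the cell mask. 1 means a
#' perfectly oriented texture, 0 an isotropic one.
#'
#' @param factin Intensity matrix.
#' @param cell_mask Optional logical mask (default: whole image).
#' @param pixel_size_um um/px.
#' @param window_sigma_um Gaussian window SD in um (default 2).
#' @param deriv_sigma_px Pre-smoothing SD for the gradient, in px.
#' @return Mean coherency in \[0, 1\].
#' @export
factin_coherency <- function(factin, cell_mask = NULL, pixel_size_um,
                             window_sigma_um = 2, deriv_sigma_px = 1) {
  if (is.null(cell_mask)) cell_mask <- matrix(TRUE, nrow(factin), ncol(factin))
  if (!any(cell_mask)) stop_input("empty cell mask")
  s <- EBImage::gblur(factin, deriv_sigma_px)
  nr <- nrow(s); nc <- ncol(s)
  gy <- (s[c(2:nr, nr), ] - s[c(1, 1:(nr - 1)), ]) / 2
  gx <- (s[, c(2:nc, nc)] - s[, c(1, 1:(nc - 1))]) / 2
  sw <- window_sigma_um / pixel_size_um
  jxx <- EBImage::gblur(gx * gx, sw)
  jyy <- EBImage::gblur(gy * gy, sw)
  jxy <- EBImage::gblur(gx * gy, sw)
  trace <- jxx + jyy
  coh <- matrix(0, nr, nc)
  ok <- trace > max(trace, 0) * 1e-12 & trace > 0
  coh[ok] <- sqrt((jxx[ok] - jyy[ok])^2 + 4 * jxy[ok]^2) / trace[ok]
  mean(coh[cell_mask])
}

#' Spheroid morphometrics with the invading-cell rule
#'
#' The main body is the largest connected component of `body_mask`; its
#' area, circularity and solidity are reported together with the number of
#' invading cells, defined as nucleus centroids falling outside the main
#' body footprint.
#'
#' @param body_mask Logical spheroid-body mask.
#' @param nuclei_centroids `data.frame` with pixel columns `x`, `y`.
#' @param pixel_size_um um/px.
#' @return List: `area_um2`, `circularity`, `solidity`, `n_invading`.
#' @export
spheroid_metrics <- function(body_mask, nuclei_centroids, pixel_size_um) {
  lab <- label_particles(body_mask, 8)
  if (n_labels(lab) == 0) stop_input("empty spheroid body mask")
  parts <- measure_particles(lab, pixel_size_um = pixel_size_um)
  main <- parts$label[which.max(parts$area_um2)]
  main_mask <- lab == main
  inside <- function(x, y) {
    r <- round(y); c <- round(x)
    r >= 1 & r <= nrow(main_mask) & c >= 1 & c <= ncol(main_mask) &
      main_mask[cbind(pmin(pmax(r, 1), nrow(main_mask)),
                      pmin(pmax(c, 1), ncol(main_mask)))]
  }
  n_inv <- if (nrow(nuclei_centroids)) {
    sum(!inside(nuclei_centroids$x, nuclei_centroids$y))
  } else 0L
  i <- which(parts$label == main)
  list(area_um2 = parts$area_um2[i], circularity = parts$circularity[i],
       solidity = parts$solidity[i], n_invading = as.integer(n_inv))
}

#' Migration path statistics
#'
#' Total path length (sum of consecutive Euclidean steps) and mean velocity
#' (total distance over elapsed time) for one track.
#'
#' @param path `data.frame` with columns `t_min`, `x_um`, `y_um`; time must
#'   be strictly increasing, with at least 2 samples.
#' @return List: `total_distance_um`, `mean_velocity_um_per_min`.
#' @export
path_statistics <- function(path) {
  if (nrow(path) < 2) stop_input("a path needs at least 2 samples")
  if (any(diff(path$t_min) <= 0)) stop_input("t_min must be strictly increasing")
  steps <- sqrt(diff(path$x_um)^2 + diff(path$y_um)^2)
  total <- sum(steps)
  list(total_distance_um = total,
       mean_velocity_um_per_min = total / (path$t_min[nrow(path)] - path$t_min[1]))
}

#' Read migration tracks exported as CSV
#'
#' TrackMate-export-compatible format: columns `track_id`, `t_min`, `x_um`,
#' `y_um`.
#'
#' @param file CSV path.
#' @return `data.frame` of all samples, ordered by track and time.
#' @export
read_tracks <- function(file) {
  tr <- utils::read.csv(file)
  need <- c("track_id", "t_min", "x_um", "y_um")
  if (!all(need %in% names(tr)))
    stop_input(sprintf("track CSV needs columns: %s", paste(need, collapse = ", ")))
  tr[order(tr$track_id, tr$t_min), ]
}

#' Per-track migration statistics
#'
#' @param tracks `data.frame` as returned by [read_tracks()].
#' @return `data.frame` with one row per track: `track_id`,
#'   `total_distance_um`, `mean_velocity_um_per_min`.
#' @export
track_statistics <- function(tracks) {
  ids <- unique(tracks$track_id)
  out <- lapply(ids, function(id) {
    st <- path_statistics(tracks[tracks$track_id == id, ])
    data.frame(track_id = id, total_distance_um = st$total_distance_um,
               mean_velocity_um_per_min = st$mean_velocity_um_per_min)
  })
  do.call(rbind, out)
}
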