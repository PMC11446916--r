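#' Segment nuclei from the DAPI channel
#'
#' Otsu threshold (8-bit floor 25), hole filling, and removal of objects
#' below `min_area_um2` (default 20 um^2, which excludes micronuclei: the MN
#' size window tops out at 12 um^2).
#'
#' @param dapi DAPI intensity matrix.
#' @param pixel_size_um um/px.
#' @param min_area_um2 Minimum nucleus area (um^2).
#' @param floor_8bit Minimum threshold on the 8-bit scale.
#' @return Nucleus label matrix (see [label_particles()]).
#' @export
segment_nuclei <- function(dapi, pixel_size_um, min_area_um2 = 20,
                           floor_8bit = 25) {
  thr <- auto_threshold(dapi, "otsu", floor_8bit = floor_8bit)
  mask <- dapi > thr
  mask <- EBImage::fillHull(mask * 1) > 0
  lab <- label_particles(mask, connectivity = 8)
  if (n_labels(lab) > 0) {
    area_px <- tabulate(lab[lab > 0], nbins = n_labels(lab))
    keep <- which(area_px * pixel_size_um^2 >= min_area_um2)
    lab[!(lab %in% keep)] <- 0L
    lab <- label_particles(lab > 0, connectivity = 8)
  }
  lab
}

# per-label ring (dilation minus erosion by w px) statistics, looped on
# bounding boxes for speed; pixels of other nuclei are excluded from rings
ring_stats <- function(intensity, nuclei, w_px, stat = mean) {
  nl <- n_labels(nuclei)
  out <- data.frame(nucleus = integer(0), value = numeric(0),
                    truncated = logical(0))
  if (nl == 0) return(out)
  nr <- nrow(nuclei); nc <- ncol(nuclei)
  br <- disc_brush(w_px)
  for (k in seq_len(nl)) {
    idx <- which(nuclei == k)
    rows <- ((idx - 1L) %% nr) + 1L
    cols <- ((idx - 1L) %/% nr) + 1L
    r0 <- max(1L, min(rows) - w_px - 1L); r1 <- min(nr, max(rows) + w_px + 1L)
    c0 <- max(1L, min(cols) - w_px - 1L); c1 <- min(nc, max(cols) + w_px + 1L)
    truncated <- (min(rows) - w_px < 1L) || (max(rows) + w_px > nr) ||
      (min(cols) - w_px < 1L) || (max(cols) + w_px > nc)
    sub <- nuclei[r0:r1, c0:c1]
    obj <- (sub == k) * 1
    ring <- (EBImage::dilate(obj, br) > 0) & !(EBImage::erode(obj, br) > 0)
    ring <- ring & (sub == 0 | sub == k)
    vals <- intensity[r0:r1, c0:c1][ring]
    out[k, ] <- list(k, stat(vals), truncated)
  }
  out
}

#' Per-nucleus nuclear-envelope reference intensity
#'
#' For each nucleus, the mean Emerin intensity over the NE ring, defined as
#' dilation minus erosion of the nucleus mask by `ring_width_um`. Rings of
#' nuclei touching the image border are truncated and flagged.
#'
#' @param emerin Emerin intensity matrix.
#' @param nuclei Nucleus label matrix.
#' @param pixel_size_um um/px.
#' @param ring_width_um Half-width of the ring band on each side of the
#'   nuclear boundary (default 0.9 um).
#' @return `data.frame` with columns `nucleus`, `ne_mean`, `truncated`.
#' @export
ne_reference <- function(emerin, nuclei, pixel_size_um, ring_width_um = 0.9) {
  w_px <- max(1L, as.integer(round(ring_width_um / pixel_size_um)))
  out <- ring_stats(emerin, nuclei, w_px, stat = mean)
  names(out)[2] <- "ne_mean"
  out
}

#' Detect micronucleus candidates in the Emerin channel
#'
#' Otsu threshold (8-bit floor 25) on the Emerin channel, removal of pixels
#' overlapping nucleus labels, 8-connected labelling, then a size gate
#' keeping particles with area in `size_gate_um2` (default 0.2--12 um^2, the
#' biological MN size window). Particles touching a nucleus label
#' (8-adjacency) are excluded: a candidate that overlapped a nucleus by even
#' one pixel leaves a remainder adjacent to it, and NE-rim halo residue
#' always borders its nucleus; micronuclei proper are separate structures.
#'
#' @param emerin Emerin intensity matrix.
#' @param nuclei Nucleus label matrix.
#' @param pixel_size_um um/px.
#' @param size_gate_um2 Length-2 area gate in um^2.
#' @param floor_8bit Minimum threshold on the 8-bit scale.
#' @return Particle `data.frame` (see [measure_particles()]) with a
#'   `mean_emerin` column; attribute `threshold` records the resolved
#'   threshold.
#' @export
detect_mn <- function(emerin, nuclei, pixel_size_um,
                      size_gate_um2 = c(0.2, 12), floor_8bit = 25) {
  thr <- auto_threshold(emerin, "otsu", floor_8bit = floor_8bit)
  mask <- emerin > thr
  mask[nuclei > 0] <- FALSE
  lab <- label_particles(mask, connectivity = 8)
  if (n_labels(lab) > 0 && any(nuclei > 0)) {
    near_nuc <- EBImage::dilate((nuclei > 0) * 1, disc_brush(1)) > 0
    touching <- unique(lab[lab > 0 & near_nuc])
    if (length(touching)) lab[lab %in% touching] <- 0L
    lab <- label_particles(lab > 0, connectivity = 8)
  }
  parts <- measure_particles(lab, list(emerin = emerin), pixel_size_um)
  parts <- parts[parts$area_um2 >= size_gate_um2[1] &
                   parts$area_um2 <= size_gate_um2[2], , drop = FALSE]
  rownames(parts) <- NULL
  attr(parts, "threshold") <- as.numeric(thr)
  parts
}

#' Classify micronucleus candidates as Emerin-rich or Emerin-NE-level
#'
#' Each candidate is assigned to the nucleus with the nearest border within
#' `d_max_um`; candidates with no nucleus in range are dropped (their count
#' is reported in attribute `n_dropped`). The candidate's mean Emerin is
#' divided by the assigned nucleus's NE reference; class is `rich` when the
#' ratio is at least `rich_ratio`, else `ne_level`.
#'
#' @param candidates Particle table from [detect_mn()] (needs `mean_emerin`).
#' @param ne_ref NE reference table from [ne_reference()].
#' @param nuclei Nucleus label matrix.
#' @param pixel_size_um um/px.
#' @param rich_ratio Classification threshold on the MN/NE intensity ratio
#'   (default 1.2; rich MN typically sit near 2).
#' @param d_max_um Maximum centroid-to-nucleus-border distance for
#'   assignment.
#' @return `data.frame` of MN records: particle columns plus `nucleus_id`,
#'   `dist_um`, `emerin_ratio_to_ne`, `mn_class`; attribute `n_dropped`.
#' @export
classify_mn <- function(candidates, ne_ref, nuclei, pixel_size_um,
                        rich_ratio = 1.2, d_max_um = 15) {
  out <- cbind(candidates[0, , drop = FALSE],
               data.frame(nucleus_id = integer(0), dist_um = numeric(0),
                          emerin_ratio_to_ne = numeric(0),
                          mn_class = character(0)))
  if (nrow(candidates) == 0 || nrow(ne_ref) == 0) {
    attr(out, "n_dropped") <- nrow(candidates)
    return(out)
  }
  # nucleus border pixels: label pixels with a 4-neighbour outside the label
  nr <- nrow(nuclei); nc <- ncol(nuclei)
  pad <- matrix(0L, nr + 2, nc + 2); pad[2:(nr + 1), 2:(nc + 1)] <- nuclei
  core <- pad[2:(nr + 1), 2:(nc + 1)]
  is_border <- core > 0 & (pad[1:nr, 2:(nc + 1)] != core |
                             pad[3:(nr + 2), 2:(nc + 1)] != core |
                             pad[2:(nr + 1), 1:nc] != core |
                             pad[2:(nr + 1), 3:(nc + 2)] != core)
  bidx <- which(is_border)
  blab <- core[bidx]
  brow <- ((bidx - 1L) %% nr) + 1L
  bcol <- ((bidx - 1L) %/% nr) + 1L

  n_cand <- nrow(candidates)
  nucleus_id <- integer(n_cand); dist_um <- numeric(n_cand)
  for (i in seq_len(n_cand)) {
    d2 <- (brow - candidates$y[i])^2 + (bcol - candidates$x[i])^2
    j <- which.min(d2)
    nucleus_id[i] <- blab[j]
    dist_um[i] <- sqrt(d2[j]) * pixel_size_um
  }
  keep <- dist_um <= d_max_um & nucleus_id %in% ne_ref$nucleus
  out <- candidates[keep, , drop = FALSE]
  out$nucleus_id <- nucleus_id[keep]
  out$dist_um <- dist_um[keep]
  ref <- ne_ref$ne_mean[match(out$nucleus_id, ne_ref$nucleus)]
  out$emerin_ratio_to_ne <- out$mean_emerin / ref
  out$mn_class <- ifelse(out$emerin_ratio_to_ne >= rich_ratio, "rich", "ne_level")
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Summarize a field: Emerin-rich MN per nucleus
#'
#' @param records MN record table from [classify_mn()].
#' @param n_nuclei Number of nuclei in the field (must be at least 1).
#' @return Object of class `field_summary`: `n_nuclei`, `n_rich`,
#'   `n_ne_level`, `rich_per_nucleus`.
#' @export
summarize_field <- function(records, n_nuclei) {
  if (n_nuclei < 1) stop_input("rich_per_nucleus undefined: n_nuclei = 0")
  n_rich <- sum(records$mn_class == "rich")
  n_ne <- sum(records$mn_class == "ne_level")
  structure(list(n_nuclei = as.integer(n_nuclei), n_rich = n_rich,
                 n_ne_level = n_ne, rich_per_nucleus = n_rich / n_nuclei),
            class = "field_summary")
}

#' @export
print.field_summary <- function(x, ...) {
  cat(sprintf("field: %d nuclei, %d Emerin-rich MN, %d NE-level MN; rich MN/nuclei = %.4f\n",
              x$n_nuclei, x$n_rich, x$n_ne_level, x$rich_per_nucleus))
  invisible(x)
}

#' Cohort stratification cutoffs for Emerin-rich MN per nucleus
#'
#' Defaults are the published patient-cohort percentiles of Emerin-rich
#' MN/nuclei (25th percentile 0.07538, median 0.1280, 75th percentile
#' 0.1861) and the tumor-cell fraction above which a sample counts as
#' Emerin-negative (0.85).
#'
#' @param p25,median,p75 Quartile cutoffs (must increase).
#' @param neg_cell_fraction Fraction of tumor cells with negative/low Emerin
#'   defining an Emerin-negative sample.
#' @return Object of class `strat_cutoffs`.
#' @export
stratification_cutoffs <- function(p25 = 0.07538, median = 0.1280,
                                   p75 = 0.1861, neg_cell_fraction = 0.85) {
  if (!(p25 < median && median < p75))
    stop_config("cutoffs must satisfy p25 < median < p75")
  if (!(neg_cell_fraction > 0 && neg_cell_fraction < 1))
    stop_config("neg_cell_fraction must be in (0, 1)")
  structure(list(p25 = p25, median = median, p75 = p75,
                 neg_cell_fraction = neg_cell_fraction),
            class = "strat_cutoffs")
}

#' Stratify per-sample Emerin-rich MN/nuclei values by quartile
#'
#' Assigns each value to one of the half-open intervals `[0, p25)`,
#' `[p25, median)`, `[median, p75)`, `[p75, Inf)`: a value equal to a cutoff
#' goes to the upper class. In `data_driven` mode the quartiles are computed
#' from the input (linear-interpolation quantiles).
#'
#' @param values Non-negative numeric vector.
#' @param cutoffs A [stratification_cutoffs()] object (used in `fixed` mode).
#' @param mode `"fixed"` or `"data_driven"`.
#' @return Factor with levels `"<p25"`, `"p25-median"`, `"median-p75"`,
#'   `">=p75"`.
#' @export
stratify <- function(values, cutoffs = stratification_cutoffs(),
                     mode = c("fixed", "data_driven")) {
  mode <- match.arg(mode)
  if (length(values) == 0) stop_input("values must be non-empty")
  if (any(values < 0)) stop_input("values must be non-negative")
  if (mode == "data_driven") {
    q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    cuts <- q
  } else {
    cuts <- c(cutoffs$p25, cutoffs$median, cutoffs$p75)
  }
  lev <- c("<p25", "p25-median", "median-p75", ">=p75")
  cls <- findInterval(values, cuts, left.open = FALSE) + 1L
  factor(lev[cls], levels = lev)
}

#' Classify a sample's Emerin phenotype as normal or pauperized
#'
#' A sample is pauperized when more than `neg_cell_fraction` of its tumor
#' cells show negative/low Emerin staining, or when its Emerin-rich
#' MN/nuclei value reaches the 75th-percentile cutoff.
#'
#' @param frac_low_cells Fraction of tumor cells with negative/low Emerin
#'   (in \[0, 1\]).
#' @param rich_per_nucleus Emerin-rich MN per nucleus.
#' @param cutoffs A [stratification_cutoffs()] object.
#' @return Character vector, `"pauperized"` or `"normal"` (vectorized).
#' @export
classify_phenotype <- function(frac_low_cells, rich_per_nucleus,
                               cutoffs = stratification_cutoffs()) {
  if (any(frac_low_cells < 0 | frac_low_cells > 1))
    stop_input("frac_low_cells must be in [0, 1]")
  ifelse(frac_low_cells > cutoffs$neg_cell_fraction |
           rich_per_nucleus >= cutoffs$p75, "pauperized", "normal")
}

#' Quantify a field end-to-end
#'
#' Runs [segment_nuclei()], [ne_reference()], [detect_mn()], [classify_mn()]
#' and [summarize_field()] with the given settings.
#'
#' @param field A [field_image()] with `dapi` and `emerin` channels.
#' @param min_area_um2,size_gate_um2,ring_width_um,rich_ratio,d_max_um,floor_8bit
#'   Stage parameters; see the stage functions.
#' @return List: `summary` (a `field_summary`), `records`, `nuclei` (label
#'   matrix), `ne_ref`.
#' @export
quantify_field <- function(field, min_area_um2 = 20,
                           size_gate_um2 = c(0.2, 12), ring_width_um = 0.9,
                           rich_ratio = 1.2, d_max_um = 15, floor_8bit = 25) {
  stopifnot(inherits(field, "field_image"))
  if (!all(c("dapi", "emerin") %in% names(field$channels)))
    stop_input("field must have 'dapi' and 'emerin' channels")
  px <- field$pixel_size_um
  nuclei <- segment_nuclei(field$channels$dapi, px, min_area_um2 = min_area_um2,
                           floor_8bit = floor_8bit)
  ref <- ne_reference(field$channels$emerin, nuclei, px,
                      ring_width_um = ring_width_um)
  cand <- detect_mn(field$channels$emerin, nuclei, px,
                    size_gate_um2 = size_gate_um2, floor_8bit = floor_8bit)
  rec <- classify_mn(cand, ref, nuclei, px, rich_ratio = rich_ratio,
                     d_max_um = d_max_um)
  list(summary = summarize_field(rec, n_labels(nuclei)), records = rec,
       nuclei = nuclei, ne_ref = ref)
}

#' Match detections against planted ground truth
#'
#' Greedy nearest matching of planted MN centroids to detected particle
#' centroids within `tol_um`; each detection matches at most one planted
#' object.
#'
#' @param truth_mn Ground-truth MN table from [generate_field()] (`x`, `y`
#'   in px, `class`).
#' @param detected Particle or MN-record table (`x`, `y` in px; `mn_class`
#'   optional).
#' @param pixel_size_um um/px.
#' @param tol_um Matching radius in um (default 2).
#' @return List: `recall`, `precision`, `n_matched`, `n_truth`,
#'   `n_detected`, `class_agreement` (fraction of matched pairs with equal
#'   class; `NA` if classes unavailable).
#' @export
match_ground_truth <- function(truth_mn, detected, pixel_size_um, tol_um = 2) {
  n_t <- nrow(truth_mn); n_d <- nrow(detected)
  if (n_t == 0 || n_d == 0)
    return(list(recall = if (n_t == 0) NA_real_ else 0,
                precision = if (n_d == 0) NA_real_ else 0,
                n_matched = 0L, n_truth = n_t, n_detected = n_d,
                class_agreement = NA_real_))
  d <- outer(truth_mn$y, detected$y, "-")^2 + outer(truth_mn$x, detected$x, "-")^2
  d <- sqrt(d) * pixel_size_um
  used <- rep(FALSE, n_d)
  match_j <- rep(NA_integer_, n_t)
  ord <- order(apply(d, 1, min))
  for (i in ord) {
    dd <- d[i, ]; dd[used] <- Inf
    j <- which.min(dd)
    if (dd[j] <= tol_um) { match_j[i] <- j; used[j] <- TRUE }
  }
  n_m <- sum(!is.na(match_j))
  agree <- NA_real_
  if (!is.null(detected$mn_class) && n_m > 0) {
    ok <- !is.na(match_j)
    agree <- mean(truth_mn$class[ok] == detected$mn_class[match_j[ok]])
  }
  list(recall = n_m / n_t, precision = n_m / n_d, n_matched = n_m,
       n_truth = n_t, n_detected = n_d, class_agreement = agree)
}
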