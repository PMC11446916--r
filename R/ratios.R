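# Defined intensity-ratio statistics: DAPI content ratio (MN vs nucleus),
# NE/cytoplasm Emerin pauperization ratio, and MN/NE Emerin ratio.

ratio_result <- function(value, numerator_mean, denominator_stat, masks_used) {
  structure(list(value = value, numerator_mean = numerator_mean,
                 denominator_stat = denominator_stat, masks_used = masks_used),
            class = "ratio_result")
}

#' @export
print.ratio_result <- function(x, ...) {
  cat(sprintf("ratio %.4f (num %.4g / den %.4g; %s)\n", x$value,
              x$numerator_mean, x$denominator_stat, x$masks_used))
  invisible(x)
}

mask_mean <- function(img, mask, what) {
  if (!any(mask)) stop_input(sprintf("empty %s mask", what))
  mean(img[mask])
}

#' DAPI content ratio of a micronucleus relative to its nucleus
#'
#' Mean DAPI over the MN mask divided by mean DAPI over the parent nucleus
#' mask; a readout of relative DNA content. When masks are derived
#' internally elsewhere in the pipeline, the DAPI channel is segmented with
#' Otsu (8-bit floor 25).
#'
#' @param dapi DAPI intensity matrix.
#' @param mn_mask,nucleus_mask Logical masks.
#' @return A `ratio_result`.
#' @export
dapi_content_ratio <- function(dapi, mn_mask, nucleus_mask) {
  num <- mask_mean(dapi, mn_mask, "micronucleus")
  den <- mask_mean(dapi, nucleus_mask, "nucleus")
  if (den <= 0) stop_input("zero nucleus mean: ratio undefined")
  ratio_result(num / den, num, den, "mn/nucleus DAPI")
}

#' NE/cytoplasm Emerin pauperization ratio
#'
#' Mean Emerin over the NE ring (dilation minus erosion of the nucleus mask
#' by `ring_width_um`) divided by the median Emerin over a cytoplasmic
#' annulus extending from `ring_width_um` to `ring_width_um +
#' cyto_annulus_um` beyond the nucleus, restricted to the segmented cell
#' region. When `cell_mask` is `NULL` the cell is delimited by an Intermodes
#' threshold (8-bit floor 25) on the Emerin channel.
#'
#' @param emerin Emerin intensity matrix (one cell).
#' @param nucleus_mask Logical nucleus mask.
#' @param pixel_size_um um/px.
#' @param ring_width_um NE ring half-width (default 0.9 um).
#' @param cyto_annulus_um Cytoplasmic annulus depth beyond the ring
#'   (default 3 um).
#' @param cell_mask Optional logical cell-region mask.
#' @param floor_8bit 8-bit threshold floor for internal cell segmentation.
#' @return A `ratio_result`.
#' @export
ne_cytoplasm_ratio <- function(emerin, nucleus_mask, pixel_size_um,
                               ring_width_um = 0.9, cyto_annulus_um = 3,
                               cell_mask = NULL, floor_8bit = 25) {
  if (!any(nucleus_mask)) stop_input("empty nucleus mask")
  if (is.null(cell_mask)) {
    thr <- auto_threshold(emerin, "intermodes", floor_8bit = floor_8bit)
    cell_mask <- emerin > thr
    cell_mask <- EBImage::fillHull(cell_mask * 1) > 0
  }
  w <- max(1L, as.integer(round(ring_width_um / pixel_size_um)))
  a <- max(w + 1L, as.integer(round((ring_width_um + cyto_annulus_um) / pixel_size_um)))
  m <- nucleus_mask * 1
  ring <- (EBImage::dilate(m, disc_brush(w)) > 0) & !(EBImage::erode(m, disc_brush(w)) > 0)
  annulus <- (EBImage::dilate(m, disc_brush(a)) > 0) &
    !(EBImage::dilate(m, disc_brush(w)) > 0) & cell_mask
  if (!any(annulus))
    stop_input("empty cytoplasmic annulus (cell cropped or too small)")
  num <- mean(emerin[ring])
  den <- stats::median(emerin[annulus])
  if (den <= 0) stop_input("non-positive cytoplasm median: ratio undefined")
  ratio_result(num / den, num, den,
               sprintf("NE ring %.3g um / cytoplasm annulus %.3g um (median)",
                       ring_width_um, cyto_annulus_um))
}

#' Micronucleus / nuclear-envelope Emerin intensity ratio
#'
#' Mean Emerin over the MN mask divided by mean Emerin over the NE ring
#' mask.
#'
#' @param emerin Emerin intensity matrix.
#' @param mn_mask,ne_ring_mask Logical masks.
#' @return A `ratio_result`.
#' @export
mn_ne_ratio <- function(emerin, mn_mask, ne_ring_mask) {
  num <- mask_mean(emerin, mn_mask, "micronucleus")
  den <- mask_mean(emerin, ne_ring_mask, "NE ring")
  if (den <= 0) stop_input("zero NE ring mean: ratio undefined")
  ratio_result(num / den, num, den, "mn/NE Emerin")
}
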