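#' Parameters for synthetic phantom fields
#'
#' Describes a widefield-like 2-D field of elliptical nuclei whose nuclear
#' envelope (NE) carries an Emerin rim, plus small extranuclear micronuclei
#' (MN) of two classes: "rich" (Emerin about twice the NE level, reduced DAPI)
#' and "ne_level" (Emerin at the NE level). Defaults emulate a 20x widefield
#' acquisition at 0.3 um/px with 20 nuclei and 4 + 4 planted MN per field.
#'
#' @param field_size_px Integer pair, image rows x columns.
#' @param pixel_size_um um per pixel.
#' @param n_nuclei Number of nuclei to place.
#' @param nucleus_axes_um Range (um) from which each ellipse semi-axis is
#'   drawn uniformly.
#' @param ne_rim_width_um Full width (um) of the painted NE rim, centred on
#'   the nuclear boundary.
#' @param n_mn_rich,n_mn_ne Planted micronuclei counts per class.
#' @param mn_area_um2_range Range (um^2) of planted MN areas; must lie within
#'   the 0.2--12 um^2 biological size window.
#' @param mn_max_dist_um Maximum distance (um) from an MN centre to the
#'   nearest nuclear boundary; micronuclei arise from, and stay near, a
#'   parent nucleus (default 12 um).
#' @param rich_emerin_factor Ratio of rich-MN Emerin intensity to the NE rim
#'   intensity (default 2: rich MN stain about twice the NE level).
#' @param ne_level_emerin_factor Same ratio for NE-level MN (default 1).
#' @param rich_dapi_factor MN-to-nucleus DAPI intensity ratio for rich MN
#'   (default 0.5, the reduced DNA content of the rich class).
#' @param ne_dapi_factor DAPI factor for NE-level MN (default 1).
#' @param noise_sd Additive Gaussian noise SD (intensity units).
#' @param background Constant background offset (intensity units).
#' @param dapi_nucleus Nuclear DAPI intensity.
#' @param ne_emerin NE rim Emerin intensity (the reference level).
#' @param emerin_nucleoplasm Intranuclear Emerin intensity.
#' @param seed RNG seed; identical parameters and seed give bit-identical
#'   fields.
#' @return An object of class `phantom_params`.
#' @export
phantom_params <- function(field_size_px = c(512L, 512L),
                           pixel_size_um = 0.3,
                           n_nuclei = 20L,
                           nucleus_axes_um = c(4, 7),
                           ne_rim_width_um = 1.8,
                           n_mn_rich = 4L,
                           n_mn_ne = 4L,
                           mn_area_um2_range = c(1, 6),
                           mn_max_dist_um = 12,
                           rich_emerin_factor = 2,
                           ne_level_emerin_factor = 1,
                           rich_dapi_factor = 0.5,
                           ne_dapi_factor = 1,
                           noise_sd = 5,
                           background = 10,
                           dapi_nucleus = 150,
                           ne_emerin = 100,
                           emerin_nucleoplasm = 20,
                           seed = 1L) {
  p <- as.list(environment())
  if (any(c(p$n_nuclei, p$n_mn_rich, p$n_mn_ne) < 0))
    stop_config("object counts must be non-negative")
  if (!(p$rich_emerin_factor > p$ne_level_emerin_factor &&
        p$ne_level_emerin_factor >= 0))
    stop_config("need rich_emerin_factor > ne_level_emerin_factor >= 0")
  if (p$mn_area_um2_range[1] < 0.2 || p$mn_area_um2_range[2] > 12)
    stop_config("mn_area_um2_range must lie within [0.2, 12] um^2")
  if (p$mn_max_dist_um <= 0) stop_config("mn_max_dist_um must be positive")
  if (p$pixel_size_um <= 0) stop_config("pixel_size_um must be positive")
  if (any(p$field_size_px < 16)) stop_config("field too small")
  structure(p, class = "phantom_params")
}

# disc structuring element of pixel radius r
disc_brush <- function(r) EBImage::makeBrush(2L * as.integer(r) + 1L, "disc")

# ellipse mask on an integer pixel grid
ellipse_mask <- function(rr, cc, cy, cx, a_px, b_px, angle) {
  dy <- outer(rr - cy, rep(1, length(cc)))
  dx <- outer(rep(1, length(rr)), cc - cx)
  u <- (dx * cos(angle) + dy * sin(angle)) / a_px
  v <- (-dx * sin(angle) + dy * cos(angle)) / b_px
  (u^2 + v^2) <= 1
}

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a phantom field with ground truth
#'
#' Paints nuclei (DAPI interior plus an Emerin NE rim) and extranuclear
#' micronuclei of the two Emerin classes, then adds Gaussian noise (clipped
#' at zero). Objects are placed by rejection sampling (at most 1000 attempts
#' per object) with no overlap between any painted structures; a 2 px
#' clearance is kept between objects.
#'
#' @param params A [phantom_params()] object.
#' @return List with elements `field` (a [field_image()] with `dapi` and
#'   `emerin` channels) and `truth` (list of data frames `nuclei` and `mn`;
#'   coordinates are pixel-centred, x = column, y = row).
#' @export
generate_field <- function(params) {
  stopifnot(inherits(params, "phantom_params"))
  p <- params
  with_seed(p$seed, {
    nr <- as.integer(p$field_size_px[1]); nc <- as.integer(p$field_size_px[2])
    px <- p$pixel_size_um
    dapi <- matrix(p$background, nr, nc)
    emerin <- matrix(p$background, nr, nc)
    occ <- matrix(FALSE, nr, nc)
    gap <- 2L
    rim_h <- max(1L, as.integer(round(p$ne_rim_width_um / 2 / px)))

    nuclei <- data.frame(x = numeric(0), y = numeric(0), a_um = numeric(0),
                         b_um = numeric(0), angle = numeric(0))
    for (i in seq_len(p$n_nuclei)) {
      placed <- FALSE
      for (att in seq_len(1000L)) {
        a_um <- stats::runif(1, p$nucleus_axes_um[1], p$nucleus_axes_um[2])
        b_um <- stats::runif(1, p$nucleus_axes_um[1], p$nucleus_axes_um[2])
        angle <- stats::runif(1, 0, pi)
        a_px <- a_um / px; b_px <- b_um / px
        ext <- ceiling(max(a_px, b_px)) + rim_h + gap + 1L
        if (2 * ext + 2 >= min(nr, nc))
          stop_placement(sprintf("nucleus %d does not fit in the field", i))
        cy <- stats::runif(1, ext + 1, nr - ext)
        cx <- stats::runif(1, ext + 1, nc - ext)
        rr <- max(1L, floor(cy - ext)):min(nr, ceiling(cy + ext))
        cc <- max(1L, floor(cx - ext)):min(nc, ceiling(cx + ext))
        ell <- ellipse_mask(rr, cc, cy, cx, a_px, b_px, angle)
        dil <- EBImage::dilate(ell * 1, disc_brush(rim_h + gap)) > 0
        if (any(occ[rr, cc] & dil)) next
        ero <- EBImage::erode(ell * 1, disc_brush(rim_h)) > 0
        rim_out <- EBImage::dilate(ell * 1, disc_brush(rim_h)) > 0
        rim <- rim_out & !ero
        sub_d <- dapi[rr, cc]; sub_e <- emerin[rr, cc]
        sub_d[ell] <- p$dapi_nucleus
        sub_e[ell & !rim] <- p$emerin_nucleoplasm
        sub_e[rim] <- p$ne_emerin
        dapi[rr, cc] <- sub_d; emerin[rr, cc] <- sub_e
        occ[rr, cc] <- occ[rr, cc] | dil
        nuclei[i, ] <- list(cx, cy, a_um, b_um, angle)
        placed <- TRUE
        break
      }
      if (!placed) stop_placement(sprintf("could not place nucleus %d", i))
    }

    n_mn <- p$n_mn_rich + p$n_mn_ne
    mn <- data.frame(x = numeric(0), y = numeric(0), area_um2 = numeric(0),
                     class = character(0), emerin_factor = numeric(0),
                     dapi_factor = numeric(0))
    for (j in seq_len(n_mn)) {
      is_rich <- j <= p$n_mn_rich
      cls <- if (is_rich) "rich" else "ne_level"
      ef <- if (is_rich) p$rich_emerin_factor else p$ne_level_emerin_factor
      df <- if (is_rich) p$rich_dapi_factor else p$ne_dapi_factor
      # approximate distance (um) from a point to the nearest nuclear boundary
      border_dist_um <- function(cy, cx) {
        d <- Inf
        for (k in seq_len(nrow(nuclei))) {
          dy <- (cy - nuclei$y[k]) * px; dx <- (cx - nuclei$x[k]) * px
          ang <- nuclei$angle[k]
          u <- dx * cos(ang) + dy * sin(ang)
          v <- -dx * sin(ang) + dy * cos(ang)
          rho <- sqrt((u / nuclei$a_um[k])^2 + (v / nuclei$b_um[k])^2)
          if (rho > 0) d <- min(d, abs(rho - 1) * sqrt(u^2 + v^2) / rho)
        }
        d
      }
      placed <- FALSE
      for (att in seq_len(1000L)) {
        area <- stats::runif(1, p$mn_area_um2_range[1], p$mn_area_um2_range[2])
        r_px <- max(1, sqrt(area / pi) / px)
        ext <- ceiling(r_px) + gap + 1L
        cy <- stats::runif(1, ext + 1, nr - ext)
        cx <- stats::runif(1, ext + 1, nc - ext)
        if (nrow(nuclei) > 0 && border_dist_um(cy, cx) > p$mn_max_dist_um) next
        rr <- max(1L, floor(cy - ext)):min(nr, ceiling(cy + ext))
        cc <- max(1L, floor(cx - ext)):min(nc, ceiling(cx + ext))
        disk <- ellipse_mask(rr, cc, cy, cx, r_px, r_px, 0)
        dil <- EBImage::dilate(disk * 1, disc_brush(gap)) > 0
        if (any(occ[rr, cc] & dil)) next
        sub_d <- dapi[rr, cc]; sub_e <- emerin[rr, cc]
        sub_d[disk] <- df * p$dapi_nucleus
        sub_e[disk] <- ef * p$ne_emerin
        dapi[rr, cc] <- sub_d; emerin[rr, cc] <- sub_e
        occ[rr, cc] <- occ[rr, cc] | dil
        mn[nrow(mn) + 1L, ] <- list(cx, cy, sum(disk) * px^2, cls, ef, df)
        placed <- TRUE
        break
      }
      if (!placed)
        stop_placement(sprintf("could not place micronucleus %d (%s)", j, cls))
    }

    if (p$noise_sd > 0) {
      dapi <- pmax(dapi + matrix(stats::rnorm(nr * nc, 0, p$noise_sd), nr, nc), 0)
      emerin <- pmax(emerin + matrix(stats::rnorm(nr * nc, 0, p$noise_sd), nr, nc), 0)
    }
    list(field = field_image(list(dapi = dapi, emerin = emerin), px,
                             provenance = sprintf("phantom seed %s", p$seed)),
         truth = list(nuclei = nuclei, mn = mn))
  })
}
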