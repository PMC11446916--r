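# Pipeline orchestration: configuration, end-to-end stages, reporting.

#' Pipeline run configuration
#'
#' A single serializable document holding every tunable of the image stages
#' and the stratification cutoffs; defaults equal the stage-level defaults.
#' Round-trips losslessly through JSON ([write_config()] / [read_config()]).
#'
#' @param pixel_size_um um/px of the input images.
#' @param channels Named channel-to-page map for plain TIFFs (1-based).
#' @param floor_8bit 8-bit threshold floor used by the image stages.
#' @param min_area_um2 Minimum nucleus area.
#' @param size_gate_um2 MN area gate (um^2).
#' @param ring_width_um NE ring half-width.
#' @param rich_ratio MN/NE ratio above which an MN is Emerin-rich.
#' @param d_max_um Maximum MN-to-nucleus assignment distance.
#' @param cutoffs A [stratification_cutoffs()] object.
#' @param seed RNG seed for the simulate stage.
#' @param n_fields Number of phantom fields for the simulate stage.
#' @return Object of class `emdmn_config` (a named list).
#' @export
emdmn_config <- function(pixel_size_um = 0.3,
                         channels = c(dapi = 1, emerin = 2),
                         floor_8bit = 25,
                         min_area_um2 = 20,
                         size_gate_um2 = c(0.2, 12),
                         ring_width_um = 0.9,
                         rich_ratio = 1.2,
                         d_max_um = 15,
                         cutoffs = stratification_cutoffs(),
                         seed = 1,
                         n_fields = 5) {
  cfg <- list(pixel_size_um = as.numeric(pixel_size_um),
              channels = vapply(channels, as.numeric, numeric(1)),
              floor_8bit = as.numeric(floor_8bit),
              min_area_um2 = as.numeric(min_area_um2),
              size_gate_um2 = as.numeric(size_gate_um2),
              ring_width_um = as.numeric(ring_width_um),
              rich_ratio = as.numeric(rich_ratio),
              d_max_um = as.numeric(d_max_um),
              cutoffs = list(p25 = as.numeric(cutoffs$p25),
                             median = as.numeric(cutoffs$median),
                             p75 = as.numeric(cutoffs$p75),
                             neg_cell_fraction = as.numeric(cutoffs$neg_cell_fraction)),
              seed = as.numeric(seed),
              n_fields = as.numeric(n_fields))
  structure(cfg, class = "emdmn_config")
}

#' @rdname emdmn_config
#' @param config An `emdmn_config` object.
#' @param path JSON file path.
#' @export
write_config <- function(config, path) {
  out <- unclass(config)
  out$channels <- as.list(out$channels)  # keep channel names as JSON keys
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname emdmn_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  defaults <- emdmn_config()
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown))
    stop_config(sprintf("unknown config field(s): %s", paste(unknown, collapse = ", ")))
  args <- utils::modifyList(unclass(defaults), raw)
  args$channels <- unlist(args$channels)
  args$cutoffs <- do.call(stratification_cutoffs, as.list(args$cutoffs))
  do.call(emdmn_config, args)
}

pipeline_log <- function(lines, file = NULL, quiet = FALSE) {
  if (!quiet) message(paste(lines, collapse = "\n"))
  if (!is.null(file)) cat(lines, file = file, sep = "\n", append = TRUE)
}

#' Run pipeline stages over a set of inputs
#'
#' Stages: `"simulate"` writes `n_fields` phantom fields (TIFF + ground-truth
#' JSON) under `out_dir/fields`; `"quantify"` runs the MN workflow over a
#' directory or vector of TIFFs, writing `fields.csv` (per-field counts,
#' rich MN/nuclei and quartile class), `mn_records.csv` and `summary.json`
#' (package version, config echo, resolved thresholds, and -- after a
#' simulate/quantify round trip -- the detection concordance against ground
#' truth); `"score"` reads a genes x samples CSV plus a survival CSV and
#' writes the score table and survival association. Identical config and
#' seed give byte-identical CSV outputs.
#'
#' @param config An [emdmn_config()] object.
#' @param images TIFF directory or character vector of TIFF paths (quantify).
#' @param matrix_file Genes x samples CSV, first column gene identifiers
#'   (score).
#' @param survival_file CSV with columns `sample`, `time`, `event` (score).
#' @param out_dir Output directory (created).
#' @param stages Subset of `c("simulate", "quantify", "score")`.
#' @param quiet Suppress console messages.
#' @return List of per-stage results, invisibly.
#' @export
run_pipeline <- function(config = emdmn_config(), images = NULL,
                         matrix_file = NULL, survival_file = NULL,
                         out_dir = ".", stages = c("simulate", "quantify"),
                         quiet = FALSE) {
  stopifnot(inherits(config, "emdmn_config"))
  bad <- setdiff(stages, c("simulate", "quantify", "score"))
  if (length(bad)) stop_config(sprintf("unknown stage(s): %s", paste(bad, collapse = ", ")))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(out_dir, "run.log")
  if (file.exists(logf)) unlink(logf)
  res <- list()
  summary_json <- list(package_version = as.character(utils::packageVersion("emdmn")),
                       config = unclass(config))

  if ("simulate" %in% stages) {
    fdir <- file.path(out_dir, "fields")
    dir.create(fdir, showWarnings = FALSE)
    truths <- list()
    for (i in seq_len(config$n_fields)) {
      pp <- phantom_params(pixel_size_um = config$pixel_size_um,
                           seed = config$seed + i - 1)
      sim <- generate_field(pp)
      fp <- file.path(fdir, sprintf("field_%03d.tif", i))
      write_field(sim$field, fp)
      jsonlite::write_json(sim$truth, paste0(fp, ".truth.json"),
                           auto_unbox = TRUE, digits = NA, dataframe = "columns")
      truths[[basename(fp)]] <- sim$truth
    }
    pipeline_log(sprintf("simulate: wrote %d field(s) to %s", config$n_fields, fdir),
                 logf, quiet)
    res$simulate <- list(dir = fdir, truths = truths)
    if (is.null(images)) images <- fdir
  }

  if ("quantify" %in% stages) {
    paths <- if (length(images) == 1 && dir.exists(images)) {
      list.files(images, pattern = "\\.tiff?$", full.names = TRUE)
    } else as.character(images)
    if (length(paths) == 0) stop_input("quantify: empty image list")
    missing <- paths[!file.exists(paths)]
    if (length(missing))
      stop_input(sprintf("unreadable input(s): %s", paste(missing, collapse = ", ")))
    rows <- list(); recs <- list(); thresholds <- list()
    recall_num <- 0; recall_den <- 0
    for (fp in sort(paths)) {
      field <- read_field(fp, pixel_size_um = config$pixel_size_um,
                          channel_names = NULL)
      if (!all(c("dapi", "emerin") %in% names(field$channels))) {
        if (max(config$channels) > length(field$channels))
          stop_input(sprintf("channel mismatch in %s", fp))
        names(field$channels)[config$channels] <- names(config$channels)
      }
      q <- quantify_field(field, min_area_um2 = config$min_area_um2,
                          size_gate_um2 = config$size_gate_um2,
                          ring_width_um = config$ring_width_um,
                          rich_ratio = config$rich_ratio,
                          d_max_um = config$d_max_um,
                          floor_8bit = config$floor_8bit)
      s <- q$summary
      cls <- as.character(stratify(s$rich_per_nucleus,
                                   do.call(stratification_cutoffs, config$cutoffs)))
      rows[[fp]] <- data.frame(field = basename(fp), n_nuclei = s$n_nuclei,
                               n_rich = s$n_rich, n_ne_level = s$n_ne_level,
                               rich_per_nucleus = s$rich_per_nucleus,
                               class = cls)
      if (nrow(q$records))
        recs[[fp]] <- cbind(field = basename(fp), q$records)
      thresholds[[basename(fp)]] <- list(
        mn_otsu = attr(q$records, "threshold"))
      tj <- paste0(fp, ".truth.json")
      if (file.exists(tj)) {
        truth <- jsonlite::read_json(tj, simplifyVector = TRUE)
        if (length(truth$mn) && nrow(as.data.frame(truth$mn))) {
          m <- match_ground_truth(as.data.frame(truth$mn), q$records,
                                  config$pixel_size_um)
          recall_num <- recall_num + m$n_matched
          recall_den <- recall_den + m$n_truth
        }
      }
    }
    fields_df <- do.call(rbind, unname(rows))
    utils::write.csv(fields_df, file.path(out_dir, "fields.csv"), row.names = FALSE)
    mn_df <- if (length(recs)) do.call(rbind, unname(recs)) else
      data.frame(field = character(0))
    utils::write.csv(mn_df, file.path(out_dir, "mn_records.csv"), row.names = FALSE)
    summary_json$quantify <- list(n_fields = nrow(fields_df),
                                  n_mn = sum(fields_df$n_rich + fields_df$n_ne_level),
                                  thresholds = thresholds)
    if (recall_den > 0)
      summary_json$quantify$concordance <- recall_num / recall_den
    pipeline_log(sprintf("quantify: %d field(s), %d MN record(s)",
                         nrow(fields_df), nrow(mn_df)), logf, quiet)
    res$quantify <- list(fields = fields_df, records = mn_df,
                         concordance = summary_json$quantify$concordance)
  }

  if ("score" %in% stages) {
    if (is.null(matrix_file) || !file.exists(matrix_file))
      stop_input("score: matrix_file missing or unreadable")
    tab <- utils::read.csv(matrix_file, check.names = FALSE)
    mat <- as.matrix(tab[, -1, drop = FALSE])
    rownames(mat) <- tab[[1]]
    st <- pauperization_score(mat)
    utils::write.csv(st, file.path(out_dir, "scores.csv"), row.names = FALSE)
    summary_json$score <- list(n_samples = nrow(st), q3 = attr(st, "q3"),
                               n_high = sum(st$high_flag))
    res$score <- list(scores = st)
    if (!is.null(survival_file)) {
      if (!file.exists(survival_file)) stop_input("score: survival_file unreadable")
      surv <- utils::read.csv(survival_file)
      surv <- surv[match(st$sample, surv$sample), ]
      sr <- survival_association(surv, st$high_flag)
      summary_json$score$hr <- sr$hr
      summary_json$score$ci95 <- sr$ci95
      summary_json$score$logrank_p <- sr$logrank_p
      res$score$survival <- sr
    }
    pipeline_log(sprintf("score: %d sample(s), %d high", nrow(st), sum(st$high_flag)),
                 logf, quiet)
  }

  jsonlite::write_json(summary_json, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(res)
}
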