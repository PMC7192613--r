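#' Run the full quantitation pipeline over a batch of lanes
#'
#' Sequences calibration, densitometry, quantitation and the binned size
#' distributions for every lane of a study, with control-lane subtraction
#' and replicate summaries.  The batch is driven by a single configuration,
#' supplied as a named list or as the path to a YAML/JSON file with the
#' same structure:
#'
#' \preformatted{
#' ladder: ladder.tsv          # profile path (or supply peaks in code)
#' ladder_sizes: [12000, ...]  # optional, default 1 kb Plus bands
#' empty: empty.tsv            # empty-lane profile path (optional)
#' genome_size: 24000000
#' options: {n_knots: 15, delta_d: 1, window: 3, ratio_threshold: 1.5,
#'           background: linear_baseline, bin_width: 50}
#' d_max: {lane_3: 118}        # optional manual cutoffs per lane
#' lanes:
#'   - {id: lane_1, path: lane1.tsv, strain: WT}
#'   - {id: lane_3, path: lane3.tsv, strain: rnh201, control: lane_1}
#' outdir: results/            # optional; write reports here
#' }
#'
#' Control references are validated before any computation; a dangling
#' control id aborts the run.  Given identical inputs the pipeline is fully
#' deterministic and its file outputs are byte-identical across reruns.
#'
#' @param config named list or path to a YAML/JSON configuration.
#' @param profiles optional named list of [intensity_profile()] objects,
#'   keyed by lane id (and optionally `".ladder"`, `".empty"`), overriding
#'   file paths; useful for in-memory batches.
#' @return An object of class `rnmp_batch`: list with `lanes` (per-lane
#'   results `data.frame`), `summary` (per-strain mean and SEM of `N_net`
#'   and density), `fits` (the `rnmp_fit` objects) and `distributions`.
#' @export
run_pipeline <- function(config, profiles = NULL) {
  if (is.character(config)) {
    config <- if (grepl("\\.ya?ml$", config)) {
      yaml::read_yaml(config)
    } else {
      jsonlite::fromJSON(config, simplifyVector = TRUE,
                         simplifyDataFrame = FALSE)
    }
  }
  stopifnot(is.list(config), !is.null(config$lanes))
  lanes_cfg <- config$lanes
  ids <- vapply(lanes_cfg, function(l) l$id, "")
  if (anyDuplicated(ids)) stop("duplicate lane ids in config", call. = FALSE)
  ctl <- vapply(lanes_cfg, function(l) l$control %||% NA_character_, "")
  bad <- !is.na(ctl) & !(ctl %in% ids)
  if (any(bad)) {
    stop("control lane(s) not defined: ",
         paste(unique(ctl[bad]), collapse = ", "), call. = FALSE)
  }
  get_profile <- function(key, path, lane_id = key) {
    if (!is.null(profiles[[key]])) return(profiles[[key]])
    if (is.null(path)) return(NULL)
    read_profile(path, lane_id = lane_id)
  }
  for (l in lanes_cfg) {
    if (is.null(profiles[[l$id]]) &&
        (is.null(l$path) || !file.exists(l$path))) {
      stop("lane '", l$id, "': profile not found", call. = FALSE)
    }
  }
  opts <- config$options %||% list()
  ladder <- get_profile(".ladder", config$ladder, "ladder")
  if (is.null(ladder)) stop("no ladder supplied", call. = FALSE)
  cal <- if (inherits(ladder, "ladder_calibration")) ladder else {
    fit_ladder(detect_ladder_peaks(
      ladder, config$ladder_sizes %||% ladder_1kb_plus()))
  }
  empty <- get_profile(".empty", config$empty, "empty")
  genome_size <- config$genome_size %||% 24e6

  fits <- list()
  for (l in lanes_cfg) {
    fits[[l$id]] <- rnmp_fit(
      get_profile(l$id, l$path),
      ladder = cal, empty = empty,
      background = opts$background %||% "linear_baseline",
      n_knots = opts$n_knots %||% 15,
      delta_d = opts$delta_d %||% 1.0,
      genome_size = genome_size,
      d_max = config$d_max[[l$id]],
      window = opts$window %||% 3,
      ratio_threshold = opts$ratio_threshold %||% 1.5)
  }
  for (i in seq_along(lanes_cfg)) {
    ci <- lanes_cfg[[i]]$control
    if (!is.null(ci) && !is.na(ci)) {
      fits[[ids[i]]]$estimate <-
        subtract_control(fits[[ids[i]]]$estimate, fits[[ci]]$estimate)
    }
  }
  rows <- lapply(seq_along(lanes_cfg), function(i) {
    f <- fits[[ids[i]]]
    e <- f$estimate
    data.frame(lane_id = ids[i],
               strain = lanes_cfg[[i]]$strain %||% NA_character_,
               a_mm = f$calibration$a, b_mm = f$calibration$b,
               d_max_mm = f$cutoff$d_max_mm,
               sz_min_nt = f$cutoff$sz_min_nt,
               N_prelim = e$N_prelim, N_corr = e$N_corr,
               control = ctl[i], N_net = e$N_net,
               density_per_gb = density_per_gb(e))
  })
  lanes_df <- do.call(rbind, rows)
  with_net <- lanes_df[!is.na(lanes_df$N_net), , drop = FALSE]
  summary_df <- if (nrow(with_net)) {
    sp <- split(with_net, with_net$strain)
    do.call(rbind, lapply(sp, function(g) {
      data.frame(strain = g$strain[1L], n_lanes = nrow(g),
                 N_net_mean = mean(g$N_net),
                 N_net_sem = if (nrow(g) > 1)
                   stats::sd(g$N_net) / sqrt(nrow(g)) else NA_real_,
                 density_mean = mean(g$density_per_gb),
                 density_sem = if (nrow(g) > 1)
                   stats::sd(g$density_per_gb) / sqrt(nrow(g)) else NA_real_)
    }))
  } else NULL
  dists <- lapply(fits, function(f) {
    bin_distribution(f$counts, bin_width = opts$bin_width %||% 50)
  })
  out <- structure(list(lanes = lanes_df, summary = summary_df,
                        fits = fits, distributions = dists,
                        calibration = cal),
                   class = "rnmp_batch")
  if (!is.null(config$outdir)) write_batch(out, config$outdir)
  out
}

# Write per-lane JSON reports, the batch TSV and binned distributions.
write_batch <- function(batch, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(nrow(batch$lanes))) {
    row <- batch$lanes[i, ]
    jsonlite::write_json(
      list(lane_id = row$lane_id, a_mm = row$a_mm, b_mm = row$b_mm,
           d_max_mm = row$d_max_mm, sz_min_nt = row$sz_min_nt,
           N_prelim = row$N_prelim, N_corr = row$N_corr,
           control_lane = row$control, N_net = row$N_net,
           density_per_gb = row$density_per_gb),
      file.path(outdir, paste0(row$lane_id, ".json")),
      auto_unbox = TRUE, digits = NA, na = "null")
  }
  utils::write.table(batch$lanes, file.path(outdir, "batch.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (id in names(batch$distributions)) {
    d <- batch$distributions[[id]]
    utils::write.table(as.data.frame(d),
                       file.path(outdir, paste0(id, "_bins.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(outdir)
}

#' @export
print.rnmp_batch <- function(x, ...) {
  cat(sprintf("rNMP quantitation batch: %d lanes\n", nrow(x$lanes)))
  print(x$lanes, row.names = FALSE, digits = 5)
  if (!is.null(x$summary)) {
    cat("\nPer-strain replicate summary (net counts):\n")
    print(x$summary, row.names = FALSE, digits = 5)
  }
  invisible(x)
}
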