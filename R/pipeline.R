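#' Read a pipeline configuration from YAML
#'
#' @param path YAML file describing a full run; see [run_pipeline()] for
#'   the expected structure.
#' @return a config list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) {
    stop("config file not found: ", path, call. = FALSE)
  }
  yaml::read_yaml(path)
}

#' Run the full analysis pipeline on a simulated cohort
#'
#' Orchestrates every stage end-to-end: simulate behavioural sessions per
#' group (optionally rasterizing to video and re-tracking), compute
#' per-fish behavioural metrics and one-minute time courses, simulate and
#' normalize brain-volume cohorts, quantify region activations against the
#' baseline group, and compare every test group to its reference with
#' Mann-Whitney U tests. All randomness derives from `config$seed`, so a
#' run is reproducible from its config alone.
#'
#' The config is a list (or YAML via [read_pipeline_config()]) with
#' optional `behavior` and `volumes` sections:
#' \describe{
#'   \item{behavior}{`reference` (label of the comparison group), `groups`
#'     (list of `label`, `n`, plus any [behavior_sim_params()] overrides
#'     such as `side_bias` or `freeze_rate_hz`), optional shared `params`
#'     overrides, and `render_videos` (default `FALSE`; when `TRUE` every
#'     session is rasterized and re-tracked instead of scoring the
#'     simulated trajectory directly).}
#'   \item{volumes}{`baseline` (label of the baseline group), `params`
#'     ([volume_sim_params()] overrides), `masks` (region names for
#'     [synthetic_region_masks()]), and `groups` (list of `label`, `n`,
#'     optional `planted_effects` named fold-change list).}
#' }
#'
#' @param config config list.
#' @return object of class `pipeline_report` with elements `behavior`
#'   (`metrics`, `binned`, `comparisons`) and `volumes` (`activation`,
#'   `comparisons`, `group_maps`), plus `seed`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!is.list(config) || is.null(config$behavior) && is.null(config$volumes)) {
    stop("config must provide a 'behavior' and/or 'volumes' section",
         call. = FALSE)
  }
  seed <- as.integer(config$seed %||% 1L)
  report <- list(seed = seed, behavior = NULL, volumes = NULL)
  if (!is.null(config$behavior)) {
    report$behavior <- run_behavior_arm(config$behavior, seed)
  }
  if (!is.null(config$volumes)) {
    report$volumes <- run_volume_arm(config$volumes, seed)
  }
  structure(report, class = "pipeline_report")
}

run_behavior_arm <- function(cfg, seed) {
  if (!length(cfg$groups)) stop("behavior section lists no groups",
                                call. = FALSE)
  render <- isTRUE(cfg$render_videos)
  shared <- cfg$params %||% list()
  metrics <- list(); binned <- list()
  for (gi in seq_along(cfg$groups)) {
    g <- cfg$groups[[gi]]
    if (is.null(g$label) || is.null(g$n)) {
      stop("each behavior group needs 'label' and 'n'", call. = FALSE)
    }
    overrides <- g[setdiff(names(g), c("label", "n"))]
    for (fi in seq_len(g$n)) {
      fish_seed <- seed + gi * 100000L + fi
      args <- utils::modifyList(utils::modifyList(
        list(seed = fish_seed), shared), overrides)
      p <- do.call(behavior_sim_params, args)
      truth <- generate_trajectory(p)
      layout <- layout_from_params(p)
      traj <- if (render) {
        track_video(rasterize_video(truth), layout)
      } else {
        as_trajectory(truth)
      }
      sm <- session_metrics(traj, layout)
      metrics[[length(metrics) + 1]] <- data.frame(
        fish_id = sprintf("%s_%03d", g$label, fi), group = g$label,
        vpi = sm$vpi, sociality = sm$sociality,
        percent_moving = sm$percent_moving,
        percent_freezing = sm$percent_freezing,
        n_valid_frames = sm$n_valid_frames,
        expected_vpi = truth$expected_vpi
      )
      bb <- sm$binned
      bb$fish_id <- sprintf("%s_%03d", g$label, fi)
      bb$group <- g$label
      binned[[length(binned) + 1]] <- bb
    }
  }
  metrics <- do.call(rbind, metrics)
  binned <- do.call(rbind, binned)

  comparisons <- NULL
  ref <- cfg$reference %||% cfg$groups[[1]]$label
  others <- setdiff(unique(metrics$group), ref)
  if (length(others)) {
    ref_df <- metrics[metrics$group == ref, , drop = FALSE]
    comparisons <- do.call(rbind, lapply(others, function(gl) {
      compare_groups(metrics[metrics$group == gl, , drop = FALSE], ref_df,
                     metrics = c("vpi", "percent_moving", "percent_freezing"),
                     group_a = gl, group_b = ref)
    }))
  }
  list(metrics = metrics, binned = binned, comparisons = comparisons,
       reference = ref)
}

run_volume_arm <- function(cfg, seed) {
  if (!length(cfg$groups)) stop("volumes section lists no groups",
                                call. = FALSE)
  shared <- cfg$params %||% list()
  dims <- as.integer(shared$dims %||% c(64, 64, 32))
  mask_names <- unlist(cfg$masks %||% list("PTN", "tectum"))
  masks <- synthetic_region_masks(dims, mask_names)

  cohorts <- list()
  for (gi in seq_along(cfg$groups)) {
    g <- cfg$groups[[gi]]
    if (is.null(g$label)) stop("each volume group needs 'label'",
                               call. = FALSE)
    args <- utils::modifyList(list(
      dims = dims, seed = seed + 500000L + gi * 1000L,
      n_fish_per_group = g$n %||% shared$n_fish_per_group %||% 10L,
      planted_effects = unlist(g$planted_effects %||% list())
    ), shared[setdiff(names(shared), c("dims", "n_fish_per_group"))])
    p <- do.call(volume_sim_params, args)
    cohort <- generate_volume_cohort(p, masks, group_label = g$label)
    cohort$volumes <- lapply(cohort$volumes,
                             function(v) normalize_volume(v)$volume)
    cohorts[[g$label]] <- cohort
  }

  baseline <- cfg$baseline %||% names(cohorts)[1]
  if (!baseline %in% names(cohorts)) {
    stop("baseline group '", baseline, "' not among volume groups",
         call. = FALSE)
  }
  base_vols <- cohorts[[baseline]]$volumes
  others <- setdiff(names(cohorts), baseline)

  activation <- list(); comparisons <- list()
  for (gl in others) {
    for (m in masks) {
      act <- region_activation(cohorts[[gl]]$volumes, base_vols, m,
                               group_label = gl, baseline_label = baseline)
      activation[[length(activation) + 1]] <- data.frame(
        mask = m$name, group = gl, baseline = baseline,
        percent_change = act$percent_change,
        true_fold = unname(cohorts[[gl]]$truth$true_region_folds[m$name]),
        n = act$n, n_baseline = act$n_baseline
      )
      cmp <- mann_whitney_u(act$per_fish_values, act$per_fish_baseline,
                            group_a = gl, group_b = baseline,
                            metric = paste0(m$name, "_mask_mean"))
      comparisons[[length(comparisons) + 1]] <- data.frame(
        metric = cmp$metric, group_a = gl, group_b = baseline,
        n_a = cmp$n_a, n_b = cmp$n_b, u_statistic = cmp$u_statistic,
        p_value = cmp$p_value, method = cmp$method
      )
    }
  }
  group_maps <- lapply(cohorts, function(co) group_mean_map(co$volumes))
  list(activation = do.call(rbind, activation),
       comparisons = do.call(rbind, comparisons),
       group_maps = group_maps, masks = masks, baseline = baseline)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pipeline report (seed", x$seed, ")\n")
  if (!is.null(x$behavior)) {
    m <- x$behavior$metrics
    agg <- stats::aggregate(
      m[, c("vpi", "percent_moving", "percent_freezing")],
      by = list(group = m$group), FUN = mean)
    cat("\nbehaviour (group means):\n")
    print(agg, row.names = FALSE)
    if (!is.null(x$behavior$comparisons)) {
      cat("\nbehaviour comparisons vs", x$behavior$reference, ":\n")
      print(x$behavior$comparisons[, c("metric", "group_a", "p_value")],
            row.names = FALSE)
    }
  }
  if (!is.null(x$volumes)) {
    cat("\nregion activation vs", x$volumes$baseline, ":\n")
    print(x$volumes$activation[, c("mask", "group", "percent_change",
                                   "true_fold")],
          row.names = FALSE)
  }
  invisible(x)
}

#' Write a pipeline report's tables to CSV
#'
#' @param report a `pipeline_report`.
#' @param dir output directory (created if absent).
#' @return character vector of written files, invisibly.
#' @export
write_pipeline_report <- function(report, dir) {
  stopifnot(inherits(report, "pipeline_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  written <- character(0)
  emit <- function(df, name) {
    if (is.null(df)) return()
    p <- file.path(dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    written[[length(written) + 1]] <<- p
  }
  if (!is.null(report$behavior)) {
    emit(report$behavior$metrics, "behavior_metrics.csv")
    emit(report$behavior$binned, "behavior_binned.csv")
    emit(report$behavior$comparisons, "behavior_comparisons.csv")
  }
  if (!is.null(report$volumes)) {
    emit(report$volumes$activation, "region_activation.csv")
    emit(report$volumes$comparisons, "region_comparisons.csv")
  }
  jsonlite::write_json(list(seed = report$seed),
                       file.path(dir, "run_manifest.json"),
                       auto_unbox = TRUE)
  invisible(written)
}
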