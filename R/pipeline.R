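#' Analysis configuration
#'
#' One structured object drives every pipeline run: preprocessing parameters,
#' entropy settings, band definitions, rejection rules, region map, inclusion
#' threshold and output location. Inputs come either from a generative
#' [cohort_design()] (`design`) or from a cohort directory written by
#' [write_cohort()] (`cohort_dir`); exactly one must be supplied at run time.
#'
#' @param design Optional [cohort_design()] used to synthesize subjects on
#'   the fly (subject recordings are generated, processed and discarded one
#'   at a time, so full-scale designs never need to be held in memory).
#' @param cohort_dir Optional path to a cohort directory.
#' @param filter_low,filter_high Broadband filter edges in Hz (defaults 0.1
#'   and 40).
#' @param resample_rate Target rate in Hz after filtering (default 500).
#' @param bands Named list of band definitions (`name`, `low`, `high`);
#'   defaults alpha 8-13 Hz and beta 13-30 Hz.
#' @param entropy An [entropy_params()] object.
#' @param tau_max Largest multiscale-entropy scale (default 20).
#' @param agg_range Scale-aggregate range for statistics (default c(10, 20)).
#' @param rejection A [rejection_rules()] object.
#' @param inclusion_threshold Retained-trial fraction for subject inclusion
#'   (default 0.7, strict).
#' @param region_map Region map for regional statistics.
#' @param rest_window List `start_ms`, `end_ms`, `window_ms`, `baseline_ms`
#'   for resting segmentation.
#' @param task_window List `tmin_ms`, `tmax_ms`, `baseline_ms` for
#'   stimulus-locked segmentation.
#' @param measures Character subset of `c("mse", "band")`: which entropy
#'   measures the task runner computes.
#' @param task_mse_by_condition Compute task-state multiscale entropy per
#'   set-size condition instead of pooled (default FALSE, pooled).
#' @param out_dir Optional output directory; when set, runners write their
#'   tables, manifest and log there.
#' @param seed Seed recorded in the manifest (generation randomness lives in
#'   the design's own seed).
#' @return An `analysis_config` object.
#' @export
analysis_config <- function(design = NULL, cohort_dir = NULL,
                            filter_low = 0.1, filter_high = 40,
                            resample_rate = 500,
                            bands = list(
                              alpha = list(name = "alpha", low = 8, high = 13),
                              beta = list(name = "beta", low = 13, high = 30)),
                            entropy = entropy_params(),
                            tau_max = 20L, agg_range = c(10L, 20L),
                            rejection = rejection_rules(),
                            inclusion_threshold = 0.7,
                            region_map = default_region_map(),
                            rest_window = list(start_ms = 10000,
                                               end_ms = 180000,
                                               window_ms = 10000,
                                               baseline_ms = 500),
                            task_window = list(tmin_ms = -200,
                                               tmax_ms = 3000,
                                               baseline_ms = 200),
                            measures = c("mse", "band"),
                            task_mse_by_condition = FALSE,
                            out_dir = NULL, seed = 1L) {
  if (!is.null(design)) stopifnot(inherits(design, "cohort_design"))
  measures <- match.arg(measures, c("mse", "band"), several.ok = TRUE)
  structure(list(design = design, cohort_dir = cohort_dir,
                 filter_low = filter_low, filter_high = filter_high,
                 resample_rate = resample_rate, bands = bands,
                 entropy = entropy, tau_max = as.integer(tau_max),
                 agg_range = as.integer(agg_range), rejection = rejection,
                 inclusion_threshold = inclusion_threshold,
                 region_map = region_map, rest_window = rest_window,
                 task_window = task_window, measures = measures,
                 task_mse_by_condition = task_mse_by_condition,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "analysis_config")
}

# unified subject access: generate on the fly or read from disk
cohort_source <- function(config, cohort = NULL) {
  if (!is.null(cohort)) {
    stopifnot(inherits(cohort, "synthetic_cohort"))
    ids <- names(cohort$subjects)
    return(list(ids = ids,
                groups = vapply(cohort$subjects, `[[`, "", "group"),
                get = function(i, what = "all") cohort$subjects[[i]],
                behavior = cohort$behavior))
  }
  if (!is.null(config$design)) {
    design <- config$design
    groups <- rep(names(design$group_sizes), design$group_sizes)
    ids <- paste0(groups, ".", unlist(lapply(design$group_sizes, seq_len)))
    return(list(ids = ids, groups = groups,
                get = function(i, what = "all") generate_subject(
                  design, groups[i], ids[i],
                  subject_stream_seed(design$seed, i), signals = what),
                behavior = NULL))
  }
  if (!is.null(config$cohort_dir)) {
    dirpath <- config$cohort_dir
    man_path <- file.path(dirpath, "manifest.yaml")
    beh_path <- file.path(dirpath, "behavior.tsv")
    for (p in c(man_path, beh_path))
      if (!file.exists(p)) stop("missing cohort file: ", p)
    man <- yaml::read_yaml(man_path)
    ids <- unlist(man$subject_ids)
    groups <- unlist(man$subject_groups)
    for (id in ids)
      for (f in c("resting.tsv", "task.tsv", "events.tsv"))
        if (!file.exists(file.path(dirpath, id, f)))
          stop("missing cohort file: ", file.path(dirpath, id, f))
    beh <- utils::read.table(beh_path, header = TRUE, sep = "\t")
    return(list(ids = ids, groups = groups,
                get = function(i, what = "all") {
                  sd <- file.path(dirpath, ids[i])
                  list(id = ids[i], group = groups[i],
                       resting = read_recording(file.path(sd, "resting.tsv")),
                       task = read_recording(file.path(sd, "task.tsv")),
                       events = read_events(file.path(sd, "events.tsv")),
                       behavior = beh[beh$subject == ids[i], ])
                },
                behavior = beh))
  }
  stop("config needs a design, a cohort_dir, or an in-memory cohort")
}

preprocess_recording <- function(rec, config) {
  rec <- rereference_average(rec)
  rec <- bandpass_filter(rec, config$filter_low, config$filter_high)
  resample_recording(rec, min(config$resample_rate, rec$rate))
}

# mean sample entropy per channel over retained epochs (NA-skipping);
# returns named vector by channel
epoch_mean_sampen <- function(ep, keep, params) {
  nch <- dim(ep$data)[2]
  out <- vapply(seq_len(nch), function(c) {
    v <- vapply(which(keep), function(e)
      sample_entropy(ep$data[e, c, ], params), numeric(1))
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
  names(out) <- ep$labels
  out
}

# mean MSE scale-aggregate per channel over retained epochs
epoch_mean_mse_agg <- function(ep, keep, params, tau_max, agg_range) {
  nch <- dim(ep$data)[2]
  out <- vapply(seq_len(nch), function(c) {
    v <- vapply(which(keep), function(e) {
      curve <- multiscale_entropy(ep$data[e, c, ], params, tau_max)
      aggregate_scales(curve, agg_range[1], agg_range[2])
    }, numeric(1))
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
  names(out) <- ep$labels
  out
}

entropy_rows <- function(subject, group, state, measure, condition, values) {
  data.frame(subject = subject, group = group, state = state,
             measure = measure, condition = condition,
             electrode = names(values), value = unname(values),
             row.names = NULL)
}

# per-electrode one-way ANOVA plus region-level pairwise tests vs the first
# (reference) group
group_stats <- function(tab, config, ref = NULL) {
  subj_level <- stats::aggregate(
    value ~ subject + group + measure + electrode, data = tab, FUN = mean,
    na.rm = TRUE, na.action = stats::na.pass)
  subj_level$value[is.nan(subj_level$value)] <- NA_real_
  effects <- do.call(rbind, lapply(
    split(subj_level, subj_level[, c("measure", "electrode")], drop = TRUE),
    function(d) {
      d <- d[!is.na(d$value), ]
      if (length(unique(d$group)) < 2L || any(table(d$group) < 2L))
        return(NULL)
      res <- one_way_anova(d$value, d$group)
      lev <- levene_check(d$value, d$group)
      data.frame(measure = d$measure[1], electrode = d$electrode[1], res,
                 levene_p = lev$p)
    }))
  if (is.null(effects) || nrow(effects) == 0L)
    stop("too few subjects per group for the per-electrode ANOVA ",
         "(every group needs at least 2 included subjects)")
  rownames(effects) <- NULL

  reg_tab <- region_average(entropy_table(
    tab[, c("subject", "group", "state", "measure", "condition",
            "electrode", "value")]), config$region_map)
  reg_subj <- stats::aggregate(
    value ~ subject + group + measure + electrode, data = reg_tab,
    FUN = mean, na.rm = TRUE, na.action = stats::na.pass)
  if (is.null(ref)) ref <- reg_subj$group[1]
  others <- setdiff(unique(reg_subj$group), ref)
  region_tests <- do.call(rbind, lapply(
    split(reg_subj, reg_subj[, c("measure", "electrode")], drop = TRUE),
    function(d) {
      d <- d[!is.na(d$value), ]
      do.call(rbind, lapply(others, function(g) {
        x <- d$value[d$group == g]; y <- d$value[d$group == ref]
        if (length(x) < 2L || length(y) < 2L) return(NULL)
        tt <- stats::t.test(x, y, var.equal = TRUE)
        data.frame(measure = d$measure[1], region = d$electrode[1],
                   comparison = paste(g, "vs", ref),
                   t = unname(tt$statistic), df = unname(tt$parameter),
                   p = tt$p.value, cohens_d = cohens_d(x, y))
      }))
    }))
  rownames(region_tests) <- NULL
  list(effects = effects, region_tests = region_tests)
}

#' Resting-state multiscale-entropy analysis
#'
#' For every subject: preprocess the resting recording (common-average
#' re-reference, broadband filter, resample), cut consecutive resting
#' segments, mark artifacts, compute the multiscale-entropy curve per
#' retained segment and channel, average curves across segments and reduce
#' to the configured scale aggregate. Optionally (when `"band"` is among the
#' configured measures) band-limited sample entropy is computed the same
#' way. Group statistics: per-electrode one-way ANOVA and region-level
#' t-tests of each patient group against the healthy (first) group.
#'
#' @param config An [analysis_config()].
#' @param cohort Optional in-memory [generate_cohort()] result.
#' @return List with `entropy` ([entropy_table()]), `effects`,
#'   `region_tests` and `manifest`.
#' @export
run_resting <- function(config, cohort = NULL) {
  src <- cohort_source(config, cohort)
  rows <- list(); counts <- list()
  for (i in seq_along(src$ids)) {
    s <- src$get(i)
    rec <- preprocess_recording(s$resting, config)
    rw <- config$rest_window
    ep <- epoch_resting(rec, rw$start_ms, rw$end_ms, rw$window_ms,
                        rw$baseline_ms)
    ep <- reject_artifacts(ep, config$rejection)
    keep <- !ep$rejected
    counts[[s$id]] <- list(subject = s$id, group = s$group,
                           total = n_epochs(ep), retained = sum(keep),
                           rejected = sum(!keep))
    if (!any(keep)) {
      counts[[s$id]]$excluded <- "no retained resting segments"
      next
    }
    vals <- epoch_mean_mse_agg(ep, keep, config$entropy, config$tau_max,
                               config$agg_range)
    rows[[length(rows) + 1L]] <- entropy_rows(s$id, s$group, "rest",
                                              "mse_agg", "none", vals)
    if ("band" %in% config$measures) {
      for (bn in names(config$bands)) {
        band_rec <- extract_band(rec, config$bands[[bn]])
        bep <- epoch_resting(band_rec, rw$start_ms, rw$end_ms, rw$window_ms,
                             rw$baseline_ms)
        bvals <- epoch_mean_sampen(bep, keep, config$entropy)
        rows[[length(rows) + 1L]] <- entropy_rows(
          s$id, s$group, "rest", paste0("sampen_", bn), "none", bvals)
      }
    }
  }
  tab <- entropy_table(do.call(rbind, rows))
  included_groups <- unique(tab$group)
  if (length(included_groups) < length(unique(src$groups)))
    stop("a group has zero included subjects; cannot run group statistics")
  st <- group_stats(tab, config, ref = src$groups[1])
  manifest <- run_manifest(config, "resting", counts)
  res <- list(entropy = tab, effects = st$effects,
              region_tests = st$region_tests, manifest = manifest)
  write_run_outputs(res, config, "resting")
  res
}

#' Task-state entropy analysis
#'
#' For every subject: preprocess the task recording, cut stimulus-locked
#' epochs, mark artifacts on the broadband epochs, apply the strict
#' retained-trial inclusion rule, then compute per retained epoch and
#' channel the band-limited sample entropy (bands are filtered on the
#' continuous recording before epoching, so filter edge effects never touch
#' epoch boundaries) and, optionally, the broadband multiscale-entropy scale
#' aggregate. Epoch values are averaged per (condition, channel) for band
#' entropy; multiscale entropy is pooled across conditions unless
#' `task_mse_by_condition` is set. Group statistics as in [run_resting()].
#'
#' Excluded subjects stay out of the statistics but are recorded in the
#' manifest with their retained-trial counts and the exclusion reason.
#'
#' @inheritParams run_resting
#' @return List with `entropy`, `effects`, `region_tests`, `behavior` (when
#'   available from the cohort) and `manifest`.
#' @export
run_task <- function(config, cohort = NULL) {
  src <- cohort_source(config, cohort)
  rows <- list(); counts <- list(); beh_rows <- list()
  for (i in seq_along(src$ids)) {
    s <- src$get(i, what = "task")
    if (!is.null(s$behavior)) beh_rows[[s$id]] <- s$behavior
    rec <- preprocess_recording(s$task, config)
    # event onsets were recorded at the native rate; rescale to the
    # preprocessed rate
    ev <- s$events
    scale <- rec$rate / s$task$rate
    if (scale != 1) {
      ev$onset_sample <- as.integer(round((ev$onset_sample - 1L) * scale)) + 1L
    }
    tw <- config$task_window
    ep <- epoch_task(rec, ev, tw$tmin_ms, tw$tmax_ms, tw$baseline_ms)
    ep <- reject_artifacts(ep, config$rejection)
    keep <- !ep$rejected
    n_oob <- attr(ep, "n_out_of_bounds")
    counts[[s$id]] <- list(subject = s$id, group = s$group,
                           total = n_epochs(ep) + n_oob,
                           retained = sum(keep), rejected = sum(!keep),
                           out_of_bounds = n_oob)
    if (!subject_included(ep, config$inclusion_threshold)) {
      counts[[s$id]]$excluded <- sprintf(
        "retained fraction %.3f not above %.2f",
        sum(keep) / n_epochs(ep), config$inclusion_threshold)
      next
    }
    if ("band" %in% config$measures) {
      for (bn in names(config$bands)) {
        band_rec <- extract_band(rec, config$bands[[bn]])
        bep <- epoch_task(band_rec, ev, tw$tmin_ms, tw$tmax_ms,
                          tw$baseline_ms)
        for (cond in unique(bep$meta$condition)) {
          sel <- keep & bep$meta$condition == cond
          if (!any(sel)) next
          vals <- epoch_mean_sampen(bep, sel, config$entropy)
          rows[[length(rows) + 1L]] <- entropy_rows(
            s$id, s$group, "task", paste0("sampen_", bn), cond, vals)
        }
      }
    }
    if ("mse" %in% config$measures) {
      if (config$task_mse_by_condition) {
        for (cond in unique(ep$meta$condition)) {
          sel <- keep & ep$meta$condition == cond
          if (!any(sel)) next
          vals <- epoch_mean_mse_agg(ep, sel, config$entropy,
                                     config$tau_max, config$agg_range)
          rows[[length(rows) + 1L]] <- entropy_rows(
            s$id, s$group, "task", "mse_agg", cond, vals)
        }
      } else {
        vals <- epoch_mean_mse_agg(ep, keep, config$entropy, config$tau_max,
                                   config$agg_range)
        rows[[length(rows) + 1L]] <- entropy_rows(
          s$id, s$group, "task", "mse_agg", "none", vals)
      }
    }
  }
  if (!length(rows))
    stop("no subject passed the inclusion rule")
  tab <- entropy_table(do.call(rbind, rows))
  if (length(unique(tab$group)) < length(unique(src$groups)))
    stop("a group has zero included subjects; cannot run group statistics")
  st <- group_stats(tab, config, ref = src$groups[1])
  manifest <- run_manifest(config, "task", counts)
  behavior <- src$behavior
  if (is.null(behavior) && length(beh_rows)) {
    behavior <- do.call(rbind, beh_rows)
    rownames(behavior) <- NULL
  }
  behavior_anova <- NULL
  if (!is.null(behavior) && length(unique(behavior$group)) >= 2L)
    behavior_anova <- tryCatch(
      mixed_two_way_anova(behavior, response = "performance"),
      error = function(e) NULL)
  res <- list(entropy = tab, effects = st$effects,
              region_tests = st$region_tests, behavior = behavior,
              behavior_anova = behavior_anova, manifest = manifest)
  write_run_outputs(res, config, "task")
  res
}

#' Entropy-performance correlation analysis
#'
#' Pearson correlations between task-state band sample entropy and the
#' performance ratio ACC/RT, per (group, band, condition): the headline
#' summary correlates each subject's all-electrode mean band entropy with
#' performance, and a per-electrode map is exported for topographic
#' plotting. Per-electrode tests are uncorrected across electrodes (flagged
#' as such in the output metadata attribute `multiplicity`).
#'
#' @param config An [analysis_config()].
#' @param task A [run_task()] result; computed on demand when `NULL`.
#' @param cohort Optional in-memory cohort (for behavior when `task` is
#'   given without one).
#' @return List with `summary` and `electrode` correlation tables.
#' @export
run_correlations <- function(config, task = NULL, cohort = NULL) {
  if (is.null(task)) task <- run_task(config, cohort)
  behavior <- task$behavior
  if (is.null(behavior) && !is.null(cohort)) behavior <- cohort$behavior
  if (is.null(behavior)) stop("no behavioral records available")
  band_tab <- task$entropy[grepl("^sampen_", task$entropy$measure), ]
  if (!nrow(band_tab)) stop("task result contains no band entropy rows")
  n_per_group <- table(unique(band_tab[, c("subject", "group")])$group)
  small <- names(n_per_group)[n_per_group < 4L]
  if (length(small)) {
    warning("group(s) with n < 4 skipped: ", paste(small, collapse = ", "))
    band_tab <- band_tab[!band_tab$group %in% small, ]
  }
  if (!nrow(band_tab)) stop("no group has the minimum of 4 subjects")
  summ <- entropy_behavior_correlation(band_tab, behavior, "summary")
  elec <- entropy_behavior_correlation(band_tab, behavior, "electrode")
  attr(elec, "multiplicity") <- "uncorrected per-electrode tests"
  res <- list(summary = summ, electrode = elec)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv_out(summ, file.path(config$out_dir, "correlations_summary.tsv"))
    write_tsv_out(elec, file.path(config$out_dir,
                                  "correlations_electrode.tsv"))
  }
  res
}

#' Run the complete analysis
#'
#' Resting analysis, task analysis and entropy-behavior correlations in
#' sequence on the same cohort, plus a combined manifest. With identical
#' config (including seeds) two runs produce byte-identical output tables.
#'
#' @inheritParams run_resting
#' @return List with `resting`, `task`, `correlations`.
#' @export
run_all <- function(config, cohort = NULL) {
  resting <- run_resting(config, cohort)
  task <- run_task(config, cohort)
  correlations <- run_correlations(config, task = task, cohort = cohort)
  list(resting = resting, task = task, correlations = correlations)
}

run_manifest <- function(config, stage, counts, timestamp = NULL) {
  cfg <- config
  cfg$design <- if (!is.null(cfg$design)) "cohort_design (see design seed)"
  list(stage = stage,
       package_version = as.character(utils::packageVersion("eegentropy")),
       seed = config$seed,
       design_seed = if (!is.null(config$design)) config$design$seed,
       config = list(filter = c(cfg$filter_low, cfg$filter_high),
                     resample_rate = cfg$resample_rate,
                     entropy = unclass(cfg$entropy),
                     tau_max = cfg$tau_max, agg_range = cfg$agg_range,
                     inclusion_threshold = cfg$inclusion_threshold,
                     measures = cfg$measures),
       subjects = unname(counts),
       timestamp = timestamp)
}

write_tsv_out <- function(df, path) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
}

write_run_outputs <- function(res, config, stage) {
  if (is.null(config$out_dir)) return(invisible(NULL))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv_out(res$entropy,
                file.path(config$out_dir, paste0(stage, "_entropy.tsv")))
  write_tsv_out(res$effects,
                file.path(config$out_dir, paste0(stage, "_effects.tsv")))
  write_tsv_out(res$region_tests,
                file.path(config$out_dir, paste0(stage, "_region_tests.tsv")))
  yaml::write_yaml(res$manifest,
                   file.path(config$out_dir, paste0(stage, "_manifest.yaml")))
  invisible(NULL)
}
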