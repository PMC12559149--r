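# Orchestration of the desk-scale experiment: cohort generation ->
# artifact corruption -> segmentation -> optional registration ->
# torsion quantification -> statistical summaries.

#' Experiment configuration
#'
#' @param n_participants number of synthetic participants.
#' @param severity_plan severity conditions acquired per participant;
#'   the default — one artifact-free condition plus the three graded
#'   ones — mirrors repeated acquisitions under standardized motion.
#' @param strategies evaluation-pipeline variants: `"raw"` (segment the
#'   corrupted stacks directly), `"preprocessed"` (crop/z-score/resample
#'   first), `"preprocessed+registration"` (additionally register
#'   motion-affected ankle stacks back to their reference before
#'   segmentation).
#' @param sides limb sides to simulate.
#' @param base_spec template [limb_spec()]. The default uses a coarser
#'   desk-scale raster (1.2 mm in-plane) than the geometry-validation
#'   phantoms; torsion recovery tolerance scales with spacing.
#' @param jitter per-participant uniform jitter ranges, as in
#'   [generate_cohort()].
#' @param seed master seed; all stage seeds derive from it.
#' @param out_dir optional output directory for CSV/JSON results.
#' @return an `experiment_config`.
#' @export
experiment_config <- function(n_participants = 20,
                              severity_plan = c("none", "mild", "moderate", "severe"),
                              strategies = "raw",
                              sides = "right",
                              base_spec = limb_spec(
                                spacing_mm = c(3.0, 1.2, 1.2),
                                stack_shape = list(hip = c(14L, 96L, 96L),
                                                   knee = c(12L, 96L, 96L),
                                                   ankle = c(10L, 64L, 64L))),
                              jitter = list(femoral_torsion_deg = c(0, 30),
                                            tibial_torsion_deg = c(20, 50),
                                            condylar_angle_deg = c(-5, 5),
                                            tibial_plateau_angle_deg = c(-5, 5)),
                              seed = 1L,
                              out_dir = NULL) {
  if (n_participants < 1) abort("experiment_config: n_participants must be >= 1")
  if (length(severity_plan) == 0) abort("experiment_config: empty severity_plan")
  strategies <- match.arg(strategies,
                          c("raw", "preprocessed", "preprocessed+registration"),
                          several.ok = TRUE)
  structure(list(n_participants = n_participants,
                 severity_plan = severity_plan,
                 strategies = strategies, sides = sides,
                 base_spec = base_spec, jitter = jitter,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "experiment_config")
}

# the five evaluated regions: (joint, label code) pairs
eval_regions <- function() {
  data.frame(joint = c("hip", "knee", "knee", "ankle", "ankle"),
             code = c(1L, 1L, 2L, 2L, 3L),
             region = c("proximal_femur", "distal_femur", "proximal_tibia",
                        "distal_tibia", "distal_fibula"),
             stringsAsFactors = FALSE)
}

#' Run the full desk-scale experiment
#'
#' For every participant, side, and severity condition the three joint
#' stacks are corrupted (`severity_to_params()`; ankle stacks use
#' slice-wise motion so through-plane misalignment is emulated), then
#' each evaluation strategy segments the stacks and measures both
#' torsion angles. Partial failures are recorded per limb and never
#' abort the run; everything is reproducible from the master seed.
#'
#' @param config an [experiment_config()].
#' @return a results bundle: `records` (one row per region and limb
#'   condition), `dsc_table` (mean/sd DSC by severity, region,
#'   strategy), `success_table` (relative and absolute completed
#'   measurements), `angle_table` (MAD/ICC/Pearson r of measured vs.
#'   true angles by severity and strategy), `lmm` (coefficient table for
#'   region + severity (+ strategy) with participant random intercept),
#'   and `config`. With `out_dir` set, CSV/JSON outputs are written,
#'   each carrying the master seed and a config hash.
#' @export
run_experiment <- function(config = experiment_config()) {
  stopifnot(inherits(config, "experiment_config"))
  cohort <- generate_cohort(config$n_participants, config$severity_plan,
                            config$base_spec, config$jitter, config$sides,
                            seed = derive_seed(config$seed, "cohort"))
  regions <- eval_regions()
  rows <- list()
  for (p in cohort) {
    for (side in config$sides) {
      limb <- p[[side]]
      for (ci in seq_along(config$severity_plan)) {
        sev <- config$severity_plan[ci]
        corrupted <- list()
        for (joint in c("hip", "knee", "ankle")) {
          cfg <- severity_to_params(sev, slice_wise = (joint == "ankle"))
          cseed <- derive_seed(config$seed,
                               paste(p$id, side, joint, ci, sep = "-"))
          corrupted[[joint]] <- sample_mri_specific(limb[[joint]]$image,
                                                    limb[[joint]]$labels,
                                                    cfg, cseed)
        }
        for (strat in config$strategies) {
          ev <- evaluate_strategy(limb, corrupted, strat, config)
          segs <- ev$segs
          tr <- measure_limb(segs$hip, segs$knee, segs$ankle, side)
          for (ri in seq_len(nrow(regions))) {
            jt <- regions$joint[ri]
            rows[[length(rows) + 1L]] <- data.frame(
              participant = p$id, side = side, joint_level = jt,
              bone = c("femur", "tibia", "fibula")[regions$code[ri]],
              region = regions$region[ri], severity = sev,
              condition = ci, strategy = strat,
              dice = dice(segs[[jt]], ev$truth[[jt]], regions$code[ri]),
              torsion_success = tr$success,
              femoral_measured = tr$femoral_torsion_deg,
              femoral_truth = limb$truth$femoral_torsion_deg,
              tibial_measured = tr$tibial_torsion_deg,
              tibial_truth = limb$truth$tibial_torsion_deg,
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  records <- do.call(rbind, rows)
  bundle <- list(records = records,
                 dsc_table = dsc_summary(records),
                 success_table = success_summary(records),
                 angle_table = angle_summary(records),
                 lmm = experiment_lmm(records),
                 config = config)
  if (!is.null(config$out_dir)) write_bundle(bundle, config)
  bundle
}

# apply one evaluation strategy; returns segmentations and the label
# stacks they should be compared against
evaluate_strategy <- function(limb, corrupted, strategy, config) {
  imgs <- lapply(corrupted, `[[`, "image")
  labs <- lapply(corrupted, `[[`, "labels")
  if (strategy %in% c("preprocessed", "preprocessed+registration")) {
    for (joint in names(imgs)) {
      pp <- preprocess_stack(imgs[[joint]], labs[[joint]])
      imgs[[joint]] <- pp$image
      labs[[joint]] <- pp$labels
    }
  }
  if (strategy == "preprocessed+registration") {
    # register the motion-affected ankle back to its clean reference
    ref <- preprocess_stack(limb$ankle$image, limb$ankle$labels)
    if (identical(dim(ref$image$values), dim(imgs$ankle$values))) {
      reg <- register_slices(imgs$ankle, ref$image)
      imgs$ankle <- reg$registered
      labs$ankle <- ref$labels  # anatomy restored to the reference frame
    }
  }
  segs <- lapply(imgs, segment_stack)
  list(segs = segs, truth = labs)
}

dsc_summary <- function(records) {
  agg <- stats::aggregate(dice ~ severity + region + strategy, records,
                          function(x) c(mean = mean(x), sd = stats::sd(x)))
  out <- data.frame(agg[c("severity", "region", "strategy")],
                    dsc_mean = agg$dice[, "mean"], dsc_sd = agg$dice[, "sd"])
  out[order(out$strategy, out$region, factor(out$severity,
            c("none", "mild", "moderate", "severe"))), ]
}

success_summary <- function(records) {
  limb_rec <- unique(records[c("participant", "side", "severity", "condition",
                               "strategy", "torsion_success")])
  agg <- stats::aggregate(torsion_success ~ severity + strategy, limb_rec,
                          function(x) c(n_success = sum(x), n_total = length(x)))
  data.frame(agg[c("severity", "strategy")],
             n_success = agg$torsion_success[, "n_success"],
             n_total = agg$torsion_success[, "n_total"],
             rate = agg$torsion_success[, "n_success"] /
               agg$torsion_success[, "n_total"])
}

angle_summary <- function(records) {
  limb_rec <- unique(records[c("participant", "side", "severity", "condition",
                               "strategy", "femoral_measured", "femoral_truth",
                               "tibial_measured", "tibial_truth")])
  groups <- unique(limb_rec[c("severity", "strategy")])
  out <- lapply(seq_len(nrow(groups)), function(i) {
    g <- limb_rec[limb_rec$severity == groups$severity[i] &
                    limb_rec$strategy == groups$strategy[i], ]
    one <- function(meas, truth) {
      ok <- is.finite(meas) & is.finite(truth)
      c(mad = tryCatch(mad_pairwise(meas, truth), error = function(e) NA_real_),
        icc = if (sum(ok) >= 5 && stats::sd(truth[ok]) > 0)
          icc_agreement(cbind(meas[ok], truth[ok]))$icc else NA_real_,
        r = tryCatch(pearson_ci(meas, truth)$r, error = function(e) NA_real_))
    }
    fem <- one(g$femoral_measured, g$femoral_truth)
    tib <- one(g$tibial_measured, g$tibial_truth)
    data.frame(severity = groups$severity[i], strategy = groups$strategy[i],
               femoral_mad = fem["mad"], femoral_icc = fem["icc"],
               femoral_r = fem["r"], tibial_mad = tib["mad"],
               tibial_icc = tib["icc"], tibial_r = tib["r"],
               row.names = NULL)
  })
  do.call(rbind, out)
}

experiment_lmm <- function(records) {
  fixed <- c("region", "severity")
  refs <- list(region = "proximal_femur", severity = "none")
  if (length(unique(records$strategy)) > 1) {
    fixed <- c(fixed, "strategy")
    refs$strategy <- "raw"
  }
  tryCatch(fit_lmm(records, response = "dice", fixed = fixed,
                   random_intercept = "participant",
                   reference_levels = refs),
           error = function(e) structure(list(error = conditionMessage(e)),
                                         class = "lmm_result"))
}

write_bundle <- function(bundle, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, nm) utils::write.csv(df, file.path(config$out_dir, nm),
                                         row.names = FALSE)
  w(bundle$records, "records.csv")
  w(bundle$dsc_table, "dsc_table.csv")
  w(bundle$success_table, "success_table.csv")
  w(bundle$angle_table, "angle_table.csv")
  cfg_txt <- utils::capture.output(utils::str(config))
  tf <- tempfile()
  writeLines(cfg_txt, tf)
  meta <- list(seed = config$seed,
               config_hash = unname(tools::md5sum(tf)),
               n_participants = config$n_participants,
               severity_plan = config$severity_plan,
               strategies = config$strategies)
  unlink(tf)
  if (!inherits(bundle$lmm, "try-error") && is.null(bundle$lmm$error)) {
    coefs <- bundle$lmm$coefficients
    lmm_df <- data.frame(term = names(coefs),
                         estimate = vapply(coefs, `[[`, numeric(1), "estimate"),
                         ci_lo = vapply(coefs, function(x) x$ci95[1], numeric(1)),
                         ci_hi = vapply(coefs, function(x) x$ci95[2], numeric(1)),
                         p_value = vapply(coefs, `[[`, numeric(1), "p_value"))
    w(lmm_df, "lmm_table.csv")
  }
  jsonlite::write_json(meta, file.path(config$out_dir, "metadata.json"),
                       auto_unbox = TRUE)
  invisible(NULL)
}
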