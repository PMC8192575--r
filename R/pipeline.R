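# Orchestration: QC accounting, run configuration, and the end-to-end
# phantom -> morphometry -> statistics run with reproducible outputs.

round_half_up <- function(x, digits = 1) {
  s <- 10^digits
  floor(x * s + 0.5) / s
}

#' Quality-control accounting
#'
#' Bookkeeping of cohort exclusions: a named count of exclusions per reason
#' is subtracted from the initial dataset count, and the anatomical-variant
#' fraction is computed on the final count. Percentages are rounded half-up
#' to one decimal.
#'
#' @param initial initial number of datasets (>= 0).
#' @param exclusions named non-negative integer vector of exclusion counts
#'   by reason; their sum must not exceed `initial`.
#' @param variant_count number of included subjects carrying the variant.
#' @param female_count optional number of included female subjects, for the
#'   cohort-description percentage.
#' @return An object of class `qc_report`: initial, exclusions, final,
#'   variant count/percent, and the arithmetic identities always hold.
#' @examples
#' qc_accounting(2115, c(noisy_segmentation = 36,
#'                       incomplete_segmentation = 86,
#'                       mis_registration = 271), variant_count = 216)
#' @export
qc_accounting <- function(initial, exclusions = integer(0), variant_count = 0,
                          female_count = NULL) {
  initial <- as.integer(initial)
  exclusions <- vapply(exclusions, as.integer, 1L)
  variant_count <- as.integer(variant_count)
  if (initial < 0 || any(exclusions < 0) || variant_count < 0)
    stop("all counts must be >= 0")
  if (sum(exclusions) > initial)
    stop(sprintf("exclusions (%d) exceed the initial count (%d)",
                 sum(exclusions), initial))
  final <- initial - sum(exclusions)
  if (variant_count > final)
    stop("variant_count exceeds the final included count")
  structure(list(
    initial = initial,
    exclusions = exclusions,
    excluded_total = sum(exclusions),
    final = final,
    variant_count = variant_count,
    variant_percent = if (final > 0)
      round_half_up(100 * variant_count / final) else NA_real_,
    normal_percent = if (final > 0)
      round_half_up(100 * (final - variant_count) / final) else NA_real_,
    female_count = if (is.null(female_count)) NA_integer_
                   else as.integer(female_count),
    female_percent = if (!is.null(female_count) && final > 0)
      round_half_up(100 * female_count / final) else NA_real_
  ), class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %d -> %d included (%d excluded)\n",
              x$initial, x$final, x$excluded_total))
  for (r in names(x$exclusions))
    cat(sprintf("  - %s: %d\n", r, x$exclusions[[r]]))
  cat(sprintf("  variant: %d (%.1f%%)\n", x$variant_count, x$variant_percent))
  invisible(x)
}

#' Configure an end-to-end run
#'
#' Exactly one input mode must be given: `simulate` (a list with `cohort` =
#' [cohort_sim_spec()] and optional phantom geometry settings) for a fully
#' synthetic run, or `real` (a list with a `table` CSV path of per-subject
#' factor rows and volume paths). Settings cover the atlas refinement
#' threshold, PLSR `k_max`, LOESS span, output directory and master seed.
#'
#' @param simulate simulation settings (list), or NULL.
#' @param real real-data settings (list), or NULL.
#' @param out_dir output directory (created if needed).
#' @param atlas_threshold refinement cut in (0, 1).
#' @param k_max PLSR components to evaluate.
#' @param loess_span LOESS window fraction.
#' @param seed master integer seed; every stochastic draw derives from it.
#' @return An object of class `run_config`.
#' @export
run_config <- function(simulate = NULL, real = NULL, out_dir,
                       atlas_threshold = 0.01, k_max = 5,
                       loess_span = 0.75, seed = 1L) {
  if (is.null(simulate) == is.null(real))
    stop("exactly one of `simulate` or `real` must be given")
  if (atlas_threshold <= 0 || atlas_threshold >= 1)
    stop("`atlas_threshold` must be in (0, 1)")
  structure(list(simulate = simulate, real = real, out_dir = out_dir,
                 atlas_threshold = atlas_threshold, k_max = as.integer(k_max),
                 loess_span = loess_span, seed = as.integer(seed)),
            class = "run_config")
}

#' Load a run configuration from YAML
#'
#' @param path YAML file with the [run_config()] fields.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$simulate) && !is.null(y$simulate$cohort))
    y$simulate$cohort <- do.call(cohort_sim_spec, y$simulate$cohort)
  run_config(simulate = y$simulate, real = y$real,
             out_dir = y$out_dir %||% ".",
             atlas_threshold = y$atlas_threshold %||% 0.01,
             k_max = y$k_max %||% 5,
             loess_span = y$loess_span %||% 0.75,
             seed = y$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# per-subject phantom: two tubes whose radii scale weakly and
# deterministically with the subject's age, so measured morphology carries
# an age signal end to end. Axes are snapped to voxel centers: thinning of
# a tube whose axis lies exactly between lattice columns is degenerate
# (the discrete medial locus is two voxels wide and retracts), for this
# algorithm family just as for the reference implementations.
subject_phantom <- function(subject_row, base_seed, shape = c(24, 24, 24),
                            spacing = 1.0) {
  g <- grid_spec(shape, spacing)
  ext <- (g$shape - 1) * g$spacing
  snap <- function(w, axis) round(w / g$spacing[axis]) * g$spacing[axis]
  f <- 1 - 0.003 * (subject_row$age - 50)
  f <- max(0.6, min(1.4, f))
  r1 <- max(2.0 * f, max(g$spacing) * 1.05)
  r2 <- max(1.5 * f, max(g$spacing) * 1.05)
  x1 <- snap(0.25 * ext[1], 1); x2 <- snap(0.72 * ext[1], 1)
  y0 <- snap(0.5 * ext[2], 2)
  segs <- list(
    list(start = c(x1, y0, 0), end = c(x1, y0, ext[3]), radius = r1),
    list(start = c(x2, y0, 0), end = c(x2, y0, ext[3]), radius = r2))
  # head size tracks the subject's simulated ICV so measured ICV varies
  icv_f <- max(0.8, min(1.0, 0.9 * (subject_row$icv_cm3 / 1402.44)^(1 / 3)))
  make_tube_phantom(phantom_spec(segs, g, noise_voxel_count = 3L,
                                 seed = base_seed, icv_scale = icv_f))
}

# keep a maximal subset of responses whose residual covariance is
# well-conditioned: drop NA-laden and constant columns, then QR-pivot the
# scaled complete-case matrix at a relative tolerance
screen_mancova_responses <- function(dat, responses) {
  ok_col <- vapply(responses, function(r) {
    v <- dat[[r]]
    mean(is.na(v)) < 0.5 && stats::var(v, na.rm = TRUE) > 1e-12
  }, logical(1))
  kept <- responses[ok_col]
  if (length(kept) >= 2) {
    M <- as.matrix(dat[, kept, drop = FALSE])
    M <- M[stats::complete.cases(M), , drop = FALSE]
    qrd <- qr(scale(M), tol = 1e-6)
    kept <- kept[sort(qrd$pivot[seq_len(qrd$rank)])]
  }
  # the multivariate test needs residual df: cap q well below n
  qmax <- max(1L, nrow(dat) - 6L)
  if (length(kept) > qmax) kept <- kept[seq_len(qmax)]
  list(kept = kept, dropped = setdiff(responses, kept))
}

write_plsr_table <- function(jack, rmse, path) {
  # table layout: RMSE row, then one row per predictor with beta and
  # significance mark columns per response
  q <- ncol(jack$beta)
  tab <- data.frame(predictor = c("RMSE", rownames(jack$beta)),
                    stringsAsFactors = FALSE)
  for (j in seq_len(q)) {
    rn <- colnames(jack$beta)[j]
    tab[[rn]] <- c(rmse[j], jack$beta[, j])
    tab[[paste0(rn, "_p")]] <- c(NA, jack$p[, j])
    tab[[paste0(rn, "_sig")]] <-
      c("", ifelse(jack$sig01[, j], "**", ifelse(jack$sig05[, j], "*", "")))
  }
  write.csv(tab, path, row.names = FALSE)
  invisible(tab)
}

#' Run the full pipeline
#'
#' Simulate mode: draws the cohort table, builds and measures one vascular
#' phantom per subject, joins factors and measurements, then (a) fits the
#' three PLSR models (territory density, territory mean radius, main-artery
#' radius) with LOO-CV component selection and jackknife inference on the
#' non-variant subjects, (b) runs the MANCOVA comparing variant carriers on
#' all subjects, (c) fits sex-specific quantile LOESS curves, and (d)
#' writes the QC report and a run manifest. Outputs are plain CSV/JSON in
#' `out_dir` and are byte-identical across re-runs with the same config.
#' Real mode reads per-subject volume paths and a factor table instead of
#' simulating.
#'
#' @param config a [run_config()].
#' @return The output directory, invisibly; side effect: files
#'   `cohort.csv`, `measurements.csv`, `plsr_<set>.csv`, `mancova.json`,
#'   `curves.csv`, `qc_report.json`, `manifest.json`.
#' @export
run_cohort <- function(config) {
  if (!inherits(config, "run_config")) stop("`config` must be a run_config")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  notices <- character(0)
  input_hashes <- list()

  if (!is.null(config$simulate)) {
    spec <- config$simulate$cohort
    spec$seed <- config$seed
    cohort <- make_cohort(spec)
    n <- nrow(cohort)
    shape <- config$simulate$grid_shape %||% c(24, 24, 24)
    spacing <- config$simulate$grid_spacing %||% 1.0
    meas <- vector("list", n)
    for (i in seq_len(n)) {
      ph <- tryCatch(
        subject_phantom(cohort[i, ], base_seed = config$seed + i,
                        shape = shape, spacing = spacing),
        error = function(e) stop(sprintf(
          "phantom stage, subject %s: %s", cohort$subject_id[i],
          conditionMessage(e))))
      m <- tryCatch(
        extract_measurements(ph$mask, ph$prob_atlas, ph$territories,
                             ph$artery_masks, ph$icv_mask,
                             threshold = config$atlas_threshold),
        error = function(e) stop(sprintf(
          "morphometry stage, subject %s: %s", cohort$subject_id[i],
          conditionMessage(e))))
      m$subject_id <- cohort$subject_id[i]
      meas[[i]] <- m
    }
    meas <- do.call(rbind, meas)
    measured <- meas[, c("subject_id", measurement_names("all"), "icv_cm3",
                         "qc_empty_refined")]
    factors <- cohort[, c("subject_id", setdiff(predictor_names(), "icv_cm3"),
                          "fetal_pca")]
    table_full <- merge(factors, measured, by = "subject_id", sort = TRUE)
  } else {
    table_path <- config$real$table
    input_hashes[[table_path]] <- unname(tools::md5sum(table_path))
    subjects <- read.csv(table_path, stringsAsFactors = FALSE)
    needed <- c("subject_id", "mask", "atlas", "territories", "arteries",
                "icv")
    if (!all(needed %in% names(subjects)))
      stop("real-mode table must have columns: ",
           paste(needed, collapse = ", "))
    meas <- vector("list", nrow(subjects))
    for (i in seq_len(nrow(subjects))) {
      s <- subjects[i, ]
      for (p in c(s$mask, s$atlas, s$territories, s$arteries, s$icv))
        input_hashes[[p]] <- unname(tools::md5sum(p))
      m <- tryCatch(extract_measurements(
        read_volume(s$mask, "binary"),
        read_volume(s$atlas, "probability"),
        read_volume(s$territories, "label",
                    setNames(1:6, paste0("territory_",
                                         c("ACA_L", "ACA_R", "MCA_L",
                                           "MCA_R", "PCA_L", "PCA_R")))),
        read_volume(s$arteries, "label",
                    setNames(1:12, paste0("artery_",
                      sub("^aradius_", "",
                          measurement_names("artery_radius"))))),
        read_volume(s$icv, "binary"),
        threshold = config$atlas_threshold),
        error = function(e) stop(sprintf(
          "morphometry stage, subject %s: %s", s$subject_id,
          conditionMessage(e))))
      m$subject_id <- s$subject_id
      meas[[i]] <- m
    }
    meas <- do.call(rbind, meas)
    measured <- meas[, c("subject_id", measurement_names("all"), "icv_cm3",
                         "qc_empty_refined")]
    table_full <- merge(subjects[, setdiff(names(subjects), needed[-1]),
                                 drop = FALSE],
                        measured, by = "subject_id", sort = TRUE)
  }

  num6 <- function(d) { # stable CSV formatting for byte-identical re-runs
    for (c in names(d)) if (is.numeric(d[[c]])) d[[c]] <- signif(d[[c]], 10)
    d
  }
  write.csv(num6(measured), file.path(config$out_dir, "measurements.csv"),
            row.names = FALSE)
  write.csv(num6(table_full), file.path(config$out_dir, "cohort.csv"),
            row.names = FALSE)

  # QC: empty refined masks are the one automated exclusion reason here
  n_all <- nrow(table_full)
  empty_n <- sum(table_full$qc_empty_refined)
  keep <- !table_full$qc_empty_refined
  dat <- table_full[keep, ]
  qc <- qc_accounting(n_all, c(empty_refined_segmentation = empty_n),
                      variant_count = sum(dat$fetal_pca %||% 0),
                      female_count = if (!is.null(dat$sex))
                        sum(dat$sex == 2) else NULL)
  jsonlite::write_json(unclass(qc), file.path(config$out_dir,
                                              "qc_report.json"),
                       auto_unbox = TRUE, digits = NA)

  has_variant <- !is.null(dat$fetal_pca) && length(unique(dat$fetal_pca)) == 2

  # MANCOVA sees all subjects; PLSR never sees a variant carrier.
  # Phantom-derived measurements can be (nearly) collinear across regions,
  # so the omnibus test runs on a maximal well-conditioned response subset.
  if (has_variant) {
    responses <- screen_mancova_responses(dat, measurement_names("all"))
    if (length(responses$dropped))
      notices <- c(notices, sprintf(
        "MANCOVA responses reduced to %d of 24 (collinear/degenerate: %s)",
        length(responses$kept), paste(responses$dropped, collapse = ", ")))
    mc <- vessel_mancova(dat, responses$kept, group = "fetal_pca")
    jsonlite::write_json(
      list(wilks = mc$wilks, posthoc = mc$posthoc, n = mc$n,
           groups = mc$groups, responses_used = responses$kept),
      file.path(config$out_dir, "mancova.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows")
  } else {
    notices <- c(notices, "MANCOVA skipped: no anatomical-variant group")
    message("MANCOVA skipped: no anatomical-variant group present")
  }

  fit_rows <- if (!is.null(dat$fetal_pca)) dat$fetal_pca == 0 else
    rep(TRUE, nrow(dat))
  fitdat <- dat[fit_rows, ]
  plsr_info <- list()
  response_sets <- c("density", "territory_radius", "artery_radius")
  for (set in response_sets) {
    yn <- measurement_names(set)
    cols <- c(predictor_names(), yn)
    if (!all(cols %in% names(fitdat))) {
      notices <- c(notices, sprintf(
        "PLSR %s skipped: missing columns %s", set,
        paste(setdiff(cols, names(fitdat)), collapse = ", ")))
      next
    }
    ok <- stats::complete.cases(fitdat[, cols])
    dropped <- sum(!ok)
    if (dropped > 0)
      message(sprintf("PLSR %s: dropped %d incomplete row(s)", set, dropped))
    dd <- fitdat[ok, ]
    if (nrow(dd) < 30) {
      notices <- c(notices, sprintf(
        "PLSR %s skipped: only %d complete non-variant rows", set, nrow(dd)))
      next
    }
    X <- as.matrix(dd[, predictor_names()])
    Y <- as.matrix(dd[, yn])
    k_max <- min(config$k_max, ncol(X))
    cv <- loo_cv(X, Y, k_max)
    jack <- jackknife_pvalues(X, Y, cv$chosen_k)
    write_plsr_table(jack, cv$rmse[cv$chosen_k, ],
                     file.path(config$out_dir, paste0("plsr_", set, ".csv")))
    plsr_info[[set]] <- list(n_fit = nrow(dd), chosen_k = cv$chosen_k,
                             dropped_incomplete = dropped)
  }

  # sex-specific normative curves when each sex has enough subjects
  curve_rows <- list()
  if (!is.null(fitdat$sex) && all(table(fitdat$sex) >= 30)) {
    for (resp in c(measurement_names("all"))) {
      if (any(is.na(fitdat[[resp]]))) next
      curve_rows[[resp]] <- normative_curves(fitdat, resp,
                                             span = config$loess_span)
    }
  }
  if (length(curve_rows)) {
    write.csv(num6(do.call(rbind, curve_rows)),
              file.path(config$out_dir, "curves.csv"), row.names = FALSE)
  } else {
    notices <- c(notices,
                 "curves skipped: fewer than 30 subjects in some sex group")
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("vesselmorph")),
    seed = config$seed,
    atlas_threshold = config$atlas_threshold,
    k_max = config$k_max,
    loess_span = config$loess_span,
    mode = if (is.null(config$simulate)) "real" else "simulate",
    plsr = plsr_info,
    input_hashes = input_hashes,
    notices = notices)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(config$out_dir)
}
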