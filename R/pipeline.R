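#' Run the full per-subject analysis
#'
#' Orchestrates the per-subject workflow on one or both eyes: sum-maps of
#' density, spacing and VCAR (one shared window pass), peak extraction,
#' spacing and VCAR at the peak location, the five isodensity contours with
#' mean roundness and area, the VCAR inside/outside-80%-contour comparison,
#' and — when both eyes are present — the interocular difference map.
#' Exclusion rules are applied and logged per eye: subjects with any
#' incomplete contour are excluded from roundness/area metrics, and an
#' incomplete 80% contour excludes the VCAR in/out comparison; peak metrics
#' are always reported.
#'
#' @param od,os [cone_mosaic()]s (either may be `NULL` for a one-eyed
#'   subject).
#' @param control A [map_control()] shared by all maps.
#' @param fractions Isodensity contour fractions.
#' @param subject_id,sex Labels; `subject_id` defaults to the mosaics'.
#' @param keep_maps Retain the `scalar_map`s in the report (memory-heavy).
#' @return An object of class `subject_report`: `eyes` (per-eye metric
#'   lists), `pair` (an `interocular_pair` or `NULL`), `exclusions`
#'   (character log).
#' @export
run_subject <- function(od = NULL, os = NULL, control = map_control(),
                        fractions = c(0.70, 0.75, 0.80, 0.85, 0.90),
                        subject_id = NULL, sex = NA_character_,
                        keep_maps = FALSE) {
  if (is.null(od) && is.null(os))
    fm_stop("at least one analyzable eye is required", "invalid_parameter")
  if (is.null(subject_id))
    subject_id <- if (!is.null(od)) od$subject_id else os$subject_id
  exclusions <- character()
  eyes <- list()
  density_maps <- list()
  for (eye in c("OD", "OS")) {
    mosaic <- if (eye == "OD") od else os
    if (is.null(mosaic)) next
    maps <- sum_maps(mosaic, control = control)
    pk <- extract_peak(maps$density)
    cs <- summarize_contours(maps$density, fractions = fractions)
    if (!cs$usable)
      exclusions <- c(exclusions, sprintf(
        "%s %s: %d/%d contours incomplete; excluded from roundness/area metrics",
        subject_id, eye, length(fractions) - cs$n_complete, length(fractions)))
    vio <- tryCatch(vcar_inside_outside(maps$vcar, cs$contours$f80),
                    error = function(e) {
                      exclusions <<- c(exclusions, sprintf(
                        "%s %s: 80%% contour unusable; excluded from VCAR in/out",
                        subject_id, eye))
                      list(mean_in = NA_real_, mean_out = NA_real_,
                           difference = NA_real_)
                    })
    eyes[[eye]] <- list(
      eye = eye,
      n_cones = nrow(mosaic$coords),
      peak_density = pk$value,
      peak_location_um = pk$location_um,
      icd_at_peak = metric_at(maps$spacing, pk$location_px),
      vcar_at_peak = metric_at(maps$vcar, pk$location_px),
      mean_roundness = cs$mean_roundness,
      mean_area_mm2 = cs$mean_area_mm2,
      contours_usable = cs$usable,
      vcar_in = vio$mean_in, vcar_out = vio$mean_out,
      vcar_in_out_diff = vio$difference,
      maps = if (keep_maps) maps else NULL)
    density_maps[[eye]] <- maps$density
  }
  pair <- NULL
  if (!is.null(density_maps$OD) && !is.null(density_maps$OS))
    pair <- align_difference(density_maps$OD, density_maps$OS,
                             subject_id = subject_id)
  structure(list(subject_id = subject_id, sex = sex, eyes = eyes,
                 pair = pair, exclusions = exclusions),
            class = "subject_report")
}

#' @export
print.subject_report <- function(x, ...) {
  cat(sprintf("subject_report %s (%s): eyes %s\n", x$subject_id, x$sex,
              paste(names(x$eyes), collapse = "+")))
  for (e in x$eyes)
    cat(sprintf(
      "  %s: peak %.0f /mm^2, ICD %.3f um, VCAR %.2f, roundness %s, area %s\n",
      e$eye, e$peak_density, e$icd_at_peak, e$vcar_at_peak,
      if (is.na(e$mean_roundness)) "excluded" else sprintf("%.3f", e$mean_roundness),
      if (is.na(e$mean_area_mm2)) "excluded" else sprintf("%.4g mm^2", e$mean_area_mm2)))
  if (!is.null(x$pair))
    cat(sprintf("  interocular mean |OD-OS| density: %.0f /mm^2\n",
                x$pair$mean_abs_diff))
  for (ex in x$exclusions) cat("  !", ex, "\n")
  invisible(x)
}

# tidy long rows from one subject report
subject_rows <- function(rep) {
  rows <- list()
  for (e in rep$eyes) {
    rows[[e$eye]] <- data.frame(
      subject = rep$subject_id, sex = rep$sex, eye = e$eye,
      metric = c("peak_density", "icd_at_peak", "vcar_at_peak",
                 "mean_roundness", "mean_area_mm2", "vcar_in_out_diff"),
      value = c(e$peak_density, e$icd_at_peak, e$vcar_at_peak,
                e$mean_roundness, e$mean_area_mm2, e$vcar_in_out_diff))
  }
  do.call(rbind, rows)
}

#' Run the analysis over a cohort and assemble the symmetry battery
#'
#' Applies [run_subject()] to every subject of a [generate_cohort()] result
#' (or a plain list of `list(od =, os =, subject_id =, sex =)` entries),
#' builds the tidy per-eye metric table, and runs the interocular symmetry
#' statistics per metric: Shapiro-Wilk-gated paired test, Bland-Altman with
#' CIs, Lin's concordance, per-sex subgroup tests; plus the peak-density
#' coefficient of variation of absolute differences, the smallest detectable
#' difference at the observed `sd_diff`, the peak-density-vs-VCAR
#' correlation, and the one-eye-per-subject VCAR inside/outside comparison.
#'
#' @param cohort A `fovea_cohort` or list of subject entries.
#' @param control A [map_control()] shared by all subjects.
#' @param fractions Contour fractions.
#' @param alpha_normality Normality gate for the paired tests.
#' @param progress Emit one message per subject.
#' @return An object of class `cohort_report`: `table` (tidy long data
#'   frame), `subjects` (list of `subject_report`s), `stats` (per-metric
#'   battery), `peak_cov`, `detectable_difference`, `density_vcar`,
#'   `vcar_inout`, `exclusions`.
#' @export
run_cohort <- function(cohort, control = map_control(),
                       fractions = c(0.70, 0.75, 0.80, 0.85, 0.90),
                       alpha_normality = 0.05, progress = FALSE) {
  subjects <- if (inherits(cohort, "fovea_cohort")) cohort$subjects else cohort
  stopifnot(length(subjects) >= 1)
  reports <- vector("list", length(subjects))
  for (i in seq_along(subjects)) {
    s <- subjects[[i]]
    if (progress) message(sprintf("analyzing %s (%d/%d)", s$subject_id, i,
                                  length(subjects)))
    reports[[i]] <- run_subject(od = s$od, os = s$os, control = control,
                                fractions = fractions,
                                subject_id = s$subject_id, sex = s$sex)
  }
  tab <- do.call(rbind, lapply(reports, subject_rows))
  rownames(tab) <- NULL

  wide <- function(metric) {
    sub <- tab[tab$metric == metric, ]
    ids <- unique(sub$subject)
    od <- sub[sub$eye == "OD", ]
    os <- sub[sub$eye == "OS", ]
    data.frame(subject = ids,
               sex = sub$sex[match(ids, sub$subject)],
               od = od$value[match(ids, od$subject)],
               os = os$value[match(ids, os$subject)])
  }
  metrics <- c("peak_density", "icd_at_peak", "vcar_at_peak",
               "mean_roundness", "mean_area_mm2")
  stats <- lapply(metrics, function(mt) {
    w <- wide(mt)
    ps <- paired_sample(w$od, w$os, subject = w$subject, metric = mt,
                        sex = w$sex)
    if (length(ps$x) < 3L) {
      fm_warn(sprintf("fewer than 3 complete pairs for %s; statistics skipped",
                      mt), "insufficient_pairs")
      return(NULL)
    }
    list(n = length(ps$x),
         test = paired_symmetry_test(ps, alpha_normality = alpha_normality),
         bland_altman = bland_altman(ps),
         by_sex = if (!is.null(ps$sex))
           suppressWarnings(subgroup_analysis(ps,
                                              alpha_normality = alpha_normality))
         else NULL)
  })
  names(stats) <- metrics

  wpk <- wide("peak_density")
  pk_pairs <- wpk[is.finite(wpk$od) & is.finite(wpk$os), ]
  abs_diffs <- abs(pk_pairs$od - pk_pairs$os)
  peak_cov <- if (nrow(pk_pairs) >= 2) cov_abs_diff(abs_diffs) else NA_real_
  det_diff <- if (!is.null(stats$peak_density))
    detectable_difference(stats$peak_density$n,
                          stats$peak_density$bland_altman$sd_diff)
  else NA_real_

  # one eye per subject (OD, else OS) for the density-regularity analyses
  one_eye <- function(metric) {
    w <- wide(metric)
    ifelse(is.finite(w$od), w$od, w$os)
  }
  dens1 <- one_eye("peak_density")
  vcar1 <- one_eye("vcar_at_peak")
  density_vcar <- tryCatch(density_vcar_correlation(dens1, vcar1),
                           error = function(e) NULL)
  vio1 <- one_eye("vcar_in_out_diff")
  vio1 <- vio1[is.finite(vio1)]
  vcar_inout <- if (length(vio1) >= 3)
    c(list(mean = mean(vio1), sd = sd(vio1), n = length(vio1)),
      unclass(t.test(vio1))[c("statistic", "parameter", "p.value")])
  else NULL

  structure(list(table = tab, subjects = reports, stats = stats,
                 mean_abs_diff_peak = if (length(abs_diffs)) mean(abs_diffs)
                                      else NA_real_,
                 peak_cov = peak_cov,
                 detectable_difference = det_diff,
                 density_vcar = density_vcar,
                 vcar_inout = vcar_inout,
                 exclusions = unlist(lapply(reports, `[[`, "exclusions"))),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("cohort_report: %d subjects, %d exclusion notes\n",
              length(x$subjects), length(x$exclusions)))
  for (mt in names(x$stats)) {
    st <- x$stats[[mt]]
    if (is.null(st)) next
    cat(sprintf(
      "  %-15s n=%2d OD %.5g+/-%.3g OS %.5g+/-%.3g %s p=%.3g r_c=%.2f bias %.4g\n",
      mt, st$n, st$test$mean_od, st$test$sd_od, st$test$mean_os,
      st$test$sd_os, st$test$test_used, st$test$p, st$test$ccc,
      st$bland_altman$bias))
  }
  if (is.finite(x$peak_cov))
    cat(sprintf("  peak density: mean |diff| %.0f, CoV %.0f%%, detectable diff %.0f\n",
                x$mean_abs_diff_peak, x$peak_cov, x$detectable_difference))
  if (!is.null(x$density_vcar))
    cat(sprintf("  density~VCAR: R^2 = %.3f, p = %.3g (n = %d)\n",
                x$density_vcar$r2, x$density_vcar$p, x$density_vcar$n))
  if (!is.null(x$vcar_inout))
    cat(sprintf("  VCAR in-out (one eye/subject): %.3f +/- %.3f, t = %.3g, p = %.3g\n",
                x$vcar_inout$mean, x$vcar_inout$sd, x$vcar_inout$statistic,
                x$vcar_inout$p.value))
  invisible(x)
}

#' Write a cohort report to CSV + JSON-lines
#'
#' The tidy table goes to `<stem>_metrics.csv`; the per-metric statistics to
#' `<stem>_stats.csv` (one row per metric). Deterministic given the same
#' report.
#'
#' @param report A `cohort_report`.
#' @param stem Output path stem.
#' @export
write_cohort_report <- function(report, stem) {
  stopifnot(inherits(report, "cohort_report"))
  write.table(report$table, paste0(stem, "_metrics.csv"), sep = ",",
              row.names = FALSE, quote = FALSE)
  rows <- lapply(names(report$stats), function(mt) {
    st <- report$stats[[mt]]
    if (is.null(st)) return(NULL)
    data.frame(metric = mt, n = st$n, test = st$test$test_used,
               statistic = st$test$statistic, p = st$test$p,
               shapiro_p = st$test$shapiro_p, pearson_r2 = st$test$pearson_r2,
               ccc = st$test$ccc, bias = st$bland_altman$bias,
               loa_low = st$bland_altman$loa_low,
               loa_high = st$bland_altman$loa_high)
  })
  write.table(do.call(rbind, rows), paste0(stem, "_stats.csv"), sep = ",",
              row.names = FALSE, quote = FALSE)
  invisible(stem)
}
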