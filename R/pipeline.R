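#' Pipeline run configuration
#'
#' Bundles the tunable parameters of the per-subject analysis and the I/O
#' locations. All tunables are validated against the ranges of their home
#' functions. A configuration can also be loaded from a YAML or JSON file
#' with [read_run_config()].
#'
#' @param input_dir Directory holding `subjects.csv`, `waveforms/`,
#'   `contours/` (the layout written by [write_cohort()]).
#' @param output_dir Directory for report files (created if needed).
#' @param foot_fraction Upstroke foot fraction, see [extract_upstroke()].
#' @param interp_factor,max_lag Transit-time settings, see [transit_time()].
#' @param bsa_formula `"mosteller"` or `"dubois"`, see [bsa()].
#' @param gap_mm Inter-slice gap for Simpson volumetry (default 0).
#' @param slice_thickness_mm Slice thickness of multi-slice contour stacks.
#' @param wall_positions Angular positions for [wall_thickness()].
#' @param seed Seed for any stochastic step.
#' @param verbose Emit progress messages.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(input_dir, output_dir = tempfile("vesselpulse-out"),
                       foot_fraction = 0.1, interp_factor = 16L,
                       max_lag = 100, bsa_formula = "mosteller", gap_mm = 0,
                       slice_thickness_mm = 6, wall_positions = 2L,
                       seed = 1L, verbose = FALSE) {
  stopifnot_scalar(foot_fraction, "foot_fraction", lower = 0, upper = 0.5,
                   strict_lower = TRUE, strict_upper = TRUE)
  interp_factor <- as.integer(interp_factor)
  if (interp_factor < 1L) stop("'interp_factor' must be >= 1")
  stopifnot_scalar(max_lag, "max_lag", lower = 0, strict_lower = TRUE)
  bsa_formula <- match.arg(bsa_formula, c("mosteller", "dubois"))
  stopifnot_scalar(gap_mm, "gap_mm", lower = 0)
  stopifnot_scalar(slice_thickness_mm, "slice_thickness_mm", lower = 0,
                   strict_lower = TRUE)
  wall_positions <- as.integer(wall_positions)
  if (wall_positions < 2L) stop("'wall_positions' must be >= 2")
  structure(list(input_dir = input_dir, output_dir = output_dir,
                 foot_fraction = foot_fraction,
                 interp_factor = interp_factor, max_lag = max_lag,
                 bsa_formula = bsa_formula, gap_mm = gap_mm,
                 slice_thickness_mm = slice_thickness_mm,
                 wall_positions = wall_positions, seed = as.integer(seed),
                 verbose = isTRUE(verbose)),
            class = "run_config")
}

#' Load a run configuration from YAML or JSON
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file whose keys are
#'   [run_config()] arguments.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the 'yaml' package")
    }
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    if (!requireNamespace("jsonlite", quietly = TRUE)) {
      stop("reading JSON configs requires the 'jsonlite' package")
    }
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("config file must end in .yaml, .yml or .json")
  }
  do.call(run_config, cfg)
}

read_csv_checked <- function(path, need) {
  if (!file.exists(path)) stop("input file missing: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("schema violation in ", path, ": missing column(s) ",
         paste(miss, collapse = ", "))
  }
  df
}

#' Read a flow-waveform CSV (`time_ms,flow_ml_s`)
#'
#' @param path CSV path.
#' @param site Site label for the waveform.
#' @return A [flow_waveform].
#' @export
read_waveform_csv <- function(path, site = basename(path)) {
  df <- read_csv_checked(path, c("time_ms", "flow_ml_s"))
  flow_waveform(df$time_ms, df$flow_ml_s, site)
}

#' Read a contour CSV
#'
#' Expects `subject_id,structure,slice_index,phase,vertex_index,x_mm,y_mm`
#' (`subject_id` optional).
#'
#' @param path CSV path.
#' @param slice_thickness_mm Slice thickness to attach, mm.
#' @return A [contour_set].
#' @export
read_contours_csv <- function(path, slice_thickness_mm = 6) {
  df <- read_csv_checked(path, c("structure", "slice_index", "phase",
                                 "vertex_index", "x_mm", "y_mm"))
  contour_set(df, slice_thickness_mm = slice_thickness_mm)
}

# area curve for one vessel structure from per-phase single-slice contours
contour_area_curve <- function(contours, structure) {
  sub <- contours[contours$structure == structure, , drop = FALSE]
  if (nrow(sub) == 0L) return(NULL)
  phases <- sort(unique(sub$phase))
  if (length(phases) < 3L) return(NULL)
  areas <- vapply(phases, function(ph) {
    s <- sub[sub$phase == ph, , drop = FALSE]
    s <- s[order(s$vertex_index), , drop = FALSE]
    polygon_area(cbind(s$x_mm, s$y_mm), check = FALSE)
  }, numeric(1))
  area_curve(areas, structure)
}

wall_pair_from_contours <- function(contours, side, level) {
  get_poly <- function(structure) {
    s <- contours[contours$structure == structure, , drop = FALSE]
    if (nrow(s) == 0L) return(NULL)
    s <- s[s$phase == min(s$phase), , drop = FALSE]
    s <- s[order(s$vertex_index), , drop = FALSE]
    cbind(s$x_mm, s$y_mm)
  }
  inner <- get_poly(paste0("carotid-inner-", side, "-", level))
  outer <- get_poly(paste0("carotid-outer-", side, "-", level))
  if (is.null(inner) || is.null(outer)) return(NULL)
  wall_contour_pair(inner, outer, side = side, level = level)
}

#' Run the full biomarker analysis for one subject
#'
#' Reads the subject's waveform and contour files, then computes every
#' biomarker the inputs support: per-location aortic (and carotid)
#' distensibility, per-segment PWV, LA landmark volumes and emptying
#' fractions, LV volumetrics and mass, and carotid wall morphometry.
#' Missing optional inputs yield `NA` fields, never silent zeros.
#'
#' @param config A [run_config].
#' @param subject_id Subject identifier (row in `subjects.csv`).
#' @return One-row data frame of biomarkers.
#' @export
run_subject <- function(config, subject_id) {
  subjects <- read_csv_checked(
    file.path(config$input_dir, "subjects.csv"),
    c("subject_id", "group", "height_cm", "weight_kg",
      "systolic_mmhg", "diastolic_mmhg"))
  subj <- subjects[subjects$subject_id == subject_id, , drop = FALSE]
  if (nrow(subj) != 1L) stop("subject '", subject_id, "' not found")

  bsa_i <- bsa(subj$height_cm, subj$weight_kg, config$bsa_formula)
  bp <- blood_pressure(subj$systolic_mmhg, subj$diastolic_mmhg)
  rec <- list(subject_id = subject_id, group = subj$group, bsa_m2 = bsa_i)

  # --- PWV per segment -----------------------------------------------------
  segs <- list(arch = "delta_x_arch_m", dao = "delta_x_dao_m",
               carotid_r = "delta_x_carotid_m",
               carotid_l = "delta_x_carotid_m")
  for (seg in names(segs)) {
    fp <- file.path(config$input_dir, "waveforms",
                    paste0(subject_id, "_", seg, "_proximal.csv"))
    fd <- file.path(config$input_dir, "waveforms",
                    paste0(subject_id, "_", seg, "_distal.csv"))
    key <- paste0("pwv_", seg, "_ms")
    if (file.exists(fp) && file.exists(fd) &&
        segs[[seg]] %in% names(subjects) && is.finite(subj[[segs[[seg]]]])) {
      est <- transit_time(read_waveform_csv(fp, seg),
                          read_waveform_csv(fd, seg),
                          interp_factor = config$interp_factor,
                          max_lag = config$max_lag,
                          foot_fraction = config$foot_fraction)
      rec[[key]] <- pulse_wave_velocity(est, subj[[segs[[seg]]]], seg)$pwv
    } else {
      rec[[key]] <- NA_real_
    }
  }

  # --- contours ------------------------------------------------------------
  cpath <- file.path(config$input_dir, "contours",
                     paste0(subject_id, ".csv"))
  contours <- if (file.exists(cpath)) {
    read_contours_csv(cpath, config$slice_thickness_mm)
  } else NULL

  dist_locs <- c(dist_root = "aortic root", dist_aao = "ascending aorta",
                 dist_isthmus = "isthmus",
                 dist_dao = "descending aorta at diaphragm",
                 dist_car_prox_r = "proximal carotid R",
                 dist_car_dist_r = "distal carotid R",
                 dist_car_prox_l = "proximal carotid L",
                 dist_car_dist_l = "distal carotid L")
  for (k in names(dist_locs)) {
    curve <- if (!is.null(contours)) {
      contour_area_curve(contours, dist_locs[[k]])
    } else NULL
    rec[[k]] <- if (is.null(curve)) NA_real_ else {
      ex <- area_extremes(curve)
      distensibility(ex["a_min"], ex["a_max"], bp,
                     dist_locs[[k]])$distensibility
    }
  }

  # --- LA volumetrics ------------------------------------------------------
  la_fields <- c("la_vol_max_i", "la_vol_ac_i", "la_vol_min_i",
                 "la_total_emptying_i", "la_v_passive_i",
                 "la_v_contractile_i", "laef_passive", "laef_contractile",
                 "laef_reservoir")
  rec[la_fields] <- NA_real_
  if (!is.null(contours) && any(contours$structure == "LA")) {
    phases <- sort(unique(contours$phase[contours$structure == "LA"]))
    vols <- vapply(phases, function(ph) {
      simpson_volume(contours, "LA", ph, gap_mm = config$gap_mm)
    }, numeric(1))
    lm <- la_landmarks(vols)
    laf <- la_function(vols[lm$phase_max], vols[lm$phase_ac],
                       vols[lm$phase_min], bsa = bsa_i)
    rec[la_fields] <- c(laf$vol_max, laf$vol_ac, laf$vol_min,
                        laf$total_emptying, laf$v_passive,
                        laf$v_contractile, laf$laef_passive,
                        laf$laef_contractile, laf$laef_reservoir)
  }

  # --- LV volumetrics ------------------------------------------------------
  lv_fields <- c("lvedv_i", "lvesv_i", "lvsv_i", "lvef", "lv_mass_i")
  rec[lv_fields] <- NA_real_
  if (!is.null(contours) && any(contours$structure == "LV-endo") &&
      any(contours$structure == "LV-epi")) {
    endo_phases <- sort(unique(contours$phase[contours$structure == "LV-endo"]))
    endo <- vapply(endo_phases, function(ph) {
      simpson_volume(contours, "LV-endo", ph, gap_mm = config$gap_mm)
    }, numeric(1))
    epi_ed <- simpson_volume(contours, "LV-epi",
                             min(contours$phase[contours$structure == "LV-epi"]),
                             gap_mm = config$gap_mm)
    lvf <- lv_function(max(endo), min(endo), max(epi_ed, max(endo)),
                       bsa = bsa_i)
    rec[lv_fields] <- c(lvf$edv, lvf$esv, lvf$sv, lvf$ef, lvf$mass)
  }

  # --- carotid wall --------------------------------------------------------
  for (side in c("right", "left")) {
    key_a <- paste0("wall_area_", substr(side, 1, 1))
    key_t <- paste0("wall_thick_", substr(side, 1, 1))
    pair <- if (!is.null(contours)) {
      wall_pair_from_contours(contours, side, "proximal")
    } else NULL
    if (is.null(pair)) {
      rec[[key_a]] <- NA_real_; rec[[key_t]] <- NA_real_
    } else {
      wm <- wall_metrics(pair, config$wall_positions)
      rec[[key_a]] <- wm$wall_area; rec[[key_t]] <- wm$wall_thickness
    }
  }

  as.data.frame(rec, stringsAsFactors = FALSE)
}

#' Run the whole cohort and emit the group-comparison report
#'
#' Analyzes every subject in `subjects.csv`, writes the per-subject record
#' table, a patients-versus-controls comparison (mean, SD per group and the
#' Mann-Whitney two-tailed p per variable, mirroring a clinical comparison
#' table), the coefficient table of the random-intercept distensibility
#' mixed model fitted on patients, and a run log echoing the configuration.
#'
#' @param config A [run_config].
#' @return (Invisibly) a list with `records`, `comparison`, `lme` and the
#'   paths of the written files.
#' @export
run_cohort <- function(config) {
  subjects <- read_csv_checked(
    file.path(config$input_dir, "subjects.csv"),
    c("subject_id", "group"))
  tab <- table(subjects$group)
  if (!all(c("patient", "control") %in% names(tab)) || any(tab < 2L)) {
    stop("need >= 2 subjects in each of the 'patient' and 'control' groups")
  }
  records <- do.call(rbind, lapply(subjects$subject_id, function(id) {
    if (config$verbose) message("analyzing subject ", id)
    suppressWarnings(run_subject(config, id))
  }))

  numvars <- setdiff(names(records)[vapply(records, is.numeric, logical(1))],
                     "bsa_m2")
  comparison <- do.call(rbind, lapply(numvars, function(v) {
    x <- records[[v]][records$group == "patient"]
    y <- records[[v]][records$group == "control"]
    x <- x[is.finite(x)]; y <- y[is.finite(y)]
    if (length(x) < 2L || length(y) < 2L) {
      return(data.frame(variable = v, patient_mean = NA, patient_sd = NA,
                        control_mean = NA, control_sd = NA, p = NA,
                        n_patient = length(x), n_control = length(y)))
    }
    mw <- mann_whitney(x, y)
    data.frame(variable = v,
               patient_mean = mean(x), patient_sd = stats::sd(x),
               control_mean = mean(y), control_sd = stats::sd(y),
               p = mw$p, n_patient = length(x), n_control = length(y))
  }))

  # distensibility mixed model on patients
  lme <- NULL
  pat <- records[records$group == "patient", , drop = FALSE]
  meta <- subjects[match(pat$subject_id, subjects$subject_id), , drop = FALSE]
  if (all(c("age_at_repair", "age_at_mri") %in% names(meta))) {
    key <- c(dist_root = "aortic root", dist_aao = "ascending aorta",
             dist_isthmus = "isthmus",
             dist_dao = "descending aorta at diaphragm")
    long <- do.call(rbind, lapply(names(key), function(k) {
      data.frame(subject_id = pat$subject_id, location = key[[k]],
                 distensibility = pat[[k]],
                 age_at_repair = meta$age_at_repair,
                 age_at_mri = meta$age_at_mri, stringsAsFactors = FALSE)
    }))
    long <- long[is.finite(long$distensibility) &
                   is.finite(long$age_at_repair), , drop = FALSE]
    lme <- tryCatch(fit_distensibility_lme(long),
                    error = function(e) {
                      warning("distensibility mixed model not fitted: ",
                              conditionMessage(e), call. = FALSE)
                      NULL
                    })
  }

  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  f_rec <- file.path(config$output_dir, "subject_records.csv")
  f_cmp <- file.path(config$output_dir, "group_comparison.csv")
  f_lme <- file.path(config$output_dir, "lme_coefficients.csv")
  f_log <- file.path(config$output_dir, "run_log.txt")
  utils::write.csv(records, f_rec, row.names = FALSE)
  utils::write.csv(comparison, f_cmp, row.names = FALSE)
  if (!is.null(lme)) {
    utils::write.csv(lme$fixed_effects, f_lme, row.names = FALSE)
  }
  n_na <- vapply(records, function(x) {
    if (is.numeric(x)) sum(!is.finite(x)) else 0L
  }, integer(1))
  n_na <- n_na[n_na > 0]
  log_lines <- c(
    paste0("vesselpulse ", as.character(utils::packageVersion("vesselpulse"))),
    paste0("run at ", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    "config:",
    paste0("  ", names(unclass(config)), " = ",
           vapply(unclass(config), function(x) paste(format(x), collapse = ","),
                  character(1))),
    if (length(n_na)) c("missing (NA) fields:",
                        paste0("  ", names(n_na), ": ", n_na, " subject(s)"))
    else "missing (NA) fields: none"
  )
  writeLines(log_lines, f_log)

  invisible(list(records = records, comparison = comparison, lme = lme,
                 files = c(records = f_rec, comparison = f_cmp,
                           lme = if (!is.null(lme)) f_lme else NA_character_,
                           log = f_log)))
}
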