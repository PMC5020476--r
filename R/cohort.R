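#' Default cohort parameter table
#'
#' Group means and SDs for the simulated two-group (post-repair coarctation
#' patients versus healthy controls) cohort: demographics, cuff pressures,
#' regional aortic distensibility and pulse wave velocity, left-atrial and
#' left-ventricular volumetric components, and the carotid-substudy
#' quantities. Values are the published cohort summaries this generator
#' emulates; the LA and LV volumes are parameterized through their
#' independent components (Vmin, contractile and passive emptying volumes;
#' ESV and SV) so that the landmark ordering Vmax >= Vac >= Vmin and
#' EDV >= ESV hold by construction. Each parameter carries a physiologic
#' floor at which the normal draw is truncated.
#'
#' @return Data frame with columns `name`, `patient_mean`, `patient_sd`,
#'   `control_mean`, `control_sd`, `floor`.
#' @export
cohort_defaults <- function() {
  p <- function(name, pm, ps, cm, cs, fl) {
    data.frame(name = name, patient_mean = pm, patient_sd = ps,
               control_mean = cm, control_sd = cs, floor = fl,
               stringsAsFactors = FALSE)
  }
  rbind(
    p("height_cm",          163.7, 24.2, 165.5, 20.9, 60),
    p("weight_kg",           61.8, 26.6,  58.0, 21.3,  8),
    p("sbp_mmhg",           111.9, 15.4, 107.0,  8.7, 70),
    p("dbp_mmhg",            60.5,  9.6,  61.6, 10.5, 35),
    p("hr_bpm",              74.1, 15.7,  70.3, 16.9, 40),
    p("age_mri_y",           18.0, 11.0,  20.0, 10.0,  0.9),
    p("age_repair_y",         4.2,  6.1,    NA,   NA,  0.01),
    p("pwv_arch_ms",          4.6,  1.7,   3.5,  0.8,  0.5),
    p("pwv_dao_ms",           4.3,  1.6,   3.9,  0.8,  0.5),
    p("dist_root",            5.6,  3.8,   7.4,  3.0,  0.3),
    p("dist_aao",             5.8,  3.1,   8.1,  3.6,  0.3),
    p("dist_isthmus",         5.7,  3.0,   6.8,  2.3,  0.3),
    p("dist_dao",             6.8,  2.8,   8.0,  2.8,  0.3),
    p("area_root_i",        449.5, 126.1, 440.5, 93.0, 100),
    p("area_aao_i",         353.2, 104.5, 356.3, 68.4,  80),
    p("area_isthmus_i",     163.2, 61.5, 176.9, 32.0,  40),
    p("area_dao_i",         151.9, 35.3, 155.2, 38.0,  40),
    p("la_vmin_i",           24.6,  6.1,  20.9,  5.1,   5),
    p("la_vcontractile_i",    7.7,  3.3,   6.5,  2.7,   0.5),
    p("la_vpassive_i",       15.3,  5.0,  15.6,  4.9,   0.5),
    p("lv_esv_i",            30.4, 12.0,  31.0,  6.2,   8),
    p("lv_sv_i",             50.6,  8.2,  49.0,  7.9,  15),
    p("lv_mass_i",           60.7, 14.1,  57.5, 14.2,  20),
    p("pwv_carotid_r",        6.8,  4.1,   3.3,  1.5,   0.5),
    p("pwv_carotid_l",        6.9,  4.0,   4.2,  1.7,   0.5),
    p("wall_area_r",         19.4,  2.4,  15.3,  2.6,   5),
    p("wall_area_l",         19.7,  4.1,  15.8,  1.9,   5),
    p("wall_thick_r",        0.90, 0.12,  0.75, 0.09,   0.3),
    p("wall_thick_l",        0.90, 0.12,  0.76, 0.08,   0.3),
    p("dist_car_prox_r",     10.4,  7.0,   5.9,  3.8,   0.3),
    p("dist_car_dist_r",      8.3,  2.9,   7.9,  3.0,   0.3),
    p("dist_car_prox_l",      8.7,  5.8,   8.1,  5.5,   0.3),
    p("dist_car_dist_l",      7.1,  4.8,   6.2,  2.2,   0.3)
  )
}

#' Specification for a simulated two-group cohort
#'
#' @param n_patients,n_controls Group sizes (>= 2 each); defaults are the
#'   study group sizes 51 and 54.
#' @param n_carotid_patients,n_carotid_controls Sizes of the carotid
#'   substudy subgroups (first subjects of each group), capped at the group
#'   size; defaults 11 and 13.
#' @param params Parameter table as returned by [cohort_defaults()];
#'   override rows to change the simulated conditions.
#' @param correlations List of rank-correlation knobs, each a list with
#'   elements `a`, `b` (parameter names) and `rho` (target Spearman
#'   correlation in \[-1, 1\]). Induced by Gaussian-copula ordering (the
#'   published associations are rank correlations). Knobs referencing
#'   `age_repair_y` apply to patients only. Defaults encode the positive
#'   association of descending-aorta PWV (and the negative association of
#'   isthmus distensibility) with age at repair, and the tendency of
#'   later-repaired patients to be older at imaging.
#' @param seed Integer RNG seed.
#' @return A validated list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 51L, n_controls = 54L,
                        n_carotid_patients = 11L, n_carotid_controls = 13L,
                        params = cohort_defaults(),
                        correlations = list(
                          list(a = "age_repair_y", b = "pwv_dao_ms", rho = 0.33),
                          list(a = "age_repair_y", b = "dist_isthmus", rho = -0.33),
                          list(a = "age_repair_y", b = "age_mri_y", rho = 0.5)
                        ),
                        seed = 1L) {
  n_patients <- as.integer(n_patients); n_controls <- as.integer(n_controls)
  if (n_patients < 2L || n_controls < 2L) stop("need n >= 2 per group")
  n_carotid_patients <- min(as.integer(n_carotid_patients), n_patients)
  n_carotid_controls <- min(as.integer(n_carotid_controls), n_controls)
  need <- c("name", "patient_mean", "patient_sd", "control_mean",
            "control_sd", "floor")
  if (!all(need %in% names(params))) {
    stop("'params' must have columns ", paste(need, collapse = ", "))
  }
  if (any(stats::na.omit(c(params$patient_sd, params$control_sd)) < 0)) {
    stop("SDs must be >= 0")
  }
  for (k in correlations) {
    if (!all(c(k$a, k$b) %in% params$name)) {
      stop("correlation knob references unknown parameter")
    }
    if (abs(k$rho) > 1) stop("correlation knobs must lie in [-1, 1]")
  }
  structure(list(n_patients = n_patients, n_controls = n_controls,
                 n_carotid_patients = n_carotid_patients,
                 n_carotid_controls = n_carotid_controls,
                 params = params, correlations = correlations,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# draw n subjects for one group: Gaussian copula with truncated-normal margins
draw_group <- function(n, params, means, sds, correlations) {
  keep <- is.finite(means)
  nm <- params$name[keep]
  means <- means[keep]; sds <- sds[keep]; floors <- params$floor[keep]
  p <- length(nm)
  sigma <- diag(p)
  dimnames(sigma) <- list(nm, nm)
  for (k in correlations) {
    if (k$a %in% nm && k$b %in% nm) {
      r <- 2 * sin(pi * k$rho / 6)  # Spearman target -> Gaussian-copula Pearson
      sigma[k$a, k$b] <- sigma[k$b, k$a] <- r
    }
  }
  ch <- tryCatch(chol(sigma),
                 error = function(e) stop("infeasible correlation matrix"))
  z <- matrix(stats::rnorm(n * p), n, p) %*% ch
  u <- stats::pnorm(z)
  x <- matrix(NA_real_, n, p, dimnames = list(NULL, nm))
  for (j in seq_len(p)) {
    if (sds[j] == 0) {
      x[, j] <- means[j]
    } else {
      # truncate the normal margin at the physiologic floor via its CDF
      plo <- stats::pnorm((floors[j] - means[j]) / sds[j])
      x[, j] <- means[j] +
        sds[j] * stats::qnorm(plo + u[, j] * (1 - plo))
    }
  }
  as.data.frame(x)
}

#' Simulate a two-group cohort with known per-subject ground truth
#'
#' Draws per-subject latent biomarker values from group-specific truncated
#' normal distributions linked by a Gaussian copula (so requested rank
#' correlations are induced), then optionally materializes raw inputs --
#' flow-waveform pairs whose transit delay encodes the subject's true PWV,
#' single-slice lumen contours encoding the true distensibility,
#' ellipsoidal LA and LV contour stacks encoding the true chamber volumes,
#' and carotid wall rings encoding the true wall area and thickness -- so
#' the full analysis pipeline can run end-to-end against known truth.
#' Reproducible under the spec seed.
#'
#' @param spec A [cohort_spec].
#' @param materialize Also generate raw waveforms/contours per subject
#'   (default `TRUE`); with `FALSE` only the subject table and latent truth
#'   are returned (sufficient for statistical power studies).
#' @return Object of class `vp_cohort`: `subjects` (data frame: identifiers,
#'   demographics, pressures, path lengths), `truth` (data frame of latent
#'   per-subject biomarker values, one column per parameter), and -- when
#'   materialized -- `inputs`, a per-subject list with `waveforms` (named
#'   segments, each `list(proximal, distal, delta_x)`) and `contours`
#'   (a [contour_set]).
#' @export
make_cohort <- function(spec, materialize = TRUE) {
  if (!inherits(spec, "cohort_spec")) stop("'spec' must be a cohort_spec")
  with_seed(spec$seed, {
    pr <- spec$params
    pat <- draw_group(spec$n_patients, pr, pr$patient_mean, pr$patient_sd,
                      spec$correlations)
    ctl <- draw_group(spec$n_controls, pr, pr$control_mean, pr$control_sd,
                      spec$correlations)
    ctl[setdiff(names(pat), names(ctl))] <- NA_real_
    truth <- rbind(pat[, names(pat)], ctl[, names(pat)])
    n <- nrow(truth)
    grp <- rep(c("patient", "control"), c(spec$n_patients, spec$n_controls))
    sexes <- c(
      sample(rep(c("F", "M"), length.out = spec$n_patients)),
      sample(rep(c("F", "M"), length.out = spec$n_controls))
    )
    # guarantee a physiologic pulse pressure
    truth$sbp_mmhg <- pmax(truth$sbp_mmhg, truth$dbp_mmhg + 10)
    # patients repaired before imaging
    truth$age_repair_y <- pmin(truth$age_repair_y, truth$age_mri_y * 0.95)
    has_car <- c(seq_len(spec$n_patients) <= spec$n_carotid_patients,
                 seq_len(spec$n_controls) <= spec$n_carotid_controls)
    scale_len <- truth$height_cm / 165
    subjects <- data.frame(
      subject_id = sprintf("S%03d", seq_len(n)),
      group = grp,
      sex = sexes,
      age_at_mri = truth$age_mri_y,
      age_at_repair = ifelse(grp == "patient", truth$age_repair_y, NA_real_),
      height_cm = truth$height_cm,
      weight_kg = truth$weight_kg,
      systolic_mmhg = truth$sbp_mmhg,
      diastolic_mmhg = truth$dbp_mmhg,
      heart_rate_bpm = truth$hr_bpm,
      antihypertensive_treatment =
        grp == "patient" & stats::runif(n) < 13 / 51,
      has_carotid = has_car,
      delta_x_arch_m = 0.12 * scale_len,
      delta_x_dao_m = 0.16 * scale_len,
      delta_x_carotid_m = 0.045 * scale_len,
      stringsAsFactors = FALSE
    )
    subjects$bsa_m2 <- bsa(subjects$height_cm, subjects$weight_kg)
    inputs <- NULL
    if (materialize) {
      inputs <- lapply(seq_len(n), function(i) {
        materialize_subject(subjects[i, ], truth[i, ],
                            seed = (spec$seed %% 1000000L) * 1000L + i)
      })
      names(inputs) <- subjects$subject_id
    }
    structure(list(spec = spec, subjects = subjects, truth = truth,
                   inputs = inputs),
              class = "vp_cohort")
  })
}

#' @method print vp_cohort
#' @export
print.vp_cohort <- function(x, ...) {
  tab <- table(x$subjects$group)
  cat(sprintf("<vp_cohort> %d patients, %d controls%s\n",
              tab[["patient"]], tab[["control"]],
              if (is.null(x$inputs)) " (latent only)" else ", raw inputs materialized"))
  invisible(x)
}

# circle contour rows for one structure/phase
circle_rows <- function(structure, phase, area_mm2, m = 64L, slice_index = 1L,
                        center = c(0, 0)) {
  r <- sqrt(area_mm2 / pi)
  ang <- 2 * pi * (0:(m - 1L)) / m
  data.frame(structure = structure, slice_index = slice_index, phase = phase,
             vertex_index = seq_len(m),
             x_mm = center[1] + r * cos(ang), y_mm = center[2] + r * sin(ang))
}

# raw inputs for one subject from its latent truth
materialize_subject <- function(subj, tru, seed = 1L) {
  pp <- subj$systolic_mmhg - subj$diastolic_mmhg
  bsa_i <- subj$bsa_m2
  rr <- 60000 / subj$heart_rate_bpm

  wf_for <- function(pwv, delta_x, sd_off) {
    delay <- delta_x / pwv * 1000
    sp <- waveform_spec(rr_interval = rr, sample_spacing = 9,
                        systole_onset = 60, upstroke_duration = 300,
                        peak_flow = 400, baseline_flow = 6, true_delay = delay,
                        attenuation = 0.85, noise_sd = 4,
                        seed = seed + sd_off)
    pair <- make_waveform_pair(sp)
    list(proximal = pair$proximal, distal = pair$distal, delta_x = delta_x,
         true_delay = delay)
  }
  waveforms <- list(
    arch = wf_for(tru$pwv_arch_ms, subj$delta_x_arch_m, 1L),
    dao = wf_for(tru$pwv_dao_ms, subj$delta_x_dao_m, 2L)
  )

  rows <- list()
  # aortic lumen: one circular contour per phase whose area follows the
  # pulsation curve of the location's true distensibility
  aorta <- list(
    c("aortic root", "area_root_i", "dist_root"),
    c("ascending aorta", "area_aao_i", "dist_aao"),
    c("isthmus", "area_isthmus_i", "dist_isthmus"),
    c("descending aorta at diaphragm", "area_dao_i", "dist_dao")
  )
  for (k in seq_along(aorta)) {
    loc <- aorta[[k]][1]
    a_max <- tru[[aorta[[k]][2]]] * bsa_i
    d <- tru[[aorta[[k]][3]]]
    a_min <- a_max / (1 + d * 1e-3 * pp)
    curve <- make_area_curve(
      lumen_spec(a_min = a_min, target_distensibility = d,
                 pulse_pressure = pp, phases = 25L), location = loc)
    for (ph in seq_along(curve$areas)) {
      rows[[length(rows) + 1L]] <-
        circle_rows(loc, ph, curve$areas[ph], m = 48L)
    }
  }

  # LA: ellipsoidal stack following the canonical bi-phasic volume profile
  la_abs <- c(
    vmin = tru$la_vmin_i * bsa_i,
    vac = (tru$la_vmin_i + tru$la_vcontractile_i) * bsa_i,
    vmax = (tru$la_vmin_i + tru$la_vcontractile_i + tru$la_vpassive_i) * bsa_i
  )
  la_prof <- make_la_profile(la_abs["vmax"], la_abs["vac"], la_abs["vmin"],
                             phases = 25L)
  a_la <- (3 * la_abs["vmax"] * 1000 / (4 * pi * 1.3))^(1 / 3)
  la_stack <- make_ellipsoid_stack(
    ellipsoid_spec(semi_axes = c(a_la, a_la, 1.3 * a_la), slice_thickness = 6,
                   vertices_per_contour = 48L, phases = 25L,
                   volume_time_profile = (la_prof / max(la_prof))^(1 / 3)),
    structure = "LA")

  # LV: endocardial stack at ED (phase 1) and ES (phase 2), epicardial at ED
  edv <- (tru$lv_esv_i + tru$lv_sv_i) * bsa_i
  esv <- tru$lv_esv_i * bsa_i
  epi <- edv + tru$lv_mass_i * bsa_i / 1.05
  a_lv <- function(V) (3 * V * 1000 / (4 * pi * 1.8))^(1 / 3)
  lv_endo <- make_ellipsoid_stack(
    ellipsoid_spec(semi_axes = c(a_lv(edv), a_lv(edv), 1.8 * a_lv(edv)),
                   slice_thickness = 6, vertices_per_contour = 48L,
                   phases = 2L,
                   volume_time_profile = c(1, (esv / edv)^(1 / 3))),
    structure = "LV-endo")
  lv_epi <- make_ellipsoid_stack(
    ellipsoid_spec(semi_axes = c(a_lv(epi), a_lv(epi), 1.8 * a_lv(epi)),
                   slice_thickness = 6, vertices_per_contour = 48L,
                   phases = 1L),
    structure = "LV-epi")

  if (isTRUE(subj$has_carotid)) {
    waveforms$carotid_r <- wf_for(tru$pwv_carotid_r, subj$delta_x_carotid_m, 3L)
    waveforms$carotid_l <- wf_for(tru$pwv_carotid_l, subj$delta_x_carotid_m, 4L)
    for (side in c("r", "l")) {
      w <- tru[[paste0("wall_area_", side)]]
      t <- tru[[paste0("wall_thick_", side)]]
      r_in <- (w / (pi * t) - t) / 2
      lab <- if (side == "r") "right" else "left"
      rows[[length(rows) + 1L]] <-
        circle_rows(paste0("carotid-inner-", lab, "-proximal"), 1L,
                    pi * r_in^2, m = 64L)
      rows[[length(rows) + 1L]] <-
        circle_rows(paste0("carotid-outer-", lab, "-proximal"), 1L,
                    pi * (r_in + t)^2, m = 64L)
      for (lev in c("prox", "dist")) {
        loc <- paste0(if (lev == "prox") "proximal" else "distal",
                      " carotid ", toupper(side))
        d <- tru[[paste0("dist_car_", lev, "_", side)]]
        curve <- make_area_curve(
          lumen_spec(a_min = 28, target_distensibility = d,
                     pulse_pressure = pp, phases = 25L), location = loc)
        for (ph in seq_along(curve$areas)) {
          rows[[length(rows) + 1L]] <-
            circle_rows(loc, ph, curve$areas[ph], m = 48L)
        }
      }
    }
  }

  vessel <- do.call(rbind, rows)
  contours <- contour_set(
    rbind(vessel, as.data.frame(la_stack), as.data.frame(lv_endo),
          as.data.frame(lv_epi)),
    slice_thickness_mm = 6)
  list(waveforms = waveforms, contours = contours)
}

#' Write a materialized cohort to the pipeline's CSV layout
#'
#' Emits exactly the CSV dialects the pipeline reads, so generated fixtures
#' are indistinguishable from real exports: `subjects.csv`, one waveform CSV
#' per site (`waveforms/<id>_<segment>_<proximal|distal>.csv` with columns
#' `time_ms,flow_ml_s`), and one contour CSV per subject
#' (`contours/<id>.csv` with columns
#' `subject_id,structure,slice_index,phase,vertex_index,x_mm,y_mm`).
#'
#' @param cohort A materialized `vp_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!inherits(cohort, "vp_cohort")) stop("'cohort' must be a vp_cohort")
  if (is.null(cohort$inputs)) {
    stop("cohort was generated with materialize = FALSE; nothing to write")
  }
  dir.create(file.path(dir, "waveforms"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "contours"), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort$subjects, file.path(dir, "subjects.csv"),
                   row.names = FALSE)
  for (id in names(cohort$inputs)) {
    inp <- cohort$inputs[[id]]
    for (seg in names(inp$waveforms)) {
      wfp <- inp$waveforms[[seg]]
      for (end in c("proximal", "distal")) {
        w <- wfp[[end]]
        utils::write.csv(
          data.frame(time_ms = w$times, flow_ml_s = w$flow),
          file.path(dir, "waveforms", paste0(id, "_", seg, "_", end, ".csv")),
          row.names = FALSE)
      }
    }
    df <- as.data.frame(inp$contours)
    df <- cbind(subject_id = id, df)
    utils::write.csv(df, file.path(dir, "contours", paste0(id, ".csv")),
                     row.names = FALSE)
  }
  invisible(dir)
}
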