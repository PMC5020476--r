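#' Construct a contour set
#'
#' Per-structure, per-slice, per-phase planar polygons, the substrate for all
#' areas and chamber volumes. One row per vertex, matching the contour CSV
#' dialect `subject_id,structure,slice_index,phase,vertex_index,x_mm,y_mm`
#' (the `subject_id` column is optional in-memory).
#'
#' @param df Data frame with columns `structure`, `slice_index`, `phase`,
#'   `vertex_index`, `x_mm`, `y_mm`.
#' @param slice_thickness_mm Common slice thickness in mm (> 0), shared by
#'   all multi-slice structures in the set.
#' @return Object of class `contour_set` (the data frame, with the thickness
#'   stored as attribute `slice_thickness_mm`).
#' @export
contour_set <- function(df, slice_thickness_mm = 6) {
  need <- c("structure", "slice_index", "phase", "vertex_index", "x_mm", "y_mm")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("contour table lacks columns: ", paste(miss, collapse = ", "))
  stopifnot_scalar(slice_thickness_mm, "slice_thickness_mm", lower = 0,
                   strict_lower = TRUE)
  df <- as.data.frame(df)
  if (!all(is.finite(df$x_mm)) || !all(is.finite(df$y_mm))) {
    stop("contour vertices contain non-finite coordinates")
  }
  attr(df, "slice_thickness_mm") <- slice_thickness_mm
  class(df) <- c("contour_set", "data.frame")
  df
}

slice_thickness_of <- function(contours) {
  th <- attr(contours, "slice_thickness_mm")
  if (is.null(th)) stop("contour set carries no slice thickness")
  th
}

#' Chamber volume by Simpson's rule
#'
#' Volume of a chamber at one cardiac phase as the sum over slices of
#' planimetered polygon area times slice spacing (the accepted meaning of
#' "Simpson's rule" in cardiac MR -- slice-area summation, not the
#' quadrature rule of the same name). Slices without a contour at the phase
#' contribute nothing; a phase with no contours at all is an error, never a
#' silent zero volume.
#'
#' @param contours A [contour_set].
#' @param structure Structure label to planimeter (`"LA"`, `"LV-endo"`,
#'   `"LV-epi"`, ...).
#' @param phase Cardiac phase index.
#' @param gap_mm Inter-slice gap added to the thickness (default 0).
#' @param check_polygons Verify polygon simplicity (slower); off by default
#'   for bulk use on generated contours.
#' @return Volume in ml.
#' @export
simpson_volume <- function(contours, structure, phase, gap_mm = 0,
                           check_polygons = FALSE) {
  if (!inherits(contours, "contour_set")) {
    stop("'contours' must be a contour_set")
  }
  stopifnot_scalar(gap_mm, "gap_mm", lower = 0)
  th <- slice_thickness_of(contours) + gap_mm
  sub <- contours[contours$structure == structure & contours$phase == phase, ,
                  drop = FALSE]
  if (nrow(sub) == 0L) {
    stop("no contours for structure '", structure, "' at phase ", phase)
  }
  areas <- vapply(split(sub, sub$slice_index), function(s) {
    s <- s[order(s$vertex_index), , drop = FALSE]
    polygon_area(cbind(s$x_mm, s$y_mm), check = check_polygons)
  }, numeric(1))
  sum(areas) * th / 1000  # mm^3 -> ml
}

#' Left-atrial volume-curve landmarks
#'
#' Identifies the three LA landmark phases on a volume-versus-phase curve
#' covering one cardiac cycle: the maximal volume before mitral valve
#' opening, the volume just before atrial contraction (the pre-atrial-kick
#' shoulder), and the minimal volume at mitral valve closure.
#' `phase_max` is the global maximum; `phase_min` is the global minimum
#' occurring after `phase_max`; `phase_ac` is the last local maximum strictly
#' between them. When no interior local maximum exists (fused diastasis and
#' atrial kick), a fallback selects the phase of minimal downslope magnitude
#' between mid-diastole and `phase_min`, and the result is flagged.
#'
#' @param volumes Numeric vector of LA volumes (ml), one per phase, >= 3
#'   phases over a full cycle.
#' @return List with `phase_max`, `phase_ac`, `phase_min` (1-based phase
#'   indices) and logical `fallback`.
#' @export
la_landmarks <- function(volumes) {
  v <- as.numeric(volumes)
  n <- length(v)
  if (n < 3L) stop("LA landmarking needs >= 3 phases")
  if (!all(is.finite(v))) stop("volume curve contains non-finite values")
  if (diff(range(v)) == 0) stop("no atrial cycle detected: constant volume curve")
  i_max <- which.max(v)
  if (i_max >= n) stop("no atrial cycle detected: maximum at the end of the cycle")
  after <- (i_max + 1L):n
  if (min(v[after]) > min(v)) {
    stop("no atrial cycle detected: global minimum precedes the maximum")
  }
  i_min <- after[which.min(v[after])]
  # keep the latest phase attaining the minimum (mitral closure)
  i_min <- max(after[v[after] == v[i_min]])

  fallback <- FALSE
  interior <- if (i_min - i_max >= 2L) (i_max + 1L):(i_min - 1L) else integer()
  i_ac <- NA_integer_
  if (length(interior)) {
    is_locmax <- vapply(interior, function(k) {
      v[k] >= v[k - 1L] && v[k] > v[k + 1L] && v[k] < v[i_max]
    }, logical(1))
    if (any(is_locmax)) i_ac <- max(interior[is_locmax])
  }
  if (is.na(i_ac)) {
    if (!length(interior)) {
      stop("no atrial cycle detected: no phases between maximum and minimum")
    }
    # fallback: flattest point of the emptying limb from mid-diastole on
    fallback <- TRUE
    k_mid <- i_max + max(1L, (i_min - i_max) %/% 2L)
    cand <- k_mid:(i_min - 1L)
    slopes <- abs(v[cand + 1L] - v[cand])
    i_ac <- cand[which.min(slopes)]
  }
  list(phase_max = i_max, phase_ac = i_ac, phase_min = i_min,
       fallback = fallback)
}

#' Left-atrial function parameters
#'
#' The six LA emptying parameters derived from the three landmark volumes,
#' indexed to body surface area:
#' total emptying volume = Vmax - Vmin; passive emptying volume
#' V_Passive = Vmax - Vac; contractile volume V_Contractile = Vac - Vmin;
#' LAEF_Passive = (Vmax - Vac) * 100 / Vmax;
#' LAEF_Contractile = (Vac - Vmin) * 100 / Vac;
#' LAEF_Reservoir = (Vmax - Vmin) * 100 / Vmax.
#' The reservoir fraction satisfies the algebraic identity
#' LAEF_Reservoir = 100 * (1 - (1 - LAEF_Passive/100) * (1 - LAEF_Contractile/100)).
#' The emptying fractions are ratios and therefore unaffected by BSA
#' indexing; volumes are reported per m^2.
#'
#' @param vol_max,vol_ac,vol_min Landmark volumes in ml,
#'   `vol_max >= vol_ac >= vol_min >= 0`, `vol_max > 0`.
#' @param bsa Body surface area in m^2 (> 0); default 1 leaves volumes
#'   unindexed.
#' @return Object of class `la_function`: indexed volumes (`vol_max`,
#'   `vol_ac`, `vol_min`, `total_emptying`, `v_passive`, `v_contractile`,
#'   ml/m^2) and fractions (`laef_passive`, `laef_contractile`,
#'   `laef_reservoir`, percent).
#' @examples
#' la_function(47.5, 32.3, 24.6)$v_contractile  # 7.7
#' @export
la_function <- function(vol_max, vol_ac, vol_min, bsa = 1) {
  stopifnot_scalar(vol_max, "vol_max", lower = 0, strict_lower = TRUE)
  stopifnot_scalar(vol_ac, "vol_ac", lower = 0)
  stopifnot_scalar(vol_min, "vol_min", lower = 0)
  stopifnot_scalar(bsa, "bsa", lower = 0, strict_lower = TRUE)
  if (vol_max < vol_ac || vol_ac < vol_min) {
    stop("landmark volumes must satisfy vol_max >= vol_ac >= vol_min")
  }
  laef_contractile <- if (vol_ac > 0) (vol_ac - vol_min) * 100 / vol_ac else 0
  structure(list(
    vol_max = vol_max / bsa,
    vol_ac = vol_ac / bsa,
    vol_min = vol_min / bsa,
    total_emptying = (vol_max - vol_min) / bsa,
    v_passive = (vol_max - vol_ac) / bsa,
    v_contractile = (vol_ac - vol_min) / bsa,
    laef_passive = (vol_max - vol_ac) * 100 / vol_max,
    laef_contractile = laef_contractile,
    laef_reservoir = (vol_max - vol_min) * 100 / vol_max,
    bsa = bsa
  ), class = "la_function")
}

#' @method print la_function
#' @export
print.la_function <- function(x, ...) {
  cat(sprintf(
    paste0("<la_function> Vmax %.1f, Vac %.1f, Vmin %.1f ml/m^2 | ",
           "V_Passive %.1f, V_Contractile %.1f ml/m^2\n",
           "  LAEF passive %.1f%%, contractile %.1f%%, reservoir %.1f%%\n"),
    x$vol_max, x$vol_ac, x$vol_min, x$v_passive, x$v_contractile,
    x$laef_passive, x$laef_contractile, x$laef_reservoir))
  invisible(x)
}

#' Left-ventricular function parameters
#'
#' Stroke volume, ejection fraction and myocardial mass from endocardial and
#' epicardial volumes: SV = EDV - ESV, EF = 100 * SV / EDV, and
#' mass = (epicardial EDV - endocardial EDV) * 1.05 g/ml (the standard
#' myocardial density). Volumes and mass are indexed to BSA.
#'
#' @param endo_ed Endocardial end-diastolic volume (LVEDV), ml.
#' @param endo_es Endocardial end-systolic volume (LVESV), ml.
#' @param epi_ed Epicardial end-diastolic volume, ml;
#'   `epi_ed >= endo_ed >= endo_es >= 0` and `endo_ed > 0`.
#' @param bsa Body surface area in m^2 (> 0); default 1 leaves values
#'   unindexed.
#' @return Object of class `lv_function`: `edv`, `esv`, `sv` (ml/m^2),
#'   `ef` (%), `mass` (g/m^2).
#' @examples
#' lv_function(81.0, 30.4, 140)$sv  # 50.6
#' @export
lv_function <- function(endo_ed, endo_es, epi_ed, bsa = 1) {
  stopifnot_scalar(endo_ed, "endo_ed", lower = 0, strict_lower = TRUE)
  stopifnot_scalar(endo_es, "endo_es", lower = 0)
  stopifnot_scalar(epi_ed, "epi_ed", lower = 0)
  stopifnot_scalar(bsa, "bsa", lower = 0, strict_lower = TRUE)
  if (epi_ed < endo_ed || endo_ed < endo_es) {
    stop("volumes must satisfy epi_ed >= endo_ed >= endo_es")
  }
  sv <- endo_ed - endo_es
  structure(list(
    edv = endo_ed / bsa,
    esv = endo_es / bsa,
    sv = sv / bsa,
    ef = 100 * sv / endo_ed,
    mass = (epi_ed - endo_ed) * 1.05 / bsa,
    bsa = bsa
  ), class = "lv_function")
}

#' @method print lv_function
#' @export
print.lv_function <- function(x, ...) {
  cat(sprintf(
    "<lv_function> EDV %.1f, ESV %.1f, SV %.1f ml/m^2, EF %.1f%%, mass %.1f g/m^2\n",
    x$edv, x$esv, x$sv, x$ef, x$mass))
  invisible(x)
}
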