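#' Planar polygon area (shoelace formula)
#'
#' Absolute area of a simple planar polygon given its vertices in order.
#' Orientation-independent. Underlies every cross-sectional area and
#' planimetered chamber slice in the package.
#'
#' @param vertices Two-column numeric matrix (or data frame) of x/y vertex
#'   coordinates in mm, in traversal order, at least 3 rows. The closing
#'   edge back to the first vertex is implicit.
#' @param check Verify that the polygon is simple (no self-intersection).
#'   `TRUE` by default; internal bulk callers on contours that are simple by
#'   construction disable it for speed.
#' @return Area in mm^2 (non-negative scalar).
#' @examples
#' polygon_area(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))  # 1
#' @export
polygon_area <- function(vertices, check = TRUE) {
  v <- as.matrix(vertices)
  if (!is.numeric(v) || ncol(v) != 2L) {
    stop("'vertices' must be a two-column numeric matrix")
  }
  n <- nrow(v)
  if (n < 3L) stop("a polygon needs at least 3 vertices, got ", n)
  if (!all(is.finite(v))) stop("polygon vertices contain non-finite values")
  if (isTRUE(check) && polygon_self_intersects(v)) {
    stop("polygon is self-intersecting")
  }
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

polygon_self_intersects <- function(v) {
  n <- nrow(v)
  for (i in seq_len(n - 2L)) {
    jmax <- if (i == 1L) n - 1L else n
    j <- i + 2L
    while (j <= jmax) {
      a <- v[i, ]; b <- v[i + 1L, ]
      c_ <- v[j, ]; d <- v[if (j == n) 1L else j + 1L, ]
      if (segments_cross(a, b, c_, d)) return(TRUE)
      j <- j + 1L
    }
  }
  FALSE
}

polygon_centroid <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(c(mean(x), mean(y)))
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

#' Construct a lumen area curve
#'
#' Cross-sectional area of a vessel lumen over the cardiac cycle at one
#' anatomic location, as planimetered from cine images.
#'
#' @param areas Numeric vector of areas in mm^2, one per cardiac phase;
#'   all positive, at least 3 phases.
#' @param location Anatomic label, e.g. `"ascending aorta"`.
#' @return An object of class `area_curve`.
#' @export
area_curve <- function(areas, location = "unknown") {
  areas <- as.numeric(areas)
  if (length(areas) < 3L) stop("an area curve needs >= 3 cardiac phases")
  if (!all(is.finite(areas)) || any(areas <= 0)) {
    stop("all areas must be positive and finite")
  }
  structure(list(location = as.character(location), areas = areas),
            class = "area_curve")
}

#' @method print area_curve
#' @export
print.area_curve <- function(x, ...) {
  cat(sprintf("<area_curve> '%s': %d phases, %.1f-%.1f mm^2\n",
              x$location, length(x$areas), min(x$areas), max(x$areas)))
  invisible(x)
}

#' Minimal and maximal cross-sectional area over the cardiac cycle
#'
#' Returns the global minimum and maximum of the lumen area curve, the two
#' distension extremes entering the distensibility formula. An optional
#' moving-average smoother is available for noisy planimetry; it is off by
#' default, so extremes are taken on the raw curve.
#'
#' @param curve An [area_curve] (or plain numeric vector of areas).
#' @param smooth_window Odd integer width of a centered moving average
#'   applied before taking extremes; 1 (default) disables smoothing.
#' @return Named numeric vector `c(a_min = , a_max = )` in mm^2.
#' @export
area_extremes <- function(curve, smooth_window = 1L) {
  a <- if (inherits(curve, "area_curve")) curve$areas else as.numeric(curve)
  if (length(a) < 3L) stop("an area curve needs >= 3 cardiac phases")
  w <- as.integer(smooth_window)
  if (w < 1L || w %% 2L == 0L) stop("'smooth_window' must be a positive odd integer")
  if (w > 1L) {
    half <- (w - 1L) %/% 2L
    # cyclic moving average: the cardiac cycle wraps
    n <- length(a)
    idx <- outer(seq_len(n), -half:half, function(i, k) ((i + k - 1L) %% n) + 1L)
    a <- rowMeans(matrix(a[idx], nrow = n))
  }
  c(a_min = min(a), a_max = max(a))
}

#' Cuff blood pressure
#'
#' @param systolic Systolic pressure in mmHg.
#' @param diastolic Diastolic pressure in mmHg; must be positive and below
#'   systolic.
#' @return Object of class `blood_pressure` with a `pulse_pressure` element.
#' @export
blood_pressure <- function(systolic, diastolic) {
  stopifnot_scalar(systolic, "systolic", lower = 0, strict_lower = TRUE)
  stopifnot_scalar(diastolic, "diastolic", lower = 0, strict_lower = TRUE)
  if (systolic <= diastolic) {
    stop("systolic pressure (", systolic, ") must exceed diastolic (",
         diastolic, ")")
  }
  structure(list(systolic = systolic, diastolic = diastolic,
                 pulse_pressure = systolic - diastolic),
            class = "blood_pressure")
}

#' Regional vessel distensibility
#'
#' Distensibility of a vessel segment from its cross-sectional area extremes
#' and the cuff pulse pressure:
#' \deqn{D = (A_{max} - A_{min}) / (A_{min} \cdot (P_{sys} - P_{dia}))}
#' reported in the conventional units of 10^-3 mmHg^-1. Distensibility is an
#' inverse stiffness measure: stiffer vessels distend less per unit pulse
#' pressure.
#'
#' @param a_min Minimal cross-sectional area over the cycle, mm^2 (> 0).
#' @param a_max Maximal cross-sectional area, mm^2 (>= `a_min`).
#' @param bp A [blood_pressure] object (cuff systolic/diastolic in mmHg).
#' @param location Optional anatomic label carried into the result.
#' @return Object of class `distensibility_result` with elements `location`,
#'   `a_min`, `a_max` and `distensibility` (10^-3 mmHg^-1). Use
#'   `$distensibility` or `as.numeric()` for the bare value.
#' @examples
#' d <- distensibility(250, 300, blood_pressure(120, 70))
#' d$distensibility  # 4.0
#' @export
distensibility <- function(a_min, a_max, bp, location = "unknown") {
  a_min <- unname(a_min); a_max <- unname(a_max)
  stopifnot_scalar(a_min, "a_min", lower = 0, strict_lower = TRUE)
  stopifnot_scalar(a_max, "a_max", lower = a_min)
  if (!inherits(bp, "blood_pressure")) {
    stop("'bp' must be a blood_pressure object")
  }
  d <- (a_max - a_min) / (a_min * bp$pulse_pressure) * 1e3
  structure(list(location = as.character(location), a_min = a_min,
                 a_max = a_max, distensibility = d),
            class = "distensibility_result")
}

#' @method print distensibility_result
#' @export
print.distensibility_result <- function(x, ...) {
  cat(sprintf(
    "<distensibility> %s: A_min %.1f, A_max %.1f mm^2 -> %.2f x 10^-3 mmHg^-1\n",
    x$location, x$a_min, x$a_max, x$distensibility))
  invisible(x)
}

#' @export
as.numeric.distensibility_result <- function(x, ...) x$distensibility

#' Body surface area
#'
#' BSA used to index chamber volumes and mass across body sizes.
#'
#' @param height_cm Height in cm (> 0).
#' @param weight_kg Weight in kg (> 0).
#' @param formula `"mosteller"` (default), sqrt(h*w/3600), or `"dubois"`.
#' @return BSA in m^2.
#' @examples
#' bsa(180, 80)  # 2.0
#' @export
bsa <- function(height_cm, weight_kg, formula = c("mosteller", "dubois")) {
  formula <- match.arg(formula)
  if (any(!is.finite(height_cm)) || any(height_cm <= 0) ||
      any(!is.finite(weight_kg)) || any(weight_kg <= 0)) {
    stop("height and weight must be positive")
  }
  switch(formula,
    mosteller = sqrt(height_cm * weight_kg / 3600),
    dubois = 0.007184 * height_cm^0.725 * weight_kg^0.425
  )
}
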