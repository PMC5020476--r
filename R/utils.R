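# internal helpers shared across modules

# Evaluate expr with a temporary RNG seed, restoring global RNG state after.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

stopifnot_scalar <- function(x, name, lower = -Inf, upper = Inf,
                             strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop("'", name, "' must be a single finite number")
  }
  ok_lo <- if (strict_lower) x > lower else x >= lower
  ok_hi <- if (strict_upper) x < upper else x <= upper
  if (!ok_lo || !ok_hi) {
    stop("'", name, "' = ", x, " outside allowed range ",
         if (strict_lower) "(" else "[", lower, ", ", upper,
         if (strict_upper) ")" else "]")
  }
  invisible(x)
}

# do segments p1-p2 and p3-p4 properly intersect (share an interior point)?
segments_cross <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

# even-odd ray casting; vertices on the boundary are not "strictly inside"
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    if (((vy[i] > py) != (vy[j] > py)) &&
        (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])) {
      inside <- !inside
    }
    j <- i
  }
  inside
}

`%||%` <- function(a, b) if (is.null(a)) b else a
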