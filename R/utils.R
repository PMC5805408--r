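# Internal helpers shared across modules.

#' Evaluate an expression under a fixed RNG seed, restoring the caller's RNG state
#' @noRd
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @noRd
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Field-by-field validation with errors naming the offending field.
#' @noRd
checkField <- function(ok, field, what) {
  if (!isTRUE(ok)) stopf("invalid %s: %s", field, what)
}

# Fold an angle (degrees) to the axial range [0, 90] relative to the x (AP) axis.
#' @noRd
axialAngle90 <- function(deg) {
  a <- deg %% 180
  ifelse(a > 90, 180 - a, a)
}

# Fold to [0, 180) (undirected axis).
#' @noRd
axialAngle180 <- function(deg) deg %% 180

# Second central moments of a pixel coordinate set (0-based centres), with the
# 1/12 px^2 variance of the square pixel footprint added so that discrete masks
# reproduce the moments of the continuous region they sample.
#' @noRd
pixelMoments <- function(xs, ys) {
  mx <- mean(xs); my <- mean(ys)
  dx <- xs - mx; dy <- ys - my
  list(mx = mx, my = my,
       mxx = mean(dx * dx) + 1 / 12,
       myy = mean(dy * dy) + 1 / 12,
       mxy = mean(dx * dy))
}

# Equivalent-ellipse axis lengths (4*sqrt(eigenvalue)) and major-axis
# orientation (degrees, axial in [0,180)) from second central moments.
#' @noRd
momentAxes <- function(m) {
  tr <- m$mxx + m$myy
  det <- m$mxx * m$myy - m$mxy^2
  disc <- sqrt(max(0, (tr / 2)^2 - det))
  l1 <- tr / 2 + disc
  l2 <- max(tr / 2 - disc, 1e-12)
  theta <- 0.5 * atan2(2 * m$mxy, m$mxx - m$myy) * 180 / pi
  list(major = 4 * sqrt(l1), minor = 4 * sqrt(l2),
       orientation = axialAngle180(theta))
}

# md5 of the analysis parameters, used for provenance blocks (stable across
# sessions; output location does not change the analysis identity).
#' @noRd
configHash <- function(config) {
  config$out_dir <- NULL
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  yaml::write_yaml(config, tf)
  unname(tools::md5sum(tf))
}
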