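#' Parametric thermoscape configuration
#'
#' Describes the analytic temperature field over the arena: a uniform plate
#' baseline modified by peak-normalized Gaussian bumps at each Peltier
#' source, so that the field equals `source_C` exactly at a source centre
#' and relaxes to `plate_C` away from all sources.
#'
#' The default layout matches the assay arena: a 170 x 170 mm plate at
#' 21 degC with four sources at the quarter positions, two cold (14 degC) on
#' one diagonal and two warm (28 degC) on the other, Gaussian spread 0.1 in
#' normalized arena units (arena side = 1).
#'
#' @param arena_mm arena side lengths in mm, length-2 numeric.
#' @param plate_C plate baseline temperature, degC.
#' @param sources data.frame with columns `x`, `y` (mm) and `temp_C`.
#' @param spread Gaussian spatial scale in normalized arena units.
#' @return An object of class `thermoscape_config`.
#' @export
thermoscape_config <- function(arena_mm = c(170, 170),
                               plate_C = 21,
                               sources = NULL,
                               spread = 0.1) {
  stopifnot(length(arena_mm) == 2, all(arena_mm > 0), spread > 0)
  if (is.null(sources)) {
    w <- arena_mm[1]; h <- arena_mm[2]
    sources <- data.frame(
      x = c(0.25, 0.75, 0.75, 0.25) * w,
      y = c(0.25, 0.75, 0.25, 0.75) * h,
      temp_C = c(14, 14, 28, 28)
    )
  }
  stopifnot(is.data.frame(sources),
            all(c("x", "y", "temp_C") %in% names(sources)))
  structure(list(arena_mm = as.numeric(arena_mm), plate_C = plate_C,
                 sources = sources, spread = spread,
                 spread_mm = spread * arena_mm[1]),
            class = "thermoscape_config")
}

#' Evaluate the thermoscape temperature field
#'
#' `T(x, y) = plate_C + sum_src (source_C - plate_C) *
#'   exp(-||(x,y) - mu_src||^2 / (2 * spread_mm^2))`
#' with `spread_mm` the Gaussian scale converted to mm.
#'
#' @param x,y coordinates in mm (vectorized).
#' @param config a [thermoscape_config()].
#' @return Temperatures in degC.
#' @export
thermoscape_at <- function(x, y, config) {
  stopifnot(inherits(config, "thermoscape_config"))
  if (any(x < 0 | x > config$arena_mm[1] | y < 0 | y > config$arena_mm[2]))
    stop("coordinates outside the arena")
  T <- rep(config$plate_C, length(x))
  two_s2 <- 2 * config$spread_mm^2
  for (j in seq_len(nrow(config$sources))) {
    d2 <- (x - config$sources$x[j])^2 + (y - config$sources$y[j])^2
    T <- T + (config$sources$temp_C[j] - config$plate_C) * exp(-d2 / two_s2)
  }
  T
}

#' Rasterize the thermoscape onto a pixel grid
#'
#' Pixel centres span the full arena (first pixel at 0, last at the arena
#' edge); rows index y, columns index x.
#'
#' @param config a [thermoscape_config()].
#' @param nrow,ncol grid size in pixels.
#' @return A numeric matrix of temperatures, degC.
#' @export
thermoscape_grid <- function(config, nrow = 120, ncol = 160) {
  xs <- seq(0, config$arena_mm[1], length.out = ncol)
  ys <- seq(0, config$arena_mm[2], length.out = nrow)
  outer(ys, xs, function(y, x) thermoscape_at(x, y, config))
}
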