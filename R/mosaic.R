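# Vegetation-patch mosaic: a square arena with circular shrub patches,
# point-in-patch habitat labelling, and closed-form line-of-sight.
#
# Patches are discs.  Real shrubs are irregular, but disc geometry admits
# an exact segment-disc intersection test and an exact point-in-patch
# test, which the visibility index and habitat labelling rely on.

PLANT_SPECIES <- c("greasewood", "sage", "shadscale", "rabbit_brush",
                   "horse_brush", "ryegrass")

#' Construct a habitat mosaic
#'
#' @param arena_side side length of the square arena, metres; the arena
#'   spans `[0, arena_side]` in x and y.
#' @param patches data frame with columns `x`, `y` (centre, metres), `r`
#'   (radius, metres, > 0) and `species` (plant-species label).  Every
#'   disc must lie fully inside the arena.
#' @return object of class `habitat_mosaic`.
#' @export
habitat_mosaic <- function(arena_side, patches = empty_patches()) {
  patches <- as.data.frame(patches)
  stopifnot(arena_side > 0, all(c("x", "y", "r", "species") %in%
                                  names(patches)))
  if (nrow(patches) > 0) {
    if (any(patches$r <= 0)) stop("patch radius must be positive")
    inside <- patches$x - patches$r >= 0 & patches$x + patches$r <= arena_side &
      patches$y - patches$r >= 0 & patches$y + patches$r <= arena_side
    if (!all(inside))
      stop("patch(es) extend outside the arena: ",
           paste(which(!inside), collapse = ", "))
  }
  structure(list(arena_side = arena_side, patches = patches),
            class = "habitat_mosaic")
}

empty_patches <- function() {
  data.frame(x = numeric(0), y = numeric(0), r = numeric(0),
             species = character(0), stringsAsFactors = FALSE)
}

#' @export
print.habitat_mosaic <- function(x, ...) {
  cover <- if (nrow(x$patches)) sum(pi * x$patches$r^2) / x$arena_side^2 else 0
  cat(sprintf(
    "Habitat mosaic: %.0f x %.0f m arena, %d patches (~%.1f%% cover, overlap ignored)\n",
    x$arena_side, x$arena_side, nrow(x$patches), 100 * cover))
  invisible(x)
}

#' Which patch contains a point?
#'
#' @param x,y point coordinates, metres.
#' @param mosaic a `habitat_mosaic`.
#' @return index of the containing patch with the nearest centre, or
#'   `NA_integer_` if the point is in the open.
#' @export
patch_at <- function(x, y, mosaic) {
  p <- mosaic$patches
  if (nrow(p) == 0L) return(NA_integer_)
  d2 <- (p$x - x)^2 + (p$y - y)^2
  inside <- d2 <= p$r^2
  if (!any(inside)) return(NA_integer_)
  which(inside)[which.min(d2[inside])]
}

#' Geometric line of sight between two points
#'
#' `TRUE` when the segment from `p0` to `p1` crosses no vegetation disc.
#' Discs containing either endpoint are transparent: an animal at the
#' edge of a bush sees out of its own bush, matching a sighting taken
#' just above the substrate over the location marker itself.  The
#' segment-disc test is closed form: the minimum distance from each disc
#' centre to the segment is compared with the radius.
#'
#' @param p0,p1 numeric length-2 points `c(x, y)`, metres.
#' @param mosaic a `habitat_mosaic`.
#' @return logical.
#' @export
line_of_sight <- function(p0, p1, mosaic) {
  p <- mosaic$patches
  if (nrow(p) == 0L) return(TRUE)
  # transparent discs: those containing an endpoint
  d0 <- (p$x - p0[1])^2 + (p$y - p0[2])^2
  d1 <- (p$x - p1[1])^2 + (p$y - p1[2])^2
  opaque <- d0 > p$r^2 & d1 > p$r^2
  if (!any(opaque)) return(TRUE)
  dx <- p1[1] - p0[1]
  dy <- p1[2] - p0[2]
  L2 <- dx^2 + dy^2
  if (L2 == 0) return(TRUE) # no movement: nothing to obstruct
  tt <- pmin(pmax(((p$x - p0[1]) * dx + (p$y - p0[2]) * dy) / L2, 0), 1)
  qx <- p0[1] + tt * dx
  qy <- p0[2] + tt * dy
  dist2 <- (p$x - qx)^2 + (p$y - qy)^2
  !any(opaque & dist2 < p$r^2)
}

#' Generate a random habitat mosaic
#'
#' Patch centres are uniform over the admissible region (discs fully
#' inside the arena), radii lognormal, and plant species drawn from the
#' configured weights.  Deterministic given the seed.
#'
#' @param config a `simulation_config` (fields `arena_side`, `n_patches`,
#'   `patch_r_meanlog`, `patch_r_sdlog`, `plant_weights` are used).
#' @param seed integer RNG seed.
#' @return a `habitat_mosaic`.
#' @export
generate_mosaic <- function(config, seed) {
  n <- config$n_patches
  stopifnot(n >= 0)
  if (n == 0L) return(habitat_mosaic(config$arena_side))
  with_seed(seed, {
    r <- stats::rlnorm(n, config$patch_r_meanlog, config$patch_r_sdlog)
    # degenerate-mosaic guard: requested patch area vs arena area
    if (sum(pi * r^2) > 0.8 * config$arena_side^2)
      stop("requested patch area exceeds 80% of the arena; ",
           "reduce n_patches or patch radii")
    if (any(2 * r >= config$arena_side))
      stop("patch diameter exceeds arena side")
    x <- stats::runif(n, r, config$arena_side - r)
    y <- stats::runif(n, r, config$arena_side - r)
    w <- config$plant_weights
    sp <- sample(names(w), n, replace = TRUE, prob = as.numeric(w))
    habitat_mosaic(config$arena_side,
                   data.frame(x = x, y = y, r = r, species = sp,
                              stringsAsFactors = FALSE))
  })
}
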