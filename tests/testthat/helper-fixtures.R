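# Builders for in-code fixtures: observations from bare coordinates,
# small mosaics, and random walks for property sweeps.

# Observation from a coordinate matrix/data.frame (columns x, y); open
# habitat, no weather, visibility flags all clear unless supplied.
make_obs <- function(coords, id = "obs_1", lizard = "liz_1",
                     species = "visual", t = NULL, habitat = NULL,
                     plant = NULL, visible = NULL) {
  coords <- as.data.frame(coords)
  names(coords)[1:2] <- c("x", "y")
  n <- nrow(coords)
  if (is.null(t)) t <- 0:(n - 1L)
  if (is.null(habitat)) habitat <- rep("open", n)
  if (is.null(plant)) plant <- ifelse(habitat == "vegetation", "sage",
                                      NA_character_)
  if (is.null(visible)) visible <- c(NA, rep(TRUE, n - 1L))
  observation(id, lizard, species,
              fixes = data.frame(t = t, x = coords$x, y = coords$y,
                                 habitat = habitat, plant_species = plant,
                                 visible_from_previous = visible,
                                 stringsAsFactors = FALSE))
}

# Random-walk observation with n fixes and given movement probability.
random_obs <- function(n = 31L, p_move = 0.7, id = "obs_1",
                       lizard = "liz_1", species = "visual") {
  mv <- runif(n - 1) < p_move
  x <- cumsum(c(0, ifelse(mv, rnorm(n - 1), 0)))
  y <- cumsum(c(0, ifelse(mv, rnorm(n - 1), 0)))
  make_obs(cbind(x, y), id = id, lizard = lizard, species = species)
}

# A tiny mosaic with known geometry.
small_mosaic <- function(arena = 20) {
  habitat_mosaic(arena, data.frame(
    x = c(10, 4), y = c(10, 15), r = c(1, 2),
    species = c("sage", "greasewood"), stringsAsFactors = FALSE))
}

# Small two-species synthetic dataset for pipeline tests.
small_dataset <- function(n = 8L, seed = 5L, arena_side = 80) {
  cfg <- simulation_config(n_visual = n, n_chemosensory = n,
                           arena_side = arena_side, master_seed = seed)
  generate_dataset(cfg)
}

# Brute-force line-of-sight by 1-cm sampling along the segment,
# ignoring discs that contain either endpoint.
brute_los <- function(p0, p1, mosaic, spacing = 0.01) {
  p <- mosaic$patches
  if (nrow(p) == 0L) return(TRUE)
  d0 <- (p$x - p0[1])^2 + (p$y - p0[2])^2
  d1 <- (p$x - p1[1])^2 + (p$y - p1[2])^2
  opaque <- which(d0 > p$r^2 & d1 > p$r^2)
  if (length(opaque) == 0L) return(TRUE)
  L <- sqrt(sum((p1 - p0)^2))
  if (L == 0) return(TRUE)
  tt <- seq(0, 1, by = spacing / L)
  qx <- p0[1] + tt * (p1[1] - p0[1])
  qy <- p0[2] + tt * (p1[2] - p0[2])
  for (j in opaque) {
    if (any((p$x[j] - qx)^2 + (p$y[j] - qy)^2 < p$r[j]^2)) return(FALSE)
  }
  TRUE
}
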