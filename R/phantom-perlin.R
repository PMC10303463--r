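#' Perlin (gradient-lattice) fractal noise
#'
#' Classic 3D Perlin noise summed over octaves. Gradients sit on an integer
#' lattice and are drawn from the 12 cube-edge directions through a seeded
#' permutation table; values are interpolated with the quintic fade, so the
#' field is smooth and has zero mean by construction. Octave `o` is sampled
#' at spatial frequency `base_frequency_mm * lacunarity^o` with amplitude
#' `persistence^o`, which yields the multi-scale "fractal" texture used for
#' parenchyma synthesis.
#'
#' @param x,y,z numeric vectors of equal length; sample coordinates in mm.
#' @param cfg a [perlin_config()].
#' @return numeric vector of noise values (approximately in \[-1, 1\]).
#' @export
perlin_fractal <- function(x, y, z, cfg) {
  stopifnot(length(x) == length(y), length(y) == length(z))
  tables <- perlin_tables(cfg$seed)
  # per-octave lattice offsets decorrelate the octaves
  rs <- with_seed(cfg$seed,
                  matrix(stats::runif(3L * cfg$octaves, 0, 256), ncol = 3L))
  cpp_perlin_fractal(x, y, z, tables$perm, tables$grad, rs,
                     cfg$base_frequency_mm, cfg$persistence, cfg$lacunarity)
}

# pure-R reference implementation of the same field (slow; used as the
# independent oracle in tests)
perlin_fractal_r <- function(x, y, z, cfg) {
  tables <- perlin_tables(cfg$seed)
  rs <- with_seed(cfg$seed,
                  matrix(stats::runif(3L * cfg$octaves, 0, 256), ncol = 3L))
  out <- numeric(length(x))
  freq <- cfg$base_frequency_mm
  amp <- 1
  for (o in seq_len(cfg$octaves)) {
    out <- out + amp * perlin3(x * freq + rs[o, 1L],
                               y * freq + rs[o, 2L],
                               z * freq + rs[o, 3L], tables)
    freq <- freq * cfg$lacunarity
    amp <- amp * cfg$persistence
  }
  out
}

#' Perlin noise configuration
#'
#' @param octaves number of octaves summed (>= 1).
#' @param base_frequency_mm frequency of the first octave in cycles/mm; the
#'   default 1/40 places the coarsest structure at breast scale (~40 mm).
#' @param persistence amplitude ratio between octaves, in (0, 1].
#' @param lacunarity frequency ratio between octaves, > 1.
#' @param density_threshold_quantile quantile at which interior noise is
#'   thresholded into dense tissue; dense fraction = 1 - quantile.
#' @param seed integer seed for the gradient tables and octave offsets.
#' @export
perlin_config <- function(octaves = 6L, base_frequency_mm = 1 / 40,
                          persistence = 0.5, lacunarity = 2.0,
                          density_threshold_quantile = 0.8, seed = 1L) {
  stopifnot(octaves >= 1, base_frequency_mm > 0,
            persistence > 0, persistence <= 1, lacunarity > 1,
            density_threshold_quantile > 0, density_threshold_quantile < 1)
  structure(list(octaves = as.integer(octaves),
                 base_frequency_mm = base_frequency_mm,
                 persistence = persistence, lacunarity = lacunarity,
                 density_threshold_quantile = density_threshold_quantile,
                 seed = as.integer(seed)),
            class = "perlin_config")
}

# seeded permutation table and the 12 cube-edge gradient directions
perlin_tables <- function(seed) {
  perm <- with_seed(seed, sample.int(256L) - 1L)
  perm2 <- c(perm, perm)
  g <- rbind(c(1, 1, 0), c(-1, 1, 0), c(1, -1, 0), c(-1, -1, 0),
             c(1, 0, 1), c(-1, 0, 1), c(1, 0, -1), c(-1, 0, -1),
             c(0, 1, 1), c(0, -1, 1), c(0, 1, -1), c(0, -1, -1))
  list(perm = perm2, grad = g)
}

fade5 <- function(t) t * t * t * (t * (t * 6 - 15) + 10)

# single-octave classic Perlin, fully vectorized
perlin3 <- function(x, y, z, tables) {
  perm <- tables$perm
  grad <- tables$grad
  xi <- floor(x); yi <- floor(y); zi <- floor(z)
  xf <- x - xi; yf <- y - yi; zf <- z - zi
  xi <- as.integer(xi %% 256); yi <- as.integer(yi %% 256)
  zi <- as.integer(zi %% 256)
  u <- fade5(xf); v <- fade5(yf); w <- fade5(zf)

  corner <- function(dx, dy, dz) {
    h <- perm[perm[perm[xi + dx + 1L] + yi + dy + 1L] + zi + dz + 1L] %% 12L + 1L
    grad[h, 1L] * (xf - dx) + grad[h, 2L] * (yf - dy) + grad[h, 3L] * (zf - dz)
  }
  lerp <- function(a, b, t) a + t * (b - a)
  x00 <- lerp(corner(0L, 0L, 0L), corner(1L, 0L, 0L), u)
  x10 <- lerp(corner(0L, 1L, 0L), corner(1L, 1L, 0L), u)
  x01 <- lerp(corner(0L, 0L, 1L), corner(1L, 0L, 1L), u)
  x11 <- lerp(corner(0L, 1L, 1L), corner(1L, 1L, 1L), u)
  lerp(lerp(x00, x10, v), lerp(x01, x11, v), w)
}
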