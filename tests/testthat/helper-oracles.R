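# fixtures and brute-force oracles used across the test files

flat_chm <- function(h, nr = 6, nc = 6, res = 1) {
  chm(matrix(h, nr, nc), resolution = res)
}

random_chm <- function(seed, nr = 8, nc = 8, res = 1, hmax = 20) {
  set.seed(seed)
  chm(matrix(runif(nr * nc, 0, hmax), nr, nc), resolution = res)
}

# linear-interpolation quantile, written from the definition: order statistics
# with the index h = (n - 1) * p + 1 and linear interpolation between them
oracle_quantile <- function(v, p) {
  v <- sort(v)
  n <- length(v)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  v[lo] + (h - lo) * (v[hi] - v[lo])
}

# triangle area from its three 3D vertices via Heron's formula
heron_area <- function(a, b, c) {
  la <- sqrt(sum((b - c)^2))
  lb <- sqrt(sum((a - c)^2))
  lc <- sqrt(sum((a - b)^2))
  s <- (la + lb + lc) / 2
  sqrt(max(s * (s - la) * (s - lb) * (s - lc), 0))
}

# brute-force triangulated surface area: explicit per-cell loop over both
# triangles, lower-left -> upper-right diagonal, pixel-centre grid
oracle_surface_area <- function(x) {
  z <- x$heights
  r <- x$resolution
  nr <- nrow(z)
  nc <- ncol(z)
  total <- 0
  for (i in 1:(nr - 1)) {
    for (j in 1:(nc - 1)) {
      # map row i to a y coordinate so row nr is y = 0 (south)
      yU <- (nr - i) * r
      yL <- (nr - i - 1) * r
      xL <- (j - 1) * r
      xR <- j * r
      ul <- c(xL, yU, z[i, j])
      ur <- c(xR, yU, z[i, j + 1])
      ll <- c(xL, yL, z[i + 1, j])
      lr <- c(xR, yL, z[i + 1, j + 1])
      total <- total + heron_area(ll, lr, ur) + heron_area(ll, ur, ul)
    }
  }
  total
}

default_truth <- trajectory_truth()

make_noiseless <- function(n = 500, seed = 1) {
  simulate_plot_table(
    default_truth,
    generator_config(n_plots = n, seed = seed,
                     noise_sd = list(h_max = 0, cover = 0, h_cv = 0,
                                     rumple_norm = 0, basal_area = 0,
                                     log10_density = 0))
  )
}

small_table <- function(seed = 1, n = 60, noise0 = FALSE) {
  ns <- if (noise0) {
    list(h_max = 0, cover = 0, h_cv = 0, rumple_norm = 0, basal_area = 0,
         log10_density = 0)
  } else {
    list()
  }
  simulate_plot_table(default_truth,
                      generator_config(n_plots = n, noise_sd = ns, seed = seed))
}
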