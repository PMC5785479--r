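# Shared fixtures: all inputs are built in code at test time.

# write a small well-table CSV and return its path
write_wells_csv <- function(lines, file = tempfile(fileext = ".csv")) {
  writeLines(c("sample_id,primer_id,ct,tm_peaks,replicate", lines), file)
  file
}

# image with a filled disk of given radius (intensity `fg` on 0 background)
disk_image <- function(nr, nc, center, radius, fg = 255) {
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  img <- matrix(0, nr, nc)
  img[(cols - center[1])^2 + (rows - center[2])^2 <= radius^2] <- fg
  img
}

add_disk <- function(img, center, radius, fg = 255) {
  nr <- nrow(img); nc <- ncol(img)
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  img[(cols - center[1])^2 + (rows - center[2])^2 <= radius^2] <- fg
  img
}

# random star-shaped (hence simple) polygon around a center
random_simple_polygon <- function(n_vertices = 8, radius = c(3, 10)) {
  theta <- sort(runif(n_vertices, 0, 2 * pi))
  r <- runif(n_vertices, radius[1], radius[2])
  cbind(x = 12 + r * cos(theta), y = 12 + r * sin(theta))
}

# Monte-Carlo point-in-polygon area (ray casting), the independent oracle
# for the shoelace formula
mc_polygon_area <- function(v, n = 4e5) {
  xr <- range(v[, 1]); yr <- range(v[, 2])
  px <- runif(n, xr[1], xr[2])
  py <- runif(n, yr[1], yr[2])
  nv <- nrow(v)
  inside <- rep(FALSE, n)
  j <- nv
  for (i in seq_len(nv)) {
    xi <- v[i, 1]; yi <- v[i, 2]; xj <- v[j, 1]; yj <- v[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  mean(inside) * diff(xr) * diff(yr)
}

# noise-free simulation configuration (perfect chemistry, no dropout noise)
noise_free_config <- function(seed, n_embryos = 60, ...) {
  sim_config(seed = seed, n_embryos = n_embryos,
             load_sigma_log = 0, ct_noise_sd = 0, host_ct_sd = 0,
             conc_sdlog = 0, qc_fail_frac = 0, dimer_rate = 0,
             engraft_rate = 1,
             allele_offsets = list(WT_HOM = c(mean = 9.85, sd = 0),
                                   HET = c(mean = 0, sd = 0),
                                   MUT_HOM = c(mean = -5.65, sd = 0)),
             ...)
}
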