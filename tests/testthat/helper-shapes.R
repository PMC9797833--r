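# Digital test shapes and small phantom configurations shared across tests.

# filled digital disk: pixel centres within r_px of the centre
digital_disk <- function(r_px, pad = 10L, label = 1L) {
  n <- 2L * r_px + 2L * pad + 1L
  ctr <- r_px + pad + 1L
  xy <- as.matrix(expand.grid(seq_len(n), seq_len(n)))
  m <- matrix(0L, n, n)
  m[xy[(xy[, 1] - ctr)^2 + (xy[, 2] - ctr)^2 <= r_px^2, , drop = FALSE]] <- label
  attr(m, "center") <- c(ctr, ctr)
  m
}

digital_ellipse <- function(a_px, b_px, pad = 10L) {
  nr <- 2L * a_px + 2L * pad + 1L
  nc <- 2L * b_px + 2L * pad + 1L
  cr <- a_px + pad + 1L; cc <- b_px + pad + 1L
  xy <- as.matrix(expand.grid(seq_len(nr), seq_len(nc)))
  m <- matrix(0L, nr, nc)
  sel <- ((xy[, 1] - cr) / a_px)^2 + ((xy[, 2] - cc) / b_px)^2 <= 1
  m[xy[sel, , drop = FALSE]] <- 1L
  attr(m, "center") <- c(cr, cc)
  m
}

# Ramanujan's second approximation to an ellipse perimeter (semi-axes in mm)
ramanujan_perimeter <- function(a, b) {
  h <- ((a - b) / (a + b))^2
  pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
}

# exhaustive 4-neighbour boundary scan (independent of the package's tracer)
scan_boundary4 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(0L, 0, 2)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!mask[i, j]) next
    nb <- c(i > 1 && mask[i - 1, j], i < nr && mask[i + 1, j],
            j > 1 && mask[i, j - 1], j < nc && mask[i, j + 1])
    edge <- i == 1 || i == nr || j == 1 || j == nc
    if (edge || !all(nb)) out <- rbind(out, c(i, j))
  }
  out
}

# seeded 2D "slice phantom": ellipse with short-wavelength radial texture and
# papillary-analogue notches, plus the smooth truth perimeter (numeric arc
# length of the unperturbed ellipse). No atrium: contours stay closed.
textured_ellipse_slice <- function(seed, a_mm = 35, b_mm = 22, spacing = 0.5,
                                   texture_amp = 0.8, n_modes = 6L,
                                   freq_range = c(8L, 16L),
                                   notch_depth = 5, n_notch = 2L) {
  set.seed(seed)
  amp_coef <- stats::rnorm(n_modes)
  amp_coef <- amp_coef / sqrt(sum(amp_coef^2) / 2)
  freqs <- sample(freq_range[1]:freq_range[2], n_modes, replace = TRUE)
  phs <- stats::runif(n_modes, 0, 2 * pi)
  notch_az <- stats::runif(n_notch, 0, 2 * pi)

  nr <- ceiling(2 * (a_mm + 5) / spacing); nc <- ceiling(2 * (b_mm + 5) / spacing)
  cr <- nr / 2; cc <- nc / 2
  xy <- as.matrix(expand.grid(seq_len(nr), seq_len(nc)))
  dx <- (xy[, 1] - cr) * spacing; dy <- (xy[, 2] - cc) * spacing
  th <- atan2(dy / b_mm, dx / a_mm)
  u <- sqrt((dx / a_mm)^2 + (dy / b_mm)^2)
  r_loc <- sqrt((a_mm * cos(th))^2 + (b_mm * sin(th))^2)
  f <- 0
  for (k in seq_len(n_modes)) f <- f + amp_coef[k] * cos(freqs[k] * th + phs[k])
  inside <- u <= 1 + texture_amp * f / r_loc
  # notches: spherical-cap bites on the boundary
  for (az in notch_az) {
    bx <- a_mm * cos(az); by <- b_mm * sin(az)
    rho <- notch_depth * 1.6
    cxn <- bx * (1 + (rho - notch_depth) / sqrt(bx^2 + by^2))
    cyn <- by * (1 + (rho - notch_depth) / sqrt(bx^2 + by^2))
    inside <- inside & ((dx - cxn)^2 + (dy - cyn)^2 >= rho^2)
  }
  m <- matrix(0L, nr, nc)
  m[xy[inside, , drop = FALSE]] <- 1L
  tt <- seq(0, 2 * pi, length.out = 20001)
  truth <- sum(sqrt(diff(a_mm * cos(tt))^2 + diff(b_mm * sin(tt))^2))
  list(slice = lax_slice(m, spacing), truth = truth)
}

# small, fast phantom spec for unit tests
small_phantom_spec <- function(seed = 1L, ...) {
  phantom_spec(grid_shape = c(48L, 48L, 48L), spacing = 2.5, seed = seed, ...)
}
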