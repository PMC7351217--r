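# Independent brute-force oracles the tests compare the package against.
# These deliberately share no code with the implementation paths.

# Scalar even-odd ray-casting point-in-polygon, boundary-inclusive.
oracle_point_in_polygon <- function(px, py, v) {
  n <- nrow(v)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- v[i, 1]; yi <- v[i, 2]; xj <- v[j, 1]; yj <- v[j, 2]
    # boundary: |cross| ~ 0 and within segment bbox
    if (abs((xj - xi) * (py - yi) - (yj - yi) * (px - xi)) < 1e-9 &&
        px >= min(xi, xj) - 1e-9 && px <= max(xi, xj) + 1e-9 &&
        py >= min(yi, yj) - 1e-9 && py <= max(yi, yj) + 1e-9)
      return(TRUE)
    if ((yi > py) != (yj > py) &&
        px < (xj - xi) * (py - yi) / (yj - yi) + xi)
      inside <- !inside
    j <- i
  }
  inside
}

oracle_rasterize <- function(v, shape) {
  mask <- matrix(FALSE, shape[1], shape[2])
  for (i in seq_len(shape[1])) {
    for (j in seq_len(shape[2])) {
      mask[i, j] <- oracle_point_in_polygon(j - 1, i - 1, v)
    }
  }
  mask
}

# Random star-shaped (hence simple) polygon on a grid, 0-based coords.
random_simple_polygon <- function(shape, n_vertices = sample(3:9, 1)) {
  cx <- runif(1, shape[2] * 0.3, shape[2] * 0.7)
  cy <- runif(1, shape[1] * 0.3, shape[1] * 0.7)
  ang <- sort(runif(n_vertices, 0, 2 * pi))
  rad <- runif(n_vertices, 0.15, 0.45) * min(shape)
  x <- pmin(pmax(cx + rad * cos(ang), 0), shape[2] - 1 - 1e-6)
  y <- pmin(pmax(cy + rad * sin(ang), 0), shape[1] - 1 - 1e-6)
  cbind(x, y)
}

# Exhaustive full-containment kernel enumeration.
oracle_enumerate <- function(mask, k, stride = 1L) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- NULL
  if (nr >= k && nc >= k) {
    for (i in seq.int(1L, nr - k + 1L, by = stride)) {
      for (j in seq.int(1L, nc - k + 1L, by = stride)) {
        if (all(mask[i:(i + k - 1L), j:(j + k - 1L)]))
          out <- rbind(out, c(i, j))
      }
    }
  }
  if (is.null(out))
    out <- matrix(integer(0), 0, 2)
  unname(out)
}

# Explicit-summation two-way ANOVA (triple loop, no matrix algebra).
oracle_anova <- function(y) {
  n <- nrow(y); k <- ncol(y)
  gm <- sum(y) / (n * k)
  rmeans <- numeric(n); cmeans <- numeric(k)
  for (i in seq_len(n)) rmeans[i] <- sum(y[i, ]) / k
  for (j in seq_len(k)) cmeans[j] <- sum(y[, j]) / n
  ssr <- 0; ssc <- 0; sse <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(k)) {
      ssr <- ssr + (rmeans[i] - gm)^2
      ssc <- ssc + (cmeans[j] - gm)^2
      sse <- sse + (y[i, j] - rmeans[i] - cmeans[j] + gm)^2
    }
  }
  list(ms_rows = ssr / (n - 1), ms_cols = ssc / (k - 1),
       ms_error = sse / ((n - 1) * (k - 1)))
}

oracle_icc_consistency <- function(y) {
  ms <- oracle_anova(y)
  k <- ncol(y)
  (ms$ms_rows - ms$ms_error) / (ms$ms_rows + (k - 1) * ms$ms_error)
}

oracle_icc_absolute <- function(y) {
  ms <- oracle_anova(y)
  n <- nrow(y); k <- ncol(y)
  (ms$ms_rows - ms$ms_error) /
    (ms$ms_rows + (k - 1) * ms$ms_error +
       (k / n) * (ms$ms_cols - ms$ms_error))
}

# Frequency-bin width of the padded spectrum, mm^-1.
bin_width <- function(pad = 128, spacing = 6.6 / 96) 1 / (pad * spacing)
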