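# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths: plain-R loops and closed forms only.

# even-odd point-in-polygon, straight from the crossing-number definition
pip_oracle <- function(px, py, poly) {
  n <- nrow(poly)
  vapply(seq_along(px), function(i) {
    x <- px[i]; y <- py[i]
    inside <- FALSE
    j <- n
    for (k in seq_len(n)) {
      xa <- poly[k, 1]; ya <- poly[k, 2]
      xb <- poly[j, 1]; yb <- poly[j, 2]
      if ((ya > y) != (yb > y) &&
          x < xa + (y - ya) * (xb - xa) / (yb - ya)) inside <- !inside
      j <- k
    }
    inside
  }, logical(1))
}

# 8-connected component count by breadth-first flood fill
flood_count_oracle <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  count <- 0
  for (r0 in seq_len(nr)) for (c0 in seq_len(nc)) {
    if (mask[r0, c0] == 0 || seen[r0, c0]) next
    count <- count + 1
    queue <- list(c(r0, c0)); seen[r0, c0] <- TRUE
    while (length(queue) > 0) {
      p <- queue[[1]]; queue <- queue[-1]
      for (dr in -1:1) for (dc in -1:1) {
        r <- p[1] + dr; c <- p[2] + dc
        if (r >= 1 && r <= nr && c >= 1 && c <= nc &&
            mask[r, c] != 0 && !seen[r, c]) {
          seen[r, c] <- TRUE
          queue[[length(queue) + 1]] <- c(r, c)
        }
      }
    }
  }
  count
}

# per-pixel summation oracles for the losses
ce_oracle <- function(rho, y, eps = 1e-7) {
  p <- pmin(pmax(rho, eps), 1 - eps)
  total <- 0
  for (i in seq_along(p))
    total <- total - (y[i] * log(p[i]) + (1 - y[i]) * log(1 - p[i]))
  total
}

wce_oracle <- function(rho, y, w0, w1, eps = 1e-7) {
  p <- pmin(pmax(rho, eps), 1 - eps)
  total <- 0
  for (i in seq_along(p)) {
    total <- total - if (y[i] == 1) (1 - w1) * log(p[i])
                     else (1 - w0) * log(1 - p[i])
  }
  total
}

dice_oracle <- function(rho, y, epsilon = 1) {
  tp <- 0; fp <- 0; fn <- 0
  for (i in seq_along(rho)) {
    tp <- tp + rho[i] * y[i]
    fp <- fp + rho[i] * (1 - y[i])
    fn <- fn + (1 - rho[i]) * y[i]
  }
  1 - (2 * tp + epsilon) / (fp + 2 * tp + fn + epsilon)
}

# O(n^2) pairwise Mann-Whitney AUC
auc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# synthetic band masks used by partition tests
straight_band_mask <- function(width, height, thickness, x0 = 100) {
  m <- matrix(0L, height, width)
  rows <- (height - thickness) %/% 2 + seq_len(thickness)
  m[rows, (x0 + 1):(width - x0)] <- 1L
  m
}

sinusoidal_band_mask <- function(width, height, thickness, amplitude,
                                 wavelength, phase = 0, margin = 20) {
  xs <- seq_len(width) - 1
  centre <- height / 2 + amplitude * sin(2 * pi * xs / wavelength + phase)
  rowg <- matrix(seq_len(height) - 1, height, width)
  cmat <- matrix(centre, height, width, byrow = TRUE)
  in_x <- matrix(xs >= margin & xs <= width - 1 - margin, height, width, byrow = TRUE)
  (abs(rowg - cmat) <= thickness / 2 & in_x) * 1L
}

# reference palette matching the generator's rendering colours
test_palettes <- function() {
  list(
    se = list(h = c(0.65, 0.95), s = c(0.2, 1), v = c(0, 1)),
    hsil = list(h = c(0.65, 0.80), s = c(0.3, 1), v = c(0, 0.62)),
    dab = list(h = c(0.0, 0.15), s = c(0.3, 1), v = c(0, 1))
  )
}

quad_polygon <- function(q) q$corners[c("C'", "C", "D", "D'"), , drop = FALSE]

# fraction of region mask pixels claimed by the union of quads, and the
# maximum number of quads claiming one pixel (point-in-polygon itself is
# validated against pip_oracle in the annotation tests, so the fast path is
# safe to reuse here)
quad_coverage <- function(patches, region) {
  idx <- which(region$mask_crop == 1, arr.ind = TRUE)
  px <- idx[, 2] - 1 + region$offset[["x"]]
  py <- idx[, 1] - 1 + region$offset[["y"]]
  claims <- rep(0L, length(px))
  for (q in patches)
    claims <- claims + silkit:::cpp_points_in_polygon(px, py, quad_polygon(q))
  list(coverage = mean(claims > 0), max_claims = max(claims))
}
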