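# Internal helpers shared across modules.
#
# Coordinate convention (package-wide): 0-based, x = column, y = row;
# the centre of matrix element [r, c] (1-based R indices) is (x, y) =
# (c - 1, r - 1). Windows are half-open [offset, offset + size).

sil_stop <- function(msg, class = "silkit_error", call. = FALSE) {
  stop(structure(
    class = c(class, "silkit_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  ))
}

sil_config_error <- function(msg) sil_stop(msg, "silkit_config_error")
sil_data_error <- function(msg) sil_stop(msg, "silkit_data_error")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Sample a numeric grid with bilinear interpolation
#'
#' @param grid numeric matrix (rows = y, columns = x).
#' @param x,y query coordinates (0-based pixel centres); values outside the
#'   grid are clamped to the border.
#' @return numeric vector of interpolated values.
#' @keywords internal
sample_bilinear <- function(grid, x, y) {
  nr <- nrow(grid); nc <- ncol(grid)
  x <- pmin(pmax(x, 0), nc - 1)
  y <- pmin(pmax(y, 0), nr - 1)
  x0 <- pmin(floor(x), nc - 2); x0 <- pmax(x0, 0)
  y0 <- pmin(floor(y), nr - 2); y0 <- pmax(y0, 0)
  fx <- x - x0; fy <- y - y0
  if (nc == 1) { x0 <- 0; fx <- 0 }
  if (nr == 1) { y0 <- 0; fy <- 0 }
  i00 <- (x0) * nr + y0 + 1
  v00 <- grid[i00]; v10 <- grid[i00 + nr * (nc > 1)]
  v01 <- grid[i00 + (nr > 1)]; v11 <- grid[i00 + nr * (nc > 1) + (nr > 1)]
  (1 - fx) * (1 - fy) * v00 + fx * (1 - fy) * v10 +
    (1 - fx) * fy * v01 + fx * fy * v11
}

#' Sample a grid with nearest-neighbour lookup
#'
#' Out-of-bounds queries return `outside` (label 0 by default, so absent
#' evidence never creates positive labels).
#' @keywords internal
sample_nearest <- function(grid, x, y, outside = 0) {
  nr <- nrow(grid); nc <- ncol(grid)
  xi <- as.integer(round(x)); yi <- as.integer(round(y))
  ok <- xi >= 0 & xi < nc & yi >= 0 & yi < nr
  out <- rep(outside, length(x))
  idx <- xi[ok] * nr + yi[ok] + 1
  out[ok] <- grid[idx]
  out
}

# Nearest-neighbour resize with the standard half-pixel mapping:
# destination pixel i (1-based) reads source pixel floor((i - 0.5) * s) + 1.
resize_nearest <- function(m, new_h, new_w) {
  ri <- pmin(floor(((seq_len(new_h) - 0.5) * nrow(m)) / new_h) + 1, nrow(m))
  ci <- pmin(floor(((seq_len(new_w) - 0.5) * ncol(m)) / new_w) + 1, ncol(m))
  m[ri, ci, drop = FALSE]
}

# Bilinear resize for a single channel.
resize_bilinear <- function(m, new_h, new_w) {
  xs <- ((seq_len(new_w) - 0.5) * ncol(m)) / new_w - 0.5
  ys <- ((seq_len(new_h) - 0.5) * nrow(m)) / new_h - 0.5
  g <- expand.grid(y = ys, x = xs)
  matrix(sample_bilinear(m, g$x, g$y), new_h, new_w)
}

resize_rgb <- function(a, new_h, new_w) {
  out <- array(0, c(new_h, new_w, dim(a)[3]))
  for (ch in seq_len(dim(a)[3])) out[, , ch] <- resize_bilinear(a[, , ch], new_h, new_w)
  out
}

# Homography mapping the four source corners onto the four destination
# corners (both 4x2, matched rows). Returns the 3x3 matrix H with
# dst ~ H %*% c(src, 1).
solve_homography <- function(src, dst) {
  stopifnot(nrow(src) == 4, nrow(dst) == 4)
  A <- matrix(0, 8, 8); b <- numeric(8)
  for (i in 1:4) {
    x <- src[i, 1]; y <- src[i, 2]; u <- dst[i, 1]; v <- dst[i, 2]
    A[2 * i - 1, ] <- c(x, y, 1, 0, 0, 0, -u * x, -u * y)
    A[2 * i, ]     <- c(0, 0, 0, x, y, 1, -v * x, -v * y)
    b[2 * i - 1] <- u; b[2 * i] <- v
  }
  h <- tryCatch(solve(A, b), error = function(e) {
    sil_data_error("degenerate quadrilateral: homography is singular")
  })
  matrix(c(h, 1), 3, 3, byrow = TRUE)
}

apply_homography <- function(H, x, y) {
  d <- H[3, 1] * x + H[3, 2] * y + H[3, 3]
  list(
    x = (H[1, 1] * x + H[1, 2] * y + H[1, 3]) / d,
    y = (H[2, 1] * x + H[2, 2] * y + H[2, 3]) / d
  )
}

# RGB array (h x w x 3, [0,1]) -> HSV matrices. grDevices::rgb2hsv works on a
# 3 x n matrix; hue rescaled to [0, 1].
rgb_to_hsv_planes <- function(a) {
  d <- dim(a)
  m <- rbind(
    as.vector(a[, , 1]),
    as.vector(a[, , 2]),
    as.vector(a[, , 3])
  )
  hsv <- grDevices::rgb2hsv(m, maxColorValue = 1)
  list(
    h = matrix(hsv[1, ], d[1], d[2]),
    s = matrix(hsv[2, ], d[1], d[2]),
    v = matrix(hsv[3, ], d[1], d[2])
  )
}

md5_of <- function(paths) {
  unname(tools::md5sum(paths))
}
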