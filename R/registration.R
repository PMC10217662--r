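# IHC-to-H&E label transfer through a dense displacement field.
#
# Convention (fixed package-wide): the field is stored on the H&E frame and
# the IHC coordinate of an H&E point (x, y) is
#     (x - f_x(x, y), y - f_y(x, y)).
# Mapping a contour applies this point-wise; pulling back a mask samples the
# IHC raster at the mapped position of every H&E pixel.

#' Displacement field
#'
#' Two scalar planes (`f_x`, `f_y`) in pixels, defined on H&E coordinates.
#'
#' @param f_x,f_y numeric matrices of identical shape with finite entries.
#' @return object of class `displacement_field`.
#' @export
displacement_field <- function(f_x, f_y) {
  if (!is.matrix(f_x) || !is.matrix(f_y) || !all(dim(f_x) == dim(f_y)))
    sil_data_error("f_x and f_y must be matrices of one shape")
  if (!all(is.finite(f_x)) || !all(is.finite(f_y)))
    sil_data_error("displacement planes must be finite")
  structure(list(f_x = f_x, f_y = f_y), class = "displacement_field")
}

#' @export
print.displacement_field <- function(x, ...) {
  cat(sprintf(
    "<displacement_field> %d x %d px, |f| max %.2f px\n",
    nrow(x$f_x), ncol(x$f_x), max(abs(c(x$f_x, x$f_y)))
  ))
  invisible(x)
}

#' @export
dim.displacement_field <- function(x) dim(x$f_x)

#' Map a contour from the H&E frame to the IHC frame
#'
#' Each contour point `(x, y)` maps to `(x - f_x(x, y), y - f_y(x, y))`,
#' with the field evaluated by bilinear interpolation at non-integer
#' positions.
#'
#' @param contour n x 2 matrix of H&E-frame points (0-based x, y), or a
#'   polygon list with a `points` element.
#' @param field a [displacement_field()].
#' @return n x 2 matrix of IHC-frame points.
#' @export
map_contour_to_ihc <- function(contour, field) {
  pts <- if (is.list(contour) && !is.null(contour$points)) contour$points else contour
  if (!is.matrix(pts) || ncol(pts) != 2)
    sil_data_error("contour must be an n x 2 matrix")
  d <- dim(field$f_x)
  out_of <- pts[, 1] < 0 | pts[, 1] > d[2] - 1 | pts[, 2] < 0 | pts[, 2] > d[1] - 1
  if (any(out_of))
    sil_data_error(sprintf(
      "contour point(s) outside the field domain: index %s",
      paste(which(out_of), collapse = ", ")
    ))
  fx <- sample_bilinear(field$f_x, pts[, 1], pts[, 2])
  fy <- sample_bilinear(field$f_y, pts[, 1], pts[, 2])
  cbind(x = pts[, 1] - fx, y = pts[, 2] - fy)
}

#' Pull an IHC mask back onto the H&E frame
#'
#' For every H&E pixel `(x, y)` the IHC mask is sampled with
#' nearest-neighbour lookup at `(x - f_x, y - f_y)`. Nearest-neighbour keeps
#' labels integral; samples falling outside the IHC raster are 0, so absent
#' IHC evidence never creates positive labels.
#'
#' @param ihc_mask integer mask in the IHC frame.
#' @param field a [displacement_field()] defined on the H&E frame.
#' @param he_shape integer `c(height, width)` of the H&E frame; must equal
#'   the field shape.
#' @return integer mask of shape `he_shape` in the H&E frame.
#' @export
pull_back_mask <- function(ihc_mask, field, he_shape = dim(field)) {
  d <- dim(field$f_x)
  if (!all(d == he_shape))
    sil_data_error(sprintf(
      "field shape (%d x %d) does not match he_shape (%d x %d)",
      d[1], d[2], he_shape[1], he_shape[2]
    ))
  g <- expand.grid(y = seq_len(he_shape[1]) - 1, x = seq_len(he_shape[2]) - 1)
  sx <- g$x - as.vector(field$f_x)
  sy <- g$y - as.vector(field$f_y)
  m <- as_binary_mask(ihc_mask)
  matrix(
    as.integer(sample_nearest(m, sx, sy, outside = 0L)),
    he_shape[1], he_shape[2]
  )
}

#' Construct synthetic displacement fields
#'
#' Field estimation on clinical slide pairs is delegated to a registration
#' toolbox and arrives as an input; these generators produce fields of known
#' form so the transfer machinery is fully testable.
#'
#' Kinds:
#' * `identity` — zero planes.
#' * `translation` — constant planes; `params = list(dx, dy)` so that the
#'   IHC coordinate is `(x - dx, y - dy)`.
#' * `affine` — the field of the affine map `T(x) = A x + b`
#'   (`f(x) = x - T(x)`); `params = list(A = 2x2 matrix, b = length-2)`.
#' * `smooth_random` — a band-limited Gaussian random field: white noise on
#'   a coarse lattice of spacing `correlation_length`, bilinearly upsampled
#'   and scaled so the maximum absolute displacement equals `amplitude`;
#'   `params = list(amplitude, correlation_length)`.
#'
#' @param kind one of `"identity"`, `"translation"`, `"affine"`,
#'   `"smooth_random"`.
#' @param params parameter list per kind (see Details).
#' @param shape integer `c(height, width)`.
#' @param seed integer seed (smooth_random only); same seed, same field.
#' @return a [displacement_field()].
#' @export
make_field <- function(kind, params = list(), shape, seed = 1L) {
  h <- shape[1]; w <- shape[2]
  if (kind == "identity") {
    displacement_field(matrix(0, h, w), matrix(0, h, w))
  } else if (kind == "translation") {
    if (is.null(params$dx) || is.null(params$dy))
      sil_config_error("translation field needs params dx and dy")
    displacement_field(
      matrix(params$dx, h, w),
      matrix(params$dy, h, w)
    )
  } else if (kind == "affine") {
    A <- params$A; b <- params$b
    if (is.null(A) || is.null(b))
      sil_config_error("affine field needs params A (2x2) and b (length 2)")
    g <- expand.grid(y = seq_len(h) - 1, x = seq_len(w) - 1)
    tx <- A[1, 1] * g$x + A[1, 2] * g$y + b[1]
    ty <- A[2, 1] * g$x + A[2, 2] * g$y + b[2]
    displacement_field(
      matrix(g$x - tx, h, w),
      matrix(g$y - ty, h, w)
    )
  } else if (kind == "smooth_random") {
    amp <- params$amplitude %||% 8
    cl <- params$correlation_length %||% 256
    withr::with_seed(seed, {
      nh <- max(2, ceiling(h / cl) + 2)
      nw <- max(2, ceiling(w / cl) + 2)
      plane <- function() {
        coarse <- matrix(stats::rnorm(nh * nw), nh, nw)
        xs <- (seq_len(w) - 1) / cl + 1
        ys <- (seq_len(h) - 1) / cl + 1
        g <- expand.grid(y = ys, x = xs)
        fine <- matrix(sample_bilinear(coarse, g$x - 1, g$y - 1), h, w)
        fine / max(abs(fine)) * amp
      }
      displacement_field(plane(), plane())
    })
  } else {
    sil_config_error(sprintf("unknown field kind '%s'", kind))
  }
}

# Approximate inverse of the H&E -> IHC map x' = x - f(x): fixed-point
# iteration x = x' + f(x), convergent while |grad f| < 1 (smooth fields of
# small amplitude). Used by the synthetic generator to render IHC-frame
# rasters from H&E-frame geometry.
invert_field_at <- function(field, xi, yi, iterations = 5) {
  x <- xi; y <- yi
  for (k in seq_len(iterations)) {
    x <- xi + sample_bilinear(field$f_x, x, y)
    y <- yi + sample_bilinear(field$f_y, x, y)
  }
  list(x = x, y = y)
}
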