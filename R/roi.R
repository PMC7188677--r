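#' Regions of interest
#'
#' ROIs address pixels in image coordinates: 1-based (row, column), pixel
#' centers at integers. `roi_rect()` covers an inclusive row/column range,
#' `roi_polygon()` the pixels whose centers fall inside a closed polygon
#' (even-odd rule), and `roi_line()` a line segment for cross-section
#' profiling.
#'
#' @param rows,cols Inclusive index ranges (length-2 vectors) for a rectangle.
#' @param label Text label carried into result tables.
#' @return An object of class `roi`.
#' @export
roi_rect <- function(rows, cols, label = "roi") {
  structure(list(kind = "rectangle", rows = sort(rows[c(1, length(rows))]),
                 cols = sort(cols[c(1, length(cols))]), label = label),
            class = "roi")
}

#' @rdname roi_rect
#' @param vertices Two-column matrix of (row, col) polygon vertices.
#' @export
roi_polygon <- function(vertices, label = "roi") {
  vertices <- as.matrix(vertices)
  if (nrow(vertices) < 3L) abort("A polygon needs at least 3 vertices.")
  structure(list(kind = "polygon", vertices = vertices, label = label),
            class = "roi")
}

#' @rdname roi_rect
#' @param from,to Segment endpoints `c(row, col)`.
#' @export
roi_line <- function(from, to, label = "section") {
  structure(list(kind = "line_segment", from = as.numeric(from),
                 to = as.numeric(to), label = label),
            class = "roi")
}

#' @rdname roi_rect
#' @param mask Logical matrix defining the ROI directly.
#' @export
roi_mask_spec <- function(mask, label = "roi") {
  structure(list(kind = "mask", mask = mask, label = label), class = "roi")
}

#' Rasterize an ROI to a pixel mask
#'
#' @param roi An `roi` (rectangle, polygon, or mask; not a line segment).
#' @param dim Image dimensions `c(height, width)`.
#' @return A logical matrix.
#' @export
roi_to_mask <- function(roi, dim) {
  h <- dim[1]; w <- dim[2]
  m <- matrix(FALSE, h, w)
  switch(roi$kind,
    rectangle = {
      r <- pmax(1L, pmin(h, roi$rows)); c <- pmax(1L, pmin(w, roi$cols))
      m[r[1]:r[2], c[1]:c[2]] <- TRUE
    },
    polygon = {
      pr <- rep(seq_len(h), w)
      pc <- rep(seq_len(w), each = h)
      m[] <- point_in_polygon(pr, pc, roi$vertices)
    },
    mask = {
      if (!all(dim(roi$mask) == dim)) abort("ROI mask shape mismatch.")
      m <- roi$mask
    },
    abort(sprintf("Cannot rasterize an ROI of kind '%s'.", roi$kind))
  )
  if (!any(m)) abort("ROI covers no pixels.")
  m
}

# even-odd ray casting, vectorized over query points
point_in_polygon <- function(pr, pc, vertices) {
  n <- nrow(vertices)
  inside <- rep(FALSE, length(pr))
  j <- n
  for (i in seq_len(n)) {
    yi <- vertices[i, 1]; xi <- vertices[i, 2]
    yj <- vertices[j, 1]; xj <- vertices[j, 2]
    crosses <- ((yi > pr) != (yj > pr)) &
      (pc < (xj - xi) * (pr - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# bilinear interpolation at fractional (row, col); NA outside or on NA cells
interp_bilinear <- function(mat, r, c) {
  h <- nrow(mat); w <- ncol(mat)
  r0 <- pmax(1L, pmin(h - 1L, floor(r)))
  c0 <- pmax(1L, pmin(w - 1L, floor(c)))
  fr <- r - r0
  fc <- c - c0
  v00 <- mat[cbind(r0, c0)]
  v10 <- mat[cbind(r0 + 1L, c0)]
  v01 <- mat[cbind(r0, c0 + 1L)]
  v11 <- mat[cbind(r0 + 1L, c0 + 1L)]
  out <- v00 * (1 - fr) * (1 - fc) + v10 * fr * (1 - fc) +
    v01 * (1 - fr) * fc + v11 * fr * fc
  out[r < 1 | r > h | c < 1 | c > w] <- NA_real_
  out
}
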