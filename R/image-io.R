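# Image and ROI input/output.
#
# Coordinate convention (documented, used everywhere):
#   * pixel grids are R matrices: rows = axial (depth), cols = lateral;
#   * a matrix element [i, j] (1-based) has its center at the continuous
#     0-based point (x = j - 1, y = i - 1), x lateral, y axial;
#   * ROI polygon vertices are (x, y) in that 0-based continuous frame.

#' Construct a B-mode image
#'
#' A B-mode image couples a non-negative intensity grid with the physical
#' pixel spacing on each axis, which is what turns DFT bin indices into
#' spatial frequencies in mm^-1.
#'
#' @param pixels Numeric matrix of intensities (rows = axial, cols =
#'   lateral); all values must be finite and >= 0.
#' @param spacing_axial,spacing_lateral Pixel spacing in mm (> 0).
#' @param source_id Free-text identifier, e.g. the originating file name.
#' @return An object of class `bmode_image`.
#' @export
bmode_image <- function(pixels, spacing_axial, spacing_lateral,
                        source_id = "") {
  if (!is.matrix(pixels) || !is.numeric(pixels) ||
      nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop_validation("`pixels` must be a numeric matrix with >= 1 row/col")
  if (any(!is.finite(pixels)) || any(pixels < 0))
    stop_validation("image intensities must be finite and >= 0")
  check_scalar_positive(spacing_axial, "spacing_axial")
  check_scalar_positive(spacing_lateral, "spacing_lateral")
  structure(
    list(pixels = pixels,
         spacing_axial = as.numeric(spacing_axial),
         spacing_lateral = as.numeric(spacing_lateral),
         source_id = as.character(source_id)[1]),
    class = "bmode_image"
  )
}

#' @export
print.bmode_image <- function(x, ...) {
  cat(sprintf("<bmode_image> %d x %d px, spacing %.5g x %.5g mm/px%s\n",
              nrow(x$pixels), ncol(x$pixels),
              x$spacing_axial, x$spacing_lateral,
              if (nzchar(x$source_id)) paste0(" [", x$source_id, "]") else ""))
  invisible(x)
}

#' Load a grayscale B-mode image from PNG or PGM
#'
#' PNG files are read with the `png` package; RGB(A) input is collapsed to
#' luminance with Rec.601 weights (0.299, 0.587, 0.114).  PGM (P2 ASCII or
#' P5 binary, maxval <= 65535) is parsed natively.  Intensities are kept on
#' their stored integer scale (0..255 or 0..65535), never rescaled.
#'
#' @param path Image file (`.png`, `.pgm`).
#' @param spacing_axial,spacing_lateral Pixel spacing in mm (> 0); this is
#'   acquisition metadata that PNG/PGM cannot carry, so the caller supplies
#'   it (default 6.6/96 mm on both axes, a 96 px kernel spanning 6.6 mm).
#' @return A [bmode_image()].
#' @export
load_bmode_image <- function(path, spacing_axial = 6.6 / 96,
                             spacing_lateral = 6.6 / 96) {
  check_scalar_positive(spacing_axial, "spacing_axial")
  check_scalar_positive(spacing_lateral, "spacing_lateral")
  if (!file.exists(path))
    stop_io("image file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png = read_png_intensities(path),
    pgm = read_pgm(path),
    stop_io("unsupported image format '.%s' (use .png or .pgm): %s",
            ext, path)
  )
  bmode_image(px, spacing_axial, spacing_lateral, source_id = basename(path))
}

read_png_intensities <- function(path) {
  img <- tryCatch(png::readPNG(path, info = TRUE),
                  error = function(e) stop_io("cannot read PNG %s: %s",
                                              path, conditionMessage(e)))
  info <- attr(img, "info")
  depth <- if (!is.null(info$bit.depth)) info$bit.depth else 8L
  maxval <- 2^depth - 1
  if (length(dim(img)) == 3L) {
    nc <- dim(img)[3]
    if (nc >= 3L) {
      img <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
    } else {
      img <- img[, , 1]
    }
  }
  # matrix() drops readPNG's metadata attributes
  matrix(as.integer(round(img * maxval)), nrow(img), ncol(img))
}

#' Write a B-mode image to PNG or PGM
#'
#' PNG output is 8-bit (intensities are clamped to 0..255); for bit-exact
#' 16-bit round trips use PGM.  PGM is written as plain-text P2, maxval 255
#' or 65535, so fixtures stay human-readable.
#'
#' @param image A [bmode_image()] (or bare numeric matrix).
#' @param path Destination ending in `.png` or `.pgm`.
#' @param bit_depth 8 or 16 (PGM only; PNG is always 8).
#' @return `path`, invisibly.
#' @export
write_bmode_image <- function(image, path, bit_depth = 8) {
  px <- if (inherits(image, "bmode_image")) image$pixels else image
  if (!bit_depth %in% c(8, 16))
    stop_validation("bit_depth must be 8 or 16")
  maxval <- 2^bit_depth - 1
  q <- pmin(pmax(round(px), 0), maxval)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    if (bit_depth != 8)
      stop_validation("PNG output is 8-bit only; use .pgm for 16-bit")
    png::writePNG(q / maxval, path)
  } else if (ext == "pgm") {
    write_pgm(q, path, maxval = maxval)
  } else {
    stop_io("unsupported output format '.%s' (use .png or .pgm)", ext)
  }
  invisible(path)
}

# -- Plain PGM codec (P2 ASCII / P5 binary, maxval <= 65535) -----------------

read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  tokens <- character(0)
  # header tokens: magic, width, height, maxval; '#' starts a comment
  read_token <- function() {
    tok <- ""
    repeat {
      ch <- readChar(con, 1, useBytes = TRUE)
      if (length(ch) == 0 || !nzchar(ch))
        stop_io("truncated PGM header: %s", path)
      if (ch == "#") {
        repeat {
          ch <- readChar(con, 1, useBytes = TRUE)
          if (!length(ch) || ch == "\n") break
        }
        next
      }
      if (grepl("[[:space:]]", ch)) {
        if (nzchar(tok)) return(tok) else next
      }
      tok <- paste0(tok, ch)
    }
  }
  magic <- read_token()
  if (!magic %in% c("P2", "P5"))
    stop_io("not a PGM file (magic '%s'): %s", magic, path)
  width <- as.integer(read_token())
  height <- as.integer(read_token())
  maxval <- as.integer(read_token())
  if (anyNA(c(width, height, maxval)) || width < 1 || height < 1 ||
      maxval < 1 || maxval > 65535)
    stop_io("bad PGM dimensions/maxval in %s", path)
  n <- width * height
  vals <- if (magic == "P2") {
    raw_rest <- readChar(con, file.size(path), useBytes = TRUE)
    raw_rest <- gsub("#[^\n]*", " ", raw_rest)
    v <- suppressWarnings(as.integer(
      strsplit(trimws(raw_rest), "[[:space:]]+")[[1]]))
    if (length(v) < n || anyNA(v[seq_len(n)]))
      stop_io("truncated or malformed P2 pixel data: %s", path)
    v[seq_len(n)]
  } else {
    bytes_per <- if (maxval > 255) 2L else 1L
    v <- readBin(con, "integer", n = n, size = bytes_per,
                 signed = FALSE, endian = "big")
    if (length(v) < n) stop_io("truncated P5 pixel data: %s", path)
    v
  }
  if (any(vals < 0 | vals > maxval))
    stop_io("PGM pixel values outside 0..maxval: %s", path)
  matrix(vals, nrow = height, ncol = width, byrow = TRUE)
}

write_pgm <- function(pixels, path, maxval = 255) {
  if (any(pixels < 0 | pixels > maxval))
    stop_validation("pixel values outside 0..%d", maxval)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(pixels), nrow(pixels)),
               as.character(maxval)), con)
  # one image row per line keeps files diffable
  rows <- apply(pixels, 1L, function(r) paste(as.integer(r), collapse = " "))
  writeLines(rows, con)
  invisible(path)
}

# -- ROI polygons ------------------------------------------------------------

#' Construct a polygonal region of interest
#'
#' Vertices are ordered (x, y) points in the 0-based continuous pixel frame
#' (x = column = lateral, y = row = axial).  The polygon must be simple:
#' at least 3 distinct vertices, no self-intersection, nonzero area.
#'
#' @param vertices Two-column numeric matrix (or data frame / list of pairs)
#'   of (x, y) vertices.
#' @param image_id Free-text identifier of the parent image.
#' @return An object of class `roi_polygon`.
#' @export
roi_polygon <- function(vertices, image_id = "") {
  v <- as.matrix(vertices)
  if (is.list(vertices) && !is.data.frame(vertices))
    v <- do.call(rbind, lapply(vertices, function(p) as.numeric(p)))
  storage.mode(v) <- "double"
  if (ncol(v) != 2L || nrow(v) < 3L || any(!is.finite(v)))
    stop_validation("a polygon needs >= 3 finite (x, y) vertices")
  # drop an explicitly closed ring
  if (nrow(v) > 3L && all(v[1, ] == v[nrow(v), ])) v <- v[-nrow(v), , drop = FALSE]
  if (nrow(v) < 3L) stop_validation("a polygon needs >= 3 distinct vertices")
  nxt <- c(2:nrow(v), 1L)
  if (any(v[, 1] == v[nxt, 1] & v[, 2] == v[nxt, 2]))
    stop_validation("degenerate polygon: repeated consecutive vertices")
  if (abs(polygon_area(v)) < 1e-12)
    stop_validation("degenerate polygon: zero area")
  if (!polygon_is_simple(v))
    stop_validation("polygon is self-intersecting")
  structure(list(vertices = unname(v), image_id = as.character(image_id)[1]),
            class = "roi_polygon")
}

polygon_area <- function(v) {
  n <- nrow(v)
  j <- c(2:n, 1L)
  sum(v[, 1] * v[j, 2] - v[j, 1] * v[, 2]) / 2
}

# Simplicity check: no two non-adjacent edges intersect; adjacent edges may
# only share their common endpoint.
polygon_is_simple <- function(v) {
  n <- nrow(v)
  seg <- cbind(v, v[c(2:n, 1L), , drop = FALSE])
  cross <- function(ox, oy, ax, ay, bx, by)
    (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  on_seg <- function(px, py, ax, ay, bx, by)
    px >= pmin(ax, bx) - 1e-12 & px <= pmax(ax, bx) + 1e-12 &
    py >= pmin(ay, by) - 1e-12 & py <= pmax(ay, by) + 1e-12
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      adjacent <- (j == i + 1L) || (i == 1L && j == n)
      a <- seg[i, ]; b <- seg[j, ]
      d1 <- cross(b[1], b[2], b[3], b[4], a[1], a[2])
      d2 <- cross(b[1], b[2], b[3], b[4], a[3], a[4])
      d3 <- cross(a[1], a[2], a[3], a[4], b[1], b[2])
      d4 <- cross(a[1], a[2], a[3], a[4], b[3], b[4])
      proper <- ((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
        ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))
      if (proper && !adjacent) return(FALSE)
      if (!adjacent) {
        # collinear overlap or endpoint touching a non-adjacent edge
        touch <- (abs(d1) < 1e-12 && on_seg(a[1], a[2], b[1], b[2], b[3], b[4])) ||
          (abs(d2) < 1e-12 && on_seg(a[3], a[4], b[1], b[2], b[3], b[4])) ||
          (abs(d3) < 1e-12 && on_seg(b[1], b[2], a[1], a[2], a[3], a[4])) ||
          (abs(d4) < 1e-12 && on_seg(b[3], b[4], a[1], a[2], a[3], a[4]))
        if (touch) return(FALSE)
      }
    }
  }
  TRUE
}

#' Read / write ROI polygons as JSON
#'
#' The exchange schema is a JSON object
#' `{"image": "<id>", "vertices": [[x, y], ...]}` with 0-based continuous
#' pixel coordinates (x lateral, y axial).
#'
#' @param path JSON file.
#' @return `read_roi_json()` returns an [roi_polygon()];
#'   `write_roi_json()` returns `path` invisibly.
#' @export
read_roi_json <- function(path) {
  if (!file.exists(path)) stop_io("ROI file not found: %s", path)
  obj <- tryCatch(jsonlite::fromJSON(path),
                  error = function(e) stop_io("cannot parse ROI JSON %s: %s",
                                              path, conditionMessage(e)))
  if (is.null(obj$vertices))
    stop_validation("ROI JSON %s lacks a 'vertices' field", path)
  roi_polygon(obj$vertices,
              image_id = if (is.null(obj$image)) "" else obj$image)
}

#' @rdname read_roi_json
#' @param polygon An [roi_polygon()].
#' @export
write_roi_json <- function(polygon, path) {
  stopifnot(inherits(polygon, "roi_polygon"))
  jsonlite::write_json(
    list(image = polygon$image_id, vertices = polygon$vertices),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# -- Rasterization -----------------------------------------------------------

#' Rasterize an ROI polygon to a boolean mask
#'
#' A pixel belongs to the mask exactly when its center (integer point
#' `(x = j - 1, y = i - 1)` for matrix element `[i, j]`) lies inside the
#' polygon or on its boundary, by the even-odd rule.
#'
#' @param polygon An [roi_polygon()]; vertices must lie in
#'   `[0, cols) x [0, rows)`.
#' @param shape Integer `(rows, cols)` of the parent image.
#' @return An object of class `roi_mask` with fields `mask` (logical
#'   matrix) and `area_px`.
#' @export
rasterize_roi <- function(polygon, shape) {
  stopifnot(inherits(polygon, "roi_polygon"))
  shape <- as.integer(shape)
  if (length(shape) != 2L || any(shape < 1L))
    stop_validation("`shape` must be (rows, cols) with positive entries")
  v <- polygon$vertices
  if (any(v[, 1] < 0 | v[, 1] >= shape[2] | v[, 2] < 0 | v[, 2] >= shape[1]))
    stop_validation("polygon vertices fall outside [0, cols) x [0, rows)")
  rows <- shape[1]; cols <- shape[2]
  # restrict the test to the bounding box
  x0 <- max(0L, floor(min(v[, 1]))); x1 <- min(cols - 1L, ceiling(max(v[, 1])))
  y0 <- max(0L, floor(min(v[, 2]))); y1 <- min(rows - 1L, ceiling(max(v[, 2])))
  xs <- x0:x1; ys <- y0:y1
  px <- rep(xs, each = length(ys))
  py <- rep(ys, times = length(xs))
  inside <- point_in_polygon(px, py, v)
  mask <- matrix(FALSE, rows, cols)
  mask[cbind(py + 1L, px + 1L)] <- inside
  roi_mask(mask)
}

#' Construct an ROI mask from a logical matrix
#'
#' @param mask Logical matrix congruent with the parent image.
#' @return Object of class `roi_mask` with fields `mask` and `area_px`.
#' @export
roi_mask <- function(mask) {
  if (!is.matrix(mask) || !is.logical(mask))
    stop_validation("`mask` must be a logical matrix")
  structure(list(mask = mask, area_px = sum(mask)), class = "roi_mask")
}

#' Even-odd point-in-polygon test, boundary-inclusive
#'
#' Vectorised crossing-number test over point vectors; points exactly on a
#' polygon edge (within 1e-9) count as inside.
#'
#' @param px,py Point coordinates.
#' @param vertices Two-column vertex matrix.
#' @return Logical vector.
#' @export
point_in_polygon <- function(px, py, vertices) {
  v <- as.matrix(vertices)
  n <- nrow(v)
  j <- c(2:n, 1L)
  inside <- logical(length(px))
  boundary <- logical(length(px))
  for (e in seq_len(n)) {
    x1 <- v[e, 1]; y1 <- v[e, 2]; x2 <- v[j[e], 1]; y2 <- v[j[e], 2]
    # on-segment check
    d <- abs((x2 - x1) * (py - y1) - (y2 - y1) * (px - x1))
    len <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
    on <- d <= 1e-9 * max(1, len) &
      px >= min(x1, x2) - 1e-9 & px <= max(x1, x2) + 1e-9 &
      py >= min(y1, y2) - 1e-9 & py <= max(y1, y2) + 1e-9
    boundary <- boundary | on
    crosses <- ((y1 > py) != (y2 > py)) &
      (px < (x2 - x1) * (py - y1) / (y2 - y1) + x1)
    inside <- xor(inside, crosses)
  }
  inside | boundary
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> %d x %d, area %d px\n",
              nrow(x$mask), ncol(x$mask), x$area_px))
  invisible(x)
}

#' Write a binary mask as an image (white ROI on black)
#'
#' @param mask An [roi_mask()] or logical matrix.
#' @param path Destination `.png` or `.pgm`.
#' @export
write_mask_image <- function(mask, path) {
  m <- if (inherits(mask, "roi_mask")) mask$mask else mask
  write_bmode_image(ifelse(m, 255, 0) * 1, path, bit_depth = 8)
}

#' Read a binary mask image back to an roi_mask
#'
#' Any strictly positive pixel counts as inside.
#' @param path Mask image file.
#' @export
read_mask_image <- function(path) {
  img <- load_bmode_image(path)
  roi_mask(img$pixels > 0)
}
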