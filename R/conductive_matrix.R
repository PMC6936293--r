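#' Construct a conductive matrix
#'
#' A conductive matrix marks, voxel by voxel, where actin-bundle material
#' exists inside the droplet. Only conductive voxels take part in the
#' excitable automaton; everything else is inert background.
#'
#' @param grid Logical 3D array (`n_x` x `n_y` x `n_z`); `TRUE` marks a
#'   conductive voxel.
#' @param voxel_size Numeric length-3 vector, physical voxel size in
#'   micrometres `(dx, dy, dz)`. Metadata only: all geometry in the package
#'   is computed in voxel index units.
#' @param provenance One of `"thresholded"`, `"synthetic"`, `"loaded"`.
#' @return An object of class `conductive_matrix`.
#' @export
conductive_matrix <- function(grid,
                              voxel_size = c(0.22, 0.22, 4),
                              provenance = c("thresholded", "synthetic", "loaded")) {
  provenance <- match.arg(provenance)
  if (!is.array(grid) || length(dim(grid)) != 3L)
    stop("`grid` must be a 3D array", call. = FALSE)
  storage.mode(grid) <- "logical"
  if (anyNA(grid)) stop("`grid` must not contain NA", call. = FALSE)
  structure(
    list(grid = grid,
         voxel_size = as.numeric(voxel_size),
         provenance = provenance),
    class = "conductive_matrix"
  )
}

#' @export
print.conductive_matrix <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf("<conductive_matrix> %d x %d x %d voxels (%s)\n",
              d[1], d[2], d[3], x$provenance))
  cat(sprintf("  conductive voxels: %d (%.1f%%)\n",
              sum(x$grid), 100 * mean(x$grid)))
  cat(sprintf("  voxel size: %.3g x %.3g x %.3g um\n",
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  invisible(x)
}

#' @export
dim.conductive_matrix <- function(x) dim(x$grid)

#' Construct an RGB image stack
#'
#' Container for a confocal slice stack: integer RGB channels per voxel.
#'
#' @param r,g,b Integer 3D arrays of identical dimensions, channel values
#'   in 0..255.
#' @param voxel_size Physical voxel size in micrometres, metadata only.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(r, g, b, voxel_size = c(0.22, 0.22, 4)) {
  for (ch in list(r, g, b)) {
    if (!is.array(ch) || length(dim(ch)) != 3L)
      stop("channels must be 3D arrays", call. = FALSE)
    if (!identical(dim(ch), dim(r)))
      stop("channel dimensions differ (ragged stack)", call. = FALSE)
    if (anyNA(ch) || min(ch) < 0 || max(ch) > 255)
      stop("channel values must lie in [0, 255]", call. = FALSE)
  }
  structure(list(r = r, g = g, b = b, voxel_size = as.numeric(voxel_size)),
            class = "image_stack")
}

#' @export
dim.image_stack <- function(x) dim(x$r)

#' Threshold an RGB stack into a conductive matrix
#'
#' A voxel is conductive iff all three channels strictly exceed their
#' thresholds. The defaults reproduce the segmentation rule used for
#' laboratory confocal stacks of crowding-induced actin bundle networks:
#' red > 40, green > 19, blue > 19.
#'
#' @param stack An [image_stack].
#' @param r_min,g_min,b_min Strict lower thresholds per channel.
#' @return A [conductive_matrix] with provenance `"thresholded"`.
#' @export
threshold_stack <- function(stack, r_min = 40, g_min = 19, b_min = 19) {
  stopifnot(inherits(stack, "image_stack"))
  grid <- (stack$r > r_min) & (stack$g > g_min) & (stack$b > b_min)
  conductive_matrix(grid, voxel_size = stack$voxel_size,
                    provenance = "thresholded")
}

#' Render a conductive matrix back to an RGB stack
#'
#' Conductive voxels become white (255, 255, 255), background black.
#' Useful for round-tripping through image containers.
#'
#' @param mat A [conductive_matrix].
#' @return An [image_stack].
#' @export
matrix_to_stack <- function(mat) {
  stopifnot(inherits(mat, "conductive_matrix"))
  ch <- array(ifelse(mat$grid, 255L, 0L), dim = dim(mat$grid))
  image_stack(ch, ch, ch, voxel_size = mat$voxel_size)
}

#' Compress a conductive matrix along the z axis
#'
#' Bins of `factor` consecutive slices are reduced to one slice; the last
#' bin may be short. Reducer `"OR"` (and its alias `"MAX"` for a boolean
#' grid) marks an output voxel conductive iff any slice of its bin is.
#' Compression trades z-resolution for simulation cost; with `factor = 1`
#' the matrix is returned unchanged.
#'
#' @param mat A [conductive_matrix].
#' @param factor Positive integer bin width.
#' @param reducer `"OR"` or `"MAX"` (identical on logical grids).
#' @return A [conductive_matrix] with depth `ceiling(n_z / factor)`.
#' @export
compress_z <- function(mat, factor = 1, reducer = c("OR", "MAX")) {
  stopifnot(inherits(mat, "conductive_matrix"))
  reducer <- match.arg(reducer)
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L)
    stop("`factor` must be a positive integer", call. = FALSE)
  if (factor == 1L) return(mat)
  d <- dim(mat$grid)
  nz_out <- ceiling(d[3] / factor)
  out <- array(FALSE, dim = c(d[1], d[2], nz_out))
  for (zo in seq_len(nz_out)) {
    zin <- ((zo - 1L) * factor + 1L):min(zo * factor, d[3])
    sub <- mat$grid[, , zin, drop = FALSE]
    out[, , zo] <- apply(sub, c(1, 2), any)
  }
  vs <- mat$voxel_size
  conductive_matrix(out, voxel_size = c(vs[1], vs[2], vs[3] * factor),
                    provenance = mat$provenance)
}

#' Write a conductive matrix to a TIFF stack with a JSON sidecar
#'
#' The container is a multi-page greyscale TIFF (0/255 per voxel, one page
#' per z slice) plus `<path>.json` holding shape, voxel size and
#' provenance, so the geometry is inspectable with standard viewers and
#' round-trips losslessly.
#'
#' @param mat A [conductive_matrix].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_matrix_tiff <- function(mat, path) {
  stopifnot(inherits(mat, "conductive_matrix"))
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("package 'tiff' is required for TIFF output", call. = FALSE)
  d <- dim(mat$grid)
  # tiff uses row-major images; store slice z as an n_y x n_x image so that
  # pixel (row j, col i) is voxel (i, j, z)
  pages <- lapply(seq_len(d[3]), function(z) t(mat$grid[, , z]) * 1.0)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  sidecar <- list(shape = d, voxel_size = mat$voxel_size,
                  provenance = mat$provenance)
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a conductive matrix from a TIFF stack
#'
#' Accepts a multi-page TIFF written by [write_matrix_tiff()] (any pixel
#' value > 0.5 counts as conductive). Voxel size and provenance are taken
#' from the JSON sidecar when present.
#'
#' @param path TIFF path.
#' @return A [conductive_matrix].
#' @export
read_matrix_tiff <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("package 'tiff' is required for TIFF input", call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) if (length(dim(p)) == 3L) p[, , 1] else p)
  d <- dim(pages[[1]])
  grid <- array(FALSE, dim = c(d[2], d[1], length(pages)))
  for (z in seq_along(pages)) grid[, , z] <- t(pages[[z]] > 0.5)
  voxel_size <- c(0.22, 0.22, 4)
  provenance <- "loaded"
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(meta$voxel_size)) voxel_size <- meta$voxel_size
  }
  conductive_matrix(grid, voxel_size = voxel_size, provenance = provenance)
}

#' Read an RGB stack from a directory of PNG slices
#'
#' Slices are ordered by file name. Each PNG must be an RGB (or RGBA)
#' image; all slices must share one size.
#'
#' @param dir Directory containing the per-slice PNG files.
#' @param voxel_size Physical voxel size metadata.
#' @return An [image_stack].
#' @export
read_stack_png <- function(dir, voxel_size = c(0.22, 0.22, 4)) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("package 'png' is required for PNG input", call. = FALSE)
  files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  if (length(files) == 0L) stop("no PNG slices found in ", dir, call. = FALSE)
  slices <- lapply(files, png::readPNG)
  d <- dim(slices[[1]])
  if (length(d) != 3L || d[3] < 3L)
    stop("PNG slices must be RGB images", call. = FALSE)
  if (!all(vapply(slices, function(s) identical(dim(s)[1:2], d[1:2]), TRUE)))
    stop("PNG slices differ in size (ragged stack)", call. = FALSE)
  m <- length(slices)
  mk <- function(ch) {
    a <- array(0L, dim = c(d[2], d[1], m))
    for (z in seq_len(m)) a[, , z] <- as.integer(round(t(slices[[z]][, , ch]) * 255))
    a
  }
  image_stack(mk(1), mk(2), mk(3), voxel_size = voxel_size)
}
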