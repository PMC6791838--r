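#' 3D image volume with voxel spacing
#'
#' A `volume` wraps a 3D array indexed `(z, y, x)` together with the voxel
#' spacing `(dz, dy, dx)` in millimetres. Grayscale volumes hold values in
#' `[0, 255]` (numeric or integer); binary volumes hold logicals. The world
#' coordinate of voxel `(k, j, i)` (1-based) is
#' `((i-1)*dx, (j-1)*dy, (k-1)*dz)` mm, so all geometric thresholds
#' downstream are honoured under anisotropic spacing.
#'
#' @param data 3D array (z, y, x): logical for binary volumes, numeric in
#'   `[0, 255]` for grayscale.
#' @param spacing numeric length-3 `(dz, dy, dx)` in mm, all strictly
#'   positive.
#' @return An object of class `volume`.
#' @examples
#' v <- volume(array(0, dim = c(4, 8, 8)), spacing = c(0.1, 0.5, 0.5))
#' dim(v)
#' @export
volume <- function(data, spacing) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("data must be a 3D array indexed (z, y, x)")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three strictly positive values (dz, dy, dx) in mm")
  if (!is.logical(data)) {
    rng <- suppressWarnings(range(data, na.rm = TRUE))
    if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 255))
      stop("grayscale values must lie in [0, 255]")
  }
  structure(list(data = data, spacing = spacing), class = "volume")
}

#' @export
dim.volume <- function(x) dim(x$data)

#' @export
print.volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume> %s, %d x %d x %d voxels (z y x), spacing %s mm\n",
              if (is.logical(x$data)) "binary" else "grayscale",
              d[1], d[2], d[3],
              paste(format(x$spacing), collapse = " x ")))
  invisible(x)
}

is_binary_volume <- function(v) inherits(v, "volume") && is.logical(v$data)

stopifnot_volume <- function(v, binary = NA) {
  if (!inherits(v, "volume")) stop("expected a volume object")
  if (isTRUE(binary) && !is.logical(v$data))
    stop("expected a binary volume")
  if (isFALSE(binary) && is.logical(v$data))
    stop("expected a grayscale volume")
  invisible(v)
}

# world coordinates (x, y, z) mm of 1-based voxel indices (k, j, i)
voxel_to_mm <- function(kji, spacing) {
  kji <- if (is.matrix(kji)) kji else matrix(kji, ncol = 3)
  cbind(x = (kji[, 3] - 1) * spacing[3],
        y = (kji[, 2] - 1) * spacing[2],
        z = (kji[, 1] - 1) * spacing[1])
}

# nearest 1-based voxel indices (k, j, i) of world points (x, y, z) mm
mm_to_voxel <- function(xyz, spacing, dims) {
  xyz <- if (is.matrix(xyz)) xyz else matrix(xyz, ncol = 3)
  k <- pmin(pmax(round(xyz[, 3] / spacing[1]) + 1, 1), dims[1])
  j <- pmin(pmax(round(xyz[, 2] / spacing[2]) + 1, 1), dims[2])
  i <- pmin(pmax(round(xyz[, 1] / spacing[3]) + 1, 1), dims[3])
  cbind(k = k, j = j, i = i)
}

sort_slice_files <- function(files) {
  # numeric-aware ordering: sort by trailing number when every name has one
  num <- suppressWarnings(as.numeric(sub("^.*?(\\d+)\\D*$", "\\1", basename(files))))
  if (!anyNA(num)) files[order(num, basename(files))] else files[order(basename(files))]
}

read_slice <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path, as.is = TRUE)
  } else if (ext == "png") {
    img <- png::readPNG(path)
    img <- round(img * 255)
  } else stop("unsupported slice format: ", path)
  if (length(dim(img)) == 3L) {
    warning("multi-channel slice ", basename(path), ": using first channel")
    img <- img[, , 1]
  }
  if (max(img) > 255) {
    warning("slice ", basename(path), " exceeds 8-bit range; rescaling to [0, 255]")
    img <- img / max(img) * 255
  }
  img
}

#' Read an image stack into a volume
#'
#' Reads either a multi-page TIFF or a directory of equally sized 2D slices
#' (TIFF or PNG), stacking slices along z in page order or numeric-aware
#' filename order. Spacing is supplied by the caller, not parsed from TIFF
#' tags (such tags are frequently absent or wrong); if resolution tags are
#' present and disagree with the supplied in-plane spacing, a warning is
#' issued. Bit depths above 8 are rescaled to `[0, 255]` with a warning.
#'
#' @param path multi-page TIFF file or directory of slice images.
#' @param spacing voxel spacing `(dz, dy, dx)` in mm.
#' @return A grayscale [volume].
#' @export
read_stack <- function(path, spacing) {
  if (!file.exists(path)) stop("no such path: ", path)
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.(tif|tiff|png)$", ignore.case = TRUE,
                        full.names = TRUE)
    if (length(files) == 0) stop("no TIFF/PNG slices found in ", path)
    files <- sort_slice_files(files)
    slices <- lapply(files, read_slice)
  } else {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    check_resolution_tags(pages[[1]], spacing)
    slices <- lapply(pages, function(img) {
      if (length(dim(img)) == 3L) img <- img[, , 1]
      if (max(img) > 255) {
        warning("TIFF page exceeds 8-bit range; rescaling to [0, 255]")
        img <- img / max(img) * 255
      }
      img
    })
  }
  dims <- vapply(slices, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("inconsistent slice dimensions across the stack")
  arr <- array(0, dim = c(length(slices), dims[1, 1], dims[2, 1]))
  for (k in seq_along(slices)) arr[k, , ] <- slices[[k]]
  volume(arr, spacing)
}

check_resolution_tags <- function(page, spacing) {
  xres <- attr(page, "x.resolution")
  unit <- attr(page, "resolution.unit")
  if (is.null(xres) || is.null(unit) || !is.numeric(xres) || xres <= 0)
    return(invisible(NULL))
  per_mm <- switch(as.character(unit), inch = xres / 25.4, cm = xres / 10, NULL)
  if (!is.null(per_mm) && abs(1 / per_mm - spacing[3]) > 0.05 * spacing[3])
    warning(sprintf(
      "TIFF resolution tag implies %.4g mm in-plane spacing but %.4g mm was supplied; using the supplied value",
      1 / per_mm, spacing[3]))
  invisible(NULL)
}

#' Write a volume as a multi-page TIFF
#'
#' Binary volumes are stored as 0/255 8-bit images for viewer compatibility;
#' grayscale volumes are rounded to 8-bit. The result round-trips through
#' [read_stack()] (binary content is recovered by thresholding at 128).
#'
#' @param v a [volume].
#' @param path output file path.
#' @export
write_stack <- function(v, path) {
  stopifnot_volume(v)
  dat <- v$data
  if (is.logical(dat)) dat <- dat * 255
  dat <- round(dat)
  pages <- lapply(seq_len(dim(dat)[1]), function(k) dat[k, , ] / 255)
  ok <- try(tiff::writeTIFF(pages, path, bits.per.sample = 8L), silent = TRUE)
  if (inherits(ok, "try-error")) stop("cannot write TIFF to ", path)
  invisible(path)
}

branch_table_columns <- c("branch_id", "length_mm", "median_thickness_mm",
                          "n_points", "n_contacts", "horizontal_angle_deg",
                          "scaffold_flag")

#' Validate a per-branch summary table
#'
#' Checks the column contract of the per-branch table: unique ids, positive
#' lengths, non-negative thicknesses, horizontal angles in `[0, 90]`.
#'
#' @param table data.frame with columns `branch_id`, `length_mm`,
#'   `median_thickness_mm`, `n_points`, `n_contacts`,
#'   `horizontal_angle_deg`, `scaffold_flag`.
#' @return The table, invisibly; errors describe the violated constraint.
#' @export
validate_branch_table <- function(table) {
  missing <- setdiff(branch_table_columns, names(table))
  if (length(missing)) stop("branch table misses columns: ",
                            paste(missing, collapse = ", "))
  if (anyDuplicated(table$branch_id)) stop("branch_id values must be unique")
  if (nrow(table)) {
    if (any(table$length_mm <= 0)) stop("length_mm must be > 0")
    if (any(table$median_thickness_mm < 0)) stop("median_thickness_mm must be >= 0")
    if (any(table$horizontal_angle_deg < 0 | table$horizontal_angle_deg > 90))
      stop("horizontal_angle_deg must lie in [0, 90]")
  }
  invisible(table)
}

#' Write / read the per-branch table as CSV
#'
#' Plain CSV with a header row; numeric values round-trip losslessly well
#' below 1e-6 mm.
#'
#' @param table a valid branch table (see [validate_branch_table()]).
#' @param path CSV file path.
#' @export
write_branch_table <- function(table, path) {
  validate_branch_table(table)
  write.csv(table[, branch_table_columns, drop = FALSE], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_branch_table
#' @export
read_branch_table <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  if (nrow(tab)) tab$scaffold_flag <- as.logical(tab$scaffold_flag)
  else tab$scaffold_flag <- logical(0)
  validate_branch_table(tab)
  tab
}
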