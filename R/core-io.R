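#' Construct a 4-D BOLD object
#'
#' Container for one subject's resting-state BOLD run on an X x Y x Z voxel
#' grid over T time points, plus the spatial metadata every downstream
#' operation needs (voxel size, repetition time, voxel-to-mm affine).
#'
#' @param data numeric 4-D array (X, Y, Z, T); all values finite, T >= 2.
#' @param voxel_size_mm length-3 positive numeric, voxel edge lengths in mm.
#' @param tr_s repetition time in seconds (> 0).
#' @param affine 4 x 4 voxel-to-mm matrix (NIfTI convention, 0-based voxel
#'   offsets). Defaults to a diagonal scaling by `voxel_size_mm`.
#' @param subject_id character subject identifier.
#' @return An object of class `bold4d`.
#' @export
bold4d <- function(data, voxel_size_mm, tr_s, affine = NULL,
                   subject_id = "subject") {
  data <- unclass(data)
  attributes(data) <- list(dim = dim(data))
  if (length(dim(data)) != 4L) stop("expected 4-D data, got ",
                                    length(dim(data)), "-D")
  if (dim(data)[4] < 2L) stop("need T >= 2 time points")
  if (!all(is.finite(data))) stop("non-finite values in BOLD data")
  voxel_size_mm <- rep_len(as.numeric(voxel_size_mm), 3L)
  if (any(voxel_size_mm <= 0)) stop("voxel_size_mm must be positive")
  if (!is.numeric(tr_s) || length(tr_s) != 1L || tr_s <= 0)
    stop("tr_s must be a positive scalar (header pixdim[4])")
  if (is.null(affine)) affine <- diag(c(voxel_size_mm, 1))
  stopifnot(all(dim(affine) == c(4L, 4L)))
  structure(list(data = data, voxel_size_mm = voxel_size_mm, tr_s = tr_s,
                 affine = affine, subject_id = as.character(subject_id)),
            class = "bold4d")
}

#' @export
print.bold4d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<bold4d> %s: %d x %d x %d grid, %d volumes, TR = %g s\n",
              x$subject_id, d[1], d[2], d[3], d[4], x$tr_s))
  invisible(x)
}

#' @export
dim.bold4d <- function(x) dim(x$data)

#' Construct a brain-mask volume
#'
#' @param data logical/numeric 3-D array; nonzero entries are in-mask.
#' @param affine 4 x 4 voxel-to-mm matrix.
#' @return An object of class `mask_volume` (logical 3-D array + affine).
#' @export
mask_volume <- function(data, affine = NULL) {
  if (length(dim(data)) != 3L) stop("mask must be 3-D")
  m <- array(data != 0, dim = dim(data))
  if (!any(m)) stop("mask is empty (no nonzero voxels)")
  if (is.null(affine)) affine <- diag(4)
  structure(list(data = m, affine = affine), class = "mask_volume")
}

#' @export
print.mask_volume <- function(x, ...) {
  cat(sprintf("<mask_volume> %s grid, %d in-mask voxels\n",
              paste(dim(x$data), collapse = " x "), sum(x$data)))
  invisible(x)
}

#' @export
dim.mask_volume <- function(x) dim(x$data)

nifti_header_for <- function(voxel_size_mm, tr_s, affine) {
  list(pixdim = c(-1, voxel_size_mm, tr_s, 0, 0, 0),
       srow_x = affine[1, ], srow_y = affine[2, ], srow_z = affine[3, ],
       sform_code = 2L, xyzt_units = 10L)  # mm + seconds
}

#' Read a 4-D BOLD NIfTI file
#'
#' The repetition time is taken from the NIfTI header time-axis spacing
#' (`pixdim[4]`); an explicit `tr_s` argument overrides the header, since
#' many writers leave that field wrong.
#'
#' @param path NIfTI-1/NIfTI-2 file (`.nii` or `.nii.gz`).
#' @param subject_id subject identifier; defaults to the file stem.
#' @param tr_s optional repetition-time override in seconds.
#' @return A [bold4d()] object.
#' @export
read_bold4d <- function(path, subject_id = NULL, tr_s = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L) stop("expected 4-D BOLD volume, got ", length(d),
                            "-D: ", path)
  pd <- RNifti::pixdim(img)
  tr <- tr_s %||% (if (length(pd) >= 4) pd[4] else 0)
  if (!is.finite(tr) || tr <= 0)
    stop("repetition time missing or zero in NIfTI header field pixdim[4]; ",
         "pass tr_s explicitly")
  if (is.null(subject_id))
    subject_id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))
  bold4d(arr, voxel_size_mm = pd[1:3], tr_s = tr,
         affine = RNifti::xform(img), subject_id = subject_id)
}

#' Write a 4-D BOLD object as NIfTI-1
#'
#' @param bold a [bold4d()] object.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_bold4d <- function(bold, path) {
  stopifnot(inherits(bold, "bold4d"))
  hdr <- nifti_header_for(bold$voxel_size_mm, bold$tr_s, bold$affine)
  img <- RNifti::asNifti(bold$data, hdr)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a brain mask and check it against a reference grid
#'
#' @param path 3-D NIfTI file; nonzero voxels become in-mask.
#' @param reference optional [bold4d()] (or 3-D dims) whose spatial grid the
#'   mask must match.
#' @return A [mask_volume()].
#' @export
read_mask <- function(path, reference = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) { img <- img[, , , 1]; d <- dim(img) }
  if (length(d) != 3L) stop("mask must be 3-D: ", path)
  if (!is.null(reference)) {
    ref_dims <- if (inherits(reference, "bold4d")) dim(reference$data)[1:3]
                else reference[1:3]
    if (!all(d == ref_dims))
      stop("mask dims (", paste(d, collapse = "x"),
           ") do not match reference (", paste(ref_dims, collapse = "x"), ")")
  }
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))
  mask_volume(arr, affine = RNifti::xform(img))
}

#' Write a mask volume as NIfTI-1
#' @param mask a [mask_volume()].
#' @param path output path.
#' @param voxel_size_mm voxel size written to the header.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path, voxel_size_mm = c(1, 1, 1)) {
  stopifnot(inherits(mask, "mask_volume"))
  hdr <- list(pixdim = c(-1, rep_len(voxel_size_mm, 3), 1, 0, 0, 0),
              srow_x = mask$affine[1, ], srow_y = mask$affine[2, ],
              srow_z = mask$affine[3, ], sform_code = 2L, xyzt_units = 10L)
  img <- RNifti::asNifti(array(as.integer(mask$data), dim = dim(mask$data)),
                         hdr)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Define a seed region
#'
#' A seed is either an explicit mask volume, a sphere around an mm
#' coordinate (resolved through the mask's affine), or a sphere around a
#' 1-based voxel coordinate (radius in voxel units).
#'
#' @param name seed name, used to label the resulting connectivity measure
#'   (e.g. `"LeftPCu"`).
#' @param mask optional [mask_volume()] giving the seed explicitly.
#' @param center_mm optional length-3 mm coordinate of the sphere centre.
#' @param radius_mm sphere radius in mm (default 6).
#' @param center_vox optional length-3 1-based voxel coordinate.
#' @param radius_vox sphere radius in voxel units (used with `center_vox`).
#' @return An object of class `seed_spec`.
#' @export
seed_spec <- function(name, mask = NULL, center_mm = NULL, radius_mm = 6,
                      center_vox = NULL, radius_vox = NULL) {
  n_def <- sum(!is.null(mask), !is.null(center_mm), !is.null(center_vox))
  if (n_def != 1L)
    stop("seed_spec needs exactly one of mask, center_mm, center_vox")
  structure(list(name = as.character(name), mask = mask,
                 center_mm = center_mm, radius_mm = radius_mm,
                 center_vox = center_vox, radius_vox = radius_vox),
            class = "seed_spec")
}

# mm coordinates of all voxel centres of a grid (0-based voxel offsets
# through the affine, matching the NIfTI convention)
voxel_centers_mm <- function(dims, affine) {
  g <- as.matrix(expand.grid(i = seq_len(dims[1]) - 1,
                             j = seq_len(dims[2]) - 1,
                             k = seq_len(dims[3]) - 1))
  t(affine %*% t(cbind(g, 1)))[, 1:3, drop = FALSE]
}

#' Resolve a seed definition to an in-mask voxel set
#'
#' Sphere definitions include every voxel whose centre lies within the
#' radius of the given coordinate; the result is intersected with the brain
#' mask and must be non-empty.
#'
#' @param spec a [seed_spec()].
#' @param mask the brain [mask_volume()].
#' @return A [mask_volume()] with the resolved seed voxels.
#' @export
resolve_seed <- function(spec, mask) {
  stopifnot(inherits(spec, "seed_spec"), inherits(mask, "mask_volume"))
  dims <- dim(mask$data)
  if (!is.null(spec$mask)) {
    if (!all(dim(spec$mask$data) == dims))
      stop("seed mask dims do not match brain mask")
    sel <- spec$mask$data & mask$data
  } else if (!is.null(spec$center_vox)) {
    r <- spec$radius_vox %||% spec$radius_mm
    g <- expand.grid(i = seq_len(dims[1]), j = seq_len(dims[2]),
                     k = seq_len(dims[3]))
    d2 <- (g$i - spec$center_vox[1])^2 + (g$j - spec$center_vox[2])^2 +
      (g$k - spec$center_vox[3])^2
    sel <- array(d2 <= r^2 + 1e-9, dim = dims) & mask$data
  } else {
    mm <- voxel_centers_mm(dims, mask$affine)
    d2 <- colSums((t(mm) - spec$center_mm)^2)
    sel <- array(d2 <= spec$radius_mm^2 + 1e-9, dim = dims) & mask$data
  }
  if (!any(sel))
    stop("seed '", spec$name, "' contains no in-mask voxels")
  mask_volume(sel, affine = mask$affine)
}

#' Read a cohort manifest
#'
#' A manifest is a CSV with columns `subject_id`, `label` (0/1) and `path`
#' (NIfTI file per subject), as written by [generate_cohort()].
#'
#' @param path CSV file.
#' @return A tibble with the three columns.
#' @export
read_manifest <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "label", "path")
  if (!all(need %in% names(df)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  tibble::as_tibble(df[need])
}
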