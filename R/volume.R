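#' 3-D image volume with voxel spacing
#'
#' Lightweight container for a scalar 3-D grid plus the physical metadata the
#' preprocessing chain needs: per-axis voxel spacing (mm) and origin (mm,
#' position of the first voxel centre). A `channel` tag identifies the MR
#' series (`"CET1"` or `"T2"`) and a `filter` tag tracks what has been applied
#' (`"original"` or `"log-sigma-<s>-0"`).
#'
#' @param data numeric 3-D array.
#' @param spacing numeric length-3, voxel spacing in mm (> 0).
#' @param origin numeric length-3, physical position of voxel (1,1,1) in mm.
#' @param channel series tag, e.g. `"CET1"`.
#' @param filter filter tag, `"original"` unless a filter has been applied.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(data, spacing, origin = c(0, 0, 0),
                         channel = "CET1", filter = "original") {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three positive finite values (mm)")
  structure(
    list(data = data, spacing = spacing, origin = as.numeric(origin),
         channel = channel, filter = filter),
    class = "image_volume"
  )
}

#' Binary ROI mask on an image grid
#'
#' @param data logical (or 0/1) 3-D array, same dimensions as its image.
#' @param spacing voxel spacing in mm.
#' @param origin physical position of voxel (1,1,1) in mm.
#' @param role `"tumor"` (GTVnp) or `"reference"` (brainstem surrogate).
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(data, spacing, origin = c(0, 0, 0), role = "tumor") {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-D array")
  storage.mode(data) <- "logical"
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three positive finite values (mm)")
  structure(
    list(data = data, spacing = spacing, origin = as.numeric(origin),
         role = role),
    class = "roi_mask"
  )
}

#' @exportS3Method base::print
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume> %s [%s] %s voxels, spacing %s mm\n",
              x$channel, x$filter, paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing), collapse = "x")))
  invisible(x)
}

#' @exportS3Method base::print
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> role=%s, %d voxels set, spacing %s mm\n",
              x$role, sum(x$data), paste(format(x$spacing), collapse = "x")))
  invisible(x)
}

#' @export
dim.image_volume <- function(x) dim(x$data)

#' @export
dim.roi_mask <- function(x) dim(x$data)

#' Number of voxels inside a mask
#' @param mask a [roi_mask()].
#' @return integer voxel count.
#' @export
mask_size <- function(mask) sum(mask$data)

#' Physical volume of one voxel in mm^3
#' @param x an [image_volume()] or [roi_mask()].
#' @return voxel volume in mm^3.
#' @export
voxel_volume <- function(x) prod(x$spacing)

.same_grid <- function(img, mask) {
  identical(dim(img$data), dim(mask$data)) &&
    isTRUE(all.equal(img$spacing, mask$spacing, tolerance = 1e-8))
}

.check_grid <- function(img, mask) {
  if (!.same_grid(img, mask))
    stop("image and mask are not on the same grid")
  invisible(TRUE)
}

#' Write a volume or mask to NIfTI
#'
#' @param x an [image_volume()] or [roi_mask()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_nifti_volume <- function(x, path) {
  dat <- x$data
  if (is.logical(dat)) storage.mode(dat) <- "integer"
  img <- RNifti::asNifti(dat)
  RNifti::pixdim(img) <- x$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI file as an image volume or ROI mask
#'
#' @param path NIfTI file path.
#' @param as `"image"` or `"mask"`.
#' @param channel,filter,role metadata tags for the returned object.
#' @return An [image_volume()] or [roi_mask()].
#' @export
read_nifti_volume <- function(path, as = c("image", "mask"),
                              channel = "CET1", filter = "original",
                              role = "tumor") {
  as <- match.arg(as)
  img <- RNifti::readNifti(path)
  spacing <- RNifti::pixdim(img)[seq_len(3)]
  dat <- array(as.numeric(img), dim = dim(img)[seq_len(3)])
  if (as == "image")
    image_volume(dat, spacing, channel = channel, filter = filter)
  else
    roi_mask(dat > 0.5, spacing, role = role)
}
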