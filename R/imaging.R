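# Volume standardization and ROI-to-patch preprocessing for the deep-feature
# pathway. Grids are indexed (slice, row, column), 1-based in R; spacing is
# stored in the same axis order, in mm.

#' CT image volume
#'
#' @param intensities 3D numeric array of HU values, indexed
#'   (slice, row, column).
#' @param spacing positive numeric length-3, mm per voxel per axis.
#' @param origin physical offset in mm.
#' @return an `image_volume` object.
#' @export
image_volume <- function(intensities, spacing, origin = c(0, 0, 0)) {
  if (!is.array(intensities) || length(dim(intensities)) != 3L) {
    stop("`intensities` must be a 3D array", call. = FALSE)
  }
  if (length(spacing) != 3L || any(spacing <= 0)) {
    stop("`spacing` must be three positive values", call. = FALSE)
  }
  structure(list(intensities = intensities, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("image_volume %s, spacing %s mm, HU range [%.1f, %.1f]\n",
              paste(dim(x$intensities), collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              min(x$intensities), max(x$intensities)))
  invisible(x)
}

#' Binary region-of-interest mask
#'
#' @param mask logical/0-1 3D array aligned with its volume; values > 0 are
#'   foreground.
#' @param kind lesion kind, `"tumor"` or `"lymph_node"`.
#' @return a `roi_mask` object.
#' @export
roi_mask <- function(mask, kind = c("lymph_node", "tumor")) {
  kind <- match.arg(kind)
  if (!is.array(mask) || length(dim(mask)) != 3L) {
    stop("`mask` must be a 3D array", call. = FALSE)
  }
  m <- mask > 0
  if (!any(m)) stop("mask has no foreground voxel", call. = FALSE)
  structure(list(mask = m, kind = kind), class = "roi_mask")
}

#' Default imaging configuration
#'
#' Target voxel spacing 1 x 1 x 5 mm (in (row, column, slice) physical terms,
#' stored here in (slice, row, column) order), mediastinal window
#' (width 350 HU, level 40 HU), 224-pixel patches, 2-voxel in-plane dilation.
#' @return named list of imaging constants.
#' @export
imaging_config <- function() {
  list(target_spacing = c(5, 1, 1), window_width = 350, window_level = 40,
       patch_size = 224L, dilation_voxels = 2)
}

# cubic-spline interpolation of a vector sampled at `xs` onto `xt`
spline_axis <- function(y, xs, xt) {
  stats::splinefun(xs, y, method = "natural")(xt)
}

#' Resample a volume to a target voxel spacing
#'
#' Standardizes voxel size via separable cubic-spline interpolation,
#' preserving the physical extent to within one voxel. A degenerate axis
#' (single voxel) is extended as constant.
#'
#' @param volume an [image_volume()].
#' @param target_spacing positive numeric length-3 (mm), axis order
#'   (slice, row, column).
#' @return a resampled [image_volume()].
#' @export
resample_volume <- function(volume, target_spacing) {
  stopifnot(inherits(volume, "image_volume"))
  if (length(target_spacing) != 3L || any(target_spacing <= 0)) {
    stop("`target_spacing` must be three positive values", call. = FALSE)
  }
  arr <- volume$intensities
  sp <- volume$spacing
  for (ax in 1:3) {
    n <- dim(arr)[ax]
    if (sp[ax] == target_spacing[ax]) next
    if (n == 1L) next  # constant extension: single-sample axis keeps its value
    extent <- (n - 1) * sp[ax]
    n_new <- max(1L, as.integer(round(extent / target_spacing[ax])) + 1L)
    xs <- (seq_len(n) - 1) * sp[ax]
    xt <- (seq_len(n_new) - 1) * target_spacing[ax]
    arr <- apply_along_axis(arr, ax, function(y) spline_axis(y, xs, xt), n_new)
  }
  image_volume(arr, target_spacing, volume$origin)
}

# Apply f (vector length n -> length n_out) along axis `ax` of a 3D array.
apply_along_axis <- function(arr, ax, f, n_out) {
  d <- dim(arr)
  perm <- c(ax, setdiff(1:3, ax))
  m <- matrix(aperm(arr, perm), nrow = d[ax])
  out <- vapply(seq_len(ncol(m)), function(j) f(m[, j]), numeric(n_out))
  out <- array(t(out), dim = c(d[perm][2:3], n_out))
  aperm(out, order(c(perm[2:3], ax)))
}

#' Select the key slice triplet for patch extraction
#'
#' Returns the slice with the largest ROI cross-sectional area together with
#' its immediate neighbours; at volume boundaries the window is shifted
#' inward so three valid contiguous indices are returned. Area ties go to
#' the lowest slice index.
#'
#' @param mask an [roi_mask()].
#' @return integer vector of three contiguous slice indices (1-based).
#' @export
select_key_slices <- function(mask) {
  stopifnot(inherits(mask, "roi_mask"))
  areas <- apply(mask$mask, 1L, sum)
  n <- length(areas)
  i <- which.max(areas)  # first maximum = lowest index on ties
  if (n < 3L) return(pmin(pmax(c(i - 1L, i, i + 1L), 1L), n))
  lo <- min(max(i - 1L, 1L), n - 2L)
  lo + 0:2
}

#' In-plane morphological dilation of an ROI
#'
#' Dilates each slice independently with a Euclidean disk (offsets with
#' dx^2 + dy^2 <= radius^2); there is no growth across slices.
#'
#' @param mask an [roi_mask()].
#' @param radius_voxels disk radius in voxels (default 2).
#' @return a dilated [roi_mask()]; the result always contains the input.
#' @export
dilate_roi_2d <- function(mask, radius_voxels = 2) {
  stopifnot(inherits(mask, "roi_mask"))
  m <- mask$mask
  d <- dim(m)
  out <- m
  r <- radius_voxels
  for (dx in -floor(r):floor(r)) {
    for (dy in -floor(r):floor(r)) {
      if (dx == 0 && dy == 0) next
      if (dx * dx + dy * dy > r * r) next
      src_r <- seq_len(d[2L]) - dx
      src_c <- seq_len(d[3L]) - dy
      ok_r <- src_r >= 1L & src_r <= d[2L]
      ok_c <- src_c >= 1L & src_c <= d[3L]
      out[, ok_r, ok_c] <- out[, ok_r, ok_c, drop = FALSE] |
        m[, src_r[ok_r], src_c[ok_c], drop = FALSE]
    }
  }
  structure(list(mask = out, kind = mask$kind), class = "roi_mask")
}

# bilinear resize with corner alignment
resize_bilinear <- function(mat, nr, nc) {
  r_in <- nrow(mat); c_in <- ncol(mat)
  rx <- if (r_in == 1L) rep(1, nr) else 1 + (seq_len(nr) - 1) * (r_in - 1) / (nr - 1)
  cx <- if (c_in == 1L) rep(1, nc) else 1 + (seq_len(nc) - 1) * (c_in - 1) / (nc - 1)
  r0 <- pmin(floor(rx), r_in - 1L); r0[r_in == 1L] <- 1L
  c0 <- pmin(floor(cx), c_in - 1L); c0[c_in == 1L] <- 1L
  if (r_in == 1L) r0 <- rep(1L, nr)
  if (c_in == 1L) c0 <- rep(1L, nc)
  fr <- rx - r0; fc <- cx - c0
  r1 <- pmin(r0 + 1L, r_in); c1 <- pmin(c0 + 1L, c_in)
  a <- mat[r0, c0, drop = FALSE]; b <- mat[r0, c1, drop = FALSE]
  cc <- mat[r1, c0, drop = FALSE]; dd <- mat[r1, c1, drop = FALSE]
  wr <- matrix(fr, nr, nc); wc <- matrix(fc, nr, nc, byrow = TRUE)
  a * (1 - wr) * (1 - wc) + b * (1 - wr) * wc + cc * wr * (1 - wc) + dd * wr * wc
}

#' Extract a pseudo-3-channel patch around a lesion
#'
#' Crops the tight bounding box of the dilated mask on the central key slice,
#' applies that box to all three key slices, suppresses voxels outside the
#' dilated mask to the window floor, clips intensities to the mediastinal
#' window `[L - W/2, L + W/2]`, min-max scales the window range to `[0, 1]`,
#' and resizes bilinearly to `size x size`.
#'
#' @param volume an [image_volume()].
#' @param dilated_mask an [roi_mask()] (typically from [dilate_roi_2d()]).
#' @param key_slices integer triplet from [select_key_slices()].
#' @param size output spatial size (default 224).
#' @param window c(width, level) in HU (default c(350, 40)).
#' @param suppress_background set out-of-mask voxels to the window floor
#'   (default TRUE).
#' @return a `patch_triplet`: array `(3, size, size)` in `[0, 1]` plus the
#'   slice indices used.
#' @export
extract_patch <- function(volume, dilated_mask, key_slices, size = 224L,
                          window = c(350, 40), suppress_background = TRUE) {
  stopifnot(inherits(volume, "image_volume"), inherits(dilated_mask, "roi_mask"))
  W <- window[1L]; L <- window[2L]
  lo <- L - W / 2; hi <- L + W / 2
  central <- dilated_mask$mask[key_slices[2L], , ]
  if (!any(central)) stop("mask empty on the central key slice", call. = FALSE)
  rr <- range(which(rowSums(central) > 0))
  cr <- range(which(colSums(central) > 0))
  if (diff(rr) < 0 || diff(cr) < 0) stop("zero-area bounding box", call. = FALSE)
  out <- array(0, dim = c(3L, size, size))
  for (ch in 1:3) {
    sl <- volume$intensities[key_slices[ch], rr[1L]:rr[2L], cr[1L]:cr[2L], drop = TRUE]
    sl <- matrix(sl, rr[2L] - rr[1L] + 1L, cr[2L] - cr[1L] + 1L)
    if (suppress_background) {
      msl <- matrix(dilated_mask$mask[key_slices[ch], rr[1L]:rr[2L], cr[1L]:cr[2L]],
                    nrow(sl), ncol(sl))
      sl[!msl] <- lo
    }
    sl <- pmin(pmax(sl, lo), hi)
    sl <- (sl - lo) / W
    out[ch, , ] <- resize_bilinear(sl, size, size)
  }
  structure(list(channels = out, slices = key_slices, window = window),
            class = "patch_triplet")
}

#' Read / write NIfTI volumes and masks
#'
#' Thin wrappers over the RNifti reader; arrays are reoriented so that axis 1
#' is the slice axis, matching the package's (slice, row, column) convention.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @return [read_volume()] returns an [image_volume()]; [read_mask()] an
#'   [roi_mask()].
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)
  arr <- aperm(array(as.numeric(img), dim = dim(img)), c(3L, 1L, 2L))
  image_volume(arr, spacing = sp[c(3L, 1L, 2L)])
}

#' @rdname read_volume
#' @param kind lesion kind for the mask.
#' @export
read_mask <- function(path, kind = "lymph_node") {
  v <- read_volume(path)
  roi_mask(v$intensities > 0, kind = kind)
}

#' @rdname read_volume
#' @param volume an [image_volume()] to write.
#' @export
write_volume <- function(volume, path) {
  arr <- aperm(volume$intensities, c(2L, 3L, 1L))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- volume$spacing[c(2L, 3L, 1L)]
  RNifti::writeNifti(img, path)
  invisible(path)
}
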