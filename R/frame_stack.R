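#' Image stack with per-frame roles and timestamps
#'
#' Container for an acquired or simulated movie: a 3-D array of count
#' images, strictly increasing timestamps, one protocol role per frame
#' (`"pre-bleach"`, `"post-bleach"`, `"recovery"`, ...), and the bleached
#' rectangle in pixel coordinates.
#'
#' @param frames 3-D array `rows x cols x n_frames` of camera counts.
#' @param timestamps numeric vector, seconds, strictly increasing.
#' @param roles character vector of frame roles.
#' @param bleach_region integer vector `c(row_min, row_max, col_min,
#'   col_max)` (inclusive, 1-based), inside the field of view.
#' @param camera the [camera_model()] the frames were acquired with.
#' @param metadata free-form list (simulation ground truth, warnings,
#'   `bleach_end` time in seconds, ...).
#' @return An object of class `frame_stack`.
#' @export
frame_stack <- function(frames, timestamps, roles, bleach_region, camera,
                        metadata = list()) {
  stopifnot(is.array(frames), length(dim(frames)) == 3,
            inherits(camera, "camera_model"))
  nf <- dim(frames)[3]
  stopifnot(length(timestamps) == nf, length(roles) == nf)
  if (any(diff(timestamps) <= 0)) stop("timestamps must be strictly increasing")
  br <- as.integer(bleach_region)
  if (length(br) != 4 || br[1] < 1 || br[3] < 1 ||
      br[2] > dim(frames)[1] || br[4] > dim(frames)[2] ||
      br[1] > br[2] || br[3] > br[4]) {
    stop("bleach_region must be c(row_min, row_max, col_min, col_max) inside the field of view")
  }
  structure(
    list(frames = frames, timestamps = as.numeric(timestamps),
         roles = as.character(roles), bleach_region = br,
         camera = camera, metadata = metadata),
    class = "frame_stack"
  )
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<frame_stack> %d frames of %d x %d px | roles: %s\n",
              d[3], d[1], d[2], paste(x$roles, collapse = ", ")))
  invisible(x)
}

#' Extract frames with a given role, as photon images
#'
#' @param stack a [frame_stack()].
#' @param role role label to select.
#' @param clip clip negative photon values (default FALSE: detection and
#'   integration are unbiased on unclipped images).
#' @return List of photon matrices (possibly empty).
#' @export
stack_photons <- function(stack, role, clip = FALSE) {
  stopifnot(inherits(stack, "frame_stack"))
  idx <- which(stack$roles == role)
  lapply(idx, function(i) {
    counts_to_photons(stack$frames[, , i], stack$camera, clip = clip)
  })
}

#' Write / read a frame stack as multi-page TIFF plus JSON sidecar
#'
#' Frames are stored as 32-bit float TIFF pages scaled to `[0, 1]` by the
#' camera saturation value; timestamps, roles, bleach region, camera model
#' and metadata go to `<path>.json`.
#'
#' @param stack a [frame_stack()].
#' @param path TIFF file path (sidecar is `paste0(path, ".json")`).
#' @return `write_frame_stack`: the path, invisibly. `read_frame_stack`:
#'   the reconstructed `frame_stack`.
#' @export
write_frame_stack <- function(stack, path) {
  stopifnot(inherits(stack, "frame_stack"))
  scale <- stack$camera$saturation
  pages <- lapply(seq_len(dim(stack$frames)[3]),
                  function(i) pmin(pmax(stack$frames[, , i] / scale, 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  side <- list(
    timestamps = stack$timestamps, roles = stack$roles,
    bleach_region = stack$bleach_region,
    scale = scale,
    camera = unclass(stack$camera),
    metadata = stack$metadata
  )
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_frame_stack
#' @export
read_frame_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  cam <- do.call(camera_model, side$camera[names(side$camera) != "saturation"])
  cam$saturation <- side$camera$saturation
  frames <- array(0, c(dim(pages[[1]]), length(pages)))
  for (i in seq_along(pages)) frames[, , i] <- pages[[i]] * side$scale
  md <- side$metadata
  if (is.null(md)) md <- list()
  frame_stack(frames, side$timestamps, side$roles, side$bleach_region,
              cam, md)
}

# pixel rectangle (um) -> c(rmin, rmax, cmin, cmax), 1-based inclusive
um_rect_to_px <- function(rect_um, camera) {
  px <- camera$pixel_size
  c(floor(rect_um[1] / px) + 1, ceiling(rect_um[2] / px),
    floor(rect_um[3] / px) + 1, ceiling(rect_um[4] / px))
}
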