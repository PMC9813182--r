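#' Landmark pose dataset
#'
#' Container for per-frame landmark coordinates: an `n_frames x n_bp x d`
#' array plus an explicit missing-value mask. A landmark is always missing as
#' a whole point (all `d` coordinates); any per-axis `NA` in the input is
#' promoted to whole-point missing. The mask is authoritative: wherever it is
#' `TRUE` the coordinates are stored as `NA`.
#'
#' @param coords numeric array `n_frames x n_bp x d` (or a single pose matrix
#'   `n_bp x d`, treated as one frame). Coordinates are unitless.
#' @param mask optional logical matrix `n_frames x n_bp`; defaults to the
#'   non-finite pattern of `coords`.
#' @param point_names optional character vector of landmark names.
#' @param frame_ids optional integer frame identifiers.
#' @return An object of class `pose_dataset` with fields `coords`, `mask`,
#'   `point_names`, `frame_ids`, `d`, `n_bp`, `n_frames`.
#' @examples
#' x <- array(rnorm(2 * 4 * 3), c(2, 4, 3))
#' ds <- pose_dataset(x)
#' ds
#' @export
pose_dataset <- function(coords, mask = NULL, point_names = NULL,
                         frame_ids = NULL) {
  if (is.matrix(coords)) coords <- array(coords, c(1L, nrow(coords), ncol(coords)))
  stopifnot(is.array(coords), length(dim(coords)) == 3L)
  n <- dim(coords)[1]; n_bp <- dim(coords)[2]; d <- dim(coords)[3]
  if (!d %in% c(2L, 3L))
    ssm_stop("coordinate dimension must be 2 or 3", "ssmpose_format_error")
  if (n_bp < 3L)
    ssm_stop("at least 3 body points are required for alignment",
             "ssmpose_format_error")
  bad <- apply(!is.finite(coords), c(1, 2), any)   # per-axis NA -> whole point
  if (is.null(mask)) mask <- bad else mask <- mask | bad
  storage.mode(coords) <- "double"
  for (k in seq_len(d)) {
    slab <- coords[, , k, drop = FALSE]
    slab[mask] <- NA_real_
    coords[, , k] <- slab
  }
  if (any(!is.finite(coords[, , 1][!mask])))
    ssm_stop("non-finite coordinates outside the missing mask",
             "ssmpose_format_error")
  if (is.null(point_names)) point_names <- paste0("p", seq_len(n_bp))
  if (is.null(frame_ids)) frame_ids <- seq_len(n)
  structure(list(coords = coords, mask = mask,
                 point_names = as.character(point_names),
                 frame_ids = as.integer(frame_ids),
                 d = as.integer(d), n_bp = as.integer(n_bp),
                 n_frames = as.integer(n)),
            class = "pose_dataset")
}

#' @export
print.pose_dataset <- function(x, ...) {
  cat(sprintf("<pose_dataset> %d frames, %d points, d = %d; %d/%d points missing (%.1f%%)\n",
              x$n_frames, x$n_bp, x$d, sum(x$mask), length(x$mask),
              100 * mean(x$mask)))
  invisible(x)
}

#' @export
`[.pose_dataset` <- function(x, i, ...) {
  pose_dataset(x$coords[i, , , drop = FALSE], x$mask[i, , drop = FALSE],
               x$point_names, x$frame_ids[i])
}

# n x (d * n_bp) vectorised view (point-major), NA at masked points
dataset_matrix <- function(dataset) {
  n <- dataset$n_frames; d <- dataset$d
  out <- matrix(NA_real_, n, d * dataset$n_bp)
  for (k in seq_len(d)) out[, seq(k, ncol(out), by = d)] <- dataset$coords[, , k]
  out
}

matrix_to_dataset <- function(m, d, template = NULL) {
  n_bp <- ncol(m) / d
  coords <- array(NA_real_, c(nrow(m), n_bp, d))
  for (k in seq_len(d)) coords[, , k] <- m[, seq(k, ncol(m), by = d)]
  pose_dataset(coords,
               point_names = if (!is.null(template)) template$point_names,
               frame_ids = if (!is.null(template)) template$frame_ids)
}

pose_at <- function(dataset, i) {
  list(coords = matrix(dataset$coords[i, , ], dataset$n_bp, dataset$d),
       obs = !dataset$mask[i, ])
}

complete_frames <- function(dataset) which(rowSums(dataset$mask) == 0L)
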