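#' Read a landmark table
#'
#' Supported dialects:
#' * `long_csv`: columns `frame,point,x,y[,z]`; one row per landmark. Lossless.
#' * `wide_csv`: one row per frame; a `frame` column plus `<point>_x`,
#'   `<point>_y` (and `_z`) columns.
#' * `dlc_csv`: the DeepLabCut export — three header rows
#'   (scorer / bodyparts / coords), first column the frame index, per body
#'   part `x,y[,z]` and optionally `likelihood`. Detections whose likelihood
#'   falls below `likelihood_cutoff` are masked as missing.
#'
#' Empty cells and `NA`/`NaN` tokens become masked points; per-axis gaps are
#' promoted to whole-point missing.
#'
#' @param path file to read.
#' @param dialect one of `"long_csv"`, `"wide_csv"`, `"dlc_csv"`.
#' @param likelihood_cutoff for `dlc_csv`: mask points whose likelihood is
#'   below this value (default `NULL`, no likelihood filtering).
#' @return a [pose_dataset()].
#' @export
read_pose_table <- function(path, dialect = c("long_csv", "wide_csv", "dlc_csv"),
                            likelihood_cutoff = NULL) {
  dialect <- match.arg_dialect(dialect)
  if (!file.exists(path))
    ssm_stop(sprintf("file not found: %s", path), "ssmpose_io_error")
  switch(dialect,
         long_csv = read_long_csv(path),
         wide_csv = read_wide_csv(path),
         dlc_csv = read_dlc_csv(path, likelihood_cutoff))
}

match.arg_dialect <- function(dialect) {
  dialect <- dialect[1]
  if (identical(dialect, "hdf5"))
    ssm_stop("the hdf5 dialect is not supported in this installation (no HDF5 R bindings); use long_csv",
             "ssmpose_format_error")
  if (!dialect %in% c("long_csv", "wide_csv", "dlc_csv"))
    ssm_stop(sprintf("unsupported dialect '%s'", dialect), "ssmpose_format_error")
  dialect
}

read_long_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame", "point", "x", "y")
  if (!all(need %in% names(df)))
    ssm_stop("long_csv requires columns frame,point,x,y[,z]", "ssmpose_format_error")
  d <- if ("z" %in% names(df)) 3L else 2L
  frames <- sort(unique(df$frame))
  points <- unique(df$point)          # header order = first appearance
  per_frame <- table(df$frame)
  if (length(unique(per_frame)) > 1L)
    ssm_stop("inconsistent point counts across frames", "ssmpose_format_error")
  coords <- array(NA_real_, c(length(frames), length(points), d))
  fi <- match(df$frame, frames); pi <- match(df$point, points)
  coords[cbind(fi, pi, 1L)] <- df$x
  coords[cbind(fi, pi, 2L)] <- df$y
  if (d == 3L) coords[cbind(fi, pi, 3L)] <- df$z
  pose_dataset(coords, point_names = points, frame_ids = frames)
}

read_wide_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  cn <- names(df)
  frame_col <- which(cn == "frame")
  coord_cols <- grep("_(x|y|z)$", cn)
  if (length(coord_cols) == 0L)
    ssm_stop("wide_csv requires <point>_x/<point>_y[/z] columns", "ssmpose_format_error")
  axes <- sub("^.*_", "", cn[coord_cols])
  pts <- sub("_(x|y|z)$", "", cn[coord_cols])
  points <- unique(pts)
  d <- if ("z" %in% axes) 3L else 2L
  ax_names <- c("x", "y", "z")[seq_len(d)]
  coords <- array(NA_real_, c(nrow(df), length(points), d))
  for (p in seq_along(points)) for (k in seq_len(d)) {
    col <- paste0(points[p], "_", ax_names[k])
    if (!col %in% cn)
      ssm_stop(sprintf("wide_csv: missing column %s", col), "ssmpose_format_error")
    coords[, p, k] <- as.numeric(df[[col]])
  }
  ids <- if (length(frame_col)) as.integer(df[[frame_col]]) else seq_len(nrow(df))
  pose_dataset(coords, point_names = points, frame_ids = ids)
}

read_dlc_csv <- function(path, likelihood_cutoff = NULL) {
  hdr <- readLines(path, n = 3L)
  if (length(hdr) < 3L)
    ssm_stop("dlc_csv needs three header rows (scorer/bodyparts/coords)",
             "ssmpose_format_error")
  bodyparts <- strsplit(hdr[2], ",")[[1]][-1]
  axes <- strsplit(hdr[3], ",")[[1]][-1]
  if (length(bodyparts) != length(axes))
    ssm_stop("malformed dlc_csv header", "ssmpose_format_error")
  df <- read.csv(path, skip = 3L, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) != length(axes) + 1L)
    ssm_stop("dlc_csv data width does not match header", "ssmpose_format_error")
  points <- unique(bodyparts)
  d <- if ("z" %in% axes) 3L else 2L
  ax_names <- c("x", "y", "z")[seq_len(d)]
  n <- nrow(df)
  coords <- array(NA_real_, c(n, length(points), d))
  lik <- matrix(Inf, n, length(points))
  for (p in seq_along(points)) {
    cols <- which(bodyparts == points[p]) + 1L
    for (k in seq_len(d)) {
      j <- cols[axes[cols - 1L] == ax_names[k]]
      if (length(j) != 1L)
        ssm_stop(sprintf("dlc_csv: body part %s lacks a %s column",
                         points[p], ax_names[k]), "ssmpose_format_error")
      coords[, p, k] <- as.numeric(df[[j]])
    }
    jl <- cols[axes[cols - 1L] == "likelihood"]
    if (length(jl) == 1L) lik[, p] <- as.numeric(df[[jl]])
  }
  mask <- NULL
  if (!is.null(likelihood_cutoff)) mask <- lik < likelihood_cutoff
  pose_dataset(coords, mask = mask, point_names = points,
               frame_ids = as.integer(df[[1]]))
}

#' Write a landmark table
#'
#' `long_csv` round-trips losslessly (masked points serialize as empty cells).
#' `wide_csv` writes one row per frame. An empty dataset writes a header-only
#' file.
#'
#' @param dataset a [pose_dataset()].
#' @param path output file.
#' @param dialect `"long_csv"` or `"wide_csv"`.
#' @export
write_pose_table <- function(dataset, path, dialect = c("long_csv", "wide_csv")) {
  dialect <- match.arg_dialect(dialect)
  if (dialect == "dlc_csv")
    ssm_stop("writing the dlc_csv dialect is not supported", "ssmpose_format_error")
  d <- dataset$d
  ax <- c("x", "y", "z")[seq_len(d)]
  if (dialect == "long_csv") {
    n <- dataset$n_frames
    df <- data.frame(
      frame = rep(dataset$frame_ids, each = dataset$n_bp),
      point = rep(dataset$point_names, times = n))
    for (k in seq_len(d)) df[[ax[k]]] <- as.vector(t(dataset$coords[, , k]))
    if (n == 0L) df <- df[0, , drop = FALSE]
    write.csv(df, path, row.names = FALSE, na = "")
  } else {
    df <- data.frame(frame = dataset$frame_ids)
    for (p in seq_len(dataset$n_bp)) for (k in seq_len(d))
      df[[paste0(dataset$point_names[p], "_", ax[k])]] <- dataset$coords[, p, k]
    write.csv(df, path, row.names = FALSE, na = "")
  }
  invisible(path)
}

MODEL_FORMAT_VERSION <- "1.0"

#' Save / load a fitted shape model
#'
#' The model file is a JSON container (format version, dimensions, mean pose,
#' eigenposes, eigenvalues, noise floor) written at full double precision.
#' Orthonormality of the eigenposes is re-validated on load.
#'
#' @param model a [shape_model()].
#' @param path file path (conventionally `.json`).
#' @export
save_model <- function(model, path) {
  payload <- list(format = "ssmpose-shape-model",
                  version = MODEL_FORMAT_VERSION,
                  d = model$d, n_bp = model$n_bp, r = model$r,
                  alignment_policy = model$alignment_policy,
                  sigma2 = model$sigma2, mu = model$mu,
                  eigenvalues = model$eigenvalues,
                  eigenposes = model$eigenposes,
                  point_names = model$point_names)
  json <- jsonlite::toJSON(payload, digits = NA, auto_unbox = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- tryCatch(jsonlite::fromJSON(path),
                  error = function(e)
                    ssm_stop(sprintf("cannot parse model file %s: %s", path,
                                     conditionMessage(e)), "ssmpose_io_error"))
  if (!identical(obj$format, "ssmpose-shape-model"))
    ssm_stop("not a shape-model file", "ssmpose_io_error")
  if (!identical(obj$version, MODEL_FORMAT_VERSION))
    ssm_stop(sprintf("model file version %s != supported %s", obj$version,
                     MODEL_FORMAT_VERSION), "ssmpose_io_error")
  shape_model(mu = as.numeric(obj$mu),
              eigenposes = matrix(obj$eigenposes, ncol = obj$r),
              eigenvalues = as.numeric(obj$eigenvalues),
              sigma2 = obj$sigma2, d = obj$d,
              alignment_policy = obj$alignment_policy,
              point_names = obj$point_names)
}
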