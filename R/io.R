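#' Load NIfTI volumes into a dataset
#'
#' Reads a set of equally shaped NIfTI volumes (already spatially
#' normalized to a common space) and pairs each with its class label from
#' a delimited table.  Volumes with any NaN voxel, with a shape different
#' from the first volume, or with a label outside the known classes are
#' rejected with an error naming the offending file.
#'
#' @param paths character vector of NIfTI file paths.
#' @param labels a data frame with columns `file` and `class`, or the path
#'   of a comma- or tab-separated file with those columns.  Files are
#'   matched by basename (full paths also accepted).
#' @param class_names optional fixed class order; defaults to the sorted
#'   unique labels.
#' @return an [mtr_data()] in the order of `paths`.
#' @export
load_volumes <- function(paths, labels, class_names = NULL) {
  if (length(paths) < 1L) stop("no volume paths given")
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0L)
    stop(sprintf("missing volume file(s): %s",
                 paste(missing, collapse = ", ")))
  if (is.character(labels)) {
    if (!file.exists(labels)) stop(sprintf("labels file not found: %s",
                                           labels))
    labels <- utils::read.csv(labels, sep = if (grepl("\\.tsv$", labels))
      "\t" else ",", stringsAsFactors = FALSE)
  }
  if (!all(c("file", "class") %in% names(labels)))
    stop("labels table must have columns `file` and `class`")
  key <- stats::setNames(as.character(labels$class),
                         basename(labels$file))
  lab <- key[basename(paths)]
  if (anyNA(lab))
    stop(sprintf("no label for volume(s): %s",
                 paste(basename(paths)[is.na(lab)], collapse = ", ")))
  if (is.null(class_names)) class_names <- sort(unique(as.character(
    labels$class)))
  bad <- setdiff(unique(lab), class_names)
  if (length(bad) > 0L)
    stop(sprintf("unknown class label(s) %s; valid classes: %s",
                 paste(bad, collapse = ", "),
                 paste(class_names, collapse = ", ")))
  imgs <- vector("list", length(paths))
  shape <- NULL
  for (i in seq_along(paths)) {
    v <- as.array(RNifti::readNifti(paths[i]))
    if (length(dim(v)) != 3L)
      stop(sprintf("%s is not a 3D volume", paths[i]))
    if (anyNA(v))
      stop(sprintf("volume %s contains NaN voxels", paths[i]))
    if (is.null(shape)) shape <- dim(v)
    else if (!all(dim(v) == shape))
      stop(sprintf("volume %s has shape (%s); expected (%s)", paths[i],
                   paste(dim(v), collapse = ", "),
                   paste(shape, collapse = ", ")))
    imgs[[i]] <- v
  }
  mtr_data(imgs, lab, class_names = class_names)
}

#' Write a dataset as NIfTI volumes with a label sidecar
#'
#' Each subject is written as `vol_<i>.nii.gz` and the labels as
#' `labels.csv` (columns `file`, `class`) in `dir`.
#'
#' @param data an [mtr_data()].
#' @param dir output directory, created if needed.
#' @return character vector of the volume paths, invisibly.
#' @export
write_volumes <- function(data, dir) {
  stopifnot(inherits(data, "mtr_data"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- n_subjects(data)
  paths <- file.path(dir, sprintf("vol_%04d.nii.gz", seq_len(n)))
  for (i in seq_len(n))
    RNifti::writeNifti(RNifti::asNifti(get_volume(data, i)), paths[i])
  utils::write.csv(data.frame(file = basename(paths),
                              class = as.character(data$labels)),
                   file.path(dir, "labels.csv"), row.names = FALSE)
  invisible(paths)
}

#' Save fitted parameters to JSON
#'
#' Serializes an [mtr_params()] (factors, class names, reference class,
#' optional intercepts/covariate coefficients/standardization statistics)
#' at full double precision, so a reload reproduces predictions
#' bit-for-bit.
#'
#' @param params an [mtr_params()] or `mtr_fit` (its `params` are saved).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_params <- function(params, path) {
  if (inherits(params, "mtr_fit")) params <- params$params
  stopifnot(inherits(params, "mtr_params"))
  # numeric payloads are written as %.17g strings, which round-trip
  # doubles exactly (predictions after a reload are bit-identical)
  num17 <- function(x) sprintf("%.17g", as.numeric(x))
  enc <- list(
    format = "mtreg-params-1",
    class_names = params$class_names,
    reference = params$reference,
    shape = params$shape,
    rank = params$rank,
    factors = lapply(params$cp, function(b)
      lapply(b$factors, function(f) list(dim = dim(f),
                                         values = num17(f)))),
    intercepts = if (!is.null(params$intercepts))
      num17(params$intercepts),
    gamma = if (!is.null(params$gamma))
      list(dim = dim(params$gamma), values = num17(params$gamma)),
    standardize = if (!is.null(params$standardize))
      list(center = num17(params$standardize$center),
           scale = num17(params$standardize$scale)))
  jsonlite::write_json(enc, path, auto_unbox = FALSE, null = "null")
  invisible(path)
}

#' Load parameters saved by [save_params()]
#'
#' @param path JSON file path.
#' @return an [mtr_params()].
#' @export
load_params <- function(path) {
  if (!file.exists(path)) stop(sprintf("parameter file not found: %s",
                                       path))
  enc <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  if (!identical(enc$format, "mtreg-params-1"))
    stop(sprintf("%s is not an mtreg parameter file", path))
  remat <- function(m) matrix(as.numeric(m$values), m$dim[1L], m$dim[2L])
  cp <- lapply(enc$factors, function(fs) cp_tensor(lapply(fs, remat)))
  mtr_params(cp, enc$class_names, reference = enc$reference,
             intercepts = if (!is.null(enc$intercepts))
               as.numeric(enc$intercepts),
             gamma = if (!is.null(enc$gamma)) remat(enc$gamma),
             standardize = if (!is.null(enc$standardize))
               list(center = as.numeric(enc$standardize$center),
                    scale = as.numeric(enc$standardize$scale)))
}

#' Coefficient surfaces localizing discriminative regions
#'
#' For each non-reference class the three pairwise outer-product matrices
#' of the CP factors — \eqn{\beta^1 \circ \beta^2} (\eqn{d_1 \times
#' d_2}), \eqn{\beta^1 \circ \beta^3} and \eqn{\beta^2 \circ \beta^3},
#' summed over ranks — shown as heatmaps in neuroimaging applications to
#' mark image regions whose structure discriminates that class from the
#' reference.  Every axial slice of a rank-1 coefficient tensor is a
#' scalar multiple of \eqn{\beta^1 \circ \beta^2}, so these surfaces
#' summarize the full 3D coefficient pattern.  A mask marks the top
#' `threshold` fraction of cells by absolute value in each surface
#' ("most discriminative" cells); an all-zero surface yields an empty
#' mask.
#'
#' When `dir` is given, each surface is written as a CSV matrix and a PNG
#' heatmap, plus `surfaces.json` recording the threshold and shapes.
#'
#' @param params an [mtr_params()] or `mtr_fit`.
#' @param dir optional output directory.
#' @param threshold top fraction of cells masked, default 0.05.
#' @return object of class `mtr_surfaces`: per class, `surfaces` and
#'   logical `masks` for the axis pairs `"1x2"`, `"1x3"`, `"2x3"`.
#' @export
export_surfaces <- function(params, dir = NULL, threshold = 0.05) {
  if (inherits(params, "mtr_fit")) params <- params$params
  stopifnot(inherits(params, "mtr_params"), threshold > 0, threshold <= 1)
  pair_idx <- list("1x2" = c(1L, 2L), "1x3" = c(1L, 3L), "2x3" = c(2L, 3L))
  out <- lapply(params$cp, function(b) {
    surfaces <- lapply(pair_idx, function(pr)
      b$factors[[pr[1L]]] %*% t(b$factors[[pr[2L]]]))
    masks <- lapply(surfaces, function(s) {
      if (all(s == 0)) return(s != 0)  # empty mask for the zero surface
      cut <- stats::quantile(abs(s), 1 - threshold, names = FALSE)
      abs(s) >= cut
    })
    list(surfaces = surfaces, masks = masks)
  })
  names(out) <- names(params$cp)
  res <- structure(out, threshold = threshold, class = "mtr_surfaces")
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (cl in names(out)) for (pr in names(pair_idx)) {
      stem <- file.path(dir, sprintf("%s_surface_%s", cl, pr))
      utils::write.table(out[[cl]]$surfaces[[pr]],
                         paste0(stem, ".csv"), sep = ",",
                         row.names = FALSE, col.names = FALSE)
      grDevices::png(paste0(stem, ".png"), width = 480, height = 480)
      graphics::image(out[[cl]]$surfaces[[pr]],
                      main = sprintf("%s: axes %s", cl, pr),
                      useRaster = TRUE)
      grDevices::dev.off()
    }
    jsonlite::write_json(
      list(threshold = threshold, classes = names(out),
           shape = params$shape, rank = params$rank),
      file.path(dir, "surfaces.json"), auto_unbox = TRUE)
  }
  res
}

#' @export
print.mtr_surfaces <- function(x, ...) {
  cat(sprintf("<mtr_surfaces> classes: %s; mask threshold top %.1f%%\n",
              paste(names(x), collapse = ", "),
              100 * attr(x, "threshold")))
  invisible(x)
}
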