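# Readers/writers for the package's plain-text interchange formats and
# NIfTI voxel volumes.

#' Write / read a trial table
#'
#' Tab-delimited with header `participant, target_id, distractor_id, label,
#' rt_seconds, correct` (`correct` as 0/1). Decision trial tables also
#' carry `display_id`.
#'
#' @param trials trial table.
#' @param path file path.
#' @return `write_trials` returns `path` invisibly; `read_trials` returns
#'   the trial table with `rt` in seconds and logical `correct`.
#' @export
write_trials <- function(trials, path) {
  out <- trials
  names(out)[names(out) == "rt"] <- "rt_seconds"
  out$correct <- as.integer(out$correct)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  out <- read.delim(path, stringsAsFactors = FALSE)
  if (!"rt_seconds" %in% names(out)) stop("missing rt_seconds column")
  names(out)[names(out) == "rt_seconds"] <- "rt"
  out$correct <- as.logical(out$correct)
  if (any(out$rt <= 0, na.rm = TRUE)) stop("trial table has non-positive RTs")
  out
}

#' Write / read a dissimilarity matrix as square TSV
#'
#' Object ids appear as both header row and first column.
#'
#' @param d symmetric dissimilarity matrix with object dimnames.
#' @param path file path.
#' @export
write_dissimilarity <- function(d, path) {
  out <- data.frame(object_id = rownames(d), d, check.names = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dissimilarity
#' @export
read_dissimilarity <- function(path) {
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  storage.mode(m) <- "double"
  m
}

#' Write an embedding as TSV plus JSON metadata
#'
#' Coordinates go to `<path>` (`object_id`, `dim_1..dim_k`); stress, fit_r,
#' criterion and seed go to `<path>.json`.
#'
#' @param emb a `vh_embedding`.
#' @param path TSV path.
#' @export
write_embedding <- function(emb, path) {
  tab <- data.frame(object_id = emb$objects, emb$coords, check.names = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(k = emb$k, stress = emb$stress, fit_r = emb$fit_r,
               criterion = emb$criterion)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Write / read display tables
#'
#' @param displays display table.
#' @param path file path.
#' @export
write_displays <- function(displays, path) {
  write.table(displays, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_displays
#' @export
read_displays <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Export / import a voxel dataset as NIfTI-1 volumes
#'
#' Writes one volume per condition (`beta_<condition>.nii.gz`), a mask
#' volume, and a JSON sidecar listing the condition order.
#'
#' @param data a [voxel_dataset()].
#' @param dir output directory (created if needed).
#' @export
write_nifti_dataset <- function(data, dir) {
  stopifnot(inherits(data, "vh_voxel_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  RNifti::writeNifti(RNifti::asNifti(array(as.numeric(data$mask),
                                           dim(data$mask))),
                     file.path(dir, "mask.nii.gz"))
  for (i in seq_along(data$conditions)) {
    vol <- data$betas[, , , i]
    vol[is.na(vol)] <- 0
    RNifti::writeNifti(RNifti::asNifti(vol),
                       file.path(dir, sprintf("beta_%03d.nii.gz", i)))
  }
  jsonlite::write_json(list(conditions = data$conditions,
                            voxel_size = data$voxel_size),
                       file.path(dir, "conditions.json"), digits = NA)
  invisible(dir)
}

#' @rdname write_nifti_dataset
#' @export
read_nifti_dataset <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "conditions.json"),
                              simplifyVector = TRUE)
  mask <- as.array(RNifti::readNifti(file.path(dir, "mask.nii.gz"))) > 0.5
  vols <- lapply(seq_along(meta$conditions), function(i) {
    as.array(RNifti::readNifti(file.path(dir, sprintf("beta_%03d.nii.gz", i))))
  })
  betas <- array(unlist(vols), c(dim(mask), length(vols)))
  betas[array(!mask, dim(betas))] <- NA_real_
  voxel_dataset(betas, mask, meta$conditions,
                voxel_size = meta$voxel_size %||% c(3, 3, 3))
}
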