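# Subject-level file I/O: one 4D NIfTI per velocity direction plus one 4D
# magnitude NIfTI, a JSON sidecar with venc/seed/truth metadata, and a
# cohort manifest CSV.

nifti_with_geometry <- function(arr, spacing, frame_dt) {
  # full 8-element pixdim: qfac, dx, dy, dz, dt, then unused
  RNifti::asNifti(arr, reference = list(
    pixdim = c(1, spacing, frame_dt, 0, 0, 0),
    xyzt_units = 10L # mm + ms
  ))
}

#' Write one subject's 4D-flow dataset
#'
#' @param subject list with \code{velocity}, \code{magnitude} and
#'   optionally \code{truth}, \code{config}, \code{id}, \code{group} (as
#'   produced by \code{\link{generate_cohorts}}).
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_subject <- function(subject, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  field <- subject$velocity
  d <- dim(field$data)
  for (dirn in 1:3) {
    arr <- field$data[, , , dirn, ]
    dim(arr) <- d[c(1:3, 5)]
    RNifti::writeNifti(
      nifti_with_geometry(arr, field$spacing, field$frame_dt),
      file.path(dir, sprintf("vel_%s.nii.gz", c("x", "y", "z")[dirn])))
  }
  RNifti::writeNifti(
    nifti_with_geometry(subject$magnitude$data, field$spacing, field$frame_dt),
    file.path(dir, "mag.nii.gz"))
  meta <- list(
    id = subject$id, group = subject$group,
    spacing = field$spacing, frame_dt = field$frame_dt, venc = field$venc,
    seed = subject$config$seed
  )
  if (!is.null(subject$truth)) {
    meta$truth <- list(
      v_max_true = subject$truth$v_max_true,
      wall_wss_analytic = subject$truth$wall_wss_analytic,
      el_analytic = subject$truth$el_analytic,
      mask_voxels = sum(subject$truth$mask$data)
    )
    RNifti::writeNifti(
      nifti_with_geometry(array(as.integer(subject$truth$mask$data),
                                dim(subject$truth$mask$data)),
                          field$spacing, field$frame_dt),
      file.path(dir, "truth_mask.nii.gz"))
  }
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

# Plain numeric array from a NIfTI file, shedding header attributes.
read_volume_array <- function(path) {
  a <- as.array(RNifti::readNifti(path))
  array(as.numeric(a), dim(a))
}

#' Read one subject's 4D-flow dataset
#'
#' @param dir directory written by \code{\link{write_subject}} (or any
#'   directory with the same layout).
#' @return list with \code{velocity}, \code{magnitude}, \code{id},
#'   \code{group} and (if present) \code{truth_mask}.
#' @export
read_subject <- function(dir) {
  meta_path <- file.path(dir, "meta.json")
  if (!file.exists(meta_path)) {
    stop(sprintf("missing metadata file: %s", meta_path), call. = FALSE)
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  comp <- lapply(c("x", "y", "z"), function(ax) {
    f <- file.path(dir, sprintf("vel_%s.nii.gz", ax))
    if (!file.exists(f)) stop(sprintf("missing velocity file: %s", f),
                              call. = FALSE)
    read_volume_array(f)
  })
  d <- dim(comp[[1]])
  vel <- array(0, c(d[1:3], 3, d[4]))
  for (i in 1:3) vel[, , , i, ] <- comp[[i]]
  field <- velocity_field(vel, meta$spacing, meta$frame_dt, meta$venc)
  mag <- magnitude_series(read_volume_array(file.path(dir, "mag.nii.gz")),
                          meta$spacing)
  out <- list(id = meta$id, group = meta$group, velocity = field,
              magnitude = mag, meta = meta)
  tm <- file.path(dir, "truth_mask.nii.gz")
  if (file.exists(tm)) {
    out$truth_mask <- aorta_mask(read_volume_array(tm) > 0.5,
                                 meta$spacing)
  }
  out
}

#' Write a cohort of subjects plus a manifest
#'
#' @param cohorts output of \code{\link{generate_cohorts}}.
#' @param dir output root; one subdirectory per subject.
#' @return path of the manifest CSV, invisibly.
#' @export
write_cohort <- function(cohorts, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  subjects <- c(cohorts$stented, cohorts$stentless)
  rows <- lapply(subjects, function(s) {
    write_subject(s, file.path(dir, s$id))
    tibble::tibble(id = s$id, group = s$group, path = s$id)
  })
  manifest <- dplyr::bind_rows(rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(file.path(dir, "manifest.csv"))
}

#' Export wall points (optionally with WSS vectors) as a plain-text table
#'
#' @param wall \code{wall_points} or \code{wss_map}.
#' @param path output path (tab-separated).
#' @return path, invisibly.
#' @export
write_wall_table <- function(wall, path) {
  utils::write.table(as.data.frame(wall), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
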