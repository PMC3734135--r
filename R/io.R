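#' @importFrom RNifti asNifti writeNifti readNifti xform pixdim
NULL

# Wrap an array as a NIfTI image with the study affine in both qform and
# sform (code 2, "aligned to anatomy").
.as_nifti <- function(arr, affine, voxel_size_mm, tr_seconds = NULL) {
  img <- RNifti::asNifti(arr)
  aff <- structure(affine, code = 2L)
  img <- RNifti::`sform<-`(img, aff)
  img <- RNifti::`qform<-`(img, aff)
  pd <- as.numeric(voxel_size_mm)
  if (!is.null(tr_seconds)) pd <- c(pd, tr_seconds)
  RNifti::pixdim(img) <- pd
  img
}

#' Write one session (BOLD, tissue masks, motion parameters) to disk
#'
#' Persists the 4D time series as NIfTI-1, each tissue mask as a 3D
#' NIfTI volume, and the motion parameters as whitespace-delimited text
#' with 6 columns and one row per volume. File names follow a BIDS-like
#' `sub-XX_task-YY_ses-ZZ` pattern.
#'
#' @param session a [bold_session].
#' @param masks tissue masks (list with logical arrays `gray`, `white`,
#'   `csf`).
#' @param nuisance a nuisance set whose `motion` matrix is written.
#' @param directory output directory (created if missing).
#' @return named character vector of the written file paths (`bold`,
#'   `gray`, `white`, `csf`, `motion`).
#' @export
write_session <- function(session, masks, nuisance, directory) {
  stopifnot(inherits(session, "bold_session"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory)) stop("cannot create output directory: ", directory)
  stem <- sprintf("%s_task-%s_ses-%02d", session$subject_id,
                  session$condition, session$session_index)
  paths <- c(bold = file.path(directory, paste0(stem, "_bold.nii.gz")),
             gray = file.path(directory, "mask_gray.nii.gz"),
             white = file.path(directory, "mask_white.nii.gz"),
             csf = file.path(directory, "mask_csf.nii.gz"),
             motion = file.path(directory, paste0(stem, "_motion.txt")))
  writeNifti(.as_nifti(session$data, session$affine, session$voxel_size_mm,
                       session$tr_seconds), paths[["bold"]])
  for (m in c("gray", "white", "csf"))
    writeNifti(.as_nifti(array(as.integer(masks[[m]]), dim = dim(masks[[m]])),
                         session$affine, session$voxel_size_mm), paths[[m]])
  write.table(format(nuisance$motion, digits = 10), paths[["motion"]],
              row.names = FALSE, col.names = FALSE, quote = FALSE)
  paths
}

#' Read one session back from files written by [write_session()]
#'
#' Global, white-matter and CSF mean signals are recomputed from the
#' stored data over the stored masks (the global signal over the union
#' of all three tissue masks), so a round trip through disk reproduces
#' the in-memory nuisance set.
#'
#' @param bold_path path to the 4D NIfTI.
#' @param mask_paths named character vector with elements `gray`,
#'   `white`, `csf`.
#' @param motion_path path to the 6-column motion text file.
#' @param subject_id,condition,session_index session labels; defaults
#'   are parsed from the BOLD file name when it follows the
#'   `sub-XX_task-YY_ses-ZZ` pattern.
#' @return list with elements `bold`, `masks`, `nuisance`.
#' @export
read_session <- function(bold_path, mask_paths, motion_path,
                         subject_id = NULL, condition = NULL,
                         session_index = NULL) {
  img <- readNifti(bold_path)
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = dim(aff))
  vox <- RNifti::pixdim(img)[1:3]
  tr <- RNifti::pixdim(img)[4]
  dat <- array(as.numeric(img), dim = dim(img))
  base <- basename(bold_path)
  if (is.null(subject_id))
    subject_id <- sub("^(sub-[0-9A-Za-z]+).*$", "\\1", base)
  if (is.null(condition))
    condition <- sub("^.*task-([a-z]+).*$", "\\1", base)
  if (is.null(session_index))
    session_index <- as.integer(sub("^.*ses-([0-9]+).*$", "\\1", base))
  bold <- bold_session(dat, voxel_size_mm = vox, tr_seconds = tr,
                       affine = aff, subject_id = subject_id,
                       condition = condition, session_index = session_index)
  masks <- lapply(mask_paths[c("gray", "white", "csf")],
                  function(p) array(as.numeric(readNifti(p)) > 0.5,
                                    dim = dim(readNifti(p))))
  motion <- as.matrix(read.table(motion_path))
  dimnames(motion) <- NULL
  if (ncol(motion) != 6L)
    stop("motion file must have 6 columns: ", motion_path)
  n <- dim(dat)[4]
  flat <- matrix(dat, nrow = prod(dim(dat)[1:3]), ncol = n)
  brain <- as.vector(masks$gray | masks$white | masks$csf)
  nuisance <- structure(list(
    motion = motion,
    global_signal = colMeans(flat[brain, , drop = FALSE]),
    white_signal = colMeans(flat[as.vector(masks$white), , drop = FALSE]),
    csf_signal = colMeans(flat[as.vector(masks$csf), , drop = FALSE])),
    class = "nuisance_set")
  list(bold = bold, masks = masks, nuisance = nuisance)
}

#' Write a whole synthetic study and its manifest
#'
#' Writes every session with [write_session()] and a JSON manifest
#' listing all file paths and session labels, suitable as the file-mode
#' input of [run_study()].
#'
#' @param study a `voxnet_study` from [generate_study()].
#' @param directory output directory.
#' @return path of the written manifest JSON.
#' @export
write_study <- function(study, directory) {
  stopifnot(inherits(study, "voxnet_study"))
  rows <- lapply(study$sessions, function(s) {
    p <- write_session(s$bold, s$masks, s$nuisance, directory)
    data.frame(subject = s$bold$subject_id, condition = s$bold$condition,
               session = s$bold$session_index,
               bold = p[["bold"]], motion = p[["motion"]],
               stringsAsFactors = FALSE)
  })
  manifest <- list(
    n_volumes = study$config$n_volumes,
    tr_seconds = study$config$tr_seconds,
    masks = list(gray = file.path(directory, "mask_gray.nii.gz"),
                 white = file.path(directory, "mask_white.nii.gz"),
                 csf = file.path(directory, "mask_csf.nii.gz")),
    sessions = do.call(rbind, rows))
  path <- file.path(directory, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  path
}

.read_manifest <- function(manifest) {
  if (is.character(manifest)) manifest <- jsonlite::read_json(manifest,
                                                              simplifyVector = TRUE)
  manifest
}
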