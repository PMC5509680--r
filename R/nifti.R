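# Minimal NIfTI-1 I/O (single-file uncompressed .nii, float32 data).
# No NIfTI reader is available in the target R environment, so the package
# carries its own: enough of the standard to round-trip 3D volumes with
# voxel spacing, plus reading the common integer/float data types. Not a
# general-purpose implementation (no .hdr/.img pairs, no gzip, no
# orientation handling beyond a diagonal sform).

#' Write a 3D volume as NIfTI-1
#'
#' @param data numeric 3D array.
#' @param path output path (conventionally `.nii`).
#' @param spacing voxel spacing in mm (x, y, z); stored in `pixdim` and as a
#'   diagonal sform.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(data, path, spacing = c(1, 1, 1)) {
  if (length(dim(data)) != 3L) stopf("data must be a 3D array")
  spacing <- as.numeric(spacing)
  con <- file(path, "wb")
  on.exit(close(con))
  d <- dim(data)
  writeBin(348L, con, size = 4)                       # sizeof_hdr
  writeBin(raw(36), con)                              # unused
  writeBin(as.integer(c(3, d, 1, 1, 1, 1)), con, size = 2)  # dim[8]
  writeBin(numeric(3), con, size = 4)                 # intent_p1..p3
  writeBin(0L, con, size = 2)                         # intent_code
  writeBin(16L, con, size = 2)                        # datatype: float32
  writeBin(32L, con, size = 2)                        # bitpix
  writeBin(0L, con, size = 2)                         # slice_start
  writeBin(c(1, spacing, 0, 0, 0, 0), con, size = 4)  # pixdim[8]
  writeBin(352, con, size = 4)                        # vox_offset
  writeBin(c(1, 0), con, size = 4)                    # scl_slope, scl_inter
  writeBin(0L, con, size = 2)                         # slice_end
  writeBin(as.raw(c(0, 10)), con)                     # slice_code, xyzt=mm|s
  writeBin(numeric(4), con, size = 4)                 # cal_max..toffset
  writeBin(integer(2), con, size = 4)                 # glmax, glmin
  desc <- raw(104)                                    # descrip + aux_file
  writeBin(desc, con)
  writeBin(c(0L, 1L), con, size = 2)                  # qform=0, sform=1
  writeBin(numeric(6), con, size = 4)                 # quatern b,c,d + qoffset
  srow <- rbind(c(spacing[1], 0, 0, 0),
                c(0, spacing[2], 0, 0),
                c(0, 0, spacing[3], 0))
  writeBin(as.numeric(t(srow)), con, size = 4)        # srow_x/y/z
  writeBin(raw(16), con)                              # intent_name
  writeBin(charToRaw("n+1"), con)
  writeBin(raw(1), con)                               # magic terminator
  writeBin(raw(4), con)                               # extension flag
  writeBin(as.numeric(data), con, size = 4)
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' Supports uncompressed single-file NIfTI-1 with data types uint8, int16,
#' int32, float32 or float64 and applies the scl slope/intercept. Only the
#' first three dimensions are read.
#'
#' @param path path to a `.nii` file.
#' @return List with `data` (numeric 3D array) and `spacing` (mm).
#' @export
read_nifti <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  endian <- "little"
  hdr_size <- readBin(con, "integer", 1, size = 4, endian = endian)
  if (hdr_size != 348L) {
    endian <- "big"
    seek(con, 0)
    hdr_size <- readBin(con, "integer", 1, size = 4, endian = endian)
    if (hdr_size != 348L) stopf("%s is not a NIfTI-1 file", path)
  }
  seek(con, 40)
  dims <- readBin(con, "integer", 8, size = 2, endian = endian)
  ndim <- dims[1]
  if (ndim < 3L) stopf("expected a 3D volume, got %d dims", ndim)
  d <- dims[2:4]
  seek(con, 70)
  datatype <- readBin(con, "integer", 1, size = 2, endian = endian)
  seek(con, 76)
  pixdim <- readBin(con, "numeric", 8, size = 4, endian = endian)
  vox_offset <- readBin(con, "numeric", 1, size = 4, endian = endian)
  scl_slope <- readBin(con, "numeric", 1, size = 4, endian = endian)
  scl_inter <- readBin(con, "numeric", 1, size = 4, endian = endian)
  n <- prod(d)
  seek(con, vox_offset)
  vals <- switch(as.character(datatype),
    "2" = as.numeric(readBin(con, "integer", n, size = 1, signed = FALSE,
                             endian = endian)),
    "4" = as.numeric(readBin(con, "integer", n, size = 2, endian = endian)),
    "8" = as.numeric(readBin(con, "integer", n, size = 4, endian = endian)),
    "16" = readBin(con, "numeric", n, size = 4, endian = endian),
    "64" = readBin(con, "numeric", n, size = 8, endian = endian),
    stopf("unsupported NIfTI datatype code %d", datatype)
  )
  if (is.finite(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0)) {
    vals <- vals * scl_slope + scl_inter
  }
  list(data = array(vals, d), spacing = pixdim[2:4])
}

#' Write one subject's volumes and mask as NIfTI files
#'
#' @param phantom a per-subject list with `volume` and `labels` (as returned
#'   by [generate_phantom()]).
#' @param dir output directory (created if missing).
#' @return Named character vector of the four file paths.
#' @export
write_subject <- function(phantom, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vol <- phantom$volume
  id <- vol$subject_id
  paths <- c(
    t2w = file.path(dir, sprintf("%s_t2w.nii", id)),
    dwi_b0 = file.path(dir, sprintf("%s_dwi-b0.nii", id)),
    dwi_high_b = file.path(dir, sprintf("%s_dwi-highb.nii", id)),
    mask = file.path(dir, sprintf("%s_mask.nii", id))
  )
  for (s in c("t2w", "dwi_b0", "dwi_high_b")) {
    write_nifti(vol$sequences[[s]], paths[[s]], vol$spacing)
  }
  write_nifti(phantom$labels$mask, paths[["mask"]], vol$spacing)
  paths
}

#' Read one subject back from NIfTI files
#'
#' @param paths named character vector as produced by [write_subject()].
#' @param subject_id identifier for the reconstructed volume.
#' @return List with `volume` ([mp_volume]) and `labels` ([label_map]).
#' @export
read_subject <- function(paths, subject_id = "subject") {
  t2w <- read_nifti(paths[["t2w"]])
  b0 <- read_nifti(paths[["dwi_b0"]])
  hb <- read_nifti(paths[["dwi_high_b"]])
  mask <- read_nifti(paths[["mask"]])
  list(
    volume = mp_volume(t2w$data, b0$data, hb$data, t2w$spacing, subject_id),
    labels = label_map(round(mask$data))
  )
}

#' Write a cohort with manifest
#'
#' Writes every subject's four NIfTI volumes under `dir` and a plain-text
#' tab-separated manifest (`manifest.tsv`) with subject id, file paths and
#' discovery/validation split assignment.
#'
#' @param cohort a `phantom_cohort`.
#' @param dir output directory.
#' @param split character vector of "discovery"/"validation" per subject,
#'   or NULL to assign by subject-number parity (even = discovery).
#' @return The manifest data frame, invisibly.
#' @export
write_cohort <- function(cohort, dir, split = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ids <- vapply(cohort, function(s) s$volume$subject_id, character(1))
  if (is.null(split)) split <- split_by_parity(ids)
  rows <- vector("list", length(cohort))
  for (i in seq_along(cohort)) {
    paths <- write_subject(cohort[[i]], dir)
    rows[[i]] <- data.frame(
      subject_id = ids[i], t2w = paths[["t2w"]], dwi_b0 = paths[["dwi_b0"]],
      dwi_high_b = paths[["dwi_high_b"]], mask = paths[["mask"]],
      split = split[i], stringsAsFactors = FALSE
    )
  }
  manifest <- do.call(rbind, rows)
  write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

#' Read a cohort manifest
#'
#' @param path path to a `manifest.tsv` (or the directory containing it).
#' @return Manifest data frame.
#' @export
read_manifest <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "manifest.tsv")
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Assign discovery/validation split by subject-number parity
#'
#' Subjects whose numeric identifier is even go to the discovery set, odd
#' to validation, mirroring an assignment by (even/odd) patient identifier.
#'
#' @param subject_ids character vector; the trailing integer in each id is
#'   used (e.g. `"sub-012"` is 12, hence discovery).
#' @return Character vector of "discovery"/"validation".
#' @export
split_by_parity <- function(subject_ids) {
  num <- suppressWarnings(as.integer(sub(".*?(\\d+)$", "\\1", subject_ids)))
  if (any(is.na(num))) stopf("subject ids must end in an integer for parity split")
  ifelse(num %% 2L == 0L, "discovery", "validation")
}
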