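#' Write a volume to a NIfTI-1 file
#'
#' Minimal single-file NIfTI-1 (.nii) writer: float64 data, axis-aligned
#' sform affine built from the voxel size and origin, TR stored in
#' pixdim[5] (seconds). Values round-trip bit-for-bit through
#' [read_volume()].
#'
#' @param x a [bold_run()], [zmap()], or a 3D/4D numeric/logical array.
#' @param path output path (conventionally ending in .nii).
#' @param tr_s,voxel_size_mm,origin_mm metadata when `x` is a bare array.
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path, tr_s = 0, voxel_size_mm = c(1, 1, 1),
                         origin_mm = c(0, 0, 0)) {
  if (inherits(x, "bold_run")) {
    data <- x$data; tr_s <- x$tr_s
    voxel_size_mm <- x$voxel_size_mm; origin_mm <- x$origin_mm
  } else if (inherits(x, "zmap")) {
    data <- x$data; voxel_size_mm <- x$voxel_size_mm; origin_mm <- x$origin_mm
  } else data <- x
  if (is.logical(data)) data <- array(as.numeric(data), dim = dim(data))
  d <- dim(data)
  if (!(length(d) %in% c(3L, 4L))) stop("only 3D or 4D volumes are supported")
  ndim <- length(d)
  dim8 <- c(ndim, d, rep(1L, 7L - length(d)))
  pixdim8 <- c(1, voxel_size_mm, if (ndim == 4L) tr_s else 1, 1, 1, 1)

  con <- file(path, "wb")
  on.exit(close(con))
  wi32 <- function(v) writeBin(as.integer(v), con, size = 4L, endian = "little")
  wi16 <- function(v) writeBin(as.integer(v), con, size = 2L, endian = "little")
  wf32 <- function(v) writeBin(as.numeric(v), con, size = 4L, endian = "little")
  wchar <- function(s, n) {
    raw <- charToRaw(s)
    writeBin(c(raw[seq_len(min(length(raw), n))],
               rep(as.raw(0), max(0L, n - length(raw)))), con)
  }
  wi32(348)                       # sizeof_hdr
  wchar("", 10); wchar("", 18)    # data_type, db_name
  wi32(0); wi16(0); wchar("r", 1); wchar("", 1)  # extents, session_error, regular, dim_info
  wi16(dim8)                      # dim[8]
  wf32(c(0, 0, 0)); wi16(0)       # intent_p1..3, intent_code
  wi16(64); wi16(64); wi16(0)     # datatype float64, bitpix, slice_start
  wf32(pixdim8)                   # pixdim[8]
  wf32(352)                       # vox_offset
  wf32(1); wf32(0)                # scl_slope, scl_inter
  wi16(0); wchar("", 1)           # slice_end, slice_code
  writeBin(as.raw(10), con)       # xyzt_units: mm | sec
  wf32(c(0, 0, 0, 0))             # cal_max, cal_min, slice_duration, toffset
  wi32(0); wi32(0)                # glmax, glmin
  wchar("blockmvpa", 80); wchar("", 24)  # descrip, aux_file
  wi16(0); wi16(1)                # qform_code, sform_code
  wf32(c(0, 0, 0)); wf32(c(0, 0, 0))     # quaternion, qoffset
  wf32(c(voxel_size_mm[1], 0, 0, origin_mm[1]))  # srow_x
  wf32(c(0, voxel_size_mm[2], 0, origin_mm[2]))  # srow_y
  wf32(c(0, 0, voxel_size_mm[3], origin_mm[3]))  # srow_z
  wchar("", 16)                   # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0)), con)  # magic
  writeBin(rep(as.raw(0), 4), con)               # extension flag
  writeBin(as.numeric(data), con, size = 8L, endian = "little")
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' Reads single-file NIfTI-1 images written by [write_volume()] (and plain
#' uncompressed .nii files with datatype uint8/int16/int32/float32/float64).
#'
#' @param path file path.
#' @return for 4D images a [bold_run()]; for 3D images a list with `data`,
#'   `voxel_size_mm`, `origin_mm` of class `volume3d`.
#' @export
read_volume <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ri32 <- function(n) readBin(con, "integer", n, size = 4L, endian = "little")
  ri16 <- function(n) readBin(con, "integer", n, size = 2L, endian = "little")
  rf32 <- function(n) readBin(con, "numeric", n, size = 4L, endian = "little")
  hdr <- ri32(1)
  if (!length(hdr) || hdr != 348)
    stop(sprintf("malformed NIfTI header in '%s': sizeof_hdr = %s", path,
                 if (length(hdr)) hdr else "EOF"))
  invisible(readBin(con, "raw", 36))            # up to dim
  dim8 <- ri16(8)
  ndim <- dim8[1]
  if (!(ndim %in% c(3L, 4L)))
    stop(sprintf("malformed NIfTI header: dim[0] = %d (need 3 or 4)", ndim))
  d <- dim8[2:(1 + ndim)]
  invisible(rf32(3)); invisible(ri16(1))        # intent
  datatype <- ri16(1); invisible(ri16(2))       # datatype, bitpix, slice_start
  pixdim <- rf32(8)
  vox_offset <- rf32(1)
  scl <- rf32(2)
  invisible(readBin(con, "raw", 252 - 120))     # to qform_code
  qform <- ri16(1); sform <- ri16(1)
  invisible(rf32(6))
  srow <- matrix(rf32(12), nrow = 3, byrow = TRUE)
  invisible(readBin(con, "raw", 16))
  magic <- readBin(con, "raw", 4)
  if (!identical(rawToChar(magic[1:3]), "n+1"))
    stop(sprintf("malformed NIfTI header in '%s': magic = '%s'", path,
                 rawToChar(magic[magic != as.raw(0)])))
  seek(con, vox_offset)
  nvals <- prod(d)
  vals <- switch(as.character(datatype),
    "2"  = as.numeric(readBin(con, "integer", nvals, size = 1L, signed = FALSE)),
    "4"  = as.numeric(readBin(con, "integer", nvals, size = 2L, endian = "little")),
    "8"  = as.numeric(readBin(con, "integer", nvals, size = 4L, endian = "little")),
    "16" = readBin(con, "numeric", nvals, size = 4L, endian = "little"),
    "64" = readBin(con, "numeric", nvals, size = 8L, endian = "little"),
    stop(sprintf("unsupported NIfTI datatype %d", datatype)))
  if (length(vals) < nvals)
    stop(sprintf("truncated NIfTI file '%s': expected %d values, got %d",
                 path, nvals, length(vals)))
  if (scl[1] != 0 && !(scl[1] == 1 && scl[2] == 0))
    vals <- vals * scl[1] + scl[2]
  voxel_size_mm <- pixdim[2:4]
  origin <- if (sform > 0) srow[, 4] else c(0, 0, 0)
  arr <- array(vals, dim = d)
  if (ndim == 4L)
    bold_run(arr, tr_s = pixdim[5], voxel_size_mm = voxel_size_mm,
             origin_mm = origin)
  else structure(list(data = arr, voxel_size_mm = voxel_size_mm,
                      origin_mm = origin), class = "volume3d")
}

#' Write an event table as a BIDS-style events TSV
#'
#' Tab-separated, columns `onset`, `duration`, `trial_type`, `session`,
#' `subjective`, `objective_correct` (plus any extra columns present);
#' missing values are written as `n/a`.
#'
#' @param events event table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  df <- as.data.frame(events)
  lead <- intersect(c("onset", "duration", "trial_type", "session",
                      "subjective", "objective_correct"), names(df))
  df <- df[, c(lead, setdiff(names(df), lead)), drop = FALSE]
  out <- df
  for (j in seq_along(out)) {
    v <- out[[j]]
    if (is.logical(v)) v <- c("false", "true")[v + 1L]
    v <- as.character(v)
    v[is.na(v)] <- "n/a"
    out[[j]] <- v
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BIDS-style events TSV
#'
#' @param path file path.
#' @param tr_s optional repetition time to attach; enables bounds checks.
#' @param n_volumes optional run length in volumes; onsets beyond the run
#'   raise an error.
#' @return event table data.frame; unknown columns are preserved.
#' @export
read_events <- function(path, tr_s = NULL, n_volumes = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, na.strings = "n/a")
  need <- c("onset", "duration", "trial_type")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("events file '%s' is missing required column '%s'",
                 path, miss[1]))
  if (!"session" %in% names(df)) df$session <- 1L
  if (!"subjective" %in% names(df)) df$subjective <- "none"
  df$subjective[is.na(df$subjective)] <- "none"
  bad <- setdiff(unique(df$subjective), c("knew", "guessed", "none"))
  if (length(bad))
    stop(sprintf("invalid subjective label '%s'", bad[1]))
  if ("objective_correct" %in% names(df)) {
    v <- df$objective_correct
    if (!is.logical(v)) {
      v <- tolower(as.character(v))
      ok <- v %in% c("true", "false") | is.na(v)
      if (!all(ok)) stop("objective_correct must be true/false/n/a")
      v <- v == "true"
    }
    df$objective_correct <- v
  } else df$objective_correct <- NA
  if (!is.null(tr_s)) attr(df, "tr_s") <- tr_s
  if (!is.null(n_volumes)) {
    if (any(df$onset >= n_volumes * tr_s - 1e-9))
      stop("event onset lies beyond the end of the run")
    attr(df, "n_volumes") <- as.integer(n_volumes)
  }
  df
}

#' Write a decoding/summary table as TSV
#' @param df data.frame.
#' @param path output path.
#' @export
write_table_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
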