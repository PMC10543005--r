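# Minimal uncompressed NIfTI-1 I/O (float32, sform affine).  None of the
# pre-installed R packages reads NIfTI, and the format's single-file variant
# is a fixed 348-byte header followed by raw voxel data, so a small
# self-contained implementation is used here.  Covers exactly what the
# package needs: 3-D/4-D float volumes with an affine; no extensions,
# no compression, native little-endian byte order.

#' Write a volume to an uncompressed NIfTI-1 file
#'
#' @param x a [volume_map()], [signature_map()] (weights are written), a
#'   3-D/4-D numeric array, or an integer label array.
#' @param path output path (conventionally `.nii`).
#' @param affine 4x4 voxel-to-world matrix; taken from the object when it
#'   carries one.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(x, path, affine = NULL) {
  if (inherits(x, "signature_map")) {
    affine <- affine %||% x$affine
    arr <- x$weights
  } else if (inherits(x, "volume_map")) {
    affine <- affine %||% x$affine
    arr <- x$values
  } else arr <- x
  affine <- affine %||% diag(c(2, 2, 2, 1))
  nd <- length(dim(arr))
  stop_if_not(nd %in% c(3L, 4L), "only 3-D or 4-D arrays are supported")
  dims <- dim(arr)

  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(v, size) writeBin(as.integer(v), con, size = size, endian = "little")
  wf <- function(v) writeBin(as.numeric(v), con, size = 4, endian = "little")
  wraw <- function(n) writeBin(raw(n), con)

  wi(348L, 4)                      # sizeof_hdr
  wraw(36)                         # data_type..dim_info (unused)
  wi(c(nd, dims, rep(1L, 7 - nd)), 2)  # dim[8]
  wf(c(0, 0, 0))                   # intent_p1..p3
  wi(0L, 2)                        # intent_code
  wi(16L, 2)                       # datatype: float32
  wi(32L, 2)                       # bitpix
  wi(0L, 2)                        # slice_start
  vox <- sqrt(colSums(affine[1:3, 1:3]^2))
  wf(c(1, vox, rep(1, 7 - 3)))     # pixdim[8] (qfac 1)
  wf(352)                          # vox_offset
  wf(c(1, 0))                      # scl_slope, scl_inter
  wi(0L, 2); wi(0L, 1); wi(0L, 1)  # slice_end, slice_code, xyzt_units
  wf(c(0, 0, 0))                   # cal_max, cal_min, slice_duration
  wf(0)                            # toffset
  wi(c(0L, 0L), 4)                 # glmax, glmin
  wraw(80 + 24)                    # descrip, aux_file
  wi(0L, 2)                        # qform_code
  wi(1L, 2)                        # sform_code
  wf(rep(0, 6))                    # quatern b,c,d + qoffset x,y,z
  wf(affine[1, ]); wf(affine[2, ]); wf(affine[3, ])  # srow_x/y/z
  wraw(16)                         # intent_name
  writeChar("n+1", con, nchars = 3, eos = NULL); wraw(1)  # magic
  wraw(4)                          # extension flag
  wf(as.numeric(arr))
  invisible(path)
}

#' Read an uncompressed NIfTI-1 file
#'
#' @param path file written by [write_nifti()] or any single-file
#'   uncompressed little-endian NIfTI-1 volume.
#' @param as_volume_map return a [volume_map()] (3-D only) instead of a
#'   plain array.
#' @return array with attribute `affine`, or a [volume_map()].
#' @export
read_nifti <- function(path, as_volume_map = FALSE) {
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n, size) readBin(con, "integer", n = n, size = size,
                                  endian = "little")
  rf <- function(n) readBin(con, "numeric", n = n, size = 4, endian = "little")
  hdr_size <- ri(1, 4)
  stop_if_not(hdr_size == 348, "not a NIfTI-1 file (sizeof_hdr != 348)")
  invisible(readBin(con, "raw", 36))
  dims8 <- ri(8, 2)
  nd <- dims8[1]; dims <- dims8[2:(1 + nd)]
  rf(3); ri(1, 2)
  datatype <- ri(1, 2)
  stop_if_not(datatype %in% c(2L, 4L, 8L, 16L, 64L),
              "unsupported NIfTI datatype %d", datatype)
  ri(1, 2); ri(1, 2)
  rf(8)
  vox_offset <- rf(1)
  scl <- rf(2)
  invisible(readBin(con, "raw", 2 + 1 + 1)); rf(3); rf(1); ri(2, 4)
  invisible(readBin(con, "raw", 104))
  ri(1, 2); sform <- ri(1, 2)
  rf(6)
  srow <- rbind(rf(4), rf(4), rf(4))
  affine <- rbind(srow, c(0, 0, 0, 1))
  if (sform == 0) affine <- diag(4)
  seek(con, vox_offset)
  n_vox <- prod(dims)
  vals <- switch(as.character(datatype),
    "2" = readBin(con, "integer", n_vox, size = 1, signed = FALSE),
    "4" = readBin(con, "integer", n_vox, size = 2, endian = "little"),
    "8" = readBin(con, "integer", n_vox, size = 4, endian = "little"),
    "16" = readBin(con, "numeric", n_vox, size = 4, endian = "little"),
    "64" = readBin(con, "numeric", n_vox, size = 8, endian = "little"))
  if (scl[1] != 0 && !(scl[1] == 1 && scl[2] == 0))
    vals <- vals * scl[1] + scl[2]
  arr <- array(vals, dims)
  if (as_volume_map) {
    stop_if_not(nd == 3, "as_volume_map requires a 3-D volume")
    return(volume_map(arr, affine))
  }
  attr(arr, "affine") <- affine
  arr
}
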