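# Minimal MRC2014 container I/O (mode 2, 32-bit float, little endian): the
# standard cryo-EM format for images, stacks and volumes. Only the fields
# the pipeline needs are interpreted; the pixel size travels in the cell
# dimensions (cella = m* * pixel size).

.mrc_header_template <- function(nx, ny, nz, pixel_size, is_volume) {
  list(nx = nx, ny = ny, nz = nz, mode = 2L,
       nxstart = 0L, nystart = 0L, nzstart = 0L,
       mx = nx, my = ny, mz = if (is_volume) nz else 1L,
       cella = c(nx, ny, if (is_volume) nz else 1L) * pixel_size,
       cellb = c(90, 90, 90),
       mapc = 1L, mapr = 2L, maps = 3L,
       ispg = if (is_volume) 1L else 0L, nsymbt = 0L)
}

#' Write an image, stack or volume as MRC2014
#'
#' Mode 2 (32-bit float), little endian. A 2D matrix is written as a single
#' image, a 3D array as a volume when `volume = TRUE` (the default for
#' cubic arrays) or as an image stack otherwise. The pixel size is stored
#' in the cell dimensions.
#'
#' @param data real matrix or 3D array.
#' @param path output file path.
#' @param pixel_size pixel/voxel size in Angstrom (defaults to the data's
#'   `pixel_size` attribute, else 1).
#' @param volume write a 3D array as a volume rather than a stack; default
#'   `TRUE` for cubic arrays.
#' @return `path`, invisibly.
#' @export
write_mrc <- function(data, path, pixel_size = NULL, volume = NULL) {
  if (is.null(pixel_size)) pixel_size <- attr(data, "pixel_size") %||% 1
  d <- dim(data)
  if (is.null(d) || !length(d) %in% 2:3)
    stop("data must be a matrix or 3D array")
  if (length(d) == 2) d <- c(d, 1L)
  if (is.null(volume)) volume <- (d[1] == d[2] && d[2] == d[3])
  h <- .mrc_header_template(d[1], d[2], d[3], pixel_size,
                            is_volume = volume && d[3] > 1)
  vals <- as.numeric(data)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(c(h$nx, h$ny, h$nz, h$mode, h$nxstart, h$nystart, h$nzstart,
       h$mx, h$my, h$mz))
  wf(c(h$cella, h$cellb))
  wi(c(h$mapc, h$mapr, h$maps))
  wf(c(min(vals), max(vals), mean(vals)))
  wi(c(h$ispg, h$nsymbt))
  wi(rep(0L, 25))                       # extra space incl. extended-header tags
  wf(c(0, 0, 0))                        # origin
  writeChar("MAP ", con, 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  wf(stats::sd(vals))
  wi(0L)                                # nlabl
  writeBin(raw(800), con)               # labels
  wf(vals)
  invisible(path)
}

#' Read an MRC2014 file
#'
#' Reads mode 2 (32-bit float) little-endian files as written by
#' [write_mrc()] and by mainstream cryo-EM software. Volumes (`mz > 1`)
#' come back as 3D arrays, stacks as 3D arrays with a `stack = TRUE`
#' attribute, single images as matrices; the `pixel_size` attribute is
#' recovered from the cell dimensions. Malformed or unsupported headers
#' raise an error naming the offending field.
#'
#' @param path file path.
#' @return the data with attributes `pixel_size`, `stack`.
#' @export
read_mrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n, size = 4, endian = "little")
  rf <- function(n) readBin(con, "numeric", n, size = 4, endian = "little")
  dims <- ri(3)
  mode <- ri(1)
  ri(3)                                 # nxstart..
  m <- ri(3)
  cella <- rf(3)
  rf(3)                                 # cellb
  mapcrs <- ri(3)
  rf(3)                                 # dmin dmax dmean
  ri(2)                                 # ispg nsymbt
  ri(25)
  rf(3)                                 # origin
  magic <- readChar(con, 4, useBytes = TRUE)
  stamp <- readBin(con, "raw", 4)
  rf(1)                                 # rms
  ri(1)                                 # nlabl
  readBin(con, "raw", 800)

  if (!identical(magic, "MAP "))
    stop("not an MRC2014 file: map magic is ", deparse(magic))
  if (!(as.integer(stamp[1]) %in% c(0x44)))
    stop("unsupported machine stamp (not little-endian): ",
         paste(sprintf("%02x", as.integer(stamp)), collapse = " "))
  if (any(dims <= 0) || any(dims > 1e5))
    stop("implausible dimensions nx/ny/nz: ", paste(dims, collapse = "x"))
  if (mode != 2L)
    stop("unsupported mode ", mode, " (only mode 2, float32, is handled)")
  if (!identical(mapcrs, c(1L, 2L, 3L)))
    stop("unsupported axis order mapc/mapr/maps: ",
         paste(mapcrs, collapse = ","))

  nvals <- prod(dims)
  vals <- rf(nvals)
  if (length(vals) != nvals)
    stop("truncated data section: expected ", nvals, " values, read ",
         length(vals))
  apix <- if (m[1] > 0 && cella[1] > 0) cella[1] / m[1] else 1
  is_stack <- dims[3] > 1 && m[3] == 1L
  out <- if (dims[3] == 1) matrix(vals, dims[1], dims[2]) else
    array(vals, dims)
  structure(out, pixel_size = apix, stack = is_stack)
}
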