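#' Construct a point cloud
#'
#' A point cloud is a data frame with numeric columns \code{x}, \code{y},
#' \code{z} (meters, z-up, right-handed) and an optional \code{intensity}
#' column (unitless reflectance amplitude). All coordinates must be finite.
#'
#' @param x,y,z numeric coordinate vectors of equal length, in meters.
#' @param intensity optional numeric vector, one value per point.
#' @return an object of class \code{point_cloud} (a data frame).
#' @export
point_cloud <- function(x, y, z, intensity = NULL) {
  x <- as.numeric(x); y <- as.numeric(y); z <- as.numeric(z)
  n <- length(x)
  if (length(y) != n || length(z) != n)
    stop("x, y, z must have equal length", call. = FALSE)
  if (n > 0 && !all(is.finite(x), is.finite(y), is.finite(z)))
    stop("point coordinates must all be finite", call. = FALSE)
  df <- data.frame(x = x, y = y, z = z)
  if (!is.null(intensity)) {
    if (length(intensity) != n)
      stop("intensity must have one value per point", call. = FALSE)
    df$intensity <- as.numeric(intensity)
  }
  class(df) <- c("point_cloud", "data.frame")
  df
}

#' Coerce a matrix or data frame to a point cloud
#' @param x matrix (>= 3 columns: x, y, z, optional intensity) or data frame
#'   with columns x, y, z and optionally intensity.
#' @return a \code{point_cloud}.
#' @export
as_point_cloud <- function(x) {
  if (inherits(x, "point_cloud")) return(x)
  if (is.matrix(x)) {
    intens <- if (ncol(x) >= 4) x[, 4] else NULL
    return(point_cloud(x[, 1], x[, 2], x[, 3], intens))
  }
  point_cloud(x$x, x$y, x$z, x$intensity)
}

#' Number of points in a cloud
#' @param cloud a \code{point_cloud}.
#' @return integer point count.
#' @export
n_points <- function(cloud) nrow(cloud)

#' Coordinate matrix of a cloud
#' @param cloud a \code{point_cloud}.
#' @return n x 3 numeric matrix with columns x, y, z.
#' @export
xyz_matrix <- function(cloud) {
  cbind(x = cloud$x, y = cloud$y, z = cloud$z)
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("point_cloud: %d points%s\n", nrow(x),
              if ("intensity" %in% names(x)) " (with intensity)" else ""))
  if (nrow(x) > 0) {
    r <- apply(xyz_matrix(x), 2, range)
    cat(sprintf("  x: [%.3f, %.3f] m  y: [%.3f, %.3f] m  z: [%.3f, %.3f] m\n",
                r[1, 1], r[2, 1], r[1, 2], r[2, 2], r[1, 3], r[2, 3]))
  }
  invisible(x)
}

stop_if_empty <- function(cloud, what = "operation") {
  if (nrow(cloud) == 0)
    stop(sprintf("empty point cloud passed to %s", what), call. = FALSE)
  invisible(cloud)
}

infer_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         las = "las", laz = "las",
         ply = "ply",
         xyz = "xyz", txt = "xyz", csv = "xyz",
         stop(sprintf("cannot infer point-cloud format from extension '.%s'", ext),
              call. = FALSE))
}

#' Read a point cloud from disk
#'
#' Supported formats: \code{xyz} text (whitespace- or comma-separated
#' \code{x y z [intensity]}, lines starting with \code{#} ignored), \code{ply}
#' (ascii and binary_little_endian), and \code{las} (LAS 1.2+, point record
#' formats 0--3; the header's scale and offset are honored). Coordinates are
#' meters; stored point order is preserved.
#'
#' @param path file path.
#' @param format one of \code{"las"}, \code{"ply"}, \code{"xyz"}; inferred
#'   from the extension when missing.
#' @return a \code{point_cloud}.
#' @export
read_point_cloud <- function(path, format = infer_format(path)) {
  if (!file.exists(path))
    stop(sprintf("point-cloud file not found: %s", path), call. = FALSE)
  format <- match.arg(format, c("las", "ply", "xyz"))
  cloud <- switch(format,
                  xyz = read_xyz(path),
                  ply = read_ply(path),
                  las = read_las(path))
  if (nrow(cloud) == 0)
    stop(sprintf("empty point cloud: %s", path), call. = FALSE)
  cloud
}

#' Write a point cloud to disk
#'
#' Round-trips through \code{\link{read_point_cloud}} with coordinates
#' preserved to 0.1 mm or better (LAS uses a 0.0001 m quantization step;
#' xyz and PLY store more digits).
#'
#' @param cloud a non-empty \code{point_cloud}.
#' @param path output file path.
#' @param format one of \code{"las"}, \code{"ply"}, \code{"xyz"}.
#' @param binary for PLY: write binary_little_endian instead of ascii.
#' @export
write_point_cloud <- function(cloud, path, format = infer_format(path),
                              binary = FALSE) {
  cloud <- as_point_cloud(cloud)
  stop_if_empty(cloud, "write_point_cloud")
  format <- match.arg(format, c("las", "ply", "xyz"))
  switch(format,
         xyz = write_xyz(cloud, path),
         ply = write_ply(cloud, path, binary = binary),
         las = write_las(cloud, path))
  invisible(path)
}

## -- xyz text dialect -------------------------------------------------------

read_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lines <- lines[keep]
  if (length(lines) == 0) return(point_cloud(numeric(0), numeric(0), numeric(0)))
  lines <- gsub(",", " ", lines, fixed = TRUE)
  toks <- strsplit(trimws(lines), "\\s+")
  nf <- lengths(toks)
  if (any(nf < 3)) {
    bad <- which(keep)[which(nf < 3)[1]]
    stop(sprintf("xyz parse error at line %d of %s: fewer than 3 fields",
                 bad, path), call. = FALSE)
  }
  vals <- suppressWarnings(lapply(toks, function(t) as.numeric(t[1:min(4, length(t))])))
  m <- do.call(rbind, lapply(vals, function(v) c(v, rep(NA_real_, 4 - length(v)))))
  if (anyNA(m[, 1:3])) {
    bad <- which(keep)[which(apply(is.na(m[, 1:3, drop = FALSE]), 1, any))[1]]
    stop(sprintf("xyz parse error at line %d of %s: non-numeric coordinate",
                 bad, path), call. = FALSE)
  }
  intens <- if (all(nf >= 4) && !anyNA(m[, 4])) m[, 4] else NULL
  point_cloud(m[, 1], m[, 2], m[, 3], intens)
}

write_xyz <- function(cloud, path) {
  m <- xyz_matrix(cloud)
  if ("intensity" %in% names(cloud)) m <- cbind(m, cloud$intensity)
  lines <- apply(m, 1, function(r) paste(sprintf("%.6f", r), collapse = " "))
  writeLines(lines, path)
}

## -- PLY --------------------------------------------------------------------

ply_type_size <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
                   short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
                   int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
                   float = 4L, float32 = 4L, double = 8L, float64 = 8L)

read_ply_binval <- function(con, type, n) {
  switch(type,
         char = , int8 = readBin(con, "integer", n, size = 1, signed = TRUE),
         uchar = , uint8 = readBin(con, "integer", n, size = 1, signed = FALSE),
         short = , int16 = readBin(con, "integer", n, size = 2, signed = TRUE,
                                   endian = "little"),
         ushort = , uint16 = readBin(con, "integer", n, size = 2, signed = FALSE,
                                     endian = "little"),
         int = , int32 = , uint = , uint32 =
           readBin(con, "integer", n, size = 4, endian = "little"),
         float = , float32 = readBin(con, "double", n, size = 4, endian = "little"),
         double = , float64 = readBin(con, "double", n, size = 8, endian = "little"),
         stop(sprintf("unsupported PLY property type '%s'", type), call. = FALSE))
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1)
  if (!identical(trimws(magic), "ply"))
    stop(sprintf("not a PLY file: %s", path), call. = FALSE)
  fmt <- NULL; elements <- list(); cur <- NULL
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0)
      stop(sprintf("PLY header of %s ends before end_header", path), call. = FALSE)
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(tok) == 0 || tok[1] == "comment") next
    if (tok[1] == "format") {
      fmt <- tok[2]
    } else if (tok[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2], count = as.integer(tok[3]),
                  props = character(0), types = character(0))
    } else if (tok[1] == "property") {
      if (tok[2] == "list")
        stop(sprintf("PLY list properties not supported (%s)", path), call. = FALSE)
      cur$types <- c(cur$types, tok[2])
      cur$props <- c(cur$props, tok[3])
    } else if (tok[1] == "end_header") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      break
    }
  }
  if (!"vertex" %in% names(elements))
    stop(sprintf("PLY file %s has no vertex element", path), call. = FALSE)
  if (is.null(fmt) || !fmt %in% c("ascii", "binary_little_endian"))
    stop(sprintf("unsupported PLY format '%s' in %s", fmt, path), call. = FALSE)
  vert <- elements$vertex
  if (fmt == "ascii") {
    rows <- readLines(con, n = vert$count)
    m <- do.call(rbind, lapply(strsplit(trimws(rows), "\\s+"), as.numeric))
    colnames(m) <- vert$props
  } else {
    # read record-wise: properties may mix sizes
    np <- length(vert$props)
    m <- matrix(NA_real_, nrow = vert$count, ncol = np,
                dimnames = list(NULL, vert$props))
    same <- length(unique(vert$types)) == 1
    if (same) {
      vals <- read_ply_binval(con, vert$types[1], vert$count * np)
      m[] <- matrix(vals, ncol = np, byrow = TRUE)
    } else {
      for (i in seq_len(vert$count))
        for (j in seq_len(np))
          m[i, j] <- read_ply_binval(con, vert$types[j], 1)
    }
  }
  ix <- match(c("x", "y", "z"), colnames(m))
  if (anyNA(ix))
    stop(sprintf("PLY vertex element of %s lacks x/y/z", path), call. = FALSE)
  intens <- if ("intensity" %in% colnames(m)) m[, "intensity"] else NULL
  point_cloud(m[, ix[1]], m[, ix[2]], m[, ix[3]], intens)
}

write_ply <- function(cloud, path, binary = FALSE) {
  has_int <- "intensity" %in% names(cloud)
  hdr <- c("ply",
           sprintf("format %s 1.0",
                   if (binary) "binary_little_endian" else "ascii"),
           sprintf("element vertex %d", nrow(cloud)),
           "property double x", "property double y", "property double z",
           if (has_int) "property double intensity",
           "end_header")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con)
  m <- xyz_matrix(cloud)
  if (has_int) m <- cbind(m, cloud$intensity)
  if (binary) {
    writeBin(as.numeric(t(m)), con, size = 8, endian = "little")
  } else {
    writeLines(apply(m, 1, function(r) paste(sprintf("%.9f", r), collapse = " ")),
               con)
  }
}

## -- LAS 1.2 ----------------------------------------------------------------

las_point_size <- c(`0` = 20L, `1` = 28L, `2` = 26L, `3` = 34L)

read_las <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  sig <- rawToChar(readBin(con, "raw", 4))
  if (!identical(sig, "LASF"))
    stop(sprintf("not a LAS file (bad signature): %s", path), call. = FALSE)
  seek(con, 24)
  ver <- readBin(con, "integer", 2, size = 1, signed = FALSE)
  if (ver[1] != 1)
    stop(sprintf("unsupported LAS major version %d in %s", ver[1], path),
         call. = FALSE)
  seek(con, 96)
  offset_to_points <- readBin(con, "integer", 1, size = 4, endian = "little")
  readBin(con, "integer", 1, size = 4, endian = "little")  # n VLRs
  pdrf <- readBin(con, "integer", 1, size = 1, signed = FALSE)
  rec_len <- readBin(con, "integer", 1, size = 2, signed = FALSE, endian = "little")
  npts <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (!as.character(pdrf) %in% names(las_point_size))
    stop(sprintf("unsupported LAS point data format %d in %s", pdrf, path),
         call. = FALSE)
  seek(con, 131)  # skip returns-by-count (5 x uint32 at offset 111)
  scale <- readBin(con, "double", 3, size = 8, endian = "little")
  off <- readBin(con, "double", 3, size = 8, endian = "little")
  seek(con, offset_to_points)
  raw_all <- readBin(con, "raw", npts * rec_len)
  if (length(raw_all) < npts * rec_len)
    stop(sprintf("LAS file %s truncated: expected %d point records", path, npts),
         call. = FALSE)
  recm <- matrix(raw_all, nrow = rec_len)
  int_from_raw <- function(rows, signed) {
    sub <- recm[rows, , drop = FALSE]
    readBin(as.vector(sub), "integer", n = npts, size = length(rows),
            signed = signed, endian = "little")
  }
  X <- int_from_raw(1:4, TRUE)
  Y <- int_from_raw(5:8, TRUE)
  Z <- int_from_raw(9:12, TRUE)
  intens <- int_from_raw(13:14, FALSE)
  point_cloud(X * scale[1] + off[1], Y * scale[2] + off[2], Z * scale[3] + off[3],
              if (any(intens != 0)) intens else NULL)
}

write_las <- function(cloud, path) {
  m <- xyz_matrix(cloud)
  scale <- rep(1e-4, 3)                      # 0.1 mm quantization
  off <- floor(apply(m, 2, min))
  X <- as.integer(round((m[, 1] - off[1]) / scale[1]))
  Y <- as.integer(round((m[, 2] - off[2]) / scale[2]))
  Z <- as.integer(round((m[, 3] - off[3]) / scale[3]))
  intens <- if ("intensity" %in% names(cloud))
    as.integer(pmax(0, pmin(65535, round(cloud$intensity)))) else
    integer(nrow(cloud))
  n <- nrow(cloud)
  hdr_size <- 227L; rec_len <- 20L
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("LASF"), con)
  writeBin(raw(20), con)                     # source id .. GUID etc.
  writeBin(as.raw(c(1L, 2L)), con)           # version 1.2
  sysid <- charToRaw(formatC("canopymotion", width = 32, flag = "-"))
  gensw <- charToRaw(formatC("canopymotion", width = 32, flag = "-"))
  writeBin(sysid, con); writeBin(gensw, con)
  writeBin(as.integer(c(1L, 2026L)), con, size = 2, endian = "little")
  writeBin(as.integer(hdr_size), con, size = 2, endian = "little")
  writeBin(as.integer(hdr_size), con, size = 4, endian = "little")  # offset to points
  writeBin(0L, con, size = 4, endian = "little")                    # no VLRs
  writeBin(as.raw(0L), con)                                         # PDRF 0
  writeBin(as.integer(rec_len), con, size = 2, endian = "little")
  writeBin(as.integer(n), con, size = 4, endian = "little")
  writeBin(as.integer(c(n, 0L, 0L, 0L, 0L)), con, size = 4, endian = "little")
  writeBin(scale, con, size = 8, endian = "little")
  writeBin(as.numeric(off), con, size = 8, endian = "little")
  mx <- apply(m, 2, max); mn <- apply(m, 2, min)
  writeBin(as.numeric(c(mx[1], mn[1], mx[2], mn[2], mx[3], mn[3])), con,
           size = 8, endian = "little")
  rec <- matrix(raw(0), nrow = rec_len, ncol = 0)
  to_raw4 <- function(v) matrix(writeBin(v, raw(), size = 4, endian = "little"),
                                nrow = 4)
  to_raw2 <- function(v) matrix(writeBin(v, raw(), size = 2, endian = "little"),
                                nrow = 2)
  body <- rbind(to_raw4(X), to_raw4(Y), to_raw4(Z), to_raw2(intens),
                matrix(as.raw(0), nrow = 6, ncol = n))
  writeBin(as.vector(body), con)
}

## -- scan records and series ------------------------------------------------

#' Construct a scan record
#' @param scan_id character identifier, unique within a series.
#' @param timestamp POSIXct (or anything \code{as.POSIXct} accepts, UTC).
#' @param cloud a \code{point_cloud}.
#' @return a \code{scan_record}.
#' @export
scan_record <- function(scan_id, timestamp, cloud) {
  if (is.character(timestamp))  # accept ISO-8601 "T" separator
    timestamp <- sub("T", " ", timestamp, fixed = TRUE)
  structure(list(scan_id = as.character(scan_id),
                 timestamp = as.POSIXct(timestamp, tz = "UTC"),
                 cloud = as_point_cloud(cloud)),
            class = "scan_record")
}

#' Construct a scan series
#'
#' An ordered, timestamped sequence of co-registered (or to-be-registered)
#' scans sharing one coordinate frame. Records are sorted by timestamp;
#' duplicate timestamps or scan ids are rejected.
#'
#' @param records list of \code{scan_record}s.
#' @param frame_of_reference character tag naming the shared frame.
#' @return a \code{scan_series}.
#' @export
scan_series <- function(records, frame_of_reference = "scanner") {
  stopifnot(length(records) >= 1)
  ts <- as.POSIXct(vapply(records, function(r) as.numeric(r$timestamp), 0),
                   origin = "1970-01-01", tz = "UTC")
  ord <- order(ts)
  records <- records[ord]; ts <- ts[ord]
  if (any(diff(as.numeric(ts)) <= 0))
    stop("scan timestamps must be strictly increasing (duplicates present)",
         call. = FALSE)
  ids <- vapply(records, `[[`, "", "scan_id")
  if (anyDuplicated(ids))
    stop(sprintf("duplicate scan_id in series: %s", ids[duplicated(ids)][1]),
         call. = FALSE)
  structure(list(records = records,
                 frame_of_reference = as.character(frame_of_reference)),
            class = "scan_series")
}

#' @export
length.scan_series <- function(x) length(x$records)

#' @export
print.scan_series <- function(x, ...) {
  ts <- series_times(x)
  cat(sprintf("scan_series: %d scans over %.2f h (frame '%s')\n",
              length(x), diff(range(as.numeric(ts))) / 3600,
              x$frame_of_reference))
  invisible(x)
}

#' Scan ids of a series
#' @param series a \code{scan_series}.
#' @return character vector.
#' @export
series_ids <- function(series) vapply(series$records, `[[`, "", "scan_id")

#' Timestamps of a series
#' @param series a \code{scan_series}.
#' @return POSIXct vector.
#' @export
series_times <- function(series) {
  as.POSIXct(vapply(series$records, function(r) as.numeric(r$timestamp), 0),
             origin = "1970-01-01", tz = "UTC")
}

#' Hours since the first scan
#' @param series a \code{scan_series}.
#' @return numeric vector, first element 0.
#' @export
series_hours <- function(series) {
  t <- as.numeric(series_times(series))
  (t - t[1]) / 3600
}

#' Load a scan series from a manifest
#'
#' The manifest is a CSV with header \code{scan_id,timestamp,path}
#' (ISO-8601 timestamps; paths relative to the manifest's directory or
#' absolute). Rows may appear in any order; the returned series is sorted by
#' timestamp and duplicate timestamps are an error.
#'
#' @param manifest_path path to the manifest CSV.
#' @param frame_of_reference frame tag for the resulting series.
#' @return a \code{scan_series}.
#' @export
load_scan_series <- function(manifest_path, frame_of_reference = "scanner") {
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  need <- c("scan_id", "timestamp", "path")
  if (!all(need %in% names(man)))
    stop(sprintf("manifest must have columns %s", paste(need, collapse = ", ")),
         call. = FALSE)
  base <- dirname(normalizePath(manifest_path))
  records <- lapply(seq_len(nrow(man)), function(i) {
    p <- man$path[i]
    if (!file.exists(p)) p <- file.path(base, man$path[i])
    if (!file.exists(p))
      stop(sprintf("scan '%s': point-cloud file not found: %s",
                   man$scan_id[i], man$path[i]), call. = FALSE)
    scan_record(man$scan_id[i], man$timestamp[i], read_point_cloud(p))
  })
  scan_series(records, frame_of_reference)
}
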