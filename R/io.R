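#' Read a point cloud from file
#'
#' Supported dialects:
#' \describe{
#'   \item{`xyz` / `labeled-matrix`}{Whitespace- or comma-delimited text,
#'     one point per row: `x y z [label [instance]]`, coordinates in meters.
#'     Lines starting with `#` are treated as comments/header.  A 4th column
#'     becomes the binary semantic label (0 = branch, 1 = leaf), a 5th the
#'     instance id.}
#'   \item{`ply`}{Stanford PLY, ASCII or binary_little_endian.  Vertex
#'     properties `x`, `y`, `z` are required; scalar properties named
#'     `label`/`semantic` and `instance` are picked up when present.}
#'   \item{`pcd`}{PCL PCD, `DATA ascii`, with fields `x y z [label
#'     [instance]]`.}
#' }
#'
#' @param path path to the file.
#' @param format one of `"auto"`, `"xyz"`, `"labeled-matrix"`, `"ply"`,
#'   `"pcd"`.  `"auto"` dispatches on the file extension.
#' @return A [leaf_cloud()].
#' @seealso [write_cloud()]
#' @export
read_cloud <- function(path, format = c("auto", "xyz", "labeled-matrix",
                                        "ply", "pcd")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, ply = "ply", pcd = "pcd", "xyz")
  }
  switch(format,
         ply = read_ply(path),
         pcd = read_pcd(path),
         read_labeled_matrix(path))
}

#' Write a point cloud to file
#'
#' @inheritParams read_cloud
#' @param cloud a [leaf_cloud()].
#' @return `path`, invisibly.
#' @export
write_cloud <- function(cloud, path, format = c("auto", "xyz",
                                                "labeled-matrix", "ply",
                                                "pcd")) {
  stopifnot(inherits(cloud, "leaf_cloud"))
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, ply = "ply", pcd = "pcd", "xyz")
  }
  switch(format,
         ply = write_ply(cloud, path),
         pcd = write_pcd(cloud, path),
         write_labeled_matrix(cloud, path))
  invisible(path)
}

read_labeled_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  if (!any(keep)) stop("parse error in ", path, ": file has no data rows")
  lineno <- which(keep)
  rows <- strsplit(trimws(gsub(",", " ", lines[keep])), "\\s+")
  ncols <- lengths(rows)
  if (any(ncols != ncols[1])) {
    bad <- which(ncols != ncols[1])[1]
    stop("parse error in ", path, " at line ", lineno[bad],
         ": expected ", ncols[1], " columns, found ", ncols[bad])
  }
  if (ncols[1] < 3L || ncols[1] > 5L)
    stop("parse error in ", path, " at line ", lineno[1],
         ": need 3-5 columns (x y z [label [instance]])")
  m <- matrix(suppressWarnings(as.numeric(unlist(rows))),
              nrow = length(rows), byrow = TRUE)
  if (anyNA(m)) {
    bad <- which(apply(m, 1, anyNA))[1]
    stop("parse error in ", path, " at line ", lineno[bad],
         ": non-numeric value")
  }
  semantic <- NULL
  instance <- NULL
  if (ncol(m) >= 4L) {
    if (!all(m[, 4] %in% c(0, 1))) {
      bad <- which(!(m[, 4] %in% c(0, 1)))[1]
      stop("parse error in ", path, " at line ", lineno[bad],
           ": semantic label must be 0 or 1, found ", m[bad, 4])
    }
    semantic <- as.integer(m[, 4])
  }
  if (ncol(m) == 5L) instance <- as.integer(m[, 5])
  leaf_cloud(m[, 1:3, drop = FALSE], semantic = semantic, instance = instance)
}

write_labeled_matrix <- function(cloud, path) {
  m <- cloud$coords
  if (!is.null(cloud$semantic)) {
    m <- cbind(m, cloud$semantic)
    if (!is.null(cloud$instance)) m <- cbind(m, cloud$instance)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# x y z [label [instance]]", con)
  utils::write.table(m, con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character()
  repeat {
    ln <- readLines(con, n = 1L)
    if (!length(ln)) stop("parse error in ", path, ": truncated PLY header")
    hdr <- c(hdr, ln)
    if (trimws(ln) == "end_header") break
    if (length(hdr) > 200L) stop("parse error in ", path, ": no end_header")
  }
  if (!grepl("^ply", hdr[1])) stop("parse error in ", path, ": not a PLY file")
  fmt_line <- grep("^format ", hdr, value = TRUE)[1]
  fmt <- strsplit(trimws(fmt_line), "\\s+")[[1]][2]
  # vertex element and its properties (other elements are skipped on read)
  el <- grep("^element ", hdr)
  vline <- grep("^element vertex ", hdr)
  if (!length(vline)) stop("parse error in ", path, ": no vertex element")
  nvert <- as.integer(strsplit(trimws(hdr[vline[1]]), "\\s+")[[1]][3])
  nxt <- el[el > vline[1]]
  pend <- if (length(nxt)) nxt[1] else length(hdr)
  props <- hdr[(vline[1] + 1):(pend - 1)]
  props <- props[grepl("^property ", props)]
  ptypes <- vapply(strsplit(trimws(props), "\\s+"), `[`, "", 2)
  pnames <- vapply(strsplit(trimws(props), "\\s+"), `[`, "", 3)
  if (!all(c("x", "y", "z") %in% pnames))
    stop("parse error in ", path, ": PLY vertex needs x, y, z properties")
  if (fmt == "ascii") {
    vals <- scan(con, what = double(), n = nvert * length(pnames),
                 quiet = TRUE)
    m <- matrix(vals, ncol = length(pnames), byrow = TRUE)
  } else if (fmt == "binary_little_endian") {
    sizes <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
               short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
               int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
               float = 4L, float32 = 4L, double = 8L, float64 = 8L)
    if (!all(ptypes %in% names(sizes)))
      stop("parse error in ", path, ": unsupported PLY property type")
    m <- matrix(0, nvert, length(pnames))
    for (i in seq_len(nvert)) {
      for (j in seq_along(pnames)) {
        tp <- ptypes[j]
        m[i, j] <- if (tp %in% c("float", "float32", "double", "float64")) {
          readBin(con, "double", 1L, size = sizes[[tp]], endian = "little")
        } else {
          readBin(con, "integer", 1L, size = sizes[[tp]],
                  signed = !(tp %in% c("uchar", "uint8", "ushort", "uint16")),
                  endian = "little")
        }
      }
    }
  } else {
    stop("parse error in ", path, ": unsupported PLY format ", fmt)
  }
  coords <- m[, match(c("x", "y", "z"), pnames), drop = FALSE]
  sem_col <- match(c("label", "semantic"), pnames)
  sem_col <- sem_col[!is.na(sem_col)][1]
  inst_col <- match("instance", pnames)
  leaf_cloud(coords,
             semantic = if (!is.na(sem_col)) as.integer(m[, sem_col]),
             instance = if (!is.na(inst_col)) as.integer(m[, inst_col]))
}

write_ply <- function(cloud, path) {
  n <- nrow(cloud$coords)
  hdr <- c("ply", "format ascii 1.0",
           sprintf("element vertex %d", n),
           "property double x", "property double y", "property double z")
  m <- cloud$coords
  if (!is.null(cloud$semantic)) {
    hdr <- c(hdr, "property int label")
    m <- cbind(m, cloud$semantic)
  }
  if (!is.null(cloud$instance)) {
    hdr <- c(hdr, "property int instance")
    m <- cbind(m, cloud$instance)
  }
  hdr <- c(hdr, "end_header")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(m, con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
}

read_pcd <- function(path) {
  lines <- readLines(path, warn = FALSE)
  di <- grep("^DATA ", lines)
  if (!length(di)) stop("parse error in ", path, ": no DATA line in PCD")
  if (!grepl("^DATA ascii", lines[di[1]]))
    stop("parse error in ", path, ": only DATA ascii PCD is supported")
  fi <- grep("^FIELDS ", lines)
  if (!length(fi)) stop("parse error in ", path, ": no FIELDS line in PCD")
  fields <- strsplit(trimws(lines[fi[1]]), "\\s+")[[1]][-1]
  if (!all(c("x", "y", "z") %in% fields))
    stop("parse error in ", path, ": PCD needs x, y, z fields")
  body <- lines[(di[1] + 1):length(lines)]
  body <- body[!grepl("^\\s*$", body)]
  rows <- strsplit(trimws(body), "\\s+")
  if (any(lengths(rows) != length(fields))) {
    bad <- which(lengths(rows) != length(fields))[1]
    stop("parse error in ", path, " at data row ", bad,
         ": expected ", length(fields), " values")
  }
  m <- matrix(as.numeric(unlist(rows)), nrow = length(rows), byrow = TRUE)
  sem_col <- match(c("label", "semantic"), fields)
  sem_col <- sem_col[!is.na(sem_col)][1]
  inst_col <- match("instance", fields)
  if (!is.na(sem_col) && !all(m[, sem_col] %in% c(0, 1)))
    stop("parse error in ", path, ": semantic label must be 0 or 1")
  leaf_cloud(m[, match(c("x", "y", "z"), fields), drop = FALSE],
             semantic = if (!is.na(sem_col)) as.integer(m[, sem_col]),
             instance = if (!is.na(inst_col)) as.integer(m[, inst_col]))
}

write_pcd <- function(cloud, path) {
  n <- nrow(cloud$coords)
  fields <- c("x", "y", "z")
  m <- cloud$coords
  if (!is.null(cloud$semantic)) {
    fields <- c(fields, "label")
    m <- cbind(m, cloud$semantic)
  }
  if (!is.null(cloud$instance)) {
    fields <- c(fields, "instance")
    m <- cbind(m, cloud$instance)
  }
  k <- length(fields)
  hdr <- c("# .PCD v0.7 - Point Cloud Data file format",
           "VERSION 0.7",
           paste("FIELDS", paste(fields, collapse = " ")),
           paste("SIZE", paste(rep(8, k), collapse = " ")),
           paste("TYPE", paste(rep("F", k), collapse = " ")),
           paste("COUNT", paste(rep(1, k), collapse = " ")),
           sprintf("WIDTH %d", n), "HEIGHT 1",
           "VIEWPOINT 0 0 0 1 0 0 0",
           sprintf("POINTS %d", n), "DATA ascii")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(m, con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
}
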