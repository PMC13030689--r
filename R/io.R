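#' Read a point cloud from PLY, OBJ or XYZ
#'
#' Format is inferred from the file extension (`.ply`, `.obj`, anything else
#' is treated as whitespace-separated XYZ). PLY supports ascii and
#' binary_little_endian encodings with float/double/int vertex properties;
#' properties beyond x, y, z are returned as feature channels. OBJ parsing
#' uses vertex (`v`) records only.
#'
#' @param path file path.
#' @return A `pm_cloud` (positions in mm; extra PLY vertex properties as
#'   named feature channels).
#' @export
pm_read_cloud <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         ply = read_ply(path),
         obj = read_obj(path),
         read_xyz(path))
}

#' Write a point cloud to PLY, OBJ or XYZ
#'
#' @param cloud a `pm_cloud`.
#' @param path output path; extension selects the format as in
#'   [pm_read_cloud()].
#' @param binary for PLY only: write binary_little_endian float32 instead of
#'   ascii.
#' @param labels optional `pm_labels` to embed as an extra `label` vertex
#'   property (PLY) or to ignore for OBJ/XYZ (use [pm_write_labels()]).
#' @return `path`, invisibly.
#' @export
pm_write_cloud <- function(cloud, path, binary = FALSE, labels = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (!is.null(labels) && length(labels) != pm_n_points(cloud)) {
    stop("labels must be aligned with the cloud")
  }
  switch(ext,
         ply = write_ply(cloud, path, binary = binary, labels = labels),
         obj = write_obj(cloud, path),
         write_xyz(cloud, path))
  invisible(path)
}

ply_prop_size <- function(type) {
  switch(type,
         char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
         short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
         int = 4L, uint = 4L, int32 = 4L, uint32 = 4L, float = 4L, float32 = 4L,
         double = 8L, float64 = 8L,
         stop("unsupported PLY property type: ", type))
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character()
  repeat {
    line <- readLines(con, n = 1L)
    if (!length(line)) stop("unexpected end of PLY header")
    header <- c(header, line)
    if (trimws(line) == "end_header") break
  }
  if (trimws(header[1]) != "ply") stop("not a PLY file: ", path)
  fmt_line <- grep("^format", header, value = TRUE)[1]
  fmt <- strsplit(trimws(fmt_line), "\\s+")[[1]][2]
  if (!fmt %in% c("ascii", "binary_little_endian")) {
    stop("unsupported PLY format: ", fmt)
  }
  # collect elements in declared order; only 'vertex' is decoded
  elems <- list()
  cur <- NULL
  for (line in header) {
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (tok[1] == "element") {
      if (!is.null(cur)) elems[[cur$name]] <- cur
      cur <- list(name = tok[2], count = as.integer(tok[3]),
                  props = character(), types = character(), list_prop = logical())
    } else if (tok[1] == "property" && !is.null(cur)) {
      if (tok[2] == "list") {
        cur$props <- c(cur$props, tok[5])
        cur$types <- c(cur$types, tok[4])
        cur$list_prop <- c(cur$list_prop, TRUE)
      } else {
        cur$props <- c(cur$props, tok[3])
        cur$types <- c(cur$types, tok[2])
        cur$list_prop <- c(cur$list_prop, FALSE)
      }
    }
  }
  if (!is.null(cur)) elems[[cur$name]] <- cur
  if (is.null(elems$vertex)) stop("PLY file has no vertex element")

  vert <- NULL
  if (fmt == "ascii") {
    for (el in elems) {
      lines <- readLines(con, n = el$count)
      if (el$name == "vertex") {
        if (any(el$list_prop)) stop("list properties on vertices are unsupported")
        vals <- scan(text = lines, quiet = TRUE)
        vert <- matrix(vals, ncol = length(el$props), byrow = TRUE,
                       dimnames = list(NULL, el$props))
        break  # vertex decoded; trailing elements not needed
      }
    }
  } else {
    for (el in elems) {
      if (el$name == "vertex") {
        if (any(el$list_prop)) stop("list properties on vertices are unsupported")
        sizes <- vapply(el$types, ply_prop_size, integer(1))
        stride <- sum(sizes)
        raw <- readBin(con, "raw", n = el$count * stride)
        if (length(raw) < el$count * stride) stop("truncated PLY vertex data")
        vert <- matrix(0, el$count, length(el$props),
                       dimnames = list(NULL, el$props))
        off <- cumsum(c(0L, sizes[-length(sizes)]))
        for (j in seq_along(el$props)) {
          byte_idx <- as.vector(outer(seq_len(sizes[j]),
                                      (seq_len(el$count) - 1L) * stride + off[j], "+"))
          col_raw <- raw[byte_idx]
          type <- el$types[j]
          vert[, j] <- if (type %in% c("float", "float32", "double", "float64")) {
            readBin(col_raw, "double", n = el$count, size = sizes[j], endian = "little")
          } else {
            readBin(col_raw, "integer", n = el$count, size = sizes[j],
                    endian = "little", signed = !grepl("^u", type))
          }
        }
        break
      } else {
        if (any(el$list_prop)) break  # cannot skip variable-size element before vertex
        stride <- sum(vapply(el$types, ply_prop_size, integer(1)))
        invisible(readBin(con, "raw", n = el$count * stride))
      }
    }
  }
  if (is.null(vert)) stop("failed to decode PLY vertex element")
  need <- c("x", "y", "z")
  if (!all(need %in% colnames(vert))) stop("PLY vertex element lacks x/y/z")
  extra <- setdiff(colnames(vert), need)
  pm_cloud(vert[, need, drop = FALSE],
           features = if (length(extra)) vert[, extra, drop = FALSE] else NULL)
}

write_ply <- function(cloud, path, binary = FALSE, labels = NULL) {
  P <- cloud$positions
  n <- nrow(P)
  props <- c("property float x", "property float y", "property float z")
  if (!is.null(labels)) props <- c(props, "property int label")
  header <- c("ply",
              sprintf("format %s 1.0", if (binary) "binary_little_endian" else "ascii"),
              sprintf("element vertex %d", n), props, "end_header")
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(header, con)
    if (is.null(labels)) {
      m <- t(P)
      writeBin(as.vector(m), con, size = 4L, endian = "little")
    } else {
      # interleave per-vertex: 3 float32 + 1 int32
      for (i in seq_len(n)) {
        writeBin(P[i, ], con, size = 4L, endian = "little")
        writeBin(as.integer(labels[i]), con, size = 4L, endian = "little")
      }
    }
  } else {
    body <- if (is.null(labels)) {
      sprintf("%.6f %.6f %.6f", P[, 1], P[, 2], P[, 3])
    } else {
      sprintf("%.6f %.6f %.6f %d", P[, 1], P[, 2], P[, 3], as.integer(labels))
    }
    writeLines(c(header, body), path)
  }
  invisible(path)
}

read_obj <- function(path) {
  lines <- readLines(path)
  v <- grep("^v\\s", lines, value = TRUE)
  if (!length(v)) stop("OBJ file has no vertex records")
  vals <- scan(text = sub("^v\\s+", "", v), quiet = TRUE)
  m <- matrix(vals, ncol = length(vals) / length(v), byrow = TRUE)
  pm_cloud(m[, 1:3, drop = FALSE])
}

write_obj <- function(cloud, path) {
  P <- cloud$positions
  writeLines(sprintf("v %.6f %.6f %.6f", P[, 1], P[, 2], P[, 3]), path)
  invisible(path)
}

read_xyz <- function(path) {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  pm_cloud(m[, 1:3, drop = FALSE])
}

write_xyz <- function(cloud, path) {
  P <- cloud$positions
  writeLines(sprintf("%.6f %.6f %.6f", P[, 1], P[, 2], P[, 3]), path)
  invisible(path)
}

#' Read / write per-point labels as a one-column sidecar text file
#'
#' @param path file path (one integer label per line).
#' @param n_classes,semantics see [pm_labels()].
#' @return `pm_read_labels` returns a `pm_labels`; `pm_write_labels` returns
#'   `path` invisibly.
#' @export
pm_read_labels <- function(path, n_classes = NULL, semantics = "roi") {
  v <- scan(path, what = integer(), quiet = TRUE)
  if (is.null(n_classes)) n_classes <- max(v) + 1L
  pm_labels(v, n_classes, semantics)
}

#' @rdname pm_read_labels
#' @param labels a `pm_labels`.
#' @export
pm_write_labels <- function(labels, path) {
  writeLines(as.character(as.integer(labels)), path)
  invisible(path)
}

#' Read / write landmarks as CSV (columns name, x, y, z; mm)
#'
#' @param path file path.
#' @return `pm_read_landmarks` returns a `pm_landmarks`;
#'   `pm_write_landmarks` returns `path` invisibly.
#' @export
pm_read_landmarks <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "x", "y", "z")
  if (!all(need %in% names(df))) stop("landmark CSV must have columns name,x,y,z")
  m <- as.matrix(df[, c("x", "y", "z")])
  rownames(m) <- df$name
  pm_landmarks(m)
}

#' @rdname pm_read_landmarks
#' @param landmarks a `pm_landmarks`.
#' @param frame frame tag recorded in an extra column when not `NULL`
#'   (e.g. `"scan"` or `"aligned"`).
#' @export
pm_write_landmarks <- function(landmarks, path, frame = NULL) {
  df <- as.data.frame(pm_landmarks_tbl(landmarks))
  if (!is.null(frame)) df$frame <- frame
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
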