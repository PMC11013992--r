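# Reading and writing point-cloud files (XYZL text, PLY) and split manifests.

#' Read a point cloud from an XYZL text file
#'
#' One point per line, `X Y Z` or `X Y Z Label`, separated by whitespace or
#' commas. This is the plain-text interchange format used for labelled
#' orchard scans.
#'
#' @param path file to read.
#' @param has_labels `TRUE` if lines carry a fourth integer label column.
#' @param name scene identifier; defaults to the file name without extension.
#' @return a `point_cloud`.
#' @export
read_xyzl <- function(path, has_labels = TRUE, name = NULL) {
  if (!file.exists(path)) stop_dfseg("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  if (!any(keep)) stop_dfseg("empty point-cloud file: %s", path)
  line_no <- which(keep)
  toks <- strsplit(trimws(lines[keep]), "[,[:space:]]+")
  want <- if (has_labels) 4L else 3L
  nf <- lengths(toks)
  if (any(nf != want)) {
    bad <- which(nf != want)[1L]
    stop_dfseg("parse error at line %d of %s: expected %d fields, found %d",
               line_no[bad], path, want, nf[bad])
  }
  vals <- suppressWarnings(as.numeric(unlist(toks, use.names = FALSE)))
  if (anyNA(vals)) {
    bad <- which(is.na(matrix(vals, ncol = want, byrow = TRUE)), arr.ind = TRUE)[1L, 1L]
    stop_dfseg("parse error at line %d of %s: non-numeric field", line_no[bad], path)
  }
  m <- matrix(vals, ncol = want, byrow = TRUE)
  labels <- NULL
  if (has_labels) {
    lab <- m[, 4L]
    if (any(lab != round(lab))) {
      bad <- which(lab != round(lab))[1L]
      stop_dfseg("label at line %d of %s is not an integer", line_no[bad], path)
    }
    labels <- as.integer(lab)
  }
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  point_cloud(m[, 1:3, drop = FALSE], labels = labels, name = name)
}

#' Write a point cloud to an XYZL text file
#'
#' Space-delimited, coordinates with 6 decimal places, label (if present) as
#' a bare integer. `read_xyzl(write_xyzl(cloud, f))` reproduces labels
#' exactly and coordinates to formatting precision.
#'
#' @param cloud a `point_cloud`.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_xyzl <- function(cloud, path) {
  stopifnot(inherits(cloud, "point_cloud"))
  xyz <- sprintf("%.6f %.6f %.6f", cloud$coords[, 1L], cloud$coords[, 2L], cloud$coords[, 3L])
  lines <- if (is.null(cloud$labels)) xyz else paste(xyz, cloud$labels)
  ok <- tryCatch({ writeLines(lines, path); TRUE }, error = function(e) e)
  if (!isTRUE(ok)) stop_dfseg("cannot write %s: %s", path, conditionMessage(ok))
  invisible(path)
}

# -- PLY ----------------------------------------------------------------------

ply_type_info <- function(types) {
  sizes <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
             short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
             int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
             float = 4L, float32 = 4L, double = 8L, float64 = 8L)
  what <- c(char = "integer", uchar = "integer", int8 = "integer", uint8 = "integer",
            short = "integer", ushort = "integer", int16 = "integer", uint16 = "integer",
            int = "integer", uint = "integer", int32 = "integer", uint32 = "integer",
            float = "double", float32 = "double", double = "double", float64 = "double")
  signed <- !(types %in% c("uchar", "uint8", "ushort", "uint16", "uint", "uint32"))
  if (anyNA(sizes[types])) stop_dfseg("unsupported PLY property type: %s",
                                      paste(setdiff(types, names(sizes)), collapse = ", "))
  list(size = unname(sizes[types]), what = unname(what[types]), signed = signed)
}

#' Read a point cloud from a PLY file
#'
#' Supports `ascii` and `binary_little_endian` PLY dialects. The x/y/z vertex
#' properties become coordinates; an integer-typed property whose name
#' contains "label" or "class" (case-insensitive), if present, becomes the
#' labels. Other elements (faces etc.) are ignored.
#'
#' @param path PLY file.
#' @param name scene identifier; defaults to the file name.
#' @return a `point_cloud`.
#' @export
read_ply <- function(path, name = NULL) {
  if (!file.exists(path)) stop_dfseg("file not found: %s", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!identical(trimws(magic), "ply")) stop_dfseg("%s is not a PLY file", path)
  fmt <- NULL; header <- character()
  repeat {
    ln <- readLines(con, n = 1L)
    if (length(ln) == 0L) stop_dfseg("unterminated PLY header in %s", path)
    header <- c(header, ln)
    if (identical(trimws(ln), "end_header")) break
  }
  toks <- strsplit(trimws(header), "[[:space:]]+")
  elements <- list(); cur <- NULL
  for (tk in toks) {
    if (tk[1L] == "format") fmt <- tk[2L]
    else if (tk[1L] == "element") {
      cur <- tk[2L]
      elements[[cur]] <- list(n = as.integer(tk[3L]), types = character(), names = character())
    } else if (tk[1L] == "property" && !is.null(cur)) {
      if (tk[2L] == "list") {
        elements[[cur]]$types <- c(elements[[cur]]$types, paste("list", tk[3L], tk[4L]))
        elements[[cur]]$names <- c(elements[[cur]]$names, tk[5L])
      } else {
        elements[[cur]]$types <- c(elements[[cur]]$types, tk[2L])
        elements[[cur]]$names <- c(elements[[cur]]$names, tk[3L])
      }
    }
  }
  if (is.null(elements$vertex)) stop_dfseg("PLY file %s has no vertex element", path)
  if (!fmt %in% c("ascii", "binary_little_endian")) {
    stop_dfseg("unsupported PLY format '%s' (ascii and binary_little_endian only)", fmt)
  }
  ve <- elements$vertex
  if (any(startsWith(ve$types, "list"))) stop_dfseg("list-typed vertex properties are not supported")
  vals <- if (fmt == "ascii") {
    # vertex element always comes first in files we accept; read its n lines
    lns <- readLines(con, n = ve$n)
    m <- matrix(as.numeric(unlist(strsplit(trimws(lns), "[[:space:]]+"), use.names = FALSE)),
                ncol = length(ve$names), byrow = TRUE)
    m
  } else {
    info <- ply_type_info(ve$types)
    stride <- sum(info$size)
    raw <- readBin(con, "raw", n = stride * ve$n)
    if (length(raw) < stride * ve$n) stop_dfseg("truncated PLY payload in %s", path)
    off <- cumsum(c(0L, info$size))
    m <- matrix(0, nrow = ve$n, ncol = length(ve$names))
    for (j in seq_along(ve$names)) {
      idx <- as.vector(outer(seq_len(info$size[j]), (seq_len(ve$n) - 1L) * stride + off[j], "+"))
      m[, j] <- readBin(raw[idx], info$what[j], n = ve$n, size = info$size[j],
                        signed = info$signed[j], endian = "little")
    }
    m
  }
  cols <- tolower(ve$names)
  need <- match(c("x", "y", "z"), cols)
  if (anyNA(need)) stop_dfseg("PLY vertex element lacks x/y/z properties")
  lab_col <- grep("label|class", cols)
  labels <- if (length(lab_col)) as.integer(round(vals[, lab_col[1L]])) else NULL
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  point_cloud(vals[, need, drop = FALSE], labels = labels, name = name)
}

# -- dataset manifests --------------------------------------------------------

#' Write a train/test split manifest
#'
#' Two whitespace-separated columns: scene identifier, split ("train"/"test").
#' @param split a list as returned by [split_scenes()].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(split, path) {
  lines <- c(paste(split$train, "train"), paste(split$test, "test"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a split manifest written by [write_manifest()]
#' @param path manifest file.
#' @return list with `train` and `test` character vectors.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop_dfseg("file not found: %s", path)
  toks <- strsplit(trimws(readLines(path, warn = FALSE)), "[[:space:]]+")
  toks <- toks[lengths(toks) == 2L]
  sc <- vapply(toks, `[`, "", 1L)
  sp <- vapply(toks, `[`, "", 2L)
  list(train = sc[sp == "train"], test = sc[sp == "test"])
}
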