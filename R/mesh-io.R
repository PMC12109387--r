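#' Read a triangular surface mesh
#'
#' Ingests the formats intraoral scanners export: STL (binary or ASCII), PLY
#' (ASCII or binary little-endian) and OBJ (`v`/`f` records). Degenerate faces
#' (repeated vertex indices) are dropped with a message. STL files carry no
#' connectivity, so identical vertices are merged on read.
#'
#' @param path file path; format is detected from the extension
#'   (`.stl`, `.ply`, `.obj`) and, for STL, from the file content.
#' @return An object of class `mesh`: list with `vertices` (`M x 3` double)
#'   and `faces` (`T x 3` integer, 1-based).
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) stop("format error: file not found: ", path)
  if (file.size(path) == 0L) stop("format error: empty file: ", path)
  ext <- tolower(tools::file_ext(path))
  m <- switch(ext,
    stl = read_stl(path),
    ply = read_ply_mesh(path),
    obj = read_obj(path),
    stop("format error: unknown mesh extension '", ext, "' for ", path)
  )
  validate_mesh(m)
}

validate_mesh <- function(m) {
  v <- m$vertices
  f <- m$faces
  storage.mode(v) <- "double"
  storage.mode(f) <- "integer"
  dimnames(v) <- NULL
  dimnames(f) <- NULL
  if (nrow(f)) {
    if (min(f) < 1L || max(f) > nrow(v)) {
      stop("format error: face index out of range")
    }
    degen <- f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 1] == f[, 3]
    if (any(degen)) {
      message("dropped ", sum(degen), " degenerate face(s)")
      f <- f[!degen, , drop = FALSE]
    }
  }
  structure(list(vertices = v, faces = f), class = "mesh")
}

#' @export
print.mesh <- function(x, ...) {
  cat("mesh:", nrow(x$vertices), "vertices,", nrow(x$faces), "faces\n")
  invisible(x)
}

#' Write a triangular mesh
#'
#' Writes ASCII STL, ASCII PLY or OBJ depending on the extension of `path`.
#'
#' @param mesh a `mesh` object.
#' @param path output path ending in `.stl`, `.ply` or `.obj`.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path) {
  stopifnot(inherits(mesh, "mesh"))
  ext <- tolower(tools::file_ext(path))
  v <- mesh$vertices
  f <- mesh$faces
  if (ext == "obj") {
    lines <- c(sprintf("v %.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]),
               sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3]))
    writeLines(lines, path)
  } else if (ext == "ply") {
    header <- c("ply", "format ascii 1.0",
                paste("element vertex", nrow(v)),
                "property float x", "property float y", "property float z",
                paste("element face", nrow(f)),
                "property list uchar int vertex_indices", "end_header")
    lines <- c(header,
               sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]),
               sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L))
    writeLines(lines, path)
  } else if (ext == "stl") {
    a <- v[f[, 1], , drop = FALSE]
    b <- v[f[, 2], , drop = FALSE]
    c_ <- v[f[, 3], , drop = FALSE]
    n <- cross3(b - a, c_ - a)
    len <- sqrt(rowSums(n^2))
    len[len == 0] <- 1
    n <- n / len
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid mesh", con)
    for (i in seq_len(nrow(f))) {
      writeLines(c(
        sprintf("  facet normal %.9g %.9g %.9g", n[i, 1], n[i, 2], n[i, 3]),
        "    outer loop",
        sprintf("      vertex %.9g %.9g %.9g", a[i, 1], a[i, 2], a[i, 3]),
        sprintf("      vertex %.9g %.9g %.9g", b[i, 1], b[i, 2], b[i, 3]),
        sprintf("      vertex %.9g %.9g %.9g", c_[i, 1], c_[i, 2], c_[i, 3]),
        "    endloop", "  endfacet"), con)
    }
    writeLines("endsolid mesh", con)
  } else {
    stop("format error: unknown mesh extension '", ext, "'")
  }
  invisible(path)
}

# ---- STL ----------------------------------------------------------------

read_stl <- function(path) {
  sz <- file.size(path)
  con <- file(path, "rb")
  head <- readBin(con, "raw", n = min(512L, sz))
  close(con)
  txt_head <- rawToChar(head[head != as.raw(0)])
  is_ascii <- grepl("^\\s*solid", txt_head, useBytes = TRUE) &&
    grepl("facet", txt_head, useBytes = TRUE)
  if (!is_ascii && sz >= 84) {
    con <- file(path, "rb")
    invisible(readBin(con, "raw", n = 80L))
    ntri <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
    close(con)
    if (sz == 84 + 50 * as.numeric(ntri)) return(read_stl_binary(path, ntri))
  }
  if (is_ascii) return(read_stl_ascii(path))
  stop("format error: unrecognized STL layout in ", path)
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (!length(vl) || length(vl) %% 3L != 0L) {
    stop("format error: malformed ASCII STL: ", path)
  }
  nums <- t(vapply(strsplit(trimws(vl), "\\s+"),
                   function(x) as.numeric(x[2:4]), numeric(3)))
  stl_weld(nums)
}

read_stl_binary <- function(path, ntri) {
  con <- file(path, "rb")
  on.exit(close(con))
  invisible(readBin(con, "raw", n = 80L))
  invisible(readBin(con, "integer", n = 1L, size = 4L, endian = "little"))
  tris <- matrix(NA_real_, ntri * 3L, 3L)
  for (i in seq_len(ntri)) {
    rec <- readBin(con, "numeric", n = 12L, size = 4L, endian = "little")
    invisible(readBin(con, "integer", n = 1L, size = 2L, signed = FALSE,
                      endian = "little"))
    tris[(3L * i - 2L):(3L * i), ] <- matrix(rec[4:12], 3L, 3L, byrow = TRUE)
  }
  stl_weld(tris)
}

# merge identical vertices of the STL triangle soup into an indexed mesh
stl_weld <- function(tri_verts) {
  key <- paste(tri_verts[, 1], tri_verts[, 2], tri_verts[, 3])
  uk <- !duplicated(key)
  verts <- tri_verts[uk, , drop = FALSE]
  idx <- match(key, key[uk])
  faces <- matrix(idx, ncol = 3L, byrow = TRUE)
  list(vertices = verts, faces = faces)
}

# ---- OBJ ----------------------------------------------------------------

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^v\\s", lines, value = TRUE)
  fl <- grep("^f\\s", lines, value = TRUE)
  if (!length(vl)) stop("format error: no vertices in OBJ: ", path)
  verts <- t(vapply(strsplit(trimws(vl), "\\s+"),
                    function(x) as.numeric(x[2:4]), numeric(3)))
  faces <- if (length(fl)) {
    t(vapply(strsplit(trimws(fl), "\\s+"), function(x) {
      as.integer(vapply(strsplit(x[2:4], "/"), `[[`, "", 1L))
    }, integer(3)))
  } else matrix(integer(), 0L, 3L)
  list(vertices = verts, faces = faces)
}

# ---- PLY ----------------------------------------------------------------

ply_type_info <- function(t) {
  # returns list(what, size, signed)
  switch(t,
    char = , int8 = list("integer", 1L, TRUE),
    uchar = , uint8 = list("integer", 1L, FALSE),
    short = , int16 = list("integer", 2L, TRUE),
    ushort = , uint16 = list("integer", 2L, FALSE),
    int = , int32 = list("integer", 4L, TRUE),
    uint = , uint32 = list("integer", 4L, TRUE),  # R has no u32; values here are small
    float = , float32 = list("numeric", 4L, TRUE),
    double = , float64 = list("numeric", 8L, TRUE),
    stop("format error: unsupported PLY type '", t, "'")
  )
}

parse_ply_header <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  lines <- character()
  nbytes <- 0L                    # bytes consumed including newlines
  repeat {
    ch <- character()
    repeat {
      b <- readBin(con, "raw", n = 1L)
      if (!length(b)) stop("format error: PLY header not terminated: ", path)
      nbytes <- nbytes + 1L
      if (b == as.raw(10L)) break
      ch <- c(ch, rawToChar(b))
    }
    line <- sub("\r$", "", paste(ch, collapse = ""))
    lines <- c(lines, line)
    if (line == "end_header") break
    if (length(lines) > 1000L) stop("format error: oversized PLY header")
  }
  if (lines[1] != "ply") stop("format error: not a PLY file: ", path)
  fmt_line <- grep("^format ", lines, value = TRUE)[1]
  fmt <- strsplit(fmt_line, "\\s+")[[1]][2]
  if (!fmt %in% c("ascii", "binary_little_endian")) {
    stop("format error: unsupported PLY format '", fmt, "'")
  }
  elements <- list()
  cur <- NULL
  for (line in lines) {
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (tok[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2], count = as.integer(tok[3]), props = list())
    } else if (tok[1] == "property" && !is.null(cur)) {
      if (tok[2] == "list") {
        cur$props[[length(cur$props) + 1L]] <-
          list(name = tok[5], list = TRUE, count_type = tok[3], type = tok[4])
      } else {
        cur$props[[length(cur$props) + 1L]] <-
          list(name = tok[3], list = FALSE, type = tok[2])
      }
    }
  }
  if (!is.null(cur)) elements[[cur$name]] <- cur
  list(format = fmt, elements = elements, data_offset = nbytes)
}

read_ply <- function(path) {
  hdr <- parse_ply_header(path)
  out <- list()
  if (hdr$format == "ascii") {
    all_lines <- readLines(path, warn = FALSE)
    i <- grep("^end_header\\s*$", all_lines)[1] + 1L
    for (el in hdr$elements) {
      n <- el$count
      lines <- all_lines[seq.int(i, length.out = n)]
      i <- i + n
      toks <- strsplit(trimws(lines), "\\s+")
      if (any(vapply(el$props, `[[`, TRUE, "list"))) {
        # single list property per element supported (faces)
        vals <- lapply(toks, function(x) as.integer(x[-1]))
        out[[el$name]] <- list(list_values = vals)
      } else {
        m <- matrix(as.numeric(unlist(toks)), nrow = n, byrow = TRUE)
        colnames(m) <- vapply(el$props, `[[`, "", "name")
        out[[el$name]] <- list(table = m)
      }
    }
  } else {
    con <- file(path, "rb")
    on.exit(close(con))
    invisible(readBin(con, "raw", n = hdr$data_offset))
    for (el in hdr$elements) {
      n <- el$count
      if (any(vapply(el$props, `[[`, TRUE, "list"))) {
        p <- el$props[[1]]
        ct <- ply_type_info(p$count_type)
        vt <- ply_type_info(p$type)
        vals <- vector("list", n)
        for (j in seq_len(n)) {
          cnt <- readBin(con, ct[[1]], n = 1L, size = ct[[2]],
                         signed = ct[[2]] >= 4L || ct[[3]], endian = "little")
          vals[[j]] <- as.integer(
            readBin(con, vt[[1]], n = cnt, size = vt[[2]],
                    signed = vt[[2]] >= 4L || vt[[3]], endian = "little"))
        }
        out[[el$name]] <- list(list_values = vals)
      } else {
        infos <- lapply(el$props, function(p) ply_type_info(p$type))
        rec_size <- sum(vapply(infos, `[[`, 0L, 2L))
        raw <- readBin(con, "raw", n = rec_size * n)
        m <- matrix(NA_real_, n, length(el$props))
        off <- 0L
        for (q in seq_along(el$props)) {
          info <- infos[[q]]
          starts <- rep(seq.int(0L, by = rec_size, length.out = n), each = info[[2]]) +
            off + rep(seq_len(info[[2]]), times = n)
          m[, q] <- readBin(raw[starts], info[[1]], n = n, size = info[[2]],
                            signed = info[[2]] >= 4L || info[[3]],
                            endian = "little")
          off <- off + info[[2]]
        }
        colnames(m) <- vapply(el$props, `[[`, "", "name")
        out[[el$name]] <- list(table = m)
      }
    }
  }
  out
}

read_ply_mesh <- function(path) {
  d <- read_ply(path)
  if (is.null(d$vertex)) stop("format error: PLY without vertex element: ", path)
  vt <- d$vertex$table
  verts <- vt[, c("x", "y", "z"), drop = FALSE]
  faces <- if (!is.null(d$face)) {
    fl <- d$face$list_values
    if (length(fl) && any(lengths(fl) != 3L)) {
      stop("format error: non-triangular PLY faces")
    }
    matrix(unlist(fl), ncol = 3L, byrow = TRUE) + 1L
  } else matrix(integer(), 0L, 3L)
  list(vertices = verts, faces = faces)
}

# ---- labelled cloud IO ---------------------------------------------------

#' Read and write labelled point clouds
#'
#' Two on-disk forms are supported: PLY with a per-vertex integer property
#' `label` (binary little-endian is written; ASCII and binary are read), and
#' whitespace text with one `x y z label` record per line (`.xyz` / `.txt`).
#' Coordinates are stored as 32-bit floats; labels round-trip exactly.
#'
#' @param path file path (`.ply`, `.xyz` or `.txt`).
#' @param n_classes label range to validate against (default 33).
#' @param allow_unlabeled if `TRUE`, a PLY without a `label` property (or a
#'   3-column text file) is read as an unlabelled cloud instead of erroring.
#' @return `read_labeled_cloud`: a [labeled_cloud()].
#' @export
read_labeled_cloud <- function(path, n_classes = 33L, allow_unlabeled = FALSE) {
  if (!file.exists(path)) stop("format error: file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "ply") {
    d <- read_ply(path)
    if (is.null(d$vertex)) stop("format error: PLY without vertex element: ", path)
    vt <- d$vertex$table
    pts <- vt[, c("x", "y", "z"), drop = FALSE]
    if ("label" %in% colnames(vt)) {
      labels <- as.integer(vt[, "label"])
    } else if (allow_unlabeled) {
      labels <- NULL
    } else {
      stop("format error: PLY has no 'label' property (use allow_unlabeled)")
    }
  } else {
    m <- as.matrix(utils::read.table(path))
    if (ncol(m) == 4L) {
      pts <- m[, 1:3, drop = FALSE]
      labels <- as.integer(m[, 4])
    } else if (ncol(m) == 3L && allow_unlabeled) {
      pts <- m
      labels <- NULL
    } else {
      stop("format error: expected 'x y z label' records in ", path)
    }
  }
  if (!is.null(labels)) {
    bad <- which(labels < 0L | labels >= n_classes)
    if (length(bad)) {
      stop("validation error: labels outside [0, ", n_classes, ") at indices: ",
           paste(utils::head(bad, 10L), collapse = ", "),
           if (length(bad) > 10L) " ..." else "")
    }
  }
  labeled_cloud(pts, labels = labels, n_classes = n_classes)
}

#' @rdname read_labeled_cloud
#' @param cloud a [labeled_cloud()] to write.
#' @return `write_labeled_cloud`: `path`, invisibly.
#' @export
write_labeled_cloud <- function(cloud, path) {
  stopifnot(inherits(cloud, "labeled_cloud"))
  ext <- tolower(tools::file_ext(path))
  p <- cloud$points
  lab <- cloud$labels
  if (ext == "ply") {
    header <- c("ply", "format binary_little_endian 1.0",
                paste("element vertex", nrow(p)),
                "property float x", "property float y", "property float z",
                if (!is.null(lab)) "property int label",
                "end_header")
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(charToRaw(paste0(paste(header, collapse = "\n"), "\n")), con)
    n <- nrow(p)
    coord_raw <- writeBin(as.numeric(t(p)), raw(), size = 4L, endian = "little")
    if (is.null(lab)) {
      writeBin(coord_raw, con)
    } else {
      lab_raw <- writeBin(lab, raw(), size = 4L, endian = "little")
      rec <- raw(16L * n)
      base <- rep((seq_len(n) - 1L) * 16L, each = 12L)
      rec[base + rep(1:12, times = n)] <- coord_raw
      base4 <- rep((seq_len(n) - 1L) * 16L, each = 4L)
      rec[base4 + rep(13:16, times = n)] <- lab_raw
      writeBin(rec, con)
    }
  } else {
    xyz <- sprintf("%.9g %.9g %.9g", as_float32(p[, 1]), as_float32(p[, 2]),
                   as_float32(p[, 3]))
    lines <- if (is.null(lab)) xyz else paste(xyz, lab)
    writeLines(lines, path)
  }
  invisible(path)
}
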