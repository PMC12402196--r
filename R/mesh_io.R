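# Triangle-mesh container and STL/PLY input/output. Both ASCII and binary
# dialects are accepted on read; PLY is written binary little-endian with
# double-precision coordinates by default (STL's on-disk format is single
# precision by definition).

#' Triangle surface mesh
#'
#' @param vertices n x 3 numeric matrix of vertex coordinates (mm).
#' @param faces m x 3 integer matrix of 1-based vertex indices (may have 0
#'   rows for a bare point cloud).
#' @param normals Optional n x 3 matrix of per-vertex unit normals.
#' @return Object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces = matrix(integer(0), 0, 3),
                         normals = NULL) {
  vertices <- as.matrix(vertices)
  stopifnot(is.numeric(vertices), ncol(vertices) == 3)
  faces <- matrix(as.integer(faces), ncol = 3)
  if (nrow(faces) && (min(faces) < 1 || max(faces) > nrow(vertices)))
    stop("face indices out of range", call. = FALSE)
  if (!is.null(normals)) {
    normals <- as.matrix(normals)
    stopifnot(nrow(normals) == nrow(vertices), ncol(normals) == 3)
  }
  structure(list(vertices = vertices, faces = faces, normals = normals),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices, %d faces\n", nrow(x$vertices),
              nrow(x$faces)))
  invisible(x)
}

format_error <- function(path, what) {
  stop(sprintf("cannot parse '%s': %s", path, what), call. = FALSE)
}

#' Read a triangle mesh from STL or PLY
#'
#' Format is chosen by file extension; ASCII and binary dialects of both
#' formats are detected automatically. STL (which stores a vertex triple per
#' facet) has exactly coincident vertices merged into shared mesh vertices.
#'
#' @param path Path to a `.stl` or `.ply` file.
#' @return A [surface_mesh].
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (file.size(path) == 0) format_error(path, "empty file")
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         stl = read_stl(path),
         ply = read_ply(path),
         stop("unsupported mesh format: .", ext, call. = FALSE))
}

#' Write a triangle mesh as STL or PLY
#'
#' @param mesh A [surface_mesh].
#' @param path Output path; format chosen by extension (`.stl` or `.ply`).
#' @param ascii Write the ASCII dialect instead of binary.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, ascii = FALSE) {
  stopifnot(inherits(mesh, "surface_mesh"))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         stl = write_stl(mesh, path, ascii),
         ply = write_ply(mesh, path, ascii),
         stop("unsupported mesh format: .", ext, call. = FALSE))
  invisible(path)
}

# ---- STL ----

stl_is_ascii <- function(path) {
  head <- readBin(path, "raw", n = 512)
  txt <- rawToChar(head[head != as.raw(0)], multiple = FALSE)
  # byte-wise matching: a binary STL header holds arbitrary bytes
  grepl("^[[:space:]]*solid", txt, ignore.case = TRUE, useBytes = TRUE) &&
    grepl("facet", txt, ignore.case = TRUE, useBytes = TRUE)
}

# merge per-facet vertex triples into shared vertices (exact coincidence)
facets_to_mesh <- function(tri) {
  key <- paste(tri[, 1], tri[, 2], tri[, 3], sep = "/")
  first <- !duplicated(key)
  idx <- match(key, key[first])
  surface_mesh(tri[first, , drop = FALSE],
               matrix(idx, ncol = 3, byrow = TRUE))
}

read_stl <- function(path) {
  if (stl_is_ascii(path)) {
    lines <- readLines(path, warn = FALSE)
    vlines <- grep("^\\s*vertex\\s", lines, value = TRUE)
    if (!length(vlines) || length(vlines) %% 3 != 0)
      format_error(path, "ASCII STL without a whole number of vertex triples")
    nums <- lapply(strsplit(trimws(vlines), "\\s+"), function(x) {
      v <- suppressWarnings(as.numeric(x[2:4]))
      if (anyNA(v)) format_error(path, paste("bad vertex line:", x[1]))
      v
    })
    facets_to_mesh(do.call(rbind, nums))
  } else {
    sz <- file.size(path)
    if (sz < 84) format_error(path, "binary STL shorter than its header")
    con <- file(path, "rb"); on.exit(close(con))
    readBin(con, "raw", n = 80)
    nfac <- readBin(con, "integer", size = 4, endian = "little")
    if (nfac < 0 || sz < 84 + 50 * nfac)
      format_error(path, "binary STL facet count disagrees with file size")
    body <- readBin(con, "raw", n = 50 * nfac)
    m <- matrix(body, nrow = 50)
    tri <- readBin(as.raw(m[13:48, ]), "numeric", size = 4, n = 9 * nfac,
                   endian = "little")
    facets_to_mesh(matrix(tri, ncol = 3, byrow = TRUE))
  }
}

write_stl <- function(mesh, path, ascii) {
  F <- mesh$faces
  if (!nrow(F)) stop("STL requires faces", call. = FALSE)
  V <- mesh$vertices
  v1 <- V[F[, 1], , drop = FALSE]
  v2 <- V[F[, 2], , drop = FALSE]
  v3 <- V[F[, 3], , drop = FALSE]
  e1 <- v2 - v1; e2 <- v3 - v1
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(nrm^2)); len[len == 0] <- 1
  nrm <- nrm / len
  if (ascii) {
    con <- file(path, "w"); on.exit(close(con))
    writeLines("solid mesh", con)
    for (i in seq_len(nrow(F))) {
      writeLines(c(sprintf("  facet normal %.9g %.9g %.9g", nrm[i, 1],
                           nrm[i, 2], nrm[i, 3]),
                   "    outer loop",
                   sprintf("      vertex %.9g %.9g %.9g", v1[i, 1], v1[i, 2], v1[i, 3]),
                   sprintf("      vertex %.9g %.9g %.9g", v2[i, 1], v2[i, 2], v2[i, 3]),
                   sprintf("      vertex %.9g %.9g %.9g", v3[i, 1], v3[i, 2], v3[i, 3]),
                   "    endloop",
                   "  endfacet"), con)
    }
    writeLines("endsolid mesh", con)
  } else {
    con <- file(path, "wb"); on.exit(close(con))
    writeBin(as.raw(rep(0L, 80)), con)
    writeBin(as.integer(nrow(F)), con, size = 4, endian = "little")
    block <- rbind(t(nrm), t(v1), t(v2), t(v3))   # 12 floats per facet
    for (i in seq_len(nrow(F))) {
      writeBin(block[, i], con, size = 4, endian = "little")
      writeBin(as.raw(c(0L, 0L)), con)
    }
  }
  invisible(path)
}

# ---- PLY ----

.ply_sizes <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
                short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
                int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
                float = 4L, float32 = 4L, double = 8L, float64 = 8L)
.ply_is_float <- function(type) type %in% c("float", "float32", "double", "float64")

read_ply_header <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  lines <- character(0)
  nbytes <- 0L
  repeat {
    ch <- character(0); line_raw <- raw(0)
    repeat {
      b <- readBin(con, "raw", n = 1)
      if (!length(b)) format_error(path, "PLY header not terminated")
      nbytes <- nbytes + 1L
      if (b == as.raw(10)) break
      line_raw <- c(line_raw, b)
    }
    line <- trimws(rawToChar(line_raw))
    lines <- c(lines, line)
    if (lines[1] != "ply") format_error(path, "missing 'ply' magic")
    if (line == "end_header") break
    if (nbytes > 65536) format_error(path, "PLY header not terminated")
  }
  fmt_line <- grep("^format ", lines, value = TRUE)
  if (!length(fmt_line)) format_error(path, "missing PLY format line")
  fmt <- strsplit(fmt_line[1], "\\s+")[[1]][2]
  elements <- list()
  cur <- NULL
  for (line in lines) {
    tok <- strsplit(line, "\\s+")[[1]]
    if (tok[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2], count = as.integer(tok[3]), props = list())
    } else if (tok[1] == "property" && !is.null(cur)) {
      if (tok[2] == "list") {
        cur$props[[tok[5]]] <- list(list = TRUE, count_type = tok[3],
                                    item_type = tok[4])
      } else {
        cur$props[[tok[3]]] <- list(list = FALSE, type = tok[2])
      }
    }
  }
  if (!is.null(cur)) elements[[cur$name]] <- cur
  list(format = fmt, elements = elements, header_bytes = nbytes)
}

read_ply <- function(path) {
  hd <- read_ply_header(path)
  if (is.null(hd$elements$vertex)) format_error(path, "no vertex element")
  if (hd$format == "ascii") read_ply_ascii(path, hd) else {
    if (hd$format != "binary_little_endian")
      format_error(path, paste("unsupported PLY format:", hd$format))
    read_ply_binary(path, hd)
  }
}

read_ply_ascii <- function(path, hd) {
  lines <- readLines(path, warn = FALSE)
  body <- lines[(which(trimws(lines) == "end_header")[1] + 1):length(lines)]
  body <- body[nzchar(trimws(body))]
  pos <- 1L
  verts <- NULL; faces <- matrix(integer(0), 0, 3)
  for (el in hd$elements) {
    if (el$count == 0) next
    if (pos + el$count - 1L > length(body))
      format_error(path, sprintf("truncated element '%s'", el$name))
    chunk <- body[pos:(pos + el$count - 1L)]
    pos <- pos + el$count
    if (el$name == "vertex") {
      pn <- names(el$props)
      vals <- do.call(rbind, lapply(strsplit(trimws(chunk), "\\s+"),
                                    as.numeric))
      verts <- vals[, match(c("x", "y", "z"), pn), drop = FALSE]
    } else if (el$name == "face") {
      faces <- do.call(rbind, lapply(strsplit(trimws(chunk), "\\s+"),
                                     function(x) {
        n <- as.integer(x[1])
        if (n != 3) format_error(path, "non-triangular face")
        as.integer(x[2:4]) + 1L
      }))
    }
  }
  if (is.null(verts)) format_error(path, "no vertex data")
  surface_mesh(verts, faces)
}

read_ply_binary <- function(path, hd) {
  raw_all <- readBin(path, "raw", n = file.size(path))
  off <- hd$header_bytes
  take <- function(n) {
    if (off + n > length(raw_all)) format_error(path, "truncated binary body")
    r <- raw_all[(off + 1):(off + n)]
    off <<- off + n
    r
  }
  read_scalar <- function(type) {
    sz <- .ply_sizes[[type]]
    r <- take(sz)
    if (.ply_is_float(type)) readBin(r, "numeric", size = sz, endian = "little")
    else readBin(r, "integer", size = sz, endian = "little",
                 signed = !(sz < 4 && grepl("^u", type)))
  }
  verts <- NULL; faces <- matrix(integer(0), 0, 3)
  for (el in hd$elements) {
    if (el$name == "vertex") {
      types <- vapply(el$props, `[[`, character(1), "type")
      sizes <- .ply_sizes[types]
      stride <- sum(sizes)
      body <- take(stride * el$count)
      m <- matrix(body, nrow = stride)
      offsets <- c(0L, cumsum(sizes))
      getcol <- function(j) {
        bytes <- as.raw(m[(offsets[j] + 1):(offsets[j + 1]), , drop = FALSE])
        if (.ply_is_float(types[j]))
          readBin(bytes, "numeric", size = sizes[j], n = el$count,
                  endian = "little")
        else readBin(bytes, "integer", size = sizes[j], n = el$count,
                     endian = "little",
                     signed = !(sizes[j] < 4 && grepl("^u", types[j])))
      }
      pn <- names(el$props)
      verts <- cbind(getcol(match("x", pn)), getcol(match("y", pn)),
                     getcol(match("z", pn)))
    } else if (el$name == "face") {
      lp <- el$props[[1]]
      fl <- matrix(0L, el$count, 3)
      for (i in seq_len(el$count)) {
        n <- read_scalar(lp$count_type)
        if (n != 3) format_error(path, "non-triangular face")
        fl[i, ] <- c(read_scalar(lp$item_type), read_scalar(lp$item_type),
                     read_scalar(lp$item_type))
      }
      faces <- fl + 1L
    } else {
      # skip unknown fixed-stride elements
      types <- vapply(el$props, function(p) if (isTRUE(p$list)) NA_character_
                      else p$type, character(1))
      if (anyNA(types))
        format_error(path, sprintf("cannot skip list element '%s'", el$name))
      take(sum(.ply_sizes[types]) * el$count)
    }
  }
  if (is.null(verts)) format_error(path, "no vertex data")
  surface_mesh(verts, faces)
}

write_ply <- function(mesh, path, ascii) {
  V <- mesh$vertices; F <- mesh$faces
  hdr <- c("ply",
           sprintf("format %s 1.0",
                   if (ascii) "ascii" else "binary_little_endian"),
           sprintf("element vertex %d", nrow(V)),
           "property double x", "property double y", "property double z",
           sprintf("element face %d", nrow(F)),
           "property list uchar int vertex_indices",
           "end_header")
  if (ascii) {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(hdr, con)
    writeLines(sprintf("%.17g %.17g %.17g", V[, 1], V[, 2], V[, 3]), con)
    if (nrow(F))
      writeLines(sprintf("3 %d %d %d", F[, 1] - 1L, F[, 2] - 1L, F[, 3] - 1L),
                 con)
  } else {
    con <- file(path, "wb"); on.exit(close(con))
    writeChar(paste0(paste(hdr, collapse = "\n"), "\n"), con, eos = NULL)
    writeBin(as.numeric(t(V)), con, size = 8, endian = "little")
    for (i in seq_len(nrow(F))) {
      writeBin(as.raw(3L), con)
      writeBin(as.integer(F[i, ] - 1L), con, size = 4, endian = "little")
    }
  }
  invisible(path)
}
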