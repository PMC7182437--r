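#' Read a triangle mesh from PLY, STL or OBJ
#'
#' Format is chosen by file extension. PLY supports ascii and
#' binary_little_endian; STL supports ascii and binary (facet soups are
#' welded into shared vertices with a 1e-6 mm tolerance); OBJ reads `v`
#' and `f` records.
#'
#' @param path path to a mesh file.
#' @return a `triangle_mesh`.
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  if (file.size(path) == 0) stop("empty mesh file: ", path)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         ply = read_ply(path),
         stl = read_stl(path),
         obj = read_obj(path),
         stop("unsupported mesh format: .", ext))
}

#' Write a triangle mesh to PLY, STL or OBJ
#'
#' @param mesh a `triangle_mesh`.
#' @param path output path; extension selects the format.
#' @param binary for PLY, write binary_little_endian (default `TRUE`,
#'   lossless for double precision is not guaranteed by the PLY float type;
#'   coordinates are stored as 32-bit floats as is conventional). Ignored
#'   for STL (ascii) and OBJ.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, binary = TRUE) {
  stopifnot(is_triangle_mesh(mesh))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         ply = write_ply(mesh, path, binary = binary),
         stl = write_stl_ascii(mesh, path),
         obj = write_obj(mesh, path),
         stop("unsupported mesh format: .", ext))
  invisible(path)
}

# PLY ---------------------------------------------------------------------

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!identical(trimws(magic), "ply")) stop("not a PLY file: ", path)
  fmt <- NULL
  nv <- nf <- NA_integer_
  vprops <- character()
  in_vertex <- FALSE
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("malformed PLY header: ", path)
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(tok) == 0L) next
    if (tok[1] == "format") fmt <- tok[2]
    else if (tok[1] == "element") {
      in_vertex <- tok[2] == "vertex"
      if (tok[2] == "vertex") nv <- as.integer(tok[3])
      if (tok[2] == "face") nf <- as.integer(tok[3])
    } else if (tok[1] == "property" && in_vertex && tok[2] != "list") {
      vprops <- c(vprops, tok[3])
    } else if (tok[1] == "end_header") break
  }
  if (is.na(nv) || is.na(nf)) stop("PLY header lacks vertex/face counts")
  xyz <- match(c("x", "y", "z"), vprops)
  if (anyNA(xyz)) stop("PLY vertex element lacks x/y/z properties")
  np <- length(vprops)
  if (identical(fmt, "ascii")) {
    rest <- readLines(con)
    rest <- rest[nzchar(trimws(rest))]
    vlines <- rest[seq_len(nv)]
    vm <- matrix(as.numeric(unlist(strsplit(trimws(vlines), "\\s+"))),
                 ncol = np, byrow = TRUE)
    v <- vm[, xyz, drop = FALSE]
    flines <- rest[nv + seq_len(nf)]
    f <- t(vapply(strsplit(trimws(flines), "\\s+"), function(tk) {
      k <- as.integer(tk[1])
      if (k != 3L) stop("only triangle faces are supported")
      as.integer(tk[2:4])
    }, integer(3)))
  } else if (identical(fmt, "binary_little_endian")) {
    raw_v <- readBin(con, "numeric", n = nv * np, size = 4L,
                     endian = "little")
    vm <- matrix(raw_v, ncol = np, byrow = TRUE)
    v <- vm[, xyz, drop = FALSE]
    f <- matrix(0L, nf, 3)
    for (i in seq_len(nf)) {
      k <- readBin(con, "integer", n = 1L, size = 1L, signed = FALSE)
      if (k != 3L) stop("only triangle faces are supported")
      f[i, ] <- readBin(con, "integer", n = 3L, size = 4L, endian = "little")
    }
  } else stop("unsupported PLY format: ", fmt)
  triangle_mesh(v, f + 1L)
}

write_ply <- function(mesh, path, binary = TRUE) {
  v <- mesh$vertices
  f <- mesh$faces - 1L
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("ply",
           if (binary) "format binary_little_endian 1.0" else "format ascii 1.0",
           sprintf("element vertex %d", nrow(v)),
           "property float x", "property float y", "property float z",
           sprintf("element face %d", nrow(f)),
           "property list uchar int vertex_indices",
           "end_header")
  writeLines(hdr, con)
  if (binary) {
    writeBin(as.numeric(t(v)), con, size = 4L, endian = "little")
    for (i in seq_len(nrow(f))) {
      writeBin(as.raw(3L), con)
      writeBin(as.integer(f[i, ]), con, size = 4L, endian = "little")
    }
  } else {
    writeLines(apply(v, 1, function(r) paste(format(r, digits = 9), collapse = " ")), con)
    writeLines(apply(f, 1, function(r) paste(c(3L, r), collapse = " ")), con)
  }
  invisible(path)
}

# OBJ ---------------------------------------------------------------------

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  vl <- lines[startsWith(lines, "v ")]
  fl <- lines[startsWith(lines, "f ")]
  if (length(vl) == 0L) stop("OBJ file contains no vertices: ", path)
  v <- matrix(as.numeric(unlist(lapply(strsplit(vl, "\\s+"),
                                       function(tk) tk[2:4]))),
              ncol = 3, byrow = TRUE)
  f <- t(vapply(strsplit(fl, "\\s+"), function(tk) {
    if (length(tk) != 4L) stop("only triangle faces are supported")
    as.integer(vapply(strsplit(tk[2:4], "/"), `[[`, "", 1L))
  }, integer(3)))
  triangle_mesh(v, f)
}

write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(apply(mesh$vertices, 1, function(r)
    paste("v", paste(format(r, digits = 9), collapse = " "))), con)
  writeLines(apply(mesh$faces, 1, function(r)
    paste("f", paste(r, collapse = " "))), con)
  invisible(path)
}

# STL ---------------------------------------------------------------------

read_stl <- function(path) {
  sz <- file.size(path)
  con <- file(path, "rb")
  head80 <- readBin(con, "raw", n = min(80L, sz))
  is_ascii <- grepl("^solid", rawToChar(head80[seq_len(min(5L, length(head80)))]))
  if (is_ascii) {
    # ascii solids can still be binary files starting with "solid";
    # check that the expected binary size does not match
    if (sz >= 84) {
      nf <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
      if (!is.na(nf) && sz == 84 + 50 * as.numeric(nf)) is_ascii <- FALSE
    }
  }
  close(con)
  tri <- if (is_ascii) read_stl_ascii(path) else read_stl_binary(path)
  weld_vertices(tri, tol = 1e-6)
}

read_stl_ascii <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  vl <- lines[startsWith(lines, "vertex")]
  if (length(vl) == 0L || length(vl) %% 3L != 0L)
    stop("malformed ascii STL: ", path)
  matrix(as.numeric(unlist(lapply(strsplit(vl, "\\s+"),
                                  function(tk) tk[2:4]))),
         ncol = 3, byrow = TRUE)
}

read_stl_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 80L)
  nf <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  dat <- readBin(con, "numeric", n = nf * 12L + nf, size = 4L,
                 endian = "little")
  # each facet: 12 floats (normal + 3 vertices) then 2 attribute bytes;
  # re-read per facet to honour the attribute bytes
  close(con)
  on.exit(NULL)
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 84L)
  tri <- matrix(0, nf * 3L, 3L)
  for (i in seq_len(nf)) {
    vals <- readBin(con, "numeric", n = 12L, size = 4L, endian = "little")
    readBin(con, "raw", n = 2L)
    tri[(i - 1L) * 3L + 1:3, ] <- matrix(vals[4:12], 3, 3, byrow = TRUE)
  }
  tri
}

# weld a facet-soup vertex list into shared vertices
weld_vertices <- function(tri, tol = 1e-6) {
  key <- apply(round(tri / tol), 1, paste, collapse = ",")
  first <- !duplicated(key)
  ids <- match(key, key[first])
  v <- tri[first, , drop = FALSE]
  f <- matrix(ids, ncol = 3, byrow = TRUE)
  if (any(f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 1] == f[, 3]))
    stop("degenerate facets after welding")
  triangle_mesh(v, f)
}

write_stl_ascii <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid mesh", con)
  for (i in seq_len(nrow(f))) {
    a <- v[f[i, 1], ]; b <- v[f[i, 2], ]; cc <- v[f[i, 3], ]
    n <- c((b[2] - a[2]) * (cc[3] - a[3]) - (b[3] - a[3]) * (cc[2] - a[2]),
           (b[3] - a[3]) * (cc[1] - a[1]) - (b[1] - a[1]) * (cc[3] - a[3]),
           (b[1] - a[1]) * (cc[2] - a[2]) - (b[2] - a[2]) * (cc[1] - a[1]))
    nn <- sqrt(sum(n^2))
    if (nn > 0) n <- n / nn
    writeLines(sprintf("  facet normal %g %g %g", n[1], n[2], n[3]), con)
    writeLines("    outer loop", con)
    writeLines(sprintf("      vertex %.9g %.9g %.9g",
                       c(a[1], b[1], cc[1]), c(a[2], b[2], cc[2]),
                       c(a[3], b[3], cc[3])), con)
    writeLines("    endloop", con)
    writeLines("  endfacet", con)
  }
  writeLines("endsolid mesh", con)
  invisible(path)
}
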