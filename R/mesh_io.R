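#' Read a triangle mesh from PLY or OBJ
#'
#' Supports ascii and binary_little_endian PLY and Wavefront OBJ. Vertex order
#' is preserved from the file. Faces must be triangles: quads or general
#' polygons are an error rather than being silently triangulated, so that
#' downstream distance maps never depend on an implicit triangulation choice.
#' All mesh invariants are validated on load; no silent repair.
#'
#' @param path file path.
#' @param format `"ply"` or `"obj"`; guessed from the file extension when
#'   missing.
#' @return a [hand_mesh].
#' @export
read_mesh <- function(path, format = c("auto", "ply", "obj")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- switch(tolower(tools::file_ext(path)),
                     ply = "ply", obj = "obj",
                     stop("cannot guess mesh format from extension of ", path))
  if (format == "ply") read_ply(path) else read_obj(path)
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1)
  if (!identical(trimws(magic), "ply")) stop("not a PLY file (missing 'ply' magic): ", path)

  fmt <- NULL
  nvert <- NULL
  nface <- NULL
  vert_props <- character()
  vert_types <- character()
  face_prop <- NULL
  cur_elem <- ""
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0) stop("unexpected end of PLY header in ", path)
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (!length(tok)) next
    if (tok[1] == "comment") next
    if (tok[1] == "format") {
      fmt <- tok[2]
      if (!fmt %in% c("ascii", "binary_little_endian"))
        stop("unsupported PLY format ", sQuote(fmt),
             " (ascii and binary_little_endian are supported)")
    } else if (tok[1] == "element") {
      cur_elem <- tok[2]
      if (tok[2] == "vertex") nvert <- as.integer(tok[3])
      if (tok[2] == "face") nface <- as.integer(tok[3])
    } else if (tok[1] == "property") {
      if (cur_elem == "vertex") {
        if (tok[2] == "list") stop("list property on vertex element not supported")
        vert_types <- c(vert_types, tok[2])
        vert_props <- c(vert_props, tok[3])
      } else if (cur_elem == "face") {
        if (tok[2] != "list")
          stop("face element property must be a list (found ", sQuote(tok[2]), ")")
        face_prop <- tok[3:4]
      }
    } else if (tok[1] == "end_header") break
  }
  if (is.null(fmt)) stop("PLY header has no format line")
  if (is.null(nvert) || is.null(nface))
    stop("PLY header must declare vertex and face elements")
  xyz <- match(c("x", "y", "z"), vert_props)
  if (anyNA(xyz)) stop("PLY vertex element lacks x/y/z properties")

  type_size <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
                 short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
                 int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
                 float = 4L, float32 = 4L, double = 8L, float64 = 8L)

  if (fmt == "ascii") {
    txt <- readLines(con)
    txt <- txt[nzchar(trimws(txt))]
    if (length(txt) < nvert + nface)
      stop("PLY body truncated: expected ", nvert + nface, " data lines")
    vl <- strsplit(trimws(txt[seq_len(nvert)]), "\\s+")
    verts <- t(vapply(vl, function(v) as.numeric(v[xyz]), numeric(3)))
    fl <- strsplit(trimws(txt[nvert + seq_len(nface)]), "\\s+")
    faces <- t(vapply(seq_along(fl), function(i) {
      v <- as.integer(fl[[i]])
      if (v[1] != 3L)
        stop("face ", i, " has ", v[1],
             " vertices; only triangles are accepted (no auto-triangulation)")
      v[2:4] + 1L
    }, integer(3)))
  } else {
    read_scalar <- function(ty, n = 1L) {
      if (ty %in% c("float", "float32")) readBin(con, "double", n, size = 4, endian = "little")
      else if (ty %in% c("double", "float64")) readBin(con, "double", n, size = 8, endian = "little")
      else if (ty %in% c("uchar", "uint8", "char", "int8")) readBin(con, "integer", n, size = 1, signed = ty %in% c("char", "int8"), endian = "little")
      else if (ty %in% c("short", "int16", "ushort", "uint16")) readBin(con, "integer", n, size = 2, signed = ty %in% c("short", "int16"), endian = "little")
      else readBin(con, "integer", n, size = 4, endian = "little")
    }
    nprop <- length(vert_props)
    verts <- matrix(0, nvert, 3)
    if (length(unique(vert_types)) == 1L && vert_types[1] %in% c("float", "float32", "double", "float64")) {
      sz <- if (vert_types[1] %in% c("float", "float32")) 4 else 8
      all_v <- readBin(con, "double", nvert * nprop, size = sz, endian = "little")
      m <- matrix(all_v, nvert, nprop, byrow = TRUE)
      verts <- m[, xyz, drop = FALSE]
    } else {
      for (i in seq_len(nvert)) {
        row <- numeric(nprop)
        for (j in seq_len(nprop)) row[j] <- as.numeric(read_scalar(vert_types[j]))
        verts[i, ] <- row[xyz]
      }
    }
    faces <- matrix(0L, nface, 3)
    for (i in seq_len(nface)) {
      cnt <- as.integer(read_scalar(face_prop[1]))
      if (length(cnt) == 0) stop("PLY body truncated at face ", i)
      if (cnt != 3L)
        stop("face ", i, " has ", cnt,
             " vertices; only triangles are accepted (no auto-triangulation)")
      faces[i, ] <- as.integer(read_scalar(face_prop[2], 3L)) + 1L
    }
  }
  if (any(!is.finite(verts))) stop("non-finite vertex coordinate in ", path)
  hand_mesh(verts, faces)
}

read_obj <- function(path) {
  txt <- readLines(path, warn = FALSE)
  txt <- trimws(txt)
  txt <- txt[nzchar(txt) & !startsWith(txt, "#")]
  vlines <- txt[startsWith(txt, "v ")]
  flines <- txt[startsWith(txt, "f ")]
  if (!length(vlines)) stop("OBJ file has no vertices: ", path)
  verts <- t(vapply(strsplit(vlines, "\\s+"), function(v) as.numeric(v[2:4]),
                    numeric(3)))
  faces <- t(vapply(seq_along(flines), function(i) {
    tok <- strsplit(flines[i], "\\s+")[[1]][-1]
    if (length(tok) != 3L)
      stop("face ", i, " has ", length(tok),
           " vertices; only triangles are accepted (no auto-triangulation)")
    # strip texture/normal references (v/vt/vn)
    as.integer(vapply(strsplit(tok, "/"), `[`, character(1), 1))
  }, integer(3)))
  if (any(!is.finite(verts))) stop("non-finite vertex coordinate in ", path)
  hand_mesh(verts, faces)
}

#' Write a triangle mesh to PLY or OBJ
#'
#' Writes coordinates with enough precision that a write/read round trip
#' reproduces them to within 1e-6 mm (binary PLY is exact for doubles stored
#' as float64).
#'
#' @param mesh a [hand_mesh].
#' @param path output file path.
#' @param format `"ply"`, `"ply_binary"`, or `"obj"`; guessed from the
#'   extension when `"auto"` (extension `.ply` writes ascii).
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = c("auto", "ply", "ply_binary", "obj")) {
  format <- match.arg(format)
  stopifnot(inherits(mesh, "hand_mesh"))
  if (format == "auto")
    format <- switch(tolower(tools::file_ext(path)),
                     ply = "ply", obj = "obj",
                     stop("cannot guess mesh format from extension of ", path))
  v <- mesh$vertices
  f <- mesh$faces
  if (format == "obj") {
    con <- file(path, "wt")
    on.exit(close(con))
    writeLines(sprintf("v %.9f %.9f %.9f", v[, 1], v[, 2], v[, 3]), con)
    writeLines(sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3]), con)
  } else {
    header <- c("ply",
                paste("format", if (format == "ply") "ascii" else "binary_little_endian", "1.0"),
                paste("element vertex", nrow(v)),
                "property double x", "property double y", "property double z",
                paste("element face", nrow(f)),
                "property list uchar int vertex_indices",
                "end_header")
    if (format == "ply") {
      con <- file(path, "wt")
      on.exit(close(con))
      writeLines(header, con)
      writeLines(sprintf("%.9f %.9f %.9f", v[, 1], v[, 2], v[, 3]), con)
      writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
    } else {
      con <- file(path, "wb")
      on.exit(close(con))
      writeLines(header, con)
      writeBin(as.numeric(t(v)), con, size = 8, endian = "little")
      for (i in seq_len(nrow(f))) {
        writeBin(as.raw(3L), con)
        writeBin(as.integer(f[i, ] - 1L), con, size = 4, endian = "little")
      }
    }
  }
  invisible(path)
}

#' Read a landmark set from CSV or JSON
#'
#' CSV files have a header `label,x,y,z` (comma separator, dot decimal) and
#' may carry `# schema: <id>` / `# side: <left|right>` comment lines; the JSON
#' form is an object with `schema_id`, `side`, and a `points` object mapping
#' label to `[x, y, z]`. Rows may appear in any order: labels are normalised
#' to the schema order. Duplicate labels and labels outside the schema are
#' errors.
#'
#' @param path file path (`.csv` or `.json`).
#' @param schema schema label vector or schema name; defaults to the schema
#'   named in the file, or the file's own label order.
#' @return a [landmark_set].
#' @export
read_landmarks <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    pts <- do.call(rbind, obj$points)
    rownames(pts) <- names(obj$points)
    schema_id <- obj$schema_id %||% "custom"
    side <- obj$side %||% "right"
  } else {
    txt <- readLines(path, warn = FALSE)
    meta <- txt[startsWith(trimws(txt), "#")]
    schema_id <- sub("^#\\s*schema:\\s*", "", grep("^#\\s*schema:", meta, value = TRUE))
    side <- sub("^#\\s*side:\\s*", "", grep("^#\\s*side:", meta, value = TRUE))
    if (!length(schema_id)) schema_id <- "custom"
    if (!length(side)) side <- "right"
    df <- read.csv(text = txt[!startsWith(trimws(txt), "#")],
                   stringsAsFactors = FALSE)
    need <- c("label", "x", "y", "z")
    if (!all(need %in% names(df)))
      stop("landmark CSV must have header label,x,y,z")
    if (anyDuplicated(df$label))
      stop("duplicate landmark label: ", df$label[duplicated(df$label)][1])
    pts <- as.matrix(df[, c("x", "y", "z")])
    rownames(pts) <- df$label
  }
  if (is.null(schema)) {
    schema <- if (schema_id != "custom" && schema_id %in% names(.schemas))
      landmark_schema(schema_id)$labels else rownames(pts)
  }
  landmark_set(pts, schema = schema, schema_id = schema_id, side = side)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a landmark set to CSV or JSON
#'
#' @param lm a [landmark_set].
#' @param path output file path (`.csv` or `.json`).
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(lm, path) {
  stopifnot(inherits(lm, "landmark_set"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    pts <- lapply(seq_len(nrow(lm$points)), function(i) unname(lm$points[i, ]))
    names(pts) <- rownames(lm$points)
    jsonlite::write_json(list(schema_id = lm$schema_id, side = lm$side,
                              points = pts),
                         path, auto_unbox = TRUE, digits = NA)
  } else {
    con <- file(path, "wt")
    on.exit(close(con))
    writeLines(c(paste("# schema:", lm$schema_id), paste("# side:", lm$side),
                 "label,x,y,z"), con)
    writeLines(sprintf("%s,%.9f,%.9f,%.9f", rownames(lm$points),
                       lm$points[, 1], lm$points[, 2], lm$points[, 3]), con)
  }
  invisible(path)
}

#' Read per-vertex region labels
#'
#' CSV with header `vertex_index,region`, one row per mesh vertex (1-based
#' indices). Count mismatches and unknown region names are errors.
#'
#' @param path file path.
#' @param mesh the [hand_mesh] the labels describe.
#' @return a [region_map] bound to `mesh`.
#' @export
read_region_labels <- function(path, mesh) {
  stopifnot(inherits(mesh, "hand_mesh"))
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("vertex_index", "region") %in% names(df)))
    stop("region label CSV must have header vertex_index,region")
  n <- nrow(mesh$vertices)
  if (nrow(df) != n)
    stop("region label count (", nrow(df),
         ") does not match vertex count (", n, ")")
  if (!setequal(df$vertex_index, seq_len(n)))
    stop("vertex_index must cover 1..", n, " exactly once")
  labels <- df$region[order(df$vertex_index)]
  region_map(labels, mesh)
}

#' Write per-vertex region labels
#'
#' @param regions a [region_map].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_region_labels <- function(regions, path) {
  df <- data.frame(vertex_index = seq_along(regions),
                   region = as.character(regions))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
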