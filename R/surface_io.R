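# FreeSurfer binary triangle-surface magic number (0xFFFFFE)
FS_TRIANGLE_MAGIC <- 16777214L

read_fs_int3 <- function(con) {
  b <- readBin(con, "integer", 3, size = 1, signed = FALSE)
  b[1] * 65536L + b[2] * 256L + b[3]
}

write_fs_int3 <- function(con, x) {
  writeBin(as.integer(c(x %/% 65536, (x %/% 256) %% 256, x %% 256)),
           con, size = 1)
}

#' Read / write cortical surfaces
#'
#' Supports the FreeSurfer binary triangle format (big-endian: 3-byte magic,
#' comment line terminated by `\n\n`, vertex and face counts, float32 vertex
#' coordinates, int32 0-based face indices) and a plain-text fallback with
#' lines `vertex x y z` and `face i j k` (1-based indices). The format is
#' chosen by probing the magic bytes on read and by the `format` argument on
#' write.
#'
#' @param path File path.
#' @return `read_surface()`: list with `vertices` (n x 3 matrix, mm) and
#'   `faces` (m x 3 integer matrix, 1-based).
#' @export
read_surface <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "integer", 3, size = 1, signed = FALSE)
  magic_val <- magic[1] * 65536L + magic[2] * 256L + magic[3]
  if (length(magic) == 3 && magic_val == FS_TRIANGLE_MAGIC) {
    # comment string: bytes up to "\n\n"
    prev <- as.raw(0)
    repeat {
      ch <- readBin(con, "raw", 1)
      if (length(ch) == 0) stop("truncated surface file: ", path)
      if (ch == as.raw(10) && prev == as.raw(10)) break
      prev <- ch
    }
    nv <- readBin(con, "integer", 1, size = 4, endian = "big")
    nf <- readBin(con, "integer", 1, size = 4, endian = "big")
    verts <- matrix(readBin(con, "numeric", 3 * nv, size = 4, endian = "big"),
                    nv, 3, byrow = TRUE)
    faces <- matrix(readBin(con, "integer", 3 * nf, size = 4, endian = "big"),
                    nf, 3, byrow = TRUE) + 1L
    return(list(vertices = verts, faces = faces))
  }
  close(con)
  on.exit(NULL)
  read_surface_text(path)
}

read_surface_text <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  vl <- lines[startsWith(lines, "vertex")]
  fl <- lines[startsWith(lines, "face")]
  if (length(vl) == 0) stop("no 'vertex' lines found in ", path)
  verts <- do.call(rbind, lapply(strsplit(vl, "\\s+"), function(p)
    as.numeric(p[2:4])))
  faces <- if (length(fl) > 0)
    do.call(rbind, lapply(strsplit(fl, "\\s+"), function(p)
      as.integer(p[2:4])))
  else matrix(integer(0), 0, 3)
  list(vertices = verts, faces = faces)
}

#' @param vertices n x 3 matrix of coordinates (mm).
#' @param faces m x 3 integer matrix of 1-based triangle indices.
#' @param format `"freesurfer"` (binary) or `"text"`.
#' @rdname read_surface
#' @export
write_surface <- function(vertices, faces, path,
                          format = c("freesurfer", "text")) {
  format <- match.arg(format)
  vertices <- as.matrix(vertices)
  faces <- if (is.null(faces)) matrix(integer(0), 0, 3) else as.matrix(faces)
  if (format == "text") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste("vertex", vertices[, 1], vertices[, 2], vertices[, 3]), con)
    if (nrow(faces) > 0)
      writeLines(paste("face", faces[, 1], faces[, 2], faces[, 3]), con)
    return(invisible(path))
  }
  con <- file(path, "wb")
  on.exit(close(con))
  write_fs_int3(con, FS_TRIANGLE_MAGIC)
  writeBin(charToRaw("created by cortmd\n\n"), con)
  writeBin(as.integer(nrow(vertices)), con, size = 4, endian = "big")
  writeBin(as.integer(nrow(faces)), con, size = 4, endian = "big")
  writeBin(as.numeric(t(vertices)), con, size = 4, endian = "big")
  writeBin(as.integer(t(faces) - 1L), con, size = 4, endian = "big")
  invisible(path)
}

#' Read / write per-vertex parcellations
#'
#' Supports the FreeSurfer `.annot` binary format (big-endian: vertex count,
#' interleaved vertex/annotation-int pairs, optional colour table mapping
#' annotation ints to structure names) and a two-column plain-text fallback
#' `vertex label` (0-based vertex index, character label). On read, annotation
#' integers are mapped to names via the embedded colour table when present.
#'
#' @param path File path.
#' @param n_vertices Expected vertex count (text fallback validation).
#' @return `read_annot()`: character vector of per-vertex labels.
#' @export
read_annot <- function(path, n_vertices = NULL) {
  first <- readBin(path, "raw", 4)
  is_binary <- !all(first %in% c(charToRaw("0123456789 \t-"), as.raw(c(10, 13))))
  # binary .annot starts with a big-endian int32 vertex count; a text file
  # starts with ASCII digits. Probe by attempting the binary parse.
  res <- try(read_annot_binary(path), silent = TRUE)
  if (!inherits(res, "try-error")) return(res)
  tab <- utils::read.table(path, header = FALSE,
                           col.names = c("vertex", "label"),
                           colClasses = c("integer", "character"))
  labels <- character(max(tab$vertex) + 1L)
  labels[tab$vertex + 1L] <- tab$label
  if (!is.null(n_vertices) && length(labels) != n_vertices)
    stop("annotation covers ", length(labels), " vertices, expected ",
         n_vertices)
  labels
}

read_annot_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  nv <- readBin(con, "integer", 1, size = 4, endian = "big")
  if (!length(nv) || is.na(nv) || nv <= 0 || nv > 1e8) stop("not binary annot")
  pairs <- readBin(con, "integer", 2 * nv, size = 4, endian = "big")
  if (length(pairs) < 2 * nv) stop("truncated annot")
  vert <- pairs[seq(1, 2 * nv, 2)]
  ann <- pairs[seq(2, 2 * nv, 2)]
  labels <- as.character(ann)
  tag <- readBin(con, "integer", 1, size = 4, endian = "big")
  if (length(tag) == 1 && !is.na(tag) && tag == 1L) {   # colour table present
    ctab_n <- readBin(con, "integer", 1, size = 4, endian = "big")
    if (ctab_n > 0) {
      lut <- read_ctab_old(con, ctab_n)
    } else {
      lut <- read_ctab_v2(con)
    }
    m <- match(ann, lut$code)
    labels <- ifelse(is.na(m), UNKNOWN_LABEL, lut$name[m])
  }
  out <- character(nv)
  out[vert + 1L] <- labels
  out
}

read_ctab_old <- function(con, n_entries) {
  len <- readBin(con, "integer", 1, size = 4, endian = "big")
  readBin(con, "raw", len)                      # original colour-table filename
  name <- character(n_entries); code <- integer(n_entries)
  for (i in seq_len(n_entries)) {
    len <- readBin(con, "integer", 1, size = 4, endian = "big")
    nm <- rawToChar(readBin(con, "raw", len))
    name[i] <- sub("\\0+$", "", nm)
    rgba <- readBin(con, "integer", 4, size = 4, endian = "big")
    code[i] <- rgba[1] + rgba[2] * 256L + rgba[3] * 65536L
  }
  list(name = name, code = code)
}

read_ctab_v2 <- function(con) {
  version <- readBin(con, "integer", 1, size = 4, endian = "big")  # -2
  n_max <- readBin(con, "integer", 1, size = 4, endian = "big")
  len <- readBin(con, "integer", 1, size = 4, endian = "big")
  readBin(con, "raw", len)
  n_used <- readBin(con, "integer", 1, size = 4, endian = "big")
  name <- character(n_used); code <- integer(n_used)
  for (i in seq_len(n_used)) {
    readBin(con, "integer", 1, size = 4, endian = "big")           # structure id
    len <- readBin(con, "integer", 1, size = 4, endian = "big")
    nm <- rawToChar(readBin(con, "raw", len))
    name[i] <- sub("\\0+$", "", nm)
    rgba <- readBin(con, "integer", 4, size = 4, endian = "big")
    code[i] <- rgba[1] + rgba[2] * 256L + rgba[3] * 65536L
  }
  list(name = name, code = code)
}

#' @param labels Character vector of per-vertex labels.
#' @param format `"annot"` (binary with colour table) or `"text"`.
#' @rdname read_annot
#' @export
write_annot <- function(labels, path, format = c("annot", "text")) {
  format <- match.arg(format)
  if (format == "text") {
    utils::write.table(
      data.frame(vertex = seq_along(labels) - 1L, label = labels),
      path, row.names = FALSE, col.names = FALSE, quote = FALSE)
    return(invisible(path))
  }
  uniq <- unique(labels)
  code <- seq_along(uniq) * 257L        # arbitrary distinct RGB-packed codes
  ann <- code[match(labels, uniq)]
  con <- file(path, "wb")
  on.exit(close(con))
  nv <- length(labels)
  writeBin(as.integer(nv), con, size = 4, endian = "big")
  inter <- integer(2 * nv)
  inter[seq(1, 2 * nv, 2)] <- seq_len(nv) - 1L
  inter[seq(2, 2 * nv, 2)] <- ann
  writeBin(inter, con, size = 4, endian = "big")
  writeBin(1L, con, size = 4, endian = "big")               # colour table tag
  writeBin(length(uniq), con, size = 4, endian = "big")     # old format
  fname <- charToRaw("cortmd.ctab")
  writeBin(length(fname), con, size = 4, endian = "big")
  writeBin(fname, con)
  for (i in seq_along(uniq)) {
    nm <- charToRaw(uniq[i])
    writeBin(length(nm), con, size = 4, endian = "big")
    writeBin(nm, con)
    r <- code[i] %% 256L; g <- (code[i] %/% 256L) %% 256L
    b <- code[i] %/% 65536L
    writeBin(as.integer(c(r, g, b, 0L)), con, size = 4, endian = "big")
  }
  invisible(path)
}

#' Read / write a full surface bundle
#'
#' Convenience wrappers serialising the white surface, pial surface and
#' parcellation of a [make_surface_bundle()] object as three files sharing a
#' path prefix.
#'
#' @param bundle A `surface_bundle`.
#' @param prefix Path prefix; files `<prefix>.white`, `<prefix>.pial`,
#'   `<prefix>.annot` are written.
#' @param format Surface format passed to [write_surface()]; the parcellation
#'   uses the matching annot/text format.
#' @return `read_surface_bundle()`: a `surface_bundle`.
#' @export
write_surface_bundle <- function(bundle, prefix,
                                 format = c("freesurfer", "text")) {
  format <- match.arg(format)
  validate_bundle(bundle)
  ext <- if (format == "text") ".txt" else ""
  write_surface(bundle$white, bundle$faces, paste0(prefix, ".white", ext), format)
  write_surface(bundle$pial, bundle$faces, paste0(prefix, ".pial", ext), format)
  write_annot(bundle$parcellation, paste0(prefix, ".annot", ext),
              if (format == "text") "text" else "annot")
  invisible(prefix)
}

#' @rdname write_surface_bundle
#' @export
read_surface_bundle <- function(prefix, format = c("freesurfer", "text")) {
  format <- match.arg(format)
  ext <- if (format == "text") ".txt" else ""
  white <- read_surface(paste0(prefix, ".white", ext))
  pial <- read_surface(paste0(prefix, ".pial", ext))
  labels <- read_annot(paste0(prefix, ".annot", ext), nrow(white$vertices))
  roi_names <- setdiff(unique(labels), UNKNOWN_LABEL)
  if (all(dk_roi_names() %in% roi_names)) roi_names <- dk_roi_names()
  validate_bundle(structure(
    list(white = white$vertices, pial = pial$vertices, faces = white$faces,
         parcellation = labels, roi_names = roi_names),
    class = "surface_bundle"))
}
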