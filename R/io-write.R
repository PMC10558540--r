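#' Write landmark datasets
#'
#' Inverse of [read_landmarks()] for the wide CSV, long CSV (+ metadata
#' sidecar) and TPS dialects. `read_landmarks(write_landmarks(x))` reproduces
#' the coordinates to full double precision.
#'
#' @param x A `specimen_set`.
#' @param path Output file.
#' @param format `"wide"`, `"long"` or `"tps"`.
#' @param metadata_path Optional sidecar CSV for the specimen metadata (long
#'   and tps formats).
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(x, path, format = c("wide", "long", "tps"),
                            metadata_path = NULL) {
  stopifnot(inherits(x, "specimen_set"))
  format <- match.arg(format)
  arr <- x$array
  k <- dim(arr)[1]; n <- dim(arr)[3]
  if (format == "wide") {
    co <- t(vapply(seq_len(n), function(i) as.vector(t(arr[, , i])), numeric(3 * k)))
    colnames(co) <- as.vector(t(outer(seq_len(k), c("x", "y", "z"),
                                      function(i, a) paste0(a, "_", i))))
    df <- dplyr::bind_cols(x$specimens, as_tibble(co))
    readr::write_csv(df, path)
  } else if (format == "long") {
    readr::write_csv(as_tibble(x)[, c("specimen_id", "point_id", "x", "y", "z")], path)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    for (i in seq_len(n)) {
      writeLines(sprintf("LM3=%d", k), con)
      writeLines(apply(arr[, , i], 1, function(r) {
        paste(format(r, digits = 17, scientific = FALSE, trim = TRUE), collapse = " ")
      }), con)
      writeLines(sprintf("ID=%s", dimnames(arr)[[3]][i]), con)
    }
  }
  if (!is.null(metadata_path)) readr::write_csv(x$specimens, metadata_path)
  invisible(path)
}

# linear cool->warm ramp (blue -> light grey -> red) on [0, 1]
coolwarm_colors <- function(t) {
  ramp <- grDevices::colorRamp(c("#3B4CC0", "#DDDDDD", "#B40426"))
  rgb <- ramp(pmin(1, pmax(0, t)))
  storage.mode(rgb) <- "integer"
  rgb
}

#' Write a mesh as ASCII PLY with per-vertex colors
#'
#' @param coords `n x 3` vertex matrix.
#' @param faces `m x 3` 1-based triangle index matrix (written 0-based).
#' @param values Optional per-vertex scalar mapped linearly from
#'   `[min, max]` onto a cool-to-warm ramp (constant fields map to the
#'   mid-ramp color).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_ply <- function(coords, faces, path, values = NULL) {
  coords <- as.matrix(coords)
  faces <- validate_faces(faces, nrow(coords))
  has_col <- !is.null(values)
  hdr <- c(
    "ply", "format ascii 1.0", "comment morphosignal accuracy map",
    sprintf("element vertex %d", nrow(coords)),
    "property float x", "property float y", "property float z",
    if (has_col) c("property uchar red", "property uchar green", "property uchar blue"),
    sprintf("element face %d", nrow(faces)),
    "property list uchar int vertex_indices", "end_header"
  )
  if (has_col) {
    rng <- range(values, na.rm = TRUE)
    t <- if (diff(rng) < 1e-12) rep(0.5, length(values)) else (values - rng[1]) / diff(rng)
    t[is.na(t)] <- 0.5
    rgb <- coolwarm_colors(t)
    vlines <- sprintf("%.9g %.9g %.9g %d %d %d", coords[, 1], coords[, 2],
                      coords[, 3], rgb[, 1], rgb[, 2], rgb[, 3])
  } else {
    vlines <- sprintf("%.9g %.9g %.9g", coords[, 1], coords[, 2], coords[, 3])
  }
  flines <- sprintf("3 %d %d %d", faces[, 1] - 1L, faces[, 2] - 1L, faces[, 3] - 1L)
  writeLines(c(hdr, vlines, flines), path)
  invisible(path)
}

#' Read an ASCII PLY mesh (structural check / round-trips)
#'
#' @param path PLY file.
#' @return List with `vertices`, `faces` (1-based) and, when present, `rgb`.
#' @export
read_ply <- function(path) {
  lines <- readLines(path)
  if (lines[1] != "ply") abort("not a PLY file")
  end <- match("end_header", lines)
  hdr <- lines[seq_len(end)]
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", hdr, value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face", hdr, value = TRUE)))
  has_col <- any(grepl("property uchar red", hdr))
  if (length(lines) < end + nv + nf) abort("truncated PLY: fewer rows than the header declares")
  vparts <- strsplit(lines[end + seq_len(nv)], "\\s+")
  vm <- do.call(rbind, lapply(vparts, as.numeric))
  fparts <- strsplit(lines[end + nv + seq_len(nf)], "\\s+")
  fm <- do.call(rbind, lapply(fparts, as.integer))
  if (any(fm[, 1] != 3)) abort("non-triangular face in PLY")
  out <- list(vertices = vm[, 1:3, drop = FALSE], faces = fm[, 2:4, drop = FALSE] + 1L)
  if (has_col) out$rgb <- vm[, 4:6, drop = FALSE]
  out
}

#' Write an accuracy map as CSV and colored PLY
#'
#' @param map An `accuracy_map`.
#' @param out_csv Output CSV (one row per point: point_id, acc_total, acc_f,
#'   acc_m, space).
#' @param out_ply Optional PLY path; needs `faces` (and uses the consensus
#'   stored in the map unless `consensus` is given).
#' @param faces Triangulation for the PLY output.
#' @param consensus Optional `n x 3` vertex matrix overriding the map's
#'   consensus.
#' @return `out_csv`, invisibly.
#' @export
write_accuracy_map <- function(map, out_csv, out_ply = NULL, faces = NULL,
                               consensus = NULL) {
  stopifnot(inherits(map, "accuracy_map"))
  df <- tibble(point_id = map$point_id, acc_total = map$acc_total,
               acc_f = map$acc_f, acc_m = map$acc_m,
               space = attr(map, "space"))
  readr::write_csv(df, out_csv)
  if (!is.null(out_ply)) {
    cons <- consensus %||% attr(map, "consensus")
    if (is.null(cons)) abort("no consensus coordinates available for the PLY output")
    if (is.null(faces)) abort("faces are required for PLY output")
    if (nrow(cons) != nrow(map)) abort("map length does not match the vertex count")
    write_ply(cons, faces, out_ply, values = map$acc_total)
  }
  invisible(out_csv)
}

#' Read an accuracy map CSV back into an accuracy_map
#'
#' @param path CSV written by [write_accuracy_map()].
#' @return An `accuracy_map` tibble (without consensus/neighborhood
#'   attributes).
#' @export
read_accuracy_map <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  out <- tibble(point_id = as.character(df$point_id), acc_total = df$acc_total,
                acc_f = df$acc_f, acc_m = df$acc_m)
  class(out) <- c("accuracy_map", class(out))
  attr(out, "space") <- df$space[1]
  out
}
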