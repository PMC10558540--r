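#' Read landmark datasets
#'
#' Reads per-specimen 3D landmark/semilandmark coordinates (mm) plus
#' specimen metadata into a [as_specimen_set()] object. Supported dialects:
#'
#' * `"wide"` CSV — one row per specimen: `specimen_id`, optional `sex`,
#'   `population`, `replicate_of`, then `x_1, y_1, z_1, x_2, ...`;
#' * `"long"` CSV — one row per point: `specimen_id, point_id, x, y, z`,
#'   with metadata either inline or in a sidecar CSV
#'   (`specimen_id, sex, population, replicate_of`);
#' * `"tps"` — Rohlf TPS with `LM3=` blocks, coordinate rows and `ID=`
#'   lines (`SCALE=` is applied when present);
#' * `"fcsv"` — 3D Slicer markups, one file per specimen (pass a vector of
#'   files or a directory); the header's `CoordinateSystem` is honored and
#'   coordinates converted to `coordinate_system` (LPS and RAS differ by the
#'   sign of x and y), never silently mixed.
#'
#' File dialects with 1-based or label-based point numbering are converted
#' to the package's 0-independent internal ordering at this boundary.
#' Missing or non-numeric coordinates are rejected, not imputed.
#'
#' @param path File path (or, for fcsv, files/directory).
#' @param format One of `"auto"`, `"wide"`, `"long"`, `"tps"`, `"fcsv"`.
#'   `"auto"` picks by file extension and header.
#' @param metadata Optional sidecar metadata: a path to a CSV or a data
#'   frame with `specimen_id` plus `sex`/`population`/`replicate_of`.
#' @param points Optional point-scheme tibble (see [as_specimen_set()]).
#' @param coordinate_system Target system for fcsv input: `"RAS"` (default)
#'   or `"LPS"`.
#' @return A `specimen_set`.
#' @export
read_landmarks <- function(path, format = c("auto", "wide", "long", "tps", "fcsv"),
                           metadata = NULL, points = NULL,
                           coordinate_system = c("RAS", "LPS")) {
  format <- match.arg(format)
  coordinate_system <- match.arg(coordinate_system)
  if (format == "auto") format <- guess_format(path)
  meta <- read_metadata(metadata)
  set <- switch(format,
    wide = read_wide_csv(path),
    long = read_long_csv(path),
    tps = read_tps(path),
    fcsv = read_fcsv_set(path, coordinate_system),
    abort(paste0("unknown landmark format: ", format))
  )
  if (!is.null(meta)) {
    set <- as_specimen_set(set$array, specimens = meta, points = points %||% set$points)
  } else if (!is.null(points)) {
    set <- as_specimen_set(set$array, specimens = set$specimens, points = points)
  }
  set
}

guess_format <- function(path) {
  if (length(path) > 1 || (length(path) == 1 && dir.exists(path))) return("fcsv")
  ext <- tolower(tools::file_ext(path))
  if (ext == "tps") return("tps")
  if (ext == "fcsv") return("fcsv")
  if (ext == "csv") {
    hdr <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE))
    if (all(c("point_id", "x", "y", "z") %in% hdr)) return("long")
    return("wide")
  }
  abort(paste0("cannot guess landmark format of '", path, "'"))
}

read_metadata <- function(metadata) {
  if (is.null(metadata)) return(NULL)
  if (is.character(metadata)) {
    metadata <- readr::read_csv(metadata, show_col_types = FALSE)
  }
  as_tibble(metadata)
}

check_numeric_coords <- function(df, cols, path) {
  for (col in cols) {
    if (is.character(df[[col]])) {
      suppressWarnings(num <- as.numeric(df[[col]]))
      bad <- which(is.na(num) & !is.na(df[[col]]))
      if (length(bad) > 0) {
        abort(sprintf("non-numeric coordinate in '%s', column %s, line %d",
                      path, col, bad[1] + 1L))
      }
      df[[col]] <- num
    }
    if (anyNA(df[[col]])) {
      abort(sprintf("missing coordinate in '%s', column %s, line %d",
                    path, col, which(is.na(df[[col]]))[1] + 1L))
    }
  }
  df
}

read_long_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  need <- c("specimen_id", "point_id", "x", "y", "z")
  miss <- setdiff(need, names(df))
  if (length(miss)) abort(paste0("'", path, "' lacks column(s): ", paste(miss, collapse = ", ")))
  df <- check_numeric_coords(df, c("x", "y", "z"), path)
  meta_cols <- intersect(c("sex", "population", "replicate_of"), names(df))
  meta <- NULL
  if (length(meta_cols) > 0) {
    meta <- dplyr::distinct(df[, c("specimen_id", meta_cols)])
  }
  as_specimen_set(df[, need], specimens = meta)
}

read_wide_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  if (!"specimen_id" %in% names(df)) abort(paste0("'", path, "' lacks specimen_id"))
  xcols <- grep("^x_", names(df), value = TRUE)
  idx <- as.integer(sub("^x_", "", xcols))
  if (length(xcols) == 0 || anyNA(idx)) abort(paste0("'", path, "' has no x_<i> coordinate columns"))
  ord <- order(idx)
  k <- length(xcols)
  coord_cols <- as.vector(rbind(paste0("x_", idx[ord]), paste0("y_", idx[ord]),
                                paste0("z_", idx[ord])))
  miss <- setdiff(coord_cols, names(df))
  if (length(miss)) abort(paste0("'", path, "' lacks column(s): ", paste(head(miss, 3), collapse = ", ")))
  df <- check_numeric_coords(df, coord_cols, path)
  n <- nrow(df)
  arr <- array(NA_real_, c(k, 3, n),
               dimnames = list(paste0("p", idx[ord]), c("x", "y", "z"), df$specimen_id))
  for (i in seq_len(n)) {
    arr[, 1, i] <- as.numeric(unlist(df[i, paste0("x_", idx[ord])]))
    arr[, 2, i] <- as.numeric(unlist(df[i, paste0("y_", idx[ord])]))
    arr[, 3, i] <- as.numeric(unlist(df[i, paste0("z_", idx[ord])]))
  }
  meta_cols <- intersect(c("sex", "population", "replicate_of"), names(df))
  meta <- if (length(meta_cols)) df[, c("specimen_id", meta_cols)] else NULL
  as_specimen_set(arr, specimens = meta)
}

read_tps <- function(path) {
  lines <- readLines(path)
  blocks <- list(); ids <- character(); cur <- NULL; expect <- 0L; scale <- 1
  bn <- 0L
  for (ln in seq_along(lines)) {
    line <- trimws(lines[ln])
    if (line == "") next
    if (grepl("^LM3?\\s*=", line, ignore.case = TRUE)) {
      if (!is.null(cur)) {
        blocks[[bn]] <- finish_tps_block(cur, expect, scale, path, ln)
      }
      bn <- bn + 1L
      expect <- as.integer(sub(".*=\\s*", "", line))
      cur <- matrix(NA_real_, 0, 3); scale <- 1
      ids[bn] <- paste0("specimen_", bn)
    } else if (grepl("^ID\\s*=", line, ignore.case = TRUE)) {
      ids[bn] <- sub(".*=\\s*", "", line)
    } else if (grepl("^SCALE\\s*=", line, ignore.case = TRUE)) {
      scale <- as.numeric(sub(".*=\\s*", "", line))
    } else if (grepl("^(IMAGE|CURVES|POINTS)\\s*=", line, ignore.case = TRUE)) {
      next
    } else {
      if (bn == 0L) abort(sprintf("coordinate row before any LM3= header in '%s', line %d", path, ln))
      vals <- suppressWarnings(as.numeric(strsplit(line, "\\s+")[[1]]))
      if (length(vals) != 3 || anyNA(vals)) {
        abort(sprintf("non-numeric coordinate in '%s', line %d", path, ln))
      }
      cur <- rbind(cur, vals)
    }
  }
  if (!is.null(cur)) blocks[[bn]] <- finish_tps_block(cur, expect, scale, path, length(lines))
  if (length(blocks) == 0) abort(paste0("no LM3 blocks found in '", path, "'"))
  ks <- vapply(blocks, nrow, integer(1))
  if (length(unique(ks)) != 1) {
    abort(sprintf("mismatched point counts in '%s': specimen '%s' has %d points, expected %d",
                  path, ids[which(ks != ks[1])[1]], ks[ks != ks[1]][1], ks[1]))
  }
  arr <- array(NA_real_, c(ks[1], 3, length(blocks)),
               dimnames = list(paste0("p", seq_len(ks[1])), c("x", "y", "z"), ids))
  for (i in seq_along(blocks)) arr[, , i] <- blocks[[i]]
  as_specimen_set(arr)
}

finish_tps_block <- function(cur, expect, scale, path, ln) {
  if (nrow(cur) != expect) {
    abort(sprintf("TPS block in '%s' (near line %d) has %d coordinate rows but LM3=%d",
                  path, ln, nrow(cur), expect))
  }
  unname(cur * scale)
}

# One 3D Slicer markups fcsv file = one specimen
read_fcsv <- function(path, coordinate_system = "RAS") {
  lines <- readLines(path)
  header <- grep("^#", lines, value = TRUE)
  sys_line <- grep("CoordinateSystem", header, value = TRUE)
  file_sys <- "RAS"
  if (length(sys_line) > 0) {
    v <- trimws(sub(".*[=:]\\s*", "", sys_line[1]))
    file_sys <- switch(v, "0" = "RAS", "1" = "LPS", "RAS" = "RAS", "LPS" = "LPS",
                       abort(paste0("unknown CoordinateSystem '", v, "' in ", path)))
  }
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0) abort(paste0("no landmark rows in '", path, "'"))
  cols_line <- grep("columns\\s*=", header, value = TRUE, ignore.case = TRUE)
  col_names <- if (length(cols_line) > 0) {
    strsplit(trimws(sub(".*=\\s*", "", cols_line[1])), ",")[[1]]
  } else {
    c("id", "x", "y", "z", "ow", "ox", "oy", "oz", "vis", "sel", "lock",
      "label", "desc", "associatedNodeID")
  }
  df <- utils::read.csv(text = body, header = FALSE, stringsAsFactors = FALSE)
  names(df)[seq_along(col_names)] <- col_names
  need <- c("x", "y", "z")
  if (!all(need %in% names(df))) abort(paste0("'", path, "' lacks x/y/z columns"))
  df <- check_numeric_coords(df, need, path)
  m <- as.matrix(df[, need])
  if (file_sys != coordinate_system) m[, 1:2] <- -m[, 1:2]  # LPS <-> RAS
  labels <- if ("label" %in% names(df) && !anyNA(df$label) && !anyDuplicated(df$label)) {
    as.character(df$label)
  } else {
    paste0("p", seq_len(nrow(m)))
  }
  rownames(m) <- labels
  m
}

read_fcsv_set <- function(path, coordinate_system) {
  files <- path
  if (length(path) == 1 && dir.exists(path)) {
    files <- list.files(path, pattern = "\\.fcsv$", full.names = TRUE)
  }
  if (length(files) == 0) abort("no fcsv files found")
  mats <- lapply(files, read_fcsv, coordinate_system = coordinate_system)
  ids <- sub("\\.fcsv$", "", basename(files))
  ks <- vapply(mats, nrow, integer(1))
  if (length(unique(ks)) != 1) {
    bad <- which(ks != ks[1])[1]
    abort(sprintf("mismatched point counts: specimen '%s' has %d points, expected %d",
                  ids[bad], ks[bad], ks[1]))
  }
  arr <- array(NA_real_, c(ks[1], 3, length(mats)),
               dimnames = list(rownames(mats[[1]]), c("x", "y", "z"), ids))
  for (i in seq_along(mats)) {
    m <- mats[[i]]
    if (!identical(rownames(m), rownames(mats[[1]]))) {
      if (setequal(rownames(m), rownames(mats[[1]]))) {
        m <- m[rownames(mats[[1]]), , drop = FALSE]
      } else {
        abort(sprintf("specimen '%s' has point labels inconsistent with '%s'",
                      ids[i], ids[1]))
      }
    }
    arr[, , i] <- m
  }
  as_specimen_set(arr)
}
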