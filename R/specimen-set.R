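#' Assemble a specimen set from landmark records
#'
#' A `specimen_set` holds the ordered 3D landmark/semilandmark configurations
#' of a sample of specimens sharing one point scheme, together with specimen
#' metadata (sex, population, replicate structure) and per-point roles and
#' bilateral pairing. It is the input to [gpa()], [map_signal()] and the rest
#' of the pipeline.
#'
#' @param x Either a long data frame with columns `specimen_id`, `point_id`,
#'   `x`, `y`, `z` (coordinates in mm), or a numeric array of dimension
#'   `n_points x 3 x n_specimens`.
#' @param specimens Optional tibble of specimen metadata with columns
#'   `specimen_id` and any of `sex` (`"F"`/`"M"`), `population`,
#'   `replicate_of`. Missing columns are filled with `NA`.
#' @param points Optional tibble describing the point scheme: `point_id`,
#'   `role` (`"landmark"` or `"semilandmark"`), `side` (`"L"`, `"R"`, `"M"`
#'   for midline, or `NA`), `pair` (integer id shared by the left and right
#'   member of a bilateral pair, `NA` otherwise).
#' @return An object of class `specimen_set`.
#' @examples
#' df <- tibble::tibble(
#'   specimen_id = rep(c("a", "b"), each = 4),
#'   point_id = rep(paste0("p", 1:4), 2),
#'   x = rnorm(8), y = rnorm(8), z = rnorm(8)
#' )
#' as_specimen_set(df)
#' @export
as_specimen_set <- function(x, specimens = NULL, points = NULL) {
  if (is.array(x) && length(dim(x)) == 3) {
    arr <- x
    if (dim(arr)[2] != 3) abort("coordinate array must be n_points x 3 x n_specimens")
    if (is.null(dimnames(arr)[[1]])) dimnames(arr)[[1]] <- paste0("p", seq_len(dim(arr)[1]))
    if (is.null(dimnames(arr)[[3]])) dimnames(arr)[[3]] <- paste0("s", seq_len(dim(arr)[3]))
    dimnames(arr)[[2]] <- c("x", "y", "z")
  } else if (is.data.frame(x)) {
    need <- c("specimen_id", "point_id", "x", "y", "z")
    miss <- setdiff(need, names(x))
    if (length(miss) > 0) {
      abort(paste0("long landmark table lacks column(s): ", paste(miss, collapse = ", ")))
    }
    spec_ids <- unique(as.character(x$specimen_id))
    first <- x[x$specimen_id == spec_ids[1], ]
    pt_ids <- as.character(first$point_id)
    if (anyDuplicated(pt_ids)) abort("duplicated point_id within a specimen")
    arr <- array(NA_real_, dim = c(length(pt_ids), 3, length(spec_ids)),
                 dimnames = list(pt_ids, c("x", "y", "z"), spec_ids))
    for (s in spec_ids) {
      rows <- x[x$specimen_id == s, ]
      if (nrow(rows) != length(pt_ids) || !setequal(as.character(rows$point_id), pt_ids)) {
        abort(paste0("specimen '", s, "' has a point set inconsistent with specimen '",
                     spec_ids[1], "'"))
      }
      m <- as.matrix(rows[match(pt_ids, as.character(rows$point_id)), c("x", "y", "z")])
      arr[, , s] <- m
    }
  } else {
    abort("x must be a long data frame or a 3D array")
  }
  if (!all(is.finite(arr))) abort("all landmark coordinates must be finite")
  if (dim(arr)[1] < 4) abort("a configuration needs at least 4 points")

  sp <- tibble(specimen_id = dimnames(arr)[[3]])
  if (!is.null(specimens)) {
    specimens <- as_tibble(specimens)
    specimens$specimen_id <- as.character(specimens$specimen_id)
    if (!all(sp$specimen_id %in% specimens$specimen_id)) {
      abort("metadata is missing rows for some specimens")
    }
    sp <- dplyr::left_join(sp, specimens, by = "specimen_id")
  }
  for (col in c("sex", "population", "replicate_of")) {
    if (!col %in% names(sp)) sp[[col]] <- NA_character_
  }
  bad_sex <- !is.na(sp$sex) & !sp$sex %in% c("F", "M")
  if (any(bad_sex)) {
    abort(paste0("sex labels must be 'F' or 'M'; offending specimen(s): ",
                 paste(sp$specimen_id[bad_sex], collapse = ", ")))
  }

  pt <- tibble(point_id = dimnames(arr)[[1]])
  if (!is.null(points)) {
    points <- as_tibble(points)
    points$point_id <- as.character(points$point_id)
    if (!setequal(points$point_id, pt$point_id)) {
      abort("points table must describe exactly the points present")
    }
    pt <- dplyr::left_join(pt, points, by = "point_id")
  }
  if (!"role" %in% names(pt)) pt$role <- "semilandmark"
  if (!"side" %in% names(pt)) pt$side <- NA_character_
  if (!"pair" %in% names(pt)) pt$pair <- NA_integer_
  pt$pair <- as.integer(pt$pair)
  validate_pairing(pt)

  structure(list(array = arr, specimens = sp, points = pt), class = "specimen_set")
}

validate_pairing <- function(pt) {
  paired <- !is.na(pt$pair)
  if (any(paired & !is.na(pt$side) & pt$side == "M")) {
    abort("a point cannot be both midline and member of a bilateral pair")
  }
  if (any(paired)) {
    tb <- table(pt$pair[paired])
    if (any(tb != 2)) abort("every pair id must occur on exactly two points")
    sides <- split(pt$side[paired], pt$pair[paired])
    ok <- vapply(sides, function(s) setequal(s, c("L", "R")), logical(1))
    if (!all(ok)) abort("each bilateral pair needs one 'L' and one 'R' point")
  }
  invisible(pt)
}

#' @export
print.specimen_set <- function(x, ...) {
  d <- dim(x$array)
  sx <- table(factor(x$specimens$sex, levels = c("F", "M")))
  cat("<specimen_set> ", d[3], " specimens x ", d[1], " points\n", sep = "")
  cat("  sex: F=", sx[["F"]], " M=", sx[["M"]],
      "  paired points: ", sum(!is.na(x$points$pair)),
      "  midline: ", sum(!is.na(x$points$side) & x$points$side == "M"), "\n", sep = "")
  invisible(x)
}

#' Landmark coordinate array of a specimen set
#' @param x A `specimen_set`.
#' @return Numeric array `n_points x 3 x n_specimens`.
#' @export
landmark_array <- function(x) {
  stopifnot(inherits(x, "specimen_set"))
  x$array
}

#' Specimen metadata of a specimen set
#' @param x A `specimen_set`.
#' @return A tibble with one row per specimen.
#' @export
specimen_info <- function(x) {
  stopifnot(inherits(x, "specimen_set"))
  x$specimens
}

#' Point scheme of a specimen set
#' @param x A `specimen_set`.
#' @return A tibble with one row per point (role, side, pair).
#' @export
point_info <- function(x) {
  stopifnot(inherits(x, "specimen_set"))
  x$points
}

#' @export
dim.specimen_set <- function(x) dim(x$array)

n_specimens <- function(x) dim(x$array)[3]
n_points_of <- function(x) dim(x$array)[1]

#' @export
as_tibble.specimen_set <- function(x, ...) {
  arr <- x$array
  k <- dim(arr)[1]; n <- dim(arr)[3]
  out <- tibble(
    specimen_id = rep(dimnames(arr)[[3]], each = k),
    point_id = rep(dimnames(arr)[[1]], times = n),
    x = as.vector(arr[, 1, ]),
    y = as.vector(arr[, 2, ]),
    z = as.vector(arr[, 3, ])
  )
  dplyr::left_join(out, x$specimens, by = "specimen_id")
}

#' Subset a specimen set by specimen
#'
#' @param x A `specimen_set`.
#' @param which Logical, integer or character vector selecting specimens.
#' @return A `specimen_set` with the selected specimens, in the given order.
#' @export
filter_specimens <- function(x, which) {
  stopifnot(inherits(x, "specimen_set"))
  ids <- dimnames(x$array)[[3]]
  if (is.logical(which)) which <- ids[which]
  if (is.numeric(which)) which <- ids[which]
  arr <- x$array[, , which, drop = FALSE]
  sp <- x$specimens[match(which, x$specimens$specimen_id), ]
  structure(list(array = arr, specimens = sp, points = x$points), class = "specimen_set")
}

#' Subset a specimen set by point
#'
#' @param x A `specimen_set`.
#' @param idx Integer indices (or point ids) of the points to keep.
#' @return A `specimen_set` restricted to those points. Pairing information is
#'   kept only for pairs whose two members both survive.
#' @export
subset_points <- function(x, idx) {
  stopifnot(inherits(x, "specimen_set"))
  if (is.character(idx)) idx <- match(idx, dimnames(x$array)[[1]])
  arr <- x$array[idx, , , drop = FALSE]
  pt <- x$points[idx, ]
  broken <- !is.na(pt$pair) & !(pt$pair %in% pt$pair[duplicated(pt$pair)])
  pt$pair[broken] <- NA_integer_
  pt$side[broken] <- NA_character_
  structure(list(array = arr, specimens = x$specimens, points = pt), class = "specimen_set")
}

# (left, right) index matrix and midline indices, for symmetrization
pairs_matrix <- function(x) {
  pt <- x$points
  ids <- which(!is.na(pt$pair))
  if (length(ids) == 0) return(matrix(integer(0), ncol = 2))
  sp <- split(ids, pt$pair[ids])
  t(vapply(sp, function(ii) {
    c(ii[pt$side[ii] == "L"], ii[pt$side[ii] == "R"])
  }, integer(2)))
}

midline_indices <- function(x) {
  which(!is.na(x$points$side) & x$points$side == "M")
}
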