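# Reader/writer for the 5-column whitespace text export of IMOD
# segmentation models ("object contour x y z", one point per line).

#' Read a model2point contour file
#'
#' Parses the 5-column `object contour x y z` dialect into a
#' [contour_scene()]. Object indices carry no semantics in the file, so a
#' mapping from object index to label must be supplied (the deposited data
#' layout is not self-describing).
#'
#' @param path text file of whitespace-separated rows.
#' @param labels named character vector mapping object index to label,
#'   e.g. `c("1" = "mitochondrion", "2" = "vesicle")`.
#' @param scale nm per pixel for the scene.
#' @return a [contour_scene()]; coordinates stay in pixels.
#' @examples
#' f <- tempfile()
#' writeLines(c("1 1 0 0 0", "1 1 10 0 0", "1 1 10 10 0"), f)
#' sc <- read_model2point(f, labels = c("1" = "mitochondrion"), scale = 1)
#' @export
read_model2point <- function(path, labels, scale) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (!length(nonblank)) {
    warning("empty model2point file: ", path, call. = FALSE)
    return(contour_scene(list(), scale = scale, source = path))
  }
  parts <- strsplit(trimws(lines[nonblank]), "\\s+")
  bad <- which(lengths(parts) != 5L)
  if (length(bad)) {
    stop(sprintf("line %d of %s has %d fields (expected 5)",
                 nonblank[bad[1L]], path, lengths(parts)[bad[1L]]),
         call. = FALSE)
  }
  m <- matrix(suppressWarnings(as.numeric(unlist(parts))),
              ncol = 5L, byrow = TRUE)
  if (any(!is.finite(m))) {
    stop("non-numeric field in ", path, call. = FALSE)
  }
  obj_idx <- m[, 1L]
  objects <- list()
  for (oi in unique(obj_idx)) {
    key <- as.character(as.integer(oi))
    if (!key %in% names(labels)) {
      stop(sprintf("object index %s has no label mapping", key),
           call. = FALSE)
    }
    sub <- m[obj_idx == oi, , drop = FALSE]
    contours <- lapply(unique(sub[, 2L]), function(ci) {
      pts <- sub[sub[, 2L] == ci, 3:5, drop = FALSE]
      colnames(pts) <- c("x", "y", "z")
      pts
    })
    objects[[length(objects) + 1L]] <-
      list(label = unname(labels[key]), contours = contours)
  }
  contour_scene(objects, scale = scale, source = path)
}

#' Write a scene as model2point text
#'
#' Inverse of [read_model2point()]: emits one `object contour x y z` row
#' per point, objects and contours numbered from 1 in scene order.
#' Coordinates are written with enough digits to round-trip to 1e-6.
#'
#' @param scene a [contour_scene()].
#' @param path output file.
#' @return invisibly, the label mapping used (for the reader).
#' @export
write_model2point <- function(scene, path) {
  lines <- character(0)
  labels <- character(0)
  for (oi in seq_along(scene$objects)) {
    ob <- scene$objects[[oi]]
    labels[as.character(oi)] <- ob$label
    for (ci in seq_along(ob$contours)) {
      ct <- ob$contours[[ci]]
      lines <- c(lines, sprintf("%d %d %.12g %.12g %.12g", oi, ci,
                                ct[, 1L], ct[, 2L], ct[, 3L]))
    }
  }
  writeLines(lines, path)
  invisible(labels)
}

#' Write ground truth (or any metadata) as a JSON sidecar
#'
#' @param x a list (e.g. from [ground_truth()]).
#' @param path output `.json` file.
#' @export
write_ground_truth <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", null = "null")
  invisible(path)
}

#' Read a JSON ground-truth sidecar
#'
#' @param path `.json` file written by [write_ground_truth()].
#' @return a list.
#' @export
read_ground_truth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
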