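# Reading/writing labelled point clouds (ASCII PLY, delimited text) and chunk
# manifests (JSON). Only the ASCII 1.0 PLY subset with per-vertex
# x y z red green blue [integer label] properties is supported; binary PLY is
# out of scope.

PLY_LABEL_PROPERTY <- "scalar_label"  # CloudCompare's scalar-field convention

#' Read a labelled point cloud from disk
#'
#' Supported formats: \code{"ply_ascii"} (per-vertex properties
#' \code{x y z red green blue} plus an optional integer label property,
#' by default \code{scalar_label}) and \code{"xyz_table"} (whitespace- or
#' comma-delimited text with 6 columns \code{x y z r g b} or 7 columns with a
#' trailing integer label). A missing label column yields an all-unlabelled
#' cloud; an on-disk label of \code{-1} is the unlabelled sentinel.
#'
#' @param path file to read.
#' @param format \code{"ply_ascii"} or \code{"xyz_table"}; default guesses
#'   from the file extension (".ply" vs anything else).
#' @param scheme the \code{\linkS4class{ClassScheme}} labels refer to.
#' @param labelProperty for PLY: name of the integer per-vertex property
#'   holding the class label.
#' @param cloudId identifier for the returned cloud; defaults to the file
#'   name without extension.
#' @return a validated \code{\linkS4class{LabeledPointCloud}}.
#' @seealso \code{\link{writeCloud}}
#' @export
readCloud <- function(path, format = c("auto", "ply_ascii", "xyz_table"),
                      scheme = defaultClassScheme(),
                      labelProperty = PLY_LABEL_PROPERTY, cloudId = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.ply$", path, ignore.case = TRUE)) "ply_ascii" else "xyz_table"
  if (is.null(cloudId)) cloudId <- sub("\\.[^.]*$", "", basename(path))
  tab <- switch(format,
                ply_ascii = readPlyTable(path, labelProperty),
                xyz_table = readXyzTable(path))
  labels <- tab$labels
  C <- nClasses(scheme)
  if (!is.null(labels)) {
    labels[labels == -1] <- NA_integer_
    bad <- which(!is.na(labels) & (labels < 0 | labels >= C))
    if (length(bad))
      stop(sprintf("label %d at record %d of '%s' is outside 0..%d",
                   labels[bad[1]], bad[1], path, C - 1L))
  }
  LabeledPointCloud(tab$positions, tab$colours, labels,
                    cloudId = cloudId, scheme = scheme)
}

readPlyTable <- function(path, labelProperty) {
  con <- file(path, "r")
  on.exit(close(con))
  if (!identical(trimws(readLines(con, n = 1)), "ply"))
    stop("malformed PLY header in '", path, "': missing 'ply' magic line")
  props <- character()
  nVertex <- NA_integer_
  inVertex <- FALSE
  nHeader <- 1L
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0) stop("malformed PLY header in '", path, "': no end_header")
    nHeader <- nHeader + 1L
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (identical(tok[1], "format")) {
      if (!identical(tok[2], "ascii"))
        stop("only ASCII PLY is supported ('", path, "' is ", tok[2], ")")
    } else if (identical(tok[1], "element")) {
      inVertex <- identical(tok[2], "vertex")
      if (inVertex) nVertex <- as.integer(tok[3])
    } else if (identical(tok[1], "property") && inVertex) {
      props <- c(props, tok[length(tok)])
    } else if (identical(tok[1], "end_header")) break
  }
  if (is.na(nVertex)) stop("malformed PLY header in '", path, "': no vertex element")
  need <- c("x", "y", "z", "red", "green", "blue")
  if (!all(need %in% props))
    stop("PLY '", path, "' lacks required vertex properties: ",
         paste(setdiff(need, props), collapse = ", "))
  tab <- utils::read.table(path, skip = nHeader, nrows = nVertex,
                           col.names = props, colClasses = "numeric",
                           fill = FALSE)
  if (nrow(tab) < nVertex)
    stop("PLY '", path, "' declares ", nVertex, " vertices but has ", nrow(tab))
  labels <- NULL
  if (labelProperty %in% props) {
    lab <- tab[[labelProperty]]
    if (any(abs(lab - round(lab)) > 1e-9))
      stop(sprintf("non-integer label at record %d of '%s'",
                   which(abs(lab - round(lab)) > 1e-9)[1], path))
    labels <- as.integer(round(lab))
  }
  list(positions = as.matrix(tab[, c("x", "y", "z")]),
       colours = as.matrix(tab[, c("red", "green", "blue")]),
       labels = labels)
}

readXyzTable <- function(path) {
  first <- readLines(path, n = 1)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  tab <- tryCatch(utils::read.table(path, sep = sep, header = FALSE),
                  error = function(e) stop("malformed table '", path, "': ",
                                           conditionMessage(e)))
  if (!ncol(tab) %in% c(6L, 7L))
    stop("'", path, "' must have 6 or 7 columns, found ", ncol(tab))
  if (!all(vapply(tab, is.numeric, logical(1))))
    stop("non-numeric value in '", path, "'")
  labels <- NULL
  if (ncol(tab) == 7L) {
    lab <- tab[[7]]
    if (any(abs(lab - round(lab)) > 1e-9))
      stop(sprintf("non-integer label at record %d of '%s'",
                   which(abs(lab - round(lab)) > 1e-9)[1], path))
    labels <- as.integer(round(lab))
  }
  list(positions = as.matrix(tab[, 1:3]), colours = as.matrix(tab[, 4:6]),
       labels = labels)
}

#' Write a labelled point cloud to disk
#'
#' Inverse of \code{\link{readCloud}}: \code{readCloud(writeCloud(x))}
#' restores positions (to 6 decimals), colours and labels. A fully
#' unlabelled cloud is written without a label column/property; otherwise
#' unlabelled points are written as \code{-1}.
#'
#' @param cloud a \code{\linkS4class{LabeledPointCloud}}.
#' @param path output file.
#' @param format \code{"ply_ascii"} or \code{"xyz_table"}.
#' @param labelProperty PLY label property name.
#' @return \code{path}, invisibly.
#' @export
writeCloud <- function(cloud, path, format = c("ply_ascii", "xyz_table"),
                       labelProperty = PLY_LABEL_PROPERTY) {
  format <- match.arg(format)
  stopifnot(is(cloud, "LabeledPointCloud"))
  validObject(cloud)
  lab <- cloud@labels
  hasLabels <- any(!is.na(lab))
  lab[is.na(lab)] <- -1L
  pos <- formatC(cloud@positions, format = "f", digits = 6)
  body <- cbind(pos, cloud@colours)
  if (hasLabels) body <- cbind(body, lab)
  rows <- do.call(paste, c(lapply(seq_len(ncol(body)), function(j) body[, j]),
                           sep = " "))
  if (format == "ply_ascii") {
    header <- c("ply", "format ascii 1.0",
                sprintf("comment cloud_id %s", cloud@cloudId),
                sprintf("element vertex %d", nPoints(cloud)),
                "property float x", "property float y", "property float z",
                "property uchar red", "property uchar green", "property uchar blue",
                if (hasLabels) sprintf("property int %s", labelProperty),
                "end_header")
    writeLines(c(header, rows), path)
  } else {
    writeLines(rows, path)
  }
  invisible(path)
}

#' Write / read a chunk manifest (JSON)
#'
#' A chunk set is serialised as a single JSON document recording the source
#' cloud id, its point count (when known), the requested \code{k} and, per
#' chunk, the 1-based anchor index, the anchor class (\code{-1} when
#' unlabelled) and the ordered 1-based member indices. The round trip is
#' lossless.
#'
#' @param chunks list of \code{\linkS4class{Chunk}} objects.
#' @param cloudId identifier of the source cloud.
#' @param path output (input) file.
#' @param nPoints number of points of the source cloud; recorded in the
#'   manifest and used to bounds-check member indices on read.
#' @return \code{writeChunkSet}: \code{path}, invisibly.
#'   \code{readChunkSet}: a list with elements \code{cloudId},
#'   \code{nPoints} (may be \code{NA}) and \code{chunks}.
#' @export
writeChunkSet <- function(chunks, cloudId, path, nPoints = NA_integer_) {
  stopifnot(all(vapply(chunks, is, logical(1), "Chunk")))
  if (!is.na(nPoints)) checkChunkBounds(chunks, nPoints, cloudId)
  doc <- list(
    cloud_id = cloudId,
    n_points = if (is.na(nPoints)) NULL else as.integer(nPoints),
    chunks = lapply(chunks, function(ch) list(
      anchor_index = ch@anchorIndex,
      anchor_class = if (is.na(ch@anchorClass)) -1L else ch@anchorClass,
      k = ch@k,
      member_indices = ch@memberIndices)))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeChunkSet
#' @export
readChunkSet <- function(path, nPoints = NULL) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  n <- if (!is.null(nPoints)) as.integer(nPoints)
       else if (!is.null(doc$n_points)) as.integer(doc$n_points)
       else NA_integer_
  chunks <- lapply(doc$chunks, function(ch) {
    ac <- as.integer(ch$anchor_class)
    Chunk(anchorIndex = ch$anchor_index,
          memberIndices = ch$member_indices, k = ch$k,
          anchorClass = if (ac == -1L) NA_integer_ else ac)
  })
  if (!is.na(n)) checkChunkBounds(chunks, n, doc$cloud_id)
  list(cloudId = doc$cloud_id, nPoints = n, chunks = chunks)
}

checkChunkBounds <- function(chunks, nPoints, cloudId) {
  for (ch in chunks) {
    bad <- ch@memberIndices < 1L | ch@memberIndices > nPoints
    if (any(bad))
      stop(sprintf("chunk member index %d exceeds the %d points of cloud '%s'",
                   ch@memberIndices[which(bad)[1]], nPoints, cloudId))
  }
  invisible(TRUE)
}
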