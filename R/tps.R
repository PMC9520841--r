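## TPS landmark file I/O and the 5-landmark + resampled-curve configuration
## used for flea head shape.

#' Read a TPS landmark file
#'
#' Parses the TPS dialect written by tpsDig/tpsUtil: each record starts with
#' \code{LM=n} followed by n whitespace-separated coordinate pairs, an
#' optional \code{CURVES=c} block where each curve is introduced by
#' \code{POINTS=k} and followed by k coordinate pairs, and optional
#' \code{IMAGE=}, \code{ID=} and \code{SCALE=} keys.
#'
#' Coordinates are kept exactly as stored (tpsDig's origin is at the lower
#' left of the image; no y flip is applied unless \code{flip_y = TRUE}).
#' \code{SCALE=} is recorded but only multiplied into the coordinates when
#' \code{apply_scale = TRUE}.
#'
#' @param path path to a TPS file.
#' @param apply_scale logical; multiply coordinates by the SCALE factor.
#' @param flip_y logical; negate y coordinates (image-convention files).
#' @return A list of \linkS4class{LandmarkSpecimen} objects, one per
#'   \code{LM=} record.
#' @examples
#' tf <- tempfile(fileext = ".tps")
#' writeLines(c("LM=2", "0 0", "1 1", "ID=a"), tf)
#' readTPS(tf)
#' @seealso [writeTPS()], [buildConfiguration()]
#' @export
readTPS <- function(path, apply_scale = FALSE, flip_y = FALSE) {
  if (!file.exists(path)) stop("TPS file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  n_lines <- length(lines)
  specimens <- list()
  i <- 1L
  record <- 0L

  read_coords <- function(start, k, what) {
    if (start + k - 1L > n_lines)
      stop("record ", record, ": file ends inside ", what,
           " block (expected ", k, " coordinate rows)")
    block <- lines[start:(start + k - 1L)]
    parts <- strsplit(block, "[[:space:]]+")
    bad <- which(vapply(parts, length, 0L) != 2L)
    if (length(bad))
      stop("record ", record, ": line ", start + bad[1] - 1L,
           " is not a coordinate pair inside ", what, " block")
    m <- matrix(suppressWarnings(as.numeric(unlist(parts))),
                ncol = 2L, byrow = TRUE)
    if (anyNA(m)) {
      bad <- which(apply(is.na(m), 1, any))[1]
      stop("record ", record, ": non-numeric coordinate at line ",
           start + bad - 1L)
    }
    m
  }

  while (i <= n_lines) {
    if (!grepl("^LM\\s*=", lines[i], ignore.case = TRUE))
      stop("expected LM= at line ", i, ", found: ", lines[i])
    record <- record + 1L
    n_lm <- suppressWarnings(as.integer(sub("^LM\\s*=\\s*", "", lines[i],
                                            ignore.case = TRUE)))
    if (is.na(n_lm) || n_lm < 0L)
      stop("record ", record, ": malformed LM= count at line ", i)
    i <- i + 1L
    lm <- read_coords(i, n_lm, "LM")
    i <- i + n_lm
    # a non-key line here means LM= overstated or understated the count
    if (i <= n_lines && !grepl("^(LM|CURVES|POINTS|IMAGE|ID|SCALE)\\s*=",
                               lines[i], ignore.case = TRUE))
      stop("record ", record, ": LM=", n_lm,
           " does not match the number of coordinate rows (extra row at line ",
           i, ")")
    curves <- list()
    if (i <= n_lines && grepl("^CURVES\\s*=", lines[i], ignore.case = TRUE)) {
      n_curves <- as.integer(sub("^CURVES\\s*=\\s*", "", lines[i],
                                 ignore.case = TRUE))
      i <- i + 1L
      for (cc in seq_len(n_curves)) {
        if (i > n_lines || !grepl("^POINTS\\s*=", lines[i], ignore.case = TRUE))
          stop("record ", record, ": expected POINTS= for curve ", cc)
        k <- as.integer(sub("^POINTS\\s*=\\s*", "", lines[i],
                            ignore.case = TRUE))
        i <- i + 1L
        curves[[cc]] <- read_coords(i, k, "POINTS")
        i <- i + k
      }
    }
    id <- NA_character_; image <- ""; scale <- NA_real_
    while (i <= n_lines &&
           grepl("^(IMAGE|ID|SCALE)\\s*=", lines[i], ignore.case = TRUE)) {
      key <- toupper(sub("\\s*=.*$", "", lines[i]))
      val <- sub("^[^=]*=\\s*", "", lines[i])
      if (key == "ID") id <- val
      if (key == "IMAGE") image <- val
      if (key == "SCALE") {
        scale <- suppressWarnings(as.numeric(val))
        if (is.na(scale)) stop("record ", record, ": non-numeric SCALE=")
      }
      i <- i + 1L
    }
    if (is.na(id)) id <- as.character(record)
    if (flip_y) {
      lm[, 2] <- -lm[, 2]
      curves <- lapply(curves, function(m) { m[, 2] <- -m[, 2]; m })
    }
    if (apply_scale && !is.na(scale)) {
      lm <- lm * scale
      curves <- lapply(curves, function(m) m * scale)
    }
    specimens[[record]] <- LandmarkSpecimen(id, lm, curves,
                                            scale = scale, imageRef = image)
  }
  specimens
}

#' Write specimens to a TPS file
#'
#' Emits LM=/CURVES=/POINTS=/IMAGE=/ID=/SCALE= records parseable by
#' [readTPS()]. Coordinates are formatted with 15 significant digits so the
#' read/write round trip is the identity to double precision.
#'
#' @param specimens list of \linkS4class{LandmarkSpecimen}.
#' @param path output file path.
#' @return Invisibly, \code{path}.
#' @export
writeTPS <- function(specimens, path) {
  fmt <- function(m) paste(format(m[, 1], digits = 15, trim = TRUE,
                                  scientific = FALSE),
                           format(m[, 2], digits = 15, trim = TRUE,
                                  scientific = FALSE))
  out <- character(0)
  for (sp in specimens) {
    stopifnot(is(sp, "LandmarkSpecimen"))
    validObject(sp)
    out <- c(out, paste0("LM=", nrow(sp@landmarks)), fmt(sp@landmarks))
    if (length(sp@curves)) {
      out <- c(out, paste0("CURVES=", length(sp@curves)))
      for (cv in sp@curves)
        out <- c(out, paste0("POINTS=", nrow(cv)), fmt(cv))
    }
    if (nzchar(sp@imageRef)) out <- c(out, paste0("IMAGE=", sp@imageRef))
    out <- c(out, paste0("ID=", sp@specimenID))
    if (!is.na(sp@scale))
      out <- c(out, paste0("SCALE=", format(sp@scale, digits = 15,
                                            trim = TRUE)))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(out, con)
  invisible(path)
}

#' Resample an open polyline at equal arc-length spacing
#'
#' Returns k points spaced \code{total_length / (k - 1)} apart measured
#' along the polyline, with the first and last output points equal to the
#' polyline endpoints. This is how a digitized head-outline curve becomes a
#' fixed number of semilandmarks.
#'
#' @param polyline numeric matrix (>= 2 rows x 2 cols), an ordered open
#'   polyline.
#' @param k integer >= 2, number of output points.
#' @return k x 2 numeric matrix.
#' @examples
#' resampleCurve(rbind(c(0, 0), c(4, 0), c(9, 0)), k = 10)
#' @export
resampleCurve <- function(polyline, k) {
  polyline <- as.matrix(polyline)
  if (nrow(polyline) < 2L || ncol(polyline) != 2L)
    stop("polyline must have >= 2 points in 2-D")
  if (length(k) != 1L || k != as.integer(k) || k < 2L)
    stop("k must be an integer >= 2")
  k <- as.integer(k)
  seg <- diff(polyline)
  seg_len <- sqrt(rowSums(seg^2))
  total <- sum(seg_len)
  if (total <= 0) stop("degenerate curve: zero total arc length")
  cum <- c(0, cumsum(seg_len))
  targets <- seq(0, total, length.out = k)
  out <- matrix(NA_real_, k, 2)
  out[1, ] <- polyline[1, ]
  out[k, ] <- polyline[nrow(polyline), ]
  # walk interior targets; findInterval handles zero-length segments by
  # snapping to the next segment start
  for (j in seq_len(max(k - 2L, 0L)) + 1L) {
    t <- targets[j]
    i <- findInterval(t, cum, rightmost.closed = TRUE)
    i <- min(max(i, 1L), length(seg_len))
    frac <- if (seg_len[i] > 0) (t - cum[i]) / seg_len[i] else 0
    out[j, ] <- polyline[i, ] + frac * seg[i, ]
  }
  out
}

#' Build the fixed 13-landmark configuration from a digitized specimen
#'
#' Concatenates the specimen's fixed landmarks with its first curve
#' resampled into \code{curve_points} semilandmarks. Resampled curve
#' endpoints that fall within \code{merge_tolerance} of a fixed landmark are
#' merged into that landmark (the fixed landmark is kept), so the default
#' scheme of 5 fixed landmarks + a 10-point curve with both endpoints
#' anchored on landmarks yields exactly 13 points.
#'
#' @param specimen a \linkS4class{LandmarkSpecimen} with >= \code{n_fixed}
#'   landmarks and >= 1 curve.
#' @param n_fixed number of fixed landmarks used (default 5).
#' @param curve_points number of semilandmarks the curve is resampled into
#'   (default 10).
#' @param merge_tolerance distance below which a curve endpoint is merged
#'   with a fixed landmark; default \code{1e-6} times the configuration
#'   diameter.
#' @param expected_merges number of endpoint merges required (default 2);
#'   any other observed count is an error unless \code{force = TRUE}.
#' @param force logical; accept any merge count.
#' @return list with \code{points} (p x 2 matrix, p = n_fixed +
#'   curve_points - merges), \code{provenance} (character per point,
#'   "fixed"/"semilandmark") and \code{merges} (integer).
#' @export
buildConfiguration <- function(specimen, n_fixed = 5L, curve_points = 10L,
                               merge_tolerance = NULL, expected_merges = 2L,
                               force = FALSE) {
  stopifnot(is(specimen, "LandmarkSpecimen"))
  if (nrow(specimen@landmarks) < n_fixed)
    stop("specimen has fewer than n_fixed = ", n_fixed, " landmarks")
  if (!length(specimen@curves))
    stop("specimen has no curve to resample")
  fixed <- specimen@landmarks[seq_len(n_fixed), , drop = FALSE]
  semis <- resampleCurve(specimen@curves[[1]], curve_points)
  allpts <- rbind(fixed, semis)
  if (is.null(merge_tolerance)) {
    diam <- max(dist(allpts))
    merge_tolerance <- 1e-6 * diam
  }
  keep <- rep(TRUE, curve_points)
  merges <- 0L
  for (j in c(1L, curve_points)) {    # only endpoints can coincide with landmarks
    d <- sqrt(colSums((t(fixed) - semis[j, ])^2))
    if (min(d) <= merge_tolerance) {
      keep[j] <- FALSE
      merges <- merges + 1L
    }
  }
  if (!force && merges != expected_merges)
    stop("configuration error: ", merges, " curve-endpoint merge(s) found, ",
         "expected ", expected_merges,
         " (use force = TRUE to accept)")
  points <- rbind(fixed, semis[keep, , drop = FALSE])
  provenance <- c(rep("fixed", n_fixed), rep("semilandmark", sum(keep)))
  list(points = points, provenance = provenance, merges = merges)
}

#' Assemble a ShapeDataset from digitized specimens
#'
#' Applies [buildConfiguration()] to each specimen and stacks the results,
#' collecting labels from each specimen's label vector.
#'
#' @param specimens list of \linkS4class{LandmarkSpecimen}.
#' @param ... passed to [buildConfiguration()].
#' @return A \linkS4class{ShapeDataset}.
#' @export
buildShapeDataset <- function(specimens, ...) {
  cfgs <- lapply(specimens, buildConfiguration, ...)
  p <- nrow(cfgs[[1]]$points)
  if (any(vapply(cfgs, function(cf) nrow(cf$points), 0L) != p))
    stop("specimens yield configurations of differing size")
  coords <- array(NA_real_, c(p, 2L, length(specimens)),
                  dimnames = list(NULL, c("x", "y"),
                                  vapply(specimens, function(s) s@specimenID,
                                         "")))
  for (i in seq_along(cfgs)) coords[, , i] <- cfgs[[i]]$points
  lab_names <- unique(unlist(lapply(specimens,
                                    function(s) names(s@labels))))
  labels <- as.data.frame(
    lapply(stats::setNames(lab_names, lab_names), function(nm)
      vapply(specimens, function(s)
        if (nm %in% names(s@labels)) s@labels[[nm]] else NA_character_, "")),
    optional = TRUE)
  if (!length(lab_names)) labels <- data.frame(row.names = seq_along(specimens))
  ShapeDataset(coords, labels = labels, provenance = cfgs[[1]]$provenance)
}

#' Export configurations as TSV
#'
#' Long-format table: specimen_id, point index, x, y, provenance.
#'
#' @param dataset a \linkS4class{ShapeDataset}.
#' @param path output TSV path.
#' @return Invisibly, \code{path}.
#' @export
writeConfigurationTSV <- function(dataset, path) {
  d <- dim(dataset@coords)
  ids <- dimnames(dataset@coords)[[3]]
  if (is.null(ids)) ids <- as.character(seq_len(d[3]))
  prov <- if (length(dataset@provenance)) dataset@provenance
          else rep(NA_character_, d[1])
  df <- data.frame(
    specimen_id = rep(ids, each = d[1]),
    point = rep(seq_len(d[1]), d[3]),
    x = as.vector(dataset@coords[, 1, ]),
    y = as.vector(dataset@coords[, 2, ]),
    provenance = rep(prov, d[3]))
  write.table(format(df, digits = 10), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
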