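#' Landmark set container
#'
#' Bundles the landmark configurations of a sample: a `p x 2 x n`
#' coordinate array, specimen and species identifiers, and a per-specimen
#' scale factor (mm per coordinate unit, as carried by the `SCALE=` record
#' of a TPS file). Coordinates are stored as digitised; [landmark_mm()]
#' returns them in mm.
#'
#' @param coords `p x 2 x n` numeric array of raw coordinates.
#' @param specimen_id character vector of length `n`, unique.
#' @param species_id optional character vector of length `n`.
#' @param scale numeric vector of length `n` (or 1, recycled); mm per
#'   coordinate unit.
#' @return an object of class `landmark_set`.
#' @export
landmark_set <- function(coords, specimen_id, species_id = NULL, scale = 1) {
  if (!is.array(coords) || length(dim(coords)) != 3L || dim(coords)[2L] != 2L) {
    stop_fm("coords must be a p x 2 x n array")
  }
  n <- dim(coords)[3L]
  specimen_id <- as.character(specimen_id)
  if (length(specimen_id) != n) stop_fm("specimen_id must have length n")
  if (anyDuplicated(specimen_id)) {
    stop_fm(
      "duplicate specimen id: ",
      paste(unique(specimen_id[duplicated(specimen_id)]), collapse = ", ")
    )
  }
  if (!all(is.finite(coords))) stop_fm("coords contain non-finite values")
  scale <- rep_len(as.numeric(scale), n)
  if (any(!is.finite(scale)) || any(scale <= 0)) {
    stop_fm("scale must be positive and finite")
  }
  if (!is.null(species_id)) {
    species_id <- as.character(rep_len(species_id, n))
  }
  dimnames(coords)[[3L]] <- specimen_id
  structure(
    list(
      coords = coords,
      specimen_id = specimen_id,
      species_id = species_id,
      scale = scale
    ),
    class = "landmark_set"
  )
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(
    "Landmark set: ", dim(x$coords)[3L], " configurations of ",
    dim(x$coords)[1L], " landmarks\n",
    sep = ""
  )
  invisible(x)
}

#' Landmark coordinates in mm
#'
#' Applies each configuration's scale factor multiplicatively, returning
#' the coordinate array in mm.
#'
#' @param x a [landmark_set].
#' @return a `p x 2 x n` array.
#' @export
landmark_mm <- function(x) {
  stopifnot(inherits(x, "landmark_set"))
  out <- x$coords
  for (i in seq_along(x$scale)) out[, , i] <- out[, , i] * x$scale[i]
  out
}

#' Read a TPS landmark file
#'
#' Parses the plain-text TPS landmark dialect: records introduced by
#' `LM=<count>` followed by that many `x y` coordinate lines, an
#' `ID=<specimen_id>` line, and an optional `SCALE=<mm/unit>` line. Keys
#' are accepted in upper or lower case. The scale is retained on the
#' returned [landmark_set] and applied multiplicatively by
#' [landmark_mm()].
#'
#' @param path path to the TPS file.
#' @param n_landmarks if given, every record must have exactly this many
#'   landmarks.
#' @return a [landmark_set].
#' @export
read_tps <- function(path, n_landmarks = NULL) {
  lines <- readLines(path)
  recs <- list()
  cur <- NULL
  finish <- function(cur, lineno) {
    if (is.null(cur)) {
      return(invisible(NULL))
    }
    if (nrow(cur$coords) != cur$lm) {
      stop_fm(
        "TPS parse error near line ", lineno, ": record declares LM=",
        cur$lm, " but has ", nrow(cur$coords), " coordinate lines"
      )
    }
    if (is.null(cur$id)) {
      stop_fm("TPS parse error near line ", lineno, ": record has no ID=")
    }
    cur
  }
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "") next
    up <- toupper(ln)
    if (startsWith(up, "LM=")) {
      if (!is.null(cur)) recs[[length(recs) + 1L]] <- finish(cur, i)
      lm <- suppressWarnings(as.integer(sub("^LM=", "", up)))
      if (is.na(lm) || lm < 1L) {
        stop_fm("TPS parse error at line ", i, ": bad landmark count")
      }
      cur <- list(
        lm = lm, coords = matrix(numeric(0), 0L, 2L),
        id = NULL, scale = 1
      )
    } else if (startsWith(up, "ID=")) {
      if (is.null(cur)) stop_fm("TPS parse error at line ", i, ": ID= before LM=")
      cur$id <- sub("^[Ii][Dd]=", "", ln)
    } else if (startsWith(up, "SCALE=")) {
      if (is.null(cur)) {
        stop_fm("TPS parse error at line ", i, ": SCALE= before LM=")
      }
      sc <- suppressWarnings(as.numeric(sub("^SCALE=", "", up)))
      if (is.na(sc) || sc <= 0) {
        stop_fm("TPS parse error at line ", i, ": bad SCALE value")
      }
      cur$scale <- sc
    } else {
      if (is.null(cur)) {
        stop_fm("TPS parse error at line ", i, ": coordinates before LM=")
      }
      xy <- suppressWarnings(as.numeric(strsplit(ln, "[[:space:]]+")[[1L]]))
      if (length(xy) != 2L || any(is.na(xy))) {
        stop_fm("TPS parse error at line ", i, ": non-numeric coordinate line")
      }
      if (nrow(cur$coords) >= cur$lm) {
        stop_fm(
          "TPS parse error at line ", i, ": more than LM=", cur$lm,
          " coordinate lines"
        )
      }
      cur$coords <- rbind(cur$coords, xy)
    }
  }
  if (!is.null(cur)) recs[[length(recs) + 1L]] <- finish(cur, length(lines))
  if (length(recs) == 0L) stop_fm("no TPS records found in ", path)
  p <- unique(vapply(recs, function(r) r$lm, integer(1)))
  if (length(p) != 1L) {
    stop_fm("TPS records have mismatched landmark counts: ", paste(p, collapse = ", "))
  }
  if (!is.null(n_landmarks) && p != n_landmarks) {
    stop_fm("expected ", n_landmarks, " landmarks per record, found ", p)
  }
  ids <- vapply(recs, function(r) r$id, character(1))
  if (anyDuplicated(ids)) {
    stop_fm(
      "duplicate specimen ID in TPS file: ",
      paste(unique(ids[duplicated(ids)]), collapse = ", ")
    )
  }
  coords <- array(0, dim = c(p, 2L, length(recs)))
  for (i in seq_along(recs)) coords[, , i] <- recs[[i]]$coords
  landmark_set(
    coords, ids,
    scale = vapply(recs, function(r) r$scale, numeric(1))
  )
}

#' Write a TPS landmark file
#'
#' Emits one record per configuration: `LM=`, the coordinate lines, the
#' `SCALE=` line when the scale differs from 1, and `ID=`. Output written
#' by this function round-trips through [read_tps()].
#'
#' @param x a [landmark_set] (or `p x 2 x n` array).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tps <- function(x, path) {
  if (!inherits(x, "landmark_set")) {
    x <- landmark_set(x, dimnames(x)[[3L]] %||% sprintf("s%03d", seq_len(dim(x)[3L])))
  }
  p <- dim(x$coords)[1L]
  out <- character(0)
  for (i in seq_along(x$specimen_id)) {
    out <- c(
      out,
      sprintf("LM=%d", p),
      apply(x$coords[, , i], 1L, function(r) {
        sprintf("%.10g %.10g", r[1L], r[2L])
      }),
      if (x$scale[i] != 1) sprintf("SCALE=%.10g", x$scale[i]),
      sprintf("ID=%s", x$specimen_id[i])
    )
  }
  writeLines(out, path)
  invisible(path)
}

specimen_csv_map <- c(
  species = "species_id",
  specimen_id = "specimen_id",
  foot_length_mm = "foot_length",
  foot_width_mm = "foot_width",
  perimeter_mm = "perimeter",
  foot_area_mm2 = "foot_area",
  body_weight_g = "body_weight"
)

#' Write a specimen covariate table as CSV
#'
#' Column layout: `species,specimen_id,foot_length_mm,foot_width_mm,`
#' `perimeter_mm,foot_area_mm2,body_weight_g`. Missing body weights are
#' written as empty fields.
#'
#' @param table a specimen data.frame as produced by [generate_dataset()]
#'   (internal column names).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_specimens <- function(table, path) {
  need <- unname(specimen_csv_map)
  missing_cols <- setdiff(need, names(table))
  if (length(missing_cols)) {
    stop_fm("specimen table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  out <- table[, unname(specimen_csv_map)]
  names(out) <- names(specimen_csv_map)
  write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a specimen covariate table from CSV
#'
#' Reads the CSV layout of [write_specimens()], restores internal column
#' names, re-derives sinuosity as `perimeter / foot_width`, and treats
#' empty body-weight fields as missing.
#'
#' @param path CSV path.
#' @return a data.frame with columns `specimen_id`, `species_id`,
#'   `foot_length`, `foot_width`, `perimeter`, `sinuosity`, `foot_area`,
#'   `body_weight`.
#' @export
read_specimens <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(names(specimen_csv_map), names(raw))
  if (length(missing_cols)) {
    stop_fm(
      "specimen CSV lacks columns: ",
      paste(missing_cols, collapse = ", ")
    )
  }
  out <- raw[, names(specimen_csv_map)]
  names(out) <- unname(specimen_csv_map)
  if (anyDuplicated(out$specimen_id)) stop_fm("duplicate specimen_id in ", path)
  numeric_cols <- c("foot_length", "foot_width", "perimeter", "foot_area")
  for (cl in numeric_cols) {
    if (any(!is.finite(out[[cl]]))) stop_fm("non-finite values in column ", cl)
  }
  out$sinuosity <- out$perimeter / out$foot_width
  out[, c(
    "specimen_id", "species_id", "foot_length", "foot_width",
    "perimeter", "sinuosity", "foot_area", "body_weight"
  )]
}
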