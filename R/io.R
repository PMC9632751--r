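# Readers/writers for the plain-text interchange formats: landmark tables,
# trait tables and pedigrees. Comma-separated, UTF-8, header row mandatory,
# "." decimal, empty field = missing.

trait_columns <- function() {
  c("animal_id", "pond", "BW", "BL", "BS", "HS", "AS", "AP", "TT", "FBR", "CF", "CFL")
}

read_delim_auto <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  read.csv(path, sep = sep, stringsAsFactors = FALSE)
}

#' Read a landmark coordinate table
#'
#' Expects columns `animal_id`, `label`, and either `x_cm`/`y_cm` (already
#' scaled) or `x_px`/`y_px` with a per-row `scale_cm_per_px` column (or a
#' single `scale` argument applied to all rows). Rows that cannot form a valid
#' 12-landmark configuration are skipped with a warning.
#'
#' @param path CSV/TSV file path.
#' @param scale Optional pixel-to-cm scale applied when the file holds pixel
#'   coordinates and carries no scale column.
#' @return Named list of [landmark_set()] objects, one per animal.
#' @export
read_landmarks <- function(path, scale = NULL) {
  df <- read_delim_auto(path)
  need <- c("animal_id", "label")
  if (!all(need %in% names(df))) {
    stop("landmark file must have columns animal_id, label and coordinates", call. = FALSE)
  }
  if (all(c("x_cm", "y_cm") %in% names(df))) {
    df$x <- as.numeric(df$x_cm); df$y <- as.numeric(df$y_cm)
  } else if (all(c("x_px", "y_px") %in% names(df))) {
    sc <- if ("scale_cm_per_px" %in% names(df)) as.numeric(df$scale_cm_per_px)
          else if (!is.null(scale)) scale
          else stop("pixel coordinates need a scale_cm_per_px column or `scale`", call. = FALSE)
    df$x <- as.numeric(df$x_px) * sc; df$y <- as.numeric(df$y_px) * sc
  } else {
    stop("landmark file needs x_cm/y_cm or x_px/y_px columns", call. = FALSE)
  }
  out <- list(); skipped <- 0L
  for (id in unique(df$animal_id)) {
    sub <- df[df$animal_id == id, ]
    lm <- tryCatch({
      pts <- cbind(sub$x, sub$y)
      rownames(pts) <- sub$label
      landmark_set(id, pts)
    }, error = function(e) {
      warning("skipping animal ", id, ": ", conditionMessage(e), call. = FALSE)
      NULL
    })
    if (is.null(lm)) skipped <- skipped + 1L else out[[as.character(id)]] <- lm
  }
  if (skipped > 0L) {
    message(length(out), " landmark set(s) read, ", skipped, " skipped")
  }
  out
}

#' Write landmark sets in canonical cm-scaled form
#'
#' @param lms List of [landmark_set()] objects.
#' @param path Output CSV path (columns `animal_id, label, x_cm, y_cm`).
#' @export
write_landmarks <- function(lms, path) {
  rows <- lapply(lms, function(lm) {
    data.frame(animal_id = lm$animal_id, label = rownames(lm$points),
               x_cm = lm$points[, 1], y_cm = lm$points[, 2],
               stringsAsFactors = FALSE)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
}

#' Read / write a trait table
#'
#' The trait table has one row per animal with columns exactly
#' `animal_id, pond, BW, BL, BS, HS, AS, AP, TT, FBR, CF, CFL`.
#'
#' @param path File path.
#' @return `read_traits`: data.frame in canonical column order.
#' @export
read_traits <- function(path) {
  df <- read_delim_auto(path)
  miss <- setdiff(trait_columns(), names(df))
  if (length(miss)) stop("trait table missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  df <- df[, trait_columns()]
  df$animal_id <- as.character(df$animal_id)
  df$pond <- as.character(df$pond)
  df
}

#' @rdname read_traits
#' @param traits Data.frame of trait records.
#' @export
write_traits <- function(traits, path) {
  stopifnot(all(trait_columns() %in% names(traits)))
  write.csv(traits[, trait_columns()], path, row.names = FALSE, quote = FALSE)
}
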