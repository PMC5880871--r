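LANDMARK_COLUMNS <- c("case_id", "pair_id", "landmark_id", "fx", "fy", "fz",
                      "annotator_id", "mx", "my", "mz", "uncertain")

#' Read a landmark annotation table
#'
#' Landmarks are stored as CSV with one row per (landmark, annotator):
#' columns `case_id, pair_id, landmark_id, fx, fy, fz, annotator_id,
#' mx, my, mz, uncertain`. Fixed (`f*`) and moving (`m*`) coordinates are
#' world mm; `uncertain` is 0/1 (a landmark flagged by an annotator during
#' re-annotation; uncertain landmarks are excluded from statistics).
#'
#' @param path CSV file path.
#' @return A `data.frame` with the columns above, `uncertain` as logical.
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  validate_landmarks(df)
}

#' @rdname read_landmarks
#' @param landmarks a landmark `data.frame`.
#' @export
write_landmarks <- function(landmarks, path) {
  landmarks <- validate_landmarks(landmarks)
  out <- landmarks[, LANDMARK_COLUMNS]
  out$uncertain <- as.integer(out$uncertain)
  write.csv(format(out, digits = 10, trim = TRUE), path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

validate_landmarks <- function(df) {
  missing <- setdiff(LANDMARK_COLUMNS, names(df))
  if (length(missing))
    stop("landmark table is missing columns: ", paste(missing, collapse = ", "))
  for (col in c("fx", "fy", "fz", "mx", "my", "mz")) {
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
    if (nrow(df) && anyNA(df[[col]]))
      stop("non-numeric coordinates in column ", col)
  }
  df$uncertain <- as.logical(as.integer(df$uncertain))
  df
}

# unique (case, pair, landmark) keys, preserving first-appearance order
landmark_keys <- function(landmarks) {
  key <- paste(landmarks$case_id, landmarks$pair_id, landmarks$landmark_id,
               sep = "\r")
  unique(key)
}

# drop every row of a landmark flagged uncertain by any annotator
drop_uncertain <- function(landmarks) {
  key <- paste(landmarks$case_id, landmarks$pair_id, landmarks$landmark_id,
               sep = "\r")
  bad <- unique(key[landmarks$uncertain])
  landmarks[!(key %in% bad), , drop = FALSE]
}
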