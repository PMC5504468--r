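#' Read and write landmark coordinate tables
#'
#' Landmark tables are TSV files with the columns
#' `subject_id age_months label hemisphere x_mm y_mm z_mm space`, one row
#' per landmark, coordinates in AC-PC millimetres. `space` is `"acpc"` or
#' `"native"`; `hemisphere` is `"L"`, `"R"` or `"M"` (midline).
#'
#' @param path TSV file path.
#' @return a data.frame with the columns above.
#' @export
read_landmarks <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("subject_id", "age_months", "label", "hemisphere",
            "x_mm", "y_mm", "z_mm", "space")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop("landmark table is missing columns: ", paste(miss, collapse = ", "))
  if (!all(df$hemisphere %in% c("L", "R", "M")))
    stop("hemisphere must be one of L, R, M")
  if (!all(df$space %in% c("acpc", "native")))
    stop("space must be 'acpc' or 'native'")
  df[need]
}

#' @rdname read_landmarks
#' @param landmarks a landmark data.frame in the same layout.
#' @param digits coordinate precision in the written file.
#' @export
write_landmarks <- function(landmarks, path, digits = 6L) {
  df <- landmarks
  for (col in c("x_mm", "y_mm", "z_mm"))
    df[[col]] <- formatC(df[[col]], format = "f", digits = digits)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# one subject's landmarks as a label-keyed coordinate matrix
landmark_matrix <- function(landmarks, labels, hemisphere) {
  sel <- landmarks$hemisphere == hemisphere & landmarks$label %in% labels
  sub <- landmarks[sel, , drop = FALSE]
  m <- as.matrix(sub[match(labels, sub$label), c("x_mm", "y_mm", "z_mm")])
  rownames(m) <- as.character(labels)
  if (anyNA(m))
    stop("missing landmarks for hemisphere ", hemisphere, ": ",
         paste(labels[is.na(m[, 1L])], collapse = ", "))
  m
}
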