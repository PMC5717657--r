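#' Read landmark configurations from a TPS file
#'
#' Parses the classic TPS layout: each record starts with `LM=k`, followed by
#' k lines of `x y` coordinates and optional `IMAGE=`, `ID=`, and `SCALE=`
#' lines. `SCALE` is applied multiplicatively to the coordinates. The specimen
#' id is taken from `ID=` when present, else from `IMAGE=` (extension
#' stripped), else a running index.
#'
#' @param file path to a TPS file.
#' @return Named list of k x 2 numeric matrices.
#' @export
read_tps <- function(file) {
  lines <- trimws(readLines(file, warn = FALSE))
  lines <- lines[nzchar(lines)]
  out <- list()
  i <- 1L
  rec <- 0L
  while (i <= length(lines)) {
    if (!grepl("^LM\\s*=", lines[i], ignore.case = TRUE))
      .input_error("malformed TPS file at line ", i, ": expected LM= record")
    k <- as.integer(sub("^LM\\s*=\\s*", "", lines[i], ignore.case = TRUE))
    if (is.na(k) || k < 1L) .input_error("invalid landmark count at line ", i)
    if (i + k > length(lines)) .input_error("truncated coordinate block at line ", i)
    coords <- lines[(i + 1L):(i + k)]
    xy <- t(vapply(seq_along(coords), function(j) {
      v <- suppressWarnings(as.numeric(strsplit(coords[j], "\\s+")[[1L]]))
      if (length(v) != 2L || anyNA(v))
        .input_error("malformed coordinate at line ", i + j)
      v
    }, numeric(2)))
    i <- i + k + 1L
    rec <- rec + 1L
    id <- NULL; img <- NULL; scl <- 1
    while (i <= length(lines) && !grepl("^LM\\s*=", lines[i], ignore.case = TRUE)) {
      key <- toupper(sub("=.*$", "", lines[i]))
      val <- sub("^[^=]*=\\s*", "", lines[i])
      if (key == "ID") id <- val
      else if (key == "IMAGE") img <- sub("\\.[A-Za-z0-9]+$", "", basename(val))
      else if (key == "SCALE") {
        s <- suppressWarnings(as.numeric(val))
        if (is.na(s)) .input_error("invalid SCALE at line ", i)
        scl <- scl * s
      }
      i <- i + 1L
    }
    name <- if (!is.null(id) && nzchar(id)) id else if (!is.null(img)) img else paste0("specimen", rec)
    out[[name]] <- xy * scl
  }
  if (!length(out)) .input_error("no landmark records in ", file)
  out
}

#' Write landmark configurations to a TPS file
#'
#' @param configs named list of k x 2 matrices.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_tps <- function(configs, file) {
  if (is.null(names(configs))) names(configs) <- paste0("specimen", seq_along(configs))
  con <- file(file, "w")
  on.exit(close(con))
  for (nm in names(configs)) {
    m <- as.matrix(configs[[nm]])
    writeLines(sprintf("LM=%d", nrow(m)), con)
    writeLines(sprintf("%.12g %.12g", m[, 1L], m[, 2L]), con)
    writeLines(sprintf("ID=%s", nm), con)
  }
  invisible(file)
}

#' Read or write shape-variable scores as CSV
#'
#' The score table has a `specimen_id` column followed by one column per axis
#' (`PC1`, `PC2`, ...). Reading a precomputed score table bypasses alignment
#' and ordination entirely.
#'
#' @param file CSV path.
#' @param scores matrix of scores with specimen ids as row names, or a
#'   `shape_space` (retained axes are written).
#' @return `read_scores_csv` returns a numeric matrix with specimen row names.
#' @export
read_scores_csv <- function(file) {
  d <- utils::read.csv(file, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"specimen_id" %in% names(d)) .input_error("score table needs a 'specimen_id' column")
  m <- as.matrix(d[, setdiff(names(d), "specimen_id"), drop = FALSE])
  if (!is.numeric(m) || anyNA(m)) .input_error("non-numeric or missing scores in ", file)
  rownames(m) <- d$specimen_id
  m
}

#' @rdname read_scores_csv
#' @export
write_scores_csv <- function(scores, file) {
  if (inherits(scores, "shape_space")) scores <- retained_scores(scores)
  d <- data.frame(specimen_id = rownames(scores), scores, check.names = FALSE)
  utils::write.csv(d, file, row.names = FALSE)
  invisible(file)
}
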