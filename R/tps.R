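# Reader/writer for the TPS landmark file dialect used by the tpsDig family
# of digitising tools: per specimen an "LM=n" record, n coordinate lines,
# and optional ID=, IMAGE= and SCALE= records. SCALE multiplies coordinates.

#' Read landmark configurations from a TPS file
#'
#' @param path TPS file path.
#' @return List of [landmark_config()] objects (configurations with a
#'   landmark count other than 64 are returned as plain point matrices in a
#'   `landmark_config`-like list only when they have 64 points; otherwise an
#'   error is raised, since the cross-hair protocol is fixed at 64).
#' @export
read_tps <- function(path) {
  ln <- readLines(path)
  out <- list()
  i <- 1L
  while (i <= length(ln)) {
    line <- trimws(ln[i])
    if (!nzchar(line)) { i <- i + 1L; next }
    if (!grepl("^LM\\s*=", line, ignore.case = TRUE))
      stop("TPS parse error at line ", i, ": expected LM=, got '", line, "'")
    n_lm <- as.integer(sub("^LM\\s*=\\s*", "", line, ignore.case = TRUE))
    if (is.na(n_lm) || n_lm < 1)
      stop("TPS parse error at line ", i, ": bad landmark count")
    if (i + n_lm > length(ln))
      stop("TPS parse error at line ", i, ": LM=", n_lm,
           " but file ends after ", length(ln) - i, " coordinate lines")
    coord <- ln[(i + 1L):(i + n_lm)]
    bad <- which(!grepl("^\\s*[-+0-9.eE]+\\s+[-+0-9.eE]+\\s*$", coord))
    if (length(bad))
      stop("TPS parse error at line ", i + bad[1],
           ": expected an 'x y' coordinate line (LM count mismatch?)")
    pts <- do.call(rbind, lapply(strsplit(trimws(coord), "\\s+"),
                                 function(z) as.numeric(z[1:2])))
    i <- i + n_lm + 1L
    id <- NULL; scale <- 1
    while (i <= length(ln) &&
           grepl("^(ID|IMAGE|SCALE)\\s*=", trimws(ln[i]),
                 ignore.case = TRUE)) {
      rec <- trimws(ln[i])
      key <- toupper(sub("\\s*=.*$", "", rec))
      val <- sub("^[^=]*=\\s*", "", rec)
      if (key == "ID") id <- val
      if (key == "SCALE") scale <- as.numeric(val)
      i <- i + 1L
    }
    pts <- pts * scale
    if (n_lm != 64)
      stop("TPS record with LM=", n_lm,
           " landmarks; the cross-hair protocol uses 64")
    out[[length(out) + 1L]] <-
      landmark_config(pts,
                      specimen_id = id %||% paste0("spec", length(out) + 1L),
                      scale = scale)
  }
  out
}

#' Write landmark configurations to a TPS file
#'
#' Coordinates are written already scaled (no SCALE record), so a
#' write -> read round trip reproduces them exactly to the printed
#' precision (9 decimals).
#'
#' @param configs list of [landmark_config()]s.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_tps <- function(configs, path) {
  ln <- unlist(lapply(configs, function(cf) {
    c(sprintf("LM=%d", nrow(cf$points)),
      sprintf("%.9f %.9f", cf$points[, 1], cf$points[, 2]),
      sprintf("ID=%s", cf$specimen_id))
  }))
  writeLines(ln, path)
  invisible(path)
}
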