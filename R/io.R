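## Plain-text interchange: CSV for tables, profiles and streamlines, JSON
## for specs, fit reports and run manifests. (The environment provides no
## NIfTI/GIFTI/TCK reader, so volumes and meshes stay in-memory objects;
## see the methods vignette.)

#' Write / read streamlines as CSV
#'
#' Long format: `streamline`, `point`, `x`, `y`, `z` (mm).
#' @param streamlines list of n x 3 matrices.
#' @param path output file.
#' @export
write_streamlines_csv <- function(streamlines, path) {
  rows <- do.call(rbind, lapply(seq_along(streamlines), function(i) {
    p <- streamlines[[i]]
    data.frame(streamline = i, point = seq_len(nrow(p)),
               x = p[, 1], y = p[, 2], z = p[, 3])
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_streamlines_csv
#' @export
read_streamlines_csv <- function(path) {
  df <- utils::read.csv(path)
  lapply(split(df, df$streamline), function(s) {
    as.matrix(s[order(s$point), c("x", "y", "z")])
  })
}

#' Write a JSON report
#'
#' @param x a list (unboxed scalars, full precision).
#' @param path output file.
#' @export
write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}
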