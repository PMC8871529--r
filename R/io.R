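#' @title Multi-page float TIFF + JSON sidecar I/O
#'
#' @description Image stacks are exchanged as multi-page 32-bit float TIFF.
#' `tiff::writeTIFF` stores float samples on the \[0, 1\] interval, so stacks
#' whose values exceed 1 (e.g. attenuation volumes in 1/mm) are divided by a
#' `scale` factor that is recorded in the JSON sidecar and re-applied on read.
#'
#' @param arr numeric array, either `rows x cols` or `rows x cols x pages`.
#' @param path output TIFF path; the sidecar is written to `<path>.json`.
#' @param meta named list of metadata serialized to the sidecar.
#' @return `write_float_tiff` returns `path` invisibly; `read_float_tiff`
#'   returns a list with elements `data` (array) and `meta`.
#' @keywords internal
write_float_tiff <- function(arr, path, meta = list()) {
  if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
  lo <- min(arr, 0)
  hi <- max(arr, 1)
  scale <- hi - lo
  pages <- lapply(seq_len(dim(arr)[3]),
                  function(k) (arr[, , k] - lo) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  meta$scale <- scale
  meta$offset <- lo
  meta$dim <- dim(arr)
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_float_tiff
#' @keywords internal
read_float_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  arr <- array(unlist(pages), c(dim(pages[[1]]), length(pages)))
  off <- if (is.null(meta$offset)) 0 else meta$offset
  arr <- arr * meta$scale + off
  list(data = arr, meta = meta)
}
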