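#' Write / read a relationship matrix
#'
#' Matrices are stored as plain CSV with an `id` header column, one row per
#' individual, values written with the shortest lossless decimal
#' representation (so read-back is bit-exact). The kernel kind and the
#' psd-adjustment flag are stored in a `#` comment header line.
#'
#' @param K a [relationship_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(K, path) {
  stopifnot(inherits(K, "RelationshipMatrix"))
  header <- sprintf("# kind=%s psd_adjusted=%s", attr(K, "kind"),
                    attr(K, "psd_adjusted"))
  writeLines(header, path)
  # %.17g guarantees doubles survive the text round-trip bit-exactly
  vals <- matrix(sprintf("%.17g", unclass(K)), nrow(K), ncol(K),
                 dimnames = dimnames(K))
  dt <- data.table::data.table(id = rownames(K))
  dt <- cbind(dt, data.table::as.data.table(vals))
  data.table::fwrite(dt, path, append = TRUE, col.names = TRUE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_matrix
#' @param ids optional expected ids; an error is raised if the file does
#'   not contain exactly these, in this order.
#' @export
read_matrix <- function(path, ids = NULL) {
  first <- readLines(path, n = 1L)
  kind <- sub(".*kind=(\\S+).*", "\\1", first)
  psd <- identical(sub(".*psd_adjusted=(\\S+).*", "\\1", first), "TRUE")
  dt <- data.table::fread(path, skip = 1L, header = TRUE)
  values <- as.matrix(dt[, -1L, drop = FALSE])
  file_ids <- as.character(dt[[1L]])
  dimnames(values) <- list(file_ids, file_ids)
  if (!is.null(ids) && !identical(file_ids, as.character(ids)))
    stop("id mismatch between file and expectation")
  relationship_matrix(values, kind, ids = file_ids, psd_adjusted = psd)
}
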