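#' Read / write community tables, taxonomy, metadata and distances as TSV
#'
#' Count tables are written samples-as-rows with a leading `sample_id`
#' column; taxonomy as a two-column `taxon_id` / `genus` table; distance
#' matrices as square TSV with id header and rownames.
#'
#' @param path File path.
#' @param table,taxonomy,metadata,dist Objects to write.
#' @name camnet_io
NULL

#' @rdname camnet_io
#' @export
write_count_table <- function(table, path) {
  df <- data.frame(sample_id = rownames(table), unclass(table),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname camnet_io
#' @param taxonomy_path Optional taxonomy TSV to attach on read.
#' @export
read_count_table <- function(path, taxonomy_path = NULL) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  tx <- if (!is.null(taxonomy_path)) read_taxonomy(taxonomy_path) else NULL
  count_table(df, taxonomy = tx)
}

#' @rdname camnet_io
#' @export
write_taxonomy <- function(taxonomy, path) {
  write.table(data.frame(taxon_id = names(taxonomy), genus = unname(taxonomy)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname camnet_io
#' @export
read_taxonomy <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  setNames(as.character(df$genus), df$taxon_id)
}

#' @rdname camnet_io
#' @export
write_metadata <- function(metadata, path) {
  write.table(as.data.frame(metadata), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname camnet_io
#' @export
read_metadata <- function(path) {
  tibble::as_tibble(read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname camnet_io
#' @export
write_distance <- function(dist, path) {
  df <- data.frame(sample_id = rownames(dist), dist, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname camnet_io
#' @export
read_distance <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[-1L])
  rownames(m) <- df$sample_id
  as_distance_matrix(m, rownames(m))
}
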