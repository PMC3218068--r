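#' Write result tables
#'
#' Writes detection results (candidate regions, elements, subfamilies, ...) to
#' disk. Three formats are supported:
#'
#' * `"tsv"` — one row per record; list-columns are collapsed to
#'   comma-separated strings. Zero records yield a header-only file.
#' * `"json"` — full nested detail via [jsonlite::serializeJSON()]; reading
#'   the file back with [read_results()] reproduces the records exactly.
#' * `"gff3"` — for element tables only: one `mobile_genetic_element` parent
#'   feature per element with `attachment_site` child features for every
#'   attL/attR copy.
#'
#' @param records A tibble of result records (for `"gff3"` an element table
#'   from [delimit_elements()]).
#' @param path Output file path.
#' @param format `"tsv"`, `"json"` or `"gff3"`.
#' @return `path`, invisibly.
#' @export
write_results <- function(records, path, format = c("tsv", "json", "gff3")) {
  if (length(format) != 1L || !format %in% c("tsv", "json", "gff3")) {
    stop("unknown results format: ", paste(format, collapse = "/"), call. = FALSE)
  }
  switch(format,
    tsv = {
      flat <- flatten_list_cols(records)
      readr::write_tsv(flat, path)
    },
    json = {
      writeLines(jsonlite::serializeJSON(records, digits = NA), path)
    },
    gff3 = write_elements_gff3(records, path))
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path, format = c("tsv", "json")) {
  format <- match.arg(format)
  switch(format,
    tsv = readr::read_tsv(path, show_col_types = FALSE),
    json = jsonlite::unserializeJSON(paste(readLines(path), collapse = "\n")))
}

flatten_list_cols <- function(records) {
  is_list <- vapply(records, is.list, logical(1))
  for (col in names(records)[is_list]) {
    records[[col]] <- vapply(records[[col]], function(x) {
      if (is.null(x) || (is.data.frame(x) && nrow(x) == 0L)) return(NA_character_)
      if (is.data.frame(x)) return(sprintf("<%d rows>", nrow(x)))
      paste(unlist(x), collapse = ",")
    }, character(1))
  }
  records
}

# elements table -> GFF3 with att sites as child features
write_elements_gff3 <- function(elements, path) {
  lines <- "##gff-version 3"
  if (nrow(elements)) {
    for (i in seq_len(nrow(elements))) {
      e <- elements[i, ]
      eid <- e$element_id
      lines <- c(lines, sprintf(
        "%s\taicescan\tmobile_genetic_element\t%d\t%d\t.\t+\t.\tID=%s;status=%s",
        e$replicon_id, e$start, e$end, eid, e$status))
      pairs <- e$att_pairs[[1]]
      if (!is.null(pairs) && nrow(pairs)) {
        for (j in seq_len(nrow(pairs))) {
          p <- pairs[j, ]
          lines <- c(lines, sprintf(
            "%s\taicescan\tattachment_site\t%d\t%d\t.\t+\t.\tID=%s_attL%d;Parent=%s;site=attL",
            e$replicon_id, p$attL_start, p$attL_end, eid, j, eid))
          lines <- c(lines, sprintf(
            "%s\taicescan\tattachment_site\t%d\t%d\t.\t+\t.\tID=%s_attR%d;Parent=%s;site=attR",
            e$replicon_id, p$attR_start, p$attR_end, eid, j, eid))
        }
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Import an externally computed domain-hit table
#'
#' Accepts hit tables produced outside the package (e.g. by an HMMER run with
#' the published Pfam roster) so that downstream element calling can be
#' applied unchanged. Required columns: `replicon_id`, `feature_id`,
#' `profile`, `role`, `score_bits`, `passed`; `midpoint_bp` is recomputed
#' from `replicon` when missing.
#'
#' @param path Path to the TSV file.
#' @param replicon Optional `Replicon` used to fill in gene midpoints.
#' @return A domain-hit tibble as produced by [search_proteome()].
#' @export
read_hits_tsv <- function(path, replicon = NULL) {
  hits <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("replicon_id", "feature_id", "profile", "role", "score_bits", "passed")
  missing <- setdiff(need, names(hits))
  if (length(missing)) {
    stop("hit table lacks column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!"midpoint_bp" %in% names(hits)) {
    if (is.null(replicon)) stop("need `replicon` to compute midpoint_bp", call. = FALSE)
    f <- replicon$features
    idx <- match(hits$feature_id, f$id)
    hits$midpoint_bp <- as.integer((f$start[idx] + f$end[idx]) %/% 2L)
  }
  tibble::as_tibble(hits)
}
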