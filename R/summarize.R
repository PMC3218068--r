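#' Tabulate domain hits per genome class
#'
#' Counts passing hits per domain profile for complete versus draft
#' genomes, with a bottom row of called element totals — the summary table
#' of a whole-collection scan.
#'
#' @param hits Combined hit table over all replicons.
#' @param metadata Metadata tibble with `replicon_id` and `genome_class`
#'   (`"complete"`/`"draft"`; missing column counts everything as complete).
#' @param regions Optional combined region table; adds an `AICEs` row.
#' @return Tibble: `domain`, one count column per genome class.
#' @export
domain_hit_table <- function(hits, metadata = NULL, regions = NULL) {
  classes <- c("complete", "draft")
  cls <- function(rid) {
    if (is.null(metadata) || is.null(metadata$genome_class)) {
      return(rep("complete", length(rid)))
    }
    out <- metadata$genome_class[match(rid, metadata$replicon_id)]
    ifelse(is.na(out), "complete", out)
  }
  h <- hits[hits$passed, , drop = FALSE]
  h$genome_class <- cls(h$replicon_id)
  counts <- h |>
    dplyr::count(.data$profile, .data$genome_class) |>
    tidyr::pivot_wider(names_from = "genome_class", values_from = "n",
                       values_fill = 0L)
  for (cl in classes) if (is.null(counts[[cl]])) counts[[cl]] <- 0L
  counts <- dplyr::rename(counts, domain = "profile")[, c("domain", classes)]
  if (!is.null(regions)) {
    r <- regions[regions$status %in% c("AICE", "PLASMID_ICE"), , drop = FALSE]
    r$genome_class <- cls(r$replicon_id)
    counts <- dplyr::bind_rows(counts, tibble::tibble(
      domain = "AICEs",
      complete = sum(r$genome_class == "complete"),
      draft = sum(r$genome_class == "draft")))
  }
  counts
}

#' Element distribution per host group
#'
#' Per-genome element counts summarized by host suborder, environmental
#' niche, or genome-size bin: median, standard deviation and extreme values
#' per group. Genomes without any element count as zeros; an unknown group
#' label goes into an `"unclassified"` bucket.
#'
#' @param regions Combined region table (statuses `AICE`/`PLASMID_ICE`
#'   count; remnants and rejected candidates never do).
#' @param metadata Metadata with `replicon_id` plus the grouping column.
#' @param group_by `"suborder"`, `"niche"` or `"size_bin"`.
#' @param size_bin_mbp Genome-size bin width (Mbp) for `"size_bin"`.
#' @return Tibble: `group`, `n_genomes`, `n_elements`, `median`, `sd`,
#'   `min`, `max`.
#' @export
element_distribution <- function(regions, metadata,
                                 group_by = c("suborder", "niche", "size_bin"),
                                 size_bin_mbp = 1) {
  group_by <- match.arg(group_by)
  md <- tibble::as_tibble(metadata)
  if (group_by == "size_bin") {
    mbp <- md$genome_size_bp / 1e6
    md$group <- sprintf("%g-%g Mbp",
                        floor(mbp / size_bin_mbp) * size_bin_mbp,
                        (floor(mbp / size_bin_mbp) + 1) * size_bin_mbp)
  } else {
    md$group <- md[[group_by]]
  }
  md$group[is.na(md$group) | md$group == ""] <- "unclassified"

  counted <- regions[regions$status %in% c("AICE", "PLASMID_ICE"), , drop = FALSE]
  per_genome <- md |>
    dplyr::mutate(n = vapply(.data$replicon_id,
                             function(rid) sum(counted$replicon_id == rid),
                             integer(1)))
  per_genome |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n_genomes = dplyr::n(),
      n_elements = sum(.data$n),
      median = stats::median(.data$n),
      sd = ifelse(dplyr::n() > 1L, stats::sd(.data$n), 0),
      min = min(.data$n),
      max = max(.data$n),
      .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$n_elements))
}
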