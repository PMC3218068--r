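#' Scan one replicon end to end
#'
#' Profile search, Prim-Pol partner annotation, element calling (including
#' order-filter exclusion, T4SS-type detection, remnants, plasmid
#' classification), att-site resolution and in-silico excision.
#'
#' @param replicon A `Replicon`.
#' @param profiles Calibrated profile roster (default
#'   [default_profile_set()]).
#' @param max_window Maximum region span (bp).
#' @param allow_rep_other Admit `REP_OTHER:*` replication families in
#'   element calls.
#' @param att Named list of att-resolution settings passed to
#'   [resolve_att_sites()] (`flank`, `min_len`, `min_identity`,
#'   `trna_terminal`, `int_trna_dist`).
#' @return A list: `hits`, `regions`, `elements`, `products`.
#' @export
scan_replicon <- function(replicon, profiles = default_profile_set(),
                          max_window = 60000, allow_rep_other = FALSE,
                          att = list()) {
  hits <- search_proteome(replicon, profiles)
  hits <- annotate_reppp(hits, replicon)
  regions <- call_elements(replicon, hits, max_window = max_window,
                           allow_rep_other = allow_rep_other)
  elements <- rlang::exec(delimit_elements, regions, replicon, !!!att)
  bounded <- elements[!elements$unbounded, , drop = FALSE]
  products <- purrr::map_dfr(seq_len(nrow(bounded)), function(i) {
    excision_products(bounded[i, ], replicon)
  })
  if (!nrow(products)) products <- empty_products()
  products <- resolve_tandem(elements, replicon, products = products)
  list(hits = hits, regions = regions, elements = elements,
       products = products)
}

#' Scan a genome collection
#'
#' Runs [scan_replicon()] over a set of replicons (or FASTA/GFF3 file
#' pairs), combines the per-replicon tables, and derives the collection
#' summaries (domain-hit table and element distributions). Results can be
#' written to an output directory as TSV/GFF3/JSON together with a run log
#' recording parameters and seed.
#'
#' @param replicons A list of `Replicon` objects, or a data frame with
#'   columns `fasta`, `gff` (paths) to be loaded via [read_replicons()].
#' @param metadata Optional metadata tibble ([read_metadata()]).
#' @param out_dir Optional output directory.
#' @param seed Integer recorded in the run log (scanning itself is
#'   deterministic).
#' @inheritParams scan_replicon
#' @return An `aice_scan` object: list of combined `hits`, `regions`,
#'   `elements`, `products`, `summary` tables plus `params`.
#' @export
run_scan <- function(replicons, metadata = NULL,
                     profiles = default_profile_set(), max_window = 60000,
                     allow_rep_other = FALSE, att = list(), out_dir = NULL,
                     seed = NA_integer_) {
  if (is.data.frame(replicons)) {
    replicons <- purrr::flatten(purrr::map2(replicons$fasta, replicons$gff,
                                            function(fa, gf) {
                                              read_replicons(fa, gf, meta = metadata)
                                            }))
  }
  if (methods::is(replicons, "Replicon")) replicons <- list(replicons)
  per <- purrr::map(replicons, scan_replicon, profiles = profiles,
                    max_window = max_window,
                    allow_rep_other = allow_rep_other, att = att)
  res <- list(
    hits = purrr::map_dfr(per, "hits"),
    regions = purrr::map_dfr(per, "regions"),
    elements = purrr::map_dfr(per, "elements"),
    products = purrr::map_dfr(per, "products"))
  res$summary <- domain_hit_table(res$hits, metadata, res$regions)
  res$distribution <- if (!is.null(metadata)) {
    element_distribution(res$regions, metadata, "niche")
  }
  res$params <- list(max_window = max_window,
                     allow_rep_other = allow_rep_other, att = att,
                     n_replicons = length(replicons), seed = seed)
  class(res) <- "aice_scan"
  if (!is.null(out_dir)) write_scan_outputs(res, out_dir)
  res
}

write_scan_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_results(dplyr::select(res$regions, -dplyr::any_of("region")),
                file.path(out_dir, "regions.tsv"), "tsv")
  write_results(dplyr::select(res$elements, -dplyr::any_of(c("region", "att_pairs"))),
                file.path(out_dir, "elements.tsv"), "tsv")
  if (nrow(res$elements)) {
    write_results(res$elements, file.path(out_dir, "elements.gff3"), "gff3")
  }
  write_results(dplyr::select(res$products, -dplyr::any_of(c("chrom_after", "circle"))),
                file.path(out_dir, "products.tsv"), "tsv")
  write_results(res$summary, file.path(out_dir, "domain_hits.tsv"), "tsv")
  write_results(res$regions, file.path(out_dir, "regions.json"), "json")
  log_lines <- c(
    paste0("# aicescan ", as.character(utils::packageVersion("aicescan"))),
    paste0("# seed: ", res$params$seed),
    paste0("# max_window: ", res$params$max_window),
    paste0("# allow_rep_other: ", res$params$allow_rep_other),
    paste0("# replicons: ", res$params$n_replicons))
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}

#' @export
print.aice_scan <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<aice_scan: %d replicon(s); %d AICE, %d T4SS ICE, %d remnant, %d rejected; %d excision product(s)>\n",
    x$params$n_replicons, g$n_aice, g$n_t4ss_ice, g$n_remnant, g$n_rejected,
    g$n_products))
  invisible(x)
}

#' Tidy a scan result
#'
#' @param x An `aice_scan` object.
#' @param what Which table: `"elements"` (default), `"regions"`, `"hits"`,
#'   `"products"`, `"summary"`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.aice_scan <- function(x, what = c("elements", "regions", "hits",
                                       "products", "summary"), ...) {
  what <- match.arg(what)
  out <- x[[what]]
  if (what == "elements") out <- dplyr::select(out, -dplyr::any_of("region"))
  tibble::as_tibble(out)
}

#' One-row summary of a scan result
#'
#' @param x An `aice_scan` object.
#' @param ... Unused.
#' @return A one-row tibble with element/remnant/product counts and the
#'   mean element G+C.
#' @export
glance.aice_scan <- function(x, ...) {
  r <- x$regions
  tibble::tibble(
    n_replicons = x$params$n_replicons,
    n_aice = sum(r$status == "AICE"),
    n_t4ss_ice = sum(r$status == "T4SS_ICE"),
    n_plasmid_ice = sum(r$status == "PLASMID_ICE"),
    n_remnant = sum(r$status == "REMNANT"),
    n_rejected = sum(r$status == "REJECTED"),
    n_products = nrow(x$products),
    mean_element_gc = if (nrow(x$elements)) mean(x$elements$gc) else NA_real_)
}

#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @export
glance <- function(x, ...) UseMethod("glance")

#' Plot the element-count distribution per host group
#'
#' Box-style summary (median, spread, extremes) of per-genome element
#' counts by suborder, niche or genome-size bin.
#'
#' @param distribution An [element_distribution()] tibble.
#' @return A ggplot object.
#' @export
plot_element_distribution <- function(distribution) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  ggplot2::ggplot(distribution,
                  ggplot2::aes(x = stats::reorder(.data$group, -.data$n_elements))) +
    ggplot2::geom_linerange(ggplot2::aes(ymin = .data$min, ymax = .data$max)) +
    ggplot2::geom_crossbar(ggplot2::aes(y = .data$median,
                                        ymin = pmax(0, .data$median - .data$sd),
                                        ymax = .data$median + .data$sd),
                           width = 0.5, fill = "grey85") +
    ggplot2::labs(x = NULL, y = "elements per genome") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Map of one element's gene organization
#'
#' Draws the element span, its att sites and the genes inside it along the
#' chromosome coordinate.
#'
#' @param element One row of an element table.
#' @param replicon The `Replicon`.
#' @return A ggplot object.
#' @export
plot_element_map <- function(element, replicon) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  f <- replicon$features
  genes <- f[f$start >= element$start & f$end <= element$end, , drop = FALSE]
  genes$ypos <- 1
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = tibble::tibble(x = element$start, xend = element$end),
                          ggplot2::aes(x = .data$x, xend = .data$xend, y = 1, yend = 1),
                          linewidth = 0.3, colour = "grey60") +
    ggplot2::geom_rect(data = genes,
                       ggplot2::aes(xmin = .data$start, xmax = .data$end,
                                    ymin = 0.9, ymax = 1.1, fill = .data$ftype)) +
    ggplot2::annotate("point", x = c(element$attL_start, element$attR_end),
                      y = 1, shape = 17, size = 3) +
    ggplot2::labs(x = sprintf("%s (bp)", replicon$id), y = NULL,
                  title = element$element_id) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}
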