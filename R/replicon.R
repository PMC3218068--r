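#' Replicon objects
#'
#' A `Replicon` bundles one chromosome or plasmid sequence with its gene
#' annotation and host metadata. The sequence is a plain `{A,C,G,T,N}` string;
#' features live in a tibble with 1-based inclusive coordinates (GFF3 dialect).
#' For circular replicons a feature crossing the origin is stored with
#' `end > length(seq)` (the GFF3 convention for origin-spanning features);
#' `feature_segments()` expands such a feature into its two in-range segments.
#'
#' @param id Replicon identifier.
#' @param seq DNA sequence (character scalar over A,C,G,T,N).
#' @param features Tibble with columns `id`, `start`, `end`, `strand`,
#'   `ftype` (`"CDS"` or `"tRNA"`), `product`, `translation` (CDS),
#'   `trna_isotype` (tRNA).
#' @param topology `"circular"` or `"linear"`.
#' @param kind `"chromosome"` or `"plasmid"`.
#' @param meta Named list of host metadata (`suborder`, `genus`, `niche`,
#'   `genome_size_bp`). Missing entries are filled with `NA`.
#' @return A `Replicon` object.
#' @export
new_replicon <- function(id, seq, features = NULL,
                         topology = c("linear", "circular"),
                         kind = c("chromosome", "plasmid"),
                         meta = list()) {
  topology <- match.arg(topology)
  kind <- match.arg(kind)
  seq <- toupper(seq)
  if (grepl("[^ACGTN]", seq)) {
    stop("replicon sequence may only contain A, C, G, T, N", call. = FALSE)
  }
  n <- nchar(seq)
  features <- normalize_features(features, n, topology)
  meta_full <- list(suborder = NA_character_, genus = NA_character_,
                    niche = NA_character_, genome_size_bp = NA_integer_)
  meta_full[names(meta)] <- meta
  structure(
    list(id = id, seq = seq, topology = topology, kind = kind,
         features = features, meta = meta_full),
    class = "Replicon")
}

empty_features <- function() {
  tibble::tibble(id = character(), start = integer(), end = integer(),
                 strand = character(), ftype = character(),
                 product = character(), translation = character(),
                 trna_isotype = character())
}

normalize_features <- function(features, n, topology) {
  if (is.null(features) || nrow(features) == 0L) return(empty_features())
  features <- tibble::as_tibble(features)
  for (col in c("product", "translation", "trna_isotype")) {
    if (is.null(features[[col]])) features[[col]] <- NA_character_
  }
  if (is.null(features$strand)) features$strand <- "+"
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  # start > end is only legal on a circular replicon: wrap-normalize so that
  # end = start + length - 1 in the virtually doubled coordinate space
  wraps <- features$end < features$start
  if (any(wraps)) {
    if (topology != "circular") {
      stop("feature with start > end on a linear replicon", call. = FALSE)
    }
    features$end[wraps] <- features$end[wraps] + n
  }
  if (any(features$start < 1L)) stop("feature start < 1", call. = FALSE)
  limit <- if (topology == "circular") 2L * n else n
  if (any(features$end > limit)) {
    stop("feature interval extends beyond the sequence", call. = FALSE)
  }
  if (anyDuplicated(features$id)) {
    stop("feature ids must be unique within a replicon", call. = FALSE)
  }
  features[order(features$start, features$end), , drop = FALSE]
}

#' @export
print.Replicon <- function(x, ...) {
  cat(sprintf("<Replicon %s: %s %s, %s bp, %d features (%d CDS, %d tRNA)>\n",
              x$id, x$topology, x$kind, format(nchar(x$seq), big.mark = ","),
              nrow(x$features), sum(x$features$ftype == "CDS"),
              sum(x$features$ftype == "tRNA")))
  invisible(x)
}

#' Expand features into origin-normalized segments
#'
#' Origin-spanning features of circular replicons (stored with
#' `end > nchar(seq)`) are expanded into their two in-range segments; all
#' other features yield one segment. Total segment length equals feature
#' length.
#'
#' @param replicon A [new_replicon()] object.
#' @return Tibble with columns `id`, `segment`, `start`, `end`.
#' @export
feature_segments <- function(replicon) {
  n <- nchar(replicon$seq)
  purrr::pmap_dfr(
    replicon$features[, c("id", "start", "end")],
    function(id, start, end) {
      if (end <= n) {
        tibble::tibble(id = id, segment = 1L, start = start, end = end)
      } else {
        tibble::tibble(id = id, segment = c(1L, 2L),
                       start = c(start, 1L), end = c(n, end - n))
      }
    })
}

feature_length <- function(start, end) end - start + 1L

#' Read replicons from FASTA + GFF3
#'
#' Loads one replicon per FASTA record, attaching CDS and tRNA features from
#' the GFF3 file (seqids must match the FASTA ids). CDS translations are taken
#' from the GFF3 `translation` attribute when present, otherwise translated
#' in-frame from the coordinates with the bacterial genetic code (table 11).
#' A CDS whose span is not a multiple of three and has no annotated
#' translation is kept without a translation and flagged with a warning.
#'
#' @param fasta_path Path to a (multi-)FASTA file.
#' @param gff_path Path to a GFF3 file with CDS and tRNA features.
#' @param meta Named list (single replicon) or data frame of per-replicon
#'   metadata with a `replicon_id` column (see [read_metadata()]).
#' @param topology,kind Defaults applied when `meta` does not carry
#'   `topology`/`kind` columns.
#' @return A named list of `Replicon` objects.
#' @export
read_replicons <- function(fasta_path, gff_path = NULL, meta = NULL,
                           topology = "linear", kind = "chromosome") {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  feats <- if (is.null(gff_path)) NULL else import_feature_table(gff_path)
  out <- lapply(names(seqs), function(sid) {
    f <- if (is.null(feats)) NULL else feats[feats$seqid == sid, , drop = FALSE]
    m <- replicon_meta(meta, sid)
    topo <- m$topology %||% topology
    knd <- m$kind %||% kind
    m$topology <- NULL; m$kind <- NULL
    rep <- new_replicon(sid, as.character(seqs[[sid]]),
                        features = if (is.null(f)) NULL else f[, setdiff(names(f), "seqid")],
                        topology = topo, kind = knd, meta = m)
    fill_translations(rep)
  })
  if (!is.null(feats)) {
    orphan <- setdiff(unique(feats$seqid), names(seqs))
    if (length(orphan)) {
      stop("GFF3 seqid(s) without a FASTA sequence: ",
           paste(orphan, collapse = ", "), call. = FALSE)
    }
  }
  setNames(out, names(seqs))
}

#' @rdname read_replicons
#' @export
read_replicon <- function(fasta_path, gff_path = NULL, meta = NULL,
                          topology = "linear", kind = "chromosome") {
  reps <- read_replicons(fasta_path, gff_path, meta, topology, kind)
  if (length(reps) != 1L) {
    stop("expected exactly one FASTA record; use read_replicons()", call. = FALSE)
  }
  reps[[1L]]
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1L && is.na(a))) b else a

replicon_meta <- function(meta, sid) {
  if (is.null(meta)) return(list())
  if (is.data.frame(meta)) {
    row <- meta[meta$replicon_id == sid, , drop = FALSE]
    if (nrow(row) == 0L) return(list())
    m <- as.list(row[1L, setdiff(names(row), "replicon_id")])
    return(m)
  }
  as.list(meta)
}

import_feature_table <- function(gff_path) {
  gr <- rtracklayer::import(gff_path, format = "gff3")
  keep <- as.character(gr$type) %in% c("CDS", "tRNA")
  gr <- gr[keep]
  mc <- S4Vectors::mcols(gr)
  get_attr <- function(name) {
    if (name %in% names(mc)) as.character(mc[[name]]) else rep(NA_character_, length(gr))
  }
  ids <- get_attr("ID")
  if (anyNA(ids)) {
    ids[is.na(ids)] <- paste0("feature_", which(is.na(ids)))
  }
  tibble::tibble(
    seqid = as.character(GenomicRanges::seqnames(gr)),
    id = ids,
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = ifelse(as.character(GenomicRanges::strand(gr)) == "-", "-", "+"),
    ftype = as.character(gr$type),
    product = get_attr("product"),
    translation = get_attr("translation"),
    trna_isotype = get_attr("isotype"))
}

# fill missing CDS translations from coordinates (genetic code table 11)
fill_translations <- function(replicon) {
  f <- replicon$features
  todo <- which(f$ftype == "CDS" & (is.na(f$translation) | f$translation == ""))
  if (!length(todo)) return(replicon)
  n <- nchar(replicon$seq)
  code <- Biostrings::getGeneticCode("11")
  for (i in todo) {
    len <- feature_length(f$start[i], f$end[i])
    if (len %% 3L != 0L) {
      warning(sprintf("CDS %s on %s: span not a multiple of 3 and no annotated translation; kept without translation",
                      f$id[i], replicon$id), call. = FALSE)
      next
    }
    dna <- extract_seq(replicon, f$start[i], f$end[i])
    if (f$strand[i] == "-") {
      dna <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(dna)))
    }
    aa <- as.character(Biostrings::translate(
      Biostrings::DNAString(dna), genetic.code = code, if.fuzzy.codon = "X"))
    f$translation[i] <- sub("\\*$", "", aa)
  }
  replicon$features <- f
  replicon
}

# substring with circular wrap-around (end may exceed length on circular)
extract_seq <- function(replicon, start, end) {
  n <- nchar(replicon$seq)
  if (end <= n) return(substr(replicon$seq, start, end))
  if (replicon$topology != "circular" || end > 2L * n) {
    stop("interval beyond sequence end on a linear replicon", call. = FALSE)
  }
  paste0(substr(replicon$seq, start, n), substr(replicon$seq, 1L, end - n))
}

#' G+C content of a replicon interval
#'
#' Fraction (G+C)/(A+C+G+T) over a 1-based inclusive interval; `N` bases are
#' excluded from the denominator. On circular replicons the interval may span
#' the origin (`end > nchar(seq)` in doubled coordinates).
#'
#' @param replicon A `Replicon`.
#' @param start,end Interval bounds (default: whole sequence).
#' @return Fraction in `[0, 1]`.
#' @export
gc_content <- function(replicon, start = 1L, end = nchar(replicon$seq)) {
  n <- nchar(replicon$seq)
  limit <- if (replicon$topology == "circular") 2L * n else n
  if (length(start) != 1L || length(end) != 1L || is.na(start) || is.na(end) ||
      start < 1L || end > limit || start > end) {
    stop("invalid or empty interval for gc_content()", call. = FALSE)
  }
  s <- extract_seq(replicon, start, end)
  gc <- stringr::str_count(s, "[GC]")
  at <- stringr::str_count(s, "[AT]")
  if (gc + at == 0L) stop("interval contains no unambiguous bases", call. = FALSE)
  gc / (gc + at)
}

#' Write a replicon back to FASTA and GFF3
#'
#' Coordinates are emitted exactly as stored (1-based inclusive;
#' origin-spanning features of circular replicons keep `end > seqlen`, the
#' GFF3 circular-genome convention), so a load/write/load cycle preserves
#' every interval.
#'
#' @param replicon A `Replicon`.
#' @param fasta_path,gff_path Output paths (either may be `NULL` to skip).
#' @return `replicon`, invisibly.
#' @export
write_replicon <- function(replicon, fasta_path = NULL, gff_path = NULL) {
  if (!is.null(fasta_path)) {
    ss <- Biostrings::DNAStringSet(setNames(replicon$seq, replicon$id))
    Biostrings::writeXStringSet(ss, fasta_path)
  }
  if (!is.null(gff_path)) {
    f <- replicon$features
    lines <- c("##gff-version 3",
               sprintf("##sequence-region %s 1 %d", replicon$id, nchar(replicon$seq)))
    if (nrow(f)) {
      attrs <- purrr::pmap_chr(f, function(id, start, end, strand, ftype,
                                           product, translation, trna_isotype) {
        a <- c(sprintf("ID=%s", id))
        if (!is.na(product)) a <- c(a, sprintf("product=%s", gff_escape(product)))
        if (!is.na(translation)) a <- c(a, sprintf("translation=%s", translation))
        if (!is.na(trna_isotype)) a <- c(a, sprintf("isotype=%s", trna_isotype))
        paste(a, collapse = ";")
      })
      lines <- c(lines, sprintf("%s\taicescan\t%s\t%d\t%d\t.\t%s\t.\t%s",
                                replicon$id, f$ftype, f$start, f$end, f$strand, attrs))
    }
    writeLines(lines, gff_path)
  }
  invisible(replicon)
}

gff_escape <- function(x) {
  x <- gsub("%", "%25", x, fixed = TRUE)
  x <- gsub(";", "%3B", x, fixed = TRUE)
  x <- gsub("=", "%3D", x, fixed = TRUE)
  gsub(",", "%2C", x, fixed = TRUE)
}

#' Read a per-genome metadata table
#'
#' TSV with columns `replicon_id`, `suborder`, `genus`, `niche`,
#' `genome_size_bp` and optionally `topology`, `kind`, `genome_class`
#' (`"complete"`/`"draft"`).
#'
#' @param path Path to the TSV file.
#' @return A tibble.
#' @export
read_metadata <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}
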