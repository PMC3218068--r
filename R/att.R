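#' Find direct repeats in a sequence interval
#'
#' Same-orientation repeat pairs are found by exact k-mer seeding and
#' ungapped extension with mismatches. On each alignment diagonal, maximal
#' exact match runs of at least `k` bases seed an extension: first rightward
#' then leftward, the adjacent exact run is absorbed when it is worth the
#' mismatches crossed (run length strictly greater than five matches per
#' mismatch in the gap) and the interval identity stays at or above
#' `min_identity`; intervals always begin and end on a match. The gain rule
#' keeps a repeat from creeping into coincidental flanking matches, which a
#' bare identity threshold would happily absorb. Reported pairs have length
#' at least `min_len`, identity at least `min_identity`, non-overlapping
#' copies, and are maximal on their diagonal (no reported pair is contained
#' in another). `N` never matches.
#'
#' @param replicon A `Replicon` (or a plain DNA string).
#' @param start,end Interval to scan (1-based inclusive; defaults to the
#'   whole sequence). Intervals longer than 80 kb are refused.
#' @param min_len Minimum repeat length (bp).
#' @param min_identity Minimum fraction of matching positions.
#' @param k Exact seed length.
#' @return Tibble sorted by decreasing (length, identity):
#'   `start1`, `end1`, `start2`, `end2` (replicon coordinates),
#'   `length`, `identity`.
#' @export
find_direct_repeats <- function(replicon, start = NULL, end = NULL,
                                min_len = 14, min_identity = 0.9, k = 12) {
  s <- if (is.character(replicon)) replicon else replicon$seq
  n0 <- nchar(s)
  start <- start %||% 1L
  end <- end %||% n0
  if (!is.character(replicon)) {
    s <- extract_seq(replicon, start, end)
  } else {
    s <- substr(s, start, end)
  }
  n <- nchar(s)
  if (n > 80000L) stop("interval longer than 80 kb; narrow the scan window", call. = FALSE)
  if (n < 2L * min_len) return(empty_repeat_pairs())

  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  # exact k-mer seeds: positions sharing a k-mer, grouped
  nk <- n - k + 1L
  kmers <- substring(s, 1:nk, k:n)
  ok <- !grepl("N", kmers, fixed = TRUE)
  groups <- split(which(ok), kmers[ok])
  groups <- groups[lengths(groups) >= 2L]

  # diagonal -> seed positions (position in the first copy)
  diag_seeds <- list()
  for (g in groups) {
    if (length(g) > 30L) g <- g[seq_len(30L)]  # guard against simple repeats
    for (a in seq_len(length(g) - 1L)) {
      for (b in (a + 1L):length(g)) {
        d <- g[b] - g[a]
        key <- as.character(d)
        diag_seeds[[key]] <- c(diag_seeds[[key]], g[a])
      }
    }
  }
  if (!length(diag_seeds)) return(empty_repeat_pairs())

  out <- list()
  for (key in names(diag_seeds)) {
    d <- as.integer(key)
    len_diag <- n - d
    if (len_diag < min_len) next
    match_vec <- chars[seq_len(len_diag)] == chars[seq_len(len_diag) + d] &
      chars[seq_len(len_diag)] != "N"
    runs <- rle(match_vec)
    run_end <- cumsum(runs$lengths)
    run_start <- run_end - runs$lengths + 1L
    matched <- which(runs$values)
    # seed runs: exact runs containing a k-mer seed (>= k long)
    seed_runs <- matched[runs$lengths[matched] >= k]
    seeds_here <- unique(diag_seeds[[key]])
    seed_runs <- seed_runs[vapply(seed_runs, function(r) {
      any(seeds_here >= run_start[r] & seeds_here + k - 1L <= run_end[r])
    }, logical(1))]
    if (!length(seed_runs)) next
    ivs <- unique(lapply(seed_runs, function(r) {
      extend_repeat_run(r, runs$lengths, run_start, run_end, matched, min_identity)
    }))
    for (iv in ivs) {
      a <- iv[1L]; b <- iv[2L]
      len <- b - a + 1L
      if (len < min_len || len > d) next
      ident <- mean(match_vec[a:b])
      if (ident < min_identity) next
      out[[length(out) + 1L]] <- c(a, b, d, len, ident)
    }
  }
  if (!length(out)) return(empty_repeat_pairs())
  m <- do.call(rbind, out)
  res <- tibble::tibble(start1 = as.integer(m[, 1]), end1 = as.integer(m[, 2]),
                        d = as.integer(m[, 3]), length = as.integer(m[, 4]),
                        identity = m[, 5])
  res <- dplyr::distinct(res)
  # drop intervals contained in a longer reported interval on the same diagonal
  keep <- vapply(seq_len(nrow(res)), function(i) {
    !any(res$d == res$d[i] & res$start1 <= res$start1[i] & res$end1 >= res$end1[i] &
           res$length > res$length[i])
  }, logical(1))
  res <- res[keep, , drop = FALSE]
  res <- tibble::tibble(
    start1 = res$start1 + start - 1L, end1 = res$end1 + start - 1L,
    start2 = res$start1 + res$d + start - 1L, end2 = res$end1 + res$d + start - 1L,
    length = res$length, identity = res$identity)
  res[order(-res$length, -res$identity, res$start1), , drop = FALSE]
}

empty_repeat_pairs <- function() {
  tibble::tibble(start1 = integer(), end1 = integer(), start2 = integer(),
                 end2 = integer(), length = integer(), identity = double())
}

# canonical extension of one exact run over the run-length encoding of a
# diagonal's match vector: rightward then leftward, absorb the adjacent
# exact run when run_length > MISMATCH_COST * gap and the interval identity
# stays >= min_identity; returns c(first_pos, last_pos)
MISMATCH_COST <- 5L

extend_repeat_run <- function(r, run_lens, run_start, run_end, matched, min_identity) {
  lo_run <- r; hi_run <- r
  a <- run_start[r]; b <- run_end[r]
  n_match <- run_lens[r]
  repeat {   # rightward
    right <- matched[matched > hi_run]
    if (!length(right)) break
    rr <- right[1L]
    gap <- run_start[rr] - b - 1L
    new_matches <- n_match + run_lens[rr]
    new_ident <- new_matches / (run_end[rr] - a + 1L)
    if (run_lens[rr] <= MISMATCH_COST * gap || new_ident < min_identity) break
    hi_run <- rr; b <- run_end[rr]; n_match <- new_matches
  }
  repeat {   # leftward
    left <- matched[matched < lo_run]
    if (!length(left)) break
    ll <- left[length(left)]
    gap <- a - run_end[ll] - 1L
    new_matches <- n_match + run_lens[ll]
    new_ident <- new_matches / (b - run_start[ll] + 1L)
    if (run_lens[ll] <= MISMATCH_COST * gap || new_ident < min_identity) break
    lo_run <- ll; a <- run_start[ll]; n_match <- new_matches
  }
  c(a, b)
}

#' Resolve attachment sites for a candidate region
#'
#' Searches the region span plus `flank` on each side for direct repeats and
#' returns every pair whose copies bracket all core module genes, widest
#' first within rank. A pair is tRNA-anchored when one copy overlaps the
#' 3'-terminal `trna_terminal` bp of a tRNA gene lying within
#' `int_trna_dist` of the region's integrase gene; anchored pairs outrank
#' longer unanchored pairs (integration sites of these elements are tRNA 3'
#' ends duplicated as the att repeat). Pairs spanning core genes of another
#' candidate region are dropped — in a tandem array they delimit the
#' composite form, which [resolve_tandem()] reports instead. After ranking,
#' only pairs that share a copy with the top-ranked pair are kept: the att
#' sites of one element are all copies of one integration-target sequence
#' (a multi-attL element shares its attR between pairs), whereas an
#' unrelated short repeat that happens to bracket the core genes is not an
#' alternative attachment site.
#'
#' @param region One row of a region table (status `AICE` or `T4SS_ICE`).
#' @param replicon The `Replicon`.
#' @param other_regions Optional region table used to exclude pairs spanning
#'   foreign core genes.
#' @param flank Search margin around the region span (bp).
#' @param min_len,min_identity Repeat thresholds (see
#'   [find_direct_repeats()]).
#' @param trna_terminal tRNA 3'-end overlap window (bp).
#' @param int_trna_dist Maximum integrase-to-tRNA distance for anchoring (bp).
#' @return Tibble of att pairs ranked anchored-first, then by repeat
#'   length, then width: `attL_start`, `attL_end`, `attR_start`,
#'   `attR_end`, `repeat_len`, `identity`, `trna_anchor` (feature id or
#'   `NA`), `anchored`, `width`. Zero rows when the element is unbounded.
#' @export
resolve_att_sites <- function(region, replicon, other_regions = NULL,
                              flank = 5000, min_len = 14, min_identity = 0.9,
                              trna_terminal = 25, int_trna_dist = 2000) {
  if (!region$status %in% c("AICE", "T4SS_ICE", "CANDIDATE")) {
    stop("att resolution applies to AICE/T4SS_ICE regions", call. = FALSE)
  }
  n <- nchar(replicon$seq)
  win_lo <- max(1L, region$start - as.integer(flank))
  win_hi <- min(if (replicon$topology == "circular") 2L * n else n,
                region$end + as.integer(flank))
  pairs <- find_direct_repeats(replicon, win_lo, win_hi,
                               min_len = min_len, min_identity = min_identity)
  if (!nrow(pairs)) return(empty_att_pairs())

  f <- replicon$features
  col_or_na <- function(nm) {
    if (nm %in% names(region)) region[[nm]] else NA_character_
  }
  core_ids <- stats::na.omit(c(region$int_id, region$tra_id,
                               unlist(region$rep_ids), col_or_na("t4cp_id"),
                               col_or_na("virb4_id"), col_or_na("mob_id")))
  core <- f[f$id %in% core_ids, , drop = FALSE]
  core_mid <- (core$start + core$end) / 2
  # copies must flank every core gene
  ok <- pairs$end1 < min(core_mid) & pairs$start2 > max(core_mid)
  pairs <- pairs[ok, , drop = FALSE]
  if (!nrow(pairs)) return(empty_att_pairs())

  # drop pairs spanning a different region's integrase (tandem composite span)
  if (!is.null(other_regions) && nrow(other_regions)) {
    others <- other_regions[other_regions$status %in% c("AICE", "T4SS_ICE", "CANDIDATE") &
                              !(other_regions$start == region$start &
                                  other_regions$end == region$end), , drop = FALSE]
    if (nrow(others)) {
      other_int <- f[f$id %in% others$int_id, , drop = FALSE]
      other_mid <- (other_int$start + other_int$end) / 2
      spans_foreign <- vapply(seq_len(nrow(pairs)), function(i) {
        any(other_mid > pairs$end1[i] & other_mid < pairs$start2[i])
      }, logical(1))
      pairs <- pairs[!spans_foreign, , drop = FALSE]
    }
  }
  if (!nrow(pairs)) return(empty_att_pairs())

  # tRNA anchoring
  trna <- f[f$ftype == "tRNA", , drop = FALSE]
  int_feat <- f[f$id == region$int_id, , drop = FALSE]
  anchor <- rep(NA_character_, nrow(pairs))
  if (nrow(trna) && nrow(int_feat)) {
    near_int <- interval_gap(trna$start, trna$end, int_feat$start, int_feat$end) <=
      int_trna_dist
    trna <- trna[near_int, , drop = FALSE]
    if (nrow(trna)) {
      # 3' terminal window on the forward axis (strand-aware)
      t_lo <- ifelse(trna$strand == "-", trna$start,
                     pmax(trna$start, trna$end - trna_terminal + 1L))
      t_hi <- ifelse(trna$strand == "-",
                     pmin(trna$end, trna$start + trna_terminal - 1L), trna$end)
      for (i in seq_len(nrow(pairs))) {
        hit <- which(
          (pairs$start1[i] <= t_hi & pairs$end1[i] >= t_lo) |
            (pairs$start2[i] <= t_hi & pairs$end2[i] >= t_lo))
        if (length(hit)) anchor[i] <- trna$id[hit[1L]]
      }
    }
  }
  res <- tibble::tibble(
    attL_start = pairs$start1, attL_end = pairs$end1,
    attR_start = pairs$start2, attR_end = pairs$end2,
    repeat_len = pairs$length, identity = pairs$identity,
    trna_anchor = anchor, anchored = !is.na(anchor),
    width = pairs$end2 - pairs$start1 + 1L)
  # rank: tRNA anchoring, then repeat length (a long high-identity repeat is
  # far stronger evidence of an att duplication than a minimum-length one),
  # then width
  res <- res[order(-res$anchored, -res$repeat_len, -res$width), , drop = FALSE]
  # same-att-family rule: alternatives must share a copy with the top pair
  top <- res[1L, ]
  copies_overlap <- function(s1, e1, s2, e2) s1 <= e2 & e1 >= s2
  share <- copies_overlap(res$attL_start, res$attL_end, top$attL_start, top$attL_end) |
    copies_overlap(res$attL_start, res$attL_end, top$attR_start, top$attR_end) |
    copies_overlap(res$attR_start, res$attR_end, top$attL_start, top$attL_end) |
    copies_overlap(res$attR_start, res$attR_end, top$attR_start, top$attR_end)
  res[share, , drop = FALSE]
}

empty_products <- function() {
  tibble::tibble(element_id = character(), pair = integer(),
                 attL_start = integer(), attL_end = integer(),
                 attR_start = integer(), attR_end = integer(),
                 repeat_len = integer(), circle_len = integer(),
                 attP_seq = character(), attB_seq = character(),
                 composite = logical())
}

empty_att_pairs <- function() {
  tibble::tibble(attL_start = integer(), attL_end = integer(),
                 attR_start = integer(), attR_end = integer(),
                 repeat_len = integer(), identity = double(),
                 trna_anchor = character(), anchored = logical(),
                 width = integer())
}

#' Delimit called regions by their attachment sites
#'
#' Attaches att pairs to every `AICE`/`T4SS_ICE` region and sets element
#' boundaries to the top-ranked pair (tRNA-anchored first, then longest
#' repeat, then widest — for a multi-attL element this is the widest pair
#' of the att repeat family); all alternative pairs are kept in the
#' `att_pairs` list-column.
#' Regions without a qualifying pair are reported unbounded, with the core
#' gene span as boundaries.
#'
#' @param regions A [call_elements()] table.
#' @param replicon The `Replicon`.
#' @param ... Passed to [resolve_att_sites()].
#' @return Element tibble: `element_id`, `replicon_id`, `status`, `start`,
#'   `end`, `gc`, `unbounded`, att columns of the boundary pair, and the
#'   full `att_pairs` list-column.
#' @export
delimit_elements <- function(regions, replicon, ...) {
  sel <- regions[regions$status %in% c("AICE", "T4SS_ICE"), , drop = FALSE]
  if (!nrow(sel)) return(empty_elements())
  purrr::map_dfr(seq_len(nrow(sel)), function(i) {
    region <- sel[i, ]
    pairs <- resolve_att_sites(region, replicon, other_regions = regions, ...)
    eid <- sprintf("%s_elem_%05d", replicon$id,
                   as.integer(norm_start(region$start, nchar(replicon$seq),
                                         replicon$topology)) %/% 1000L)
    if (!nrow(pairs)) {
      return(tibble::tibble(
        element_id = eid, replicon_id = replicon$id, status = region$status,
        start = region$start, end = region$end,
        gc = gc_content(replicon, region$start, region$end),
        unbounded = TRUE, attL_start = NA_integer_, attL_end = NA_integer_,
        attR_start = NA_integer_, attR_end = NA_integer_,
        repeat_len = NA_integer_, trna_anchor = NA_character_,
        att_pairs = list(pairs), region = list(region)))
    }
    best <- pairs[1L, ]   # top-ranked pair
    tibble::tibble(
      element_id = eid, replicon_id = replicon$id, status = region$status,
      start = best$attL_start, end = best$attR_end,
      gc = gc_content(replicon, best$attL_start, best$attR_end),
      unbounded = FALSE, attL_start = best$attL_start, attL_end = best$attL_end,
      attR_start = best$attR_start, attR_end = best$attR_end,
      repeat_len = best$repeat_len, trna_anchor = best$trna_anchor,
      att_pairs = list(pairs), region = list(region))
  })
}

empty_elements <- function() {
  tibble::tibble(element_id = character(), replicon_id = character(),
                 status = character(), start = integer(), end = integer(),
                 gc = double(), unbounded = logical(),
                 attL_start = integer(), attL_end = integer(),
                 attR_start = integer(), attR_end = integer(),
                 repeat_len = integer(), trna_anchor = character(),
                 att_pairs = list(), region = list())
}

# core string surgery for one att pair; the upstream (attL) copy stays on
# the chromosome, the downstream copy travels on the circle as attP
excise_at <- function(seq, attL_start, attL_end, attR_start, attR_end,
                      context = 20L) {
  n <- nchar(seq)
  chrom_after <- paste0(substr(seq, 1L, attL_end), substr(seq, attR_end + 1L, n))
  circle <- substr(seq, attL_end + 1L, attR_end)
  clen <- nchar(circle)
  rep_len <- attR_end - attR_start + 1L
  # attP: the repeat copy on the circle with circular context on both sides
  left_ctx <- substr(circle, max(1L, clen - rep_len - context + 1L), clen - rep_len)
  right_ctx <- substr(circle, 1L, min(context, clen - rep_len))
  attP_seq <- paste0(left_ctx, substr(circle, clen - rep_len + 1L, clen), right_ctx)
  attB_seq <- paste0(substr(seq, max(1L, attL_start - context), attL_end),
                     substr(seq, attR_end + 1L, min(n, attR_end + context)))
  list(chrom_after = chrom_after, circle = circle, circle_len = clen,
       attP_seq = attP_seq, attB_seq = attB_seq)
}

#' In-silico excision products of an element
#'
#' For every att pair, site-specific recombination between attL and attR is
#' simulated by string surgery: one repeat copy stays at the chromosomal
#' attB locus (the upstream copy, by convention) and the element circularizes
#' carrying the other copy as the junction-spanning attP. Sequence is
#' conserved exactly: the post-excision chromosome plus the circle
#' re-concatenated at attB/attP reproduce the input, and
#' `circle_len = (attR_end - attL_start + 1) - repeat_len`.
#'
#' @param element One row of a [delimit_elements()] table (>= 1 att pair).
#' @param replicon The `Replicon`.
#' @param keep_seqs Keep the full post-excision chromosome and circle
#'   sequences in the output (for verification; off by default).
#' @return Tibble of excision products: `element_id`, `pair`, att
#'   coordinates, `repeat_len`, `circle_len`, `attP_seq`, `attB_seq`,
#'   `composite` (`FALSE` here), and optionally `chrom_after`/`circle`.
#' @export
excision_products <- function(element, replicon, keep_seqs = FALSE) {
  pairs <- element$att_pairs[[1L]]
  if (is.null(pairs) || !nrow(pairs)) {
    stop("element has no att pairs; cannot excise", call. = FALSE)
  }
  purrr::map_dfr(seq_len(nrow(pairs)), function(j) {
    p <- pairs[j, ]
    if (p$attR_end - p$attL_start + 1L <= 2L * p$repeat_len) {
      stop("degenerate att pair: repeat covers the whole span", call. = FALSE)
    }
    ex <- excise_at(replicon$seq, p$attL_start, p$attL_end,
                    p$attR_start, p$attR_end)
    out <- tibble::tibble(
      element_id = element$element_id, pair = j,
      attL_start = p$attL_start, attL_end = p$attL_end,
      attR_start = p$attR_start, attR_end = p$attR_end,
      repeat_len = p$repeat_len, circle_len = ex$circle_len,
      attP_seq = ex$attP_seq, attB_seq = ex$attB_seq, composite = FALSE)
    if (keep_seqs) {
      out$chrom_after <- ex$chrom_after
      out$circle <- ex$circle
    }
    out
  })
}

#' Re-integrate an excision circle at its attB locus
#'
#' The inverse of [excision_products()]: inserting the circle immediately
#' after the retained repeat copy restores the original attL...attR locus
#' exactly.
#'
#' @param chrom_after Post-excision chromosome sequence.
#' @param circle Circle sequence (as returned with `keep_seqs = TRUE`).
#' @param attL_end End position of the retained repeat copy.
#' @return The re-integrated chromosome sequence.
#' @export
integrate_circle <- function(chrom_after, circle, attL_end) {
  paste0(substr(chrom_after, 1L, attL_end), circle,
         substr(chrom_after, attL_end + 1L, nchar(chrom_after)))
}

#' Composite excision products of tandem elements
#'
#' Two adjacent elements that share an att copy (or abut within a few bases,
#' or share a tRNA anchor) can excise associatively as one large circle in
#' addition to their independent circles. For every such pair of elements a
#' composite product using the outermost attL and outermost attR is appended
#' to the product table; individual products are retained.
#'
#' @param elements A [delimit_elements()] table.
#' @param replicon The `Replicon`.
#' @param products Optional pre-computed individual product table; computed
#'   when omitted.
#' @param max_gap Maximum bp between one element's attR and the next
#'   element's attL to count as abutting.
#' @return Product tibble with `composite = TRUE` rows appended.
#' @export
resolve_tandem <- function(elements, replicon, products = NULL, max_gap = 5L) {
  bounded <- elements[!elements$unbounded, , drop = FALSE]
  if (is.null(products)) {
    products <- purrr::map_dfr(seq_len(nrow(bounded)),
                               function(i) excision_products(bounded[i, ], replicon))
  }
  if (nrow(bounded) < 2L) return(products)
  bounded <- bounded[order(bounded$start), , drop = FALSE]
  for (i in seq_len(nrow(bounded) - 1L)) {
    for (j in (i + 1L):nrow(bounded)) {
      e1 <- bounded[i, ]; e2 <- bounded[j, ]
      shares_copy <- e1$attR_start == e2$attL_start && e1$attR_end == e2$attL_end
      abuts <- !shares_copy && abs(e2$attL_start - e1$attR_end) <= max_gap + 1L
      same_anchor <- !is.na(e1$trna_anchor) && !is.na(e2$trna_anchor) &&
        e1$trna_anchor == e2$trna_anchor
      if (!(shares_copy || abuts || same_anchor)) next
      ex <- excise_at(replicon$seq, e1$attL_start, e1$attL_end,
                      e2$attR_start, e2$attR_end)
      products <- dplyr::bind_rows(products, tibble::tibble(
        element_id = paste(e1$element_id, e2$element_id, sep = "+"),
        pair = NA_integer_,
        attL_start = e1$attL_start, attL_end = e1$attL_end,
        attR_start = e2$attR_start, attR_end = e2$attR_end,
        repeat_len = e1$attL_end - e1$attL_start + 1L,
        circle_len = ex$circle_len, attP_seq = ex$attP_seq,
        attB_seq = ex$attB_seq, composite = TRUE))
    }
  }
  products
}
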