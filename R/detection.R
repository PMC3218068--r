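#' Call candidate element regions from a domain-hit table
#'
#' Applies the co-localization rule for FtsK/SpoIIIE-type elements: a region
#' no longer than `max_window` containing at least one gene of each of the
#' three core modules — integrase (Int), DNA translocase (Tra) and
#' replication initiator (Rep). Every window-compatible (Tra, Rep)
#' combination is enumerated per integrase, and hits are assigned globally:
#' as many integrases as possible are assembled, with minimal total span
#' and as few integrase-between-rep-and-tra arrangements as possible; each
#' core hit serves at most one region. The global view matters for tandem
#' arrays, where the downstream element's integrase lies closer to its
#' neighbour's transfer gene than to its own. On circular replicons hits
#' are scanned over doubled coordinates and rotated duplicates removed, so
#' origin-spanning regions are found.
#'
#' @param replicon A `Replicon`.
#' @param hits A [search_proteome()] table (only `passed` hits are used).
#' @param max_window Maximum region span in bp.
#' @param allow_rep_other Admit `REP_OTHER:*` families as the replication
#'   module (off by default: elements are expected to carry a RepSA-, RepAM-
#'   or Prim-Pol-type initiator; other Rep families are an opt-in extension).
#' @return Tibble of candidate regions with one row per region: `replicon_id`,
#'   `start`, `end`, `span_bp`, `status` (`"CANDIDATE"` here),
#'   `int_id`, `tra_id`, `rep_ids`, `wraps_origin`.
#' @export
find_candidate_regions <- function(replicon, hits, max_window = 60000,
                                   allow_rep_other = FALSE) {
  h <- scan_hits(replicon, hits)
  n <- nchar(replicon$seq)
  ints <- h[h$role %in% INT_ROLES, , drop = FALSE]
  tras <- h[h$role == "TRA", , drop = FALSE]
  reps <- h[is_rep_role(h$role, allow_rep_other) & h$role != "REP_PP", , drop = FALSE]
  if (!nrow(ints) || !nrow(tras) || !nrow(reps)) return(empty_regions())

  # Feasible assemblies per integrase: every (Tra, Rep) combination within
  # the window, labelled with span and whether the integrase would sit
  # between the two (int-internal). Hit assignment is then solved globally:
  # maximize the number of integrases assembled, then minimize the total
  # span, then the number of int-internal assemblies. A sequential
  # nearest-hit greedy mis-pairs tandem arrays, where the downstream
  # element's integrase lies closer to its neighbour's transfer gene than
  # to its own.
  combos_by_int <- lapply(split(ints, ints$feature_id), function(rows) {
    out <- purrr::pmap_dfr(rows[, c("feature_id", "midpoint_bp", "start", "end")],
      function(feature_id, midpoint_bp, start, end) {
        tc <- tras[abs(tras$midpoint_bp - midpoint_bp) <= max_window, , drop = FALSE]
        rc <- reps[abs(reps$midpoint_bp - midpoint_bp) <= max_window, , drop = FALSE]
        if (!nrow(tc) || !nrow(rc)) return(empty_candidates())
        grid <- tidyr::expand_grid(ti = seq_len(nrow(tc)), ri = seq_len(nrow(rc)))
        purrr::pmap_dfr(grid, function(ti, ri) {
          tra <- tc[ti, ]; rep <- rc[ri, ]
          lo <- min(start, tra$start, rep$start)
          hi <- max(end, tra$end, rep$end)
          internal <- midpoint_bp > min(rep$midpoint_bp, tra$midpoint_bp) &&
            midpoint_bp < max(rep$midpoint_bp, tra$midpoint_bp)
          tibble::tibble(int_id = feature_id, tra_id = tra$feature_id,
                         rep_id = rep$feature_id, start = lo, end = hi,
                         span_bp = hi - lo + 1L, int_internal = internal)
        })
      })
    out <- out[out$span_bp <= max_window, , drop = FALSE]
    if (!nrow(out)) return(out)
    # one entry per distinct hit pair; keep the tightest geometry, cap the
    # alternatives considered per integrase
    out <- out[order(out$int_internal, out$span_bp, out$start), , drop = FALSE]
    out <- out[!duplicated(paste(out$tra_id, out$rep_id)), , drop = FALSE]
    utils::head(out, 10L)
  })
  combos_by_int <- combos_by_int[vapply(combos_by_int, nrow, integer(1)) > 0L]
  if (!length(combos_by_int)) return(empty_regions())
  cand <- assign_core_hits(combos_by_int)
  if (!nrow(cand)) return(empty_regions())

  # circular rotations: same hit set at shifted coordinates -> keep canonical
  key <- purrr::pmap_chr(cand[, c("int_id", "tra_id", "rep_id")],
                         function(int_id, tra_id, rep_id) {
                           paste(sort(c(int_id, tra_id, rep_id)), collapse = "|")
                         })
  cand <- cand[order(cand$start), , drop = FALSE]
  cand <- cand[!duplicated(key[order(cand$start)]), , drop = FALSE]

  # all passing rep hits inside each region (for module classification)
  rep_ids <- purrr::map2(cand$start, cand$end, function(lo, hi) {
    reps$feature_id[reps$midpoint_bp >= lo & reps$midpoint_bp <= hi]
  })
  tibble::tibble(
    replicon_id = replicon$id,
    start = norm_start(cand$start, n, replicon$topology),
    end = norm_end(cand$start, cand$end, n, replicon$topology),
    span_bp = cand$span_bp, status = "CANDIDATE",
    int_id = cand$int_id, tra_id = cand$tra_id,
    rep_ids = purrr::map2(rep_ids, cand$rep_id, ~ union(.y, .x)),
    wraps_origin = cand$end > n & cand$start <= n,
    reject_reason = NA_character_)
}

empty_candidates <- function() {
  tibble::tibble(int_id = character(), tra_id = character(),
                 rep_id = character(), start = integer(), end = integer(),
                 span_bp = integer(), int_internal = logical())
}

# Globally consistent hit assignment: split integrases into conflict
# components (sharing any Tra/Rep hit across their combos) and, within each
# component, search assignments exhaustively for
# (max assembled, min total span, min int-internal), deterministic
# tie-break on leftmost starts. Components are tiny in practice (an
# integrase only conflicts with neighbours within the window); a node cap
# guards pathological inputs with a greedy fallback.
assign_core_hits <- function(combos_by_int, node_cap = 50000L) {
  ids <- names(combos_by_int)
  hitsets <- lapply(combos_by_int, function(cb) unique(c(cb$tra_id, cb$rep_id)))
  comp <- seq_along(ids)
  repeat {
    changed <- FALSE
    for (i in seq_along(ids)) {
      for (j in seq_along(ids)) {
        if (comp[i] != comp[j] && length(intersect(hitsets[[i]], hitsets[[j]]))) {
          comp[comp == comp[j]] <- comp[i]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  out <- list()
  for (cp in unique(comp)) {
    members <- which(comp == cp)
    # order by leftmost combo start for determinism
    members <- members[order(vapply(members, function(i) {
      min(combos_by_int[[i]]$start)
    }, numeric(1)))]
    sel <- solve_component(combos_by_int[members], node_cap)
    out[[length(out) + 1L]] <- sel
  }
  dplyr::bind_rows(empty_candidates(), out)
}

solve_component <- function(combos, node_cap) {
  n <- length(combos)
  best <- NULL
  best_key <- NULL
  nodes <- 0L
  rec <- function(i, consumed, chosen, count, span, internal) {
    nodes <<- nodes + 1L
    if (nodes > node_cap) return()
    if (i > n) {
      key <- c(-count, span, internal,
               if (length(chosen)) sum(vapply(chosen, function(x) x$start, numeric(1))) else 0)
      if (is.null(best_key) || compare_keys(key, best_key) < 0) {
        best <<- chosen
        best_key <<- key
      }
      return()
    }
    # optimistic bound on the assembly count
    if (!is.null(best_key) && -(count + (n - i + 1L)) > best_key[1L]) return()
    cb <- combos[[i]]
    for (j in seq_len(nrow(cb))) {
      row <- cb[j, ]
      if (row$tra_id %in% consumed || row$rep_id %in% consumed) next
      rec(i + 1L, c(consumed, row$tra_id, row$rep_id),
          c(chosen, list(row)), count + 1L, span + row$span_bp,
          internal + row$int_internal)
    }
    rec(i + 1L, consumed, chosen, count, span, internal)   # leave unassembled
  }
  rec(1L, character(0), list(), 0L, 0, 0L)
  if (nodes > node_cap) {
    # greedy fallback: smallest span first
    all <- dplyr::bind_rows(combos)
    all <- all[order(all$int_internal, all$span_bp, all$start), , drop = FALSE]
    used <- character(0)
    keep <- logical(nrow(all))
    for (j in seq_len(nrow(all))) {
      members <- c(all$int_id[j], all$tra_id[j], all$rep_id[j])
      if (!any(members %in% used)) {
        keep[j] <- TRUE
        used <- c(used, members)
      }
    }
    return(all[keep, , drop = FALSE])
  }
  dplyr::bind_rows(empty_candidates(), best)
}

compare_keys <- function(a, b) {
  for (k in seq_along(a)) {
    if (a[k] < b[k]) return(-1L)
    if (a[k] > b[k]) return(1L)
  }
  0L
}

empty_regions <- function() {
  tibble::tibble(replicon_id = character(), start = integer(), end = integer(),
                 span_bp = integer(), status = character(), int_id = character(),
                 tra_id = character(), rep_ids = list(),
                 wraps_origin = logical(), reject_reason = character())
}

# passing hits with gene intervals attached; duplicated over the doubled
# coordinate space for circular replicons
scan_hits <- function(replicon, hits) {
  h <- hits[hits$passed, , drop = FALSE]
  f <- replicon$features
  idx <- match(h$feature_id, f$id)
  h$start <- f$start[idx]
  h$end <- f$end[idx]
  if (replicon$topology == "circular" && nrow(h)) {
    n <- nchar(replicon$seq)
    h2 <- h
    h2$start <- h2$start + n
    h2$end <- h2$end + n
    h2$midpoint_bp <- h2$midpoint_bp + n
    h <- dplyr::bind_rows(h, h2)
  }
  h[order(h$midpoint_bp), , drop = FALSE]
}

norm_start <- function(start, n, topology) {
  if (topology == "circular") ((start - 1L) %% n) + 1L else start
}
norm_end <- function(start, end, n, topology) {
  if (topology != "circular") return(end)
  s <- ((start - 1L) %% n) + 1L
  s + (end - start)
}

#' Exclude candidates with an internal integrase gene
#'
#' Integrase genes sit next to one of the two attachment sites flanking an
#' integrated element, so a candidate whose integrase lies strictly between
#' its replication and transfer genes (by gene midpoint on the forward axis)
#' is rejected with reason `"int-internal"`.
#'
#' @param regions A [find_candidate_regions()] table.
#' @param replicon The scanned `Replicon`.
#' @param hits The hit table (used for gene midpoints).
#' @return `regions` with `status`/`reject_reason` updated.
#' @export
apply_order_filter <- function(regions, replicon, hits) {
  if (!nrow(regions)) return(regions)
  f <- replicon$features
  mid <- function(id) {
    i <- match(id, f$id)
    (f$start[i] + f$end[i]) / 2
  }
  for (i in seq_len(nrow(regions))) {
    mi <- mid(regions$int_id[i])
    mt <- mid(regions$tra_id[i])
    # use the rep gene nearest the integrase (the one that formed the region)
    mr <- mid(regions$rep_ids[[i]][1L])
    if (mi > min(mr, mt) && mi < max(mr, mt)) {
      regions$status[i] <- "REJECTED"
      regions$reject_reason[i] <- "int-internal"
    }
  }
  regions
}

#' Detect element remnants (two of three core modules)
#'
#' Regions carrying exactly two of the three core module classes (Int, Tra,
#' Rep) within `max_window`, not overlapping any full-element call, are
#' reported with status `REMNANT`. They are never counted in element totals.
#' A region with a single class (e.g. a lone chromosomal FtsK/SpoIIIE gene)
#' yields nothing.
#'
#' @inheritParams find_candidate_regions
#' @param regions Full-element calls whose hits must not be re-used.
#' @return Tibble of `REMNANT` regions (same columns as candidate regions;
#'   missing core genes are `NA`).
#' @export
detect_remnants <- function(replicon, hits, regions = empty_regions(),
                            max_window = 60000, allow_rep_other = FALSE) {
  h <- scan_hits(replicon, hits)
  n <- nchar(replicon$seq)
  h <- h[h$role %in% INT_ROLES | h$role == "TRA" |
           (is_rep_role(h$role, allow_rep_other) & h$role != "REP_PP"), , drop = FALSE]
  consumed <- unlist(c(regions$int_id[regions$status != "REJECTED"],
                       regions$tra_id[regions$status != "REJECTED"],
                       regions$rep_ids[regions$status != "REJECTED"]))
  h <- h[!h$feature_id %in% consumed, , drop = FALSE]
  h <- h[!duplicated(h$feature_id), , drop = FALSE]
  if (!nrow(h)) return(empty_regions())

  # left-to-right clustering: a gap above the window starts a new cluster;
  # clusters whose total span still exceeds the window are dropped below
  h <- h[order(h$midpoint_bp), , drop = FALSE]
  cluster <- cumsum(c(1L, diff(h$midpoint_bp) > max_window))
  out <- list()
  for (cl in split(seq_len(nrow(h)), cluster)) {
    sub <- h[cl, , drop = FALSE]
    classes <- unique(ifelse(sub$role %in% INT_ROLES, "INT",
                             ifelse(sub$role == "TRA", "TRA", "REP")))
    lo <- min(sub$start); hi <- max(sub$end)
    if (length(classes) != 2L || hi - lo + 1L > max_window) next
    if (nrow(regions)) {
      overlap <- any(regions$status %in% c("AICE", "CANDIDATE", "T4SS_ICE") &
                       regions$start <= hi & regions$end >= lo)
      if (overlap) next
    }
    int_ids <- sub$feature_id[sub$role %in% INT_ROLES]
    tra_ids <- sub$feature_id[sub$role == "TRA"]
    rep_ids <- sub$feature_id[!sub$role %in% c(INT_ROLES, "TRA")]
    out[[length(out) + 1L]] <- tibble::tibble(
      replicon_id = replicon$id,
      start = norm_start(lo, n, replicon$topology),
      end = norm_end(lo, hi, n, replicon$topology),
      span_bp = hi - lo + 1L, status = "REMNANT",
      int_id = if (length(int_ids)) int_ids[1L] else NA_character_,
      tra_id = if (length(tra_ids)) tra_ids[1L] else NA_character_,
      rep_ids = list(rep_ids),
      wraps_origin = hi > n & lo <= n,
      reject_reason = NA_character_)
  }
  res <- dplyr::bind_rows(empty_regions(), out)
  # circular duplicates (same features at rotated coordinates)
  res[!duplicated(paste(res$int_id, res$tra_id,
                        purrr::map_chr(res$rep_ids, paste, collapse = ","))), , drop = FALSE]
}

#' Detect T4SS-type integrative conjugative elements
#'
#' Calls regions within `max_window` containing an integrase plus the
#' type-IV-secretion conjugation triplet: (i) a coupling protein (T4CP),
#' (ii) a VirB4/TraC-like ATPase and (iii) a MOB_F-family relaxase.
#' A replication initiator is not required; replication hits inside the
#' region are recorded as annotations. Regions that also satisfy the
#' FtsK/SpoIIIE-type core rule are reported once with status `AICE` by
#' [call_elements()]; here every region matching the T4SS rule is returned.
#'
#' @inheritParams find_candidate_regions
#' @return Tibble of `T4SS_ICE` regions with `t4cp_id`, `virb4_id`, `mob_id`
#'   columns and optional `rep_ids`.
#' @export
detect_t4ss_ice <- function(replicon, hits, max_window = 60000) {
  h <- scan_hits(replicon, hits)
  n <- nchar(replicon$seq)
  ints <- h[h$role %in% INT_ROLES, , drop = FALSE]
  parts <- lapply(c(T4CP = "T4CP", VIRB4 = "VIRB4", MOB_F = "MOB_F"),
                  function(r) h[h$role == r, , drop = FALSE])
  if (!nrow(ints) || any(vapply(parts, nrow, integer(1)) == 0L)) {
    return(tibble::tibble())
  }
  reps <- h[is_rep_role(h$role, TRUE) & h$role != "REP_PP", , drop = FALSE]

  cand <- purrr::pmap_dfr(ints[, c("feature_id", "midpoint_bp", "start", "end")],
    function(feature_id, midpoint_bp, start, end) {
      sel <- lapply(parts, function(p) p[which.min(abs(p$midpoint_bp - midpoint_bp)), ])
      lo <- min(start, vapply(sel, function(x) as.numeric(x$start), numeric(1)))
      hi <- max(end, vapply(sel, function(x) as.numeric(x$end), numeric(1)))
      tibble::tibble(int_id = feature_id,
                     t4cp_id = sel$T4CP$feature_id,
                     virb4_id = sel$VIRB4$feature_id,
                     mob_id = sel$MOB_F$feature_id,
                     start = lo, end = hi, span_bp = hi - lo + 1L)
    })
  cand <- cand[cand$span_bp <= max_window, , drop = FALSE]
  if (!nrow(cand)) return(tibble::tibble())
  key <- paste(cand$int_id, cand$t4cp_id, cand$virb4_id, cand$mob_id)
  cand <- cand[order(cand$start), , drop = FALSE]
  cand <- cand[!duplicated(key[order(cand$start)]), , drop = FALSE]

  cand <- cand[order(cand$span_bp, cand$start), , drop = FALSE]
  used <- character(0); keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    members <- c(cand$int_id[i], cand$t4cp_id[i], cand$virb4_id[i], cand$mob_id[i])
    if (!any(members %in% used)) { keep[i] <- TRUE; used <- c(used, members) }
  }
  cand <- cand[keep, , drop = FALSE][order(cand$start[keep]), , drop = FALSE]

  rep_ids <- purrr::map2(cand$start, cand$end, function(lo, hi) {
    reps$feature_id[reps$midpoint_bp >= lo & reps$midpoint_bp <= hi]
  })
  tibble::tibble(
    replicon_id = replicon$id,
    start = norm_start(cand$start, n, replicon$topology),
    end = norm_end(cand$start, cand$end, n, replicon$topology),
    span_bp = cand$span_bp, status = "T4SS_ICE",
    int_id = cand$int_id, tra_id = NA_character_,
    rep_ids = rep_ids, wraps_origin = cand$end > n & cand$start <= n,
    reject_reason = NA_character_,
    t4cp_id = cand$t4cp_id, virb4_id = cand$virb4_id, mob_id = cand$mob_id)
}

#' Classify a plasmid as an element in its excised form
#'
#' A plasmid carrying at least one integrase, one FtsK/SpoIIIE transfer gene
#' and one replication initiator anywhere on its sequence is the excised,
#' autonomously replicating form of an integrative element (no window
#' applies: the whole plasmid is the element). A conjugative plasmid without
#' an integrase yields no call.
#'
#' @param replicon A `Replicon` with `kind = "plasmid"`.
#' @param hits A [search_proteome()] table for the plasmid.
#' @param allow_rep_other Admit `REP_OTHER:*` replication families.
#' @return `"PLASMID_ICE"` or `NA_character_`.
#' @export
classify_plasmid <- function(replicon, hits, allow_rep_other = FALSE) {
  if (replicon$kind != "plasmid") {
    stop("classify_plasmid() expects a plasmid replicon", call. = FALSE)
  }
  h <- hits[hits$passed, , drop = FALSE]
  has_int <- any(h$role %in% INT_ROLES)
  has_tra <- any(h$role == "TRA")
  has_rep <- any(is_rep_role(h$role, allow_rep_other) & h$role != "REP_PP")
  if (has_int && has_tra && has_rep) "PLASMID_ICE" else NA_character_
}

#' Classify the module combination of a called region
#'
#' Labels the integrase type (tyrosine vs serine recombinase), the set of
#' replication module types found in the region (RepSA, RepAM, Prim-Pol,
#' RepPP partner genes, other Rep families) with a primary label chosen by
#' the priority RepSA > RepAM > Prim-Pol > RepOther, and the transfer type
#' (FtsK/SpoIIIE or T4SS).
#'
#' @param region One row of a region table.
#' @param hits The hit table for the replicon.
#' @return A tibble row: `integrase_type`, `replication_types`,
#'   `primary_rep`, `transfer_type`.
#' @export
classify_modules <- function(region, hits) {
  if (identical(region$status, "REJECTED")) {
    stop("cannot classify a rejected candidate", call. = FALSE)
  }
  h <- hits[hits$passed, , drop = FALSE]
  int_role <- h$role[h$feature_id == region$int_id & h$role %in% INT_ROLES][1L]
  integrase_type <- c(INT_TYR = "Int-Tyr", INT_SER = "Int-Ser")[[int_role]]

  region_ids <- h$feature_id[h$midpoint_bp >= region$start & h$midpoint_bp <= region$end]
  rep_ids <- unique(c(unlist(region$rep_ids), intersect(region_ids, h$feature_id[is_rep_role(h$role, TRUE)])))
  rep_roles <- unique(h$role[h$feature_id %in% rep_ids & is_rep_role(h$role, TRUE)])
  label <- function(r) {
    switch(r, REP_SA = "RepSA", REP_AM = "RepAM", PRIM_POL = "Prim-Pol",
           REP_PP = "RepPP", sub("^REP_OTHER:", "RepOther:", r))
  }
  rep_types <- vapply(rep_roles, label, character(1), USE.NAMES = FALSE)
  priority <- c("RepSA", "RepAM", "Prim-Pol", "RepPP")
  primary <- c(intersect(priority, rep_types), sort(rep_types))[1L]
  transfer <- if (identical(region$status, "T4SS_ICE")) "T4SS" else "FtsK/SpoIIIE"
  tibble::tibble(
    integrase_type = integrase_type,
    replication_types = list(sort(rep_types)),
    primary_rep = primary %||% NA_character_,
    transfer_type = transfer)
}

#' Call all elements on a replicon
#'
#' End-to-end region calling: candidate construction, integrase-order
#' exclusion, T4SS-type detection (a region matching both rules is reported
#' once, as `AICE`, with the T4SS genes recorded), remnant detection, and
#' module classification. Plasmids are classified as a whole instead of
#' windowed.
#'
#' @inheritParams find_candidate_regions
#' @return A region tibble with statuses `AICE`, `T4SS_ICE`, `REMNANT`,
#'   `REJECTED` or `PLASMID_ICE` plus module-combination columns.
#' @export
call_elements <- function(replicon, hits, max_window = 60000,
                          allow_rep_other = FALSE) {
  if (replicon$kind == "plasmid") {
    status <- classify_plasmid(replicon, hits, allow_rep_other)
    if (is.na(status)) return(empty_regions())
    h <- hits[hits$passed, , drop = FALSE]
    f <- replicon$features
    int_id <- h$feature_id[h$role %in% INT_ROLES][1L]
    tra_id <- h$feature_id[h$role == "TRA"][1L]
    rep_ids <- h$feature_id[is_rep_role(h$role, allow_rep_other) & h$role != "REP_PP"]
    region <- tibble::tibble(
      replicon_id = replicon$id, start = 1L, end = nchar(replicon$seq),
      span_bp = nchar(replicon$seq), status = status, int_id = int_id,
      tra_id = tra_id, rep_ids = list(rep_ids), wraps_origin = FALSE,
      reject_reason = NA_character_)
    return(dplyr::bind_cols(region, classify_modules(region[1L, ], hits)))
  }

  aice <- find_candidate_regions(replicon, hits, max_window, allow_rep_other)
  aice <- apply_order_filter(aice, replicon, hits)
  aice$status[aice$status == "CANDIDATE"] <- "AICE"

  t4ss <- detect_t4ss_ice(replicon, hits, max_window)
  if (nrow(t4ss)) {
    # a region satisfying both rules keeps the AICE status; record T4SS genes
    overlap <- vapply(seq_len(nrow(t4ss)), function(i) {
      any(aice$status == "AICE" & aice$start <= t4ss$end[i] & aice$end >= t4ss$start[i])
    }, logical(1))
    if (any(overlap)) {
      for (col in c("t4cp_id", "virb4_id", "mob_id")) {
        if (!col %in% names(aice)) aice[[col]] <- NA_character_
      }
      for (i in which(overlap)) {
        j <- which(aice$status == "AICE" & aice$start <= t4ss$end[i] &
                     aice$end >= t4ss$start[i])[1L]
        aice$t4cp_id[j] <- t4ss$t4cp_id[i]
        aice$virb4_id[j] <- t4ss$virb4_id[i]
        aice$mob_id[j] <- t4ss$mob_id[i]
      }
      t4ss <- t4ss[!overlap, , drop = FALSE]
    }
  }
  regions <- dplyr::bind_rows(aice, t4ss)
  remn <- detect_remnants(replicon, hits, regions, max_window, allow_rep_other)
  regions <- dplyr::bind_rows(regions, remn)
  regions <- regions[order(regions$start), , drop = FALSE]
  if (!nrow(regions)) return(regions)

  mods <- purrr::map_dfr(seq_len(nrow(regions)), function(i) {
    if (regions$status[i] %in% c("REJECTED", "REMNANT") ||
        is.na(regions$int_id[i])) {
      return(tibble::tibble(integrase_type = NA_character_,
                            replication_types = list(character(0)),
                            primary_rep = NA_character_,
                            transfer_type = NA_character_))
    }
    classify_modules(regions[i, ], hits)
  })
  dplyr::bind_cols(regions, mods)
}
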