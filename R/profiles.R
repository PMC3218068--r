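#' Build a position-specific protein profile from an alignment
#'
#' Columns whose residue occupancy (non-gap fraction) is at least
#' `occupancy_threshold` become match states. Per-state emissions are
#' pseudocounted log-odds in bits,
#' `log2(((count + pseudocount) / (n + 20 * pseudocount)) / background)`,
#' against the background residue frequencies of the whole alignment
#' (pseudocounted the same way). This mirrors how a custom replication
#' initiator profile is built from a trimmed multiple alignment of known
#' representatives before scanning proteomes.
#'
#' @param alignment Character vector of aligned, equal-length protein
#'   sequences (gap `-`), or a `Biostrings::AAStringSet`.
#' @param name Profile name (e.g. `"RepSA"` or a Pfam-style accession label).
#' @param role Functional role label: one of `INT_TYR`, `INT_SER`, `TRA`,
#'   `REP_SA`, `REP_AM`, `PRIM_POL`, `T4CP`, `VIRB4`, `MOB_F`, or
#'   `REP_OTHER:<family>`.
#' @param occupancy_threshold Minimum column occupancy for a match state.
#' @param pseudocount Additive pseudocount for emissions and background.
#' @param gap_open,gap_extend Affine gap penalties (bits) used when scoring.
#' @return A `ProfileModel` object.
#' @export
build_profile <- function(alignment, name, role,
                          occupancy_threshold = 0.5, pseudocount = 1,
                          gap_open = 4, gap_extend = 1) {
  if (methods::is(alignment, "AAStringSet")) alignment <- as.character(alignment)
  alignment <- toupper(unname(alignment))
  if (length(alignment) < 2L) stop("need >= 2 aligned sequences", call. = FALSE)
  if (length(unique(nchar(alignment))) != 1L) {
    stop("aligned sequences must have equal length", call. = FALSE)
  }
  mat <- do.call(rbind, strsplit(alignment, "", fixed = TRUE))
  n_seq <- nrow(mat)

  # Background = alignment residue frequencies smoothed half-and-half with
  # the uniform distribution: a residue absent from a small alignment must
  # not acquire a near-zero background (and thereby inflated log-odds at
  # every match state).
  counts_all <- table(factor(mat[mat %in% AA_ALPHABET], levels = AA_ALPHABET))
  background <- (as.numeric(counts_all) + sum(counts_all) / 20) /
    (2 * sum(counts_all))
  names(background) <- AA_ALPHABET

  occupancy <- colMeans(matrix(mat %in% AA_ALPHABET, nrow = n_seq))
  match_cols <- which(occupancy >= occupancy_threshold)
  if (!length(match_cols)) {
    stop("no alignment column reaches the occupancy threshold", call. = FALSE)
  }

  probs <- t(vapply(match_cols, function(j) {
    cnt <- table(factor(mat[, j][mat[, j] %in% AA_ALPHABET], levels = AA_ALPHABET))
    (as.numeric(cnt) + pseudocount) / (n_seq + 20 * pseudocount)
  }, numeric(20)))
  emissions <- log2(sweep(probs, 2L, background, `/`))
  colnames(emissions) <- AA_ALPHABET

  # consensus = most probable residue per column (ties resolved in alphabet
  # order); deliberately from the probabilities, not the log-odds, which can
  # rank a residue absent from a small alignment above an observed one
  consensus <- paste(AA_ALPHABET[apply(probs, 1L, which.max)], collapse = "")
  structure(
    list(name = name, role = role, emissions = emissions,
         consensus = consensus, background = background,
         gap_open = gap_open, gap_extend = gap_extend,
         occupancy_threshold = occupancy_threshold,
         pseudocount = pseudocount, threshold = NA_real_),
    class = "ProfileModel")
}

#' @export
print.ProfileModel <- function(x, ...) {
  cat(sprintf("<ProfileModel %s [%s]: %d match states, threshold %s bits>\n",
              x$name, x$role, nrow(x$emissions),
              if (is.na(x$threshold)) "uncalibrated" else format(round(x$threshold, 2))))
  invisible(x)
}

#' Score a protein against a profile
#'
#' Best semi-global alignment score (bits) of the profile's match states
#' against any substring of the protein, with affine gaps on both sides
#' (deleted states and inserted residues). Residues outside the aligned span
#' are free; `X`/unknown residues emit the background score 0.
#'
#' @param profile A [build_profile()] object.
#' @param protein Protein sequence (a trailing `*` is ignored).
#' @return A list with `score` (bits), `start` and `end` (1-based protein
#'   positions of the aligned span; 0/0 when all states are deleted).
#' @export
score_protein <- function(profile, protein) {
  protein <- sub("\\*$", "", toupper(protein))
  if (!nzchar(protein)) stop("empty protein sequence", call. = FALSE)
  profile_align_cpp(profile$emissions, encode_protein(protein),
                    profile$gap_open, profile$gap_extend)
}

#' Calibrate a score acceptance threshold from a shuffled null
#'
#' The null model scores shuffled copies of the profile consensus embedded in
#' random flanking sequence; embedding (rather than scoring the bare
#' 60-odd-residue decoy) gives the null the same alignment-offset
#' multiplicity as a genuine full-length protein, without which the maximum
#' over a large screened proteome would routinely exceed the calibrated
#' threshold. Each of the `n_shuffles` replicates is the maximum score of one
#' shuffled consensus over `n_contexts` random embeddings of total length
#' `null_len`; the threshold is the maximum replicate score plus `margin`.
#'
#' @param profile A `ProfileModel`.
#' @param n_shuffles Number of shuffled-consensus replicates (a value below
#'   10 triggers a warning).
#' @param seed Integer seed; the same seed reproduces the same threshold.
#' @param margin Bits added on top of the empirical null maximum.
#' @param n_contexts Random embeddings scored per replicate.
#' @param null_len Total decoy length per embedding.
#' @return The profile with its `threshold` field set (bits).
#' @export
calibrate_threshold <- function(profile, n_shuffles = 100, seed = 1,
                                margin = 2, n_contexts = 25, null_len = 600) {
  if (n_shuffles < 10) {
    warning("n_shuffles < 10: threshold calibration will be unstable", call. = FALSE)
  }
  cons <- strsplit(profile$consensus, "", fixed = TRUE)[[1]]
  m <- length(cons)
  len <- max(null_len, m + 20L)
  decoys <- withr::with_seed(seed, {
    unlist(lapply(seq_len(n_shuffles), function(i) {
      shuf <- paste(sample(cons), collapse = "")
      vapply(seq_len(n_contexts), function(j) {
        at <- sample.int(len - m + 1L, 1L)
        paste0(random_protein(at - 1L), shuf, random_protein(len - m - at + 1L))
      }, character(1))
    }))
  })
  scores <- profile_score_many_cpp(profile$emissions, lapply(decoys, encode_protein),
                                   profile$gap_open, profile$gap_extend)
  nulls <- vapply(seq_len(n_shuffles), function(i) {
    max(scores[((i - 1L) * n_contexts + 1L):(i * n_contexts)])
  }, numeric(1))
  profile$threshold <- max(nulls) + margin
  profile$null_scores <- nulls
  profile
}

#' Sample a protein from a profile
#'
#' Emits one residue per match state, drawn from the exponentiated emission
#' distribution (`background * 2^emission`, i.e. the pseudocounted column
#' probabilities). Used by the synthetic-genome generator to plant
#' recoverable module genes.
#'
#' @param profile A `ProfileModel`.
#' @param seed Integer seed (same seed, same sequence).
#' @return A protein string with one residue per match state.
#' @export
sample_profile <- function(profile, seed = 1) {
  probs <- sweep(2^profile$emissions, 2L, profile$background, `*`)
  withr::with_seed(seed, {
    paste(apply(probs, 1L, function(p) sample(AA_ALPHABET, 1L, prob = p)),
          collapse = "")
  })
}

#' Scan a replicon's proteome with a profile roster
#'
#' Scores every CDS translation against every profile and flags hits passing
#' the profile's calibrated threshold. A CDS may carry several roles; hits
#' carry the gene midpoint for downstream co-localization. CDS without a
#' translation are skipped (with a message).
#'
#' @param replicon A `Replicon` with CDS translations.
#' @param profiles A list of calibrated `ProfileModel`s (see
#'   [default_profile_set()]).
#' @param thresholds Optional named numeric vector overriding per-profile
#'   thresholds.
#' @return Tibble with columns `replicon_id`, `feature_id`, `profile`,
#'   `role`, `score_bits`, `threshold`, `passed`, `midpoint_bp`.
#' @export
search_proteome <- function(replicon, profiles, thresholds = NULL) {
  cds <- replicon$features[replicon$features$ftype == "CDS", , drop = FALSE]
  skipped <- is.na(cds$translation) | cds$translation == ""
  if (any(skipped)) {
    message(sum(skipped), " CDS without translation skipped on ", replicon$id)
    cds <- cds[!skipped, , drop = FALSE]
  }
  empty <- tibble::tibble(replicon_id = character(), feature_id = character(),
                          profile = character(), role = character(),
                          score_bits = double(), threshold = double(),
                          passed = logical(), midpoint_bp = integer())
  if (nrow(cds) == 0L || length(profiles) == 0L) return(empty)

  encoded <- lapply(sub("\\*$", "", cds$translation), encode_protein)
  mid <- as.integer((cds$start + cds$end) %/% 2L)

  purrr::map_dfr(profiles, function(p) {
    thr <- if (!is.null(thresholds) && p$name %in% names(thresholds)) {
      thresholds[[p$name]]
    } else {
      p$threshold
    }
    if (is.na(thr)) {
      stop("profile ", p$name, " has no calibrated threshold", call. = FALSE)
    }
    scores <- profile_score_many_cpp(p$emissions, encoded, p$gap_open, p$gap_extend)
    tibble::tibble(replicon_id = replicon$id, feature_id = cds$id,
                   profile = p$name, role = p$role, score_bits = scores,
                   threshold = thr, passed = scores >= thr, midpoint_bp = mid)
  })
}

#' Annotate putative partner replication genes next to Prim-Pol hits
#'
#' Primase-polymerase replication modules typically work as a small operon
#' with a downstream replication gene that has no dedicated domain profile.
#' Any CDS within at most one intervening gene of a passing `PRIM_POL` hit
#' (and within `max_gap` bp of it), carrying no passing hit of its own, is
#' annotated with role `REP_PP`.
#'
#' @param hits A [search_proteome()] table.
#' @param replicon The scanned `Replicon`.
#' @param max_gap Maximum bp between the Prim-Pol gene and the partner.
#' @return `hits` with `REP_PP` annotation rows appended.
#' @export
annotate_reppp <- function(hits, replicon, max_gap = 2000) {
  pp <- hits[hits$passed & hits$role == "PRIM_POL", , drop = FALSE]
  if (nrow(pp) == 0L) return(hits)
  cds <- replicon$features[replicon$features$ftype == "CDS", , drop = FALSE]
  cds <- cds[order(cds$start), , drop = FALSE]
  passing_ids <- unique(hits$feature_id[hits$passed])
  new_rows <- list()
  for (fid in unique(pp$feature_id)) {
    i <- match(fid, cds$id)
    if (is.na(i)) next
    nb <- setdiff(intersect(seq_len(nrow(cds)), (i - 2L):(i + 2L)), i)
    for (j in nb) {
      if (cds$id[j] %in% passing_ids) next
      if (interval_gap(cds$start[i], cds$end[i],
                       cds$start[j], cds$end[j]) > max_gap) next
      new_rows[[length(new_rows) + 1L]] <- tibble::tibble(
        replicon_id = replicon$id, feature_id = cds$id[j],
        profile = "RepPP_adjacent", role = "REP_PP",
        score_bits = NA_real_, threshold = NA_real_, passed = TRUE,
        midpoint_bp = as.integer((cds$start[j] + cds$end[j]) %/% 2L))
    }
  }
  if (!length(new_rows)) return(hits)
  dplyr::distinct(dplyr::bind_rows(hits, new_rows),
                  .data$feature_id, .data$profile, .keep_all = TRUE)
}

#' Serialize a profile to/from JSON
#'
#' A documented plain-JSON dialect: `name`, `role`, `alphabet`, `consensus`,
#' `gap_open`, `gap_extend`, `background`, `threshold`, and `emissions` as a
#' row-per-state array of 20 log-odds values.
#'
#' @param profile A `ProfileModel`.
#' @param path Output (input) file path.
#' @return `write_profile_json()` returns `path` invisibly;
#'   `read_profile_json()` returns a `ProfileModel`.
#' @export
write_profile_json <- function(profile, path) {
  obj <- list(name = profile$name, role = profile$role,
              alphabet = AA_ALPHABET, consensus = profile$consensus,
              gap_open = profile$gap_open, gap_extend = profile$gap_extend,
              background = unname(profile$background),
              threshold = profile$threshold,
              emissions = unname(apply(profile$emissions, 1L, c, simplify = FALSE)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_profile_json
#' @export
read_profile_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  emissions <- obj$emissions
  if (is.list(emissions)) emissions <- do.call(rbind, emissions)
  emissions <- matrix(as.numeric(emissions), ncol = 20L,
                      dimnames = list(NULL, AA_ALPHABET))
  structure(
    list(name = obj$name, role = obj$role, emissions = emissions,
         consensus = obj$consensus,
         background = setNames(obj$background, AA_ALPHABET),
         gap_open = obj$gap_open, gap_extend = obj$gap_extend,
         threshold = obj$threshold %||% NA_real_),
    class = "ProfileModel")
}
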