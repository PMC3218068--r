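# Independent oracles and small fixture builders shared across the suite.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

rand_protein <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")
rand_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# ---- exhaustive alignment enumeration (profile-scoring oracle) ----------
# Recursively enumerates every alignment of all match states against a
# substring of the protein under the same move set and affine costs as the
# DP: match, state deletion, residue insertion between consumed states,
# free flanks outside the aligned span.
enumerate_align_score <- function(emissions, prot_idx, gap_open, gap_extend) {
  m <- nrow(emissions)
  n <- length(prot_idx)
  rec <- function(i, j, prev) {
    if (i > m) return(0)
    out <- -Inf
    if (j <= n) {
      aa <- prot_idx[j]
      e <- if (aa >= 0L) emissions[i, aa + 1L] else 0
      out <- max(out, e + rec(i + 1L, j + 1L, "M"))
    }
    dcost <- if (prev == "D") gap_extend else gap_open
    out <- max(out, -dcost + rec(i + 1L, j, "D"))
    if (j <= n && i > 1L) {
      icost <- if (prev == "I") gap_extend else gap_open
      out <- max(out, -icost + rec(i, j + 1L, "I"))
    }
    out
  }
  max(vapply(0:n, function(f) rec(1L, f + 1L, "S"), numeric(1)))
}

# ---- O(n^2) direct-repeat oracle ----------------------------------------
# Full diagonal scan (no k-mer hashing) with an independently written
# implementation of the same canonical extension rule: rightward then
# leftward over raw match vectors, absorb an exact run when its length
# exceeds five times the mismatch gap and identity stays >= min_identity.
oracle_extend <- function(mv, a0, b0, min_identity, cost = 5L) {
  a <- a0; b <- b0
  L <- length(mv)
  repeat {
    j <- b + 1L
    while (j <= L && !mv[j]) j <- j + 1L
    if (j > L) break
    jend <- j
    while (jend < L && mv[jend + 1L]) jend <- jend + 1L
    gap <- j - b - 1L
    runlen <- jend - j + 1L
    newid <- sum(mv[a:jend]) / (jend - a + 1L)
    if (runlen <= cost * gap || newid < min_identity) break
    b <- jend
  }
  repeat {
    j <- a - 1L
    while (j >= 1L && !mv[j]) j <- j - 1L
    if (j < 1L) break
    jstart <- j
    while (jstart > 1L && mv[jstart - 1L]) jstart <- jstart - 1L
    gap <- a - j - 1L
    runlen <- j - jstart + 1L
    newid <- sum(mv[jstart:b]) / (b - jstart + 1L)
    if (runlen <= cost * gap || newid < min_identity) break
    a <- jstart
  }
  c(a, b)
}

brute_repeats <- function(s, min_len = 14, min_identity = 0.9, k = 12) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(ch)
  rows <- list()
  for (d in seq_len(n - min_len)) {
    L <- n - d
    if (L < min_len) next
    mv <- ch[seq_len(L)] == ch[seq_len(L) + d] & ch[seq_len(L)] != "N"
    if (!any(mv)) next
    # seed positions: starts of exact runs of length >= k
    r <- rle(mv)
    re <- cumsum(r$lengths)
    rs <- re - r$lengths + 1L
    seeds <- which(r$values & r$lengths >= k)
    if (!length(seeds)) next
    ivs <- unique(lapply(seeds, function(sr) {
      oracle_extend(mv, rs[sr], re[sr], min_identity)
    }))
    for (iv in ivs) {
      len <- iv[2L] - iv[1L] + 1L
      if (len < min_len || len > d) next
      ident <- mean(mv[iv[1L]:iv[2L]])
      if (ident < min_identity) next
      rows[[length(rows) + 1L]] <- c(iv[1L], iv[2L], d, len, ident)
    }
  }
  if (!length(rows)) {
    return(tibble::tibble(start1 = integer(), end1 = integer(),
                          start2 = integer(), end2 = integer(),
                          length = integer(), identity = double()))
  }
  m <- unique(do.call(rbind, rows))
  keep <- vapply(seq_len(nrow(m)), function(i) {
    !any(m[, 3] == m[i, 3] & m[, 1] <= m[i, 1] & m[, 2] >= m[i, 2] &
           m[, 4] > m[i, 4])
  }, logical(1))
  m <- m[keep, , drop = FALSE]
  out <- tibble::tibble(start1 = as.integer(m[, 1]), end1 = as.integer(m[, 2]),
                        start2 = as.integer(m[, 1] + m[, 3]),
                        end2 = as.integer(m[, 2] + m[, 3]),
                        length = as.integer(m[, 4]), identity = m[, 5])
  out[order(out$start1, out$start2), , drop = FALSE]
}

expect_same_repeats <- function(found, expected) {
  found <- found[order(found$start1, found$start2), , drop = FALSE]
  expected <- expected[order(expected$start1, expected$start2), , drop = FALSE]
  expect_equal(nrow(found), nrow(expected))
  if (nrow(found)) {
    expect_equal(found$start1, expected$start1)
    expect_equal(found$end1, expected$end1)
    expect_equal(found$start2, expected$start2)
    expect_equal(found$end2, expected$end2)
    expect_equal(found$identity, expected$identity, tolerance = 1e-12)
  }
}

# ---- clade-extraction oracle --------------------------------------------
# Enumerates internal nodes by walking the edge matrix directly (no
# phangorn), applies the three thresholds, keeps maximal clades.
brute_clades <- function(tree, min_size, max_diameter, min_support) {
  ntip <- length(tree$tip.label)
  dm <- ape::cophenetic.phylo(tree)
  tips_under <- function(node) {
    if (node <= ntip) return(tree$tip.label[node])
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, tips_under))
  }
  out <- list()
  for (node in (ntip + 1L):(ntip + tree$Nnode)) {
    tips <- tips_under(node)
    if (length(tips) < min_size) next
    if (max(dm[tips, tips]) > max_diameter) next
    supp <- tree$node.support[node - ntip]
    if (!(supp > min_support)) next
    out[[length(out) + 1L]] <- sort(tips)
  }
  if (!length(out)) return(list())
  maximal <- out[vapply(seq_along(out), function(i) {
    !any(vapply(seq_along(out), function(j) {
      j != i && length(out[[j]]) > length(out[[i]]) &&
        all(out[[i]] %in% out[[j]])
    }, logical(1)))
  }, logical(1))]
  unique(maximal)
}

# ---- toy replicon + hit-table builders ----------------------------------
# genes: tibble with id, start, end, role (NA for no hit), ftype
toy_replicon <- function(genes, length_bp = NULL, topology = "linear",
                         kind = "chromosome", seq = NULL) {
  length_bp <- length_bp %||% (max(genes$end) + 1000L)
  if (is.null(seq)) seq <- rand_dna(length_bp)
  ftype <- if ("ftype" %in% names(genes)) genes$ftype else rep("CDS", nrow(genes))
  feats <- tibble::tibble(
    id = genes$id, start = as.integer(genes$start), end = as.integer(genes$end),
    strand = "+", ftype = ftype, product = "x",
    translation = ifelse(ftype == "CDS", "MAAA", NA),
    trna_isotype = ifelse(ftype == "tRNA", "Lys", NA))
  new_replicon("toy", seq, features = feats, topology = topology, kind = kind)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

toy_hits <- function(replicon, roles) {
  # roles: named character vector feature_id -> role
  f <- replicon$features
  idx <- match(names(roles), f$id)
  tibble::tibble(
    replicon_id = replicon$id, feature_id = names(roles),
    profile = unname(roles), role = unname(roles),
    score_bits = 100, threshold = 10, passed = TRUE,
    midpoint_bp = as.integer((f$start[idx] + f$end[idx]) %/% 2L))
}

# small cached roster/simulation shared across test files
roster_cache <- new.env()
cached_profiles <- function() {
  if (is.null(roster_cache$p)) roster_cache$p <- default_profile_set()
  roster_cache$p
}
cached_sim <- function() {
  if (is.null(roster_cache$sim)) {
    roster_cache$sim <- simulate_genome(seed = 420, profiles = cached_profiles())
  }
  roster_cache$sim
}
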