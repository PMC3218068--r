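#' Parse a newick tree with bootstrap labels
#'
#' Wraps [ape::read.tree()]: internal node labels are read as bootstrap
#' support values (missing labels and missing branch lengths default to 0).
#'
#' @param newick_text Newick string (or a file path when `file = TRUE`).
#' @param file Treat `newick_text` as a path.
#' @return An [ape::phylo] tree; node supports in `$node.support`.
#' @export
parse_tree <- function(newick_text, file = FALSE) {
  tree <- if (file) ape::read.tree(newick_text) else ape::read.tree(text = newick_text)
  if (is.null(tree)) stop("malformed newick", call. = FALSE)
  if (is.null(tree$edge.length)) tree$edge.length <- rep(0, nrow(tree$edge))
  tree$edge.length[is.na(tree$edge.length)] <- 0
  supp <- suppressWarnings(as.numeric(tree$node.label))
  if (is.null(tree$node.label)) supp <- rep(0, tree$Nnode)
  supp[is.na(supp)] <- 0
  tree$node.support <- supp
  tree
}

#' Extract protein subfamilies from a bootstrapped tree
#'
#' A subfamily is a clade with at least `min_size` members, patristic
#' diameter (maximum leaf-to-leaf path length) at most `max_diameter`, and
#' bootstrap support strictly greater than `min_support`. Only maximal
#' qualifying clades are reported (a qualifying clade nested inside another
#' qualifying clade is absorbed). Unrooted trees are midpoint-rooted first.
#' The conventional cutoffs are a diameter of 1 for integrase and
#' replication-initiator trees and 2 for transfer-protein trees, with
#' support > 80 over 100 bootstrap replicates.
#'
#' @param tree A [parse_tree()] tree.
#' @param min_size Minimum clade size.
#' @param max_diameter Patristic diameter cutoff.
#' @param min_support Support threshold (strict inequality).
#' @param anchors Optional character vector of representative names; a
#'   subfamily is named after the first anchor among its members, else its
#'   lexicographically first member.
#' @return Tibble: `name`, `size`, `diameter`, `support`, `members`
#'   (list-column), sorted by decreasing size.
#' @export
extract_subfamilies <- function(tree, min_size = 4, max_diameter = 1,
                                min_support = 80, anchors = character(0)) {
  if (!ape::is.rooted(tree)) {
    message("unrooted tree: midpoint-rooting before clade enumeration")
    supp <- tree$node.support
    tree <- phangorn::midpoint(tree, node.labels = "label")
    supp2 <- suppressWarnings(as.numeric(tree$node.label))
    if (is.null(tree$node.label)) supp2 <- rep(0, tree$Nnode)
    supp2[is.na(supp2)] <- 0
    tree$node.support <- supp2
  }
  ntip <- length(tree$tip.label)
  dm <- ape::cophenetic.phylo(tree)
  clades <- candidate_clades(tree, min_size, max_diameter, min_support, dm)
  if (!nrow(clades)) {
    return(tibble::tibble(name = character(), size = integer(),
                          diameter = double(), support = double(),
                          members = list()))
  }
  # maximal clades only
  keep <- vapply(seq_len(nrow(clades)), function(i) {
    !any(vapply(seq_len(nrow(clades)), function(j) {
      j != i && all(clades$members[[i]] %in% clades$members[[j]]) &&
        length(clades$members[[j]]) > length(clades$members[[i]])
    }, logical(1)))
  }, logical(1))
  clades <- clades[keep, , drop = FALSE]
  clades$name <- vapply(clades$members, function(m) {
    hit <- anchors[anchors %in% m]
    if (length(hit)) hit[1L] else sort(m)[1L]
  }, character(1))
  clades <- clades[order(-clades$size, clades$name), , drop = FALSE]
  clades[, c("name", "size", "diameter", "support", "members")]
}

# every internal node satisfying the three thresholds
candidate_clades <- function(tree, min_size, max_diameter, min_support, dm) {
  ntip <- length(tree$tip.label)
  rows <- list()
  for (node in (ntip + 1L):(ntip + tree$Nnode)) {
    tips <- tree$tip.label[phangorn::Descendants(tree, node, "tips")[[1L]]]
    if (length(tips) < min_size) next
    diam <- max(dm[tips, tips])
    if (diam > max_diameter) next
    supp <- tree$node.support[node - ntip]
    if (!(supp > min_support)) next
    rows[[length(rows) + 1L]] <- tibble::tibble(
      size = length(tips), diameter = diam, support = supp, members = list(tips))
  }
  dplyr::bind_rows(tibble::tibble(size = integer(), diameter = double(),
                                  support = double(), members = list()), rows)
}

#' Neighbor-joining tree from pairwise p-distances
#'
#' Computes p-distances (mismatches over pairwise-comparable columns, gaps
#' excluded per pair) from an alignment and builds a neighbor-joining tree;
#' negative branch lengths are clamped to 0. A desk-scale fallback for
#' ingesting externally inferred maximum-likelihood trees.
#'
#' @param alignment Named character vector of aligned protein (or DNA)
#'   sequences, length >= 3.
#' @return An [ape::phylo] tree.
#' @export
p_distance_nj <- function(alignment) {
  if (length(alignment) < 3L) stop("need >= 3 sequences for NJ", call. = FALSE)
  if (is.null(names(alignment))) {
    names(alignment) <- paste0("seq", seq_along(alignment))
  }
  nj_tree(p_distance_matrix(alignment))
}

#' @describeIn p_distance_nj Neighbor-joining from a distance matrix
#'   (negative branch lengths clamped to 0).
#' @param dm Symmetric distance matrix with labelled rows/columns.
#' @export
nj_tree <- function(dm) {
  if (nrow(as.matrix(dm)) < 3L) stop("need >= 3 taxa for NJ", call. = FALSE)
  tree <- ape::nj(stats::as.dist(dm))
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}

p_distance_matrix <- function(alignment) {
  mat <- do.call(rbind, strsplit(toupper(alignment), "", fixed = TRUE))
  n <- nrow(mat)
  dm <- matrix(0, n, n, dimnames = list(names(alignment), names(alignment)))
  gap <- mat == "-" | mat == "."
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- !gap[i, ] & !gap[j, ]
      dm[i, j] <- dm[j, i] <-
        if (any(ok)) mean(mat[i, ok] != mat[j, ok]) else 0
    }
  }
  dm
}

#' Non-parametric bootstrap supports for the NJ tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree per
#' replicate and reports, for each internal edge of the reference tree, the
#' percentage of replicates containing the same bipartition.
#'
#' @param alignment As in [p_distance_nj()].
#' @param n Number of bootstrap replicates.
#' @param seed Integer seed (same seed, same supports).
#' @return The reference NJ tree with `$node.support` percentages (root
#'   node: 100).
#' @export
bootstrap_supports <- function(alignment, n = 100, seed = 1) {
  ref <- p_distance_nj(alignment)
  len <- unique(nchar(alignment))[1L]
  boots <- withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      cols <- sample.int(len, len, replace = TRUE)
      resampled <- vapply(strsplit(toupper(alignment), "", fixed = TRUE),
                          function(ch) paste(ch[cols], collapse = ""), character(1))
      p_distance_nj(resampled)
    })
  })
  counts <- ape::prop.clades(ref, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0
  ref$node.support <- 100 * counts / n
  ref$node.label <- as.character(ref$node.support)
  ref
}

#' Position frequency matrices for alignment motif windows
#'
#' Computes gap-excluded residue frequency matrices over column windows of
#' an alignment (suitable for sequence-logo rendering) and checks the two
#' hallmarks of rolling-circle replication initiators: a
#' His-hydrophobic-His (HUH) metal-binding pattern in the second window and
#' a majority-tyrosine catalytic column in the third.
#'
#' @param alignment Named character vector of aligned protein sequences.
#' @param motif_windows List of `c(start, end)` column ranges (typically
#'   three: motifs 1-3).
#' @return A list with one entry per window: `pfm` (residues x positions
#'   frequency matrix), plus `huh` (window 2) and `has_catalytic_tyr`
#'   (window 3) flags.
#' @export
motif_pfm <- function(alignment, motif_windows) {
  mat <- do.call(rbind, strsplit(toupper(alignment), "", fixed = TRUE))
  width <- ncol(mat)
  hydrophobic <- c("A", "V", "L", "I", "M", "F", "W", "C", "U")
  out <- purrr::imap(motif_windows, function(win, w) {
    if (win[1L] < 1L || win[2L] > width || win[1L] > win[2L]) {
      stop("motif window outside the alignment", call. = FALSE)
    }
    cols <- win[1L]:win[2L]
    pfm <- vapply(cols, function(j) {
      res <- mat[, j]
      res <- res[res %in% AA_ALPHABET]
      if (!length(res)) return(setNames(rep(0, 20), AA_ALPHABET))
      tab <- table(factor(res, levels = AA_ALPHABET))
      as.numeric(tab) / length(res)
    }, numeric(20))
    rownames(pfm) <- AA_ALPHABET
    colnames(pfm) <- paste0("col", cols)
    top <- AA_ALPHABET[apply(pfm, 2L, which.max)]
    entry <- list(pfm = pfm, window = win)
    if (w == 2L && length(cols) >= 3L) {
      huh <- FALSE
      for (j in seq_len(length(cols) - 2L)) {
        if (top[j] == "H" && top[j + 2L] == "H" && top[j + 1L] %in% hydrophobic) {
          huh <- TRUE
        }
      }
      entry$huh <- huh
    }
    if (w == 3L) entry$has_catalytic_tyr <- any(pfm["Y", ] > 0.5)
    entry
  })
  out
}
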