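#' Synthetic genomes with planted elements
#'
#' `simulate_genome()` emulates a high-G+C actinobacterial replicon:
#' background sequence at a target G+C, tRNA genes with a fixed canonical
#' 3'-end sequence, background CDS, planted integrative elements
#' (FtsK/SpoIIIE-type and T4SS-type, with attL/attR direct repeats
#' duplicating the tRNA 3' end, optional multi-attL, tandem,
#' circularly-permuted, serine-integrase and int-internal trap variants),
#' element remnants and decoys — together with a machine-readable truth
#' table so every pipeline stage can be scored without downloads.
#'
#' @name simulate_genome
NULL

# canonical tRNA 3'-terminal sequence (last 25 bp of every simulated tRNA;
# T-loop-like + discriminator + CCA)
TRNA_TERMINAL <- "GGTTCGAATCCCGGTACGGGCACCA"
TRNA_ISOTYPES <- c("Lys", "Arg", "Leu", "Met", "Thr", "Ser")

# codon choices per amino acid, bacterial code (table 11), stops excluded
codon_env <- new.env(parent = emptyenv())
codon_table <- function() {
  if (!is.null(codon_env$map)) return(codon_env$map)
  code <- Biostrings::getGeneticCode("11")
  code <- code[code != "*"]
  map <- split(names(code), unname(code))
  gc_frac <- lapply(map, function(cods) {
    vapply(strsplit(cods, ""), function(ch) sum(ch %in% c("G", "C")), numeric(1))
  })
  codon_env$map <- list(codons = map, n_gc = gc_frac)
  codon_env$map
}

# reverse-translate at a target G+C by weighting synonymous codons;
# per-amino-acid codon distributions are cached per G+C value. The
# weighting is calibrated so that, together with the biased amino-acid
# usage of biased_protein(), coding sequence realizes approximately the
# requested G+C (the amino acid fixes most of a codon's composition, so
# synonymous choice alone cannot reach high-G+C values).
reverse_translate <- function(protein, gc = 0.7) {
  key <- sprintf("gc%0.3f", gc)
  dist <- codon_env[[key]]
  if (is.null(dist)) {
    tab <- codon_table()
    lambda <- 6 * (2 * gc - 1)
    dist <- lapply(setNames(nm = names(tab$codons)), function(aa) {
      w <- exp(lambda * tab$n_gc[[aa]])
      list(codons = tab$codons[[aa]], cum = cumsum(w / sum(w)))
    })
    codon_env[[key]] <- dist
  }
  aas <- strsplit(protein, "", fixed = TRUE)[[1]]
  aas[!aas %in% names(dist)] <- "A"
  u <- stats::runif(length(aas))
  out <- character(length(aas))
  for (aa in unique(aas)) {
    idx <- aas == aa
    d <- dist[[aa]]
    out[idx] <- d$codons[findInterval(u[idx], d$cum) + 1L]
  }
  paste(out, collapse = "")
}

# random protein with the amino-acid usage of a genome at the given G+C
# (high-G+C organisms are Ala/Gly/Pro/Arg-rich); uniform at gc = 0.5
biased_protein <- function(n, gc = 0.5) {
  key <- sprintf("aa%0.3f", gc)
  w <- codon_env[[key]]
  if (is.null(w)) {
    tab <- codon_table()
    mean_ngc <- vapply(AA_ALPHABET, function(aa) {
      v <- tab$n_gc[[aa]]
      if (is.null(v)) 1.5 else mean(v)
    }, numeric(1))
    w <- exp(1.5 * (2 * gc - 1) * mean_ngc)
    codon_env[[key]] <- w
  }
  paste(sample(AA_ALPHABET, n, replace = TRUE, prob = w), collapse = "")
}

# an ORF with clean start/stop; translation carried alongside so annotation
# is independent of any translation code
make_gene <- function(id, protein, gc, product) {
  dna <- paste0("ATG", reverse_translate(protein, gc), "TGA")
  list(id = id, dna = dna, len = nchar(dna),
       translation = paste0("M", protein), product = product)
}

# a planted module gene must be a detectable family member: resample the
# emission draw until it scores clear of the profile's accept threshold
# (the lowest-information draws of a weak profile occasionally fall short)
sampled_core_protein <- function(profile, flank_min = 8L, flank_max = 20L) {
  for (try in seq_len(25L)) {
    core <- sample_profile(profile, seed = sample.int(2^30, 1L))
    if (is.na(profile$threshold) ||
        score_protein(profile, core)$score >= profile$threshold + 5) break
  }
  paste0(random_protein(sample(flank_min:flank_max, 1L)), core,
         random_protein(sample(flank_min:flank_max, 1L)))
}

# ---- element content assembly ------------------------------------------

# build the DNA content block of one planted item; returns dna, features
# (coordinates relative to the block) and relative positions of any repeat
# copies embedded in the block
build_content <- function(genes, gc, repeat_seq = NULL, lead_copies = 0L,
                          prefix_dna = NULL) {
  blocks <- character(0)
  feats <- list()
  rel_copies <- integer(0)
  pos <- 0L
  add_dna <- function(dna) {
    blocks[[length(blocks) + 1L]] <<- dna
    pos <<- pos + nchar(dna)
  }
  if (!is.null(prefix_dna)) add_dna(prefix_dna)
  if (lead_copies > 0L) {
    for (i in seq_len(lead_copies)) {
      rel_copies <- c(rel_copies, pos + 1L)
      add_dna(repeat_seq)
      add_dna(random_dna(sample(40:80, 1L), gc))
    }
  }
  for (g in genes) {
    if (identical(g$kind, "spacer")) {
      add_dna(random_dna(g$len, gc))
      next
    }
    if (identical(g$kind, "repeat")) {
      rel_copies <- c(rel_copies, pos + 1L)
      add_dna(repeat_seq)
      add_dna(random_dna(sample(40:80, 1L), gc))
      next
    }
    start <- pos + 1L
    add_dna(g$dna)
    feats[[length(feats) + 1L]] <- tibble::tibble(
      id = g$id, start = start, end = pos, strand = "+", ftype = "CDS",
      product = g$product, translation = g$translation,
      trna_isotype = NA_character_)
    add_dna(random_dna(sample(60:150, 1L), gc))
  }
  if (!is.null(repeat_seq)) {   # trailing attR copy
    rel_copies <- c(rel_copies, pos + 1L)
    add_dna(repeat_seq)
  }
  list(dna = paste(blocks, collapse = ""), len = pos,
       features = dplyr::bind_rows(empty_features(), feats),
       rel_copies = rel_copies)
}

spacer <- function(len) list(kind = "spacer", len = len)
repeat_marker <- function() list(kind = "repeat")

# gene roster for one element, by module-combination spec
element_genes <- function(eid, profiles, integrase = "Phage_integrase",
                          rep_type = "RepSA", order = "standard",
                          n_cargo = 6L, cargo_gc = 0.5, gc = 0.7) {
  g_int <- make_gene(paste0(eid, "_int"),
                     sampled_core_protein(profiles[[integrase]]), gc,
                     "site-specific recombinase")
  g_xis <- make_gene(paste0(eid, "_xis"), biased_protein(70L, gc), gc,
                     "recombination directionality factor")
  g_tra <- make_gene(paste0(eid, "_tra"),
                     sampled_core_protein(profiles[["FtsK_SpoIIIE"]]), gc,
                     "FtsK/SpoIIIE family DNA translocase")
  rep_profile <- switch(rep_type, RepSA = "RepSA", RepAM = "DUF3631",
                        `Prim-Pol` = "Prim-Pol", RepSA)
  g_rep <- make_gene(paste0(eid, "_rep"),
                     sampled_core_protein(profiles[[rep_profile]]), gc,
                     "replication initiator protein")
  reps <- list(g_rep)
  if (rep_type == "Prim-Pol") {
    reps <- c(reps, list(make_gene(paste0(eid, "_reppp"),
                                   biased_protein(120L, gc), gc,
                                   "putative replication protein")))
  }
  # a subset of cargo genes carries low-G+C sequence (recent acquisitions
  # from outside the high-G+C hosts)
  cargo <- lapply(seq_len(n_cargo), function(i) {
    cgc <- if (i <= ceiling(n_cargo / 3)) cargo_gc else gc
    make_gene(sprintf("%s_cargo%02d", eid, i),
              biased_protein(sample(120:350, 1L), cgc), cgc,
              "hypothetical protein")
  })
  # cargo is interspersed between the core genes (not appended after them)
  # so that both att sites stay close to the core gene span
  h <- length(cargo) %/% 2L
  c1 <- cargo[seq_len(h)]
  c2 <- cargo[setdiff(seq_along(cargo), seq_len(h))]
  switch(order,
    standard = c(list(g_int, g_xis), c1, reps, c2, list(g_tra)),
    permuted = c(list(g_int, g_tra), c1, reps, c2, list(g_xis)),
    trap = c(reps, c1, list(g_xis, g_int), c2, list(g_tra)),
    stop("unknown element gene order: ", order))
}

t4ss_genes <- function(eid, profiles, n_cargo = 4L, cargo_gc = 0.5, gc = 0.7) {
  core <- list(
    make_gene(paste0(eid, "_int"),
              sampled_core_protein(profiles[["Phage_integrase"]]), gc,
              "site-specific recombinase"),
    make_gene(paste0(eid, "_t4cp"),
              sampled_core_protein(profiles[["T4SS-DNA_transf"]]), gc,
              "type IV coupling protein"),
    make_gene(paste0(eid, "_virb4"),
              sampled_core_protein(profiles[["AAA_10"]]), gc,
              "VirB4-like conjugation ATPase"),
    make_gene(paste0(eid, "_mob"),
              sampled_core_protein(profiles[["TrwC"]]), gc,
              "MOB_F family relaxase"))
  cargo <- lapply(seq_len(n_cargo), function(i) {
    cgc <- if (i == 1L) cargo_gc else gc
    make_gene(sprintf("%s_cargo%02d", eid, i),
              biased_protein(sample(120:300, 1L), cgc), cgc,
              "hypothetical protein")
  })
  h <- length(cargo) %/% 2L
  c(core[1:2], cargo[seq_len(h)], core[3],
    cargo[setdiff(seq_along(cargo), seq_len(h))], core[4])
}

# make the bases flanking the repeat copies pairwise distinct so that the
# emitted maximal repeat is exactly the planted one (a coincidental match
# just outside a copy would otherwise extend the true repeat beyond the
# truth record). Only mutable positions are touched: every adjusted base
# lies in inserted spacer or intergenic background, never in a feature or
# a repeat copy.
distinct_flanks <- function(draft, copies) {
  seq <- draft$replicon$seq
  k <- length(copies)
  base_at <- function(p) substr(seq, p, p)
  # two offsets per side: with both flanking bases mismatched, the repeat
  # finder's gain rule would need an 11-base chance run to creep outward,
  # which has negligible probability even in high-G+C sequence
  for (off in 1:2) {
    # prev side: copy 1 keeps its bases, later copies must differ
    seen <- base_at(copies[[1L]][1L] - off)
    for (i in seq_len(k)[-1L]) {
      p <- copies[[i]][1L] - off
      if (base_at(p) %in% seen) {
        substr(seq, p, p) <- setdiff(c("A", "C", "G", "T"), seen)[1L]
      }
      seen <- c(seen, base_at(p))
    }
    # next side: last copy keeps its bases, earlier copies must differ
    seen <- base_at(copies[[k]][2L] + off)
    for (i in seq_len(k - 1L)) {
      p <- copies[[i]][2L] + off
      if (base_at(p) %in% seen) {
        substr(seq, p, p) <- setdiff(c("A", "C", "G", "T"), seen)[1L]
      }
      seen <- c(seen, base_at(p))
    }
  }
  draft$replicon$seq <- seq
  draft
}

# ---- draft manipulation -------------------------------------------------

# insert a content block immediately after position `at`, shifting all
# downstream coordinates (features, truth records, planted intervals)
insert_content <- function(draft, at, content) {
  len <- content$len
  seq <- draft$replicon$seq
  draft$replicon$seq <- paste0(substr(seq, 1L, at), content$dna,
                               substr(seq, at + 1L, nchar(seq)))
  shift <- function(x) ifelse(x > at, x + len, x)
  f <- draft$replicon$features
  f$start <- shift(f$start); f$end <- shift(f$end)
  newf <- content$features
  if (nrow(newf)) {
    newf$start <- newf$start + at
    newf$end <- newf$end + at
  }
  draft$replicon$features <- dplyr::bind_rows(f, newf)
  draft$replicon$features <-
    draft$replicon$features[order(draft$replicon$features$start), , drop = FALSE]
  if (nrow(draft$truth)) {
    for (col in intersect(names(draft$truth),
                          c("start", "end", "attL_start", "attL_end",
                            "attL2_start", "attL2_end", "attR_start", "attR_end"))) {
      draft$truth[[col]] <- shift(draft$truth[[col]])
    }
  }
  draft$planted <- lapply(draft$planted, function(iv) {
    c(shift(iv[1L]), shift(iv[2L]))
  })
  draft$planted_partial <- lapply(draft$planted_partial, function(iv) {
    c(shift(iv[1L]), shift(iv[2L]))
  })
  draft
}

new_truth_row <- function(...) {
  defaults <- list(id = NA_character_, kind = NA_character_,
                   expected_status = NA_character_,
                   start = NA_integer_, end = NA_integer_,
                   attL_start = NA_integer_, attL_end = NA_integer_,
                   attL2_start = NA_integer_, attL2_end = NA_integer_,
                   attR_start = NA_integer_, attR_end = NA_integer_,
                   repeat_len = NA_integer_, circle_lens = list(integer(0)),
                   integrase_type = NA_character_,
                   rep_types = list(character(0)),
                   transfer_type = NA_character_, tandem = FALSE,
                   multi_attl = FALSE, anchor_trna = NA_character_)
  args <- list(...)
  defaults[names(args)] <- args
  tibble::as_tibble(defaults)
}

# pick an insertion anchor: the 3' end of an unused tRNA (tRNA-anchored
# items) or an intergenic position, at least `spacing` bp from every
# previously planted item. Placement is stratified: each item aims at a
# pre-assigned target position (evenly spread over the genome) so that the
# spacing constraint stays satisfiable.
pick_anchor <- function(draft, use_trna, spacing, target = NULL,
                        partial = FALSE) {
  f <- draft$replicon$features
  n <- nchar(draft$replicon$seq)
  if (is.null(target)) target <- sample.int(n - 2000L, 1L) + 1000L
  clear_of <- function(pos, intervals, dist) {
    all(vapply(intervals, function(iv) {
      min(abs(pos - iv[1L]), abs(pos - iv[2L])) > dist &&
        !(pos >= iv[1L] && pos <= iv[2L])
    }, logical(1)))
  }
  far_enough <- function(pos) {
    clear_of(pos, draft$planted, draft$near_spacing) &&
      (!partial || clear_of(pos, draft$planted_partial, spacing))
  }
  if (use_trna) {
    trnas <- f[f$ftype == "tRNA" & !f$id %in% draft$used_trnas, , drop = FALSE]
    trnas <- trnas[order(abs(trnas$end - target)), , drop = FALSE]
    for (i in seq_len(nrow(trnas))) {
      if (far_enough(trnas$end[i])) {
        return(list(at = trnas$end[i], trna = trnas[i, ]))
      }
    }
    stop("cannot place element: no free tRNA anchor respects the spacing; ",
         "reduce the number of planted items or enlarge the genome",
         call. = FALSE)
  }
  for (try in seq_len(400L)) {
    jitter <- sample.int(10000L, 1L) - 5000L
    pos <- min(n - 1000L, max(1000L, target + jitter * ((try + 3L) %/% 4L)))
    inside <- any(f$start <= pos & f$end >= pos)
    if (!inside && far_enough(pos)) return(list(at = pos, trna = NULL))
  }
  stop("cannot place item: genome capacity exceeded for the requested spacing",
       call. = FALSE)
}

#' Plant one element into a genome draft
#'
#' Inserts a synthetic integrative element at the 3' end of a tRNA gene
#' (duplicating the tRNA terminal sequence as the attL/attR direct repeat)
#' or, for the serine-integrase variant, at a random position between two
#' copies of a random repeat. Supported variants: `"standard"`
#' (att-int-xis-rep-tra-cargo-att, integrase adjacent to the tRNA-anchored
#' att), `"permuted"` (transfer gene ahead of the replication gene),
#' `"serine"` (serine integrase, no tRNA target), `"trap"` (integrase
#' strictly between rep and tra; expected to be rejected), `"multi_attl"`
#' (an extra internal attL copy giving two excision circles) and
#' `"tandem_pair"` (two elements sharing an att copy, excising
#' independently and associatively).
#'
#' @param draft A genome draft from [simulate_genome()] internals (list with
#'   `replicon`, `truth`, `planted`, `used_trnas`, `profiles`).
#' @param spec List: `kind` (`"aice"`/`"t4ss"`), `variant`, `rep_type`
#'   (`"RepSA"`, `"RepAM"`, `"Prim-Pol"`), `att_len`, `n_cargo`, `cargo_gc`.
#' @param seed Integer seed.
#' @return The modified draft; the new truth rows are appended to
#'   `draft$truth`.
#' @export
plant_element <- function(draft, spec = list(), seed = 1) {
  withr::with_seed(seed, plant_element_impl(draft, spec))
}

plant_element_impl <- function(draft, spec) {
  kind <- spec$kind %||% "aice"
  variant <- spec$variant %||% "standard"
  att_len <- as.integer(spec$att_len %||% 50L)
  n_cargo <- as.integer(spec$n_cargo %||% 6L)
  cargo_gc <- spec$cargo_gc %||% 0.5
  rep_type <- spec$rep_type %||% "RepSA"
  target <- spec$target
  gc <- spec$gc %||% draft$gc
  spacing <- spec$spacing %||% draft$spacing
  profiles <- draft$profiles
  eid <- sprintf("elem%02d", nrow(draft$truth) + 1L)

  if (att_len < 14L && !identical(variant, "trap")) {
    warning("att repeat shorter than the default detector minimum (14 bp): ",
            "the element may be reported unbounded", call. = FALSE)
  }

  if (variant == "serine") {
    anchor <- pick_anchor(draft, use_trna = FALSE, spacing = spacing, target = target)
    repeat_seq <- random_dna(att_len, gc)
    genes <- element_genes(eid, profiles, integrase = "Recombinase",
                           rep_type = rep_type, order = "standard",
                           n_cargo = n_cargo, cargo_gc = cargo_gc, gc = gc)
    content <- build_content(c(list(spacer(10L)), genes), gc,
                             repeat_seq = repeat_seq, lead_copies = 1L)
    draft2 <- insert_content(draft, anchor$at, content)
    attL_start <- anchor$at + content$rel_copies[1L]
    attR_start <- anchor$at + content$rel_copies[2L]
    draft2 <- distinct_flanks(draft2, list(
      c(attL_start, attL_start + att_len - 1L),
      c(attR_start, attR_start + att_len - 1L)))
    truth <- new_truth_row(
      id = eid, kind = "aice", expected_status = "AICE",
      start = attL_start, end = attR_start + att_len - 1L,
      attL_start = attL_start, attL_end = attL_start + att_len - 1L,
      attR_start = attR_start, attR_end = attR_start + att_len - 1L,
      repeat_len = att_len,
      circle_lens = list(attR_start + att_len - 1L - (attL_start + att_len - 1L)),
      integrase_type = "Int-Ser", rep_types = list(rep_type),
      transfer_type = "FtsK/SpoIIIE")
    draft2$truth <- dplyr::bind_rows(draft2$truth, truth)
    draft2$planted <- c(draft2$planted, list(c(truth$start, truth$end)))
    return(draft2)
  }

  anchor <- pick_anchor(draft, use_trna = TRUE, spacing = spacing, target = target)
  t_end <- anchor$at
  repeat_seq <- substr(draft$replicon$seq, t_end - att_len + 1L, t_end)

  if (variant == "tandem_pair") {
    make_interior <- function(sub_eid) {
      genes <- element_genes(sub_eid, profiles, rep_type = rep_type,
                            order = "standard", n_cargo = max(2L, n_cargo - 3L),
                            cargo_gc = cargo_gc, gc = gc)
      build_content(c(list(spacer(10L)), genes), gc, repeat_seq = repeat_seq)
    }
    c1 <- make_interior(paste0(eid, "a"))
    c2 <- make_interior(paste0(eid, "b"))
    combined <- list(dna = paste0(c1$dna, c2$dna), len = c1$len + c2$len,
                     features = {
                       f2 <- c2$features
                       f2$start <- f2$start + c1$len; f2$end <- f2$end + c1$len
                       dplyr::bind_rows(c1$features, f2)
                     },
                     rel_copies = c(c1$rel_copies, c1$len + c2$rel_copies))
    draft2 <- insert_content(draft, t_end, combined)
    attL1 <- c(t_end - att_len + 1L, t_end)
    attM <- c(t_end + c1$len - att_len + 1L, t_end + c1$len)       # shared copy
    attR2 <- c(t_end + combined$len - att_len + 1L, t_end + combined$len)
    draft2 <- distinct_flanks(draft2, list(attL1, attM, attR2))
    th1 <- new_truth_row(
      id = paste0(eid, "a"), kind = "aice", expected_status = "AICE",
      start = attL1[1L], end = attM[2L],
      attL_start = attL1[1L], attL_end = attL1[2L],
      attR_start = attM[1L], attR_end = attM[2L], repeat_len = att_len,
      circle_lens = list(attM[2L] - attL1[2L]),
      integrase_type = "Int-Tyr", rep_types = list(rep_type),
      transfer_type = "FtsK/SpoIIIE", tandem = TRUE,
      anchor_trna = anchor$trna$id)
    th2 <- new_truth_row(
      id = paste0(eid, "b"), kind = "aice", expected_status = "AICE",
      start = attM[1L], end = attR2[2L],
      attL_start = attM[1L], attL_end = attM[2L],
      attR_start = attR2[1L], attR_end = attR2[2L], repeat_len = att_len,
      circle_lens = list(attR2[2L] - attM[2L]),
      integrase_type = "Int-Tyr", rep_types = list(rep_type),
      transfer_type = "FtsK/SpoIIIE", tandem = TRUE,
      anchor_trna = anchor$trna$id)
    draft2$truth <- dplyr::bind_rows(draft2$truth, th1, th2)
    draft2$planted <- c(draft2$planted, list(c(attL1[1L], attR2[2L])))
    draft2$used_trnas <- c(draft2$used_trnas, anchor$trna$id)
    return(draft2)
  }

  if (kind == "t4ss") {
    genes <- t4ss_genes(eid, profiles, n_cargo = max(2L, n_cargo - 2L),
                        cargo_gc = cargo_gc, gc = gc)
    expected <- "T4SS_ICE"
    integrase_type <- "Int-Tyr"; rep_types <- character(0)
    transfer <- "T4SS"
  } else {
    order <- switch(variant, standard = "standard", multi_attl = "standard",
                    permuted = "permuted", trap = "trap", "standard")
    genes <- element_genes(eid, profiles, rep_type = rep_type, order = order,
                           n_cargo = n_cargo, cargo_gc = cargo_gc, gc = gc)
    expected <- if (variant == "trap") "REJECTED" else "AICE"
    integrase_type <- "Int-Tyr"
    rep_types <- if (rep_type == "Prim-Pol") c("Prim-Pol", "RepPP") else rep_type
    transfer <- "FtsK/SpoIIIE"
  }

  prefix <- NULL; lead <- 0L
  if (variant == "multi_attl") {
    # internal attL2 ~1.4 kb downstream of attL so that the integrase stays
    # within anchoring distance of the tRNA for both pair choices
    prefix <- random_dna(1400L, gc)
    lead <- 1L
  }
  content <- build_content(c(list(spacer(10L)), genes), gc,
                           repeat_seq = repeat_seq, lead_copies = lead,
                           prefix_dna = prefix)
  draft2 <- insert_content(draft, t_end, content)
  copies <- t_end + content$rel_copies
  attL <- c(t_end - att_len + 1L, t_end)
  attR <- c(copies[length(copies)], copies[length(copies)] + att_len - 1L)
  all_copies <- c(list(attL),
                  lapply(copies, function(p) c(p, p + att_len - 1L)))
  draft2 <- distinct_flanks(draft2, all_copies)
  circle_all <- attR[2L] - attL[2L]
  truth <- new_truth_row(
    id = eid, kind = kind, expected_status = expected,
    start = attL[1L], end = attR[2L],
    attL_start = attL[1L], attL_end = attL[2L],
    attR_start = attR[1L], attR_end = attR[2L], repeat_len = att_len,
    circle_lens = list(circle_all),
    integrase_type = integrase_type, rep_types = list(rep_types),
    transfer_type = transfer, anchor_trna = anchor$trna$id,
    multi_attl = identical(variant, "multi_attl"))
  if (variant == "multi_attl") {
    attL2 <- c(copies[1L], copies[1L] + att_len - 1L)
    truth$attL2_start <- attL2[1L]; truth$attL2_end <- attL2[2L]
    truth$circle_lens <- list(c(circle_all, attR[2L] - attL2[2L]))
  }
  draft2$truth <- dplyr::bind_rows(draft2$truth, truth)
  draft2$planted <- c(draft2$planted, list(c(truth$start, truth$end)))
  draft2$used_trnas <- c(draft2$used_trnas, anchor$trna$id)
  draft2
}

#' Plant decoys into a genome draft
#'
#' Decoys exercise the exclusion rules: `lone_ftsk` (a single chromosomal
#' FtsK/SpoIIIE gene far from any element), `prophage_int_only` (an
#' integrase with cargo but no transfer/replication module),
#' `remnant_two_of_three` (integrase + replication gene but no transfer
#' gene; the expected call is `REMNANT`), and `random_repeat_pair` (a
#' duplicated 50-mer with no genes nearby). None satisfies the full element
#' rule.
#'
#' @param draft Genome draft.
#' @param kinds Character vector of decoy kinds (above).
#' @param seed Integer seed.
#' @return The modified draft with truth rows of `expected_status`
#'   `"none"` or `"REMNANT"`.
#' @export
plant_decoys <- function(draft, kinds, seed = 1, targets = NULL) {
  withr::with_seed(seed, {
    for (i in seq_along(kinds)) {
      draft <- plant_decoy_impl(draft, kinds[i],
                                if (is.null(targets)) NULL else targets[i])
    }
    draft
  })
}

plant_decoy_impl <- function(draft, kind, target = NULL) {
  gc <- draft$gc
  profiles <- draft$profiles
  did <- sprintf("decoy%02d", nrow(draft$truth) + 1L)
  genes <- switch(kind,
    lone_ftsk = list(make_gene(paste0(did, "_ftsk"),
                               sampled_core_protein(profiles[["FtsK_SpoIIIE"]]),
                               gc, "cell division protein FtsK")),
    prophage_int_only = c(
      list(make_gene(paste0(did, "_int"),
                     sampled_core_protein(profiles[["Phage_integrase"]]), gc,
                     "prophage integrase")),
      lapply(1:3, function(i) make_gene(sprintf("%s_orf%d", did, i),
                                        biased_protein(sample(100:250, 1L), gc),
                                        gc, "phage protein"))),
    remnant_two_of_three = list(
      make_gene(paste0(did, "_int"),
                sampled_core_protein(profiles[["Phage_integrase"]]), gc,
                "site-specific recombinase"),
      make_gene(paste0(did, "_xis"), biased_protein(70L, gc), gc,
                "recombination directionality factor"),
      make_gene(paste0(did, "_rep"),
                sampled_core_protein(profiles[["RepSA"]]), gc,
                "replication initiator protein")),
    random_repeat_pair = NULL,
    stop("unknown decoy kind: ", kind))

  if (kind == "random_repeat_pair") {
    anchor <- pick_anchor(draft, use_trna = FALSE, spacing = 10000L, target = target)
    rep_seq <- random_dna(50L, gc)
    content <- list(dna = paste0(rep_seq, random_dna(3000L, gc), rep_seq),
                    len = 100L + 3000L, features = empty_features(),
                    rel_copies = c(1L, 3051L))
    draft2 <- insert_content(draft, anchor$at, content)
    truth <- new_truth_row(id = did, kind = kind, expected_status = "none",
                           start = anchor$at + 1L, end = anchor$at + content$len)
    draft2$truth <- dplyr::bind_rows(draft2$truth, truth)
    return(draft2)
  }

  anchor <- pick_anchor(draft, use_trna = FALSE, spacing = draft$spacing,
                        target = target, partial = TRUE)
  content <- build_content(c(list(spacer(10L)), genes), gc)
  draft2 <- insert_content(draft, anchor$at, content)
  expected <- if (kind == "remnant_two_of_three") "REMNANT" else "none"
  truth <- new_truth_row(id = did, kind = kind, expected_status = expected,
                         start = anchor$at + 1L, end = anchor$at + content$len)
  draft2$truth <- dplyr::bind_rows(draft2$truth, truth)
  draft2$planted <- c(draft2$planted, list(c(truth$start, truth$end)))
  draft2$planted_partial <- c(draft2$planted_partial,
                              list(c(truth$start, truth$end)))
  draft2
}

#' @describeIn simulate_genome Generate one synthetic replicon plus truth.
#'
#' @param config Named list overriding the defaults: `length` (background bp,
#'   500000), `gc` (0.70), `topology` (`"circular"`), `kind`
#'   (`"chromosome"`), `n_trna` (10), `n_background_cds` (200), `n_aice`
#'   (2), `n_t4ss` (1), `n_remnant` (1), `decoys`
#'   (`lone_ftsk`, `prophage_int_only`, `random_repeat_pair`), `att_len`
#'   (50), `n_cargo` (6), `cargo_gc` (0.5), `spacing` (61000, minimum bp
#'   between planted items so that windowed detection cannot chain them),
#'   `aice_variants` (recycled over planted elements; `"standard"`),
#'   `rep_types` (recycled; `"RepSA"`).
#' @param seed Integer seed; the same seed reproduces byte-identical
#'   sequence, annotation and truth.
#' @param out_dir Optional directory: writes `<id>.fasta`, `<id>.gff3`,
#'   `<id>_truth.json` and a metadata row `<id>_meta.tsv`.
#' @param profiles Profile roster used to sample module proteins
#'   (default [default_profile_set()]).
#' @return List with `replicon`, `truth` (tibble) and `files` (paths or
#'   `NULL`).
#' @export
simulate_genome <- function(config = list(), seed = 1, out_dir = NULL,
                            profiles = default_profile_set()) {
  cfg <- utils::modifyList(list(
    id = sprintf("syn%04d", seed %% 10000L),
    length = 500000L, gc = 0.70, topology = "circular", kind = "chromosome",
    n_trna = NULL, n_background_cds = NULL,
    n_aice = 2L, n_t4ss = 1L, n_remnant = 1L,
    decoys = c("lone_ftsk", "prophage_int_only", "random_repeat_pair"),
    att_len = 50L, n_cargo = 6L, cargo_gc = 0.5, spacing = 61000L,
    near_spacing = 12000L,
    aice_variants = "standard", rep_types = "RepSA",
    suborder = "Frankineae", genus = "Frankia", niche = "plant",
    genome_class = "complete"), config)
  # gene complement scales with the replicon unless set explicitly
  # (~1 CDS / 2.5 kb, ~1 tRNA / 50 kb)
  if (is.null(cfg$n_background_cds)) {
    cfg$n_background_cds <- max(20L, as.integer(round(cfg$length / 2500)))
  }
  if (is.null(cfg$n_trna)) {
    cfg$n_trna <- max(3L, as.integer(round(cfg$length / 50000)))
  }

  n_partial <- cfg$n_remnant + sum(cfg$decoys %in%
                                     c("lone_ftsk", "prophage_int_only"))
  n_items <- cfg$n_aice + cfg$n_t4ss + n_partial
  if ((n_partial > 1L && (n_partial - 1L) * cfg$spacing > 0.84 * cfg$length) ||
      (n_items > 1L && (n_items - 1L) * cfg$near_spacing + 10000L > cfg$length)) {
    stop("requested items cannot respect the spacing on a genome of ",
         cfg$length, " bp", call. = FALSE)
  }

  draft <- withr::with_seed(seed, build_background(cfg))
  draft$profiles <- profiles

  # Anchor targets by item class. Partial items (remnants and gene-bearing
  # decoys) must sit pairwise >= `spacing` apart, so they take maximally
  # spread positions; full elements only need the small mutual buffer and
  # interleave between them.
  n_elem <- cfg$n_aice + cfg$n_t4ss
  partial_kinds <- c(rep("remnant_two_of_three", cfg$n_remnant),
                     cfg$decoys[cfg$decoys != "random_repeat_pair"])
  np <- length(partial_kinds)
  partial_targets <- if (np == 1L) {
    round(cfg$length / 2)
  } else if (np > 1L) {
    round(0.08 * cfg$length + (seq_len(np) - 1L) / (np - 1L) * 0.84 * cfg$length)
  } else {
    integer(0)
  }
  elem_targets <- if (n_elem) {
    round((seq_len(n_elem) - 0.5) * cfg$length / n_elem)
  } else {
    integer(0)
  }
  elem_targets <- withr::with_seed(seed * 7L + 3L, sample(elem_targets))

  item_seed <- function(i) (seed * 131L + i * 7919L) %% .Machine$integer.max
  k <- 0L
  variants <- rep(cfg$aice_variants, length.out = cfg$n_aice)
  rep_types <- rep(cfg$rep_types, length.out = cfg$n_aice)
  for (i in seq_len(cfg$n_aice)) {
    k <- k + 1L
    draft <- plant_element(draft, list(
      kind = "aice", variant = variants[i], rep_type = rep_types[i],
      att_len = cfg$att_len, n_cargo = cfg$n_cargo, cargo_gc = cfg$cargo_gc,
      target = elem_targets[k]),
      seed = item_seed(k))
  }
  for (i in seq_len(cfg$n_t4ss)) {
    k <- k + 1L
    draft <- plant_element(draft, list(kind = "t4ss", att_len = cfg$att_len,
                                       n_cargo = cfg$n_cargo,
                                       cargo_gc = cfg$cargo_gc,
                                       target = elem_targets[k]),
                           seed = item_seed(k))
  }
  if (np > 0L) {
    draft <- plant_decoys(draft, partial_kinds, seed = item_seed(k + 1L),
                          targets = partial_targets)
    k <- k + np
  }
  if ("random_repeat_pair" %in% cfg$decoys) {
    k <- k + 1L
    draft <- plant_decoys(draft, "random_repeat_pair", seed = item_seed(k))
  }

  replicon <- draft$replicon
  replicon$meta <- list(suborder = cfg$suborder, genus = cfg$genus,
                        niche = cfg$niche,
                        genome_size_bp = nchar(replicon$seq))
  files <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    fasta <- file.path(out_dir, paste0(cfg$id, ".fasta"))
    gff <- file.path(out_dir, paste0(cfg$id, ".gff3"))
    truth_path <- file.path(out_dir, paste0(cfg$id, "_truth.json"))
    meta_path <- file.path(out_dir, paste0(cfg$id, "_meta.tsv"))
    write_replicon(replicon, fasta, gff)
    jsonlite::write_json(draft$truth, truth_path, auto_unbox = FALSE,
                         digits = NA, na = "null", pretty = TRUE)
    readr::write_tsv(tibble::tibble(
      replicon_id = replicon$id, suborder = cfg$suborder, genus = cfg$genus,
      niche = cfg$niche, genome_size_bp = nchar(replicon$seq),
      topology = cfg$topology, kind = cfg$kind,
      genome_class = cfg$genome_class), meta_path)
    files <- list(fasta = fasta, gff = gff, truth = truth_path,
                  meta = meta_path)
  }
  list(replicon = replicon, truth = draft$truth, files = files)
}

# background replicon: tRNAs spread evenly (with jitter), background CDS at
# random slots, intergenic G+C solved so the whole sequence hits the target
build_background <- function(cfg) {
  n_genes <- cfg$n_background_cds
  orfs <- lapply(seq_len(n_genes), function(i) {
    make_gene(sprintf("bg_cds_%04d", i),
              biased_protein(sample(150:400, 1L), cfg$gc), cfg$gc,
              "hypothetical protein")
  })
  trna_bodies <- lapply(seq_len(cfg$n_trna), function(i) {
    list(id = sprintf("trna_%02d", i),
         dna = paste0(random_dna(51L, cfg$gc), TRNA_TERMINAL),
         isotype = TRNA_ISOTYPES[(i - 1L) %% length(TRNA_ISOTYPES) + 1L])
  })
  gene_len <- sum(vapply(orfs, `[[`, integer(1), "len")) +
    cfg$n_trna * 76L
  inter_total <- cfg$length - gene_len
  if (inter_total < (n_genes + cfg$n_trna + 1L) * 20L) {
    stop("genome too short for the requested gene complement", call. = FALSE)
  }
  # solve the intergenic G+C so the overall background hits the target
  orf_gc_count <- sum(vapply(orfs, function(g) {
    stringr::str_count(g$dna, "[GC]")
  }, integer(1))) + sum(vapply(trna_bodies, function(t) {
    stringr::str_count(t$dna, "[GC]")
  }, integer(1)))
  inter_gc <- (cfg$gc * cfg$length - orf_gc_count) / inter_total
  inter_gc <- min(0.95, max(0.05, inter_gc))

  slots <- n_genes + cfg$n_trna
  # even tRNA spread with jitter, CDS in the remaining slots
  trna_slots <- unique(pmin(slots, pmax(1L, round(seq(1L, slots, length.out = cfg$n_trna)) +
                                          sample(-2:2, cfg$n_trna, replace = TRUE))))
  while (length(trna_slots) < cfg$n_trna) {
    trna_slots <- unique(c(trna_slots, sample.int(slots, 1L)))
  }
  gaps <- as.vector(stats::rmultinom(1L, inter_total, rep(1, slots + 1L)))

  blocks <- character(0)
  feats <- list()
  pos <- 0L
  oi <- 0L; ti <- 0L
  for (s in seq_len(slots)) {
    blocks <- c(blocks, random_dna(gaps[s], inter_gc))
    pos <- pos + gaps[s]
    if (s %in% trna_slots && ti < cfg$n_trna) {
      ti <- ti + 1L
      t <- trna_bodies[[ti]]
      feats[[length(feats) + 1L]] <- tibble::tibble(
        id = t$id, start = pos + 1L, end = pos + nchar(t$dna), strand = "+",
        ftype = "tRNA", product = paste0("tRNA-", t$isotype),
        translation = NA_character_, trna_isotype = t$isotype)
      blocks <- c(blocks, t$dna)
      pos <- pos + nchar(t$dna)
    } else {
      oi <- oi + 1L
      g <- orfs[[oi]]
      feats[[length(feats) + 1L]] <- tibble::tibble(
        id = g$id, start = pos + 1L, end = pos + g$len, strand = "+",
        ftype = "CDS", product = g$product, translation = g$translation,
        trna_isotype = NA_character_)
      blocks <- c(blocks, g$dna)
      pos <- pos + g$len
    }
  }
  blocks <- c(blocks, random_dna(gaps[slots + 1L], inter_gc))
  replicon <- new_replicon(cfg$id, paste(blocks, collapse = ""),
                           features = dplyr::bind_rows(feats),
                           topology = cfg$topology, kind = cfg$kind)
  list(replicon = replicon, truth = new_truth_row()[0L, ], planted = list(),
       planted_partial = list(), used_trnas = character(0), gc = cfg$gc,
       spacing = cfg$spacing, near_spacing = cfg$near_spacing)
}

#' Read a truth table written by [simulate_genome()]
#'
#' @param path Path to the `*_truth.json` file.
#' @return The truth tibble.
#' @export
read_truth <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = TRUE)
  out <- tibble::as_tibble(obj)
  for (col in c("circle_lens", "rep_types")) {
    if (!is.list(out[[col]])) out[[col]] <- as.list(out[[col]])
    out[[col]] <- lapply(out[[col]], function(x) if (is.null(x)) character(0) else x)
  }
  out
}
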