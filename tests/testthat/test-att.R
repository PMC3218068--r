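test_that("a planted exact duplicate is found with full length and identity", {
  set.seed(71)
  s <- rand_dna(20000)
  unit <- rand_dna(81)
  # distinct flanking bases prevent accidental extension of the true repeat
  s <- paste0(substr(s, 1, 999), "A", unit, "C",
              substr(s, 1083, 15999), "G", unit, "T",
              substr(s, 17083, 20000))
  pairs <- find_direct_repeats(s, min_len = 14, min_identity = 0.9)
  top <- pairs[1, ]
  expect_equal(top$length, 81L)
  expect_equal(top$identity, 1.0)
  expect_equal(top$start1, 1001L)
  expect_equal(substr(s, top$start1, top$end1), substr(s, top$start2, top$end2))
})

test_that("a random high-complexity sequence yields no att-sized repeat call", {
  # at the 14-bp floor a random 20-kb sequence can contain one or two short
  # chance repeats; at attachment-site lengths (>= 20 bp) chance hits are
  # essentially impossible
  set.seed(72)
  s <- rand_dna(20000, gc = 0.5)
  expect_lte(nrow(find_direct_repeats(s)), 2L)
  expect_equal(nrow(find_direct_repeats(s, min_len = 20)), 0L)
})

test_that("seed-and-extend equals the quadratic diagonal-scan oracle", {
  set.seed(73)
  for (case in 1:30) {
    n <- sample(300:2000, 1)
    gc <- sample(c(0.5, 0.7), 1)
    s <- rand_dna(n, gc)
    if (case %% 3 == 0) {       # plant an exact duplicate
      u <- rand_dna(sample(20:60, 1))
      p1 <- sample(10:(n %/% 3), 1)
      p2 <- sample((n %/% 2):(n - 80), 1)
      substr(s, p1, p1 + nchar(u) - 1) <- u
      substr(s, p2, p2 + nchar(u) - 1) <- u
    }
    if (case %% 3 == 1) {       # degraded duplicate (1-2 mismatches)
      u <- rand_dna(40)
      v <- u
      mut <- sample(5:35, 2)
      for (mm in mut) substr(v, mm, mm) <- setdiff(c("A", "C", "G", "T"),
                                                   substr(u, mm, mm))[1]
      p1 <- 20; p2 <- n - 60
      substr(s, p1, p1 + 39) <- u
      substr(s, p2, p2 + 39) <- v
    }
    expect_same_repeats(find_direct_repeats(s), brute_repeats(s))
  }
})

test_that("tRNA-anchored att pairs outrank longer unanchored repeats", {
  set.seed(74)
  att <- rand_dna(40)        # first 25 bp double as the tRNA 3' terminal
  wide <- rand_dna(60)
  blocks <- c(rand_dna(500), wide,                       #  1 2: attL' (unanchored)
              rand_dna(300), paste0(rand_dna(50), "A"),  #  3 4: tRNA 5' body
              att,                                       #  5: attL (anchored)
              paste0("G", rand_dna(199)),                #  6
              paste0("ATG", rand_dna(600), "TGA"),       #  7: int
              rand_dna(100),                             #  8
              paste0("ATG", rand_dna(300), "TGA"),       #  9: rep
              rand_dna(100),                             # 10
              paste0("ATG", rand_dna(450), "TGA"),       # 11: tra
              paste0(rand_dna(399), "C"),                # 12
              att,                                       # 13: attR
              paste0("T", rand_dna(299)),                # 14
              wide,                                      # 15: attR' (unanchored)
              rand_dna(500))                             # 16
  seq <- paste(blocks, collapse = "")
  off <- cumsum(c(0, nchar(blocks)))
  at <- function(i) off[i] + 1L
  feats <- tibble::tibble(
    id = c("t1", "int", "rep", "tra"),
    start = c(at(4), at(7), at(9), at(11)),
    end = c(at(5) + 24L, off[8], off[10], off[12]),   # tRNA ends inside attL
    strand = "+", ftype = c("tRNA", "CDS", "CDS", "CDS"),
    product = "x", translation = c(NA, "M", "M", "M"),
    trna_isotype = c("Lys", NA, NA, NA))
  rep <- new_replicon("r", seq, features = feats)
  region <- tibble::tibble(replicon_id = "r", start = feats$start[2],
                           end = feats$end[4], span_bp = 1L,
                           status = "AICE", int_id = "int", tra_id = "tra",
                           rep_ids = list("rep"), wraps_origin = FALSE,
                           reject_reason = NA_character_)
  pairs <- resolve_att_sites(region, rep)
  expect_gt(nrow(pairs), 0L)
  expect_true(pairs$anchored[1])
  expect_equal(pairs$trna_anchor[1], "t1")
  expect_equal(pairs$repeat_len[1], 40L)   # anchored 40-mer beats wider 60-mer
})

test_that("excision conserves sequence exactly and re-integration inverts it", {
  set.seed(75)
  s <- rand_dna(20000)
  unit <- rand_dna(81)
  s <- paste0(substr(s, 1, 1000), unit, substr(s, 1082, 15999),
              "G", unit, "T", substr(s, 17084, 20000))
  # attL 1001..1081, attR 16001..16081 (exact 81-bp repeat)
  rep <- new_replicon("r", s)
  element <- tibble::tibble(
    element_id = "e1",
    att_pairs = list(tibble::tibble(attL_start = 1001L, attL_end = 1081L,
                                    attR_start = 16001L, attR_end = 16081L,
                                    repeat_len = 81L, identity = 1.0)))
  prod <- excision_products(element, rep, keep_seqs = TRUE)
  expect_equal(prod$circle_len, (16081L - 1001L + 1L) - 81L)
  expect_equal(prod$circle_len, 15000L)
  # conservation: lengths and characters
  expect_equal(nchar(prod$chrom_after) + prod$circle_len, nchar(s))
  restored <- integrate_circle(prod$chrom_after, prod$circle, 1081L)
  expect_identical(restored, s)
  # attP carries exactly one repeat copy; attB locus retains exactly one
  expect_equal(stringr::str_count(prod$attP_seq, stringr::fixed(unit)), 1L)
  expect_equal(stringr::str_count(prod$attB_seq, stringr::fixed(unit)), 1L)
  expect_equal(stringr::str_count(prod$chrom_after, stringr::fixed(unit)), 1L)

  degenerate <- tibble::tibble(
    element_id = "d",
    att_pairs = list(tibble::tibble(attL_start = 1001L, attL_end = 1081L,
                                    attR_start = 1082L, attR_end = 1162L,
                                    repeat_len = 81L, identity = 1.0)))
  expect_error(excision_products(degenerate, rep), "degenerate")
})

test_that("multi-attL elements report two pairs sharing attR and two circles", {
  sim <- simulate_genome(list(n_aice = 1L, n_t4ss = 0L, n_remnant = 0L,
                              decoys = character(0),
                              aice_variants = "multi_attl"),
                         seed = 76, profiles = cached_profiles())
  res <- scan_replicon(sim$replicon)
  expect_equal(nrow(res$elements), 1L)
  pairs <- res$elements$att_pairs[[1]]
  expect_equal(nrow(pairs), 2L)
  expect_equal(length(unique(pairs$attR_start)), 1L)   # shared attR
  expect_equal(length(unique(pairs$attL_start)), 2L)
  expect_equal(nrow(res$products), 2L)
  expect_setequal(res$products$circle_len, unlist(sim$truth$circle_lens))
})

test_that("tandem elements excise independently and associatively", {
  sim <- simulate_genome(list(n_aice = 1L, n_t4ss = 0L, n_remnant = 0L,
                              decoys = character(0),
                              aice_variants = "tandem_pair"),
                         seed = 77, profiles = cached_profiles())
  res <- scan_replicon(sim$replicon)
  expect_equal(nrow(res$elements), 2L)
  expect_equal(nrow(res$products), 3L)    # 2 single + 1 composite
  expect_equal(sum(res$products$composite), 1L)
  singles <- res$products[!res$products$composite, ]
  composite <- res$products[res$products$composite, ]
  expect_setequal(singles$circle_len, unlist(sim$truth$circle_lens))
  # composite circle length equals the sum of the two independent circles
  # (shared copy counted once): conservation arithmetic
  expect_equal(composite$circle_len, sum(singles$circle_len))
  # conservation of the composite by direct string surgery
  ex <- aicescan:::excise_at(sim$replicon$seq,
                             composite$attL_start, composite$attL_end,
                             composite$attR_start, composite$attR_end)
  restored <- integrate_circle(ex$chrom_after, ex$circle, composite$attL_end)
  expect_identical(restored, sim$replicon$seq)
  # non-adjacent elements yield no composite
  sim2 <- simulate_genome(list(n_aice = 2L, n_t4ss = 0L, n_remnant = 0L,
                               decoys = character(0)),
                          seed = 78, profiles = cached_profiles())
  res2 <- scan_replicon(sim2$replicon)
  expect_equal(sum(res2$products$composite), 0L)
})
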