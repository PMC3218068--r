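# Co-localization fixtures use 1-bp genes at stated positions so spans are
# exactly the midpoint distances.
point_genes <- function(pos) {
  tibble::tibble(id = names(pos), start = unname(pos), end = unname(pos))
}

test_that("three-component windowed co-localization forms minimal regions", {
  rep <- toy_replicon(point_genes(c(int = 5000, rep = 10000, tra = 20000)),
                      length_bp = 100000)
  hits <- toy_hits(rep, c(int = "INT_TYR", rep = "REP_SA", tra = "TRA"))
  cand <- find_candidate_regions(rep, hits)
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$span_bp, 20000L - 5000L + 1L)

  # minimal interval exceeds the 60-kb window -> no region
  rep2 <- toy_replicon(point_genes(c(int = 5000, rep = 40000, tra = 70000)),
                       length_bp = 100000)
  hits2 <- toy_hits(rep2, c(int = "INT_TYR", rep = "REP_SA", tra = "TRA"))
  expect_equal(nrow(find_candidate_regions(rep2, hits2)), 0L)

  # no integrase anywhere -> empty
  rep3 <- toy_replicon(point_genes(c(rep = 1000, tra = 4000)), length_bp = 10000)
  hits3 <- toy_hits(rep3, c(rep = "REP_SA", tra = "TRA"))
  expect_equal(nrow(find_candidate_regions(rep3, hits3)), 0L)
})

test_that("an integrase between rep and tra rejects the candidate, flanking keeps it", {
  run_order <- function(pos) {
    rep <- toy_replicon(point_genes(pos), length_bp = 60000)
    hits <- toy_hits(rep, setNames(c("INT_TYR", "REP_SA", "TRA"),
                                   c("int", "rep", "tra")))
    cand <- find_candidate_regions(rep, hits)
    apply_order_filter(cand, rep, hits)$status
  }
  expect_equal(run_order(c(rep = 5000, int = 10000, tra = 15000)), "REJECTED")
  expect_equal(run_order(c(int = 5000, rep = 10000, tra = 15000)), "CANDIDATE")
  expect_equal(run_order(c(tra = 5000, rep = 10000, int = 15000)), "CANDIDATE")
  rep <- toy_replicon(point_genes(c(rep = 5000, int = 10000, tra = 15000)),
                      length_bp = 60000)
  hits <- toy_hits(rep, c(int = "INT_TYR", rep = "REP_SA", tra = "TRA"))
  cand <- apply_order_filter(find_candidate_regions(rep, hits), rep, hits)
  expect_equal(cand$reject_reason, "int-internal")
})

test_that("two-of-three regions are remnants; lone or complete sets are not", {
  rep <- toy_replicon(point_genes(c(int = 5000, rep = 15000)),
                      length_bp = 100000)
  hits <- toy_hits(rep, c(int = "INT_TYR", rep = "REP_SA"))
  remn <- detect_remnants(rep, hits)
  expect_equal(nrow(remn), 1L)
  expect_equal(remn$status, "REMNANT")

  lone <- toy_replicon(point_genes(c(ftsk = 30000)), length_bp = 100000)
  expect_equal(nrow(detect_remnants(lone, toy_hits(lone, c(ftsk = "TRA")))), 0L)

  full <- toy_replicon(point_genes(c(int = 5000, rep = 10000, tra = 20000)),
                       length_bp = 100000)
  fh <- toy_hits(full, c(int = "INT_TYR", rep = "REP_SA", tra = "TRA"))
  regions <- find_candidate_regions(full, fh)
  expect_equal(nrow(detect_remnants(full, fh, regions)), 0L)
})

test_that("T4SS-type regions need int+T4CP+VirB4+Mob; replication is optional", {
  rep <- toy_replicon(point_genes(c(int = 5000, t4cp = 12000, virb4 = 20000,
                                    mob = 35000)), length_bp = 100000)
  hits <- toy_hits(rep, c(int = "INT_TYR", t4cp = "T4CP", virb4 = "VIRB4",
                          mob = "MOB_F"))
  ice <- detect_t4ss_ice(rep, hits)
  expect_equal(nrow(ice), 1L)
  expect_equal(ice$status, "T4SS_ICE")
  expect_equal(length(ice$rep_ids[[1]]), 0L)

  rep2 <- toy_replicon(point_genes(c(int = 5000, t4cp = 12000, virb4 = 20000)),
                       length_bp = 100000)
  hits2 <- toy_hits(rep2, c(int = "INT_TYR", t4cp = "T4CP", virb4 = "VIRB4"))
  expect_equal(nrow(detect_t4ss_ice(rep2, hits2)), 0L)
})

test_that("a region matching both rules is reported once with AICE precedence", {
  pos <- c(int = 5000, rep = 8000, tra = 12000, t4cp = 16000,
           virb4 = 20000, mob = 24000)
  rep <- toy_replicon(point_genes(pos), length_bp = 100000)
  hits <- toy_hits(rep, c(int = "INT_TYR", rep = "REP_SA", tra = "TRA",
                          t4cp = "T4CP", virb4 = "VIRB4", mob = "MOB_F"))
  regions <- call_elements(rep, hits)
  expect_equal(sum(regions$status == "AICE"), 1L)
  expect_equal(sum(regions$status == "T4SS_ICE"), 0L)
  expect_equal(regions$t4cp_id[regions$status == "AICE"], "t4cp")
})

test_that("plasmids are classified whole, with no window", {
  mk <- function(roles) {
    genes <- point_genes(setNames(seq(1000, by = 4000,
                                      length.out = length(roles)),
                                  names(roles)))
    p <- toy_replicon(genes, length_bp = 14000, kind = "plasmid")
    classify_plasmid(p, toy_hits(p, roles))
  }
  expect_equal(mk(c(int = "INT_TYR", tra = "TRA", rep = "REP_SA")),
               "PLASMID_ICE")
  expect_true(is.na(mk(c(tra = "TRA", rep = "REP_SA"))))   # conjugative plasmid
  p0 <- toy_replicon(point_genes(c(g = 1000)), length_bp = 5000,
                     kind = "plasmid")
  expect_true(is.na(classify_plasmid(p0, toy_hits(p0, c(g = "REP_SA"))[0, ])))
  expect_error(classify_plasmid(toy_replicon(point_genes(c(g = 1000))),
                                toy_hits(p0, c(g = "REP_SA"))), "plasmid")
})

test_that("module combinations label integrase, replication set and transfer type", {
  rep <- toy_replicon(point_genes(c(int = 5000, rep = 10000, tra = 15000)),
                      length_bp = 60000)
  hits <- toy_hits(rep, c(int = "INT_SER", rep = "REP_SA", tra = "TRA"))
  region <- find_candidate_regions(rep, hits)
  mods <- classify_modules(region[1, ], hits)
  expect_equal(mods$integrase_type, "Int-Ser")
  expect_equal(mods$replication_types[[1]], "RepSA")
  expect_equal(mods$transfer_type, "FtsK/SpoIIIE")

  hits2 <- toy_hits(rep, c(int = "INT_TYR", rep = "REP_AM", tra = "TRA"))
  hits2 <- dplyr::bind_rows(hits2, dplyr::mutate(hits2[2, ], role = "PRIM_POL",
                                                 profile = "Prim-Pol"))
  region2 <- find_candidate_regions(rep, hits2)
  mods2 <- classify_modules(region2[1, ], hits2)
  expect_setequal(mods2$replication_types[[1]], c("RepAM", "Prim-Pol"))
  expect_equal(mods2$primary_rep, "RepAM")   # RepSA > RepAM > Prim-Pol priority

  hits3 <- toy_hits(rep, c(int = "INT_TYR", rep = "REP_OTHER:Rep_2", tra = "TRA"))
  region3 <- find_candidate_regions(rep, hits3, allow_rep_other = TRUE)
  expect_equal(nrow(region3), 1L)
  expect_equal(classify_modules(region3[1, ], hits3)$primary_rep, "RepOther:Rep_2")
  # default config does not admit the extra Rep families
  expect_equal(nrow(find_candidate_regions(rep, hits3)), 0L)
})

test_that("origin-spanning regions are found once on circular replicons", {
  n <- 100000L
  genes <- tibble::tibble(id = c("int", "rep", "tra"),
                          start = c(97000L, 99000L, 1500L),
                          end = c(97600L, 99600L, 2100L))
  rep <- toy_replicon(genes, length_bp = n, topology = "circular",
                      seq = rand_dna(n))
  hits <- toy_hits(rep, c(int = "INT_TYR", rep = "REP_SA", tra = "TRA"))
  cand <- find_candidate_regions(rep, hits)
  expect_equal(nrow(cand), 1L)
  expect_true(cand$wraps_origin)
  expect_equal(cand$start, 97000L)
  expect_equal(cand$end, 100000L + 2100L)   # doubled-coordinate end
  expect_equal(cand$span_bp, 2100L + n - 97000L + 1L)
})

test_that("adjacent complete elements are resolved without chimeric pairing", {
  pos1 <- c(a_int = 2000, a_rep = 4000, a_tra = 6000)
  pos2 <- c(b_int = 6500, b_rep = 8500, b_tra = 10500)
  rep <- toy_replicon(point_genes(c(pos1, pos2)), length_bp = 50000)
  hits <- toy_hits(rep, c(a_int = "INT_TYR", a_rep = "REP_SA", a_tra = "TRA",
                          b_int = "INT_TYR", b_rep = "REP_SA", b_tra = "TRA"))
  cand <- apply_order_filter(find_candidate_regions(rep, hits), rep, hits)
  expect_equal(nrow(cand), 2L)
  expect_equal(sum(cand$status == "CANDIDATE"), 2L)
  expect_setequal(cand$int_id, c("a_int", "b_int"))
  expect_equal(cand$tra_id[cand$int_id == "b_int"], "b_tra")
})

test_that("identical inputs produce identical region tables", {
  sim <- cached_sim()
  h1 <- search_proteome(sim$replicon, cached_profiles())
  r1 <- call_elements(sim$replicon, h1)
  r2 <- call_elements(sim$replicon, search_proteome(sim$replicon, cached_profiles()))
  expect_identical(r1, r2)
})
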