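test_that("FASTA+GFF3 loading keeps features sorted with translations attached", {
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "g.fasta")
  gff <- file.path(dir, "g.gff3")
  set.seed(11)
  seq <- rand_dna(4000)
  # CDS 3 carries no translation attribute and must be translated in-frame
  # (table 11); plant a known 4-codon ORF at 3001..3012
  known <- "ATGAAACGTTGA"   # M K R *
  substr(seq, 3001, 3012) <- known
  writeLines(c(">g1 test replicon", seq), fa)
  writeLines(c(
    "##gff-version 3",
    "g1\tx\tCDS\t101\t400\t.\t+\t.\tID=c1;translation=MABC;product=p1",
    "g1\tx\ttRNA\t900\t975\t.\t+\t.\tID=t1;isotype=Lys",
    "g1\tx\tCDS\t2001\t2300\t.\t+\t.\tID=c2;translation=MDEF",
    "g1\tx\tCDS\t3001\t3012\t.\t+\t.\tID=c3"), gff)
  rep <- read_replicon(fa, gff)
  expect_s3_class(rep$features, "tbl_df")
  expect_equal(nrow(rep$features), 4L)
  expect_equal(rep$features$id, c("c1", "t1", "c2", "c3"))   # sorted by start
  expect_false(is.unsorted(rep$features$start))
  expect_equal(rep$features$translation[rep$features$id == "c3"], "MKR")
  expect_equal(rep$features$trna_isotype[rep$features$id == "t1"], "Lys")
})

test_that("feature intervals beyond a linear sequence are rejected", {
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "g.fasta"); gff <- file.path(dir, "g.gff3")
  writeLines(c(">g1", rand_dna(500)), fa)
  writeLines(c("##gff-version 3",
               "g1\tx\tCDS\t400\t600\t.\t+\t.\tID=c1;translation=M"), gff)
  expect_error(read_replicon(fa, gff), "beyond")
})

test_that("origin-wrapping features normalize to two segments of conserved length", {
  feats <- tibble::tibble(id = "w1", start = 950, end = 30, strand = "+",
                          ftype = "CDS", product = "x", translation = "M",
                          trna_isotype = NA)
  rep <- new_replicon("c", rand_dna(1000), features = feats,
                      topology = "circular")
  expect_equal(rep$features$end, 1030L)   # doubled-coordinate normalization
  seg <- feature_segments(rep)
  expect_equal(nrow(seg), 2L)
  expect_equal(sum(seg$end - seg$start + 1L), 1030L - 950L + 1L)  # = 81, by hand
  expect_equal(sum(seg$end - seg$start + 1L), 81L)
  expect_error(new_replicon("l", rand_dna(1000), features = feats,
                            topology = "linear"),
               "start > end")
})

test_that("gc_content matches hand values and is a length-weighted mean over partitions", {
  expect_equal(gc_content(new_replicon("a", "ATGC")), 0.5)
  expect_equal(gc_content(new_replicon("b", "GGCC")), 1.0)
  expect_equal(gc_content(new_replicon("c", "AGGT"), 2, 3), 1.0)
  # N excluded from the denominator
  expect_equal(gc_content(new_replicon("d", "GGNN")), 1.0)
  expect_error(gc_content(new_replicon("e", "ACGT"), 3, 2))
  set.seed(7)
  rep <- new_replicon("r", rand_dna(5000, gc = 0.63))
  cuts <- sort(sample(2:4999, 6))
  bounds <- rbind(c(1, cuts[1]),
                  cbind(cuts[-6] + 1, cuts[-1]),
                  c(cuts[6] + 1, 5000))
  parts <- apply(bounds, 1, function(b) {
    c(gc = gc_content(rep, b[1], b[2]), w = b[2] - b[1] + 1)
  })
  expect_equal(sum(parts["gc", ] * parts["w", ]) / sum(parts["w", ]),
               gc_content(rep), tolerance = 1e-12)
})

test_that("replicon write/read round-trip preserves every interval", {
  sim <- simulate_genome(list(length = 60000L, n_background_cds = 25L,
                              n_trna = 3L, n_aice = 0L, n_t4ss = 0L,
                              n_remnant = 0L, decoys = character(0)),
                         seed = 5, profiles = cached_profiles())
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "x.fa"); gff <- file.path(dir, "x.gff3")
  write_replicon(sim$replicon, fa, gff)
  back <- read_replicon(fa, gff, topology = "circular")
  expect_equal(back$features$start, sim$replicon$features$start)
  expect_equal(back$features$end, sim$replicon$features$end)
  expect_equal(back$features$translation, sim$replicon$features$translation)
  expect_equal(back$seq, sim$replicon$seq)
})

test_that("result writers: header-only TSV, lossless JSON, GFF3 parent/child counts", {
  dir <- withr::local_tempdir()
  tsv <- file.path(dir, "r.tsv")
  write_results(empty_regions(), tsv, "tsv")
  expect_equal(length(readLines(tsv)), 1L)   # header only

  recs <- tibble::tibble(id = c("a", "b"), n = c(1L, 5L),
                         members = list(c("x", "y"), "z"))
  js <- file.path(dir, "r.json")
  write_results(recs, js, "json")
  expect_identical(read_results(js, "json"), recs)

  elem <- tibble::tibble(
    element_id = "e1", replicon_id = "g1", status = "AICE",
    start = 100L, end = 900L,
    att_pairs = list(tibble::tibble(attL_start = c(100L, 150L),
                                    attL_end = c(120L, 170L),
                                    attR_start = c(880L, 880L),
                                    attR_end = c(900L, 900L))))
  gff <- file.path(dir, "e.gff3")
  write_results(elem, gff, "gff3")
  gr <- rtracklayer::import(gff, format = "gff3")
  expect_equal(sum(gr$type == "mobile_genetic_element"), 1L)
  expect_equal(sum(gr$type == "attachment_site"), 4L)
  expect_error(write_results(recs, tsv, "xlsx"), "unknown")
})

test_that("external hit tables import with midpoints recomputed", {
  rep <- toy_replicon(tibble::tibble(id = c("g1", "g2"),
                                     start = c(100, 2000), end = c(700, 2900)))
  dir <- withr::local_tempdir()
  path <- file.path(dir, "hits.tsv")
  readr::write_tsv(tibble::tibble(
    replicon_id = "toy", feature_id = c("g1", "g2"),
    profile = c("Phage_integrase", "FtsK_SpoIIIE"),
    role = c("INT_TYR", "TRA"), score_bits = c(50, 60),
    passed = c(TRUE, TRUE)), path)
  hits <- read_hits_tsv(path, rep)
  expect_equal(hits$midpoint_bp, c(400L, 2450L))
  expect_error(read_hits_tsv(path), "midpoint")
  readr::write_tsv(tibble::tibble(feature_id = "g1"), path)
  expect_error(read_hits_tsv(path, rep), "lacks")
})
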