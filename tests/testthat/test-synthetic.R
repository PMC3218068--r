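small_cfg <- function(...) {
  utils::modifyList(list(length = 150000L, n_background_cds = 50L, n_trna = 4L,
                         n_aice = 1L, n_t4ss = 0L, n_remnant = 0L,
                         decoys = character(0)), list(...))
}

test_that("the truth table mirrors the requested element complement", {
  sim <- simulate_genome(list(n_aice = 2L), seed = 30,
                         profiles = cached_profiles())
  expect_equal(sum(sim$truth$kind == "aice"), 2L)
  expect_equal(sum(sim$truth$expected_status == "AICE"), 2L)
  expect_equal(sum(sim$truth$kind == "t4ss"), 1L)
  expect_equal(sum(sim$truth$expected_status == "REMNANT"), 1L)
  # truth spans lie within the genome and att copies are exact duplicates
  n <- nchar(sim$replicon$seq)
  el <- sim$truth[!is.na(sim$truth$attL_start), ]
  expect_true(all(el$start >= 1 & el$end <= n))
  for (i in seq_len(nrow(el))) {
    expect_identical(
      substr(sim$replicon$seq, el$attL_start[i], el$attL_end[i]),
      substr(sim$replicon$seq, el$attR_start[i], el$attR_end[i]))
  }
})

test_that("the same seed reproduces byte-identical FASTA, GFF3 and truth files", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  s1 <- simulate_genome(small_cfg(decoys = "lone_ftsk"), seed = 31,
                        out_dir = d1, profiles = cached_profiles())
  s2 <- simulate_genome(small_cfg(decoys = "lone_ftsk"), seed = 31,
                        out_dir = d2, profiles = cached_profiles())
  for (f in c("fasta", "gff", "truth")) {
    expect_identical(readLines(s1$files[[f]]), readLines(s2$files[[f]]))
  }
  s3 <- simulate_genome(small_cfg(decoys = "lone_ftsk"), seed = 32,
                        profiles = cached_profiles())
  expect_false(identical(s3$replicon$seq, s1$replicon$seq))
})

test_that("simulated genomes hit the target G+C within the tolerance band", {
  sim <- cached_sim()     # defaults: 500 kb, gc 0.70
  gc <- gc_content(sim$replicon)
  expect_gte(gc, 0.68)
  expect_lte(gc, 0.72)
  # low-G+C cargo is present inside elements
  el <- sim$truth[sim$truth$expected_status == "AICE", ][1, ]
  f <- sim$replicon$features
  cargo <- f[grepl("_cargo01", f$id) & f$start > el$start & f$end < el$end, ]
  expect_equal(nrow(cargo), 1L)
  rep <- sim$replicon
  expect_lt(gc_content(rep, cargo$start, cargo$end), 0.60)
})

test_that("over-packed configurations fail with a capacity error", {
  expect_error(
    simulate_genome(list(length = 100000L, n_aice = 2L, n_t4ss = 1L,
                         n_remnant = 3L,
                         decoys = c("lone_ftsk", "prophage_int_only")),
                    seed = 1, profiles = cached_profiles()),
    "spacing")
})

test_that("short att repeats trigger a detectability warning", {
  draft <- withr::with_seed(2, aicescan:::build_background(
    list(id = "w", length = 120000L, gc = 0.7, topology = "linear",
         kind = "chromosome", n_trna = 3L, n_background_cds = 30L,
         spacing = 61000L, near_spacing = 12000L)))
  draft$profiles <- cached_profiles()
  expect_warning(plant_element(draft, list(att_len = 10L), seed = 2),
                 "unbounded|shorter")
})

test_that("decoys never satisfy the element rule and remnants are called", {
  sim <- simulate_genome(small_cfg(n_aice = 0L, n_remnant = 1L,
                                   decoys = c("lone_ftsk", "prophage_int_only",
                                              "random_repeat_pair")),
                         seed = 33, profiles = cached_profiles())
  res <- scan_replicon(sim$replicon, profiles = cached_profiles())
  expect_equal(sum(res$regions$status %in% c("AICE", "T4SS_ICE")), 0L)
  expect_equal(sum(res$regions$status == "REMNANT"), 1L)
  # the lone FtsK produced a passing TRA hit that detection ignored
  ftsk <- res$hits[grepl("_ftsk", res$hits$feature_id) & res$hits$passed, ]
  expect_equal(ftsk$role, "TRA")
  # the bare repeat pair received no element boundaries
  rrp <- sim$truth[sim$truth$kind == "random_repeat_pair", ]
  expect_equal(nrow(res$elements), 0L)
  expect_true(nrow(rrp) == 1L)
})

test_that("truth JSON round-trips through read_truth", {
  dir <- withr::local_tempdir()
  sim <- simulate_genome(small_cfg(), seed = 34, out_dir = dir,
                         profiles = cached_profiles())
  back <- read_truth(sim$files$truth)
  expect_equal(back$id, sim$truth$id)
  expect_equal(back$start, sim$truth$start)
  expect_equal(back$end, sim$truth$end)
  expect_equal(unlist(back$circle_lens), unlist(sim$truth$circle_lens))
  expect_equal(back$expected_status, sim$truth$expected_status)
})

test_that("run_scan writes deterministic reports and tidies into tibbles", {
  sim <- cached_sim()
  md <- tibble::tibble(replicon_id = sim$replicon$id, suborder = "Frankineae",
                       genus = "Frankia", niche = "plant",
                       genome_size_bp = nchar(sim$replicon$seq),
                       genome_class = "complete")
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  scan1 <- run_scan(list(sim$replicon), metadata = md, out_dir = d1, seed = 1,
                    profiles = cached_profiles())
  scan2 <- run_scan(list(sim$replicon), metadata = md, out_dir = d2, seed = 1,
                    profiles = cached_profiles())
  for (f in c("regions.tsv", "elements.tsv", "elements.gff3", "products.tsv",
              "domain_hits.tsv", "run_log.txt")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  expect_s3_class(tidy(scan1), "tbl_df")
  expect_s3_class(tidy(scan1, "hits"), "tbl_df")
  g <- glance(scan1)
  expect_equal(g$n_aice, 2L)
  expect_equal(g$n_t4ss_ice, 1L)
  expect_equal(g$n_remnant, 1L)
  expect_output(print(scan1), "aice_scan")
})
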