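test_that("profile construction follows the occupancy and consensus rules", {
  p <- build_profile(c("ACD", "ACD", "A-D"), "t", "REP_SA",
                     occupancy_threshold = 0.5)
  expect_equal(nrow(p$emissions), 3L)   # column 2 occupancy 2/3 >= 0.5
  p2 <- build_profile(c("ACD", "ACD", "A-D"), "t", "REP_SA",
                      occupancy_threshold = 0.7)
  expect_equal(nrow(p2$emissions), 2L)  # column 2 drops out
  p3 <- build_profile(c("MKWY", "MKWY", "MKWY"), "t", "REP_SA")
  expect_equal(p3$consensus, "MKWY")    # identical sequences -> any input
  expect_error(build_profile(c("-", "-"), "t", "REP_SA"), "occupancy")
  expect_error(build_profile("AAA", "t", "REP_SA"), ">= 2")
  expect_error(build_profile(c("AA", "AAA"), "t", "REP_SA"), "equal length")
})

test_that("consensus scoring attains the per-column maximum and ignores flanks", {
  # family-like alignment: a dominant residue per column, so the consensus
  # (most probable residue) also carries the maximal emission per state
  set.seed(21)
  anc <- rand_protein(30)
  aln <- vapply(1:12, function(i) {
    x <- strsplit(anc, "")[[1]]
    mut <- runif(30) < 0.1
    x[mut] <- sample(AA20, sum(mut), replace = TRUE)
    paste(x, collapse = "")
  }, character(1))
  p <- build_profile(aln, "t", "REP_SA")
  cons_score <- score_protein(p, p$consensus)$score
  # gapless scoring of the consensus: no gap penalty leaks into the score
  cons_idx <- match(strsplit(p$consensus, "")[[1]], AA20)
  expect_equal(cons_score, sum(p$emissions[cbind(seq_along(cons_idx), cons_idx)]),
               tolerance = 1e-9)
  # the argmax-emission query attains the gapless upper bound
  best_query <- paste(AA20[apply(p$emissions, 1, which.max)], collapse = "")
  expect_equal(score_protein(p, best_query)$score,
               sum(apply(p$emissions, 1, max)), tolerance = 1e-9)
  # semi-global: residues outside the aligned span are free
  flanked <- paste0(rand_protein(40), p$consensus, rand_protein(40))
  expect_equal(score_protein(p, flanked)$score, cons_score, tolerance = 1e-9)
  span <- score_protein(p, flanked)
  expect_equal(span$start, 41)
  expect_equal(span$end, 40 + nchar(p$consensus))
  expect_error(score_protein(p, ""), "empty")
})

test_that("dynamic-programming scores equal exhaustive alignment enumeration", {
  set.seed(31)
  for (case in 1:60) {
    m <- sample(1:4, 1)
    n <- sample(1:6, 1)
    emissions <- matrix(round(rnorm(m * 20, 0, 2), 3), nrow = m,
                        dimnames = list(NULL, AA20))
    go <- sample(c(2, 4, 7), 1)
    ge <- sample(c(0.5, 1, 2), 1)
    prot <- sample(0:19, n, replace = TRUE)
    got <- aicescan:::profile_align_cpp(emissions, as.integer(prot), go, ge)$score
    want <- enumerate_align_score(emissions, prot, go, ge)
    expect_equal(got, want, tolerance = 1e-9,
                 info = sprintf("case %d (m=%d n=%d)", case, m, n))
  }
})

test_that("appending a positively emitting match state never lowers the score", {
  # the appended state emits positively for the residue just after the
  # optimal aligned span (appended to the protein when the span already
  # reaches its end), so the alignment can always grow by one match
  set.seed(32)
  for (case in 1:25) {
    m <- sample(2:5, 1); n <- sample(3:8, 1)
    emissions <- matrix(rnorm(m * 20, 0, 2), nrow = m,
                        dimnames = list(NULL, AA20))
    prot <- sample(0:19, n, replace = TRUE)
    r1 <- aicescan:::profile_align_cpp(emissions, as.integer(prot), 4, 1)
    if (r1$end == 0) next          # fully deleted profile: span undefined
    if (r1$end < n) {
      nxt <- prot[r1$end + 1]
      prot2 <- prot
    } else {
      nxt <- sample(0:19, 1)
      prot2 <- c(prot, nxt)
    }
    new_row <- rnorm(20, 0, 2)
    new_row[nxt + 1] <- abs(new_row[nxt + 1]) + 0.1
    s2 <- aicescan:::profile_align_cpp(rbind(emissions, new_row),
                                       as.integer(prot2), 4, 1)$score
    expect_gte(s2, r1$score - 1e-9)
  }
})

test_that("threshold calibration is reproducible and bounded by definition", {
  set.seed(41)
  p <- build_profile(replicate(8, {
    x <- rand_protein(40); x
  }) |> (\(x) {for (i in 2:8) substr(x[i], 1, 30) <- substr(x[1], 1, 30); x})(),
  "t", "REP_SA")
  a <- calibrate_threshold(p, seed = 99)
  b <- calibrate_threshold(p, seed = 99)
  expect_identical(a$threshold, b$threshold)
  expect_lt(a$threshold, score_protein(p, p$consensus)$score)
  # margin 0, 10 shuffles: threshold is exactly the empirical null maximum
  c0 <- suppressWarnings(calibrate_threshold(p, n_shuffles = 10, seed = 7,
                                             margin = 0))
  expect_equal(c0$threshold, max(c0$null_scores))
  expect_warning(calibrate_threshold(p, n_shuffles = 5, seed = 1), "unstable")
})

test_that("profile sampling is deterministic and recapitulates strong columns", {
  profiles <- cached_profiles()
  p <- profiles$RepSA
  expect_identical(sample_profile(p, seed = 3), sample_profile(p, seed = 3))
  # near-deterministic profile emits its consensus
  sharp <- build_profile(rep("MKWYDE", 12), "s", "REP_SA", pseudocount = 0.01)
  expect_equal(sample_profile(sharp, seed = 1), "MKWYDE")
  # samples score far above shuffled controls
  set.seed(55)
  samp <- vapply(1:50, function(s) score_protein(p, sample_profile(p, seed = s))$score,
                 numeric(1))
  shuf <- vapply(1:50, function(s) {
    score_protein(p, paste(sample(strsplit(p$consensus, "")[[1]]), collapse = ""))$score
  }, numeric(1))
  expect_gt(mean(samp), mean(shuf) + 20)
})

test_that("proteome search recovers a planted family member with no false pass", {
  profiles <- cached_profiles()
  set.seed(61)
  n_bg <- 50
  genes <- tibble::tibble(
    id = sprintf("cds%02d", seq_len(n_bg + 1)),
    start = seq(1000, by = 2000, length.out = n_bg + 1))
  genes$end <- genes$start + 900
  rep <- toy_replicon(genes, length_bp = max(genes$end) + 1000)
  rep$features$translation <- c(
    vapply(seq_len(n_bg), function(i) rand_protein(sample(150:350, 1)), character(1)),
    paste0(rand_protein(12), sample_profile(profiles$RepSA, seed = 8), rand_protein(15)))
  hits <- search_proteome(rep, profiles)
  expect_equal(nrow(hits), (n_bg + 1L) * length(profiles))
  passed <- hits[hits$passed, ]
  expect_equal(passed$feature_id, sprintf("cds%02d", n_bg + 1))
  expect_equal(passed$role, "REP_SA")
  # empty proteome
  empty_rep <- new_replicon("e", rand_dna(1000))
  expect_equal(nrow(search_proteome(empty_rep, profiles)), 0L)
})

test_that("profile JSON serialization round-trips scores and thresholds", {
  p <- cached_profiles()$TrwC
  dir <- withr::local_tempdir()
  path <- file.path(dir, "p.json")
  write_profile_json(p, path)
  q <- read_profile_json(path)
  expect_equal(q$role, "MOB_F")
  expect_equal(q$threshold, p$threshold)
  set.seed(3)
  prot <- rand_protein(120)
  expect_equal(score_protein(q, prot)$score, score_protein(p, prot)$score,
               tolerance = 1e-9)
})

test_that("Prim-Pol partner genes are annotated next to passing Prim-Pol hits", {
  genes <- tibble::tibble(id = c("a", "pp", "partner", "far"),
                          start = c(1000, 3000, 4200, 30000),
                          end = c(1900, 3900, 5000, 30900))
  rep <- toy_replicon(genes)
  hits <- toy_hits(rep, c(pp = "PRIM_POL"))
  aug <- annotate_reppp(hits, rep)
  reppp <- aug[aug$role == "REP_PP", ]
  expect_true(all(c("a", "partner") %in% reppp$feature_id))  # <=1 intervening
  expect_false("far" %in% reppp$feature_id)
})
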