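test_that("landscape models are fully determined by their seed", {
  ref <- fix_ref20()
  m1 <- sampleLandscapeModel(ref, seed = 1L)
  m2 <- sampleLandscapeModel(ref, seed = 1L)
  expect_identical(m1@additive, m2@additive)
  expect_identical(m1@pairwise, m2@pairwise)
  expect_identical(m1@compensatory, m2@compensatory)
  m3 <- sampleLandscapeModel(ref, seed = 2L)
  expect_false(identical(m1@additive, m3@additive))
})

test_that("epistasis_scale = 0 yields a purely additive landscape", {
  m <- sampleLandscapeModel(fix_ref20(), epistasis_scale = 0, seed = 4L)
  expect_length(m@pairwise, 0L)
  expect_length(m@threeway, 0L)
  expect_identical(nrow(m@compensatory), 0L)
})

test_that("compensatory doubles beat both constituent singles", {
  ref <- fix_ref20()
  for (link in c("logistic", "exp")) {
    m <- sampleLandscapeModel(ref, n_compensatory_pairs = 2L,
                              epistasis_scale = 0.6, seed = 8L, link = link)
    for (k in seq_len(nrow(m@compensatory))) {
      cp <- m@compensatory[k, ]
      rb <- strsplit(ref, "")[[1]]
      gi <- paste0(rb[cp$pos_i], cp$pos_i, cp$alt_i)
      gj <- paste0(rb[cp$pos_j], cp$pos_j, cp$alt_j)
      gd <- formatGenotype(rbind(parseGenotype(gi, ref), parseGenotype(gj, ref)))
      a <- trueActivity(m, c(gi, gj, gd))
      expect_gt(a[3], max(a[1], a[2]))
    }
  }
})

test_that("true activity is the linked latent sum and stays in [0,1]", {
  ref <- fix_ref20()
  m <- sampleLandscapeModel(ref, n_compensatory_pairs = 1L,
                            epistasis_scale = 0.7, seed = 6L, n_threeway = 5L,
                            threeway_scale = 1)
  expect_equal(trueActivity(m, "WT"), plogis(m@baseline))
  set.seed(10)
  gts <- sampleDopedLibrary(ref, 100, 0.15, seed = 12L)
  a <- trueActivity(m, gts)
  expect_true(all(a >= 0 & a <= 1))
  # order-3 genotype: hand-summed latent recomputed from the JSON dump
  g3 <- gts[genotypeOrder(gts) == 3L][1]
  path <- withr::local_tempfile(fileext = ".json")
  writeLandscapeModel(m, path)
  dump <- jsonlite::read_json(path, simplifyVector = TRUE)
  mut <- parseGenotype(g3, ref)
  keys <- paste0(mut$pos, mut$alt)
  latent <- dump$baseline + sum(unlist(dump$additive[keys]))
  prs <- combn(keys, 2, FUN = paste, collapse = "|")
  trs <- combn(keys, 3, FUN = paste, collapse = "|")
  latent <- latent + sum(unlist(dump$pairwise[prs])) +
    sum(unlist(dump$threeway[trs]))
  expect_equal(trueActivity(m, g3), plogis(latent), tolerance = 1e-12)
  # JSON round trip restores the model
  m2 <- readLandscapeModel(path)
  expect_equal(m2@additive, m@additive)
  expect_equal(trueActivity(m2, gts), a)
})

test_that("doped library matches the binomial per-position model", {
  ref <- fix_ref20()
  expect_true(all(sampleDopedLibrary(ref, 50, 0, seed = 1L) == "WT"))
  expect_identical(sampleDopedLibrary(ref, 200, 0.03, seed = 2L),
                   sampleDopedLibrary(ref, 200, 0.03, seed = 2L))
  n <- 20000L; rate <- 0.03; L <- 20L
  lib <- sampleDopedLibrary(ref, n, rate, seed = 3L)
  mean_order <- mean(genotypeOrder(lib))
  se <- sqrt(L * rate * (1 - rate) / n)
  expect_lt(abs(mean_order - L * rate), 3 * se)
})

test_that("direct activity-table simulation honours the estimator contract", {
  ref <- fix_ref20()
  m <- fix_additive_model()
  gts <- c("WT", enumerateSingleMutants(ref)[1:49])
  at <- simulateActivityTable(m, gts, depth = 1e6L, seed = 5L)
  d <- activityData(at)
  expect_identical(nrow(d), 50L)
  expect_true(all(abs(d$fraction_cleaved - trueActivity(m, gts)) < 5e-3))
  at2 <- simulateActivityTable(m, gts, depth = 1e6L, seed = 5L)
  expect_identical(activityData(at2), d)
})

test_that("read simulation encodes cleavage state in the upstream segment", {
  ref <- fix_ref20()
  up <- fix_upstream(); pr <- fix_primer()
  gts <- c("WT", enumerateSingleMutants(ref)[1:9])
  # activity exactly 1 (exp link, zero latent): no read carries the upstream seq
  m1 <- sampleLandscapeModel(ref, epistasis_scale = 0, seed = 1L,
                             link = "exp", baseline = 0)
  m1@additive[] <- 0
  f1 <- withr::local_tempfile(fileext = ".fastq")
  simulateReads(m1, gts, f1, mean_depth = 30, depth_dispersion = 0,
                upstream_seq = up, primer_site = pr, seed = 2L)
  reads1 <- as.character(Biostrings::readDNAStringSet(f1, format = "fastq"))
  expect_false(any(grepl(chartr("U", "T", up), reads1, fixed = TRUE)))
  # activity exactly 0: every read carries it
  m0 <- sampleLandscapeModel(ref, epistasis_scale = 0, seed = 1L,
                             baseline = -1000)
  m0@additive[] <- 0
  f0 <- withr::local_tempfile(fileext = ".fastq")
  simulateReads(m0, gts, f0, mean_depth = 30, depth_dispersion = 0,
                upstream_seq = up, primer_site = pr, seed = 3L)
  reads0 <- as.character(Biostrings::readDNAStringSet(f0, format = "fastq"))
  expect_true(all(grepl(chartr("U", "T", up), reads0, fixed = TRUE)))
})

test_that("simulated cleaved fraction sits within binomial error of truth", {
  ref <- fix_ref20()
  # wild-type activity pinned to 0.37 through the logistic baseline
  m <- sampleLandscapeModel(ref, epistasis_scale = 0, seed = 1L,
                            baseline = qlogis(0.37))
  f <- withr::local_tempfile(fileext = ".fastq")
  man <- simulateReads(m, "WT", f, mean_depth = 10000, depth_dispersion = 0,
                       seed = 4L)
  at <- countGenotypes(f, ref, fix_upstream(), fix_primer(),
                       mode = "match_list", expected = "WT")
  fc <- activityData(at)$fraction_cleaved
  n <- activityData(at)$total
  expect_lt(abs(fc - 0.37), 3 * sqrt(0.37 * 0.63 / n))
})

test_that("read simulator agrees with direct binomial sampling within 3 sigma", {
  ref <- fix_ref20()
  m <- fix_additive_model()
  gts <- c("WT", enumerateSingleMutants(ref)[seq(1, 60, by = 3)])
  f <- withr::local_tempfile(fileext = ".fastq")
  simulateReads(m, gts, f, mean_depth = 400, depth_dispersion = 0, seed = 6L)
  at_reads <- countGenotypes(f, ref, fix_upstream(), fix_primer(),
                             mode = "match_list", expected = gts)
  at_direct <- simulateActivityTable(m, gts, depth = 400L, seed = 7L)
  dr <- activityData(at_reads); dd <- activityData(at_direct)
  act <- trueActivity(m, dr$genotype)
  se <- sqrt(act * (1 - act) / dr$total)
  expect_true(all(abs(dr$fraction_cleaved - act) <= 3 * se + 1e-12))
  act2 <- trueActivity(m, dd$genotype)
  se2 <- sqrt(act2 * (1 - act2) / dd$total)
  expect_true(mean(abs(dd$fraction_cleaved - act2) <= 3 * se2 + 1e-12) >= 0.95)
})
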