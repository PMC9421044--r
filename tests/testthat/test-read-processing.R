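test_that("fraction cleaved handles counts, thresholds and missingness", {
  expect_identical(fractionCleaved(170, 0), 1)
  expect_identical(fractionCleaved(0, 0), NA_real_)
  expect_equal(fractionCleaved(34, 66), 0.34)
  expect_equal(fractionCleaved(c(50, 2), c(50, 1), min_reads = 5),
               c(0.5, NA_real_))
  expect_error(fractionCleaved(-1, 3), "non-negative")
})

test_that("relative activity normalizes to the wild-type", {
  expect_identical(relativeActivity(0.8, 0.8), 1)
  expect_identical(relativeActivity(0.4, 0.8), 0.5)
  expect_identical(relativeActivity(0, 0.8), 0)
  expect_error(relativeActivity(0.4, 0), "positive")
})

test_that("constructed reads classify to their genotype and cleavage state", {
  ref <- fix_ref20()
  up <- fix_upstream(); pr <- fix_primer()
  g1 <- enumerateSingleMutants(ref)[1]
  expected <- c("WT", enumerateSingleMutants(ref))
  reads <- c(paste0(up, ref, pr),                            # WT uncleaved
             paste0(genotypeToSequence(g1, ref), pr))        # single, cleaved
  cls <- classifyReads(reads, ref, up, pr, "match_list", expected = expected)
  expect_identical(cls$genotype, c("WT", g1))
  expect_identical(cls$cleaved, c(FALSE, TRUE))
  expect_true(all(is.na(cls$reason)))
})

test_that("every reject rule fires with its reason code", {
  ref <- fix_ref20()
  up <- fix_upstream(); pr <- fix_primer()
  expected <- c("WT", enumerateSingleMutants(ref))
  wt_clv <- paste0(ref, pr)
  sub1 <- function(s, i) {  # substitute a base that differs from the current
    b <- setdiff(c("A", "C", "G", "U"), substr(s, i, i))[1]
    substr(s, i, i) <- b; s
  }
  # substitution inside the primer site
  bad_primer <- paste0(ref, sub1(pr, 3))
  # two primer-site copies
  twice <- paste0(ref, pr, pr)
  # cleaved read truncated into the ribozyme
  short <- substr(wt_clv, 5, nchar(wt_clv))
  # substitution in the uncleaved (upstream) portion
  bad_up <- paste0(sub1(up, 2), ref, pr)
  # order-3 variant not in the expected list
  g3 <- formatGenotype(do.call(rbind, lapply(
    enumerateSingleMutants(ref)[c(1, 10, 40)], parseGenotype, ref = ref)))
  unexpected <- paste0(genotypeToSequence(g3, ref), pr)
  cls <- classifyReads(c(bad_primer, twice, short, bad_up, unexpected),
                       ref, up, pr, "match_list", expected = expected)
  expect_identical(cls$reason,
                   c("no_primer_site", "ambiguous_primer_site", "too_short",
                     "unexpected_upstream", "unexpected_mutation"))
  expect_true(all(is.na(cls$genotype)))
})

test_that("variable-positions mode reads genotypes off the scheme positions", {
  ref <- fix_ref20()
  rb <- strsplit(ref, "")[[1]]
  up <- fix_upstream(); pr <- fix_primer()
  alt1 <- setdiff(c("A", "C", "G", "U"), rb[4])[1]
  alt2 <- setdiff(c("A", "C", "G", "U"), rb[9])[1:2]
  sch <- variableScheme(c(4L, 9L), list(alt1, alt2), ref)
  g <- paste0(rb[4], 4, alt1)
  reads <- c(paste0(genotypeToSequence(g, ref), pr),
             paste0(up, ref, pr))
  cls <- classifyReads(reads, ref, up, pr, "variable_positions", scheme = sch)
  expect_identical(cls$genotype, c(g, "WT"))
  expect_identical(cls$cleaved, c(TRUE, FALSE))
  # disallowed base at a variable position
  forb <- setdiff(c("A", "C", "G", "U"), c(rb[9], alt2))
  s <- genotypeToSequence("WT", ref); substr(s, 9, 9) <- forb
  # mutation outside the variable positions
  s2 <- genotypeToSequence("WT", ref)
  substr(s2, 15, 15) <- setdiff(c("A", "C", "G", "U"), rb[15])[1]
  cls2 <- classifyReads(paste0(c(s, s2), pr), ref, up, pr,
                        "variable_positions", scheme = sch)
  expect_identical(cls2$reason,
                   c("unexpected_variable_base", "unexpected_mutation"))
})

test_that("counting pools reads per genotype with conservation", {
  ref <- fix_ref20()
  up <- fix_upstream(); pr <- fix_primer()
  g1 <- enumerateSingleMutants(ref)[5]
  seqs <- c(rep(paste0(ref, pr), 100),                        # 100 cleaved WT
            rep(paste0(up, genotypeToSequence(g1, ref), pr), 50),
            rep(paste0(genotypeToSequence(g1, ref), pr), 50),
            "ACGT")                                           # junk
  f <- withr::local_tempfile(fileext = ".fastq")
  fix_write_fastq(seqs, f)
  at <- countGenotypes(f, ref, up, pr, "match_list",
                       expected = c("WT", g1))
  d <- activityData(at)
  expect_identical(d$fraction_cleaved[d$genotype == "WT"], 1)
  expect_identical(d$fraction_cleaved[d$genotype == g1], 0.5)
  prov <- provenance(at)
  expect_identical(sum(d$total) + sum(unlist(prov$rejected)),
                   prov$total_reads)
  expect_identical(sum(unlist(prov$rejected)), 1L)
})

test_that("gzipped FASTQ gives identical counts to plain", {
  ref <- fix_ref20()
  up <- fix_upstream(); pr <- fix_primer()
  m <- fix_additive_model()
  gts <- c("WT", enumerateSingleMutants(ref)[1:10])
  f <- withr::local_tempfile(fileext = ".fastq")
  simulateReads(m, gts, f, mean_depth = 40, seed = 3L)
  fz <- paste0(f, ".gz")
  writeLines(readLines(f), gzfile(fz)); close
  at1 <- countGenotypes(f, ref, up, pr, "match_list", expected = gts)
  at2 <- countGenotypes(fz, ref, up, pr, "match_list", expected = gts)
  expect_identical(activityData(at1), activityData(at2))
})

test_that("error-free simulated reads are never rejected in match-list mode", {
  ref <- fix_ref20()
  m <- fix_additive_model()
  gts <- c("WT", enumerateSingleMutants(ref),
           enumerateDoubleMutants(ref)[seq(1, 1700, by = 17)])
  f <- withr::local_tempfile(fileext = ".fastq")
  simulateReads(m, gts, f, mean_depth = 20, seed = 9L)
  at <- countGenotypes(f, ref, fix_upstream(), fix_primer(),
                       mode = "match_list", expected = gts)
  expect_identical(sum(unlist(provenance(at)$rejected)), 0L)
})

test_that("estimator error shrinks with depth on a simulated library", {
  ref <- fix_ref20()
  m <- fix_additive_model()
  gts <- c("WT", enumerateSingleMutants(ref)[1:39])
  mae <- vapply(c(100L, 1000L), function(dep) {
    at <- simulateActivityTable(m, gts, depth = dep, seed = dep)
    mean(abs(activityData(at)$fraction_cleaved - trueActivity(m, gts)))
  }, numeric(1))
  expect_lt(mae[2], mae[1])
})

test_that("activity tables round-trip through TSV with provenance sidecar", {
  ref <- fix_ref20()
  m <- fix_additive_model()
  at <- simulateActivityTable(m, c("WT", enumerateSingleMutants(ref)[1:5]),
                              depth = 500L, seed = 2L, min_reads = 3L)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeActivityTable(at, f)
  back <- readActivityTable(f)
  expect_identical(activityData(back), activityData(at))
  expect_identical(refSequence(back), ref)
  expect_identical(back@provenance$min_reads, 3L)
})
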