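# synthetic table with chosen per-order bin sizes (activities arbitrary)
mk_order_table <- function(ref, sizes) {
  gts <- "WT"
  singles <- enumerateSingleMutants(ref)
  set.seed(99)
  for (o in seq_along(sizes)) {
    if (o == 1L) { gts <- c(gts, singles[seq_len(sizes[1])]); next }
    got <- character(0)
    while (length(got) < sizes[o]) {
      g <- sample(singles, o)
      p <- as.integer(gsub("[A-Z]", "", g))
      if (anyDuplicated(p)) next
      got <- unique(c(got, formatGenotype(
        do.call(rbind, lapply(g, parseGenotype, ref = ref)))))
    }
    gts <- c(gts, got[seq_len(sizes[o])])
  }
  fc <- round(runif(length(gts)), 3)
  activityTable(gts, round(fc * 1000), 1000 - round(fc * 1000), ref)
}

test_that("per-order split holds out 20% with orders <= 2 fully in training", {
  ref <- fix_ref20()
  at <- mk_order_table(ref, c(40, 100, 100, 518))
  sp <- splitByOrder(at, test_fraction = 0.2, seed = 1L)
  po <- sp$per_order
  expect_identical(po$n_test[po$order <= 2L], rep(0L, 3))
  expect_identical(po$n_test[po$order == 3L], 20L)
  # round-half-up rule: 20% of 518 = 103.6 -> 104
  expect_identical(po$n_test[po$order == 4L], 104L)
  expect_identical(po$n_train[po$order == 4L], 414L)
  # conservation and disjointness
  expect_identical(po$n_train + po$n_test, po$n)
  expect_length(intersect(sp$train, sp$test), 0L)
  expect_setequal(c(sp$train, sp$test), activityData(at)$genotype)
})

test_that("splits are deterministic per seed and row-order independent", {
  ref <- fix_ref20()
  at <- mk_order_table(ref, c(30, 60, 50))
  s1 <- splitByOrder(at, seed = 5L)
  s2 <- splitByOrder(at, seed = 5L)
  expect_identical(s1$test, s2$test)
  # permuting table rows leaves the split unchanged
  d <- activityData(at)
  set.seed(1)
  at_perm <- activityTable(d$genotype[sample(nrow(d))],
                           d$cleaved[sample(nrow(d))] * 0 + 500,
                           rep(500, nrow(d)), ref)
  expect_setequal(splitByOrder(at_perm, seed = 5L)$test, s1$test)
  s3 <- splitByOrder(at, seed = 6L)
  expect_false(identical(sort(s1$test), sort(s3$test)))
})

test_that("tiny bins fall back to training with a warning", {
  ref <- fix_ref20()
  gts <- c("WT", enumerateSingleMutants(ref)[1:3],
           "A1C;C2A;C5G")  # fabricate a lone order-3 genotype
  gts[5] <- formatGenotype(do.call(rbind, lapply(
    enumerateSingleMutants(ref)[c(1, 10, 40)], parseGenotype, ref = ref)))
  at <- activityTable(gts, rep(500, 5), rep(500, 5), ref)
  expect_warning(sp <- splitByOrder(at, 0.5, seed = 1L), "all to training")
  expect_length(sp$test, 0L)
})

test_that("order count table mirrors the split bookkeeping", {
  ref <- fix_ref20()
  at <- mk_order_table(ref, c(40, 80, 50))
  sp <- splitByOrder(at, seed = 2L)
  tab <- orderCountTable(sp)
  expect_identical(names(tab), c("n_mutations", "training", "testing"))
  expect_identical(tab$n_mutations, 1:3)
  expect_true(all(is.na(tab$testing[tab$n_mutations <= 2])))
  expect_identical(tab$training[3] + tab$testing[3], 50L)
})

test_that("cumulative training sets nest and count correctly", {
  ref <- fix_ref20()
  at <- mk_order_table(ref, c(30, 60, 50, 40))
  sp <- splitByOrder(at, seed = 3L)
  d1 <- buildCumulativeTraining(sp, at, 1L)
  d2 <- buildCumulativeTraining(sp, at, 2L)
  d3 <- buildCumulativeTraining(sp, at, 3L)
  expect_true(all(d1$genotype %in% d2$genotype))
  expect_true(all(d2$genotype %in% d3$genotype))
  po <- sp$per_order
  # wild-type (the order-0 bin) is included in training, never in test
  expect_identical(length(d2$genotype),
                   sum(po$n_train[po$order <= 2L]))
  expect_true("WT" %in% d2$genotype)
  expect_false("WT" %in% sp$test)
  expect_identical(length(d3$genotype),
                   sum(po$n_train[po$order <= 3L]))
  expect_warning(d9 <- buildCumulativeTraining(sp, at, 9L), "clamped")
  expect_identical(length(d9$genotype), length(sp$train) + 0L)
})

test_that("subsampling is exact, seeded and membership-random", {
  ref <- fix_ref20()
  at <- mk_order_table(ref, c(40, 100))
  dat <- encodeDataset(at, "onehot")
  expect_identical(subsampleTraining(dat, 1, seed = 1L)$genotype, dat$genotype)
  n <- length(dat$targets)
  s10 <- subsampleTraining(dat, 0.1, seed = 2L)
  expect_length(s10$genotype, floor(0.1 * n + 0.5))
  s10b <- subsampleTraining(dat, 0.1, seed = 3L)
  expect_identical(length(s10$genotype), length(s10b$genotype))
  expect_false(setequal(s10$genotype, s10b$genotype))
  expect_error(subsampleTraining(dat, 0.001, seed = 1L), "too small")
})

test_that("metrics match textbook formulas to 1e-12", {
  set.seed(8)
  p <- rnorm(50); o <- 0.6 * p + rnorm(50, 0, 0.5)
  m <- computeMetrics(p, o)
  # independent direct-formula recomputation
  r_direct <- sum((p - mean(p)) * (o - mean(o))) /
    sqrt(sum((p - mean(p))^2) * sum((o - mean(o))^2))
  expect_equal(m$pearson_r, r_direct, tolerance = 1e-12)
  expect_equal(m$mse, sum((p - o)^2) / 50, tolerance = 1e-12)
  expect_equal(m$r_squared, r_direct^2, tolerance = 1e-12)
  mc <- computeMetrics(p, o, r2 = "cod")
  expect_equal(mc$r_squared, 1 - sum((o - p)^2) / sum((o - mean(o))^2),
               tolerance = 1e-12)
  # identity and anticorrelation
  expect_equal(computeMetrics(o, o)$pearson_r, 1)
  expect_equal(computeMetrics(o, o)$mse, 0)
  expect_equal(computeMetrics(-o + 2, o)$pearson_r, -1)
  # degenerate vectors flagged
  z <- computeMetrics(rep(1, 10), o[1:10])
  expect_true(z$degenerate)
  expect_true(is.na(z$pearson_r))
})

test_that("experiment harness runs the factorial with one persisted split", {
  fx <- fix_trend()
  m <- fx$metrics
  # one record per (max_order, test_order) cell
  expect_identical(nrow(m), 2L)
  expect_identical(m$test_order, c(6L, 6L))
  # training-set nesting shows up as larger n_train at higher max order
  expect_gt(m$n_train[2], m$n_train[1])
  # same test bin for both cells
  expect_identical(m$n_test[1], m$n_test[2])
})

test_that("identical test data across model kinds and reruns", {
  ref <- fix_ref20()
  at <- mk_order_table(ref, c(30, 80, 60, 40))
  r1 <- runPredictionExperiment(at, model_kinds = c("random_forest", "linear"),
                                max_orders = 2L, test_orders = c(3L, 4L),
                                seed = 11L, num_trees = 50L)
  r2 <- runPredictionExperiment(at, model_kinds = c("random_forest", "linear"),
                                max_orders = 2L, test_orders = c(3L, 4L),
                                seed = 11L, num_trees = 50L)
  # byte-identical persisted split
  expect_identical(r1$split$test, r2$split$test)
  # rf and linear rows saw exactly the same test genotypes
  k_rf <- grep("^random_forest", names(r1$predictions), value = TRUE)
  k_li <- grep("^linear", names(r1$predictions), value = TRUE)
  for (i in seq_along(k_rf))
    expect_identical(r1$predictions[[k_rf[i]]]$genotype,
                     r1$predictions[[k_li[i]]]$genotype)
  # deterministic rerun for the deterministic models
  expect_equal(r1$metrics$pearson_r, r2$metrics$pearson_r, tolerance = 1e-12)
  # factorial bookkeeping: 2 kinds x 1 max_order x 2 test orders
  expect_identical(nrow(r1$metrics), 4L)
})

test_that("subsample replicates vary membership but share the test set", {
  ref <- fix_ref20()
  at <- mk_order_table(ref, c(40, 120, 80, 60))
  res <- runPredictionExperiment(at, model_kinds = "random_forest",
                                 max_orders = 3L, test_orders = 4L,
                                 subsample = list(fractions = c(1, 0.5),
                                                  replicates = c(1L, 2L)),
                                 seed = 7L, num_trees = 50L)
  m <- res$metrics
  expect_identical(nrow(m), 3L)   # 1 + 2 replicates
  expect_identical(unique(m$n_test), m$n_test[1])
  halves <- m[m$fraction == 0.5, ]
  expect_identical(halves$n_train[1], halves$n_train[2])
  expect_false(identical(halves$seed[1], halves$seed[2]))
})
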