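# Shared fixtures, all built in code with pinned seeds. Expensive ones
# (trained models) are cached for the duration of the test run.

.fix <- new.env(parent = emptyenv())

fix_cached <- function(name, builder) {
  if (!exists(name, envir = .fix)) assign(name, builder(), envir = .fix)
  get(name, envir = .fix)
}

# 20-nt toy reference used across module tests
fix_ref20 <- function() {
  set.seed(42)
  paste(sample(c("A", "C", "G", "U"), 20, replace = TRUE), collapse = "")
}

fix_upstream <- function() "CUGCAGAAUUCGCC"
fix_primer <- function() "GGAUCCUCUAGAGUCGAC"

# activity table whose fractions equal the model's true activities to ~1e-9
# (counts at depth 1e9): the "infinite depth" limit for statistic tests
fix_exact_table <- function(model, genotype) {
  act <- trueActivity(model, genotype)
  depth <- 1e9
  cleaved <- round(act * depth)
  activityTable(genotype, cleaved, depth - cleaved, model@reference)
}

# purely additive landscape on the toy reference, with its full
# singles + doubles table at effectively infinite depth
fix_additive_model <- function() {
  fix_cached("additive_model", function()
    sampleLandscapeModel(fix_ref20(), n_compensatory_pairs = 0L,
                         epistasis_scale = 0, seed = 3L))
}

fix_additive_table <- function() {
  fix_cached("additive_table", function() {
    ref <- fix_ref20()
    gts <- c("WT", enumerateSingleMutants(ref), enumerateDoubleMutants(ref))
    fix_exact_table(fix_additive_model(), gts)
  })
}

# 200 random order-3 genotypes held out from the additive fixture
fix_triples <- function() {
  fix_cached("triples", function() {
    ref <- fix_ref20()
    singles <- enumerateSingleMutants(ref)
    set.seed(11)
    tri <- replicate(230, {
      repeat {
        g <- sample(singles, 3L)
        p <- as.integer(gsub("[A-Z]", "", g))
        if (!anyDuplicated(p)) break
      }
      formatGenotype(do.call(rbind, lapply(g, parseGenotype, ref = ref)))
    })
    unique(tri)[1:200]
  })
}

# random forest trained on all singles + doubles of the additive landscape
fix_rf_recovery <- function() {
  fix_cached("rf_recovery", function() {
    dat <- encodeDataset(fix_additive_table(), "onehot")
    bundle <- trainRandomForest(dat, seed = 1L)
    tri <- fix_triples()
    pred <- predict(bundle, tri)
    truth <- trueActivity(fix_additive_model(), tri)
    list(bundle = bundle, pred = pred, truth = truth,
         r = cor(pred, truth))
  })
}

# hybrid (LSTM features -> random forest) on the same fixture
fix_hybrid_recovery <- function() {
  fix_cached("hybrid_recovery", function() {
    dat <- encodeDataset(fix_additive_table(), "index")
    bundle <- trainHybrid(dat, lstmConfig(seed = 1L), seed = 1L)
    tri <- fix_triples()
    pred <- predict(bundle, tri)
    truth <- trueActivity(fix_additive_model(), tri)
    list(bundle = bundle, pred = pred, truth = truth,
         r = cor(pred, truth))
  })
}

# combinatorial landscape with planted three-way structure: a 13-position
# biallelic library, three-way latent terms drawn over those mutations
fix_trend <- function() {
  fix_cached("trend", function() {
    ref <- fix_ref20()
    rb <- strsplit(ref, "")[[1]]
    set.seed(13)
    vp <- sort(sample(20L, 13L))
    alts <- lapply(vp, function(p) setdiff(c("A", "C", "G", "U"), rb[p])[1])
    sch <- variableScheme(vp, alts, ref)
    pool <- unlist(lapply(seq_along(vp), function(k) paste0(vp[k], alts[[k]])))
    model <- sampleLandscapeModel(ref, n_compensatory_pairs = 2L,
                                  epistasis_scale = 0.8, seed = 17L,
                                  n_threeway = 40L, threeway_scale = 2,
                                  threeway_pool = pool)
    gts <- enumerateCombinatorialVariants(ref, sch)
    table <- simulateActivityTable(model, gts, depth = 10000L, seed = 19L)
    res <- runPredictionExperiment(table, model_kinds = "random_forest",
                                   max_orders = c(2L, 3L), test_orders = 6L,
                                   seed = 23L)
    list(model = model, scheme = sch, table = table, metrics = res$metrics,
         split = res$split)
  })
}

# hand-built FASTQ writer for tiny constructed read fixtures
fix_write_fastq <- function(seqs, path) {
  dna <- chartr("U", "T", seqs)
  lines <- as.vector(rbind(paste0("@r", seq_along(dna)), dna, "+",
                           vapply(nchar(dna), function(w) strrep("I", w), "")))
  writeLines(lines, path)
  path
}
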