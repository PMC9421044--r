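#' Per-mutational-distance train/test split
#'
#' Bins genotypes by mutational order; within each bin of order >= 3 a
#' fraction (default 20%) is chosen uniformly at random without replacement
#' as test data. Orders 0-2 (wild-type, singles, doubles) go entirely to
#' training. Per-bin test size is round-half-up of
#' \code{test_fraction * bin size} (capped at bin size - 1); bins smaller
#' than 2 go entirely to training with a warning. The split depends only on
#' the table's genotype set and the seed, so persisting it guarantees the
#' identical test data for every model.
#'
#' @param table An [ActivityTable-class] (rows with NA activity are
#'   excluded from both sides).
#' @param test_fraction Test proportion per bin (default 0.2).
#' @param seed Integer seed.
#' @return List of class \code{"binnedSplit"}: \code{train}, \code{test}
#'   (genotype vectors), \code{per_order} (data.frame order, n, n_train,
#'   n_test), \code{test_fraction}, \code{seed}.
#' @export
splitByOrder <- function(table, test_fraction = 0.2, seed = 1L) {
  stopifnot(test_fraction >= 0, test_fraction < 1)
  d <- activityData(table)
  d <- d[!is.na(d$fraction_cleaved), , drop = FALSE]
  orders <- sort(unique(d$order))
  train <- character(0); test <- character(0)
  rows <- vector("list", length(orders))
  set.seed(as.integer(seed))
  for (k in seq_along(orders)) {
    o <- orders[k]
    g <- sort(d$genotype[d$order == o])  # row-order independent
    n <- length(g)
    n_test <- if (o <= 2L) 0L else as.integer(floor(test_fraction * n + 0.5))
    if (n < 2L && n_test > 0L) {
      warning("order-", o, " bin has ", n, " genotype(s); all to training")
      n_test <- 0L
    }
    n_test <- min(n_test, max(n - 1L, 0L))
    te <- if (n_test > 0L) g[sample.int(n, n_test)] else character(0)
    tr <- setdiff(g, te)
    train <- c(train, tr); test <- c(test, te)
    rows[[k]] <- data.frame(order = o, n = n, n_train = length(tr),
                            n_test = n_test)
  }
  structure(list(train = train, test = test,
                 per_order = do.call(rbind, rows),
                 test_fraction = test_fraction, seed = as.integer(seed)),
            class = "binnedSplit")
}

#' Per-order train/test accounting table
#'
#' The split's bookkeeping in the layout of a counts-of-sequences table:
#' one row per mutational order with training and testing counts (testing
#' is NA for the orders forced fully into training).
#'
#' @param split From [splitByOrder()].
#' @param include_wildtype Keep the order-0 row (default FALSE).
#' @return data.frame with columns \code{n_mutations}, \code{training},
#'   \code{testing}.
#' @export
orderCountTable <- function(split, include_wildtype = FALSE) {
  po <- split$per_order
  if (!include_wildtype) po <- po[po$order > 0L, , drop = FALSE]
  data.frame(n_mutations = po$order, training = po$n_train,
             testing = ifelse(po$n_test == 0L & po$order <= 2L, NA_integer_,
                              po$n_test))
}

#' Cumulative training set up to a maximal mutational order
#'
#' Union of the training portions of all bins with order 1..max_order
#' (plus the wild-type row when present and requested) — "all sequences up
#' to and including" the given number of mutations.
#'
#' @param split From [splitByOrder()].
#' @param table The same [ActivityTable-class] the split was built from.
#' @param max_order Highest mutational order to include.
#' @param include_wildtype Include the order-0 row (default TRUE).
#' @param encoding Encoding for the returned dataset.
#' @return An [encodeDataset()] result restricted to the cumulative
#'   training genotypes.
#' @export
buildCumulativeTraining <- function(split, table, max_order,
                                    include_wildtype = TRUE,
                                    encoding = c("onehot", "index")) {
  encoding <- match.arg(encoding)
  stopifnot(max_order >= 1L)
  avail <- max(split$per_order$order)
  if (max_order > avail) {
    warning("max_order ", max_order, " exceeds available orders; clamped to ",
            avail)
    max_order <- avail
  }
  ord <- genotypeOrder(split$train)
  keep <- ord >= 1L & ord <= max_order
  if (include_wildtype) keep <- keep | ord == 0L
  encodeDataset(table, encoding = encoding, genotypes = split$train[keep])
}

#' Subsample a training dataset
#'
#' Uniform sample without replacement of round-half-up
#' \code{fraction * n} rows; \code{fraction = 1} returns the identical
#' dataset.
#'
#' @param data An [encodeDataset()] result.
#' @param fraction Proportion in (0, 1].
#' @param seed Integer seed.
#' @return The subsampled dataset (same class/fields).
#' @export
subsampleTraining <- function(data, fraction, seed = 1L) {
  stopifnot(fraction > 0, fraction <= 1)
  n <- length(data$targets)
  if (fraction == 1) return(data)
  m <- floor(fraction * n + 0.5)
  if (m < 2L) stop("subsample of ", m, " row(s) is too small to train on")
  set.seed(as.integer(seed))
  rows <- sort(sample.int(n, m))
  out <- data
  out$features <- data$features[rows, , drop = FALSE]
  out$targets <- data$targets[rows]
  out$genotype <- data$genotype[rows]
  out
}

#' Prediction metrics: Pearson r, R-squared, MSE
#'
#' Pearson correlation between predicted and observed, R-squared (default:
#' the square of Pearson r; \code{r2 = "cod"} gives the coefficient of
#' determination 1 - SS_res/SS_tot instead), and mean squared error.
#'
#' @param predicted,observed Equal-length numeric vectors (n >= 2).
#' @param r2 \code{"pearson"} (default) or \code{"cod"}.
#' @return List: \code{pearson_r}, \code{r_squared}, \code{mse}, \code{n};
#'   r is NA (flagged by \code{degenerate = TRUE}) when either vector has
#'   zero variance.
#' @export
computeMetrics <- function(predicted, observed, r2 = c("pearson", "cod")) {
  r2 <- match.arg(r2)
  stopifnot(length(predicted) == length(observed), length(observed) >= 2L)
  mse <- mean((predicted - observed)^2)
  degenerate <- stats::sd(predicted) == 0 || stats::sd(observed) == 0
  r <- if (degenerate) NA_real_ else cor(predicted, observed)
  rsq <- if (r2 == "pearson") r^2
  else 1 - sum((observed - predicted)^2) / sum((observed - mean(observed))^2)
  list(pearson_r = r, r_squared = rsq, mse = mse,
       n = length(observed), degenerate = degenerate)
}

modelSeedScheme <- function(base_seed, counter) {
  # documented scheme: one base seed reproduces a whole run; each trained
  # model consumes the next derived seed (kept well below 2^31)
  as.integer((as.numeric(base_seed) + 7919 * counter) %% 2147483647)
}

#' Run a full prediction experiment over the factorial design
#'
#' The end-to-end harness: one persisted per-order split (identical test
#' data for every model), then the full factorial over model kind x
#' cumulative max training order x optional subsample fraction/replicate,
#' evaluating each trained model on every requested test-order bin.
#'
#' @param table An [ActivityTable-class].
#' @param model_kinds Subset of \code{c("random_forest", "lstm_hybrid",
#'   "linear", "mlp")}.
#' @param max_orders Integer vector of cumulative training cut-offs.
#' @param test_orders Integer vector of test bins to evaluate (default:
#'   all orders with a nonempty test set).
#' @param test_fraction Per-bin holdout (default 0.2).
#' @param subsample Optional list(fractions = numeric, replicates =
#'   integer vector recycled over fractions); NULL for no subsampling.
#' @param seed Base seed; split and model seeds derive from it.
#' @param lstm_cfg [lstmConfig()] template for hybrid models (its seed is
#'   replaced by the derived model seed).
#' @param num_trees Forest size for RF/hybrid (default 500).
#' @return List: \code{metrics} (data.frame with one row per design cell x
#'   test order), \code{split}, \code{predictions} (named list of
#'   data.frames genotype/observed/predicted).
#' @export
runPredictionExperiment <- function(table,
                                    model_kinds = "random_forest",
                                    max_orders = 2L,
                                    test_orders = NULL,
                                    test_fraction = 0.2,
                                    subsample = NULL,
                                    seed = 1L,
                                    lstm_cfg = lstmConfig(),
                                    num_trees = 500L) {
  stopifnot(all(model_kinds %in% c("random_forest", "lstm_hybrid",
                                   "linear", "mlp")))
  split <- splitByOrder(table, test_fraction = test_fraction, seed = seed)
  d <- activityData(table)
  if (is.null(test_orders)) {
    po <- split$per_order
    test_orders <- po$order[po$n_test > 0L]
  }
  test_sets <- lapply(test_orders, function(o)
    split$test[genotypeOrder(split$test) == o])
  names(test_sets) <- test_orders
  fractions <- if (is.null(subsample)) 1 else subsample$fractions
  reps <- if (is.null(subsample)) 1L
  else rep_len(subsample$replicates, length(fractions))
  obs <- setNames(d$fraction_cleaved, d$genotype)

  metrics <- list(); predictions <- list(); counter <- 0L
  for (kind in model_kinds) {
    enc <- if (kind == "lstm_hybrid") "index" else "onehot"
    for (mo in max_orders) {
      base_data <- buildCumulativeTraining(split, table, mo, encoding = enc)
      for (fi in seq_along(fractions)) {
        for (rep_i in seq_len(if (is.null(subsample)) 1L else reps[fi])) {
          counter <- counter + 1L
          mseed <- modelSeedScheme(seed, counter)
          cell <- tryCatch({
            data <- if (fractions[fi] < 1)
              subsampleTraining(base_data, fractions[fi], seed = mseed)
            else base_data
            bundle <- switch(kind,
              random_forest = trainRandomForest(data, seed = mseed,
                                                num_trees = num_trees),
              lstm_hybrid = {
                cfg <- lstm_cfg; cfg$seed <- mseed
                trainHybrid(data, cfg = cfg, seed = mseed,
                            num_trees = num_trees)
              },
              linear = trainBaseline(data, "linear", seed = mseed),
              mlp = trainBaseline(data, "mlp", seed = mseed))
            rows <- list()
            for (o in names(test_sets)) {
              gts <- test_sets[[o]]
              if (length(gts) < 2L) next
              pred <- predict(bundle, gts)
              m <- computeMetrics(pred, unname(obs[gts]))
              key <- paste(kind, "max", mo, "frac", fractions[fi], "rep",
                           rep_i, "test", o, sep = "_")
              predictions[[key]] <- data.frame(genotype = gts,
                                                observed = unname(obs[gts]),
                                                predicted = pred)
              rows[[o]] <- data.frame(model = kind, max_order = mo,
                                      fraction = fractions[fi],
                                      replicate = rep_i,
                                      test_order = as.integer(o),
                                      n_train = length(data$targets),
                                      n_test = m$n,
                                      pearson_r = m$pearson_r,
                                      r_squared = m$r_squared,
                                      mse = m$mse, seed = mseed)
            }
            do.call(rbind, rows)
          }, error = function(e) {
            warning("cell failed (", kind, ", max_order ", mo, "): ",
                    conditionMessage(e))
            NULL
          })
          if (!is.null(cell)) metrics[[length(metrics) + 1L]] <- cell
        }
      }
    }
  }
  out_metrics <- do.call(rbind, metrics)
  rownames(out_metrics) <- NULL
  list(metrics = out_metrics, split = split, predictions = predictions)
}
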