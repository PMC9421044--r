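#' Build an encoded training/test dataset from an activity table
#'
#' Pairs each genotype's encoded sequence with its fraction-cleaved target.
#' Rows with missing (NA) targets are never admitted: they are dropped and
#' counted (\code{n_dropped}).
#'
#' @param table An [ActivityTable-class].
#' @param encoding \code{"onehot"} (n x 4L flattened position-major binary
#'   matrix, for tree/linear/MLP models) or \code{"index"} (n x L symbol
#'   indices, for the LSTM path).
#' @param genotypes Optional subset of genotype strings (default: all rows).
#' @return List of class \code{"encodedDataset"}: \code{features},
#'   \code{targets}, \code{genotype}, \code{encoding}, \code{reference},
#'   \code{n_dropped}.
#' @export
encodeDataset <- function(table, encoding = c("onehot", "index"),
                          genotypes = NULL) {
  encoding <- match.arg(encoding)
  d <- activityData(table)
  if (!is.null(genotypes)) {
    miss <- setdiff(genotypes, d$genotype)
    if (length(miss)) stop("genotypes not in table: ", paste(head(miss), collapse = ", "))
    d <- d[match(genotypes, d$genotype), , drop = FALSE]
  }
  keep <- !is.na(d$fraction_cleaved)
  n_dropped <- sum(!keep)
  d <- d[keep, , drop = FALSE]
  feats <- if (encoding == "onehot") oneHotEncode(d$genotype, refSequence(table))
  else indexEncode(d$genotype, refSequence(table))
  structure(list(features = feats, targets = d$fraction_cleaved,
                 genotype = d$genotype, encoding = encoding,
                 reference = refSequence(table), n_dropped = n_dropped),
            class = "encodedDataset")
}

datasetFingerprint <- function(data) {
  list(n = length(data$targets),
       target_sum = round(sum(data$targets), 10),
       encoding = data$encoding)
}

#' Train a random-forest activity regressor
#'
#' Fits a tree ensemble (\pkg{ranger}) on flattened one-hot features with
#' library-default hyperparameters (recorded in the bundle), impurity-based
#' feature importance, and a fixed seed on a single thread so predictions
#' are bitwise reproducible.
#'
#' @param data One-hot [encodeDataset()] output.
#' @param seed Integer training seed.
#' @param num_trees Ensemble size (default 500, the library default).
#' @return A [RegressorBundle-class] of kind \code{"random_forest"}.
#' @export
trainRandomForest <- function(data, seed = 1L, num_trees = 500L) {
  if (data$encoding != "onehot") stop("random forest needs one-hot features")
  if (length(data$targets) < 2L) stop("need at least 2 training rows")
  df <- as.data.frame(data$features)
  df$..y <- data$targets
  fit <- ranger::ranger(dependent.variable.name = "..y", data = df,
                        num.trees = num_trees, importance = "impurity",
                        seed = as.integer(seed), num.threads = 1L)
  new("RegressorBundle", kind = "random_forest",
      fit = list(model = fit,
                 hyper = list(num_trees = num_trees,
                              mtry = fit$mtry,
                              min_node_size = fit$min.node.size,
                              engine = "ranger")),
      encoding = "onehot", reference = data$reference,
      seed = as.integer(seed), fingerprint = datasetFingerprint(data))
}

#' Train the LSTM-feature hybrid regressor
#'
#' Two-stage pipeline: an LSTM extractor trained against fraction cleaved
#' ([trainLstmExtractor()]), whose final hidden state h_n for each training
#' sequence becomes the feature vector for a random-forest regressor. Both
#' stages are persisted in the bundle.
#'
#' @param data Index-encoded [encodeDataset()] output.
#' @param cfg [lstmConfig()] for the extractor stage.
#' @param seed Seed for the random-forest stage.
#' @param num_trees Forest size (default 500).
#' @return A [RegressorBundle-class] of kind \code{"lstm_hybrid"}.
#' @export
trainHybrid <- function(data, cfg = lstmConfig(), seed = 1L,
                        num_trees = 500L) {
  if (data$encoding != "index") stop("hybrid model needs index encoding")
  extractor <- trainLstmExtractor(data, cfg)
  h <- lstmFeatures(extractor, data$features)
  df <- as.data.frame(h)
  df$..y <- data$targets
  fit <- ranger::ranger(dependent.variable.name = "..y", data = df,
                        num.trees = num_trees, importance = "none",
                        seed = as.integer(seed), num.threads = 1L)
  new("RegressorBundle", kind = "lstm_hybrid",
      fit = list(extractor = extractor, model = fit,
                 hyper = list(num_trees = num_trees, lstm = unclass(cfg))),
      encoding = "index", reference = data$reference,
      seed = as.integer(seed), fingerprint = datasetFingerprint(data))
}

#' Train a baseline regressor (linear or MLP)
#'
#' Benchmarks on flattened one-hot features: ordinary least squares
#' (rank-deficient designs fall back to ridge with lambda = 1e-6, recorded
#' in the bundle) or a small single-hidden-layer feedforward network
#' (\pkg{nnet}, 16 units, weight decay 1e-4).
#'
#' @param data One-hot [encodeDataset()] output.
#' @param kind \code{"linear"} or \code{"mlp"}.
#' @param seed Integer seed (MLP initialization).
#' @return A [RegressorBundle-class].
#' @export
trainBaseline <- function(data, kind = c("linear", "mlp"), seed = 1L) {
  kind <- match.arg(kind)
  if (data$encoding != "onehot") stop("baselines need one-hot features")
  X <- data$features
  y <- data$targets
  if (kind == "linear") {
    Xi <- cbind(`(Intercept)` = 1, X)
    fit0 <- lm.fit(Xi, y)
    if (fit0$rank < ncol(Xi)) {
      lambda <- 1e-6
      XtX <- crossprod(Xi) + diag(lambda, ncol(Xi))
      beta <- solve(XtX, crossprod(Xi, y))
      coef <- drop(beta); ridge <- TRUE
    } else {
      coef <- fit0$coefficients; ridge <- FALSE
    }
    coef[is.na(coef)] <- 0
    fit <- list(coef = coef, ridge = ridge)
  } else {
    set.seed(as.integer(seed))
    net <- nnet::nnet(X, y, size = 16L, linout = TRUE, decay = 1e-4,
                      maxit = 300L, trace = FALSE,
                      MaxNWts = (ncol(X) + 2L) * 16L + 32L)
    fit <- list(net = net)
  }
  new("RegressorBundle", kind = kind, fit = fit, encoding = "onehot",
      reference = data$reference, seed = as.integer(seed),
      fingerprint = datasetFingerprint(data))
}

#' Predict activities for genotypes with a trained bundle
#'
#' Encodes the genotypes under the bundle's contract and returns one raw
#' regressor output per genotype, order-preserving. Raw values may fall
#' slightly outside [0,1]; set \code{clip = TRUE} to clamp (off by
#' default — scatter comparisons use raw outputs).
#'
#' @param object A [RegressorBundle-class].
#' @param genotype Character vector of genotype strings.
#' @param clip Clamp predictions to [0,1] (default FALSE).
#' @param ... Ignored.
#' @return Numeric vector aligned to \code{genotype}.
#' @export
setMethod("predict", "RegressorBundle",
  function(object, genotype, clip = FALSE, ...) {
    if (!length(genotype)) return(numeric(0))
    out <- switch(object@kind,
      random_forest = {
        X <- oneHotEncode(genotype, object@reference)
        stats::predict(object@fit$model, data = as.data.frame(X),
                       num.threads = 1L)$predictions
      },
      lstm_hybrid = {
        idx <- indexEncode(genotype, object@reference)
        h <- lstmFeatures(object@fit$extractor, idx)
        stats::predict(object@fit$model, data = as.data.frame(h),
                       num.threads = 1L)$predictions
      },
      linear = {
        X <- cbind(1, oneHotEncode(genotype, object@reference))
        drop(X %*% object@fit$coef)
      },
      mlp = {
        X <- oneHotEncode(genotype, object@reference)
        drop(stats::predict(object@fit$net, X))
      })
    if (clip) out <- pmin(1, pmax(0, out))
    unname(out)
  })

#' Feature importance of a one-hot random-forest bundle
#'
#' Maps the forest's impurity-based importances back to (position, base)
#' labels, normalized to sum 1, with a per-position aggregate (sum over
#' the three alternative bases plus the reference column). Only defined
#' for \code{kind == "random_forest"}: hybrid features are latent and
#' carry no positional mapping.
#'
#' @param bundle A random-forest [RegressorBundle-class].
#' @return List: \code{features} (data.frame position, base, importance;
#'   sorted descending), \code{per_position} (named numeric, sums to 1),
#'   \code{degenerate} (TRUE when the forest carried no impurity signal,
#'   e.g. constant targets; importances then near-uniform by convention).
#' @export
featureImportance <- function(bundle) {
  if (bundleKind(bundle) != "random_forest")
    stop("feature importance is only supported for random_forest bundles (got ",
         bundleKind(bundle), ")")
  imp <- ranger::importance(bundle@fit$model)
  degenerate <- sum(imp) <= 0 || all(!is.finite(imp))
  if (degenerate) imp[] <- 1
  imp <- pmax(imp, 0)
  imp <- imp / sum(imp)
  pos <- as.integer(sub("\\..*$", "", names(imp)))
  base <- sub("^.*\\.", "", names(imp))
  feats <- data.frame(position = pos, base = base, importance = unname(imp),
                      stringsAsFactors = FALSE)
  feats <- feats[order(-feats$importance, feats$position, feats$base), ]
  rownames(feats) <- NULL
  per_pos <- tapply(feats$importance, feats$position, sum)
  per_pos <- setNames(as.numeric(per_pos), names(per_pos))
  per_pos <- per_pos[order(as.integer(names(per_pos)))]
  list(features = feats, per_position = per_pos, degenerate = degenerate)
}

#' Persist / restore a trained bundle
#'
#' A versioned directory with human-readable JSON metadata (kind, encoding,
#' seed, fingerprint, hyperparameters) plus the opaque fitted state.
#'
#' @param bundle A [RegressorBundle-class].
#' @param dir Target directory (created).
#' @return \code{dir}, invisibly (save); a [RegressorBundle-class] (load).
#' @export
saveBundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(format_version = 1L, kind = bundle@kind,
               encoding = bundle@encoding, reference = bundle@reference,
               seed = bundle@seed, fingerprint = bundle@fingerprint,
               hyper = bundle@fit$hyper)
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  saveRDS(bundle@fit, file.path(dir, "state.rds"))
  invisible(dir)
}

#' @rdname saveBundle
#' @export
loadBundle <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  fit <- readRDS(file.path(dir, "state.rds"))
  new("RegressorBundle", kind = meta$kind, fit = fit,
      encoding = meta$encoding, reference = meta$reference,
      seed = as.integer(meta$seed),
      fingerprint = as.list(meta$fingerprint))
}
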