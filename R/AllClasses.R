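#' ActivityTable: per-genotype cleavage counts and fraction cleaved
#'
#' The central container of the pipeline: one row per genotype with cleaved
#' and uncleaved read counts, total, the activity estimate
#' \eqn{fraction\ cleaved = cleaved / (cleaved + uncleaved)}, and the
#' mutational order. Rows whose total falls below the \code{min_reads}
#' threshold recorded in the provenance carry \code{NA} fraction cleaved
#' (an explicit missing marker, never a silent zero).
#'
#' @slot data data.frame with columns \code{genotype}, \code{cleaved},
#'   \code{uncleaved}, \code{total}, \code{fraction_cleaved}, \code{order}.
#' @slot reference Reference sequence (canonical RNA form, 1-based positions).
#' @slot provenance Named list: source files, filter settings, seeds,
#'   rejection tallies.
#' @export
setClass("ActivityTable",
  representation(data = "data.frame", reference = "character",
                 provenance = "list"),
  prototype(provenance = list()))

setValidity("ActivityTable", function(object) {
  d <- object@data
  need <- c("genotype", "cleaved", "uncleaved", "total", "fraction_cleaved", "order")
  if (!all(need %in% names(d)))
    return(paste("data must have columns:", paste(need, collapse = ", ")))
  if (length(object@reference) != 1L) return("reference must be a single string")
  if (anyDuplicated(d$genotype)) return("duplicate genotype rows")
  if (any(d$cleaved < 0 | d$uncleaved < 0)) return("negative counts")
  if (!all(d$total == d$cleaved + d$uncleaved)) return("total != cleaved + uncleaved")
  fc <- d$fraction_cleaved
  if (any(!is.na(fc) & (fc < 0 | fc > 1))) return("fraction_cleaved outside [0,1]")
  TRUE
})

#' Construct an ActivityTable
#'
#' @param genotype Character vector of genotype strings.
#' @param cleaved,uncleaved Non-negative integer count vectors.
#' @param ref Reference sequence.
#' @param min_reads Minimum total reads for a defined fraction cleaved
#'   (default 1); rows below it get \code{NA}.
#' @param provenance Optional named list recorded verbatim.
#' @return An [ActivityTable-class] object.
#' @export
activityTable <- function(genotype, cleaved, uncleaved, ref, min_reads = 1L,
                          provenance = list()) {
  ref <- riboReference(ref)
  total <- cleaved + uncleaved
  fc <- fractionCleaved(cleaved, uncleaved, min_reads = min_reads)
  d <- data.frame(genotype = genotype, cleaved = cleaved, uncleaved = uncleaved,
                  total = total, fraction_cleaved = fc,
                  order = genotypeOrder(genotype), stringsAsFactors = FALSE)
  provenance$min_reads <- min_reads
  new("ActivityTable", data = d, reference = ref, provenance = provenance)
}

#' @describeIn ActivityTable-class the underlying data.frame
#' @param x,object An ActivityTable.
#' @export
activityData <- function(x) x@data

#' @describeIn ActivityTable-class the reference sequence
#' @export
refSequence <- function(x) x@reference

#' @describeIn ActivityTable-class provenance list
#' @export
provenance <- function(x) x@provenance

setMethod("show", "ActivityTable", function(object) {
  d <- object@data
  cat("ActivityTable:", nrow(d), "genotypes on a", nchar(object@reference),
      "nt reference\n")
  if (nrow(d)) {
    tab <- table(d$order)
    cat("  orders:", paste0(names(tab), " (", tab, ")", collapse = ", "), "\n")
    cat("  fraction cleaved: defined for", sum(!is.na(d$fraction_cleaved)),
        "rows; wild-type",
        if ("WT" %in% d$genotype)
          sprintf("%.3f", d$fraction_cleaved[d$genotype == "WT"]) else "absent",
        "\n")
  }
})

#' LandscapeModel: synthetic ground-truth activity surface
#'
#' A seeded generative model of ribozyme activity: a latent score
#' \eqn{baseline + \sum additive + \sum pairwise (+ \sum threeway)} over a
#' genotype's mutations, pushed through a monotone link onto [0,1]. The
#' pairwise terms plant compensatory base-pair epistasis (each single break
#' deleterious, the paired double restored) over a background of negative
#' epistasis; the optional three-way terms plant higher-order structure
#' invisible in double-mutant data.
#'
#' @slot reference Reference sequence.
#' @slot baseline Latent wild-type score.
#' @slot additive Named numeric, one entry per (position, alt) keyed
#'   \code{"<pos><alt>"}.
#' @slot pairwise Named numeric keyed \code{"<posA><altA>|<posB><altB>"}
#'   (position-sorted).
#' @slot threeway Named numeric keyed over sorted mutation triples.
#' @slot link \code{"logistic"} (activity = plogis(latent)) or \code{"exp"}
#'   (activity = min(1, exp(latent)); exactly multiplicative activities).
#' @slot compensatory data.frame of planted pairs: columns \code{pos_i},
#'   \code{alt_i}, \code{pos_j}, \code{alt_j}.
#' @slot seed Integer seed the model was drawn with.
#' @slot config Named list of generator settings (for JSON dumps).
#' @export
setClass("LandscapeModel",
  representation(reference = "character", baseline = "numeric",
                 additive = "numeric", pairwise = "numeric",
                 threeway = "numeric", link = "character",
                 compensatory = "data.frame", seed = "integer",
                 config = "list"))

setValidity("LandscapeModel", function(object) {
  if (!object@link %in% c("logistic", "exp"))
    return("link must be 'logistic' or 'exp'")
  L <- nchar(object@reference)
  if (length(object@additive) != 3L * L)
    return("additive must hold one term per single mutation (3L)")
  TRUE
})

setMethod("show", "LandscapeModel", function(object) {
  cat("LandscapeModel on a", nchar(object@reference), "nt reference;",
      "link:", object@link, "\n")
  cat("  baseline latent", sprintf("%.3f", object@baseline),
      "-> wild-type activity",
      sprintf("%.3f", trueActivity(object, "WT")), "\n")
  cat(" ", nrow(object@compensatory), "compensatory pair(s),",
      length(object@pairwise), "pairwise term(s),",
      length(object@threeway), "three-way term(s); seed", object@seed, "\n")
})

#' RegressorBundle: a trained activity predictor
#'
#' Wraps a fitted regressor (random forest, LSTM-feature hybrid, linear or
#' MLP baseline) together with its encoding contract, reference and seed so
#' that predictions are reproducible and persistable.
#'
#' @slot kind One of \code{"random_forest"}, \code{"lstm_hybrid"},
#'   \code{"linear"}, \code{"mlp"}.
#' @slot fit Opaque fitted state (list).
#' @slot encoding \code{"onehot"} or \code{"index"}.
#' @slot reference Reference sequence the encoding is anchored to.
#' @slot seed Training seed.
#' @slot fingerprint Training-set fingerprint (n, target digest).
#' @export
setClass("RegressorBundle",
  representation(kind = "character", fit = "list", encoding = "character",
                 reference = "character", seed = "integer",
                 fingerprint = "list"))

setValidity("RegressorBundle", function(object) {
  if (!object@kind %in% c("random_forest", "lstm_hybrid", "linear", "mlp"))
    return("unknown regressor kind")
  TRUE
})

setMethod("show", "RegressorBundle", function(object) {
  cat("RegressorBundle:", object@kind, "| encoding:", object@encoding,
      "| trained on n =", object@fingerprint$n, "| seed", object@seed, "\n")
})

#' @describeIn RegressorBundle-class model kind
#' @param x A RegressorBundle.
#' @export
bundleKind <- function(x) x@kind
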