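#' Pairwise epistasis statistic
#'
#' \eqn{\epsilon = \log_{10}(W_{AB} W_{wt} / (W_A W_B))}, where the W are
#' fraction-cleaved activities of the wild-type, the two single mutants and
#' the double mutant. Negative values mean the combination is worse than
#' the multiplicative expectation. Vectorized; any non-positive or missing
#' activity yields \code{NA} (the record is undefined, to be excluded and
#' counted by callers, never replaced by a pseudocount).
#'
#' @param W_wt,W_A,W_B,W_AB Fraction-cleaved activities.
#' @return Numeric vector of epsilon values.
#' @export
pairwiseEpistasis <- function(W_wt, W_A, W_B, W_AB) {
  n <- max(length(W_wt), length(W_A), length(W_B), length(W_AB))
  W_wt <- rep_len(W_wt, n); W_A <- rep_len(W_A, n)
  W_B <- rep_len(W_B, n); W_AB <- rep_len(W_AB, n)
  ok <- !is.na(W_wt) & !is.na(W_A) & !is.na(W_B) & !is.na(W_AB) &
    W_wt > 0 & W_A > 0 & W_B > 0 & W_AB > 0
  out <- rep(NA_real_, n)
  out[ok] <- log10((W_AB[ok] * W_wt[ok]) / (W_A[ok] * W_B[ok]))
  out
}

#' Epistasis distribution over all double mutants of a table
#'
#' Computes one epistasis record per double mutant whose two constituent
#' single mutants and the wild-type are present with positive activity;
#' the rest are tallied by exclusion reason.
#'
#' @param table An [ActivityTable-class] containing the wild-type, single
#'   and double mutants.
#' @return List with \code{records} (data.frame: mutation_a, mutation_b,
#'   W_wt, W_A, W_B, W_AB, epsilon), \code{exclusions} (named counts:
#'   missing_single, nonpositive_activity, missing_double_activity), and
#'   \code{summary} (n, mean, quantiles of epsilon).
#' @export
epistasisDistribution <- function(table) {
  d <- activityData(table)
  wt <- d$fraction_cleaved[d$genotype == "WT"]
  if (!length(wt)) stop("table lacks a wild-type row")
  if (is.na(wt) || wt <= 0) stop("wild-type activity missing or non-positive")
  fc <- setNames(d$fraction_cleaved, d$genotype)
  doubles <- d$genotype[d$order == 2L]
  toks <- strsplit(doubles, ";", fixed = TRUE)
  a <- vapply(toks, `[`, "", 1L)
  b <- vapply(toks, `[`, "", 2L)
  W_A <- fc[a]; W_B <- fc[b]; W_AB <- fc[doubles]
  missing_single <- is.na(match(a, names(fc))) | is.na(match(b, names(fc)))
  reason <- rep(NA_character_, length(doubles))
  reason[is.na(W_AB)] <- "missing_double_activity"
  nonpos <- !missing_single &
    (is.na(W_A) | is.na(W_B) | W_A <= 0 | W_B <= 0 |
       (!is.na(W_AB) & W_AB <= 0))
  reason[nonpos & is.na(reason)] <- "nonpositive_activity"
  reason[missing_single] <- "missing_single"
  keep <- is.na(reason)
  eps <- pairwiseEpistasis(wt, W_A[keep], W_B[keep], W_AB[keep])
  records <- data.frame(mutation_a = a[keep], mutation_b = b[keep],
                        W_wt = wt, W_A = unname(W_A[keep]),
                        W_B = unname(W_B[keep]), W_AB = unname(W_AB[keep]),
                        epsilon = eps, stringsAsFactors = FALSE)
  excl <- table(factor(reason[!keep], levels = c("missing_single",
                                                 "nonpositive_activity",
                                                 "missing_double_activity")))
  qs <- if (nrow(records))
    quantile(records$epsilon, c(0, 0.25, 0.5, 0.75, 1), names = TRUE)
  else setNames(rep(NA_real_, 5L), c("0%", "25%", "50%", "75%", "100%"))
  list(records = records,
       exclusions = as.list(excl),
       summary = list(n = nrow(records),
                      mean = if (nrow(records)) mean(records$epsilon) else NA_real_,
                      quantiles = qs))
}

#' Double-mutant activity matrix (heatmap data)
#'
#' Arranges (relative) activities of all double mutants on a square grid
#' whose axes are the 3L single-mutation features \code{"<ref><pos><alt>"}.
#' Symmetric by construction; cells for two mutations at the same position
#' (which cannot co-occur) and absent doubles are \code{NA}. The singles'
#' own activities are attached as the \code{"singles"} attribute.
#'
#' @param table An [ActivityTable-class].
#' @param normalize_to_wildtype Divide by the wild-type fraction cleaved
#'   (default TRUE, the usual heatmap display).
#' @return 3L x 3L numeric matrix with mutation-token dimnames.
#' @export
doubleMutantMatrix <- function(table, normalize_to_wildtype = TRUE) {
  d <- activityData(table)
  ref <- refSequence(table)
  feats <- enumerateSingleMutants(ref)
  scale <- 1
  if (normalize_to_wildtype) {
    wt <- d$fraction_cleaved[d$genotype == "WT"]
    if (!length(wt) || is.na(wt) || wt <= 0)
      stop("wild-type activity needed for normalization")
    scale <- wt
  }
  M <- matrix(NA_real_, length(feats), length(feats),
              dimnames = list(feats, feats))
  doubles <- d[d$order == 2L, , drop = FALSE]
  if (nrow(doubles)) {
    toks <- strsplit(doubles$genotype, ";", fixed = TRUE)
    a <- vapply(toks, `[`, "", 1L)
    b <- vapply(toks, `[`, "", 2L)
    val <- doubles$fraction_cleaved / scale
    M[cbind(a, b)] <- val
    M[cbind(b, a)] <- val
  }
  singles <- d[d$order == 1L, , drop = FALSE]
  sv <- setNames(rep(NA_real_, length(feats)), feats)
  sv[singles$genotype] <- singles$fraction_cleaved / scale
  attr(M, "singles") <- sv
  M
}
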