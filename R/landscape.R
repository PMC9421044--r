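#' Build the genotype (Hamming) network of a fitness landscape
#'
#' Nodes are the table's genotypes; undirected edges join every pair of
#' genotypes whose full sequences differ at exactly one position. Neighbor
#' search indexes genotypes by their sequence with one position wildcarded
#' (L buckets per genotype) rather than comparing all pairs, and equals the
#' brute-force all-pairs adjacency on small inputs.
#'
#' @param table An [ActivityTable-class].
#' @param quintiles Attach activity quintile node attributes via
#'   [quintileBins()] (default TRUE when >= 5 activities are defined).
#' @return An \pkg{igraph} undirected graph with vertex attributes
#'   \code{genotype}, \code{fraction_cleaved}, \code{order} and (optionally)
#'   \code{quintile}.
#' @export
buildGenotypeNetwork <- function(table, quintiles = NULL) {
  d <- activityData(table)
  if (!nrow(d)) stop("empty activity table")
  ref <- refSequence(table)
  L <- nchar(ref)
  seqs <- genotypeToSequence(d$genotype, ref)
  if (anyDuplicated(seqs)) stop("duplicate sequences in table")
  edges <- vector("list", L)
  for (p in seq_len(L)) {
    key <- paste0(substr(seqs, 1L, p - 1L), "*", substr(seqs, p + 1L, L))
    grp <- split(seq_along(seqs), key)
    grp <- grp[lengths(grp) > 1L]
    if (length(grp))
      edges[[p]] <- do.call(cbind, lapply(grp, utils::combn, m = 2L))
  }
  em <- do.call(cbind, edges[!vapply(edges, is.null, TRUE)])
  g <- igraph::make_empty_graph(n = nrow(d), directed = FALSE)
  if (!is.null(em)) g <- igraph::add_edges(g, as.vector(em))
  igraph::V(g)$name <- d$genotype
  igraph::V(g)$genotype <- d$genotype
  igraph::V(g)$fraction_cleaved <- d$fraction_cleaved
  igraph::V(g)$order <- d$order
  if (is.null(quintiles)) quintiles <- sum(!is.na(d$fraction_cleaved)) >= 5L
  if (quintiles) {
    qb <- quintileBins(table)
    igraph::V(g)$quintile <- unname(qb$bins[d$genotype])
  }
  g
}

#' Bin genotypes into activity quintiles
#'
#' Default: five equal-width activity bins over \code{limits} (right-closed
#' intervals, lowest bin closed on both sides), matching a value-range
#' reading of "quintiles of ribozyme activity"; \code{method = "count"}
#' gives rank-based equal-count quintiles instead.
#'
#' @param table An [ActivityTable-class].
#' @param method \code{"width"} (default) or \code{"count"}.
#' @param limits Activity range for width binning (default \code{c(0, 1)}).
#' @return List: \code{bins} (named integer vector, genotype -> 1..5; NA
#'   for undefined activities), \code{counts} (length-5 integer vector),
#'   \code{method}, \code{breaks}.
#' @export
quintileBins <- function(table, method = c("width", "count"),
                         limits = c(0, 1)) {
  method <- match.arg(method)
  d <- activityData(table)
  fc <- d$fraction_cleaved
  if (all(is.na(fc))) stop("no defined activities to bin")
  if (method == "width") {
    breaks <- seq(limits[1L], limits[2L], length.out = 6L)
    idx <- cut(fc, breaks = breaks, include.lowest = TRUE, labels = FALSE,
               right = TRUE)
  } else {
    breaks <- quantile(fc, probs = seq(0, 1, 0.2), na.rm = TRUE)
    idx <- findInterval(fc, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  }
  bins <- setNames(as.integer(idx), d$genotype)
  counts <- tabulate(idx, nbins = 5L)
  list(bins = bins, counts = counts, method = method, breaks = breaks)
}

#' Export a genotype network as an edge-list TSV
#'
#' @param g Graph from [buildGenotypeNetwork()].
#' @param path Output TSV path (columns: from, to).
#' @return \code{path}, invisibly.
#' @export
writeNetworkEdges <- function(g, path) {
  el <- igraph::as_edgelist(g)
  write.table(data.frame(from = el[, 1L], to = el[, 2L]), path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
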