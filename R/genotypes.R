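#' @import methods
#' @importFrom stats rbinom rnorm rpois rnbinom runif setNames cor quantile lm.fit predict
#' @importFrom utils head write.table read.table
NULL

RIBO_ALPHABET <- c("A", "C", "G", "U")

#' Normalize and validate a reference sequence
#'
#' Accepts an RNA or DNA string (case-insensitive, \code{T} is converted to
#' \code{U}) and returns the canonical uppercase RNA form used throughout the
#' package. Positions are 1-based, so the naming convention \code{G1}
#' (first nucleotide), \code{U20}, and so on refers directly to string
#' offsets.
#'
#' @param ref Character scalar over \code{A,C,G,U/T}.
#' @return Uppercase RNA character scalar.
#' @examples
#' riboReference("gattaca")  # "GAUUACA"
#' @export
riboReference <- function(ref) {
  if (!is.character(ref) || length(ref) != 1L || is.na(ref) || nchar(ref) < 1L)
    stop("reference must be a single non-empty character string")
  x <- chartr("t", "u", tolower(ref))
  x <- toupper(x)
  bases <- strsplit(x, "", fixed = TRUE)[[1L]]
  bad <- setdiff(unique(bases), RIBO_ALPHABET)
  if (length(bad))
    stop("reference contains non-ACGU(T) symbols: ", paste(bad, collapse = ", "))
  x
}

refBases <- function(ref) strsplit(ref, "", fixed = TRUE)[[1L]]

#' Parse a genotype string into a mutation table
#'
#' Genotypes are written as semicolon-joined substitution tokens
#' \code{"<refbase><pos><altbase>"}, e.g. \code{"G1A;U20C"}; the wild-type is
#' \code{"WT"}. Tokens are canonically ordered by position.
#'
#' @param genotype Character scalar in genotype string syntax.
#' @param ref Reference sequence (validated with [riboReference()]); if
#'   supplied, each token's reference base is checked against it.
#' @return A data.frame with columns \code{pos}, \code{ref}, \code{alt};
#'   zero rows for the wild-type.
#' @export
parseGenotype <- function(genotype, ref = NULL) {
  if (!is.character(genotype) || length(genotype) != 1L || is.na(genotype))
    stop("genotype must be a single character string")
  if (toupper(genotype) == "WT" || genotype == "")
    return(data.frame(pos = integer(0), ref = character(0), alt = character(0),
                      stringsAsFactors = FALSE))
  toks <- chartr("T", "U", toupper(strsplit(genotype, ";", fixed = TRUE)[[1L]]))
  m <- regmatches(toks, regexec("^([ACGU])([0-9]+)([ACGU])$", toks))
  ok <- vapply(m, length, 1L) == 4L
  if (!all(ok)) stop("malformed genotype token(s): ", paste(toks[!ok], collapse = ", "))
  pos <- vapply(m, function(z) as.integer(z[3L]), 1L)
  refb <- vapply(m, function(z) z[2L], "")
  altb <- vapply(m, function(z) z[4L], "")
  if (anyDuplicated(pos)) stop("duplicate positions in genotype: ", genotype)
  if (any(refb == altb)) stop("alt base equals ref base in genotype: ", genotype)
  o <- order(pos)
  out <- data.frame(pos = pos[o], ref = refb[o], alt = altb[o], stringsAsFactors = FALSE)
  if (!is.null(ref)) {
    rb <- refBases(ref)
    if (any(out$pos > length(rb)))
      stop("genotype position exceeds reference length ", length(rb))
    mism <- rb[out$pos] != out$ref
    if (any(mism))
      stop("genotype ref base disagrees with reference at position ",
           paste(out$pos[mism], collapse = ", "))
  }
  out
}

#' Format a mutation table as a canonical genotype string
#'
#' @param mut data.frame with columns \code{pos}, \code{ref}, \code{alt}.
#' @return Canonical genotype string (\code{"WT"} for zero mutations).
#' @export
formatGenotype <- function(mut) {
  if (nrow(mut) == 0L) return("WT")
  o <- order(mut$pos)
  paste0(mut$ref[o], mut$pos[o], mut$alt[o], collapse = ";")
}

#' Mutational order (distance from wild-type) of genotype strings
#'
#' @param genotype Character vector of genotype strings.
#' @return Integer vector: number of substitutions per genotype.
#' @export
genotypeOrder <- function(genotype) {
  ifelse(toupper(genotype) == "WT" | genotype == "", 0L,
         lengths(strsplit(genotype, ";", fixed = TRUE)))
}

# batch parser: one regex pass over all tokens of many genotypes.
# returns data.frame(row, pos, ref, alt); validates against ref when given.
parseGenotypeTokens <- function(genotype, ref = NULL) {
  is_wt <- toupper(genotype) == "WT" | genotype == ""
  toks <- strsplit(genotype, ";", fixed = TRUE)
  toks[is_wt] <- list(character(0))
  row <- rep(seq_along(genotype), lengths(toks))
  tk <- toupper(chartr("T", "U", unlist(toks)))
  if (!length(tk))
    return(data.frame(row = integer(0), pos = integer(0),
                      ref = character(0), alt = character(0)))
  ok <- grepl("^[ACGU][0-9]+[ACGU]$", tk)
  if (!all(ok)) stop("malformed genotype token(s): ",
                     paste(head(unique(tk[!ok])), collapse = ", "))
  pos <- as.integer(substr(tk, 2L, nchar(tk) - 1L))
  refb <- substr(tk, 1L, 1L)
  altb <- substr(tk, nchar(tk), nchar(tk))
  if (any(refb == altb)) stop("alt base equals ref base in genotype token")
  if (!is.null(ref)) {
    rb <- refBases(ref)
    if (any(pos > length(rb))) stop("genotype position exceeds reference length")
    if (any(rb[pos] != refb))
      stop("genotype ref base disagrees with reference")
  }
  dup <- duplicated(cbind(row, pos))
  if (any(dup)) stop("duplicate positions within a genotype")
  data.frame(row = row, pos = pos, ref = refb, alt = altb)
}

#' Reconstruct full variant sequences from genotype strings
#'
#' @param genotype Character vector of genotype strings.
#' @param ref Reference sequence.
#' @return Character vector of full-length RNA sequences.
#' @export
genotypeToSequence <- function(genotype, ref) {
  ref <- riboReference(ref)
  rb <- refBases(ref)
  L <- length(rb)
  mut <- parseGenotypeTokens(genotype, ref)
  M <- matrix(rb, nrow = length(genotype), ncol = L, byrow = TRUE)
  if (nrow(mut)) M[cbind(mut$row, mut$pos)] <- mut$alt
  apply(M, 1L, paste, collapse = "")
}

#' Express full sequences as genotype strings relative to a reference
#'
#' @param seqs Character vector of sequences, each the same length as the
#'   reference (DNA accepted, normalized to RNA).
#' @param ref Reference sequence.
#' @return Character vector of canonical genotype strings.
#' @export
sequenceToGenotype <- function(seqs, ref) {
  ref <- riboReference(ref)
  rb <- refBases(ref)
  L <- length(rb)
  vapply(seqs, function(s) {
    s <- toupper(chartr("Tt", "Uu", s))
    sb <- strsplit(s, "", fixed = TRUE)[[1L]]
    if (length(sb) != L) stop("sequence length ", length(sb),
                              " does not match reference length ", L)
    d <- which(sb != rb)
    if (!length(d)) return("WT")
    paste0(rb[d], d, sb[d], collapse = ";")
  }, "", USE.NAMES = FALSE)
}

#' Enumerate all single mutants of a reference
#'
#' Produces the 3L order-1 genotypes in deterministic order (position, then
#' alternative base A<C<G<U); 207 for a 69-nt ribozyme.
#'
#' @param ref Reference sequence.
#' @return Character vector of genotype strings.
#' @export
enumerateSingleMutants <- function(ref) {
  ref <- riboReference(ref)
  rb <- refBases(ref)
  out <- character(0)
  for (i in seq_along(rb)) {
    alts <- setdiff(RIBO_ALPHABET, rb[i])
    out <- c(out, paste0(rb[i], i, alts))
  }
  out
}

#' Enumerate all double mutants of a reference
#'
#' Produces the 9 C(L,2) order-2 genotypes in deterministic order; 21,114
#' for a 69-nt ribozyme.
#'
#' @param ref Reference sequence.
#' @return Character vector of genotype strings.
#' @export
enumerateDoubleMutants <- function(ref) {
  ref <- riboReference(ref)
  rb <- refBases(ref)
  L <- length(rb)
  if (L < 2L) stop("reference of length ", L, " has no position pairs")
  res <- vector("list", L * (L - 1L) / 2L)
  k <- 0L
  for (i in seq_len(L - 1L)) {
    ai <- paste0(rb[i], i, setdiff(RIBO_ALPHABET, rb[i]))
    for (j in (i + 1L):L) {
      aj <- paste0(rb[j], j, setdiff(RIBO_ALPHABET, rb[j]))
      k <- k + 1L
      res[[k]] <- paste(rep(ai, each = 3L), rep(aj, times = 3L), sep = ";")
    }
  }
  unlist(res)
}

#' Construct a variable-position scheme
#'
#' Describes a combinatorial (e.g. phylogenetically derived) library: a set
#' of positions each with its allowed alternative bases.
#'
#' @param pos Integer vector of distinct 1-based positions.
#' @param alts List of character vectors: allowed alternative bases per
#'   position (reference base excluded).
#' @param ref Reference sequence used to validate entries.
#' @return A data.frame with columns \code{pos}, \code{ref}, and list column
#'   \code{alts}, ordered by position.
#' @export
variableScheme <- function(pos, alts, ref) {
  ref <- riboReference(ref)
  rb <- refBases(ref)
  pos <- as.integer(pos)
  if (anyDuplicated(pos)) stop("duplicate positions in scheme")
  if (length(pos) != length(alts)) stop("pos and alts lengths differ")
  if (any(pos < 1L | pos > length(rb))) stop("scheme position out of range")
  alts <- lapply(alts, function(a) toupper(chartr("T", "U", a)))
  for (k in seq_along(pos)) {
    if (!length(alts[[k]])) stop("empty alternative set at position ", pos[k])
    if (rb[pos[k]] %in% alts[[k]])
      stop("alternative set at position ", pos[k], " contains the reference base")
    if (!all(alts[[k]] %in% RIBO_ALPHABET))
      stop("invalid base in alternative set at position ", pos[k])
  }
  o <- order(pos)
  out <- data.frame(pos = pos[o], ref = rb[pos[o]], stringsAsFactors = FALSE)
  out$alts <- alts[o]
  out
}

#' Enumerate the combinatorial variants of a variable-position scheme
#'
#' Full Cartesian product of \{reference base\} plus allowed alternatives at
#' each scheme position; the all-reference combination is the wild-type.
#'
#' @param ref Reference sequence.
#' @param scheme Scheme from [variableScheme()].
#' @param include_wildtype Keep the order-0 combination (default TRUE).
#' @return Character vector of genotype strings.
#' @export
enumerateCombinatorialVariants <- function(ref, scheme, include_wildtype = TRUE) {
  ref <- riboReference(ref)
  if (nrow(scheme) == 0L) return(if (include_wildtype) "WT" else character(0))
  choices <- lapply(seq_len(nrow(scheme)), function(k) {
    c("", paste0(scheme$ref[k], scheme$pos[k], scheme$alts[[k]]))
  })
  grid <- do.call(expand.grid, c(rev(choices), stringsAsFactors = FALSE))
  grid <- grid[, rev(seq_along(choices)), drop = FALSE]
  out <- apply(grid, 1L, function(row) {
    toks <- row[row != ""]
    if (!length(toks)) "WT" else paste(toks, collapse = ";")
  })
  out <- unname(out)
  if (!include_wildtype) out <- out[out != "WT"]
  out
}

#' Hamming distance between genotypes
#'
#' Number of sequence positions at which the reconstructed variants differ.
#' Vectorized over pairs; \code{hammingDistance(g, "WT")} equals the
#' mutational order of \code{g}.
#'
#' @param a,b Character vectors of genotype strings (recycled to equal
#'   length) on the same reference.
#' @param ref Reference sequence.
#' @return Integer vector of distances.
#' @export
hammingDistance <- function(a, b, ref) {
  ref <- riboReference(ref)
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  vapply(seq_len(n), function(i) {
    ma <- parseGenotype(a[i], ref)
    mb <- parseGenotype(b[i], ref)
    # positions mutated in exactly one, or mutated differently in both
    shared <- intersect(ma$pos, mb$pos)
    diff_shared <- sum(ma$alt[match(shared, ma$pos)] != mb$alt[match(shared, mb$pos)])
    length(setdiff(ma$pos, shared)) + length(setdiff(mb$pos, shared)) + diff_shared
  }, 1L)
}

#' One-hot encode genotypes
#'
#' Encodes each genotype's full sequence as an L x 4 indicator matrix with
#' fixed column order A, C, G, U, returned flattened position-major into a
#' length-4L row of an n x 4L matrix (the representation used by the tree
#' ensemble models). Column names are \code{"<pos>.<base>"}.
#'
#' @param genotype Character vector of genotype strings.
#' @param ref Reference sequence.
#' @return n x 4L binary matrix, one row per genotype.
#' @export
oneHotEncode <- function(genotype, ref) {
  ref <- riboReference(ref)
  rb <- refBases(ref)
  L <- length(rb)
  base_idx <- match(rb, RIBO_ALPHABET)
  n <- length(genotype)
  X <- matrix(0L, n, 4L * L,
              dimnames = list(NULL, paste0(rep(seq_len(L), each = 4L), ".",
                                           rep(RIBO_ALPHABET, L))))
  ref_cols <- (seq_len(L) - 1L) * 4L + base_idx
  cols <- matrix(ref_cols, nrow = n, ncol = L, byrow = TRUE)
  mut <- parseGenotypeTokens(genotype, ref)
  if (nrow(mut))
    cols[cbind(mut$row, mut$pos)] <-
      (mut$pos - 1L) * 4L + match(mut$alt, RIBO_ALPHABET)
  X[cbind(rep(seq_len(n), L), as.vector(cols))] <- 1L
  X
}

#' Decode one-hot rows back to sequences
#'
#' @param X n x 4L binary matrix from [oneHotEncode()].
#' @return Character vector of RNA sequences.
#' @export
oneHotDecode <- function(X) {
  L <- ncol(X) / 4L
  if (L != floor(L)) stop("column count is not a multiple of 4")
  apply(X, 1L, function(row) {
    m <- matrix(row, nrow = 4L)
    if (!all(colSums(m) == 1L)) stop("row is not a valid one-hot encoding")
    paste(RIBO_ALPHABET[apply(m, 2L, which.max)], collapse = "")
  })
}

#' Integer-index encoding for the recurrent model
#'
#' @param genotype Character vector of genotype strings.
#' @param ref Reference sequence.
#' @return n x L integer matrix with entries 1..4 (A,C,G,U).
#' @export
indexEncode <- function(genotype, ref) {
  ref <- riboReference(ref)
  rb <- refBases(ref)
  L <- length(rb)
  mut <- parseGenotypeTokens(genotype, ref)
  M <- matrix(match(rb, RIBO_ALPHABET), nrow = length(genotype), ncol = L,
              byrow = TRUE)
  if (nrow(mut))
    M[cbind(mut$row, mut$pos)] <- match(mut$alt, RIBO_ALPHABET)
  dimnames(M) <- NULL
  M
}
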