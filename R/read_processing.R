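#' Fraction cleaved estimator
#'
#' \code{fraction cleaved = cleaved / (cleaved + uncleaved)}. Vectorized;
#' rows with fewer than \code{min_reads} total reads (including 0 + 0)
#' return \code{NA}, an explicit missing marker.
#'
#' @param cleaved,uncleaved Non-negative count vectors.
#' @param min_reads Minimum total for a defined estimate (default 1).
#' @return Numeric vector in [0,1] with NA where undefined.
#' @export
fractionCleaved <- function(cleaved, uncleaved, min_reads = 1L) {
  if (any(cleaved < 0 | uncleaved < 0)) stop("counts must be non-negative")
  total <- cleaved + uncleaved
  ifelse(total >= min_reads & total > 0, cleaved / total, NA_real_)
}

#' Activity relative to the wild-type (display normalization)
#'
#' @param fc Fraction cleaved value(s).
#' @param fc_wildtype Wild-type fraction cleaved (> 0).
#' @return \code{fc / fc_wildtype}.
#' @export
relativeActivity <- function(fc, fc_wildtype) {
  if (length(fc_wildtype) != 1L || is.na(fc_wildtype) || fc_wildtype <= 0)
    stop("wild-type fraction cleaved must be a single positive value")
  fc / fc_wildtype
}

REJECT_REASONS <- c("no_primer_site", "ambiguous_primer_site", "too_short",
                    "unexpected_upstream", "unexpected_mutation",
                    "unexpected_variable_base")

#' Classify reads as (genotype, cleaved/uncleaved) or reject them
#'
#' Implements the read-to-genotype logic of the cleavage assay: the
#' reverse-transcription primer binding site is located at the 3' end by
#' exact match (no mismatch tolerance) and anchors the ribozyme
#' coordinates; a read is cleaved iff the 5' upstream segment is absent.
#' In \code{"match_list"} mode the ribozyme portion must exactly equal one
#' of the expected variant sequences (e.g. all mutants up to order 2); in
#' \code{"variable_positions"} mode every base outside the scheme's
#' variable positions must equal the reference and variable positions must
#' carry the reference base or an allowed alternative. Reads with
#' unexpected mutations in the primer site, the upstream (uncleaved)
#' portion, or the ribozyme are rejected with a reason code.
#'
#' @param seqs Character vector of read sequences (DNA or RNA).
#' @param ref Reference sequence.
#' @param upstream_seq 5' segment marking uncleaved reads.
#' @param primer_site 3' primer binding site.
#' @param mode \code{"match_list"} or \code{"variable_positions"}.
#' @param expected For match_list mode: character vector of expected
#'   genotype strings.
#' @param scheme For variable_positions mode: a [variableScheme()].
#' @return data.frame with columns \code{genotype} (NA when rejected),
#'   \code{cleaved} (logical, NA when rejected), \code{reason} (NA when
#'   accepted).
#' @export
classifyReads <- function(seqs, ref, upstream_seq, primer_site,
                          mode = c("match_list", "variable_positions"),
                          expected = NULL, scheme = NULL) {
  mode <- match.arg(mode)
  ref <- riboReference(ref)
  upstream_seq <- riboReference(upstream_seq)
  primer_site <- riboReference(primer_site)
  L <- nchar(ref)
  rb <- refBases(ref)
  if (mode == "match_list") {
    if (is.null(expected)) stop("match_list mode needs an expected genotype list")
    exp_seq <- genotypeToSequence(expected, ref)
  } else {
    if (is.null(scheme)) stop("variable_positions mode needs a scheme")
    var_pos <- scheme$pos
    allowed <- lapply(seq_len(nrow(scheme)),
                      function(k) c(scheme$ref[k], scheme$alts[[k]]))
  }
  seqs <- toupper(chartr("Tt", "Uu", seqs))
  n <- length(seqs)
  genotype <- rep(NA_character_, n)
  cleaved <- rep(NA, n)
  reason <- rep(NA_character_, n)

  # fully vectorized classification: one pass of string ops over all reads
  p1 <- regexpr(primer_site, seqs, fixed = TRUE)
  reason[p1 == -1L] <- "no_primer_site"
  live <- p1 != -1L
  tail_after <- substr(seqs, p1 + nchar(primer_site), nchar(seqs))
  ambig <- live & regexpr(primer_site, tail_after, fixed = TRUE) != -1L
  reason[ambig] <- "ambiguous_primer_site"
  live <- live & !ambig
  rib_start <- p1 - L
  short <- live & rib_start < 1L
  reason[short] <- "too_short"
  live <- live & !short
  rib <- substr(seqs, pmax(rib_start, 1L), p1 - 1L)
  prefix <- substr(seqs, 1L, rib_start - 1L)
  is_cleaved <- prefix == ""
  bad_up <- live & !is_cleaved & prefix != upstream_seq
  reason[bad_up] <- "unexpected_upstream"
  live <- live & !bad_up

  if (mode == "match_list") {
    gidx <- match(rib, exp_seq)
    bad <- live & is.na(gidx)
    reason[bad] <- "unexpected_mutation"
    live <- live & !bad
    genotype[live] <- expected[gidx[live]]
  } else {
    is_var <- seq_len(L) %in% var_pos
    bad_fixed <- rep(FALSE, n)
    bad_var <- rep(FALSE, n)
    toks <- rep("", n)
    for (p in seq_len(L)) {
      ch <- substring(rib, p, p)
      if (!is_var[p]) {
        bad_fixed <- bad_fixed | ch != rb[p]
      } else {
        k <- match(p, var_pos)
        bad_var <- bad_var | !(ch %in% allowed[[k]])
        mut <- ch != rb[p] & ch %in% allowed[[k]]
        toks[mut] <- paste0(toks[mut],
                            ifelse(toks[mut] == "", "", ";"),
                            rb[p], p, ch[mut])
      }
    }
    reason[live & bad_fixed] <- "unexpected_mutation"
    live_fixed <- live & !bad_fixed
    reason[live_fixed & bad_var] <- "unexpected_variable_base"
    live <- live_fixed & !bad_var
    genotype[live] <- ifelse(toks[live] == "", "WT", toks[live])
  }
  cleaved[live] <- is_cleaved[live]
  data.frame(genotype = genotype, cleaved = cleaved, reason = reason,
             stringsAsFactors = FALSE)
}

#' Count cleaved/uncleaved reads per genotype
#'
#' Single pass over one or more FASTQ files (plain or gzipped): classifies
#' every read with [classifyReads()], tallies cleaved and uncleaved counts
#' per unique genotype, computes fraction cleaved, and records rejected
#' reads by reason code. Counts are pooled across input files.
#'
#' @param paths Character vector of FASTQ paths.
#' @param ref Reference sequence.
#' @param upstream_seq,primer_site,mode,expected,scheme See
#'   [classifyReads()].
#' @param min_reads Minimum total reads for a defined fraction cleaved.
#' @return An [ActivityTable-class]; provenance holds the per-reason
#'   rejection tally, total reads, and inputs.
#' @export
countGenotypes <- function(paths, ref, upstream_seq, primer_site,
                           mode = c("match_list", "variable_positions"),
                           expected = NULL, scheme = NULL, min_reads = 1L) {
  mode <- match.arg(mode)
  for (p in paths) if (!file.exists(p)) stop("input FASTQ not found: ", p)
  seqs <- character(0)
  for (p in paths) {
    x <- tryCatch(Biostrings::readDNAStringSet(p, format = "fastq"),
                  error = function(e)
                    stop("unreadable FASTQ '", p, "': ", conditionMessage(e)))
    seqs <- c(seqs, as.character(x))
  }
  cls <- classifyReads(seqs, ref, upstream_seq, primer_site, mode,
                       expected = expected, scheme = scheme)
  acc <- cls[!is.na(cls$genotype), , drop = FALSE]
  rej <- table(factor(cls$reason[is.na(cls$genotype)], levels = REJECT_REASONS))
  if (nrow(acc)) {
    key <- acc$genotype
    cl <- tapply(acc$cleaved, key, sum)
    tot <- tapply(rep(1L, nrow(acc)), key, sum)
    gts <- names(tot)
    cleaved <- as.integer(cl[gts])
    uncleaved <- as.integer(tot[gts]) - cleaved
  } else {
    gts <- character(0); cleaved <- integer(0); uncleaved <- integer(0)
  }
  stopifnot(sum(cleaved) + sum(uncleaved) + sum(rej) == length(seqs))
  activityTable(gts, cleaved, uncleaved, ref, min_reads = min_reads,
                provenance = list(source = paths, mode = mode,
                                  upstream_seq = upstream_seq,
                                  primer_site = primer_site,
                                  total_reads = length(seqs),
                                  rejected = as.list(rej)))
}

#' Write / read an ActivityTable as TSV
#'
#' TSV with header columns genotype, cleaved, uncleaved, total,
#' fraction_cleaved, order, preceded by comment lines recording the
#' reference (positions are 1-based) and the min_reads setting; provenance
#' goes to a JSON sidecar.
#'
#' @param x An [ActivityTable-class].
#' @param path Output TSV path.
#' @param sidecar Optional JSON sidecar path (default \code{path + ".json"};
#'   NULL to skip).
#' @return \code{path} invisibly (write); an [ActivityTable-class] (read).
#' @export
writeActivityTable <- function(x, path, sidecar = paste0(path, ".json")) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# reference: ", x@reference, " (positions 1-based)"),
               paste0("# min_reads: ", x@provenance$min_reads %||% 1L)), con)
  write.table(x@data, con, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(sidecar))
    jsonlite::write_json(x@provenance, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeActivityTable
#' @export
readActivityTable <- function(x, sidecar = paste0(x, ".json")) {
  hdr <- readLines(x, n = 2L)
  ref <- sub("^# reference: ([ACGU]+).*$", "\\1", hdr[1L])
  min_reads <- as.integer(sub("^# min_reads: ", "", hdr[2L]))
  d <- read.table(x, sep = "\t", header = TRUE, comment.char = "#",
                  stringsAsFactors = FALSE)
  prov <- if (!is.null(sidecar) && file.exists(sidecar))
    jsonlite::read_json(sidecar, simplifyVector = TRUE) else list()
  activityTable(d$genotype, d$cleaved, d$uncleaved, ref,
                min_reads = min_reads, provenance = as.list(prov))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
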