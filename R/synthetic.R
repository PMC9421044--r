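#' Draw a synthetic ground-truth activity landscape
#'
#' Builds a seeded [LandscapeModel-class]: every single mutation gets an
#' additive latent effect drawn from a mixture of near-neutral
#' (N(0, 0.15), weight 0.35) and deleterious (-|N(2.5, 1)|, weight 0.65)
#' components; designated compensatory base pairs get strongly deleterious
#' single breaks (latent -4) whose paired double is rescued by a +6
#' pairwise term, so the double's activity exceeds both singles; remaining
#' pairwise terms are a sparse background of predominantly negative
#' epistasis. With \code{epistasis_scale = 0} the landscape is purely
#' additive (no pairwise or three-way terms, no planted pairs).
#'
#' All distributions here are documented fixtures of the generator, not
#' estimates from data.
#'
#' @param ref Reference sequence.
#' @param n_compensatory_pairs Number of planted base-pair partners
#'   (requires 2 x pairs <= L).
#' @param epistasis_scale Magnitude of background pairwise epistasis
#'   (latent units); 0 disables all pairwise structure.
#' @param seed Integer seed; the model is fully determined by it plus the
#'   arguments.
#' @param link \code{"logistic"} (default; activity = plogis(latent)) or
#'   \code{"exp"} (activity = min(1, exp(latent)), exactly multiplicative;
#'   all additive effects are forced negative so the clamp is never hit in
#'   the purely additive regime).
#' @param n_background_pairs Number of background pairwise terms (default
#'   \code{10 * L}).
#' @param n_threeway Number of planted three-way latent interaction terms
#'   (default 0); drawn over \code{threeway_pool}.
#' @param threeway_scale Magnitude of three-way terms (mean
#'   \code{-threeway_scale}); negative epistasis dominates, as observed in
#'   RNA fitness landscapes.
#' @param threeway_pool Optional character vector of mutation keys
#'   (\code{"<pos><alt>"}, e.g. \code{"12A"}) the three-way triples are
#'   drawn from; default all single mutations.
#' @param baseline Latent wild-type score; default gives wild-type activity
#'   about 0.8 under either link.
#' @return A [LandscapeModel-class].
#' @export
sampleLandscapeModel <- function(ref, n_compensatory_pairs = 2L,
                                 epistasis_scale = 0.5, seed = 1L,
                                 link = c("logistic", "exp"),
                                 n_background_pairs = NULL,
                                 n_threeway = 0L, threeway_scale = 2,
                                 threeway_pool = NULL,
                                 baseline = NULL) {
  ref <- riboReference(ref)
  link <- match.arg(link)
  rb <- refBases(ref)
  L <- length(rb)
  if (2L * n_compensatory_pairs > L)
    stop("2 * n_compensatory_pairs exceeds reference length")
  if (is.null(baseline))
    baseline <- if (link == "logistic") stats::qlogis(0.8) else log(0.8)
  if (is.null(n_background_pairs)) n_background_pairs <- 10L * L

  set.seed(as.integer(seed))
  mut_keys <- unlist(lapply(seq_len(L), function(i)
    paste0(i, setdiff(RIBO_ALPHABET, rb[i]))))
  n_mut <- length(mut_keys)
  neutral <- runif(n_mut) < 0.35
  eff <- ifelse(neutral, rnorm(n_mut, 0, 0.15), -abs(rnorm(n_mut, 2.5, 1)))
  if (link == "exp") eff <- -abs(eff)  # keep latent <= baseline: clamp never hit
  additive <- setNames(eff, mut_keys)

  pairwise <- setNames(numeric(0), character(0))
  comp <- data.frame(pos_i = integer(0), alt_i = character(0),
                     pos_j = integer(0), alt_j = character(0),
                     stringsAsFactors = FALSE)
  threeway <- setNames(numeric(0), character(0))

  if (epistasis_scale > 0) {
    break_mag <- if (link == "logistic") 4 else 2
    if (n_compensatory_pairs > 0L) {
      pos <- sample.int(L, 2L * n_compensatory_pairs)
      for (k in seq_len(n_compensatory_pairs)) {
        i <- min(pos[2L * k - 1L], pos[2L * k])
        j <- max(pos[2L * k - 1L], pos[2L * k])
        alt_i <- sample(setdiff(RIBO_ALPHABET, rb[i]), 1L)
        alt_j <- sample(setdiff(RIBO_ALPHABET, rb[j]), 1L)
        ki <- paste0(i, alt_i); kj <- paste0(j, alt_j)
        additive[ki] <- -break_mag
        additive[kj] <- -break_mag
        pairwise[paste(ki, kj, sep = "|")] <- 1.5 * break_mag
        comp <- rbind(comp, data.frame(pos_i = i, alt_i = alt_i,
                                       pos_j = j, alt_j = alt_j,
                                       stringsAsFactors = FALSE))
      }
    }
    if (n_background_pairs > 0L) {
      for (k in seq_len(n_background_pairs)) {
        pr <- sample(mut_keys, 2L)
        ppos <- as.integer(sub("[ACGU]$", "", pr))
        if (ppos[1L] == ppos[2L]) next  # same-position pair never co-occurs
        key <- paste(pr[order(ppos)], collapse = "|")
        if (key %in% names(pairwise)) next
        pairwise[key] <- rnorm(1L, -0.5 * epistasis_scale, 0.5 * epistasis_scale)
      }
    }
    if (n_threeway > 0L) {
      pool <- if (is.null(threeway_pool)) mut_keys else threeway_pool
      if (!all(pool %in% mut_keys)) stop("threeway_pool has unknown mutation keys")
      for (k in seq_len(n_threeway)) {
        tr <- sample(pool, 3L)
        tpos <- as.integer(sub("[ACGU]$", "", tr))
        if (anyDuplicated(tpos)) next
        key <- paste(tr[order(tpos)], collapse = "|")
        if (key %in% names(threeway)) next
        threeway[key] <- rnorm(1L, -threeway_scale, threeway_scale / 3)
      }
    }
  }

  new("LandscapeModel", reference = ref, baseline = baseline,
      additive = additive, pairwise = pairwise, threeway = threeway,
      link = link, compensatory = comp, seed = as.integer(seed),
      config = list(n_compensatory_pairs = n_compensatory_pairs,
                    epistasis_scale = epistasis_scale,
                    n_background_pairs = n_background_pairs,
                    n_threeway = n_threeway,
                    threeway_scale = threeway_scale))
}

linkActivity <- function(link, latent) {
  switch(link,
         logistic = stats::plogis(latent),
         exp = pmin(1, exp(latent)),
         stop("unknown link"))
}

#' Ground-truth activity of genotypes under a landscape model
#'
#' Latent score = baseline + sum of additive effects over the genotype's
#' mutations + sum of pairwise terms over its mutation pairs + sum of
#' three-way terms over its triples, pushed through the model's link onto
#' [0,1]. Deterministic.
#'
#' @param model A [LandscapeModel-class].
#' @param genotype Character vector of genotype strings.
#' @return Numeric vector of activities in [0,1].
#' @export
trueActivity <- function(model, genotype) {
  mut <- parseGenotypeTokens(genotype, model@reference)
  keys_by_row <- split(paste0(mut$pos, mut$alt),
                       factor(mut$row, levels = seq_along(genotype)))
  vapply(seq_along(genotype), function(gi) {
    keys <- keys_by_row[[gi]]
    latent <- model@baseline + sum(model@additive[keys])
    m <- length(keys)
    if (m >= 2L && length(model@pairwise)) {
      prs <- utils::combn(keys, 2L, FUN = paste, collapse = "|")
      hit <- model@pairwise[prs]
      latent <- latent + sum(hit, na.rm = TRUE)
    }
    if (m >= 3L && length(model@threeway)) {
      trs <- utils::combn(keys, 3L, FUN = paste, collapse = "|")
      hit <- model@threeway[trs]
      latent <- latent + sum(hit, na.rm = TRUE)
    }
    linkActivity(model@link, latent)
  }, numeric(1L), USE.NAMES = FALSE)
}

#' Dump / restore a landscape model as JSON
#'
#' Writes every parameter (baseline, additive, pairwise, three-way terms,
#' link, planted pairs, seed, config) so activities can be recomputed
#' independently of the package.
#'
#' @param model A [LandscapeModel-class].
#' @param path Output JSON path.
#' @return \code{path}, invisibly (write); a [LandscapeModel-class] (read).
#' @export
writeLandscapeModel <- function(model, path) {
  obj <- list(reference = model@reference, baseline = model@baseline,
              additive = as.list(model@additive),
              pairwise = as.list(model@pairwise),
              threeway = as.list(model@threeway),
              link = model@link, compensatory = model@compensatory,
              seed = model@seed, config = model@config)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeLandscapeModel
#' @export
readLandscapeModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  comp <- as.data.frame(obj$compensatory, stringsAsFactors = FALSE)
  if (!nrow(comp))
    comp <- data.frame(pos_i = integer(0), alt_i = character(0),
                       pos_j = integer(0), alt_j = character(0),
                       stringsAsFactors = FALSE)
  as_named <- function(x)
    if (length(x)) unlist(x) else setNames(numeric(0), character(0))
  new("LandscapeModel", reference = obj$reference, baseline = obj$baseline,
      additive = as_named(obj$additive), pairwise = as_named(obj$pairwise),
      threeway = as_named(obj$threeway), link = obj$link,
      compensatory = comp, seed = as.integer(obj$seed),
      config = as.list(obj$config))
}

#' Sample a doped-synthesis mutant library
#'
#' Emulates chemical synthesis with doped phosphoramidites: each molecule
#' mutates every position independently with probability
#' \code{per_position_mutation_rate} (default 0.03, i.e. 97% wild-type
#' nucleotide and 1% each of the other three), alternative base uniform
#' over the three non-reference bases.
#'
#' @param ref Reference sequence.
#' @param n_molecules Number of molecules to draw.
#' @param per_position_mutation_rate Per-position mutation probability in
#'   [0, 1).
#' @param seed Integer seed.
#' @return Character vector of genotype strings, one per molecule (with
#'   multiplicity).
#' @export
sampleDopedLibrary <- function(ref, n_molecules,
                               per_position_mutation_rate = 0.03,
                               seed = 1L) {
  ref <- riboReference(ref)
  rate <- per_position_mutation_rate
  if (rate < 0 || rate >= 1) stop("per_position_mutation_rate must be in [0, 1)")
  rb <- refBases(ref)
  L <- length(rb)
  set.seed(as.integer(seed))
  vapply(seq_len(n_molecules), function(i) {
    hit <- which(runif(L) < rate)
    if (!length(hit)) return("WT")
    alts <- vapply(hit, function(p) sample(setdiff(RIBO_ALPHABET, rb[p]), 1L), "")
    paste0(rb[hit], hit, alts, collapse = ";")
  }, "")
}

#' Simulate an activity table directly (no reads)
#'
#' Binomial cleaved counts at each genotype's true activity — the fast path
#' for testing downstream statistics without read-level simulation. The
#' estimator contract matches [countGenotypes()]: fraction cleaved =
#' cleaved / total.
#'
#' @param model A [LandscapeModel-class].
#' @param genotype Character vector of genotype strings (unique).
#' @param depth Reads per genotype (scalar or per-genotype vector).
#' @param seed Integer seed.
#' @param min_reads Threshold below which fraction cleaved is NA.
#' @return An [ActivityTable-class].
#' @export
simulateActivityTable <- function(model, genotype, depth, seed = 1L,
                                  min_reads = 1L) {
  if (any(depth < 1L)) stop("depth must be >= 1")
  if (anyDuplicated(genotype)) stop("genotypes must be unique")
  act <- trueActivity(model, genotype)
  set.seed(as.integer(seed))
  depth <- rep_len(as.integer(depth), length(genotype))
  cleaved <- rbinom(length(genotype), depth, act)
  activityTable(genotype, cleaved, depth - cleaved, model@reference,
                min_reads = min_reads,
                provenance = list(source = "simulateActivityTable",
                                  seed = as.integer(seed)))
}

#' Simulate co-transcriptional cleavage sequencing reads
#'
#' Per genotype, read depth is drawn from an overdispersed count
#' distribution (negative binomial with mean \code{mean_depth} and
#' dispersion \code{depth_dispersion}; Poisson when the dispersion is 0),
#' and each read is cleaved with probability equal to the genotype's true
#' activity. Cleaved reads are \code{ribozyme + primer_site}; uncleaved
#' reads retain the 5' upstream segment:
#' \code{upstream_seq + ribozyme + primer_site}. Optional uniform
#' substitution errors at \code{sequencing_error_rate}. Reads are written
#' as DNA (U -> T) FASTQ with constant quality.
#'
#' @param model A [LandscapeModel-class].
#' @param genotype Character vector of genotype strings (unique).
#' @param path Output FASTQ path.
#' @param mean_depth Mean reads per genotype.
#' @param depth_dispersion Negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2); 0 gives Poisson depths.
#' @param upstream_seq 5' segment present iff the read is uncleaved.
#' @param primer_site 3' reverse-transcription primer binding site, present
#'   on every read.
#' @param sequencing_error_rate Per-base substitution error probability.
#' @param seed Integer seed.
#' @return Invisibly, a data.frame manifest: genotype, true_activity,
#'   depth, cleaved.
#' @export
simulateReads <- function(model, genotype, path, mean_depth = 100,
                          depth_dispersion = 0.2,
                          upstream_seq = "CUGCAGAAUUCGCC",
                          primer_site = "GGAUCCUCUAGAGUCGAC",
                          sequencing_error_rate = 0, seed = 1L) {
  upstream_seq <- riboReference(upstream_seq)
  primer_site <- riboReference(primer_site)
  if (grepl(upstream_seq, primer_site, fixed = TRUE) ||
      grepl(primer_site, upstream_seq, fixed = TRUE))
    stop("upstream_seq and primer_site must be disjoint")
  if (anyDuplicated(genotype)) stop("genotypes must be unique")
  act <- trueActivity(model, genotype)
  seqs <- genotypeToSequence(genotype, model@reference)
  set.seed(as.integer(seed))
  n <- length(genotype)
  depth <- if (depth_dispersion > 0)
    rnbinom(n, mu = mean_depth, size = 1 / depth_dispersion)
  else rpois(n, mean_depth)
  cleaved <- rbinom(n, depth, act)
  reads <- vector("list", n)
  for (i in seq_len(n)) {
    if (depth[i] == 0L) { reads[[i]] <- character(0); next }
    reads[[i]] <- c(rep(paste0(seqs[i], primer_site), cleaved[i]),
                    rep(paste0(upstream_seq, seqs[i], primer_site),
                        depth[i] - cleaved[i]))
  }
  reads <- unlist(reads)
  if (sequencing_error_rate > 0 && length(reads)) {
    reads <- vapply(reads, function(r) {
      b <- strsplit(r, "", fixed = TRUE)[[1L]]
      hit <- which(runif(length(b)) < sequencing_error_rate)
      for (p in hit) b[p] <- sample(setdiff(RIBO_ALPHABET, b[p]), 1L)
      paste(b, collapse = "")
    }, "", USE.NAMES = FALSE)
  }
  dna <- chartr("U", "T", reads)
  ids <- sprintf("read_%06d", seq_along(dna))
  if (length(dna)) {
    x <- Biostrings::DNAStringSet(dna)
    names(x) <- ids
    qual <- Biostrings::PhredQuality(
      vapply(nchar(dna), function(w) strrep("I", w), ""))
    Biostrings::writeXStringSet(
      Biostrings::QualityScaledDNAStringSet(x, qual),
      path, format = "fastq")
  } else {
    file.create(path)
  }
  invisible(data.frame(genotype = genotype, true_activity = act,
                       depth = depth, cleaved = cleaved,
                       stringsAsFactors = FALSE))
}
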