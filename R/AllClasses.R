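#' TEConsensus: a transposable-element consensus with annotated landmarks
#'
#' Holds one TE consensus sequence together with named landmark intervals
#' (1-based closed, [IRanges::IRanges]) and the subfamily label. Landmarks
#' used by the pipeline: \code{five_prime_utr}, \code{orf1}, \code{orf2},
#' \code{three_prime_utr} (which must end at the last base of the sequence)
#' and \code{promoter_cpg_island} (which must lie inside the 5' UTR).
#'
#' @slot name Identifier of the consensus.
#' @slot sequence A [Biostrings::DNAString] over A/C/G/T.
#' @slot landmarks Named [IRanges::IRanges] of landmark intervals.
#' @slot family One of \code{"L1-Ta"}, \code{"L1PA2"}, \code{"Alu"}.
#' @export
setClass("TEConsensus",
  representation(
    name = "character",
    sequence = "DNAString",
    landmarks = "IRanges",
    family = "character"
  )
)

setValidity("TEConsensus", function(object) {
  msg <- character()
  if (!object@family %in% c("L1-Ta", "L1PA2", "Alu"))
    msg <- c(msg, "family must be one of L1-Ta, L1PA2, Alu")
  L <- length(object@sequence)
  lm <- object@landmarks
  if (length(lm)) {
    if (is.null(names(lm))) msg <- c(msg, "landmarks must be named")
    if (any(IRanges::start(lm) < 1L) || any(IRanges::end(lm) > L))
      msg <- c(msg, "landmark intervals must lie within the sequence")
    if ("three_prime_utr" %in% names(lm) &&
        IRanges::end(lm["three_prime_utr"]) != L)
      msg <- c(msg, "three_prime_utr must end at the sequence end")
    if (all(c("promoter_cpg_island", "five_prime_utr") %in% names(lm))) {
      isl <- lm["promoter_cpg_island"]; utr <- lm["five_prime_utr"]
      if (IRanges::start(isl) < IRanges::start(utr) ||
          IRanges::end(isl) > IRanges::end(utr))
        msg <- c(msg, "promoter_cpg_island must lie within five_prime_utr")
    }
  }
  if (!all(strsplit(as.character(object@sequence), "")[[1]] %in%
           c("A", "C", "G", "T")))
    msg <- c(msg, "sequence alphabet must be A/C/G/T")
  if (length(msg)) msg else TRUE
})

#' Construct a TEConsensus
#'
#' @param name Identifier.
#' @param sequence DNAString or character.
#' @param landmarks Named [IRanges::IRanges].
#' @param family Subfamily label.
#' @return A [TEConsensus-class] object.
#' @export
TEConsensus <- function(name, sequence, landmarks, family) {
  if (is.character(sequence)) sequence <- Biostrings::DNAString(sequence)
  new("TEConsensus", name = name, sequence = sequence,
      landmarks = landmarks, family = family)
}

#' @describeIn TEConsensus-class Consensus sequence as a DNAString.
#' @param x A TEConsensus.
#' @export
consensusSequence <- function(x) x@sequence

#' @describeIn TEConsensus-class Named landmark IRanges.
#' @export
landmarks <- function(x) x@landmarks

#' @describeIn TEConsensus-class Subfamily label.
#' @export
teFamily <- function(x) x@family

setMethod("show", "TEConsensus", function(object) {
  cat("TEConsensus", object@name, sprintf("(%s)", object@family),
      length(object@sequence), "nt\n")
  cat("  landmarks:", paste(sprintf("%s[%d-%d]", names(object@landmarks),
      IRanges::start(object@landmarks), IRanges::end(object@landmarks)),
      collapse = " "), "\n")
})

#' Read simulation configuration
#'
#' Parameters of the capture-enriched paired-end read simulator: sonication
#' fragment window (bp), read length (bp), target mean genome-wide depth,
#' per-base substitution error probability, fold enrichment of fragment
#' sampling density over probe regions, and RNG seed.
#'
#' @slot fragment_min,fragment_max Integer fragment size window (bp).
#' @slot read_len Integer read length (bp).
#' @slot coverage Target mean depth (x) from the uniform component.
#' @slot error_rate Per-base substitution probability.
#' @slot enrichment_factor Sampling density multiplier inside probe regions.
#' @slot seed Integer RNG seed.
#' @export
setClass("ReadSimConfig",
  representation(
    fragment_min = "integer", fragment_max = "integer", read_len = "integer",
    coverage = "numeric", error_rate = "numeric",
    enrichment_factor = "numeric", seed = "integer"
  )
)

setValidity("ReadSimConfig", function(object) {
  msg <- character()
  if (object@fragment_min > object@fragment_max)
    msg <- c(msg, "fragment_min must be <= fragment_max")
  if (object@read_len > object@fragment_max)
    msg <- c(msg, "read_len must be <= fragment_max")
  if (object@coverage <= 0) msg <- c(msg, "coverage must be > 0")
  if (object@error_rate < 0 || object@error_rate >= 0.1)
    msg <- c(msg, "error_rate must be in [0, 0.1)")
  if (object@enrichment_factor < 1)
    msg <- c(msg, "enrichment_factor must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct a ReadSimConfig
#'
#' Defaults mirror an RC-seq style library: 230-260 bp sonication fragments
#' sequenced as 150-mer pairs.
#'
#' @param fragment_min,fragment_max Fragment size window (bp).
#' @param read_len Read length (bp).
#' @param coverage Target mean depth of the uniform component.
#' @param error_rate Per-base substitution probability.
#' @param enrichment_factor Fold enrichment over probe regions.
#' @param seed Integer seed.
#' @return A [ReadSimConfig-class] object.
#' @export
ReadSimConfig <- function(fragment_min = 230L, fragment_max = 260L,
                          read_len = 150L, coverage = 10, error_rate = 0.001,
                          enrichment_factor = 1, seed = 1L) {
  new("ReadSimConfig",
      fragment_min = as.integer(fragment_min),
      fragment_max = as.integer(fragment_max),
      read_len = as.integer(read_len), coverage = coverage,
      error_rate = error_rate, enrichment_factor = enrichment_factor,
      seed = as.integer(seed))
}

setMethod("show", "ReadSimConfig", function(object) {
  cat(sprintf(
    "ReadSimConfig: %d-%d bp fragments, 2x%d nt, %.1fx, err %.4f, enr %.1fx\n",
    object@fragment_min, object@fragment_max, object@read_len,
    object@coverage, object@error_rate, object@enrichment_factor))
})

#' Bisulfite amplicon simulation configuration
#'
#' @slot per_cpg_methylation Probability a given island CpG cytosine is
#'   methylated (read as C), indexed by island CpG.
#' @slot conversion_efficiency Probability an unmethylated non-CpG cytosine
#'   reads as T.
#' @slot n_read_pairs Number of amplicon molecules simulated.
#' @slot read_len Read length (overlapping inward pairs).
#' @slot error_rate Per-base substitution probability.
#' @slot seed Integer RNG seed.
#' @export
setClass("BisulfiteSimConfig",
  representation(
    per_cpg_methylation = "numeric", conversion_efficiency = "numeric",
    n_read_pairs = "integer", read_len = "integer", error_rate = "numeric",
    seed = "integer"
  )
)

setValidity("BisulfiteSimConfig", function(object) {
  msg <- character()
  if (any(object@per_cpg_methylation < 0 | object@per_cpg_methylation > 1))
    msg <- c(msg, "per_cpg_methylation must be probabilities")
  if (object@conversion_efficiency < 0 || object@conversion_efficiency > 1)
    msg <- c(msg, "conversion_efficiency must be a probability")
  if (object@n_read_pairs < 1) msg <- c(msg, "n_read_pairs must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct a BisulfiteSimConfig
#'
#' @param per_cpg_methylation Numeric vector of per-CpG methylation
#'   probabilities (length = number of island CpGs, or length 1, recycled).
#' @param conversion_efficiency Probability an unmethylated cytosine converts.
#' @param n_read_pairs Number of molecules.
#' @param read_len Read length (2 x read_len overlapping pairs).
#' @param error_rate Substitution error probability.
#' @param seed Integer seed.
#' @return A [BisulfiteSimConfig-class] object.
#' @export
BisulfiteSimConfig <- function(per_cpg_methylation, conversion_efficiency = 0.99,
                               n_read_pairs = 1000L, read_len = 250L,
                               error_rate = 0, seed = 1L) {
  new("BisulfiteSimConfig",
      per_cpg_methylation = per_cpg_methylation,
      conversion_efficiency = conversion_efficiency,
      n_read_pairs = as.integer(n_read_pairs),
      read_len = as.integer(read_len),
      error_rate = error_rate, seed = as.integer(seed))
}

#' Per-CpG methylation profile over the consensus promoter island
#'
#' @slot cpg_positions Consensus coordinates (1-based) of island CpG
#'   cytosines.
#' @slot methylated_counts,total_counts Integer counts per CpG position.
#' @slot excluded_positions Positions flagged as mutated CpGs and excluded.
#' @slot per_read_conversion Named numeric, non-CpG conversion rate per
#'   retained read pair.
#' @slot group_label Sample-group identifier.
#' @export
setClass("MethylationProfile",
  representation(
    cpg_positions = "integer", methylated_counts = "integer",
    total_counts = "integer", excluded_positions = "integer",
    per_read_conversion = "numeric", group_label = "character"
  )
)

setValidity("MethylationProfile", function(object) {
  msg <- character()
  if (length(object@methylated_counts) != length(object@cpg_positions) ||
      length(object@total_counts) != length(object@cpg_positions))
    msg <- c(msg, "count vectors must match cpg_positions in length")
  if (any(object@methylated_counts > object@total_counts))
    msg <- c(msg, "methylated_counts must be <= total_counts")
  if (length(msg)) msg else TRUE
})

#' Per-CpG methylated fractions of a profile
#'
#' @param x A [MethylationProfile-class].
#' @param drop_excluded Drop positions flagged as mutated CpGs.
#' @return Named numeric vector of methylated fractions (NA where uncovered).
#' @export
methylationFractions <- function(x, drop_excluded = TRUE) {
  f <- ifelse(x@total_counts > 0, x@methylated_counts / x@total_counts, NA_real_)
  names(f) <- as.character(x@cpg_positions)
  if (drop_excluded && length(x@excluded_positions))
    f <- f[!x@cpg_positions %in% x@excluded_positions]
  f
}

setMethod("show", "MethylationProfile", function(object) {
  f <- methylationFractions(object)
  cat(sprintf(
    "MethylationProfile '%s': %d CpGs (%d excluded), mean methylation %.3f\n",
    object@group_label, length(object@cpg_positions),
    length(object@excluded_positions), mean(f, na.rm = TRUE)))
})
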