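#' Quantification configuration
#'
#' @param p_percent percent of the 1C genome represented by the analyzed
#'   reads (default 0.75, i.e. 0.75% of 1C — the denominator of the
#'   copy-number normalization).
#' @param min_identity minimum alignment identity for assignment.
#' @param min_aligned_frac minimum aligned fraction of the read.
#' @param margin uniqueness margin: the best family score must exceed the
#'   runner-up by at least this much (ties are never assigned).
#' @param kmer seed k-mer size of the aligner.
#' @param seed subsampling seed (optional; can also be passed to
#'   [sample_reads()] directly).
#' @return list of class `quant_config`.
#' @export
quant_config <- function(p_percent = 0.75, min_identity = 0.90,
                         min_aligned_frac = 0.80, margin = 1L,
                         kmer = 12L, seed = NULL) {
  stopifnot(p_percent > 0, p_percent <= 100,
            min_identity > 0, min_identity <= 1,
            min_aligned_frac > 0, min_aligned_frac <= 1,
            margin >= 0, kmer >= 4, kmer <= 31)
  structure(list(p_percent = p_percent, min_identity = min_identity,
                 min_aligned_frac = min_aligned_frac,
                 margin = as.integer(margin), kmer = as.integer(kmer),
                 seed = seed), class = "quant_config")
}

#' Subsample read pairs to a fraction of the 1C genome
#'
#' Uniform random subsample of read pairs, without replacement, whose
#' total base count is within one pair of `p_percent`/100 times the 1C
#' genome size. Subsampling is by pair, preserving mate pairing.
#'
#' @param rs a `read_set`.
#' @param genome_size_1C_bp haploid genome size in bp.
#' @param p_percent requested percent of 1C (0 < p <= 100).
#' @param seed integer seed.
#' @return a `read_set` with the retained pairs.
#' @export
sample_reads <- function(rs, genome_size_1C_bp, p_percent, seed) {
  stopifnot(inherits(rs, "read_set"), genome_size_1C_bp > 0,
            p_percent > 0, p_percent <= 100)
  target_bp <- p_percent / 100 * genome_size_1C_bp
  pair_bp <- 2 * rs$read_length
  n_keep <- round(target_bp / pair_bp)
  if (n_keep > n_pairs(rs)) {
    achievable <- n_pairs(rs) * pair_bp / genome_size_1C_bp * 100
    stop(sprintf(paste0("not enough reads: %d pairs needed for p = %.4g%%",
                        " but only %d available (achievable p = %.4g%%)"),
                 n_keep, p_percent, n_pairs(rs), achievable))
  }
  keep <- with_seed(seed, sort(sample.int(n_pairs(rs), n_keep)))
  structure(list(read1 = rs$read1[keep], read2 = rs$read2[keep],
                 qual1 = rs$qual1[keep], qual2 = rs$qual2[keep],
                 read_length = rs$read_length, sample_id = rs$sample_id),
            class = "read_set")
}

#' Uniquely assign reads to TE subfamilies and sum coverage
#'
#' Each mate is aligned independently against every reference with a
#' k-mer-seeded, ungapped diagonal alignment (match +1, mismatch -1,
#' clipped at reference ends; the reverse complement is always tried). A
#' mate is assigned to the single best-scoring subfamily only when the
#' alignment passes `min_identity` and `min_aligned_frac` and the best
#' score beats the runner-up subfamily by at least `margin`; otherwise it
#' stays unassigned. Per-subfamily coverage is the summed aligned bp of
#' assigned mates (bedcov-style per-base depth sum).
#'
#' @param rs a `read_set`, or a plain character vector of reads.
#' @param te_library a `te_library`.
#' @param config a [quant_config()].
#' @return data.frame of class `coverage_table` with columns `family`,
#'   `length_bp`, `coverage_bp`, `reads`; attributes `total_read_bp`,
#'   `n_unassigned`, `config`.
#' @export
assign_reads_unique <- function(rs, te_library, config = quant_config()) {
  stopifnot(inherits(te_library, "te_library"),
            inherits(config, "quant_config"))
  if (length(te_library) == 0) stop("empty reference library")
  mates <- if (inherits(rs, "read_set")) c(rs$read1, rs$read2)
           else as.character(rs)
  fam_names <- te_library$info$name
  if (length(mates) == 0) {
    out <- data.frame(family = fam_names,
                      length_bp = te_library$info$length_bp,
                      coverage_bp = 0L, reads = 0L,
                      stringsAsFactors = FALSE)
  } else {
    hit <- cpp_assign_reads(mates, unname(te_library$seq), config$kmer,
                            config$min_identity, config$min_aligned_frac,
                            config$margin)
    cov <- vapply(seq_along(fam_names), function(i)
      sum(hit$aligned_bp[hit$family == i]), 0)
    nread <- vapply(seq_along(fam_names), function(i)
      sum(hit$family == i), 0L)
    out <- data.frame(family = fam_names,
                      length_bp = te_library$info$length_bp,
                      coverage_bp = cov, reads = nread,
                      stringsAsFactors = FALSE)
  }
  attr(out, "total_read_bp") <- sum(nchar(mates))
  attr(out, "n_unassigned") <- length(mates) - sum(out$reads)
  attr(out, "config") <- config
  class(out) <- c("coverage_table", "data.frame")
  out
}

#' Copy number from summed coverage
#'
#' `copies = (coverage_bp / family_length_bp) * (100 / p_percent)` where
#' `p_percent` is the percent of 1C represented by the analyzed reads.
#' With reads drawn from a diploid individual this literal normalization
#' yields copies per 1C; `scale = "per-2C"` multiplies by two. Ratio
#' statistics downstream (X density) are invariant to the choice.
#'
#' @param coverage_bp summed aligned bp on the subfamily reference.
#' @param family_length_bp reference length in bp (> 0).
#' @param p_percent percent of 1C sampled (> 0).
#' @param scale `"per-1C"` (the literal normalization, default) or `"per-2C"`.
#' @return numeric copy number(s).
#' @examples
#' copy_number(1500000, 10000, 0.75)  # 20000
#' @export
copy_number <- function(coverage_bp, family_length_bp, p_percent,
                        scale = c("per-1C", "per-2C")) {
  scale <- match.arg(scale)
  if (any(family_length_bp <= 0)) stop("family_length_bp must be > 0")
  if (any(p_percent <= 0)) stop("p_percent must be > 0")
  if (any(coverage_bp < 0)) stop("coverage_bp must be >= 0")
  out <- (coverage_bp / family_length_bp) * (100 / p_percent)
  if (scale == "per-2C") out <- 2 * out
  out
}

#' Genome proportion of a subfamily
#'
#' Fraction of all sampled read bases assigned to the subfamily.
#' @param coverage_bp summed aligned bp (\eqn{\le} total).
#' @param total_sampled_bp total bases of the analyzed reads (> 0).
#' @return numeric in \[0, 1].
#' @export
genome_proportion <- function(coverage_bp, total_sampled_bp) {
  if (any(total_sampled_bp <= 0)) stop("total_sampled_bp must be > 0")
  if (any(coverage_bp < 0)) stop("coverage_bp must be >= 0")
  if (any(coverage_bp > total_sampled_bp))
    stop("coverage cannot exceed total sampled bp")
  coverage_bp / total_sampled_bp
}

#' Quantify one sample: coverage, proportions, copy numbers
#'
#' Convenience wrapper running [assign_reads_unique()] and applying
#' [copy_number()] and [genome_proportion()] with the configured
#' `p_percent`.
#'
#' @inheritParams assign_reads_unique
#' @param scale copy-number scale, see [copy_number()].
#' @return the `coverage_table` with added `proportion` and `copies`
#'   columns.
#' @export
quantify_sample <- function(rs, te_library, config = quant_config(),
                            scale = c("per-1C", "per-2C")) {
  scale <- match.arg(scale)
  cov <- assign_reads_unique(rs, te_library, config)
  total <- attr(cov, "total_read_bp")
  cov$proportion <- if (total > 0)
    genome_proportion(cov$coverage_bp, total) else 0
  cov$copies <- copy_number(cov$coverage_bp, cov$length_bp,
                            config$p_percent, scale)
  cov
}
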