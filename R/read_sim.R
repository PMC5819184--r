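#' Simulate paired-end reads from a rendered genome
#'
#' Fragments are drawn uniformly from the diploid sequence (chromosome
#' picked proportional to length, start uniform within the chromosome),
#' with Gaussian insert sizes truncated to at least the read length. The
#' second mate is the reverse complement of the fragment end; fragments
#' come off either strand with equal probability. Sequencing errors, when
#' enabled, are uniform substitutions; qualities are constant Q30
#' (Phred+33).
#'
#' @param genome named character vector of chromosome sequences
#'   ([render_genome()] output), or a `genome_blueprint` (then
#'   `te_library` must be supplied).
#' @param n_pairs number of read pairs; alternatively give `mean_depth`.
#' @param mean_depth target reads-per-base over the whole genome; converted
#'   to `n_pairs = round(depth * genome_bp / (2 * read_length))`.
#' @param read_length mate length in bp (default 150).
#' @param insert_mean,insert_sd fragment-size distribution (default 350/30).
#' @param error_rate per-base substitution probability in \[0, 0.05].
#' @param seed integer seed; output is deterministic.
#' @param sample_id label stored with the reads and used in FASTQ ids.
#' @param te_library needed only when `genome` is a blueprint.
#' @return An object of class `read_set`: list with `read1`, `read2`,
#'   `qual1`, `qual2`, `read_length`, `sample_id`.
#' @export
simulate_reads <- function(genome, n_pairs = NULL, mean_depth = NULL,
                           read_length = 150L, insert_mean = 350,
                           insert_sd = 30, error_rate = 0, seed,
                           sample_id = "sample", te_library = NULL) {
  if (inherits(genome, "genome_blueprint")) {
    if (is.null(te_library))
      stop("te_library required to render a blueprint")
    genome <- render_genome(genome, te_library)
  }
  stopifnot(is.character(genome), length(genome) >= 1)
  if (error_rate < 0 || error_rate > 0.05)
    stop("error_rate must be in [0, 0.05]")
  if (insert_mean < read_length)
    stop("insert size must be at least the read length")
  clen <- nchar(genome)
  if (any(clen < read_length)) stop("chromosome shorter than read length")
  gbp <- sum(as.numeric(clen))
  if (is.null(n_pairs)) {
    if (is.null(mean_depth)) stop("give n_pairs or mean_depth")
    n_pairs <- round(mean_depth * gbp / (2 * read_length))
  }
  n_pairs <- as.integer(n_pairs)
  if (n_pairs == 0) {
    warning("0 read pairs requested: returning an empty read set")
    return(structure(list(read1 = character(0), read2 = character(0),
                          qual1 = character(0), qual2 = character(0),
                          read_length = as.integer(read_length),
                          sample_id = sample_id), class = "read_set"))
  }
  with_seed(seed, {
    chrom <- sample.int(length(genome), n_pairs, replace = TRUE,
                        prob = clen)
    ins <- pmax(read_length,
                pmin(round(rnorm(n_pairs, insert_mean, insert_sd)),
                     clen[chrom]))
    start <- floor(runif(n_pairs) * (clen[chrom] - ins + 1)) + 1L
    frag_strand <- runif(n_pairs) < 0.5
    r1 <- character(n_pairs); r2 <- character(n_pairs)
    for (ci in unique(chrom)) {
      sel <- chrom == ci
      s <- start[sel]; e <- start[sel] + ins[sel] - 1L
      left <- substring(genome[[ci]], s, s + read_length - 1L)
      right <- revcomp_chr(substring(genome[[ci]], e - read_length + 1L, e))
      r1[sel] <- left; r2[sel] <- right
    }
    # minus-strand fragments: mate roles swap
    flip <- frag_strand
    tmp <- r1[flip]; r1[flip] <- r2[flip]; r2[flip] <- tmp
    if (error_rate > 0) {
      r1 <- add_errors(r1, error_rate)
      r2 <- add_errors(r2, error_rate)
    }
    q <- strrep(rawToChar(as.raw(30L + 33L)), read_length)
    structure(list(read1 = r1, read2 = r2,
                   qual1 = rep(q, n_pairs), qual2 = rep(q, n_pairs),
                   read_length = as.integer(read_length),
                   sample_id = sample_id), class = "read_set")
  })
}

# sparse uniform substitution errors
add_errors <- function(reads, rate) {
  L <- nchar(reads[1])
  total <- length(reads) * L
  n_err <- rbinom(1L, total, rate)
  if (n_err == 0) return(reads)
  pos <- sample.int(total, n_err)
  ridx <- (pos - 1L) %/% L + 1L
  cidx <- (pos - 1L) %% L + 1L
  bases <- c("A", "C", "G", "T")
  for (k in seq_len(n_err)) {
    cur <- substr(reads[ridx[k]], cidx[k], cidx[k])
    sub <- sample(setdiff(bases, cur), 1L)
    substr(reads[ridx[k]], cidx[k], cidx[k]) <- sub
  }
  reads
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("read_set '%s': %d pairs x 2 x %d bp\n",
              x$sample_id, length(x$read1), x$read_length))
  invisible(x)
}

#' Number of read pairs in a read set
#' @param rs a `read_set`.
#' @export
n_pairs <- function(rs) {
  stopifnot(inherits(rs, "read_set"))
  length(rs$read1)
}

#' Total sequenced bases in a read set
#' @param rs a `read_set`.
#' @export
total_read_bp <- function(rs) {
  stopifnot(inherits(rs, "read_set"))
  sum(nchar(rs$read1)) + sum(nchar(rs$read2))
}

#' Write / read paired FASTQ (Phred+33)
#'
#' @param rs a `read_set`.
#' @param file1,file2 output paths for mate 1 and mate 2.
#' @return `read_fastq_pairs` returns a `read_set`.
#' @export
write_fastq <- function(rs, file1, file2) {
  stopifnot(inherits(rs, "read_set"))
  ids <- sprintf("%s:%d", rs$sample_id, seq_along(rs$read1))
  for (mate in 1:2) {
    seqs <- Biostrings::DNAStringSet(if (mate == 1) rs$read1 else rs$read2)
    quals <- Biostrings::BStringSet(if (mate == 1) rs$qual1 else rs$qual2)
    names(seqs) <- sprintf("%s/%d", ids, mate)
    Biostrings::writeXStringSet(seqs, if (mate == 1) file1 else file2,
                                format = "fastq", qualities = quals)
  }
  invisible(c(file1, file2))
}

#' @rdname write_fastq
#' @param sample_id label for the returned read set.
#' @export
read_fastq_pairs <- function(file1, file2, sample_id = "sample") {
  # suppress Biostrings' note about dropped metadata columns
  s1 <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(file1))
  s2 <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(file2))
  if (length(s1) != length(s2)) stop("mate files differ in read count")
  L <- if (length(s1)) Biostrings::width(s1)[1] else 0L
  structure(list(read1 = unname(as.character(s1)),
                 read2 = unname(as.character(s2)),
                 qual1 = unname(as.character(Biostrings::quality(s1))),
                 qual2 = unname(as.character(Biostrings::quality(s2))),
                 read_length = as.integer(L), sample_id = sample_id),
            class = "read_set")
}
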