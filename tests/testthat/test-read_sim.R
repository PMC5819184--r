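test_that("error-free mates are exact substrings of the genome", {
  lib <- small_lib()
  bp <- small_blueprint(lib, "female", seed = 8)
  g <- render_genome(bp, lib)
  rs <- simulate_reads(g, n_pairs = 30, read_length = 80,
                       insert_mean = 200, insert_sd = 15,
                       error_rate = 0, seed = 9)
  joined <- paste(g, collapse = "|")
  for (m in c(rs$read1, rs$read2)) {
    hit <- grepl(m, joined, fixed = TRUE) ||
      grepl(oracle_revcomp(m), joined, fixed = TRUE)
    expect_true(hit)
  }
  expect_true(all(nchar(c(rs$read1, rs$read2)) == 80L))
  expect_true(all(nchar(c(rs$qual1, rs$qual2)) == 80L))
})

test_that("requested yield is conserved and simulation is deterministic", {
  lib <- small_lib()
  bp <- small_blueprint(lib, "male", seed = 10)
  g <- render_genome(bp, lib)
  gbp <- sum(nchar(g))
  rs <- simulate_reads(g, mean_depth = 2, read_length = 100, seed = 11)
  expect_lt(abs(total_read_bp(rs) - 2 * gbp) / (2 * gbp), 0.01)
  rs2 <- simulate_reads(g, mean_depth = 2, read_length = 100, seed = 11)
  expect_identical(rs[c("read1", "read2")], rs2[c("read1", "read2")])
  expect_warning(simulate_reads(g, n_pairs = 0, seed = 1), "empty")
})

test_that("read bp hitting a TE region matches its genomic fraction", {
  # one AT-only chromosome with one GC-only insert: TE-derived read bases
  # are exactly the G/C bases, so the binomial check needs no aligner
  set.seed(1)
  bb1 <- paste(sample(c("A", "T"), 60000, TRUE), collapse = "")
  bb2 <- paste(sample(c("A", "T"), 140000, TRUE), collapse = "")
  te <- paste(sample(c("G", "C"), 12000, TRUE), collapse = "")
  genome <- c(chr = paste0(bb1, te, bb2))
  f <- 12000 / nchar(genome)
  rs <- simulate_reads(genome, n_pairs = 4000, read_length = 100,
                       insert_mean = 250, insert_sd = 20,
                       error_rate = 0, seed = 12)
  mates <- c(rs$read1, rs$read2)
  te_bp <- sum(nchar(gsub("[AT]", "", mates)))
  frac <- te_bp / sum(nchar(mates))
  se <- sqrt(f * (1 - f) / length(mates))   # conservative per-mate binomial
  expect_lt(abs(frac - f), 3 * se)
})

test_that("substitution errors appear at the configured rate", {
  genome <- c(chr = strrep("A", 50000))
  rs <- simulate_reads(genome, n_pairs = 1000, read_length = 100,
                       error_rate = 0.01, seed = 13)
  # mates read off the minus strand are all-T; errors are whatever
  # disagrees with the mate's majority base
  mates <- c(rs$read1, rs$read2)
  nA <- nchar(gsub("[^A]", "", mates))
  nT <- nchar(gsub("[^T]", "", mates))
  n_err <- sum(nchar(mates) - pmax(nA, nT))
  n_tot <- sum(nchar(mates))
  expect_lt(abs(n_err / n_tot - 0.01), 3 * sqrt(0.01 * 0.99 / n_tot))
  expect_error(simulate_reads(genome, n_pairs = 1, error_rate = 0.2,
                              seed = 1), "error_rate")
})

test_that("FASTQ writing is Phred+33 and round trips byte-identically", {
  lib <- small_lib()
  bp <- small_blueprint(lib, "female", seed = 14)
  rs <- simulate_reads(render_genome(bp, lib), n_pairs = 25,
                       read_length = 90, insert_mean = 220,
                       seed = 15, sample_id = "s1")
  d <- withr::local_tempdir()
  f1 <- file.path(d, "s1_1.fastq"); f2 <- file.path(d, "s1_2.fastq")
  write_fastq(rs, f1, f2)
  lines <- readLines(f1)
  expect_identical(length(lines), 100L)
  expect_identical(substr(lines[1], 1, 1), "@")
  expect_true(all(strsplit(lines[4], "")[[1]] == rawToChar(as.raw(63))))
  back <- read_fastq_pairs(f1, f2, sample_id = "s1")
  expect_identical(back$read1, rs$read1)
  expect_identical(back$read2, rs$read2)
  expect_identical(back$qual1, rs$qual1)
  # byte-identical on re-write: determinism of the FASTQ path
  g1 <- file.path(d, "t1.fastq"); g2 <- file.path(d, "t2.fastq")
  write_fastq(rs, g1, g2)
  expect_identical(readLines(g1), readLines(f1))
})
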