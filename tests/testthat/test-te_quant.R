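test_that("subsampling hits the bp target and stays pair-coherent", {
  # 1C = 1 Mbp at p = 0.75% with 2 x 150 bp pairs -> exactly 25 pairs
  rs <- local({
    set.seed(42)
    n <- 60
    mk <- function() vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "G", "T"), 150, TRUE), collapse = ""), "")
    structure(list(read1 = mk(), read2 = mk(),
                   qual1 = rep(strrep("?", 150), n),
                   qual2 = rep(strrep("?", 150), n),
                   read_length = 150L, sample_id = "s"),
              class = "read_set")
  })
  sub <- sample_reads(rs, 1e6, 0.75, seed = 1)
  expect_identical(n_pairs(sub), 25L)
  expect_lte(abs(total_read_bp(sub) - 7500), 300)
  # pairing preserved
  i <- match(sub$read1[1], rs$read1)
  expect_identical(sub$read2[1], rs$read2[i])
  # identity when the target equals everything available
  all_p <- n_pairs(rs) * 300 / 1e6 * 100
  expect_identical(n_pairs(sample_reads(rs, 1e6, all_p, seed = 2)), 60L)
  # different seeds, different subsets of equal size
  s1 <- sample_reads(rs, 1e6, 0.9, seed = 3)
  s2 <- sample_reads(rs, 1e6, 0.9, seed = 4)
  expect_identical(n_pairs(s1), n_pairs(s2))
  expect_false(identical(s1$read1, s2$read1))
  # insufficient reads: error states the achievable fraction
  expect_error(sample_reads(rs, 1e6, 50, seed = 5), "achievable p")
})

test_that("unique assignment follows the margin and threshold rules", {
  lib <- small_lib()
  cfg <- quant_config(p_percent = 100)
  # an exact substring of exactly one family is assigned with full length
  read <- substr(lib$seq[["gypA"]], 101, 220)
  cov <- assign_reads_unique(read, lib, cfg)
  expect_identical(cov$coverage_bp[cov$family == "gypA"], 120)
  expect_identical(sum(cov$reads), 1L)
  # its reverse complement maps identically
  cov_rc <- assign_reads_unique(oracle_revcomp(read), lib, cfg)
  expect_identical(cov_rc$coverage_bp, cov$coverage_bp)
  # a read matching two families with identical score stays unassigned
  lib2 <- lib
  lib2$seq[["copB"]] <- paste0(substr(lib$seq[["gypA"]], 1, 300),
                               substr(lib$seq[["copB"]], 301, 700))
  cov2 <- assign_reads_unique(substr(lib$seq[["gypA"]], 51, 170),
                              lib2, cfg)
  expect_identical(sum(cov2$reads), 0L)
  expect_identical(sum(cov2$coverage_bp), 0)
  # empty read set: zero records for every family
  empty <- assign_reads_unique(character(0), lib, cfg)
  expect_identical(empty$coverage_bp, rep(0L, 3))
  expect_identical(empty$reads, rep(0L, 3))
})

test_that("assignment equals the exhaustive brute-force oracle", {
  lib <- small_lib(seed = 31)
  bp <- small_blueprint(lib, "female", seed = 32)
  g <- render_genome(bp, lib)
  rs <- simulate_reads(g, n_pairs = 150, read_length = 100,
                       insert_mean = 240, insert_sd = 20,
                       error_rate = 0, seed = 33)
  mates <- c(rs$read1, rs$read2)
  cfg <- quant_config(p_percent = 100)
  got <- assign_reads_unique(mates, lib, cfg)
  want <- oracle_coverage(mates, lib, cfg)
  expect_equal(got$coverage_bp, want)
})

test_that("copy number and genome proportion follow their formulas", {
  expect_equal(copy_number(1500000, 10000, 0.75), 20000)
  expect_identical(copy_number(0, 5000, 0.75), 0)
  # doubling the sampled fraction halves the copies; scaling is linear
  expect_equal(copy_number(1200, 600, 1.5),
               copy_number(1200, 600, 3) * 2)
  expect_equal(copy_number(3 * 1200, 600, 1.5),
               3 * copy_number(1200, 600, 1.5))
  expect_equal(copy_number(1500, 1000, 0.75, scale = "per-2C"),
               2 * copy_number(1500, 1000, 0.75))
  expect_error(copy_number(100, 0, 0.75), "length")
  expect_error(copy_number(100, 500, 0), "p_percent")

  expect_identical(genome_proportion(500, 500), 1)
  expect_identical(genome_proportion(0, 500), 0)
  expect_error(genome_proportion(501, 500), "exceed")
})

test_that("coverage is monotone under added reads", {
  lib <- small_lib()
  cfg <- quant_config(p_percent = 100)
  reads <- vapply(1:20, function(i)
    substr(lib$seq[["gypA"]], 10 * i, 10 * i + 119), "")
  cum <- vapply(seq_along(reads), function(k) {
    cov <- assign_reads_unique(reads[seq_len(k)], lib, cfg)
    cov$coverage_bp[cov$family == "gypA"]
  }, 0)
  expect_true(all(diff(cum) >= 0))
})
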