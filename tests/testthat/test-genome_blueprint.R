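test_that("blueprints realize per-class targets exactly and obey invariants", {
  lib <- small_lib()
  targets <- data.frame(family = c("gypA", "copB", "linC"),
                        autosome = c(20L, 10L, 0L),
                        X = c(4L, 0L, 2L), Y = 0L)
  bp <- small_blueprint(lib, "female", seed = 3, targets = targets)
  expect_silent(validate_blueprint(bp))
  tt <- truth_table(bp)
  get <- function(fam, cls) {
    v <- tt$copies[tt$family == fam & tt$class == cls]
    if (length(v)) v else 0L
  }
  expect_identical(get("gypA", "autosome"), 20L)
  expect_identical(get("gypA", "X"), 4L)
  expect_identical(get("copB", "autosome"), 10L)
  expect_identical(get("linC", "X"), 2L)
  # conservation: total insertions equal the sum of all targets
  expect_identical(nrow(bp$insertions), 36L)
  # female sex chromosomes
  expect_identical(sum(bp$chromosomes$class == "X"), 2L)
  expect_identical(sum(bp$chromosomes$class == "Y"), 0L)
})

test_that("male blueprints carry X and Y; female Y targets are rejected", {
  lib <- small_lib()
  targets <- data.frame(family = "gypA", autosome = 6L, X = 2L, Y = 3L)
  bp <- small_blueprint(lib, "male", seed = 4, targets = targets)
  expect_silent(validate_blueprint(bp))
  tt <- truth_table(bp)
  expect_identical(tt$copies[tt$class == "Y"], 3L)
  expect_identical(sum(bp$chromosomes$class == "X"), 1L)
  expect_identical(sum(bp$chromosomes$class == "Y"), 1L)
  expect_error(small_blueprint(lib, "female", targets = targets),
               "Y-linked")
})

test_that("all-zero targets give an empty catalog", {
  lib <- small_lib()
  targets <- data.frame(family = "gypA", autosome = 0L, X = 0L, Y = 0L)
  bp <- small_blueprint(lib, "female", seed = 5, targets = targets)
  expect_identical(nrow(bp$insertions), 0L)
  expect_identical(nrow(truth_table(bp)), 0L)
})

test_that("infeasible packing errors name the chromosome", {
  lib <- small_lib()
  kar <- karyotype_config(60000, 2000, 35000, n_autosomes = 1)
  targets <- data.frame(family = "gypA", autosome = 0L, X = 10L, Y = 0L)
  # 10 x 900 bp cannot fit into 2 x 2000 bp of X
  expect_error(
    genome_blueprint(kar, lib, targets, "female", seed = 6),
    "infeasible packing on chromosome X")
})

test_that("rendered genomes splice TEs at the cataloged coordinates", {
  lib <- small_lib()
  bp <- small_blueprint(lib, "female", seed = 7)
  g <- render_genome(bp, lib)
  expect_identical(unname(nchar(g)),
                   as.integer(bp$chromosomes$length_bp))
  ins <- bp$insertions
  for (k in seq_len(nrow(ins))) {
    found <- substr(g[[ins$chrom[k]]], ins$start[k] + 1L,
                    ins$start[k] + ins$length_bp[k])
    want <- lib$seq[[ins$family[k]]]
    if (ins$strand[k] == "-") want <- oracle_revcomp(want)
    expect_identical(found, want)
  }
  # determinism: same blueprint renders byte-identically
  expect_identical(g, render_genome(bp, lib))
})
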