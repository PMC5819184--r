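#' Construct a simulation spec for a multi-ecotype dioecious study
#'
#' A `sim_spec` bundles everything [run_pipeline()] needs to simulate and
#' analyze a male + female genome-skimming study: the TE family table
#' (with proliferation modes), per-ecotype karyotypes and insertion
#' targets for each sex, read-simulation parameters, and quantification
#' settings.
#'
#' @param ecotypes character vector of ecotype ids.
#' @param families data.frame with columns `name`, `superfamily`,
#'   `length_bp`, `gc_fraction`, `mode` (one of `female_limited`,
#'   `male_limited`, `male_biased`, `unbiased`, `silent`; informational
#'   ground truth).
#' @param karyotypes named list (per ecotype) of lists with `female` and
#'   `male` karyotype data.frames ([karyotype_config()]).
#' @param targets named list (per ecotype) of lists with `female` and
#'   `male` target data.frames (see [genome_blueprint()]).
#' @param read list: `read_length`, `insert_mean`, `insert_sd`,
#'   `error_rate`, `sim_factor` (simulated yield as a multiple of the
#'   subsampling target).
#' @param quant list merged into [quant_config()] (notably `p_percent`).
#' @param x_fraction X share of genome length used by [x_density()].
#' @param seed master seed.
#' @return object of class `sim_spec`.
#' @export
sim_spec <- function(ecotypes, families, karyotypes, targets,
                     read = list(), quant = list(), x_fraction = 0.15,
                     seed = 1L) {
  read <- modifyList(list(read_length = 150L, insert_mean = 350,
                          insert_sd = 30, error_rate = 0.002,
                          sim_factor = 1.3), read)
  spec <- structure(list(
    ecotypes = as.character(ecotypes), families = as.data.frame(families),
    karyotypes = karyotypes, targets = targets, read = read,
    quant = quant, x_fraction = x_fraction, seed = as.integer(seed)),
    class = "sim_spec")
  validate_sim_spec(spec)
  spec
}

#' Validate a sim_spec
#'
#' Checks that every ecotype has a female and a male karyotype and target
#' table and that targets only reference declared families.
#' @param spec a `sim_spec`.
#' @return `TRUE` invisibly; otherwise an error.
#' @export
validate_sim_spec <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  need <- c("name", "superfamily", "length_bp", "gc_fraction", "mode")
  if (!all(need %in% names(spec$families)))
    stop("families needs columns: ", paste(need, collapse = ", "))
  for (eco in spec$ecotypes) {
    for (sx in c("female", "male")) {
      if (is.null(spec$karyotypes[[eco]][[sx]]))
        stop("ecotype ", eco, " lacks a ", sx, " karyotype")
      tg <- spec$targets[[eco]][[sx]]
      if (is.null(tg)) stop("ecotype ", eco, " lacks ", sx, " targets")
      bad <- setdiff(tg$family, spec$families$name)
      if (length(bad))
        stop("ecotype ", eco, " targets unknown families: ",
             paste(bad, collapse = ", "))
    }
  }
  invisible(TRUE)
}

#' @export
print.sim_spec <- function(x, ...) {
  cat(sprintf("sim_spec: %d ecotypes x 2 sexes, %d TE families, seed %d\n",
              length(x$ecotypes), nrow(x$families), x$seed))
  invisible(x)
}

#' Default multi-ecotype simulation spec mirroring the target system
#'
#' Encodes the structural facts of the studied karyotype at desk scale
#' (total 1C around 7-8 Mbp instead of ~2.8 Gbp): 11 autosome pairs plus
#' XY; X close to 15% of the haploid genome; Y exactly 1.4 times the X;
#' male genomes 2-4.5% larger than female; seven ecotypes whose female
#' genome sizes span close to 1.07-fold, driven by three transpositionally
#' active families. The nine TE families cover the observed behavioural
#' classes: a female-limited active family (X-enriched at the 4/3
#' residency expectation, absent from the Y), a male-biased family whose
#' Y-linked copy number varies across ecotypes, silent families, and
#' unbiased ones.
#'
#' @param seed master seed (default 1).
#' @return a [sim_spec()].
#' @export
paper_like_spec <- function(seed = 1L) {
  families <- data.frame(
    name = c("AthilaA", "OgreF", "ChromoU", "TekayS", "AngelaA",
             "AngelaY", "SireU", "LineL", "EnSpmD"),
    superfamily = c("Ty3/Gypsy", "Ty3/Gypsy", "Ty3/Gypsy", "Ty3/Gypsy",
                    "Ty1/Copia", "Ty1/Copia", "Ty1/Copia", "LINE",
                    "DNA-transposon"),
    length_bp = c(4500, 5500, 4000, 4200, 5000, 4800, 3500, 3000, 3200),
    gc_fraction = c(0.40, 0.42, 0.41, 0.43, 0.44, 0.45, 0.42, 0.38, 0.39),
    mode = c("unbiased", "female_limited", "unbiased", "silent",
             "unbiased", "male_biased", "unbiased", "silent", "unbiased"),
    stringsAsFactors = FALSE)

  n_eco <- 7L
  ecotypes <- sprintf("eco%d", seq_len(n_eco))
  n_auto <- 11L
  auto_bb <- 386364        # per-autosome backbone, ~4.25 Mbp over 11
  x_bb <- 750000           # X backbone: 15% of the 5 Mbp 1C backbone
  # per-ecotype Y-linked copies of the male-biased family: scattered,
  # uncorrelated with genome size (Y chromosomes polymorphic in TE load)
  y_biased <- c(26L, 40L, 18L, 34L, 50L, 30L, 44L)
  # X-density boost relative to autosomes per family: 4/3 for the
  # female-limited family (residency expectation), X-depleted for the
  # male-biased one, neutral otherwise; Y depletion factors likewise
  x_boost <- c(1, 4 / 3, 1, 1, 1, 0.5, 1, 1, 1)
  y_boost <- c(0.8, 0, 0.8, 0.8, 0.8, NA, 0.8, 0.8, 0.8)

  karyotypes <- targets <- stats::setNames(vector("list", n_eco), ecotypes)
  for (e in seq_len(n_eco)) {
    d <- (e - 1) / (n_eco - 1)
    auto_copies <- c(
      AthilaA = 80L + as.integer(round(30 * d)),
      OgreF = 120L + as.integer(round(84 * d)),
      ChromoU = 90L, TekayS = 500L,
      AngelaA = 100L + as.integer(round(60 * d)),
      AngelaY = 56L, SireU = 80L, LineL = 20L, EnSpmD = 40L)
    auto_te_bp <- sum(auto_copies * families$length_bp)
    a_len <- round(auto_bb + auto_te_bp / (2 * n_auto))
    rho <- auto_copies / (2 * n_auto * a_len)   # copies per bp, autosomes
    # X length and X copies are mutually dependent; a short fixed point
    x_len <- x_bb
    for (it in 1:4) {
      x_copies <- as.integer(round(rho * x_len * x_boost))
      x_len <- x_bb + sum(x_copies * families$length_bp)
    }
    y_len <- round(1.4 * x_len)
    y_copies <- as.integer(round(rho * y_len * y_boost))
    y_copies[is.na(y_copies)] <- y_biased[e]

    karyotypes[[e]] <- list(
      female = karyotype_config(a_len, x_len, y_len, n_auto),
      male = karyotype_config(a_len, x_len, y_len, n_auto))
    targets[[e]] <- list(
      female = data.frame(family = families$name,
                          autosome = unname(auto_copies),
                          X = 2L * x_copies, Y = 0L,
                          stringsAsFactors = FALSE),
      male = data.frame(family = families$name,
                        autosome = unname(auto_copies),
                        X = x_copies, Y = y_copies,
                        stringsAsFactors = FALSE))
  }
  sim_spec(ecotypes, families, karyotypes, targets,
           read = list(read_length = 150L, insert_mean = 350,
                       insert_sd = 30, error_rate = 0.002,
                       sim_factor = 1.3),
           quant = list(p_percent = 100),
           x_fraction = 0.15, seed = seed)
}

pipeline_stage <- function(stage, sample, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed for sample '%s': %s",
                 stage, sample, conditionMessage(e)), call. = FALSE))
}

spec_hash <- function(spec, seed) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(list(spec = unclass(spec), seed = seed)), f)
  unname(tools::md5sum(f))
}

#' Run the full simulate - quantify - compare pipeline
#'
#' Simulates every ecotype x sex sample of a [sim_spec()] (blueprint,
#' rendered genome, paired-end reads), subsamples the reads to the
#' configured fraction of that sample's 1C, assigns them uniquely to the
#' TE reference library, and derives the cross-ecotype statistics:
#' genome proportions, copy numbers, male-female genome-size differences,
#' abundance versus genome-size correlations (both proportions and copy
#' numbers), copy-number variability per sex, and per-ecotype X-density
#' estimates for subfamilies without a Y-accumulation signature.
#'
#' @param spec a `sim_spec`.
#' @param seed run seed (defaults to the spec's seed).
#' @param out_dir if non-NULL, all result tables are written there as TSV
#'   (UTF-8, tab-separated, dot decimal), each carrying the run manifest
#'   hash as a leading comment line.
#' @param scale copy-number scale, see [copy_number()].
#' @param verbose print per-stage progress to stderr.
#' @return object of class `te_report` with elements `composition`,
#'   `copy_numbers`, `sizes`, `sex_difference`, `correlations`,
#'   `variability`, `x_density`, `truth`, `manifest`.
#' @export
run_pipeline <- function(spec, seed = spec$seed, out_dir = NULL,
                         scale = c("per-1C", "per-2C"),
                         verbose = FALSE) {
  scale <- match.arg(scale)
  validate_sim_spec(spec)
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- proc.time()[["elapsed"]]

  lib <- pipeline_stage("te_reference", "library",
    te_reference(spec$families[, c("name", "superfamily", "length_bp",
                                   "gc_fraction")],
                 seed = child_seed(seed, "library")))
  qc_args <- modifyList(spec$quant, list(seed = NULL))
  qc <- do.call(quant_config, qc_args)

  comp <- cn <- sizes <- truth <- list()
  k <- 0L
  for (eco in spec$ecotypes) {
    for (sx in c("female", "male")) {
      id <- paste0(eco, "_", sx)
      bp <- pipeline_stage("blueprint", id,
        genome_blueprint(spec$karyotypes[[eco]][[sx]], lib,
                         spec$targets[[eco]][[sx]], sex = sx,
                         seed = child_seed(seed, paste0("bp:", id))))
      say("[%s] blueprint: %d insertions, %.3g pg/2C (%.1fs)", id,
          nrow(bp$insertions), bp$genome_size_pg_2C,
          proc.time()[["elapsed"]] - t0)
      one_c <- bp$genome_bp / 2
      target_pairs <- round(qc$p_percent / 100 * one_c /
                              (2 * spec$read$read_length))
      sim_pairs <- ceiling(spec$read$sim_factor * target_pairs)
      rs <- pipeline_stage("simulate_reads", id,
        simulate_reads(bp, te_library = lib, n_pairs = sim_pairs,
                       read_length = spec$read$read_length,
                       insert_mean = spec$read$insert_mean,
                       insert_sd = spec$read$insert_sd,
                       error_rate = spec$read$error_rate,
                       seed = child_seed(seed, paste0("reads:", id)),
                       sample_id = id))
      rs <- pipeline_stage("sample_reads", id,
        sample_reads(rs, one_c, qc$p_percent,
                     seed = child_seed(seed, paste0("sub:", id))))
      qt <- pipeline_stage("quantify", id,
        quantify_sample(rs, lib, qc, scale = scale))
      say("[%s] quantified %d pairs (%.1fs)", id, n_pairs(rs),
          proc.time()[["elapsed"]] - t0)
      k <- k + 1L
      comp[[k]] <- data.frame(ecotype = eco, sex = sx, family = qt$family,
                              proportion = qt$proportion,
                              percent = 100 * qt$proportion,
                              stringsAsFactors = FALSE)
      cn[[k]] <- data.frame(ecotype = eco, sex = sx, family = qt$family,
                            coverage_bp = qt$coverage_bp,
                            copies = qt$copies, stringsAsFactors = FALSE)
      sizes[[k]] <- data.frame(ecotype = eco, sex = sx,
                               genome_bp = bp$genome_bp,
                               genome_size_pg_2C = bp$genome_size_pg_2C,
                               stringsAsFactors = FALSE)
      tt <- truth_table(bp)
      truth[[k]] <- cbind(ecotype = eco, sex = sx, tt,
                          stringsAsFactors = FALSE)
    }
  }
  comp <- do.call(rbind, comp); cn <- do.call(rbind, cn)
  sizes <- do.call(rbind, sizes); truth <- do.call(rbind, truth)

  # sex differences per ecotype (Fig on genome-size differences)
  fs <- sizes[sizes$sex == "female", ]; ms <- sizes[sizes$sex == "male", ]
  ms <- ms[match(fs$ecotype, ms$ecotype), ]
  sexdiff <- data.frame(
    ecotype = fs$ecotype, F_pg_2C = fs$genome_size_pg_2C,
    M_pg_2C = ms$genome_size_pg_2C,
    diff = sex_size_difference(ms$genome_size_pg_2C,
                               fs$genome_size_pg_2C),
    stringsAsFactors = FALSE)
  sexdiff$diff_percent <- 100 * sexdiff$diff

  corr_prop <- correlate_abundance(comp, sizes, value = "proportion")
  corr_prop$measure <- "proportion"
  corr_cn <- correlate_abundance(cn, sizes, value = "copies")
  corr_cn$measure <- "copies"
  correlations <- rbind(corr_prop, corr_cn)

  variability <- copy_number_variability(cn)

  # X density per ecotype for subfamilies without Y-accumulation signature
  yflag <- variability$stats$male_ge_female[
    match(unique(cn$family), variability$stats$family)]
  xd <- list(); k <- 0L
  for (fam in unique(cn$family)) {
    sub <- cn[cn$family == fam, ]
    acc <- yflag[match(fam, unique(cn$family))]
    for (eco in unique(sub$ecotype)) {
      fcop <- sub$copies[sub$ecotype == eco & sub$sex == "female"]
      mcop <- sub$copies[sub$ecotype == eco & sub$sex == "male"]
      if (!length(fcop) || !length(mcop) || fcop <= 0) next
      k <- k + 1L
      xd[[k]] <- data.frame(
        ecotype = eco, family = fam,
        x_density = if (acc) NA_real_ else
          x_density(fcop, mcop, spec$x_fraction),
        applicable = !acc, stringsAsFactors = FALSE)
    }
  }
  xdens <- do.call(rbind, xd)

  manifest <- data.frame(
    hash = spec_hash(spec, seed), seed = seed,
    package_version = as.character(utils::packageVersion("dioecyTE")),
    scale = scale, p_percent = qc$p_percent,
    n_ecotypes = length(spec$ecotypes), n_families = nrow(spec$families),
    stringsAsFactors = FALSE)

  report <- structure(list(
    composition = comp, copy_numbers = cn, sizes = sizes,
    sex_difference = sexdiff, correlations = correlations,
    variability = variability, x_density = xdens, truth = truth,
    manifest = manifest), class = "te_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Write all report tables as TSV
#'
#' Tab-separated, UTF-8, dot decimal; every table starts with a comment
#' line carrying the run manifest hash so any number can be traced back
#' to its run.
#' @param report a `te_report`.
#' @param out_dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "te_report"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tabs <- list(composition = report$composition,
               copy_numbers = report$copy_numbers,
               sizes = report$sizes,
               sex_difference = report$sex_difference,
               correlations = report$correlations,
               variability = report$variability$stats,
               cn_difference = as.data.frame(report$variability$difference),
               x_density = report$x_density,
               truth = report$truth,
               manifest = report$manifest)
  written <- character(0)
  ok <- FALSE
  on.exit(if (!ok) unlink(written))  # no partial bundles
  for (nm in names(tabs)) {
    f <- file.path(out_dir, paste0(nm, ".tsv"))
    con <- file(f, open = "wt", encoding = "UTF-8")
    writeLines(paste0("# manifest ", report$manifest$hash), con)
    write.table(tabs[[nm]], con, sep = "\t", quote = FALSE,
                row.names = nm == "cn_difference", col.names = TRUE)
    close(con)
    written <- c(written, f)
  }
  ok <- TRUE
  invisible(out_dir)
}

#' @export
print.te_report <- function(x, ...) {
  cat(sprintf("te_report: %d ecotypes x 2 sexes, %d TE families (hash %s)\n",
              x$manifest$n_ecotypes, x$manifest$n_families,
              substr(x$manifest$hash, 1, 8)))
  cat(sprintf("  mean male-female genome-size difference: %.2f%%\n",
              mean(x$sex_difference$diff_percent)))
  cat("  tables: composition, copy_numbers, sizes, sex_difference,\n",
      "         correlations, variability, x_density, truth\n")
  invisible(x)
}

#' @export
summary.te_report <- function(object, ...) {
  cat("Genome sizes (pg/2C):\n")
  print(object$sex_difference, row.names = FALSE, digits = 4)
  cat("\nFemale abundance vs female genome size (proportions):\n")
  pr <- object$correlations
  print(pr[pr$sex == "female" & pr$measure == "proportion",
           c("family", "r", "n", "df", "p", "p_adj")],
        row.names = FALSE, digits = 3)
  cat("\nCopy-number variability flags (male CV >= female CV):\n")
  print(object$variability$stats[, c("family", "cv_male", "cv_female",
                                     "male_ge_female")],
        row.names = FALSE, digits = 3)
  invisible(object)
}

#' @export
plot.te_report <- function(x, measure = c("copies", "proportion"), ...) {
  measure <- match.arg(measure)
  tab <- if (measure == "copies") x$copy_numbers else x$composition
  fams <- unique(tab$family)
  nf <- length(fams)
  mf <- grDevices::n2mfrow(nf)
  op <- graphics::par(mfrow = mf, mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (fam in fams) {
    sub <- tab[tab$family == fam, ]
    sz <- x$sizes$genome_size_pg_2C[match(paste(sub$ecotype, sub$sex),
                                          paste(x$sizes$ecotype,
                                                x$sizes$sex))]
    col <- ifelse(sub$sex == "female", "firebrick", "steelblue")
    graphics::plot(sz, sub[[measure]], col = col, pch = 19, main = fam,
                   xlab = "genome size (pg/2C)", ylab = measure, ...)
  }
  invisible(x)
}
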