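#' Convert picograms of DNA to base pairs
#'
#' Uses 1 pg = 0.978e9 bp, the standard flow-cytometry conversion.
#' @param pg DNA amount in picograms (>= 0).
#' @return base pairs, rounded to the nearest integer (numeric to allow
#'   genome-scale values).
#' @examples
#' pg_to_bp(1)  # 978000000
#' @export
pg_to_bp <- function(pg) {
  if (any(pg < 0)) stop("pg must be non-negative")
  round(pg * PG_TO_BP)
}

#' Relative male-female genome-size difference
#'
#' `(M - F) / F` with M the male and F the female genome size (same
#' units, typically pg/2C). In an XY species with a large Y this is
#' positive and reflects the Y-X size excess. Returned as a fraction;
#' multiply by 100 for percent.
#'
#' @param M,F male and female genome sizes (> 0); vectorized.
#' @return numeric fraction(s).
#' @examples
#' sex_size_difference(6.31, 6.09)  # 0.0361 -> 3.61%
#' @export
sex_size_difference <- function(M, F) {
  if (any(F <= 0) || any(M <= 0)) stop("genome sizes must be positive")
  (M - F) / F
}

#' X-chromosome TE density relative to the genome average
#'
#' `((F - M) / F) * 2 / x_fraction` where F and M are the copy numbers of
#' a subfamily in the female and male genome and `x_fraction` is the X
#' chromosome's share of the haploid genome (0.15 for the target
#' karyotype). The male lacks one X relative to the female, so F - M
#' counts the copies on a single X; scaling by the X length share turns
#' that into a per-bp density relative to the genome average. Valid only
#' when the subfamily's Y-linked copy number is negligible — for
#' Y-accumulating subfamilies the difference undercounts the X and the
#' statistic is not applicable (`y_accumulating = TRUE` returns `NA` with
#' a warning rather than a misleading number).
#'
#' @param F_copies,M_copies female and male copy numbers (same scale).
#' @param x_fraction X share of genome length, in (0, 1); default 0.15.
#' @param y_accumulating flag subfamilies with substantial Y-linked
#'   copies; vectorized.
#' @return numeric; `NA` where flagged not applicable.
#' @examples
#' x_density(1000, 887.5)  # 1.5
#' @export
x_density <- function(F_copies, M_copies, x_fraction = 0.15,
                      y_accumulating = FALSE) {
  if (any(F_copies <= 0)) stop("F_copies must be > 0")
  if (any(x_fraction <= 0 | x_fraction >= 1))
    stop("x_fraction must be in (0, 1)")
  out <- ((F_copies - M_copies) / F_copies) * 2 / x_fraction
  if (any(y_accumulating)) {
    warning("x_density is not applicable to Y-accumulating subfamilies; ",
            "returning NA for those")
    out[rep_len(y_accumulating, length(out))] <- NA_real_
  }
  out
}

#' Pearson correlation with two-sided t-based p-value
#'
#' Standard Pearson r with the two-sided p-value from
#' `t = r * sqrt(df / (1 - r^2))`, `df = n - 2`.
#'
#' @param x,y numeric vectors of equal length `n >= 3` with non-zero
#'   variance.
#' @return object of class `correlation_result`: list with `r`, `n`,
#'   `df`, `p`.
#' @export
pearson_with_p <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3) stop("need at least 3 observations")
  if (sd(x) == 0 || sd(y) == 0)
    stop("zero variance: correlation undefined")
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  structure(list(r = unname(ct$estimate), n = n,
                 df = unname(ct$parameter), p = ct$p.value),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson r = %.4f (n = %d, df = %d), two-sided p = %.4g\n",
              x$r, x$n, x$df, x$p))
  invisible(x)
}

#' Fold variation of a set of positive values
#'
#' `max(values) / min(values)`; e.g. the spread of female genome sizes
#' across ecotypes.
#' @param values positive numeric vector, length >= 2.
#' @return numeric fold change >= 1.
#' @examples
#' fold_variation(c(5.69, 6.09))  # 1.07 at 2 d.p.
#' @export
fold_variation <- function(values) {
  if (length(values) < 2) stop("need at least 2 values")
  if (any(values <= 0)) stop("values must be positive")
  max(values) / min(values)
}

#' Copy-number variability within males and within females
#'
#' For every subfamily, computes the dispersion of copy numbers across
#' ecotypes separately within males and within females (both SD and CV;
#' CV is the headline comparison because male means carry the systematic
#' Y-driven offset), plus the per-ecotype male-minus-female difference
#' vector. A subfamily whose male dispersion is at least the female
#' dispersion is flagged: if Y-linked copies were fixed across
#' populations, male variability could not exceed female variability, so
#' the flag marks Y-linked TE polymorphism.
#'
#' @param table data.frame with columns `ecotype`, `sex`
#'   (`"male"`/`"female"`), `family`, `copies`. Ecotypes missing one sex
#'   for a family are excluded with a warning.
#' @return list of class `cn_variability`: `stats` (per-family SD/CV per
#'   sex and the `male_ge_female` flag) and `difference` (families x
#'   ecotypes matrix of M - F copy numbers).
#' @export
copy_number_variability <- function(table) {
  table <- as.data.frame(table)
  need <- c("ecotype", "sex", "family", "copies")
  if (!all(need %in% names(table)))
    stop("table needs columns: ", paste(need, collapse = ", "))
  fams <- unique(table$family)
  ecos <- unique(table$ecotype)
  diff_mat <- matrix(NA_real_, length(fams), length(ecos),
                     dimnames = list(fams, ecos))
  stats_rows <- vector("list", length(fams))
  for (fi in seq_along(fams)) {
    sub <- table[table$family == fams[fi], , drop = FALSE]
    m <- sub[sub$sex == "male", ]
    f <- sub[sub$sex == "female", ]
    both <- intersect(m$ecotype, f$ecotype)
    missing <- setdiff(ecos, both)
    if (length(missing))
      warning("family ", fams[fi], ": ecotype(s) ",
              paste(missing, collapse = ", "),
              " lack one sex and are excluded")
    if (length(both) < 2)
      stop("family ", fams[fi],
           ": need >= 2 ecotypes with both sexes")
    mv <- m$copies[match(both, m$ecotype)]
    fv <- f$copies[match(both, f$ecotype)]
    diff_mat[fi, both] <- mv - fv
    cv <- function(v) if (mean(v) == 0) NA_real_ else sd(v) / mean(v)
    stats_rows[[fi]] <- data.frame(
      family = fams[fi], n_ecotypes = length(both),
      sd_male = sd(mv), sd_female = sd(fv),
      cv_male = cv(mv), cv_female = cv(fv),
      male_ge_female = isTRUE(cv(mv) >= cv(fv)),
      stringsAsFactors = FALSE)
  }
  structure(list(stats = do.call(rbind, stats_rows),
                 difference = diff_mat), class = "cn_variability")
}

#' @export
print.cn_variability <- function(x, ...) {
  cat("copy-number variability across ecotypes (per sex):\n")
  print(x$stats, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Correlate per-family abundance with genome size across ecotypes
#'
#' Runs [pearson_with_p()] per subfamily and sex between a per-sample
#' abundance measure and genome size, with Benjamini-Hochberg adjusted
#' p-values across subfamilies within each sex.
#'
#' @param table data.frame with columns `ecotype`, `sex`, `family`, and
#'   the value column named by `value`.
#' @param sizes data.frame with columns `ecotype`, `sex`,
#'   `genome_size_pg_2C`.
#' @param value column of `table` to correlate (default `"proportion"`).
#' @return data.frame with `family`, `sex`, `r`, `n`, `df`, `p`, `p_adj`.
#' @export
correlate_abundance <- function(table, sizes, value = "proportion") {
  table <- as.data.frame(table); sizes <- as.data.frame(sizes)
  stopifnot(value %in% names(table))
  out <- list(); k <- 0L
  for (sx in unique(table$sex)) {
    sz <- sizes[sizes$sex == sx, ]
    for (fam in unique(table$family)) {
      sub <- table[table$sex == sx & table$family == fam, ]
      idx <- match(sub$ecotype, sz$ecotype)
      ok <- !is.na(idx)
      if (sum(ok) < 3) next
      ct <- pearson_with_p(sz$genome_size_pg_2C[idx[ok]],
                           sub[[value]][ok])
      k <- k + 1L
      out[[k]] <- data.frame(family = fam, sex = sx, r = ct$r, n = ct$n,
                             df = ct$df, p = ct$p,
                             stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    return(data.frame(family = character(0), sex = character(0),
                      r = numeric(0), n = integer(0), df = integer(0),
                      p = numeric(0), p_adj = numeric(0)))
  res$p_adj <- NA_real_
  for (sx in unique(res$sex))
    res$p_adj[res$sex == sx] <- p.adjust(res$p[res$sex == sx],
                                         method = "BH")
  res
}
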