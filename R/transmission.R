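#' Closed-form X:autosome and Y:autosome insertion-density ratios
#'
#' In an XY dioecious population at even sex ratio, an X chromosome spends
#' 2/3 of generations in females (females carry two of every three X
#' copies), an autosome 1/2, and a Y none. A transposable element that
#' proliferates only in the female germline therefore hits the X
#' (4/3 = (2/3)/(1/2) ~ 1.33) times as often per bp as an autosome and
#' never hits the Y; a male-limited element gives (1/3)/(1/2) = 2/3 for
#' the X and 1/(1/2) = 2 for the Y; an unbiased element is neutral.
#'
#' @param mode one of `"female_limited"`, `"male_limited"`, `"unbiased"`.
#'   `"silent"` has no insertions, so its density ratio is undefined and
#'   raises an error.
#' @return named numeric vector `c(X_A = ..., Y_A = ...)`.
#' @examples
#' expected_density_ratio("female_limited")  # c(X_A = 4/3, Y_A = 0)
#' @export
expected_density_ratio <- function(mode) {
  mode <- match.arg(mode, c("female_limited", "male_limited", "unbiased",
                            "silent"))
  if (mode == "silent")
    stop("density ratio is undefined for a silent element (no insertions)")
  res_female <- c(autosome = 1 / 2, X = 2 / 3, Y = 0)
  carrier_time <- switch(mode,
    female_limited = res_female,
    male_limited = 1 - res_female,
    unbiased = c(autosome = 1, X = 1, Y = 1))
  c(X_A = unname(carrier_time["X"] / carrier_time["autosome"]),
    Y_A = unname(carrier_time["Y"] / carrier_time["autosome"]))
}

#' Simulate transgenerational chromosome transmission and TE accumulation
#'
#' A constant-size, discrete-generation, randomly mating population with
#' `n_per_sex` individuals of each sex. Offspring inherit one random
#' homolog of each autosome pair from each parent; daughters receive the
#' father's X and one of the mother's two X copies; sons receive one of
#' the mother's X copies and the father's Y. In each generation, germline
#' insertions occur in individuals of the carrier sex (both sexes for
#' `"unbiased"`) at rate `activity` per existing copy; each new insertion
#' lands on a chromosome copy of that individual with probability
#' proportional to chromosome length. No recombination, no
#' pseudoautosomal region, no excision.
#'
#' Initial copies are seeded on autosomes only (an ancestral autosomal
#' load); with multiplicative activity they are a vanishing fraction of
#' the final counts after a few hundred generations.
#'
#' @param n_per_sex individuals per sex (>= 2).
#' @param generations number of generations (>= 1).
#' @param mode `"female_limited"`, `"male_limited"` or `"unbiased"`.
#' @param activity expected new insertions per existing copy per
#'   generation in the carrier sex (non-negative).
#' @param n_autosome_pairs number of autosome pairs (default 11).
#' @param autosome_rel,x_rel,y_rel relative chromosome lengths; defaults
#'   mimic an X about twice the mean autosome and a Y 1.4 times the X.
#' @param initial_per_autosome starting TE copies on every autosome copy.
#' @param seed integer seed.
#' @return object of class `residency_result` with female-residency
#'   fractions, mean copies and per-bp densities per chromosome class,
#'   and the X:A and Y:A density ratios.
#' @export
simulate_transmission <- function(n_per_sex, generations,
                                  mode = c("female_limited", "male_limited",
                                           "unbiased"),
                                  activity = 0.05,
                                  n_autosome_pairs = 11L,
                                  autosome_rel = 1, x_rel = 1.94,
                                  y_rel = 2.72,
                                  initial_per_autosome = 5L, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(n_per_sex >= 2, generations >= 1, activity >= 0)
  nA <- as.integer(n_autosome_pairs)
  nF <- nM <- as.integer(n_per_sex)
  La <- autosome_rel; Lx <- x_rel; Ly <- y_rel

  with_seed(seed, {
    FA <- matrix(as.numeric(initial_per_autosome), nF, 2L * nA)
    FX <- matrix(0, nF, 2L)
    MA <- matrix(as.numeric(initial_per_autosome), nM, 2L * nA)
    MX <- matrix(0, nM, 1L)
    MY <- matrix(0, nM, 1L)
    init_total <- sum(FA) + sum(MA)

    res_fem_A <- res_fem_X <- res_fem_Y <- 0
    w_female <- c(rep(La, 2L * nA), Lx, Lx)
    w_male <- c(rep(La, 2L * nA), Lx, Ly)

    for (g in seq_len(generations)) {
      # residency bookkeeping: where does each chromosome copy sit?
      res_fem_A <- res_fem_A + (nF * 2 * nA) / ((nF + nM) * 2 * nA)
      res_fem_X <- res_fem_X + (2 * nF) / (2 * nF + nM)
      res_fem_Y <- res_fem_Y + 0

      # germline insertions in the carrier sex (pre-meiosis)
      if (activity > 0 && mode %in% c("female_limited", "unbiased")) {
        for (i in seq_len(nF)) {
          tot <- sum(FA[i, ]) + sum(FX[i, ])
          if (tot == 0) next
          n_new <- rpois(1L, activity * tot)
          if (n_new == 0) next
          hit <- rmultinom(1L, n_new, w_female)[, 1L]
          FA[i, ] <- FA[i, ] + hit[seq_len(2L * nA)]
          FX[i, ] <- FX[i, ] + hit[2L * nA + 1:2]
        }
      }
      if (activity > 0 && mode %in% c("male_limited", "unbiased")) {
        for (i in seq_len(nM)) {
          tot <- sum(MA[i, ]) + MX[i, 1L] + MY[i, 1L]
          if (tot == 0) next
          n_new <- rpois(1L, activity * tot)
          if (n_new == 0) next
          hit <- rmultinom(1L, n_new, w_male)[, 1L]
          MA[i, ] <- MA[i, ] + hit[seq_len(2L * nA)]
          MX[i, 1L] <- MX[i, 1L] + hit[2L * nA + 1L]
          MY[i, 1L] <- MY[i, 1L] + hit[2L * nA + 2L]
        }
      }

      # reproduction: constant population size, random mating
      nOff <- nF + nM
      mo <- sample.int(nF, nOff, replace = TRUE)
      fa <- sample.int(nM, nOff, replace = TRUE)
      pickA <- function(P, parents) {
        choice <- matrix(sample.int(2L, nOff * nA, replace = TRUE),
                         nOff, nA)
        cols <- 2L * (col(choice) - 1L) + choice
        matrix(P[cbind(rep(parents, nA), as.vector(cols))], nOff, nA)
      }
      offMatA <- pickA(FA, mo)   # maternal autosome per pair
      offPatA <- pickA(MA, fa)   # paternal autosome per pair
      momX <- FX[cbind(mo, sample.int(2L, nOff, replace = TRUE))]

      newA <- matrix(0, nOff, 2L * nA)
      newA[, seq(1L, 2L * nA, by = 2L)] <- offMatA
      newA[, seq(2L, 2L * nA, by = 2L)] <- offPatA
      dIdx <- seq_len(nF); sIdx <- nF + seq_len(nM)
      FA <- newA[dIdx, , drop = FALSE]
      FX <- cbind(momX[dIdx], MX[fa[dIdx], 1L])
      MA <- newA[sIdx, , drop = FALSE]
      MX <- matrix(momX[sIdx], nM, 1L)
      MY <- matrix(MY[fa[sIdx], 1L], nM, 1L)
    }

    dens_A <- (sum(FA) + sum(MA)) / ((nF + nM) * 2 * nA) / La
    dens_X <- (sum(FX) + sum(MX)) / (2 * nF + nM) / Lx
    dens_Y <- sum(MY) / nM / Ly
    structure(list(
      residency = c(autosome = res_fem_A / generations,
                    X = res_fem_X / generations,
                    Y = res_fem_Y / generations),
      mean_copies = c(autosome = (sum(FA) + sum(MA)) / ((nF + nM) * 2 * nA),
                      X = (sum(FX) + sum(MX)) / (2 * nF + nM),
                      Y = sum(MY) / nM),
      density = c(autosome = dens_A, X = dens_X, Y = dens_Y),
      density_ratio = c(X_A = if (dens_A > 0) dens_X / dens_A else NA_real_,
                        Y_A = if (dens_A > 0) dens_Y / dens_A else NA_real_),
      total_copies = sum(FA) + sum(MA) + sum(FX) + sum(MX) + sum(MY),
      initial_copies = init_total,
      mode = mode, activity = activity, generations = generations,
      n_per_sex = n_per_sex), class = "residency_result")
  })
}

#' @export
print.residency_result <- function(x, ...) {
  cat(sprintf("residency_result (%s, activity %.3g, %d generations, %d/sex)\n",
              x$mode, x$activity, x$generations, x$n_per_sex))
  cat("  female residency:",
      paste(sprintf("%s %.3f", names(x$residency), x$residency),
            collapse = ", "), "\n")
  cat(sprintf("  density ratios: X:A = %.3f, Y:A = %.3f\n",
              x$density_ratio[["X_A"]], x$density_ratio[["Y_A"]]))
  invisible(x)
}
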