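# Independent brute-force oracles used to validate the aligner and the
# statistics. Deliberately naive: exhaustive diagonals, definitional
# formulas, numeric integration. Nothing here shares code with the
# package internals.

ORACLE_BASES <- c("A", "C", "G", "T")

oracle_encode <- function(s) match(strsplit(toupper(s), "")[[1]],
                                   ORACLE_BASES)

oracle_revcomp <- function(s) {
  chartr("ACGTacgt", "TGCAtgca",
         paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# match counts on every diagonal of an ungapped read-vs-ref alignment,
# via shift-and-add; diagonal k corresponds to offset d = k - L
oracle_diag_scores <- function(q, r) {
  L <- length(q); N <- length(r)
  nd <- L + N - 1L
  matches <- numeric(nd)
  for (i in seq_len(L)) {
    if (is.na(q[i])) next
    cmp <- as.numeric(!is.na(r) & r == q[i])
    idx <- seq_len(N) + (L - i)
    matches[idx] <- matches[idx] + cmp
  }
  d <- seq_len(nd) - L
  alen <- pmin(L, N - d) - pmax(0, -d)
  list(matches = matches, alen = alen, score = 2 * matches - alen)
}

# best ungapped alignment of one read against one reference, both strands
oracle_best_alignment <- function(read, ref) {
  r <- oracle_encode(ref)
  best <- NULL
  for (qs in c(read, oracle_revcomp(read))) {
    q <- oracle_encode(qs)
    ds <- oracle_diag_scores(q, r)
    ok <- ds$alen > 0
    if (!any(ok)) next
    k <- which(ok)[which.max(ds$score[ok])]
    cand <- list(score = ds$score[k], alen = ds$alen[k],
                 matches = ds$matches[k])
    if (is.null(best) || cand$score > best$score) best <- cand
  }
  best
}

# exhaustive re-implementation of the unique-assignment rule
oracle_assign <- function(mates, lib, config) {
  fam <- integer(length(mates)); alen_out <- integer(length(mates))
  for (qi in seq_along(mates)) {
    L <- nchar(mates[qi])
    per_fam <- lapply(lib$seq, function(ref)
      oracle_best_alignment(mates[qi], ref))
    scores <- vapply(per_fam, function(b)
      if (is.null(b)) -Inf else b$score, 0)
    bi <- which.max(scores); bs <- scores[bi]
    second <- if (length(scores) > 1) max(scores[-bi]) else -Inf
    b <- per_fam[[bi]]
    pass <- is.finite(bs) &&
      b$alen >= config$min_aligned_frac * L - 1e-9 &&
      (b$matches / b$alen) >= config$min_identity - 1e-9 &&
      bs > second &&
      (bs - max(second, -2 * L)) >= config$margin
    if (pass) { fam[qi] <- bi; alen_out[qi] <- b$alen }
  }
  data.frame(family = fam, aligned_bp = alen_out)
}

oracle_coverage <- function(mates, lib, config) {
  hit <- oracle_assign(mates, lib, config)
  vapply(seq_along(lib$seq), function(i)
    sum(hit$aligned_bp[hit$family == i]), 0)
}

# sliding-window (all-diagonal) identity between two sequences
oracle_pair_identity <- function(a, b, min_overlap) {
  r <- oracle_encode(b)
  best <- 0
  for (qs in c(a, oracle_revcomp(a))) {
    q <- oracle_encode(qs)
    ds <- oracle_diag_scores(q, r)
    ok <- ds$alen >= min_overlap
    if (any(ok))
      best <- max(best, max(ds$matches[ok] / ds$alen[ok]))
  }
  best
}

# definitional Pearson r and two-sided p by numeric integration of the
# t density (gamma-function form, no pt())
oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  r <- sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
  df <- n - 2
  tstat <- abs(r) * sqrt(df / (1 - r^2))
  tdens <- function(t) {
    exp(lgamma((df + 1) / 2) - lgamma(df / 2)) / sqrt(df * pi) *
      (1 + t^2 / df)^(-(df + 1) / 2)
  }
  p <- 2 * stats::integrate(tdens, tstat, Inf, rel.tol = 1e-13)$value
  list(r = r, df = df, p = p)
}

# small shared fixtures -------------------------------------------------

small_lib <- function(seed = 11) {
  te_reference(data.frame(
    name = c("gypA", "copB", "linC"),
    superfamily = c("Ty3/Gypsy", "Ty1/Copia", "LINE"),
    length_bp = c(900, 700, 500), gc_fraction = c(0.42, 0.45, 0.38),
    stringsAsFactors = FALSE), seed = seed)
}

small_blueprint <- function(lib, sex = "female", seed = 21,
                            targets = NULL) {
  kar <- karyotype_config(60000, 25000, 35000, n_autosomes = 3)
  if (is.null(targets))
    targets <- data.frame(family = c("gypA", "copB", "linC"),
                          autosome = c(12L, 8L, 6L),
                          X = c(4L, 2L, 2L), Y = 0L)
  genome_blueprint(kar, lib, targets, sex, seed = seed)
}

# tiny two-ecotype sim spec for pipeline shape/determinism tests
toy_spec <- function(seed = 5) {
  fams <- data.frame(
    name = c("gypA", "copB"), superfamily = c("Ty3/Gypsy", "Ty1/Copia"),
    length_bp = c(900, 700), gc_fraction = c(0.42, 0.45),
    mode = c("unbiased", "silent"), stringsAsFactors = FALSE)
  ecos <- c("ecoA", "ecoB", "ecoC")
  kar <- targ <- list()
  for (e in seq_along(ecos)) {
    a_len <- 50000 + 5000 * (e - 1)
    k <- karyotype_config(a_len, 20000, 28000, n_autosomes = 3)
    kar[[ecos[e]]] <- list(female = k, male = k)
    tg <- data.frame(family = fams$name,
                     autosome = c(40L + 12L * (e - 1L), 30L),
                     X = c(4L, 4L), Y = 0L)
    tgm <- tg; tgm$X <- c(2L, 2L); tgm$Y <- c(2L, 1L)
    targ[[ecos[e]]] <- list(female = tg, male = tgm)
  }
  sim_spec(ecos, fams, kar, targ,
           read = list(read_length = 100L, insert_mean = 250,
                       insert_sd = 20, error_rate = 0, sim_factor = 1.4),
           quant = list(p_percent = 100, kmer = 12),
           x_fraction = 0.15, seed = seed)
}
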