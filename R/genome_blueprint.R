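#' Describe a karyotype for blueprint construction
#'
#' Chromosome lengths are final lengths: TE insertions live inside them and
#' the non-TE backbone of each chromosome copy is whatever length remains.
#' A dioecious XY karyotype has `n_autosomes` autosome pairs plus X and Y.
#'
#' @param autosome_bp length of each autosome, scalar (recycled) or vector
#'   of length `n_autosomes`.
#' @param x_bp,y_bp sex chromosome lengths in bp.
#' @param n_autosomes number of autosome pairs (default 11).
#' @return data.frame with columns `name`, `class`, `length_bp`.
#' @export
karyotype_config <- function(autosome_bp, x_bp, y_bp, n_autosomes = 11L) {
  stopifnot(n_autosomes >= 1, all(autosome_bp > 0), x_bp > 0, y_bp > 0)
  autosome_bp <- rep_len(as.numeric(autosome_bp), n_autosomes)
  data.frame(
    name = c(sprintf("A%02d", seq_len(n_autosomes)), "X", "Y"),
    class = c(rep("autosome", n_autosomes), "X", "Y"),
    length_bp = c(autosome_bp, as.numeric(x_bp), as.numeric(y_bp)),
    stringsAsFactors = FALSE)
}

diploid_copies <- function(karyotype, sex) {
  auto <- karyotype[karyotype$class == "autosome", , drop = FALSE]
  x <- karyotype[karyotype$class == "X", , drop = FALSE]
  y <- karyotype[karyotype$class == "Y", , drop = FALSE]
  if (nrow(x) != 1) stop("karyotype must contain exactly one X")
  copies <- rbind(
    transform(auto[rep(seq_len(nrow(auto)), each = 2), ],
              copy = paste0(rep(auto$name, each = 2), "_", 1:2)),
    if (sex == "female")
      transform(x[c(1, 1), ], copy = c("X_1", "X_2"))
    else {
      if (nrow(y) != 1) stop("male karyotype requires a Y")
      rbind(transform(x, copy = "X_1"), transform(y, copy = "Y_1"))
    })
  rownames(copies) <- NULL
  copies[, c("copy", "name", "class", "length_bp")]
}

#' Build a diploid genome blueprint with an exact TE insertion catalog
#'
#' Places the requested number of TE copies per chromosome class
#' (`autosome`, `X`, `Y`; targets are totals over all copies of the class
#' in the individual). Each insertion is attached to a chromosome copy with
#' probability proportional to copy length, then positions within a copy
#' are drawn uniformly at random among non-overlapping placements.
#' Realized per-class counts equal the targets exactly; a female carries
#' two X and no Y, a male one X and one Y.
#'
#' @param karyotype data.frame from [karyotype_config()].
#' @param te_library a [te_reference()] library.
#' @param targets data.frame with columns `family`, `autosome`, `X`, `Y`
#'   (non-negative integer copy counts per individual).
#' @param sex `"female"` or `"male"`.
#' @param seed integer seed; blueprint (and its rendered sequence) is
#'   deterministic given the arguments.
#' @param genome_size_pg_2C optional measured 2C value in pg; defaults to
#'   the blueprint's own bp total converted at 0.978e9 bp/pg.
#' @param backbone_gc GC fraction of the non-TE backbone (default 0.36).
#' @return An object of class `genome_blueprint`.
#' @export
genome_blueprint <- function(karyotype, te_library, targets, sex,
                             seed, genome_size_pg_2C = NULL,
                             backbone_gc = 0.36) {
  sex <- match.arg(sex, c("female", "male"))
  stopifnot(inherits(te_library, "te_library"))
  targets <- as.data.frame(targets)
  if (!all(c("family", "autosome", "X", "Y") %in% names(targets)))
    stop("targets needs columns family, autosome, X, Y")
  unknown <- setdiff(targets$family, te_library$info$name)
  if (length(unknown))
    stop("targets reference unknown families: ",
         paste(unknown, collapse = ", "))
  cnt <- as.matrix(targets[, c("autosome", "X", "Y")])
  if (any(cnt < 0) || any(cnt != round(cnt)))
    stop("targets must be non-negative integers")
  if (sex == "female" && any(targets$Y > 0))
    stop("female blueprint cannot realize Y-linked targets")

  copies <- diploid_copies(karyotype, sex)
  fam_len <- stats::setNames(te_library$info$length_bp,
                             te_library$info$name)

  ins <- with_seed(seed, {
    # attach every insertion to a chromosome copy, class by class
    alloc <- vector("list", nrow(targets) * 3L)
    k <- 0L
    for (i in seq_len(nrow(targets))) {
      for (cls in c("autosome", "X", "Y")) {
        n <- targets[[cls]][i]
        if (n == 0) next
        pool <- copies[copies$class == cls, , drop = FALSE]
        if (nrow(pool) == 0)
          stop("no ", cls, " present in a ", sex,
               " blueprint but targets request copies")
        pick <- pool$copy[sample.int(nrow(pool), n, replace = TRUE,
                                     prob = pool$length_bp)]
        k <- k + 1L
        alloc[[k]] <- data.frame(family = targets$family[i], copy = pick,
                                 stringsAsFactors = FALSE)
      }
    }
    alloc <- do.call(rbind, alloc[seq_len(k)])
    empty <- data.frame(family = character(0), chrom = character(0),
                        start = integer(0), strand = character(0),
                        length_bp = integer(0))
    # place elements within each copy: uniform non-overlapping
    out <- vector("list", nrow(copies))
    if (!is.null(alloc)) for (ci in seq_len(nrow(copies))) {
      cp <- copies$copy[ci]
      el <- alloc[alloc$copy == cp, , drop = FALSE]
      if (nrow(el) == 0) next
      el <- el[sample.int(nrow(el)), , drop = FALSE]
      lens <- unname(fam_len[el$family])
      clen <- copies$length_bp[ci]
      if (sum(lens) > clen)
        stop("infeasible packing on chromosome ", cp, ": ",
             sum(lens), " bp of TE requested but chromosome is ",
             clen, " bp")
      free <- clen - sum(lens)
      gaps <- sort(sample.int(free + 1L, nrow(el), replace = TRUE)) - 1L
      starts <- gaps + cumsum(c(0, lens[-length(lens)]))
      out[[ci]] <- data.frame(
        family = el$family, chrom = cp, start = as.integer(starts),
        strand = sample(c("+", "-"), nrow(el), replace = TRUE),
        length_bp = as.integer(lens), stringsAsFactors = FALSE)
    }
    res <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
    if (is.null(res)) res <- empty
    rownames(res) <- NULL
    res
  })

  genome_bp <- sum(copies$length_bp)
  structure(list(
    sex = sex,
    chromosomes = copies,
    insertions = ins,
    genome_bp = genome_bp,
    genome_size_pg_2C = genome_size_pg_2C %||% (genome_bp / PG_TO_BP),
    backbone_gc = backbone_gc,
    seed = as.integer(seed)), class = "genome_blueprint")
}

#' @export
print.genome_blueprint <- function(x, ...) {
  cat(sprintf("genome_blueprint: %s, %d chromosome copies, %d TE insertions\n",
              x$sex, nrow(x$chromosomes), nrow(x$insertions)))
  cat(sprintf("  diploid size: %s bp (%.4g pg/2C)\n",
              format(x$genome_bp, big.mark = ","), x$genome_size_pg_2C))
  invisible(x)
}

#' Ground-truth copy counts of a blueprint
#'
#' @param blueprint a `genome_blueprint`.
#' @return data.frame with per-family, per-chromosome-class realized copy
#'   counts and total TE bp — the machine-readable truth table used by the
#'   downstream recovery tests.
#' @export
truth_table <- function(blueprint) {
  stopifnot(inherits(blueprint, "genome_blueprint"))
  ins <- blueprint$insertions
  cls <- blueprint$chromosomes$class[match(ins$chrom,
                                           blueprint$chromosomes$copy)]
  if (nrow(ins) == 0)
    return(data.frame(family = character(0), class = character(0),
                      copies = integer(0), te_bp = integer(0)))
  agg <- aggregate(list(copies = rep(1L, nrow(ins)), te_bp = ins$length_bp),
                   by = list(family = ins$family, class = cls), FUN = sum)
  agg[order(agg$family, agg$class), ]
}

#' Validate genome_blueprint invariants
#'
#' Sex chromosome constitution, insertion containment and pairwise
#' non-overlap within each chromosome copy.
#' @param blueprint a `genome_blueprint`.
#' @return `TRUE` invisibly; otherwise an error.
#' @export
validate_blueprint <- function(blueprint) {
  stopifnot(inherits(blueprint, "genome_blueprint"))
  ch <- blueprint$chromosomes
  nx <- sum(ch$class == "X"); ny <- sum(ch$class == "Y")
  if (blueprint$sex == "female" && !(nx == 2 && ny == 0))
    stop("female must carry exactly 2 X and 0 Y")
  if (blueprint$sex == "male" && !(nx == 1 && ny == 1))
    stop("male must carry exactly 1 X and 1 Y")
  ins <- blueprint$insertions
  for (cp in unique(ins$chrom)) {
    clen <- ch$length_bp[match(cp, ch$copy)]
    el <- ins[ins$chrom == cp, , drop = FALSE]
    if (any(el$start < 0) || any(el$start + el$length_bp > clen))
      stop("insertion outside chromosome ", cp)
    el <- el[order(el$start), , drop = FALSE]
    if (nrow(el) > 1) {
      ends <- el$start + el$length_bp
      if (any(el$start[-1] < ends[-nrow(el)]))
        stop("overlapping insertions on chromosome ", cp)
    }
  }
  invisible(TRUE)
}

#' Render a blueprint into chromosome sequences
#'
#' Generates the random non-TE backbone of every chromosome copy (derived
#' deterministically from the blueprint seed) and splices the TE reference
#' sequences in at the cataloged positions, reverse-complemented for
#' minus-strand insertions.
#'
#' @param blueprint a `genome_blueprint`.
#' @param te_library the library the blueprint was built against.
#' @return named character vector of chromosome-copy sequences; lengths
#'   equal the blueprint's `length_bp` exactly.
#' @export
render_genome <- function(blueprint, te_library) {
  stopifnot(inherits(blueprint, "genome_blueprint"),
            inherits(te_library, "te_library"))
  ch <- blueprint$chromosomes
  ins <- blueprint$insertions
  out <- character(nrow(ch))
  for (ci in seq_len(nrow(ch))) {
    cp <- ch$copy[ci]
    el <- ins[ins$chrom == cp, , drop = FALSE]
    el <- el[order(el$start), , drop = FALSE]
    bb_len <- ch$length_bp[ci] - sum(el$length_bp)
    if (bb_len < 0) stop("TE content exceeds length of ", cp)
    bb <- with_seed(child_seed(blueprint$seed, paste0("bb:", cp)),
                    random_dna(bb_len, blueprint$backbone_gc))
    if (nrow(el) == 0) { out[ci] <- bb; next }
    te_seq <- te_library$seq[el$family]
    flip <- el$strand == "-"
    if (any(flip)) te_seq[flip] <- revcomp_chr(te_seq[flip])
    # backbone segment between consecutive elements (in final coordinates)
    gap_before <- el$start - c(0L, head(el$start + el$length_bp, -1L))
    pieces <- character(2L * nrow(el) + 1L)
    pos <- 1L
    for (j in seq_len(nrow(el))) {
      pieces[2L * j - 1L] <- substr(bb, pos, pos + gap_before[j] - 1L)
      pieces[2L * j] <- te_seq[[j]]
      pos <- pos + gap_before[j]
    }
    pieces[2L * nrow(el) + 1L] <- substr(bb, pos, bb_len)
    out[ci] <- paste0(pieces, collapse = "")
  }
  names(out) <- ch$copy
  stopifnot(identical(unname(nchar(out)), as.integer(ch$length_bp)))
  out
}
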