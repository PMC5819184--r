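#' Build a synthetic TE subfamily reference library
#'
#' Generates one reference nucleotide sequence per transposable-element
#' subfamily with a prescribed length and GC content. Sequences are drawn
#' independently and re-drawn until every pair of references has maximal
#' ungapped identity below `max_pairwise_identity`, so that unique read
#' assignment across subfamilies is well-posed.
#'
#' @param specs data.frame with columns `name`, `superfamily` (one of
#'   `"Ty1/Copia"`, `"Ty3/Gypsy"`, `"LINE"`, `"DNA-transposon"`, `"other"`),
#'   `length_bp` (>= 300) and `gc_fraction` (in (0, 1)).
#' @param seed integer seed; the library is deterministic given `specs`
#'   and `seed`.
#' @param max_pairwise_identity reject threshold for the best ungapped
#'   diagonal identity between any two references (default 0.70).
#' @return An object of class `te_library`: a list with `info`
#'   (the validated spec table) and `seq` (named character vector of
#'   reference sequences).
#' @examples
#' lib <- te_reference(data.frame(
#'   name = c("OgreX", "AngelaX"), superfamily = "Ty3/Gypsy",
#'   length_bp = c(1000, 800), gc_fraction = 0.4), seed = 1)
#' lib
#' @export
te_reference <- function(specs, seed, max_pairwise_identity = 0.70) {
  specs <- as.data.frame(specs)
  required <- c("name", "superfamily", "length_bp", "gc_fraction")
  if (!all(required %in% names(specs)))
    stop("specs must have columns: ", paste(required, collapse = ", "))
  specs$name <- as.character(specs$name)
  specs$superfamily <- as.character(specs$superfamily)
  if (anyDuplicated(specs$name))
    stop("duplicate subfamily names in reference specs: ",
         paste(unique(specs$name[duplicated(specs$name)]), collapse = ", "))
  ok_super <- c("Ty1/Copia", "Ty3/Gypsy", "LINE", "DNA-transposon", "other")
  bad <- setdiff(specs$superfamily, ok_super)
  if (length(bad))
    stop("unknown superfamily: ", paste(bad, collapse = ", "))
  if (any(specs$length_bp < 300))
    stop("reference lengths must be >= 300 bp")
  if (any(specs$gc_fraction <= 0 | specs$gc_fraction >= 1))
    stop("gc_fraction must be strictly between 0 and 1")

  n <- nrow(specs)
  seqs <- character(n)
  with_seed(seed, {
    for (i in seq_len(n)) {
      for (attempt in 1:100) {
        cand <- random_dna(specs$length_bp[i], specs$gc_fraction[i])
        divergent <- TRUE
        if (i > 1) {
          min_ov <- min(300L, min(specs$length_bp[seq_len(i)]))
          for (j in seq_len(i - 1)) {
            if (cpp_pair_identity(cand, seqs[j], min_ov) >=
                max_pairwise_identity) { divergent <- FALSE; break }
          }
        }
        if (divergent) { seqs[i] <- cand; break }
      }
      if (seqs[i] == "")
        stop("could not generate a sufficiently divergent sequence for ",
             specs$name[i])
    }
  })
  names(seqs) <- specs$name
  structure(list(info = specs[, required], seq = seqs),
            class = "te_library")
}

#' @export
print.te_library <- function(x, ...) {
  cat("TE reference library:", nrow(x$info), "subfamilies\n")
  print(x$info, row.names = FALSE)
  invisible(x)
}

#' @export
length.te_library <- function(x) nrow(x$info)

#' Write / read a TE reference library as FASTA
#'
#' The superfamily is stored in the FASTA description after the name;
#' sequence lengths are recomputed on read.
#' @param lib a `te_library`.
#' @param file path to a FASTA file.
#' @return `read_te_library` returns a `te_library`.
#' @export
write_te_library <- function(lib, file) {
  stopifnot(inherits(lib, "te_library"))
  x <- Biostrings::DNAStringSet(lib$seq)
  names(x) <- paste(lib$info$name, lib$info$superfamily)
  Biostrings::writeXStringSet(x, file)
  invisible(file)
}

#' @rdname write_te_library
#' @export
read_te_library <- function(file) {
  x <- Biostrings::readDNAStringSet(file)
  parts <- strsplit(names(x), " ", fixed = TRUE)
  nm <- vapply(parts, `[[`, "", 1L)
  super <- vapply(parts, function(p) if (length(p) > 1) p[[2]] else "other",
                  "")
  seqs <- as.character(x)
  names(seqs) <- nm
  gc <- vapply(seqs, function(s) {
    tab <- table(strsplit(s, "")[[1]])
    sum(tab[intersect(c("C", "G"), names(tab))]) / nchar(s)
  }, 0)
  structure(list(
    info = data.frame(name = nm, superfamily = super,
                      length_bp = nchar(seqs), gc_fraction = unname(gc),
                      stringsAsFactors = FALSE),
    seq = seqs), class = "te_library")
}

#' Validate te_library invariants
#'
#' Checks that stated lengths match sequences, that sequences are
#' A/C/G/T/N with N fraction below 5%, and that names are unique.
#' @param lib a `te_library`.
#' @return `TRUE` invisibly; otherwise an error.
#' @export
validate_te_library <- function(lib) {
  stopifnot(inherits(lib, "te_library"))
  if (!identical(unname(nchar(lib$seq)), as.integer(lib$info$length_bp)))
    stop("length_bp does not match sequence lengths")
  if (anyDuplicated(lib$info$name)) stop("duplicate subfamily names")
  for (i in seq_along(lib$seq)) {
    s <- lib$seq[[i]]
    n_other <- nchar(gsub("[ACGTN]", "", s))
    if (n_other > 0) stop("non-ACGTN characters in ", lib$info$name[i])
    n_N <- nchar(gsub("[^N]", "", s))
    if (n_N / nchar(s) >= 0.05)
      stop("N fraction >= 5% in ", lib$info$name[i])
  }
  invisible(TRUE)
}
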