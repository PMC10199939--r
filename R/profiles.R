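# Conservation profiles: gapped homolog alignments -> position-specific
# scoring matrices in reference coordinates, and the PSSM-based mutation
# filter applied before any energy calculation.

#' Read a pre-aligned FASTA multiple sequence alignment
#'
#' Reads a gapped amino-acid alignment and locates the reference sequence.
#' Columns are later mapped to ungapped reference coordinates, so the
#' reference row must contain the full reference sequence once gaps are
#' removed.
#'
#' @param path Path to an aligned FASTA file (gaps as `-`).
#' @param reference_id FASTA identifier of the reference sequence.
#' @return An object of class `pocket_alignment`: a list with `matrix`
#'   (character matrix, rows = sequences, columns = alignment columns),
#'   `ids`, `reference_index`, and `ref_columns` (alignment column of each
#'   ungapped reference position).
#' @export
read_alignment <- function(path, reference_id) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  seqs <- seqinr::read.fasta(path, seqtype = "AA", as.string = FALSE,
                             set.attributes = FALSE)
  ids <- names(seqs)
  lens <- lengths(seqs)
  if (length(unique(lens)) != 1L)
    stop("alignment rows have unequal lengths (", paste(unique(lens),
         collapse = ", "), "); not a valid alignment")
  ref_idx <- match(reference_id, ids)
  if (is.na(ref_idx)) stop("reference id '", reference_id,
                           "' not present in alignment")
  m <- toupper(do.call(rbind, seqs))
  m[m %in% c(".", "*")] <- "-"
  ok <- m %in% c(AA_ALPHABET, "-", "X")
  if (!all(ok)) stop("alignment contains unexpected characters: ",
                     paste(unique(m[!ok]), collapse = ", "))
  ref_columns <- which(m[ref_idx, ] != "-")
  structure(list(matrix = m, ids = ids, reference_index = ref_idx,
                 ref_columns = ref_columns),
            class = "pocket_alignment")
}

#' @export
print.pocket_alignment <- function(x, ...) {
  cat("Alignment:", nrow(x$matrix), "sequences x", ncol(x$matrix),
      "columns;", length(x$ref_columns), "reference positions (reference: ",
      x$ids[x$reference_index], ")\n", sep = " ")
  invisible(x)
}

#' Build a position-specific scoring matrix from an alignment
#'
#' Computes per-position log-odds conservation scores in bits,
#' \deqn{s(p,a) = \log_2\frac{n_{pa} + m\,q_a}{(N_p + m)\,q_a},}
#' where \eqn{n_{pa}} is the count of amino acid \eqn{a} in the alignment
#' column of reference position \eqn{p}, \eqn{N_p} the number of non-gap
#' characters in that column, \eqn{q_a} the background frequency and
#' \eqn{m} the pseudocount mass (background-proportional additive smoothing).
#' Columns aligned to gaps in the reference are dropped; gap characters do
#' not contribute to counts.
#'
#' @param aln A `pocket_alignment` from [read_alignment()].
#' @param background Named numeric vector of background frequencies over
#'   the 20 amino acids, summing to 1. Default: uniform (0.05 each).
#' @param pseudocount_mass Non-negative scalar pseudocount mass; default 1.
#' @return An object of class `pssm`: list with `scores` (positions x 20
#'   matrix of bits, rows named by 1-based reference position), `background`
#'   and `pseudocount_mass`.
#' @export
build_pssm <- function(aln, background = NULL, pseudocount_mass = 1) {
  stopifnot(inherits(aln, "pocket_alignment"), pseudocount_mass >= 0)
  if (is.null(background))
    background <- stats::setNames(rep(1 / 20, 20), AA_ALPHABET)
  background <- background[AA_ALPHABET]
  if (anyNA(background) || abs(sum(background) - 1) > 1e-8)
    stop("background must be a named frequency vector over the 20 amino acids summing to 1")
  m <- aln$matrix[, aln$ref_columns, drop = FALSE]
  P <- ncol(m)
  scores <- matrix(0, P, 20, dimnames = list(seq_len(P), AA_ALPHABET))
  for (p in seq_len(P)) {
    col <- m[, p]
    col <- col[col %in% AA_ALPHABET]
    Np <- length(col)
    if (Np == 0L) {
      warning("column for reference position ", p,
              " has no non-gap residues; scores set to 0")
      next
    }
    n_pa <- table(factor(col, levels = AA_ALPHABET))
    num <- as.numeric(n_pa) + pseudocount_mass * background
    den <- (Np + pseudocount_mass) * background
    s <- log2(num / den)
    # with zero pseudocount, unobserved identities get -Inf; clamp to a
    # large finite penalty so scores stay finite as the type requires
    s[!is.finite(s)] <- -30
    scores[p, ] <- s
  }
  structure(list(scores = scores, background = background,
                 pseudocount_mass = pseudocount_mass),
            class = "pssm")
}

#' @export
print.pssm <- function(x, ...) {
  cat("PSSM:", nrow(x$scores), "positions x 20 amino acids (bits);",
      "pseudocount mass", x$pseudocount_mass, "\n")
  invisible(x)
}

#' Write / read a PSSM as TSV
#'
#' TSV with a `pos` column (1-based reference position) and one column per
#' amino acid.
#'
#' @param pssm A `pssm` object.
#' @param path Output file path.
#' @return `write_pssm` returns `path` invisibly; `read_pssm` returns a
#'   `pssm` object (background/pseudocount metadata is not stored in TSV).
#' @export
write_pssm <- function(pssm, path) {
  df <- data.frame(pos = as.integer(rownames(pssm$scores)),
                   pssm$scores, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pssm
#' @export
read_pssm <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  scores <- as.matrix(df[, AA_ALPHABET])
  rownames(scores) <- df$pos
  structure(list(scores = scores,
                 background = stats::setNames(rep(1 / 20, 20), AA_ALPHABET),
                 pseudocount_mass = NA_real_),
            class = "pssm")
}

#' Conservation filter: mutations allowed by the PSSM
#'
#' For each position, returns the identities scoring strictly above the
#' threshold (default -2 bits, the standard pre-scan filter). The reference
#' identity is always included regardless of its score.
#'
#' @param pssm A `pssm` object.
#' @param positions Integer vector of reference positions.
#' @param reference Named character vector giving the reference identity at
#'   each position in `positions`.
#' @param threshold Score threshold in bits; identities with
#'   `score > threshold` pass. Default -2.
#' @return Named list, one character vector of allowed identities per
#'   position (reference identity first).
#' @export
pssm_allowed_mutations <- function(pssm, positions, reference,
                                   threshold = -2) {
  stopifnot(inherits(pssm, "pssm"))
  keys <- .pos_key(positions)
  missing_pos <- setdiff(keys, rownames(pssm$scores))
  if (length(missing_pos))
    stop("positions absent from PSSM: ", paste(missing_pos, collapse = ", "))
  out <- lapply(keys, function(k) {
    ref_aa <- reference[[k]]
    passing <- AA_ALPHABET[pssm$scores[k, ] > threshold]
    c(ref_aa, setdiff(passing, ref_aa))
  })
  names(out) <- keys
  out
}

#' Per-position PSSM score differences for a genotype
#'
#' For each designed position, the conservation score of the mutated
#' identity minus that of the reference identity (0 where they coincide),
#' together with the sum, mean and max over the genotype's positions.
#'
#' @param genotype Named character vector (position -> identity).
#' @param reference Named character vector on the same positions.
#' @param pssm A `pssm` object covering those positions.
#' @return List with `per_position` (named numeric), `sum`, `mean`, `max`.
#' @export
delta_pssm <- function(genotype, reference, pssm) {
  .check_genotype(genotype)
  keys <- names(genotype)
  stopifnot(all(keys %in% names(reference)),
            all(keys %in% rownames(pssm$scores)))
  mut_s <- pssm$scores[cbind(keys, genotype)]
  ref_s <- pssm$scores[cbind(keys, reference[keys])]
  d <- ifelse(genotype == reference[keys], 0, mut_s - ref_s)
  names(d) <- keys
  list(per_position = d, sum = sum(d), mean = mean(d), max = max(d))
}
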