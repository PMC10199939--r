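# Origin-fixation evolutionary model over a combinatorial genotype space:
# substitution-rate matrix, selection-strength calibration and
# diffusion-coordinate visualization of the fitness landscape.

#' Origin-fixation substitution rate
#'
#' Relative fixation rate of a mutation with scaled selection coefficient
#' S: \eqn{S / (1 - e^{-S})}, extended continuously to 1 at S = 0 (the
#' neutral rate). Satisfies the detailed-balance identity
#' rate(S)/rate(-S) = e^S.
#'
#' @param S Numeric vector of scaled selection coefficients.
#' @return Numeric vector of substitution rates.
#' @export
#' @examples
#' fixation_rate(0)   # 1: neutral substitutions fix at the mutation rate
#' fixation_rate(1) / fixation_rate(-1)  # exp(1)
fixation_rate <- function(S) {
  stopifnot(all(is.finite(S)))
  out <- numeric(length(S))
  small <- abs(S) < 1e-12
  out[small] <- 1
  big_neg <- !small & S < -500     # 1 - exp(-S) overflows; rate -> 0
  out[big_neg] <- 0
  rest <- !small & !big_neg
  out[rest] <- S[rest] / (1 - exp(-S[rest]))
  out
}

#' Enumerate the genotype space of a library
#'
#' Enumerates all genotypes of a combinatorial library (positions with
#' allowed identity sets) for desk-scale analysis. Single-position identity
#' changes define adjacency, under which the space is connected.
#'
#' @param lib A `library_definition` or named allowed list.
#' @param max_size Enumeration guard; default 2e5.
#' @return An object of class `genotype_space`: list with `genotypes`
#'   (character matrix), `allowed`, `size`, `positions`.
#' @export
genotype_space <- function(lib, max_size = 2e5) {
  allowed <- if (inherits(lib, "library_definition")) lib$allowed else lib
  size <- prod(vapply(allowed, length, integer(1)))
  if (size > max_size)
    stop("genotype space has ", format(size, big.mark = ","),
         " genotypes, above the enumeration cap (", max_size,
         "); reduce the library or raise max_size")
  keys <- names(allowed)
  G <- .decode_indices(seq_len(size), allowed, keys)
  structure(list(genotypes = G, allowed = allowed, size = size,
                 positions = keys),
            class = "genotype_space")
}

# mixed-radix digit weights: index = 1 + sum_j digit_j * weight_j
.radix_weights <- function(sizes) {
  w <- cumprod(c(1, sizes))
  w[seq_along(sizes)]
}

#' Build the sparse substitution-rate matrix of a fitness landscape
#'
#' For mutationally adjacent genotypes i, j (single amino-acid changes) the
#' scaled selection coefficient is \eqn{S_{ij} = c (f_j - f_i)} with f the
#' 0/1 functional indicator, so S is +c entering the functional set, -c
#' leaving it and 0 otherwise; off-diagonal rates are
#' [fixation_rate()] of S (time measured so each possible amino-acid
#' mutation occurs at rate 1) and diagonal entries make rows sum to zero.
#' The chain is reversible with respect to \eqn{\pi_i \propto e^{c f_i}}.
#'
#' @param space A `genotype_space`.
#' @param f Numeric or logical vector of length `space$size`: functional
#'   indicator per genotype.
#' @param c Scaled selection coefficient (non-negative).
#' @return A sparse `dgCMatrix` rate matrix Q.
#' @export
build_rate_matrix <- function(space, f, c) {
  stopifnot(inherits(space, "genotype_space"), length(f) == space$size,
            c >= 0)
  f <- as.numeric(f)
  sizes <- vapply(space$allowed, length, integer(1))
  n <- space$size
  w <- .radix_weights(sizes)
  ii <- list(); jj <- list(); ss <- list()
  for (p in seq_along(sizes)) {
    kp <- sizes[p]
    if (kp < 2) next
    digit <- ((seq_len(n) - 1) %/% w[p]) %% kp
    for (a in 0:(kp - 1)) for (b in 0:(kp - 1)) {
      if (a == b) next
      i <- which(digit == a)
      j <- i + (b - a) * w[p]
      ii[[length(ii) + 1L]] <- i
      jj[[length(jj) + 1L]] <- j
      ss[[length(ss) + 1L]] <- fixation_rate(c * (f[j] - f[i]))
    }
  }
  i <- unlist(ii); j <- unlist(jj); x <- unlist(ss)
  Q <- Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(n, n))
  Matrix::diag(Q) <- -Matrix::rowSums(Q)
  Q
}

#' Stationary distribution of the evolutionary model
#'
#' Closed form \eqn{\pi_i \propto e^{c f_i}} for the reversible
#' origin-fixation chain on a regular mutation graph.
#'
#' @param f Functional indicator per genotype.
#' @param c Scaled selection coefficient.
#' @return Numeric probability vector.
#' @export
stationary_distribution <- function(f, c) {
  w <- exp(c * as.numeric(f))
  w / sum(w)
}

#' Calibrate the selection coefficient to a target functional occupancy
#'
#' Chooses c so that the stationary distribution puts `target_occupancy` of
#' its mass on functional genotypes:
#' \eqn{c = \ln\left(\frac{t}{1-t}\cdot\frac{N_{nonfunc}}{N_{func}}\right)}.
#' The default target of 60 percent long-run occupancy of functional
#' sequences corresponds to strong but not overwhelming selection on a
#' mostly nonfunctional space.
#'
#' @param f Functional indicator per genotype.
#' @param target_occupancy Target stationary mass on functional genotypes,
#'   in (0, 1); default 0.6.
#' @return The calibrated scaled selection coefficient c.
#' @export
calibrate_c <- function(f, target_occupancy = 0.6) {
  stopifnot(target_occupancy > 0, target_occupancy < 1)
  f <- as.logical(f)
  nf <- sum(f); nn <- sum(!f)
  if (nf == 0) stop("no functional genotypes; cannot calibrate")
  if (nn == 0) stop("no nonfunctional genotypes; cannot calibrate")
  log(target_occupancy / (1 - target_occupancy) * nn / nf)
}

#' Diffusion coordinates of a fitness landscape
#'
#' Computes the subdominant right eigenvectors of the rate matrix
#' associated with the smallest-magnitude nonzero eigenvalues,
#' pi-orthonormalized and scaled by \eqn{1/\sqrt{-\lambda_k}} so the axes
#' carry units of sqrt(time): squared Euclidean distances between genotypes
#' approximate round-trip evolutionary times (commute times). The
#' computation symmetrizes Q with the stationary distribution
#' (\eqn{A = D_\pi^{1/2} Q D_\pi^{-1/2}}), which is exact for this
#' reversible chain. Signs follow a fixed convention: the entry of largest
#' magnitude on each axis is positive.
#'
#' @param Q Sparse rate matrix from [build_rate_matrix()].
#' @param pi Stationary distribution.
#' @param k Number of diffusion axes; default 2.
#' @param method "dense" (full [eigen()], default below 5000 genotypes) or
#'   "iterative" (Lanczos via [igraph::arpack()]).
#' @return Numeric matrix (n x k) of coordinates, columns `axis1..axisk`,
#'   with eigenvalues in attribute `lambda`.
#' @export
diffusion_coordinates <- function(Q, pi, k = 2,
                                  method = c("auto", "dense", "iterative")) {
  n <- nrow(Q)
  if (k >= n) stop("k must be smaller than the number of genotypes")
  method <- match.arg(method)
  if (method == "auto") method <- if (n < 5000) "dense" else "iterative"
  sq <- sqrt(pi)
  A <- Matrix::Diagonal(x = sq) %*% Q %*% Matrix::Diagonal(x = 1 / sq)
  A <- (A + Matrix::t(A)) / 2   # exact symmetry up to round-off
  if (method == "dense") {
    eig <- eigen(as.matrix(A), symmetric = TRUE)
    vals <- eig$values[seq_len(k + 1)]
    vecs <- eig$vectors[, seq_len(k + 1), drop = FALSE]
  } else {
    res <- igraph::arpack(
      function(x, extra = NULL) as.numeric(A %*% x),
      options = list(n = n, nev = k + 1, ncv = min(n, max(20, 4 * (k + 1))),
                     which = "LA", maxiter = 5000),
      sym = TRUE)
    ord <- order(res$values, decreasing = TRUE)
    vals <- res$values[ord][seq_len(k + 1)]
    vecs <- res$vectors[, ord, drop = FALSE][, seq_len(k + 1), drop = FALSE]
  }
  # drop the stationary eigenvector (eigenvalue 0)
  lam <- vals[-1]
  V <- vecs[, -1, drop = FALSE]
  coords <- matrix(0, n, k, dimnames = list(NULL,
                                            paste0("axis", seq_len(k))))
  for (m in seq_len(k)) {
    u <- V[, m] / sq                      # right eigenvector of Q
    u <- u / sqrt(sum(pi * u^2))          # pi-orthonormal
    if (u[which.max(abs(u))] < 0) u <- -u # deterministic sign
    coords[, m] <- u / sqrt(-lam[m])
  }
  attr(coords, "lambda") <- lam
  coords
}

#' Per-region position-frequency matrices along a diffusion axis
#'
#' Partitions functional genotypes by intervals of one diffusion axis and
#' returns, per region, the per-position amino-acid frequency matrix (rows
#' sum to 1), suitable as sequence-logo input. The default thresholds
#' (-2.25, -0.5) carve three regions along the axis that separates
#' spectral classes in the fluorescent-protein analysis.
#'
#' @param coordinates Matrix from [diffusion_coordinates()].
#' @param genotypes Character matrix aligned with `coordinates` rows.
#' @param axis Axis index; default 2.
#' @param thresholds Ascending numeric cut points; default c(-2.25, -0.5).
#' @param functional Optional logical mask restricting to functional
#'   genotypes.
#' @return Named list of regions; each a list with `interval`, `n`, and
#'   `frequencies` (positions x 20 matrix).
#' @export
region_logos <- function(coordinates, genotypes, axis = 2,
                         thresholds = c(-2.25, -0.5), functional = NULL) {
  stopifnot(!is.unsorted(thresholds))
  x <- coordinates[, axis]
  if (!is.null(functional)) {
    genotypes <- genotypes[functional, , drop = FALSE]
    x <- x[functional]
  }
  breaks <- c(-Inf, thresholds, Inf)
  bin <- cut(x, breaks = breaks, include.lowest = TRUE)
  out <- lapply(seq_len(nlevels(bin)), function(b) {
    sel <- which(as.integer(bin) == b)
    freq <- matrix(0, ncol(genotypes), 20,
                   dimnames = list(colnames(genotypes), AA_ALPHABET))
    if (!length(sel)) {
      warning("region ", levels(bin)[b], " contains no genotypes")
    } else {
      for (p in seq_len(ncol(genotypes))) {
        tab <- table(factor(genotypes[sel, p], levels = AA_ALPHABET))
        freq[p, ] <- as.numeric(tab) / length(sel)
      }
    }
    list(interval = levels(bin)[b], n = length(sel), frequencies = freq)
  })
  names(out) <- levels(bin)
  out
}

#' Write diffusion coordinates as TSV
#'
#' @param coordinates Matrix from [diffusion_coordinates()].
#' @param genotypes Character matrix of genotypes (rows aligned).
#' @param functional Logical vector of functional labels.
#' @param path Output path.
#' @export
write_coordinates <- function(coordinates, genotypes, functional, path) {
  df <- data.frame(genotype = apply(genotypes, 1, paste, collapse = ""),
                   coordinates, functional = functional)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
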