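# Energy oracle contract and the synthetic additive-plus-pairwise landscape
# that stands in for an atomistic energy program in tests and demos. The
# landscape is gauged so the reference genotype has energy 0, hence every
# energy is directly a ddG relative to the reference.

#' Generate a synthetic epistatic energy landscape
#'
#' Builds an additive-plus-pairwise (Potts-style) energy function over the
#' designed positions: per-(position, identity) field terms plus
#' per-(position-pair, identity-pair) coupling terms restricted to
#' contacting position pairs. All terms vanish on reference identities, so
#' the reference genotype scores exactly 0. A chosen number of
#' (position-pair, identity-pair) combinations among the contacts receive an
#' additional large positive penalty: these planted incompatible pairs are
#' the controlled source of strong epistasis, and are recorded in the
#' returned object so tests can verify they are excluded downstream.
#'
#' @param designed Integer vector of designed positions.
#' @param allowed Named list: position -> allowed identities (reference
#'   identity first).
#' @param reference Named character vector of reference identities.
#' @param contacts Two-column matrix or data frame of contacting position
#'   pairs (p, q).
#' @param field_scale Standard deviation of the Gaussian field terms;
#'   default 1.
#' @param coupling_scale Standard deviation of the Gaussian coupling terms;
#'   default 0.25.
#' @param n_incompatible_pairs Number of planted incompatible
#'   (position-pair, identity-pair) combinations; default 0.
#' @param incompatible_penalty Energy penalty added to each planted pair;
#'   default `8 * field_scale`.
#' @param seed Integer seed; the landscape is fully reproducible from it.
#' @return An object of class `synthetic_landscape`: fields `h` (list of
#'   named numeric vectors), `J` (list of matrices keyed "p:q"), `planted`
#'   (data frame of planted incompatibilities), `reference`, `allowed`.
#' @export
generate_landscape <- function(designed, allowed, reference, contacts,
                               field_scale = 1, coupling_scale = 0.25,
                               n_incompatible_pairs = 0,
                               incompatible_penalty = 8 * field_scale,
                               seed = 1) {
  keys <- .pos_key(designed)
  stopifnot(all(keys %in% names(allowed)), all(keys %in% names(reference)))
  contacts <- as.matrix(contacts)[, 1:2, drop = FALSE]
  storage.mode(contacts) <- "integer"
  set.seed(seed)
  h <- lapply(keys, function(k) {
    aa <- allowed[[k]]
    v <- stats::setNames(stats::rnorm(length(aa), 0, field_scale), aa)
    v[reference[[k]]] <- 0
    v
  })
  names(h) <- keys
  J <- list()
  for (i in seq_len(nrow(contacts))) {
    p <- min(contacts[i, ]); q <- max(contacts[i, ])
    kp <- as.character(p); kq <- as.character(q)
    if (!(kp %in% keys && kq %in% keys)) next
    ap <- allowed[[kp]]; aq <- allowed[[kq]]
    m <- matrix(stats::rnorm(length(ap) * length(aq), 0, coupling_scale),
                length(ap), length(aq), dimnames = list(ap, aq))
    m[reference[[kp]], ] <- 0
    m[, reference[[kq]]] <- 0
    J[[paste(kp, kq, sep = ":")]] <- m
  }
  # plant incompatible identity pairs on contacting positions
  planted <- data.frame(p = integer(0), q = integer(0),
                        aa_p = character(0), aa_q = character(0),
                        penalty = numeric(0))
  if (n_incompatible_pairs > 0) {
    cand <- list()
    for (key in names(J)) {
      pq <- as.integer(strsplit(key, ":")[[1]])
      ap <- setdiff(allowed[[as.character(pq[1])]], reference[[as.character(pq[1])]])
      aq <- setdiff(allowed[[as.character(pq[2])]], reference[[as.character(pq[2])]])
      for (a in ap) for (b in aq)
        cand[[length(cand) + 1L]] <- list(p = pq[1], q = pq[2], a = a, b = b)
    }
    if (n_incompatible_pairs > length(cand))
      stop("n_incompatible_pairs (", n_incompatible_pairs,
           ") exceeds available contacting identity pairs (", length(cand), ")")
    pick <- sample.int(length(cand), n_incompatible_pairs)
    for (ix in pick) {
      cc <- cand[[ix]]
      key <- paste(cc$p, cc$q, sep = ":")
      J[[key]][cc$a, cc$b] <- J[[key]][cc$a, cc$b] + incompatible_penalty
      planted <- rbind(planted,
                       data.frame(p = cc$p, q = cc$q, aa_p = cc$a,
                                  aa_q = cc$b,
                                  penalty = incompatible_penalty))
    }
  }
  structure(list(h = h, J = J, planted = planted,
                 reference = reference[keys], allowed = allowed[keys],
                 seed = seed, field_scale = field_scale,
                 coupling_scale = coupling_scale),
            class = "synthetic_landscape")
}

#' @export
print.synthetic_landscape <- function(x, ...) {
  cat("Synthetic landscape:", length(x$h), "positions,", length(x$J),
      "coupled pairs,", nrow(x$planted), "planted incompatible pairs",
      "(seed", paste0(x$seed, ")"), "\n")
  invisible(x)
}

#' Evaluate landscape energy of genotypes
#'
#' Energy of a genotype is the sum of its field terms plus the coupling
#' terms over contacting position pairs; the reference genotype scores 0.
#'
#' @param oracle A `synthetic_landscape`.
#' @param genotypes Named character vector (one genotype) or character
#'   matrix with position colnames (one genotype per row). Positions absent
#'   from a genotype implicitly carry the reference identity.
#' @return Numeric vector of energies (arbitrary energy units).
#' @export
landscape_energy <- function(oracle, genotypes) {
  stopifnot(inherits(oracle, "synthetic_landscape"))
  G <- .as_genotype_matrix(genotypes)
  keys <- names(oracle$h)
  # fill missing positions with reference
  miss <- setdiff(keys, colnames(G))
  if (length(miss)) {
    G <- cbind(G, matrix(rep(oracle$reference[miss], each = nrow(G)),
                         nrow(G), length(miss),
                         dimnames = list(NULL, miss)))
  }
  for (k in keys) {
    bad <- setdiff(unique(G[, k]), oracle$allowed[[k]])
    if (length(bad))
      stop("identity outside landscape alphabet at position ", k, ": ",
           paste(bad, collapse = ", "))
  }
  E <- numeric(nrow(G))
  for (k in keys) E <- E + oracle$h[[k]][G[, k]]
  for (key in names(oracle$J)) {
    pq <- strsplit(key, ":")[[1]]
    E <- E + oracle$J[[key]][cbind(G[, pq[1]], G[, pq[2]])]
  }
  unname(E)
}

#' Single-mutation ddG scan
#'
#' Models each candidate point mutation separately on the reference
#' background and records its energy difference from the reference
#' (ddG). Candidates equal to the reference identity are dropped with a
#' message.
#'
#' @param oracle A `synthetic_landscape` (or any object for which
#'   [landscape_energy()] is defined).
#' @param reference Named character vector of reference identities.
#' @param candidates Named list: position -> candidate identities.
#' @return Data frame (class `ddg_scan`): position, from_aa, to_aa, ddg.
#' @export
ddg_scan <- function(oracle, reference, candidates) {
  rows <- list()
  e_ref <- landscape_energy(oracle, reference[names(oracle$h)])
  for (k in names(candidates)) {
    for (aa in candidates[[k]]) {
      if (aa == reference[[k]]) next
      g <- reference[names(oracle$h)]
      g[[k]] <- aa
      rows[[length(rows) + 1L]] <- data.frame(
        position = as.integer(k), from_aa = reference[[k]], to_aa = aa,
        ddg = landscape_energy(oracle, g) - e_ref)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(position = integer(0), from_aa = character(0),
               to_aa = character(0), ddg = numeric(0))
  class(out) <- c("ddg_scan", "data.frame")
  out
}

#' Read / write a ddG scan as TSV
#'
#' Columns: position, from_aa, to_aa, ddg (chain optional on read).
#'
#' @param scan A `ddg_scan` data frame.
#' @param path File path.
#' @return `read_ddg_scan` returns a `ddg_scan` data frame.
#' @export
write_ddg_scan <- function(scan, path) {
  utils::write.table(scan, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_ddg_scan
#' @export
read_ddg_scan <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("position", "from_aa", "to_aa", "ddg")
  if (!all(need %in% names(df)))
    stop("scan TSV must have columns: ", paste(need, collapse = ", "))
  out <- df[, need]
  class(out) <- c("ddg_scan", "data.frame")
  out
}

#' Filter a scan by ddG threshold
#'
#' Retains mutations with `ddg <= threshold` (boundary inclusive); the
#' reference identity is always allowed.
#'
#' @param scan A `ddg_scan`.
#' @param threshold ddG threshold in energy units.
#' @return Named list: position -> allowed identities (reference first).
#' @export
filter_by_ddg <- function(scan, threshold) {
  pos <- sort(unique(scan$position))
  out <- lapply(pos, function(p) {
    sub <- scan[scan$position == p, , drop = FALSE]
    keep <- sub$to_aa[sub$ddg <= threshold]
    c(sub$from_aa[1], keep)
  })
  names(out) <- as.character(pos)
  out
}

#' Epistasis gap of multipoint mutants
#'
#' For each combination of mutations, the energy of the multipoint mutant
#' minus the sum of its constituent single-mutation ddG values. On a purely
#' additive landscape the gap is identically 0; planted incompatible pairs
#' surface as large positive gaps.
#'
#' @param oracle Energy oracle.
#' @param combos List of named character vectors (position -> mutated
#'   identity), each a set of mutations applied together.
#' @param scan A `ddg_scan` covering every constituent mutation.
#' @param reference Named character vector of reference identities.
#' @return List with `delta` (numeric vector, one gap per combo) and
#'   `summary` (quartiles and 1.5 IQR whisker bounds).
#' @export
epistasis_gap <- function(oracle, combos, scan, reference) {
  key <- paste(scan$position, scan$to_aa)
  e_ref <- landscape_energy(oracle, reference[names(oracle$h)])
  delta <- vapply(combos, function(cmb) {
    g <- reference[names(oracle$h)]
    g[names(cmb)] <- cmb
    idx <- match(paste(names(cmb), cmb), key)
    if (anyNA(idx)) stop("combo contains a mutation absent from the scan")
    (landscape_energy(oracle, g) - e_ref) - sum(scan$ddg[idx])
  }, numeric(1))
  q <- stats::quantile(delta, c(0.25, 0.5, 0.75), names = FALSE)
  iqr <- q[3] - q[1]
  list(delta = delta,
       summary = c(q1 = q[1], median = q[2], q3 = q[3],
                   whisker_low = q[1] - 1.5 * iqr,
                   whisker_high = q[3] + 1.5 * iqr))
}

#' Serialize / load a synthetic landscape as JSON
#'
#' @param oracle A `synthetic_landscape`.
#' @param path File path.
#' @return `read_landscape` returns a `synthetic_landscape`.
#' @export
write_landscape <- function(oracle, path) {
  obj <- list(
    reference = as.list(oracle$reference),
    allowed = oracle$allowed,
    h = lapply(oracle$h, as.list),
    J = lapply(oracle$J, function(m)
      list(rows = rownames(m), cols = colnames(m), values = as.vector(m))),
    planted = oracle$planted, seed = oracle$seed,
    field_scale = oracle$field_scale, coupling_scale = oracle$coupling_scale)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_landscape
#' @export
read_landscape <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  h <- lapply(obj$h, function(v) unlist(v))
  J <- lapply(obj$J, function(jj)
    matrix(jj$values, length(jj$rows), length(jj$cols),
           dimnames = list(jj$rows, jj$cols)))
  allowed <- lapply(obj$allowed, unlist)
  planted <- as.data.frame(obj$planted)
  structure(list(h = h, J = J, planted = planted,
                 reference = unlist(obj$reference), allowed = allowed,
                 seed = obj$seed, field_scale = obj$field_scale,
                 coupling_scale = obj$coupling_scale),
            class = "synthetic_landscape")
}
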