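# Neighborhood enumeration, energy-based labeling, single-hidden-layer
# neural-network ranking of mutations and combinatorial library selection.

#' Size of the combinatorial sequence space of a library
#'
#' Exact product of the per-position allowed-identity counts (reference
#' identity included). Returned as a double so astronomically large spaces
#' (e.g. 20^27, about 1e35) are representable.
#'
#' @param lib A `library_definition` or a named list position -> allowed
#'   identities.
#' @return Numeric scalar, the number of genotypes in the space.
#' @export
space_size <- function(lib) {
  allowed <- if (inherits(lib, "library_definition")) lib$allowed else lib
  prod(vapply(allowed, length, integer(1)))
}

#' Select the ddG threshold bounding the modeled sequence space
#'
#' For each threshold on a grid, computes the total number of designs
#' implied across all neighborhoods, where a neighborhood with member
#' positions \eqn{p} contributes \eqn{\prod_p (1 + m_p(t))} designs
#' (\eqn{m_p(t)} = mutations at position p passing threshold t). Returns
#' the largest grid threshold whose total stays strictly under
#' `max_total` (default 1e6, the standard modeling budget).
#'
#' @param neighborhoods List of `neighborhood` objects.
#' @param scan A `ddg_scan`.
#' @param grid Ascending numeric vector of candidate thresholds.
#' @param max_total Upper bound on the total number of designs; default 1e6.
#' @return The selected threshold, with attribute `sizes`: data frame
#'   (threshold, total).
#' @export
select_ddg_threshold <- function(neighborhoods, scan, grid,
                                 max_total = 1e6) {
  stopifnot(max_total > 0, !is.unsorted(grid))
  totals <- vapply(grid, function(t) {
    allowed <- filter_by_ddg(scan, t)
    sum(vapply(neighborhoods, function(nb) {
      prod(vapply(as.character(nb$members), function(k) {
        a <- allowed[[k]]
        if (is.null(a)) 1 else length(a)
      }, numeric(1)))
    }, numeric(1)))
  }, numeric(1))
  ok <- which(totals < max_total)
  if (!length(ok)) {
    warning("no grid threshold keeps the total sequence space under ",
            max_total, "; returning the smallest grid value")
    sel <- grid[1]
  } else {
    sel <- grid[max(ok)]
  }
  attr(sel, "sizes") <- data.frame(threshold = grid, total = totals)
  sel
}

# decode linear indices (1-based) of a mixed-radix space into genotype rows
.decode_indices <- function(idx, allowed, keys) {
  sizes <- vapply(allowed[keys], length, integer(1))
  G <- matrix("", length(idx), length(keys), dimnames = list(NULL, keys))
  rem <- idx - 1
  for (j in seq_along(keys)) {
    G[, j] <- allowed[[keys[j]]][(rem %% sizes[j]) + 1]
    rem <- rem %/% sizes[j]
  }
  G
}

#' Enumerate or sample the sequence space of a neighborhood
#'
#' Neighborhoods whose space (product over member positions of allowed
#' identity counts) is smaller than `full_limit` are fully enumerated;
#' larger neighborhoods are sampled uniformly without replacement at
#' `sample_fraction` of the space.
#'
#' @param nbhd A `neighborhood`.
#' @param allowed Named list position -> allowed identities (reference
#'   included).
#' @param full_limit Full-enumeration limit; default 10000.
#' @param sample_fraction Fraction sampled for larger spaces; default 0.1.
#' @param seed Integer seed for the sampling branch.
#' @return Character matrix, one genotype per row, columns = member
#'   positions.
#' @export
enumerate_neighborhood <- function(nbhd, allowed, full_limit = 10000,
                                   sample_fraction = 0.1, seed = 1) {
  stopifnot(sample_fraction > 0, sample_fraction <= 1)
  keys <- .pos_key(nbhd$members)
  miss <- setdiff(keys, names(allowed))
  if (length(miss)) stop("no allowed identities for position(s): ",
                         paste(miss, collapse = ", "))
  size <- prod(vapply(allowed[keys], length, integer(1)))
  if (size < full_limit) {
    idx <- seq_len(size)
  } else {
    n <- ceiling(sample_fraction * size)
    set.seed(seed)
    if (size <= .Machine$integer.max) {
      idx <- sample.int(size, n)
    } else {
      # rejection sampling with deduplication for spaces beyond int range
      idx <- unique(floor(stats::runif(2 * n, 1, size + 1)))
      while (length(idx) < n)
        idx <- unique(c(idx, floor(stats::runif(n, 1, size + 1))))
      idx <- idx[seq_len(n)]
    }
  }
  .decode_indices(idx, allowed, keys)
}

#' Energy-based success/fail labeling of neighborhood designs
#'
#' Designs scoring strictly better (lower) than the reference energy are
#' successes (1). The worst 50 percent of the neighborhood sample (by
#' descending energy, ceiling(n/2) designs) are failures (0) unless they
#' already qualify as successes (the success rule takes precedence).
#' Remaining designs are undetermined and excluded from training.
#'
#' @param energies Numeric vector of design energies.
#' @param reference_energy Energy of the reference genotype.
#' @return Character vector in {"success", "fail", "undetermined"}.
#' @export
label_designs <- function(energies, reference_energy) {
  stopifnot(length(energies) > 0, all(is.finite(energies)))
  n <- length(energies)
  lab <- rep("undetermined", n)
  worst <- order(energies, decreasing = TRUE)[seq_len(ceiling(n / 2))]
  lab[worst] <- "fail"
  lab[energies < reference_energy] <- "success"
  lab
}

# one-hot encoding over the full designed-position space
.one_hot_columns <- function(allowed) {
  unlist(lapply(names(allowed), function(k)
    paste0("p", k, ".", allowed[[k]])), use.names = FALSE)
}

.one_hot_encode <- function(G, allowed) {
  keys <- names(allowed)
  cols <- .one_hot_columns(allowed)
  X <- matrix(0, nrow(G), length(cols), dimnames = list(NULL, cols))
  for (k in keys) {
    bad <- setdiff(unique(G[, k]), allowed[[k]])
    if (length(bad))
      stop("identity not in allowed set at position ", k, ": ",
           paste(bad, collapse = ", "))
    X[cbind(seq_len(nrow(G)), match(paste0("p", k, ".", G[, k]), cols))] <- 1
  }
  X
}

.one_hot_decode <- function(X, allowed) {
  keys <- names(allowed)
  G <- matrix("", nrow(X), length(keys), dimnames = list(NULL, keys))
  off <- 0L
  for (k in keys) {
    nk <- length(allowed[[k]])
    block <- X[, off + seq_len(nk), drop = FALSE]
    G[, k] <- allowed[[k]][max.col(block)]
    off <- off + nk
  }
  G
}

#' Pool labeled neighborhood samples into a training dataset
#'
#' Each neighborhood genotype is embedded into the full designed-position
#' space (reference identity at non-member positions), one-hot encoded over
#' the allowed identities (reference included per position), and pooled
#' across neighborhoods. Undetermined designs are dropped.
#'
#' @param samples List of neighborhood samples; each a list with elements
#'   `genotypes` (character matrix over member positions), `energies`, and
#'   optionally `labels` (computed from energies when absent) and
#'   `neighborhood`.
#' @param allowed Named list over all designed positions.
#' @param reference Named character vector of reference identities.
#' @param reference_energy Energy of the reference; default 0.
#' @return An object of class `epinnet_dataset`: list with `X` (one-hot
#'   matrix), `y` (factor success/fail), `provenance` (neighborhood of
#'   origin per row), `allowed`, `reference`.
#' @export
assemble_dataset <- function(samples, allowed, reference,
                             reference_energy = 0) {
  keys <- names(allowed)
  Xs <- list(); ys <- list(); prov <- list()
  for (i in seq_along(samples)) {
    smp <- samples[[i]]
    lab <- smp$labels
    if (is.null(lab)) lab <- label_designs(smp$energies, reference_energy)
    keep <- lab != "undetermined"
    if (!any(keep)) next
    G <- smp$genotypes[keep, , drop = FALSE]
    full <- matrix(rep(reference[keys], each = nrow(G)), nrow(G),
                   length(keys), dimnames = list(NULL, keys))
    full[, colnames(G)] <- G
    Xs[[length(Xs) + 1L]] <- .one_hot_encode(full, allowed)
    ys[[length(ys) + 1L]] <- lab[keep]
    ctr <- if (!is.null(smp$neighborhood)) smp$neighborhood$center else i
    prov[[length(prov) + 1L]] <- rep(ctr, sum(keep))
  }
  if (!length(Xs)) stop("no labeled designs to assemble")
  structure(list(X = do.call(rbind, Xs),
                 y = factor(unlist(ys), levels = c("fail", "success")),
                 provenance = unlist(prov),
                 allowed = allowed, reference = reference[keys]),
            class = "epinnet_dataset")
}

#' Train the mutation-ranking neural network
#'
#' Fits a multi-layer perceptron with a single hidden layer whose width
#' equals the number of designed positions, on the one-hot encoded
#' success/fail data, using an 80/20 train/test split. The trained network
#' scores genotypes by their probability of being a low-energy (success)
#' design.
#'
#' @param ds An `epinnet_dataset`.
#' @param hidden_size Hidden-layer width; default = number of designed
#'   positions.
#' @param max_iter Maximum training iterations; default 2000.
#' @param train_fraction Fraction of rows used for training; default 0.8.
#' @param decay L2 weight decay; default 0.5. Strong regularization keeps
#'   single-mutation scores anchored to marginal success statistics across
#'   mutation combinations, which is what the downstream ranking uses.
#' @param seed Integer seed controlling the split and initial weights.
#' @return An object of class `epinnet_model`: list with `net` (the fitted
#'   [nnet::nnet] object), `allowed`, `reference`, `holdout_accuracy`.
#' @export
train_epinnet <- function(ds, hidden_size = NULL, max_iter = 2000,
                          train_fraction = 0.8, decay = 0.5, seed = 1) {
  stopifnot(inherits(ds, "epinnet_dataset"))
  if (nlevels(droplevels(ds$y)) < 2)
    stop("training requires both success and fail labels")
  if (is.null(hidden_size)) hidden_size <- length(ds$allowed)
  set.seed(seed)
  n <- nrow(ds$X)
  tr <- sample.int(n, floor(train_fraction * n))
  te <- setdiff(seq_len(n), tr)
  y01 <- as.integer(ds$y == "success")
  net <- nnet::nnet(x = ds$X[tr, , drop = FALSE], y = y01[tr],
                    size = hidden_size, maxit = max_iter, decay = decay,
                    entropy = TRUE, trace = FALSE,
                    MaxNWts = 100000)
  acc <- if (length(te)) {
    pred <- as.numeric(stats::predict(net, ds$X[te, , drop = FALSE]))
    mean((pred > 0.5) == y01[te])
  } else NA_real_
  structure(list(net = net, allowed = ds$allowed,
                 reference = ds$reference, holdout_accuracy = acc,
                 hidden_size = hidden_size, seed = seed),
            class = "epinnet_model")
}

#' @export
print.epinnet_model <- function(x, ...) {
  cat("Mutation-ranking MLP:", length(x$allowed), "positions, hidden width",
      x$hidden_size, "| held-out accuracy",
      sprintf("%.3f", x$holdout_accuracy), "\n")
  invisible(x)
}

#' Score a set of genotypes with a trained model
#'
#' @param model An `epinnet_model`.
#' @param genotypes Named character vector or character matrix.
#' @return Numeric vector of success probabilities.
#' @export
epinnet_score <- function(model, genotypes) {
  G <- .as_genotype_matrix(genotypes)
  keys <- names(model$allowed)
  miss <- setdiff(keys, colnames(G))
  if (length(miss))
    G <- cbind(G, matrix(rep(model$reference[miss], each = nrow(G)),
                         nrow(G), length(miss),
                         dimnames = list(NULL, miss)))
  as.numeric(stats::predict(model$net, .one_hot_encode(G[, keys, drop = FALSE],
                                                       model$allowed)))
}

#' Rank tolerated single mutations by predicted compatibility
#'
#' Feeds each tolerated single-point mutation (on the reference background)
#' through the trained network and sorts by descending success probability.
#' Ties are broken by lower ddG (when a scan is supplied), then position,
#' then alphabetical identity.
#'
#' @param model An `epinnet_model`.
#' @param tolerated Named list position -> tolerated mutant identities.
#' @param scan Optional `ddg_scan` used for tie-breaking and reporting.
#' @return Data frame (class `mutation_ranking`): position, from_aa, to_aa,
#'   score, ddg (NA without a scan), sorted best first.
#' @export
rank_mutations <- function(model, tolerated, scan = NULL) {
  keys <- names(model$allowed)
  rows <- list()
  for (k in names(tolerated)) {
    if (!k %in% keys) stop("position ", k, " outside the model encoding")
    for (aa in tolerated[[k]]) {
      if (aa == model$reference[[k]]) next
      if (!aa %in% model$allowed[[k]])
        stop("mutation ", k, aa, " outside the model encoding")
      g <- model$reference
      g[[k]] <- aa
      rows[[length(rows) + 1L]] <- data.frame(
        position = as.integer(k), from_aa = model$reference[[k]],
        to_aa = aa, score = epinnet_score(model, g))
    }
  }
  out <- do.call(rbind, rows)
  out$ddg <- NA_real_
  if (!is.null(scan)) {
    idx <- match(paste(out$position, out$to_aa),
                 paste(scan$position, scan$to_aa))
    out$ddg <- scan$ddg[idx]
  }
  # scores are quantized so near-saturated predictions tie and defer to ddG
  ddg_key <- ifelse(is.na(out$ddg), 0, out$ddg)
  out <- out[order(-round(out$score, 3), ddg_key, out$position, out$to_aa), ]
  rownames(out) <- NULL
  class(out) <- c("mutation_ranking", "data.frame")
  out
}

#' Select the enriched library from ranked mutations
#'
#' Adds mutations in rank order, recomputing the combinatorial space size
#' after each addition, and stops at the first addition that makes the
#' space at least `target_size` (that mutation is included).
#'
#' @param ranked A `mutation_ranking`.
#' @param reference Named character vector of reference identities over the
#'   designed positions.
#' @param target_size Experimental size limit; default 4e6.
#' @return An object of class `library_definition`: list with `allowed`
#'   (position -> identities, reference always present), `reference`, and
#'   `trace` (data frame: step, position, to_aa, score, space_size).
#' @export
select_library <- function(ranked, reference, target_size = 4e6) {
  stopifnot(target_size >= 1)
  allowed <- lapply(reference, function(a) a)
  names(allowed) <- names(reference)
  trace <- data.frame(step = integer(0), position = integer(0),
                      to_aa = character(0), score = numeric(0),
                      space_size = numeric(0))
  size <- 1
  for (i in seq_len(nrow(ranked))) {
    if (size >= target_size) break
    k <- as.character(ranked$position[i])
    allowed[[k]] <- c(allowed[[k]], ranked$to_aa[i])
    size <- space_size(allowed)
    trace <- rbind(trace, data.frame(
      step = nrow(trace) + 1L, position = ranked$position[i],
      to_aa = ranked$to_aa[i], score = ranked$score[i], space_size = size))
  }
  if (size < target_size)
    warning("ranked list exhausted before reaching target size ",
            target_size, " (space = ", size, ")")
  structure(list(allowed = allowed, reference = reference, trace = trace),
            class = "library_definition")
}

#' @export
print.library_definition <- function(x, ...) {
  nmut <- sum(vapply(x$allowed, length, integer(1)) - 1L)
  cat("Library:", length(x$allowed), "positions,", nmut, "mutations,",
      "space size", format(space_size(x), big.mark = ","), "\n")
  invisible(x)
}

#' Write a library definition as TSV
#'
#' One row per position: position, reference identity, comma-separated
#' allowed identities.
#'
#' @param lib A `library_definition`.
#' @param path Output path.
#' @export
write_library <- function(lib, path) {
  df <- data.frame(position = as.integer(names(lib$allowed)),
                   reference = unname(lib$reference[names(lib$allowed)]),
                   allowed = vapply(lib$allowed, paste, collapse = ",",
                                    FUN.VALUE = character(1)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Sample genotypes uniformly from a library's sequence space
#'
#' Draws each position's identity independently and uniformly from its
#' allowed set.
#'
#' @param lib A `library_definition` or named allowed list.
#' @param n Number of genotypes.
#' @param seed Integer seed.
#' @return Character matrix, one genotype per row.
#' @export
sample_space <- function(lib, n, seed = 1) {
  stopifnot(n >= 1)
  allowed <- if (inherits(lib, "library_definition")) lib$allowed else lib
  set.seed(seed)
  keys <- names(allowed)
  G <- matrix("", n, length(keys), dimnames = list(NULL, keys))
  for (k in keys)
    G[, k] <- sample(allowed[[k]], n, replace = TRUE)
  G
}

#' Compare energy distributions of enriched vs. filtered spaces
#'
#' Samples both spaces, scores them with the oracle, and reports per-space
#' energy summaries and the fraction of designs scoring strictly below the
#' reference energy (the headline in-silico validation of enrichment).
#'
#' @param oracle Energy oracle.
#' @param enriched,filtered `library_definition`s (or allowed lists).
#' @param n Samples per space; default 10000.
#' @param seed Integer seed.
#' @param reference_energy Reference energy; default 0.
#' @return An object of class `space_validation`: per-space list with
#'   `energies`, `fraction_below`, `mean`, `quartiles`.
#' @export
validate_spaces <- function(oracle, enriched, filtered, n = 10000,
                            seed = 1, reference_energy = 0) {
  eval_space <- function(lib, seed_offset) {
    G <- sample_space(lib, n, seed + seed_offset)
    e <- landscape_energy(oracle, G)
    list(energies = e,
         fraction_below = mean(e < reference_energy),
         mean = mean(e),
         quartiles = stats::quantile(e, c(0.25, 0.5, 0.75)))
  }
  structure(list(enriched = eval_space(enriched, 0L),
                 filtered = eval_space(filtered, 1L),
                 n = n, reference_energy = reference_energy),
            class = "space_validation")
}

#' @export
print.space_validation <- function(x, ...) {
  cat("In-silico space validation (n =", x$n, "per space)\n")
  cat(sprintf("  enriched: mean %.3f, %.1f%% below reference\n",
              x$enriched$mean, 100 * x$enriched$fraction_below))
  cat(sprintf("  filtered: mean %.3f, %.1f%% below reference\n",
              x$filtered$mean, 100 * x$filtered$fraction_below))
  invisible(x)
}
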