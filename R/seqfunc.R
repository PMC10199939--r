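# From sorted/presorted sequencing counts to functional calls, classifier
# features, allele-preference logos and the mutational-decline fit.

#' Read a variant count table
#'
#' TSV with columns genotype, sample, count; returns a wide count table.
#'
#' @param path Path to the TSV.
#' @return An object of class `count_table`: list with `counts` (genotype x
#'   sample integer matrix) and `totals` (per-sample sums).
#' @export
read_count_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("genotype", "sample", "count")
  if (!all(need %in% names(df)))
    stop("count TSV must have columns: ", paste(need, collapse = ", "))
  count_table(df$genotype, df$sample, df$count)
}

#' @rdname read_count_table
#' @param genotype,sample,count Vectors defining the long-format counts.
#' @export
count_table <- function(genotype, sample, count) {
  if (any(count < 0)) stop("counts must be non-negative")
  counts <- stats::xtabs(count ~ genotype + sample,
                         data = data.frame(genotype, sample, count))
  counts <- matrix(as.numeric(counts), nrow(counts), ncol(counts),
                   dimnames = dimnames(counts))
  structure(list(counts = counts, totals = colSums(counts)),
            class = "count_table")
}

#' Per-genotype enrichment between a sorted and a presorted sample
#'
#' Ratio of read frequencies:
#' (count_sorted / total_sorted) / (count_presorted / total_presorted).
#' Genotypes present in the sorted sample but absent from the presorted one
#' get an infinite enrichment sentinel (the presorted pool was too large to
#' be covered completely, so sorted-only sequences are treated as
#' enriched); a minimum sorted read support for this rule can be set.
#'
#' @param ct A `count_table`.
#' @param sorted,presorted Sample (column) names.
#' @param min_sorted_reads Minimum sorted count for the sorted-only
#'   infinity rule; default 1.
#' @return Named numeric vector of enrichments (possibly Inf).
#' @export
enrichment <- function(ct, sorted, presorted, min_sorted_reads = 1) {
  stopifnot(inherits(ct, "count_table"))
  for (s in c(sorted, presorted))
    if (!s %in% colnames(ct$counts)) stop("sample not present: ", s)
  ts <- ct$totals[[sorted]]; tp <- ct$totals[[presorted]]
  if (ts == 0 || tp == 0) stop("zero total reads in a sample")
  cs <- ct$counts[, sorted]; cp <- ct$counts[, presorted]
  e <- (cs / ts) / (cp / tp)
  only_sorted <- cp == 0 & cs >= min_sorted_reads
  e[only_sorted] <- Inf
  e[cp == 0 & !only_sorted] <- 0
  e
}

#' Call functional hits from per-gate enrichments
#'
#' A genotype is a hit in a gate when its enrichment exceeds the threshold
#' (default 1). Labels combine the two fluorescence gates: "GFP",
#' "AmCyan", "both", or "nonfunctional".
#'
#' @param enrichments Named list of per-gate enrichment vectors (names =
#'   gate names, typically "GFP" and "AmCyan"), on the same genotypes.
#' @param threshold Enrichment threshold; default 1.
#' @return Data frame (class `functional_calls`): genotype, one enrichment
#'   column per gate, label.
#' @export
call_hits <- function(enrichments, threshold = 1) {
  stopifnot(threshold >= 0, length(enrichments) >= 1)
  gs <- names(enrichments[[1]])
  for (e in enrichments) stopifnot(identical(names(e), gs))
  hit <- vapply(enrichments, function(e) e > threshold,
                logical(length(gs)))
  if (is.null(dim(hit))) hit <- matrix(hit, nrow = 1)
  label <- apply(hit, 1, function(h) {
    on <- names(enrichments)[h]
    if (length(on) == 0) "nonfunctional"
    else if (length(on) == length(enrichments) && length(on) > 1) "both"
    else paste(on, collapse = "+")
  })
  out <- data.frame(genotype = gs, as.data.frame(enrichments),
                    label = label, row.names = NULL)
  class(out) <- c("functional_calls", "data.frame")
  out
}

#' Keep variants mutated only inside the pocket
#'
#' Retains variants whose every mutation relative to the reference sequence
#' falls inside the given pocket positions (1-based coordinates on the
#' reference). The unmutated reference passes vacuously.
#'
#' @param sequences Character vector of full-length variant sequences.
#' @param reference Reference sequence (same length).
#' @param pocket Integer vector of pocket positions.
#' @return Logical vector: TRUE for variants to keep.
#' @export
pocket_filter <- function(sequences, reference, pocket) {
  ref <- strsplit(reference, "")[[1]]
  vapply(sequences, function(s) {
    v <- strsplit(s, "")[[1]]
    if (length(v) != length(ref))
      stop("variant length ", length(v), " does not match reference length ",
           length(ref))
    muts <- which(v != ref)
    all(muts %in% pocket)
  }, logical(1), USE.NAMES = FALSE)
}

#' Fraction of functional variants by number of mutations
#'
#' Groups variants by mutation count and reports the functional fraction
#' and total count per bin; empty bins are omitted.
#'
#' @param n_mutations Integer vector of per-variant mutation counts.
#' @param functional Logical vector of functional labels.
#' @return Data frame: n, fraction, count.
#' @export
functional_fraction_by_n <- function(n_mutations, functional) {
  stopifnot(length(n_mutations) == length(functional))
  ns <- sort(unique(n_mutations))
  data.frame(
    n = ns,
    fraction = vapply(ns, function(k) mean(functional[n_mutations == k]),
                      numeric(1)),
    count = vapply(ns, function(k) sum(n_mutations == k), numeric(1)))
}

#' Fit the exponential-decline and negative-epistasis curve
#'
#' Fits \eqn{F(n) = \exp(-A n - B n(n-1)/2)}, the exponential-decline and
#' negative-epistasis curve with robustness \eqn{A \ge 0} (per-mutation
#' cost) and epistasis \eqn{B \ge 0} (per-mutation-pair cost), to the
#' functional fraction versus mutation count by constrained nonlinear
#' least squares on the linear scale (robust to near-zero fractions).
#' The equivalent quadratic form \eqn{F(n) = \exp(-\alpha n - \beta n^2)}
#' has \eqn{\alpha = A - B/2} and \eqn{\beta = B/2} (matching the
#' coefficients of \eqn{n} and \eqn{n^2}).
#'
#' @param n Integer vector of mutation counts (>= 1 for at least 2 points).
#' @param F Numeric functional fractions in (0, 1].
#' @param weights Optional per-point weights.
#' @return An object of class `decline_fit`: list with `A`, `B`, `alpha`,
#'   `beta`, `fitted` (function of n), `residuals`.
#' @export
fit_decline <- function(n, F, weights = NULL) {
  stopifnot(length(n) == length(F), sum(n >= 1) >= 2)
  if (all(F == 0)) stop("all functional fractions are zero; nothing to fit")
  if (any(F < 0 | F > 1)) stop("fractions must lie in [0, 1]")
  if (is.null(weights)) weights <- rep(1, length(n))
  # crude log-linear start, clamped into the feasible region
  pos <- F > 0 & n >= 1
  A0 <- max(0.1, -stats::coef(stats::lm(log(F[pos]) ~ 0 + n[pos]))[[1]])
  model <- function(p, n) exp(-p[1] * n - p[2] * n * (n - 1) / 2)
  fit <- minpack.lm::nls.lm(
    par = c(A = A0, B = 0.01), lower = c(0, 0),
    fn = function(p) sqrt(weights) * (F - model(p, n)),
    control = minpack.lm::nls.lm.control(maxiter = 1000, ftol = 1e-15,
                                         ptol = 1e-15))
  A <- unname(fit$par["A"]); B <- unname(fit$par["B"])
  structure(list(A = A, B = B, alpha = A - B / 2, beta = B / 2,
                 fitted = function(n) exp(-A * n - B * n * (n - 1) / 2),
                 residuals = F - model(c(A, B), n)),
            class = "decline_fit")
}

#' @export
print.decline_fit <- function(x, ...) {
  cat(sprintf(
    "Decline fit: A (robustness) = %.4g, B (epistasis) = %.4g (alpha = %.4g, beta = %.4g)\n",
    x$A, x$B, x$alpha, x$beta))
  invisible(x)
}

#' Sequence-derived classifier features for genotypes
#'
#' Builds the feature table for genotype-phenotype classification: the
#' identity at each variable position, the total mutation count, the
#' mutation count per spatial neighborhood, optional user-defined position
#' groups, and per-position conservation-score change (dPSSM),
#' accessible-area change (dSASA, tabulated per-identity maxima) and
#' amino-acid category-change flag, each with its mean and max.
#'
#' @param genotypes Character matrix (rows = genotypes, columns =
#'   positions).
#' @param reference Named character vector of reference identities.
#' @param pssm A `pssm` covering the positions.
#' @param neighborhoods List of `neighborhood` objects.
#' @param groups Optional named list of position groups (extra mutation
#'   counters).
#' @return Data frame of features, one row per genotype.
#' @export
build_features <- function(genotypes, reference, pssm, neighborhoods,
                           groups = NULL) {
  G <- .as_genotype_matrix(genotypes)
  keys <- colnames(G)
  ref <- reference[keys]
  mut <- G != matrix(ref, nrow(G), ncol(G), byrow = TRUE)
  out <- data.frame(row.names = seq_len(nrow(G)))
  for (k in keys) out[[paste0("aa_", k)]] <- G[, k]
  out$n_mutations <- rowSums(mut)
  for (nb in neighborhoods) {
    cols <- intersect(as.character(nb$members), keys)
    out[[paste0("nbhd_", nb$center)]] <-
      rowSums(mut[, cols, drop = FALSE])
  }
  if (!is.null(groups)) {
    for (gn in names(groups)) {
      cols <- intersect(as.character(groups[[gn]]), keys)
      out[[paste0("group_", gn)]] <- rowSums(mut[, cols, drop = FALSE])
    }
  }
  dps <- matrix(0, nrow(G), length(keys))
  dsa <- matrix(0, nrow(G), length(keys))
  dct <- matrix(0, nrow(G), length(keys))
  for (j in seq_along(keys)) {
    k <- keys[j]
    m <- mut[, j]
    if (any(m)) {
      dps[m, j] <- pssm$scores[cbind(rep(k, sum(m)), G[m, j])] -
        pssm$scores[k, ref[[k]]]
      dsa[m, j] <- max_sasa_delta(rep(ref[[k]], sum(m)), G[m, j])
      dct[m, j] <- as.numeric(aa_category(G[m, j]) !=
                                aa_category(rep(ref[[k]], sum(m))))
    }
  }
  colnames(dps) <- paste0("dpssm_", keys)
  colnames(dsa) <- paste0("dsasa_", keys)
  colnames(dct) <- paste0("catchange_", keys)
  out <- cbind(out, dps, dsa, dct)
  out$dpssm_mean <- rowMeans(dps); out$dpssm_max <- apply(dps, 1, max)
  out$dsasa_mean <- rowMeans(dsa); out$dsasa_max <- apply(dsa, 1, max)
  out$catchange_mean <- rowMeans(dct); out$catchange_max <- apply(dct, 1, max)
  out
}

# numeric design matrix for tree models: one-hot the identity columns
.feature_matrix <- function(features) {
  aa_cols <- grep("^aa_", names(features), value = TRUE)
  num <- features[, setdiff(names(features), aa_cols), drop = FALSE]
  X <- as.matrix(num)
  for (col in aa_cols) {
    lv <- sort(unique(features[[col]]))
    oh <- outer(features[[col]], lv, "==") * 1
    colnames(oh) <- paste0(col, ".", lv)
    X <- cbind(X, oh)
  }
  X
}

# subsample every class down to the size of the smallest
.balance_classes <- function(y) {
  idx <- split(seq_along(y), y)
  m <- min(lengths(idx))
  sort(unlist(lapply(idx, function(i) sample(i, m))))
}

#' Two-stage genotype-phenotype classifier
#'
#' Stage 1 classifies genotypes as functional vs. nonfunctional; stage 2
#' classifies stage-1 positives into phenotype classes (e.g. GFP, AmCyan,
#' both). Both stages use gradient-boosted trees by default. Accuracy is
#' reported on a class-balanced held-out set (majority classes subsampled);
#' zero-variance features are dropped before training.
#'
#' @param features Feature data frame from [build_features()].
#' @param labels Character vector of phenotype labels; "nonfunctional"
#'   marks the negative class for stage 1.
#' @param engine "xgboost" (default) or "randomForest".
#' @param test_fraction Held-out fraction; default 0.2.
#' @param nrounds Boosting rounds; default 200.
#' @param seed Integer seed.
#' @return An object of class `two_stage_classifier`: stage models, dropped
#'   features, balanced held-out accuracies and per-feature importance.
#' @export
two_stage_classify <- function(features, labels,
                               engine = c("xgboost", "randomForest"),
                               test_fraction = 0.2, nrounds = 200,
                               seed = 1) {
  engine <- match.arg(engine)
  stopifnot(nrow(features) == length(labels))
  if (!any(labels == "nonfunctional") || all(labels == "nonfunctional"))
    stop("labels must contain nonfunctional and at least one functional class")
  X <- .feature_matrix(features)
  keep <- apply(X, 2, function(v) stats::var(v) > 0)
  dropped <- colnames(X)[!keep]
  X <- X[, keep, drop = FALSE]
  set.seed(seed)
  n <- nrow(X)
  te <- sample.int(n, floor(test_fraction * n))
  tr <- setdiff(seq_len(n), te)

  fit_one <- function(Xtr, ytr) {
    if (engine == "xgboost") {
      nc <- nlevels(ytr)
      param <- if (nc == 2)
        list(objective = "binary:logistic", max_depth = 4, eta = 0.2,
             nthread = 1)
      else
        list(objective = "multi:softmax", num_class = nc, max_depth = 4,
             eta = 0.2, nthread = 1)
      yenc <- as.integer(ytr) - 1L
      bst <- xgboost::xgb.train(
        params = param,
        data = xgboost::xgb.DMatrix(Xtr, label = yenc, nthread = 1),
        nrounds = nrounds, verbose = 0)
      list(model = bst, levels = levels(ytr),
           predict = function(Xnew) {
             p <- stats::predict(bst, Xnew)
             if (nc == 2) levels(ytr)[(p > 0.5) + 1L]
             else levels(ytr)[p + 1L]
           },
           importance = tryCatch({
             imp <- xgboost::xgb.importance(model = bst)
             stats::setNames(imp$Gain, imp$Feature)
           }, error = function(e) NULL))
    } else {
      rf <- randomForest::randomForest(x = Xtr, y = ytr)
      list(model = rf, levels = levels(ytr),
           predict = function(Xnew)
             as.character(stats::predict(rf, Xnew)),
           importance = randomForest::importance(rf)[, 1])
    }
  }

  y1 <- factor(ifelse(labels == "nonfunctional", "nonfunctional",
                      "functional"),
               levels = c("nonfunctional", "functional"))
  stage1 <- fit_one(X[tr, , drop = FALSE], y1[tr])
  func_tr <- tr[labels[tr] != "nonfunctional"]
  y2_tr <- droplevels(factor(labels[func_tr]))
  stage2 <- if (nlevels(y2_tr) >= 2)
    fit_one(X[func_tr, , drop = FALSE], y2_tr) else NULL

  # balanced held-out accuracy, stage 1
  bal1 <- te[.balance_classes(y1[te])]
  pred1 <- stage1$predict(X[bal1, , drop = FALSE])
  acc1 <- mean(pred1 == as.character(y1[bal1]))
  # full pipeline on functional-classed held-out rows
  acc2 <- NA_real_
  if (!is.null(stage2)) {
    te_func <- te[labels[te] != "nonfunctional"]
    y2_te <- factor(labels[te_func], levels = levels(y2_tr))
    ok <- !is.na(y2_te)
    if (sum(ok) > 0 && nlevels(droplevels(y2_te[ok])) >= 2) {
      balf <- te_func[ok][.balance_classes(droplevels(y2_te[ok]))]
      pred2 <- stage2$predict(X[balf, , drop = FALSE])
      acc2 <- mean(pred2 == labels[balf])
    }
  }
  structure(list(stage1 = stage1, stage2 = stage2,
                 dropped_features = dropped,
                 balanced_accuracy_stage1 = acc1,
                 balanced_accuracy_stage2 = acc2,
                 feature_names = colnames(X)),
            class = "two_stage_classifier")
}

#' @export
print.two_stage_classifier <- function(x, ...) {
  cat(sprintf(
    "Two-stage classifier: stage-1 balanced accuracy %.3f; stage-2 %.3f\n",
    x$balanced_accuracy_stage1, x$balanced_accuracy_stage2))
  invisible(x)
}

#' Predict phenotype labels with a two-stage classifier
#'
#' @param object A `two_stage_classifier`.
#' @param features New feature data frame.
#' @param ... Unused.
#' @return Character labels; stage-2 classes for stage-1 positives,
#'   "nonfunctional" otherwise.
#' @export
predict.two_stage_classifier <- function(object, features, ...) {
  X <- .feature_matrix(features)
  miss <- setdiff(object$feature_names, colnames(X))
  if (length(miss)) {
    X <- cbind(X, matrix(0, nrow(X), length(miss),
                         dimnames = list(NULL, miss)))
  }
  X <- X[, object$feature_names, drop = FALSE]
  lab <- object$stage1$predict(X)
  if (!is.null(object$stage2)) {
    pos <- lab == "functional"
    if (any(pos))
      lab[pos] <- object$stage2$predict(X[pos, , drop = FALSE])
  }
  lab
}

# Hamming distance of each row of G to the nearest row of centers
.min_hamming <- function(G, centers) {
  apply(G, 1, function(g)
    min(apply(centers, 1, function(cc) sum(g != cc))))
}

#' Allele-preference logo from an additive logistic model
#'
#' Fits an L2-penalized additive (one-hot) logistic regression of a binary
#' functional label on genotype, optionally restricted to genotypes within
#' a Hamming radius of a set of center genotypes, and returns per-(position,
#' identity) coefficients as mean-centered log2 odds ratios -- the allele
#' preferences drawn as a sequence logo.
#'
#' @param genotypes Character matrix (rows = genotypes).
#' @param labels Logical or 0/1 functional labels.
#' @param C Inverse regularization strength (sklearn convention,
#'   lambda = 1/(C n)); default 0.5. Set to NULL to pick lambda by
#'   cross-validation.
#' @param cv_folds Folds when cross-validating; default 10.
#' @param neighborhood_filter Optional list(centers = character matrix,
#'   radius = integer): restrict to genotypes within `radius` mutations of
#'   any center.
#' @return Matrix (positions x identities present) of centered log2 odds
#'   coefficients; rows mean-center to 0 over each position's observed
#'   identities.
#' @export
logistic_logo <- function(genotypes, labels, C = 0.5, cv_folds = 10,
                          neighborhood_filter = NULL) {
  G <- .as_genotype_matrix(genotypes)
  y <- as.integer(as.logical(labels))
  if (!is.null(neighborhood_filter)) {
    centers <- .as_genotype_matrix(neighborhood_filter$centers)
    keep <- .min_hamming(G, centers) <= neighborhood_filter$radius
    G <- G[keep, , drop = FALSE]
    y <- y[keep]
  }
  if (nrow(G) < 2) stop("fewer than 2 genotypes after filtering")
  if (length(unique(y)) < 2)
    stop("need both labels present after filtering")
  allowed <- lapply(seq_len(ncol(G)), function(j) sort(unique(G[, j])))
  names(allowed) <- colnames(G)
  X <- .one_hot_encode(G, allowed)
  if (is.null(C)) {
    cv <- glmnet::cv.glmnet(X, y, family = "binomial", alpha = 0,
                            nfolds = cv_folds)
    lambda <- cv$lambda.min
  } else {
    lambda <- 1 / (C * nrow(X))
  }
  fit <- glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                        lambda = lambda)
  beta <- as.numeric(stats::coef(fit))[-1]   # drop intercept
  names(beta) <- colnames(X)
  beta <- beta / log(2)                      # natural log -> log2
  out <- matrix(NA_real_, ncol(G), 20,
                dimnames = list(colnames(G), AA_ALPHABET))
  for (k in colnames(G)) {
    aas <- allowed[[k]]
    b <- beta[paste0("p", k, ".", aas)]
    out[k, aas] <- b - mean(b)               # mean-center by site
  }
  out
}
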