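toy_counts <- function() {
  genos <- c("g1", "g2", "g3", "g4")
  count_table(
    genotype = rep(genos, 3),
    sample = rep(c("presorted", "sorted_GFP", "sorted_AmCyan"), each = 4),
    count = c(5, 100, 200, 0,      # presorted (g4 unseen presorted)
              10, 50, 30, 10,      # GFP sort
              0, 40, 5, 0))        # AmCyan sort
}

test_that("enrichment is a frequency ratio with the sorted-only rule", {
  ct <- toy_counts()
  e <- enrichment(ct, "sorted_GFP", "presorted")
  # g1: (10/100)/(5/305) = 6.1
  expect_equal(unname(e["g1"]), (10 / 100) / (5 / 305), tolerance = 1e-12)
  # sorted 10/100 vs presorted 5/1000 -> enrichment 20
  ct2 <- count_table(genotype = c("x", "y", "x", "y"),
                     sample = c("s", "s", "p", "p"),
                     count = c(10, 90, 5, 995))
  expect_equal(unname(enrichment(ct2, "s", "p")["x"]), 20,
               tolerance = 1e-12)
  # absent from the sorted sample -> 0; sorted-only -> Inf
  e_am <- enrichment(ct, "sorted_AmCyan", "presorted")
  expect_equal(unname(e_am["g1"]), 0)
  expect_equal(unname(e["g4"]), Inf)
  # raising the minimum sorted support disables the Inf sentinel
  e_strict <- enrichment(ct, "sorted_GFP", "presorted",
                         min_sorted_reads = 20)
  expect_equal(unname(e_strict["g4"]), 0)
  expect_error(enrichment(ct, "nope", "presorted"), "not present")
})

test_that("enrichment is invariant to per-sample count scaling", {
  ct <- toy_counts()
  e1 <- enrichment(ct, "sorted_GFP", "presorted")
  scaled <- count_table(
    genotype = rep(c("g1", "g2", "g3", "g4"), 2),
    sample = rep(c("presorted", "sorted_GFP"), each = 4),
    count = c(c(5, 100, 200, 0) * 7, c(10, 50, 30, 10) * 3))
  e2 <- enrichment(scaled, "sorted_GFP", "presorted")
  expect_equal(e2, e1[names(e2)], tolerance = 1e-12)
})

test_that("hit calling combines gates into phenotype labels", {
  enr <- list(GFP = c(a = 2.0, b = 0.5, c = 3, d = 0.2),
              AmCyan = c(a = 0.5, b = 2.5, c = 1.5, d = 0.9))
  calls <- call_hits(enr, threshold = 1)
  expect_equal(calls$label, c("GFP", "AmCyan", "both", "nonfunctional"))
  # Inf enrichments count as hits
  enr2 <- list(GFP = c(a = Inf), AmCyan = c(a = 0))
  expect_equal(call_hits(enr2)$label, "GFP")
})

test_that("the counts-demo fixture recovers exactly the planted hit set", {
  paths <- make_fixture("counts-demo", seed = 7)
  ct <- read_count_table(paths$counts)
  truth <- jsonlite::read_json(paths$ground_truth, simplifyVector = TRUE)
  calls <- call_hits(list(GFP = enrichment(ct, "sorted_GFP", "presorted"),
                          AmCyan = enrichment(ct, "sorted_AmCyan",
                                              "presorted")))
  expect_setequal(calls$genotype[calls$label == "GFP"], truth$GFP)
  expect_setequal(calls$genotype[calls$label == "both"], truth$both)
  expect_true(all(calls$label[!calls$genotype %in%
                                c(truth$GFP, truth$both)] ==
                    "nonfunctional"))
})

test_that("pocket filtering keeps variants mutated only inside the pocket", {
  ref <- "ACDEFG"
  keep <- pocket_filter(c("ACDEFG",   # reference itself
                          "AVDEFG",   # mutation at 2 (pocket)
                          "AVDEFW",   # extra mutation at 6 (outside)
                          "ACDEFW"),  # mutation at 6 only
                        ref, pocket = c(2, 3))
  expect_equal(keep, c(TRUE, TRUE, FALSE, FALSE))
  expect_error(pocket_filter("ACD", ref, 1:2), "length")
})

test_that("functional fractions partition variants by mutation count", {
  n <- c(1, 1, 1, 2, 2, 4)
  f <- c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE)
  tab <- functional_fraction_by_n(n, f)
  expect_equal(tab$n, c(1, 2, 4))          # empty bins omitted
  expect_equal(tab$fraction, c(1, 0.5, 0))
  expect_equal(sum(tab$count), length(n))
})

test_that("decline fit recovers parameters and honors the constraints", {
  A <- 0.5; B <- 0.1
  n <- 0:8
  F <- exp(-A * n - B * n * (n - 1) / 2)
  fit <- fit_decline(n, F)
  expect_equal(fit$A, A, tolerance = 1e-6)
  expect_equal(fit$B, B, tolerance = 1e-6)
  expect_equal(fit$alpha, A - B / 2, tolerance = 1e-6)
  expect_equal(fit$beta, B / 2, tolerance = 1e-6)
  expect_equal(fit$fitted(0), 1)           # F(0) = 1 by construction
  # the two parameterizations agree on a grid
  grid <- 0:12
  expect_equal(exp(-fit$alpha * grid - fit$beta * grid^2),
               fit$fitted(grid), tolerance = 1e-9)
  # pure exponential data fit with negligible epistasis term
  F0 <- exp(-0.3 * n)
  fit0 <- fit_decline(n, F0)
  expect_lt(fit0$B, 1e-6)
  expect_error(fit_decline(c(1, 2), c(0, 0)), "zero")
})

test_that("feature tables carry the documented blocks with exact counts", {
  case <- ring_design_case(6, n_plants = 0)
  G <- sample_space(case$allowed, 30, seed = 2)
  # a PSSM over the ring positions
  rows <- list(ref = paste(case$reference, collapse = ""))
  for (i in 1:9) rows[[paste0("h", i)]] <-
    paste(sample_space(case$allowed, 1, seed = i), collapse = "")
  pssm <- build_pssm(read_alignment(write_toy_alignment(rows), "ref"))
  feats <- build_features(G, case$reference, pssm, case$neighborhoods)
  P <- length(case$keys); K <- length(case$neighborhoods)
  expect_equal(ncol(feats), 4 * P + K + 7)
  # reference genotype: all deltas and counts zero
  ref_row <- build_features(case$reference, case$reference, pssm,
                            case$neighborhoods)
  num <- ref_row[, !grepl("^aa_", names(ref_row))]
  expect_true(all(num == 0))
  # mutations inside one neighborhood are counted there
  g <- case$reference
  nb1 <- case$neighborhoods[[1]]
  two <- as.character(nb1$members[1:2])
  for (k in two) g[[k]] <- setdiff(case$allowed[[k]], g[[k]])[1]
  row2 <- build_features(g, case$reference, pssm, case$neighborhoods)
  expect_equal(row2[[paste0("nbhd_", nb1$center)]], 2)
  expect_equal(row2$n_mutations, 2)
  # category-change flag: aromatic -> aliphatic
  expect_equal(aa_category("Y"), "aromatic")
  expect_equal(aa_category("M"), "aliphatic")
  ref2 <- c(`1` = "Y"); g2 <- c(`1` = "M")
  pssm2 <- structure(list(scores = matrix(
    0, 1, 20, dimnames = list("1", AA_ALPHABET))), class = "pssm")
  r <- build_features(g2, ref2, pssm2, list())
  expect_equal(r$catchange_1, 1)
})

test_that("two-stage classification separates a determined rule", {
  case <- ring_design_case(8, n_plants = 0)
  G <- sample_space(case$allowed, 600, seed = 3)
  rows <- list(ref = paste(case$reference, collapse = ""))
  for (i in 1:9) rows[[paste0("h", i)]] <-
    paste(sample_space(case$allowed, 1, seed = i), collapse = "")
  pssm <- build_pssm(read_alignment(write_toy_alignment(rows), "ref"))
  feats <- build_features(G, case$reference, pssm, case$neighborhoods)
  # labels fully determined by one feature (mutation count)
  labels <- ifelse(feats$n_mutations <= 2,
                   ifelse(G[, "1"] == case$reference[["1"]],
                          "GFP", "AmCyan"),
                   "nonfunctional")
  fit <- two_stage_classify(feats, labels, seed = 4)
  expect_gt(fit$balanced_accuracy_stage1, 0.95)
  expect_gt(fit$balanced_accuracy_stage2, 0.95)
  pred <- predict(fit, feats)
  expect_gt(mean((pred == "nonfunctional") ==
                   (labels == "nonfunctional")), 0.95)
  # permuted labels carry no signal
  set.seed(5)
  fit_perm <- two_stage_classify(feats, sample(labels), seed = 4)
  expect_lt(fit_perm$balanced_accuracy_stage1, 0.65)
  expect_error(two_stage_classify(feats, rep("GFP", nrow(feats))),
               "nonfunctional")
})

test_that("logistic logos localize an allele-determined label", {
  keys <- as.character(1:4)
  allowed <- stats::setNames(rep(list(c("A", "C", "D")), 4), keys)
  G <- sample_space(allowed, 800, seed = 11)
  # functional depends only on the allele at position 3
  prob <- c(A = 0.9, C = 0.5, D = 0.1)[G[, "3"]]
  set.seed(12)
  y <- stats::runif(nrow(G)) < prob
  logo <- logistic_logo(G, y, C = 0.5)
  # centered coefficients at each position average to zero
  for (k in keys)
    expect_equal(mean(logo[k, allowed[[k]]]), 0, tolerance = 1e-9)
  # effect mass concentrates at position 3, ordered A > C > D
  mass <- apply(logo, 1, function(r) max(abs(r), na.rm = TRUE))
  expect_equal(names(which.max(mass)), "3")
  expect_gt(logo["3", "A"], logo["3", "C"])
  expect_gt(logo["3", "C"], logo["3", "D"])
  # brute-force marginal log-odds agree in sign and order
  lo <- vapply(c("A", "C", "D"), function(a) {
    p <- mean(y[G[, "3"] == a]); log2(p / (1 - p))
  }, numeric(1))
  expect_equal(order(logo["3", c("A", "C", "D")]), order(lo))
})

test_that("Hamming-radius filtering keeps exactly the ball", {
  keys <- as.character(1:4)
  allowed <- stats::setNames(rep(list(c("A", "C")), 4), keys)
  space <- genotype_space(allowed)
  G <- space$genotypes
  center <- G[1, , drop = FALSE]
  d <- apply(G, 1, function(g) sum(g != center[1, ]))
  y <- as.logical(rep(c(TRUE, FALSE), length.out = nrow(G)))
  # radius-2 ball: filter inside logistic_logo must match brute force
  in_ball <- d <= 2
  logo <- suppressWarnings(
    logistic_logo(G, y, C = 0.5,
                  neighborhood_filter = list(centers = center,
                                             radius = 2)))
  logo_manual <- suppressWarnings(
    logistic_logo(G[in_ball, , drop = FALSE], y[in_ball], C = 0.5))
  expect_equal(logo, logo_manual, tolerance = 1e-9)
  expect_error(logistic_logo(G, y,
                             neighborhood_filter = list(centers = center,
                                                        radius = -1)),
               "2 genotypes|labels")
})
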