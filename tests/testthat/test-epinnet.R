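test_that("space sizes are exact products", {
  expect_equal(space_size(list(`1` = "A")), 1)
  expect_equal(space_size(list(`1` = c("A", "C", "D"),
                               `2` = c("A", "C", "D", "E"))), 12)
  sz <- space_size(stats::setNames(rep(list(AA_ALPHABET), 27),
                                   as.character(1:27)))
  expect_equal(sz, 20^27)
})

test_that("ddg threshold selection respects the modeling budget", {
  # one neighborhood over 3 positions; per-position mutation counts grow
  # with the threshold: brute-force the implied sizes
  nb <- list(structure(list(center = 1, members = 1:3),
                       class = "neighborhood"))
  scan <- structure(data.frame(
    position = rep(1:3, each = 4),
    from_aa = "A",
    to_aa = rep(c("C", "D", "E", "F"), 3),
    ddg = c(0.5, 1.5, 2.5, 3.5,  0.7, 1.7, 2.7, 3.7,  0.9, 1.9, 2.9, 3.9)),
    class = c("ddg_scan", "data.frame"))
  # at t=1: sizes 2*2*2=8; at t=2: 27; at t=3: 64; at t=4: 125
  sel <- select_ddg_threshold(nb, scan, grid = 1:4, max_total = 30)
  expect_equal(as.numeric(sel), 2)
  expect_equal(attr(sel, "sizes")$total, c(8, 27, 64, 125))
  # all under budget -> the largest grid value
  expect_equal(as.numeric(select_ddg_threshold(nb, scan, 1:4, 1e6)), 4)
  # nothing under budget -> smallest value with a warning
  expect_warning(sel0 <- select_ddg_threshold(nb, scan, 1:4, 5),
                 "smallest")
  expect_equal(as.numeric(sel0), 1)
})

test_that("neighborhood enumeration is exhaustive below the limit and seeded above", {
  nb <- structure(list(center = 1, members = 1:3), class = "neighborhood")
  allowed <- stats::setNames(rep(list(c("A", "C")), 3), as.character(1:3))
  G <- enumerate_neighborhood(nb, allowed)
  expect_equal(nrow(G), 8)
  expect_equal(nrow(unique(G)), 8)
  # sampling branch: 10% of the space, distinct rows, reproducible
  allowed4 <- stats::setNames(rep(list(c("A", "C", "D", "E")), 6),
                              as.character(1:6))
  nb6 <- structure(list(center = 1, members = 1:6), class = "neighborhood")
  G1 <- enumerate_neighborhood(nb6, allowed4, full_limit = 1000,
                               sample_fraction = 0.1, seed = 9)
  expect_equal(nrow(G1), ceiling(0.1 * 4^6))
  expect_equal(nrow(unique(G1)), nrow(G1))
  G2 <- enumerate_neighborhood(nb6, allowed4, full_limit = 1000,
                               sample_fraction = 0.1, seed = 9)
  expect_identical(G1, G2)
})

test_that("energy labeling partitions the sample as specified", {
  lab <- label_designs(c(-2, -1, 0, 1, 2, 3), 0)
  expect_equal(lab, c("success", "success", "undetermined",
                      "fail", "fail", "fail"))
  # success rule wins when the whole sample beats the reference
  expect_equal(label_designs(c(-4, -3, -2, -1), 0), rep("success", 4))
  # a single design worse than the reference is its own worst half
  expect_equal(label_designs(2, 0), "fail")
  # partition property: counts add up, fail count = ceiling(n/2) whenever
  # the worst half does not beat the reference
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(3:40, 1)
    e <- stats::rnorm(n)
    lab <- label_designs(e, min(e) - 1)  # nothing beats the reference
    expect_equal(sum(lab == "fail"), ceiling(n / 2))
    expect_equal(length(lab), n)
  }
})

test_that("dataset assembly embeds neighborhoods in the full space", {
  case <- ring_design_case(2, n_plants = 0)
  samples <- ring_samples(case)
  ds <- assemble_dataset(samples, case$allowed, case$reference)
  expect_s3_class(ds, "epinnet_dataset")
  # one active column per position per row
  off <- 0L
  for (k in case$keys) {
    nk <- length(case$allowed[[k]])
    expect_true(all(rowSums(ds$X[, off + seq_len(nk), drop = FALSE]) == 1))
    off <- off + nk
  }
  # pooling: rows = sum over neighborhoods of labeled designs
  expected_rows <- sum(vapply(samples, function(s)
    sum(label_designs(s$energies, 0) != "undetermined"), numeric(1)))
  expect_equal(nrow(ds$X), expected_rows)
  # encode/decode round trip
  G <- pocketlib:::.one_hot_decode(ds$X, case$allowed)
  expect_equal(pocketlib:::.one_hot_encode(G, case$allowed), ds$X)
  # rows from a neighborhood carry reference identity outside its members
  first_nb <- samples[[1]]$neighborhood
  outside <- setdiff(case$positions, first_nb$members)
  rows1 <- which(ds$provenance == first_nb$center)
  if (length(outside) && length(rows1)) {
    for (k in as.character(outside))
      expect_true(all(G[rows1, k] == case$reference[[k]]))
  }
})

test_that("the network separates a linearly separable rule and is seeded", {
  # success iff mutation X (position 1 = C) absent
  keys <- as.character(1:3)
  allowed <- stats::setNames(rep(list(c("A", "C")), 3), keys)
  ref <- stats::setNames(rep("A", 3), keys)
  G <- as.matrix(expand.grid(allowed, stringsAsFactors = FALSE))
  colnames(G) <- keys
  G <- G[rep(seq_len(nrow(G)), 10), ]
  y <- ifelse(G[, "1"] == "C", "fail", "success")
  ds <- structure(list(X = pocketlib:::.one_hot_encode(G, allowed),
                       y = factor(y, levels = c("fail", "success")),
                       provenance = rep(1, nrow(G)),
                       allowed = allowed, reference = ref),
                  class = "epinnet_dataset")
  m <- train_epinnet(ds, decay = 1e-3, seed = 2)
  expect_equal(m$holdout_accuracy, 1.0)
  m2 <- train_epinnet(ds, decay = 1e-3, seed = 2)
  expect_identical(m$net$wts, m2$net$wts)
  # shuffled labels carry no signal
  set.seed(4)
  ds_shuf <- ds
  ds_shuf$y <- sample(ds$y)
  m3 <- train_epinnet(ds_shuf, seed = 2)
  expect_lt(m3$holdout_accuracy, 0.75)
  # single-class data refuses to train
  ds1 <- ds
  ds1$y <- factor(rep("success", nrow(G)), levels = c("fail", "success"))
  expect_error(train_epinnet(ds1), "both")
})

test_that("ranking demotes the separating mutation and respects tie-breaks", {
  keys <- as.character(1:3)
  allowed <- stats::setNames(rep(list(c("A", "C")), 3), keys)
  ref <- stats::setNames(rep("A", 3), keys)
  G <- as.matrix(expand.grid(allowed, stringsAsFactors = FALSE))
  colnames(G) <- keys
  G <- G[rep(seq_len(nrow(G)), 10), ]
  y <- ifelse(G[, "1"] == "C", "fail", "success")
  ds <- structure(list(X = pocketlib:::.one_hot_encode(G, allowed),
                       y = factor(y, levels = c("fail", "success")),
                       provenance = rep(1, nrow(G)),
                       allowed = allowed, reference = ref),
                  class = "epinnet_dataset")
  m <- train_epinnet(ds, decay = 1e-3, seed = 2)
  tol <- stats::setNames(rep(list("C"), 3), keys)
  rk <- rank_mutations(m, tol)
  expect_equal(nrow(rk), 3)
  expect_equal(rk$position[3], 1L)  # the failure-defining mutation is last
  expect_error(rank_mutations(m, list(`9` = "C")), "outside")
  # degenerate all-success labels: scores tie, order falls to tie-breaks
  ds_all <- ds
  ds_all$y <- factor(ifelse(seq_len(nrow(G)) == 1, "fail", "success"),
                     levels = c("fail", "success"))
  m_all <- train_epinnet(ds_all, decay = 10, seed = 2)
  scan <- structure(data.frame(position = c(1L, 2L, 3L), from_aa = "A",
                               to_aa = "C", ddg = c(3, 1, 2)),
                    class = c("ddg_scan", "data.frame"))
  rk2 <- rank_mutations(m_all, tol, scan)
  expect_equal(rk2$position, c(2L, 3L, 1L))  # ddg breaks the score ties
})

test_that("library selection stops at the target and traces monotonically", {
  ref <- c(`1` = "A", `2` = "A")
  ranked <- structure(data.frame(
    position = c(1L, 2L, 1L, 2L, 2L),
    from_aa = "A", to_aa = c("C", "C", "D", "D", "E"),
    score = c(0.9, 0.8, 0.7, 0.6, 0.5), ddg = 1:5),
    class = c("mutation_ranking", "data.frame"))
  lib <- select_library(ranked, ref, target_size = 12)
  # spaces: 2, 4, 6, 9, 12 -> stops once >= 12, including that mutation
  expect_equal(lib$trace$space_size, c(2, 4, 6, 9, 12))
  expect_equal(space_size(lib), 12)
  expect_true(all(diff(lib$trace$space_size) > 0))
  # degenerate target: empty library
  lib1 <- select_library(ranked, ref, target_size = 1)
  expect_equal(space_size(lib1), 1)
  expect_equal(nrow(lib1$trace), 0)
  # exhausting the list warns
  expect_warning(select_library(ranked, ref, target_size = 1e6),
                 "exhausted")
  # trace length equals the number of included mutations
  expect_equal(nrow(lib$trace),
               sum(lengths(lib$allowed)) - length(lib$allowed))
})

test_that("space sampling is uniform per position and seeded", {
  allowed <- list(`1` = c("A", "C"), `2` = "A")
  G1 <- sample_space(allowed, 500, seed = 8)
  G2 <- sample_space(allowed, 500, seed = 8)
  expect_identical(G1, G2)
  expect_true(all(G1[, "2"] == "A"))
  expect_gt(mean(G1[, "1"] == "C"), 0.4)
  # reference-only library: all samples identical, nothing below reference
  case <- ring_design_case(3, n_plants = 0)
  ref_only <- lapply(case$reference, identity)
  rep_val <- validate_spaces(case$oracle, ref_only, ref_only, n = 50)
  expect_equal(rep_val$enriched$fraction_below, 0)
})

test_that("selection excludes planted incompatible pairs end to end", {
  # the seeded study condition: 6 ring positions, 2 planted pairs at 8x
  # the field scale, exhaustively verifiable space
  case <- ring_design_case(42)
  scan <- ddg_scan(case$oracle, case$reference, case$allowed)
  samples <- ring_samples(case)
  ds <- assemble_dataset(samples, case$allowed, case$reference)
  model <- train_epinnet(ds, seed = 1)
  tol <- lapply(case$keys, function(k)
    setdiff(case$allowed[[k]], case$reference[[k]]))
  names(tol) <- case$keys
  ranked <- rank_mutations(model, tol, scan)
  target <- ceiling(space_size(case$allowed) / 64)
  lib <- select_library(ranked, case$reference, target)
  # every planted incompatible pair is broken
  for (i in seq_len(nrow(case$oracle$planted))) {
    pl <- case$oracle$planted[i, ]
    both_in <- pl$aa_p %in% lib$allowed[[as.character(pl$p)]] &&
      pl$aa_q %in% lib$allowed[[as.character(pl$q)]]
    expect_false(both_in)
  }
  # enriched space beats the filtered space on exhaustive mean energy
  e_enr <- landscape_energy(case$oracle, genotype_space(lib)$genotypes)
  e_fil <- landscape_energy(case$oracle,
                            genotype_space(case$allowed)$genotypes)
  expect_lt(mean(e_enr), mean(e_fil))
})

test_that("on an additive landscape selection equals ddg sorting", {
  case <- spaced_additive_case()
  scan <- ddg_scan(case$oracle, case$reference, case$allowed)
  samples <- lapply(case$neighborhoods, function(nb) {
    G <- enumerate_neighborhood(nb, case$allowed)
    list(neighborhood = nb, genotypes = G,
         energies = landscape_energy(case$oracle, G))
  })
  ds <- assemble_dataset(samples, case$allowed, case$reference)
  model <- train_epinnet(ds, seed = 1)
  tol <- stats::setNames(rep(list(c("C", "D")), 5), case$keys)
  ranked <- rank_mutations(model, tol, scan)
  # scores track ddg (local swaps of mid-range scores are tolerated; the
  # substantive check is the chosen-set equality below)
  expect_gt(stats::cor(rank(-ranked$score), rank(ranked$ddg),
                       method = "spearman"), 0.75)
  target <- ceiling(space_size(case$allowed) / 16)
  lib <- select_library(ranked, case$reference, target)
  by_ddg <- ranked[order(ranked$ddg, ranked$position, ranked$to_aa), ]
  lib_ddg <- select_library(by_ddg, case$reference, target)
  mutset <- function(l) sort(unlist(lapply(names(l$allowed), function(k)
    paste0(k, ":", setdiff(l$allowed[[k]], case$reference[[k]])))))
  expect_equal(mutset(lib), mutset(lib_ddg))
})
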