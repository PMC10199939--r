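# Shared synthetic fixtures, built in code at test time.

# ring-pocket design problem: 6 positions on a ring, contacts out to ring
# distance `width`, 3-4 allowed identities per position, optional planted
# incompatible pairs at 8x the field scale
ring_design_case <- function(seed, width = 2, coupling_scale = 0.25,
                             n_plants = 2, n_positions = 6,
                             ident_range = 2:3) {
  keys <- as.character(seq_len(n_positions))
  ref <- stats::setNames(rep("A", n_positions), keys)
  set.seed(seed)
  pool <- c("C", "D", "E", "F", "G", "I")
  allowed <- stats::setNames(
    lapply(seq_len(n_positions),
           function(i) c("A", sample(pool, sample(ident_range, 1)))),
    keys)
  ringd <- function(i, j) min((i - j) %% n_positions,
                              (j - i) %% n_positions)
  contacts <- t(utils::combn(n_positions, 2))
  contacts <- contacts[apply(contacts, 1,
                             function(r) ringd(r[1], r[2]) <= width), ,
                       drop = FALSE]
  oracle <- generate_landscape(seq_len(n_positions), allowed, ref, contacts,
                               field_scale = 1,
                               coupling_scale = coupling_scale,
                               n_incompatible_pairs = n_plants,
                               incompatible_penalty = 8, seed = seed)
  neighborhoods <- lapply(seq_len(n_positions), function(i) {
    mem <- c(i, which(vapply(seq_len(n_positions),
                             function(j) ringd(i, j) <= width && j != i,
                             logical(1))))
    structure(list(center = i, members = mem), class = "neighborhood")
  })
  list(positions = seq_len(n_positions), keys = keys, reference = ref,
       allowed = allowed, contacts = contacts, oracle = oracle,
       neighborhoods = neighborhoods)
}

# full neighborhood enumeration + energies for a ring_design_case
ring_samples <- function(case) {
  lapply(case$neighborhoods, function(nb) {
    G <- enumerate_neighborhood(nb, case$allowed)
    list(neighborhood = nb, genotypes = G,
         energies = landscape_energy(case$oracle, G))
  })
}

# additive landscape with hand-spaced distinct field terms over 5 positions
spaced_additive_case <- function() {
  keys <- as.character(1:5)
  ref <- stats::setNames(rep("A", 5), keys)
  allowed <- stats::setNames(rep(list(c("A", "C", "D")), 5), keys)
  oracle <- generate_landscape(1:5, allowed, ref, cbind(1:4, 2:5),
                               field_scale = 0, coupling_scale = 0,
                               n_incompatible_pairs = 0, seed = 1)
  vals <- seq(-2.5, 2.0, by = 0.5)
  i <- 1
  for (k in keys) for (aa in c("C", "D")) {
    oracle$h[[k]][aa] <- vals[i]
    i <- i + 1
  }
  neighborhoods <- lapply(1:5, function(i)
    structure(list(center = i,
                   members = unique(c(i, max(1, i - 1), min(5, i + 1)))),
              class = "neighborhood"))
  list(keys = keys, reference = ref, allowed = allowed, oracle = oracle,
       neighborhoods = neighborhoods)
}

# tiny gapped alignment written to a temp FASTA
write_toy_alignment <- function(rows, path = tempfile(fileext = ".fasta")) {
  con <- file(path, "w")
  for (nm in names(rows)) writeLines(c(paste0(">", nm), rows[[nm]]), con)
  close(con)
  path
}
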