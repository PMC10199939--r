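# End-to-end orchestration: configuration defaults, the design run
# (profiles -> pocket -> energy -> ranking -> library -> validation), the
# landscape run, and programmatic generation of synthetic demo fixtures.

#' Pocket position lists for the fluorescent-protein libraries
#'
#' Returns the curated chromophore-pocket position list for the two
#' designed libraries: `nohbonds` (27 positions, excluding residues that
#' hydrogen-bond directly to the chromophore) or `hbonds` (24 positions,
#' including them). Parsed from a plain-text file shipped with the package.
#'
#' @param library "nohbonds" or "hbonds".
#' @return Integer vector of residue positions.
#' @export
pocket_positions <- function(library = c("nohbonds", "hbonds")) {
  library <- match.arg(library)
  path <- system.file("extdata",
                      paste0("pocket_positions_", library, ".txt"),
                      package = "pocketlib", mustWork = TRUE)
  lines <- sub("#.*$", "", readLines(path, warn = FALSE))
  txt <- paste(lines, collapse = " ")
  as.integer(strsplit(trimws(txt), "[,[:space:]]+")[[1]])
}

#' Default run configuration
#'
#' All thresholds default to the standard protocol values: conservation
#' filter -2 bits, contact criterion 2 heavy atoms within 6 A, ligand
#' shell 8 A, full neighborhood enumeration below 10,000 designs with 10
#' percent sampling above, total modeled space under 1e6, library target
#' size 4e6, enrichment threshold 1, target functional occupancy 0.6.
#'
#' @param ... Overrides merged over the defaults.
#' @return Named list of configuration values.
#' @export
default_config <- function(...) {
  cfg <- list(
    chain = "A",
    pssm_threshold = -2,
    pseudocount_mass = 1,
    contact_cutoff = 6,
    min_atom_pairs = 2,
    shell_cutoff = 8,
    ddg_grid = seq(0.5, 8, by = 0.5),
    max_total = 1e6,
    full_limit = 10000,
    sample_fraction = 0.1,
    target_size = 4e6,
    n_validation = 10000,
    enrichment_threshold = 1,
    target_occupancy = 0.6,
    n_axes = 2,
    field_scale = 1,
    coupling_scale = 0.25,
    n_incompatible_pairs = 0,
    incompatible_penalty = 8,
    seed = 1
  )
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Read a YAML run configuration
#'
#' @param path Path to a YAML file; fields override [default_config()].
#' @return Configuration list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  do.call(default_config, yaml::read_yaml(path))
}

.require_cfg <- function(cfg, fields) {
  miss <- fields[!vapply(fields, function(f) !is.null(cfg[[f]]), logical(1))]
  if (length(miss))
    stop("configuration is missing required field(s): ",
         paste(miss, collapse = ", "))
}

#' Run the full library-design pipeline
#'
#' Executes conservation profiling, pocket-neighborhood construction,
#' single-mutation scanning, ddG-threshold selection, neighborhood
#' enumeration and energy labeling, neural-network training and mutation
#' ranking, library selection, and in-silico validation of the enriched
#' vs. filtered spaces. The energy oracle is either a synthetic landscape
#' (generated from the config's landscape parameters) or, when
#' `cfg$scan_tsv` is given, an external ddG table used additively.
#'
#' @param cfg Configuration list ([default_config()]) or path to a YAML
#'   file. Required fields: `msa`, `reference_id`, `pdb`, `ligand`,
#'   `designed` (positions).
#' @param out_dir Optional output directory; when given, all artifacts
#'   (PSSM, neighborhoods, scan, library, trace, validation, manifest) are
#'   written there as TSV/JSON.
#' @return List with `library`, `ranking`, `validation`, `model`, `scan`,
#'   `pssm`, `neighborhoods`, `oracle`, `threshold`, `manifest`.
#' @export
run_design <- function(cfg, out_dir = NULL) {
  if (is.character(cfg)) cfg <- read_config(cfg)
  .require_cfg(cfg, c("msa", "reference_id", "pdb", "ligand", "designed"))
  designed <- sort(as.integer(cfg$designed))
  keys <- .pos_key(designed)

  aln <- read_alignment(cfg$msa, cfg$reference_id)
  pssm <- build_pssm(aln, pseudocount_mass = cfg$pseudocount_mass)
  ref_row <- aln$matrix[aln$reference_index, aln$ref_columns]
  if (max(designed) > length(ref_row))
    stop("designed position beyond reference length (", length(ref_row), ")")
  reference <- stats::setNames(ref_row[designed], keys)

  s <- parse_structure(cfg$pdb, cfg$ligand)
  shell <- ligand_shell(s, cfg$shell_cutoff, chain = cfg$chain)
  outside <- setdiff(designed, shell)
  if (length(outside))
    warning("designed position(s) outside the ", cfg$shell_cutoff,
            " A ligand shell: ", paste(outside, collapse = ", "))
  nbhds <- build_neighborhoods(s, designed, chain = cfg$chain,
                               cutoff = cfg$contact_cutoff,
                               min_atom_pairs = cfg$min_atom_pairs,
                               prune = cfg$prune)

  allowed_pssm <- pssm_allowed_mutations(pssm, designed, reference,
                                         cfg$pssm_threshold)

  contacts <- do.call(rbind, lapply(nbhds, function(nb) {
    if (length(nb$members) < 2) return(NULL)
    cbind(nb$center, setdiff(nb$members, nb$center))
  }))
  if (!is.null(cfg$scan_tsv)) {
    scan <- read_ddg_scan(cfg$scan_tsv)
    scan <- scan[scan$position %in% designed, , drop = FALSE]
    # additive oracle from the external scan (no coupling information)
    oracle <- generate_landscape(designed, allowed_pssm, reference,
                                 contacts, field_scale = 0,
                                 coupling_scale = 0, seed = cfg$seed)
    for (i in seq_len(nrow(scan))) {
      k <- as.character(scan$position[i])
      if (scan$to_aa[i] %in% names(oracle$h[[k]]))
        oracle$h[[k]][scan$to_aa[i]] <- scan$ddg[i]
    }
  } else {
    oracle <- generate_landscape(
      designed, allowed_pssm, reference, contacts,
      field_scale = cfg$field_scale, coupling_scale = cfg$coupling_scale,
      n_incompatible_pairs = cfg$n_incompatible_pairs,
      incompatible_penalty = cfg$incompatible_penalty, seed = cfg$seed)
    scan <- ddg_scan(oracle, reference, allowed_pssm)
  }

  threshold <- select_ddg_threshold(nbhds, scan, cfg$ddg_grid,
                                    cfg$max_total)
  tolerated <- filter_by_ddg(scan, threshold)
  # positions with no scanned mutation keep reference only
  for (k in keys)
    if (is.null(tolerated[[k]])) tolerated[[k]] <- reference[[k]]
  tolerated <- tolerated[keys]

  samples <- lapply(seq_along(nbhds), function(i) {
    G <- enumerate_neighborhood(nbhds[[i]], tolerated,
                                full_limit = cfg$full_limit,
                                sample_fraction = cfg$sample_fraction,
                                seed = cfg$seed + i)
    list(neighborhood = nbhds[[i]], genotypes = G,
         energies = landscape_energy(oracle, G))
  })
  ds <- assemble_dataset(samples, tolerated, reference)
  model <- train_epinnet(ds, seed = cfg$seed)
  mut_only <- lapply(keys, function(k) setdiff(tolerated[[k]],
                                               reference[[k]]))
  names(mut_only) <- keys
  mut_only <- mut_only[lengths(mut_only) > 0]
  ranked <- rank_mutations(model, mut_only, scan)
  lib <- select_library(ranked, reference, cfg$target_size)
  validation <- validate_spaces(oracle, lib, tolerated,
                                n = cfg$n_validation, seed = cfg$seed)

  manifest <- list(
    config = cfg[order(names(cfg))],
    designed = designed,
    n_alignment_rows = nrow(aln$matrix),
    ddg_threshold = as.numeric(threshold),
    n_training_rows = nrow(ds$X),
    holdout_accuracy = model$holdout_accuracy,
    n_ranked = nrow(ranked),
    library_space = space_size(lib),
    filtered_space = space_size(tolerated))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_pssm(pssm, file.path(out_dir, "pssm.tsv"))
    write_neighborhoods(nbhds, file.path(out_dir, "neighborhoods.json"))
    write_ddg_scan(scan, file.path(out_dir, "scan.tsv"))
    write_library(lib, file.path(out_dir, "library.tsv"))
    utils::write.table(lib$trace, file.path(out_dir, "trace.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(enriched = validation$enriched[c("fraction_below", "mean")],
           filtered = validation$filtered[c("fraction_below", "mean")]),
      file.path(out_dir, "validation.json"), auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(library = lib, ranking = ranked, validation = validation,
       model = model, scan = scan, pssm = pssm, neighborhoods = nbhds,
       oracle = oracle, threshold = threshold, manifest = manifest)
}

#' Run the fitness-landscape visualization
#'
#' Enumerates the genotype space of a library, labels genotypes functional
#' via `label_fun`, calibrates the selection coefficient to the target
#' occupancy, builds the rate matrix and computes diffusion coordinates and
#' region logos.
#'
#' @param lib A `library_definition` (or allowed list).
#' @param label_fun Function taking the genotype character matrix and
#'   returning a logical functional indicator, or a precomputed logical
#'   vector.
#' @param cfg Configuration list; uses `target_occupancy`, `n_axes`.
#' @param logo_axis,logo_thresholds Region-logo settings (default axis 2,
#'   thresholds c(-2.25, -0.5)).
#' @param out_dir Optional output directory for coordinates and logos.
#' @return List with `space`, `functional`, `c`, `Q`, `pi`, `coordinates`,
#'   `logos`.
#' @export
run_landscape <- function(lib, label_fun, cfg = default_config(),
                          logo_axis = 2, logo_thresholds = c(-2.25, -0.5),
                          out_dir = NULL) {
  space <- genotype_space(lib)
  f <- if (is.function(label_fun)) label_fun(space$genotypes) else
    as.logical(label_fun)
  stopifnot(length(f) == space$size)
  c_sel <- calibrate_c(f, cfg$target_occupancy)
  Q <- build_rate_matrix(space, f, c_sel)
  pi <- stationary_distribution(f, c_sel)
  coords <- diffusion_coordinates(Q, pi, k = cfg$n_axes)
  logos <- region_logos(coords, space$genotypes,
                        axis = min(logo_axis, cfg$n_axes),
                        thresholds = logo_thresholds, functional = f)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_coordinates(coords, space$genotypes, f,
                      file.path(out_dir, "coordinates.tsv"))
    for (i in seq_along(logos)) {
      utils::write.table(
        data.frame(position = rownames(logos[[i]]$frequencies),
                   logos[[i]]$frequencies, check.names = FALSE),
        file.path(out_dir, paste0("logo_region", i, ".tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  list(space = space, functional = f, c = c_sel, Q = Q, pi = pi,
       coordinates = coords, logos = logos)
}

# ---- synthetic fixtures ----------------------------------------------------

.pdb_atom_line <- function(serial, name, resname, chain, resno, x, y, z,
                           occ = 1, b = 0, element, het = FALSE) {
  sprintf("%-6s%5d  %-3s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          if (het) "HETATM" else "ATOM", serial, name, resname, chain,
          resno, x, y, z, occ, b, element)
}

# ring of residues around a central ligand; a crude beta-barrel cross-section
.write_demo_pdb <- function(path, n_res = 8, ring_radius = 6) {
  resnames <- c("LEU", "THR", "GLN", "TYR", "VAL", "SER", "ILE", "PHE",
                "MET", "ALA", "HIS", "ASN")[seq_len(n_res)]
  lines <- character(0)
  serial <- 1L
  for (i in seq_len(n_res)) {
    th <- 2 * pi * (i - 1) / n_res
    for (atom in list(list(nm = "CA", r = ring_radius + 0.5, el = "C"),
                      list(nm = "CB", r = ring_radius - 0.8, el = "C"),
                      list(nm = "CG", r = ring_radius - 1.8, el = "C"))) {
      lines <- c(lines, .pdb_atom_line(
        serial, atom$nm, resnames[i], "A", i,
        atom$r * cos(th), atom$r * sin(th), 0, element = atom$el))
      serial <- serial + 1L
    }
  }
  for (atom in list(list(nm = "C1", xyz = c(0.8, 0, 0), el = "C"),
                    list(nm = "N1", xyz = c(-0.8, 0, 0), el = "N"),
                    list(nm = "O1", xyz = c(0, 0.9, 0), el = "O"))) {
    lines <- c(lines, .pdb_atom_line(serial, atom$nm, "CRO", "A", 99,
                                     atom$xyz[1], atom$xyz[2], atom$xyz[3],
                                     element = atom$el, het = TRUE))
    serial <- serial + 1L
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

# gapped MSA whose column compositions are drawn from planted profiles
.write_demo_msa <- function(path, reference, n_seqs = 40, seed = 7) {
  set.seed(seed)
  L <- nchar(reference)
  ref <- strsplit(reference, "")[[1]]
  rows <- list(ref = ref)
  for (i in seq_len(n_seqs - 1)) {
    s <- ref
    for (p in seq_len(L)) {
      if (stats::runif(1) < 0.3) {
        # substitute from a small per-position repertoire
        rep_aas <- AA_ALPHABET[(p + seq_len(3)) %% 20 + 1]
        s[p] <- sample(c(ref[p], rep_aas), 1,
                       prob = c(0.5, 0.3, 0.15, 0.05))
      }
      if (stats::runif(1) < 0.02) s[p] <- "-"
    }
    rows[[paste0("hom", i)]] <- s
  }
  con <- file(path, "w")
  for (nm in names(rows))
    writeLines(c(paste0(">", nm), paste(rows[[nm]], collapse = "")), con)
  close(con)
  invisible(path)
}

#' Generate synthetic demo fixtures
#'
#' Writes self-contained synthetic inputs for demos and tests:
#' \describe{
#'   \item{design-demo}{a toy ring-shaped pocket PDB with a central "CRO"
#'     ligand, a gapped homolog MSA for an 8-residue reference, a synthetic
#'     landscape with planted incompatible pairs (JSON), and ground truth.}
#'   \item{counts-demo}{sorted/presorted count tables with a planted
#'     enriched genotype set whose enrichments clear the threshold with
#'     margin, plus ground truth.}
#'   \item{two-island}{a 2-allele library whose functional genotypes form
#'     two islands separated by nonfunctional genotypes, plus the island
#'     assignment.}
#' }
#' Ground-truth files are for tests only and are never read by analysis
#' code.
#'
#' @param kind One of "design-demo", "counts-demo", "two-island".
#' @param seed Integer seed.
#' @param out_dir Output directory (created if needed).
#' @return Named list of written file paths, invisibly.
#' @export
make_fixture <- function(kind = c("design-demo", "counts-demo",
                                  "two-island"),
                         seed = 7, out_dir = tempfile("fixture")) {
  kind <- match.arg(kind)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  if (kind == "design-demo") {
    reference <- "LTQYVSIF"
    paths$pdb <- file.path(out_dir, "pocket.pdb")
    .write_demo_pdb(paths$pdb)
    paths$msa <- file.path(out_dir, "homologs.fasta")
    .write_demo_msa(paths$msa, reference, seed = seed)
    designed <- 1:8
    keys <- .pos_key(designed)
    ref <- stats::setNames(strsplit(reference, "")[[1]], keys)
    allowed <- lapply(keys, function(k)
      c(ref[[k]], setdiff(sample(AA_ALPHABET, 4), ref[[k]])[1:3]))
    names(allowed) <- keys
    contacts <- cbind(1:8, c(2:8, 1))
    oracle <- generate_landscape(designed, allowed, ref, contacts,
                                 field_scale = 1, coupling_scale = 0.25,
                                 n_incompatible_pairs = 2,
                                 incompatible_penalty = 8, seed = seed)
    paths$landscape <- file.path(out_dir, "landscape.json")
    write_landscape(oracle, paths$landscape)
    paths$ground_truth <- file.path(out_dir, "ground_truth.json")
    jsonlite::write_json(list(reference = reference,
                              planted = oracle$planted),
                         paths$ground_truth, auto_unbox = TRUE, digits = NA)
  } else if (kind == "counts-demo") {
    set.seed(seed)
    genos <- apply(expand.grid(c("A", "S"), c("Q", "L"), c("T", "M")), 1,
                   paste, collapse = "")
    enriched_gfp <- genos[c(2, 4)]
    enriched_both <- genos[6]
    presort <- stats::setNames(rep(1000, length(genos)), genos)
    sorted_gfp <- stats::setNames(rep(100, length(genos)), genos)
    sorted_amc <- stats::setNames(rep(100, length(genos)), genos)
    # planted hits get 5x the baseline frequency; others sit well below 1
    sorted_gfp[c(enriched_gfp, enriched_both)] <- 5000
    sorted_amc[enriched_both] <- 5000
    df <- rbind(
      data.frame(genotype = genos, sample = "presorted", count = presort),
      data.frame(genotype = genos, sample = "sorted_GFP",
                 count = sorted_gfp),
      data.frame(genotype = genos, sample = "sorted_AmCyan",
                 count = sorted_amc))
    paths$counts <- file.path(out_dir, "counts.tsv")
    utils::write.table(df, paths$counts, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths$ground_truth <- file.path(out_dir, "ground_truth.json")
    jsonlite::write_json(list(GFP = enriched_gfp, both = enriched_both),
                         paths$ground_truth, auto_unbox = FALSE)
  } else {
    # two functional islands: all-reference-like vs all-mutant corners of
    # a binary hypercube, separated by a nonfunctional middle
    n_pos <- 5
    allowed <- stats::setNames(
      lapply(seq_len(n_pos), function(i) c("A", "V")),
      as.character(seq_len(n_pos)))
    space <- genotype_space(allowed)
    nmut <- rowSums(space$genotypes == "V")
    island <- ifelse(nmut <= 1, 1L, ifelse(nmut >= n_pos - 1, 2L, 0L))
    paths$library <- file.path(out_dir, "library.tsv")
    lib <- structure(list(
      allowed = allowed,
      reference = stats::setNames(rep("A", n_pos),
                                  as.character(seq_len(n_pos))),
      trace = NULL), class = "library_definition")
    write_library(lib, paths$library)
    paths$islands <- file.path(out_dir, "islands.tsv")
    utils::write.table(
      data.frame(genotype = apply(space$genotypes, 1, paste, collapse = ""),
                 island = island),
      paths$islands, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(paths)
}
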