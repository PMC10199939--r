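# Pocket geometry: PDB parsing, ligand shell, atomic-contact neighborhoods
# and solvent accessibility. Distances use heavy atoms only.

#' Parse a PDB structure with a designated ligand residue
#'
#' Reads a PDB file, discards hydrogens, resolves alternate locations to the
#' highest-occupancy conformer, and records the residue named `ligand_name`
#' (e.g. a chromophore) as the ligand.
#'
#' @param path Path to a PDB file.
#' @param ligand_name Three-letter residue name of the ligand (e.g. "CRO").
#' @return An object of class `pocket_structure`: list with `atoms` (data
#'   frame: chain, resno, resid, elety, elesy, x, y, z, o) and `ligand`
#'   (list: chain, resno, resid).
#' @export
parse_structure <- function(path, ligand_name) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  pdb <- suppressWarnings(bio3d::read.pdb(path, rm.alt = FALSE,
                                          verbose = FALSE))
  at <- pdb$atom
  # heavy atoms only
  elesy <- at$elesy
  if (all(is.na(elesy)) || is.null(elesy)) {
    elesy <- substr(trimws(at$elety), 1, 1)
  }
  at <- at[!(trimws(elesy) %in% c("H", "D")), , drop = FALSE]
  # altloc: keep highest occupancy per (chain, resno, atom name)
  at$alt[is.na(at$alt)] <- ""
  if (any(at$alt != "")) {
    key <- paste(at$chain, at$resno, at$elety, sep = "|")
    o <- at$o
    o[is.na(o)] <- 1
    ord <- order(key, -o)
    at <- at[ord, , drop = FALSE]
    at <- at[!duplicated(paste(at$chain, at$resno, at$elety, sep = "|")), ,
             drop = FALSE]
  }
  atoms <- data.frame(chain = at$chain, resno = at$resno, resid = at$resid,
                      elety = trimws(at$elety),
                      elesy = trimws(substr(at$elety, 1, 1)),
                      x = at$x, y = at$y, z = at$z,
                      o = ifelse(is.na(at$o), 1, at$o),
                      stringsAsFactors = FALSE)
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite coordinates in ", path)
  lig <- atoms[atoms$resid == ligand_name, , drop = FALSE]
  if (nrow(lig) == 0L)
    stop("ligand residue '", ligand_name, "' not found in structure")
  structure(list(atoms = atoms,
                 ligand = list(chain = lig$chain[1], resno = lig$resno[1],
                               resid = ligand_name)),
            class = "pocket_structure")
}

#' @export
print.pocket_structure <- function(x, ...) {
  nres <- nrow(unique(x$atoms[, c("chain", "resno")]))
  cat("Structure:", nres, "residues,", nrow(x$atoms),
      "heavy atoms; ligand", x$ligand$resid,
      paste0(x$ligand$chain, x$ligand$resno), "\n")
  invisible(x)
}

# coordinates of the heavy atoms of one residue
.res_coords <- function(s, resno, chain) {
  sel <- s$atoms$resno == resno & s$atoms$chain == chain
  as.matrix(s$atoms[sel, c("x", "y", "z"), drop = FALSE])
}

# residue table excluding the ligand
.protein_residues <- function(s) {
  res <- unique(s$atoms[, c("chain", "resno", "resid")])
  res[!(res$chain == s$ligand$chain & res$resno == s$ligand$resno), ,
      drop = FALSE]
}

# for each atom of B, the minimum distance to any atom of A
.min_dist_per_atom <- function(A, B) {
  d2 <- outer(rowSums(B^2), rowSums(A^2), "+") - 2 * B %*% t(A)
  sqrt(pmax(apply(d2, 1, min), 0))
}

#' Residues in direct atomic contact with a center residue
#'
#' A candidate residue is a contact of the center when at least
#' `min_atom_pairs` of its heavy atoms each lie within `cutoff` of some
#' heavy atom of the center residue. The center itself and the ligand are
#' excluded.
#'
#' @param s A `pocket_structure`.
#' @param center Residue number of the center.
#' @param chain Chain identifier; default "A".
#' @param cutoff Distance cutoff in Angstrom; default 6.
#' @param min_atom_pairs Minimum number of candidate heavy atoms within the
#'   cutoff; default 2.
#' @return Integer vector of contacting residue numbers (same chain).
#' @export
residue_contacts <- function(s, center, chain = "A", cutoff = 6,
                             min_atom_pairs = 2) {
  stopifnot(inherits(s, "pocket_structure"), cutoff > 0)
  A <- .res_coords(s, center, chain)
  if (nrow(A) == 0L) stop("center residue ", chain, center,
                          " not found in structure")
  res <- .protein_residues(s)
  res <- res[res$chain == chain & res$resno != center, , drop = FALSE]
  hits <- vapply(res$resno, function(r) {
    B <- .res_coords(s, r, chain)
    sum(.min_dist_per_atom(A, B) <= cutoff) >= min_atom_pairs
  }, logical(1))
  sort(res$resno[hits])
}

#' Residues within a distance shell of the ligand
#'
#' Returns residues having any heavy atom within `cutoff` (inclusive) of any
#' heavy atom of the ligand residue.
#'
#' @param s A `pocket_structure`.
#' @param cutoff Shell radius in Angstrom; default 8.
#' @param chain Restrict to one chain; default the ligand's chain.
#' @return Integer vector of residue numbers.
#' @export
ligand_shell <- function(s, cutoff = 8, chain = s$ligand$chain) {
  stopifnot(inherits(s, "pocket_structure"))
  if (cutoff <= 0) return(integer(0))
  L <- .res_coords(s, s$ligand$resno, s$ligand$chain)
  res <- .protein_residues(s)
  res <- res[res$chain == chain, , drop = FALSE]
  hits <- vapply(res$resno, function(r) {
    B <- .res_coords(s, r, chain)
    any(.min_dist_per_atom(L, B) <= cutoff)
  }, logical(1))
  sort(res$resno[hits])
}

#' Build overlapping spatial neighborhoods around designed positions
#'
#' One neighborhood per designed position: the center plus every designed
#' position in direct atomic contact with it ([residue_contacts()]).
#' Because the contact criterion is symmetric, proximal neighborhoods
#' overlap, so no position-pair interaction is missed. An optional
#' per-center exclusion list mirrors manual curation of spurious contacts.
#'
#' @param s A `pocket_structure`.
#' @param designed Integer vector of designed residue numbers.
#' @param chain Chain identifier; default "A".
#' @param cutoff,min_atom_pairs Contact criterion, see [residue_contacts()].
#' @param prune Optional named list: center (as character) -> positions to
#'   drop from that center's neighborhood. Pruning a center is an error.
#' @return List of `neighborhood` objects: list(center, members) with the
#'   center first in `members`.
#' @export
build_neighborhoods <- function(s, designed, chain = "A", cutoff = 6,
                                min_atom_pairs = 2, prune = NULL) {
  stopifnot(inherits(s, "pocket_structure"))
  designed <- sort(as.integer(designed))
  out <- lapply(designed, function(ctr) {
    contacts <- residue_contacts(s, ctr, chain, cutoff, min_atom_pairs)
    members <- intersect(contacts, designed)
    if (!is.null(prune)) {
      drop <- prune[[as.character(ctr)]]
      if (!is.null(drop)) {
        if (ctr %in% drop)
          stop("cannot prune the center (", ctr, ") from its own neighborhood")
        members <- setdiff(members, drop)
      }
    }
    structure(list(center = ctr, members = c(ctr, sort(members))),
              class = "neighborhood")
  })
  names(out) <- as.character(designed)
  out
}

#' @export
print.neighborhood <- function(x, ...) {
  cat("Neighborhood center", x$center, "| members:",
      paste(x$members, collapse = ", "), "\n")
  invisible(x)
}

#' Write neighborhoods to JSON
#'
#' @param neighborhoods List of `neighborhood` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_neighborhoods <- function(neighborhoods, path) {
  jsonlite::write_json(
    lapply(neighborhoods, function(n) list(center = n$center,
                                           members = n$members)),
    path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}

# evenly distributed points on the unit sphere (Fibonacci / golden spiral)
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# van der Waals radii (A) by element for SASA
.VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80)

#' Solvent-accessible surface area by sphere sampling
#'
#' Shrake-Rupley style numerical SASA: each heavy atom's solvent-expanded
#' sphere (van der Waals radius + probe) is sampled with evenly distributed
#' points; points falling inside any neighboring atom's expanded sphere are
#' buried. Per-residue areas are normalized by tabulated per-amino-acid
#' theoretical maxima to give relative accessibility; residues with relative
#' accessibility below `buried_threshold` are flagged buried.
#'
#' @param s A `pocket_structure`.
#' @param probe Probe radius in Angstrom; default 1.4 (water).
#' @param n_points Sample points per atom; default 500.
#' @param buried_threshold Relative-accessibility cutoff for the buried
#'   flag; default 0.2.
#' @return Data frame: chain, resno, resid, sasa (A^2), rel_sasa, buried.
#'   Ligand and non-standard residues get `NA` relative accessibility.
#' @export
relative_sasa <- function(s, probe = 1.4, n_points = 500,
                          buried_threshold = 0.2) {
  stopifnot(inherits(s, "pocket_structure"))
  at <- s$atoms
  xyz <- as.matrix(at[, c("x", "y", "z")])
  rad <- .VDW_RADII[at$elesy]
  rad[is.na(rad)] <- 1.80
  rext <- rad + probe
  sp <- .sphere_points(n_points)
  n <- nrow(xyz)
  areas <- numeric(n)
  for (i in seq_len(n)) {
    pts <- sweep(sp * rext[i], 2, xyz[i, ], "+")
    # candidate occluders: atoms whose expanded spheres can reach atom i's
    d2 <- colSums((t(xyz) - xyz[i, ])^2)
    nb <- which(d2 < (rext[i] + rext)^2 & seq_len(n) != i)
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(acc)) break
      dj <- colSums((t(pts[acc, , drop = FALSE]) - xyz[j, ])^2)
      acc[acc] <- dj > rext[j]^2
    }
    areas[i] <- 4 * pi * rext[i]^2 * mean(acc)
  }
  key <- paste(at$chain, at$resno, sep = "|")
  res <- unique(data.frame(chain = at$chain, resno = at$resno,
                           resid = at$resid, key = key,
                           stringsAsFactors = FALSE))
  res$sasa <- vapply(res$key, function(k) sum(areas[key == k]), numeric(1))
  one <- AA_THREE_TO_ONE[res$resid]
  res$rel_sasa <- res$sasa / AA_MAX_SASA[one]
  res$buried <- res$rel_sasa < buried_threshold
  res$key <- NULL
  rownames(res) <- NULL
  res
}
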