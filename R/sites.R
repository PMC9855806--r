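# Heme-site extraction: altloc/occupancy resolution, skeleton completeness,
# axial-ligand detection, heme coverage, and sequence-redundancy filtering.

#' Resolve alternate locations by occupancy
#'
#' Collapses alternate-conformer records so that at most one atom remains
#' per (chain, residue number, atom name).  Only the requested model is
#' kept (default model 1).  Where occupancies differ the largest wins;
#' where they tie (including the common 0.5/0.5 A/B case) the record with
#' the lexicographically smallest altloc identifier is kept, so a 0.5/0.5
#' tie keeps altloc "A".
#'
#' @param atoms atom data frame (see [read_mmcif_atoms()]).
#' @param model_num model number to keep.
#' @return the filtered atom data frame; idempotent.
#' @export
resolve_altlocs <- function(atoms, model_num = 1L) {
  if (!nrow(atoms)) return(atoms)
  if ("model" %in% names(atoms))
    atoms <- atoms[atoms$model == model_num, , drop = FALSE]
  if (!nrow(atoms)) return(atoms)
  altloc <- if ("altloc" %in% names(atoms)) atoms$altloc else ""
  ord <- order(atoms$chain, atoms$residue_seq, atoms$atom_name,
               -atoms$occupancy, altloc)
  atoms <- atoms[ord, , drop = FALSE]
  key <- paste(atoms$chain, atoms$residue_seq, atoms$atom_name, sep = "\r")
  atoms <- atoms[!duplicated(key), , drop = FALSE]
  rownames(atoms) <- NULL
  atoms
}

#' Check completeness of the Fe-porphyrin skeleton
#'
#' @param heme_atoms atom data frame of one heme instance (altlocs already
#'   resolved).
#' @return `TRUE` iff each of the 25 skeleton atom names occurs exactly
#'   once.  Substituent atoms (vinyl, propionate, ...) are ignored.
#' @export
check_skeleton_complete <- function(heme_atoms) {
  counts <- table(heme_atoms$atom_name[heme_atoms$atom_name %in%
                                         heme_skeleton_names()])
  length(counts) == 25L && all(counts == 1L)
}

#' Find axial ligands of a heme iron
#'
#' Returns every residue or non-protein molecule (water included) with at
#' least one atom within `cutoff` of the iron; the boundary is inclusive.
#' The heme's own atoms are excluded.
#'
#' @param site a `heme_site` object or a list with elements `iron`
#'   (numeric xyz), `protein` and `hetero` (atom data frames).
#' @param cutoff distance cutoff in angstrom.
#' @return data frame (`chain`, `residue_seq`, `residue_name`,
#'   `min_dist`, `is_polymer`), one row per coordinating residue, ordered
#'   by distance; zero rows when nothing coordinates.
#' @export
find_axial_ligands <- function(site, cutoff = 3.1) {
  stopifnot_scalar_number(cutoff, "cutoff")
  cand <- rbind(site$protein[, c("chain", "residue_seq", "residue_name",
                                 "x", "y", "z", "is_polymer")],
                site$hetero[, c("chain", "residue_seq", "residue_name",
                                "x", "y", "z", "is_polymer")])
  if (!nrow(cand)) {
    return(data.frame(chain = character(), residue_seq = integer(),
                      residue_name = character(), min_dist = numeric(),
                      is_polymer = logical()))
  }
  d <- sqrt((cand$x - site$iron[1])^2 + (cand$y - site$iron[2])^2 +
              (cand$z - site$iron[3])^2)
  key <- paste(cand$chain, cand$residue_seq, cand$residue_name, sep = "\r")
  mind <- tapply(d, key, min)
  first <- !duplicated(key)
  res <- data.frame(chain = cand$chain[first],
                    residue_seq = cand$residue_seq[first],
                    residue_name = cand$residue_name[first],
                    is_polymer = cand$is_polymer[first],
                    stringsAsFactors = FALSE)
  res$min_dist <- as.numeric(mind[paste(res$chain, res$residue_seq,
                                        res$residue_name, sep = "\r")])
  res <- res[res$min_dist <= cutoff, , drop = FALSE]
  res <- res[order(res$min_dist), , drop = FALSE]
  rownames(res) <- NULL
  res[, c("chain", "residue_seq", "residue_name", "min_dist", "is_polymer")]
}

#' Heme coverage by the host protein
#'
#' Fraction of heme heavy atoms that have at least one host-protein atom
#' within `contact_cutoff`.  This is a proxy for the burial of the heme;
#' sites whose biological and asymmetric units differ typically leave much
#' of the heme without protein contacts and score low.
#'
#' @param site a `heme_site` object (or list with `heme` and `protein`
#'   atom data frames).
#' @param contact_cutoff contact distance in angstrom.
#' @return fraction in \[0, 1\]; 0 when there are no protein atoms.
#' @export
compute_heme_coverage <- function(site, contact_cutoff = 5.0) {
  stopifnot_scalar_number(contact_cutoff, "contact_cutoff")
  hx <- site$heme
  px <- site$protein
  if (!nrow(px) || !nrow(hx)) return(0)
  pm <- as.matrix(px[, c("x", "y", "z")])
  hm <- as.matrix(hx[, c("x", "y", "z")])
  cut2 <- contact_cutoff^2
  hit <- vapply(seq_len(nrow(hm)), function(i) {
    d2 <- (pm[, 1] - hm[i, 1])^2 + (pm[, 2] - hm[i, 2])^2 +
      (pm[, 3] - hm[i, 3])^2
    any(d2 <= cut2)
  }, logical(1))
  mean(hit)
}

#' Greedy sequence-redundancy filter
#'
#' First-come greedy filter over protein sequences: a sequence is dropped
#' when its global pairwise identity to any already-kept sequence exceeds
#' `identity_threshold` (percent).  Identity is PID1 (identities over
#' alignment length) from a global Needleman-Wunsch alignment
#' (BLOSUM62, gap open 10, gap extend 0.5).
#'
#' @param ids character vector of sequence identifiers.
#' @param sequences character vector of one-letter amino-acid sequences.
#' @param identity_threshold percent identity above which a sequence is
#'   considered redundant (e.g. 99.99, 80, 60, 25).
#' @return character vector of kept ids (in input order).
#' @export
filter_redundant_chains <- function(ids, sequences,
                                    identity_threshold = 99.99) {
  stopifnot(length(ids) == length(sequences))
  if (!length(ids)) return(character())
  if (identity_threshold <= 0 || identity_threshold > 100)
    stop("'identity_threshold' must be in (0, 100]", call. = FALSE)
  kept <- integer()
  for (i in seq_along(ids)) {
    redundant <- FALSE
    for (j in kept) {
      if (pairwise_identity(sequences[i], sequences[j]) >
            identity_threshold) {
        redundant <- TRUE
        break
      }
    }
    if (!redundant) kept <- c(kept, i)
  }
  ids[kept]
}

#' Global pairwise sequence identity (percent)
#' @keywords internal
pairwise_identity <- function(a, b) {
  if (identical(a, b)) return(100)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 0.5)
  Biostrings::pid(aln, type = "PID1")
}

#' Assemble and filter heme sites from an atom table
#'
#' Runs the full extraction chain on the atoms of one structure entry:
#' altloc/occupancy resolution (model 1), location of heme instances
#' (compound ids HEM/HEA/HEB/HEC/HEO), skeleton-completeness check,
#' axial-ligand detection and heme-coverage computation.  Waters and other
#' non-protein molecules may coordinate the iron but are never part of a
#' site's protein atoms.
#'
#' @param atoms atom data frame for one entry ([read_mmcif_atoms()]).
#' @param entry_id entry identifier recorded on each site.
#' @param axial_cutoff axial-ligand distance cutoff (angstrom).
#' @param contact_cutoff contact cutoff used for coverage (angstrom).
#' @param coverage_min minimum coverage; sites below it fail the filter.
#' @return list with `sites` (list of `heme_site` objects that pass all
#'   filters) and `table` (data frame with one row per heme instance found
#'   and its per-filter pass/fail status).
#' @examples
#' cif <- system.file("extdata", "synthetic_site.cif",
#'                    package = "hemepocket")
#' ex <- extract_sites(read_mmcif_atoms(cif), entry_id = "SYNOB001")
#' ex$table
#' @export
extract_sites <- function(atoms, entry_id = "XXXX", axial_cutoff = 3.1,
                          contact_cutoff = 5.0, coverage_min = 0.6) {
  atoms <- resolve_altlocs(atoms, model_num = 1L)
  is_heme <- atoms$residue_name %in% heme_compound_ids()
  heme_key <- paste(atoms$chain, atoms$residue_seq, atoms$residue_name,
                    sep = "\r")
  sites <- list()
  rows <- list()
  for (key in unique(heme_key[is_heme])) {
    sel <- is_heme & heme_key == key
    heme_atoms <- atoms[sel, , drop = FALSE]
    other <- atoms[!sel, , drop = FALSE]
    complete <- check_skeleton_complete(heme_atoms)
    fe <- heme_atoms[heme_atoms$atom_name == "FE", , drop = FALSE]
    info <- data.frame(
      entry_id = entry_id,
      compound_id = heme_atoms$residue_name[1],
      chain = heme_atoms$chain[1],
      residue_seq = heme_atoms$residue_seq[1],
      complete = complete,
      has_axial = FALSE, axial = "", coverage = NA_real_, pass = FALSE,
      stringsAsFactors = FALSE)
    if (complete && nrow(fe) == 1L) {
      site <- structure(list(
        entry_id = entry_id,
        compound_id = heme_atoms$residue_name[1],
        chain = heme_atoms$chain[1],
        residue_seq = heme_atoms$residue_seq[1],
        heme = heme_atoms,
        iron = c(fe$x, fe$y, fe$z),
        protein = other[other$is_polymer, , drop = FALSE],
        hetero = other[!other$is_polymer, , drop = FALSE]
      ), class = "heme_site")
      site$axial <- find_axial_ligands(site, cutoff = axial_cutoff)
      site$coverage <- compute_heme_coverage(site, contact_cutoff)
      info$has_axial <- nrow(site$axial) > 0L
      info$axial <- paste(sprintf("%s/%s%d", site$axial$residue_name,
                                  site$axial$chain, site$axial$residue_seq),
                          collapse = ";")
      info$coverage <- site$coverage
      info$pass <- info$has_axial && site$coverage >= coverage_min
      if (info$pass) sites[[length(sites) + 1L]] <- site
    }
    rows[[length(rows) + 1L]] <- info
  }
  list(sites = sites, table = do.call(rbind, c(rows, list(
    make.row.names = FALSE))))
}

#' @export
print.heme_site <- function(x, ...) {
  cat(sprintf("heme site %s (%s %s%d)\n", x$entry_id, x$compound_id,
              x$chain, x$residue_seq))
  cat(sprintf("  heme atoms: %d, protein atoms: %d, hetero atoms: %d\n",
              nrow(x$heme), nrow(x$protein), nrow(x$hetero)))
  if (!is.null(x$axial) && nrow(x$axial))
    cat(sprintf("  axial: %s (%.2f A)\n",
                paste(x$axial$residue_name, collapse = ","),
                min(x$axial$min_dist)))
  if (!is.null(x$coverage))
    cat(sprintf("  coverage: %.2f\n", x$coverage))
  invisible(x)
}
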