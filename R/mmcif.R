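# Minimal PDBx/mmCIF atom_site I/O.
#
# Only the atom_site category is read; that is the only category the
# pipeline consumes.  Fields honoured: group_PDB, type_symbol,
# label_atom_id, label_alt_id, label_comp_id, auth_asym_id/label_asym_id,
# auth_seq_id/label_seq_id, Cartn_x/y/z, occupancy, pdbx_PDB_model_num.

#' Read atom records from a PDBx/mmCIF file
#'
#' Parses the `atom_site` loop of a PDBx/mmCIF file into a data frame of
#' atom records.  Hydrogen/deuterium atoms are dropped (the pipeline works
#' on heavy atoms only).  `auth_*` identifiers are preferred over
#' `label_*` ones when both are present, matching how axial ligands and
#' altloc groups are keyed.
#'
#' @param path path to an mmCIF file.
#' @return data frame with columns `group` ("ATOM"/"HETATM"), `atom_name`,
#'   `element`, `altloc` (empty string when absent), `residue_name`,
#'   `residue_seq` (integer), `chain`, `x`, `y`, `z`, `occupancy`,
#'   `model` (integer) and `is_polymer` (logical, `group == "ATOM"`).
#' @export
read_mmcif_atoms <- function(path) {
  lines <- readLines(path, warn = FALSE)
  i <- 1L
  n <- length(lines)
  fields <- character()
  rows <- character()
  while (i <= n) {
    if (grepl("^\\s*loop_\\s*$", lines[i])) {
      j <- i + 1L
      fl <- character()
      while (j <= n && grepl("^\\s*_", lines[j])) {
        fl <- c(fl, sub("^\\s*(\\S+).*$", "\\1", lines[j]))
        j <- j + 1L
      }
      if (length(fl) && all(startsWith(fl, "_atom_site."))) {
        fields <- sub("^_atom_site\\.", "", fl)
        while (j <= n && !grepl("^\\s*(#|loop_|data_|_)", lines[j])) {
          if (nzchar(trimws(lines[j]))) rows <- c(rows, lines[j])
          j <- j + 1L
        }
        break
      }
      i <- j
    } else {
      i <- i + 1L
    }
  }
  if (!length(fields))
    stop("no atom_site loop found in ", path, call. = FALSE)
  tok <- strsplit(trimws(rows), "\\s+")
  bad <- lengths(tok) != length(fields)
  if (any(bad))
    stop("malformed atom_site rows in ", path, call. = FALSE)
  m <- do.call(rbind, tok)
  colnames(m) <- fields
  get <- function(a, b = NULL) {
    if (a %in% fields) m[, a]
    else if (!is.null(b) && b %in% fields) m[, b]
    else rep(NA_character_, nrow(m))
  }
  blank <- function(x) ifelse(x %in% c(".", "?"), "", x)
  df <- data.frame(
    group        = get("group_PDB"),
    atom_name    = blank(get("label_atom_id", "auth_atom_id")),
    element      = toupper(blank(get("type_symbol"))),
    altloc       = blank(get("label_alt_id")),
    residue_name = blank(get("label_comp_id", "auth_comp_id")),
    residue_seq  = suppressWarnings(as.integer(blank(get("auth_seq_id",
                                                         "label_seq_id")))),
    chain        = blank(get("auth_asym_id", "label_asym_id")),
    x            = as.numeric(get("Cartn_x")),
    y            = as.numeric(get("Cartn_y")),
    z            = as.numeric(get("Cartn_z")),
    occupancy    = as.numeric(blank(get("occupancy"))),
    model        = suppressWarnings(as.integer(blank(get("pdbx_PDB_model_num")))),
    stringsAsFactors = FALSE
  )
  df$occupancy[is.na(df$occupancy)] <- 1
  df$model[is.na(df$model)] <- 1L
  df$is_polymer <- df$group == "ATOM"
  df[!(df$element %in% c("H", "D")), , drop = FALSE]
}

#' Write atom records to a PDBx/mmCIF file
#'
#' Emits a single `atom_site` loop.  The inverse of [read_mmcif_atoms()]:
#' reading the written file recovers the atom table (heavy atoms).
#'
#' @param atoms data frame in the layout returned by [read_mmcif_atoms()].
#' @param path output path.
#' @param entry_id data block name.
#' @export
write_mmcif_atoms <- function(atoms, path, entry_id = "XXXX") {
  need <- c("group", "atom_name", "element", "altloc", "residue_name",
            "residue_seq", "chain", "x", "y", "z", "occupancy")
  miss <- setdiff(need, names(atoms))
  if (length(miss))
    stop("atoms is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  model <- if ("model" %in% names(atoms)) atoms$model else 1L
  dot <- function(x) ifelse(is.na(x) | x == "", ".", x)
  body <- sprintf("%s %d %s %s %s %s %s %d ? %.3f %.3f %.3f %.2f 0.00 %d %s %d",
                  atoms$group, seq_len(nrow(atoms)), dot(atoms$element),
                  dot(atoms$atom_name), dot(atoms$altloc),
                  dot(atoms$residue_name), dot(atoms$chain),
                  atoms$residue_seq, atoms$x, atoms$y, atoms$z,
                  atoms$occupancy, atoms$residue_seq, dot(atoms$chain),
                  as.integer(model))
  header <- c(paste0("data_", entry_id), "#", "loop_",
              paste0("_atom_site.",
                     c("group_PDB", "id", "type_symbol", "label_atom_id",
                       "label_alt_id", "label_comp_id", "label_asym_id",
                       "label_seq_id", "pdbx_PDB_ins_code", "Cartn_x",
                       "Cartn_y", "Cartn_z", "occupancy", "B_iso_or_equiv",
                       "auth_seq_id", "auth_asym_id", "pdbx_PDB_model_num")))
  writeLines(c(header, body, "#"), path)
  invisible(path)
}
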