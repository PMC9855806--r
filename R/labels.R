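# Function assignment: EC / GO / keyword / description rule cascade,
# manual dual-function overrides, and the 0/1 label encodings.

# Concept synonym tables for case-insensitive substring matching.  The
# cascade names concepts rather than exact vocabulary strings, so each
# concept carries a small list of synonyms.
go_priority <- function() list(
  "oxygen-binding"    = c("oxygen binding", "oxygen-binding",
                          "oxygen carrier", "oxygen transport",
                          "oxygen storage"),
  "oxidoreductase"    = c("oxidoreductase"),
  "electron-transfer" = c("electron transfer", "electron transport",
                          "electron carrier"),
  "transcription"     = c("transcription"),
  "heme-transport"    = c("heme transport", "haem transport")
)

keyword_priority <- function() list(
  "hemophore"         = c("hemophore", "haemophore"),
  "electron-transfer" = c("electron transfer", "electron transport"),
  "oxygen-binding"    = c("oxygen binding", "oxygen-binding",
                          "oxygen storage", "oxygen transport"),
  "oxidoreductase"    = c("oxidoreductase"),
  "heme-extraction"   = c("heme extraction", "haem extraction"),
  "signaling"         = c("signaling protein", "signalling protein"),
  "NO-transport"      = c("nitrophorin", "no transport",
                          "nitric oxide transport"),
  "heme-transport"    = c("heme transport", "haem transport")
)

match_concept <- function(strings, synonyms) {
  if (!length(strings)) return(FALSE)
  any(vapply(synonyms, function(s)
    any(grepl(s, strings, ignore.case = TRUE, fixed = FALSE)),
    logical(1)))
}

#' Map a set of function terms to a class name
#'
#' @param functions character vector of assigned function terms.
#' @return one of "OB", "OR", "OB-OR", "ET", "other", "unclassified".
#' @export
function_class <- function(functions) {
  functions <- setdiff(unique(functions), "")
  if (!length(functions) || identical(functions, "unclassified"))
    return("unclassified")
  ob <- "oxygen-binding" %in% functions
  or <- "oxidoreductase" %in% functions
  et <- "electron-transfer" %in% functions
  extra <- length(setdiff(functions,
                          c("oxygen-binding", "oxidoreductase",
                            "electron-transfer")))
  if (extra > 0) return("other")
  if (ob && or) "OB-OR"
  else if (ob) "OB"
  else if (or) "OR"
  else if (et) "ET"
  else "other"
}

#' Assign a function label from annotations
#'
#' Applies the rule cascade, in this fixed order:
#' \enumerate{
#'   \item EC number of the chain(s) carrying the axial ligand(s): the
#'     first digit is assigned (digit 1 = oxidoreductase; any other digit
#'     maps to class "other" and is excluded from modelling).
#'   \item Otherwise, the first matching GO concept in priority order:
#'     oxygen binding, oxidoreductase activity, electron transfer
#'     activity, transcription, heme transport.
#'   \item Otherwise, the first matching keyword concept in priority
#'     order: hemophore, electron transfer, oxygen binding,
#'     oxidoreductase, heme extraction, signaling protein, nitrophorin
#'     (NO transport), heme transport.
#'   \item Otherwise, a description containing "cytochrome p460" assigns
#'     oxidoreductase.
#'   \item Otherwise (or with no axial ligand at all), "unclassified".
#' }
#' Matching is case-insensitive substring matching against a synonym
#' table; the priority comes from the fixed rule lists, never from the
#' order of the input annotation strings.
#'
#' @param annotation list or one-row data frame with elements
#'   `ec_numbers`, `go_terms`, `keywords` (character vectors, possibly
#'   empty or ";"-separated strings) and `description` (string).  A
#'   missing/NULL annotation falls through to "unclassified".
#' @param has_axial does the site have an axial ligand?
#' @return object of class `function_label`: list with `functions`
#'   (character vector), `class_name` and `source` (which cascade stage
#'   fired).
#' @export
assign_function <- function(annotation, has_axial = TRUE) {
  label <- function(functions, source)
    structure(list(functions = functions,
                   class_name = function_class(functions),
                   source = source),
              class = "function_label")
  if (!has_axial || is.null(annotation))
    return(label("unclassified", "none"))
  split_terms <- function(x) {
    if (is.null(x)) return(character())
    x <- unlist(strsplit(as.character(x), ";", fixed = TRUE))
    trimws(x[nzchar(trimws(x))])
  }
  ec <- split_terms(annotation$ec_numbers)
  go <- split_terms(annotation$go_terms)
  kw <- split_terms(annotation$keywords)
  desc <- if (is.null(annotation$description)) "" else
    as.character(annotation$description)[1]
  ec <- ec[grepl("^[0-9]+(\\.[0-9n-]+)*$", ec)]
  if (length(ec)) {
    digits <- unique(sub("^([0-9]+).*$", "\\1", ec))
    fns <- ifelse(digits == "1", "oxidoreductase", "other")
    return(label(unique(fns), "ec"))
  }
  for (concept in names(go_priority()))
    if (match_concept(go, go_priority()[[concept]]))
      return(label(concept, "go"))
  for (concept in names(keyword_priority()))
    if (match_concept(kw, keyword_priority()[[concept]]))
      return(label(concept, "keyword"))
  if (grepl("cytochrome p460", desc, ignore.case = TRUE))
    return(label("oxidoreductase", "description"))
  label("unclassified", "none")
}

#' Manual dual-function overrides
#'
#' Dehaloperoxidase entries, and myoglobin entries whose cascade result
#' includes oxidoreductase activity, are reassigned to the dual-function
#' class OB-OR (oxygen binding and oxidoreductase).  All other labels are
#' returned unchanged.
#'
#' @param label a `function_label`.
#' @param protein_name protein name/description of the entry.
#' @return possibly modified `function_label`.
#' @export
apply_manual_overrides <- function(label, protein_name) {
  name <- tolower(paste(protein_name, collapse = " "))
  dual <- structure(list(
    functions = c("oxygen-binding", "oxidoreductase"),
    class_name = "OB-OR", source = "override"), class = "function_label")
  if (grepl("dehaloperoxidase", name, fixed = TRUE)) return(dual)
  if (grepl("myoglobin", name, fixed = TRUE) &&
        "oxidoreductase" %in% label$functions) return(dual)
  label
}

#' @export
print.function_label <- function(x, ...) {
  cat(sprintf("function label: %s [%s] (from %s)\n", x$class_name,
              paste(x$functions, collapse = " + "), x$source))
  invisible(x)
}

encoding_table <- function(scheme) {
  switch(scheme,
    "two-label" = rbind(OB = c(0L, 1L), OR = c(1L, 0L),
                        "OB-OR" = c(1L, 1L)),
    "three-label" = rbind(OB = c(0L, 1L, 0L), OR = c(1L, 0L, 0L),
                          "OB-OR" = c(1L, 1L, 0L), ET = c(0L, 0L, 1L)),
    stop("unknown scheme: ", scheme, call. = FALSE))
}

#' Encode a function class as a 0/1 label vector
#'
#' Two-label scheme (classes OB, OR, OB-OR): `(0, 1)`, `(1, 0)`, `(1, 1)`.
#' Three-label scheme (plus ET): `(0, 1, 0)`, `(1, 0, 0)`, `(1, 1, 0)`,
#' `(0, 0, 1)`.  The positions are (oxidoreductase, oxygen binding\[,
#' electron transfer\]).
#'
#' @param class_name class name or a `function_label`.
#' @param scheme "two-label" or "three-label".
#' @return integer 0/1 vector.
#' @export
encode_labels <- function(class_name, scheme = c("two-label", "three-label")) {
  scheme <- match.arg(scheme)
  if (inherits(class_name, "function_label"))
    class_name <- class_name$class_name
  tab <- encoding_table(scheme)
  if (!class_name %in% rownames(tab))
    stop(sprintf("class '%s' has no %s encoding; exclude it upstream",
                 class_name, scheme), call. = FALSE)
  tab[class_name, ]
}

#' Decode a 0/1 label vector to a class name
#'
#' The inverse of [encode_labels()].  Any vector that does not match a
#' class encoding -- in particular the all-zero vector -- decodes to
#' "Others".
#'
#' @param encoding integer 0/1 vector of length 2 or 3.
#' @param scheme "two-label" or "three-label".
#' @return class name, or "Others".
#' @export
decode_labels <- function(encoding, scheme = c("two-label", "three-label")) {
  scheme <- match.arg(scheme)
  tab <- encoding_table(scheme)
  if (length(encoding) != ncol(tab))
    stop("encoding length does not match scheme", call. = FALSE)
  hit <- which(apply(tab, 1L, function(r) all(r == encoding)))
  if (length(hit) == 1L) rownames(tab)[hit] else "Others"
}

#' Read an annotation table
#'
#' Annotation CSVs carry one row per (entry, chain) with ";"-separated
#' multi-valued fields: `entry_id, chain_id, ec, go, keywords,
#' description`.
#'
#' @param path CSV path.
#' @return data frame with columns `entry_id`, `chain_id`, `ec_numbers`,
#'   `go_terms`, `keywords`, `description` (multi-valued fields remain
#'   ";"-separated strings).
#' @export
read_annotations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", na.strings = NULL)
  names(df)[names(df) == "ec"] <- "ec_numbers"
  names(df)[names(df) == "go"] <- "go_terms"
  df
}

#' Assign function labels to a set of sites
#'
#' Looks up each site's axial-ligand chain(s) in the annotation table,
#' runs the cascade and the manual overrides, and encodes the label where
#' the class admits it.
#'
#' @param sites list of `heme_site` objects.
#' @param annotations annotation data frame ([read_annotations()]).
#' @param scheme encoding scheme passed to [encode_labels()].
#' @return data frame: `entry_id`, `class_name`, `functions`, `source`,
#'   `encodable` (does the class belong to the scheme's class set?).
#' @export
assign_site_functions <- function(sites, annotations,
                                  scheme = c("two-label", "three-label")) {
  scheme <- match.arg(scheme)
  tab <- encoding_table(scheme)
  rows <- lapply(sites, function(site) {
    ax_chains <- unique(site$axial$chain[site$axial$is_polymer])
    ann <- annotations[annotations$entry_id == site$entry_id &
                         annotations$chain_id %in% ax_chains, , drop = FALSE]
    ann_rec <- if (nrow(ann)) list(
      ec_numbers = paste(ann$ec_numbers, collapse = ";"),
      go_terms = paste(ann$go_terms, collapse = ";"),
      keywords = paste(ann$keywords, collapse = ";"),
      description = paste(ann$description, collapse = "; ")) else NULL
    lab <- assign_function(ann_rec, has_axial = nrow(site$axial) > 0L)
    lab <- apply_manual_overrides(lab,
                                  if (is.null(ann_rec)) "" else
                                    ann_rec$description)
    data.frame(entry_id = site$entry_id, class_name = lab$class_name,
               functions = paste(lab$functions, collapse = ";"),
               source = lab$source,
               encodable = lab$class_name %in% rownames(tab),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
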