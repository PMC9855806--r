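# Portable on-disk containers for voxel grids and cavity vectors: a flat
# 0/1 text array next to a JSON sidecar carrying the geometry, so other
# toolchains can consume them without R.

#' Write a voxel grid to a portable container
#'
#' Writes the binary values as one line of 0/1 digits (x fastest, then
#' y, z, channel) and a `<path>.json` sidecar with the dimensions, edge
#' and voxel lengths, channel order and any extra metadata.
#'
#' @param grid a grid from [voxelize_site()].
#' @param path output path for the value file.
#' @param meta optional named list merged into the sidecar (e.g.
#'   `entry_id`).
#' @return `path`, invisibly.
#' @export
write_voxel_grid <- function(grid, path, meta = list()) {
  sidecar <- c(list(dims = dim(grid), edge = attr(grid, "edge"),
                    voxel = attr(grid, "voxel"),
                    channels = dimnames(grid)[[4]]), meta)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE)
  writeLines(paste(as.integer(grid), collapse = ""), path)
  invisible(path)
}

#' Read a voxel grid written by [write_voxel_grid()]
#'
#' @param path path to the value file (sidecar expected at
#'   `<path>.json`).
#' @return the reconstructed grid with `edge`/`voxel` attributes; extra
#'   sidecar fields are attached as a `meta` attribute.
#' @export
read_voxel_grid <- function(path) {
  sidecar <- jsonlite::read_json(paste0(path, ".json"),
                                 simplifyVector = TRUE)
  vals <- as.integer(strsplit(readLines(path, n = 1L), "")[[1]])
  dims <- as.integer(sidecar$dims)
  stopifnot(length(vals) == prod(dims))
  grid <- array(vals, dim = dims,
                dimnames = list(NULL, NULL, NULL, sidecar$channels))
  extra <- sidecar[setdiff(names(sidecar),
                           c("dims", "edge", "voxel", "channels"))]
  structure(grid, edge = sidecar$edge, voxel = sidecar$voxel,
            meta = if (length(extra)) extra else NULL)
}

#' Write cavity vectors to a portable container
#'
#' One line of 0/1 digits per sample plus a JSON sidecar with the
#' lattice geometry and the sample identifiers.
#'
#' @param vectors list of `cavity_vector`s (equal length).
#' @param path output path for the value file.
#' @param ids sample identifiers (defaults to the list names or an
#'   index).
#' @return `path`, invisibly.
#' @export
write_cavity_vectors <- function(vectors, path, ids = NULL) {
  if (is.null(ids))
    ids <- if (!is.null(names(vectors))) names(vectors) else
      as.character(seq_along(vectors))
  stopifnot(length(ids) == length(vectors),
            length(unique(lengths(vectors))) == 1L)
  v1 <- vectors[[1]]
  sidecar <- list(n_points = length(v1), radius = attr(v1, "radius"),
                  spacing = attr(v1, "spacing"), ids = ids)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE)
  writeLines(vapply(vectors, function(v)
    paste(as.integer(v), collapse = ""), character(1)), path)
  invisible(path)
}

#' Read cavity vectors written by [write_cavity_vectors()]
#'
#' @param path path to the value file.
#' @return named list of `cavity_vector`s.
#' @export
read_cavity_vectors <- function(path) {
  sidecar <- jsonlite::read_json(paste0(path, ".json"),
                                 simplifyVector = TRUE)
  lines <- readLines(path)
  out <- lapply(lines, function(l) {
    v <- as.integer(strsplit(l, "")[[1]])
    structure(v, radius = sidecar$radius, spacing = sidecar$spacing,
              n_points = length(v), class = "cavity_vector")
  })
  names(out) <- sidecar$ids
  out
}
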