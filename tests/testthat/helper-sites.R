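# Shared fixtures: hand-built toy sites and brute-force oracles.

# atom data frame in the package layout from a coordinate matrix
make_atoms <- function(xyz, element = "C", atom_name = NULL,
                       residue_name = "ALA", residue_seq = NULL,
                       chain = "A", occupancy = 1, altloc = "",
                       group = "ATOM") {
  xyz <- matrix(xyz, ncol = 3L)
  n <- nrow(xyz)
  element <- rep_len(element, n)
  if (is.null(atom_name)) atom_name <- paste0(element, seq_len(n))
  if (is.null(residue_seq)) residue_seq <- seq_len(n)
  data.frame(group = rep_len(group, n), atom_name = atom_name,
             element = element, altloc = rep_len(altloc, n),
             residue_name = rep_len(residue_name, n),
             residue_seq = as.integer(rep_len(residue_seq, n)),
             chain = rep_len(chain, n), x = xyz[, 1], y = xyz[, 2],
             z = xyz[, 3], occupancy = rep_len(occupancy, n),
             model = rep_len(1L, n),
             is_polymer = rep_len(group, n) == "ATOM",
             stringsAsFactors = FALSE)
}

# toy heme site: ideal porphyrin (optionally posed) + given protein atoms
toy_site <- function(protein = make_atoms(matrix(numeric(), ncol = 3)),
                     rotation = diag(3), translation = c(0, 0, 0)) {
  heme <- make_porphyrin(rotation, translation)
  fe <- unlist(heme[heme$atom_name == "FE", c("x", "y", "z")],
               use.names = FALSE)
  structure(list(entry_id = "TOY1", compound_id = "HEM", chain = "A",
                 residue_seq = 500L, heme = heme, iron = fe,
                 protein = protein, hetero = protein[0, ]),
            class = "heme_site")
}

# brute-force voxelization oracle: per-(voxel, atom) scan, center rule
voxelize_oracle <- function(site, frame, edge, voxel) {
  n <- as.integer(edge / voxel)
  grid <- array(0L, dim = c(n, n, n, 4L),
                dimnames = list(NULL, NULL, NULL, c("C", "N", "O", "S")))
  atoms <- site$protein
  if (!nrow(atoms)) return(structure(grid, edge = edge, voxel = voxel))
  fc <- to_frame(frame, atoms)
  lows <- -edge / 2 + (seq_len(n) - 1) * voxel
  for (a in seq_len(nrow(atoms))) {
    ch <- match(atoms$element[a], c("C", "N", "O", "S"))
    if (is.na(ch)) next
    for (ix in seq_len(n)) for (iy in seq_len(n)) for (iz in seq_len(n)) {
      inside <- fc[a, 1] >= lows[ix] && fc[a, 1] < lows[ix] + voxel &&
        fc[a, 2] >= lows[iy] && fc[a, 2] < lows[iy] + voxel &&
        fc[a, 3] >= lows[iz] && fc[a, 3] < lows[iz] + voxel
      if (inside) grid[ix, iy, iz, ch] <- 1L
    }
  }
  structure(grid, edge = edge, voxel = voxel)
}

# brute-force cavity oracle: per-point nearest-atom distance test
cavity_oracle <- function(site, frame, radius = 8.5, spacing = 1,
                          radii = vdw_radii(), padding = 0,
                          default_radius = 1.8) {
  off <- cavity_lattice(radius, spacing)
  fe <- drop(to_frame(frame, matrix(site$iron, ncol = 3)))
  pts <- sweep(off, 2, fe, `+`)
  atoms <- site$protein
  if (!nrow(atoms)) return(rep(1L, nrow(pts)))
  fc <- to_frame(frame, atoms)
  rr <- unname(radii[atoms$element])
  rr[is.na(rr)] <- default_radius
  rr <- rr + padding
  vapply(seq_len(nrow(pts)), function(i) {
    d <- sqrt((fc[, 1] - pts[i, 1])^2 + (fc[, 2] - pts[i, 2])^2 +
                (fc[, 3] - pts[i, 3])^2)
    if (any(d <= rr)) 0L else 1L
  }, integer(1))
}

# brute-force per-class metric oracle from a count matrix
metrics_oracle <- function(m) {
  L <- rownames(m)
  total <- sum(m)
  out <- list()
  for (i in seq_along(L)) {
    tp <- m[i, i]
    fp <- sum(m[, i]) - tp
    fn <- sum(m[i, ]) - tp
    tn <- total - tp - fp - fn
    out[[L[i]]] <- c(accuracy = (tp + tn) / total,
                     recall = tp / (tp + fn),
                     precision = if (tp + fp == 0) NA_real_ else
                       tp / (tp + fp),
                     specificity = tn / (tn + fp))
  }
  out
}

# small deterministic random-cloud site for oracle-equivalence loops
random_toy_site <- function(seed, n_atoms = 40, spread = 10) {
  with_seed_test(seed, {
    xyz <- matrix(stats::runif(3 * n_atoms, -spread, spread),
                  ncol = 3L)
    elt <- sample(c("C", "N", "O", "S", "FE"), n_atoms, TRUE,
                  prob = c(0.4, 0.2, 0.2, 0.1, 0.1))
    rot <- random_rotation()
    tr <- stats::runif(3, -15, 15)
    site <- toy_site(make_atoms(xyz %*% t(rot) + rep(tr, each = n_atoms),
                                element = elt),
                     rotation = rot, translation = tr)
    site
  })
}

with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}
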