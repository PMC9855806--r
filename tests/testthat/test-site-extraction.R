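# Altloc/occupancy resolution, skeleton completeness, axial ligands,
# coverage and the sequence-redundancy filter.

test_that("resolve_altlocs keeps the right conformer", {
  base <- make_atoms(rbind(c(0, 0, 0), c(0.3, 0, 0)), atom_name = "CA",
                     residue_seq = 1L)
  base$altloc <- c("A", "B")

  # differing occupancies: largest wins
  a <- base; a$occupancy <- c(0.7, 0.3)
  expect_equal(resolve_altlocs(a)$altloc, "A")
  a$occupancy <- c(0.3, 0.7)
  expect_equal(resolve_altlocs(a)$altloc, "B")

  # 0.5/0.5 tie: altloc A wins regardless of input order
  b <- base; b$occupancy <- 0.5
  expect_equal(resolve_altlocs(b)$altloc, "A")
  expect_equal(resolve_altlocs(b[2:1, ])$altloc, "A")

  # equal non-0.5 tie: lexicographically smallest altloc (documented)
  d <- base; d$occupancy <- 0.4; d$altloc <- c("C", "B")
  expect_equal(resolve_altlocs(d)$altloc, "B")

  # full-occupancy records pass through unchanged
  full <- make_atoms(diag(3), atom_name = c("N", "CA", "C"))
  expect_equal(resolve_altlocs(full), full)

  # idempotence on a mixed table
  mix <- rbind(a, full)
  expect_equal(resolve_altlocs(resolve_altlocs(mix)),
               resolve_altlocs(mix))

  # only the requested model is kept
  two_models <- rbind(full, transform(full, model = 2L))
  expect_equal(nrow(resolve_altlocs(two_models, model_num = 1L)), 3L)
})

test_that("skeleton completeness requires all 25 names exactly once", {
  p <- make_porphyrin()
  expect_true(check_skeleton_complete(p))
  expect_false(check_skeleton_complete(p[p$atom_name != "CHA", ]))
  # duplicate CHB replacing CHC: still 25 rows but wrong name set
  q <- p
  q$atom_name[q$atom_name == "CHC"] <- "CHB"
  expect_false(check_skeleton_complete(q))
  # invariance under reordering and rigid motion
  expect_true(check_skeleton_complete(p[sample(25), ]))
  expect_true(check_skeleton_complete(
    make_porphyrin(random_rotation(seed = 4), c(3, 1, -2))))
})

test_that("axial-ligand search is inclusive at the cutoff", {
  at <- function(d, name, seq) {
    a <- make_atoms(c(0, 0, d), element = "N", residue_name = name,
                    residue_seq = seq)
    a$atom_name <- "NE2"
    a
  }
  site <- toy_site(rbind(at(2.1, "HIS", 1L), at(3.2, "MET", 2L),
                         at(3.1, "TYR", 3L)))
  ax <- find_axial_ligands(site, cutoff = 3.1)
  expect_setequal(ax$residue_name, c("HIS", "TYR"))   # 3.2 A excluded
  expect_equal(ax$residue_name[1], "HIS")             # ordered by distance

  # water (non-polymer) counts as a possible ligand
  w <- at(2.3, "HOH", 9L); w$group <- "HETATM"; w$is_polymer <- FALSE
  site2 <- toy_site(); site2$hetero <- w
  expect_equal(find_axial_ligands(site2)$residue_name, "HOH")

  # nothing in range -> empty
  expect_equal(nrow(find_axial_ligands(toy_site(at(5, "HIS", 1L)))), 0L)
})

test_that("heme coverage counts contacted heme atoms", {
  expect_equal(compute_heme_coverage(toy_site()), 0)

  # one protein atom within cutoff of every heme atom -> full coverage
  close <- make_atoms(c(0, 0, 1.0))
  expect_equal(compute_heme_coverage(toy_site(close), 6), 1)

  # constructed site with exactly 15 of 25 heme atoms in contact:
  # place one protein atom 0.5 A above 15 chosen skeleton atoms and use a
  # cutoff too small to reach any other heme atom
  p <- make_porphyrin()
  chosen <- p[1:15, ]
  probes <- make_atoms(cbind(chosen$x, chosen$y, chosen$z + 0.5))
  expect_equal(compute_heme_coverage(toy_site(probes), 0.6), 15 / 25)

  # monotone non-decreasing in the contact cutoff
  site <- random_toy_site(11)
  cuts <- c(1, 2, 3, 4, 6, 8)
  cov <- vapply(cuts, function(ct) compute_heme_coverage(site, ct),
                numeric(1))
  expect_true(all(diff(cov) >= 0))
})

test_that("greedy redundancy filter drops near-identical sequences", {
  s1 <- "MKVLYAAGHTWREQDNPLIK"
  expect_equal(filter_redundant_chains(c("a", "b"), c(s1, s1), 99.99), "a")

  # ~50% identity survives a 99.99% threshold
  s2 <- "MKVAYAAGHTWREQDNPLIK"   # 1 mismatch, 95% identity
  s3 <- "GGGGYAAGHTPPPPDNPGGG"
  expect_setequal(filter_redundant_chains(c("a", "c"), c(s1, s3), 99.99),
                  c("a", "c"))

  # pairwise identities {95, ~30, ~30}: threshold 25 keeps only the first
  kept <- filter_redundant_chains(c("a", "b", "c"), c(s1, s2, s3), 25)
  expect_equal(kept, "a")
  # ... and threshold 99.99 keeps a, c but drops the 95% duplicate? No:
  # 95 < 99.99, so all three survive
  expect_equal(filter_redundant_chains(c("a", "b", "c"), c(s1, s2, s3),
                                       99.99), c("a", "b", "c"))

  # output never contains a pair above the threshold (exhaustive check)
  pool <- c(s1, s2, s3, "MKVLYAAGHTWREQDNPLIV", "AAAAAAAAAAGGGGGGGGGG")
  for (thr in c(25, 60, 99.99)) {
    kept <- filter_redundant_chains(letters[1:5], pool, thr)
    seqs <- pool[match(kept, letters[1:5])]
    if (length(seqs) > 1) {
      combs <- utils::combn(length(seqs), 2)
      ids <- apply(combs, 2, function(ij)
        hemepocket:::pairwise_identity(seqs[ij[1]], seqs[ij[2]]))
      expect_true(all(ids <= thr))
    }
  }
  expect_equal(filter_redundant_chains(character(), character()),
               character())
})

test_that("mmCIF atom tables round-trip through write/read", {
  site <- generate_site("OR", seed = 5)$site
  atoms <- rbind(site$protein, site$heme)
  path <- withr::local_tempfile(fileext = ".cif")
  write_mmcif_atoms(atoms, path, entry_id = "RT01")
  back <- read_mmcif_atoms(path)
  expect_equal(nrow(back), nrow(atoms))
  expect_equal(back$atom_name, atoms$atom_name)
  expect_equal(back$element, atoms$element)
  expect_equal(back$is_polymer, atoms$is_polymer)
  expect_equal(back$x, atoms$x, tolerance = 1e-3)
  # the porphyrin nitrogen named "NA" must survive as text
  expect_true("NA" %in% back$atom_name)
})

test_that("extract_sites applies completeness, axial and coverage filters", {
  ss <- generate_site("OB", seed = 21)$site
  atoms <- rbind(ss$protein, ss$heme)
  ex <- extract_sites(atoms, entry_id = "E1")
  expect_equal(length(ex$sites), 1L)
  expect_true(ex$table$pass)
  expect_equal(ex$sites[[1]]$coverage, ss$coverage)

  # removing one skeleton atom fails the completeness filter
  ex2 <- extract_sites(atoms[atoms$atom_name != "CHD", ], entry_id = "E2")
  expect_equal(length(ex2$sites), 0L)
  expect_false(ex2$table$complete)

  # stripping the protein removes the axial ligand and zeroes coverage
  ex3 <- extract_sites(ss$heme, entry_id = "E3")
  expect_false(ex3$table$pass)
  expect_equal(ex3$table$coverage, 0)
})
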