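# The EC/GO/keyword/description cascade, the manual overrides, and the
# label encodings.

test_that("cascade follows EC, then GO, then keywords, then description", {
  # case 1: EC first digit 1 -> oxidoreductase, regardless of GO
  lab <- assign_function(list(ec_numbers = "1.11.1.7",
                              go_terms = "oxygen binding"))
  expect_equal(lab$class_name, "OR")
  expect_equal(lab$source, "ec")

  # EC digit other than 1 -> class "other" (excluded from modelling)
  expect_equal(assign_function(list(ec_numbers = "3.4.21.4"))$class_name,
               "other")
  # several ECs with mixed digits -> multi-function -> "other"
  expect_equal(assign_function(list(
    ec_numbers = c("1.11.1.7", "3.4.21.4")))$class_name, "other")

  # case 2: GO priority order, not input order
  lab <- assign_function(list(go_terms = c("electron transfer activity",
                                           "oxygen binding")))
  expect_equal(lab$functions, "oxygen-binding")
  lab <- assign_function(list(go_terms = c("transcription regulation",
                                           "electron transfer activity")))
  expect_equal(lab$functions, "electron-transfer")

  # case 3: keyword priority puts hemophore first
  lab <- assign_function(list(keywords = c("oxygen binding", "hemophore")))
  expect_equal(lab$functions, "hemophore")
  expect_equal(lab$class_name, "other")
  expect_equal(assign_function(
    list(keywords = "nitrophorin"))$functions, "NO-transport")

  # case 4: cytochrome p460 description
  lab <- assign_function(list(description = "Cytochrome P460 from N. europaea"))
  expect_equal(lab$class_name, "OR")
  expect_equal(lab$source, "description")

  # case 5: nothing matches, or no axial ligand at all
  expect_equal(assign_function(list(description = "a protein"))$class_name,
               "unclassified")
  expect_equal(assign_function(NULL)$class_name, "unclassified")
  expect_equal(assign_function(list(ec_numbers = "1.1.1.1"),
                               has_axial = FALSE)$class_name,
               "unclassified")

  # permuting annotation list order never changes the result
  ann <- list(go_terms = c("heme transport", "oxidoreductase activity",
                           "oxygen binding"))
  ref <- assign_function(ann)$functions
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1)))
    expect_equal(assign_function(list(
      go_terms = ann$go_terms[perm]))$functions, ref)
})

test_that("manual overrides create the dual-function class", {
  or_label <- assign_function(list(ec_numbers = "1.11.1.16"))
  expect_equal(apply_manual_overrides(or_label,
                                      "dehaloperoxidase B")$class_name,
               "OB-OR")
  expect_equal(apply_manual_overrides(or_label,
                                      "myoglobin H64D mutant")$class_name,
               "OB-OR")
  # myoglobin without oxidoreductase activity keeps its OB label
  ob_label <- assign_function(list(go_terms = "oxygen binding"))
  expect_equal(apply_manual_overrides(ob_label, "myoglobin")$class_name,
               "OB")
  # unrelated proteins are untouched
  expect_equal(apply_manual_overrides(or_label, "catalase")$class_name,
               "OR")
})

test_that("encodings match the printed label vectors and invert cleanly", {
  expect_equal(unname(encode_labels("OB", "two-label")), c(0L, 1L))
  expect_equal(unname(encode_labels("OR", "two-label")), c(1L, 0L))
  expect_equal(unname(encode_labels("OB-OR", "two-label")), c(1L, 1L))
  expect_equal(unname(encode_labels("OB", "three-label")), c(0L, 1L, 0L))
  expect_equal(unname(encode_labels("OR", "three-label")), c(1L, 0L, 0L))
  expect_equal(unname(encode_labels("OB-OR", "three-label")),
               c(1L, 1L, 0L))
  expect_equal(unname(encode_labels("ET", "three-label")), c(0L, 0L, 1L))
  # ET has no two-label encoding
  expect_error(encode_labels("ET", "two-label"), "encoding")

  # decode inverts encode on the defined classes
  for (cl in c("OB", "OR", "OB-OR"))
    expect_equal(decode_labels(encode_labels(cl, "two-label"),
                               "two-label"), cl)
  for (cl in c("OB", "OR", "OB-OR", "ET"))
    expect_equal(decode_labels(encode_labels(cl, "three-label"),
                               "three-label"), cl)
  # all-zero predictions decode to Others
  expect_equal(decode_labels(c(0, 0), "two-label"), "Others")
  expect_equal(decode_labels(c(0, 0, 0), "three-label"), "Others")
  # vectors matching no class also decode to Others
  expect_equal(decode_labels(c(1, 1, 1), "three-label"), "Others")
})

test_that("site labeling joins annotations through the axial chain", {
  gen <- lapply(c("OB", "OR", "ET", "OB-OR"), function(cl)
    generate_site(cl, seed = 30 + match(cl, c("OB", "OR", "ET", "OB-OR"))))
  sites <- lapply(gen, `[[`, "site")
  ann <- do.call(rbind, lapply(gen, `[[`, "annotation"))
  lab <- assign_site_functions(sites, ann, scheme = "three-label")
  expect_equal(lab$class_name, c("OB", "OR", "ET", "OB-OR"))
  expect_true(all(lab$encodable))
  # a site whose entry has no annotation row falls through to unclassified
  lab2 <- assign_site_functions(sites[1], ann[0, ], scheme = "three-label")
  expect_equal(lab2$class_name, "unclassified")
  expect_false(lab2$encodable)
})
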