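# Shortest-path fragment enumeration and the descriptor matrix.

test_that("canonical fragment strings pick the lexicographically smaller direction", {
  expect_equal(canonical_fragment(c("N", "C", "C"), c(1, 2)), "C=C-N")
  expect_equal(canonical_fragment(c("C", "C"), 1), "C-C")
  expect_equal(canonical_fragment(c("C", "O"), 2), "C=O")
  # two-letter symbols are compared as whole strings
  expect_equal(canonical_fragment(c("Cl", "C", "Br"), c(1, 1)), "Br-C-Cl")
  # tokenizer inverts the writer
  tok <- fragment_tokens("C-C-P-C=C")
  expect_equal(tok$elements, c("C", "C", "P", "C", "C"))
  expect_equal(tok$orders, c(1L, 1L, 1L, 2L))
})

test_that("small alkanes count their shortest paths", {
  expect_equal(count_fragments(parse_smiles("CC")), c("C-C" = 1L))
  expect_equal(count_fragments(parse_smiles("CCC")),
               c("C-C" = 2L, "C-C-C" = 1L))
  # single atom and empty bounds behave
  expect_equal(length(count_fragments(parse_smiles("C"))), 0L)
  expect_error(count_fragments(parse_smiles("CC"), min_atoms = 1), "min_atoms")
})

test_that("benzene yields the exact Kekule shortest-path multiset", {
  # 6 adjacent pairs split 3/3 by bond order; 6 pairs at distance 2; the 3
  # antipodal pairs each have two shortest paths of opposite alternation
  g <- parse_smiles("c1ccccc1")
  expect_equal(count_fragments(g),
               c("C-C" = 3L, "C-C=C" = 6L, "C-C=C-C" = 3L,
                 "C=C" = 3L, "C=C-C=C" = 3L))
  expect_equal(sum(count_fragments(g)), 18L)
})

test_that("enumeration agrees with the brute-force oracle on random small graphs", {
  graphs <- random_small_graphs(40, max_atoms = 8L, seed = 99)
  for (g in graphs) {
    expect_identical(count_fragments(g), oracle_fragment_counts(g),
                     info = g$id)
  }
})

test_that("a pyridine dicarboxamide ionophore matches the oracle at worked scale", {
  # N2,N2,N6,N6-tetraethylpyridine-2,6-dicarboxamide
  g <- parse_smiles("CCN(CC)C(=O)c1cccc(C(=O)N(CC)CC)n1", "TEPDC")
  got <- count_fragments(g)
  expect_identical(got, oracle_fragment_counts(g))
  # spot values derivable by hand: one carbonyl pair per arm
  expect_equal(unname(got["C=O"]), 2L)
  expect_true(got["C-N"] >= 4L)
})

test_that("emitted fragment strings are palindromically canonical and bounds are monotone", {
  graphs <- random_small_graphs(15, max_atoms = 8L, seed = 3)
  rev_frag <- function(s) {
    tok <- fragment_tokens(s)
    canonical_fragment(rev(tok$elements), rev(tok$orders))
  }
  for (g in graphs) {
    cc <- count_fragments(g, 2, 9)
    for (s in names(cc)) expect_identical(s, rev_frag(s))
    # widening the window keeps all fragments and all counts
    inner <- count_fragments(g, 3, 5)
    expect_true(all(names(inner) %in% names(cc)))
    expect_true(all(cc[names(inner)] >= inner))
  }
})

test_that("atom-only fragment strings are available as an option", {
  cc <- count_fragments(parse_smiles("C=CO"), bonds_in_string = FALSE)
  expect_equal(cc, c("C.C" = 1L, "C.C.O" = 1L, "C.O" = 1L))
})

test_that("descriptor matrices build in training and prediction modes", {
  gs <- parse_smiles(c("CC", "CCC"), ids = c("ethane", "propane"))
  m <- descriptor_matrix(gs)
  expect_equal(colnames(m), c("C-C", "C-C-C"))
  expect_equal(unname(m), matrix(c(1L, 2L, 0L, 1L), 2, 2))
  expect_equal(rownames(m), c("ethane", "propane"))

  # prediction mode: fixed vocabulary, zero-fill, unknown fragments ignored
  m2 <- descriptor_matrix(gs["ethane"], vocabulary = c("C-C-C"))
  expect_equal(unname(m2), matrix(0L, 1, 1))
  m3 <- descriptor_matrix(gs, vocabulary = c("C-C-C", "C-C"))
  expect_equal(colnames(m3), c("C-C-C", "C-C"))
  expect_equal(unname(m3[, "C-C"]), c(1L, 2L))

  expect_error(descriptor_matrix(list()), "no molecules")
})

test_that("fragment support counts rows containing a fragment", {
  gs <- parse_smiles(c("CC", "CCC"), ids = c("e", "p"))
  m <- descriptor_matrix(gs)
  expect_equal(unname(fragment_support(m, "C-C")), 2L)
  expect_equal(unname(fragment_support(m, "C-C-C")), 1L)
  expect_error(fragment_support(m, "C=O"), "unknown fragment")
})

test_that("descriptor matrices round-trip through CSV and triplet formats", {
  gs <- parse_smiles(c("CCO", "c1ccccc1", "CC(=O)C"), ids = c("a", "b", "c"))
  m <- descriptor_matrix(gs)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_descriptor_matrix(m, f1, "csv")
  expect_identical(read_descriptor_matrix(f1, "csv"), m)
  write_descriptor_matrix(m, f2, "triplet")
  m2 <- read_descriptor_matrix(f2, "triplet")
  # triplet keeps only fragments observed somewhere: same here
  expect_identical(m2[rownames(m), colnames(m)], m)
})
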