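# SMILES parsing into Kekule graphs and the dataset table formats.

test_that("simple SMILES parse to the expected hydrogen-suppressed graphs", {
  g <- parse_smiles("CC", "ethane")
  expect_s3_class(g, "molecular_graph")
  expect_equal(n_atoms(g), 2L)
  expect_equal(g$elements, c("C", "C"))
  expect_equal(nrow(g$bonds), 1L)
  expect_equal(g$bonds$order, 1L)

  g2 <- parse_smiles("C=C")
  expect_equal(g2$bonds$order, 2L)

  g3 <- parse_smiles("C#N")
  expect_equal(g3$bonds$order, 3L)
  expect_setequal(g3$elements, c("C", "N"))

  # no explicit hydrogens survive
  g4 <- parse_smiles("[H]C([H])([H])[H]")
  expect_equal(g4$elements, "C")
  expect_equal(nrow(g4$bonds), 0L)
})

test_that("aromatic rings are kekulized deterministically", {
  g <- parse_smiles("c1ccccc1", "benzene")
  expect_equal(n_atoms(g), 6L)
  expect_equal(sort(g$bonds$order), c(1L, 1L, 1L, 2L, 2L, 2L))
  # parsing is deterministic: identical graphs on repeated calls
  g2 <- parse_smiles("c1ccccc1", "benzene")
  expect_identical(g, g2)
  # pyridine keeps its nitrogen and kekulizes too
  gp <- parse_smiles("c1ccncc1")
  expect_equal(sum(gp$elements == "N"), 1L)
  expect_equal(sort(gp$bonds$order), c(1L, 1L, 1L, 2L, 2L, 2L))
})

test_that("formal charges are retained on atoms", {
  g <- parse_smiles("C[N+](C)(C)C")
  expect_equal(g$charges[g$elements == "N"], 1L)
  g2 <- parse_smiles("CC(=O)[O-]")
  expect_equal(sum(g2$charges == -1L), 1L)
})

test_that("unparseable SMILES raise an error naming the molecule id", {
  expect_error(parse_smiles("C1CC", ids = "broken_ring"), "broken_ring")
  expect_error(parse_smiles(c("CC", "xyz("), ids = c("ok", "bad1")), "bad1")
})

test_that("relabelled SMILES of one molecule give isomorphic graphs and equal fragment counts", {
  pairs <- list(
    c("CCO", "OCC"),
    c("CC(C)C", "C(C)(C)C"),
    c("c1ccccc1O", "Oc1ccccc1"),
    c("CC(=O)N(C)C", "CN(C)C(C)=O"),
    c("N#CCCl", "ClCC#N"),
    c("CCOC(=O)C", "CC(=O)OCC"))
  for (p in pairs) {
    g1 <- parse_smiles(p[1]); g2 <- parse_smiles(p[2])
    expect_true(graphs_isomorphic(g1, g2), info = paste(p, collapse = " vs "))
    expect_identical(count_fragments(g1), count_fragments(g2))
  }
})

test_that("sensitivity CSV reading enforces the schema and keeps blanks missing", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,smiles,sens_Cu,sens_Cd,sens_Pb",
               "m1,CCO,10.5,20.1,",
               "m2,CCN,,15.0,30.2"), f)
  ds <- read_sensitivity_data(f)
  expect_equal(nrow(ds), 2L)
  expect_true(is.na(ds$sens_Pb[1]))
  expect_true(is.na(ds$sens_Cu[2]))
  expect_equal(ds$sens_Cd, c(20.1, 15.0))

  # header-only file -> empty table
  writeLines("id,smiles,sens_Cd", f)
  expect_equal(nrow(read_sensitivity_data(f)), 0L)

  # duplicate ids are rejected with the offender named
  writeLines(c("id,smiles,sens_Cd", "a,CC,1", "a,CCC,2"), f)
  expect_error(read_sensitivity_data(f), "duplicate.*a")

  # missing mandatory column
  writeLines(c("name,smiles,sens_Cd", "a,CC,1"), f)
  expect_error(read_sensitivity_data(f), "id")

  # no sensitivity column at all
  writeLines(c("id,smiles", "a,CC"), f)
  expect_error(read_sensitivity_data(f), "sens_")
})

test_that("dataset CSV round-trips exactly, including missing cells", {
  ds <- data.frame(id = c("m1", "m2"), smiles = c("CCO", "c1ccccc1"),
                   sens_Cu = c(10.5, NA), sens_Cd = c(20.125, 31.5),
                   stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".csv")
  write_sensitivity_data(ds, f)
  expect_equal(read_sensitivity_data(f), ds)
})

test_that(".smi files parse into id/smiles tables", {
  f <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("# comment", "CCO ethanol", "c1ccccc1\tbenzene", "CCN"), f)
  tab <- read_smi(f)
  expect_equal(tab$smiles, c("CCO", "c1ccccc1", "CCN"))
  expect_equal(tab$id[1:2], c("ethanol", "benzene"))
})

test_that("the candidate-ionophore fixture encodes four parseable structures", {
  t1 <- table1_ionophores()
  expect_equal(nrow(t1), 4L)
  gs <- parse_smiles(t1$smiles, ids = t1$id)
  # every substance carries two phosphorus atoms (two phosphoryl arms)
  expect_true(all(vapply(gs, function(g) sum(g$elements == "P"), 0L) == 2L))
  # substances 1-3 differ only in linker length; substance 2 is reconstructed
  expect_true(t1$reconstructed[2])
  sizes <- unname(vapply(gs, n_atoms, 0L))
  expect_equal(sizes[2] - sizes[1], 1L)
  expect_equal(sizes[3] - sizes[1], 2L)
  # the printed (ambiguous) variant is reachable by parameter
  t1b <- table1_ionophores(substance2_linker = 4)
  expect_identical(t1b$smiles[1], t1b$smiles[2])
  # substance 4: piperazine linker, two ring nitrogens
  expect_equal(sum(gs[[4]]$elements == "N"), 2L)
})

test_that("molecular_graph validates its invariants", {
  expect_error(molecular_graph("C", data.frame(i = 1, j = 1, order = 1)), "self-loop")
  expect_error(molecular_graph(c("C", "C"),
                               data.frame(i = c(1, 2), j = c(2, 1), order = 1)),
               "duplicate")
  expect_error(molecular_graph(c("C", "C"), data.frame(i = 1, j = 2, order = 4)),
               "order")
  expect_error(molecular_graph(c("C", "C"), data.frame(i = 1, j = 3, order = 1)),
               "range")
})
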