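test_that("a written PDB round-trips to the same sequence and coordinates", {
  f <- withr::local_tempfile(fileext = ".pdb")
  coords <- matrix(c(0, 0, 0, 3.8, 0, 0, 7.6, 0, 0), 3, 3, byrow = TRUE)
  writeTestPDB(f, c("ALA", "CYS", "ASP"), coords)
  ch <- parseStructure(f, "A")
  expect_s4_class(ch, "ResidueChain")
  expect_equal(chainSequence(ch), "ACD")
  expect_equal(unname(caCoords(ch)), coords, tolerance = 1e-3)
  expect_equal(ch@numbering, c("1", "2", "3"))
})

test_that("residues without a C-alpha are dropped and logged", {
  f <- withr::local_tempfile(fileext = ".pdb")
  coords <- matrix(c(0, 0, 0, 3.8, 0, 0, 7.6, 0, 0), 3, 3, byrow = TRUE)
  writeTestPDB(f, c("ALA", "CYS", "ASP"), coords,
               elety = c("CA", "CB", "CA"))
  expect_message(ch <- parseStructure(f, "A"), "without C-alpha")
  expect_equal(chainSequence(ch), "AD")
  expect_equal(length(ch), 2L)
})

test_that("unknown chain, zero C-alpha and short chains are distinct errors", {
  f <- withr::local_tempfile(fileext = ".pdb")
  coords <- matrix(c(0, 0, 0, 3.8, 0, 0, 7.6, 0, 0), 3, 3, byrow = TRUE)
  writeTestPDB(f, c("ALA", "CYS", "ASP"), coords)
  expect_error(parseStructure(f, "Z"), "unknown chain")
  expect_error(parseStructure("/nonexistent/file.pdb", "A"), "not found")

  f2 <- withr::local_tempfile(fileext = ".pdb")
  writeTestPDB(f2, c("ALA", "CYS", "ASP"), coords,
               elety = c("CB", "CB", "CB"))
  expect_error(parseStructure(f2, "A"), "no C-alpha")

  f3 <- withr::local_tempfile(fileext = ".pdb")
  writeTestPDB(f3, c("ALA", "CYS", "ASP"), coords,
               elety = c("CA", "CB", "CB"))
  expect_error(suppressMessages(parseStructure(f3, "A")),
               "fewer than 2 resolved")
})

test_that("non-standard residues map to X and altlocs keep top occupancy", {
  f <- withr::local_tempfile(fileext = ".pdb")
  coords <- matrix(c(0, 0, 0, 3.8, 0, 0, 7.6, 0, 0, 7.6, 2, 0),
                   4, 3, byrow = TRUE)
  writeTestPDB(f, c("ALA", "XYZ", "CYS", "CYS"), coords,
               resno = c(1, 2, 3, 3), altloc = c("", "", "A", "B"),
               occ = c(1, 1, 0.4, 0.6))
  ch <- parseStructure(f, "A")
  expect_equal(chainSequence(ch), "AXC")
  # altloc B had occupancy 0.6 -> its coordinates win
  expect_equal(unname(caCoords(ch)[3, ]), c(7.6, 2, 0), tolerance = 1e-3)
})

test_that("mmCIF input parses to the same chain as PDB", {
  coords <- matrix(c(0, 0, 0, 3.8, 0, 0, 6, 2, 1), 3, 3, byrow = TRUE)
  fc <- withr::local_tempfile(fileext = ".cif")
  writeTestCIF(fc, c("ALA", "GLY", "TRP"), coords)
  ch <- parseStructure(fc, "A")
  expect_equal(chainSequence(ch), "AGW")
  expect_equal(unname(caCoords(ch)), coords, tolerance = 1e-3)
})

test_that("contact map uses a strict cutoff and matches the brute-force oracle", {
  ch2 <- residueChain("p", "AC",
                      matrix(c(0, 0, 0, 5, 0, 0), 2, 3, byrow = TRUE))
  expect_equal(adjacency(contactMap(ch2, 10))[1, 2], 1)
  ch3 <- residueChain("p", "AC",
                      matrix(c(0, 0, 0, 12, 0, 0), 2, 3, byrow = TRUE))
  expect_equal(adjacency(contactMap(ch3, 10))[1, 2], 0)
  # exactly at the cutoff: excluded
  ch4 <- residueChain("p", "AC",
                      matrix(c(0, 0, 0, 10, 0, 0), 2, 3, byrow = TRUE))
  expect_equal(adjacency(contactMap(ch4, 10))[1, 2], 0)
  expect_error(contactMap(ch2, -1), "positive")

  set.seed(7)
  coords <- matrix(rnorm(30 * 3, sd = 6), 30, 3)
  ch <- residueChain("p", paste(rep("A", 30), collapse = ""), coords)
  cm <- contactMap(ch, 10)
  expect_equal(adjacency(cm), oracleContacts(coords, 10))
  expect_true(all(diag(adjacency(cm)) == 0))
  expect_equal(adjacency(cm), t(adjacency(cm)))
})

test_that("contact map is invariant to rigid motion and equivariant to permutation", {
  set.seed(11)
  coords <- matrix(rnorm(20 * 3, sd = 5), 20, 3)
  ch <- residueChain("p", paste(rep("G", 20), collapse = ""), coords)
  A0 <- adjacency(contactMap(ch))
  # random rotation (QR of a gaussian matrix) + translation
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  moved <- coords %*% R + matrix(c(5, -3, 2), 20, 3, byrow = TRUE)
  chM <- residueChain("p", chainSequence(ch), moved)
  expect_equal(adjacency(contactMap(chM)), A0, tolerance = 1e-12)

  pi_ <- sample(20)
  chP <- residueChain("p", paste(strsplit(chainSequence(ch), "")[[1]][pi_],
                                 collapse = ""), coords[pi_, ])
  expect_equal(adjacency(contactMap(chP)), A0[pi_, pi_])
})

test_that("unresolved residues get no edges", {
  coords <- matrix(c(0, 0, 0, 3.8, 0, 0, 7.6, 0, 0), 3, 3, byrow = TRUE)
  ch <- residueChain("p", "ACD", coords,
                     resolvedMask = c(TRUE, FALSE, TRUE))
  A <- adjacency(contactMap(ch, 10))
  expect_true(all(A[2, ] == 0) && all(A[, 2] == 0))
  expect_equal(A[1, 3], 1)
})

test_that("edge list export contains every contact with its distance", {
  set.seed(3)
  ch <- generateChain(12, proteinId = "e")
  cm <- contactMap(ch)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeEdgeList(cm, f)
  df <- read.delim(f)
  expect_equal(nrow(df), sum(adjacency(cm)) / 2)
  d <- sqrt(sum((caCoords(ch)[df$i[1], ] - caCoords(ch)[df$j[1], ])^2))
  expect_equal(df$distance[1], d, tolerance = 1e-3)
})
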