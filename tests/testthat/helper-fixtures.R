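# programmatic fixtures: everything is built in code at test time

# write a minimal CA-only PDB file; coords is L x 3, resid are 3-letter codes
writeTestPDB <- function(path, resid, coords, chain = "A",
                         resno = seq_along(resid), insert = rep("", length(resid)),
                         altloc = rep("", length(resid)),
                         occ = rep(1, length(resid)),
                         elety = rep("CA", length(resid))) {
  lines <- vapply(seq_along(resid), function(i) {
    sprintf("ATOM  %5d  %-3s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f           C",
            i, elety[i], altloc[i], resid[i], chain, resno[i], insert[i],
            coords[i, 1], coords[i, 2], coords[i, 3], occ[i], 0)
  }, character(1))
  writeLines(c(lines, "END"), path)
  path
}

# minimal mmCIF with an atom_site loop
writeTestCIF <- function(path, resid, coords, chain = "A") {
  hdr <- c("data_test", "#", "loop_",
           "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
           "_atom_site.label_atom_id", "_atom_site.label_alt_id",
           "_atom_site.label_comp_id", "_atom_site.label_asym_id",
           "_atom_site.label_entity_id", "_atom_site.label_seq_id",
           "_atom_site.pdbx_PDB_ins_code", "_atom_site.Cartn_x",
           "_atom_site.Cartn_y", "_atom_site.Cartn_z",
           "_atom_site.occupancy", "_atom_site.B_iso_or_equiv",
           "_atom_site.pdbx_formal_charge", "_atom_site.auth_seq_id",
           "_atom_site.auth_comp_id", "_atom_site.auth_asym_id",
           "_atom_site.auth_atom_id", "_atom_site.pdbx_PDB_model_num")
  rows <- vapply(seq_along(resid), function(i) {
    sprintf("ATOM %d C CA . %s %s 1 %d ? %.3f %.3f %.3f 1.00 0.00 ? %d %s %s CA 1",
            i, resid[i], chain, i, coords[i, 1], coords[i, 2], coords[i, 3],
            i, resid[i], chain)
  }, character(1))
  writeLines(c(hdr, rows, "#"), path)
  path
}

# small random symmetric adjacency (connected-ish path + extras)
randomAdjacency <- function(L, extraProb = 0.2) {
  A <- matrix(0, L, L)
  for (i in seq_len(L - 1)) A[i, i + 1] <- A[i + 1, i] <- 1
  up <- which(upper.tri(A) & A == 0, arr.ind = TRUE)
  add <- up[stats::runif(nrow(up)) < extraProb, , drop = FALSE]
  A[add] <- 1
  A[add[, c(2, 1), drop = FALSE]] <- 1
  A
}

randomGraph <- function(L, Fdim = 5, id = "g") {
  new("ProteinGraph", proteinId = id,
      X = matrix(stats::rnorm(L * Fdim), L, Fdim),
      A = randomAdjacency(L), blocks = list(feat = Fdim))
}

tinyModel <- function(Fdim = 5, C = 3, D = 6, N = 2, K = 2, H = 2,
                      pooling = "hgt", seed = 42) {
  funPredModel(Fdim, C, hiddenDim = D, nGcnLayers = N, nSuperNodes = K,
               nHeads = H, pooling = pooling, seed = seed, quiet = TRUE)
}

# tiny ontology: two namespaces, chains and a diamond
#   MF: mfRoot <- mfMid <- mfLeaf ;  mfRoot <- mfMid2 <- mfLeaf (diamond)
#   BP: bpRoot <- bpLeaf
tinyDag <- function() {
  goDag(
    terms = c("GO:0001", "GO:0002", "GO:0003", "GO:0004", "GO:0101",
              "GO:0102"),
    parents = list(`GO:0002` = "GO:0001",
                   `GO:0003` = "GO:0001",
                   `GO:0004` = c("GO:0002", "GO:0003"),
                   `GO:0102` = "GO:0101"),
    namespace = c(`GO:0001` = "MF", `GO:0002` = "MF", `GO:0003` = "MF",
                  `GO:0004` = "MF", `GO:0101` = "BP", `GO:0102` = "BP"))
}

tinyOBOText <- function() {
  c("format-version: 1.2", "",
    "[Term]", "id: GO:0001", "name: rootA", "namespace: molecular_function",
    "",
    "[Term]", "id: GO:0002", "name: mid", "namespace: molecular_function",
    "is_a: GO:0001 ! rootA",
    "",
    "[Term]", "id: GO:0003", "name: leaf", "namespace: molecular_function",
    "is_a: GO:0002 ! mid",
    "relationship: part_of GO:0001 ! rootA",
    "",
    "[Term]", "id: GO:0900", "name: gone", "namespace: molecular_function",
    "is_obsolete: true",
    "",
    "[Typedef]", "id: part_of", "name: part of")
}
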