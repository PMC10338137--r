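#' Parse a protein structure file into a ResidueChain
#'
#' Reads a PDB or mmCIF file (dispatched on extension: `.cif`/`.mmcif` go to
#' the mmCIF reader, everything else to the PDB reader), selects one chain,
#' and extracts the C-alpha trace. Residues lacking a C-alpha atom are dropped
#' with a message; alternate conformers keep the highest-occupancy location;
#' non-standard residues map to the unknown code `"X"`. Insertion codes are
#' preserved in the author numbering used by exports.
#'
#' @param path structure file path.
#' @param chainId chain identifier to extract.
#' @param modelIndex 1-based model number for multi-model files (default 1).
#' @param proteinId identifier to store; defaults to the file base name.
#' @return A [ResidueChain-class].
#' @export
parseStructure <- function(path, chainId = "A", modelIndex = 1L,
                           proteinId = NULL) {
  if (!file.exists(path)) stop("structure file not found: ", path)
  if (is.null(proteinId))
    proteinId <- sub("\\.(pdb|ent|cif|mmcif)$", "", basename(path),
                     ignore.case = TRUE)
  ext <- tolower(tools::file_ext(path))
  pdb <- if (ext %in% c("cif", "mmcif")) {
    suppressWarnings(bio3d::read.cif(path, rm.alt = FALSE, verbose = FALSE))
  } else {
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                                     verbose = FALSE))
  }
  atoms <- pdb$atom
  if (!chainId %in% unique(atoms$chain))
    stop("unknown chain '", chainId, "' in ", basename(path))
  inChain <- atoms$chain == chainId & !is.na(atoms$resid)

  # residues present in the chain, in file order, keyed by resno+insert
  ins <- atoms$insert
  ins[is.na(ins)] <- ""
  key <- paste0(atoms$resno, ins)
  chainKeys <- unique(key[inChain])

  isCA <- inChain & atoms$elety == "CA"
  if (!any(isCA)) stop("no C-alpha atoms in chain '", chainId, "'")

  caIdx <- which(isCA)
  # altloc: keep highest occupancy per residue (ties -> first record)
  occ <- atoms$o[caIdx]
  occ[is.na(occ)] <- 1
  keep <- vapply(split(seq_along(caIdx), key[caIdx])[unique(key[caIdx])],
                 function(ii) caIdx[ii[which.max(occ[match(caIdx[ii], caIdx)])]],
                 integer(1))
  # restore file order
  keep <- keep[order(match(keep, caIdx))]

  dropped <- setdiff(chainKeys, key[keep])
  if (length(dropped))
    message(length(dropped), " residue(s) without C-alpha dropped in ",
            proteinId, "/", chainId, ": ",
            paste(utils::head(dropped, 5), collapse = ", "),
            if (length(dropped) > 5) ", ..." else "")

  nModels <- if (is.matrix(pdb$xyz)) nrow(pdb$xyz) else 1L
  if (modelIndex < 1L || modelIndex > nModels)
    stop("modelIndex ", modelIndex, " out of range (file has ",
         nModels, " model(s))")
  xyzRow <- if (is.matrix(pdb$xyz)) pdb$xyz[modelIndex, ] else pdb$xyz
  coords <- matrix(xyzRow[bio3d::atom2xyz(keep)], ncol = 3, byrow = TRUE)

  seq1 <- threeToOne(atoms$resid[keep])
  chain <- residueChain(
    proteinId = proteinId, chainId = chainId,
    sequence = paste(seq1, collapse = ""),
    coords = coords,
    numbering = paste0(atoms$resno[keep], trimws(ins[keep]))
  )
  if (sum(chain@resolvedMask) < 2L)
    stop("chain '", chainId, "' has fewer than 2 resolved residues; ",
         "no meaningful contact graph can be built")
  chain
}

# three-letter -> one-letter residue codes; anything unknown becomes "X"
threeToOne <- function(res3) {
  out <- suppressWarnings(bio3d::aa321(res3))
  out[is.na(out) | !out %in% RESIDUE_ALPHABET] <- "X"
  out
}

#' Build the C-alpha contact map of a chain
#'
#' An edge joins residues i and j (i != j) when both are resolved and their
#' C-alpha Euclidean distance is strictly less than `cutoff` (a pair at
#' exactly the cutoff is not in contact). Unresolved residues get no edges.
#'
#' @param chain a [ResidueChain-class].
#' @param cutoff contact cutoff in Angstrom (default 10).
#' @return A [ContactGraph-class].
#' @export
contactMap <- function(chain, cutoff = 10) {
  stopifnot(is(chain, "ResidueChain"))
  if (cutoff <= 0) stop("cutoff must be positive")
  if (sum(chain@resolvedMask) < 1L) stop("chain has no resolved residues")
  L <- length(chain)
  D <- as.matrix(stats::dist(chain@coords))
  unres <- !chain@resolvedMask
  D[unres, ] <- NA_real_
  D[, unres] <- NA_real_
  A <- matrix(0, L, L)
  A[!is.na(D) & D < cutoff] <- 1
  diag(A) <- 0
  new("ContactGraph", adjacency = A, cutoff = as.numeric(cutoff),
      distances = D)
}

#' Export a contact graph as an edge-list TSV
#'
#' Writes one row per undirected edge with 1-based residue indices and the
#' C-alpha distance in Angstrom.
#'
#' @param graph a [ContactGraph-class].
#' @param path output TSV path.
#' @return The path, invisibly.
#' @export
writeEdgeList <- function(graph, path) {
  stopifnot(is(graph, "ContactGraph"))
  idx <- which(upper.tri(graph@adjacency) & graph@adjacency == 1,
               arr.ind = TRUE)
  df <- data.frame(i = idx[, 1], j = idx[, 2],
                   distance = round(graph@distances[idx], 4))
  df <- df[order(df$i, df$j), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a C-alpha-only PDB file for a chain
#'
#' Used to export synthetic chains and to project per-residue scores into the
#' B-factor column for structure viewers.
#'
#' @param chain a [ResidueChain-class].
#' @param path output PDB path.
#' @param bfactor optional length-L numeric written to the B-factor column.
#' @return The path, invisibly.
#' @export
writeChainPDB <- function(chain, path, bfactor = NULL) {
  stopifnot(is(chain, "ResidueChain"))
  L <- length(chain)
  if (is.null(bfactor)) bfactor <- rep(0, L)
  stopifnot(length(bfactor) == L)
  aa1 <- strsplit(chain@sequence, "")[[1]]
  aa3 <- vapply(aa1, function(a)
    if (a == "X") "UNK" else bio3d::aa123(a), character(1))
  resno <- suppressWarnings(as.integer(sub("[A-Za-z]$", "", chain@numbering)))
  if (any(is.na(resno))) resno <- seq_len(L)
  bio3d::write.pdb(file = path, xyz = as.vector(t(chain@coords)),
                   type = rep("ATOM", L), resno = resno, resid = aa3,
                   eleno = seq_len(L), elety = rep("CA", L),
                   chain = rep(chain@chainId, L), o = rep(1, L),
                   b = round(bfactor, 2), elesy = rep("C", L))
  invisible(path)
}
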