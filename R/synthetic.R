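#' Default motif catalogue for the synthetic benchmark
#'
#' Three spatial motifs, each a triplet of one reserved residue letter that
#' must sit mutually within the stated pairwise C-alpha radius. One term is
#' driven by each motif. Reserved letters (C, H, W) are excluded from the
#' background sequence so that a label is a clean function of the planted
#' geometry; isolated decoy copies of each letter are planted separately so
#' letter content alone does not reveal a motif.
#'
#' @return list of motifs, each with `id`, `residues` (length-3 letters) and
#'   `radius` (maximum pairwise C-alpha distance in Angstrom).
#' @export
defaultMotifCatalogue <- function() {
  list(
    list(id = "M1", residues = c("C", "C", "C"), radius = 10),
    list(id = "M2", residues = c("H", "H", "H"), radius = 10),
    list(id = "M3", residues = c("W", "W", "W"), radius = 10)
  )
}

#' Synthetic corpus specification
#'
#' Defines the study conditions for the download-free benchmark: chain
#' geometry (consecutive C-alpha spacing, clash distance), the motif
#' catalogue, the label rule mapping motif sets to terms, the label-flip
#' noise, and the split proportions.
#'
#' @param nProteins number of chains to generate.
#' @param lengthRange inclusive range of chain lengths.
#' @param stepLength consecutive C-alpha spacing in Angstrom (default 3.8).
#' @param clashDistance minimum non-bonded C-alpha distance (default 3.6).
#' @param motifs motif catalogue (see [defaultMotifCatalogue()]).
#' @param labelRules named list: term id -> character vector of required
#'   motif ids; default one term per motif.
#' @param motifProb probability each motif is planted in a chain.
#' @param labelNoise per-(protein, term) label flip probability, in
#'   `[0, 0.5)`.
#' @param nDecoys isolated copies of each motif letter planted per chain.
#' @param contactCutoff contact-map cutoff used to build graphs.
#' @param split train/valid/test proportions (sum to 1).
#' @param seed integer seed.
#' @return named list of settings.
#' @export
syntheticSpec <- function(nProteins = 300, lengthRange = c(40, 60),
                          stepLength = 3.8, clashDistance = 3.6,
                          motifs = defaultMotifCatalogue(),
                          labelRules = NULL, motifProb = 0.5,
                          labelNoise = 0.05, nDecoys = 2,
                          contactCutoff = 10,
                          split = c(train = 0.8, valid = 0.1, test = 0.1),
                          seed = 1L) {
  stopifnot(stepLength > 0, clashDistance < contactCutoff,
            labelNoise >= 0, labelNoise < 0.5, length(motifs) >= 1,
            abs(sum(split) - 1) < 1e-9)
  if (is.null(labelRules)) {
    labelRules <- stats::setNames(
      lapply(motifs, function(m) m$id),
      paste0("T", seq_along(motifs)))
  }
  list(nProteins = nProteins, lengthRange = lengthRange,
       stepLength = stepLength, clashDistance = clashDistance,
       motifs = motifs, labelRules = labelRules, motifProb = motifProb,
       labelNoise = labelNoise, nDecoys = nDecoys,
       contactCutoff = contactCutoff, split = split, seed = seed)
}

#' Generate a self-avoiding random-walk chain
#'
#' Places C-alpha positions sequentially: each consecutive pair is exactly
#' `step` apart and every non-bonded pair at least `clash` apart. The walk
#' has local direction persistence (`stiffness`), mimicking backbone
#' stiffness, so 10-Angstrom contact neighbourhoods have realistic size
#' (degree roughly 6-12) instead of the dense blob an uncorrelated walk
#' produces. Residue letters are drawn uniformly from the 20 standard
#' residues. Uses the current RNG stream.
#'
#' @param length number of residues (>= 3).
#' @param step consecutive spacing in Angstrom.
#' @param clash minimum pairwise distance in Angstrom.
#' @param proteinId identifier for the chain.
#' @param alphabet letters to draw the sequence from.
#' @param stiffness direction-persistence weight in `[0, 1)`: each step
#'   direction is the normalised mix of the previous direction (weight
#'   `stiffness`) and a uniform random unit vector.
#' @param maxRetries chain-level restarts before giving up.
#' @return A [ResidueChain-class].
#' @export
generateChain <- function(length, step = 3.8, clash = 3.6,
                          proteinId = "synthetic",
                          alphabet = RESIDUE_ALPHABET[1:20],
                          stiffness = 0.7, maxRetries = 50) {
  stopifnot(length >= 3, step > 0, clash < 2 * step,
            stiffness >= 0, stiffness < 1)
  for (attempt in seq_len(maxRetries)) {
    x <- matrix(NA_real_, length, 3)
    x[1, ] <- 0
    dirPrev <- runifSphere(3)
    ok <- TRUE
    for (i in 2:length) {
      placed <- FALSE
      for (try in 1:100) {
        d <- stiffness * dirPrev + (1 - stiffness) * runifSphere(3)
        d <- d / sqrt(sum(d * d))
        cand <- x[i - 1, ] + step * d
        if (i > 2) {
          d2 <- rowSums((x[1:(i - 2), , drop = FALSE] -
                           matrix(cand, i - 2, 3, byrow = TRUE))^2)
          if (min(d2) < clash^2) next
        }
        x[i, ] <- cand; dirPrev <- d; placed <- TRUE; break
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok)
      return(residueChain(
        proteinId = proteinId,
        sequence = paste(sample(alphabet, length, replace = TRUE),
                         collapse = ""),
        coords = x))
  }
  stop("self-avoiding walk failed after ", maxRetries,
       " restarts (length ", length, ", clash ", clash, ")")
}

# distance helpers
pairDist <- function(x, i, j) sqrt(sum((x[i, ] - x[j, ])^2))

# iterative constraint relaxation: pull each motif's residues mutually
# within its target radius while keeping consecutive spacing within
# `step +/- tol` and non-bonded pairs above `clash`. Gaussian windows
# spread the pull over sequence neighbours so the chain deforms smoothly.
relaxMotifs <- function(coords, motifGroups, step, clash,
                        tol = 0.2, maxIter = 4000) {
  L <- nrow(coords)
  x <- coords
  win <- 5
  # precompute the (i, j) pairs behind dist()'s packed vector and mark
  # bonded (consecutive) pairs, which the clash constraint ignores
  jj <- rep.int(seq_len(L - 1L), times = (L - 1L):1L)
  ii <- sequence((L - 1L):1L) + jj
  bonded <- (ii - jj) == 1L
  motifPairs <- lapply(motifGroups, function(g)
    t(utils::combn(g$positions, 2)))

  satisfied <- function(x) {
    for (gi in seq_along(motifGroups)) {
      pr <- motifPairs[[gi]]
      dd <- sqrt(rowSums((x[pr[, 1], , drop = FALSE] -
                            x[pr[, 2], , drop = FALSE])^2))
      if (any(dd >= motifGroups[[gi]]$radius - 1e-6)) return(FALSE)
    }
    bond <- sqrt(rowSums((x[-1, , drop = FALSE] - x[-L, , drop = FALSE])^2))
    if (any(abs(bond - step) > tol)) return(FALSE)
    d <- as.vector(stats::dist(x))
    all(d[!bonded] >= clash - 1e-6)
  }
  for (iter in seq_len(maxIter)) {
    # motif pulls (target strictly inside the radius)
    for (gi in seq_along(motifGroups)) {
      target <- max(motifGroups[[gi]]$radius - 2, clash + 0.5)
      pr <- motifPairs[[gi]]
      for (k in seq_len(nrow(pr))) {
        p <- pr[k, 1]; q <- pr[k, 2]
        d <- pairDist(x, p, q)
        if (d <= target) next
        delta <- 0.15 * (d - target) / d * (x[q, ] - x[p, ])
        for (end in list(c(p, 1), c(q, -1))) {
          ctr <- end[1]; sgn <- end[2]
          kk <- max(1, ctr - win):min(L, ctr + win)
          w <- exp(-((kk - ctr) / 2.5)^2)
          x[kk, ] <- x[kk, ] + sgn * outer(w, delta)
        }
      }
    }
    # bond projection (Jacobi, damped)
    for (rep in 1:4) {
      v <- x[-1, , drop = FALSE] - x[-L, , drop = FALSE]
      d <- sqrt(rowSums(v * v))
      corr <- (0.5 * (d - step) / pmax(d, 1e-9)) * v
      x[-L, ] <- x[-L, ] + 0.5 * corr
      x[-1, ] <- x[-1, ] - 0.5 * corr
    }
    # clash resolution on non-bonded pairs
    d <- as.vector(stats::dist(x))
    viol <- which(d < clash & !bonded)
    for (k in viol) {
      i <- ii[k]; j <- jj[k]
      dk <- pairDist(x, i, j)
      if (dk >= clash) next
      push <- 0.55 * (clash - dk) / max(dk, 1e-9) * (x[j, ] - x[i, ])
      x[i, ] <- x[i, ] - push
      x[j, ] <- x[j, ] + push
    }
    if (iter %% 5 == 0 && satisfied(x)) return(x)
  }
  if (satisfied(x)) return(x)
  NULL
}

#' Plant a spatial motif into a chain
#'
#' Rewrites the residue letters at the requested positions and locally
#' deforms the coordinates (iterative constraint relaxation) so that all
#' motif pairs fall strictly within the motif radius — hence mutually in
#' contact — while consecutive C-alpha spacing stays within +/- 0.2 Angstrom
#' of the step length and the clash constraint is preserved. Positions must
#' be at least 10 apart in sequence, so the created contacts are long-range.
#'
#' @param chain a [ResidueChain-class].
#' @param motif one catalogue entry (`id`, `residues`, `radius`).
#' @param positions integer vector (length = motif size) of target residues,
#'   pairwise >= 10 apart in sequence.
#' @param step,clash geometry constants of the chain.
#' @return list with `chain` (modified) and `positions`.
#' @export
plantMotif <- function(chain, motif, positions, step = 3.8, clash = 3.6) {
  stopifnot(is(chain, "ResidueChain"),
            length(positions) == length(motif$residues))
  if (min(dist(positions)) < 10)
    stop("motif positions must be pairwise >= 10 apart in sequence")
  x <- relaxMotifs(chain@coords,
                   list(list(positions = positions, radius = motif$radius)),
                   step = step, clash = clash)
  if (is.null(x))
    stop("infeasible deformation: could not bring positions ",
         paste(positions, collapse = ","), " within ", motif$radius, " A")
  sq <- strsplit(chain@sequence, "")[[1]]
  sq[positions] <- motif$residues
  list(chain = residueChain(chain@proteinId, paste(sq, collapse = ""), x,
                            chainId = chain@chainId,
                            numbering = chain@numbering),
       positions = positions)
}

# choose pairwise-separated positions for all motifs of one chain
chooseMotifPositions <- function(L, motifIds, motifSize = 3,
                                 minSep = 10, crossSep = 4) {
  chosen <- list()
  taken <- integer(0)
  for (id in motifIds) {
    for (try in 1:200) {
      pos <- sort(sample.int(L, motifSize))
      if (length(pos) > 1 && min(diff(pos)) < minSep) next
      if (length(taken) && min(abs(outer(pos, taken, "-"))) < crossSep) next
      chosen[[id]] <- pos
      taken <- c(taken, pos)
      break
    }
    if (is.null(chosen[[id]])) {
      # deterministic interleaved layout: copy j of motif i sits at
      # (j-1)*(nMotifs*crossSep) + (i-1)*crossSep + 1, giving within-motif
      # spacing nMotifs*crossSep and cross-motif spacing crossSep
      nM <- length(motifIds)
      stride <- max(minSep, nM * crossSep)
      lay <- lapply(seq_along(motifIds), function(i)
        (seq_len(motifSize) - 1L) * stride + (i - 1L) * crossSep + 1L)
      if (max(unlist(lay)) > L) return(NULL)
      return(stats::setNames(lay, motifIds))
    }
  }
  chosen
}

#' Geometric motif re-detector
#'
#' Brute-force search for each catalogue motif: every combination of residues
#' carrying the motif letters with all pairwise C-alpha distances strictly
#' below the motif radius. Used to verify that planted motifs are
#' geometrically present and that decoy letters do not fake one.
#'
#' @param chain a [ResidueChain-class].
#' @param motifs motif catalogue.
#' @return named list: motif id -> matrix of detected position triplets
#'   (zero rows when absent).
#' @export
detectMotifs <- function(chain, motifs = defaultMotifCatalogue()) {
  sq <- strsplit(chain@sequence, "")[[1]]
  D <- as.matrix(stats::dist(chain@coords))
  out <- list()
  for (m in motifs) {
    cand <- lapply(m$residues, function(a) which(sq == a))
    hits <- matrix(integer(0), 0, length(m$residues))
    if (all(lengths(cand) > 0)) {
      grid <- expand.grid(cand, KEEP.OUT.ATTRS = FALSE)
      grid <- as.matrix(grid)
      keep <- apply(grid, 1, function(r) {
        r <- as.integer(r)
        if (anyDuplicated(r)) return(FALSE)
        if (is.unsorted(r)) return(FALSE)  # canonical order, one per set
        pr <- utils::combn(r, 2)
        all(D[t(pr)] < m$radius)
      })
      hits <- grid[keep, , drop = FALSE]
    }
    out[[m$id]] <- hits
  }
  out
}

# sequence assembly: background letters avoid motif letters; decoys are
# isolated copies that must not complete a geometric motif.
assembleSequence <- function(chain, spec, planted) {
  motifLetters <- unique(unlist(lapply(spec$motifs, `[[`, "residues")))
  background <- setdiff(RESIDUE_ALPHABET[1:20], motifLetters)
  L <- length(chain)
  sq <- sample(background, L, replace = TRUE)
  for (id in names(planted)) {
    m <- spec$motifs[[which(vapply(spec$motifs, `[[`, "", "id") == id)]]
    sq[planted[[id]]] <- m$residues
  }
  # decoys are *isolated* copies of the motif letters: a decoy never has a
  # same-letter residue within the contact cutoff, so letter content alone
  # does not reveal a motif while spatial clustering does
  free <- setdiff(seq_len(L), unlist(planted))
  if (spec$nDecoys > 0 && length(free)) {
    D <- as.matrix(stats::dist(chain@coords))
    for (m in spec$motifs) {
      letter <- m$residues[1]
      for (k in seq_len(spec$nDecoys)) {
        same <- which(sq == letter)
        cand <- free[vapply(free, function(p)
          !length(same) || min(D[p, same]) >= spec$contactCutoff,
          logical(1))]
        if (!length(cand)) break
        p <- if (length(cand) == 1L) cand else sample(cand, 1)
        sq[p] <- letter
        free <- setdiff(free, p)
      }
    }
  }
  sq
}

#' Generate a synthetic planted-motif corpus
#'
#' Each chain is a self-avoiding walk into which a random subset of the
#' catalogue motifs is planted (each with probability `motifProb`) by
#' constraint relaxation; labels are the deterministic motif-rule outputs
#' flipped with probability `labelNoise`; per-protein motif masks record the
#' planted residues for saliency evaluation; proteins are split
#' train/valid/test by the spec proportions.
#'
#' @param spec a [syntheticSpec()] list.
#' @return list with `chains`, `graphs` (one-hot [ProteinGraph-class]s),
#'   `labels` (n x C binary matrix, colnames = term ids), `cleanLabels`
#'   (pre-noise), `masks` (per protein, per term logical residue masks),
#'   `split` (factor train/valid/test), `spec`.
#' @export
generateDataset <- function(spec = syntheticSpec()) {
  if (!length(spec$motifs)) stop("empty motif catalogue")
  set.seed(spec$seed)
  n <- spec$nProteins
  terms <- names(spec$labelRules)
  motifIds <- vapply(spec$motifs, `[[`, "", "id")
  chains <- vector("list", n)
  masks <- vector("list", n)
  clean <- matrix(0L, n, length(terms), dimnames = list(NULL, terms))
  plantedList <- vector("list", n)
  ids <- sprintf("SYN%04d", seq_len(n))

  for (i in seq_len(n)) {
    present <- motifIds[stats::runif(length(motifIds)) < spec$motifProb]
    done <- FALSE
    for (attempt in 1:20) {
      L <- sample(spec$lengthRange[1]:spec$lengthRange[2], 1)
      ch <- tryCatch(
        generateChain(L, spec$stepLength, spec$clashDistance,
                      proteinId = ids[i]),
        error = function(e) NULL)
      if (is.null(ch)) next
      planted <- list()
      if (length(present)) {
        pos <- chooseMotifPositions(L, present)
        if (is.null(pos)) next
        groups <- lapply(present, function(id) {
          m <- spec$motifs[[which(motifIds == id)]]
          list(positions = pos[[id]], radius = m$radius)
        })
        x <- relaxMotifs(ch@coords, groups, spec$stepLength,
                         spec$clashDistance)
        if (is.null(x)) next
        ch <- residueChain(ids[i], ch@sequence, x)
        planted <- pos
      }
      sq <- assembleSequence(ch, spec, planted)
      ch <- residueChain(ids[i], paste(sq, collapse = ""), ch@coords)
      chains[[i]] <- ch
      plantedList[[i]] <- planted
      done <- TRUE
      break
    }
    if (!done)
      stop("could not generate protein ", ids[i],
           " after 20 attempts (motifs: ",
           paste(present, collapse = ","), ")")
    # labels from the motif rule
    clean[i, ] <- vapply(terms, function(tt)
      as.integer(all(spec$labelRules[[tt]] %in% names(plantedList[[i]]))),
      integer(1))
    # per-term residue masks (union of required motifs' planted positions)
    masks[[i]] <- lapply(stats::setNames(terms, terms), function(tt) {
      req <- spec$labelRules[[tt]]
      mk <- rep(FALSE, length(chains[[i]]))
      mk[unlist(plantedList[[i]][intersect(req, names(plantedList[[i]]))])] <- TRUE
      mk
    })
  }

  flips <- matrix(stats::runif(n * length(terms)) < spec$labelNoise,
                  n, length(terms))
  labels <- ifelse(flips, 1L - clean, clean)
  dimnames(labels) <- dimnames(clean)
  rownames(labels) <- rownames(clean) <- ids
  names(chains) <- names(masks) <- ids

  graphs <- lapply(chains, buildProteinGraph, cutoff = spec$contactCutoff)

  sizes <- floor(spec$split * n)
  sizes[1] <- n - sum(sizes[-1])
  splitVec <- factor(rep(names(spec$split), times = sizes),
                     levels = names(spec$split))
  splitVec <- splitVec[sample.int(n)]
  names(splitVec) <- ids

  list(chains = chains, graphs = graphs, labels = labels,
       cleanLabels = clean, masks = masks, split = splitVec,
       planted = plantedList, spec = spec)
}

#' Write a synthetic corpus to disk
#'
#' Emits one C-alpha PDB per chain, an annotation TSV (protein_id, term_id,
#' namespace), a motif-mask TSV (protein_id, term_id, residue_number), a
#' split table, and a JSON manifest recording every generation parameter.
#'
#' @param ds a [generateDataset()] result.
#' @param outDir output directory (created if needed).
#' @return `outDir`, invisibly.
#' @export
writeDataset <- function(ds, outDir) {
  dir.create(file.path(outDir, "structures"), recursive = TRUE,
             showWarnings = FALSE)
  for (id in names(ds$chains))
    writeChainPDB(ds$chains[[id]],
                  file.path(outDir, "structures", paste0(id, ".pdb")))
  ann <- which(ds$labels == 1, arr.ind = TRUE)
  annDf <- data.frame(protein_id = rownames(ds$labels)[ann[, 1]],
                      term_id = colnames(ds$labels)[ann[, 2]],
                      namespace = "MF")
  annDf <- annDf[order(annDf$protein_id, annDf$term_id), ]
  utils::write.table(annDf, file.path(outDir, "annotations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  maskRows <- list()
  for (id in names(ds$masks))
    for (tt in names(ds$masks[[id]])) {
      w <- which(ds$masks[[id]][[tt]])
      if (length(w))
        maskRows[[paste(id, tt)]] <-
          data.frame(protein_id = id, term_id = tt, residue_number = w)
    }
  maskDf <- do.call(rbind, maskRows) %||%
    data.frame(protein_id = character(0), term_id = character(0),
               residue_number = integer(0))
  utils::write.table(maskDf, file.path(outDir, "motif_masks.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(protein_id = names(ds$split), split = as.character(ds$split)),
    file.path(outDir, "split.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  manifest <- ds$spec
  manifest$motifs <- lapply(manifest$motifs, function(m)
    list(id = m$id, residues = paste(m$residues, collapse = ""),
         radius = m$radius))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(outDir)
}
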