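OBO_NAMESPACES <- c(molecular_function = "MF", biological_process = "BP",
                    cellular_component = "CC")

#' Construct a GO DAG from explicit term/parent tables
#'
#' @param terms character vector of term ids.
#' @param parents named list mapping term id to parent term ids (terms with
#'   no entry are roots).
#' @param namespace named character mapping term id to "MF"/"BP"/"CC";
#'   a single unnamed value recycles over all terms.
#' @return A [GODag-class].
#' @export
goDag <- function(terms, parents = list(), namespace = "MF") {
  if (length(namespace) == 1L && is.null(names(namespace)))
    namespace <- stats::setNames(rep(namespace, length(terms)), terms)
  parents <- parents[names(parents) %in% terms]
  dag <- new("GODag", terms = terms, parents = parents,
             namespace = namespace)
  assertAcyclic(dag)
  dag
}

assertAcyclic <- function(dag) {
  # Kahn-style peeling; leftover nodes imply a cycle
  remaining <- dag@terms
  repeat {
    np <- vapply(remaining, function(t) {
      p <- intersect(dag@parents[[t]] %||% character(0), remaining)
      length(p)
    }, integer(1))
    if (!length(remaining)) return(invisible(TRUE))
    if (all(np > 0)) stop("ontology graph contains a cycle")
    remaining <- remaining[np > 0]
    if (!length(remaining)) return(invisible(TRUE))
  }
}

#' Read a Gene Ontology graph from an OBO file
#'
#' Minimal reader for the OBO flat-file format covering what annotation
#' propagation needs: `[Term]` stanzas with `id`, `name`, `namespace`,
#' `is_a` and `relationship: part_of` links; obsolete terms are skipped.
#' Both `is_a` and `part_of` count as parent edges (configurable).
#'
#' @param path OBO file path.
#' @param relations parent relations to traverse.
#' @return A [GODag-class].
#' @export
readOBO <- function(path, relations = c("is_a", "part_of")) {
  if (!file.exists(path)) stop("OBO file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  termStarts <- which(lines == "[Term]")
  if (!length(termStarts)) stop("no [Term] stanzas in ", path)
  blockEnds <- c(which(grepl("^\\[", lines)), length(lines) + 1L)
  terms <- character(0); parents <- list(); namespace <- character(0)
  for (s in termStarts) {
    e <- min(blockEnds[blockEnds > s]) - 1L
    block <- lines[(s + 1L):e]
    getv <- function(key) sub(paste0("^", key, ":\\s*"), "",
                              grep(paste0("^", key, ":"), block, value = TRUE))
    if (length(getv("is_obsolete")) && any(getv("is_obsolete") == "true"))
      next
    id <- getv("id")[1]
    if (is.na(id) || !length(id)) next
    ns <- getv("namespace")[1]
    pa <- character(0)
    if ("is_a" %in% relations)
      pa <- c(pa, sub("\\s*!.*$", "", getv("is_a")))
    if ("part_of" %in% relations) {
      rel <- getv("relationship")
      po <- rel[grepl("^part_of ", rel)]
      pa <- c(pa, sub("\\s*!.*$", "", sub("^part_of\\s+", "", po)))
    }
    terms <- c(terms, id)
    if (length(pa)) parents[[id]] <- unique(pa)
    namespace[id] <- OBO_NAMESPACES[ns] %||% NA_character_
    if (is.na(namespace[id])) namespace[id] <- "MF"
  }
  # drop parent links pointing outside the parsed universe
  parents <- lapply(parents, function(p) intersect(p, terms))
  parents <- parents[lengths(parents) > 0]
  goDag(terms, parents, namespace)
}

#' Ancestral closure of a term set
#'
#' Returns the input terms plus all their ancestors reachable through the
#' DAG's parent links, restricted to each term's own namespace (the CAFA
#' propagation convention).
#'
#' @param terms character vector of term ids, all present in `dag`.
#' @param dag a [GODag-class].
#' @return sorted character vector (idempotent: propagating a propagated set
#'   changes nothing).
#' @export
propagateTerms <- function(terms, dag) {
  stopifnot(is(dag, "GODag"))
  unknown <- setdiff(terms, dag@terms)
  if (length(unknown))
    stop("unknown term(s): ", paste(utils::head(unknown, 5), collapse = ", "))
  out <- character(0)
  for (t in terms) {
    ns <- dag@namespace[[t]]
    frontier <- t
    seen <- character(0)
    while (length(frontier)) {
      seen <- union(seen, frontier)
      nxt <- unique(unlist(dag@parents[frontier], use.names = FALSE))
      nxt <- nxt[!is.na(dag@namespace[nxt]) & dag@namespace[nxt] == ns]
      frontier <- setdiff(nxt, seen)
    }
    out <- union(out, seen)
  }
  sort(out)
}

#' Root terms of a DAG
#'
#' Terms with no parents (per namespace these are the ontology roots).
#'
#' @param dag a [GODag-class].
#' @return character vector of root term ids.
#' @export
rootTerms <- function(dag) {
  stopifnot(is(dag, "GODag"))
  dag@terms[!dag@terms %in% names(dag@parents)[lengths(dag@parents) > 0]]
}

#' Information content of GO terms
#'
#' \eqn{IC = -\log_2(\mathrm{count}/n)} in bits: the rarer (more specific) a
#' term is in the reference set, the higher its information content. Terms
#' with zero count have undefined IC; they are excluded with a warning and
#' later dropped from semantic-distance sums.
#'
#' @param termCounts named numeric of per-term annotation counts.
#' @param nProteins number of proteins in the reference set.
#' @return named numeric of IC values (zero-count terms absent).
#' @export
informationContent <- function(termCounts, nProteins) {
  if (nProteins <= 0) stop("nProteins must be positive")
  if (any(termCounts > nProteins)) stop("counts cannot exceed nProteins")
  zero <- termCounts <= 0
  if (any(zero))
    warning(sum(zero), " zero-count term(s) excluded from IC")
  tc <- termCounts[!zero]
  -log2(tc / nProteins)
}

#' Build an AnnotationStore from protein-to-term assignments
#'
#' Optionally ancestor-propagates every protein's term set over a DAG, then
#' derives per-term counts and information content from the stored proteins
#' (or from a supplied reference count table).
#'
#' @param assignments named list: protein id -> character vector of terms.
#' @param dag optional [GODag-class] used to propagate assignments.
#' @param referenceCounts optional named counts (e.g. from a training set) to
#'   use for IC instead of counting `assignments`.
#' @param nProteins reference-set size for IC; defaults to
#'   `length(assignments)`.
#' @return An [AnnotationStore-class].
#' @export
annotationStore <- function(assignments, dag = NULL, referenceCounts = NULL,
                            nProteins = length(assignments)) {
  if (!is.null(dag))
    assignments <- lapply(assignments, propagateTerms, dag = dag)
  counts <- if (is.null(referenceCounts)) {
    tab <- table(unlist(assignments, use.names = FALSE))
    stats::setNames(as.numeric(tab), names(tab))
  } else referenceCounts
  ic <- suppressWarnings(informationContent(counts, nProteins))
  new("AnnotationStore", assignments = assignments, termCounts = counts,
      ic = ic, nProteins = as.numeric(nProteins))
}

#' Read protein annotations
#'
#' `readAnnotationsTSV` reads a headerless (or headered) tab-separated table
#' with columns protein_id, term_id and optionally namespace. `readGAF`
#' accepts GAF 2.x files read-only, using the DB object id (column 2), GO id
#' (column 5) and aspect (column 9); `!` comment lines are skipped. Malformed
#' rows are dropped with a message.
#'
#' @param path input file.
#' @return named list: protein id -> character vector of term ids.
#' @export
readAnnotationsTSV <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, fill = TRUE,
                          quote = "", comment.char = "#")
  if (identical(tolower(df[1, 1]), "protein_id")) df <- df[-1, , drop = FALSE]
  bad <- is.na(df[[1]]) | is.na(df[[2]]) | df[[1]] == "" | df[[2]] == ""
  if (any(bad)) {
    message(sum(bad), " malformed annotation row(s) skipped")
    df <- df[!bad, , drop = FALSE]
  }
  if (!nrow(df)) stop("no usable annotation rows in ", path)
  split(df[[2]], df[[1]])
}

#' @rdname readAnnotationsTSV
#' @export
readGAF <- function(path) {
  if (!file.exists(path)) stop("GAF file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "!") & nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ok <- lengths(parts) >= 9
  if (any(!ok)) message(sum(!ok), " malformed GAF row(s) skipped")
  parts <- parts[ok]
  prot <- vapply(parts, `[[`, character(1), 2L)
  term <- vapply(parts, `[[`, character(1), 5L)
  split(term, prot)
}
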