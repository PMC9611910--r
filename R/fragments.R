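# Substructure molecular fragments: shortest atom/bond paths written as
# canonical alternating atom/bond strings, and the molecule x fragment
# count matrix built from them.

.bond_symbol <- c("-", "=", "#")

#' Canonical fragment string for an atom/bond path
#'
#' A fragment is written as alternating element and bond symbols
#' (`-` single, `=` double, `#` triple), e.g. `"C-C=C"`. The canonical form
#' is the byte-wise lexicographically smaller of the string and its reversal
#' (reversal swaps the atom sequence end-for-end together with the bonds).
#'
#' @param elements character vector of element symbols along the path.
#' @param orders integer bond orders between consecutive atoms
#'   (`length(elements) - 1` of them).
#' @return canonical fragment string.
#' @examples
#' canonical_fragment(c("N", "C", "C"), c(1, 2))  # "C=C-N"
#' @export
canonical_fragment <- function(elements, orders) {
  k <- length(elements)
  if (length(orders) != k - 1L) stop("canonical_fragment: need one bond per atom pair")
  b <- .bond_symbol[orders]
  fwd <- paste0(elements, c(b, ""), collapse = "")
  rev_ <- paste0(rev(elements), c(rev(b), ""), collapse = "")
  # radix sort compares bytes in C locale, independent of the session locale
  sort(c(fwd, rev_), method = "radix")[1]
}

#' Split a fragment string into element and bond tokens
#'
#' Inverse of the fragment writing convention: element symbols are an upper
#' case letter optionally followed by one lower case letter; bond symbols are
#' `-`, `=`, `#`.
#'
#' @param fragment a fragment string such as `"C-C=N"`.
#' @return list with `elements` (character) and `orders` (integer).
#' @export
fragment_tokens <- function(fragment) {
  toks <- regmatches(fragment,
                     gregexpr("[A-Z][a-z]?|[-=#]", fragment))[[1]]
  if (paste0(toks, collapse = "") != fragment) {
    stop(sprintf("fragment_tokens: cannot tokenize '%s'", fragment))
  }
  is_bond <- toks %in% .bond_symbol
  list(elements = toks[!is_bond],
       orders = match(toks[is_bond], .bond_symbol))
}

#' Enumerate substructure molecular fragments of a molecule
#'
#' Counts every shortest atom/bond path of `min_atoms` to `max_atoms` atoms in
#' a molecular graph. For each unordered atom pair whose graph distance (in
#' bonds) lies in `[min_atoms - 1, max_atoms - 1]`, every distinct shortest
#' path between the pair contributes one occurrence of its canonical fragment
#' string; pairs connected by several equal-length shortest paths (e.g. the
#' antipodal atoms of a six-ring) therefore contribute once per path, which
#' keeps counts invariant under atom relabelling. Implicit hydrogens are never
#' path atoms and formal charges are not printed in fragment symbols.
#'
#' @param g a `molecular_graph`.
#' @param min_atoms,max_atoms fragment length bounds in atoms (defaults 2 and 9).
#' @param bonds_in_string if `FALSE`, fragments are written as atom sequences
#'   only (no bond symbols); the default embeds bond symbols.
#' @return named integer vector: canonical fragment string -> occurrence count,
#'   in lexicographic (byte) order. Empty for a single-atom molecule.
#' @examples
#' count_fragments(parse_smiles("CCC"))   # propane: C-C x2, C-C-C x1
#' @export
count_fragments <- function(g, min_atoms = 2L, max_atoms = 9L,
                            bonds_in_string = TRUE) {
  stopifnot(inherits(g, "molecular_graph"))
  min_atoms <- as.integer(min_atoms); max_atoms <- as.integer(max_atoms)
  if (min_atoms < 2L || min_atoms > max_atoms) {
    stop("count_fragments: need 2 <= min_atoms <= max_atoms")
  }
  n <- n_atoms(g)
  empty <- stats::setNames(integer(0), character(0))
  if (n < 2L || nrow(g$bonds) == 0L) return(empty)

  ig <- .as_igraph(g)
  # bond-order lookup keyed on "i:j" with i < j
  key <- paste(g$bonds$i, g$bonds$j, sep = ":")
  order_of <- stats::setNames(g$bonds$order, key)
  d <- igraph::distances(ig)

  acc <- vector("list", n - 1L)
  for (u in seq_len(n - 1L)) {
    reach <- which(d[u, ] >= min_atoms - 1L & d[u, ] <= max_atoms - 1L)
    reach <- reach[reach > u]
    if (length(reach) == 0L) next
    paths <- igraph::all_shortest_paths(ig, from = u, to = reach)$res
    acc[[u]] <- vapply(paths, function(p) {
      v <- as.integer(p)
      k <- length(v)
      if (k < min_atoms || k > max_atoms) return(NA_character_)
      a <- v[-k]; b <- v[-1L]
      orders <- unname(order_of[paste(pmin(a, b), pmax(a, b), sep = ":")])
      if (bonds_in_string) {
        canonical_fragment(g$elements[v], orders)
      } else {
        s1 <- paste(g$elements[v], collapse = ".")
        s2 <- paste(rev(g$elements[v]), collapse = ".")
        sort(c(s1, s2), method = "radix")[1]
      }
    }, "")
  }
  frags <- unlist(acc, use.names = FALSE)
  frags <- frags[!is.na(frags)]
  if (length(frags) == 0L) return(empty)
  tab <- table(frags)
  out <- stats::setNames(as.integer(tab), names(tab))
  out[sort(names(out), method = "radix")]
}

#' Build a molecule x fragment descriptor matrix
#'
#' In training mode (no `vocabulary`) the columns are the union of all
#' fragments found across the molecules, in lexicographic byte order. In
#' prediction mode a fixed `vocabulary` defines the columns: fragments of a
#' molecule outside the vocabulary are ignored and vocabulary fragments absent
#' from a molecule count zero, so rows always conform to an existing model.
#'
#' @param graphs a `molecular_graph` or list of them (names become row ids).
#' @param vocabulary optional character vector of canonical fragment strings.
#' @param min_atoms,max_atoms,bonds_in_string passed to [count_fragments()].
#' @return integer matrix with molecule ids as row names and canonical
#'   fragment strings as column names.
#' @examples
#' gs <- parse_smiles(c("CC", "CCC"), ids = c("ethane", "propane"))
#' descriptor_matrix(gs)
#' @export
descriptor_matrix <- function(graphs, vocabulary = NULL,
                              min_atoms = 2L, max_atoms = 9L,
                              bonds_in_string = TRUE) {
  if (inherits(graphs, "molecular_graph")) graphs <- list(graphs)
  if (length(graphs) == 0L) stop("descriptor_matrix: no molecules given")
  counts <- lapply(graphs, count_fragments, min_atoms = min_atoms,
                   max_atoms = max_atoms, bonds_in_string = bonds_in_string)
  ids <- names(graphs)
  if (is.null(ids)) ids <- vapply(graphs, function(g) g$id, "")
  ids[!nzchar(ids)] <- paste0("mol", which(!nzchar(ids)))
  if (anyDuplicated(ids)) stop("descriptor_matrix: duplicate molecule ids")
  if (is.null(vocabulary)) {
    vocabulary <- sort(unique(unlist(lapply(counts, names), use.names = FALSE)),
                       method = "radix")
  } else {
    vocabulary <- as.character(vocabulary)
    if (anyDuplicated(vocabulary)) stop("descriptor_matrix: duplicate vocabulary entries")
  }
  m <- matrix(0L, nrow = length(counts), ncol = length(vocabulary),
              dimnames = list(ids, vocabulary))
  for (r in seq_along(counts)) {
    cc <- counts[[r]]
    hit <- intersect(names(cc), vocabulary)
    if (length(hit)) m[r, hit] <- cc[hit]
  }
  m
}

#' Number of molecules containing a fragment
#'
#' The support of a fragment is the number of rows of a descriptor matrix
#' with a positive count for it — the basis of the "present in at least five
#' structures" filter used in importance reporting.
#'
#' @param m descriptor matrix from [descriptor_matrix()].
#' @param fragment canonical fragment string(s); must be matrix columns.
#' @return integer vector of supports, named by fragment.
#' @export
fragment_support <- function(m, fragment) {
  missing <- setdiff(fragment, colnames(m))
  if (length(missing)) {
    stop("fragment_support: unknown fragment(s): ", paste(missing, collapse = ", "))
  }
  vapply(fragment, function(f) sum(m[, f] > 0L), integer(1))
}

#' Write / read a descriptor matrix
#'
#' `write_descriptor_matrix` stores the matrix as CSV (first column `id`,
#' remaining columns the canonical fragment strings) or as a sparse triplet
#' TSV with columns `id`, `fragment`, `count`. `read_descriptor_matrix`
#' reverses either format.
#'
#' @param m descriptor matrix.
#' @param path file path.
#' @param format `"csv"` (dense) or `"triplet"` (sparse TSV).
#' @return `write_descriptor_matrix` returns `path` invisibly;
#'   `read_descriptor_matrix` returns the integer matrix.
#' @export
write_descriptor_matrix <- function(m, path, format = c("csv", "triplet")) {
  format <- match.arg(format)
  if (format == "csv") {
    df <- data.frame(id = rownames(m), m, check.names = FALSE)
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    idx <- which(m > 0L, arr.ind = TRUE)
    df <- data.frame(id = rownames(m)[idx[, 1]],
                     fragment = colnames(m)[idx[, 2]],
                     count = m[idx])
    df <- df[order(df$id, df$fragment, method = "radix"), ]
    utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' @rdname write_descriptor_matrix
#' @export
read_descriptor_matrix <- function(path, format = c("csv", "triplet")) {
  format <- match.arg(format)
  if (format == "csv") {
    df <- utils::read.csv(path, check.names = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(m) <- "integer"
    rownames(m) <- df$id
    return(m)
  }
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("character", "character", "integer"))
  ids <- unique(df$id)
  vocab <- sort(unique(df$fragment), method = "radix")
  m <- matrix(0L, length(ids), length(vocab), dimnames = list(ids, vocab))
  m[cbind(match(df$id, ids), match(df$fragment, vocab))] <- df$count
  m
}
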