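# Hydrogen-suppressed Kekule molecular graphs.

#' Construct a molecular graph
#'
#' A `molecular_graph` is the hydrogen-suppressed, Kekule-form labelled graph
#' used throughout the package: atoms carry an element symbol and a formal
#' charge, bonds carry an integer order (1 = single, 2 = double, 3 = triple).
#' Aromatic bonds never appear; aromatic input is resolved to a Kekule
#' structure at parse time. Atom indices are 1-based and contiguous.
#'
#' @param elements character vector of element symbols, one per heavy atom.
#' @param bonds data frame (or matrix) with columns `i`, `j`, `order`;
#'   `i`/`j` are 1-based atom indices. May have zero rows.
#' @param charges integer vector of formal charges (default all 0).
#' @param id molecule identifier string.
#' @return an object of class `molecular_graph`.
#' @examples
#' g <- molecular_graph(c("C", "C"), data.frame(i = 1, j = 2, order = 1), id = "ethane")
#' g
#' @export
molecular_graph <- function(elements, bonds, charges = integer(length(elements)),
                            id = "") {
  elements <- as.character(elements)
  n <- length(elements)
  if (n == 0L) stop("molecular_graph: at least one atom is required")
  charges <- as.integer(charges)
  if (length(charges) != n) stop("molecular_graph: charges length must match atoms")
  bonds <- as.data.frame(bonds)
  if (nrow(bonds) == 0L) {
    bonds <- data.frame(i = integer(0), j = integer(0), order = integer(0))
  } else {
    if (!all(c("i", "j", "order") %in% names(bonds))) {
      stop("molecular_graph: bonds need columns i, j, order")
    }
    bonds <- data.frame(i = as.integer(bonds$i), j = as.integer(bonds$j),
                        order = as.integer(bonds$order))
    # store each bond with i < j; reject self-loops and duplicates
    flip <- bonds$i > bonds$j
    tmp <- bonds$i[flip]; bonds$i[flip] <- bonds$j[flip]; bonds$j[flip] <- tmp
    if (any(bonds$i == bonds$j)) stop("molecular_graph: self-loop bond")
    if (any(bonds$i < 1L | bonds$j > n)) stop("molecular_graph: bond index out of range")
    if (anyDuplicated(bonds[, c("i", "j")])) stop("molecular_graph: duplicate bond")
    if (!all(bonds$order %in% 1:3)) {
      stop("molecular_graph: bond orders must be 1, 2 or 3 (Kekule form)")
    }
  }
  structure(list(id = as.character(id), elements = elements, charges = charges,
                 bonds = bonds),
            class = "molecular_graph")
}

#' @export
print.molecular_graph <- function(x, ...) {
  cat(sprintf("<molecular_graph '%s': %d atoms, %d bonds>\n",
              x$id, n_atoms(x), nrow(x$bonds)))
  comp <- table(x$elements)
  cat("  composition:", paste(names(comp), comp, sep = ":", collapse = " "), "\n")
  invisible(x)
}

#' Number of heavy atoms in a molecular graph
#' @param g a `molecular_graph`.
#' @return integer atom count.
#' @export
n_atoms <- function(g) length(g$elements)

# MOL-file charge codes (field after the element symbol).
.mol_charge <- c(`0` = 0L, `1` = 3L, `2` = 2L, `3` = 1L, `4` = 0L,
                 `5` = -1L, `6` = -2L, `7` = -3L)

# One SDFset compound -> molecular_graph
.sdf_to_graph <- function(sdf, id) {
  ab <- ChemmineR::atomblock(sdf)
  elements <- sub("_.*$", "", rownames(ab))
  charges <- integer(length(elements))
  if ("C6" %in% colnames(ab)) {
    code <- as.character(as.integer(ab[, "C6"]))
    code[!code %in% names(.mol_charge)] <- "0"
    charges <- unname(.mol_charge[code])
  }
  bb <- ChemmineR::bondblock(sdf)
  if (is.null(dim(bb)) || nrow(bb) == 0L) {
    bonds <- data.frame(i = integer(0), j = integer(0), order = integer(0))
  } else {
    bonds <- data.frame(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
                        order = as.integer(bb[, 3]))
  }
  keep <- !elements %in% c("H", "D", "T")
  if (!all(keep)) { # explicit hydrogens in the input are suppressed
    idx <- cumsum(keep)
    bonds <- bonds[keep[bonds$i] & keep[bonds$j], , drop = FALSE]
    bonds$i <- idx[bonds$i]; bonds$j <- idx[bonds$j]
    elements <- elements[keep]; charges <- charges[keep]
  }
  if (any(bonds$order > 3L)) {
    stop(sprintf("parse_smiles: molecule '%s' retained a non-Kekule bond order", id))
  }
  molecular_graph(elements, bonds, charges, id = id)
}

#' Parse SMILES strings into molecular graphs
#'
#' Converts SMILES to hydrogen-suppressed molecular graphs in Kekule form via
#' OpenBabel (through \pkg{ChemmineR}). Aromatic perception happens at parse
#' time only, producing a deterministic Kekule assignment: the same SMILES
#' string always yields the same atom ordering and bond orders. Explicit
#' hydrogens, if present in the input, are removed.
#'
#' @param smiles character vector of SMILES strings.
#' @param ids molecule identifiers (defaults to `mol1`, `mol2`, ...).
#' @return a single `molecular_graph` if `length(smiles) == 1`, otherwise a
#'   named list of them.
#' @examples
#' parse_smiles("CC")              # ethane: 2 atoms, 1 single bond
#' parse_smiles("c1ccccc1")        # benzene, kekulized: 3 single + 3 double
#' @export
parse_smiles <- function(smiles, ids = NULL) {
  smiles <- as.character(smiles)
  if (length(smiles) == 0L) return(list())
  if (is.null(ids)) ids <- paste0("mol", seq_along(smiles))
  ids <- as.character(ids)
  if (length(ids) != length(smiles)) stop("parse_smiles: ids/smiles length mismatch")
  # single-atom molecules come straight from the SMILES token (the SDF route
  # degenerates for bond-less molecules)
  single <- regmatches(smiles, regexec(
    "^\\[?([A-Z][a-z]?)(?:H[0-9]*)?([+-][0-9]?)?\\]?$", smiles))
  if (all(lengths(single) == 3L)) {
    out <- lapply(seq_along(smiles), function(k) {
      chg <- switch(single[[k]][3], "+" = 1L, "-" = -1L,
                    "+2" = 2L, "-2" = -2L, 0L)
      molecular_graph(single[[k]][2],
                      data.frame(i = integer(0), j = integer(0),
                                 order = integer(0)),
                      charges = chg, id = ids[k])
    })
    names(out) <- ids
    return(if (length(out) == 1L) out[[1]] else out)
  }
  if (any(lengths(single) == 3L)) {
    # mixed batch: recurse element-wise
    out <- lapply(seq_along(smiles), function(k) parse_smiles(smiles[k], ids[k]))
    names(out) <- ids
    return(out)
  }
  sdfs <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(stats::setNames(smiles, ids))),
    error = function(e) NULL)
  if (is.null(sdfs) || length(sdfs) != length(smiles)) {
    # batch conversion failed: parse one by one to name the offender
    out <- vector("list", length(smiles))
    for (k in seq_along(smiles)) {
      one <- tryCatch(suppressWarnings(ChemmineR::smiles2sdf(smiles[k])),
                      error = function(e) NULL)
      if (is.null(one) || length(one) != 1L ||
          nrow(ChemmineR::atomblock(one[[1]])) == 0L) {
        stop(sprintf("parse_smiles: unparseable SMILES for id '%s': %s",
                     ids[k], smiles[k]), call. = FALSE)
      }
      out[[k]] <- .sdf_to_graph(one[[1]], ids[k])
    }
  } else {
    out <- lapply(seq_along(smiles), function(k) .sdf_to_graph(sdfs[[k]], ids[k]))
  }
  names(out) <- ids
  if (length(out) == 1L) out[[1]] else out
}

# igraph view of a molecular graph (edges keep the bond order attribute)
.as_igraph <- function(g) {
  ig <- igraph::make_empty_graph(n = n_atoms(g), directed = FALSE)
  if (nrow(g$bonds) > 0L) {
    ig <- igraph::add_edges(ig, rbind(g$bonds$i, g$bonds$j),
                            attr = list(order = g$bonds$order))
  }
  ig
}

#' Test whether two molecular graphs are the same molecule
#'
#' Graph isomorphism respecting element symbols, formal charges and bond
#' orders (VF2). Used to verify that different SMILES writings of one molecule
#' parse to the same structure.
#'
#' @param g1,g2 `molecular_graph` objects.
#' @return logical.
#' @export
graphs_isomorphic <- function(g1, g2) {
  if (n_atoms(g1) != n_atoms(g2) || nrow(g1$bonds) != nrow(g2$bonds)) return(FALSE)
  lab <- function(g) paste(g$elements, g$charges)
  levs <- union(lab(g1), lab(g2))
  igraph::isomorphic(.as_igraph(g1), .as_igraph(g2), method = "vf2",
                     vertex.color1 = match(lab(g1), levs),
                     vertex.color2 = match(lab(g2), levs),
                     edge.color1 = g1$bonds$order,
                     edge.color2 = g2$bonds$order)
}
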