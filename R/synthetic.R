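# Seeded generator of random valence-legal small molecules plus a planted
# fragment-additive sensitivity, for end-to-end simulation studies.

.valence <- c(C = 4L, N = 3L, O = 2L, P = 5L, S = 2L)

#' Specification for a synthetic QSPR dataset
#'
#' Describes a population of random acyclic-or-monocyclic molecules over a
#' small-element alphabet and a planted linear structure-property law:
#' `y = baseline + sum_f w_f * count_f + Normal(0, noise_sd^2)`, where the
#' active fragments `f` are drawn from fragments actually present in at
#' least 10% of the generated molecules and are mutually decorrelated so the
#' law is identifiable. Defaults emulate a corpus of small fragment-like
#' molecules — 3-7 heavy atoms, mostly carbon with N/O/P/S heteroatoms —
#' whose fragment vocabulary across 100 molecules is a couple of hundred
#' descriptors, with a baseline of 20 mV/decade, fragment weights of 1-4
#' mV/decade per occurrence in either direction, and 1 mV/decade of
#' measurement noise. At that vocabulary-to-sample ratio a planted sparse
#' law is recoverable by cross-validated PLS; much larger molecules bury the
#' five active columns among thousands of autoscaled nuisance fragments and
#' no regression method recovers them from 100 samples.
#'
#' @param n_molecules number of molecules.
#' @param alphabet named probability vector over elements C, N, O, P, S.
#' @param size_range molecule size bounds in heavy atoms (within 2-100).
#' @param branch_prob probability a new atom attaches to a random eligible
#'   atom rather than continuing the current chain.
#' @param double_prob probability a new bond is a double bond (valence
#'   permitting).
#' @param ring_prob probability of closing one ring per molecule.
#' @param n_active number of planted active fragments.
#' @param weight_range magnitude range of active-fragment weights
#'   (mV/decade per count); signs are random.
#' @param baseline intercept of the planted law (mV/decade).
#' @param noise_sd Gaussian noise standard deviation (mV/decade).
#' @param seed integer seed; every random choice flows from it.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_molecules = 100L,
                           alphabet = c(C = 0.75, N = 0.10, O = 0.10,
                                        P = 0.03, S = 0.02),
                           size_range = c(3L, 7L),
                           branch_prob = 0.25, double_prob = 0.10,
                           ring_prob = 0.30,
                           n_active = 5L, weight_range = c(1, 4),
                           baseline = 20, noise_sd = 1, seed = 1L) {
  if (is.null(names(alphabet)) || !all(names(alphabet) %in% names(.valence))) {
    stop("synthetic_spec: alphabet elements must be among ",
         paste(names(.valence), collapse = ", "))
  }
  probs <- c(branch_prob, double_prob, ring_prob)
  if (any(probs < 0 | probs > 1)) stop("synthetic_spec: probabilities must be in [0,1]")
  if (noise_sd < 0) stop("synthetic_spec: noise_sd must be >= 0")
  size_range <- as.integer(size_range)
  if (length(size_range) != 2L || size_range[1] < 2L || size_range[2] > 100L ||
      size_range[1] > size_range[2]) {
    stop("synthetic_spec: size_range must lie within [2, 100]")
  }
  structure(list(n_molecules = as.integer(n_molecules),
                 alphabet = alphabet / sum(alphabet),
                 size_range = size_range,
                 branch_prob = branch_prob, double_prob = double_prob,
                 ring_prob = ring_prob, n_active = as.integer(n_active),
                 weight_range = as.numeric(weight_range),
                 baseline = baseline, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# grow one random molecule; returns molecular_graph or NULL if stuck
.grow_molecule <- function(spec, id) {
  n <- if (spec$size_range[1] == spec$size_range[2]) spec$size_range[1] else
    sample(spec$size_range[1]:spec$size_range[2], 1L)
  elements <- sample(names(spec$alphabet), n, replace = TRUE,
                     prob = spec$alphabet)
  free <- unname(.valence[elements])
  bonds <- matrix(0L, n, 3L, dimnames = list(NULL, c("i", "j", "order")))
  for (k in seq_len(n)[-1]) {
    eligible <- which(free[seq_len(k - 1L)] >= 1L)
    if (length(eligible) == 0L) return(NULL)
    parent <- if (stats::runif(1) < spec$branch_prob || !((k - 1L) %in% eligible)) {
      if (length(eligible) == 1L) eligible else sample(eligible, 1L)
    } else k - 1L
    ord <- 1L
    if (stats::runif(1) < spec$double_prob &&
        free[parent] >= 2L && free[k] >= 2L) ord <- 2L
    bonds[k - 1L, ] <- c(parent, k, ord)
    free[parent] <- free[parent] - ord
    free[k] <- free[k] - ord
  }
  nb <- n - 1L
  if (n >= 4L && stats::runif(1) < spec$ring_prob) {
    bm <- bonds[seq_len(nb), , drop = FALSE]
    adj <- matrix(FALSE, n, n)
    adj[bm[, 1:2]] <- TRUE
    adj[bm[, 2:1]] <- TRUE
    g0 <- molecular_graph(elements, as.data.frame(bm), id = id)
    d <- igraph::distances(.as_igraph(g0))
    cand <- which(upper.tri(d) & d >= 2 & d <= 5, arr.ind = TRUE)
    ok <- cand[free[cand[, 1]] >= 1L & free[cand[, 2]] >= 1L &
                 !adj[cand], , drop = FALSE]
    if (nrow(ok) > 0L) {
      pick <- ok[sample(nrow(ok), 1L), ]
      bonds[n, ] <- c(pick[1], pick[2], 1L)  # row n is unused by the tree
      nb <- n
    }
  }
  molecular_graph(elements, as.data.frame(bonds[seq_len(nb), , drop = FALSE]),
                  id = id)
}

# SMILES writer for the generated graphs (single/double bonds, any number of
# ring closures, neutral atoms with organic-subset symbols)
.graph_to_smiles <- function(g) {
  n <- n_atoms(g)
  if (n == 1L) return(g$elements[1])
  nb <- vector("list", n)
  for (r in seq_len(nrow(g$bonds))) {
    i <- g$bonds$i[r]; j <- g$bonds$j[r]; o <- g$bonds$order[r]
    nb[[i]] <- rbind(nb[[i]], c(j, o)); nb[[j]] <- rbind(nb[[j]], c(i, o))
  }
  visited <- logical(n)
  used <- new.env(parent = emptyenv())        # edges already placed
  tree_children <- vector("list", n)
  closures <- vector("list", n)               # per atom: rows (digit, order)
  n_closures <- 0L
  ekey <- function(a, b) paste(min(a, b), max(a, b))
  dfs <- function(u) {
    visited[u] <<- TRUE
    for (r in seq_len(NROW(nb[[u]]))) {
      v <- nb[[u]][r, 1]; o <- nb[[u]][r, 2]
      k <- ekey(u, v)
      if (!is.null(used[[k]])) next
      used[[k]] <- TRUE
      if (!visited[v]) {
        tree_children[[u]] <<- rbind(tree_children[[u]], c(v, o))
        dfs(v)
      } else {                                # back edge -> ring closure
        n_closures <<- n_closures + 1L
        closures[[u]] <<- rbind(closures[[u]], c(n_closures, o))
        closures[[v]] <<- rbind(closures[[v]], c(n_closures, o))
      }
    }
  }
  dfs(1L)
  bsym <- c("", "=", "#")
  digit <- function(d) if (d <= 9L) as.character(d) else sprintf("%%%02d", d)
  emit <- function(u) {
    s <- g$elements[u]
    cl <- closures[[u]]
    if (!is.null(cl)) {
      for (r in seq_len(nrow(cl))) {
        s <- paste0(s, bsym[cl[r, 2]], digit(cl[r, 1]))
      }
    }
    kids <- tree_children[[u]]
    if (!is.null(kids)) {
      for (r in seq_len(nrow(kids))) {
        branch <- paste0(bsym[kids[r, 2]], emit(kids[r, 1]))
        s <- paste0(s, if (r < nrow(kids)) paste0("(", branch, ")") else branch)
      }
    }
    s
  }
  emit(1L)
}

#' Generate random valence-legal molecules
#'
#' Molecules are grown as random trees over the spec's element alphabet —
#' each new atom bonds to an atom with free valence, continuing a chain or
#' branching — with an optional single ring closure. Bond orders never exceed
#' the element's valence (C 4, N 3, O 2, P 5, S 2, counting bond orders), the
#' graph is connected and hydrogen-suppressed, and a SMILES string is written
#' for every molecule. Fully reproducible from `spec$seed`.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `graphs` (named list of `molecular_graph`) and `smiles`
#'   (named character vector); names are `syn001`, `syn002`, ...
#' @export
generate_molecules <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  ids <- sprintf("syn%03d", seq_len(spec$n_molecules))
  graphs <- vector("list", spec$n_molecules)
  for (k in seq_len(spec$n_molecules)) {
    g <- NULL
    for (try in 1:50) {
      g <- .grow_molecule(spec, ids[k])
      if (!is.null(g)) break
    }
    if (is.null(g)) {
      stop("generate_molecules: could not grow a valence-legal molecule; ",
           "the spec appears unsatisfiable")
    }
    graphs[[k]] <- g
  }
  names(graphs) <- ids
  smiles <- vapply(graphs, .graph_to_smiles, "")
  list(graphs = graphs, smiles = smiles)
}

#' Plant a fragment-additive property on a set of molecules
#'
#' Chooses `spec$n_active` active fragments among those present in at least
#' 10% of the molecules, assigns each a weight drawn from
#' `weight_range` with a random sign, and emits
#' `y_i = baseline + sum_f w_f count_f(i) + Normal(0, noise_sd^2)`.
#' The ground truth is returned so recovery tests never re-derive it.
#'
#' @param graphs named list of `molecular_graph` objects.
#' @param spec a [synthetic_spec()].
#' @param seed seed for fragment choice, weights and noise (default
#'   `spec$seed + 1`, keeping all randomness a function of the one spec seed).
#' @return list with `y` (named numeric), `active` (data frame
#'   fragment/weight), `baseline`, `noise_sd`, and `counts` (the molecule x
#'   active-fragment count matrix used).
#' @export
plant_property <- function(graphs, spec, seed = spec$seed + 1L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  X <- descriptor_matrix(graphs)
  n <- nrow(X)
  support <- colSums(X > 0L)
  eligible <- colnames(X)[support >= ceiling(0.10 * n)]
  if (length(eligible) < spec$n_active) {
    stop(sprintf(
      "plant_property: only %d fragments occur in >= 10%% of molecules; cannot plant %d",
      length(eligible), spec$n_active))
  }
  set.seed(seed)
  # Sample actives with bounded mutual count correlation so the planted law
  # is identifiable: with near-collinear actives (e.g. nested fragments) the
  # attribution of weights between them is arbitrary and "recovery" would be
  # ill-defined regardless of the model.
  pool <- sample(eligible)
  active <- character(0)
  if (spec$n_active > 0L) {
    # greedy under a correlation cap, relaxing the cap only if the pool is
    # too entangled to supply enough distinct fragments
    for (cap in c(0.5, 0.6, 0.7, 0.8)) {
      active <- pool[1]
      for (f in pool[-1]) {
        if (length(active) == spec$n_active) break
        r <- suppressWarnings(stats::cor(X[, f], X[, active]))
        if (all(is.na(r) | abs(r) <= cap)) active <- c(active, f)
      }
      if (length(active) == spec$n_active) break
    }
    if (length(active) < spec$n_active) {
      stop(sprintf(
        "plant_property: could not find %d mutually distinct active fragments",
        spec$n_active))
    }
  }
  w <- stats::runif(spec$n_active, spec$weight_range[1], spec$weight_range[2]) *
    sample(c(-1, 1), spec$n_active, replace = TRUE)
  counts <- X[, active, drop = FALSE]
  signal <- if (spec$n_active > 0L) as.numeric(counts %*% w) else numeric(n)
  y <- spec$baseline + signal + stats::rnorm(n, 0, spec$noise_sd)
  list(y = stats::setNames(y, rownames(X)),
       active = data.frame(fragment = active, weight = w,
                           stringsAsFactors = FALSE),
       baseline = spec$baseline, noise_sd = spec$noise_sd, counts = counts)
}

#' Apply an existing planted law to new molecules
#'
#' Evaluates the ground truth returned by [plant_property()] — same active
#' fragments, weights and baseline — on a fresh set of molecules, adding new
#' Gaussian noise. This is how held-out test responses are produced in
#' recovery studies: the law is fixed, only the molecules and the noise draw
#' change.
#'
#' @param graphs named list of `molecular_graph` objects.
#' @param truth a [plant_property()] result (or any list with `active`,
#'   `baseline`, `noise_sd`).
#' @param noise_sd noise level; defaults to the truth's.
#' @param seed seed for the noise draw.
#' @return named numeric vector of responses.
#' @export
planted_response <- function(graphs, truth, noise_sd = truth$noise_sd, seed = 1L) {
  counts <- descriptor_matrix(graphs, vocabulary = truth$active$fragment)
  set.seed(seed)
  y <- truth$baseline + as.numeric(counts %*% truth$active$weight) +
    stats::rnorm(nrow(counts), 0, noise_sd)
  stats::setNames(y, rownames(counts))
}

#' Generate a complete synthetic training dataset
#'
#' Convenience wrapper: [generate_molecules()] then [plant_property()],
#' assembled into the standard dataset table (`id`, `smiles`,
#' `sens_<label>`). Optionally writes the table as CSV and the ground truth
#' as JSON next to it.
#'
#' @param spec a [synthetic_spec()].
#' @param label response label; the sensitivity column is `sens_<label>`.
#' @param path optional CSV output path; the ground truth is then written to
#'   `<path without .csv>_truth.json`.
#' @return list with `data` (the dataset table), `graphs`, and `truth`
#'   (the [plant_property()] result).
#' @export
synthetic_dataset <- function(spec, label = "synthetic", path = NULL) {
  mols <- generate_molecules(spec)
  truth <- plant_property(mols$graphs, spec)
  data <- data.frame(id = names(mols$smiles), smiles = unname(mols$smiles),
                     stringsAsFactors = FALSE)
  data[[paste0("sens_", label)]] <- unname(truth$y)
  if (!is.null(path)) {
    write_sensitivity_data(data, path)
    truth_path <- paste0(sub("\\.csv$", "", path), "_truth.json")
    jsonlite::write_json(list(active = truth$active,
                              baseline = truth$baseline,
                              noise_sd = truth$noise_sd,
                              seed = spec$seed),
                         truth_path, auto_unbox = TRUE, digits = NA)
  }
  list(data = data, graphs = mols$graphs, truth = truth)
}
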