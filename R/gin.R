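#' Construct a molecular (sub)structure graph
#'
#' Nodes are atoms with feature vectors, edges are undirected bonds. The
#' graph must be simple: no self-loops, no duplicate edges. If `features` is
#' not given it is built as one-hot atom type (over `n_atom_types`) plus the
#' node degree as a final scalar column.
#'
#' @param n_nodes number of atoms (>= 1).
#' @param edges two-column integer matrix of undirected bonds (may have zero
#'   rows).
#' @param features optional `n_nodes x F` numeric matrix.
#' @param atom_type optional integer vector (1..`n_atom_types`) used to build
#'   default features.
#' @param n_atom_types number of atom types for the one-hot block.
#' @return object of class `molecule_graph` with a precomputed dense
#'   adjacency matrix.
#' @export
new_molecule_graph <- function(n_nodes, edges, features = NULL,
                               atom_type = NULL, n_atom_types = NULL) {
  n_nodes <- as.integer(n_nodes)
  stopifnot(n_nodes >= 1L)
  if (is.null(edges) || length(edges) == 0L)
    edges <- matrix(integer(0), 0, 2)
  edges <- matrix(as.integer(edges), ncol = 2)
  if (nrow(edges)) {
    if (any(edges < 1L | edges > n_nodes))
      stop("edge references a node outside 1..", n_nodes)
    if (any(edges[, 1] == edges[, 2])) stop("self-loops are not allowed")
    key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    if (anyDuplicated(key)) stop("duplicate edges are not allowed")
  }
  adj <- matrix(0, n_nodes, n_nodes)
  if (nrow(edges)) {
    adj[edges] <- 1
    adj[edges[, c(2, 1), drop = FALSE]] <- 1
  }
  if (is.null(features)) {
    if (is.null(atom_type) || is.null(n_atom_types))
      stop("either features or atom_type + n_atom_types must be given")
    atom_type <- as.integer(atom_type)
    stopifnot(length(atom_type) == n_nodes,
              all(atom_type >= 1L & atom_type <= n_atom_types))
    features <- matrix(0, n_nodes, n_atom_types + 1L)
    features[cbind(seq_len(n_nodes), atom_type)] <- 1
    features[, n_atom_types + 1L] <- rowSums(adj)
  }
  features <- as_rows(features)
  if (nrow(features) != n_nodes)
    stop("feature rows (", nrow(features), ") do not match n_nodes (", n_nodes, ")")
  structure(list(n_nodes = n_nodes, edges = edges, adj = adj,
                 features = features, atom_type = atom_type),
            class = "molecule_graph")
}

#' Check that a graph is connected (breadth-first traversal)
#' @param graph a `molecule_graph`.
#' @return logical scalar.
#' @export
is_connected_graph <- function(graph) {
  n <- graph$n_nodes
  if (n == 1L) return(TRUE)
  seen <- logical(n)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    nb <- which(graph$adj[v, ] > 0 & !seen)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  all(seen)
}

#' Initialise three-layer GIN parameters
#'
#' Each layer owns a learnable scalar `eps` and a two-linear-layer MLP with
#' ReLU between (widths `feature_dim -> dim -> dim` for layer 1, then
#' `dim -> dim -> dim`).
#'
#' @param feature_dim node feature width of the input graphs.
#' @param dim output embedding width (equal to the model width so the
#'   substructure table can act directly as a CA-MHSA query).
#' @return list of 3 layer parameter lists.
#' @export
init_gin_params <- function(feature_dim, dim) {
  make_layer <- function(d_in) list(W1 = glorot(d_in, dim), b1 = numeric(dim),
                                    W2 = glorot(dim, dim), b2 = numeric(dim),
                                    eps = 0)
  list(make_layer(feature_dim), make_layer(dim), make_layer(dim))
}

#' One GIN propagation layer
#'
#' For each node v: `MLP((1 + eps) * b_v + sum over neighbours u of b_u)`,
#' where the MLP is linear-ReLU-linear.
#'
#' @param graph a `molecule_graph`.
#' @param features `n_nodes x d_in` matrix of current node states.
#' @param layer one layer from [init_gin_params()].
#' @return `n_nodes x dim` matrix of new node states.
#' @export
gin_layer <- function(graph, features, layer)
  gin_layer_fwd(graph, features, layer)$out

gin_layer_fwd <- function(graph, features, layer) {
  features <- as_rows(features)
  if (nrow(features) != graph$n_nodes)
    stop("gin_layer: feature rows do not match graph nodes")
  if (ncol(features) != nrow(layer$W1))
    stop("gin_layer: feature width ", ncol(features),
         " does not match MLP input width ", nrow(layer$W1))
  agg <- (1 + layer$eps) * features + graph$adj %*% features
  A1 <- sweep(agg %*% layer$W1, 2L, layer$b1, `+`)
  R <- A1 * (A1 > 0)
  out <- sweep(R %*% layer$W2, 2L, layer$b2, `+`)
  list(out = out, cache = list(X = features, agg = agg, A1 = A1, R = R,
                               adj = graph$adj, eps = layer$eps))
}

gin_layer_bwd <- function(dY, cache, layer) {
  dR <- dY %*% t(layer$W2)
  dW2 <- t(cache$R) %*% dY
  db2 <- colSums(dY)
  dA1 <- dR * (cache$A1 > 0)
  dW1 <- t(cache$agg) %*% dA1
  db1 <- colSums(dA1)
  dagg <- dA1 %*% t(layer$W1)
  dX <- (1 + cache$eps) * dagg + cache$adj %*% dagg
  deps <- sum(dagg * cache$X)
  list(dX = dX,
       grads = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2, eps = deps))
}

#' Encode one substructure graph to a vector
#'
#' Applies the three GIN layers and global mean-pooling over the final node
#' states. Permutation-invariant in the node order.
#'
#' @param graph a `molecule_graph` with at least one node.
#' @param params from [init_gin_params()].
#' @return numeric vector of length `dim`.
#' @export
encode_substructure <- function(graph, params)
  encode_substructure_fwd(graph, params)$out

encode_substructure_fwd <- function(graph, params) {
  if (graph$n_nodes < 1L) stop("encode_substructure: empty graph")
  X <- graph$features
  caches <- vector("list", length(params))
  for (k in seq_along(params)) {
    f <- gin_layer_fwd(graph, X, params[[k]])
    caches[[k]] <- f$cache
    X <- f$out
  }
  list(out = colMeans(X), cache = list(layers = caches, n = graph$n_nodes))
}

encode_substructure_bwd <- function(d_pool, cache, params) {
  dX <- matrix(d_pool / cache$n, cache$n, length(d_pool), byrow = TRUE)
  grads <- vector("list", length(params))
  for (k in rev(seq_along(params))) {
    b <- gin_layer_bwd(dX, cache$layers[[k]], params[[k]])
    grads[[k]] <- b$grads
    dX <- b$dX
  }
  grads
}

#' Build the substructure table E_drug
#'
#' Encodes every distinct fragment referenced by at least one medication
#' (shared fragments are encoded once) and stacks the embeddings into a
#' matrix, rows ordered by fragment id.
#'
#' @param library a `fragment_library`.
#' @param params GIN parameters.
#' @return object of class `substructure_table`: `matrix` (S x dim),
#'   `fragment_ids`, and `drug_rows` mapping each medication to its row
#'   indices.
#' @export
build_substructure_table <- function(library, params) {
  f <- substructure_table_fwd(library, params)
  f$table
}

substructure_table_fwd <- function(library, params) {
  ids <- sort(unique(unlist(library$drug_fragments, use.names = FALSE)))
  if (length(ids) == 0L) stop("fragment library references no fragments")
  dim_out <- ncol(params[[1]]$W2)
  E <- matrix(0, length(ids), dim_out)
  caches <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    f <- encode_substructure_fwd(library$pool[[ids[i]]], params)
    E[i, ] <- f$out
    caches[[i]] <- f$cache
  }
  row_of <- stats::setNames(seq_along(ids), ids)
  drug_rows <- lapply(library$drug_fragments, function(v)
    unname(row_of[as.character(v)]))
  table <- structure(list(matrix = E, fragment_ids = ids,
                          drug_rows = drug_rows),
                     class = "substructure_table")
  list(table = table, caches = caches)
}

substructure_table_bwd <- function(dE, caches, params) {
  grads <- grad_zero_like(params)
  for (i in seq_along(caches)) {
    gi <- encode_substructure_bwd(dE[i, ], caches[[i]], params)
    grads <- grad_add(grads, gi)
  }
  grads
}

#' BRICS decomposition of a molecule via the RDKit backend
#'
#' Breaks a molecule into chemically meaningful fragments using the BRICS
#' bond-breaking rules and returns the deduplicated canonical fragment
#' SMILES, sorted. A molecule with no BRICS-cleavable bond returns its own
#' canonical SMILES. Requires a `python` interpreter with RDKit on the path;
#' without one, an explicit capability error points at the synthetic
#' fragment-library path instead.
#'
#' @param smiles a single SMILES string.
#' @param python path to the python executable.
#' @return character vector of canonical fragment SMILES.
#' @export
brics_decompose <- function(smiles, python = Sys.which("python")) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  if (!nzchar(python))
    stop("chemistry backend unavailable: no python interpreter found; ",
         "use the synthetic fragment library instead (generate_fragment_library)")
  script <- paste(
    "import sys",
    "try:",
    "    from rdkit import Chem",
    "    from rdkit.Chem import BRICS",
    "except Exception:",
    "    sys.stderr.write('NO_RDKIT'); sys.exit(3)",
    "smi = sys.argv[1]",
    "mol = Chem.MolFromSmiles(smi)",
    "if mol is None:",
    "    sys.stderr.write('BAD_SMILES'); sys.exit(4)",
    "frags = sorted(set(BRICS.BRICSDecompose(mol)))",
    "if not frags:",
    "    frags = [Chem.MolToSmiles(mol)]",
    "print('\\n'.join(Chem.CanonSmiles(f) for f in frags))",
    sep = "\n")
  out <- suppressWarnings(system2(python, c("-c", shQuote(script), shQuote(smiles)),
                                  stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status") %||% 0L
  if (status == 3L)
    stop("chemistry backend unavailable: RDKit not importable from ", python,
         "; use the synthetic fragment library instead (generate_fragment_library)")
  if (status == 4L)
    stop("unparsable SMILES: ", smiles)
  if (status != 0L)
    stop("BRICS decomposition failed for ", smiles, ": ",
         paste(out, collapse = " "))
  sort(unique(out[nzchar(out)]))
}
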