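#' Fisher-z connectivity matrix for tumor-as-node graphs
#'
#' Builds the (P+1) x (P+1) weight matrix over one seed node plus the
#' cortical parcels: pairwise Pearson correlations, Fisher z-transformed
#' with |r| capped just below 1. Rows for missing parcels stay `NA`.
#'
#' @param seed_series numeric series for the seed node.
#' @param parcel_mat parcels x T matrix (rows may be `NA`).
#' @return Symmetric numeric matrix, node 1 = seed, nodes 2..P+1 =
#'   parcels; diagonal 0.
#' @export
fc_matrix <- function(seed_series, parcel_mat) {
  x <- rbind(seed = seed_series, parcel_mat)
  usable <- rowSums(is.na(x)) == 0
  n <- nrow(x)
  r <- matrix(NA_real_, n, n)
  r[usable, usable] <- suppressWarnings(cor(t(x[usable, , drop = FALSE])))
  cap <- 1 - 1e-15
  z <- atanh(pmin(pmax(r, -cap), cap))
  diag(z) <- 0
  z
}

#' Binary graph at a sparsity threshold
#'
#' Retains the K = round(sparsity * N(N-1)/2) node pairs with the largest
#' signed Fisher-z weights as unweighted edges (strong positive coupling
#' first; `ranking = "absolute"` ranks |z| instead). Ties are broken by
#' lexicographic node-pair order; `NA` weights are never selected.
#'
#' @param z_matrix symmetric weight matrix (`NA` allowed off-diagonal).
#' @param sparsity retained-edge proportion in (0, 1).
#' @param ranking `"signed"` (default) or `"absolute"`.
#' @return Object of class `functional_graph`: list with `adjacency`
#'   (binary symmetric), `sparsity`, `weights`, `n_nodes`.
#' @export
build_graph <- function(z_matrix, sparsity, ranking = c("signed", "absolute")) {
  ranking <- match.arg(ranking)
  n <- nrow(z_matrix)
  stopifnot(n == ncol(z_matrix), sparsity > 0, sparsity < 1)
  k <- round(sparsity * n * (n - 1) / 2)
  if (k < 1) stop("sparsity too low: no edge retained")
  ut <- which(upper.tri(z_matrix), arr.ind = TRUE)
  w <- z_matrix[ut]
  if (ranking == "absolute") w <- abs(w)
  w[is.na(w)] <- -Inf
  ord <- order(-w, ut[, 1], ut[, 2])
  keep <- ord[seq_len(min(k, sum(is.finite(w))))]
  adj <- matrix(0L, n, n)
  adj[ut[keep, , drop = FALSE]] <- 1L
  adj <- adj + t(adj)
  structure(list(adjacency = adj, sparsity = sparsity, weights = z_matrix,
                 n_nodes = n),
            class = "functional_graph")
}

#' @export
print.functional_graph <- function(x, ...) {
  cat("functional_graph:", x$n_nodes, "nodes,", sum(x$adjacency) / 2,
      "edges (sparsity", x$sparsity, ")\n")
  invisible(x)
}

as_igraph <- function(graph) {
  igraph::graph_from_adjacency_matrix(graph$adjacency, mode = "undirected")
}

#' Does the graph contain isolated nodes?
#'
#' @param graph a `functional_graph`.
#' @return `TRUE` iff some node has degree 0.
#' @export
has_isolates <- function(graph) {
  any(rowSums(graph$adjacency) == 0)
}

#' Nodal topology metrics
#'
#' Degree centrality (degree / (N-1)), normalized shortest-path
#' betweenness, Wasserman–Faust component-scaled closeness (the reachable
#' count n scales the classic closeness by n / (N-1), so nodes of small
#' components are penalized), and the local clustering coefficient
#' (triangles over possible neighbor pairs; 0 for degree < 2). The seed
#' node and parcel nodes run through the same path.
#'
#' @param graph a `functional_graph`.
#' @param nodes integer node indices (default: all).
#' @return Tibble: node, degree_centrality, betweenness_centrality,
#'   closeness_centrality, clustering_coefficient.
#' @export
nodal_metrics <- function(graph, nodes = seq_len(graph$n_nodes)) {
  stopifnot(all(nodes >= 1), all(nodes <= graph$n_nodes))
  g <- as_igraph(graph)
  n <- graph$n_nodes
  deg <- rowSums(graph$adjacency) / (n - 1)
  btw <- igraph::betweenness(g, directed = FALSE, normalized = TRUE)
  dist <- igraph::distances(g)
  clo <- vapply(seq_len(n), function(u) {
    d <- dist[u, ]
    reach <- is.finite(d) & seq_len(n) != u
    nr <- sum(reach)
    if (nr == 0) return(0)
    (nr / (n - 1)) * (nr / sum(d[reach]))
  }, numeric(1))
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  tibble::tibble(node = nodes,
                 degree_centrality = deg[nodes],
                 betweenness_centrality = btw[nodes],
                 closeness_centrality = clo[nodes],
                 clustering_coefficient = cc[nodes])
}

#' Small-world index sigma
#'
#' sigma = (C / C_rand) / (L / L_rand), where C is the mean local
#' clustering coefficient, L the mean shortest path length over connected
#' pairs, and the reference values average `n_random` degree-preserving
#' rewirings (10 swap attempts per edge each). A disconnected graph is
#' reduced to its largest component with a warning.
#'
#' @param graph a `functional_graph` with >= 4 nodes.
#' @param n_random number of rewired reference graphs (default 10).
#' @param seed RNG seed for the rewiring.
#' @return Scalar sigma (`NA` with a warning if the reference clustering
#'   is 0).
#' @export
small_world_sigma <- function(graph, n_random = 10, seed = 1L) {
  if (graph$n_nodes < 4) stop("sigma needs at least 4 nodes")
  g <- as_igraph(graph)
  comp <- igraph::components(g)
  if (comp$no > 1) {
    warning("graph is disconnected; sigma computed on the largest component")
    keep <- which(comp$membership == which.max(comp$csize))
    g <- igraph::induced_subgraph(g, keep)
  }
  cl_path <- function(gg) {
    c(mean(igraph::transitivity(gg, type = "local", isolates = "zero")),
      igraph::mean_distance(gg, directed = FALSE))
  }
  obs <- cl_path(g)
  set.seed(seed)
  ref <- vapply(seq_len(n_random), function(i) {
    gr <- igraph::rewire(g, igraph::keeping_degseq(
      niter = 10 * igraph::ecount(g)))
    cl_path(gr)
  }, numeric(2))
  c_rand <- mean(ref[1, ]); l_rand <- mean(ref[2, ])
  if (c_rand == 0 || !is.finite(l_rand) || l_rand == 0) {
    warning("degenerate rewired reference; sigma undefined")
    return(NA_real_)
  }
  (obs[1] / c_rand) / (obs[2] / l_rand)
}

#' Sparsity sweep with no-isolate and small-world validation
#'
#' Examines each candidate sparsity level on every subject's weight
#' matrix: a level is validated when no subject's graph has isolated
#' nodes and every subject's sigma exceeds `sigma_min`.
#'
#' @param z_matrices list of symmetric weight matrices (one per subject).
#' @param candidates sparsity levels (default 0.15–0.40 by 0.05).
#' @param sigma_min small-world criterion (default 1.1).
#' @param n_random rewired references per sigma evaluation.
#' @param seed RNG seed for the sigma references.
#' @param compute_sigma set `FALSE` to check isolates only.
#' @return List of class `sparsity_sweep`: `levels` tibble (sparsity,
#'   subject, no_isolates, sigma, pass), `validated` (levels where all
#'   subjects pass), `graphs` (nested list `graphs[[level]][[subject]]`).
#' @export
sweep_sparsity <- function(z_matrices, candidates = seq(0.15, 0.40, by = 0.05),
                           sigma_min = 1.1, n_random = 5, seed = 1L,
                           compute_sigma = TRUE) {
  stopifnot(length(z_matrices) >= 1)
  graphs <- list()
  rows <- list()
  for (li in seq_along(candidates)) {
    s <- candidates[li]
    graphs[[li]] <- lapply(z_matrices, build_graph, sparsity = s)
    for (si in seq_along(z_matrices)) {
      gph <- graphs[[li]][[si]]
      iso <- has_isolates(gph)
      sig <- if (compute_sigma && !iso) {
        suppressWarnings(small_world_sigma(gph, n_random, seed))
      } else {
        NA_real_
      }
      pass <- !iso && (!compute_sigma || (!is.na(sig) && sig > sigma_min))
      rows[[length(rows) + 1L]] <-
        tibble::tibble(sparsity = s, subject = si, no_isolates = !iso,
                       sigma = sig, pass = pass)
    }
  }
  levels <- dplyr::bind_rows(rows)
  validated <- levels |>
    dplyr::summarise(all_pass = all(.data$pass), .by = "sparsity") |>
    dplyr::filter(.data$all_pass) |>
    dplyr::pull("sparsity")
  structure(list(levels = levels, validated = validated, graphs = graphs,
                 candidates = candidates),
            class = "sparsity_sweep")
}
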