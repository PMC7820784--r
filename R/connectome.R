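#' Generate a directed small-world topology
#'
#' Builds an undirected Watts-Strogatz graph — a ring lattice of `n_nodes`
#' vertices each joined to its `k` nearest neighbours, with every edge's far
#' endpoint rewired to a uniformly chosen vertex with probability
#' `rewire_prob` (self-loops and duplicate edges are redrawn) — and then
#' expands every undirected edge into the two directed edges, one in each
#' orientation. Rewiring preserves the edge count, so the directed graph
#' always has `n_nodes * k` edges.
#'
#' @param n_nodes number of vertices (>= 3); vertex ids are 0-based.
#' @param k even ring degree, `2 <= k < n_nodes`.
#' @param rewire_prob per-edge rewiring probability in \[0, 1\].
#' @param seed integer seed fixing the rewired structure.
#' @return an object of class `critnet_topology` with fields `n_nodes`, `k`,
#'   `rewire_prob`, `seed`, and `edges`, a two-column integer matrix of
#'   0-based (source, target) pairs covering both orientations of every
#'   undirected edge.
#' @examples
#' top <- generate_small_world(12, 4, 0.3, seed = 42)
#' nrow(top$edges)  # 12 * 4 = 48 directed edges
#' @export
generate_small_world <- function(n_nodes, k, rewire_prob, seed) {
  stopifnot(length(n_nodes) == 1, length(k) == 1, length(rewire_prob) == 1)
  if (!is.finite(n_nodes) || n_nodes < 3 || n_nodes != round(n_nodes))
    stop("n_nodes must be an integer >= 3")
  if (!is.finite(k) || k != round(k) || k < 2 || k %% 2 != 0)
    stop("k must be an even integer >= 2")
  if (k >= n_nodes)
    stop("k must be smaller than n_nodes")
  if (!is.finite(rewire_prob) || rewire_prob < 0 || rewire_prob > 1)
    stop("rewire_prob must lie in [0, 1]")
  n_nodes <- as.integer(n_nodes); k <- as.integer(k)

  # ring lattice: node i -> i + 1 .. i + k/2 (mod n), undirected
  src <- rep(seq_len(n_nodes) - 1L, each = k %/% 2L)
  off <- rep(seq_len(k %/% 2L), times = n_nodes)
  tgt <- (src + off) %% n_nodes

  # rewire the far endpoint of each lattice edge with probability rewire_prob,
  # redrawing targets that would create a self-loop or duplicate an edge
  edges <- local_seed(seed, {
    key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    present <- new.env(hash = TRUE, parent = emptyenv())
    for (kk in key(src, tgt)) assign(kk, TRUE, envir = present)
    do_rewire <- stats::runif(length(src)) < rewire_prob
    for (e in which(do_rewire)) {
      old <- key(src[e], tgt[e])
      # give up (keep the lattice edge) if the source's neighborhood is
      # saturated and no admissible target turns up
      for (attempt in seq_len(8L * n_nodes)) {
        cand <- sample.int(n_nodes, 1L) - 1L
        if (cand == src[e]) next
        kk <- key(src[e], cand)
        if (!exists(kk, envir = present, inherits = FALSE)) {
          rm(list = old, envir = present)
          assign(kk, TRUE, envir = present)
          tgt[e] <- cand
          break
        }
      }
    }
    cbind(src, tgt)
  })

  directed <- rbind(edges, edges[, 2:1, drop = FALSE])
  colnames(directed) <- c("source", "target")
  structure(
    list(n_nodes = n_nodes, k = k, rewire_prob = rewire_prob,
         seed = as.integer(seed),
         edges = directed[order(directed[, 1], directed[, 2]), , drop = FALSE]),
    class = "critnet_topology")
}

#' @export
print.critnet_topology <- function(x, ...) {
  cat(sprintf("small-world topology: %d nodes, k = %d, rewire p = %g, %d directed edges\n",
              x$n_nodes, x$k, x$rewire_prob, nrow(x$edges)))
  invisible(x)
}

#' Draw synaptic weights for a topology
#'
#' Assigns each directed edge an independent weight drawn uniformly from
#' \[0, `g_max`\] (normalized conductance units). The two orientations of an
#' undirected edge receive independent draws.
#'
#' @param topology a `critnet_topology`.
#' @param g_max maximum synaptic weight (>= 0); `g_max = 0` yields a
#'   fully decoupled network.
#' @param weight_seed integer seed fixing the draw.
#' @return a `critnet_connectome`: the topology plus `weights` (one per edge
#'   row), `g_min = 0`, `g_max`, and `weight_seed`.
#' @export
assign_weights <- function(topology, g_max, weight_seed) {
  stopifnot(inherits(topology, "critnet_topology"))
  if (!is.finite(g_max) || g_max < 0) stop("g_max must be >= 0")
  w <- local_seed(weight_seed, stats::runif(nrow(topology$edges), 0, g_max))
  structure(
    list(topology = topology, weights = w, g_min = 0, g_max = g_max,
         weight_seed = as.integer(weight_seed)),
    class = "critnet_connectome")
}

#' @export
print.critnet_connectome <- function(x, ...) {
  print(x$topology)
  cat(sprintf("weights: uniform [0, %g], seed %d\n", x$g_max, x$weight_seed))
  invisible(x)
}

# dense weight matrix W[source+1, target+1]; rows = presynaptic
weight_matrix <- function(connectome) {
  n <- connectome$topology$n_nodes
  W <- matrix(0, n, n)
  W[connectome$topology$edges + 1L] <- connectome$weights
  W
}

#' Small-world summary metrics
#'
#' Computes the clustering coefficient (transitivity) and mean shortest path
#' length of the topology's undirected projection, and a small-world index
#' `(C / C_rand) / (L / L_rand)` against a seeded degree-preserving rewired
#' random graph. A ring lattice (`rewire_prob = 0`) has clustering
#' `3 (k - 2) / (4 (k - 1))` exactly.
#'
#' @param topology a `critnet_topology`.
#' @param rand_seed seed for the randomized reference graph.
#' @return list with `clustering_coefficient`, `mean_path_length`,
#'   `small_world_index`, and `disconnected` (TRUE when the undirected
#'   projection is not connected, in which case the path length is computed
#'   over reachable pairs only).
#' @export
network_metrics <- function(topology, rand_seed = 1L) {
  g <- igraph_undirected(topology)
  C <- igraph::transitivity(g, type = "global")
  L <- igraph::mean_distance(g, directed = FALSE, unconnected = TRUE)
  disconnected <- !igraph::is_connected(g)
  swi <- local_seed(rand_seed, {
    gr <- igraph::rewire(g, igraph::keeping_degseq(niter = 20 * igraph::ecount(g)))
    C_r <- igraph::transitivity(gr, type = "global")
    L_r <- igraph::mean_distance(gr, directed = FALSE, unconnected = TRUE)
    if (is.finite(C_r) && C_r > 0 && is.finite(L_r) && L_r > 0)
      (C / C_r) / (L / L_r) else NA_real_
  })
  list(clustering_coefficient = C, mean_path_length = L,
       small_world_index = swi, disconnected = disconnected)
}

igraph_undirected <- function(topology) {
  und <- unique(cbind(pmin(topology$edges[, 1], topology$edges[, 2]),
                      pmax(topology$edges[, 1], topology$edges[, 2])))
  g <- igraph::graph_from_edgelist(und + 1L, directed = FALSE)
  igraph::add_vertices(g, max(0L, topology$n_nodes - igraph::vcount(g)))
}

#' Write / read a weighted edge list
#'
#' Serializes a connectome as plain three-column text (`source target weight`,
#' 0-based indices) preceded by `#`-comment header lines recording `n_nodes`,
#' `k`, `rewire_prob`, the topology and weight seeds, and `g_max`.
#' `read_edge_list(write_edge_list(x))` reproduces the edge set exactly and
#' the weights to printed precision.
#'
#' @param connectome a `critnet_connectome`.
#' @param path file path.
#' @return `write_edge_list` returns `path` invisibly; `read_edge_list`
#'   returns a `critnet_connectome`.
#' @export
write_edge_list <- function(connectome, path) {
  t <- connectome$topology
  hdr <- c(
    sprintf("# n_nodes %d", t$n_nodes),
    sprintf("# k %d", t$k),
    sprintf("# rewire_prob %.17g", t$rewire_prob),
    sprintf("# seed %d", t$seed),
    sprintf("# weight_seed %d", connectome$weight_seed),
    sprintf("# g_max %.17g", connectome$g_max))
  body <- sprintf("%d %d %.12g", t$edges[, 1], t$edges[, 2], connectome$weights)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
read_edge_list <- function(path) {
  lines <- readLines(path)
  is_hdr <- grepl("^#", lines)
  hdr <- lines[is_hdr]
  get_hdr <- function(name) {
    hit <- grep(paste0("^#\\s*", name, "\\s"), hdr, value = TRUE)
    if (length(hit) != 1) stop("edge-list header missing field: ", name)
    as.numeric(sub(paste0("^#\\s*", name, "\\s+"), "", hit[1]))
  }
  n_nodes <- get_hdr("n_nodes"); k <- get_hdr("k")
  rewire_prob <- get_hdr("rewire_prob")
  seed <- get_hdr("seed"); weight_seed <- get_hdr("weight_seed")
  g_max <- get_hdr("g_max")

  body <- lines[!is_hdr]
  body <- body[nzchar(trimws(body))]
  n_e <- length(body)
  edges <- matrix(0L, n_e, 2, dimnames = list(NULL, c("source", "target")))
  weights <- numeric(n_e)
  line_no <- which(!is_hdr)[seq_len(n_e)]
  for (i in seq_len(n_e)) {
    parts <- strsplit(trimws(body[i]), "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(parts))
    if (length(vals) != 3 || anyNA(vals) ||
        vals[1] != round(vals[1]) || vals[2] != round(vals[2]))
      stop(sprintf("malformed edge-list line %d: '%s'", line_no[i], body[i]))
    if (vals[1] < 0 || vals[1] >= n_nodes || vals[2] < 0 || vals[2] >= n_nodes)
      stop(sprintf("node index out of range on line %d", line_no[i]))
    if (vals[3] < 0 || vals[3] > g_max)
      stop(sprintf("weight outside [0, g_max] on line %d", line_no[i]))
    edges[i, ] <- as.integer(vals[1:2]); weights[i] <- vals[3]
  }
  topology <- structure(
    list(n_nodes = as.integer(n_nodes), k = as.integer(k),
         rewire_prob = rewire_prob, seed = as.integer(seed), edges = edges),
    class = "critnet_topology")
  structure(
    list(topology = topology, weights = weights, g_min = 0, g_max = g_max,
         weight_seed = as.integer(weight_seed)),
    class = "critnet_connectome")
}

# evaluate expr under a temporary RNG state seeded with `seed`
local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
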