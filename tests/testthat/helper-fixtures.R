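# Fixtures are built in code; nothing is loaded from disk.

# Small random group dataset.
make_group <- function(n = 4, t_len = 30, c_len = 3, seed = 1, fs = 7.81) {
  set.seed(seed)
  mats <- replicate(n, matrix(rnorm(t_len * c_len), t_len, c_len),
                    simplify = FALSE)
  group_dataset(mats, fs = fs)
}

# Independent closeness oracle: explicit weighted shortest paths (igraph),
# then (N-1) / sum of geodesic distances, averaged over nodes. Shares no
# code with the package's row-sum implementation.
oracle_mean_closeness <- function(d) {
  g <- igraph::graph_from_adjacency_matrix(d, mode = "undirected",
                                           weighted = TRUE)
  sp <- igraph::distances(g, algorithm = "dijkstra")
  mean((nrow(d) - 1) / rowSums(sp))
}

# Random Euclidean distance matrix from a point cloud.
random_metric_matrix <- function(n, dim = 3) {
  pts <- matrix(rnorm(n * dim), n, dim)
  as.matrix(dist(pts))
}

# Circular lag-k autocorrelation (wrap-around definition).
circ_acf <- function(x, k) {
  xc <- x - mean(x)
  sum(xc * xc[((seq_along(x) - 1 + k) %% length(x)) + 1]) / sum(xc^2)
}
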