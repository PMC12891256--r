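# Build a vf_result with every location not-significant, then override.
make_vf <- function(pd_prob = NULL, td = NULL, md = -1, psd = 1.5, fp = 0.05,
                    pd_available = TRUE) {
  n <- 52
  if (is.null(pd_prob)) pd_prob <- rep("ns", n)
  if (is.null(td)) td <- rep(0, n)
  vf_result(thresholds_dB = rep(30, n) + td,
            total_deviation_dB = td,
            pattern_deviation_dB = td,
            td_prob = rep("ns", n),
            pd_prob = if (pd_available) pd_prob else NULL,
            md_dB = md, psd_dB = psd, false_positive_rate = fp,
            pd_map_available = pd_available)
}

# Index of the analyzable location at (x, y) degrees.
loc_at <- function(x, y) {
  g <- vf_grid_analyzable()
  i <- which(g$x_deg == x & g$y_deg == y)
  stopifnot(length(i) == 1)
  i
}

# Independent HPA oracle: connected components via igraph on the flagged
# subgraph, then the group-size / p<1 conditions.
hpa_oracle <- function(pd_prob, neighbourhood = 8, hemifield_restricted = TRUE) {
  g <- vf_grid_analyzable()
  lv <- c("p<0.5", "p<1", "p<2", "p<5", "ns")
  r <- match(pd_prob, lv)
  member <- which(r <= 4)
  out <- rep(FALSE, nrow(g))
  if (length(member) == 0) return(out)
  adj <- outer(seq_along(member), seq_along(member), function(a, b) {
    ia <- member[a]; ib <- member[b]
    dx <- abs(g$x_deg[ia] - g$x_deg[ib]) / 6
    dy <- abs(g$y_deg[ia] - g$y_deg[ib]) / 6
    near <- if (neighbourhood == 8) dx <= 1 & dy <= 1 else dx + dy <= 1
    if (hemifield_restricted) near <- near & (g$y_deg[ia] > 0) == (g$y_deg[ib] > 0)
    near & !(ia == ib)
  })
  gr <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(gr)$membership
  for (k in unique(comp)) {
    grp <- member[comp == k]
    if (length(grp) >= 3 && any(r[grp] <= 2)) out[grp] <- TRUE
  }
  out
}

# Random probability map with given flag rates.
random_pd_prob <- function(p_flag = 0.15) {
  lv <- c("p<0.5", "p<1", "p<2", "p<5", "ns")
  probs <- c(p_flag / 4, p_flag / 4, p_flag / 4, p_flag / 4, 1 - p_flag)
  sample(lv, 52, replace = TRUE, prob = probs)
}

# Small uniform thickness map.
uniform_map <- function(value = 60, n = 160) {
  thickness_map(matrix(value, n, n))
}

# A schematic assignment on the default raster, cached per session.
default_assignment <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_cluster_assignment(uniform_map())
    cache
  }
})
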