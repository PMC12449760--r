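# Metrics operate on the unsigned, unweighted topology of a pn_network
# (or a bare igraph graph).

pn_graph <- function(net) {
  if (inherits(net, "pn_network")) net$graph
  else if (igraph::is_igraph(net)) net
  else abort("expected a pn_network or igraph graph")
}

#' Connectance of an undirected network
#'
#' Realized fraction of possible undirected links, `L / (S(S-1)/2)`.
#'
#' @param net A `pn_network` or igraph graph with at least 2 nodes.
#' @return Connectance in \[0, 1\].
#' @export
connectance <- function(net) {
  g <- pn_graph(net)
  s <- igraph::vcount(g)
  if (s < 2) abort("connectance needs at least 2 nodes")
  igraph::ecount(g) / (s * (s - 1) / 2)
}

#' Mean degree centrality
#'
#' Average number of links per node, `(1/S) * sum(degree) = 2L/S`.
#'
#' @param net A `pn_network` or igraph graph with at least 1 node.
#' @return Mean degree (links per node).
#' @export
mean_degree <- function(net) {
  g <- pn_graph(net)
  if (igraph::vcount(g) == 0) abort("mean degree of an empty node set is undefined")
  mean(igraph::degree(g))
}

#' Skewness of the degree distribution
#'
#' Third standardized moment of node degrees. The default (`"adjusted"`)
#' divides the third central moment sum by `(S - 1) * sigma^3` with sigma
#' the sample (n-1) standard deviation; `"moment"` is the biased moment
#' ratio `m3 / m2^(3/2)` used by several common skewness routines. The two
#' disagree for small S. A regular graph (all degrees equal) has zero
#' skewness by convention, flagged as degenerate.
#'
#' @param net A `pn_network`, igraph graph, or a numeric degree vector with
#'   at least 3 values.
#' @param method `"adjusted"` (default) or `"moment"`.
#' @return Skewness (dimensionless); attribute `degenerate` is `TRUE` when
#'   all degrees are equal.
#' @export
degree_skewness <- function(net, method = c("adjusted", "moment")) {
  method <- match.arg(method)
  x <- if (is.numeric(net)) net else igraph::degree(pn_graph(net))
  s <- length(x)
  if (s < 3) abort("degree skewness needs at least 3 nodes")
  if (sd(x) == 0) return(structure(0, degenerate = TRUE))
  m <- mean(x)
  val <- if (method == "adjusted") {
    sum((x - m)^3) / ((s - 1) * sd(x)^3)
  } else {
    (sum((x - m)^3) / s) / (sum((x - m)^2) / s)^1.5
  }
  structure(val, degenerate = FALSE)
}

#' Modularity of a node partition
#'
#' Newman-Girvan modularity with a resolution parameter:
#' `Q = (1/2L) * sum_ij (A_ij - gamma * k_i k_j / 2L) * delta(c_i, c_j)`,
#' summed over ordered node pairs (self-pairs contribute only the null
#' term, as A_ii = 0 in a simple graph).
#'
#' @param net A `pn_network` or igraph graph with at least one edge.
#' @param membership Integer/character community label per node, in node
#'   order.
#' @param gamma Resolution parameter (default 1).
#' @return Modularity Q.
#' @export
net_modularity <- function(net, membership, gamma = 1) {
  g <- pn_graph(net)
  L <- igraph::ecount(g)
  if (L == 0) abort("modularity is undefined for an edgeless graph")
  s <- igraph::vcount(g)
  if (length(membership) != s) abort("membership must label every node")
  k <- igraph::degree(g)
  comm <- as.integer(factor(membership))
  el <- igraph::as_edgelist(g, names = FALSE)
  within_edges <- sum(comm[el[, 1]] == comm[el[, 2]])
  null_term <- sum(tapply(k, comm, sum)^2) / (2 * L)^2
  within_edges / L - gamma * null_term
}

#' Girvan-Newman community detection
#'
#' Divisive edge-betweenness clustering: repeatedly remove the edge with
#' the highest betweenness (recomputed after every removal; ties broken by
#' lexicographic edge order for determinism), record the component
#' structure after each removal, and return the recorded partition with
#' maximum modularity on the original graph (ties broken toward fewer
#' communities). An edgeless graph yields singleton communities.
#'
#' @param net A `pn_network` or igraph graph.
#' @param gamma Resolution parameter for the modularity criterion.
#' @return List of class `pn_partition`: `membership` (named integer
#'   vector), `modularity` (Q of the returned cut), `n_communities`, and
#'   `dendrogram` (tibble of all recorded cuts with their Q).
#' @export
girvan_newman <- function(net, gamma = 1) {
  g0 <- pn_graph(net)
  s <- igraph::vcount(g0)
  if (s == 0) abort("cannot partition an empty graph")
  nodes <- igraph::V(g0)$name %||% as.character(seq_len(s))
  L <- igraph::ecount(g0)
  cuts <- list(igraph::components(g0)$membership)
  # edge endpoints tracked alongside the shrinking graph (igraph keeps the
  # remaining edges in order after a deletion); lexicographic keys on the
  # node names give the deterministic tie-break
  el0 <- igraph::as_edgelist(g0, names = FALSE)
  nm <- cbind(nodes[el0[, 1]], nodes[el0[, 2]])
  akey <- pmin(nm[, 1], nm[, 2]); bkey <- pmax(nm[, 1], nm[, 2])
  g <- g0
  n_comp <- max(cuts[[1]])
  while (length(akey) > 0) {
    eb <- igraph::edge_betweenness(g, directed = FALSE)
    drop <- order(-eb, akey, bkey)[1]
    g <- igraph::delete_edges(g, drop)
    akey <- akey[-drop]; bkey <- bkey[-drop]
    memb <- igraph::components(g)$membership
    if (max(memb) > n_comp) {
      n_comp <- max(memb)
      cuts[[length(cuts) + 1]] <- memb
    }
  }
  if (L == 0) {
    memb <- setNames(seq_len(s), nodes)
    return(structure(list(membership = memb, modularity = NA_real_,
                          n_communities = s,
                          dendrogram = tibble::tibble(n_communities = s,
                                                      modularity = NA_real_)),
                     class = "pn_partition"))
  }
  k <- tabulate(el0, nbins = s)
  two_l_sq <- (2 * L)^2
  qs <- vapply(cuts, function(m) {
    within <- sum(m[el0[, 1]] == m[el0[, 2]])
    within / L - gamma * sum(rowsum(k, m)^2) / two_l_sq
  }, 0)
  ncomm <- vapply(cuts, function(m) as.integer(max(m)), 0L)
  best <- order(-qs, ncomm)[1]
  memb <- setNames(as.integer(cuts[[best]]), nodes)
  structure(list(membership = memb, modularity = qs[best],
                 n_communities = max(memb),
                 dendrogram = tibble::tibble(n_communities = ncomm,
                                             modularity = qs)),
            class = "pn_partition")
}

#' @export
print.pn_partition <- function(x, ...) {
  cat("<pn_partition> ", x$n_communities, " communities, Q = ",
      format(x$modularity, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Summary metrics of a co-occurrence network
#'
#' One row with node count S, link count L, connectance, modularity of the
#' max-Q Girvan-Newman partition, mean degree centrality and skewness of
#' the degree distribution. Degenerate cases (edgeless graph, regular
#' degree distribution) are flagged rather than fatal: modularity is NA
#' when L = 0 and skewness is 0 with `skewness_degenerate = TRUE` when all
#' degrees are equal.
#'
#' @param net A `pn_network` or igraph graph.
#' @param gamma Resolution parameter for modularity (default 1).
#' @param metrics Character subset of
#'   `c("connectance", "modularity", "mean_degree", "skewness")` to
#'   compute (all by default); skipping modularity avoids the community
#'   detection for large ensembles where only other metrics are needed.
#' @param skewness_method Passed to [degree_skewness()].
#' @return One-row tibble: `label`, `S`, `L`, the requested metrics, and
#'   flags.
#' @export
network_summary <- function(net, gamma = 1,
                            metrics = c("connectance", "modularity",
                                        "mean_degree", "skewness"),
                            skewness_method = "adjusted") {
  g <- pn_graph(net)
  metrics <- match.arg(metrics, several.ok = TRUE)
  s <- igraph::vcount(g)
  L <- igraph::ecount(g)
  out <- tibble::tibble(
    label = if (inherits(net, "pn_network")) net$label else NA_character_,
    S = s, L = L
  )
  if ("connectance" %in% metrics) {
    out$connectance <- if (s >= 2) connectance(g) else NA_real_
  }
  if ("modularity" %in% metrics) {
    out$modularity <- if (L > 0) girvan_newman(g, gamma = gamma)$modularity else NA_real_
  }
  if ("mean_degree" %in% metrics) out$mean_degree <- mean_degree(g)
  if ("skewness" %in% metrics) {
    if (s >= 3) {
      sk <- degree_skewness(g, method = skewness_method)
      out$skewness <- as.numeric(sk)
      out$skewness_degenerate <- attr(sk, "degenerate")
    } else {
      out$skewness <- NA_real_
      out$skewness_degenerate <- TRUE
    }
  }
  out
}

#' @rdname network_summary
#' @param x A `pn_network`.
#' @param ... Passed to [network_summary()].
#' @method glance pn_network
#' @export
glance.pn_network <- function(x, ...) {
  network_summary(x, ...)
}

#' Format a metrics table at report precision
#'
#' Rounds connectance to 3 decimals and the other metrics to 2, the
#' precision used in summary tables.
#'
#' @param metrics A tibble from [network_summary()] rows.
#' @return The tibble with rounded metric columns.
#' @export
format_metrics <- function(metrics) {
  out <- metrics
  if ("connectance" %in% names(out)) out$connectance <- round(out$connectance, 3)
  for (cl in intersect(c("modularity", "mean_degree", "skewness"), names(out))) {
    out[[cl]] <- round(out[[cl]], 2)
  }
  out
}
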