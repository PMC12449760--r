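#' Pairwise Spearman correlations with p-values
#'
#' Computes Spearman's rho for every taxon pair of a (typically
#' Hellinger-transformed) abundance table, using average ranks for ties,
#' and a two-sided p-value from the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom
#' (the convention of the usual correlation-matrix routines). Pairs with
#' `|rho| = 1` get `p = 0`; zero-variance taxa are masked (NA rho and p).
#'
#' @param x An abundance (or count) tibble with at least 5 samples.
#' @return A list of class `pn_correlation`: `rho` and `p` (symmetric
#'   taxa-by-taxa matrices), `n_obs`, and `masked` (zero-variance taxa).
#' @export
spearman_matrix <- function(x) {
  m <- pn_matrix(x)
  n <- nrow(m)
  if (n < 5) abort("at least 5 samples are required for a correlation network")
  sds <- apply(m, 2, sd)
  masked <- colnames(m)[sds == 0]
  rho <- suppressWarnings(cor(m, method = "spearman"))
  rho[masked, ] <- NA_real_
  rho[, masked] <- NA_real_
  r <- pmin(pmax(rho, -1), 1)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 0))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  p[abs(r) >= 1 - 1e-12] <- 0
  diag(p) <- 0
  p[is.na(r)] <- NA_real_
  structure(list(rho = rho, p = p, n_obs = n, masked = masked),
            class = "pn_correlation")
}

#' Build a co-occurrence network from a correlation result
#'
#' Nodes are the taxa present (nonzero in at least one sample) in the
#' group, including taxa that end up with no significant link; edges join
#' unmasked pairs with `p < alpha`, keeping the sign and magnitude of rho
#' (negative associations are retained as ordinary links). All topology
#' metrics operate on the unweighted, unsigned simple graph.
#'
#' @param cr A `pn_correlation` from [spearman_matrix()].
#' @param alpha Significance level for an edge, in (0, 1).
#' @param present_taxa Character vector of node taxa; defaults to all
#'   unmasked and masked taxa of `cr`.
#' @param label Optional group/zone label stored on the network.
#' @return An object of class `pn_network`: igraph graph plus `alpha`,
#'   `label` and `n_obs`.
#' @export
build_network <- function(cr, alpha, present_taxa = NULL, label = NA_character_) {
  stopifnot(inherits(cr, "pn_correlation"))
  if (alpha <= 0 || alpha >= 1) abort("alpha must lie in (0, 1)")
  taxa <- colnames(cr$rho)
  if (is.null(present_taxa)) present_taxa <- taxa
  if (length(present_taxa) == 0) abort("present_taxa must be non-empty")
  if (!all(present_taxa %in% taxa)) abort("present_taxa must be a subset of the correlated taxa")
  sub <- match(present_taxa, taxa)
  p <- cr$p[sub, sub, drop = FALSE]
  rho <- cr$rho[sub, sub, drop = FALSE]
  idx <- which(upper.tri(p) & !is.na(p) & p < alpha, arr.ind = TRUE)
  rho_e <- rho[idx]
  edges <- tibble::tibble(
    taxon_a = present_taxa[idx[, 1]],
    taxon_b = present_taxa[idx[, 2]],
    rho = rho_e,
    p = p[idx],
    sign = ifelse(rho_e >= 0, 1L, -1L)
  )
  g <- igraph::graph_from_data_frame(edges[, c("taxon_a", "taxon_b")],
                                     directed = FALSE,
                                     vertices = data.frame(name = present_taxa))
  igraph::E(g)$rho <- edges$rho
  igraph::E(g)$p <- edges$p
  igraph::E(g)$sign <- edges$sign
  new_pn_network(g, alpha = alpha, label = label, n_obs = cr$n_obs)
}

new_pn_network <- function(g, alpha = NA_real_, label = NA_character_,
                           n_obs = NA_integer_) {
  structure(list(graph = g, alpha = alpha, label = label, n_obs = n_obs),
            class = "pn_network")
}

#' @export
print.pn_network <- function(x, ...) {
  cat("<pn_network>", if (!is.na(x$label)) paste0(" ", x$label), "\n",
      "  S = ", igraph::vcount(x$graph), " taxa, L = ",
      igraph::ecount(x$graph), " links (alpha = ", x$alpha, ")\n", sep = "")
  invisible(x)
}

#' Edge table of a co-occurrence network
#'
#' @param x A `pn_network`.
#' @param ... Unused.
#' @return Tibble with one row per link: `taxon_a`, `taxon_b`, `rho`, `p`,
#'   `sign`.
#' @method tidy pn_network
#' @export
tidy.pn_network <- function(x, ...) {
  g <- x$graph
  if (igraph::ecount(g) == 0) {
    return(tibble::tibble(taxon_a = character(), taxon_b = character(),
                          rho = double(), p = double(), sign = integer()))
  }
  el <- igraph::as_edgelist(g)
  tibble::tibble(taxon_a = el[, 1], taxon_b = el[, 2],
                 rho = igraph::E(g)$rho, p = igraph::E(g)$p,
                 sign = igraph::E(g)$sign)
}

#' Split an assemblage table into analysis groups
#'
#' For the landscape (top-bottom) design, one subset per combination of
#' `group` (impact class) and `time_slice`; for a zoned core, one subset
#' per zone label in `group`. Taxa with all-zero counts within a subset are
#' recorded as absent (the subset's node set is its present taxa).
#'
#' @param x A count tibble with a `group` column (and optionally
#'   `time_slice`).
#' @return Tibble with one row per subset: `group`, `time_slice` (if
#'   present), `n_samples`, `present_taxa` (list column), `data` (list
#'   column of count tibbles).
#' @export
subset_by_group <- function(x) {
  if (!"group" %in% names(x)) abort("subset_by_group() needs a 'group' column")
  keys <- intersect(c("group", "time_slice"), names(x))
  nested <- tidyr::nest(dplyr::group_by(x, dplyr::across(dplyr::all_of(keys))))
  nested <- dplyr::ungroup(nested)
  empty <- purrr::map_int(nested$data, nrow) == 0
  if (any(empty)) {
    warn("skipping group(s) with zero samples")
    nested <- nested[!empty, ]
  }
  nested$data <- purrr::map(nested$data, function(d) {
    dplyr::bind_cols(tibble::tibble(sample_id = d$sample_id),
                     d[, setdiff(names(d), c("sample_id", keys)), drop = FALSE])
  })
  dplyr::mutate(
    nested,
    n_samples = purrr::map_int(.data$data, nrow),
    present_taxa = purrr::map(.data$data, function(d) {
      taxa <- taxon_names(d)
      taxa[colSums(d[, taxa, drop = FALSE]) > 0]
    }),
    .before = "data"
  )
}

#' Build one network per sample group
#'
#' Convenience wrapper: relative abundance, Hellinger transform, Spearman
#' correlation and thresholding, applied within each subset returned by
#' [subset_by_group()].
#'
#' @param x A count tibble with `group` (and optionally `time_slice`).
#' @param alpha Edge significance level.
#' @return The [subset_by_group()] tibble with a `network` list column of
#'   `pn_network` objects (subsets with fewer than 5 samples are dropped
#'   with a warning).
#' @export
build_group_networks <- function(x, alpha) {
  subs <- subset_by_group(x)
  ok <- subs$n_samples >= 5
  if (any(!ok)) {
    warn(paste0("dropping ", sum(!ok),
                " group(s) with fewer than 5 samples"))
    subs <- subs[ok, ]
  }
  labels <- if ("time_slice" %in% names(subs)) {
    paste(subs$group, subs$time_slice, sep = ":")
  } else as.character(subs$group)
  subs$network <- purrr::pmap(
    list(subs$data, subs$present_taxa, labels),
    function(d, taxa, lab) {
      h <- hellinger_transform(to_relative_abundance(d))
      cr <- spearman_matrix(h[, c("sample_id", taxa)])
      build_network(cr, alpha = alpha, present_taxa = taxa, label = lab)
    }
  )
  subs
}
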