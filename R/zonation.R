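#' Bray-Curtis dissimilarity matrix of an abundance table
#'
#' Percentage-difference dissimilarity
#' `d_ij = sum|x_ik - x_jk| / sum(x_ik + x_jk)` between sample rows, in
#' stratigraphic (row) order.
#'
#' @param x An abundance or count tibble with non-empty rows.
#' @return Symmetric matrix with zero diagonal, dimnames = sample ids.
#' @export
bray_curtis <- function(x) {
  m <- pn_matrix(x)
  if (sum(rowSums(m) == 0) >= 2) {
    abort("Bray-Curtis is undefined between two all-zero samples")
  }
  d <- as.matrix(vegan::vegdist(m, method = "bray"))
  dimnames(d) <- list(x$sample_id, x$sample_id)
  d
}

# within-cluster dispersion of index set `idx` from squared dissimilarities:
# sum_{i<j} d_ij^2 / |idx|  (the incremental sum-of-squares objective)
cluster_dispersion <- function(d2, idx) {
  if (length(idx) < 2) return(0)
  sum(d2[idx, idx][upper.tri(d2[idx, idx])]) / length(idx)
}

#' Constrained incremental sum-of-squares clustering (CONISS)
#'
#' Agglomerative clustering of stratigraphically ordered samples in which
#' only adjacent clusters may merge. The merge cost is the increase in
#' within-cluster dispersion (incremental sum of squares computed from
#' squared dissimilarities, the Ward-type objective generalized to an
#' arbitrary dissimilarity matrix); merges are chosen greedily by minimum
#' increment, ties broken toward the stratigraphically earlier pair.
#'
#' @param d A symmetric dissimilarity matrix with samples in stratigraphic
#'   order (e.g. from [bray_curtis()]); at least 3 samples.
#' @return An object of class `pn_coniss`: `merges` tibble (one row per
#'   merge: the boundary position joined and the dispersion increment),
#'   `increments`, `total_dispersion`, `n`, `labels`.
#' @export
coniss <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3) abort("CONISS needs at least 3 samples")
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8))) abort("dissimilarity matrix must be symmetric")
  d2 <- d^2
  # clusters held as a list of contiguous index runs, in order
  clusters <- as.list(seq_len(n))
  disp <- rep(0, n)
  merges <- vector("list", n - 1)
  for (step in seq_len(n - 1)) {
    k <- length(clusters)
    inc <- vapply(seq_len(k - 1), function(i) {
      merged <- c(clusters[[i]], clusters[[i + 1]])
      cluster_dispersion(d2, merged) - disp[i] - disp[i + 1]
    }, 0)
    i <- which.min(inc) # ties -> earliest adjacent pair (which.min is first)
    merges[[step]] <- tibble::tibble(
      step = step,
      left_end = max(clusters[[i]]),
      increment = inc[i],
      n_clusters = k - 1
    )
    clusters[[i]] <- c(clusters[[i]], clusters[[i + 1]])
    disp[i] <- disp[i] + disp[i + 1] + inc[i]
    clusters[[i + 1]] <- NULL
    disp <- disp[-(i + 1)]
  }
  merges <- dplyr::bind_rows(merges)
  structure(list(merges = merges, increments = merges$increment,
                 total_dispersion = sum(merges$increment), n = n,
                 labels = rownames(d) %||% as.character(seq_len(n))),
            class = "pn_coniss")
}

#' @export
print.pn_coniss <- function(x, ...) {
  cat("<pn_coniss> ", x$n, " stratigraphic samples, total dispersion ",
      format(x$total_dispersion, digits = 4), "\n", sep = "")
  invisible(x)
}

# partition of 1..n into k contiguous zones implied by cutting the merge
# sequence: the boundaries are the k-1 merges done last
coniss_cut <- function(tree, n_zones) {
  n <- tree$n
  if (n_zones < 1 || n_zones > n) abort("invalid zone count")
  if (n_zones == n) return(seq_len(n))
  # boundaries removed in merge order; remaining after cutting = last merges undone
  undone <- tail(tree$merges$left_end, n_zones - 1)
  boundaries <- sort(undone)
  zone <- findInterval(seq_len(n), c(0.5, boundaries + 0.5))
  as.integer(zone)
}

#' Broken-stick validation of a CONISS tree
#'
#' Compares the dispersion explained by each successive split (the merge
#' increments taken in reverse order) against the broken-stick expectation
#' for that split, `T/(n-1) * sum_{j=k}^{n-1} 1/j` where T is the total
#' dispersion. The number of significant zones is 1 plus the number of
#' leading splits whose observed explained dispersion exceeds the
#' expectation.
#'
#' @param tree A `pn_coniss` object.
#' @return List: `n_zones`, and `table` (tibble of split number, observed
#'   explained dispersion, broken-stick expectation).
#' @export
broken_stick <- function(tree) {
  stopifnot(inherits(tree, "pn_coniss"))
  n <- tree$n
  observed <- rev(tree$increments) # split k = the (n-k)-th merge undone
  ks <- seq_len(n - 1)
  expected <- vapply(ks, function(k) sum(1 / (k:(n - 1))), 0) *
    tree$total_dispersion / (n - 1)
  sig <- observed > expected
  lead <- if (!sig[1]) 0L else (which(!sig)[1] %||% n) - 1L
  if (all(sig)) lead <- n - 1L
  list(n_zones = 1L + lead,
       table = tibble::tibble(split = ks, observed = observed,
                              expected = expected, significant = sig))
}

#' Cut a CONISS tree into contiguous zones
#'
#' Cuts at `n_zones`; any cut producing a zone smaller than
#' `min_intervals` is rejected and `n_zones` decremented until every zone
#' is large enough (a minimum of 5 intervals per zone keeps each zone
#' usable for a correlation network).
#'
#' @param tree A `pn_coniss` object.
#' @param n_zones Requested zone count (e.g. from [broken_stick()]).
#' @param min_intervals Minimum intervals per zone (default 5).
#' @param ages Optional numeric ages (CE) per interval, in stratigraphic
#'   order, used for the per-zone median year.
#' @param depths Optional numeric depths per interval.
#' @return Tibble of class `pn_zones`: one row per interval with
#'   `sample_id`, `zone`, and `age_ce`/`depth_cm` when supplied; attribute
#'   `zone_summary` holds per-zone n, median year and boundaries.
#' @export
assign_zones <- function(tree, n_zones, min_intervals = 5, ages = NULL,
                         depths = NULL) {
  stopifnot(inherits(tree, "pn_coniss"))
  n <- tree$n
  k <- min(n_zones, n)
  repeat {
    zone <- coniss_cut(tree, k)
    if (min(table(zone)) >= min_intervals) break
    k <- k - 1
    if (k < 1) abort(paste0("record too short: even a single zone has fewer than ",
                            min_intervals, " intervals"))
  }
  out <- tibble::tibble(sample_id = tree$labels, zone = zone)
  if (!is.null(ages)) out$age_ce <- ages
  if (!is.null(depths)) out$depth_cm <- depths
  summ <- dplyr::summarise(
    dplyr::group_by(out, .data$zone),
    n_intervals = dplyr::n(),
    median_year = if (!is.null(ages)) median(.data$age_ce) else NA_real_,
    .groups = "drop"
  )
  attr(out, "zone_summary") <- summ
  class(out) <- c("pn_zones", class(out))
  out
}

#' Zonation of a stratigraphic record in one call
#'
#' Hellinger-transforms the counts, computes Bray-Curtis dissimilarity,
#' runs CONISS, chooses the zone count by the broken-stick model and
#' enforces the minimum zone size.
#'
#' @param x A count tibble in stratigraphic order with `depth_cm` and
#'   `age_ce`.
#' @param min_intervals Minimum intervals per zone (default 5).
#' @param transform `"hellinger"` (default) to cluster on
#'   Hellinger-transformed relative abundances, `"relative"` for raw
#'   relative abundances.
#' @return A `pn_zones` tibble (see [assign_zones()]); attributes carry
#'   the `pn_coniss` tree and broken-stick table.
#' @export
zonate_core <- function(x, min_intervals = 5,
                        transform = c("hellinger", "relative")) {
  transform <- match.arg(transform)
  ab <- to_relative_abundance(x)
  if (transform == "hellinger") ab <- hellinger_transform(ab)
  tree <- coniss(bray_curtis(ab))
  bs <- broken_stick(tree)
  zones <- assign_zones(tree, bs$n_zones, min_intervals = min_intervals,
                        ages = x$age_ce, depths = x$depth_cm)
  attr(zones, "tree") <- tree
  attr(zones, "broken_stick") <- bs$table
  zones
}
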