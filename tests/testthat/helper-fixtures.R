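# small in-code fixtures shared across test files

tiny_counts <- function() {
  tibble::tibble(
    sample_id = c("s1", "s2", "s3"),
    taxon_a = c(5L, 1L, 3L),
    taxon_b = c(0L, 4L, 1L),
    taxon_c = c(5L, 5L, 0L)
  )
}

core_counts <- function(n = 12, seed = 42) {
  set.seed(seed)
  m <- matrix(rpois(n * 6, lambda = 30), n, 6,
              dimnames = list(NULL, paste0("t", 1:6)))
  tibble::tibble(sample_id = paste0("d", seq_len(n)),
                 depth_cm = seq_len(n) - 0.5,
                 age_ce = round(seq(2017, 1800, length.out = n))) |>
    dplyr::bind_cols(tibble::as_tibble(m))
}

write_counts_csv <- function(x, path = tempfile(fileext = ".csv")) {
  readr::write_csv(x, path)
  path
}

# two disjoint m-cliques as a named igraph graph
two_cliques <- function(m = 4) {
  g <- igraph::disjoint_union(igraph::make_full_graph(m),
                              igraph::make_full_graph(m))
  igraph::V(g)$name <- paste0("v", seq_len(2 * m))
  g
}

# brute-force within-cluster dispersion of a contiguous partition, straight
# from the incremental sum-of-squares definition (independent of coniss())
dispersion_oracle <- function(d, zones) {
  d2 <- as.matrix(d)^2
  sum(vapply(unique(zones), function(z) {
    idx <- which(zones == z)
    if (length(idx) < 2) return(0)
    sub <- d2[idx, idx]
    sum(sub[upper.tri(sub)]) / length(idx)
  }, 0))
}
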