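#' Read a sample-by-taxon count matrix
#'
#' Reads a CSV or TSV file (delimiter inferred from the header line) whose
#' first column holds sample identifiers and whose remaining columns are
#' either reserved metadata columns (`group`, `time_slice`, `depth_cm`,
#' `age_ce`, `hii`) or taxon counts. Counts must be non-negative integers.
#'
#' @param path Path to a UTF-8 text file with a header row.
#' @return A count tibble: `sample_id`, any metadata columns present, then
#'   one integer-valued column per taxon.
#' @export
read_count_matrix <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  header <- readLines(path, n = 1L)
  delim <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  x <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                         progress = FALSE, name_repair = "minimal")
  names(x)[1] <- "sample_id"
  x$sample_id <- as.character(x$sample_id)
  validate_count_matrix(x)
}

#' Validate an assemblage count table
#'
#' Checks uniqueness of sample ids and taxon names, non-negative integral
#' counts (naming the offending cell on failure), and strictly ordered
#' depths when `depth_cm` is present.
#'
#' @param x A tibble with a `sample_id` column, optional reserved metadata
#'   columns, and taxon count columns.
#' @return `x`, invisibly validated, with taxon columns coerced to integer.
#' @export
validate_count_matrix <- function(x) {
  x <- tibble::as_tibble(x, .name_repair = "minimal")
  if (!"sample_id" %in% names(x)) abort("count table needs a 'sample_id' column")
  if (anyDuplicated(names(x))) {
    abort(paste0("duplicated taxon name: ", names(x)[duplicated(names(x))][1]))
  }
  if (anyDuplicated(x$sample_id)) {
    abort(paste0("duplicated sample id: ",
                 x$sample_id[duplicated(x$sample_id)][1]))
  }
  taxa <- taxon_names(x)
  if (length(taxa) == 0) abort("no taxon columns found")
  if (anyDuplicated(taxa)) {
    abort(paste0("duplicated taxon name: ", taxa[duplicated(taxa)][1]))
  }
  for (tx in taxa) {
    v <- x[[tx]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))) | is.na(v))[1]
      abort(paste0("non-numeric count in taxon '", tx, "', sample '",
                   x$sample_id[if (is.na(bad)) 1 else bad], "'"))
    }
    bad <- which(is.na(v) | v < 0 | v != round(v))
    if (length(bad) > 0) {
      abort(paste0("count must be a non-negative integer: taxon '", tx,
                   "', sample '", x$sample_id[bad[1]], "' has value ",
                   v[bad[1]]))
    }
    x[[tx]] <- as.integer(round(v))
  }
  if ("depth_cm" %in% names(x)) {
    d <- x$depth_cm
    if (anyNA(d) || (length(d) > 1 && !(all(diff(d) > 0) || all(diff(d) < 0)))) {
      abort("depth_cm must be strictly ordered down the core")
    }
  }
  x
}

#' Convert counts to relative abundances
#'
#' Each row is divided by its total; rows with zero total stay all-zero and
#' are reported in the `zero_rows` attribute.
#'
#' @param x A count tibble (see [read_count_matrix()]).
#' @return An abundance tibble with transform tag `"relative"`.
#' @export
to_relative_abundance <- function(x) {
  m <- pn_matrix(x)
  tot <- rowSums(m)
  if (all(tot == 0)) abort("all rows have zero total")
  keep <- tot > 0
  m[keep, ] <- m[keep, , drop = FALSE] / tot[keep]
  out <- pn_rebuild(pn_meta(x), m, transform = "relative")
  attr(out, "zero_rows") <- x$sample_id[!keep]
  out
}

#' Hellinger-transform relative abundances
#'
#' Takes the element-wise square root of relative abundances, so each
#' non-empty row has unit sum of squares. Standard pre-treatment that makes
#' Euclidean-type analyses appropriate for compositional community data.
#'
#' @param x An abundance tibble with transform tag `"relative"`.
#' @return An abundance tibble with transform tag `"hellinger"`.
#' @export
hellinger_transform <- function(x) {
  if (!identical(pn_transform(x), "relative")) {
    abort("hellinger_transform() expects a relative-abundance table; call to_relative_abundance() first")
  }
  m <- sqrt(pn_matrix(x))
  out <- pn_rebuild(pn_meta(x), m, transform = "hellinger")
  attr(out, "zero_rows") <- attr(x, "zero_rows")
  out
}

#' Rarefy counts to a common depth
#'
#' Draws a single seeded without-replacement subsample of exactly `depth`
#' individuals from each sample. Samples whose total is below `depth` are
#' dropped with a warning and listed in the `dropped` attribute.
#'
#' @param x A count tibble.
#' @param depth Number of individuals to retain per sample (>= 1).
#' @param seed Integer seed; the draw is reproducible.
#' @return A count tibble whose retained rows all total `depth`.
#' @export
rarefy_counts <- function(x, depth, seed = 1L) {
  if (depth < 1) abort("rarefaction depth must be >= 1")
  m <- pn_matrix(x)
  tot <- rowSums(m)
  keep <- tot >= depth
  if (!any(keep)) abort("rarefaction depth exceeds every sample total")
  if (any(!keep)) {
    warn(paste0("dropping ", sum(!keep), " sample(s) with total < ", depth,
                ": ", paste(x$sample_id[!keep], collapse = ", ")))
  }
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    code
  }
  mk <- m[keep, , drop = FALSE]
  # counts are validated upstream; rrarefy's "observed counts" heuristic
  # warning is spurious here
  r <- withr_seed(suppressWarnings(vegan::rrarefy(mk, depth)))
  out <- pn_rebuild(pn_meta(x)[keep, , drop = FALSE], r)
  for (tx in taxon_names(out)) out[[tx]] <- as.integer(out[[tx]])
  attr(out, "dropped") <- x$sample_id[!keep]
  out
}

#' Shannon diversity of a count vector
#'
#' H = -sum p_i log p_i over taxa with nonzero count, in the units of
#' `base` (natural log, hence nats, by default).
#'
#' @param counts Non-negative count vector with positive total.
#' @param base Logarithm base (default `exp(1)`).
#' @return Shannon index (scalar).
#' @export
shannon_index <- function(counts, base = exp(1)) {
  if (any(counts < 0)) abort("counts must be non-negative")
  tot <- sum(counts)
  if (tot <= 0) abort("Shannon index undefined for an all-zero sample")
  p <- counts[counts > 0] / tot
  -sum(p * log(p)) / log(base)
}

#' Per-sample rarefied Shannon diversity
#'
#' Rarefies all samples to a common depth (single seeded draw) and returns
#' one Shannon value per retained sample.
#'
#' @inheritParams rarefy_counts
#' @return Tibble: `sample_id`, metadata columns, `rarefaction_depth`,
#'   `shannon` (nats).
#' @export
rarefied_shannon <- function(x, depth, seed = 1L) {
  r <- rarefy_counts(x, depth, seed = seed)
  m <- pn_matrix(r)
  dplyr::mutate(pn_meta(r),
                rarefaction_depth = as.integer(depth),
                shannon = apply(m, 1, shannon_index))
}

#' Combine adjacent core intervals
#'
#' Sums counts within each bin of stratigraphically adjacent intervals.
#' A binned interval's age is the midpoint of its members' ages and its
#' depth the midpoint of member depths (reported with a range label in
#' `sample_id`).
#'
#' @param x A count tibble with `depth_cm` (and usually `age_ce`) metadata,
#'   rows in stratigraphic order.
#' @param bins List of integer vectors of row indices; each must be a run of
#'   consecutive indices and bins must not overlap. Rows not mentioned are
#'   kept as singleton bins.
#' @return A count tibble with one row per bin, in stratigraphic order.
#' @export
bin_intervals <- function(x, bins) {
  n <- nrow(x)
  for (b in bins) {
    if (length(b) == 0 || any(b < 1 | b > n)) abort("bin index out of range")
    if (!all(diff(sort(b)) == 1)) abort("bins must contain consecutive intervals")
  }
  used <- unlist(bins)
  if (anyDuplicated(used)) abort("bins must be disjoint")
  all_bins <- c(bins, as.list(setdiff(seq_len(n), used)))
  all_bins <- all_bins[order(vapply(all_bins, min, 1L))]
  m <- pn_matrix(x)
  rows <- purrr::map(all_bins, function(b) {
    cnt <- as.integer(colSums(m[b, , drop = FALSE]))
    names(cnt) <- colnames(m)
    meta <- tibble::tibble(
      sample_id = if (length(b) == 1) x$sample_id[b] else
        paste0(x$sample_id[min(b)], "-", x$sample_id[max(b)])
    )
    if ("group" %in% names(x)) meta$group <- x$group[min(b)]
    if ("time_slice" %in% names(x)) meta$time_slice <- x$time_slice[min(b)]
    if ("depth_cm" %in% names(x)) meta$depth_cm <- mean(range(x$depth_cm[b]))
    if ("age_ce" %in% names(x)) meta$age_ce <- mean(range(x$age_ce[b]))
    dplyr::bind_cols(meta, tibble::as_tibble(as.list(cnt)))
  })
  dplyr::bind_rows(rows)
}

#' Classify a human impact index score
#'
#' Watershed land-use intensity scores in \[0, 1\] map to impact classes:
#' `hii <= 0.1` is `"low"`, `0.1 < hii < 0.5` is `"moderate"`, and
#' `hii >= 0.5` is `"high"`.
#'
#' @param hii Numeric vector of scores in \[0, 1\].
#' @return Factor with levels `low`, `moderate`, `high`.
#' @export
classify_hii <- function(hii) {
  if (any(is.na(hii) | hii < 0 | hii > 1)) {
    abort("hii scores must lie in [0, 1]")
  }
  cls <- ifelse(hii <= 0.1, "low", ifelse(hii < 0.5, "moderate", "high"))
  factor(cls, levels = c("low", "moderate", "high"))
}
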