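#' Configuration for the synthetic assemblage generator
#'
#' The generator draws a latent Gaussian vector per sample from a
#' block-structured correlation matrix (taxa grouped into modules with
#' within-module correlation `rho_w`, zero between modules, and a small
#' number of negative pairs planted by flipping one taxon's loading), maps
#' it through an exponential link onto a dominance profile, and draws
#' multinomial counts at a per-sample counting effort uniform on
#' `total_range`. Because the downstream statistic is rank-based, only the
#' latent rank structure matters; any monotone link would do.
#'
#' @param n_taxa Number of taxa (default 45, the scale of a regional
#'   subfossil cladoceran pool).
#' @param n_samples Number of samples (lakes or intervals; default 100).
#' @param n_modules Number of latent association modules (default 9,
#'   i.e. guilds of ~5 taxa at the default pool size; small guilds keep
#'   each module's aggregate share of the composition modest, so closure
#'   effects stay mild).
#' @param rho_w Within-module latent correlation, in \[0, 1) (default 0.7).
#' @param prop_negative Fraction of modules that receive one sign-flipped
#'   (negatively associated) taxon (default 0.2).
#' @param dominance_ratio Geometric decay of log-abundance means across
#'   taxa ranked by abundance; a few dominant taxa, many rare (default
#'   0.92, a ~45-fold abundance range over the default pool that keeps the
#'   rarest taxa countable at the configured counting effort).
#' @param latent_scale Scale of the latent effect on log abundance
#'   (default 1).
#' @param total_range Per-sample total-count range, inclusive (default
#'   `c(100, 600)`, the counting-effort range of subfossil counts).
#' @param seed Integer seed.
#' @return A list of class `pn_synth_config`.
#' @export
synth_config <- function(n_taxa = 45, n_samples = 100, n_modules = 9,
                         rho_w = 0.7, prop_negative = 0.2,
                         dominance_ratio = 0.92, latent_scale = 1,
                         total_range = c(100L, 600L), seed = 1L) {
  if (rho_w < 0 || rho_w >= 1) abort("rho_w must lie in [0, 1)")
  if (any(total_range < 1) || total_range[2] < total_range[1]) {
    abort("total_range must be positive and ordered")
  }
  structure(list(n_taxa = n_taxa, n_samples = n_samples,
                 n_modules = n_modules, rho_w = rho_w,
                 prop_negative = prop_negative,
                 dominance_ratio = dominance_ratio,
                 latent_scale = latent_scale,
                 total_range = as.integer(total_range), seed = seed),
            class = "pn_synth_config")
}

# module memberships: taxa split as evenly as possible over modules
synth_modules <- function(n_taxa, n_modules) {
  sort(rep_len(seq_len(n_modules), n_taxa))
}

# block correlation matrix with one optional sign-flipped taxon per module
synth_sigma <- function(modules, rho_w, flip) {
  n <- length(modules)
  sgn <- rep(1, n)
  sgn[flip] <- -1
  sigma <- diag(n)
  for (m in unique(modules)) {
    idx <- which(modules == m)
    sigma[idx, idx] <- rho_w
  }
  diag(sigma) <- 1
  sigma <- sigma * tcrossprod(sgn)
  diag(sigma) <- 1
  ev <- min(eigen(sigma, symmetric = TRUE, only.values = TRUE)$values)
  if (ev < -1e-8) abort("planted correlation matrix is not positive semi-definite; lower rho_w")
  sigma
}

synth_truth <- function(cfg, modules, sigma, change_point = NA_integer_) {
  pairs <- which(abs(sigma) >= min(cfg$rho_w, 0.999) - 1e-9 &
                   upper.tri(sigma), arr.ind = TRUE)
  planted <- tibble::tibble(
    taxon_a = paste0("taxon_", sprintf("%02d", pairs[, 1])),
    taxon_b = paste0("taxon_", sprintf("%02d", pairs[, 2])),
    sign = sign(sigma[pairs])
  )
  if (cfg$rho_w == 0) planted <- planted[0, ]
  list(sigma = sigma, modules = modules, planted_pairs = planted,
       change_point = change_point)
}

# one latent draw -> one multinomial count row
synth_counts <- function(z, mu, cfg) {
  w <- exp(matrix(mu, nrow(z), ncol(z), byrow = TRUE) + cfg$latent_scale * z)
  total <- sample(cfg$total_range[1]:cfg$total_range[2], nrow(z), replace = TRUE)
  counts <- matrix(0L, nrow(z), ncol(z))
  for (i in seq_len(nrow(z))) {
    counts[i, ] <- as.integer(rmultinom(1, total[i], w[i, ] / sum(w[i, ])))
  }
  counts
}

synth_latent <- function(n, sigma) {
  ch <- chol(sigma + diag(1e-10, nrow(sigma)))
  matrix(rnorm(n * nrow(sigma)), n) %*% ch
}

#' Generate a synthetic assemblage with planted associations
#'
#' Top-bottom-style generator: many sites, no stratigraphic structure,
#' planted pairwise associations defined by the latent block-correlation
#' matrix. Deterministic under `cfg$seed`.
#'
#' @param cfg A [synth_config()].
#' @return List with `counts` (a count tibble) and `truth` (latent
#'   correlation matrix, module memberships, planted signed pairs).
#' @export
generate_assemblage <- function(cfg) {
  stopifnot(inherits(cfg, "pn_synth_config"))
  set.seed(cfg$seed)
  modules <- synth_modules(cfg$n_taxa, cfg$n_modules)
  n_flip <- round(cfg$prop_negative * cfg$n_modules)
  flip <- if (n_flip > 0 && cfg$rho_w > 0) {
    vapply(seq_len(n_flip), function(m) max(which(modules == m)), 1L)
  } else integer(0)
  sigma <- synth_sigma(modules, cfg$rho_w, flip)
  mu <- log(cfg$dominance_ratio) * (seq_len(cfg$n_taxa) - 1)
  z <- synth_latent(cfg$n_samples, sigma)
  counts <- synth_counts(z, mu, cfg)
  colnames(counts) <- paste0("taxon_", sprintf("%02d", seq_len(cfg$n_taxa)))
  x <- dplyr::bind_cols(
    tibble::tibble(sample_id = paste0("site_", sprintf("%03d", seq_len(cfg$n_samples)))),
    tibble::as_tibble(counts)
  )
  list(counts = x, truth = synth_truth(cfg, modules, sigma))
}

#' Generate a synthetic full-core record with a compositional change point
#'
#' Stratigraphic generator: intervals ordered from core top (youngest)
#' down, a linear age model spanning roughly 1750 CE (bottom) to 2017 CE
#' (top), and a log-abundance offset `shift` applied to the intervals above
#' (younger than) `change_point`, emulating an early-20th-century
#' assemblage shift.
#'
#' @param cfg A [synth_config()]; `n_samples` is the number of intervals
#'   (typically 10-30) and `n_taxa` around 20 for a within-lake pool.
#' @param change_point Interval index (counting from the core top) of the
#'   last "modern" interval; both sides must have at least 5 intervals.
#' @param shift Numeric log-abundance offset, recycled over taxa, added to
#'   the modern intervals' dominance profile.
#' @param ar Optional temporal persistence of the latent assemblage state
#'   between adjacent intervals (stationary AR(1) coefficient, default 0:
#'   independent intervals). The stationary marginal keeps the planted
#'   cross-taxon correlation matrix. Note that persistent drift is itself
#'   assemblage change, so nonzero `ar` weakens the one-zone null.
#' @return List with `counts` (count tibble with `depth_cm` and `age_ce`)
#'   and `truth` (including `change_point`).
#' @export
generate_zoned_core <- function(cfg, change_point, shift, ar = 0) {
  stopifnot(inherits(cfg, "pn_synth_config"))
  n <- cfg$n_samples
  if (change_point <= 1 || change_point >= n) abort("change_point must be interior")
  if (change_point < 5 || n - change_point < 5) {
    abort("each side of the change point needs at least 5 intervals")
  }
  set.seed(cfg$seed)
  modules <- synth_modules(cfg$n_taxa, cfg$n_modules)
  sigma <- synth_sigma(modules, cfg$rho_w, integer(0))
  mu <- log(cfg$dominance_ratio) * (seq_len(cfg$n_taxa) - 1)
  shift <- rep_len(shift, cfg$n_taxa)
  eps <- synth_latent(n, sigma)
  z <- eps
  if (ar > 0) {
    # stationary AR(1) in time: z_t = ar z_{t-1} + sqrt(1-ar^2) eps_t
    for (i in 2:n) z[i, ] <- ar * z[i - 1, ] + sqrt(1 - ar^2) * eps[i, ]
  }
  mu_mat <- matrix(mu, n, cfg$n_taxa, byrow = TRUE)
  modern <- seq_len(change_point)
  mu_mat[modern, ] <- mu_mat[modern, , drop = FALSE] +
    matrix(shift, length(modern), cfg$n_taxa, byrow = TRUE)
  w <- exp(mu_mat + cfg$latent_scale * z)
  total <- sample(cfg$total_range[1]:cfg$total_range[2], n, replace = TRUE)
  counts <- matrix(0L, n, cfg$n_taxa)
  for (i in seq_len(n)) {
    counts[i, ] <- as.integer(rmultinom(1, total[i], w[i, ] / sum(w[i, ])))
  }
  colnames(counts) <- paste0("taxon_", sprintf("%02d", seq_len(cfg$n_taxa)))
  depth <- seq_len(n) - 0.5
  age <- round(seq(2017, 1750, length.out = n))
  x <- dplyr::bind_cols(
    tibble::tibble(sample_id = paste0("int_", sprintf("%02d", seq_len(n))),
                   depth_cm = depth, age_ce = age),
    tibble::as_tibble(counts)
  )
  list(counts = x,
       truth = synth_truth(cfg, modules, sigma,
                           change_point = as.integer(change_point)))
}

#' Generate a synthetic top-bottom landscape dataset
#'
#' Composes one assemblage per impact class and time slice, sharing a
#' latent module structure but allowing the within-module correlation to
#' differ per cell — e.g. a weakened `rho_w` in the modern slice of the
#' high-impact class plants a decorrelation (connectance loss) for
#' end-to-end power checks. Class HII scores are drawn uniformly within
#' the class's score band.
#'
#' @param n_per_class Named integer vector of lakes per impact class
#'   (default `c(low = 43, moderate = 39, high = 19)`, the design's class
#'   sizes).
#' @param rho_w Named list/vector giving `rho_w` per `"class:slice"` cell;
#'   unnamed scalar applies everywhere. Default 0.7 everywhere.
#' @param cfg Base [synth_config()]; `n_samples` is ignored.
#' @return List with `counts` (count tibble with `group`, `time_slice`,
#'   `hii`) and `truth` (per-cell planted structure).
#' @export
generate_topbottom <- function(n_per_class = c(low = 43, moderate = 39, high = 19),
                               rho_w = 0.7,
                               cfg = synth_config()) {
  classes <- names(n_per_class)
  hii_band <- list(low = c(0, 0.1), moderate = c(0.11, 0.49), high = c(0.5, 1))
  cell_rho <- function(cls, slice) {
    key <- paste0(cls, ":", slice)
    if (length(rho_w) == 1 && is.null(names(rho_w))) return(rho_w[[1]])
    if (key %in% names(rho_w)) rho_w[[key]] else 0.7
  }
  out <- list(); truth <- list(); k <- 0
  for (cls in classes) {
    set.seed(cfg$seed + 17L * k)
    hii <- round(runif(n_per_class[[cls]], hii_band[[cls]][1], hii_band[[cls]][2]), 3)
    for (slice in c("bottom", "top")) {
      k <- k + 1
      cell_cfg <- cfg
      cell_cfg$n_samples <- n_per_class[[cls]]
      cell_cfg$rho_w <- cell_rho(cls, slice)
      cell_cfg$seed <- cfg$seed + 1000L * k
      sim <- generate_assemblage(cell_cfg)
      d <- dplyr::mutate(sim$counts,
                         sample_id = paste(cls, slice, .data$sample_id, sep = "_"),
                         group = cls, time_slice = slice, hii = hii,
                         .after = 1)
      d <- dplyr::relocate(d, "sample_id")
      out[[k]] <- d
      truth[[paste0(cls, ":", slice)]] <- sim$truth
    }
  }
  list(counts = dplyr::bind_rows(out), truth = truth)
}

#' Study conditions for the synthetic full-core record
#'
#' [synth_config()] preset for the stratigraphic (full-core) mode: a
#' within-lake pool of 20 taxa over 20 one-centimetre intervals, and a
#' calmer latent scale (0.6) than the landscape mode's 1 — interval-to-
#' interval fluctuation within one lake is smaller than compositional
#' contrast across lakes.
#'
#' @param n_taxa,n_samples,latent_scale See [synth_config()].
#' @param ... Further arguments passed to [synth_config()].
#' @return A `pn_synth_config`.
#' @export
core_config <- function(n_taxa = 20, n_samples = 20, latent_scale = 0.6, ...) {
  synth_config(n_taxa = n_taxa, n_samples = n_samples,
               latent_scale = latent_scale, ...)
}
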