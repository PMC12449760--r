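#' Erdos-Renyi random network
#'
#' G(n, p): each of the `S(S-1)/2` unordered node pairs becomes an edge
#' independently with probability `p`. This is the null model used to ask
#' whether an observed network's metrics could arise from random wiring at
#' the observed size and connectance.
#'
#' @param S Node count (>= 2).
#' @param p Edge probability in \[0, 1\].
#' @param seed Optional integer seed for a reproducible draw.
#' @return A `pn_network` (alpha NA, label `"ER"`).
#' @export
erdos_renyi <- function(S, p, seed = NULL) {
  if (S < 2) abort("S must be at least 2")
  if (is.na(p) || p < 0 || p > 1) abort("p must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  g <- igraph::sample_gnp(S, p, directed = FALSE)
  igraph::V(g)$name <- paste0("n", seq_len(S))
  new_pn_network(g, label = "ER")
}

#' Constrained random-network ensemble
#'
#' Generates `n_reps` Erdos-Renyi networks constrained by the observed
#' node count S and edge probability p (the observed connectance), and
#' summarizes each with [network_summary()]. Replicates with zero edges
#' get NA modularity. Per-replicate seeds are derived deterministically
#' from `seed`.
#'
#' @param S Node count.
#' @param p Edge probability (observed connectance).
#' @param n_reps Ensemble size (default 30, the scale of the per-class
#'   sample sizes the design mirrors).
#' @param seed Integer root seed.
#' @param label Group/zone label attached to every replicate row.
#' @param metrics Metric subset passed to [network_summary()].
#' @return Tibble with `n_reps` rows: `label`, `replicate`, `S`, `L` and
#'   the requested metrics.
#' @export
null_ensemble <- function(S, p, n_reps = 30, seed = 1L, label = "group",
                          metrics = c("connectance", "modularity",
                                      "mean_degree", "skewness")) {
  reps <- purrr::map(seq_len(n_reps), function(r) {
    net <- erdos_renyi(S, p, seed = seed + 7919L * r)
    s <- network_summary(net, metrics = metrics)
    s$label <- label
    s$replicate <- r
    s
  })
  dplyr::relocate(dplyr::bind_rows(reps), "label", "replicate")
}

#' One-way ANOVA with Tukey HSD post-hoc contrasts
#'
#' Fixed-effects one-way ANOVA of a metric across groups, followed by
#' Tukey honest-significant-difference pairwise p-values from the
#' studentized range distribution. Degenerate input (zero pooled
#' variance) is flagged, with `p = 1` when the group means are also equal.
#'
#' @param data Data frame with the value and group columns.
#' @param value,group Column names (strings) of the metric values and the
#'   group labels.
#' @return List of class `pn_anova`: `f_statistic`, `p_value`, `df`,
#'   `pairwise` (tibble of Tukey contrasts), `degenerate`.
#' @export
anova_tukey <- function(data, value = "value", group = "group") {
  v <- data[[value]]
  gr <- factor(data[[group]])
  ok <- !is.na(v)
  if (sum(!ok) > 0) warn(paste0("dropping ", sum(!ok), " missing value(s)"))
  v <- v[ok]; gr <- droplevels(gr[ok])
  if (nlevels(gr) < 2) abort("need at least 2 groups")
  if (min(table(gr)) < 2) abort("each group needs at least 2 values")
  within_var <- tapply(v, gr, stats::var)
  if (all(within_var == 0)) {
    means <- tapply(v, gr, mean)
    equal <- max(means) - min(means) == 0
    pw <- tibble::as_tibble(t(combn(levels(gr), 2)), .name_repair = ~c("group_a", "group_b"))
    pw$diff <- apply(pw, 1, function(r) means[r[2]] - means[r[1]])
    pw$p_tukey <- if (equal) 1 else 0
    return(structure(list(f_statistic = if (equal) 0 else Inf,
                          p_value = if (equal) 1 else 0,
                          df = c(nlevels(gr) - 1, length(v) - nlevels(gr)),
                          pairwise = pw, degenerate = TRUE),
                     class = "pn_anova"))
  }
  dd <- data.frame(value = v, group = gr)
  fit <- aov(value ~ group, data = dd)
  an <- summary(fit)[[1]]
  tuk <- TukeyHSD(fit)$group
  pairs <- strsplit(rownames(tuk), "-", fixed = TRUE)
  pw <- tibble::tibble(
    group_a = vapply(pairs, `[`, "", 2),
    group_b = vapply(pairs, `[`, "", 1),
    diff = tuk[, "diff"],
    p_tukey = tuk[, "p adj"]
  )
  structure(list(f_statistic = an[["F value"]][1],
                 p_value = an[["Pr(>F)"]][1],
                 df = c(an[["Df"]][1], an[["Df"]][2]),
                 pairwise = pw, degenerate = FALSE),
            class = "pn_anova")
}

#' @export
print.pn_anova <- function(x, ...) {
  cat("<pn_anova> F(", x$df[1], ", ", x$df[2], ") = ",
      format(x$f_statistic, digits = 4), ", p = ",
      format(x$p_value, digits = 4), "\n", sep = "")
  invisible(x)
}

#' @method tidy pn_anova
#' @export
tidy.pn_anova <- function(x, ...) {
  dplyr::mutate(x$pairwise, f_statistic = x$f_statistic,
                p_anova = x$p_value, degenerate = x$degenerate)
}

#' @method glance pn_anova
#' @export
glance.pn_anova <- function(x, ...) {
  tibble::tibble(f_statistic = x$f_statistic, p_value = x$p_value,
                 df_between = x$df[1], df_within = x$df[2],
                 degenerate = x$degenerate)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up FDR adjustment with monotonicity enforcement, applied within a
#' test family (here: the four network-metric tests plus the Shannon
#' diversity test of one impact class or one lake).
#'
#' @param p Numeric vector of raw p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
fdr_adjust <- function(p) {
  if (length(p) == 0) abort("empty p-value family")
  if (any(is.na(p) | p < 0 | p > 1)) abort("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Mann-Whitney-Wilcoxon rank-sum test
#'
#' Two-sided test of a location shift between two samples: exact p for
#' small samples without ties, normal approximation with tie correction
#' otherwise. Degenerate pooled data (all values equal) gives p = 1 with a
#' flag.
#'
#' @param x,y Numeric samples (non-empty).
#' @return Tibble: `u_statistic` (U for `x`), `p_value`, `method`,
#'   `degenerate`.
#' @export
mann_whitney <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) abort("both samples must be non-empty")
  pooled <- c(x, y)
  if (max(pooled) - min(pooled) == 0) {
    return(tibble::tibble(u_statistic = length(x) * length(y) / 2,
                          p_value = 1, method = "degenerate",
                          degenerate = TRUE))
  }
  ties <- anyDuplicated(pooled) > 0
  small <- length(x) < 50 && length(y) < 50
  exact <- small && !ties
  wt <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = TRUE))
  tibble::tibble(u_statistic = unname(wt$statistic), p_value = wt$p.value,
                 method = if (exact) "exact" else "normal approximation",
                 degenerate = FALSE)
}

#' Compare groups' network metrics against constrained null ensembles
#'
#' For each group (time period or zone) builds an Erdos-Renyi ensemble
#' constrained by that group's observed S and connectance, runs a one-way
#' ANOVA + Tukey HSD across groups for each metric, and FDR-adjusts the
#' family of p-values.
#'
#' @param observed Tibble with one row per group: `label`, `S`,
#'   `connectance` (e.g. [network_summary()] rows).
#' @param n_reps Replicates per ensemble (default 30).
#' @param seed Integer root seed; per-group streams are derived from it.
#' @param metrics Metrics to test (default all four).
#' @param extra_p Optional named numeric of additional raw p-values (e.g.
#'   the rarefied-Shannon Mann-Whitney p) to include in the FDR family.
#' @return List of class `pn_comparison`: `tests` (tibble: metric, F, raw
#'   p, Tukey pairwise p per group pair, FDR-adjusted p), `ensemble` (all
#'   replicate metric rows).
#' @export
compare_groups <- function(observed, n_reps = 30, seed = 1L,
                           metrics = c("connectance", "modularity",
                                       "mean_degree", "skewness"),
                           extra_p = NULL) {
  if (nrow(observed) < 2) abort("need at least 2 groups to compare")
  ens <- purrr::map2(observed$label, seq_len(nrow(observed)), function(lab, i) {
    null_ensemble(observed$S[i], observed$connectance[i], n_reps = n_reps,
                  seed = seed + 104729L * i, label = lab, metrics = metrics)
  })
  ens <- dplyr::bind_rows(ens)
  tests <- purrr::map(metrics, function(mt) {
    at <- anova_tukey(ens, value = mt, group = "label")
    dplyr::mutate(tidy(at), metric = mt, .before = 1)
  })
  tests <- dplyr::bind_rows(tests)
  fam <- dplyr::distinct(tests, .data$metric, .keep_all = TRUE)
  fam_p <- setNames(fam$p_anova, fam$metric)
  if (!is.null(extra_p)) fam_p <- c(fam_p, extra_p)
  adj <- fdr_adjust(fam_p)
  tests$p_fdr <- adj[tests$metric]
  extra <- if (!is.null(extra_p)) {
    tibble::tibble(metric = names(extra_p), p_anova = unname(extra_p),
                   p_fdr = unname(adj[names(extra_p)]))
  } else NULL
  structure(list(tests = tests, extra_tests = extra, ensemble = ens,
                 n_reps = n_reps, seed = seed),
            class = "pn_comparison")
}

#' @export
print.pn_comparison <- function(x, ...) {
  cat("<pn_comparison> ", length(unique(x$ensemble$label)), " groups x ",
      x$n_reps, " null replicates\n", sep = "")
  print(x$tests[, c("metric", "group_a", "group_b", "f_statistic",
                    "p_anova", "p_tukey", "p_fdr")])
  invisible(x)
}

#' @method tidy pn_comparison
#' @export
tidy.pn_comparison <- function(x, ...) {
  out <- x$tests
  out$stars <- significance_stars(out$p_fdr)
  out
}

#' Significance stars at the conventional thresholds
#'
#' @param p Numeric p-values.
#' @return Character vector: `****` p < 1e-4, `***` p < 1e-3, `**` p <
#'   0.01, `*` p < 0.05, `""` otherwise.
#' @export
significance_stars <- function(p) {
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 0.05, Inf),
      labels = c("****", "***", "**", "*", ""), right = FALSE) |>
    as.character()
}
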