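#' Run configuration for the two study designs
#'
#' Defaults follow the conventions of the analysis: an edge threshold of
#' P < 0.01 for the landscape (top-bottom) design and P < 0.05 within a
#' single core (smaller taxon pool, within-lake comparison); 30 null
#' replicates; a minimum of 5 intervals per zone; resolution 1 for
#' modularity; rarefaction to the minimum retained sample total unless a
#' depth is given.
#'
#' @param mode `"topbottom"` or `"fullcore"`.
#' @param alpha Edge significance level; mode-specific default.
#' @param rarefaction_depth Individuals per sample for diversity; `NULL`
#'   means the minimum sample total in the data.
#' @param min_intervals Minimum intervals per zone (fullcore).
#' @param n_reps Null-ensemble size.
#' @param gamma Modularity resolution.
#' @param truncate_age Earliest age (CE) retained in fullcore mode
#'   (default 1750).
#' @param seed Integer seed for all randomness in the run.
#' @return List of class `pn_config`.
#' @export
run_config <- function(mode = c("topbottom", "fullcore"), alpha = NULL,
                       rarefaction_depth = NULL, min_intervals = 5,
                       n_reps = 30, gamma = 1, truncate_age = 1750,
                       seed = 1L) {
  mode <- match.arg(mode)
  default_alpha <- if (mode == "topbottom") 0.01 else 0.05
  if (is.null(alpha)) {
    alpha <- default_alpha
  } else if (alpha != default_alpha) {
    warn(paste0("alpha = ", alpha, " overrides the ", mode,
                " default of ", default_alpha))
  }
  structure(list(mode = mode, alpha = alpha,
                 rarefaction_depth = rarefaction_depth,
                 min_intervals = min_intervals, n_reps = n_reps,
                 gamma = gamma, truncate_age = truncate_age,
                 seed = as.integer(seed)),
            class = "pn_config")
}

pick_depth <- function(x, cfg) {
  cfg$rarefaction_depth %||% min(rowSums(pn_matrix(x)))
}

#' Landscape (top-bottom) analysis
#'
#' End-to-end run of the snapshot design: classify sites by human impact
#' index (unless a `group` column is already present), build one network
#' per impact class and time slice, summarize the four metrics per
#' network, compare time slices within each class against constrained
#' Erdos-Renyi ensembles (ANOVA + Tukey), test rarefied Shannon diversity
#' between slices (Mann-Whitney), and FDR-adjust the five p-values within
#' each class.
#'
#' @param x Count tibble with `time_slice` (`"top"`/`"bottom"`) and either
#'   `group` or `hii` per sample.
#' @param config A [run_config()] with mode `"topbottom"`.
#' @return List of class `pn_report`: `metrics`, `networks`, `tests`,
#'   `diversity`, `config`.
#' @export
run_topbottom <- function(x, config = run_config("topbottom")) {
  stopifnot(inherits(config, "pn_config"))
  if (!"time_slice" %in% names(x)) abort("topbottom mode needs a 'time_slice' column")
  if (!"group" %in% names(x)) {
    if (!"hii" %in% names(x)) abort("need either a 'group' or an 'hii' column")
    x$group <- as.character(classify_hii(x$hii))
  }
  nets <- build_group_networks(x, alpha = config$alpha)
  metrics <- dplyr::bind_rows(purrr::map(nets$network, network_summary,
                                         gamma = config$gamma))
  metrics <- dplyr::bind_cols(nets[, intersect(c("group", "time_slice"), names(nets))],
                              metrics)
  depth <- pick_depth(x, config)
  div <- rarefied_shannon(x, depth, seed = config$seed)
  tests <- purrr::imap(split(metrics, metrics$group), function(mm, cls) {
    if (nrow(mm) < 2) return(NULL)
    dd <- div[div$group == cls, ]
    mw <- mann_whitney(dd$shannon[dd$time_slice == "top"],
                       dd$shannon[dd$time_slice == "bottom"])
    cmp <- compare_groups(mm, n_reps = config$n_reps,
                          seed = config$seed + utf8ToInt(substr(cls, 1, 1)),
                          extra_p = c(shannon = mw$p_value))
    out <- tidy(cmp)
    out$group <- cls
    extra <- dplyr::mutate(cmp$extra_tests, group = cls,
                           u_statistic = mw$u_statistic)
    list(tests = out, extra = extra)
  })
  tests <- purrr::compact(tests)
  structure(list(
    metrics = metrics,
    networks = nets,
    tests = dplyr::bind_rows(purrr::map(tests, "tests")),
    diversity_tests = dplyr::bind_rows(purrr::map(tests, "extra")),
    diversity = div,
    config = config
  ), class = "pn_report")
}

#' Full-core (zonal) analysis
#'
#' End-to-end run of the stratigraphic design: truncate the record at the
#' configured earliest age, delineate zones (Hellinger, Bray-Curtis,
#' CONISS, broken stick, minimum zone size), build one depth-by-taxon
#' network per zone, summarize metrics, compare zones against constrained
#' Erdos-Renyi ensembles, test rarefied Shannon diversity across zones,
#' and FDR-adjust within the lake. With a single significant zone, no
#' between-zone comparison is attempted.
#'
#' @param x Count tibble in stratigraphic order with `depth_cm` and
#'   `age_ce`.
#' @param config A [run_config()] with mode `"fullcore"`.
#' @param bins Optional list of interval-index bins passed to
#'   [bin_intervals()] before the diversity calculation (used when recent
#'   intervals accumulate much faster than deep ones).
#' @return List of class `pn_report`: `zones`, `metrics`, `networks`,
#'   `tests`, `diversity`, `config`.
#' @export
run_fullcore <- function(x, config = run_config("fullcore"), bins = NULL) {
  stopifnot(inherits(config, "pn_config"))
  if (!all(c("depth_cm", "age_ce") %in% names(x))) {
    abort("fullcore mode needs 'depth_cm' and 'age_ce' columns")
  }
  x <- x[x$age_ce >= config$truncate_age, ]
  if (nrow(x) < 2 * config$min_intervals) {
    abort("record too short to form two zones after truncation")
  }
  zones <- zonate_core(x, min_intervals = config$min_intervals)
  xz <- dplyr::mutate(x, group = paste0("zone_", zones$zone))
  div_input <- if (!is.null(bins)) bin_intervals(xz, bins) else xz
  depth <- pick_depth(div_input, config)
  div <- rarefied_shannon(div_input, depth, seed = config$seed)
  if (max(zones$zone) < 2) {
    return(structure(list(zones = zones, metrics = NULL, networks = NULL,
                          tests = NULL, diversity_tests = NULL,
                          diversity = div, config = config),
                     class = "pn_report"))
  }
  nets <- build_group_networks(xz, alpha = config$alpha)
  metrics <- dplyr::bind_rows(purrr::map(nets$network, network_summary,
                                         gamma = config$gamma))
  metrics <- dplyr::bind_cols(nets[, "group"], metrics)
  zs <- attr(zones, "zone_summary")
  metrics$median_year <- zs$median_year[match(metrics$group,
                                              paste0("zone_", zs$zone))]
  div_split <- split(div$shannon, div$group)
  mw <- if (length(div_split) >= 2) {
    mann_whitney(div_split[[1]], div_split[[2]])
  } else tibble::tibble(u_statistic = NA_real_, p_value = NA_real_,
                        method = "none", degenerate = TRUE)
  cmp <- compare_groups(metrics[, c("label", "S", "connectance")],
                        n_reps = config$n_reps, seed = config$seed,
                        extra_p = c(shannon = mw$p_value))
  tests <- tidy(cmp)
  structure(list(zones = zones, metrics = metrics, networks = nets,
                 tests = tests,
                 diversity_tests = dplyr::mutate(cmp$extra_tests,
                                                 u_statistic = mw$u_statistic),
                 diversity = div, config = config),
            class = "pn_report")
}

#' @export
print.pn_report <- function(x, ...) {
  cat("<pn_report> mode =", x$config$mode, "\n")
  if (!is.null(x$metrics)) {
    cat("\nNetwork metrics:\n")
    print(format_metrics(x$metrics))
  }
  if (!is.null(x$tests)) {
    cat("\nNull-ensemble tests:\n")
    print(x$tests[, c("metric", "group_a", "group_b", "p_anova",
                      "p_tukey", "p_fdr", "stars")])
  }
  invisible(x)
}

#' Write a report's tables to a directory
#'
#' Writes `metrics.csv`, `edges_<label>.csv` per network, `zones.csv`
#' (fullcore), `tests.csv`, `diversity.csv` and `report.json` (config and
#' seed provenance).
#'
#' @param report A `pn_report`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wcsv <- function(d, f) readr::write_csv(d, file.path(dir, f))
  if (!is.null(report$metrics)) wcsv(format_metrics(report$metrics), "metrics.csv")
  if (!is.null(report$networks)) {
    for (net in report$networks$network) {
      lab <- gsub("[^A-Za-z0-9_]+", "_", net$label)
      wcsv(tidy(net), paste0("edges_", lab, ".csv"))
    }
  }
  if (!is.null(report$zones)) wcsv(tibble::as_tibble(report$zones), "zones.csv")
  if (!is.null(report$tests)) wcsv(report$tests, "tests.csv")
  if (!is.null(report$diversity)) wcsv(report$diversity, "diversity.csv")
  prov <- c(unclass(report$config),
            list(package_version = as.character(utils::packageVersion("paleonet"))))
  jsonlite::write_json(prov, file.path(dir, "report.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Command-line entry point
#'
#' Thin dispatcher over the package functions. Subcommands:
#' `simulate --seed S --out DIR [--mode topbottom|fullcore]` writes a
#' synthetic count CSV plus a truth JSON; `topbottom --input F --out DIR`
#' and `fullcore --input F --out DIR` run the pipelines; `metrics --input
#' F` prints a one-row metrics table for an edge-list CSV
#' (`taxon_a,taxon_b`) with `--nodes` optionally naming a node-list CSV.
#'
#' @param args Character vector of command-line arguments.
#' @return Integer exit status (0 on success), invisibly.
#' @export
pn_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- function() {
    message("usage: paleonet <simulate|topbottom|fullcore|metrics> [--input F] [--out DIR] [--seed S] [--alpha A] [--mode M] [--nodes F]")
    invisible(1L)
  }
  if (length(args) == 0) return(usage())
  cmd <- args[1]
  opts <- list(seed = 1L, mode = "topbottom", alpha = NULL)
  rest <- args[-1]
  i <- 1
  while (i <= length(rest)) {
    key <- sub("^--", "", rest[i])
    if (!grepl("^--", rest[i]) || i == length(rest)) return(usage())
    opts[[key]] <- rest[i + 1]
    i <- i + 2
  }
  opts$seed <- as.integer(opts$seed)
  tryCatch({
    switch(cmd,
      simulate = {
        if (is.null(opts$out)) { message("simulate needs --out"); return(invisible(1L)) }
        dir.create(opts$out, showWarnings = FALSE, recursive = TRUE)
        if (opts$mode == "fullcore") {
          sim <- generate_zoned_core(synth_config(n_taxa = 20, n_samples = 20,
                                                  seed = opts$seed),
                                     change_point = 10, shift = rep(c(2, 0), 10))
        } else {
          sim <- generate_assemblage(synth_config(seed = opts$seed))
        }
        readr::write_csv(sim$counts, file.path(opts$out, "counts.csv"))
        truth <- list(modules = sim$truth$modules,
                      planted_pairs = sim$truth$planted_pairs,
                      change_point = sim$truth$change_point,
                      sigma = sim$truth$sigma)
        jsonlite::write_json(truth, file.path(opts$out, "truth.json"),
                             auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
        invisible(0L)
      },
      topbottom = ,
      fullcore = {
        if (is.null(opts$input) || is.null(opts$out)) {
          message(cmd, " needs --input and --out"); return(invisible(1L))
        }
        x <- read_count_matrix(opts$input)
        cfg <- run_config(cmd, alpha = if (!is.null(opts$alpha)) as.numeric(opts$alpha),
                          seed = opts$seed)
        rep <- if (cmd == "topbottom") run_topbottom(x, cfg) else run_fullcore(x, cfg)
        write_report(rep, opts$out)
        invisible(0L)
      },
      metrics = {
        if (is.null(opts$input)) { message("metrics needs --input"); return(invisible(1L)) }
        edges <- readr::read_csv(opts$input, show_col_types = FALSE)
        verts <- if (!is.null(opts$nodes)) {
          readr::read_csv(opts$nodes, show_col_types = FALSE)[[1]]
        } else unique(c(edges[[1]], edges[[2]]))
        g <- igraph::graph_from_data_frame(edges[, 1:2], directed = FALSE,
                                           vertices = data.frame(name = verts))
        print(format_metrics(network_summary(g)))
        invisible(0L)
      },
      usage()
    )
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    invisible(1L)
  })
}
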