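test_that("count matrices round-trip through CSV and bad input is caught", {
  x <- tiny_counts()
  path <- write_counts_csv(x)
  rt <- read_count_matrix(path)
  expect_equal(rt, x)

  bad <- x
  bad$taxon_b[2] <- -3L
  expect_error(read_count_matrix(write_counts_csv(bad)), "s2")

  dup <- x
  names(dup)[4] <- "taxon_a"
  p <- tempfile(fileext = ".csv")
  writeLines(c("sample_id,taxon_a,taxon_b,taxon_a", "s1,1,2,3"), p)
  expect_error(read_count_matrix(p), "duplicated taxon")

  p2 <- tempfile(fileext = ".csv")
  writeLines(c("sample_id,taxon_a", "s1,1", "s1,2"), p2)
  expect_error(read_count_matrix(p2), "duplicated sample")
})

test_that("relative abundance divides by row totals and flags empty rows", {
  x <- tibble::tibble(sample_id = c("a", "b", "c"),
                      t1 = c(4L, 1L, 0L), t2 = c(0L, 1L, 0L),
                      t3 = c(0L, 1L, 0L), t4 = c(0L, 1L, 0L))
  ra <- to_relative_abundance(x)
  expect_equal(unlist(ra[1, c("t1", "t2", "t3", "t4")], use.names = FALSE),
               c(1, 0, 0, 0))
  expect_equal(unlist(ra[2, c("t1", "t2", "t3", "t4")], use.names = FALSE),
               rep(0.25, 4))
  expect_equal(attr(ra, "zero_rows"), "c")
  # direct-division oracle on an uneven row
  y <- tibble::tibble(sample_id = "s", t1 = 3L, t2 = 1L)
  expect_equal(unlist(to_relative_abundance(y)[, c("t1", "t2")],
                      use.names = FALSE), c(3, 1) / 4)
})

test_that("relative rows sum to 1 and Hellinger rows have unit sum of squares", {
  set.seed(1)
  x <- tibble::tibble(sample_id = paste0("s", 1:20)) |>
    dplyr::bind_cols(tibble::as_tibble(matrix(rpois(20 * 8, 5), 20, 8,
                                              dimnames = list(NULL, paste0("t", 1:8)))))
  ra <- to_relative_abundance(x)
  m <- as.matrix(ra[, taxon_names(ra)])
  expect_true(all(abs(rowSums(m) - 1) < 1e-12))
  h <- hellinger_transform(ra)
  hm <- as.matrix(h[, taxon_names(h)])
  expect_true(all(abs(rowSums(hm^2) - 1) < 1e-12))
  # square-root oracle
  expect_equal(unname(hm), unname(sqrt(m)))
  # matches the standard community-ecology implementation
  expect_equal(unname(hm), unname(vegan::decostand(as.matrix(x[, -1]), "hellinger")),
               tolerance = 1e-12, ignore_attr = TRUE)
  # tag discipline
  expect_error(hellinger_transform(x), "relative")
  expect_error(hellinger_transform(h), "relative")
})

test_that("rarefaction subsamples without replacement to the exact depth", {
  x <- tiny_counts()
  r <- suppressWarnings(rarefy_counts(x, 5, seed = 7)) # s3 (total 4) is dropped
  m <- as.matrix(r[, taxon_names(r)])
  expect_true(all(rowSums(m) == 5))
  expect_true(all(m <= as.matrix(x[, taxon_names(x)][x$sample_id %in% r$sample_id, ])))
  # depth equal to a sample total reproduces its composition
  one <- x[1, ]
  expect_equal(rarefy_counts(one, 10, seed = 1)[, taxon_names(one)],
               one[, taxon_names(one)], ignore_attr = TRUE)
  # depth 1 leaves a single individual
  r1 <- rarefy_counts(one, 1, seed = 3)
  expect_equal(sum(as.matrix(r1[, taxon_names(r1)])), 1)
  # shallow samples are dropped with a warning
  expect_warning(r2 <- rarefy_counts(x, 6, seed = 1), "dropping")
  expect_false("s3" %in% r2$sample_id)
  expect_error(suppressWarnings(rarefy_counts(x, 100, seed = 1)), "every sample")
  # seeded determinism
  expect_equal(suppressWarnings(rarefy_counts(x, 5, seed = 11)),
               suppressWarnings(rarefy_counts(x, 5, seed = 11)),
               ignore_attr = TRUE)
})

test_that("rarefied counts match the hypergeometric expectation", {
  # one sample, expectation depth * p_j; average over many seeded draws
  x <- tibble::tibble(sample_id = "s", t1 = 60L, t2 = 30L, t3 = 10L)
  depth <- 20
  draws <- vapply(1:2000, function(s) {
    as.numeric(as.matrix(rarefy_counts(x, depth, seed = s)[, c("t1", "t2", "t3")]))
  }, numeric(3))
  expected <- depth * c(60, 30, 10) / 100
  # hypergeometric variance for each taxon
  n_tot <- 100
  v <- depth * (c(60, 30, 10) / n_tot) * (1 - c(60, 30, 10) / n_tot) *
    (n_tot - depth) / (n_tot - 1)
  se <- sqrt(v / 2000)
  expect_true(all(abs(rowMeans(draws) - expected) < 3 * se + 1e-9))
})

test_that("Shannon index follows the entropy formula and its invariances", {
  expect_equal(shannon_index(c(50, 50)), log(2))
  expect_equal(shannon_index(c(100, 0, 0)), 0)
  expect_equal(shannon_index(rep(1, 5)), log(5))
  # permutation invariance and the uniform maximum
  set.seed(2)
  v <- rpois(6, 10) + 1
  expect_equal(shannon_index(v), shannon_index(sample(v)))
  expect_lte(shannon_index(v), log(6))
  # agrees with the standard implementation
  expect_equal(shannon_index(v), unname(vegan::diversity(v, "shannon")))
  # configurable base
  expect_equal(shannon_index(c(50, 50), base = 2), 1)
  expect_error(shannon_index(c(0, 0)), "all-zero")
})

test_that("interval binning sums counts and takes midpoint ages", {
  x <- core_counts(6)
  b <- bin_intervals(x, list(1:3))
  expect_equal(nrow(b), 4)
  expect_equal(as.numeric(b[1, taxon_names(b)]),
               unname(colSums(as.matrix(x[1:3, taxon_names(x)]))))
  expect_equal(b$age_ce[1], mean(range(x$age_ce[1:3])))
  expect_equal(b$sample_id[1], "d1-d3")
  # conservation of totals
  expect_equal(sum(as.matrix(b[, taxon_names(b)])),
               sum(as.matrix(x[, taxon_names(x)])))
  # singleton bin leaves the row unchanged
  b1 <- bin_intervals(x, list(2L))
  expect_equal(b1[, names(x)], x)
  expect_error(bin_intervals(x, list(c(1, 3))), "consecutive")
  expect_error(bin_intervals(x, list(1:2, 2:3)), "disjoint")
})

test_that("impact classification uses the documented thresholds and is monotone", {
  expect_equal(as.character(classify_hii(0.21)), "moderate")
  expect_equal(as.character(classify_hii(0.05)), "low")
  expect_equal(as.character(classify_hii(0.5)), "high")
  expect_equal(as.character(classify_hii(0.1)), "low")
  expect_equal(as.character(classify_hii(c(0, 1))), c("low", "high"))
  # total and monotone on [0,1]
  grid <- seq(0, 1, by = 0.01)
  cls <- as.integer(classify_hii(grid))
  expect_true(all(diff(cls) >= 0))
  expect_error(classify_hii(1.2), "0, 1")
  expect_error(classify_hii(-0.1), "0, 1")
})
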