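test_that("length normalization divides counts by gene length", {
  catalog <- tiny_catalog(length = c(1500L, 600L, 500L))
  counts <- tiny_counts(catalog, c(300L, 120L, 0L))
  norm <- length_normalize(catalog, counts)
  expect_equal(norm$norm_count, c(300 / 1500, 120 / 600, 0))
  expect_equal(norm$norm_count[1], 0.2)
})

test_that("Pfam collation credits multi-Pfam genes fully and drops unannotated", {
  catalog <- tiny_catalog(
    length = c(1L, 1L, 1L),
    pfams = list("X", c("X", "Y"), character(0))
  )
  counts <- tiny_counts(catalog, c(2L, 3L, 5L))  # norm counts 0.2/0.3/0.5 scaled
  catalog$length <- c(10L, 10L, 10L)
  norm <- length_normalize(catalog, counts)
  collated <- collate_by_pfam(norm, catalog)
  expect_equal(collated$p_raw[collated$pfam == "X"], 0.5)
  expect_equal(collated$p_raw[collated$pfam == "Y"], 0.3)
  expect_false("g3" %in% collated$pfam)      # unannotated gene contributes nowhere
  expect_equal(sort(collated$pfam), c("X", "Y"))
  expect_equal(collated$n_expressed[collated$pfam == "X"], 2L)

  # all genes unannotated -> empty collation
  none <- tiny_catalog(pfams = list(character(0), character(0), character(0)))
  expect_equal(nrow(collate_by_pfam(length_normalize(none, counts), none)), 0)
})

test_that("n_expressed counts only annotated genes with at least one read", {
  catalog <- tiny_catalog(pfams = list("X", "X", "X"))
  counts <- tiny_counts(catalog, c(5L, 0L, 1L))
  collated <- collate_by_pfam(length_normalize(catalog, counts), catalog)
  expect_equal(collated$n_expressed, 2L)
})

long_praw <- function(a, b, pfams = paste0("PF", seq_along(a))) {
  tibble::tibble(
    community_id = rep(c("a", "b"), each = length(a)),
    pfam = rep(pfams, 2),
    p_raw = c(a, b)
  )
}

test_that("size factors follow the median-of-ratios construction", {
  sf <- compute_size_factors(long_praw(c(2, 2, 2), c(8, 8, 8)))
  expect_equal(sf$size_factor[sf$community_id == "a"], 0.5)
  expect_equal(sf$size_factor[sf$community_id == "b"], 2)

  same <- compute_size_factors(long_praw(c(1, 5, 9), c(1, 5, 9)))
  expect_equal(same$size_factor, c(1, 1))

  mixed <- compute_size_factors(long_praw(c(2, 8, 4), c(8, 2, 4)))
  expect_equal(mixed$size_factor, c(1, 1))  # per-Pfam ratios {0.5, 2, 1}

  # Pfams at zero in one community are excluded from the median
  with_zero <- compute_size_factors(
    long_praw(c(2, 2, 2, 7), c(8, 8, 8, 0))
  )
  expect_equal(with_zero$size_factor, c(0.5, 2))

  expect_error(compute_size_factors(long_praw(c(1, 0), c(0, 1))),
               "no Pfam")
})

test_that("two-community odd-Pfam size factors are exact reciprocals", {
  set.seed(42)
  for (i in 1:20) {
    n <- sample(c(3, 5, 7, 9, 33), 1)
    sf <- compute_size_factors(
      long_praw(rlnorm(n, 0, 1.5), rlnorm(n, 1, 1.5))
    )
    expect_equal(prod(sf$size_factor), 1, tolerance = 1e-12)
  }
})

test_that("size factors match the DESeq median-of-ratios implementation", {
  set.seed(7)
  # odd Pfam count: with an even count the even-median conventions differ
  # (arithmetic mean of the central ratios here vs geometric mean in DESeq)
  mat <- matrix(rpois(62, lambda = 200), ncol = 2,
                dimnames = list(paste0("PF", 1:31), c("a", "b")))
  ours <- compute_size_factors(long_praw(mat[, 1], mat[, 2],
                                         pfams = rownames(mat)))
  ref <- DESeq2::estimateSizeFactorsForMatrix(mat)
  expect_equal(ours$size_factor, unname(ref[ours$community_id]),
               tolerance = 1e-10)
})

test_that("size normalization divides by the community size factor", {
  tbl <- long_praw(c(2, 2, 2), c(8, 8, 8))
  sf <- compute_size_factors(tbl)
  norm <- normalize_pfam_expression(tbl, sf)
  expect_equal(norm$P_norm, rep(4, 6))  # depth difference removed, all D = 0
  ident <- normalize_pfam_expression(
    tbl, tibble::tibble(community_id = c("a", "b"), size_factor = c(1, 1))
  )
  expect_equal(ident$P_norm, ident$p_raw)
})

test_that("uniform depth scaling leaves normalized expression ratios unchanged", {
  catalog <- dplyr::bind_rows(
    tiny_catalog("a", gene_id = paste0("a", 1:3),
                 pfams = list("X", "Y", c("X", "Z"))),
    tiny_catalog("b", gene_id = paste0("b", 1:3),
                 pfams = list("X", "Y", "Z"))
  )
  counts <- dplyr::bind_rows(
    tiny_counts(catalog[catalog$community_id == "a", ], c(30L, 10L, 25L)),
    tiny_counts(catalog[catalog$community_id == "b", ], c(12L, 40L, 7L))
  )
  base <- quantify_pfams(catalog, counts)$aggregates
  scaled_counts <- dplyr::mutate(
    counts,
    count = ifelse(.data$community_id == "b", count * 7L, count)
  )
  scaled <- quantify_pfams(catalog, scaled_counts)$aggregates
  ratio_of <- function(agg) {
    wide <- tidyr::pivot_wider(agg[c("community_id", "pfam", "P_norm")],
                               names_from = "community_id",
                               values_from = "P_norm", values_fill = 0)
    wide <- wide[order(wide$pfam), ]
    wide$a / wide$b
  }
  # both P vectors scale by a common factor, so all ratios (and hence all
  # fold changes and D signs) are unchanged
  expect_equal(ratio_of(scaled), ratio_of(base), tolerance = 1e-12)
})

test_that("collation is additive over disjoint gene sets", {
  set.seed(3)
  cat1 <- tiny_catalog("a", gene_id = paste0("p", 1:3),
                       pfams = list("X", c("X", "Y"), "Y"))
  cat2 <- tiny_catalog("a", gene_id = paste0("q", 1:3),
                       pfams = list("Y", "X", character(0)))
  cnt1 <- tiny_counts(cat1, c(4L, 9L, 2L))
  cnt2 <- tiny_counts(cat2, c(1L, 6L, 8L))
  both_cat <- dplyr::bind_rows(cat1, cat2)
  both_cnt <- dplyr::bind_rows(cnt1, cnt2)
  whole <- collate_by_pfam(length_normalize(both_cat, both_cnt), both_cat)
  part1 <- collate_by_pfam(length_normalize(cat1, cnt1), cat1)
  part2 <- collate_by_pfam(length_normalize(cat2, cnt2), cat2)
  merged <- dplyr::full_join(part1, part2, by = c("community_id", "pfam"))
  merged[is.na(merged)] <- 0
  expect_equal(whole$p_raw,
               (merged$p_raw.x + merged$p_raw.y)[match(whole$pfam, merged$pfam)])
  expect_equal(whole$n_expressed,
               as.integer(merged$n_expressed.x +
                            merged$n_expressed.y)[match(whole$pfam, merged$pfam)])
})

test_that("Pfams with zero counts everywhere do not move the size factors", {
  base <- long_praw(c(2, 3, 5), c(4, 9, 10))
  padded <- dplyr::bind_rows(
    base,
    tibble::tibble(community_id = c("a", "b"), pfam = "PFZERO", p_raw = 0)
  )
  expect_equal(compute_size_factors(base), compute_size_factors(padded))
})
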