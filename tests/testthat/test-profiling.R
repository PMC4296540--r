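test_that("sequencing metrics derive the printed percentages", {
  metrics <- tibble::tibble(
    community_id = c("meso", "thermo"),
    total_reads = c(68754440, 50014968),
    mrna_reads = c(43825869, 24348655),
    mapped_mrna_reads = c(3916829, 2153529),
    lignocellulolytic_reads = c(6167, 3481)
  )
  rep <- sequencing_metrics_report(metrics)
  expect_equal(rep$rrna_pct, c(36.3, 51.3))
  expect_equal(rep$mapped_pct, c(8.9, 8.8))
  expect_equal(rep$lignocellulolytic_pct, c(0.16, 0.16))

  flat <- sequencing_metrics_report(tibble::tibble(
    community_id = "x", total_reads = 10, mrna_reads = 10,
    mapped_mrna_reads = 10, lignocellulolytic_reads = 10
  ))
  expect_equal(flat$rrna_pct, 0)
  expect_equal(flat$mapped_pct, 100)
  expect_equal(flat$lignocellulolytic_pct, 100)

  bad <- metrics
  bad$mrna_reads[1] <- bad$total_reads[1] + 1
  expect_error(sequencing_metrics_report(bad), "non-increasing")
})

profiling_targets <- tibble::tibble(
  accession = c("PF00001", "PF00002", "PF00003", "PF00010"),
  label = c("GH_one", "GH_two", "GH_three", "CBM_one"),
  category = c("GH", "GH", "GH", "CBM")
)

test_that("composition shares are GH-only percentages that sum to 100", {
  agg <- tibble::tibble(
    community_id = "a",
    pfam = c("PF00001", "PF00002", "PF00003", "PF00010"),
    p_raw = c(1, 3, 0, 50)   # the CBM must not enter the denominator
  )
  prof <- composition_profile(agg, profiling_targets)
  expect_equal(sort(prof$pfam), sort(profiling_targets$accession[1:3]))
  expect_equal(prof$share_pct[prof$pfam == "PF00001"], 25)
  expect_equal(prof$share_pct[prof$pfam == "PF00002"], 75)
  expect_equal(prof$share_pct[prof$pfam == "PF00003"], 0)
  expect_equal(sum(prof$share_pct), 100)

  single <- composition_profile(
    tibble::tibble(community_id = "a", pfam = "PF00001", p_raw = 7),
    profiling_targets
  )
  expect_equal(single$share_pct[single$pfam == "PF00001"], 100)

  expect_error(
    composition_profile(
      tibble::tibble(community_id = "a", pfam = "PF00010", p_raw = 5),
      profiling_targets
    ),
    "no GH-family expression"
  )
})

test_that("composition shares do not depend on the size factor", {
  agg <- tibble::tibble(
    community_id = "a",
    pfam = c("PF00001", "PF00002"),
    p_raw = c(2, 6)
  )
  scaled <- dplyr::mutate(agg, p_raw = p_raw / 0.48)  # divide by any S
  expect_equal(
    composition_profile(agg, profiling_targets)$share_pct,
    composition_profile(scaled, profiling_targets)$share_pct
  )
})

test_that("fold changes carry direction and handle zero expression", {
  fc <- fold_change(c(6, 0, 3, 0, 2), c(2, 2, 3, 0, 8),
                    names = c("A", "B"))
  expect_equal(fc$fold, c(3, NA, 1, NA, 4))
  expect_equal(fc$direction, c("A", "B", "tie", NA, "B"))
})

test_that("genus attribution finds the >50% dominant prefix", {
  catalog <- tiny_catalog(
    "a",
    gene_id = paste0("g", 1:4),
    length = rep(100L, 4),
    pfams = list("PF00001", "PF00001", "PF00001", "PF00001"),
    genus = c("Micromonospora", "Niastella", "Pseudoxanthomonas",
              "Micromonospora"),
    phylum = c("Actinobacteria", "Bacteroidetes", "Proteobacteria",
               "Actinobacteria")
  )
  # shares 40 / 35 / 25
  counts <- tiny_counts(catalog, c(30L, 35L, 25L, 10L))
  norm <- length_normalize(catalog, counts)
  att <- genus_attribution(norm, catalog, profiling_targets)
  expect_equal(att$genus, c("Micromonospora", "Niastella",
                            "Pseudoxanthomonas"))
  expect_equal(att$share_pct, c(40, 35, 25))
  expect_equal(att$dominant, c(TRUE, TRUE, FALSE))  # 40+35 > 50
  expect_equal(sum(att$share_pct), 100)             # every genus known

  # 50/50 split: 50 is not > 50, both genera needed
  counts5050 <- tiny_counts(catalog, c(25L, 50L, 0L, 25L))
  att5050 <- genus_attribution(length_normalize(catalog, counts5050),
                               catalog, profiling_targets)
  expect_equal(att5050$dominant, c(TRUE, TRUE))

  # single genus holds everything
  counts_one <- tiny_counts(catalog, c(10L, 0L, 0L, 30L))
  att_one <- genus_attribution(length_normalize(catalog, counts_one),
                               catalog, profiling_targets)
  expect_equal(att_one$genus, "Micromonospora")
  expect_equal(att_one$share_pct, 100)
  expect_true(att_one$dominant)

  # phylum rollup merges the two Micromonospora-like rows
  phyl <- phylum_attribution(norm, catalog, profiling_targets)
  expect_equal(phyl$phylum[1], "Actinobacteria")
  expect_equal(phyl$share_pct[1], 40)
})

test_that("unknown-genus genes stay in the denominator but get no row", {
  catalog <- tiny_catalog(
    "a", gene_id = c("g1", "g2"), length = c(100L, 100L),
    pfams = list("PF00001", "PF00001"),
    genus = c("Micromonospora", "unknown"),
    phylum = c("Actinobacteria", "unknown")
  )
  counts <- tiny_counts(catalog, c(30L, 70L))
  att <- genus_attribution(length_normalize(catalog, counts), catalog,
                           profiling_targets)
  expect_equal(att$genus, "Micromonospora")
  expect_equal(att$share_pct, 30)
  expect_false(att$dominant)   # known genera never exceed 50%
})

test_that("top genes cover the requested share of a Pfam's expression", {
  catalog <- tiny_catalog(
    "a", gene_id = paste0("g", 1:3), length = rep(100L, 3),
    pfams = list("PF00001", "PF00001", "PF00001"),
    genus = rep("Micromonospora", 3),
    phylum = rep("Actinobacteria", 3)
  )
  counts <- tiny_counts(catalog, c(85L, 10L, 5L))
  norm <- length_normalize(catalog, counts)
  top <- top_genes(norm, catalog, "PF00001")
  expect_equal(top$gene_id, c("g1", "g2"))      # 0.85 + 0.10 >= 0.90
  expect_equal(top$cum_share[2], 0.95)

  all_genes <- top_genes(norm, catalog, "PF00001", coverage = 1)
  expect_equal(all_genes$gene_id, c("g1", "g2", "g3"))

  single <- top_genes(
    length_normalize(catalog, tiny_counts(catalog, c(0L, 9L, 0L))),
    catalog, "PF00001"
  )
  expect_equal(single$gene_id, "g2")
  expect_equal(single$share, 1)

  none <- top_genes(
    length_normalize(catalog, tiny_counts(catalog, c(0L, 0L, 0L))),
    catalog, "PF00001"
  )
  expect_equal(nrow(none), 0)
})

test_that("rarefaction endpoints are exact and depths beyond the total error", {
  counts <- tibble::tibble(
    community_id = "a",
    gene_id = paste0("g", 1:4),
    count = c(5L, 3L, 0L, 1L)
  )
  curve <- rarefaction_curve(counts, depths = c(0L, 9L), reps = 10, seed = 1)
  expect_equal(curve$mean_detected[curve$depth == 0], 0)
  expect_equal(curve$mean_detected[curve$depth == 9], 3)  # genes with count >= 1
  expect_error(rarefaction_curve(counts, depths = 10L), "total mapped reads")
})

test_that("rarefaction means match the hypergeometric closed form", {
  counts <- tibble::tibble(
    community_id = "a",
    gene_id = paste0("g", 1:2),
    count = c(2L, 1L)
  )
  # m = 1 from {g1, g1, g2}: expected detections exactly 1
  curve <- rarefaction_curve(counts, depths = 1L, reps = 500, seed = 2)
  expect_equal(curve$mean_detected, 1)

  set.seed(4)
  cnt <- as.integer(rpois(8, 6) + 1)
  counts8 <- tibble::tibble(
    community_id = "a", gene_id = paste0("g", 1:8), count = cnt
  )
  depths <- as.integer(round(seq(1, sum(cnt), length.out = 5)))
  curve8 <- rarefaction_curve(counts8, depths = depths, reps = 200, seed = 3)
  for (i in seq_along(depths)) {
    expect_true(!is.unsorted(curve8$mean_detected))
    exact <- expected_detected(cnt, depths[i])
    # cross-check the closed form itself against vegan's analytic rarefaction
    expect_equal(exact,
                 as.numeric(suppressWarnings(
                   vegan::rarefy(cnt, sample = depths[i])
                 )),
                 tolerance = 1e-8)
    se <- curve8$sd_detected[i] / sqrt(curve8$reps[i])
    expect_lt(abs(curve8$mean_detected[i] - exact), 3 * max(se, 1e-6) + 1e-9)
  }
})
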