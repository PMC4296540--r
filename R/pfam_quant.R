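#' Length-normalize mapped read counts
#'
#' Divides each gene's mapped-read count by its length in nucleotides, the
#' per-gene quantity `g/l` that all downstream Pfam pooling works with.  Zero
#' counts map to 0.
#'
#' @param catalog Gene catalog tibble (one or more communities).
#' @param counts Count tibble paired with the catalog (`community_id`,
#'   `gene_id`, `count`).
#' @return A tibble `community_id`, `gene_id`, `count`, `norm_count` with
#'   `norm_count = count / length`.
#' @export
length_normalize <- function(catalog, counts) {
  joined <- dplyr::inner_join(
    counts,
    catalog[c("community_id", "gene_id", "length")],
    by = c("community_id", "gene_id")
  )
  if (nrow(joined) != nrow(counts)) {
    stop("count table contains genes missing from the catalog", call. = FALSE)
  }
  dplyr::mutate(
    joined,
    norm_count = .data$count / .data$length,
    length = NULL
  )
}

#' Pool length-normalized counts by Pfam
#'
#' Collates per-gene normalized counts into per-Pfam sums: for each Pfam `i`
#' in each community, `p_raw` is the sum of `count/length` over genes carrying
#' that annotation.  A gene with several Pfam annotations contributes its full
#' normalized count to each of them; genes without any Pfam annotation are
#' discarded.  `n_expressed` counts the annotated genes with at least one
#' mapped read — the gene-group size the pseudo-Pfam permutation test matches
#' when it assembles random gene groups.
#'
#' @param norm_counts Output of [length_normalize()].
#' @param catalog The corresponding gene catalog.
#' @return A tibble `community_id`, `pfam`, `p_raw`, `n_expressed` with one
#'   row per (community, Pfam) that has at least one annotated gene.  Pfams
#'   with no annotated genes are simply absent (equivalent to `p_raw = 0`).
#' @export
collate_by_pfam <- function(norm_counts, catalog) {
  ann <- tidyr::unnest(
    catalog[c("community_id", "gene_id", "pfams")],
    "pfams"
  )
  ann <- dplyr::rename(ann, pfam = "pfams")
  joined <- dplyr::inner_join(
    ann,
    norm_counts[c("community_id", "gene_id", "count", "norm_count")],
    by = c("community_id", "gene_id")
  )
  out <- dplyr::summarise(
    dplyr::group_by(joined, .data$community_id, .data$pfam),
    p_raw = sum(.data$norm_count),
    n_expressed = sum(.data$count >= 1L),
    .groups = "drop"
  )
  dplyr::arrange(out, .data$community_id, .data$pfam)
}

#' Median-of-ratios size factors
#'
#' Estimates one sequencing-depth scaling constant per community from the
#' per-Pfam length-normalized sums: each Pfam's `p_raw` is divided by the
#' geometric mean of that Pfam's `p_raw` across all communities, and the
#' median of those ratios is the community's size factor.  Pfams with zero
#' `p_raw` in any community are excluded (their geometric mean is zero).  For
#' two communities and an odd number of usable Pfams the two factors are exact
#' reciprocals, so their product is 1.
#'
#' @param p_raw_tables A long tibble `community_id`, `pfam`, `p_raw` covering
#'   at least two communities (extra columns are ignored), e.g. the output of
#'   [collate_by_pfam()] for several communities bound together.
#' @return A tibble `community_id`, `size_factor`.
#' @export
#' @examples
#' tbl <- tibble::tibble(
#'   community_id = rep(c("a", "b"), each = 3),
#'   pfam = rep(c("PF1", "PF2", "PF3"), 2),
#'   p_raw = c(2, 2, 2, 8, 8, 8)
#' )
#' compute_size_factors(tbl)  # 0.5 and 2
compute_size_factors <- function(p_raw_tables) {
  wide <- tidyr::pivot_wider(
    p_raw_tables[c("community_id", "pfam", "p_raw")],
    names_from = "community_id",
    values_from = "p_raw",
    values_fill = 0
  )
  mat <- as.matrix(wide[-1])
  if (ncol(mat) < 2) {
    stop("size factors need at least two communities", call. = FALSE)
  }
  usable <- apply(mat, 1, function(r) all(is.finite(r) & r > 0))
  if (!any(usable)) {
    stop(
      "no Pfam has positive length-normalized counts in every community; ",
      "size factors cannot be estimated",
      call. = FALSE
    )
  }
  m <- mat[usable, , drop = FALSE]
  geo <- exp(rowMeans(log(m)))
  sf <- apply(m / geo, 2, stats::median)
  tibble::tibble(community_id = colnames(mat), size_factor = unname(sf))
}

#' Size-normalize per-Pfam expression
#'
#' Divides each per-Pfam length-normalized sum by its community's size factor,
#' giving the depth-corrected expression `P = p_raw / S` that the
#' between-community difference `D = P_A - P_B` is built from.
#'
#' @param p_raw_tables Long tibble with `community_id`, `pfam`, `p_raw`
#'   (and optionally `n_expressed`).
#' @param size_factors Output of [compute_size_factors()].
#' @return The input tibble with a `P_norm` column appended.
#' @export
normalize_pfam_expression <- function(p_raw_tables, size_factors) {
  out <- dplyr::left_join(p_raw_tables, size_factors, by = "community_id")
  if (anyNA(out$size_factor)) {
    stop("size factors missing for some community", call. = FALSE)
  }
  out$P_norm <- out$p_raw / out$size_factor
  out$size_factor <- NULL
  out
}

#' Quantify Pfam-level expression across communities
#'
#' Convenience pipeline over [length_normalize()], [collate_by_pfam()],
#' [compute_size_factors()] and [normalize_pfam_expression()] for a
#' multi-community catalog/count pair.
#'
#' @param catalog Gene catalog tibble covering all communities.
#' @param counts Count tibble covering the same communities.
#' @return A list with elements `aggregates` (tibble `community_id`, `pfam`,
#'   `p_raw`, `n_expressed`, `P_norm`), `size_factors`, and `norm_counts`
#'   (per-gene `count/length` values, used by the sampling pools and the
#'   profiling layers).
#' @export
quantify_pfams <- function(catalog, counts) {
  norm_counts <- length_normalize(catalog, counts)
  collated <- collate_by_pfam(norm_counts, catalog)
  size_factors <- compute_size_factors(collated)
  aggregates <- normalize_pfam_expression(collated, size_factors)
  list(
    aggregates = aggregates,
    size_factors = size_factors,
    norm_counts = norm_counts
  )
}
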