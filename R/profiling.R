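#' Sequencing and processing metrics report
#'
#' From the per-community read-processing chain — total reads sequenced, reads
#' surviving rRNA filtering (mRNA), mRNA reads mapped to the paired
#' metagenome, and mapped reads falling in the target GH/CBM Pfams — derives
#' the percentages usually reported alongside: the rRNA fraction of all reads,
#' the mapped fraction of mRNA reads, and the lignocellulolytic share of
#' mapped reads.  Percentages are rounded to one decimal (two for the
#' lignocellulolytic share, which is typically well below 1%).
#'
#' @param metrics A tibble with columns `community_id`, `total_reads`,
#'   `mrna_reads`, `mapped_mrna_reads`, `lignocellulolytic_reads`.  The chain
#'   must be non-increasing.
#' @return The input with `rrna_pct`, `mapped_pct`, `lignocellulolytic_pct`
#'   appended.
#' @export
sequencing_metrics_report <- function(metrics) {
  needed <- c("community_id", "total_reads", "mrna_reads",
              "mapped_mrna_reads", "lignocellulolytic_reads")
  missing <- setdiff(needed, names(metrics))
  if (length(missing) > 0) {
    stop("metrics lack column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  ok <- metrics$total_reads >= metrics$mrna_reads &
    metrics$mrna_reads >= metrics$mapped_mrna_reads &
    metrics$mapped_mrna_reads >= metrics$lignocellulolytic_reads &
    metrics$lignocellulolytic_reads >= 0
  if (!all(ok)) {
    stop(
      "read-processing chain must be non-increasing ",
      "(total >= mRNA >= mapped >= lignocellulolytic >= 0) for: ",
      paste(metrics$community_id[!ok], collapse = ", "),
      call. = FALSE
    )
  }
  dplyr::mutate(
    metrics,
    rrna_pct = round(
      (.data$total_reads - .data$mrna_reads) / .data$total_reads * 100, 1
    ),
    mapped_pct = round(
      .data$mapped_mrna_reads / .data$mrna_reads * 100, 1
    ),
    lignocellulolytic_pct = round(
      .data$lignocellulolytic_reads / .data$mapped_mrna_reads * 100, 2
    )
  )
}

#' Composition of the lignocellulolytic GH transcriptome
#'
#' Shares of each glycoside hydrolase family in a community's
#' lignocellulolytic GH transcriptome: `p_raw(family)` divided by the summed
#' `p_raw` over all GH-category target Pfams, as a percentage.  CBM families
#' are not part of the denominator (carbohydrate binding modules are
#' non-catalytic and are profiled separately).  The shares are invariant to
#' the size factor, which cancels within a community.
#'
#' @param aggregates Aggregate tibble (from [quantify_pfams()] or
#'   [collate_by_pfam()]).
#' @param target_pfams Target list tibble with a `category` column.
#' @param community_id Optional single community to profile; default profiles
#'   every community present.
#' @return A tibble `community_id`, `pfam`, `label`, `share_pct` covering
#'   every GH-category target Pfam (zero-expression families appear with
#'   share 0); shares sum to 100 within each community.
#' @export
composition_profile <- function(aggregates, target_pfams,
                                community_id = NULL) {
  gh <- target_pfams[target_pfams$category == "GH", ]
  communities <- if (is.null(community_id)) {
    unique(aggregates$community_id)
  } else {
    community_id
  }
  grid <- tidyr::expand_grid(
    community_id = communities,
    pfam = gh$accession
  )
  grid <- dplyr::left_join(
    grid,
    aggregates[c("community_id", "pfam", "p_raw")],
    by = c("community_id", "pfam")
  )
  grid$p_raw[is.na(grid$p_raw)] <- 0
  out <- dplyr::group_by(grid, .data$community_id)
  totals <- dplyr::summarise(out, total = sum(.data$p_raw))
  if (any(totals$total <= 0)) {
    stop(
      "no GH-family expression in community: ",
      paste(totals$community_id[totals$total <= 0], collapse = ", "),
      call. = FALSE
    )
  }
  out <- dplyr::mutate(out, share_pct = .data$p_raw / sum(.data$p_raw) * 100)
  out <- dplyr::ungroup(out)
  out <- dplyr::left_join(
    out,
    gh[c("accession", "label")],
    by = c(pfam = "accession")
  )
  out[c("community_id", "pfam", "label", "share_pct")]
}

#' Fold change and direction of per-Pfam expression
#'
#' `fold = max(P_a, P_b) / min(P_a, P_b)` with the direction naming the
#' community with the larger size-normalized expression.  When exactly one
#' community has zero expression the fold change is undefined (`NA`) but the
#' direction is still the non-zero community; when both are zero the Pfam was
#' not detected and both are `NA`.
#'
#' @param p_a,p_b Size-normalized expression vectors (`P_norm`).
#' @param names Length-2 character vector naming the two communities; used
#'   for the `direction` values (default `c("a", "b")`).
#' @return A tibble `fold`, `direction` (`names[1]`, `names[2]`, `"tie"`, or
#'   `NA` when not detected).
#' @export
fold_change <- function(p_a, p_b, names = c("a", "b")) {
  stopifnot(length(p_a) == length(p_b), length(names) == 2)
  hi <- pmax(p_a, p_b)
  lo <- pmin(p_a, p_b)
  fold <- ifelse(hi == 0, NA_real_, ifelse(lo == 0, NA_real_, hi / lo))
  direction <- dplyr::case_when(
    p_a == 0 & p_b == 0 ~ NA_character_,
    p_a == p_b ~ "tie",
    p_a > p_b ~ names[1],
    TRUE ~ names[2]
  )
  tibble::tibble(fold = fold, direction = direction)
}

#' Taxonomic attribution of per-family expression
#'
#' For each target family, the share of its length-normalized transcripts
#' contributed by each genus (or phylum, after rolling up the catalog's
#' phylum bins).  Genes with an `"unknown"` taxon stay in the family total but
#' get no row of their own, so per-family shares sum to at most 100%.  The
#' `dominant` flag marks the shortest prefix of genera (descending share,
#' alphabetical tie-break) whose cumulative share strictly exceeds 50% — the
#' genera that together express the majority of that family.
#'
#' @param norm_counts Per-gene normalized counts from [length_normalize()].
#' @param catalog Gene catalog with `genus`/`phylum` bins.
#' @param target_pfams Target list tibble.
#' @param rank `"genus"` (default) or `"phylum"`.
#' @return A tibble `community_id`, `pfam`, `label`, taxon column (`genus` or
#'   `phylum`), `share_pct`, `rank`, `dominant`, covering families with
#'   positive expression.
#' @export
genus_attribution <- function(norm_counts, catalog, target_pfams,
                              rank = c("genus", "phylum")) {
  rank <- match.arg(rank)
  ann <- tidyr::unnest(
    catalog[c("community_id", "gene_id", "pfams", "genus", "phylum")],
    "pfams"
  )
  ann <- dplyr::rename(ann, pfam = "pfams")
  ann <- ann[ann$pfam %in% target_pfams$accession, ]
  joined <- dplyr::inner_join(
    ann,
    norm_counts[c("community_id", "gene_id", "norm_count")],
    by = c("community_id", "gene_id")
  )
  joined <- joined[joined$norm_count > 0, ]   # unexpressed genes carry no share
  joined$taxon <- joined[[rank]]
  totals <- dplyr::summarise(
    dplyr::group_by(joined, .data$community_id, .data$pfam),
    family_total = sum(.data$norm_count),
    .groups = "drop"
  )
  totals <- totals[totals$family_total > 0, ]
  by_taxon <- dplyr::summarise(
    dplyr::group_by(joined, .data$community_id, .data$pfam, .data$taxon),
    value = sum(.data$norm_count),
    .groups = "drop"
  )
  out <- dplyr::inner_join(by_taxon, totals,
                           by = c("community_id", "pfam"))
  out <- out[out$taxon != "unknown", ]
  out$share_pct <- out$value / out$family_total * 100
  out <- dplyr::arrange(
    out, .data$community_id, .data$pfam,
    dplyr::desc(.data$share_pct), .data$taxon
  )
  out <- dplyr::group_by(out, .data$community_id, .data$pfam)
  out <- dplyr::mutate(
    out,
    rank = dplyr::row_number(),
    dominant = dominant_prefix(.data$share_pct)
  )
  out <- dplyr::ungroup(out)
  out <- dplyr::left_join(
    out,
    target_pfams[c("accession", "label")],
    by = c(pfam = "accession")
  )
  names(out)[names(out) == "taxon"] <- rank
  out[c("community_id", "pfam", "label", rank, "share_pct", "rank",
        "dominant")]
}

# shortest prefix (shares already sorted descending) with cumulative share
# strictly > 50%; if the known taxa never reach 50%, no prefix qualifies
dominant_prefix <- function(share_pct) {
  cum <- cumsum(share_pct)
  k <- which(cum > 50)
  if (length(k) == 0) {
    return(rep(FALSE, length(share_pct)))
  }
  seq_along(share_pct) <= min(k)
}

#' @rdname genus_attribution
#' @export
phylum_attribution <- function(norm_counts, catalog, target_pfams) {
  genus_attribution(norm_counts, catalog, target_pfams, rank = "phylum")
}

#' Genes dominating a Pfam's expression
#'
#' Genes annotated to a Pfam, sorted by descending normalized count
#' (ties broken by `gene_id`), cut at the shortest prefix whose cumulative
#' share of the Pfam's expression reaches `coverage` — the handful of genes
#' that typically account for most of an overexpressed family.
#'
#' @param norm_counts Per-gene normalized counts from [length_normalize()]
#'   (one community).
#' @param catalog The community's gene catalog.
#' @param pfam A single Pfam accession.
#' @param coverage Cumulative share cutoff in (0, 1], default 0.90.
#' @return A tibble `gene_id`, `genus`, `norm_count`, `share`, `cum_share`;
#'   empty if the Pfam has no expression.
#' @export
top_genes <- function(norm_counts, catalog, pfam, coverage = 0.90) {
  pfam <- normalize_pfam_acc(pfam)
  stopifnot(length(pfam) == 1, coverage > 0, coverage <= 1)
  members <- catalog$gene_id[
    vapply(catalog$pfams, function(p) pfam %in% p, logical(1))
  ]
  sub <- norm_counts[norm_counts$gene_id %in% members &
                       norm_counts$norm_count > 0, ]
  if (nrow(sub) == 0) {
    return(tibble::tibble(
      gene_id = character(0), genus = character(0),
      norm_count = numeric(0), share = numeric(0), cum_share = numeric(0)
    ))
  }
  sub <- dplyr::arrange(sub, dplyr::desc(.data$norm_count), .data$gene_id)
  sub$share <- sub$norm_count / sum(sub$norm_count)
  sub$cum_share <- cumsum(sub$share)
  keep <- seq_len(min(which(sub$cum_share >= coverage - 1e-12)))
  sub <- sub[keep, ]
  sub$genus <- catalog$genus[match(sub$gene_id, catalog$gene_id)]
  sub[c("gene_id", "genus", "norm_count", "share", "cum_share")]
}

#' Rarefaction of expressed genes
#'
#' Expected number of distinct genes detected (count >= 1) as a function of
#' sequencing depth, estimated by repeatedly subsampling reads without
#' replacement from the mapped-read multiset.  An asymptote indicates the
#' sequencing depth was sufficient to observe most expressed genes.
#'
#' @param counts Count tibble for one community (`gene_id`, `count`).
#' @param depths Integer vector of subsampling depths, each `<=` the total
#'   mapped reads.
#' @param reps Subsampling repetitions per depth (default 100).
#' @param seed Optional integer seed for reproducibility.
#' @return A tibble `depth`, `mean_detected`, `sd_detected`, `reps`.
#' @export
rarefaction_curve <- function(counts, depths, reps = 100L, seed = NULL) {
  cnt <- counts$count
  total <- sum(cnt)
  depths <- as.integer(depths)
  if (any(depths < 0) || any(depths > total)) {
    stop("depths must lie in [0, total mapped reads = ", total, "]",
         call. = FALSE)
  }
  cum <- cumsum(cnt)
  detect_once <- function(m) {
    if (m == 0L) return(0L)
    idx <- sample.int(total, m)
    length(unique(findInterval(idx - 0.5, cum) + 1L))
  }
  body <- function() {
    purrr::map_dfr(depths, function(m) {
      det <- vapply(seq_len(reps), function(i) detect_once(m), integer(1))
      tibble::tibble(
        depth = m,
        mean_detected = mean(det),
        sd_detected = stats::sd(det),
        reps = as.integer(reps)
      )
    })
  }
  if (is.null(seed)) body() else withr::with_seed(seed, body())
}
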