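#' Build per-community sampling pools for the pseudo-Pfam test
#'
#' The permutation null draws random gene groups ("pseudo-Pfams") from the set
#' of genes that carry at least one Pfam annotation and have a non-zero read
#' count.  Pool values are the per-gene size- and length-normalized counts
#' `count / length / S`, so pseudo-group sums live on the same scale as the
#' observed size-normalized Pfam expression `P`.
#'
#' @param catalog Gene catalog tibble (all communities).
#' @param counts Count tibble (all communities).
#' @param size_factors Output of [compute_size_factors()].
#' @return A tibble `community_id`, `gene_id`, `value` with `value > 0`.
#' @export
sampling_pools <- function(catalog, counts, size_factors) {
  norm <- length_normalize(catalog, counts)
  annotated <- catalog$gene_id[lengths(catalog$pfams) > 0]
  pool <- norm[norm$count >= 1L & norm$gene_id %in% annotated, ]
  pool <- dplyr::left_join(pool, size_factors, by = "community_id")
  tibble::tibble(
    community_id = pool$community_id,
    gene_id = pool$gene_id,
    value = pool$norm_count / pool$size_factor
  )
}

#' Observed between-community expression difference
#'
#' `D = P_focal - P_other`, the signed difference in size-normalized Pfam
#' expression whose null distribution the pseudo-Pfam resampling builds.
#'
#' @param p_focal,p_other Size-normalized expression values (`P_norm`).
#' @return Numeric vector of signed differences.
#' @export
observed_difference <- function(p_focal, p_other) {
  p_focal - p_other
}

#' Sum a randomly assembled pseudo-Pfam
#'
#' Draws `n` genes uniformly without replacement from a sampling pool and sums
#' their normalized values.  Drawing `n = 0` genes gives 0, the expression of
#' a Pfam with no expressed genes in that community.
#'
#' @param pool Numeric vector of pool values (one community).
#' @param n Number of genes to draw; must not exceed the pool size.
#' @return A single numeric sum.
#' @export
sample_pseudo_pfam <- function(pool, n) {
  n <- as.integer(n)
  if (n == 0L) return(0)
  if (n > length(pool)) {
    stop(
      "pseudo-Pfam group size (", n, ") exceeds pool size (", length(pool),
      "); cap n at the pool size",
      call. = FALSE
    )
  }
  sum(pool[sample.int(length(pool), n)])
}

#' Monte-Carlo null distribution of pseudo-Pfam differences
#'
#' Repeats the pseudo-Pfam construction `reps` times: draw `n_a` genes from
#' community A's pool and `n_b` from community B's, independently across
#' repetitions, and record the difference of the two pseudo-group sums.
#'
#' @param pool_a,pool_b Numeric pool value vectors.
#' @param n_a,n_b Group sizes matching the observed Pfam's expressed-gene
#'   counts in each community.
#' @param reps Number of Monte-Carlo repetitions (default 10000).
#' @return Numeric vector of `reps` null difference values.
#' @export
permutation_null <- function(pool_a, pool_b, n_a, n_b, reps = 10000L) {
  draw_sums(pool_a, n_a, reps) - draw_sums(pool_b, n_b, reps)
}

draw_sums <- function(pool, n, reps) {
  n <- as.integer(n)
  if (n == 0L) return(numeric(reps))
  if (n > length(pool)) {
    stop(
      "pseudo-Pfam group size (", n, ") exceeds pool size (", length(pool),
      "); cap n at the pool size",
      call. = FALSE
    )
  }
  N <- length(pool)
  vapply(
    seq_len(reps),
    function(i) sum(pool[sample.int(N, n)]),
    numeric(1)
  )
}

#' Monte-Carlo p-value for an observed difference
#'
#' One-sided in the fixed screening direction: the probability of a null
#' difference at least as large as the observed `D`, with add-one smoothing so
#' the p-value is never exactly zero.  An observed difference below the entire
#' null therefore gets p close to 1; overexpression in the *other* community
#' is not flagged by this statistic (it is visible in the fold-change
#' direction instead).
#'
#' @param d_obs Observed difference `P_focal - P_other`.
#' @param null Numeric vector of null differences from [permutation_null()].
#' @return `(#\{null >= d_obs\} + 1) / (length(null) + 1)`.
#' @export
pseudo_pfam_pvalue <- function(d_obs, null) {
  if (length(null) == 0) {
    stop("empty null distribution", call. = FALSE)
  }
  (sum(null >= d_obs) + 1) / (length(null) + 1)
}

#' Run the pseudo-Pfam permutation test over a target list
#'
#' For each target Pfam, computes the observed difference in size-normalized
#' expression between the focal community and the other community, builds
#' `n_runs` independent Monte-Carlo null distributions of `reps` pseudo-Pfam
#' differences each, and reports the per-run p-values and their mean.  Pfams
#' with zero expression in both communities are flagged not detected and get
#' no p-value.
#'
#' @param aggregates Aggregate tibble from [quantify_pfams()] (exactly two
#'   communities).
#' @param pools Sampling pools from [sampling_pools()].
#' @param target_pfams Target list tibble from [load_target_pfams()].
#' @param focal Community id screened for overexpression (`D = P_focal -
#'   P_other`).  Defaults to the first community in `aggregates`.
#' @param reps Pseudo-Pfam draws per run (default 10000).
#' @param n_runs Independent Monte-Carlo runs averaged per Pfam (default 3).
#' @param seed Optional integer seed; fixing it fixes every p-value exactly.
#' @return A tibble with one row per target Pfam: `pfam`, `label`, `detected`,
#'   `d_obs`, `n_focal`, `n_other`, `p_runs` (list-column of per-run
#'   p-values), `p_pseudo` (their mean), plus `reps` and `n_runs`.
#' @export
run_pseudo_pfam_test <- function(aggregates, pools, target_pfams,
                                 focal = NULL, reps = 10000L, n_runs = 3L,
                                 seed = NULL) {
  communities <- unique(aggregates$community_id)
  if (length(communities) != 2) {
    stop("pseudo-Pfam test compares exactly two communities", call. = FALSE)
  }
  focal <- if (is.null(focal)) communities[1] else as.character(focal)
  if (!focal %in% communities) {
    stop("focal community '", focal, "' not in aggregates", call. = FALSE)
  }
  other <- setdiff(communities, focal)

  pool_f <- pools$value[pools$community_id == focal]
  pool_o <- pools$value[pools$community_id == other]

  lookup <- function(pfam, cid, col) {
    v <- aggregates[[col]][aggregates$pfam == pfam &
                             aggregates$community_id == cid]
    if (length(v) == 0) 0 else v
  }

  run_one <- function(pfam) {
    p_raw_f <- lookup(pfam, focal, "p_raw")
    p_raw_o <- lookup(pfam, other, "p_raw")
    detected <- p_raw_f > 0 || p_raw_o > 0
    if (!detected) {
      return(tibble::tibble(
        pfam = pfam, detected = FALSE, d_obs = NA_real_,
        n_focal = 0L, n_other = 0L,
        p_runs = list(numeric(0)), p_pseudo = NA_real_
      ))
    }
    n_f <- as.integer(lookup(pfam, focal, "n_expressed"))
    n_o <- as.integer(lookup(pfam, other, "n_expressed"))
    d_obs <- observed_difference(
      lookup(pfam, focal, "P_norm"), lookup(pfam, other, "P_norm")
    )
    p_runs <- vapply(seq_len(n_runs), function(r) {
      null <- permutation_null(pool_f, pool_o, n_f, n_o, reps)
      pseudo_pfam_pvalue(d_obs, null)
    }, numeric(1))
    p_mean <- mean(p_runs)
    tibble::tibble(
      pfam = pfam, detected = TRUE, d_obs = d_obs,
      n_focal = n_f, n_other = n_o,
      p_runs = list(p_runs), p_pseudo = p_mean
    )
  }

  body <- function() {
    dplyr::bind_rows(lapply(target_pfams$accession, run_one))
  }
  res <- if (is.null(seed)) body() else withr::with_seed(seed, body())

  res <- dplyr::left_join(
    res,
    target_pfams[c("accession", "label")],
    by = c(pfam = "accession")
  )
  res$reps <- as.integer(reps)
  res$n_runs <- as.integer(n_runs)
  res[c("pfam", "label", "detected", "d_obs", "n_focal", "n_other",
        "p_runs", "p_pseudo", "reps", "n_runs")]
}
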