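#' Per-Pfam integer count matrix for the negative-binomial test
#'
#' The NB machinery works on integer counts, while the pipeline pools
#' length-normalized values; the per-Pfam sums are therefore rounded to the
#' nearest integer (round-half-to-even).  Pfams whose rounded count is zero in
#' both communities are dropped — there is nothing to test.
#'
#' @param aggregates Aggregate tibble from [quantify_pfams()] (two
#'   communities).
#' @param target_pfams Target list tibble; only these Pfams are kept.
#' @return A tibble `pfam`, `k_a`, `k_b` with an attribute `communities`
#'   giving the two community ids (in `k_a`, `k_b` order).
#' @export
pfam_count_matrix <- function(aggregates, target_pfams) {
  communities <- unique(aggregates$community_id)
  if (length(communities) != 2) {
    stop("the NB test compares exactly two communities", call. = FALSE)
  }
  wide <- tidyr::pivot_wider(
    aggregates[aggregates$pfam %in% target_pfams$accession,
               c("community_id", "pfam", "p_raw")],
    names_from = "community_id",
    values_from = "p_raw",
    values_fill = 0
  )
  for (cid in communities) if (!cid %in% names(wide)) wide[[cid]] <- 0
  out <- tibble::tibble(
    pfam = wide$pfam,
    k_a = as.integer(round(wide[[communities[1]]])),
    k_b = as.integer(round(wide[[communities[2]]]))
  )
  out <- out[out$k_a + out$k_b > 0L, ]
  attr(out, "communities") <- communities
  out
}

#' Pooled-duplicate dispersion estimate
#'
#' With a single metatranscriptome per community there are no replicates, so
#' the two communities are temporarily pooled and treated as duplicate samples
#' to estimate count variance, under the working assumption that most Pfams
#' are not differentially expressed.  Per Pfam, the two size-normalized counts
#' give a method-of-moments mean `q` and variance `w`; the shot-noise
#' contribution `q * mean(1/S)` is subtracted and the single dispersion
#' `alpha` of the variance model `var = mu + alpha * mu^2` (`alpha = 0` is
#' the Poisson limit) is the median of the per-Pfam moment ratios
#' `excess / q^2` over Pfams with positive excess.  The median keeps a small
#' minority of genuinely discordant Pfams — exactly the ones the test is
#' meant to find — from inflating the dispersion for everyone, while a
#' broken working assumption still pushes `alpha` up, never down: the test
#' then loses power rather than gaining false positives.
#'
#' @param count_tbl Output of [pfam_count_matrix()].
#' @param size_factors Size factors from [compute_size_factors()] for the same
#'   two communities.
#' @return An object of class `pfamdiff_dispersion`: a list with `alpha` and
#'   `fit`, the per-Pfam tibble of `(q, w, excess)` points used in the fit.
#' @export
estimate_pooled_dispersion <- function(count_tbl, size_factors) {
  communities <- attr(count_tbl, "communities")
  s <- size_factors$size_factor[match(communities, size_factors$community_id)]
  if (anyNA(s)) {
    stop("size factors missing for the count-matrix communities",
         call. = FALSE)
  }
  usable <- count_tbl$k_a + count_tbl$k_b > 0L
  if (sum(usable) < 3) {
    stop(
      "pooled dispersion needs at least 3 Pfams with positive counts, got ",
      sum(usable),
      call. = FALSE
    )
  }
  q_a <- count_tbl$k_a / s[1]
  q_b <- count_tbl$k_b / s[2]
  q <- (q_a + q_b) / 2
  w <- (q_a - q_b)^2 / 2            # sample variance of two duplicates
  excess <- w - q * mean(1 / s)     # remove size-scaled shot noise
  fit <- tibble::tibble(pfam = count_tbl$pfam, q = q, w = w, excess = excess)
  pos <- excess > 0 & q > 0
  alpha <- if (any(pos)) {
    stats::median(excess[pos] / q[pos]^2)
  } else {
    0
  }
  structure(
    list(alpha = alpha, fit = fit, communities = communities),
    class = "pfamdiff_dispersion"
  )
}

#' @export
print.pfamdiff_dispersion <- function(x, ...) {
  cat(
    "Pooled-duplicate NB dispersion: alpha =", format(x$alpha, digits = 4),
    "fit on", nrow(x$fit), "Pfams\n"
  )
  invisible(x)
}

#' Conditional negative-binomial test for one Pfam
#'
#' Tests the null hypothesis that a Pfam's counts in the two communities
#' differ only by sequencing depth.  Conditioning on the total
#' `k_s = k_a + k_b`, each split `(a, k_s - a)` gets a joint probability from
#' independent NB marginals with means proportional to the size factors
#' (`mu_j = q_hat * S_j`, `q_hat = k_s / (S_a + S_b)`) and variance
#' `mu + alpha * mu^2`; the two-sided p-value is the total probability of
#' splits no more likely than the observed one, divided by the probability of
#' all splits.  Ties with the observed probability are included.  At
#' `alpha = 0` and equal size factors this reduces to the two-sided
#' conditional binomial(`k_s`, 1/2) test.
#'
#' @param k_a,k_b Non-negative integer counts, `k_a + k_b >= 1`.
#' @param s_a,s_b Positive size factors.
#' @param alpha Dispersion (`>= 0`), e.g. from
#'   [estimate_pooled_dispersion()].
#' @return A p-value in (0, 1].
#' @export
nb_conditional_test <- function(k_a, k_b, s_a, s_b, alpha = 0) {
  if (k_a < 0 || k_b < 0 || k_a != floor(k_a) || k_b != floor(k_b)) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  k_s <- k_a + k_b
  if (k_s < 1) {
    stop("total count must be at least 1", call. = FALSE)
  }
  q_hat <- k_s / (s_a + s_b)
  mu_a <- q_hat * s_a
  mu_b <- q_hat * s_b
  a <- 0:k_s
  if (alpha <= 0) {
    la <- stats::dpois(a, mu_a, log = TRUE)
    lb <- stats::dpois(a, mu_b, log = TRUE)
  } else {
    size <- 1 / alpha   # var = mu + alpha * mu^2  <=>  NB size = 1/alpha
    la <- stats::dnbinom(a, mu = mu_a, size = size, log = TRUE)
    lb <- stats::dnbinom(a, mu = mu_b, size = size, log = TRUE)
  }
  joint <- la + rev(lb)              # split (a, k_s - a)
  obs <- joint[k_a + 1]
  # include ties up to a small relative tolerance on the probability
  keep <- joint <= obs + 1e-7
  min(1, exp(logsumexp(joint[keep]) - logsumexp(joint)))
}

logsumexp <- function(x) {
  x <- x[x > -Inf]
  if (length(x) == 0) return(-Inf)
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of a vector of p-values, returned
#' in the input order.  Thin wrapper around [stats::p.adjust()].
#'
#' @param p Numeric vector of raw p-values in (0, 1].
#' @return Adjusted p-values, each `>=` its raw value, capped at 1.
#' @export
bh_adjust <- function(p) {
  stats::p.adjust(p, method = "BH")
}

#' Run the pooled-duplicate NB test over a target list
#'
#' Builds the per-Pfam integer count matrix, estimates the pooled-duplicate
#' dispersion, applies the conditional NB test to every testable Pfam, and
#' adjusts the p-values with Benjamini-Hochberg.
#'
#' @param aggregates Aggregate tibble from [quantify_pfams()] (two
#'   communities).
#' @param size_factors Size factors for the same communities.
#' @param target_pfams Target list tibble.
#' @return A tibble `pfam`, `label`, `k_a`, `k_b`, `p_nb`, `p_nb_adjusted`,
#'   with one row per target Pfam; Pfams dropped from the count matrix (zero
#'   in both communities) carry `NA` p-values.  The dispersion object is
#'   attached as attribute `dispersion`.
#' @export
run_nb_test <- function(aggregates, size_factors, target_pfams) {
  counts <- pfam_count_matrix(aggregates, target_pfams)
  communities <- attr(counts, "communities")
  disp <- estimate_pooled_dispersion(counts, size_factors)
  s <- size_factors$size_factor[match(communities, size_factors$community_id)]
  p_nb <- vapply(seq_len(nrow(counts)), function(i) {
    nb_conditional_test(counts$k_a[i], counts$k_b[i], s[1], s[2], disp$alpha)
  }, numeric(1))
  tested <- tibble::tibble(
    pfam = counts$pfam,
    k_a = counts$k_a,
    k_b = counts$k_b,
    p_nb = p_nb,
    p_nb_adjusted = bh_adjust(p_nb)
  )
  out <- dplyr::left_join(
    target_pfams[c("accession", "label")],
    tested,
    by = c(accession = "pfam")
  )
  out <- dplyr::rename(out, pfam = "accession")
  attr(out, "dispersion") <- disp
  attr(out, "communities") <- communities
  out
}

#' Significance calls at a fixed false-discovery threshold
#'
#' The permutation method is called significant on its raw (unadjusted) mean
#' p-value — false negatives being costlier than false positives when
#' screening for candidate enzymes — while the NB method is called on its
#' BH-adjusted p-value.  The consensus call requires both, the rule used to
#' select Pfams for follow-up.  The threshold is inclusive (`<=`).
#'
#' @param results A tibble carrying `p_pseudo` and `p_nb_adjusted` columns
#'   (e.g. the joined output of the two tests).
#' @param threshold Significance threshold, default 0.10.
#' @return The input with logical columns `sig_pseudo`, `sig_nb`, and
#'   `significant` (consensus) appended; `NA` p-values are never significant.
#' @export
call_significance <- function(results, threshold = 0.10) {
  sig <- function(p) !is.na(p) & p <= threshold
  dplyr::mutate(
    results,
    sig_pseudo = sig(.data$p_pseudo),
    sig_nb = sig(.data$p_nb_adjusted),
    significant = .data$sig_pseudo & .data$sig_nb
  )
}
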