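#' Pfam-level differential expression between two communities
#'
#' End-to-end comparison of two metatranscriptomes that may share no genes:
#' length-normalizes counts, pools them by Pfam, estimates median-of-ratios
#' size factors, and tests every target Pfam with both the pseudo-Pfam
#' permutation test (raw mean p, screening for overexpression in the focal
#' community) and the pooled-duplicate conditional NB test (BH-adjusted,
#' two-sided), calling consensus significance at the chosen threshold.
#'
#' @param catalog Gene catalog tibble covering both communities.
#' @param counts Count tibble covering the same communities.
#' @param targets Target-Pfam tibble, default the builtin 33 GH/CBM families.
#' @param focal Community screened for overexpression by the permutation
#'   test; defaults to the first community in the catalog.
#' @param reps,n_runs,seed Permutation-test controls, see
#'   [run_pseudo_pfam_test()].
#' @param threshold Significance threshold for both methods (inclusive),
#'   default 0.10.
#' @return An object of class `pfam_diff`; see [tidy.pfam_diff()] for the
#'   per-Pfam results table and [glance.pfam_diff()] for the one-row summary.
#' @export
#' @examples
#' sim <- simulate_communities(synthetic_config(seed = 42))
#' fit <- pfam_diff(sim$catalog, sim$counts, targets = sim$targets,
#'                  focal = "thermo", reps = 500, seed = 1)
#' tidy(fit)
#' glance(fit)
pfam_diff <- function(catalog, counts, targets = load_target_pfams(),
                      focal = NULL, reps = 10000L, n_runs = 3L, seed = NULL,
                      threshold = 0.10) {
  communities <- unique(catalog$community_id)
  if (length(communities) != 2) {
    stop("pfam_diff() compares exactly two communities", call. = FALSE)
  }
  focal <- if (is.null(focal)) communities[1] else as.character(focal)
  if (!focal %in% communities) {
    stop("focal community '", focal, "' not in the catalog", call. = FALSE)
  }
  other <- setdiff(communities, focal)

  quant <- quantify_pfams(catalog, counts)
  pools <- sampling_pools(catalog, counts, quant$size_factors)
  pseudo <- run_pseudo_pfam_test(
    quant$aggregates, pools, targets,
    focal = focal, reps = reps, n_runs = n_runs, seed = seed
  )
  nb <- run_nb_test(quant$aggregates, quant$size_factors, targets)
  dispersion <- attr(nb, "dispersion")

  agg_of <- function(cid, col) {
    sub <- quant$aggregates[quant$aggregates$community_id == cid, ]
    v <- sub[[col]][match(targets$accession, sub$pfam)]
    v[is.na(v)] <- 0
    v
  }
  fc <- fold_change(
    agg_of(focal, "P_norm"), agg_of(other, "P_norm"),
    names = c(focal, other)
  )
  results <- tibble::tibble(
    pfam = targets$accession,
    label = targets$label,
    category = targets$category,
    p_raw_focal = agg_of(focal, "p_raw"),
    p_raw_other = agg_of(other, "p_raw"),
    n_focal = as.integer(agg_of(focal, "n_expressed")),
    n_other = as.integer(agg_of(other, "n_expressed")),
    P_focal = agg_of(focal, "P_norm"),
    P_other = agg_of(other, "P_norm"),
    d_obs = pseudo$d_obs[match(targets$accession, pseudo$pfam)],
    fold = fc$fold,
    direction = fc$direction,
    detected = pseudo$detected[match(targets$accession, pseudo$pfam)],
    p_pseudo = pseudo$p_pseudo[match(targets$accession, pseudo$pfam)],
    p_nb = nb$p_nb[match(targets$accession, nb$pfam)],
    p_nb_adjusted = nb$p_nb_adjusted[match(targets$accession, nb$pfam)]
  )
  results <- call_significance(results, threshold = threshold)

  structure(
    list(
      results = results,
      aggregates = quant$aggregates,
      size_factors = quant$size_factors,
      norm_counts = quant$norm_counts,
      dispersion = dispersion,
      focal = focal,
      other = other,
      threshold = threshold,
      reps = as.integer(reps),
      n_runs = as.integer(n_runs)
    ),
    class = "pfam_diff"
  )
}

#' Tidy the per-Pfam results of a `pfam_diff` fit
#'
#' One row per target Pfam: pooled expression in each community, signed
#' difference, fold change and direction, both p-values, and the three
#' significance flags.  `fold` is `NA` when one community has zero expression
#' (undefined fold, direction still reported) and everything is `NA` when the
#' Pfam was not detected in either community.
#'
#' @param x A [pfam_diff()] object.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy pfam_diff
#' @export
tidy.pfam_diff <- function(x, ...) {
  x$results
}

#' One-row summary of a `pfam_diff` fit
#'
#' @param x A [pfam_diff()] object.
#' @param ... Unused.
#' @return A tibble with community ids, size factors, NB dispersion, counts
#'   of detected/significant Pfams, and the test controls.
#' @method glance pfam_diff
#' @export
glance.pfam_diff <- function(x, ...) {
  sf <- stats::setNames(x$size_factors$size_factor,
                        x$size_factors$community_id)
  tibble::tibble(
    focal = x$focal,
    other = x$other,
    size_factor_focal = unname(sf[x$focal]),
    size_factor_other = unname(sf[x$other]),
    alpha = x$dispersion$alpha,
    n_targets = nrow(x$results),
    n_detected = sum(x$results$detected),
    n_sig_pseudo = sum(x$results$sig_pseudo),
    n_sig_nb = sum(x$results$sig_nb),
    n_sig_consensus = sum(x$results$significant),
    threshold = x$threshold,
    reps = x$reps,
    n_runs = x$n_runs
  )
}

#' @export
print.pfam_diff <- function(x, ...) {
  g <- glance(x)
  cat("Pfam-level differential expression (", x$focal, " vs ", x$other,
      ")\n", sep = "")
  cat(sprintf(
    "  size factors: %s = %.3f, %s = %.3f;  NB dispersion alpha = %.4f\n",
    x$focal, g$size_factor_focal, x$other, g$size_factor_other, g$alpha
  ))
  cat(sprintf(
    "  %d target Pfams: %d detected, %d pseudo-significant, %d NB-significant, %d consensus (threshold %.2f)\n",
    g$n_targets, g$n_detected, g$n_sig_pseudo, g$n_sig_nb, g$n_sig_consensus,
    x$threshold
  ))
  hits <- x$results[x$results$significant, ]
  if (nrow(hits) > 0) {
    cat("  consensus-significant:",
        paste(sprintf("%s (%s)", hits$label, hits$pfam), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Plot a `pfam_diff` fit
#'
#' Per-Pfam fold change (log scale, signed towards the overexpressing
#' community) coloured by the consensus significance call.  Pfams with an
#' undefined fold (zero in one community) or not detected are omitted.
#'
#' @param object A [pfam_diff()] object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pfam_diff
#' @export
autoplot.pfam_diff <- function(object, ...) {
  res <- object$results[!is.na(object$results$fold), ]
  res$signed_log2_fold <- ifelse(
    res$direction == object$focal, log2(res$fold), -log2(res$fold)
  )
  call_of <- function(r) {
    ifelse(r$significant, "both methods",
           ifelse(r$sig_pseudo, "permutation only",
                  ifelse(r$sig_nb, "NB only", "neither")))
  }
  res$call <- factor(
    call_of(res),
    levels = c("both methods", "permutation only", "NB only", "neither")
  )
  ggplot2::ggplot(
    res,
    ggplot2::aes(
      x = stats::reorder(.data$label, .data$signed_log2_fold),
      y = .data$signed_log2_fold,
      fill = .data$call
    )
  ) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = NULL,
      y = sprintf("log2 fold change (positive = higher in %s)",
                  object$focal),
      fill = sprintf("significant at %.2f", object$threshold)
    ) +
    ggplot2::theme_minimal()
}

#' Write / read a combined results table
#'
#' Flat TSV export of [tidy.pfam_diff()] with list-free columns, suitable for
#' spreadsheets and downstream tooling.
#'
#' @param fit A [pfam_diff()] object (or its tidy tibble).
#' @param path Output TSV path.
#' @return The results tibble, invisibly.
#' @export
write_results <- function(fit, path) {
  res <- if (inherits(fit, "pfam_diff")) tidy(fit) else fit
  readr::write_tsv(res, path)
  invisible(res)
}

#' Plot a rarefaction curve
#'
#' @param curve Output of [rarefaction_curve()], optionally with a
#'   `community_id` column to draw one line per community.
#' @return A ggplot.
#' @export
plot_rarefaction <- function(curve) {
  aes <- if ("community_id" %in% names(curve)) {
    ggplot2::aes(.data$depth, .data$mean_detected,
                 colour = .data$community_id)
  } else {
    ggplot2::aes(.data$depth, .data$mean_detected)
  }
  ggplot2::ggplot(curve, aes) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "reads subsampled", y = "expressed genes detected",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a GH-family composition profile
#'
#' @param profile Output of [composition_profile()].
#' @return A ggplot.
#' @export
plot_composition <- function(profile) {
  ggplot2::ggplot(
    profile,
    ggplot2::aes(x = .data$label, y = .data$share_pct,
                 fill = .data$community_id)
  ) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "% of lignocellulolytic GH transcriptome",
                  fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60,
                                                       hjust = 1))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
#' @keywords internal
"_PACKAGE"
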