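#' Configuration for the two-community synthetic data generator
#'
#' Describes a pair of enriched communities with disjoint gene sets but a
#' shared Pfam universe, the statistical structure the comparative analysis
#' assumes: per-gene counts are negative-binomial with mean proportional to a
#' per-Pfam baseline transcription rate (reads per nucleotide), gene length,
#' a community library-size factor, and a planted fold change on a small set
#' of target Pfams overexpressed in one community.
#'
#' Defaults emulate the study design the pipeline is meant for: two
#' communities, one sequenced ~4 times deeper than the other, ~30 target
#' Pfams, planted folds of 130, 50 and 30 in the shallow community, per-gene
#' lengths log-uniform on 300-3000 nt, and order-of-magnitude variation in
#' per-Pfam baseline expression.
#'
#' @param n_genes Genes per community (each community gets its own genes).
#' @param n_pfams Number of Pfam categories in the shared universe.
#' @param n_target_pfams Number of those used as the differential-expression
#'   target list (the first `n_target_pfams`).
#' @param genes_per_pfam_min Guaranteed minimum genes per Pfam per community;
#'   remaining annotated genes are assigned uniformly at random.
#' @param length_range Gene-length range in nucleotides (log-uniform).
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters of the
#'   per-Pfam baseline transcription rate, in reads per nucleotide at library
#'   factor 1.  `baseline_sdlog = 0` makes all Pfams (and hence all annotated
#'   genes) exchangeable — the regime in which the pseudo-Pfam test's null is
#'   exact.
#' @param alpha Negative-binomial dispersion of per-gene counts
#'   (`var = mu + alpha * mu^2`); 0 gives Poisson counts.
#' @param library_ratio Library-size factor of the first community relative
#'   to the second (default 4, i.e. the first community is sequenced four
#'   times deeper).
#' @param planted_folds Fold changes (> 1) planted on the first
#'   `length(planted_folds)` target Pfams; empty vector plants nothing.
#' @param planted_community Community in which the planted Pfams are
#'   overexpressed (default the shallow, second community).
#' @param communities Length-2 character vector of community ids; the first
#'   carries `library_ratio`.
#' @param multi_pfam_frac Fraction of annotated genes carrying a second Pfam
#'   annotation.
#' @param unannotated_frac Fraction of genes with no Pfam annotation.
#' @param shared_gene_frac Fraction of the second community's annotated genes
#'   copied verbatim (id, length, annotations) from the first; default 0 —
#'   fully disjoint gene sets.
#' @param n_genera,n_phyla Size of the taxonomy model; genera are assigned to
#'   phyla round-robin and every Pfam gets a community-specific dominant
#'   genus.
#' @param seed Integer seed; the whole dataset is a pure function of the
#'   config, including this seed.
#' @return An object of class `synthetic_config` (a validated list).
#' @export
synthetic_config <- function(n_genes = 1200L,
                             n_pfams = 120L,
                             n_target_pfams = 30L,
                             genes_per_pfam_min = 3L,
                             length_range = c(300L, 3000L),
                             baseline_meanlog = 0,
                             baseline_sdlog = 1,
                             alpha = 0.05,
                             library_ratio = 4,
                             planted_folds = c(130, 50, 30),
                             planted_community = NULL,
                             communities = c("meso", "thermo"),
                             multi_pfam_frac = 0.10,
                             unannotated_frac = 0.25,
                             shared_gene_frac = 0,
                             n_genera = 12L,
                             n_phyla = 4L,
                             seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes),
    n_pfams = as.integer(n_pfams),
    n_target_pfams = as.integer(n_target_pfams),
    genes_per_pfam_min = as.integer(genes_per_pfam_min),
    length_range = as.integer(length_range),
    baseline_meanlog = baseline_meanlog,
    baseline_sdlog = baseline_sdlog,
    alpha = alpha,
    library_ratio = library_ratio,
    planted_folds = as.numeric(planted_folds),
    planted_community = if (is.null(planted_community)) {
      communities[2]
    } else {
      as.character(planted_community)
    },
    communities = as.character(communities),
    multi_pfam_frac = multi_pfam_frac,
    unannotated_frac = unannotated_frac,
    shared_gene_frac = shared_gene_frac,
    n_genera = as.integer(n_genera),
    n_phyla = as.integer(n_phyla),
    seed = as.integer(seed)
  )
  if (length(cfg$communities) != 2 ||
      anyDuplicated(cfg$communities) > 0) {
    stop("communities must be two distinct ids", call. = FALSE)
  }
  if (!cfg$planted_community %in% cfg$communities) {
    stop("planted_community must be one of the two communities",
         call. = FALSE)
  }
  if (length(cfg$planted_folds) > 0 && any(cfg$planted_folds <= 1)) {
    stop("planted fold changes must exceed 1", call. = FALSE)
  }
  if (cfg$n_target_pfams > cfg$n_pfams) {
    stop("n_target_pfams cannot exceed n_pfams", call. = FALSE)
  }
  if (length(cfg$planted_folds) > cfg$n_target_pfams) {
    stop("more planted folds than target Pfams", call. = FALSE)
  }
  n_ann <- round(cfg$n_genes * (1 - cfg$unannotated_frac))
  if (n_ann < cfg$n_pfams * cfg$genes_per_pfam_min) {
    stop(
      "infeasible config: ", n_ann, " annotated genes cannot give every one ",
      "of ", cfg$n_pfams, " Pfams at least ", cfg$genes_per_pfam_min,
      " genes",
      call. = FALSE
    )
  }
  if (cfg$library_ratio <= 0 || cfg$alpha < 0) {
    stop("library_ratio must be positive and alpha non-negative",
         call. = FALSE)
  }
  structure(cfg, class = "synthetic_config")
}

# deterministic synthetic Pfam universe (accessions in a reserved high range
# so they cannot collide with real target lists)
synthetic_pfam_universe <- function(config) {
  sprintf("PF9%04d", seq_len(config$n_pfams))
}

#' Target list for a synthetic dataset
#'
#' The first `n_target_pfams` of the synthetic Pfam universe, shaped like
#' [load_target_pfams()] output so it drops into the tests.  Categories
#' alternate GH/CBM so that GH-only operations (e.g. composition profiles)
#' are exercised.
#'
#' @param config A [synthetic_config()].
#' @return A tibble `accession`, `label`, `category`.
#' @export
synthetic_target_pfams <- function(config) {
  acc <- synthetic_pfam_universe(config)[seq_len(config$n_target_pfams)]
  tibble::tibble(
    accession = acc,
    label = acc,
    category = rep_len(c("GH", "CBM"), length(acc))
  )
}

#' Ground truth of planted effects
#'
#' Pure function of the config (no randomness): which target Pfams carry a
#' planted fold change, in which community, and the null remainder.
#'
#' @param config A [synthetic_config()].
#' @return A tibble `pfam`, `planted`, `fold`, `favored_community` covering
#'   every target Pfam (`fold = 1`, `favored_community = NA` for nulls).
#' @export
synthetic_truth <- function(config) {
  targets <- synthetic_target_pfams(config)$accession
  n_planted <- length(config$planted_folds)
  tibble::tibble(
    pfam = targets,
    planted = seq_along(targets) <= n_planted,
    fold = c(config$planted_folds,
             rep(1, length(targets) - n_planted)),
    favored_community = ifelse(
      seq_along(targets) <= n_planted, config$planted_community, NA_character_
    )
  )
}

#' Generate the two community gene catalogs
#'
#' Each community gets its own genes (disjoint ids unless
#' `shared_gene_frac > 0`): lengths log-uniform over `length_range`, every
#' Pfam guaranteed `genes_per_pfam_min` genes with the remainder assigned
#' uniformly, a `multi_pfam_frac` share of genes carrying a second Pfam, an
#' `unannotated_frac` share carrying none, and genus/phylum bins drawn from a
#' per-Pfam dominant-genus taxonomy model.
#'
#' @param config A [synthetic_config()].
#' @return A catalog tibble covering both communities (same shape as
#'   [read_gene_catalog()] output).
#' @export
generate_catalogs <- function(config) {
  withr::with_seed(config$seed, generate_catalogs_impl(config))
}

generate_catalogs_impl <- function(config) {
  universe <- synthetic_pfam_universe(config)
  genera <- sprintf("genus_%02d", seq_len(config$n_genera))
  phyla <- sprintf("phylum_%02d", seq_len(config$n_phyla))
  phylum_of <- stats::setNames(
    rep_len(phyla, config$n_genera), genera
  )

  one_community <- function(cid) {
    n <- config$n_genes
    n_ann <- round(n * (1 - config$unannotated_frac))
    gene_id <- sprintf("%s_g%05d", cid, seq_len(n))
    length_nt <- as.integer(round(exp(stats::runif(
      n, log(config$length_range[1]), log(config$length_range[2])
    ))))
    length_nt <- pmax(length_nt, config$length_range[1])

    # primary Pfam: deal the guaranteed minimum round-robin, rest uniform
    base <- rep(seq_len(config$n_pfams), config$genes_per_pfam_min)
    extra <- sample.int(config$n_pfams, n_ann - length(base), replace = TRUE)
    primary <- sample(c(base, extra))        # shuffle over annotated genes
    pfams <- vector("list", n)
    pfams[seq_len(n_ann)] <- lapply(primary, function(i) universe[i])
    pfams[seq(n_ann + 1, length.out = n - n_ann)] <-
      replicate(n - n_ann, character(0), simplify = FALSE)

    n_multi <- floor(config$multi_pfam_frac * n_ann)
    if (n_multi > 0) {
      which_multi <- sample.int(n_ann, n_multi)
      for (g in which_multi) {
        others <- setdiff(seq_len(config$n_pfams), primary[g])
        pfams[[g]] <- c(pfams[[g]], universe[sample(others, 1)])
      }
    }

    dominant <- sample(genera, config$n_pfams, replace = TRUE)
    genus <- character(n)
    for (g in seq_len(n_ann)) {
      genus[g] <- if (stats::runif(1) < 0.6) {
        dominant[primary[g]]
      } else {
        sample(genera, 1)
      }
    }
    if (n > n_ann) {
      genus[seq(n_ann + 1, n)] <- sample(genera, n - n_ann, replace = TRUE)
    }

    tibble::tibble(
      community_id = cid,
      gene_id = gene_id,
      length = length_nt,
      pfams = pfams,
      phylum = unname(phylum_of[genus]),
      genus = genus
    )
  }

  cat_a <- one_community(config$communities[1])
  cat_b <- one_community(config$communities[2])

  if (config$shared_gene_frac > 0) {
    ann_a <- which(lengths(cat_a$pfams) > 0)
    ann_b <- which(lengths(cat_b$pfams) > 0)
    k <- floor(config$shared_gene_frac * length(ann_b))
    if (k > 0) {
      src <- ann_a[seq_len(min(k, length(ann_a)))]
      dst <- ann_b[seq_along(src)]
      cat_b$gene_id[dst] <- cat_a$gene_id[src]
      cat_b$length[dst] <- cat_a$length[src]
      cat_b$pfams[dst] <- cat_a$pfams[src]
      cat_b$genus[dst] <- cat_a$genus[src]
      cat_b$phylum[dst] <- cat_a$phylum[src]
    }
  }

  validate_gene_catalog(dplyr::bind_rows(cat_a, cat_b))
}

#' Generate mapped-read counts for synthetic catalogs
#'
#' Per-gene counts are negative-binomial with mean
#' `baseline(pfam) * length * library_factor * planted_fold`, where the
#' baseline is a per-Pfam transcription rate shared by both communities
#' (log-normal across Pfams), the library factor is `library_ratio` for the
#' first community and 1 for the second, and the planted fold applies only in
#' the favored community to genes annotated to a planted Pfam.  Unannotated
#' genes draw their own rate from the same baseline distribution.  Gene
#' length enters the mean multiplicatively, so length normalization is
#' genuinely exercised downstream.
#'
#' @param catalogs Catalog tibble from [generate_catalogs()].
#' @param config The same [synthetic_config()].
#' @return A count tibble covering both communities (`community_id`,
#'   `gene_id`, `count`).
#' @export
generate_counts <- function(catalogs, config) {
  withr::with_seed(
    config$seed + 1L,
    generate_counts_impl(catalogs, config)
  )
}

generate_counts_impl <- function(catalogs, config) {
  universe <- synthetic_pfam_universe(config)
  rate <- stats::setNames(
    stats::rlnorm(config$n_pfams, config$baseline_meanlog,
                  config$baseline_sdlog),
    universe
  )
  truth <- synthetic_truth(config)
  fold_of <- stats::setNames(truth$fold, truth$pfam)
  lib <- stats::setNames(
    c(config$library_ratio, 1), config$communities
  )

  n <- nrow(catalogs)
  gene_rate <- numeric(n)
  gene_fold <- rep(1, n)
  primary <- vapply(
    catalogs$pfams,
    function(p) if (length(p) > 0) p[1] else NA_character_,
    character(1)
  )
  ann <- !is.na(primary)
  gene_rate[ann] <- rate[primary[ann]]
  gene_rate[!ann] <- stats::rlnorm(
    sum(!ann), config$baseline_meanlog, config$baseline_sdlog
  )
  favored <- catalogs$community_id == config$planted_community
  if (any(truth$planted)) {
    planted_fold <- fold_of[truth$pfam[truth$planted]]
    max_planted <- vapply(catalogs$pfams, function(p) {
      hit <- intersect(p, names(planted_fold))
      if (length(hit) == 0) 1 else max(planted_fold[hit])
    }, numeric(1))
    gene_fold[favored] <- max_planted[favored]
  }

  mu <- gene_rate * catalogs$length * unname(lib[catalogs$community_id]) *
    gene_fold
  counts <- if (config$alpha <= 0) {
    stats::rpois(n, mu)
  } else {
    stats::rnbinom(n, mu = mu, size = 1 / config$alpha)
  }
  tibble::tibble(
    community_id = catalogs$community_id,
    gene_id = catalogs$gene_id,
    count = as.integer(counts)
  )
}

#' Simulate a complete two-community dataset
#'
#' Catalogs, counts, target list and ground truth in one call; the result is
#' a pure function of the config.
#'
#' @param config A [synthetic_config()].
#' @return A list with `catalog`, `counts`, `targets`, `truth`, `config`.
#' @export
simulate_communities <- function(config = synthetic_config()) {
  catalog <- generate_catalogs(config)
  counts <- generate_counts(catalog, config)
  list(
    catalog = catalog,
    counts = counts,
    targets = synthetic_target_pfams(config),
    truth = synthetic_truth(config),
    config = config
  )
}
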