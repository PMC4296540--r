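# Small in-code fixtures and independent oracles shared across test files.

# a tiny single-community catalog built directly as a tibble
tiny_catalog <- function(community_id = "a",
                         gene_id = c("g1", "g2", "g3"),
                         length = c(1500L, 1000L, 500L),
                         pfams = list("PF00001", c("PF00001", "PF00002"),
                                      character(0)),
                         genus = c("Micromonospora", "Niastella", "unknown"),
                         phylum = c("Actinobacteria", "Bacteroidetes",
                                    "unknown")) {
  tibble::tibble(
    community_id = community_id,
    gene_id = gene_id,
    length = length,
    pfams = pfams,
    phylum = phylum,
    genus = genus
  )
}

tiny_counts <- function(catalog, counts) {
  tibble::tibble(
    community_id = catalog$community_id,
    gene_id = catalog$gene_id,
    count = as.integer(counts)
  )
}

# write a catalog TSV from raw strings (to exercise the parser dialect)
write_catalog_file <- function(lines,
                               header = "gene_id\tlength\tpfams\tphylum\tgenus") {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(c(header, lines), path)
  path
}

write_counts_file <- function(lines, header = "gene_id\tcount") {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(c(header, lines), path)
  path
}

# --- independent oracles -------------------------------------------------

# exact pseudo-Pfam p-value by exhaustive enumeration of all unordered draws
# of n_a from pool_a and n_b from pool_b: P(sum_a - sum_b >= d_obs).
exhaustive_pseudo_pvalue <- function(pool_a, pool_b, n_a, n_b, d_obs) {
  sums_of <- function(pool, n) {
    if (n == 0) return(0)
    combos <- utils::combn(length(pool), n)
    colSums(matrix(pool[combos], nrow = n))
  }
  sa <- sums_of(pool_a, n_a)
  sb <- sums_of(pool_b, n_b)
  diff <- outer(sa, sb, `-`)
  mean(diff >= d_obs)
}

# exact null distribution of pseudo differences (value, probability)
exhaustive_pseudo_null <- function(pool_a, pool_b, n_a, n_b) {
  sums_of <- function(pool, n) {
    if (n == 0) return(0)
    combos <- utils::combn(length(pool), n)
    colSums(matrix(pool[combos], nrow = n))
  }
  as.vector(outer(sums_of(pool_a, n_a), sums_of(pool_b, n_b), `-`))
}

# two-sided conditional binomial test: total k_s split with probability 1/2,
# summing outcomes no more likely than the observed split (ties included)
binomial_conditional_pvalue <- function(k_a, k_b) {
  k_s <- k_a + k_b
  pr <- stats::dbinom(0:k_s, k_s, 0.5)
  obs <- pr[k_a + 1]
  sum(pr[pr <= obs * (1 + 1e-7)])
}

# expected number of genes detected when m reads are drawn without
# replacement from the count multiset (hypergeometric closed form)
expected_detected <- function(counts, m) {
  total <- sum(counts)
  sum(1 - exp(lchoose(total - counts, m) - lchoose(total, m)))
}
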