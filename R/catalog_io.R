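#' Read a gene catalog
#'
#' A gene catalog describes one community's metagenome genes: identifier,
#' length in nucleotides, zero or more Pfam domain annotations, and a
#' phylum/genus bin from phylogenetic binning of the assembly.  Mapped-read
#' counts (read separately, see [read_count_table()]) are length-normalized
#' against these lengths, so lengths are in nucleotides, not codons.
#'
#' The file is tab-separated with header columns `gene_id`, `length`, `pfams`,
#' `phylum`, `genus`.  `pfams` is a semicolon-separated list of accessions and
#' may be blank (such genes are kept in the catalog but never enter Pfam-level
#' pooling); blank taxon fields become `"unknown"`.
#'
#' @param path Path to the TSV file.
#' @param community_id Identifier attached to every record, e.g. `"meso"`.
#' @return A tibble with columns `community_id`, `gene_id`, `length` (integer),
#'   `pfams` (list-column of character vectors, normalized accessions),
#'   `phylum`, `genus`.
#' @export
read_gene_catalog <- function(path, community_id) {
  if (!file.exists(path)) {
    stop("gene catalog file not found: ", path, call. = FALSE)
  }
  raw <- readr::read_tsv(
    path,
    col_types = readr::cols(
      gene_id = readr::col_character(),
      length = readr::col_double(),
      pfams = readr::col_character(),
      phylum = readr::col_character(),
      genus = readr::col_character()
    ),
    na = character()  # keep blanks as "", they carry meaning here
  )
  missing <- setdiff(c("gene_id", "length", "pfams", "phylum", "genus"),
                     names(raw))
  if (length(missing) > 0) {
    stop(
      "gene catalog lacks column(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  catalog <- tibble::tibble(
    community_id = as.character(community_id),
    gene_id = raw$gene_id,
    length = raw$length,
    pfams = split_pfam_field(raw$pfams),
    phylum = ifelse(is.na(raw$phylum) | raw$phylum == "", "unknown", raw$phylum),
    genus = ifelse(is.na(raw$genus) | raw$genus == "", "unknown", raw$genus)
  )
  validate_gene_catalog(catalog)
}

split_pfam_field <- function(x) {
  lapply(strsplit(ifelse(is.na(x), "", x), ";", fixed = TRUE), function(p) {
    p <- trimws(p)
    normalize_pfam_acc(p[p != ""])
  })
}

#' Validate a gene catalog tibble
#'
#' Checks the catalog invariants: unique `gene_id` within each community and
#' strictly positive integer lengths.  Called by [read_gene_catalog()] and the
#' synthetic generator; useful directly when a catalog is assembled in code.
#'
#' @param catalog A tibble shaped like the output of [read_gene_catalog()].
#' @return The catalog, invisibly unchanged, for piping.
#' @export
validate_gene_catalog <- function(catalog) {
  needed <- c("community_id", "gene_id", "length", "pfams", "phylum", "genus")
  missing <- setdiff(needed, names(catalog))
  if (length(missing) > 0) {
    stop(
      "catalog lacks column(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  bad_len <- !is.finite(catalog$length) | catalog$length < 1 |
    catalog$length != floor(catalog$length)
  if (any(bad_len)) {
    stop(
      "non-positive or non-integer gene length for: ",
      paste(utils::head(catalog$gene_id[bad_len], 5), collapse = ", "),
      call. = FALSE
    )
  }
  for (cid in unique(catalog$community_id)) {
    ids <- catalog$gene_id[catalog$community_id == cid]
    dup <- unique(ids[duplicated(ids)])
    if (length(dup) > 0) {
      stop(
        "duplicated gene_id in community '", cid, "': ",
        paste(utils::head(dup, 5), collapse = ", "),
        call. = FALSE
      )
    }
  }
  catalog$length <- as.integer(catalog$length)
  catalog
}

#' Read a mapped-read count table
#'
#' Counts of mRNA reads mapped to each catalog gene, one community per file.
#' The file is a TSV with header `gene_id`, `count`.  Genes present in the
#' catalog but absent from the file get count 0 — a metagenome typically
#' contains many genes that are never detected as expressed — while a
#' `gene_id` absent from the catalog is an error.
#'
#' @param path Path to the TSV file.
#' @param catalog The paired gene catalog (one community) from
#'   [read_gene_catalog()].
#' @return A tibble with columns `community_id`, `gene_id`, `count` (integer),
#'   one row per catalog gene in catalog order.
#' @export
read_count_table <- function(path, catalog) {
  if (!file.exists(path)) {
    stop("count table file not found: ", path, call. = FALSE)
  }
  cid <- unique(catalog$community_id)
  if (length(cid) != 1) {
    stop("count tables are per-community; catalog has ",
         length(cid), " community ids", call. = FALSE)
  }
  raw <- readr::read_tsv(
    path,
    col_types = readr::cols(
      gene_id = readr::col_character(),
      count = readr::col_double()
    )
  )
  missing <- setdiff(c("gene_id", "count"), names(raw))
  if (length(missing) > 0) {
    stop(
      "count table lacks column(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  unknown <- setdiff(raw$gene_id, catalog$gene_id)
  if (length(unknown) > 0) {
    stop(
      "count table gene_id(s) not in catalog: ",
      paste(utils::head(unknown, 5), collapse = ", "),
      call. = FALSE
    )
  }
  dup <- unique(raw$gene_id[duplicated(raw$gene_id)])
  if (length(dup) > 0) {
    stop(
      "duplicated gene_id in count table: ",
      paste(utils::head(dup, 5), collapse = ", "),
      call. = FALSE
    )
  }
  bad <- !is.finite(raw$count) | raw$count < 0 | raw$count != floor(raw$count)
  if (any(bad)) {
    stop(
      "negative or non-integer count for: ",
      paste(utils::head(raw$gene_id[bad], 5), collapse = ", "),
      call. = FALSE
    )
  }
  counts <- tibble::tibble(
    community_id = cid,
    gene_id = catalog$gene_id,
    count = raw$count[match(catalog$gene_id, raw$gene_id)]
  )
  counts$count[is.na(counts$count)] <- 0
  counts$count <- as.integer(counts$count)
  counts
}

#' Write a gene catalog / count table to TSV
#'
#' Inverse of [read_gene_catalog()] and [read_count_table()]: writing then
#' reading reproduces the in-memory tibbles exactly (multi-Pfam annotations are
#' re-joined with `";"`).
#'
#' @param catalog,counts Tibbles as produced by the readers (one community).
#' @param path Output file path.
#' @return The input, invisibly.
#' @export
write_gene_catalog <- function(catalog, path) {
  out <- tibble::tibble(
    gene_id = catalog$gene_id,
    length = catalog$length,
    pfams = vapply(catalog$pfams, paste, character(1), collapse = ";"),
    phylum = catalog$phylum,
    genus = catalog$genus
  )
  readr::write_tsv(out, path)
  invisible(catalog)
}

#' @rdname write_gene_catalog
#' @export
write_count_table <- function(counts, path) {
  readr::write_tsv(counts[c("gene_id", "count")], path)
  invisible(counts)
}
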