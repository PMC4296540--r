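#' Canonicalize Pfam accessions
#'
#' Pfam accessions appear in the wild as `PF02011`, `Pfam02011`, or `pf2011`.
#' All are normalized to the zero-padded `PF#####` form so catalogs and target
#' lists written in different styles join correctly.  Strings that do not look
#' like a Pfam accession (e.g. ad hoc category labels in custom target lists)
#' are returned unchanged.
#'
#' @param x Character vector of accession strings.
#' @return Character vector of the same length.
#' @export
#' @examples
#' normalize_pfam_acc(c("Pfam02011", "PF00553", "pf150", "my_custom_family"))
normalize_pfam_acc <- function(x) {
  x <- trimws(as.character(x))
  hit <- grepl("^(pf|pfam)[0-9]{1,7}$", x, ignore.case = TRUE)
  if (any(hit)) {
    num <- as.integer(sub("^(pf|pfam)", "", x[hit], ignore.case = TRUE))
    x[hit] <- sprintf("PF%05d", num)
  }
  x
}

# The 33 lignocellulose-relevant GH/CBM protein families targeted by the
# differential-expression analysis: 21 glycoside hydrolase domain families and
# 12 carbohydrate binding module families.
builtin_target_table <- function() {
  gh <- c(
    PF00150 = "GH5",   PF00232 = "GH1",   PF00331 = "GH10", PF00457 = "GH11",
    PF00722 = "GH16",  PF00759 = "GH9",   PF00840 = "GH7",  PF00933 = "GH3",
    PF01270 = "GH8",   PF01341 = "GH6",   PF01670 = "GH12", PF01915 = "GH3C",
    PF02011 = "GH48",  PF02015 = "GH45",  PF02156 = "GH26", PF03443 = "GH61",
    PF03648 = "GH67N", PF03664 = "GH62",  PF04616 = "GH43", PF07477 = "GH67C",
    PF07488 = "GH67M"
  )
  cbm <- c(
    PF00553 = "CBM2",  PF00734 = "CBM1",  PF00942 = "CBM3",
    PF02013 = "CBM10", PF02018 = "CBM4,9", PF03067 = "CBM33",
    PF03422 = "CBM6",  PF03424 = "CBM17,28", PF03425 = "CBM11",
    PF03426 = "CBM15", PF09212 = "CBM27", PF09478 = "CBM49"
  )
  tibble::tibble(
    accession = c(names(gh), names(cbm)),
    label = unname(c(gh, cbm)),
    category = rep(c("GH", "CBM"), c(length(gh), length(cbm)))
  )
}

#' Load a target-Pfam list
#'
#' The target list names the protein families whose pooled expression is
#' compared between communities.  The builtin default is the 33 glycoside
#' hydrolase (GH) and carbohydrate binding module (CBM) Pfam families relevant
#' to lignocellulose deconstruction, e.g. `PF02011` (GH48, reducing-end-acting
#' cellobiohydrolases), `PF00553` (CBM2) and `PF03067` (CBM33, lytic
#' polysaccharide monooxygenases).
#'
#' @param source `"builtin"` for the default 33-family list, or a path to a
#'   tab-separated file with columns `accession`, `label`, `category`
#'   (`category` must be `"GH"` or `"CBM"`).
#' @return A tibble with columns `accession` (normalized, see
#'   [normalize_pfam_acc()]), `label`, and `category`.
#' @export
#' @examples
#' targets <- load_target_pfams()
#' nrow(targets)  # 33
#' targets[targets$label == "GH48", ]
load_target_pfams <- function(source = "builtin") {
  if (identical(source, "builtin")) {
    return(builtin_target_table())
  }
  if (!file.exists(source)) {
    stop("target-Pfam file not found: ", source, call. = FALSE)
  }
  tbl <- readr::read_tsv(
    source,
    col_types = readr::cols(
      accession = readr::col_character(),
      label = readr::col_character(),
      category = readr::col_character()
    )
  )
  missing <- setdiff(c("accession", "label", "category"), names(tbl))
  if (length(missing) > 0) {
    stop(
      "target-Pfam file lacks column(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  tbl <- tibble::as_tibble(tbl[c("accession", "label", "category")])
  tbl$accession <- normalize_pfam_acc(tbl$accession)
  bad_cat <- setdiff(unique(tbl$category), c("GH", "CBM"))
  if (length(bad_cat) > 0) {
    stop(
      "malformed target category (must be GH or CBM): ",
      paste(bad_cat, collapse = ", "),
      call. = FALSE
    )
  }
  dup <- tbl$accession[duplicated(tbl$accession)]
  if (length(dup) > 0) {
    stop(
      "duplicated target accession(s): ", paste(unique(dup), collapse = ", "),
      call. = FALSE
    )
  }
  tbl
}
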