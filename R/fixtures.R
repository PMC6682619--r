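#' Packaged strain overview table
#'
#' Loads the packaged transcription of the re-analyzed mouse strain overview:
#' one row per modified strain with gene symbol(s), protein, genetic
#' modification, background, wild-type database id, the reported direction of
#' the surface-area-coverage change, and the in vivo thrombosis and bleeding
#' phenotype labels.
#'
#' Phenotype tokens are validated against the fixed vocabulary
#' (`up`, `down`, `o`, `nd`, plus the composite `o/up`) and normalised to
#' categorical labels: thrombosis `increased`/`decreased`/`unchanged`/`nd`,
#' bleeding `prolonged`/`shortened`/`unchanged`/`nd`. Composite tokens are
#' resolved to the more severe phenotype; the raw token is kept in the
#' `*_token` columns.
#'
#' @return a data.frame with one row per strain; attributes `n_strains`,
#'   `n_genes` (distinct gene symbols, dual-deficiency rows split on "/"),
#'   and `n_wildtype_datasets` (distinct database ids).
#' @examples
#' tab <- load_table1_fixture()
#' attr(tab, "n_strains")
#' subset(tab, gene == "Gp6")[, c("thrombosis", "bleeding")]
#' @export
load_table1_fixture <- function() {
  path <- system.file("extdata", "table1_strains.tsv", package = "thrombomap",
                      mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  tok_ok <- c("up", "down", "o", "nd", "o/up")
  for (col in c("delta_sac", "thrombosis", "bleeding")) {
    tok <- normalize_token(tab[[col]])
    bad <- which(!tok %in% tok_ok)
    if (length(bad))
      stop(sprintf("parse error: unknown %s token '%s' in row %d",
                   col, tab[[col]][bad[1]], bad[1]), call. = FALSE)
    tab[[paste0(col, "_token")]] <- tok
  }
  tab$thrombosis <- map_token(tab$thrombosis_token,
                              c(up = "increased", down = "decreased",
                                o = "unchanged", nd = "nd", `o/up` = "increased"))
  tab$bleeding <- map_token(tab$bleeding_token,
                            c(up = "prolonged", down = "shortened",
                              o = "unchanged", nd = "nd", `o/up` = "prolonged"))
  tab$strain_id <- tab$gene
  attr(tab, "n_strains") <- nrow(tab)
  attr(tab, "n_genes") <- length(unique(unlist(strsplit(tab$gene, "/", fixed = TRUE))))
  attr(tab, "n_wildtype_datasets") <- length(unique(tab$database_id))
  tab
}

normalize_token <- function(x) {
  x <- trimws(tolower(x))
  x[x %in% c("n.d.", "n.d")] <- "nd"
  x
}

map_token <- function(tok, map) unname(map[tok])

#' Parameter definitions and observed ranges
#'
#' The eight thrombus-formation parameters with their image type (brightfield
#' or fluorescence), valid value range, and the common 0-10 scaling maximum.
#' P1/P2 and P6-P8 are %SAC values; P3-P5 are visual scores assigned against
#' standard images.
#'
#' @return a data.frame with columns `parameter`, `description`, `image`,
#'   `range_min`, `range_max`, `scale_max`.
#' @export
load_table2_ranges <- function() {
  path <- system.file("extdata", "table2_parameters.tsv", package = "thrombomap",
                      mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

# named list: parameter -> c(min, max) of the valid value range
parameter_ranges <- function() {
  # score ranges fixed by the assay; %SAC ranges are bounded by 100
  list(P1 = c(0, 100), P2 = c(0, 100), P3 = c(0, 5), P4 = c(0, 3),
       P5 = c(0, 3), P6 = c(0, 100), P7 = c(0, 100), P8 = c(0, 100))
}

parameter_names <- function() paste0("P", 1:8)
visual_scores <- function() c("P3", "P4", "P5")
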