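#' Phenotype annotation record
#'
#' Categorical in vivo phenotype labels for one strain, with a fixed
#' vocabulary: thrombosis `decreased`/`unchanged`/`increased`/`nd` and
#' bleeding `prolonged`/`unchanged`/`shortened`/`nd`.
#'
#' @param strain_id strain label matching the delta matrix rows.
#' @param thrombosis,bleeding category tokens.
#' @return one-row data.frame.
#' @export
phenotype_annotation <- function(strain_id, thrombosis, bleeding) {
  tok_t <- c("decreased", "unchanged", "increased", "nd")
  tok_b <- c("prolonged", "unchanged", "shortened", "nd")
  if (!thrombosis %in% tok_t)
    stop("parse error: unknown thrombosis category '", thrombosis, "'", call. = FALSE)
  if (!bleeding %in% tok_b)
    stop("parse error: unknown bleeding category '", bleeding, "'", call. = FALSE)
  data.frame(strain_id = strain_id, thrombosis = thrombosis, bleeding = bleeding,
             stringsAsFactors = FALSE)
}

#' In vitro / in vivo phenotype concordance
#'
#' Classifies each modified strain by the sign of its relevance-filtered
#' overall effect on thrombus formation (summed P1-P5 deltas at the given
#' surface): `decreased`, `unchanged` (all cells irrelevant or net zero), or
#' `increased`. The classes are then cross-tabulated against the annotated
#' in vivo thrombosis and bleeding phenotypes; `nd` annotations are
#' tabulated in their own column.
#'
#' @param dm a [build_delta_matrix()] result.
#' @param annotations data.frame with `strain_id`, `thrombosis`, `bleeding`
#'   (e.g. from [load_table1_fixture()]).
#' @param surface microspot used for the in vitro classification.
#' @return list with `classes` (per-strain data.frame: strain_id,
#'   in_vitro_class, effect, thrombosis, bleeding), and contingency tables
#'   `thrombosis` and `bleeding` (rows = in vitro class).
#' @export
concordance_table <- function(dm, annotations, surface = "M1") {
  stopifnot(inherits(dm, "delta_matrix"))
  req <- c("strain_id", "thrombosis", "bleeding")
  if (!all(req %in% names(annotations)))
    stop("annotations must have columns ", paste(req, collapse = ", "), call. = FALSE)
  for (i in seq_len(nrow(annotations)))      # vocabulary validation
    phenotype_annotation(annotations$strain_id[i], annotations$thrombosis[i],
                         annotations$bleeding[i])

  eff <- effect_sum(dm, parameters = paste0("P", 1:5), surface = surface)
  cls <- ifelse(eff < 0, "decreased", ifelse(eff > 0, "increased", "unchanged"))
  classes <- data.frame(strain_id = names(eff), in_vitro_class = cls,
                        effect = unname(eff), stringsAsFactors = FALSE)
  classes <- merge(classes, annotations[, req], by = "strain_id",
                   all.x = TRUE, sort = TRUE)
  classes$thrombosis[is.na(classes$thrombosis)] <- "nd"
  classes$bleeding[is.na(classes$bleeding)] <- "nd"

  lv_cls <- c("decreased", "unchanged", "increased")
  xt <- function(col, lv) table(factor(classes$in_vitro_class, lv_cls),
                                factor(classes[[col]], lv),
                                dnn = c("in_vitro", col))
  list(classes = classes,
       thrombosis = xt("thrombosis", c("decreased", "unchanged", "increased", "nd")),
       bleeding = xt("bleeding", c("prolonged", "unchanged", "shortened", "nd")))
}
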