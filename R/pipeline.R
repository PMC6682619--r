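#' Pipeline run configuration
#'
#' Assembles and validates the configuration driving [run_pipeline()].
#' Unknown keys are rejected, so configs round-trip losslessly through
#' their YAML representation ([read_run_config()] / [write_run_config()]).
#'
#' Exactly one input source is used, checked in this order: `images_csv`
#' (per-image quantification from files listed in a manifest CSV),
#' `experiments_csv` (a precomputed tidy experiment table), or `simulate`
#' (parameters passed to [generate_strain_table()]).
#'
#' @param seed seed for every stochastic step of the run.
#' @param out_dir output directory.
#' @param images_csv optional manifest CSV (columns `image_id`, `path`,
#'   `channel`, `strain_id`, `database_id`, `genotype_class`, `surface`,
#'   `experiment_id`).
#' @param scores_csv visual-score CSV (`experiment_id`, `P3`, `P4`, `P5`);
#'   required when `images_csv` is used.
#' @param experiments_csv optional tidy experiment table CSV.
#' @param simulate optional named list of [generate_strain_table()]
#'   arguments.
#' @param morphology named list of [morphology_config()] arguments.
#' @param threshold `"auto"` or a numeric intensity.
#' @param composite relevance-filter composite-SD rule (`"rms"`/`"max"`).
#' @param annotations `"table1"`, `"none"`, or a CSV path with `strain_id`,
#'   `thrombosis`, `bleeding`.
#' @param edges optional STRING-style TSV path; enables the network stage.
#' @param min_confidence edge confidence cutoff.
#' @param mcode named list of [mcode()] arguments.
#' @param log_level `"info"` or `"quiet"`.
#' @return validated config list of class `run_config`.
#' @export
run_config <- function(seed = 1L, out_dir = "thrombomap_out",
                       images_csv = NULL, scores_csv = NULL,
                       experiments_csv = NULL, simulate = NULL,
                       morphology = list(), threshold = "auto",
                       composite = "rms", annotations = "table1",
                       edges = NULL, min_confidence = 0.40,
                       mcode = list(), log_level = "info") {
  cfg <- list(seed = as.integer(seed), out_dir = out_dir,
              images_csv = images_csv, scores_csv = scores_csv,
              experiments_csv = experiments_csv, simulate = simulate,
              morphology = morphology, threshold = threshold,
              composite = composite, annotations = annotations,
              edges = edges, min_confidence = min_confidence,
              mcode = mcode, log_level = log_level)
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  known <- c("seed", "out_dir", "images_csv", "scores_csv", "experiments_csv",
             "simulate", "morphology", "threshold", "composite", "annotations",
             "edges", "min_confidence", "mcode", "log_level")
  extra <- setdiff(names(cfg), known)
  if (length(extra))
    stop("unknown config key(s): ", paste(extra, collapse = ", "), call. = FALSE)
  sub_ok <- list(
    morphology = names(formals(morphology_config)),
    mcode = setdiff(names(formals(mcode)), "graph"),
    simulate = names(formals(generate_strain_table)))
  for (s in names(sub_ok)) {
    extra <- setdiff(names(cfg[[s]]), sub_ok[[s]])
    if (length(extra))
      stop("unknown config key(s) under '", s, "': ",
           paste(extra, collapse = ", "), call. = FALSE)
  }
  if (!cfg$composite %in% c("rms", "max"))
    stop("composite must be 'rms' or 'max'", call. = FALSE)
  if (is.null(cfg$images_csv) && is.null(cfg$experiments_csv) &&
      is.null(cfg$simulate))
    stop("config needs one of images_csv, experiments_csv, simulate", call. = FALSE)
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  cfg$seed <- as.integer(cfg$seed)
  validate_run_config(cfg)
}

#' @rdname run_config
#' @param cfg a `run_config`.
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  yaml::write_yaml(unclass(cfg)[!vapply(cfg, is.null, TRUE)], path)
  invisible(path)
}

#' Run the full comparison pipeline
#'
#' Executes quantify (when images are supplied) -> parameterize -> compare
#' (-> network when an edge list is supplied), writing every artifact under
#' `cfg$out_dir` and a manifest listing each output file with its MD5
#' content hash. Identical config + inputs yield identical manifest hashes.
#' Stage failures are re-raised with the stage name; partially written
#' stages are flagged in the manifest.
#'
#' @param cfg a [run_config()].
#' @return list with `status` (0 = ok), `manifest` (data.frame `file`,
#'   `md5`), and the in-memory stage results (`experiments`, `summary`,
#'   `scaled`, `deltas`, `concordance`, `network`).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!identical(cfg$log_level, "quiet")) message(...)
  stage <- function(name, expr)
    tryCatch(expr, error = function(e)
      stop("stage ", name, ": ", conditionMessage(e), call. = FALSE))
  outputs <- character(0)
  track <- function(p) outputs <<- c(outputs, p)
  emit <- function(df, name) {
    p <- file.path(cfg$out_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    track(p)
    p
  }

  # --- quantify + parameterize: obtain the tidy experiment table
  experiments <- stage("quantify", {
    if (!is.null(cfg$images_csv)) {
      per_image <- quantify_image_set(cfg)
      emit(per_image, "per_image.csv")
      per_image
    } else NULL
  })
  experiments <- stage("parameterization", {
    if (!is.null(cfg$images_csv)) {
      if (is.null(cfg$scores_csv))
        stop("scores CSV required to assemble P3-P5 for brightfield analysis")
      assemble_experiments(experiments, utils::read.csv(cfg$scores_csv))
    } else if (!is.null(cfg$experiments_csv)) {
      utils::read.csv(cfg$experiments_csv, colClasses = c(database_id = "character"))
    } else {
      do.call(generate_strain_table,
              utils::modifyList(list(seed = cfg$seed), cfg$simulate))$experiments
    }
  })
  emit(experiments, "experiments.csv")

  # --- compare
  res <- stage("compare", {
    summary <- summarize_strains(experiments)
    scaled <- scale_strain_means(summary)
    dm <- build_delta_matrix(scaled, composite = cfg$composite)
    emit(summary, "strain_summary.csv")
    emit(as.data.frame(scaled$values), "scaled_means.csv")
    emit(data.frame(column = names(scaled$anchors), anchor_max = scaled$anchors,
                    row.names = NULL), "anchors.csv")
    emit(as.data.frame(dm$delta), "delta_values.csv")
    emit(as.data.frame(dm$relevant), "delta_relevance.csv")
    surf <- sub("\\..*", "", colnames(dm$delta)[1])
    rk <- rank_and_cluster(dm, "signature", surface = surf)
    emit(data.frame(strain_id = rk$rows, signature_delta = rk$values),
         "ranking_signature.csv")
    means_wide <- as.data.frame(scaled$values)
    cm <- tryCatch(correlation_matrix(stats::setNames(
      means_wide[paste0(surf, ".", c("P1", "P2", "P3", "P4", "P5"))],
      c("P1", "P2", "P3", "P4", "P5"))), error = function(e) NULL)
    if (!is.null(cm)) emit(as.data.frame(cm$tau), "correlation_tau.csv")
    cv <- tryCatch(wildtype_cv(summary, surface = surf), error = function(e) NULL)
    if (!is.null(cv))
      emit(data.frame(parameter = names(cv), cv_percent = cv), "wildtype_cv.csv")
    conc <- NULL
    ann <- load_annotations(cfg$annotations)
    if (!is.null(ann)) {
      matched <- intersect(rownames(dm$delta), ann$strain_id)
      if (length(matched)) {
        conc <- concordance_table(dm, ann, surface = surf)
        emit(conc$classes, "concordance_classes.csv")
      }
    }
    list(summary = summary, scaled = scaled, deltas = dm, concordance = conc)
  })

  # --- network (optional)
  net <- NULL
  if (!is.null(cfg$edges)) {
    net <- stage("network", {
      g <- load_edges(cfg$edges, min_confidence = cfg$min_confidence)
      clusters <- do.call(mcode, c(list(graph = g), cfg$mcode))
      ann <- annotate_effects(g, res$deltas)
      paths <- export_network(g, ann, clusters, out_dir = cfg$out_dir)
      track(unname(paths))
      list(graph = g, clusters = clusters, annotations = ann)
    })
  }

  manifest <- data.frame(file = basename(outputs),
                         md5 = unname(tools::md5sum(outputs)),
                         stringsAsFactors = FALSE)
  manifest <- manifest[order(manifest$file), ]
  rownames(manifest) <- NULL
  utils::write.csv(manifest, file.path(cfg$out_dir, "manifest.csv"),
                   row.names = FALSE)
  say(sprintf("wrote %d artifacts to %s", nrow(manifest), cfg$out_dir))
  list(status = 0L, manifest = manifest, experiments = experiments,
       summary = res$summary, scaled = res$scaled, deltas = res$deltas,
       concordance = res$concordance, network = net)
}

load_annotations <- function(spec) {
  if (identical(spec, "none") || is.null(spec)) return(NULL)
  if (identical(spec, "table1")) return(load_table1_fixture())
  utils::read.csv(spec, stringsAsFactors = FALSE)
}

# quantify every image listed in the manifest CSV
quantify_image_set <- function(cfg) {
  man <- utils::read.csv(cfg$images_csv, stringsAsFactors = FALSE,
                         colClasses = c(database_id = "character"))
  req <- c("image_id", "path", "channel", "strain_id", "database_id",
           "genotype_class", "surface", "experiment_id")
  if (!all(req %in% names(man)))
    stop("images CSV must have columns ", paste(req, collapse = ", "))
  mcfg <- do.call(morphology_config, cfg$morphology)
  rows <- lapply(seq_len(nrow(man)), function(i) {
    r <- man[i, ]
    img <- read_gray_image(r$path, channel = r$channel)
    q <- if (r$channel == "brightfield")
      quantify_brightfield(img, mcfg, threshold = cfg$threshold)
    else quantify_fluorescence(img, threshold = cfg$threshold)
    data.frame(r, sac_percent = q$sac_percent,
               aggregate_percent = if (r$channel == "brightfield")
                 q$aggregate_percent else NA_real_,
               threshold = q$threshold, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# per-image rows + visual scores -> tidy per-experiment parameter table
assemble_experiments <- function(per_image, scores) {
  chan_param <- c(annexinA5 = "P6", CD62P = "P7", JONA = "P8")
  rows <- lapply(split(per_image, per_image$experiment_id), function(g) {
    imgs <- lapply(split(g, g$image_id), function(ir) {
      args <- list(surface = ir$surface[1], image_id = ir$image_id[1])
      bf <- ir[ir$channel == "brightfield", ]
      if (nrow(bf)) { args$P1 <- bf$sac_percent; args$P2 <- bf$aggregate_percent }
      for (ch in names(chan_param)) {
        fl <- ir[ir$channel == ch, ]
        if (nrow(fl)) args[[chan_param[[ch]]]] <- fl$sac_percent
      }
      do.call(image_parameters, args)
    })
    avg <- suppressWarnings(average_experiment(unname(imgs)))
    sc <- scores[scores$experiment_id == g$experiment_id[1], ]
    if (nrow(sc) == 1)
      avg$values[c("P3", "P4", "P5")] <- unlist(sc[c("P3", "P4", "P5")])
    experiment_record(strain_id = g$strain_id[1], database_id = g$database_id[1],
                      genotype_class = g$genotype_class[1], surface = g$surface[1],
                      parameters = avg, n_images = length(imgs))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
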