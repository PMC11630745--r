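# End-to-end pipeline: simulate/load -> quantify -> annotate -> PCA ->
# distribution -> checklist derivation -> validation, with every stage
# writing serialized artifacts so a run is restartable and bit-reproducible
# from (config, seed).

#' Build a pipeline run configuration
#'
#' All tunable stage parameters live here with their defaults, so a config
#' file records every analysis choice. The configuration round-trips
#' through YAML ([read_pipeline_config()] / [write_pipeline_config()]).
#'
#' @param out_dir Output directory for run artifacts.
#' @param seed Master seed for every stochastic step.
#' @param cohort_dir Optional directory of an existing cohort
#'   (`manifest.csv`, `norms.csv`, transcripts); when `NULL` a synthetic
#'   cohort is generated.
#' @param group_sizes Named group sizes for simulation.
#' @param n_words Background lexicon size for simulation.
#' @param n_components Components retained in both PCAs (`NULL` = scree
#'   selection).
#' @param quartile_edges Fixed score-bin edges.
#' @param cv_folds CV folds for checklist fitting.
#' @param top_n Checklist size.
#' @param merge_psp_cbs Merge PSP/CBS in stage-3 validation.
#' @param function_word_file Optional override list.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, seed = 1L, cohort_dir = NULL,
                            group_sizes = c(control = 24, svPPA = 9,
                                            lvPPA = 9, nfvPPA = 9,
                                            PSP = 10, CBS = 13),
                            n_words = 500L, n_components = 3L,
                            quartile_edges = c(-4, -2, 0, 2, 4),
                            cv_folds = 4L, top_n = 15L,
                            merge_psp_cbs = TRUE,
                            function_word_file = NULL) {
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 cohort_dir = cohort_dir,
                 group_sizes = group_sizes, n_words = as.integer(n_words),
                 n_components = n_components,
                 quartile_edges = quartile_edges,
                 cv_folds = as.integer(cv_folds), top_n = as.integer(top_n),
                 merge_psp_cbs = merge_psp_cbs,
                 function_word_file = function_word_file,
                 version = as.character(utils::packageVersion("connspeech"))),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML path.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$group_sizes <- unlist(cfg$group_sizes)
  do.call(pipeline_config,
          cfg[setdiff(names(cfg), "version")])
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  cfg <- unclass(config)
  cfg$group_sizes <- as.list(cfg$group_sizes)  # keep names through YAML
  yaml::write_yaml(cfg, path)
  invisible(path)
}

config_fingerprint <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  cfg <- config
  cfg$out_dir <- NULL  # a run's identity is its parameters, not its path
  write_pipeline_config(cfg, tmp)
  unname(tools::md5sum(tmp))
}

write_json_artifact <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

pca_artifact <- function(fit) {
  list(feature_names = fit$feature_names,
       center = as.list(fit$center), scale = as.list(fit$scale),
       eigenvalues = fit$eigenvalues, k = fit$k,
       loadings = apply(fit$loadings, 2, identity, simplify = FALSE),
       explained = as.list(fit$explained),
       total_explained = fit$total_explained,
       labels = fit$labels)
}

#' Run the full connected-speech pipeline
#'
#' Executes simulate/load -> quantify -> annotate -> PCA -> distribution ->
#' derive-checklist -> validate, writing CSV/JSON artifacts under
#' `config$out_dir`. Reruns with an identical config are byte-identical.
#' Referenced input files are checked before any stage runs.
#'
#' @param config A [pipeline_config()].
#' @return Invisible list of artifact paths plus key in-memory results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  # pre-flight checks before any stage runs
  if (!is.null(config$cohort_dir)) {
    for (f in file.path(config$cohort_dir, c("manifest.csv", "norms.csv"))) {
      if (!file.exists(f)) stop_pre("missing input file: ", f)
    }
  }
  if (!is.null(config$function_word_file) &&
      !file.exists(config$function_word_file)) {
    stop_pre("missing function word list: ", config$function_word_file)
  }
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  write_pipeline_config(config, file.path(out, "config.yaml"))
  write_json_artifact(list(seed = config$seed,
                           config_md5 = config_fingerprint(config),
                           version = config$version),
                      file.path(out, "run_info.json"))
  fun_list <- function_words(config$function_word_file)

  # stage 1: cohort ---------------------------------------------------
  if (is.null(config$cohort_dir)) {
    cohort <- generate_cohort(config$group_sizes, seed = config$seed,
                              n_words = config$n_words)
    cohort_dir <- file.path(out, "cohort")
    write_cohort(cohort, cohort_dir)
    transcripts <- cohort$transcripts
    lexicon <- cohort$lexicon
    manifest <- utils::read.csv(file.path(cohort_dir, "manifest.csv"),
                                stringsAsFactors = FALSE)
  } else {
    loaded <- read_cohort(file.path(config$cohort_dir, "manifest.csv"))
    transcripts <- loaded$transcripts
    manifest <- loaded$manifest
    lexicon <- read_norms_lexicon(file.path(config$cohort_dir, "norms.csv"))
  }
  clean <- lapply(transcripts, parse_transcript)

  # stage 2: fluency quantification -----------------------------------
  profiles <- fluency_profiles(clean, fun_list)
  utils::write.csv(profiles, file.path(out, "fluency_wide.csv"),
                   row.names = FALSE)
  utils::write.csv(fluency_long(profiles), file.path(out, "fluency_long.csv"),
                   row.names = FALSE)

  # stage 3a: fluency PCA ---------------------------------------------
  fl_features <- setdiff(names(profiles),
                         c("participant_id", "group", "picture"))
  fl_mat <- profiles[stats::complete.cases(profiles[fl_features]),
                     , drop = FALSE]
  constant <- fl_features[vapply(fl_features, function(f)
    stats::sd(fl_mat[[f]]) == 0, logical(1))]
  if (length(constant) > 0L) {
    message("dropping constant fluency measure(s) from the PCA: ",
            paste(constant, collapse = ", "))
    fl_features <- setdiff(fl_features, constant)
  }
  # the 13 measures are deliberately redundant (counts, ratios derived
  # from them), so the correlation matrix can be near-singular; the
  # pseudoinverse form of KMO handles that
  fl_kmo <- kmo(fl_mat[fl_features], pseudo_inverse = TRUE)
  fl_k <- config$n_components %||%
    scree_select(eigen(stats::cor(fl_mat[fl_features]),
                       symmetric = TRUE, only.values = TRUE)$values)
  fluency_pca <- label_components(pca_varimax(fl_mat[fl_features], fl_k),
                                  fluency_measure_labels())
  fl_scores <- cbind(fl_mat[c("participant_id", "group", "picture")],
                     as.data.frame(fluency_pca$scores))
  utils::write.csv(fl_scores, file.path(out, "fluency_pca_scores.csv"),
                   row.names = FALSE)
  write_json_artifact(c(pca_artifact(fluency_pca), list(kmo = fl_kmo)),
                      file.path(out, "fluency_pca.json"))

  # stage 3b: word-properties PCA on the pooled unique-word corpus ----
  annotated <- annotate_cohort(clean, lexicon, fun_list)
  corpus <- unique(annotated$tokens[c("token", norm_properties())])
  word_kmo <- kmo(corpus[norm_properties()])
  w_k <- config$n_components %||%
    scree_select(eigen(stats::cor(corpus[norm_properties()]),
                       symmetric = TRUE, only.values = TRUE)$values)
  word_pca <- label_components(pca_varimax(corpus[norm_properties()], w_k),
                               word_property_labels())
  write_json_artifact(c(pca_artifact(word_pca), list(kmo = word_kmo)),
                      file.path(out, "word_pca.json"))
  token_scores <- cbind(
    annotated$tokens[c("participant_id", "group", "picture", "token")],
    as.data.frame(pca_project(word_pca, annotated$tokens)))
  participant_word_scores <- project_words_and_average(word_pca,
                                                       annotated$tokens)
  utils::write.csv(participant_word_scores,
                   file.path(out, "participant_word_scores.csv"),
                   row.names = FALSE)

  # stage 4: distribution analysis ------------------------------------
  pcs <- colnames(word_pca$scores)
  quartiles <- lapply(pcs, function(pc)
    cohort_quartile_counts(token_scores, pc, config$quartile_edges))
  names(quartiles) <- pcs
  for (pc in pcs) {
    utils::write.csv(quartiles[[pc]],
                     file.path(out, paste0("quartile_counts_", pc, ".csv")),
                     row.names = FALSE)
  }
  diff_maps <- list()
  if (length(pcs) >= 2L && "control" %in% token_scores$group) {
    pmaps <- lapply(split(token_scores, list(token_scores$participant_id,
                                             token_scores$picture),
                          drop = TRUE),
                    function(d) proportion_map(d[[pcs[1]]], d[[pcs[2]]],
                                               config$quartile_edges))
    map_group <- vapply(names(pmaps), function(nm) {
      token_scores$group[match(sub("\\.[^.]+$", "", nm),
                               token_scores$participant_id)]
    }, "")
    ctrl <- pmaps[map_group == "control"]
    for (g in setdiff(unique(map_group), "control")) {
      dm <- difference_map(pmaps[map_group == g], ctrl)
      diff_maps[[g]] <- dm
      utils::write.csv(
        data.frame(cell_row = rep(quartile_labels(), 4),
                   cell_col = rep(quartile_labels(), each = 4),
                   difference = as.vector(dm$difference),
                   t = as.vector(dm$t), p = as.vector(dm$p)),
        file.path(out, paste0("difference_map_", g, ".csv")),
        row.names = FALSE)
    }
  }

  # stage 5 + 6: checklist derivation and validation -------------------
  checklists <- list()
  validation <- list()
  cog_cols <- grep("^(acer|mlse)_", names(manifest), value = TRUE)
  for (pic in unique(vapply(clean, `[[`, "", "picture"))) {
    trs <- Filter(function(tr) tr$picture == pic, clean)
    grp <- vapply(trs, `[[`, "", "group")
    der <- derive_checklist(trs, grp, function_list = fun_list,
                            top_n = config$top_n,
                            cv_folds = config$cv_folds,
                            seed = derive_seed(config$seed,
                                               match(pic, speech_pictures())))
    checklists[[pic]] <- der
    write_checklist(der$checklist,
                    file.path(out, paste0("checklist_", pic, ".csv")),
                    rerun = der$rerun)
    if (!is.null(der$table)) {
      utils::write.csv(der$table,
                       file.path(out, paste0("ranked_words_", pic, ".csv")),
                       row.names = FALSE)
    }
    if (length(der$checklist$classes) > 0L) {
      xcl <- build_indicator_matrix(trs, der$checklist$classes)
      reports <- hierarchical_validate(
        xcl, grp, scheme = "kfold", k = config$cv_folds,
        seed = derive_seed(config$seed, 50L, match(pic, speech_pictures())),
        merge_psp_cbs = config$merge_psp_cbs)
      validation[[pic]] <- lapply(reports, function(r) {
        list(contrast = r$contrast, scheme = r$scheme,
             confusion = apply(r$confusion, 1, identity, simplify = FALSE),
             accuracy = r$accuracy, sensitivity = r$sensitivity,
             specificity = r$specificity, n = r$n)
      })
    }
  }
  write_json_artifact(list(seed = config$seed, validation = validation),
                      file.path(out, "validation.json"))

  invisible(list(out_dir = out, profiles = profiles,
                 fluency_pca = fluency_pca, fluency_kmo = fl_kmo,
                 word_pca = word_pca, word_kmo = word_kmo,
                 participant_word_scores = participant_word_scores,
                 quartiles = quartiles, difference_maps = diff_maps,
                 checklists = checklists, validation = validation))
}
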