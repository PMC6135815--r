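# Configuration, file formats, and the end-to-end pipeline orchestrator.
#
# File dialects: UTF-8 CSV with a header row; timestamps ISO-8601
# (YYYY-MM-DDTHH:MM:SS, UTC); connectivity matrices as square
# comma-delimited numeric text with a node-id header; node masks as
# newline-delimited id lists.

#' Default pipeline configuration
#'
#' Returns the configuration profile encoding the pipeline's standard
#' thresholds: stratification alpha 0.05 with 10000 permutations, FDR 0.05
#' with 5000 permutations, Bonferroni divisor 37, feature-selection p
#' 0.001, 1000 null label draws, 100 Louvain repetitions per subject with
#' agreement threshold 0.5, inner 10-fold tuning. Every stochastic stage
#' has an explicit seed derived from the top-level seed.
#'
#' @param seed top-level integer seed.
#' @return nested list (class `pipeline_config`).
#' @export
default_config <- function(seed = 1L) {
  cfg <- list(
    seed = as.integer(seed),
    synthetic = list(enabled = TRUE, n_ptx = 43L, n_notx = 20L),
    stratification = list(alpha = 0.05, n_perm = 10000L),
    questionnaires = list(m_comparisons = 37L, alpha = 0.05, outlier_k = 3),
    network = list(n_perm = 5000L, fdr_alpha = 0.05,
                   louvain_reps = 100L, agree_threshold = 0.5,
                   resolution = 1),
    prediction = list(inner_folds = 10L, p_thresh = 0.001,
                      n_label_draws = 1000L, report_threshold = 0.84),
    stages = list(ratings = TRUE, questionnaires = TRUE, network = TRUE,
                  prediction = TRUE)
  )
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

#' Read / write a pipeline configuration (YAML)
#'
#' Configurations round-trip through serialization unchanged.
#'
#' @param path YAML file path.
#' @return for `read_config`, a `pipeline_config`.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$seed)) stop("config must carry a seed", call. = FALSE)
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

#' @rdname read_config
#' @param config a `pipeline_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Hash a configuration
#'
#' MD5 of the canonical YAML serialization; changes iff the configuration
#' changes.
#'
#' @param config a `pipeline_config`.
#' @return character MD5 hash.
#' @export
config_hash <- function(config) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  write_config(config, f)
  unname(tools::md5sum(f))
}

iso_fmt <- "%Y-%m-%dT%H:%M:%S"

#' Read and write pipeline CSV tables
#'
#' `ratings.csv` has columns `subject_id`, `timestamp` (ISO-8601, UTC),
#' `vas`; `visits.csv` has `subject_id`, `visit_1` ... `visit_6` (dates);
#' `questionnaires.csv` and `volumes.csv` are plain header CSVs. Malformed
#' timestamps are rejected with their line numbers. Round trips preserve
#' values to full precision.
#'
#' @param path CSV file path.
#' @return a data frame.
#' @export
read_ratings <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "timestamp", "vas")
  if (!all(need %in% names(x)))
    stop(sprintf("%s: missing column(s) %s", path,
                 paste(setdiff(need, names(x)), collapse = ", ")),
         call. = FALSE)
  ts <- as.POSIXct(x$timestamp, format = iso_fmt, tz = "UTC")
  if (anyNA(ts)) {
    bad <- which(is.na(ts)) + 1L   # +1 for the header line
    stop(sprintf("%s: non-ISO-8601 timestamp at line(s) %s", path,
                 paste(head(bad, 5), collapse = ", ")), call. = FALSE)
  }
  x$timestamp <- ts
  x$vas <- as.numeric(x$vas)
  x
}

#' @rdname read_ratings
#' @param ratings ratings data frame.
#' @export
write_ratings <- function(ratings, path) {
  out <- ratings[c("subject_id", "timestamp", "vas")]
  out$timestamp <- format(as.POSIXct(out$timestamp, tz = "UTC"), iso_fmt,
                          tz = "UTC")
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_ratings
#' @export
read_visits <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  for (v in grep("^visit_", names(x), value = TRUE)) {
    d <- as.Date(x[[v]], format = "%Y-%m-%d")
    if (anyNA(d))
      stop(sprintf("%s: malformed date in %s at line(s) %s", path, v,
                   paste(which(is.na(d)) + 1L, collapse = ", ")),
           call. = FALSE)
    x[[v]] <- d
  }
  x
}

#' @rdname read_ratings
#' @param visits visits data frame.
#' @export
write_visits <- function(visits, path) {
  write.csv(visits, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_ratings
#' @export
read_questionnaires <- function(path) {
  read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' @rdname read_ratings
#' @param table a data frame to write.
#' @export
write_questionnaires <- function(table, path) {
  write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_ratings
#' @export
read_volumes <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname read_ratings
#' @export
write_volumes <- function(table, path) {
  write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a connectivity matrix file
#'
#' Square comma-delimited numeric text; the header row and first column
#' carry the node ids. Non-square payloads are rejected.
#'
#' @param path matrix file path.
#' @return numeric matrix with node-id dimnames.
#' @export
read_matrix <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                row.names = 1)
  m <- as.matrix(x)
  if (nrow(m) != ncol(m))
    stop(sprintf("%s: non-square matrix payload (%d x %d)", path,
                 nrow(m), ncol(m)), call. = FALSE)
  storage.mode(m) <- "double"
  if (anyNA(m))
    stop(sprintf("%s: non-numeric entries in matrix", path), call. = FALSE)
  m
}

#' @rdname read_matrix
#' @param mat matrix to write.
#' @export
write_matrix <- function(mat, path) {
  write.csv(as.data.frame(mat), path, quote = FALSE)
  invisible(path)
}

#' Read / write a node mask
#'
#' Newline-delimited node-id list.
#'
#' @param path file path.
#' @return character vector of node ids.
#' @export
read_node_mask <- function(path) {
  x <- readLines(path, warn = FALSE)
  x[nzchar(trimws(x))]
}

#' @rdname read_node_mask
#' @param nodes character vector of node ids.
#' @export
write_node_mask <- function(nodes, path) {
  writeLines(as.character(nodes), path)
  invisible(path)
}

#' Write a synthetic cohort to a directory in the pipeline's file formats
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_ratings(cohort$ratings, file.path(dir, "ratings.csv"))
  write_visits(cohort$visits, file.path(dir, "visits.csv"))
  write_questionnaires(cohort$questionnaires,
                       file.path(dir, "questionnaires.csv"))
  if (!is.null(cohort$volumes))
    write_volumes(cohort$volumes, file.path(dir, "volumes.csv"))
  write.csv(cohort$subjects, file.path(dir, "subjects.csv"),
            row.names = FALSE, quote = FALSE)
  if (!is.null(cohort$connectivity)) {
    mdir <- file.path(dir, "matrices")
    dir.create(mdir, showWarnings = FALSE)
    for (id in names(cohort$connectivity))
      for (v in names(cohort$connectivity[[id]]))
        write_matrix(cohort$connectivity[[id]][[v]],
                     file.path(mdir, sprintf("%s_%s.csv", id, v)))
  }
  invisible(dir)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order -- rating cleanup and period assignment,
#' permutation responder stratification, analgesia summary, questionnaire
#' screen, network statistics (edgewise test between responder groups on
#' the pre-treatment scan) and asymmetry contrast, and cross-validated
#' prediction -- and writes all artifacts plus a manifest (config hash,
#' seeds, stage counts) into `out_dir`. With the same configuration the
#' run is reproducible.
#'
#' @param config a `pipeline_config` (see [default_config()]).
#' @param out_dir output directory.
#' @param cohort optionally, a pre-built `synthetic_cohort`; otherwise one
#'   is generated when `config$synthetic$enabled`, else inputs are read
#'   from `config$paths`.
#' @return (invisibly) a list of the stage results, with `out_dir` attached.
#' @export
run_pipeline <- function(config, out_dir, cohort = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  logit <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    message("pipeline: ", line)
    log_lines <<- c(log_lines, line)
  }

  if (is.null(cohort)) {
    if (isTRUE(config$synthetic$enabled)) {
      params <- cohort_params(n_ptx = config$synthetic$n_ptx,
                              n_notx = config$synthetic$n_notx,
                              seed = config$seed)
      cohort <- generate_cohort(params,
                                include_brain = isTRUE(config$stages$network))
      logit("generated synthetic cohort: %d PTx + %d NoTx subjects",
            params$n_ptx, params$n_notx)
    } else {
      p <- config$paths
      for (nm in c("ratings", "visits"))
        if (is.null(p[[nm]]) || !file.exists(p[[nm]]))
          stop(sprintf("missing required input: %s", nm), call. = FALSE)
      cohort <- list(
        ratings = read_ratings(p$ratings),
        visits = read_visits(p$visits),
        questionnaires = if (!is.null(p$questionnaires))
          read_questionnaires(p$questionnaires),
        volumes = if (!is.null(p$volumes)) read_volumes(p$volumes),
        subjects = NULL, connectivity = NULL)
    }
  }

  # --- ratings: dedup, period labels, stratification, analgesia ----------
  n_raw <- nrow(cohort$ratings)
  clean <- do.call(rbind, lapply(split(cohort$ratings,
                                       cohort$ratings$subject_id),
                                 dedupe_ratings))
  logit("dedup: %d ratings in, %d retained", n_raw, nrow(clean))
  labelled <- do.call(rbind, lapply(split(clean, clean$subject_id),
    function(x) {
      v <- cohort$visits[cohort$visits$subject_id == x$subject_id[1], ]
      suppressMessages(assign_periods(
        x, as.Date(unlist(v[paste0("visit_", 1:6)]),
                   origin = "1970-01-01")))
    }))
  rownames(labelled) <- NULL

  strat <- stratify_cohort(labelled, alpha = config$stratification$alpha,
                           n_perm = config$stratification$n_perm,
                           seed = config$seed)
  analg <- analgesia_summary(labelled, cohort$visits)
  write.csv(strat, file.path(out_dir, "stratification.csv"),
            row.names = FALSE, quote = FALSE)
  write.csv(analg, file.path(out_dir, "analgesia.csv"),
            row.names = FALSE, quote = FALSE)
  logit("stratification: %d/%d responders",
        sum(strat$label == "Responder"), nrow(strat))

  results <- list(stratification = strat, analgesia = analg)

  arm_of <- function(ids) {
    if (!is.null(cohort$subjects))
      cohort$subjects$arm[match(ids, cohort$subjects$subject_id)]
    else ifelse(grepl("^NTX", ids), "NoTx", "PTx")
  }
  ptx_ids <- strat$subject_id[arm_of(strat$subject_id) == "PTx"]
  lbl <- setNames(strat$label, strat$subject_id)
  mag <- setNames(analg$pct_analgesia, analg$subject_id)

  # --- questionnaires -----------------------------------------------------
  if (isTRUE(config$stages$questionnaires) &&
      !is.null(cohort$questionnaires)) {
    q <- cohort$questionnaires
    qs <- as.matrix(q[match(ptx_ids, q$subject_id), -1, drop = FALSE])
    screen <- univariate_screen(qs, lbl[ptx_ids], mag[ptx_ids],
                                m_comparisons = config$questionnaires$m_comparisons,
                                alpha = config$questionnaires$alpha,
                                outlier_k = config$questionnaires$outlier_k)
    write.table(screen, file.path(out_dir, "screen.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    logit("questionnaire screen: %d/%d subscales significant at p < %.2g",
          sum(screen$sig_cor, na.rm = TRUE), nrow(screen),
          attr(screen, "threshold"))
    results$screen <- screen
  }

  # --- network ------------------------------------------------------------
  if (isTRUE(config$stages$network) && !is.null(cohort$connectivity)) {
    resp_ids <- ptx_ids[lbl[ptx_ids] == "Responder"]
    nonr_ids <- ptx_ids[lbl[ptx_ids] == "NonResponder"]
    zmats <- function(ids) lapply(ids, function(id)
      fisher_z(cohort$connectivity[[id]][["V2"]]))
    et <- edgewise_permutation_test(zmats(resp_ids), zmats(nonr_ids),
                                    n_perm = config$network$n_perm,
                                    fdr_alpha = config$network$fdr_alpha,
                                    seed = config$seed + 7L)
    write.table(et, file.path(out_dir, "edges.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    logit("edgewise test: %d/%d edges flagged at FDR %.2f",
          sum(et$flag), nrow(et), config$network$fdr_alpha)
    results$edges <- et

    if (!is.null(cohort$volumes)) {
      v2 <- cohort$volumes[cohort$volumes$visit == "V2", ]
      v2$ratio <- vapply(seq_len(nrow(v2)), function(k)
        asymmetry_ratio(c(v2$nac_r[k], v2$amy_r[k], v2$hip_r[k]),
                        c(v2$nac_l[k], v2$amy_l[k], v2$hip_l[k])),
        numeric(1))
      v2 <- v2[v2$subject_id %in% ptx_ids, ]
      adj <- adjust_covariates(v2$ratio,
                               data.frame(pgm = v2$peripheral_gm,
                                          age = v2$age,
                                          sex = factor(v2$sex)))
      tt <- t.test(adj[lbl[v2$subject_id] == "Responder"],
                   adj[lbl[v2$subject_id] == "NonResponder"],
                   var.equal = TRUE)
      results$asymmetry <- list(t = unname(tt$statistic), p = tt$p.value,
                                ratios = setNames(v2$ratio, v2$subject_id))
      logit("asymmetry contrast (covariate-adjusted): t = %.2f, p = %.3g",
            results$asymmetry$t, results$asymmetry$p)
    }
  }

  # --- prediction ---------------------------------------------------------
  if (isTRUE(config$stages$prediction) &&
      !is.null(cohort$questionnaires)) {
    q <- cohort$questionnaires
    qs <- as.matrix(q[match(ptx_ids, q$subject_id), -1, drop = FALSE])
    # upstream mean imputation: models require complete features
    for (j in seq_len(ncol(qs)))
      qs[is.na(qs[, j]), j] <- mean(qs[, j], na.rm = TRUE)
    clf <- nested_loocv_classify(qs, factor(lbl[ptx_ids]),
                                 inner_folds = config$prediction$inner_folds,
                                 seed = config$seed + 11L)
    lasso <- nested_loocv_lasso(qs, mag[ptx_ids], selection = NULL,
                                inner_folds = config$prediction$inner_folds,
                                seed = config$seed + 13L,
                                report_threshold = config$prediction$report_threshold)
    write.csv(cbind(subject_id = ptx_ids, clf$predictions[-1]),
              file.path(out_dir, "predictions_class.csv"),
              row.names = FALSE, quote = FALSE)
    write.csv(cbind(subject_id = ptx_ids, lasso$predictions[-1]),
              file.path(out_dir, "predictions_magnitude.csv"),
              row.names = FALSE, quote = FALSE)
    write.table(lasso$consensus, file.path(out_dir, "weights.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    logit("classifier accuracy %.2f [%.2f, %.2f]; LASSO out-of-fold r = %.2f",
          clf$accuracy["estimate"], clf$accuracy["lower"],
          clf$accuracy["upper"], lasso$r)
    results$classifier <- clf
    results$lasso <- lasso
  }

  manifest <- list(config_hash = config_hash(config), seed = config$seed,
                   n_subjects = length(unique(strat$subject_id)),
                   stages = names(results), log = log_lines)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  writeLines(log_lines, file.path(out_dir, "run.log"))
  attr(results, "out_dir") <- out_dir
  invisible(results)
}
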