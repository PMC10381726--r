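# Manifest reading/curation, checkpoints, and the pipeline orchestration
# tying generation, curation, splitting, training, evaluation, saliency and
# effective-dimension analysis together. Manifests follow the CheXpert CSV
# convention: per-finding labels are 1 (positive), 0 (negative), -1
# (uncertain) or blank (unmentioned), and the distinction is preserved
# through read/write round trips.

.meta_columns <- c("Path", "PatientID", "Sex", "Age", "Frontal/Lateral",
                   "AP/PA", "StudyOrder", "CTR")

#' Read a manifest CSV
#'
#' @param path CSV file with a header row; comma-separated, UTF-8.
#' @return Data frame with label columns as integers (`NA` = blank).
#' @export
read_manifest <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                        na.strings = NULL)
  for (nm in names(df)) {
    if (nm %in% c("Age", "CTR")) {
      df[[nm]] <- suppressWarnings(as.numeric(ifelse(df[[nm]] == "", NA,
                                                     df[[nm]])))
    } else if (nm == "StudyOrder") {
      df[[nm]] <- suppressWarnings(as.integer(ifelse(df[[nm]] == "", NA,
                                                     df[[nm]])))
    } else if (!nm %in% .meta_columns) {
      df[[nm]] <- suppressWarnings(as.integer(ifelse(df[[nm]] == "", NA,
                                                     df[[nm]])))
    }
  }
  if (anyDuplicated(df$Path)) warning("manifest contains duplicated paths")
  df
}

#' Write a manifest CSV
#'
#' Blank (unmentioned) labels are written as empty fields, preserving the
#' blank / 0 / -1 distinctions.
#'
#' @param manifest Data frame.
#' @param path Output path.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Keep each patient's first posteroanterior view
#'
#' Retains rows with a frontal PA view and, within each patient, the row
#' with the smallest study order, yielding one row per retained patient.
#' Rows with malformed view values are dropped with a warning.
#'
#' @param manifest Manifest data frame with `Frontal/Lateral`, `AP/PA`,
#'   `PatientID` and `StudyOrder` columns.
#' @return The filtered manifest.
#' @export
select_first_pa <- function(manifest) {
  fl <- manifest[["Frontal/Lateral"]]; ap <- manifest[["AP/PA"]]
  if (is.null(fl) || is.null(ap)) stop("view columns missing")
  malformed <- !(fl %in% c("Frontal", "Lateral")) |
    !(ap %in% c("AP", "PA", ""))
  if (any(malformed))
    warning(sum(malformed), " rows with malformed view values dropped")
  keep <- !malformed & fl == "Frontal" & ap == "PA"
  m <- manifest[keep, , drop = FALSE]
  if (nrow(m) == 0) return(m)
  ord <- order(m$PatientID, m$StudyOrder)
  m <- m[ord, , drop = FALSE]
  m[!duplicated(m$PatientID), , drop = FALSE]
}

#' Resolve uncertain labels
#'
#' Maps a CheXpert-style finding column to binary: 1 stays positive,
#' 0 and blank become negative, and uncertain (-1) rows are excluded or
#' remapped according to `policy`.
#'
#' @param manifest Manifest data frame.
#' @param column Label column name.
#' @param policy One of `"exclude"`, `"as_negative"`, `"as_positive"`.
#' @return The manifest with a binary label column.
#' @export
apply_label_policy <- function(manifest, column = "Cardiomegaly",
                               policy = c("exclude", "as_negative",
                                          "as_positive")) {
  policy <- match.arg(policy)
  lab <- manifest[[column]]
  if (is.null(lab)) stop("label column not found: ", column)
  lab[is.na(lab)] <- 0L
  if (policy == "exclude") {
    manifest <- manifest[lab != -1L, , drop = FALSE]
    lab <- lab[lab != -1L]
  } else {
    lab[lab == -1L] <- if (policy == "as_positive") 1L else 0L
  }
  manifest[[column]] <- lab
  manifest
}

#' Balance a manifest by undersampling the majority class
#'
#' @param manifest Manifest with a binary label column.
#' @param label_column Label column name.
#' @param seed Sampling seed.
#' @return Balanced manifest (equal class counts).
#' @export
balance_undersample <- function(manifest, label_column = "Cardiomegaly",
                                seed = 1L) {
  lab <- manifest[[label_column]]
  counts <- table(factor(lab, c(0L, 1L)))
  if (any(counts == 0)) stop("both classes must be present")
  n_min <- min(counts)
  keep <- with_seed(seed, {
    unlist(lapply(c(0L, 1L), function(cl) {
      ix <- which(lab == cl)
      if (length(ix) > n_min) sort(sample(ix, n_min)) else ix
    }))
  })
  manifest[sort(keep), , drop = FALSE]
}

#' Save / load a model checkpoint
#'
#' Checkpoints are plain JSON holding all weights, the head/extractor
#' configuration and the training seed, so a model can be reconstructed
#' without any binary serialization.
#'
#' @param model A `hybrid_model`.
#' @param path Output file.
#' @param config Optional `train_config` stored alongside.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path, config = NULL) {
  head <- model$head
  ex <- model$extractor
  obj <- list(
    extractor = list(kind = ex$kind, f = ex$f, seed = ex$seed,
                     pool_to = ex$pool_to, W = ex$W, b = ex$b),
    head = c(list(variant = head$variant, f = head$f),
             head[intersect(c("n_qubits", "depth", "D", "shots", "hidden",
                              "W1", "b1", "theta", "W2", "b2"),
                            names(head))]),
    config = if (is.null(config)) NULL else unclass(config))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       force = TRUE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  ex <- toy_extractor(f = obj$extractor$f, seed = obj$extractor$seed,
                      pool_to = obj$extractor$pool_to)
  ex$W <- matrix(unlist(obj$extractor$W), nrow = ex$patch^2,
                 byrow = FALSE)
  ex$b <- as.numeric(obj$extractor$b)
  h <- obj$head
  head <- classifier_head(h$variant, f = h$f,
                          n_qubits = if (!is.null(h$n_qubits)) h$n_qubits else 4L,
                          depth = if (!is.null(h$depth)) h$depth else 4L,
                          D = if (!is.null(h$D)) h$D else 2L,
                          hidden = if (!is.null(h$hidden)) h$hidden else 512L)
  for (nm in c("W1", "W2")) {
    w <- h[[nm]]
    head[[nm]] <- if (is.matrix(w)) w else matrix(unlist(w), nrow = nrow(head[[nm]]))
  }
  head$b1 <- as.numeric(h$b1); head$b2 <- as.numeric(h$b2)
  if (!is.null(h$theta)) head$theta <- as.numeric(h$theta)
  hybrid_model(ex, head)
}

#' Pipeline configuration
#'
#' @param head_variant Classifier head variant.
#' @param f Feature dimension of the toy extractor.
#' @param n_qubits,depth,D Quantum head geometry.
#' @param n_per_class Synthetic records per class.
#' @param synthetic A `synthetic_config`.
#' @param training A `train_config`.
#' @param split A `split_spec`.
#' @param out_dir Output directory for artifacts.
#' @param do_saliency,do_nged Optional analysis stages.
#' @param seed Root seed (propagated to stages that were not given their
#'   own).
#' @return A `run_config`.
#' @export
run_config <- function(head_variant = "classical", f = 64L, n_qubits = 4L,
                       depth = 4L, D = 2L, n_per_class = 50L,
                       synthetic = NULL, training = NULL, split = NULL,
                       out_dir = tempfile("qcxr_run_"),
                       do_saliency = FALSE, do_nged = FALSE, seed = 1L) {
  seed <- as.integer(seed)
  structure(list(head_variant = head_variant, f = as.integer(f),
                 n_qubits = as.integer(n_qubits), depth = as.integer(depth),
                 D = as.integer(D), n_per_class = as.integer(n_per_class),
                 synthetic = if (is.null(synthetic)) synthetic_config(seed = seed)
                             else synthetic,
                 training = if (is.null(training)) train_config(seed = seed)
                            else training,
                 split = if (is.null(split)) split_spec(seed = seed)
                         else split,
                 out_dir = out_dir, do_saliency = do_saliency,
                 do_nged = do_nged, seed = seed),
            class = "run_config")
}

.stage <- function(name, log_path, expr) {
  res <- tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  cat(jsonlite::toJSON(list(stage = name, time = format(Sys.time()),
                            status = "ok"), auto_unbox = TRUE),
      "\n", file = log_path, append = TRUE, sep = "")
  res
}

#' Run the full pipeline
#'
#' Generates a synthetic dataset, splits it, trains the configured model,
#' evaluates it, and optionally runs saliency assessment and the
#' effective-dimension analysis. Artifacts are written under
#' `config$out_dir`: `metrics.csv` (metric, value or fold summary),
#' `roc.csv`, `loss_history.csv`, `checkpoint.json`,
#' `heatmap_assessments.csv`, `nged.csv` and a JSON-lines `run_log.jsonl`.
#'
#' @param config A `run_config`.
#' @return Invisibly, a list with the trained fit, reports and artifact
#'   paths.
#' @export
run_pipeline <- function(config = run_config()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run_log.jsonl")
  cat(jsonlite::toJSON(list(stage = "config", seed = config$seed,
                            head = config$head_variant,
                            version = as.character(utils::packageVersion("qcxr"))),
                       auto_unbox = TRUE), "\n",
      file = log_path, sep = "")
  ds <- .stage("generate", log_path,
               generate_dataset(config$n_per_class, config$synthetic))
  images <- lapply(ds$records, `[[`, "image")
  labels <- ds$manifest$Cardiomegaly
  write_manifest(ds$manifest, file.path(config$out_dir, "manifest.csv"))

  make_model <- function() {
    hybrid_model(toy_extractor(f = config$f, seed = config$seed),
                 classifier_head(config$head_variant, f = config$f,
                                 n_qubits = config$n_qubits,
                                 depth = config$depth, D = config$D,
                                 seed = config$seed))
  }
  splits <- .stage("split", log_path, make_splits(labels, config$split))

  fits <- list(); reports <- list()
  for (i in seq_along(splits)) {
    sp <- splits[[i]]
    fit <- .stage(paste0("train_fold", i), log_path,
                  train(make_model(), images[sp$train], labels[sp$train],
                        config$training))
    rep <- .stage(paste0("evaluate_fold", i), log_path,
                  evaluate_model(fit$model, images[sp$test],
                                 labels[sp$test]))
    fits[[i]] <- fit; reports[[i]] <- rep
  }

  # metrics artifact: per-fold values plus (for k >= 2) fold summary
  per_fold <- do.call(rbind, lapply(seq_along(reports), function(i) {
    r <- reports[[i]]
    data.frame(fold = i, metric = .metric_names,
               value = unlist(r[.metric_names]), row.names = NULL)
  }))
  utils::write.csv(per_fold, file.path(config$out_dir, "metrics.csv"),
                   row.names = FALSE)
  if (length(reports) >= 2) {
    fs <- summarize_folds(reports)
    utils::write.csv(as.data.frame(fs),
                     file.path(config$out_dir, "metrics_summary.csv"),
                     row.names = FALSE)
  }
  roc <- roc_points(labels[splits[[1]]$test], attr(reports[[1]], "scores"))
  utils::write.csv(roc, file.path(config$out_dir, "roc.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(epoch = seq_along(fits[[1]]$loss_history),
                              split = "train",
                              loss = fits[[1]]$loss_history),
                   file.path(config$out_dir, "loss_history.csv"),
                   row.names = FALSE)
  save_checkpoint(fits[[1]]$model,
                  file.path(config$out_dir, "checkpoint.json"),
                  config$training)

  if (config$do_saliency) {
    tab <- .stage("saliency", log_path,
                  assess_heatmaps(fits[[1]]$model,
                                  ds$records[splits[[1]]$test]))
    utils::write.csv(tab, file.path(config$out_dir,
                                    "heatmap_assessments.csv"),
                     row.names = FALSE)
  }
  if (config$do_nged && config$head_variant != "classical") {
    spec <- build_pqc(config$n_qubits, config$depth)
    curve <- .stage("nged", log_path,
                    nged_curve(spec, round(10^seq(2, 6, length.out = 9)),
                               D = config$D, seed = config$seed))
    utils::write.csv(as.data.frame(curve),
                     file.path(config$out_dir, "nged.csv"),
                     row.names = FALSE)
  }
  cat(jsonlite::toJSON(list(stage = "done", time = format(Sys.time())),
                       auto_unbox = TRUE), "\n",
      file = log_path, append = TRUE, sep = "")
  invisible(list(fits = fits, reports = reports, out_dir = config$out_dir))
}

#' Write synthetic records to disk as PNG images and masks
#'
#' @param dataset Result of [generate_dataset()].
#' @param dir Output directory.
#' @return The manifest with `Path` pointing at the written PNGs.
#' @export
write_synthetic_dataset <- function(dataset, dir) {
  dir.create(file.path(dir, "images"), showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(dir, "masks"), showWarnings = FALSE)
  man <- dataset$manifest
  for (i in seq_along(dataset$records)) {
    r <- dataset$records[[i]]
    img_path <- file.path(dir, "images", paste0(r$patient_id, ".png"))
    png::writePNG(t(r$image), img_path)
    png::writePNG(t(r$heart_mask * 1), file.path(dir, "masks",
                                         paste0(r$patient_id, "_heart.png")))
    man$Path[i] <- img_path
  }
  write_manifest(man, file.path(dir, "manifest.csv"))
  man
}
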