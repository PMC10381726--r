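# Synthetic chest-radiograph generator. Produces grayscale thorax images
# whose class label is governed by the cardiothoracic ratio (CTR), together
# with ground-truth heart and thorax masks and a CheXpert-style manifest.
# The generator is the package's stand-in for a curated clinical dataset:
# control images draw CTR in [0.35, 0.45], cardiomegaly images in
# [0.55, 0.70], mirroring the curation thresholds (control <= 0.45,
# disease >= 0.55).

# evaluate a block with a private RNG stream, restoring global state after
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv())
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Configuration for the synthetic radiograph generator
#'
#' @param image_size Side of the square image in pixels.
#' @param ctr_control,ctr_cardiomegaly Length-2 CTR sampling ranges for the
#'   two classes. Defaults keep a gap between the curation thresholds so
#'   the classes are separable by construction.
#' @param noise_sd Standard deviation of additive Gaussian pixel noise.
#' @param confounder_prob Probability of an effusion-like basal opacity,
#'   placed independently of class.
#' @param hard_mode If `TRUE`, the CTR ranges are narrowed towards the
#'   decision boundary (`[0.42, 0.49]` vs `[0.51, 0.58]`) for stress
#'   testing; the separability gap shrinks accordingly.
#' @param seed Root seed for all randomness in the generator.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(image_size = 320,
                             ctr_control = c(0.35, 0.45),
                             ctr_cardiomegaly = c(0.55, 0.70),
                             noise_sd = 0.03,
                             confounder_prob = 0.15,
                             hard_mode = FALSE,
                             seed = 1L) {
  if (hard_mode) {
    ctr_control <- c(0.42, 0.49)
    ctr_cardiomegaly <- c(0.51, 0.58)
  } else {
    stopifnot(ctr_control[2] <= 0.45, ctr_cardiomegaly[1] >= 0.55)
  }
  structure(list(image_size = as.integer(image_size),
                 ctr_control = ctr_control,
                 ctr_cardiomegaly = ctr_cardiomegaly,
                 noise_sd = noise_sd, confounder_prob = confounder_prob,
                 hard_mode = hard_mode, seed = as.integer(seed)),
            class = "synthetic_config")
}

.ellipse_mask <- function(S, cx, cy, a, b) {
  x <- matrix(seq_len(S), S, S, byrow = TRUE)
  y <- matrix(seq_len(S), S, S)
  ((x - cx) / a)^2 + ((y - cy) / b)^2 <= 1
}

#' Generate one synthetic radiograph
#'
#' Draws a dark background, a bright thorax ellipse containing two darker
#' lung fields, and a bright cardiac ellipse low-central in the thorax
#' whose maximal width equals `ctr` times the inner thoracic width.
#' Additive Gaussian noise and an optional basal opacity confounder
#' (independent of class) complete the image. Deterministic given `seed`.
#'
#' @param ctr Target cardiothoracic ratio in `[0.2, 0.9]`.
#' @param config A `synthetic_config`.
#' @param seed Seed for this record (defaults to `config$seed`).
#' @param confounder Force the confounder on/off; `NULL` draws it with
#'   `config$confounder_prob`.
#' @return A `synthetic_record`: list with `image` (S x S in `[0, 1]`),
#'   `label` (1 iff `ctr >= 0.55`... see Details), `ctr_true`,
#'   `heart_mask`, `thorax_mask`, `has_confounder`, `patient_id`, `view`,
#'   `study_order`.
#' @details The stored `label` is the deterministic class of `ctr_true`
#'   under the curation thresholds: 1 when `ctr >= 0.5`, 0 otherwise
#'   (with the default configuration no CTR falls in the ambiguous band).
#' @export
generate_cxr <- function(ctr, config = synthetic_config(), seed = config$seed,
                         confounder = NULL) {
  if (ctr < 0.2 || ctr > 0.9) stop("ctr must lie in [0.2, 0.9]")
  S <- config$image_size
  with_seed(seed, {
    cx <- 0.50 * S; cy <- 0.52 * S
    a_t <- 0.38 * S; b_t <- 0.42 * S
    # placement jitter: documented bound +/- 0.5% of image size
    jx <- runif(1, -0.005, 0.005) * S
    jy <- runif(1, -0.005, 0.005) * S
    a_h <- ctr * a_t; b_h <- 0.8 * a_h
    hx <- cx + 0.01 * S + jx
    hy <- cy + 0.25 * b_t + jy

    thorax <- .ellipse_mask(S, cx, cy, a_t, b_t)
    lung_l <- .ellipse_mask(S, cx - 0.19 * S, cy - 0.04 * S, 0.15 * S, 0.33 * S)
    lung_r <- .ellipse_mask(S, cx + 0.19 * S, cy - 0.04 * S, 0.15 * S, 0.33 * S)
    heart <- .ellipse_mask(S, hx, hy, a_h, b_h) & thorax

    img <- matrix(0.05, S, S)
    img[thorax] <- 0.50
    img[(lung_l | lung_r) & thorax] <- 0.22
    img[heart] <- 0.78

    has_conf <- if (is.null(confounder)) runif(1) < config$confounder_prob
                else isTRUE(confounder)
    if (has_conf) {
      side <- sample(c(-1, 1), 1)
      conf <- .ellipse_mask(S, cx + side * 0.19 * S, cy + 0.24 * S,
                            0.12 * S, 0.09 * S) & thorax & !heart
      img[conf] <- img[conf] + 0.30
    }
    if (config$noise_sd > 0)
      img <- img + matrix(stats::rnorm(S * S, 0, config$noise_sd), S, S)
    img <- pmin(pmax(img, 0), 1)

    structure(list(image = img, label = as.integer(ctr >= 0.5),
                   ctr_true = ctr, heart_mask = heart, thorax_mask = thorax,
                   has_confounder = has_conf,
                   patient_id = NA_character_, view = "PA",
                   study_order = 1L),
              class = "synthetic_record")
  })
}

#' Measure the cardiothoracic ratio from masks
#'
#' CTR = maximal horizontal extent of the heart mask divided by the
#' maximal horizontal inner extent of the thorax mask (widest row of each).
#'
#' @param heart_mask,thorax_mask Logical matrices; the heart must be
#'   contained in the thorax.
#' @return The measured CTR (scalar).
#' @export
measure_ctr <- function(heart_mask, thorax_mask) {
  row_extent <- function(m) {
    w <- apply(m, 1, function(r) {
      idx <- which(r)
      if (!length(idx)) 0L else diff(range(idx)) + 1L
    })
    max(w)
  }
  if (!any(heart_mask) || !any(thorax_mask)) stop("empty mask")
  if (any(heart_mask & !thorax_mask)) stop("heart mask not inside thorax mask")
  row_extent(heart_mask) / row_extent(thorax_mask)
}

#' Generate a balanced synthetic dataset with manifest
#'
#' Draws `n_per_class` control and cardiomegaly records (one synthetic
#' patient per record) with CTRs from the class-specific ranges, and
#' builds a CheXpert-style manifest. Demographics follow the shape of a
#' typical curated cohort: control age ~ N(54.4, 17.2), cardiomegaly age
#' ~ N(62.9, 17.1) (truncated to [18, 100]); male fraction 0.65 vs 0.59.
#'
#' @param n_per_class Records per class (>= 1).
#' @param config A `synthetic_config`.
#' @return List with `records` (list of `synthetic_record`) and
#'   `manifest` (data frame with columns `Path`, `PatientID`, `Sex`,
#'   `Age`, `Frontal/Lateral`, `AP/PA`, `StudyOrder`, `Cardiomegaly`,
#'   `CTR`).
#' @export
generate_dataset <- function(n_per_class, config = synthetic_config()) {
  stopifnot(n_per_class >= 1)
  n_tot <- 2L * n_per_class
  meta <- with_seed(config$seed, {
    ctr <- c(runif(n_per_class, config$ctr_control[1], config$ctr_control[2]),
             runif(n_per_class, config$ctr_cardiomegaly[1],
                   config$ctr_cardiomegaly[2]))
    label <- rep(c(0L, 1L), each = n_per_class)
    age_mu <- ifelse(label == 0, 54.4, 62.9)
    age_sd <- ifelse(label == 0, 17.2, 17.1)
    age <- round(pmin(pmax(stats::rnorm(n_tot, age_mu, age_sd), 18), 100))
    sex <- ifelse(stats::runif(n_tot) < ifelse(label == 0, 0.65, 0.59),
                  "Male", "Female")
    rec_seed <- sample.int(.Machine$integer.max - 1L, n_tot)
    list(ctr = ctr, label = label, age = age, sex = sex, rec_seed = rec_seed)
  })
  records <- vector("list", n_tot)
  for (i in seq_len(n_tot)) {
    rec <- generate_cxr(meta$ctr[i], config, seed = meta$rec_seed[i])
    rec$patient_id <- sprintf("SYN%05d", i)
    records[[i]] <- rec
  }
  manifest <- data.frame(
    Path = sprintf("synthetic/SYN%05d.png", seq_len(n_tot)),
    PatientID = sprintf("SYN%05d", seq_len(n_tot)),
    Sex = meta$sex, Age = meta$age,
    `Frontal/Lateral` = "Frontal", `AP/PA` = "PA", StudyOrder = 1L,
    Cardiomegaly = meta$label, CTR = meta$ctr,
    check.names = FALSE, stringsAsFactors = FALSE)
  list(records = records, manifest = manifest)
}

#' Requalify labels from the CTR column
#'
#' Applies the curation rule used when re-reviewing mislabeled studies: a
#' record labeled cardiomegaly with CTR <= 0.45 is flipped to control, a
#' record labeled control with CTR >= 0.55 is flipped to cardiomegaly,
#' and intermediate CTRs keep their label (doubtful cases stay intact).
#' Idempotent. Rows with missing CTR are skipped with a warning.
#'
#' @param manifest Data frame with `Cardiomegaly` and `CTR` columns.
#' @param label_column Name of the label column.
#' @param ctr_column Name of the CTR column.
#' @return The manifest with requalified labels.
#' @export
requalify_labels <- function(manifest, label_column = "Cardiomegaly",
                             ctr_column = "CTR") {
  if (!ctr_column %in% names(manifest)) stop("manifest has no CTR column")
  ctr <- manifest[[ctr_column]]
  lab <- manifest[[label_column]]
  miss <- is.na(ctr)
  if (any(miss))
    warning(sum(miss), " rows have missing CTR and were skipped")
  to_control <- !miss & lab == 1L & ctr <= 0.45
  to_cardio <- !miss & lab == 0L & ctr >= 0.55
  lab[to_control] <- 0L
  lab[to_cardio] <- 1L
  manifest[[label_column]] <- lab
  manifest
}
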