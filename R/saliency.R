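# Grad-CAM++ saliency over the extractor's convolutional feature maps, and
# automated trustworthiness classification of the resulting heatmaps with
# respect to the cardiac silhouette.
#
# The pixel-wise weights alpha use first, second and third derivatives of
# the class score with respect to the feature maps. Scores are taken
# pre-softmax and passed through the exponential (standard Grad-CAM++
# practice), which for a locally linear score collapses alpha to the
# gradient-power form g^2 / (2 g^2 + sum_ab A_ab g^3). Because the class
# score reaches the maps only through global average pooling, all
# derivatives are constant within a map and the per-map alpha is computed
# in closed form from the per-feature derivatives of the head.

#' Trustworthiness rules
#'
#' Operationalizes a reader's criteria for accepting a heatmap: the hot
#' zone (pixels above `hot_threshold` of the maximum) must be visible,
#' not cover more than `max_extent` of the image, not split into several
#' zones of similar size (second-largest at least `multiplicity_ratio` of
#' the largest), and its largest component must cover at least
#' `coverage_min` of the heart mask.
#'
#' @param hot_threshold Fraction of the heatmap maximum defining "hot".
#' @param coverage_min Minimal fraction of the heart covered by the
#'   largest hot zone.
#' @param max_extent Maximal fraction of the image the hot area may
#'   cover.
#' @param multiplicity_ratio Similar-size threshold for multiple zones.
#' @return A `trust_rules` list.
#' @export
trust_rules <- function(hot_threshold = 0.5, coverage_min = 0.5,
                        max_extent = 0.5, multiplicity_ratio = 0.5) {
  vals <- c(hot_threshold, coverage_min, max_extent, multiplicity_ratio)
  stopifnot(all(vals > 0 & vals < 1))
  structure(list(hot_threshold = hot_threshold, coverage_min = coverage_min,
                 max_extent = max_extent,
                 multiplicity_ratio = multiplicity_ratio),
            class = "trust_rules")
}

# per-feature first derivative of the pre-softmax class score (analytic),
# plus second and third derivatives. For the piecewise-linear classical
# head the higher derivatives are exactly zero; for quantum heads they are
# obtained by five-point central stencils on the (smooth) head score, all
# feature evaluations batched through one forward pass.
.head_score_derivs <- function(head, x, target_class, eps = 0.05) {
  f <- length(x)
  ci <- target_class + 1L
  fw <- .head_forward(head, matrix(x, 1), want_grad = TRUE)
  onehot <- matrix(0, 1, 2); onehot[1, ci] <- 1
  bk <- .head_backward(head, fw, onehot)
  g <- as.numeric(bk$dX)
  if (head$variant == "classical")
    return(list(score = fw$logits[1, ci], g = g, h = numeric(f),
                t3 = numeric(f)))
  # stencil batch: rows = 1 base + 4 offsets per feature
  offs <- c(-2, -1, 1, 2) * eps
  X <- matrix(x, 1 + 4 * f, f, byrow = TRUE)
  for (k in seq_len(f)) X[1 + 4 * (k - 1) + 1:4, k] <- x[k] + offs
  sc <- .head_forward(head, X)$logits[, ci]
  y0 <- sc[1]
  h <- numeric(f); t3 <- numeric(f)
  for (k in seq_len(f)) {
    y <- sc[1 + 4 * (k - 1) + 1:4]      # at -2e, -e, +e, +2e
    h[k] <- (-y[4] + 16 * y[3] - 30 * y0 + 16 * y[2] - y[1]) / (12 * eps^2)
    t3[k] <- (y[4] - 2 * y[3] + 2 * y[2] - y[1]) / (2 * eps^3)
  }
  list(score = y0, g = g, h = h, t3 = t3)
}

#' Grad-CAM++ heatmap
#'
#' Computes the Grad-CAM++ saliency map of the class score over the toy
#' extractor's post-ReLU convolutional feature maps, upsampled bilinearly
#' into the coordinates of the original input image (regions outside the
#' center crop receive zero) and normalized so the maximum is 1 (an
#' all-zero map stays all-zero). For heads with a shot-sampled circuit,
#' derivatives flow through the exact-expectation path.
#'
#' @param model A `hybrid_model` with a toy extractor.
#' @param image Raw 2D grayscale image.
#' @param target_class Class whose evidence is visualized (0/1; default
#'   the predicted class).
#' @return A `heatmap` object: list with `values` (matrix in input-image
#'   coordinates, in `[0, 1]`), `source_layer`, `target_class`,
#'   `raw_map` (the un-upsampled map) and `score`.
#' @export
gradcam_pp <- function(model, image, target_class = NULL) {
  if (model$extractor$kind != "toy")
    stop("saliency requires the differentiable toy extractor")
  x3 <- preprocess_image(image, model$preprocess)
  fu <- .extract_one_full(x3, model$extractor)
  x <- fu$features
  if (is.null(target_class)) {
    p <- .head_forward(model$head, matrix(x, 1))$probs
    target_class <- as.integer(p[1, 2] >= 0.5)
  }
  dv <- .head_score_derivs(model$head, x, target_class)
  HW <- nrow(fu$maps)
  G <- dv$g / HW; H <- dv$h / HW^2; T3 <- dv$t3 / HW^3
  S_k <- colSums(fu$maps)
  num <- G^2 + H
  den <- 2 * num + S_k * (G^3 + 3 * G * H + T3)
  alpha <- ifelse(abs(den) < 1e-300, 0, num / den)
  w <- alpha * HW * pmax(G, 0)
  L <- pmax(as.numeric(fu$maps %*% w), 0)
  side <- fu$map_side
  raw <- matrix(L, side, side)

  # place into original-image coordinates through the preprocessing chain
  S <- nrow(image)
  sp <- model$preprocess
  off <- (sp$resize_to - sp$crop_to) %/% 2
  up_size <- max(1L, round(sp$crop_to * S / sp$resize_to))
  off_orig <- round(off * S / sp$resize_to)
  up <- EBImage::resize(raw, w = up_size, h = up_size, filter = "bilinear")
  vals <- matrix(0, S, ncol(image))
  rows <- off_orig + seq_len(up_size)
  cols <- off_orig + seq_len(min(up_size, ncol(image) - off_orig))
  vals[rows[rows <= S], cols] <- up[rows <= S, seq_along(cols)]
  vals <- pmax(vals, 0)
  if (max(vals) > 0) vals <- vals / max(vals)
  structure(list(values = vals, source_layer = "conv_bank",
                 target_class = target_class, raw_map = raw,
                 score = dv$score),
            class = "heatmap")
}

#' Classify a heatmap as trustworthy or not
#'
#' Applies the rule set in order: `not_visible` (no hot pixels),
#' `extensive` (hot area above `max_extent` of the image),
#' `multiple_zones` (second-largest hot component of similar size to the
#' largest), `outside_cardiac` (largest component covers less than
#' `coverage_min` of the heart), otherwise trustworthy. Verdicts are
#' invariant to positive rescaling of the raw heatmap because the hot
#' threshold is a fraction of the maximum.
#'
#' @param heatmap A `heatmap` object or plain nonnegative matrix.
#' @param heart_mask Logical matrix aligned to the heatmap coordinates.
#' @param rules A `trust_rules`.
#' @return A `trust_assessment`: list with `verdict` (`"trustworthy"` /
#'   `"non_trustworthy"`), `reason` (one of `ok`, `outside_cardiac`,
#'   `extensive`, `not_visible`, `multiple_zones`), `coverage`,
#'   `hot_fraction`.
#' @export
classify_trustworthy <- function(heatmap, heart_mask, rules = trust_rules()) {
  vals <- if (inherits(heatmap, "heatmap")) heatmap$values else heatmap
  if (!any(heart_mask)) stop("empty heart mask")
  if (!all(dim(vals) == dim(heart_mask)))
    stop("heatmap and mask dimensions differ")
  res <- function(reason, coverage = NA_real_, hot_fraction = NA_real_)
    structure(list(verdict = if (reason == "ok") "trustworthy"
                             else "non_trustworthy",
                   reason = reason, coverage = coverage,
                   hot_fraction = hot_fraction),
              class = "trust_assessment")
  m <- max(vals)
  if (m <= 0) return(res("not_visible"))
  hot <- vals >= rules$hot_threshold * m
  if (!any(hot)) return(res("not_visible"))
  hot_fraction <- mean(hot)
  if (hot_fraction > rules$max_extent)
    return(res("extensive", hot_fraction = hot_fraction))
  lab <- EBImage::bwlabel(hot)
  areas <- sort(tabulate(lab[lab > 0]), decreasing = TRUE)
  if (length(areas) >= 2 && areas[2] >= rules$multiplicity_ratio * areas[1])
    return(res("multiple_zones", hot_fraction = hot_fraction))
  largest <- lab == which.max(tabulate(lab[lab > 0]))
  coverage <- sum(largest & heart_mask) / sum(heart_mask)
  if (coverage < rules$coverage_min)
    return(res("outside_cardiac", coverage, hot_fraction))
  res("ok", coverage, hot_fraction)
}

#' @export
print.trust_assessment <- function(x, ...) {
  cat(sprintf("<trust_assessment> %s (%s; coverage %.2f, hot %.2f)\n",
              x$verdict, x$reason, x$coverage, x$hot_fraction))
  invisible(x)
}

#' Assess heatmaps for a set of images
#'
#' @param model A `hybrid_model`.
#' @param records List of `synthetic_record` objects (images plus heart
#'   masks).
#' @param rules A `trust_rules`.
#' @param target_class Per-image target class (`NULL` = predicted).
#' @return Data frame with one row per record: `id`, `verdict`, `reason`,
#'   `coverage`.
#' @export
assess_heatmaps <- function(model, records, rules = trust_rules(),
                            target_class = NULL) {
  rows <- lapply(seq_along(records), function(i) {
    r <- records[[i]]
    hm <- gradcam_pp(model, r$image, target_class)
    ta <- classify_trustworthy(hm, r$heart_mask, rules)
    data.frame(id = if (is.na(r$patient_id)) as.character(i) else r$patient_id,
               verdict = ta$verdict, reason = ta$reason,
               coverage = ta$coverage, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
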