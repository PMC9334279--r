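#' Measure dye infiltration in a foam scan
#'
#' Segments the dye-infiltrated region of an 8-bit flatbed scan of a foam
#' block by a fixed intensity threshold (default 150; the dye is darker than
#' the foam, so pixels at or below the threshold are dye), keeps the largest
#' connected component, and measures either the inlet diameter (front view:
#' maximal Feret extent of the component) or the infiltration depth (section
#' view: maximal extent along the sonication axis).
#'
#' @param img Numeric matrix of pixel values in `[0, 255]`, or a path to a
#'   PNG/TIFF file.
#' @param mm_per_px Pixel size in mm.
#' @param view `"front"` (diameter) or `"section"` (depth).
#' @param threshold Segmentation threshold on the 0-255 scale (default 150).
#' @param polarity `"dark"` (dye at or below threshold, default) or
#'   `"bright"`.
#' @param axis Image axis of sonication for the depth measure: `"row"` or
#'   `"col"`.
#' @return A one-row tibble: `view`, `measure`, `value_mm`, `n_px`,
#'   `threshold`.
#' @export
foam_infiltration <- function(img, mm_per_px, view = c("front", "section"),
                              threshold = 150, polarity = c("dark", "bright"),
                              axis = c("row", "col")) {
  view <- match.arg(view); polarity <- match.arg(polarity)
  axis <- match.arg(axis)
  img <- load_gray(img)
  if (mm_per_px <= 0) stop("mm_per_px must be positive", call. = FALSE)
  mask <- if (polarity == "dark") img <= threshold else img >= threshold
  measure <- if (view == "front") "inlet_diameter" else "depth"
  if (!any(mask)) {
    warning("empty dye mask: no pixels ",
            if (polarity == "dark") "at or below " else "at or above ",
            threshold, call. = FALSE)
    return(tibble::tibble(view = view, measure = measure, value_mm = 0,
                          n_px = 0L, threshold = threshold))
  }
  lab <- EBImage::bwlabel(mask)
  sizes <- tabulate(lab[lab > 0])
  comp <- lab == which.max(sizes)
  pix <- which(comp, arr.ind = TRUE)
  value_mm <- if (view == "front") {
    hull <- pix[grDevices::chull(pix), , drop = FALSE]
    (sqrt(max(as.matrix(stats::dist(hull))^2)) + 1) * mm_per_px
  } else {
    ax_idx <- if (axis == "row") pix[, 1] else pix[, 2]
    (diff(range(ax_idx)) + 1) * mm_per_px
  }
  tibble::tibble(view = view, measure = measure, value_mm = value_mm,
                 n_px = sum(comp), threshold = threshold)
}

# read a grayscale image (matrix in 0..255) from matrix/png/tiff
load_gray <- function(img) {
  if (is.character(img)) {
    img <- if (grepl("\\.png$", img, ignore.case = TRUE)) {
      png::readPNG(img) * 255
    } else {
      tiff::readTIFF(img) * 255
    }
  }
  if (length(dim(img)) == 3) img <- img[, , 1]
  stopifnot(is.matrix(img))
  img
}

#' Automatic brain mask from background fluorescence
#'
#' Fallback segmentation when no external brain mask is supplied: global Otsu
#' threshold on the background-fluorescence channel, hole filling, largest
#' connected component.
#'
#' @param channel Numeric matrix of fluorescence intensities.
#' @return Logical matrix.
#' @export
auto_brain_mask <- function(channel) {
  rng <- range(channel)
  if (diff(rng) == 0) stop("constant channel: cannot segment a brain mask",
                           call. = FALSE)
  norm <- (channel - rng[1]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(norm))
  # if bright tracer deposits dominate the split, the foreground is a small
  # fraction of the image; re-threshold below them to recover the dimmer
  # brain background
  if (mean(norm > thr) < 0.2) {
    thr <- EBImage::otsu(EBImage::Image(pmin(norm, thr) / thr)) * thr
  }
  mask <- EBImage::fillHull(EBImage::bwlabel(norm > thr))
  lab <- EBImage::bwlabel(mask > 0)
  sizes <- tabulate(lab[lab > 0])
  as.matrix(lab == which.max(sizes))
}

#' Quantify tracer uptake in a fluorescence section
#'
#' Per tracer channel: min-max normalization of the image to the 0-255
#' scale, background taken as the minimum normalized intensity inside the
#' brain mask (floored at 1 grey level to keep the multiplicative threshold
#' meaningful), uptake segmented as pixels above 170% of that background
#' minimum, and percent uptake reported as the uptake area relative to the
#' brain area. Invariant to affine intensity rescaling of the input.
#'
#' @param channels Named list of numeric matrices (e.g. `list(oa = ...,
#'   fitc_d = ...)`), one per tracer.
#' @param brain_mask Logical matrix; `NULL` triggers [auto_brain_mask()] on
#'   the first channel.
#' @param section_offset_mm Rostro-caudal offset of the section (metadata).
#' @param background_factor Multiplicative uptake threshold (default 1.7).
#' @return A tibble with one row per tracer: `tracer`, `section_offset_mm`,
#'   `percent_uptake`, `background_min`, `threshold`, `brain_px`.
#' @export
tracer_uptake <- function(channels, brain_mask = NULL, section_offset_mm = NA,
                          background_factor = 1.7) {
  stopifnot(is.list(channels), length(channels) >= 1,
            !is.null(names(channels)))
  if (is.null(brain_mask)) brain_mask <- auto_brain_mask(channels[[1]])
  if (!any(brain_mask)) stop("empty brain mask", call. = FALSE)
  purrr::imap_dfr(channels, function(ch, nm) {
    stopifnot(identical(dim(ch), dim(brain_mask)))
    rng <- range(ch)
    norm <- if (diff(rng) == 0) ch * 0 else (ch - rng[1]) / diff(rng) * 255
    bg <- max(min(norm[brain_mask]), 1)
    thr <- background_factor * bg
    up <- sum(norm[brain_mask] > thr)
    tibble::tibble(tracer = nm, section_offset_mm = section_offset_mm,
                   percent_uptake = 100 * up / sum(brain_mask),
                   background_min = bg, threshold = thr,
                   brain_px = sum(brain_mask))
  })
}

#' Quantify a full section set
#'
#' Applies [tracer_uptake()] to each section of a section set (as produced by
#' [make_section_set()] or assembled by hand), using the per-section ground
#' truth masks when present, otherwise the automatic mask.
#'
#' @param sections List of sections; each has `channels` (named list of
#'   matrices), optional `brain_mask`, and `section_offset_mm`.
#' @param ... Passed to [tracer_uptake()].
#' @return A tibble, one row per section x tracer.
#' @export
quantify_sections <- function(sections, ...) {
  purrr::map_dfr(sections, function(s) {
    tracer_uptake(s$channels, brain_mask = s$brain_mask,
                  section_offset_mm = s$section_offset_mm, ...)
  })
}

#' One-way ANOVA with Tukey HSD post-hoc comparisons
#'
#' Standard one-way analysis of variance across groups followed by Tukey
#' honest-significant-difference pairwise comparisons on the studentized
#' range distribution.
#'
#' @param data A data frame.
#' @param value,group Columns (tidy-eval) holding the response and the group
#'   factor.
#' @param conf_level Family-wise confidence level (default 0.95).
#' @return An object of class `group_stats`; see [tidy.group_stats()] and
#'   [glance.group_stats()].
#' @examples
#' df <- data.frame(y = c(1, 2, 3, 2, 3, 4, 3, 4, 5),
#'                  g = rep(c("a", "b", "c"), each = 3))
#' glance(group_stats(df, y, g))$statistic   # F = 3 on (2, 6) df
#' @export
group_stats <- function(data, value, group, conf_level = 0.95) {
  df <- dplyr::tibble(value = dplyr::pull(data, {{ value }}),
                      group = factor(dplyr::pull(data, {{ group }})))
  if (nlevels(df$group) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(table(df$group) < 2)) stop("every group needs >= 2 values",
                                     call. = FALSE)
  fit <- stats::aov(value ~ group, data = df)
  an <- stats::anova(fit)
  if (an[1, "Mean Sq"] == 0 && an[2, "Mean Sq"] == 0) {
    warning("degenerate data: zero variance within and between groups",
            call. = FALSE)
  }
  tk <- stats::TukeyHSD(fit, conf.level = conf_level)$group
  structure(list(
    fit = fit,
    anova = tibble::tibble(statistic = an[1, "F value"],
                           df_between = an[1, "Df"], df_within = an[2, "Df"],
                           p_value = an[1, "Pr(>F)"]),
    tukey = tibble::tibble(contrast = rownames(tk), estimate = tk[, "diff"],
                           conf_low = tk[, "lwr"], conf_high = tk[, "upr"],
                           adj_p_value = tk[, "p adj"],
                           significant = tk[, "p adj"] < 1 - conf_level),
    conf_level = conf_level), class = "group_stats")
}

#' @export
print.group_stats <- function(x, ...) {
  a <- x$anova
  cat("<group_stats> one-way ANOVA: F(", a$df_between, ",", a$df_within,
      ") = ", signif(a$statistic, 4), ", p = ", signif(a$p_value, 3),
      "\n", sep = "")
  print(x$tukey)
  invisible(x)
}

#' Paired two-tailed t test
#'
#' @param a,b Paired measurement vectors of equal length.
#' @return A one-row tibble: `statistic`, `df`, `p_value`, `estimate`.
#' @export
paired_t <- function(a, b) {
  if (length(a) != length(b)) stop("paired samples must have equal length",
                                   call. = FALSE)
  tt <- stats::t.test(a, b, paired = TRUE, alternative = "two.sided")
  tibble::tibble(statistic = unname(tt$statistic),
                 df = unname(tt$parameter), p_value = tt$p.value,
                 estimate = unname(tt$estimate))
}
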