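# Spatial quantification: positive-cell fractions for a marker gene,
# cell-coordinate co-localization against an annotated population, and the
# image route (RGB thresholding, binary dilation, composite rendering).

#' Positive-cell fraction of a gene in a section
#'
#' The denominator is the full cell population of the section, not any
#' annotation subset.
#'
#' @param section an [new_expression_section()].
#' @param gene gene id present in the section.
#' @param threshold positivity cutoff on normalized expression; a cell is
#'   positive when expression is strictly greater (default 0).
#' @return Proportion of positive cells among all cells.
#' @export
positive_cell_fraction <- function(section, gene, threshold = 0) {
  stopifnot(inherits(section, "expression_section"))
  if (!gene %in% colnames(section$expr)) {
    stop(sprintf("unknown gene '%s'", gene), call. = FALSE)
  }
  mean(section$expr[, gene] > threshold)
}

#' Positive-cell time course over a section series
#'
#' @param sections named list of sections (one per timepoint, in order).
#' @param gene marker gene id.
#' @param threshold positivity cutoff (default 0).
#' @return data.frame with columns `condition` and `positive_fraction`.
#' @export
positive_fraction_course <- function(sections, gene, threshold = 0) {
  stopifnot(is.list(sections), length(sections) > 0)
  data.frame(
    condition = vapply(sections, function(s) s$condition, character(1)),
    positive_fraction = vapply(sections, positive_cell_fraction,
                               numeric(1), gene = gene,
                               threshold = threshold),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Cell-coordinate co-localization of a marker with an annotation
#'
#' A marker-positive cell co-localizes when some cell carrying the target
#' annotation lies within Euclidean distance `radius` (an annotated
#' positive cell co-localizes with itself at any radius >= 0).
#'
#' @param section an [new_expression_section()].
#' @param gene marker gene id.
#' @param annotation target cell-type label.
#' @param radius co-localization distance (>= 0), in coordinate units.
#' @param threshold positivity cutoff (default 0).
#' @return A `coloc_cells` list: `n_cells`, `n_positive`, `n_annotation`,
#'   `n_colocalized`, `colocalized_fraction` (of positive cells; `NA` when
#'   there are none), `positive_cell_fraction`.
#' @export
annotation_overlap <- function(section, gene, annotation, radius,
                               threshold = 0) {
  stopifnot(inherits(section, "expression_section"))
  if (!is.numeric(radius) || length(radius) != 1L || radius < 0) {
    stop("`radius` must be a single non-negative number", call. = FALSE)
  }
  if (!annotation %in% section$cells$celltype) {
    stop(sprintf("annotation '%s' absent from section", annotation),
         call. = FALSE)
  }
  if (!gene %in% colnames(section$expr)) {
    stop(sprintf("unknown gene '%s'", gene), call. = FALSE)
  }
  pos <- which(section$expr[, gene] > threshold)
  ann <- which(section$cells$celltype == annotation)
  n_coloc <- 0L
  if (length(pos) && length(ann)) {
    px <- section$cells$x[pos]; py <- section$cells$y[pos]
    ax <- section$cells$x[ann]; ay <- section$cells$y[ann]
    d2 <- outer(px, ax, `-`)^2 + outer(py, ay, `-`)^2
    n_coloc <- sum(apply(d2, 1, min) <= radius^2)
  }
  structure(list(
    n_cells = nrow(section$cells),
    n_positive = length(pos),
    n_annotation = length(ann),
    n_colocalized = n_coloc,
    colocalized_fraction = if (length(pos)) n_coloc / length(pos) else NA_real_,
    positive_cell_fraction = length(pos) / nrow(section$cells)
  ), class = "coloc_cells")
}

# parse "R>=120,G<=80,B<=80" into per-channel [lower, upper] bounds
.parse_rgb_rule <- function(rule) {
  channels <- c(R = 1L, G = 2L, B = 3L, A = 4L)
  bounds <- matrix(rep(c(0, 255), each = 4), 4, 2,
                   dimnames = list(names(channels), c("lower", "upper")))
  used <- rep(FALSE, 4)
  if (is.character(rule)) {
    parts <- trimws(strsplit(rule, ",", fixed = TRUE)[[1]])
    parts <- parts[nzchar(parts)]
    if (length(parts) == 0) stop("empty threshold rule", call. = FALSE)
    for (p in parts) {
      m <- regmatches(p, regexec("^([RGBA])\\s*(>=|<=)\\s*([0-9.]+)$", p))[[1]]
      if (length(m) != 4) {
        stop(sprintf("cannot parse rule clause '%s'", p), call. = FALSE)
      }
      ch <- channels[[m[2]]]
      val <- as.numeric(m[4])
      if (m[3] == ">=") bounds[ch, "lower"] <- max(bounds[ch, "lower"], val)
      else bounds[ch, "upper"] <- min(bounds[ch, "upper"], val)
      used[ch] <- TRUE
    }
  } else if (is.list(rule)) {
    for (nm in names(rule)) {
      if (!nm %in% names(channels)) {
        stop(sprintf("unknown channel '%s' in rule", nm), call. = FALSE)
      }
      b <- rule[[nm]]
      if (length(b) != 2L) stop("list rules need c(lower, upper) per channel",
                                call. = FALSE)
      bounds[channels[[nm]], ] <- as.numeric(b)
      used[channels[[nm]]] <- TRUE
    }
  } else {
    stop("`rule` must be a string or named list", call. = FALSE)
  }
  if (any(bounds[, "lower"] > bounds[, "upper"])) {
    stop("contradictory rule: a channel lower bound exceeds its upper bound",
         call. = FALSE)
  }
  list(bounds = bounds, used = used)
}

#' Threshold a raster image in RGB space
#'
#' A pixel enters the mask iff all the rule's channel inequalities hold.
#' The alpha channel is ignored unless the rule names `A`.
#'
#' @param img a [new_raster_image()].
#' @param rule a rule string like `"R>=120,G<=80,B<=80"` or a named list
#'   `list(R = c(120, 255), ...)` of per-channel `c(lower, upper)` bounds.
#' @return A [new_binary_mask()] of the image's shape.
#' @export
threshold_rgb <- function(img, rule) {
  stopifnot(inherits(img, "raster_image"))
  parsed <- .parse_rgb_rule(rule)
  d <- dim(img$pixels)
  mask <- matrix(TRUE, d[1], d[2])
  for (ch in 1:4) {
    if (ch == 4L && !parsed$used[4]) next  # alpha only when named
    mask <- mask & img$pixels[, , ch] >= parsed$bounds[ch, "lower"] &
      img$pixels[, , ch] <= parsed$bounds[ch, "upper"]
  }
  new_binary_mask(mask)
}

#' Binary dilation of a mask
#'
#' Morphological dilation with a disk structuring element of the given
#' radius (Euclidean metric; `shape = "square"` gives the Chebyshev
#' square). Radius 0 is the identity; output always contains the input.
#'
#' @param mask a [new_binary_mask()].
#' @param radius dilation radius in pixels (>= 0).
#' @param shape `"disk"` (default) or `"square"` structuring element.
#' @return The dilated `binary_mask`.
#' @export
dilate <- function(mask, radius, shape = c("disk", "square")) {
  stopifnot(inherits(mask, "binary_mask"))
  shape <- match.arg(shape)
  if (!is.numeric(radius) || length(radius) != 1L || radius < 0) {
    stop("`radius` must be a single non-negative number", call. = FALSE)
  }
  r <- floor(radius)
  if (r == 0) return(mask)
  h <- nrow(mask); w <- ncol(mask)
  offsets <- expand.grid(dy = -r:r, dx = -r:r)
  if (shape == "disk") {
    offsets <- offsets[offsets$dx^2 + offsets$dy^2 <= radius^2, ]
  }
  out <- matrix(FALSE, h, w)
  m <- unclass(mask)
  for (i in seq_len(nrow(offsets))) {
    dy <- offsets$dy[i]; dx <- offsets$dx[i]
    src_r <- max(1, 1 - dy):min(h, h - dy)
    src_c <- max(1, 1 - dx):min(w, w - dx)
    out[src_r + dy, src_c + dx] <- out[src_r + dy, src_c + dx] |
      m[src_r, src_c]
  }
  new_binary_mask(out)
}

# rendering constants, fixed for bit-stable output PNGs
.LUMA <- c(0.299, 0.587, 0.114)        # ITU-R 601 grayscale weights
.RED_LOW <- 120L                        # red gradient endpoints
.RED_HIGH <- 255L
.YELLOW <- c(255L, 255L, 0L)

#' Compose a marker/population co-localization image
#'
#' Renders the marker image as grayscale background, tints marker-mask
#' pixels on a red gradient scaled by the original pixel intensity, paints
#' population-mask pixels yellow, and draws pixels in both masks with the
#' marker encoding (red over yellow). The alpha channel is transparent
#' outside any mask or tissue (nonzero-luma) pixel. Pixel counts for the
#' two masks and their intersection are returned alongside.
#'
#' @param marker_img the marker [new_raster_image()].
#' @param marker_mask marker-signal [new_binary_mask()].
#' @param population_mask population [new_binary_mask()].
#' @return List with `image` (composite `raster_image`) and `result`
#'   (a `coloc_result`: `marker_pixels`, `population_pixels`,
#'   `overlap_pixels`, `overlap_fraction_of_marker`).
#' @export
compose <- function(marker_img, marker_mask, population_mask) {
  stopifnot(inherits(marker_img, "raster_image"),
            inherits(marker_mask, "binary_mask"),
            inherits(population_mask, "binary_mask"))
  d <- dim(marker_img$pixels)
  if (!identical(dim(unclass(marker_mask)), d[1:2]) ||
      !identical(dim(unclass(population_mask)), d[1:2])) {
    stop("image and mask shapes disagree", call. = FALSE)
  }
  mm <- unclass(marker_mask); pm <- unclass(population_mask)
  luma <- .LUMA[1] * marker_img$pixels[, , 1] +
    .LUMA[2] * marker_img$pixels[, , 2] +
    .LUMA[3] * marker_img$pixels[, , 3]
  gray <- as.integer(round(luma))
  R <- gray; G <- gray; B <- gray
  A <- ifelse(gray > 0 | mm | pm, 255L, 0L)
  # population first, marker (red) over yellow in the overlap
  R[pm] <- .YELLOW[1]; G[pm] <- .YELLOW[2]; B[pm] <- .YELLOW[3]
  intensity <- luma / 255
  redv <- as.integer(round(.RED_LOW + (.RED_HIGH - .RED_LOW) * intensity))
  R[mm] <- redv[mm]; G[mm] <- 0L; B[mm] <- 0L
  px <- array(0L, d)
  px[, , 1] <- R; px[, , 2] <- G; px[, , 3] <- B; px[, , 4] <- A
  marker_pixels <- sum(mm)
  population_pixels <- sum(pm)
  overlap <- sum(mm & pm)
  result <- structure(list(
    marker_pixels = marker_pixels,
    population_pixels = population_pixels,
    overlap_pixels = overlap,
    overlap_fraction_of_marker = if (marker_pixels > 0)
      overlap / marker_pixels else NA_real_
  ), class = "coloc_result")
  list(image = new_raster_image(px), result = result)
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("<coloc_result> marker %d px, population %d px, overlap %d px (%.1f%% of marker)\n",
              x$marker_pixels, x$population_pixels, x$overlap_pixels,
              100 * (x$overlap_fraction_of_marker %||% NA_real_)))
  invisible(x)
}
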