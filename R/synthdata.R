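# Synthetic multi-section spatial single-cell data with planted
# co-expression structure.
#
# The generator emulates the structure of an injury time-course atlas:
# one section per condition label (uninjured controls first, then a
# days-post-injury series), 10-40 annotated cell-types laid out as spatial
# blobs, planted co-expression modules realized through a per-module latent
# factor, a marker gene whose positive-cell fraction follows a configured
# rise-and-decay course, and a mixed gene namespace (human-like symbols vs
# "AMEX60DD_"-prefixed species-specific identifiers, with some raw
# pipe-delimited names carrying taxonomic suffixes).

#' Configuration for the synthetic section generator
#'
#' Defaults encode the emulated study conditions: a juvenile control
#' followed by the 2/5/10/15/20/30/60 days-post-injury (DPI) series, and a
#' marker-gene positive-cell course of 6/37/33/25/24/28/7/6 percent across
#' those timepoints.
#'
#' @param timepoint_labels ordered condition labels, controls first; labels
#'   ending in `"dpi"` (case-insensitive) are classed as regeneration,
#'   all others as control.
#' @param n_celltypes number of annotated cell-types per section.
#' @param cells_per_type cells simulated per cell-type per section.
#' @param n_genes total genes.
#' @param n_modules_shared planted modules active in every section.
#' @param n_modules_regen_only planted modules active only in regeneration
#'   (DPI) sections.
#' @param module_size genes per planted module; a scalar or one entry per
#'   planted module.
#' @param within_module_rho target mean pairwise Pearson correlation of a
#'   planted module's genes in sections where the module is active.
#' @param noise_sd standard deviation of background (non-module) expression.
#' @param marker_fraction_course per-timepoint target positive-cell fraction
#'   for the planted marker gene; length must equal
#'   `length(timepoint_labels)`.
#' @param amex_fraction fraction of genes given `"AMEX60DD_"` identifiers.
#' @param raw_symbol_fraction fraction of symbol-named genes whose raw name
#'   is emitted in pipe-delimited form with a taxonomic suffix.
#' @param seed integer RNG seed.
#' @return A validated `synth_config` object.
#' @export
synth_config <- function(timepoint_labels = c("juvenile", "2dpi", "5dpi",
                                              "10dpi", "15dpi", "20dpi",
                                              "30dpi", "60dpi"),
                         n_celltypes = 10,
                         cells_per_type = 1000,
                         n_genes = 600,
                         n_modules_shared = 3,
                         n_modules_regen_only = 2,
                         module_size = c(50, 45, 40, 35, 35),
                         within_module_rho = 0.7,
                         noise_sd = 1,
                         marker_fraction_course = c(0.06, 0.37, 0.33, 0.25,
                                                    0.24, 0.28, 0.07, 0.06),
                         amex_fraction = 0.25,
                         raw_symbol_fraction = 0.1,
                         seed = 1L) {
  timepoint_labels <- as.character(timepoint_labels)
  if (anyDuplicated(timepoint_labels)) {
    stop("invalid config: `timepoint_labels` must be unique", call. = FALSE)
  }
  if (length(timepoint_labels) < 1L) {
    stop("invalid config: at least one timepoint label required", call. = FALSE)
  }
  n_celltypes <- check_count(n_celltypes, "n_celltypes")
  cells_per_type <- check_count(cells_per_type, "cells_per_type")
  n_genes <- check_count(n_genes, "n_genes")
  n_modules_shared <- check_count(n_modules_shared, "n_modules_shared", min = 0L)
  n_modules_regen_only <- check_count(n_modules_regen_only,
                                      "n_modules_regen_only", min = 0L)
  n_planted_chk <- n_modules_shared + n_modules_regen_only
  if (length(module_size) == 1L) {
    module_size <- rep(module_size, n_planted_chk)
  }
  if (n_planted_chk > 0 && length(module_size) != n_planted_chk) {
    stop("invalid config: `module_size` must be scalar or one entry per planted module",
         call. = FALSE)
  }
  module_size <- vapply(module_size, check_count, integer(1),
                        what = "module_size")
  within_module_rho <- check_fraction(within_module_rho, "within_module_rho")
  amex_fraction <- check_fraction(amex_fraction, "amex_fraction")
  raw_symbol_fraction <- check_fraction(raw_symbol_fraction,
                                        "raw_symbol_fraction")
  marker_fraction_course <- check_fraction(marker_fraction_course,
                                           "marker_fraction_course")
  if (length(marker_fraction_course) != length(timepoint_labels)) {
    stop("invalid config: `marker_fraction_course` must have one entry per timepoint label",
         call. = FALSE)
  }
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || noise_sd < 0) {
    stop("invalid config: `noise_sd` must be a single non-negative number",
         call. = FALSE)
  }
  if (sum(module_size) > n_genes - 1L) {
    # the -1 reserves the marker gene, which never belongs to a module
    stop("invalid config: total planted module size must leave room for non-module genes (<= n_genes - 1)",
         call. = FALSE)
  }
  seed <- check_count(seed, "seed", min = 0L)
  structure(list(
    timepoint_labels = timepoint_labels,
    condition_class = ifelse(grepl("dpi$", timepoint_labels,
                                   ignore.case = TRUE),
                             "regeneration", "control"),
    n_timepoints = length(timepoint_labels),
    n_celltypes = n_celltypes,
    cells_per_type = cells_per_type,
    n_genes = n_genes,
    n_modules_shared = n_modules_shared,
    n_modules_regen_only = n_modules_regen_only,
    module_size = module_size,
    within_module_rho = within_module_rho,
    noise_sd = noise_sd,
    marker_fraction_course = marker_fraction_course,
    amex_fraction = amex_fraction,
    raw_symbol_fraction = raw_symbol_fraction,
    seed = seed
  ), class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  cat(sprintf("<synth_config> %d timepoints (%s), %d cell-types x %d cells, %d genes\n",
              x$n_timepoints, paste(x$timepoint_labels, collapse = ", "),
              x$n_celltypes, x$cells_per_type, x$n_genes))
  cat(sprintf("  planted modules: %d shared + %d regeneration-only, sizes %s, rho %.2f\n",
              x$n_modules_shared, x$n_modules_regen_only,
              paste(unique(x$module_size), collapse = "/"),
              x$within_module_rho))
  invisible(x)
}

#' Create an expression section container
#'
#' @param expr numeric cell x gene matrix with cell ids as row names and
#'   gene ids as column names.
#' @param cells data.frame with columns `cell_id`, `celltype`, `x`, `y`.
#' @param condition single condition/timepoint label.
#' @param genes optional data.frame with columns `gene_id`, `raw_name`.
#' @return An `expression_section` object.
#' @export
new_expression_section <- function(expr, cells, condition, genes = NULL) {
  stopifnot(is.matrix(expr), is.data.frame(cells))
  req <- c("cell_id", "celltype", "x", "y")
  if (!all(req %in% names(cells))) {
    stop("`cells` must have columns cell_id, celltype, x, y", call. = FALSE)
  }
  if (nrow(expr) != nrow(cells) || !identical(rownames(expr),
                                              as.character(cells$cell_id))) {
    stop("row names of `expr` must match `cells$cell_id`", call. = FALSE)
  }
  if (any(!is.finite(cells$x)) || any(!is.finite(cells$y))) {
    stop("cell coordinates must be finite", call. = FALSE)
  }
  if (any(!nzchar(as.character(cells$celltype)))) {
    stop("cell annotations must be nonempty strings", call. = FALSE)
  }
  if (is.null(genes)) {
    genes <- data.frame(gene_id = colnames(expr), raw_name = colnames(expr),
                        stringsAsFactors = FALSE)
  }
  structure(list(expr = expr, cells = cells,
                 condition = as.character(condition), genes = genes),
            class = "expression_section")
}

#' @export
print.expression_section <- function(x, ...) {
  cat(sprintf("<expression_section> '%s': %d cells x %d genes, %d cell-types\n",
              x$condition, nrow(x$expr), ncol(x$expr),
              length(unique(x$cells$celltype))))
  invisible(x)
}

# gene naming: unique symbol-like names, marker forced to "TRH"
.make_gene_names <- function(n_genes, amex_fraction, marker_index) {
  n_amex <- round(amex_fraction * n_genes)
  is_amex <- rep(FALSE, n_genes)
  candidates <- setdiff(seq_len(n_genes), marker_index)
  if (n_amex > 0) {
    is_amex[sample(candidates, min(n_amex, length(candidates)))] <- TRUE
  }
  ids <- character(n_genes)
  ids[is_amex] <- sprintf("AMEX60DD_%06d", sample.int(999999L, sum(is_amex)))
  n_sym <- sum(!is_amex)
  syms <- character(0)
  while (length(syms) < n_sym) {
    need <- n_sym - length(syms)
    cand <- vapply(seq_len(need), function(i) {
      paste0(paste(sample(LETTERS, sample(3:4, 1), replace = TRUE),
                   collapse = ""),
             sample(c("", as.character(1:9)), 1))
    }, character(1))
    syms <- unique(c(syms, setdiff(cand, "TRH")))
  }
  ids[!is_amex] <- syms[seq_len(n_sym)]
  ids[marker_index] <- "TRH"
  ids
}

#' Generate synthetic expression sections with planted structure
#'
#' One section is produced per configured timepoint label. Planted modules
#' are realized as a per-module latent factor shared by member genes
#' (expression = 3 + loading x factor + noise, clipped at zero), with
#' loadings drawn uniformly in \[0.7, 1\] and per-gene noise calibrated so
#' the mean pairwise correlation matches `within_module_rho` while
#' individual gene-factor correlations spread around `sqrt(rho)`, as kME
#' values do in real modules. Background genes are not independent noise:
#' they share weak latent factors (blocks of 3-25 genes, gene-factor
#' correlation 0.1-0.55), emulating the pervasive weak co-expression of
#' real transcriptomes that gives co-expression networks their
#' heavy-tailed, approximately scale-free degree distributions.
#' Regeneration-only modules carry their factor structure only in
#' DPI-labelled sections; elsewhere their genes are background noise. The
#' marker gene ("TRH") is set positive in exactly
#' `round(course x n_cells)` cells per section and zero elsewhere, so
#' measured fractions match the configured course exactly.
#'
#' @param config a [synth_config()].
#' @return A list with elements `sections` (list of
#'   [new_expression_section()] objects, one per timepoint) and `truth`
#'   (a `synth_truth` object: `module_membership`, `regen_only_modules`,
#'   `marker_gene`, `marker_positive_cells`, `celltype_of_cell`,
#'   `loadings`).
#' @export
generate_sections <- function(config) {
  if (!inherits(config, "synth_config")) {
    stop("`config` must be created by synth_config()", call. = FALSE)
  }
  with_seed(config$seed, {
    g <- config$n_genes
    n_planted <- config$n_modules_shared + config$n_modules_regen_only
    module_ids <- if (n_planted > 0) sprintf("P%d", seq_len(n_planted)) else character(0)
    regen_only <- if (config$n_modules_regen_only > 0) {
      module_ids[seq(config$n_modules_shared + 1L, n_planted)]
    } else character(0)

    marker_index <- g  # reserve the last gene slot for the marker
    gene_ids <- .make_gene_names(g, config$amex_fraction, marker_index)

    # assign planted module members among non-marker genes
    membership <- rep(NA_character_, g)
    pool <- setdiff(seq_len(g), marker_index)
    members_of <- list()
    for (mi in seq_along(module_ids)) {
      m <- module_ids[mi]
      idx <- sample(pool, config$module_size[mi])
      pool <- setdiff(pool, idx)
      membership[idx] <- m
      members_of[[m]] <- idx
    }

    loadings <- rep(NA_real_, g)
    in_module <- !is.na(membership)
    loadings[in_module] <- runif(sum(in_module), 0.7, 1)

    # Per-gene factor correlation a_g spread around sqrt(rho_m): pairwise
    # correlation of members i, j is a_i * a_j, so the module mean tracks
    # its target while individual genes differ in connectivity (like real
    # kME). Module targets rho_m are jittered evenly around rho (mean
    # preserved), as real modules differ in tightness; both spreads give
    # the network the connectivity continuum real data shows.
    rho <- config$within_module_rho
    factor_cor <- rep(NA_real_, g)
    if (n_planted > 0 && rho > 0) {
      offs <- if (n_planted > 1) {
        seq(-0.06, 0.06, length.out = n_planted)
      } else 0
      for (mi in seq_len(n_planted)) {
        idx <- members_of[[module_ids[mi]]]
        if (rho >= 0.99) {
          factor_cor[idx] <- 1
        } else {
          rho_m <- min(0.98, max(0.05, rho + offs[mi]))
          a_lo <- max(0.05, sqrt(rho_m) - 0.07)
          a_hi <- min(0.97, sqrt(rho_m) + 0.07)
          factor_cor[idx] <- runif(length(idx), a_lo, a_hi)
        }
      }
    }

    # raw pipe-delimited names for a subset of symbol-named genes
    raw_names <- gene_ids
    sym_idx <- setdiff(which(!startsWith(gene_ids, "AMEX60DD_")), marker_index)
    n_raw <- round(config$raw_symbol_fraction * length(sym_idx))
    if (n_raw > 0) {
      raw_idx <- sample(sym_idx, n_raw)
      raw_names[raw_idx] <- sprintf("%s | %s_XENLA", gene_ids[raw_idx],
                                    gene_ids[raw_idx])
    }
    genes_df <- data.frame(gene_id = gene_ids, raw_name = raw_names,
                           stringsAsFactors = FALSE)

    # spatial layout: one Gaussian blob per cell-type on a coarse grid
    celltypes <- sprintf("CT%02d", seq_len(config$n_celltypes))
    grid_cols <- ceiling(sqrt(config$n_celltypes))
    centers <- cbind(100 + 200 * ((seq_len(config$n_celltypes) - 1) %% grid_cols),
                     100 + 200 * ((seq_len(config$n_celltypes) - 1) %/% grid_cols))

    sections <- vector("list", config$n_timepoints)
    names(sections) <- config$timepoint_labels
    marker_positive_cells <- vector("list", config$n_timepoints)
    names(marker_positive_cells) <- config$timepoint_labels
    celltype_of_cell <- character(0)

    for (t in seq_len(config$n_timepoints)) {
      label <- config$timepoint_labels[t]
      is_regen <- config$condition_class[t] == "regeneration"
      n <- config$n_celltypes * config$cells_per_type
      cell_ids <- sprintf("%s_c%05d", label, seq_len(n))
      ct <- rep(celltypes, each = config$cells_per_type)

      expr <- matrix(rnorm(n * g, mean = 0.5, sd = config$noise_sd), n, g,
                     dimnames = list(cell_ids, gene_ids))
      active <- module_ids[module_ids %in%
                             c(head(module_ids, config$n_modules_shared),
                               if (is_regen) regen_only)]
      for (m in active) {
        idx <- members_of[[m]]
        a <- factor_cor[idx]
        if (any(is.na(a))) next  # rho = 0: leave members as noise
        l <- loadings[idx]
        sigma_g <- ifelse(a >= 1, 0, l * sqrt(1 - a^2) / a)
        f <- rnorm(n)
        noise <- vapply(sigma_g, function(s) rnorm(n, 0, s), numeric(n))
        expr[, idx] <- 3 + outer(f, l) + noise
      }
      # Background co-expression: genes outside active modules are not
      # independent noise. Most share broad weak latent factors (blocks of
      # 3-25 genes, factor correlation 0.15-0.55); about a quarter sit in
      # small tight blocks (3-12 genes, factor correlation 0.55-0.85)
      # emulating compact housekeeping programs (ribosomal, mitochondrial,
      # cell-cycle). Together they give the network the connectivity
      # continuum real transcriptomes show; tight blocks stay below
      # detectable module size.
      # Inactive planted (regeneration-only) genes stay plain noise in
      # control sections: injury programs are quiescent in uninjured
      # tissue, so they must not co-vary with background structure there.
      bg <- setdiff(which(is.na(membership)), marker_index)
      if (length(bg) > 1 && config$noise_sd > 0) {
        bg <- sample(bg)  # random composition per section
        n_tight <- round(0.25 * length(bg))
        tight <- bg[seq_len(n_tight)]
        broad <- bg[-seq_len(n_tight)]
        # small tight blocks (compact housekeeping-like programs); kept
        # below detectable module size
        p2 <- 1L
        while (p2 <= length(tight)) {
          ws <- min(length(tight) - p2 + 1L, sample(3:12, 1))
          idx <- tight[p2:(p2 + ws - 1L)]
          p2 <- p2 + ws
          f <- rnorm(n)
          a <- runif(length(idx), 0.55, 0.85)
          w <- config$noise_sd * a / sqrt(1 - a^2)
          expr[, idx] <- expr[, idx] + outer(f, w)
        }
        # broad cell-state factors: each remaining gene loads on 1-3 of
        # 10 section-wide factors with right-skewed communality, giving
        # the per-gene connectivity continuum real transcriptomes show
        if (length(broad)) {
          n_broad <- 10L
          FB <- matrix(rnorm(n * n_broad), n, n_broad)
          for (j in broad) {
            h2 <- 0.8 * rbeta(1, 1, 2.5)
            nf <- sample(1:3, 1)
            fs <- sample.int(n_broad, nf)
            share <- as.vector(rmultinom(1, 20, rep(1 / nf, nf))) / 20
            w <- config$noise_sd * sqrt(h2 * share / (1 - h2))
            expr[, j] <- expr[, j] + FB[, fs, drop = FALSE] %*% w
          }
        }
      }
      expr[expr < 0] <- 0

      # marker positivity imposed post hoc so fractions are exact
      n_pos <- round(config$marker_fraction_course[t] * n)
      pos <- if (n_pos > 0) sample(n, n_pos) else integer(0)
      expr[, marker_index] <- 0
      if (n_pos > 0) expr[pos, marker_index] <- 0.5 + abs(rnorm(n_pos))
      marker_positive_cells[[label]] <- sort(cell_ids[pos])

      xy <- centers[match(ct, celltypes), , drop = FALSE] +
        matrix(rnorm(2 * n, 0, 35), n, 2)
      cells <- data.frame(cell_id = cell_ids, celltype = ct,
                          x = xy[, 1], y = xy[, 2],
                          condition = label, stringsAsFactors = FALSE)
      celltype_of_cell <- c(celltype_of_cell, setNames(ct, cell_ids))
      sections[[t]] <- new_expression_section(expr, cells, label, genes_df)
    }

    truth <- structure(list(
      module_membership = setNames(membership, gene_ids),
      regen_only_modules = regen_only,
      marker_gene = "TRH",
      marker_positive_cells = marker_positive_cells,
      celltype_of_cell = celltype_of_cell,
      loadings = setNames(loadings, gene_ids)
    ), class = "synth_truth")

    list(sections = sections, truth = truth)
  })
}

# filled-disk membership on the pixel grid (0-based pixel coordinates)
.disk_mask <- function(width, height, center, radius) {
  xs <- matrix(rep(0:(width - 1), each = height), height, width)
  ys <- matrix(rep(0:(height - 1), times = width), height, width)
  (xs - center[1])^2 + (ys - center[2])^2 <= radius^2
}

#' Generate a paired marker/population image fixture
#'
#' Produces a marker-expression image (signal intensity in the red channel
#' over a faint noisy background), a population image (presence encoded in
#' yellow), and the ground-truth overlap mask of the filled marker and
#' population disks.
#'
#' @param width,height image size in pixels (>= 1).
#' @param marker_blobs list of `list(center = c(x, y), radius, intensity)`
#'   with 0-based pixel-center coordinates and intensity in \[0, 1\].
#' @param population_blobs list of `list(center = c(x, y), radius)`.
#' @param seed integer seed for the background noise.
#' @return List with elements `marker` and `population`
#'   ([new_raster_image()]) and `truth_overlap` ([new_binary_mask()]).
#' @export
generate_coloc_image <- function(width, height, marker_blobs,
                                 population_blobs, seed = 1L) {
  width <- check_count(width, "width")
  height <- check_count(height, "height")
  check_blob <- function(b, need_intensity) {
    if (is.null(b$center) || length(b$center) != 2L || is.null(b$radius)) {
      stop("each blob needs `center` (length 2) and `radius`", call. = FALSE)
    }
    if (b$center[1] - b$radius < 0 || b$center[1] + b$radius > width - 1 ||
        b$center[2] - b$radius < 0 || b$center[2] + b$radius > height - 1) {
      stop("blob extends outside the image bounds", call. = FALSE)
    }
    if (need_intensity) check_fraction(b$intensity %||% 1, "intensity")
    invisible(NULL)
  }
  lapply(marker_blobs, check_blob, need_intensity = TRUE)
  lapply(population_blobs, check_blob, need_intensity = FALSE)

  with_seed(seed, {
    noise <- function() {
      matrix(sample.int(13L, height * width, replace = TRUE) - 1L,
             height, width)
    }
    marker_px <- array(0L, c(height, width, 4L))
    marker_px[, , 1] <- noise(); marker_px[, , 2] <- noise()
    marker_px[, , 3] <- noise(); marker_px[, , 4] <- 255L
    marker_union <- matrix(FALSE, height, width)
    for (b in marker_blobs) {
      d <- .disk_mask(width, height, b$center, b$radius)
      marker_union <- marker_union | d
      val <- as.integer(round(255 * (b$intensity %||% 1)))
      ch <- marker_px[, , 1]
      ch[d] <- pmax(ch[d], val)
      marker_px[, , 1] <- ch
    }

    pop_px <- array(0L, c(height, width, 4L))
    pop_px[, , 1] <- noise(); pop_px[, , 2] <- noise()
    pop_px[, , 3] <- noise(); pop_px[, , 4] <- 255L
    pop_union <- matrix(FALSE, height, width)
    for (b in population_blobs) {
      d <- .disk_mask(width, height, b$center, b$radius)
      pop_union <- pop_union | d
    }
    r <- pop_px[, , 1]; gch <- pop_px[, , 2]; bch <- pop_px[, , 3]
    r[pop_union] <- 255L; gch[pop_union] <- 255L; bch[pop_union] <- 0L
    pop_px[, , 1] <- r; pop_px[, , 2] <- gch; pop_px[, , 3] <- bch

    list(marker = new_raster_image(marker_px),
         population = new_raster_image(pop_px),
         truth_overlap = new_binary_mask(marker_union & pop_union))
  })
}

#' Generate a random module-membership atlas fixture
#'
#' Seed-deterministic gene-to-module assignments per (timepoint, cell-type)
#' context, used as an oracle input for the set-algebra stage. "grey"
#' draws mean the gene is unassigned in that context and are excluded from
#' the atlas.
#'
#' @param n_genes number of genes (ids `g0001`, ...).
#' @param contexts data.frame with columns `timepoint` and `celltype`, or a
#'   list of length-2 character vectors `(timepoint, celltype)`.
#' @param assignment_probabilities named numeric vector of module-label
#'   probabilities (may include `"grey"`), or a list of such vectors, one
#'   per context. Each must sum to 1.
#' @param seed integer RNG seed.
#' @return A `membership_atlas` (see [build_membership_atlas()]).
#' @export
generate_atlas_fixture <- function(n_genes, contexts,
                                   assignment_probabilities, seed = 1L) {
  n_genes <- check_count(n_genes, "n_genes")
  if (is.data.frame(contexts)) {
    ctx <- contexts[, c("timepoint", "celltype")]
  } else if (is.list(contexts) && length(contexts) > 0) {
    ctx <- data.frame(timepoint = vapply(contexts, `[[`, "", 1L),
                      celltype = vapply(contexts, `[[`, "", 2L),
                      stringsAsFactors = FALSE)
  } else {
    stop("`contexts` must be a nonempty list or data.frame", call. = FALSE)
  }
  if (nrow(ctx) == 0) stop("`contexts` must be nonempty", call. = FALSE)
  probs <- if (is.list(assignment_probabilities) &&
               !is.data.frame(assignment_probabilities)) {
    if (length(assignment_probabilities) != nrow(ctx)) {
      stop("one probability vector per context required", call. = FALSE)
    }
    assignment_probabilities
  } else {
    rep(list(assignment_probabilities), nrow(ctx))
  }
  for (p in probs) {
    if (is.null(names(p)) || abs(sum(p) - 1) > 1e-8) {
      stop("assignment probabilities must be named and sum to 1",
           call. = FALSE)
    }
  }
  genes <- sprintf("g%04d", seq_len(n_genes))
  with_seed(seed, {
    rows <- list()
    for (i in seq_len(nrow(ctx))) {
      p <- probs[[i]]
      lab <- sample(names(p), n_genes, replace = TRUE, prob = p)
      keep <- lab != "grey"
      if (any(keep)) {
        rows[[length(rows) + 1L]] <- data.frame(
          gene = genes[keep], timepoint = ctx$timepoint[i],
          celltype = ctx$celltype[i], module = lab[keep],
          stringsAsFactors = FALSE)
      }
    }
    entries <- if (length(rows)) do.call(rbind, rows) else
      data.frame(gene = character(0), timepoint = character(0),
                 celltype = character(0), module = character(0),
                 stringsAsFactors = FALSE)
    tps <- unique(ctx$timepoint)
    classes <- setNames(ifelse(grepl("dpi$", tps, ignore.case = TRUE),
                               "regeneration", "control"), tps)
    new_membership_atlas(entries, classes)
  })
}
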