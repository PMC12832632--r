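# End-to-end orchestration: synthesize (or load) sections, build per
# (cell-type, condition) networks, extract hubs, derive
# regeneration-specific gene sets, measure the marker time course, and
# render a co-localization composite. Reruns with the same config and seed
# reproduce byte-identical TSV outputs.

#' Pipeline configuration
#'
#' All network-stage defaults mirror the field-standard printed parameters:
#' detection fraction 0.05, metacell k = 25 with max_shared 30, candidate
#' powers 1-30 with fit threshold 0.80, 10 hubs per module, PPI score
#' cutoff 0.40.
#'
#' @param out_dir output directory for all written artifacts.
#' @param synth a [synth_config()] describing the synthetic input.
#' @param metacell a [metacell_params()].
#' @param network a [network_params()].
#' @param n_hubs hubs retained per module (default 10).
#' @param ppi_threshold combined-score cutoff for PPI summaries
#'   (default 0.40).
#' @param coloc_rule RGB threshold rule for the image stage.
#' @param coloc_dilate dilation radius in pixels for the image stage.
#' @param seed master seed; stage seeds are derived deterministically.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(out_dir,
                            synth = synth_config(),
                            metacell = metacell_params(),
                            network = network_params(),
                            n_hubs = 10,
                            ppi_threshold = 0.40,
                            coloc_rule = "R>=64,G<=80,B<=80",
                            coloc_dilate = 2,
                            seed = 1L) {
  stopifnot(inherits(synth, "synth_config"),
            inherits(metacell, "metacell_params"),
            inherits(network, "network_params"))
  n_hubs <- check_count(n_hubs, "n_hubs")
  ppi_threshold <- check_fraction(ppi_threshold, "ppi_threshold")
  seed <- check_count(seed, "seed", min = 0L)
  structure(list(out_dir = out_dir, synth = synth, metacell = metacell,
                 network = network, n_hubs = n_hubs,
                 ppi_threshold = ppi_threshold, coloc_rule = coloc_rule,
                 coloc_dilate = coloc_dilate, seed = seed),
            class = "pipeline_config")
}

# stable config hash via a canonical deparse written to a temp file
.config_hash <- function(config) {
  tmp <- tempfile(fileext = ".txt")
  on.exit(unlink(tmp))
  writeLines(deparse(config[setdiff(names(config), "out_dir")]), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full pipeline
#'
#' Stages, per (cell-type, condition) context: detection-fraction gene
#' filter, metacell aggregation and normalization, soft-power selection
#' (contexts with no qualifying power are excluded downstream but
#' recorded), adjacency, TOM, module detection, eigengenes, kME and hub
#' extraction. Afterwards: membership atlas, gene set reports, hub
#' frequency, marker-gene positive-fraction time course, and the
#' image-based co-localization composite.
#'
#' @param config a [pipeline_config()].
#' @return A `run_manifest` list: `config_hash`, `contexts` (per-context
#'   outcome table), `set_sizes`, `n_hub_genes`, `course`, `files`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  files <- character(0)
  synth <- config$synth

  sim <- generate_sections(synth)
  sections <- sim$sections
  truth <- sim$truth

  assignments <- list()
  hub_tables <- list()
  outcome_rows <- list()
  ctx_i <- 0L
  for (label in names(sections)) {
    section <- sections[[label]]
    groups <- sort(unique(section$cells$celltype))
    for (grp in groups) {
      ctx_i <- ctx_i + 1L
      ctx_name <- sprintf("%s@%s", grp, label)
      record <- function(outcome, n_modules = 0L, n_grey = NA_integer_,
                         power = NA_integer_) {
        outcome_rows[[ctx_i]] <<- data.frame(
          context = ctx_name, celltype = grp, condition = label,
          outcome = outcome, power = power, n_modules = n_modules,
          n_grey = n_grey, stringsAsFactors = FALSE)
      }
      genes <- filter_genes_by_fraction(section, grp,
                                        config$network$fraction)
      if (length(genes) < max(10L, config$network$min_module_size)) {
        record("TOO_FEW_GENES")
        next
      }
      mc_params <- metacell_params(k = config$metacell$k,
                                   max_shared = config$metacell$max_shared,
                                   n_components = config$metacell$n_components,
                                   seed = config$seed + ctx_i)
      sub <- new_expression_section(
        section$expr[section$cells$celltype == grp, , drop = FALSE],
        section$cells[section$cells$celltype == grp, , drop = FALSE],
        section$condition, section$genes)
      mc <- withCallingHandlers(
        build_metacells(sub, mc_params, genes = genes),
        warning = function(w) invokeRestart("muffleWarning"))
      if (nrow(mc$values) < 3L) {
        record("TOO_FEW_CELLS")
        next
      }
      mc <- normalize_metacells(mc)
      # constant genes can arise after aggregation; drop them
      keep <- apply(mc$values, 2, sd) > 0
      if (sum(keep) < config$network$min_module_size) {
        record("TOO_FEW_GENES")
        next
      }
      expr <- mc$values[, keep, drop = FALSE]
      sel <- select_soft_power(expr, config$network)
      if (sel$excluded) {
        record("EXCLUDED")
        next
      }
      adj <- compute_adjacency(expr, sel$power, config$network$network_type)
      tom <- compute_tom(adj)
      modules <- detect_modules(tom, config$network, expr = expr,
                                context = list(celltype = grp,
                                               condition = label))
      n_mod <- length(setdiff(unique(modules$labels), "grey"))
      n_grey <- sum(modules$labels == "grey")
      if (n_mod == 0) {
        record("ALL_GREY", 0L, n_grey, sel$power)
        next
      }
      eig <- compute_eigengenes(expr, modules)
      kme <- compute_kme(expr, eig)
      hubs <- extract_hubs(kme, modules, config$n_hubs)
      assignments[[ctx_name]] <- modules
      hub_tables[[ctx_name]] <- hubs
      record("OK", n_mod, n_grey, sel$power)
    }
  }
  outcomes <- do.call(rbind, outcome_rows)

  condition_classes <- setNames(synth$condition_class,
                                synth$timepoint_labels)
  atlas <- if (length(assignments)) {
    build_membership_atlas(assignments, condition_classes)
  } else {
    new_membership_atlas(data.frame(gene = character(0),
                                    timepoint = character(0),
                                    celltype = character(0),
                                    module = character(0)),
                         condition_classes)
  }
  p <- file.path(out_dir, "membership_atlas.tsv")
  write_tsv_file(atlas$entries, p); files <- c(files, p)

  sets <- if (nrow(atlas$entries) > 0 &&
              any(condition_classes[unique(atlas$entries$timepoint)] ==
                    "regeneration")) {
    withCallingHandlers(derive_gene_sets(atlas),
                        warning = function(w) invokeRestart("muffleWarning"))
  } else {
    structure(list(all_regen = character(0), all_control = character(0),
                   shared_all_stages = character(0),
                   regen_specific = character(0), amex_genes = character(0),
                   ortholog_genes = character(0)),
              class = "gene_set_report")
  }
  set_paths <- write_gene_set_report(sets, file.path(out_dir, "gene_sets"))
  files <- c(files, unname(set_paths))

  all_hubs <- if (length(hub_tables)) {
    do.call(rbind, lapply(hub_tables, as.data.frame))
  } else {
    data.frame(gene = character(0), celltype = character(0),
               condition = character(0), module = character(0),
               rank = integer(0), kme = numeric(0))
  }
  rownames(all_hubs) <- NULL
  p <- file.path(out_dir, "hub_table.tsv")
  write_tsv_file(all_hubs, p); files <- c(files, p)
  freq <- if (length(hub_tables)) hub_frequency(hub_tables) else
    data.frame(gene = character(0), hub_occurrences = integer(0),
               occurrences = character(0), best_rank = integer(0))
  p <- file.path(out_dir, "hub_frequency.tsv")
  write_tsv_file(as.data.frame(freq), p); files <- c(files, p)

  course <- positive_fraction_course(sections, truth$marker_gene)
  p <- file.path(out_dir, "marker_course.tsv")
  write_tsv_file(course, p); files <- c(files, p)

  # image-route co-localization on a generated fixture
  fix <- generate_coloc_image(
    width = 120, height = 120,
    marker_blobs = list(list(center = c(45, 60), radius = 25,
                             intensity = 0.9)),
    population_blobs = list(list(center = c(70, 60), radius = 25)),
    seed = config$seed)
  marker_mask <- threshold_rgb(fix$marker, config$coloc_rule)
  marker_mask <- dilate(marker_mask, config$coloc_dilate)
  pop_mask <- threshold_rgb(fix$population,
                            "R>=200,G>=200,B<=80")
  comp <- compose(fix$marker, marker_mask, pop_mask)
  p <- file.path(out_dir, "coloc_composite.png")
  write_png_raster(comp$image, p, dpi = 300); files <- c(files, p)
  coloc_df <- data.frame(marker_pixels = comp$result$marker_pixels,
                         population_pixels = comp$result$population_pixels,
                         overlap_pixels = comp$result$overlap_pixels,
                         overlap_fraction_of_marker =
                           comp$result$overlap_fraction_of_marker)
  p <- file.path(out_dir, "coloc_report.tsv")
  write_tsv_file(coloc_df, p); files <- c(files, p)

  p <- file.path(out_dir, "context_outcomes.tsv")
  write_tsv_file(outcomes, p); files <- c(files, p)

  manifest <- structure(list(
    config_hash = .config_hash(config),
    contexts = outcomes,
    set_sizes = vapply(sets, length, integer(1)),
    n_hub_genes = length(unique(all_hubs$gene)),
    course = course,
    truth = truth,
    files = sort(files)
  ), class = "run_manifest")
  p <- file.path(out_dir, "manifest.tsv")
  write_tsv_file(data.frame(key = c("config_hash", "n_contexts_ok",
                                    "n_contexts_excluded", "n_hub_genes",
                                    names(manifest$set_sizes)),
                            value = c(manifest$config_hash,
                                      sum(outcomes$outcome == "OK"),
                                      sum(outcomes$outcome == "EXCLUDED"),
                                      manifest$n_hub_genes,
                                      unname(manifest$set_sizes))),
                 p)
  manifest$files <- sort(c(manifest$files, p))
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("<run_manifest> %s\n", x$config_hash))
  cat(sprintf("  contexts: %d ok, %d excluded, %d other\n",
              sum(x$contexts$outcome == "OK"),
              sum(x$contexts$outcome == "EXCLUDED"),
              sum(!x$contexts$outcome %in% c("OK", "EXCLUDED"))))
  cat(sprintf("  regeneration-specific genes: %d (%d AMEX, %d ortholog); hub genes: %d\n",
              x$set_sizes[["regen_specific"]], x$set_sizes[["amex_genes"]],
              x$set_sizes[["ortholog_genes"]], x$n_hub_genes))
  invisible(x)
}
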