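# Gene x context module-membership atlas and the set algebra that
# isolates regeneration-restricted gene programs; identifier handling for
# the mixed namespace (species-specific "AMEX60DD_" ids vs ortholog
# symbols, raw pipe-delimited names); STRING-style PPI edge table
# summaries.

#' Create a module-membership atlas
#'
#' @param entries data.frame with columns `gene`, `timepoint`, `celltype`,
#'   `module`; grey entries are excluded; `(gene, timepoint, celltype)`
#'   must be unique.
#' @param condition_class named character vector mapping each timepoint to
#'   `"control"` or `"regeneration"`.
#' @return A `membership_atlas` object.
#' @export
new_membership_atlas <- function(entries, condition_class) {
  req <- c("gene", "timepoint", "celltype", "module")
  if (!is.data.frame(entries) || !all(req %in% names(entries))) {
    stop("`entries` must have columns gene, timepoint, celltype, module",
         call. = FALSE)
  }
  entries <- entries[, req]
  entries <- entries[entries$module != "grey", , drop = FALSE]
  key <- paste(entries$gene, entries$timepoint, entries$celltype, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (gene, timepoint, celltype) entries in atlas",
         call. = FALSE)
  }
  tps <- unique(entries$timepoint)
  unmapped <- setdiff(tps, names(condition_class))
  if (length(unmapped)) {
    stop("timepoints without a condition class: ",
         paste(unmapped, collapse = ", "), call. = FALSE)
  }
  if (!all(condition_class %in% c("control", "regeneration"))) {
    stop("condition classes must be 'control' or 'regeneration'",
         call. = FALSE)
  }
  rownames(entries) <- NULL
  structure(list(entries = entries, condition_class = condition_class),
            class = "membership_atlas")
}

#' @export
print.membership_atlas <- function(x, ...) {
  cat(sprintf("<membership_atlas> %d entries, %d genes, %d timepoints (%d regeneration)\n",
              nrow(x$entries), length(unique(x$entries$gene)),
              length(unique(x$entries$timepoint)),
              sum(x$condition_class[unique(x$entries$timepoint)] ==
                    "regeneration")))
  invisible(x)
}

#' Build a membership atlas from per-context module assignments
#'
#' Grey-labelled genes are dropped; each assignment contributes one entry
#' per module-assigned gene under its (timepoint, cell-type) context.
#'
#' @param assignments list of [detect_modules()] results, each carrying a
#'   `context` with `celltype` and `condition` (the condition doubles as
#'   the timepoint label).
#' @param condition_classes named character vector mapping every
#'   represented timepoint to `"control"` or `"regeneration"`.
#' @return A [new_membership_atlas()].
#' @export
build_membership_atlas <- function(assignments, condition_classes) {
  if (inherits(assignments, "module_assignment")) {
    assignments <- list(assignments)
  }
  rows <- lapply(assignments, function(a) {
    stopifnot(inherits(a, "module_assignment"))
    if (is.null(a$context) || is.null(a$context$condition) ||
        is.null(a$context$celltype)) {
      stop("every assignment must carry a (celltype, condition) context",
           call. = FALSE)
    }
    keep <- a$labels != "grey"
    if (!any(keep)) return(NULL)
    data.frame(gene = names(a$labels)[keep],
               timepoint = a$context$condition,
               celltype = a$context$celltype,
               module = unname(a$labels[keep]), stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  entries <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(0), timepoint = character(0),
               celltype = character(0), module = character(0),
               stringsAsFactors = FALSE)
  new_membership_atlas(entries, condition_classes)
}

#' Derive shared and regeneration-specific gene sets
#'
#' A gene is "present" at a timepoint if it belongs to any cell-type's
#' module there. The report contains: `all_regen` (present in at least one
#' regeneration context), `all_control` (present in at least one control
#' context), `shared_all_stages` (present at every regeneration timepoint
#' represented in the atlas), `regen_specific`
#' (`all_regen` minus `all_control`), and its partition into `amex_genes`
#' and `ortholog_genes` by identifier prefix. All sets are sorted.
#'
#' @param atlas a [new_membership_atlas()] with at least one regeneration
#'   timepoint.
#' @return A `gene_set_report` list.
#' @export
derive_gene_sets <- function(atlas) {
  stopifnot(inherits(atlas, "membership_atlas"))
  e <- atlas$entries
  cls <- atlas$condition_class
  tps <- unique(e$timepoint)
  regen_tps <- tps[cls[tps] == "regeneration"]
  control_tps <- tps[cls[tps] == "control"]
  if (length(regen_tps) == 0) {
    stop("atlas has no regeneration timepoints", call. = FALSE)
  }
  present_at <- lapply(setNames(tps, tps),
                       function(tp) unique(e$gene[e$timepoint == tp]))
  all_regen <- sort(unique(unlist(present_at[regen_tps])))
  all_control <- sort(unique(unlist(present_at[control_tps])))
  if (length(control_tps) == 0) {
    warning("no control contexts in atlas: regen_specific equals all_regen",
            call. = FALSE)
  }
  shared_all_stages <- sort(Reduce(intersect, present_at[regen_tps]))
  regen_specific <- setdiff(all_regen, all_control)
  parts <- partition_by_prefix(regen_specific)
  structure(list(all_regen = all_regen, all_control = all_control,
                 shared_all_stages = shared_all_stages,
                 regen_specific = regen_specific,
                 amex_genes = parts$amex, ortholog_genes = parts$ortholog),
            class = "gene_set_report")
}

#' @export
print.gene_set_report <- function(x, ...) {
  cat(sprintf(paste0("<gene_set_report> regen: %d, control: %d, ",
                     "shared all stages: %d, regeneration-specific: %d ",
                     "(%d AMEX + %d ortholog)\n"),
              length(x$all_regen), length(x$all_control),
              length(x$shared_all_stages), length(x$regen_specific),
              length(x$amex_genes), length(x$ortholog_genes)))
  invisible(x)
}

#' Partition gene ids by species-specific prefix
#'
#' @param genes character vector of gene ids.
#' @param prefix identifier prefix marking species-specific (non-ortholog)
#'   genes (default `"AMEX60DD"`); matching is case-sensitive.
#' @return List with `amex` (prefix-matched) and `ortholog` (the rest),
#'   both preserving input order.
#' @export
partition_by_prefix <- function(genes, prefix = "AMEX60DD") {
  genes <- as.character(genes)
  is_amex <- startsWith(genes, prefix)
  list(amex = genes[is_amex], ortholog = genes[!is_amex])
}

#' Standardize raw gene names to symbols
#'
#' Raw names may be pipe-delimited (`"TRH | TRH_XENLA"`); the first
#' nonempty field is taken, whitespace is stripped, a trailing
#' `_<TAXON>` suffix is removed when the suffix is fully alphabetic and
#' uppercase, and the result is uppercased. Empty raw names are recorded
#' as `NA` (with a warning), never dropped silently.
#'
#' @param raw character vector of raw gene names.
#' @return Character vector of standardized symbols, same length as `raw`.
#' @export
standardize_symbols <- function(raw) {
  raw <- as.character(raw)
  out <- vapply(raw, function(r) {
    if (is.na(r)) return(NA_character_)
    fields <- trimws(strsplit(r, "|", fixed = TRUE)[[1]])
    fields <- fields[nzchar(fields)]
    if (length(fields) == 0) return(NA_character_)
    sym <- sub("_[A-Z]+$", "", fields[1])
    toupper(sym)
  }, character(1), USE.NAMES = FALSE)
  n_missing <- sum(is.na(out))
  if (n_missing > 0) {
    warning(sprintf("%d empty raw name(s) recorded as NA", n_missing),
            call. = FALSE)
  }
  out
}

#' Summarize a STRING-style PPI edge table
#'
#' Reads an exported edge table (columns `node1`, `node2`,
#' `combined_score`; the 0-999 score dialect is detected and divided by
#' 1000), retains edges with combined score at or above `threshold`,
#' deduplicates undirected pairs keeping the maximum score, and classifies
#' nodes by degree: high connectivity (> 10 interactions) and low
#' connectivity (1-3 interactions).
#'
#' @param edge_table path to a TSV file or a data.frame.
#' @param threshold minimum retained combined score (default 0.40,
#'   inclusive).
#' @return A `ppi_summary` list: `edges` (protein_a, protein_b, score),
#'   `degree`, `n_nodes`, `n_edges`, `high_connectivity`,
#'   `low_connectivity`, `threshold`.
#' @export
summarize_ppi <- function(edge_table, threshold = 0.40) {
  threshold <- check_fraction(threshold, "threshold")
  if (is.character(edge_table)) {
    df <- read.delim(edge_table, stringsAsFactors = FALSE)
  } else if (is.data.frame(edge_table)) {
    df <- edge_table
  } else {
    stop("`edge_table` must be a file path or data.frame", call. = FALSE)
  }
  cols <- tolower(names(df))
  pick <- function(candidates, fallback) {
    hit <- which(cols %in% candidates)
    if (length(hit)) hit[1] else fallback
  }
  i1 <- pick(c("node1", "protein1", "protein_a"), 1L)
  i2 <- pick(c("node2", "protein2", "protein_b"), 2L)
  is <- pick(c("combined_score", "score"), 3L)
  if (ncol(df) < max(i1, i2, is)) {
    stop("edge table needs two protein columns and a combined score",
         call. = FALSE)
  }
  a <- as.character(df[[i1]])
  b <- as.character(df[[i2]])
  s <- suppressWarnings(as.numeric(df[[is]]))
  bad <- which(is.na(a) | is.na(b) | !nzchar(a) | !nzchar(b) | is.na(s))
  if (length(bad)) {
    stop(sprintf("malformed edge table row(s): %s",
                 paste(head(bad, 5), collapse = ", ")), call. = FALSE)
  }
  if (any(s > 1)) s <- s / 1000   # STRING 0-999 integer dialect
  self <- a == b
  if (any(self)) {
    warning(sprintf("dropping %d self-edge(s)", sum(self)), call. = FALSE)
    a <- a[!self]; b <- b[!self]; s <- s[!self]
  }
  keep <- s >= threshold
  a <- a[keep]; b <- b[keep]; s <- s[keep]
  pa <- pmin(a, b); pb <- pmax(a, b)
  key <- paste(pa, pb, sep = "\r")
  if (length(key)) {
    best <- tapply(s, key, max)
    first <- !duplicated(key)
    edges <- data.frame(protein_a = pa[first], protein_b = pb[first],
                        score = unname(best[key[first]]),
                        stringsAsFactors = FALSE)
    edges <- edges[order(edges$protein_a, edges$protein_b), ]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(protein_a = character(0), protein_b = character(0),
                        score = numeric(0), stringsAsFactors = FALSE)
  }
  degree <- table(c(edges$protein_a, edges$protein_b))
  degree <- setNames(as.integer(degree), names(degree))
  structure(list(edges = edges, degree = degree,
                 n_nodes = length(degree), n_edges = nrow(edges),
                 high_connectivity = sort(names(degree)[degree > 10]),
                 low_connectivity = sort(names(degree)[degree >= 1 &
                                                         degree <= 3]),
                 threshold = threshold),
            class = "ppi_summary")
}

#' @export
print.ppi_summary <- function(x, ...) {
  cat(sprintf("<ppi_summary> %d nodes, %d edges (score >= %.2f); %d high- and %d low-connectivity nodes\n",
              x$n_nodes, x$n_edges, x$threshold,
              length(x$high_connectivity), length(x$low_connectivity)))
  invisible(x)
}

#' Write a gene set report as TSV files
#'
#' Emits one single-column TSV per set (`all_regen`, `all_control`,
#' `shared_all_stages`, `regen_specific`, `amex_genes`, `ortholog_genes`).
#'
#' @param report a [derive_gene_sets()] result.
#' @param dir output directory (created if absent).
#' @return Named character vector of written paths, invisibly.
#' @export
write_gene_set_report <- function(report, dir) {
  stopifnot(inherits(report, "gene_set_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sets <- c("all_regen", "all_control", "shared_all_stages",
            "regen_specific", "amex_genes", "ortholog_genes")
  paths <- setNames(file.path(dir, paste0(sets, ".tsv")), sets)
  for (s in sets) {
    write_tsv_file(data.frame(gene = report[[s]]), paths[[s]])
  }
  invisible(paths)
}
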