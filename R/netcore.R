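# Weighted co-expression network construction for one
# (cell-type, condition) context: gene detection filter, soft-power
# selection by scale-free topology fit, adjacency, topological overlap,
# and deterministic module detection.

#' Network construction parameters
#'
#' @param fraction detection threshold: a gene must be expressed (nonzero)
#'   in at least this fraction of a group's cells to enter the network
#'   (default 0.05).
#' @param power_candidates ordered candidate soft-threshold powers
#'   (default `1:30`).
#' @param r2_threshold required scale-free topology fit index
#'   (default 0.80).
#' @param network_type `"signed"` (default) or `"unsigned"` adjacency.
#' @param min_module_size smallest allowed module at detection time
#'   (default 30); smaller clusters are sent to "grey".
#' @param merge_cut eigengene-dissimilarity threshold below which modules
#'   are merged (default 0.25, i.e. merge when eigengene correlation
#'   is at least 0.75).
#' @param min_kme membership floor: after detection, module members whose
#'   own-module kME falls below this are reassigned to "grey"
#'   (default 0.50; chosen above the null-correlation scale of aggregated,
#'   partially overlapping metacells); applied only when
#'   expression is available.
#' @param n_bins connectivity histogram bins for the scale-free fit
#'   (default 10).
#' @param deep_split integer 0..4 controlling how aggressively dendrogram
#'   branches are split (default 2; larger splits more).
#' @return A `network_params` object.
#' @export
network_params <- function(fraction = 0.05, power_candidates = 1:30,
                           r2_threshold = 0.80,
                           network_type = c("signed", "unsigned"),
                           min_module_size = 30, merge_cut = 0.25,
                           min_kme = 0.50, n_bins = 10, deep_split = 2) {
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction >= 1) {
    stop("`fraction` must lie in (0, 1)", call. = FALSE)
  }
  power_candidates <- as.integer(power_candidates)
  if (length(power_candidates) < 1L || any(power_candidates <= 0) ||
      any(diff(power_candidates) <= 0)) {
    stop("`power_candidates` must be strictly increasing positive integers",
         call. = FALSE)
  }
  if (!is.numeric(r2_threshold) || length(r2_threshold) != 1L ||
      r2_threshold <= 0) {
    stop("`r2_threshold` must be positive", call. = FALSE)
  }
  # values above 1 are permitted: the signed fit index never exceeds 1, so
  # such a threshold deliberately excludes every context
  network_type <- match.arg(network_type)
  min_module_size <- check_count(min_module_size, "min_module_size")
  if (!is.numeric(merge_cut) || length(merge_cut) != 1L ||
      merge_cut < 0 || merge_cut > 1) {
    stop("`merge_cut` must lie in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(min_kme) || length(min_kme) != 1L ||
      min_kme < 0 || min_kme >= 1) {
    stop("`min_kme` must lie in [0, 1)", call. = FALSE)
  }
  n_bins <- check_count(n_bins, "n_bins", min = 2L)
  deep_split <- check_count(deep_split, "deep_split", min = 0L)
  if (deep_split > 4L) stop("`deep_split` must be in 0..4", call. = FALSE)
  structure(list(fraction = fraction, power_candidates = power_candidates,
                 r2_threshold = r2_threshold, network_type = network_type,
                 min_module_size = min_module_size, merge_cut = merge_cut,
                 min_kme = min_kme, n_bins = n_bins, deep_split = deep_split),
            class = "network_params")
}

# accept a metacell_matrix, expression_section, or plain sample x gene
# matrix and return the numeric matrix
.expr_values <- function(x) {
  if (inherits(x, "metacell_matrix")) return(x$values)
  if (inherits(x, "expression_section")) return(x$expr)
  if (is.matrix(x)) return(x)
  stop("expected a metacell_matrix, expression_section, or matrix",
       call. = FALSE)
}

#' Filter genes by detection fraction within a group
#'
#' A gene is retained only if it has nonzero expression in at least
#' `fraction` of the group's cells (boundary inclusive). Gene order is
#' preserved from the input.
#'
#' @param x an [new_expression_section()] or [new_metacell_matrix()].
#' @param group annotation label; rows of `x` belonging to this group form
#'   the denominator.
#' @param fraction detection threshold in (0, 1).
#' @return Character vector of retained gene ids.
#' @export
filter_genes_by_fraction <- function(x, group, fraction = 0.05) {
  fraction <- check_fraction(fraction, "fraction")
  if (inherits(x, "expression_section")) {
    rows <- which(x$cells$celltype == group)
    values <- x$expr
  } else if (inherits(x, "metacell_matrix")) {
    rows <- which(x$group == group)
    values <- x$values
  } else {
    stop("`x` must be an expression_section or metacell_matrix",
         call. = FALSE)
  }
  if (length(rows) == 0) {
    stop(sprintf("group '%s' is empty or absent", group), call. = FALSE)
  }
  det <- colMeans(values[rows, , drop = FALSE] != 0)
  colnames(values)[det >= fraction]
}

.check_constant_genes <- function(values) {
  sds <- apply(values, 2, sd)
  bad <- colnames(values)[sds == 0 | is.na(sds)]
  if (length(bad)) {
    stop("constant gene(s) not allowed in network construction: ",
         paste(head(bad, 5), collapse = ", "),
         if (length(bad) > 5) sprintf(" (+%d more)", length(bad) - 5),
         call. = FALSE)
  }
  invisible(NULL)
}

.adjacency_from_cor <- function(C, power, network_type) {
  A <- if (network_type == "signed") ((1 + C) / 2)^power else abs(C)^power
  diag(A) <- 1
  A
}

#' Compute the soft-thresholded adjacency matrix
#'
#' Signed networks use `a_ij = ((1 + cor(x_i, x_j)) / 2)^power`; unsigned
#' use `a_ij = |cor(x_i, x_j)|^power`, with Pearson correlation taken over
#' samples (metacells). The diagonal is forced to 1.
#'
#' @param expr a [new_metacell_matrix()] or plain sample x gene matrix with
#'   at least 3 samples and 2 non-constant genes.
#' @param power soft-threshold exponent (beta).
#' @param network_type `"signed"` or `"unsigned"`.
#' @return An `adjacency_matrix` object with fields `values`, `power`,
#'   `network_type`.
#' @export
compute_adjacency <- function(expr, power,
                              network_type = c("signed", "unsigned")) {
  network_type <- match.arg(network_type)
  values <- .expr_values(expr)
  if (nrow(values) < 3L) stop("need at least 3 samples", call. = FALSE)
  if (ncol(values) < 2L) stop("need at least 2 genes", call. = FALSE)
  if (!is.numeric(power) || length(power) != 1L || power <= 0) {
    stop("`power` must be a single positive number", call. = FALSE)
  }
  .check_constant_genes(values)
  C <- cor(values)
  structure(list(values = .adjacency_from_cor(C, power, network_type),
                 power = power, network_type = network_type),
            class = "adjacency_matrix")
}

#' Scale-free topology fit of a network's degree distribution
#'
#' Connectivity `k_i = sum_{j != i} a_ij` is binned into `n_bins`
#' equal-width bins; the log10 mean frequency per nonempty bin is
#' regressed on the log10 mean connectivity per bin. The signed fit index
#' is `-sign(slope) * R^2`, so decreasing (scale-free-like) degree laws
#' score positively and increasing ones negatively.
#'
#' @param adj an [compute_adjacency()] result.
#' @param n_bins number of connectivity bins (default 10).
#' @return A `scale_free_fit` object: `r_squared` (signed), `slope`,
#'   `mean_connectivity`, `connectivity`, `n_bins_used`.
#' @export
scale_free_fit <- function(adj, n_bins = 10) {
  stopifnot(inherits(adj, "adjacency_matrix"))
  n_bins <- check_count(n_bins, "n_bins", min = 2L)
  A <- adj$values
  diag(A) <- 0
  k <- rowSums(A)
  if (diff(range(k)) == 0) {
    stop("fewer than 2 nonempty connectivity bins (all k equal)",
         call. = FALSE)
  }
  breaks <- seq(min(k), max(k), length.out = n_bins + 1L)
  bin <- cut(k, breaks = breaks, include.lowest = TRUE)
  counts <- tabulate(bin, nbins = n_bins)
  nonempty <- counts > 0
  if (sum(nonempty) < 2L) {
    stop("fewer than 2 nonempty connectivity bins", call. = FALSE)
  }
  freq <- counts[nonempty] / length(k)
  kmean <- tapply(k, bin, mean)[nonempty]
  fit <- lm(log10(freq) ~ log10(kmean))
  slope <- unname(coef(fit)[2])
  r2 <- summary(fit)$r.squared
  structure(list(r_squared = if (slope == 0) 0 else -sign(slope) * r2,
                 slope = slope, mean_connectivity = mean(k),
                 connectivity = k, n_bins_used = sum(nonempty)),
            class = "scale_free_fit")
}

#' Select the soft-threshold power by scale-free fit
#'
#' Candidate powers are evaluated in increasing order; the selection is the
#' lowest power whose signed scale-free fit index reaches
#' `params$r2_threshold`. When no candidate qualifies, the context is
#' marked excluded from downstream network analysis (a distinguished
#' outcome, not an error).
#'
#' @param expr a [new_metacell_matrix()] or sample x gene matrix.
#' @param params a [network_params()].
#' @return A `power_selection` object: `power` (integer or `NA` when
#'   excluded), `excluded` (logical), and `fits` (a data.frame with one row
#'   per candidate: power, r_squared, slope, mean_connectivity).
#' @export
select_soft_power <- function(expr, params = network_params()) {
  stopifnot(inherits(params, "network_params"))
  values <- .expr_values(expr)
  if (nrow(values) < 3L) stop("need at least 3 samples", call. = FALSE)
  .check_constant_genes(values)
  C <- cor(values)
  fits <- data.frame(power = params$power_candidates,
                     r_squared = NA_real_, slope = NA_real_,
                     mean_connectivity = NA_real_)
  for (i in seq_along(params$power_candidates)) {
    p <- params$power_candidates[i]
    adj <- structure(list(values = .adjacency_from_cor(C, p,
                                                       params$network_type),
                          power = p, network_type = params$network_type),
                     class = "adjacency_matrix")
    sf <- tryCatch(scale_free_fit(adj, params$n_bins),
                   error = function(e) NULL)
    if (!is.null(sf)) {
      fits$r_squared[i] <- sf$r_squared
      fits$slope[i] <- sf$slope
      fits$mean_connectivity[i] <- sf$mean_connectivity
    }
  }
  qualifying <- which(!is.na(fits$r_squared) &
                        fits$r_squared >= params$r2_threshold)
  if (length(qualifying)) {
    structure(list(power = fits$power[qualifying[1]], excluded = FALSE,
                   fits = fits), class = "power_selection")
  } else {
    structure(list(power = NA_integer_, excluded = TRUE, fits = fits),
              class = "power_selection")
  }
}

#' @export
print.power_selection <- function(x, ...) {
  if (x$excluded) {
    cat("<power_selection> EXCLUDED: no candidate power reached the fit threshold\n")
  } else {
    cat(sprintf("<power_selection> beta = %d\n", x$power))
  }
  invisible(x)
}

#' Compute the topological overlap matrix (TOM)
#'
#' `TOM_ij = (sum_{u != i,j} a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)`
#' for `i != j`, with `k_i = sum_{u != i} a_iu`; the diagonal is 1.
#'
#' @param adj an [compute_adjacency()] result.
#' @return A `tom_matrix` object with field `values`.
#' @export
compute_tom <- function(adj) {
  stopifnot(inherits(adj, "adjacency_matrix"))
  A <- adj$values
  if (any(A < 0) || any(A > 1)) {
    stop("adjacency entries must lie in [0, 1]", call. = FALSE)
  }
  A0 <- A
  diag(A0) <- 0
  k <- rowSums(A0)
  shared <- A0 %*% A0                 # sum_u a_iu a_uj with u != i, j
  numer <- shared + A0
  denom <- outer(k, k, pmin) + 1 - A0
  if (any(denom <= 0)) {
    stop("internal error: non-positive TOM denominator", call. = FALSE)
  }
  tom <- numer / denom
  diag(tom) <- 1
  tom <- (tom + t(tom)) / 2           # enforce exact symmetry
  dimnames(tom) <- dimnames(A)
  structure(list(values = tom), class = "tom_matrix")
}

# Recursive dendrogram cutting: descend while a node is above the static
# cut height or separated from its children by a large height gap; nodes
# where recursion stops become clusters.
.cut_tree_gaps <- function(dend, cut_height, gap_threshold) {
  clusters <- list()
  recurse <- function(node) {
    if (is.leaf(node)) {
      clusters[[length(clusters) + 1L]] <<- as.integer(attr(node, "label"))
      return(invisible(NULL))
    }
    h <- attr(node, "height")
    child_h <- vapply(seq_along(node), function(i) {
      if (is.leaf(node[[i]])) 0 else attr(node[[i]], "height")
    }, numeric(1))
    gap <- h - max(child_h)
    if (h > cut_height || gap > gap_threshold) {
      for (i in seq_along(node)) recurse(node[[i]])
    } else {
      leaves <- as.integer(labels(node))
      clusters[[length(clusters) + 1L]] <<- leaves
    }
    invisible(NULL)
  }
  recurse(dend)
  clusters
}

# deterministic module labels: by descending size, ties broken by the
# lexicographically smallest member gene id
.label_modules <- function(member_sets, genes) {
  if (length(member_sets) == 0) return(setNames(rep("grey", length(genes)), genes))
  sizes <- vapply(member_sets, length, integer(1))
  firsts <- vapply(member_sets, function(s) min(genes[s]), character(1))
  ord <- order(-sizes, firsts)
  labels <- setNames(rep("grey", length(genes)), genes)
  for (j in seq_along(ord)) {
    labels[genes[member_sets[[ord[j]]]]] <- sprintf("M%d", j)
  }
  labels
}

#' Detect co-expression modules from a TOM
#'
#' Average-linkage hierarchical clustering of the dissimilarity `1 - TOM`,
#' cut by a deterministic adaptive procedure: a static cut at
#' dissimilarity 0.99 combined with recursive splitting of branches whose
#' height gap to their children exceeds a `deep_split`-controlled
#' threshold. Clusters smaller than `min_module_size` are assigned to
#' "grey". When `expr` is supplied, modules whose eigengenes correlate at
#' `>= 1 - merge_cut` are merged. Final labels are `"M1"`, `"M2"`, ...
#' ordered by descending module size (ties broken by the smallest member
#' gene id); an all-grey outcome is valid.
#'
#' @param tom a [compute_tom()] result.
#' @param params a [network_params()].
#' @param expr optional sample x gene matrix (or metacell matrix) used for
#'   the eigengene-based merge step; when omitted, merging is skipped.
#' @param context optional `list(celltype =, condition =)` recorded in the
#'   assignment.
#' @return A `module_assignment` object: `labels` (named gene -> module
#'   character vector, "grey" for unassigned) and `context`.
#' @export
detect_modules <- function(tom, params = network_params(), expr = NULL,
                           context = NULL) {
  stopifnot(inherits(tom, "tom_matrix"), inherits(params, "network_params"))
  V <- tom$values
  genes <- colnames(V) %||% sprintf("gene%d", seq_len(ncol(V)))
  n <- ncol(V)
  if (n < 2L) {
    return(structure(list(labels = setNames(rep("grey", n), genes),
                          context = context), class = "module_assignment"))
  }
  d <- as.dist(1 - V)
  h <- hclust(d, method = "average")
  dend <- as.dendrogram(h)
  # leaves must be identifiable by position in the original ordering
  dend <- stats::dendrapply(dend, function(nd) {
    if (is.leaf(nd)) attr(nd, "label") <- as.character(nd[1])
    nd
  })
  # static cut at 99% of the top merge height (the conventional cut for
  # 1 - TOM dendrograms, whose spurious merges crowd toward the top):
  # branches joining above it are separated, and the gap rule below splits
  # well-separated sub-branches that happen to join lower down; a
  # degenerate tree (all merges at one height) stays a single cluster
  h_range <- diff(range(h$height))
  cut_height <- if (h_range < 1e-10) max(h$height) else
    0.99 * max(h$height)
  gap_threshold <- (0.25 - 0.05 * params$deep_split) * max(h_range, 1e-12)
  clusters <- .cut_tree_gaps(dend, cut_height, gap_threshold)
  keep <- clusters[vapply(clusters, length, integer(1)) >=
                     params$min_module_size]
  labels <- .label_modules(keep, genes)

  if (!is.null(expr) && length(keep) >= 1L) {
    values <- .expr_values(expr)
    if (length(keep) >= 2L && params$merge_cut > 0) {
      labels <- .merge_close_modules(values, labels, params$merge_cut)
    }
    if (params$min_kme > 0 && any(labels != "grey")) {
      labels <- .apply_kme_floor(values, labels, params$min_kme)
    }
  }
  structure(list(labels = labels, context = context),
            class = "module_assignment")
}

# iteratively merge the most correlated eigengene pair until none reach
# the merge threshold, then relabel deterministically
.merge_close_modules <- function(values, labels, merge_cut) {
  repeat {
    mods <- setdiff(unique(labels), "grey")
    if (length(mods) < 2L) break
    eig <- tryCatch(
      compute_eigengenes(values,
                         structure(list(labels = labels, context = NULL),
                                   class = "module_assignment")),
      error = function(e) NULL)
    if (is.null(eig)) break
    C <- cor(eig$values)
    diag(C) <- -Inf
    best <- which(C == max(C), arr.ind = TRUE)[1, ]
    if (C[best[1], best[2]] < 1 - merge_cut) break
    a <- colnames(C)[best[1]]; b <- colnames(C)[best[2]]
    labels[labels == b] <- a
  }
  genes <- names(labels)
  member_sets <- lapply(setdiff(unique(labels), "grey"),
                        function(m) which(labels == m))
  .label_modules(member_sets, genes)
}

# send module members with own-module kME below the floor to grey, then
# relabel deterministically
.apply_kme_floor <- function(values, labels, min_kme) {
  assignment <- structure(list(labels = labels, context = NULL),
                          class = "module_assignment")
  eig <- tryCatch(compute_eigengenes(values, assignment),
                  error = function(e) NULL)
  if (is.null(eig)) return(labels)
  for (m in colnames(eig$values)) {
    members <- names(labels)[labels == m]
    kme <- suppressWarnings(
      as.vector(cor(values[, members, drop = FALSE], eig$values[, m])))
    drop <- members[is.na(kme) | kme < min_kme]
    labels[drop] <- "grey"
  }
  genes <- names(labels)
  member_sets <- lapply(setdiff(unique(labels), "grey"),
                        function(m) which(labels == m))
  member_sets <- member_sets[vapply(member_sets, length, integer(1)) > 0]
  .label_modules(member_sets, genes)
}

#' @export
print.module_assignment <- function(x, ...) {
  tab <- table(x$labels)
  ctx <- if (is.null(x$context)) "" else
    sprintf(" [%s @ %s]", x$context$celltype %||% "?",
            x$context$condition %||% "?")
  cat(sprintf("<module_assignment>%s %d genes, %d modules, %d grey\n",
              ctx, length(x$labels),
              length(setdiff(names(tab), "grey")),
              if ("grey" %in% names(tab)) tab[["grey"]] else 0L))
  invisible(x)
}
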