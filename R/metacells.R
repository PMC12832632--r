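# KNN metacell aggregation within annotation groups.
#
# Correlations estimated on sparse single-cell profiles are noisy; summing
# k transcriptomically similar cells of the same annotated type trades
# resolution for stable co-expression estimates before network
# construction.

#' Metacell construction parameters
#'
#' @param k neighbors aggregated per metacell (default 25).
#' @param max_shared maximum number of member cells any two accepted
#'   metacells of a group may share (default 30; clamped to `k - 1`).
#' @param n_components dimensionality of the PCA embedding used for the
#'   neighbor search (default 20).
#' @param seed integer seed controlling the cell visiting order.
#' @return A `metacell_params` object.
#' @export
metacell_params <- function(k = 25, max_shared = 30, n_components = 20,
                            seed = 1L) {
  k <- check_count(k, "k", min = 2L)
  max_shared <- check_count(max_shared, "max_shared", min = 0L)
  n_components <- check_count(n_components, "n_components", min = 2L)
  seed <- check_count(seed, "seed", min = 0L)
  if (max_shared >= k) max_shared <- k - 1L  # overlap of k would duplicate a metacell
  structure(list(k = k, max_shared = max_shared,
                 n_components = n_components, seed = seed),
            class = "metacell_params")
}

#' Create a metacell matrix container
#'
#' @param values metacell x gene aggregated expression matrix.
#' @param members list of member-cell id vectors, one per metacell.
#' @param group annotation label per metacell.
#' @param source_section condition label of the source section.
#' @return A `metacell_matrix` object.
#' @export
new_metacell_matrix <- function(values, members, group, source_section) {
  stopifnot(is.matrix(values), length(members) == nrow(values),
            length(group) == nrow(values))
  structure(list(values = values, members = members, group = group,
                 source_section = as.character(source_section)),
            class = "metacell_matrix")
}

#' @export
print.metacell_matrix <- function(x, ...) {
  cat(sprintf("<metacell_matrix> %d metacells x %d genes from '%s' (%d group(s))\n",
              nrow(x$values), ncol(x$values), x$source_section,
              length(unique(x$group))))
  invisible(x)
}

#' Aggregate cells into metacells within annotation groups
#'
#' Within each annotation group, cells are embedded by truncated PCA of the
#' group's expression and visited in a seed-determined random order. Each
#' visited cell proposes a candidate metacell consisting of itself and its
#' `k - 1` nearest Euclidean neighbors in the embedding; the candidate is
#' accepted iff its member overlap with every previously accepted metacell
#' of the group is at most `max_shared`. Aggregation is by per-gene sum
#' over members. Groups with fewer than `k` cells yield no metacells and
#' are reported with a warning.
#'
#' @param section an [new_expression_section()].
#' @param params a [metacell_params()].
#' @param genes optional gene subset (character vector of gene ids).
#' @return A [new_metacell_matrix()] covering all processable groups.
#' @export
build_metacells <- function(section, params = metacell_params(),
                            genes = NULL) {
  stopifnot(inherits(section, "expression_section"),
            inherits(params, "metacell_params"))
  expr <- section$expr
  if (!is.null(genes)) {
    missing <- setdiff(genes, colnames(expr))
    if (length(missing)) {
      stop("unknown genes: ", paste(head(missing, 5), collapse = ", "),
           call. = FALSE)
    }
    expr <- expr[, genes, drop = FALSE]
  }
  if (length(expr) == 0 || nrow(expr) == 0 || ncol(expr) == 0) {
    stop("empty expression matrix", call. = FALSE)
  }
  groups <- sort(unique(as.character(section$cells$celltype)))
  k <- params$k
  values <- list(); members <- list(); mgroup <- character(0)
  skipped <- character(0)

  with_seed(params$seed, {
    for (grp in groups) {
      idx <- which(section$cells$celltype == grp)
      n <- length(idx)
      if (n < k) {
        skipped <- c(skipped, grp)
        next
      }
      X <- expr[idx, , drop = FALSE]
      ncomp <- min(params$n_components, n - 1L, ncol(X))
      emb <- tryCatch(
        prcomp(X, center = TRUE, scale. = FALSE, rank. = ncomp)$x,
        error = function(e) X)
      D <- as.matrix(dist(emb))
      visit <- sample(n)
      accepted <- list()
      # cell x metacell incidence of accepted members; overlap of a
      # candidate with every accepted metacell is one colSums call
      inc <- matrix(0L, n, 0)
      for (ci in visit) {
        # k - 1 nearest neighbors; distance ties broken by cell index
        ord <- order(D[ci, ], seq_len(n))
        ord <- ord[ord != ci]
        cand <- sort(c(ci, ord[seq_len(k - 1L)]))
        ok <- ncol(inc) == 0L ||
          max(colSums(inc[cand, , drop = FALSE])) <= params$max_shared
        if (ok) {
          accepted[[length(accepted) + 1L]] <- cand
          col <- integer(n)
          col[cand] <- 1L
          inc <- cbind(inc, col)
        }
      }
      for (j in seq_along(accepted)) {
        mem <- idx[accepted[[j]]]
        values[[length(values) + 1L]] <- colSums(expr[mem, , drop = FALSE])
        members[[length(members) + 1L]] <-
          as.character(section$cells$cell_id[mem])
        mgroup <- c(mgroup, grp)
      }
    }
  })
  if (length(skipped)) {
    warning(sprintf("groups with fewer than k = %d cells yielded no metacells: %s",
                    k, paste(skipped, collapse = ", ")), call. = FALSE)
  }
  vals <- if (length(values)) do.call(rbind, values) else
    matrix(numeric(0), 0, ncol(expr))
  colnames(vals) <- colnames(expr)
  if (nrow(vals) > 0) {
    rownames(vals) <- sprintf("%s#%03d", mgroup,
                              stats::ave(seq_along(mgroup), mgroup,
                                         FUN = seq_along))
  }
  out <- new_metacell_matrix(vals, members, mgroup, section$condition)
  attr(out, "skipped_groups") <- skipped
  out
}

#' Library-size normalize metacells
#'
#' Each metacell's expression is scaled so its total equals the median
#' metacell total, then log1p-transformed. All-zero metacells are left as
#' zeros and flagged via the `"zero_metacells"` attribute.
#'
#' @param m a [new_metacell_matrix()] of non-negative aggregated values.
#' @return A normalized `metacell_matrix`; scaled row totals (before log)
#'   are equal across non-zero metacells.
#' @export
normalize_metacells <- function(m) {
  stopifnot(inherits(m, "metacell_matrix"))
  v <- m$values
  if (any(v < 0)) stop("metacell values must be non-negative", call. = FALSE)
  totals <- rowSums(v)
  nz <- totals > 0
  out <- v
  if (any(nz)) {
    target <- median(totals[nz])
    out[nz, ] <- v[nz, , drop = FALSE] * (target / totals[nz])
  }
  out <- log1p(out)
  res <- new_metacell_matrix(out, m$members, m$group, m$source_section)
  attr(res, "zero_metacells") <- rownames(v)[!nz] %||% which(!nz)
  attr(res, "normalized") <- TRUE
  res
}
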