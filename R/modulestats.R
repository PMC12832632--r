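# Module eigengenes, gene-module connectivity (kME), hub ranking and
# cross-context hub frequency bookkeeping.

#' Compute module eigengenes
#'
#' For each non-grey module, member-gene columns are standardized (zero
#' mean, unit variance over samples) and the module eigengene (ME) is the
#' sample-score vector of the first principal component. Each ME is sign
#' oriented so that its mean correlation with the module's genes is
#' non-negative, then scaled to unit variance.
#'
#' @param expr sample x gene matrix (or [new_metacell_matrix()] /
#'   [new_expression_section()]).
#' @param modules a [detect_modules()] result whose genes appear in `expr`.
#' @return An `eigengene_matrix` object: `values` (sample x module matrix)
#'   and `variance_explained` (named per-module proportion).
#' @export
compute_eigengenes <- function(expr, modules) {
  stopifnot(inherits(modules, "module_assignment"))
  values <- .expr_values(expr)
  mods <- setdiff(unique(modules$labels), "grey")
  mods <- mods[order(nchar(mods), mods)]  # M1, M2, ..., M10 natural order
  if (length(mods) == 0) {
    stop("no non-grey modules to summarize", call. = FALSE)
  }
  me <- matrix(NA_real_, nrow(values), length(mods),
               dimnames = list(rownames(values), mods))
  varexp <- setNames(numeric(length(mods)), mods)
  for (m in mods) {
    members <- names(modules$labels)[modules$labels == m]
    missing <- setdiff(members, colnames(values))
    if (length(missing)) {
      stop(sprintf("module %s has members absent from `expr`", m),
           call. = FALSE)
    }
    X <- values[, members, drop = FALSE]
    sds <- apply(X, 2, sd)
    if (all(sds == 0)) {
      stop(sprintf("module %s consists of constant genes", m),
           call. = FALSE)
    }
    if (any(sds == 0)) {
      warning(sprintf("module %s: dropping %d constant gene(s) from the eigengene",
                      m, sum(sds == 0)), call. = FALSE)
      X <- X[, sds > 0, drop = FALSE]
    }
    if (ncol(X) < 2L) {
      stop(sprintf("module %s has fewer than 2 non-constant genes", m),
           call. = FALSE)
    }
    Xs <- scale(X)
    s <- svd(Xs)
    scores <- s$u[, 1] * s$d[1]
    if (mean(cor(scores, Xs)) < 0) scores <- -scores
    me[, m] <- scores / sd(scores)
    varexp[m] <- s$d[1]^2 / sum(s$d^2)
  }
  structure(list(values = me, variance_explained = varexp),
            class = "eigengene_matrix")
}

#' @export
print.eigengene_matrix <- function(x, ...) {
  cat(sprintf("<eigengene_matrix> %d samples x %d modules\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Compute gene-module connectivity (kME)
#'
#' `kME(g, M)` is the Pearson correlation between gene `g`'s expression and
#' module `M`'s eigengene, computed for every gene against every module.
#' Constant genes have undefined kME and are recorded as `NA` (with a
#' warning), never silently zero.
#'
#' @param expr sample x gene matrix (or metacell matrix) aligned with the
#'   eigengene samples.
#' @param eig a [compute_eigengenes()] result.
#' @return A `kme_table` object: `values` (gene x module correlation
#'   matrix); [as.data.frame()] yields the long `(gene, module, kme)` form.
#' @export
compute_kme <- function(expr, eig) {
  stopifnot(inherits(eig, "eigengene_matrix"))
  values <- .expr_values(expr)
  if (nrow(values) != nrow(eig$values)) {
    stop("sample sets of `expr` and eigengenes do not align", call. = FALSE)
  }
  sds <- apply(values, 2, sd)
  constant <- sds == 0 | is.na(sds)
  if (any(constant)) {
    warning(sprintf("%d constant gene(s) have undefined kME (recorded as NA)",
                    sum(constant)), call. = FALSE)
  }
  K <- suppressWarnings(cor(values, eig$values))
  K[constant, ] <- NA_real_
  structure(list(values = K), class = "kme_table")
}

#' @export
as.data.frame.kme_table <- function(x, ...) {
  data.frame(gene = rep(rownames(x$values), ncol(x$values)),
             module = rep(colnames(x$values), each = nrow(x$values)),
             kme = as.vector(x$values), stringsAsFactors = FALSE)
}

#' Extract ranked hub genes per module
#'
#' Within each (context, module), member genes are ranked by their
#' own-module kME in decreasing order (ties broken lexicographically by
#' gene id, so output is bit-stable) and the top `n_hubs` are kept; rank 1
#' is the most central hub.
#'
#' @param kme a [compute_kme()] result covering all module members.
#' @param modules the [detect_modules()] assignment.
#' @param n_hubs hubs retained per module (default 10).
#' @param use_abs rank by absolute kME instead of signed kME
#'   (default `FALSE`).
#' @return A `hub_table` data.frame with columns `gene`, `celltype`,
#'   `condition`, `module`, `rank`, `kme`.
#' @export
extract_hubs <- function(kme, modules, n_hubs = 10, use_abs = FALSE) {
  stopifnot(inherits(kme, "kme_table"), inherits(modules, "module_assignment"))
  n_hubs <- check_count(n_hubs, "n_hubs")
  use_abs <- check_flag(use_abs, "use_abs")
  ctx <- modules$context %||% list(celltype = NA_character_,
                                   condition = NA_character_)
  mods <- setdiff(unique(modules$labels), "grey")
  mods <- mods[order(nchar(mods), mods)]
  rows <- list()
  for (m in mods) {
    members <- names(modules$labels)[modules$labels == m]
    if (length(members) == 0) next
    missing <- setdiff(members, rownames(kme$values))
    if (length(missing)) {
      stop(sprintf("kME table does not cover all members of module %s", m),
           call. = FALSE)
    }
    kv <- kme$values[members, m]
    score <- if (use_abs) abs(kv) else kv
    ord <- order(-score, members)
    top <- ord[seq_len(min(n_hubs, length(members)))]
    rows[[m]] <- data.frame(gene = members[top],
                            celltype = ctx$celltype %||% NA_character_,
                            condition = ctx$condition %||% NA_character_,
                            module = m, rank = seq_along(top),
                            kme = unname(kv[top]), stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(0), celltype = character(0),
               condition = character(0), module = character(0),
               rank = integer(0), kme = numeric(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("hub_table", "data.frame")
  attr(out, "n_hubs") <- n_hubs
  out
}

#' Count hub occurrences across contexts
#'
#' Tallies, per gene, the distinct (context, module) pairs in which it
#' appears as a hub, along with the best (minimum) rank attained. Output is
#' sorted by occurrence count (descending), then gene id.
#'
#' @param tables a `hub_table` or list of `hub_table`s.
#' @return A `frequency_table` data.frame with columns `gene`,
#'   `hub_occurrences`, `occurrences` (semicolon-joined
#'   `celltype@condition/module` strings), `best_rank`.
#' @export
hub_frequency <- function(tables) {
  if (inherits(tables, "hub_table")) tables <- list(tables)
  if (!is.list(tables) || length(tables) == 0) {
    stop("`tables` must be a nonempty list of hub tables", call. = FALSE)
  }
  df <- do.call(rbind, lapply(tables, function(t) {
    stopifnot(inherits(t, "hub_table"))
    as.data.frame(t)
  }))
  if (nrow(df) == 0) {
    out <- data.frame(gene = character(0), hub_occurrences = integer(0),
                      occurrences = character(0), best_rank = integer(0),
                      stringsAsFactors = FALSE)
    class(out) <- c("frequency_table", "data.frame")
    return(out)
  }
  df$pair <- sprintf("%s@%s/%s", df$celltype, df$condition, df$module)
  split_rows <- split(df, df$gene)
  out <- do.call(rbind, lapply(split_rows, function(d) {
    pairs <- unique(d$pair)
    data.frame(gene = d$gene[1], hub_occurrences = length(pairs),
               occurrences = paste(sort(pairs), collapse = ";"),
               best_rank = as.integer(min(d$rank)),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(-out$hub_occurrences, out$gene), ]
  rownames(out) <- NULL
  class(out) <- c("frequency_table", "data.frame")
  out
}
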