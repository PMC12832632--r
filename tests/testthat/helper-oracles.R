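# Independent oracle implementations used to pin expected values. These
# deliberately use naive loops so they share no code path with the
# package.

oracle_tom <- function(A) {
  n <- nrow(A)
  A0 <- A
  diag(A0) <- 0
  k <- rowSums(A0)
  out <- diag(1, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      s <- 0
      for (u in seq_len(n)) {
        if (u != i && u != j) s <- s + A0[i, u] * A0[u, j]
      }
      out[i, j] <- (s + A0[i, j]) / (min(k[i], k[j]) + 1 - A0[i, j])
    }
  }
  out
}

oracle_dilate <- function(mask, radius, shape = "disk") {
  h <- nrow(mask); w <- ncol(mask)
  r <- floor(radius)
  out <- matrix(FALSE, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      hit <- FALSE
      for (di in -r:r) {
        for (dj in -r:r) {
          if (shape == "disk" && di^2 + dj^2 > radius^2) next
          ii <- i + di; jj <- j + dj
          if (ii >= 1 && ii <= h && jj >= 1 && jj <= w && mask[ii, jj]) {
            hit <- TRUE
          }
        }
      }
      out[i, j] <- hit
    }
  }
  out
}

# naive set algebra over an atlas entries data.frame
oracle_gene_sets <- function(entries, classes) {
  tps <- unique(entries$timepoint)
  regen_tps <- tps[classes[tps] == "regeneration"]
  control_tps <- tps[classes[tps] == "control"]
  all_regen <- character(0); all_control <- character(0)
  for (g in unique(entries$gene)) {
    gtps <- unique(entries$timepoint[entries$gene == g])
    if (any(gtps %in% regen_tps)) all_regen <- c(all_regen, g)
    if (any(gtps %in% control_tps)) all_control <- c(all_control, g)
  }
  shared <- character(0)
  for (g in all_regen) {
    gtps <- unique(entries$timepoint[entries$gene == g])
    if (all(regen_tps %in% gtps)) shared <- c(shared, g)
  }
  regen_specific <- all_regen[!(all_regen %in% all_control)]
  list(all_regen = sort(all_regen), all_control = sort(all_control),
       shared_all_stages = sort(shared),
       regen_specific = sort(regen_specific))
}

oracle_hub_tally <- function(rows) {
  out <- list()
  for (i in seq_len(nrow(rows))) {
    g <- rows$gene[i]
    pair <- paste(rows$celltype[i], rows$condition[i], rows$module[i])
    if (is.null(out[[g]])) out[[g]] <- list(pairs = character(0), best = Inf)
    if (!pair %in% out[[g]]$pairs) {
      out[[g]]$pairs <- c(out[[g]]$pairs, pair)
    }
    out[[g]]$best <- min(out[[g]]$best, rows$rank[i])
  }
  data.frame(gene = names(out),
             hub_occurrences = vapply(out, function(x) length(x$pairs), 1L),
             best_rank = vapply(out, function(x) as.integer(x$best), 1L),
             row.names = NULL, stringsAsFactors = FALSE)
}

# closed-form area of the intersection of two disks (radius r1, r2,
# center distance d)
oracle_lens_area <- function(r1, r2, d) {
  if (d >= r1 + r2) return(0)
  if (d <= abs(r1 - r2)) return(pi * min(r1, r2)^2)
  a1 <- r1^2 * acos((d^2 + r1^2 - r2^2) / (2 * d * r1))
  a2 <- r2^2 * acos((d^2 + r2^2 - r1^2) / (2 * d * r2))
  a3 <- 0.5 * sqrt((-d + r1 + r2) * (d + r1 - r2) * (d - r1 + r2) *
                     (d + r1 + r2))
  a1 + a2 - a3
}

adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)
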