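# Fixtures built in code at test time.

# a tiny hand-made section: 6 cells, 4 genes, 2 cell-types
tiny_section <- function() {
  expr <- matrix(c(
    1, 0, 2, 0,
    2, 0, 1, 0,
    3, 0, 2, 1,
    0, 1, 0, 4,
    0, 2, 0, 5,
    0, 3, 1, 6), nrow = 6, byrow = TRUE,
    dimnames = list(sprintf("c%d", 1:6), c("GA", "GB", "GC", "GD")))
  cells <- data.frame(cell_id = rownames(expr),
                      celltype = rep(c("T1", "T2"), each = 3),
                      x = c(0, 1, 2, 10, 11, 12), y = c(0, 1, 0, 10, 11, 10),
                      stringsAsFactors = FALSE)
  new_expression_section(expr, cells, "2dpi")
}

# random symmetric adjacency with unit diagonal, entries in [0, 1]
random_adjacency <- function(n, seed) {
  set.seed(seed)
  A <- matrix(runif(n * n), n, n)
  A <- (A + t(A)) / 2
  diag(A) <- 1
  dimnames(A) <- list(sprintf("g%02d", 1:n), sprintf("g%02d", 1:n))
  structure(list(values = A, power = 1, network_type = "signed"),
            class = "adjacency_matrix")
}

# the planted-recovery study conditions: 4 modules of 20-40 genes at
# rho = 0.7, 200 samples standing in for metacells
recovery_config <- function(seed) {
  synth_config(n_celltypes = 1, cells_per_type = 200, n_genes = 400,
               timepoint_labels = "2dpi", marker_fraction_course = 0.37,
               n_modules_shared = 4, n_modules_regen_only = 0,
               module_size = c(20, 30, 35, 40), within_module_rho = 0.7,
               seed = seed)
}

# run the netcore + modulestats pipeline on a recovery fixture; returns
# NULL when the context is excluded
run_recovery <- function(seed, n_hubs = 10) {
  sim <- generate_sections(recovery_config(seed))
  s <- sim$sections[[1]]
  genes <- filter_genes_by_fraction(s, "CT01", 0.05)
  np <- network_params(min_module_size = 15)
  sel <- select_soft_power(s$expr[, genes], np)
  if (sel$excluded) return(NULL)
  adj <- compute_adjacency(s$expr[, genes], sel$power)
  modules <- detect_modules(compute_tom(adj), np, expr = s$expr[, genes],
                            context = list(celltype = "CT01",
                                           condition = "2dpi"))
  eig <- compute_eigengenes(s$expr[, genes], modules)
  kme <- compute_kme(s$expr[, genes], eig)
  hubs <- extract_hubs(kme, modules, n_hubs)
  truth <- ifelse(is.na(sim$truth$module_membership[genes]), "none",
                  sim$truth$module_membership[genes])
  list(modules = modules, hubs = hubs, truth = truth, sim = sim,
       power = sel$power, genes = genes)
}

# a small pipeline config sized for test runtime: 3 timepoints x
# 2 cell-types at the default per-type depth
small_pipeline_config <- function(out_dir, seed = 5) {
  cfg <- synth_config(timepoint_labels = c("juvenile", "2dpi", "5dpi"),
                      marker_fraction_course = c(0.06, 0.37, 0.33),
                      n_celltypes = 2, seed = seed)
  pipeline_config(out_dir = out_dir, synth = cfg, seed = seed)
}
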