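test_that("generation is deterministic given a seed", {
  cfg <- synth_config(timepoint_labels = c("juvenile", "2dpi"),
                      marker_fraction_course = c(0.06, 0.37),
                      n_celltypes = 2, cells_per_type = 40, n_genes = 80,
                      n_modules_shared = 1, n_modules_regen_only = 1,
                      module_size = 10, seed = 1)
  a <- generate_sections(cfg)
  b <- generate_sections(cfg)
  expect_identical(a$sections[["2dpi"]]$expr, b$sections[["2dpi"]]$expr)
  expect_identical(a$truth$module_membership, b$truth$module_membership)
  expect_identical(a$truth$marker_positive_cells,
                   b$truth$marker_positive_cells)
})

test_that("planted modules hit the target within-module correlation", {
  cfg <- synth_config(timepoint_labels = "2dpi",
                      marker_fraction_course = 0.37,
                      n_celltypes = 1, cells_per_type = 400, n_genes = 120,
                      n_modules_shared = 1, n_modules_regen_only = 0,
                      module_size = 20, within_module_rho = 0.7, seed = 3)
  sim <- generate_sections(cfg)
  members <- names(sim$truth$module_membership)[
    !is.na(sim$truth$module_membership)]
  C <- cor(sim$sections[[1]]$expr[, members])
  expect_gte(mean(C[upper.tri(C)]), 0.6)
  expect_lte(mean(C[upper.tri(C)]), 0.8)
})

test_that("regeneration-only modules are structured only in DPI sections", {
  cfg <- synth_config(timepoint_labels = c("juvenile", "2dpi"),
                      marker_fraction_course = c(0.06, 0.37),
                      n_celltypes = 1, cells_per_type = 300, n_genes = 150,
                      n_modules_shared = 1, n_modules_regen_only = 1,
                      module_size = 20, within_module_rho = 0.7, seed = 4)
  sim <- generate_sections(cfg)
  tr <- sim$truth
  ro <- names(tr$module_membership)[
    !is.na(tr$module_membership) &
      tr$module_membership %in% tr$regen_only_modules]
  C_dpi <- cor(sim$sections[["2dpi"]]$expr[, ro])
  C_ctl <- cor(sim$sections[["juvenile"]]$expr[, ro])
  expect_gte(mean(C_dpi[upper.tri(C_dpi)]), 0.5)
  expect_lte(abs(mean(C_ctl[upper.tri(C_ctl)])), 0.15)
})

test_that("marker positivity matches the configured course exactly", {
  cfg <- synth_config(timepoint_labels = c("juvenile", "2dpi"),
                      marker_fraction_course = c(0.06, 0.37),
                      n_celltypes = 2, cells_per_type = 500, n_genes = 60,
                      n_modules_shared = 1, n_modules_regen_only = 0,
                      module_size = 10, seed = 2)
  sim <- generate_sections(cfg)
  s <- sim$sections[["2dpi"]]
  expect_identical(sum(s$expr[, "TRH"] > 0), 370L)
  expect_setequal(rownames(s$expr)[s$expr[, "TRH"] > 0],
                  sim$truth$marker_positive_cells[["2dpi"]])
  expect_identical(sum(sim$sections[["juvenile"]]$expr[, "TRH"] > 0), 60L)
})

test_that("gene namespace mixes AMEX ids, symbols, and raw pipe names", {
  cfg <- synth_config(timepoint_labels = "2dpi",
                      marker_fraction_course = 0.37,
                      n_celltypes = 1, cells_per_type = 30, n_genes = 200,
                      n_modules_shared = 1, n_modules_regen_only = 0,
                      module_size = 10, amex_fraction = 0.3,
                      raw_symbol_fraction = 0.2, seed = 5)
  sim <- generate_sections(cfg)
  genes <- sim$sections[[1]]$genes
  n_amex <- sum(grepl("^AMEX60DD_\\d{6}$", genes$gene_id))
  expect_equal(n_amex, 60)
  expect_true("TRH" %in% genes$gene_id)
  raw <- genes$raw_name[genes$raw_name != genes$gene_id]
  expect_gt(length(raw), 0)
  expect_true(all(grepl("^[A-Z0-9]+ \\| [A-Z0-9]+_XENLA$", raw)))
})

test_that("invalid configs are rejected with the violated invariant named", {
  expect_error(synth_config(timepoint_labels = c("2dpi", "2dpi"),
                            marker_fraction_course = c(0.1, 0.1)),
               "unique")
  expect_error(synth_config(n_genes = 50, module_size = 30,
                            n_modules_shared = 2, n_modules_regen_only = 0,
                            timepoint_labels = "2dpi",
                            marker_fraction_course = 0.1),
               "non-module genes")
  expect_error(synth_config(timepoint_labels = "2dpi",
                            marker_fraction_course = 1.2),
               "marker_fraction_course")
  expect_error(synth_config(within_module_rho = -0.1), "within_module_rho")
})

test_that("coloc image fixture matches disk geometry", {
  # disjoint disks
  fix <- generate_coloc_image(80, 60,
                              list(list(center = c(15, 30), radius = 8,
                                        intensity = 1)),
                              list(list(center = c(60, 30), radius = 8)),
                              seed = 1)
  expect_identical(sum(fix$truth_overlap), 0L)
  expect_identical(dim(unclass(fix$truth_overlap)), c(60L, 80L))
  # identical disks: overlap = disk area
  fix2 <- generate_coloc_image(60, 60,
                               list(list(center = c(30, 30), radius = 10,
                                         intensity = 1)),
                               list(list(center = c(30, 30), radius = 10)),
                               seed = 1)
  disk_px <- sum(outer(0:59, 0:59, function(y, x)
    (x - 30)^2 + (y - 30)^2 <= 100))
  expect_identical(sum(fix2$truth_overlap), disk_px)
  # lens: rasterized overlap close to the analytic area
  fix3 <- generate_coloc_image(80, 60,
                               list(list(center = c(30, 30), radius = 10,
                                         intensity = 1)),
                               list(list(center = c(40, 30), radius = 10)),
                               seed = 1)
  lens <- oracle_lens_area(10, 10, 10)
  perim <- 2 * pi * 10
  expect_lt(abs(sum(fix3$truth_overlap) - lens), perim)
  # determinism and bounds checking
  fix4 <- generate_coloc_image(80, 60,
                               list(list(center = c(30, 30), radius = 10,
                                         intensity = 1)),
                               list(list(center = c(40, 30), radius = 10)),
                               seed = 1)
  expect_identical(fix3$marker$pixels, fix4$marker$pixels)
  expect_error(generate_coloc_image(0, 10, list(), list(), 1), "width")
  expect_error(generate_coloc_image(40, 40,
                                    list(list(center = c(35, 20),
                                              radius = 10, intensity = 1)),
                                    list(), 1),
               "outside")
})

test_that("atlas fixture respects forced and degenerate probabilities", {
  ctx <- data.frame(timepoint = c("2dpi", "juvenile"),
                    celltype = c("T1", "T1"), stringsAsFactors = FALSE)
  grey_only <- generate_atlas_fixture(10, ctx, c(grey = 1), seed = 1)
  expect_identical(nrow(grey_only$entries), 0L)
  forced <- generate_atlas_fixture(1, ctx, list(c(M1 = 1), c(M2 = 1)),
                                   seed = 1)
  expect_identical(forced$entries$module[forced$entries$timepoint == "2dpi"],
                   "M1")
  expect_identical(forced$entries$module[
    forced$entries$timepoint == "juvenile"], "M2")
  a <- generate_atlas_fixture(100, ctx, c(M1 = 0.4, M2 = 0.3, grey = 0.3),
                              seed = 7)
  b <- generate_atlas_fixture(100, ctx, c(M1 = 0.4, M2 = 0.3, grey = 0.3),
                              seed = 7)
  expect_identical(a$entries, b$entries)
  expect_error(generate_atlas_fixture(5, list(), c(M1 = 1), 1), "nonempty")
  expect_error(generate_atlas_fixture(5, ctx, c(M1 = 0.5), 1), "sum to 1")
})
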