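test_that("gene detection filter is boundary-inclusive", {
  n <- 100
  expr <- matrix(0, n, 3,
                 dimnames = list(sprintf("c%d", 1:n), c("keep", "drop", "zero")))
  expr[1:5, "keep"] <- 1    # 5% exactly
  expr[1:4, "drop"] <- 1    # 4%
  cells <- data.frame(cell_id = rownames(expr), celltype = "T1",
                      x = 0, y = 0, stringsAsFactors = FALSE)
  s <- new_expression_section(expr, cells, "2dpi")
  expect_identical(filter_genes_by_fraction(s, "T1", 0.05), "keep")
  expect_error(filter_genes_by_fraction(s, "missing"), "empty or absent")
})

test_that("signed adjacency follows the power transform of correlation", {
  # cor(x, y) = 0.5 exactly for these vectors
  expr <- cbind(a = c(1, 2, 3), b = c(1, 3, 2))
  adj <- compute_adjacency(expr, power = 9, network_type = "signed")
  expect_equal(adj$values["a", "b"], 0.75^9, tolerance = 1e-12)
  # perfectly correlated genes: a_ij = 1 for any power
  expr2 <- cbind(a = c(1, 2, 3), b = c(2, 4, 6))
  adj2 <- compute_adjacency(expr2, power = 7)
  expect_equal(adj2$values["a", "b"], 1)
  # perfect anticorrelation, signed, power 2: ((1 - 1)/2)^2 = 0
  expr3 <- cbind(a = c(1, 2, 3), b = c(3, 2, 1))
  adj3 <- compute_adjacency(expr3, power = 2)
  expect_equal(adj3$values["a", "b"], 0)
  # unsigned uses |cor|
  adj4 <- compute_adjacency(expr3, power = 3, network_type = "unsigned")
  expect_equal(adj4$values["a", "b"], 1)
  expect_error(compute_adjacency(cbind(a = c(1, 1, 1), b = c(1, 2, 3)), 2),
               "constant gene.*a")
})

test_that("raising the power weakly decreases off-diagonal adjacency", {
  set.seed(1)
  expr <- matrix(rnorm(30 * 8), 30, 8,
                 dimnames = list(NULL, sprintf("g%d", 1:8)))
  for (type in c("signed", "unsigned")) {
    prev <- NULL
    for (p in c(1, 2, 4, 8, 16)) {
      A <- compute_adjacency(expr, p, type)$values
      off <- A[upper.tri(A)]
      if (!is.null(prev)) expect_true(all(off <= prev + 1e-12))
      prev <- off
    }
  }
})

test_that("scale-free fit index carries the sign of the degree law", {
  # two connectivity groups: many low-k genes, few high-k genes ->
  # two collinear log-log points with negative slope -> index = 1
  w <- c(rep(0.1, 16), rep(0.9, 4))
  A <- outer(w, w)
  diag(A) <- 1
  adj <- structure(list(values = A, power = 1, network_type = "signed"),
                   class = "adjacency_matrix")
  fit <- suppressWarnings(scale_free_fit(adj, n_bins = 4))
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_lt(fit$slope, 0)
  # inverted frequencies (few low-k, many high-k) -> index <= 0
  w2 <- c(rep(0.1, 4), rep(0.9, 16))
  A2 <- outer(w2, w2)
  diag(A2) <- 1
  adj2 <- structure(list(values = A2, power = 1, network_type = "signed"),
                    class = "adjacency_matrix")
  fit2 <- suppressWarnings(scale_free_fit(adj2, n_bins = 4))
  expect_lte(fit2$r_squared, 0)
  # degenerate connectivity is rejected
  A3 <- matrix(0.5, 5, 5); diag(A3) <- 1
  adj3 <- structure(list(values = A3, power = 1, network_type = "signed"),
                    class = "adjacency_matrix")
  expect_error(scale_free_fit(adj3), "bins")
})

test_that("hub-structured networks outscore uniform random ones", {
  sim <- generate_sections(recovery_config(31))
  expr <- sim$sections[[1]]$expr
  planted <- compute_adjacency(expr[, 1:200], 6)
  set.seed(99)
  noise <- matrix(rnorm(200 * 200), 200, 200,
                  dimnames = list(NULL, sprintf("n%d", 1:200)))
  random <- compute_adjacency(noise, 6)
  expect_gt(scale_free_fit(planted)$r_squared,
            scale_free_fit(random)$r_squared)
})

test_that("soft power selection returns the minimum qualifying candidate", {
  sim <- generate_sections(recovery_config(12))
  expr <- sim$sections[[1]]$expr
  params <- network_params(min_module_size = 15)
  sel <- select_soft_power(expr, params)
  expect_false(sel$excluded)
  # exhaustive scan agrees
  manual <- vapply(params$power_candidates, function(p) {
    f <- tryCatch(scale_free_fit(compute_adjacency(expr, p), params$n_bins),
                  error = function(e) NULL)
    if (is.null(f)) NA_real_ else f$r_squared
  }, numeric(1))
  expect_identical(sel$power,
                   params$power_candidates[
                     which(!is.na(manual) & manual >= 0.80)[1]])
  # an unattainable threshold excludes the context
  sel2 <- select_soft_power(expr, network_params(r2_threshold = 1.01))
  expect_true(sel2$excluded)
  expect_true(is.na(sel2$power))
})

test_that("TOM matches hand calculations on canonical graphs", {
  # complete 3-node graph
  A <- matrix(1, 3, 3)
  adj <- structure(list(values = A, power = 1, network_type = "signed"),
                   class = "adjacency_matrix")
  expect_equal(compute_tom(adj)$values[1, 2], 1)
  # star: a_12 = a_13 = 1, a_23 = 0 -> TOM_23 = 0.5
  S <- matrix(c(1, 1, 1, 1, 1, 0, 1, 0, 1), 3, 3)
  adjS <- structure(list(values = S, power = 1, network_type = "signed"),
                    class = "adjacency_matrix")
  expect_equal(compute_tom(adjS)$values[2, 3], 0.5)
})

test_that("TOM equals the brute-force oracle on random matrices", {
  for (seed in 1:5) {
    n <- sample(5:20, 1)
    adj <- random_adjacency(n, seed)
    tom <- compute_tom(adj)$values
    expect_lt(max(abs(tom - oracle_tom(adj$values))), 1e-12)
    expect_equal(tom, t(tom))
    expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
  }
})

test_that("module detection separates planted TOM blocks", {
  # two 40-gene blocks with high internal overlap, low between
  n <- 100
  genes <- sprintf("g%03d", 1:n)
  V <- matrix(0.02, n, n, dimnames = list(genes, genes))
  V[1:40, 1:40] <- 0.6
  V[41:80, 41:80] <- 0.6
  diag(V) <- 1
  tom <- structure(list(values = V), class = "tom_matrix")
  mod <- detect_modules(tom, network_params(min_module_size = 30))
  truth <- c(rep("A", 40), rep("B", 40), rep("none", 20))
  expect_equal(adjusted_rand(mod$labels, truth), 1)
  # deterministic labels: M1/M2 by size tie -> lexicographic smallest gene
  expect_setequal(unique(mod$labels[1:40]), "M1")
  expect_setequal(unique(mod$labels[41:80]), "M2")
  expect_setequal(unique(mod$labels[81:100]), "grey")
})

test_that("min_module_size and degenerate TOMs behave as documented", {
  n <- 50
  genes <- sprintf("g%02d", 1:n)
  V <- matrix(0.5, n, n, dimnames = list(genes, genes))
  diag(V) <- 1
  tom <- structure(list(values = V), class = "tom_matrix")
  # identical rows -> a single module
  mod <- detect_modules(tom, network_params(min_module_size = 30))
  expect_setequal(unname(mod$labels), "M1")
  # min_module_size larger than any cluster -> all grey
  mod2 <- detect_modules(tom, network_params(min_module_size = 51))
  expect_setequal(unname(mod2$labels), "grey")
})

test_that("planted modules are recovered end to end across seeds", {
  for (seed in 1:3) {
    res <- run_recovery(seed)
    expect_false(is.null(res))
    expect_gte(adjusted_rand(res$modules$labels[res$genes], res$truth), 0.8)
  }
})
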