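test_that("control adjustment centres on the pooled control mean and inverts", {
  fx <- random_dataset(n_genes = 6, seed = 21)
  adj <- adjust_to_control(fx$dataset, fx$sheet)
  controls <- fx$sheet$sample_id[fx$sheet$group == "control"]
  treated <- fx$sheet$sample_id[fx$sheet$group == "treated"]
  cm <- rowMeans(fx$dataset$values[, controls])
  expect_equal(dim(adj$values), c(6L, length(treated)))
  # worked example: controls {2, 4}, treated 5 -> adjusted 2
  X <- matrix(c(2, 4, 5), 1, 3,
              dimnames = list("g", c("c1", "c2", "t1")))
  sh <- sample_sheet(c("c1", "c2", "t1"), c("control", "control", "treated"),
                     c(1, 1, 1))
  a1 <- adjust_to_control(expression_dataset(X), sh)
  expect_equal(unname(a1$values["g", "t1"]), 2)
  # treated equal to control mean -> all zeros
  X2 <- matrix(c(2, 4, 3), 1, 3,
               dimnames = list("g", c("c1", "c2", "t1")))
  a2 <- adjust_to_control(expression_dataset(X2), sh)
  expect_equal(unname(a2$values["g", "t1"]), 0)
  # round trip: adding the control means back restores the input
  restored <- adj$values + adj$control_means
  expect_lt(max(abs(restored - fx$dataset$values[, treated])), 1e-12)
  # no controls -> error unless "none" requested
  tr_only <- fx$sheet[fx$sheet$group == "treated", ]
  expect_error(adjust_to_control(fx$dataset, tr_only), "no control samples")
  expect_silent(adjust_to_control(fx$dataset, tr_only, mode = "none"))
})

test_that("per-timepoint stats match hand arithmetic", {
  X <- rbind(g1 = c(1, 2, 3), g2 = c(2, 4, 6), g3 = c(1, 1, 2))
  adj <- adj_from_matrix(X, times = c(1, 1, 1))
  st <- per_time_stats(adj, 1)
  expect_equal(unname(st$sd["g1"]), 1)
  expect_equal(unname(st$sd["g2"]), 2)
  expect_equal(unname(st$pcc["g1", "g2"]), 1)
  expect_equal(unname(st$pcc["g1", "g3"]), 0.5 / (1 * sqrt(1 / 3)),
               tolerance = 1e-10)   # cov 0.5, sds 1 and 0.57735 -> 0.8660
  expect_equal(unname(st$pcc["g1", "g3"]), 0.8660, tolerance = 1e-4)
  expect_error(per_time_stats(adj, 99), ">= 3 treated replicates")
  # constant gene: sd 0 and undefined correlations mapped to 0
  Xc <- rbind(g1 = c(1, 2, 3), g2 = c(5, 5, 5))
  stc <- per_time_stats(adj_from_matrix(Xc, c(1, 1, 1)), 1)
  expect_equal(unname(stc$sd["g2"]), 0)
  expect_equal(unname(stc$pcc["g1", "g2"]), 0)
  expect_gt(attr(stc$pcc, "n_undefined"), 0)
})

test_that("clustering recovers planted correlation blocks", {
  set.seed(7)
  u <- c(0, 1, 2, 3, 4); v <- c(2, -1, 3, 0, 1)
  blockA <- t(sapply(1:10, function(i) i * u + i))        # all r = 1 with u
  blockB <- t(sapply(1:10, function(i) (i + 1) * v - i))  # all r = 1 with v
  # noise genes built in the centred subspace orthogonal to u and v, with
  # tiny jitter, so they cannot attach to either block by chance
  ones <- rep(1, 5)
  basis <- qr.Q(qr(cbind(ones, u, v, rnorm(5), rnorm(5))))[, 4:5]
  coef <- matrix(rnorm(30), 15, 2)
  noise <- coef %*% t(basis) + matrix(rnorm(75, sd = 0.01), 15, 5)
  X <- rbind(blockA, blockB, noise)
  rownames(X) <- sprintf("g%02d", 1:35)
  adj <- adj_from_matrix(X, rep(1, 5))
  cand <- candidate_modules(adj, 1, min_size = 5)
  ov <- vapply(cand, function(m)
    max(length(intersect(m, rownames(X)[1:10])),
        length(intersect(m, rownames(X)[11:20]))), integer(1))
  big <- cand[vapply(cand, length, integer(1)) >= 10 & ov >= 10]
  expect_gte(length(big), 2L)   # both blocks recovered as candidates
  cand2 <- candidate_modules(adj, 1, min_size = 2)
  expect_true(any(vapply(cand2, function(m) setequal(m, rownames(X)[1:10]),
                         logical(1))))
  expect_true(any(vapply(cand2, function(m) setequal(m, rownames(X)[11:20]),
                         logical(1))))
  # iid noise with an unreachable min_size -> no candidates
  adjn <- adj_from_matrix(matrix(rnorm(100), 20, 5,
                                 dimnames = list(sprintf("n%02d", 1:20), NULL)),
                          rep(1, 5))
  expect_length(candidate_modules(adjn, 1, min_size = 20), 0L)
})

test_that("composite index reproduces the worked example and guards", {
  X <- rbind(g1 = c(1, 2, 3), g2 = c(2, 4, 6), g3 = c(1, 1, 2))
  adj <- adj_from_matrix(X, c(1, 1, 1))
  sc <- composite_index(adj, c("g1", "g2"), 1)
  expect_equal(sc$pcc_in, 1)
  expect_equal(sc$sd_in, 1.5)
  expect_equal(sc$pcc_out, 0.8660, tolerance = 1e-4)
  expect_equal(sc$ci, 1.7321, tolerance = 1e-4)
  expect_equal(sc$ci, sc$pcc_in * sc$sd_in / sc$pcc_out, tolerance = 1e-12)
  # constant module -> SD 0 -> CI 0
  Xc <- rbind(g1 = c(2, 2, 2), g2 = c(3, 3, 3), g3 = c(1, 5, 2))
  scc <- composite_index(adj_from_matrix(Xc, c(1, 1, 1)), c("g1", "g2"), 1)
  expect_equal(scc$ci, 0)
  # outside uncorrelated (constant outside gene) -> eps guard
  Xg <- rbind(g1 = c(1, 2, 3), g2 = c(2, 4, 6), g3 = c(7, 7, 7))
  scg <- composite_index(adj_from_matrix(Xg, c(1, 1, 1)), c("g1", "g2"), 1,
                         eps = 1e-6)
  expect_true(is.finite(scg$ci))
  expect_equal(scg$ci, scg$pcc_in * scg$sd_in / 1e-6)
  # error contracts
  expect_error(composite_index(adj, c("g1", "g2", "g3"), 1), "all genes")
  expect_error(composite_index(adj, "g1", 1), ">= 2 genes")
  expect_error(composite_index(adj, c("g1", "nope"), 1), "absent")
})

test_that("composite index equals brute-force pair enumeration", {
  for (s in 1:20) {
    set.seed(s)
    X <- matrix(rnorm(100), 20, 5,
                dimnames = list(sprintf("g%02d", 1:20), NULL))
    adj <- adj_from_matrix(X, rep(1, 5))
    idx <- sort(sample(20, 6))
    got <- composite_index(adj, rownames(X)[idx], 1)
    ref <- brute_ci(X, idx)
    expect_equal(got$pcc_in, ref$pcc_in, tolerance = 1e-10)
    expect_equal(got$pcc_out, ref$pcc_out, tolerance = 1e-10)
    expect_equal(got$sd_in, ref$sd_in, tolerance = 1e-10)
    expect_equal(got$ci, ref$ci, tolerance = 1e-10)
  }
})

test_that("scores are scale-equivariant", {
  set.seed(3)
  X <- matrix(rnorm(60, 5), 12, 5, dimnames = list(sprintf("g%02d", 1:12), NULL))
  mod <- c("g01", "g02", "g03")
  a <- composite_index(adj_from_matrix(X, rep(1, 5)), mod, 1)
  b <- composite_index(adj_from_matrix(X * 7, rep(1, 5)), mod, 1)
  expect_equal(b$pcc_in, a$pcc_in, tolerance = 1e-12)
  expect_equal(b$pcc_out, a$pcc_out, tolerance = 1e-12)
  expect_equal(b$sd_in, 7 * a$sd_in, tolerance = 1e-12)
  expect_equal(b$ci, 7 * a$ci, tolerance = 1e-10)
})

test_that("the dominant module per timepoint is the max-CI candidate", {
  sim <- simulate_expression(simulation_design(n_genes = 80, module_size = 10,
                                               seed = 12))
  fit <- select_dnb(sim$dataset, sim$sheet, n_perm = 1, seed = 1,
                    refine = FALSE)
  adj <- adjust_to_control(sim$dataset, sim$sheet)
  for (i in seq_len(nrow(fit$table))) {
    t <- fit$table$time[i]
    cand <- candidate_modules(adj, t)
    if (!length(cand)) next
    cis <- vapply(cand, function(m) composite_index(adj, m, t)$ci, numeric(1))
    expect_equal(fit$table$ci[i], max(cis), tolerance = 1e-10)
    expect_setequal(fit$modules[[paste0("t", t)]], cand[[which.max(cis)]])
  }
})

test_that("an overwhelming planted module is called at its timepoint", {
  # three timepoints, module of 6 genes fluctuating collectively at t2 only
  set.seed(42)
  n <- 60; reps <- 5
  times <- rep(c(1, 2, 3), each = reps)
  X <- matrix(rnorm(n * length(times), sd = 0.3), n, length(times),
              dimnames = list(sprintf("g%02d", 1:n), NULL))
  z <- rnorm(reps)
  t2 <- which(times == 2)
  for (g in 1:6) X[g, t2] <- 4 * z + rnorm(reps, sd = 0.1)
  adj <- adj_from_matrix(X, times)
  ds <- expression_dataset(`colnames<-`(X, sprintf("s%02d", seq_along(times))))
  sheet <- sample_sheet(colnames(ds$values), rep("treated", length(times)),
                        times)
  fit <- select_dnb(ds, sheet, adjust = "none", n_perm = 99, seed = 5)
  expect_equal(fit$tipping_time, 2L)
  expect_lt(fit$p_value, 0.05)
  expect_gte(length(intersect(fit$dnb_genes, sprintf("g%02d", 1:6))), 5L)
  # criteria flags at the called timepoint
  flags <- fit$table[fit$table$time == 2, c("pcc_in_up", "sd_in_up",
                                            "pcc_out_down")]
  expect_true(all(unlist(flags)))
})

test_that("permutation p-values are reproducible and schemes agree on nulls", {
  sim <- simulate_expression(simulation_design(n_genes = 60, module_size = 6,
                                               rho_in = 0, var_fold = 1,
                                               de_fraction = 0, seed = 8))
  f1 <- select_dnb(sim$dataset, sim$sheet, n_perm = 30, seed = 99)
  f2 <- select_dnb(sim$dataset, sim$sheet, n_perm = 30, seed = 99)
  expect_identical(f1$p_value, f2$p_value)
  expect_identical(f1$modules, f2$modules)
  f3 <- select_dnb(sim$dataset, sim$sheet, n_perm = 30, seed = 99,
                   perm_scheme = "across_time")
  expect_true(f3$p_value > 0.05)  # no signal to find under either scheme
})

test_that("refinement recovers planted members the cluster missed", {
  sim <- simulate_expression(simulation_design(seed = 9))
  adj <- adjust_to_control(sim$dataset, sim$sheet)
  cand <- candidate_modules(adj, 9)
  cis <- vapply(cand, function(m) composite_index(adj, m, 9)$ci, numeric(1))
  seedmod <- cand[[which.max(cis)]]
  ref <- refine_module(adj, seedmod, 9)
  expect_gt(jaccard(ref, sim$truth$module),
            jaccard(seedmod, sim$truth$module))
})

test_that("replicate dispersion matches hand arithmetic and peaks at t*", {
  # identical replicates -> 0
  X <- matrix(5, 3, 4, dimnames = list(c("a", "b", "c"), NULL))
  adj <- adj_from_matrix(X, c(1, 1, 2, 2))
  d <- sample_dispersion(adj)
  expect_equal(d$dispersion, c(0, 0))
  # two samples differing by 3 in one gene -> distance 3
  X2 <- matrix(0, 3, 2, dimnames = list(c("a", "b", "c"), NULL))
  X2[2, 2] <- 3
  expect_equal(sample_dispersion(adj_from_matrix(X2, c(1, 1)))$dispersion, 3)
  # strong planted effect: dispersion maximal at the tipping time usually
  hits <- vapply(1:15, function(s) {
    sim <- simulate_expression(simulation_design(
      n_genes = 120, module_size = 40, var_fold = 8, de_fraction = 0,
      seed = s))
    adj <- adjust_to_control(sim$dataset, sim$sheet)
    d <- sample_dispersion(adj)
    d$time[which.max(d$dispersion)] == 9
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})
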