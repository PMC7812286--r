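# Small in-code fixtures shared across test files.

# A dataset + sheet with an arbitrary matrix laid out as treated-only
# columns, one column per (time, replicate); `times` gives the time label
# of each column. Returned pre-adjusted with mode = "none" so per-timepoint
# statistics can be asserted by hand.
adj_from_matrix <- function(X, times) {
  stopifnot(ncol(X) == length(times))
  colnames(X) <- sprintf("s%02d", seq_len(ncol(X)))
  ds <- expression_dataset(X, scale = "log2")
  sheet <- sample_sheet(colnames(X), rep("treated", ncol(X)), times)
  adjust_to_control(ds, sheet, mode = "none")
}

# genes x samples dataset with both groups: treated at `times` (reps each)
# and controls; values N(mu, sd).
random_dataset <- function(n_genes = 20, times = c(1, 2, 3), reps = 3,
                           n_control = 3, mu = 6, sd = 1, seed = 1) {
  set.seed(seed)
  t_ids <- unlist(lapply(times, function(t) sprintf("T%d_r%d", t, 1:reps)))
  c_ids <- sprintf("C_r%d", seq_len(n_control))
  X <- matrix(rnorm(n_genes * (length(t_ids) + n_control), mu, sd),
              n_genes, length(t_ids) + n_control,
              dimnames = list(sprintf("g%03d", 1:n_genes), c(t_ids, c_ids)))
  sheet <- sample_sheet(c(t_ids, c_ids),
                        c(rep("treated", length(t_ids)),
                          rep("control", n_control)),
                        c(rep(times, each = reps), rep(times[1], n_control)))
  list(dataset = expression_dataset(X, "log2"), sheet = sheet)
}

# Reference (brute-force) composite index: explicit loops over all pairs.
brute_ci <- function(X, module_idx, eps = 1e-6) {
  n <- nrow(X)
  sds <- apply(X, 1, stats::sd)
  outside <- setdiff(seq_len(n), module_idx)
  pin <- c()
  for (i in module_idx) for (j in module_idx) if (i < j) {
    r <- suppressWarnings(stats::cor(X[i, ], X[j, ]))
    pin <- c(pin, if (is.na(r)) 0 else abs(r))
  }
  pout <- c()
  for (i in module_idx) for (j in outside) {
    r <- suppressWarnings(stats::cor(X[i, ], X[j, ]))
    pout <- c(pout, if (is.na(r)) 0 else abs(r))
  }
  pcc_in <- mean(pin); pcc_out <- mean(pout)
  sd_in <- mean(sds[module_idx])
  list(pcc_in = pcc_in, pcc_out = pcc_out, sd_in = sd_in,
       ci = pcc_in * sd_in / max(pcc_out, eps))
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))
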