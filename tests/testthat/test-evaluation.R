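test_that("auc_roc matches hand-checked cases and handles ties", {
  expect_equal(auc_roc(c(0.9, 0.1), c(1, 0)), 1.0)
  expect_equal(auc_roc(c(0.5, 0.5), c(1, 0)), 0.5)
  expect_equal(auc_roc(c(3, 1, 2), c(1, 0, 1)), 1.0)
  expect_equal(auc_roc(c(1, 3, 2), c(1, 0, 1)), 0.0)
  expect_true(is.na(auc_roc(c(1, 2), c(1, 1))))
  expect_true(is.na(auc_roc(c(1, 2), c(0, 0))))
})

test_that("auc_roc equals the brute-force pairwise oracle and pROC", {
  set.seed(41)
  for (rep in 1:200) {
    n <- sample(2:12, 1)
    scores <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # force ties
    labels <- sample(0:1, n, replace = TRUE)
    expected <- brute_auc(scores, labels)
    got <- auc_roc(scores, labels)
    if (is.na(expected)) expect_true(is.na(got))
    else expect_equal(got, expected, tolerance = 1e-12)
  }
  # one independent library cross-check on a non-trivial tied instance
  scores <- c(0.2, 0.8, 0.5, 0.5, 0.1, 0.9)
  labels <- c(0, 1, 0, 1, 0, 1)
  expect_equal(auc_roc(scores, labels),
               as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE))))
})

test_that("auc_roc is rank-invariant and complementary without ties", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(4:12, 1)
    scores <- runif(n)
    labels <- c(1, 0, sample(0:1, n - 2, replace = TRUE))
    a <- auc_roc(scores, labels)
    expect_equal(auc_roc(exp(3 * scores) + 5, labels), a)  # monotone transform
    expect_equal(auc_roc(-scores, labels), 1 - a, tolerance = 1e-12)
  }
})

test_that("oracle attributions achieve AUC 1 on labeled synthetic peaks", {
  ds <- generate_dataset(30, seed = 43)
  peaks <- collect_labeled_peaks(ds)
  n_checked <- 0
  for (p in peaks) {
    for (ch in c("core", "virtual")) {
      w <- p$labels[[paste0(ch, "_weights")]]
      lab <- p$labels[[paste0(ch, "_labels")]]
      a <- auc_roc(w, lab)
      if (!is.na(a)) {
        expect_equal(a, 1.0)
        n_checked <- n_checked + 1
      }
    }
  }
  expect_gt(n_checked, 20)
})

test_that("uniform-random attributions average to the 0.5 baseline", {
  ds <- generate_dataset(200, seed = 44)
  peaks <- collect_labeled_peaks(ds)
  set.seed(45)
  aucs <- c()
  for (p in peaks) {
    scores <- runif(p$entry$graph$n_atoms)
    a <- auc_roc(scores, p$labels$core_labels)
    if (!is.na(a)) aucs <- c(aucs, a)
    a <- auc_roc(scores, p$labels$virtual_labels)
    if (!is.na(a)) aucs <- c(aucs, a)
  }
  expect_gt(length(aucs), 300)
  expect_lt(abs(mean(aucs) - 0.5), 0.03)
})

test_that("explain_molecule scores an oracle attribution perfectly", {
  grid <- energy_grid(270, 300, 100)
  tr <- generate_transitions("CCO", seed = 46, molecule_id = "m")
  # oracle: spread each peak's ground-truth core weights over the grid
  spec <- broaden(tr$sticks, grid)
  oracle <- matrix(0, tr$graph$n_atoms, grid$n_grid)
  for (pk in find_peaks(spec)) {
    if (!length(assign_sticks_to_peak(tr$sticks, pk))) next
    lab <- labels_for_peak(tr$sticks, tr$transitions, pk, tr$graph$n_atoms)
    oracle[, pk$window] <- lab$core_weights / length(pk$window)
  }
  ex <- explain_molecule(NULL, tr$graph, tr$sticks, tr$transitions, grid,
                         attribution = oracle)
  expect_gt(length(ex), 0)
  for (pe in ex) {
    if (!is.na(pe$auc_core)) expect_equal(pe$auc_core, 1.0)
  }
})

test_that("explanation reports aggregate only defined AUC values", {
  mk_pe <- function(ac, av) structure(
    list(molecule_id = "m", peak = NULL, cam_peak_scores = NULL,
         labels = NULL, auc_core = ac, auc_virtual = av),
    class = "peak_explanation")
  rep <- explain_report(list(
    list(mk_pe(1.0, 0.5), mk_pe(NA_real_, 0.7)),
    list(mk_pe(0.6, NA_real_))
  ), rse_values = c(0.1, 0.2))
  expect_equal(rep$per_molecule$mean_auc_core, c(1.0, 0.6))
  expect_equal(rep$per_molecule$mean_auc_virtual, c(0.6, NA_real_))
  expect_equal(rep$per_molecule$n_undefined_core, c(1L, 0L))
  expect_equal(rep$mean_auc_core, 0.8)
  expect_equal(rep$mean_rse, 0.15)
})

test_that("RSE deciles split remainders over the first bins", {
  prof <- rse_decile_profile(seq_len(20) / 100, rep(0.7, 20))
  expect_equal(prof$n, rep(2L, 10))
  expect_equal(prof$mean_auc, rep(0.7, 10))

  prof25 <- rse_decile_profile(runif(25), runif(25))
  expect_equal(prof25$n, c(3L, 3L, 3L, 3L, 3L, 2L, 2L, 2L, 2L, 2L))
  expect_equal(sum(prof25$n), 25L)

  # AUC strictly decreasing in RSE gives strictly decreasing bin means
  r <- seq(0.01, 0.2, length.out = 30)
  a <- 1 - r
  prof30 <- rse_decile_profile(r, a)
  expect_true(all(diff(prof30$mean_auc) < 0))
  expect_true(all(diff(prof30$mean_rse) > 0))

  expect_error(rse_decile_profile(runif(9), runif(9)), "at least 10")
})

test_that("delta_auc computes the percentage change per channel", {
  mk_rep <- function(core, virt) structure(
    list(per_molecule = data.frame(), mean_auc_core = core,
         mean_auc_virtual = virt, mean_rse = NA_real_),
    class = "explain_report")
  expect_equal(delta_auc(mk_rep(0.8, 0.7), mk_rep(0.8, 0.7)),
               c(core = 0, virtual = 0))
  expect_equal(delta_auc(mk_rep(0.8, 0.7), mk_rep(0.6, 0.49)),
               c(core = -25, virtual = -30))
  expect_error(delta_auc(mk_rep(0, 0.7), mk_rep(0.6, 0.49)), "zero")
})
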