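make_tr <- function(state_id, energy, f, core_pop, virt_pop,
                    core_id = "c", virt_id = "v") {
  transition_record(
    state_id = state_id, energy = energy, osc_strength = f,
    pairs = list(list(core_mo = core_id, virtual_mo = virt_id, weight = 1)),
    mo_populations = stats::setNames(list(core_pop, virt_pop),
                                     c(core_id, virt_id))
  )
}

test_that("atom weights follow the oscillator-strength population sum", {
  # single transition fully on atom 2
  tr <- make_tr("s1", 285, 0.5, c(0, 0, 1), c(1, 0, 0))
  expect_equal(atom_weights(list(tr), "core", 3), c(0, 0, 1))
  expect_equal(atom_weights(list(tr), "virtual", 3), c(1, 0, 0))

  # two transitions f = 0.2 and 0.8 on different atoms' core MOs:
  # weights proportional 0.25 : 1 after max-normalization
  t1 <- make_tr("s1", 285, 0.2, c(1, 0), c(0.5, 0.5), "c1", "v1")
  t2 <- make_tr("s2", 286, 0.8, c(0, 1), c(0.5, 0.5), "c2", "v2")
  expect_equal(atom_weights(list(t1, t2), "core", 2), c(0.25, 1))

  # all-zero oscillator strengths give all-zero weights
  t0 <- make_tr("s1", 285, 0, c(1, 0), c(0, 1))
  expect_equal(atom_weights(list(t0), "core", 2), c(0, 0))

  expect_error(atom_weights(list(), "core", 2), "non-empty")
})

test_that("unnormalized channel weights sum to the total oscillator strength", {
  set.seed(31)
  for (rep in 1:10) {
    n <- sample(2:9, 1)
    trs <- lapply(1:3, function(s) {
      cp <- runif(n); vp <- runif(n)
      make_tr(sprintf("s%d", s), 280 + s, runif(1, 0.01, 0.2),
              cp / sum(cp), vp / sum(vp),
              sprintf("c%d", s), sprintf("v%d", s))
    })
    f_tot <- sum(vapply(trs, `[[`, numeric(1), "osc_strength"))
    raw_max <- function(channel) {
      w <- atom_weights(trs, channel, n)
      # undo max-normalization with an independent computation of the max
      raw <- Reduce(`+`, lapply(trs, function(tr) {
        mo <- if (channel == "core") tr$pairs[[1]]$core_mo
              else tr$pairs[[1]]$virtual_mo
        tr$osc_strength * tr$mo_populations[[mo]]
      }))
      expect_equal(w, raw / max(raw), tolerance = 1e-12)
      sum(raw)
    }
    expect_equal(raw_max("core"), f_tot, tolerance = 1e-12)
    expect_equal(raw_max("virtual"), f_tot, tolerance = 1e-12)
  }
})

test_that("channels are independent and labels scale-invariant", {
  t1 <- make_tr("s1", 285, 0.3, c(0.9, 0.1), c(0.2, 0.8))
  t2 <- make_tr("s1", 285, 0.3, c(0.9, 0.1), c(0.7, 0.3))  # virtual changed
  expect_equal(atom_weights(list(t1), "core", 2),
               atom_weights(list(t2), "core", 2))
  expect_false(isTRUE(all.equal(atom_weights(list(t1), "virtual", 2),
                                atom_weights(list(t2), "virtual", 2))))
  # scaling all oscillator strengths leaves labels unchanged
  t3 <- make_tr("s1", 285, 0.3 * 50, c(0.9, 0.1), c(0.2, 0.8))
  expect_equal(binarize(atom_weights(list(t1), "core", 2)),
               binarize(atom_weights(list(t3), "core", 2)))
})

test_that("binarization thresholds relative to the maximum, boundary inclusive", {
  expect_equal(binarize(c(1, 0, 0), 0.1), c(1L, 0L, 0L))
  expect_equal(binarize(c(0, 0, 0), 0.1), c(0L, 0L, 0L))
  expect_equal(binarize(c(1, 0.1, 0.09), 0.1), c(1L, 1L, 0L))
  expect_error(binarize(c(1, 0), 0), "0, 1")
  expect_error(binarize(c(1, 0), 1), "0, 1")
})

test_that("a missing orbital population is reported by name", {
  tr <- make_tr("s1", 285, 0.5, c(1, 0), c(0, 1))
  tr$mo_populations[["v"]] <- NULL
  expect_error(atom_weights(list(tr), "virtual", 2), "'v'")
})

test_that("peak labeling composes window assignment, weights and binarization", {
  grid <- energy_grid(270, 300, 100)
  # one transition localized on atom 1 in both channels
  tr <- make_tr("s1", 285, 0.1, c(1, 0, 0), c(1, 0, 0))
  sticks <- stick_spectrum(285, 0.1, molecule_id = "m")
  pk <- find_peaks(broaden(sticks, grid))[[1]]
  lab <- labels_for_peak(sticks, list(tr), pk, 3)
  expect_equal(lab$core_labels, c(1L, 0L, 0L))
  expect_equal(lab$virtual_labels, c(1L, 0L, 0L))
  expect_equal(lab$member_state_ids, "s1")

  # a peak window holding no sticks is an error
  empty_pk <- peak_region(275, 17, 0.8, window = 16:18)
  expect_error(labels_for_peak(sticks, list(tr), empty_pk, 3), "empty")
})

test_that("transition records validate and normalize their inputs", {
  expect_error(transition_record("s", 285, -0.1, list(), list()), "nonnegative")
  expect_error(transition_record("s", 285, 0.1, list(), list()), "orbital pair")
  # pair weights are normalized per transition
  tr <- transition_record("s", 285, 0.1,
    pairs = list(list(core_mo = "c1", virtual_mo = "v1", weight = 3),
                 list(core_mo = "c2", virtual_mo = "v2", weight = 1)),
    mo_populations = list(c1 = c(1, 0), v1 = c(0, 1),
                          c2 = c(0, 1), v2 = c(1, 0)))
  expect_equal(vapply(tr$pairs, `[[`, numeric(1), "weight"), c(0.75, 0.25))
  # populations off by more than 1e-6 are renormalized with a warning
  expect_warning(
    transition_record("s", 285, 0.1,
      pairs = list(list(core_mo = "c", virtual_mo = "v", weight = 1)),
      mo_populations = list(c = c(0.6, 0.3), v = c(0.5, 0.5))),
    "renormalizing")
})

test_that("transition records round-trip through JSON lines", {
  trs <- list(
    make_tr("s1", 284.5, 0.05, c(0.92, 0.08), c(0.5, 0.5)),
    transition_record("s2", 290.25, 0.011,
      pairs = list(list(core_mo = "c1", virtual_mo = "v1", weight = 0.6),
                   list(core_mo = "c1", virtual_mo = "v2", weight = 0.4)),
      mo_populations = list(c1 = c(1, 0), v1 = c(0.25, 0.75),
                            v2 = c(0.5, 0.5)))
  )
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_transitions_jsonl(trs, path)
  back <- read_transitions_jsonl(path)
  expect_length(back, 2)
  expect_equal(back[[1]]$energy, 284.5)
  expect_equal(back[[2]]$pairs[[1]]$weight, 0.6)
  expect_equal(back[[2]]$mo_populations$v1, c(0.25, 0.75))
  expect_equal(back[[1]]$osc_strength, trs[[1]]$osc_strength)
})
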