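test_that("CSV event round-trip is lossless and preserves marker names", {
  dir <- withr::local_tempdir()
  ev <- one_sample(cells = 80L, seed = 6L)
  path <- file.path(dir, "s.csv")
  write_events(ev, path)
  back <- read_events(path)
  expect_equal(back$exprs, ev$exprs, ignore_attr = TRUE)
  expect_identical(colnames(back$exprs), colnames(ev$exprs))
  expect_identical(back$channels$role, ev$channels$role)
  expect_identical(back$sample_id, ev$sample_id)
  # bare CSV without sidecar: shape contract + role inference
  m <- matrix(c(1, 2, 3, 4, 5, 6), 3, 2,
              dimnames = list(NULL, c("CD3", "DNA1_Ir191")))
  write.csv(as.data.frame(m), file.path(dir, "bare.csv"),
            row.names = FALSE)
  bare <- read_events(file.path(dir, "bare.csv"))
  expect_equal(dim(bare$exprs), c(3L, 2L))
  expect_identical(bare$channels$role, c("lineage", "DNA"))
  expect_error(read_events(file.path(dir, "nope.csv")), "no such file")
})

test_that("unknown channels warn and get role 'unassigned'", {
  expect_warning(roles <- channel_roles(c("CD3", "mystery_channel")),
                 "unassigned")
  expect_identical(roles, c("lineage", "unassigned"))
})

test_that("arcsinh transform has the right closed form and inverse", {
  ev <- one_sample(cells = 200L, seed = 7L)
  mk <- which(ev$channels$role %in% c("lineage", "functional"))
  raw <- ev$exprs
  tr <- arcsinh_transform(ev, cofactor = 5)
  # x = 0 -> 0 and x = cofactor -> asinh(1) = log(1 + sqrt(2))
  expect_equal(asinh(0), 0)
  probe <- ev
  probe$exprs[1, mk[1]] <- 5
  expect_equal(unname(arcsinh_transform(probe)$exprs[1, mk[1]]),
               log(1 + sqrt(2)))
  # inverse recovers raw to machine precision
  expect_equal(5 * sinh(tr$exprs[, mk]), raw[, mk], tolerance = 1e-12)
  # structural channels untouched
  stru <- setdiff(seq_len(ncol(raw)), mk)
  expect_identical(tr$exprs[, stru], raw[, stru])
  # strictly increasing
  xs <- sort(runif(50, 0, 100))
  expect_true(all(diff(asinh(xs / 5)) > 0))
  expect_error(arcsinh_transform(one_sample(50), cofactor = 0),
               "positive")
  expect_error(arcsinh_transform(tr), "already transformed")
})

test_that("gating retains everything under a vacuous config and is exact on fixtures", {
  ev <- one_sample(cells = 300L, seed = 8L)
  vac <- gate_events(ev, gate_config())
  expect_equal(nrow(vac$events$exprs), 300L)
  expect_equal(vac$report$removed, 0)

  # 10 injected dead cells -> exactly those removed by the viability rule
  dead <- inject_artifacts(one_sample(cells = 100L, seed = 9L),
                           dead_rate = 0.1, seed = 10L)
  g <- gate_events(dead, fixture_gate())
  expect_equal(unname(g$report$flagged["viability"]), 10)
  expect_equal(g$report$removed, 10)
  expect_false(any(g$events$truth$dead))

  # injected doublets removed via DNA/event-length rules
  dbl <- inject_artifacts(one_sample(cells = 200L, seed = 11L),
                          doublet_rate = 0.1, seed = 12L)
  g2 <- gate_events(dbl, fixture_gate())
  expect_equal(g2$report$removed, 20)
  expect_false(any(g2$events$truth$doublet))
  expect_gte(unname(g2$report$flagged["dna"]), 20)

  # accounting identity: exclusive counts + multiply-flagged = removed
  both <- inject_artifacts(one_sample(cells = 400L, seed = 13L),
                           doublet_rate = 0.05, dead_rate = 0.05,
                           seed = 14L)
  g3 <- gate_events(both, fixture_gate())
  expect_equal(sum(g3$report$exclusive) + g3$report$multi,
               g3$report$removed)
  expect_equal(g3$report$retained + g3$report$removed, 400)
  expect_error(gate_events(arcsinh_transform(one_sample(50))),
               "raw intensities")
})

test_that("default gates are derived from robust statistics", {
  ev <- one_sample(cells = 500L, seed = 15L)
  cfg <- default_gate_config(ev)
  expect_lt(cfg$dna_min, cfg$dna_max)
  expect_true(is.finite(cfg$event_length_max))
  clean <- gate_events(ev, cfg)
  # clean synthetic data: only a small tail is cut
  expect_lt(clean$report$removed / 500, 0.1)
})

test_that("bead normalization inverts a linear sensitivity decay", {
  ev <- one_sample(cells = 800L, seed = 16L)
  withbeads <- add_bead_events(ev, n_beads = 400L, seed = 17L)
  # identity drift: output equals input minus bead events
  norm0 <- bead_normalize(withbeads, n_windows = 4L)
  expect_equal(nrow(norm0$exprs), 800L)
  rep0 <- attr(norm0, "bead_report")
  expect_equal(rep0$n_beads, 400L)

  # 20% linear decay: post-normalization bead medians constant within 1%
  drifted <- apply_sensitivity_drift(withbeads, total_decay = 0.2)
  norm <- bead_normalize(drifted, n_windows = 8L)
  rep <- attr(norm, "bead_report")
  bead_col <- "bead_Ce140"
  meds <- rep$bead_medians[, bead_col]
  expect_true(all(abs(meds / rep$reference[[bead_col]] - 1) < 0.01))

  # no beads: warn and pass through
  expect_warning(same <- bead_normalize(ev), "no bead events")
  expect_identical(same$exprs, ev$exprs)

  # all-bead input: empty cell output
  allbead <- add_bead_events(
    cell_events("empty",
                ev$exprs[0, , drop = FALSE], ev$channels),
    n_beads = 50L, seed = 18L)
  emptied <- bead_normalize(allbead, n_windows = 2L)
  expect_equal(nrow(emptied$exprs), 0L)
})

test_that("gate decisions are unaffected by transformation order", {
  # gates act on raw scale: the retained raw events, transformed, equal
  # the result of the normalize -> gate -> transform pipeline
  ev <- inject_artifacts(one_sample(cells = 300L, seed = 19L),
                         doublet_rate = 0.05, dead_rate = 0.05,
                         seed = 20L)
  cfg <- fixture_gate()
  direct <- arcsinh_transform(gate_events(ev, cfg)$events)
  piped <- preprocess_events(ev, cfg = cfg)
  expect_identical(direct$exprs, piped$events$exprs)
})
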