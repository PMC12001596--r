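test_that("condition permutation acts at the individual level and preserves values", {
  qt <- toy_qt(seed = 71, n_ind = 6L)
  out <- permute_condition(qt, seed = 1)
  expect_identical(out$values, qt$values)
  # each individual keeps one label; label multiset preserved
  lab <- tapply(as.character(out$design$condition), out$design$individual,
                unique)
  expect_true(all(lengths(lab) == 1L))
  expect_equal(sort(table(unlist(lab))),
               sort(table(tapply(as.character(qt$design$condition),
                                 qt$design$individual, unique))),
               ignore_attr = TRUE)
  # determinism under a fixed seed
  expect_identical(permute_condition(qt, seed = 9)$design,
                   permute_condition(qt, seed = 9)$design)
})

test_that("with two individuals both label assignments occur across seeds", {
  qt <- toy_qt(seed = 72, n_ind = 2L)
  seen <- vapply(1:20, function(s) {
    paste(tapply(as.character(permute_condition(qt, seed = s)$design$condition),
                 permute_condition(qt, seed = s)$design$individual, unique),
          collapse = "")
  }, "")
  expect_setequal(unique(seen), c("ctltrt", "trtctl"))
  # single condition: unchanged with a warning
  d <- toy_design(n_ind = 2L, conditions = "only")
  v <- matrix(runif(12), 6, 2, dimnames = list(d$sample_id, c("m1", "m2")))
  q1 <- quant_table(v, d)
  expect_warning(out <- permute_condition(q1), "single condition")
  expect_identical(out$design, q1$design)
})

test_that("time erasure repeats the first-time block and applies range-scaled noise", {
  qt <- toy_qt(seed = 73, n_ind = 6L)
  z <- erase_time(qt, noise_factor = 0)
  for (tt in c("t2", "t3")) {
    expect_equal(z$values[z$design$time == tt, ],
                 z$values[z$design$time == "t1", ],
                 ignore_attr = TRUE)
  }
  # noise variance: empirical check over ~10^4 cells, values kept away
  # from 0 so the nonnegativity floor does not truncate the noise
  d <- toy_design(n_ind = 25L, times = c("t1", "t2"))
  set.seed(73)
  v <- matrix(runif(50 * 200, min = 5, max = 12), 50, 200,
              dimnames = list(d$sample_id, sprintf("x%03d", 1:200)))
  qt2 <- quant_table(v, d)
  out <- erase_time(qt2, noise_factor = 0.05, seed = 74)
  det <- v[qt2$design$time == "t1", ][rep(1:25, 2), ]
  s2 <- 0.05 * (max(v) - min(v))
  emp <- var(as.vector(out$values - det))
  expect_equal(emp, s2, tolerance = 0.05)
  # an individual missing the first time point is an error
  qt3 <- toy_qt(seed = 75, n_ind = 4L)
  keep <- !(qt3$design$individual == "i02" & qt3$design$time == "t1")
  qt3 <- quant_table(qt3$values[qt3$design$sample_id[keep], ],
                     qt3$design[keep, ])
  expect_error(erase_time(qt3, seed = 1), "i02")
})

test_that("condition injection multiplies target cells by the per-condition factor", {
  qt <- toy_qt(seed = 76, n_ind = 6L)
  g <- condition_gamma(1, c("ctl", "trt"))     # scenario 1: 1 / 10
  out <- inject_condition_effect(qt, c("met_01", "met_02"), g)
  trt <- qt$design$condition == "trt"
  expect_equal(out$values[trt, "met_01"], 10 * qt$values[trt, "met_01"])
  expect_equal(out$values[!trt, "met_01"], qt$values[!trt, "met_01"])
  expect_identical(out$values[, -(1:2)], qt$values[, -(1:2)])
  # scenario 3 doubles; identity gammas change nothing
  g3 <- condition_gamma(3, c("ctl", "trt"))
  expect_equal(unname(g3), c(1, 2))
  out1 <- inject_condition_effect(qt, "met_01", c(ctl = 1, trt = 1))
  expect_identical(out1$values, qt$values)
  expect_error(inject_condition_effect(qt, "met_01", c(ctl = 1, oops = 2)),
               "unknown condition")
})

test_that("time injection rebuilds targets from the repeated first-time block", {
  qt <- toy_qt(seed = 77, n_ind = 6L)
  g <- time_gamma(1, levels(qt$design$time))   # 1, 5, 10
  out <- inject_time_effect(qt, c("met_01", "met_02"), g,
                            noise_factor = 0, nontargets = "keep")
  t1 <- qt$values[qt$design$time == "t1", c("met_01", "met_02")]
  expect_equal(out$values[out$design$time == "t2", c("met_01", "met_02")],
               5 * t1, ignore_attr = TRUE)
  expect_equal(out$values[out$design$time == "t3", c("met_01", "met_02")],
               10 * t1, ignore_attr = TRUE)
  expect_identical(out$values[, -(1:2)], qt$values[, -(1:2)])
  # identity gammas at zero noise coincide with zero-noise time erasure
  out2 <- inject_time_effect(qt, colnames(qt$values),
                             stats::setNames(c(1, 1, 1), levels(qt$design$time)),
                             noise_factor = 0)
  expect_equal(out2$values, erase_time(qt, noise_factor = 0)$values,
               tolerance = 1e-12)
  # default mode erases non-target time signal too (plus same-law noise)
  out3 <- inject_time_effect(qt, c("met_01", "met_02"), g,
                             noise_factor = 0, nontargets = "erase")
  expect_equal(out3$values[, -(1:2)],
               erase_time(qt, noise_factor = 0)$values[, -(1:2)])
})

test_that("H1 construction selects k pathways and injects exactly their union", {
  spec <- generator_spec(seed = 78)
  base <- generate_dataset(spec)
  sp <- scenario_spec("condition", "H1",
                      gamma_d = condition_gamma(3, c("control", "treated")),
                      k = 3, seed = 78)
  h1 <- make_h1_dataset(base$qt, base$pathways, sp)
  expect_length(h1$selected_pathways, 3L)
  expect_setequal(h1$target_metabolites,
                  unique(unlist(base$pathways$pathways[h1$selected_pathways])))
  # only target columns changed
  changed <- colnames(base$qt$values)[
    colSums(h1$qt$values != base$qt$values) > 0]
  expect_true(all(changed %in% h1$target_metabolites))
  # determinism
  h1b <- make_h1_dataset(base$qt, base$pathways, sp)
  expect_identical(h1$selected_pathways, h1b$selected_pathways)
  expect_identical(h1$qt$values, h1b$qt$values)
  expect_error(make_h1_dataset(base$qt, base$pathways,
                               scenario_spec("condition", "H1",
                                             gamma_d = c(control = 1, treated = 2),
                                             k = 99, seed = 1)),
               "k exceeds")
})

test_that("condition_time mode composes the two injections in the stated order", {
  spec <- generator_spec(seed = 79)
  base <- generate_dataset(spec)
  g_d <- condition_gamma(1, c("control", "treated"))
  g_t <- time_gamma(2, c("t1", "t2", "t3"))
  sp <- scenario_spec("condition_time", "H1", gamma_d = g_d, gamma_t = g_t,
                      noise_factor = 0, seed = 80)
  h1 <- make_h1_dataset(base$qt, base$pathways, sp)
  # oracle: same pathway draw, explicit time-then-condition composition
  set.seed(80)
  sel <- sample(names(base$pathways$pathways), 3)
  targets <- unique(unlist(base$pathways$pathways[sel]))
  manual <- inject_condition_effect(
    inject_time_effect(base$qt, targets, g_t, noise_factor = 0),
    targets, g_d)
  expect_identical(h1$selected_pathways, sel)
  expect_equal(h1$qt$values, manual$values, tolerance = 1e-12)
})

test_that("pathway-size datasets alter exactly p_tilde members of the largest pathway", {
  spec <- generator_spec(seed = 81)
  base <- generate_dataset(spec)
  g_d <- condition_gamma(1, c("control", "treated"))
  big <- names(which.max(lengths(base$pathways$pathways)))
  big_size <- max(lengths(base$pathways$pathways))
  expect_equal(big_size, 32L)
  for (pt in c(1L, big_size)) {
    sp <- scenario_spec("condition", "VSize", gamma_d = g_d,
                        p_tilde = pt, seed = 82)
    vs <- make_vsize_dataset(base$qt, base$pathways, sp)
    expect_equal(vs$vsize_pathway, big)
    expect_length(vs$vsize_members, pt)
    changed <- colnames(base$qt$values)[
      colSums(vs$qt$values != base$qt$values) > 0]
    expect_true(all(changed %in% vs$target_metabolites))
    expect_length(vs$selected_pathways, 2L)  # the k - 1 others
  }
  # p_tilde = size is full-pathway injection for the largest pathway
  sp_full <- scenario_spec("condition", "VSize", gamma_d = g_d,
                           p_tilde = big_size, seed = 82)
  vs_full <- make_vsize_dataset(base$qt, base$pathways, sp_full)
  expect_setequal(vs_full$vsize_members, base$pathways$pathways[[big]])
  expect_error(scenario_spec("condition", "VSize", gamma_d = g_d,
                             p_tilde = 0, seed = 1),
               "p_tilde")
})

test_that("every transform yields a valid quantification table", {
  spec <- generator_spec(seed = 83)
  base <- generate_dataset(spec)
  g_d <- condition_gamma(2, c("control", "treated"))
  g_t <- time_gamma(3, c("t1", "t2", "t3"))
  outs <- list(
    permute_condition(base$qt, seed = 1),
    erase_time(base$qt, seed = 2),
    make_h0_dataset(base$qt, "condition_time", seed = 3),
    make_h1_dataset(base$qt, base$pathways,
                    scenario_spec("time", "H1", gamma_t = g_t, seed = 4))$qt,
    make_h1_dataset(base$qt, base$pathways,
                    scenario_spec("condition", "H1", gamma_d = g_d,
                                  seed = 5))$qt)
  for (o in outs) {
    expect_s3_class(o, "quant_table")
    expect_true(all(o$values >= 0))
    expect_equal(dim(o), dim(base$qt))
  }
})
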