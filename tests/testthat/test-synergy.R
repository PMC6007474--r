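test_that("normalization maps the control mean to 1 and is idempotent", {
  tab <- data.frame(group = c("control", "control", "A"),
                    replicate = c(1, 2, 1), value = c(100, 100, 80))
  n1 <- normalize_viability(tab)
  expect_identical(n1$value, c(1, 1, 0.8))
  expect_identical(normalize_viability(n1)$value, n1$value)
  # arithmetic oracle on a randomized table
  set.seed(1)
  tab2 <- data.frame(group = rep(c("control", "A", "B"), each = 4),
                     replicate = rep(1:4, 3), value = runif(12, 50, 150))
  expect_identical(normalize_viability(tab2)$value,
                   tab2$value / mean(tab2$value[tab2$group == "control"]))
  bad <- data.frame(group = c("control", "control"), replicate = 1:2,
                    value = c(-5, 5))
  expect_error(normalize_viability(bad), "positive")
})

test_that("projected-additive products follow Bliss independence", {
  expect_equal(projected_additive(0.8, 0.7, pairing = "pairwise"), 0.56)
  expect_equal(sort(projected_additive(c(0.9, 0.8), c(0.6, 0.5),
                                       pairing = "pairwise")),
               sort(c(0.54, 0.45, 0.48, 0.40)))
  # brute-force enumeration oracle
  set.seed(2)
  fa <- runif(4); fb <- runif(3)
  got <- projected_additive(fa, fb, pairing = "pairwise")
  oracle <- vapply(seq_along(fa), function(i) fa[i] * fb, numeric(3))
  expect_identical(sort(got), sort(as.vector(oracle)))
  # identity element and symmetry
  expect_identical(sort(projected_additive(c(1, 1, 1), fb[1:3],
                                           pairing = "pairwise")),
                   sort(rep(fb[1:3], 3)))
  expect_identical(sort(projected_additive(fa, fb, "pairwise")),
                   sort(projected_additive(fb, fa, "pairwise")))
  # matched pairing multiplies index-wise
  expect_equal(projected_additive(c(0.9, 0.8), c(0.6, 0.5)), c(0.54, 0.40))
  expect_error(projected_additive(c(0.9, 0.8), c(0.6, 0.5, 0.4)), "equal")
  expect_error(projected_additive(c(-0.1, 0.5), c(0.5, 0.5)), "non-negative")
})

test_that("projected fractions never exceed either single-agent mean", {
  for (s in 1:20) {
    set.seed(s)
    fa <- runif(6, 0.2, 1); fb <- runif(6, 0.2, 1)
    proj <- projected_additive(fa, fb, pairing = "pairwise")
    expect_lte(max(proj), min(mean(fa), mean(fb)) +
                 max(fa) * max(fb) - min(fa) * min(fb) + 1e-12)
    expect_lte(mean(proj), min(mean(fa), mean(fb)) + 1e-12)
  }
})

test_that("identical samples are additive; separated samples classify by direction", {
  x <- c(0.5, 0.52, 0.48, 0.51)
  call <- classify_interaction(x, x)
  expect_identical(call$classification, "additive")
  lower <- classify_interaction(x - 0.3, x)
  expect_identical(lower$classification, "synergistic")
  higher <- classify_interaction(x + 0.3, x)
  expect_identical(higher$classification, "antagonistic")
  # degenerate zero-variance identical samples: additive with p = 1, flagged
  deg <- classify_interaction(rep(0.5, 3), rep(0.5, 3))
  expect_identical(deg$classification, "additive")
  expect_identical(deg$p_value, 1)
  expect_true(deg$degenerate)
})

test_that("false non-additive rate under Bliss truth is near alpha", {
  calls <- vapply(1:150, function(s) {
    tab <- normalize_viability(make_viability_table(viability_sim_spec(
      interaction = "bliss", seed = s)))
    proj <- projected_additive(tab$value[tab$group == "A"],
                               tab$value[tab$group == "B"],
                               fc = tab$value[tab$group == "control"])
    classify_interaction(tab$value[tab$group == "AB"], proj)$classification
  }, character(1))
  rate <- mean(calls != "additive")
  # 99% binomial band around 0.05 at n = 150
  expect_lt(abs(rate - 0.05), 2.576 * sqrt(0.05 * 0.95 / 150))
})

test_that("a 0.2 synergistic shift is detected with high power", {
  calls <- vapply(1:100, function(s) {
    tab <- normalize_viability(make_viability_table(viability_sim_spec(
      interaction = "synergistic", interaction_shift = 0.2, seed = s + 5000)))
    proj <- projected_additive(tab$value[tab$group == "A"],
                               tab$value[tab$group == "B"],
                               fc = tab$value[tab$group == "control"])
    classify_interaction(tab$value[tab$group == "AB"], proj)$classification
  }, character(1))
  expect_gte(mean(calls == "synergistic"), 0.9)
})

test_that("power is monotone in the interaction shift", {
  rate_at <- function(shift) {
    calls <- vapply(1:60, function(s) {
      tab <- normalize_viability(make_viability_table(viability_sim_spec(
        interaction = "synergistic", interaction_shift = shift,
        seed = s + 900)))
      proj <- projected_additive(tab$value[tab$group == "A"],
                                 tab$value[tab$group == "B"],
                                 fc = tab$value[tab$group == "control"])
      classify_interaction(tab$value[tab$group == "AB"],
                           proj)$classification == "synergistic"
    }, logical(1))
    mean(calls)
  }
  rates <- vapply(c(0.05, 0.12, 0.25), rate_at, numeric(1))
  expect_true(all(diff(rates) >= 0))
})

test_that("multi-dose reports recover generator truths at low noise", {
  specs <- list(
    synergistic = viability_sim_spec(interaction = "synergistic",
                                     interaction_shift = 0.2, cv = 0.02,
                                     dose = "d1", seed = 71),
    bliss = viability_sim_spec(interaction = "bliss", cv = 0.02,
                               dose = "d2", seed = 72),
    antagonistic = viability_sim_spec(interaction = "antagonistic",
                                      interaction_shift = 0.2, cv = 0.02,
                                      dose = "d3", seed = 73))
  tabs <- lapply(specs, make_viability_table)
  shared <- tabs[[1]][tabs[[1]]$group %in% c("control", "A"), ]
  combined <- rbind(shared,
                    do.call(rbind, lapply(tabs, function(t)
                      t[t$group %in% c("B", "AB"), ])))
  rep_df <- synergy_report(combined)
  expect_identical(nrow(rep_df), 3L)
  got <- rep_df$classification[match(c("d1", "d2", "d3"), rep_df$dose)]
  expect_identical(got, c("synergistic", "additive", "antagonistic"))
  # per-dose mode agrees at this effect size
  rep_pd <- synergy_report(combined, multiplicity = "per_dose")
  expect_identical(rep_pd$classification[match(c("d1", "d2", "d3"), rep_pd$dose)],
                   c("synergistic", "additive", "antagonistic"))
})

test_that("empty dose lists and missing groups are handled as documented", {
  tab <- make_viability_table(viability_sim_spec(dose = "d1", seed = 2))
  expect_identical(nrow(synergy_report(tab, dose_levels = character(0))), 0L)
  no_b <- tab[!(tab$group == "B"), ]
  expect_warning(out <- synergy_report(no_b), "skipped")
  expect_identical(nrow(out), 0L)
})
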