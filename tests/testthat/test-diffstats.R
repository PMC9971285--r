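design3 <- experiment_design(3L)

counts_tbl <- function(...) {
  # build a per-sample count table from named vectors: list(acc = c(sample = n))
  args <- list(...)
  dplyr::bind_rows(purrr::imap(args, function(v, acc) {
    tibble::tibble(accession = acc, sample = names(v), unique_peptides = unname(v))
  }))
}

test_that("the inclusion/exclusion rules behave as stated on hand-built cases", {
  tbl <- counts_tbl(
    bg = c(PBS_1 = 2, OPP_vehicle_1 = 5, OPP_vehicle_2 = 5),
    ok = c(PBS_1 = 1, PBS_2 = 1, PBS_3 = 1, OPP_vehicle_1 = 2, OPP_vehicle_2 = 3),
    split = c(OPP_vehicle_1 = 4, OPP_inhibitor_1 = 4)
  )
  got <- filter_nascent(tbl, design3)
  expect_identical(got$kept, "ok")
  expect_setequal(got$excluded$accession, c("bg", "split"))
  expect_identical(
    got$excluded$reason[got$excluded$accession == "bg"], "background"
  )
  # one qualifying replicate per condition is not enough: the rule requires
  # two within a single condition
  expect_identical(
    got$excluded$reason[got$excluded$accession == "split"],
    "insufficient_replication"
  )
  expect_error(
    filter_nascent(counts_tbl(x = c(nonsample = 1)), design3),
    "not in design"
  )
})

test_that("filter_nascent agrees with the literal rule oracle on random tables", {
  withr::with_seed(53, {
    for (i in 1:1000) {
      n_prot <- sample(1:6, 1)
      tbl <- tidyr::expand_grid(
        accession = paste0("P", seq_len(n_prot)),
        sample = design3$sample
      )
      tbl$unique_peptides <- sample(0:4, nrow(tbl), replace = TRUE)
      tbl <- tbl[runif(nrow(tbl)) > 0.3, ] # some proteins miss some samples
      if (nrow(tbl) == 0) next
      got <- filter_nascent(tbl, design3)
      want <- oracle_filter(tbl, design3)
      expect_setequal(got$kept, want)
    }
  })
})

test_that("log2 ratios pair replicates and respect missingness", {
  intens <- tibble::tibble(
    accession = "P",
    sample = c("OPP_vehicle_1", "OPP_inhibitor_1", "OPP_vehicle_2", "OPP_inhibitor_3"),
    summed_intensity = c(100, 50, 80, 120)
  )
  got <- log2_ratios(intens, design3)
  expect_identical(got$log2_ratio[got$replicate == 1], -1)
  expect_true(is.na(got$log2_ratio[got$replicate == 2])) # inhibitor missing
  expect_true(is.na(got$log2_ratio[got$replicate == 3])) # vehicle missing
  same <- log2_ratios(
    tibble::tibble(
      accession = "P",
      sample = c("OPP_vehicle_1", "OPP_inhibitor_1"),
      summed_intensity = c(64, 64)
    ),
    design3
  )
  expect_identical(same$log2_ratio[same$replicate == 1], 0)
})

test_that("median centering aligns every replicate to the pooled median", {
  ratios <- tibble::tibble(
    accession = rep(c("a", "b", "c"), 2),
    replicate = rep(1:2, each = 3),
    log2_ratio = c(0, 1, 2, 2, 3, 4)
  )
  got <- median_center(ratios)
  expect_equal(got$log2_ratio[got$replicate == 1], c(1, 2, 3))
  expect_equal(got$log2_ratio[got$replicate == 2], c(1, 2, 3))
  g <- median(got$log2_ratio)
  for (r in 1:2) {
    expect_lt(abs(median(got$log2_ratio[got$replicate == r]) - g), 1e-12)
  }
  # identical columns are a fixed point
  same <- ratios
  same$log2_ratio <- rep(c(0, 1, 2), 2)
  expect_equal(median_center(same)$log2_ratio, same$log2_ratio)
  # adding a constant shifts the center but not the shape
  shifted <- ratios
  shifted$log2_ratio <- ratios$log2_ratio + 5
  expect_equal(
    median_center(shifted)$log2_ratio - median_center(ratios)$log2_ratio,
    rep(5, 6)
  )
  allna <- ratios
  allna$log2_ratio[allna$replicate == 2] <- NA
  expect_error(median_center(allna), "no non-missing")
})

test_that("the one-sample t test matches its closed form and flags degenerate input", {
  got <- one_sample_ttest(c(0.5, 1.0, 1.5))
  expect_equal(round(got$t, 4), 3.4641)
  expect_equal(got$p_value, 2 * pt(-3.46410161513775, df = 2), tolerance = 1e-6)
  sym <- one_sample_ttest(c(-0.7, 0, 0.7))
  expect_equal(sym$t, 0)
  expect_equal(sym$p_value, 1)
  const <- one_sample_ttest(c(0.3, 0.3, 0.3))
  expect_false(const$tested)
  expect_true(is.na(const$p_value))
  expect_false(one_sample_ttest(c(1, NA, 2))$tested)
  expect_false(one_sample_ttest(0.5)$tested)
})

test_that("volcano classification uses strict cutoffs", {
  res <- tibble::tibble(
    log2_fc = c(-1.5, -1.5, 1.0, 2.0, 0.5),
    p_value = c(0.01, 0.2, 0.001, 0.01, 0.01),
    tested = c(TRUE, TRUE, TRUE, TRUE, TRUE)
  )
  got <- classify_volcano(res)
  expect_identical(
    as.character(got$class),
    c(
      "down_significant", "not_significant", "not_significant",
      "up_significant", "not_significant"
    )
  )
  un <- classify_volcano(tibble::tibble(log2_fc = -3, p_value = NA, tested = FALSE))
  expect_identical(as.character(un$class), "untested")
})

test_that("the full differential stage recovers simulated fold changes", {
  cfg <- sim_config(rng_seed = 61)
  q <- simulate_quant(cfg)
  dx <- diff_expression(q$protein_table, q$design)
  res <- dplyr::inner_join(tidy(dx), q$truth, by = "accession")
  nascent <- res[res$is_nascent, ]
  for (fc in unique(na.omit(nascent$true_log2fc))) {
    grp <- nascent$log2_fc[nascent$true_log2fc == fc]
    expect_lt(abs(mean(grp, na.rm = TRUE) - fc), 0.2)
  }
  # no contaminant survives the filter
  expect_identical(sum(res$is_contaminant), 0L)
})

test_that("a strongly repressed translatome yields an asymmetric volcano", {
  cfg <- sim_config(
    fc_levels = c(-2, -1, 0, 1),
    fc_props = c(0.15, 0.15, 0.6, 0.1), # 30% repressed
    rng_seed = 67
  )
  q <- simulate_quant(cfg)
  dx <- diff_expression(q$protein_table, q$design)
  g <- glance(dx)
  expect_gt(g$n_down, g$n_up)
})
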