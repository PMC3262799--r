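test_that("simulation is deterministic under a fixed seed", {
  a <- simulate_cohort(small_config(seed = 5))
  b <- simulate_cohort(small_config(seed = 5))
  expect_identical(unclass(a$mirna), unclass(b$mirna))
  expect_identical(unclass(a$mrna), unclass(b$mrna))
  expect_identical(a$metadata, b$metadata)
  expect_identical(as.data.frame(a$predictions),
                   as.data.frame(b$predictions))
  expect_identical(a$truth$true_links, b$truth$true_links)
  c <- simulate_cohort(small_config(seed = 6))
  expect_false(identical(unclass(a$mrna), unclass(c$mrna)))
})

test_that("planted structure honours the design constraints", {
  co <- simulate_cohort(small_config(seed = 8))
  tr <- co$truth$specific_transcripts
  lin <- simulation_config()$lineages
  k3 <- tr[tr$k == 3, ]
  for (cts in strsplit(k3$cell_types, ";"))
    expect_equal(length(unique(lin[cts])), 1L)  # lineage-coherent
  # true and decoy links never overlap
  expect_equal(nrow(merge(co$truth$true_links, co$truth$decoy_links)), 0L)
  # predictions carry every true link plus decoys, confirmed by 2 sources
  key_pred <- paste(co$predictions$mirna_family, co$predictions$gene)
  expect_true(all(paste(co$truth$true_links$mirna,
                        co$truth$true_links$gene) %in% key_pred))
  expect_true(all(vapply(prediction_sources(co$predictions), length,
                         integer(1)) >= 2))
  # shared targets have two distinct regulators
  deg <- table(co$truth$true_links$gene)
  expect_equal(sum(deg == 2), 4L)
})

test_that("strong couplings force anti-correlated cell-type profiles", {
  co <- simulate_cohort(simulation_config(seed = 13))
  z_mi <- ztransform_profiles(co$mirna, co$metadata)
  z_mr <- ztransform_profiles(co$mrna, co$metadata)
  corr <- correlate_pairs(z_mi, z_mr)
  tl <- co$truth$true_links
  r_true <- corr$r[match(paste(tl$mirna, tl$gene),
                         paste(corr$mirna, corr$mrna))]
  expect_lt(mean(r_true), -0.55)
})

test_that("a null simulation has centred correlations and no calls", {
  cfg <- small_config(seed = 14, coupling_beta = 0)
  cfg$n_specific_up <- list(mirna = c(0, 0, 0), mrna = c(0, 0, 0))
  cfg$n_specific_down <- list(mirna = c(0, 0, 0), mrna = c(0, 0, 0))
  cfg$n_coupled_mirna <- 0
  cfg$n_shared_targets <- 0
  co <- simulate_cohort(cfg)
  calls <- call_cohort(co)
  expect_equal(nrow(calls$mirna) + nrow(calls$mrna), 0L)
  z_mi <- ztransform_profiles(co$mirna, co$metadata)
  z_mr <- ztransform_profiles(co$mrna, co$metadata)
  r <- correlate_pairs(z_mi, z_mr)$r
  expect_lt(abs(mean(r, na.rm = TRUE)), 0.05)
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(n_mirna = 5), "more specific")
  expect_error(simulation_config(n_mrna = 30), "more specific|planted")
  expect_error(simulation_config(n_coupled_mirna = 50), "n_coupled_mirna")
  expect_error(simulation_config(noise_sd = 0), "noise_sd")
})

test_that("the second cohort shares truth but not noise", {
  co <- simulate_cohort(small_config(seed = 15))
  b1 <- simulate_second_cohort(co$truth, seed = 99)
  b2 <- simulate_second_cohort(co$truth, seed = 99)
  expect_identical(unclass(b1$mrna), unclass(b2$mrna))
  b3 <- simulate_second_cohort(co$truth, seed = 100)
  expect_false(identical(unclass(b1$mrna), unclass(b3$mrna)))
  # default panel drops the dendritic subsets
  expect_setequal(unique(b1$metadata$cell_type),
                  c("Neutrophils", "Eosinophils", "Monocytes",
                    "T", "B", "NK"))
  expect_identical(rownames(b1$mirna), rownames(co$mirna))
  expect_error(simulate_second_cohort(co$truth, cell_types = "Platelets"),
               "no cell type")
  expect_error(simulate_second_cohort(list()), "simulate_cohort")
})

test_that("replicated-pair recovery across cohorts is high", {
  co <- simulate_cohort(small_config(seed = 16))
  second <- simulate_second_cohort(co$truth)
  pairs_for <- function(cohort) {
    z_mi <- matched_sample_profiles(cohort$mirna, cohort$metadata)
    z_mr <- matched_sample_profiles(cohort$mrna, cohort$metadata)
    corr <- correlate_pairs(z_mi, z_mr)
    cut <- calibrate_cutoff(z_mi, z_mr, seed = 3)
    preds <- filter_confirmed_predictions(co$predictions)
    do.call(rbind, lapply(unique(corr$mirna), function(m) {
      tl <- negcorr_target_list(corr, cut$cutoff, preds, m)
      if (nrow(tl)) data.frame(mirna = m, gene = tl$gene) else NULL
    }))
  }
  repl <- replicated_pairs(pairs_for(co), pairs_for(second))
  truth_key <- paste(co$truth$true_links$mirna, co$truth$true_links$gene)
  expect_gte(mean(truth_key %in% paste(repl$mirna, repl$gene)), 0.8)
})
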