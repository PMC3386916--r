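test_that("config validation enforces the stated world", {
  expect_error(sim_config(n_taxa = 1), "n_taxa")
  expect_error(sim_config(env_mixing_weight = 1.5), "env_mixing_weight")
  expect_error(sim_config(count_depth = 100), "250")
  expect_error(sim_config(clone_dropout_prob = -0.1), "\\[0, 1\\]")
  expect_error(sim_config(age_range_bp = c(5000, 700)), "increasing")
})

test_that("fixed seed gives byte-identical datasets", {
  cfg <- small_config(seed = 1)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_dataset(simulate_dataset(cfg), d1)
  write_dataset(simulate_dataset(cfg), d2)
  files <- list.files(d1)
  expect_setequal(files, list.files(d2))
  for (f in files)
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)),
                     label = paste("file", f))
})

test_that("pollen counts are exact multinomials at the stated depth", {
  sim <- simulate_dataset(small_config(seed = 2))
  expect_true(all(pollen_sums(sim$pollen) == 250))
  expect_true(all(sim$pollen$counts >= 0))
})

test_that("with no environmental mixing, proportions converge to the diet", {
  cfg <- sim_config(n_individuals = 1, events_per_individual = 1,
                    coprolites_per_event = 1, n_taxa = 10,
                    diet_subset_size = 5, env_mixing_weight = 0,
                    count_depth = 100000L, n_dna_samples = 0,
                    seed = 8)
  # with a single bird most taxa are legitimately undetected by any proxy
  sim <- suppressWarnings(simulate_dataset(cfg))
  phat <- sim$pollen$counts[1, sim$pollen$in_pollen_sum] / 100000
  expect_lt(max(abs(phat - sim$truth$diet[1, ])), 0.01)
})

test_that("haplotype map respects the two-haplotype world", {
  sim <- simulate_dataset(small_config(seed = 3,
                                       n_individuals = 5,
                                       events_per_individual = 1,
                                       age_range_bp = c(700, 6400)))
  tr <- sim$truth$assignments
  expect_length(unique(tr$individual), 5)
  expect_setequal(unique(tr$haplotype), c("C", "T"))
  # constant haplotype within individual
  for (i in unique(tr$individual))
    expect_length(unique(tr$haplotype[tr$individual == i]), 1)
  # more haplotypes can be requested for recovery experiments
  sim5 <- simulate_dataset(small_config(seed = 3, n_individuals = 5,
                                        events_per_individual = 1,
                                        age_range_bp = c(700, 6400),
                                        n_haplotypes = 5))
  expect_length(unique(sim5$truth$assignments$haplotype), 5)
})

test_that("event structure: shared ages within, separation between", {
  cfg <- small_config(seed = 4, n_individuals = 4,
                      events_per_individual = 2,
                      age_range_bp = c(700, 6400))
  sim <- simulate_dataset(cfg)
  tr <- sim$truth$assignments
  expect_true(all(table(tr$event) == cfg$coprolites_per_event))
  for (e in unique(tr$event))
    expect_length(unique(tr$age_true[tr$event == e]), 1)
  ev_ages <- unique(tr$age_true)
  expect_true(min(diff(sort(ev_ages))) >= cfg$min_age_separation - 1)
  # measured ages are curve values plus noise only
  mu <- tr$age_true # identity curve
  expect_true(all(abs(sim$ages$cra - mu) < 6 * cfg$age_error))
})

test_that("clone libraries come from the depositor's diet", {
  sim <- simulate_dataset(small_config(seed = 5))
  cl <- sim$rbcl$clones
  tr <- sim$truth$assignments
  if (nrow(cl)) {
    ind <- tr$individual[match(cl$coprolite, tr$coprolite)]
    props <- sim$truth$diet[cbind(ind, cl$taxon)]
    expect_true(all(props > 0))
    sizes <- table(cl$coprolite)
    expect_true(all(sizes >= 6 & sizes <= 10))
  }
  # depositor amplicons carry the planted haplotype base at site 25
  q <- sim$moa$queries
  base25 <- substr(q, 25, 25)
  planted <- tr$haplotype[match(names(q), tr$coprolite)]
  expect_equal(unname(base25), planted)
})

test_that("registry flags are consistent with the generated data", {
  sim <- simulate_dataset(small_config(seed = 6))
  reg <- sim$registry
  expect_true(all(reg$taxon[reg$detected_dna] %in% sim$rbcl$clones$taxon))
  in_pollen <- colSums(sim$pollen$counts[, reg$taxon, drop = FALSE]) > 0
  expect_equal(unname(reg$detected_pollen), unname(in_pollen))
  expect_true(all(reg$epi_mode %in% c(1, 3)))
  expect_true(all(reg$epi_production %in% 1:3))
})

test_that("pure pollen rain ranks taxa by EPI (all-neutral world)", {
  cfg <- sim_config(n_individuals = 2, events_per_individual = 1,
                    coprolites_per_event = 2, n_taxa = 15,
                    env_mixing_weight = 1, count_depth = 20000L,
                    n_dna_samples = 0, age_range_bp = c(700, 3000),
                    seed = 9)
  sim <- simulate_dataset(cfg)
  tab <- epi_representation(pollen_percentages(sim$pollen), sim$registry)
  # within an EPI tie class ranks are arbitrary: the derived neutral band
  # is half the largest tie-class width plus sampling slack
  m_max <- max(table(tab$epi))
  margin <- (m_max - 1) / 2 + 2
  calls <- classify_representation(tab$observed_rank, tab$expected_rank,
                                   margin = margin)
  expect_true(all(calls == "neutral"))
})
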