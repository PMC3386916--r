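test_that("pollen percentages follow the pollen-sum convention", {
  m <- matrix(c(125L, 125L), 1, dimnames = list("C1", c("A", "B")))
  expect_equal(pollen_percentages(toy_pollen(m))["C1", ],
               c(A = 50, B = 50))

  # spike-style out-of-sum column is excluded from the denominator
  m2 <- matrix(c(250L, 50L), 1, dimnames = list("C1", c("A", "spike")))
  pm2 <- toy_pollen(m2, in_sum = c(TRUE, FALSE))
  expect_equal(pollen_percentages(pm2)["C1", "A"], 100)
  # ... but is still reported relative to the sum when requested
  expect_equal(pollen_percentages(pm2, in_sum_only = FALSE)["C1", "spike"],
               20)

  m3 <- matrix(c(10L, 0L, 5L, 0L), 2,
               dimnames = list(c("C1", "C2"), c("A", "B")))
  expect_error(pollen_percentages(toy_pollen(m3)), "C2")
})

test_that("in-sum percentage rows total 100 on random matrices", {
  for (seed in 1:5) {
    pm <- random_pollen(n_cop = 4, n_taxa = 10, seed = seed)
    expect_equal(unname(rowSums(pollen_percentages(pm))),
                 rep(100, 4), tolerance = 1e-4)
  }
})

test_that("occurrence_percent matches reporting conventions", {
  expect_identical(occurrence_percent(33, 35), 94.3)
  expect_identical(occurrence_percent(35, 35), 100)
  expect_identical(occurrence_percent(0, 35), 0)
  expect_identical(occurrence_percent(8, 12, digits = 0), 67)
  expect_error(occurrence_percent(1, 0), "positive")
  expect_error(occurrence_percent(5, 3), "\\[0, n\\]")
  # monotone non-decreasing in k at fixed n
  vals <- occurrence_percent(0:35, 35)
  expect_true(all(diff(vals) >= 0))
})

test_that("spike concentration arithmetic", {
  expect_equal(pollen_concentration(250, 50, 10000, 0.39), 128205.1,
               tolerance = 1e-6)
  expect_equal(pollen_concentration(0, 50, 10000, 0.39), 0)
  expect_equal(pollen_concentration(250, 50, 10000, 0.78),
               pollen_concentration(250, 50, 10000, 0.39) / 2)
  expect_error(pollen_concentration(250, 0, 10000, 0.39), "undefined")
})

test_that("loss on ignition", {
  expect_equal(loi_organic(1.000, 0.486), 51.4)
  expect_equal(loi_organic(1, 1), 0)
  expect_equal(loi_organic(1, 0), 100)
  expect_error(loi_organic(1, 1.2), "ash")
})

test_that("occurrence summary has ordered min <= mean <= max", {
  pm <- random_pollen(seed = 42)
  os <- occurrence_summary(pm)
  expect_true(all(os$pct_min <= os$pct_mean + 1e-9))
  expect_true(all(os$pct_mean <= os$pct_max + 1e-9))
  expect_true(all(os$n_present >= 0 & os$n_present <= os$n_total))
})

test_that("pollen matrix round-trips through TSV", {
  pm <- random_pollen(seed = 7)
  pm$in_pollen_sum[3] <- FALSE
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pollen_matrix(pm, path)
  back <- read_pollen_matrix(path)
  expect_identical(back$counts, pm$counts)
  expect_identical(back$in_pollen_sum, pm$in_pollen_sum)
  expect_identical(back$spike_total, pm$spike_total)
})

test_that("multiproxy venn partitions the registry", {
  reg <- taxon_registry(data.frame(
    taxon = c("a", "b", "c"),
    detected_dna = c(TRUE, FALSE, FALSE),
    detected_pollen = c(FALSE, TRUE, FALSE),
    detected_macrofossil = c(FALSE, FALSE, TRUE)))
  v <- multiproxy_venn(reg)
  expect_equal(v[["dna"]], 1)
  expect_equal(v[["pollen"]], 1)
  expect_equal(v[["macrofossil"]], 1)
  expect_equal(sum(v), 3)

  reg2 <- taxon_registry(data.frame(
    taxon = "x", detected_dna = TRUE, detected_pollen = TRUE,
    detected_macrofossil = TRUE))
  v2 <- multiproxy_venn(reg2)
  expect_equal(v2[["dna+pollen+macrofossil"]], 1)
  expect_equal(sum(v2), 1)

  reg3 <- toy_registry(12)
  expect_equal(sum(multiproxy_venn(reg3)), 12)
})

test_that("habitat tally handles multi-membership and validation", {
  reg <- taxon_registry(data.frame(
    taxon = c("a", "b"), habitats = c("F", "F,G")))
  tal <- habitat_tally(reg)
  expect_equal(tal$n_taxa[tal$habitat == "F"], 2)
  expect_equal(tal$n_taxa[tal$habitat == "G"], 1)

  reg0 <- taxon_registry(data.frame(taxon = c("a", "b"),
                                    habitats = c("", "")))
  tal0 <- habitat_tally(reg0, communities = c("F", "G"))
  expect_equal(tal0$n_taxa, c(0, 0))

  expect_error(habitat_tally(reg, communities = c("F")), "valid names: F")

  # 12 of 35 taxa restricted to sinkhole walls -> 34.3%
  reg2 <- taxon_registry(data.frame(
    taxon = paste0("t", 1:35),
    habitats = c(rep("sinkhole walls", 12), rep("grassland", 23))))
  tal2 <- habitat_tally(reg2)
  expect_equal(tal2$percent[tal2$habitat == "sinkhole walls"], 34.3)
})

test_that("packaged occurrence fixture matches the published counts", {
  t1 <- table1_occurrences()
  row <- function(x) t1[t1$taxon == x, ]
  expect_equal(row("Monolete fern")$pollen_k, 34)
  expect_equal(row("Monolete fern")$pollen_n, 35)
  expect_equal(row("Fuscospora (pollen type)")$pollen_k, 35)
  expect_equal(row("Nothofagus menziesii")$pollen_k, 30)
  expect_equal(row("Moss undetermined")$macro_k, "17")
  expect_equal(row("Poaceae (Undetermined)")$pollen_min, 0.7)
  expect_equal(row("Poaceae (Undetermined)")$pollen_mean, 36.4)
  expect_equal(row("Poaceae (Undetermined)")$pollen_max, 86.0)

  t2 <- table2_dates()
  expect_equal(nrow(t2), 12)
  expect_equal(t2$cra[t2$lab_code == "Wk28344"], 694)
})
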