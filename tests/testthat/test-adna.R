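make_moa_refs <- function() {
  set.seed(1)
  base <- paste(sample(c("A", "C", "G", "T"), 31, TRUE), collapse = "")
  substr(base, 25, 25) <- "C"
  hapT <- base
  substr(hapT, 25, 25) <- "T"
  other <- base
  for (p in c(3, 9, 14, 20))
    substr(other, p, p) <- setdiff(c("A", "C", "G", "T"),
                                   substr(other, p, p))[1]
  reference_set(
    c(focal_hapC = base, focal_hapT = hapT, other_sp = other),
    marker = "cr31",
    sidecar = data.frame(id = c("focal_hapC", "focal_hapT", "other_sp"),
                         taxon = c("Focal species", "Focal species",
                                   "Other species")))
}

test_that("haplotype calling: identity, diagnostic base, damage flag", {
  refs <- make_moa_refs()
  q <- as.character(refs$seqs[["focal_hapC"]])
  call_c <- call_haplotype(q, refs)
  expect_equal(call_c$identity, 100)
  expect_equal(call_c$species, "Focal species")
  expect_equal(call_c$diagnostic_base, "C")
  expect_false(call_c$ambiguous)

  qT <- q
  substr(qT, 25, 25) <- "T"
  call_t <- call_haplotype(qT, refs)
  expect_equal(call_t$species, "Focal species")
  expect_equal(call_t$diagnostic_base, "T")
  # both calls are separated only by a C/T site, so both are flagged as
  # consistent with cytosine-deamination damage
  expect_true(call_c$damage_consistent)
  expect_true(call_t$damage_consistent)
})

test_that("ties between references are reported as ambiguous", {
  set.seed(2)
  a <- paste(sample(c("A", "C", "G", "T"), 31, TRUE), collapse = "")
  b <- a; substr(b, 5, 5) <- setdiff(c("A", "C", "G", "T"),
                                     substr(a, 5, 5))[1]
  q <- a; substr(q, 5, 5) <- setdiff(c("A", "C", "G", "T"),
                                     c(substr(a, 5, 5), substr(b, 5, 5)))[1]
  refs <- reference_set(c(sp1 = a, sp2 = b), marker = "cr31",
                        sidecar = data.frame(id = c("sp1", "sp2"),
                                             taxon = c("Species 1",
                                                       "Species 2")))
  call <- call_haplotype(q, refs)
  expect_true(call$ambiguous)
  expect_true(is.na(call$species))
  expect_setequal(call$candidates, c("Species 1", "Species 2"))
})

test_that("haplotype queries are validated", {
  refs <- make_moa_refs()
  expect_error(call_haplotype("ACGT", refs), "31 bp")
  expect_error(call_haplotype(strrep("Q", 31), refs), "IUPAC")
})

test_that("internal stop codon detection honours frame and boundaries", {
  expect_false(detect_stop_codon("ATGGCT", 0))
  expect_true(detect_stop_codon("ATGTAAGCT", 0))
  # stop only in the trailing partial codon is not internal
  expect_false(detect_stop_codon("ATGGCTTA", 0))
  # frame shifts change the codon grid
  expect_true(detect_stop_codon("ATAAGCT", 1))
  expect_false(detect_stop_codon("ATAAGCT", 0))
  expect_error(detect_stop_codon("AT", 0), "short")
  expect_error(detect_stop_codon("ATGTAA", 3), "frame_offset")
})

test_that("clone assignment: exact substring, threshold rule, stops", {
  fix <- toy_rbcl_refs(n_taxa = 3, seed = 3)
  refs <- fix$refs
  win <- fix$window
  amp <- substr(as.character(refs$seqs[["taxon2"]]), win[1], win[2])

  hit <- assign_clone(amp, refs)
  expect_equal(hit$identity, 100)
  expect_equal(hit$best_taxon, "taxon2")
  expect_true(hit$assigned)
  expect_false(hit$internal_stop)

  # 5 substitutions over 95 columns -> 94.7% < 96 -> unassigned
  dmg <- amp
  v <- strsplit(dmg, "")[[1]]
  set.seed(4)
  pos <- sample(95, 5)
  for (p in pos) v[p] <- setdiff(c("A", "C", "G", "T"), v[p])[1]
  dmg <- paste(v, collapse = "")
  miss <- assign_clone(dmg, refs)
  expect_equal(round(miss$identity, 1), 94.7)
  expect_false(miss$assigned)
  expect_equal(miss$best_taxon, "taxon2") # best reported even if unassigned

  # plant an in-frame TAA inside the clone: flagged and vetoed
  v <- strsplit(amp, "")[[1]]
  aln_start <- win[1]
  phase <- (aln_start - 1 - 1) %% 3 # sidecar frame_offset = 1
  first_codon <- (3 - phase) %% 3 + 1
  v[first_codon + 9:11] <- c("T", "A", "A")
  stopped <- assign_clone(paste(v, collapse = ""), refs)
  expect_true(stopped$internal_stop)
  expect_false(stopped$assigned)
  expect_true(assign_clone(paste(v, collapse = ""), refs,
                           allow_stop = TRUE)$assigned)

  expect_error(assign_clone(strrep("A", 20), refs), "60-150")
  expect_error(assign_clone(amp, reference_set(
    Biostrings::DNAStringSet(setNames(character(0), character(0))))),
    "unique names|empty")
})

test_that("every reference's amplicon assigns to itself", {
  fix <- toy_rbcl_refs(n_taxa = 4, seed = 5)
  for (rn in names(fix$refs$seqs)) {
    amp <- substr(as.character(fix$refs$seqs[[rn]]),
                  fix$window[1], fix$window[2])
    a <- assign_clone(amp, fix$refs)
    expect_equal(a$best_taxon, rn)
    expect_equal(a$identity, 100)
  }
})

test_that("raising the threshold never assigns more clones", {
  sim <- simulate_dataset(small_config(seed = 31, damage_rate = 0.03))
  clones <- setNames(sim$rbcl$clones$sequence, sim$rbcl$clones$clone)
  expect_gt(length(clones), 0)
  counts <- vapply(c(80, 90, 96, 99, 100),
                   function(th) sum(assign_clones(clones, sim$rbcl$refs,
                                                  threshold = th)$assigned),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("batch assignment equals the single-clone path", {
  fix <- toy_rbcl_refs(n_taxa = 3, seed = 8)
  amp <- substr(as.character(fix$refs$seqs[["taxon1"]]),
                fix$window[1], fix$window[2])
  v <- strsplit(amp, "")[[1]]
  v[10] <- setdiff(c("A", "C", "G", "T"), v[10])[1]
  clones <- c(a = amp, b = paste(v, collapse = ""), c = amp)
  tab <- assign_clones(clones, fix$refs)
  single <- lapply(clones, assign_clone, refs = fix$refs)
  expect_equal(tab$identity,
               unname(vapply(single, `[[`, numeric(1), "identity")))
  expect_equal(tab$best_taxon,
               unname(vapply(single, `[[`, character(1), "best_taxon")))
  expect_equal(tab$assigned,
               unname(vapply(single, `[[`, logical(1), "assigned")))
})

test_that("unique clone collapse preserves multiplicity and provenance", {
  out <- collapse_unique_clones(c("AAA", "AAA", "AAA", "CCC"),
                                coprolite = c("c1", "c2", "c1", "c2"))
  expect_equal(out$sequence, c("AAA", "CCC"))
  expect_equal(out$multiplicity, c(3L, 1L))
  expect_equal(out$coprolites, c("c1,c2", "c2"))

  empty <- collapse_unique_clones(character(0))
  expect_equal(nrow(empty), 0)

  set.seed(10)
  seqs <- sample(c("ACGT", "AGGT", "ACGA", "TTTT"), 50, TRUE)
  expect_equal(nrow(collapse_unique_clones(seqs)), length(unique(seqs)))
  expect_equal(sum(collapse_unique_clones(seqs)$multiplicity), 50)
})
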