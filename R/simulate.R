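#' Simulation configuration
#'
#' Parameters of the synthetic coprolite world.  The defaults emulate the
#' deposit the package is built around: a few dozen coprolites left by a
#' small number of individual birds in punctuated defecation events over
#' several millennia; pollen counts of at least 250 grains per sample over
#' ~50 taxa mixing each bird's dietary signal with EPI-weighted
#' environmental pollen rain; two mitochondrial haplotypes differing by a
#' single C/T site; clone libraries of 16-52 sequences with per-site C->T
#' deamination damage and per-sample dropout (8 of 12 samples succeeding
#' on average); and radiocarbon ages spanning roughly 700-6,400 14C yr BP.
#'
#' @param n_individuals number of depositing birds.
#' @param events_per_individual defecation events per bird.
#' @param coprolites_per_event boli per event (>= 1).
#' @param n_taxa number of plant taxa (>= 2).
#' @param diet_concentration Dirichlet concentration of per-individual diet
#'   profiles (small = a few staple foods).
#' @param diet_subset_size taxa in each individual's dietary repertoire.
#' @param env_mixing_weight fraction of the expected pollen count that is
#'   environmental rain (EPI-proportional) rather than diet, in `[0, 1]`.
#' @param count_depth pollen/spores counted per coprolite (>= 250, the
#'   usual counting standard).
#' @param spike_total exotic spike spores added per sample.
#' @param clone_library_size_range integer pair, clones sequenced per
#'   successful library.
#' @param clone_dropout_prob probability a sampled coprolite yields no
#'   plant-DNA library.
#' @param n_dna_samples coprolites attempted for plant DNA.
#' @param moa_success_prob probability the depositor amplicon amplifies.
#' @param damage_rate per-site C->T deamination probability on clones.
#' @param age_range_bp calendar range of event ages (yr BP).
#' @param age_error radiocarbon measurement error (1 sigma, yr).
#' @param min_age_separation minimum gap between event ages (yr);
#'   deposition is punctuated, so events are well separated by default.
#' @param n_haplotypes distinct mitochondrial haplotypes available (2 in
#'   the emulated system; more can be requested for recovery experiments).
#' @param diet_low_epi when TRUE, dietary taxa are planted with low EPI
#'   factors (animal-pollinated herbs) and environmental taxa with high
#'   ones, the configuration used by over-representation recovery tests.
#' @param seed integer RNG seed; all draws flow from this one generator.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 5L, events_per_individual = 3L,
                       coprolites_per_event = 2L, n_taxa = 50L,
                       diet_concentration = 0.3, diet_subset_size = 8L,
                       env_mixing_weight = 0.3, count_depth = 250L,
                       spike_total = 20848L,
                       clone_library_size_range = c(16L, 52L),
                       clone_dropout_prob = 1 / 3, n_dna_samples = 12L,
                       moa_success_prob = 33 / 35, damage_rate = 0.01,
                       age_range_bp = c(700, 6400), age_error = 30,
                       min_age_separation = 200, n_haplotypes = 2L,
                       diet_low_epi = FALSE, seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(n_individuals >= 1, events_per_individual >= 1,
            coprolites_per_event >= 1)
  if (n_taxa < 2) stop("n_taxa must be at least 2")
  if (env_mixing_weight < 0 || env_mixing_weight > 1)
    stop("env_mixing_weight must lie in [0, 1]")
  for (p in c("clone_dropout_prob", "moa_success_prob", "damage_rate"))
    if (cfg[[p]] < 0 || cfg[[p]] > 1) stop(p, " must lie in [0, 1]")
  if (count_depth < 250)
    stop("count_depth must be >= 250 (the minimum counting standard)")
  if (diet_concentration <= 0) stop("diet_concentration must be positive")
  if (age_error <= 0) stop("age_error must be positive")
  if (length(age_range_bp) != 2 || diff(age_range_bp) <= 0)
    stop("age_range_bp must be an increasing pair")
  cfg$diet_subset_size <- min(diet_subset_size, n_taxa)
  class(cfg) <- "sim_config"
  cfg
}

DNA_BASES <- c("A", "C", "G", "T")
STOPS <- c("TAA", "TAG", "TGA")

random_dna <- function(n) paste(sample(DNA_BASES, n, replace = TRUE),
                                collapse = "")

# substitute positions without creating an in-frame stop codon
mutate_no_stop <- function(seq, positions, frame_offset) {
  v <- strsplit(seq, "")[[1]]
  for (p in positions) {
    cands <- sample(setdiff(DNA_BASES, v[p]))
    for (b in cands) {
      old <- v[p]
      v[p] <- b
      cs <- frame_offset + 1L + 3L * ((p - frame_offset - 1L) %/% 3L)
      if (cs >= 1 && cs + 2 <= length(v) &&
          paste(v[cs:(cs + 2)], collapse = "") %in% STOPS) {
        v[p] <- old
      } else break
    }
  }
  paste(v, collapse = "")
}

# codon-safe random gene: leading frame_offset bases then sense codons
random_gene <- function(n_codons, frame_offset = 1L) {
  sense <- setdiff(apply(expand.grid(DNA_BASES, DNA_BASES, DNA_BASES), 1,
                         paste, collapse = ""), STOPS)
  paste0(random_dna(frame_offset),
         paste(sample(sense, n_codons, replace = TRUE), collapse = ""))
}

# uniform ages conditional on all pairwise gaps >= min_sep: draw sorted
# uniforms in the slack left after reserving the k-1 mandatory gaps
draw_event_ages <- function(k, range_bp, min_sep) {
  slack <- diff(range_bp) - (k - 1) * min_sep
  if (slack < 0)
    stop("cannot place ", k, " event ages with separation ", min_sep,
         " in range [", range_bp[1], ", ", range_bp[2], "]")
  u <- sort(runif(k, 0, slack))
  round(range_bp[1] + u + (seq_len(k) - 1) * min_sep)
}

#' Simulate a complete coprolite dataset with known ground truth
#'
#' Generates, from one seed, every input the analysis pipeline consumes —
#' pollen count matrix with exotic spike, taxon registry with EPI factors
#' and proxy detections, depositor and dietary amplicon sets with
#' references, radiocarbon measurements — plus the truth that produced
#' them.  Per coprolite, pollen counts are multinomial with expected
#' proportions `(1 - w) * diet + w * rain` where `rain` is proportional to
#' per-taxon EPI; coprolites of one event share their individual's diet
#' profile and calendar age; haplotypes are constant within an individual;
#' clone libraries are multinomial draws over the dietary proportions with
#' per-sample dropout and per-site C->T damage; and measured radiocarbon
#' ages are the curve value at the true age plus Gaussian noise.
#'
#' @param config a [sim_config()].
#' @param curve calibration curve used to map true calendar ages to
#'   measured radiocarbon ages; default an identity curve padded around
#'   `age_range_bp`.
#' @return a list of class `copro_sim` with elements `pollen`
#'   ([pollen_matrix()]), `registry` ([taxon_registry()]), `moa`
#'   (`$queries`, `$refs`), `rbcl` (`$refs`, `$clones` data.frame
#'   `clone`, `coprolite`, `taxon`, `sequence`), `ages` (data.frame),
#'   `curve`, and `truth` (`$assignments`, `$diet`, `$epi`, `$rain`,
#'   `$amplicon_window`).
#' @export
simulate_dataset <- function(config = sim_config(), curve = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  if (is.null(curve)) {
    pad <- 20 * config$age_error
    curve <- identity_curve(max(0, config$age_range_bp[1] - pad),
                            config$age_range_bp[2] + pad, by = 10)
  }

  taxa <- sprintf("taxon%02d", seq_len(config$n_taxa))
  n_ind <- config$n_individuals
  individuals <- sprintf("I%d", seq_len(n_ind))

  # per-individual diet: Dirichlet over a random taxon subset
  diet <- matrix(0, n_ind, config$n_taxa, dimnames = list(individuals, taxa))
  for (i in seq_len(n_ind)) {
    sub <- sample(config$n_taxa, config$diet_subset_size)
    g <- stats::rgamma(length(sub), shape = config$diet_concentration)
    if (sum(g) == 0) g[sample(length(g), 1)] <- 1
    diet[i, sub] <- g / sum(g)
  }
  dietary <- colSums(diet) > 0

  # EPI factors; optionally plant dietary taxa with low prevalence
  if (config$diet_low_epi) {
    mode <- ifelse(dietary, 1L, 3L)
    production <- ifelse(dietary, sample(1:2, config$n_taxa, TRUE),
                         sample(2:3, config$n_taxa, TRUE))
    dispersal <- ifelse(dietary, sample(1:2, config$n_taxa, TRUE),
                        sample(2:3, config$n_taxa, TRUE))
  } else {
    mode <- sample(c(1L, 3L), config$n_taxa, TRUE)
    production <- sample(1:3, config$n_taxa, TRUE)
    dispersal <- sample(1:3, config$n_taxa, TRUE)
  }
  epi <- compute_epi(mode, production, dispersal)
  rain <- epi / sum(epi)

  # structure: individuals -> events -> coprolites
  n_events <- n_ind * config$events_per_individual
  event_ind <- rep(seq_len(n_ind), each = config$events_per_individual)
  event_age <- draw_event_ages(n_events, config$age_range_bp,
                               config$min_age_separation)
  copro_event <- rep(seq_len(n_events), each = config$coprolites_per_event)
  n_cop <- length(copro_event)
  coprolites <- sprintf("C%02d", seq_len(n_cop))
  copro_ind <- event_ind[copro_event]

  # haplotypes: a 31 bp control-region fragment; site 25 separates the two
  # core haplotypes (C vs T); extra requested haplotypes vary other sites
  frag <- random_dna(31L)
  substr(frag, 25, 25) <- "C"
  hap_seqs <- c(C = frag, T = `substr<-`(frag, 25, 25, "T"))
  if (config$n_haplotypes > 2) {
    extra_sites <- setdiff(seq_len(31), 25)
    for (h in seq_len(config$n_haplotypes - 2)) {
      s <- hap_seqs[["C"]]
      p <- extra_sites[h]
      v <- substr(s, p, p)
      substr(s, p, p) <- sample(setdiff(DNA_BASES, v), 1)
      hap_seqs[paste0("H", h + 2)] <- s
    }
  }
  hap_of_ind <- names(hap_seqs)[(seq_len(n_ind) - 1L) %%
                                  length(hap_seqs) + 1L]
  # two decoy species at ~4 substitutions from the focal fragment
  decoys <- vapply(1:2, function(i)
    mutate_no_stop(frag, sample(setdiff(1:31, 25), 4), 0L), character(1))
  moa_ref_seqs <- c(setNames(hap_seqs,
                             paste0("Megalapteryx_didinus_hap",
                                    names(hap_seqs))),
                    setNames(decoys, paste0("Decoy_species_", 1:2)))
  moa_refs <- reference_set(
    moa_ref_seqs, marker = "control-region-31bp",
    sidecar = data.frame(
      id = names(moa_ref_seqs),
      taxon = c(rep("Megalapteryx didinus", length(hap_seqs)),
                paste("Decoy species", 1:2))))

  # depositor queries (no damage on these; success rate < 1)
  moa_ok <- runif(n_cop) < config$moa_success_prob
  moa_queries <- setNames(hap_seqs[hap_of_ind[copro_ind]],
                          coprolites)[moa_ok]

  # rbcL references: one base gene, per-taxon codon-safe substitutions;
  # clones are read from a fixed 95 bp window
  frame_offset <- 1L
  base_gene <- random_gene(467L, frame_offset) # 1402 bp
  win <- c(start = 601L, end = 695L)
  # each taxon carries 4 guaranteed substitutions inside the amplicon
  # window (so taxa are separable from a 95 bp read) plus 26 elsewhere
  rbcl_seqs <- vapply(seq_len(config$n_taxa), function(i)
    mutate_no_stop(base_gene,
                   c(sample(win["start"]:win["end"], 4),
                     sample(setdiff(seq_len(nchar(base_gene)),
                                    win["start"]:win["end"]), 26)),
                   frame_offset),
    character(1))
  names(rbcl_seqs) <- taxa
  rbcl_refs <- reference_set(
    rbcl_seqs, marker = "rbcL",
    sidecar = data.frame(id = taxa, taxon = taxa,
                         frame_offset = frame_offset))

  # clone libraries over dietary DNA proportions, with dropout and damage
  dna_samples <- coprolites[seq_len(min(config$n_dna_samples, n_cop))]
  clone_rows <- list()
  for (cp in dna_samples) {
    if (runif(1) < config$clone_dropout_prob) next
    ind <- copro_ind[match(cp, coprolites)]
    sz <- sample(config$clone_library_size_range[1]:
                   config$clone_library_size_range[2], 1)
    k <- rmultinom(1, sz, diet[ind, ])[, 1]
    for (t in which(k > 0)) {
      amp <- substr(rbcl_seqs[[t]], win["start"], win["end"])
      for (r in seq_len(k[t])) {
        v <- strsplit(amp, "")[[1]]
        cs <- which(v == "C")
        hit <- cs[runif(length(cs)) < config$damage_rate]
        v[hit] <- "T"
        clone_rows[[length(clone_rows) + 1L]] <- data.frame(
          coprolite = cp, taxon = taxa[t],
          sequence = paste(v, collapse = ""))
      }
    }
  }
  clones <- if (length(clone_rows)) do.call(rbind, clone_rows)
    else data.frame(coprolite = character(), taxon = character(),
                    sequence = character())
  if (nrow(clones))
    clones <- cbind(clone = sprintf("%s_cl%02d", clones$coprolite,
                                    stats::ave(seq_len(nrow(clones)),
                                               clones$coprolite,
                                               FUN = seq_along)),
                    clones)

  # pollen counts: dietary signal mixed with EPI-proportional rain
  w <- config$env_mixing_weight
  counts <- matrix(0L, n_cop, config$n_taxa,
                   dimnames = list(coprolites, taxa))
  for (c_i in seq_len(n_cop)) {
    p <- (1 - w) * diet[copro_ind[c_i], ] + w * rain
    counts[c_i, ] <- rmultinom(1, config$count_depth, p)[, 1]
  }
  # out-of-sum coprophilous fungus column
  sporo <- ifelse(runif(n_cop) < 0.37, rpois(n_cop, 3) + 1L, 0L)
  counts <- cbind(counts, Sporormiella = sporo)
  pollen <- pollen_matrix(
    counts,
    spike_observed = rpois(n_cop, 60) + 1L,
    spike_total = config$spike_total,
    sample_mass_g = round(runif(n_cop, 0.08, 0.54), 2),
    in_pollen_sum = c(rep(TRUE, config$n_taxa), FALSE))

  # measured radiocarbon ages: curve value at the true age + noise
  true_age <- event_age[copro_event]
  mu <- curve_at(curve, true_age)$mu
  ages <- data.frame(coprolite = coprolites,
                     cra = round(mu + rnorm(n_cop, 0, config$age_error)),
                     error = config$age_error)

  communities <- c("beech forest", "subalpine grassland", "shrubland",
                   "herbfield", "sinkhole walls", "rock outcrop",
                   "flaxland", "tussockland", "wetland")
  registry <- taxon_registry(data.frame(
    taxon = taxa,
    growth_form = sample(c("tree_shrub", "dicot_herb", "monocot",
                           "fern_ally"), config$n_taxa, TRUE),
    detected_dna = taxa %in% clones$taxon,
    detected_pollen = colSums(counts[, taxa, drop = FALSE] > 0) > 0,
    detected_macrofossil = colMeans(diet) >= 0.05,
    habitats = vapply(seq_len(config$n_taxa), function(i)
      paste(sample(communities, sample(1:3, 1)), collapse = ","),
      character(1)),
    epi_mode = mode, epi_production = production, epi_dispersal = dispersal,
    epi_include = TRUE))

  truth <- list(
    assignments = data.frame(
      coprolite = coprolites,
      individual = individuals[copro_ind],
      event = sprintf("E%d", copro_event),
      haplotype = hap_of_ind[copro_ind],
      age_true = true_age,
      moa_amplified = moa_ok),
    diet = diet, rain = setNames(rain, taxa),
    epi = data.frame(taxon = taxa, epi = epi, dietary = dietary),
    amplicon_window = win,
    config = config)

  structure(list(pollen = pollen, registry = registry,
                 moa = list(queries = moa_queries, refs = moa_refs),
                 rbcl = list(refs = rbcl_refs, clones = clones),
                 ages = ages, curve = curve, truth = truth),
            class = "copro_sim")
}

#' Write a simulated dataset to disk
#'
#' Emits the same plain-text formats the analysis modules read: pollen
#' matrix TSV, registry TSV, FASTA for queries/references/clones (clone
#' headers are `<clone>|<coprolite>`), reference sidecar TSVs, ages TSV,
#' calibration curve `.14c`, and the ground-truth assignment TSV.
#'
#' @param sim a [simulate_dataset()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "copro_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(dir, ...)
  write_pollen_matrix(sim$pollen, p("pollen.tsv"))
  write_taxon_registry(sim$registry, p("registry.tsv"))
  write_fasta(sim$moa$queries, p("moa_queries.fasta"))
  write_fasta(as.character(sim$moa$refs$seqs), p("moa_refs.fasta"))
  write.table(data.frame(id = names(sim$moa$refs$seqs),
                         taxon = unname(sim$moa$refs$taxon)),
              p("moa_refs.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  write_fasta(as.character(sim$rbcl$refs$seqs), p("rbcl_refs.fasta"))
  write.table(data.frame(id = names(sim$rbcl$refs$seqs),
                         taxon = unname(sim$rbcl$refs$taxon),
                         frame_offset = unname(sim$rbcl$refs$frame_offset)),
              p("rbcl_refs.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  if (nrow(sim$rbcl$clones))
    write_fasta(setNames(sim$rbcl$clones$sequence,
                         paste0(sim$rbcl$clones$clone, "|",
                                sim$rbcl$clones$coprolite)),
                p("clones.fasta"))
  write.table(sim$ages, p("ages.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_curve(sim$curve, p("curve.14c"))
  write.table(sim$truth$assignments, p("truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

# minimal deterministic FASTA writer (fixed 70-column wrap)
write_fasta <- function(seqs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1, nchar(s), by = 70)
    writeLines(substring(s, starts, pmin(starts + 69, nchar(s))), con)
  }
  invisible(path)
}
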