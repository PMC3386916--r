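# Shared fixture builders. Everything is generated in code; no binary data.

# small pollen matrix with optional out-of-sum spike column
toy_pollen <- function(counts, in_sum = NULL, ...) {
  pollen_matrix(counts, spike_observed = 50L, spike_total = 10000L,
                sample_mass_g = 0.39, in_pollen_sum = in_sum,
                min_count = 0L, ...)
}

random_pollen <- function(n_cop = 5, n_taxa = 8, depth = 300, seed = 1) {
  set.seed(seed)
  m <- t(stats::rmultinom(n_cop, depth, stats::runif(n_taxa, 0.2, 2)))
  dimnames(m) <- list(paste0("C", seq_len(n_cop)),
                      paste0("T", seq_len(n_taxa)))
  toy_pollen(m)
}

# tiny registry with all metadata columns populated
toy_registry <- function(n = 6, seed = 1) {
  set.seed(seed)
  taxon_registry(data.frame(
    taxon = paste0("T", seq_len(n)),
    growth_form = "dicot_herb",
    detected_dna = seq_len(n) %% 2 == 0,
    detected_pollen = TRUE,
    detected_macrofossil = seq_len(n) %% 3 == 0,
    habitats = rep_len(c("forest", "forest,grassland", ""), n),
    epi_mode = sample(c(1L, 3L), n, TRUE),
    epi_production = sample(1:3, n, TRUE),
    epi_dispersal = sample(1:3, n, TRUE),
    epi_include = TRUE))
}

# small reference set of coding sequences sharing one base gene, each taxon
# with `div` guaranteed substitutions inside a 95 bp window
toy_rbcl_refs <- function(n_taxa = 4, len_codons = 120, seed = 1, div = 4) {
  set.seed(seed)
  sense <- setdiff(apply(expand.grid(c("A", "C", "G", "T"),
                                     c("A", "C", "G", "T"),
                                     c("A", "C", "G", "T")), 1,
                         paste, collapse = ""), c("TAA", "TAG", "TGA"))
  base <- paste0("G", paste(sample(sense, len_codons, TRUE), collapse = ""))
  win <- c(101L, 195L)
  seqs <- vapply(seq_len(n_taxa), function(i) {
    v <- strsplit(base, "")[[1]]
    for (p in sample(win[1]:win[2], div)) {
      repl <- setdiff(c("A", "C", "G", "T"), v[p])
      for (b in sample(repl)) {
        old <- v[p]; v[p] <- b
        cs <- 2L + 3L * ((p - 2L) %/% 3L)
        if (cs >= 1 && cs + 2 <= length(v) &&
            paste(v[cs:(cs + 2)], collapse = "") %in%
              c("TAA", "TAG", "TGA")) v[p] <- old else break
      }
    }
    paste(v, collapse = "")
  }, character(1))
  names(seqs) <- paste0("taxon", seq_len(n_taxa))
  list(refs = reference_set(seqs, marker = "rbcL",
                            sidecar = data.frame(id = names(seqs),
                                                 taxon = names(seqs),
                                                 frame_offset = 1L)),
       window = win)
}

# order-independent representation of an hclust merge matrix
normalize_merge <- function(m) {
  leafset <- function(i) {
    if (i < 0) return(-i)
    sort(unlist(lapply(m[i, ], leafset)))
  }
  lapply(seq_len(nrow(m)), leafset)
}

# fast config for simulator-heavy tests; any field can be overridden
small_config <- function(seed = 1, ...) {
  base <- list(n_individuals = 3L, events_per_individual = 1L,
               coprolites_per_event = 2L, n_taxa = 12L,
               diet_subset_size = 4L, n_dna_samples = 4L,
               clone_library_size_range = c(6L, 10L),
               age_range_bp = c(700, 4000), seed = seed)
  do.call(sim_config, utils::modifyList(base, list(...)))
}
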