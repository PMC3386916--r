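#' Taxon registry
#'
#' The registry is a plain data.frame with one row per taxon carrying the
#' metadata the analyses need: which proxies detected it (ancient DNA,
#' pollen, macrofossil), its growth form, the local vegetation communities
#' it occurs in, and the three environmental-prevalence-index factors
#' (pollination mode, pollen production, dispersability).  These functions
#' validate, read and write that table and derive the standard summaries.
#'
#' Expected columns: `taxon` (unique, free text), optional `family`,
#' `growth_form`, logical `detected_dna`, `detected_pollen`,
#' `detected_macrofossil`, `habitats` (comma-separated community names, may
#' be empty), integer `epi_mode` (1 = animal, 3 = wind), `epi_production`
#' and `epi_dispersal` (1-3), logical `epi_include` (whether index data
#' exist for the taxon).
#'
#' @param df data.frame to validate.
#' @return the validated data.frame, invisibly classed `taxon_registry`.
#' @export
taxon_registry <- function(df) {
  if (!"taxon" %in% names(df)) stop("registry needs a 'taxon' column")
  if (anyDuplicated(df$taxon)) stop("duplicate taxon names in registry")
  for (col in c("detected_dna", "detected_pollen", "detected_macrofossil"))
    if (col %in% names(df)) df[[col]] <- as.logical(df[[col]])
  det <- intersect(c("detected_dna", "detected_pollen", "detected_macrofossil"),
                   names(df))
  if (length(det) == 3) {
    none <- !Reduce(`|`, df[det])
    if (any(none))
      warning("taxa detected by no proxy: ",
              paste(df$taxon[none], collapse = ", "))
  }
  if (all(c("epi_mode", "epi_production", "epi_dispersal") %in% names(df))) {
    keep <- if ("epi_include" %in% names(df)) df$epi_include else
      !is.na(df$epi_mode)
    ok <- is.na(df$epi_mode) | !keep |
      (df$epi_mode %in% c(1L, 3L) & df$epi_production %in% 1:3 &
         df$epi_dispersal %in% 1:3)
    if (!all(ok))
      stop("invalid EPI factors for: ", paste(df$taxon[!ok], collapse = ", "))
  }
  class(df) <- c("taxon_registry", "data.frame")
  df
}

#' @rdname taxon_registry
#' @param path TSV file path.
#' @export
read_taxon_registry <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                   comment.char = "#")
  taxon_registry(df)
}

#' @rdname taxon_registry
#' @param registry a registry data.frame.
#' @export
write_taxon_registry <- function(registry, path) {
  write.table(registry, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Multiproxy detection breakdown
#'
#' Counts taxa in each of the seven non-empty subsets of
#' {DNA, pollen, macrofossil} (the three-circle Venn layout).  Every taxon
#' is counted in exactly one subset, so the counts partition the registry.
#'
#' @param registry a [taxon_registry()] with the three `detected_*` columns.
#' @return named integer vector over subsets `"dna"`, `"pollen"`,
#'   `"macrofossil"`, `"dna+pollen"`, `"dna+macrofossil"`,
#'   `"pollen+macrofossil"`, `"dna+pollen+macrofossil"`.
#' @export
multiproxy_venn <- function(registry) {
  need <- c("detected_dna", "detected_pollen", "detected_macrofossil")
  if (!all(need %in% names(registry)))
    stop("registry needs columns: ", paste(need, collapse = ", "))
  d <- isTRUE_vec(registry$detected_dna)
  p <- isTRUE_vec(registry$detected_pollen)
  m <- isTRUE_vec(registry$detected_macrofossil)
  labels <- c("dna", "pollen", "macrofossil", "dna+pollen",
              "dna+macrofossil", "pollen+macrofossil",
              "dna+pollen+macrofossil")
  out <- setNames(integer(7), labels)
  lab <- vapply(seq_along(d), function(i) {
    parts <- c("dna", "pollen", "macrofossil")[c(d[i], p[i], m[i])]
    paste(parts, collapse = "+")
  }, character(1))
  tab <- table(lab[lab != ""])
  out[names(tab)] <- as.integer(tab)
  out
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' Habitat (vegetation community) tally
#'
#' Counts how many registry taxa occur in each vegetation community.  Taxa
#' may belong to several communities, so counts can sum to more than the
#' number of taxa; fractions use the total number of registry taxa as the
#' denominator.
#'
#' @param registry a [taxon_registry()] with a `habitats` column of
#'   comma-separated community names (empty string = no membership).
#' @param communities optional character vector of valid community names;
#'   when supplied, any membership outside it is an error.
#' @return data.frame with columns `habitat`, `n_taxa`, `fraction`,
#'   `percent` (half-up, 1 decimal).
#' @export
habitat_tally <- function(registry, communities = NULL) {
  if (!"habitats" %in% names(registry))
    stop("registry needs a 'habitats' column")
  mem <- strsplit(ifelse(is.na(registry$habitats), "", registry$habitats),
                  "\\s*,\\s*")
  mem <- lapply(mem, function(h) h[nzchar(h)])
  all_h <- unique(unlist(mem))
  if (!is.null(communities)) {
    bad <- setdiff(all_h, communities)
    if (length(bad))
      stop("unknown habitat name(s): ", paste(bad, collapse = ", "),
           "; valid names: ", paste(communities, collapse = ", "))
    all_h <- communities
  }
  n_total <- nrow(registry)
  counts <- vapply(all_h, function(h)
    sum(vapply(mem, function(x) h %in% x, logical(1))), integer(1))
  data.frame(habitat = all_h,
             n_taxa = unname(counts),
             fraction = unname(counts) / n_total,
             percent = round_half_up(100 * unname(counts) / n_total, 1),
             row.names = NULL)
}

#' Packaged occurrence fixture: plant taxa from 35 upland-moa coprolites
#'
#' A transcription of the published occurrence table for the Euphrates Cave
#' coprolite series: per taxon, the number of the 35 coprolites in which it
#' was detected by ancient DNA (of the 8 fully-profiled samples for the
#' DNA counts' denominator of 12-sample subset, stored as printed k/n),
#' pollen (with min-mean-max percentages of the pollen sum) and
#' macrofossils.  Used by the acceptance tests as a desk-checkable input.
#'
#' @return data.frame with columns `group`, `family`, `taxon`, `dna_k`,
#'   `dna_n`, `pollen_k`, `pollen_n`, `pollen_min`, `pollen_mean`,
#'   `pollen_max`, `macro_kind`, `macro_k`, `macro_n`.
#' @export
table1_occurrences <- function() {
  path <- system.file("extdata", "table1_occurrences.tsv",
                      package = "coproecol", mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
             comment.char = "#", na.strings = c("NA", ""))
}

#' Packaged radiocarbon fixture: dated coprolites
#'
#' The published table of 12 AMS radiocarbon dates on coprolites: lab code,
#' conventional radiocarbon age (CRA, yr BP), 1-sigma error, delta-13C, and
#' the published 95.4% calibrated range (cal yr BP, older bound first).
#'
#' @return data.frame with columns `sample`, `lab_code`, `cra`, `error`,
#'   `d13c`, `cal_older`, `cal_younger`.
#' @export
table2_dates <- function() {
  path <- system.file("extdata", "table2_dates.tsv",
                      package = "coproecol", mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
}
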