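#' Pipeline configuration
#'
#' Reads (or builds) the key-value configuration driving
#' [run_pipeline()].  Serialised as JSON; unknown keys are an error so
#' that typos fail loudly.  `as_pipeline_config()` fills defaults and
#' validates ranges; the config round-trips losslessly through
#' [write_pipeline_config()] / [read_pipeline_config()].
#'
#' @param path JSON file path.
#' @return a named list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  as_pipeline_config(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' @rdname read_pipeline_config
#' @param config named list of options (see Details).
#' @details Recognised keys: input paths `pollen`, `registry`,
#'   `moa_queries`, `moa_refs`, `moa_refs_sidecar`, `clones`, `rbcl_refs`,
#'   `rbcl_refs_sidecar`, `ages`, `curve`; analysis options `metric`,
#'   `linkage`, `cluster_threshold`, `epi_margin`, `identity_threshold`,
#'   `hpd_level`, `strict_events`; and `out_dir`, `seed`.
#' @export
as_pipeline_config <- function(config = list()) {
  defaults <- list(
    pollen = NULL, registry = NULL, moa_queries = NULL, moa_refs = NULL,
    moa_refs_sidecar = NULL, clones = NULL, rbcl_refs = NULL,
    rbcl_refs_sidecar = NULL, ages = NULL, curve = NULL,
    metric = "uncentered", linkage = "average", cluster_threshold = 0.1,
    epi_margin = 0, identity_threshold = 96, hpd_level = 0.954,
    strict_events = FALSE, out_dir = ".", seed = 1L)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config, keep.null = TRUE)
  if (cfg$cluster_threshold < 0) stop("cluster_threshold must be >= 0")
  if (cfg$epi_margin < 0) stop("epi_margin must be >= 0")
  if (cfg$identity_threshold < 0 || cfg$identity_threshold > 100)
    stop("identity_threshold must lie in [0, 100]")
  if (cfg$hpd_level <= 0 || cfg$hpd_level >= 1)
    stop("hpd_level must lie in (0, 1)")
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       pretty = TRUE, null = "null", digits = NA)
  invisible(path)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full multiproxy pipeline
#'
#' Executes pollen percentages -> EPI representation -> assemblage
#' clustering -> depositor haplotyping -> dietary clone assignment ->
#' radiocarbon calibration -> deposition events / MNI, writing every
#' intermediate table to `out_dir` plus a human-readable `report.txt`.
#' Any input may be omitted; downstream stages that need it are skipped
#' and recorded as such in the report.
#'
#' @param config a [as_pipeline_config()] list, or a path to its JSON.
#' @return a list (invisibly): `percent`, `occurrence`, `epi`, `tree`,
#'   `groups`, `haplotypes`, `assignments`, `calibrated`, `events`,
#'   `individuals`, `mni`, `report`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  cfg <- as_pipeline_config(unclass(config))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  outp <- function(...) file.path(cfg$out_dir, ...)
  res <- list()
  tsv <- function(df, name) write.table(df, outp(name), sep = "\t",
                                        quote = FALSE, row.names = FALSE)

  if (is.null(cfg$pollen)) stop("config must name a 'pollen' matrix TSV")
  pm <- stage("pollen", read_pollen_matrix(must_exist(cfg$pollen)))
  pct <- stage("percentages", pollen_percentages(pm))
  res$percent <- pct
  tsv(cbind(coprolite = rownames(pct), as.data.frame(pct)), "percent.tsv")
  res$occurrence <- occurrence_summary(pm)
  tsv(res$occurrence, "occurrence.tsv")

  registry <- NULL
  if (!is.null(cfg$registry)) {
    registry <- stage("registry", read_taxon_registry(must_exist(cfg$registry)))
    res$epi <- stage("epi",
                     epi_representation(pct, registry, cfg$epi_margin))
    tsv(res$epi, "epi.tsv")
  }

  if (nrow(pct) >= 2) {
    d <- stage("clustering", assemblage_distance(pct, cfg$metric))
    res$tree <- stage("clustering", hierarchical_cluster(d, cfg$linkage))
    write_tree_newick(res$tree, outp("tree.nwk"))
    mem <- assemblage_membership(res$tree, cfg$cluster_threshold)
    res$groups <- mem
    tsv(data.frame(coprolite = names(mem), group = paste0("G", mem)),
        "groups.tsv")
  }

  haplotypes <- NULL
  if (!is.null(cfg$moa_queries) && !is.null(cfg$moa_refs)) {
    refs <- stage("haplotype",
                  read_reference_set(must_exist(cfg$moa_refs),
                                     marker = "control-region",
                                     sidecar = cfg$moa_refs_sidecar))
    qs <- stage("haplotype",
                Biostrings::readDNAStringSet(must_exist(cfg$moa_queries)))
    calls <- lapply(as.character(qs), call_haplotype, refs = refs)
    haplotypes <- vapply(calls, `[[`, character(1), "diagnostic_base")
    names(haplotypes) <- names(qs)
    res$haplotypes <- data.frame(
      coprolite = names(qs),
      species = vapply(calls, function(x)
        x$species %||% NA_character_, character(1)),
      identity = vapply(calls, `[[`, numeric(1), "identity"),
      haplotype = unname(haplotypes),
      damage_consistent = vapply(calls, `[[`, logical(1),
                                 "damage_consistent"))
    tsv(res$haplotypes, "haplotypes.tsv")
  }

  if (!is.null(cfg$clones) && !is.null(cfg$rbcl_refs)) {
    refs <- stage("assign",
                  read_reference_set(must_exist(cfg$rbcl_refs),
                                     marker = "rbcL",
                                     sidecar = cfg$rbcl_refs_sidecar))
    cl <- stage("assign",
                Biostrings::readDNAStringSet(must_exist(cfg$clones)))
    res$assignments <- stage("assign",
                             assign_clones(cl, refs,
                                           threshold = cfg$identity_threshold))
    tsv(res$assignments, "assignments.tsv")
  }

  calibrated <- NULL
  if (!is.null(cfg$ages)) {
    if (is.null(cfg$curve))
      stop("pipeline stage 'calibrate' failed: ages supplied without a ",
           "calibration curve file", call. = FALSE)
    curve <- stage("calibrate", load_curve(must_exist(cfg$curve)))
    ages <- stage("calibrate",
                  read.delim(must_exist(cfg$ages),
                             stringsAsFactors = FALSE))
    calibrated <- stage("calibrate",
                        calibrate_table(ages, curve))
    res$calibrated <- data.frame(
      coprolite = names(calibrated),
      cra = ages$cra, error = ages$error,
      cal_range = vapply(calibrated, format_cal_ranges, character(1)),
      median = vapply(calibrated, `[[`, numeric(1), "median"))
    tsv(res$calibrated, "calibrated.tsv")
  }

  ev <- stage("events", group_events(
    rownames(pct),
    assemblage_groups = if (!is.null(res$groups))
      setNames(paste0("G", res$groups), names(res$groups)),
    haplotypes = haplotypes,
    calibrated_dates = calibrated,
    strict = cfg$strict_events))
  ind <- stage("events", link_individuals(ev))
  res$events <- events_table(ev, ind)
  res$individuals <- ind
  res$mni <- mni(ind)
  tsv(res$events, "events.tsv")
  res$report <- paste0(deposition_report(ev, ind), "\n")
  writeLines(res$report, outp("report.txt"), sep = "")
  invisible(res)
}

must_exist <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  path
}
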