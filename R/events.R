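#' Group coprolites into deposition events
#'
#' Joins coprolites into inferred single-defecation events using three
#' lines of evidence: shared ("highly similar") pollen-assemblage group,
#' identical mtDNA haplotype, and overlapping 95.4% calibrated age ranges.
#' Two coprolites belong to one event iff they share an assemblage group
#' AND their haplotypes are equal (a missing haplotype cannot veto) AND
#' their calibrated ranges overlap (a missing date cannot veto).  Events
#' are the transitive closure of this pairwise relation, so by default a
#' chain may pass through an undated coprolite; `strict = TRUE` requires
#' both members of every joining pair to be haplotyped and dated.
#' Conflicting haplotypes inside one assemblage group always split it.
#'
#' @param coprolites character vector of coprolite ids.
#' @param assemblage_groups named vector of group ids (e.g. from
#'   [assemblage_membership()]); missing entries mean "its own group".
#' @param haplotypes named character vector of haplotype labels; NA =
#'   unhaplotyped.
#' @param calibrated_dates named list of [calibrate()] results; missing or
#'   NULL entries mean undated.
#' @param strict require haplotype and date evidence on both sides of
#'   every joining pair (default FALSE, the permissive reading).
#' @return data.frame of class `deposition_events`: `coprolite`, `event`,
#'   `assemblage_group`, `haplotype`, `dated`.
#' @export
group_events <- function(coprolites, assemblage_groups = NULL,
                         haplotypes = NULL, calibrated_dates = NULL,
                         strict = FALSE) {
  n <- length(coprolites)
  grp <- lookup(assemblage_groups, coprolites,
                default = paste0(".solo.", seq_len(n)))
  hap <- lookup(haplotypes, coprolites, default = NA_character_)
  dat <- lapply(coprolites, function(id)
    if (!is.null(calibrated_dates)) calibrated_dates[[id]] else NULL)

  parent <- seq_len(n)
  comp_hap <- hap # haplotype carried by each component root
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union_ <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri == rj) return(invisible())
    # conflicting component haplotypes are split, never merged -- this
    # also blocks chains running through an unhaplotyped coprolite
    hi <- comp_hap[ri]; hj <- comp_hap[rj]
    if (!is.na(hi) && !is.na(hj) && hi != hj) return(invisible())
    r <- min(ri, rj)
    parent[ri] <<- parent[rj] <<- r
    comp_hap[r] <<- if (is.na(hi)) hj else hi
  }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (grp[i] != grp[j]) next
    hap_ok <- if (strict) !is.na(hap[i]) && !is.na(hap[j]) && hap[i] == hap[j]
      else is.na(hap[i]) || is.na(hap[j]) || hap[i] == hap[j]
    if (!hap_ok) next
    both_dated <- !is.null(dat[[i]]) && !is.null(dat[[j]])
    age_ok <- if (strict) both_dated && ranges_overlap(dat[[i]], dat[[j]])
      else !both_dated || ranges_overlap(dat[[i]], dat[[j]])
    if (age_ok) union_(i, j)
  }
  root <- vapply(seq_len(n), find, integer(1))
  ev <- match(root, unique(root))
  out <- data.frame(coprolite = coprolites,
                    event = paste0("E", ev),
                    assemblage_group = grp,
                    haplotype = hap,
                    dated = !vapply(dat, is.null, logical(1)),
                    row.names = NULL)
  attr(out, "dates") <- setNames(dat, coprolites)
  class(out) <- c("deposition_events", "data.frame")
  out
}

lookup <- function(x, ids, default) {
  if (is.null(x)) return(rep_len(default, length(ids)))
  out <- rep_len(default, length(ids))
  hit <- ids %in% names(x)
  out[hit] <- unname(x[ids[hit]])
  out
}

# consensus haplotype (unique non-NA value, else NA) and age range union
event_summary <- function(events) {
  dates <- attr(events, "dates")
  by_ev <- split(seq_len(nrow(events)), events$event)
  rows <- lapply(names(by_ev), function(e) {
    idx <- by_ev[[e]]
    haps <- unique(stats::na.omit(events$haplotype[idx]))
    dated <- events$dated[idx]
    dts <- dates[idx][dated]
    rng <- if (length(dts)) consensus_range(dts) else NULL
    list(event = e, coprolites = events$coprolite[idx],
         haplotype = if (length(haps) == 1) haps else NA_character_,
         n = length(idx), dated = any(dated), range = rng)
  })
  names(rows) <- names(by_ev)
  rows
}

# intersection of members' HPD hulls: [max(younger), min(older)]
consensus_range <- function(dts) {
  old <- min(vapply(dts, function(d) max(d$ranges$older), numeric(1)))
  yng <- max(vapply(dts, function(d) min(d$ranges$younger), numeric(1)))
  c(older = old, younger = yng)
}

#' Link events to candidate individual birds
#'
#' Merges deposition events into probable individuals: two events are
#' linked iff both carry the same non-missing haplotype AND their
#' consensus calibrated ranges overlap — the situation of coprolites with
#' distinct assemblages but identical haplotype and age, read as "the same
#' bird on a different day".  The evidence here is deliberately stricter
#' than for events: missing haplotypes or missing dates never link.
#' Events are preserved inside each individual group (linking is a
#' "probable" flag, not a collapse).
#'
#' @param events a [group_events()] result.
#' @return data.frame of class `individual_groups`: `event`, `individual`,
#'   `haplotype`, `probable_link` (TRUE when the individual joins more
#'   than one event).
#' @export
link_individuals <- function(events) {
  ev <- event_summary(events)
  m <- length(ev)
  parent <- seq_len(m)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (m > 1) for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    a <- ev[[i]]; b <- ev[[j]]
    if (is.na(a$haplotype) || is.na(b$haplotype)) next
    if (a$haplotype != b$haplotype) next
    if (is.null(a$range) || is.null(b$range)) next
    if (a$range["younger"] <= b$range["older"] &&
        b$range["younger"] <= a$range["older"]) {
      ri <- find(i); rj <- find(j)
      parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  root <- vapply(seq_len(m), find, integer(1))
  ind <- match(root, unique(root))
  multi <- table(ind)
  out <- data.frame(event = names(ev),
                    individual = paste0("I", ind),
                    haplotype = vapply(ev, `[[`, character(1), "haplotype"),
                    probable_link = as.integer(multi[as.character(ind)]) > 1,
                    row.names = NULL)
  class(out) <- c("individual_groups", "data.frame")
  out
}

#' Minimum number of individuals
#'
#' The number of individual groups recovered by [link_individuals()]: the
#' smallest number of depositors consistent with the assemblage, haplotype
#' and age evidence.  Always at least the number of distinct haplotypes
#' observed and at most the number of coprolites.
#'
#' @param individual_groups a [link_individuals()] result.
#' @return integer.
#' @export
mni <- function(individual_groups) {
  length(unique(individual_groups$individual))
}

#' Events / individuals table and narrative report
#'
#' Joins the per-coprolite event assignment with individual links into one
#' table (`events_table`) or a short human-readable accumulation report
#' (`deposition_report`).
#'
#' @param events a [group_events()] result.
#' @param individuals a [link_individuals()] result.
#' @return `events_table`: data.frame `coprolite`, `event`, `individual`,
#'   `assemblage_group`, `haplotype`, `dated`.
#' @export
events_table <- function(events, individuals) {
  idx <- match(events$event, individuals$event)
  data.frame(coprolite = events$coprolite,
             event = events$event,
             individual = individuals$individual[idx],
             assemblage_group = events$assemblage_group,
             haplotype = events$haplotype,
             dated = events$dated,
             row.names = NULL)
}

#' @rdname events_table
#' @export
deposition_report <- function(events, individuals) {
  tab <- events_table(events, individuals)
  ev <- event_summary(events)
  lines <- c(
    sprintf("%d coprolites form %d deposition events; MNI = %d individuals.",
            nrow(tab), length(ev), mni(individuals)),
    vapply(ev, function(e) {
      rng <- if (is.null(e$range)) "undated"
      else sprintf("%d-%d cal BP", round(e$range["older"]),
                   round(e$range["younger"]))
      sprintf("  %s: %s [haplotype %s, %s]", e$event,
              paste(e$coprolites, collapse = ", "),
              ifelse(is.na(e$haplotype), "?", e$haplotype), rng)
    }, character(1)))
  multi <- unique(individuals$individual[individuals$probable_link])
  for (m in multi) {
    evs <- individuals$event[individuals$individual == m]
    lines <- c(lines, sprintf(
      "  %s probably links events %s (same haplotype, overlapping ages).",
      m, paste(evs, collapse = " + ")))
  }
  paste(lines, collapse = "\n")
}
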