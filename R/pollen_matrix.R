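#' Construct a pollen count matrix
#'
#' A `pollen_matrix` bundles raw pollen/spore counts per coprolite with the
#' bookkeeping needed for standard palynological summaries: the observed and
#' total counts of an exotic spike (e.g. *Lycopodium* tablets added before
#' acetolysis) for concentration estimates, per-sample dry masses, and a flag
#' saying which taxa belong to the pollen sum (the denominator used for
#' percentages).  Coprophilous fungal spores such as *Sporormiella* and the
#' spike itself are conventionally kept out of the sum.
#'
#' @param counts non-negative integer matrix, coprolites in rows, taxa in
#'   columns; must have row and column names.
#' @param spike_observed non-negative integer vector, spike grains counted per
#'   coprolite (recycled if length 1).
#' @param spike_total positive integer, number of exotic spores added to every
#'   sample.
#' @param sample_mass_g positive numeric vector, dry subsample mass in grams
#'   (recycled if length 1).
#' @param in_pollen_sum logical vector over taxa; `TRUE` for taxa counted in
#'   the pollen sum.  Default: all taxa in-sum.
#' @param min_count pollen sums below this value are flagged with a warning
#'   (counts of at least 250 are the usual standard).
#' @return An object of class `pollen_matrix`.
#' @export
pollen_matrix <- function(counts, spike_observed = NA_integer_,
                          spike_total = NA_integer_, sample_mass_g = NA_real_,
                          in_pollen_sum = NULL, min_count = 250L) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have row (coprolite) and column (taxon) names")
  if (any(counts < 0) || any(counts != floor(counts)))
    stop("counts must be non-negative integers")
  n <- nrow(counts)
  if (is.null(in_pollen_sum)) in_pollen_sum <- rep(TRUE, ncol(counts))
  if (length(in_pollen_sum) != ncol(counts))
    stop("in_pollen_sum must have one entry per taxon")
  spike_observed <- rep_len(as.integer(spike_observed), n)
  sample_mass_g <- rep_len(as.numeric(sample_mass_g), n)
  x <- structure(list(
    counts = counts,
    spike_observed = setNames(spike_observed, rownames(counts)),
    spike_total = as.integer(spike_total),
    sample_mass_g = setNames(sample_mass_g, rownames(counts)),
    in_pollen_sum = setNames(as.logical(in_pollen_sum), colnames(counts))
  ), class = "pollen_matrix")
  low <- pollen_sums(x) < min_count
  if (any(low))
    warning("pollen sum below ", min_count, " for: ",
            paste(rownames(counts)[low], collapse = ", "))
  x
}

#' @export
print.pollen_matrix <- function(x, ...) {
  cat("<pollen_matrix> ", nrow(x$counts), " coprolites x ", ncol(x$counts),
      " taxa (", sum(x$in_pollen_sum), " in pollen sum)\n", sep = "")
  invisible(x)
}

#' Per-coprolite pollen sums
#'
#' Total count over in-sum taxa for each coprolite.
#' @param x a [pollen_matrix()].
#' @return named integer vector.
#' @export
pollen_sums <- function(x) {
  stopifnot(inherits(x, "pollen_matrix"))
  rowSums(x$counts[, x$in_pollen_sum, drop = FALSE])
}

#' Percentages of the pollen sum
#'
#' Converts raw counts to percentages of the per-coprolite pollen sum.  Only
#' in-sum taxa contribute to the denominator; out-of-sum columns (exotic
#' spike, coprophilous fungi) are still expressed relative to that sum, the
#' standard convention in pollen diagrams.  Rows restricted to in-sum taxa
#' total 100.
#'
#' @param x a [pollen_matrix()].
#' @param in_sum_only drop out-of-sum columns from the result (default TRUE).
#' @return numeric matrix of percentages, same row order as `x`.
#' @export
pollen_percentages <- function(x, in_sum_only = TRUE) {
  stopifnot(inherits(x, "pollen_matrix"))
  tot <- pollen_sums(x)
  if (any(tot == 0))
    stop("zero pollen sum for coprolite(s): ",
         paste(names(tot)[tot == 0], collapse = ", "))
  pct <- sweep(x$counts, 1, tot, "/") * 100
  if (in_sum_only) pct <- pct[, x$in_pollen_sum, drop = FALSE]
  pct
}

#' Occurrence percentage
#'
#' Percent of samples in which something was observed, rounded half-up to the
#' requested precision (the convention used when reporting e.g. "33 of 35
#' coprolites (94.3%)").
#'
#' @param k number of samples with the observation, `0 <= k <= n`.
#' @param n total number of samples, `> 0`.
#' @param digits decimal places to round to (half-up). Default 1.
#' @return numeric percentage.
#' @export
#' @examples
#' occurrence_percent(33, 35) # 94.3
occurrence_percent <- function(k, n, digits = 1) {
  if (any(n <= 0)) stop("n must be positive")
  if (any(k < 0) || any(k > n)) stop("k must be in [0, n]")
  round_half_up(100 * k / n, digits)
}

#' Pollen concentration from an exotic spike
#'
#' Estimates grains per gram of dry sample from the ratio of fossil counts to
#' counted spike grains: `(count / spike_observed) * spike_total / mass_g`.
#'
#' @param count fossil grains counted.
#' @param spike_observed spike grains counted alongside (must be >= 1).
#' @param spike_total spike grains added to the sample.
#' @param mass_g dry sample mass in grams (> 0).
#' @return grains per gram.
#' @export
pollen_concentration <- function(count, spike_observed, spike_total, mass_g) {
  if (any(spike_observed < 1))
    stop("concentration undefined: no spike grains observed")
  if (any(mass_g <= 0)) stop("mass_g must be positive")
  (count / spike_observed) * spike_total / mass_g
}

#' Organic content by loss on ignition
#'
#' Percent mass lost on combustion relative to the original dry mass:
#' `100 * (dry - ash) / dry`.
#'
#' @param dry_mass_g dry mass before combustion (> 0).
#' @param ash_mass_g mass after combustion, `0 <= ash <= dry`.
#' @return percent organic content in `[0, 100]`.
#' @export
loi_organic <- function(dry_mass_g, ash_mass_g) {
  if (any(dry_mass_g <= 0)) stop("dry mass must be positive")
  if (any(ash_mass_g < 0) || any(ash_mass_g > dry_mass_g))
    stop("ash mass must be in [0, dry mass]")
  100 * (dry_mass_g - ash_mass_g) / dry_mass_g
}

#' Per-taxon occurrence summary
#'
#' For each taxon: the number of coprolites in which it occurs and the
#' minimum, mean and maximum percentage of the pollen sum across all
#' coprolites (the "k/n (min-mean-max)" layout of published occurrence
#' tables).
#'
#' @param x a [pollen_matrix()].
#' @param digits rounding for the percentage columns (half-up).
#' @return data.frame with columns `taxon`, `n_present`, `n_total`,
#'   `pct_min`, `pct_mean`, `pct_max`.
#' @export
occurrence_summary <- function(x, digits = 1) {
  stopifnot(inherits(x, "pollen_matrix"))
  pct <- pollen_percentages(x, in_sum_only = FALSE)
  data.frame(
    taxon = colnames(pct),
    n_present = colSums(x$counts > 0),
    n_total = nrow(x$counts),
    pct_min = round_half_up(apply(pct, 2, min), digits),
    pct_mean = round_half_up(colMeans(pct), digits),
    pct_max = round_half_up(apply(pct, 2, max), digits),
    row.names = NULL
  )
}

#' Read / write a pollen matrix as TSV
#'
#' The layout is one row per coprolite with columns `coprolite`,
#' `spike_observed`, `sample_mass_g`, then one column per taxon.  Out-of-sum
#' taxa are marked by a leading `!` on the column name; `spike_total` is
#' stored on a `# spike_total=<int>` comment line.
#'
#' @param path file path.
#' @return [read_pollen_matrix()] returns a `pollen_matrix`.
#' @export
read_pollen_matrix <- function(path) {
  first <- readLines(path, n = 1L)
  spike_total <- NA_integer_
  skip <- 0L
  if (startsWith(first, "#")) {
    m <- regmatches(first, regexec("spike_total=([0-9]+)", first))[[1]]
    if (length(m) == 2) spike_total <- as.integer(m[2])
    skip <- 1L
  }
  df <- read.delim(path, skip = skip, check.names = FALSE,
                   stringsAsFactors = FALSE)
  meta <- c("coprolite", "spike_observed", "sample_mass_g")
  if (!all(meta %in% names(df)))
    stop("pollen matrix TSV must have columns: ", paste(meta, collapse = ", "))
  taxa <- setdiff(names(df), meta)
  cm <- as.matrix(df[, taxa, drop = FALSE])
  rownames(cm) <- df$coprolite
  out_of_sum <- startsWith(taxa, "!")
  colnames(cm) <- sub("^!", "", taxa)
  pollen_matrix(cm, spike_observed = df$spike_observed,
                spike_total = spike_total,
                sample_mass_g = df$sample_mass_g,
                in_pollen_sum = !out_of_sum, min_count = 0L)
}

#' @rdname read_pollen_matrix
#' @param x a `pollen_matrix`.
#' @export
write_pollen_matrix <- function(x, path) {
  stopifnot(inherits(x, "pollen_matrix"))
  taxa <- colnames(x$counts)
  hdr <- ifelse(x$in_pollen_sum, taxa, paste0("!", taxa))
  df <- data.frame(coprolite = rownames(x$counts),
                   spike_observed = x$spike_observed,
                   sample_mass_g = x$sample_mass_g,
                   check.names = FALSE)
  df <- cbind(df, as.data.frame(x$counts))
  names(df) <- c("coprolite", "spike_observed", "sample_mass_g", hdr)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.na(x$spike_total))
    writeLines(paste0("# spike_total=", x$spike_total), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
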