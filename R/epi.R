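#' Environmental prevalence index (EPI)
#'
#' The EPI predicts how common a pollen type should be in the environmental
#' pollen rain, independent of diet, as the product of three ordinal
#' factors: pollination mode (wind = 3, insect or other animals = 1),
#' pollen production (1-3) and dispersability (1-3).  Values range from 1
#' (animal pollinated, low production, restricted dispersal) to 27 (wind
#' pollinated, prolific production, wide dispersal).
#'
#' @param mode 1 (animal) or 3 (wind).
#' @param production integer 1-3.
#' @param dispersal integer 1-3.
#' @return integer EPI in `[1, 27]`.
#' @export
#' @examples
#' compute_epi(3, 3, 3) # 27
compute_epi <- function(mode, production, dispersal) {
  if (!all(mode %in% c(1L, 3L)))
    stop("pollination mode must be 1 (animal) or 3 (wind)")
  if (!all(production %in% 1:3)) stop("pollen production must be in 1:3")
  if (!all(dispersal %in% 1:3)) stop("dispersability must be in 1:3")
  as.integer(mode) * as.integer(production) * as.integer(dispersal)
}

#' Ranked pollen abundance
#'
#' Ranks taxa by their summed percentages over all coprolites: rank 1 is the
#' most abundant pollen/spore type; ties receive the average of the tied
#' rank positions.
#'
#' @param pct percentage matrix (coprolites x taxa), e.g. from
#'   [pollen_percentages()].
#' @return named numeric vector of ranks.
#' @export
ranked_abundance <- function(pct) {
  pct <- as.matrix(pct)
  if (ncol(pct) < 1) stop("percentage matrix is empty")
  sums <- colSums(pct)
  rank(-sums, ties.method = "average")
}

#' Expected rank under the EPI null
#'
#' The null model says coprolite pollen abundance tracks environmental
#' prevalence: sorting taxa by EPI descending gives the expected abundance
#' order (the cumulative-frequency line of a rank-vs-EPI plot).  Taxa tied
#' on EPI share the average of their tied positions.
#'
#' @param epi named numeric vector of per-taxon EPI values in `[1, 27]`.
#' @return named numeric vector of expected ranks.
#' @export
null_expected_rank <- function(epi) {
  if (any(epi < 1 | epi > 27)) stop("EPI values must lie in [1, 27]")
  rank(-epi, ties.method = "average")
}

#' Classify taxa as over-, under- or neutrally represented
#'
#' A taxon whose observed abundance rank beats its EPI-expected rank
#' (smaller number = more abundant than the environment predicts) is called
#' "over" (a likely dietary component); one ranking worse than expected is
#' "under" (incidental or environmental); within `margin` of the line is
#' "neutral".
#'
#' @param observed_rank observed abundance ranks ([ranked_abundance()]).
#' @param expected_rank expected ranks under the null
#'   ([null_expected_rank()]).
#' @param margin non-negative half-width of the neutral band, in rank units
#'   (default 0).
#' @return character vector with levels `"over"`, `"neutral"`, `"under"`.
#' @export
classify_representation <- function(observed_rank, expected_rank, margin = 0) {
  if (margin < 0) stop("margin must be non-negative")
  out <- rep("neutral", length(observed_rank))
  out[observed_rank < expected_rank - margin] <- "over"
  out[observed_rank > expected_rank + margin] <- "under"
  names(out) <- names(observed_rank)
  out
}

#' EPI representation analysis
#'
#' Convenience wrapper joining a percentage matrix to registry EPI factors:
#' computes per-taxon EPI, observed and expected ranks, and the
#' over/neutral/under call.  Taxa without index data (`epi_include` FALSE
#' or missing factors) are dropped, mirroring the usual practice of
#' excluding taxa for which no prevalence scores exist.
#'
#' @param pct percentage matrix (coprolites x taxa).
#' @param registry a [taxon_registry()] carrying `epi_mode`,
#'   `epi_production`, `epi_dispersal` and optionally `epi_include`.
#' @param margin neutral band half-width, see [classify_representation()].
#' @return data.frame `taxon`, `epi`, `summed_pct`, `observed_rank`,
#'   `expected_rank`, `call`.
#' @export
epi_representation <- function(pct, registry, margin = 0) {
  pct <- as.matrix(pct)
  idx <- match(colnames(pct), registry$taxon)
  keep <- !is.na(idx)
  reg <- registry[idx[keep], , drop = FALSE]
  if ("epi_include" %in% names(reg)) keep2 <- isTRUE_vec(reg$epi_include)
  else keep2 <- !is.na(reg$epi_mode)
  reg <- reg[keep2, , drop = FALSE]
  pct <- pct[, colnames(pct) %in% reg$taxon, drop = FALSE]
  if (ncol(pct) == 0) stop("no taxa with EPI factor data")
  reg <- reg[match(colnames(pct), reg$taxon), ]
  epi <- compute_epi(reg$epi_mode, reg$epi_production, reg$epi_dispersal)
  obs <- ranked_abundance(pct)
  expd <- null_expected_rank(setNames(epi, colnames(pct)))
  data.frame(taxon = colnames(pct),
             epi = epi,
             summed_pct = colSums(pct),
             observed_rank = unname(obs),
             expected_rank = unname(expd),
             call = unname(classify_representation(obs, expd, margin)),
             row.names = NULL)
}

#' Permutation-based neutral margin (optional)
#'
#' The published method reads over/under representation straight off the
#' rank-vs-null scatter with no formal test.  As an optional aid this
#' estimates the spread of |observed - expected| rank differences when
#' abundances are shuffled across taxa, returning the requested quantile as
#' a margin for [classify_representation()].  Off by default in the
#' pipeline.
#'
#' @param epi per-taxon EPI values.
#' @param n_perm number of shuffles.
#' @param quantile_level quantile of the null |rank difference| to return.
#' @param seed RNG seed.
#' @return a single non-negative margin in rank units.
#' @export
epi_permutation_margin <- function(epi, n_perm = 999, quantile_level = 0.95,
                                   seed = 1L) {
  n <- length(epi)
  expd <- null_expected_rank(epi)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  diffs <- replicate(n_perm, {
    obs <- sample(seq_len(n))
    max(abs(obs - expd))
  })
  as.numeric(stats::quantile(diffs, quantile_level))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Blank EPI factor template
#'
#' Returns an editable per-taxon template for the three EPI factors.  The
#' package deliberately ships no asserted factor values: scores come from
#' regional palynological reference works and are a user input.
#'
#' @param taxa character vector of taxon names.
#' @return data.frame with empty factor columns and `epi_include = TRUE`.
#' @export
epi_factor_template <- function(taxa) {
  data.frame(taxon = taxa, epi_mode = NA_integer_,
             epi_production = NA_integer_, epi_dispersal = NA_integer_,
             epi_include = TRUE, row.names = NULL)
}
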