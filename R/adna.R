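#' Read a reference sequence set
#'
#' Loads a FASTA reference set (e.g. control-region fragments for species
#' identification, or full-length rbcL genes for dietary assignment) with an
#' optional sidecar TSV mapping record ids to taxon labels and, for coding
#' markers, the reading-frame offset of each record (0, 1 or 2 bases before
#' the first complete codon).
#'
#' @param fasta path to a FASTA file.
#' @param marker marker name (free text, stored on the object).
#' @param sidecar optional TSV with columns `id`, `taxon`, and optionally
#'   `frame_offset`.
#' @return a list of class `reference_set`: `$seqs` (a
#'   [Biostrings::DNAStringSet]), `$marker`, `$taxon` (named), and
#'   `$frame_offset` (named integer, default 0).
#' @export
read_reference_set <- function(fasta, marker = "marker", sidecar = NULL) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  if (anyDuplicated(names(seqs))) stop("duplicate reference ids")
  reference_set(seqs, marker = marker,
                sidecar = if (!is.null(sidecar))
                  read.delim(sidecar, stringsAsFactors = FALSE))
}

#' @rdname read_reference_set
#' @param seqs a named [Biostrings::DNAStringSet] (or named character
#'   vector) of reference sequences.
#' @export
reference_set <- function(seqs, marker = "marker", sidecar = NULL) {
  if (!inherits(seqs, "DNAStringSet"))
    seqs <- Biostrings::DNAStringSet(seqs)
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("reference sequences must have unique names")
  taxon <- setNames(names(seqs), names(seqs))
  frame <- setNames(rep(0L, length(seqs)), names(seqs))
  if (!is.null(sidecar)) {
    idx <- match(names(seqs), sidecar$id)
    if ("taxon" %in% names(sidecar))
      taxon[!is.na(idx)] <- sidecar$taxon[idx[!is.na(idx)]]
    if ("frame_offset" %in% names(sidecar))
      frame[!is.na(idx)] <- as.integer(sidecar$frame_offset[idx[!is.na(idx)]])
  }
  structure(list(seqs = seqs, marker = marker, taxon = taxon,
                 frame_offset = frame),
            class = "reference_set")
}

#' @export
print.reference_set <- function(x, ...) {
  cat("<reference_set> ", length(x$seqs), " ", x$marker, " sequences, ",
      "lengths ", min(Biostrings::width(x$seqs)), "-",
      max(Biostrings::width(x$seqs)), " bp\n", sep = "")
  invisible(x)
}

# percent identity between equal-length ungapped strings; positions where
# either side is N (or gap) are dropped from numerator and denominator
hamming_identity <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  if (length(av) != length(bv)) stop("sequences differ in length")
  use <- av != "N" & bv != "N" & av != "-" & bv != "-"
  if (!any(use)) return(NA_real_)
  100 * sum(av[use] == bv[use]) / sum(use)
}

#' Species / haplotype call from a short diagnostic amplicon
#'
#' Identifies the depositing species from a short (here 31 bp,
#' primer-trimmed) mitochondrial control-region fragment by maximum
#' ungapped identity against a reference set, and reads off the haplotype
#' state at a diagnostic position.  Equal best identity across several
#' species is a legal outcome and is reported as ambiguous rather than
#' broken arbitrarily — very short fragments cannot separate all species
#' pairs.  A call is flagged damage-consistent when it differs from its
#' best reference, or from another reference, only by C/T substitutions:
#' cytosine deamination in ancient DNA produces exactly such transitions.
#'
#' @param query a single DNA sequence (character or DNAString), length
#'   `fragment_length` after primer trimming.
#' @param refs a [reference_set()] whose sequences cover the fragment.
#' @param diagnostic_pos 1-based position of the diagnostic site
#'   (default 25).
#' @param fragment_length required query length (default 31).
#' @return a list of class `haplotype_call`: `query`, `species` (NA when
#'   ambiguous), `ambiguous`, `candidates`, `identity`, `diagnostic_base`,
#'   `damage_consistent`.
#' @export
call_haplotype <- function(query, refs, diagnostic_pos = 25L,
                           fragment_length = 31L) {
  q <- toupper(as.character(query))
  if (nchar(q) != fragment_length)
    stop("query must be ", fragment_length, " bp after primer trimming, got ",
         nchar(q))
  if (grepl("[^ACGTRYSWKMBDHVN-]", q))
    stop("query contains non-IUPAC characters")
  rs <- toupper(as.character(refs$seqs))
  rs <- substr(rs, 1L, fragment_length)
  if (any(nchar(rs) < fragment_length))
    stop("references do not span the diagnostic fragment")
  ids <- vapply(rs, hamming_identity, numeric(1), a = q)
  best <- max(ids)
  hits <- names(refs$seqs)[ids == best]
  species <- unique(refs$taxon[hits])
  ambiguous <- length(species) > 1
  # all mismatches to some reference are C<->T?
  ct_only <- vapply(rs, function(r) {
    av <- strsplit(q, "")[[1]]; bv <- strsplit(r, "")[[1]]
    mm <- which(av != bv & av != "N" & bv != "N")
    length(mm) >= 1 &&
      all((av[mm] == "C" & bv[mm] == "T") | (av[mm] == "T" & bv[mm] == "C"))
  }, logical(1))
  structure(list(
    query = q,
    species = if (ambiguous) NA_character_ else species,
    ambiguous = ambiguous,
    candidates = species,
    identity = best,
    diagnostic_base = substr(q, diagnostic_pos, diagnostic_pos),
    damage_consistent = any(ct_only)
  ), class = "haplotype_call")
}

#' Internal stop codon check
#'
#' Translates a nucleotide fragment in the stated frame and reports whether
#' any complete, in-frame codon is a stop (TAA/TAG/TGA).  A stop pattern
#' that would only arise in the trailing partial codon does not count: only
#' complete codons inside the fragment are "internal".  In a
#' highly-conserved protein-coding marker such as rbcL an internal stop is
#' a hallmark of post-mortem damage (or a pseudogene), not a real dietary
#' sequence difference.
#'
#' @param seq nucleotide sequence (character or DNAString).
#' @param frame_offset bases to skip before the first complete codon (0-2).
#' @return logical.
#' @export
detect_stop_codon <- function(seq, frame_offset = 0L) {
  s <- toupper(as.character(seq))
  if (!frame_offset %in% 0:2) stop("frame_offset must be 0, 1 or 2")
  s <- substr(s, frame_offset + 1L, nchar(s))
  n_codons <- nchar(s) %/% 3L
  if (n_codons < 1L) stop("fragment too short to contain a complete codon")
  starts <- 3L * (seq_len(n_codons) - 1L) + 1L
  codons <- substring(s, starts, starts + 2L)
  any(codons %in% c("TAA", "TAG", "TGA"))
}

#' Assign a cloned dietary amplicon to a reference taxon
#'
#' Aligns a short clone (here a 95 bp rbcL fragment) semi-globally against
#' each full-length reference (clone global, reference local; match +1,
#' mismatch -1, gap -2 by default), computes percent identity over aligned
#' columns (positions involving N are dropped from both numerator and
#' denominator), and assigns the clone to the best reference when identity
#' exceeds the threshold and the clone carries no internal stop codon in
#' the reference reading frame.  The best reference is reported even for
#' unassigned clones.
#'
#' @param clone a single DNA sequence, 60-150 bp.
#' @param refs a [reference_set()] of full-length coding references.
#' @param threshold percent identity that must be exceeded (default 96).
#' @param match,mismatch,gap alignment scores (gap applies per gapped
#'   column).
#' @param allow_stop if TRUE, an internal stop does not veto assignment.
#' @return a list of class `clone_assignment`: `clone`, `best_taxon`,
#'   `best_ref`, `identity`, `ref_start`, `ref_end`, `internal_stop`,
#'   `assigned`.
#' @export
assign_clone <- function(clone, refs, threshold = 96, match = 1,
                         mismatch = -1, gap = -2, allow_stop = FALSE) {
  q <- toupper(as.character(clone))
  if (nchar(q) < 60 || nchar(q) > 150)
    stop("clone length must be 60-150 bp, got ", nchar(q))
  if (length(refs$seqs) == 0) stop("empty reference set")
  sub_mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = match, mismatch = mismatch, baseOnly = FALSE)
  best <- list(id = -Inf, ref = NA_character_)
  for (rn in names(refs$seqs)) {
    aln <- Biostrings::pairwiseAlignment(
      pattern = Biostrings::DNAString(q), subject = refs$seqs[[rn]],
      type = "global-local", substitutionMatrix = sub_mat,
      gapOpening = 0, gapExtension = -gap)
    pa <- as.character(Biostrings::alignedPattern(aln))
    sa <- as.character(Biostrings::alignedSubject(aln))
    idn <- aligned_identity(pa, sa)
    if (!is.na(idn) && idn > best$id) {
      best <- list(id = idn, ref = rn,
                   start = Biostrings::start(Biostrings::subject(aln)),
                   end = Biostrings::end(Biostrings::subject(aln)))
    }
  }
  # reading frame of the clone inferred from its aligned span on the ref
  fo_ref <- refs$frame_offset[[best$ref]] %||% 0L
  phase <- (best$start - 1L - fo_ref) %% 3L
  clone_frame <- (3L - phase) %% 3L
  stop_hit <- detect_stop_codon(q, clone_frame)
  structure(list(
    clone = q,
    best_taxon = unname(refs$taxon[[best$ref]]),
    best_ref = best$ref,
    identity = best$id,
    ref_start = best$start,
    ref_end = best$end,
    internal_stop = stop_hit,
    assigned = best$id > threshold && (allow_stop || !stop_hit)
  ), class = "clone_assignment")
}

# identity over aligned columns; N-containing and double-gap columns dropped
aligned_identity <- function(pa, sa) {
  av <- strsplit(pa, "")[[1]]
  bv <- strsplit(sa, "")[[1]]
  use <- av != "N" & bv != "N" & !(av == "-" & bv == "-")
  if (!any(use)) return(NA_real_)
  100 * sum(av[use] == bv[use]) / sum(use)
}

#' Assign many clones
#'
#' Batch version of [assign_clone()] returning a tidy table.  Duplicate
#' sequences are aligned once, and all clones are aligned against each
#' reference in a single vectorised call, so large libraries stay fast.
#'
#' @param clones named character vector or DNAStringSet of clone sequences.
#' @param refs a [reference_set()].
#' @param threshold,match,mismatch,gap,allow_stop as in [assign_clone()].
#' @return data.frame with one row per clone.
#' @export
assign_clones <- function(clones, refs, threshold = 96, match = 1,
                          mismatch = -1, gap = -2, allow_stop = FALSE) {
  seqs <- toupper(as.character(clones))
  ids <- names(seqs) %||% paste0("clone", seq_along(seqs))
  if (length(refs$seqs) == 0) stop("empty reference set")
  bad <- nchar(seqs) < 60 | nchar(seqs) > 150
  if (any(bad)) stop("clone length must be 60-150 bp: ",
                     paste(ids[bad], collapse = ", "))
  uniq <- unique(seqs)
  best_id <- rep(-Inf, length(uniq))
  best_ref <- rep(NA_character_, length(uniq))
  best_start <- best_end <- rep(NA_integer_, length(uniq))
  # exact substring of a reference = identity 100, the attainable maximum
  for (i in seq_along(uniq)) {
    if (grepl("N", uniq[i], fixed = TRUE)) next
    for (rn in names(refs$seqs)) {
      hit <- Biostrings::matchPattern(uniq[i], refs$seqs[[rn]])
      if (length(hit) > 0) {
        best_id[i] <- 100
        best_ref[i] <- rn
        best_start[i] <- Biostrings::start(hit)[1]
        best_end[i] <- Biostrings::end(hit)[1]
        break
      }
    }
  }
  # substitution-only hits: escalate a mismatch-tolerant exact search
  # (cytosine-deamination damage is substitutional, so this resolves
  # nearly everything without dynamic programming)
  for (k in c(2L, 4L, 8L)) {
    todo <- which(!is.finite(best_id))
    if (!length(todo)) break
    for (i in todo) {
      if (grepl("N", uniq[i], fixed = TRUE)) next
      for (rn in names(refs$seqs)) {
        hit <- Biostrings::matchPattern(uniq[i], refs$seqs[[rn]],
                                        max.mismatch = k)
        if (length(hit) == 0) next
        ids <- vapply(seq_along(hit), function(h)
          hamming_identity(uniq[i], as.character(hit[[h]])), numeric(1))
        h <- which.max(ids)
        if (ids[h] > best_id[i]) {
          best_id[i] <- ids[h]
          best_ref[i] <- rn
          best_start[i] <- Biostrings::start(hit)[h]
          best_end[i] <- Biostrings::end(hit)[h]
        }
      }
    }
  }
  todo <- which(!is.finite(best_id))
  if (length(todo)) {
    qset <- Biostrings::DNAStringSet(uniq[todo])
    sub_mat <- Biostrings::nucleotideSubstitutionMatrix(
      match = match, mismatch = mismatch, baseOnly = FALSE)
    for (rn in names(refs$seqs)) {
      aln <- Biostrings::pairwiseAlignment(
        pattern = qset, subject = refs$seqs[[rn]],
        type = "global-local", substitutionMatrix = sub_mat,
        gapOpening = 0, gapExtension = -gap)
      pa <- as.character(Biostrings::alignedPattern(aln))
      sa <- as.character(Biostrings::alignedSubject(aln))
      idn <- mapply(aligned_identity, pa, sa, USE.NAMES = FALSE)
      better <- !is.na(idn) & idn > best_id[todo]
      ss <- Biostrings::start(Biostrings::subject(aln))
      se <- Biostrings::end(Biostrings::subject(aln))
      best_id[todo[better]] <- idn[better]
      best_ref[todo[better]] <- rn
      best_start[todo[better]] <- ss[better]
      best_end[todo[better]] <- se[better]
    }
  }
  stop_hit <- vapply(seq_along(uniq), function(i) {
    fo_ref <- refs$frame_offset[[best_ref[i]]]
    phase <- (best_start[i] - 1L - fo_ref) %% 3L
    detect_stop_codon(uniq[i], (3L - phase) %% 3L)
  }, logical(1))
  m <- match(seqs, uniq)
  data.frame(clone = ids,
             best_taxon = unname(refs$taxon[best_ref[m]]),
             identity = best_id[m],
             ref_start = best_start[m], ref_end = best_end[m],
             internal_stop = stop_hit[m],
             assigned = best_id[m] > threshold &
               (allow_stop | !stop_hit[m]),
             row.names = NULL)
}

#' Collapse clone libraries to unique sequences
#'
#' Exact-sequence deduplication across clone libraries, preserving how many
#' times each unique sequence was seen and in which coprolites.
#'
#' @param clones character vector of sequences.
#' @param coprolite optional parallel vector of source coprolite ids.
#' @return data.frame `sequence`, `multiplicity`, `coprolites`
#'   (comma-separated unique sources), ordered by first appearance.
#' @export
collapse_unique_clones <- function(clones, coprolite = NULL) {
  clones <- toupper(as.character(clones))
  if (length(clones) == 0)
    return(data.frame(sequence = character(), multiplicity = integer(),
                      coprolites = character()))
  if (is.null(coprolite)) coprolite <- rep(NA_character_, length(clones))
  first <- !duplicated(clones)
  uniq <- clones[first]
  data.frame(
    sequence = uniq,
    multiplicity = as.integer(table(factor(clones, levels = uniq))),
    coprolites = vapply(uniq, function(s) {
      src <- unique(coprolite[clones == s])
      paste(src[!is.na(src)], collapse = ",")
    }, character(1), USE.NAMES = FALSE),
    row.names = NULL
  )
}
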