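## epitope_engine: the PIRCHE-T2-style score.
##
## For a donor-recipient pair: enumerate all 15-mers of mismatched donor
## alleles, drop peptides that occur verbatim anywhere in the recipient's
## own HLA sequences (self peptides, compared against all five scored loci,
## not only the mismatched locus), score the survivors against each
## recipient DRB1 presenter under the active binding criterion, and count
## unique (peptide sequence, presenter) tuples per locus, per class, and
## pooled over all loci. The same peptide sequence arising from two donor
## alleles counts once.

#' Enumerate all k-mer windows of a protein sequence
#'
#' Windows are 0-based, half-open: the peptide at `start` covers residues
#' `[start, start + k)`.
#'
#' @param sequence amino-acid string.
#' @param k window length (default 15).
#' @param source_allele optional allele name recorded with each peptide.
#' @return Data frame with columns `peptide`, `start`, `source_allele`
#'   (`max(0, nchar(sequence) - k + 1)` rows, in order of `start`).
#' @export
enumerate_peptides <- function(sequence, k = 15L, source_allele = NA_character_) {
  stopifnot(length(sequence) == 1L, k >= 1L)
  assert_aa(sequence)
  L <- nchar(sequence)
  n <- L - k + 1L
  if (n <= 0L) {
    return(data.frame(peptide = character(0), start = integer(0),
                      source_allele = character(0), stringsAsFactors = FALSE))
  }
  starts <- 0:(n - 1L)
  data.frame(peptide = substring(sequence, starts + 1L, starts + k),
             start = starts, source_allele = source_allele,
             stringsAsFactors = FALSE)
}

#' Remove self peptides
#'
#' A peptide is self when its sequence occurs as an exact substring of any
#' recipient sequence. Order is preserved.
#'
#' @param peptides data frame as returned by [enumerate_peptides()], or a
#'   character vector of peptide sequences.
#' @param recipient_sequences character vector of recipient protein
#'   sequences (may be empty, in which case nothing is filtered).
#' @return The non-self subset of `peptides`, same type as the input.
#' @export
filter_self_peptides <- function(peptides, recipient_sequences) {
  seqs <- if (is.data.frame(peptides)) peptides$peptide else peptides
  if (!length(seqs) || !length(recipient_sequences)) return(peptides)
  is_self <- vapply(seqs, function(p) {
    any(vapply(recipient_sequences,
               function(s) grepl(p, s, fixed = TRUE), logical(1)))
  }, logical(1), USE.NAMES = FALSE)
  if (is.data.frame(peptides)) peptides[!is_self, , drop = FALSE] else peptides[!is_self]
}

#' Precompute peptide sets and per-presenter pass matrices for a catalog
#'
#' Internal workhorse shared by score_pair and score_cohort: all unique
#' k-mers across the catalog are scored once against every DRB1 allele in
#' the catalog, for each requested mode.
#' @noRd
scoring_context <- function(catalog, predictor, modes, k = predictor$k) {
  entries <- catalog$entries
  pep_by_allele <- lapply(seq_len(nrow(entries)), function(i) {
    enumerate_peptides(entries$sequence[i], k = k)$peptide
  })
  names(pep_by_allele) <- entries$allele
  U <- unique(unlist(pep_by_allele, use.names = FALSE))
  idx_by_allele <- lapply(pep_by_allele, match, table = U)
  presenters <- entries$allele[entries$locus == "DRB1"]
  U_mat <- peptides_to_int(U, k)
  pass <- lapply(modes, function(mode) {
    m <- matrix(FALSE, nrow = length(U), ncol = length(presenters),
                dimnames = list(NULL, presenters))
    for (p in presenters) {
      raw <- pwm_score_matrix(U_mat, predictor_pwm(predictor, p))
      m[, p] <- mode_passes(mode,
                            affinity_nM = predictor$A * exp(-predictor$b * raw),
                            percentile_rank = percentile_rank_of(predictor, raw, p))
    }
    m
  })
  names(pass) <- vapply(modes, function(m) m$name, "")
  list(U = U, idx_by_allele = idx_by_allele, presenters = presenters,
       pass = pass, k = k)
}

#' @noRd
score_pair_ctx <- function(pair, ctx, mode_name) {
  mm <- find_mismatches(pair)
  self_idx <- unique(unlist(ctx$idx_by_allele[unique(unlist(pair$recipient))],
                            use.names = FALSE))
  presenters <- unique(pair$presenters)
  pm <- ctx$pass[[mode_name]]
  pcols <- match(presenters, colnames(pm))
  if (anyNA(pcols)) {
    stop("presenter(s) not in catalog: ",
         paste(presenters[is.na(pcols)], collapse = ", "), call. = FALSE)
  }
  nU <- length(ctx$U)
  per_locus <- setNames(integer(length(LOCI)), LOCI)
  all_keys <- integer(0)
  for (locus in intersect(LOCI, names(mm))) {
    if (!length(mm[[locus]])) next
    cand <- setdiff(unique(unlist(ctx$idx_by_allele[mm[[locus]]],
                                  use.names = FALSE)), self_idx)
    if (!length(cand)) next
    keys <- integer(0)
    for (j in seq_along(pcols)) {
      hit <- cand[pm[cand, pcols[j]]]
      if (length(hit)) keys <- c(keys, hit + (j - 1L) * nU)
    }
    per_locus[locus] <- length(keys)  # unique by construction within a locus
    all_keys <- c(all_keys, keys)
  }
  list(per_locus = per_locus, total = length(unique(all_keys)))
}

#' Score one donor-recipient pair
#'
#' Counts unique (peptide sequence, presenter) tuples from mismatched donor
#' alleles that survive the self filter and satisfy the mode's binding
#' criterion, per locus and pooled.
#'
#' @param pair a [transplant_pair()].
#' @param catalog an [allele_catalog()] resolving all allele names.
#' @param mode a [predictor_mode()].
#' @param predictor a [surrogate_predictor()] (or adapter-compatible object).
#' @return Object of class `pirche_score`: list with `per_locus` (named
#'   integer over A, B, C, DRB1, DQB1), `class1` (= A + B + C), `class2`
#'   (= DRB1 + DQB1), `total` (unique tuples pooled over loci), `mode`.
#' @export
score_pair <- function(pair, catalog, mode, predictor) {
  stopifnot(inherits(pair, "transplant_pair"),
            inherits(catalog, "allele_catalog"),
            inherits(mode, "predictor_mode"))
  if (!length(pair$presenters)) stop("pair has no presenters", call. = FALSE)
  catalog_sequence(catalog, unique(unlist(c(pair$donor, pair$recipient))))
  ctx <- scoring_context(catalog, predictor, list(mode))
  res <- score_pair_ctx(pair, ctx, mode$name)
  new_pirche_score(res$per_locus, res$total, mode)
}

#' @noRd
new_pirche_score <- function(per_locus, total, mode) {
  structure(list(per_locus = per_locus,
                 class1 = sum(per_locus[CLASS1_LOCI]),
                 class2 = sum(per_locus[CLASS2_LOCI]),
                 total = total, mode = mode),
            class = "pirche_score")
}

#' @export
print.pirche_score <- function(x, ...) {
  cat(sprintf("<pirche_score> mode=%s(threshold=%g) total=%d class1=%d class2=%d\n",
              x$mode$name, x$mode$threshold, x$total, x$class1, x$class2))
  print(x$per_locus)
  invisible(x)
}

#' Score a cohort of pairs under one or more modes
#'
#' Produces one row per patient with per-locus, class, and total scores
#' under each mode (column suffixes taken from `labels`), plus per-locus
#' mismatch counts. Per-patient failures are recorded and skipped with a
#' warning; the pipeline continues.
#'
#' @param pairs named list of [transplant_pair()] objects.
#' @param catalog an [allele_catalog()].
#' @param modes list of [predictor_mode()] objects (default: both the
#'   affinity and the rank criterion at their default thresholds).
#' @param predictor a [surrogate_predictor()].
#' @param labels character column suffixes, one per mode (default
#'   `"v3"`/`"v4"` for the default modes).
#' @return Data frame with columns `patient_id`, `nmm_<locus>`, and for each
#'   mode label `m`: `A_<m>` ... `DQB1_<m>`, `class1_<m>`, `class2_<m>`,
#'   `total_<m>`. Attribute `skipped` lists failed patients and reasons.
#' @export
score_cohort <- function(pairs, catalog,
                         modes = list(predictor_mode("affinity_v3"),
                                      predictor_mode("rank_v4")),
                         predictor = surrogate_predictor(),
                         labels = NULL) {
  if (is.null(labels)) {
    labels <- vapply(modes, function(m) {
      switch(m$name, affinity_v3 = "v3", rank_v4 = "v4", m$name)
    }, "")
  }
  stopifnot(length(labels) == length(modes), !anyDuplicated(labels))
  ids <- names(pairs)
  if (is.null(ids)) ids <- sprintf("P%04d", seq_along(pairs))
  ctx <- scoring_context(catalog, predictor, modes)
  rows <- vector("list", length(pairs))
  skipped <- list()
  for (i in seq_along(pairs)) {
    res <- tryCatch({
      pair <- pairs[[i]]
      mm <- find_mismatches(pair)
      nmm <- setNames(integer(length(LOCI)), LOCI)
      nmm[names(mm)] <- lengths(mm)
      row <- c(setNames(as.list(nmm), paste0("nmm_", LOCI)))
      for (j in seq_along(modes)) {
        sc <- score_pair_ctx(pair, ctx, modes[[j]]$name)
        lab <- labels[j]
        row <- c(row,
                 setNames(as.list(sc$per_locus), paste0(LOCI, "_", lab)),
                 setNames(list(sum(sc$per_locus[CLASS1_LOCI]),
                               sum(sc$per_locus[CLASS2_LOCI]),
                               sc$total),
                          paste0(c("class1_", "class2_", "total_"), lab)))
      }
      row
    }, error = function(e) e)
    if (inherits(res, "error")) {
      skipped[[ids[i]]] <- conditionMessage(res)
    } else {
      rows[[i]] <- data.frame(c(list(patient_id = ids[i]), res),
                              stringsAsFactors = FALSE)
    }
  }
  if (length(skipped)) {
    warning(length(skipped), " patient(s) skipped during scoring; see attr 'skipped'",
            call. = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) out <- data.frame(patient_id = character(0))
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Write a cohort score table to CSV
#'
#' @param scores data frame from [score_cohort()].
#' @param path output path.
#' @export
write_score_table <- function(scores, path) {
  write.csv(scores, path, row.names = FALSE)
  invisible(path)
}
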