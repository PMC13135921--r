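## fixtures: deterministic toy catalogs and the exhaustive scoring oracle.
##
## Toy catalogs use the standard 20-letter amino-acid alphabet so they are
## valid inputs to any external predictor adapter. The brute-force scorer
## materializes every (peptide, presenter) tuple explicitly with scalar
## calls and no shortcuts; it exists as an independent reference for the
## vectorized engine and is only meant for small catalogs.

#' Generate a deterministic toy allele catalog
#'
#' Per locus, a seeded ancestral sequence is drawn and each allele is
#' derived from it by independent point substitutions at the given rate
#' (substitutions always change the residue). Allele names are
#' `"LOCUS*01"`, `"LOCUS*02"`, ...
#'
#' @param n_alleles alleles per locus (default 8).
#' @param length sequence length (default 30; must be >= the peptide
#'   length you intend to score).
#' @param rate per-position substitution probability in (0, 1], or 0 for
#'   identical alleles (default 0.2).
#' @param seed integer seed (default 7).
#' @param loci loci to generate (default all five scored loci).
#' @return An [allele_catalog()].
#' @export
make_toy_catalog <- function(n_alleles = 8L, length = 30L, rate = 0.2,
                             seed = 7L, loci = LOCI) {
  stopifnot(n_alleles >= 1L, length >= 1L, rate >= 0, rate <= 1)
  with_seed(seed, {
    alleles <- character(0)
    seqs <- character(0)
    for (locus in loci) {
      anc <- sample(AA_ALPHABET, length, replace = TRUE)
      for (i in seq_len(n_alleles)) {
        s <- anc
        mut <- runif(length) < rate
        if (any(mut)) {
          s[mut] <- vapply(s[mut], function(a) {
            sample(setdiff(AA_ALPHABET, a), 1L)
          }, "", USE.NAMES = FALSE)
        }
        alleles <- c(alleles, sprintf("%s*%02d", locus, i))
        seqs <- c(seqs, paste(s, collapse = ""))
      }
    }
    allele_catalog(alleles, seqs)
  })
}

#' Sample a random transplant pair from a catalog
#'
#' Convenience fixture: donor and recipient genotypes drawn independently,
#' two chromosomes per locus, uniform over the catalog's alleles (or with
#' supplied per-locus frequencies).
#'
#' @param catalog an [allele_catalog()].
#' @param freqs optional named list (locus -> named probability vector).
#' @return A [transplant_pair()]. Uses the session RNG stream; seed with
#'   `set.seed()` (or draw inside `with_seed`-style wrappers) for
#'   reproducibility.
#' @export
random_pair <- function(catalog, freqs = NULL) {
  draw <- function() {
    g <- lapply(LOCI, function(locus) {
      av <- catalog$entries$allele[catalog$entries$locus == locus]
      pr <- if (!is.null(freqs)) freqs[[locus]][av] else NULL
      unique(sample(av, 2L, replace = TRUE, prob = pr))
    })
    genotype(setNames(g, LOCI))
  }
  transplant_pair(draw(), draw())
}

#' Exhaustive brute-force reference scorer
#'
#' Independent oracle for [score_pair()]: enumerates every window of every
#' mismatched donor allele with scalar calls, checks self status by
#' substring scan against each recipient sequence, scores each surviving
#' (peptide, presenter) tuple with a scalar [predict_binding()] call, and
#' counts unique tuples per locus and pooled.
#'
#' @param pair a [transplant_pair()].
#' @param catalog an [allele_catalog()].
#' @param mode a [predictor_mode()].
#' @param predictor a [surrogate_predictor()].
#' @param k peptide length (default the predictor's k).
#' @param max_tuples guard on the number of materialized tuples
#'   (default 1e5); exceeding it is an error.
#' @return A `pirche_score`, comparable field-by-field with [score_pair()].
#' @export
brute_force_score <- function(pair, catalog, mode, predictor,
                              k = predictor$k, max_tuples = 1e5) {
  mm <- find_mismatches(pair)
  recip_seqs <- unname(catalog_sequence(catalog, unique(unlist(pair$recipient))))
  presenters <- unique(pair$presenters)
  per_locus <- setNames(integer(length(LOCI)), LOCI)
  pooled <- character(0)
  n_tuples <- 0
  for (locus in intersect(LOCI, names(mm))) {
    locus_tuples <- character(0)
    for (allele in mm[[locus]]) {
      seq <- catalog_sequence(catalog, allele)[[1]]
      peps <- enumerate_peptides(seq, k = k, source_allele = allele)
      for (r in seq_len(nrow(peps))) {
        pep <- peps$peptide[r]
        self <- FALSE
        for (s in recip_seqs) {
          if (grepl(pep, s, fixed = TRUE)) { self <- TRUE; break }
        }
        if (self) next
        for (p in presenters) {
          n_tuples <- n_tuples + 1
          if (n_tuples > max_tuples) {
            stop("brute-force tuple budget exceeded (", max_tuples, ")",
                 call. = FALSE)
          }
          b <- predict_binding(predictor, pep, p)
          if (mode_passes(mode, b$affinity_nM, b$percentile_rank)) {
            locus_tuples <- c(locus_tuples, paste(pep, p, sep = "|"))
          }
        }
      }
    }
    locus_tuples <- unique(locus_tuples)
    per_locus[locus] <- length(locus_tuples)
    pooled <- c(pooled, locus_tuples)
  }
  new_pirche_score(per_locus, length(unique(pooled)), mode)
}
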