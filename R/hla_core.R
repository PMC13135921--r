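## hla_core: allele catalog I/O, genotypes, transplant pairs, mismatch calling.
##
## Mismatch comparison is at the allele-name level exactly as typed; the
## catalog maps each supplied name to one representative mature-chain protein
## sequence. Imputation of low-resolution typing to high-resolution alleles
## and serologic split/broad equivalence are out of scope. All sequence
## window coordinates in the package are 0-based, half-open.

#' Construct an HLA allele catalog
#'
#' An allele catalog maps allele names (e.g. `"A*01"`, `"DRB1*03"`) to a
#' locus and a mature-chain amino-acid sequence. It is the substrate for
#' peptide enumeration: donor-derived peptides are read off these sequences
#' and the recipient's sequences define the self-peptide reference set.
#'
#' @param alleles character vector of allele names of the form `"LOCUS*NAME"`.
#' @param sequences character vector of amino-acid sequences (standard
#'   20-letter alphabet; `X` and other ambiguity codes are rejected).
#' @return An object of class `allele_catalog`: a list with a data frame
#'   `entries` (columns `allele`, `locus`, `sequence`).
#' @export
allele_catalog <- function(alleles, sequences) {
  alleles <- as.character(alleles)
  sequences <- as.character(sequences)
  stopifnot(length(alleles) == length(sequences))
  if (anyDuplicated(alleles)) {
    stop("duplicate allele name(s): ",
         paste(unique(alleles[duplicated(alleles)]), collapse = ", "),
         call. = FALSE)
  }
  bad_header <- !grepl("^[A-Z0-9]+\\*", alleles)
  if (any(bad_header)) {
    stop("malformed allele name(s), expected 'LOCUS*NAME': ",
         paste(alleles[bad_header], collapse = ", "), call. = FALSE)
  }
  locus <- allele_locus(alleles)
  unknown <- !(locus %in% LOCI)
  if (any(unknown)) {
    stop("allele name(s) with unsupported locus prefix: ",
         paste(alleles[unknown], collapse = ", "),
         "; supported loci: ", paste(LOCI, collapse = ", "), call. = FALSE)
  }
  for (i in seq_along(sequences)) {
    if (!is_aa_string(sequences[i])) {
      stop(sprintf("sequence for allele '%s' contains non-standard amino-acid characters",
                   alleles[i]), call. = FALSE)
    }
  }
  structure(
    list(entries = data.frame(allele = alleles, locus = locus,
                              sequence = sequences, stringsAsFactors = FALSE)),
    class = "allele_catalog"
  )
}

#' @export
print.allele_catalog <- function(x, ...) {
  tab <- table(x$entries$locus)
  cat("<allele_catalog> ", nrow(x$entries), " alleles (",
      paste(sprintf("%s: %d", names(tab), as.integer(tab)), collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

#' Read an HLA allele catalog from FASTA
#'
#' Headers must be of the form `LOCUS*NAME`; anything after the first
#' whitespace is treated as a description and dropped. Sequences must use
#' the standard 20-letter amino-acid alphabet.
#'
#' @param path path to a FASTA file.
#' @return An [allele_catalog()].
#' @export
read_allele_catalog <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0L) {
    warning("empty FASTA file: ", path, call. = FALSE)
    return(allele_catalog(character(0), character(0)))
  }
  nm <- sub("\\s.*$", "", names(seqs))
  allele_catalog(nm, as.character(seqs))
}

#' Write an allele catalog to FASTA
#'
#' Inverse of [read_allele_catalog()]; sequences round-trip byte-identically.
#'
#' @param catalog an [allele_catalog()].
#' @param path output FASTA path.
#' @export
write_allele_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "allele_catalog"))
  x <- Biostrings::AAStringSet(catalog$entries$sequence)
  names(x) <- catalog$entries$allele
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @noRd
catalog_sequence <- function(catalog, alleles) {
  idx <- match(alleles, catalog$entries$allele)
  if (anyNA(idx)) {
    stop("allele(s) not in catalog: ",
         paste(alleles[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  setNames(catalog$entries$sequence[idx], alleles)
}

#' Construct a genotype
#'
#' A genotype stores 1 or 2 allele names per locus; a single allele denotes
#' homozygosity.
#'
#' @param ... named character vectors, one per locus (names among
#'   A, B, C, DRB1, DQB1).
#' @return An object of class `genotype`: a named list of character vectors.
#' @export
genotype <- function(...) {
  g <- list(...)
  if (length(g) == 1L && is.list(g[[1]]) && is.null(names(g))) g <- g[[1]]
  if (is.null(names(g)) || any(!nzchar(names(g)))) {
    stop("genotype loci must be named", call. = FALSE)
  }
  unknown <- setdiff(names(g), LOCI)
  if (length(unknown)) {
    stop("unknown locus: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  g <- lapply(g, function(a) sort(unique(as.character(a))))
  n <- lengths(g)
  if (any(n < 1L | n > 2L)) {
    stop("each locus must carry 1 or 2 distinct allele names", call. = FALSE)
  }
  structure(g, class = "genotype")
}

#' Construct a donor-recipient transplant pair
#'
#' The recipient's DRB1 alleles double as the class II presenters through
#' which donor-derived peptides are displayed (a homozygous presenter
#' contributes a single presenter name).
#'
#' @param donor,recipient [genotype()] objects.
#' @return An object of class `transplant_pair` with fields `donor`,
#'   `recipient`, and `presenters` (the recipient's DRB1 alleles).
#' @export
transplant_pair <- function(donor, recipient) {
  stopifnot(inherits(donor, "genotype"), inherits(recipient, "genotype"))
  if (is.null(recipient$DRB1)) {
    stop("recipient genotype must include DRB1 (the presenter locus)",
         call. = FALSE)
  }
  structure(list(donor = donor, recipient = recipient,
                 presenters = recipient$DRB1),
            class = "transplant_pair")
}

#' Determine per-locus donor-recipient HLA mismatches
#'
#' A mismatch is a donor allele name absent from the recipient's typing at
#' the same locus; a homozygous donor allele appears at most once.
#'
#' @param pair a [transplant_pair()].
#' @return A named list (class `mismatch_set`), one character vector of
#'   mismatched donor allele names per donor-typed locus.
#' @export
find_mismatches <- function(pair) {
  stopifnot(inherits(pair, "transplant_pair"))
  missing <- setdiff(names(pair$donor), names(pair$recipient))
  if (length(missing)) {
    stop("recipient typing missing for donor-typed locus: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  mm <- lapply(names(pair$donor), function(locus) {
    setdiff(pair$donor[[locus]], pair$recipient[[locus]])
  })
  structure(setNames(mm, names(pair$donor)), class = "mismatch_set")
}

#' Read donor/recipient genotype tables from CSV
#'
#' Expected columns: `patient_id`, `role` (`donor` or `recipient`), then one
#' column per locus with `/`-separated allele names. Each patient must have
#' exactly one donor and one recipient row.
#'
#' @param path CSV path.
#' @param catalog optional [allele_catalog()] used to validate that every
#'   allele name is resolvable.
#' @return Named list of [transplant_pair()] objects (names = patient ids).
#' @export
read_genotype_table <- function(path, catalog = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("patient_id", "role")
  if (!all(need %in% names(df))) {
    stop("genotype table must have columns patient_id and role", call. = FALSE)
  }
  loci <- intersect(LOCI, names(df))
  if (!length(loci)) stop("genotype table has no locus columns", call. = FALSE)
  parse_row <- function(row) {
    g <- lapply(loci, function(l) strsplit(row[[l]], "/", fixed = TRUE)[[1]])
    genotype(setNames(g, loci))
  }
  ids <- unique(df$patient_id)
  pairs <- lapply(ids, function(id) {
    sub <- df[df$patient_id == id, , drop = FALSE]
    d <- sub[sub$role == "donor", , drop = FALSE]
    r <- sub[sub$role == "recipient", , drop = FALSE]
    if (nrow(d) != 1L || nrow(r) != 1L) {
      stop("patient '", id, "' must have exactly one donor and one recipient row",
           call. = FALSE)
    }
    transplant_pair(parse_row(d[1, ]), parse_row(r[1, ]))
  })
  names(pairs) <- ids
  if (!is.null(catalog)) {
    for (p in pairs) {
      catalog_sequence(catalog, unique(unlist(c(p$donor, p$recipient))))
    }
  }
  pairs
}

#' Write transplant pairs to a genotype CSV
#'
#' @param pairs named list of [transplant_pair()] objects.
#' @param path output CSV path.
#' @export
write_genotype_table <- function(pairs, path) {
  ids <- names(pairs)
  if (is.null(ids)) ids <- as.character(seq_along(pairs))
  loci <- LOCI[LOCI %in% unique(unlist(lapply(pairs, function(p) names(p$donor))))]
  row_of <- function(id, role, g) {
    c(patient_id = id, role = role,
      setNames(vapply(loci, function(l) paste(g[[l]], collapse = "/"), ""), loci))
  }
  rows <- do.call(rbind, unlist(lapply(seq_along(pairs), function(i) {
    list(row_of(ids[i], "donor", pairs[[i]]$donor),
         row_of(ids[i], "recipient", pairs[[i]]$recipient))
  }), recursive = FALSE))
  write.csv(as.data.frame(rows, stringsAsFactors = FALSE), path, row.names = FALSE)
  invisible(path)
}
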