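#' Load the 5-component physico-chemical descriptor table
#'
#' Each standard amino acid is represented by five dimensionless descriptor
#' scores, the leading components of an eigen-decomposition of a large
#' collection of published physico-chemical property scales.  The bundled
#' table was derived once from the numeric amino-acid indices shipped with
#' the AAindex collection (531 complete scales, standardised, first five
#' principal components, rescaled to `[-1, 1]`) and is frozen as plain text
#' so that encodings are reproducible.  Users may substitute their own table
#' (e.g. the descriptors of a specific publication) via `path`.
#'
#' @param path Path to a TSV with columns `aa, d1..d5`, one row per standard
#'   amino acid.  `NULL` (default) loads the bundled table.
#' @param x_fallback Numeric length-5 vector used for `X`/unknown residues.
#' @return A matrix with 21 rows (`A` .. `V` in PSSM column order, plus `X`)
#'   and 5 columns, of class `loc_physchem`.
#' @export
load_physchem <- function(path = NULL, x_fallback = rep(0, 5)) {
  path <- path %||% .extdata("aa_descriptors5.tsv")
  if (!file.exists(path)) .stopf("physico-chemical table '%s' does not exist", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(tab) < 6) .stopf("physico-chemical table must have an 'aa' column plus 5 descriptors")
  missing <- setdiff(AA_ORDER, tab[[1]])
  if (length(missing) > 0)
    .stopf("physico-chemical table is missing amino acid(s): %s",
           paste(missing, collapse = ", "))
  m <- as.matrix(tab[, 2:6])
  rownames(m) <- tab[[1]]
  m <- m[AA_ORDER, , drop = FALSE]
  stopifnot(length(x_fallback) == 5)
  m <- rbind(m, X = as.numeric(x_fallback))
  storage.mode(m) <- "double"
  class(m) <- c("loc_physchem", class(m))
  m
}

#' Read a PSI-BLAST ASCII PSSM profile
#'
#' Parses the plain-text position-specific scoring matrix emitted by
#' PSI-BLAST (`-out_ascii_pssm`).  Only the first 20 columns (log-odds
#' scores, PSSM header order `A R N D C Q E G H I L K M F P S T W Y V`) are
#' used.
#'
#' @param path Path to the ASCII PSSM file.
#' @param sequence The protein sequence the profile belongs to; its length
#'   must equal the profile's row count and its residues must match the
#'   profile's residue column.
#' @return A numeric `L x 20` matrix of class `loc_profile` with attribute
#'   `source_flag = "pssm"`.
#' @export
read_pssm <- function(path, sequence) {
  if (!file.exists(path)) .stopf("PSSM file '%s' does not exist", path)
  lines <- readLines(path, warn = FALSE)
  res <- split_residues(sequence)

  rows <- list()
  row_letters <- character(0)
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!grepl("^[0-9]+\\s+[A-Za-z]\\s+-?[0-9]", ln)) next
    parts <- strsplit(ln, "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(parts[3:min(length(parts), 22)]))
    if (length(vals) < 20 || anyNA(vals))
      .stopf("unparsable PSSM line %d: fewer than 20 numeric scores", i)
    rows[[length(rows) + 1L]] <- vals[1:20]
    row_letters <- c(row_letters, toupper(parts[2]))
  }
  if (length(rows) == 0) .stopf("no PSSM rows found in '%s'", path)
  if (length(rows) != length(res))
    .stopf("PSSM has %d rows but sequence has %d residues", length(rows), length(res))
  m <- do.call(rbind, rows)
  colnames(m) <- AA_ORDER
  attr(m, "source_flag") <- "pssm"
  attr(m, "residues") <- row_letters
  class(m) <- c("loc_profile", class(m))
  m
}

#' BLOSUM62 fallback profile
#'
#' When no PSSM is available the per-residue profile is taken directly from
#' the BLOSUM62 substitution matrix: row *i* of the profile is the BLOSUM62
#' score row of residue *i*.  Unknown letters receive the `X` row.
#'
#' @param sequence Amino-acid string.
#' @param matrix_path Optional path to an NCBI-format substitution matrix;
#'   defaults to the bundled BLOSUM62.
#' @return A numeric `L x 20` matrix of class `loc_profile` with attribute
#'   `source_flag = "blosum62"`.
#' @export
blosum_fallback <- function(sequence, matrix_path = NULL) {
  blo <- load_blosum(matrix_path)
  res <- split_residues(sequence)
  m <- blo[res, AA_ORDER, drop = FALSE]
  rownames(m) <- NULL
  attr(m, "source_flag") <- "blosum62"
  class(m) <- c("loc_profile", class(m))
  m
}

#' Load an NCBI-format substitution matrix
#'
#' @param path Path to the matrix text file; `NULL` loads bundled BLOSUM62.
#' @return A square numeric matrix with residue letters as dimnames.
#' @export
load_blosum <- local({
  cache <- new.env(parent = emptyenv())
  function(path = NULL) {
    path <- path %||% .extdata("BLOSUM62.txt")
    key <- normalizePath(path)
    if (!is.null(cache[[key]])) return(cache[[key]])
    m <- as.matrix(utils::read.table(path, comment.char = "#", check.names = FALSE))
    storage.mode(m) <- "double"
    cache[[key]] <- m
    m
  }
})

#' Build a protein record
#'
#' A light tabular-friendly constructor; records are ordinarily carried in a
#' tibble with list-columns `organelles` / `suborganelles` (see
#' [simulate_proteome()]), and this helper builds one row of it.
#'
#' @param accession Identifier.
#' @param sequence Amino-acid string (non-empty).
#' @param organelles Character vector of organelle labels.
#' @param suborganelles Character vector of suborganelle labels.
#' @param cleavage_site Optional 1-based index of the last residue of the
#'   targeting peptide; must be `>= 1` and `< nchar(sequence)`.
#' @param created_year Optional integer year of database entry creation.
#' @param evidence_experimental Logical; experimentally verified annotation.
#' @param ... Further metadata columns (e.g. `existence_level`, `fragment`).
#' @return A one-row tibble.
#' @export
protein_record <- function(accession, sequence,
                           organelles = character(0),
                           suborganelles = character(0),
                           cleavage_site = NA_integer_,
                           created_year = NA_integer_,
                           evidence_experimental = TRUE, ...) {
  if (!nzchar(sequence)) .stopf("sequence of '%s' is empty", accession)
  if (!is.na(cleavage_site) &&
      (cleavage_site < 1 || cleavage_site >= nchar(sequence)))
    .stopf("cleavage_site of '%s' must be in [1, length-1]", accession)
  tibble(accession = accession, sequence = sequence,
         organelles = list(organelles), suborganelles = list(suborganelles),
         cleavage_site = as.integer(cleavage_site),
         created_year = as.integer(created_year),
         evidence_experimental = evidence_experimental, ...)
}

#' Encode a protein into the fixed-length network input
#'
#' Each residue becomes a 25-dimension vector: 5 physico-chemical descriptor
#' scores followed by the 20 profile scores (PSSM or BLOSUM62 fallback).
#' The encoding length is fixed (default 1000): longer proteins keep the
#' first `encode_len/2` N-terminal and last `encode_len/2` C-terminal
#' residues; shorter proteins are zero-padded at the C-terminal end and the
#' padding is masked out of all downstream computation.
#'
#' @param sequence Amino-acid string (or a one-row record tibble, in which
#'   case its `sequence` column is used).
#' @param profile `loc_profile` with one row per raw residue.
#' @param physchem `loc_physchem` table from [load_physchem()].
#' @param normalize_profile Squash profile scores through the logistic
#'   function `1/(1+exp(-x))` before insertion (default `TRUE`); raw
#'   log-odds pass through when `FALSE`.
#' @param encode_len Even encoding length, default 1000.
#' @return A `loc_encoded` object: list with `features` (`encode_len x 25`),
#'   `mask` (0/1 vector), `origin_map` (1-based raw index per encoded row,
#'   `NA` for padding), `length_raw`, `accession`.
#' @export
encode <- function(sequence, profile, physchem = load_physchem(),
                   normalize_profile = TRUE, encode_len = 1000) {
  accession <- NA_character_
  if (is.data.frame(sequence)) {
    accession <- sequence$accession[1]
    sequence <- sequence$sequence[1]
  }
  if (encode_len %% 2 != 0) .stopf("encode_len must be even")
  res <- split_residues(sequence)
  L <- length(res)
  if (nrow(profile) != L)
    .stopf("profile has %d rows but sequence has %d residues", nrow(profile), L)

  prof <- unclass(profile)[, 1:20, drop = FALSE]
  attributes(prof)[c("source_flag", "residues", "class")] <- NULL
  if (normalize_profile) prof <- 1 / (1 + exp(-prof))

  half <- encode_len %/% 2L
  if (L > encode_len) {
    origin <- c(seq_len(half), seq.int(L - half + 1L, L))
  } else {
    origin <- seq_len(L)
  }
  n_valid <- length(origin)

  feats <- matrix(0, nrow = encode_len, ncol = 25)
  feats[seq_len(n_valid), 1:5] <- unclass(physchem)[res[origin], , drop = FALSE]
  feats[seq_len(n_valid), 6:25] <- prof[origin, , drop = FALSE]
  mask <- c(rep(1, n_valid), rep(0, encode_len - n_valid))
  origin_map <- c(origin, rep(NA_integer_, encode_len - n_valid))

  structure(list(features = feats, mask = mask, origin_map = origin_map,
                 length_raw = L, accession = accession,
                 residues = res,
                 profile_source = attr(profile, "source_flag") %||% "unknown"),
            class = "loc_encoded")
}

#' @export
print.loc_encoded <- function(x, ...) {
  cat(sprintf("<loc_encoded> %s: %d residues, %d encoded, %d padded (%s profile)\n",
              x$accession %||% "?", x$length_raw, sum(x$mask),
              length(x$mask) - sum(x$mask), x$profile_source))
  invisible(x)
}

#' Encode a table of records with the BLOSUM62 fallback
#'
#' Convenience vectorised encoder used by the simulator-driven pipeline,
#' where no PSSM profiles exist.
#'
#' @param records Record tibble (see [protein_record()]).
#' @param physchem Descriptor table.
#' @param encode_len Encoding length.
#' @param normalize_profile Logistic squashing flag, see [encode()].
#' @return A list of `loc_encoded`, named by accession.
#' @export
encode_records <- function(records, physchem = load_physchem(),
                           encode_len = 1000, normalize_profile = TRUE) {
  out <- lapply(seq_len(nrow(records)), function(i) {
    encode(records[i, ], blosum_fallback(records$sequence[i]),
           physchem = physchem, normalize_profile = normalize_profile,
           encode_len = encode_len)
  })
  names(out) <- records$accession
  out
}
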