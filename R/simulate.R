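#' Specify a planted sorting-signal motif
#'
#' @param placement `"Nterm"`, `"Cterm"` or `"internal"`.
#' @param generator Function `(rng_ready) -> character` returning one motif
#'   instance (the package RNG is already seeded when it is called).
#' @param cleavage Logical; record the motif end as the cleavage site
#'   (N-terminal targeting peptides).
#' @return A `loc_motif` list.
#' @export
motif_spec <- function(placement = c("Nterm", "Cterm", "internal"),
                       generator, cleavage = placement == "Nterm") {
  placement <- match.arg(placement)
  structure(list(placement = placement, generator = generator,
                 cleavage = cleavage),
            class = "loc_motif")
}

# Built-in motif library: a signal-peptide-like N-terminal stretch
# (initial Met, one basic residue, 8-12 hydrophobics), a C-terminal
# peroxisomal-style tripeptide, and an internal basic (K/R) stretch.
default_motifs <- function() {
  hydrophobic <- c("L", "A", "V", "I", "F")
  list(
    signal_nterm = motif_spec("Nterm", function() {
      paste0("M", sample(c("K", "R"), 1),
             paste(sample(hydrophobic, sample(8:12, 1), replace = TRUE),
                   collapse = ""))
    }),
    tripeptide_cterm = motif_spec("Cterm", function() {
      sample(c("SKL", "SRL", "SRM"), 1)
    }, cleavage = FALSE),
    basic_internal = motif_spec("internal", function() {
      paste(sample(c("K", "R"), sample(4:5, 1), replace = TRUE),
            collapse = "")
    }, cleavage = FALSE)
  )
}

# Approximate background amino-acid frequencies of a eukaryotic proteome.
default_background_freqs <- function() {
  f <- c(A = 8.3, R = 5.5, N = 4.1, D = 5.5, C = 1.4, Q = 3.9, E = 6.7,
         G = 7.1, H = 2.3, I = 5.9, L = 9.7, K = 5.8, M = 2.4, F = 3.9,
         P = 4.7, S = 6.7, T = 5.4, W = 1.1, Y = 2.9, V = 6.9)
  f / sum(f)
}

#' Simulation configuration for a planted-motif proteome
#'
#' The default models the desk-scale study system: three signal classes
#' (an N-terminal signal-peptide-like stretch with a recorded cleavage
#' site, a C-terminal tripeptide, an internal basic stretch) plus a
#' background class with no motif, 150 proteins per class, lengths uniform
#' on 80-300, and a 10 percent multi-label fraction.
#'
#' @param classes Tibble with columns `name, organelle, suborganelle,
#'   motif` (list-column of `loc_motif` or `NULL` for background).
#' @param n_per_class Proteins per class (default 150).
#' @param len_range Length range, uniform draw (default `c(80, 300)`).
#' @param multi_label_fraction Fraction of proteins carrying a second
#'   class's label and motif (default 0.1).
#' @param lv1_only_fraction Fraction of records stripped to organelle-only
#'   annotation, so the alternating training scheme has level-1 samples
#'   (default 0.25).
#' @param background_freqs Named length-20 letter distribution.
#' @param seed Integer seed.
#' @return A `loc_simconfig` list.
#' @export
sim_config <- function(classes = NULL, n_per_class = 150,
                       len_range = c(80, 300), multi_label_fraction = 0.1,
                       lv1_only_fraction = 0.25,
                       background_freqs = default_background_freqs(),
                       seed = 1L) {
  if (is.null(classes)) {
    motifs <- default_motifs()
    classes <- tibble(
      name = c("secretory", "peroxisomal", "nuclear", "cytosolic"),
      organelle = c("extracellular", "peroxisome", "nucleus", "cytoplasm"),
      suborganelle = c("secreted", "peroxisome_matrix", "nucleoplasm",
                       "cytosol"),
      motif = list(motifs$signal_nterm, motifs$tripeptide_cterm,
                   motifs$basic_internal, NULL))
  }
  stopifnot(multi_label_fraction >= 0, multi_label_fraction < 1,
            lv1_only_fraction >= 0, lv1_only_fraction < 1,
            len_range[1] >= 20, len_range[2] >= len_range[1])
  structure(list(classes = classes, n_per_class = as.integer(n_per_class),
                 len_range = as.integer(len_range),
                 multi_label_fraction = multi_label_fraction,
                 lv1_only_fraction = lv1_only_fraction,
                 background_freqs = background_freqs,
                 seed = as.integer(seed)),
            class = "loc_simconfig")
}

#' The label hierarchy of the default simulated proteome
#'
#' One occupied suborganelle cell per simulated organelle; a compact
#' layout for desk-scale training.
#'
#' @param cfg A `loc_simconfig`.
#' @return A `loc_hierarchy`.
#' @export
sim_hierarchy <- function(cfg = sim_config()) {
  cl <- cfg$classes
  spec <- split(cl$suborganelle, factor(cl$organelle, levels = unique(cl$organelle)))
  hierarchy(spec)
}

#' Simulate a planted-motif proteome
#'
#' Every protein starts with methionine and draws its remaining residues
#' from the background letter distribution; signal-class proteins carry
#' exactly one instance of their class motif at the prescribed placement
#' (N-terminal motifs start at residue 1 and record their end as the
#' cleavage site; C-terminal motifs end at the last residue; internal
#' motifs are placed uniformly inside the interior).  Multi-label proteins
#' carry the motifs and labels of both assigned classes.  Output is
#' byte-stable given the seed.
#'
#' @param cfg A `loc_simconfig`.
#' @return List with `records` (record tibble, incl. curation metadata
#'   columns), `motifs` (ground-truth tibble `accession, class, start,
#'   end`), `hierarchy`.
#' @export
simulate_proteome <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  cl <- cfg$classes
  n_cls <- nrow(cl)
  letters20 <- names(cfg$background_freqs)
  draw_bg <- function(n) sample(letters20, n, replace = TRUE,
                                prob = cfg$background_freqs)

  recs <- list(); truths <- list()
  acc_i <- 0L
  for (ci in seq_len(n_cls)) {
    for (k in seq_len(cfg$n_per_class)) {
      acc_i <- acc_i + 1L
      accession <- sprintf("SIM%05d", acc_i)
      L <- sample(seq(cfg$len_range[1], cfg$len_range[2]), 1)
      res <- c("M", draw_bg(L - 1L))
      class_ids <- ci
      if (cfg$multi_label_fraction > 0 &&
          runif(1) < cfg$multi_label_fraction && n_cls > 1) {
        other <- sample(setdiff(seq_len(n_cls), ci), 1)
        class_ids <- c(ci, other)
      }
      cleavage <- NA_integer_
      for (cid in class_ids) {
        ms <- cl$motif[[cid]]
        if (is.null(ms)) next
        m <- strsplit(ms$generator(), "", fixed = TRUE)[[1]]
        lm <- length(m)
        if (L < lm + 30)
          .stopf("length range too short for motif of class '%s'",
                 cl$name[cid])
        start <- switch(ms$placement,
          Nterm = 1L,
          Cterm = L - lm + 1L,
          internal = sample(seq(15L, L - lm - 14L), 1))
        res[start:(start + lm - 1L)] <- m
        if (ms$placement == "Nterm") res[1] <- "M"
        if (ms$cleavage) cleavage <- start + lm - 1L
        truths[[length(truths) + 1L]] <- tibble(
          accession = accession, class = cl$name[cid],
          start = as.integer(start), end = as.integer(start + lm - 1L))
      }
      orgs <- unique(cl$organelle[class_ids])
      subs <- unique(cl$suborganelle[class_ids])
      recs[[acc_i]] <- protein_record(
        accession, paste(res, collapse = ""),
        organelles = orgs, suborganelles = subs,
        cleavage_site = cleavage,
        created_year = sample(2000:2023, 1),
        evidence_experimental = TRUE,
        existence_level = "protein", fragment = FALSE,
        encoded_in = "nuclear",
        sim_class = paste(cl$name[class_ids], collapse = "+"))
    }
  }
  records <- dplyr::bind_rows(recs)
  if (cfg$lv1_only_fraction > 0) {
    drop <- runif(nrow(records)) < cfg$lv1_only_fraction
    records$suborganelles[drop] <- list(character(0))
    records$lv2_annotated <- !drop
  } else {
    records$lv2_annotated <- TRUE
  }
  list(records = records,
       motifs = if (length(truths)) dplyr::bind_rows(truths)
                else tibble(accession = character(0), class = character(0),
                            start = integer(0), end = integer(0)),
       hierarchy = sim_hierarchy(cfg))
}

#' Simulate a train-vs-test alignment hit table with known outcomes
#'
#' Emits BLAST-tabular-style hit rows with controlled identity, coverage
#' and E-value: planted near-duplicate pairs produce hits that the
#' redundancy filter must remove, `weak` pairs produce hits that fail one
#' gate each, and unrelated pairs produce no row.
#'
#' @param train,test Record tibbles.
#' @param duplicates Tibble `train_id, test_id` of planted redundant pairs.
#' @param weak Optional tibble `train_id, test_id, reason` where `reason`
#'   is `"coverage"` (identity high, coverage low) or `"weak_both"`
#'   (identity and E-value both below the cuts).
#' @return List with `hits` (tibble in [read_blast_hits()] layout) and
#'   `expected_removed` (character).
#' @export
simulate_hits <- function(train, test, duplicates,
                          weak = NULL) {
  len_of <- function(ids, recs) nchar(recs$sequence[match(ids, recs$accession)])
  mk <- function(q, s, pident, cov, evalue) {
    qlen <- len_of(q, train); slen <- len_of(s, test)
    tibble(qseqid = q, sseqid = s, pident = pident,
           length = as.integer(ceiling(cov * pmin(qlen, slen))),
           mismatch = 0L, gapopen = 0L, qstart = 1L,
           qend = as.integer(ceiling(cov * pmin(qlen, slen))),
           sstart = 1L, send = as.integer(ceiling(cov * pmin(qlen, slen))),
           evalue = evalue, bitscore = 100,
           qlen = qlen, slen = slen)
  }
  hits <- list()
  if (nrow(duplicates) > 0)
    hits[[1]] <- mk(duplicates$train_id, duplicates$test_id,
                    pident = 100, cov = 1.0, evalue = 1e-50)
  if (!is.null(weak) && nrow(weak) > 0) {
    wc <- weak[weak$reason == "coverage", ]
    if (nrow(wc) > 0)
      hits[[length(hits) + 1L]] <- mk(wc$train_id, wc$test_id,
                                      pident = 90, cov = 0.5, evalue = 1e-30)
    wb <- weak[weak$reason == "weak_both", ]
    if (nrow(wb) > 0)
      hits[[length(hits) + 1L]] <- mk(wb$train_id, wb$test_id,
                                      pident = 25, cov = 0.95, evalue = 1.0)
  }
  hits <- if (length(hits)) dplyr::bind_rows(hits)
          else read_blast_hits_empty()
  list(hits = hits, expected_removed = unique(duplicates$train_id))
}

read_blast_hits_empty <- function() {
  tibble(qseqid = character(0), sseqid = character(0), pident = numeric(0),
         length = integer(0), mismatch = integer(0), gapopen = integer(0),
         qstart = integer(0), qend = integer(0), sstart = integer(0),
         send = integer(0), evalue = numeric(0), bitscore = numeric(0),
         qlen = integer(0), slen = integer(0))
}

#' Write records as FASTA plus an annotation TSV
#'
#' Byte-stable given the same records: fixed column order, fixed number
#' formatting, Unix newlines.
#'
#' @param records Record tibble.
#' @param fasta_path,tsv_path Output paths.
#' @return Invisibly, a list of the two paths.
#' @export
write_records <- function(records, fasta_path, tsv_path) {
  con <- file(fasta_path, "wb")
  for (i in seq_len(nrow(records)))
    writeLines(c(paste0(">", records$accession[i]),
                 records$sequence[i]), con, sep = "\n")
  close(con)
  flat <- tibble(
    accession = records$accession,
    sequence = records$sequence,
    organelles = vapply(records$organelles, paste, "", collapse = ";"),
    suborganelles = vapply(records$suborganelles, paste, "", collapse = ";"),
    cleavage_site = records$cleavage_site,
    created_year = records$created_year,
    evidence_experimental = records$evidence_experimental)
  con <- file(tsv_path, "wb")
  writeLines(paste(names(flat), collapse = "\t"), con, sep = "\n")
  writeLines(do.call(paste, c(lapply(flat, function(x) {
    x <- as.character(x); x[is.na(x)] <- "NA"; x
  }), sep = "\t")), con, sep = "\n")
  close(con)
  invisible(list(fasta = fasta_path, tsv = tsv_path))
}

#' Read an annotation TSV (+ optional FASTA) back into records
#'
#' @param tsv_path Annotation TSV written by [write_records()] (or the
#'   documented schema: `accession, sequence?, organelles, suborganelles,
#'   cleavage_site, created_year, evidence_experimental`, labels
#'   semicolon-separated).
#' @param fasta_path Optional FASTA supplying the sequences.
#' @return Record tibble.
#' @export
read_records <- function(tsv_path, fasta_path = NULL) {
  tab <- utils::read.table(tsv_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, na.strings = "NA")
  if (!is.null(fasta_path)) {
    seqs <- read_fasta(fasta_path)
    tab$sequence <- as.character(seqs[tab$accession])
  }
  split_labels <- function(x) {
    lapply(x, function(s) {
      if (is.na(s) || !nzchar(s)) character(0)
      else strsplit(s, ";", fixed = TRUE)[[1]]
    })
  }
  tibble(accession = tab$accession, sequence = tab$sequence,
         organelles = split_labels(tab$organelles),
         suborganelles = split_labels(tab$suborganelles),
         cleavage_site = as.integer(tab$cleavage_site),
         created_year = as.integer(tab$created_year),
         evidence_experimental = as.logical(tab$evidence_experimental))
}

#' Read a (possibly line-wrapped, multi-record) FASTA file
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}
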