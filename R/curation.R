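#' Annotation-quality record filters
#'
#' Applies the dataset-construction rules: protein/transcript-level
#' existence evidence, no fragments, no organelle-encoded proteins, an
#' initial methionine, and a minimum length of 40 residues (a 40-residue
#' protein passes; the rule is strict-less-than).  A record is kept iff it
#' passes every enabled rule; the tally reports per-rule rejection counts
#' in application order (outcome is order-independent, tallies are not).
#'
#' @param records Record tibble.  Rules require metadata columns:
#'   `existence_level` (character) for `"existence"`, `fragment` (logical)
#'   for `"fragment"`, `encoded_in` (character; `"mitochondrion"`,
#'   `"chloroplast"`, `"plastid"` are rejected) for `"organelle_encoded"`.
#' @param rules Character vector of enabled rules, any of `"existence"`,
#'   `"fragment"`, `"organelle_encoded"`, `"met_start"`, `"min_length"`.
#' @param min_length Minimum sequence length (default 40).
#' @return List with `kept` (record tibble) and `tally` (tibble
#'   `rule, rejected`).
#' @export
filter_records <- function(records,
                           rules = c("existence", "fragment",
                                     "organelle_encoded", "met_start",
                                     "min_length"),
                           min_length = 40) {
  known <- c("existence", "fragment", "organelle_encoded", "met_start",
             "min_length")
  bad <- setdiff(rules, known)
  if (length(bad) > 0) .stopf("unknown filter rule '%s'", bad[1])
  need <- c(existence = "existence_level", fragment = "fragment",
            organelle_encoded = "encoded_in")
  for (r in intersect(rules, names(need)))
    if (!need[[r]] %in% names(records))
      .stopf("rule '%s' requires a '%s' column", r, need[[r]])

  passes <- function(rule) {
    switch(rule,
      existence = tolower(records$existence_level) %in%
        c("protein", "transcript", "protein level", "transcript level"),
      fragment = !records$fragment,
      organelle_encoded = !(tolower(records$encoded_in %||% "nuclear") %in%
        c("mitochondrion", "chloroplast", "plastid")),
      met_start = toupper(substr(records$sequence, 1, 1)) == "M",
      min_length = nchar(records$sequence) >= min_length)
  }
  keep <- rep(TRUE, nrow(records))
  tally <- list()
  for (r in rules) {
    ok <- passes(r)
    tally[[length(tally) + 1L]] <- tibble(rule = r, rejected = sum(keep & !ok))
    keep <- keep & ok
  }
  list(kept = records[keep, ], tally = dplyr::bind_rows(tally))
}

#' Retain sufficiently populated suborganelle classes
#'
#' Suborganelle classes with more than `min_count` member proteins are
#' retained (the rule is strict: a class with exactly `min_count` members
#' is dropped).  Labels of dropped classes are removed from the records;
#' organelle labels are kept, so a protein whose only suborganelle label is
#' dropped becomes a level-1-only record.
#'
#' @param records Record tibble.
#' @param h A `loc_hierarchy` (labels outside it are ignored in counting).
#' @param min_count Strict lower bound on class size (default 50).
#' @return List with `records` (labels pruned), `retained` (character),
#'   `counts` (tibble `suborganelle, n, retained`).
#' @export
select_classes <- function(records, h, min_count = 50) {
  labs <- unlist(records$suborganelles, use.names = FALSE)
  counts <- table(factor(labs, levels = h$cells$suborganelle))
  keep <- names(counts)[counts > min_count]
  records$organelles <- lapply(seq_len(nrow(records)), function(i) {
    subs <- records$suborganelles[[i]]
    extra <- h$cells$organelle[h$cells$suborganelle %in% subs]
    union(records$organelles[[i]], extra)
  })
  records$suborganelles <- lapply(records$suborganelles, intersect, y = keep)
  list(records = records, retained = keep,
       counts = tibble(suborganelle = names(counts), n = as.integer(counts),
                       retained = names(counts) %in% keep))
}

#' Year-aware stratified train/test split
#'
#' For each class, `ceiling(fraction * n)` test samples are selected:
#' records created after `year_cutoff` first, topped up (or thinned) by a
#' seeded random draw.  The class of a record is its suborganelle label set
#' when present, its organelle labels otherwise.  A record selected as test
#' for any of its classes is test globally.  Classes with fewer than two
#' members go wholly to train with a warning.
#'
#' @param records Record tibble with `created_year`.
#' @param fraction Test fraction (default 0.15).
#' @param year_cutoff Records with `created_year > year_cutoff` are
#'   preferred for the test set (default 2018).
#' @param seed Integer seed.
#' @return A `loc_split` tibble `accession, split, provenance` with a
#'   `class_fractions` attribute.
#' @export
split_test <- function(records, fraction = 0.15, year_cutoff = 2018,
                       seed = 1L) {
  classes_of <- function(i) {
    s <- records$suborganelles[[i]]
    if (length(s) > 0) s else records$organelles[[i]]
  }
  cls <- lapply(seq_len(nrow(records)), classes_of)
  all_classes <- sort(unique(unlist(cls)))
  test <- rep(FALSE, nrow(records))
  provenance <- rep(NA_character_, nrow(records))
  set.seed(seed)
  for (cl in all_classes) {
    members <- which(vapply(cls, function(x) cl %in% x, TRUE))
    n <- length(members)
    if (n < 2) {
      .warnf("class '%s' has %d member(s); kept entirely in train", cl, n)
      next
    }
    n_test <- ceiling(fraction * n)
    yr <- records$created_year[members]
    post <- members[!is.na(yr) & yr > year_cutoff]
    chosen <- if (length(post) >= n_test) {
      post[sample.int(length(post), n_test)]
    } else {
      rest <- setdiff(members, post)
      c(post, rest[sample.int(length(rest), n_test - length(post))])
    }
    test[chosen] <- TRUE
    provenance[chosen] <- ifelse(chosen %in% post, "year", "random")
  }
  plan <- tibble(accession = records$accession,
                 split = ifelse(test, "test", "train"),
                 provenance = provenance)
  frac <- vapply(all_classes, function(cl) {
    members <- which(vapply(cls, function(x) cl %in% x, TRUE))
    mean(test[members])
  }, numeric(1))
  structure(plan, class = c("loc_split", class(plan)),
            class_fractions = setNames(frac, all_classes))
}

#' Read BLAST tabular (outfmt 6) alignment hits
#'
#' @param path Path to the tabular file.
#' @param columns Column order; the default is the standard 12-column
#'   outfmt-6 layout extended by the `qlen slen` columns the redundancy
#'   filter needs.
#' @return Tibble of hits with at least `qseqid, sseqid, pident, length,
#'   evalue, qlen, slen`.
#' @export
read_blast_hits <- function(path,
                            columns = c("qseqid", "sseqid", "pident",
                                        "length", "mismatch", "gapopen",
                                        "qstart", "qend", "sstart", "send",
                                        "evalue", "bitscore", "qlen",
                                        "slen")) {
  tab <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(tab) != length(columns))
    .stopf("expected %d columns, found %d", length(columns), ncol(tab))
  names(tab) <- columns
  as_tibble(tab)
}

#' Alignment-based train/test redundancy filter
#'
#' A training protein is removed when some alignment against a test
#' protein covers more than `coverage_cut` of the shorter of the two full
#' sequences and shows either sequence identity above `identity_cut`
#' percent or an E-value at or below `evalue_cut`.
#'
#' @param train_ids,test_ids Character vectors of accessions.
#' @param hits Hit tibble (see [read_blast_hits()]); `qseqid` are training
#'   queries, `sseqid` test subjects.
#' @param identity_cut Percent identity cut (default 40).
#' @param evalue_cut E-value cut (default 1e-5).
#' @param coverage_cut Alignment-coverage cut over the shorter sequence
#'   (default 0.8, strict greater-than).
#' @param identity_strict Use strict `>` on identity (default); `FALSE`
#'   switches to `>=`.
#' @return List with `kept` (train ids), `removed`, and `log` (tibble of
#'   triggering hits).
#' @export
redundancy_filter <- function(train_ids, test_ids, hits,
                              identity_cut = 40, evalue_cut = 1e-5,
                              coverage_cut = 0.8, identity_strict = TRUE) {
  unknown <- setdiff(unique(c(hits$qseqid, hits$sseqid)),
                     c(train_ids, test_ids))
  if (length(unknown) > 0)
    .stopf("hit references unknown id '%s'", unknown[1])
  h <- hits[hits$qseqid %in% train_ids & hits$sseqid %in% test_ids, ]
  coverage <- h$length / pmin(h$qlen, h$slen)
  ident_hit <- if (identity_strict) h$pident > identity_cut
               else h$pident >= identity_cut
  trigger <- coverage > coverage_cut & (ident_hit | h$evalue <= evalue_cut)
  log <- h[trigger, ]
  log$coverage <- coverage[trigger]
  removed <- unique(log$qseqid)
  list(kept = setdiff(train_ids, removed), removed = removed,
       log = as_tibble(log))
}
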