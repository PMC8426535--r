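curation_records <- function() {
  dplyr::bind_rows(
    protein_record("ok40", paste0("M", strrep("A", 39)),
                   existence_level = "protein", fragment = FALSE,
                   encoded_in = "nuclear"),
    protein_record("short39", paste0("M", strrep("A", 38)),
                   existence_level = "protein", fragment = FALSE,
                   encoded_in = "nuclear"),
    protein_record("nomet", strrep("A", 50),
                   existence_level = "protein", fragment = FALSE,
                   encoded_in = "nuclear"),
    protein_record("fragment", paste0("M", strrep("A", 60)),
                   existence_level = "protein", fragment = TRUE,
                   encoded_in = "nuclear"),
    protein_record("homology", paste0("M", strrep("A", 60)),
                   existence_level = "homology", fragment = FALSE,
                   encoded_in = "nuclear"),
    protein_record("mtDNA", paste0("M", strrep("A", 60)),
                   existence_level = "protein", fragment = FALSE,
                   encoded_in = "mitochondrion"))
}

test_that("annotation filters apply the documented rules", {
  recs <- curation_records()
  out <- filter_records(recs)
  expect_equal(out$kept$accession, "ok40")
  tally <- setNames(out$tally$rejected, out$tally$rule)
  expect_equal(unname(tally["min_length"]), 1)
  expect_equal(unname(tally["met_start"]), 1)
  expect_equal(unname(tally["fragment"]), 1)
  expect_equal(unname(tally["existence"]), 1)
  expect_equal(unname(tally["organelle_encoded"]), 1)

  expect_error(filter_records(recs[, setdiff(names(recs), "fragment")]),
               "fragment")
  expect_error(filter_records(recs, rules = "bogus"), "bogus")
})

test_that("filter outcome is order-independent; tallies are not", {
  recs <- curation_records()
  rules <- c("existence", "fragment", "organelle_encoded", "met_start",
             "min_length")
  base <- filter_records(recs, rules)$kept$accession
  set.seed(6)
  for (i in 1:5) {
    perm <- sample(rules)
    expect_equal(filter_records(recs, perm)$kept$accession, base)
  }
})

test_that("class selection keeps strictly-more-than-min classes", {
  h <- toy_hierarchy()
  mk <- function(n, sub, org, prefix) {
    dplyr::bind_rows(lapply(seq_len(n), function(i)
      protein_record(paste0(prefix, i), random_sequence(45),
                     organelles = org, suborganelles = sub)))
  }
  set.seed(2)
  recs <- dplyr::bind_rows(mk(51, "a1", "alpha", "p"),
                           mk(50, "b1", "beta", "q"),
                           mk(3, "g1", "gamma", "r"))
  out <- select_classes(recs, h, min_count = 50)
  expect_equal(out$retained, "a1")
  cc <- out$counts
  expect_true(cc$retained[cc$suborganelle == "a1"])
  expect_false(cc$retained[cc$suborganelle == "b1"])

  dropped <- out$records[out$records$accession == "q1", ]
  expect_equal(length(dropped$suborganelles[[1]]), 0L)
  expect_equal(dropped$organelles[[1]], "beta")   # becomes lv1-only

  # tally-vs-loop oracle on random assignments
  set.seed(14)
  labs <- sample(h$cells$suborganelle, 200, replace = TRUE)
  recs2 <- dplyr::bind_rows(lapply(seq_along(labs), function(i)
    protein_record(paste0("z", i), random_sequence(45),
                   suborganelles = labs[i])))
  out2 <- select_classes(recs2, h, min_count = 40)
  loop <- table(labs)
  for (cl in names(loop))
    expect_equal(cl %in% out2$retained, unname(loop[cl]) > 40)
})

test_that("test split prefers recent records and rounds up per class", {
  set.seed(9)
  recs <- dplyr::bind_rows(lapply(1:20, function(i)
    protein_record(paste0("s", i), random_sequence(45),
                   organelles = "alpha", suborganelles = "a1",
                   created_year = if (i <= 2) 2020L else 2010L)))
  plan <- suppressWarnings(split_test(recs, seed = 3))
  test_ids <- plan$accession[plan$split == "test"]
  expect_equal(length(test_ids), 3L)                  # ceil(0.15 * 20)
  expect_true(all(c("s1", "s2") %in% test_ids))       # post-cutoff first
  expect_equal(sum(plan$provenance[plan$split == "test"] == "year"), 2)

  # plenty of post-cutoff records: test drawn from the post pool only
  recs2 <- recs
  recs2$created_year <- rep(c(2020L, 2010L), c(8, 12))
  plan2 <- split_test(recs2, seed = 3)
  post <- recs2$accession[recs2$created_year > 2018]
  expect_true(all(plan2$accession[plan2$split == "test"] %in% post))

  expect_identical(as.data.frame(split_test(recs, seed = 3)),
                   as.data.frame(split_test(recs, seed = 3)))

  tinycl <- protein_record("solo", random_sequence(45),
                           organelles = "beta", suborganelles = "b1")
  expect_warning(split_test(dplyr::bind_rows(recs, tinycl), seed = 1),
                 "kept entirely in train")
})

test_that("BLAST tabular reader enforces the column contract", {
  hits <- attnloc:::read_blast_hits_empty()
  hits <- dplyr::bind_rows(hits, tibble::tibble(
    qseqid = "t1", sseqid = "v1", pident = 45, length = 85L,
    mismatch = 0L, gapopen = 0L, qstart = 1L, qend = 85L, sstart = 1L,
    send = 85L, evalue = 1.0, bitscore = 100, qlen = 100L, slen = 110L))
  path <- tempfile(fileext = ".tsv")
  utils::write.table(hits, path, sep = "\t", col.names = FALSE,
                     row.names = FALSE, quote = FALSE)
  back <- read_blast_hits(path)
  expect_equal(back$pident, 45)
  expect_equal(back$qlen, 100L)
  bad <- tempfile(fileext = ".tsv")
  utils::write.table(hits[, 1:12], bad, sep = "\t", col.names = FALSE,
                     row.names = FALSE, quote = FALSE)
  expect_error(read_blast_hits(bad), "14 columns")
})

test_that("redundancy filter implements the coverage-gated disjunction", {
  mk_hit <- function(pident, evalue, cov, qlen = 100L, slen = 120L) {
    tibble::tibble(qseqid = "t1", sseqid = "v1", pident = pident,
                   length = as.integer(cov * min(qlen, slen)),
                   mismatch = 0L, gapopen = 0L, qstart = 1L, qend = 1L,
                   sstart = 1L, send = 1L, evalue = evalue, bitscore = 1,
                   qlen = qlen, slen = slen)
  }
  run <- function(hit) redundancy_filter("t1", "v1", hit)

  expect_equal(run(mk_hit(45, 1.0, 0.85))$removed, "t1")     # identity branch
  expect_equal(run(mk_hit(35, 1e-6, 0.90))$removed, "t1")    # E-value branch
  expect_equal(run(mk_hit(50, 1e-20, 0.50))$removed,
               character(0))                                  # coverage gate
  expect_equal(run(mk_hit(40, 1.0, 0.9))$removed, character(0))  # strict >
  expect_equal(redundancy_filter("t1", "v1", mk_hit(40, 1, 0.9),
                                 identity_strict = FALSE)$removed, "t1")
  expect_error(redundancy_filter("t1", "v1",
                                 mk_hit(45, 1, 0.9) |>
                                   dplyr::mutate(qseqid = "ghost")),
               "ghost")
})

test_that("redundancy filter equals brute force on random hit tables", {
  set.seed(77)
  train_ids <- paste0("t", 1:30)
  test_ids <- paste0("v", 1:10)
  for (rep in 1:20) {
    n <- 60
    hits <- tibble::tibble(
      qseqid = sample(train_ids, n, replace = TRUE),
      sseqid = sample(test_ids, n, replace = TRUE),
      pident = runif(n, 20, 100),
      qlen = sample(80:300, n, replace = TRUE),
      slen = sample(80:300, n, replace = TRUE),
      evalue = 10^runif(n, -30, 1), bitscore = 1,
      mismatch = 0L, gapopen = 0L, qstart = 1L, qend = 1L,
      sstart = 1L, send = 1L)
    hits$length <- as.integer(runif(n, 0.3, 1) * pmin(hits$qlen, hits$slen))
    got <- redundancy_filter(train_ids, test_ids, hits)
    brute <- character(0)
    for (i in seq_len(n)) {
      cov <- hits$length[i] / min(hits$qlen[i], hits$slen[i])
      if (cov > 0.8 && (hits$pident[i] > 40 || hits$evalue[i] <= 1e-5))
        brute <- c(brute, hits$qseqid[i])
    }
    expect_setequal(got$removed, unique(brute))
    expect_setequal(got$kept, setdiff(train_ids, brute))
  }
})
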