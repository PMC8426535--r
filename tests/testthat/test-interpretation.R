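fake_profile <- function(weights, accession = "p") {
  structure(tibble::tibble(position = seq_along(weights),
                           residue = rep("A", length(weights)),
                           weight = weights),
            class = c("loc_attention", "tbl_df", "tbl", "data.frame"),
            accession = accession, gap = NULL)
}

test_that("per-protein attention is head-averaged and sums to one", {
  m <- toy_model()
  for (len in c(12, 35)) {
    s <- random_sequence(len, seed = len)
    enc <- encode(s, blosum_fallback(s), encode_len = m$cfg$encode_len)
    p <- protein_attention(m, enc)
    expect_equal(nrow(p), len)
    expect_equal(p$position, seq_len(len))
    expect_true(all(p$weight >= 0))
    expect_equal(sum(p$weight), 1, tolerance = 1e-6)
  }
})

test_that("long proteins keep raw coordinates with a recorded gap", {
  m <- toy_model()
  s <- random_sequence(55, seed = 5)
  enc <- encode(s, blosum_fallback(s), encode_len = 40)
  p <- protein_attention(m, enc)
  expect_equal(p$position, c(1:20, 36:55))
  expect_equal(attr(p, "gap"), c(from = 21L, to = 35L))
})

test_that("terminus profiles average per aligned position", {
  p1 <- fake_profile(c(0.2, rep(0.8 / 59, 59)))
  p2 <- fake_profile(c(0.4, rep(0.6 / 59, 59)))
  seqs <- c(strrep("A", 60), strrep("K", 60))
  gp <- terminus_profile(list(p1, p2), seqs, end = "N", span = 50)
  expect_equal(gp$mean_attention[1], 0.3)
  expect_equal(nrow(gp), 50L)
  freq <- attr(gp, "freq")
  expect_equal(unname(freq[1, "A"]), 0.5)
  expect_equal(unname(freq[1, "K"]), 0.5)

  # identical profiles: group equals the individual profile
  gp1 <- terminus_profile(list(p1, p1), c(seqs[1], seqs[1]), "N", 50)
  expect_equal(gp1$mean_attention, p1$weight[1:50])

  # C-terminal anchoring counts from the right
  gpc <- terminus_profile(list(p1, p2), seqs, end = "C", span = 10)
  expect_equal(gpc$position, -9:0)
  expect_equal(gpc$mean_attention[10],
               mean(c(p1$weight[60], p2$weight[60])))
})

test_that("group profile equals a brute-force mean over proteins", {
  set.seed(55)
  profs <- list(); seqs <- character(0)
  for (i in 1:50) {
    L <- sample(50:80, 1)
    w <- runif(L); w <- w / sum(w)
    profs[[i]] <- fake_profile(w)
    seqs[i] <- random_sequence(L)
  }
  gp <- terminus_profile(profs, seqs, end = "N", span = 50)
  brute <- sapply(1:50, function(pos)
    mean(sapply(profs, function(p) p$weight[pos])))
  expect_equal(gp$mean_attention, brute)
})

test_that("short proteins are skipped from terminus alignment", {
  p <- fake_profile(rep(0.1, 10))
  expect_warning(
    gp <- terminus_profile(list(p, fake_profile(rep(0.02, 50))),
                           c(strrep("A", 10), strrep("A", 50)),
                           end = "N", span = 50),
    "skipped")
  expect_equal(gp$n[1], 1L)
  expect_error(terminus_profile(list(p), strrep("A", 10), "N", 50), "span")
})

test_that("cleavage alignment anchors position zero at the site", {
  recs <- dplyr::bind_rows(
    protein_record("c1", random_sequence(60, seed = 1), cleavage_site = 25))
  prof <- list(fake_profile(seq(60, 1) / sum(1:60)))
  gp <- cleavage_profile(prof, recs, before = 10, after = 10)
  expect_equal(nrow(gp), 21L)
  expect_equal(gp$position, -10:10)
  expect_equal(gp$mean_attention[gp$position == 0],
               prof[[1]]$weight[25])
  expect_true(all(gp$n == 1))

  recs2 <- dplyr::bind_rows(
    protein_record("c2", random_sequence(60, seed = 2), cleavage_site = 5))
  gp2 <- cleavage_profile(list(fake_profile(rep(1 / 60, 60))), recs2,
                          before = 10, after = 10)
  expect_true(all(is.na(gp2$mean_attention[gp2$position < -4])))
  expect_true(all(gp2$n[gp2$position < -4] == 0))

  recs3 <- dplyr::bind_rows(recs, protein_record("nosite",
                                                 random_sequence(50, seed = 3)))
  expect_warning(cleavage_profile(list(prof[[1]], fake_profile(rep(0.02, 50))),
                                  recs3, 5, 5), "without cleavage site")
})

test_that("shuffling preserves composition and is seed-reproducible", {
  recs <- toy_records(2, seed = 8)
  s1 <- shuffle_records(recs, seed = 4)
  s2 <- shuffle_records(recs, seed = 4)
  s3 <- shuffle_records(recs, seed = 5)
  expect_identical(s1$sequence, s2$sequence)
  expect_false(all(s1$sequence == s3$sequence))
  for (i in seq_len(nrow(recs))) {
    expect_equal(sort(strsplit(s1$sequence[i], "")[[1]]),
                 sort(strsplit(recs$sequence[i], "")[[1]]))
    expect_false(identical(s1$sequence[i], recs$sequence[i]) &&
                   nchar(recs$sequence[i]) > 20)
  }
})

test_that("attention ratio divides matched positions and flags floors", {
  p <- fake_profile(rep(0.02, 50))
  gp <- terminus_profile(list(p), strrep("A", 50), "N", span = 20)
  same <- attention_ratio(gp, gp)
  expect_true(all(same$ratio == 1))

  gp2 <- gp
  gp2$mean_attention <- gp$mean_attention / 2
  expect_equal(attention_ratio(gp, gp2)$ratio, rep(2, 20))

  gp3 <- gp
  gp3$mean_attention[5] <- 0
  r <- attention_ratio(gp, gp3)
  expect_true(is.na(r$ratio[5]))
  expect_false(r$defined[5])

  gpc <- terminus_profile(list(p), strrep("A", 50), "C", span = 20)
  expect_error(attention_ratio(gp, gpc), "anchor")
})

test_that("segment extraction windows, clips, merges and spaces with X", {
  w <- rep(0.001, 30); w[15] <- 0.5
  seg <- extract_segments(fake_profile(w), random_sequence(30, seed = 6),
                          top_k = 1, flank = 10)
  expect_equal(seg$segments$start, 5)
  expect_equal(seg$segments$end, 25)
  expect_equal(nchar(seg$segments$sequence), 21)

  w2 <- rep(0.001, 30); w2[3] <- 0.5
  seg2 <- extract_segments(fake_profile(w2), random_sequence(30, seed = 7),
                           top_k = 1, flank = 10)
  expect_equal(c(seg2$segments$start, seg2$segments$end), c(1, 13))

  w3 <- rep(0.001, 40); w3[15] <- 0.5; w3[20] <- 0.4
  seg3 <- extract_segments(fake_profile(w3), random_sequence(40, seed = 8),
                           top_k = 2, flank = 10)
  expect_equal(nrow(seg3$segments), 1L)
  expect_equal(c(seg3$segments$start, seg3$segments$end), c(5, 30))

  # ties break toward the smaller index
  w4 <- rep(0.001, 60); w4[c(10, 40)] <- 0.5
  seg4 <- extract_segments(fake_profile(w4), random_sequence(60, seed = 9),
                           top_k = 1, flank = 3)
  expect_equal(seg4$segments$start, 7)
})

test_that("segment strings reconstruct substrings of the input", {
  set.seed(10)
  for (i in 1:10) {
    L <- sample(40:120, 1)
    s <- random_sequence(L)
    w <- runif(L)
    seg <- extract_segments(fake_profile(w / sum(w)), s)
    parts <- strsplit(gsub("X+", " ", seg$string), " ")[[1]]
    parts <- parts[nzchar(parts)]
    for (p in parts) {
      # X spacers may merge with sequence letters; anchor via coordinates
      expect_true(any(vapply(seq_len(nrow(seg$segments)), function(j)
        grepl(p, substr(s, seg$segments$start[j], seg$segments$end[j]),
              fixed = TRUE), TRUE)))
    }
    for (j in seq_len(nrow(seg$segments)))
      expect_equal(seg$segments$sequence[j],
                   substr(s, seg$segments$start[j], seg$segments$end[j]))
  }
})

test_that("motif-discovery export writes FASTA plus parameter sidecar", {
  out <- tempfile(fileext = ".fasta")
  write_motif_input(c(p1 = "MKLVXXXAAA", p2 = "KKKK"), out)
  fa <- read_fasta(out)
  expect_equal(unname(fa["p1"]), "MKLVXXXAAA")
  side <- readLines(paste0(out, ".params.txt"))
  expect_true(any(grepl("initial_columns: 15", side)))
  expect_true(any(grepl("maximum_columns: 30", side)))
})
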