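#' Per-residue attention profile for one protein
#'
#' The attention matrix is averaged over heads (each head's weights sum to
#' one over the valid positions, so the average does too), averaged over
#' ensemble sub-models, and mapped back to raw sequence coordinates via the
#' encoding's origin map.  For proteins longer than the encoding length the
#' unencoded middle has no attention; the profile keeps raw coordinates and
#' records the gap.
#'
#' @param ens A `loc_ensemble` or `loc_model`.
#' @param enc A `loc_encoded` input.
#' @return A `loc_attention`: tibble `position, residue, weight` with
#'   attributes `accession`, `gap` (`c(from, to)` raw positions not
#'   encoded, or `NULL`).
#' @export
protein_attention <- function(ens, enc) {
  sc <- ensemble_predict(ens, enc)
  n <- sc$n_valid
  w <- colMeans(sc$A[, seq_len(n), drop = FALSE])
  pos <- enc$origin_map[seq_len(n)]
  out <- tibble(position = pos, residue = enc$residues[pos], weight = w)
  gap <- NULL
  if (enc$length_raw > length(enc$mask)) {
    half <- length(enc$mask) %/% 2L
    gap <- c(from = half + 1L, to = enc$length_raw - half)
  }
  structure(out, class = c("loc_attention", class(out)),
            accession = enc$accession, gap = gap)
}

profile_weights <- function(p) {
  w <- p$weight
  names(w) <- p$position
  w
}

#' Group attention profile aligned at a terminus
#'
#' Aligns the first (N) or last (C) `span` residues of each protein and
#' averages the attention per aligned position; also tabulates per-position
#' residue frequencies (sequence-logo input).  Proteins shorter than the
#' span are skipped with a warning.
#'
#' @param profiles List of `loc_attention` profiles.
#' @param sequences Character vector of the matching raw sequences.
#' @param end `"N"` or `"C"`.
#' @param span Number of aligned positions (default 50).
#' @return A `loc_group_profile`: tibble `position, mean_attention, n` with
#'   attributes `anchor`, `span`, `freq` (span x 20 matrix).
#' @export
terminus_profile <- function(profiles, sequences, end = c("N", "C"), span = 50) {
  end <- match.arg(end)
  stopifnot(length(profiles) == length(sequences))
  keep <- nchar(sequences) >= span
  if (!any(keep)) .stopf("no protein has length >= span (%d)", span)
  if (any(!keep))
    .warnf("%d protein(s) shorter than span %d skipped", sum(!keep), span)
  profiles <- profiles[keep]; sequences <- sequences[keep]

  acc <- matrix(0, nrow = span, ncol = length(profiles))
  freq <- matrix(0, nrow = span, ncol = 20, dimnames = list(NULL, AA_ORDER))
  for (i in seq_along(profiles)) {
    p <- profiles[[i]]
    L <- nchar(sequences[i])
    raw_pos <- if (end == "N") seq_len(span) else seq.int(L - span + 1L, L)
    w <- profile_weights(p)[as.character(raw_pos)]
    w[is.na(w)] <- 0   # unencoded middle of very long proteins
    acc[, i] <- w
    res <- split_residues(sequences[i])[raw_pos]
    for (j in seq_len(span))
      if (res[j] %in% AA_ORDER) freq[j, res[j]] <- freq[j, res[j]] + 1
  }
  out <- tibble(position = if (end == "N") seq_len(span)
                           else seq.int(-span + 1L, 0L),
                mean_attention = rowMeans(acc),
                n = length(profiles))
  structure(out, class = c("loc_group_profile", class(out)),
            anchor = paste0(end, "-terminus"), span = span,
            freq = freq / length(profiles))
}

#' Group attention profile aligned at the cleavage site
#'
#' Position 0 is anchored at the annotated last residue of the targeting
#' peptide; positions `-before .. after` are averaged where available and
#' counted as missing outside a protein's range.
#'
#' @param profiles List of `loc_attention`.
#' @param records Record tibble with a `cleavage_site` column.
#' @param before,after Residues kept before/after the site (defaults
#'   100/50; secreted proteins are conventionally shown with 50/100).
#' @return A `loc_group_profile` tibble `position, mean_attention, n` with
#'   attribute `anchor = "cleavage"`; `n` is the per-position count of
#'   contributing proteins.
#' @export
cleavage_profile <- function(profiles, records, before = 100, after = 50) {
  stopifnot(length(profiles) == nrow(records))
  has_site <- !is.na(records$cleavage_site)
  if (any(!has_site)) {
    .warnf("%d record(s) without cleavage site skipped", sum(!has_site))
    profiles <- profiles[has_site]; records <- records[has_site, ]
  }
  if (length(profiles) == 0) .stopf("no record carries a cleavage site")
  offsets <- seq.int(-before, after)
  sums <- numeric(length(offsets)); counts <- integer(length(offsets))
  for (i in seq_along(profiles)) {
    site <- records$cleavage_site[i]
    L <- nchar(records$sequence[i])
    w <- profile_weights(profiles[[i]])
    raw <- site + offsets
    ok <- raw >= 1 & raw <= L
    wv <- w[as.character(raw[ok])]
    present <- !is.na(wv)
    sums[ok][present] <- sums[ok][present] + wv[present]
    counts[ok][present] <- counts[ok][present] + 1L
  }
  out <- tibble(position = offsets,
                mean_attention = ifelse(counts > 0, sums / counts, NA_real_),
                n = counts)
  structure(out, class = c("loc_group_profile", class(out)),
            anchor = "cleavage", span = c(before = before, after = after),
            freq = NULL)
}

#' Shuffled-sequence attention control
#'
#' Residue order of every protein is permuted uniformly (seeded), the
#' shuffled proteins are re-encoded and re-run through the model, and the
#' resulting profiles are aggregated as a terminus-aligned group profile.
#' Comparing real and shuffled profiles separates genuine sorting signals
#' from the terminus bias of the architecture.  Several independent
#' shuffle replicates can be averaged to reduce the sampling noise of the
#' control.
#'
#' @param ens A `loc_ensemble` or `loc_model`.
#' @param records Record tibble (typically one localization class).
#' @param seed Integer seed for the permutations.
#' @param end,span Terminus alignment, see [terminus_profile()].
#' @param replicates Number of independent shuffle replicates averaged
#'   into the control profile (default 3).
#' @return List with `profile` (the averaged shuffled
#'   `loc_group_profile`), `shuffled` (the first replicate's record
#'   tibble), and `replicates`.
#' @export
shuffle_control <- function(ens, records, seed = 1L, end = "N", span = 50,
                            replicates = 3) {
  cfg <- ens$cfg
  profs <- vector("list", replicates)
  shuffled1 <- NULL
  for (r in seq_len(replicates)) {
    shuffled <- shuffle_records(records, seed = seed + (r - 1L) * 7919L)
    if (r == 1) shuffled1 <- shuffled
    enc <- encode_records(shuffled, encode_len = cfg$encode_len)
    profiles <- lapply(enc, function(e) protein_attention(ens, e))
    profs[[r]] <- terminus_profile(profiles, shuffled$sequence,
                                   end = end, span = span)
  }
  avg <- profs[[1]]
  if (replicates > 1) {
    avg$mean_attention <- rowMeans(vapply(profs, function(p) p$mean_attention,
                                          numeric(nrow(avg))))
    attr(avg, "freq") <- Reduce(`+`, lapply(profs, attr, "freq")) / replicates
  }
  list(profile = avg, shuffled = shuffled1, replicates = replicates)
}

#' Seeded residue shuffling of record sequences
#' @param records Record tibble.
#' @param seed Integer seed.
#' @return The records with permuted sequences (composition preserved).
#' @export
shuffle_records <- function(records, seed = 1L) {
  set.seed(seed)
  records$sequence <- vapply(records$sequence, function(s) {
    r <- strsplit(s, "", fixed = TRUE)[[1]]
    paste(r[sample.int(length(r))], collapse = "")
  }, character(1), USE.NAMES = FALSE)
  records
}

#' Attention ratio of a real over a shuffled group profile
#'
#' Element-wise ratio of mean attention, real over shuffled control, per
#' aligned position.  Positions where the shuffled mean falls below the
#' floor `eps` are flagged (`defined = FALSE`) instead of divided.
#'
#' @param real,shuffled `loc_group_profile`s with matching anchors and
#'   spans.
#' @param eps Division floor (default `1e-6`).
#' @return Tibble `position, ratio, defined`.
#' @export
attention_ratio <- function(real, shuffled, eps = 1e-6) {
  if (!identical(attr(real, "anchor"), attr(shuffled, "anchor")) ||
      !identical(attr(real, "span"), attr(shuffled, "span")))
    .stopf("profiles have mismatching anchors or spans")
  ok <- !is.na(shuffled$mean_attention) & shuffled$mean_attention >= eps
  tibble(position = real$position,
         ratio = ifelse(ok, real$mean_attention / shuffled$mean_attention,
                        NA_real_),
         defined = ok)
}

#' Extract high-attention segments for motif discovery
#'
#' The `top_k` residues by attention (ties break toward the smaller index)
#' are each expanded by `flank` residues on both sides (clipped at the
#' sequence ends); overlapping windows are merged.  Segments are joined by
#' an `X` spacer of length `flank` into one string suitable for
#' variable-length gapped motif discovery.
#'
#' @param profile A `loc_attention`.
#' @param sequence The raw sequence.
#' @param top_k Number of peak residues (default 5).
#' @param flank Window half-width (default 10).
#' @return List with `segments` (tibble `start, end, sequence`, 1-based
#'   inclusive) and `string` (concatenated, X-spaced).
#' @export
extract_segments <- function(profile, sequence, top_k = 5, flank = 10) {
  L <- nchar(sequence)
  if (L < 1) .stopf("sequence is empty")
  w <- profile$weight
  pos <- profile$position
  ord <- order(-w, pos)              # ties -> smaller index first
  peaks <- sort(pos[ord[seq_len(min(top_k, length(ord)))]])
  ivs <- cbind(pmax(peaks - flank, 1L), pmin(peaks + flank, L))
  merged <- list()
  cur <- ivs[1, ]
  for (i in seq_len(nrow(ivs))[-1]) {
    if (ivs[i, 1] <= cur[2]) cur[2] <- max(cur[2], ivs[i, 2])
    else { merged[[length(merged) + 1L]] <- cur; cur <- ivs[i, ] }
  }
  merged[[length(merged) + 1L]] <- cur
  seg <- dplyr::bind_rows(lapply(merged, function(iv)
    tibble(start = iv[1], end = iv[2],
           sequence = substr(sequence, iv[1], iv[2]))))
  list(segments = seg,
       string = paste(seg$sequence,
                      collapse = strrep("X", flank)))
}

#' Write motif-discovery input for high-attention segments
#'
#' Writes the extracted segments of a protein group as FASTA plus a sidecar
#' parameter file with the recommended gapped-motif-search settings
#' (initial aligned columns 15, maximum aligned columns 30).  The motif
#' search itself (GLAM2/MEME) is external.
#'
#' @param segment_strings Named character vector (accession -> segment
#'   string from [extract_segments()]).
#' @param path Output FASTA path; the sidecar is `<path>.params.txt`.
#' @return Invisibly, the FASTA path.
#' @export
write_motif_input <- function(segment_strings, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  for (nm in names(segment_strings))
    writeLines(c(paste0(">", nm), segment_strings[[nm]]), con, sep = "\n")
  writeLines(c("tool: GLAM2 (MEME suite)",
               "initial_columns: 15",
               "maximum_columns: 30",
               "other parameters: defaults"),
             paste0(path, ".params.txt"))
  invisible(path)
}
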